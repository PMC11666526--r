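# Cohort data model: somatic variants, foci, patients, and the per-sample
# mutation-landscape summaries (class tallies, SNV spectra, TMB, gene ranks).

#' Recognised somatic variant classifications
#'
#' The coding-consequence vocabulary used throughout the package, following
#' MAF `Variant_Classification` semantics. `SILENT` variants are parsed and
#' retained but excluded from all burden and peptide computations.
#'
#' @format Character vector of nine class labels.
#' @export
VARIANT_CLASSES <- c(
  "MISSENSE", "NONSENSE", "NONSTOP", "SPLICE_SITE",
  "FRAMESHIFT_DEL", "FRAMESHIFT_INS", "IN_FRAME_DEL", "IN_FRAME_INS",
  "SILENT"
)

#' Six pyrimidine-reference SNV substitution classes
#' @format Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
SNV_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# MAF Variant_Classification -> internal class
.maf_class_map <- c(
  Missense_Mutation = "MISSENSE",
  Nonsense_Mutation = "NONSENSE",
  Nonstop_Mutation  = "NONSTOP",
  Splice_Site       = "SPLICE_SITE",
  Frame_Shift_Del   = "FRAMESHIFT_DEL",
  Frame_Shift_Ins   = "FRAMESHIFT_INS",
  In_Frame_Del      = "IN_FRAME_DEL",
  In_Frame_Ins      = "IN_FRAME_INS",
  Silent            = "SILENT"
)

.hla_pattern <- "^HLA-[ABC]\\*\\d{2}:\\d{2}$"

.variant_ids <- function(v) {
  paste(v$sample_id, v$gene, v$chrom, v$pos, v$ref_allele, v$alt_allele,
        sep = ":")
}

.infer_variant_type <- function(ref, alt) {
  ifelse(ref != "-" & alt != "-" & nchar(ref) == 1 & nchar(alt) == 1, "SNV",
         ifelse(nchar(gsub("-", "", alt)) > nchar(gsub("-", "", ref)),
                "INS", "DEL"))
}

.check_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  req <- c("sample_id", "gene", "variant_class", "variant_type")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    stop("variant table lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(variants$variant_class), VARIANT_CLASSES)
  if (length(bad) > 0) {
    stop("unknown variant_class value(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(VARIANT_CLASSES, collapse = ", "))
  }
  invisible(variants)
}

#' Read somatic variant calls
#'
#' Parses per-focus somatic calls from either a MAF (tab-separated, one row
#' per variant) or a single-sample annotated VCF whose INFO field carries
#' `GENE`, `CLASS` and `PCHANGE` keys. Coordinates are 1-based inclusive;
#' VCF records are used as-is since both conventions agree for SNVs and the
#' package's indel fixtures carry transcript-relative positions.
#'
#' Silent rows are retained (flagged by `variant_class == "SILENT"`) so that
#' downstream tallies can exclude them explicitly.
#'
#' @param path Path to the variant file.
#' @param dialect `"MAF"` (default) or `"ANNOTATED_VCF"`.
#' @return A list with `variants` (data frame: `variant_id`, `sample_id`,
#'   `gene`, `chrom`, `pos`, `ref_allele`, `alt_allele`, `variant_class`,
#'   `variant_type`, `protein_change`) and `foci` (data frame: `sample_id`,
#'   `patient_id`; the patient id is the sample id stripped of a trailing
#'   `.k` focus suffix).
#' @export
read_maf <- function(path, dialect = c("MAF", "ANNOTATED_VCF")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "MAF") {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE, check.names = FALSE)
    req <- c("Hugo_Symbol", "Chromosome", "Start_Position",
             "Reference_Allele", "Tumor_Seq_Allele2",
             "Variant_Classification", "Variant_Type",
             "Tumor_Sample_Barcode")
    miss <- setdiff(req, names(tab))
    if (length(miss) > 0) {
      stop("MAF is missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    known <- tab$Variant_Classification %in% names(.maf_class_map)
    if (!all(known)) {
      stop("unknown Variant_Classification value(s): ",
           paste(unique(tab$Variant_Classification[!known]), collapse = ", "),
           "; accepted: ", paste(names(.maf_class_map), collapse = ", "))
    }
    vt <- toupper(tab$Variant_Type)
    vt[vt == "SNP"] <- "SNV"
    variants <- data.frame(
      sample_id      = as.character(tab$Tumor_Sample_Barcode),
      gene           = as.character(tab$Hugo_Symbol),
      chrom          = as.character(tab$Chromosome),
      pos            = as.integer(tab$Start_Position),
      ref_allele     = as.character(tab$Reference_Allele),
      alt_allele     = as.character(tab$Tumor_Seq_Allele2),
      variant_class  = unname(.maf_class_map[tab$Variant_Classification]),
      variant_type   = vt,
      protein_change = if ("HGVSp_Short" %in% names(tab))
        as.character(tab$HGVSp_Short) else rep(NA_character_, nrow(tab)),
      stringsAsFactors = FALSE
    )
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    info_field <- function(key) {
      if (nrow(fix) == 0) return(character(0))
      out <- unname(vcfR::extract.info(vcf, element = key))
      rep_len(as.character(out), nrow(fix))
    }
    sample_ids <- colnames(vcf@gt)
    sample_ids <- setdiff(sample_ids, "FORMAT")
    if (length(sample_ids) != 1) {
      stop("ANNOTATED_VCF dialect expects a single-sample VCF, found ",
           length(sample_ids), " sample column(s)")
    }
    gene <- info_field("GENE")
    cls <- info_field("CLASS")
    if (nrow(fix) > 0 && (all(is.na(gene)) || all(is.na(cls)))) {
      stop("ANNOTATED_VCF requires INFO keys GENE and CLASS")
    }
    bad <- setdiff(unique(cls), c(VARIANT_CLASSES, NA))
    if (length(bad) > 0) {
      stop("unknown CLASS value(s): ", paste(bad, collapse = ", "),
           "; accepted: ", paste(VARIANT_CLASSES, collapse = ", "))
    }
    ref <- fix$REF
    alt <- fix$ALT
    variants <- data.frame(
      sample_id      = rep(sample_ids, nrow(fix)),
      gene           = as.character(gene),
      chrom          = as.character(fix$CHROM),
      pos            = as.integer(fix$POS),
      ref_allele     = as.character(ref),
      alt_allele     = as.character(alt),
      variant_class  = as.character(cls),
      variant_type   = .infer_variant_type(ref, alt),
      protein_change = as.character(info_field("PCHANGE")),
      stringsAsFactors = FALSE
    )
    if (nrow(variants) == 0) {
      variants$protein_change <- character(0)
    }
  }
  variants$variant_id <- .variant_ids(variants)
  variants <- variants[, c("variant_id", "sample_id", "gene", "chrom", "pos",
                           "ref_allele", "alt_allele", "variant_class",
                           "variant_type", "protein_change")]
  sample_ids <- unique(variants$sample_id)
  foci <- data.frame(
    sample_id  = sample_ids,
    patient_id = sub("\\.\\d+$", "", sample_ids),
    stringsAsFactors = FALSE
  )
  list(variants = variants, foci = foci)
}

#' Read cohort metadata
#'
#' Tab-separated file with columns `sample_id`, `patient_id`, `stage`
#' (`PRE_INVASIVE` or `INVASIVE`) and `hla_alleles` (semicolon-separated,
#' e.g. `HLA-A*02:01;HLA-A*33:03`).
#'
#' @param path Path to the TSV.
#' @return List with `foci` (sample_id, patient_id, stage) and `patients`
#'   (patient_id, hla_alleles as a list column).
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "stage", "hla_alleles")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in cohort table")
  if (!all(tab$stage %in% c("PRE_INVASIVE", "INVASIVE"))) {
    stop("stage must be PRE_INVASIVE or INVASIVE")
  }
  alleles <- strsplit(tab$hla_alleles, ";", fixed = TRUE)
  allele_vec <- unlist(alleles)
  bad <- allele_vec[!grepl(.hla_pattern, allele_vec)]
  if (length(bad) > 0) {
    stop("malformed HLA allele(s): ", paste(unique(bad), collapse = ", "))
  }
  patients_tab <- unique(tab[, c("patient_id", "hla_alleles")])
  if (anyDuplicated(patients_tab$patient_id)) {
    stop("inconsistent hla_alleles for a patient_id")
  }
  list(
    foci = tab[, c("sample_id", "patient_id", "stage")],
    patients = data.frame(
      patient_id = patients_tab$patient_id,
      hla_alleles = I(strsplit(patients_tab$hla_alleles, ";", fixed = TRUE)),
      stringsAsFactors = FALSE
    )
  )
}

#' Tally variant classifications
#'
#' Counts and proportions by variant class, over the whole cohort or per
#' sample. Proportions are computed over non-silent variants when
#' `exclude_silent` is `TRUE` (the default), so a cohort dominated by
#' missense calls reports e.g. a missense proportion of 0.754.
#'
#' @param variants Variant data frame (see [read_maf()]).
#' @param exclude_silent Drop `SILENT` rows before counting (default `TRUE`).
#' @param by_sample Tally per `sample_id` instead of cohort-wide.
#' @return Data frame with `variant_class`, `n`, `proportion` (and
#'   `sample_id` when `by_sample`). With zero qualifying variants the counts
#'   are zero and proportions `NA`.
#' @export
tally_variant_classes <- function(variants, exclude_silent = TRUE,
                                  by_sample = FALSE) {
  .check_variants(variants)
  if (exclude_silent) variants <- variants[variants$variant_class != "SILENT", ]
  classes <- if (exclude_silent) setdiff(VARIANT_CLASSES, "SILENT") else
    VARIANT_CLASSES
  tally_one <- function(v) {
    n <- table(factor(v$variant_class, levels = classes))
    data.frame(
      variant_class = classes,
      n = as.integer(n),
      proportion = if (sum(n) > 0) as.numeric(n) / sum(n) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (!by_sample) return(tally_one(variants))
  out <- lapply(split(variants, variants$sample_id), tally_one)
  res <- do.call(rbind, Map(function(s, d) cbind(sample_id = s, d),
                            names(out), out))
  rownames(res) <- NULL
  res
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Six-class SNV substitution spectrum
#'
#' Collapses single-base substitutions onto the pyrimidine reference (a G>A
#' call is reported as C>T, A>G as T>C, and so on) and returns per-sample
#' counts and proportions over the six canonical classes.
#'
#' @param variants Variant data frame; only `variant_type == "SNV"` rows are
#'   considered.
#' @param by_sample Per-sample spectrum (default) or pooled.
#' @return Data frame with `snv_class`, `n`, `proportion` (plus `sample_id`
#'   when `by_sample`); proportions sum to 1 per sample when the sample has
#'   at least one SNV, and are `NA` otherwise.
#' @export
snv_six_class_spectrum <- function(variants, by_sample = TRUE) {
  .check_variants(variants)
  snv <- variants[variants$variant_type == "SNV", , drop = FALSE]
  ref <- toupper(snv$ref_allele)
  alt <- toupper(snv$alt_allele)
  flip <- ref %in% c("G", "A")
  ref[flip] <- .complement[toupper(snv$ref_allele)[flip]]
  alt[flip] <- .complement[toupper(snv$alt_allele)[flip]]
  snv$snv_class <- paste0(ref, ">", alt)
  tally_one <- function(v) {
    n <- table(factor(v$snv_class, levels = SNV_CLASSES))
    data.frame(
      snv_class = SNV_CLASSES,
      n = as.integer(n),
      proportion = if (sum(n) > 0) as.numeric(n) / sum(n) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (!by_sample) return(tally_one(snv))
  out <- lapply(split(snv, snv$sample_id), tally_one)
  res <- do.call(rbind, Map(function(s, d) cbind(sample_id = s, d),
                            names(out), out))
  rownames(res) <- NULL
  res
}

#' Tumor mutational burden per sample
#'
#' TMB is the number of non-silent somatic mutations per megabase of
#' interrogated genomic sequence, reported separately for SNV- and
#' indel-derived burden (their sum is the total by construction).
#'
#' @param variants Variant data frame.
#' @param interrogated_mb Size of the interrogated region in megabases;
#'   default 38 (a typical human whole-exome capture).
#' @return Data frame `sample_id`, `tmb_snv`, `tmb_indel`, `tmb_total`
#'   (mutations/Mb).
#' @export
compute_tmb <- function(variants, interrogated_mb = 38) {
  .check_variants(variants)
  if (!is.numeric(interrogated_mb) || length(interrogated_mb) != 1 ||
      interrogated_mb <= 0) {
    stop("interrogated_mb must be a single positive number")
  }
  ns <- variants[variants$variant_class != "SILENT", , drop = FALSE]
  samples <- sort(unique(variants$sample_id))
  snv <- table(factor(ns$sample_id[ns$variant_type == "SNV"],
                      levels = samples))
  indel <- table(factor(ns$sample_id[ns$variant_type != "SNV"],
                        levels = samples))
  data.frame(
    sample_id = samples,
    tmb_snv = as.numeric(snv) / interrogated_mb,
    tmb_indel = as.numeric(indel) / interrogated_mb,
    tmb_total = (as.numeric(snv) + as.numeric(indel)) / interrogated_mb,
    stringsAsFactors = FALSE
  )
}

#' Rank genes by mutation frequency
#'
#' Orders genes by the number of samples carrying a non-silent mutation
#' (descending), breaking ties by total variant count then by gene symbol,
#' and returns the top `n` together with the gene-by-sample count matrix
#' restricted to them — the tabular core of a descending-frequency oncoplot.
#'
#' @param variants Variant data frame.
#' @param n Number of top genes to return (default 100); values beyond the
#'   gene universe return all genes.
#' @return List with `ranking` (data frame `gene`, `n_samples`,
#'   `n_variants`) and `matrix` (genes x samples, non-silent variant counts).
#' @export
rank_genes <- function(variants, n = 100) {
  .check_variants(variants)
  stopifnot(n >= 1)
  ns <- variants[variants$variant_class != "SILENT", , drop = FALSE]
  if (nrow(ns) == 0) {
    return(list(ranking = data.frame(gene = character(0),
                                     n_samples = integer(0),
                                     n_variants = integer(0)),
                matrix = matrix(0L, 0, 0)))
  }
  samples <- sort(unique(ns$sample_id))
  mat <- table(factor(ns$gene), factor(ns$sample_id, levels = samples))
  mat <- matrix(as.integer(mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  n_samples <- rowSums(mat > 0)
  n_variants <- rowSums(mat)
  ord <- order(-n_samples, -n_variants, rownames(mat))
  keep <- ord[seq_len(min(n, nrow(mat)))]
  list(
    ranking = data.frame(gene = rownames(mat)[keep],
                         n_samples = as.integer(n_samples[keep]),
                         n_variants = as.integer(n_variants[keep]),
                         stringsAsFactors = FALSE),
    matrix = mat[keep, , drop = FALSE]
  )
}

#' Genes mutated consistently across every patient
#'
#' A gene qualifies when every patient in the cohort carries at least one
#' non-silent mutation in it in at least one focus, and all observed
#' classifications for that gene collapse to a single variant class across
#' the whole cohort ("the same type of mutation").
#'
#' @param variants Variant data frame.
#' @param foci Focus data frame mapping `sample_id` to `patient_id`.
#' @param gene_pool Genes to screen (typically the top-ranked genes);
#'   default all mutated genes.
#' @return Data frame `gene`, `variant_class`, `n_patients`.
#' @export
consistent_genes_across_patients <- function(variants, foci,
                                             gene_pool = NULL) {
  .check_variants(variants)
  stopifnot(all(c("sample_id", "patient_id") %in% names(foci)))
  n_patients <- length(unique(foci$patient_id))
  if (n_patients < 2) stop("need at least 2 patients")
  ns <- variants[variants$variant_class != "SILENT", , drop = FALSE]
  ns$patient_id <- foci$patient_id[match(ns$sample_id, foci$sample_id)]
  if (anyNA(ns$patient_id)) {
    stop("variants reference sample_id(s) absent from foci")
  }
  if (!is.null(gene_pool)) ns <- ns[ns$gene %in% gene_pool, , drop = FALSE]
  hits <- lapply(split(ns, ns$gene), function(g) {
    classes <- unique(g$variant_class)
    if (length(unique(g$patient_id)) == n_patients && length(classes) == 1) {
      data.frame(gene = g$gene[1], variant_class = classes,
                 n_patients = n_patients, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, hits)
  if (is.null(res)) {
    res <- data.frame(gene = character(0), variant_class = character(0),
                      n_patients = integer(0))
  }
  rownames(res) <- NULL
  res[order(res$gene), , drop = FALSE]
}

#' Bundle the per-sample landscape summaries
#'
#' Convenience wrapper producing the class tallies, variant-type counts,
#' six-class SNV spectra, gene-by-sample matrix and TMB in one object.
#'
#' @param variants Variant data frame.
#' @param foci Focus data frame.
#' @param interrogated_mb TMB denominator in megabases.
#' @param top_n_genes Genes kept in the ranking (default 100).
#' @return List of class `cohort_summary`.
#' @export
cohort_summary <- function(variants, foci, interrogated_mb = 38,
                           top_n_genes = 100) {
  ns <- variants[variants$variant_class != "SILENT", , drop = FALSE]
  type_counts <- as.data.frame(table(
    sample_id = ns$sample_id,
    variant_type = factor(ns$variant_type, levels = c("SNV", "INS", "DEL"))
  ), stringsAsFactors = FALSE)
  names(type_counts)[3] <- "n"
  structure(list(
    class_tally = tally_variant_classes(variants, by_sample = TRUE),
    class_tally_cohort = tally_variant_classes(variants, by_sample = FALSE),
    type_counts = type_counts,
    snv_spectrum = snv_six_class_spectrum(variants, by_sample = TRUE),
    gene_ranking = rank_genes(variants, n = top_n_genes),
    tmb = compute_tmb(variants, interrogated_mb),
    foci = foci,
    n_nonsilent = nrow(ns),
    n_genes = length(unique(ns$gene))
  ), class = "cohort_summary")
}

#' @exportS3Method base::print
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", nrow(x$tmb), "samples,", x$n_nonsilent,
      "non-silent variants in", x$n_genes, "genes\n")
  cat("Mean TMB:", round(mean(x$tmb$tmb_total), 2), "mutations/Mb\n")
  top <- utils::head(x$gene_ranking$ranking, 5)
  cat("Top genes:", paste(top$gene, collapse = ", "), "\n")
  invisible(x)
}

#' Write per-sample summary tables
#'
#' Writes the class counts, type counts, SNV spectrum and TMB as one TSV and
#' the gene ranking as another.
#'
#' @param summary A [cohort_summary()] object.
#' @param summary_path,ranking_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_summary <- function(summary, summary_path, ranking_path) {
  stopifnot(inherits(summary, "cohort_summary"))
  tmb <- summary$tmb
  per_sample <- tmb
  cls <- summary$class_tally
  for (k in setdiff(VARIANT_CLASSES, "SILENT")) {
    sub <- cls[cls$variant_class == k, , drop = FALSE]
    per_sample[[paste0("n_", tolower(k))]] <-
      sub$n[match(per_sample$sample_id, sub$sample_id)]
  }
  spec <- summary$snv_spectrum
  for (k in SNV_CLASSES) {
    sub <- spec[spec$snv_class == k, , drop = FALSE]
    per_sample[[paste0("prop_", sub(">", "_to_", k))]] <-
      sub$proportion[match(per_sample$sample_id, sub$sample_id)]
  }
  utils::write.table(per_sample, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary$gene_ranking$ranking, ranking_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(summary_path, ranking_path))
}
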