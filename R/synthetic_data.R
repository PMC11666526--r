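# Synthetic multi-patient, multi-focus cohorts with known ground truth.
#
# The generator emulates the study design it is calibrated against: a small
# LUAD cohort where one patient is multifocal (two pre-invasive and two
# invasive foci), variant classes are missense-dominant, a configurable
# fraction of each patient's mutations are trunk (shared by all of that
# patient's foci), and a configurable fraction of mutations yield a
# high-binder neopeptide.

.default_class_weights <- c(
  MISSENSE = 0.754, FRAMESHIFT_DEL = 0.088, IN_FRAME_DEL = 0.056,
  FRAMESHIFT_INS = 0.033, NONSENSE = 0.030, SPLICE_SITE = 0.020,
  IN_FRAME_INS = 0.012, NONSTOP = 0.007, SILENT = 0
)

.default_hla <- list(
  c("HLA-A*02:07", "HLA-A*02:03"),
  c("HLA-A*33:03", "HLA-A*24:02"),
  c("HLA-A*02:07", "HLA-A*11:01"),
  c("HLA-A*02:01", "HLA-A*33:03")
)

#' Simulation configuration
#'
#' Defaults reproduce the emulated study design: 4 patients, the last one
#' multifocal with four foci (invasive and pre-invasive alternating), a
#' missense-dominant class mix (missense 0.754, frameshift-deletion 0.088,
#' in-frame-deletion 0.056, frameshift-insertion 0.033, remainder split
#' over the other coding classes), and recurrently mutated genes (MUC16,
#' EGFR, RBM10) implanted at elevated frequency.
#'
#' @param n_patients Number of patients (default 4).
#' @param foci_per_patient Integer vector of focus counts per patient
#'   (default `c(1, 1, 1, 4)`); in multifocal patients stages alternate
#'   INVASIVE, PRE_INVASIVE, ...
#' @param n_genes Size of the toy gene universe (default 60).
#' @param transcript_length_range Codon-count range for toy CDSs,
#'   default `c(100, 300)`.
#' @param class_weights Named probabilities over variant classes; must sum
#'   to 1.
#' @param trunk_fraction Probability a variant is trunk, i.e. shared by all
#'   foci of its patient (default 0.3).
#' @param transition_bias Relative weight of the transition partner when an
#'   SNV alternate base is drawn (default 4, giving the transition-dominant
#'   C>T / T>C spectra typical of lung adenocarcinoma exomes; 1 is
#'   uniform).
#' @param mutations_per_focus Poisson mean of the per-focus mutation count
#'   (default 50).
#' @param binder_fraction Probability a variant's peptide set contains a
#'   high binder (default 0.1).
#' @param interrogated_mb TMB denominator, default 38.
#' @param hot_genes Gene symbols implanted at elevated mutation frequency.
#' @param hot_gene_boost Sampling-weight multiplier for hot genes.
#' @param hla_alleles List of per-patient HLA allele vectors (recycled).
#' @param seed Integer seed; the whole cohort is reconstructible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 4,
                       foci_per_patient = c(1, 1, 1, 4),
                       n_genes = 60,
                       transcript_length_range = c(100, 300),
                       class_weights = .default_class_weights,
                       trunk_fraction = 0.3,
                       transition_bias = 4,
                       mutations_per_focus = 50,
                       binder_fraction = 0.1,
                       interrogated_mb = 38,
                       hot_genes = c("MUC16", "EGFR", "RBM10"),
                       hot_gene_boost = 20,
                       hla_alleles = .default_hla,
                       seed = 1) {
  stopifnot(n_patients >= 1,
            length(foci_per_patient) == n_patients,
            all(foci_per_patient >= 1),
            n_genes >= length(hot_genes) + 1,
            abs(sum(class_weights) - 1) < 1e-8,
            all(names(class_weights) %in% VARIANT_CLASSES),
            trunk_fraction >= 0, trunk_fraction <= 1,
            transition_bias > 0,
            binder_fraction >= 0, binder_fraction <= 1,
            mutations_per_focus >= 0, interrogated_mb > 0)
  structure(list(
    n_patients = n_patients, foci_per_patient = foci_per_patient,
    n_genes = n_genes, transcript_length_range = transcript_length_range,
    class_weights = class_weights, trunk_fraction = trunk_fraction,
    transition_bias = transition_bias,
    mutations_per_focus = mutations_per_focus,
    binder_fraction = binder_fraction, interrogated_mb = interrogated_mb,
    hot_genes = hot_genes, hot_gene_boost = hot_gene_boost,
    hla_alleles = hla_alleles, seed = as.integer(seed)
  ), class = "sim_config")
}

.codons_no_stop <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

.random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(.codons_no_stop, n_codons - 2, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

.codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[[codon]])

# draw one variant of the requested class on a transcript; NULL if the
# class cannot be realised there after bounded retries
.draw_variant <- function(class, tx, transition_bias = 1) {
  cds <- tx$cds
  L <- nchar(cds)
  aa_at <- function(pos) .codon_aa(substr(cds, 3 * ((pos - 1) %/% 3) + 1,
                                          3 * ((pos - 1) %/% 3) + 3))
  if (class == "SPLICE_SITE") {
    # intronic flank in the toy model: placed past the CDS end
    return(list(pos = L + 10L, ref = sample(c("A", "C", "G", "T"), 1),
                alt = sample(c("A", "C", "G", "T"), 1), type = "SNV",
                pchange = NA_character_))
  }
  if (class %in% c("MISSENSE", "NONSENSE", "SILENT", "NONSTOP")) {
    rng <- if (class == "NONSTOP") (L - 2):L else 4:(L - 3)
    for (try in 1:300) {
      pos <- if (length(rng) == 1) rng else sample(rng, 1)
      ref <- substr(cds, pos, pos)
      others <- setdiff(c("A", "C", "G", "T"), ref)
      partner <- c(A = "G", G = "A", C = "T", T = "C")[[ref]]
      alt <- sample(others, 1,
                    prob = ifelse(others == partner, transition_bias, 1))
      c0 <- 3 * ((pos - 1) %/% 3) + 1
      wt_codon <- substr(cds, c0, c0 + 2)
      mt_codon <- wt_codon
      substr(mt_codon, pos - c0 + 1, pos - c0 + 1) <- alt
      wt_aa <- .codon_aa(wt_codon)
      mt_aa <- .codon_aa(mt_codon)
      ok <- switch(class,
        MISSENSE = wt_aa != "*" && mt_aa != "*" && wt_aa != mt_aa,
        NONSENSE = wt_aa != "*" && mt_aa == "*",
        SILENT   = wt_aa == mt_aa,
        NONSTOP  = wt_aa == "*" && mt_aa != "*")
      if (ok) {
        aa_pos <- (pos - 1) %/% 3 + 1
        return(list(pos = pos, ref = ref, alt = alt, type = "SNV",
                    pchange = paste0("p.", wt_aa, aa_pos, mt_aa)))
      }
    }
    return(NULL)
  }
  del_len <- switch(class, FRAMESHIFT_DEL = sample(1:2, 1),
                    IN_FRAME_DEL = 3L, FRAMESHIFT_INS = NA,
                    IN_FRAME_INS = NA)
  aa_pos_of <- function(pos) (pos - 1) %/% 3 + 1
  if (class %in% c("FRAMESHIFT_DEL", "IN_FRAME_DEL")) {
    pos <- sample(4:(L - 3 - del_len), 1)
    ref <- substr(cds, pos, pos + del_len - 1)
    suffix <- if (del_len %% 3 == 0) paste0("del", del_len %/% 3) else "fs"
    return(list(pos = pos, ref = ref, alt = "-", type = "DEL",
                pchange = paste0("p.", aa_pos_of(pos), suffix)))
  }
  ins_len <- if (class == "FRAMESHIFT_INS") sample(1:2, 1) else 3L
  pos <- sample(4:(L - 4), 1)
  ins <- paste(sample(c("A", "C", "G", "T"), ins_len, replace = TRUE),
               collapse = "")
  suffix <- if (ins_len %% 3 == 0) paste0("ins", ins) else "fs"
  list(pos = pos, ref = "-", alt = ins, type = "INS",
       pchange = paste0("p.", aa_pos_of(pos), suffix))
}

#' Simulate a multi-patient, multi-focus cohort
#'
#' Draws toy transcripts, per-focus somatic variants (trunk variants shared
#' with identical coordinates and classes by every focus of their patient),
#' and writes the MAF, transcript FASTA and cohort TSV in exactly the
#' dialects the package readers consume, together with a ground-truth JSON.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List: `paths` (maf, fasta, cohort, ground_truth), `variants`,
#'   `transcripts`, `foci`, `patients`, `ground_truth`.
#' @export
simulate_cohort <- function(config, dir = tempfile("cohort")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  genes <- c(config$hot_genes,
             sprintf("GENE%04d", seq_len(config$n_genes -
                                           length(config$hot_genes))))
  n_codons <- sample(config$transcript_length_range[1]:
                       config$transcript_length_range[2],
                     length(genes), replace = TRUE)
  transcripts <- data.frame(
    gene = genes,
    tx_id = paste0("TX_", genes),
    cds = vapply(n_codons, .random_cds, ""),
    stringsAsFactors = FALSE
  )
  aa <- vapply(transcripts$cds, .translate, "", USE.NAMES = FALSE)
  transcripts$protein <- substr(aa, 1, nchar(aa) - 1)
  gene_weights <- ifelse(genes %in% config$hot_genes,
                         config$hot_gene_boost, 1)

  # foci & patients
  foci <- list(); patients <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- paste0("P", i)
    k <- config$foci_per_patient[i]
    sids <- if (k == 1) pid else paste0(pid, ".", seq_len(k))
    stages <- if (k == 1) "INVASIVE" else
      rep(c("INVASIVE", "PRE_INVASIVE"), length.out = k)
    foci[[i]] <- data.frame(sample_id = sids, patient_id = pid,
                            stage = stages, stringsAsFactors = FALSE)
    alleles <- config$hla_alleles[[(i - 1) %% length(config$hla_alleles) + 1]]
    patients[[i]] <- data.frame(
      patient_id = pid, hla_alleles = paste(alleles, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  foci <- do.call(rbind, foci)
  patients <- do.call(rbind, patients)

  class_pool <- names(config$class_weights)[config$class_weights > 0]
  class_prob <- config$class_weights[class_pool]
  draw_one <- function() {
    for (try in 1:50) {
      gi <- sample(length(genes), 1, prob = gene_weights)
      cls <- sample(class_pool, 1, prob = class_prob)
      d <- .draw_variant(cls, transcripts[gi, ], config$transition_bias)
      if (!is.null(d)) {
        return(data.frame(gene = genes[gi],
                          chrom = paste0("chr", (gi - 1) %% 22 + 1),
                          pos = d$pos, ref_allele = d$ref,
                          alt_allele = d$alt, variant_class = cls,
                          variant_type = d$type, protein_change = d$pchange,
                          stringsAsFactors = FALSE))
      }
    }
    stop("could not realise a variant after 50 gene/class draws")
  }

  rows <- list()
  truth_origin <- list()
  for (pid in unique(foci$patient_id)) {
    psamples <- foci$sample_id[foci$patient_id == pid]
    n_trunk <- stats::rpois(1, config$mutations_per_focus *
                              config$trunk_fraction)
    if (n_trunk > 0) {
      for (j in seq_len(n_trunk)) {
        v <- draw_one()
        for (s in psamples) {
          rows[[length(rows) + 1]] <- cbind(sample_id = s, v)
          truth_origin[[length(truth_origin) + 1]] <-
            data.frame(sample_id = s, origin = "TRUNK")
        }
      }
    }
    for (s in psamples) {
      n_priv <- stats::rpois(1, config$mutations_per_focus *
                               (1 - config$trunk_fraction))
      if (n_priv > 0) {
        for (j in seq_len(n_priv)) {
          v <- draw_one()
          rows[[length(rows) + 1]] <- cbind(sample_id = s, v)
          truth_origin[[length(truth_origin) + 1]] <-
            data.frame(sample_id = s, origin = "PRIVATE")
        }
      }
    }
  }
  variants <- do.call(rbind, rows)
  variants$variant_id <- .variant_ids(variants)
  origin <- do.call(rbind, truth_origin)
  variants <- variants[, c("variant_id", "sample_id", "gene", "chrom", "pos",
                           "ref_allele", "alt_allele", "variant_class",
                           "variant_type", "protein_change")]

  paths <- list(
    maf = file.path(dir, "cohort.maf"),
    fasta = file.path(dir, "transcripts.fa"),
    cohort = file.path(dir, "cohort.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  maf <- data.frame(
    Hugo_Symbol = variants$gene,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref_allele,
    Tumor_Seq_Allele2 = variants$alt_allele,
    Variant_Classification =
      names(.maf_class_map)[match(variants$variant_class, .maf_class_map)],
    Variant_Type = variants$variant_type,
    Tumor_Sample_Barcode = variants$sample_id,
    HGVSp_Short = variants$protein_change,
    stringsAsFactors = FALSE
  )
  utils::write.table(maf, paths$maf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste0(">", transcripts$gene, "|", transcripts$tx_id, "\n",
                    transcripts$cds), paths$fasta)
  cohort_tab <- merge(foci, patients, by = "patient_id", sort = FALSE)
  cohort_tab <- cohort_tab[, c("sample_id", "patient_id", "stage",
                               "hla_alleles")]
  utils::write.table(cohort_tab, paths$cohort, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  class_counts <- table(variants$sample_id, variants$variant_class)
  ground_truth <- list(
    seed = config$seed,
    class_weights = as.list(config$class_weights),
    trunk_fraction = config$trunk_fraction,
    mutations_per_focus = config$mutations_per_focus,
    binder_fraction = config$binder_fraction,
    interrogated_mb = config$interrogated_mb,
    variant_origin = data.frame(variant_id = variants$variant_id,
                                sample_id = variants$sample_id,
                                origin = origin$origin,
                                stringsAsFactors = FALSE),
    class_counts = as.data.frame.matrix(class_counts)
  )
  jsonlite::write_json(ground_truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA)

  list(paths = paths, variants = variants, transcripts = transcripts,
       foci = foci, patients = patients, ground_truth = ground_truth)
}

#' Simulate binding records with planted high binders
#'
#' Per originating variant, with probability `binder_fraction` the variant's
#' whole peptide set is planted as high binders: mutant IC50 drawn
#' Uniform(10, 450) nM and wild-type IC50 set to mutant x Uniform(1.5, 10),
#' so both filter conditions hold by construction. All other pairs violate
#' the filter by construction (mutant IC50 drawn above the 500 nM cutoff).
#' Eluted-ligand and SYFPEITHI records are
#' generated rank-concordant with the affinity values plus noise.
#'
#' @param pairs Peptide-pair data frame (deduplicated; needs `variant_id`
#'   unless every pair is its own variant).
#' @param config A [sim_config()] (supplies `binder_fraction` and the seed).
#' @param allele Allele attached to the records, default `"HLA-A*02:01"`.
#' @return List: `records` (binding records across NETMHCPAN, IEDB_BA,
#'   IEDB_EL, SYFPEITHI), `planted` (pair_id/variant_id of planted
#'   binders).
#' @export
simulate_binding <- function(pairs, config, allele = "HLA-A*02:01") {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 7777L) %% .Machine$integer.max)
  if (nrow(pairs) == 0) {
    return(list(records = data.frame(peptide = character(0),
                                     allele = character(0),
                                     algorithm = character(0),
                                     pre_score_a = numeric(0),
                                     direction = character(0)),
                planted = pairs))
  }
  vid <- if ("variant_id" %in% names(pairs)) pairs$variant_id else
    pairs$pair_id
  variant_ids <- unique(vid)
  binder_variant <- stats::setNames(
    stats::runif(length(variant_ids)) < config$binder_fraction, variant_ids)
  planted <- binder_variant[vid]

  # scores are assigned per unique peptide (predictors score sequences, so
  # a peptide occurring in several pairs must get one value); planted-pair
  # constraints are then enforced on the shared value map
  mt_peps <- unique(pairs$mt_seq)
  mt_planted <- mt_peps %in% pairs$mt_seq[planted]
  value <- stats::setNames(
    ifelse(mt_planted, stats::runif(length(mt_peps), 10, 450),
           stats::runif(length(mt_peps), 600, 5000)),
    mt_peps)
  wt_peps <- setdiff(unique(pairs$wt_seq), mt_peps)
  # wild types of planted pairs sit strictly above every planted mutant
  # they are paired with; all other wild types fail the 500 nM cut too
  max_mt_by_wt <- tapply(value[pairs$mt_seq[planted]],
                         pairs$wt_seq[planted], max)
  has_planted <- wt_peps %in% names(max_mt_by_wt)
  wt_val <- stats::runif(length(wt_peps), 600, 10000)
  wt_val[has_planted] <- unname(max_mt_by_wt[wt_peps[has_planted]]) *
    stats::runif(sum(has_planted), 1.5, 10)
  value[wt_peps] <- wt_val
  # a peptide can be the mutant of one planted pair and the wild type of
  # another; push the dependent mutant values down until consistent
  for (sweep in 1:20) {
    viol <- planted & value[pairs$mt_seq] >= value[pairs$wt_seq]
    if (!any(viol)) break
    for (i in which(viol)) {
      value[pairs$mt_seq[i]] <- value[pairs$wt_seq[i]] *
        stats::runif(1, 0.2, 0.65)
    }
  }
  mt_rec <- data.frame(peptide = mt_peps, allele = allele,
                       algorithm = "NETMHCPAN",
                       pre_score_a = unname(value[mt_peps]),
                       stringsAsFactors = FALSE)
  wt_rec <- data.frame(peptide = wt_peps, allele = allele,
                       algorithm = "NETMHCPAN",
                       pre_score_a = unname(value[wt_peps]),
                       stringsAsFactors = FALSE)
  ba <- rbind(mt_rec, wt_rec)

  iedb_ba <- transform(mt_rec, algorithm = "IEDB_BA",
                       pre_score_a = pre_score_a *
                         exp(stats::rnorm(nrow(mt_rec), 0, 0.2)))
  iedb_el <- transform(mt_rec, algorithm = "IEDB_EL",
                       pre_score_a = pmax(
                         0.01, 5 - log10(mt_rec$pre_score_a) +
                           stats::rnorm(nrow(mt_rec), 0, 0.1)))
  syf <- transform(mt_rec, algorithm = "SYFPEITHI",
                   pre_score_a = pmax(
                     1, round(36 - 7 * log10(mt_rec$pre_score_a) +
                                stats::rnorm(nrow(mt_rec), 0, 1))))
  records <- rbind(ba, iedb_ba, iedb_el, syf)
  records$direction <- .algorithm_direction(records$algorithm)
  rownames(records) <- NULL
  list(records = records,
       planted = pairs[planted, intersect(c("pair_id", "variant_id", "gene",
                                            "mt_seq"), names(pairs)),
                       drop = FALSE])
}
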