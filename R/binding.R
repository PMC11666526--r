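# Binding-prediction backends: the deterministic toy predictor, parsers for
# external predictor tables, the first-round high-binder filter, and TNB.

BA_ALGORITHMS <- c("NETMHCPAN", "IEDB_BA", "TOY")
ALL_ALGORITHMS <- c("NETMHCPAN", "IEDB_BA", "IEDB_EL", "SYFPEITHI", "TOY")

.algorithm_direction <- function(algorithm) {
  ifelse(algorithm %in% BA_ALGORITHMS, "LOWER_IS_BETTER", "HIGHER_IS_BETTER")
}

.aa_standard <- "ACDEFGHIKLMNPQRSTVWY"

# stable polynomial string hash in [0, 1); exact in doubles (< 2^53),
# independent of R's RNG
.hash01 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483647
  }
  h / 2147483647
}

#' Deterministic toy binding predictor
#'
#' A self-contained stand-in binding model so the pipeline runs end-to-end
#' offline. The predicted pseudo-IC50 (nM) is driven by the canonical
#' HLA-A*02:01 anchor residues — L/M at position 2 and V/L/I at the
#' C-terminus — with a seeded sequence hash jittering within the decade set
#' by the anchor count, so anchors dominate: a two-anchor peptide always
#' scores below (binds better than) a one-anchor permutation of itself.
#' `log10(IC50) = 4.2 - 1.6 * anchors + 0.5 * u`, clamped to (0, 50000].
#'
#' @param peptide Peptide (length 8-11, standard residues).
#' @param allele HLA allele string, e.g. `"HLA-A*02:01"`.
#' @param seed Integer folded into the hash; same inputs, same output.
#' @return One-row data frame (`peptide`, `allele`, `algorithm = "TOY"`,
#'   `pre_score_a`, `direction = "LOWER_IS_BETTER"`).
#' @export
toy_predict <- function(peptide, allele, seed = 0) {
  if (nchar(peptide) < 8 || nchar(peptide) > 11) {
    stop("peptide length must be 8-11, got ", nchar(peptide))
  }
  if (grepl(paste0("[^", .aa_standard, "]"), peptide)) {
    stop("nonstandard residue in peptide: ", peptide)
  }
  p2 <- substr(peptide, 2, 2)
  pomega <- substr(peptide, nchar(peptide), nchar(peptide))
  anchors <- (p2 %in% c("L", "M")) + (pomega %in% c("V", "L", "I"))
  u <- .hash01(paste(peptide, allele, seed, sep = "/"))
  ic50 <- min(10^(4.2 - 1.6 * anchors + 0.5 * u), 50000)
  data.frame(peptide = peptide, allele = allele, algorithm = "TOY",
             pre_score_a = ic50, direction = "LOWER_IS_BETTER",
             stringsAsFactors = FALSE)
}

#' Score many peptides with the toy predictor
#' @param peptides Character vector of peptides.
#' @param alleles Character vector of alleles (recycled against peptides via
#'   a full cross).
#' @param seed Integer seed.
#' @return Binding-record data frame, one row per peptide x allele.
#' @export
toy_predict_all <- function(peptides, alleles, seed = 0) {
  grid <- expand.grid(peptide = unique(peptides), allele = unique(alleles),
                      stringsAsFactors = FALSE)
  do.call(rbind, Map(function(p, a) toy_predict(p, a, seed),
                     grid$peptide, grid$allele))
}

#' Parse an external predictor output table
#'
#' Three tabular dialects are supported (one golden fixture of each ships
#' under `inst/extdata/`):
#' \describe{
#'   \item{NETMHCPAN_XLS}{Tab-separated with columns `HLA`, `Peptide`,
#'     `Aff(nM)`; affinity in nM, lower is better.}
#'   \item{IEDB_CSV}{Comma-separated with columns `allele`, `peptide`,
#'     `method` (`ba` or `el`) and `score` (nM IC50 for `ba`, eluted-ligand
#'     score for `el`).}
#'   \item{SYFPEITHI_TSV}{Tab-separated with columns `Peptide`, `Score`;
#'     higher is better. The allele is not part of SYFPEITHI rows and is
#'     supplied via `allele`.}
#' }
#'
#' @param path Input file.
#' @param format One of `"NETMHCPAN_XLS"`, `"IEDB_CSV"`, `"SYFPEITHI_TSV"`.
#' @param allele Allele attached to SYFPEITHI rows (default
#'   `"HLA-A*02:01"`).
#' @return Binding-record data frame (`peptide`, `allele`, `algorithm`,
#'   `pre_score_a`, `direction`).
#' @export
parse_predictor_table <- function(path,
                                  format = c("NETMHCPAN_XLS", "IEDB_CSV",
                                             "SYFPEITHI_TSV"),
                                  allele = "HLA-A*02:01") {
  format <- match.arg(format)
  if (format == "NETMHCPAN_XLS") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    req <- c("HLA", "Peptide", "Aff(nM)")
    if (!all(req %in% names(tab))) {
      stop("unrecognised NetMHCpan layout; detected header: ",
           paste(names(tab), collapse = ", "))
    }
    rec <- data.frame(peptide = tab$Peptide, allele = tab$HLA,
                      algorithm = rep("NETMHCPAN", nrow(tab)),
                      pre_score_a = as.numeric(tab[["Aff(nM)"]]),
                      stringsAsFactors = FALSE)
  } else if (format == "IEDB_CSV") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("allele", "peptide", "method", "score")
    if (!all(req %in% names(tab))) {
      stop("unrecognised IEDB layout; detected header: ",
           paste(names(tab), collapse = ", "))
    }
    if (!all(tab$method %in% c("ba", "el"))) {
      stop("IEDB method must be 'ba' or 'el'")
    }
    rec <- data.frame(peptide = tab$peptide, allele = tab$allele,
                      algorithm = ifelse(tab$method == "ba",
                                         "IEDB_BA", "IEDB_EL"),
                      pre_score_a = as.numeric(tab$score),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    req <- c("Peptide", "Score")
    if (!all(req %in% names(tab))) {
      stop("unrecognised SYFPEITHI layout; detected header: ",
           paste(names(tab), collapse = ", "))
    }
    rec <- data.frame(peptide = tab$Peptide,
                      allele = rep(allele, nrow(tab)),
                      algorithm = rep("SYFPEITHI", nrow(tab)),
                      pre_score_a = as.numeric(tab$Score),
                      stringsAsFactors = FALSE)
  }
  if (any(!is.finite(rec$pre_score_a) | rec$pre_score_a <= 0)) {
    stop("pre-scores must be positive finite numbers")
  }
  rec$direction <- .algorithm_direction(rec$algorithm)
  rec
}

.ba_lookup <- function(records, algorithm = NULL) {
  ba <- records[records$direction == "LOWER_IS_BETTER", , drop = FALSE]
  if (!is.null(algorithm)) {
    ba <- ba[ba$algorithm == algorithm, , drop = FALSE]
  }
  ba
}

#' First-round high-binder filter
#'
#' A mutant peptide is a high binder when its predicted IC50 is strictly
#' below `ic50_threshold` (default 500 nM) AND strictly below the IC50 of
#' its wild-type counterpart, for at least one of the supplied alleles.
#' Pairs failing either condition are retained with
#' `is_high_binder = FALSE`; pairs with a missing wild-type or mutant score
#' are skipped with a warning.
#'
#' @param pairs Peptide-pair data frame.
#' @param records Binding-record data frame with affinity-type
#'   (lower-is-better, nM) scores for both peptides of each pair.
#' @param ic50_threshold High-binder cutoff in nM, default 500.
#' @param alleles Alleles to consider; default all alleles in `records`.
#' @param algorithm Affinity algorithm supplying the IC50s; by default the
#'   first of NETMHCPAN, TOY, IEDB_BA present in `records`. The first-round
#'   filter is single-predictor; other algorithms only enter the
#'   second-round harmonized display.
#' @return Data frame `pair_id`, `allele` (best allele for the mutant),
#'   `ic50_wt`, `ic50_mut`, `is_high_binder`.
#' @export
call_high_binders <- function(pairs, records, ic50_threshold = 500,
                              alleles = NULL, algorithm = NULL) {
  stopifnot(ic50_threshold > 0)
  if (is.null(algorithm)) {
    present <- intersect(c("NETMHCPAN", "TOY", "IEDB_BA"),
                         unique(records$algorithm))
    if (length(present) == 0) stop("no affinity-type records supplied")
    algorithm <- present[1]
  }
  ba <- .ba_lookup(records, algorithm)
  if (is.null(alleles)) alleles <- unique(ba$allele)
  ba <- ba[ba$allele %in% alleles, , drop = FALSE]
  n <- nrow(pairs)
  best_mt <- rep(NA_real_, n)
  best_wt <- rep(NA_real_, n)
  best_al <- rep(NA_character_, n)
  for (al in alleles) {
    sub <- ba[ba$allele == al, , drop = FALSE]
    if (nrow(sub) == 0) next
    score <- tapply(sub$pre_score_a, sub$peptide, min)  # best per peptide
    mt <- unname(score[pairs$mt_seq])
    wt <- unname(score[pairs$wt_seq])
    upd <- !is.na(mt) & !is.na(wt) & (is.na(best_mt) | mt < best_mt)
    best_mt[upd] <- mt[upd]
    best_wt[upd] <- wt[upd]
    best_al[upd] <- al
  }
  have <- !is.na(best_mt)
  if (any(!have)) {
    warning(sum(!have),
            " pair(s) skipped: missing wild-type or mutant score")
  }
  res <- data.frame(
    pair_id = pairs$pair_id[have],
    allele = best_al[have],
    ic50_wt = best_wt[have],
    ic50_mut = best_mt[have],
    is_high_binder = best_mt[have] < ic50_threshold &
      best_mt[have] < best_wt[have],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Tumor neoantigen burden per sample
#'
#' TNB counts, per sample, the distinct somatic variants yielding at least
#' one high-binder peptide, split by SNV versus indel origin (the two
#' components sum to the total). Binder calls are tied back to variants
#' through the `variant_id` carried on the peptide pairs.
#'
#' @param variants Variant data frame.
#' @param calls High-binder calls from [call_high_binders()].
#' @param pairs The peptide pairs the calls were made on (provides the
#'   `pair_id` to `variant_id` mapping).
#' @param mhc_class `"I"` (default) or `"II"`; recorded in the output.
#' @return Data frame `sample_id`, `mhc_class`, `tnb_snv`, `tnb_indel`,
#'   `tnb_total`.
#' @export
compute_tnb <- function(variants, calls, pairs, mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  .check_variants(variants)
  stopifnot("variant_id" %in% names(pairs))
  hb <- calls[calls$is_high_binder, , drop = FALSE]
  hit_variants <- unique(pairs$variant_id[pairs$pair_id %in% hb$pair_id])
  samples <- sort(unique(variants$sample_id))
  v <- variants[variants$variant_id %in% hit_variants, , drop = FALSE]
  snv <- table(factor(v$sample_id[v$variant_type == "SNV"], levels = samples))
  indel <- table(factor(v$sample_id[v$variant_type != "SNV"],
                        levels = samples))
  data.frame(
    sample_id = samples,
    mhc_class = mhc_class,
    tnb_snv = as.integer(snv),
    tnb_indel = as.integer(indel),
    tnb_total = as.integer(snv) + as.integer(indel),
    stringsAsFactors = FALSE
  )
}

#' Write binder calls as TSV
#' @param calls Output of [call_high_binders()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_binder_calls <- function(calls, path) {
  out <- calls
  out$ic50_wt <- round(out$ic50_wt, 1)
  out$ic50_mut <- round(out$ic50_mut, 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
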