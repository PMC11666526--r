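# Score harmonization across prediction algorithms, consensus ranking,
# top-n selection, and the multifocal sharing screen.
#
# Affinity-type predictors report a binding concentration a (nM): higher a
# means weaker binding. It is transformed to b = 1/log(a) so that b
# increases with affinity; eluted-ligand and SYFPEITHI scores already do and
# pass through untouched. Each score column is then min-max rescaled onto
# [1, 20] for cross-algorithm comparison.

#' Transform a pre-score into an affinity-increasing score
#'
#' For affinity-type algorithms (NetMHCpan, IEDB BA, the toy predictor) the
#' transform is `b = 1/log(a)` with base `log_base` (default 10); it is
#' strictly decreasing in `a` on (1, Inf), so stronger binders get larger
#' `b`. Eluted-ligand and SYFPEITHI scores need no pre-treatment and are
#' returned unchanged. Affinity pre-scores at or below `1 + eps` would make
#' the log blow up and are clamped to `1 + eps` with a warning (sub-nM
#' affinities do occur in real predictor output).
#'
#' @param raw_a Positive pre-score(s).
#' @param algorithm One of `"NETMHCPAN"`, `"IEDB_BA"`, `"TOY"`,
#'   `"IEDB_EL"`, `"SYFPEITHI"`.
#' @param log_base Base of the logarithm, default 10.
#' @param eps Guard band around `a = 1`, default 0.01.
#' @return Numeric vector of scores `b`.
#' @export
transform_b <- function(raw_a, algorithm, log_base = 10, eps = 0.01) {
  stopifnot(length(algorithm) == 1, algorithm %in% ALL_ALGORITHMS)
  if (any(!is.finite(raw_a) | raw_a <= 0)) {
    stop("pre-scores must be positive")
  }
  if (!(algorithm %in% BA_ALGORITHMS)) return(raw_a)
  low <- raw_a <= 1 + eps
  if (any(low)) {
    warning(sum(low), " pre-score(s) at or below ", 1 + eps,
            " clamped before the log transform")
    raw_a[low] <- 1 + eps
  }
  1 / log(raw_a, base = log_base)
}

#' Fold change of wild-type over mutant pre-score
#'
#' `FC = a_wt / a_mut` on affinity pre-scores; values above 1 mean the
#' mutant binds at a lower concentration, i.e. better, than its wild-type
#' counterpart.
#'
#' @param a_wt,a_mut Positive pre-scores (nM) of the wild-type and mutant
#'   peptides.
#' @return Numeric fold change(s).
#' @export
fold_change <- function(a_wt, a_mut) {
  if (any(!is.finite(a_mut) | a_mut <= 0)) stop("a_mut must be positive")
  if (any(!is.finite(a_wt) | a_wt <= 0)) stop("a_wt must be positive")
  a_wt / a_mut
}

#' Min-max rescale onto [1, 20]
#'
#' `c = (b - min(b)) / (max(b) - min(b)) * span + floor`; with the defaults
#' the batch minimum maps to 1 and the maximum to 20, preserving order. A
#' degenerate batch (all values equal) maps to the midpoint of the range.
#'
#' @param values Numeric vector (at least one value).
#' @param floor Lower end of the target range, default 1.
#' @param span Width of the target range, default 19.
#' @return Rescaled values.
#' @export
rescale_c <- function(values, floor = 1, span = 19) {
  if (length(values) == 0) stop("cannot rescale an empty batch")
  if (any(!is.finite(values))) stop("non-finite value in batch")
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(rep(floor + span / 2, length(values)))
  (values - lo) / (hi - lo) * span + floor
}

.split_foci <- function(foci_strings) {
  strsplit(gsub("[[:space:]]", "", foci_strings), ",", fixed = TRUE)
}

.harmonized_columns <- function(pairs, records, log_base = 10) {
  cols <- list()
  for (alg in setdiff(ALL_ALGORITHMS, "TOY")) {
    rec <- records[records$algorithm == alg, , drop = FALSE]
    if (nrow(rec) == 0) next
    a <- rec$pre_score_a[match(pairs$mt_seq, rec$peptide)]
    if (all(is.na(a))) next
    b <- rep(NA_real_, length(a))
    ok <- !is.na(a)
    b[ok] <- suppressWarnings(transform_b(a[ok], alg, log_base = log_base))
    cv <- rep(NA_real_, length(b))
    cv[ok] <- rescale_c(b[ok])
    cols[[paste0("c_", tolower(alg))]] <- cv
  }
  # fold change from the affinity predictor's wt/mt pre-scores
  fc_source <- if (any(records$algorithm == "NETMHCPAN")) "NETMHCPAN"
    else if (any(records$algorithm == "TOY")) "TOY" else NA
  if (!is.na(fc_source)) {
    rec <- records[records$algorithm == fc_source, , drop = FALSE]
    a_mt <- rec$pre_score_a[match(pairs$mt_seq, rec$peptide)]
    a_wt <- rec$pre_score_a[match(pairs$wt_seq, rec$peptide)]
    ok <- !is.na(a_mt) & !is.na(a_wt)
    fc <- rep(NA_real_, nrow(pairs))
    fc[ok] <- fold_change(a_wt[ok], a_mt[ok])
    cols$fc <- fc
    cfc <- rep(NA_real_, nrow(pairs))
    if (any(ok)) cfc[ok] <- rescale_c(fc[ok])
    cols$c_fc <- cfc
  }
  cols
}

#' Select the top candidate neopeptides
#'
#' First-round ranking: high-binder pairs ordered by mutant IC50
#' (ascending) and cut at `n` (default 30). For the second-round display,
#' every available algorithm's scores are harmonized onto [1, 20] within
#' the selected batch, a fold-change column is added, and a consensus score
#' per pair is computed (default: unweighted mean of the available `c`
#' values; `"rank_sum"` averages within-column ranks instead). The returned
#' ranking is ordered by consensus, descending; ties break by mutant IC50
#' then pair id.
#'
#' @param pairs Deduplicated peptide-pair data frame.
#' @param calls High-binder calls from [call_high_binders()].
#' @param records Binding-record data frame across algorithms (used for the
#'   per-algorithm score columns and fold change).
#' @param n Number of candidates to keep, default 30; when fewer high
#'   binders exist, all are returned with a message.
#' @param consensus `"mean"` (default) or `"rank_sum"`.
#' @param log_base Passed to [transform_b()].
#' @return A `candidate_ranking` list: `table` (pairs with `ic50_wt`,
#'   `ic50_mut`, per-algorithm `c_*` columns, `fc`, `consensus`, `foci`),
#'   `c_matrix`, and `foci_matrix` (pairs x foci presence).
#' @export
select_top <- function(pairs, calls, records = NULL, n = 30,
                       consensus = c("mean", "rank_sum"), log_base = 10) {
  consensus <- match.arg(consensus)
  stopifnot(n >= 1)
  tab <- merge(pairs, calls[, c("pair_id", "allele", "ic50_wt", "ic50_mut",
                                "is_high_binder")],
               by = "pair_id", sort = FALSE)
  tab <- tab[tab$is_high_binder, , drop = FALSE]
  if (nrow(tab) < n) {
    message("only ", nrow(tab), " high-binder pair(s) available for top-", n)
  }
  tab <- tab[order(tab$ic50_mut, tab$pair_id), , drop = FALSE]
  tab <- utils::head(tab, n)
  if (nrow(tab) > 0 && !is.null(records)) {
    cols <- .harmonized_columns(tab, records, log_base = log_base)
    for (nm in names(cols)) tab[[nm]] <- cols[[nm]]
  }
  c_cols <- grep("^c_", names(tab), value = TRUE)
  if (length(c_cols) > 0) {
    cmat <- as.matrix(tab[, c_cols, drop = FALSE])
    rownames(cmat) <- tab$pair_id
    tab$consensus <- if (consensus == "mean") {
      rowMeans(cmat, na.rm = TRUE)
    } else {
      rmat <- apply(cmat, 2, function(x) rank(x, na.last = "keep"))
      rowMeans(as.matrix(rmat), na.rm = TRUE)
    }
  } else {
    # no second-round scores attached: consensus falls back to affinity
    cmat <- matrix(numeric(0), nrow = nrow(tab), ncol = 0,
                   dimnames = list(tab$pair_id, NULL))
    tab$consensus <- if (nrow(tab) > 0) rescale_c(-tab$ic50_mut) else numeric(0)
  }
  ord <- order(-tab$consensus, tab$ic50_mut, tab$pair_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  foci_sets <- .split_foci(tab$foci)
  all_foci <- sort(unique(unlist(foci_sets)))
  fmat <- matrix(FALSE, nrow(tab), length(all_foci),
                 dimnames = list(tab$pair_id, all_foci))
  for (i in seq_along(foci_sets)) fmat[i, foci_sets[[i]]] <- TRUE
  structure(list(table = tab,
                 c_matrix = if (nrow(tab) > 0) cmat[tab$pair_id, , drop = FALSE]
                            else cmat,
                 foci_matrix = fmat),
            class = "candidate_ranking")
}

#' @exportS3Method base::print
print.candidate_ranking <- function(x, ...) {
  cat("Candidate ranking:", nrow(x$table), "pairs across",
      ncol(x$foci_matrix), "foci\n")
  print(utils::head(x$table[, intersect(
    c("pair_id", "gene", "mt_seq", "ic50_mut", "consensus", "foci"),
    names(x$table))], 10))
  invisible(x)
}

#' Candidates shared across tumor foci
#'
#' Restricts a ranking (or a plain pair table) to candidates present in at
#' least `min_foci` foci — the multifocal sharing screen.
#'
#' @param ranking A `candidate_ranking` from [select_top()], or a
#'   peptide-pair data frame with a `foci` column.
#' @param min_foci Minimum number of foci, default 2.
#' @return List with `table` (qualifying pairs, with `n_foci`) and
#'   `presence` (qualifying pairs x foci logical matrix).
#' @export
foci_distribution <- function(ranking, min_foci = 2) {
  stopifnot(min_foci >= 1)
  tab <- if (inherits(ranking, "candidate_ranking")) ranking$table else ranking
  stopifnot("foci" %in% names(tab))
  foci_sets <- .split_foci(tab$foci)
  n_foci <- lengths(foci_sets)
  keep <- n_foci >= min_foci
  out <- tab[keep, , drop = FALSE]
  out$n_foci <- n_foci[keep]
  all_foci <- sort(unique(unlist(foci_sets)))
  pres <- matrix(FALSE, nrow(out), length(all_foci),
                 dimnames = list(out$pair_id, all_foci))
  kept_sets <- foci_sets[keep]
  for (i in seq_along(kept_sets)) pres[i, kept_sets[[i]]] <- TRUE
  rownames(out) <- NULL
  list(table = out, presence = pres)
}

#' Write a candidate ranking as TSV
#'
#' Relative scores are printed at 4 decimals and IC50 columns at 1 decimal.
#'
#' @param ranking A `candidate_ranking`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "candidate_ranking"))
  tab <- ranking$table
  for (nm in grep("^(c_|consensus|fc$)", names(tab), value = TRUE)) {
    tab[[nm]] <- round(tab[[nm]], 4)
  }
  for (nm in intersect(c("ic50_wt", "ic50_mut"), names(tab))) {
    tab[[nm]] <- round(tab[[nm]], 1)
  }
  drop <- intersect(c("length", "start", "is_high_binder"), names(tab))
  tab <- tab[, setdiff(names(tab), drop), drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dot plot of harmonized affinity scores
#'
#' Mirrors the second-round display: one dot per candidate and algorithm,
#' with dot size and darkness encoding the relative score `c`. Requires
#' ggplot2.
#'
#' @param ranking A `candidate_ranking` with harmonized columns.
#' @return A ggplot object.
#' @export
plot_affinity_dotplot <- function(ranking) {
  stopifnot(inherits(ranking, "candidate_ranking"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  cmat <- ranking$c_matrix
  if (ncol(cmat) == 0) stop("ranking has no harmonized score columns")
  df <- data.frame(
    pair_id = rep(rownames(cmat), ncol(cmat)),
    algorithm = rep(sub("^c_", "", colnames(cmat)), each = nrow(cmat)),
    score = as.vector(cmat)
  )
  df$pair_id <- factor(df$pair_id, levels = rev(rownames(cmat)))
  ggplot2::ggplot(df, ggplot2::aes(x = algorithm, y = pair_id,
                                   size = score, colour = score)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_colour_gradient(low = "grey80", high = "grey10") +
    ggplot2::scale_size(range = c(1, 6)) +
    ggplot2::labs(x = NULL, y = NULL, size = "score c", colour = "score c") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("algorithm", "pair_id", "score"))
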