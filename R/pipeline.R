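# End-to-end pipeline wiring and run manifests. The numbered scripts under
# analysis/ are thin drivers over these functions.

#' Pipeline run configuration
#'
#' Collects every tunable threshold with its default: 500 nM IC50 cutoff,
#' peptide lengths 8-11, top 30 candidates, sharing screen at >= 2 foci,
#' base-10 logarithm for the affinity transform.
#'
#' @param interrogated_mb TMB denominator in megabases (default 38).
#' @param ic50_threshold High-binder IC50 cutoff in nM (default 500).
#' @param lengths Peptide lengths (default `8:11`).
#' @param top_n Candidates kept by the ranking (default 30).
#' @param min_foci Sharing-screen threshold (default 2).
#' @param log_base Base for the affinity transform (default 10).
#' @param consensus Consensus mode, `"mean"` or `"rank_sum"`.
#' @param dedup_policy Passed to [deduplicate()].
#' @param allele Allele used when scoring with the built-in toy predictor.
#' @param seed Integer seed for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(interrogated_mb = 38, ic50_threshold = 500,
                       lengths = 8:11, top_n = 30, min_foci = 2,
                       log_base = 10, consensus = "mean",
                       dedup_policy = "BY_GENE_AND_PEPTIDE",
                       allele = "HLA-A*02:01", seed = 1) {
  stopifnot(interrogated_mb > 0, ic50_threshold > 0, all(lengths >= 1),
            top_n >= 1, min_foci >= 1, log_base > 1)
  structure(list(interrogated_mb = interrogated_mb,
                 ic50_threshold = ic50_threshold, lengths = lengths,
                 top_n = top_n, min_foci = min_foci, log_base = log_base,
                 consensus = consensus, dedup_policy = dedup_policy,
                 allele = allele, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the screening pipeline end to end
#'
#' Reads somatic calls, transcripts and cohort metadata; computes the
#' landscape summaries and TMB; enumerates and deduplicates peptide pairs;
#' scores them (with supplied binding records, or the built-in toy
#' predictor when none are given); applies the high-binder filter; computes
#' TNB; ranks the top candidates with harmonized scores; and runs the
#' multifocal sharing screen. When `outdir` is given, all tables plus a run
#' manifest are written there.
#'
#' @param maf_path Somatic calls (MAF dialect).
#' @param fasta_path Transcript CDS FASTA.
#' @param cohort_path Cohort metadata TSV (optional; foci fall back to the
#'   samples seen in the MAF).
#' @param records Binding-record data frame; `NULL` uses [toy_predict_all()].
#' @param config A [run_config()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return List: `summary`, `pairs`, `calls`, `tnb`, `ranking`, `shared`,
#'   plus the inputs read.
#' @export
run_pipeline <- function(maf_path, fasta_path, cohort_path = NULL,
                         records = NULL, config = run_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  calls_in <- read_maf(maf_path)
  variants <- calls_in$variants
  foci <- if (!is.null(cohort_path)) read_cohort(cohort_path)$foci else
    calls_in$foci
  transcripts <- read_transcript_fasta(fasta_path)

  summary <- cohort_summary(variants, foci,
                            interrogated_mb = config$interrogated_mb)
  pairs <- peptide_pairs(variants, transcripts, lengths = config$lengths)
  pairs <- deduplicate(pairs, policy = config$dedup_policy)

  if (is.null(records)) {
    peps <- unique(c(pairs$wt_seq, pairs$mt_seq))
    records <- if (length(peps) > 0)
      toy_predict_all(peps, config$allele, seed = config$seed)
    else NULL
  }
  calls <- call_high_binders(pairs, records,
                             ic50_threshold = config$ic50_threshold)
  tnb <- compute_tnb(variants, calls, pairs)
  ranking <- select_top(pairs, calls, records, n = config$top_n,
                        consensus = config$consensus,
                        log_base = config$log_base)
  shared <- foci_distribution(ranking, min_foci = config$min_foci)

  res <- list(summary = summary, pairs = pairs, records = records,
              calls = calls, tnb = tnb, ranking = ranking, shared = shared,
              variants = variants, foci = foci, transcripts = transcripts,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_summary(summary, file.path(outdir, "sample_summary.tsv"),
                         file.path(outdir, "gene_ranking.tsv"))
    write_pair_table(pairs, file.path(outdir, "peptide_pairs.tsv"))
    write_binder_calls(calls, file.path(outdir, "binder_calls.tsv"))
    utils::write.table(tnb, file.path(outdir, "tnb.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_ranking(ranking, file.path(outdir, "candidate_ranking.tsv"))
    write_ranking_shared(shared, file.path(outdir, "shared_candidates.tsv"))
    write_manifest(
      file.path(outdir, "manifest.json"), config,
      inputs = c(maf = maf_path, fasta = fasta_path,
                 cohort = if (is.null(cohort_path)) NULL else cohort_path))
  }
  res
}

write_ranking_shared <- function(shared, path) {
  tab <- shared$table
  for (nm in grep("^(c_|consensus|fc$)", names(tab), value = TRUE)) {
    tab[[nm]] <- round(tab[[nm]], 4)
  }
  for (nm in intersect(c("ic50_wt", "ic50_mut"), names(tab))) {
    tab[[nm]] <- round(tab[[nm]], 1)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Echoes the configuration, input checksums (md5) and package version so a
#' run can be reproduced byte-for-byte.
#'
#' @param path Output JSON path.
#' @param config A [run_config()].
#' @param inputs Named character vector of input file paths.
#' @param warnings Character vector of surfaced warnings.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, config, inputs = character(0),
                           warnings = character(0)) {
  manifest <- list(
    package = "neoscreen",
    version = as.character(utils::packageVersion("neoscreen")),
    config = unclass(config),
    inputs = if (length(inputs) > 0)
      as.list(tools::md5sum(inputs)) else list(),
    warnings = as.list(warnings)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
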