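# Mutant protein construction and 8-11-mer peptide enumeration.
#
# Variants are mapped transcript-relative: `pos` minus `cds_offset` gives the
# 1-based coordinate within the coding sequence. Only plus-strand toy
# transcripts are modelled; splice-site variants yield no peptides.

.translate <- function(dna) {
  dna <- substr(dna, 1, 3 * (nchar(dna) %/% 3))
  if (nchar(dna) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(dna)))
}

# translate until the first stop; attr "runthrough" TRUE when no stop found
.translate_to_stop <- function(dna) {
  aa <- .translate(dna)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    structure(substr(aa, 1, stop_at - 1), runthrough = FALSE)
  } else {
    structure(aa, runthrough = TRUE)
  }
}

.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Read coding-sequence FASTA
#'
#' Headers follow the `gene|transcript_id` convention. Every CDS must start
#' with ATG, end with a stop codon, have length divisible by 3 and contain
#' no internal stop.
#'
#' @param path FASTA path.
#' @return Data frame `gene`, `tx_id`, `cds`, `protein` (protein excludes
#'   the terminal stop).
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    return(data.frame(gene = character(0), tx_id = character(0),
                      cds = character(0), protein = character(0)))
  }
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1)
  tx_id <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], "")
  cds <- as.character(seqs)
  ok_len <- nchar(cds) %% 3 == 0
  if (!all(ok_len)) {
    stop("CDS length not divisible by 3 for: ",
         paste(gene[!ok_len], collapse = ", "))
  }
  aa <- vapply(cds, .translate, "", USE.NAMES = FALSE)
  ok <- startsWith(cds, "ATG") & endsWith(aa, "*") &
    !grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
  if (!all(ok)) {
    stop("malformed CDS (needs ATG start, single terminal stop) for: ",
         paste(gene[!ok], collapse = ", "))
  }
  data.frame(gene = gene, tx_id = tx_id, cds = cds,
             protein = substr(aa, 1, nchar(aa) - 1),
             stringsAsFactors = FALSE)
}

#' Apply a somatic variant to a transcript
#'
#' Edits the coding sequence, re-translates, and classifies the
#' protein-level consequence. Substitutions yield `SUBSTITUTION`,
#' `STOP_GAIN` or `STOP_LOSS`; in-frame indels `IN_FRAME_INDEL`; frameshifts
#' re-translate from the shifted codon to the first novel stop
#' (`FRAMESHIFT`; when no downstream stop exists translation runs to the CDS
#' end and the event is flagged `runthrough`). Synonymous edits and variants
#' outside the CDS return `NULL`.
#'
#' Insertions are placed after the stated position (`ref_allele == "-"`);
#' deletions remove `ref_allele` starting at the stated position.
#'
#' @param transcript One row of [read_transcript_fasta()] output (or a list
#'   with `gene`, `cds`, `protein`).
#' @param variant One variant row (needs `pos`, `ref_allele`, `alt_allele`,
#'   `variant_type`, `variant_class`).
#' @param cds_offset Genomic-to-CDS offset; CDS position is
#'   `pos - cds_offset`. Default 0 (positions already transcript-relative).
#' @return A `mutant_protein_event` list (`gene`, `wt_protein`,
#'   `mt_protein`, `altered_span`, `consequence`, `runthrough`) or `NULL`.
#' @export
apply_variant <- function(transcript, variant, cds_offset = 0) {
  cds <- as.character(transcript$cds)
  wt <- as.character(transcript$protein)
  if (variant$variant_class == "SPLICE_SITE") return(NULL)
  cds_pos <- as.integer(variant$pos) - cds_offset
  ref <- as.character(variant$ref_allele)
  alt <- as.character(variant$alt_allele)
  if (is.na(cds_pos) || cds_pos < 1 || cds_pos > nchar(cds)) return(NULL)

  if (variant$variant_type == "SNV") {
    if (substr(cds, cds_pos, cds_pos) != ref) {
      warning("reference allele mismatch at CDS position ", cds_pos,
              " for gene ", transcript$gene)
    }
    mt_cds <- paste0(substr(cds, 1, cds_pos - 1), alt,
                     substr(cds, cds_pos + 1, nchar(cds)))
  } else if (ref == "-" || nchar(gsub("-", "", alt)) > nchar(gsub("-", "", ref))) {
    ins <- gsub("-", "", alt)
    mt_cds <- paste0(substr(cds, 1, cds_pos), ins,
                     substr(cds, cds_pos + 1, nchar(cds)))
  } else {
    del <- gsub("-", "", ref)
    if (substr(cds, cds_pos, cds_pos + nchar(del) - 1) != del) {
      warning("deleted sequence mismatch at CDS position ", cds_pos,
              " for gene ", transcript$gene)
    }
    mt_cds <- paste0(substr(cds, 1, cds_pos - 1),
                     substr(cds, cds_pos + nchar(del), nchar(cds)))
  }

  mt_full <- .translate_to_stop(mt_cds)
  runthrough <- attr(mt_full, "runthrough")
  mt <- as.character(mt_full)
  if (identical(mt, wt)) return(NULL)

  # span of differing/novel residues: strip common prefix, then suffix
  shared <- min(nchar(wt), nchar(mt))
  wt_chars <- strsplit(wt, "")[[1]]
  mt_chars <- strsplit(mt, "")[[1]]
  prefix <- 0
  while (prefix < shared && wt_chars[prefix + 1] == mt_chars[prefix + 1]) {
    prefix <- prefix + 1
  }
  frameshift <- variant$variant_type != "SNV" &&
    abs(nchar(gsub("-", "", ref)) - nchar(gsub("-", "", alt))) %% 3 != 0

  if (frameshift) {
    consequence <- "FRAMESHIFT"
    span <- c(prefix + 1, nchar(mt))
  } else if (variant$variant_type == "SNV") {
    if (nchar(mt) < nchar(wt)) {
      consequence <- "STOP_GAIN"
      span <- c(nchar(mt) + 1, nchar(mt) + 1)
    } else if (nchar(mt) > nchar(wt)) {
      consequence <- "STOP_LOSS"
      span <- c(nchar(wt) + 1, nchar(mt))
    } else {
      consequence <- "SUBSTITUTION"
      span <- c(prefix + 1, prefix + 1)
    }
  } else {
    consequence <- "IN_FRAME_INDEL"
    suffix <- 0
    while (suffix < shared - prefix &&
           wt_chars[nchar(wt) - suffix] == mt_chars[nchar(mt) - suffix]) {
      suffix <- suffix + 1
    }
    lo <- prefix + 1
    hi <- nchar(mt) - suffix
    if (hi < lo) hi <- lo  # pure deletion: junction residue
    span <- c(min(lo, nchar(mt)), min(hi, nchar(mt)))
  }

  structure(list(
    gene = as.character(transcript$gene),
    wt_protein = wt,
    mt_protein = mt,
    altered_span = as.integer(span),
    consequence = consequence,
    runthrough = isTRUE(runthrough)
  ), class = "mutant_protein_event")
}

#' Enumerate mutant peptide windows
#'
#' Slides windows of each requested length across the mutant protein and
#' keeps every window overlapping at least one altered residue. The
#' wild-type counterpart is the same-coordinate window of the unmutated
#' protein (for frameshifts it may share no residues with the mutant
#' window); windows are clipped at the protein termini and a wild-type
#' window falling off the wild-type terminus is reported as `NA`.
#'
#' @param event A `mutant_protein_event` from [apply_variant()].
#' @param lengths Window lengths, default `8:11`.
#' @return Data frame `start`, `length`, `wt_seq`, `mt_seq`.
#' @export
enumerate_peptides <- function(event, lengths = 8:11) {
  stopifnot(inherits(event, "mutant_protein_event"))
  L <- nchar(event$mt_protein)
  Lwt <- nchar(event$wt_protein)
  span <- event$altered_span
  out <- list()
  for (k in sort(unique(as.integer(lengths)))) {
    if (k > L) next
    s_min <- max(1L, span[1] - k + 1L)
    s_max <- min(span[2], L - k + 1L)
    if (s_max < s_min) next
    starts <- s_min:s_max
    mt <- substring(event$mt_protein, starts, starts + k - 1)
    wt <- ifelse(starts + k - 1 <= Lwt,
                 substring(event$wt_protein, starts, starts + k - 1),
                 NA_character_)
    out[[length(out) + 1]] <- data.frame(
      start = starts, length = k, wt_seq = wt, mt_seq = mt,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), length = integer(0),
                      wt_seq = character(0), mt_seq = character(0)))
  }
  do.call(rbind, out)
}

#' Build peptide pairs for a variant table
#'
#' Runs [apply_variant()] and [enumerate_peptides()] for every coding,
#' non-silent variant that has a transcript, and assembles candidate
#' mutant/wild-type pairs. Windows without a complete wild-type counterpart,
#' windows identical to wild type, and peptides containing stop or
#' ambiguous residues are dropped before scoring.
#'
#' @param variants Variant data frame (see [read_maf()]).
#' @param transcripts Transcript data frame (see [read_transcript_fasta()]).
#' @param lengths Peptide lengths, default `8:11`.
#' @param cds_offset Passed to [apply_variant()].
#' @return Data frame of peptide pairs: `pair_id` (gene|mt_seq), `gene`,
#'   `wt_seq`, `mt_seq`, `mutation_type` (`SNV`/`INDEL`), `foci`
#'   (comma-joined sample ids), `variant_id`, `length`, `start`.
#' @export
peptide_pairs <- function(variants, transcripts, lengths = 8:11,
                          cds_offset = 0) {
  .check_variants(variants)
  keep <- !(variants$variant_class %in% c("SILENT", "SPLICE_SITE"))
  variants <- variants[keep, , drop = FALSE]
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ti <- match(v$gene, transcripts$gene)
    if (is.na(ti)) next
    ev <- apply_variant(transcripts[ti, ], v, cds_offset = cds_offset)
    if (is.null(ev)) next
    win <- enumerate_peptides(ev, lengths = lengths)
    if (nrow(win) == 0) next
    ok <- !is.na(win$wt_seq) & win$wt_seq != win$mt_seq &
      !grepl("[^ACDEFGHIKLMNPQRSTVWY]", win$wt_seq) &
      !grepl("[^ACDEFGHIKLMNPQRSTVWY]", win$mt_seq)
    win <- win[ok, , drop = FALSE]
    if (nrow(win) == 0) next
    rows[[i]] <- data.frame(
      pair_id = paste(v$gene, win$mt_seq, sep = "|"),
      gene = v$gene,
      wt_seq = win$wt_seq,
      mt_seq = win$mt_seq,
      mutation_type = if (v$variant_type == "SNV") "SNV" else "INDEL",
      foci = v$sample_id,
      variant_id = v$variant_id,
      length = win$length,
      start = win$start,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(pair_id = character(0), gene = character(0),
                      wt_seq = character(0), mt_seq = character(0),
                      mutation_type = character(0), foci = character(0),
                      variant_id = character(0), length = integer(0),
                      start = integer(0))
  }
  rownames(res) <- NULL
  res
}

.union_foci <- function(foci_strings) {
  paste(sort(unique(unlist(strsplit(foci_strings, ",", fixed = TRUE)))),
        collapse = ",")
}

#' Remove repeated genes or peptides
#'
#' Collapses duplicate candidates. Under the default policy at most one pair
#' survives per (gene, mutant peptide); under `BY_PEPTIDE`, per mutant
#' peptide. Among duplicates the pair with the best (lowest) mutant
#' IC50 survives when an `ic50_mut` column is attached, otherwise the first
#' occurrence; foci sets of merged duplicates are unioned.
#'
#' @param pairs Peptide-pair data frame.
#' @param policy `"BY_GENE_AND_PEPTIDE"` (default) or `"BY_PEPTIDE"`.
#' @return The deduplicated pair data frame (first-occurrence order).
#' @export
deduplicate <- function(pairs, policy = c("BY_GENE_AND_PEPTIDE",
                                          "BY_PEPTIDE")) {
  policy <- match.arg(policy)
  if (nrow(pairs) == 0) return(pairs)
  key <- if (policy == "BY_GENE_AND_PEPTIDE") {
    paste(pairs$gene, pairs$mt_seq, sep = "\r")
  } else {
    pairs$mt_seq
  }
  idx <- split(seq_len(nrow(pairs)), key)
  survivors <- vapply(idx, function(ii) {
    if (length(ii) == 1) return(ii)
    if ("ic50_mut" %in% names(pairs) && !anyNA(pairs$ic50_mut[ii])) {
      ii[which.min(pairs$ic50_mut[ii])]
    } else {
      ii[1]
    }
  }, integer(1))
  merged_foci <- vapply(idx, function(ii) .union_foci(pairs$foci[ii]), "")
  out <- pairs[sort(survivors), , drop = FALSE]
  out$foci <- merged_foci[match(
    if (policy == "BY_GENE_AND_PEPTIDE")
      paste(out$gene, out$mt_seq, sep = "\r") else out$mt_seq,
    names(idx))]
  rownames(out) <- NULL
  out
}

#' Read a peptide-pair table
#'
#' TSV with columns `pair_id`, `gene`, `wt_seq`, `mt_seq`, `mutation_type`,
#' `foci` (comma-joined sample ids). Validates the pair invariants: lengths
#' 8-11, mutant differs from wild type, SNV pairs equal length.
#'
#' @param path TSV path.
#' @return Peptide-pair data frame.
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("pair_id", "gene", "wt_seq", "mt_seq", "mutation_type", "foci")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("pair table missing column(s): ", paste(miss, collapse = ", "))
  }
  tab$foci <- gsub("[[:space:]]", "", tab$foci)
  len <- nchar(tab$mt_seq)
  if (any(len < 8 | len > 11)) stop("mutant peptide length outside 8-11")
  if (any(tab$mt_seq == tab$wt_seq)) stop("mutant equals wild-type peptide")
  snv <- tab$mutation_type == "SNV"
  if (any(nchar(tab$wt_seq[snv]) != nchar(tab$mt_seq[snv]))) {
    stop("SNV pair with unequal wild-type/mutant lengths")
  }
  tab
}

#' Write peptide pairs as TSV
#' @param pairs Peptide-pair data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- intersect(c("pair_id", "gene", "wt_seq", "mt_seq", "mutation_type",
                      "foci", "variant_id", "length", "start"),
                    names(pairs))
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write candidate peptides as FASTA for external predictors
#'
#' One record per peptide; ids are `<pair_id>_MT` / `<pair_id>_WT`.
#'
#' @param pairs Peptide-pair data frame.
#' @param path Output FASTA path.
#' @param which `"both"` (default), `"mt"` or `"wt"`.
#' @return Invisibly, `path`.
#' @export
write_peptide_fasta <- function(pairs, path, which = c("both", "mt", "wt")) {
  which <- match.arg(which)
  seqs <- character(0)
  if (which %in% c("both", "mt")) {
    mt <- pairs$mt_seq
    names(mt) <- paste0(pairs$pair_id, "_MT")
    seqs <- c(seqs, mt)
  }
  if (which %in% c("both", "wt")) {
    wt <- pairs$wt_seq
    names(wt) <- paste0(pairs$pair_id, "_WT")
    seqs <- c(seqs, wt)
  }
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}
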