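# Codon-level helpers for building targeted fixtures
aa_to_codon <- c(W = "TGG", L = "CTG", T = "ACG", P = "CCT", V = "GTT",
                 I = "ATT", A = "GCT", M = "ATG", G = "GGT", S = "TCT")

cds_for <- function(protein) {
  paste0("ATG", paste(aa_to_codon[strsplit(protein, "")[[1]]],
                      collapse = ""), "TAA")
}

tx_for <- function(protein, gene = "GX") {
  cds <- cds_for(protein)
  list(gene = gene, cds = cds,
       protein = oracle_translate(cds))
}

snv <- function(pos, ref, alt, class = "MISSENSE") {
  data.frame(pos = pos, ref_allele = ref, alt_allele = alt,
             variant_type = "SNV", variant_class = class,
             stringsAsFactors = FALSE)
}

test_that("transcript FASTA reader enforces the CDS contract", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">GX|TX_GX", cds_for("WLTPVIPAL")), f)
  tx <- read_transcript_fasta(f)
  expect_equal(tx$gene, "GX")
  expect_equal(tx$protein, "MWLTPVIPAL")

  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">GY|TX_GY", "ATGTAATGG"), f2)  # internal stop, no terminal
  expect_error(read_transcript_fasta(f2), "malformed")
})

test_that("a substitution swaps one residue: WLTPVIPAL -> WLMPVIPAL", {
  tx <- tx_for("WLTPVIPAL")
  # T is residue 4 of MWLTPVIPAL; its codon ACG starts at CDS position 10;
  # ACG -> ATG (C>T at codon position 2) turns T into M
  ev <- apply_variant(tx, snv(11, "C", "T"))
  expect_equal(ev$consequence, "SUBSTITUTION")
  expect_equal(ev$mt_protein, "MWLMPVIPAL")
  expect_equal(ev$altered_span, c(4L, 4L))
})

test_that("synonymous codon changes yield no event", {
  tx <- tx_for("WLTPVIPAL")
  # CTG -> CTA still leucine (residue 3, CDS positions 7-9)
  ev <- apply_variant(tx, snv(9, "G", "A"))
  expect_null(ev)
})

test_that("variants outside the CDS and splice-site variants yield no event", {
  tx <- tx_for("WLTPVIPAL")
  expect_null(apply_variant(tx, snv(1000, "C", "T")))
  expect_null(apply_variant(tx, snv(11, "C", "T", class = "SPLICE_SITE")))
})

test_that("1-bp deletion re-translates like the independent oracle", {
  set.seed(7)
  for (i in 1:20) {
    cds <- oracle_random_cds(30)
    prot <- oracle_translate(cds)
    tx <- list(gene = "GD", cds = cds, protein = prot)
    pos <- sample(4:(nchar(cds) - 6), 1)
    v <- data.frame(pos = pos, ref_allele = substr(cds, pos, pos),
                    alt_allele = "-", variant_type = "DEL",
                    variant_class = "FRAMESHIFT_DEL",
                    stringsAsFactors = FALSE)
    ev <- apply_variant(tx, v)
    edited <- paste0(substr(cds, 1, pos - 1),
                     substr(cds, pos + 1, nchar(cds)))
    want <- oracle_translate(edited)
    if (is.null(ev)) {
      expect_equal(want, prot)
    } else {
      expect_equal(ev$mt_protein, want)
      expect_equal(ev$consequence, "FRAMESHIFT")
    }
  }
})

test_that("in-frame insertion adds residues and marks the novel span", {
  tx <- tx_for("WLTPVIPAL")
  # insert GGT (G) after CDS position 12 (between residues 4 and 5)
  v <- data.frame(pos = 12, ref_allele = "-", alt_allele = "GGT",
                  variant_type = "INS", variant_class = "IN_FRAME_INS",
                  stringsAsFactors = FALSE)
  ev <- apply_variant(tx, v)
  expect_equal(ev$consequence, "IN_FRAME_INDEL")
  expect_equal(ev$mt_protein, "MWLTGPVIPAL")
  expect_equal(ev$altered_span, c(5L, 5L))
})

test_that("window enumeration matches the brute-force window set", {
  set.seed(17)
  for (i in 1:50) {
    L <- sample(20:200, 1)
    p <- sample(1:L, 1)
    k <- sample(8:11, 1)
    if (k > L) next
    wt <- paste(sample(c("A", "C", "D", "E", "F"), L, replace = TRUE),
                collapse = "")
    mt <- wt
    substr(mt, p, p) <- "W"
    ev <- structure(list(gene = "G", wt_protein = wt, mt_protein = mt,
                         altered_span = c(p, p),
                         consequence = "SUBSTITUTION", runthrough = FALSE),
                    class = "mutant_protein_event")
    win <- enumerate_peptides(ev, lengths = k)
    expect_equal(win$start, oracle_window_starts(p, k, L))
    # every mutant window carries the substituted residue
    expect_true(all(vapply(seq_len(nrow(win)), function(j) {
      grepl("W", win$mt_seq[j], fixed = TRUE)
    }, logical(1))))
  }
})

test_that("interior substitutions give k windows; termini clip to fewer", {
  wt <- paste(rep("A", 200), collapse = "")
  mt <- wt; substr(mt, 50, 50) <- "W"
  ev <- structure(list(gene = "G", wt_protein = wt, mt_protein = mt,
                       altered_span = c(50L, 50L),
                       consequence = "SUBSTITUTION", runthrough = FALSE),
                  class = "mutant_protein_event")
  win9 <- enumerate_peptides(ev, lengths = 9)
  expect_equal(nrow(win9), 9)
  expect_equal(win9$start, 42:50)

  mt1 <- wt; substr(mt1, 1, 1) <- "W"
  ev1 <- structure(list(gene = "G", wt_protein = wt, mt_protein = mt1,
                        altered_span = c(1L, 1L),
                        consequence = "SUBSTITUTION", runthrough = FALSE),
                   class = "mutant_protein_event")
  win8 <- enumerate_peptides(ev1, lengths = 8)
  expect_equal(nrow(win8), 1)
  expect_equal(win8$start, 1)
})

test_that("SNV-derived pairs are equal length with Hamming distance 1", {
  set.seed(27)
  for (i in 1:10) {
    cds <- oracle_random_cds(60)
    prot <- oracle_translate(cds)
    tx <- list(gene = "GS", cds = cds, protein = prot)
    pos <- sample(7:(nchar(cds) - 6), 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ev <- apply_variant(tx, snv(pos, ref, alt))
    if (is.null(ev) || ev$consequence != "SUBSTITUTION") next
    win <- enumerate_peptides(ev)
    for (j in seq_len(nrow(win))) {
      expect_equal(nchar(win$wt_seq[j]), nchar(win$mt_seq[j]))
      d <- sum(strsplit(win$wt_seq[j], "")[[1]] !=
                 strsplit(win$mt_seq[j], "")[[1]])
      expect_equal(d, 1)
    }
  }
})

test_that("deduplication merges foci, keeps best scores, and is idempotent", {
  pairs <- data.frame(
    pair_id = c("a", "b", "c", "d", "e"),
    gene = c("G1", "G1", "G2", "G2", "G3"),
    wt_seq = rep("AAAAAAAA", 5),
    mt_seq = c("WAAAAAAA", "WAAAAAAA", "WAAAAAAA", "CAAAAAAA", "DAAAAAAA"),
    mutation_type = "SNV",
    foci = c("P4.1", "P4.2", "P4.1", "P4.1", "P4.3"),
    stringsAsFactors = FALSE
  )
  out <- deduplicate(pairs)
  expect_equal(nrow(out), 4)  # G1 duplicates collapse
  expect_equal(out$foci[out$gene == "G1"], "P4.1,P4.2")
  expect_equal(deduplicate(out), out)

  # BY_PEPTIDE collapses across genes too
  out2 <- deduplicate(pairs, policy = "BY_PEPTIDE")
  expect_equal(nrow(out2), 3)

  # score-aware survivor selection
  pairs$ic50_mut <- c(100, 20, 5, 1, 1)
  out3 <- deduplicate(pairs)
  expect_equal(out3$pair_id[out3$gene == "G1"], "b")

  # all-distinct input is untouched
  expect_equal(nrow(deduplicate(pairs[3:5, ])), 3)
})

test_that("the pair-table reader validates Table-2-style files", {
  pairs <- read_pair_table(extdata("table2_pairs.tsv"))
  expect_equal(nrow(pairs), 7)
  snvp <- pairs[pairs$mutation_type == "SNV", ]
  expect_equal(nrow(snvp), 4)
  for (j in seq_len(nrow(snvp))) {
    expect_equal(nchar(snvp$wt_seq[j]), nchar(snvp$mt_seq[j]))
  }
})
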