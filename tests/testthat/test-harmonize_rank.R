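test_that("the affinity transform inverts the log of the pre-score", {
  expect_equal(transform_b(10, "NETMHCPAN"), 1.0)
  expect_equal(transform_b(100, "NETMHCPAN"), 0.5)
  expect_equal(transform_b(500, "NETMHCPAN"), 1 / log10(500))
  # eluted-ligand and SYFPEITHI scores pass through untouched
  expect_equal(transform_b(0.93, "IEDB_EL"), 0.93)
  expect_equal(transform_b(21, "SYFPEITHI"), 21)
  # near-1 affinities are clamped, not exploded
  expect_warning(b <- transform_b(c(0.5, 10), "NETMHCPAN"), "clamped")
  expect_equal(b[1], 1 / log10(1.01))
  # configurable base only rescales
  expect_equal(transform_b(exp(2), "NETMHCPAN", log_base = exp(1)), 0.5)
})

test_that("fold change is wild-type over mutant pre-score", {
  expect_equal(fold_change(600, 300), 2.0)
  expect_equal(fold_change(7, 7), 1.0)
  expect_equal(fold_change(34.2, 342), 0.1)
  expect_error(fold_change(100, 0), "positive")
})

test_that("min-max rescaling hits the 1-20 contract exactly", {
  expect_equal(rescale_c(c(0.2, 0.5, 0.8)), c(1, 10.5, 20))
  expect_equal(rescale_c(c(7, 7, 7)), c(10.5, 10.5, 10.5))
  expect_equal(rescale_c(c(0.37, 1.0, 0.5)),
               c(1, 20, (0.5 - 0.37) / (1.0 - 0.37) * 19 + 1))
  expect_error(rescale_c(numeric(0)), "empty")
})

test_that("rescaling preserves order and endpoints over random batches", {
  set.seed(13)
  for (i in 1:200) {
    x <- runif(sample(2:40, 1), min = -50, max = 50)
    if (max(x) == min(x)) next
    cc <- rescale_c(x)
    expect_equal(min(cc), 1)
    expect_equal(max(cc), 20)
    expect_equal(order(cc), order(x))
  }
})

test_that("the a -> b -> c composition is monotone decreasing in a", {
  set.seed(23)
  for (i in 1:50) {
    a <- runif(sample(3:30, 1), min = 2, max = 40000)
    b <- transform_b(a, "NETMHCPAN")
    cc <- rescale_c(b)
    # stronger binder (smaller a) always ends up with the larger c
    expect_equal(order(cc, decreasing = TRUE), order(a))
  }
})

rank_fixture <- function(n, seed = 1) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mt <- replicate(n, paste(sample(aas, 9, replace = TRUE), collapse = ""))
  pairs <- data.frame(
    pair_id = sprintf("p%03d", seq_len(n)),
    gene = sprintf("G%03d", seq_len(n)),
    wt_seq = replicate(n, paste(sample(aas, 9, replace = TRUE),
                                collapse = "")),
    mt_seq = mt,
    mutation_type = "SNV",
    foci = sample(c("P4.1", "P4.1,P4.2", "P4.1,P4.3,P4.4"), n,
                  replace = TRUE),
    variant_id = sprintf("v%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  ic50_mut <- runif(n, 10, 480)
  calls <- data.frame(pair_id = pairs$pair_id, allele = "HLA-A*02:01",
                      ic50_wt = ic50_mut * runif(n, 2, 8),
                      ic50_mut = ic50_mut, is_high_binder = TRUE,
                      stringsAsFactors = FALSE)
  records <- rbind(
    data.frame(peptide = pairs$mt_seq, allele = "HLA-A*02:01",
               algorithm = "NETMHCPAN", pre_score_a = ic50_mut,
               direction = "LOWER_IS_BETTER", stringsAsFactors = FALSE),
    data.frame(peptide = pairs$wt_seq, allele = "HLA-A*02:01",
               algorithm = "NETMHCPAN", pre_score_a = calls$ic50_wt,
               direction = "LOWER_IS_BETTER", stringsAsFactors = FALSE),
    data.frame(peptide = pairs$mt_seq, allele = "HLA-A*02:01",
               algorithm = "SYFPEITHI",
               pre_score_a = round(36 - 7 * log10(ic50_mut)),
               direction = "HIGHER_IS_BETTER", stringsAsFactors = FALSE)
  )
  list(pairs = pairs, calls = calls, records = records)
}

test_that("top-n selection matches a full-sort-then-head oracle", {
  fx <- rank_fixture(50, seed = 2)
  rk <- select_top(fx$pairs, fx$calls, fx$records, n = 30)
  expect_equal(nrow(rk$table), 30)
  cut <- sort(fx$calls$ic50_mut)[31]
  expect_true(all(rk$table$ic50_mut < cut))
  # brute force on the whole batch: the selected sets agree
  want <- fx$calls$pair_id[order(fx$calls$ic50_mut)][1:30]
  expect_setequal(rk$table$pair_id, want)
  # returned ordering is by consensus, descending
  expect_true(all(diff(rk$table$consensus) <= 1e-12))
})

test_that("fewer available pairs than n returns them all", {
  fx <- rank_fixture(7, seed = 3)
  expect_message(rk <- select_top(fx$pairs, fx$calls, fx$records, n = 30),
                 "7 high-binder")
  expect_equal(nrow(rk$table), 7)
})

test_that("consensus mean ordering is shift-invariant across score columns", {
  cmat <- matrix(runif(15, 1, 20), 5, 3)
  base_order <- order(-rowMeans(cmat))
  shifted <- cmat + 3  # constant added to every column
  expect_equal(order(-rowMeans(shifted)), base_order)
})

test_that("the sharing screen returns exactly the multifocal candidates", {
  pairs <- read_pair_table(extdata("table2_pairs.tsv"))
  shared <- foci_distribution(pairs, min_foci = 2)
  expect_setequal(shared$table$pair_id, c("LUAD-1", "LUAD-6", "LUAD-7"))
  expect_setequal(shared$table$gene, c("TAS2R46", "UBQLN2", "NANOGNB"))

  # min_foci = 1 is the identity on pair sets
  all1 <- foci_distribution(pairs, min_foci = 1)
  expect_setequal(all1$table$pair_id, pairs$pair_id)

  # only the pan-focal candidate survives min_foci = 4
  all4 <- foci_distribution(pairs, min_foci = 4)
  expect_equal(all4$table$pair_id, "LUAD-1")
  expect_equal(sum(all4$presence["LUAD-1", ]), 4)
})
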