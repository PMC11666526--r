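test_that("MAF parsing maps classifications and keeps silent rows flagged", {
  res <- read_maf(extdata("tiny.maf"))
  expect_equal(nrow(res$variants), 2)
  v <- res$variants[1, ]
  expect_equal(v$gene, "NANOGNB")
  expect_equal(v$variant_class, "MISSENSE")
  expect_equal(v$sample_id, "P4.1")
  expect_equal(v$variant_type, "SNV")
  # one of the two rows is silent and drops out of the non-silent tally
  tal <- tally_variant_classes(res$variants, exclude_silent = TRUE)
  expect_equal(sum(tal$n), 1)
  expect_equal(res$foci$patient_id, "P4")
})

test_that("annotated VCF dialect parses INFO keys into the same model", {
  res <- read_maf(extdata("tiny.vcf"), dialect = "ANNOTATED_VCF")
  expect_equal(nrow(res$variants), 1)
  expect_equal(res$variants$gene, "NANOGNB")
  expect_equal(res$variants$variant_class, "MISSENSE")
  expect_equal(res$variants$sample_id, "P4.1")
  expect_equal(res$variants$protein_change, "p.T3M")
})

test_that("an empty variant section with a valid header parses to zero rows", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(paste("Hugo_Symbol", "Chromosome", "Start_Position",
                   "Reference_Allele", "Tumor_Seq_Allele2",
                   "Variant_Classification", "Variant_Type",
                   "Tumor_Sample_Barcode", sep = "\t"), f)
  res <- read_maf(f)
  expect_equal(nrow(res$variants), 0)
})

test_that("format errors name the missing column or the bad vocabulary", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tChromosome", "TP53\tchr17"), f)
  expect_error(read_maf(f), "Variant_Classification")
  f2 <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(paste("Hugo_Symbol", "Chromosome", "Start_Position",
                     "Reference_Allele", "Tumor_Seq_Allele2",
                     "Variant_Classification", "Variant_Type",
                     "Tumor_Sample_Barcode", sep = "\t"),
               paste("TP53", "chr17", "10", "C", "T", "Weird_Class", "SNP",
                     "S1", sep = "\t")), f2)
  expect_error(read_maf(f2), "Weird_Class")
})

test_that("class tallies give the expected proportions and conserve counts", {
  v <- make_variants(c(rep("MISSENSE", 754), rep("NONSENSE", 146),
                       rep("FRAMESHIFT_DEL", 100)))
  tal <- tally_variant_classes(v)
  expect_equal(tal$proportion[tal$variant_class == "MISSENSE"], 0.754)
  expect_equal(sum(tal$n), 1000)
  expect_equal(sum(tal$proportion), 1)

  single <- make_variants("MISSENSE")
  expect_equal(tally_variant_classes(single)$proportion[1], 1.0)

  # conservation with silent exclusion
  v2 <- make_variants(c("MISSENSE", "SILENT", "NONSENSE"))
  tal2 <- tally_variant_classes(v2, exclude_silent = TRUE)
  expect_equal(sum(tal2$n), 2)
})

test_that("six-class spectrum collapses onto the pyrimidine reference", {
  v <- make_variants(rep("MISSENSE", 5), ref = c("G", "G", "G", "C", "C"),
                     alt = c("A", "A", "A", "T", "T"))
  sp <- snv_six_class_spectrum(v, by_sample = FALSE)
  expect_equal(sp$proportion[sp$snv_class == "C>T"], 1.0)

  v2 <- make_variants(rep("MISSENSE", 2), ref = c("C", "T"), alt = c("T", "C"))
  sp2 <- snv_six_class_spectrum(v2, by_sample = FALSE)
  expect_equal(sp2$proportion[sp2$snv_class %in% c("C>T", "T>C")],
               c(0.5, 0.5))
})

test_that("complement collapse is idempotent", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 200, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  v <- make_variants(rep("MISSENSE", 200), ref = ref, alt = alt)
  sp1 <- snv_six_class_spectrum(v, by_sample = FALSE)
  # feed the collapsed classes back in as variants: collapse again
  v2 <- make_variants(rep("MISSENSE", sum(sp1$n)),
                      ref = rep(substr(sp1$snv_class, 1, 1), sp1$n),
                      alt = rep(substr(sp1$snv_class, 3, 3), sp1$n))
  sp2 <- snv_six_class_spectrum(v2, by_sample = FALSE)
  expect_equal(sp2$n, sp1$n)
})

test_that("TMB is mutations per megabase, split additively by origin", {
  v <- make_variants(rep("MISSENSE", 76))
  tmb <- compute_tmb(v, interrogated_mb = 38)
  expect_equal(tmb$tmb_total, 2.0)

  v0 <- make_variants("SILENT")
  expect_equal(compute_tmb(v0, 38)$tmb_total, 0.0)

  expect_error(compute_tmb(v, interrogated_mb = 0), "positive")

  # additivity on random fixtures
  set.seed(21)
  for (i in 1:5) {
    cls <- sample(setdiff(VARIANT_CLASSES, "SILENT"), 50, replace = TRUE)
    v <- make_variants(cls, sample_id = sample(c("A", "B"), 50,
                                               replace = TRUE))
    tmb <- compute_tmb(v, 7)
    expect_equal(tmb$tmb_snv + tmb$tmb_indel, tmb$tmb_total)
  }
})

test_that("gene ranking orders by samples mutated with documented tie-breaks", {
  v <- make_variants(rep("MISSENSE", 4),
                     sample_id = c("S1", "S2", "S3", "S1"),
                     gene = c("geneA", "geneA", "geneA", "geneB"))
  rk <- rank_genes(v, n = 10)
  expect_equal(rk$ranking$gene, c("geneA", "geneB"))

  # tie at 2 samples each; geneB has 3 total variants vs geneA's 2
  v2 <- make_variants(rep("MISSENSE", 5),
                      sample_id = c("S1", "S2", "S1", "S1", "S2"),
                      gene = c("geneA", "geneA", "geneB", "geneB", "geneB"))
  rk2 <- rank_genes(v2, n = 2)
  expect_equal(rk2$ranking$gene, c("geneB", "geneA"))
})

test_that("gene ranking agrees with a brute-force sort on small cohorts", {
  set.seed(31)
  for (i in 1:5) {
    v <- make_variants(rep("MISSENSE", 120),
                       sample_id = sample(paste0("S", 1:6), 120,
                                          replace = TRUE),
                       gene = sample(sprintf("G%02d", 1:20), 120,
                                     replace = TRUE))
    rk <- rank_genes(v, n = 20)
    # independent comparator: aggregate + order()
    agg <- aggregate(cbind(one = rep(1, nrow(v))) ~ gene + sample_id, v, sum)
    ns <- tapply(agg$sample_id, agg$gene, function(x) length(unique(x)))
    nv <- tapply(v$gene, v$gene, length)
    genes <- names(ns)
    ord <- genes[order(-ns, -nv[genes], genes)]
    expect_equal(rk$ranking$gene, unname(ord))
  }
})

test_that("cross-patient consistency requires every patient and one class", {
  foci <- data.frame(sample_id = paste0("P", 1:4),
                     patient_id = paste0("P", 1:4))
  v <- make_variants(rep("MISSENSE", 4), sample_id = paste0("P", 1:4),
                     gene = "BCLAF1")
  hit <- consistent_genes_across_patients(v, foci)
  expect_equal(hit$gene, "BCLAF1")
  expect_equal(hit$variant_class, "MISSENSE")

  # class mismatch in one patient excludes the gene
  v$variant_class[4] <- "FRAMESHIFT_DEL"
  v$variant_type[4] <- "DEL"
  expect_equal(nrow(consistent_genes_across_patients(v, foci)), 0)
})

test_that("consistency screen matches an exhaustive set-intersection oracle", {
  set.seed(41)
  foci <- data.frame(sample_id = paste0("P", 1:4),
                     patient_id = paste0("P", 1:4))
  for (rep in 1:5) {
    n <- 60
    v <- make_variants(sample(c("MISSENSE", "NONSENSE"), n, replace = TRUE),
                       sample_id = sample(paste0("P", 1:4), n, replace = TRUE),
                       gene = sample(sprintf("G%02d", 1:10), n,
                                     replace = TRUE))
    got <- consistent_genes_across_patients(v, foci)$gene
    want <- character(0)
    for (g in unique(v$gene)) {
      sub <- v[v$gene == g, ]
      if (length(unique(sub$sample_id)) == 4 &&
          length(unique(sub$variant_class)) == 1) {
        want <- c(want, g)
      }
    }
    expect_setequal(got, want)
  }
})

test_that("cohort metadata round-trips and malformed HLA strings are refused", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpatient_id\tstage\thla_alleles",
               "P4.1\tP4\tINVASIVE\tHLA-A*02:01;HLA-A*33:03",
               "P4.2\tP4\tPRE_INVASIVE\tHLA-A*02:01;HLA-A*33:03"), f)
  co <- read_cohort(f)
  expect_equal(nrow(co$foci), 2)
  expect_equal(co$patients$hla_alleles[[1]], c("HLA-A*02:01", "HLA-A*33:03"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpatient_id\tstage\thla_alleles",
               "P1\tP1\tINVASIVE\tHLA-A02:01"), f2)
  expect_error(read_cohort(f2), "HLA")
})
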