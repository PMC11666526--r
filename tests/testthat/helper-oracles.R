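# Independent oracles, deliberately not sharing code with the package.

# hand-typed standard codon table (NCBI table 1)
ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# translate until (and excluding) the first stop; codon-by-codon lookup
oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  out <- character(0)
  for (i in seq_len(n)) {
    aa <- ORACLE_CODON[[substr(dna, 3 * i - 2, 3 * i)]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# brute-force window starts for a substitution at position p, length k,
# protein length L
oracle_window_starts <- function(p, k, L) {
  s <- seq_len(L)
  s[s <= p & s + k - 1 >= p & s + k - 1 <= L]
}

# random toy CDS over the oracle's codon table
oracle_random_cds <- function(n_codons) {
  body <- sample(names(ORACLE_CODON)[ORACLE_CODON != "*"], n_codons - 2,
                 replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

# quick variant-table builder for tally/burden tests
make_variants <- function(classes,
                          sample_id = "S1",
                          type = NULL,
                          gene = NULL,
                          ref = "C", alt = "T") {
  n <- length(classes)
  indel <- grepl("DEL$|INS$", classes) & grepl("FRAME", classes) |
    classes %in% c("IN_FRAME_DEL", "IN_FRAME_INS", "FRAMESHIFT_DEL",
                   "FRAMESHIFT_INS")
  if (is.null(type)) {
    type <- ifelse(classes %in% c("FRAMESHIFT_DEL", "IN_FRAME_DEL"), "DEL",
                   ifelse(classes %in% c("FRAMESHIFT_INS", "IN_FRAME_INS"),
                          "INS", "SNV"))
  }
  v <- data.frame(
    sample_id = rep_len(sample_id, n),
    gene = if (is.null(gene)) sprintf("G%03d", seq_len(n)) else
      rep_len(gene, n),
    chrom = "chr1",
    pos = seq_len(n) * 10L,
    ref_allele = rep_len(ref, n),
    alt_allele = rep_len(alt, n),
    variant_class = classes,
    variant_type = type,
    protein_change = NA_character_,
    stringsAsFactors = FALSE
  )
  v$variant_id <- paste(v$sample_id, v$gene, v$pos, sep = ":")
  v
}

extdata <- function(f) system.file("extdata", f, package = "neoscreen")
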