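# The standard genetic code, written out independently as the oracle for
# everything codon-level.
STD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

test_that("the genetic code used by the package matches the standard code", {
  census <- cpg_ct_codon_census()
  expect_equal(unname(STD_CODE[census$ref_codon]), census$ref_aa)
  expect_equal(unname(STD_CODE[census$alt_codon]), census$alt_aa)
})

test_that("worked codon examples: CGA>TGA, Glu>Lys, wobble silent", {
  # genome: one plus-strand transcript CGA GAA GGC, with C before it so
  # the GAA's G (pos 4) sits in a minus-strand CpG (5' C)
  g <- Biostrings::DNAStringSet(c(k = "TTCGAGAAGGCTT"))
  cds <- GenomicRanges::GRanges("k", IRanges::IRanges(3, 11), strand = "+")
  cds$transcript <- "t1"
  mk <- function(pos, ref, alt) {
    data.frame(contig = "k", pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
  # CGA codon, C>T at position 1 -> TGA nonsense (Arg -> stop), CpG context
  e <- annotate_coding(mk(3L, "C", "T"), cds, g)
  expect_equal(e$ref_codon, "CGA")
  expect_equal(e$alt_codon, "TGA")
  expect_equal(e$effect, "nonsense")
  expect_equal(e$ref_aa, "R")
  expect_true(e$is_cpg_ct)
  # GAA (Glu), G>A at codon position 1 with 5' C -> AAA, Glu -> Lys;
  # needs the previous codon to end in C: GCC GAA GGC
  g2 <- Biostrings::DNAStringSet(c(k = "TTGCCGAAGGCTT"))
  e <- annotate_coding(mk(6L, "G", "A"), cds, g2)
  expect_equal(e$ref_codon, "GAA")
  expect_equal(e$alt_codon, "AAA")
  expect_equal(e$ref_aa, "E")
  expect_equal(e$alt_aa, "K")
  expect_equal(e$effect, "missense")
  expect_true(e$is_cpg_ct)   # CpG on the minus strand
  # third-position GGC>GGT is silent
  e <- annotate_coding(mk(11L, "C", "T"), cds, g)
  expect_equal(e$ref_codon, "GGC")
  expect_equal(e$alt_codon, "GGT")
  expect_equal(e$effect, "silent")
})

test_that("census: CGA>TGA is the unique coding-strand CpG nonsense", {
  census <- cpg_ct_codon_census()
  # independent brute force over codons x positions, stop set {TAA,TAG,TGA}
  stops <- c("TAA", "TAG", "TGA")
  oracle <- character(0)
  for (codon in names(STD_CODE)) {
    b <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      if (b[p] != "C") next
      if (p < 3 && b[p + 1] != "G") next   # p == 3: flank G possible
      alt <- b; alt[p] <- "T"
      altc <- paste(alt, collapse = "")
      if (altc %in% stops && STD_CODE[codon] != "*") {
        oracle <- c(oracle, paste(codon, altc))
      }
    }
  }
  expect_equal(oracle, "CGA TGA")
  cen_nons <- census[census$strand_of_c == "coding" &
                       census$effect == "nonsense", ]
  expect_equal(nrow(cen_nons), 1L)
  expect_equal(cen_nons$ref_codon, "CGA")
  expect_equal(cen_nons$alt_codon, "TGA")
})

test_that("census structure: Arg codons, single-position changes", {
  census <- cpg_ct_codon_census()
  # all four CGN arginine codons are CpG at positions 1-2: first-position
  # C>T entries exist with no flank requirement
  cgn <- census[census$strand_of_c == "coding" & census$codon_pos == 1 &
                  census$required_flank == "none", ]
  expect_true(all(c("CGA", "CGC", "CGG", "CGT") %in% cgn$ref_codon))
  expect_true(all(STD_CODE[grep("^CG", names(STD_CODE), value = TRUE)] == "R"))
  # no entry differs from its ref codon at more than one position
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, census$ref_codon, census$alt_codon)
  expect_true(all(diffs == 1L))
})

test_that("annotate_coding agrees with the census on a synthetic CDS", {
  census <- cpg_ct_codon_census()
  for (i in seq_len(nrow(census))) {
    en <- census[i, ]
    b <- strsplit(en$ref_codon, "")[[1]]
    # two-codon transcript; second codon chosen to satisfy the flank
    codon2 <- switch(en$required_flank,
                     "next codon starts with G" = "GGG", "AAA")
    lead <- if (en$required_flank == "previous codon ends with C") {
      "GCC"   # previous codon ends with C
    } else "AAA"
    seqs <- paste0("TT", lead, en$ref_codon, codon2, "TT")
    g <- Biostrings::DNAStringSet(stats::setNames(seqs, "z"))
    cds <- GenomicRanges::GRanges("z", IRanges::IRanges(3, 11),
                                  strand = "+")
    cds$transcript <- "t"
    pos <- 5L + en$codon_pos   # variant inside the middle codon
    ref <- b[en$codon_pos]
    alt <- if (en$strand_of_c == "coding") "T" else "A"
    d <- data.frame(contig = "z", pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
    e <- annotate_coding(d, cds, g)
    expect_equal(e$ref_codon, en$ref_codon, info = paste("entry", i))
    expect_equal(e$alt_codon, en$alt_codon, info = paste("entry", i))
    expect_equal(e$effect, en$effect, info = paste("entry", i))
    expect_true(e$is_cpg_ct, info = paste("entry", i))
  }
})

test_that("minus-strand annotation equals the plus-strand construction", {
  # plus-strand gene: CGA GAA GGC at 3..11 of a 13-mer
  s <- "TTCGAGAAGGCTT"
  g_plus <- Biostrings::DNAStringSet(c(m = s))
  cds_plus <- GenomicRanges::GRanges("m", IRanges::IRanges(3, 11),
                                     strand = "+")
  cds_plus$transcript <- "t"
  # same gene encoded on the minus strand of the reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  g_minus <- Biostrings::DNAStringSet(c(m = rc))
  L <- nchar(s)
  cds_minus <- GenomicRanges::GRanges(
    "m", IRanges::IRanges(L - 11 + 1, L - 3 + 1), strand = "-")
  cds_minus$transcript <- "t"
  d_plus <- data.frame(contig = "m", pos = 3L, ref = "C", alt = "T",
                       stringsAsFactors = FALSE)
  d_minus <- data.frame(contig = "m", pos = L - 3 + 1L, ref = "G",
                        alt = "A", stringsAsFactors = FALSE)
  e1 <- annotate_coding(d_plus, cds_plus, g_plus)
  e2 <- annotate_coding(d_minus, cds_minus, g_minus)
  for (col in c("ref_codon", "alt_codon", "ref_aa", "alt_aa", "effect",
                "codon_index")) {
    expect_equal(e2[[col]], e1[[col]], info = col)
  }
})

test_that("frame validation and genome/CDS consistency errors", {
  g <- Biostrings::DNAStringSet(c(m = "TTCGAGAAGGCTT"))
  cds <- GenomicRanges::GRanges("m", IRanges::IRanges(3, 11), strand = "+")
  cds$transcript <- "t"
  cds$frame <- 1L   # wrong: single exon must start in frame 0
  d <- data.frame(contig = "m", pos = 3L, ref = "C", alt = "T",
                  stringsAsFactors = FALSE)
  expect_error(annotate_coding(d, cds, g), "inconsistent frame")
})

test_that("summarize_effects: severity collapse, conservation, Arg share", {
  eff <- rbind(
    data.frame(contig = "c", pos = 1L, ref = "C", alt = "T",
               transcript = c("a", "b"), codon_index = 1L, codon_pos = 1L,
               ref_codon = "CGA", alt_codon = c("TGA", "CCA"),
               ref_aa = "R", alt_aa = c("*", "P"),
               effect = c("nonsense", "missense"), is_cpg_ct = TRUE,
               stringsAsFactors = FALSE),
    data.frame(contig = "c", pos = 9L, ref = "C", alt = "T",
               transcript = "a", codon_index = 3L, codon_pos = 3L,
               ref_codon = "GGC", alt_codon = "GGT", ref_aa = "G",
               alt_aa = "G", effect = "silent", is_cpg_ct = TRUE,
               stringsAsFactors = FALSE)
  )
  s <- summarize_effects(eff)
  # the double-annotated variant counts once, as nonsense
  expect_equal(unname(s$counts), c(1L, 0L, 1L))
  expect_equal(s$n_total, 2L)
  expect_equal(sum(s$counts), s$n_total)
  expect_equal(s$arg_fraction, 0.5)
  s0 <- summarize_effects(eff[0, ])
  expect_equal(s0$n_total, 0L)
})
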