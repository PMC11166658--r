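test_that("classification follows the strand-collapse definition", {
  g <- Biostrings::DNAStringSet(c(x = "ACGTTCAGCA"))
  #        1234567890:  A C G T T C A G C A
  cls <- function(pos, ref, alt) {
    d <- data.frame(contig = "x", pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
    classify_calls(g, d)
  }
  # plus-strand C>T with next base G -> CpG
  r <- cls(2L, "C", "T")
  expect_equal(r$mut_class, "C>T")
  expect_equal(r$three_prime_base, "G")
  expect_true(r$is_cpg)
  # plus-strand G>A with previous base C: reverse complement by hand gives
  # C>T with 3' neighbor G (CpG on the minus strand)
  r <- cls(3L, "G", "A")
  expect_equal(r$mut_class, "C>T")
  expect_equal(r$three_prime_base, "G")
  expect_true(r$is_cpg)
  # plus-strand C>T with next base A -> non-CpG
  r <- cls(6L, "C", "T")
  expect_equal(r$mut_class, "C>T")
  expect_equal(r$three_prime_base, "A")
  expect_false(r$is_cpg)
  # purine transversion with 5' A: G>T at pos 8 -> C>A, neighbor comp(A)=T
  r <- cls(8L, "G", "T")
  expect_equal(r$mut_class, "C>A")
  expect_equal(r$three_prime_base, "T")
})

test_that("N or missing context is excluded, not misclassified", {
  g <- Biostrings::DNAStringSet(c(x = "CNCGT"))
  d <- data.frame(contig = "x", pos = c(1L, 5L, 3L),
                  ref = c("C", "T", "C"), alt = c("T", "A", "T"),
                  stringsAsFactors = FALSE)
  r <- classify_calls(g, d)
  expect_true(is.na(r$mut_class[1]))    # 3' neighbor is N
  expect_true(is.na(r$mut_class[2]))    # pyrimidine at contig end
  expect_equal(r$mut_class[3], "C>T")   # CG context fine
  expect_equal(attr(r, "n_excluded_context"), 2L)
})

test_that("collapsed dinucleotide abundance matches manual enumeration", {
  # "CG" is its own reverse complement: both strands contribute
  expect_equal(count_dinucleotide_abundance(
    Biostrings::DNAStringSet(c(a = "CG")))["C", "G"], 2)
  # "CA": plus strand C.A; minus strand reads TG
  ab <- count_dinucleotide_abundance(Biostrings::DNAStringSet(c(a = "CA")))
  expect_equal(ab["C", "A"], 1)
  expect_equal(ab["T", "G"], 1)
  expect_equal(sum(ab), 2)
  # additivity under concatenation (two contigs: no boundary term)
  g1 <- session_genome()
  g2 <- c(g1, stats::setNames(g1, "dup"))
  expect_equal(count_dinucleotide_abundance(g2),
               2 * count_dinucleotide_abundance(g1))
})

test_that("normalized rate arithmetic and degenerate cells", {
  g <- session_genome()
  mut <- simulate_mutations(g, rate_table(), 400, seed = 12)
  sp <- build_spectrum(g, classify_calls(g, mut))
  expect_equal(sum(sp$counts), 400L)
  ab <- count_dinucleotide_abundance(g)
  expect_equal(sp$rate["C>T", "G"],
               sp$counts["C>T", "G"] / ab["C", "G"] * 1e9)
  # empty call list -> all zero
  sp0 <- build_spectrum(g, classify_calls(g, mut[0, ]))
  expect_true(all(sp0$counts == 0L))
  expect_true(all(sp0$rate == 0, na.rm = TRUE))
  # zero-abundance context with nonzero count is an inconsistency error
  g_nocg <- Biostrings::DNAStringSet(c(x = "CACACACACA"))
  calls <- data.frame(contig = "x", pos = 3L, ref = "C", alt = "T",
                      mut_class = "C>T", three_prime_base = "G",
                      is_cpg = TRUE, stringsAsFactors = FALSE)
  expect_error(build_spectrum(g_nocg, calls), "zero genomic abundance")
})

test_that("every classified call lands in exactly one of 24 cells", {
  g <- session_genome()
  mut <- simulate_mutations(g, rate_table(), 1000, seed = 13)
  cls <- classify_calls(g, mut)
  sp <- build_spectrum(g, cls)
  expect_equal(sum(sp$counts) + sp$n_excluded_context, nrow(mut))
})

test_that("spectrum is invariant under reverse complement of the genome", {
  g1 <- session_genome()
  s <- as.character(g1[[1]])
  L <- nchar(s)
  g_rc <- Biostrings::DNAStringSet(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  names(g_rc) <- names(g1)[1]
  mut <- simulate_mutations(g1, rate_table(), 800, seed = 14)
  sp1 <- build_spectrum(g1, classify_calls(g1, mut))
  mut_rc <- mut[, c("contig", "pos", "ref", "alt")]
  mut_rc$pos <- L - mut$pos + 1L
  mut_rc$ref <- chartr("ACGT", "TGCA", mut$ref)
  mut_rc$alt <- chartr("ACGT", "TGCA", mut$alt)
  sp2 <- build_spectrum(g_rc, classify_calls(g_rc, mut_rc))
  expect_equal(sp2$counts, sp1$counts)
  expect_equal(sp2$abundance, sp1$abundance)
  expect_lt(max(abs(sp2$rate - sp1$rate) / pmax(sp1$rate, 1e-12)), 1e-6)
})

test_that("duplicating genome and calls leaves normalized rates unchanged", {
  g1 <- session_genome()
  g2 <- c(g1, stats::setNames(g1, "dup"))
  mut <- simulate_mutations(g1, rate_table(), 600, seed = 15)
  mut_dup <- mut
  mut_dup$contig <- "dup"
  sp1 <- build_spectrum(g1, classify_calls(g1, mut))
  sp2 <- build_spectrum(g2, classify_calls(g2, rbind(mut, mut_dup)))
  expect_lt(max(abs(sp2$rate - sp1$rate) / pmax(sp1$rate, 1e-12)), 1e-6)
})

test_that("cpg_partition counts and percentages are consistent", {
  g <- session_genome()
  mut <- simulate_mutations(g, rate_table(), 500, seed = 16)
  part <- cpg_partition(classify_calls(g, mut))
  ct_total <- sum(mut$mut_class == "C>T")
  expect_equal(part$n_ct_cpg + part$n_ct_noncpg, ct_total)
  expect_equal(part$pct_ct_cpg, 100 * part$n_ct_cpg / part$n_total)
  # all-CpG and no-C>T corner cases
  all_cpg <- classify_calls(g, mut)[classify_calls(g, mut)$is_cpg &
    classify_calls(g, mut)$mut_class == "C>T", ]
  expect_equal(cpg_partition(all_cpg)$pct_ct_cpg, 100)
  no_ct <- classify_calls(g, mut)
  no_ct <- no_ct[no_ct$mut_class != "C>T", ]
  p0 <- cpg_partition(no_ct)
  expect_equal(p0$pct_ct_cpg, 0)
  expect_equal(p0$pct_ct_noncpg, 0)
})

test_that("partition correlation: perfect, degenerate, and biphasic cases", {
  mk <- function(n_total, pct_cpg, pct_non) {
    list(n_total = n_total, n_ct_cpg = round(n_total * pct_cpg / 100),
         n_ct_noncpg = round(n_total * pct_non / 100),
         pct_ct_cpg = pct_cpg, pct_ct_noncpg = pct_non)
  }
  up <- lapply(1:5, function(i) mk(100 * i, 5 + i, 10))
  expect_equal(correlate_partition(up)$r_cpg, 1)
  flat <- lapply(1:5, function(i) mk(100 * i, 7, 7))
  r <- correlate_partition(flat)
  expect_true(is.na(r$r_cpg))
  expect_true(r$degenerate)
  # biphasic cohort: fixed CpG C>T count, deamination load growing with
  # total burden -> positive non-CpG correlation, negative CpG correlation
  biph <- lapply(1:10, function(i) {
    n <- 100 + 150 * i
    mk(n, 100 * 30 / n, 100 * (0.4 * n - 30) / n)
  })
  r <- correlate_partition(biph)
  expect_gt(r$r_noncpg, 0)
  expect_lt(r$r_cpg, 0)
  expect_error(correlate_partition(flat[1:2]), "at least 3")
})
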