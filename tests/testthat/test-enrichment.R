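simple_ann <- function() {
  annotation_set(
    repeats = {
      gr <- GenomicRanges::GRanges(
        "c1", IRanges::IRanges(c(100, 300, 500), width = 50))
      gr$class <- c("SINE", "LINE", "LTR")
      gr$subfamily <- c("AluY", "L1PA", "ERVK")
      gr
    },
    cgi = GenomicRanges::GRanges("c1", IRanges::IRanges(20000, 21000)),
    tss = GenomicRanges::GRanges("c1", IRanges::IRanges(1000, 1000),
                                 strand = "+"),
    dmr = GenomicRanges::GRanges("c1", IRanges::IRanges(40000, 42000)),
    cds = {
      gr <- GenomicRanges::GRanges(
        "c1", IRanges::IRanges(c(60000, 60200), width = c(90, 60)),
        strand = "+")
      gr$transcript <- "t1"
      gr
    }
  )
}

pt <- function(pos, contig = "c1") {
  data.frame(contig = contig, pos = as.integer(pos), ref = "C", alt = "T",
             mut_class = "C>T", three_prime_base = "G", is_cpg = TRUE,
             stringsAsFactors = FALSE)
}

test_that("compartment assignment: CDS > intron > intergenic, flags free", {
  ann <- simple_ann()
  d <- pt(c(60010, 60150, 125, 5))
  r <- assign_regions(d, ann)
  expect_equal(r$compartment, c("CDS", "intron", "intergenic", "intergenic"))
  expect_equal(r$in_sine, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(r$repeat_subfamily, c(NA, NA, "AluY", NA))
  # partition property
  expect_equal(sum(table(r$compartment)), nrow(d))
  # a variant can carry several flags but one compartment
  ann2 <- ann
  ann2$cgi <- GenomicRanges::GRanges("c1", IRanges::IRanges(100, 160))
  r2 <- assign_regions(pt(125), ann2)
  expect_true(r2$in_sine & r2$in_cgi)
  expect_equal(r2$compartment, "intergenic")
})

test_that("overlapping repeats: longest-overlap subfamily wins", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(100, 90), c(150, 400)))
  gr$class <- c("SINE", "SINE")
  gr$subfamily <- c("AluY", "AluSx")
  ann <- annotation_set(repeats = gr)
  r <- assign_regions(pt(120), ann)
  expect_equal(r$repeat_subfamily, "AluSx")  # the 311-bp interval
  expect_true(r$in_sine)
})

test_that("CGI shore boundaries at +/- 5 kb", {
  ann <- simple_ann()   # CGI at 20000-21000
  d <- pt(c(20500, 19999, 21001, 26000, 26001, 15000, 14999))
  r <- assign_regions(d, ann)
  expect_equal(r$in_cgi, c(TRUE, rep(FALSE, 6)))
  expect_equal(r$in_cgi_shore,
               c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  cnt <- cgi_shore_counts(d, ann)
  expect_equal(cnt$n_cgi, 1L)
  expect_equal(cnt$n_shore, 4L)
})

test_that("TSS distances: exact values and brute-force oracle", {
  ann <- simple_ann()   # single TSS at 1000
  prof <- tss_distance_profile(pt(c(1000, 1500)), ann)
  expect_equal(attr(prof, "distances"), c(0, 500))
  # oracle: nearest over many TSSs by exhaustive scan
  set.seed(31)
  tss_pos <- sort(sample.int(5e5, 200))
  ann2 <- annotation_set(tss = GenomicRanges::GRanges(
    "c1", IRanges::IRanges(tss_pos, width = 1), strand = "+"))
  calls <- pt(sample.int(5e5, 1000))
  d_pkg <- attr(tss_distance_profile(calls, ann2), "distances")
  d_oracle <- vapply(calls$pos,
                     function(p) min(abs(p - tss_pos)), numeric(1))
  expect_equal(d_pkg, d_oracle)
  expect_error(tss_distance_profile(calls, annotation_set()), "TSS track")
})

test_that("two-proportion Z-test: hand values and symmetry", {
  r0 <- z_test_two_proportions(30, 100, 30, 100)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)
  # hand computation of the pooled formula:
  # p = 0.4; z = 0.2 / sqrt(0.4*0.6*(0.02)) = 2.886751
  r <- z_test_two_proportions(50, 100, 30, 100)
  expect_equal(r$z, 0.2 / sqrt(0.4 * 0.6 * 0.02), tolerance = 1e-12)
  expect_equal(r$z, 2.886751, tolerance = 1e-6)
  r_sw <- z_test_two_proportions(30, 100, 50, 100)
  expect_equal(r_sw$z, -r$z)
  expect_equal(r_sw$p_value, r$p_value)
  expect_true(z_test_two_proportions(0, 10, 0, 10)$degenerate)
})

test_that("retrotransposon percentages: support and both denominators", {
  ann <- simple_ann()
  d <- rbind(pt(c(110, 120)),                 # CpG C>T in SINE
             within(pt(700), is_cpg <- FALSE))  # non-CpG C>T outside
  r <- retrotransposon_rates(d, ann)
  sine <- r[r$class == "SINE", ]
  expect_equal(sine$pct_of_status_cpg, 100)
  expect_equal(sine$pct_of_status_noncpg, 0)
  expect_equal(sine$pct_of_all_cpg, 100 * 2 / 3)
  expect_error(retrotransposon_rates(d, annotation_set()), "repeat track")
})

test_that("DMR ratio: null, enriched, and empty cases", {
  g <- session_genome()
  ann <- generate_annotations(g, seed = 41)
  # enumerate CpG cytosine sites independently of the package internals
  s <- as.character(g[[1]])
  cg_plus <- as.integer(gregexpr("CG", s)[[1]])
  cpg_sites <- sort(c(cg_plus, cg_plus + 1L))
  dmr <- ann$dmr
  in_dmr <- rep(FALSE, length(cpg_sites))
  for (k in seq_along(dmr)) {
    in_dmr <- in_dmr | (cpg_sites >= GenomicRanges::start(dmr)[k] &
                          cpg_sites <= GenomicRanges::end(dmr)[k])
  }
  draw_calls <- function(w_in) {
    w <- ifelse(in_dmr, w_in, 1)
    idx <- sample(seq_along(cpg_sites), 600, prob = w / sum(w))
    p <- cpg_sites[idx]
    ref <- substring(s, p, p)
    data.frame(contig = names(g)[1], pos = p, ref = ref,
               alt = ifelse(ref == "C", "T", "A"),
               mut_class = "C>T", three_prime_base = "G", is_cpg = TRUE,
               stringsAsFactors = FALSE)
  }
  set.seed(43)
  r_null <- dmr_ratio(draw_calls(1), ann, g)
  cpg_row <- r_null[r_null$status == "cpg", ]
  # null: per-site rates in/out equal in expectation; allow 99%-ish slack
  expect_gt(cpg_row$ratio, 0.5)
  expect_lt(cpg_row$ratio, 2.0)
  r_enr <- dmr_ratio(draw_calls(3), ann, g)
  cpg_row <- r_enr[r_enr$status == "cpg", ]
  expect_gt(cpg_row$ratio, 2.0)
  expect_lt(cpg_row$ratio, 4.5)
  # all calls outside DMRs -> ratio 0
  outside <- draw_calls(1)
  keep <- !IRanges::overlapsAny(
    GenomicRanges::GRanges(outside$contig,
                           IRanges::IRanges(outside$pos, width = 1)), dmr)
  r0 <- dmr_ratio(outside[keep, ], ann, g)
  expect_equal(r0$ratio[r0$status == "cpg"], 0)
  expect_error(dmr_ratio(outside, annotation_set(), g), "DMR track")
})

test_that("SINE subfamily enrichment: identity and designed enrichment", {
  g <- session_genome()
  ann <- generate_annotations(g, seed = 47)
  sine <- ann$repeats[ann$repeats$class == "SINE"]
  s <- as.character(g[[1]])
  # CpG cytosines inside SINE intervals, labelled by subfamily
  cg_plus <- as.integer(gregexpr("CG", s)[[1]])
  cpg_sites <- sort(c(cg_plus, cg_plus + 1L))
  site_sub <- rep(NA_character_, length(cpg_sites))
  for (k in seq_along(sine)) {
    hit <- cpg_sites >= GenomicRanges::start(sine)[k] &
      cpg_sites <= GenomicRanges::end(sine)[k]
    site_sub[hit] <- sine$subfamily[k]
  }
  pool <- which(!is.na(site_sub))
  draw <- function(w_aluy) {
    # independent per-site Bernoulli thinning: per-site rates scale exactly
    # with the weights, with no finite-pool depletion of the small AluY set
    w <- ifelse(site_sub[pool] == "AluY", w_aluy, 1)
    idx <- pool[stats::runif(length(pool)) < 0.12 * w]
    p <- cpg_sites[idx]
    ref <- substring(s, p, p)
    data.frame(contig = names(g)[1], pos = p, ref = ref,
               alt = ifelse(ref == "C", "T", "A"), mut_class = "C>T",
               three_prime_base = "G", is_cpg = TRUE,
               stringsAsFactors = FALSE)
  }
  set.seed(53)
  same <- draw(1)
  r_id <- sine_subfamily_enrichment(same, same, ann)
  expect_true(all(abs(r_id$groups$ratio_rel_aluj - 1) < 1e-9,
                  na.rm = TRUE))
  # 4x rate in AluY only; germline uniform over SINE CpG sites. The
  # AluJ rescaling cancels the within-cohort normalization, so the
  # expected rescaled AluY ratio is exactly 4; check on the log scale
  # against the delta-method 99% CI from the four realized counts
  r <- sine_subfamily_enrichment(draw(4), draw(1), ann)
  grp <- r$groups
  aluy <- grp[grp$group == "AluY", ]
  aluj <- grp[grp$group == "AluJ", ]
  se_log <- sqrt(1 / aluy$n_ipsc + 1 / aluy$n_germline +
                   1 / aluj$n_ipsc + 1 / aluj$n_germline)
  expect_lt(abs(log(aluy$ratio_rel_aluj / 4)), 2.576 * se_log)
  expect_equal(aluj$ratio_rel_aluj, 1)
})

test_that("interval overlap flags agree with an exhaustive scan oracle", {
  set.seed(59)
  iv_start <- sort(sample.int(1e5, 400))
  iv_end <- iv_start + sample(20:200, 400, TRUE)
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(iv_start, iv_end))
  gr$class <- "SINE"
  gr$subfamily <- "AluY"
  ann <- annotation_set(repeats = gr)
  calls <- pt(sample.int(1.1e5, 1000))
  r <- assign_regions(calls, ann)
  oracle <- vapply(calls$pos, function(p) {
    any(p >= iv_start & p <= iv_end)
  }, logical(1))
  expect_identical(r$in_sine, oracle)
})
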