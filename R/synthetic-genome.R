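# Synthetic genome generation. The only sequence property the downstream
# normalization depends on is the dinucleotide composition — in particular
# CpG abundance — so the generator is a first-order Markov chain over bases
# constructed from a target joint dinucleotide distribution Q with
#   Q(C,G) = oe * pC * pG         (oe = CpG observed/expected ratio)
# and both marginals equal to the target base composition pi. Q is the
# independent product pi (x) pi plus a rank-one correction c * u (x) v with
# u = e_C - pi, v = e_G - pi; u and v sum to zero, so the marginals of Q are
# exactly pi, the chain P = Q / pi is stationary at pi, and the stationary
# dinucleotide frequency is exactly Q.

markov_dinucleotide_model <- function(gc_fraction, cpg_obs_exp) {
  stopifnot(gc_fraction > 0, gc_fraction < 1, cpg_obs_exp > 0)
  pi0 <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  u <- -pi0; u["C"] <- 1 - pi0["C"]
  v <- -pi0; v["G"] <- 1 - pi0["G"]
  cc <- (cpg_obs_exp - 1) * pi0["C"] * pi0["G"] /
    ((1 - pi0["C"]) * (1 - pi0["G"]))
  Q <- outer(pi0, pi0) + cc * outer(u, v)
  if (any(Q < 0)) {
    c_max <- min(pi0["C"] / (1 - pi0["C"]), pi0["G"] / (1 - pi0["G"]))
    oe_max <- 1 + c_max * (1 - pi0["C"]) * (1 - pi0["G"]) /
      (pi0["C"] * pi0["G"])
    stop(sprintf(paste0(
      "infeasible (gc_fraction, cpg_observed_expected) combination; ",
      "at gc = %.3f the feasible o/e range is (0, %.3f]"),
      gc_fraction, oe_max))
  }
  P <- Q / rowSums(Q)
  list(pi = pi0, Q = Q, P = P)
}

sample_markov_bases <- function(n, pi0, P) {
  # inverse-CDF walk; plain loop, ~1 s per Mb
  cum <- t(apply(P, 1, cumsum))
  c1 <- cum[, 1]; c2 <- cum[, 2]; c3 <- cum[, 3]
  u <- stats::runif(n)
  s <- integer(n)
  cur <- findInterval(u[1], cumsum(pi0)) + 1L
  s[1] <- cur
  for (i in seq_len(n)[-1]) {
    ui <- u[i]
    cur <- if (ui <= c1[cur]) 1L else if (ui <= c2[cur]) 2L else
      if (ui <= c3[cur]) 3L else 4L
    s[i] <- cur
  }
  s
}

#' Generate a synthetic genome with controlled GC and CpG density
#'
#' Bases are emitted by a first-order Markov chain whose stationary base
#' composition equals the target exactly and whose stationary CpG
#' dinucleotide frequency is exactly
#' `cpg_observed_expected * (gc_fraction/2)^2`. Defaults mimic a mammalian
#' genome: GC 41% and the genome-wide CpG depletion to about one fifth of
#' the expectation under independence.
#'
#' @param length Total genome length in bases, split evenly over contigs.
#' @param gc_fraction Target G+C fraction in (0,1). Default 0.41.
#' @param cpg_observed_expected Target CpG observed/expected ratio (> 0);
#'   values above the composition-dependent feasibility bound are an error
#'   stating the bound. Default 0.2.
#' @param n_contigs Number of contigs (named `chr1..chrN`).
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @return Named `DNAStringSet`.
#' @examples
#' g <- generate_genome(1e4, seed = 1)
#' Biostrings::letterFrequency(g, "GC", as.prob = TRUE)
#' @export
generate_genome <- function(length, gc_fraction = 0.41,
                            cpg_observed_expected = 0.2,
                            n_contigs = 1L, seed = NULL) {
  stopifnot(length >= n_contigs, n_contigs >= 1)
  m <- markov_dinucleotide_model(gc_fraction, cpg_observed_expected)
  if (!is.null(seed)) set.seed(seed)
  lens <- rep(length %/% n_contigs, n_contigs)
  lens[1] <- lens[1] + length %% n_contigs
  seqs <- vapply(lens, function(n) {
    s <- sample_markov_bases(n, m$pi, m$P)
    intToUtf8(c(65L, 67L, 71L, 84L)[s])
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_contigs))
  genome
}

place_track_bins <- function(genome, n, width, weights_fun = NULL,
                             top = FALSE) {
  # disjoint bins of `width` with a random phase per contig; sampling whole
  # bins keeps within-track placement non-overlapping by construction
  lens <- Biostrings::width(genome)
  bins <- list()
  for (k in seq_along(genome)) {
    if (lens[k] < 2 * width) next
    phase <- sample.int(width, 1) - 1L
    starts <- seq(1L + phase, lens[k] - width + 1L, by = width)
    bins[[k]] <- GenomicRanges::GRanges(
      names(genome)[k], IRanges::IRanges(start = starts, width = width))
  }
  if (n == 0L) return(GenomicRanges::GRanges())
  bins <- do.call(c, bins)
  if (is.null(bins) || n > length(bins)) {
    stop("genome too short for requested track: need ", n,
         " intervals of width ", width)
  }
  if (!is.null(weights_fun)) {
    w <- weights_fun(bins)
    if (top) {
      pick <- order(w, decreasing = TRUE)[seq_len(n)]
    } else {
      pick <- sample.int(length(bins), n, prob = w + 1e-9)
    }
  } else {
    pick <- sample.int(length(bins), n)
  }
  GenomicRanges::sort(bins[pick])
}

cpg_count_in <- function(genome, gr) {
  if (length(gr) == 0) return(numeric(0))
  ctg <- as.character(GenomicRanges::seqnames(gr))
  out <- numeric(length(gr))
  for (cg in unique(ctg)) {
    i <- which(ctg == cg)
    v <- Biostrings::Views(genome[[cg]],
                           GenomicRanges::start(gr)[i],
                           GenomicRanges::end(gr)[i])
    out[i] <- Biostrings::vcountPattern("CG", Biostrings::DNAStringSet(v))
  }
  out
}

DEFAULT_SUBFAMILY_MIX <- c(
  AluJb = 0.11, AluJo = 0.10, AluSx = 0.25, AluSp = 0.12, AluSg = 0.09,
  AluSq = 0.08, AluY = 0.17, AluYa5 = 0.05, AluYb8 = 0.03
)

#' Generate annotation tracks over a genome
#'
#' Places non-overlapping intervals (within each track) covering roughly the
#' requested fraction of the genome per track, shaped like the inputs the
#' analysis consumes: a repeat track with class and subfamily labels, CpG
#' islands (always placed on the most CpG-dense windows, as real CGIs are),
#' DMRs, simple repeats, a CDS model (multi-exon transcripts with strand,
#' spliced length divisible by 3), and TSS positions at transcript starts
#' plus random extras.
#'
#' @param genome Named `DNAStringSet`.
#' @param fractions Named list of genome fractions per track; defaults
#'   `list(sine = 0.1, line = 0.15, ltr = 0.05, cgi = 0.007, dmr = 0.02,
#'   simple = 0.005)` echo mammalian repeat/CGI content at reduced scale.
#'   All-zero fractions yield empty tracks.
#' @param widths Interval widths per track; defaults
#'   `c(sine = 300, line = 3000, ltr = 500, cgi = 1000, dmr = 2000,
#'   simple = 100)` (an Alu is ~300 bp, LINE-1 up to 6 kb).
#' @param subfamily_mix Named proportions of SINE subfamilies (normalized
#'   internally); default a realistic AluJ/AluS/AluY mix.
#' @param cpg_bias_in_sine Place SINE intervals preferentially on CpG-rich
#'   windows (Alu elements are CpG-rich); default `TRUE`.
#' @param n_transcripts,n_extra_tss CDS model size; each transcript
#'   contributes one TSS at its start.
#' @param seed Integer seed.
#' @return An [annotation_set()].
#' @export
generate_annotations <- function(genome,
                                 fractions = list(sine = 0.1, line = 0.15,
                                                  ltr = 0.05, cgi = 0.007,
                                                  dmr = 0.02, simple = 0.005),
                                 widths = c(sine = 300, line = 3000,
                                            ltr = 500, cgi = 1000,
                                            dmr = 2000, simple = 100),
                                 subfamily_mix = DEFAULT_SUBFAMILY_MIX,
                                 cpg_bias_in_sine = TRUE,
                                 n_transcripts = 10L, n_extra_tss = 10L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- sum(Biostrings::width(genome))
  frac <- function(nm) fractions[[nm]] %||% 0
  if (frac("sine") + frac("line") + frac("ltr") > 1 ||
      any(unlist(fractions) < 0)) {
    stop("track fractions must be >= 0 and repeat fractions sum <= 1")
  }
  n_of <- function(nm) as.integer(round(frac(nm) * total / widths[[nm]]))
  cpg_w <- function(bins) cpg_count_in(genome, bins)

  # repeats: one track; classes placed on a shared grid so they never overlap
  n_sine <- n_of("sine"); n_line <- n_of("line"); n_ltr <- n_of("ltr")
  repeats <- GenomicRanges::GRanges()
  if (n_sine + n_line + n_ltr > 0) {
    # LINE intervals on their own coarse grid; SINE/LTR share a fine grid
    line_gr <- if (n_line > 0) {
      place_track_bins(genome, n_line, widths[["line"]])
    } else GenomicRanges::GRanges()
    # SINE and LTR share one grid sized to the larger width; each interval
    # is then trimmed to its class width, so it stays inside its own bin
    # and the whole repeat track is overlap-free by construction
    w_fine <- max(widths[["sine"]], widths[["ltr"]])
    fine <- place_track_bins(
      genome, n_sine + n_ltr, w_fine,
      weights_fun = if (cpg_bias_in_sine) cpg_w else NULL)
    fine <- fine[!IRanges::overlapsAny(fine, line_gr)]
    if (length(fine) < n_sine + n_ltr) {
      # lost a few to LINE overlap; acceptable shortfall is refilled blind
      need <- n_sine + n_ltr - length(fine)
      extra <- place_track_bins(genome, need + 5L, w_fine)
      extra <- extra[!IRanges::overlapsAny(extra, c(fine, line_gr))]
      fine <- c(fine, utils::head(extra, need))
    }
    sine_gr <- utils::head(fine, n_sine)
    if (length(sine_gr) > 0) {
      GenomicRanges::end(sine_gr) <-
        GenomicRanges::start(sine_gr) + widths[["sine"]] - 1L
    }
    ltr_gr <- utils::tail(fine, max(0L, length(fine) - n_sine))
    if (length(ltr_gr) > 0) {
      GenomicRanges::end(ltr_gr) <-
        GenomicRanges::start(ltr_gr) + widths[["ltr"]] - 1L
    }
    mix <- subfamily_mix / sum(subfamily_mix)
    parts <- list()
    if (length(sine_gr) > 0) {
      sine_gr$subfamily <- sample(names(mix), length(sine_gr),
                                  replace = TRUE, prob = mix)
      sine_gr$class <- "SINE"
      parts <- c(parts, list(sine_gr))
    }
    if (length(line_gr) > 0) {
      line_gr$subfamily <- sample(c("L1MA", "L1PA", "L2"), length(line_gr),
                                  replace = TRUE, prob = c(0.4, 0.35, 0.25))
      line_gr$class <- "LINE"
      parts <- c(parts, list(line_gr))
    }
    if (length(ltr_gr) > 0) {
      ltr_gr$subfamily <- sample(c("ERVL", "ERVK"), length(ltr_gr),
                                 replace = TRUE)
      ltr_gr$class <- "LTR"
      parts <- c(parts, list(ltr_gr))
    }
    repeats <- GenomicRanges::sort(do.call(c, parts))
  }

  cgi <- if (n_of("cgi") > 0) {
    place_track_bins(genome, n_of("cgi"), widths[["cgi"]],
                     weights_fun = cpg_w, top = TRUE)
  } else GenomicRanges::GRanges()
  dmr <- if (n_of("dmr") > 0) {
    place_track_bins(genome, n_of("dmr"), widths[["dmr"]])
  } else GenomicRanges::GRanges()
  simple <- if (n_of("simple") > 0) {
    place_track_bins(genome, n_of("simple"), widths[["simple"]])
  } else GenomicRanges::GRanges()

  cds <- GenomicRanges::GRanges()
  tss <- GenomicRanges::GRanges()
  if (n_transcripts > 0) {
    span_w <- 3000L
    spans <- place_track_bins(genome, n_transcripts, span_w)
    cds_parts <- list()
    tss_pos <- integer(0); tss_ctg <- character(0); tss_str <- character(0)
    for (t in seq_along(spans)) {
      ctg <- as.character(GenomicRanges::seqnames(spans))[t]
      s0 <- GenomicRanges::start(spans)[t]
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(1:3, 1)
      ex_w <- 3L * sample(30:80, n_ex)          # spliced length % 3 == 0
      gaps <- sample(100:400, n_ex)
      starts <- s0 + cumsum(c(0L, utils::head(ex_w + gaps, -1L)))
      ex <- GenomicRanges::GRanges(
        ctg, IRanges::IRanges(start = starts, width = ex_w),
        strand = strand)
      ex$transcript <- sprintf("tx%02d", t)
      w <- GenomicRanges::width(ex)
      off <- cumsum(c(0L, utils::head(
        if (strand == "+") w else rev(w), -1L)))
      ex$frame <- if (strand == "+") off %% 3L else rev(off %% 3L)
      cds_parts[[t]] <- ex
      tss_ctg <- c(tss_ctg, ctg)
      tss_pos <- c(tss_pos,
                   if (strand == "+") min(starts) else
                     max(starts + ex_w - 1L))
      tss_str <- c(tss_str, strand)
    }
    cds <- GenomicRanges::sort(do.call(c, cds_parts))
    if (n_extra_tss > 0) {
      k <- sample(seq_along(genome), n_extra_tss, replace = TRUE)
      tss_ctg <- c(tss_ctg, names(genome)[k])
      tss_pos <- c(tss_pos, vapply(
        Biostrings::width(genome)[k],
        function(L) sample.int(L, 1), integer(1)))
      tss_str <- c(tss_str, sample(c("+", "-"), n_extra_tss, replace = TRUE))
    }
    tss <- GenomicRanges::GRanges(
      tss_ctg, IRanges::IRanges(start = tss_pos, width = 1L),
      strand = tss_str)
  }

  annotation_set(repeats = repeats, cgi = cgi, tss = tss, dmr = dmr,
                 simple_repeats = simple, cds = cds, genome = genome)
}
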