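# Regional distribution and enrichment statistics. Variants are 1-based
# points; every overlap query converts them to width-1 GRanges, so the
# point-vs-interval convention is handled in one place (calls_granges).

#' CGI shore regions
#'
#' The shore is the union of the `width`-bp flanks on both sides of every
#' CpG island, minus any CGI overlap, clipped at contig ends when the
#' genome is supplied.
#'
#' @param cgi CGI `GRanges`.
#' @param genome Optional genome for clipping.
#' @param width Flank width in bp (default 5000).
#' @return `GRanges` of shore regions.
#' @export
cgi_shores <- function(cgi, genome = NULL, width = 5000L) {
  if (length(cgi) == 0) return(GenomicRanges::GRanges())
  left <- GenomicRanges::flank(cgi, width, start = TRUE)
  right <- GenomicRanges::flank(cgi, width, start = FALSE)
  sh <- GenomicRanges::reduce(c(left, right))
  GenomicRanges::start(sh) <- pmax(1L, GenomicRanges::start(sh))
  if (!is.null(genome)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    ctg <- as.character(GenomicRanges::seqnames(sh))
    GenomicRanges::end(sh) <- pmin(GenomicRanges::end(sh), lens[ctg])
  }
  GenomicRanges::setdiff(sh, GenomicRanges::reduce(cgi))
}

#' Assign genomic compartments and track overlap flags
#'
#' Each variant gets exactly one compartment — `CDS`, `intron` (inside a
#' transcript span but not in its CDS), or `intergenic`, in that precedence
#' — plus independent overlap flags for the repeat classes (with the
#' longest-overlap subfamily), CGI, CGI shore, and DMR tracks.
#'
#' @param calls Call `data.frame`.
#' @param annotations An [annotation_set()].
#' @param genome Optional genome (shore clipping).
#' @return `calls` with columns `compartment`, `in_sine`, `in_line`,
#'   `in_ltr`, `repeat_subfamily` (`NA` outside repeats), `in_cgi`,
#'   `in_cgi_shore`, `in_dmr`.
#' @export
assign_regions <- function(calls, annotations, genome = NULL) {
  gr <- calls_granges(calls)
  n <- nrow(calls)
  cds <- annotations$cds
  comp <- rep("intergenic", n)
  if (length(cds) > 0) {
    spans <- unlist(range(S4Vectors::split(cds, cds$transcript)))
    in_tx <- IRanges::overlapsAny(gr, spans, ignore.strand = TRUE)
    in_cds <- IRanges::overlapsAny(gr, cds, ignore.strand = TRUE)
    comp[in_tx] <- "intron"
    comp[in_cds] <- "CDS"
  }
  calls$compartment <- comp
  rep_tr <- annotations$repeats
  for (cls in c("SINE", "LINE", "LTR")) {
    col <- paste0("in_", tolower(cls))
    calls[[col]] <- if (length(rep_tr) > 0) {
      IRanges::overlapsAny(gr, rep_tr[rep_tr$class == cls],
                           ignore.strand = TRUE)
    } else rep(FALSE, n)
  }
  calls$repeat_subfamily <- rep(NA_character_, n)
  if (length(rep_tr) > 0 && n > 0) {
    hits <- GenomicRanges::findOverlaps(gr, rep_tr, ignore.strand = TRUE)
    if (length(hits) > 0) {
      hd <- data.frame(q = S4Vectors::queryHits(hits),
                       s = S4Vectors::subjectHits(hits))
      hd$w <- GenomicRanges::width(rep_tr)[hd$s]
      hd <- hd[order(hd$q, -hd$w), ]
      hd <- hd[!duplicated(hd$q), ]
      calls$repeat_subfamily[hd$q] <- rep_tr$subfamily[hd$s]
    }
  }
  calls$in_cgi <- IRanges::overlapsAny(gr, annotations$cgi,
                                       ignore.strand = TRUE)
  calls$in_cgi_shore <- IRanges::overlapsAny(
    gr, cgi_shores(annotations$cgi, genome), ignore.strand = TRUE)
  calls$in_dmr <- IRanges::overlapsAny(gr, annotations$dmr,
                                       ignore.strand = TRUE)
  calls
}

#' Retrotransposon-class C>T percentages with Z-tests
#'
#' For each repeat class (LINE/SINE/LTR) and each CpG status, the
#' percentage of C>T calls of that status falling inside the class; the
#' two-proportion Z-test compares the CpG vs non-CpG proportions per
#' class. Because the natural denominator is ambiguous (all mutations vs
#' all C>T of the status), both are emitted: `pct_of_status` (denominator
#' = all C>T calls of the status) and `pct_of_all` (denominator = all
#' calls).
#'
#' @param calls Classified calls.
#' @param annotations An [annotation_set()] with a repeat track.
#' @return `data.frame` with one row per class: counts, both percentage
#'   conventions for CpG and non-CpG C>T, and `z`/`p_value`.
#' @export
retrotransposon_rates <- function(calls, annotations) {
  if (length(annotations$repeats) == 0) stop("repeat track is empty")
  calls <- assign_regions(calls, annotations)
  ct <- !is.na(calls$mut_class) & calls$mut_class == "C>T"
  cpg <- ct & calls$is_cpg
  non <- ct & !calls$is_cpg
  n_all <- nrow(calls)
  out <- lapply(c("SINE", "LINE", "LTR"), function(cls) {
    inside <- calls[[paste0("in_", tolower(cls))]]
    x1 <- sum(cpg & inside); n1 <- sum(cpg)
    x2 <- sum(non & inside); n2 <- sum(non)
    zt <- if (n1 > 0 && n2 > 0) {
      z_test_two_proportions(x1, n1, x2, n2)
    } else list(z = NA_real_, p_value = NA_real_)
    data.frame(
      class = cls, n_cpg_ct = x1, n_noncpg_ct = x2,
      pct_of_status_cpg = if (n1 > 0) 100 * x1 / n1 else NA_real_,
      pct_of_status_noncpg = if (n2 > 0) 100 * x2 / n2 else NA_real_,
      pct_of_all_cpg = if (n_all > 0) 100 * x1 / n_all else NA_real_,
      pct_of_all_noncpg = if (n_all > 0) 100 * x2 / n_all else NA_real_,
      z = zt$z, p_value = zt$p_value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

default_subfamily_groups <- function(subfamilies) {
  list(
    AluJ = grep("^AluJ", subfamilies, value = TRUE),
    AluS = grep("^AluS", subfamilies, value = TRUE),
    AluY = intersect("AluY", subfamilies),
    `AluYa-k` = grep("^AluY[a-k]", subfamilies, value = TRUE)
  )
}

#' SINE-subfamily CpG C>T enrichment relative to germline
#'
#' For each SINE subfamily, the percentage of CpG C>T calls inside that
#' subfamily among all CpG C>T calls inside whole SINEs, computed for the
#' test cohort (e.g. iPSC) and the germline comparator; the
#' test-to-germline ratio per subfamily is then rescaled so AluJ (the sum
#' of AluJ* subfamilies) equals 1 — the oldest Alu family as the neutral
#' yardstick. Subfamilies absent from the germline percentages have an
#' undefined ratio (`NA`).
#'
#' @param ipsc_calls,germline_calls Classified call `data.frame`s.
#' @param annotations An [annotation_set()] whose repeat track carries
#'   subfamily labels.
#' @param groups Named list mapping group -> subfamily labels; defaults to
#'   AluJ*/AluS* sums, AluY alone, and the AluYa..AluYk sum.
#' @return List with `per_subfamily` (percentages in both cohorts, raw
#'   ratio, `ratio_rel_aluj`) and `groups` (same columns per group).
#' @export
sine_subfamily_enrichment <- function(ipsc_calls, germline_calls,
                                      annotations, groups = NULL) {
  rep_tr <- annotations$repeats
  sine <- rep_tr[rep_tr$class == "SINE"]
  if (length(sine) == 0) stop("no SINE intervals in repeat track")
  subfam <- sort(unique(sine$subfamily))
  count_in_subfam <- function(calls) {
    calls <- assign_regions(calls, annotations)
    sel <- !is.na(calls$mut_class) & calls$mut_class == "C>T" &
      calls$is_cpg & calls$in_sine
    tab <- table(factor(calls$repeat_subfamily[sel], levels = subfam))
    as.integer(tab)
  }
  n_i <- count_in_subfam(ipsc_calls)
  n_g <- count_in_subfam(germline_calls)
  pct_i <- if (sum(n_i) > 0) 100 * n_i / sum(n_i) else rep(NA_real_, length(n_i))
  pct_g <- if (sum(n_g) > 0) 100 * n_g / sum(n_g) else rep(NA_real_, length(n_g))
  ratio <- ifelse(pct_g > 0, pct_i / pct_g, NA_real_)
  per <- data.frame(subfamily = subfam, n_ipsc = n_i, n_germline = n_g,
                    pct_ipsc = pct_i, pct_germline = pct_g, ratio = ratio,
                    stringsAsFactors = FALSE)
  if (is.null(groups)) groups <- default_subfamily_groups(subfam)
  grp <- lapply(names(groups), function(g) {
    sel <- per$subfamily %in% groups[[g]]
    pi_ <- sum(per$pct_ipsc[sel]); pg_ <- sum(per$pct_germline[sel])
    data.frame(group = g, n_ipsc = sum(per$n_ipsc[sel]),
               n_germline = sum(per$n_germline[sel]),
               pct_ipsc = pi_, pct_germline = pg_,
               ratio = if (!is.na(pg_) && pg_ > 0) pi_ / pg_ else NA_real_,
               stringsAsFactors = FALSE)
  })
  grp <- do.call(rbind, grp)
  aluj <- grp$ratio[grp$group == "AluJ"]
  scale <- if (length(aluj) == 1 && !is.na(aluj) && aluj > 0) aluj else NA_real_
  per$ratio_rel_aluj <- per$ratio / scale
  grp$ratio_rel_aluj <- grp$ratio / scale
  list(per_subfamily = per, groups = grp)
}

# positions (1-based) of CpG cytosines and of other Cs, on both strands:
# a plus-strand CG occurrence at i contributes sites i (C, plus) and i+1
# (G on plus = C on minus); a C not followed by G is a non-CpG C site, as
# is a G not preceded by C.
c_site_positions <- function(genome, contig) {
  r <- charToRaw(as.character(genome[[contig]]))
  n <- length(r)
  C <- as.integer(charToRaw("C")); G <- as.integer(charToRaw("G"))
  b <- as.integer(r)
  is_c <- b == C; is_g <- b == G
  nxt_g <- c(is_g[-1L], FALSE)
  prv_c <- c(FALSE, is_c[-n])
  list(
    cpg = sort(c(which(is_c & nxt_g), which(is_g & prv_c))),
    other_c = sort(c(which(is_c & !nxt_g), which(is_g & !prv_c)))
  )
}

count_sites_in <- function(pos, iv_start, iv_end) {
  if (length(iv_start) == 0 || length(pos) == 0) return(0L)
  idx <- findInterval(pos, iv_start)
  sum(idx > 0 & pos <= iv_end[pmax(idx, 1L)])
}

#' C>T rate ratio inside vs outside DMRs
#'
#' Rates are per available site: CpG C>T counts are divided by the number
#' of CpG cytosines (both strands), non-CpG C>T counts by the number of
#' other-C sites, inside and outside the DMR track; the statistic is
#' `ratio = rate_in / rate_out` for each status. `rate_out = 0` makes the
#' ratio undefined (`NA`, flagged).
#'
#' @param calls Classified calls.
#' @param annotations An [annotation_set()] with a non-empty DMR track.
#' @param genome Named `DNAStringSet` (site abundance source).
#' @return `data.frame` with rows `cpg` and `noncpg`: counts and site
#'   abundances in/out, rates, `ratio`, `undefined` flag.
#' @export
dmr_ratio <- function(calls, annotations, genome) {
  dmr <- GenomicRanges::reduce(annotations$dmr)
  if (length(dmr) == 0) stop("DMR track is empty")
  ab_in <- c(cpg = 0, other = 0)
  ab_out <- c(cpg = 0, other = 0)
  for (cg in names(genome)) {
    sites <- c_site_positions(genome, cg)
    d <- dmr[GenomicRanges::seqnames(dmr) == cg]
    s <- GenomicRanges::start(d); e <- GenomicRanges::end(d)
    for (kind in c("cpg", "other_c")) {
      nm <- if (kind == "cpg") "cpg" else "other"
      n_in <- count_sites_in(sites[[kind]], s, e)
      ab_in[nm] <- ab_in[nm] + n_in
      ab_out[nm] <- ab_out[nm] + length(sites[[kind]]) - n_in
    }
  }
  ct <- calls[!is.na(calls$mut_class) & calls$mut_class == "C>T", ]
  in_dmr <- IRanges::overlapsAny(calls_granges(ct), dmr)
  out <- lapply(c(TRUE, FALSE), function(want_cpg) {
    sel <- ct$is_cpg == want_cpg
    nm <- if (want_cpg) "cpg" else "other"
    x_in <- sum(sel & in_dmr); x_out <- sum(sel & !in_dmr)
    r_in <- if (ab_in[nm] > 0) x_in / ab_in[nm] else NA_real_
    r_out <- if (ab_out[nm] > 0) x_out / ab_out[nm] else NA_real_
    undef <- is.na(r_out) || r_out == 0
    data.frame(
      status = if (want_cpg) "cpg" else "noncpg",
      n_in = x_in, n_out = x_out,
      sites_in = unname(ab_in[nm]), sites_out = unname(ab_out[nm]),
      rate_in = r_in, rate_out = r_out,
      ratio = if (undef) NA_real_ else r_in / r_out,
      undefined = undef, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Per-clone counts of calls in CGI and CGI shore
#'
#' @param call_sets A single call `data.frame` or a list of per-clone
#'   `data.frame`s.
#' @param annotations An [annotation_set()] with a CGI track.
#' @param genome Optional genome (shore clipping).
#' @param shore_width Shore flank width (default 5000 bp).
#' @return `data.frame` with one row per clone: `n_cgi`, `n_shore`.
#' @export
cgi_shore_counts <- function(call_sets, annotations, genome = NULL,
                             shore_width = 5000L) {
  if (is.data.frame(call_sets)) call_sets <- list(call_sets)
  cgi <- GenomicRanges::reduce(annotations$cgi)
  shore <- cgi_shores(annotations$cgi, genome, shore_width)
  out <- lapply(seq_along(call_sets), function(i) {
    gr <- calls_granges(call_sets[[i]])
    data.frame(
      clone = names(call_sets)[i] %||% paste0("clone", i),
      n_cgi = sum(IRanges::overlapsAny(gr, cgi)),
      n_shore = sum(IRanges::overlapsAny(gr, shore)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Distance-to-nearest-TSS profile
#'
#' Strandless absolute distance from each call to the nearest TSS,
#' histogrammed over `breaks`; optionally a per-bin ratio of test to
#' germline counts after scaling each to per-clone / per-individual units
#' (the germline cohort set to 1).
#'
#' @param calls Call `data.frame`.
#' @param annotations An [annotation_set()] with a non-empty TSS track.
#' @param breaks Right-closed distance bin edges in bp; default
#'   `c(0, 1, 2, 5, 10, 20, 50, 100, Inf) * 1000`.
#' @param germline_calls Optional comparator call set.
#' @param n_clones,n_individuals Cohort sizes used for the per-unit
#'   scaling of the ratio (defaults 1).
#' @return `data.frame` per bin: `n`, `per_clone`, and with a comparator
#'   `n_germline`, `per_individual`, `ratio`.
#' @export
tss_distance_profile <- function(calls, annotations,
                                 breaks = c(0, 1, 2, 5, 10, 20, 50, 100,
                                            Inf) * 1000,
                                 germline_calls = NULL, n_clones = 1,
                                 n_individuals = 1) {
  if (length(annotations$tss) == 0) stop("TSS track is empty")
  # |pos - TSS|, not the GRanges gap metric (which is |diff| - 1 for
  # non-touching points); nearest() minimizes the same ordering, so the
  # minimizer is reused and the absolute difference recomputed
  dist_to_tss <- function(cl) {
    gr <- calls_granges(cl)
    near <- GenomicRanges::nearest(gr, annotations$tss,
                                   ignore.strand = TRUE)
    abs(GenomicRanges::start(gr) -
          GenomicRanges::start(annotations$tss)[near])
  }
  bin_counts <- function(d) {
    as.integer(table(cut(d, breaks = breaks, include.lowest = TRUE,
                         right = TRUE)))
  }
  d <- dist_to_tss(calls)
  out <- data.frame(
    bin = levels(cut(numeric(0), breaks = breaks, include.lowest = TRUE)),
    n = bin_counts(d),
    stringsAsFactors = FALSE
  )
  out$per_clone <- out$n / n_clones
  if (!is.null(germline_calls)) {
    out$n_germline <- bin_counts(dist_to_tss(germline_calls))
    out$per_individual <- out$n_germline / n_individuals
    out$ratio <- ifelse(out$per_individual > 0,
                        out$per_clone / out$per_individual, NA_real_)
  }
  attr(out, "distances") <- d
  out
}
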