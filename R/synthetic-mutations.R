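# Mutation simulation with context-specific rates. Sites are sampled
# without replacement with probability proportional to the summed rate of
# their context (Efraimidis-Spirakis exponential keys: fully vectorized,
# exact, and deterministic under a seed), so a site mutates at most once.

#' Construct a per-context relative rate table
#'
#' Rates are keyed by (pyrimidine-strand substitution class, 3' neighbor):
#' a 6 x 4 matrix over [MUT_CLASSES] and `A,C,G,T`. Only ratios matter.
#' The default is a flat background of 1 with the CpG C>T cell (`C>T` with
#' 3' `G`) raised `cpg_ct_fold`-fold; the default fold of 10 mirrors the
#' CpG C>T transition efficiency observed in iPSC genomes, more than 10x
#' the low-frequency contexts.
#'
#' @param values Optional 6 x 4 numeric matrix (rownames [MUT_CLASSES],
#'   colnames bases); non-negative, at least one positive.
#' @param cpg_ct_fold Fold enrichment of the CpG C>T cell when building the
#'   default table.
#' @return A `rate_table` (numeric matrix with class attribute).
#' @export
rate_table <- function(values = NULL, cpg_ct_fold = 10) {
  if (is.null(values)) {
    values <- matrix(1, nrow = 6, ncol = 4,
                     dimnames = list(MUT_CLASSES, BASES))
    values["C>T", "G"] <- cpg_ct_fold
  }
  stopifnot(is.matrix(values), nrow(values) == 6, ncol(values) == 4)
  if (is.null(rownames(values))) rownames(values) <- MUT_CLASSES
  if (is.null(colnames(values))) colnames(values) <- BASES
  values <- values[MUT_CLASSES, BASES]
  if (any(values < 0) || all(values == 0)) {
    stop("rates must be >= 0 with at least one > 0")
  }
  structure(values, class = c("rate_table", "matrix"))
}

# Enumerate all mutable sites of a genome on the pyrimidine strand.
# Returns parallel vectors: contig index, position, plus-strand base index
# (1..4 = A,C,G,T), pyrimidine ref (1 = C, 2 = T), neighbor index (1..4).
# Sites whose context includes N (or falls off the contig) are dropped.
enumerate_sites <- function(genome) {
  lookup <- integer(256)
  lookup[as.integer(charToRaw("ACGTN")) + 1L] <- 1:5
  comp_idx <- c(4L, 3L, 2L, 1L, 5L)
  res <- list()
  for (k in seq_along(genome)) {
    r <- charToRaw(as.character(genome[[k]]))
    b <- lookup[as.integer(r) + 1L]
    n <- length(b)
    if (n < 2L) next
    nxt <- c(b[-1L], 5L)          # base 3' on plus strand (5 = off end / N)
    prv <- c(5L, b[-n])           # base 5' on plus strand
    is_pyr <- b == 2L | b == 4L   # C or T
    is_pur <- b == 1L | b == 3L   # A or G
    ok <- (is_pyr & nxt <= 4L) | (is_pur & prv <= 4L)
    pos <- which(ok)
    bb <- b[pos]
    pyr <- ifelse(bb == 2L | bb == 4L, ifelse(bb == 2L, 1L, 2L),
                  ifelse(bb == 3L, 1L, 2L))   # G collapses to C, A to T
    nbr <- ifelse(bb == 2L | bb == 4L, nxt[pos], comp_idx[prv[pos]])
    res[[k]] <- data.frame(contig = k, pos = pos, base = bb,
                           pyr = pyr, nbr = nbr)
  }
  do.call(rbind, res)
}

#' Simulate mutations with context-proportional rates
#'
#' Draws `n_total` distinct sites from the genome, each with probability
#' proportional to the total rate of its (pyrimidine base, 3' neighbor)
#' context summed over the three alternative alleles, then draws the
#' alternative allele from the within-context rates. Emitted records carry
#' plus-strand `ref`/`alt` plus the truth classification (`mut_class`,
#' `three_prime_base`, `is_cpg`).
#'
#' @param genome Named `DNAStringSet`.
#' @param rates A [rate_table()].
#' @param n_total Number of mutations; exceeding the number of eligible
#'   sites is an error.
#' @param seed Integer seed.
#' @return `data.frame` of truth calls, ordered by contig and position.
#' @export
simulate_mutations <- function(genome, rates = rate_table(), n_total,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_total == 0L) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      mut_class = character(0),
                      three_prime_base = character(0), is_cpg = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  sites <- enumerate_sites(genome)
  # summed rate per (pyr, nbr) context
  w8 <- rbind(C = colSums(unclass(rates)[1:3, ]),
              T = colSums(unclass(rates)[4:6, ]))
  w <- w8[cbind(sites$pyr, sites$nbr)]
  eligible <- sum(w > 0)
  if (n_total > eligible) {
    stop("n_total (", n_total, ") exceeds eligible sites (", eligible, ")")
  }
  key <- stats::rexp(nrow(sites)) / w      # Inf where w == 0: never chosen
  pick <- order(key)[seq_len(n_total)]
  sel <- sites[pick, ]
  # alternative allele per selected site, from within-context class rates
  alt_pyr <- integer(nrow(sel))
  pyr_base <- c("C", "T")
  for (p in 1:2) {
    alts <- setdiff(BASES, pyr_base[p])
    cls <- paste0(pyr_base[p], ">", alts)
    for (nb in 1:4) {
      i <- which(sel$pyr == p & sel$nbr == nb)
      if (length(i) == 0) next
      pr <- unclass(rates)[cls, nb]
      alt_pyr[i] <- sample.int(3L, length(i), replace = TRUE, prob = pr)
    }
  }
  pyr_alt_base <- t(vapply(1:2, function(p) setdiff(BASES, pyr_base[p]),
                           character(3)))
  alt_on_pyr <- pyr_alt_base[cbind(sel$pyr, alt_pyr)]
  plus_is_pyr <- sel$base == 2L | sel$base == 4L
  out <- data.frame(
    contig = names(genome)[sel$contig],
    pos = sel$pos,
    ref = BASES[sel$base],
    alt = ifelse(plus_is_pyr, alt_on_pyr, comp_base(alt_on_pyr)),
    mut_class = paste0(pyr_base[sel$pyr], ">", alt_on_pyr),
    three_prime_base = BASES[sel$nbr],
    is_cpg = sel$pyr == 1L & sel$nbr == 3L,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Clone-family simulation configuration
#'
#' @param n_clones Number of sister clones (>= 1).
#' @param n_private_per_clone De novo mutations private to each clone; the
#'   default of 742 matches the mean burden of ~740 SNVs per clone observed
#'   across 35 mouse sister lines.
#' @param shared List of `list(clones = c(i, j, ...), n = k)` entries: `k`
#'   mutations common to exactly that clone subset.
#' @param n_preexisting Sub-clonal variants present in the parental
#'   population.
#' @param preexisting_fraction Cell fraction of the parental sub-clone
#'   carrying them (default 0.3).
#' @param preexisting_clones Indices of clones descending from that
#'   sub-clone (they carry the pre-existing variants as ordinary
#'   heterozygous calls).
#' @param vaf_shape Beta(a, a) shape for the true VAF around 0.5
#'   (default 50, giving the 35-65% heterozygous band).
#' @param depth_mean Mean sequencing depth (default 40, i.e. ~130 Gb on a
#'   3 Gb genome); also used for the parental sample.
#' @param metric_noise Draw read-level metrics stochastically; with `FALSE`
#'   every record gets clean passing metrics (depth = `depth_mean`,
#'   VAF = 0.5, high qualities), so no filter should remove it.
#' @param fail_fraction Fraction of records per clone deliberately forced
#'   to fail one named filter (rotating over depth, central quality,
#'   surrounding quality, gap/mismatch, VAF low/high, known variant,
#'   simple repeat, homopolymer, parental); ground truth for filter tests.
#' @param seed Integer seed fixing the complete output.
#' @return A `clone_family_config` list.
#' @export
clone_family_config <- function(n_clones, n_private_per_clone = 742L,
                                shared = list(), n_preexisting = 0L,
                                preexisting_fraction = 0.3,
                                preexisting_clones = integer(0),
                                vaf_shape = 50, depth_mean = 40L,
                                metric_noise = TRUE, fail_fraction = 0,
                                seed = 1L) {
  stopifnot(n_clones >= 1, n_private_per_clone >= 0, n_preexisting >= 0,
            preexisting_fraction > 0, preexisting_fraction <= 1,
            fail_fraction >= 0, fail_fraction <= 1)
  for (s in shared) {
    if (any(s$clones < 1) || any(s$clones > n_clones) ||
        length(s$clones) < 2) {
      stop("shared subset indices out of range (need >= 2 clones in 1..",
           n_clones, ")")
    }
  }
  if (length(preexisting_clones) > 0 &&
      (any(preexisting_clones < 1) || any(preexisting_clones > n_clones))) {
    stop("preexisting_clones indices out of range")
  }
  structure(list(
    n_clones = as.integer(n_clones),
    n_private_per_clone = as.integer(n_private_per_clone),
    shared = shared, n_preexisting = as.integer(n_preexisting),
    preexisting_fraction = preexisting_fraction,
    preexisting_clones = as.integer(preexisting_clones),
    vaf_shape = vaf_shape, depth_mean = as.integer(depth_mean),
    metric_noise = isTRUE(metric_noise), fail_fraction = fail_fraction,
    seed = as.integer(seed)
  ), class = "clone_family_config")
}

FAIL_MODES <- c("depth", "central_qual", "surround_qual", "gap_mismatch",
                "vaf_low", "vaf_high", "known", "simple_repeat",
                "homopolymer", "parental")

draw_metrics <- function(n, cfg) {
  if (!cfg$metric_noise) {
    return(data.frame(
      depth = rep(cfg$depth_mean, n),
      vaf_true = rep(0.5, n),
      alt_count = rep(as.integer(round(cfg$depth_mean * 0.5)), n),
      central_qual = rep(38, n), surround_qual = rep(32, n),
      gap_mismatch = rep(0L, n)
    ))
  }
  depth <- pmax(1L, stats::rpois(n, cfg$depth_mean))
  vaf_true <- stats::rbeta(n, cfg$vaf_shape, cfg$vaf_shape)
  data.frame(
    depth = depth,
    vaf_true = vaf_true,
    alt_count = stats::rbinom(n, depth, vaf_true),
    central_qual = pmin(40, round(stats::rnorm(n, 38, 1.2), 1)),
    surround_qual = pmin(40, round(stats::rnorm(n, 32, 2.5), 1)),
    gap_mismatch = stats::rpois(n, 0.15)
  )
}

# which filter (if any) removes a record, checked in reporting order by
# plain comparisons -- deliberately independent of the filtering module
expected_fail_label <- function(d, params_default = NULL) {
  ifelse(d$depth < 20, "depth",
  ifelse(d$central_qual < 30, "central_qual",
  ifelse(d$surround_qual < 15, "surround_qual",
  ifelse(d$gap_mismatch > 2, "gap_mismatch",
  ifelse(d$parental_alt_count >= 2, "parental",
  ifelse(d$known_variant, "known",
  ifelse(vapply(d$sister_alt, function(s) any(s >= 2), logical(1)), "sister",
  ifelse(d$in_simple_repeat, "simple_repeat",
  ifelse(d$in_homopolymer, "homopolymer",
  ifelse(d$alt_count / d$depth < 0.35 | d$alt_count / d$depth > 0.65,
         "vaf", "none"))))))))))
}

#' Simulate a sister-clone family with ground truth
#'
#' Emulates the experimental design of many iPSC lines derived from one
#' parental somatic cell population: each clone carries private de novo
#' mutations, designated clone subsets share injected mutations, and
#' sub-clonal "pre-existing" variants of the parental population appear in
#' the parental allele table (at their cell fraction) and in the clones
#' descending from that sub-clone. All sites are drawn in a single
#' without-replacement pass, so no site is reused anywhere in the family.
#'
#' @param genome Named `DNAStringSet`.
#' @param rates A [rate_table()].
#' @param config A [clone_family_config()].
#' @return List with `clones` (per-clone candidate `data.frame`s including
#'   read metrics), `parental` (allele table of pre-existing variants),
#'   `ledger` (one row per emitted candidate: clone, key, origin
#'   private/shared/preexisting, shared group, and `expected_fail` — the
#'   filter that should remove it, or `"none"`), and `config`.
#' @export
simulate_clone_family <- function(genome, rates = rate_table(), config) {
  stopifnot(inherits(config, "clone_family_config"))
  set.seed(config$seed)
  n_shared_tot <- sum(vapply(config$shared, `[[`, numeric(1), "n"))
  n_needed <- config$n_preexisting + n_shared_tot +
    config$n_clones * config$n_private_per_clone
  all_mut <- simulate_mutations(genome, rates, n_needed)
  all_mut <- all_mut[sample.int(nrow(all_mut)), ]   # decouple from position order
  take <- function(n) {
    out <- all_mut[seq_len(n), , drop = FALSE]
    # note: all_mut[-integer(0), ] would select zero rows, not all
    if (n > 0) all_mut <<- all_mut[-seq_len(n), , drop = FALSE]
    out
  }
  pre <- take(config$n_preexisting)
  shared_list <- lapply(config$shared, function(s) take(s$n))
  private_list <- lapply(seq_len(config$n_clones), function(i) {
    take(config$n_private_per_clone)
  })

  parental <- data.frame(
    contig = pre$contig, pos = pre$pos, ref = pre$ref, alt = pre$alt,
    cell_fraction = rep(config$preexisting_fraction, nrow(pre)),
    parental_alt_count = if (nrow(pre) > 0) {
      stats::rbinom(nrow(pre), config$depth_mean,
                    config$preexisting_fraction / 2)
    } else integer(0),
    stringsAsFactors = FALSE
  )

  clones <- vector("list", config$n_clones)
  ledger <- list()
  for (i in seq_len(config$n_clones)) {
    origin <- character(0); group <- integer(0)
    mut <- private_list[[i]]
    origin <- rep("private", nrow(mut)); group <- rep(NA_integer_, nrow(mut))
    for (g in seq_along(config$shared)) {
      if (i %in% config$shared[[g]]$clones) {
        mut <- rbind(mut, shared_list[[g]])
        origin <- c(origin, rep("shared", nrow(shared_list[[g]])))
        group <- c(group, rep(g, nrow(shared_list[[g]])))
      }
    }
    if (i %in% config$preexisting_clones && nrow(pre) > 0) {
      mut <- rbind(mut, pre)
      origin <- c(origin, rep("preexisting", nrow(pre)))
      group <- c(group, rep(NA_integer_, nrow(pre)))
    }
    m <- draw_metrics(nrow(mut), config)
    d <- data.frame(
      contig = mut$contig, pos = mut$pos, ref = mut$ref, alt = mut$alt,
      depth = m$depth, alt_count = m$alt_count,
      central_qual = m$central_qual, surround_qual = m$surround_qual,
      gap_mismatch = as.integer(m$gap_mismatch),
      parental_alt_count = 0L,
      known_variant = FALSE, in_simple_repeat = FALSE,
      in_homopolymer = FALSE, stringsAsFactors = FALSE
    )
    if (any(origin == "preexisting")) {
      idx <- match(variant_key(d$contig, d$pos, d$ref, d$alt),
                   variant_key(parental$contig, parental$pos,
                               parental$ref, parental$alt))
      d$parental_alt_count[!is.na(idx)] <-
        parental$parental_alt_count[idx[!is.na(idx)]]
    }
    # sister allele counts over the other clones, ascending order
    others <- setdiff(seq_len(config$n_clones), i)
    key_i <- variant_key(d$contig, d$pos, d$ref, d$alt)
    in_clone <- function(j, keys) {
      member <- rep(FALSE, length(keys))
      for (g in seq_along(config$shared)) {
        if (j %in% config$shared[[g]]$clones) {
          sk <- shared_list[[g]]
          member <- member | keys %in% variant_key(sk$contig, sk$pos,
                                                   sk$ref, sk$alt)
        }
      }
      if (j %in% config$preexisting_clones && nrow(pre) > 0) {
        member <- member | keys %in% variant_key(pre$contig, pre$pos,
                                                 pre$ref, pre$alt)
      }
      member
    }
    sis <- lapply(others, function(j) {
      present <- in_clone(j, key_i)
      cnt <- integer(length(key_i))
      if (any(present)) {
        cnt[present] <- if (config$metric_noise) {
          pmax(2L, stats::rbinom(sum(present), config$depth_mean, 0.5))
        } else as.integer(round(config$depth_mean * 0.5))
      }
      cnt
    })
    d$sister_alt <- lapply(seq_len(nrow(d)), function(r) {
      vapply(sis, `[[`, integer(1), r)
    })
    # deliberately filter-failing records, rotating over the fail modes
    n_fail <- round(config$fail_fraction * nrow(d))
    if (n_fail > 0) {
      vic <- sample.int(nrow(d), n_fail)
      mode <- FAIL_MODES[(seq_len(n_fail) - 1L) %% length(FAIL_MODES) + 1L]
      for (k in seq_len(n_fail)) {
        r <- vic[k]
        switch(mode[k],
          depth = { d$depth[r] <- 19L
                    d$alt_count[r] <- min(d$alt_count[r], 9L) },
          central_qual = d$central_qual[r] <- 25,
          surround_qual = d$surround_qual[r] <- 12,
          gap_mismatch = d$gap_mismatch[r] <- 4L,
          vaf_low = d$alt_count[r] <- as.integer(floor(0.2 * d$depth[r])),
          vaf_high = d$alt_count[r] <- as.integer(ceiling(0.8 * d$depth[r])),
          known = d$known_variant[r] <- TRUE,
          simple_repeat = d$in_simple_repeat[r] <- TRUE,
          homopolymer = d$in_homopolymer[r] <- TRUE,
          parental = d$parental_alt_count[r] <- 3L
        )
      }
    }
    clones[[i]] <- d
    ledger[[i]] <- data.frame(
      clone = i, contig = d$contig, pos = d$pos, ref = d$ref, alt = d$alt,
      key = key_i, origin = origin, shared_group = group,
      expected_fail = expected_fail_label(d),
      stringsAsFactors = FALSE
    )
  }
  list(clones = clones, parental = parental,
       ledger = do.call(rbind, ledger), config = config)
}
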