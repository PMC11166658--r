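# SNV identification filters. Acceptance is a conjunction of independent
# predicates, so it is order-free; the report attributes each removed
# record to the FIRST failing predicate in the documented order
# (quality/depth -> parental -> known -> sister -> repeat/homopolymer ->
# VAF), matching how the filters are listed in the source protocol.

#' Filter parameters
#'
#' Defaults are the published thresholds of the variant-identification
#' protocol: minimum central-base quality 30, minimum mean surrounding
#' quality 15 over an 11-base window, at most 2 gaps+mismatches in the
#' window, depth >= 20; exclusion of variants with >= 2 variant alleles in
#' the parental sample or in any sister clone, of known (dbSNP) variants,
#' of simple-repeat and homopolymer positions; and a VAF window of
#' 35-65%, both bounds inclusive (the heterozygous band).
#'
#' @param min_central_qual,min_surround_qual,window_length,max_gap_mismatch,min_depth
#'   Read-level quality thresholds. `window_length` is carried for
#'   provenance; the window statistics arrive precomputed per candidate.
#' @param max_parental_alt,max_sister_alt Maximum tolerated variant-allele
#'   reads in the parental sample / in any sister clone (records with more
#'   are excluded; the published rule is "exclude when >= 2", i.e. max 1).
#' @param vaf_min,vaf_max Inclusive VAF bounds.
#' @param exclude_known,exclude_sisters,exclude_simple_repeat,exclude_homopolymer
#'   Switches for the membership filters. `exclude_sisters` is ON by
#'   default and must be turned OFF for shared-SNV analysis.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_central_qual = 30, min_surround_qual = 15,
                          window_length = 11L, max_gap_mismatch = 2L,
                          min_depth = 20L, max_parental_alt = 1L,
                          max_sister_alt = 1L, vaf_min = 0.35,
                          vaf_max = 0.65, exclude_known = TRUE,
                          exclude_sisters = TRUE,
                          exclude_simple_repeat = TRUE,
                          exclude_homopolymer = TRUE) {
  stopifnot(vaf_min >= 0, vaf_min < vaf_max, vaf_max <= 1,
            min_depth >= 0, max_gap_mismatch >= 0)
  structure(list(
    min_central_qual = min_central_qual,
    min_surround_qual = min_surround_qual,
    window_length = as.integer(window_length),
    max_gap_mismatch = as.integer(max_gap_mismatch),
    min_depth = as.integer(min_depth),
    max_parental_alt = as.integer(max_parental_alt),
    max_sister_alt = as.integer(max_sister_alt),
    vaf_min = vaf_min, vaf_max = vaf_max,
    exclude_known = exclude_known, exclude_sisters = exclude_sisters,
    exclude_simple_repeat = exclude_simple_repeat,
    exclude_homopolymer = exclude_homopolymer
  ), class = "filter_params")
}

FILTER_ORDER <- c("depth", "central_qual", "surround_qual", "gap_mismatch",
                  "parental", "known", "sister", "simple_repeat",
                  "homopolymer", "blacklist", "vaf")

REQUIRED_METRICS <- c("depth", "alt_count", "central_qual", "surround_qual",
                      "gap_mismatch", "parental_alt_count", "known_variant",
                      "in_simple_repeat", "in_homopolymer")

# per-predicate pass matrix (TRUE = passes); disabled predicates pass all
filter_pass_matrix <- function(candidates, params, blacklist = NULL) {
  n <- nrow(candidates)
  for (f in REQUIRED_METRICS) {
    if (!f %in% names(candidates)) {
      stop("candidate table lacks required metric field: ", f)
    }
    if (anyNA(candidates[[f]])) {
      stop("missing (NA) values in metric field: ", f)
    }
  }
  vaf <- candidates$alt_count / candidates$depth
  sister_max <- if ("sister_alt" %in% names(candidates)) {
    vapply(candidates$sister_alt,
           function(s) if (length(s) == 0) 0L else max(s), integer(1))
  } else rep(0L, n)
  in_bl <- if (is.null(blacklist) || length(blacklist) == 0) {
    rep(FALSE, n)
  } else {
    IRanges::overlapsAny(calls_granges(candidates), blacklist)
  }
  m <- cbind(
    depth = candidates$depth >= params$min_depth,
    central_qual = candidates$central_qual >= params$min_central_qual,
    surround_qual = candidates$surround_qual >= params$min_surround_qual,
    gap_mismatch = candidates$gap_mismatch <= params$max_gap_mismatch,
    parental = candidates$parental_alt_count <= params$max_parental_alt,
    known = !(params$exclude_known & candidates$known_variant),
    sister = !params$exclude_sisters | sister_max <= params$max_sister_alt,
    simple_repeat = !(params$exclude_simple_repeat &
                        candidates$in_simple_repeat),
    homopolymer = !(params$exclude_homopolymer &
                      candidates$in_homopolymer),
    blacklist = !in_bl,
    vaf = vaf >= params$vaf_min & vaf <= params$vaf_max
  )
  m[, FILTER_ORDER, drop = FALSE]
}

#' Apply the SNV identification filters
#'
#' A candidate is accepted iff it passes every enabled predicate; the
#' outcome does not depend on filter order. The report counts removals by
#' the first failing predicate in the documented order and satisfies
#' `input = accepted + sum(removals)`.
#'
#' @param candidates Candidate `data.frame` (see [read_variants()]).
#' @param params A [filter_params()].
#' @param genome Optional genome; when supplied, accepted records are
#'   classified into the 24-category scheme ([classify_calls()]), turning
#'   them into calls with `vaf`, `mut_class`, `three_prime_base`, `is_cpg`.
#' @param blacklist Optional `GRanges` of manually excluded regions (the
#'   stand-in for visual curation of alignment-error regions).
#' @return List with `accepted` (filtered table) and `report`
#'   (`filter_report`: `n_input`, `n_accepted`, ordered `removed` counts,
#'   and `first_fail` label per input record, `"none"` for accepted).
#' @export
apply_filters <- function(candidates, params = filter_params(),
                          genome = NULL, blacklist = NULL) {
  m <- filter_pass_matrix(candidates, params, blacklist)
  pass_all <- if (nrow(candidates) == 0) logical(0) else rowSums(!m) == 0L
  first_fail <- rep("none", nrow(candidates))
  if (nrow(candidates) > 0) {
    fail_idx <- apply(!m, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)
    first_fail[!is.na(fail_idx)] <- FILTER_ORDER[fail_idx[!is.na(fail_idx)]]
  }
  removed <- vapply(FILTER_ORDER, function(f) sum(first_fail == f),
                    integer(1))
  accepted <- candidates[pass_all, , drop = FALSE]
  rownames(accepted) <- NULL
  if (!is.null(genome)) {
    accepted <- classify_calls(genome, accepted)
  } else if (nrow(accepted) > 0) {
    accepted$vaf <- accepted$alt_count / accepted$depth
  }
  report <- structure(list(
    n_input = nrow(candidates),
    n_accepted = sum(pass_all),
    removed = removed,
    first_fail = first_fail
  ), class = "filter_report")
  list(accepted = accepted, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "candidates ->", x$n_accepted,
      "accepted\n")
  rem <- x$removed[x$removed > 0]
  if (length(rem) > 0) {
    for (nm in names(rem)) cat(sprintf("  removed by %-14s %d\n", nm, rem[nm]))
  }
  invisible(x)
}

#' Flag candidates inside homopolymer runs
#'
#' A position is flagged iff it lies inside a single-base run of length
#' >= `min_run` in the reference genome. The published protocol names the
#' homopolymer exclusion without a length; 7 is this package's default and
#' it is configurable.
#'
#' @param genome Named `DNAStringSet`.
#' @param candidates Candidate `data.frame`.
#' @param min_run Minimum run length (default 7).
#' @return `candidates` with `in_homopolymer` set.
#' @export
detect_homopolymer_flags <- function(genome, candidates, min_run = 7L) {
  flag <- rep(FALSE, nrow(candidates))
  for (cg in unique(candidates$contig)) {
    i <- which(candidates$contig == cg)
    r <- rle(strsplit(as.character(genome[[cg]]), "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$lengths >= min_run)
    if (length(runs) == 0) next
    for (k in runs) {
      flag[i] <- flag[i] |
        (candidates$pos[i] >= starts[k] & candidates$pos[i] <= ends[k])
    }
  }
  candidates$in_homopolymer <- flag
  candidates
}
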