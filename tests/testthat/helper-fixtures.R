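# Shared fixtures, all built in code.

# small fixed genome with known content
tiny_genome <- function() {
  g <- Biostrings::DNAStringSet(c(
    c1 = "ACGTACGTCGCGATTACGGA",
    c2 = "TTTTCGCGCGATATATGGCC"
  ))
  g
}

# one fully specified candidate that passes every default filter
make_candidate <- function(contig = "c1", pos = 9L, ref = "C", alt = "T",
                           depth = 40L, alt_count = 20L,
                           central_qual = 38, surround_qual = 30,
                           gap_mismatch = 0L, parental_alt_count = 0L,
                           sister_alt = list(c(0L, 0L)),
                           known_variant = FALSE, in_simple_repeat = FALSE,
                           in_homopolymer = FALSE) {
  d <- data.frame(
    contig = contig, pos = pos, ref = ref, alt = alt, depth = depth,
    alt_count = alt_count, central_qual = central_qual,
    surround_qual = surround_qual, gap_mismatch = gap_mismatch,
    parental_alt_count = parental_alt_count,
    known_variant = known_variant, in_simple_repeat = in_simple_repeat,
    in_homopolymer = in_homopolymer, stringsAsFactors = FALSE
  )
  d$sister_alt <- sister_alt
  d
}

# a larger reusable random genome (memoised per session)
session_genome <- local({
  g <- NULL
  function(len = 5e5, seed = 424242) {
    if (is.null(g)) g <<- generate_genome(len, seed = seed)
    g
  }
})

# independent per-predicate brute force, deliberately written as plain
# comparisons (the oracle for apply_filters)
brute_force_accept <- function(d, p = filter_params()) {
  vaf <- d$alt_count / d$depth
  smax <- vapply(d$sister_alt,
                 function(s) if (length(s)) max(s) else 0L, integer(1))
  d$depth >= p$min_depth &
    d$central_qual >= p$min_central_qual &
    d$surround_qual >= p$min_surround_qual &
    d$gap_mismatch <= p$max_gap_mismatch &
    d$parental_alt_count <= p$max_parental_alt &
    (!p$exclude_known | !d$known_variant) &
    (!p$exclude_sisters | smax <= p$max_sister_alt) &
    (!p$exclude_simple_repeat | !d$in_simple_repeat) &
    (!p$exclude_homopolymer | !d$in_homopolymer) &
    vaf >= p$vaf_min & vaf <= p$vaf_max
}
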