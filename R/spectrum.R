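# Strand-collapsed mutation spectrum. Every substitution is represented with
# a pyrimidine (C or T) reference base: purine-reference changes are read off
# the reverse-complement strand, so their "3' neighbor" is the complement of
# the base 5' of the variant on the plus strand. With the 3'-neighbor
# dimension this yields the 24 = 6 x 4 category scheme, and normalization
# divides each cell by the genomic abundance of the corresponding collapsed
# dinucleotide (counted on both strands), scaled per 1e9 bases.

#' The six pyrimidine-strand substitution classes
#' @export
MUT_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Classify calls into the 24-category strand-collapsed scheme
#'
#' Adds `mut_class`, `three_prime_base`, `is_cpg` (and `vaf` when depth and
#' alt_count columns are present) to a variant table. A call whose
#' dinucleotide context contains `N`, or whose 3' neighbor falls off the
#' contig end, is excluded from classification: its `mut_class` is `NA` and
#' it is counted in the `n_excluded_context` attribute — consistent with
#' abundance counting, which skips the same windows.
#'
#' @param genome Named `DNAStringSet`.
#' @param variants `data.frame` with `contig`, `pos`, `ref`, `alt`.
#' @return The input with classification columns appended; attribute
#'   `n_excluded_context` counts NA-context calls.
#' @export
classify_calls <- function(genome, variants) {
  n <- nrow(variants)
  variants$mut_class <- rep(NA_character_, n)
  variants$three_prime_base <- rep(NA_character_, n)
  variants$is_cpg <- rep(NA, n)
  if (all(c("depth", "alt_count") %in% names(variants))) {
    variants$vaf <- variants$alt_count / variants$depth
  }
  if (n == 0) {
    attr(variants, "n_excluded_context") <- 0L
    return(variants)
  }
  stopifnot(all(variants$ref %in% BASES), all(variants$alt %in% BASES),
            all(variants$ref != variants$alt))
  gb <- genome_base(genome, variants$contig, variants$pos)
  if (any(gb != variants$ref)) {
    bad <- which(gb != variants$ref)[1]
    stop("genome base does not match ref at ",
         variants$contig[bad], ":", variants$pos[bad],
         " (genome ", gb[bad], ", ref ", variants$ref[bad], ")")
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  is_pyr <- variants$ref %in% c("C", "T")
  nb <- rep(NA_character_, n)
  # pyrimidine ref: neighbor is the next base on the plus strand
  i <- which(is_pyr & variants$pos < lens[variants$contig])
  if (length(i) > 0) {
    nb[i] <- genome_base(genome, variants$contig[i], variants$pos[i] + 1L)
  }
  # purine ref: neighbor is the previous plus-strand base, complemented
  j <- which(!is_pyr & variants$pos > 1L)
  if (length(j) > 0) {
    nb[j] <- comp_base(genome_base(genome, variants$contig[j], variants$pos[j] - 1L))
  }
  ok <- !is.na(nb) & nb != "N"
  cls_ref <- ifelse(is_pyr, variants$ref, comp_base(variants$ref))
  cls_alt <- ifelse(is_pyr, variants$alt, comp_base(variants$alt))
  variants$mut_class[ok] <- paste0(cls_ref[ok], ">", cls_alt[ok])
  variants$three_prime_base[ok] <- nb[ok]
  variants$is_cpg[ok] <- cls_ref[ok] == "C" & nb[ok] == "G"
  attr(variants, "n_excluded_context") <- sum(!ok)
  variants
}

#' Genomic abundance of the eight collapsed dinucleotides
#'
#' Counts, for each pyrimidine base X in \{C,T\} and each 3' neighbor Y,
#' the occurrences of the dinucleotide XY on both strands of the genome:
#' plus-strand XY occurrences plus plus-strand occurrences of its reverse
#' complement (which read XY on the minus strand). Overlapping occurrences
#' count; windows containing `N` do not. Note CG and TA are their own
#' reverse complements, so each plus-strand occurrence contributes twice —
#' the same convention under which a CpG C>T call on either strand is one
#' event at one of two strand-symmetric sites.
#'
#' @param genome Named `DNAStringSet`.
#' @return A 2 x 4 matrix (rows `C`,`T`; columns `A`,`C`,`G`,`T`) of site
#'   counts.
#' @export
count_dinucleotide_abundance <- function(genome) {
  din <- colSums(Biostrings::dinucleotideFrequency(genome))
  ab <- matrix(0, nrow = 2, ncol = 4, dimnames = list(c("C", "T"), BASES))
  for (x in c("C", "T")) {
    for (y in BASES) {
      d <- paste0(x, y)
      ab[x, y] <- din[[d]] + din[[revcomp(d)]]
    }
  }
  ab
}

#' Build the 24-category normalized mutation spectrum
#'
#' @param genome Named `DNAStringSet`.
#' @param calls Classified calls (see [classify_calls()]); unclassified
#'   (NA-context) calls are tallied separately, never silently dropped.
#' @return A `spectrum_table`: list with `counts` (6 x 4), `abundance`
#'   (2 x 4 collapsed dinucleotide sites), `rate` (6 x 4, counts/abundance
#'   x 1e9, `NA` where abundance is 0 and flagged in `undefined_cells`),
#'   and `n_excluded_context`.
#' @export
build_spectrum <- function(genome, calls) {
  if (!"mut_class" %in% names(calls)) {
    stop("calls are not classified; run classify_calls() first")
  }
  counts <- matrix(0L, nrow = 6, ncol = 4,
                   dimnames = list(MUT_CLASSES, BASES))
  cl <- calls$mut_class
  keep <- !is.na(cl)
  if (any(keep)) {
    tab <- table(factor(cl[keep], levels = MUT_CLASSES),
                 factor(calls$three_prime_base[keep], levels = BASES))
    counts[] <- as.integer(tab)
  }
  ab <- count_dinucleotide_abundance(genome)
  ab6 <- ab[substr(MUT_CLASSES, 1, 1), , drop = FALSE]
  rownames(ab6) <- MUT_CLASSES
  if (any(counts > 0 & ab6 == 0)) {
    stop("mutation count in a context with zero genomic abundance; ",
         "calls do not belong to this genome")
  }
  rate <- counts / ab6 * 1e9
  undef <- which(ab6 == 0, arr.ind = TRUE)
  rate[ab6 == 0] <- NA_real_
  structure(
    list(counts = counts, abundance = ab, rate = rate,
         undefined_cells = undef,
         n_excluded_context = sum(!keep)),
    class = "spectrum_table"
  )
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("spectrum_table:", sum(x$counts), "classified SNVs",
      sprintf("(%d excluded, N context)\n", x$n_excluded_context))
  cat("normalized rate per 1e9 bases (rows: class, cols: 3' neighbor):\n")
  print(round(x$rate, 2))
  invisible(x)
}

#' CpG / non-CpG partition of C>T calls
#'
#' @param calls Classified calls.
#' @return List with `n_total` (all calls, including NA-context), `n_ct_cpg`,
#'   `n_ct_noncpg`, and the two percentages of `n_total`.
#' @export
cpg_partition <- function(calls) {
  n_total <- nrow(calls)
  ct <- !is.na(calls$mut_class) & calls$mut_class == "C>T"
  n_cpg <- sum(ct & calls$is_cpg)
  n_non <- sum(ct & !calls$is_cpg)
  list(
    n_total = n_total,
    n_ct_cpg = n_cpg,
    n_ct_noncpg = n_non,
    pct_ct_cpg = if (n_total > 0) 100 * n_cpg / n_total else 0,
    pct_ct_noncpg = if (n_total > 0) 100 * n_non / n_total else 0
  )
}

#' Correlate CpG and non-CpG C>T percentages with total SNV load
#'
#' Pearson correlation across clones between each clone's total SNV count
#' and its percentage of CpG (resp. non-CpG) C>T mutations — the statistic
#' behind the observation that non-CpG C>T load (deamination-like) scales
#' with total burden while the CpG fraction runs the other way.
#'
#' @param partitions List of per-clone partitions from [cpg_partition()].
#' @return List with `r_cpg`, `r_noncpg` (NA and flagged via the `degenerate`
#'   element when a variance is zero) and the underlying per-clone table.
#' @export
correlate_partition <- function(partitions) {
  if (length(partitions) < 3) stop("need at least 3 clones")
  tab <- data.frame(
    n_total = vapply(partitions, `[[`, numeric(1), "n_total"),
    pct_ct_cpg = vapply(partitions, `[[`, numeric(1), "pct_ct_cpg"),
    pct_ct_noncpg = vapply(partitions, `[[`, numeric(1), "pct_ct_noncpg")
  )
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }
  r_cpg <- safe_cor(tab$n_total, tab$pct_ct_cpg)
  r_noncpg <- safe_cor(tab$n_total, tab$pct_ct_noncpg)
  list(r_cpg = r_cpg, r_noncpg = r_noncpg,
       degenerate = is.na(r_cpg) || is.na(r_noncpg),
       per_clone = tab)
}
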