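# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' @noRd
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Variant identity key
#'
#' Variants are matched across call sets on (contig, position, ref, alt);
#' position alone is not sufficient (sister module requires identical alt).
#' @noRd
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract single bases from a genome, vectorized over positions.
#'
#' `contig`/`pos` recycle against each other; out-of-range positions are an
#' error (1-based, VCF convention).
#' @noRd
genome_base <- function(genome, contig, pos) {
  stopifnot(length(contig) == length(pos) || length(contig) == 1L)
  if (length(contig) == 1L) contig <- rep(contig, length(pos))
  out <- character(length(pos))
  for (cg in unique(contig)) {
    i <- which(contig == cg)
    if (!cg %in% names(genome)) {
      stop("contig not in genome: ", cg)
    }
    s <- genome[[cg]]
    if (any(pos[i] < 1L | pos[i] > length(s))) {
      stop("position out of range on contig ", cg)
    }
    out[i] <- as.character(Biostrings::extractAt(s, IRanges::IRanges(pos[i], pos[i])))
  }
  out
}

#' Convert 1-based point positions to a GRanges for overlap queries.
#' @noRd
calls_granges <- function(calls, genome = NULL) {
  sl <- NULL
  if (!is.null(genome)) sl <- stats::setNames(Biostrings::width(genome), names(genome))
  gr <- GenomicRanges::GRanges(
    seqnames = calls$contig,
    ranges = IRanges::IRanges(start = calls$pos, width = 1L)
  )
  if (!is.null(sl)) GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  gr
}
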