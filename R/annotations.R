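# Annotation tracks. BED files are 0-based half-open; internally every track
# is a GRanges (1-based closed), the conversion happens only at I/O.

TRACK_NAMES <- c("repeats", "cgi", "tss", "dmr", "simple_repeats", "cds")

#' Construct an annotation set
#'
#' Bundles the interval tracks consumed by the enrichment and coding modules:
#' repeat elements (with class and subfamily), CpG islands, transcription
#' start sites, differentially methylated regions, simple repeats, and a CDS
#' model. Tracks not supplied default to empty; statistics that need a
#' missing track fail loudly rather than silently returning zeros.
#'
#' @param repeats `GRanges` with metadata columns `class` (one of
#'   `LINE`,`SINE`,`LTR`,`other`) and `subfamily` (e.g. `AluY`).
#' @param cgi,dmr,simple_repeats Plain `GRanges` interval tracks (strandless).
#' @param tss Width-1 `GRanges` with strand.
#' @param cds `GRanges` with metadata column `transcript` and strand; per
#'   transcript, exons must be non-overlapping and their total width a
#'   multiple of 3.
#' @param genome Optional genome (`DNAStringSet`); when supplied, every
#'   interval is checked against contig bounds.
#' @return An object of class `annotation_set` (a named list of `GRanges`).
#' @export
annotation_set <- function(repeats = GenomicRanges::GRanges(),
                           cgi = GenomicRanges::GRanges(),
                           tss = GenomicRanges::GRanges(),
                           dmr = GenomicRanges::GRanges(),
                           simple_repeats = GenomicRanges::GRanges(),
                           cds = GenomicRanges::GRanges(),
                           genome = NULL) {
  ann <- list(repeats = repeats, cgi = cgi, tss = tss, dmr = dmr,
              simple_repeats = simple_repeats, cds = cds)
  for (nm in TRACK_NAMES) {
    if (!methods::is(ann[[nm]], "GRanges")) {
      stop("track '", nm, "' must be a GRanges")
    }
  }
  if (length(repeats) > 0 &&
      !all(c("class", "subfamily") %in% names(S4Vectors::mcols(repeats)))) {
    stop("repeat track needs 'class' and 'subfamily' metadata columns")
  }
  if (length(cds) > 0) {
    if (!"transcript" %in% names(S4Vectors::mcols(cds))) {
      stop("cds track needs a 'transcript' metadata column")
    }
    for (tx in unique(cds$transcript)) {
      ex <- cds[cds$transcript == tx]
      if (length(GenomicRanges::reduce(ex)) != length(ex)) {
        stop("overlapping CDS intervals in transcript ", tx)
      }
      if (sum(GenomicRanges::width(ex)) %% 3L != 0L) {
        stop("CDS length of transcript ", tx, " not divisible by 3")
      }
      if (length(unique(as.character(GenomicRanges::strand(ex)))) != 1L) {
        stop("mixed strands in transcript ", tx)
      }
    }
  }
  if (!is.null(genome)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    for (nm in TRACK_NAMES) {
      gr <- ann[[nm]]
      if (length(gr) == 0) next
      ctg <- as.character(GenomicRanges::seqnames(gr))
      if (!all(ctg %in% names(lens))) {
        stop("track '", nm, "' references contigs absent from the genome")
      }
      if (any(GenomicRanges::start(gr) < 1L) ||
          any(GenomicRanges::end(gr) > lens[ctg])) {
        stop("track '", nm, "' has intervals outside contig bounds")
      }
    }
  }
  structure(ann, class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set\n")
  for (nm in TRACK_NAMES) {
    cat(sprintf("  %-15s %d intervals\n", nm, length(x[[nm]])))
  }
  invisible(x)
}

read_bed_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(NULL)
  utils::read.table(text = lines, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, quote = "")
}

bed_to_granges <- function(tab) {
  if (is.null(tab)) return(GenomicRanges::GRanges())
  if (any(tab[[3]] <= tab[[2]])) stop("BED interval with end <= start")
  GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges = IRanges::IRanges(start = tab[[2]] + 1L, end = tab[[3]])
  )
}

#' Read annotation tracks from BED / CDS files
#'
#' All interval files are BED-style: 0-based half-open, tab-separated, with
#' track-specific extra columns:
#' \describe{
#'   \item{repeats}{col 4 = subfamily (e.g. `AluY`), col 5 = class
#'     (`LINE`/`SINE`/`LTR`/`other`).}
#'   \item{tss}{col 4 = name (optional), col 5 = score (ignored), col 6 =
#'     strand; intervals should have width 1 (the TSS base).}
#'   \item{cds}{col 4 = transcript id, col 5 = strand, col 6 = frame
#'     (0/1/2, of the exon's first base in transcript order).}
#'   \item{cgi, dmr, simple_repeats}{plain BED3+.}
#' }
#' Empty files yield empty tracks. Out-of-bounds intervals are an error when
#' `genome` is supplied.
#'
#' @param repeats,cgi,tss,dmr,simple_repeats,cds File paths (each optional).
#' @param genome Optional genome for bounds checking.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(repeats = NULL, cgi = NULL, tss = NULL,
                             dmr = NULL, simple_repeats = NULL, cds = NULL,
                             genome = NULL) {
  out <- list()
  if (!is.null(repeats)) {
    tab <- read_bed_table(repeats)
    gr <- bed_to_granges(tab)
    if (length(gr) > 0) {
      if (ncol(tab) < 5L) stop("repeat BED needs subfamily (col 4) and class (col 5)")
      gr$subfamily <- as.character(tab[[4]])
      gr$class <- as.character(tab[[5]])
    }
    out$repeats <- gr
  }
  for (nm in c("cgi", "dmr", "simple_repeats")) {
    p <- switch(nm, cgi = cgi, dmr = dmr, simple_repeats = simple_repeats)
    if (!is.null(p)) out[[nm]] <- bed_to_granges(read_bed_table(p))
  }
  if (!is.null(tss)) {
    tab <- read_bed_table(tss)
    gr <- bed_to_granges(tab)
    if (length(gr) > 0 && ncol(tab) >= 6L) {
      GenomicRanges::strand(gr) <- tab[[6]]
    }
    out$tss <- gr
  }
  if (!is.null(cds)) {
    tab <- read_bed_table(cds)
    gr <- bed_to_granges(tab)
    if (length(gr) > 0) {
      if (ncol(tab) < 5L) stop("CDS track needs transcript (col 4) and strand (col 5)")
      gr$transcript <- as.character(tab[[4]])
      GenomicRanges::strand(gr) <- tab[[5]]
      if (ncol(tab) >= 6L) gr$frame <- as.integer(tab[[6]])
    }
    out$cds <- gr
  }
  do.call(annotation_set, c(out, list(genome = genome)))
}

#' Write a track as BED (0-based half-open)
#'
#' The inverse of [read_annotations()] for a single track; extra metadata
#' columns are appended in the track-specific order documented there.
#'
#' @param gr A `GRanges` track.
#' @param path Output path.
#' @param kind One of `"plain"`, `"repeats"`, `"tss"`, `"cds"`.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(gr, path, kind = "plain") {
  if (length(gr) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  base <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  extra <- switch(kind,
    plain = NULL,
    repeats = data.frame(sub = gr$subfamily, cls = gr$class),
    tss = data.frame(name = gr$name %||% paste0("tss", seq_along(gr)),
                     score = 0L,
                     strand = as.character(GenomicRanges::strand(gr))),
    cds = data.frame(tx = gr$transcript,
                     strand = as.character(GenomicRanges::strand(gr)),
                     frame = gr$frame %||% 0L),
    stop("unknown BED kind: ", kind)
  )
  tab <- if (is.null(extra)) base else cbind(base, extra)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
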