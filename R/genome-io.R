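#' Read a reference genome from FASTA
#'
#' Contigs are returned as a named [Biostrings::DNAStringSet] in file order.
#' Sequence is uppercased and every character outside `A/C/G/T/N` (including
#' IUPAC ambiguity codes) is replaced by `N`, so downstream context
#' classification and abundance counting see a single alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; names are the first whitespace-delimited
#'   word of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtn"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("empty FASTA: no sequence records in ", path)
  }
  nm <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  chars <- toupper(as.character(raw))
  chars <- gsub("[^ACGTN]", "N", chars)
  if (any(nchar(chars) == 0L)) stop("zero-length contig in FASTA")
  genome <- Biostrings::DNAStringSet(chars)
  names(genome) <- nm
  genome
}

#' Write a genome to FASTA
#'
#' @param genome A named `DNAStringSet` (as returned by [read_genome()] or
#'   [generate_genome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
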