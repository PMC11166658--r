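# Candidate/call VCF I/O. Positions are 1-based (VCF convention). Read-level
# metrics travel in custom INFO tags, declared in the header by the writer
# and validated by the reader:
#   DP   depth                       CQ  phred quality of the central base
#   VAC  variant-allele read count   SQ  mean quality over the 11-base window
#   GM   gaps+mismatches in window   PAC variant-allele reads in the parent
#   SAC  variant-allele reads in each sister clone (Number=.)
#   KNOWN/SRPT/HPOL flags: dbSNP-listed / simple repeat / homopolymer run

METRIC_TAGS <- c("DP", "VAC", "CQ", "SQ", "GM", "PAC", "SAC")
FLAG_TAGS <- c("KNOWN", "SRPT", "HPOL")

vcf_header_lines <- function(genome, with_metrics) {
  h <- c("##fileformat=VCFv4.2", "##source=cpgmutspec")
  if (!is.null(genome)) {
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                      Biostrings::width(genome)))
  }
  if (with_metrics) {
    h <- c(h,
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##INFO=<ID=VAC,Number=1,Type=Integer,Description="Variant allele read count">',
      '##INFO=<ID=CQ,Number=1,Type=Float,Description="Quality of central base">',
      '##INFO=<ID=SQ,Number=1,Type=Float,Description="Mean quality of surrounding 11-base window">',
      '##INFO=<ID=GM,Number=1,Type=Integer,Description="Gap and mismatch count in window">',
      '##INFO=<ID=PAC,Number=1,Type=Integer,Description="Variant allele reads in parental cells">',
      '##INFO=<ID=SAC,Number=.,Type=Integer,Description="Variant allele reads in each sister clone">',
      '##INFO=<ID=KNOWN,Number=0,Type=Flag,Description="Known variant (dbSNP)">',
      '##INFO=<ID=SRPT,Number=0,Type=Flag,Description="In simple repeat region">',
      '##INFO=<ID=HPOL,Number=0,Type=Flag,Description="In homopolymer run">'
    )
  }
  c(h, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Write variants (candidates or calls) to VCF
#'
#' When the metric columns of a candidate set are present they are written as
#' the custom INFO tags documented in [read_variants()]; a bare call set
#' (contig/pos/ref/alt only) is written with `INFO=.`. One ALT per record.
#'
#' @param variants Candidate or call `data.frame`.
#' @param path Output path.
#' @param genome Optional genome; adds `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, genome = NULL) {
  with_metrics <- all(c("depth", "alt_count") %in% names(variants))
  lines <- vcf_header_lines(genome, with_metrics)
  if (nrow(variants) > 0) {
    info <- "."
    if (with_metrics) {
      sac <- vapply(seq_len(nrow(variants)), function(i) {
        s <- variants$sister_alt[[i]]
        if (length(s) == 0) "" else paste0(";SAC=", paste(s, collapse = ","))
      }, character(1))
      info <- sprintf("DP=%d;VAC=%d;CQ=%g;SQ=%g;GM=%d;PAC=%d%s%s%s%s",
        as.integer(variants$depth), as.integer(variants$alt_count),
        variants$central_qual, variants$surround_qual,
        as.integer(variants$gap_mismatch),
        as.integer(variants$parental_alt_count), sac,
        ifelse(variants$known_variant, ";KNOWN", ""),
        ifelse(variants$in_simple_repeat, ";SRPT", ""),
        ifelse(variants$in_homopolymer, ";HPOL", ""))
    }
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
      variants$contig, as.integer(variants$pos),
      variants$ref, variants$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SNV candidates (or bare calls) from VCF
#'
#' Multi-allelic records are split into one candidate per ALT; records whose
#' REF or ALT is not a single A/C/G/T base (indels, symbolic alleles) are
#' skipped and counted in the `n_skipped_non_snv` attribute of the result.
#' With `require_metrics = TRUE` (default) the custom INFO tags listed in
#' the package VCF dialect (`DP`,`VAC`,`CQ`,`SQ`,`GM`,`PAC`,`SAC`, and the
#' flags `KNOWN`,`SRPT`,`HPOL`) must be declared in the header — a missing
#' tag is a hard error, never a silently passing default.
#'
#' @param path VCF file path.
#' @param genome Optional genome; REF bases are checked against it.
#' @param require_metrics Validate and load the read-level metric tags.
#' @return A `data.frame` of candidates (columns `contig`, `pos`, `ref`,
#'   `alt`, and with metrics `depth`, `alt_count`, `central_qual`,
#'   `surround_qual`, `gap_mismatch`, `parental_alt_count`, `sister_alt`
#'   (list column), `known_variant`, `in_simple_repeat`, `in_homopolymer`),
#'   with attribute `n_skipped_non_snv`.
#' @export
read_variants <- function(path, genome = NULL, require_metrics = TRUE) {
  vcf <- VariantAnnotation::readVcf(path)
  if (require_metrics) {
    have <- rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))
    missing <- setdiff(c(METRIC_TAGS, FLAG_TAGS), have)
    if (length(missing) > 0) {
      stop("VCF header lacks required metric tag(s): ",
           paste(missing, collapse = ", "))
    }
  }
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES
  n_skip <- sum(!is_snv)
  if (n_skip > 0) {
    message("read_variants: skipped ", n_skip, " non-SNV record(s)")
  }
  keep <- which(is_snv)
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE
  )
  if (require_metrics) {
    inf <- VariantAnnotation::info(vcf)
    out$depth <- as.integer(inf$DP[keep])
    out$alt_count <- as.integer(inf$VAC[keep])
    out$central_qual <- as.numeric(inf$CQ[keep])
    out$surround_qual <- as.numeric(inf$SQ[keep])
    out$gap_mismatch <- as.integer(inf$GM[keep])
    out$parental_alt_count <- as.integer(inf$PAC[keep])
    out$sister_alt <- lapply(as.list(inf$SAC[keep]), as.integer)
    out$known_variant <- as.logical(inf$KNOWN[keep])
    out$in_simple_repeat <- as.logical(inf$SRPT[keep])
    out$in_homopolymer <- as.logical(inf$HPOL[keep])
    bad <- vapply(out[c("depth", "alt_count", "central_qual", "surround_qual",
                        "gap_mismatch", "parental_alt_count")],
                  function(v) anyNA(v), logical(1))
    if (any(bad)) {
      stop("missing metric value(s) in VCF records for tag(s): ",
           paste(names(bad)[bad], collapse = ", "))
    }
  }
  if (!is.null(genome) && nrow(out) > 0) {
    gb <- genome_base(genome, out$contig, out$pos)
    if (any(gb != out$ref)) {
      stop("REF base disagrees with genome at ",
           sum(gb != out$ref), " position(s), first: ",
           out$contig[gb != out$ref][1], ":", out$pos[gb != out$ref][1])
    }
  }
  attr(out, "n_skipped_non_snv") <- n_skip
  out
}
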