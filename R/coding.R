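# Codon-level consequence annotation. The standard genetic code only;
# coordinates are mapped into spliced CDS space per transcript, with
# minus-strand transcripts read off the reverse complement.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

effect_class <- function(ref_aa, alt_aa) {
  ifelse(alt_aa == ref_aa, "silent",
         ifelse(alt_aa == "*", "nonsense", "missense"))
}

codon_at <- function(spliced, idx) substr(spliced, 3L * idx - 2L, 3L * idx)

# per-transcript structure: exons in transcript order with cumulative
# spliced offsets, plus the spliced sequence on the coding strand
build_transcript_model <- function(cds, genome) {
  models <- list()
  for (tx in unique(cds$transcript)) {
    ex <- cds[cds$transcript == tx]
    ex <- GenomicRanges::sort(ex)                   # genomic order
    strand <- as.character(GenomicRanges::strand(ex))[1]
    ctg <- as.character(GenomicRanges::seqnames(ex))[1]
    seqs <- as.character(Biostrings::Views(genome[[ctg]],
                                           GenomicRanges::start(ex),
                                           GenomicRanges::end(ex)))
    spliced_plus <- paste(seqs, collapse = "")
    spliced <- if (strand == "-") revcomp(spliced_plus) else spliced_plus
    if (nchar(spliced) %% 3L != 0L) {
      stop("spliced CDS of ", tx, " not divisible by 3")
    }
    tx_order <- if (strand == "-") rev(seq_along(ex)) else seq_along(ex)
    w <- GenomicRanges::width(ex)
    off <- integer(length(ex))
    off[tx_order] <- cumsum(c(0L, utils::head(w[tx_order], -1L)))
    if (!is.null(ex$frame)) {
      if (any(ex$frame != off %% 3L)) {
        stop("inconsistent frame annotation in transcript ", tx)
      }
    }
    models[[tx]] <- list(tx = tx, contig = ctg, strand = strand,
                         start = GenomicRanges::start(ex),
                         end = GenomicRanges::end(ex),
                         offset = off, spliced = spliced)
  }
  models
}

#' Annotate coding consequences of SNVs
#'
#' Maps each call falling in a CDS exon into spliced coding coordinates
#' (reverse-complemented for minus-strand transcripts), rebuilds the
#' affected codon, and classifies the change as nonsense, missense or
#' silent under the standard genetic code. Calls overlapping several
#' transcripts yield one effect per transcript.
#'
#' @param calls Call `data.frame`; when already classified, `is_cpg_ct`
#'   is derived from `mut_class`/`is_cpg`, otherwise calls are classified
#'   against `genome` first.
#' @param cds CDS `GRanges` (metadata `transcript`, strand, optional
#'   `frame` which is validated).
#' @param genome Named `DNAStringSet`.
#' @return `data.frame`: one row per (call, transcript) with `transcript`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect`, `is_cpg_ct`.
#' @export
annotate_coding <- function(calls, cds, genome) {
  if (!"mut_class" %in% names(calls)) {
    calls <- classify_calls(genome, calls)
  }
  models <- build_transcript_model(cds, genome)
  out <- list()
  for (mod in models) {
    sel <- which(calls$contig == mod$contig)
    for (i in sel) {
      pos <- calls$pos[i]
      ex <- which(pos >= mod$start & pos <= mod$end)
      if (length(ex) == 0) next
      ex <- ex[1]
      cdspos <- if (mod$strand == "+") {
        mod$offset[ex] + (pos - mod$start[ex] + 1L)
      } else {
        mod$offset[ex] + (mod$end[ex] - pos + 1L)
      }
      ci <- (cdspos - 1L) %/% 3L + 1L
      cp <- (cdspos - 1L) %% 3L + 1L
      ref_tx <- if (mod$strand == "+") calls$ref[i] else comp_base(calls$ref[i])
      alt_tx <- if (mod$strand == "+") calls$alt[i] else comp_base(calls$alt[i])
      ref_codon <- codon_at(mod$spliced, ci)
      if (substr(ref_codon, cp, cp) != ref_tx) {
        stop("CDS model inconsistent with genome at ", mod$contig, ":", pos)
      }
      alt_codon <- ref_codon
      substr(alt_codon, cp, cp) <- alt_tx
      ref_aa <- GENETIC_CODE_TABLE[[ref_codon]]
      alt_aa <- GENETIC_CODE_TABLE[[alt_codon]]
      out[[length(out) + 1L]] <- data.frame(
        contig = calls$contig[i], pos = pos,
        ref = calls$ref[i], alt = calls$alt[i],
        transcript = mod$tx, codon_index = ci, codon_pos = cp,
        ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = ref_aa, alt_aa = alt_aa,
        effect = effect_class(ref_aa, alt_aa),
        is_cpg_ct = !is.na(calls$mut_class[i]) &&
          calls$mut_class[i] == "C>T" && isTRUE(calls$is_cpg[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      contig = character(0), pos = integer(0), ref = character(0),
      alt = character(0), transcript = character(0),
      codon_index = integer(0), codon_pos = integer(0),
      ref_codon = character(0), alt_codon = character(0),
      ref_aa = character(0), alt_aa = character(0), effect = character(0),
      is_cpg_ct = logical(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

#' Census of codon changes reachable by a CpG-context C>T
#'
#' Pure enumeration, no inputs: every codon, every codon position, both
#' strand configurations of the CpG — a `C>T` on the coding strand (the C
#' needs a 3' `G`, which sits in the next codon when the C is at position
#' 3) and a `G>A` on the coding strand (the CpG lies on the template
#' strand; the G needs a 5' `C`, in the previous codon when the G is at
#' position 1). Entries whose CpG partner falls outside the codon state
#' the required flanking base.
#'
#' @return `data.frame`: `ref_codon`, `codon_pos`, `strand_of_c`
#'   (`"coding"`/`"template"`), `alt_codon`, `ref_aa`, `alt_aa`, `effect`,
#'   `required_flank` (`"none"`, `"next codon starts with G"`, or
#'   `"previous codon ends with C"`).
#' @export
cpg_ct_codon_census <- function() {
  codons <- names(GENETIC_CODE_TABLE)
  rows <- list()
  for (codon in codons) {
    b <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      # coding-strand C>T: base p is C, 3' neighbor G
      if (b[p] == "C") {
        flank <- if (p < 3) {
          if (b[p + 1] == "G") "none" else NA_character_
        } else "next codon starts with G"
        if (!is.na(flank)) {
          alt <- b; alt[p] <- "T"
          rows[[length(rows) + 1L]] <- data.frame(
            ref_codon = codon, codon_pos = p, strand_of_c = "coding",
            alt_codon = paste(alt, collapse = ""),
            required_flank = flank, stringsAsFactors = FALSE)
        }
      }
      # template-strand CpG: coding-strand G>A, 5' neighbor C
      if (b[p] == "G") {
        flank <- if (p > 1) {
          if (b[p - 1] == "C") "none" else NA_character_
        } else "previous codon ends with C"
        if (!is.na(flank)) {
          alt <- b; alt[p] <- "A"
          rows[[length(rows) + 1L]] <- data.frame(
            ref_codon = codon, codon_pos = p, strand_of_c = "template",
            alt_codon = paste(alt, collapse = ""),
            required_flank = flank, stringsAsFactors = FALSE)
        }
      }
    }
  }
  census <- do.call(rbind, rows)
  census$ref_aa <- unname(GENETIC_CODE_TABLE[census$ref_codon])
  census$alt_aa <- unname(GENETIC_CODE_TABLE[census$alt_codon])
  census$effect <- effect_class(census$ref_aa, census$alt_aa)
  census
}

SEVERITY <- c(nonsense = 3L, missense = 2L, silent = 1L)

#' Summarize coding effects
#'
#' Counts nonsense:missense:silent, tabulates amino-acid substitutions,
#' and reports the fraction of effects hitting an arginine codon. Each
#' variant counts once, by its most severe effect across overlapping
#' transcripts (nonsense > missense > silent).
#'
#' @param effects Output of [annotate_coding()].
#' @return List with `counts` (named vector), `n_total`,
#'   `substitutions` (`ref_aa`/`alt_aa`/`n` table), `arg_fraction`.
#' @export
summarize_effects <- function(effects) {
  if (nrow(effects) == 0) {
    return(list(counts = c(nonsense = 0L, missense = 0L, silent = 0L),
                n_total = 0L,
                substitutions = data.frame(ref_aa = character(0),
                                           alt_aa = character(0),
                                           n = integer(0)),
                arg_fraction = NA_real_))
  }
  key <- variant_key(effects$contig, effects$pos, effects$ref, effects$alt)
  ord <- order(key, -SEVERITY[effects$effect])
  eff1 <- effects[ord, ][!duplicated(key[ord]), ]
  counts <- vapply(c("nonsense", "missense", "silent"),
                   function(e) sum(eff1$effect == e), integer(1))
  subs <- as.data.frame(table(ref_aa = eff1$ref_aa, alt_aa = eff1$alt_aa),
                        responseName = "n", stringsAsFactors = FALSE)
  subs <- subs[subs$n > 0, ]
  rownames(subs) <- NULL
  list(counts = counts, n_total = nrow(eff1), substitutions = subs,
       arg_fraction = sum(eff1$ref_aa == "R") / nrow(eff1))
}
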