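# Shared-SNV detection across sister clones and reference-swap concordance.
# Variants are matched on (contig, pos, ref, alt) -- identical alternative
# allele required, not just position.

#' Shared SNVs across clone call sets
#'
#' Call sets must have been produced with the sister-exclusion filter OFF
#' (otherwise shared variants are removed upstream by construction).
#' The overall shared fraction is reported under both natural definitions,
#' which differ when a variant is shared by more than two clones:
#' `shared_fraction_unique` = shared variant keys / all distinct keys, and
#' `shared_fraction_instances` = call-set entries that are shared /
#' total entries summed over clones.
#'
#' @param call_sets Named (or unnamed) list of per-clone call
#'   `data.frame`s with `contig`, `pos`, `ref`, `alt`. Duplicate keys
#'   within one clone are an upstream bug and an error.
#' @return A `shared_snv_result`: `per_clone_total`, `pairwise` (symmetric
#'   matrix, zero diagonal), `shared_keys` (`data.frame` of each shared key
#'   and the clone subset carrying it), and the two shared fractions.
#' @export
shared_snvs <- function(call_sets) {
  n <- length(call_sets)
  nms <- names(call_sets) %||% paste0("clone", seq_len(n))
  if (is.null(names(call_sets))) names(call_sets) <- nms
  keys <- lapply(call_sets, function(d) {
    k <- variant_key(d$contig, d$pos, d$ref, d$alt)
    if (anyDuplicated(k)) {
      stop("duplicate variant keys within one clone call set")
    }
    k
  })
  pairwise <- matrix(0L, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        s <- length(intersect(keys[[i]], keys[[j]]))
        pairwise[i, j] <- s
        pairwise[j, i] <- s
      }
    }
  }
  all_keys <- unlist(keys, use.names = FALSE)
  tab <- table(all_keys)
  shared <- names(tab)[tab >= 2]
  shared_df <- data.frame(
    key = shared,
    clones = vapply(shared, function(k) {
      paste(nms[vapply(keys, function(x) k %in% x, logical(1))],
            collapse = ",")
    }, character(1)),
    n_clones = as.integer(tab[shared]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    per_clone_total = vapply(keys, length, integer(1)),
    pairwise = pairwise,
    shared_keys = shared_df,
    shared_fraction_unique =
      if (length(tab) > 0) length(shared) / length(tab) else NA_real_,
    shared_fraction_instances =
      if (length(all_keys) > 0) {
        sum(all_keys %in% shared) / length(all_keys)
      } else NA_real_
  ), class = "shared_snv_result")
}

#' @export
print.shared_snv_result <- function(x, ...) {
  cat("shared_snv_result:", length(x$per_clone_total), "clones,",
      nrow(x$shared_keys), "shared variant(s)\n")
  print(x$pairwise)
  invisible(x)
}

#' Concordance between two identifications of the same clone
#'
#' Measures how similar the SNV sets are when the same clone is analyzed
#' against two different reference samples (e.g. parental cells vs a sister
#' clone). Default is the Jaccard index |A n B| / |A u B| as a percentage
#' — symmetric, 100 for identical sets; `method = "overlap"` gives the
#' asymmetric |A n B| / |A| instead.
#'
#' @param set_a,set_b Call `data.frame`s (`contig`, `pos`, `ref`, `alt`).
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return Concordance in percent; `NA` (with a warning) when both sets
#'   are empty.
#' @export
reference_swap_concordance <- function(set_a, set_b,
                                       method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  a <- unique(variant_key(set_a$contig, set_a$pos, set_a$ref, set_a$alt))
  b <- unique(variant_key(set_b$contig, set_b$pos, set_b$ref, set_b$alt))
  if (length(a) == 0 && length(b) == 0) {
    warning("both call sets empty; concordance undefined")
    return(NA_real_)
  }
  inter <- length(intersect(a, b))
  denom <- switch(method,
                  jaccard = length(union(a, b)),
                  overlap = length(a))
  if (denom == 0) return(NA_real_)
  100 * inter / denom
}
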