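## Callset comparison inside high-confidence regions.  Matching is exact on
## the canonical key (chrom, start, end, ref, alt): genotype- and
## zygosity-blind, presence-only.  True negatives are counted in reference
## base pairs, which makes specificity well-defined for a genome-scale
## negative class.

#' Restrict a canonical callset to high-confidence regions
#'
#' A variant is kept iff its `[start, end]` interval (for insertions, the
#' anchor base) lies fully inside one region.  Full containment, rather than
#' any overlap, avoids counting half-covered deletions at panel edges whose
#' truth status is ambiguous.
#'
#' @param calls A canonical data.frame (from [harmonize_callset()]).
#' @param regions A merged `bed_regions` set (from [read_bed()]).
#' @return The kept subset of `calls`.
#' @export
restrict_to_regions <- function(calls, regions) {
  if (nrow(calls) == 0L || nrow(regions) == 0L) {
    return(calls[integer(0), , drop = FALSE])
  }
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    r <- regions[regions$chrom == calls$chrom[i], , drop = FALSE]
    ## regions: 0-based half-open -> 1-based inclusive is (start+1, end)
    keep[i] <- any(calls$start[i] >= r$start + 1L & calls$end[i] <= r$end)
  }
  calls[keep, , drop = FALSE]
}

#' Match a query callset against a truth callset
#'
#' Exact-key matching on `(chrom, start, end, ref, alt)` between two
#' harmonized, region-restricted canonical sets.  TPs and FPs carry the
#' query's quality parameters; FNs start with the truth row's coordinates,
#' parameters absent, and `fn_subtype = "unchecked"` until the read re-check
#' runs.
#'
#' @param query,truth Canonical data.frames.
#' @return A classified-call data.frame: canonical columns plus `class`
#'   (`TP`/`FP`/`FN`) and `fn_subtype` (`b-FN`/`seq-FN`/`unchecked`).
#' @export
match_callsets <- function(query, truth) {
  tp <- query[query$key %in% truth$key, , drop = FALSE]
  fp <- query[!query$key %in% truth$key, , drop = FALSE]
  fn <- truth[!truth$key %in% query$key, , drop = FALSE]
  for (pc in param_cols) fn[[pc]] <- rep(NA_real_, nrow(fn))
  add <- function(df, klass, sub) {
    if (nrow(df)) { df$class <- klass; df$fn_subtype <- sub }
    else { df$class <- character(0); df$fn_subtype <- character(0) }
    df
  }
  out <- rbind(add(tp, "TP", "none"), add(fp, "FP", "none"),
               add(fn, "FN", "unchecked"))
  rownames(out) <- NULL
  out
}

## 1-based reference positions claimed by a call: every deleted base for a
## DEL, the anchor base for an INS, start..end otherwise.
call_positions <- function(calls) {
  if (nrow(calls) == 0L) return(character(0))
  unlist(lapply(seq_len(nrow(calls)), function(i) {
    pos <- if (calls$vclass[i] == "INS") calls$start[i]
           else seq.int(calls$start[i], calls$end[i])
    paste0(calls$chrom[i], ":", pos)
  }), use.names = FALSE)
}

#' Count true-negative bases
#'
#' `tn_bases` = (total bases in the merged regions) minus the number of
#' distinct reference positions inside the regions claimed by any TP or FP
#' call (a deletion claims every deleted base; an insertion claims its one
#' anchor base).  FN positions are not subtracted: specificity concerns the
#' query's positive claims only.
#'
#' @param regions A merged `bed_regions` set.
#' @param calls A classified-call data.frame (region-restricted).
#' @return Integer count of true-negative bases.
#' @export
count_tn_bases <- function(regions, calls) {
  pos <- unique(call_positions(calls[calls$class %in% c("TP", "FP"), , drop = FALSE]))
  total_bases(regions) - length(pos)
}

#' Compute the accuracy metric set
#'
#' Standard set-level metrics plus the maximum theoretical recall
#' (`recall_max`), which credits back the bioinformatic false negatives —
#' expected variants that the re-check found supporting reads for, hence
#' callable in principle under relaxed caller parameters:
#' `recall_max = (TP + bFN) / (TP + FN)`.
#' Any ratio whose denominator is zero is reported as `NA` (serialised as
#' null), never as NaN.
#'
#' @param calls A classified-call data.frame, or a named list/vector with
#'   integer counts `tp`, `fp`, `fn`.
#' @param tn_bases True-negative base count from [count_tn_bases()], or `NA`.
#' @param bfn_count Number of bioinformatic FNs among the FNs (0 before the
#'   re-check; `NA` when the re-check has not run, in which case `recall_max`
#'   is not reported).
#' @return A `metric_set` list: counts `tp`, `fp`, `fn`, `bfn`, `tn_bases`
#'   and metrics `recall`, `precision`, `specificity`, `f1`, `fdr`,
#'   `recall_max`.
#' @export
compute_metrics <- function(calls, tn_bases = NA_integer_, bfn_count = 0L) {
  if (is.data.frame(calls)) {
    tp <- sum(calls$class == "TP")
    fp <- sum(calls$class == "FP")
    fn <- sum(calls$class == "FN")
  } else {
    tp <- calls[["tp"]]; fp <- calls[["fp"]]; fn <- calls[["fn"]]
  }
  if (!is.na(bfn_count) && bfn_count > fn) {
    vb_stop("bfn_count (%d) exceeds FN count (%d)", bfn_count, fn)
  }
  ratio <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  recall <- ratio(tp, tp + fn)
  precision <- ratio(tp, tp + fp)
  fdr <- if (is.na(precision)) NA_real_ else 1 - precision
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  specificity <- if (is.na(tn_bases)) NA_real_ else ratio(tn_bases, tn_bases + fp)
  recall_max <- if (is.na(bfn_count)) NA_real_ else ratio(tp + bfn_count, tp + fn)
  structure(list(
    tp = tp, fp = fp, fn = fn,
    bfn = if (is.na(bfn_count)) NA_integer_ else as.integer(bfn_count),
    tn_bases = tn_bases,
    recall = recall, precision = precision, specificity = specificity,
    f1 = f1, fdr = fdr, recall_max = recall_max
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "null" else sprintf("%.4f", v)
  cat(sprintf("counts: TP=%d FP=%d FN=%d (b-FN=%s) TN_bases=%s\n",
              x$tp, x$fp, x$fn,
              if (is.na(x$bfn)) "?" else x$bfn,
              if (is.na(x$tn_bases)) "?" else x$tn_bases))
  cat(sprintf("recall=%s precision=%s specificity=%s F1=%s FDR=%s recall_max=%s\n",
              fmt(x$recall), fmt(x$precision), fmt(x$specificity),
              fmt(x$f1), fmt(x$fdr), fmt(x$recall_max)))
  invisible(x)
}
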