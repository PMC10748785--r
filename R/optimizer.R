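## Parameter analysis on the sequencing-positive set: which quality
## parameters separate callable variants (TPs, b-FNs) from artifacts (FPs),
## how well (AUROC), where to cut (Youden's J), and what accuracy a new set
## of caller thresholds would yield.

## Default ROC direction per parameter: larger VAF/DP/QUAL/QD favours a real
## call; larger strand bias favours an artifact.
param_directions <- c(vaf = "greater", dp = "greater", stb = "smaller",
                      qual = "greater", qd = "greater")

#' Quality by depth
#'
#' Scaled variant quality normalised by site depth, `QD = 4 * qual / dp`,
#' used as a fallback for callers that do not report a QD of their own.
#' Kept as a single function so the scaling can be swapped in one place.
#'
#' @param qual Variant quality (Phred-scaled).
#' @param dp Site depth.
#' @return QD, or `NA` when `dp` is 0 or either input is missing.
#' @export
compute_qd <- function(qual, dp) {
  if (is.na(qual) || is.na(dp) || dp == 0) return(NA_real_)
  4 * qual / dp
}

#' Compare parameter distributions across call classes
#'
#' Two-sided Mann-Whitney tests of a quality parameter between TPs and FPs
#' and between TPs and b-FNs, at significance level `alpha`.  The p-value is
#' exact (full enumeration of the rank distribution) when both groups have at
#' most 8 observations and the data are tie-free, and uses the normal
#' approximation with tie and continuity correction otherwise.  A comparison
#' with an empty or all-missing group is skipped and reported as
#' not-computable.
#'
#' @param calls A classified and re-checked call data.frame.
#' @param parameter One of `"vaf"`, `"dp"`, `"stb"`, `"qual"`, `"qd"`.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with one row per comparison: group sizes, U
#'   statistic, two-sided p-value, method and significance flag.
#' @export
compare_distributions <- function(calls, parameter = "vaf", alpha = 0.05) {
  stopifnot(parameter %in% param_cols)
  vals <- function(sel) {
    v <- calls[[parameter]][sel]
    v[!is.na(v)]
  }
  tp <- vals(calls$class == "TP")
  fp <- vals(calls$class == "FP")
  bfn <- vals(calls$class == "FN" & calls$fn_subtype == "b-FN")
  one <- function(x, y, label) {
    if (length(x) == 0L || length(y) == 0L) {
      return(data.frame(comparison = label, parameter = parameter,
                        n1 = length(x), n2 = length(y),
                        U = NA_real_, p = NA_real_, method = "not-computable",
                        significant = NA, stringsAsFactors = FALSE))
    }
    tie_free <- !anyDuplicated(c(x, y))
    exact <- length(x) <= 8L && length(y) <= 8L && tie_free
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE))
    data.frame(comparison = label, parameter = parameter,
               n1 = length(x), n2 = length(y),
               U = unname(wt$statistic), p = wt$p.value,
               method = if (exact) "exact" else "normal-approx",
               significant = wt$p.value < alpha, stringsAsFactors = FALSE)
  }
  rbind(one(tp, fp, "TP_vs_FP"), one(tp, bfn, "TP_vs_bFN"))
}

#' ROC curve of one quality parameter on the SeqPos set
#'
#' Thresholds are placed at midpoints between consecutive distinct observed
#' values, plus infinite sentinels.  For `direction = "greater"` a record is
#' predicted callable when its value is at or above the threshold (and at or
#' below for `"smaller"`).  The AUROC is the trapezoidal area, which equals
#' the pairwise concordance statistic U/(n1*n0) with ties credited 1/2 —
#' both are computed and cross-checked in the test suite.  Records with a
#' missing parameter are excluded and counted.
#'
#' @param records A SeqPos data.frame from [build_seqpos()].
#' @param parameter One of `"vaf"`, `"dp"`, `"stb"`, `"qual"`, `"qd"`.
#' @param direction `"greater"` if larger values indicate a callable variant,
#'   `"smaller"` for the reverse; defaults to the per-parameter convention
#'   (`stb` is `"smaller"`, the rest `"greater"`).
#' @return A `roc_result` list: `parameter`, `direction`, `points`
#'   (data.frame `threshold`, `sensitivity`, `specificity`, sorted by
#'   threshold), `auroc`, `auroc_concordance`, `optimal_cutpoint`,
#'   `optimal_j`, `n_pos`, `n_neg`, `n_missing`.
#' @export
roc_curve <- function(records, parameter = "vaf",
                      direction = param_directions[[parameter]]) {
  stopifnot(parameter %in% param_cols)
  direction <- match.arg(direction, c("greater", "smaller"))
  v <- records[[parameter]]
  keep <- !is.na(v)
  n_missing <- sum(!keep)
  v <- v[keep]; lab <- records$label[keep]
  if (!any(lab == 1L) || !any(lab == 0L)) {
    vb_stop("ROC undefined: need both labels among records with non-missing '%s'",
            parameter)
  }
  s <- if (direction == "greater") v else -v
  pos <- s[lab == 1L]; neg <- s[lab == 0L]
  d <- sort(unique(s))
  thr <- c(-Inf, if (length(d) > 1L) (d[-1] + d[-length(d)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  ## trapezoid over the ROC polygon (FPR = 1 - specificity)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auroc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  ## pairwise concordance with half-credit for ties (internal cross-check)
  conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auroc_conc <- mean(conc)
  j <- sens + spec - 1
  best_j <- max(j)
  ## ties broken toward the threshold retaining more positives (lower in the
  ## transformed scale)
  best_idx <- which(j >= best_j - 1e-12)[1]
  cut_s <- thr[best_idx]
  cutpoint <- if (direction == "greater") cut_s else -cut_s
  points <- data.frame(
    threshold = if (direction == "greater") thr else -thr,
    sensitivity = sens, specificity = spec)
  points <- points[order(points$threshold), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(parameter = parameter, direction = direction,
                 points = points, auroc = auroc,
                 auroc_concordance = auroc_conc,
                 optimal_cutpoint = cutpoint, optimal_j = best_j,
                 n_pos = length(pos), n_neg = length(neg),
                 n_missing = n_missing),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC for %s (%s-is-positive): AUROC=%.4f, cutpoint=%s (J=%.3f), n+=%d n-=%d\n",
              x$parameter, x$direction, x$auroc,
              format(x$optimal_cutpoint, digits = 4), x$optimal_j,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal cutpoint of a ROC curve
#'
#' The threshold maximising Youden's J = sensitivity + specificity - 1, ties
#' broken toward the threshold retaining more positives.  Thresholds are
#' midpoints between the bounding observed values (already so in
#' [roc_curve()]).
#'
#' @param roc A `roc_result`.
#' @return The cutpoint (numeric scalar).
#' @export
optimal_cutpoint <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$optimal_cutpoint
}

#' Threshold set for accuracy simulation
#'
#' @param min_vaf,min_dp,min_qual,min_qd Lower bounds (call must be at or
#'   above to pass); `NULL` means no constraint.
#' @param max_stb Upper bound on strand bias.
#' @param ... Unknown parameter names are a configuration error.
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(min_vaf = NULL, min_dp = NULL, max_stb = NULL,
                          min_qual = NULL, min_qd = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    vb_stop("unknown threshold parameter(s): %s",
            paste(names(extra), collapse = ", "))
  }
  structure(list(min_vaf = min_vaf, min_dp = min_dp, max_stb = max_stb,
                 min_qual = min_qual, min_qd = min_qd),
            class = "threshold_set")
}

call_passes <- function(calls, thresholds) {
  pass <- rep(TRUE, nrow(calls))
  chk <- function(pass, value, bound, op) {
    ## a missing parameter never fails a call
    ok <- is.na(value) | op(value, bound)
    pass & ok
  }
  if (!is.null(thresholds$min_vaf)) pass <- chk(pass, calls$vaf, thresholds$min_vaf, `>=`)
  if (!is.null(thresholds$min_dp)) pass <- chk(pass, calls$dp, thresholds$min_dp, `>=`)
  if (!is.null(thresholds$max_stb)) pass <- chk(pass, calls$stb, thresholds$max_stb, `<=`)
  if (!is.null(thresholds$min_qual)) pass <- chk(pass, calls$qual, thresholds$min_qual, `>=`)
  if (!is.null(thresholds$min_qd)) pass <- chk(pass, calls$qd, thresholds$min_qd, `>=`)
  pass
}

#' Simulate accuracy under new caller thresholds
#'
#' Re-evaluates every TP, FP and b-FN against a [threshold_set()] using its
#' own parameters (caller parameters for TP/FP, pileup parameters for b-FN):
#' passing TPs stay TP and failing TPs become FN; passing FPs stay FP and
#' failing FPs are removed from the positive calls (their reference positions
#' return to the true-negative bases); passing b-FNs are recovered as TPs;
#' seq-FNs always stay FN.  A missing parameter never fails a call.  With an
#' empty threshold set every b-FN is recovered, so the simulated recall
#' equals the input's `recall_max` while the FP count is unchanged.
#'
#' @param calls A classified and re-checked call data.frame.
#' @param thresholds A [threshold_set()].
#' @param tn_bases True-negative bases of the un-simulated run.
#' @return List: `metrics` (a `metric_set`), `calls` (re-classified
#'   data.frame).
#' @export
simulate_thresholds <- function(calls, thresholds = threshold_set(),
                                tn_bases = NA_integer_) {
  stopifnot(inherits(thresholds, "threshold_set"))
  new_calls <- calls
  pass <- call_passes(calls, thresholds)
  is_tp <- calls$class == "TP"
  is_fp <- calls$class == "FP"
  is_bfn <- calls$class == "FN" & calls$fn_subtype == "b-FN"
  new_calls$class[is_tp & !pass] <- "FN"
  new_calls$fn_subtype[is_tp & !pass] <- "b-FN"  # still sequenced & callable
  new_calls$class[is_bfn & pass] <- "TP"
  new_calls$fn_subtype[is_bfn & pass] <- "none"
  drop_fp <- is_fp & !pass
  ## positions freed by removed FPs (and demoted TPs) return to TN bases
  new_tn <- tn_bases
  if (!is.na(tn_bases)) {
    old_cov <- unique(call_positions(calls[calls$class %in% c("TP", "FP"), , drop = FALSE]))
    kept <- new_calls[!drop_fp, , drop = FALSE]
    new_cov <- unique(call_positions(kept[kept$class %in% c("TP", "FP"), , drop = FALSE]))
    new_tn <- tn_bases + length(old_cov) - length(new_cov)
  }
  new_calls <- new_calls[!drop_fp, , drop = FALSE]
  bfn <- sum(new_calls$class == "FN" & new_calls$fn_subtype == "b-FN")
  metrics <- compute_metrics(new_calls, tn_bases = new_tn, bfn_count = bfn)
  list(metrics = metrics, calls = new_calls)
}
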