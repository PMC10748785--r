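seqpos_df <- function(vals, labels) {
  data.frame(key = paste0("k", seq_along(vals)), vclass = "SNV",
             vaf = vals, dp = NA_real_, stb = NA_real_, qual = NA_real_,
             qd = NA_real_, label = labels, stringsAsFactors = FALSE)
}

classified_df <- function(tp = numeric(0), fp = numeric(0), bfn = numeric(0),
                          seqfn = 0L, param = "vaf") {
  mk <- function(v, klass, sub) {
    if (!length(v)) return(NULL)
    df <- do.call(rbind, lapply(seq_along(v), function(i)
      cv_row("c1", i + 1000 * match(klass, c("TP", "FP", "FN")),
             i + 1000 * match(klass, c("TP", "FP", "FN")), "A", "G", "SNV")))
    df[[param]] <- v
    cbind(df, class = klass, fn_subtype = sub)
  }
  sq <- if (seqfn > 0) mk(rep(NA_real_, seqfn), "FN", "seq-FN") else NULL
  out <- rbind(mk(tp, "TP", "none"), mk(fp, "FP", "none"),
               mk(bfn, "FN", "b-FN"), sq)
  ## distinct keys per class block
  out$key <- paste0(out$class, out$fn_subtype, seq_len(nrow(out)))
  out$start <- seq_len(nrow(out)); out$end <- out$start
  out
}

test_that("Mann-Whitney: exact p for {1,2,3} vs {4,5,6} is 0.1", {
  calls <- classified_df(tp = c(1, 2, 3), fp = c(4, 5, 6))
  res <- compare_distributions(calls, "vaf")
  row <- res[res$comparison == "TP_vs_FP", ]
  expect_equal(row$U, 0)
  expect_equal(row$p, 0.1)
  expect_equal(row$method, "exact")
  expect_false(row$significant)
})

test_that("Mann-Whitney exact p equals full enumeration for all small sizes", {
  set.seed(5)
  for (n1 in 1:6) {
    for (n2 in 1:6) {
      x <- sample(seq(0.01, 0.99, by = 0.01), n1)
      y <- sample(setdiff(seq(0.01, 0.99, by = 0.01), x), n2)
      calls <- classified_df(tp = x, fp = y)
      p_pkg <- compare_distributions(calls, "vaf")[1, "p"]
      expect_equal(p_pkg, mw_enum_p(x, y), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("identical small groups are not significant", {
  calls <- classified_df(tp = c(1, 2), fp = c(1, 2))
  row <- compare_distributions(calls, "vaf")[1, ]
  expect_gt(row$p, 0.05)
  expect_false(row$significant)
})

test_that("empty or all-missing groups are reported not-computable", {
  calls <- classified_df(tp = c(1, 2, 3))
  res <- compare_distributions(calls, "vaf")
  expect_equal(res$method[res$comparison == "TP_vs_FP"], "not-computable")
  expect_true(is.na(res$p[res$comparison == "TP_vs_FP"]))
})

test_that("separated generator classes are detected as significant", {
  ## TP VAFs two SDs above FP VAFs at n = 200: significant in >= 95% of seeds
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    tp <- rnorm(100, 0.5, 0.1)
    fp <- rnorm(100, 0.3, 0.1)
    calls <- classified_df(tp = tp, fp = fp)
    hits <- hits + compare_distributions(calls, "vaf")[1, "significant"]
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("ROC handles perfect, inverted and shuffled data", {
  r1 <- roc_curve(seqpos_df(c(0.4, 0.5, 0.1, 0.2), c(1, 1, 0, 0)), "vaf")
  expect_equal(r1$auroc, 1.0)

  r2 <- roc_curve(seqpos_df(c(0.1, 0.3, 0.2, 0.4), c(1, 1, 0, 0)), "vaf")
  expect_equal(r2$auroc, 0.25)

  set.seed(17)
  vals <- runif(1000)
  labs <- sample(rep(0:1, 500))
  r3 <- roc_curve(seqpos_df(vals, labs), "vaf")
  expect_lt(abs(r3$auroc - 0.5), 0.05)

  expect_error(roc_curve(seqpos_df(c(1, 2), c(1, 1)), "vaf"), "ROC undefined")
})

test_that("trapezoid AUROC equals the pairwise concordance statistic", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(4:40, 1)
    ## discrete support forces ties
    vals <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labs <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_curve(seqpos_df(vals, labs), "vaf")
    expect_equal(r$auroc, r$auroc_concordance, tolerance = 1e-12)
    expect_equal(r$auroc, auroc_concordance(vals, labs), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  set.seed(3)
  vals <- c(rnorm(40, 1), rnorm(40))
  labs <- rep(c(1, 0), each = 40)
  r <- roc_curve(seqpos_df(vals, labs), "vaf")
  ref <- as.numeric(pROC::auc(pROC::roc(labs, vals, direction = "<",
                                        quiet = TRUE)))
  expect_equal(r$auroc, ref, tolerance = 1e-10)
})

test_that("optimal cutpoint maximises Youden's J at an observed-value midpoint", {
  r <- roc_curve(seqpos_df(c(0.3, 0.4, 0.5, 0.05, 0.1), c(1, 1, 1, 0, 0)), "vaf")
  expect_equal(optimal_cutpoint(r), 0.2)
  expect_equal(r$optimal_j, 1)

  ## interleaved values: J = 0 attained at the -Inf sentinel
  ri <- roc_curve(seqpos_df(c(1, 3, 2, 4), c(1, 1, 0, 0)), "vaf")
  expect_equal(ri$optimal_j, 0)
  expect_equal(optimal_cutpoint(ri), -Inf)
})

test_that("smaller-is-positive direction flips the decision rule", {
  ## strand bias: positives balanced (low), negatives biased (high)
  sp <- seqpos_df(rep(NA_real_, 4), c(1, 1, 0, 0))
  sp$stb <- c(0.5, 0.55, 0.9, 0.95)
  r <- roc_curve(sp, "stb")
  expect_equal(r$auroc, 1.0)
  expect_equal(r$direction, "smaller")
  ## cutpoint sits between 0.55 and 0.9 on the original scale
  expect_gt(optimal_cutpoint(r), 0.55)
  expect_lt(optimal_cutpoint(r), 0.9)
})

test_that("threshold simulation follows the recovery and demotion rules", {
  calls <- classified_df(tp = c(0.4, 0.03), fp = 0.02, bfn = 0.1)
  sim <- simulate_thresholds(calls, threshold_set(min_vaf = 0.05))
  expect_equal(sim$metrics$tp, 2L)   # 0.4 kept + 0.1 recovered
  expect_equal(sim$metrics$fp, 0L)
  expect_equal(sim$metrics$fn, 1L)
  expect_equal(sim$metrics$recall, 2 / 3)
  expect_equal(sim$metrics$precision, 1.0)

  ## impossible threshold removes every positive call
  sim2 <- simulate_thresholds(calls, threshold_set(min_vaf = 1.1))
  expect_equal(sim2$metrics$tp, 0L)
  expect_equal(sim2$metrics$fp, 0L)
})

test_that("empty thresholds recover all b-FNs: recall becomes recall_max", {
  set.seed(41)
  for (rep in 1:10) {
    calls <- classified_df(tp = runif(sample(3:20, 1)),
                           fp = runif(sample(1:10, 1)),
                           bfn = runif(sample(1:6, 1)),
                           seqfn = sample(0:4, 1))
    base <- compute_metrics(calls, tn_bases = 10000L,
                            bfn_count = sum(calls$fn_subtype == "b-FN"))
    sim <- simulate_thresholds(calls, threshold_set(), tn_bases = 10000L)
    expect_equal(sim$metrics$recall, base$recall_max)
    expect_equal(sim$metrics$fp, base$fp)
    expect_lte(sim$metrics$precision, 1)
  }
})

test_that("tightening min_vaf is monotone non-increasing in recall and conserves totals", {
  set.seed(53)
  calls <- classified_df(tp = runif(30), fp = runif(10), bfn = runif(6),
                         seqfn = 3L)
  truth_n <- sum(calls$class %in% c("TP", "FN"))
  prev <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    sim <- simulate_thresholds(calls, threshold_set(min_vaf = t))
    expect_lte(sim$metrics$recall, prev)
    prev <- sim$metrics$recall
    ## conservation of truth membership after every simulation
    expect_equal(sim$metrics$tp + sim$metrics$fn, truth_n)
  }
})

test_that("missing parameters never fail a call in simulation", {
  calls <- classified_df(tp = c(0.4, NA), fp = numeric(0), bfn = numeric(0))
  sim <- simulate_thresholds(calls, threshold_set(min_vaf = 0.3))
  expect_equal(sim$metrics$tp, 2L)
})

test_that("unknown threshold parameters are a configuration error", {
  expect_error(threshold_set(min_vax = 1), "unknown threshold")
})

test_that("quality by depth", {
  expect_equal(compute_qd(100, 50), 8)
  expect_equal(compute_qd(0, 50), 0)
  expect_true(is.na(compute_qd(10, 0)))
})

test_that("simulation frees removed FP positions back to TN bases", {
  calls <- classified_df(tp = 0.4, fp = c(0.02, 0.03))
  sim <- simulate_thresholds(calls, threshold_set(min_vaf = 0.05),
                             tn_bases = 500L)
  expect_equal(sim$metrics$tn_bases, 502L)
  expect_equal(sim$metrics$fp, 0L)
})
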