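# deterministic toy fixtures shared below
op_from <- function(p, y, target, stage = "A") threshold_at_specificity(p, y, target, stage)

test_that("rank AUC agrees with pROC", {
  set.seed(71)
  y <- rbinom(200, 1, 0.4)
  p <- runif(200)
  expect_equal(auc_rank(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("specificity-targeted thresholds meet their target on the selection set", {
  # toy: negatives {0.1, 0.2}, positives {0.8, 0.9}
  p <- c(0.1, 0.2, 0.8, 0.9); y <- c(0, 0, 1, 1)
  op <- op_from(p, y, 0.9)
  expect_true(op$threshold > 0.2 && op$threshold <= 0.8)
  expect_equal(op$specificity, 1)
  expect_equal(op$sensitivity, 1)
  # target 0 forwards everything at the smallest score
  op0 <- op_from(p, y, 0)
  expect_equal(op0$threshold, 0.1)
  expect_equal(op0$sensitivity, 1)
  # all negatives at zero: any positive threshold is fully specific
  op1 <- op_from(c(0, 0, 0.5, 0.7), c(0, 0, 1, 1), 0.99)
  expect_equal(op1$specificity, 1)
  expect_equal(op1$sensitivity, 1)
  # unreachable target warns with zero sensitivity
  expect_warning(opu <- op_from(c(0.9, 0.9, 0.1), c(0, 0, 1), 0.95),
                 "unreachable")
  expect_equal(opu$sensitivity, 0)
})

test_that("threshold selection matches a brute-force candidate search", {
  set.seed(72)
  for (i in 1:50) {
    n <- 60
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2) # force ties
    target <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    op <- suppressWarnings(op_from(p, y, target))
    expect_gte(op$specificity, target)
    # oracle: smallest candidate threshold achieving the target
    cand <- c(sort(unique(p)), max(p) + 1e-9)
    ok <- cand[vapply(cand, function(t) mean(p[y == 0] < t) >= target,
                      logical(1))]
    expect_equal(op$threshold, min(ok))
  }
})

test_that("routing partitions scans and matches the per-scan rule oracle", {
  set.seed(73)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  p_a <- runif(n)
  op_a <- op_from(p_a, y, 0.8, "A")
  pass <- p_a >= op_a$threshold
  p_b <- rep(NA_real_, n)
  p_b[pass] <- runif(sum(pass))
  op_b <- suppressWarnings(op_from(p_b[pass], y[pass], 0.85, "B85"))
  cr <- route_cascade(p_a, p_b, op_a, op_b)
  oracle <- ifelse(p_a < op_a$threshold, "removed_A",
                   ifelse(p_b >= op_b$threshold, "forwarded", "not_forwarded_B"))
  expect_identical(as.character(cr$route), oracle)
  expect_equal(sum(cr$counts), n)
  expect_equal(cr$f, mean(oracle == "forwarded"))
  # threshold 0 forwards everything; threshold above 1 forwards nothing
  op_all <- list(stage = "B", threshold = 0)
  op_none <- list(stage = "B", threshold = 1 + 1e-9)
  pb_full <- runif(n)
  expect_equal(route_cascade(p_a, pb_full, list(threshold = 0), op_all)$f, 1)
  expect_equal(route_cascade(p_a, pb_full, list(threshold = 0), op_none)$f, 0)
  # raising a threshold never increases the forwarded count
  f_hi <- route_cascade(p_a, p_b, op_a,
                        list(threshold = op_b$threshold + 0.05))$f
  expect_lte(f_hi, cr$f)
})

test_that("stacked stages cover each scan once and keep subjects within folds", {
  co <- make_triage_cohort(triage_cohort_spec(n_subjects = 120,
                                              knees_per_subject = 2L, seed = 74))
  feats <- attr(co, "features")
  ref <- fit_reference(co, feats, co$knee_abnormal == 0)
  x <- cbind(as.matrix(zscore(co, ref)), sex = co$sex, age = co$age,
             weight = co$weight)
  st <- fit_stage(x, co$knee_abnormal, co$subject_id, seed = 75)
  expect_false(anyNA(st$oof$stacked))
  expect_equal(nrow(st$oof), nrow(co))
  # every subject's scans share one fold
  expect_true(all(tapply(st$folds, co$subject_id,
                         function(f) length(unique(f))) == 1L))
  # predictions on new data are probabilities
  pnew <- predict(st, x[1:5, ])
  expect_true(all(pnew >= 0 & pnew <= 1))
})

test_that("a separable cohort reaches near-perfect out-of-fold AUC", {
  sh <- mskmark:::.default_shifts()
  sh[2:4, ] <- sh[2:4, ] * 6
  co <- make_triage_cohort(triage_cohort_spec(n_subjects = 250, shifts = sh,
                                              noise_sd = 0.3, seed = 76))
  feats <- attr(co, "features")
  ref <- fit_reference(co, feats, co$knee_abnormal == 0)
  x <- cbind(as.matrix(zscore(co, ref)), sex = co$sex, age = co$age,
             weight = co$weight)
  st <- suppressWarnings(fit_stage(x, co$knee_abnormal, co$subject_id, seed = 77))
  expect_gte(st$auc, 0.99)
})

test_that("stage C averages its two learners and bins calibration", {
  set.seed(78)
  p <- stats::runif(5000)
  y <- stats::rbinom(5000, 1, p)
  cb <- calibration_bins(p, y, 10L)
  expect_lte(max(abs(cb$obs_freq - cb$mean_pred)), 0.05)
  cb1 <- calibration_bins(rep(0.55, 40), rbinom(40, 1, 0.55), 10L)
  expect_equal(nrow(cb1), 1L)
  # single-class task skipped with a warning
  x <- matrix(stats::rnorm(60), 30, 2)
  labs <- data.frame(t1 = rep(1L, 30), t2 = rbinom(30, 1, 0.5))
  expect_warning(res <- stage_c(x, labs, seed = 1), "single class")
  expect_named(res, "t2")
  expect_true(all(res$t2$prob >= 0 & res$t2$prob <= 1))
})

test_that("stage metrics report confusion-derived NPV/PPV with bootstrap CIs", {
  # printed toy confusion: TP 10, FP 20, TN 80, FN 5 at threshold 0.5
  p <- c(rep(0.9, 10), rep(0.9, 20), rep(0.1, 80), rep(0.1, 5))
  y <- c(rep(1, 10), rep(0, 20), rep(0, 80), rep(1, 5))
  op <- list(threshold = 0.5)
  m <- evaluate_stage(p, y, op, nboot = 50, seed = 1)
  expect_equal(unname(m$estimates["npv"]), 80 / 85, tolerance = 1e-12)
  expect_equal(unname(m$estimates["ppv"]), 10 / 30, tolerance = 1e-12)
  # perfect ranking: AUC 1 with degenerate CI
  pp <- c(0.1, 0.2, 0.8, 0.9); yy <- c(0, 0, 1, 1)
  mp <- evaluate_stage(pp, yy, list(threshold = 0.5), nboot = 100, seed = 2)
  expect_equal(unname(mp$estimates["auc"]), 1)
  expect_equal(unname(mp$ci[, "auc"]), c(1, 1))
})

test_that("workload arithmetic is linear and guards its domain", {
  wl <- workload(99, 930, 2)
  expect_equal(wl$minutes_per_1000, 99 / 930 * 2000)
  expect_equal(workload(0, 930, 2)$minutes_per_1000, 0)
  expect_equal(workload(198, 930, 2)$minutes_per_1000,
               2 * wl$minutes_per_1000)
  expect_equal(workload(99, 930, 4)$minutes_per_1000,
               2 * wl$minutes_per_1000)
  expect_error(workload(1, 0, 2), "total")
  expect_error(workload(-1, 10, 2), "forwarded")
})
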