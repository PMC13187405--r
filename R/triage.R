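# Multi-stage knee triage cascade: stacked screening classifiers with
# subject-grouped cross-validation, specificity-targeted operating points,
# deterministic routing, an equal-weight localization ensemble with
# calibration bins, bootstrap metrics, and workload accounting.

.xgb_fit <- function(x, y, w, seed, hist = FALSE) {
  params <- list(objective = "binary:logistic", eta = 0.1,
                 max_depth = if (hist) 6L else 3L,
                 tree_method = if (hist) "hist" else "exact",
                 max_bin = if (hist) 64L else 256L,
                 nthread = 1L, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = 150L,
                     verbose = 0)
}

.enet_fit <- function(x, y, w, seed) {
  set.seed(seed)
  foldid <- sample(rep_len(1:5, length(y)))
  glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0.5, weights = w,
                    foldid = foldid, standardize = TRUE)
}

.base_predict <- function(models, x) {
  cbind(
    enet = as.numeric(stats::predict(models$enet, newx = x, s = "lambda.min",
                                     type = "response")),
    xgb = stats::predict(models$xgb, xgboost::xgb.DMatrix(x)),
    hgb = stats::predict(models$hgb, xgboost::xgb.DMatrix(x)))
}

#' Fit one triage stage (stacked screen with grouped cross-validation)
#'
#' Base learners are elastic-net penalized logistic regression (mixing
#' parameter 0.5, class-balanced weights), gradient-boosted trees, and
#' histogram-binned gradient boosting. Five-fold subject-grouped
#' cross-validation produces out-of-fold base probabilities, which a
#' logistic meta-learner stacks into one out-of-fold probability per scan.
#'
#' @param x numeric feature matrix (z-scored biomarkers plus demographics;
#'   the reference used for z-scoring must be global, not per fold).
#' @param y binary labels (1 = abnormal).
#' @param groups subject identifiers; no subject ever straddles a fold.
#' @param stage label stored with the fit ("A", "B", ...).
#' @param n_folds folds (default 5).
#' @param seed controls fold assignment and learner RNG.
#' @return object of class `triage_stage` with out-of-fold probabilities
#'   (`$oof$stacked` covers every scan exactly once), fold ids, and the
#'   full-data refit used by `predict()`.
#' @export
fit_stage <- function(x, y, groups, stage = "A", n_folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  .assert(length(y) == nrow(x) && length(groups) == nrow(x),
          "x, y, groups must align")
  .assert(all(y %in% 0:1), "y must be binary 0/1")
  seeds <- derive_seeds(seed, n_folds + 2L)
  folds <- grouped_kfold(groups, n_folds, seeds[n_folds + 1L])
  oof <- matrix(NA_real_, nrow(x), 3L,
                dimnames = list(NULL, c("enet", "xgb", "hgb")))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      stop("fold ", f, " is missing a class; use fewer folds", call. = FALSE)
    .assert(length(intersect(groups[tr], groups[te])) == 0L,
            "internal error: group straddles fold %d", f)
    w <- balanced_weights(y[tr])
    models <- list(enet = .enet_fit(x[tr, , drop = FALSE], y[tr], w, seeds[f]),
                   xgb = .xgb_fit(x[tr, , drop = FALSE], y[tr], w, seeds[f]),
                   hgb = .xgb_fit(x[tr, , drop = FALSE], y[tr], w, seeds[f],
                                  hist = TRUE))
    oof[te, ] <- .base_predict(models, x[te, , drop = FALSE])
  }
  .assert(!anyNA(oof), "internal error: incomplete out-of-fold coverage")
  meta_df <- data.frame(y = y, oof)
  meta <- stats::glm(y ~ enet + xgb + hgb, data = meta_df,
                     family = stats::binomial())
  stacked <- as.numeric(stats::fitted(meta))
  w_all <- balanced_weights(y)
  full <- list(enet = .enet_fit(x, y, w_all, seeds[n_folds + 2L]),
               xgb = .xgb_fit(x, y, w_all, seeds[n_folds + 2L]),
               hgb = .xgb_fit(x, y, w_all, seeds[n_folds + 2L], hist = TRUE))
  structure(list(stage = stage,
                 oof = data.frame(oof, stacked = stacked),
                 folds = folds, y = y, groups = groups,
                 auc = auc_rank(stacked, y),
                 meta = meta, models = full, seed = seed),
            class = "triage_stage")
}

#' @export
print.triage_stage <- function(x, ...) {
  cat(sprintf("<triage_stage %s> n = %d (%d abnormal), out-of-fold AUC = %.3f\n",
              x$stage, length(x$y), sum(x$y), x$auc))
  invisible(x)
}

#' @export
predict.triage_stage <- function(object, newdata, ...) {
  base <- as.data.frame(.base_predict(object$models, as.matrix(newdata)))
  as.numeric(stats::predict(object$meta, newdata = base, type = "response"))
}

#' Select the probability threshold meeting a specificity target
#'
#' The decision rule at threshold t forwards scans with probability >= t
#' (inclusive). Candidates are the sorted unique probabilities (plus a
#' sentinel above the maximum); the smallest candidate whose achieved
#' specificity TN/(TN+FP) meets the target is selected, which resolves ties
#' toward higher sensitivity. If only the sentinel qualifies the target is
#' unreachable on the observed scores and a warning is issued (sensitivity
#' 0 at the returned threshold).
#'
#' @param p probabilities; @param y binary labels (1 = abnormal).
#' @param target specificity target in \[0, 1\].
#' @param stage stage tag stored in the result.
#' @return object of class `operating_point`: threshold, achieved
#'   specificity/sensitivity and selection-set confusion counts.
#' @export
threshold_at_specificity <- function(p, y, target, stage = "A") {
  y <- as.integer(y)
  .assert(all(y %in% 0:1) && length(unique(y)) == 2L,
          "both classes must be present")
  .assert(target >= 0 && target <= 1, "target must be in [0, 1]")
  cand <- c(sort(unique(p)), max(p) + 1e-9)
  neg <- p[y == 0L]
  for (t in cand) {
    spec <- mean(neg < t)
    if (spec >= target) {
      if (t > max(p))
        warning("specificity target unreachable; threshold above all scores, sensitivity 0")
      tp <- sum(p >= t & y == 1L); fp <- sum(p >= t & y == 0L)
      tn <- sum(p < t & y == 0L); fn <- sum(p < t & y == 1L)
      return(structure(list(stage = stage, target = target, threshold = t,
                            tp = tp, fp = fp, tn = tn, fn = fn,
                            specificity = tn / (tn + fp),
                            sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
                       class = "operating_point"))
    }
  }
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "<operating_point %s> target spec %.2f -> threshold %.4f (spec %.3f, sens %.3f)\n",
    x$stage, x$target, x$threshold, x$specificity, x$sensitivity))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Route scans through the two screening stages
#'
#' Scans below the Stage-A threshold are removed (confidently normal);
#' Stage-B probabilities, computed only on the Stage-A pass set, forward
#' scans at or above the Stage-B threshold for verification. Routes are
#' mutually exclusive and exhaustive.
#'
#' @param p_a Stage-A probabilities for every scan.
#' @param p_b Stage-B probabilities, `NA` for scans removed at Stage A.
#' @param op_a,op_b [threshold_at_specificity()] operating points.
#' @return object of class `cascade_result`: per-scan route factor
#'   (removed_A / not_forwarded_B / forwarded), forwarded fraction `f`,
#'   and counts.
#' @export
route_cascade <- function(p_a, p_b, op_a, op_b) {
  .assert(length(p_a) == length(p_b), "p_a and p_b must align (NA off the pass set)")
  pass <- p_a >= op_a$threshold
  .assert(!anyNA(p_b[pass]), "missing Stage-B probability on the pass set")
  route <- rep("removed_A", length(p_a))
  route[pass] <- ifelse(p_b[pass] >= op_b$threshold, "forwarded",
                        "not_forwarded_B")
  route <- factor(route, levels = c("removed_A", "not_forwarded_B", "forwarded"))
  structure(list(route = route,
                 counts = table(route),
                 f = mean(route == "forwarded"),
                 op_a = op_a, op_b = op_b),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  n <- length(x$route)
  cat(sprintf("<cascade_result> %d scans: removed %d, not forwarded %d, forwarded %d (f = %.3f)\n",
              n, x$counts[1], x$counts[2], x$counts[3], x$f))
  invisible(x)
}

#' Observed-vs-predicted calibration in equal-width bins
#'
#' @param p predicted probabilities; @param y binary outcomes.
#' @param bins number of equal-width bins on \[0, 1\] (default 10); empty
#'   bins are omitted.
#' @export
calibration_bins <- function(p, y, bins = 10L) {
  br <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(p, br, rightmost.closed = TRUE), 1L), bins)
  occupied <- sort(unique(idx))
  data.frame(bin = occupied,
             mean_pred = vapply(occupied, function(b) mean(p[idx == b]), numeric(1)),
             obs_freq = vapply(occupied, function(b) mean(y[idx == b]), numeric(1)),
             n = vapply(occupied, function(b) sum(idx == b), numeric(1)))
}

#' Stage-C localization ensemble
#'
#' For each binary task (joint-level, then tissue-within-joint), averages a
#' logistic regression and a gradient-boosted classifier with equal weight,
#' fit on the routed subset without additional cross-validation (apparent
#' performance; optimism is expected and documented). Calibration uses 10
#' equal-width bins; no recalibration is applied. Tasks with a single
#' observed class are skipped with a warning.
#'
#' @param x feature matrix for the routed subset.
#' @param labels data.frame of binary task columns, aligned to `x`.
#' @param seed learner seed.
#' @param bins calibration bins.
#' @return list of class `stage_c_result`, one element per completed task:
#'   probabilities, AUC (apparent), calibration table.
#' @export
stage_c <- function(x, labels, seed = 1L, bins = 10L) {
  x <- as.matrix(x)
  .assert(nrow(x) > 0, "routed subset is empty")
  out <- list()
  for (task in names(labels)) {
    y <- as.integer(labels[[task]])
    if (length(unique(y)) < 2L) {
      warning("task ", task, " has a single class; skipped")
      next
    }
    df <- data.frame(y = y, x)
    lr <- stats::glm(y ~ ., data = df, family = stats::binomial())
    p_lr <- as.numeric(stats::fitted(lr))
    xgb <- .xgb_fit(x, y, rep(1, length(y)), seed)
    p_xgb <- stats::predict(xgb, xgboost::xgb.DMatrix(x))
    p <- (p_lr + p_xgb) / 2
    out[[task]] <- list(prob = p, auc = auc_rank(p, y),
                        calibration = calibration_bins(p, y, bins), n = length(y))
  }
  structure(out, class = "stage_c_result")
}

#' Evaluate a stage at an operating point with bootstrap intervals
#'
#' Reports AUC, sensitivity at the stored threshold, NPV = TN/(TN+FN) and
#' PPV = TP/(TP+FP), with percentile 95% intervals from a non-parametric
#' bootstrap resampling subjects with replacement (2000 draws by default).
#' Resamples that lose a class are redrawn and counted.
#'
#' @param p probabilities; @param y labels; @param op an `operating_point`.
#' @param groups subject ids (default: each scan its own subject).
#' @param nboot bootstrap draws; @param seed bootstrap seed.
#' @return object of class `stage_metrics`.
#' @export
evaluate_stage <- function(p, y, op, groups = NULL, nboot = 2000L, seed = 1L) {
  y <- as.integer(y)
  if (is.null(groups)) groups <- seq_along(y)
  idx_by_g <- split(seq_along(y), as.character(groups))
  t <- op$threshold
  point <- function(pp, yy) {
    tp <- sum(pp >= t & yy == 1L); fp <- sum(pp >= t & yy == 0L)
    tn <- sum(pp < t & yy == 0L); fn <- sum(pp < t & yy == 1L)
    c(auc = auc_rank(pp, yy),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA)
  }
  est <- point(p, y)
  set.seed(seed)
  ng <- length(idx_by_g)
  draws <- matrix(NA_real_, nboot, 4L)
  redrawn <- 0L
  for (b in seq_len(nboot)) {
    repeat {
      gi <- sample.int(ng, ng, replace = TRUE)
      ii <- unlist(idx_by_g[gi], use.names = FALSE)
      if (length(unique(y[ii])) == 2L) break
      redrawn <- redrawn + 1L
    }
    draws[b, ] <- point(p[ii], y[ii])
  }
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, type = 7)
  colnames(ci) <- names(est)
  if (redrawn > 0L) message(redrawn, " degenerate bootstrap resample(s) redrawn")
  structure(list(estimates = est, ci = ci, threshold = t, nboot = nboot,
                 n_redrawn = redrawn),
            class = "stage_metrics")
}

#' @export
print.stage_metrics <- function(x, ...) {
  for (m in names(x$estimates))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", m, x$estimates[m],
                x$ci[1, m], x$ci[2, m]))
  invisible(x)
}

#' Triage verification workload
#'
#' forwarded_fraction x per-exam minutes, reported per 1000 scans
#' (minutes and hours; hours printed to one decimal).
#'
#' @param forwarded forwarded scan count; @param total total scans > 0.
#' @param minutes_per_exam verification minutes per forwarded exam (> 0).
#' @return object of class `workload_estimate`: minutes_per_1000,
#'   hours_per_1000, forwarded_pct.
#' @export
workload <- function(forwarded, total, minutes_per_exam = 2) {
  .assert(total > 0, "total must be > 0")
  .assert(minutes_per_exam > 0, "minutes_per_exam must be > 0")
  .assert(forwarded >= 0 && forwarded <= total, "need 0 <= forwarded <= total")
  mins <- forwarded / total * 1000 * minutes_per_exam
  structure(list(minutes_per_1000 = mins, hours_per_1000 = mins / 60,
                 forwarded_pct = 100 * forwarded / total,
                 forwarded = forwarded, total = total,
                 minutes_per_exam = minutes_per_exam),
            class = "workload_estimate")
}

#' @export
print.workload_estimate <- function(x, ...) {
  cat(sprintf("%d/%d forwarded (%.1f%%) at %g min/exam -> %.1f min = %.1f h per 1000 scans\n",
              x$forwarded, x$total, x$forwarded_pct, x$minutes_per_exam,
              x$minutes_per_1000, x$hours_per_1000))
  invisible(x)
}

#' Run the full triage cascade on a feature cohort
#'
#' Convenience wrapper: freezes the healthy reference (normal for both bone
#' and cartilage), z-scores the six biomarkers, fits Stage A on all scans,
#' selects the Stage-A operating point, fits Stage B on the pass set with
#' its two specificity targets, routes, fits the Stage-C ensemble on the
#' forwarded subset, and accounts workload.
#'
#' @param cohort a [make_triage_cohort()] data.frame (or equivalent).
#' @param spec_a Stage-A specificity target (default 0.90).
#' @param spec_b Stage-B targets (default 0.85 and 0.90).
#' @param minutes_per_exam workload assumption (default 2).
#' @param seed master seed.
#' @return list of class `triage_run`.
#' @export
run_triage <- function(cohort, spec_a = 0.90, spec_b = c(0.85, 0.90),
                       minutes_per_exam = 2, seed = 1L) {
  feats <- attr(cohort, "features") %||%
    c("thick_femur", "thick_tibia", "thick_patella",
      "bone_femur", "bone_tibia", "bone_patella")
  ref <- fit_reference(cohort, feats,
                       reference = cohort$cart_label == 0 & cohort$bone_label == 0,
                       provenance = "healthy knees (bone_label = 0, cart_label = 0)")
  x <- cbind(as.matrix(zscore(cohort, ref)),
             sex = cohort$sex, age = cohort$age, weight = cohort$weight)
  y <- cohort$knee_abnormal
  groups <- cohort$subject_id
  seeds <- derive_seeds(seed, 4L)

  stage_a <- fit_stage(x, y, groups, stage = "A", seed = seeds[1])
  op_a <- threshold_at_specificity(stage_a$oof$stacked, y, spec_a, stage = "A")
  pass <- stage_a$oof$stacked >= op_a$threshold
  stage_b <- fit_stage(x[pass, , drop = FALSE], y[pass], groups[pass],
                       stage = "B", seed = seeds[2])
  p_b <- rep(NA_real_, length(y))
  p_b[pass] <- stage_b$oof$stacked
  ops_b <- lapply(spec_b, function(tg)
    threshold_at_specificity(stage_b$oof$stacked, y[pass], tg,
                             stage = sprintf("B%.0f", 100 * tg)))
  names(ops_b) <- sprintf("B%.0f", 100 * spec_b)
  routes <- lapply(ops_b, function(op)
    route_cascade(stage_a$oof$stacked, p_b, op_a, op))
  fwd <- routes[[1]]$route == "forwarded"
  c_tasks <- grep("^(joint_|abn_)", names(cohort), value = TRUE)
  stage_c_res <- if (any(fwd) && length(c_tasks) > 0)
    suppressWarnings(stage_c(x[fwd, , drop = FALSE],
                             cohort[fwd, c_tasks, drop = FALSE],
                             seed = seeds[3])) else NULL
  wl <- lapply(routes, function(r)
    workload(sum(r$route == "forwarded"), length(y), minutes_per_exam))
  structure(list(reference = ref, stage_a = stage_a, op_a = op_a,
                 stage_b = stage_b, ops_b = ops_b, routes = routes,
                 stage_c = stage_c_res, workload = wl, seed = seed),
            class = "triage_run")
}

#' @export
print.triage_run <- function(x, ...) {
  cat("<triage_run>\n Stage A: "); print(x$stage_a)
  cat(" Stage B: "); print(x$stage_b)
  for (nm in names(x$routes)) {
    cat(sprintf(" %s: f = %.3f; ", nm, x$routes[[nm]]$f))
    print(x$workload[[nm]])
  }
  invisible(x)
}
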