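# Landmark-time risk modeling: a fixed prediction time t0 (48 months), a
# risk set of knees event-free and uncensored at t0 with complete
# biomarkers, binary outcomes over the subsequent horizon, stratified
# participant-grouped cross-validation with per-fold isotonic calibration,
# discrimination / calibration / decision-curve evaluation, and survival
# comparators (Cox with Harrell's and IPCW concordance, Kaplan-Meier by
# risk group).

#' Build the landmark risk set and feature matrix
#'
#' Knees with an event or censoring at or before the landmark are excluded.
#' Thickness levels at each visit and annual changes between consecutive
#' visits are z-standardized per feature using knees with baseline
#' Kellgren-Lawrence grade 0-1 as the frozen reference; demographics are
#' appended unstandardized. The binary outcome is an event inside
#' (landmark, landmark + horizon]. Knees censored inside the window without
#' an event are coded 0 under the primary convention (`censored_in_window =
#' "negative"`) and flagged; `"exclude"` drops them as a sensitivity path.
#' The incident-OA task restricts to baseline KL < 2.
#'
#' @param cohort a [make_landmark_cohort()] result (or list with `visits`
#'   and `knees` of the same layout).
#' @param landmark_month landmark t0 (default 48).
#' @param horizon_months prediction window length (default 48).
#' @param task `"tkr"` (all knees) or `"oa"` (baseline KL < 2).
#' @param impute per-knee mean imputation of missing visits instead of
#'   dropping incomplete knees (sensitivity path; identical results when no
#'   visit is missing).
#' @param censored_in_window `"negative"` (primary) or `"exclude"`.
#' @return data.frame of class `landmark_cohort` with z-scored features,
#'   demographics, outcome, and survival columns (months since landmark);
#'   attributes carry the feature names and the reference.
#' @export
build_landmark <- function(cohort, landmark_month = 48, horizon_months = 48,
                           task = c("tkr", "oa"), impute = FALSE,
                           censored_in_window = c("negative", "exclude")) {
  task <- match.arg(task)
  censored_in_window <- match.arg(censored_in_window)
  vis <- cohort$visits
  kn <- cohort$knees
  .assert(all(kn$event_time > 0), "event/censor bookkeeping inconsistency")
  visit_months <- sort(unique(vis$visit_month))
  visit_months <- visit_months[visit_months <= landmark_month]
  comps <- sort(unique(vis$compartment))

  # wide thickness levels: one column per compartment x visit
  key <- paste(vis$compartment, vis$visit_month, sep = "_m")
  wide <- stats::reshape(
    data.frame(knee_id = vis$knee_id, key = key, value = vis$thickness_mm),
    idvar = "knee_id", timevar = "key", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  lvl_cols <- as.vector(outer(comps, visit_months,
                              function(a, b) paste0(a, "_m", b)))
  lvl_cols <- intersect(lvl_cols, names(wide))
  if (impute) {
    for (comp in comps) {
      cc <- grep(paste0("^", comp, "_m"), lvl_cols, value = TRUE)
      block <- wide[, cc, drop = FALSE]
      rm_ <- rowMeans(block, na.rm = TRUE)
      for (j in cc) {
        miss <- is.na(block[[j]])
        wide[[j]][miss] <- rm_[miss]
      }
    }
  }
  complete <- stats::complete.cases(wide[, lvl_cols, drop = FALSE])
  wide <- wide[complete, , drop = FALSE]

  # annual changes between consecutive available visits
  chg_cols <- character(0)
  for (comp in comps) {
    for (i in seq_len(length(visit_months) - 1L)) {
      a <- paste0(comp, "_m", visit_months[i])
      b <- paste0(comp, "_m", visit_months[i + 1L])
      nm <- paste0(comp, "_chg_m", visit_months[i + 1L])
      wide[[nm]] <- (wide[[b]] - wide[[a]]) /
        ((visit_months[i + 1L] - visit_months[i]) / 12)
      chg_cols <- c(chg_cols, nm)
    }
  }

  df <- merge(wide, kn, by = "knee_id")
  # risk set: event-free and uncensored at the landmark
  at_risk <- !(df$event == 1L & df$event_time <= landmark_month) &
    df$event_time > landmark_month
  df <- df[at_risk, , drop = FALSE]
  if (task == "oa") df <- df[df$kl_baseline < 2, , drop = FALSE]
  .assert(nrow(df) > 0, "empty risk set")

  end <- landmark_month + horizon_months
  outcome <- as.integer(df$event == 1L & df$event_time <= end)
  cens_in_window <- df$event == 0L & df$event_time < end
  if (censored_in_window == "exclude") {
    keep <- !(cens_in_window & outcome == 0L)
    df <- df[keep, , drop = FALSE]
    outcome <- outcome[keep]
    cens_in_window <- cens_in_window[keep]
  }

  feat_cols <- c(lvl_cols, chg_cols)
  ref <- fit_reference(df, feat_cols, reference = df$kl_baseline < 2,
                       provenance = "baseline KL 0-1 knees")
  z <- zscore(df, ref)
  out <- data.frame(knee_id = df$knee_id, participant_id = df$participant_id,
                    z, age = df$age, sex = df$sex, bmi = df$bmi,
                    kl_baseline = df$kl_baseline,
                    outcome = outcome,
                    censored_in_window = as.integer(cens_in_window),
                    time_since_landmark = pmin(df$event_time, end) - landmark_month,
                    event_in_window = outcome,
                    stringsAsFactors = FALSE)
  attr(out, "features") <- c(feat_cols, "age", "sex", "bmi")
  attr(out, "baseline_features") <-
    c(paste0(comps, "_m0"), "age", "sex", "bmi")
  attr(out, "reference") <- ref
  attr(out, "landmark_month") <- landmark_month
  attr(out, "horizon_months") <- horizon_months
  attr(out, "task") <- task
  class(out) <- c("landmark_cohort", "data.frame")
  out
}

# isotonic calibration map fit on (p, y); returns a function. NA pairs are
# dropped (random-forest out-of-bag predictions can be undefined for rows
# in-bag in every tree).
.isotonic_map <- function(p, y) {
  ok <- !is.na(p)
  p <- p[ok]; y <- y[ok]
  o <- order(p)
  fit <- stats::isoreg(p[o], y[o])
  xs <- fit$x
  ys <- fit$yf
  function(newp) stats::approx(xs, ys, xout = newp, rule = 2, ties = "ordered")$y
}

#' Fit the landmark risk model with grouped stratified cross-validation
#'
#' Five-fold cross-validation grouped by participant (paired knees are
#' never split) and stratified by outcome. The TKR task uses a 400-tree
#' random forest (minimum leaf size 10, class-balanced weights) with a
#' logistic-regression baseline; the OA task uses L2-regularized logistic
#' regression with balanced class weights. Out-of-fold raw probabilities
#' are calibrated with isotonic regression fit per fold on the training
#' data only.
#'
#' @param lc a [build_landmark()] cohort.
#' @param model `"rf"` or `"lr"`; defaults to the task convention (rf for
#'   tkr, lr for oa).
#' @param n_folds folds (default 5); each fold must contain events.
#' @param rf_trees,rf_min_leaf random-forest size (defaults 400 / 10).
#' @param lambda ridge penalty for the lr model (default 0.01).
#' @param seed controls folds and forest RNG.
#' @return data.frame of class `risk_predictions`: knee_id, fold, raw and
#'   calibrated out-of-fold probability, outcome, survival columns.
#' @export
fit_risk_model <- function(lc, model = NULL, n_folds = 5L,
                           rf_trees = 400L, rf_min_leaf = 10L,
                           lambda = 0.01, seed = 1L) {
  stopifnot(inherits(lc, "landmark_cohort"))
  task <- attr(lc, "task")
  model <- model %||% if (identical(task, "oa")) "lr" else "rf"
  feats <- attr(lc, "features")
  x <- as.matrix(lc[, feats])
  y <- lc$outcome
  seeds <- derive_seeds(seed, n_folds + 1L)
  folds <- stratified_grouped_kfold(lc$participant_id, y, n_folds,
                                    seeds[n_folds + 1L])
  for (f in seq_len(n_folds))
    if (sum(y[folds == f]) == 0L || sum(y[folds != f]) == 0L)
      stop("fold ", f, " has zero events; use fewer folds", call. = FALSE)
  p_raw <- p_cal <- rep(NA_real_, length(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    w <- balanced_weights(y[tr])
    if (model == "rf") {
      fit <- ranger::ranger(x = x[tr, , drop = FALSE],
                            y = factor(y[tr], levels = 0:1),
                            num.trees = rf_trees, min.node.size = rf_min_leaf,
                            probability = TRUE, case.weights = w,
                            seed = seeds[f], num.threads = 1L)
      p_tr <- fit$predictions[, "1"]
      p_te <- stats::predict(fit, data = x[te, , drop = FALSE],
                             num.threads = 1L)$predictions[, "1"]
    } else {
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = 0, lambda = lambda, weights = w,
                            standardize = TRUE)
      p_tr <- as.numeric(stats::predict(fit, newx = x[tr, , drop = FALSE],
                                        type = "response"))
      p_te <- as.numeric(stats::predict(fit, newx = x[te, , drop = FALSE],
                                        type = "response"))
    }
    cal <- .isotonic_map(p_tr, y[tr])
    p_raw[te] <- p_te
    p_cal[te] <- cal(p_te)
  }
  out <- data.frame(knee_id = lc$knee_id, participant_id = lc$participant_id,
                    fold = folds, p_raw = p_raw, p_cal = p_cal,
                    outcome = y,
                    time_since_landmark = lc$time_since_landmark,
                    event_in_window = lc$event_in_window,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- model
  attr(out, "task") <- task
  class(out) <- c("risk_predictions", "data.frame")
  out
}

#' Evaluate out-of-fold risk predictions
#'
#' AUC with a percentile bootstrap interval (knee-level resampling, 1000
#' draws by default), Brier score and calibration slope (logistic
#' regression of the outcome on the prediction log-odds), each for raw and
#' calibrated probabilities. Constant predictions give an undefined slope,
#' reported as `NaN` with a warning.
#'
#' @param rp a [fit_risk_model()] result.
#' @param nboot bootstrap draws; @param seed bootstrap seed.
#' @return list of class `risk_metrics`.
#' @export
evaluate_risk <- function(rp, nboot = 1000L, seed = 1L) {
  stopifnot(inherits(rp, "risk_predictions"))
  .assert(!anyNA(rp$p_raw), "incomplete out-of-fold predictions")
  y <- rp$outcome
  one <- function(p) {
    slope <- if (stats::sd(p) == 0) {
      warning("constant predictions: calibration slope undefined")
      NaN
    } else {
      lp <- stats::qlogis(clip01(p))
      unname(stats::coef(suppressWarnings(
        stats::glm(y ~ lp, family = stats::binomial())))[2])
    }
    list(auc = auc_rank(p, y), brier = mean((p - y)^2),
         calibration_slope = slope)
  }
  raw <- one(rp$p_raw)
  cal <- one(rp$p_cal)
  set.seed(seed)
  n <- length(y)
  bs <- replicate(nboot, {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[i])) < 2L) NA_real_ else auc_rank(rp$p_cal[i], y[i])
  })
  ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(auc = cal$auc, auc_ci = ci,
                 auc_raw = raw$auc,
                 brier_raw = raw$brier, brier_calibrated = cal$brier,
                 slope_raw = raw$calibration_slope,
                 slope_calibrated = cal$calibration_slope,
                 n = n, prevalence = mean(y), nboot = nboot),
            class = "risk_metrics")
}

#' @export
print.risk_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), Brier %.3f (raw %.3f), slope %.3f (raw %.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$brier_calibrated, x$brier_raw,
              x$slope_calibrated, x$slope_raw))
  invisible(x)
}

#' Decision-curve net benefit
#'
#' NB(pt) = TP/n - (FP/n) * pt / (1 - pt) for the model rule
#' "treat if probability >= pt", together with treat-all and treat-none
#' references and percentile bootstrap bands (2000 draws by default). An
#' optional constant harm per intervention is subtracted from the model and
#' treat-all curves (an experimental interpretation of test/intervention
#' penalties in net-benefit units). Thresholds at 1 are excluded.
#'
#' @param rp a [fit_risk_model()] result (calibrated probabilities used).
#' @param thresholds probability thresholds in (0, 1).
#' @param harm constant harm per intervention in net-benefit units.
#' @param nboot bootstrap draws (0 disables bands); @param seed seed.
#' @param use `"calibrated"` or `"raw"` probabilities.
#' @return data.frame of class `decision_curve`: threshold, net benefit of
#'   model / treat-all / treat-none, and bootstrap bands.
#' @export
decision_curve <- function(rp, thresholds = seq(0.05, 0.5, by = 0.05),
                           harm = 0, nboot = 2000L, seed = 1L,
                           use = c("calibrated", "raw")) {
  use <- match.arg(use)
  p <- if (use == "calibrated") rp$p_cal else rp$p_raw
  y <- rp$outcome
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  .assert(length(thresholds) > 0, "no valid thresholds in (0, 1)")
  nb <- function(pp, yy, pt) {
    n <- length(yy)
    tp <- sum(pp >= pt & yy == 1L)
    fp <- sum(pp >= pt & yy == 0L)
    tp / n - fp / n * pt / (1 - pt) - harm
  }
  nb_all <- function(yy, pt) mean(yy) - (1 - mean(yy)) * pt / (1 - pt) - harm
  out <- data.frame(threshold = thresholds,
                    nb_model = vapply(thresholds, function(t) nb(p, y, t), numeric(1)),
                    nb_all = vapply(thresholds, function(t) nb_all(y, t), numeric(1)),
                    nb_none = 0)
  if (nboot > 0) {
    set.seed(seed)
    n <- length(y)
    draws <- replicate(nboot, {
      i <- sample.int(n, n, replace = TRUE)
      vapply(thresholds, function(t) nb(p[i], y[i], t), numeric(1))
    })
    if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
    out$nb_lower <- apply(draws, 1, stats::quantile, 0.025, type = 7)
    out$nb_upper <- apply(draws, 1, stats::quantile, 0.975, type = 7)
  }
  attr(out, "harm") <- harm
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' Cox proportional-hazards comparator on baseline features
#'
#' Fits a Cox model on month-0 features over the post-landmark follow-up
#' and reports Harrell's C (ties counted one half) and the inverse
#' probability of censoring weighted (IPCW) C truncated at the horizon.
#'
#' @param lc a [build_landmark()] cohort.
#' @return list of class `cox_comparator`: fit, c_harrell, c_ipcw.
#' @export
cox_comparator <- function(lc) {
  stopifnot(inherits(lc, "landmark_cohort"))
  feats <- attr(lc, "baseline_features")
  feats <- intersect(feats, names(lc))
  .assert(length(feats) > 0, "no baseline features available")
  df <- data.frame(time = lc$time_since_landmark, status = lc$event_in_window,
                   lc[, feats, drop = FALSE])
  .assert(any(df$status == 1), "no events after the landmark")
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(feats, collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  ch <- survival::concordance(fit)
  horizon <- attr(lc, "horizon_months")
  ci <- survival::concordance(fit, timewt = "n/G2", ymax = horizon)
  structure(list(fit = fit, c_harrell = unname(ch$concordance),
                 c_ipcw = unname(ci$concordance)),
            class = "cox_comparator")
}

#' @export
print.cox_comparator <- function(x, ...) {
  cat(sprintf("Cox comparator: Harrell C = %.3f, IPCW C = %.3f\n",
              x$c_harrell, x$c_ipcw))
  invisible(x)
}

#' Kaplan-Meier curves by median-split risk group
#'
#' Splits knees at the median predicted risk and estimates the
#' product-limit survivor function per group over the post-landmark window.
#'
#' @param rp a [fit_risk_model()] result.
#' @param use `"calibrated"` or `"raw"`.
#' @return data.frame of class `km_table`: group, time, n_risk, n_event,
#'   survival.
#' @export
km_by_risk_group <- function(rp, use = c("calibrated", "raw")) {
  use <- match.arg(use)
  p <- if (use == "calibrated") rp$p_cal else rp$p_raw
  grp <- factor(ifelse(p >= stats::median(p), "high", "low"),
                levels = c("low", "high"))
  sf <- survival::survfit(survival::Surv(rp$time_since_landmark,
                                         rp$event_in_window) ~ grp)
  strata <- rep(names(sf$strata) %||% "all", sf$strata %||% length(sf$time))
  out <- data.frame(group = sub("^grp=", "", strata), time = sf$time,
                    n_risk = sf$n.risk, n_event = sf$n.event,
                    survival = sf$surv)
  class(out) <- c("km_table", "data.frame")
  out
}
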