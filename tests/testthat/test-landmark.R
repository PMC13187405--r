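# hand-built longitudinal cohort for rule tests
toy_cohort <- function(events) {
  # events: data.frame(knee, event_time, event)
  visits <- expand.grid(knee = events$knee, visit_month = c(0, 12, 24, 36, 48),
                        compartment = c("femoral", "tibial"),
                        KEEP.OUT.ATTRS = FALSE)
  set.seed(424)
  visits <- data.frame(knee_id = as.character(visits$knee),
                       participant_id = as.character(visits$knee),
                       visit_month = visits$visit_month,
                       compartment = as.character(visits$compartment),
                       thickness_mm = stats::rnorm(nrow(visits), 2, 0.2))
  knees <- data.frame(knee_id = as.character(events$knee),
                      participant_id = as.character(events$knee),
                      event_time = events$event_time, event = events$event,
                      censor_month = 96, age = 60, sex = 1, bmi = 28,
                      kl_baseline = rep(c(0, 1), length.out = nrow(events)))
  list(visits = visits, knees = knees)
}

test_that("landmark risk-set rules include, exclude and flag correctly", {
  ev <- data.frame(knee = sprintf("k%02d", 1:8),
                   event_time = c(36, 60, 50, 96, 96, 70, 96, 96),
                   event = c(1, 1, 0, 0, 1, 1, 0, 0))
  lc <- build_landmark(toy_cohort(ev), landmark_month = 48, horizon_months = 48)
  # TKR at month 36 is excluded from the risk set
  expect_false("k01" %in% lc$knee_id)
  # event at month 60 with horizon 48: included, outcome 1
  expect_equal(lc$outcome[lc$knee_id == "k02"], 1L)
  # censored at month 50 without event: outcome 0 under the primary
  # convention, flagged
  expect_equal(lc$outcome[lc$knee_id == "k03"], 0L)
  expect_equal(lc$censored_in_window[lc$knee_id == "k03"], 1L)
  # sensitivity path drops within-window censored knees
  lc2 <- build_landmark(toy_cohort(ev), censored_in_window = "exclude")
  expect_false("k03" %in% lc2$knee_id)
})

test_that("the OA task restricts to baseline KL below 2", {
  raw <- make_landmark_cohort(landmark_cohort_spec(n_knees = 300, seed = 81))
  lc <- build_landmark(raw, task = "oa")
  expect_true(all(lc$kl_baseline < 2))
  expect_identical(attr(lc, "task"), "oa")
})

test_that("mean imputation is the identity when no visits are missing", {
  raw <- make_landmark_cohort(landmark_cohort_spec(n_knees = 200, seed = 82))
  a <- build_landmark(raw, impute = FALSE)
  b <- build_landmark(raw, impute = TRUE)
  expect_identical(a, b)
  # with missing visits the imputation path keeps more knees
  rawm <- make_landmark_cohort(landmark_cohort_spec(n_knees = 200,
                                                    missing_prob = 0.2,
                                                    seed = 83))
  expect_gte(nrow(build_landmark(rawm, impute = TRUE)),
             nrow(build_landmark(rawm, impute = FALSE)))
})

test_that("grouped CV keeps paired knees together and calibration is isotone", {
  raw <- make_landmark_cohort(landmark_cohort_spec(
    n_knees = 400, knees_per_participant = 2L, seed = 84))
  lc <- build_landmark(raw)
  rp <- fit_risk_model(lc, seed = 85)
  expect_true(all(tapply(rp$fold, rp$participant_id,
                         function(f) length(unique(f))) == 1L))
  for (f in unique(rp$fold)) {
    d <- rp[rp$fold == f, ]
    o <- order(d$p_raw)
    expect_true(all(diff(d$p_cal[o]) >= -1e-12))
  }
  expect_false(anyNA(rp$p_raw))
})

test_that("risk ranking tracks the generative signal and its direction", {
  raw <- make_landmark_cohort(landmark_cohort_spec(n_knees = 1000, seed = 86))
  lc <- build_landmark(raw)
  rp <- fit_risk_model(lc, seed = 87)
  expect_gt(auc_rank(rp$p_raw, rp$outcome), 0.70)
  # knees losing thickness faster are predicted at higher risk
  chg <- rowMeans(lc[, grep("_chg_", names(lc))])
  expect_lt(stats::cor(chg, rp$p_raw), 0)
  # logistic-regression variant recovers the same direction
  rp_lr <- fit_risk_model(lc, model = "lr", seed = 88)
  expect_gt(auc_rank(rp_lr$p_raw, rp_lr$outcome), 0.70)
})

test_that("risk metrics match their analytic expectations", {
  set.seed(89)
  # constant prediction at prevalence: Brier = p(1-p), slope undefined
  p0 <- 0.3; n <- 5000
  y <- stats::rbinom(n, 1, p0)
  expect_warning(m <- evaluate_risk(make_rp(rep(p0, n), y), nboot = 50),
                 "constant")
  expect_equal(m$brier_raw, p0 * (1 - p0), tolerance = 0.02)
  expect_true(is.nan(m$slope_raw))
  # calibrated logits give slope near 1
  lp <- stats::rnorm(n, -1, 1.5)
  p <- stats::plogis(lp)
  y2 <- stats::rbinom(n, 1, p)
  m2 <- evaluate_risk(make_rp(p, y2), nboot = 50)
  expect_equal(m2$slope_raw, 1, tolerance = 0.1)
  # perfect ranking
  expect_equal(evaluate_risk(make_rp(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)),
                             nboot = 20)$auc, 1)
})

test_that("net benefit matches its closed forms", {
  # treat-none is zero; treat-all at prevalence 0.2 and pt 0.2 is zero
  set.seed(90)
  y <- c(rep(1, 20), rep(0, 80))
  rp <- make_rp(stats::runif(100), y)
  dc <- decision_curve(rp, thresholds = 0.2, nboot = 0)
  expect_equal(dc$nb_none, 0)
  expect_equal(dc$nb_all, 0.2 - 0.8 * 0.25, tolerance = 1e-12)
  # toy confusion n = 100, TP = 10, FP = 20 at pt = 0.2 -> NB = 0.05
  p <- c(rep(0.9, 30), rep(0.05, 70))
  y2 <- c(rep(1, 10), rep(0, 20), rep(1, 10), rep(0, 60))
  dc2 <- decision_curve(make_rp(p, y2), thresholds = 0.2, nboot = 0)
  expect_equal(dc2$nb_model, 0.10 - 0.20 * 0.25, tolerance = 1e-12)
  # constant harm shifts the model curve down by exactly the harm
  dc3 <- decision_curve(make_rp(p, y2), thresholds = 0.2, harm = 0.02,
                        nboot = 0)
  expect_equal(dc3$nb_model, dc2$nb_model - 0.02, tolerance = 1e-12)
  expect_error(decision_curve(rp, thresholds = 1), "no valid thresholds")
  # bootstrap bands bracket the point estimate
  dc4 <- decision_curve(rp, thresholds = c(0.1, 0.2), nboot = 100, seed = 4)
  expect_true(all(dc4$nb_lower <= dc4$nb_model + 1e-9 &
                    dc4$nb_model <= dc4$nb_upper + 1e-9))
})

test_that("concordance agrees with brute-force pair enumeration", {
  # 4 subjects, all events, perfectly ordered scores
  tt <- c(2, 4, 6, 8); ss <- c(1, 1, 1, 1); sc <- c(0.9, 0.7, 0.5, 0.1)
  expect_equal(brute_cindex(tt, ss, sc), 1)
  cc <- survival::concordance(survival::Surv(tt, ss) ~ sc, reverse = TRUE)
  expect_equal(unname(cc$concordance), 1)
  # swapping two scores loses one of six comparable pairs
  sc2 <- c(0.7, 0.9, 0.5, 0.1)
  expect_equal(brute_cindex(tt, ss, sc2), 5 / 6)
  cc2 <- survival::concordance(survival::Surv(tt, ss) ~ sc2, reverse = TRUE)
  expect_equal(unname(cc2$concordance), 5 / 6)
  # random instances with censoring, n <= 50
  set.seed(91)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    tt <- stats::rexp(n); ss <- stats::rbinom(n, 1, 0.7)
    sc <- stats::runif(n)
    if (sum(ss) == 0) next
    expect_equal(unname(survival::concordance(
      survival::Surv(tt, ss) ~ sc, reverse = TRUE)$concordance),
      brute_cindex(tt, ss, sc), tolerance = 1e-12)
  }
})

test_that("the Cox comparator reports both concordance flavors", {
  raw <- make_landmark_cohort(landmark_cohort_spec(n_knees = 500, seed = 92))
  lc <- build_landmark(raw)
  cx <- cox_comparator(lc)
  expect_true(cx$c_harrell >= 0 && cx$c_harrell <= 1)
  expect_true(cx$c_ipcw >= 0 && cx$c_ipcw <= 1)
})

test_that("Kaplan-Meier by risk group follows the product-limit estimator", {
  # times (1, 2, 3), all events, one group: S after the second event = 1/3
  rp <- make_rp(c(0.5, 0.5, 0.5), c(1, 1, 1), time = c(1, 2, 3),
                event = c(1, 1, 1))
  km <- km_by_risk_group(rp)
  expect_equal(km$survival[km$time == 2], (2 / 3) * (1 / 2))
  # no events: survival stays 1
  rp0 <- make_rp(stats::runif(10), rep(0, 10), time = rep(5, 10),
                 event = rep(0, 10))
  km0 <- km_by_risk_group(rp0)
  expect_true(all(km0$survival == 1))
  # median split balances groups
  set.seed(93)
  rpm <- make_rp(stats::runif(101), stats::rbinom(101, 1, 0.2),
                 time = stats::rexp(101, 0.1), event = stats::rbinom(101, 1, 0.5))
  kmm <- km_by_risk_group(rpm)
  sizes <- tapply(kmm$n_risk, kmm$group, max)
  expect_lte(abs(sizes[["low"]] - sizes[["high"]]), 1)
})
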