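test_that("slab phantom rasterizes by voxel-center inclusion with exact truth", {
  ph <- make_phantom(phantom_spec("slab", spacing = c(0.5, 0.5, 0.5),
                                  slab_width = 10.5))
  expect_equal(ph$truth$thickness_mm, 10.5)
  expect_equal(ph$truth$n_across, 21L) # 21 voxels across at 0.5 mm
  prof <- apply(ph$mask$labels[, , 1] != 0, 1, any)
  expect_equal(sum(prof), 21L)
})

test_that("ellipsoid truth and rasterization match the implicit surface", {
  ph <- make_phantom(phantom_spec("ellipsoid", spacing = c(0.5, 0.5, 0.5),
                                  semi_axes = c(10, 10, 10)))
  expect_equal(ph$truth$volume_cm3, 4.18879, tolerance = 1e-5)
  # brute-force voxel-center test against the implicit surface
  d <- dim(ph$mask$labels)
  s <- 0.5
  ctr <- (ceiling(d / 2) - 0.5) * s
  ref <- array(0L, d)
  for (k in seq_len(d[3])) {
    x <- ((seq_len(d[1]) - 0.5) * s - ctr[1]) / 10
    y <- ((seq_len(d[2]) - 0.5) * s - ctr[2]) / 10
    z <- ((k - 0.5) * s - ctr[3]) / 10
    ref[, , k] <- as.integer(outer(x^2, y^2, `+`) + z^2 <= 1)
  }
  expect_identical(ph$mask$labels, ref)
  # voxel-count volume within 2% of the analytic volume at 0.5 mm
  vol <- sum(ph$mask$labels != 0) * 0.5^3 / 1000
  expect_lt(abs(vol - 4.18879) / 4.18879, 0.02)
})

test_that("rasterized volume error shrinks as spacing is refined", {
  errs <- vapply(c(1, 0.5, 0.25), function(s) {
    ph <- make_phantom(phantom_spec("ellipsoid", spacing = c(s, s, s),
                                    semi_axes = c(10.3, 8.1, 5.7)))
    abs(tissue_volume(ph$mask, 1L) - ph$truth$volume_cm3) / ph$truth$volume_cm3
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # two halvings shrink the error at least about four-fold
  expect_lt(errs[3] / errs[1], 0.35)
})

test_that("degenerate geometry is rejected", {
  expect_error(make_phantom(phantom_spec("slab", spacing = c(1, 1, 1),
                                         slab_width = 0.4)),
               "degenerate phantom")
  expect_error(phantom_spec("slab", slab_width = -1), "strictly positive")
  expect_error(phantom_spec("slab", spacing = c(0, 1, 1)), "strictly positive")
})

test_that("triage cohort recovers its class-conditional construction", {
  spec <- triage_cohort_spec(n_subjects = 2000, seed = 42)
  co <- make_triage_cohort(spec)
  co2 <- make_triage_cohort(spec)
  expect_identical(co, co2) # same seed, bit-identical
  # cart-only class shifted -1.5 SD on femoral thickness
  mu_n <- mean(co$thick_femur[co$class == "normal"])
  mu_c <- mean(co$thick_femur[co$class == "cart_only"])
  sd_f <- 0.25
  se <- sd_f * sqrt(1 / sum(co$class == "normal") + 1 / sum(co$class == "cart_only"))
  expect_lt(abs((mu_c - mu_n) - (-1.5 * sd_f)), 3 * se)
  # label hierarchy: any joint or tissue abnormality implies knee abnormal
  joints <- co[, c("joint_femur", "joint_tibia", "joint_patella")]
  expect_true(all(rowSums(joints) == 0 | co$knee_abnormal == 1))
  expect_true(all(co$knee_abnormal[co$cart_label == 1 | co$bone_label == 1] == 1))
})

test_that("null shifts give equal class means; pure-normal prevalence gives no labels", {
  sh <- matrix(0, 4, 6, dimnames = dimnames(mskmark:::.default_shifts()))
  co <- make_triage_cohort(triage_cohort_spec(n_subjects = 2000, shifts = sh,
                                              seed = 7))
  mu_n <- mean(co$thick_tibia[co$class == "normal"])
  mu_b <- mean(co$thick_tibia[co$class == "both"])
  se <- 0.22 * sqrt(1 / sum(co$class == "normal") + 1 / sum(co$class == "both"))
  expect_lt(abs(mu_n - mu_b), 3 * se)
  co1 <- make_triage_cohort(triage_cohort_spec(n_subjects = 200,
                                               prevalence = c(1, 0, 0, 0),
                                               seed = 1))
  expect_true(all(co1$knee_abnormal == 0))
  expect_warning(make_triage_cohort(
    triage_cohort_spec(n_subjects = 100, prevalence = c(0.99, 0.01, 0, 0),
                       seed = 1)),
    "expected count < 2")
})

test_that("longitudinal cohort honors censoring, visits and the null hazard", {
  spec <- landmark_cohort_spec(n_knees = 400, seed = 5)
  lc <- make_landmark_cohort(spec)
  expect_identical(lc$visits, make_landmark_cohort(spec)$visits)
  expect_true(all(lc$knees$event_time > 0))
  expect_true(all(lc$knees$event_time[lc$knees$event == 0] == 96))
  expect_true(all(lc$knees$event_time <= 96))
  # no missing visits by default: 5 visits x 4 compartments per knee
  expect_true(all(table(lc$visits$knee_id) == 20))
  # missing-visit probability drops whole visits but keeps baseline
  lcm <- make_landmark_cohort(landmark_cohort_spec(n_knees = 300,
                                                   missing_prob = 0.3, seed = 6))
  base_rows <- lcm$visits[lcm$visits$visit_month == 0, ]
  expect_equal(length(unique(base_rows$knee_id)), 300L)
  expect_lt(nrow(lcm$visits), 300 * 20)
})

test_that("zero hazard coefficient decouples events from trajectories", {
  lc <- make_landmark_cohort(landmark_cohort_spec(
    n_knees = 2000, hazard_coef = 0, hazard_base = 2e-3, seed = 11))
  ev <- lc$knees[lc$knees$event == 1, ]
  tau <- stats::cor(ev$true_slope, ev$event_time, method = "kendall")
  expect_lt(abs(tau), 0.05)
})

test_that("paired knees share a participant id", {
  lc <- make_landmark_cohort(landmark_cohort_spec(
    n_knees = 100, knees_per_participant = 2, seed = 2))
  expect_equal(length(unique(lc$knees$participant_id)), 50L)
  expect_true(all(table(lc$knees$participant_id) == 2))
})
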