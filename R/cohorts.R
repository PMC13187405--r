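# Synthetic tabular cohorts: a cross-sectional knee cohort with six
# z-scorable biomarkers and hierarchical normal/abnormal labels for the
# triage cascade, and a longitudinal cohort with visit-wise thickness
# trajectories and event times for the landmark models. Both are fully
# reproducible under a fixed seed.

.triage_features <- data.frame(
  feature = c("thick_femur", "thick_tibia", "thick_patella",
              "bone_femur", "bone_tibia", "bone_patella"),
  joint   = rep(c("femur", "tibia", "patella"), 2),
  tissue  = rep(c("cartilage", "bone"), each = 3),
  mu      = c(2.2, 2.0, 2.5, 180, 150, 18),
  sigma   = c(0.25, 0.22, 0.30, 20, 18, 3),
  stringsAsFactors = FALSE)

.default_shifts <- function() {
  m <- matrix(0, 4, 6,
              dimnames = list(c("normal", "cart_only", "bone_only", "both"),
                              .triage_features$feature))
  m["cart_only", 1:3] <- -1.5
  m["bone_only", 4:6] <- 1.2
  m["both", ] <- c(-1.5, -1.5, -1.5, 1.2, 1.2, 1.2)
  m
}

#' Specify a synthetic triage cohort
#'
#' Four hierarchical classes (normal, cartilage-only, bone-only, both); each
#' class shifts the six biomarkers (cartilage thickness and bone volume for
#' femur, tibia, patella) by a stated number of reference SDs. Demographics
#' are sampled independently of the class so that signal recovery is
#' attributable to the biomarkers alone.
#'
#' @param n_subjects number of subjects.
#' @param prevalence length-4 class prevalences (normal, cart_only,
#'   bone_only, both); must sum to 1.
#' @param shifts 4 x 6 matrix of class mean shifts in reference-SD units
#'   (rows = classes, cols = features); default: -1.5 SD on thickness for
#'   cartilage-abnormal classes, +1.2 SD on bone volume for bone-abnormal.
#' @param noise_sd within-class feature SD in reference-SD units (> 0).
#' @param sex_p,age_mean,age_sd,weight_mean,weight_sd demographic model.
#' @param knees_per_subject 1 or 2 (paired knees share the subject id).
#' @param seed RNG seed.
#' @export
triage_cohort_spec <- function(n_subjects = 600L,
                               prevalence = c(0.55, 0.15, 0.15, 0.15),
                               shifts = .default_shifts(),
                               noise_sd = 1,
                               sex_p = 0.5, age_mean = 55, age_sd = 10,
                               weight_mean = 80, weight_sd = 15,
                               knees_per_subject = 1L, seed = 1L) {
  .assert(abs(sum(prevalence) - 1) < 1e-8, "prevalences must sum to 1")
  .assert(all(prevalence >= 0), "prevalences must be non-negative")
  .assert(noise_sd > 0, "noise SD must be > 0")
  .assert(identical(dim(shifts), c(4L, 6L)), "shifts must be a 4 x 6 matrix")
  dimnames(shifts) <- dimnames(.default_shifts())
  .assert(knees_per_subject %in% 1:2, "knees_per_subject must be 1 or 2")
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 shifts = shifts, noise_sd = noise_sd, sex_p = sex_p,
                 age_mean = age_mean, age_sd = age_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 knees_per_subject = as.integer(knees_per_subject),
                 seed = as.integer(seed)),
            class = "triage_cohort_spec")
}

#' Generate a synthetic triage cohort
#'
#' @param spec a [triage_cohort_spec()].
#' @return data.frame with one row per knee: subject_id, knee_id, class,
#'   the six biomarkers in physical units, sex/age/weight, and the label
#'   hierarchy (knee_abnormal, cart_label, bone_label, per-joint and
#'   per-joint-tissue labels). The label hierarchy is consistent by
#'   construction: any joint- or tissue-level abnormality implies
#'   `knee_abnormal`.
#' @export
make_triage_cohort <- function(spec) {
  stopifnot(inherits(spec, "triage_cohort_spec"))
  set.seed(spec$seed)
  classes <- rownames(spec$shifts)
  n_knees <- spec$n_subjects * spec$knees_per_subject
  exp_n <- spec$prevalence * n_knees
  if (any(exp_n > 0 & exp_n < 2))
    warning("expected count < 2 for class(es): ",
            paste(classes[exp_n > 0 & exp_n < 2], collapse = ", "))
  subject_id <- sprintf("S%04d", rep(seq_len(spec$n_subjects),
                                     each = spec$knees_per_subject))
  knee_id <- sprintf("%s_K%d", subject_id,
                     rep(seq_len(spec$knees_per_subject), spec$n_subjects))
  cls <- sample(classes, n_knees, replace = TRUE, prob = spec$prevalence)
  fi <- .triage_features
  z <- spec$shifts[cls, , drop = FALSE] +
    matrix(stats::rnorm(n_knees * 6, 0, spec$noise_sd), n_knees, 6)
  vals <- sweep(sweep(z, 2, fi$sigma, `*`), 2, fi$mu, `+`)
  colnames(vals) <- fi$feature
  # demographics sampled per subject, replicated over paired knees
  sex_s <- stats::rbinom(spec$n_subjects, 1, spec$sex_p)
  age_s <- stats::rnorm(spec$n_subjects, spec$age_mean, spec$age_sd)
  wt_s <- stats::rnorm(spec$n_subjects, spec$weight_mean, spec$weight_sd)
  rep_i <- rep(seq_len(spec$n_subjects), each = spec$knees_per_subject)
  out <- data.frame(subject_id, knee_id, class = cls, vals,
                    sex = sex_s[rep_i], age = age_s[rep_i],
                    weight = wt_s[rep_i], stringsAsFactors = FALSE)
  out$cart_label <- as.integer(cls %in% c("cart_only", "both"))
  out$bone_label <- as.integer(cls %in% c("bone_only", "both"))
  out$knee_abnormal <- as.integer(cls != "normal")
  shifted <- spec$shifts != 0
  for (j in unique(fi$joint)) {
    feats <- fi$feature[fi$joint == j]
    out[[paste0("joint_", j)]] <-
      as.integer(rowSums(shifted[cls, feats, drop = FALSE] != 0) > 0)
    for (tis in unique(fi$tissue)) {
      f <- fi$feature[fi$joint == j & fi$tissue == tis]
      out[[paste0("abn_", tis, "_", j)]] <- as.integer(shifted[cls, f])
    }
  }
  attr(out, "spec") <- spec
  attr(out, "features") <- fi$feature
  out
}

#' Specify a synthetic longitudinal knee cohort
#'
#' Visits are fixed at 0, 12, 24, 36 and 48 months. Each knee carries a
#' per-compartment linear thickness trajectory; the surgical-event hazard is
#' piecewise constant over 12-month intervals with log-hazard increasing
#' linearly in the cumulative thickness lost up to the interval start, and
#' event times are drawn by inverse-transform sampling. Follow-up is
#' administratively censored at `censor_month`.
#'
#' @param n_knees number of knees.
#' @param knees_per_participant 1 or 2.
#' @param compartments compartment names.
#' @param baseline_mean,baseline_sd per-compartment baseline thickness (mm).
#' @param slope_mean,slope_sd knee-level thickness slope distribution
#'   (mm/year, negative = loss); compartments add N(0, 0.02) jitter.
#' @param noise_sd visit-level measurement noise SD (mm).
#' @param hazard_base baseline hazard per month.
#' @param hazard_coef log-hazard increase per mm of cumulative loss summed
#'   over compartments; 0 decouples events from trajectories.
#' @param censor_month administrative censoring month (96 or 120).
#' @param missing_prob probability a post-baseline visit is missing.
#' @param kl_prev baseline Kellgren-Lawrence grade prevalences (grades 0-4).
#' @param seed RNG seed.
#' @export
landmark_cohort_spec <- function(n_knees = 600L, knees_per_participant = 1L,
                                 compartments = c("femoral", "tibial_lateral",
                                                  "tibial_medial", "patellar"),
                                 baseline_mean = c(2.2, 1.9, 2.0, 2.5),
                                 baseline_sd = 0.25,
                                 slope_mean = -0.05, slope_sd = 0.08,
                                 noise_sd = 0.05,
                                 hazard_base = 5e-5, hazard_coef = 1.5,
                                 censor_month = 96, missing_prob = 0,
                                 kl_prev = c(0.35, 0.30, 0.20, 0.10, 0.05),
                                 seed = 1L) {
  .assert(length(baseline_mean) == length(compartments),
          "baseline_mean must match compartments")
  .assert(censor_month %in% c(96, 120), "censor_month must be 96 or 120")
  .assert(hazard_base > 0, "hazard_base must be > 0")
  .assert(hazard_coef >= 0, "hazard_coef must be >= 0")
  .assert(abs(sum(kl_prev) - 1) < 1e-8, "KL prevalences must sum to 1")
  .assert(knees_per_participant %in% 1:2, "knees_per_participant must be 1 or 2")
  structure(list(n_knees = as.integer(n_knees),
                 knees_per_participant = as.integer(knees_per_participant),
                 compartments = compartments, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, slope_mean = slope_mean,
                 slope_sd = slope_sd, noise_sd = noise_sd,
                 hazard_base = hazard_base, hazard_coef = hazard_coef,
                 censor_month = censor_month, missing_prob = missing_prob,
                 kl_prev = kl_prev, seed = as.integer(seed)),
            class = "landmark_cohort_spec")
}

#' Generate a synthetic longitudinal cohort
#'
#' @param spec a [landmark_cohort_spec()].
#' @return list of class `longitudinal_cohort` with `visits` (long format:
#'   knee_id, participant_id, visit_month, compartment, thickness_mm) and
#'   `knees` (knee_id, participant_id, event_time, event, censor_month,
#'   age, sex, bmi, kl_baseline, true_slope).
#' @export
make_landmark_cohort <- function(spec) {
  stopifnot(inherits(spec, "landmark_cohort_spec"))
  set.seed(spec$seed)
  visits <- c(0, 12, 24, 36, 48)
  nc <- length(spec$compartments)
  n <- spec$n_knees
  kpp <- spec$knees_per_participant
  n_part <- ceiling(n / kpp)
  participant_id <- sprintf("P%04d", rep(seq_len(n_part), each = kpp)[seq_len(n)])
  knee_id <- sprintf("%s_K%d", participant_id,
                     stats::ave(seq_len(n), participant_id, FUN = seq_along))

  base <- matrix(stats::rnorm(n * nc, rep(spec$baseline_mean, each = n),
                              spec$baseline_sd), n, nc)
  slope_knee <- stats::rnorm(n, spec$slope_mean, spec$slope_sd)
  slope <- slope_knee + matrix(stats::rnorm(n * nc, 0, 0.02), n, nc)

  # piecewise-constant hazard per 12-month interval; cumulative loss at the
  # interval start drives the log-hazard
  loss_rate <- rowSums(pmax(-slope, 0)) # mm per year, summed over compartments
  breaks <- seq(0, spec$censor_month, by = 12)
  E <- stats::rexp(n)
  event_time <- rep(Inf, n)
  cumhaz <- numeric(n)
  for (j in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[j]; t1 <- breaks[j + 1L]
    lam <- spec$hazard_base * exp(spec$hazard_coef * loss_rate * t0 / 12)
    add <- lam * (t1 - t0)
    hit <- is.infinite(event_time) & (cumhaz + add >= E)
    event_time[hit] <- t0 + (E[hit] - cumhaz[hit]) / lam[hit]
    cumhaz <- cumhaz + add
  }
  event <- as.integer(is.finite(event_time) & event_time <= spec$censor_month)
  time_obs <- ifelse(event == 1L, event_time, spec$censor_month)

  obs <- expand.grid(visit = visits, comp = seq_len(nc), knee = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE)
  tm <- obs$visit / 12
  th <- base[cbind(obs$knee, obs$comp)] + slope[cbind(obs$knee, obs$comp)] * tm +
    stats::rnorm(nrow(obs), 0, spec$noise_sd)
  vis <- data.frame(knee_id = knee_id[obs$knee],
                    participant_id = participant_id[obs$knee],
                    visit_month = obs$visit,
                    compartment = spec$compartments[obs$comp],
                    thickness_mm = th, stringsAsFactors = FALSE)
  if (spec$missing_prob > 0) {
    # whole visits go missing (all compartments at once); baseline is kept
    key <- paste(vis$knee_id, vis$visit_month)
    uk <- unique(key[vis$visit_month > 0])
    drop <- uk[stats::runif(length(uk)) < spec$missing_prob]
    vis <- vis[!(key %in% drop), ]
  }

  sex_p <- stats::rbinom(n_part, 1, 0.55)
  age_p <- stats::rnorm(n_part, 61, 9)
  bmi_p <- stats::rnorm(n_part, 28.5, 4.8)
  pid_i <- as.integer(factor(participant_id, levels = sprintf("P%04d", seq_len(n_part))))
  knees <- data.frame(knee_id, participant_id,
                      event_time = time_obs, event = event,
                      censor_month = spec$censor_month,
                      age = age_p[pid_i], sex = sex_p[pid_i], bmi = bmi_p[pid_i],
                      kl_baseline = sample(0:4, n, replace = TRUE,
                                           prob = spec$kl_prev),
                      true_slope = slope_knee,
                      stringsAsFactors = FALSE)
  structure(list(visits = vis, knees = knees, spec = spec),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat(sprintf("<longitudinal_cohort> %d knees, %d participants, %d visit rows\n",
              nrow(x$knees), length(unique(x$knees$participant_id)),
              nrow(x$visits)))
  cat(sprintf("  events: %d (%.1f%%) by month %d\n", sum(x$knees$event),
              100 * mean(x$knees$event), x$spec$censor_month))
  invisible(x)
}

#' Write a cohort to CSV files
#' @param x a triage cohort data.frame or `longitudinal_cohort`.
#' @param dir output directory.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "longitudinal_cohort")) {
    utils::write.csv(x$visits, file.path(dir, "visits.csv"), row.names = FALSE)
    utils::write.csv(x$knees, file.path(dir, "knees.csv"), row.names = FALSE)
  } else {
    utils::write.csv(x, file.path(dir, "cohort.csv"), row.names = FALSE)
  }
  invisible(dir)
}
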