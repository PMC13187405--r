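# Assumption-gated agreement analysis between model-derived and reference
# biomarker values: Shapiro-Wilk / Levene screening decides between a
# parametric arm (two-way single-measurement ICC with F-based intervals,
# mean +/- 1.96 SD Bland-Altman limits, OLS regression with R^2) and a
# non-parametric arm (random-intercept variance-ratio ICC with subject-level
# bootstrap intervals, percentile Bland-Altman limits, Gaussian-process
# regression); Spearman's rho is always reported and Benjamini-Hochberg
# control is applied across an analysis batch.

#' Screen distributional assumptions for a paired comparison
#'
#' Shapiro-Wilk on the paired differences (normality) and Levene's test
#' across the two measurement arms (homogeneity of variance), both at
#' p >= 0.05. The parametric flag is the conjunction and drives the ICC,
#' Bland-Altman and regression variants downstream; it is a pure function
#' of the two p-values.
#'
#' @param x,y paired measurements (reference, model), n >= 4.
#' @param alpha screening level (default 0.05).
#' @param center centering function for Levene's test (`mean` is the
#'   classic Levene form).
#' @return list of class `assumption_gate`: shapiro_p, levene_p,
#'   parametric.
#' @export
gate_assumptions <- function(x, y, alpha = 0.05, center = mean) {
  .assert(length(x) == length(y), "x and y must be paired")
  .assert(length(x) >= 4L, "insufficient pairs (n < 4)")
  d <- y - x
  sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  if (is.na(sw))
    warning("Shapiro-Wilk undefined (degenerate differences); non-parametric path")
  lev <- tryCatch({
    df <- data.frame(value = c(x, y),
                     arm = factor(rep(c("x", "y"), each = length(x))))
    car::leveneTest(value ~ arm, data = df, center = center)[1, "Pr(>F)"]
  }, error = function(e) NA_real_)
  parametric <- isTRUE(sw >= alpha) && isTRUE(lev >= alpha)
  structure(list(shapiro_p = sw, levene_p = lev, parametric = parametric),
            class = "assumption_gate")
}

# two-way mean squares for n subjects x 2 raters
.icc_ms <- function(x, y) {
  m <- cbind(x, y)
  n <- nrow(m); k <- 2L
  gm <- mean(m)
  ms_r <- k * sum((rowMeans(m) - gm)^2) / (n - 1)            # subjects
  ms_c <- n * sum((colMeans(m) - gm)^2) / (k - 1)            # raters
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + gm)^2)
  list(n = n, k = k, msr = ms_r, msc = ms_c, mse = sse / ((n - 1) * (k - 1)))
}

#' Intraclass correlation for two paired measurement arms
#'
#' `mode = "parametric"`: two-way, single-measurement ICC from the
#' mean-squares decomposition. `type = "consistency"` is the two-way
#' mixed-effects consistency form (default); `type = "agreement"` the
#' two-way absolute-agreement form. Confidence intervals are F-based
#' (exact for consistency; the standard Satterthwaite approximation for
#' agreement). `mode = "bootstrap"`: variance-ratio
#' sigma^2_subject / (sigma^2_subject + sigma^2_error) from a
#' random-intercept decomposition with a percentile interval from
#' subject-level resamples.
#'
#' @param x,y paired values, n >= 5.
#' @param mode `"parametric"` or `"bootstrap"`.
#' @param type `"consistency"` or `"agreement"` (parametric mode).
#' @param conf confidence level.
#' @param nboot bootstrap resamples (default 10000).
#' @param seed bootstrap seed.
#' @return list of class `icc_result`: estimate, lower, upper, method tag.
#' @export
icc <- function(x, y, mode = c("parametric", "bootstrap"),
                type = c("consistency", "agreement"),
                conf = 0.95, nboot = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  .assert(length(x) == length(y) && length(x) >= 5L,
          "need >= 5 paired measurements")
  ms <- .icc_ms(x, y)
  .assert(ms$msr + ms$mse > 0, "zero total variance")
  n <- ms$n; k <- ms$k
  a <- (1 - conf) / 2
  if (mode == "parametric") {
    if (type == "consistency") {
      est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
      fo <- ms$msr / ms$mse
      fl <- fo / stats::qf(1 - a, n - 1, (n - 1) * (k - 1))
      fu <- fo * stats::qf(1 - a, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
      tag <- "parametric_two_way_single_consistency"
    } else {
      est <- (ms$msr - ms$mse) /
        (ms$msr + (k - 1) * ms$mse + k / n * (ms$msc - ms$mse))
      # Satterthwaite df for the agreement interval (McGraw & Wong)
      fj <- ms$msc / ms$mse
      num <- (k - 1) * (n - 1) *
        (k * est * fj + n * (1 + (k - 1) * est) - k * est)^2
      den <- (n - 1) * k^2 * est^2 * fj^2 +
        (n * (1 + (k - 1) * est) - k * est)^2
      v <- num / den
      fl <- stats::qf(1 - a, n - 1, v)
      fu <- stats::qf(1 - a, v, n - 1)
      lo <- n * (ms$msr - fl * ms$mse) /
        (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      hi <- n * (fu * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
      tag <- "parametric_two_way_single_agreement"
    }
  } else {
    vr <- function(xx, yy) {
      mm <- .icc_ms(xx, yy)
      s2s <- max(0, (mm$msr - mm$mse) / 2)
      s2s / (s2s + mm$mse)
    }
    est <- vr(x, y)
    set.seed(seed)
    bs <- replicate(nboot, {
      i <- sample.int(n, n, replace = TRUE)
      vr(x[i], y[i])
    })
    qs <- stats::quantile(bs, c(a, 1 - a), names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
    tag <- "bootstrap_mixed_effects"
  }
  structure(list(estimate = est, lower = lo, upper = hi,
                 method = tag, n = n, conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f (%d%% CI %.4f to %.4f; %s, n = %d)\n",
              x$estimate, round(100 * x$conf), x$lower, x$upper, x$method, x$n))
  invisible(x)
}

#' Bland-Altman bias and limits of agreement
#'
#' Parametric: bias = mean difference, limits = bias +/- 1.96 SD of the
#' differences. Non-parametric: bias = median difference, limits = 2.5th
#' and 97.5th percentiles of the differences.
#'
#' @param x,y paired values (difference is `y - x`), n >= 4.
#' @param parametric logical, normally the [gate_assumptions()] outcome.
#' @return list of class `bland_altman`: bias, lower, upper, method.
#' @export
bland_altman <- function(x, y, parametric = TRUE) {
  .assert(length(x) == length(y) && length(x) >= 4L, "need >= 4 pairs")
  d <- y - x
  if (parametric) {
    bias <- mean(d)
    s <- stats::sd(d)
    res <- list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
                method = "parametric")
  } else {
    res <- list(bias = stats::median(d),
                lower = unname(stats::quantile(d, 0.025, type = 7)),
                upper = unname(stats::quantile(d, 0.975, type = 7)),
                method = "percentile")
  }
  structure(res, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %.4f, limits [%.4f, %.4f]\n",
              x$method, x$bias, x$lower, x$upper))
  invisible(x)
}

#' Regression-based agreement summary
#'
#' Parametric: ordinary least squares of the model values on the reference
#' (reference on the x axis) with R^2. Non-parametric: Gaussian-process
#' regression (RBF kernel plus noise variance) on standardized inputs with
#' a 95% pointwise predictive band, de-standardized for reporting; on GP
#' failure the Spearman summary alone is returned with a warning.
#' Spearman's rho and its p-value are always reported.
#'
#' @param x reference values; @param y model values.
#' @param parametric gate outcome.
#' @return list of class `regression_agreement`.
#' @export
regression_agreement <- function(x, y, parametric = TRUE) {
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  out <- list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
  if (parametric) {
    fit <- stats::lm(y ~ x)
    out$method <- "OLS"
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
    out$r_squared <- summary(fit)$r.squared
  } else {
    gp <- tryCatch({
      mx <- mean(x); sx <- stats::sd(x); my <- mean(y); sy <- stats::sd(y)
      xs <- (x - mx) / sx; ys <- (y - my) / sy
      fit <- kernlab::gausspr(matrix(xs), ys, variance.model = TRUE,
                              kpar = "automatic")
      grid <- seq(min(xs), max(xs), length.out = 100)
      mu <- kernlab::predict(fit, matrix(grid))
      sdev <- kernlab::predict(fit, matrix(grid), type = "sdeviation")
      list(x = grid * sx + mx,
           mean = mu * sy + my,
           lower = (mu - 1.96 * sdev) * sy + my,
           upper = (mu + 1.96 * sdev) * sy + my)
    }, error = function(e) NULL)
    if (is.null(gp)) {
      warning("GP fit failed; reporting Spearman only")
      out$method <- "spearman_only"
    } else {
      out$method <- "GP"
      out$gp <- gp
    }
  }
  structure(out, class = "regression_agreement")
}

#' Run the agreement suite over a batch of biomarkers
#'
#' For each biomarker: assumption gate, gate-matched ICC, Bland-Altman and
#' regression, Spearman correlation; Benjamini-Hochberg adjustment of the
#' Spearman p-values across the whole batch.
#'
#' @param data data.frame with columns `biomarker`, `value_ref`,
#'   `value_pred` (one row per subject x biomarker).
#' @param nboot bootstrap resamples for the non-parametric ICC arm.
#' @param seed bootstrap seed.
#' @return data.frame of class `agreement_suite`, one row per biomarker.
#' @export
agreement_suite <- function(data, nboot = 10000L, seed = 1L) {
  need <- c("biomarker", "value_ref", "value_pred")
  .assert(all(need %in% names(data)), "need columns %s",
          paste(need, collapse = ", "))
  rows <- lapply(split(data, data$biomarker), function(d) {
    x <- d$value_ref; y <- d$value_pred
    g <- gate_assumptions(x, y)
    ic <- icc(x, y, mode = if (g$parametric) "parametric" else "bootstrap",
              nboot = nboot, seed = seed)
    ba <- bland_altman(x, y, parametric = g$parametric)
    rg <- suppressWarnings(regression_agreement(x, y, parametric = g$parametric))
    data.frame(biomarker = d$biomarker[1], n = length(x),
               shapiro_p = g$shapiro_p, levene_p = g$levene_p,
               parametric = g$parametric,
               icc = ic$estimate, icc_lower = ic$lower, icc_upper = ic$upper,
               icc_method = ic$method,
               ba_bias = ba$bias, ba_lower = ba$lower, ba_upper = ba$upper,
               ba_method = ba$method,
               regression = rg$method,
               r_squared = if (!is.null(rg$r_squared)) rg$r_squared else NA_real_,
               spearman_rho = rg$spearman_rho, spearman_p = rg$spearman_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$spearman_p_adj <- stats::p.adjust(out$spearman_p, method = "BH")
  class(out) <- c("agreement_suite", "data.frame")
  out
}
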