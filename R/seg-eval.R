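# Overlap metrics (Dice, Jaccard) computed per slice, aggregated slice ->
# subject (mean) -> structure (median) with lower-tail summaries, and the
# paired non-parametric model-comparison framework (Friedman, then pairwise
# Wilcoxon signed-rank with Benjamini-Hochberg control at 5%).

#' Per-slice overlap metrics between predicted and reference masks
#'
#' Dice = 2|A∩B| / (|A| + |B|), Jaccard = |A∩B| / |A∪B|, per slice.
#' Slices with an empty reference are excluded from the records (set
#' `include_empty = TRUE` to score them 1 when the prediction is also
#' empty); a non-empty reference met by an empty prediction scores 0.
#'
#' @param pred,ref `mask_volume`s (or 3D arrays) of identical shape.
#' @param label_id label to score.
#' @param subject_id carried into the records.
#' @param include_empty score empty-reference slices as 1/0 rather than
#'   excluding them.
#' @return data.frame of class `overlap_records`: subject_id, slice,
#'   label_id, dice, jaccard.
#' @export
overlap_metrics <- function(pred, ref, label_id, subject_id = "subject",
                            include_empty = FALSE) {
  pa <- if (inherits(pred, "mask_volume")) pred$labels else pred
  ra <- if (inherits(ref, "mask_volume")) ref$labels else ref
  .assert(identical(dim(pa), dim(ra)), "shape mismatch")
  ns <- dim(pa)[3]
  out <- vector("list", ns)
  for (k in seq_len(ns)) {
    a <- pa[, , k] == label_id
    b <- ra[, , k] == label_id
    nb <- sum(b)
    if (nb == 0L && !include_empty) next
    na <- sum(a)
    ni <- sum(a & b)
    dice <- if (na + nb == 0L) 1 else 2 * ni / (na + nb)
    jac <- if (na + nb == 0L) 1 else ni / (na + nb - ni)
    out[[k]] <- data.frame(subject_id = subject_id, slice = k,
                           label_id = label_id, dice = dice, jaccard = jac)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(subject_id = character(0), slice = integer(0),
                      label_id = integer(0), dice = numeric(0),
                      jaccard = numeric(0))
  class(res) <- c("overlap_records", "data.frame")
  res
}

#' Aggregate overlap records to subject and dataset level
#'
#' Slice scores are aggregated to the subject by the mean (the median is
#' also emitted), subjects to the structure by the median, and the dataset
#' tail is summarized by the median, 5th percentile and minimum across
#' subjects. Percentiles use linear interpolation between order statistics
#' (type 7).
#'
#' @param records `overlap_records` rows (possibly several subjects /
#'   labels), optionally with a `structure` column (defaults to the label).
#' @param metric `"dice"` or `"jaccard"`.
#' @return list of class `subject_summary` with `subjects` (per subject x
#'   structure) and `structures` (median, p5, min, n across subjects).
#' @export
summarize_subjects <- function(records, metric = c("dice", "jaccard")) {
  metric <- match.arg(metric)
  .assert(nrow(records) > 0, "no records")
  if (is.null(records$structure)) records$structure <- as.character(records$label_id)
  key <- interaction(records$subject_id, records$structure, drop = TRUE)
  subj <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(subject_id = d$subject_id[1], structure = d$structure[1],
               mean_score = mean(d[[metric]]),
               median_score = stats::median(d[[metric]]),
               n_slices = nrow(d))
  }))
  rownames(subj) <- NULL
  strs <- do.call(rbind, lapply(split(subj, subj$structure), function(d) {
    data.frame(structure = d$structure[1],
               median = stats::median(d$mean_score),
               p5 = unname(stats::quantile(d$mean_score, 0.05, type = 7)),
               min = min(d$mean_score),
               n_subjects = nrow(d))
  }))
  rownames(strs) <- NULL
  structure(list(subjects = subj, structures = strs, metric = metric),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("<subject_summary> metric = %s\n", x$metric))
  print(x$structures)
  invisible(x)
}

#' Paired non-parametric comparison of segmentation models
#'
#' Friedman test across all models, followed by two-sided pairwise Wilcoxon
#' signed-rank tests with Benjamini-Hochberg step-up control of the false
#' discovery rate at 5%. Subjects must be identical (paired) across models.
#'
#' @param scores matrix or data.frame, rows = subjects, columns = models
#'   (per-subject scores, e.g. mean Dice).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return list of class `model_comparison`: Friedman statistic and p,
#'   pairwise table with statistic, raw and BH-adjusted p, significance.
#' @export
compare_models <- function(scores, alpha = 0.05) {
  m <- as.matrix(scores)
  .assert(ncol(m) >= 2L, "need at least 2 models")
  .assert(!anyNA(m), "unpaired input: missing scores")
  if (is.null(colnames(m))) colnames(m) <- paste0("model", seq_len(ncol(m)))
  fr <- stats::friedman.test(m)
  pairs <- utils::combn(colnames(m), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (all(m[, a] == m[, b])) {
      data.frame(model_a = a, model_b = b, statistic = NA_real_, p_raw = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(m[, a], m[, b], paired = TRUE,
                                                exact = FALSE))
      data.frame(model_a = a, model_b = b,
                 statistic = unname(wt$statistic), p_raw = wt$p.value)
    }
  }))
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "BH")
  pw$significant <- pw$p_adj < alpha
  structure(list(friedman_statistic = unname(fr$statistic),
                 friedman_p = fr$p.value, pairwise = pw, alpha = alpha),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> Friedman chi^2 = %.3f, p = %.3g\n",
              x$friedman_statistic, x$friedman_p))
  print(x$pairwise)
  invisible(x)
}
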