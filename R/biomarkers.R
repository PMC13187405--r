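# Measurement interface: labelled masks (plus optional parametric maps) to
# physical-unit biomarkers and z-scored features.
#
# Thickness follows the medial-axis construction: per 2D slice, the binary
# compartment mask is thinned to its medial-axis skeleton and the
# spacing-aware Euclidean distance to the nearest tissue boundary is sampled
# at every skeleton pixel. The distance-to-boundary subtracts half an
# in-plane spacing from the voxel-center distance transform (the boundary
# lies midway between a foreground and a background voxel center). Samples
# are pooled across slices and averaged per compartment. `half_width`
# reports the boundary distance itself, `full_width` (laminar thickness)
# twice it.

#' Medial-axis compartment thickness
#'
#' @param mask a [mask_volume()].
#' @param label_id label of the compartment to measure.
#' @param mode `"full_width"` (laminar thickness, default) or
#'   `"half_width"` (medial-axis boundary distance).
#' @param min_skeleton_px compartments with fewer skeleton samples per
#'   volume yield `NaN` with a warning (medial axes of tiny blobs are
#'   noise); default 5.
#' @return object of class `thickness_result`: mean thickness (mm),
#'   per-slice sample counts, mode and aggregation metadata. Empty
#'   compartments give `NaN` with a warning, never an error.
#' @export
compartment_thickness <- function(mask, label_id, mode = c("full_width", "half_width"),
                                  min_skeleton_px = 5L) {
  stopifnot(inherits(mask, "mask_volume"))
  mode <- match.arg(mode)
  if (!is.null(mask$label_map))
    .assert(as.character(label_id) %in% names(mask$label_map),
            "label %s not in label_map", label_id)
  sx <- mask$spacing[1]; sy <- mask$spacing[2]
  half_px <- mean(c(sx, sy)) / 2
  d <- dim(mask$labels)
  samples <- numeric(0)
  n_per_slice <- integer(d[3])
  for (k in seq_len(d[3])) {
    sl <- mask$labels[, , k] == label_id
    if (!any(sl)) next
    dt <- edt2d(sl, sx, sy)
    sk <- thin2d(sl)
    v <- dt[sk & dt > 0]
    v <- pmax(v - half_px, 0)
    n_per_slice[k] <- length(v)
    samples <- c(samples, v)
  }
  if (length(samples) < min_skeleton_px) {
    warning(sprintf("compartment %s: %d skeleton samples (< %d); thickness is NaN",
                    label_id, length(samples), min_skeleton_px))
    mean_mm <- NaN
  } else {
    mean_mm <- mean(samples) * if (mode == "full_width") 2 else 1
  }
  structure(list(label_id = label_id,
                 compartment = if (!is.null(mask$label_map))
                   mask$label_map[[as.character(label_id)]]$name else as.character(label_id),
                 mean_thickness_mm = mean_mm,
                 n_samples = length(samples),
                 n_per_slice = n_per_slice,
                 mode = mode, units = "mm",
                 aggregation = "pooled skeleton samples, mean per compartment"),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("<thickness_result> %s: %.3f mm (%s, %d skeleton samples)\n",
              x$compartment, x$mean_thickness_mm, x$mode, x$n_samples))
  invisible(x)
}

#' Intervertebral disc heights per level
#'
#' Per slice, connected components identify disc instances; the axis-aligned
#' bounding-box extent along the declared cranio-caudal axis times the pixel
#' spacing is the slice-level height. Instances are associated into levels
#' by centroid ordering along the cranio-caudal axis (reference slice = the
#' slice with the most instances; nearest-centroid assignment, with a
#' warning when an assignment is ambiguous). The per-level height is the
#' maximum across slices.
#'
#' @param mask a [mask_volume()].
#' @param disc_label disc label id.
#' @param cranio_caudal_axis `"row"` (default) or `"col"`.
#' @param connectivity 2D connectivity for instance detection (default 8).
#' @return data.frame with level, height_mm, n_slices; empty masks give a
#'   zero-row result.
#' @export
disc_heights <- function(mask, disc_label, cranio_caudal_axis = c("row", "col"),
                         connectivity = 8L) {
  stopifnot(inherits(mask, "mask_volume"))
  axis <- match.arg(cranio_caudal_axis)
  sp <- if (axis == "row") mask$spacing[1] else mask$spacing[2]
  d <- dim(mask$labels)
  inst <- list()
  for (k in seq_len(d[3])) {
    sl <- mask$labels[, , k] == disc_label
    if (!any(sl)) next
    lab <- label_components(sl, connectivity)
    for (cmp in seq_len(max(lab))) {
      ij <- which(lab == cmp, arr.ind = TRUE)
      ax <- if (axis == "row") ij[, 1] else ij[, 2]
      inst[[length(inst) + 1L]] <- data.frame(
        slice = k,
        centroid = mean(ax) * sp,
        height_mm = (max(ax) - min(ax) + 1L) * sp)
    }
  }
  if (length(inst) == 0L)
    return(data.frame(level = integer(0), height_mm = numeric(0),
                      n_slices = integer(0)))
  inst <- do.call(rbind, inst)
  per_slice <- table(inst$slice)
  ref_slice <- as.integer(names(per_slice)[which.max(per_slice)])
  centers <- sort(inst$centroid[inst$slice == ref_slice])
  if (length(centers) > 1L) {
    gaps <- diff(centers)
    spread <- stats::ave(inst$centroid, findInterval(inst$centroid, centers),
                         FUN = length)
    if (min(gaps) < 2 * sp)
      warning("disc level centroids closer than 2 pixels; assignment may be ambiguous")
  }
  lvl <- vapply(inst$centroid, function(cc) which.min(abs(centers - cc)), integer(1))
  if (any(tapply(lvl, inst$slice, function(v) anyDuplicated(v) > 0)))
    warning("overlapping centroid ranges: nearest-centroid assignment used")
  agg <- tapply(inst$height_mm, lvl, max)
  data.frame(level = as.integer(names(agg)),
             height_mm = as.numeric(agg),
             n_slices = as.integer(tapply(inst$slice, lvl,
                                          function(s) length(unique(s)))))
}

#' Tissue volume in cubic centimeters
#'
#' Voxel count times the voxel volume sx*sy*sz (mm^3), reported in cm^3.
#' Empty compartments give 0.
#'
#' @inheritParams compartment_thickness
#' @export
tissue_volume <- function(mask, label_id) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$labels == label_id) * voxel_volume(mask) / 1000
}

#' Mean relaxation time within a compartment
#'
#' Map voxels inside the compartment mask are clipped to the stated range
#' (default 0-100 ms) and pooled into an arithmetic mean across the whole
#' compartment (pooled voxel mean across slices).
#'
#' @param map a [parametric_map()].
#' @param mask a [mask_volume()] on the same grid.
#' @param label_id compartment label.
#' @param clip length-2 clipping range in ms.
#' @return mean in ms; `NaN` with a warning for an empty compartment.
#' @export
relaxometry_mean <- function(map, mask, label_id, clip = c(0, 100)) {
  stopifnot(inherits(map, "parametric_map"), inherits(mask, "mask_volume"))
  check_paired(map, mask)
  v <- map$values[mask$labels == label_id]
  if (length(v) == 0L) {
    warning(sprintf("compartment %s empty: relaxometry mean is NaN", label_id))
    return(NaN)
  }
  mean(pmin(pmax(v, clip[1]), clip[2]))
}

# ---- reference statistics and z-scoring ------------------------------------

#' Freeze reference statistics for z-scoring
#'
#' Computes the per-feature mean and sample SD over a designated reference
#' subset (for example radiographically normal knees). The reference is
#' frozen once, globally - never per cross-validation fold - so that
#' downstream features are comparable across folds and stages.
#'
#' @param data data.frame of features.
#' @param features character vector of feature columns.
#' @param reference logical vector selecting the reference rows (default:
#'   all rows).
#' @param provenance free-text tag recording how the reference was defined.
#' @return object of class `reference_stats`.
#' @export
fit_reference <- function(data, features, reference = rep(TRUE, nrow(data)),
                          provenance = "unspecified reference") {
  .assert(all(features %in% names(data)), "missing feature columns: %s",
          paste(setdiff(features, names(data)), collapse = ", "))
  ref <- data[reference, features, drop = FALSE]
  .assert(nrow(ref) >= 3L, "reference subset has %d rows (< 3)", nrow(ref))
  mu <- vapply(ref, mean, numeric(1))
  sd_ <- vapply(ref, stats::sd, numeric(1))
  bad <- features[!is.finite(sd_) | sd_ == 0]
  .assert(length(bad) == 0L, "zero reference SD for feature(s): %s",
          paste(bad, collapse = ", "))
  structure(list(features = features, mean = mu, sd = sd_, n_ref = nrow(ref),
                 provenance = provenance),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> %d features, n_ref = %d (%s)\n",
              length(x$features), x$n_ref, x$provenance))
  print(data.frame(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Z-score features against frozen reference statistics
#'
#' @param data data.frame containing the reference features.
#' @param ref a [fit_reference()] result.
#' @return data.frame of z-scored features (same rows, reference feature
#'   columns only), units `z`.
#' @export
zscore <- function(data, ref) {
  stopifnot(inherits(ref, "reference_stats"))
  .assert(all(ref$features %in% names(data)), "data lacks reference features")
  out <- data[, ref$features, drop = FALSE]
  for (f in ref$features) out[[f]] <- (out[[f]] - ref$mean[[f]]) / ref$sd[[f]]
  out
}

#' Annual change between consecutive visits
#'
#' (value_t - value_(t-1)) / elapsed years, computed between consecutive
#' *available* visits of each series.
#'
#' @param visit_months numeric visit times (months).
#' @param values measurements at those visits.
#' @return data.frame with from, to (months) and annual_change per interval.
#' @export
annual_change <- function(visit_months, values) {
  o <- order(visit_months)
  vm <- visit_months[o]; v <- values[o]
  if (length(vm) < 2L)
    return(data.frame(from = numeric(0), to = numeric(0),
                      annual_change = numeric(0)))
  data.frame(from = vm[-length(vm)], to = vm[-1L],
             annual_change = diff(v) / (diff(vm) / 12))
}

#' Extract a standardized biomarker table from one labelled volume
#'
#' Runs thickness (cartilage/meniscus labels), volume (all labels) and,
#' when a parametric map is supplied, the relaxometry mean for cartilage
#' labels; returns one [biomarker_table()] in physical units.
#'
#' @param mask a [mask_volume()] with a label map (tissue classes decide
#'   which measures apply).
#' @param subject_id,visit_month identifiers for the output rows.
#' @param map optional [parametric_map()].
#' @param thickness_mode passed to [compartment_thickness()].
#' @export
extract_biomarkers <- function(mask, subject_id, visit_month = 0, map = NULL,
                               thickness_mode = "full_width") {
  stopifnot(inherits(mask, "mask_volume"))
  .assert(!is.null(mask$label_map), "extract_biomarkers needs a label map")
  rows <- list()
  for (id in names(mask$label_map)) {
    info <- mask$label_map[[id]]
    lab <- as.integer(id)
    if (sum(mask$labels == lab) == 0L) next
    vol <- tissue_volume(mask, lab)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, visit_month = visit_month,
      compartment = info$name, biomarker = "volume", value = vol, units = "cm3")
    if (info$tissue %in% c("cartilage", "meniscus", "phantom")) {
      th <- suppressWarnings(
        compartment_thickness(mask, lab, mode = thickness_mode))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, visit_month = visit_month,
        compartment = info$name, biomarker = "thickness",
        value = th$mean_thickness_mm, units = "mm")
      if (!is.null(map)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subject_id, visit_month = visit_month,
          compartment = info$name, biomarker = "relaxation_time",
          value = relaxometry_mean(map, mask, lab), units = "ms")
      }
    }
  }
  biomarker_table(do.call(rbind, rows))
}
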