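# Standardized refinement of raw predicted masks before measurement:
# sigmoid thresholding of logits, small-component removal, one morphological
# closing pass, optional light boundary smoothing (3x3 median).

#' Refinement configuration
#'
#' @param threshold probability threshold in (0, 1); the decision rule is
#'   `sigmoid(logit) >= threshold`.
#' @param min_component_voxels components strictly smaller than this are
#'   removed (0 disables removal).
#' @param closing_radius_px radius of the disc/ball structuring element for
#'   the single closing pass (0 disables closing).
#' @param smoothing `"none"` or `"median3"` (3x3 in-plane median filter).
#' @param connectivity_2d 4 or 8; @param connectivity_3d 6 or 26.
#' @param mode `"2d"` (slice-wise, the default) or `"3d"`.
#' @export
refine_config <- function(threshold = 0.5, min_component_voxels = 10L,
                          closing_radius_px = 1L,
                          smoothing = c("none", "median3"),
                          connectivity_2d = 8L, connectivity_3d = 26L,
                          mode = c("2d", "3d")) {
  .assert(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  .assert(min_component_voxels >= 0, "min_component_voxels must be >= 0")
  .assert(closing_radius_px >= 0, "closing_radius_px must be >= 0")
  structure(list(threshold = threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 closing_radius_px = as.integer(closing_radius_px),
                 smoothing = match.arg(smoothing),
                 connectivity_2d = as.integer(connectivity_2d),
                 connectivity_3d = as.integer(connectivity_3d),
                 mode = match.arg(mode)),
            class = "refine_config")
}

#' Binarize a logit array
#'
#' `mask = sigmoid(logit) >= threshold`; at the default threshold 0.5 a
#' zero logit is included (sigmoid(0) = 0.5, inclusive convention).
#'
#' @param logits numeric array of logits (finite).
#' @param threshold probability threshold in (0, 1).
#' @return logical array of the same shape.
#' @export
binarize_logits <- function(logits, threshold = 0.5) {
  .assert(!anyNA(logits), "NaN/NA logits")
  .assert(all(is.finite(logits)), "non-finite logits")
  .assert(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  m <- stats::plogis(logits) >= threshold
  dim(m) <- dim(logits)
  m
}

.remove_small <- function(m, min_vox, connectivity) {
  if (min_vox <= 0L || !any(m)) return(m)
  lab <- label_components(m, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_vox)
  array(lab %in% keep, dim(m))
}

.median3 <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  pad <- sl[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  acc <- matrix(0L, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + pad[seq_len(nr) + di, seq_len(nc) + dj]
  acc >= 5L # majority of the 9-neighbourhood
}

#' Refine a binary mask
#'
#' Applies, in order: small-component removal at the configured
#' connectivity, exactly one morphological closing pass with a disc (2D) or
#' ball (3D) of the configured radius, and optional 3x3 median smoothing.
#' With `min_component_voxels = 0`, `closing_radius_px = 0` and
#' `smoothing = "none"` this is the identity. Empty input yields empty
#' output.
#'
#' @param mask logical/0-1 array, 2D slice or 3D volume.
#' @param config a [refine_config()].
#' @return logical array of the same shape.
#' @export
refine_prediction <- function(mask, config = refine_config()) {
  stopifnot(inherits(config, "refine_config"))
  d <- dim(mask)
  m <- mask != 0
  dim(m) <- d
  if (length(d) == 2L) {
    m <- .remove_small(m, config$min_component_voxels, config$connectivity_2d)
    m <- morph_close(m, config$closing_radius_px)
    if (config$smoothing == "median3") m <- .median3(m)
    return(m)
  }
  .assert(length(d) == 3L, "mask must be 2D or 3D")
  if (config$mode == "2d") {
    for (k in seq_len(d[3])) {
      sl <- m[, , k]
      sl <- .remove_small(sl, config$min_component_voxels, config$connectivity_2d)
      sl <- morph_close(sl, config$closing_radius_px)
      if (config$smoothing == "median3") sl <- .median3(sl)
      m[, , k] <- sl
    }
  } else {
    m <- .remove_small(m, config$min_component_voxels, config$connectivity_3d)
    m <- morph_close(m, config$closing_radius_px)
    if (config$smoothing == "median3")
      for (k in seq_len(d[3])) m[, , k] <- .median3(m[, , k])
  }
  m
}
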