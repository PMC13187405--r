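#' Labelled mask volume
#'
#' The measurement substrate: a 3D integer label array with physical voxel
#' spacing and a label map. Arrays are indexed (row, col, slice); the first
#' two axes are in-plane with pixel spacings `sx`, `sy` (mm) and the third
#' axis is the slice direction with slice thickness `sz` (mm).
#'
#' @param labels 3D integer array of label ids (0 = background).
#' @param spacing numeric length-3, `c(sx, sy, sz)` in mm, all > 0.
#' @param label_map named list mapping label id (as character) to a list with
#'   `name` and `tissue`; every nonzero value in `labels` must appear.
#' @return an object of class `mask_volume`.
#' @export
mask_volume <- function(labels, spacing, label_map = NULL) {
  .assert(length(dim(labels)) == 3L, "labels must be a 3D array")
  .assert(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
          "spacing must be 3 positive values (mm)")
  if (is.double(labels)) {
    .assert(!anyNA(labels) && all(labels == round(labels)),
            "labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  if (!is.null(label_map)) {
    known <- suppressWarnings(as.integer(names(label_map)))
    .assert(!anyNA(known), "label_map names must be integer label ids")
    missing <- setdiff(present, known)
    .assert(length(missing) == 0L,
            "labels not in label_map: %s", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 label_map = label_map),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  lv <- sort(unique(as.vector(x$labels)))
  lv <- lv[lv != 0]
  for (l in lv) {
    nm <- if (!is.null(x$label_map)) x$label_map[[as.character(l)]]$name else "?"
    cat(sprintf("  label %d (%s): %d voxels\n", l, nm, sum(x$labels == l)))
  }
  invisible(x)
}

#' Voxel volume of a mask volume in mm^3
#' @param x a `mask_volume` or spacing vector.
#' @export
voxel_volume <- function(x) {
  sp <- if (inherits(x, "mask_volume") || inherits(x, "parametric_map")) x$spacing else x
  prod(sp)
}

#' Parametric relaxometry map
#'
#' A co-registered quantitative map (values in ms) sharing the grid of its
#' paired mask volume.
#'
#' @param values 3D numeric array (ms).
#' @param spacing voxel spacing `c(sx, sy, sz)` in mm.
#' @param modality `"T1rho"` or `"T2"`.
#' @export
parametric_map <- function(values, spacing, modality = c("T2", "T1rho")) {
  modality <- match.arg(modality)
  .assert(length(dim(values)) == 3L, "values must be a 3D array")
  .assert(length(spacing) == 3L && all(spacing > 0), "spacing must be 3 positive values")
  structure(list(values = values, spacing = as.numeric(spacing),
                 modality = modality),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<parametric_map> %s, %d x %d x %d voxels, range %.1f-%.1f ms\n",
              x$modality, d[1], d[2], d[3],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# Shared shape check used wherever a map is paired with a mask.
check_paired <- function(map, mask) {
  .assert(identical(dim(map$values), dim(mask$labels)), "shape mismatch")
  invisible(TRUE)
}
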