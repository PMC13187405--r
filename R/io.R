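# NIfTI, CSV and YAML input/output. NIfTI is the single mask dialect; label
# maps and run configuration are YAML; biomarker tables are CSV with a units
# column. All I/O round-trips arrays, spacings and tables exactly.

#' Read a label volume from NIfTI
#'
#' @param path path to a 3D integer-valued NIfTI file (.nii / .nii.gz).
#' @param label_map_path optional YAML/JSON label map file: entries
#'   `id: {name: ..., tissue: ...}`.
#' @return a [mask_volume()]. Spacing is taken from the header `pixdim`; the
#'   affine orientation code is recorded as attribute `orientation`.
#' @export
read_mask_volume <- function(path, label_map_path = NULL) {
  img <- RNifti::readNifti(path)
  .assert(length(dim(img)) == 3L, "expected a 3D volume, got %dD", length(dim(img)))
  arr <- as.array(img)
  .assert(all(arr == round(arr)), "non-integer label values in %s", path)
  lm <- if (!is.null(label_map_path)) read_label_map(label_map_path) else NULL
  mv <- mask_volume(array(as.integer(arr), dim(arr)),
                    spacing = RNifti::pixdim(img)[1:3], label_map = lm)
  attr(mv, "orientation") <- tryCatch(RNifti::orientation(img),
                                      error = function(e) NA_character_)
  mv
}

#' Write a mask volume (or parametric map) to NIfTI
#' @param x a `mask_volume` or `parametric_map`.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "mask_volume")) x$labels else x$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parametric map from NIfTI
#' @inheritParams read_mask_volume
#' @param modality `"T2"` or `"T1rho"`.
#' @export
read_parametric_map <- function(path, modality = c("T2", "T1rho")) {
  img <- RNifti::readNifti(path)
  .assert(length(dim(img)) == 3L, "expected a 3D volume, got %dD", length(dim(img)))
  arr <- as.array(img)
  parametric_map(array(as.numeric(arr), dim(arr)), RNifti::pixdim(img)[1:3],
                 match.arg(modality))
}

#' Read a YAML label map
#' @param path YAML file mapping label id to `name` and `tissue`.
#' @export
read_label_map <- function(path) {
  lm <- yaml::read_yaml(path)
  .assert(is.list(lm) && length(lm) > 0, "empty label map")
  for (id in names(lm)) {
    .assert(!is.na(suppressWarnings(as.integer(id))),
            "label map key '%s' is not an integer id", id)
    .assert(all(c("name", "tissue") %in% names(lm[[id]])),
            "label %s needs fields name, tissue", id)
  }
  lm
}

# ---- biomarker tables ------------------------------------------------------

.bm_units <- c("mm", "cm3", "ms", "z")

#' Construct / validate a biomarker table
#'
#' Long-format standardized measurement record with one row per
#' (subject, visit, compartment, biomarker).
#'
#' @param df data.frame with columns subject_id, visit_month, compartment,
#'   biomarker, value, units (one of mm, cm3, ms, z).
#' @export
biomarker_table <- function(df) {
  need <- c("subject_id", "visit_month", "compartment", "biomarker", "value", "units")
  .assert(all(need %in% names(df)), "missing columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[, need]
  .assert(all(df$units %in% .bm_units), "units must be one of %s",
          paste(.bm_units, collapse = ", "))
  key <- do.call(paste, c(df[c("subject_id", "visit_month", "compartment", "biomarker")],
                          sep = "\r"))
  .assert(!anyDuplicated(key), "duplicate (subject, visit, compartment, biomarker) rows")
  un <- tapply(df$units, df$biomarker, function(u) length(unique(u)))
  .assert(all(un == 1L), "inconsistent units for biomarker(s): %s",
          paste(names(un)[un != 1L], collapse = ", "))
  class(df) <- c("biomarker_table", "data.frame")
  df
}

#' Write a biomarker table to CSV at full float precision
#' @param df a [biomarker_table()].
#' @param path output CSV path.
#' @export
write_biomarker_table <- function(df, path) {
  df <- biomarker_table(df)
  out <- as.data.frame(df)
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a biomarker table from CSV
#' @param path CSV path written by [write_biomarker_table()].
#' @export
read_biomarker_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  biomarker_table(df)
}

# ---- run configuration -----------------------------------------------------

.config_defaults <- function() {
  list(
    io = list(cranio_caudal_axis = "row"),
    biomarkers = list(thickness_mode = "full_width", mode_2d = TRUE,
                      min_skeleton_px = 5L, relaxometry_clip = c(0, 100)),
    triage = list(spec_target_a = 0.90, spec_targets_b = c(0.85, 0.90),
                  minutes_per_exam = 2, n_folds = 5L, n_boot = 2000L),
    landmark = list(landmark_month = 48, horizon_months = 48, n_folds = 5L,
                    rf_trees = 400L, rf_min_leaf = 10L, n_boot_auc = 1000L,
                    n_boot_dca = 2000L),
    seeds = list(global = 20240101L, cv = 1L, bootstrap = 2L, learners = 3L)
  )
}

#' Load and validate a run configuration
#'
#' A single YAML file with sections `io`, `biomarkers`, `triage`, `landmark`
#' and `seeds`. Unknown keys (at either level) are rejected with their key
#' path; absent keys take package defaults. Defaulted seeds are reported via
#' a message so runs are auditable.
#'
#' @param path YAML file; `NULL` returns the full default configuration.
#' @return validated configuration list of class `msk_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- .config_defaults()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  .assert(length(unknown) == 0L, "unknown config section: %s", unknown[1])
  out <- defaults
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    .assert(length(bad) == 0L, "unknown config key: %s.%s", sec, bad[1])
    out[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  if (is.null(cfg$seeds) || length(setdiff(names(defaults$seeds),
                                           names(cfg$seeds %||% list()))) > 0) {
    message("seeds defaulted: ",
            paste(sprintf("%s=%d", names(out$seeds), unlist(out$seeds)),
                  collapse = ", "))
  }
  .assert(out$triage$spec_target_a > 0 && out$triage$spec_target_a <= 1,
          "triage.spec_target_a must be in (0, 1]")
  structure(out, class = "msk_config")
}
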