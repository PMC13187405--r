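# Geometric phantoms with analytically known thickness / height / volume.
# Rasterization is by voxel-center inclusion: a voxel belongs to the shape
# iff its center satisfies the implicit-surface inequality. Voxel centers
# along an axis with spacing s sit at (i - 0.5) * s, i = 1..n, and shapes are
# centered on a voxel center, so geometry is exactly reproducible by a
# brute-force center test.

#' Specify a geometric phantom
#'
#' @param shape one of `"slab"` (plate of constant width across the row
#'   axis), `"annulus"` (in-plane ring), `"ellipsoid"`, `"disc_stack"`
#'   (stack of rectangular discs along the row axis).
#' @param spacing voxel spacing `c(sx, sy, sz)` mm.
#' @param label_id integer label for the foreground.
#' @param slab_width,slab_length slab width (the measured thickness) and
#'   in-plane length, mm.
#' @param annulus_inner,annulus_outer annulus radii, mm; thickness truth is
#'   the difference.
#' @param semi_axes ellipsoid semi-axes `c(a, b, c)` mm.
#' @param disc_height,disc_width,disc_count,disc_gap disc-stack geometry, mm
#'   (count is an integer).
#' @param n_slices number of slices for the slice-wise shapes.
#' @param seed integer; recorded for provenance (rasterization itself is
#'   deterministic).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("slab", "annulus", "ellipsoid", "disc_stack"),
                         spacing = c(0.5, 0.5, 0.5), label_id = 1L,
                         slab_width = 10.5, slab_length = 20,
                         annulus_inner = 12, annulus_outer = 15,
                         semi_axes = c(10, 10, 10),
                         disc_height = 12, disc_width = 30, disc_count = 3L,
                         disc_gap = 6, n_slices = 3L, seed = 1L) {
  shape <- match.arg(shape)
  geom <- switch(shape,
    slab = c(slab_width, slab_length),
    annulus = c(annulus_inner, annulus_outer, annulus_outer - annulus_inner),
    ellipsoid = semi_axes,
    disc_stack = c(disc_height, disc_width, disc_count, disc_gap))
  .assert(all(geom > 0), "all geometry parameters must be strictly positive")
  .assert(all(spacing > 0), "spacing must be strictly positive")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 label_id = as.integer(label_id),
                 slab_width = slab_width, slab_length = slab_length,
                 annulus_inner = annulus_inner, annulus_outer = annulus_outer,
                 semi_axes = semi_axes, disc_height = disc_height,
                 disc_width = disc_width, disc_count = as.integer(disc_count),
                 disc_gap = disc_gap, n_slices = as.integer(n_slices),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-center coordinates for n voxels at spacing s
.centers <- function(n, s) (seq_len(n) - 0.5) * s
# coordinate of the central voxel's center
.cmid <- function(n, s) (ceiling(n / 2) - 0.5) * s

#' Rasterize a phantom and return its analytic ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list of class `msk_phantom` with elements `mask` (a
#'   [mask_volume()]) and `truth` (analytic thickness mm / heights mm /
#'   volume cm^3 as applicable).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sx <- spec$spacing[1]; sy <- spec$spacing[2]; sz <- spec$spacing[3]
  lab <- spec$label_id
  small <- switch(spec$shape,
    slab = spec$slab_width < sx,
    annulus = (spec$annulus_outer - spec$annulus_inner) < min(sx, sy),
    ellipsoid = any(2 * spec$semi_axes < spec$spacing),
    disc_stack = spec$disc_height < sx || spec$disc_width < sy)
  .assert(!small, "degenerate phantom: geometry smaller than one voxel")

  if (spec$shape == "slab") {
    nr <- 2L * floor(spec$slab_width / (2 * sx)) + 1L + 8L
    nc <- max(4L, round(spec$slab_length / sy))
    ns <- spec$n_slices
    x <- .centers(nr, sx); c0 <- .cmid(nr, sx)
    rows <- abs(x - c0) <= spec$slab_width / 2
    arr <- array(0L, c(nr, nc, ns))
    arr[rows, , ] <- lab
    truth <- list(thickness_mm = spec$slab_width,
                  n_across = sum(rows))
  } else if (spec$shape == "annulus") {
    ro <- spec$annulus_outer
    nr <- 2L * ceiling(ro / sx) + 9L
    nc <- 2L * ceiling(ro / sy) + 9L
    ns <- spec$n_slices
    x <- .centers(nr, sx) - .cmid(nr, sx)
    y <- .centers(nc, sy) - .cmid(nc, sy)
    rho <- sqrt(outer(x^2, y^2, `+`))
    sl <- (rho >= spec$annulus_inner & rho <= ro) * lab
    arr <- array(rep(as.integer(sl), ns), c(nr, nc, ns))
    truth <- list(thickness_mm = ro - spec$annulus_inner)
  } else if (spec$shape == "ellipsoid") {
    a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cc <- spec$semi_axes[3]
    nr <- 2L * ceiling(a / sx) + 5L
    nc <- 2L * ceiling(b / sy) + 5L
    ns <- 2L * ceiling(cc / sz) + 5L
    x <- (.centers(nr, sx) - .cmid(nr, sx)) / a
    y <- (.centers(nc, sy) - .cmid(nc, sy)) / b
    z <- (.centers(ns, sz) - .cmid(ns, sz)) / cc
    q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
    arr <- array(as.integer(q <= 1) * lab, c(nr, nc, ns))
    truth <- list(volume_cm3 = 4 / 3 * pi * a * b * cc / 1000)
  } else { # disc_stack
    h <- spec$disc_height; wd <- spec$disc_width
    k <- spec$disc_count; gap <- spec$disc_gap
    # discs occupy half-open row intervals [start, start + h) anchored on
    # voxel boundaries so commensurate heights rasterize exactly
    margin <- 3L
    starts <- margin * sx + (seq_len(k) - 1L) * (h + gap)
    nr <- ceiling((max(starts) + h) / sx) + margin
    nc <- round(wd / sy) + 2L * margin
    ns <- spec$n_slices
    x <- .centers(nr, sx)
    y <- .centers(nc, sy)
    c0 <- margin * sy
    cols <- y >= c0 & y < c0 + wd
    sl <- matrix(0L, nr, nc)
    for (s0 in starts) sl[x >= s0 & x < s0 + h, cols] <- lab
    arr <- array(rep(sl, ns), c(nr, nc, ns))
    truth <- list(heights_mm = rep(h, k), n_levels = k)
  }

  lm <- stats::setNames(list(list(name = spec$shape, tissue = "phantom")),
                        as.character(lab))
  structure(list(mask = mask_volume(arr, spec$spacing, lm),
                 truth = truth, spec = spec),
            class = "msk_phantom")
}

#' @export
print.msk_phantom <- function(x, ...) {
  cat(sprintf("<msk_phantom> %s\n", x$spec$shape))
  print(x$mask)
  cat("truth:", paste(names(x$truth),
                      vapply(x$truth, function(v) paste(signif(v, 6), collapse = ","),
                             character(1)),
                      sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Write a phantom as NIfTI plus a JSON ground-truth sidecar
#' @param phantom a [make_phantom()] result.
#' @param dir output directory.
#' @param stem file stem, defaults to the shape name.
#' @export
write_phantom <- function(phantom, dir, stem = phantom$spec$shape) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$mask, file.path(dir, paste0(stem, ".nii.gz")))
  jsonlite::write_json(phantom$truth, file.path(dir, paste0(stem, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  lm <- phantom$mask$label_map
  yaml::write_yaml(lm, file.path(dir, paste0(stem, "_labels.yaml")))
  invisible(dir)
}
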