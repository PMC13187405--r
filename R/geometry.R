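# Geometric primitives for slice-wise mask measurement: an anisotropic exact
# Euclidean distance transform, Zhang-Suen thinning, and connectivity-
# controlled connected-component labelling. These back the medial-axis
# thickness pipeline and the mask refinement operators.
#
# Boundary convention: the array edge is NOT an object boundary. The distance
# transform measures distance to in-array background only, and thinning
# replicates edge pixels, so structures clipped by the field of view are
# measured as if they continued beyond it.

# 1D squared-distance lower-envelope pass (Felzenszwalb & Huttenlocher).
# f: squared distances at grid positions i*s; returns the envelope minimum
# min_q ((i-q)^2 s^2 + f[q]) for every i.
.edt1d_sq <- function(f, s) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  s2 <- s * s
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  if (length(fin) > 1L) {
    for (q in fin[-1L]) {
      repeat {
        p <- v[k]
        sx <- ((f[q] + q * q * s2) - (f[p] + p * p * s2)) / (2 * s2 * (q - p))
        if (sx <= z[k]) { k <- k - 1L } else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- sx
      z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  j <- 1L
  for (i in seq_len(n)) {
    while (z[j + 1L] < i) j <- j + 1L
    d[i] <- (i - v[j])^2 * s2 + f[v[j]]
  }
  d
}

# Exact Euclidean distance transform of a logical 2D mask with per-axis
# spacing (sx along rows, sy along columns), in mm. Background pixels get 0.
edt2d <- function(m, sx = 1, sy = 1) {
  nr <- nrow(m); nc <- ncol(m)
  d <- matrix(Inf, nr, nc)
  d[!m] <- 0
  if (nr > 1L) {
    for (i in 2:nr) d[i, ] <- pmin(d[i, ], d[i - 1L, ] + sx)
    for (i in (nr - 1L):1L) d[i, ] <- pmin(d[i, ], d[i + 1L, ] + sx)
  }
  d2 <- d * d
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) out[i, ] <- .edt1d_sq(d2[i, ], sy)
  sqrt(out)
}

# Count of 0->1 transitions around the 8-neighbourhood, and neighbour sum,
# for Zhang-Suen. `pads` is the padded logical matrix, `core` the index grid.
.zs_neighbours <- function(pad) {
  nr <- nrow(pad); nc <- ncol(pad)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  list(
    p2 = pad[ri - 1L, ci], p3 = pad[ri - 1L, ci + 1L],
    p4 = pad[ri, ci + 1L], p5 = pad[ri + 1L, ci + 1L],
    p6 = pad[ri + 1L, ci], p7 = pad[ri + 1L, ci - 1L],
    p8 = pad[ri, ci - 1L], p9 = pad[ri - 1L, ci - 1L]
  )
}

# Zhang-Suen thinning of a logical 2D mask to a one-pixel-wide skeleton.
# Edge pixels are replicated when padding (see boundary convention above).
thin2d <- function(m) {
  m <- m != 0
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      pad <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
      nb <- .zs_neighbours(pad)
      bsum <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      a <- matrix(0L, nr, nc)
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1L]])
      if (pass == 1L) {
        c1 <- !(nb$p2 & nb$p4 & nb$p6)
        c2 <- !(nb$p4 & nb$p6 & nb$p8)
      } else {
        c1 <- !(nb$p2 & nb$p4 & nb$p8)
        c2 <- !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- m & bsum >= 2 & bsum <= 6 & a == 1L & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Connected-component labelling of a logical 2D or 3D array by breadth-first
# flood fill. connectivity: 4 or 8 (2D), 6 or 26 (3D). Returns an integer
# array of component labels (0 = background).
label_components <- function(m, connectivity = NULL) {
  d <- dim(m)
  nd <- length(d)
  .assert(nd %in% c(2L, 3L), "mask must be 2D or 3D")
  if (nd == 2L) {
    connectivity <- connectivity %||% 8L
    .assert(connectivity %in% c(4L, 8L), "2D connectivity must be 4 or 8")
    offs <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    if (connectivity == 8L)
      offs <- rbind(offs, c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
    d <- c(d, 1L)
    m <- array(m, d)
    offs <- cbind(offs, 0L)
  } else {
    connectivity <- connectivity %||% 26L
    .assert(connectivity %in% c(6L, 26L), "3D connectivity must be 6 or 26")
    if (connectivity == 6L) {
      offs <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                    c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
    } else {
      offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
      storage.mode(offs) <- "integer"
    }
  }
  lab <- array(0L, d)
  fg <- which(m != 0)
  if (length(fg) == 0L) {
    return(if (nd == 2L) array(lab, d[1:2]) else lab)
  }
  nxny <- d[1L] * d[2L]
  cur <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      idx <- queue
      queue <- integer(0)
      i0 <- ((idx - 1L) %% d[1L]) + 1L
      j0 <- (((idx - 1L) %/% d[1L]) %% d[2L]) + 1L
      k0 <- ((idx - 1L) %/% nxny) + 1L
      for (r in seq_len(nrow(offs))) {
        i <- i0 + offs[r, 1L]; j <- j0 + offs[r, 2L]; k <- k0 + offs[r, 3L]
        ok <- i >= 1L & i <= d[1L] & j >= 1L & j <= d[2L] & k >= 1L & k <= d[3L]
        if (!any(ok)) next
        nidx <- (k[ok] - 1L) * nxny + (j[ok] - 1L) * d[1L] + i[ok]
        nidx <- nidx[m[nidx] != 0 & lab[nidx] == 0L]
        if (length(nidx) > 0L) {
          lab[nidx] <- cur
          queue <- c(queue, nidx)
        }
      }
      queue <- unique(queue)
    }
  }
  if (nd == 2L) array(lab, d[1:2]) else lab
}

# Binary dilation/erosion by a flat disc (2D) or ball (3D) of the given
# pixel radius, implemented by shifting. The disc is taken in the Chebyshev
# metric (radius 1 = the full 3x3/3x3x3 neighbourhood) so that a radius-1
# closing bridges single-pixel diagonal gaps. Outside-of-array counts as
# background for dilation and as foreground for erosion (the array edge is
# not an object boundary).
.ball_offsets <- function(radius, nd) {
  r <- as.integer(radius)
  if (r == 0L) return(matrix(0L, 1L, nd))
  rng <- -r:r
  g <- if (nd == 2L) expand.grid(rng, rng) else expand.grid(rng, rng, rng)
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  g
}

.shift_arr <- function(m, off, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    o <- off[ax]
    if (o >= 0) {
      dst[[ax]] <- seq_len(d[ax] - o) + o
      src[[ax]] <- seq_len(d[ax] - o)
    } else {
      dst[[ax]] <- seq_len(d[ax] + o)
      src[[ax]] <- seq_len(d[ax] + o) - o
    }
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

morph_op <- function(m, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(m)
  nd <- length(d)
  m <- m != 0
  if (radius == 0L) return(m)
  offs <- .ball_offsets(radius, nd)
  if (nd == 2L) {
    dim(m) <- c(d, 1L)
    offs <- cbind(offs, 0L)
  }
  acc <- NULL
  for (r in seq_len(nrow(offs))) {
    sh <- .shift_arr(m, offs[r, ], fill = (op == "erode"))
    acc <- if (is.null(acc)) sh else if (op == "dilate") acc | sh else acc & sh
  }
  if (nd == 2L) dim(acc) <- d
  acc
}

morph_close <- function(m, radius) {
  if (radius == 0L) return(m != 0)
  morph_op(morph_op(m, radius, "dilate"), radius, "erode")
}
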