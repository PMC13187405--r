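# Independent brute-force oracles used across the suite.

# O(n^2) Euclidean distance transform by exhaustive search over background
# voxel centers, with anisotropic spacing.
brute_edt2d <- function(m, sx, sy) {
  bg <- which(!m, arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  if (nrow(bg) == 0L) {
    out[] <- Inf
    return(out)
  }
  fg <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    di <- (fg[r, 1] - bg[, 1]) * sx
    dj <- (fg[r, 2] - bg[, 2]) * sy
    out[fg[r, 1], fg[r, 2]] <- sqrt(min(di * di + dj * dj))
  }
  out
}

# set-arithmetic Dice/Jaccard from voxel index sets
brute_overlap <- function(a, b) {
  ia <- which(a != 0)
  ib <- which(b != 0)
  ni <- length(intersect(ia, ib))
  list(dice = if (length(ia) + length(ib) == 0) 1 else
         2 * ni / (length(ia) + length(ib)),
       jaccard = if (length(ia) + length(ib) == 0) 1 else
         ni / length(union(ia, ib)))
}

# Harrell's C by exhaustive pair enumeration (ties in score = 0.5)
brute_cindex <- function(time, status, score) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    # comparable if the earlier time is an event
    if (ti < tj && status[i] == 1 || tj < ti && status[j] == 1) {
      den <- den + 1
      early_hi <- if (ti < tj) score[i] > score[j] else score[j] > score[i]
      if (early_hi) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  num / den
}

# linear-interpolation percentile between order statistics (independent of
# stats::quantile)
brute_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# a risk_predictions object from bare vectors (for metric tests)
make_rp <- function(p_raw, outcome, p_cal = p_raw,
                    time = NULL, event = NULL) {
  n <- length(p_raw)
  out <- data.frame(knee_id = sprintf("K%04d", seq_len(n)),
                    participant_id = sprintf("P%04d", seq_len(n)),
                    fold = rep_len(1:5, n),
                    p_raw = p_raw, p_cal = p_cal, outcome = outcome,
                    time_since_landmark = time %||% rep(1, n),
                    event_in_window = event %||% outcome)
  attr(out, "model") <- "manual"
  attr(out, "task") <- "tkr"
  class(out) <- c("risk_predictions", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_blob <- function(nr = 24, nc = 24, p = 0.45) {
  m <- matrix(stats::runif(nr * nc) < p, nr, nc)
  m
}
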