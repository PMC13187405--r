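`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form of the AUC: the probability that a randomly chosen
#' positive receives a higher score than a randomly chosen negative, with
#' ties counted one half.
#'
#' @param p numeric scores (higher = more positive).
#' @param y binary labels (0/1 or logical).
#' @return AUC in \[0, 1\]; `NA` if either class is absent.
#' @export
auc_rank <- function(p, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Assign groups to k folds, balancing member counts. Returns an integer fold
# id per observation; all observations of a group share a fold.
grouped_kfold <- function(groups, k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.character(groups)
  ug <- unique(g)
  .assert(length(ug) >= k, "need at least %d groups for %d folds", k, k)
  sizes <- table(g)[ug]
  ord <- sample(seq_along(ug))
  ug <- ug[ord]
  sizes <- as.integer(sizes[ord])
  # largest groups first, greedy to the lightest fold
  o <- order(-sizes)
  fold_of <- integer(length(ug))
  names(fold_of) <- ug
  load <- numeric(k)
  for (i in o) {
    f <- which.min(load)
    fold_of[ug[i]] <- f
    load[f] <- load[f] + sizes[i]
  }
  unname(fold_of[g])
}

# Grouped k-fold additionally balancing a binary outcome across folds: groups
# are stratified by their event status (any member positive) before greedy
# assignment, so each fold receives its share of event-carrying groups.
stratified_grouped_kfold <- function(groups, y, k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.character(groups)
  y <- as.integer(y)
  ug <- unique(g)
  .assert(length(ug) >= k, "need at least %d groups for %d folds", k, k)
  gy <- vapply(split(y, g)[ug], function(v) as.integer(any(v == 1L)), integer(1))
  fold_of <- integer(length(ug))
  names(fold_of) <- ug
  for (s in unique(gy)) {
    idx <- which(gy == s)
    idx <- idx[sample(length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  unname(fold_of[g])
}

# Class-balanced observation weights: n / (n_classes * n_class), the
# "balanced" convention.
balanced_weights <- function(y) {
  y <- as.integer(y)
  n <- length(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  w <- n / (2 * as.numeric(tab))
  ifelse(y == 1L, w[2], w[1])
}

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Draw sub-seeds from a master seed without consuming the caller's RNG
# stream more than once; keeps every derived seed inside 32-bit range.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
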