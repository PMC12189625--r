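#' Replicate 70/30 presence splits
#'
#' Uniform random split without replacement; the training set holds
#' `round(fraction * n)` presences.
#'
#' @param n number of presence records (>= 5).
#' @param fraction training fraction (default 0.7).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_presences <- function(n, fraction = 0.7, seed = 1L) {
  if (n < 5) stop("insufficient data: need at least 5 presences to split",
                  call. = FALSE)
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split fraction leaves an empty train or test set", call. = FALSE)
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' ROC AUC for presence vs background scores
#'
#' The Mann-Whitney form: the probability that a random presence outscores
#' a random background point, ties counted one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param presence,background numeric score vectors (each non-empty).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(presence, background) {
  if (length(presence) == 0 || length(background) == 0)
    stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(presence, background))
  m <- length(presence)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(background))
}

#' True skill statistic (max over thresholds)
#'
#' Background points are treated as absences. For every candidate threshold
#' (the distinct observed scores) compute sensitivity + specificity - 1,
#' with a point predicted present when its score >= threshold; return the
#' maximum.
#'
#' @inheritParams roc_auc
#' @return TSS in \[-1, 1\].
#' @export
tss <- function(presence, background) {
  if (length(presence) == 0 || length(background) == 0)
    stop("both score vectors must be non-empty", call. = FALSE)
  th <- sort(unique(c(presence, background)))
  best <- -1
  for (t in th) {
    sens <- mean(presence >= t)
    spec <- mean(background < t)
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Run replicate 70/30 fits and evaluate them
#'
#' For each replicate `i` (seeded `base_seed + i`), split the presences,
#' fit a MaxEnt model on the training rows against the full background,
#' and score test AUC / TSS with the background as pseudo-absence.
#'
#' @param presence,background design matrices (rows x variables).
#' @param beta_multiplier regularization multiplier for every replicate.
#' @param reps number of replicates.
#' @param base_seed seeds are `base_seed + 1 .. base_seed + reps`.
#' @param contributions also compute per-variable permutation
#'   contributions for each replicate (slower).
#' @param ... passed to [train_maxent()].
#' @return list with `results` (data.frame: replicate, seed, auc, tss),
#'   `models` (list of fitted models), `splits`, and `contributions`
#'   (matrix reps x variables or NULL).
#' @export
replicate_fits <- function(presence, background, beta_multiplier = 1,
                           reps = 10, base_seed = 0L,
                           contributions = FALSE, ...) {
  n <- nrow(presence)
  models <- vector("list", reps)
  splits <- vector("list", reps)
  contrib <- NULL
  res <- data.frame(replicate = seq_len(reps),
                    seed = base_seed + seq_len(reps),
                    auc = NA_real_, tss = NA_real_)
  for (i in seq_len(reps)) {
    sp <- split_presences(n, seed = base_seed + i)
    model <- train_maxent(presence[sp$train, , drop = FALSE], background,
                          beta_multiplier = beta_multiplier, ...)
    # clamping to the background range is routine for held-out presences
    s_test <- suppressWarnings(
      predict(model, presence[sp$test, , drop = FALSE], type = "logistic"))
    s_bg <- predict(model, background, type = "logistic")
    res$auc[i] <- roc_auc(s_test, s_bg)
    res$tss[i] <- tss(s_test, s_bg)
    models[[i]] <- model; splits[[i]] <- sp
    if (contributions) {
      ci <- variable_contribution(model, presence[sp$train, , drop = FALSE],
                                  background, seed = base_seed + i)
      if (is.null(contrib)) contrib <- matrix(NA_real_, reps, length(ci),
                                              dimnames = list(NULL, names(ci)))
      contrib[i, ] <- ci
    }
  }
  list(results = res, models = models, splits = splits,
       contributions = contrib)
}

#' Aggregate replicate AUC/TSS results
#'
#' @param results data.frame with columns `auc` and `tss` (>= 2 rows).
#' @return list with means, sample standard deviations (n - 1 denominator)
#'   and `"mean ± sd"` strings formatted to 4 decimals.
#' @export
aggregate_replicates <- function(results) {
  stopifnot(nrow(results) >= 2)
  fmt <- function(m, s) sprintf("%.4f ± %.4f", m, s)
  out <- list(auc_mean = mean(results$auc), auc_sd = stats::sd(results$auc),
              tss_mean = mean(results$tss), tss_sd = stats::sd(results$tss))
  out$auc <- fmt(out$auc_mean, out$auc_sd)
  out$tss <- fmt(out$tss_mean, out$tss_sd)
  out
}
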