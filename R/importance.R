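#' Permutation-based percent contribution of each variable
#'
#' The native MaxEnt "percent contribution" depends on the training path of
#' a particular implementation and is not reproducible outside it; this
#' package uses the standard permutation surrogate instead: for each
#' variable, its values are permuted jointly across the combined
#' presence + background rows, the model is re-applied, and the drop in
#' training AUC is averaged over `n_permutations` seeded permutations.
#' Drops are floored at 0 and normalized to percentages summing to 100.
#'
#' @param model a fitted `maxent_model` carrying feature definitions.
#' @param presence,background design matrices (rows x variables).
#' @param n_permutations permutations per variable.
#' @param seed RNG seed.
#' @return Named numeric vector of percentages (sums to 100).
#' @export
variable_contribution <- function(model, presence, background,
                                  n_permutations = 10, seed = 1L) {
  if (!isTRUE(model$fitted)) stop("model is not fitted", call. = FALSE)
  fd <- model$feature_defs
  if (is.null(fd))
    stop("variable_contribution needs a model with feature definitions",
         call. = FALSE)
  vars <- fd$vars
  if (length(vars) == 1L) return(stats::setNames(100, vars))
  presence <- as.matrix(presence)[, vars, drop = FALSE]
  background <- as.matrix(background)[, vars, drop = FALSE]
  m <- nrow(presence)
  score <- function(pres, bg) {
    s <- predict(model, rbind(pres, bg), type = "raw")
    roc_auc(s[seq_len(m)], s[-seq_len(m)])
  }
  base <- suppressWarnings(score(presence, background))
  set.seed(seed)
  drops <- vapply(vars, function(v) {
    d <- numeric(n_permutations)
    for (t in seq_len(n_permutations)) {
      comb <- c(presence[, v], background[, v])
      comb <- comb[sample.int(length(comb))]
      pres_p <- presence; bg_p <- background
      pres_p[, v] <- comb[seq_len(m)]
      bg_p[, v] <- comb[-seq_len(m)]
      d[t] <- base - suppressWarnings(score(pres_p, bg_p))
    }
    mean(d)
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) drops <- rep(1, length(vars))
  stats::setNames(100 * drops / sum(drops), vars)
}

#' Marginal response curve of a variable
#'
#' Sweeps one variable across its background range while holding the other
#' variables at their background means, and returns the model's logistic
#' output along the sweep. A null (constant) model gives a flat curve at
#' 0.5.
#'
#' @param model a fitted `maxent_model` trained via [train_maxent()].
#' @param variable variable name to sweep.
#' @param n_points number of evenly spaced sweep points (>= 2).
#' @return data.frame with columns `value` and `hsi`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  fd <- model$feature_defs
  if (is.null(fd))
    stop("response_curve needs a model with feature definitions", call. = FALSE)
  if (!variable %in% fd$vars)
    stop("unknown variable '", variable, "'", call. = FALSE)
  if (is.null(model$bg_means))
    stop("model does not store background means", call. = FALSE)
  stopifnot(n_points >= 2)
  sweep_vals <- seq(fd$lo[[variable]], fd$hi[[variable]], length.out = n_points)
  design <- matrix(rep(model$bg_means[fd$vars], each = n_points),
                   nrow = n_points, dimnames = list(NULL, fd$vars))
  design[, variable] <- sweep_vals
  data.frame(value = sweep_vals,
             hsi = predict(model, design, type = "logistic"))
}
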