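#' MaxEnt feature expansion
#'
#' Variables are first rescaled to \[0, 1\] using their min/max over the
#' background sample; features are then built on the scaled value `x`:
#'
#' * `linear`: `x`
#' * `quadratic`: `x^2`
#' * `hinge`: for each of `n_hinge_knots` equally spaced interior knots `k`,
#'   a forward hinge `max(0, (x - k) / (1 - k))` and a reverse hinge
#'   `max(0, (k - x) / k)`.
#'
#' All features lie in \[0, 1\] on the background. Variables that are
#' constant over the background carry no information and are dropped with a
#' warning.
#'
#' @param background design matrix (background rows x variables) used for
#'   standardization.
#' @param kinds subset of `c("linear", "quadratic", "hinge")`.
#' @param n_hinge_knots number of hinge knot pairs per variable.
#' @return A `feature_defs` object: per-feature kind, source variable, knot
#'   and the per-variable scaling range.
#' @export
make_feature_defs <- function(background, kinds = c("linear", "quadratic", "hinge"),
                              n_hinge_knots = 5) {
  kinds <- match.arg(kinds, c("linear", "quadratic", "hinge"), several.ok = TRUE)
  stopifnot(is.matrix(background), ncol(background) >= 1)
  vars <- colnames(background)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(background)))
  lo <- apply(background, 2, min)
  hi <- apply(background, 2, max)
  const <- hi - lo <= 0
  if (any(const))
    warning("constant variable(s) dropped from feature expansion: ",
            paste(vars[const], collapse = ", "), call. = FALSE)
  defs <- list()
  knots <- if (n_hinge_knots > 0) seq_len(n_hinge_knots) / (n_hinge_knots + 1) else numeric(0)
  for (i in which(!const)) {
    v <- vars[i]
    if ("linear" %in% kinds)
      defs[[length(defs) + 1L]] <- list(kind = "linear", var = v, knot = NA_real_)
    if ("quadratic" %in% kinds)
      defs[[length(defs) + 1L]] <- list(kind = "quadratic", var = v, knot = NA_real_)
    if ("hinge" %in% kinds)
      for (k in knots) {
        defs[[length(defs) + 1L]] <- list(kind = "hinge_fwd", var = v, knot = k)
        defs[[length(defs) + 1L]] <- list(kind = "hinge_rev", var = v, knot = k)
      }
  }
  structure(list(defs = defs, vars = vars[!const],
                 lo = lo[!const], hi = hi[!const]),
            class = "feature_defs")
}

#' @rdname make_feature_defs
#' @param fd a `feature_defs` object.
#' @param design matrix of raw variable values (rows x variables); values
#'   beyond the background range are clamped to it.
#' @param warn_clamp warn when clamping occurs (used by prediction on novel
#'   layers).
#' @return `expand_features()` returns the feature matrix (rows x features).
#' @export
expand_features <- function(fd, design, warn_clamp = FALSE) {
  stopifnot(inherits(fd, "feature_defs"))
  missing <- setdiff(fd$vars, colnames(design))
  if (length(missing))
    stop("design is missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  scaled <- matrix(NA_real_, nrow(design), length(fd$vars),
                   dimnames = list(NULL, fd$vars))
  for (v in fd$vars)
    scaled[, v] <- (design[, v] - fd$lo[[v]]) / (fd$hi[[v]] - fd$lo[[v]])
  if (warn_clamp && (any(scaled < -1e-9) || any(scaled > 1 + 1e-9)))
    warning("values outside the background range clamped for prediction",
            call. = FALSE)
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  out <- matrix(0, nrow(design), length(fd$defs))
  nm <- character(length(fd$defs))
  for (j in seq_along(fd$defs)) {
    d <- fd$defs[[j]]
    x <- scaled[, d$var]
    out[, j] <- switch(d$kind,
      linear    = x,
      quadratic = x^2,
      hinge_fwd = pmax(0, (x - d$knot) / (1 - d$knot)),
      hinge_rev = pmax(0, (d$knot - x) / d$knot))
    nm[j] <- if (d$kind %in% c("linear", "quadratic")) paste(d$kind, d$var, sep = ".")
             else sprintf("%s.%s.%.3f", d$kind, d$var, d$knot)
  }
  colnames(out) <- nm
  out
}

# kind -> regularization class constant (hinge features are penalized less,
# mirroring the published MaxEnt default structure)
feature_class_const <- function(fd) {
  vapply(fd$defs, function(d)
    if (startsWith(d$kind, "hinge")) 0.5 else 1.0, numeric(1))
}

# source variable of each feature column
feature_source_var <- function(fd) {
  vapply(fd$defs, function(d) d$var, character(1))
}
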