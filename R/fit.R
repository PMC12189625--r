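#' Fit a MaxEnt presence-background model on feature matrices
#'
#' Minimizes the L1-penalized convex MaxEnt objective
#' \deqn{-\frac1m \sum_{i \in pres} \lambda' f(x_i) + \log Z(\lambda)
#'       + \sum_j \beta_j |\lambda_j|,}
#' where \eqn{Z(\lambda) = \sum_{bg} \exp(\lambda' f(x))} sums over the
#' background cells, so the fitted raw scores
#' \eqn{\exp(\lambda' f(x)) / Z} form a Gibbs distribution over the
#' background. Per-feature penalties are
#' \eqn{\beta_j = \beta \cdot c_j \cdot s_j / \sqrt m} with \eqn{\beta} the
#' beta multiplier, \eqn{c_j} the feature-class constant (1 for
#' linear/quadratic, 0.5 for hinge), \eqn{s_j} the feature's sample sd over
#' the presences floored at 0.01, and \eqn{m} the presence count.
#'
#' Optimization uses a monotone accelerated proximal-gradient method with
#' backtracking (soft-thresholding prox), so the objective is
#' non-increasing across iterations and the fit is deterministic.
#'
#' @param presence feature matrix of presence rows (m x p).
#' @param background feature matrix of background rows (n x p).
#' @param beta_multiplier global regularization multiplier (>= 0).
#' @param tol KKT residual tolerance declaring convergence.
#' @param max_iter iteration cap; exceeding it raises a convergence error
#'   carrying the final residual.
#' @param class_const optional per-feature class constants `c_j` (default
#'   all 1; [train_maxent()] supplies 0.5 for hinge features).
#' @param penalties optional explicit per-feature penalties overriding the
#'   default formula.
#' @return A `maxent_model` with weights, penalties, `logZ`, background
#'   entropy `H` (nats), the objective trace and convergence diagnostics.
#' @seealso [train_maxent()] for the design-matrix interface with feature
#'   expansion, [predict.maxent_model()] for the output transforms.
#' @export
fit_maxent <- function(presence, background, beta_multiplier = 1,
                       tol = 1e-6, max_iter = 10000L,
                       class_const = NULL, penalties = NULL) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  m <- nrow(presence); n <- nrow(background); p <- ncol(presence)
  if (m < 5) stop("need at least 5 presence rows", call. = FALSE)
  if (n < m) stop("background must have at least as many rows as presence",
                  call. = FALSE)
  if (ncol(background) != p) stop("feature dimension mismatch", call. = FALSE)
  if (beta_multiplier < 0) stop("beta_multiplier must be >= 0", call. = FALSE)
  if (is.null(class_const)) class_const <- rep(1, p)
  if (is.null(penalties)) {
    sdj <- pmax(apply(presence, 2, stats::sd), 0.01)
    penalties <- beta_multiplier * class_const * sdj / sqrt(m)
  }
  fbar <- colMeans(presence)

  smooth_val <- function(lam) {
    eta <- drop(background %*% lam)
    mx <- max(eta)
    -sum(fbar * lam) + mx + log(sum(exp(eta - mx)))
  }
  smooth_grad <- function(lam) {
    eta <- drop(background %*% lam)
    w <- exp(eta - max(eta)); pr <- w / sum(w)
    list(g = drop(crossprod(background, pr)) - fbar, pr = pr)
  }
  obj <- function(lam) smooth_val(lam) + sum(penalties * abs(lam))
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  kkt_resid <- function(lam, g) {
    r <- ifelse(lam != 0, abs(g + penalties * sign(lam)),
                pmax(abs(g) - penalties, 0))
    max(r)
  }

  # Orthant-wise proximal Newton on a working set: Newton steps use the
  # exact Hessian of log Z restricted to the active coordinates, with an
  # orthant-projected backtracking line search on the full penalized
  # objective (so the objective is non-increasing across iterations) and a
  # proximal-gradient fallback when the Newton direction stalls.
  pseudo_grad <- function(lam, g) {
    pg <- numeric(length(lam))
    pos <- lam > 0 | (lam == 0 & g + penalties < 0)
    neg <- lam < 0 | (lam == 0 & g - penalties > 0)
    pg[pos] <- g[pos] + penalties[pos]
    pg[neg] <- g[neg] - penalties[neg]
    pg
  }
  x <- numeric(p)
  Fx <- obj(x)
  trace <- Fx
  kkt <- Inf
  L <- 1
  for (it in seq_len(max_iter)) {
    gr <- smooth_grad(x)
    kkt <- kkt_resid(x, gr$g)
    if (kkt <= tol) break
    pg <- pseudo_grad(x, gr$g)
    act <- which(x != 0 | pg != 0)
    step_done <- FALSE
    if (length(act)) {
      Ba <- background[, act, drop = FALSE]
      mu <- drop(crossprod(Ba, gr$pr))
      Hw <- crossprod(Ba * sqrt(gr$pr)) - tcrossprod(mu)
      diag(Hw) <- diag(Hw) + 1e-9 * max(diag(Hw), 1)
      d <- tryCatch(-solve(Hw, pg[act]), error = function(e) NULL)
      if (!is.null(d) && sum(d * pg[act]) < 0) {
        orth <- ifelse(x[act] != 0, sign(x[act]), -sign(pg[act]))
        t_ls <- 1
        for (ls in 1:40) {
          x_new <- x
          x_new[act] <- x[act] + t_ls * d
          flip <- sign(x_new[act]) != orth & x_new[act] != 0
          x_new[act][flip] <- 0
          F_new <- obj(x_new)
          if (F_new <= Fx - 1e-12 * abs(Fx) - 1e-14) {
            x <- x_new; Fx <- F_new; step_done <- TRUE; break
          }
          t_ls <- t_ls / 2
        }
      }
    }
    if (!step_done) {
      # proximal-gradient fallback with backtracking
      fy <- -sum(fbar * x) + {
        eta <- drop(background %*% x); mx <- max(eta)
        mx + log(sum(exp(eta - mx)))
      }
      repeat {
        z <- soft(x - gr$g / L, penalties / L)
        dz <- z - x
        if (smooth_val(z) <= fy + sum(gr$g * dz) + L / 2 * sum(dz^2) + 1e-12)
          break
        L <- L * 2
      }
      Fz <- obj(z)
      if (Fz <= Fx) { x <- z; Fx <- Fz }
      L <- max(L * 0.9, 1e-4)
    }
    trace <- c(trace, Fx)
  }
  if (kkt > tol) {
    cond <- structure(
      class = c("sdm_convergence_error", "error", "condition"),
      list(message = sprintf(
        "MaxEnt fit did not converge in %d iterations (KKT residual %.3g > tol %.3g)",
        max_iter, kkt, tol), call = sys.call(-1), residual = kkt))
    stop(cond)
  }
  eta <- drop(background %*% x)
  mx <- max(eta)
  logZ <- mx + log(sum(exp(eta - mx)))
  pr <- exp(eta - logZ)
  # H = logZ - E[eta]; exact (no round-off) for the all-zero-weight model
  H <- logZ - sum(pr * eta)
  structure(list(weights = x, penalties = penalties,
                 beta_multiplier = beta_multiplier,
                 logZ = logZ, entropy = H, n_background = n, n_presence = m,
                 feature_names = colnames(presence),
                 obj_trace = trace, kkt = kkt, iterations = it,
                 feature_defs = NULL, fitted = TRUE),
            class = "maxent_model")
}

#' Fit a MaxEnt model from design matrices
#'
#' Convenience wrapper: builds [make_feature_defs()] on the background
#' design, expands presence and background features and calls
#' [fit_maxent()] with hinge features penalized at half weight. The
#' returned model can then predict directly from an [env_stack()].
#'
#' @inheritParams fit_maxent
#' @param presence,background design matrices (rows x named variables).
#' @param kinds,n_hinge_knots passed to [make_feature_defs()].
#' @return A fitted `maxent_model` carrying its feature definitions.
#' @export
train_maxent <- function(presence, background, beta_multiplier = 1,
                         kinds = c("linear", "quadratic", "hinge"),
                         n_hinge_knots = 5, tol = 1e-6, max_iter = 10000L) {
  fd <- make_feature_defs(background, kinds = kinds,
                          n_hinge_knots = n_hinge_knots)
  fp <- expand_features(fd, presence)
  fb <- expand_features(fd, background)
  model <- fit_maxent(fp, fb, beta_multiplier = beta_multiplier, tol = tol,
                      max_iter = max_iter, class_const = feature_class_const(fd))
  model$feature_defs <- fd
  model$variables <- fd$vars
  model$bg_means <- colMeans(background[, fd$vars, drop = FALSE])
  model
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features, beta %.2g, %d active weights, H = %.3f nats\n",
    length(x$weights), x$beta_multiplier, sum(x$weights != 0), x$entropy))
  invisible(x)
}

#' Predict from a fitted MaxEnt model
#'
#' Output transforms: `raw` is the Gibbs density
#' \eqn{\exp(\lambda' f) / Z} (sums to 1 over the training background);
#' `logistic` is \eqn{c\,raw / (1 + c\,raw)} and `cloglog` is
#' \eqn{1 - \exp(-c\,raw)}, both with \eqn{c = e^H}. Under a null
#' (all-zero-weight) model the logistic output is exactly 0.5 everywhere.
#'
#' @param object a fitted `maxent_model`.
#' @param newdata an [env_stack()] (requires the model to carry feature
#'   definitions), a design matrix of raw variables, or — for models fitted
#'   directly on features — a feature matrix.
#' @param type output scale.
#' @param ... unused.
#' @return For a stack: a matrix of scores (NA on masked cells); otherwise a
#'   numeric vector.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "cloglog"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$fitted)) stop("model is not fitted", call. = FALSE)
  as_stack <- is_env_stack(newdata)
  if (as_stack) {
    if (is.null(object$feature_defs))
      stop("model has no feature definitions; predict needs a feature matrix",
           call. = FALSE)
    missing <- setdiff(object$feature_defs$vars, names(newdata$layers))
    if (length(missing))
      stop("stack is missing variable(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    design <- stack_design(newdata, object$feature_defs$vars)
    feat <- expand_features(object$feature_defs, design, warn_clamp = TRUE)
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(object$feature_defs) &&
        all(object$feature_defs$vars %in% colnames(newdata))) {
      feat <- expand_features(object$feature_defs,
                              newdata[, object$feature_defs$vars, drop = FALSE],
                              warn_clamp = TRUE)
    } else {
      if (ncol(newdata) != length(object$weights))
        stop("feature matrix has wrong number of columns", call. = FALSE)
      feat <- newdata
    }
  }
  eta <- drop(feat %*% object$weights)
  raw <- exp(eta - object$logZ)
  out <- switch(type,
    raw = raw,
    logistic = {
      cr <- exp(object$entropy + eta - object$logZ)
      cr / (1 + cr)
    },
    cloglog = 1 - exp(-exp(object$entropy) * raw))
  if (as_stack) {
    scores <- matrix(NA_real_, newdata$grid$nrow, newdata$grid$ncol)
    scores[attr(design, "cell_index")] <- out
    scores
  } else out
}

#' Serialize a MaxEnt model to JSON and back
#'
#' @param model a fitted `maxent_model`.
#' @param path JSON file path.
#' @return `read_maxent_json()` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_maxent_json <- function(model, path) {
  fd <- model$feature_defs
  doc <- list(
    format = "sargassdm-maxent", version = 1L,
    beta_multiplier = model$beta_multiplier,
    weights = model$weights, penalties = model$penalties,
    logZ = model$logZ, entropy = model$entropy,
    n_background = model$n_background, n_presence = model$n_presence,
    feature_names = model$feature_names,
    bg_means = if (is.null(model$bg_means)) NULL else as.list(model$bg_means),
    feature_defs = if (is.null(fd)) NULL else list(
      defs = fd$defs, vars = fd$vars,
      lo = as.list(fd$lo), hi = as.list(fd$hi)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_maxent_json
#' @export
read_maxent_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "sargassdm-maxent"))
    stop("not a serialized MaxEnt model", call. = FALSE)
  fd <- NULL
  if (!is.null(doc$feature_defs) && length(doc$feature_defs)) {
    raw_defs <- doc$feature_defs$defs
    defs <- lapply(seq_len(nrow(raw_defs)), function(i)
      list(kind = raw_defs$kind[i], var = raw_defs$var[i],
           knot = as.numeric(raw_defs$knot[i])))
    fd <- structure(list(defs = defs, vars = doc$feature_defs$vars,
                         lo = unlist(doc$feature_defs$lo),
                         hi = unlist(doc$feature_defs$hi)),
                    class = "feature_defs")
  }
  structure(list(weights = doc$weights, penalties = doc$penalties,
                 beta_multiplier = doc$beta_multiplier,
                 logZ = doc$logZ, entropy = doc$entropy,
                 n_background = doc$n_background, n_presence = doc$n_presence,
                 feature_names = doc$feature_names,
                 obj_trace = NULL, kkt = NA_real_, iterations = NA_integer_,
                 feature_defs = fd, variables = if (is.null(fd)) NULL else fd$vars,
                 bg_means = if (is.null(doc$bg_means)) NULL else unlist(doc$bg_means),
                 fitted = TRUE),
            class = "maxent_model")
}
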