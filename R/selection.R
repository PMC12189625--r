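#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from an ordinary least-squares regression of
#' variable `k` on the remaining variables over the background cells.
#' Perfect collinearity yields `Inf` with a warning.
#'
#' @param background design matrix (background cells x >= 2 variables).
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(background) {
  background <- as.matrix(background)
  p <- ncol(background)
  if (p < 2) stop("need at least 2 variables for VIF", call. = FALSE)
  if (nrow(background) <= p)
    stop("need more background rows than variables", call. = FALSE)
  vars <- colnames(background)
  out <- stats::setNames(numeric(p), vars)
  for (k in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, background[, -k, drop = FALSE]),
                         background[, k])
    y <- background[, k]
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    out[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out)))
    warning("perfect collinearity: infinite VIF for ",
            paste(vars[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

#' Screen variables by contribution and pairwise correlation
#'
#' Iterative loop: fit `reps` replicate 70/30 models on the current
#' variable set, average the permutation contributions; drop every variable
#' with mean contribution strictly below `contribution_threshold`; then,
#' while any retained pair has background Pearson `|r| >` `corr_threshold`,
#' drop the lower-contribution member of the strongest such pair
#' (ties: the lexicographically later name). Repeat until the set is
#' stable.
#'
#' @param presence,background design matrices over the candidate variables.
#' @param contribution_threshold percent-contribution cut (strict `<`).
#' @param corr_threshold absolute Pearson correlation cut (strict `>`).
#' @param reps replicate models per pass.
#' @param beta_multiplier regularization used during screening.
#' @param base_seed replicate seeds are `base_seed + 1 ..`.
#' @param ... passed to [train_maxent()].
#' @return A `selection_report`: `retained`, `excluded` (data.frame with
#'   reasons), `contribution` (last-pass means), and the pass history.
#' @export
screen_variables <- function(presence, background,
                             contribution_threshold = 5,
                             corr_threshold = 0.7,
                             reps = 10, beta_multiplier = 1,
                             base_seed = 0L, ...) {
  candidates <- colnames(background)
  if (length(candidates) < 2)
    stop("need at least 2 candidate variables", call. = FALSE)
  current <- candidates
  excluded <- data.frame(variable = character(), reason = character(),
                         stringsAsFactors = FALSE)
  history <- list()
  contrib_mean <- NULL
  repeat {
    if (length(current) == 0) {
      cond <- structure(
        class = c("sdm_selection_error", "error", "condition"),
        list(message = "variable screening excluded every candidate",
             call = sys.call(-1), excluded = excluded, history = history))
      stop(cond)
    }
    if (length(current) == 1) break
    rf <- replicate_fits(presence[, current, drop = FALSE],
                         background[, current, drop = FALSE],
                         beta_multiplier = beta_multiplier, reps = reps,
                         base_seed = base_seed, contributions = TRUE, ...)
    contrib_mean <- colMeans(rf$contributions)
    history[[length(history) + 1L]] <- contrib_mean
    dropped <- character()
    low <- names(contrib_mean)[contrib_mean < contribution_threshold]
    if (length(low)) {
      excluded <- rbind(excluded, data.frame(variable = low,
                                             reason = "low-contribution"))
      current <- setdiff(current, low)
      dropped <- low
    }
    # correlation filter on the survivors, strongest pair first
    repeat {
      if (length(current) < 2) break
      cm <- abs(stats::cor(background[, current, drop = FALSE]))
      diag(cm) <- 0
      if (max(cm) <= corr_threshold) break
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      a <- current[ij[1]]; b <- current[ij[2]]
      ca <- contrib_mean[[a]]; cb <- contrib_mean[[b]]
      victim <- if (ca < cb) a else if (cb < ca) b else max(a, b)
      excluded <- rbind(excluded, data.frame(variable = victim,
                                             reason = "correlated"))
      current <- setdiff(current, victim)
      dropped <- c(dropped, victim)
    }
    if (length(dropped) == 0) break
  }
  structure(list(retained = current, excluded = excluded,
                 contribution = contrib_mean[names(contrib_mean) %in% current],
                 history = history, candidates = candidates),
            class = "selection_report")
}

#' Choose the beta multiplier by replicate test AUC
#'
#' For each candidate beta, run `reps` replicate 70/30 fits and record the
#' mean test AUC; return the beta attaining the maximum (ties: the smallest
#' beta).
#'
#' @param presence,background design matrices over the screened variables.
#' @param betas candidate grid (default 1 to 10 by 0.5: 19 values).
#' @param reps replicates per beta.
#' @param base_seed replicate seed base (shared across betas so every beta
#'   sees the same splits).
#' @param ... passed to [train_maxent()].
#' @return list with `beta` (chosen) and `auc_table`
#'   (data.frame: beta, mean_auc, sd_auc).
#' @export
sweep_beta <- function(presence, background, betas = seq(1, 10, by = 0.5),
                       reps = 10, base_seed = 0L, ...) {
  stopifnot(length(betas) >= 1, !is.unsorted(betas))
  tab <- data.frame(beta = betas, mean_auc = NA_real_, sd_auc = NA_real_)
  for (i in seq_along(betas)) {
    rf <- replicate_fits(presence, background, beta_multiplier = betas[i],
                         reps = reps, base_seed = base_seed, ...)
    tab$mean_auc[i] <- mean(rf$results$auc)
    tab$sd_auc[i] <- stats::sd(rf$results$auc)
  }
  best <- which(tab$mean_auc == max(tab$mean_auc))[1]  # ties: smallest beta
  list(beta = betas[best], auc_table = tab)
}

#' Full variable-selection and beta-tuning procedure
#'
#' (1) contribution + correlation screening loop; (2) beta sweep on the
#' survivors; (3) VIF check on the survivors — while any VIF >=
#' `vif_threshold`, the worst offender is removed and the procedure
#' re-screens from step 1 on the reduced candidate set.
#'
#' @inheritParams screen_variables
#' @inheritParams sweep_beta
#' @param vif_threshold VIF gate (strict `<` retains).
#' @return A `selection_report` augmented with `vif`, `beta`, `auc_table`.
#' @export
select_model <- function(presence, background,
                         contribution_threshold = 5, corr_threshold = 0.7,
                         vif_threshold = 5, betas = seq(1, 10, by = 0.5),
                         reps = 10, base_seed = 0L, ...) {
  candidates <- colnames(background)
  vif_excluded <- data.frame(variable = character(), reason = character())
  repeat {
    rep_scr <- screen_variables(presence[, candidates, drop = FALSE],
                                background[, candidates, drop = FALSE],
                                contribution_threshold = contribution_threshold,
                                corr_threshold = corr_threshold,
                                reps = reps, base_seed = base_seed, ...)
    retained <- rep_scr$retained
    if (length(retained) < 2) break
    vifs <- compute_vif(background[, retained, drop = FALSE])
    if (max(vifs) < vif_threshold) break
    worst <- names(vifs)[which.max(vifs)]
    vif_excluded <- rbind(vif_excluded,
                          data.frame(variable = worst, reason = "high-VIF"))
    candidates <- setdiff(candidates, worst)
  }
  retained <- rep_scr$retained
  vifs <- if (length(retained) >= 2)
    compute_vif(background[, retained, drop = FALSE])
  else stats::setNames(rep(NA_real_, length(retained)), retained)
  sw <- sweep_beta(presence[, retained, drop = FALSE],
                   background[, retained, drop = FALSE],
                   betas = betas, reps = reps, base_seed = base_seed, ...)
  rep_scr$excluded <- rbind(rep_scr$excluded, vif_excluded)
  rep_scr$vif <- vifs
  rep_scr$beta <- sw$beta
  rep_scr$auc_table <- sw$auc_table
  rep_scr
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$excluded))
    cat(" excluded:", paste(sprintf("%s (%s)", x$excluded$variable,
                                    x$excluded$reason), collapse = ", "), "\n")
  if (!is.null(x$beta)) cat(" beta multiplier:", x$beta, "\n")
  invisible(x)
}

#' Write a selection report as CSV
#'
#' One row per candidate variable with contribution, VIF, status and reason.
#'
#' @param report a `selection_report`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(report, path) {
  vars <- report$candidates
  df <- data.frame(
    variable = vars,
    contribution = vapply(vars, function(v) {
      if (v %in% names(report$contribution)) report$contribution[[v]] else NA_real_
    }, numeric(1)),
    vif = vapply(vars, function(v) {
      if (!is.null(report$vif) && v %in% names(report$vif)) report$vif[[v]] else NA_real_
    }, numeric(1)),
    status = ifelse(vars %in% report$retained, "retained", "excluded"),
    reason = vapply(vars, function(v) {
      i <- match(v, report$excluded$variable)
      if (is.na(i)) "" else report$excluded$reason[i]
    }, character(1)))
  data.table::fwrite(df, path)
  invisible(path)
}
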