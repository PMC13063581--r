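#' Hyperparameter tuning configuration
#'
#' The elastic net has two hyperparameters: the mixing parameter (L1
#' share of the penalty, on the fixed grid 0.1, 0.2, ..., 1.0) and the
#' overall regularization strength. For every mixing value the strength
#' is tuned by repeated 15-fold outcome-stratified cross-validation on
#' validation AUC.
#'
#' @param mixing_grid Mixing parameters in (0, 1].
#' @param n_folds Folds per repeat (default 15).
#' @param n_repeats Cross-validation repeats (default 5).
#' @param strength_grid Strictly decreasing positive regularization
#'   strengths; `NULL` derives a 25-point log-spaced grid from the data.
#' @param seed Integer seed for the fold assignments.
#' @return Object of class `tuning_config`.
#' @export
tuning_config <- function(mixing_grid = seq(0.1, 1, by = 0.1),
                          n_folds = 15, n_repeats = 5,
                          strength_grid = NULL, seed = 1L) {
  if (any(mixing_grid <= 0) || any(mixing_grid > 1)) {
    stop("mixing parameters must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(strength_grid)) {
    if (any(strength_grid <= 0) || is.unsorted(rev(strength_grid), strictly = TRUE)) {
      stop("`strength_grid` must be positive and strictly decreasing",
           call. = FALSE)
    }
  }
  structure(list(mixing_grid = mixing_grid, n_folds = n_folds,
                 n_repeats = n_repeats, strength_grid = strength_grid,
                 seed = as.integer(seed)),
            class = "tuning_config")
}

# Rank (Mann-Whitney) AUC of scores against a binary outcome; average
# ranks handle ties, so a constant score gives 0.5.
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Outcome-stratified fold assignment: within each class, a shuffled
# cyclic allocation over 1..n_folds, so fold class sizes differ by at
# most one.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds) {
      stop("stratification error: outcome class ", cl, " has fewer than ",
           n_folds, " members", call. = FALSE)
    }
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

default_strength_grid <- function(x, y, n_points = 25,
                                  min_mixing = 0.1, ratio = 1e-4) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / (nrow(x) * min_mixing)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_points))
}

# glmnet requires >= 2 columns; single-column designs get an all-zero
# pad column whose coefficient is identically 0
pad1 <- function(x) if (ncol(x) == 1) cbind(x, `..pad..` = 0) else x

enet_path <- function(x, y, mixing, strengths) {
  glmnet::glmnet(pad1(x), y, family = "binomial", alpha = mixing,
                 lambda = strengths, standardize = FALSE, thresh = 1e-9)
}

#' Cross-validated tuning grid
#'
#' For every (mixing, strength) pair: the mean and standard deviation of
#' the validation AUC over all folds of all repeats of an
#' outcome-stratified cross-validation, plus the number of non-zero
#' coefficients of the full-data fit at that pair. AUC is computed per
#' fold and averaged. Indicator columns are penalized as-is (no
#' standardization).
#'
#' @param dm A [build_design_matrix()] result.
#' @param config A [tuning_config()].
#' @return Data frame of class `tuning_grid` with columns `mixing`,
#'   `strength`, `mean_cv_auc`, `sd_cv_auc`, `se_cv_auc`, `n_eval`,
#'   `n_nonzero_at_full_fit`.
#' @export
cv_tune <- function(dm, config = tuning_config()) {
  stopifnot(inherits(dm, "design_matrix"))
  x <- dm$x
  y <- dm$y
  if (length(unique(y)) < 2) {
    stop("stratification error: outcome has a single class", call. = FALSE)
  }
  strengths <- config$strength_grid
  if (is.null(strengths)) {
    strengths <- default_strength_grid(x, y, min_mixing = min(config$mixing_grid))
  }
  n_eval <- config$n_folds * config$n_repeats
  fold_sets <- with_stream(config$seed, "cv_folds", {
    lapply(seq_len(config$n_repeats), function(r)
      stratified_folds(y, config$n_folds))
  })

  out <- list()
  for (mixing in config$mixing_grid) {
    aucs <- matrix(NA_real_, nrow = n_eval, ncol = length(strengths))
    row <- 0
    for (folds in fold_sets) {
      for (f in seq_len(config$n_folds)) {
        row <- row + 1
        test <- folds == f
        fit <- enet_path(x[!test, , drop = FALSE], y[!test], mixing, strengths)
        pred <- stats::predict(fit, pad1(x[test, , drop = FALSE]),
                               s = strengths, type = "link")
        aucs[row, ] <- apply(pred, 2, auc_rank, y = y[test])
      }
    }
    full <- enet_path(x, y, mixing, strengths)
    nnz <- apply(as.matrix(full$beta), 2, function(b) sum(b != 0))
    out[[length(out) + 1]] <- data.frame(
      mixing = mixing,
      strength = strengths,
      mean_cv_auc = colMeans(aucs),
      sd_cv_auc = apply(aucs, 2, stats::sd),
      se_cv_auc = apply(aucs, 2, stats::sd) / sqrt(n_eval),
      n_eval = n_eval,
      n_nonzero_at_full_fit = as.integer(nnz)
    )
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  class(grid) <- c("tuning_grid", "data.frame")
  grid
}

#' Strength choice at the elbow
#'
#' Operationalizes the elbow point (maximal AUC, minimal number of
#' non-zero coefficients) as the one-standard-error rule: among all
#' strengths whose mean cross-validated AUC is within one standard error
#' of the best row's AUC, the largest (sparsest) strength is chosen;
#' ties go to the larger strength.
#'
#' @param rows Tuning-grid rows for a single mixing value, with columns
#'   `strength`, `mean_cv_auc`, `se_cv_auc`.
#' @return The selected strength.
#' @export
select_strength <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) {
    stop("`rows` must contain at least one strength", call. = FALSE)
  }
  best_auc <- max(rows$mean_cv_auc)
  best_rows <- rows[rows$mean_cv_auc == best_auc, , drop = FALSE]
  best <- best_rows[which.max(best_rows$strength), , drop = FALSE]
  ok <- rows$mean_cv_auc >= best_auc - best$se_cv_auc
  max(rows$strength[ok])
}

#' Final penalized fit at fixed hyperparameters
#'
#' Elastic-net-penalized logistic regression on the full data at one
#' (mixing, strength) pair. The model is summarized by its non-zero
#' coefficient count (intercept excluded) and by an AIC defined with the
#' unpenalized log-likelihood evaluated at the penalized estimates and
#' k = n_nonzero + 1 degrees of freedom (the standard
#' degrees-of-freedom result for the lasso).
#'
#' @param dm A [build_design_matrix()] result.
#' @param mixing Mixing parameter in (0, 1].
#' @param strength Positive regularization strength.
#' @return Object of class `enet_fit`: `mixing`, `strength`, `intercept`,
#'   `beta` (named coefficient vector), `n_nonzero`, `log_likelihood`,
#'   `aic`.
#' @export
fit_final <- function(dm, mixing, strength) {
  stopifnot(inherits(dm, "design_matrix"), strength > 0)
  x <- dm$x
  y <- dm$y
  # glmnet is more reliable warm-started down a path than cold at a
  # single strength; fit a short path ending at the target and read off
  # the exact-strength coefficients
  path <- sort(unique(c(strength * c(8, 4, 2), strength)), decreasing = TRUE)
  fit <- enet_path(x, y, mixing, path)
  cf <- as.numeric(stats::coef(fit, s = strength))  # strength is on the path
  intercept <- cf[1]
  beta <- stats::setNames(cf[1 + seq_len(ncol(x))], colnames(x))
  eta <- intercept + as.numeric(x %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  nnz <- sum(beta != 0)
  structure(list(mixing = mixing, strength = strength, intercept = intercept,
                 beta = beta, n_nonzero = nnz, log_likelihood = ll,
                 aic = 2 * (nnz + 1) - 2 * ll),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("enet_fit: mixing %.2f, strength %.4g, %d non-zero, AIC %.1f\n",
              x$mixing, x$strength, x$n_nonzero, x$aic))
  invisible(x)
}

#' Choose among the per-mixing candidate models
#'
#' Lexicographic choice: the lowest number of non-zero coefficients
#' first, ties broken by the lowest AIC, remaining ties by the larger
#' mixing parameter.
#'
#' @param candidates List of [fit_final()] results, one per mixing.
#' @return The chosen `enet_fit`.
#' @export
choose_model <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate models", call. = FALSE)
  nnz <- vapply(candidates, `[[`, numeric(1), "n_nonzero")
  aic <- vapply(candidates, `[[`, numeric(1), "aic")
  mixing <- vapply(candidates, `[[`, numeric(1), "mixing")
  ord <- order(nnz, aic, -mixing)
  candidates[[ord[1]]]
}

#' Tune, fit per mixing, and choose the final model
#'
#' Full model-selection stage: cross-validated tuning grid, per-mixing
#' strength choice at the elbow, one full-data fit per mixing at its
#' selected strength, and the sparsity/AIC choice among those
#' candidates.
#'
#' @inheritParams cv_tune
#' @return List with `grid` (the [cv_tune()] result), `candidates`
#'   (one [fit_final()] per mixing) and `chosen` (the [choose_model()]
#'   winner).
#' @export
tune_and_choose <- function(dm, config = tuning_config()) {
  grid <- cv_tune(dm, config)
  candidates <- lapply(config$mixing_grid, function(m) {
    rows <- grid[grid$mixing == m, , drop = FALSE]
    fit_final(dm, m, select_strength(rows))
  })
  list(grid = grid, candidates = candidates, chosen = choose_model(candidates))
}
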