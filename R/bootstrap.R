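#' Bootstrap configuration
#'
#' @param n_samples Number of bootstrap resamples B (default 10,000, the
#'   analysis setting; tests and examples use far fewer).
#' @param ci_level Percentile-interval coverage in (0, 1).
#' @param seed Integer seed.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_samples = 10000, ci_level = 0.95, seed = 1L) {
  stopifnot(n_samples >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_samples = as.integer(n_samples), ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' One stratified resample
#'
#' Samples row indices with replacement separately within each outcome
#' class, preserving each class's size exactly, so every resample has
#' the observed case/control split.
#'
#' @param y Binary outcome vector with both classes present.
#' @return Integer vector of row indices (cases first, then controls,
#'   each block in draw order).
#' @export
stratified_resample <- function(y) {
  classes <- unique(y)
  if (length(classes) < 2) {
    stop("stratification error: outcome has a single class", call. = FALSE)
  }
  unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    idx[sample.int(length(idx), length(idx), replace = TRUE)]
  }), use.names = FALSE)
}

#' Bootstrap the chosen model's coefficients
#'
#' Refits the elastic-net logistic model B times at the chosen (mixing,
#' strength) pair -- hyperparameters are fixed, not re-tuned -- on
#' stratified resamples of the design matrix. Coefficients shrunk out of
#' a replicate's support are recorded as exactly 0. Replicates that fail
#' to converge are dropped and counted; more than 1% drops is an error.
#'
#' @param dm A [build_design_matrix()] result.
#' @param mixing,strength The chosen model's hyperparameters.
#' @param config A [bootstrap_config()].
#' @return Matrix of B rows by one column per design column, with
#'   attributes `intercepts` (numeric vector) and `n_dropped`.
#' @export
bootstrap_coefficients <- function(dm, mixing, strength,
                                   config = bootstrap_config()) {
  stopifnot(inherits(dm, "design_matrix"))
  B <- config$n_samples
  betas <- matrix(NA_real_, nrow = B, ncol = ncol(dm$x),
                  dimnames = list(NULL, colnames(dm$x)))
  intercepts <- numeric(B)
  dropped <- logical(B)
  with_stream(config$seed, "bootstrap", {
    for (b in seq_len(B)) {
      idx <- stratified_resample(dm$y)
      rep_fit <- tryCatch({
        sub <- dm
        sub$x <- dm$x[idx, , drop = FALSE]
        sub$y <- dm$y[idx]
        fit_final(sub, mixing, strength)
      }, error = function(e) NULL)
      if (is.null(rep_fit)) {
        dropped[b] <- TRUE
      } else {
        betas[b, ] <- rep_fit$beta
        intercepts[b] <- rep_fit$intercept
      }
    }
  })
  if (mean(dropped) > 0.01) {
    stop(sprintf("bootstrap failure: %d of %d replicates did not converge",
                 sum(dropped), B), call. = FALSE)
  }
  betas <- betas[!dropped, , drop = FALSE]
  attr(betas, "intercepts") <- intercepts[!dropped]
  attr(betas, "n_dropped") <- sum(dropped)
  betas
}

#' Percentile confidence interval
#'
#' Empirical quantiles of the replicates at (1 - level)/2 and
#' 1 - (1 - level)/2, with the linear-interpolation quantile definition
#' ([stats::quantile()] type 7).
#'
#' @param replicates Numeric vector of bootstrap replicates (>= 2).
#' @param level Coverage in (0, 1).
#' @return Named vector `c(low, high)`.
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  stopifnot(length(replicates) >= 2)
  alpha <- (1 - level) / 2
  q <- stats::quantile(replicates, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' One-sided bootstrap p-value
#'
#' The share of replicates contradicting the full-data point estimate's
#' sign: p = (1 + #\{replicates with the opposite sign or exactly 0\}) /
#' (B + 1). Replicates shrunk to exactly 0 count against significance,
#' and the +1 smoothing keeps p > 0. A zero point estimate gives p = 1.
#'
#' @param replicates Numeric vector of bootstrap replicates.
#' @param point_estimate Full-data coefficient of the chosen model.
#' @return p-value in (0, 1].
#' @export
bootstrap_p <- function(replicates, point_estimate) {
  if (point_estimate == 0) return(1)
  B <- length(replicates)
  against <- sum(replicates == 0 | sign(replicates) != sign(point_estimate))
  min(1, (1 + against) / (B + 1))
}

#' Per-coefficient bootstrap summary
#'
#' Combines the full-data chosen model (the point estimates) with the
#' replicate table: percentile confidence interval, one-sided bootstrap
#' p-value, and the share of replicates in which each coefficient was
#' shrunk to exactly 0.
#'
#' @param replicates A [bootstrap_coefficients()] matrix.
#' @param fit The chosen [fit_final()] model.
#' @param ci_level Coverage of the percentile interval.
#' @return Data frame with one row per design column: `column`, `beta`,
#'   `ci_low`, `ci_high`, `p_one_sided`, `zero_fraction`.
#' @export
bootstrap_summary <- function(replicates, fit, ci_level = 0.95) {
  stopifnot(inherits(fit, "enet_fit"),
            identical(colnames(replicates), names(fit$beta)))
  rows <- lapply(colnames(replicates), function(cn) {
    reps <- replicates[, cn]
    ci <- percentile_ci(reps, ci_level)
    data.frame(column = cn, beta = unname(fit$beta[cn]),
               ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
               p_one_sided = bootstrap_p(reps, fit$beta[cn]),
               zero_fraction = mean(reps == 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
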