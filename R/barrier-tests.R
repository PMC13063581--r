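#' Yates-corrected chi-squared test for a 2x2 table
#'
#' Pearson chi-squared test with continuity correction on a 2x2 table of
#' counts, 1 degree of freedom, upper-tail p-value. The continuity
#' correction subtracts 0.5 from |observed - expected| in every cell and
#' is conservative relative to the uncorrected statistic.
#'
#' @param a,b,c,d Non-negative integer counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`. Rows are groups (e.g. citing / not citing
#'   a reason), columns are strata.
#' @return The two-sided p-value.
#' @seealso [fisher_exact()], [choose_test()]
#' @export
chi2_yates <- function(a, b, c, d) {
  tab <- as_2x2(a, b, c, d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: table has a zero margin", call. = FALSE)
  }
  suppressWarnings(stats::chisq.test(tab, correct = TRUE))$p.value
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric probabilities no larger than that
#' of the observed table (the probability-mass definition, as in
#' [stats::fisher.test()]). Degenerate tables (a zero margin) return 1.
#'
#' @inheritParams chi2_yates
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  tab <- as_2x2(a, b, c, d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Choose between chi-squared and Fisher's exact test
#'
#' The chi-squared approximation is unreliable at low expected counts, so
#' Fisher's exact test is used whenever any expected cell count falls
#' below 5 (and for degenerate tables); otherwise the Yates-corrected
#' chi-squared test is used.
#'
#' @inheritParams chi2_yates
#' @return `"fisher_exact"` or `"chi_squared_yates"`.
#' @export
choose_test <- function(a, b, c, d) {
  tab <- as_2x2(a, b, c, d)
  n <- sum(tab)
  if (n == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return("fisher_exact")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) "fisher_exact" else "chi_squared_yates"
}

as_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(length(counts) == 4, is.numeric(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("2x2 table entries must be non-negative integers", call. = FALSE)
  }
  matrix(counts, nrow = 2, byrow = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction across a family of tests:
#' p-values are sorted ascending, `p(i)` is replaced by
#' `min_{j >= i} p(j) * m / j` capped at 1, and results are returned in
#' the input order. Raw (unrounded) p-values must be supplied.
#'
#' @param p Numeric vector of p-values, each in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score-based interval inverts the normal approximation to the score
#' test and remains well-behaved at small counts and proportions near the
#' boundary, which makes it the standard choice for rare-event
#' participation probabilities.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n > 0`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(low, high)` on the proportion scale.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("`k` must lie in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Per-reason tests on a counts table
#'
#' Runs, for every reason, the 2x2 test comparing two strata (citing vs
#' not citing, stratum 1 vs stratum 2), choosing chi-squared with
#' continuity correction or Fisher's exact test per [choose_test()], and
#' adjusts the raw p-values across the reason family with
#' Benjamini-Hochberg.
#'
#' @param counts Data frame with columns `reason`, `k1`, `n1`, `k2`, `n2`:
#'   citing counts and stratum totals for the two compared strata.
#' @return Data frame with columns `reason`, `k1`, `n1`, `k2`, `n2`,
#'   `test_used`, `p_raw`, `p_adjusted`.
#' @export
reason_tests <- function(counts) {
  required <- c("reason", "k1", "n1", "k2", "n2")
  if (!all(required %in% names(counts))) {
    stop("`counts` must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  res <- counts[required]
  cells <- function(i) {
    with(counts[i, ], c(k1, n1 - k1, k2, n2 - k2))
  }
  res$test_used <- vapply(seq_len(nrow(counts)), function(i) {
    do.call(choose_test, as.list(cells(i)))
  }, character(1))
  res$p_raw <- vapply(seq_len(nrow(counts)), function(i) {
    f <- if (res$test_used[i] == "fisher_exact") fisher_exact else chi2_yates
    do.call(f, as.list(cells(i)))
  }, numeric(1))
  res$p_adjusted <- bh_adjust(res$p_raw)
  res
}

#' Reason-citation counts from an analysis cohort
#'
#' Tabulates, for each of the multi-select reasons for not using PrEP,
#' how many non-users in each stratum cited it. Two stratifications are
#' supported: by PrEP-indication subgroup (the two single-criterion
#' subgroups are compared; the "both criteria" subgroup is displayed but
#' excluded from the test) and by HIV-specialist density of the federal
#' state of residence (low = bands 0 through 6-9, high = band 10-13;
#' records with an unknown density band are excluded).
#'
#' @param cohort An [apply_selection_flow()] cohort data frame, or any
#'   data frame of non-users carrying `reason_*` indicator columns plus
#'   `indication_subgroup` or `density_band` as required.
#' @param stratify `"indication"` or `"density"`.
#' @return Counts data frame as expected by [reason_tests()], with an
#'   extra `k_all`/`n_all` pair covering all non-users and, for the
#'   indication stratification, `k_both`/`n_both` for the displayed-only
#'   "both" column.
#' @export
reason_counts <- function(cohort, stratify = c("indication", "density")) {
  stratify <- match.arg(stratify)
  nonusers <- cohort[cohort$prep_status == "never", , drop = FALSE]
  reason_cols <- grep("^reason_", names(nonusers), value = TRUE)
  if (length(reason_cols) == 0) {
    stop("cohort has no `reason_*` indicator columns", call. = FALSE)
  }
  if (stratify == "indication") {
    g1 <- nonusers$indication_subgroup == "partners_sti_hcv"
    g2 <- nonusers$indication_subgroup == "sdu_only"
    gb <- nonusers$indication_subgroup == "both"
  } else {
    band <- nonusers$density_band
    g1 <- !is.na(band) & band != "missing" & band != "10-13"
    g2 <- !is.na(band) & band == "10-13"
    gb <- rep(FALSE, nrow(nonusers))
  }
  cite <- function(col, idx) sum(nonusers[[col]][idx] == 1, na.rm = TRUE)
  out <- data.frame(
    reason = sub("^reason_", "", reason_cols),
    k1 = vapply(reason_cols, cite, numeric(1), idx = g1),
    n1 = sum(g1),
    k2 = vapply(reason_cols, cite, numeric(1), idx = g2),
    n2 = sum(g2),
    k_all = vapply(reason_cols, cite, numeric(1), idx = rep(TRUE, nrow(nonusers))),
    n_all = nrow(nonusers),
    row.names = NULL
  )
  if (stratify == "indication") {
    out$k_both <- vapply(reason_cols, cite, numeric(1), idx = gb)
    out$n_both <- sum(gb)
  }
  out
}

#' Stratified reasons-for-non-use analysis
#'
#' Convenience wrapper: tabulates citation counts with [reason_counts()]
#' and tests each reason with [reason_tests()].
#'
#' @inheritParams reason_counts
#' @return The [reason_tests()] result with the extra count columns from
#'   [reason_counts()] retained.
#' @export
build_reason_analysis <- function(cohort, stratify = c("indication", "density")) {
  stratify <- match.arg(stratify)
  counts <- reason_counts(cohort, stratify)
  tested <- reason_tests(counts)
  extra <- setdiff(names(counts), names(tested))
  cbind(tested, counts[extra])
}

#' PrEP user proportion by federal state
#'
#' @param counts Data frame with columns `state`, `n_participants`,
#'   `n_users`; states with zero participants are omitted.
#' @param digits Rounding applied to the reported proportion (default 2,
#'   the reporting convention).
#' @return Data frame `state`, `n_participants`, `n_users`, `proportion`.
#' @export
user_proportion <- function(counts, digits = 2) {
  stopifnot(all(c("state", "n_participants", "n_users") %in% names(counts)))
  out <- counts[counts$n_participants > 0,
                c("state", "n_participants", "n_users")]
  out$proportion <- round(out$n_users / out$n_participants, digits)
  out
}

#' Participation probability by federal state with Wilson intervals
#'
#' For each state, the probability that a member of the estimated gay
#' population participated (and met the PrEP-indication criteria), with a
#' Wilson score confidence interval.
#'
#' @param counts Data frame with columns `state`, `population`,
#'   `n_participants`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with per-state `probability`, `ci_low`, `ci_high`
#'   on the proportion scale.
#' @export
participation_table <- function(counts, level = 0.95) {
  stopifnot(all(c("state", "population", "n_participants") %in% names(counts)))
  ci <- t(vapply(seq_len(nrow(counts)), function(i) {
    wilson_ci(counts$n_participants[i], counts$population[i], level)
  }, numeric(2)))
  data.frame(
    state = counts$state,
    population = counts$population,
    n_participants = counts$n_participants,
    probability = counts$n_participants / counts$population,
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    row.names = NULL
  )
}
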