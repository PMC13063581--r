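#' Published summary counts from the German MSM PrEP survey
#'
#' The individual-level survey data behind this analysis are not publicly
#' deposited; what is public are the summary tables: per-reason citation
#' counts among PrEP non-users with a PrEP indication (stratified by
#' indication subgroup and by HIV-specialist density), and per-state
#' participant, user and estimated-population counts. These ship with the
#' package as plain CSV and are the inputs to the contingency and
#' proportion analyses.
#'
#' @param stratify `"indication"` (subgroup columns: both criteria,
#'   partners/STI/hepatitis-C only as stratum 1, sexualized drug use only
#'   as stratum 2) or `"density"` (stratum 1 = low density bands 0
#'   through 6-9, stratum 2 = high band 10-13; the strata totals exclude
#'   non-users whose state, and hence band, is unknown).
#' @return For `survey_reason_counts()`, a counts data frame as accepted
#'   by [reason_tests()]; for `survey_state_counts()`, a data frame with
#'   columns `state`, `population` (estimated gay population),
#'   `n_participants` (with PrEP indication) and `n_users`.
#' @export
survey_reason_counts <- function(stratify = c("indication", "density")) {
  stratify <- match.arg(stratify)
  file <- if (stratify == "indication") "reasons_by_indication.csv" else "reasons_by_density.csv"
  utils::read.csv(pkg_extdata(file), stringsAsFactors = FALSE)
}

#' @rdname survey_reason_counts
#' @export
survey_state_counts <- function() {
  utils::read.csv(pkg_extdata("state_summary.csv"), stringsAsFactors = FALSE)
}

#' HIV-specialist density per federal state
#'
#' Licensed HIV-care physicians per 10,000 estimated gay men, per German
#' federal state. Only the three city states' densities are public
#' (Berlin 10.27, Hamburg 10.73, Bremen 12.73); the remaining thirteen
#' values in the shipped map are synthetic, chosen to respect the
#' published band distribution and the reported east-west gradient, and
#' are intended for simulation only. Users with the real map can supply
#' their own via the `map` argument of [density_band()].
#'
#' @return Named numeric vector, state -> specialists per 10,000 gay men.
#' @export
default_density_map <- function() {
  d <- utils::read.csv(pkg_extdata("specialist_density_synthetic.csv"),
                       stringsAsFactors = FALSE)
  stats::setNames(d$specialists_per_10k, d$state)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "prepbarriers")
  if (path == "") stop("missing packaged data file: ", file, call. = FALSE)
  path
}
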