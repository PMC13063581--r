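# Per-purpose RNG streams: every sampled quantity gets its own seed
# derived from the master seed and a stream name, so adding or removing
# one variable never shifts another variable's draws.
stream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(seed) %% 2000000 + 1) * 1000 + h %% 1000 + h)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, name))
  expr
}

REASON_LABELS <- c("risk_too_low", "no_prescriber", "doctor_visit_effort",
                   "discuss_sex_life", "negative_reactions", "side_effects",
                   "daily_pill", "medical_reasons")

PROTECTED_FIELDS <- c("participant_id", "prep_status")

#' Synthetic cohort configuration
#'
#' Bundles everything the generator needs: the number of participants,
#' per-variable category marginals, a logistic outcome model for current
#' PrEP use, per-reason and per-indication-stratum citation
#' probabilities for the multi-select reasons for non-use, per-variable
#' missingness rates, rates for the selection-flow states (former /
#' unspecified PrEP status), and the seed. Covariates are sampled
#' independently across variables; the generator emulates marginal
#' structure, not covariate correlation.
#'
#' @param n_participants Number of records to generate (>= 0).
#' @param covariate_marginals Named list, variable -> named probability
#'   vector over its categories (each summing to 1).
#' @param outcome_model List with `intercept` (log-odds of current PrEP
#'   use) and `effects`, a named list variable -> named vector of
#'   per-category log-odds shifts (unlisted categories contribute 0).
#' @param reason_probs Named list, reason -> named probability vector
#'   over the indication strata `both`, `partners_sti_hcv`, `sdu_only`,
#'   `none`.
#' @param missing_rate Named numeric vector of per-field missingness
#'   probabilities in \[0, 1); applied by [inject_missingness()].
#' @param former_user_rate,unspecified_prep_rate Probability that a
#'   record's PrEP status is `"former"` / `"missing"` instead of being
#'   drawn from the outcome model.
#' @param seed Integer master seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          covariate_marginals = default_marginals(),
                          outcome_model = default_outcome_model(),
                          reason_probs = default_reason_probs(),
                          missing_rate = default_missing_rates(),
                          former_user_rate = 0.034,
                          unspecified_prep_rate = 0.017,
                          seed = 1L) {
  config <- structure(list(
    n_participants = n_participants,
    covariate_marginals = covariate_marginals,
    outcome_model = outcome_model,
    reason_probs = reason_probs,
    missing_rate = missing_rate,
    former_user_rate = former_user_rate,
    unspecified_prep_rate = unspecified_prep_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(config)
  config
}

validate_cohort_config <- function(config) {
  if (!is.numeric(config$n_participants) || config$n_participants < 0) {
    stop("`n_participants` must be >= 0", call. = FALSE)
  }
  for (v in names(config$covariate_marginals)) {
    p <- config$covariate_marginals[[v]]
    if (any(p < 0) || any(p > 1)) {
      stop("configuration error: variable `", v,
           "` has probabilities outside [0, 1]", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("configuration error: variable `", v,
           "` probabilities sum to ", sum(p), ", not 1", call. = FALSE)
    }
    if (is.null(names(p)) || any(names(p) == "")) {
      stop("configuration error: variable `", v,
           "` has unnamed categories", call. = FALSE)
    }
  }
  for (r in names(config$reason_probs)) {
    p <- config$reason_probs[[r]]
    if (any(p < 0) || any(p > 1)) {
      stop("configuration error: reason `", r,
           "` has probabilities outside [0, 1]", call. = FALSE)
    }
  }
  if (any(config$missing_rate < 0) || any(config$missing_rate >= 1)) {
    stop("configuration error: missing rates must lie in [0, 1)", call. = FALSE)
  }
  invisible(config)
}

#' Default generator settings
#'
#' The defaults transcribe the published marginal distributions of the
#' survey's baseline table where available (age bands, origin, condom
#' use, partner numbers, sexualized drug use, per-state participation)
#' and otherwise use plausible values for a German MSM online survey;
#' marginals over observed categories are renormalised to 1 since
#' missingness is injected separately. The default outcome model points
#' the reported directions of association (fewer partners, sexualized
#' drug use, young age, low income and discontent with one's sex life
#' lower the odds of current PrEP use; a past chlamydia diagnosis and a
#' high-specialist-density city state raise them). Default reason
#' probabilities follow the published per-subgroup citation rates. All
#' of these are defaults for simulation, not assertions about any
#' dataset.
#'
#' @return `default_marginals()`: named list of probability vectors;
#'   `default_outcome_model()`: list with `intercept` and `effects`;
#'   `default_reason_probs()`: named list of per-stratum probability
#'   vectors; `default_missing_rates()`: named numeric vector.
#' @export
default_marginals <- function() {
  norm <- function(x) x / sum(x)
  states <- survey_state_counts()
  list(
    gender_identity = c(male = 0.97, "non-binary" = 0.02, female = 0.01),
    sex_assigned_at_birth = c(male = 0.99, female = 0.01),
    survey_completed = c("TRUE" = 0.824, "FALSE" = 0.176),
    prior_wave_participation = c("TRUE" = 0.02, "FALSE" = 0.98),
    hiv_status_confirmed_negative = c("TRUE" = 0.9, "FALSE" = 0.1),
    age_band = norm(c("18-29" = 0.231, "30-39" = 0.336,
                      "40-49" = 0.276, "50-80" = 0.157)),
    country_of_origin = c(Germany = 0.812, "Outside Germany" = 0.188),
    household_income_category = c("<500" = 0.05, "500-<1000" = 0.08,
                                  "1000-<2000" = 0.17, "2000-<3000" = 0.25,
                                  "3000-<4000" = 0.20, "4000-<5000" = 0.15,
                                  ">=5000" = 0.10),
    household_size = c("1" = 0.45, "2" = 0.40, "3" = 0.08,
                       "4" = 0.05, "5" = 0.02),
    federal_state = norm(stats::setNames(states$n_participants, states$state)),
    urban_rural = c(urban = 0.8, rural = 0.2),
    school_qualification = c(none = 0.01, class_8_9 = 0.07,
                             class_10 = 0.22, a_levels = 0.70),
    satisfaction_sex_life = c(content = 0.55, discontent = 0.30,
                              sex_not_important = 0.15),
    condom_use_category = norm(c("0%" = 0.263, "25%" = 0.310, "50%" = 0.175,
                                 "75%" = 0.110, ">95%" = 0.126)),
    n_partners_6m_category = norm(c("0" = 0.007, "1" = 0.016, "2-3" = 0.176,
                                    "4-5" = 0.182, "6-10" = 0.223,
                                    "11-20" = 0.156, ">20" = 0.228)),
    sdu_6m = norm(c(yes = 0.227, no = 0.752)),
    sti_syphilis_12m = c("0" = 0.93, "1" = 0.06, "2+" = 0.01),
    sti_gonorrhea_12m = c("0" = 0.82, "1" = 0.15, "2+" = 0.03),
    sti_chlamydia_12m = c("0" = 0.82, "1" = 0.15, "2+" = 0.03),
    sti_hcv_12m = c("0" = 0.995, "1" = 0.004, "2+" = 0.001),
    partner_male = c(yes = 0.98, no = 0.02),
    partner_female = c(yes = 0.07, no = 0.93),
    partner_nonbinary = c(yes = 0.03, no = 0.97)
  )
}

#' @rdname default_marginals
#' @export
default_outcome_model <- function() {
  list(
    intercept = 0.87,  # logit of roughly 70% current users among indicated
    effects = list(
      n_partners_6m_category = c("0" = -1.5, "1" = -1.2, "2-3" = -0.77,
                                 "4-5" = -0.31, "11-20" = 0.26),
      sdu_6m = c(yes = -0.46),
      sti_chlamydia_12m = c("1" = 0.56, "2+" = 0.56),
      age_band = c("18-29" = -0.24),
      satisfaction_sex_life = c(discontent = -0.31),
      household_income_category = c("<500" = -0.54, "500-<1000" = -0.54),
      federal_state = c(Berlin = 0.29, Hamburg = 0.29, Bremen = 0.29),
      partner_female = c(yes = -0.35)
    )
  )
}

#' @rdname default_marginals
#' @export
default_reason_probs <- function() {
  tab <- survey_reason_counts("indication")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    c(both = tab$k_both[i] / tab$n_both[i],
      partners_sti_hcv = tab$k1[i] / tab$n1[i],
      sdu_only = tab$k2[i] / tab$n2[i],
      none = tab$k_all[i] / tab$n_all[i])
  })
  stats::setNames(out, tab$reason)
}

#' @rdname default_marginals
#' @export
default_missing_rates <- function() {
  c(household_income_category = 0.043, household_size = 0.01,
    federal_state = 0.027, condom_use_category = 0.016,
    n_partners_6m_category = 0.011, sdu_6m = 0.021,
    sti_syphilis_12m = 0.40, sti_gonorrhea_12m = 0.40,
    sti_chlamydia_12m = 0.40, sti_hcv_12m = 0.40,
    school_qualification = 0.02, satisfaction_sex_life = 0.02,
    urban_rural = 0.01)
}

#' Generate a synthetic survey cohort
#'
#' Samples `n_participants` records: each covariate independently from
#' its configured marginal, age in years uniformly within the sampled
#' age band, PrEP status from the logistic outcome model applied to the
#' sampled covariates (with fixed shares of former users and of records
#' that left PrEP status unspecified), and -- for non-users -- each of
#' the eight multi-select reasons for non-use independently with the
#' probability of the record's indication stratum. Identical
#' configuration (including seed) reproduces the cohort exactly.
#' Missingness is not applied here; see [inject_missingness()].
#'
#' @param config A [cohort_config()].
#' @return Data frame, one row per participant.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_participants
  seed <- config$seed
  vars <- names(config$covariate_marginals)
  records <- data.frame(participant_id = seq_len(n))
  for (v in vars) {
    p <- config$covariate_marginals[[v]]
    records[[v]] <- with_stream(seed, paste0("cov:", v), {
      if (n == 0) character(0) else
        sample(names(p), n, replace = TRUE, prob = p)
    })
  }
  if ("age_band" %in% vars) {
    bounds <- list("18-29" = c(18, 29), "30-39" = c(30, 39),
                   "40-49" = c(40, 49), "50-80" = c(50, 80))
    records$age_years <- with_stream(seed, "age_years", {
      vapply(records$age_band, function(b) {
        rng <- bounds[[b]]
        if (is.null(rng)) NA_integer_ else
          as.integer(stats::runif(1, rng[1], rng[2] + 1))
      }, integer(1), USE.NAMES = FALSE)
    })
  }

  # PrEP status: fixed shares of former / unspecified, else a Bernoulli
  # draw from the logistic model on the sampled covariates
  eta <- rep(config$outcome_model$intercept, n)
  for (v in names(config$outcome_model$effects)) {
    eff <- config$outcome_model$effects[[v]]
    if (v %in% names(records)) {
      shift <- eff[records[[v]]]
      shift[is.na(shift)] <- 0
      eta <- eta + shift
    }
  }
  cls <- with_stream(seed, "prep_class", stats::runif(n))
  use <- with_stream(seed, "prep_status", stats::runif(n))
  status <- ifelse(cls < config$former_user_rate, "former",
            ifelse(cls < config$former_user_rate + config$unspecified_prep_rate,
                   "missing",
                   ifelse(use < stats::plogis(eta), "current", "never")))
  records$prep_status <- if (n == 0) character(0) else unname(status)

  # reasons: non-users only, one independent Bernoulli per reason, with
  # the stratum-specific probability of the record's indication subgroup
  stratum <- rep("none", n)
  nonuser <- records$prep_status == "never"
  if (length(config$reason_probs) > 0 && any(nonuser)) {
    sub <- records[nonuser, , drop = FALSE]
    ind <- has_indication(sub, "prep_non_user")
    lab <- rep("none", nrow(sub))
    if (any(ind)) {
      lab[ind] <- classify_subgroup(sub[ind, , drop = FALSE], "prep_non_user")
    }
    stratum[nonuser] <- lab
  }
  for (r in names(config$reason_probs)) {
    p <- config$reason_probs[[r]][stratum]
    p[is.na(p)] <- 0
    u <- with_stream(seed, paste0("reason:", r), stats::runif(n))
    records[[paste0("reason_", r)]] <- as.integer(nonuser & u < p)
  }
  records
}

#' Inject missingness into a cohort
#'
#' Independently replaces each eligible field value by the `"missing"`
#' sentinel with its configured per-field rate. PrEP status and the
#' participant id are protected and may never be masked. Draws are
#' seeded per field, so the operation is deterministic and idempotent:
#' already-missing entries stay missing.
#'
#' @param records Cohort data frame.
#' @param missing_rate Named numeric vector of per-field rates in
#'   \[0, 1).
#' @param seed Integer seed.
#' @return The cohort with missingness applied.
#' @export
inject_missingness <- function(records, missing_rate = default_missing_rates(),
                               seed = 1L) {
  if (any(missing_rate < 0) || any(missing_rate >= 1)) {
    stop("configuration error: missing rates must lie in [0, 1)", call. = FALSE)
  }
  hit_protected <- intersect(names(missing_rate), PROTECTED_FIELDS)
  if (length(hit_protected) > 0) {
    stop("configuration error: field(s) ",
         paste(hit_protected, collapse = ", "), " may not be masked",
         call. = FALSE)
  }
  for (field in names(missing_rate)) {
    if (!field %in% names(records)) next
    u <- with_stream(seed, paste0("miss:", field), stats::runif(nrow(records)))
    mask <- u < missing_rate[[field]]
    records[[field]] <- as.character(records[[field]])
    records[[field]][mask] <- "missing"
  }
  records
}

#' Read and write cohort CSV files
#'
#' Cohorts are exchanged as UTF-8 CSV with a header row and the literal
#' string `"missing"` as the missingness sentinel; all survey fields are
#' read as character so that the sentinel survives a round trip.
#'
#' @param records Cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  for (col in c("participant_id", "age_years", grep("^reason_", names(rec), value = TRUE))) {
    if (col %in% names(rec)) rec[[col]] <- as.integer(rec[[col]])
  }
  rec
}

#' Read or write a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `read_cohort_config()` returns a validated [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  # named atomic vectors must become YAML maps, not sequences
  mapify <- function(x) lapply(x, as.list)
  out <- unclass(config)
  out$covariate_marginals <- mapify(out$covariate_marginals)
  out$outcome_model$effects <- mapify(out$outcome_model$effects)
  out$reason_probs <- mapify(out$reason_probs)
  out$missing_rate <- as.list(out$missing_rate)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  listify <- function(x) lapply(x, function(el) unlist(el))
  cohort_config(
    n_participants = raw$n_participants,
    covariate_marginals = listify(raw$covariate_marginals),
    outcome_model = list(intercept = raw$outcome_model$intercept,
                         effects = listify(raw$outcome_model$effects)),
    reason_probs = listify(raw$reason_probs),
    missing_rate = unlist(raw$missing_rate),
    former_user_rate = raw$former_user_rate,
    unspecified_prep_rate = raw$unspecified_prep_rate,
    seed = raw$seed
  )
}
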