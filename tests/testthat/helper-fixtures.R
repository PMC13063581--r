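# Builders for small hand-constructed records and cohorts.

# one fully-specified eligible participant; override any field
make_record <- function(...) {
  base <- list(
    participant_id = 1L,
    gender_identity = "male",
    sex_assigned_at_birth = "male",
    survey_completed = "TRUE",
    prior_wave_participation = "FALSE",
    hiv_status_confirmed_negative = "TRUE",
    age_band = "30-39",
    age_years = 34L,
    country_of_origin = "Germany",
    household_income_category = "2000-<3000",
    household_size = "1",
    federal_state = "Berlin",
    urban_rural = "urban",
    school_qualification = "a_levels",
    satisfaction_sex_life = "content",
    condom_use_category = "25%",
    n_partners_6m_category = "6-10",
    sdu_6m = "no",
    sti_syphilis_12m = "0",
    sti_gonorrhea_12m = "0",
    sti_chlamydia_12m = "1",
    sti_hcv_12m = "0",
    partner_male = "yes",
    partner_female = "no",
    partner_nonbinary = "no",
    prep_status = "current"
  )
  override <- list(...)
  base[names(override)] <- override
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$participant_id <- seq_len(nrow(out))
  out
}

# a generator configuration in which every selection filter passes
all_pass_config <- function(n, seed = 1L, ...) {
  marg <- default_marginals()
  marg$gender_identity <- c(male = 1)
  marg$sex_assigned_at_birth <- c(male = 1)
  marg$survey_completed <- c("TRUE" = 1)
  marg$prior_wave_participation <- c("FALSE" = 1)
  marg$hiv_status_confirmed_negative <- c("TRUE" = 1)
  marg$sdu_6m <- c(yes = 1)  # everyone indicated via the SDU criterion
  cohort_config(n, covariate_marginals = marg,
                former_user_rate = 0, unspecified_prep_rate = 0,
                missing_rate = numeric(0), seed = seed, ...)
}

# a bare design matrix built directly from a binary covariate matrix,
# bypassing the encoder (for model-fitting tests)
make_dm <- function(x, y) {
  colnames(x) <- colnames(x) %||% paste0("v", seq_len(ncol(x)), "=1")
  structure(list(
    x = x, y = y,
    meta = data.frame(column = colnames(x),
                      variable = sub("=.*$", "", colnames(x)),
                      category = "1", is_missing_indicator = FALSE),
    reference = stats::setNames(rep("0", ncol(x)), sub("=.*$", "", colnames(x))),
    missing_mode = "separate_category"
  ), class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent hypergeometric-enumeration oracle for the two-sided
# Fisher p (probability-mass definition, with fisher.test's relative
# tolerance on "no larger than")
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n_ <- c + d         # row 2 total
  k <- a + c          # column 1 total
  if (m == 0 || n_ == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
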