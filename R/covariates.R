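#' Household income schema
#'
#' Answer options for monthly household net income, as ordered categories
#' with Euro bounds, plus the value imputed for the open-ended top
#' category and the six reporting bands for the derived net equivalent
#' income. The default grid is 500 EUR steps below 1,000 EUR and
#' 1,000 EUR steps above; the open top category is valued at 6,260 EUR,
#' the population-weighted median household income above 5,000 EUR
#' (SOEP 2018). Category means are arithmetic midpoints of the bounds.
#' Surveys with different answer options should supply their own schema.
#'
#' @param bounds Data frame with columns `category`, `lower`, `upper`
#'   (upper `NA` marks the open-ended top category).
#' @param top_value Euro value used for the open-ended top category.
#' @param bands Character vector of the six equivalised-income band
#'   labels, ascending; band edges are parsed from the labels.
#' @return An object of class `income_schema`.
#' @export
income_schema <- function(bounds = NULL, top_value = 6260,
                          bands = c("<1000", "1000-<2000", "2000-<3000",
                                    "3000-<4000", "4000-<5000", ">=5000")) {
  if (is.null(bounds)) {
    bounds <- data.frame(
      category = c("<500", "500-<1000", "1000-<2000", "2000-<3000",
                   "3000-<4000", "4000-<5000", ">=5000"),
      lower = c(0, 500, 1000, 2000, 3000, 4000, 5000),
      upper = c(500, 1000, 2000, 3000, 4000, 5000, NA),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("category", "lower", "upper") %in% names(bounds)))
  fin <- !is.na(bounds$upper)
  if (any(bounds$lower[fin] >= bounds$upper[fin]) ||
      is.unsorted(bounds$lower, strictly = TRUE)) {
    stop("income bounds must be ascending and non-overlapping", call. = FALSE)
  }
  if (top_value <= max(bounds$lower)) {
    stop("`top_value` must exceed the highest lower bound", call. = FALSE)
  }
  band_edges <- c(as.numeric(sub("^<", "", bands[1])),
                  vapply(bands[-1], function(b) {
                    as.numeric(sub("^>?=?([0-9]+).*$", "\\1", b))
                  }, numeric(1)))
  structure(list(bounds = bounds, top_value = top_value,
                 bands = bands, band_edges = unname(band_edges)),
            class = "income_schema")
}

#' Monthly net equivalent income
#'
#' The equivalised income divides the mean of the reported household net
#' income category by the square root of the household size (square-root
#' equivalence scale), then assigns one of the six reporting bands. The
#' category mean is the midpoint of the category bounds; the open-ended
#' top category uses the schema's fixed top value.
#'
#' @param income_category Character vector of schema categories (or
#'   `"missing"`).
#' @param household_size Positive integer vector (or `NA`/`"missing"`).
#' @param schema An [income_schema()].
#' @return Data frame with columns `value` (EUR, `NA` when missing) and
#'   `band` (character, `"missing"` when either input is missing).
#' @export
equivalised_income <- function(income_category, household_size,
                               schema = income_schema()) {
  stopifnot(inherits(schema, "income_schema"))
  household_size <- suppressWarnings(as.numeric(household_size))
  n <- max(length(income_category), length(household_size))
  income_category <- rep_len(as.character(income_category), n)
  household_size <- rep_len(household_size, n)
  b <- schema$bounds
  idx <- match(income_category, b$category)
  unknown <- is.na(idx) & !income_category %in% "missing"
  if (any(unknown)) {
    stop("income category not in schema: ",
         paste(unique(income_category[unknown]), collapse = ", "),
         call. = FALSE)
  }
  mean_val <- ifelse(is.na(b$upper[idx]), schema$top_value,
                     (b$lower[idx] + b$upper[idx]) / 2)
  bad_size <- !is.na(household_size) & household_size < 1
  if (any(bad_size)) stop("household size must be >= 1", call. = FALSE)
  value <- mean_val / sqrt(household_size)
  value[is.na(idx) | is.na(household_size)] <- NA_real_
  band <- income_band(value, schema)
  data.frame(value = value, band = band, stringsAsFactors = FALSE)
}

income_band <- function(value, schema) {
  edges <- c(schema$band_edges, Inf)
  band <- schema$bands[findInterval(value, edges[-1]) + 1]
  # below the first edge is still the lowest band ("<1000")
  band[!is.na(value) & value < edges[1]] <- schema$bands[1]
  band[is.na(value)] <- "missing"
  band
}

#' HIV-specialist density band for a federal state
#'
#' States enter the regression not directly but through the density of
#' HIV-specialist physicians per 10,000 estimated gay men, grouped into
#' the five bands 0, 1-2, 3-5, 6-9 and 10-13. A state's real-valued
#' density is rounded to the nearest integer (half away from zero),
#' clamped to \[0, 13\], and assigned to the band containing it.
#'
#' @param state Character vector of federal state names (or `"missing"`).
#' @param map Named numeric vector, state -> specialists per 10,000 gay
#'   men; defaults to [default_density_map()].
#' @return Character vector of band labels; unmapped or missing states
#'   give `"missing"`.
#' @export
density_band <- function(state, map = default_density_map()) {
  d <- map[as.character(state)]
  r <- pmin(pmax(floor(d + 0.5), 0), 13)
  band <- rep("missing", length(state))
  known <- !is.na(r)
  labels <- c("0", "1-2", "3-5", "6-9", "10-13")
  lower <- c(0, 1, 3, 6, 10)
  band[known] <- labels[findInterval(r[known], lower)]
  band
}

#' Recode declined and don't-know answers as missing
#'
#' The answer options "I do not know" and "Prefer not to say" carry no
#' usable category information and are recoded to the `"missing"`
#' sentinel across every character column; all other values are kept.
#'
#' @param records Data frame of survey records.
#' @return The data frame with sentinels recoded.
#' @export
recode_missing <- function(records) {
  sentinels <- c("I do not know", "Prefer not to say")
  for (col in names(records)) {
    if (is.character(records[[col]])) {
      records[[col]][records[[col]] %in% sentinels] <- "missing"
    }
  }
  records
}

#' Default covariate grouping specification
#'
#' Ordered category lists for every modelled variable, matching the
#' survey's answer options after grouping. Category order fixes both the
#' design-matrix column order and the tie-break when two categories are
#' equally frequent (the earlier one becomes the reference).
#'
#' @return Named list, variable -> character vector of categories
#'   (excluding the `"missing"` sentinel, which is always permitted).
#' @export
default_grouping_spec <- function() {
  sti_levels <- c("0", "1", "2+")
  list(
    age_band = c("18-29", "30-39", "40-49", "50-80"),
    country_of_origin = c("Germany", "Outside Germany"),
    income_band = income_schema()$bands,
    density_band = c("0", "1-2", "3-5", "6-9", "10-13"),
    urban_rural = c("urban", "rural"),
    school_qualification = c("none", "class_8_9", "class_10", "a_levels"),
    satisfaction_sex_life = c("content", "discontent", "sex_not_important"),
    condom_use_category = c("0%", "25%", "50%", "75%", ">95%"),
    n_partners_6m_category = c("0", "1", "2-3", "4-5", "6-10", "11-20", ">20"),
    sdu_6m = c("yes", "no"),
    sti_syphilis_12m = sti_levels,
    sti_gonorrhea_12m = sti_levels,
    sti_chlamydia_12m = sti_levels,
    sti_hcv_12m = sti_levels,
    partner_male = c("no", "yes"),
    partner_female = c("no", "yes"),
    partner_nonbinary = c("no", "yes")
  )
}

#' Derive grouped analysis variables from a selected cohort
#'
#' Computes the derived covariates the regression uses: the age band from
#' age in years, the equivalised-income band from household income
#' category and household size, and the HIV-specialist density band from
#' the federal state. Raw fields already at analysis granularity are
#' passed through.
#'
#' @param cohort Cohort data frame (e.g. from [apply_selection_flow()]).
#' @param schema An [income_schema()].
#' @param density_map Named state -> density vector.
#' @return The cohort with `age_band`, `income_band` and `density_band`
#'   columns added.
#' @export
prepare_covariates <- function(cohort, schema = income_schema(),
                               density_map = default_density_map()) {
  age <- suppressWarnings(as.numeric(cohort$age_years))
  cuts <- c(18, 30, 40, 50, 81)
  lab <- c("18-29", "30-39", "40-49", "50-80")
  cohort$age_band <- ifelse(is.na(age), "missing", lab[findInterval(age, cuts)])
  eq <- equivalised_income(cohort$household_income_category,
                           ifelse(cohort$household_size %in% "missing",
                                  NA, cohort$household_size),
                           schema)
  cohort$income_band <- eq$band
  cohort$density_band <- density_band(cohort$federal_state, density_map)
  cohort
}

#' Build the one-hot design matrix
#'
#' Encodes the grouped covariates as binary indicator columns, one per
#' non-reference category, where the reference is the most frequent
#' non-missing category of each variable in the cohort (ties broken by
#' the grouping-spec order). Missing values are handled in one of two
#' modes: as their own indicator column per variable
#' (`"separate_category"`, the primary analysis) or folded into the
#' reference (`"reference"`, the sensitivity analysis, where rows with a
#' missing value are all-zero for that variable). Columns constant over
#' the cohort are inestimable and dropped.
#'
#' @param cohort Non-empty data frame holding every variable in
#'   `grouping_spec` (values must be spec categories or `"missing"`) and
#'   the outcome.
#' @param grouping_spec Named list, variable -> ordered categories; see
#'   [default_grouping_spec()].
#' @param missing_mode `"separate_category"` or `"reference"`.
#' @param outcome Name of the binary outcome column; coded 1 for current
#'   PrEP users and 0 for non-users via `outcome_level`.
#' @param outcome_level Value of the outcome column coded as 1.
#' @return An object of class `design_matrix`: list with the indicator
#'   matrix `x`, outcome vector `y`, per-column metadata `meta`
#'   (`column`, `variable`, `category`, `is_missing_indicator`), the
#'   per-variable `reference` categories, and `missing_mode`.
#' @export
build_design_matrix <- function(cohort, grouping_spec = default_grouping_spec(),
                                missing_mode = c("separate_category", "reference"),
                                outcome = "prep_status",
                                outcome_level = "current") {
  missing_mode <- match.arg(missing_mode)
  if (nrow(cohort) == 0) stop("cohort must be non-empty", call. = FALSE)
  if (!outcome %in% names(cohort)) {
    stop("outcome column `", outcome, "` not found", call. = FALSE)
  }
  y <- as.integer(cohort[[outcome]] == outcome_level)

  cols <- list()
  meta <- list()
  reference <- character(0)
  for (v in names(grouping_spec)) {
    cats <- grouping_spec[[v]]
    if (!v %in% names(cohort)) {
      stop("variable `", v, "` missing from cohort", call. = FALSE)
    }
    vals <- as.character(cohort[[v]])
    bad <- setdiff(unique(vals), c(cats, "missing"))
    if (length(bad) > 0) {
      stop("variable `", v, "`: value(s) outside grouping spec: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    counts <- vapply(cats, function(ct) sum(vals == ct), numeric(1))
    ref <- cats[which.max(counts)]  # which.max keeps first on ties: spec order
    reference[v] <- ref
    for (ct in setdiff(cats, ref)) {
      cols[[paste0(v, "=", ct)]] <- as.numeric(vals == ct)
      meta[[paste0(v, "=", ct)]] <- c(v, ct, FALSE)
    }
    if (missing_mode == "separate_category" && any(vals == "missing")) {
      cols[[paste0(v, "=missing")]] <- as.numeric(vals == "missing")
      meta[[paste0(v, "=missing")]] <- c(v, "missing", TRUE)
    }
  }
  x <- do.call(cbind, cols)
  if (is.null(x)) x <- matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  keep <- apply(x, 2, function(col) any(col != 0) && any(col != 1))
  x <- x[, keep, drop = FALSE]
  meta_df <- data.frame(
    column = colnames(x),
    variable = vapply(colnames(x), function(cn) meta[[cn]][1], character(1)),
    category = vapply(colnames(x), function(cn) meta[[cn]][2], character(1)),
    is_missing_indicator = vapply(colnames(x), function(cn)
      as.logical(meta[[cn]][3]), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(x = x, y = y, meta = meta_df, reference = reference,
                 missing_mode = missing_mode),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$x), "records,", ncol(x$x), "indicator columns,",
      sum(x$y), "cases /", sum(1 - x$y), "controls; missing_mode =",
      x$missing_mode, "\n")
  invisible(x)
}

#' Decode a design matrix back to grouped categories
#'
#' Inverts the encoding: for every variable, a row with an active
#' indicator takes that indicator's category, and an all-zero row takes
#' the reference. Exact inversion holds in `separate_category` mode for
#' variables whose columns were not dropped as constant; in `reference`
#' mode missing values decode to the reference by construction.
#'
#' @param dm A `design_matrix`.
#' @return Data frame of grouped categorical variables.
#' @export
decode_design_matrix <- function(dm) {
  stopifnot(inherits(dm, "design_matrix"))
  out <- list()
  for (v in names(dm$reference)) {
    vals <- rep(dm$reference[[v]], nrow(dm$x))
    vcols <- dm$meta$column[dm$meta$variable == v]
    for (cn in vcols) {
      hit <- dm$x[, cn] == 1
      vals[hit] <- dm$meta$category[dm$meta$column == cn]
    }
    out[[v]] <- vals
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}
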