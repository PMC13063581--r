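# Indication clauses operate on the behavioural fields of a record:
# sexualized drug use in the last 6 months, any bacterial STI (syphilis,
# gonorrhea, chlamydia) or hepatitis C diagnosis in the last 12 months,
# and >= 2 sex partners in the last 6 months combined -- for non-users
# only -- with low condom use (0-50%). A missing field never satisfies a
# clause: eligibility must be demonstrated, not assumed.

STI_COLS <- c("sti_syphilis_12m", "sti_gonorrhea_12m",
              "sti_chlamydia_12m", "sti_hcv_12m")
MULTI_PARTNER_CATS <- c("2-3", "4-5", "6-10", "11-20", ">20")
LOW_CONDOM_CATS <- c("0%", "25%", "50%")

sdu_clause <- function(records) {
  records$sdu_6m %in% "yes"
}

sti_clause <- function(records) {
  hit <- rep(FALSE, nrow(records))
  for (col in STI_COLS) hit <- hit | records[[col]] %in% c("1", "2+")
  hit
}

partner_clause <- function(records, role) {
  many <- records$n_partners_6m_category %in% MULTI_PARTNER_CATS
  if (role == "prep_non_user") {
    many & records$condom_use_category %in% LOW_CONDOM_CATS
  } else {
    # users already behave differently under PrEP, so the low-condom
    # requirement is waived for them
    many
  }
}

#' PrEP indication predicate
#'
#' A participant has a PrEP indication if at least one criterion holds:
#' sexualized drug use in the last six months; a syphilis, gonorrhea,
#' chlamydia or hepatitis C diagnosis in the last twelve months; or two
#' or more sex partners in the last six months combined with low condom
#' use (0-50% of contacts). For current PrEP users the low-condom-use
#' requirement is waived (two or more partners suffice), since condom
#' behaviour under PrEP is not informative about pre-PrEP eligibility.
#' Missing fields never satisfy a clause.
#'
#' @param records Data frame of participant records.
#' @param role `"prep_user"` or `"prep_non_user"`.
#' @return Logical vector.
#' @export
has_indication <- function(records, role = c("prep_non_user", "prep_user")) {
  role <- match.arg(role)
  sdu_clause(records) | sti_clause(records) | partner_clause(records, role)
}

#' Indication subgroup of an eligible record
#'
#' Partitions eligible participants by which criterion family fired:
#' `"sdu_only"` (sexualized drug use alone), `"partners_sti_hcv"`
#' (partner/condom and/or STI/hepatitis-C criteria alone) or `"both"`
#' (both families). The partner and STI clauses are one family, matching
#' how the stratified reason tables are laid out.
#'
#' @inheritParams has_indication
#' @return Character vector of subgroup labels.
#' @export
classify_subgroup <- function(records, role = c("prep_non_user", "prep_user")) {
  role <- match.arg(role)
  sdu <- sdu_clause(records)
  other <- sti_clause(records) | partner_clause(records, role)
  if (any(!sdu & !other)) {
    stop("classify_subgroup called on record(s) without indication",
         call. = FALSE)
  }
  ifelse(sdu & other, "both", ifelse(sdu, "sdu_only", "partners_sti_hcv"))
}

#' Participant selection flow
#'
#' Applies the analysis inclusion filters in their fixed order, keeping
#' an auditable ledger of counts at every step:
#' survey completed; cis-male (male gender identity and male sex assigned
#' at birth); PrEP status specified, former users removed; repeat
#' participants removed; non-users without confirmed HIV-negative status
#' removed; and finally the PrEP-indication filter applied per role.
#' Retained records are annotated with their `role` and, via
#' [classify_subgroup()], their `indication_subgroup`.
#'
#' @param records Data frame of participant records.
#' @return Object of class `analysis_cohort`: list with `records` (the
#'   retained rows plus `role` and `indication_subgroup`) and `ledger`
#'   (data frame `filter_name`, `n_before`, `n_removed`, `n_after`).
#' @export
apply_selection_flow <- function(records) {
  steps <- list(
    survey_completed = function(r) r$survey_completed %in% c(TRUE, "TRUE"),
    cis_male = function(r) r$gender_identity %in% "male" &
      r$sex_assigned_at_birth %in% "male",
    prep_status_known_not_former = function(r)
      r$prep_status %in% c("current", "never"),
    not_repeat_participant = function(r)
      !(r$prior_wave_participation %in% c(TRUE, "TRUE")),
    nonuser_hiv_negative_confirmed = function(r)
      r$prep_status %in% "current" |
        r$hiv_status_confirmed_negative %in% c(TRUE, "TRUE"),
    prep_indication = function(r) {
      role <- ifelse(r$prep_status %in% "current", "prep_user", "prep_non_user")
      ind <- rep(FALSE, nrow(r))
      ind[role == "prep_user"] <-
        has_indication(r[role == "prep_user", , drop = FALSE], "prep_user")
      ind[role == "prep_non_user"] <-
        has_indication(r[role == "prep_non_user", , drop = FALSE],
                       "prep_non_user")
      ind
    }
  )
  ledger <- data.frame(filter_name = names(steps),
                       n_before = NA_integer_, n_removed = NA_integer_,
                       n_after = NA_integer_)
  for (i in seq_along(steps)) {
    n_before <- nrow(records)
    keep <- if (n_before == 0) logical(0) else steps[[i]](records)
    records <- records[keep, , drop = FALSE]
    ledger$n_before[i] <- n_before
    ledger$n_removed[i] <- n_before - nrow(records)
    ledger$n_after[i] <- nrow(records)
  }
  if (nrow(records) > 0) {
    records$role <- ifelse(records$prep_status == "current",
                           "prep_user", "prep_non_user")
    records$indication_subgroup <- NA_character_
    for (rl in c("prep_user", "prep_non_user")) {
      sel <- records$role == rl
      if (any(sel)) {
        records$indication_subgroup[sel] <-
          classify_subgroup(records[sel, , drop = FALSE], rl)
      }
    }
  } else {
    records$role <- character(0)
    records$indication_subgroup <- character(0)
  }
  rownames(records) <- NULL
  structure(list(records = records, ledger = ledger),
            class = "analysis_cohort")
}

#' @export
print.analysis_cohort <- function(x, ...) {
  cat("analysis_cohort:", nrow(x$records), "records retained (",
      sum(x$records$role == "prep_user"), "users /",
      sum(x$records$role == "prep_non_user"), "non-users )\n")
  print(x$ledger, row.names = FALSE)
  invisible(x)
}
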