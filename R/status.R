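# ADA-based per-visit glycemic classification and longitudinal progression
# grouping.

.status_levels <- c("NGT", "PREDM", "DM")

#' Classify one OGTT visit by ADA criteria
#'
#' Diabetes when any of: current antidiabetic medication, fasting plasma
#' glucose >= 126 mg/dL, HbA1c >= 6.5%, or 2-hour post-load glucose >= 200
#' mg/dL. Otherwise prediabetes when any of: FPG in \[100, 126), HbA1c in
#' \[5.7, 6.5), or 2-h PG in \[140, 200). Otherwise NGT, provided at least one
#' criterion was evaluable (all present criteria below the prediabetes
#' cutoffs); with nothing evaluable the visit is `UNKNOWN`. All arguments are
#' vectorized.
#'
#' @param fpg fasting plasma glucose, mg/dL (or `NA`).
#' @param pg2h 2-hour post-load plasma glucose, mg/dL (or `NA`).
#' @param hba1c HbA1c, percent (or `NA`).
#' @param on_medication logical; current insulin or oral antidiabetic drug
#'   treatment (`NA` treated as `FALSE`).
#' @return character vector in `{"NGT","PREDM","DM","UNKNOWN"}`.
#' @export
classify_visit <- function(fpg = NA, pg2h = NA, hba1c = NA,
                           on_medication = FALSE) {
  n <- max(length(fpg), length(pg2h), length(hba1c), length(on_medication))
  fpg <- rep_len(as.numeric(fpg), n)
  pg2h <- rep_len(as.numeric(pg2h), n)
  hba1c <- rep_len(as.numeric(hba1c), n)
  med <- rep_len(as.logical(on_medication), n)
  med[is.na(med)] <- FALSE
  if (any(fpg < 0, na.rm = TRUE) || any(pg2h < 0, na.rm = TRUE) ||
      any(hba1c < 0, na.rm = TRUE)) {
    stop("negative glucose or HbA1c input")
  }
  has <- function(x) !is.na(x)
  dm <- med |
    (has(fpg) & fpg >= 126) |
    (has(hba1c) & hba1c >= 6.5) |
    (has(pg2h) & pg2h >= 200)
  predm <- (has(fpg) & fpg >= 100 & fpg < 126) |
    (has(hba1c) & hba1c >= 5.7 & hba1c < 6.5) |
    (has(pg2h) & pg2h >= 140 & pg2h < 200)
  evaluable <- med | has(fpg) | has(pg2h) | has(hba1c)
  out <- rep("UNKNOWN", n)
  out[evaluable] <- "NGT"
  out[predm] <- "PREDM"
  out[dm] <- "DM"
  out
}

#' Numeric severity of a glycemic status
#'
#' `NGT` < `PREDM` < `DM` (1, 2, 3); `UNKNOWN` maps to `NA`.
#' @param status character vector of statuses.
#' @return integer vector.
#' @export
status_severity <- function(status) {
  match(status, .status_levels)
}

#' Classify every visit of a cohort
#'
#' @param cohort a `glyco_cohort`.
#' @return the cohort with a `status` column appended.
#' @export
classify_cohort <- function(cohort) {
  cohort$status <- classify_visit(cohort$g0, cohort$g120, cohort$hba1c,
                                  cohort$on_medication)
  cohort
}

#' Filter a cohort to study-eligible participants
#'
#' Retains participants who, in this order of checks: (a) classify NGT at the
#' baseline visit, (b) carry no antidiabetic-medication flag at baseline,
#' (c) have a fully evaluable baseline OGTT (`g0`, `g120` and `hba1c` all
#' present, so the NGT call is conjunctive over all three criteria), and
#' (d) have a year-10 visit (index 5) with at least one OGTT analyte present.
#' Each removed participant gets one exclusion reason - the first failing
#' rule.
#'
#' @param cohort a `glyco_cohort`.
#' @return list with `cohort` (eligible subset, a `glyco_cohort`) and
#'   `exclusions` (data frame `id`, `reason`).
#' @export
filter_eligible <- function(cohort) {
  ids <- unique(cohort$id)
  base <- cohort[cohort$visit_index == 0, , drop = FALSE]
  base <- base[match(ids, base$id), , drop = FALSE]
  v5 <- cohort[cohort$visit_index == 5, , drop = FALSE]
  v5 <- v5[match(ids, v5$id), , drop = FALSE]

  reason <- rep(NA_character_, length(ids))
  no_base <- is.na(base$id)
  reason[no_base] <- "no baseline visit"

  base_status <- classify_visit(base$g0, base$g120, base$hba1c,
                                base$on_medication)
  fail_a <- !no_base & base_status != "NGT"
  reason[is.na(reason) & fail_a] <- "baseline not NGT"

  fail_b <- !no_base & !is.na(base$on_medication) & base$on_medication
  reason[is.na(reason) & fail_b] <- "baseline antidiabetic medication"

  fail_c <- !no_base & (is.na(base$g0) | is.na(base$g120) | is.na(base$hba1c))
  reason[is.na(reason) & fail_c] <- "baseline OGTT incomplete"

  ogtt_cols <- c("g0", "g60", "g120", "i0", "i60", "i120")
  has_v5 <- !is.na(v5$id) &
    rowSums(!is.na(as.matrix(v5[, ogtt_cols]))) > 0
  reason[is.na(reason) & !has_v5] <- "no year-10 OGTT"

  keep_ids <- ids[is.na(reason)]
  excl <- data.frame(id = ids[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  kept <- cohort[cohort$id %in% keep_ids, , drop = FALSE]
  kept <- as_cohort(kept, provenance = attr(cohort, "provenance") %||%
                      "filtered")
  list(cohort = kept, exclusions = excl)
}

#' Assign longitudinal progression groups
#'
#' Labels each participant by their post-baseline glycemic course. Under
#' `"ever-worst"` (default) the label is the maximum severity attained at any
#' post-baseline visit: any diabetes visit gives `T2D_P`, else any prediabetes
#' visit gives `PREDM_P`, else `NON_P`. Under `"final-visit"` the label is the
#' status at the last post-baseline visit with a known status. `UNKNOWN`
#' visits are skipped, never imputed.
#'
#' @param cohort a `glyco_cohort` (status computed internally if absent).
#' @param rule `"ever-worst"` or `"final-visit"`.
#' @return data frame `id`, `progression` (`NON_P`, `PREDM_P`, `T2D_P`).
#' @export
assign_progression <- function(cohort, rule = c("ever-worst", "final-visit")) {
  rule <- match.arg(rule)
  if (!"status" %in% names(cohort)) cohort <- classify_cohort(cohort)
  post <- cohort[cohort$visit_index > 0 & cohort$status != "UNKNOWN", ,
                 drop = FALSE]
  ids <- unique(cohort$id)
  if (!all(ids %in% post$id)) {
    missing_ids <- setdiff(ids, post$id)
    stop("no evaluable post-baseline visit for: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  sev <- status_severity(post$status)
  if (rule == "ever-worst") {
    worst <- tapply(sev, post$id, max)
  } else {
    ord <- order(post$id, post$visit_index)
    last <- tapply(sev[ord], post$id[ord], function(s) s[length(s)])
    worst <- last
  }
  prog <- c("NON_P", "PREDM_P", "T2D_P")[worst[ids]]
  data.frame(id = ids, progression = prog, stringsAsFactors = FALSE)
}
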