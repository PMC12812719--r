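# OGTT surrogate indices of insulin sensitivity and beta-cell function, and
# the 10-year change statistics built from them. Undefined values propagate
# as NA, never as numeric sentinels.

#' Trapezoidal mean over the 0/60/120-min OGTT
#'
#' The trapezoidal AUC over 0-120 min divided by 120 min, which reduces to
#' `(v0 + 2*v60 + v120) / 4`.
#'
#' @param v0,v60,v120 values at 0, 60 and 120 minutes (same units);
#'   vectorized.
#' @return same units; `NA` where any value is absent or negative.
#' @export
trapezoid_mean <- function(v0, v60, v120) {
  out <- (v0 + 2 * v60 + v120) / 4
  out[!is.na(v0) & v0 < 0] <- NA_real_
  out[!is.na(v60) & v60 < 0] <- NA_real_
  out[!is.na(v120) & v120 < 0] <- NA_real_
  out
}

#' Matsuda whole-body insulin sensitivity index
#'
#' `10000 / sqrt(Ibar * Gbar * I0 * G0)` with glucose in mg/dL, insulin in
#' uU/mL, and `Ibar`, `Gbar` the trapezoidal means over the 0/60/120-min OGTT.
#'
#' @param g0,g60,g120 glucose, mg/dL.
#' @param i0,i60,i120 insulin, uU/mL.
#' @return dimensionless; `NA` where any input is absent or non-positive.
#' @export
matsuda_index <- function(g0, g60, g120, i0, i60, i120) {
  gbar <- trapezoid_mean(g0, g60, g120)
  ibar <- trapezoid_mean(i0, i60, i120)
  out <- 10000 / sqrt(ibar * gbar * i0 * g0)
  bad <- is.na(g0) | is.na(g60) | is.na(g120) |
    is.na(i0) | is.na(i60) | is.na(i120) |
    g0 <= 0 | g60 <= 0 | g120 <= 0 | i0 <= 0 | i60 <= 0 | i120 <= 0
  out[bad] <- NA_real_
  out
}

#' HOMA insulin sensitivity and resistance
#'
#' `homa_is = 405 / (i0 * g0)`; `homa_ir` is its reciprocal
#' `i0 * g0 / 405`.
#'
#' @param g0 fasting glucose, mg/dL.
#' @param i0 fasting insulin, uU/mL.
#' @return dimensionless; `NA` where either input is absent or non-positive.
#' @export
homa_is <- function(g0, i0) {
  out <- 405 / (i0 * g0)
  out[is.na(g0) | is.na(i0) | g0 <= 0 | i0 <= 0] <- NA_real_
  out
}

#' @rdname homa_is
#' @export
homa_ir <- function(g0, i0) {
  out <- i0 * g0 / 405
  out[is.na(g0) | is.na(i0) | g0 <= 0 | i0 <= 0] <- NA_real_
  out
}

#' HOMA beta-cell function
#'
#' `360 * i0 / (g0 - 63)`; undefined (with a logged message) at
#' `g0 <= 63` mg/dL where the denominator degenerates.
#'
#' @param g0 fasting glucose, mg/dL.
#' @param i0 fasting insulin, uU/mL.
#' @return dimensionless; `NA` where undefined.
#' @export
homa_beta <- function(g0, i0) {
  out <- 360 * i0 / (g0 - 63)
  bad <- is.na(g0) | is.na(i0) | i0 <= 0 | g0 <= 63
  n_degenerate <- sum(!is.na(g0) & g0 <= 63)
  if (n_degenerate > 0) {
    message("homa_beta undefined for ", n_degenerate,
            " value(s) with g0 <= 63 mg/dL")
  }
  out[bad] <- NA_real_
  out
}

#' Insulinogenic index over 0-60 minutes
#'
#' Early-phase insulin secretion surrogate
#' `(i60 - i0) / (g60 - g0)`, in (uU/mL)/(mg/dL). May legitimately be
#' negative; undefined when the glucose increment is zero.
#'
#' @param g0,g60 glucose, mg/dL.
#' @param i0,i60 insulin, uU/mL.
#' @return (uU/mL)/(mg/dL); `NA` where undefined.
#' @export
igi60 <- function(g0, g60, i0, i60) {
  out <- (i60 - i0) / (g60 - g0)
  out[is.na(g0) | is.na(g60) | is.na(i0) | is.na(i60) | g60 == g0] <- NA_real_
  out
}

#' Disposition index
#'
#' Product of an insulin-sensitivity measure and a beta-cell measure; used
#' both for the oral disposition index (Matsuda x IGI60) and for externally
#' supplied model-derived pairs.
#'
#' @param is_value insulin-sensitivity measure.
#' @param bcf_value beta-cell-function measure.
#' @return product; `NA` where either factor is undefined.
#' @export
disposition_index <- function(is_value, bcf_value) {
  is_value * bcf_value
}

#' Decline from baseline to year 10
#'
#' `x_baseline - x_year10`; by convention positive values mean decline.
#'
#' @param x_baseline,x_year10 measure at year 0 and year 10.
#' @return change; `NA` where either is undefined.
#' @export
delta_decline <- function(x_baseline, x_year10) {
  x_baseline - x_year10
}

#' Percent decline from baseline
#'
#' `100 * (x_baseline - x_year10) / x_baseline`; undefined for non-positive
#' baselines.
#'
#' @inheritParams delta_decline
#' @return percent; `NA` where undefined.
#' @export
percent_decline <- function(x_baseline, x_year10) {
  out <- 100 * (x_baseline - x_year10) / x_baseline
  out[!is.na(x_baseline) & x_baseline <= 0] <- NA_real_
  out
}

#' Append surrogate indices to every cohort visit
#'
#' Adds `matsuda`, `homa_is`, `homa_ir`, `homa_beta`, `igi60` and `odi`
#' (Matsuda x IGI60) columns. Externally computed model-derived columns
#' (`msi`, `mbcf`) merged beforehand with [merge_model_derived()] get their
#' product `mdi` appended too.
#'
#' @param cohort a `glyco_cohort`.
#' @return the cohort with index columns appended.
#' @export
compute_indices <- function(cohort) {
  cohort$matsuda <- matsuda_index(cohort$g0, cohort$g60, cohort$g120,
                                  cohort$i0, cohort$i60, cohort$i120)
  cohort$homa_is <- homa_is(cohort$g0, cohort$i0)
  cohort$homa_ir <- homa_ir(cohort$g0, cohort$i0)
  cohort$homa_beta <- suppressMessages(homa_beta(cohort$g0, cohort$i0))
  cohort$igi60 <- igi60(cohort$g0, cohort$g60, cohort$i0, cohort$i60)
  cohort$odi <- disposition_index(cohort$matsuda, cohort$igi60)
  if (all(c("msi", "mbcf") %in% names(cohort))) {
    cohort$mdi <- disposition_index(cohort$msi, cohort$mbcf)
  }
  cohort
}

#' Merge externally computed model-derived indices
#'
#' Plug-in slot for insulin sensitivity / beta-cell function values computed
#' outside this package (e.g. by a physiological model): a CSV or data frame
#' with columns `id`, `visit_index` and any of `msi`, `mbcf`, `mdi` is merged
#' by participant and visit.
#'
#' @param cohort a `glyco_cohort`.
#' @param model_derived data frame or CSV path.
#' @return the cohort with the supplied columns appended.
#' @export
merge_model_derived <- function(cohort, model_derived) {
  if (is.character(model_derived)) {
    model_derived <- utils::read.csv(model_derived, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "visit_index") %in% names(model_derived)))
  value_cols <- intersect(c("msi", "mbcf", "mdi"), names(model_derived))
  if (!length(value_cols)) stop("no msi/mbcf/mdi columns to merge")
  key_c <- paste(cohort$id, cohort$visit_index)
  key_m <- paste(model_derived$id, model_derived$visit_index)
  idx <- match(key_c, key_m)
  for (col in value_cols) cohort[[col]] <- model_derived[[col]][idx]
  cohort
}

#' Per-participant 10-year change statistics (DIS, DBCF)
#'
#' Computes, for each participant with a baseline (visit 0) and year-10
#' (visit 5) value of the chosen measures, the declines
#' `dis = IS(year 0) - IS(year 10)` and `dbcf = BCF(year 0) - BCF(year 10)`
#' (positive = decline), plus the baseline values and baseline covariates.
#'
#' @param cohort a `glyco_cohort` with indices ([compute_indices()]) already
#'   appended (and model-derived columns merged, if used).
#' @param measures length-2 character vector naming the insulin-sensitivity
#'   and beta-cell columns, default `c(is = "matsuda", bcf = "igi60")`; use
#'   `c(is = "msi", bcf = "mbcf")` for externally supplied values.
#' @return data frame with one row per participant: `id`, `is0`, `is10`,
#'   `bcf0`, `bcf10`, `dis`, `dbcf`, `sex`, `baseline_age`, `bmi0`;
#'   attribute `which_measures` records the measure pair.
#' @export
compute_deltas <- function(cohort, measures = c(is = "matsuda",
                                                bcf = "igi60")) {
  is_col <- unname(measures[1]); bcf_col <- unname(measures[2])
  for (col in c(is_col, bcf_col)) {
    if (!col %in% names(cohort)) {
      stop("measure column not present in cohort: ", col,
           " (run compute_indices() or merge_model_derived() first)")
    }
  }
  ids <- unique(cohort$id)
  b <- cohort[cohort$visit_index == 0, , drop = FALSE]
  b <- b[match(ids, b$id), , drop = FALSE]
  y10 <- cohort[cohort$visit_index == 5, , drop = FALSE]
  y10 <- y10[match(ids, y10$id), , drop = FALSE]
  out <- data.frame(id = ids,
                    is0 = b[[is_col]], is10 = y10[[is_col]],
                    bcf0 = b[[bcf_col]], bcf10 = y10[[bcf_col]],
                    stringsAsFactors = FALSE)
  out$dis <- delta_decline(out$is0, out$is10)
  out$dbcf <- delta_decline(out$bcf0, out$bcf10)
  out$sex <- b$sex
  out$baseline_age <- b$baseline_age
  out$bmi0 <- b$bmi
  attr(out, "which_measures") <- c(is = is_col, bcf = bcf_col)
  out
}
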