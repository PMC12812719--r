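# End-to-end progression analysis: eligibility -> classification -> indices
# -> strata -> incidence -> model suite -> trajectories.

#' Run the full dysglycemia-progression analysis
#'
#' Applies, in order: study-eligibility filtering ([filter_eligible()]),
#' per-visit glycemic classification, progression-group assignment
#' ([assign_progression()]), surrogate-index computation
#' ([compute_indices()]), 10-year decline statistics ([compute_deltas()]),
#' median stratification ([assign_strata()]), the stratified incidence table
#' ([stratified_incidence()]), the three-model logistic suite
#' ([model_suite()]), per-group index trajectories and a baseline
#' between-group comparison table.
#'
#' @param cohort a `glyco_cohort`.
#' @param rule progression rule, `"ever-worst"` (default) or
#'   `"final-visit"`.
#' @param measures insulin-sensitivity / beta-cell measure pair for the
#'   decline statistics, default `c(is = "matsuda", bcf = "igi60")`; use
#'   `c(is = "msi", bcf = "mbcf")` with `model_derived` for externally
#'   computed values.
#' @param model_derived optional CSV path or data frame merged via
#'   [merge_model_derived()].
#' @return object of class `glyco_analysis` with components `cohort`
#'   (eligible, classified, indexed), `exclusions`, `progression`, `deltas`
#'   (with strata), `incidence`, `suite`, `trajectories` (one data frame per
#'   measure), `baseline_tests`, `counts`, `settings`. Methods: `print`,
#'   `summary`, `coef`, `plot`.
#' @export
progression_analysis <- function(cohort,
                                 rule = c("ever-worst", "final-visit"),
                                 measures = c(is = "matsuda", bcf = "igi60"),
                                 model_derived = NULL) {
  rule <- match.arg(rule)
  flt <- filter_eligible(cohort)
  eligible <- flt$cohort
  if (length(unique(eligible$id)) < 10) {
    stop("fewer than 10 eligible participants")
  }
  eligible <- classify_cohort(eligible)
  if (!is.null(model_derived)) {
    eligible <- merge_model_derived(eligible, model_derived)
  }
  eligible <- compute_indices(eligible)
  progression <- assign_progression(eligible, rule = rule)
  deltas <- compute_deltas(eligible, measures = measures)
  deltas <- merge(deltas, progression, by = "id", sort = FALSE)
  deltas <- assign_strata(deltas)

  complete <- !is.na(deltas$bcf_stratum) & !is.na(deltas$dis_stratum) &
    !is.na(deltas$progression)
  incidence <- stratified_incidence(deltas[complete, , drop = FALSE])

  suite_data <- deltas[stats::complete.cases(
    deltas[, c("dis", "dbcf", "is0", "bcf0", "sex", "baseline_age",
               "bmi0", "progression")]), , drop = FALSE]
  suite <- model_suite(suite_data)

  trajectories <- list()
  for (col in unique(unname(measures))) {
    trajectories[[col]] <- trajectory_summary(eligible, progression,
                                              measure = col)
  }

  base <- eligible[eligible$visit_index == 0, , drop = FALSE]
  base <- merge(base, progression, by = "id")
  baseline_tests <- list()
  for (col in c("baseline_age", "bmi", "fat_mass", "g0", "g60", "g120",
                "hba1c")) {
    v <- base[[col]]
    if (sum(!is.na(v)) >= 6) {
      baseline_tests[[col]] <- group_tests(v, base$progression)
    }
  }

  out <- list(cohort = eligible, exclusions = flt$exclusions,
              progression = progression, deltas = deltas,
              incidence = incidence, suite = suite,
              trajectories = trajectories,
              baseline_tests = baseline_tests,
              counts = list(
                input_participants = length(unique(cohort$id)),
                eligible = length(unique(eligible$id)),
                excluded = nrow(flt$exclusions),
                by_group = table(progression$progression)),
              settings = list(rule = rule, measures = measures))
  class(out) <- "glyco_analysis"
  out
}

#' @export
print.glyco_analysis <- function(x, ...) {
  cat("Dysglycemia progression analysis\n")
  cat("  eligible participants:", x$counts$eligible, "of",
      x$counts$input_participants,
      sprintf("(%d excluded)\n", x$counts$excluded))
  tab <- x$counts$by_group
  cat("  progression groups (rule ", x$settings$rule, "): ",
      paste(names(tab), as.integer(tab), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  measures: IS = ", x$settings$measures[1],
      ", BCF = ", x$settings$measures[2], "\n\n", sep = "")
  print(x$incidence)
  cat("\n")
  print(x$suite)
  invisible(x)
}

#' @export
summary.glyco_analysis <- function(object, ...) {
  print(object)
  cat("\nExclusions:\n")
  print(table(object$exclusions$reason))
  is_col <- object$settings$measures[1]
  cat("\nTrajectory of", is_col, "(group means by visit):\n")
  tr <- object$trajectories[[is_col]]
  print(format_trajectory(tr), row.names = FALSE)
  invisible(object)
}

#' @export
coef.glyco_analysis <- function(object, ...) {
  rows <- list()
  for (oc in names(object$suite$fits)) {
    for (m in names(object$suite$fits[[oc]])) {
      fit <- object$suite$fits[[oc]][[m]]
      for (param in intersect(c("dis", "dbcf"),
                              rownames(fit$coefficients))) {
        rows[[length(rows) + 1]] <- data.frame(
          outcome = oc, model = as.integer(m), parameter = param,
          beta = fit$coefficients[param, "estimate"],
          beta_std = fit$standardized[param, "estimate"],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
plot.glyco_analysis <- function(x, measure = NULL, ...) {
  measure <- measure %||% unname(x$settings$measures[1])
  tr <- x$trajectories[[measure]]
  if (is.null(tr)) stop("no trajectory for measure ", measure)
  groups <- unique(tr$progression)
  years <- 2 * sort(unique(tr$visit_index))
  cols <- c(NON_P = "forestgreen", PREDM_P = "orange", T2D_P = "firebrick")
  ylim <- range(tr$mean, na.rm = TRUE)
  graphics::plot(NA, xlim = range(years), ylim = ylim,
                 xlab = "Years of follow-up", ylab = measure,
                 main = paste("Group-mean", measure, "trajectory"), ...)
  for (g in groups) {
    d <- tr[tr$progression == g, ]
    graphics::lines(2 * d$visit_index, d$mean, col = cols[[g]] %||% "grey40",
                    lwd = 2, type = "b", pch = 16)
  }
  graphics::legend("topright", legend = groups, lwd = 2,
                   col = vapply(groups,
                                function(g) cols[[g]] %||% "grey40", ""))
  invisible(x)
}
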