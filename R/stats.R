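# Median stratification, stratified incidence tables and group-comparison
# tests.

#' Median split into low/high strata
#'
#' Elements strictly above the sample median get the high label; elements at
#' or below the median go to the low side (so with odd n the median element
#' itself is low). `NA` values stay unlabeled.
#'
#' @param values numeric vector with at least 2 defined values.
#' @param labels length-2 character vector `c(low, high)`.
#' @return character vector of labels (with `NA` for undefined values).
#' @export
median_split <- function(values, labels = c("LOW", "HIGH")) {
  defined <- !is.na(values)
  if (sum(defined) < 2) stop("median_split needs at least 2 defined values")
  med <- stats::median(values[defined])
  if (all(values[defined] == values[defined][1])) {
    warning("all values identical; every element labeled '", labels[1], "'")
  }
  out <- rep(NA_character_, length(values))
  out[defined] <- ifelse(values[defined] > med, labels[2], labels[1])
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' The uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on the table
#' `rbind(c(a, b), c(c, d))`, referred to chi-square with 1 df. No Yates
#' continuity correction.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return list `statistic`, `df`, `p_value`, `undefined` (`TRUE` with a zero
#'   margin, where the statistic does not exist).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0), a + b + c + d > 0)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_,
                undefined = TRUE))
  }
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       undefined = FALSE)
}

#' Stratified incidence table
#'
#' Cross-tabulates progression outcome by beta-cell-function stratum
#' (low/high at baseline) and insulin-sensitivity-decline stratum
#' (large/small), with within-column percentages and, for each BCF stratum
#' and outcome, the 2x2 chi-square p-value comparing large vs small DIS
#' (outcome vs rest).
#'
#' @param labels data frame with columns `bcf_stratum` (`"LOW"`/`"HIGH"`),
#'   `dis_stratum` (`"LARGE"`/`"SMALL"`) and `progression`
#'   (`"NON_P"`/`"PREDM_P"`/`"T2D_P"`), one row per participant.
#' @return object of class `glyco_incidence`: list with `counts` (outcome x
#'   column matrix over columns LOW.LARGE, LOW.SMALL, HIGH.LARGE,
#'   HIGH.SMALL), `n` (column totals), `pct` (within-column percentages,
#'   1 decimal), `p_values` (BCF stratum x outcome matrix).
#' @export
stratified_incidence <- function(labels) {
  stopifnot(all(c("bcf_stratum", "dis_stratum", "progression") %in%
                  names(labels)))
  bcf <- factor(labels$bcf_stratum, levels = c("LOW", "HIGH"))
  dis <- factor(labels$dis_stratum, levels = c("LARGE", "SMALL"))
  prog <- factor(labels$progression, levels = c("T2D_P", "PREDM_P", "NON_P"))
  if (anyNA(bcf) || anyNA(dis) || anyNA(prog)) {
    stop("every participant must carry bcf/dis stratum and progression labels")
  }
  tab <- table(prog, dis, bcf)
  counts <- cbind(LOW.LARGE = tab[, "LARGE", "LOW"],
                  LOW.SMALL = tab[, "SMALL", "LOW"],
                  HIGH.LARGE = tab[, "LARGE", "HIGH"],
                  HIGH.SMALL = tab[, "SMALL", "HIGH"])
  n_col <- colSums(counts)
  pct <- counts
  for (j in seq_len(ncol(counts))) {
    pct[, j] <- if (n_col[j] > 0) {
      round_half_up(100 * counts[, j] / n_col[j], 1)
    } else NA_real_
  }
  p_values <- matrix(NA_real_, 2, 3,
                     dimnames = list(c("LOW", "HIGH"), rownames(counts)))
  for (stratum in c("LOW", "HIGH")) {
    large <- counts[, paste0(stratum, ".LARGE")]
    small <- counts[, paste0(stratum, ".SMALL")]
    if (sum(large) + sum(small) == 0) next  # empty stratum: undefined
    for (outcome in rownames(counts)) {
      res <- chi_square_2x2(large[outcome], sum(large) - large[outcome],
                            small[outcome], sum(small) - small[outcome])
      p_values[stratum, outcome] <- res$p_value
    }
  }
  out <- list(counts = counts, n = n_col, pct = pct, p_values = p_values,
              total = sum(counts))
  class(out) <- "glyco_incidence"
  out
}

#' @export
print.glyco_incidence <- function(x, ...) {
  cat("Incidence by baseline BCF stratum and insulin-sensitivity decline\n")
  hdr <- sprintf("%-8s %s", "",
                 paste(sprintf("%-18s", colnames(x$counts)), collapse = ""))
  cat(hdr, "\n")
  cat(sprintf("%-8s %s", "N",
              paste(sprintf("%-18d", x$n), collapse = "")), "\n")
  for (outcome in rownames(x$counts)) {
    cells <- sprintf("%-18s",
                     fmt_count_pct(x$counts[outcome, ], x$n))
    cat(sprintf("%-8s %s", outcome, paste(cells, collapse = "")), "\n")
  }
  cat("large-vs-small DIS chi-square p-values (columns = outcome):\n")
  print(signif(x$p_values, 3))
  invisible(x)
}

#' Group comparison tests with Bonferroni post hoc
#'
#' Two groups: classic pooled-variance two-sample t-test. Three or more:
#' one-way ANOVA F test, with Bonferroni-adjusted pairwise pooled t-tests
#' (raw pairwise p multiplied by the number of pairs, capped at 1).
#'
#' @param values numeric vector.
#' @param group grouping vector (2+ levels, each with n >= 2).
#' @return list `method`, `statistic`, `df`, `p_value`, and for 3+ groups
#'   `posthoc` (data frame of pairwise comparisons).
#' @export
group_tests <- function(values, group) {
  group <- factor(group)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  ns <- table(group)
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (k == 2) {
    tt <- stats::t.test(values ~ group, var.equal = TRUE)
    return(list(method = "two-sample t-test (pooled variance)",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value))
  }
  fit <- stats::aov(values ~ group)
  an <- stats::anova(fit)
  pairs <- utils::combn(levels(group), 2)
  m <- ncol(pairs)
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        p_raw = NA_real_, p_bonferroni = NA_real_,
                        stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    sel <- group %in% pairs[, j]
    tt <- stats::t.test(values[sel] ~ droplevels(group[sel]),
                        var.equal = TRUE)
    posthoc$p_raw[j] <- tt$p.value
    posthoc$p_bonferroni[j] <- min(1, tt$p.value * m)
  }
  list(method = "one-way ANOVA",
       statistic = an[["F value"]][1],
       df = c(an$Df[1], an$Df[2]),
       p_value = an[["Pr(>F)"]][1],
       posthoc = posthoc)
}

#' Per-group per-visit trajectory summary
#'
#' For one index column: group x visit sample size, mean, SD, percent decline
#' of the group mean from baseline, and a paired t-test of each visit against
#' baseline (within participants observed at both), flagged at p < 0.05.
#'
#' @param cohort a `glyco_cohort` with the index column present.
#' @param progression data frame `id`, `progression`
#'   (from [assign_progression()] or a generator label set).
#' @param measure index column name, default `"matsuda"`.
#' @return data frame `progression`, `visit_index`, `n`, `mean`, `sd`,
#'   `pct_decline`, `p_vs_baseline`, `significant`.
#' @export
trajectory_summary <- function(cohort, progression, measure = "matsuda") {
  stopifnot(measure %in% names(cohort))
  df <- merge(as.data.frame(cohort)[, c("id", "visit_index", measure)],
              progression, by = "id")
  names(df)[names(df) == measure] <- "value"
  groups <- sort(unique(df$progression))
  rows <- list()
  for (g in groups) {
    dg <- df[df$progression == g, , drop = FALSE]
    base <- dg[dg$visit_index == 0, c("id", "value")]
    names(base)[2] <- "value0"
    mean0 <- mean(base$value0, na.rm = TRUE)
    for (v in sort(unique(dg$visit_index))) {
      dv <- dg[dg$visit_index == v, , drop = FALSE]
      vals <- dv$value[!is.na(dv$value)]
      p <- NA_real_
      if (v > 0) {
        paired <- merge(dv[, c("id", "value")], base, by = "id")
        paired <- paired[stats::complete.cases(paired), , drop = FALSE]
        if (nrow(paired) >= 2 &&
            stats::sd(paired$value - paired$value0) > 0) {
          p <- stats::t.test(paired$value, paired$value0,
                             paired = TRUE)$p.value
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        progression = g, visit_index = v, n = length(vals),
        mean = mean(vals), sd = stats::sd(vals),
        pct_decline = if (v == 0) 0 else
          percent_decline(mean0, mean(vals)),
        p_vs_baseline = p,
        significant = !is.na(p) & p < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Assign the analysis strata
#'
#' Baseline beta-cell function is split low/high at its median over the
#' supplied participants; the insulin-sensitivity decline (DIS) is split
#' large/small at its median *within* each BCF stratum (the stratum-specific
#' split is what makes the four column sizes near-equal).
#'
#' @param deltas data frame from [compute_deltas()].
#' @return `deltas` with `bcf_stratum` (`LOW`/`HIGH`) and `dis_stratum`
#'   (`LARGE`/`SMALL`) columns appended.
#' @export
assign_strata <- function(deltas) {
  deltas$bcf_stratum <- median_split(deltas$bcf0, c("LOW", "HIGH"))
  deltas$dis_stratum <- NA_character_
  for (stratum in c("LOW", "HIGH")) {
    sel <- !is.na(deltas$bcf_stratum) & deltas$bcf_stratum == stratum
    if (sum(sel) >= 2) {
      deltas$dis_stratum[sel] <-
        median_split(deltas$dis[sel], c("SMALL", "LARGE"))
    }
  }
  deltas
}
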