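# Synthetic longitudinal OGTT cohort generator.
#
# Observation model: each participant carries latent insulin sensitivity
# (SI, on the HOMA-IS scale) and beta-cell function (BCF, on the IGI scale)
# that decline log-linearly over 10 years to group-specific fractional
# declines (with per-subject slope jitter). Measurements are synthesized by
# inverting the surrogate-index relations: fasting insulin from glucose and
# SI through the HOMA-IS identity, the 0-60-min insulin increment from the
# glucose increment and BCF through the IGI identity, and post-load glucose
# excursions rising as the disposition (SI x BCF) falls. Multiplicative
# log-normal measurement noise is applied to each analyte.

.sim_groups <- c("NON_P", "PREDM_P", "T2D_P")

#' Simulation configuration for synthetic cohorts
#'
#' Defaults encode the study conditions of a lean East Asian adult cohort
#' followed biannually for 10 years: group sizes 824/1803/183 of 2810
#' (non-progressors, progressors to prediabetes, progressors to diabetes),
#' group-conditional baseline OGTT and anthropometric distributions, 10-year
#' fractional declines of latent insulin sensitivity (16.8/31.0/46.2%) and
#' beta-cell function (9.4/18.4/43.6%), BMI and fat-mass drift confined to
#' the progressor groups, and a 10% per-visit missing-follow-up probability.
#' Group-indexed vectors are ordered (non-progressor, prediabetes
#' progressor, diabetes progressor).
#'
#' @param n number of participants.
#' @param group_probs probabilities of the three progression groups
#'   (must sum to 1).
#' @param seed integer seed fixing all randomness, or `NULL`.
#' @param g0_mean,g0_sd baseline fasting glucose, mg/dL.
#' @param d60_mean,d120_mean mean baseline glucose increments at 60/120 min,
#'   mg/dL; `delta_sdlog` is their between-subject log-scale SD.
#' @param si_mean,si_sdlog latent baseline insulin sensitivity (HOMA-IS
#'   scale; log-normal).
#' @param bcf_mean,bcf_sdlog latent baseline beta-cell function (IGI scale;
#'   log-normal).
#' @param si_decline,bcf_decline 10-year fractional declines in \[0, 1).
#' @param slope_jitter_sd per-subject SD of the per-year log-decline slope.
#' @param alpha_g0,alpha_g60,alpha_g120 elasticities tying fasting glucose
#'   and the 60/120-min increments to the fall in disposition
#'   (`value_t = value_0 * (DI_0/DI_t)^alpha`).
#' @param i120_fraction 120-min insulin increment as a fraction of the
#'   60-min increment.
#' @param hba1c_intercept,hba1c_slope,hba1c_sd HbA1c as a noisy linear
#'   function of latent mean OGTT glucose.
#' @param glucose_cv,insulin_cv multiplicative measurement noise
#'   (coefficients of variation).
#' @param bmi_mean,bmi_sd,bmi_drift,bmi_noise_sd baseline BMI and per-year
#'   drift per group.
#' @param fat_mean,fat_sd,fat_drift,fat_noise_sd body fat mass, kg.
#' @param p_male,age_mean,age_sd demographics per group.
#' @param missing_prob probability each follow-up visit (index 1..5) is
#'   missing; visit 0 is never dropped.
#' @param missing_mechanism `"MCAR"` or `"MAR-BMI"` (drop probability rises
#'   with baseline BMI on the logit scale with slope `mar_coef` per BMI SD).
#' @param mar_coef logit slope for the MAR mechanism.
#' @param inject optional list from [inject_effects()]; when present,
#'   progression labels are drawn from a logistic model on the realized
#'   decline statistics instead of the latent group assignment.
#' @return object of class `glyco_simconfig` (a named list).
#' @export
sim_config <- function(n = 2810,
                       group_probs = c(824, 1803, 183) / 2810,
                       seed = NULL,
                       g0_mean = c(78.7, 81.1, 82.3),
                       g0_sd = c(6.3, 6.7, 7.9),
                       d60_mean = c(33.8, 47.2, 65.2),
                       d120_mean = c(17.0, 22.3, 26.1),
                       delta_sdlog = 0.35,
                       si_mean = c(0.87, 0.77, 0.76),
                       si_sdlog = 0.40,
                       bcf_mean = c(0.63, 0.50, 0.42),
                       bcf_sdlog = 0.40,
                       si_decline = c(0.168, 0.310, 0.462),
                       bcf_decline = c(0.094, 0.184, 0.436),
                       slope_jitter_sd = 0.015,
                       alpha_g0 = 0.30,
                       alpha_g60 = 1.0,
                       alpha_g120 = 1.1,
                       i120_fraction = 0.72,
                       hba1c_intercept = 4.35,
                       hba1c_slope = 0.009,
                       hba1c_sd = 0.15,
                       glucose_cv = 0.05,
                       insulin_cv = 0.20,
                       bmi_mean = c(23.6, 24.4, 24.2),
                       bmi_sd = c(2.8, 2.9, 3.1),
                       bmi_drift = c(0, 0.04, 0.05),
                       bmi_noise_sd = 0.3,
                       fat_mean = c(15.3, 16.7, 16.3),
                       fat_sd = c(4.7, 5.0, 4.9),
                       fat_drift = c(0, 0.06, 0.08),
                       fat_noise_sd = 0.5,
                       p_male = c(0.442, 0.461, 0.590),
                       age_mean = c(48.6, 50.5, 51.3),
                       age_sd = c(7.6, 8.2, 8.3),
                       missing_prob = 0.10,
                       missing_mechanism = c("MCAR", "MAR-BMI"),
                       mar_coef = 0.7,
                       inject = NULL) {
  cfg <- as.list(environment())
  cfg$missing_mechanism <- match.arg(missing_mechanism)
  .validate_sim_config(cfg)
  class(cfg) <- "glyco_simconfig"
  cfg
}

.validate_sim_config <- function(cfg) {
  if (cfg$n < 1) stop("n must be >= 1")
  if (abs(sum(cfg$group_probs) - 1) > 1e-8) {
    stop("group_probs must sum to 1")
  }
  if (length(cfg$group_probs) != 3 || any(cfg$group_probs < 0)) {
    stop("group_probs must be 3 non-negative probabilities")
  }
  for (field in c("si_decline", "bcf_decline")) {
    v <- cfg[[field]]
    if (any(v < 0 | v >= 1)) stop(field, " must lie in [0, 1)")
  }
  for (field in c("g0_mean", "g0_sd", "d60_mean", "d120_mean", "si_mean",
                  "bcf_mean", "bmi_mean", "bmi_sd", "fat_mean", "fat_sd",
                  "p_male", "age_mean", "age_sd", "si_decline",
                  "bcf_decline", "bmi_drift", "fat_drift")) {
    if (length(cfg[[field]]) != 3) stop(field, " must have length 3")
  }
  if (cfg$missing_prob < 0 || cfg$missing_prob >= 1) {
    stop("missing_prob must lie in [0, 1)")
  }
  if (!is.null(cfg$inject)) {
    for (b in c("beta_dis", "beta_dbcf")) {
      if (!is.finite(cfg$inject[[b]])) stop("inject ", b, " must be finite")
    }
  }
  invisible(cfg)
}

# log-normal draw parameterized by its mean on the natural scale
.rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic longitudinal OGTT cohort
#'
#' Draws each participant's progression group, latent baseline insulin
#' sensitivity and beta-cell function, and 10-year decline slopes; then
#' synthesizes the six biannual visits by inverting the surrogate-index
#' relations (see the package vignette) with multiplicative measurement
#' noise, drifting BMI/fat mass, and follow-up visits dropped per the
#' configured missingness mechanism. Fully deterministic under the config
#' seed.
#'
#' @param config a [sim_config()] object.
#' @return a `glyco_cohort` with extra columns `group` (the generating
#'   label) and attribute `latent` (per-participant latent values). With an
#'   [inject_effects()] config the attribute `injected_progression` holds
#'   the label set drawn from the logistic outcome model.
#' @export
generate_cohort <- function(config = sim_config()) {
  .validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  g <- sample.int(3, n, replace = TRUE, prob = config$group_probs)

  sex <- ifelse(stats::runif(n) < config$p_male[g], "male", "female")
  age <- pmin(pmax(stats::rnorm(n, config$age_mean[g], config$age_sd[g]),
                   40), 69)
  g0_0 <- pmax(stats::rnorm(n, config$g0_mean[g], config$g0_sd[g]), 50)
  d60_0 <- .rlnorm_mean(n, config$d60_mean[g], config$delta_sdlog)
  d120_0 <- .rlnorm_mean(n, config$d120_mean[g], config$delta_sdlog)
  si_0 <- .rlnorm_mean(n, config$si_mean[g], config$si_sdlog)
  bcf_0 <- .rlnorm_mean(n, config$bcf_mean[g], config$bcf_sdlog)
  slope_si <- log(1 - config$si_decline[g]) / 10 +
    stats::rnorm(n, 0, config$slope_jitter_sd)
  slope_bcf <- log(1 - config$bcf_decline[g]) / 10 +
    stats::rnorm(n, 0, config$slope_jitter_sd)
  bmi_0 <- pmax(stats::rnorm(n, config$bmi_mean[g], config$bmi_sd[g]), 14)
  fat_0 <- pmax(stats::rnorm(n, config$fat_mean[g], config$fat_sd[g]), 2)

  years <- 2 * (0:5)
  rows <- vector("list", 6)
  for (v in 0:5) {
    t <- years[v + 1]
    si_t <- si_0 * exp(slope_si * t)
    bcf_t <- bcf_0 * exp(slope_bcf * t)
    ratio <- (si_0 * bcf_0) / (si_t * bcf_t)  # DI_0 / DI_t
    G0 <- g0_0 * ratio^config$alpha_g0
    D60 <- d60_0 * ratio^config$alpha_g60
    D120 <- d120_0 * ratio^config$alpha_g120
    G60 <- G0 + D60
    G120 <- G0 + D120
    I0 <- 405 / (si_t * G0)
    I60 <- I0 + bcf_t * D60
    I120 <- I0 + config$i120_fraction * (I60 - I0)
    gbar <- (G0 + 2 * G60 + G120) / 4
    hba1c <- config$hba1c_intercept + config$hba1c_slope * gbar +
      stats::rnorm(n, 0, config$hba1c_sd)
    gnoise <- function(x) x * exp(stats::rnorm(n, 0, config$glucose_cv) -
                                    config$glucose_cv^2 / 2)
    inoise <- function(x) x * exp(stats::rnorm(n, 0, config$insulin_cv) -
                                    config$insulin_cv^2 / 2)
    rows[[v + 1]] <- data.frame(
      id = sprintf("S%05d", seq_len(n)),
      visit_index = v,
      sex = sex,
      baseline_age = age,
      g0 = gnoise(G0), g60 = gnoise(G60), g120 = gnoise(G120),
      i0 = inoise(I0), i60 = inoise(I60), i120 = inoise(I120),
      hba1c = pmin(pmax(hba1c, 3), 20),
      bmi = bmi_0 + config$bmi_drift[g] * t +
        stats::rnorm(n, 0, config$bmi_noise_sd) * (v > 0),
      fat_mass = fat_0 + config$fat_drift[g] * t +
        stats::rnorm(n, 0, config$fat_noise_sd) * (v > 0),
      on_medication = FALSE,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)

  injected <- NULL
  if (!is.null(config$inject)) {
    injected <- .draw_injected_labels(df, config)
  }

  # missingness: visit 0 never dropped
  drop_p <- rep(config$missing_prob, n)
  if (config$missing_mechanism == "MAR-BMI" && config$missing_prob > 0) {
    z <- (bmi_0 - mean(bmi_0)) / stats::sd(bmi_0)
    drop_p <- stats::plogis(stats::qlogis(config$missing_prob) +
                              config$mar_coef * z)
  }
  drop_p_row <- drop_p[match(df$id, sprintf("S%05d", seq_len(n)))]
  dropped <- df$visit_index > 0 & stats::runif(nrow(df)) < drop_p_row
  df <- df[!dropped, , drop = FALSE]

  cohort <- as_cohort(df, provenance = "synthetic")
  grp <- .sim_groups[g]
  attr(cohort, "group") <- data.frame(id = sprintf("S%05d", seq_len(n)),
                                      group = grp,
                                      stringsAsFactors = FALSE)
  attr(cohort, "latent") <- data.frame(
    id = sprintf("S%05d", seq_len(n)), group = grp,
    si_0 = si_0, bcf_0 = bcf_0,
    si_10 = si_0 * exp(slope_si * 10), bcf_10 = bcf_0 * exp(slope_bcf * 10),
    stringsAsFactors = FALSE)
  if (!is.null(injected)) attr(cohort, "injected_progression") <- injected
  cohort
}

# Draw binary progression labels from a logistic model on the realized
# (measured) decline statistics; overrides the latent group assignment.
.draw_injected_labels <- function(df, config) {
  inj <- config$inject
  cohort <- compute_indices(as_cohort(df, provenance = "pre-injection"))
  deltas <- compute_deltas(cohort, measures = inj$measures)
  ok <- !is.na(deltas$dis) & !is.na(deltas$dbcf)
  eta <- inj$beta_dis * deltas$dis[ok] + inj$beta_dbcf * deltas$dbcf[ok]
  b0 <- inj$intercept
  if (is.null(b0)) {
    # solve the intercept so the marginal event rate hits the target
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                           inj$target_rate,
                         interval = c(-30, 30))$root
  }
  y <- stats::rbinom(sum(ok), 1, stats::plogis(b0 + eta))
  data.frame(id = deltas$id[ok],
             progression = ifelse(y == 1, inj$case_label, "NON_P"),
             stringsAsFactors = FALSE)
}

#' Inject logistic progression effects into a simulation config
#'
#' Returns a config variant in which each participant's progression label is
#' drawn from `P(progress) = plogis(b0 + beta_dis * DIS + beta_dbcf * DBCF)`
#' on the participant's realized (measured) decline statistics, overriding
#' the threshold-driven group labels. This makes exact parameter-recovery
#' experiments possible: the fitted logistic model is correctly specified by
#' construction.
#'
#' @param config a [sim_config()] object.
#' @param beta_dis,beta_dbcf log-odds per unit of DIS / DBCF.
#' @param intercept fixed intercept, or `NULL` to solve it so the marginal
#'   event rate equals `target_rate`.
#' @param target_rate marginal event probability used when `intercept` is
#'   `NULL`; defaults to the diabetes-progressor fraction 183/2810.
#' @param measures measure pair the decline statistics are computed on;
#'   defaults to `c(is = "homa_is", bcf = "igi60")`, whose units match the
#'   scale the default coefficients are expressed on.
#' @param case_label progression label drawn on the event (default
#'   `"T2D_P"`).
#' @return a `glyco_simconfig`.
#' @export
inject_effects <- function(config, beta_dis, beta_dbcf, intercept = NULL,
                           target_rate = 183 / 2810,
                           measures = c(is = "homa_is", bcf = "igi60"),
                           case_label = "T2D_P") {
  stopifnot(is.finite(beta_dis), is.finite(beta_dbcf))
  config$inject <- list(beta_dis = beta_dis, beta_dbcf = beta_dbcf,
                        intercept = intercept, target_rate = target_rate,
                        measures = measures, case_label = case_label)
  .validate_sim_config(config)
  config
}

#' Deterministic stratified-incidence fixture
#'
#' A labeled cohort of 2,810 participants whose cross-tabulation by baseline
#' beta-cell-function stratum, insulin-sensitivity-decline stratum and
#' progression group equals a fixed 12-cell reference table (column sizes
#' 703/702/703/702).
#'
#' @return data frame `id`, `bcf_stratum`, `dis_stratum`, `progression`.
#' @export
build_table2_fixture <- function() {
  cells <- data.frame(
    bcf_stratum = rep(c("LOW", "LOW", "HIGH", "HIGH"), each = 3),
    dis_stratum = rep(c("LARGE", "SMALL", "LARGE", "SMALL"), each = 3),
    progression = rep(c("T2D_P", "PREDM_P", "NON_P"), 4),
    count = c(45, 358, 300,
              18, 237, 447,
              18, 269, 416,
              9, 190, 503),
    stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), cells$count)
  out <- cells[idx, c("bcf_stratum", "dis_stratum", "progression")]
  out <- data.frame(id = sprintf("F%04d", seq_len(nrow(out))), out,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
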