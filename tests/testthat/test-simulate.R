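test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n = 150, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, p1); write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the draw
  c3 <- generate_cohort(sim_config(n = 150, seed = 100))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("degenerate no-noise no-decline config is a fixed point", {
  cfg <- sim_config(
    n = 120, seed = 5, group_probs = c(1, 0, 0),
    g0_sd = rep(0, 3), delta_sdlog = 0, si_sdlog = 0, bcf_sdlog = 0,
    si_decline = rep(0, 3), bcf_decline = rep(0, 3), slope_jitter_sd = 0,
    glucose_cv = 0, insulin_cv = 0, hba1c_sd = 0,
    bmi_sd = rep(0, 3), fat_sd = rep(0, 3), bmi_noise_sd = 0,
    fat_noise_sd = 0, missing_prob = 0)
  co <- generate_cohort(cfg)
  co <- classify_cohort(co)
  expect_true(all(co$status == "NGT"))
  prog <- assign_progression(co)
  expect_true(all(prog$progression == "NON_P"))
  # every visit repeats the baseline values exactly
  expect_equal(length(unique(round(co$g0, 10))), 1)
  expect_equal(length(unique(round(co$i60, 10))), 1)
})

test_that("generated cohorts pass read validation with zero rejections", {
  co <- generate_cohort(sim_config(n = 250, seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(attr(back, "rejected")), 0)
  expect_equal(nrow(back), nrow(co))
})

test_that("baseline distributions track the configured anchors", {
  co <- generate_cohort(sim_config(n = 4000, seed = 31))
  base <- co[co$visit_index == 0, ]
  # weighted across groups the anchors imply g0 ~ 80.5, BMI ~ 24.1 (2.9)
  expect_equal(mean(base$g0), 80.5, tolerance = 0.01)
  expect_equal(mean(base$bmi), 24.1, tolerance = 0.01)
  expect_equal(sd(base$bmi), 2.9, tolerance = 0.05)
  expect_equal(mean(base$hba1c), 5.34, tolerance = 0.02)
  # fasting insulin follows from the HOMA-IS inversion
  expect_equal(mean(base$i0), 7.4, tolerance = 0.03)
})

test_that("programmed latent declines are recovered by the surrogates", {
  # HOMA-IS is the exact inverse of the latent sensitivity when noise is off
  cfg <- sim_config(n = 600, seed = 41, glucose_cv = 0, insulin_cv = 0,
                    si_decline = rep(0.30, 3), bcf_decline = rep(0, 3),
                    slope_jitter_sd = 0, missing_prob = 0)
  co <- compute_indices(generate_cohort(cfg))
  d <- compute_deltas(co, measures = c(is = "homa_is", bcf = "igi60"))
  pct <- percent_decline(d$is0, d$is10)
  expect_equal(mean(pct), 30, tolerance = 0.01)
  latent <- attr(co, "latent")
  expect_equal(d$is0, latent$si_0[match(d$id, latent$id)], tolerance = 1e-10)

  # the Matsuda surrogate moves with the latent decline but attenuates it
  dm <- compute_deltas(co, measures = c(is = "matsuda", bcf = "igi60"))
  pct_m <- percent_decline(dm$is0, dm$is10)
  expect_gt(mean(pct_m), 20)
  expect_lt(mean(pct_m), 45)
})

test_that("missingness mechanisms drop follow-up visits as configured", {
  cfg <- sim_config(n = 1500, seed = 53, missing_prob = 0.2)
  co <- generate_cohort(cfg)
  tab <- table(factor(co$visit_index, levels = 0:5))
  expect_equal(as.integer(tab[1]), 1500)  # visit 0 never dropped
  expect_equal(mean(as.integer(tab[-1])) / 1500, 0.8, tolerance = 0.03)

  # MAR-on-BMI: retention of the year-10 visit depends on baseline BMI
  cfg_mar <- sim_config(n = 3000, seed = 54, missing_prob = 0.3,
                        missing_mechanism = "MAR-BMI", mar_coef = 1.2)
  co_mar <- generate_cohort(cfg_mar)
  base <- co_mar[co_mar$visit_index == 0, ]
  has5 <- base$id %in% co_mar$id[co_mar$visit_index == 5]
  expect_lt(mean(base$bmi[has5]), mean(base$bmi[!has5]) - 0.5)
})

test_that("injected logistic effects scale linearly in the generator", {
  base_cfg <- sim_config(n = 2500, seed = 61, missing_prob = 0)
  fit_slope <- function(beta) {
    cfg <- inject_effects(base_cfg, beta_dis = beta, beta_dbcf = 0,
                          target_rate = 0.2)
    co <- compute_indices(generate_cohort(cfg))
    inj <- attr(co, "injected_progression")
    d <- compute_deltas(co, measures = c(is = "homa_is", bcf = "igi60"))
    d <- merge(d, inj, by = "id")
    d <- d[complete.cases(d[, c("dis", "dbcf")]), ]
    fit <- fit_logistic(as.numeric(d$progression == "T2D_P"),
                        d[, c("dis", "dbcf")])
    coef(fit)["dis"]
  }
  s1 <- fit_slope(1.0)
  s2 <- fit_slope(2.0)
  expect_equal(unname(s2 / s1), 2, tolerance = 0.35)
  # null injection: slope near zero
  s0 <- fit_slope(0)
  expect_lt(abs(s0), 0.45)
})

test_that("the deterministic fixture reproduces its reference counts", {
  fx <- build_table2_fixture()
  expect_equal(nrow(fx), 2810)
  expect_equal(sum(fx$bcf_stratum == "LOW" & fx$dis_stratum == "LARGE" &
                     fx$progression == "T2D_P"), 45)
  ns <- table(fx$bcf_stratum, fx$dis_stratum)
  expect_true(all(ns %in% c(702, 703)))
  expect_identical(build_table2_fixture(), fx)  # deterministic
})

test_that("invalid configs are rejected before sampling", {
  expect_error(sim_config(n = 0), "n must be")
  expect_error(sim_config(group_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(si_decline = c(0.2, 1.2, 0.3)), "lie in")
  expect_error(sim_config(missing_prob = 1.5), "missing_prob")
  expect_error(inject_effects(sim_config(), Inf, 1), "finite")
})
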