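test_that("logistic MLE on a saturated 2x2 equals the closed-form log OR", {
  # 45 events / 703 exposed, 18 events / 702 unexposed
  x <- c(rep(1, 703), rep(0, 702))
  y <- c(rep(1, 45), rep(0, 658), rep(1, 18), rep(0, 684))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_equal(unname(coef(fit)["x"]), log((45 * 684) / (658 * 18)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients["x", "or"],
               (45 / 658) / (18 / 684), tolerance = 1e-6)
})

test_that("standardization is a pure reparameterization", {
  set.seed(20)
  n <- 500
  d <- data.frame(a = rnorm(n, 5, 2), b = rnorm(n, -1, 0.3),
                  flag = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-1 + 0.3 * d$a - 2 * d$b + 0.5 * d$flag))
  fit <- fit_logistic(y, d)
  expect_equal(fit$deviance, fit$deviance_standardized, tolerance = 1e-8)
  # standardized slope = unstandardized slope * sample SD for continuous
  expect_equal(fit$standardized["a", "estimate"],
               fit$coefficients["a", "estimate"] * sd(d$a),
               tolerance = 1e-6)
  # binary covariates are left untouched
  expect_equal(fit$standardized["flag", "estimate"],
               fit$coefficients["flag", "estimate"], tolerance = 1e-6)
  # OR = exp(beta) componentwise; CI bounds ordered
  expect_equal(fit$coefficients$or, exp(fit$coefficients$estimate))
  expect_true(all(fit$coefficients$ci_lower < fit$coefficients$ci_upper))
})

test_that("null covariates give slopes near zero at large n", {
  set.seed(21)
  n <- 4000
  d <- data.frame(x = rnorm(n))
  y <- rbinom(n, 1, 0.3)
  fit <- fit_logistic(y, d)
  expect_lt(abs(coef(fit)["x"]), 3 / sqrt(n * 0.21))
})

test_that("degenerate designs and separation raise errors", {
  set.seed(22)
  n <- 100
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.5)
  expect_error(fit_logistic(y, data.frame(x = x, x2 = x)),
               "rank deficient")
  expect_error(fit_logistic(rep(1, n), data.frame(x = x)), "degenerate")
  ysep <- as.numeric(x > 0)
  expect_error(fit_logistic(ysep, data.frame(x = x)), "separation")
})

test_that("fit methods behave like a classed model object", {
  set.seed(23)
  n <- 300
  d <- data.frame(x = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$x))
  fit <- fit_logistic(y, d, outcome_label = "toy", model_id = 1)
  expect_s3_class(fit, "glyco_logit")
  expect_named(coef(fit), c("(Intercept)", "x"))
  ci <- confint(fit)
  expect_true(ci["x", 1] < coef(fit)["x"] && coef(fit)["x"] < ci["x", 2])
  expect_length(predict(fit), n)
  expect_true(all(predict(fit) >= 0 & predict(fit) <= 1))
  expect_length(residuals(fit), n)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(n, 3))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_output(print(fit), "unstandardized beta")
})

test_that("model suite fits both contrasts and all three models", {
  set.seed(24)
  n <- 1200
  deltas <- data.frame(
    id = sprintf("p%04d", 1:n),
    is0 = rlnorm(n, 0, 0.3), bcf0 = rlnorm(n, -0.5, 0.3),
    dis = rnorm(n, 0.2, 0.1), dbcf = rnorm(n, 0.05, 0.08),
    sex = sample(c("male", "female"), n, TRUE),
    baseline_age = rnorm(n, 50, 8), bmi0 = rnorm(n, 24, 3))
  lin <- 2 * deltas$dis + 1 * deltas$dbcf
  p_pre <- plogis(-1 + lin)
  grp <- ifelse(runif(n) < 0.1, "T2D_P",
                ifelse(runif(n) < p_pre, "PREDM_P", "NON_P"))
  deltas$progression <- grp
  suite <- model_suite(deltas)
  expect_named(suite$fits, c("PREDM", "DM"))
  for (oc in names(suite$fits)) {
    expect_named(suite$fits[[oc]], c("1", "2", "3"))
    for (m in names(suite$fits[[oc]])) {
      fit <- suite$fits[[oc]][[m]]
      expect_s3_class(fit, "glyco_logit")
      expect_true(is.finite(fit$ratio_std_dis_dbcf))
    }
  }
  expect_equal(nrow(suite$ratios), 6)
  # third group excluded from each contrast
  expect_equal(suite$fits$PREDM$`1`$n,
               sum(grp %in% c("PREDM_P", "NON_P")))

  # degenerate baseline stratum is dropped with a warning
  deltas2 <- deltas
  deltas2$is0 <- 1  # single value -> single stratum level
  warns <- capture_warnings(model_suite(deltas2))
  expect_true(any(grepl("degenerate", warns)))
})

test_that("models 1 and 2 agree when extra covariates are independent", {
  set.seed(25)
  n <- 6000
  deltas <- data.frame(
    id = seq_len(n),
    is0 = rlnorm(n, 0, 0.3), bcf0 = rlnorm(n, -0.5, 0.3),
    dis = rnorm(n, 0.2, 0.15), dbcf = rnorm(n, 0.05, 0.1),
    sex = sample(c("male", "female"), n, TRUE),
    baseline_age = rnorm(n, 50, 8), bmi0 = rnorm(n, 24, 3))
  p <- plogis(-2 + 1.5 * deltas$dis + 0.8 * deltas$dbcf)
  deltas$progression <- ifelse(rbinom(n, 1, p) == 1, "PREDM_P", "NON_P")
  deltas$progression[sample(n, 300)] <- "T2D_P"
  suite <- model_suite(deltas)
  b1 <- coef(suite$fits$PREDM$`1`)["dis"]
  b2 <- coef(suite$fits$PREDM$`2`)["dis"]
  se1 <- sqrt(diag(vcov(suite$fits$PREDM$`1`)))["dis"]
  expect_lt(abs(b1 - b2), 3 * se1)
})
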