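# Small in-code fixtures shared across tests.

# three-participant cohort with assorted missingness
toy_cohort <- function() {
  as_cohort(data.frame(
    id = c("A", "A", "A", "B", "B", "C", "C"),
    visit_index = c(0, 2, 5, 0, 5, 0, 5),
    sex = c("male", "male", "male", "female", "female", "female", "female"),
    baseline_age = c(50, 50, 50, 45, 45, 60, 60),
    g0 = c(90, 95, 99, 85, 104, 92, 130),
    g60 = c(120, 125, 130, 110, 150, 125, 210),
    g120 = c(100, 110, 120, 95, 141, 110, 205),
    i0 = c(7, 8, 9, 6, 10, 7, 12),
    i60 = c(30, 32, 35, 25, 42, 31, 48),
    i120 = c(24, 25, 27, 20, 33, 24, 40),
    hba1c = c(5.3, 5.4, 5.5, 5.2, 5.8, 5.4, 6.6),
    bmi = c(24, 24.2, 24.5, 22, 23, 26, 27),
    fat_mass = c(16, 16.2, 16.5, 14, 14.5, 19, 20),
    on_medication = FALSE))
}

# independent numeric trapezoid oracle: AUC over 0..120 min divided by 120
trapz_oracle <- function(v0, v60, v120) {
  x <- c(0, 60, 120)
  y <- c(v0, v60, v120)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / 120
}

# independent Matsuda oracle built on the numeric trapezoid
matsuda_oracle <- function(g, i) {
  10000 / sqrt(trapz_oracle(g[1], g[2], g[3]) * trapz_oracle(i[1], i[2], i[3]) *
                 i[1] * g[1])
}

# observed-data log-likelihood MLE for a bivariate normal with missing
# values, by direct numerical optimisation (independent of the EM route)
mvn_mle_oracle <- function(Y) {
  nll <- function(par) {
    mu <- par[1:2]
    L <- matrix(c(exp(par[3]), par[5], 0, exp(par[4])), 2, 2)
    S <- L %*% t(L)
    if (rcond(S) < 1e-12 || any(!is.finite(S))) return(1e10)
    ll <- 0
    for (r in seq_len(nrow(Y))) {
      obs <- which(!is.na(Y[r, ]))
      ll <- ll + mvtnorm_logd(Y[r, obs], mu[obs], S[obs, obs, drop = FALSE])
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  mvtnorm_logd <- function(y, mu, S) {
    k <- length(y)
    -0.5 * (k * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus +
              drop(t(y - mu) %*% solve(S) %*% (y - mu)))
  }
  start <- c(colMeans(Y, na.rm = TRUE), 0, 0, 0)
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  L <- matrix(c(exp(fit$par[3]), fit$par[5], 0, exp(fit$par[4])), 2, 2)
  list(mu = fit$par[1:2], sigma = L %*% t(L))
}

# Little's statistic computed directly from supplied mu/sigma
little_stat_oracle <- function(Y, mu, sigma) {
  pat <- apply(!is.na(Y), 1, paste, collapse = "")
  d2 <- 0
  for (g in split(seq_len(nrow(Y)), pat)) {
    obs <- which(!is.na(Y[g[1], ]))
    ybar <- colMeans(Y[g, obs, drop = FALSE])
    dev <- ybar - mu[obs]
    d2 <- d2 + length(g) * drop(t(dev) %*%
                                  solve(sigma[obs, obs, drop = FALSE]) %*% dev)
  }
  d2
}
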