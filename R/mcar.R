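# Little's (1988) MCAR test.
#
# ML estimates of the mean vector and covariance matrix under multivariate
# normality with missing data are obtained by EM; the test statistic compares
# each missingness pattern's observed-variable means against the ML grand
# means, weighted by the pattern size and the corresponding submatrix of the
# ML covariance:
#   d^2 = sum_j n_j (ybar_j - mu_oj)' Sigma_oj^{-1} (ybar_j - mu_oj),
#   df  = sum_j p_j - p,
# referred to a chi-square distribution under the MCAR null.

# solve() with a tiny ridge fallback for near-singular covariance blocks
.solve_safe <- function(S) {
  tryCatch(solve(S), error = function(e) {
    solve(S + diag(nrow(S)) * 1e-8 * (mean(diag(S)) + 1))
  })
}

# EM for multivariate normal mean/covariance with arbitrary missingness.
.em_norm <- function(Y, max_iter = 500, tol = 1e-10) {
  n <- nrow(Y); p <- ncol(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  d <- diag(S)
  d[d <= 0 | is.na(d)] <- stats::var(as.numeric(Y), na.rm = TRUE)
  diag(S) <- d
  # nudge toward positive definite if pairwise estimate is not
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) S <- S + diag(p) * (1e-8 + abs(min(ev)))

  pat <- apply(!is.na(Y), 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), pat)

  for (iter in seq_len(max_iter)) {
    sum_y <- numeric(p)
    sum_yy <- matrix(0, p, p)
    for (rows in groups) {
      obs <- which(!is.na(Y[rows[1], ]))
      mis <- setdiff(seq_len(p), obs)
      Yo <- Y[rows, obs, drop = FALSE]
      X <- matrix(NA_real_, length(rows), p)
      X[, obs] <- Yo
      C <- matrix(0, p, p)
      if (length(mis)) {
        Soo_inv <- .solve_safe(S[obs, obs, drop = FALSE])
        B <- S[mis, obs, drop = FALSE] %*% Soo_inv
        resid <- sweep(Yo, 2, mu[obs])
        X[, mis] <- matrix(mu[mis], length(rows), length(mis), byrow = TRUE) +
          resid %*% t(B)
        C[mis, mis] <- S[mis, mis, drop = FALSE] -
          B %*% S[obs, mis, drop = FALSE]
      }
      sum_y <- sum_y + colSums(X)
      sum_yy <- sum_yy + crossprod(X) + length(rows) * C
    }
    mu_new <- sum_y / n
    S_new <- sum_yy / n - tcrossprod(mu_new)
    S_new <- (S_new + t(S_new)) / 2
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new; S <- S_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = S, iterations = iter)
}

#' Little's MCAR test
#'
#' Tests whether a table's missingness is consistent with being Missing
#' Completely At Random, by comparing the observed-variable means of each
#' distinct missingness pattern with maximum-likelihood grand means estimated
#' under multivariate normality (EM). Returns the chi-square statistic, its
#' degrees of freedom and p-value, alongside per-variable missing counts and
#' the pattern table. With a single missingness pattern there is nothing to
#' compare and the test is flagged as not applicable (`df = 0`).
#'
#' @param rows data frame or matrix of numeric variables with `NA` for
#'   missing entries; at least 2 variables and 2 rows. Rows missing every
#'   variable are dropped before testing.
#' @return object of class `glyco_mcar`: list with `statistic`, `df`,
#'   `p_value`, `applicable`, `n_patterns`, `patterns` (pattern x count table),
#'   `missing_counts`, `n_used`.
#' @references Little, R. J. A. (1988). A test of missing completely at
#'   random for multivariate data with missing values. JASA 83, 1198-1202.
#' @export
mcar_test <- function(rows) {
  Y <- as.matrix(as.data.frame(rows))
  storage.mode(Y) <- "double"
  if (ncol(Y) < 2) stop("mcar_test needs at least 2 variables")
  all_missing <- rowSums(!is.na(Y)) == 0
  if (all(all_missing)) stop("all rows fully missing")
  Y <- Y[!all_missing, , drop = FALSE]
  if (nrow(Y) < 2) stop("mcar_test needs at least 2 usable rows")
  n <- nrow(Y); p <- ncol(Y)

  pat_str <- apply(!is.na(Y), 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), pat_str)
  patterns <- data.frame(pattern = names(groups),
                         count = vapply(groups, length, integer(1)),
                         row.names = NULL, stringsAsFactors = FALSE)
  missing_counts <- colSums(is.na(Y))

  if (length(groups) == 1) {
    out <- list(statistic = 0, df = 0L, p_value = NA_real_,
                applicable = FALSE, n_patterns = 1L, patterns = patterns,
                missing_counts = missing_counts, n_used = n)
    class(out) <- "glyco_mcar"
    return(out)
  }

  fit <- .em_norm(Y)
  d2 <- 0
  sum_pj <- 0L
  for (rows_j in groups) {
    obs <- which(!is.na(Y[rows_j[1], ]))
    sum_pj <- sum_pj + length(obs)
    ybar <- colMeans(Y[rows_j, obs, drop = FALSE])
    dev <- ybar - fit$mu[obs]
    d2 <- d2 + length(rows_j) *
      drop(t(dev) %*% .solve_safe(fit$sigma[obs, obs, drop = FALSE]) %*% dev)
  }
  df <- sum_pj - p
  out <- list(statistic = d2, df = as.integer(df),
              p_value = stats::pchisq(d2, df, lower.tail = FALSE),
              applicable = TRUE, n_patterns = length(groups),
              patterns = patterns, missing_counts = missing_counts,
              n_used = n, em_iterations = fit$iterations,
              mu = fit$mu, sigma = fit$sigma)
  class(out) <- "glyco_mcar"
  out
}

#' @export
print.glyco_mcar <- function(x, ...) {
  cat("Little's MCAR test\n")
  if (!x$applicable) {
    cat("  single missingness pattern: test not applicable (df = 0)\n")
  } else {
    cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  cat("  rows analysed:", x$n_used,
      " patterns:", x$n_patterns, "\n")
  invisible(x)
}
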