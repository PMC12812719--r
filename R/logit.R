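# Logistic regression layer: maximum-likelihood fits (IRLS via stats::glm)
# with Wald intervals, plus the standardized refit used to compare effect
# sizes of covariates expressed in different units.

#' Fit a logistic regression with unstandardized and standardized coefficients
#'
#' Fits the binary-outcome model by maximum likelihood (iteratively
#' reweighted least squares) and, when `standardize = TRUE`, refits after
#' centering continuous covariates and scaling them to unit standard
#' deviation; binary covariates and factors are left as they are, so
#' standardized coefficients are comparable across covariates measured in
#' different units. Standardization is a reparameterization: both fits have
#' identical deviance.
#'
#' @param outcome logical or 0/1 vector.
#' @param design data frame of covariates (numeric, logical or factor
#'   columns).
#' @param standardize also fit the standardized model (default `TRUE`).
#' @param outcome_label optional label stored on the fit.
#' @param model_id optional model identifier (1, 2 or 3 in the model suite).
#' @return object of class `glyco_logit` with components `coefficients`
#'   (data frame: `estimate`, `ci_lower`, `ci_upper`, `or`, `p_value`),
#'   `standardized` (same shape or `NULL`), `deviance`, `fit` (the underlying
#'   `glm`). Methods: `print`, `summary`, `coef`, `confint`, `predict`,
#'   `residuals`, `simulate`, `vcov`.
#' @export
fit_logistic <- function(outcome, design, standardize = TRUE,
                         outcome_label = "outcome", model_id = NA) {
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% 0:1))
  design <- as.data.frame(design)
  keep <- stats::complete.cases(design) & !is.na(outcome)
  design <- design[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (length(unique(outcome)) < 2) stop("outcome is degenerate")

  dat <- cbind(data.frame(.y = outcome), design)
  X <- stats::model.matrix(~ ., data = design)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (duplicated or collinear columns)")
  }

  fit_one <- function(d) {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = d, family = stats::binomial(),
                 control = stats::glm.control(maxit = 50)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged) {
      stop("logistic fit did not converge within 50 IRLS iterations",
           if (sep_warn) " (fitted probabilities at 0/1: possible separation)")
    }
    if (sep_warn) {
      # extreme fitted probabilities are only an error if the linear
      # predictor actually separates the outcome classes
      eta <- stats::predict(fit, type = "link")
      y <- fit$y
      if (min(eta[y == 1]) >= max(eta[y == 0]) ||
          min(eta[y == 0]) >= max(eta[y == 1])) {
        stop("perfect or quasi-perfect separation detected")
      }
    }
    fit
  }
  coef_table <- function(fit) {
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    z <- stats::qnorm(0.975)
    data.frame(estimate = est,
               ci_lower = est - z * se, ci_upper = est + z * se,
               or = exp(est), p_value = 2 * stats::pnorm(-abs(est / se)))
  }

  fit <- fit_one(dat)
  std_table <- NULL
  fit_std <- NULL
  if (standardize) {
    dstd <- design
    for (col in names(dstd)) {
      v <- dstd[[col]]
      if (is.numeric(v) && length(unique(v)) > 2) {
        dstd[[col]] <- (v - mean(v)) / stats::sd(v)
      }
    }
    fit_std <- fit_one(cbind(data.frame(.y = outcome), dstd))
    std_table <- coef_table(fit_std)
  }
  out <- list(coefficients = coef_table(fit), standardized = std_table,
              deviance = stats::deviance(fit),
              deviance_standardized = if (!is.null(fit_std))
                stats::deviance(fit_std) else NULL,
              n = length(outcome), n_events = sum(outcome),
              outcome_label = outcome_label, model_id = model_id,
              fit = fit, fit_std = fit_std)
  class(out) <- "glyco_logit"
  out
}

#' @export
coef.glyco_logit <- function(object, type = c("unstandardized",
                                              "standardized"), ...) {
  type <- match.arg(type)
  tab <- if (type == "standardized") object$standardized
         else object$coefficients
  if (is.null(tab)) stop("standardized fit not available")
  stats::setNames(tab$estimate, rownames(tab))
}

#' @export
confint.glyco_logit <- function(object, parm, level = 0.95,
                                type = c("unstandardized", "standardized"),
                                ...) {
  type <- match.arg(type)
  tab <- if (type == "standardized") object$standardized
         else object$coefficients
  out <- as.matrix(tab[, c("ci_lower", "ci_upper")])
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.glyco_logit <- function(object, newdata = NULL,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(stats::predict(object$fit, type = type))
  stats::predict(object$fit, newdata = newdata, type = type)
}

#' @export
residuals.glyco_logit <- function(object, type = "deviance", ...) {
  stats::residuals(object$fit, type = type)
}

#' @export
simulate.glyco_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::fitted(object$fit)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
vcov.glyco_logit <- function(object, ...) stats::vcov(object$fit)

#' @export
print.glyco_logit <- function(x, digits = 3, ...) {
  cat("Logistic regression (", x$outcome_label,
      if (!is.na(x$model_id)) paste0(", model ", x$model_id), "): ",
      x$n_events, "/", x$n, " events\n", sep = "")
  tab <- x$coefficients
  cat("  unstandardized beta (95% CI):\n")
  for (nm in rownames(tab)) {
    cat(sprintf("    %-16s %s\n", nm,
                fmt_beta_ci(tab[nm, "estimate"], tab[nm, "ci_lower"],
                            tab[nm, "ci_upper"], digits)))
  }
  if (!is.null(x$standardized)) {
    cat("  standardized beta (95% CI):\n")
    for (nm in rownames(x$standardized)) {
      cat(sprintf("    %-16s %s\n", nm,
                  fmt_beta_ci(x$standardized[nm, "estimate"],
                              x$standardized[nm, "ci_lower"],
                              x$standardized[nm, "ci_upper"], digits)))
    }
  }
  invisible(x)
}

#' @export
summary.glyco_logit <- function(object, ...) {
  print(object)
  cat(sprintf("  deviance: %.3f on %d residual df\n", object$deviance,
              object$fit$df.residual))
  invisible(object)
}

#' Fit the three-model logistic suite
#'
#' For each of the two binary outcome contrasts (progression to prediabetes
#' vs non-progression; progression to diabetes vs non-progression - the
#' third group is excluded from each fit), fits: model 1 with the decline
#' statistics `dis + dbcf`; model 2 adding sex, baseline age and baseline
#' BMI; model 3 adding the baseline insulin-sensitivity and beta-cell median
#' strata (high vs low, categorical). Each fit carries unstandardized and
#' standardized coefficients and the DIS:DBCF ratio of standardized
#' coefficients.
#'
#' @param deltas data frame from [compute_deltas()] merged with a
#'   `progression` column; [assign_strata()]-style `bcf_stratum` plus a
#'   baseline-IS stratum are derived internally from `is0`/`bcf0` medians.
#' @return object of class `glyco_suite`: nested list
#'   `fits[[outcome]][[model]]` of `glyco_logit` objects plus a `ratios`
#'   table of standardized DIS:DBCF coefficient ratios.
#' @export
model_suite <- function(deltas) {
  stopifnot("progression" %in% names(deltas))
  deltas$base_is_stratum <- factor(median_split(deltas$is0, c("LOW", "HIGH")),
                                   levels = c("LOW", "HIGH"))
  deltas$base_bcf_stratum <- factor(median_split(deltas$bcf0,
                                                 c("LOW", "HIGH")),
                                    levels = c("LOW", "HIGH"))
  deltas$sex_male <- as.numeric(deltas$sex == "male")

  covariate_sets <- list(
    `1` = c("dis", "dbcf"),
    `2` = c("dis", "dbcf", "sex_male", "baseline_age", "bmi0"),
    `3` = c("dis", "dbcf", "sex_male", "baseline_age", "bmi0",
            "base_is_stratum", "base_bcf_stratum"))
  outcomes <- list(PREDM = c(case = "PREDM_P", ref = "NON_P"),
                   DM = c(case = "T2D_P", ref = "NON_P"))

  fits <- list()
  ratio_rows <- list()
  for (oc in names(outcomes)) {
    sel <- deltas$progression %in% outcomes[[oc]]
    d <- deltas[sel, , drop = FALSE]
    y <- as.numeric(d$progression == outcomes[[oc]]["case"])
    fits[[oc]] <- list()
    for (m in names(covariate_sets)) {
      cols <- covariate_sets[[m]]
      design <- d[, cols, drop = FALSE]
      # degenerate factors (single observed level) are dropped with a warning
      for (col in cols) {
        v <- design[[col]]
        if ((is.factor(v) && nlevels(droplevels(v[!is.na(v)])) < 2) ||
            (!is.factor(v) && length(unique(v[!is.na(v)])) < 2)) {
          warning("covariate '", col, "' is degenerate in outcome ", oc,
                  " model ", m, "; dropped")
          design[[col]] <- NULL
        }
      }
      fit <- fit_logistic(y, design, standardize = TRUE,
                          outcome_label = paste0("progression to ", oc),
                          model_id = as.integer(m))
      std <- fit$standardized
      ratio <- if (all(c("dis", "dbcf") %in% rownames(std))) {
        std["dis", "estimate"] / std["dbcf", "estimate"]
      } else NA_real_
      fit$ratio_std_dis_dbcf <- ratio
      fits[[oc]][[m]] <- fit
      ratio_rows[[length(ratio_rows) + 1]] <-
        data.frame(outcome = oc, model = as.integer(m), ratio = ratio)
    }
  }
  out <- list(fits = fits, ratios = do.call(rbind, ratio_rows))
  class(out) <- "glyco_suite"
  out
}

#' @export
print.glyco_suite <- function(x, ...) {
  cat("Logistic model suite (DIS + DBCF; two outcome contrasts)\n")
  for (oc in names(x$fits)) {
    for (m in names(x$fits[[oc]])) {
      fit <- x$fits[[oc]][[m]]
      tab <- fit$coefficients
      std <- fit$standardized
      for (param in intersect(c("dis", "dbcf"), rownames(tab))) {
        cat(sprintf("  %-5s model %s %-5s beta %s  std %s%s\n",
                    oc, m, toupper(param),
                    fmt_beta_ci(tab[param, "estimate"],
                                tab[param, "ci_lower"],
                                tab[param, "ci_upper"]),
                    fmt_beta_ci(std[param, "estimate"],
                                std[param, "ci_lower"],
                                std[param, "ci_upper"]),
                    if (param == "dis" && !is.na(fit$ratio_std_dis_dbcf))
                      sprintf("  ratio %.3f", fit$ratio_std_dis_dbcf)
                    else ""))
      }
    }
  }
  invisible(x)
}
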