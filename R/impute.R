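#' Multiple imputation by chained equations
#'
#' Fills missing cells with `m` completed copies of the cohort.  Each
#' incomplete variable gets a conditional model on all other imputation
#' variables plus the always-observed demographics and attrition weight:
#' binary cells are drawn from a Bayesian logistic model (coefficients drawn
#' from their asymptotic normal posterior, then Bernoulli draws), continuous
#' cells from a normal linear model with drawn residual variance and
#' coefficients.  Variables are visited in order of increasing missingness
#' for a fixed number of cycles per imputation.
#'
#' Adult outcomes are included as predictors of the childhood variables (and
#' vice versa) so the imputation model is congenial with the downstream
#' analysis models; the earnings-model controls are excluded.
#'
#' @param cohort A `cati_cohort`, possibly with `NA` cells in components,
#'   scale waves or adult outcomes.  Demographics must be complete.
#' @param m Number of imputations (>= 2; the published pipeline uses 20).
#' @param seed Integer seed; the imputation stream is independent of other
#'   pipeline stages.
#' @param iter Chained-equation cycles per imputation.
#' @return A `cati_imputation_set`: list with `copies` (list of `m` completed
#'   cohorts), `m`, `seed`, `iter`, and `complete` (TRUE when the input had
#'   no missing cells, in which case all copies are the input itself).
#' @export
impute_chained <- function(cohort, m = 20, seed = 1L, iter = 10) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (anyNA(cohort$age) || anyNA(cohort$sex) || anyNA(cohort$race_ethnicity)) {
    stop("demographics must be fully observed", call. = FALSE)
  }
  vars <- imputable_columns(cohort)
  n_miss <- vapply(vars, function(v) sum(is.na(cohort[[v]])), integer(1))
  if (all(n_miss == 0)) {
    return(structure(list(copies = rep(list(cohort), m), m = m,
                          seed = as.integer(seed), iter = iter,
                          complete = TRUE),
                     class = "cati_imputation_set"))
  }
  zero_obs <- vars[vapply(vars, function(v) all(is.na(cohort[[v]])),
                          logical(1))]
  if (length(zero_obs)) {
    stop("unimputable variable(s) with no observed cases: ",
         paste(zero_obs, collapse = ", "), call. = FALSE)
  }
  incomplete <- names(sort(n_miss[n_miss > 0]))
  binary <- vapply(vars, function(v) {
    obs <- cohort[[v]][!is.na(cohort[[v]])]
    all(obs %in% c(0, 1))
  }, logical(1))
  names(binary) <- vars

  demo <- design_demographics(cohort)
  base_pred <- cbind(demo, log_attrition = log(cohort$attrition_weight))

  copies <- vector("list", m)
  for (l in seq_len(m)) {
    copies[[l]] <- with_seed(substream_seed(seed, "impute", l), {
      imp <- cohort
      # initialize missing cells from the observed marginal
      for (v in incomplete) {
        nas <- is.na(imp[[v]])
        imp[[v]][nas] <- sample(imp[[v]][!nas], sum(nas), replace = TRUE)
      }
      for (it in seq_len(iter)) {
        for (v in incomplete) {
          others <- setdiff(vars, v)
          X <- cbind(`(Intercept)` = 1, base_pred,
                     as.matrix(as.data.frame(imp[others])))
          nas <- is.na(cohort[[v]])
          drawn <- draw_conditional(
            y_obs = cohort[[v]][!nas],
            X_obs = X[!nas, , drop = FALSE],
            X_mis = X[nas, , drop = FALSE],
            binary = binary[[v]]
          )
          if (v == "peak_earnings") drawn <- pmax(0, round(drawn))
          imp[[v]][nas] <- drawn
        }
      }
      imp
    })
  }
  structure(list(copies = copies, m = m, seed = as.integer(seed),
                 iter = iter, complete = FALSE),
            class = "cati_imputation_set")
}

imputable_columns <- function(cohort) {
  c(component_columns(cohort),
    unlist(lapply(CATI_SCALES, scale_wave_columns, data = cohort)),
    intersect(c("ever_fair_poor_health", "ever_depressed", "peak_earnings"),
              names(cohort)))
}

# One proper-imputation draw for a single variable.  Falls back to marginal
# resampling if the conditional fit is degenerate (e.g. separation).
draw_conditional <- function(y_obs, X_obs, X_mis, binary) {
  X_obs <- drop_constant_cols(X_obs, keep_first = TRUE)
  X_mis <- X_mis[, colnames(X_obs), drop = FALSE]
  draw <- tryCatch({
    if (binary) {
      fit <- suppressWarnings(glm.fit(X_obs, y_obs, family = binomial()))
      beta <- coef_draw(fit, X_obs, binary = TRUE)
      rbinom(nrow(X_mis), 1L, plogis(drop(X_mis %*% beta)))
    } else {
      fit <- stats::lm.fit(X_obs, y_obs)
      ok <- !is.na(fit$coefficients)
      Xo <- X_obs[, ok, drop = FALSE]
      XtX <- crossprod(Xo)
      R <- chol(XtX + diag(1e-8 * diag(XtX), ncol(Xo)))
      df <- max(1, nrow(Xo) - ncol(Xo))
      sigma2 <- sum(fit$residuals^2) / rchisq(1, df)
      beta_hat <- fit$coefficients[ok]
      beta <- beta_hat +
        sqrt(sigma2) * backsolve(R, rnorm(ncol(Xo)))
      drop(X_mis[, ok, drop = FALSE] %*% beta) +
        rnorm(nrow(X_mis), sd = sqrt(sigma2))
    }
  }, error = function(e) NULL)
  if (is.null(draw)) {
    draw <- sample(y_obs, nrow(X_mis), replace = TRUE)
  }
  if (binary) as.integer(draw) else draw
}

coef_draw <- function(fit, X, binary) {
  beta_hat <- fit$coefficients
  ok <- !is.na(beta_hat)
  w <- fit$weights # glm.fit IRLS weights at convergence
  A <- crossprod(X[, ok, drop = FALSE] * sqrt(pmax(w, 1e-10)))
  R <- tryCatch(chol(A), error = function(e) NULL)
  beta <- beta_hat
  if (!is.null(R)) {
    beta[ok] <- beta_hat[ok] + backsolve(R, rnorm(sum(ok)))
  }
  beta[!ok] <- 0
  beta
}

drop_constant_cols <- function(X, keep_first = FALSE) {
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  if (keep_first) keep[1] <- TRUE
  X[, keep, drop = FALSE]
}

#' @export
print.cati_imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, ", cycles =", x$iter,
      if (x$complete) "(input complete; copies identical)" else "", "\n")
  invisible(x)
}

#' Pool estimates across imputations (Rubin's rules)
#'
#' Combines per-imputation point estimates and variances: the pooled
#' estimate is the mean, the between-imputation variance is the sample
#' variance of the estimates, and the total variance is
#' `within + (1 + 1/m) * between`.  Degrees of freedom follow the
#' Barnard--Rubin small-sample adjustment given the complete-data degrees of
#' freedom; the p-value is from a two-sided t test of the estimate against
#' zero.
#'
#' @param per_imputation List of `c(estimate, variance)` pairs (or a 2-column
#'   matrix), one per imputation; length >= 2.
#' @param df_com Complete-data degrees of freedom (default `Inf`).
#' @return A list of class `cati_pooled`: `estimate`, `within_var`,
#'   `between_var`, `total_var`, `df`, `p_value`, `m`.
#' @export
pool_estimates <- function(per_imputation, df_com = Inf) {
  if (is.list(per_imputation)) {
    per_imputation <- do.call(rbind, lapply(per_imputation, function(x) {
      c(x[[1]], x[[2]])
    }))
  }
  m <- nrow(per_imputation)
  if (is.null(m) || m < 2) {
    stop("pooling requires at least 2 imputations", call. = FALSE)
  }
  est <- per_imputation[, 1]
  v <- per_imputation[, 2]
  if (any(v < 0)) stop("variances must be nonnegative", call. = FALSE)
  qbar <- mean(est)
  W <- mean(v)
  B <- var(est)
  Tv <- W + (1 + 1 / m) * B
  if (Tv <= 0) {
    df <- df_com
    p <- if (qbar == 0) 1 else 0
  } else {
    lambda <- (1 + 1 / m) * B / Tv
    if (lambda < .Machine$double.eps) {
      df <- df_com
    } else {
      df_old <- (m - 1) / lambda^2
      if (is.finite(df_com)) {
        df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
        df <- df_old * df_obs / (df_old + df_obs)
      } else {
        df <- df_old
      }
    }
    tstat <- qbar / sqrt(Tv)
    p <- if (is.finite(df)) 2 * pt(-abs(tstat), df) else 2 * pnorm(-abs(tstat))
  }
  structure(list(estimate = qbar, within_var = W, between_var = B,
                 total_var = Tv, df = df, p_value = p, m = m),
            class = "cati_pooled")
}

#' @export
print.cati_pooled <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (SE %.4f), df %.1f, p %.4g [m = %d]\n",
              x$estimate, sqrt(x$total_var), x$df, x$p_value, x$m))
  invisible(x)
}

#' Serialize / restore an imputation set
#'
#' Writes the `m` completed copies as CSV files plus a JSON manifest
#' (seed, m, cycle count) in `dir`.
#'
#' @param imps A `cati_imputation_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputation_set <- function(imps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_len(imps$m)) {
    write.csv(as.data.frame(imps$copies[[l]]),
              file.path(dir, sprintf("imputation_%02d.csv", l)),
              row.names = FALSE, na = "")
  }
  jsonlite::write_json(list(m = imps$m, seed = imps$seed, iter = imps$iter,
                            complete = imps$complete),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
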