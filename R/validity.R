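# Weighted Efron (squared-residual) R^2; coincides with ordinary R^2 for
# linear models, keeping the full-minus-base partial R^2 arithmetic
# well-defined across outcome families.
efron_r2 <- function(y, fitted, w) {
  ybar <- weighted.mean(y, w)
  1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
}

# Average marginal effect of a +1 shift in `score_col` for a weighted
# logistic fit, with an influence-function variance that accounts for both
# the sampling of beta and the averaging over the sample.
ame_logistic <- function(X, y, wt, score_col, method = c("fd", "derivative")) {
  method <- match.arg(method)
  fit <- suppressWarnings(glm.fit(X, y, weights = wt, family = binomial()))
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  b_s <- beta[score_col]
  n <- nrow(X)
  v <- wt / sum(wt)
  if (method == "fd") {
    eta1 <- eta + b_s
    p1 <- plogis(eta1)
    g <- p1 - p
    dp1 <- p1 * (1 - p1)
    dp <- p * (1 - p)
    e_s <- as.numeric(colnames(X) == score_col)
    # dAME/dbeta: sum_i v_i [p'(eta_i + b_s)(x_i + e_s) - p'(eta_i) x_i]
    G <- drop(crossprod(X, v * (dp1 - dp))) + sum(v * dp1) * e_s
  } else {
    dp <- p * (1 - p)
    g <- dp * b_s
    ddp <- dp * (1 - 2 * p)
    e_s <- as.numeric(colnames(X) == score_col)
    G <- drop(crossprod(X, v * ddp * b_s)) + sum(v * dp) * e_s
  }
  ame <- sum(v * g)
  A <- crossprod(X * sqrt(wt * p * (1 - p)))
  IF_beta <- t(n * solve(A, t(X * (wt * (y - p))))) # n x p
  infl <- n * v * (g - ame) + drop(IF_beta %*% G)
  list(ame = ame, var = sum(infl^2) / n^2, infl = infl, beta = beta,
       fitted = p, fit = fit)
}

#' Predictive validity of an index for a binary young-adult outcome
#'
#' Per imputation copy, a weighted logistic regression of the outcome on the
#' standardized index score plus demographics (age, sex, race/ethnicity) is
#' fitted with attrition weights; the average marginal effect of a one
#' standard deviation increase in the score is the weighted sample mean of
#' `p(score + 1) - p(score)`.  AMEs and their influence-function variances
#' are pooled across imputations with Rubin's rules.  The partial R-squared
#' is Efron's R-squared of the full model minus that of the
#' demographics-only model (averaged across imputations).
#'
#' @param imps A `cati_imputation_set`.
#' @param scores List of per-imputation `cati_scores` (or a single
#'   `cati_scores` reused for all copies).
#' @param outcome `"ever_fair_poor_health"` or `"ever_depressed"` (any
#'   binary column).
#' @param variant Label for reporting.
#' @param ame_method `"fd"` (finite difference, default) or
#'   `"derivative"`.
#' @param keep_fits Keep per-imputation influence functions and design
#'   matrices (needed by [compare_indices()]).
#' @return A `cati_margin`: estimate (percentage-point change per SD, as a
#'   proportion), `ci95`, `p_value`, `partial_r2`, `r2_full`, `r2_base`,
#'   pooled details and (optionally) per-imputation fits.
#' @export
binary_validity <- function(imps, scores, outcome, variant = "index",
                            ame_method = "fd", keep_fits = TRUE) {
  scores <- as_score_list(scores, imps$m)
  per <- vector("list", imps$m)
  run_one <- function(l) {
    d <- imps$copies[[l]]
    y <- d[[outcome]]
    if (length(unique(y)) < 2) {
      stop("outcome ", outcome, " has no variation", call. = FALSE)
    }
    wt <- d$attrition_weight
    demo <- design_demographics(d)
    X <- cbind(`(Intercept)` = 1, score = scores[[l]]$cati_std, demo)
    res <- ame_logistic(X, y, wt, "score", method = ame_method)
    Xb <- cbind(`(Intercept)` = 1, demo)
    fit_b <- suppressWarnings(glm.fit(Xb, y, weights = wt,
                                      family = binomial()))
    res$r2_full <- efron_r2(y, res$fitted, wt)
    res$r2_base <- efron_r2(y, fit_b$fitted.values, wt)
    res$y <- y; res$X <- X; res$wt <- wt
    res
  }
  if (isTRUE(imps$complete)) {
    per <- rep(list(run_one(1)), imps$m)
  } else {
    per <- lapply(seq_len(imps$m), run_one)
  }
  finalize_margin(per, outcome, variant, scale = 1, keep_fits = keep_fits)
}

as_score_list <- function(scores, m) {
  if (inherits(scores, "cati_scores")) rep(list(scores), m) else scores
}

finalize_margin <- function(per, outcome, variant, scale, keep_fits) {
  m <- length(per)
  if (m >= 2) {
    pooled <- pool_estimates(lapply(per, function(f) c(f$ame, f$var)))
    est <- pooled$estimate
    se <- sqrt(pooled$total_var)
    pval <- pooled$p_value
  } else {
    pooled <- NULL
    est <- per[[1]]$ame
    se <- sqrt(per[[1]]$var)
    pval <- 2 * pnorm(-abs(est / se))
  }
  r2_full <- mean(vapply(per, `[[`, numeric(1), "r2_full"))
  r2_base <- mean(vapply(per, `[[`, numeric(1), "r2_base"))
  out <- list(outcome = outcome, variant = variant,
              estimate = est * scale,
              ci95 = c(est - 1.96 * se, est + 1.96 * se) * scale,
              se = se * scale, p_value = pval,
              partial_r2 = r2_full - r2_base,
              r2_full = r2_full, r2_base = r2_base,
              pooled = pooled)
  if (keep_fits) out$fits <- per
  class(out) <- "cati_margin"
  out
}

#' @export
print.cati_margin <- function(x, ...) {
  cat(sprintf("%s ~ %s: marginal effect %.4f [%.4f, %.4f], p = %.3g\n",
              x$outcome, x$variant, x$estimate, x$ci95[1], x$ci95[2],
              x$p_value))
  cat(sprintf("  partial R^2 = %.4f (%.4f vs %.4f)\n",
              x$partial_r2, x$r2_full, x$r2_base))
  invisible(x)
}

#' Predictive validity of an index for peak earnings
#'
#' Per imputation copy, a weighted Poisson regression of peak earnings on
#' the standardized score, demographics, years observed at ages 20--29,
#' enrollment at peak, and household position, with a robust (sandwich,
#' HC0) covariance.  The reported effect is the percent change in earnings
#' per one standard deviation of the score, `100 (exp(beta) - 1)`, pooled
#' across imputations (delta-method variance); the response-scale average
#' marginal effect (dollars per SD) is also computed.  The partial
#' R-squared compares squared-correlation R-squared of the full vs the
#' controls-only model.
#'
#' @inheritParams binary_validity
#' @param outcome Earnings column (default `"peak_earnings"`).
#' @return A `cati_margin` with `estimate` in percent and extra fields
#'   `beta_score` and `ame_dollars`.
#' @export
earnings_validity <- function(imps, scores, outcome = "peak_earnings",
                              variant = "index", keep_fits = FALSE) {
  scores <- as_score_list(scores, imps$m)
  run_one <- function(l) {
    d <- imps$copies[[l]]
    y <- d[[outcome]]
    if (all(y == 0)) stop("all earnings are zero", call. = FALSE)
    dat <- data.frame(y = y, score = scores[[l]]$cati_std,
                      age = d$age, sex = d$sex,
                      race_ethnicity = d$race_ethnicity,
                      years = d$years_observed_20_29,
                      enrolled = d$enrolled_at_peak,
                      position = d$household_position,
                      wt = d$attrition_weight)
    fit <- glm(y ~ score + age + sex + race_ethnicity + years + enrolled +
                 position, family = quasipoisson(), data = dat,
               weights = wt)
    V <- sandwich::vcovHC(fit, type = "HC0")
    b <- coef(fit)["score"]
    vb <- V["score", "score"]
    mu <- fit$fitted.values
    mu1 <- mu * exp(b)
    fit0 <- glm(y ~ age + sex + race_ethnicity + years + enrolled + position,
                family = quasipoisson(), data = dat, weights = wt)
    r2 <- function(f) cor(dat$y, f$fitted.values)^2
    list(ame = b, var = vb,
         pct = 100 * (exp(b) - 1), pct_var = (100 * exp(b))^2 * vb,
         ame_dollars = weighted.mean(mu1 - mu, dat$wt),
         r2_full = r2(fit), r2_base = r2(fit0),
         se_classical = sqrt(vcov(fit)["score", "score"] /
                               summary(fit)$dispersion),
         fit = if (keep_fits) fit else NULL)
  }
  per <- if (isTRUE(imps$complete)) rep(list(run_one(1)), imps$m)
         else lapply(seq_len(imps$m), run_one)
  m <- length(per)
  pooled_pct <- pool_estimates(lapply(per, function(f) c(f$pct, f$pct_var)))
  pooled_b <- pool_estimates(lapply(per, function(f) c(f$ame, f$var)))
  r2_full <- mean(vapply(per, `[[`, numeric(1), "r2_full"))
  r2_base <- mean(vapply(per, `[[`, numeric(1), "r2_base"))
  out <- list(outcome = outcome, variant = variant,
              estimate = pooled_pct$estimate,
              ci95 = pooled_pct$estimate +
                c(-1.96, 1.96) * sqrt(pooled_pct$total_var),
              se = sqrt(pooled_pct$total_var),
              p_value = pooled_pct$p_value,
              partial_r2 = r2_full - r2_base,
              r2_full = r2_full, r2_base = r2_base,
              beta_score = pooled_b$estimate,
              ame_dollars = mean(vapply(per, `[[`, numeric(1),
                                        "ame_dollars")),
              pooled = pooled_pct)
  if (keep_fits) out$fits <- per
  class(out) <- "cati_margin"
  out
}

#' Compare the marginal effects of two index variants
#'
#' Tests whether two indices fitted on the same respondents and outcome
#' differ in their average marginal effect.  The default method stacks the
#' two estimating-equation systems and uses the empirical covariance of the
#' per-respondent influence functions (which accounts for the shared
#' sample, in the spirit of seemingly-unrelated estimation); a paired
#' bootstrap is available as a cross-check.  Differences and variances are
#' pooled across imputations.
#'
#' @param effect_a,effect_b `cati_margin` objects from [binary_validity()]
#'   fitted with `keep_fits = TRUE` on identical samples.
#' @param method `"stacked"` (default) or `"bootstrap"`.
#' @param reps Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A `cati_comparison`: `difference`, `se`, `p_value`, `method`.
#' @export
compare_indices <- function(effect_a, effect_b, method = c("stacked",
                                                           "bootstrap"),
                            reps = 999, seed = 1L) {
  method <- match.arg(method)
  fa <- effect_a$fits
  fb <- effect_b$fits
  if (is.null(fa) || is.null(fb)) {
    stop("compare_indices needs fits kept via keep_fits = TRUE",
         call. = FALSE)
  }
  if (length(fa) != length(fb) ||
      any(vapply(seq_along(fa), function(l) {
        length(fa[[l]]$infl) != length(fb[[l]]$infl) ||
          !isTRUE(all.equal(fa[[l]]$y, fb[[l]]$y))
      }, logical(1)))) {
    stop("the two effects must be fitted on identical samples and outcome",
         call. = FALSE)
  }
  m <- length(fa)
  if (method == "stacked") {
    per <- lapply(seq_len(m), function(l) {
      n <- length(fa[[l]]$infl)
      d <- fa[[l]]$ame - fb[[l]]$ame
      v <- sum((fa[[l]]$infl - fb[[l]]$infl)^2) / n^2
      c(d, v)
    })
  } else {
    per <- lapply(seq_len(m), function(l) {
      A <- fa[[l]]; B <- fb[[l]]
      n <- length(A$y)
      d_hat <- A$ame - B$ame
      ds <- with_seed(substream_seed(seed, "boot", l), {
        vapply(seq_len(reps), function(r) {
          idx <- sample.int(n, n, replace = TRUE)
          ra <- ame_logistic(A$X[idx, , drop = FALSE], A$y[idx],
                             A$wt[idx], "score")
          rb <- ame_logistic(B$X[idx, , drop = FALSE], B$y[idx],
                             B$wt[idx], "score")
          ra$ame - rb$ame
        }, numeric(1))
      })
      c(d_hat, var(ds))
    })
  }
  if (m >= 2) {
    pooled <- pool_estimates(per)
    d <- pooled$estimate
    se <- sqrt(pooled$total_var)
    p <- pooled$p_value
  } else {
    d <- per[[1]][1]
    se <- sqrt(per[[1]][2])
    p <- if (d == 0) 1 else if (se == 0) 0 else 2 * pnorm(-abs(d / se))
  }
  structure(list(pair = c(effect_a$variant, effect_b$variant),
                 difference = d, se = se, p_value = p, method = method),
            class = "cati_comparison")
}

#' @export
print.cati_comparison <- function(x, ...) {
  cat(sprintf("AME difference (%s - %s): %.4f (SE %.4f), p = %.3g [%s]\n",
              x$pair[1], x$pair[2], x$difference, x$se, x$p_value,
              x$method))
  invisible(x)
}
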