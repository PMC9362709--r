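#' Adaptive LASSO screen for one imputation copy
#'
#' Two-stage procedure on a single completed dataset: a ridge pilot fit on a
#' random 80% training split yields per-component penalty weights
#' `1 / |pilot|^gamma`; a weighted-penalty LASSO path (100 log-spaced
#' penalties) is fitted on the training split with demographic controls
#' unpenalized, and the penalty minimizing mean squared error on the held
#' out 20% is chosen.  Components with nonzero coefficients at that penalty
#' are returned.  Components whose pilot coefficient is exactly zero get an
#' infinite penalty (excluded, not an error); constant columns are dropped
#' with a warning.  The screen is run unweighted — attrition weights enter
#' only the post-LASSO regressions.
#'
#' @param X Numeric design matrix: 0/1 component columns plus demographic
#'   columns.
#' @param y Standardized outcome (one subjective scale).
#' @param penalized Character vector naming the penalized (component)
#'   columns of `X`; all other columns are treated as unpenalized controls.
#' @param split_fraction Held-out validation fraction (default 0.2).
#' @param seed Integer seed for the train/validation split.
#' @param gamma Adaptive-weight exponent (default 1).
#' @param nlambda Number of penalties on the log-spaced grid.
#' @param ridge_pilot Ridge penalty (per observation) for the pilot fit.
#' @return Character vector of kept component names (possibly empty), with
#'   attributes `lambda` (chosen penalty) and `cv_mse`.
#' @export
fit_adaptive_lasso <- function(X, y, penalized = colnames(X),
                               split_fraction = 0.2, seed = 1L,
                               gamma = 1, nlambda = 100,
                               ridge_pilot = 0.01) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  keep_cols <- apply(X, 2, function(col) length(unique(col)) > 1)
  if (!all(keep_cols)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[!keep_cols], collapse = ", "), call. = FALSE)
    X <- X[, keep_cols, drop = FALSE]
    penalized <- intersect(penalized, colnames(X))
  }
  n <- nrow(X)
  idx <- with_seed(seed, sample.int(n, size = floor((1 - split_fraction) * n)))
  Xtr <- X[idx, , drop = FALSE]
  ytr <- y[idx]
  Xva <- X[-idx, , drop = FALSE]
  yva <- y[-idx]

  # ridge pilot on the training split (defined under collinearity)
  Xc <- scale(Xtr, center = TRUE, scale = FALSE)
  yc <- ytr - mean(ytr)
  A <- crossprod(Xc) / nrow(Xc) + ridge_pilot * diag(ncol(Xc))
  pilot <- drop(solve(A, crossprod(Xc, yc) / nrow(Xc)))
  names(pilot) <- colnames(X)

  pen_idx <- which(colnames(X) %in% penalized)
  w <- rep(0, ncol(X)) # unpenalized controls
  w[pen_idx] <- 1 / abs(pilot[pen_idx])^gamma
  excluded <- pen_idx[!is.finite(w[pen_idx])]
  w[excluded] <- 0 # handled via `exclude`
  fit <- glmnet::glmnet(Xtr, ytr, family = "gaussian",
                        penalty.factor = w,
                        exclude = excluded,
                        nlambda = nlambda, lambda.min.ratio = 1e-4,
                        standardize = FALSE)
  pred <- predict(fit, newx = Xva)
  mse <- colMeans((yva - pred)^2)
  best <- which.min(mse)
  beta <- fit$beta[, best]
  kept <- intersect(penalized, names(beta)[abs(beta) > 0])
  structure(kept, lambda = fit$lambda[best], cv_mse = unname(mse[best]))
}

#' Aggregate per-imputation kept-sets with a majority retention rule
#'
#' A component initially survives the LASSO stage only if it was kept in at
#' least `ceiling(m/2)` of the `m` imputations (10 of 20 at the default);
#' otherwise its status is `removed_lasso`.
#'
#' @param kept_sets List of character vectors (one per imputation).
#' @param candidates Character vector of all candidate component names.
#' @param m Number of imputations (defaults to `length(kept_sets)`).
#' @return A `cati_selection_mask`: data frame with `component`,
#'   `retention_count` and `status` (`kept` / `removed_lasso`).
#' @export
aggregate_selection <- function(kept_sets, candidates, m = length(kept_sets)) {
  if (length(kept_sets) == 0) stop("no kept-sets supplied", call. = FALSE)
  counts <- vapply(candidates, function(z) {
    sum(vapply(kept_sets, function(s) z %in% s, logical(1)))
  }, integer(1))
  threshold <- ceiling(m / 2)
  out <- data.frame(component = candidates,
                    retention_count = unname(counts),
                    status = ifelse(counts >= threshold, "kept",
                                    "removed_lasso"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  class(out) <- c("cati_selection_mask", "data.frame")
  out
}

# Pooled attrition-weighted least squares of a standardized outcome on the
# given components + demographics across an imputation set.  When the set is
# flagged complete (identical copies), the fit is done once and replicated.
pooled_wls <- function(imps, outcome_values, comps) {
  m <- imps$m
  fit_one <- function(l) {
    d <- imps$copies[[l]]
    y <- outcome_values[[l]]
    X <- cbind(`(Intercept)` = 1,
               if (length(comps))
                 as.matrix(as.data.frame(d[paste0("comp_", comps)])),
               design_demographics(d))
    if (length(comps)) {
      colnames(X)[2:(1 + length(comps))] <- comps
    }
    wt <- d$attrition_weight
    fit <- lm.wfit(X, y, wt)
    p <- ncol(X)
    df <- nrow(X) - p
    rss <- sum(wt * fit$residuals^2)
    sigma2 <- rss / df
    XtWX <- crossprod(X * sqrt(wt))
    V <- tryCatch(solve(XtWX) * sigma2,
                  error = function(e) MASS_ginv(XtWX) * sigma2)
    list(coef = fit$coefficients[comps], var = diag(V)[comps], df = df)
  }
  fits <- if (isTRUE(imps$complete)) rep(list(fit_one(1)), m)
          else lapply(seq_len(m), fit_one)
  df_com <- fits[[1]]$df
  pooled <- lapply(seq_along(comps), function(k) {
    pool_estimates(lapply(fits, function(f) c(f$coef[k], f$var[k])),
                   df_com = df_com)
  })
  names(pooled) <- comps
  pooled
}

# Minimal Moore-Penrose fallback (avoids importing MASS for one corner case).
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' One-at-a-time backward elimination under sign and p-value rules
#'
#' Starting from the LASSO-surviving components, repeatedly fits pooled
#' attrition-weighted regressions of the standardized outcome on the kept
#' components plus demographics.  If any kept component has a pooled
#' coefficient whose sign contradicts the expectation for the outcome, the
#' wrong-signed component with the largest pooled p-value is removed first;
#' otherwise, if any pooled p-value exceeds `p_cut` (0.25), the component
#' with the largest p-value is removed.  Iterates to a fixed point.
#' Removals are marked `removed_post`.
#'
#' @param imps A `cati_imputation_set`.
#' @param outcome One of `fl, pd, wr, sa, ls` (a scale) — its standardized
#'   wave-averaged values are computed per imputation copy — or a list of
#'   per-imputation numeric outcome vectors.
#' @param mask A `cati_selection_mask` from [aggregate_selection()].
#' @param sign_expectations Named vector over outcomes (+1 / -1); defaults
#'   to [cati_sign_expectations()] for the five scales.  Use a single
#'   unnamed value for a custom outcome.
#' @param p_cut Removal threshold for the pooled p-value.
#' @return List with `mask` (statuses updated to `removed_post`),
#'   `coefficients` (data frame: component, estimate, se, p, status over all
#'   candidates; zeros where removed) and `trace` (removal log).
#' @export
backward_eliminate <- function(imps, outcome, mask,
                               sign_expectations = cati_sign_expectations(),
                               p_cut = 0.25) {
  if (is.character(outcome) && length(outcome) == 1) {
    expected_sign <- unname(sign_expectations[outcome])
    yvals <- lapply(imps$copies, function(d) preprocess_scales(d)[, outcome])
  } else {
    expected_sign <- if (length(sign_expectations) == 1)
      unname(sign_expectations) else 1
    yvals <- outcome
  }
  kept <- mask$component[mask$status == "kept"]
  trace <- character(0)
  pooled <- list()
  while (length(kept) > 0) {
    pooled <- pooled_wls(imps, yvals, kept)
    est <- vapply(pooled, `[[`, numeric(1), "estimate")
    pv <- vapply(pooled, `[[`, numeric(1), "p_value")
    wrong <- sign(est) != expected_sign
    if (any(wrong)) {
      drop_z <- kept[wrong][which.max(pv[wrong])]
      trace <- c(trace, paste0(drop_z, ": wrong sign (p=",
                               signif(pv[drop_z], 3), ")"))
    } else if (any(pv > p_cut)) {
      drop_z <- kept[which.max(pv)]
      trace <- c(trace, paste0(drop_z, ": p=", signif(max(pv), 3),
                               " > ", p_cut))
    } else break
    kept <- setdiff(kept, drop_z)
    mask$status[mask$component == drop_z] <- "removed_post"
    pooled <- pooled[kept]
  }
  if (length(kept) == 0 && length(trace) > 0) {
    message("backward elimination removed every component for this outcome")
  }
  coefs <- data.frame(component = mask$component,
                      estimate = 0, se = 0, p = NA_real_,
                      status = mask$status, stringsAsFactors = FALSE)
  for (z in kept) {
    i <- match(z, coefs$component)
    coefs$estimate[i] <- pooled[[z]]$estimate
    coefs$se[i] <- sqrt(pooled[[z]]$total_var)
    coefs$p[i] <- pooled[[z]]$p_value
  }
  list(mask = mask, coefficients = coefs, trace = trace)
}

#' Full two-step selection over the five subjective scales
#'
#' For each scale: per-imputation adaptive-LASSO screens (unweighted, fresh
#' 80/20 split per imputation with seeds derived from the master seed), the
#' majority retention rule, then pooled attrition-weighted backward
#' elimination.  Demographic controls are never penalized nor eliminable.
#'
#' @param imps A `cati_imputation_set`.
#' @param candidates Character vector of candidate component names (bare
#'   names, without the `comp_` column prefix).
#' @param seed Master seed for the split substreams.
#' @param outcomes Scales to use as benchmarks (default all five).
#' @param split_fraction,nlambda,p_cut Passed through to the stages.
#' @return A `cati_coefmat`: list with `beta` (5 x K pooled coefficient
#'   matrix, zeros where removed), `se`, `p`, `masks` (per-outcome
#'   selection masks with POST statuses), `table` (tidy per outcome x
#'   component data frame) and `trace`.
#' @export
select_components <- function(imps, candidates, seed = 1L,
                              outcomes = CATI_SCALES,
                              split_fraction = 0.2, nlambda = 100,
                              p_cut = 0.25) {
  K <- length(candidates)
  beta <- se <- matrix(0, length(outcomes), K,
                       dimnames = list(outcomes, candidates))
  pmat <- matrix(NA_real_, length(outcomes), K,
                 dimnames = list(outcomes, candidates))
  masks <- list()
  traces <- list()
  scales_per_copy <- lapply(imps$copies, preprocess_scales)
  demo_per_copy <- lapply(imps$copies, design_demographics)
  comp_cols <- paste0("comp_", candidates)
  for (j in outcomes) {
    kept_sets <- vector("list", imps$m)
    for (l in seq_len(imps$m)) {
      d <- imps$copies[[l]]
      X <- cbind(as.matrix(as.data.frame(d[comp_cols])), demo_per_copy[[l]])
      colnames(X)[seq_len(K)] <- candidates
      y <- scales_per_copy[[l]][, j]
      kept_sets[[l]] <- suppressWarnings(fit_adaptive_lasso(
        X, y, penalized = candidates,
        split_fraction = split_fraction,
        seed = substream_seed(seed, "lasso", j, l),
        nlambda = nlambda
      ))
    }
    mask <- aggregate_selection(kept_sets, candidates, m = imps$m)
    elim <- backward_eliminate(imps, j, mask, p_cut = p_cut)
    masks[[j]] <- elim$mask
    traces[[j]] <- elim$trace
    beta[j, ] <- elim$coefficients$estimate
    se[j, ] <- elim$coefficients$se
    pmat[j, ] <- elim$coefficients$p
  }
  tab <- do.call(rbind, lapply(outcomes, function(j) {
    data.frame(outcome = j, component = candidates,
               estimate = beta[j, ], se = se[j, ], p = pmat[j, ],
               status = masks[[j]]$status,
               retention_count = masks[[j]]$retention_count,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(beta = beta, se = se, p = pmat, masks = masks,
                 table = tab, trace = traces),
            class = "cati_coefmat")
}

#' @export
print.cati_coefmat <- function(x, ...) {
  cat("Pooled selection coefficients (rows = scales, 0 = removed):\n")
  print(round(x$beta, 3))
  invisible(x)
}
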