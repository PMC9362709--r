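#' Pipeline configuration
#'
#' Options controlling an end-to-end index construction run.
#'
#' @param m Number of imputations.
#' @param seed Master seed; all stage randomness (imputation draws,
#'   train/validation splits, bootstraps) flows from it through named
#'   substreams.
#' @param inclusion `"individual"` (default: individual-level components
#'   only), `"individual+contextual"`, or `"custom"` with `components`
#'   naming the candidates.
#' @param components Custom candidate list (used when
#'   `inclusion = "custom"`).
#' @param benchmarks `"scales"` (the five subjective scales, default) or
#'   the name of a single alternative benchmark column (e.g.
#'   `"peak_earnings"`); in the single-benchmark mode weights reduce to
#'   normalized absolute coefficients.
#' @param benchmark_sign Expected coefficient sign in single-benchmark
#'   mode (+1 if higher benchmark values indicate better well-being).
#' @param p_cut Backward-elimination p-value threshold.
#' @param split_fraction,nlambda Adaptive-LASSO options.
#' @param iter Chained-equation cycles.
#' @param ame_method `"fd"` or `"derivative"` marginal effects.
#' @param equal_weight_set Components counted by the equal-weight
#'   comparator; defaults to the analysis candidates.
#' @return A `cati_config` list.
#' @export
cati_config <- function(m = 20, seed = 1L, inclusion = "individual",
                        components = NULL, benchmarks = "scales",
                        benchmark_sign = 1, p_cut = 0.25,
                        split_fraction = 0.2, nlambda = 100, iter = 10,
                        ame_method = "fd", equal_weight_set = NULL) {
  stopifnot(inclusion %in% c("individual", "individual+contextual",
                             "custom"))
  if (inclusion == "custom" && is.null(components)) {
    stop("configuration error: inclusion = 'custom' needs `components`",
         call. = FALSE)
  }
  structure(list(m = m, seed = as.integer(seed), inclusion = inclusion,
                 components = components, benchmarks = benchmarks,
                 benchmark_sign = benchmark_sign, p_cut = p_cut,
                 split_fraction = split_fraction, nlambda = nlambda,
                 iter = iter, ame_method = ame_method,
                 equal_weight_set = equal_weight_set),
            class = "cati_config")
}

candidate_names <- function(cohort, config) {
  cat_tab <- attr(cohort, "components")
  if (is.null(cat_tab)) {
    all_comps <- sub("^comp_", "", component_columns(cohort))
    cat_tab <- data.frame(name = all_comps, class = "individual",
                          stringsAsFactors = FALSE)
  }
  switch(config$inclusion,
         "individual" = cat_tab$name[cat_tab$class == "individual"],
         "individual+contextual" = cat_tab$name,
         "custom" = {
           unknown <- setdiff(config$components, cat_tab$name)
           if (length(unknown)) {
             stop("unknown components: ", paste(unknown, collapse = ", "),
                  call. = FALSE)
           }
           config$components
         })
}

#' Run the full index-construction pipeline
#'
#' Imputes, selects, weights, scores and validates in one call:
#' chained-equations MI, per-imputation adaptive LASSO with the majority
#' retention rule, pooled weighted backward elimination, PCA double
#' weighting (per-imputation scale correlation matrices are averaged before
#' the eigendecomposition), scoring of every imputation copy, and
#' predictive-validity models for both binary outcomes and peak earnings,
#' including an equal-weight comparator index and stacked
#' seemingly-unrelated comparisons against it.  Identical configuration
#' (including the seed) reproduces identical output.
#'
#' @param cohort A `cati_cohort` (possibly with missing cells).
#' @param config A [cati_config()].
#' @param out_dir Optional directory: weights, scores, the validity report
#'   and a manifest are written there.
#' @return A `cati_pipeline_result` with elements `weights`, `loadings`,
#'   `coefs`, `scores` (average across imputations), `validity` (list of
#'   `cati_margin`), `comparisons`, `candidates`, `config`.
#' @export
run_pipeline <- function(cohort, config = cati_config(), out_dir = NULL) {
  candidates <- candidate_names(cohort, config)
  imps <- impute_chained(cohort, m = config$m,
                         seed = substream_seed(config$seed, "mi"),
                         iter = config$iter)
  if (identical(config$benchmarks, "scales")) {
    coefs <- select_components(imps, candidates,
                               seed = substream_seed(config$seed, "select"),
                               split_fraction = config$split_fraction,
                               nlambda = config$nlambda,
                               p_cut = config$p_cut)
    Rbar <- Reduce(`+`, lapply(imps$copies, function(d) {
      cor(preprocess_scales(d))
    })) / imps$m
    loadings <- pca_first_component(Rbar)
    weights <- compute_weights(loadings, coefs)
  } else {
    res <- select_single_benchmark(imps, candidates, config)
    coefs <- res$coefs
    loadings <- res$loadings
    weights <- res$weights
  }

  score_list <- lapply(imps$copies, score_index, weights = weights)
  scores <- score_list[[1]]
  scores$cati <- rowMeans(vapply(score_list, `[[`, numeric(nrow(scores)),
                                 "cati"))
  scores$cati_std <- (scores$cati - mean(scores$cati)) / sd(scores$cati)

  eq_set <- config$equal_weight_set %||% candidates
  eq_list <- lapply(imps$copies, equal_weight_index,
                    component_list = eq_set)

  validity <- list(
    fair_poor_health = binary_validity(imps, score_list,
                                       "ever_fair_poor_health",
                                       variant = "cati",
                                       ame_method = config$ame_method),
    depressed = binary_validity(imps, score_list, "ever_depressed",
                                variant = "cati",
                                ame_method = config$ame_method),
    earnings = earnings_validity(imps, score_list, variant = "cati"),
    fair_poor_health_equal = binary_validity(imps, eq_list,
                                             "ever_fair_poor_health",
                                             variant = "equal_weight",
                                             ame_method = config$ame_method),
    depressed_equal = binary_validity(imps, eq_list, "ever_depressed",
                                      variant = "equal_weight",
                                      ame_method = config$ame_method),
    earnings_equal = earnings_validity(imps, eq_list,
                                       variant = "equal_weight")
  )
  comparisons <- list(
    fair_poor_health = compare_indices(validity$fair_poor_health,
                                       validity$fair_poor_health_equal),
    depressed = compare_indices(validity$depressed,
                                validity$depressed_equal)
  )
  # influence vectors are only needed for the comparisons above
  for (nm in names(validity)) validity[[nm]]$fits <- NULL

  result <- structure(list(weights = weights, loadings = loadings,
                           coefs = coefs, scores = scores,
                           validity = validity, comparisons = comparisons,
                           candidates = candidates, config = config),
                      class = "cati_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

select_single_benchmark <- function(imps, candidates, config) {
  bench <- config$benchmarks
  yvals <- lapply(imps$copies, function(d) {
    y <- as.numeric(d[[bench]])
    (y - mean(y)) / sd(y)
  })
  demo_per_copy <- lapply(imps$copies, design_demographics)
  comp_cols <- paste0("comp_", candidates)
  kept_sets <- lapply(seq_len(imps$m), function(l) {
    d <- imps$copies[[l]]
    X <- cbind(as.matrix(as.data.frame(d[comp_cols])), demo_per_copy[[l]])
    colnames(X)[seq_along(candidates)] <- candidates
    suppressWarnings(fit_adaptive_lasso(
      X, yvals[[l]], penalized = candidates,
      split_fraction = config$split_fraction,
      seed = substream_seed(config$seed, "lasso", bench, l),
      nlambda = config$nlambda))
  })
  mask <- aggregate_selection(kept_sets, candidates, m = imps$m)
  elim <- backward_eliminate(imps, yvals, mask,
                             sign_expectations = config$benchmark_sign,
                             p_cut = config$p_cut)
  beta <- matrix(elim$coefficients$estimate, nrow = 1,
                 dimnames = list(bench, candidates))
  loadings <- new_loading_vector(setNames(1, bench), 1)
  list(coefs = structure(list(beta = beta,
                              masks = setNames(list(elim$mask), bench),
                              table = elim$coefficients,
                              trace = elim$trace),
                         class = "cati_coefmat"),
       loadings = loadings,
       weights = compute_weights(setNames(1, bench), beta))
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(result$weights)[c("component", "weight")],
            file.path(out_dir, "weights.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$scores),
            file.path(out_dir, "scores.csv"), row.names = FALSE)
  val <- lapply(result$validity, function(v) {
    list(outcome = v$outcome, variant = v$variant, estimate = v$estimate,
         ci95 = v$ci95, p_value = v$p_value, partial_r2 = v$partial_r2,
         r2_full = v$r2_full, r2_base = v$r2_base)
  })
  cmp <- lapply(result$comparisons, function(x) {
    list(pair = x$pair, difference = x$difference, p_value = x$p_value)
  })
  jsonlite::write_json(list(validity = val, comparisons = cmp),
                       file.path(out_dir, "validity.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = result$config$seed, m = result$config$m,
    inclusion = result$config$inclusion,
    candidates = result$candidates,
    weights_checksum = sum(result$weights$weight * seq_along(
      result$weights$weight))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Index validity report", "",
          sprintf("- %s (%s): %.4f [%.4f, %.4f], partial R2 %.4f",
                  vapply(result$validity, `[[`, character(1), "outcome"),
                  vapply(result$validity, `[[`, character(1), "variant"),
                  vapply(result$validity, `[[`, numeric(1), "estimate"),
                  vapply(result$validity, function(v) v$ci95[1], numeric(1)),
                  vapply(result$validity, function(v) v$ci95[2], numeric(1)),
                  vapply(result$validity, `[[`, numeric(1), "partial_r2")))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.cati_pipeline_result <- function(x, ...) {
  cat("Index construction result:", length(x$candidates),
      "candidates,", sum(x$weights$weight > 0), "weighted components\n")
  print(x$weights)
  for (v in x$validity[1:3]) print(v)
  invisible(x)
}

#' Published reference inputs and weights (CATI 1.0)
#'
#' Loads the bundled fixture of the published first-principal-component
#' loadings, the per-scale pooled regression coefficients of the 11
#' surviving components (removed cells as zero), and the published
#' normalized weights.
#'
#' @return List with `loadings` (a `cati_loadings`), `beta`
#'   (5 x 11 matrix) and `published` (data frame component/weight).
#' @export
cati_reference_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "cati",
                                 mustWork = TRUE)
  lo <- read.csv(ext("cati10_pca_loadings.csv"))
  co <- read.csv(ext("cati10_coefficients.csv"))
  we <- read.csv(ext("cati10_weights.csv"))
  loadings <- new_loading_vector(setNames(lo$loading, lo$scale),
                                 lo$eigenvalue)
  beta <- t(as.matrix(co[CATI_SCALES]))
  colnames(beta) <- co$component
  rownames(beta) <- CATI_SCALES
  list(loadings = loadings, beta = beta, published = we)
}

#' Golden check against the published index weights
#'
#' Recomputes the 11 normalized weights from the bundled published loadings
#' and coefficients via [compute_weights()] and compares them, one by one,
#' to the published values.
#'
#' @param tolerance Allowed absolute deviation per weight (default 0.005,
#'   the slack implied by the three-decimal rounding of the published
#'   inputs).
#' @return Data frame of class `cati_golden`: `component`, `computed`,
#'   `published`, `delta`, `pass`; attributes `top3_share` and `all_pass`.
#' @export
golden_check <- function(tolerance = 0.005) {
  fx <- cati_reference_fixture()
  w <- compute_weights(fx$loadings, fx$beta)
  out <- merge(data.frame(component = w$component, computed = w$weight),
               setNames(fx$published[c("component", "weight")],
                        c("component", "published")),
               by = "component")
  out$delta <- out$computed - out$published
  out$pass <- abs(out$delta) <= tolerance
  top3 <- sum(sort(w$weight, decreasing = TRUE)[1:3])
  attr(out, "top3_share") <- top3
  attr(out, "all_pass") <- all(out$pass)
  class(out) <- c("cati_golden", "data.frame")
  out
}

#' @export
print.cati_golden <- function(x, ...) {
  cat("Golden check of the double-weighting reconstruction:\n")
  print(data.frame(component = x$component,
                   computed = round(x$computed, 4),
                   published = x$published,
                   delta = round(x$delta, 4), pass = x$pass),
        row.names = FALSE)
  cat(sprintf("top-3 weight share: %.3f; all within tolerance: %s\n",
              attr(x, "top3_share"), attr(x, "all_pass")))
  invisible(x)
}
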