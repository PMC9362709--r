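#' Simulation configuration for a synthetic child cohort
#'
#' Describes the data-generating process the index pipeline assumes: binary
#' candidate components with fixed prevalences whose positive status shifts
#' five latent subjective well-being scales, a shared standard-normal latent
#' well-being factor, per-wave idiosyncratic noise, demographics, attrition
#' weights, young-adult outcomes driven by the latent factor, and a
#' missing-at-random mechanism.  The default configuration emulates a
#' PSID-like cohort: component prevalences, scale locations/spreads and
#' outcome rates match the descriptive statistics of the published CATI 1.0
#' analysis sample, and the scale model is calibrated so the first principal
#' component of the five scales explains roughly half their variance
#' (first eigenvalue near 2.6).
#'
#' Components are stored in positive framing (1 = good status, e.g.
#' "Food Secure"); the conventional negative-framing display labels are kept
#' in the `label_negative` column of `components`.
#'
#' @param n_children Number of children to simulate (>= 1).
#' @param components Data frame with columns `name`, `class`
#'   ("individual" or "contextual"), `prevalence` (probability of positive
#'   status) and optionally `label_negative`.
#' @param effects Numeric matrix, one row per component and one column per
#'   scale (`fl`, `pd`, `wr`, `sa`, `ls`): the shift in the latent scale
#'   (standard-normal latent units) caused by positive status.
#' @param scale_model List with per-scale vectors `loading` (loading on the
#'   shared latent well-being factor; signs of `pd`, `wr`, `sa` negative),
#'   `idio_sd` (per-wave idiosyncratic noise SD), `waves` (1--3 observation
#'   waves), `center` and `unit` (affine map to the native response range)
#'   and logical `integerize` (round to integers on the native scale, as for
#'   a 1--5 life-satisfaction item).
#' @param demographics_model List: `age_range` (years), `p_female`,
#'   `race_probs` (named, 4 levels, sums to 1).
#' @param outcome_model List with `health` and `depression`
#'   (`list(slope, prevalence)`: logit slope on latent well-being and target
#'   marginal prevalence) and `earnings` (`list(slope, sd_log, mean,
#'   coef_years, coef_enrolled, coef_spouse, coef_other)` for the
#'   log-linear peak-earnings model).
#' @param attrition_model List: `coef_age`, `coef_female`, `sd_log` for the
#'   log-normal attrition weight generator (weights normalized to mean 1).
#' @param missing_rate Target fraction of rows with at least one missing
#'   cell, in `[0, 1)`.
#' @param seed Integer master seed.
#'
#' @return An object of class `cati_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_children = 500, seed = 7)
#' cohort <- generate_cohort(cfg)
sim_config <- function(n_children = 5000,
                       components = cati_default_components(),
                       effects = cati_default_effects(components),
                       scale_model = cati_default_scale_model(),
                       demographics_model = list(
                         age_range = c(18, 28),
                         p_female = 0.51,
                         race_probs = c(white = 0.42, black = 0.40,
                                        latinx = 0.10, other = 0.08)
                       ),
                       outcome_model = list(
                         health = list(slope = -0.8, prevalence = 0.212),
                         depression = list(slope = -0.7, prevalence = 0.293),
                         earnings = list(slope = 0.15, sd_log = 0.8,
                                         mean = 31259,
                                         coef_years = 0.03,
                                         coef_enrolled = -0.25,
                                         coef_spouse = -0.05,
                                         coef_other = -0.25)
                       ),
                       attrition_model = list(coef_age = 0.01,
                                              coef_female = 0.05,
                                              sd_log = 0.15),
                       missing_rate = 0.40,
                       seed = 1L) {
  cfg <- structure(
    list(n_children = n_children, components = components,
         effects = effects, scale_model = scale_model,
         demographics_model = demographics_model,
         outcome_model = outcome_model, attrition_model = attrition_model,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "cati_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Default candidate-component catalog
#'
#' Thirteen individual-level and six contextual binary components with
#' prevalences matching the published analysis sample (positive framing).
#'
#' @return Data frame with columns `name`, `class`, `prevalence`,
#'   `label_negative`.
#' @export
cati_default_components <- function() {
  data.frame(
    name = c("food_secure", "attended_preschool", "grad_hs_on_time",
             "math_proficient", "reading_proficient", "non_low_birthweight",
             "non_obese", "not_fair_poor_health", "didnt_smoke",
             "didnt_drink", "didnt_try_marijuana", "never_pregnant",
             "never_arrested",
             "never_housing_burdened", "never_household_poverty",
             "never_parent_unemployed", "family_never_moved",
             "parent_hs_degree", "married_household_head"),
    class = c(rep("individual", 13), rep("contextual", 6)),
    prevalence = c(0.867, 0.376, 0.800, 0.244, 0.265, 0.729, 0.673, 0.939,
                   0.742, 0.823, 0.501, 0.753, 0.835,
                   0.395, 0.538, 0.483, 0.183, 0.735, 0.262),
    label_negative = c("Ever Food Insecure", "Never in Preschool",
                       "Didn't Graduate High School on Time",
                       "Ever Nonproficient in Math",
                       "Ever Nonproficient in Reading", "Low Birthweight",
                       "Ever Obese", "Ever in Fair/Poor Health",
                       "Ever Smoked Regularly", "Ever Drank Regularly",
                       "Tried Marijuana", "Ever Pregnant", "Ever Arrested",
                       "Ever in a Housing Burdened Household",
                       "Ever in Household Poverty",
                       "Ever in a Household with Parent Unemployed",
                       "Family Ever Moved",
                       "Ever in a Household Where No Parent Had High School Degree",
                       "Ever in Household With Unmarried Head"),
    stringsAsFactors = FALSE
  )
}

#' Default true component effects on the latent scales
#'
#' Effect magnitudes (in latent standard-normal units) chosen to mirror the
#' size ordering of the published per-scale regression coefficients, with a
#' uniform sign pattern: positive status raises flourishing and life
#' satisfaction and lowers distress, worry and social anxiety.
#'
#' @param components Component catalog (see [cati_default_components()]).
#' @return Matrix `n_components x 5` with scale columns `fl, pd, wr, sa, ls`.
#' @export
cati_default_effects <- function(components = cati_default_components()) {
  mag <- c(food_secure = 0.16, attended_preschool = 0.07,
           grad_hs_on_time = 0.24, math_proficient = 0.09,
           reading_proficient = 0.08, non_low_birthweight = 0.08,
           non_obese = 0.06, not_fair_poor_health = 0.08,
           didnt_smoke = 0.20, didnt_drink = 0.03,
           didnt_try_marijuana = 0.11, never_pregnant = 0.02,
           never_arrested = 0.08,
           never_housing_burdened = 0.08, never_household_poverty = 0.12,
           never_parent_unemployed = 0.08, family_never_moved = 0.04,
           parent_hs_degree = 0.10, married_household_head = 0.07)
  sgn <- cati_sign_expectations()
  rel <- c(fl = 1.0, pd = 0.95, wr = 1.05, sa = 0.7, ls = 0.9)
  m <- outer(unname(mag[components$name]), unname(sgn * rel))
  dimnames(m) <- list(components$name, CATI_SCALES)
  m
}

#' Default subjective-scale model
#'
#' Loadings and noise calibrated so the first eigenvalue of the correlation
#' matrix of the wave-averaged scales is near 2.6 (of 5); native centers and
#' spreads match the published scale descriptives.  Life satisfaction is a
#' 1--5 integer item; the others are treated as continuous scores.
#'
#' @return List with `loading`, `idio_sd`, `waves`, `center`, `unit`,
#'   `integerize`, each named over the five scales.
#' @export
cati_default_scale_model <- function() {
  sgn <- cati_sign_expectations()
  list(
    loading = 0.60 * sgn,
    idio_sd = setNames(rep(1.31, 5), CATI_SCALES),
    waves = setNames(rep(3L, 5), CATI_SCALES),
    center = c(fl = 13.65, pd = 5.04, wr = 3.51, sa = 3.36, ls = 2.26),
    unit = c(fl = 2.06, pd = 3.15, wr = 1.35, sa = 1.22, ls = 0.67),
    integerize = c(fl = FALSE, pd = FALSE, wr = FALSE, sa = FALSE, ls = TRUE)
  )
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_children) || length(cfg$n_children) != 1 ||
      cfg$n_children < 1) {
    stop("configuration error: n_children must be a single value >= 1",
         call. = FALSE)
  }
  comps <- cfg$components
  if (!is.data.frame(comps) ||
      !all(c("name", "class", "prevalence") %in% names(comps))) {
    stop("configuration error: components must have name/class/prevalence",
         call. = FALSE)
  }
  if (anyDuplicated(comps$name)) {
    stop("configuration error: duplicated component names", call. = FALSE)
  }
  if (!all(comps$class %in% c("individual", "contextual"))) {
    stop("configuration error: component class must be individual|contextual",
         call. = FALSE)
  }
  if (any(comps$prevalence < 0 | comps$prevalence > 1)) {
    stop("configuration error: prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (!is.matrix(cfg$effects) || nrow(cfg$effects) != nrow(comps) ||
      ncol(cfg$effects) != 5) {
    stop("configuration error: effects must be an n_components x 5 matrix",
         call. = FALSE)
  }
  sm <- cfg$scale_model
  for (fld in c("loading", "idio_sd", "waves", "center", "unit")) {
    if (length(sm[[fld]]) != 5) {
      stop("configuration error: scale_model$", fld, " must have 5 entries",
           call. = FALSE)
    }
  }
  if (any(sm$idio_sd < 0) || any(sm$unit <= 0)) {
    stop("configuration error: scale noise SDs and units must be positive",
         call. = FALSE)
  }
  if (any(sm$waves < 1 | sm$waves > 3)) {
    stop("configuration error: waves per scale must be 1-3", call. = FALSE)
  }
  dm <- cfg$demographics_model
  if (abs(sum(dm$race_probs) - 1) > 1e-8 || any(dm$race_probs < 0) ||
      dm$p_female < 0 || dm$p_female > 1) {
    stop("configuration error: demographic proportions invalid",
         call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("configuration error: missing_rate must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cati_sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n_children:  ", x$n_children, "\n")
  cat("  components:  ", nrow(x$components), "(",
      sum(x$components$class == "individual"), "individual,",
      sum(x$components$class == "contextual"), "contextual )\n")
  cat("  missing_rate:", x$missing_rate, "  seed:", x$seed, "\n")
  invisible(x)
}

# Analytic covariance of the wave-averaged scales in latent units:
# shared factor + component-induced covariance + averaged idiosyncratic noise.
# Native affine maps cancel under standardization and are ignored.
analytic_scale_cov <- function(cfg) {
  l <- cfg$scale_model$loading[CATI_SCALES]
  w <- cfg$scale_model$waves[CATI_SCALES]
  s2 <- cfg$scale_model$idio_sd[CATI_SCALES]^2 / w
  p <- cfg$components$prevalence
  E <- cfg$effects # n_comp x 5
  Sigma <- tcrossprod(l) + t(E) %*% (E * (p * (1 - p))) + diag(s2)
  dimnames(Sigma) <- list(CATI_SCALES, CATI_SCALES)
  Sigma
}

#' Ground-truth index weights implied by a simulation configuration
#'
#' Applies the double-weighting formula analytically: the population first
#' principal component of the wave-averaged scale correlation matrix is
#' combined with the configured true effects expressed per standardized
#' scale (effect divided by the analytic SD of the averaged scale), giving
#' the normalized weight vector the estimation pipeline targets.
#'
#' @param config A [sim_config()] object.
#' @return A `cati_weights` object (see [compute_weights()]).
#' @export
true_weights <- function(config) {
  validate_sim_config(config)
  Sigma <- analytic_scale_cov(config)
  R <- cov2cor(Sigma)
  eig <- eigen(R, symmetric = TRUE)
  load <- eig$vectors[, 1]
  if (load[1] < 0) load <- -load # orient so flourishing loads positively
  loadings <- new_loading_vector(setNames(load, CATI_SCALES), eig$values)
  beta <- t(config$effects) / sqrt(diag(Sigma)) # 5 x n_comp, standardized
  rownames(beta) <- CATI_SCALES
  if (all(abs(beta) < .Machine$double.eps)) {
    stop("all true effects are zero: normalized weights are undefined",
         call. = FALSE)
  }
  compute_weights(loadings, beta)
}
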