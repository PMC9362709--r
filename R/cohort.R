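#' Generate a fully observed synthetic cohort
#'
#' Draws a child-level cohort from the data-generating process described by a
#' [sim_config()]: independent Bernoulli components, a standard-normal latent
#' well-being factor, per-wave scale observations
#' `center + unit * (loading * latent + sum(effects) + noise)`, demographics,
#' log-normal attrition weights (mean 1), and young-adult outcomes driven by
#' the latent factor (logit models for fair/poor health and depression,
#' calibrated to their target prevalences; a log-linear model with Gaussian
#' noise for peak earnings, rounded to whole dollars).
#'
#' No missingness is introduced here; see [apply_missingness()].
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` of class `cati_cohort` with one row per child:
#'   `id`, demographics, `comp_*` columns (0/1), `<scale>_w<k>` wave columns,
#'   `attrition_weight`, adult outcomes and earnings controls.  The component
#'   catalog and scale model travel in attributes `components` and `scales`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_children)
  with_seed(substream_seed(config$seed, "cohort"), {
    dm <- config$demographics_model
    age <- runif(n, dm$age_range[1], dm$age_range[2])
    sex <- factor(ifelse(runif(n) < dm$p_female, "female", "male"),
                  levels = c("male", "female"))
    race <- factor(sample(names(dm$race_probs), n, replace = TRUE,
                          prob = dm$race_probs),
                   levels = names(dm$race_probs))

    comps <- config$components
    C <- matrix(0L, n, nrow(comps),
                dimnames = list(NULL, paste0("comp_", comps$name)))
    for (z in seq_len(nrow(comps))) {
      C[, z] <- rbinom(n, 1L, comps$prevalence[z])
    }

    latent <- rnorm(n)
    sm <- config$scale_model
    shift <- C %*% config$effects # n x 5, component contribution per scale
    scale_cols <- list()
    for (j in CATI_SCALES) {
      lat_j <- sm$loading[j] * latent + shift[, j]
      for (w in seq_len(sm$waves[j])) {
        val <- sm$center[j] +
          sm$unit[j] * (lat_j + rnorm(n, sd = sm$idio_sd[j]))
        if (isTRUE(sm$integerize[j])) val <- pmax(1, pmin(5, round(val)))
        scale_cols[[paste0(j, "_w", w)]] <- val
      }
    }

    am <- config$attrition_model
    wt <- exp(am$coef_age * (age - mean(dm$age_range)) +
                am$coef_female * (sex == "female") +
                rnorm(n, sd = am$sd_log))
    wt <- wt / mean(wt)

    # overall well-being: the shared factor plus the components' average
    # signed contribution to the five scales — adult outcomes must reflect
    # the components, not just the idiosyncratic factor
    sgn <- cati_sign_expectations()
    wellbeing <- latent + drop(shift %*% (sgn / 5))

    om <- config$outcome_model
    health <- draw_calibrated_logit(wellbeing, om$health$slope,
                                    om$health$prevalence)
    depressed <- draw_calibrated_logit(wellbeing, om$depression$slope,
                                       om$depression$prevalence)

    em <- om$earnings
    years_observed <- sample(4:10, n, replace = TRUE)
    enrolled <- rbinom(n, 1L, 0.25)
    position <- factor(sample(c("head", "spouse", "other"), n, replace = TRUE,
                              prob = c(0.55, 0.30, 0.15)),
                       levels = c("head", "spouse", "other"))
    lp <- em$slope * wellbeing + em$coef_years * (years_observed - 7) +
      em$coef_enrolled * enrolled +
      em$coef_spouse * (position == "spouse") +
      em$coef_other * (position == "other")
    mu0 <- log(em$mean) - em$sd_log^2 / 2 - log(mean(exp(lp)))
    earnings <- pmax(0, round(exp(mu0 + lp + rnorm(n, sd = em$sd_log))))

    out <- data.frame(id = seq_len(n), age = age, sex = sex,
                      race_ethnicity = race, C,
                      scale_cols, attrition_weight = wt,
                      ever_fair_poor_health = health,
                      ever_depressed = depressed,
                      peak_earnings = earnings,
                      years_observed_20_29 = years_observed,
                      enrolled_at_peak = enrolled,
                      household_position = position,
                      check.names = FALSE, stringsAsFactors = FALSE)
    attr(out, "components") <- comps
    attr(out, "scales") <- sm
    attr(out, "latent") <- latent
    attr(out, "wellbeing") <- wellbeing
    class(out) <- c("cati_cohort", "data.frame")
    out
  })
}

# Bernoulli draws from a logit model on the latent factor, with the
# intercept calibrated so the sample-average probability hits `prevalence`.
draw_calibrated_logit <- function(latent, slope, prevalence) {
  f <- function(a) mean(plogis(a + slope * latent)) - prevalence
  a <- uniroot(f, c(-20, 20))$root
  rbinom(length(latent), 1L, plogis(a + slope * latent))
}

#' Introduce missing-at-random cells into a cohort
#'
#' Row-level missingness propensity is a logistic function of age, sex and
#' the attrition weight only (all always observed), with the intercept
#' calibrated so the expected fraction of rows with at least one missing
#' cell equals `config$missing_rate`.  Within a flagged row, each component,
#' scale-wave and adult-outcome cell is blanked independently (at least one
#' cell per flagged row).  Demographics, attrition weights and earnings
#' controls are never missing.
#'
#' @param cohort A fully observed `cati_cohort`.
#' @param config The [sim_config()] that produced it (or any config with the
#'   desired `missing_rate` and `seed`).
#' @param cell_rate Probability that an eligible cell in a flagged row is
#'   blanked.
#' @return The cohort with `NA` cells.
#' @export
apply_missingness <- function(cohort, config, cell_rate = 0.12) {
  rate <- config$missing_rate
  if (rate < 0 || rate >= 1) {
    stop("configuration error: missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(cohort)
  eligible <- c(component_columns(cohort),
                unlist(lapply(CATI_SCALES, scale_wave_columns, data = cohort)),
                intersect(c("ever_fair_poor_health", "ever_depressed",
                            "peak_earnings"), names(cohort)))
  with_seed(substream_seed(config$seed, "missingness"), {
    z <- 0.6 * scale(cohort$age)[, 1] +
      0.4 * (cohort$sex == "female") +
      0.8 * log(cohort$attrition_weight)
    a <- uniroot(function(a) mean(plogis(a + z)) - rate, c(-30, 30))$root
    flagged <- which(runif(nrow(cohort)) < plogis(a + z))
    for (i in flagged) {
      hit <- eligible[runif(length(eligible)) < cell_rate]
      if (length(hit) == 0) hit <- sample(eligible, 1)
      cohort[i, hit] <- NA
    }
    cohort
  })
}

#' Write / read a cohort as CSV plus JSON sidecar
#'
#' The CSV holds the data; the sidecar records the component catalog, the
#' scale model and (if supplied) the generating configuration, so a cohort
#' round-trips losslessly.
#'
#' @param cohort A `cati_cohort`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param config Optional [sim_config()] to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  side <- list(
    components = attr(cohort, "components"),
    scales = lapply(attr(cohort, "scales"), function(x) as.list(x)),
    factor_levels = list(
      sex = levels(cohort$sex),
      race_ethnicity = levels(cohort$race_ethnicity),
      household_position = if ("household_position" %in% names(cohort))
        levels(cohort$household_position) else NULL
    )
  )
  if (!is.null(config)) {
    side$config <- unclass(config)
    side$config$effects <- as.data.frame(config$effects)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fl <- side$factor_levels
  df$sex <- factor(df$sex, levels = fl$sex)
  df$race_ethnicity <- factor(df$race_ethnicity, levels = fl$race_ethnicity)
  if (!is.null(fl$household_position) &&
      "household_position" %in% names(df)) {
    df$household_position <- factor(df$household_position,
                                    levels = fl$household_position)
  }
  attr(df, "components") <- as.data.frame(side$components)
  sm <- side$scales
  attr(df, "scales") <- lapply(sm, function(x) {
    v <- unlist(x)
    names(v) <- CATI_SCALES
    v
  })
  class(df) <- c("cati_cohort", "data.frame")
  df
}
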