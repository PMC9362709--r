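# Shared fixtures, all generated in code.

# Small generic cohort configuration for unit tests.
tiny_config <- function(n = 400, seed = 1, missing_rate = 0,
                        n_comp = 4, effects_scale = 1) {
  comps <- data.frame(
    name = paste0("c", seq_len(n_comp)),
    class = "individual",
    prevalence = seq(0.3, 0.7, length.out = n_comp),
    label_negative = "",
    stringsAsFactors = FALSE
  )
  eff <- effects_scale *
    outer(seq(0.3, 0.1, length.out = n_comp),
          unname(cati_sign_expectations()))
  dimnames(eff) <- list(comps$name, c("fl", "pd", "wr", "sa", "ls"))
  sm <- cati_default_scale_model()
  sm$center[] <- 0
  sm$unit[] <- 1
  sm$integerize[] <- FALSE
  sim_config(n_children = n, components = comps, effects = eff,
             scale_model = sm, missing_rate = missing_rate, seed = seed)
}

# Configuration for the large-n parameter-recovery exercise: 11 components
# whose effect magnitudes are proportional to a known weight vector plus 5
# null components, complete data, unit-scale continuous scales.
recovery_config <- function(seed, n = 20000) {
  mag <- c(0.285, 0.199, 0.192, 0.069, 0.054, 0.052, 0.052,
           0.027, 0.027, 0.025, 0.020) * 1.05
  comps <- data.frame(
    name = c(paste0("true_", sprintf("%02d", 1:11)), paste0("null_", 1:5)),
    class = "individual",
    prevalence = c(0.85, 0.6, 0.7, 0.45, 0.3, 0.75, 0.65, 0.9, 0.5, 0.35,
                   0.8, 0.4, 0.55, 0.25, 0.7, 0.6),
    label_negative = "",
    stringsAsFactors = FALSE
  )
  eff <- outer(c(mag, rep(0, 5)), unname(cati_sign_expectations()))
  dimnames(eff) <- list(comps$name, c("fl", "pd", "wr", "sa", "ls"))
  sm <- cati_default_scale_model()
  sm$center[] <- 0
  sm$unit[] <- 1
  sm$integerize[] <- FALSE
  sim_config(n_children = n, components = comps, effects = eff,
             scale_model = sm, missing_rate = 0, seed = seed)
}

# Run the LASSO screen + majority retention rule on a single complete
# dataset (per-split seeds derived from `seed`).
screen_with_retention <- function(y, X, comps, seed, m = 20) {
  kept_sets <- lapply(seq_len(m), function(l) {
    suppressWarnings(fit_adaptive_lasso(
      X, y, penalized = comps,
      seed = cati:::substream_seed(seed, "lasso", l)
    ))
  })
  mask <- aggregate_selection(kept_sets, comps, m = m)
  mask$component[mask$status == "kept"]
}

# Wrap a complete cohort as an m-copy imputation set.
complete_imps <- function(cohort, m = 2) {
  impute_chained(cohort, m = m, seed = 1)
}
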