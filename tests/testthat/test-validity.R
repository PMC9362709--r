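# Small complete cohort with a latent-driven outcome for validity tests.
validity_cohort <- function(n = 2000, seed = 1, effects_scale = 1.5) {
  cfg <- tiny_config(n = n, seed = seed, effects_scale = effects_scale)
  generate_cohort(cfg)
}

unit_weights <- function(names) {
  structure(data.frame(component = names, raw = 1 / length(names),
                       weight = 1 / length(names)),
            class = c("cati_weights", "data.frame"))
}

test_that("logistic AME matches a brute-force finite-difference oracle", {
  coh <- validity_cohort(n = 1500, seed = 51)
  imps <- complete_imps(coh, m = 2)
  w <- unit_weights(paste0("c", 1:4))
  sc <- score_index(coh, w)
  res <- binary_validity(imps, sc, "ever_fair_poor_health")

  # oracle: refit independently, loop over respondents
  X <- cbind(1, score = sc$cati_std, cati:::design_demographics(coh))
  fit <- suppressWarnings(glm.fit(X, coh$ever_fair_poor_health,
                                  weights = coh$attrition_weight,
                                  family = binomial()))
  b <- fit$coefficients
  diffs <- numeric(nrow(coh))
  for (i in seq_len(nrow(coh))) {
    eta <- sum(X[i, ] * b)
    diffs[i] <- plogis(eta + b[2]) - plogis(eta)
  }
  oracle <- sum(coh$attrition_weight * diffs) / sum(coh$attrition_weight)
  expect_equal(res$estimate, oracle, tolerance = 1e-10)
  expect_true(res$ci95[1] <= res$estimate && res$estimate <= res$ci95[2])
  expect_equal(res$partial_r2, res$r2_full - res$r2_base, tolerance = 1e-9)
})

test_that("AME is invariant to affine recoding of demographic covariates", {
  coh <- validity_cohort(n = 1200, seed = 52)
  w <- unit_weights(paste0("c", 1:4))
  sc <- score_index(coh, w)
  res1 <- binary_validity(complete_imps(coh, 2), sc, "ever_depressed")
  coh2 <- coh
  coh2$age <- 10 * (coh2$age - 23)
  res2 <- binary_validity(complete_imps(coh2, 2), sc, "ever_depressed")
  expect_equal(res1$estimate, res2$estimate, tolerance = 1e-6)
})

test_that("a permuted (null) score has no detectable marginal effect", {
  coh <- validity_cohort(n = 5000, seed = 53)
  w <- unit_weights(paste0("c", 1:4))
  sc <- score_index(coh, w)
  set.seed(99)
  sc$cati_std <- sample(sc$cati_std)
  imps <- complete_imps(coh, 2)
  res <- binary_validity(imps, sc, "ever_fair_poor_health")
  expect_lt(abs(res$estimate), 2 * res$se)
  expect_lt(res$partial_r2, 0.005)

  earn <- earnings_validity(imps, sc)
  expect_lt(abs(earn$estimate), 2 * earn$se)
})

test_that("a protective index yields a negative effect with CI excluding 0", {
  cfg <- tiny_config(n = 6000, seed = 54, effects_scale = 2)
  coh <- generate_cohort(cfg)
  w <- true_weights(cfg)
  sc <- score_index(coh, w)
  res <- binary_validity(complete_imps(coh, 2), sc, "ever_fair_poor_health")
  expect_lt(res$estimate, 0)
  expect_lt(res$ci95[2], 0)
})

test_that("earnings effect recovers a planted percent change", {
  # plant a log-linear score effect directly: beta = log(1.10) per SD
  set.seed(61)
  n <- 10000
  coh <- validity_cohort(n = n, seed = 55, effects_scale = 0)
  sc <- score_index(coh, unit_weights(paste0("c", 1:4)))
  mu <- exp(log(25000) + log(1.10) * sc$cati_std)
  coh$peak_earnings <- rpois(n, mu)
  res <- earnings_validity(complete_imps(coh, 2), sc)
  expect_equal(res$estimate, 10, tolerance = 0.15) # percent, sim error
  expect_equal(res$estimate, 100 * (exp(res$beta_score) - 1),
               tolerance = 1e-12)

  # robust SEs exceed classical Poisson SEs under overdispersion
  coh2 <- coh
  set.seed(62)
  coh2$peak_earnings <- rpois(n, mu * exp(rnorm(n, sd = 0.8) - 0.32))
  res2 <- earnings_validity(complete_imps(coh2, 2), sc, keep_fits = TRUE)
  f <- res2$fits[[1]]
  expect_gt(sqrt(f$var), f$se_classical)
})

test_that("comparing an index with itself gives difference 0 and p = 1", {
  coh <- validity_cohort(n = 800, seed = 56)
  sc <- score_index(coh, unit_weights(paste0("c", 1:4)))
  imps <- complete_imps(coh, 2)
  a <- binary_validity(imps, sc, "ever_depressed", variant = "a")
  cmp <- compare_indices(a, a)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("stacked and bootstrap comparisons agree within Monte Carlo error", {
  coh <- validity_cohort(n = 1200, seed = 57)
  sc1 <- score_index(coh, unit_weights(paste0("c", 1:4)))
  sc2 <- equal_weight_index(coh, paste0("c", 1:3))
  imps <- complete_imps(coh, 2)
  a <- binary_validity(imps, sc1, "ever_depressed", variant = "full")
  b <- binary_validity(imps, sc2, "ever_depressed", variant = "subset")
  st <- compare_indices(a, b)
  bo <- compare_indices(a, b, method = "bootstrap", reps = 199, seed = 3)
  expect_equal(st$difference, bo$difference, tolerance = 1e-12)
  # bootstrap SE within 35% of the analytic one at 199 resamples
  expect_lt(abs(st$se - bo$se) / st$se, 0.35)
})

test_that("comparison refuses non-identical samples", {
  coh <- validity_cohort(n = 600, seed = 58)
  sc <- score_index(coh, unit_weights(paste0("c", 1:4)))
  imps <- complete_imps(coh, 2)
  a <- binary_validity(imps, sc, "ever_depressed")
  b <- binary_validity(imps, sc, "ever_fair_poor_health")
  expect_error(compare_indices(a, b), "identical samples")
})
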