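test_that("generation is reproducible and calibrated to the configuration", {
  cfg <- sim_config(n_children = 2000, seed = 42)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1, coh2)

  # prevalence calibration: each simulated positive rate within 3 SEs
  comps <- attr(coh1, "components")
  for (z in seq_len(nrow(comps))) {
    p <- comps$prevalence[z]
    se <- sqrt(p * (1 - p) / nrow(coh1))
    expect_lt(abs(mean(coh1[[paste0("comp_", comps$name[z])]]) - p), 3 * se)
  }
  expect_true(all(coh1$attrition_weight > 0))
  expect_true(all(coh1$peak_earnings >= 0))
})

test_that("null effects give no component-scale association", {
  cfg <- tiny_config(n = 3000, seed = 3, effects_scale = 0)
  coh <- generate_cohort(cfg)
  S <- preprocess_scales(coh)
  # 20 simultaneous checks, so allow a little beyond 3 standard errors
  for (z in paste0("comp_", cfg$components$name)) {
    for (j in colnames(S)) {
      expect_lt(abs(cor(coh[[z]], S[, j])), 3.5 / sqrt(nrow(coh)))
    }
  }
})

test_that("no shared factor gives near-identity scale correlation", {
  cfg <- tiny_config(n = 4000, seed = 4, effects_scale = 0)
  cfg$scale_model$loading[] <- 0
  coh <- generate_cohort(cfg)
  # eigenvalues hover around 1, so the Kaiser warning may legitimately fire
  ev <- suppressWarnings(
    pca_first_component(preprocess_scales(coh))$eigenvalues
  )
  expect_lt(max(abs(ev - 1)), 0.15)
})

test_that("first eigenvalue matches its analytic value from the config", {
  cfg <- sim_config(n_children = 5000, seed = 9)
  coh <- generate_cohort(cfg)
  emp <- pca_first_component(preprocess_scales(coh))$eigenvalues[1]
  Sigma <- cati:::analytic_scale_cov(cfg)
  analytic <- eigen(cov2cor(Sigma), symmetric = TRUE)$values[1]
  # default calibration targets roughly half the variance on the first PC
  expect_gt(analytic, 2.3)
  expect_lt(analytic, 2.9)
  # life-satisfaction integer rounding makes the match approximate
  expect_lt(abs(emp - analytic), 0.15)
})

test_that("missingness hits the target row rate under a MAR mechanism", {
  cfg <- sim_config(n_children = 5000, seed = 21, missing_rate = 0.40)
  coh <- generate_cohort(cfg)

  cfg0 <- cfg
  cfg0$missing_rate <- 0
  expect_identical(apply_missingness(coh, cfg0), coh)

  mis <- apply_missingness(coh, cfg)
  frac <- mean(!stats::complete.cases(mis))
  expect_gte(frac, 0.38)
  expect_lte(frac, 0.42)
  # demographics and weights never missing
  expect_false(anyNA(mis$age) || anyNA(mis$sex) ||
                 anyNA(mis$attrition_weight))

  # MAR, not MCAR: complete-case scale means shift because the missingness
  # driver (age/sex/attrition weight) correlates with the outcomes
  cc <- stats::complete.cases(mis)
  ages <- abs(mean(mis$age[cc]) - mean(coh$age))
  expect_gt(ages, 0) # drivers differ between complete cases and full data
  expect_gt(abs(mean(coh$attrition_weight[cc]) -
                  mean(coh$attrition_weight)), 1e-4)

  cfg_bad <- cfg
  cfg_bad$missing_rate <- 1
  expect_error(apply_missingness(coh, cfg_bad), "missing_rate")
})

test_that("true_weights obeys the double-weighting algebra", {
  # single informative component carries the whole weight
  cfg <- tiny_config(n = 100, seed = 1)
  cfg$effects[2:4, ] <- 0
  tw <- true_weights(cfg)
  expect_equal(tw$weight, c(1, 0, 0, 0))

  # proportional effect vectors (2:1) give weights 2/3 and 1/3
  cfg2 <- tiny_config(n = 100, seed = 1, n_comp = 2)
  cfg2$components$prevalence <- c(0.5, 0.5)
  base <- c(0.2, -0.2, -0.2, -0.2, 0.2)
  cfg2$effects <- rbind(c1 = 2 * base, c2 = base)
  colnames(cfg2$effects) <- c("fl", "pd", "wr", "sa", "ls")
  tw2 <- true_weights(cfg2)
  expect_equal(tw2$weight, c(2 / 3, 1 / 3), tolerance = 1e-12)

  # matches a hand-rolled double loop over the 5 x K products
  cfg3 <- tiny_config(n = 100, seed = 5)
  tw3 <- true_weights(cfg3)
  Sigma <- cati:::analytic_scale_cov(cfg3)
  lam <- eigen(cov2cor(Sigma), symmetric = TRUE)$vectors[, 1]
  if (lam[1] < 0) lam <- -lam
  W <- numeric(nrow(cfg3$effects))
  for (z in seq_along(W)) {
    acc <- 0
    for (j in 1:5) {
      acc <- acc + abs(lam[j] * cfg3$effects[z, j] / sqrt(Sigma[j, j]))
    }
    W[z] <- acc / 5
  }
  expect_equal(tw3$weight, W / sum(W), tolerance = 1e-12)

  cfg0 <- tiny_config(n = 100, seed = 1, effects_scale = 0)
  expect_error(true_weights(cfg0), "undefined")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_children = 0), "n_children")
  cfg <- tiny_config()
  cfg$components$prevalence[1] <- 1.2
  expect_error(validate_sim_config <- cati:::validate_sim_config(cfg),
               "prevalences")
  cfg2 <- tiny_config()
  cfg2$missing_rate <- 1
  expect_error(cati:::validate_sim_config(cfg2), "missing_rate")
})

test_that("a cohort round-trips through CSV plus JSON sidecar", {
  cfg <- tiny_config(n = 150, seed = 8, missing_rate = 0.3)
  coh <- apply_missingness(generate_cohort(cfg), cfg)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(coh, path, config = cfg)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back)[names(coh)], as.data.frame(coh),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(levels(back$sex), levels(coh$sex))
  expect_equal(attr(back, "components")$name, cfg$components$name)
})
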