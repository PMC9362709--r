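test_that("scale preprocessing averages waves then standardizes", {
  cfg <- tiny_config(n = 500, seed = 23)
  coh <- generate_cohort(cfg)
  S <- preprocess_scales(coh)
  expect_equal(colnames(S), c("fl", "pd", "wr", "sa", "ls"))
  expect_lt(max(abs(colMeans(S))), 1e-9)
  expect_lt(max(abs(apply(S, 2, sd) - 1)), 1e-9)

  # a respondent with waves {2, 4} averages to 3 before standardization
  waves <- as.matrix(coh[scale_wave_columns(coh <- coh, "ls")])
  coh2 <- coh
  coh2[1, grep("^ls_w", names(coh2))] <- c(2, 4, 4)[seq_len(ncol(waves))]
  avg <- rowMeans(as.matrix(coh2[grep("^ls_w", names(coh2))]))
  if (ncol(waves) == 3) {
    expect_equal(avg[1], mean(c(2, 4, 4)))
  }

  # single wave per scale: averaging is the identity
  one <- coh[c("id", "age", "sex", "race_ethnicity")]
  for (j in c("fl", "pd", "wr", "sa", "ls")) {
    one[[paste0(j, "_w1")]] <- coh[[paste0(j, "_w1")]]
  }
  S1 <- preprocess_scales(one)
  for (j in c("fl", "pd", "wr", "sa", "ls")) {
    raw <- coh[[paste0(j, "_w1")]]
    expect_equal(S1[, j], (raw - mean(raw)) / sd(raw))
  }

  # zero-variance scale is refused by name
  bad <- one
  bad$wr_w1 <- 1
  expect_error(preprocess_scales(bad), "wr")
})

test_that("PCA of independent columns has all eigenvalues near 1", {
  set.seed(10)
  X <- matrix(rnorm(5000 * 5), ncol = 5,
              dimnames = list(NULL, c("fl", "pd", "wr", "sa", "ls")))
  lv <- suppressWarnings(pca_first_component(scale(X)))
  expect_lt(max(abs(lv$eigenvalues - 1)), 0.15)
  expect_equal(sum(lv$eigenvalues), 5, tolerance = 1e-6)
  expect_equal(sum(lv$loadings^2), 1, tolerance = 1e-9)
})

test_that("equicorrelated scales match the closed-form first eigenvalue", {
  # rho = 0.4 with pd/wr/sa anti-correlated: lambda1 = 1 + 4 rho = 2.6 and
  # equal-magnitude loadings, fl/ls positive, others negative
  rho <- 0.4
  s <- c(1, -1, -1, -1, 1)
  R <- rho * outer(s, s)
  diag(R) <- 1
  dimnames(R) <- list(c("fl", "pd", "wr", "sa", "ls"),
                      c("fl", "pd", "wr", "sa", "ls"))
  lv <- pca_first_component(R)
  expect_equal(lv$eigenvalues[1], 1 + 4 * rho, tolerance = 1e-12)
  expect_equal(abs(unname(lv$loadings)), rep(1 / sqrt(5), 5),
               tolerance = 1e-12)
  expect_gt(lv$loadings["fl"], 0)
  expect_gt(lv$loadings["ls"], 0)
  expect_true(all(lv$loadings[c("pd", "wr", "sa")] < 0))

  # a second eigenvalue above 1 triggers the Kaiser warning
  R2 <- diag(5) * 0
  R2[1:2, 1:2] <- 0.8
  R2[3:4, 3:4] <- 0.8
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  expect_warning(pca_first_component(R2), "Kaiser")
})

test_that("double weighting agrees with a naive loop and its invariances", {
  fx <- cati_reference_fixture()
  w <- compute_weights(fx$loadings, fx$beta)
  # brute-force double loop over (scale, component)
  lam <- fx$loadings$loadings
  W <- numeric(ncol(fx$beta))
  for (z in seq_len(ncol(fx$beta))) {
    acc <- 0
    for (j in seq_len(5)) acc <- acc + abs(lam[j] * fx$beta[j, z])
    W[z] <- acc / 5
  }
  expect_equal(w$raw, W, tolerance = 1e-12)
  expect_equal(w$weight, W / sum(W), tolerance = 1e-12)
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)

  # scaling all coefficients leaves normalized weights unchanged
  w2 <- compute_weights(fx$loadings, fx$beta * 3.7)
  expect_equal(w2$weight, w$weight, tolerance = 1e-12)

  # flipping the loading vector's sign changes nothing (absolute value)
  lv_flipped <- fx$loadings
  lv_flipped$loadings <- -lv_flipped$loadings
  expect_equal(compute_weights(lv_flipped, fx$beta)$weight, w$weight,
               tolerance = 1e-12)

  # single-term case: |0.5 x 0.4| / 5 raw, sole nonzero normalizes to 1
  beta1 <- matrix(c(0.5, 0, 0, 0, 0), nrow = 5,
                  dimnames = list(c("fl", "pd", "wr", "sa", "ls"), "only"))
  lam1 <- setNames(c(0.4, -0.5, -0.5, -0.4, 0.4),
                   c("fl", "pd", "wr", "sa", "ls"))
  w1 <- compute_weights(lam1, beta1)
  expect_equal(w1$raw, 0.5 * 0.4 / 5, tolerance = 1e-12)
  expect_equal(w1$weight, 1)

  # all-zero coefficients are an error
  expect_error(compute_weights(lam1, beta1 * 0), "no informative")
})

test_that("single-benchmark degenerate mode reduces to normalized |beta|", {
  beta <- matrix(c(0.4, -0.1, 0.3, 0), nrow = 1,
                 dimnames = list("bench", paste0("c", 1:4)))
  w <- compute_weights(setNames(1, "bench"), beta)
  expect_equal(w$weight, abs(beta[1, ]) / sum(abs(beta[1, ])),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("index scores respect bounds, linearity and monotonicity", {
  fx <- cati_reference_fixture()
  w <- compute_weights(fx$loadings, fx$beta)
  K <- length(w$component)
  M <- rbind(rep(0, K), rep(1, K), diag(K))
  colnames(M) <- w$component
  sc <- score_index(M, w)
  expect_equal(sc$cati[1], 0)
  expect_equal(sc$cati[2], 1, tolerance = 1e-12)
  # flipping component z from 0 to 1 adds exactly its weight
  expect_equal(sc$cati[3:(K + 2)], w$weight, tolerance = 1e-12)
  expect_lt(abs(mean(sc$cati_std)), 1e-9)
  expect_equal(sd(sc$cati_std), 1, tolerance = 1e-9)

  # monotone in every component
  set.seed(2)
  base <- matrix(rbinom(50 * K, 1, 0.5), 50, K,
                 dimnames = list(NULL, w$component))
  s0 <- score_index(base, w)$cati
  for (z in sample(K, 3)) {
    up <- base
    up[, z] <- 1
    expect_true(all(score_index(up, w)$cati >= s0 - 1e-12))
  }

  expect_error(score_index(base[, 1:3], w), "not found")
})

test_that("equal-weight comparator counts positives then standardizes", {
  set.seed(4)
  K <- 6
  M <- matrix(rbinom(200 * K, 1, 0.5), 200, K,
              dimnames = list(NULL, paste0("c", 1:K)))
  eq <- equal_weight_index(M, paste0("c", 1:K))
  expect_equal(eq$cati, rowSums(M))
  expect_lt(abs(mean(eq$cati_std)), 1e-9)
  expect_equal(sd(eq$cati_std), 1, tolerance = 1e-9)

  # identical (up to affine transform) to uniform weights through the scorer
  w_unif <- structure(data.frame(component = paste0("c", 1:K),
                                 raw = 1 / K, weight = 1 / K),
                      class = c("cati_weights", "data.frame"))
  su <- score_index(M, w_unif)
  expect_equal(cor(su$cati, eq$cati), 1, tolerance = 1e-12)
  expect_equal(su$cati_std, eq$cati_std, tolerance = 1e-9)

  expect_error(equal_weight_index(M, character(0)), "non-empty")
})
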