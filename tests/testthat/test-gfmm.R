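# Mixture model: densities, E/M steps against brute-force oracles, EM
# monotonicity, recovery, prediction contracts, serialization.

make_params <- function(schema, K, mean = NULL, sd = NULL, p = NULL, cat = NULL,
                        prior_coef = NULL) {
  pa <- mixphen:::empty_params(K, schema)
  if (!is.null(mean)) pa$mean <- mean
  if (!is.null(sd)) pa$sd <- sd
  if (!is.null(p)) pa$p <- p
  if (!is.null(cat)) pa$cat <- cat
  if (!is.null(prior_coef)) pa$prior_coef <- prior_coef
  pa
}

test_that("component log densities match closed forms", {
  sch_c <- feature_schema("x", "continuous")
  pa <- make_params(sch_c, 1, mean = matrix(0), sd = matrix(1))
  expect_equal(component_log_density(pa, 1, 0), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  sch_b <- feature_schema("x", "binary")
  pb <- make_params(sch_b, 1, p = matrix(0.5))
  expect_equal(component_log_density(pb, 1, 1), log(0.5), tolerance = 1e-9)
  sch_k <- feature_schema("x", "categorical", n_levels = 4)
  pk <- make_params(sch_k, 1, cat = list(matrix(0.25, 1, 4)))
  expect_equal(component_log_density(pk, 1, 3), log(0.25), tolerance = 1e-9)
  expect_error(component_log_density(pk, 1, 5), "domain error")
})

test_that("e_step matches a direct Bayes-rule oracle to 1e-12", {
  sch <- feature_schema(c("x", "b"), c("continuous", "binary"))
  pa <- make_params(sch, 2,
                    mean = matrix(c(0, 2), 2, 1), sd = matrix(c(1, 1.5), 2, 1),
                    p = matrix(c(0.2, 0.7), 2, 1),
                    prior_coef = matrix(c(0, 0, 0, 0.4, 0.1, -0.05), 3, 2))
  X <- matrix(c(0.3, 1, -1.2, 0, 2.5, 1), 3, 2, byrow = TRUE)
  Z <- cbind(1, c(0, 1, 1), c(8, 10, 14))
  es <- e_step(pa, X, Z)
  # oracle: direct per-row arithmetic with plain (non-log) densities
  for (i in 1:3) {
    eta <- Z[i, ] %*% pa$prior_coef
    pri <- exp(eta) / sum(exp(eta))
    f <- sapply(1:2, function(k) {
      dnorm(X[i, 1], pa$mean[k, 1], pa$sd[k, 1]) *
        (pa$p[k, 1]^X[i, 2] * (1 - pa$p[k, 1])^(1 - X[i, 2]))
    })
    post <- pri * f / sum(pri * f)
    expect_equal(es$gamma[i, ], as.numeric(post), tolerance = 1e-12)
    expect_equal(sum(es$gamma[i, ]), 1, tolerance = 1e-10)
  }
  ll_oracle <- sum(sapply(1:3, function(i) {
    eta <- Z[i, ] %*% pa$prior_coef
    pri <- exp(eta) / sum(exp(eta))
    log(sum(pri * sapply(1:2, function(k) {
      dnorm(X[i, 1], pa$mean[k, 1], pa$sd[k, 1]) *
        pa$p[k, 1]^X[i, 2] * (1 - pa$p[k, 1])^(1 - X[i, 2])
    })))
  }))
  expect_equal(es$ll, ll_oracle, tolerance = 1e-12)
})

test_that("e_step symmetry and degenerate-prior limits", {
  sch <- feature_schema("x", "continuous")
  pa <- make_params(sch, 2, mean = matrix(0, 2, 1), sd = matrix(1, 2, 1))
  X <- matrix(rnorm(5), 5, 1)
  Z <- cbind(1, 0, 10)[rep(1, 5), ]
  es <- e_step(pa, X, Z)
  expect_equal(as.vector(es$gamma), rep(0.5, 10), tolerance = 1e-12)
  # near-degenerate prior via a huge intercept on class 1's logit
  pa2 <- make_params(sch, 2, mean = matrix(c(0, 0), 2, 1), sd = matrix(1, 2, 1),
                     prior_coef = matrix(c(0, 0, 0, -1000, 0, 0), 3, 2))
  es2 <- e_step(pa2, X, Z)
  expect_equal(as.vector(es2$gamma[, 1]), rep(1, 5), tolerance = 1e-12)
  # log-sum-exp contract: extremely small densities do not underflow
  pa3 <- make_params(sch, 2, mean = matrix(c(0, 60), 2, 1), sd = matrix(1, 2, 1))
  es3 <- e_step(pa3, matrix(c(0, 60), 2, 1), Z[1:2, ])
  expect_true(all(is.finite(es3$gamma)))
  expect_true(is.finite(es3$ll))
})

test_that("m_step reduces to subgroup statistics under hard assignment", {
  sch <- tiny_schema(n_cont = 1, n_bin = 1, n_cat = 1)
  spec <- tiny_spec(n = 300, K = 2, schema = sch, seed = 11)
  co <- generate_cohort(spec)
  X <- mixphen:::cohort_feature_matrix(co)
  Z <- mixphen:::cohort_covariates(co)
  g <- co$data$true_class
  gamma <- cbind(g == 1, g == 2) * 1
  pa <- m_step(X, Z, sch, gamma)
  for (k in 1:2) {
    xk <- X[g == k, 1]
    expect_equal(pa$mean[k, 1], mean(xk), tolerance = 1e-10)
    expect_equal(pa$sd[k, 1]^2, mean((xk - mean(xk))^2), tolerance = 1e-8)
    expect_equal(pa$p[k, 1], mean(X[g == k, 2]), tolerance = 1e-10)
    expect_equal(pa$cat[[1]][k, ],
                 as.numeric(table(factor(X[g == k, 3], levels = 1:4))) / sum(g == k),
                 tolerance = 1e-10)
  }
  # uniform responsibilities: every class receives the global parameters
  gu <- matrix(0.5, nrow(X), 2)
  pu <- m_step(X, Z, sch, gu)
  expect_equal(pu$mean[1, 1], mean(X[, 1]), tolerance = 1e-10)
  expect_equal(pu$mean[2, 1], mean(X[, 1]), tolerance = 1e-10)
  expect_equal(pu$p[1, 1], mean(X[, 2]), tolerance = 1e-10)
})

test_that("weighted means match hand arithmetic; degenerate class errors", {
  sch <- feature_schema("x", "continuous")
  X <- matrix(c(1, 2, 4), 3, 1)
  Z <- cbind(1, 0, c(8, 9, 10))
  gamma <- cbind(c(0.2, 0.3, 0.5), c(0.8, 0.7, 0.5))
  pa <- m_step(X, Z, sch, gamma)
  expect_equal(pa$mean[1, 1], (0.2 * 1 + 0.3 * 2 + 0.5 * 4) / 1.0, tolerance = 1e-12)
  g0 <- cbind(c(1, 1, 1), c(1e-9, 1e-9, 1e-9))
  expect_error(m_step(X, Z, sch, g0), "degenerate-class")
})

test_that("m_step prior coefficients agree with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  set.seed(4)
  n <- 400
  Z <- cbind(1, rbinom(n, 1, 0.5), rnorm(n, 10, 3))
  B_true <- matrix(c(0, 0, 0, 1, -0.5, -0.08), 3, 2)
  pr <- exp(Z %*% B_true); pr <- pr / rowSums(pr)
  gamma <- pr  # soft targets
  B <- mixphen:::fit_prior_coef(Z, gamma)
  fit_nn <- nnet::multinom(gamma ~ Z[, 2] + Z[, 3], trace = FALSE,
                           reltol = 1e-14)
  B_nn <- rbind(coef(fit_nn))
  expect_equal(as.numeric(B[, 2]), as.numeric(B_nn), tolerance = 1e-4)
})

test_that("K=1 fit equals the analytic single-component log-likelihood", {
  sch <- tiny_schema(n_cont = 1, n_bin = 1, n_cat = 1)
  spec <- tiny_spec(n = 200, K = 1, schema = sch, seed = 13,
                    class_effects = matrix(0, 1, 3))
  co <- generate_cohort(spec)
  fit <- gfmm_fit(co, K = 1, n_init = 1, seed = 1)
  X <- mixphen:::cohort_feature_matrix(co)
  mu <- mean(X[, 1]); v <- mean((X[, 1] - mu)^2)
  p <- mean(X[, 2])
  lvl <- as.numeric(table(factor(X[, 3], levels = 1:4))) / nrow(X)
  ll <- sum(dnorm(X[, 1], mu, sqrt(v), log = TRUE)) +
    sum(X[, 2] * log(p) + (1 - X[, 2]) * log(1 - p)) +
    sum(log(lvl[X[, 3]]))
  expect_equal(fit$ll, ll, tolerance = 1e-9)
})

test_that("well-separated two-class cohorts are recovered almost perfectly", {
  spec <- tiny_spec(n = 2000, K = 2, separation = 4, seed = 15)
  co <- generate_cohort(spec)
  fit <- gfmm_fit(co, K = 2, n_init = 4, seed = 2)
  expect_gte(adjusted_rand_index(fit$labels, co$data$true_class), 0.99)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("log-likelihood is invariant to feature order and ARI matches mclust", {
  skip_if_not_installed("mclust")
  sch <- tiny_schema()
  spec <- tiny_spec(n = 300, K = 2, schema = sch, seed = 17)
  co <- generate_cohort(spec)
  fit <- gfmm_fit(co, K = 2, n_init = 3, seed = 5)
  perm <- rev(sch$name)
  sch_perm <- sch[match(perm, sch$name), ]
  class(sch_perm) <- class(sch)
  co_perm <- phenotype_cohort(co$data, sch_perm)
  fit_perm <- gfmm_fit(co_perm, K = 2, n_init = 3, seed = 5)
  expect_equal(fit$ll, fit_perm$ll, tolerance = 1e-9)
  a <- sample(1:3, 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("predict is idempotent on the training cohort and breaks ties low", {
  spec <- tiny_spec(n = 300, K = 2, seed = 19)
  co <- generate_cohort(spec)
  fit <- gfmm_fit(co, K = 2, n_init = 2, seed = 3)
  pred <- predict(fit, co)
  expect_identical(pred$labels, fit$labels)
  # exact posterior tie: identical class parameters, equal priors
  sch <- feature_schema("x", "continuous")
  pa <- make_params(sch, 2, mean = matrix(0, 2, 1), sd = matrix(1, 2, 1))
  fake <- structure(list(params = pa, schema = sch, K = 2), class = "gfmm_fit")
  tie_co <- manual_cohort(data.frame(x = c(0, 1)), sch)
  expect_identical(predict(fake, tie_co)$labels, c(1L, 1L))
  # schema mismatch contract
  sch2 <- feature_schema("y", "continuous")
  co2 <- manual_cohort(data.frame(y = 0), sch2)
  expect_error(predict(fit, co2), "schema error")
})

test_that("individuals at a class centroid are assigned with near certainty", {
  spec <- tiny_spec(n = 1000, K = 2, separation = 5, seed = 23)
  co <- generate_cohort(spec)
  fit <- gfmm_fit(co, K = 2, n_init = 3, seed = 4)
  # build a row at class 1's parameter centroid: means for continuous,
  # modal values for binary/categorical
  centroid_row <- co$data[1, ]
  pa <- fit$params
  for (jj in seq_along(pa$j_cont)) {
    centroid_row[[co$schema$name[pa$j_cont[jj]]]] <- pa$mean[1, jj]
  }
  for (jj in seq_along(pa$j_bin)) {
    centroid_row[[co$schema$name[pa$j_bin[jj]]]] <- round(pa$p[1, jj])
  }
  for (jj in seq_along(pa$j_cat)) {
    centroid_row[[co$schema$name[pa$j_cat[jj]]]] <- which.max(pa$cat[[jj]][1, ])
  }
  one <- phenotype_cohort(centroid_row, co$schema)
  pr <- predict(fit, one)
  expect_gt(max(pr$responsibilities), 0.99)
})

test_that("variance floor keeps duplicated-point fits finite", {
  sch <- feature_schema("x", "continuous")
  feats <- data.frame(x = rep(c(0, 0, 5), each = 30))
  co <- manual_cohort(feats, sch)
  fit <- gfmm_fit(co, K = 2, n_init = 3, seed = 6)
  expect_true(is.finite(fit$ll))
  expect_true(all(fit$params$sd > 0))
})

test_that("model JSON round-trip reproduces predictions exactly", {
  spec <- tiny_spec(n = 200, K = 2, seed = 29)
  co <- generate_cohort(spec)
  fit <- gfmm_fit(co, K = 2, n_init = 2, seed = 8)
  path <- file.path(tempdir(), "model.json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  pr1 <- predict(fit, co)
  pr2 <- predict(back, co)
  expect_identical(pr1$labels, pr2$labels)
  expect_equal(pr1$responsibilities, pr2$responsibilities, tolerance = 1e-12)
})

test_that("fit rejects missing data and K larger than n", {
  sch <- feature_schema("x", "continuous")
  co <- manual_cohort(data.frame(x = c(1, NA, 3)), sch)
  expect_error(gfmm_fit(co, K = 1), "missing")
  co2 <- manual_cohort(data.frame(x = c(1, 2)), sch)
  expect_error(gfmm_fit(co2, K = 5), "value error")
})
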