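test_that("intercept-only fit recovers the pooled rate", {
  # totals: meth 300 of 1000 -> pooled rate 0.3 in every cell
  meth <- matrix(c(4L, 96L, 100L, 100L), 2, 2)
  cov <- matrix(c(10L, 290L, 350L, 350L), 2, 2)
  data <- toy_dataset(meth, cov, c("A", "U"))
  adj <- fit_covariate_model(data)
  expect_equal(unname(adj$p_hat), matrix(0.3, 2, 2))
  expect_equal(adj$r[1, 1], 4 - 0.3 * 10)  # = 1
  expect_equal(sum(adj$r), 0)
})

test_that("identical cells adjust to zero everywhere", {
  data <- toy_dataset(matrix(3L, 4, 3), matrix(10L, 4, 3),
                      rep(c("A", "U"), 2))
  adj <- fit_covariate_model(data)
  expect_equal(adj$r, matrix(0, 4, 3), ignore_attr = TRUE)
})

test_that("a binary covariate fits the saturated two-cell rates exactly", {
  # half the samples at rate 0.2, half at 0.4, equal coverage
  meth <- rbind(matrix(2L, 2, 4), matrix(4L, 2, 4))
  cov <- matrix(10L, 4, 4)
  data <- toy_dataset(meth, cov, c("A", "U", "A", "U"),
                      covariates = data.frame(batch = c(0, 0, 1, 1)))
  adj <- fit_covariate_model(data, covariates = "batch")
  expect_equal(unname(adj$p_hat[1:2, ]), matrix(0.2, 2, 4), tolerance = 1e-8)
  expect_equal(unname(adj$p_hat[3:4, ]), matrix(0.4, 2, 4), tolerance = 1e-8)
  expect_equal(sum(adj$r[1:2, ]), 0, tolerance = 1e-6)
  expect_equal(sum(adj$r[3:4, ]), 0, tolerance = 1e-6)
})

test_that("the group label is rejected as a covariate", {
  data <- random_dataset(seed = 2)
  expect_error(fit_covariate_model(data, covariates = "group"),
               "group label")
})

test_that("site group summaries reproduce the hand-computed example", {
  # 2 cases (8/10, 6/10), 2 controls (2/10, 0/10) at one site:
  # pooled p = 0.4, r_A = 14 - 8 = 6, r_U = 2 - 8 = -6, delta = 0.6
  meth <- matrix(c(8L, 6L, 2L, 0L), 4, 1)
  cov <- matrix(10L, 4, 1)
  # second site to satisfy the two-site minimum of downstream tests
  data <- toy_dataset(cbind(meth, meth), cbind(cov, cov),
                      c("A", "A", "U", "U"))
  adj <- fit_covariate_model(data)
  sgs <- site_group_summaries(adj, data)
  a_row <- sgs[sgs$group == "A" & sgs$site_index == 1, ]
  u_row <- sgs[sgs$group == "U" & sgs$site_index == 1, ]
  expect_equal(a_row$r_sum, 6)
  expect_equal(u_row$r_sum, -6)
  expect_equal(attr(sgs, "delta")$delta[1], 0.6)
})

test_that("with no covariates delta equals the raw group rate difference", {
  for (seed in 1:5) {
    data <- random_dataset(n = 10, m = 7, seed = seed)
    adj <- fit_covariate_model(data)
    delta <- attr(site_group_summaries(adj, data), "delta")$delta
    gA <- data$samples$group == "A"
    raw <- colSums(data$meth[gA, ]) / colSums(data$coverage[gA, ]) -
      colSums(data$meth[!gA, ]) / colSums(data$coverage[!gA, ])
    expect_equal(delta, unname(raw), tolerance = 1e-12)
  }
})

test_that("groups with identical per-site rates give delta = 0", {
  meth <- rbind(c(2L, 4L), c(3L, 6L), c(2L, 4L), c(3L, 6L))
  cov <- rbind(c(10L, 20L), c(15L, 30L), c(10L, 20L), c(15L, 30L))
  data <- toy_dataset(meth, cov, c("A", "A", "U", "U"))
  delta <- attr(site_group_summaries(fit_covariate_model(data), data),
                "delta")$delta
  expect_equal(delta, c(0, 0))
})

test_that("zero-coverage sites are excluded from the summaries", {
  meth <- rbind(c(2L, 0L), c(3L, 0L), c(2L, 1L), c(3L, 2L))
  cov <- rbind(c(10L, 0L), c(15L, 0L), c(10L, 5L), c(15L, 5L))
  data <- toy_dataset(meth, cov, c("A", "A", "U", "U"))
  adj <- fit_covariate_model(data)
  expect_message(sgs <- site_group_summaries(adj, data), "excluded")
  expect_equal(attr(sgs, "excluded"), 2L)
  expect_false(2L %in% sgs$site_index)
})

test_that("adjusted counts sum to zero for intercept models (conservation)", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 8; m <- 5
    cov <- matrix(rpois(n * m, 25) + 1L, n, m)
    x <- rnorm(n)
    p <- plogis(-1 + 0.8 * x)
    meth <- matrix(rbinom(n * m, as.vector(cov), rep(p, m)), n, m)
    data <- toy_dataset(meth, cov, rep(c("A", "U"), n / 2),
                        covariates = data.frame(age = x))
    expect_equal(sum(fit_covariate_model(data)$r), 0, tolerance = 1e-8)
    expect_equal(sum(fit_covariate_model(data, "age")$r), 0, tolerance = 1e-6)
  }
})

test_that("the no-covariate stage matches a brute-force oracle", {
  for (seed in 1:5) {
    data <- random_dataset(n = 6, m = 4, seed = seed + 100)
    adj <- fit_covariate_model(data)
    expect_equal(adj$r, brute_force_adjust(data$meth, data$coverage),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("clustered fit without covariates equals the pooled fit", {
  data <- random_dataset(n = 10, m = 6, seed = 3)
  simple <- fit_covariate_model(data)
  mixed <- mixed_model_adjust(data)
  expect_identical(mixed$r, simple$r)
  expect_identical(mixed$p_hat, simple$p_hat)
  expect_equal(mixed$model, "mixed")
  expect_true(is.finite(mixed$alpha))
})

test_that("exchangeable correlation estimate is near zero for independent data", {
  set.seed(42)
  n <- 200; m <- 6
  cov <- matrix(rpois(n * m, 30) + 1L, n, m)
  meth <- matrix(rbinom(n * m, as.vector(cov), 0.3), n, m)
  data <- toy_dataset(meth, cov, rep(c("A", "U"), n / 2))
  expect_lt(abs(mixed_model_adjust(data)$alpha), 0.05)
})

test_that("perfectly duplicated sites drive the exchangeable correlation to 1", {
  set.seed(7)
  n <- 40
  cov1 <- rpois(n, 30) + 1L
  meth1 <- rbinom(n, cov1, 0.3)
  data <- toy_dataset(cbind(meth1, meth1, meth1),
                      cbind(cov1, cov1, cov1),
                      rep(c("A", "U"), n / 2))
  expect_gt(mixed_model_adjust(data)$alpha, 0.9)
})

test_that("clustered fit with a covariate solves the estimating equations", {
  set.seed(9)
  n <- 60; m <- 4
  x <- rbinom(n, 1, 0.5)
  cov <- matrix(rpois(n * m, 25) + 1L, n, m)
  p <- plogis(-1.2 + 0.9 * x)
  meth <- matrix(rbinom(n * m, as.vector(cov), rep(p, m)), n, m)
  data <- toy_dataset(meth, cov, rep(c("A", "U"), n / 2),
                      covariates = data.frame(batch = x))
  mixed <- mixed_model_adjust(data, "batch")
  simple <- fit_covariate_model(data, "batch")
  # independent data: marginal estimates should agree closely with the
  # pooled logistic fit, and the robust vcov must be a valid covariance
  expect_equal(unname(mixed$coefficients), unname(simple$coefficients),
               tolerance = 0.05)
  expect_true(all(eigen(mixed$vcov_robust, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_true(all(mixed$p_hat > 0 & mixed$p_hat < 1))
})

test_that("design effect follows 1 + (cbar - 1) * icc with the ANOVA icc", {
  set.seed(15)
  n <- 12; m <- 5
  cov <- matrix(rpois(n * m, 29) + 1L, n, m)
  meth <- matrix(rbinom(n * m, as.vector(cov), 0.35), n, m)
  data <- toy_dataset(meth, cov, rep(c("A", "U"), n / 2))
  adj <- fit_covariate_model(data)
  dec <- design_effect_adjust(adj, data)

  rho_oracle <- vapply(seq_len(m), function(j)
    icc_anova_reads(data$meth[, j], data$coverage[, j]), numeric(1))
  expect_equal(dec$rho, rho_oracle, tolerance = 1e-12)

  groups <- data$samples$group
  for (k in 1:2) {
    g <- groups == c("A", "U")[k]
    cbar <- colSums(data$coverage[g, ]) / sum(g)
    expect_equal(dec$deff[k, ], pmax(1, 1 + (cbar - 1) * rho_oracle),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_true(all(dec$deff >= 1))
})

test_that("strong read clustering inflates the design effect toward coverage", {
  # half the samples fully methylated, half fully unmethylated at each
  # site: reads within a sample are perfectly correlated (icc -> 1)
  n <- 20
  cov <- matrix(30L, n, 3)
  meth <- rbind(matrix(30L, n / 2, 3), matrix(0L, n / 2, 3))
  data <- toy_dataset(meth, cov, rep(c("A", "U"), n / 2))
  dec <- design_effect_adjust(fit_covariate_model(data), data)
  expect_true(all(dec$rho > 0.9))
  expect_true(all(dec$deff > 25))
})

test_that("unit coverage gives design effect 1 regardless of clustering", {
  set.seed(21)
  n <- 16
  cov <- matrix(1L, n, 4)
  meth <- matrix(rbinom(n * 4, 1, 0.4), n, 4)
  data <- toy_dataset(meth, cov, rep(c("A", "U"), n / 2))
  dec <- design_effect_adjust(fit_covariate_model(data), data)
  expect_equal(dec$deff, matrix(1, 2, 4), ignore_attr = TRUE)
})

test_that("with no covariates the recentred counts equal the raw group counts", {
  for (seed in 6:8) {
    data <- random_dataset(n = 8, m = 5, seed = seed)
    dec <- design_effect_adjust(fit_covariate_model(data), data)
    groups <- factor(data$samples$group)
    raw <- rowsum(data$meth + 0, groups)
    expect_equal(dec$r_tilde * dec$deff, raw, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("single-sample groups fall back to design effect 1 with a warning", {
  data <- toy_dataset(rbind(c(3L, 4L), c(5L, 6L)),
                      matrix(10L, 2, 2), c("A", "U"))
  expect_warning(dec <- design_effect_adjust(fit_covariate_model(data), data),
                 "single sample")
  expect_equal(dec$deff, matrix(1, 2, 2), ignore_attr = TRUE)
})
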