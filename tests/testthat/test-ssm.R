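test_that("window likelihood ratio matches the nested log-likelihood oracle", {
  # equal proportions collapse the alternative onto the null
  expect_equal(window_lr(5, 10, 50, 100), 0)
  # 8/10 vs 2/10, checked against half the G-squared of the 2x2 table
  expect_equal(window_lr(8, 10, 2, 10), g2_2x2(8, 10, 2, 10) / 2,
               tolerance = 1e-12)
  expect_equal(window_lr(8, 10, 2, 10), 3.854895, tolerance = 1e-6)
  # symmetry under swapping groups
  expect_equal(window_lr(8, 10, 2, 10), window_lr(2, 10, 8, 10))
  # degenerate proportions are a contract violation
  expect_error(window_lr(0, 10, 5, 10), "pseudo-counts")
  expect_error(window_lr(10, 10, 5, 10), "pseudo-counts")
})

test_that("window LR agrees with deviance and share-form oracles on random tables", {
  set.seed(77)
  for (i in 1:20) {
    CA <- sample(10:200, 1); CU <- sample(10:200, 1)
    rA <- sample(seq_len(CA - 1), 1); rU <- sample(seq_len(CU - 1), 1)
    lr <- window_lr(rA, CA, rU, CU)
    expect_gte(lr, -1e-12)
    expect_equal(lr, g2_2x2(rA, CA, rU, CU) / 2, tolerance = 1e-10)
    # share-form statistic is on the per-read scale: LR / (CA + CU)
    expect_equal(lr / (CA + CU), scan_delta_shares(rA, CA, rU, CU),
                 tolerance = 1e-10)
  }
})

test_that("window LR scales linearly with coverage at fixed proportions", {
  lr1 <- window_lr(8, 20, 3, 15)
  for (k in c(2, 5, 10))
    expect_equal(window_lr(8 * k, 20 * k, 3 * k, 15 * k), k * lr1,
                 tolerance = 1e-10)
})

test_that("pseudo-counts shift counts and repair degenerate windows", {
  dec <- structure(list(r_tilde = rbind(c(0, 10), c(5, 0)),
                        C_tilde = rbind(c(10, 10), c(10, 10)),
                        deff = matrix(1, 2, 2), rho = c(0, 0),
                        groups = c("A", "U")),
                   class = "design_effect_counts")
  out <- apply_pseudocounts(dec)
  expect_equal(out$r_tilde, rbind(c(1, 11), c(6, 1)))
  expect_equal(out$C_tilde, matrix(12, 2, 2))
  # previously degenerate windows now have a finite LR
  sw <- scan_windows(out, window_sizes = 2)
  expect_true(all(is.finite(sw$lr)))
})

test_that("a single full-region window reduces the scan to one LR call", {
  data <- random_dataset(n = 8, m = 6, seed = 41)
  adj <- fit_covariate_model(data)
  dec <- apply_pseudocounts(design_effect_adjust(adj, data))
  sw <- scan_windows(dec, window_sizes = 6)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$lr,
               window_lr(sum(dec$r_tilde[1, ]), sum(dec$C_tilde[1, ]),
                         sum(dec$r_tilde[2, ]), sum(dec$C_tilde[2, ])),
               tolerance = 1e-9)
})

test_that("the global statistic is the maximum over windows and sizes", {
  data <- random_dataset(n = 12, m = 12, seed = 42)
  res <- ssm_scan(data, window_sizes = c(3, 6), permutations = 30, seed = 1)
  expect_equal(res$global_lr, max(res$per_window$lr))
  # deterministic windows agree with the standalone window table
  adj <- mixed_model_adjust(data)
  dec <- apply_pseudocounts(design_effect_adjust(adj, data))
  sw <- scan_windows(dec, window_sizes = c(3, 6))
  expect_equal(res$per_window$lr, sw$lr, tolerance = 1e-10)
})

test_that("oversized windows are skipped with a warning", {
  data <- random_dataset(n = 8, m = 5, seed = 43)
  expect_warning(res <- ssm_scan(data, window_sizes = c(3, 10),
                                 permutations = 20, seed = 2), "skipped")
  expect_true(all(res$per_window$size == 3))
})

test_that("scan is invariant under swapping the two group labels", {
  data <- random_dataset(n = 10, m = 8, seed = 44)
  swapped <- data
  swapped$samples$group <- ifelse(data$samples$group == "A", "U", "A")
  r1 <- ssm_scan(data, window_sizes = 4, permutations = 20, seed = 3)
  r2 <- ssm_scan(swapped, window_sizes = 4, permutations = 20, seed = 3)
  expect_equal(r1$per_window$lr, r2$per_window$lr, tolerance = 1e-10)
  expect_equal(r1$global_lr, r2$global_lr, tolerance = 1e-10)
})

test_that("a planted DMR is found by the argmax window", {
  set.seed(55)
  n <- 40; m <- 24
  cov <- matrix(rpois(n * m, 50) + 1L, n, m)
  p <- matrix(0.1, n, m)
  p[1:20, 10:15] <- 0.4  # cases methylated at sites 10-15
  meth <- matrix(rbinom(n * m, as.vector(cov), as.vector(p)), n, m)
  data <- toy_dataset(meth, cov, rep(c("A", "U"), c(20, 20)))
  res <- ssm_scan(data, window_sizes = 6, permutations = 100, seed = 5)
  best <- res$per_window[which.max(res$per_window$lr), ]
  expect_true(best$start_index <= 15 && best$end_index >= 10)
  expect_lt(res$global_p, 0.05)
})

test_that("greedy DMR calling keeps the best non-overlapping windows", {
  skeleton <- structure(list(
    per_window = data.frame(
      size = c(5L, 5L, 5L), start_index = c(1L, 3L, 10L),
      end_index = c(5L, 7L, 14L), start_bp = c(100L, 300L, 1000L),
      end_bp = c(500L, 700L, 1400L), lr = c(5, 4, 3),
      p_value = c(0.01, 0.02, 0.03)),
    chromosome = "chr1", n_groups = 2L, B = 100L, alpha = 0.05),
    class = "ssm_result")
  calls <- call_dmrs(skeleton, alpha = 0.05)
  # overlapping LR-4 window dropped; LR-5 and LR-3 kept, in genomic order
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$statistic, c(5, 3))
  expect_equal(calls$start_bp, c(100L, 1000L))

  expect_equal(nrow(call_dmrs(skeleton, alpha = 0.005)), 0L)
})

test_that("multinomial scan reduces exactly to the binomial scan for 2 groups", {
  data <- random_dataset(n = 10, m = 8, seed = 46)
  r1 <- ssm_scan(data, window_sizes = 4, permutations = 25, seed = 6)
  r2 <- multinomial_scan(data, window_sizes = 4, permutations = 25, seed = 6)
  expect_equal(r1$per_window$lr, r2$per_window$lr)
  expect_identical(r1$global_p, r2$global_p)
})

test_that("three-group window statistic equals half the table G-squared", {
  # toy counts 8/10, 5/10, 2/10 at a single site
  dec <- structure(list(r_tilde = matrix(c(8, 5, 2), 3, 1),
                        C_tilde = matrix(10, 3, 1),
                        deff = matrix(1, 3, 1), rho = 0,
                        groups = c("A", "B", "C")),
                   class = "design_effect_counts")
  sw <- scan_windows(dec, window_sizes = 1)
  expect_equal(sw$lr, g2_table(c(8, 5, 2), c(2, 5, 8)) / 2, tolerance = 1e-12)
})

test_that("equal group rates give a zero multinomial statistic", {
  dec <- structure(list(r_tilde = matrix(c(4, 8, 12), 3, 1),
                        C_tilde = matrix(c(10, 20, 30), 3, 1),
                        deff = matrix(1, 3, 1), rho = 0,
                        groups = c("A", "B", "C")),
                   class = "design_effect_counts")
  expect_equal(scan_windows(dec, window_sizes = 1)$lr, 0, tolerance = 1e-12)
})

test_that("three-group data runs end to end; ordered labels are refused", {
  set.seed(47)
  n <- 12; m <- 6
  cov <- matrix(rpois(n * m, 20) + 1L, n, m)
  meth <- matrix(rbinom(n * m, as.vector(cov), 0.3), n, m)
  data <- toy_dataset(meth, cov, rep(c("A", "B", "C"), 4))
  res <- multinomial_scan(data, window_sizes = 3, permutations = 30, seed = 7)
  expect_true(all(is.finite(res$per_window$lr)))
  expect_true(res$global_p > 0 && res$global_p <= 1)
  expect_error(multinomial_scan(data, ordered = TRUE), "ordered")
})

test_that("adversarial all-zero and all-one datasets scan without failures", {
  cov <- matrix(10L, 8, 6)
  groups <- rep(c("A", "U"), 4)
  for (meth in list(matrix(0L, 8, 6), matrix(10L, 8, 6))) {
    data <- toy_dataset(meth, cov, groups)
    res <- ssm_scan(data, window_sizes = 3, permutations = 20, seed = 8)
    expect_true(all(is.finite(res$per_window$lr)))
    expect_true(all(abs(res$per_window$lr) < 1e-8))  # no signal anywhere
    expect_gt(res$global_p, 0.5)
  }
})

test_that("scan results are deterministic given a seed", {
  data <- random_dataset(n = 10, m = 10, seed = 48)
  r1 <- ssm_scan(data, window_sizes = c(3, 5), permutations = 50, seed = 9)
  r2 <- ssm_scan(data, window_sizes = c(3, 5), permutations = 50, seed = 9)
  expect_identical(r1$per_window, r2$per_window)
  expect_identical(r1$global_p, r2$global_p)
})
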