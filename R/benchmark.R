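#' Empirical type-I error of the region tests under the null
#'
#' Runs the full pipeline — simulate a null dataset, covariate-adjust,
#' test — `n_reps` times and reports the fraction of permutation
#' p-values at or below each nominal level, with binomial Monte-Carlo
#' standard errors.  Refuses non-null configurations, since the rejection
#' fraction is only a type-I error when the simulated effect size is
#' zero.
#'
#' Reproducibility: the master `seed` seeds one RNG stream from which a
#' per-replicate seed triple (dataset, KDM permutations, SSM
#' permutations) is drawn up front, so results are independent of the
#' order in which methods run.
#'
#' @param cfg a null [simulation_config()] (`d == 0`).
#' @param n_reps number of simulated datasets.
#' @param alpha_levels nominal significance levels.
#' @param methods subset of `c("KDM", "SSM")`.
#' @param permutations permutations per dataset for each test.
#' @param tau kernel bandwidth passed to [kdm_test()] (site-index units;
#'   the simulated sites are 1 bp apart so bp and index coincide).
#' @param window_sizes window size(s) for [ssm_scan()].
#' @param seed master seed.
#' @return object of class `benchmark_result`: list with `rates`
#'   (data.frame method/level/rate/se), `p_values` (one row per
#'   replicate), `n_reps`, `permutations`, and the configuration.
#' @export
benchmark_type1 <- function(cfg, n_reps = 2000L,
                            alpha_levels = c(0.05, 0.01),
                            methods = c("KDM", "SSM"),
                            permutations = 500L,
                            tau = 6, window_sizes = 6L,
                            seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$d != 0)
    stop("benchmark_type1 needs a null configuration (effect size d = 0); ",
         "got d = ", cfg$d)
  run_benchmark(cfg, n_reps, alpha_levels, methods, permutations,
                tau, window_sizes, seed, label = "type1")
}

#' Empirical power of the region tests across effect sizes
#'
#' For each value of `alpha_A`, simulates `n_reps` datasets with the DMR
#' effect implied by the configuration's remaining Beta parameters and
#' reports the fraction of p-values at or below `level` per method.  The
#' effect size is `d = alpha_A/(alpha_A+beta_A) - alpha_U/(alpha_U+beta_U)`.
#' Both methods are run on the same datasets, so method contrasts are
#' paired.
#'
#' @inheritParams benchmark_type1
#' @param alpha_A vector of case Beta `alpha` values defining the effect
#'   grid.
#' @param level nominal significance level for the power estimate.
#' @return data.frame with columns `alpha_A`, `d`, `method`, `power`,
#'   `se`, `n_reps`; attribute `p_values` holds the per-replicate
#'   p-values of every grid point.
#' @export
benchmark_power <- function(cfg, alpha_A, n_reps = 500L, level = 0.05,
                            methods = c("KDM", "SSM"),
                            permutations = 200L,
                            tau = 6, window_sizes = 6L,
                            seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  out <- list()
  pvals <- list()
  if (!is.null(seed)) set.seed(seed)
  grid_seeds <- sample.int(.Machine$integer.max - 1L, length(alpha_A))
  for (g in seq_along(alpha_A)) {
    cfg_g <- cfg
    cfg_g$alpha_A <- alpha_A[g]
    cfg_g$d <- alpha_A[g] / (alpha_A[g] + cfg$beta_A) -
      cfg$alpha_U / (cfg$alpha_U + cfg$beta_U)
    if (cfg_g$d < 0) stop("alpha_A = ", alpha_A[g],
                          " gives a negative effect size")
    bm <- run_benchmark(cfg_g, n_reps, level, methods, permutations,
                        tau, window_sizes, grid_seeds[g], label = "power")
    bm$rates$alpha_A <- alpha_A[g]
    bm$rates$d <- cfg_g$d
    names(bm$rates)[names(bm$rates) == "rate"] <- "power"
    out[[g]] <- bm$rates[, c("alpha_A", "d", "method", "power", "se", "n_reps")]
    pvals[[g]] <- cbind(alpha_A = alpha_A[g], bm$p_values)
  }
  res <- do.call(rbind, out)
  attr(res, "p_values") <- do.call(rbind, pvals)
  res
}

# Shared replicate loop of the two benchmarks.
run_benchmark <- function(cfg, n_reps, alpha_levels, methods, permutations,
                          tau, window_sizes, seed, label) {
  methods <- match.arg(methods, c("KDM", "SSM"), several.ok = TRUE)
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_reps),
                      nrow = n_reps)

  p_kdm <- rep(NA_real_, n_reps)
  p_ssm <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    data <- simulate_dataset(cfg, seed = rep_seeds[i, 1L])
    if ("KDM" %in% methods) {
      p_kdm[i] <- kdm_test(data, tau = tau, distance_unit = "index",
                           permutations = permutations,
                           seed = rep_seeds[i, 2L])$p_value
    }
    if ("SSM" %in% methods) {
      p_ssm[i] <- ssm_scan(data, window_sizes = window_sizes,
                           permutations = permutations,
                           seed = rep_seeds[i, 3L])$global_p
    }
  }

  rates <- do.call(rbind, lapply(methods, function(mth) {
    p <- if (mth == "KDM") p_kdm else p_ssm
    data.frame(
      method = mth,
      level = alpha_levels,
      rate = vapply(alpha_levels, function(a) mean(p <= a), numeric(1)),
      n_reps = n_reps
    )
  }))
  rates$se <- sqrt(rates$rate * (1 - rates$rate) / n_reps)

  structure(
    list(rates = rates[, c("method", "level", "rate", "se", "n_reps")],
         p_values = data.frame(rep = seq_len(n_reps),
                               KDM = p_kdm, SSM = p_ssm),
         n_reps = n_reps,
         permutations = permutations,
         config = cfg,
         label = label),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark (", x$label, "): ", x$n_reps, " replicates, B = ",
      x$permutations, " permutations\n", sep = "")
  print(x$rates, row.names = FALSE)
  invisible(x)
}
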