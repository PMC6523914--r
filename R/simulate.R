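#' Simulation configuration for synthetic methylation data
#'
#' Describes one synthetic study: two groups of subjects measured at `m`
#' equally spaced CpG sites, with `r` consecutive sites in the middle of
#' the region forming the DMR.  Per-site latent methylation levels are
#' Beta-distributed — `Beta(alpha_U, beta_U)` everywhere except for case
#' subjects inside the DMR, where `Beta(alpha_A, beta_A)` applies — and
#' are coupled across sites through a Gaussian copula whose correlation
#' between sites decays as `rho / distance`.  Coverage is drawn as
#' `round(Normal(coverage_mean, coverage_sd))` clamped below at
#' `coverage_min`, and methylated counts are binomial given coverage and
#' rate.  The effect size is the difference of Beta means,
#' `d = alpha_A/(alpha_A+beta_A) - alpha_U/(alpha_U+beta_U)`; equal Beta
#' parameters give a null configuration (`d = 0`).
#'
#' The defaults reproduce the package's calibration study conditions: 24
#' cases and 24 controls, 24 sites with a 6-site central DMR, null Beta
#' parameters (0.1, 0.9), adjacent-site correlation 0.5, coverage
#' Normal(30, sd 13) clamped at 5.
#'
#' @param n_cases,n_controls subjects per group.
#' @param n_sites number of equally spaced CpG sites `m`.
#' @param dmr_sites number of consecutive DMR sites `r` (centered; ties
#'   resolved toward the lower index).
#' @param alpha_U,beta_U Beta parameters outside the DMR (and for
#'   controls inside).
#' @param alpha_A,beta_A Beta parameters for cases inside the DMR.
#' @param rho adjacent-site copula correlation in `[0, 1)`.
#' @param coverage_mean,coverage_sd,coverage_min coverage model.
#' @param seed default seed used by [simulate_dataset()].
#' @param proper_copula if TRUE, pass the Beta draws through their CDF
#'   before the normal-score transform so that Beta marginals are
#'   preserved exactly; the default FALSE applies the normal-score
#'   transform to the raw Beta draws (see the methods vignette for why
#'   this is the default).
#' @return validated list of class `simulation_config`, with derived
#'   element `d` (effect size).
#' @export
simulation_config <- function(n_cases = 24L, n_controls = 24L,
                              n_sites = 24L, dmr_sites = 6L,
                              alpha_U = 0.1, beta_U = 0.9,
                              alpha_A = 0.1, beta_A = 0.9,
                              rho = 0.5,
                              coverage_mean = 30, coverage_sd = 13,
                              coverage_min = 5L,
                              seed = NULL, proper_copula = FALSE) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_sites >= 2)
  if (dmr_sites > n_sites) stop("dmr_sites must be <= n_sites")
  if (any(c(alpha_U, beta_U, alpha_A, beta_A) <= 0))
    stop("Beta parameters must be positive")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (coverage_min < 1) stop("coverage_min must be >= 1")
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_sites = as.integer(n_sites), dmr_sites = as.integer(dmr_sites),
    alpha_U = alpha_U, beta_U = beta_U,
    alpha_A = alpha_A, beta_A = beta_A,
    rho = rho,
    coverage_mean = coverage_mean, coverage_sd = coverage_sd,
    coverage_min = as.integer(coverage_min),
    seed = seed, proper_copula = isTRUE(proper_copula)
  )
  cfg$d <- alpha_A / (alpha_A + beta_A) - alpha_U / (alpha_U + beta_U)
  structure(cfg, class = "simulation_config")
}

#' Distance-decaying correlation matrix and its Cholesky factor
#'
#' Correlation matrix for equally spaced sites with unit diagonal and
#' off-diagonal entries `rho / |i - j|`, so adjacent sites correlate at
#' `rho` and the correlation decays inversely with distance.  The matrix
#' is required to be positive definite as given; if the Cholesky
#' factorization fails, an error suggests a smaller `rho` rather than
#' silently repairing the matrix.
#'
#' @param m number of sites.
#' @param rho adjacent-site correlation in `[0, 1)`.
#' @param positions site positions used for distances (default
#'   `1:m`, i.e. site-index units).
#' @return list with `sigma` (the matrix) and `chol` (lower-triangular
#'   factor `C` with `C %*% t(C) = sigma`).
#' @export
correlation_matrix <- function(m, rho, positions = seq_len(m)) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  stopifnot(length(positions) == m)
  d <- abs(outer(positions, positions, "-"))
  sigma <- ifelse(d == 0, 1, rho / pmax(d, 1e-300))
  sigma <- pmin(sigma, 1)
  up <- tryCatch(chol(sigma), error = function(e)
    stop("correlation matrix is not positive definite for rho = ", rho,
         " and m = ", m, "; use a smaller rho", call. = FALSE))
  list(sigma = sigma, chol = t(up))
}

#' Simulate a synthetic methylation dataset
#'
#' Draws one dataset under a [simulation_config()].  For each subject,
#' independent per-site Beta variables `X` are drawn (cases use the DMR
#' Beta parameters at DMR sites), then mapped to correlated methylation
#' rates with the normal-score transform
#' `p = 1 - pnorm(C %*% qnorm(1 - X))`, where `C` is the Cholesky factor
#' of the distance-decaying correlation matrix.  Coverage is
#' `max(coverage_min, round(rnorm(coverage_mean, coverage_sd)))` and
#' methylated counts are `rbinom(coverage, p)`.  Sites live on
#' chromosome `"sim1"` at positions `1..m`, so base-pair and site-index
#' distances coincide.
#'
#' The draw is deterministic given the seed.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; defaults to `cfg$seed` (an error if both are
#'   `NULL` is *not* raised — the current RNG state is used).
#' @return a [methylation_dataset()] with group labels `"A"` (cases,
#'   listed first) and `"U"` (controls), plus attributes `dmr_sites`
#'   (site indices of the embedded DMR) and `rates` (the latent per-cell
#'   methylation rates, useful for copula diagnostics).
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  m <- cfg$n_sites
  n1 <- cfg$n_cases
  n2 <- cfg$n_controls
  n <- n1 + n2

  # centered DMR, ties toward the lower index
  start <- floor((m - cfg$dmr_sites) / 2) + 1L
  dmr_idx <- seq.int(start, length.out = cfg$dmr_sites)

  Cl <- correlation_matrix(m, cfg$rho)$chol

  X <- matrix(stats::rbeta(n * m, cfg$alpha_U, cfg$beta_U), n, m)
  if (cfg$d != 0 || cfg$alpha_A != cfg$alpha_U || cfg$beta_A != cfg$beta_U) {
    X[seq_len(n1), dmr_idx] <-
      stats::rbeta(n1 * length(dmr_idx), cfg$alpha_A, cfg$beta_A)
  }

  if (cfg$proper_copula) {
    # map to exact uniforms first so Beta marginals survive the transform
    ab_a <- matrix(cfg$alpha_U, n, m); ab_b <- matrix(cfg$beta_U, n, m)
    ab_a[seq_len(n1), dmr_idx] <- cfg$alpha_A
    ab_b[seq_len(n1), dmr_idx] <- cfg$beta_A
    U <- stats::pbeta(X, ab_a, ab_b)
    Zn <- stats::qnorm(pmin(pmax(1 - U, 1e-300), 1 - 1e-16))
    Y <- Zn %*% t(Cl)
    p <- stats::qbeta(stats::pnorm(Y, lower.tail = FALSE), ab_a, ab_b)
  } else {
    # transform as stated: normal scores of (1 - X) directly
    Zn <- stats::qnorm(pmin(pmax(X, 1e-300), 1 - 1e-16), lower.tail = FALSE)
    Y <- Zn %*% t(Cl)
    p <- stats::pnorm(Y, lower.tail = FALSE)
  }

  cov <- matrix(pmax(cfg$coverage_min,
                     as.integer(round(stats::rnorm(n * m, cfg$coverage_mean,
                                                   cfg$coverage_sd)))),
                n, m)
  meth <- matrix(stats::rbinom(n * m, as.vector(cov), as.vector(p)), n, m)

  data <- methylation_dataset(
    sites = data.frame(chromosome = "sim1", position = seq_len(m)),
    samples = data.frame(
      sample_id = c(sprintf("case%02d", seq_len(n1)),
                    sprintf("ctrl%02d", seq_len(n2))),
      group = rep(c("A", "U"), c(n1, n2)),
      stringsAsFactors = FALSE
    ),
    meth = meth, coverage = cov
  )
  attr(data, "dmr_sites") <- dmr_idx
  attr(data, "rates") <- p  # latent per-cell methylation rates, for diagnostics
  data
}

#' Write a simulated dataset as bismark-style coverage files
#'
#' Companion to [simulate_dataset()] for the command-line workflow: one
#' coverage file per sample plus a sample sheet, re-readable with
#' [read_coverage_files()].
#'
#' @param data a [methylation_dataset()].
#' @param prefix output path prefix; files become
#'   `<prefix>_<sample_id>.cov` and `<prefix>_samples.tsv`.
#' @return invisibly, the sample sheet path.
#' @export
write_coverage_files <- function(data, prefix) {
  n <- n_samples(data)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- paste0(prefix, "_", data$samples$sample_id[i], ".cov")
    u <- data$coverage[i, ] - data$meth[i, ]
    pct <- ifelse(data$coverage[i, ] > 0,
                  100 * data$meth[i, ] / data$coverage[i, ], 0)
    tab <- data.frame(data$sites$chromosome, data$sites$position,
                      data$sites$position, sprintf("%.6g", pct),
                      data$meth[i, ], u)
    data.table::fwrite(tab, paths[i], sep = "\t", col.names = FALSE)
  }
  sheet <- data.frame(sample_id = data$samples$sample_id,
                      path = paths,
                      group = data$samples$group)
  extra <- setdiff(names(data$samples), c("sample_id", "group"))
  if (length(extra)) sheet <- cbind(sheet, data$samples[extra])
  sheet_path <- paste0(prefix, "_samples.tsv")
  data.table::fwrite(sheet, sheet_path, sep = "\t")
  invisible(sheet_path)
}
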