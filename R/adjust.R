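#' Covariate adjustment by pooled binomial logistic regression
#'
#' Fits one logistic regression of methylated counts out of coverage on
#' sample-level covariates, pooling all samples from every group and all
#' CpG sites.  The group label is deliberately excluded: the group effect
#' is exactly what the region tests measure downstream.  Fitted
#' methylation rates depend on covariates only, so every site of a sample
#' shares the same expected rate.  The adjusted methylation count of a
#' cell is the observed count minus its expectation,
#' `r = meth - p_hat * coverage`; with an intercept in the model the
#' adjusted counts sum to zero over all cells (logistic score equation).
#'
#' With no covariates the fit has closed form: `p_hat` is the pooled rate
#' `sum(meth) / sum(coverage)` for every cell.
#'
#' @param data a [methylation_dataset()].
#' @param covariates character vector of covariate column names in
#'   `data$samples`, or `NULL` for the intercept-only model.
#' @return object of class `adjusted_counts`: list with `r` and `p_hat`
#'   (samples x sites matrices), `coefficients`, and `model` ("simple").
#' @export
fit_covariate_model <- function(data, covariates = NULL) {
  validate_methylation_dataset(data)
  if (sum(data$coverage) == 0L) stop("all-zero coverage: nothing to fit")
  if ("group" %in% covariates)
    stop("the group label must not be used as a covariate")
  n <- n_samples(data)
  m <- n_sites(data)

  if (is.null(covariates) || length(covariates) == 0L) {
    p_pool <- sum(data$meth) / sum(data$coverage)
    p_hat <- matrix(p_pool, n, m)
    coefs <- c(`(Intercept)` = stats::qlogis(p_pool))
  } else {
    missing_cov <- setdiff(covariates, names(data$samples))
    if (length(missing_cov))
      stop("covariate column not found in sample sheet: ",
           paste(missing_cov, collapse = ", "))
    X <- data$samples[covariates]
    # one row per cell; covariates are sample-level so rows repeat per site
    cell <- data.frame(
      m = as.vector(data$meth),
      c = as.vector(data$coverage),
      X[rep(seq_len(n), times = m), , drop = FALSE]
    )
    cell <- cell[cell$c > 0, , drop = FALSE]
    fml <- stats::as.formula(paste(
      "cbind(m, c - m) ~", paste(covariates, collapse = " + ")))
    fit <- stats::glm(fml, family = stats::binomial(), data = cell)
    if (!fit$converged)
      stop("logistic fit did not converge for covariates: ",
           paste(covariates, collapse = ", "))
    mu <- stats::predict(fit,
                         newdata = data$samples[covariates],
                         type = "response")
    if (any(mu <= 0 | mu >= 1))
      stop("fitted rates degenerate (possible separation) for covariates: ",
           paste(covariates, collapse = ", "))
    p_hat <- matrix(rep(mu, times = m), n, m)
    coefs <- stats::coef(fit)
  }

  structure(
    list(r = data$meth - p_hat * data$coverage,
         p_hat = p_hat,
         coefficients = coefs,
         model = "simple"),
    class = "adjusted_counts"
  )
}

#' Covariate adjustment with an exchangeable within-subject correlation
#'
#' Marginal (population-averaged) logistic fit that treats the CpG sites
#' of one subject as a cluster with a compound-symmetry working
#' correlation, solved by generalized estimating equations with a robust
#' sandwich covariance for the coefficients.  The point of the clustered
#' fit is honest uncertainty for the covariate coefficients; the marginal
#' fitted rates, which are all the region tests consume, coincide with the
#' pooled logistic fit when no covariates are present, so in that case the
#' closed-form pooled estimate is used directly and only the exchangeable
#' correlation is estimated.
#'
#' If the estimating-equation iteration fails, the fit falls back to
#' [fit_covariate_model()] with a warning.
#'
#' @param data a [methylation_dataset()] with at least 2 sites.
#' @param covariates character vector of covariate column names, or `NULL`.
#' @param max_iter,tol iteration control for the estimating equations.
#' @return `adjusted_counts` with additional elements `alpha` (estimated
#'   exchangeable correlation), `vcov_robust` (sandwich covariance of the
#'   coefficients) and `model = "mixed"`.
#' @export
mixed_model_adjust <- function(data, covariates = NULL,
                               max_iter = 25L, tol = 1e-8) {
  validate_methylation_dataset(data)
  if (n_sites(data) < 2L)
    stop("clustered adjustment needs at least 2 sites per subject")

  if (is.null(covariates) || length(covariates) == 0L) {
    adj <- fit_covariate_model(data, NULL)
    adj$alpha <- exchangeable_icc(data, adj$p_hat)
    adj$vcov_robust <- NULL
    adj$model <- "mixed"
    return(adj)
  }

  out <- tryCatch(
    gee_exchangeable(data, covariates, max_iter = max_iter, tol = tol),
    error = function(e) {
      warning("exchangeable estimating-equation fit failed (",
              conditionMessage(e),
              "); falling back to the pooled logistic fit")
      adj <- fit_covariate_model(data, covariates)
      adj$alpha <- NA_real_
      adj$model <- "mixed"
      adj
    }
  )
  out
}

# Moment estimator of the exchangeable (compound-symmetry) correlation of
# Pearson residuals within subjects, given fitted rates.
exchangeable_icc <- function(data, p_hat) {
  y <- data$meth / data$coverage
  e <- (y - p_hat) / sqrt(p_hat * (1 - p_hat) / data$coverage)
  e[data$coverage == 0 | !is.finite(e)] <- NA  # no reads, or boundary rate
  n_obs <- sum(!is.na(e))
  if (n_obs == 0L) return(0)
  phi <- sum(e^2, na.rm = TRUE) / n_obs
  num <- 0
  pairs <- 0
  for (i in seq_len(nrow(e))) {
    ei <- e[i, !is.na(e[i, ])]
    k <- length(ei)
    if (k >= 2L) {
      num <- num + (sum(ei)^2 - sum(ei^2)) / 2
      pairs <- pairs + k * (k - 1) / 2
    }
  }
  if (pairs == 0 || phi == 0) return(0)
  num / (phi * pairs)
}

# GEE with logit link, binomial variance (per-cell variance p(1-p)/coverage
# on the proportion scale), exchangeable working correlation across sites
# within a subject, and robust sandwich vcov.  Covariates are sample-level,
# so the linear predictor is constant across a subject's sites.
gee_exchangeable <- function(data, covariates, max_iter = 25L, tol = 1e-8) {
  missing_cov <- setdiff(covariates, names(data$samples))
  if (length(missing_cov))
    stop("covariate column not found in sample sheet: ",
         paste(missing_cov, collapse = ", "))
  if ("group" %in% covariates)
    stop("the group label must not be used as a covariate")
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = " + "))),
    data = data$samples)
  n <- n_samples(data)
  p <- ncol(X)

  # start from the pooled (independence) fit
  beta <- {
    adj0 <- fit_covariate_model(data, covariates)
    b <- rep(0, p); names(b) <- colnames(X)
    common <- intersect(names(adj0$coefficients), colnames(X))
    b[common] <- adj0$coefficients[common]
    b
  }

  clusters <- lapply(seq_len(n), function(i) {
    keep <- which(data$coverage[i, ] > 0)
    list(y = data$meth[i, keep] / data$coverage[i, keep],
         c = data$coverage[i, keep], x = X[i, ], k = length(keep))
  })

  alpha <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    # moment update of the exchangeable correlation
    phi_num <- 0; phi_den <- 0; a_num <- 0; a_den <- 0
    for (i in seq_len(n)) {
      cl <- clusters[[i]]
      if (cl$k == 0L) next
      ei <- (cl$y - mu[i]) / sqrt(mu[i] * (1 - mu[i]) / cl$c)
      phi_num <- phi_num + sum(ei^2); phi_den <- phi_den + cl$k
      if (cl$k >= 2L) {
        a_num <- a_num + (sum(ei)^2 - sum(ei^2)) / 2
        a_den <- a_den + cl$k * (cl$k - 1) / 2
      }
    }
    phi <- phi_num / max(phi_den - p, 1)
    alpha <- if (a_den > 0) a_num / (phi * a_den) else 0
    alpha <- min(max(alpha, 0), 0.99)

    U <- rep(0, p); H <- matrix(0, p, p); meat <- matrix(0, p, p)
    for (i in seq_len(n)) {
      cl <- clusters[[i]]
      if (cl$k == 0L) next
      k <- cl$k
      v <- mu[i] * (1 - mu[i])           # d mu / d eta = variance function
      a_sd <- sqrt(v / cl$c)             # marginal sd per cell
      res <- cl$y - mu[i]
      # z = R^{-1} (res / a_sd) via exchangeable closed form
      s <- res / a_sd
      z <- (s - alpha * sum(s) / (1 + (k - 1) * alpha)) / (1 - alpha)
      w <- z / a_sd                      # V^{-1} res (up to phi)
      d <- v * cl$x                      # derivative row, same for all cells
      Ui <- d * sum(w)
      # D' V^{-1} D with identical rows: sum over cells of 1/a_sd R^{-1} ...
      one_s <- 1 / a_sd
      z1 <- (one_s - alpha * sum(one_s) / (1 + (k - 1) * alpha)) / (1 - alpha)
      quad <- sum(z1 / a_sd)
      U <- U + Ui
      H <- H + (v^2 * quad) * tcrossprod(cl$x)
      meat <- meat + tcrossprod(Ui)
    }
    step <- solve(H, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  if (max(abs(step)) >= sqrt(tol))
    stop("estimating equations did not converge")

  mu <- stats::plogis(drop(X %*% beta))
  p_hat <- matrix(rep(mu, times = n_sites(data)), n, n_sites(data))
  Hinv <- solve(H)
  structure(
    list(r = data$meth - p_hat * data$coverage,
         p_hat = p_hat,
         coefficients = stats::setNames(beta, colnames(X)),
         alpha = alpha,
         vcov_robust = Hinv %*% meat %*% Hinv,
         model = "mixed"),
    class = "adjusted_counts"
  )
}

#' Per-site group summaries of adjusted counts
#'
#' Sums adjusted counts and coverage within each group at each CpG site
#' and forms the group effect `beta_hat = r_sum / C_sum`; for two-group
#' data the per-site difference `delta = beta_hat[case] - beta_hat[control]`
#' is attached (first group level is taken as the case group).  Sites
#' where any group has zero total coverage are excluded and reported in
#' the `excluded` attribute (both tests are undefined there).
#'
#' With no covariates the pooled fitted rate cancels in `delta`, which
#' then equals the difference of raw group methylation rates.
#'
#' @param adj an `adjusted_counts` object.
#' @param data the [methylation_dataset()] the adjustment came from.
#' @return data.frame of class `site_group_summary` with columns
#'   `site_index`, `chromosome`, `position`, `group`, `r_sum`, `C_sum`,
#'   `beta_hat`; attributes `delta` (two groups only) and `excluded`.
#' @export
site_group_summaries <- function(adj, data) {
  stopifnot(inherits(adj, "adjusted_counts"))
  groups <- factor(data$samples$group)
  lev <- levels(groups)
  m <- n_sites(data)

  r_sum <- rowsum(adj$r, groups)                    # groups x sites
  C_sum <- rowsum(data$coverage + 0, groups)
  excluded <- which(apply(C_sum == 0, 2, any))
  if (length(excluded))
    message(length(excluded),
            " site(s) excluded: zero coverage in at least one group")

  out <- data.frame(
    site_index = rep(seq_len(m), each = length(lev)),
    chromosome = rep(data$sites$chromosome, each = length(lev)),
    position = rep(data$sites$position, each = length(lev)),
    group = rep(lev, times = m),
    r_sum = as.vector(r_sum),
    C_sum = as.vector(C_sum),
    stringsAsFactors = FALSE
  )
  out$beta_hat <- ifelse(out$C_sum > 0, out$r_sum / out$C_sum, NA_real_)
  if (length(excluded)) out <- out[!(out$site_index %in% excluded), ]

  if (length(lev) == 2L) {
    keep <- setdiff(seq_len(m), excluded)
    delta <- r_sum[1L, keep] / C_sum[1L, keep] -
             r_sum[2L, keep] / C_sum[2L, keep]
    attr(out, "delta") <- data.frame(
      site_index = keep,
      chromosome = data$sites$chromosome[keep],
      position = data$sites$position[keep],
      delta = as.numeric(delta)
    )
  }
  attr(out, "excluded") <- excluded
  class(out) <- c("site_group_summary", "data.frame")
  out
}

# ANOVA moment estimator of the intra-site (read-level) correlation at each
# CpG site, pooling reads of all samples: reads within a sample form a
# cluster, the binary outcome is methylated / not.  Sites where the
# estimator is undefined (no variation, or a single contributing sample)
# get 0.
site_icc_anova <- function(meth, coverage) {
  m <- ncol(meth)
  rho <- numeric(m)
  n_tot <- colSums(coverage)
  n_eff <- colSums(coverage > 0)
  p_site <- ifelse(n_tot > 0, colSums(meth) / n_tot, 0)
  prop <- ifelse(coverage > 0, meth / coverage, 0)
  ssb <- colSums(coverage * sweep(prop, 2, p_site)^2 * (coverage > 0))
  ssw <- colSums(meth * (1 - prop))
  k <- n_eff
  msb <- ifelse(k > 1, ssb / (k - 1), 0)
  msw <- ifelse(n_tot - k > 0, ssw / (n_tot - k), 0)
  n0 <- ifelse(k > 1, (n_tot - colSums(coverage^2) / pmax(n_tot, 1)) / (k - 1), 1)
  denom <- msb + (n0 - 1) * msw
  rho <- ifelse(denom > 0 & k > 1, (msb - msw) / denom, 0)
  rho[!is.finite(rho)] <- 0
  rho
}

#' Design-effect adjustment for read clustering within CpG sites
#'
#' Reads at one CpG site of one sample are not independent Bernoulli
#' draws; treating them as such overstates the effective sample size.
#' The classical variance-inflation correction for clustered binary data
#' is applied per group and site: `deff = 1 + (cbar - 1) * rho`, with
#' `cbar` the group's mean coverage at the site and `rho` an intra-site
#' correlation estimated across samples by the one-way ANOVA moment
#' estimator (reads within a sample form a cluster).  Group counts and
#' coverages are divided by `deff`, shrinking them toward the effective
#' number of independent reads.  `rho` is estimated from all samples
#' pooled, so it does not depend on the group labels and stays fixed
#' under label permutation.
#'
#' Because the scan statistic models the adjusted counts as binomial,
#' the zero-centred residual counts are first recentred by adding back
#' the grand-mean fitted count: `R = sum_i(meth - (p_hat - p_bar) * cov)`
#' with `p_bar` the coverage-weighted mean fitted rate, clamped to
#' `[0, C]`.  With no covariates this recovers the raw methylated counts
#' exactly.
#'
#' @param adj an `adjusted_counts` object.
#' @param data the [methylation_dataset()] the adjustment came from.
#' @param deff_floor lower bound for the design effect (default 1, i.e.
#'   the correction can only shrink counts).
#' @return object of class `design_effect_counts`: list with matrices
#'   `r_tilde`, `C_tilde`, `deff` (groups x sites), vector `rho`, and the
#'   group levels.
#' @export
design_effect_adjust <- function(adj, data, deff_floor = 1) {
  stopifnot(inherits(adj, "adjusted_counts"))
  groups <- factor(data$samples$group)
  n_per <- as.vector(table(groups))
  single <- n_per < 2L
  if (any(single))
    warning("group(s) with a single sample: intra-site correlation ",
            "undefined, design effect set to 1 there")

  rho <- site_icc_anova(data$meth, data$coverage)
  p_bar <- sum(adj$p_hat * data$coverage) / sum(data$coverage)
  z <- data$meth - (adj$p_hat - p_bar) * data$coverage

  C <- rowsum(data$coverage + 0, groups)            # groups x sites
  R <- rowsum(z, groups)
  R <- pmin(pmax(R, 0), C)
  cbar <- sweep(C, 1, n_per, "/")
  deff <- 1 + sweep(cbar - 1, 2, rho, "*")
  deff <- pmax(deff, deff_floor)
  deff[single, ] <- 1

  structure(
    list(r_tilde = R / deff,
         C_tilde = C / deff,
         deff = deff,
         rho = rho,
         groups = levels(groups)),
    class = "design_effect_counts"
  )
}
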