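#' Tri-weight kernel matrix
#'
#' Compact-support kernel used to weight pairs of CpG sites by genomic
#' distance: `A[j,l] = (1 - (d[j,l]/tau)^2)^3` when the scaled distance
#' `d/tau` is at most 1, and 0 beyond.  The diagonal is always 1 and the
#' kernel reaches exactly 0 at distance `tau`.
#'
#' @param distances symmetric matrix of non-negative pairwise distances
#'   with zero diagonal (bp or site-index units).
#' @param tau positive bandwidth, in the same units as `distances`.
#' @return symmetric kernel matrix of the same dimension.
#' @examples
#' d <- abs(outer(1:4, 1:4, "-"))
#' triweight_kernel(d, tau = 2)
#' @export
triweight_kernel <- function(distances, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  d <- as.matrix(distances)
  if (any(d < 0)) stop("distances must be non-negative")
  u <- d / tau
  A <- (1 - u^2)^3
  A[u > 1] <- 0
  A
}

#' Kernel quadratic form
#'
#' The kernel distance statistic of a region: `Q = delta' A delta`, where
#' `delta` is the vector of per-site group differences and `A` a kernel
#' matrix.
#'
#' @param delta numeric vector.
#' @param A square kernel matrix, `dim(A) == c(length(delta), length(delta))`.
#' @return the scalar quadratic form.
#' @export
kernel_Q <- function(delta, A) {
  A <- as.matrix(A)
  if (length(delta) != nrow(A) || nrow(A) != ncol(A))
    stop("dimension mismatch between delta (", length(delta),
         ") and A (", nrow(A), " x ", ncol(A), ")")
  drop(crossprod(delta, A %*% delta))
}

#' First index attaining the maximum
#'
#' Tie-break rule for the bandwidth search: among bandwidths with equal
#' statistic, the smallest (first) one wins.
#'
#' @param per_tau_Q non-empty numeric vector of statistics, one per
#'   bandwidth.
#' @return integer index (1-based) of the first maximum.
#' @export
tau_argmax_ties <- function(per_tau_Q) {
  if (!length(per_tau_Q)) stop("empty statistic vector")
  which.max(per_tau_Q)  # which.max returns the first maximum
}

#' Default bandwidth grid
#'
#' Ten bandwidths linearly spaced from the smallest adjacent inter-site
#' distance up to half the span of the region, following the usual advice
#' for cluster-detection statistics to scan bandwidths up to about half
#' the region size.
#'
#' @param positions numeric vector of site positions (sorted).
#' @param n number of bandwidths (default 10).
#' @return increasing numeric vector of bandwidths.
#' @export
default_tau_grid <- function(positions, n = 10L) {
  if (length(positions) < 2L) stop("need at least 2 sites for a tau grid")
  lo <- min(diff(sort(positions)))
  hi <- (max(positions) - min(positions)) / 2
  if (hi <= lo) return(lo)
  seq(lo, hi, length.out = n)
}

# Shared permutation machinery: n x (B+1) 0/1 indicator matrix for the
# "case" group; first column is the observed labelling, the rest are
# uniform re-draws of the case set.
perm_case_indicators <- function(case, B) {
  n <- length(case)
  nA <- sum(case)
  if (nA == 0L || nA == n) stop("permutation impossible: one group is empty")
  G <- matrix(0, n, B + 1L)
  G[case, 1L] <- 1
  for (b in seq_len(B)) G[sample.int(n, nA), b + 1L] <- 1
  G
}

#' Kernel distance test for a differentially methylated region
#'
#' Two-group region test.  Per-site group differences `delta` of
#' covariate-adjusted methylation rates are combined in the quadratic
#' form `Q(tau) = delta' A(tau) delta` with a tri-weight kernel `A(tau)`;
#' the observed statistic is the maximum of `Q` over a bandwidth grid.
#' Significance comes from permuting subject group labels: the adjusted
#' counts stay fixed (the adjustment model excludes the group), group
#' sums and `delta` are recomputed for each relabelling, and the add-one
#' permutation p-value `(1 + #{Q_perm >= Q_obs}) / (B + 1)` is reported,
#' counting ties as exceedances.  Per-site percent contributions
#' `U_j / Q` at the selected bandwidth are returned for smoothing plots
#' and region localization.
#'
#' @param data a [methylation_dataset()] with exactly two groups and a
#'   single chromosome.  The first group level is treated as cases.
#' @param covariates covariate columns for [fit_covariate_model()], or
#'   `NULL`.
#' @param tau bandwidth(s).  A single value fixes the bandwidth; a vector
#'   is used as the search grid; `NULL` (default) uses
#'   [default_tau_grid()].
#' @param distance_unit `"bp"` (positions) or `"index"` (site rank).
#' @param permutations number of label permutations `B`.
#' @param seed optional integer seed for the permutation draw.
#' @return object of class `kdm_result`: list with `tau_star`, `Q_star`,
#'   `per_tau_Q`, `contributions` (per retained site), `p_value`,
#'   `delta`, `sites`, `B`.
#' @export
kdm_test <- function(data, covariates = NULL, tau = NULL,
                     distance_unit = c("bp", "index"),
                     permutations = 1000L, seed = NULL) {
  distance_unit <- match.arg(distance_unit)
  B <- as.integer(permutations)
  if (B < 1L) stop("permutations must be >= 1")
  groups <- factor(data$samples$group)
  if (nlevels(groups) != 2L)
    stop("the kernel distance test needs exactly two groups")
  if (length(unique(data$sites$chromosome)) != 1L)
    stop("analyze one chromosome (or region) at a time")
  if (n_sites(data) < 2L) stop("need at least 2 sites")

  adj <- fit_covariate_model(data, covariates)

  # drop sites with zero coverage in either group (test undefined there)
  C_by_group <- rowsum(data$coverage + 0, groups)
  keep <- which(colSums(C_by_group == 0) == 0)
  if (length(keep) < 2L) stop("fewer than 2 sites with coverage in both groups")
  if (length(keep) < n_sites(data))
    message(n_sites(data) - length(keep),
            " site(s) excluded: zero coverage in at least one group")

  pos <- if (distance_unit == "bp") data$sites$position[keep] else
    seq_along(keep)
  dmat <- abs(outer(pos, pos, "-"))
  tau_grid <- if (is.null(tau)) default_tau_grid(pos) else sort(as.numeric(tau))
  if (any(tau_grid <= 0)) stop("tau must be positive")
  if (any(duplicated(tau_grid))) stop("tau grid values must be distinct")

  rmat <- adj$r[, keep, drop = FALSE]
  cmat <- data$coverage[, keep, drop = FALSE]

  if (!is.null(seed)) set.seed(seed)
  G <- perm_case_indicators(groups == levels(groups)[1L], B)

  RA <- crossprod(rmat, G)                       # sites x (B+1)
  CA <- crossprod(cmat, G)
  RU <- colSums(rmat) - RA
  CU <- colSums(cmat) - CA
  delta <- RA / CA - RU / CU
  delta[!is.finite(delta)] <- 0  # permuted group without coverage at a site

  kernels <- lapply(tau_grid, function(t) triweight_kernel(dmat, t))
  Q_by_tau <- vapply(kernels, function(A) colSums(delta * (A %*% delta)),
                     numeric(ncol(delta)))            # (B+1) x n_tau
  Q_by_tau <- matrix(Q_by_tau, ncol = length(tau_grid))
  Q_max <- apply(Q_by_tau, 1L, max)

  obs_per_tau <- Q_by_tau[1L, ]
  i_star <- tau_argmax_ties(obs_per_tau)
  Q_star <- obs_per_tau[i_star]
  p_value <- (1 + sum(Q_max[-1L] >= Q_max[1L])) / (B + 1)

  d_obs <- delta[, 1L]
  U <- d_obs * drop(kernels[[i_star]] %*% d_obs)
  contributions <- if (Q_star != 0) U / Q_star else rep(NA_real_, length(U))

  structure(
    list(tau_star = tau_grid[i_star],
         Q_star = Q_star,
         per_tau_Q = stats::setNames(obs_per_tau, tau_grid),
         contributions = contributions,
         p_value = p_value,
         delta = d_obs,
         sites = data$sites[keep, , drop = FALSE],
         distance_unit = distance_unit,
         B = B),
    class = "kdm_result"
  )
}

#' @export
print.kdm_result <- function(x, ...) {
  cat("Kernel distance test (", nrow(x$sites), " sites)\n", sep = "")
  cat(sprintf("  Q* = %.6g at tau* = %g (%s units)\n",
              x$Q_star, x$tau_star, x$distance_unit))
  cat(sprintf("  permutation p-value = %.4g (B = %d)\n", x$p_value, x$B))
  invisible(x)
}

#' Call DMRs from test results
#'
#' Generic region-calling step.  For a scan result, windows with p-value
#' at or below `alpha` are selected greedily by descending likelihood
#' ratio, discarding windows that overlap an already selected one.  For a
#' kernel distance result, the contiguous run of sites around the peak
#' whose percent contribution exceeds the `quantile` of all contributions
#' is reported (only when the global p-value passes `alpha`).
#'
#' @param result a `kdm_result` or `ssm_result`.
#' @param alpha significance threshold.
#' @param ... further arguments passed to methods.
#' @return a [dmr_calls()] table (possibly empty).
#' @export
call_dmrs <- function(result, alpha = 0.05, ...) UseMethod("call_dmrs")

#' @rdname call_dmrs
#' @param quantile contribution quantile defining the peak run (KDM only).
#' @export
call_dmrs.kdm_result <- function(result, alpha = 0.05, quantile = 0.95, ...) {
  if (result$p_value > alpha || all(is.na(result$contributions)))
    return(dmr_calls())
  thr <- stats::quantile(result$contributions, quantile, na.rm = TRUE)
  hot <- result$contributions >= thr
  peak <- which.max(result$contributions)
  lo <- peak; while (lo > 1L && hot[lo - 1L]) lo <- lo - 1L
  hi <- peak; while (hi < length(hot) && hot[hi + 1L]) hi <- hi + 1L
  dmr_calls(
    chromosome = result$sites$chromosome[lo],
    start_bp = result$sites$position[lo],
    end_bp = result$sites$position[hi],
    n_sites = hi - lo + 1L,
    statistic = result$Q_star,
    p_value = result$p_value,
    method = "KDM"
  )
}
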