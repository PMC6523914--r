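#' Binomial window log-likelihood ratio
#'
#' Log-likelihood ratio comparing separate binomial methylation rates in
#' two groups against one shared rate, for the summed (design-effect
#' adjusted, pseudo-counted) counts of a window:
#' `LR = l(pA_hat, pU_hat) - l(p_pool)` with `pA_hat = rA/CA`,
#' `pU_hat = rU/CU` and `p_pool = (rA+rU)/(CA+CU)`.  Counts may be
#' real-valued (the design-effect adjustment rescales them).  `LR >= 0`
#' always, with equality exactly when the two group proportions coincide;
#' `2 * LR` is the G-squared deviance of the corresponding 2x2 table.
#'
#' All arguments are vectorized.
#'
#' @param rA,CA methylated count and coverage sum for the case group.
#' @param rU,CU methylated count and coverage sum for the control group.
#' @return numeric log-likelihood ratio (natural log).
#' @examples
#' window_lr(8, 10, 2, 10)   # 3.8549
#' window_lr(5, 10, 50, 100) # 0: equal proportions
#' @export
window_lr <- function(rA, CA, rU, CU) {
  if (any(rA <= 0 | rA >= CA | rU <= 0 | rU >= CU))
    stop("degenerate proportions: apply pseudo-counts before the likelihood ratio")
  pA <- rA / CA
  pU <- rU / CU
  pp <- (rA + rU) / (CA + CU)
  rA * log(pA) + (CA - rA) * log1p(-pA) +
    rU * log(pU) + (CU - rU) * log1p(-pU) -
    ((rA + rU) * log(pp) + (CA + CU - rA - rU) * log1p(-pp))
}

#' Add pseudo-counts to design-effect adjusted counts
#'
#' Adds one pseudo-read to the methylated and one to the unmethylated
#' count of every group at every CpG site (`r -> r + 1`, `C -> C + 2`),
#' pulling proportions off the 0/1 boundary so the window likelihood
#' ratio is always defined.  The implicit assumption of the added reads
#' is no differential methylation, i.e. the null.
#'
#' @param dec a `design_effect_counts` object (see
#'   [design_effect_adjust()]).
#' @return the same object with shifted counts.
#' @export
apply_pseudocounts <- function(dec) {
  stopifnot(inherits(dec, "design_effect_counts"))
  dec$r_tilde <- dec$r_tilde + 1
  dec$C_tilde <- dec$C_tilde + 2
  dec
}

# Window sums over w consecutive sites (step `step`) of each column of x.
window_sums <- function(x, w, step = 1L) {
  m <- nrow(x)
  cs <- apply(x, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = m)
  upper <- cs[seq.int(w, m), , drop = FALSE]
  lower <- rbind(0, cs[seq_len(m - w), , drop = FALSE])
  out <- upper - lower
  starts <- seq.int(1L, m - w + 1L, by = step)
  out[starts, , drop = FALSE]
}

# Window sums of one vector.
window_sums_vec <- function(v, w, step = 1L) {
  window_sums(matrix(v, ncol = 1L), w, step)[, 1L]
}

#' Per-window scan statistics from design-effect counts
#'
#' Deterministic part of the scan: for every window size and start
#' offset, sums the (pseudo-counted) adjusted counts over the window per
#' group and evaluates the multinomial/binomial log-likelihood ratio.
#' With two groups this is [window_lr()] applied to each window.
#'
#' @param dec a `design_effect_counts` object, after
#'   [apply_pseudocounts()].
#' @param window_sizes integer vector of window sizes in number of CpG
#'   sites.
#' @param step start-offset step in sites (default 1).
#' @return data.frame with columns `size`, `start_index`, `end_index`,
#'   `lr`, ordered by size then start.
#' @export
scan_windows <- function(dec, window_sizes, step = 1L) {
  stopifnot(inherits(dec, "design_effect_counts"))
  m <- ncol(dec$r_tilde)
  out <- list()
  for (w in sort(unique(as.integer(window_sizes)))) {
    if (w > m) {
      warning("window size ", w, " exceeds region length ", m, "; skipped")
      next
    }
    starts <- seq.int(1L, m - w + 1L, by = step)
    rw <- window_sums(t(dec$r_tilde), w, step)   # windows x groups
    cw <- window_sums(t(dec$C_tilde), w, step)
    lr <- multinomial_window_lr(rw, cw)
    out[[length(out) + 1L]] <- data.frame(
      size = w, start_index = starts, end_index = starts + w - 1L, lr = lr)
  }
  if (!length(out)) stop("no window size fits the region")
  do.call(rbind, out)
}

# Multinomial generalization of the window LR: rows of rw / cw are windows,
# columns are groups.  Reduces to window_lr for two groups.
multinomial_window_lr <- function(rw, cw) {
  if (any(rw <= 0 | rw >= cw))
    stop("degenerate proportions: apply pseudo-counts before the likelihood ratio")
  pk <- rw / cw
  h1 <- rowSums(rw * log(pk) + (cw - rw) * log1p(-pk))
  r <- rowSums(rw); C <- rowSums(cw)
  pp <- r / C
  h1 - (r * log(pp) + (C - r) * log1p(-pp))
}

# Core permutation engine shared by ssm_scan and multinomial_scan.
# Z: samples x sites recentred residual count matrix; rho: per-site ICC.
# Returns observed per-window LRs (all sizes), permuted global maxima, and
# the observed global maximum.
scan_engine <- function(Z, coverage, groups, rho, window_sizes, step,
                        B, deff_floor, design_effect) {
  n <- nrow(Z)
  m <- ncol(Z)
  lev <- levels(groups)
  window_sizes <- sort(unique(as.integer(window_sizes)))
  fit_sizes <- window_sizes[window_sizes <= m]
  for (w in setdiff(window_sizes, fit_sizes))
    warning("window size ", w, " exceeds region length ", m, "; skipped")
  if (!length(fit_sizes)) stop("no window size fits the region")

  # label matrix: column 1 observed, then B permutations of the labels
  lab <- matrix(0L, n, B + 1L)
  gi <- as.integer(groups)
  lab[, 1L] <- gi
  for (b in seq_len(B)) lab[, b + 1L] <- gi[sample.int(n)]

  ztot <- colSums(Z)
  ctot <- colSums(coverage)
  per_group <- vector("list", length(lev))
  for (k in seq_along(lev)) {
    Ik <- (lab == k) + 0
    nk <- sum(gi == k)
    Ck <- crossprod(coverage + 0, Ik)              # sites x (B+1)
    Rk <- pmin(pmax(crossprod(Z, Ik), 0), Ck)
    deff <- if (design_effect)
      pmax(1 + (Ck / nk - 1) * rho, deff_floor) else 1
    per_group[[k]] <- list(r = Rk / deff + 1, C = Ck / deff + 2)
  }

  obs <- list()
  gmax <- rep(-Inf, B + 1L)
  for (w in fit_sizes) {
    rw <- lapply(per_group, function(g) window_sums(g$r, w, step))
    cw <- lapply(per_group, function(g) window_sums(g$C, w, step))
    h1 <- 0; rsum <- 0; csum <- 0
    for (k in seq_along(lev)) {
      pk <- rw[[k]] / cw[[k]]
      h1 <- h1 + rw[[k]] * log(pk) + (cw[[k]] - rw[[k]]) * log1p(-pk)
      rsum <- rsum + rw[[k]]
      csum <- csum + cw[[k]]
    }
    pp <- rsum / csum
    LR <- h1 - (rsum * log(pp) + (csum - rsum) * log1p(-pp))
    starts <- seq.int(1L, m - w + 1L, by = step)
    obs[[length(obs) + 1L]] <- data.frame(
      size = w, start_index = starts, end_index = starts + w - 1L,
      lr = LR[, 1L])
    cmax <- apply(LR, 2L, max)
    gmax <- pmax(gmax, cmax)
  }
  list(per_window = do.call(rbind, obs),
       global_obs = gmax[1L],
       perm_max = gmax[-1L])
}

#' Binomial scan statistic test for differentially methylated regions
#'
#' Likelihood-based region test.  Counts are first covariate-adjusted
#' ([mixed_model_adjust()] by default, or the pooled logistic fit), then
#' corrected for read clustering within CpG sites
#' ([design_effect_adjust()]) and stabilized with pseudo-counts
#' ([apply_pseudocounts()]).  For every window of each requested size the
#' binomial log-likelihood ratio of separate vs shared group rates is
#' computed; the global statistic is the maximum over all windows and
#' sizes.  Inference permutes subject group labels, rebuilding group sums
#' and design effects for each relabelling (the per-site clustering
#' correlation is estimated from all samples pooled and is label-free);
#' the global p-value is the add-one permutation estimate, and per-window
#' p-values are computed against the permutation distribution of the
#' global maximum, which controls family-wise error across windows.
#'
#' @param data a [methylation_dataset()] on a single chromosome, two or
#'   more groups (the multinomial generalization of the window statistic
#'   is used automatically for more than two).
#' @param covariates covariate columns for the adjustment model, or
#'   `NULL`.
#' @param window_sizes window sizes in number of CpG sites.
#' @param step window start step in sites.
#' @param permutations number of label permutations `B`.
#' @param seed optional integer seed for the permutation draw.
#' @param adjustment `"mixed"` (exchangeable within-subject correlation,
#'   default) or `"simple"` (pooled logistic fit).
#' @param design_effect apply the clustering design effect (default TRUE).
#' @param deff_floor lower bound of the design effect.
#' @param alpha significance level used by the default [call_dmrs()] step.
#' @return object of class `ssm_result`: list with `per_window`
#'   (data.frame: size, start_index, end_index, start_bp, end_bp, lr,
#'   p_value), `global_lr`, `global_p`, `calls`, `B`.
#' @export
ssm_scan <- function(data, covariates = NULL,
                     window_sizes = c(5L, 10L, 15L, 20L, 25L, 30L),
                     step = 1L, permutations = 1000L, seed = NULL,
                     adjustment = c("mixed", "simple"),
                     design_effect = TRUE, deff_floor = 1,
                     alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  B <- as.integer(permutations)
  if (B < 1L) stop("permutations must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  groups <- factor(data$samples$group)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (length(unique(data$sites$chromosome)) != 1L)
    stop("analyze one chromosome (or region) at a time")

  adj <- if (adjustment == "mixed") mixed_model_adjust(data, covariates)
         else fit_covariate_model(data, covariates)

  C_by_group <- rowsum(data$coverage + 0, groups)
  keep <- which(colSums(C_by_group == 0) == 0)
  if (!length(keep)) stop("no site with coverage in every group")
  if (length(keep) < n_sites(data))
    message(n_sites(data) - length(keep),
            " site(s) excluded: zero coverage in at least one group")

  cov_k <- data$coverage[, keep, drop = FALSE]
  p_bar <- sum(adj$p_hat * data$coverage) / sum(data$coverage)
  Z <- (data$meth - (adj$p_hat - p_bar) * data$coverage)[, keep, drop = FALSE]
  rho <- if (design_effect) site_icc_anova(data$meth[, keep, drop = FALSE],
                                           cov_k) else rep(0, length(keep))

  if (!is.null(seed)) set.seed(seed)
  eng <- scan_engine(Z, cov_k, groups, rho, window_sizes, step,
                     B, deff_floor, design_effect)

  pw <- eng$per_window
  pw$start_bp <- data$sites$position[keep][pw$start_index]
  pw$end_bp <- data$sites$position[keep][pw$end_index]
  pw$p_value <- vapply(pw$lr, function(l)
    (1 + sum(eng$perm_max >= l)) / (B + 1), numeric(1))
  global_p <- (1 + sum(eng$perm_max >= eng$global_obs)) / (B + 1)

  res <- structure(
    list(per_window = pw[, c("size", "start_index", "end_index",
                             "start_bp", "end_bp", "lr", "p_value")],
         global_lr = eng$global_obs,
         global_p = global_p,
         chromosome = unique(data$sites$chromosome),
         n_groups = nlevels(groups),
         B = B,
         alpha = alpha),
    class = "ssm_result"
  )
  res$calls <- call_dmrs(res, alpha = alpha)
  res
}

#' Multinomial scan statistic for two or more groups
#'
#' Generalization of [ssm_scan()] to any number of nominal (unordered)
#' group labels: the window statistic becomes the multinomial
#' log-likelihood ratio of per-group rates vs one pooled rate, which
#' reduces exactly to the binomial [window_lr()] for two groups.  Ordered
#' group labels are not supported (the constrained maximum likelihood
#' estimates have no closed form).
#'
#' @inheritParams ssm_scan
#' @param ordered set TRUE to request an ordered-alternative scan
#'   (unsupported; raises an error).
#' @return an `ssm_result`, as for [ssm_scan()].
#' @export
multinomial_scan <- function(data, covariates = NULL,
                             window_sizes = c(5L, 10L, 15L, 20L, 25L, 30L),
                             step = 1L, permutations = 1000L, seed = NULL,
                             adjustment = c("mixed", "simple"),
                             design_effect = TRUE, deff_floor = 1,
                             alpha = 0.05, ordered = FALSE) {
  if (isTRUE(ordered))
    stop("ordered group responses are not supported by the scan statistic")
  ssm_scan(data, covariates = covariates, window_sizes = window_sizes,
           step = step, permutations = permutations, seed = seed,
           adjustment = match.arg(adjustment),
           design_effect = design_effect, deff_floor = deff_floor,
           alpha = alpha)
}

#' @export
print.ssm_result <- function(x, ...) {
  cat("Binomial scan statistic (", x$n_groups, " groups, ",
      nrow(x$per_window), " windows)\n", sep = "")
  cat(sprintf("  global LR = %.6g, permutation p-value = %.4g (B = %d)\n",
              x$global_lr, x$global_p, x$B))
  cat("  DMR calls at alpha =", x$alpha, ":", nrow(x$calls), "\n")
  invisible(x)
}

#' @rdname call_dmrs
#' @export
call_dmrs.ssm_result <- function(result, alpha = 0.05, ...) {
  pw <- result$per_window
  cand <- pw[pw$p_value <= alpha, , drop = FALSE]
  if (!nrow(cand)) return(dmr_calls())
  cand <- cand[order(-cand$lr, cand$start_index, cand$size), , drop = FALSE]
  chosen <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    w <- cand[i, ]
    overlaps <- nrow(chosen) > 0 &&
      any(w$start_index <= chosen$end_index & w$end_index >= chosen$start_index)
    if (!overlaps) chosen <- rbind(chosen, w)
  }
  chosen <- chosen[order(chosen$start_index), , drop = FALSE]
  dmr_calls(
    chromosome = rep(result$chromosome, nrow(chosen)),
    start_bp = chosen$start_bp,
    end_bp = chosen$end_bp,
    n_sites = chosen$size,
    statistic = chosen$lr,
    p_value = chosen$p_value,
    method = rep("SSM", nrow(chosen))
  )
}
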