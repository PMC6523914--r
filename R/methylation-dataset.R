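#' Construct a methylation count dataset
#'
#' The central container for per-sample, per-CpG-site bisulfite sequencing
#' counts.  Rows of the count matrices are samples, columns are CpG sites.
#' Sites must be sorted by (chromosome, position) with strictly increasing
#' positions within a chromosome, and methylated counts can never exceed
#' coverage.
#'
#' @param sites data.frame with columns `chromosome` (character) and
#'   `position` (integer, 1-based bp).
#' @param samples data.frame with columns `sample_id` (character) and
#'   `group` (factor or character, e.g. case/control labels); any further
#'   columns are treated as sample-level covariates.
#' @param meth integer matrix of methylated read counts, samples x sites.
#' @param coverage integer matrix of total read counts (methylated +
#'   unmethylated), samples x sites.
#'
#' @return An object of class `methylation_dataset`: a list with elements
#'   `sites`, `samples`, `meth`, `coverage`.
#' @examples
#' sites <- data.frame(chromosome = "chr1", position = c(100L, 200L))
#' samples <- data.frame(sample_id = c("s1", "s2"), group = c("A", "U"))
#' meth <- matrix(c(3L, 1L, 5L, 0L), 2, 2)
#' cov  <- matrix(10L, 2, 2)
#' methylation_dataset(sites, samples, meth, cov)
#' @export
methylation_dataset <- function(sites, samples, meth, coverage) {
  meth <- as.matrix(meth)
  coverage <- as.matrix(coverage)
  storage.mode(meth) <- "integer"
  storage.mode(coverage) <- "integer"
  x <- structure(
    list(
      sites = as.data.frame(sites),
      samples = as.data.frame(samples),
      meth = meth,
      coverage = coverage
    ),
    class = "methylation_dataset"
  )
  validate_methylation_dataset(x)
  x
}

#' Validate a methylation dataset
#'
#' Checks the structural invariants of a [methylation_dataset()]:
#' count bounds (0 <= meth <= coverage), matrix dimensions, site ordering
#' and group labels.  Called by the constructor; exported so readers and
#' simulators can re-check after manipulation.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_methylation_dataset <- function(x) {
  stopifnot(inherits(x, "methylation_dataset"))
  sites <- x$sites
  samples <- x$samples
  if (!all(c("chromosome", "position") %in% names(sites)))
    stop("`sites` must have columns 'chromosome' and 'position'")
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("`samples` must have columns 'sample_id' and 'group'")
  n <- nrow(samples)
  m <- nrow(sites)
  if (!identical(dim(x$meth), c(n, m)) || !identical(dim(x$coverage), c(n, m)))
    stop("count matrices must be samples x sites (", n, " x ", m, ")")
  if (anyNA(x$meth) || anyNA(x$coverage))
    stop("count matrices must not contain NA")
  if (any(x$coverage < 0L))
    stop("coverage must be non-negative")
  if (any(x$meth < 0L) || any(x$meth > x$coverage))
    stop("methylated counts must satisfy 0 <= meth <= coverage")
  if (anyNA(samples$group) || any(samples$group == ""))
    stop("every sample needs a group label")
  ord <- order(sites$chromosome, sites$position)
  if (!identical(ord, seq_len(m)))
    stop("sites must be sorted by (chromosome, position)")
  dup <- unlist(lapply(split(sites$position, sites$chromosome),
                       function(p) any(diff(p) <= 0)), use.names = FALSE)
  if (any(dup))
    stop("positions must be strictly increasing within a chromosome")
  invisible(x)
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("methylation_dataset:",
      nrow(x$samples), "samples x", nrow(x$sites), "CpG sites\n")
  cat("  groups:",
      paste(sprintf("%s=%d", names(table(x$samples$group)),
                    table(x$samples$group)), collapse = ", "), "\n")
  cov <- x$coverage[x$coverage > 0]
  if (length(cov))
    cat("  coverage: median", stats::median(cov),
        "range", min(cov), "-", max(cov), "\n")
  covars <- setdiff(names(x$samples), c("sample_id", "group"))
  if (length(covars))
    cat("  covariates:", paste(covars, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$meth)

#' Number of samples / CpG sites in a dataset
#' @param data a [methylation_dataset()].
#' @return integer count.
#' @export
n_samples <- function(data) nrow(data$samples)

#' @rdname n_samples
#' @export
n_sites <- function(data) nrow(data$sites)

#' Subset a methylation dataset by site index
#'
#' @param data a [methylation_dataset()].
#' @param site_idx integer vector of site (column) indices to keep.
#' @return a [methylation_dataset()] restricted to the selected sites.
#' @export
subset_sites <- function(data, site_idx) {
  methylation_dataset(
    data$sites[site_idx, , drop = FALSE],
    data$samples,
    data$meth[, site_idx, drop = FALSE],
    data$coverage[, site_idx, drop = FALSE]
  )
}

#' Build a table of DMR calls
#'
#' A `dmr_calls` object is a data.frame with one row per called region.
#' Coordinates are 1-based inclusive base-pair positions of the first and
#' last CpG site of the region (BED export converts to 0-based half-open).
#'
#' @param chromosome character vector.
#' @param start_bp,end_bp integer vectors, 1-based inclusive.
#' @param n_sites integer vector, number of CpG sites in each region.
#' @param statistic numeric vector, value of the test statistic.
#' @param p_value numeric vector in \[0, 1\].
#' @param method character vector, `"KDM"` or `"SSM"`.
#' @return data.frame of class `dmr_calls`.
#' @export
dmr_calls <- function(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_sites = integer(),
                      statistic = numeric(), p_value = numeric(),
                      method = character()) {
  out <- data.frame(
    chromosome = as.character(chromosome),
    start_bp = as.integer(start_bp),
    end_bp = as.integer(end_bp),
    n_sites = as.integer(n_sites),
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    method = as.character(method),
    stringsAsFactors = FALSE
  )
  if (nrow(out)) {
    if (any(out$start_bp > out$end_bp)) stop("start_bp must be <= end_bp")
    if (any(out$n_sites < 1L)) stop("n_sites must be >= 1")
    if (any(out$p_value < 0 | out$p_value > 1)) stop("p_value must be in [0, 1]")
    if (!all(out$method %in% c("KDM", "SSM"))) stop("method must be KDM or SSM")
  }
  class(out) <- c("dmr_calls", "data.frame")
  out
}
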