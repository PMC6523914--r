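#' Read a sample sheet
#'
#' The sample sheet is a TSV with mandatory columns `sample_id`, `path`
#' and `group`; any further columns are carried along as sample-level
#' covariates.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  for (col in c("sample_id", "path", "group")) {
    if (!col %in% names(sheet))
      stop("sample sheet is missing required column '", col, "'")
  }
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  sheet
}

# Parse one bismark-coverage file: chrom, start, end, %meth, n_meth, n_unmeth.
# The percent-methylation column is recomputed from the counts and only used
# as a consistency check.
read_one_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  tab <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1),
                      showProgress = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(tab) != 6L)
    stop("malformed coverage file ", path, ": expected 6 columns, found ",
         ncol(tab))
  data.table::setnames(tab, c("chromosome", "start", "end", "pct_meth",
                              "n_meth", "n_unmeth"))
  for (col in c("start", "end", "n_meth", "n_unmeth")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("malformed coverage file ", path, ": line ", bad[1],
           ", column '", col, "' is not a non-negative integer")
    tab[[col]] <- as.integer(v)
  }
  tab
}

#' Read bismark-style coverage files into a methylation dataset
#'
#' Each input file is a 6-column TSV in bismark coverage format
#' (chromosome, start, end, percent methylation, methylated count,
#' unmethylated count); coverage is reconstructed as methylated +
#' unmethylated and the percent column is ignored for computation.
#' Positions are taken from the `start` column and treated as 1-based.
#'
#' By default the returned dataset is restricted to the intersection of
#' sites observed in every sample, because both region tests need a value
#' for each sample at each site.  `merge = "union"` keeps all sites and
#' fills missing ones with zero coverage.
#'
#' @param sample_sheet data.frame as returned by [read_sample_sheet()]
#'   (columns `sample_id`, `path`, `group`, plus covariates), or a path to
#'   such a TSV.
#' @param paths optional character vector overriding `sample_sheet$path`,
#'   in sample-sheet row order.
#' @param merge `"intersection"` (default) or `"union"`.
#' @return a [methylation_dataset()].
#' @export
read_coverage_files <- function(sample_sheet, paths = NULL,
                                merge = c("intersection", "union")) {
  merge <- match.arg(merge)
  if (is.character(sample_sheet) && length(sample_sheet) == 1L)
    sample_sheet <- read_sample_sheet(sample_sheet)
  sheet <- as.data.frame(sample_sheet)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(sheet))
      stop("sample sheet is missing required column '", col, "'")
  }
  if (is.null(paths)) {
    if (!"path" %in% names(sheet))
      stop("sample sheet is missing required column 'path'")
    paths <- sheet$path
  }
  if (length(paths) != nrow(sheet))
    stop("need one coverage file per sample sheet row")
  missing <- !file.exists(paths)
  if (any(missing))
    stop("no coverage file for sample '", sheet$sample_id[which(missing)[1]],
         "': ", paths[which(missing)[1]])

  tabs <- lapply(paths, read_one_coverage)
  keys <- lapply(tabs, function(t) paste(t$chromosome, t$start, sep = ":"))
  all_keys <- if (merge == "intersection") Reduce(intersect, keys)
              else Reduce(union, keys)
  if (!length(all_keys))
    stop("no CpG site is shared by all samples (intersection is empty)")

  ref <- unique(do.call(rbind, lapply(tabs, function(t)
    data.frame(chromosome = t$chromosome, start = t$start))))
  ref <- ref[paste(ref$chromosome, ref$start, sep = ":") %in% all_keys, ,
             drop = FALSE]
  ref <- ref[order(ref$chromosome, ref$start), , drop = FALSE]
  key_order <- paste(ref$chromosome, ref$start, sep = ":")
  m <- length(key_order)
  n <- nrow(sheet)

  meth <- matrix(0L, n, m)
  cov <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    idx <- match(keys[[i]], key_order)
    keep <- !is.na(idx)
    meth[i, idx[keep]] <- tabs[[i]]$n_meth[keep]
    cov[i, idx[keep]] <- tabs[[i]]$n_meth[keep] + tabs[[i]]$n_unmeth[keep]
  }

  sites <- data.frame(chromosome = ref$chromosome,
                      position = as.integer(ref$start))
  samples <- sheet[, setdiff(names(sheet), "path"), drop = FALSE]
  rownames(samples) <- NULL
  methylation_dataset(sites, samples, meth, cov)
}

#' Write DMR calls to BED and a full-precision TSV
#'
#' Writes a BED6 file (0-based half-open coordinates, name = test method,
#' score = statistic rescaled to 0-1000, strand ".") plus a sidecar TSV
#' `<path minus extension>.tsv` carrying the statistic, number of sites
#' and p-value at full precision.  An empty call set produces an empty BED
#' and a header-only TSV.
#'
#' @param calls a [dmr_calls()] table.
#' @param path output BED path; the sidecar TSV gets the same stem.
#' @return invisibly, the sidecar TSV path.
#' @export
write_dmr_bed <- function(calls, path) {
  stopifnot(inherits(calls, "dmr_calls") || is.data.frame(calls))
  tsv_path <- paste0(sub("\\.bed$", "", path), ".tsv")
  header <- c("chromosome", "start_bp", "end_bp", "n_sites",
              "statistic", "p_value", "method")
  con_ok <- tryCatch({
    file.create(path); TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!con_ok) stop("cannot write to ", path)

  if (nrow(calls) == 0L) {
    writeLines(character(), path)
    writeLines(paste(header, collapse = "\t"), tsv_path)
    return(invisible(tsv_path))
  }
  max_stat <- max(abs(calls$statistic), 0)
  score <- if (max_stat > 0)
    as.integer(round(1000 * abs(calls$statistic) / max_stat)) else 0L
  bed <- data.frame(
    chrom = calls$chromosome,
    start = calls$start_bp - 1L,  # 1-based inclusive -> 0-based half-open
    end = calls$end_bp,
    name = calls$method,
    score = score,
    strand = "."
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)

  lines <- c(
    paste(header, collapse = "\t"),
    sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%s",
            calls$chromosome, calls$start_bp, calls$end_bp, calls$n_sites,
            sprintf("%.17g", calls$statistic),
            sprintf("%.17g", calls$p_value),
            calls$method)
  )
  writeLines(lines, tsv_path)
  invisible(tsv_path)
}

#' Read back a DMR results TSV
#'
#' Inverse of the sidecar written by [write_dmr_bed()]; numeric columns
#' round-trip bit exactly.
#'
#' @param path the `.tsv` written by [write_dmr_bed()].
#' @return a [dmr_calls()] table.
#' @export
read_dmr_table <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = list(
                                           character = c("chromosome", "method"),
                                           integer = c("start_bp", "end_bp", "n_sites"),
                                           numeric = c("statistic", "p_value"))))
  dmr_calls(tab$chromosome, tab$start_bp, tab$end_bp, tab$n_sites,
            tab$statistic, tab$p_value, tab$method)
}
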