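# Fixture builders: everything is generated in code at test time.

toy_dataset <- function(meth, coverage, groups,
                        positions = seq_len(ncol(meth)),
                        chromosome = "chr1", covariates = NULL) {
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(meth))),
    group = groups,
    stringsAsFactors = FALSE
  )
  if (!is.null(covariates)) samples <- cbind(samples, covariates)
  methylation_dataset(
    sites = data.frame(chromosome = chromosome, position = positions),
    samples = samples,
    meth = meth, coverage = coverage
  )
}

# Random binomial dataset with a common rate; two balanced groups.
random_dataset <- function(n = 8, m = 6, p = 0.3, cov_mean = 20, seed = 1) {
  set.seed(seed)
  coverage <- matrix(rpois(n * m, cov_mean) + 1L, n, m)
  meth <- matrix(rbinom(n * m, as.vector(coverage), p), n, m)
  toy_dataset(meth, coverage, rep(c("A", "U"), length.out = n))
}

write_bismark_cov <- function(path, chrom, pos, n_meth, n_unmeth) {
  pct <- ifelse(n_meth + n_unmeth > 0, 100 * n_meth / (n_meth + n_unmeth), 0)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                     chrom, pos, pos, format(pct), n_meth, n_unmeth), path)
  path
}
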