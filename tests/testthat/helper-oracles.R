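# Independent oracle for the Wilson score interval: invert the normal
# score test numerically. The endpoints p solve
#   (phat - p)^2 = z^2 * p * (1 - p) / n
# which we locate with uniroot rather than the closed form under test.
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  g <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # p = phat itself is a degenerate root of g when k = 0 or k = n, so
  # bracket strictly inside (0, phat) and (phat, 1)
  lower <- if (k == 0) 0 else
    uniroot(g, c(1e-15, phat - 1e-10), tol = 1e-14)$root
  upper <- if (k == n) 1 else
    uniroot(g, c(phat + 1e-10, 1 - 1e-15), tol = 1e-14)$root
  c(lower = lower, upper = upper)
}

# Write a small VCF from explicit record strings (for handcrafted edge
# cases such as multi-allelic records).
write_mini_vcf <- function(records, sample_ids, file = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  writeLines(c(header, records), file)
  file
}

# Single-cluster generator configuration used across test files.
single_cluster_config <- function(n, seed = 7, ...) {
  cohort_config(n_per_cluster = c(EUR = n, AFR = 0, SAS = 0, EAS = 0,
                                  Uncategorized = 0),
                seed = seed, ...)
}

# Minimal metadata frame for handcrafted calls.
mini_samples <- function(ids, sex, supercluster = "EUR") {
  data.frame(sample_id = ids, sex = sex, supercluster = supercluster,
             stringsAsFactors = FALSE)
}
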