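#' Genotype QC thresholds
#'
#' Thresholds for per-genotype quality control. All comparisons are
#' strict: a genotype passes only with GQ strictly above `gq_min`, depth
#' strictly above `dp_min`, and (for heterozygotes) allele balance
#' strictly between `ab_low` and `ab_high`. Allele balance is
#' `alt_depth / (ref_depth + alt_depth)`.
#'
#' @param gq_min Minimum genotype quality (phred-like), default 20.
#' @param dp_min Minimum read depth, default 10.
#' @param ab_low,ab_high Exclusive allele-balance bounds for
#'   heterozygotes, defaults 0.25 and 0.75.
#' @return A list of thresholds used by [qc_genotype()].
#' @export
qc_thresholds <- function(gq_min = 20, dp_min = 10,
                          ab_low = 0.25, ab_high = 0.75) {
  stopifnot(gq_min >= 0, dp_min >= 0, ab_low >= 0, ab_high <= 1,
            ab_low < ab_high)
  list(gq_min = gq_min, dp_min = dp_min, ab_low = ab_low, ab_high = ab_high)
}

#' Classify genotype zygosity, sex- and chromosome-aware
#'
#' Maps raw GT strings to zygosity classes. On autosomes (and chromosome
#' X in females): `0/0` is `hom_ref`, `0/1`/`1/0` is `het`, `1/1` is
#' `hom_alt`. For males on chromosome X, both the haploid (`0`, `1`) and
#' diploid (`0/0`, `1/1`) dialects map to `hemi_ref`/`hemi_alt`, and a
#' heterozygous male X call is flagged `anomalous` (a likely
#' pseudoautosomal or calling artifact; it is excluded from censuses and
#' logged rather than raising an error). Unparseable GT strings, missing
#' calls and calls involving a non-target alternate allele are
#' `missing`.
#'
#' @param gt Character vector of GT strings (allele symbols `0` for the
#'   reference and `1` for the target archaic allele; `|` and `/`
#'   separators both accepted).
#' @param chrom Chromosome label(s), `"X"` triggers hemizygous handling.
#' @param sex `"male"` or `"female"`, recycled as needed.
#' @return Character vector with values in `hom_ref`, `het`, `hom_alt`,
#'   `hemi_ref`, `hemi_alt`, `anomalous`, `missing`.
#' @examples
#' classify_zygosity("1", "X", "male")      # hemi_alt
#' classify_zygosity("0/1", "17", "female") # het
#' classify_zygosity("0/1", "X", "male")    # anomalous
#' @export
classify_zygosity <- function(gt, chrom, sex) {
  n <- max(length(gt), length(chrom), length(sex))
  gt <- rep_len(as.character(gt), n)
  chrom <- rep_len(as.character(chrom), n)
  sex <- rep_len(as.character(sex), n)
  g <- gsub("|", "/", gt, fixed = TRUE)
  male_x <- chrom == "X" & sex == "male"

  out <- rep("missing", n)
  dip_ref <- g == "0/0"
  dip_het <- g %in% c("0/1", "1/0")
  dip_alt <- g == "1/1"
  hap_ref <- g == "0"
  hap_alt <- g == "1"

  out[dip_ref & !male_x] <- "hom_ref"
  out[dip_het & !male_x] <- "het"
  out[dip_alt & !male_x] <- "hom_alt"
  out[(dip_ref | hap_ref) & male_x] <- "hemi_ref"
  out[(dip_alt | hap_alt) & male_x] <- "hemi_alt"
  out[dip_het & male_x] <- "anomalous"
  # haploid calls outside male chromosome X are unexpected -> missing
  out
}

#' Apply per-genotype quality control
#'
#' Evaluates the genotype QC rules on a table of calls and records, for
#' each call, whether it passes and the first failing rule in the fixed
#' order `site_filter` -> `low_gq` -> `low_dp` -> `allele_balance`. A
#' call with a missing genotype or missing required FORMAT fields fails
#' with reason `missing`. The allele-balance rule applies only to
#' heterozygotes with a positive allele-depth sum.
#'
#' @param calls Data frame with columns `site_filter` (`"PASS"` or a
#'   fail label), `gq`, `dp`, `ad_ref`, `ad_alt`, `zygosity` (see
#'   [classify_zygosity()]).
#' @param thresholds A [qc_thresholds()] list.
#' @return `calls` with logical `qc_pass` and character `qc_fail_reason`
#'   (`none` for passing calls) appended, plus the computed `ab` column
#'   (NA where undefined).
#' @export
qc_genotype <- function(calls, thresholds = qc_thresholds()) {
  assert_columns(calls,
                 c("site_filter", "gq", "dp", "ad_ref", "ad_alt", "zygosity"),
                 "`calls`")
  n <- nrow(calls)
  reason <- rep("none", n)
  het <- calls$zygosity == "het"
  ad_sum <- calls$ad_ref + calls$ad_alt
  ab <- ifelse(het & !is.na(ad_sum) & ad_sum > 0, calls$ad_alt / ad_sum, NA_real_)

  filter_fail <- is.na(calls$site_filter) | calls$site_filter != "PASS"
  field_missing <- calls$zygosity == "missing" | is.na(calls$gq) | is.na(calls$dp) |
    (het & (is.na(calls$ad_ref) | is.na(calls$ad_alt)))
  gq_fail <- !is.na(calls$gq) & calls$gq <= thresholds$gq_min
  dp_fail <- !is.na(calls$dp) & calls$dp <= thresholds$dp_min
  ab_fail <- het & !is.na(ab) & (ab <= thresholds$ab_low | ab >= thresholds$ab_high)

  reason[ab_fail] <- "allele_balance"
  reason[dp_fail] <- "low_dp"
  reason[gq_fail] <- "low_gq"
  reason[field_missing] <- "missing"
  reason[filter_fail] <- "site_filter"

  calls$ab <- ab
  calls$qc_pass <- reason == "none"
  calls$qc_fail_reason <- reason
  calls
}

CENSUS_CLASSES <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt")

# Assign each call to exactly one census bucket so that bucket counts sum
# to the number of queried samples.
census_bucket <- function(zygosity, qc_pass, qc_fail_reason) {
  out <- zygosity
  out[qc_fail_reason == "missing"] <- "missing"
  out[!qc_pass & qc_fail_reason != "missing"] <- "qc_failed"
  out[qc_pass & zygosity == "anomalous"] <- "anomalous"
  out
}

#' Discover archaic-allele carriers from a VCF
#'
#' Queries each catalog site in a VCF, applies genotype QC
#' ([qc_genotype()]) and sex-aware zygosity classification
#' ([classify_zygosity()]), and tabulates a per-site, per-supercluster
#' genotype census. A carrier is any QC-passing genotype with at least
#' one archaic allele (`het`, `hom_alt`, or `hemi_alt`). Per-site
#' denominators reflect per-site QC attrition and may differ across
#' sites. Catalog sites absent from the VCF (or with a mismatching
#' reference allele) are reported as unqueryable, never silently
#' skipped. At multi-allelic records only the configured archaic allele
#' is considered; genotypes involving another alternate allele are
#' treated as missing.
#'
#' @param vcf Path to a VCF v4.2 file (plain or gzipped).
#' @param catalog An `asnv_catalog` data frame ([load_catalog()]).
#' @param samples Data frame of samples passing sample-level QC, with
#'   columns `sample_id`, `sex`, `supercluster`.
#' @param thresholds [qc_thresholds()] for genotype QC.
#' @return An object of class `asnv_discovery`: a list with
#'   * `carriers`: one row per carrier x site (`sample_id`, `gene`,
#'     `chrom`, `pos`, `zygosity`, `supercluster`, `sex`);
#'   * `census`: per site x supercluster counts of the five zygosity
#'     classes plus `anomalous`, `qc_failed`, `missing`, `n_queried`;
#'   * `unqueryable`: catalog sites that could not be queried, with a
#'     reason;
#'   * `anomalous`: log of excluded anomalous male-X heterozygote calls;
#'   * `n_unique_carriers`, `n_carrier_instances`.
#' @export
discover_carriers <- function(vcf, catalog, samples,
                              thresholds = qc_thresholds()) {
  catalog <- validate_catalog(as.data.frame(catalog))
  assert_columns(samples, c("sample_id", "sex", "supercluster"), "`samples`")
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {  # single-record VCFs drop to a named vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  fix$CHROM <- sub("^chr", "", fix$CHROM)
  vkey <- site_key(fix$CHROM, as.integer(fix$POS))

  gt_mat <- vcfR::extract.gt(v, element = "GT")
  gq_mat <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dp_mat <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad_mat <- vcfR::extract.gt(v, element = "AD")

  vcf_samples <- colnames(gt_mat)
  missing_samples <- setdiff(samples$sample_id, vcf_samples)
  if (length(missing_samples)) {
    stopf("%d sample(s) in the metadata are absent from the VCF (first: %s)",
          length(missing_samples), missing_samples[1])
  }
  sid <- samples$sample_id
  sex <- samples$sex
  cluster <- factor(samples$supercluster, levels = SUPERCLUSTERS)

  carriers <- list()
  census <- list()
  unqueryable <- list()
  anomalous <- list()

  for (i in seq_len(nrow(catalog))) {
    ck <- site_key(catalog$chrom[i], catalog$pos[i])
    r <- which(vkey == ck)
    if (!length(r)) {
      unqueryable[[length(unqueryable) + 1]] <-
        data.frame(gene = catalog$gene[i], chrom = catalog$chrom[i],
                   pos = catalog$pos[i], reason = "absent_from_vcf",
                   stringsAsFactors = FALSE)
      next
    }
    r <- r[1]
    if (fix$REF[r] != catalog$ref[i]) {
      unqueryable[[length(unqueryable) + 1]] <-
        data.frame(gene = catalog$gene[i], chrom = catalog$chrom[i],
                   pos = catalog$pos[i], reason = "ref_mismatch",
                   stringsAsFactors = FALSE)
      next
    }
    alts <- strsplit(ifelse(is.na(fix$ALT[r]), ".", fix$ALT[r]), ",",
                     fixed = TRUE)[[1]]
    ai <- match(catalog$archaic[i], alts)  # NA when the archaic allele is absent

    gt_raw <- gt_mat[r, sid]
    # Recode allele indices: target archaic allele -> "1", other alternate
    # alleles -> "X" (renders the genotype missing for this analysis).
    gt <- ifelse(is.na(gt_raw), ".", gt_raw)
    if (is.na(ai)) {
      gt <- gsub("[1-9][0-9]*", "X", gt)
    } else if (ai != 1) {
      sep <- ifelse(grepl("|", gt, fixed = TRUE), "|", "/")
      parts <- strsplit(gt, "[/|]")
      gt <- vapply(seq_along(parts), function(j) {
        p <- parts[[j]]
        p <- ifelse(p == "0", "0",
                    ifelse(p == as.character(ai), "1",
                           ifelse(p == ".", ".", "X")))
        paste(p, collapse = sep[j])
      }, character(1))
    }

    zyg <- classify_zygosity(gt, catalog$chrom[i], sex)

    ad <- ad_mat[r, sid]
    ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
    ad_ref <- vapply(ad_split, function(x)
      if (length(x) >= 1) suppressWarnings(as.numeric(x[1])) else NA_real_,
      numeric(1))
    ad_alt <- if (is.na(ai)) rep(0, length(sid)) else vapply(ad_split, function(x)
      if (length(x) >= ai + 1) suppressWarnings(as.numeric(x[ai + 1])) else NA_real_,
      numeric(1))

    flt <- fix$FILTER[r]
    calls <- data.frame(
      sample_id = sid, sex = sex, supercluster = as.character(cluster),
      site_filter = ifelse(is.na(flt) | flt == ".", "no_filter", flt),
      gq = gq_mat[r, sid], dp = dp_mat[r, sid],
      ad_ref = ad_ref, ad_alt = ad_alt, zygosity = zyg,
      stringsAsFactors = FALSE
    )
    calls <- qc_genotype(calls, thresholds)
    bucket <- census_bucket(calls$zygosity, calls$qc_pass, calls$qc_fail_reason)

    is_carrier <- bucket %in% c("het", "hom_alt", "hemi_alt")
    if (any(is_carrier)) {
      cr <- calls[is_carrier, c("sample_id", "supercluster", "sex", "zygosity")]
      cr$gene <- catalog$gene[i]
      cr$chrom <- catalog$chrom[i]
      cr$pos <- catalog$pos[i]
      carriers[[length(carriers) + 1]] <-
        cr[, c("sample_id", "gene", "chrom", "pos", "zygosity",
               "supercluster", "sex")]
    }
    if (any(bucket == "anomalous")) {
      anomalous[[length(anomalous) + 1]] <-
        data.frame(sample_id = calls$sample_id[bucket == "anomalous"],
                   gene = catalog$gene[i], chrom = catalog$chrom[i],
                   pos = catalog$pos[i], stringsAsFactors = FALSE)
    }

    bucket_f <- factor(bucket, levels = c(CENSUS_CLASSES, "anomalous",
                                          "qc_failed", "missing"))
    tab <- table(cluster, bucket_f)
    cen <- as.data.frame.matrix(tab)
    cen <- cbind(data.frame(gene = catalog$gene[i], chrom = catalog$chrom[i],
                            pos = catalog$pos[i],
                            supercluster = rownames(cen),
                            stringsAsFactors = FALSE),
                 cen)
    cen$n_queried <- as.integer(rowSums(tab))
    rownames(cen) <- NULL
    census[[length(census) + 1]] <- cen
  }

  carriers <- if (length(carriers)) do.call(rbind, carriers) else
    data.frame(sample_id = character(), gene = character(), chrom = character(),
               pos = integer(), zygosity = character(),
               supercluster = character(), sex = character(),
               stringsAsFactors = FALSE)
  rownames(carriers) <- NULL
  out <- list(
    carriers = carriers,
    census = if (length(census)) do.call(rbind, census) else NULL,
    unqueryable = if (length(unqueryable)) do.call(rbind, unqueryable) else
      data.frame(gene = character(), chrom = character(), pos = integer(),
                 reason = character(), stringsAsFactors = FALSE),
    anomalous = if (length(anomalous)) do.call(rbind, anomalous) else
      data.frame(sample_id = character(), gene = character(),
                 chrom = character(), pos = integer(), stringsAsFactors = FALSE),
    n_unique_carriers = length(unique(carriers$sample_id)),
    n_carrier_instances = nrow(carriers)
  )
  class(out) <- "asnv_discovery"
  out
}

#' @export
print.asnv_discovery <- function(x, ...) {
  cat(sprintf("aSNV discovery: %d unique carrier(s), %d carrier instance(s) at %d queryable site(s)\n",
              x$n_unique_carriers, x$n_carrier_instances,
              if (is.null(x$census)) 0L else length(unique(site_key(x$census$chrom, x$census$pos)))))
  if (nrow(x$unqueryable)) {
    cat(sprintf("  unqueryable sites: %d (%s)\n", nrow(x$unqueryable),
                paste(site_key(x$unqueryable$chrom, x$unqueryable$pos),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Find samples carrying more than one aSNV
#'
#' Groups the per-sample carrier list by individual and reports every
#' sample carrying archaic alleles at more than one catalog site, with
#' the sorted set of carried sites and the genes involved (a sample
#' carrying sites in two genes is reported once, with both genes
#' listed).
#'
#' @param carriers Either an `asnv_discovery` object or its `carriers`
#'   data frame.
#' @return Data frame with one row per multi-carrier: `sample_id`,
#'   `n_sites`, `sites` (comma-separated `chrom:pos`, sorted), `genes`
#'   (comma-separated distinct genes). Empty when no sample carries more
#'   than one aSNV.
#' @export
find_cocarriage <- function(carriers) {
  if (inherits(carriers, "asnv_discovery")) carriers <- carriers$carriers
  empty <- data.frame(sample_id = character(), n_sites = integer(),
                      sites = character(), genes = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(carriers)) return(empty)
  split_list <- split(carriers, carriers$sample_id)
  rows <- lapply(split_list, function(d) {
    if (nrow(d) < 2) return(NULL)
    o <- order(d$chrom, d$pos)
    d <- d[o, ]
    data.frame(sample_id = d$sample_id[1], n_sites = nrow(d),
               sites = paste(site_key(d$chrom, d$pos), collapse = ","),
               genes = paste(unique(d$gene), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
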