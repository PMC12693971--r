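PLANT_CLASSES <- c("het", "hom_alt", "hemi_alt")

#' Specify genotype classes to plant
#'
#' Builds a plant specification row: at one catalog site, plant `count`
#' genotypes of the given carrier class in one stratum (supercluster x
#' sex). Background genotypes are homozygous reference (hemizygous
#' reference for males on chromosome X), so only carrier classes are
#' planted. Rows sharing a `share_group` within the same stratum are
#' realized in the same individuals across sites, which is how
#' co-carriage (tightly linked alleles inherited together) is planted;
#' rows without a share group get distinct, previously unused
#' individuals.
#'
#' @param chrom,pos Site coordinates (must appear in the catalog passed
#'   to [generate_genotypes()]).
#' @param supercluster Stratum supercluster label.
#' @param class One of `het`, `hom_alt`, `hemi_alt`.
#' @param count Number of genotypes to plant.
#' @param sex Stratum sex; defaults to `"female"` for diploid classes on
#'   chromosome X, `"male"` for hemizygous classes, `NA` (either sex)
#'   on autosomes.
#' @param share_group Optional co-carriage group label.
#' @return One-row data frame; `rbind` rows to form a full PlantSpec.
#' @export
plant <- function(chrom, pos, supercluster, class, count, sex = NA,
                  share_group = NA) {
  stopifnot(class %in% PLANT_CLASSES, count >= 0)
  if (is.na(sex)) {
    sex <- if (chrom == "X") {
      if (class == "hemi_alt") "male" else "female"
    } else NA_character_
  }
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             supercluster = supercluster, sex = sex, class = class,
             count = as.integer(count), share_group = share_group,
             stringsAsFactors = FALSE)
}

# Convert a per-site, per-supercluster allele-frequency table into a
# PlantSpec by drawing genotype classes under Hardy-Weinberg proportions.
plant_from_frequencies <- function(freqs, samples) {
  assert_columns(freqs, c("chrom", "pos", "supercluster", "freq"), "`freqs`")
  if (any(freqs$freq < 0 | freqs$freq > 1)) stopf("frequencies must lie in [0, 1]")
  rows <- list()
  for (i in seq_len(nrow(freqs))) {
    f <- freqs$freq[i]
    cl <- freqs$supercluster[i]
    x_site <- freqs$chrom[i] == "X"
    in_cl <- samples$supercluster == cl
    if (x_site) {
      n_f <- sum(in_cl & samples$sex == "female")
      n_m <- sum(in_cl & samples$sex == "male")
      het <- rbinom(1, n_f, 2 * f * (1 - f))
      hom <- rbinom(1, n_f - het, f^2)
      hemi <- rbinom(1, n_m, f)
      rows[[length(rows) + 1]] <- rbind(
        plant(freqs$chrom[i], freqs$pos[i], cl, "het", het, sex = "female"),
        plant(freqs$chrom[i], freqs$pos[i], cl, "hom_alt", hom, sex = "female"),
        plant(freqs$chrom[i], freqs$pos[i], cl, "hemi_alt", hemi, sex = "male"))
    } else {
      n <- sum(in_cl)
      het <- rbinom(1, n, 2 * f * (1 - f))
      hom <- rbinom(1, n - het, f^2)
      rows[[length(rows) + 1]] <- rbind(
        plant(freqs$chrom[i], freqs$pos[i], cl, "het", het),
        plant(freqs$chrom[i], freqs$pos[i], cl, "hom_alt", hom))
    }
  }
  out <- do.call(rbind, rows)
  out[out$count > 0, , drop = FALSE]
}

# Quality fields for a passing genotype of each class.
passing_fields <- function(class, n) {
  gq <- sample(30:99, n, replace = TRUE)
  dp <- sample(20:60, n, replace = TRUE)
  ad_alt <- switch(class,
                   het = round(dp * runif(n, 0.35, 0.65)),
                   hom_ref = , hemi_ref = rep(0L, n),
                   hom_alt = , hemi_alt = dp)
  list(gq = gq, dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt)
}

#' Generate synthetic genotypes and write a VCF
#'
#' Realizes a plant specification exactly: for each catalog site, the
#' requested carrier genotype classes are assigned to concrete samples
#' of the matching stratum, all other samples get the homozygous (or
#' male-X hemizygous) reference background, and the result is written
#' as a VCF v4.2 file with FORMAT fields `GT:GQ:DP:AD`. QC noise
#' injects genotypes that each violate exactly one genotype-QC filter
#' (low GQ, low DP, or skewed allele balance for heterozygotes) at the
#' stated per-genotype rates, without altering the planted genotype
#' classes. Male chromosome-X genotypes are written in the configured
#' dialect, haploid (`1`) or diploid (`1/1`).
#'
#' @param cohort An `asnv_cohort_data` from [generate_samples()], or a
#'   samples data frame with `sample_id`, `sex`, `supercluster`.
#' @param catalog An `asnv_catalog`: the sites to write.
#' @param plant_spec Data frame of [plant()] rows, a frequency table
#'   with columns `chrom`, `pos`, `supercluster`, `freq`, or `NULL`
#'   (all reference).
#' @param qc_noise List of per-genotype failure rates `low_gq`,
#'   `low_dp`, `skew_ab` (each default 0), and `fail_sites`, a vector
#'   of `chrom:pos` keys whose FILTER column is written as `RF` instead
#'   of `PASS`.
#' @param file Output VCF path.
#' @param male_x_dialect `"haploid"` or `"diploid"` male X encoding.
#' @param male_x_dosage Archaic-allele dosage assigned to hemizygous
#'   male carriers in the returned `dosage` vector: 1 (allele count,
#'   default) or 2 (X-inactivation-style coding).
#' @param seed Integer seed for sample assignment, quality fields and
#'   noise.
#' @return Invisibly, a list with `file`, `truth` (the planted census:
#'   one row per site x supercluster x sex x class actually realized,
#'   before QC noise), `dosage` (named per-sample archaic allele count
#'   with hemizygous males counted 1), and `noise` (per-mode injected
#'   genotype counts).
#' @export
generate_genotypes <- function(cohort, catalog, plant_spec = NULL,
                               qc_noise = list(), file,
                               male_x_dialect = c("haploid", "diploid"),
                               male_x_dosage = 1, seed = 1) {
  male_x_dialect <- match.arg(male_x_dialect)
  stopifnot(male_x_dosage %in% c(1, 2))
  samples <- if (inherits(cohort, "asnv_cohort_data")) cohort$samples else cohort
  assert_columns(samples, c("sample_id", "sex", "supercluster"), "`samples`")
  catalog <- validate_catalog(as.data.frame(catalog))
  o <- order(match(catalog$chrom, VALID_CHROMS), catalog$pos)
  catalog <- catalog[o, , drop = FALSE]
  n <- nrow(samples)
  m <- nrow(catalog)
  noise <- list(low_gq = qc_noise$low_gq %||% 0,
                low_dp = qc_noise$low_dp %||% 0,
                skew_ab = qc_noise$skew_ab %||% 0)
  fail_sites <- qc_noise$fail_sites %||% character()

  with_seed(seed, {
    if (!is.null(plant_spec) && "freq" %in% names(plant_spec)) {
      plant_spec <- plant_from_frequencies(plant_spec, samples)
    }
    if (!is.null(plant_spec) && nrow(plant_spec)) {
      assert_columns(plant_spec,
                     c("chrom", "pos", "supercluster", "sex", "class", "count"),
                     "`plant_spec`")
      if (is.null(plant_spec$share_group)) plant_spec$share_group <- NA
      ck <- site_key(plant_spec$chrom, plant_spec$pos)
      bad <- !ck %in% site_key(catalog$chrom, catalog$pos)
      if (any(bad)) stopf("plant refers to site(s) not in the catalog: %s",
                          paste(unique(ck[bad]), collapse = ", "))
    }

    # class matrix: background first
    zyg <- matrix("hom_ref", n, m)
    is_male <- samples$sex == "male"
    for (j in seq_len(m)) {
      if (catalog$chrom[j] == "X") zyg[is_male, j] <- "hemi_ref"
    }

    used_global <- rep(FALSE, n)   # samples already carrying any planted class
    share_registry <- list()
    truth <- list()
    if (!is.null(plant_spec)) {
      for (i in seq_len(nrow(plant_spec))) {
        p <- plant_spec[i, ]
        if (p$count == 0) next
        j <- which(catalog$chrom == p$chrom & catalog$pos == p$pos)
        stratum <- samples$supercluster == p$supercluster
        if (!is.na(p$sex)) stratum <- stratum & samples$sex == p$sex
        if (catalog$chrom[j] == "X" && is.na(p$sex)) {
          stratum <- stratum &
            (if (p$class == "hemi_alt") is_male else !is_male)
        }
        free_here <- zyg[, j] %in% c("hom_ref", "hemi_ref")
        rkey <- if (!is.na(p$share_group)) {
          paste(p$share_group, p$supercluster, p$sex, sep = "|")
        }
        if (!is.null(rkey) && !is.null(share_registry[[rkey]])) {
          take <- share_registry[[rkey]]
          if (length(take) != p$count) {
            stopf("share group '%s' reused with a different count at %s",
                  p$share_group, site_key(p$chrom, p$pos))
          }
          if (!all(stratum[take] & free_here[take])) {
            stopf("share group '%s' infeasible at %s", p$share_group,
                  site_key(p$chrom, p$pos))
          }
        } else {
          cand <- which(stratum & free_here & !used_global)
          if (length(cand) < p$count) {
            # allow reuse of samples already planted at other sites
            cand <- which(stratum & free_here)
          }
          if (length(cand) < p$count) {
            stopf("plant infeasible: need %d '%s' genotypes at %s in stratum %s/%s but only %d eligible sample(s)",
                  p$count, p$class, site_key(p$chrom, p$pos),
                  p$supercluster, ifelse(is.na(p$sex), "any", p$sex),
                  length(cand))
          }
          take <- if (length(cand) == 1) cand else sample(cand, p$count)
          take <- take[seq_len(p$count)]
          if (!is.null(rkey)) share_registry[[rkey]] <- take
        }
        zyg[take, j] <- p$class
        used_global[take] <- TRUE
        truth[[length(truth) + 1]] <-
          data.frame(gene = catalog$gene[j], chrom = p$chrom, pos = p$pos,
                     supercluster = p$supercluster, sex = p$sex,
                     class = p$class, count = p$count,
                     stringsAsFactors = FALSE)
      }
    }

    # quality fields and noise, then serialize
    gt_cols <- character(m)
    body <- matrix("", n, m)
    noise_counts <- c(low_gq = 0L, low_dp = 0L, skew_ab = 0L)
    dosage <- setNames(integer(n), samples$sample_id)
    for (j in seq_len(m)) {
      z <- zyg[, j]
      gq <- integer(n); dp <- integer(n); adr <- integer(n); ada <- integer(n)
      for (cls in unique(z)) {
        idx <- which(z == cls)
        f <- passing_fields(cls, length(idx))
        gq[idx] <- f$gq; dp[idx] <- f$dp
        adr[idx] <- f$ad_ref; ada[idx] <- f$ad_alt
      }
      # exactly-one-filter noise: segment a single uniform draw
      u <- runif(n)
      pick_gq <- u < noise$low_gq
      pick_dp <- !pick_gq & u < noise$low_gq + noise$low_dp
      pick_ab <- !pick_gq & !pick_dp & z == "het" &
        u < noise$low_gq + noise$low_dp + noise$skew_ab
      if (any(pick_gq)) {
        gq[pick_gq] <- sample(0:20, sum(pick_gq), replace = TRUE)
        noise_counts["low_gq"] <- noise_counts["low_gq"] + sum(pick_gq)
      }
      if (any(pick_dp)) {
        k <- sum(pick_dp)
        dp2 <- sample(4:10, k, replace = TRUE)
        dp[pick_dp] <- dp2
        het_dp <- z[pick_dp] == "het"
        alt2 <- ifelse(het_dp, floor(dp2 / 2),
                       ifelse(z[pick_dp] %in% c("hom_alt", "hemi_alt"), dp2, 0L))
        ada[pick_dp] <- alt2
        adr[pick_dp] <- dp2 - alt2
        noise_counts["low_dp"] <- noise_counts["low_dp"] + k
      }
      if (any(pick_ab)) {
        k <- sum(pick_ab)
        side_high <- runif(k) < 0.5
        frac <- ifelse(side_high, 0.85, 0.15)
        ada[pick_ab] <- round(dp[pick_ab] * frac)
        adr[pick_ab] <- dp[pick_ab] - ada[pick_ab]
        noise_counts["skew_ab"] <- noise_counts["skew_ab"] + k
      }

      x_site <- catalog$chrom[j] == "X"
      gt <- character(n)
      gt[z == "hom_ref"] <- "0/0"
      gt[z == "het"] <- "0/1"
      gt[z == "hom_alt"] <- "1/1"
      if (male_x_dialect == "haploid") {
        gt[z == "hemi_ref"] <- "0"
        gt[z == "hemi_alt"] <- "1"
      } else {
        gt[z == "hemi_ref"] <- "0/0"
        gt[z == "hemi_alt"] <- "1/1"
      }
      dosage <- dosage + (z == "het") + 2L * (z == "hom_alt") +
        as.integer(male_x_dosage) * (z == "hemi_alt")
      body[, j] <- paste0(gt, ":", gq, ":", dp, ":", adr, ",", ada)
      gt_cols[j] <- if (any(z %in% PLANT_CLASSES)) catalog$archaic[j] else "."
    }

    filt <- ifelse(site_key(catalog$chrom, catalog$pos) %in% fail_sites,
                   "RF", "PASS")
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=asnvkit_synthetic_cohort_generator",
      paste0("##contig=<ID=", unique(catalog$chrom), ">"),
      "##FILTER=<ID=RF,Description=\"Failed upstream variant classifier (synthetic)\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples$sample_id), collapse = "\t")
    )
    rows <- vapply(seq_len(m), function(j) {
      paste(c(catalog$chrom[j], catalog$pos[j], ".", catalog$ref[j],
              gt_cols[j], "100", filt[j], ".", "GT:GQ:DP:AD", body[, j]),
            collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), file)

    invisible(list(
      file = file,
      truth = if (length(truth)) do.call(rbind, truth) else
        data.frame(gene = character(), chrom = character(), pos = integer(),
                   supercluster = character(), sex = character(),
                   class = character(), count = integer(),
                   stringsAsFactors = FALSE),
      dosage = dosage,
      noise = noise_counts
    ))
  })
}
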