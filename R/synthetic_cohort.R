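#' Default principal-component cluster centroids
#'
#' Centroids (PC1--PC4, arbitrary PC units) of the isotropic Gaussian
#' clusters the sample generator draws from. The named clusters are
#' well separated; the `Uncategorized` pseudo-cluster is centered
#' between them and, combined with its large default spread, emulates
#' the dispersed cloud of unassignable samples.
#'
#' @return 5x4 numeric matrix, rows named by supercluster.
#' @export
default_pc_centroids <- function() {
  m <- rbind(
    EUR = c(0, 0, 0, 0),
    AFR = c(120, -40, 5, 0),
    SAS = c(60, 35, -5, 0),
    EAS = c(40, -85, 10, 0),
    Uncategorized = c(40, -20, 0, 0)
  )
  colnames(m) <- paste0("PC", 1:4)
  m
}

#' Configure a synthetic biobank cohort
#'
#' Bundles and validates the parameters of the synthetic sample
#' generator. Identical seed and configuration produce byte-identical
#' outputs.
#'
#' @param n_per_cluster Named integer vector: samples per supercluster
#'   (`EUR`, `AFR`, `SAS`, `EAS`, `Uncategorized`). Zero counts are
#'   allowed; negative counts are rejected.
#' @param pc_centroids 5x4 matrix of cluster centroids
#'   ([default_pc_centroids()]).
#' @param pc_spread Named positive vector: isotropic SD of each
#'   cluster's PCs.
#' @param age_mean,age_sd Age distribution parameters in years (the
#'   truncated-normal default mirrors the age structure of a
#'   middle-aged volunteer biobank).
#' @param age_range Length-2 vector `c(min, max)`, `min < max`.
#' @param age_dist `"truncnorm"` (default) or `"uniform"` over
#'   `age_range`.
#' @param sex_ratio Fraction female, in `[0, 1]`.
#' @param related_fraction Fraction of samples entering kinship pairs.
#' @param kinship_levels Kinship coefficients sampled for related pairs
#'   (defaults cover first- to third-degree).
#' @param kinship_mode `"pairs"` (disjoint pairs, default) or `"chain"`
#'   (one hub related to several others, exercising degree-prioritized
#'   pruning).
#' @param mislabel_fraction Fraction of cluster-generated samples whose
#'   self-report is replaced by a nonresponse code (hence initially
#'   Uncategorized).
#' @param strict_label_fraction Fraction of EUR samples carrying the
#'   strict `White_British` ancestry label.
#' @param qc_flag_rates Named rates for the four sample-QC flags
#'   (`sex_mismatch`, `aneuploidy`, `het_outlier`, `high_missingness`).
#' @param seed Integer RNG seed.
#' @return A validated list of class `asnv_config`.
#' @export
cohort_config <- function(n_per_cluster = c(EUR = 1000, AFR = 100, SAS = 150,
                                            EAS = 50, Uncategorized = 100),
                          pc_centroids = default_pc_centroids(),
                          pc_spread = c(EUR = 3, AFR = 3, SAS = 3, EAS = 3,
                                        Uncategorized = 40),
                          age_mean = 57, age_sd = 8, age_range = c(40, 70),
                          age_dist = c("truncnorm", "uniform"),
                          sex_ratio = 0.54,
                          related_fraction = 0,
                          kinship_levels = c(0.25, 0.125, 0.0625),
                          kinship_mode = c("pairs", "chain"),
                          mislabel_fraction = 0,
                          strict_label_fraction = 0.9,
                          qc_flag_rates = c(sex_mismatch = 0.001,
                                            aneuploidy = 0.0005,
                                            het_outlier = 0.001,
                                            high_missingness = 0.002),
                          seed = 1) {
  age_dist <- match.arg(age_dist)
  kinship_mode <- match.arg(kinship_mode)
  if (is.null(names(n_per_cluster)) ||
      length(setdiff(names(n_per_cluster), SUPERCLUSTERS))) {
    stopf("`n_per_cluster` must be named with superclusters (%s)",
          paste(SUPERCLUSTERS, collapse = ", "))
  }
  if (any(n_per_cluster < 0)) stopf("rejected config: negative cluster count")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stopf("`age_range` must be c(min, max) with min < max")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stopf("`sex_ratio` must lie in [0, 1]")
  if (related_fraction < 0 || related_fraction > 1) {
    stopf("`related_fraction` must lie in [0, 1]")
  }
  if (any(kinship_levels <= 0 | kinship_levels > 0.5)) {
    stopf("`kinship_levels` must lie in (0, 0.5]")
  }
  if (any(pc_spread[names(n_per_cluster)] <= 0, na.rm = TRUE)) {
    stopf("`pc_spread` must be positive")
  }
  structure(list(n_per_cluster = n_per_cluster, pc_centroids = pc_centroids,
                 pc_spread = pc_spread, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, age_dist = age_dist,
                 sex_ratio = sex_ratio, related_fraction = related_fraction,
                 kinship_levels = kinship_levels, kinship_mode = kinship_mode,
                 mislabel_fraction = mislabel_fraction,
                 strict_label_fraction = strict_label_fraction,
                 qc_flag_rates = qc_flag_rates, seed = as.integer(seed)),
            class = "asnv_config")
}

CLUSTER_SELF_REPORT <- c(EUR = "British", AFR = "African", SAS = "Indian",
                         EAS = "Chinese")
UNCAT_SELF_REPORT <- c("Mixed", "Other ethnic group", "Do not know",
                       "Do not want to answer")

draw_ages <- function(n, config) {
  lo <- config$age_range[1]
  hi <- config$age_range[2]
  if (config$age_dist == "uniform") return(runif(n, lo, hi))
  plo <- pnorm((lo - config$age_mean) / config$age_sd)
  phi <- pnorm((hi - config$age_mean) / config$age_sd)
  qnorm(runif(n, plo, phi)) * config$age_sd + config$age_mean
}

#' Generate synthetic sample metadata
#'
#' Draws one row per sample: a unique id, sex, age, a self-report
#' ancestry code consistent with the generating cluster (with a
#' configurable fraction mislabeled as a nonresponse code), the
#' supercluster implied by the self-report, PCs 1--4 from the cluster
#' centroid with isotropic spread, a strict ancestry label for a
#' fraction of EUR samples, and the four sample-QC flags set true at
#' their configured rates. Kinship pairs are drawn over the generated
#' ids.
#'
#' @param config An [cohort_config()].
#' @return A list of class `asnv_cohort` with `samples` (data frame),
#'   `kinship` (data frame `id1`, `id2`, `coefficient`), and the echoed
#'   `config`.
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "asnv_config"))
  with_seed(config$seed, {
    clusters <- names(config$n_per_cluster)
    n_total <- sum(config$n_per_cluster)
    cl <- rep(clusters, config$n_per_cluster)
    ids <- sprintf("S%06d", seq_len(n_total))
    sex <- ifelse(runif(n_total) < config$sex_ratio, "female", "male")
    age <- draw_ages(n_total, config)

    self_report <- character(n_total)
    for (c0 in clusters) {
      idx <- which(cl == c0)
      self_report[idx] <- if (c0 == "Uncategorized") {
        sample(UNCAT_SELF_REPORT, length(idx), replace = TRUE)
      } else CLUSTER_SELF_REPORT[[c0]]
    }
    if (config$mislabel_fraction > 0) {
      lab <- which(cl != "Uncategorized")
      flip <- lab[runif(length(lab)) < config$mislabel_fraction]
      self_report[flip] <- "Do not know"
    }
    supercluster <- suppressWarnings(map_self_report(self_report))

    pcs <- matrix(NA_real_, n_total, 4, dimnames = list(NULL, paste0("PC", 1:4)))
    for (c0 in clusters) {
      idx <- which(cl == c0)
      if (!length(idx)) next
      mu <- config$pc_centroids[c0, ]
      s <- config$pc_spread[[c0]]
      pcs[idx, ] <- matrix(rnorm(4 * length(idx)), ncol = 4) * s +
        matrix(mu, length(idx), 4, byrow = TRUE)
    }

    strict <- rep("none", n_total)
    eur <- which(cl == "EUR")
    strict[eur[runif(length(eur)) < config$strict_label_fraction]] <- "White_British"

    r <- config$qc_flag_rates
    samples <- data.frame(
      sample_id = ids, sex = sex, age = age,
      self_report = self_report, supercluster = supercluster,
      cluster_true = cl, strict_label = strict,
      PC1 = pcs[, 1], PC2 = pcs[, 2], PC3 = pcs[, 3], PC4 = pcs[, 4],
      qc_sex_mismatch = runif(n_total) < r[["sex_mismatch"]],
      qc_aneuploidy = runif(n_total) < r[["aneuploidy"]],
      qc_het_outlier = runif(n_total) < r[["het_outlier"]],
      qc_high_missingness = runif(n_total) < r[["high_missingness"]],
      stringsAsFactors = FALSE
    )

    kinship <- data.frame(id1 = character(), id2 = character(),
                          coefficient = numeric(), stringsAsFactors = FALSE)
    n_rel <- floor(config$related_fraction * n_total / 2) * 2
    if (n_rel >= 2) {
      chosen <- sample(ids, n_rel)
      if (config$kinship_mode == "pairs") {
        a <- chosen[seq(1, n_rel, by = 2)]
        b <- chosen[seq(2, n_rel, by = 2)]
      } else {
        a <- rep(chosen[1], n_rel - 1)  # hub related to all others
        b <- chosen[-1]
      }
      kinship <- data.frame(
        id1 = a, id2 = b,
        coefficient = sample(config$kinship_levels, length(a), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    structure(list(samples = samples, kinship = kinship, config = config),
              class = "asnv_cohort_data")
  })
}
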