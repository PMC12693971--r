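default_continuous_traits <- function() {
  data.frame(
    trait = c("bmi", "whole_body_fat_mass", "height"),
    mean = c(27.4, 24.8, 168.6),
    sd = c(4.8, 9.5, 9.3),
    beta = 0,
    stringsAsFactors = FALSE
  )
}

default_categorical_traits <- function() {
  list(
    overall_health_rating = list(
      levels = c("Excellent", "Good", "Fair", "Poor"),
      probs = c(0.16, 0.58, 0.21, 0.05),
      carrier_logodds = 0
    ),
    smoking_status = list(
      levels = c("Never", "Previous", "Current"),
      probs = c(0.55, 0.35, 0.10),
      carrier_logodds = 0
    )
  )
}

default_qualification_probs <- function() {
  c("College or University degree" = 0.33,
    "A levels/AS levels or equivalent" = 0.12,
    "O levels/GCSEs or equivalent" = 0.26,
    "CSEs or equivalent" = 0.06,
    "NVQ or HND or HNC or equivalent" = 0.07,
    "Other professional qualifications" = 0.16)
}

default_parcel_spec <- function() {
  data.frame(
    parcel = frontal_parcels(),
    area_mean = c(7300, 5600, 2300, 1700, 1500, 750, 2600, 1800, 5000,
                  1400, 250),
    thickness_mean = c(2.65, 2.40, 2.55, 2.60, 2.45, 2.55, 2.50, 2.45,
                       2.50, 2.40, 2.65),
    stringsAsFactors = FALSE
  )
}

#' Specify phenotype distributions and carrier effects
#'
#' Defines the trait-generating model for [generate_phenotypes()]:
#' continuous traits are Normal with an additive carrier effect (`beta`
#' in trait-SD units per archaic-allele dosage), categorical traits are
#' multinomial with an optional carrier log-odds shift on their first
#' level, qualification is a multi-response report set, and cortical
#' parcels get per-parcel Normal areas (mm^2) and thicknesses (mm) with
#' their own carrier effects (SD units per dosage).
#'
#' @param continuous Data frame with columns `trait`, `mean`, `sd`,
#'   `beta`.
#' @param categorical Named list; each element a list with `levels`,
#'   `probs` (summing to 1), `carrier_logodds`.
#' @param qualification_probs Named probabilities over qualification
#'   levels (summing to 1).
#' @param parcels Data frame with `parcel`, `area_mean`,
#'   `thickness_mean` for the 11 frontal parcels.
#' @param parcel_area_cv,parcel_thickness_sd Between-subject variation:
#'   area SD as a fraction of the parcel mean; thickness SD in mm.
#' @param beta_area,beta_thickness Carrier effects on parcels, in SD
#'   units per dosage.
#' @return A validated list of class `asnv_effects`.
#' @export
effect_spec <- function(continuous = default_continuous_traits(),
                        categorical = default_categorical_traits(),
                        qualification_probs = default_qualification_probs(),
                        parcels = default_parcel_spec(),
                        parcel_area_cv = 0.08, parcel_thickness_sd = 0.12,
                        beta_area = 0, beta_thickness = 0) {
  assert_columns(continuous, c("trait", "mean", "sd", "beta"), "`continuous`")
  if (any(continuous$sd <= 0)) stopf("continuous trait SDs must be > 0")
  for (nm in names(categorical)) {
    tr <- categorical[[nm]]
    if (length(tr$levels) != length(tr$probs)) {
      stopf("trait '%s': levels and probs differ in length", nm)
    }
    if (abs(sum(tr$probs) - 1) > 1e-8) {
      stopf("trait '%s': level probabilities must sum to 1", nm)
    }
  }
  if (abs(sum(qualification_probs) - 1) > 1e-8) {
    stopf("qualification probabilities must sum to 1")
  }
  assert_columns(parcels, c("parcel", "area_mean", "thickness_mean"),
                 "`parcels`")
  structure(list(continuous = continuous, categorical = categorical,
                 qualification_probs = qualification_probs,
                 parcels = parcels, parcel_area_cv = parcel_area_cv,
                 parcel_thickness_sd = parcel_thickness_sd,
                 beta_area = beta_area, beta_thickness = beta_thickness),
            class = "asnv_effects")
}

#' Set the carrier effect of one continuous trait
#'
#' @param effects An [effect_spec()].
#' @param trait Trait name; an unknown name is an error.
#' @param beta New effect size (trait-SD units per dosage).
#' @return The modified effects object.
#' @export
set_beta <- function(effects, trait, beta) {
  stopifnot(inherits(effects, "asnv_effects"))
  i <- match(trait, effects$continuous$trait)
  if (is.na(i)) {
    stopf("unknown trait '%s' (continuous traits: %s)", trait,
          paste(effects$continuous$trait, collapse = ", "))
  }
  effects$continuous$beta[i] <- beta
  effects
}

sample_levels <- function(n, levels, probs, shift, dosage) {
  if (any(shift * dosage != 0)) {
    out <- character(n)
    for (d in unique(dosage)) {
      idx <- which(dosage == d)
      lg <- log(probs)
      lg[1] <- lg[1] + shift * d
      p <- exp(lg) / sum(exp(lg))
      out[idx] <- sample(levels, length(idx), replace = TRUE, prob = p)
    }
    out
  } else {
    sample(levels, n, replace = TRUE, prob = probs)
  }
}

#' Generate synthetic phenotypes with a planted carrier effect
#'
#' Draws the phenotype tables of a synthetic cohort given each sample's
#' archaic-allele dosage: continuous traits `Normal(mean + beta * sd *
#' dosage, sd)`, categorical traits per level probabilities (with the
#' configured carrier log-odds shift), a multi-response qualification
#' report set, and per-parcel cortical surface areas and thicknesses
#' with their own carrier effects. Missingness is injected at a
#' configurable rate: continuous values become `NA`; categorical
#' responses become one of the literal nonresponse codes ("Do not
#' know", "Do not want to answer", "None of the above") so the
#' downstream merge rule is exercised verbatim.
#'
#' @param samples Samples data frame (needs `sample_id`).
#' @param dosage Numeric vector of archaic-allele dosages, either named
#'   by sample id or aligned to `samples` rows.
#' @param effects An [effect_spec()].
#' @param missing_rate Per-value missingness/nonresponse rate.
#' @param components Which tables to generate, a subset of
#'   `c("continuous", "categorical", "parcels")`; omitted tables are
#'   returned as `NULL`.
#' @param seed Integer RNG seed.
#' @return A list of class `asnv_phenotypes` with data frames
#'   `continuous` (`sample_id`, `dosage`, one column per trait),
#'   `categorical` (`sample_id`, traits, `qualification` as a
#'   `|`-separated report set), and `parcels` (long:
#'   `sample_id`, `hemisphere`, `parcel`, `area_mm2`, `thickness_mm`).
#' @export
generate_phenotypes <- function(samples, dosage, effects = effect_spec(),
                                missing_rate = 0.02,
                                components = c("continuous", "categorical",
                                               "parcels"),
                                seed = 1) {
  stopifnot(inherits(effects, "asnv_effects"))
  components <- match.arg(components, several.ok = TRUE)
  assert_columns(samples, "sample_id", "`samples`")
  n <- nrow(samples)
  if (!is.null(names(dosage))) {
    dosage <- dosage[samples$sample_id]
    if (anyNA(dosage)) stopf("dosage missing for some samples")
    dosage <- unname(dosage)
  }
  if (length(dosage) != n) stopf("`dosage` must align with `samples`")

  with_seed(seed, {
    cont <- NULL
    if ("continuous" %in% components) {
      cont <- data.frame(sample_id = samples$sample_id, dosage = dosage,
                         stringsAsFactors = FALSE)
      for (i in seq_len(nrow(effects$continuous))) {
        tr <- effects$continuous[i, ]
        v <- rnorm(n, tr$mean + tr$beta * tr$sd * dosage, tr$sd)
        v[runif(n) < missing_rate] <- NA
        cont[[tr$trait]] <- v
      }
    }

    cat_df <- NULL
    if ("categorical" %in% components) {
      cat_df <- data.frame(sample_id = samples$sample_id,
                           stringsAsFactors = FALSE)
      for (nm in names(effects$categorical)) {
        tr <- effects$categorical[[nm]]
        v <- sample_levels(n, tr$levels, tr$probs,
                           tr$carrier_logodds %||% 0, dosage)
        nr <- runif(n) < missing_rate
        v[nr] <- sample(NONRESPONSE_CODES, sum(nr), replace = TRUE)
        cat_df[[nm]] <- v
      }
      # multi-response qualification set: a primary level, sometimes with
      # one additional lower-ranked level reported alongside it
      qp <- effects$qualification_probs
      ranking <- names(qp)
      primary_pos <- match(sample(ranking, n, replace = TRUE, prob = qp),
                           ranking)
      n_lower <- length(ranking) - primary_pos
      has_extra <- runif(n) < 0.35 & n_lower > 0
      extra_pos <- primary_pos + ceiling(runif(n) * pmax(n_lower, 1))
      qual <- ranking[primary_pos]
      qual[has_extra] <- paste(ranking[primary_pos[has_extra]],
                               ranking[extra_pos[has_extra]], sep = "|")
      nr <- runif(n) < missing_rate
      qual[nr] <- sample(NONRESPONSE_CODES, sum(nr), replace = TRUE)
      cat_df$qualification <- qual
    }

    parcels <- NULL
    if ("parcels" %in% components) {
      pr <- effects$parcels
      k <- nrow(pr)
      parcels <- data.frame(
        sample_id = rep(samples$sample_id, each = 2 * k),
        hemisphere = rep(rep(c("lh", "rh"), each = k), n),
        parcel = rep(pr$parcel, 2 * n),
        stringsAsFactors = FALSE
      )
      area_mean <- rep(pr$area_mean, 2 * n)
      area_sd <- area_mean * effects$parcel_area_cv
      th_mean <- rep(pr$thickness_mean, 2 * n)
      dos_long <- rep(dosage, each = 2 * k)
      parcels$area_mm2 <- rnorm(nrow(parcels),
                                area_mean + effects$beta_area * area_sd * dos_long,
                                area_sd)
      parcels$thickness_mm <- rnorm(
        nrow(parcels),
        th_mean + effects$beta_thickness * effects$parcel_thickness_sd * dos_long,
        effects$parcel_thickness_sd)
    }

    structure(list(continuous = cont, categorical = cat_df, parcels = parcels),
              class = "asnv_phenotypes")
  })
}
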