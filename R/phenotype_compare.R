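#' Merge nonresponse answer options into one level
#'
#' Collapses the nonresponse answer options "Do not know", "Do not want
#' to answer" and "None of the above" into a single combined level, with
#' additive counts. Values already outside the nonresponse set pass
#' through unchanged.
#'
#' @param x Character or factor vector of categorical responses.
#' @param codes The nonresponse labels to merge.
#' @param to Label of the combined level, default `"Nonresponse"`.
#' @return Character vector with the merged level.
#' @export
merge_nonresponse <- function(x, codes = NONRESPONSE_CODES,
                              to = "Nonresponse") {
  x <- as.character(x)
  x[x %in% codes] <- to
  x
}

#' Default qualification level ranking
#'
#' Total order over qualification levels, highest first. The combined
#' nonresponse level ranks last.
#'
#' @return Character vector of levels in descending rank.
#' @export
qualification_levels <- function() {
  c("College or University degree",
    "A levels/AS levels or equivalent",
    "O levels/GCSEs or equivalent",
    "CSEs or equivalent",
    "NVQ or HND or HNC or equivalent",
    "Other professional qualifications",
    "Nonresponse")
}

#' Highest reported qualification level
#'
#' Reduces each individual's set of reported qualification levels to the
#' single highest level under a total-order ranking. Nonresponse codes
#' are merged first, so a report set of only nonresponse options yields
#' the combined nonresponse level.
#'
#' @param reported A list of character vectors (one set per individual)
#'   or a character vector of `|`-separated report sets.
#' @param ranking Character vector of levels in descending rank, see
#'   [qualification_levels()].
#' @return Character vector: the highest reported level per individual;
#'   `NA` for an empty report set.
#' @examples
#' highest_qualification("O levels/GCSEs or equivalent|College or University degree")
#' @export
highest_qualification <- function(reported, ranking = qualification_levels()) {
  if (!is.list(reported)) {
    reported <- strsplit(as.character(reported), "|", fixed = TRUE)
  }
  vapply(reported, function(set) {
    set <- merge_nonresponse(set[!is.na(set) & nzchar(set)])
    if (!length(set)) return(NA_character_)
    unknown <- setdiff(set, ranking)
    if (length(unknown)) {
      stopf("qualification level(s) not in the ranking: %s",
            paste(unknown, collapse = ", "))
    }
    ranking[min(match(set, ranking))]
  }, character(1))
}

#' Wilson score interval for a binomial proportion
#'
#' The Wilson score interval, obtained by inverting the normal score
#' test: center `(k/n + z^2/2n) / (1 + z^2/n)`, half-width
#' `(z / (1 + z^2/n)) * sqrt(k(n-k)/n^3 + z^2/4n^2)`, clipped to
#' `[0, 1]`. It always contains the point estimate `k/n` and has better
#' coverage than the Wald interval at extreme proportions.
#'
#' @param k Number of successes, `0 <= k <= n`. Vectorized.
#' @param n Number of trials, `n >= 1`.
#' @param conf Confidence level, default 0.95.
#' @param z Optional explicit critical value, overriding `conf`.
#' @return Data frame with `k`, `n`, `proportion`, `lower`, `upper`.
#' @examples
#' wilson_interval(0, 19)   # upper bound z^2 / (n + z^2)
#' @export
wilson_interval <- function(k, n, conf = 0.95, z = NULL) {
  if (any(n < 1)) stopf("`n` must be >= 1 (undefined interval for n = 0)")
  if (any(k < 0 | k > n)) stopf("`k` must satisfy 0 <= k <= n")
  z <- z %||% qnorm(1 - (1 - conf) / 2)
  if (z <= 0) stopf("`z` must be positive")
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(k * (n - k) / n^3 + z^2 / (4 * n^2))
  data.frame(k = k, n = n, proportion = p,
             lower = pmax(0, center - half),
             upper = pmin(1, center + half))
}

#' Summarize a continuous trait: carriers against a control distribution
#'
#' Places carrier values against the matched control distribution: the
#' carrier mean with its 95% confidence interval (t distribution with
#' n-1 df by default), the control quartiles (linear-interpolation
#' quantiles), Tukey 1.5 x IQR whisker bounds, and each carrier's
#' percentile rank within the control distribution (fraction of
#' controls strictly below, with midpoint correction for ties).
#'
#' @param carrier Numeric vector of carrier values (length >= 1).
#' @param control Numeric vector of control values (length >= 4).
#' @param trait Trait name carried through to the output.
#' @param conf Confidence level for the carrier mean, default 0.95.
#' @param ci_method `"t"` (default) or `"z"` for a normal-quantile
#'   interval.
#' @return A list of class `asnv_trait_summary`: `trait`, `carrier`
#'   (`n`, `mean`, `ci_lower`, `ci_upper`, `ci_defined`), `control`
#'   (`n`, `q25`, `median`, `q75`, `whisker_low`, `whisker_high`), and
#'   `carrier_percentiles`. With a single carrier the mean is reported
#'   and the interval is flagged undefined.
#' @export
summarize_continuous <- function(carrier, control, trait = "trait",
                                 conf = 0.95, ci_method = c("t", "z")) {
  ci_method <- match.arg(ci_method)
  carrier <- carrier[!is.na(carrier)]
  control <- control[!is.na(control)]
  if (length(carrier) < 1) stopf("need at least one carrier value")
  if (length(control) < 4) stopf("need at least four control values")
  n <- length(carrier)
  m <- mean(carrier)
  ci_defined <- n > 1
  if (ci_defined) {
    se <- sd(carrier) / sqrt(n)
    crit <- if (ci_method == "t") qt(1 - (1 - conf) / 2, df = n - 1) else
      qnorm(1 - (1 - conf) / 2)
    ci <- c(m - crit * se, m + crit * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  qs <- quantile(control, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  pct <- vapply(carrier, function(x)
    (sum(control < x) + 0.5 * sum(control == x)) / length(control),
    numeric(1))
  structure(list(
    trait = trait,
    carrier = list(n = n, mean = m, ci_lower = ci[1], ci_upper = ci[2],
                   ci_defined = ci_defined),
    control = list(n = length(control), q25 = qs[1], median = qs[2],
                   q75 = qs[3],
                   whisker_low = qs[1] - 1.5 * iqr,
                   whisker_high = qs[3] + 1.5 * iqr),
    carrier_percentiles = pct
  ), class = "asnv_trait_summary")
}

#' Summarize a categorical trait per arm with Wilson intervals
#'
#' Merges nonresponse options, then tabulates each level's count and
#' proportion per arm with its Wilson 95% score interval. Proportions
#' sum to one per arm over the merged levels.
#'
#' @param carrier Character vector of carrier responses.
#' @param control Character vector of control responses.
#' @param trait Trait name carried through to the output.
#' @param conf Confidence level, default 0.95.
#' @param merge Merge nonresponse options first (default `TRUE`).
#' @return Data frame with columns `trait`, `arm`, `level`, `count`,
#'   `n`, `proportion`, `lower`, `upper`.
#' @export
summarize_categorical <- function(carrier, control, trait = "trait",
                                  conf = 0.95, merge = TRUE) {
  if (merge) {
    carrier <- merge_nonresponse(carrier)
    control <- merge_nonresponse(control)
  }
  carrier <- carrier[!is.na(carrier)]
  control <- control[!is.na(control)]
  levels <- sort(unique(c(carrier, control)))
  one_arm <- function(x, arm) {
    n <- length(x)
    counts <- vapply(levels, function(l) sum(x == l), integer(1))
    w <- wilson_interval(counts, n, conf = conf)
    data.frame(trait = trait, arm = arm, level = levels, count = counts,
               n = n, proportion = w$proportion, lower = w$lower,
               upper = w$upper, stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(one_arm(carrier, "carrier"), one_arm(control, "control"))
}

#' The 11 frontal-lobe cortical parcels
#'
#' Desikan-Killiany parcels summed (surface area) or averaged (cortical
#' thickness) per hemisphere to form the frontal-lobe composites.
#'
#' @return Character vector of 11 parcel names.
#' @export
frontal_parcels <- function() {
  c("superior_frontal", "rostral_middle_frontal", "caudal_middle_frontal",
    "pars_opercularis", "pars_triangularis", "pars_orbitalis",
    "lateral_orbitofrontal", "medial_orbitofrontal", "precentral",
    "paracentral", "frontal_pole")
}

#' Frontal-lobe composite area and thickness per sample
#'
#' For each sample and hemisphere, sums the surface areas (mm^2) of the
#' 11 frontal parcels and takes the unweighted mean of their cortical
#' thicknesses (mm). A sample x hemisphere with any of the 11 parcels
#' missing gets `NA` composites and is recorded in the `incomplete`
#' attribute. Negative parcel values are an error.
#'
#' @param parcels Long data frame with columns `sample_id`,
#'   `hemisphere` (`"lh"`/`"rh"`), `parcel`, `area_mm2`,
#'   `thickness_mm`.
#' @return Data frame with one row per sample x hemisphere:
#'   `sample_id`, `hemisphere`, `area_mm2` (sum), `thickness_mm`
#'   (mean); attribute `incomplete` lists the sample x hemisphere pairs
#'   with missing parcels.
#' @export
frontal_composites <- function(parcels) {
  assert_columns(parcels,
                 c("sample_id", "hemisphere", "parcel", "area_mm2",
                   "thickness_mm"), "`parcels`")
  wanted <- frontal_parcels()
  parcels <- parcels[parcels$parcel %in% wanted, , drop = FALSE]
  if (any(parcels$area_mm2 < 0, na.rm = TRUE) ||
      any(parcels$thickness_mm < 0, na.rm = TRUE)) {
    stopf("negative parcel area or thickness")
  }
  key <- interaction(parcels$sample_id, parcels$hemisphere, drop = TRUE)
  groups <- split(parcels, key)
  rows <- lapply(groups, function(d) {
    complete <- length(unique(d$parcel)) == length(wanted) &&
      !anyNA(d$area_mm2) && !anyNA(d$thickness_mm)
    data.frame(sample_id = d$sample_id[1], hemisphere = d$hemisphere[1],
               area_mm2 = if (complete) sum(d$area_mm2) else NA_real_,
               thickness_mm = if (complete) mean(d$thickness_mm) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  incomplete <- out[is.na(out$area_mm2), c("sample_id", "hemisphere")]
  rownames(incomplete) <- NULL
  attr(out, "incomplete") <- incomplete
  out
}
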