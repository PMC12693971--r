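#' Specify a matched-cohort design
#'
#' Defines how noncarrier controls are matched to carriers: a fixed
#' number of unique controls per carrier (`ratio`), exact constraints,
#' and calipers. Exact fields must agree between carrier and control;
#' caliper fields must lie within the stated half-width of the
#' carrier's value.
#'
#' @param ratio Positive integer: unique controls per carrier.
#' @param exact_on Character subset of `c("sex", "supercluster",
#'   "strict_label")` matched exactly.
#' @param age_caliper Age half-width in years, or `NULL` for no age
#'   constraint.
#' @param pc_calipers Named numeric vector of per-PC half-widths (names
#'   among `PC1`..`PC4`), or `NULL`.
#' @return An object of class `asnv_match_spec`.
#' @seealso [match_preset()] for the shipped designs.
#' @export
match_spec <- function(ratio, exact_on = "sex", age_caliper = 2.5,
                       pc_calipers = NULL) {
  if (length(ratio) != 1 || is.na(ratio) || ratio < 1 || ratio != as.integer(ratio)) {
    stopf("`ratio` must be a positive integer")
  }
  allowed <- c("sex", "supercluster", "strict_label")
  if (length(setdiff(exact_on, allowed))) {
    stopf("`exact_on` must be a subset of: %s", paste(allowed, collapse = ", "))
  }
  if (!is.null(age_caliper) && age_caliper < 0) stopf("`age_caliper` must be >= 0")
  if (!is.null(pc_calipers)) {
    if (is.null(names(pc_calipers)) ||
        length(setdiff(names(pc_calipers), paste0("PC", 1:4)))) {
      stopf("`pc_calipers` must be named with PC1..PC4")
    }
    if (any(pc_calipers < 0)) stopf("`pc_calipers` must be >= 0")
  }
  structure(list(ratio = as.integer(ratio), exact_on = exact_on,
                 age_caliper = age_caliper, pc_calipers = pc_calipers),
            class = "asnv_match_spec")
}

#' Shipped matching design presets
#'
#' Loads one of the packaged matched-cohort designs (YAML files under
#' `inst/extdata/presets/`):
#'
#' * `ssh2`: 2079 controls per carrier, exact on sex and the strict
#'   ancestry label, age caliper 2.5 years.
#' * `tktl1_imaging`: 429 controls per carrier, matched on age (caliper
#'   2.5 years) and sex only, across ancestries.
#' * `tktl1_sensitivity`: 10 controls per carrier, exact on sex, age
#'   caliper 2.5 years, PC1/PC2 calipers 2.5.
#' * `tktl1_qualification`: 20 controls per carrier, exact on sex, age
#'   caliper 2.5 years, PC1/PC2 calipers 2.5.
#'
#' @param name Preset name.
#' @return An `asnv_match_spec`.
#' @export
match_preset <- function(name = c("ssh2", "tktl1_imaging",
                                  "tktl1_sensitivity",
                                  "tktl1_qualification")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "asnvkit", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  pc <- if (!is.null(y$pc_calipers)) unlist(y$pc_calipers)
  match_spec(ratio = y$ratio, exact_on = unlist(y$exact_on),
             age_caliper = y$age_caliper, pc_calipers = pc)
}

match_pool_columns <- function(spec) {
  cols <- c("sample_id", spec$exact_on)
  if (!is.null(spec$age_caliper)) cols <- c(cols, "age")
  if (!is.null(spec$pc_calipers)) cols <- c(cols, names(spec$pc_calipers))
  cols
}

#' Candidate controls for one carrier
#'
#' Filters a noncarrier pool to the candidates satisfying all exact
#' fields and calipers relative to one carrier, sorted by absolute age
#' difference, then Euclidean PC1/PC2 distance, then sample id. The
#' empty list is a valid result.
#'
#' @param carrier One-row data frame (the carrier).
#' @param pool Data frame of eligible noncarriers (QC-passing, unrelated
#'   noncarriers at the target site).
#' @param spec An [match_spec()].
#' @return The eligible subset of `pool`, ranked best-first.
#' @export
eligible_controls <- function(carrier, pool, spec) {
  stopifnot(inherits(spec, "asnv_match_spec"), nrow(carrier) == 1)
  assert_columns(pool, match_pool_columns(spec), "`pool`")
  assert_columns(carrier, setdiff(match_pool_columns(spec), "sample_id"),
                 "`carrier`")
  keep <- rep(TRUE, nrow(pool))
  for (f in spec$exact_on) keep <- keep & pool[[f]] == carrier[[f]]
  if (!is.null(spec$age_caliper)) {
    keep <- keep & abs(pool$age - carrier$age) <= spec$age_caliper
  }
  if (!is.null(spec$pc_calipers)) {
    for (pc in names(spec$pc_calipers)) {
      keep <- keep & abs(pool[[pc]] - carrier[[pc]]) <= spec$pc_calipers[[pc]]
    }
  }
  keep[is.na(keep)] <- FALSE
  out <- pool[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  age_d <- if (!is.null(spec$age_caliper)) abs(out$age - carrier$age) else
    rep(0, nrow(out))
  pc_d <- if (all(c("PC1", "PC2") %in% names(out)) &&
              all(c("PC1", "PC2") %in% names(carrier))) {
    sqrt((out$PC1 - carrier$PC1)^2 + (out$PC2 - carrier$PC2)^2)
  } else rep(0, nrow(out))
  out[order(age_d, pc_d, out$sample_id), , drop = FALSE]
}

#' Build a matched noncarrier cohort
#'
#' Greedy sequential matching: carriers are processed in ascending
#' sample-id order; each consumes its `ratio` best-ranked remaining
#' candidates ([eligible_controls()]), which are then removed from the
#' pool, so every control is used for exactly one carrier (global
#' uniqueness). On success the control arm has exactly
#' `ratio x n_carriers` distinct individuals. A carrier with fewer than
#' `ratio` remaining candidates aborts the run with an error naming the
#' carrier and its shortfall, unless `allow_partial = TRUE`.
#'
#' @param carriers Data frame of carriers (pairwise unrelated), with the
#'   columns the spec matches on.
#' @param pool Data frame of candidate controls, disjoint from
#'   `carriers`.
#' @param spec An [match_spec()] or [match_preset()].
#' @param allow_partial Emit a partial cohort instead of erroring when a
#'   carrier falls short.
#' @return Object of class `asnv_cohort`: list with `matches`
#'   (`carrier_id`, `control_id`, `rank`), `carriers`, `controls` (the
#'   consumed pool rows), `spec`, and `shortfalls` (empty on success).
#' @export
match_cohort <- function(carriers, pool, spec, allow_partial = FALSE) {
  stopifnot(inherits(spec, "asnv_match_spec"))
  assert_columns(carriers, setdiff(match_pool_columns(spec), "sample_id"),
                 "`carriers`")
  assert_columns(carriers, "sample_id", "`carriers`")
  assert_columns(pool, match_pool_columns(spec), "`pool`")
  if (length(intersect(carriers$sample_id, pool$sample_id))) {
    stopf("`pool` must be disjoint from `carriers`")
  }
  if (anyDuplicated(pool$sample_id)) stopf("duplicate ids in `pool`")
  carriers <- carriers[order(carriers$sample_id), , drop = FALSE]
  available <- rep(TRUE, nrow(pool))
  matches <- vector("list", nrow(carriers))
  shortfalls <- list()
  for (i in seq_len(nrow(carriers))) {
    cand <- eligible_controls(carriers[i, , drop = FALSE],
                              pool[available, , drop = FALSE], spec)
    if (nrow(cand) < spec$ratio) {
      short <- data.frame(carrier_id = carriers$sample_id[i],
                          eligible = nrow(cand),
                          shortfall = spec$ratio - nrow(cand),
                          stringsAsFactors = FALSE)
      if (!allow_partial) {
        stopf("carrier %s has only %d eligible control(s) remaining (needs %d; shortfall %d)",
              short$carrier_id, short$eligible, spec$ratio, short$shortfall)
      }
      shortfalls[[length(shortfalls) + 1]] <- short
    }
    take <- head(cand$sample_id, spec$ratio)
    if (length(take)) {
      matches[[i]] <- data.frame(carrier_id = carriers$sample_id[i],
                                 control_id = take,
                                 rank = seq_along(take),
                                 stringsAsFactors = FALSE)
      available[match(take, pool$sample_id)] <- FALSE
    }
  }
  matches <- do.call(rbind, Filter(Negate(is.null), matches))
  if (is.null(matches)) {
    matches <- data.frame(carrier_id = character(), control_id = character(),
                          rank = integer(), stringsAsFactors = FALSE)
  }
  structure(list(
    matches = matches,
    carriers = carriers,
    controls = pool[pool$sample_id %in% matches$control_id, , drop = FALSE],
    spec = spec,
    shortfalls = if (length(shortfalls)) do.call(rbind, shortfalls) else
      data.frame(carrier_id = character(), eligible = integer(),
                 shortfall = integer(), stringsAsFactors = FALSE)
  ), class = "asnv_cohort")
}

#' @export
print.asnv_cohort <- function(x, ...) {
  cat(sprintf("Matched cohort: %d carrier(s), %d distinct control(s) (ratio %d)\n",
              nrow(x$carriers), length(unique(x$matches$control_id)),
              x$spec$ratio))
  if (nrow(x$shortfalls)) {
    cat(sprintf("  PARTIAL: %d carrier(s) with shortfalls\n", nrow(x$shortfalls)))
  }
  invisible(x)
}

arm_summary <- function(df, arm) {
  n <- nrow(df)
  s <- if (n > 1) sd(df$age) else 0
  data.frame(arm = arm, n = n,
             n_female = sum(df$sex == "female"),
             age_mean = if (n) mean(df$age) else NA_real_,
             age_sd = s,
             sd_degenerate = n <= 1,
             stringsAsFactors = FALSE)
}

#' Summarize the arms of a matched cohort
#'
#' Per arm: size, female count, and mean and SD of age (sample SD, n-1
#' denominator). A single-sample arm reports SD 0 by convention and is
#' flagged via `sd_degenerate`.
#'
#' @param cohort An `asnv_cohort` from [match_cohort()].
#' @return Data frame with one row per arm (`carrier`, `control`).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "asnv_cohort"))
  rbind(arm_summary(cohort$carriers, "carrier"),
        arm_summary(cohort$controls, "control"))
}
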