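QC_FLAGS <- c("qc_sex_mismatch", "qc_aneuploidy", "qc_het_outlier",
              "qc_high_missingness")

#' Apply sample-level quality control
#'
#' Retains samples with all four QC flags false: self-reported vs
#' genetically inferred sex mismatch, putative sex-chromosome
#' aneuploidy, heterozygosity outlier (PC-corrected heterozygosity
#' beyond the upstream cutoff), and high genotype missingness. Flags are
#' consumed as booleans computed upstream, mirroring how biobanks
#' distribute precomputed sample-QC fields.
#'
#' @param samples Data frame with a `sample_id` column and logical
#'   columns `qc_sex_mismatch`, `qc_aneuploidy`, `qc_het_outlier`,
#'   `qc_high_missingness`.
#' @return List with `retained` (rows passing all flags) and `log` (one
#'   row per excluded sample with a comma-separated list of triggering
#'   flags).
#' @export
apply_sample_qc <- function(samples) {
  assert_columns(samples, c("sample_id", QC_FLAGS), "`samples`")
  flags <- as.matrix(samples[, QC_FLAGS])
  fail <- rowSums(flags, na.rm = TRUE) > 0
  log <- data.frame(
    sample_id = samples$sample_id[fail],
    flags = apply(flags[fail, , drop = FALSE], 1, function(r)
      paste(sub("^qc_", "", QC_FLAGS[which(r)]), collapse = ",")),
    stringsAsFactors = FALSE
  )
  rownames(log) <- NULL
  list(retained = samples[!fail, , drop = FALSE], log = log)
}

#' Default self-report ancestry code mapping
#'
#' Mapping from self-reported ancestral background codes to the four
#' major ancestry superclusters. Mixed, other, and nonresponse codes map
#' to `Uncategorized`. The mapping follows the UK-biobank-style ethnic
#' background codes and is fully configurable.
#'
#' @return Named character vector: names are self-report codes, values
#'   are supercluster labels.
#' @export
default_self_report_map <- function() {
  c(
    "White" = "EUR", "British" = "EUR", "White British" = "EUR",
    "Irish" = "EUR", "Any other white background" = "EUR",
    "African" = "AFR", "Caribbean" = "AFR",
    "Black or Black British" = "AFR",
    "Any other Black background" = "AFR",
    "Indian" = "SAS", "Pakistani" = "SAS", "Bangladeshi" = "SAS",
    "Asian or Asian British" = "SAS",
    "Any other Asian background" = "SAS",
    "Chinese" = "EAS",
    "Mixed" = "Uncategorized", "Other ethnic group" = "Uncategorized",
    "Other" = "Uncategorized",
    "Do not know" = "Uncategorized",
    "Do not want to answer" = "Uncategorized"
  )
}

#' Map self-reported ancestry codes to superclusters
#'
#' Deterministically maps each self-report code to one of `EUR`, `AFR`,
#' `SAS`, `EAS`, or `Uncategorized`. Codes absent from the mapping table
#' yield `Uncategorized` with a warning.
#'
#' @param code Character vector of self-report codes.
#' @param mapping Named character vector, see
#'   [default_self_report_map()].
#' @return Character vector of supercluster labels.
#' @examples
#' map_self_report(c("Mixed", "Chinese"))  # "Uncategorized", "EAS"
#' @export
map_self_report <- function(code, mapping = default_self_report_map()) {
  out <- unname(mapping[as.character(code)])
  unknown <- is.na(out)
  if (any(unknown)) {
    warnf("unknown self-report code(s) mapped to Uncategorized: %s",
          paste(unique(code[unknown]), collapse = ", "))
    out[unknown] <- "Uncategorized"
  }
  out
}

#' Fit per-cluster principal-component boxes
#'
#' For each named supercluster (everything except `Uncategorized`),
#' computes a hard-cutoff box on PC1--PC4 as the `[q, 1-q]` empirical
#' quantile interval of the cluster's self-report-labeled members. The
#' boxes reproduce hard-cutoff cluster assignment behavior without
#' externally supplied cutoff constants. A cluster with fewer than
#' `min_n` labeled members gets no box and cannot absorb reassignments.
#'
#' @param samples Data frame with columns `supercluster` and
#'   `PC1`..`PC4`.
#' @param q Quantile trimmed from each tail, default 0.01. `q = 0` spans
#'   the cluster minimum/maximum exactly.
#' @param min_n Minimum labeled members required to fit a box.
#' @return Object of class `asnv_pc_boxes`: a named list of 4x2
#'   matrices (rows PC1..PC4, columns `low`, `high`).
#' @export
fit_pc_boxes <- function(samples, q = 0.01, min_n = 20) {
  assert_columns(samples, c("supercluster", paste0("PC", 1:4)), "`samples`")
  stopifnot(q >= 0, q < 0.5)
  clusters <- setdiff(SUPERCLUSTERS, "Uncategorized")
  boxes <- list()
  for (cl in clusters) {
    sub <- samples[samples$supercluster == cl, , drop = FALSE]
    if (nrow(sub) < min_n) next
    m <- t(vapply(paste0("PC", 1:4), function(pc)
      quantile(sub[[pc]], probs = c(q, 1 - q), names = FALSE, type = 7),
      numeric(2)))
    colnames(m) <- c("low", "high")
    boxes[[cl]] <- m
  }
  structure(boxes, class = "asnv_pc_boxes", q = q)
}

in_box <- function(samples, box) {
  inside <- rep(TRUE, nrow(samples))
  for (j in 1:4) {
    v <- samples[[paste0("PC", j)]]
    inside <- inside & v >= box[j, "low"] & v <= box[j, "high"]
  }
  inside
}

#' Assign final ancestry superclusters using PC boxes
#'
#' Harmonizes self-report labels with genetic PCs: a sample labeled with
#' a named cluster keeps its label only while its PCs lie inside that
#' cluster's box, and becomes `Uncategorized` otherwise. An
#' `Uncategorized` sample whose PCs fall inside exactly one cluster's
#' box (on all four PCs) is reassigned to that cluster; inside zero or
#' several boxes it stays `Uncategorized`. A sample is never moved
#' directly between two named clusters.
#'
#' @param samples Data frame with columns `supercluster` (initial,
#'   self-report-derived) and `PC1`..`PC4`.
#' @param boxes An `asnv_pc_boxes` object from [fit_pc_boxes()].
#' @return `samples` with `supercluster` replaced by the final label.
#' @export
assign_supercluster <- function(samples, boxes) {
  assert_columns(samples, c("supercluster", paste0("PC", 1:4)), "`samples`")
  inside <- vapply(names(boxes), function(cl) in_box(samples, boxes[[cl]]),
                   logical(nrow(samples)))
  inside <- matrix(inside, nrow = nrow(samples),
                   dimnames = list(NULL, names(boxes)))
  lab <- samples$supercluster
  out <- lab
  named <- lab %in% names(boxes)
  if (any(named)) {
    own <- inside[cbind(which(named), match(lab[named], colnames(inside)))]
    out[which(named)[!own]] <- "Uncategorized"
  }
  uncat <- lab == "Uncategorized"
  n_in <- rowSums(inside)
  reassign <- uncat & n_in == 1
  if (any(reassign)) {
    out[reassign] <- colnames(inside)[apply(inside[reassign, , drop = FALSE],
                                            1, which)]
  }
  samples$supercluster <- out
  samples
}

normalize_kinship <- function(kinship) {
  assert_columns(kinship, c("id1", "id2", "coefficient"), "`kinship`")
  if (any(kinship$id1 == kinship$id2)) stopf("kinship pair with identical ids")
  if (any(kinship$coefficient < 0 | kinship$coefficient > 0.5)) {
    stopf("kinship coefficients must lie in [0, 0.5]")
  }
  a <- pmin(kinship$id1, kinship$id2)
  b <- pmax(kinship$id1, kinship$id2)
  key <- paste(a, b)
  # a pair listed in both directions must carry one coefficient
  agg <- tapply(kinship$coefficient, key, function(x) length(unique(x)))
  if (any(agg > 1)) {
    stopf("asymmetric kinship links (conflicting coefficients) for pair(s): %s",
          paste(names(agg)[agg > 1], collapse = "; "))
  }
  keep <- !duplicated(key)
  data.frame(id1 = a[keep], id2 = b[keep],
             coefficient = kinship$coefficient[keep],
             stringsAsFactors = FALSE)
}

#' Prune related samples with carrier-prioritized exclusion
#'
#' Greedy relatedness pruning: while any retained pair has a kinship
#' coefficient above `threshold`, one endpoint of the remaining related
#' pairs is removed, chosen by (1) noncarrier before carrier, (2) higher
#' degree in the remaining above-threshold kinship graph, (3)
#' lexicographically larger sample id (deterministic tie-break). The
#' default threshold 0.0442 is the conventional bound separating
#' third-degree relatives from unrelated pairs.
#'
#' @param samples Data frame with a `sample_id` column (extra columns
#'   pass through), or a character vector of sample ids.
#' @param kinship Data frame of kinship links with columns `id1`, `id2`,
#'   `coefficient`. Links are undirected; a pair listed in both
#'   directions must carry the same coefficient (else an error).
#' @param threshold Kinship coefficient above which a pair counts as
#'   related, default 0.0442.
#' @param carriers Character vector of carrier sample ids (protected
#'   from removal where possible).
#' @return List with `retained` (same shape as `samples`) and `removed`
#'   (data frame: `sample_id`, `rule` -- the criterion that decided the
#'   removal -- and `degree` at removal time).
#' @examples
#' k <- data.frame(id1 = "A", id2 = "B", coefficient = 0.25)
#' prune_related(c("A", "B"), k, carriers = "A")$retained  # "A"
#' @export
prune_related <- function(samples, kinship, threshold = 0.0442,
                          carriers = character()) {
  ids <- if (is.data.frame(samples)) samples$sample_id else as.character(samples)
  if (anyDuplicated(ids)) stopf("duplicate sample ids")
  edges <- if (is.null(kinship) || !nrow(kinship)) {
    data.frame(id1 = character(), id2 = character(), coefficient = numeric())
  } else normalize_kinship(kinship)
  edges <- edges[edges$coefficient > threshold &
                   edges$id1 %in% ids & edges$id2 %in% ids, , drop = FALSE]
  retained <- ids
  removed <- list()
  while (nrow(edges) > 0) {
    endpoints <- c(edges$id1, edges$id2)
    deg <- table(endpoints)
    cand <- names(deg)
    is_carrier <- cand %in% carriers
    degree <- as.integer(deg)
    # order: noncarriers first, then higher degree, then larger id
    o <- order(is_carrier, -degree, cand,
               decreasing = c(FALSE, FALSE, TRUE), method = "radix")
    pick <- cand[o[1]]
    n_non <- sum(!is_carrier)
    rule <- if (n_non > 0 && n_non < length(cand)) "noncarrier_first"
    else {
      top_deg <- degree[o[1]]
      if (sum(degree == top_deg) < length(cand)) "higher_degree" else "larger_id"
    }
    removed[[length(removed) + 1]] <-
      data.frame(sample_id = pick, rule = rule,
                 degree = degree[o[1]], stringsAsFactors = FALSE)
    retained <- setdiff(retained, pick)
    edges <- edges[edges$id1 != pick & edges$id2 != pick, , drop = FALSE]
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(sample_id = character(), rule = character(),
               degree = integer(), stringsAsFactors = FALSE)
  out <- if (is.data.frame(samples)) {
    samples[samples$sample_id %in% retained, , drop = FALSE]
  } else retained
  list(retained = out, removed = removed)
}
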