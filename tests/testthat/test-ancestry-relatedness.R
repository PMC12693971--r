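qc_frame <- function(n = 4) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             qc_sex_mismatch = FALSE, qc_aneuploidy = FALSE,
             qc_het_outlier = FALSE, qc_high_missingness = FALSE,
             stringsAsFactors = FALSE)
}

test_that("sample QC retains clean samples and logs every triggering flag", {
  s <- qc_frame(4)
  expect_equal(apply_sample_qc(s)$retained, s)  # all flags false -> identity
  s$qc_sex_mismatch[2] <- TRUE
  s$qc_het_outlier[2] <- TRUE
  s$qc_high_missingness[4] <- TRUE
  res <- apply_sample_qc(s)
  expect_equal(res$retained$sample_id, c("S01", "S03"))
  expect_equal(nrow(res$log), 2)  # a doubly-flagged sample is logged once
  expect_equal(res$log$flags[res$log$sample_id == "S02"],
               "sex_mismatch,het_outlier")
})

test_that("sample QC exclusion fraction matches the configured flag rates", {
  rates <- c(sex_mismatch = 0.002, aneuploidy = 0.001,
             het_outlier = 0.002, high_missingness = 0.004)
  cfg <- cohort_config(n_per_cluster = c(EUR = 30000, AFR = 0, SAS = 0,
                                         EAS = 0, Uncategorized = 0),
                       qc_flag_rates = rates, seed = 99)
  cohort <- generate_samples(cfg)
  res <- apply_sample_qc(cohort$samples)
  p_fail <- 1 - prod(1 - rates)
  expected <- 30000 * p_fail
  se <- sqrt(30000 * p_fail * (1 - p_fail))
  expect_lt(abs(nrow(res$log) - expected), 4 * se)
})

test_that("self-report codes map deterministically, unknowns warn", {
  expect_equal(map_self_report("Mixed"), "Uncategorized")
  expect_equal(map_self_report("Chinese"), "EAS")
  expect_equal(map_self_report(c("British", "African", "Indian")),
               c("EUR", "AFR", "SAS"))
  expect_warning(out <- map_self_report("Martian"), "unknown")
  expect_equal(out, "Uncategorized")
})

test_that("PC boxes are quantile intervals with documented edge cases", {
  const <- data.frame(supercluster = "EUR", PC1 = 5, PC2 = 5, PC3 = 5,
                      PC4 = 5)[rep(1, 30), ]
  b <- fit_pc_boxes(const, q = 0.01, min_n = 10)
  expect_equal(unname(b$EUR[, "low"]), rep(5, 4))   # degenerate box [c, c]
  expect_equal(unname(b$EUR[, "high"]), rep(5, 4))

  set.seed(1)
  d <- data.frame(supercluster = "AFR",
                  PC1 = rnorm(50), PC2 = rnorm(50), PC3 = rnorm(50),
                  PC4 = rnorm(50))
  b0 <- fit_pc_boxes(d, q = 0, min_n = 10)
  expect_equal(b0$AFR["PC1", "low"], min(d$PC1))    # q = 0 spans min/max
  expect_equal(b0$AFR["PC1", "high"], max(d$PC1))

  # two synthetic clusters with centroid gap >> spread give disjoint boxes
  two <- rbind(
    data.frame(supercluster = "EUR", PC1 = rnorm(500, 0, 1),
               PC2 = rnorm(500), PC3 = rnorm(500), PC4 = rnorm(500)),
    data.frame(supercluster = "AFR", PC1 = rnorm(500, 100, 1),
               PC2 = rnorm(500), PC3 = rnorm(500), PC4 = rnorm(500)))
  bb <- fit_pc_boxes(two, q = 0.01)
  expect_lt(bb$EUR["PC1", "high"], bb$AFR["PC1", "low"])

  # a cluster below min_n gets no box
  expect_null(fit_pc_boxes(d[1:5, ], q = 0.01, min_n = 10)$AFR)
})

test_that("supercluster assignment follows the box-membership rules", {
  boxes <- structure(list(
    EUR = cbind(low = c(-1, -1, -1, -1), high = c(1, 1, 1, 1)),
    AFR = cbind(low = c(9, -1, -1, -1), high = c(11, 1, 1, 1)),
    SAS = cbind(low = c(4, -1, -1, -1), high = c(6, 1, 1, 1))
  ), class = "asnv_pc_boxes")
  rownames(boxes$EUR) <- rownames(boxes$AFR) <- rownames(boxes$SAS) <-
    paste0("PC", 1:4)
  mk <- function(label, pc1) data.frame(supercluster = label, PC1 = pc1,
                                        PC2 = 0, PC3 = 0, PC4 = 0)
  # Uncategorized inside exactly the AFR box is reassigned
  expect_equal(assign_supercluster(mk("Uncategorized", 10), boxes)$supercluster,
               "AFR")
  # inside zero boxes stays Uncategorized
  expect_equal(assign_supercluster(mk("Uncategorized", 50), boxes)$supercluster,
               "Uncategorized")
  # labeled sample inside its own box keeps its label
  expect_equal(assign_supercluster(mk("EUR", 0), boxes)$supercluster, "EUR")
  # labeled sample outside its own box becomes Uncategorized, never
  # another named cluster, even when it sits inside that cluster's box
  expect_equal(assign_supercluster(mk("EUR", 10), boxes)$supercluster,
               "Uncategorized")
  # ambiguous membership: overlapping boxes keep Uncategorized
  boxes$SAS[1, ] <- c(9, 11)
  expect_equal(assign_supercluster(mk("Uncategorized", 10), boxes)$supercluster,
               "Uncategorized")
})

test_that("relatedness pruning prioritizes noncarriers, degree, then id", {
  # carrier/noncarrier pair: the noncarrier is removed
  k <- data.frame(id1 = "A", id2 = "B", coefficient = 0.25)
  res <- prune_related(c("A", "B"), k, carriers = "A")
  expect_equal(res$retained, "A")
  expect_equal(res$removed$rule, "noncarrier_first")

  # no pairs above threshold -> identity
  res <- prune_related(c("A", "B"), data.frame(id1 = "A", id2 = "B",
                                               coefficient = 0.04))
  expect_equal(res$retained, c("A", "B"))

  # star graph: the noncarrier hub is removed, all three leaves retained
  star <- data.frame(id1 = c("HUB", "HUB", "HUB"),
                     id2 = c("L1", "L2", "L3"),
                     coefficient = 0.25)
  res <- prune_related(c("HUB", "L1", "L2", "L3"), star)
  expect_equal(res$removed$sample_id, "HUB")
  expect_equal(res$removed$rule, "higher_degree")
  expect_setequal(res$retained, c("L1", "L2", "L3"))
  # brute force over single-sample removals confirms the hub is the
  # unique choice that clears the graph in one removal
  clears <- vapply(c("HUB", "L1", "L2", "L3"), function(drop) {
    e <- star[star$id1 != drop & star$id2 != drop, ]
    nrow(e) == 0
  }, logical(1))
  expect_equal(names(clears)[clears], "HUB")

  # equal status and degree: the lexicographically larger id goes
  res <- prune_related(c("A", "B"), k, carriers = c("A", "B"))
  expect_equal(res$retained, "A")
  expect_equal(res$removed$rule, "larger_id")
})

test_that("pruning output clears all above-threshold pairs and is order-invariant", {
  set.seed(7)
  ids <- sprintf("S%02d", 1:30)
  k <- data.frame(id1 = sample(ids, 25, replace = TRUE),
                  id2 = sample(ids, 25, replace = TRUE),
                  coefficient = runif(25, 0, 0.3))
  k <- k[k$id1 != k$id2, ]
  k <- k[!duplicated(paste(pmin(k$id1, k$id2), pmax(k$id1, k$id2))), ]
  carriers <- sample(ids, 8)
  res <- prune_related(ids, k, carriers = carriers)
  # exhaustive pair scan: no retained pair above threshold
  left <- k[k$coefficient > 0.0442 &
              k$id1 %in% res$retained & k$id2 %in% res$retained, ]
  expect_equal(nrow(left), 0)
  # permuting input rows changes nothing
  res2 <- prune_related(rev(ids), k[sample(nrow(k)), ], carriers = carriers)
  expect_setequal(res$retained, res2$retained)
})

test_that("conflicting duplicate kinship entries are rejected", {
  k <- data.frame(id1 = c("A", "B"), id2 = c("B", "A"),
                  coefficient = c(0.25, 0.125))
  expect_error(prune_related(c("A", "B"), k), "asymmetric")
  # consistent duplicates are fine
  k$coefficient <- c(0.25, 0.25)
  expect_equal(prune_related(c("A", "B"), k)$retained, "A")
})
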