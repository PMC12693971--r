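test_that("sample generation honors the configuration", {
  cohort <- generate_samples(single_cluster_config(100))
  s <- cohort$samples
  expect_equal(nrow(s), 100)
  expect_true(all(s$cluster_true == "EUR"))
  expect_true(all(s$age >= 40 & s$age <= 70))
  expect_false(anyDuplicated(s$sample_id) > 0)
  expect_true(all(s$sex %in% c("male", "female")))
  # no relatedness requested -> no kinship pairs emitted
  expect_equal(nrow(cohort$kinship), 0)
})

test_that("the seeding contract holds: same seed identical, new seed differs", {
  a <- generate_samples(single_cluster_config(200, seed = 7))
  b <- generate_samples(single_cluster_config(200, seed = 7))
  c <- generate_samples(single_cluster_config(200, seed = 8))
  expect_identical(a$samples, b$samples)
  expect_false(isTRUE(all.equal(a$samples$PC1, c$samples$PC1)))
})

test_that("invalid configurations are rejected", {
  expect_error(single_cluster_config(-5), "negative")
  expect_error(cohort_config(n_per_cluster = c(Oceania = 10)), "supercluster")
  expect_error(single_cluster_config(10, age_range = c(70, 40)), "min < max")
  expect_error(single_cluster_config(10, sex_ratio = 1.5), "sex_ratio")
})

test_that("kinship pairs are disjoint by default, a chain hub in chain mode", {
  cfg <- single_cluster_config(400, related_fraction = 0.2)
  k <- generate_samples(cfg)$kinship
  expect_equal(nrow(k), 40)  # 0.2 * 400 / 2 pairs
  expect_false(anyDuplicated(c(k$id1, k$id2)) > 0)
  expect_true(all(k$coefficient %in% c(0.25, 0.125, 0.0625)))

  chain <- generate_samples(single_cluster_config(100, related_fraction = 0.1,
                                                  kinship_mode = "chain"))
  expect_equal(length(unique(chain$kinship$id1)), 1)  # one hub
  expect_equal(nrow(chain$kinship), 9)
})

test_that("mislabeled samples become Uncategorized via nonresponse codes", {
  cfg <- single_cluster_config(2000, mislabel_fraction = 0.1)
  s <- generate_samples(cfg)$samples
  frac <- mean(s$supercluster == "Uncategorized")
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / 2000))
  expect_true(all(s$self_report[s$supercluster == "Uncategorized"] ==
                    "Do not know"))
})

test_that("planted genotype classes are realized exactly before QC noise", {
  cfg <- cohort_config(n_per_cluster = c(EUR = 150, AFR = 60, SAS = 0,
                                         EAS = 0, Uncategorized = 40),
                       seed = 21)
  cohort <- generate_samples(cfg)
  catalog <- rbind(asnvkit:::table1_sites()[c(3, 13), ], tktl1_site())
  pl <- rbind(
    plant("5", 178994530, "EUR", "het", 7),
    plant("5", 178994530, "AFR", "hom_alt", 2),
    plant("17", 29632016, "EUR", "het", 4),
    plant("X", 154315258, "EUR", "hemi_alt", 3),
    plant("X", 154315258, "Uncategorized", "het", 5))
  f <- tempfile(fileext = ".vcf")
  gen <- generate_genotypes(cohort, catalog, pl, file = f, seed = 22)
  expect_equal(gen$truth$count, pl$count)
  d <- discover_carriers(f, catalog, cohort$samples)
  agg <- d$census
  expect_equal(agg$het[agg$pos == 178994530 & agg$supercluster == "EUR"], 7)
  expect_equal(agg$hom_alt[agg$pos == 178994530 & agg$supercluster == "AFR"], 2)
  expect_equal(agg$hemi_alt[agg$pos == 154315258 & agg$supercluster == "EUR"], 3)
  expect_equal(sum(gen$dosage), 7 + 2 * 2 + 4 + 3 + 5)
})

test_that("an infeasible plant names the site and stratum", {
  cohort <- generate_samples(single_cluster_config(5))
  catalog <- asnvkit:::table1_sites()[13, ]
  pl <- plant("17", 29632016, "AFR", "het", 2)  # no AFR samples exist
  expect_error(
    generate_genotypes(cohort, catalog, pl, file = tempfile(), seed = 1),
    "17:29632016.*AFR")
})

test_that("QC-noise genotypes fail exactly their assigned filter", {
  cfg <- single_cluster_config(600, seed = 31)
  cohort <- generate_samples(cfg)
  catalog <- asnvkit:::table1_sites()[13, ]
  pl <- plant("17", 29632016, "EUR", "het", 200)
  f <- tempfile(fileext = ".vcf")
  gen <- generate_genotypes(cohort, catalog, pl,
                            qc_noise = list(low_gq = 0.05, low_dp = 0.05,
                                            skew_ab = 0.1),
                            file = f, seed = 32)
  d <- discover_carriers(f, catalog, cohort$samples)
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  gq <- as.numeric(vcfR::extract.gt(v, "GQ"))
  dp <- as.numeric(vcfR::extract.gt(v, "DP"))
  ad <- do.call(rbind, strsplit(as.character(vcfR::extract.gt(v, "AD")), ","))
  ab <- as.numeric(ad[, 2]) / (as.numeric(ad[, 1]) + as.numeric(ad[, 2]))
  gt <- as.character(vcfR::extract.gt(v, "GT"))
  fail_gq <- gq <= 20
  fail_dp <- dp <= 10
  fail_ab <- gt == "0/1" & (ab <= 0.25 | ab >= 0.75)
  # each injected genotype violates exactly one filter
  expect_true(all(fail_gq + fail_dp + fail_ab <= 1))
  expect_equal(sum(fail_gq), unname(gen$noise["low_gq"]))
  expect_equal(sum(fail_dp), unname(gen$noise["low_dp"]))
  expect_equal(sum(fail_ab), unname(gen$noise["skew_ab"]))
  # skewed-AB injection rate recovers within binomial error among hets
  n_het <- sum(gt == "0/1")
  p <- 0.1
  expect_lt(abs(sum(fail_ab) / n_het - p), 4 * sqrt(p * (1 - p) / n_het))
})

test_that("frequency-mode planting recovers Hardy-Weinberg class rates", {
  cfg <- single_cluster_config(20000, seed = 41)
  cohort <- generate_samples(cfg)
  catalog <- asnvkit:::table1_sites()[13, ]
  freqs <- data.frame(chrom = "17", pos = 29632016L, supercluster = "EUR",
                      freq = 0.05)
  f <- tempfile(fileext = ".vcf")
  gen <- generate_genotypes(cohort, catalog, freqs, file = f, seed = 42)
  n_het <- sum(gen$truth$count[gen$truth$class == "het"])
  p_het <- 2 * 0.05 * 0.95
  expect_lt(abs(n_het / 20000 - p_het), 4 * sqrt(p_het * (1 - p_het) / 20000))
})

test_that("fixture bundles are byte-identical across builds", {
  a <- build_fixture("table2_tktl1")
  b <- build_fixture("table2_tktl1")
  expect_identical(readLines(a$vcf), readLines(b$vcf))
  expect_identical(a$samples, b$samples)
  c1 <- build_fixture("catalog42")
  c2 <- build_fixture("catalog42")
  expect_identical(readLines(c1$path), readLines(c2$path))
  expect_error(build_fixture("not_a_fixture"), "registry")
})

test_that("phenotypes recover a null and a planted carrier effect", {
  cfg <- single_cluster_config(4000, seed = 51)
  cohort <- generate_samples(cfg)
  dosage <- rep(c(1, 0), c(400, 3600))
  # null effect: arms agree within sampling error
  p0 <- generate_phenotypes(cohort$samples, dosage, missing_rate = 0,
                            components = "continuous", seed = 52)
  d0 <- mean(p0$continuous$bmi[dosage == 1]) -
    mean(p0$continuous$bmi[dosage == 0])
  se <- 4.8 * sqrt(1 / 400 + 1 / 3600)
  expect_lt(abs(d0), 3 * se)
  # planted effect beta = 1 SD recovered within 2 SE
  eff <- set_beta(effect_spec(), "bmi", 1.0)
  p1 <- generate_phenotypes(cohort$samples, dosage, effects = eff,
                            missing_rate = 0, components = "continuous",
                            seed = 53)
  d1 <- mean(p1$continuous$bmi[dosage == 1]) -
    mean(p1$continuous$bmi[dosage == 0])
  expect_lt(abs(d1 - 1.0 * 4.8), 2 * se)
})

test_that("categorical level frequencies match their probabilities", {
  cfg <- single_cluster_config(5000, seed = 61)
  cohort <- generate_samples(cfg)
  eff <- effect_spec(categorical = list(
    toy = list(levels = c("a", "b", "c"), probs = c(0.5, 0.3, 0.2),
               carrier_logodds = 0)))
  p <- generate_phenotypes(cohort$samples, rep(0, 5000), effects = eff,
                           missing_rate = 0, components = "categorical",
                           seed = 62)
  freq <- table(p$categorical$toy) / 5000
  probs <- c(a = 0.5, b = 0.3, c = 0.2)
  for (lv in names(probs)) {
    expect_lt(abs(freq[[lv]] - probs[[lv]]),
              4 * sqrt(probs[[lv]] * (1 - probs[[lv]]) / 5000))
  }
})

test_that("unknown trait names in effect overrides are rejected", {
  expect_error(set_beta(effect_spec(), "not_a_trait", 1), "unknown trait")
  expect_error(effect_spec(categorical = list(
    bad = list(levels = c("x", "y"), probs = c(0.9, 0.2)))), "sum to 1")
})
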