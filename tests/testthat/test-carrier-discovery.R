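test_that("genotype QC applies the strict thresholds in order", {
  calls <- data.frame(
    site_filter = c("PASS", "PASS", "PASS", "RF", "PASS", "PASS"),
    gq = c(99, 99, 99, 99, 20, 99),
    dp = c(30, 10, 30, 5, 30, NA),
    ad_ref = c(15, 5, 23, 15, 15, 15),
    ad_alt = c(15, 5, 7, 15, 15, 15),
    zygosity = c("het", "het", "het", "het", "het", "het"),
    stringsAsFactors = FALSE
  )
  out <- qc_genotype(calls)
  expect_equal(out$qc_pass,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # DP = 10 fails the strict "> 10"; AB = 7/30 = 0.2333 fails the
  # exclusive 0.25 bound; failing FILTER dominates other failures;
  # GQ = 20 fails the strict "> 20"; a missing field is its own reason
  expect_equal(out$qc_fail_reason,
               c("none", "low_dp", "allele_balance", "site_filter",
                 "low_gq", "missing"))
  expect_equal(out$ab[3], 7 / 30)
})

test_that("allele-balance bounds are exclusive on both sides", {
  mk <- function(ad_ref, ad_alt) data.frame(
    site_filter = "PASS", gq = 99, dp = ad_ref + ad_alt,
    ad_ref = ad_ref, ad_alt = ad_alt, zygosity = "het",
    stringsAsFactors = FALSE)
  expect_false(qc_genotype(mk(30, 10))$qc_pass)  # AB = 0.25 exactly
  expect_false(qc_genotype(mk(10, 30))$qc_pass)  # AB = 0.75 exactly
  expect_true(qc_genotype(mk(29, 11))$qc_pass)
  # AB applies only to heterozygotes
  hom <- mk(0, 40); hom$zygosity <- "hom_alt"
  expect_true(qc_genotype(hom)$qc_pass)
})

test_that("zygosity classification is sex- and chromosome-aware", {
  expect_equal(classify_zygosity("1", "X", "male"), "hemi_alt")
  expect_equal(classify_zygosity("1/1", "X", "male"), "hemi_alt")
  expect_equal(classify_zygosity("0", "X", "male"), "hemi_ref")
  expect_equal(classify_zygosity("0/1", "X", "male"), "anomalous")
  expect_equal(classify_zygosity("0/1", "X", "female"), "het")
  expect_equal(classify_zygosity("0/1", "17", "female"), "het")
  expect_equal(classify_zygosity("1|0", "2", "male"), "het")
  expect_equal(classify_zygosity(c("0/0", "1/1", "./.", "garbage"),
                                 "5", "female"),
               c("hom_ref", "hom_alt", "missing", "missing"))
  # haploid calls outside male X are unexpected
  expect_equal(classify_zygosity("1", "5", "female"), "missing")
})

test_that("the TKTL1 fixture census reproduces the printed carrier counts", {
  fx <- build_fixture("table2_tktl1")
  d <- discover_carriers(fx$vcf, fx$catalog, fx$samples)
  expect_equal(d$n_unique_carriers, 62)
  zyg <- table(d$carriers$zygosity)
  expect_equal(unname(zyg[["het"]]), 45)
  expect_equal(unname(zyg[["hom_alt"]]), 1)
  expect_equal(unname(zyg[["hemi_alt"]]), 16)
  cen <- d$census
  expect_equal(cen$het[cen$supercluster == "EUR"], 12)
  expect_equal(cen$hemi_alt[cen$supercluster == "Uncategorized"], 11)
  expect_equal(cen$hom_alt[cen$supercluster == "Uncategorized"], 1)
  expect_equal(cen$het[cen$supercluster == "AFR"], 10)
})

test_that("male X genotypes are recovered under both VCF dialects", {
  samples <- mini_samples(c("A1", "A2", "A3"),
                          c("male", "male", "female"))
  catalog <- tktl1_site()
  pl <- rbind(plant("X", 154315258, "EUR", "hemi_alt", 1, sex = "male"),
              plant("X", 154315258, "EUR", "het", 1, sex = "female"))
  for (dialect in c("haploid", "diploid")) {
    f <- tempfile(fileext = ".vcf")
    generate_genotypes(samples, catalog, pl, file = f,
                       male_x_dialect = dialect, seed = 5)
    d <- discover_carriers(f, catalog, samples)
    expect_equal(d$n_unique_carriers, 2)
    expect_setequal(d$carriers$zygosity, c("hemi_alt", "het"))
  }
})

test_that("a QC-failing planted het is excluded from carriers and census classes", {
  samples <- mini_samples(c("B1", "B2", "B3"), "female")
  catalog <- asnvkit:::table1_sites()[13, ]  # the SSH2 site
  pl <- plant(catalog$chrom, catalog$pos, "EUR", "het", 1)
  f <- tempfile(fileext = ".vcf")
  # skew_ab = 1 forces every het genotype to fail allele balance
  generate_genotypes(samples, catalog, pl, qc_noise = list(skew_ab = 1),
                     file = f, seed = 6)
  d <- discover_carriers(f, catalog, samples)
  expect_equal(d$n_unique_carriers, 0)
  expect_equal(sum(d$census$qc_failed), 1)
  expect_equal(sum(d$census$het), 0)
  expect_equal(sum(d$census$hom_ref), 2)
})

test_that("all-reference fixtures yield zero carriers and full denominators", {
  samples <- mini_samples(sprintf("S%02d", 1:8),
                          rep(c("male", "female"), 4))
  catalog <- asnvkit:::table1_sites()[1:3, ]
  f <- tempfile(fileext = ".vcf")
  generate_genotypes(samples, catalog, NULL, file = f, seed = 7)
  d <- discover_carriers(f, catalog, samples)
  expect_equal(d$n_unique_carriers, 0)
  expect_equal(unique(d$census$n_queried[d$census$supercluster == "EUR"]), 8L)
  expect_equal(sum(d$census$hom_ref), 24)
})

test_that("catalog sites absent from the VCF are reported unqueryable", {
  samples <- mini_samples("C1", "female")
  catalog <- asnvkit:::table1_sites()[1:2, ]
  f <- tempfile(fileext = ".vcf")
  generate_genotypes(samples, catalog[1, ], NULL, file = f, seed = 8)
  d <- discover_carriers(f, catalog, samples)
  expect_equal(nrow(d$unqueryable), 1)
  expect_equal(d$unqueryable$pos, catalog$pos[2])
  expect_equal(d$unqueryable$reason, "absent_from_vcf")
})

test_that("multi-allelic records count only the archaic allele", {
  ids <- c("M1", "M2", "M3", "M4")
  samples <- mini_samples(ids, "female")
  # site 17:29632016 T>C; record carries ALT "A,C": archaic index 2
  rec <- paste(c("17", "29632016", ".", "T", "A,C", "100", "PASS", ".",
                 "GT:GQ:DP:AD",
                 "0/2:99:40:20,0,20",   # het for the archaic allele
                 "0/1:99:40:20,20,0",   # carries the other ALT -> missing
                 "0/0:99:40:40,0,0",
                 "1/2:99:40:0,20,20"),  # mixed ALTs -> missing
               collapse = "\t")
  f <- write_mini_vcf(rec, ids)
  catalog <- asnvkit:::table1_sites()[13, ]
  d <- discover_carriers(f, catalog, samples)
  expect_equal(d$n_unique_carriers, 1)
  expect_equal(d$carriers$sample_id, "M1")
  expect_equal(sum(d$census$missing), 2)
  expect_equal(sum(d$census$hom_ref), 1)
})

test_that("census buckets conserve the queried sample count", {
  fx <- build_fixture("table1")
  d <- discover_carriers(fx$vcf, fx$catalog, fx$samples)
  cen <- d$census
  total <- cen$hom_ref + cen$het + cen$hom_alt + cen$hemi_ref +
    cen$hemi_alt + cen$anomalous + cen$qc_failed + cen$missing
  expect_equal(total, cen$n_queried)
  per_site <- tapply(cen$n_queried, paste(cen$chrom, cen$pos), sum)
  expect_true(all(per_site == nrow(fx$samples)))
})

test_that("co-carriage grouping reports the planted linked-variant structure", {
  fx <- build_fixture("table1")
  d <- discover_carriers(fx$vcf, fx$catalog, fx$samples)
  expect_equal(d$n_unique_carriers, 104)
  expect_equal(d$n_carrier_instances, 118)
  co <- find_cocarriage(d)
  expect_equal(sum(co$genes == "SPAG5" & co$n_sites == 3), 5)
  expect_equal(sum(co$genes == "ADAM18" & co$n_sites == 2), 2)
  expect_equal(sum(co$genes == "KNL1" & co$n_sites == 2), 2)
  expect_equal(nrow(co), 9)
  # uniqueness relation: equality iff no co-carriage
  expect_equal(d$n_carrier_instances - d$n_unique_carriers,
               sum(co$n_sites - 1))
})

test_that("a sample carrying aSNVs in two genes is reported once with both genes", {
  samples <- mini_samples(c("X1", "X2"), "female")
  catalog <- asnvkit:::table1_sites()[c(13, 14), ]  # SSH2 and RFNG, both chr17
  pl <- rbind(
    plant(catalog$chrom[1], catalog$pos[1], "EUR", "het", 1, share_group = "g"),
    plant(catalog$chrom[2], catalog$pos[2], "EUR", "het", 1, share_group = "g"))
  f <- tempfile(fileext = ".vcf")
  generate_genotypes(samples, catalog, pl, file = f, seed = 11)
  co <- find_cocarriage(discover_carriers(f, catalog, samples))
  expect_equal(nrow(co), 1)
  expect_equal(co$genes, "SSH2,RFNG")
  # no multi-carriers -> empty output
  expect_equal(nrow(find_cocarriage(data.frame(
    sample_id = "Z", gene = "G", chrom = "1", pos = 1L,
    zygosity = "het", supercluster = "EUR", sex = "female"))), 0)
})
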