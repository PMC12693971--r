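# Seventeen aSNV sites with identified carriers, with their per-ancestry
# carrier census. `cluster` columns give heterozygous carrier counts
# unless noted via `class`.
table1_sites <- function() {
  data.frame(
    gene = c("KIF26B", "NOTO", "GRM6", "ADAM18", "ADAM18", "DCHS1",
             "KNL1", "KNL1", "ZNF106", "SPAG5", "SPAG5", "SPAG5",
             "SSH2", "RFNG", "GREB1L", "LMNB2", "C3"),
    chrom = c("1", "2", "5", "8", "8", "11", "15", "15", "15", "17",
              "17", "17", "17", "17", "18", "19", "19"),
    pos = c(245419603L, 73210883L, 178994530L, 39680099L, 39706833L,
            6633538L, 40620662L, 40623442L, 42450114L, 28592016L,
            28592759L, 28598560L, 29632016L, 82049104L, 21505418L,
            2434035L, 6685100L),
    ref = c("A", "T", "G", "C", "G", "C", "G", "A", "C", "G", "C", "A",
            "T", "G", "A", "A", "G"),
    archaic = c("G", "A", "T", "T", "A", "T", "A", "G", "T", "C", "T",
                "G", "C", "A", "G", "T", "A"),
    status = "fixed_af1",
    stringsAsFactors = FALSE
  )
}

# The 42-site catalog stand-in: the 17 carrier sites, the four sites
# removed during curation, the single non-PASS site, and 20 synthetic
# placeholder sites (two placeholder genes carry two sites each, so the
# curated catalog spans 33 distinct genes). Placeholders are synthetic
# padding, not positions from any published table.
catalog42 <- function() {
  excluded <- data.frame(
    gene = c("C1orf159", "DNHD1", "DNMT3L", "TBC1D3"),
    chrom = c("1", "11", "21", "17"),
    pos = c(1091245L, 6534188L, 44251169L, 38202786L),
    ref = "A", archaic = "G", status = "fixed_af1",
    stringsAsFactors = FALSE
  )
  non_pass <- data.frame(gene = "PLACEHOLDER_19", chrom = "9",
                         pos = 6606647L, ref = "G", archaic = "A",
                         status = "fixed_af1", stringsAsFactors = FALSE)
  pad_genes <- c(rep("PLACEHOLDER_01", 2), rep("PLACEHOLDER_02", 2),
                 sprintf("PLACEHOLDER_%02d", 3:18))
  pads <- data.frame(
    gene = pad_genes,
    chrom = as.character(c(3, 3, 4, 4, rep(c(5, 6, 7, 10, 12, 13, 14, 16,
                                             20, 22, 2, 3, 4, 6, 7, 10), 1))),
    pos = as.integer(3000001 + 137 * seq_along(pad_genes)),
    ref = "A", archaic = "G", status = "fixed_af1",
    stringsAsFactors = FALSE
  )
  validate_catalog(rbind(table1_sites(), non_pass, pads, excluded))
}

# Deterministic block of fixture samples: all QC flags pass. With
# pc_dist = "uniform", PCs lie within +/- pc_spread of the centroid
# (used for fixture carriers, guaranteeing they sit centrally in their
# cluster so caliper-eligible controls are ample).
fixture_samples <- function(ids, supercluster, sex, age,
                            pc_centroid = NULL, pc_spread = 3,
                            pc_dist = c("normal", "uniform"),
                            strict_label = "none") {
  pc_dist <- match.arg(pc_dist)
  n <- length(ids)
  if (is.null(pc_centroid)) {
    pc_centroid <- default_pc_centroids()[supercluster[1], ]
  }
  noise <- if (pc_dist == "uniform") {
    matrix(runif(4 * n, -1, 1), ncol = 4)
  } else {
    matrix(rnorm(4 * n), ncol = 4)
  }
  pcs <- noise * pc_spread + matrix(pc_centroid, n, 4, byrow = TRUE)
  data.frame(
    sample_id = ids, sex = rep_len(sex, n), age = rep_len(age, n),
    self_report = NA_character_,
    supercluster = rep_len(supercluster, n),
    cluster_true = rep_len(supercluster, n),
    strict_label = rep_len(strict_label, n),
    PC1 = pcs[, 1], PC2 = pcs[, 2], PC3 = pcs[, 3], PC4 = pcs[, 4],
    qc_sex_mismatch = FALSE, qc_aneuploidy = FALSE,
    qc_het_outlier = FALSE, qc_high_missingness = FALSE,
    stringsAsFactors = FALSE
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  qnorm(runif(n, plo, phi)) * sd + mean
}

empty_kinship <- function() {
  data.frame(id1 = character(), id2 = character(), coefficient = numeric(),
             stringsAsFactors = FALSE)
}

fixture_table2 <- function(dir) {
  catalog <- validate_catalog(tktl1_site())
  with_seed(20202, {
    # Carrier counts are exact; reference-genotype strata are the printed
    # denominators scaled down by ~1/500.
    females <- c(SAS = 8, EAS = 3, EUR = 460 + 12, AFR = 6 + 10,
                 Uncategorized = 15 + 23 + 1)
    males <- c(SAS = 9, EAS = 1, EUR = 387 + 4, AFR = 5 + 1,
               Uncategorized = 12 + 11)
    blocks <- list()
    idx <- 0
    for (cl in names(females)) {
      for (sx in c("female", "male")) {
        k <- if (sx == "female") females[[cl]] else males[[cl]]
        if (!k) next
        ids <- sprintf("S%06d", idx + seq_len(k))
        idx <- idx + k
        blocks[[length(blocks) + 1]] <- fixture_samples(
          ids, cl, sx, age = rtruncnorm1(k, 57, 8, 40, 70))
      }
    }
    samples <- do.call(rbind, blocks)
  })
  x <- "X"; p <- 154315258
  plant_spec <- rbind(
    plant(x, p, "Uncategorized", "hom_alt", 1),
    plant(x, p, "EUR", "hemi_alt", 4),
    plant(x, p, "AFR", "hemi_alt", 1),
    plant(x, p, "Uncategorized", "hemi_alt", 11),
    plant(x, p, "EUR", "het", 12),
    plant(x, p, "AFR", "het", 10),
    plant(x, p, "Uncategorized", "het", 23)
  )
  vcf <- file.path(dir, "table2_tktl1.vcf")
  gen <- generate_genotypes(samples, catalog, plant_spec, file = vcf,
                            seed = 20212)
  list(name = "table2_tktl1", catalog = catalog, samples = samples,
       kinship = empty_kinship(), vcf = vcf, plant = plant_spec,
       truth = gen$truth, dosage = gen$dosage, dir = dir)
}

fixture_table1 <- function(dir) {
  catalog <- validate_catalog(table1_sites())
  with_seed(20201, {
    background <- c(SAS = 17, EAS = 4, EUR = 848, AFR = 10,
                    Uncategorized = 27)
    carriers <- c(SAS = 0, EAS = 13, EUR = 33, AFR = 19,
                  Uncategorized = 39)
    blocks <- list()
    idx <- 0
    for (cl in names(background)) {
      k <- background[[cl]] + carriers[[cl]]
      ids <- sprintf("S%06d", idx + seq_len(k))
      idx <- idx + k
      sex <- ifelse(runif(k) < 0.54, "female", "male")
      blocks[[length(blocks) + 1]] <- fixture_samples(
        ids, cl, sex, age = rtruncnorm1(k, 57, 8, 40, 70))
    }
    samples <- do.call(rbind, blocks)
  })
  s <- table1_sites()
  at <- function(g, i = 1) which(s$gene == g)[i]
  P <- function(row, cl, class, count, share = NA) {
    plant(s$chrom[row], s$pos[row], cl, class, count, share_group = share)
  }
  plant_spec <- rbind(
    P(at("KIF26B"), "AFR", "het", 2), P(at("KIF26B"), "Uncategorized", "het", 3),
    P(at("NOTO"), "EAS", "het", 3), P(at("NOTO"), "Uncategorized", "het", 3),
    P(at("GRM6"), "Uncategorized", "hom_alt", 1),
    P(at("GRM6"), "EUR", "het", 3), P(at("GRM6"), "AFR", "het", 12),
    P(at("GRM6"), "Uncategorized", "het", 28),
    P(at("ADAM18", 1), "EAS", "het", 2, "adam18"),
    P(at("ADAM18", 1), "EUR", "het", 1),
    P(at("ADAM18", 2), "EAS", "het", 2, "adam18"),
    P(at("DCHS1"), "Uncategorized", "het", 1),
    P(at("KNL1", 1), "EAS", "het", 1, "knl1_eas"),
    P(at("KNL1", 1), "EUR", "het", 3),
    P(at("KNL1", 1), "Uncategorized", "het", 1, "knl1_unc"),
    P(at("KNL1", 1), "Uncategorized", "het", 1),
    P(at("KNL1", 2), "EAS", "het", 1, "knl1_eas"),
    P(at("KNL1", 2), "Uncategorized", "het", 1, "knl1_unc"),
    P(at("ZNF106"), "EAS", "het", 4), P(at("ZNF106"), "Uncategorized", "het", 1),
    P(at("SPAG5", 1), "AFR", "het", 5, "spag5"),
    P(at("SPAG5", 2), "AFR", "het", 5, "spag5"),
    P(at("SPAG5", 2), "EUR", "het", 1),
    P(at("SPAG5", 3), "AFR", "het", 5, "spag5"),
    P(at("SSH2"), "EUR", "het", 21),
    P(at("RFNG"), "EUR", "het", 2),
    P(at("GREB1L"), "EAS", "het", 1),
    P(at("LMNB2"), "EAS", "het", 2),
    P(at("C3"), "EUR", "het", 2)
  )
  vcf <- file.path(dir, "table1.vcf")
  gen <- generate_genotypes(samples, catalog, plant_spec, file = vcf,
                            seed = 20211)
  list(name = "table1", catalog = catalog, samples = samples,
       kinship = empty_kinship(), vcf = vcf, plant = plant_spec,
       truth = gen$truth, dosage = gen$dosage, dir = dir)
}

fixture_ssh2 <- function(dir, pool_seed = NULL) {
  site <- table1_sites()[table1_sites()$gene == "SSH2", ]
  with_seed(20203, {
    ids <- sprintf("C%02d", 1:21)
    sex <- c(rep("female", 14), rep("male", 5), "female", "male")
    strict <- c(rep("White_British", 20), "none")
    carriers <- fixture_samples(ids, "EUR", sex,
                                age = rtruncnorm1(21, 59.42, 7.94, 48, 68),
                                strict_label = strict)
    carriers$carrier <- TRUE
  })
  kinship <- data.frame(id1 = "C19", id2 = "C20", coefficient = 0.25,
                        stringsAsFactors = FALSE)
  with_seed(pool_seed %||% 20303, {
    n_pool <- 120000
    pids <- sprintf("P%06d", seq_len(n_pool))
    psex <- ifelse(seq_len(n_pool) <= 66000, "female", "male")
    pool <- fixture_samples(pids, "EUR", psex,
                            age = runif(n_pool, 45.5, 70.5),
                            strict_label = "White_British")
    pool$carrier <- FALSE
  })
  all_samples <- rbind(carriers, pool)
  dosage <- setNames(c(rep(1, nrow(carriers)), rep(0, nrow(pool))),
                     all_samples$sample_id)
  phen <- generate_phenotypes(all_samples, dosage,
                              components = c("continuous", "categorical"),
                              seed = 20313)
  list(name = "ssh2_cohort", catalog = validate_catalog(site),
       samples = all_samples, carriers = carriers, pool = pool,
       kinship = kinship, vcf = NULL, phenotypes = phen, dir = dir)
}

fixture_tktl1_imaging <- function(dir, pool_seed = NULL) {
  with_seed(20204, {
    ids <- sprintf("T%02d", 1:5)
    sex <- c("female", rep("male", 4))
    carriers <- fixture_samples(ids, "EUR", sex,
                                age = rtruncnorm1(5, 71.2, 6.14, 65, 78))
    carriers$carrier <- TRUE
  })
  with_seed(pool_seed %||% 20304, {
    n_pool <- 15000
    pids <- sprintf("P%06d", seq_len(n_pool))
    psex <- ifelse(seq_len(n_pool) <= 5000, "female", "male")
    pool <- fixture_samples(pids, "EUR", psex, age = runif(n_pool, 62, 80))
    pool$carrier <- FALSE
  })
  all_samples <- rbind(carriers, pool)
  dosage <- setNames(c(rep(1, 5), rep(0, n_pool)), all_samples$sample_id)
  phen <- generate_phenotypes(all_samples, dosage, components = "parcels",
                              seed = 20314)
  list(name = "tktl1_imaging", catalog = validate_catalog(tktl1_site()),
       samples = all_samples, carriers = carriers, pool = pool,
       kinship = empty_kinship(), vcf = NULL, phenotypes = phen, dir = dir)
}

fixture_tktl1_qualification <- function(dir, pool_seed = NULL) {
  cl_of <- c(rep("AFR", 8), rep("EUR", 7), rep("Uncategorized", 6),
             rep("AFR", 3), rep("EUR", 3), rep("Uncategorized", 3))
  with_seed(20205, {
    ids <- sprintf("Q%02d", 1:30)
    sex <- c(rep("female", 21), rep("male", 9))
    blocks <- lapply(seq_len(30), function(i) {
      fixture_samples(ids[i], cl_of[i], sex[i],
                      age = rtruncnorm1(1, 54.4, 7.67, 42, 66),
                      pc_spread = 1.5, pc_dist = "uniform")
    })
    carriers <- do.call(rbind, blocks)
    carriers$carrier <- TRUE
  })
  with_seed(pool_seed %||% 20305, {
    sizes <- c(AFR = 6000, EUR = 6000, Uncategorized = 8000)
    idx <- 0
    blocks <- list()
    for (cl in names(sizes)) {
      k <- sizes[[cl]]
      pids <- sprintf("P%06d", idx + seq_len(k))
      idx <- idx + k
      psex <- ifelse(seq_len(k) %% 2 == 0, "female", "male")
      blocks[[length(blocks) + 1]] <- fixture_samples(
        pids, cl, psex, age = runif(k, 42, 67), pc_spread = 2)
    }
    pool <- do.call(rbind, blocks)
    pool$carrier <- FALSE
  })
  all_samples <- rbind(carriers, pool)
  dosage <- setNames(c(rep(1, 30), rep(0, nrow(pool))),
                     all_samples$sample_id)
  phen <- generate_phenotypes(all_samples, dosage, components = "categorical",
                              seed = 20315)
  list(name = "tktl1_qualification",
       catalog = validate_catalog(tktl1_site()),
       samples = all_samples, carriers = carriers, pool = pool,
       kinship = empty_kinship(), vcf = NULL, phenotypes = phen, dir = dir)
}

fixture_catalog42 <- function(dir) {
  catalog <- catalog42()
  path <- file.path(dir, "catalog42_synthetic.tsv")
  out <- as.data.frame(catalog)
  names(out)[names(out) == "pos"] <- "pos_hg38"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(name = "catalog42", catalog = catalog, path = path, dir = dir)
}

FIXTURE_REGISTRY <- c("table1", "table2_tktl1", "ssh2_cohort",
                      "tktl1_imaging", "tktl1_qualification", "catalog42")

#' Build a named study fixture
#'
#' Deterministically realizes one of the packaged study configurations
#' as a full synthetic data bundle (catalog, samples, kinship, VCF
#' and/or phenotypes as applicable). Fixed internal seeds make repeated
#' builds byte-identical. Registry:
#'
#' * `table1`: the 17-site carrier census (per-ancestry heterozygote and
#'   homozygote counts, including the SPAG5 / ADAM18 / KNL1 co-carriage
#'   structure), with reference-genotype strata scaled down ~500x.
#' * `table2_tktl1`: the TKTL1 chrX census (45 het + 1 hom female, 16
#'   hemizygous male carriers; scaled reference strata) as a VCF.
#' * `ssh2_cohort`: 21 SSH2 carriers (20 White British, one related
#'   carrier pair) plus a 120,000-strong eligible noncarrier pool.
#' * `tktl1_imaging`: 5 imaging carriers (1 female) plus a 15,000 pool
#'   with cortical parcel phenotypes.
#' * `tktl1_qualification`: 30 carriers (21 female; 11 AFR / 10 EUR / 9
#'   Uncategorized) plus a 20,000 pool with qualification phenotypes.
#' * `catalog42`: the 42-site catalog stand-in (see note below).
#'
#' The `catalog42` bundle reproduces the printed carrier sites and
#' curation targets and pads the remainder with synthetic placeholder
#' sites; it is a stand-in, sufficient for count-level checks, not the
#' published supplementary table.
#'
#' @param name Fixture name from the registry.
#' @param dir Output directory for files (created if needed); defaults
#'   to a fresh temporary directory.
#' @param pool_seed Optional integer overriding the fixed seed of the
#'   noncarrier *pool* of the matching fixtures, so matched-cohort runs
#'   can be replicated over independent pools. Carrier configurations
#'   always use the fixed internal seed.
#' @return A named list bundle; components vary by fixture (see above).
#' @export
build_fixture <- function(name, dir = NULL, pool_seed = NULL) {
  if (!name %in% FIXTURE_REGISTRY) {
    stopf("unknown fixture '%s'; registry: %s", name,
          paste(FIXTURE_REGISTRY, collapse = ", "))
  }
  if (is.null(dir)) dir <- tempfile("asnv_fixture_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         table1 = fixture_table1(dir),
         table2_tktl1 = fixture_table2(dir),
         ssh2_cohort = fixture_ssh2(dir, pool_seed),
         tktl1_imaging = fixture_tktl1_imaging(dir, pool_seed),
         tktl1_qualification = fixture_tktl1_qualification(dir, pool_seed),
         catalog42 = fixture_catalog42(dir))
}
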