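# asnvkit

Tools for studying **carriers of archaic single-nucleotide variants
(aSNVs)** — genomic positions where archaic hominins (Neanderthals,
Denisovans) carry the ancestral allele while present-day humans carry a
derived allele at or near fixation — in biobank-scale exome data.

Large biobanks make it possible to find the rare living individuals who
still carry the ancestral allele at such positions and to ask whether
their phenotypes deviate from matched noncarriers. The raw data for such
studies sit behind restricted access, so this package pairs every
analysis stage with a seeded synthetic-cohort generator that reproduces
the statistical structure the pipeline assumes; every stage is testable
offline, end to end.

## What the package does

1. **Catalog curation** (`load_catalog()`, `curate_catalog()`): validate
   a table of aSNV sites (gene, chromosome, hg38 position, reference and
   archaic alleles) and apply exclusion/inclusion rules with a full
   exclusion log.
2. **Carrier discovery** (`discover_carriers()`): query each site in a
   VCF under strict genotype QC — site FILTER `PASS`, genotype quality
   GQ > 20, depth DP > 10, and allele balance 0.25 < AB < 0.75 for
   heterozygotes — with sex-aware chromosome-X zygosity (male hemizygote
   handling for both haploid `1` and diploid `1/1` dialects), and
   tabulate per-ancestry genotype censuses. `find_cocarriage()` reports
   samples carrying several aSNVs.
3. **Ancestry and relatedness** (`map_self_report()`, `fit_pc_boxes()`,
   `assign_supercluster()`, `prune_related()`): harmonize self-reported
   ancestry with genetic principal components via per-cluster
   hard-cutoff boxes, and prune related pairs (kinship coefficient
   > 0.0442) with carrier-prioritized greedy removal.
4. **Matched cohorts** (`match_cohort()` with `match_preset()`): build
   noncarrier control arms under exact constraints (sex, ancestry
   label) and calipers (age ± 2.5 years, PC1/PC2 ± 2.5), at a fixed
   ratio of globally unique controls per carrier.
5. **Phenotype comparison** (`summarize_continuous()`,
   `summarize_categorical()`, `wilson_interval()`,
   `highest_qualification()`, `frontal_composites()`): place carrier
   values against the matched control distribution; Wilson 95% score
   intervals for categorical proportions; frontal-lobe composite
   surface area (sum over 11 parcels) and mean cortical thickness per
   hemisphere.
6. **Association power** (`power_additive()`, `detectable_beta()`): for
   a variant with minor allele frequency *f* genotyped in *N*
   individuals with standardized additive effect β, the association
   chi-square statistic (1 df) has noncentrality

   λ = 2 f (1 − f) N β²,

   and power is the upper tail of the noncentral chi-square at the
   (1 − α) central quantile. `detectable_beta()` inverts this to the
   smallest effect detectable at a target power.

## Worked example

```r
library(asnvkit)

# 1. Curate the 42-site catalog down to the analysis set
cat42 <- build_fixture("catalog42")$catalog
cur   <- curate_catalog(cat42, default_exclusions(), tktl1_site())
nrow(cur$retained); cur$n_genes
#> [1] 39
#> [1] 33

# 2. Discover TKTL1 carriers in a synthetic cohort realizing the
#    published genotype census (chrX:154315258 G>A)
fx <- build_fixture("table2_tktl1")
d  <- discover_carriers(fx$vcf, fx$catalog, fx$samples)
d
#> aSNV discovery: 62 unique carrier(s), 62 carrier instance(s) at 1 queryable site(s)
table(d$carriers$zygosity)
#> hemi_alt      het  hom_alt
#>       16       45        1

# 3. Match noncarrier controls to the pruned SSH2 carrier arm
fs      <- build_fixture("ssh2_cohort")
strict  <- fs$carriers[fs$carriers$strict_label == "White_British", ]
pruned  <- prune_related(strict, fs$kinship, carriers = strict$sample_id)
cohort  <- match_cohort(pruned$retained, fs$pool, match_preset("ssh2"))
summarize_cohort(cohort)
#>       arm     n n_female age_mean   age_sd sd_degenerate
#> 1 carrier    19       14 58.49690 4.495589         FALSE
#> 2 control 39501    29106 58.50526 4.482896         FALSE

# 4. Smallest detectable effect for the SSH2 design
detectable_beta(f = 0.00005, N = 423887, alpha = 0.05 / 12,
                target_power = 0.8)
#> [1] 0.5693699
```

The 62 unique carriers split into 45 heterozygous and 1 homozygous
female plus 16 hemizygous male carriers; the matched SSH2 cohort has
exactly 19 × 2079 = 39,501 distinct controls, 14 × 2079 = 29,106 of them
female. The detectable-β value says the 423,887-sample design only has
80% power for effects of about 0.57 phenotype SD per allele or larger —
rare-variant carrier comparisons at these allele frequencies can only
rule out large effects.

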