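---
title: "Methods: archaic-variant carrier discovery and phenotype comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archaic-variant carrier discovery and phenotype comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asnvkit)
```

# The problem

A small number of genomic positions distinguish present-day humans from
archaic hominins: at an archaic single-nucleotide variant (aSNV) the
ancestral allele is shared with Neanderthals/Denisovans while the
derived allele is at or near fixation in modern populations. In a
biobank with exome sequencing, a handful of living participants still
carry the ancestral ("archaic") allele at some of these positions.
`asnvkit` implements the full analysis chain for such a study: curate
the site catalog, find carriers under genotype quality control, place
them in ancestry superclusters, remove close relatives, build matched
noncarrier cohorts, summarize carrier phenotypes against the matched
distribution, and quantify what effect sizes the design could have
detected.

Because the underlying biobank genotypes and phenotypes are access
controlled, the package ships a synthetic-cohort generator that
reproduces the *statistical structure* the pipeline assumes. All
numerical claims made by the package are computed by its test suite and
acceptance script on these synthetic cohorts, never copied from
external data.

# Carrier discovery

## Genotype QC

A genotype at a catalog site contributes to the census only if

* the site-level `FILTER` is `PASS`;
* genotype quality GQ > 20 (strict);
* read depth DP > 10 (strict);
* for heterozygotes, allele balance AB = alt/(ref+alt) satisfies
  0.25 < AB < 0.75, both bounds exclusive.

The first failing rule, in the fixed order site filter → low GQ → low
DP → allele balance, is recorded as the reason; a missing genotype or
missing FORMAT field fails with reason `missing`. The GQ threshold is
applied per genotype: the upstream pipeline's printed "QUAL" cutoff is
a per-genotype quantity in the genotype-QC tooling this mirrors, not
the site QUAL column, so the site-level check is off by default.
Because the comparisons are strict, DP = 10 and AB = 0.25 fail; the
test suite pins these boundaries.

## Sex-aware zygosity on chromosome X

Males are hemizygous on X. Both VCF dialects are understood: haploid
(`0`, `1`) and diploid-coded (`0/0`, `1/1`) male genotypes map to
`hemi_ref`/`hemi_alt`. A heterozygous male X call cannot arise from a
clean hemizygous locus; it is classified `anomalous`, excluded from
censuses and logged rather than aborting the run, since real exome
data contain pseudoautosomal and calling artifacts. At multi-allelic
records only the configured archaic allele is considered; genotypes
involving any other alternate allele are treated as missing for this
analysis.

A **carrier** is any QC-passing genotype with at least one archaic
allele (`het`, `hom_alt`, `hemi_alt`). Census buckets (five zygosity
classes, anomalous, QC-failed, missing) are mutually exclusive and sum
to the queried sample count per site — a conservation law asserted in
the tests. Per-site denominators differ because QC attrition is
per-site.

# Ancestry superclusters

Self-reported ancestry codes map deterministically to EUR, AFR, SAS,
EAS; mixed, other and nonresponse codes map to `Uncategorized`. The
genetic side uses the first four principal components. The cutoff
constants used by the original analysis are not published, so the
package *fits* per-cluster boxes: for each labeled cluster and each PC,
the `[q, 1−q]` empirical quantile interval (default q = 0.01). This
reproduces hard-cutoff assignment behavior without external constants.
A labeled sample keeps its cluster only while inside its own box;
otherwise it becomes Uncategorized. An Uncategorized sample inside
exactly one cluster's box is reassigned; inside zero or several boxes
it stays Uncategorized — the ambiguous case is deliberately
conservative, and a sample is never moved directly between two named
clusters.

# Relatedness pruning

Kinship coefficients are consumed as precomputed inputs (as biobanks
distribute them); 0.0442 is the conventional third-degree bound and the
default threshold. The source text prints both "0.0442" and "0.042" for
this bound; the package exposes a single configurable threshold rather
than guessing which figure is the typo. Pruning is greedy: while any
retained pair exceeds the threshold, remove one endpoint chosen by (1)
noncarrier before carrier, (2) higher degree in the remaining
above-threshold graph, (3) lexicographically larger sample id. The
priority order is stated by the study; the greedy algorithm and the
deterministic tie-break are this package's choices, pinned by tests
(including a star-graph case where brute force confirms the hub is the
unique one-removal solution).

# Matched cohorts

A matching design (`match_spec()`) is a ratio of unique controls per
carrier, a set of exact fields, and calipers. The shipped presets
encode the three study designs:

| preset | ratio | exact | calipers |
|---|---|---|---|
| `ssh2` | 2079 | sex, strict label | age ± 2.5 y |
| `tktl1_imaging` | 429 | sex | age ± 2.5 y |
| `tktl1_sensitivity` | 10 | sex | age ± 2.5 y, PC1/PC2 ± 2.5 |
| `tktl1_qualification` | 20 | sex | age ± 2.5 y, PC1/PC2 ± 2.5 |

The age tolerance of the 2079:1 design is not printed; the default
caliper of 2.5 years mirrors the calipers the study states for the
other designs and is configurable. Matching is greedy and sequential:
carriers in ascending id order each consume their best-ranked remaining
candidates (ranked by |Δage|, then Euclidean PC1/PC2 distance, then
id), and consumed controls leave the pool, so the control arm is
globally unique by construction. A flow-based optimal assignment is out
of scope; with the ample pools used here the greedy scheme always
attains ratio × carriers controls, and it fails loudly — naming the
carrier and the shortfall — rather than silently emitting a partial
cohort. Arm summaries use the sample SD (n−1); a single-sample arm
reports SD 0 and is flagged.

# Phenotype summaries

Continuous traits: the carrier mean is reported with a 95% confidence
interval from the t distribution with n−1 df (the method behind the
study's printed interval is unstated; t is the conservative
small-sample default, and a normal-quantile option exists). Control
distributions are summarized by linear-interpolation quartiles (R type
7 — quartile conventions differ enough across software to be worth
pinning) and Tukey 1.5 × IQR whisker bounds. Each carrier's percentile
rank is the fraction of controls strictly below, with midpoint
correction for ties.

Categorical traits first merge the three nonresponse options ("Do not
know", "Do not want to answer", "None of the above") into one level
with additive counts. Qualification reports are multi-response; each
individual is reduced to the highest reported level under a total
order (college/university degree first, combined nonresponse last).
The exact ordinal ranking is not printed in the source; the default
here is recorded in `qualification_levels()` and configurable.

Binomial proportions carry Wilson score intervals, implemented in
closed form: center $(\hat p + z^2/2n)/(1 + z^2/n)$, half-width
$(z/(1+z^2/n))\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}$, clipped to
[0, 1]. The tests compare it against an independent numeric inversion
of the score test (via `uniroot`) to ten significant digits.

Frontal-lobe composites per hemisphere: surface area is the sum over
the 11 Desikan–Killiany frontal parcels (mm²), cortical thickness the
unweighted mean over the same parcels (mm). "Averaged" thickness is
taken literally as unweighted; an area-weighted mean would be the
alternative but is not the default because no weights are stated. A
missing parcel voids that sample × hemisphere composite and is logged.

# Power model

For an additive allelic effect β (phenotype SD per allele) at minor
allele frequency *f* in *N* individuals, the 1-df association
chi-square has noncentrality λ = 2f(1−f)Nβ². Power is the exact upper
tail of the noncentral chi-square at the (1−α) central quantile; the
normal approximation Φ(√λ − z) + Φ(−√λ − z) is available for
cross-checks. `detectable_beta()` inverts power in β by bisection on a
geometrically grown bracket to relative tolerance 1e−9; tests verify
round-trip consistency to 1e−6 and the closed-form 1/√N scaling. The
source for this calculation cites course material rather than printing
a formula; the package fixes the standard additive quantitative-trait
model above and documents it. Under this model with f = 5 × 10⁻⁵,
N = 423,887 and α = 0.05/12, the computed detectable effect at 80%
power is within about 1.3% of the study's printed value; the residual
difference is consistent with an approximation or rounding choice in
the original calculator and is reported as computed, not adjusted.
Monte-Carlo agreement (10⁵ noncentral chi-square draws) is asserted
within three binomial standard errors.

# The synthetic-cohort generator

`generate_samples()` draws ancestry clusters as isotropic Gaussians in
PC1–PC4 around separated centroids — only box-assignment behavior
matters downstream, so realistic PC geometry is deliberately out of
scope. Ages default to Normal(57, 8) years truncated to [40, 70],
mirroring the age structure of a middle-aged volunteer biobank; a
uniform option exists for flat pools. Sex is Bernoulli (default 54%
female). Kinship pairs are disjoint by default; a `chain` mode creates
one hub related to several others to exercise degree-prioritized
pruning. Sample-QC flags are independent Bernoulli draws at small
configurable rates. Nonresponse codes are emitted with their literal
labels so the downstream merge rule is exercised verbatim.

`generate_genotypes()` realizes planted genotype classes *exactly*
(counts per site × supercluster × sex stratum), with co-carriage
planted via share groups (the same individuals reused across sites,
emulating tightly linked alleles inherited together). QC noise flips
quality fields, never genotype classes, and each injected genotype
violates exactly one filter: low GQ (0–20), low DP (4–10 with allele
depths rescaled to keep AB valid), or skewed AB (15%/85%) for
heterozygotes. Planted censuses therefore equal the discovered census
exactly at zero noise — the round-trip law in the tests. Male X
genotypes can be written haploid or diploid. Hemizygous male dosage
defaults to 1 allele (configurable to 2), a modeling choice the source
never makes explicit.

`generate_phenotypes()` draws continuous traits Normal(μ + β·σ·dosage,
σ) — β in SD units per archaic-allele dosage — categorical traits from
level probabilities (optional carrier log-odds shift on the first
level), multi-response qualification sets, and per-parcel cortical
areas/thicknesses (area SD 8% of the parcel mean, thickness SD 0.12
mm). No distributional parameters for any trait are published, so all
generator defaults are package choices of plausible magnitudes, not
claims about the source data.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (co-carriage is planted, not evolved), archaic
introgression tracts, realistic PC geometry, genotype-calling error
correlated with sequence context, and phenotype correlations across
traits. Passing tests therefore demonstrate that the *pipeline logic*
is correct under the stated statistical assumptions, not that it would
be robust to every artifact of real exome data.

## Fixtures

`build_fixture()` deterministically realizes the printed study
configurations (fixed internal seeds; repeated builds are
byte-identical):

* `table1` / `table2_tktl1`: the published per-ancestry carrier
  censuses with carrier counts exact and reference-genotype strata
  scaled down ~500× (the full ~450,000-sample denominators would add
  nothing to count-level checks);
* `ssh2_cohort`: 21 carriers (20 strict-labeled, one related pair) and
  a 120,000 noncarrier pool (ages uniform on [45.5, 70.5]) sized so
  every carrier retains 2079 unique in-caliper controls for any pool
  seed;
* `tktl1_imaging`: 5 carriers (1 female, ages ~N(71.2, 6.14) truncated
  to [65, 78]) and a 15,000 pool;
* `tktl1_qualification`: 30 carriers (21 female; 11 AFR / 10 EUR / 9
  Uncategorized) and a 20,000 pool; carrier PCs are drawn uniformly
  within ±1.5 of the cluster centroid while the pool is Normal with
  SD 2, so PC-caliper-eligible controls are ample for every carrier;
* `catalog42`: a 42-site catalog stand-in — the 17 published carrier
  sites, the 4 curation-excluded sites, the single non-PASS site, and
  20 synthetic placeholder sites (two placeholder genes hold two sites
  each so the curated set spans 33 distinct genes). The full published
  supplementary site list is not reproduced; the stand-in suffices for
  all count-level checks and is labeled synthetic.

# Problem sizes and numerical choices

The test suite and acceptance script run on cohorts of roughly 10²–10⁵
samples: discovery fixtures around 1,000 samples × ≤17 sites, matching
pools of 15,000–120,000, Monte-Carlo checks at 10⁵ replicates, and
parameter-recovery cohorts of 4,000–5,000 — sizes chosen so each
statistical check has comfortable resolution while the whole suite
runs in minutes on one core. All RNG flows through a seed-preserving
wrapper that pins the Mersenne-Twister/Inversion/Rejection kinds, so
fixed seeds give bit-identical output across sessions. Bisection
tolerances (1e−9 relative for detectable β) and the exclusive QC
bounds are pinned by tests. Ties: percentile ranks use midpoint
correction; matching breaks ties by sample id; pruning breaks ties by
removing the lexicographically larger id.

# Known limitations

* Greedy matching is order-dependent when candidate sets overlap; the
  processing order (ascending carrier id) makes it deterministic, and
  order invariance holds when candidate sets are disjoint.
* PC boxes fitted at q = 0.01 are a reconstruction of unpublished
  cutoffs; cluster assignments near box edges will differ from the
  original analysis.
* The power model covers a single variant with an additive effect on a
  standardized quantitative trait; binary-trait and multi-variant
  burden power are out of scope.
* Carrier-count identities that depend on the unpublished full site
  list (e.g. totals across all 42 original positions) cannot be
  reproduced from the stand-in catalog; the package works at the level
  of the published per-site censuses instead.
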