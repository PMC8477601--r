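---
title: "Screening islands as GEM field-trial sites: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening islands as GEM field-trial sites: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islescreen)
```

## The problem

A field trial of genetically engineered mosquitoes (GEMs) carrying a
low-threshold gene drive needs a site with two properties that pull in
opposite directions: enough ecological realism to make the trial a fair
test of the product, and enough containment that neither transgene escape
nor wild-type immigration confounds it. Physical islands offer both, and
their suitability can be scored from measurable attributes: how isolated
the island is geographically and genetically, how large and topographically
complex it is, and how simple its anopheline fauna is. `islescreen` encodes
this scoring as a reproducible pipeline: each criterion becomes a verdict
(`pass`, `fail`, `missing`, `deferred`), and verdicts aggregate into a
candidate/excluded decision per site.

## Geographic isolation metrics

Three complementary indices, computed by `geo_isolation` functions:

- **Distance to mainland.** Between coordinates, the haversine great-circle
  distance on a sphere of mean radius 6371.0088 km (`great_circle_km`);
  on raster scenes, the minimum centre-to-centre distance between any
  focal-island cell and any mainland cell (`distance_to_mainland`), the
  raster analogue of measuring between the two closest shore points.
- **UNEP Isolation Index** (`unep_isolation_index`): the sum of square roots
  of the distances to the nearest equivalent-or-larger island, the nearest
  archipelago, and the nearest continent. Distances are taken in km — the
  index's source does not fix the unit, but the published per-island values
  are consistent with km.
- **Surrounding landmass proportion (SLMP)** (`slmp`): for each buffer
  distance b ∈ {100, 1000, 10,000} km around the focal island's perimeter,
  the proportion of the surrounding area within b that is land, summed over
  buffers. Two conventions had to be fixed because the verbal definition
  ("sum of the proportions of landmass within buffer distances") leaves
  them open. First, the focal island is excluded from both numerator and
  denominator: an island should not count itself as surrounding landmass,
  and the exclusion is what makes each term a true proportion — an island
  embedded in unbroken land scores exactly 1 per buffer (3.0 total), and an
  island alone in open water scores 0. Second, proportions are measured
  over the full buffer disk rather than annuli between successive buffers;
  the two differ only in weighting, the disk form is the simpler to
  reason about, and the choice is isolated behind the function boundary
  should a sensitivity analysis want the other.

Scenes are flat rasters with Euclidean cell distances — a deliberate
simplification. The package's geometric claims are exercised on synthetic
scenes whose generating geometry (circles and rectangles in continuous
coordinates) provides ground truth; geodesic buffering on the ellipsoid is
out of scope, and real-world SLMP values enter the pipeline as transcribed
registry numbers, not as computations over coastline polygons.

**Topography** (`topography_summary`): relief is elevation max − min
(with sea level as the default minimum), and the steepest-gradient map is
√((∂z/∂x)² + (∂z/∂y)²) by central differences, one-sided at grid borders so
the output has the same shape as the input. Gradients scale exactly with
elevation scaling, which the tests assert.

**Archipelagos** (`archipelago_aggregate`): distance to mainland is the
minimum over members (the nearest island stands for the group), area the
sum, SLMP the mean of non-missing members, elevations the extremes. For
the two fields the published combination rules do not cover, the package
chooses: the UNEP index is averaged over non-missing members, and the
glacial-maximum connection flag is 1 if any member was land-bridged.

## Population-genetic statistics

The pipeline consumes diploid genotypes (alternate-allele counts 0/1/2 with
missingness and per-genotype read depth) from VCF via `read_vcf`, which
retains biallelic SNPs only.

**Filter chain** (`filter_variants`), in a fixed order chosen so each step's
input is well defined:

1. genotypes with depth < 8 are set missing — the depth rule is applied at
   genotype level (not site level) so that the subsequent missingness
   fraction is well defined;
2. variants outside the accessibility intervals are dropped (optional);
3. variants with missingness > 10% are dropped;
4. variants with minor allele frequency < 1% (on non-missing genotypes) are
   dropped; a variant at exactly 1% is retained, because the removal rule
   is strictly "below the threshold".

The chain is idempotent. Interval masks — including the shipped
chromosome-3 heterochromatin coordinates (`heterochromatin_mask`) — are
interpreted as 1-based with both ends inclusive, so a variant at an
interval's printed end coordinate is masked. Standard 0-based half-open BED
can be converted on read (`read_intervals(zero_based = TRUE)`).

**LD pruning and PCA.** `ld_prune` slides a window of 500 variants in steps
of 200 and greedily removes the later variant of any pair with squared
genotype correlation above 0.1 — parameters matching common practice in the
toolchain this kind of analysis uses, exposed as arguments since no
published values constrain them. Pruning is deterministic given variant
order. Note that on strongly structured data, population structure itself
induces correlation between physically unlinked loci, so pruning thins
heavily there; that is the intended behaviour of an r² rule, not an
artifact. `pca_embed` mean-imputes missing genotypes per variant (a choice
the source material leaves open), centres, and decomposes with `prcomp`;
components come back ordered by explained variance, and when more variants
are available than requested a seeded subsample of exactly `n_snps` is
drawn.

**Hudson's F_ST** (`hudson_fst`): per site,
N = (p̂_a − p̂_b)² − p̂_a(1−p̂_a)/(n_a−1) − p̂_b(1−p̂_b)/(n_b−1),
D = p̂_a(1−p̂_b) + p̂_b(1−p̂_a), and the estimate is ΣN/ΣD over sites with
D > 0 — the *ratio of averages*, which is the recommended way to combine
this estimator across sites (averaging per-site ratios is biased and
unstable at weakly informative sites). Sites where either population has
fewer than two observed alleles, or where both are monomorphic for the same
allele, are excluded and counted. Negative estimates are reported, not
clamped: they are informative about sampling noise near F_ST = 0.

**Nucleotide diversity** (`windowed_pi`): per segregating site the unbiased
pairwise-difference contribution 2p̂(1−p̂)·n/(n−1) (equal to the mean
pairwise difference among the n observed alleles), summed within
non-overlapping 10 kb windows tiled from position 1 and divided by the
window length in bases — so positions without calls count as invariant,
matching the convention of the per-window tools this statistic is usually
computed with. Whether the original pipelines included monomorphic sites in
the denominator is not recoverable from the text; the window-length
denominator is the defensible reading and is stated here as this package's
convention.

**Tests on π values.** `rank_sum_compare` wraps the two-sided Wilcoxon
rank-sum test: exact enumeration when both groups have ≤ 8 values and no
ties, otherwise the tie-corrected normal approximation without continuity
correction (so that identical groups give p = 1 exactly).
`isolation_divergence_correlation` is the Spearman rank correlation of an
isolation metric against a genetic one across sites, dropping incomplete
pairs and requiring at least 3.

## The screening engine

Verdicts come from two sources. *Computed* verdicts apply thresholds
(`screening_config`) to registry metrics; *curated* verdicts are shipped
transcriptions of published per-site judgments. When both exist,
`merge_verdicts` lets the curated verdict win — the published matrix
contains judgments not derivable from the printed metrics — but records
every disagreement, retrievable with `verdict_conflicts`. On the shipped
data five such tensions surface, among them an island whose SLMP (1.148)
exceeds the 1.0 cutoff yet carries a curated geographic-isolation pass, and
one whose UNEP index (15.6) clears the 15 cutoff yet is curated as failing.
The engine surfaces these; it does not resolve them.

Thresholds, with provenance:

| parameter | default | status |
|---|---|---|
| `unep_min` | 15 | published exclusion rule (strict `<`) |
| `slmp_max` | 1.0 | published cutoff (strict `>`) |
| `area_min` | 100 km² | calibrated, config-exposed |
| `area_max` | 10,000 km² | calibrated (excludes only Madagascar) |
| `relief_min` | 600 m | calibrated: between 551 m (excluded) and 636 m (included) |
| `richness_max` | 10 species | calibrated (oceanic islands have 1–7) |
| `fst_isolation_min` | 0.10 | calibrated: between 0.029 (lacustrine max) and 0.130 (oceanic min) |
| `flight_range_km` | 10 | published assumption on *A. gambiae* dispersal |

Boundary conventions are explicit: the published cutoffs are strict
(exactly 15 or exactly 1.0 passes), the calibrated ones inclusive (exactly
600 m relief or exactly 100 km² passes). The 100 km² floor also catches
two small lacustrine islands (66 and 80 km²) whose curated size verdicts
are passes — a calibration tension the engine reports as conflicts rather
than hiding by moving the threshold.

**Aggregation** (`aggregate_verdicts`). A site is excluded when any
eliminating primary criterion fails; otherwise it is a candidate. Two
policy decisions matter:

- *Missing is not failure.* Absent evidence (e.g. no genetic data for an
  island) does not eliminate a site; the published decisions elevate a site
  with a missing genetic-diversity entry.
- *Richness is advisory by default.* In the published evaluation no site is
  eliminated on species richness alone: richness ranks sites (fewer
  non-target anophelines is better for logistics and endpoint
  interpretation) but does not gate them — one elevated site carries a
  richness failure, and every other richness failure co-occurs with an
  eliminating failure. The default policy therefore treats a richness
  `fail` as non-eliminating; `policy = "strict"` demands explicit passes on
  all seven primary criteria.

With these defaults the curated matrix yields exactly seven candidate
islands. Aggregation is order-independent and monotone (improving any
single verdict never demotes a site), which the tests assert.

`render_matrix` emits the symbol matrix (✓/✗/‐/*) ordered oceanic →
continental → lacustrine, and `parse_matrix` is its exact inverse.

## The synthetic-data module

`simulate_divergent_populations` draws, per locus, an ancestral frequency
p ~ Uniform(a, 1−a) (default a = 0.05), then per population a frequency
from Beta(p(1−F)/F, (1−p)(1−F)/F) — the Balding–Nichols model, under which
the expected fixation index of each population against the ancestral pool
is exactly F — then diploid genotypes Binomial(2, q), Poisson depths
(mean 20), and uniform missingness (2%). Positions are drawn without
replacement along the chromosome and sorted. Every generator is a pure
function of (config, seed): the same seed reproduces output bit for bit.

Balding–Nichols was chosen over coalescent simulation deliberately: it has
a closed-form divergence parameter that Hudson's estimator targets
directly, which turns parameter recovery into a sharp test (mean estimate
within ±0.02 of F over replicates) without external simulators. The default
configuration — 2 populations, 30 diploids each, 5000 loci — mirrors the
island/mainland contrasts the pipeline is built to measure at a size a desk
machine handles in seconds.

For diversity recovery, the locus count needed to hit a target per-site
diversity θ follows in closed form from the generator: for p uniform on
[a, 1−a], E[2p(1−p)] = 1/2 − (1−2a)²/6 (`expected_heterozygosity`), so
n_loci = θ·L / E[2p(1−p)] loci on a length-L chromosome give expected
windowed π of θ. The tests use θ = 0.01 over 100 windows of 10 kb.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: linkage and recombination (loci are
independent, so LD-pruning behaviour on real linked data is only partially
exercised), demographic history (no bottlenecks, expansions or migration,
so site-frequency spectra are not realistic), selection, inversion
polymorphism, sequencing error in genotype calls, and non-uniform
missingness. The pipeline accepts real VCFs of the study's shape unchanged;
reproducing the published island-vs-mainland F_ST and π values would
require reprocessing the ~420 deposited genomes, which is explicitly out of
desk scope. The property tests substitute for that: estimator exactness
against brute-force oracles, parameter recovery under a known model, and
shape-compatibility of the full path from VCF to decision.

`simulate_geo_scene` builds raster scenes from continuous geometry in three
layouts (remote oceanic, nearshore continental, lacustrine) and returns
ground truth alongside: the island-to-mainland distance computed
analytically from the circle/rectangle geometry (rasterised measurement
agrees within one cell diagonal), and SLMP evaluated on a 4× refined
rasterisation of the same geometry. `write_fixture_bundle` materialises a
mutually consistent input set — VCF, manifest, interval mask, scene and
elevation rasters, departures table — and the simulated chromosome spans
the printed heterochromatin coordinates so that mask behaviour is exercised
end to end.

## Numerical and edge-case conventions

- Missing table entries (the en dash) become `NA`, never 0, and every
  downstream rule treats `NA` explicitly.
- Site names are normalised to Unicode NFC before comparison, so composed
  and decomposed spellings of "Annobón" or "São Tomé" match.
- The sporozoite-rate boundary of exactly 1% classifies as *primary* — the
  published wording ("above 1%" primary, "<1%" secondary) leaves the
  boundary unassigned, and inclusive-primary is the conservative choice for
  vector accounting.
- A variant at exactly the MAF threshold survives; a mask interval's end
  coordinate is masked; a connectivity total exactly at the threshold flags
  `low`; relief and area at their thresholds pass. Each boundary is pinned
  by a test.
- Empty inputs are first-class: empty registries, VCFs without variants,
  and empty verdict sets round-trip rather than erroring.

## Problem sizes and test budget

The suite runs the statistical recovery checks at 30 diploids per
population and 5000 loci with 10 replicate seeds per divergence value,
geometry oracles on 20 random 40×40 scenes, and estimator-vs-oracle checks
on 100 random small genotype tables — sizes chosen so the full suite
completes in well under a minute while keeping Monte-Carlo margins
comfortable (the recovery tolerances are several standard errors wide at
these sizes).

## Known limitations

- Raster geometry is Euclidean and flat; SLMP on real coastlines should use
  geodesic buffering, which is out of scope here.
- The screening thresholds marked "calibrated" are this package's
  defaults, chosen to separate the published worked examples; they are not
  published constants, and analyses should treat them as configuration.
- Curated verdicts are transcriptions; the species, manifest and departure
  fixtures are synthetic demonstrations carrying only the published totals.
- The rank-sum test's exact path is limited to small untied samples; with
  ties it falls back to the tie-corrected normal approximation, as the
  underlying `wilcox.test` does.
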