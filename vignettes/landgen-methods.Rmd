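---
title: "Methods and design of the landgen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the landgen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

landgen implements a complete landscape-genetics workflow for diploid
codominant markers sampled along an essentially linear landscape: genetic
diversity and within-population tests, pairwise differentiation,
geographic / resistance / wind / climate distance matrices, and
matrix-regression inference, together with a forward-time simulator that
provides ground truth for every stage. This vignette records the models,
the parameters that matter, and the design decisions taken where the
methodological literature leaves choices open.

## Genetic estimators

**Allele frequencies and heterozygosity.** All estimators work from
per-(population, locus) allele counts over non-missing gene copies.
Expected heterozygosity uses Nei's unbiased form
$\hat H_e = \frac{n}{n-1}\bigl(1-\sum_a p_a^2\bigr)$ with $n$ the number
of gene copies; entries with $n<2$ are undefined rather than zero, and
combinations with no data are flagged, never silently dropped.

**Rarefied allelic richness.** The expected number of distinct alleles in
a subsample of $g$ gene copies is computed exactly by hypergeometric
rarefaction, $AR = \sum_a \left[1-\binom{n-n_a}{g}/\binom{n}{g}\right]$,
evaluated on the log scale for numerical stability. The default $g$ is the
smallest non-zero (population, locus) gene count — the convention of the
standard diversity packages — so every population is represented at every
locus it has data for.

**Garza–Williamson index.** $M = k/(r+1)$ where $k$ is the number of
distinct alleles and $r$ the allele-size range in *repeat units*. Because
published studies rarely report their repeat motifs, the repeat unit is an
explicit user input (the simulator uses 2 bp); sizes that are not
multiples of the unit raise an error naming the locus rather than being
rounded. Whether the range should be repeat-scaled or taken in raw base
pairs is genuinely ambiguous in the descriptive literature; repeat-scaled
is the interpretation under which the contiguous-ladder value is exactly 1.

**FIS.** The per-population inbreeding coefficient is the Weir–Cockerham
$f$, the ratio $1-\sum c/\sum(b+c)$ of within-population variance
components summed over alleles and loci — not the naive $1-H_o/H_e$ —
because that is what the standard hierarchical-F packages report and the
two differ at small $n$. Confidence limits are percentile intervals from
resampling loci with replacement (1000 draws by default), and the
two-sided p-value is the bootstrap tail probability of $f$ crossing zero;
resampling over loci is the only scheme that makes sense with a single
population sample per site.

**Hardy–Weinberg exact test.** The test conditions on allele counts
(Levene's distribution) and uses the probability-based rejection region:
$p$ is the total probability of tables no more probable than the observed
one. For biallelic samples of at most 50 individuals the heterozygote-count
support is enumerated exactly. Otherwise the p-value is Monte-Carlo: each
draw randomly re-pairs the $2n$ observed gene copies into $n$ genotypes,
which is an *exact i.i.d. draw* from the conditional null — so, unlike a
Markov-chain sampler, draws are independent and the standard error of the
p-value at the default $10^6$ draws is below $10^{-3}$. The sampler is
compiled (Rcpp) and driven by R's RNG, so `set.seed()` reproduces it.

**Linkage disequilibrium.** The statistic is the $G$ log-likelihood ratio
of the two-locus genotype contingency table; the null permutes one locus's
genotypes across individuals within the population, which preserves both
marginal genotype distributions exactly. Permutation p-values use the
add-one rule $(1+\#\{G^\ast \ge G\})/(1+B)$ throughout the package, so no
p-value is ever exactly zero and ties count against rejection
(conservative).

**Pairwise FST.** Weir & Cockerham's θ̂ with the unequal-sample-size
corrections, per allele and locus, combined as the ratio of summed
components $\sum a / \sum(a+b+c)$ — not the mean of per-locus ratios,
which is biased when information differs across loci. Loci with fewer than
two genotyped individuals in either member of a pair are dropped from that
pair; negative estimates are returned unclamped because the
$F_{ST}/(1-F_{ST})$ linearization is monotone below 1 and clamping would
destroy rank information used by the matrix tests.

## Landscape matrices

**Projection.** Coordinates are projected with a spherical
transverse-Mercator (central meridian −51°, scale 0.9996, false easting
500 km, false northing 10 000 km — the UTM 22S convention). A sphere of
radius 6 371 008.8 m is used for both the projection and all great-circle
edge lengths; at a 600-km study scale the spherical-vs-ellipsoidal error
(≲0.1%) is far below the raster discretization error (up to ~8%), so an
external projection library would add a dependency without accuracy.
Points more than 12° from the central meridian trigger a distortion
warning.

**Least-cost distances.** The raster is turned into an 8-neighbour graph
over non-nodata cells; each edge costs the great-circle distance between
cell centres divided by the mean conductance of the two cells, and
population-to-population costs are Dijkstra shortest paths between the
cells containing the populations. Endpoints therefore snap to cell
centres, which for nodes that are not at cell centres can make short-range
costs deviate in either direction by up to half a cell diagonal; tests that
compare against straight-line distance place nodes at cell centres for
that reason. With uniform conductance the 8-neighbour metric overshoots
the straight line by at most ~8% (the classic octile bound; slightly more
for very oblique bearings on longitude/latitude grids, where E–W spacing
shrinks by cos φ). A population on a nodata cell is an error by default:
silent snapping changes distances invisibly; `snap = TRUE` assigns the
nearest valid cell and logs the offset. Disconnected pairs return `Inf`
with a warning rather than failing, because a severed landscape is a
legitimate model outcome.

**Resistance models.** The *continuous* model sets every cell (water
included) to conductance 1 — a null model whose least-cost distances
approximate straight lines — and the *water-bodies* model keeps land at 1
and makes freshwater nodata, i.e. an absolute barrier. These are the two
standard contrasts for testing whether large water bodies structure gene
flow.

**Wind connectivity.** Wind input is a time series of (speed, direction)
raster pairs; directions are meteorological (degrees the wind blows
*from*), converted internally by +180°. For each ordered cell pair the
conductance is the component of the wind vector along the movement
bearing, $g = \max(\varepsilon,\, s\cos(\theta-\phi))$ with a floor of
$\varepsilon = 10^{-4}$ m/s so headwind and crosswind edges are
near-impassable but finite. The named transition-layer tool this emulates
publishes no formula; the cosine projection is this package's own
definition of its stated behaviour (tailwind facilitates, headwind
blocks). Per-slice directed least-cost matrices are *averaged
arithmetically over slices* — matching the published procedure of
averaging cost matrices, not conductances — and a symmetrized version
$(M+M^\top)/2$ is provided because Mantel and MMRR require symmetric
inputs. Two consequences are worth knowing: the arithmetic slice average
is dominated by the slices in which a pair is blocked, and the symmetrized
matrix is dominated by the harder direction of travel; both push wind-cost
matrices towards being distance-like unless the wind field has persistent
corridors. This is a property of the published averaging procedure itself,
not of the implementation.

## Matrix inference

Mantel tests correlate lower-triangle vectors under joint row/column
permutation of one matrix (upper tail by default, 10 000 permutations).
MMRR regresses the response triangle on predictor triangles with an
intercept; significance of each coefficient (two-sided on |t|) and of the
overall F comes from permuting the response matrix only, the cited
procedure for distance-matrix regression. The design matrix is
standardized internally — predictors in metres and in cost units can
differ by nine orders of magnitude, and the normal equations would
otherwise be numerically singular — and coefficients are transformed back
to raw units, which leaves t, p and R² untouched. Predictors correlated
above 0.9999 in the triangle are rejected as duplicates; genuinely
collinear landscape predictors (distance vs. resistance along a linear
coast routinely correlate above 0.99) are allowed, with the usual caveat
that individual coefficients then carry wide sampling error. The
`ibd_ibe_suite()` wrapper runs the canonical sequence with linearized FST
as response: Mantel against log distance (the lattice-model
linearization), one single-predictor MMRR per resistance model, one MMRR
per climate variable *with distance as covariate*, and an MMRR on the
symmetrized wind matrix; geographic distance enters the MMRRs in raw
metres by default because regression slopes are then directly
interpretable per metre.

## Exploratory structure

**DAPC.** Genotypes become an individuals × alleles dosage matrix (0/1/2),
missing dosages imputed by the allele mean (the standard default; per-locus
imputation rates are reported), columns centred. k-means runs on all PCA
scores and k is chosen by minimum $BIC(k)= n\ln(WSS_k/n)+k\ln n$. The
discriminant step then uses a reduced number of PCs chosen by the a-score
(observed reassignment rate minus its mean under permuted cluster labels),
which guards against the well-known overfitting of discriminant axes. A
caveat established while validating the selector: with *discrete* dosage
data the minimum-BIC rule over-splits when the marker panel is small,
because k-means can always shave within-cluster sum-of-squares by cutting
along a common genotype class, and with few loci that gain outruns the
$\ln n$ penalty. The clustering validation scenario therefore uses a
30-locus panel (2 × 40 individuals), a size at which the criterion is
stable; with ~10-locus panels the BIC curve should be read for its elbow
rather than its minimum.

**sPCA.** Individuals inherit their population's coordinates plus Gaussian
jitter (σ = 0.2°, seed-controlled) so coincident points separate — the
jitter is in degrees because it perturbs geographic coordinates. A
connection network (k-nearest, Gabriel, or distance band) is row-normalized
and symmetrized into L, and the analysis eigendecomposes
$\frac1n X^\top L X$ for the centred dosage matrix X. By construction each
eigenvalue equals var(score) × Moran's I(score), an identity the tests
assert to 10⁻⁸; large positive eigenvalues are global (cline-like)
structure, large negative ones local structure. A disconnected network is
an error suggesting a larger k or d. The global and local Monte-Carlo
tests permute rows of X against locations and use the extreme eigenvalues
as statistics — a deliberate simplification of the cited spectral-ratio
statistic, chosen because the extreme eigenvalue is the quantity the
analysis itself interprets.

## The synthetic-data module

The simulator is forward-time on allele *frequencies*: per locus, a shared
ancestral Dirichlet(1) draw evolves by deterministic backward migration
$p_i' = \sum_j B_{ij} p_j$ followed by multinomial drift with $2N_e$ gene
copies per deme ($N_e = 100$ by default), for 200 generations; genotypes
are then Hardy–Weinberg draws of the sampled individuals with allele sizes
on a 2-bp ladder. Scenario topologies: panmixia, finite island,
stepping-stone chain, chain with one severed link plus a water band
(barrier), wind-driven dispersal, environmental assortment
($B_{ij}\propto e^{-d_{ij}/d_s - |e_i-e_j|/\tau}$), and a study-shaped
design that reproduces a published 15-population / 253-individual /
10-locus sampling layout with 7–17 alleles per locus along a ~600 km
strip. The island scenario is the calibration anchor: its mean pairwise θ̂
is checked against the equilibrium approximation $1/(1+4N_e m)$ (within
30%, which absorbs both the finite-island correction and drift noise at 20
replicates).

The wind-driven scenario deserves its own note. Because the published
averaging procedure makes wind-cost matrices distance-like (see above), a
generic windy chain produces a wind matrix statistically indistinguishable
from geography. The scenario therefore emulates the one wind regime that
is identifiable: zones of along-strip flow (corridors) alternating with
cross-strip flow (barriers) under a diurnal breeze reversal, with
pairwise gene flow scaling as the inverse cube of the symmetrized wind
cost — a steep dispersal kernel. These are the study conditions under
which the recovery property (wind ranked above plain distance in ≥80% of
runs) is a fair test of the inference machinery; under isotropic wind the
question itself is ill-posed.

What the generator does *not* emulate: microsatellite mutation (stepwise
or otherwise — allele counts are fixed at the ancestral draw, so rare
private alleles are scarcer than in real data), overlapping generations,
selection, spatially continuous populations, and real lagoon geometry
(the water body is a rectangle placed so that no sampling site falls in
water). Passing recovery tests therefore demonstrate that the estimators
and tests respond correctly to migration-drift structure, not that the
simulator reproduces every feature of empirical microsatellite data.

## Orchestration and reproducibility

`run_pipeline()` executes load → diversity/HWE/LD → FST → DAPC/sPCA →
matrices → MMRR with per-stage seeds derived from one master seed,
records a structured log line per stage, and writes a JSON manifest with
package version, seeds, per-stage status/timing and MD5 hashes of every
output; identical config + seed gives byte-identical reports (asserted in
the tests). A failing stage is recorded, its dependents are skipped with
a reason, and the run exits non-zero after the manifest is written.
Defaults mirror the canonical analysis settings: 10 000 permutations for
matrix tests, 1000 bootstrap replicates for FIS, 10⁶ Monte-Carlo draws
for Hardy–Weinberg. The test suite and the acceptance script scale these
down (99–999 permutations, reduced grids) to keep full validation runs in
the minutes range on a single CPU; the defaults remain what an analysis
of real data should use.

## Known limitations

GenePop input is restricted to the 3-digit-per-allele dialect (2-digit
files are rejected with a clear message, not guessed at); no VCF,
STRUCTURE or Arlequin parsing. No null-allele or stutter diagnostics. No
circuit-theory (commute-time) distances — least-cost only. Bayesian
cluster/migration models (STRUCTURE-, TESS-, BayesAss-, Migrate-style) are
out of scope; DAPC and sPCA cover the exploratory half of structure
analysis. The Mantel/MMRR framework inherits the usual caution that
distance-matrix regression p-values are anti-conservative under strong
spatial autocorrelation of both matrices.
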