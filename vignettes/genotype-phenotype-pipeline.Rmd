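---
title: "Linking taxonomic and phenotypic views of soil microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking taxonomic and phenotypic views of soil microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opulink)
```

## The problem

Amplicon sequencing describes *who* is in a soil microbial community;
single-cell Raman microspectroscopy (SCRS) describes *what the cells are
made of*. `opulink` implements both sides and the statistics that connect
them: 16S-style community structure on amplicon sequence variants (ASVs),
single-cell spectral phenotyping into operational phenotypic units (OPUs),
compositional differential abundance, co-abundance networks with hub
detection, and genotype–phenotype integration. A joint synthetic-scene
generator with recorded ground truth makes every stage testable on a
desktop, with no sequencing downloads.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic scenes do and do not emulate.

## The synthetic scene generator

A scene is a factorial field design: `n_production` systems (conventional
vs organic) × plant species × replicate plants (default 5, the standard
replication for this kind of field survey). The default desk-scale scene
uses 3 plant species, 60 taxa and 100 cells per sample — 100 is the floor
for a usable per-sample phenotype profile; full field studies are an order
of magnitude larger in samples and spectra but statistically identical in
structure.

**Abundance side.** Per-sample latent log-basis abundances are multivariate
normal: means spread with SD 1.5 across taxa (a realistic rank–abundance
profile), replicate-level SD `taxon_log_sd = 0.6` per taxon. The
correlation matrix embeds planted structure: pairwise `correlation_blocks`
and star-wired hubs (a hub taxon correlated at `hub_rho = 0.3` with 8
mutually uncorrelated partners — the star is what gives a hub its high
degree *and* bridging betweenness; positive definiteness requires
`hub_partners * hub_rho^2 < 1`). Planted differential taxa add log2
effects to production, plant, or interaction cells of the design. Basis
abundances are closed to proportions and counts drawn multinomially at
lognormal depths floored at 1,000 reads, the compositional model SparCC
assumes — which is what makes network-recovery tests well-posed. The
replicate-level SD of 0.6 places a 4-fold planted group effect in the
moderately-strong-signal regime at five replicates per plant: detectable,
but only by a calibrated test.

**Spectral side.** Each phenotype template is a Gaussian band mixture. All
templates share the biological signature bands at 1003 cm⁻¹
(phenylalanine) and 1657 cm⁻¹ (amide I); each carries three diagnostic
bands disjoint across templates, drawn from a pool of common cellular
bands (lipid CH₂ 1250/1450, protein 1358/1574, the 687 cm⁻¹
carbon-metabolism band, and others). Cells jitter their band amplitudes
(0.2 log-SD) — real cells of one phenotype vary in relative band
intensity — and every spectrum gets a random low-order polynomial
baseline, additive noise (`noise_sd = 0.02` against unit-order band
amplitudes) and multiplicative intensity jitter. Junk spectra (default
15%) omit both signature bands; outlier cells (5%) carry unique random
band sets so they become singletons under clustering. Per-sample template
mixtures decay with template rank, so the first OPUs dominate the way the
most abundant phenotypes do in real communities.

**Coupling.** A shared per-sample latent factor loads on selected taxon
log-abundances (with the recorded sign) and on selected template mixture
logits (always positively), producing monotone OPU–taxon associations;
`coupling_strength = 0` makes the two tables exactly independent.

What the scenes do *not* emulate: read-level sequencing error, chimeras,
instrument physics (cosmic rays, detector response), spatial field
structure beyond per-farm coordinates, and phylogenetic signal in the
correlation structure. Passing recovery tests therefore demonstrates that
the algorithms work under the stated statistical model, not that every
property carries over to arbitrary real data.

## Raman phenotyping

**QC gate.** A cell is kept only if, after asymmetric-least-squares (ALS)
baseline subtraction, both signature windows (1003 ± 5 and 1657 ± 5 cm⁻¹)
contain a local maximum with *prominence* at least `snr_min = 3` times a
robust noise estimate. Prominence is the drop from the peak to the higher
of its two flanking minima within an extended (±3 half-width) window: a
shoulder of a neighboring band rises on one side and so never qualifies.
Noise is 1.4826 × MAD of the raw baseline-subtracted 1750–1800 cm⁻¹
region (assumed signal-free; configurable), and the peak search runs on a
lightly Savitzky–Golay-smoothed signal so single noisy pixels cannot form
peaks. Judging prominence on the raw signal, or against smoothed noise,
both mis-classify at the few-percent level; this combination holds
recall and precision above 95% on simulated scenes.

**Preprocessing.** Interpolation to a common grid → ALS baseline
(`lambda = 1e5`, asymmetry 0.01, 10 reweighting iterations) →
Savitzky–Golay smoothing (order 3, window 11) → unit-vector (L2)
normalization, which removes multiplicative intensity differences between
cells.

**OPU clustering.** Dissimilarity is 1 − Pearson correlation between
preprocessed spectra with average-linkage hierarchical clustering — the
standard choice for Raman phenotype work, and bounded, which makes a
fixed cutoff meaningful. The default cutoff 0.44 is the AIC-adjusted
value appropriate for hyperdiverse soil communities. Singleton clusters
are pooled as `"unclassified"` and retained as a composition component
(they appear in OPU tables) but excluded from diversity metrics, which
are defined over recognized phenotype units. OPU labels are assigned in
decreasing cluster-size order (ties by smallest member cell id), so OPU-0
is always the most abundant phenotype.

**Cutoff selection.** For each candidate height the tree is cut and
AIC(h) = n·q·ln(RSS/(n·q)) + 2·k·q is evaluated in the space of principal
components explaining 95% of variance (dimensionality q), with k the
number of flat clusters and RSS the within-cluster sum of squares in that
space — a spherical-Gaussian within-cluster model. Ties go to the
smallest cutoff; a scan in which every candidate leaves all spectra
singletons is reported degenerate and returns the largest candidate.

**Fisher scores.** Per wavenumber,
F(j) = Σ_c n_c (μ_cj − μ_j)² / Σ_c n_c σ²_cj over OPU classes, with an
epsilon guard for zero variances. The top-ranked wavenumbers are the
bands that discriminate phenotypes; the ranking is invariant to global
intensity scaling.

## Community structure

Rarefaction is exact multivariate-hypergeometric subsampling to the
minimum (or given) depth; all-zero taxa are retained so tables stay
aligned. Coverage is the singleton/doubleton estimator
Ĉ = 1 − (f₁/n)·(n−1)f₁/((n−1)f₁ + 2f₂). The core-taxon filter first drops
taxa under 0.5% grand-mean relative abundance, then keeps a taxon only if
present in ≥ 80% of replicates in at least one plant group (boundary
inclusive, so 4/5 qualifies). CLR uses pseudocount 0.5 — the common
default that avoids log 0 while staying small against real counts;
exposed as an argument. Bray–Curtis, NMDS (20 random starts, stress-1)
and PERMANOVA (sequential sums of squares in the stated term order,
`production * plant` before covariates, free row permutation) go through
vegan, the field-standard implementations. Both Bray–Curtis and
CLR-Euclidean (Aitchison) distances are provided; Bray–Curtis is the
ordination default, and the PERMANOVA wrapper accepts either. Terms that
are constant across samples are reported with R² = 0, p = 1 rather than
erroring.

## Differential abundance

The ALDEx approach: `n_mc = 128` Dirichlet(counts + 0.5) Monte-Carlo
instances per sample turn count uncertainty into a posterior over CLR
tables; per instance and taxon a linear model (default
`~ production * plant`) yields sequential F-test p-values per term; BH is
applied *within* instance and term, then averaged — the published
operating characteristics (low false discovery) come from adjusting
before averaging, not after. Non-rarefied counts are the correct input:
subsampling throws away information the posterior already models. A
Welch-t shortcut is provided for two-group designs, and
`aggregate_taxa()` supports phylum-level testing. Internally the
per-instance fits are a single QR decomposition shared across taxa, so
128 instances × dozens of taxa run in seconds.

## Co-abundance networks

`sparcc_correlations()` implements the log-ratio variance algorithm: per
inner iteration (20 by default) fractions are drawn from
Dirichlet(counts + 1), the matrix t_ij = Var[ln(f_i/f_j)] is formed, and
basis variances solve ((D−2)I + 11′)ω² = rowSums(T); correlations
ρ_ij = (ω²_i + ω²_j − t_ij)/(2ω_iω_j) are clipped to [−1, 1]. The
strongest pair above 0.1 is excluded and the system re-solved, up to 10
rounds, with two safeguards: per-taxon exclusions are capped at D − 3 and
a singular solve reverts to the previous estimate (the small-D analogue
of the reference implementation's component removal). The final estimate
is the elementwise median over inner iterations. Pseudo p-values permute
each taxon's counts across samples independently — this breaks all
between-taxon association while preserving marginals; the two-sided
pseudo p is (exceedances + 1)/(n_boot + 1) with 100 resamples by default.
Edges with pseudo p < 0.1 (both signs) form the network; centralities are
computed on the unweighted skeleton.

Markov clustering alternates expansion (matrix squaring) and inflation
(elementwise power 2, column renormalization) with pruning at 1e−5 until
the flow matrix stabilizes (1e−8, max 200 sweeps); clusters are the
weakly connected components of the attractor support.

**Hubs** are nodes in the top 10% of *both* normalized betweenness and
degree. "Top 10%" is evaluated on ranks with tie groups kept whole:
values are taken in decreasing order, whole tie groups at a time, until
⌈qn⌉ nodes are covered, dropping a group that would overshoot unless
nothing is selected yet. A plain (1 − q) quantile threshold degenerates
on skewed centrality distributions — in a star graph the 90th percentile
of betweenness is the modal leaf value 0, so every node would qualify —
while the tie-group rule stays deterministic, includes ties, and picks
exactly the star center. The hub subnetwork keeps every edge incident to
a hub, with endpoints, and reports its node and edge counts. Networks are
built separately per production system by subsetting samples before
inference.

## Genotype–phenotype integration

Diversity coupling fits OLS of each OPU alpha-diversity metric on its ASV
counterpart, per treatment (production × plant by default), in raw or
log1p form (both variables transformed; log1p accommodates zeros), with
stars at 0.05/0.01/0.001. dbRDA Gower-centers −½D², drops
negative-eigenvalue axes, regresses the retained principal coordinates on
the centered OPU constraints and eigen-decomposes the fitted values; the
constrained-inertia fraction is trace(fitted)/trace(retained) and overall
significance is a permutation pseudo-F over constraint rows. Vector
fitting of OPU shares onto the ordination plane goes through vegan's
envfit (999 permutations by default; published analyses vary between 999
and 10,000 — it is an argument), with BH across OPUs and significance at
BH p < 0.1. The Spearman screen correlates core-taxon relative abundances
with OPU shares (average-rank ties, two-sided t-approximation p), BH over
the full taxon × OPU family — one heat map, one family — with stars at
BH p < 0.1 and < 0.05.

## Pipeline and reproducibility

`run_pipeline()` drives simulate → phenotype → community → diffabund →
network (per production system) → integrate from one `pipeline_config()`.
Per-stage seeds derive from the master seed by a counter-based hash, so
disabling one stage never shifts another's random stream. The manifest
records status, parameters, consumed seeds and MD5 checksums of every
artifact (with outdir-relative paths, so identical configurations produce
byte-identical manifests); a stage failure is recorded and downstream
stages are skipped. All artifacts are plain text: TSV tables, wide/long
spectra CSV, square distance TSV, GraphML for Cytoscape, JSON manifests.

## Problem sizes used in the tests

The shipped test-and-verification suite runs desk-scale versions of each
analysis: QC and clustering recovery on 500-spectrum scenes (5 planted
templates); SparCC recovery on 50 taxa × 200 samples with a planted
ρ = 0.8 pair and a fully shuffled null; differential-abundance
calibration over 50 null and 50 effect scenes (4-fold planted effect,
10 samples per group); PERMANOVA type-I over 1,000 null scenes;
the OPU–taxon screen's false-discovery behavior over 20 uncoupled scenes;
and a full two-run pipeline determinism check. These sizes were chosen to
give stable recovery statistics at interactive runtimes; all are
arguments, not limits.

## Known limitations

- The AIC cluster criterion assumes spherical within-cluster noise in PCA
  space; strongly elongated phenotype clusters may be over-split.
- SparCC's sparsity assumption fails when most taxa are mutually
  correlated; the exclusion heuristic mitigates but cannot remove this.
- The permutation null for network pseudo p-values treats samples as
  exchangeable; block structure (e.g. repeated measures) is not modeled.
- Raman preprocessing assumes a smooth additive baseline; sharp
  fluorescence artifacts would need instrument-side handling out of scope
  here.
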