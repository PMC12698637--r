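# opulink

Integrated genotype–phenotype characterization of rhizosphere microbiomes
in R: one package that takes a community from raw inputs — an ASV count
table with taxonomy and metadata on one side, per-cell Raman spectra on
the other — to linked taxonomic and phenotypic profiles.

`opulink` is for microbial ecologists who combine 16S amplicon surveys
with single-cell Raman microspectroscopy (SCRS). It provides:

- **Raman phenotyping** — QC on the biological signature peaks
  (phenylalanine 1003 cm⁻¹, amide I 1657 cm⁻¹), ALS baseline removal,
  Savitzky–Golay smoothing, L2 normalization, and clustering of cells
  into operational phenotypic units (OPUs) by average linkage on
  1 − Pearson correlation with an AIC-guided cutoff (default 0.44);
  Fisher wavenumber ranking and OPU diversity.
- **Community structure** — exact rarefaction, singleton/doubleton
  coverage, the 0.5% mean-abundance / 80% group-prevalence core filter,
  CLR and Aitchison distance, Bray–Curtis, NMDS, and PERMANOVA
  (`~ production * plant + latitude + longitude`) via vegan.
- **Differential abundance** — ALDEx-style Dirichlet Monte-Carlo CLR
  instances with per-term sequential F-tests
  (`~ production * plant`), BH within instance, expectation over
  instances.
- **Co-abundance networks** — SparCC (log-ratio variances, basis-variance
  system ((D−2)I + 11′)ω² = rowSums(T), strong-pair exclusion, median
  over 20 Dirichlet iterations), permutation pseudo p-values
  (p = (exceedances + 1)/(n_boot + 1)), edges at pseudo p < 0.1, Markov
  clustering, normalized betweenness/degree, and hub taxa in the top 10%
  of both.
- **Integration** — OPU–ASV diversity-coupling OLS (raw and log1p),
  distance-based redundancy analysis with OPU constraints, vector
  fitting with permutation tests and BH at p < 0.1, and a Spearman
  OPU × taxon correlation map.
- **Synthetic scenes** — a joint generator (compositional counts with
  planted correlation blocks, star-wired hubs and group effects; band-
  mixture spectra with junk and outlier cells; latent OPU–taxon
  couplings) that emits ground truth for every planted structure.

## Worked example

```r
library(opulink)

design <- scene_design(
  plant_species = c("alfalfa", "corn", "lettuce"),
  n_taxa = 60, spectra_per_sample = 100,
  correlation_blocks = list(list(taxa = c(1, 2), rho = 0.8)),
  planted_hubs = 10,
  da_taxa = data.frame(taxon = 5, term = "production", log2fc = 2),
  couplings = data.frame(opu = 1, taxon = 7, sign = 1),
  coupling_strength = 1)
scene <- simulate_scene(design, seed = 1)
scene$asv
#> ASV table: 30 samples x 60 taxa (total 616,742 reads)
#>   metadata: production, plant, replicate, latitude, longitude
scene$spectra
#> Raman spectrum set: 3000 cells from 30 samples, grid 600-1800 cm^-1 (1201 points)

## phenotype side: QC -> preprocess -> cluster -> OPU table
qc     <- qc_signature_filter(scene$spectra)
prep   <- preprocess_spectra(qc$passed)
assign <- cluster_opus(prep$spectra, cutoff = 0.44)
assign
#> OPU assignment: 2541 cells, 36 OPUs, 48 unclassified (cutoff 0.44)
opus <- build_opu_table(assign, samples = rownames(scene$asv$counts))

## taxonomic side: rarefy -> coverage -> core filter -> PERMANOVA
rare <- rarefy_even_depth(scene$asv, "min", seed = 2)
summary(estimate_coverage(rare))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9999  1.0000  1.0000  1.0000  1.0000  1.0000
permanova(bray_curtis(filter_core_taxa(rare)), scene$asv$metadata,
          ~ production * plant + latitude + longitude,
          n_perm = 999, seed = 3)
#> PERMANOVA (999 permutations)
#>                  df     ss     r2      f     p
#> production        1 0.2014 0.1124 3.4690 0.001
#> plant             2 0.0986 0.0550 0.8493 0.715
#> latitude          1 0.0413 0.0231 0.7120 0.799
#> longitude         1 0.0454 0.0254 0.7826 0.713
#> production:plant  2 0.1280 0.0714 1.1026 0.300
#> Residual         22 1.2772 0.7127     NA    NA
#> Total            29 1.7920 1.0000     NA    NA

## network side: the planted rho = 0.8 pair is recovered
r <- sparcc_correlations(scene$asv, seed = 4)
r$correlation[1, 2]
#> [1] 0.7359178
```

The QC gate keeps ~85% of cells (the scene plants 15% junk spectra
lacking the signature peaks); 2541 cells cluster into 36 OPUs at the 0.44
cutoff, with outlier cells pooled as unclassified. PERMANOVA attributes
11% of Bray–Curtis variation to the production system (p = 0.001) — the
scene plants a production effect and no plant effect, which is exactly
what the table shows. The SparCC estimate for the planted ρ = 0.8 basis
pair is 0.74 on this 30-sample scene (it sharpens with sample size; see
the 200-sample benchmark below).

Or run everything at once:

```r
cfg <- pipeline_config(outdir = "run1", seed = 1, design = design)
manifest <- run_pipeline(cfg)
```

which writes the scene, OPU tables, distances, ordination scores,
PERMANOVA and differential-abundance tables, per-production-system
networks (edge lists, GraphML, hub reports) and the integration outputs
(diversity-coupling regressions, dbRDA scores, fitted OPU vectors,
Spearman matrices), plus a `manifest.json` with parameters, seeds and MD5
checksums. The same config and seed reproduce every file byte-for-byte.

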