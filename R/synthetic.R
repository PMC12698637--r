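# Joint synthetic scenes: compositional ASV counts, single-cell Raman spectra,
# sample metadata and a ground-truth record for recovery tests.

#' Describe a synthetic rhizosphere scene
#'
#' A scene couples a factorial sampling design (production system x plant
#' species x replicate plants) with a latent compositional abundance model and
#' a band-mixture Raman spectral model. The object is a plain validated list;
#' every downstream generator consumes it together with a seed.
#'
#' The abundance side draws per-sample latent log-basis abundances from a
#' multivariate normal whose correlation matrix embeds requested correlation
#' blocks and hub wiring, adds group offsets for planted differential taxa,
#' closes to proportions, and samples counts multinomially at lognormal
#' sequencing depths (floored at 1,000 reads). The spectral side renders each
#' cell as a sum of Gaussian bands from its phenotype template; all templates
#' share the biological signature bands at 1003 cm^-1 (phenylalanine) and
#' 1657 cm^-1 (amide I), junk spectra lack them, and outlier cells carry
#' unique random band sets so they become singletons under clustering.
#'
#' @param plant_species character vector of plant labels.
#' @param n_production number of production systems (2: conventional/organic).
#' @param replicates_per_plant replicate plants per species per system.
#' @param n_taxa number of taxa in the count table.
#' @param depth_log_mean,depth_log_sd lognormal sequencing-depth parameters
#'   (natural-log scale).
#' @param abundance_log_spread standard deviation of the per-taxon log-mean
#'   abundances (the rank-abundance spread). Default 1.5 gives realistic
#'   order-of-magnitude abundance differences; 0 gives the equal-abundance
#'   iid lognormal basis used for pure estimator benchmarks.
#' @param taxon_log_sd replicate-level biological standard deviation of each
#'   taxon's latent log abundance. The default 0.6 puts a 4-fold group
#'   effect in the moderately-strong-signal regime at five replicates per
#'   plant, the regime the differential-abundance stage is designed for.
#' @param da_taxa data.frame with columns `taxon`, `term`
#'   (`"production"`, `"plant"` or `"interaction"`) and `log2fc`: planted
#'   differential taxa.
#' @param correlation_blocks list of `list(taxa = <indices>, rho = <value>)`
#'   basis-correlation blocks.
#' @param planted_hubs integer vector of hub taxon indices; each hub is wired
#'   as a star to `hub_partners` mutually uncorrelated partners at
#'   correlation `hub_rho` (requires hub_partners * hub_rho^2 < 1).
#' @param hub_partners,hub_rho hub wiring controls.
#' @param n_opu_templates number of phenotype templates.
#' @param spectra_per_sample cells measured per sample (>= 10; default honors
#'   the 100-spectra floor used when profiling each plant).
#' @param junk_fraction proportion of spectra lacking the signature bands.
#' @param outlier_fraction proportion of singleton-like outlier cells.
#' @param noise_sd additive spectral noise standard deviation (intensity
#'   units; bands have unit-order amplitudes).
#' @param baseline_order polynomial order of the random spectral baseline.
#' @param couplings data.frame with columns `opu` (template index, 1-based),
#'   `taxon` (taxon index) and `sign` (+1/-1): latent genotype-phenotype
#'   couplings.
#' @param coupling_strength magnitude of the shared latent factor loading
#'   (0 = independent tables).
#' @param wavenumbers spectral grid (cm^-1), strictly increasing.
#' @return an object of class `scene_design`.
#' @export
scene_design <- function(plant_species = c("alfalfa", "corn", "lettuce"),
                         n_production = 2L,
                         replicates_per_plant = 5L,
                         n_taxa = 60L,
                         depth_log_mean = log(20000),
                         depth_log_sd = 0.35,
                         abundance_log_spread = 1.5,
                         taxon_log_sd = 0.6,
                         da_taxa = NULL,
                         correlation_blocks = list(),
                         planted_hubs = integer(),
                         hub_partners = 8L,
                         hub_rho = 0.3,
                         n_opu_templates = 5L,
                         spectra_per_sample = 100L,
                         junk_fraction = 0.15,
                         outlier_fraction = 0.05,
                         noise_sd = 0.02,
                         baseline_order = 2L,
                         couplings = NULL,
                         coupling_strength = 0,
                         wavenumbers = seq(600, 1800, by = 1)) {
  design <- list(
    plant_species = as.character(plant_species),
    n_production = as.integer(n_production),
    replicates_per_plant = as.integer(replicates_per_plant),
    n_taxa = as.integer(n_taxa),
    depth_log_mean = depth_log_mean,
    depth_log_sd = depth_log_sd,
    abundance_log_spread = abundance_log_spread,
    taxon_log_sd = taxon_log_sd,
    da_taxa = da_taxa,
    correlation_blocks = correlation_blocks,
    planted_hubs = as.integer(planted_hubs),
    hub_partners = as.integer(hub_partners),
    hub_rho = hub_rho,
    n_opu_templates = as.integer(n_opu_templates),
    spectra_per_sample = as.integer(spectra_per_sample),
    junk_fraction = junk_fraction,
    outlier_fraction = outlier_fraction,
    noise_sd = noise_sd,
    baseline_order = as.integer(baseline_order),
    couplings = couplings,
    coupling_strength = coupling_strength,
    wavenumbers = as.numeric(wavenumbers)
  )
  class(design) <- "scene_design"
  validate_scene_design(design)
  design
}

validate_scene_design <- function(d) {
  fr <- c(junk = d$junk_fraction, outlier = d$outlier_fraction)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  if (d$junk_fraction + d$outlier_fraction > 1) {
    stopf("junk_fraction + outlier_fraction exceeds 1")
  }
  if (d$replicates_per_plant < 2) stopf("replicates_per_plant must be >= 2")
  if (d$spectra_per_sample < 10) stopf("spectra_per_sample must be >= 10")
  if (any(diff(d$wavenumbers) <= 0)) stopf("wavenumber grid must be strictly increasing")
  planted <- c(
    d$planted_hubs,
    unlist(lapply(d$correlation_blocks, `[[`, "taxa")),
    if (!is.null(d$da_taxa)) d$da_taxa$taxon,
    if (!is.null(d$couplings)) d$couplings$taxon
  )
  if (length(planted) && max(planted) > d$n_taxa) {
    stopf("planted taxon index %d out of range (n_taxa = %d)", max(planted), d$n_taxa)
  }
  if (!is.null(d$couplings) && nrow(d$couplings) &&
      max(d$couplings$opu) > d$n_opu_templates) {
    stopf("coupled OPU template index out of range")
  }
  if (d$coupling_strength < 0) stopf("coupling_strength must be >= 0")
  invisible(d)
}

#' @export
print.scene_design <- function(x, ...) {
  n_samp <- x$n_production * length(x$plant_species) * x$replicates_per_plant
  cat("Synthetic scene design\n")
  cat(sprintf("  %d production systems x %d plants x %d replicates = %d samples\n",
              x$n_production, length(x$plant_species), x$replicates_per_plant, n_samp))
  cat(sprintf("  %d taxa, %d phenotype templates, %d spectra/sample\n",
              x$n_taxa, x$n_opu_templates, x$spectra_per_sample))
  cat(sprintf("  junk %.0f%%, outliers %.0f%%, coupling strength %.2f\n",
              100 * x$junk_fraction, 100 * x$outlier_fraction, x$coupling_strength))
  invisible(x)
}

scene_metadata <- function(design) {
  prods <- c("conventional", "organic")[seq_len(design$n_production)]
  grid <- expand.grid(
    replicate = seq_len(design$replicates_per_plant),
    plant = design$plant_species,
    production = prods,
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("production", "plant", "replicate")]
  grid$sample_id <- sprintf("S%03d", seq_len(nrow(grid)))
  grid[, c("sample_id", "production", "plant", "replicate")]
}

# Build the taxon x taxon basis correlation matrix from blocks + hub wiring.
# Hubs are wired as stars: the hub correlates with each partner at hub_rho
# while partners stay mutually uncorrelated, so the hub alone carries high
# degree and bridging betweenness. Positive definiteness requires
# hub_partners * hub_rho^2 < 1 (checked via the Cholesky below).
scene_correlation <- function(design) {
  D <- design$n_taxa
  C <- diag(D)
  truth_pairs <- list()
  for (b in seq_along(design$correlation_blocks)) {
    blk <- design$correlation_blocks[[b]]
    idx <- as.integer(blk$taxa)
    for (i in idx) for (j in idx) if (i != j) C[i, j] <- blk$rho
    pr <- utils::combn(sort(idx), 2)
    for (k in seq_len(ncol(pr))) {
      truth_pairs[[length(truth_pairs) + 1L]] <-
        data.frame(taxon_a = pr[1, k], taxon_b = pr[2, k], rho = blk$rho)
    }
  }
  hub_partner_sets <- list()
  if (length(design$planted_hubs)) {
    used <- unique(c(design$planted_hubs,
                     unlist(lapply(design$correlation_blocks, `[[`, "taxa"))))
    free <- setdiff(seq_len(D), used)
    for (h in design$planted_hubs) {
      m <- min(design$hub_partners, length(free))
      if (m < 2) stopf("not enough free taxa to wire hub %d", h)
      part <- free[seq_len(m)]
      free <- setdiff(free, part)
      C[h, part] <- C[part, h] <- design$hub_rho
      hub_partner_sets[[as.character(h)]] <- part
      for (p in part) {
        truth_pairs[[length(truth_pairs) + 1L]] <-
          data.frame(taxon_a = min(h, p), taxon_b = max(h, p), rho = design$hub_rho)
      }
    }
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stopf("requested basis correlation matrix is not positive definite; check correlation_blocks")
  }
  list(C = C, chol = ch,
       pairs = if (length(truth_pairs)) do.call(rbind, truth_pairs) else NULL,
       hub_partner_sets = hub_partner_sets)
}

scene_group_offsets <- function(design, meta) {
  # log-scale offset matrix (sample x taxon) realizing planted log2 effects
  off <- matrix(0, nrow(meta), design$n_taxa)
  truth <- NULL
  da <- design$da_taxa
  if (is.null(da) || !nrow(da)) return(list(offsets = off, truth = NULL))
  plants <- design$plant_species
  for (k in seq_len(nrow(da))) {
    t_i <- da$taxon[k]
    eff <- da$log2fc[k] * log(2)
    term <- da$term[k]
    if (term == "production") {
      sel <- meta$production == "organic"
    } else if (term == "plant") {
      pl <- plants[1 + (k - 1) %% length(plants)]
      sel <- meta$plant == pl
    } else if (term == "interaction") {
      pl <- plants[1 + (k - 1) %% length(plants)]
      sel <- meta$production == "organic" & meta$plant == pl
    } else stopf("unknown DA term '%s'", term)
    off[sel, t_i] <- off[sel, t_i] + eff
    truth <- rbind(truth, data.frame(taxon = t_i, term = term, log2fc = da$log2fc[k]))
  }
  list(offsets = off, truth = truth)
}

#' Generate a synthetic ASV count table with known structure
#'
#' Latent log-basis abundances are drawn from a multivariate normal embedding
#' the design's correlation blocks and hub wiring; planted group effects are
#' added on the log scale; rows are closed to proportions and sampled
#' multinomially at lognormal depths (floor 1,000 reads).
#'
#' @param design a [scene_design()].
#' @param seed integer seed.
#' @param latent_factor optional per-sample latent factor used for
#'   genotype-phenotype coupling (internal; supplied by [simulate_scene()]).
#' @return a list with components `asv` (an `asv_table`) and `truth`
#'   (ground-truth record, including the latent log-basis draws).
#' @export
generate_asv_counts <- function(design, seed, latent_factor = NULL) {
  validate_scene_design(design)
  meta <- scene_metadata(design)
  n <- nrow(meta)
  D <- design$n_taxa
  corr <- scene_correlation(design)

  set.seed(derive_seed(seed, "asv-basis"))
  # per-taxon log-mean spread and dispersion give realistic rank-abundance
  mu <- rnorm(D, mean = 0, sd = design$abundance_log_spread %||% 1.5)
  sig <- rep(d_field <- design$taxon_log_sd %||% 0.6, D)
  eps <- matrix(rnorm(n * D), n, D) %*% corr$chol  # rows ~ N(0, C)
  z <- sweep(sweep(eps, 2, sig, `*`), 2, mu, `+`)

  offs <- scene_group_offsets(design, meta)
  z <- z + offs$offsets

  if (!is.null(latent_factor) && !is.null(design$couplings) &&
      nrow(design$couplings) && design$coupling_strength > 0) {
    for (k in seq_len(nrow(design$couplings))) {
      cp <- design$couplings[k, ]
      z[, cp$taxon] <- z[, cp$taxon] + design$coupling_strength * cp$sign * latent_factor
    }
  }

  props <- exp(z)
  props <- props / rowSums(props)

  set.seed(derive_seed(seed, "asv-depth"))
  depths <- pmax(1000, round(rlnorm(n, design$depth_log_mean, design$depth_log_sd)))
  counts <- matrix(0L, n, D)
  for (i in seq_len(n)) {
    counts[i, ] <- as.integer(rmultinom(1, depths[i], props[i, ]))
  }
  taxa_ids <- sprintf("ASV%03d", seq_len(D))
  dimnames(counts) <- list(meta$sample_id, taxa_ids)
  colnames(z) <- taxa_ids
  rownames(z) <- meta$sample_id

  asv <- asv_table(counts, taxonomy = scene_taxonomy(design, seed), metadata = scene_sites(meta, seed))
  truth <- list(
    true_basis_corr = corr$pairs,
    true_da_taxa = offs$truth,
    true_hubs = design$planted_hubs,
    hub_partner_sets = corr$hub_partner_sets,
    latent_log_basis = z,
    depths = depths
  )
  list(asv = asv, truth = truth)
}

scene_sites <- function(meta, seed) {
  set.seed(derive_seed(seed, "sites"))
  farm <- interaction(meta$production, meta$plant, drop = TRUE)
  lat0 <- setNames(44 + rnorm(nlevels(farm), 0, 0.6), levels(farm))
  lon0 <- setNames(-93 + rnorm(nlevels(farm), 0, 0.9), levels(farm))
  meta$latitude <- lat0[as.character(farm)] + rnorm(nrow(meta), 0, 0.01)
  meta$longitude <- lon0[as.character(farm)] + rnorm(nrow(meta), 0, 0.01)
  rownames(meta) <- meta$sample_id
  meta
}

scene_taxonomy <- function(design, seed) {
  set.seed(derive_seed(seed, "taxonomy"))
  phyla <- c("Acidobacteriota", "Actinobacteriota", "Bacteroidota", "Chloroflexota",
             "Gemmatimonadota", "Proteobacteria", "Verrucomicrobiota", "Firmicutes")
  ph <- sample(phyla, design$n_taxa, replace = TRUE)
  data.frame(
    taxon_id = sprintf("ASV%03d", seq_len(design$n_taxa)),
    domain = "Bacteria",
    phylum = ph,
    class = paste0(ph, "_c"),
    order = paste0(ph, "_o", sample(1:4, design$n_taxa, TRUE)),
    family = paste0("Fam", sprintf("%02d", sample(1:20, design$n_taxa, TRUE))),
    genus = paste0("Gen", sprintf("%03d", seq_len(design$n_taxa))),
    species = paste0("sp", sprintf("%03d", seq_len(design$n_taxa))),
    stringsAsFactors = FALSE
  )
}

gauss_band <- function(grid, center, width, amp) {
  amp * exp(-0.5 * ((grid - center) / width)^2)
}

# Diagnostic band pool: lipid CH2 (1250/1450), protein (1358/1574),
# carbon-metabolism 687, plus common cellular bands. Signature bands are
# handled separately and never appear here.
.band_pool <- c(687, 725, 785, 830, 895, 955, 1095, 1127, 1250, 1320,
                1358, 1450, 1527, 1574, 1608)

scene_templates <- function(design, seed) {
  set.seed(derive_seed(seed, "templates"))
  K <- design$n_opu_templates
  templates <- vector("list", K)
  pool <- sample(.band_pool)
  used <- c(1003, 1657)
  for (k in seq_len(K)) {
    # three diagnostic bands per template, disjoint across templates, so
    # phenotypes differ the way lipid- vs protein- vs carbon-rich cells do
    centers <- numeric(0)
    while (length(centers) < 3) {
      if (length(pool)) {
        c0 <- pool[1]; pool <- pool[-1]
      } else {
        repeat {
          c0 <- runif(1, 620, 1780)
          if (min(abs(c0 - used)) > 20) break
        }
      }
      centers <- c(centers, c0)
      used <- c(used, c0)
    }
    templates[[k]] <- data.frame(
      center = c(1003, 1657, centers),
      width = c(6, 10, runif(3, 6, 12)),
      amp = c(1, 0.9, runif(3, 0.7, 1.2))
    )
  }
  templates
}

render_spectrum <- function(grid, bands, noise_sd, baseline_order) {
  y <- rep(0, length(grid))
  for (b in seq_len(nrow(bands))) {
    y <- y + gauss_band(grid, bands$center[b], bands$width[b], bands$amp[b])
  }
  # smooth random polynomial baseline over a [0,1]-rescaled axis
  x01 <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  coef <- rnorm(baseline_order + 1, 0, 0.15)
  baseline <- drop(outer(x01, 0:baseline_order, `^`) %*% coef)
  jitter <- exp(rnorm(1, 0, 0.1))
  jitter * y + baseline + rnorm(length(grid), 0, noise_sd)
}

#' Generate synthetic single-cell Raman spectra
#'
#' Each valid cell is a noisy Gaussian band mixture from one of the design's
#' phenotype templates; all templates include the 1003 and 1657 cm^-1
#' signature bands. Junk spectra omit both signature bands; outlier cells get
#' unique random band sets (with signature bands) so that they form
#' singletons under clustering. True per-cell labels are recorded.
#'
#' @inheritParams generate_asv_counts
#' @return list with `spectra` (a `spectrum_set`) and `truth` (per-cell true
#'   labels and per-sample template mixtures).
#' @export
generate_spectra <- function(design, seed, latent_factor = NULL) {
  validate_scene_design(design)
  meta <- scene_metadata(design)
  grid <- design$wavenumbers
  templates <- scene_templates(design, seed)
  K <- design$n_opu_templates

  set.seed(derive_seed(seed, "mixtures"))
  # rank-decaying base template weights: first templates dominate, as the
  # most abundant phenotypes do in real communities
  base_w <- (seq_len(K))^(-1.2)
  base_w <- base_w / sum(base_w)
  logit_w <- matrix(log(base_w), nrow(meta), K, byrow = TRUE) +
    matrix(rnorm(nrow(meta) * K, 0, 0.4), nrow(meta), K)
  if (!is.null(latent_factor) && !is.null(design$couplings) &&
      nrow(design$couplings) && design$coupling_strength > 0) {
    for (k in seq_len(nrow(design$couplings))) {
      cp <- design$couplings[k, ]
      # the association sign lives on the taxon side; the template mixture
      # always loads positively on the shared factor
      logit_w[, cp$opu] <- logit_w[, cp$opu] +
        design$coupling_strength * latent_factor
    }
  }
  mixtures <- exp(logit_w)
  mixtures <- mixtures / rowSums(mixtures)

  set.seed(derive_seed(seed, "cells"))
  n_cells <- nrow(meta) * design$spectra_per_sample
  cell_sample <- rep(meta$sample_id, each = design$spectra_per_sample)
  cell_id <- sprintf("C%05d", seq_len(n_cells))
  u <- runif(n_cells)
  type <- ifelse(u < design$junk_fraction, "junk",
                 ifelse(u < design$junk_fraction + design$outlier_fraction,
                        "outlier", "valid"))
  true_label <- character(n_cells)
  intens <- matrix(0, length(grid), n_cells)
  for (i in seq_len(n_cells)) {
    s_row <- match(cell_sample[i], meta$sample_id)
    if (type[i] == "valid") {
      k <- sample.int(K, 1, prob = mixtures[s_row, ])
      true_label[i] <- sprintf("template-%d", k)
      bands <- templates[[k]]
      # cell-to-cell variation in relative band intensities within a phenotype
      bands$amp <- bands$amp * exp(rnorm(nrow(bands), 0, 0.2))
    } else if (type[i] == "junk") {
      true_label[i] <- "junk"
      n_b <- sample(2:4, 1)
      centers <- runif(n_b, 650, 1600)
      # keep junk free of both signature windows
      centers <- centers[abs(centers - 1003) > 25 & abs(centers - 1657) > 25]
      if (!length(centers)) centers <- 800
      bands <- data.frame(center = centers, width = runif(length(centers), 8, 20),
                          amp = runif(length(centers), 0.3, 0.8))
    } else {
      true_label[i] <- "outlier"
      n_b <- sample(4:6, 1)
      bands <- data.frame(
        center = c(1003, 1657, runif(n_b, 620, 1780)),
        width = c(6, 10, runif(n_b, 4, 9)),
        amp = c(0.9, 0.8, runif(n_b, 0.5, 1.2))
      )
    }
    intens[, i] <- render_spectrum(grid, bands, design$noise_sd, design$baseline_order)
  }
  spectra <- spectrum_set(wavenumbers = grid, intensities = intens,
                          cell_id = cell_id, sample_id = cell_sample)
  truth <- list(
    true_opu_label = setNames(true_label, cell_id),
    template_mixtures = mixtures,
    templates = templates
  )
  list(spectra = spectra, truth = truth)
}

#' Simulate a joint genotype-phenotype scene
#'
#' Generates the ASV count table and the Raman spectra for one scene. When
#' the design carries couplings with positive `coupling_strength`, a shared
#' per-sample latent factor shifts both the coupled taxon log-abundances and
#' the coupled template mixture logits, producing monotone OPU-taxon
#' associations of the recorded sign; with strength 0 the two tables are
#' independent.
#'
#' @inheritParams generate_asv_counts
#' @return list with `asv`, `spectra`, `metadata` and `truth` (merged record,
#'   including `true_couplings`).
#' @export
simulate_scene <- function(design, seed) {
  validate_scene_design(design)
  meta <- scene_metadata(design)
  latent <- NULL
  if (!is.null(design$couplings) && nrow(design$couplings) &&
      design$coupling_strength > 0) {
    set.seed(derive_seed(seed, "coupling"))
    latent <- rnorm(nrow(meta))
  }
  a <- generate_asv_counts(design, seed, latent_factor = latent)
  s <- generate_spectra(design, seed, latent_factor = latent)
  truth <- c(a$truth, s$truth)
  truth$true_couplings <- design$couplings
  truth$latent_factor <- latent
  list(asv = a$asv, spectra = s$spectra, metadata = a$asv$metadata, truth = truth)
}
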