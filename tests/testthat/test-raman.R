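test_that("QC gate passes signature-bearing spectra and rejects junk", {
  good <- toy_spectra(list(bands(c(1003, 1657, 1450), amp = c(1, 0.9, 0.8))),
                      noise_sd = 0.01)
  junk <- toy_spectra(list(bands(c(800, 1250), amp = c(0.8, 0.6))),
                      noise_sd = 0.01)
  one_peak <- toy_spectra(list(bands(1003)), noise_sd = 0.01)
  expect_equal(qc_signature_filter(good)$passed$cell_id, "cell01")
  expect_equal(qc_signature_filter(junk)$rejected, "cell01")
  expect_equal(qc_signature_filter(one_peak)$rejected, "cell01")
  # empty input is not an error
  empty <- subset_spectra(good, character())
  expect_length(qc_signature_filter(empty)$rejected, 0)
  # grid must cover both windows
  narrow <- spectrum_set(seq(600, 1200, 1), good$intensities[1:601, , drop = FALSE],
                         good$cell_id, good$sample_id)
  expect_error(qc_signature_filter(narrow), "1657")
})

test_that("QC recall and precision hold across simulated scenes", {
  recall <- precision <- numeric(10)
  for (s in 1:10) {
    d <- scene_design(plant_species = c("a", "b"), n_taxa = 10,
                      spectra_per_sample = 10, junk_fraction = 0.2)
    g <- generate_spectra(d, seed = s)
    qc <- qc_signature_filter(g$spectra)
    tl <- g$truth$true_opu_label
    recall[s] <- sum(tl[qc$rejected] == "junk") / sum(tl == "junk")
    valid <- names(tl)[tl != "junk"]
    precision[s] <- mean(valid %in% qc$passed$cell_id)
  }
  expect_gte(mean(recall), 0.95)
  expect_gte(mean(precision), 0.95)
})

test_that("preprocessing yields unit-norm spectra invariant to offsets", {
  s <- toy_spectra(list(bands(c(1003, 1657)), bands(c(900, 1450))),
                   noise_sd = 0.01)
  pp <- preprocess_spectra(s)
  norms <- sqrt(colSums(pp$spectra$intensities^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
  shifted <- spectrum_set(s$wavenumbers, s$intensities + 5, s$cell_id, s$sample_id)
  pp2 <- preprocess_spectra(shifted)
  expect_lt(max(abs(pp$spectra$intensities - pp2$spectra$intensities)), 1e-6)
})

test_that("band centers survive baseline removal and smoothing", {
  grid <- seq(600, 1800, 1)
  y <- exp(-0.5 * ((grid - 1095) / 8)^2) + 0.3 + 0.0005 * (grid - 600)
  s <- spectrum_set(grid, cbind(y), "c1", "s1")
  pp <- preprocess_spectra(s)
  peak <- grid[which.max(pp$spectra$intensities[, 1])]
  expect_lte(abs(peak - 1095), 1)
})

test_that("clustering handles identical, orthogonal and degenerate inputs", {
  base <- exp(-0.5 * ((seq(600, 1800, 1) - 1003) / 6)^2) +
    exp(-0.5 * ((seq(600, 1800, 1) - 1657) / 10)^2)
  twin <- spectrum_set(seq(600, 1800, 1), cbind(base, base), c("a", "b"),
                       c("s1", "s1"))
  a <- cluster_opus(twin, cutoff = 0.44)
  expect_equal(unname(a$labels), c("OPU-0", "OPU-0"))
  m <- matrix(0, 1201, 2)
  m[100, 1] <- 1
  m[700, 2] <- 1
  ortho <- spectrum_set(seq(600, 1800, 1), m, c("a", "b"), c("s1", "s1"))
  expect_true(all(cluster_opus(ortho, 0.44)$labels == "unclassified"))
  single <- subset_spectra(twin, "a")
  expect_equal(unname(cluster_opus(single, 0.44)$labels), "unclassified")
  expect_error(cluster_opus(twin, cutoff = 0), "cutoff")
})

test_that("planted templates are recovered at the default cutoff", {
  d <- small_scene_design(n_opu_templates = 5)
  sc <- simulate_scene(d, seed = 11)
  qc <- qc_signature_filter(sc$spectra)
  pp <- preprocess_spectra(qc$passed)
  a <- cluster_opus(pp$spectra, 0.44)
  tl <- sc$truth$true_opu_label[pp$spectra$cell_id]
  keep <- grepl("^template", tl)
  expect_gte(ari_index(a$labels[keep], tl[keep]), 0.90)
  # singleton-like outliers mostly land in the unclassified pool
  out <- tl == "outlier"
  if (any(out)) expect_gt(mean(a$labels[out] == "unclassified"), 0.5)
})

test_that("cluster labels are invariant to spectrum input order", {
  d <- scene_design(plant_species = c("a", "b"), n_taxa = 10,
                    spectra_per_sample = 15, n_opu_templates = 3)
  g <- generate_spectra(d, seed = 4)
  pp <- preprocess_spectra(g$spectra)
  a1 <- cluster_opus(pp$spectra, 0.44)
  set.seed(1)
  perm <- sample(n <- length(pp$spectra$cell_id))
  shuffled <- spectrum_set(pp$spectra$wavenumbers,
                           pp$spectra$intensities[, perm],
                           pp$spectra$cell_id[perm], pp$spectra$sample_id[perm])
  a2 <- cluster_opus(shuffled, 0.44)
  expect_identical(a1$labels[sort(names(a1$labels))],
                   a2$labels[sort(names(a2$labels))])
})

test_that("raising the cutoff never increases the number of flat clusters", {
  d <- scene_design(plant_species = c("a", "b"), n_taxa = 10,
                    spectra_per_sample = 15)
  g <- generate_spectra(d, seed = 6)
  pp <- preprocess_spectra(g$spectra)
  ks <- vapply(seq(0.1, 1.5, by = 0.2), function(h) {
    lab <- cluster_opus(pp$spectra, h)$labels
    length(unique(lab[lab != "unclassified"])) + sum(lab == "unclassified")
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("AIC cutoff selection finds planted structure and is idempotent", {
  d <- scene_design(plant_species = c("a", "b"), n_taxa = 10,
                    spectra_per_sample = 20, n_opu_templates = 3,
                    junk_fraction = 0, outlier_fraction = 0)
  g <- generate_spectra(d, seed = 9)
  pp <- preprocess_spectra(g$spectra)
  sel <- select_cutoff_by_aic(pp$spectra, seq(0.1, 0.9, 0.1))
  n_opu_at <- function(h) {
    lab <- cluster_opus(pp$spectra, h)$labels
    length(unique(lab[lab != "unclassified"]))
  }
  expect_equal(n_opu_at(sel$cutoff), 3)
  sel_dup <- select_cutoff_by_aic(pp$spectra, c(0.1, 0.1, seq(0.2, 0.9, 0.1)))
  expect_equal(sel$cutoff, sel_dup$cutoff)
  # single template: the chosen cutoff merges everything into one OPU
  d1 <- scene_design(plant_species = c("a", "b"), n_taxa = 10,
                     spectra_per_sample = 15, n_opu_templates = 1,
                     junk_fraction = 0, outlier_fraction = 0, noise_sd = 0.005)
  g1 <- generate_spectra(d1, seed = 10)
  pp1 <- preprocess_spectra(g1$spectra)
  sel1 <- select_cutoff_by_aic(pp1$spectra, seq(0.1, 0.9, 0.1))
  expect_equal(n_opu_at_1 <- {
    lab <- cluster_opus(pp1$spectra, sel1$cutoff)$labels
    length(unique(lab[lab != "unclassified"]))
  }, 1)
})

test_that("OPU tables close to one and report known shares", {
  assign_ <- structure(list(
    labels = setNames(c("OPU-0", "OPU-0", "OPU-1", "unclassified"),
                      paste0("c", 1:4)),
    sample_id = setNames(rep("s1", 4), paste0("c", 1:4)),
    cutoff = 0.44, tree = NULL), class = "opu_assignment")
  tab <- build_opu_table(assign_)
  expect_equal(unname(tab$shares["s1", c("OPU-0", "OPU-1", "unclassified")]),
               c(0.5, 0.25, 0.25))
  all_un <- structure(list(
    labels = setNames(rep("unclassified", 3), paste0("c", 1:3)),
    sample_id = setNames(rep("s1", 3), paste0("c", 1:3)),
    cutoff = 0.44, tree = NULL), class = "opu_assignment")
  expect_equal(unname(build_opu_table(all_un)$unclassified_fraction), 1)
  expect_warning(build_opu_table(assign_, samples = c("s1", "s2")), "no QC")
})

test_that("recovered OPU shares track the generating mixtures", {
  d <- scene_design(plant_species = c("a", "b"), replicates_per_plant = 2,
                    n_taxa = 10, spectra_per_sample = 200, n_opu_templates = 3,
                    junk_fraction = 0, outlier_fraction = 0)
  g <- generate_spectra(d, seed = 3)
  tl <- g$truth$true_opu_label
  assign_ <- structure(list(
    labels = setNames(sub("template-", "OPU-", tl), names(tl)),
    sample_id = setNames(g$spectra$sample_id, names(tl)),
    cutoff = 0.44, tree = NULL), class = "opu_assignment")
  tab <- build_opu_table(assign_)
  mix <- g$truth$template_mixtures
  for (k in 1:3) {
    expect_lt(max(abs(tab$shares[, paste0("OPU-", k)] - mix[, k])), 0.07)
  }
})

test_that("Fisher scores rank discriminative wavenumbers first", {
  grid <- seq(600, 1800, 1)
  mk <- function(extra_amp) {
    exp(-0.5 * ((grid - 1003) / 6)^2) + exp(-0.5 * ((grid - 1657) / 10)^2) +
      extra_amp * exp(-0.5 * ((grid - 1450) / 8)^2)
  }
  set.seed(2)
  m <- cbind(sapply(1:6, function(i) mk(0) + rnorm(1201, 0, 0.01)),
             sapply(1:6, function(i) mk(1) + rnorm(1201, 0, 0.01)))
  s <- spectrum_set(grid, m, sprintf("c%02d", 1:12), rep("s1", 12))
  assign_ <- structure(list(
    labels = setNames(rep(c("OPU-0", "OPU-1"), each = 6), s$cell_id),
    sample_id = setNames(s$sample_id, s$cell_id),
    cutoff = 0.44, tree = NULL), class = "opu_assignment")
  fs <- fisher_rank_scores(s, assign_)
  expect_lte(abs(fs$wavenumber[fs$rank == 1] - 1450), 5)
  # identical class means far from the band give near-zero scores
  expect_lt(fs$score[fs$wavenumber == 700], fs$score[fs$wavenumber == 1450] / 100)
  s2 <- spectrum_set(grid, 2 * m, s$cell_id, s$sample_id)
  fs2 <- fisher_rank_scores(s2, assign_)
  expect_equal(fs$rank, fs2$rank)
  one_class <- assign_
  one_class$labels[] <- "OPU-0"
  expect_error(fisher_rank_scores(s, one_class), "2 OPU classes")
})

test_that("OPU diversity reproduces closed forms", {
  shares <- rbind(s1 = c(0.25, 0.25, 0.25, 0.25, 0),
                  s2 = c(1, 0, 0, 0, 0),
                  s3 = c(0.5, 0.5, 0, 0, 0))
  colnames(shares) <- c(paste0("OPU-", 0:3), "unclassified")
  tab <- structure(list(shares = shares,
                        unclassified_fraction = shares[, "unclassified"]),
                   class = "opu_table")
  div <- opu_diversity(tab)
  expect_equal(div$richness, c(4, 1, 2))
  expect_equal(div$shannon, c(log(4), 0, log(2)))
  expect_equal(div$evenness, c(1, 0, 1))
})
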