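div_frame <- function(ids, richness, shannon = richness / 2,
                      evenness = pmin(1, richness / 10)) {
  data.frame(sample_id = ids, richness = richness, shannon = shannon,
             evenness = evenness)
}

test_that("diversity coupling regression recognizes exact and noisy fits", {
  ids <- sprintf("s%02d", 1:10)
  md <- data.frame(sample_id = ids, production = "conventional",
                   plant = "alfalfa")
  x <- seq(2, 20, length.out = 10)
  # y = x exactly: lm warns about the perfect fit, which is the point here
  reg <- suppressWarnings(
    diversity_coupling_regression(div_frame(ids, x), div_frame(ids, x),
                                  md, model = "linear"))
  expect_true(all(reg$r2 > 1 - 1e-12))
  expect_true(all(reg$p < 1e-12))
  expect_true(all(reg$stars == "***"))
  # a log1p-shaped relation favors the log1p model
  y <- log1p(x) * 4
  r_lin <- diversity_coupling_regression(div_frame(ids, x),
                                         div_frame(ids, y, y, y), md,
                                         model = "linear")
  r_log <- suppressWarnings(
    diversity_coupling_regression(div_frame(ids, x),
                                  div_frame(ids, y, y, y), md,
                                  model = "log1p"))
  expect_gte(r_log$r2[r_log$metric == "richness"],
             r_lin$r2[r_lin$metric == "richness"])
  # groups below n = 3 are omitted, not fabricated
  md2 <- md
  md2$plant <- c(rep("alfalfa", 8), "corn", "corn")
  reg2 <- suppressWarnings(
    diversity_coupling_regression(div_frame(ids, x), div_frame(ids, x),
                                  md2, model = "linear"))
  expect_false(any(grepl("corn", reg2$treatment)))
})

test_that("null diversity couplings are calibrated", {
  set.seed(31)
  ids <- sprintf("s%02d", 1:50)
  md <- data.frame(sample_id = ids, production = "conventional",
                   plant = "alfalfa")
  hits <- r2s <- numeric(60)
  for (r in 1:60) {
    x <- rnorm(50)
    y <- rnorm(50)
    reg <- diversity_coupling_regression(div_frame(ids, x),
                                         div_frame(ids, y, y, y), md,
                                         model = "linear")
    hits[r] <- reg$p[reg$metric == "richness"] < 0.05
    r2s[r] <- reg$r2[reg$metric == "richness"]
  }
  expect_lt(mean(hits), 0.15)
  expect_lt(mean(r2s), 3 / 49)
})

test_that("dbRDA reproduces eigen identities and matches vegan", {
  set.seed(3)
  X <- matrix(rnorm(60), 12, 5)
  rownames(X) <- paste0("s", 1:12)
  d <- dist(X)
  G <- -0.5 * as.matrix(d)^2
  J <- diag(12) - 1 / 12
  eg <- eigen(J %*% G %*% J, symmetric = TRUE)
  pc1 <- eg$vectors[, 1] * sqrt(eg$values[1])
  r1 <- dbrda(d, cbind(pc1), n_perm = 99, seed = 1)
  expect_equal(r1$constrained_fraction,
               eg$values[1] / sum(eg$values[eg$values > 1e-8]),
               tolerance = 1e-6)
  cs <- vegan::capscale(d ~ pc1)
  expect_equal(r1$constrained_fraction,
               cs$CCA$tot.chi / (cs$CCA$tot.chi + cs$CA$tot.chi),
               tolerance = 1e-6)
  # constant constraints explain nothing; saturated constraints everything
  expect_equal(dbrda(d, matrix(1, 12, 1), n_perm = 99)$constrained_fraction, 0)
  expect_equal(dbrda(d, matrix(rnorm(132), 12, 11),
                     n_perm = 99)$constrained_fraction, 1, tolerance = 1e-6)
})

test_that("dbRDA constrained fraction grows monotonically with constraints", {
  set.seed(8)
  X <- matrix(rnorm(80), 16, 5)
  d <- dist(X)
  Z <- matrix(rnorm(64), 16, 4)
  fr <- vapply(1:4, function(k)
    dbrda(d, Z[, 1:k, drop = FALSE], n_perm = 99)$constrained_fraction,
    numeric(1))
  expect_true(all(diff(fr) >= -1e-12))
  # collinear constraints collapse to a full-rank basis with a warning
  expect_warning(dbrda(d, cbind(Z[, 1], 2 * Z[, 1]), n_perm = 99), "collinear")
})

test_that("vector fitting scores alignment, nulls and floors correctly", {
  set.seed(4)
  sc <- matrix(rnorm(40), 20, 2)
  ef <- fit_opu_vectors(sc, cbind(ax = sc[, 1]), n_perm = 199, seed = 1)
  expect_equal(ef$r2[1], 1, tolerance = 1e-9)
  expect_equal(abs(ef$dir1[1]), 1, tolerance = 1e-6)
  expect_equal(ef$p[1], 1 / 200)
  # unit direction, permutation floor, BH ordering
  V <- cbind(a = sc[, 1] + rnorm(20, 0, 0.5), b = rnorm(20), c = rnorm(20))
  ef2 <- fit_opu_vectors(sc, V, n_perm = 199, seed = 2)
  expect_lt(max(abs(sqrt(ef2$dir1^2 + ef2$dir2^2) - 1)), 1e-9)
  expect_true(all(ef2$p >= 1 / 200))
  expect_true(all(ef2$bh >= ef2$p - 1e-12))
  # oracle agreement for the observed r2
  for (j in 1:3) expect_equal(ef2$r2[j], envfit_r2_oracle(sc, V[, j]),
                              tolerance = 1e-9)
  # zero-variance variables are reported inert
  ef3 <- fit_opu_vectors(sc, cbind(flat = rep(2, 20)), n_perm = 99, seed = 3)
  expect_equal(ef3$r2[1], 0)
  expect_equal(ef3$p[1], 1)
})

test_that("Spearman map matches the rank-then-Pearson oracle exactly", {
  x <- c(3.1, 5.2, 1.4, 8.8, 2.2, 7.0)
  y <- c(2.0, 6.1, 1.1, 9.9, 3.3, 5.5)
  Tx <- cbind(t1 = x, t2 = rev(x))
  Op <- cbind(o1 = y, o2 = 10 - y, o3 = c(1, 2, 2, 3, 3, 4))
  rownames(Tx) <- rownames(Op) <- paste0("s", 1:6)
  sp <- spearman_opu_taxa(Tx, Op)
  for (i in 1:2) for (j in 1:3) {
    expect_equal(sp$rho[i, j], spearman_oracle(Tx[, i], Op[, j]),
                 tolerance = 1e-12)
  }
  # monotone pairs hit the boundaries
  mono <- cbind(m = sort(x))
  updown <- cbind(up = 1:6, down = 6:1)
  rownames(mono) <- rownames(updown) <- paste0("s", 1:6)
  sp2 <- spearman_opu_taxa(mono, updown)
  expect_equal(unname(sp2$rho[1, ]), c(1, -1))
  # constant columns are reported missing
  km <- cbind(k = rep(1, 6), m = x)
  rownames(km) <- paste0("s", 1:6)
  spc <- spearman_opu_taxa(km, Op)
  expect_true(all(is.na(spc$rho["k", ])))
  expect_false(anyNA(spc$rho["m", ]))
})

test_that("planted couplings surface as significant Spearman pairs", {
  d <- scene_design(plant_species = letters[1:4], n_taxa = 30,
                    spectra_per_sample = 40,
                    couplings = data.frame(opu = 1, taxon = 5, sign = 1),
                    coupling_strength = 1.5)
  hits <- 0
  for (s in 1:5) {
    sc <- simulate_scene(d, seed = 200 + s)
    tl <- sc$truth$true_opu_label
    assign_ <- structure(list(
      labels = setNames(ifelse(grepl("^template", tl),
                               sub("template-", "OPU-", tl), "unclassified"),
                        names(tl)),
      sample_id = setNames(sc$spectra$sample_id, names(tl)),
      cutoff = 0.44, tree = NULL), class = "opu_assignment")
    shares <- build_opu_table(assign_)$shares
    rel <- relative_abundance(sc$asv)
    sp <- spearman_opu_taxa(rel, shares[rownames(rel), ])
    if (isTRUE(sp$bh["ASV005", "OPU-1"] < 0.1)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
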