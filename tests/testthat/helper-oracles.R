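# Independent oracles and small fixture builders shared across tests.
# Every oracle here is written from the definition, not from the code path
# it checks.

# Adjusted Rand index from the contingency-table definition.
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Normalized betweenness by direct geodesic enumeration: distances and
# geodesic counts from successive adjacency-matrix powers ((A^d)[s,t] counts
# walks of length d, which at d = d(s,t) are exactly the geodesics).
brute_betweenness <- function(A) {
  n <- nrow(A)
  pow <- list(diag(n), A)
  Dm <- matrix(Inf, n, n)
  diag(Dm) <- 0
  Dm[A > 0] <- 1
  k <- 1
  Ak <- A
  while (any(!is.finite(Dm)) && k < n) {
    k <- k + 1
    Ak <- Ak %*% A
    pow[[k + 1]] <- Ak
    newly <- !is.finite(Dm) & Ak > 0
    Dm[newly] <- k
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(Dm[s, t])) sigma[s, t] <- pow[[Dm[s, t] + 1]][s, t]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(Dm[s, t]) || sigma[s, t] == 0) next
      if (is.finite(Dm[s, v]) && is.finite(Dm[v, t]) &&
          Dm[s, v] + Dm[v, t] == Dm[s, t]) {
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    bc[v] <- tot
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# Classic two-group PERMANOVA pseudo-F straight from squared dissimilarities.
permanova_f_from_d <- function(Dmat, grp) {
  n <- nrow(Dmat)
  D2 <- Dmat^2
  ss_tot <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- D2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_b <- ss_tot - ss_w
  (ss_b / (length(unique(grp)) - 1)) / (ss_w / (n - length(unique(grp))))
}

# Exhaustive two-group permutation p over all balanced assignments.
exhaustive_permanova_p <- function(Dmat, grp) {
  n <- nrow(Dmat)
  g1 <- sum(grp == unique(grp)[1])
  f_obs <- permanova_f_from_d(Dmat, grp)
  sets <- utils::combn(n, g1)
  f_perm <- apply(sets, 2, function(idx) {
    lab <- rep("b", n)
    lab[idx] <- "a"
    permanova_f_from_d(Dmat, lab)
  })
  mean(f_perm >= f_obs - 1e-12)
}

# Spearman rho by explicit average-ranking then Pearson.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# r^2 of a variable on two axis columns by a normal-equations solve.
envfit_r2_oracle <- function(scores, v) {
  X <- sweep(as.matrix(scores)[, 1:2], 2, colMeans(as.matrix(scores)[, 1:2]))
  vc <- v - mean(v)
  b <- solve(crossprod(X), crossprod(X, vc))
  1 - sum((vc - X %*% b)^2) / sum(vc^2)
}

# Hand-built spectrum set: one column per cell, Gaussian bands on a grid.
toy_spectra <- function(band_sets, grid = seq(600, 1800, by = 1),
                        sample_id = NULL, noise_sd = 0) {
  n <- length(band_sets)
  m <- vapply(band_sets, function(bd) {
    y <- rep(0, length(grid))
    for (i in seq_len(nrow(bd))) {
      y <- y + bd$amp[i] * exp(-0.5 * ((grid - bd$center[i]) / bd$width[i])^2)
    }
    y + rnorm(length(grid), 0, noise_sd)
  }, numeric(length(grid)))
  spectrum_set(grid, m, sprintf("cell%02d", seq_len(n)),
               sample_id %||% rep("s1", n))
}

bands <- function(center, width = 8, amp = 1) {
  data.frame(center = center, width = width, amp = amp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small joint scene used by several modules.
small_scene_design <- function(...) {
  scene_design(plant_species = c("alfalfa", "corn"), n_taxa = 30,
               spectra_per_sample = 25, ...)
}
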