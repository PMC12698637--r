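# Genotype-phenotype integration: diversity-coupling regressions, distance-
# based redundancy analysis with OPU constraints, vector fitting with
# permutation tests, and Spearman OPU-taxon correlation maps.

#' Diversity-coupling regression between ASV and OPU alpha diversity
#'
#' For each treatment group and each metric (richness, Shannon, evenness),
#' fits OLS of the OPU metric on the ASV metric, either on the raw scale or
#' with both variables log1p-transformed. Reports R^2, the two-sided slope
#' p-value and significance stars at 0.05/0.01/0.001.
#'
#' @param asv_div,opu_div data.frames from [alpha_diversity()] and
#'   [opu_diversity()] sharing `sample_id`.
#' @param metadata data.frame with `sample_id` and the treatment columns.
#' @param treatment metadata column(s) defining the groups; default
#'   `c("production", "plant")` fits one model per production x plant cell.
#' @param model `"linear"` or `"log1p"` (both variables mapped x -> ln(1+x)).
#' @return data.frame: treatment, metric, model, n, slope, intercept, r2, p,
#'   stars. Cells with n < 3 are omitted rather than fabricated.
#' @export
diversity_coupling_regression <- function(asv_div, opu_div, metadata,
                                          treatment = c("production", "plant"),
                                          model = c("linear", "log1p")) {
  model <- match.arg(model)
  common <- intersect(asv_div$sample_id, opu_div$sample_id)
  if (length(common) < 3) stopf("fewer than 3 paired samples")
  a <- asv_div[match(common, asv_div$sample_id), ]
  o <- opu_div[match(common, opu_div$sample_id), ]
  md <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  grp <- interaction(md[treatment], drop = TRUE, sep = ":")
  out <- list()
  for (g in levels(grp)) {
    rows <- which(grp == g)
    if (length(rows) < 3) next
    for (metric in c("richness", "shannon", "evenness")) {
      x <- a[[metric]][rows]
      y <- o[[metric]][rows]
      if (model == "log1p") { x <- log1p(x); y <- log1p(y) }
      if (var(x) == 0) next
      fit <- lm(y ~ x)
      sm <- summary(fit)
      p <- sm$coefficients["x", "Pr(>|t|)"]
      out[[length(out) + 1L]] <- data.frame(
        treatment = g, metric = metric, model = model, n = length(rows),
        slope = unname(coef(fit)["x"]), intercept = unname(coef(fit)[1]),
        r2 = sm$r.squared, p = p,
        stars = if (p < 0.001) "***" else if (p < 0.01) "**" else
          if (p < 0.05) "*" else "")
    }
  }
  do.call(rbind, out)
}

#' Distance-based redundancy analysis
#'
#' The dissimilarity matrix is Gower-centered (G = -1/2 J D^2 J) and
#' eigen-decomposed; axes with negative eigenvalues are dropped. The
#' retained principal coordinates are regressed on the centered constraint
#' matrix; the eigen-decomposition of the fitted values gives the
#' constrained axes. The constrained-inertia fraction is
#' trace(fitted) / trace(retained), and overall significance comes from a
#' permutation pseudo-F over constraint rows.
#'
#' @param d a `dist` object.
#' @param constraints numeric matrix/data.frame (samples x variables),
#'   rows aligned with `d`.
#' @param n_perm permutations for the overall test (default 999).
#' @param seed integer seed.
#' @return object of class `dbrda_result`: `site_scores` (constrained axes),
#'   `biplot` (constraint arrows), `eig` (constrained eigenvalues),
#'   `constrained_fraction`, `pseudo_f`, `p`, `rank`.
#' @export
dbrda <- function(d, constraints, n_perm = 999, seed = 1) {
  Dm <- as.matrix(d)
  n <- nrow(Dm)
  X <- as.matrix(constraints)
  if (nrow(X) != n) stopf("constraint rows must align with the distance matrix")
  if (ncol(X) >= n - 1) {
    # saturated designs are allowed (fraction -> 1) but flagged
    if (ncol(X) > n - 1) warnf("more constraints than samples - 1")
  }
  G <- -0.5 * Dm^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- G + mean(-0.5 * Dm^2)   # J G J double-centering
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-8
  lambda <- eg$values[pos]
  Y <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda), sum(pos))

  Xc <- sweep(X, 2, colMeans(X))
  qrX <- qr(Xc)
  r <- qrX$rank
  if (r == 0) {
    return(structure(list(site_scores = Y[, 1:min(2, ncol(Y)), drop = FALSE],
                          biplot = NULL, eig = numeric(0),
                          constrained_fraction = 0, pseudo_f = NA_real_,
                          p = NA_real_, rank = 0L),
                     class = "dbrda_result"))
  }
  if (r < ncol(Xc)) warnf("collinear constraints reduced to a rank-%d basis", r)

  fit_stats <- function(Yc, qrXc, rk) {
    Fhat <- qr.fitted(qrXc, Yc)
    ss_c <- sum(Fhat^2)
    ss_t <- sum(Yc^2)
    list(Fhat = Fhat, ss_c = ss_c, frac = ss_c / ss_t,
         f = (ss_c / rk) / ((ss_t - ss_c) / max(n - 1 - rk, 1)))
  }
  obs <- fit_stats(Y, qrX, r)
  sv <- svd(obs$Fhat)
  keep <- sv$d > max(sv$d) * 1e-8
  axes <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  rownames(axes) <- attr(d, "Labels") %||% rownames(Dm)
  colnames(axes) <- paste0("dbRDA", seq_len(ncol(axes)))
  # biplot arrows: correlations of constraints with the constrained axes
  bip <- cor(Xc, axes[, seq_len(min(2, ncol(axes))), drop = FALSE])

  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    qp <- qr(Xc[idx, , drop = FALSE])
    if (fit_stats(Y, qp, r)$f >= obs$f) exceed <- exceed + 1L
  }
  structure(list(site_scores = axes, biplot = bip,
                 eig = (sv$d[keep]^2),
                 constrained_fraction = obs$frac,
                 pseudo_f = obs$f,
                 p = (exceed + 1) / (n_perm + 1),
                 rank = r),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: %.1f%% of inertia constrained (rank %d), pseudo-F %.2f, p = %.4g\n",
              100 * x$constrained_fraction, x$rank, x$pseudo_f, x$p))
  invisible(x)
}

#' Fit OPU vectors onto an ordination plane
#'
#' Post-hoc vector fitting of each variable onto two ordination axes (vegan
#' envfit machinery): r^2 from the regression of the centered variable on
#' the axis scores, direction as the unit coefficient vector, permutation
#' p-value with floor 1/(n_perm + 1), and BH adjustment across variables.
#'
#' @param scores sample x 2 ordination coordinates (e.g. dbRDA or NMDS).
#' @param variables sample x variable matrix/data.frame (e.g. OPU shares).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param alpha significance threshold on BH-adjusted p (default 0.1).
#' @return data.frame: variable, r2, dir1, dir2 (unit vector), p, bh, sig.
#' @export
fit_opu_vectors <- function(scores, variables, n_perm = 999, seed = 1,
                            alpha = 0.1) {
  S <- as.matrix(scores)[, 1:2]
  V <- as.matrix(variables)
  if (nrow(S) != nrow(V)) stopf("scores and variables must be row-aligned")
  keep <- apply(V, 2, function(v) var(v) > 0)
  out <- data.frame(variable = colnames(V), r2 = 0, dir1 = NA_real_,
                    dir2 = NA_real_, p = 1, row.names = NULL)
  if (any(keep)) {
    set.seed(seed)
    fit <- vegan::envfit(S, as.data.frame(V[, keep, drop = FALSE]),
                         permutations = n_perm)
    arr <- fit$vectors$arrows
    nrm <- sqrt(rowSums(arr^2))
    out$r2[keep] <- fit$vectors$r
    out$dir1[keep] <- arr[, 1] / nrm
    out$dir2[keep] <- arr[, 2] / nrm
    out$p[keep] <- fit$vectors$pvals
  }
  out$bh <- bh_adjust(out$p)
  out$sig <- out$bh < alpha
  out
}

#' Spearman correlation map between core taxa and OPU abundances
#'
#' Spearman rho with average-rank ties between every (taxon, OPU) pair,
#' two-sided p from the t approximation, BH adjustment across the full
#' pair family, and star flags at BH p < 0.1 (*) and < 0.05 (**).
#'
#' @param taxa_profiles sample x taxon abundances (e.g. relative abundances
#'   of the filtered core taxa).
#' @param opu_table an `opu_table` or sample x OPU share matrix.
#' @return list of matrices: `rho`, `p`, `bh`, `stars` (taxa x OPUs);
#'   constant columns yield NA entries.
#' @export
spearman_opu_taxa <- function(taxa_profiles, opu_table) {
  Tx <- as.matrix(taxa_profiles)
  Op <- if (inherits(opu_table, "opu_table")) opu_table$shares else as.matrix(opu_table)
  common <- intersect(rownames(Tx), rownames(Op))
  if (length(common) < 4) stopf("need >= 4 paired samples")
  Tx <- Tx[common, , drop = FALSE]
  Op <- Op[common, , drop = FALSE]
  n <- length(common)
  rho <- matrix(NA_real_, ncol(Tx), ncol(Op),
                dimnames = list(colnames(Tx), colnames(Op)))
  pmat <- rho
  const_t <- apply(Tx, 2, var) == 0
  const_o <- apply(Op, 2, var) == 0
  ok_pairs <- outer(!const_t, !const_o, `&`)
  if (any(ok_pairs)) {
    r <- cor(Tx[, !const_t, drop = FALSE], Op[, !const_o, drop = FALSE],
             method = "spearman")
    rho[!const_t, !const_o] <- r
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pmat[!const_t, !const_o] <- 2 * pt(-abs(tstat), n - 2)
  }
  bh <- matrix(bh_adjust(as.vector(pmat)), nrow(pmat), ncol(pmat),
               dimnames = dimnames(pmat))
  stars <- matrix("", nrow(pmat), ncol(pmat), dimnames = dimnames(pmat))
  stars[!is.na(bh) & bh < 0.1] <- "*"
  stars[!is.na(bh) & bh < 0.05] <- "**"
  list(rho = rho, p = pmat, bh = bh, stars = stars)
}
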