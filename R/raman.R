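# Single-cell Raman phenotyping: QC gate on biological signature peaks,
# preprocessing, OPU clustering with AIC cutoff selection, OPU tables,
# Fisher wavenumber ranking and OPU alpha diversity.

# Asymmetric least squares baseline (Eilers-style): iteratively reweighted
# penalized smoother; positive residuals (peaks) are down-weighted so the fit
# hugs the baseline under the bands.
als_baseline <- function(y, lambda = 1e5, p = 0.01, maxit = 10) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2), rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(m, w)
    z_new <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z_new, p, 1 - p)
    if (max(abs(z_new - z)) < 1e-10 * (1 + max(abs(z)))) { z <- z_new; break }
    z <- z_new
    w <- w_new
  }
  z
}

robust_noise <- function(y) 1.4826 * median(abs(y - median(y)))

# A local maximum inside the window whose prominence exceeds the threshold.
# Prominence is the drop from the peak to the HIGHER of the two flanking
# minima (evaluated over the window extended by one halfwidth each side), so
# the signal must fall away on both sides: shoulders of neighboring bands and
# tilted baselines do not qualify.
has_peak <- function(grid, y, center, halfwidth, threshold) {
  idx <- which(grid >= center - halfwidth & grid <= center + halfwidth)
  if (length(idx) < 3) return(FALSE)
  ext <- which(grid >= center - 3 * halfwidth & grid <= center + 3 * halfwidth)
  lo_ext <- min(ext); hi_ext <- max(ext)
  for (i in idx) {
    if (i <= 1 || i >= length(y)) next
    if (y[i] < y[i - 1] || y[i] < y[i + 1]) next
    left_min <- min(y[lo_ext:i])
    right_min <- min(y[i:hi_ext])
    if (y[i] - max(left_min, right_min) >= threshold) return(TRUE)
  }
  FALSE
}

#' Quality-control gate on the biological signature peaks
#'
#' A cell spectrum is kept only if, after baseline subtraction, it shows a
#' local maximum in both the phenylalanine (1003 cm^-1) and amide I
#' (1657 cm^-1) windows with height at least `snr_min` times a robust noise
#' estimate (scaled median absolute deviation of the 1750-1800 cm^-1 region,
#' assumed signal-free).
#'
#' @param spectra a [spectrum_set()] of raw spectra.
#' @param window_halfwidth half-width of each signature window (cm^-1).
#' @param snr_min minimum peak height / noise ratio.
#' @param noise_region length-2 numeric range used for the noise estimate.
#' @return list with `passed` (a `spectrum_set`, input order preserved) and
#'   `rejected` (cell ids).
#' @export
qc_signature_filter <- function(spectra, window_halfwidth = 5, snr_min = 3,
                                noise_region = c(1750, 1800)) {
  grid <- spectra$wavenumbers
  for (ctr in c(1003, 1657)) {
    if (ctr - window_halfwidth < min(grid) || ctr + window_halfwidth > max(grid)) {
      stopf("wavenumber grid does not cover the %g cm^-1 signature window", ctr)
    }
  }
  n <- n_spectra(spectra)
  if (n == 0) return(list(passed = spectra, rejected = character()))
  noise_idx <- which(grid >= noise_region[1] & grid <= noise_region[2])
  ok <- logical(n)
  for (i in seq_len(n)) {
    y <- spectra$intensities[, i]
    y <- y - als_baseline(y)
    # noise level from the raw residual; prominence judged on a lightly
    # smoothed signal so only band-shaped maxima qualify
    noise <- max(robust_noise(y[noise_idx]), 1e-12)
    y <- signal::sgolayfilt(y, p = 3, n = 11)
    thr <- snr_min * noise
    ok[i] <- has_peak(grid, y, 1003, window_halfwidth, thr) &&
      has_peak(grid, y, 1657, window_halfwidth, thr)
  }
  list(passed = subset_spectra(spectra, spectra$cell_id[ok]),
       rejected = spectra$cell_id[!ok])
}

#' Preprocess spectra for clustering
#'
#' Pipeline: linear interpolation onto a common grid, asymmetric least
#' squares baseline subtraction, Savitzky-Golay smoothing, and unit-vector
#' (L2) normalization. Spectra that are numerically zero after baseline
#' removal are flagged degenerate and dropped.
#'
#' @param spectra a [spectrum_set()].
#' @param grid target wavenumber grid (default: the input grid).
#' @param lambda,p ALS baseline parameters.
#' @param sg_window,sg_order Savitzky-Golay window length (odd) and
#'   polynomial order.
#' @return list with `spectra` (processed `spectrum_set`, each column with
#'   unit L2 norm) and `degenerate` (dropped cell ids).
#' @export
preprocess_spectra <- function(spectra, grid = NULL, lambda = 1e5, p = 0.01,
                               sg_window = 11, sg_order = 3) {
  if (is.null(grid)) grid <- spectra$wavenumbers
  if (any(diff(grid) <= 0)) stopf("target grid must be strictly increasing")
  n <- n_spectra(spectra)
  out <- matrix(0, length(grid), n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    y <- approx(spectra$wavenumbers, spectra$intensities[, i], xout = grid,
                rule = 2)$y
    y <- y - als_baseline(y, lambda = lambda, p = p)
    y <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
    nrm <- sqrt(sum(y^2))
    if (nrm < 1e-10) {
      degenerate[i] <- TRUE
    } else {
      out[, i] <- y / nrm
    }
  }
  keep <- !degenerate
  list(
    spectra = spectrum_set(grid, out[, keep, drop = FALSE],
                           spectra$cell_id[keep], spectra$sample_id[keep]),
    degenerate = spectra$cell_id[degenerate]
  )
}

#' Cluster preprocessed spectra into operational phenotypic units
#'
#' Pairwise dissimilarity is 1 - Pearson correlation between spectra;
#' average-linkage hierarchical clustering is cut at `cutoff`. Clusters of
#' size one are pooled as `"unclassified"`; the rest are labeled `OPU-0`,
#' `OPU-1`, ... in decreasing size order (ties broken by the smallest member
#' cell id).
#'
#' @param spectra a preprocessed [spectrum_set()] on a shared grid.
#' @param cutoff flat-cut dissimilarity height, in (0, 2); default 0.44
#'   (AIC-selected for hyperdiverse soil communities).
#' @return object of class `opu_assignment`: `labels` (named by cell id),
#'   `sample_id`, `cutoff`, `tree` (hclust object, NULL when < 2 spectra).
#' @export
cluster_opus <- function(spectra, cutoff = 0.44) {
  if (cutoff <= 0 || cutoff >= 2) stopf("cutoff must lie in (0, 2)")
  n <- n_spectra(spectra)
  if (n < 2) {
    labels <- setNames(rep("unclassified", n), spectra$cell_id)
    return(structure(list(labels = labels, sample_id = setNames(spectra$sample_id, spectra$cell_id),
                          cutoff = cutoff, tree = NULL),
                     class = "opu_assignment"))
  }
  d <- as.dist(1 - cor(spectra$intensities))
  tree <- hclust(d, method = "average")
  raw <- cutree(tree, h = cutoff)
  labels <- relabel_opus(raw, spectra$cell_id)
  structure(list(labels = setNames(labels, spectra$cell_id),
                 sample_id = setNames(spectra$sample_id, spectra$cell_id),
                 cutoff = cutoff, tree = tree),
            class = "opu_assignment")
}

# Canonical OPU labels: decreasing cluster size, ties by smallest member id;
# singletons become "unclassified".
relabel_opus <- function(raw, cell_id) {
  sizes <- table(raw)
  multi <- names(sizes)[sizes >= 2]
  first_member <- vapply(multi, function(cl) min(cell_id[raw == cl]), character(1))
  ord <- multi[order(-sizes[multi], first_member)]
  map <- setNames(sprintf("OPU-%d", seq_along(ord) - 1L), ord)
  out <- rep("unclassified", length(raw))
  hit <- as.character(raw) %in% names(map)
  out[hit] <- map[as.character(raw)[hit]]
  out
}

#' @export
print.opu_assignment <- function(x, ...) {
  tab <- table(x$labels)
  n_opu <- sum(names(tab) != "unclassified")
  cat(sprintf("OPU assignment: %d cells, %d OPUs, %d unclassified (cutoff %.2f)\n",
              length(x$labels), n_opu,
              sum(x$labels == "unclassified"), x$cutoff))
  invisible(x)
}

#' Select the clustering cutoff by AIC
#'
#' Spectra are projected onto the principal components explaining 95% of the
#' variance (dimensionality q). For each candidate height h the tree is cut,
#' the within-cluster residual sum of squares RSS(h) is computed in that
#' space, and AIC(h) = n q ln(RSS/(n q)) + 2 k(h) q with k the number of
#' flat clusters (non-singletons plus singletons). The argmin is returned;
#' ties go to the smallest h.
#'
#' @param spectra a preprocessed [spectrum_set()].
#' @param candidates numeric vector of candidate cutoffs (>= 2 values).
#' @param var_explained PCA variance fraction defining the projection.
#' @return list with `cutoff`, `curve` (data.frame: cutoff, k, n_opu, rss,
#'   aic) and `degenerate` flag (TRUE when every candidate left all spectra
#'   singletons, in which case the largest candidate is returned).
#' @export
select_cutoff_by_aic <- function(spectra, candidates = seq(0.1, 0.9, by = 0.02),
                                 var_explained = 0.95) {
  candidates <- sort(unique(candidates))
  if (length(candidates) < 2) stopf("need at least 2 candidate cutoffs")
  n <- n_spectra(spectra)
  if (n < 3) stopf("need at least 3 spectra to scan cutoffs")
  d <- as.dist(1 - cor(spectra$intensities))
  tree <- hclust(d, method = "average")

  pc <- prcomp(t(spectra$intensities), center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  q <- max(1L, which(cum >= var_explained)[1])
  S <- pc$x[, seq_len(q), drop = FALSE]

  curve <- data.frame(cutoff = candidates, k = NA_integer_, n_opu = NA_integer_,
                      rss = NA_real_, aic = NA_real_)
  for (ci in seq_along(candidates)) {
    cl <- cutree(tree, h = candidates[ci])
    k <- length(unique(cl))
    rss <- 0
    for (g in unique(cl)) {
      rows <- S[cl == g, , drop = FALSE]
      if (nrow(rows) > 1) {
        mu <- colMeans(rows)
        rss <- rss + sum(sweep(rows, 2, mu)^2)
      }
    }
    sizes <- table(cl)
    curve$k[ci] <- k
    curve$n_opu[ci] <- sum(sizes >= 2)
    curve$rss[ci] <- rss
    curve$aic[ci] <- n * q * log(max(rss, 1e-12) / (n * q)) + 2 * k * q
  }
  if (all(curve$k == n)) {
    warnf("every candidate cutoff leaves all spectra as singletons; returning the largest")
    return(list(cutoff = max(candidates), curve = curve, degenerate = TRUE))
  }
  best <- which.min(curve$aic)   # which.min takes the first (smallest h) on ties
  list(cutoff = curve$cutoff[best], curve = curve, degenerate = FALSE)
}

#' Per-sample OPU relative abundance table
#'
#' Shares of each OPU plus the `"unclassified"` singleton pool per sample
#' (rows sum to one). The reporting view lumping OPUs below an overall share
#' threshold is available via [lump_minor_opus()]; the full table is used
#' for statistics.
#'
#' @param assignment an `opu_assignment` from [cluster_opus()].
#' @param samples optional sample ordering (default: order of appearance).
#' @return object of class `opu_table`: `shares` (sample x OPU matrix with
#'   an `unclassified` column) and `unclassified_fraction`.
#' @export
build_opu_table <- function(assignment, samples = NULL) {
  sid <- assignment$sample_id
  lab <- assignment$labels
  if (is.null(samples)) samples <- unique(sid)
  empty <- setdiff(samples, unique(sid))
  if (length(empty)) {
    warnf("samples with no QC-passing cells dropped: %s", paste(empty, collapse = ", "))
    samples <- setdiff(samples, empty)
  }
  opu_names <- sort(unique(lab[lab != "unclassified"]))
  opu_names <- opu_names[order(as.integer(sub("OPU-", "", opu_names)))]
  cols <- c(opu_names, "unclassified")
  shares <- matrix(0, length(samples), length(cols),
                   dimnames = list(samples, cols))
  for (s in samples) {
    tab <- table(factor(lab[sid == s], levels = cols))
    shares[s, ] <- as.numeric(tab) / sum(tab)
  }
  structure(list(shares = shares,
                 unclassified_fraction = shares[, "unclassified"]),
            class = "opu_table")
}

#' @export
print.opu_table <- function(x, ...) {
  cat(sprintf("OPU table: %d samples x %d OPUs (+ unclassified pool, mean %.1f%%)\n",
              nrow(x$shares), ncol(x$shares) - 1L,
              100 * mean(x$unclassified_fraction)))
  invisible(x)
}

#' Lump minor OPUs for reporting
#'
#' OPUs whose overall (all-cells pooled) relative abundance is below
#' `threshold` are combined into a single `"Other minor OPUs"` column,
#' mirroring how sparse phenotype clusters are displayed.
#'
#' @param table an `opu_table`.
#' @param threshold overall share below which an OPU is lumped (default
#'   0.005 = 0.5%).
#' @return matrix of shares with minor OPUs combined.
#' @export
lump_minor_opus <- function(table, threshold = 0.005) {
  shares <- table$shares
  opu_cols <- setdiff(colnames(shares), "unclassified")
  overall <- colMeans(shares[, opu_cols, drop = FALSE])
  minor <- opu_cols[overall < threshold]
  major <- setdiff(opu_cols, minor)
  out <- shares[, major, drop = FALSE]
  if (length(minor)) {
    out <- cbind(out, `Other minor OPUs` = rowSums(shares[, minor, drop = FALSE]))
  }
  cbind(out, unclassified = shares[, "unclassified"])
}

#' Fisher discriminant score per wavenumber
#'
#' For OPU classes c with per-class means mu_cj and variances s2_cj at
#' wavenumber j, F(j) = sum_c n_c (mu_cj - mu_j)^2 / sum_c n_c s2_cj.
#' Unclassified cells are excluded; zero within-class variances are guarded
#' by machine epsilon. High scores mark the wavenumbers that best separate
#' phenotypes.
#'
#' @param spectra preprocessed [spectrum_set()].
#' @param assignment matching `opu_assignment`.
#' @return data.frame (wavenumber, score, rank) sorted by grid order; rank 1
#'   is the most discriminative wavenumber.
#' @export
fisher_rank_scores <- function(spectra, assignment) {
  lab <- assignment$labels[spectra$cell_id]
  keep <- lab != "unclassified"
  classes <- unique(lab[keep])
  if (length(classes) < 2) stopf("need >= 2 OPU classes for Fisher scores")
  X <- spectra$intensities[, keep, drop = FALSE]
  lab <- lab[keep]
  grand <- rowMeans(X)
  num <- den <- rep(0, nrow(X))
  for (cl in classes) {
    cols <- lab == cl
    n_c <- sum(cols)
    if (n_c < 2) stopf("class %s has fewer than 2 members", cl)
    mu_c <- rowMeans(X[, cols, drop = FALSE])
    s2_c <- apply(X[, cols, drop = FALSE], 1, var)
    num <- num + n_c * (mu_c - grand)^2
    den <- den + n_c * s2_c
  }
  score <- num / pmax(den, .Machine$double.eps)
  data.frame(wavenumber = spectra$wavenumbers, score = score,
             rank = rank(-score, ties.method = "first"))
}

# Shared alpha-diversity kernel: richness, Shannon H (natural log), Pielou
# evenness (0 when richness <= 1).
diversity_metrics <- function(p) {
  p <- p[p > 0]
  richness <- length(p)
  p <- p / sum(p)
  shannon <- if (richness == 0) 0 else -sum(p * log(p))
  evenness <- if (richness <= 1) 0 else shannon / log(richness)
  c(richness = richness, shannon = shannon, evenness = evenness)
}

#' OPU alpha diversity per sample
#'
#' Richness, Shannon index and Pielou evenness over identified OPUs; the
#' unclassified pool is excluded and shares renormalized, since diversity is
#' defined over recognized phenotype units.
#'
#' @param table an `opu_table`.
#' @return data.frame with sample_id, richness, shannon, evenness.
#' @export
opu_diversity <- function(table) {
  shares <- table$shares[, setdiff(colnames(table$shares), "unclassified"),
                         drop = FALSE]
  res <- t(apply(shares, 1, diversity_metrics))
  data.frame(sample_id = rownames(shares), res, row.names = NULL)
}
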