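# ASV-side community statistics: rarefaction, coverage, core-taxon
# filtering, CLR, Bray-Curtis, NMDS, PERMANOVA and alpha diversity.

#' Rarefy all samples to an even depth
#'
#' Exact subsampling without replacement (multivariate hypergeometric): each
#' retained sample is drawn down to exactly `depth` reads. Samples below the
#' target depth are dropped with a warning; all-zero taxon columns are kept
#' so tables stay aligned.
#'
#' @param table an [asv_table()].
#' @param depth target depth, or `"min"` for the smallest sample sum.
#' @param seed integer seed.
#' @return a rarefied `asv_table`.
#' @export
rarefy_even_depth <- function(table, depth = "min", seed = 1) {
  counts <- table$counts
  sums <- rowSums(counts)
  if (identical(depth, "min")) depth <- min(sums)
  depth <- as.integer(depth)
  if (depth <= 0) stopf("rarefaction depth must be positive")
  drop <- sums < depth
  if (any(drop)) {
    warnf("dropping %d sample(s) below depth %d: %s", sum(drop), depth,
          paste(rownames(counts)[drop], collapse = ", "))
    counts <- counts[!drop, , drop = FALSE]
  }
  set.seed(seed)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    total <- sum(x)
    if (total == depth) next
    # draw read indices without replacement; map to taxa via cumulative sums
    picked <- sample.int(total, depth)
    breaks <- cumsum(x)
    out[i, ] <- tabulate(findInterval(picked, c(0, breaks), left.open = TRUE),
                         nbins = length(x))
  }
  asv_table(out, taxonomy = table$taxonomy, metadata = table$metadata)
}

#' Good-Turing sample coverage
#'
#' Chao-style estimator: C = 1 - (f1/n) * (n-1) f1 / ((n-1) f1 + 2 f2),
#' where f1 and f2 count taxa seen exactly once and twice and n is the
#' sample read sum. With no singletons the coverage is 1; empty samples are
#' reported as NA.
#'
#' @param table an [asv_table()] (integer counts).
#' @return named numeric vector of per-sample coverage in [0, 1].
#' @export
estimate_coverage <- function(table) {
  counts <- table$counts
  apply(counts, 1, function(x) {
    n <- sum(x)
    if (n == 0) return(NA_real_)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    if (f1 == 0) return(1)
    1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  })
}

#' Core-taxon filter: mean abundance then group prevalence
#'
#' Step 1 drops taxa whose grand-mean relative abundance falls below
#' `mean_thresh`. Step 2 keeps a surviving taxon only if, in at least one
#' plant-type group, it is present (count > 0) in at least `prevalence` of
#' that group's replicates (boundary inclusive). Groups with fewer than two
#' replicates are skipped with a warning.
#'
#' @param table an [asv_table()] with metadata.
#' @param mean_thresh grand-mean relative abundance threshold (default 0.005
#'   = 0.5%).
#' @param prevalence within-group presence fraction (default 0.8).
#' @param group_by metadata column defining the groups (default `"plant"`).
#' @return filtered `asv_table` (same samples, core taxa only).
#' @export
filter_core_taxa <- function(table, mean_thresh = 0.005, prevalence = 0.8,
                             group_by = "plant") {
  rel <- relative_abundance(table)
  keep1 <- colMeans(rel) >= mean_thresh
  groups <- table$metadata[[group_by]]
  if (is.null(groups)) stopf("metadata lacks grouping column '%s'", group_by)
  keep2 <- rep(FALSE, ncol(table$counts))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < 2) {
      warnf("group '%s' has < 2 replicates; skipped in prevalence evaluation", g)
      next
    }
    present <- colMeans(table$counts[rows, , drop = FALSE] > 0)
    keep2 <- keep2 | (present >= prevalence)
  }
  keep <- keep1 & keep2
  subset_asv(table, taxa = which(keep))
}

#' Centered log-ratio transform
#'
#' Per sample: x = counts + pseudocount; CLR = ln x - mean(ln x). Every
#' output row sums to zero.
#'
#' @param table an [asv_table()] or counts matrix.
#' @param pseudocount added before the log (default 0.5).
#' @return real matrix, samples x taxa.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  m <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  lx <- log(m + pseudocount)
  sweep(lx, 1, rowMeans(lx), `-`)
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param relabund matrix of per-sample proportions (rows sum to 1), or an
#'   [asv_table()] (closed internally).
#' @return a `dist` object.
#' @export
bray_curtis <- function(relabund) {
  m <- if (inherits(relabund, "asv_table")) relative_abundance(relabund) else as.matrix(relabund)
  if (any(m < 0)) stopf("relative abundances must be non-negative")
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 minimization with multiple random starts (vegan's
#' metaMDS engine); the best configuration is centered and principal-axis
#' rotated. Stress is reported as a fraction in [0, 1].
#'
#' @param d a `dist` object.
#' @param k target dimensionality (default 2).
#' @param n_starts random starts (default 20).
#' @param seed integer seed.
#' @return object of class `ordination_result` with `scores`, `stress`,
#'   `converged`, `method`.
#' @export
nmds_ordinate <- function(d, k = 2, n_starts = 20, seed = 1) {
  n <- attr(d, "Size")
  if (n < k + 2) stopf("need at least k + 2 = %d samples", k + 2)
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  structure(list(scores = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$converged > 0,
                 method = "NMDS"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s ordination: %d sites, %d axes", x$method, nrow(x$scores),
              ncol(x$scores)))
  if (!is.null(x$stress)) cat(sprintf(", stress %.4f", x$stress))
  cat("\n")
  invisible(x)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Sequential (Type I) distance-based partitioning with a permutation
#' pseudo-F test per term, via vegan's adonis2 with free row permutation.
#' Terms are entered in the order given; `production * plant` expands to the
#' two main effects plus their interaction.
#'
#' @param d a `dist` object.
#' @param metadata data.frame of sample covariates, rows aligned to `d`.
#' @param formula right-hand-side formula over metadata columns, e.g.
#'   `~ production * plant + latitude + longitude`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return object of class `permanova_result`: data.frame with per-term df,
#'   SS, R2, pseudo-F and permutation p, plus residual and total rows.
#' @export
permanova <- function(d, metadata, formula, n_perm = 999, seed = 1) {
  if (n_perm < 99) stopf("use at least 99 permutations")
  tl <- attr(stats::terms(formula), "term.labels")
  const_var <- names(metadata)[vapply(names(metadata), function(v)
    length(unique(metadata[[v]])) < 2, logical(1))]
  dropped <- tl[vapply(tl, function(t)
    any(all.vars(stats::as.formula(paste("~", t))) %in% const_var), logical(1))]
  kept <- setdiff(tl, dropped)
  if (length(dropped)) {
    warnf("term(s) constant across samples explain nothing: %s",
          paste(dropped, collapse = ", "))
  }
  n <- attr(d, "Size")
  ss_total <- sum(d^2) / n
  if (!length(kept)) {
    res <- data.frame(df = c(rep(0L, length(dropped)), n - 1L, n - 1L),
                      ss = c(rep(0, length(dropped)), ss_total, ss_total),
                      r2 = c(rep(0, length(dropped)), 1, 1),
                      f = NA_real_, p = c(rep(1, length(dropped)), NA, NA),
                      row.names = c(dropped, "Residual", "Total"))
    return(structure(list(table = res, n_perm = n_perm),
                     class = "permanova_result"))
  }
  fml <- stats::as.formula(paste("d ~", paste(kept, collapse = " + ")),
                           env = environment())
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = metadata, permutations = n_perm,
                        by = "terms")
  res <- as.data.frame(fit)
  names(res) <- c("df", "ss", "r2", "f", "p")[seq_len(ncol(res))]
  if (length(dropped)) {
    zero <- res[rep(NA_integer_, length(dropped)), ]
    rownames(zero) <- dropped
    zero$df <- 0L; zero$ss <- 0; zero$r2 <- 0; zero$p <- 1; zero$f <- NA_real_
    res <- rbind(zero, res)
  }
  structure(list(table = res, n_perm = n_perm), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations)\n", x$n_perm))
  print(round(x$table, 4))
  invisible(x)
}

#' ASV alpha diversity per sample
#'
#' Richness, Shannon index (natural log) and Pielou evenness computed on the
#' relative abundances of the (typically rarefied) table.
#'
#' @param table an [asv_table()].
#' @return data.frame with sample_id, richness, shannon, evenness.
#' @export
alpha_diversity <- function(table) {
  rel <- relative_abundance(table)
  res <- t(apply(rel, 1, diversity_metrics))
  data.frame(sample_id = rownames(rel), res, row.names = NULL)
}

#' Aitchison (CLR-Euclidean) distance
#'
#' Euclidean distance between CLR-transformed rows; the compositional
#' alternative to Bray-Curtis for ordination and PERMANOVA.
#'
#' @inheritParams clr_transform
#' @return a `dist` object.
#' @export
aitchison_distance <- function(table, pseudocount = 0.5) {
  dist(clr_transform(table, pseudocount))
}
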