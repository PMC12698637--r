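# Compositional co-abundance networks: SparCC correlation inference,
# permutation pseudo p-values, significance-filtered graphs, Markov
# clustering, centralities and hub detection.

# One SparCC basis-correlation estimate from a single Dirichlet fraction
# draw, with iterative strong-pair exclusion under the sparsity assumption.
sparcc_basis_cor <- function(Tmat, n_exclude_rounds, exclude_thresh) {
  D <- nrow(Tmat)
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  T_work <- Tmat
  excluded <- matrix(FALSE, D, D)
  n_excl <- integer(D)          # exclusions per taxon; capped at D - 3 so the
                                # basis-variance system stays well-conditioned
  clamped <- FALSE
  compute_rho <- function() {
    v <- tryCatch(solve(M, rowSums(T_work)), error = function(e) NULL)
    if (is.null(v)) return(NULL)
    if (any(v <= 0)) { clamped <<- TRUE; v <- pmax(v, 1e-10) }
    rho <- (outer(v, v, `+`) - Tmat) / (2 * sqrt(outer(v, v)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }
  rho <- compute_rho()
  if (is.null(rho)) stopf("SparCC basis-variance system is singular")
  for (round in seq_len(n_exclude_rounds)) {
    cand <- abs(rho)
    cand[lower.tri(cand, diag = TRUE)] <- 0
    cand[excluded] <- 0
    cand[n_excl >= D - 3, ] <- 0
    cand[, n_excl >= D - 3] <- 0
    mx <- max(cand)
    if (mx <= exclude_thresh) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    n_excl[i] <- n_excl[i] + 1L
    n_excl[j] <- n_excl[j] + 1L
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    T_work[i, j] <- T_work[j, i] <- 0
    rho_new <- compute_rho()
    if (is.null(rho_new)) break   # singular after exclusion: keep previous
    rho <- rho_new
  }
  list(rho = rho, clamped = clamped)
}

sparcc_once <- function(counts, n_inner, n_exclude_rounds, exclude_thresh) {
  n <- nrow(counts); D <- ncol(counts)
  rhos <- array(NA_real_, c(D, D, n_inner))
  clamped <- FALSE
  for (it in seq_len(n_inner)) {
    g <- matrix(rgamma(n * D, shape = counts + 1), n, D)
    L <- log(g / rowSums(g))
    V <- cov(L)
    v <- diag(V)
    Tmat <- outer(v, v, `+`) - 2 * V      # Var[log(f_i/f_j)]
    est <- sparcc_basis_cor(Tmat, n_exclude_rounds, exclude_thresh)
    rhos[, , it] <- est$rho
    clamped <- clamped || est$clamped
  }
  list(rho = apply(rhos, c(1, 2), median), clamped = clamped)
}

#' SparCC basis correlations from compositional counts
#'
#' Per inner iteration, fractions are drawn from Dirichlet(counts + 1), the
#' log-ratio variance matrix t_ij = Var[ln(f_i/f_j)] is formed, and the
#' sparsity-assumption linear system ((D-2) I + 1 1') w^2 = rowSums(T) is
#' solved for basis variances, giving rho_ij = (w_i^2 + w_j^2 - t_ij) /
#' (2 w_i w_j), clipped to [-1, 1]. The strongest pair above
#' `exclude_thresh` is then iteratively removed from the system and the
#' basis re-solved, up to `n_exclude_rounds` times. The final estimate is
#' the elementwise median over inner iterations.
#'
#' @param table an [asv_table()] or counts matrix (non-rarefied; >= 4 taxa).
#' @param n_inner inner Dirichlet iterations (default 20).
#' @param n_exclude_rounds strong-pair exclusion rounds (default 10).
#' @param exclude_thresh |rho| above which a pair is excluded (default 0.1).
#' @param seed integer seed.
#' @return object of class `sparcc_result`: `correlation` (symmetric D x D,
#'   unit diagonal), estimation parameters, and `pseudo_p = NULL` until
#'   [sparcc_pseudo_p()] fills it.
#' @export
sparcc_correlations <- function(table, n_inner = 20, n_exclude_rounds = 10,
                                exclude_thresh = 0.1, seed = 1) {
  counts <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  D <- ncol(counts)
  if (D <= 3) stopf("SparCC needs more than 3 taxa (basis-variance system)")
  set.seed(seed)
  est <- sparcc_once(counts, n_inner, n_exclude_rounds, exclude_thresh)
  if (est$clamped) warnf("negative basis-variance estimates clamped to a small positive value")
  rho <- (est$rho + t(est$rho)) / 2
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  structure(list(correlation = rho, pseudo_p = NULL, n_bootstrap = 0L,
                 n_inner = n_inner, n_exclude_rounds = n_exclude_rounds,
                 exclude_thresh = exclude_thresh),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  cat(sprintf("SparCC result: %d taxa, mean |rho| %.3f%s\n",
              nrow(x$correlation), mean(abs(off)),
              if (is.null(x$pseudo_p)) "" else
                sprintf(", pseudo p from %d resamples", x$n_bootstrap)))
  invisible(x)
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' For each resample, every taxon's counts are permuted across samples
#' independently (breaking all between-taxon association while preserving
#' marginals) and SparCC recomputed; the two-sided pseudo p for a pair is
#' (#{|r_b| >= |r_obs|} + 1) / (n_boot + 1).
#'
#' @param table the same counts used for `observed`.
#' @param observed a [sparcc_correlations()] result.
#' @param n_boot resamples (default 100; fewer than 10 limits resolution and
#'   triggers a warning).
#' @param seed integer seed.
#' @return the `sparcc_result` with `pseudo_p` filled in.
#' @export
sparcc_pseudo_p <- function(table, observed, n_boot = 100, seed = 1) {
  counts <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  if (n_boot < 10) warnf("n_boot < 10: pseudo p resolution is only 1/%d", n_boot + 1)
  obs <- abs(observed$correlation)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    perm <- apply(counts, 2, sample)
    est <- suppressWarnings(
      sparcc_once(perm, observed$n_inner, observed$n_exclude_rounds,
                  observed$exclude_thresh))
    exceed <- exceed + (abs(est$rho) >= obs)
  }
  p <- (exceed + 1) / (n_boot + 1)
  dimnames(p) <- dimnames(observed$correlation)
  observed$pseudo_p <- p
  observed$n_bootstrap <- as.integer(n_boot)
  observed
}

#' Build the significance-filtered co-abundance network
#'
#' Keeps the undirected edges whose pseudo p falls below `alpha`; nodes with
#' no retained edges are omitted. Nodes carry the lowest available
#' taxonomic label and phylum when taxonomy is supplied.
#'
#' @param result a [sparcc_result] with pseudo p-values.
#' @param alpha edge-significance threshold (default 0.1).
#' @param taxonomy optional taxonomy data.frame (`taxon_id` + ranks).
#' @return object of class `sparcc_network` wrapping an igraph graph with
#'   edge attributes `r`, `pseudo_p`, `sign`.
#' @export
build_network <- function(result, alpha = 0.1, taxonomy = NULL) {
  if (is.null(result$pseudo_p)) stopf("pseudo p-values missing; run sparcc_pseudo_p first")
  rho <- result$correlation
  p <- result$pseudo_p
  ut <- which(upper.tri(rho) & p < alpha, arr.ind = TRUE)
  taxa <- rownames(rho)
  if (nrow(ut) == 0) {
    warnf("no edge passes pseudo p < %g; returning an empty network", alpha)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(from = taxa[ut[, 1]], to = taxa[ut[, 2]],
                        r = rho[ut], pseudo_p = p[ut],
                        sign = ifelse(rho[ut] >= 0, 1L, -1L))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  if (!is.null(taxonomy) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, taxonomy$taxon_id)
    rank_cols <- intersect(c("genus", "family", "order", "class", "phylum"),
                           colnames(taxonomy))
    lowest <- if (length(rank_cols)) taxonomy[[rank_cols[1]]][idx] else NA
    igraph::V(g)$label <- lowest
    if ("phylum" %in% colnames(taxonomy)) igraph::V(g)$phylum <- taxonomy$phylum[idx]
  }
  structure(list(graph = g, alpha = alpha), class = "sparcc_network")
}

#' @export
print.sparcc_network <- function(x, ...) {
  cat(sprintf("SparCC network: %d taxa, %d significant interactions (pseudo p < %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$alpha))
  invisible(x)
}

#' Markov clustering of a network
#'
#' Classic MCL on the unweighted skeleton with unit self-loops: the
#' column-stochastic matrix is alternately squared (expansion) and raised
#' elementwise to `inflation` then renormalized, with small entries pruned,
#' until the flow matrix stabilizes. Clusters are the weakly connected
#' components of the attractor support; every node receives a label.
#'
#' @param net a `sparcc_network` (or igraph graph).
#' @param inflation inflation exponent (default 2).
#' @param prune_eps entries below this are zeroed each sweep (default 1e-5).
#' @param tol,max_iter convergence controls.
#' @return named integer vector of cluster ids (attribute `converged`).
#' @export
mcl_clusters <- function(net, inflation = 2, prune_eps = 1e-5,
                         tol = 1e-8, max_iter = 200) {
  g <- if (inherits(net, "sparcc_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n == 0) stopf("empty network")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A != 0] <- 1
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), `/`)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune_eps] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, `/`)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warnf("MCL did not converge in %d iterations; clustering the last iterate", max_iter)
  supp <- (M > 0) | (t(M) > 0)
  gc <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected", diag = FALSE)
  comp <- igraph::components(gc)$membership
  out <- setNames(as.integer(comp), igraph::V(g)$name)
  attr(out, "converged") <- converged
  out
}

#' Node centralities: normalized betweenness and degree
#'
#' Betweenness by exact geodesic counting on the unweighted graph,
#' normalized by (n-1)(n-2)/2; degree is the incident edge count.
#'
#' @param net a `sparcc_network` (or igraph graph).
#' @return data.frame: node, betweenness (normalized), degree.
#' @export
node_centralities <- function(net) {
  g <- if (inherits(net, "sparcc_network")) net$graph else net
  if (igraph::vcount(g) == 0) stopf("empty network")
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = TRUE)
  data.frame(node = igraph::V(g)$name,
             betweenness = as.numeric(bc),
             degree = as.numeric(igraph::degree(g)),
             row.names = NULL)
}

#' Detect hub taxa and extract the hub subnetwork
#'
#' A hub sits in the top `quantile` of BOTH normalized betweenness and
#' degree. "Top 10%" is evaluated on ranks with tie groups kept whole:
#' values are taken in decreasing order, whole tie groups at a time, until
#' ceiling(q n) nodes are covered; a tie group that would overshoot the
#' budget is dropped unless nothing has been selected yet. This keeps hub
#' sets deterministic, includes ties, and stays meaningful on skewed
#' centrality distributions (e.g. stars), where a plain (1 - q) quantile
#' threshold degenerates to the modal value and admits every node.
#' The hub subnetwork keeps every edge incident to at least one hub, with
#' its endpoints.
#'
#' @param net a `sparcc_network`.
#' @param quantile top fraction defining hubs (default 0.10).
#' @return list: `hubs` (node names), `centralities`, `subnetwork`
#'   (igraph graph), `n_nodes`, `n_edges` (hub-subnetwork sizes).
#' @export
detect_hubs <- function(net, quantile = 0.10) {
  cent <- node_centralities(net)
  g <- if (inherits(net, "sparcc_network")) net$graph else net
  top_fraction <- function(x, q) {
    k <- max(1, ceiling(q * length(x)))
    vals <- sort(unique(x), decreasing = TRUE)
    sel <- 0L
    thr <- vals[1]
    for (v in vals) {
      cnt <- sum(x == v)
      if (sel > 0L && sel + cnt > k) break
      thr <- v
      sel <- sel + cnt
      if (sel >= k) break
    }
    x >= thr
  }
  hubs <- cent$node[top_fraction(cent$betweenness, quantile) &
                      top_fraction(cent$degree, quantile)]
  if (length(hubs) == igraph::vcount(g)) {
    warnf("degenerate centralities: every node qualifies as a hub")
  }
  eids <- unlist(igraph::incident_edges(g, hubs))
  sub <- igraph::subgraph_from_edges(g, igraph::E(g)[unique(eids)], delete.vertices = TRUE)
  list(hubs = hubs, centralities = cent, subnetwork = sub,
       n_nodes = igraph::vcount(sub), n_edges = igraph::ecount(sub))
}
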