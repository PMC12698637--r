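make_graph <- function(edges, n = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(n) && igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  structure(list(graph = g, alpha = 0.1), class = "sparcc_network")
}

test_that("SparCC estimates permute equivariantly and need > 3 taxa", {
  d <- scene_design(plant_species = c("a", "b", "c", "d"),
                    replicates_per_plant = 15, n_taxa = 10,
                    spectra_per_sample = 10,
                    correlation_blocks = list(list(taxa = c(1, 2), rho = 0.8)))
  g <- generate_asv_counts(d, seed = 2)   # 120 samples
  r1 <- sparcc_correlations(g$asv$counts, seed = 3)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7, 10, 9)
  r2 <- sparcc_correlations(g$asv$counts[, perm], seed = 3)
  # same planted pair found at the permuted position; estimates agree up to
  # Monte-Carlo noise in the Dirichlet draws
  expect_lt(abs(r2$correlation["ASV001", "ASV002"] -
                  r1$correlation["ASV001", "ASV002"]), 0.1)
  expect_lt(mean(abs(r2$correlation[colnames(g$asv$counts)[perm],
                                    colnames(g$asv$counts)[perm]] -
                       r1$correlation[perm, perm])), 0.05)
  expect_equal(r1$correlation, t(r1$correlation))
  expect_true(all(abs(r1$correlation) <= 1))
  expect_error(sparcc_correlations(g$asv$counts[, 1:3], seed = 1), "3 taxa")
})

test_that("SparCC is invariant to per-sample total scaling", {
  d <- scene_design(plant_species = c("a", "b", "c"), n_taxa = 20,
                    spectra_per_sample = 10,
                    correlation_blocks = list(list(taxa = c(1, 2), rho = 0.8)))
  g <- generate_asv_counts(d, seed = 6)
  r1 <- sparcc_correlations(g$asv$counts, seed = 4)
  scaled <- g$asv$counts
  scaled[1:10, ] <- scaled[1:10, ] * 10L
  r2 <- sparcc_correlations(scaled, seed = 4)
  expect_lt(mean(abs(r1$correlation - r2$correlation)), 0.05)
})

test_that("pseudo p-values respect the resampling floor", {
  d <- scene_design(plant_species = c("a", "b"), n_taxa = 6,
                    spectra_per_sample = 10,
                    correlation_blocks = list(list(taxa = c(1, 2), rho = 0.9)))
  g <- generate_asv_counts(d, seed = 9)
  r <- sparcc_correlations(g$asv$counts, n_inner = 5, seed = 1)
  rp <- sparcc_pseudo_p(g$asv$counts, r, n_boot = 20, seed = 2)
  off <- rp$pseudo_p[upper.tri(rp$pseudo_p)]
  expect_true(all(off >= 1 / 21))
  expect_true(all(off <= 1))
  expect_warning(sparcc_pseudo_p(g$asv$counts, r, n_boot = 5, seed = 1),
                 "resolution")
})

test_that("network construction keeps only significant edges", {
  rho <- diag(5)
  rho[1, 2] <- rho[2, 1] <- 0.8
  rho[1, 3] <- rho[3, 1] <- -0.6
  rho[4, 5] <- rho[5, 4] <- 0.5
  p <- matrix(1, 5, 5)
  p[1, 2] <- p[2, 1] <- p[1, 3] <- p[3, 1] <- p[4, 5] <- p[5, 4] <- 0.01
  dimnames(rho) <- dimnames(p) <- list(paste0("t", 1:5), paste0("t", 1:5))
  res <- structure(list(correlation = rho, pseudo_p = p, n_bootstrap = 100L),
                   class = "sparcc_result")
  net <- build_network(res, alpha = 0.1)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_lte(igraph::vcount(net$graph), 5)
  expect_setequal(unique(igraph::E(net$graph)$sign), c(1L, -1L))
  p[] <- 1
  res$pseudo_p <- p
  expect_warning(empty <- build_network(res, alpha = 0.1), "no edge")
  expect_equal(igraph::vcount(empty$graph), 0)
})

test_that("MCL recovers components, cliques and bridge-split modules", {
  tri2 <- make_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                           c(4, 5), c(5, 6), c(4, 6)))
  cl <- mcl_clusters(tri2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:3])), 1)
  k5 <- make_graph(t(utils::combn(5, 2)))
  expect_equal(length(unique(mcl_clusters(k5))), 1)
  # two dense modules joined by a single bridge edge split at the bridge
  m1 <- t(utils::combn(5, 2))
  m2 <- t(utils::combn(5, 2)) + 5
  bridge <- rbind(c(5, 6))
  g2 <- make_graph(rbind(m1, m2, bridge))
  cl2 <- mcl_clusters(g2)
  expect_equal(length(unique(cl2)), 2)
  expect_equal(length(unique(cl2[1:5])), 1)
  expect_equal(length(unique(cl2[6:10])), 1)
  # labels form a partition over all nodes
  expect_length(cl2, 10)
  expect_false(anyNA(cl2))
})

test_that("centralities match definitions on paths and stars", {
  path3 <- make_graph(rbind(c(1, 2), c(2, 3)))
  cent <- node_centralities(path3)
  expect_equal(cent$betweenness[cent$node == "v2"], 1)
  expect_equal(cent$betweenness[cent$node == "v1"], 0)
  star <- make_graph(cbind(1, 2:6))
  cs <- node_centralities(star)
  expect_equal(cs$betweenness[cs$node == "v1"], 1)
  expect_equal(cs$degree[cs$node == "v1"], 5)
})

test_that("betweenness equals brute-force geodesic enumeration", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(10:25, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.2)
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    igraph::V(g)$name <- paste0("v", 1:n)
    net <- structure(list(graph = g, alpha = 0.1), class = "sparcc_network")
    cent <- node_centralities(net)
    expect_equal(cent$betweenness, brute_betweenness(A), tolerance = 1e-9)
  }
})

test_that("hub detection intersects both top deciles and shrinks with q", {
  star <- make_graph(cbind(1, 2:21))
  h <- detect_hubs(star, quantile = 0.10)
  expect_equal(h$hubs, "v1")
  expect_equal(h$n_nodes, 21)
  expect_equal(h$n_edges, 20)
  set.seed(3)
  A <- matrix(0, 30, 30)
  A[upper.tri(A)] <- rbinom(435, 1, 0.25)
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("v", 1:30)
  net <- structure(list(graph = g, alpha = 0.1), class = "sparcc_network")
  h10 <- detect_hubs(net, 0.10)$hubs
  h05 <- detect_hubs(net, 0.05)$hubs
  expect_true(all(h05 %in% h10))
})

test_that("planted hub taxa rise to the top of both centralities", {
  found <- 0
  for (s in 1:3) {
    d <- scene_design(plant_species = c("a", "b", "c", "d", "e"),
                      replicates_per_plant = 10, n_taxa = 40,
                      spectra_per_sample = 10,
                      planted_hubs = c(5, 20), hub_partners = 8)
    g <- generate_asv_counts(d, seed = s)   # 100 samples
    r <- sparcc_correlations(g$asv$counts, seed = s)
    rp <- sparcc_pseudo_p(g$asv$counts, r, n_boot = 60, seed = s + 50)
    net <- build_network(rp, alpha = 0.1)
    h <- detect_hubs(net, 0.10)
    found <- found + sum(c("ASV005", "ASV020") %in% h$hubs)
  }
  expect_gte(found / 6, 2 / 3)
})
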