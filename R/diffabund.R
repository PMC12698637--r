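# ALDEx-style compositional differential abundance: Dirichlet Monte-Carlo
# technical replicates, CLR per instance, per-taxon linear model with
# sequential F-tests, BH within instance, expectation over instances.

#' Dirichlet Monte-Carlo CLR instances
#'
#' For every sample, `n_mc` proportion vectors are drawn from
#' Dirichlet(counts + prior) and CLR-transformed, turning sampling
#' uncertainty in the counts into a posterior stack of CLR tables. Use
#' non-rarefied counts: subsampling discards information the posterior
#' already models.
#'
#' @param table an [asv_table()] (non-rarefied counts).
#' @param n_mc number of Monte-Carlo instances (default 128).
#' @param seed integer seed.
#' @param prior per-count Dirichlet prior (default 0.5).
#' @return object of class `clr_instances`: array `[n_mc, sample, taxon]`.
#' @export
dirichlet_clr_instances <- function(table, n_mc = 128, seed = 1, prior = 0.5) {
  if (n_mc < 2) stopf("n_mc must be >= 2")
  counts <- table$counts
  n <- nrow(counts); D <- ncol(counts)
  set.seed(seed)
  arr <- array(NA_real_, dim = c(n_mc, n, D),
               dimnames = list(NULL, rownames(counts), colnames(counts)))
  shape <- counts + prior
  for (i in seq_len(n)) {
    g <- matrix(rgamma(n_mc * D, shape = rep(shape[i, ], each = n_mc)), n_mc, D)
    lp <- log(g) - log(rowSums(g))
    arr[, i, ] <- lp - rowMeans(lp)
  }
  structure(list(clr = arr, n_mc = n_mc,
                 samples = rownames(counts), taxa = colnames(counts)),
            class = "clr_instances")
}

# Sequential (Type I) design decomposition shared by all instances.
sequential_designs <- function(metadata, formula) {
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  mats <- list(matrix(1, nrow(metadata), 1))
  kept <- character()
  for (lb in labels) {
    fml <- stats::as.formula(paste("~", paste(c(kept, lb), collapse = " + ")))
    X <- stats::model.matrix(fml, data = metadata)
    if (qr(X)$rank <= qr(mats[[length(mats)]])$rank) {
      warnf("term '%s' adds no estimable degrees of freedom; dropped", lb)
      next
    }
    kept <- c(kept, lb)
    mats[[length(mats) + 1L]] <- X
  }
  qrs <- lapply(mats, qr)
  ranks <- vapply(qrs, `[[`, integer(1), "rank")
  list(labels = kept, qrs = qrs, ranks = ranks)
}

#' ALDEx-style GLM test with a Production x Plant interaction
#'
#' Per Monte-Carlo instance and taxon, a linear model of the CLR value on
#' the design (default `~ production * plant`) is fitted; each term gets a
#' sequential F-test p-value, BH-adjusted across taxa within the instance
#' and term; the expectation over instances is reported. A taxon is called
#' for a term when its expected BH p falls below `alpha`.
#'
#' @param instances a [dirichlet_clr_instances()] stack.
#' @param metadata data.frame aligned to the stack's samples.
#' @param formula model formula over metadata columns (default
#'   `~ production * plant`).
#' @param alpha significance level on expected BH p (default 0.05).
#' @return object of class `da_result`: data.frame per taxon with expected
#'   effect size (term SS / total SS), expected raw and BH p per term, and
#'   significance flags.
#' @export
aldex_glm_test <- function(instances, metadata, formula = ~ production * plant,
                           alpha = 0.05) {
  arr <- instances$clr
  n_mc <- dim(arr)[1]; n <- dim(arr)[2]; D <- dim(arr)[3]
  metadata <- metadata[match(instances$samples, metadata$sample_id), , drop = FALSE]
  des <- sequential_designs(metadata, formula)
  n_terms <- length(des$labels)
  if (!n_terms) stopf("no estimable model terms")
  df_term <- diff(des$ranks)
  df_res <- n - des$ranks[length(des$ranks)]
  if (df_res < 1) stopf("no residual degrees of freedom")

  acc_p <- acc_bh <- acc_eff <- matrix(0, D, n_terms,
                                       dimnames = list(instances$taxa, des$labels))
  for (m in seq_len(n_mc)) {
    Y <- matrix(arr[m, , ], n, D)
    tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
    rss <- vapply(des$qrs, function(q) colSums(qr.resid(q, Y)^2),
                  numeric(D))          # D x (n_terms + 1)
    rss_full <- rss[, n_terms + 1]
    for (t in seq_len(n_terms)) {
      ss_t <- rss[, t] - rss[, t + 1]
      f <- (ss_t / df_term[t]) / (rss_full / df_res)
      p <- pf(f, df_term[t], df_res, lower.tail = FALSE)
      acc_p[, t] <- acc_p[, t] + p
      acc_bh[, t] <- acc_bh[, t] + bh_adjust(p)
      acc_eff[, t] <- acc_eff[, t] + ss_t / pmax(tss, .Machine$double.eps)
    }
  }
  res <- data.frame(taxon = instances$taxa, row.names = NULL)
  for (t in seq_len(n_terms)) {
    lb <- des$labels[t]
    res[[paste0("effect.", lb)]] <- acc_eff[, t] / n_mc
    res[[paste0("p.", lb)]] <- acc_p[, t] / n_mc
    res[[paste0("bh.", lb)]] <- acc_bh[, t] / n_mc
    res[[paste0("sig.", lb)]] <- acc_bh[, t] / n_mc < alpha
  }
  structure(list(table = res, terms = des$labels, n_mc = n_mc, alpha = alpha),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("Differential abundance (ALDEx-style, %d MC instances)\n", x$n_mc))
  for (lb in x$terms) {
    cat(sprintf("  %-22s %d/%d taxa at expected BH p < %.2f\n", lb,
                sum(x$table[[paste0("sig.", lb)]]), nrow(x$table), x$alpha))
  }
  invisible(x)
}

#' Welch t shortcut for a two-level single factor
#'
#' Per instance and taxon, a Welch two-sample t-test between the two groups;
#' BH within instance, expectation over instances. Faster than the full GLM
#' when only a production contrast is needed.
#'
#' @param instances a [dirichlet_clr_instances()] stack.
#' @param group factor (or vector) with exactly two levels, aligned to the
#'   stack's samples.
#' @return data.frame per taxon: expected raw and BH p.
#' @export
aldex_welch <- function(instances, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stopf("group must have exactly 2 levels")
  arr <- instances$clr
  n_mc <- dim(arr)[1]; D <- dim(arr)[3]
  i1 <- which(group == levels(group)[1]); i2 <- which(group == levels(group)[2])
  acc_p <- acc_bh <- rep(0, D)
  for (m in seq_len(n_mc)) {
    Y <- matrix(arr[m, , ], dim(arr)[2], D)
    m1 <- colMeans(Y[i1, , drop = FALSE]); m2 <- colMeans(Y[i2, , drop = FALSE])
    v1 <- apply(Y[i1, , drop = FALSE], 2, var) / length(i1)
    v2 <- apply(Y[i2, , drop = FALSE], 2, var) / length(i2)
    se2 <- v1 + v2
    tstat <- (m1 - m2) / sqrt(pmax(se2, .Machine$double.eps))
    df <- se2^2 / pmax(v1^2 / (length(i1) - 1) + v2^2 / (length(i2) - 1),
                       .Machine$double.eps)
    p <- 2 * pt(-abs(tstat), df)
    acc_p <- acc_p + p
    acc_bh <- acc_bh + bh_adjust(p)
  }
  data.frame(taxon = instances$taxa, p = acc_p / n_mc, bh = acc_bh / n_mc)
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums counts within each level of a taxonomy column (e.g. phylum) so that
#' differential abundance can be run at that rank.
#'
#' @param table an [asv_table()] with taxonomy.
#' @param rank taxonomy column name (default `"phylum"`).
#' @return an `asv_table` with one column per rank level.
#' @export
aggregate_taxa <- function(table, rank = "phylum") {
  if (is.null(table$taxonomy)) stopf("table has no taxonomy")
  lev <- table$taxonomy[[rank]]
  if (is.null(lev)) stopf("taxonomy lacks rank '%s'", rank)
  agg <- t(rowsum(t(table$counts), group = lev))
  tax <- data.frame(taxon_id = colnames(agg))
  tax[[rank]] <- colnames(agg)
  asv_table(agg, taxonomy = tax, metadata = table$metadata)
}
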