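# End-to-end orchestration: one config object drives simulate -> phenotype
# -> community -> diffabund -> network (per production system) -> integrate,
# with per-stage seeds derived from a master seed and a JSON manifest
# recording parameters, seeds and output checksums.

#' Assemble a pipeline configuration
#'
#' Either supply a [scene_design()] (synthetic mode) or file paths to
#' counts/taxonomy/metadata TSV and spectra CSV. Stage toggles and the
#' parameters of every stage live here; unset values take the defaults
#' used throughout the package.
#'
#' @param outdir output directory.
#' @param seed master seed; per-stage seeds are derived with
#'   [derive_seed()] so disabling one stage never shifts another's stream.
#' @param design optional `scene_design` for synthetic input.
#' @param paths optional named list: counts, taxonomy, metadata, spectra.
#' @param stages character vector of stages to run (subset of simulate,
#'   phenotype, community, diffabund, network, integrate).
#' @param cutoff OPU clustering cutoff; `NA` triggers AIC selection.
#' @param qc_snr_min QC gate signal-to-noise threshold.
#' @param mean_thresh,prevalence core-taxon filter parameters.
#' @param n_mc Dirichlet Monte-Carlo instances.
#' @param n_perm permutations (PERMANOVA / dbRDA / vector fitting).
#' @param n_boot SparCC resamples.
#' @param edge_alpha network edge pseudo-p threshold.
#' @param hub_quantile top fraction for hub detection.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, design = NULL, paths = NULL,
                            stages = c("simulate", "phenotype", "community",
                                       "diffabund", "network", "integrate"),
                            cutoff = 0.44, qc_snr_min = 3,
                            mean_thresh = 0.005, prevalence = 0.8,
                            n_mc = 128, n_perm = 999, n_boot = 100,
                            edge_alpha = 0.1, hub_quantile = 0.1) {
  if (is.null(design) && is.null(paths)) {
    stopf("supply either a scene design or input paths")
  }
  if (!is.null(paths)) {
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing)) stopf("input path(s) not found: %s",
                               paste(unlist(missing), collapse = ", "))
  }
  structure(list(outdir = outdir, seed = as.integer(seed), design = design,
                 paths = paths, stages = stages, cutoff = cutoff,
                 qc_snr_min = qc_snr_min, mean_thresh = mean_thresh,
                 prevalence = prevalence, n_mc = n_mc, n_perm = n_perm,
                 n_boot = n_boot, edge_alpha = edge_alpha,
                 hub_quantile = hub_quantile),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any [pipeline_config()] field; a `design:` block is
#' passed to [scene_design()] (with `da_taxa` and `couplings` given as lists
#' of column vectors). Command-line style overrides win over file values.
#'
#' @param path YAML file path.
#' @param ... overrides forwarded to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$design)) {
    des <- cfg$design
    for (f in c("da_taxa", "couplings")) {
      if (!is.null(des[[f]])) des[[f]] <- as.data.frame(des[[f]])
    }
    if (!is.null(des$correlation_blocks)) {
      des$correlation_blocks <- lapply(des$correlation_blocks, function(b)
        list(taxa = unlist(b$taxa), rho = b$rho))
    }
    cfg$design <- do.call(scene_design, des)
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

#' Run the integrated genotype-phenotype pipeline
#'
#' Executes the enabled stages in order, writes every artifact under the
#' config's output directory and returns (and writes) a manifest recording
#' stage status, parameters, the derived seeds actually consumed, and MD5
#' checksums of all outputs. A stage failure is recorded and all downstream
#' stages are skipped.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "opulink",
                   version = as.character(utils::packageVersion("opulink")),
                   master_seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    if (failed) {
      manifest$stages[[name]] <<- list(status = "not-run (upstream failure)")
      return(invisible())
    }
    seed <- derive_seed(config$seed, name)
    rec <- tryCatch({
      outputs <- fun(seed)
      rel <- lapply(as.list(outputs), function(p)
        sub("^/", "", sub(outdir, "", p, fixed = TRUE)))
      list(status = "ok", seed = seed, outputs = rel)
    }, error = function(e) {
      failed <<- TRUE
      list(status = "failed", seed = seed, error = conditionMessage(e))
    })
    manifest$stages[[name]] <<- rec
    invisible()
  }

  run_stage("simulate", function(seed) {
    if (is.null(config$design)) {
      state$asv <- read_asv_table(config$paths$counts, config$paths$taxonomy,
                                  config$paths$metadata)
      state$spectra <- read_spectra_csv(config$paths$spectra)
      return(character())
    }
    scene <- simulate_scene(config$design, seed)
    state$asv <- scene$asv
    state$spectra <- scene$spectra
    state$truth <- scene$truth
    write_scene(scene, file.path(outdir, "scene"))
  })

  run_stage("phenotype", function(seed) {
    qc <- qc_signature_filter(state$spectra, snr_min = config$qc_snr_min)
    prep <- preprocess_spectra(qc$passed)
    cutoff <- config$cutoff
    if (is.na(cutoff)) {
      cutoff <- select_cutoff_by_aic(prep$spectra)$cutoff
    }
    assign_ <- cluster_opus(prep$spectra, cutoff = cutoff)
    state$opu_table <- build_opu_table(assign_,
                                       samples = rownames(state$asv$counts))
    state$opu_div <- opu_diversity(state$opu_table)
    p_assign <- file.path(outdir, "opu_assignment.tsv")
    write.table(data.frame(cell_id = names(assign_$labels),
                           sample_id = assign_$sample_id,
                           opu = assign_$labels),
                p_assign, sep = "\t", quote = FALSE, row.names = FALSE)
    p_table <- file.path(outdir, "opu_table.tsv")
    write.table(data.frame(sample_id = rownames(state$opu_table$shares),
                           state$opu_table$shares, check.names = FALSE),
                p_table, sep = "\t", quote = FALSE, row.names = FALSE)
    c(assignment = p_assign, opu_table = p_table)
  })

  run_stage("community", function(seed) {
    rare <- rarefy_even_depth(state$asv, "min", seed = seed)
    state$rarefied <- rare
    state$coverage <- estimate_coverage(rare)
    state$core <- filter_core_taxa(rare, config$mean_thresh, config$prevalence)
    state$bray <- bray_curtis(state$core)
    state$asv_div <- alpha_diversity(rare)
    nmds <- nmds_ordinate(state$bray, seed = derive_seed(seed, "nmds"))
    perm <- permanova(state$bray, state$asv$metadata,
                      ~ production * plant + latitude + longitude,
                      n_perm = config$n_perm, seed = derive_seed(seed, "permanova"))
    state$permanova <- perm
    p_dist <- file.path(outdir, "bray_curtis.tsv")
    write_distance_tsv(state$bray, p_dist)
    p_scores <- file.path(outdir, "nmds_scores.tsv")
    write.table(data.frame(sample_id = rownames(nmds$scores), nmds$scores),
                p_scores, sep = "\t", quote = FALSE, row.names = FALSE)
    p_perm <- file.path(outdir, "permanova.tsv")
    write.table(data.frame(term = rownames(perm$table), perm$table),
                p_perm, sep = "\t", quote = FALSE, row.names = FALSE)
    c(distance = p_dist, nmds = p_scores, permanova = p_perm)
  })

  run_stage("diffabund", function(seed) {
    inst <- dirichlet_clr_instances(state$asv, n_mc = config$n_mc, seed = seed)
    da <- aldex_glm_test(inst, state$asv$metadata)
    p_da <- file.path(outdir, "differential_abundance.tsv")
    write.table(da$table, p_da, sep = "\t", quote = FALSE, row.names = FALSE)
    c(result = p_da)
  })

  run_stage("network", function(seed) {
    outs <- character()
    prods <- unique(state$asv$metadata$production)
    for (pr in prods) {
      sub <- subset_asv(state$asv,
                        samples = state$asv$metadata$production == pr)
      res <- sparcc_correlations(sub, seed = derive_seed(seed, pr))
      res <- sparcc_pseudo_p(sub, res, n_boot = config$n_boot,
                             seed = derive_seed(seed, paste0(pr, "-boot")))
      net <- build_network(res, alpha = config$edge_alpha,
                           taxonomy = state$asv$taxonomy)
      state[[paste0("network_", pr)]] <- net
      if (igraph::ecount(net$graph) > 0) {
        hubs <- detect_hubs(net, quantile = config$hub_quantile)
        clusters <- mcl_clusters(net)
        p_edges <- file.path(outdir, sprintf("network_%s_edges.tsv", pr))
        write_edge_list_tsv(net, p_edges)
        p_gml <- file.path(outdir, sprintf("network_%s.graphml", pr))
        write_network_graphml(net, p_gml)
        p_hubs <- file.path(outdir, sprintf("network_%s_hubs.json", pr))
        jsonlite::write_json(list(hubs = hubs$hubs, n_nodes = hubs$n_nodes,
                                  n_edges = hubs$n_edges,
                                  clusters = as.list(clusters)),
                             p_hubs, auto_unbox = TRUE, digits = NA)
        outs <- c(outs, setNames(c(p_edges, p_gml, p_hubs),
                                 paste0(pr, c("_edges", "_graphml", "_hubs"))))
      }
    }
    outs
  })

  run_stage("integrate", function(seed) {
    reg <- rbind(
      diversity_coupling_regression(state$asv_div, state$opu_div,
                                    state$asv$metadata, model = "linear"),
      diversity_coupling_regression(state$asv_div, state$opu_div,
                                    state$asv$metadata, model = "log1p"))
    opu_shares <- state$opu_table$shares
    common <- intersect(labels(state$bray), rownames(opu_shares))
    bray_sub <- as.dist(as.matrix(state$bray)[common, common])
    opu_cols <- setdiff(colnames(opu_shares), "unclassified")
    db <- dbrda(bray_sub, opu_shares[common, opu_cols, drop = FALSE],
                n_perm = config$n_perm, seed = derive_seed(seed, "dbrda"))
    ef <- fit_opu_vectors(db$site_scores, opu_shares[common, , drop = FALSE],
                          n_perm = config$n_perm,
                          seed = derive_seed(seed, "envfit"))
    core_rel <- relative_abundance(state$core)[common, , drop = FALSE]
    sp <- spearman_opu_taxa(core_rel, opu_shares[common, , drop = FALSE])
    p_reg <- file.path(outdir, "diversity_coupling.tsv")
    write.table(reg, p_reg, sep = "\t", quote = FALSE, row.names = FALSE)
    p_db <- file.path(outdir, "dbrda_scores.tsv")
    write.table(data.frame(sample_id = rownames(db$site_scores),
                           db$site_scores, check.names = FALSE),
                p_db, sep = "\t", quote = FALSE, row.names = FALSE)
    p_ef <- file.path(outdir, "opu_vectors.tsv")
    write.table(ef, p_ef, sep = "\t", quote = FALSE, row.names = FALSE)
    p_sp <- file.path(outdir, "spearman_rho.tsv")
    write.table(data.frame(taxon = rownames(sp$rho), sp$rho, check.names = FALSE),
                p_sp, sep = "\t", quote = FALSE, row.names = FALSE)
    p_spp <- file.path(outdir, "spearman_bh.tsv")
    write.table(data.frame(taxon = rownames(sp$bh), sp$bh, check.names = FALSE),
                p_spp, sep = "\t", quote = FALSE, row.names = FALSE)
    c(regression = p_reg, dbrda = p_db, vectors = p_ef,
      spearman_rho = p_sp, spearman_bh = p_spp)
  })

  all_outputs <- unlist(lapply(manifest$stages, function(s) unlist(s$outputs)))
  if (length(all_outputs)) {
    sums <- tools::md5sum(file.path(outdir, all_outputs))
    manifest$checksums <- as.list(setNames(unname(sums), unname(all_outputs)))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
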