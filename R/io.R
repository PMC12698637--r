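# Plain-text readers and writers for every artifact the pipeline exchanges:
# TSV count/taxonomy/metadata tables, wide and long spectra CSV, square
# distance TSV, GraphML network export, ground-truth JSON.

#' Write / read a counts TSV (samples in rows, taxa in columns)
#'
#' @param table an [asv_table()] or counts matrix.
#' @param path file path.
#' @return `read_counts_tsv` returns an integer matrix with dimnames.
#' @export
write_counts_tsv <- function(table, path) {
  m <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a taxonomy TSV (taxon id + ranked lineage)
#' @param taxonomy data.frame with `taxon_id` first.
#' @param path file path.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy_tsv
#' @export
read_taxonomy_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read sample metadata TSV
#' @param metadata data.frame with `sample_id` first.
#' @param path file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  md <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(md) <- md$sample_id
  md
}

#' Write / read spectra as wide CSV
#'
#' Wide layout: first column `wavenumber`, then one column per cell id.
#' Sample membership is carried in a companion two-column TSV
#' (`<path>.cells.tsv`: cell_id, sample_id) written alongside.
#'
#' @param spectra a [spectrum_set()].
#' @param path CSV path.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(wavenumber = spectra$wavenumbers, spectra$intensities,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  cells <- data.frame(cell_id = spectra$cell_id, sample_id = spectra$sample_id)
  write.table(cells, paste0(path, ".cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cells_path <- paste0(path, ".cells.tsv")
  cell_id <- colnames(df)[-1]
  sample_id <- if (file.exists(cells_path)) {
    cells <- read.delim(cells_path, stringsAsFactors = FALSE)
    cells$sample_id[match(cell_id, cells$cell_id)]
  } else rep("sample1", length(cell_id))
  spectrum_set(df$wavenumber, as.matrix(df[, -1, drop = FALSE]),
               cell_id, sample_id)
}

#' Read spectra from long CSV (cell_id, wavenumber, intensity)
#'
#' All cells must share one wavenumber grid; `sample_id` may be a fourth
#' column or is defaulted.
#'
#' @param path CSV path.
#' @return a [spectrum_set()].
#' @export
read_spectra_long_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "wavenumber", "intensity")
  if (!all(need %in% colnames(df))) {
    stopf("long spectra CSV needs columns: %s", paste(need, collapse = ", "))
  }
  cells <- unique(df$cell_id)
  grid <- sort(unique(df$wavenumber))
  m <- matrix(NA_real_, length(grid), length(cells),
              dimnames = list(NULL, cells))
  for (cid in cells) {
    rows <- df[df$cell_id == cid, ]
    m[match(rows$wavenumber, grid), cid] <- rows$intensity
  }
  if (anyNA(m)) stopf("cells do not share a common wavenumber grid")
  sample_id <- if ("sample_id" %in% colnames(df)) {
    df$sample_id[match(cells, df$cell_id)]
  } else rep("sample1", length(cells))
  spectrum_set(grid, m, cells, sample_id)
}

#' Write / read a square distance matrix TSV
#' @param d a `dist` object or square matrix.
#' @param path file path.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as.dist(m)
}

#' Write / read a BIOM 1.0 JSON count table
#'
#' Dense BIOM JSON (observations = taxa in rows, samples in columns) with
#' taxonomy lineages carried in row metadata. The written file contains no
#' timestamp, so identical tables produce identical files.
#'
#' @param table an [asv_table()].
#' @param path file path.
#' @export
write_biom_json <- function(table, path) {
  counts <- table$counts
  tax <- table$taxonomy
  rank_cols <- intersect(c("domain", "phylum", "class", "order", "family",
                           "genus", "species"), colnames(tax))
  rows <- lapply(colnames(counts), function(t) {
    md <- if (!is.null(tax)) {
      list(taxonomy = as.character(unlist(tax[tax$taxon_id == t, rank_cols])))
    }
    list(id = t, metadata = md)
  })
  cols <- lapply(rownames(counts), function(s) list(id = s, metadata = NULL))
  biom <- list(
    id = "opulink-counts",
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = "opulink",
    date = "",                 # fixed so identical tables give identical files
    matrix_type = "dense",
    matrix_element_type = "int",
    shape = c(ncol(counts), nrow(counts)),
    rows = rows,
    columns = cols,
    data = unname(lapply(seq_len(ncol(counts)), function(j)
      as.integer(counts[, j])))
  )
  jsonlite::write_json(biom, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_biom_json
#' @return `read_biom_json` returns an [asv_table()] (taxonomy recovered
#'   from row metadata when present; no sample metadata).
#' @export
read_biom_json <- function(path) {
  biom <- jsonlite::read_json(path)
  taxa <- vapply(biom$rows, `[[`, "", "id")
  samples <- vapply(biom$columns, `[[`, "", "id")
  m <- matrix(0L, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  if (identical(biom$matrix_type, "dense")) {
    for (j in seq_along(taxa)) m[, j] <- as.integer(unlist(biom$data[[j]]))
  } else {
    for (triplet in biom$data) {
      m[triplet[[2]] + 1L, triplet[[1]] + 1L] <- as.integer(triplet[[3]])
    }
  }
  tax <- NULL
  lineages <- lapply(biom$rows, function(r) unlist(r$metadata$taxonomy))
  if (any(lengths(lineages) > 0)) {
    ranks <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")
    width <- max(lengths(lineages))
    tax <- data.frame(taxon_id = taxa)
    for (k in seq_len(width)) {
      tax[[ranks[k]]] <- vapply(lineages, function(x)
        if (length(x) >= k) x[k] else NA_character_, "")
    }
  }
  asv_table(m, taxonomy = tax)
}

#' Export a network as GraphML (Cytoscape-compatible)
#' @param net a `sparcc_network` or igraph graph.
#' @param path file path.
#' @export
write_network_graphml <- function(net, path) {
  g <- if (inherits(net, "sparcc_network")) net$graph else net
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the edge list of a network as TSV
#' @param net a `sparcc_network`.
#' @param path file path.
#' @export
write_edge_list_tsv <- function(net, path) {
  g <- if (inherits(net, "sparcc_network")) net$graph else net
  df <- igraph::as_data_frame(g, what = "edges")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read counts + taxonomy + metadata into an ASV table
#' @param counts_path,taxonomy_path,metadata_path TSV paths (taxonomy and
#'   metadata optional).
#' @return an [asv_table()].
#' @export
read_asv_table <- function(counts_path, taxonomy_path = NULL, metadata_path = NULL) {
  counts <- read_counts_tsv(counts_path)
  tax <- if (!is.null(taxonomy_path)) read_taxonomy_tsv(taxonomy_path)
  md <- if (!is.null(metadata_path)) read_metadata_tsv(metadata_path)
  asv_table(counts, taxonomy = tax, metadata = md)
}

#' Write a simulated scene to an output directory
#'
#' Emits counts, taxonomy and metadata TSV, spectra wide CSV and the
#' ground-truth record as JSON.
#'
#' @param scene result of [simulate_scene()].
#' @param outdir directory (created if needed).
#' @return invisible vector of file paths.
#' @export
write_scene <- function(scene, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(outdir, "counts.tsv"),
    taxonomy = file.path(outdir, "taxonomy.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    spectra = file.path(outdir, "spectra.csv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  write_counts_tsv(scene$asv, paths["counts"])
  write_taxonomy_tsv(scene$asv$taxonomy, paths["taxonomy"])
  write_metadata_tsv(scene$asv$metadata, paths["metadata"])
  write_spectra_csv(scene$spectra, paths["spectra"])
  truth <- scene$truth
  truth$latent_log_basis <- NULL     # large; regenerable from design + seed
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(paths)
}
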