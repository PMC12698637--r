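# Core data containers. Plain S3 lists around base matrices/data.frames:
# counts stay integer matrices (samples x taxa), spectra a numeric matrix
# (wavenumber x cell), so every statistical routine works on base objects.

#' ASV count table with taxonomy and sample metadata
#'
#' @param counts integer matrix, samples in rows, taxa in columns; dimnames
#'   required.
#' @param taxonomy data.frame with `taxon_id` plus ranked lineage columns
#'   covering every taxon.
#' @param metadata data.frame with `sample_id`, `production`, `plant` and
#'   optionally `latitude`/`longitude`, covering every sample.
#' @return object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must have sample rownames and taxon colnames")
  }
  if (any(counts < 0)) stopf("counts must be non-negative")
  storage.mode(counts) <- "integer"
  if (!is.null(metadata)) {
    missing <- setdiff(rownames(counts), metadata$sample_id)
    if (length(missing)) stopf("metadata missing samples: %s", paste(missing, collapse = ", "))
    metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- metadata$sample_id
  }
  if (!is.null(taxonomy)) {
    missing <- setdiff(colnames(counts), taxonomy$taxon_id)
    if (length(missing)) stopf("taxonomy missing taxa: %s", paste(missing, collapse = ", "))
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), , drop = FALSE]
    rownames(taxonomy) <- taxonomy$taxon_id
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d samples x %d taxa (total %s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$metadata)) {
    cat(sprintf("  metadata: %s\n", paste(setdiff(colnames(x$metadata), "sample_id"),
                                          collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Subset an ASV table by samples and/or taxa
#'
#' @param x an `asv_table`.
#' @param samples,taxa character or logical/integer selectors; NULL keeps all.
#' @return a new `asv_table`.
#' @export
subset_asv <- function(x, samples = NULL, taxa = NULL) {
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(taxa)) counts <- counts[, taxa, drop = FALSE]
  asv_table(counts, taxonomy = x$taxonomy, metadata = x$metadata)
}

#' Per-sample relative abundances
#'
#' @param x an `asv_table` or a counts matrix.
#' @return matrix of row-closed proportions.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "asv_table")) x$counts else as.matrix(x)
  sweep(m, 1, rowSums(m), `/`)
}

#' Collection of single-cell Raman spectra on a shared wavenumber grid
#'
#' @param wavenumbers strictly increasing numeric grid (cm^-1).
#' @param intensities numeric matrix, one column per cell, rows matching
#'   `wavenumbers`.
#' @param cell_id,sample_id per-cell labels.
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, intensities, cell_id, sample_id) {
  intensities <- as.matrix(intensities)
  if (any(diff(wavenumbers) <= 0)) stopf("wavenumbers must be strictly increasing")
  if (nrow(intensities) != length(wavenumbers)) {
    stopf("intensities rows (%d) must match wavenumber grid (%d)",
          nrow(intensities), length(wavenumbers))
  }
  if (ncol(intensities) != length(cell_id) || length(cell_id) != length(sample_id)) {
    stopf("cell_id/sample_id must match number of spectra")
  }
  if (!all(is.finite(intensities))) stopf("intensities must be finite")
  colnames(intensities) <- cell_id
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = intensities,
                 cell_id = as.character(cell_id),
                 sample_id = as.character(sample_id)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("Raman spectrum set: %d cells from %d samples, grid %g-%g cm^-1 (%d points)\n",
              length(x$cell_id), length(unique(x$sample_id)),
              min(x$wavenumbers), max(x$wavenumbers), length(x$wavenumbers)))
  invisible(x)
}

#' Subset a spectrum set by cell ids
#'
#' @param x a `spectrum_set`.
#' @param cells character vector of cell ids (order preserved from `x`).
#' @return a `spectrum_set`.
#' @export
subset_spectra <- function(x, cells) {
  keep <- x$cell_id %in% cells
  spectrum_set(x$wavenumbers, x$intensities[, keep, drop = FALSE],
               x$cell_id[keep], x$sample_id[keep])
}

n_spectra <- function(x) length(x$cell_id)
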