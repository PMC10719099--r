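#' Run the standard clustering pipeline on an SPNExperiment
#'
#' Convenience wrapper chaining [normalizeSelectScale()],
#' [reduceDimensions()], [clusterMultiresolution()] and [embed2D()],
#' storing results back on the object: the log-normalized matrix as
#' assay `"logcounts"`, PCs and UMAP in `reducedDims`, and one
#' `colData` column per clustering resolution. A single pipeline seed
#' fans out to fixed per-stage seeds.
#'
#' @param spe an [SPNExperiment] (QC-filtered).
#' @param n_variable variable genes (default 2000).
#' @param n_components PCs (default 30).
#' @param k_neighbors KNN size (default 15).
#' @param resolutions clustering resolutions (default `c(0.5, 1, 2, 3)`).
#' @param seed pipeline seed.
#' @param umap also compute the 2D embedding (default TRUE).
#' @return list with `spe` (augmented), `norm`, `var_genes`, `pca`,
#'   `clusters` (list of factors), `umap` (or NULL).
#' @export
runAtlasPipeline <- function(spe, n_variable = 2000, n_components = 30,
                             k_neighbors = 15,
                             resolutions = c(0.5, 1, 2, 3), seed = 1L,
                             umap = TRUE) {
  stopifnot(is(spe, "SPNExperiment"))
  ns <- normalizeSelectScale(spe, n_variable = n_variable)
  pca <- reduceDimensions(ns$scaled, n_components = n_components,
                          seed = seed + 1L)
  clusters <- clusterMultiresolution(pca$coords, k_neighbors = k_neighbors,
                                     resolutions = resolutions,
                                     seed = seed + 2L)
  um <- if (umap) embed2D(pca$coords, seed = seed + 3L) else NULL
  SummarizedExperiment::assay(spe, "logcounts") <- ns$norm
  SingleCellExperiment::reducedDim(spe, "PCA") <- pca$coords
  if (!is.null(um)) SingleCellExperiment::reducedDim(spe, "UMAP") <- um
  for (nm in names(clusters))
    SummarizedExperiment::colData(spe)[[nm]] <- clusters[[nm]]
  list(spe = spe, norm = ns$norm, var_genes = ns$var_genes, pca = pca,
       clusters = clusters, umap = um)
}
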