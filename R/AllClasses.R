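#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

# -- Central container ---------------------------------------------------

#' SPNExperiment: labelled count matrix with per-nucleus metadata
#'
#' Extends [SingleCellExperiment::SingleCellExperiment] for gene-by-nucleus
#' count data from retrogradely labelled nuclei. The `colData` must carry
#' the per-nucleus fields the pipeline relies on:
#' `roi_label` (dissection region), `sort_channel` (one of `"GFP"`,
#' `"mScarlet"`, `"dual"`), `xfp_count` (raw fluorophore transcript count,
#' taken from the unfiltered matrix), `mito_fraction` (proportion of counts
#' from mitochondrial genes) and `genes_detected` (genes with count > 0).
#'
#' @slot .. see [SingleCellExperiment::SingleCellExperiment]
#' @export
setClass("SPNExperiment", contains = "SingleCellExperiment")

.spn_required_cols <- c("roi_label", "sort_channel", "xfp_count",
                        "mito_fraction", "genes_detected")

setValidity("SPNExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.spn_required_cols, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks field(s): ", paste(miss, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (!length(msg)) {
    if (any(cd$mito_fraction < 0 | cd$mito_fraction > 1, na.rm = TRUE))
      msg <- c(msg, "mito_fraction must lie in [0, 1]")
    if (any(cd$xfp_count < 0, na.rm = TRUE))
      msg <- c(msg, "xfp_count must be non-negative")
    bad <- !cd$sort_channel %in% c("GFP", "mScarlet", "dual")
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "sort_channel must be one of 'GFP', 'mScarlet', 'dual'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SPNExperiment
#'
#' @param counts genes x nuclei count matrix (dense or sparse); must have
#'   row and column names.
#' @param roi_label character vector of dissection labels, one per nucleus.
#' @param sort_channel character vector in `{"GFP","mScarlet","dual"}`.
#' @param xfp_count non-negative integer vector of raw fluorophore
#'   transcript counts per nucleus.
#' @param mito_pattern regular expression identifying mitochondrial genes
#'   by name (mouse nomenclature prefix `"mt-"` by default); used to
#'   compute `mito_fraction`.
#' @param extra_coldata optional `DataFrame`/`data.frame` of further
#'   per-nucleus columns.
#'
#' @details `genes_detected` and `mito_fraction` are computed from
#'   `counts`, so they always satisfy the class invariants.
#' @return an [SPNExperiment] object.
#' @export
SPNExperiment <- function(counts, roi_label, sort_channel, xfp_count,
                          mito_pattern = "^mt-", extra_coldata = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have row (gene) and column (nucleus) names")
  n <- ncol(counts)
  stopifnot(length(roi_label) == n, length(sort_channel) == n,
            length(xfp_count) == n)
  libsize <- Matrix::colSums(counts)
  mito <- grepl(mito_pattern, rownames(counts))
  mito_fraction <- if (any(mito)) {
    mf <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(libsize, 1)
    mf[libsize == 0] <- 0
    mf
  } else rep(0, n)
  cd <- S4Vectors::DataFrame(
    roi_label = as.character(roi_label),
    sort_channel = as.character(sort_channel),
    xfp_count = as.integer(xfp_count),
    mito_fraction = as.numeric(mito_fraction),
    genes_detected = as.integer(Matrix::colSums(counts > 0)),
    row.names = colnames(counts))
  if (!is.null(extra_coldata)) cd <- cbind(cd, S4Vectors::DataFrame(extra_coldata))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  new("SPNExperiment", sce)
}

#' @describeIn SPNExperiment compact display
#' @param object an `SPNExperiment`
#' @export
setMethod("show", "SPNExperiment", function(object) {
  callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("XFP+ nuclei: %d/%d; median genes detected: %d\n",
              sum(cd$xfp_count >= 1L), ncol(object),
              as.integer(stats::median(cd$genes_detected))))
})

# -- Simulation configs --------------------------------------------------

#' Configuration for the synthetic atlas generator
#'
#' Defines the planted structure of a simulated gene-by-nucleus count
#' matrix: number of types, markers and their (natural-log) fold change,
#' library sizes, mitochondrial load, and the first-/second-order XFP
#' labelling mixture.
#'
#' @slot n_types number of planted cell types.
#' @slot nuclei_per_type nuclei simulated per type.
#' @slot n_genes total genes (marker sets are carved out of these,
#'   disjoint across types; 13 extra `mt-` genes are appended).
#' @slot n_marker_genes_per_type markers per type.
#' @slot marker_logfc natural-log fold change of a type's markers.
#' @slot library_size_mean mean library size (counts per nucleus).
#' @slot xfp_rate_first_order probability a first-order nucleus carries at
#'   least one XFP transcript.
#' @slot xfp_rate_second_order same for second-order nuclei.
#' @slot frac_second_order_types fraction of types planted as second-order.
#' @slot mito_frac_mean mean mitochondrial count fraction.
#' @slot seed RNG seed.
#' @export
setClass("AtlasSimConfig", representation(
  n_types = "integer", nuclei_per_type = "integer", n_genes = "integer",
  n_marker_genes_per_type = "integer", marker_logfc = "numeric",
  library_size_mean = "numeric", xfp_rate_first_order = "numeric",
  xfp_rate_second_order = "numeric", frac_second_order_types = "numeric",
  mito_frac_mean = "numeric", seed = "integer"))

setValidity("AtlasSimConfig", function(object) {
  msg <- character()
  cnt <- c(n_types = object@n_types, nuclei_per_type = object@nuclei_per_type,
           n_genes = object@n_genes, markers = object@n_marker_genes_per_type)
  if (any(cnt <= 0L)) msg <- c(msg, "counts must be positive")
  pr <- c(object@xfp_rate_first_order, object@xfp_rate_second_order,
          object@frac_second_order_types, object@mito_frac_mean)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@n_types * object@n_marker_genes_per_type > object@n_genes)
    msg <- c(msg, "marker sets must fit disjointly into n_genes")
  if (object@library_size_mean <= 0) msg <- c(msg, "library_size_mean must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname AtlasSimConfig-class
#' @param n_types,nuclei_per_type,n_genes,n_marker_genes_per_type,marker_logfc,library_size_mean,xfp_rate_first_order,xfp_rate_second_order,frac_second_order_types,mito_frac_mean,seed see slots.
#' @export
AtlasSimConfig <- function(n_types = 12, nuclei_per_type = 300,
                           n_genes = 2000, n_marker_genes_per_type = 50,
                           marker_logfc = 1, library_size_mean = 10000,
                           xfp_rate_first_order = 0.8,
                           xfp_rate_second_order = 0.02,
                           frac_second_order_types = 0.25,
                           mito_frac_mean = 0.02, seed = 1L) {
  new("AtlasSimConfig", n_types = as.integer(n_types),
      nuclei_per_type = as.integer(nuclei_per_type),
      n_genes = as.integer(n_genes),
      n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
      marker_logfc = marker_logfc, library_size_mean = library_size_mean,
      xfp_rate_first_order = xfp_rate_first_order,
      xfp_rate_second_order = xfp_rate_second_order,
      frac_second_order_types = frac_second_order_types,
      mito_frac_mean = mito_frac_mean, seed = as.integer(seed))
}

#' Configuration for synthetic electrophysiology recordings
#'
#' @slot sampling_rate Hz (default 20000).
#' @slot spike_amplitude mV (magnitude of the negative spike transient in
#'   cell-attached traces, and of the stylized AP in whole-cell sweeps).
#' @slot spike_half_width_true ms, full width at half amplitude of the
#'   spike template.
#' @slot firing_rate_true Hz, Poisson rate of spontaneous spikes.
#' @slot input_resistance_true megaohm.
#' @slot noise_sd mV, Gaussian recording noise.
#' @slot seed RNG seed.
#' @export
setClass("EphysSimConfig", representation(
  sampling_rate = "numeric", spike_amplitude = "numeric",
  spike_half_width_true = "numeric", firing_rate_true = "numeric",
  input_resistance_true = "numeric", noise_sd = "numeric", seed = "integer"))

setValidity("EphysSimConfig", function(object) {
  msg <- character()
  if (object@sampling_rate <= 0) msg <- c(msg, "sampling_rate must be > 0")
  if (object@spike_half_width_true <= 0 || object@spike_half_width_true >= 5)
    msg <- c(msg, "spike_half_width_true must be in (0, 5) ms")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@firing_rate_true < 0) msg <- c(msg, "firing_rate_true must be >= 0")
  if (object@input_resistance_true <= 0) msg <- c(msg, "input_resistance_true must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname EphysSimConfig-class
#' @param sampling_rate,spike_amplitude,spike_half_width_true,firing_rate_true,input_resistance_true,noise_sd,seed see slots.
#' @export
EphysSimConfig <- function(sampling_rate = 20000, spike_amplitude = 5,
                           spike_half_width_true = 1,
                           firing_rate_true = 2.5,
                           input_resistance_true = 100,
                           noise_sd = 0.1, seed = 1L) {
  new("EphysSimConfig", sampling_rate = sampling_rate,
      spike_amplitude = spike_amplitude,
      spike_half_width_true = spike_half_width_true,
      firing_rate_true = firing_rate_true,
      input_resistance_true = input_resistance_true,
      noise_sd = noise_sd, seed = as.integer(seed))
}

#' Configuration for synthetic axon/soma images
#'
#' @slot height,width image dimensions in pixels (>= 100).
#' @slot n_blobs number of blob-shaped axon signal patches (or somata in
#'   two-channel mode).
#' @slot blob_intensity 8-bit intensity of the planted signal.
#' @slot background_sd 8-bit standard deviation of the background noise.
#' @slot coloc_fraction_true fraction of masks planted as co-intense in
#'   both channels (two-channel mode).
#' @slot seed RNG seed.
#' @export
setClass("ImageSimConfig", representation(
  height = "integer", width = "integer", n_blobs = "integer",
  blob_intensity = "numeric", background_sd = "numeric",
  coloc_fraction_true = "numeric", seed = "integer"))

setValidity("ImageSimConfig", function(object) {
  msg <- character()
  if (object@height < 100L || object@width < 100L)
    msg <- c(msg, "image dimensions must be >= 100 px")
  if (object@blob_intensity < 0 || object@blob_intensity > 255)
    msg <- c(msg, "blob_intensity must lie in [0, 255]")
  if (object@background_sd < 0) msg <- c(msg, "background_sd must be >= 0")
  if (object@coloc_fraction_true < 0 || object@coloc_fraction_true > 1)
    msg <- c(msg, "coloc_fraction_true must lie in [0, 1]")
  if (object@n_blobs < 0L) msg <- c(msg, "n_blobs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ImageSimConfig-class
#' @param height,width,n_blobs,blob_intensity,background_sd,coloc_fraction_true,seed see slots.
#' @export
ImageSimConfig <- function(height = 512, width = 512, n_blobs = 40,
                           blob_intensity = 200, background_sd = 15,
                           coloc_fraction_true = 0.5, seed = 1L) {
  new("ImageSimConfig", height = as.integer(height), width = as.integer(width),
      n_blobs = as.integer(n_blobs), blob_intensity = blob_intensity,
      background_sd = background_sd,
      coloc_fraction_true = coloc_fraction_true, seed = as.integer(seed))
}

# -- Result containers ---------------------------------------------------

#' Constellation relatedness graph
#'
#' Nodes are cell types placed at their 2D embedding centroids with area
#' proportional to `log(n_nuclei)`; directed neighbour fractions give rise
#' to an undirected edge wherever either direction exceeds the edge
#' threshold (strictly). Drawn edge widths are node-width fractions,
#' normalized so the global maximum off-diagonal fraction is 100%.
#'
#' @slot nodes `DataFrame` with `type`, `centroid_x`, `centroid_y`,
#'   `n_nuclei`, `area`.
#' @slot fractions types x types row-stochastic neighbour-fraction matrix
#'   (self-fractions on the diagonal, retained but never drawn).
#' @slot edges `DataFrame` with `from`, `to`, `fraction_from`,
#'   `fraction_to`, `width_from`, `width_to`.
#' @slot k_neighbors neighbours pooled per nucleus.
#' @slot edge_threshold strict lower bound for drawing an edge.
#' @export
setClass("ConstellationGraph", representation(
  nodes = "DataFrame", fractions = "matrix", edges = "DataFrame",
  k_neighbors = "integer", edge_threshold = "numeric"))

setValidity("ConstellationGraph", function(object) {
  msg <- character()
  f <- object@fractions
  if (any(f < 0 | f > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (any(abs(rowSums(f) - 1) > 1e-8))
    msg <- c(msg, "fraction rows must sum to 1")
  if (object@edge_threshold <= 0 || object@edge_threshold >= 1)
    msg <- c(msg, "edge_threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConstellationGraph", function(object) {
  cat(sprintf("ConstellationGraph: %d types, %d edges (k = %d, threshold > %g)\n",
              nrow(object@nodes), nrow(object@edges),
              object@k_neighbors, object@edge_threshold))
})

#' Binned axon-density grid
#'
#' @slot bin_counts above-threshold pixel counts per bin (rows follow image
#'   rows); the sum equals the number of retained mask pixels exactly.
#' @slot smoothed the same grid after normalized moving-average smoothing.
#' @slot bin_px bin edge length in pixels.
#' @slot smooth_px smoothing window edge length (pixel interpretation) or
#'   window in bins times `bin_px` (bin interpretation).
#' @export
setClass("DensityGrid", representation(
  bin_counts = "matrix", smoothed = "matrix",
  bin_px = "integer", smooth_px = "integer"))

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid: %d x %d bins of %d px; %d mask pixels\n",
              nrow(object@bin_counts), ncol(object@bin_counts),
              object@bin_px, sum(object@bin_counts)))
})

#' Reference taxonomy for nearest-centroid mapping
#'
#' @slot centroids clusters x genes mean expression matrix (normalized log
#'   scale) with cluster row names.
#' @slot hierarchy `data.frame` with columns `cluster`, `supertype`,
#'   `subclass` covering every centroid row.
#' @export
setClass("ReferenceTaxonomy", representation(
  centroids = "matrix", hierarchy = "data.frame"))

setValidity("ReferenceTaxonomy", function(object) {
  msg <- character()
  if (is.null(rownames(object@centroids)))
    msg <- c(msg, "centroids must have cluster row names")
  need <- c("cluster", "supertype", "subclass")
  if (!all(need %in% colnames(object@hierarchy)))
    msg <- c(msg, "hierarchy needs columns cluster, supertype, subclass")
  else if (!all(rownames(object@centroids) %in% object@hierarchy$cluster))
    msg <- c(msg, "every centroid cluster must appear in the hierarchy map")
  if (length(msg)) msg else TRUE
})

#' @rdname ReferenceTaxonomy-class
#' @param centroids,hierarchy see slots.
#' @export
ReferenceTaxonomy <- function(centroids, hierarchy) {
  new("ReferenceTaxonomy", centroids = as.matrix(centroids),
      hierarchy = as.data.frame(hierarchy))
}

setMethod("show", "ReferenceTaxonomy", function(object) {
  cat(sprintf("ReferenceTaxonomy: %d clusters x %d genes, %d supertypes, %d subclasses\n",
              nrow(object@centroids), ncol(object@centroids),
              length(unique(object@hierarchy$supertype)),
              length(unique(object@hierarchy$subclass))))
})
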