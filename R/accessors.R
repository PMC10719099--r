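# Accessors for the result containers; slot access stays internal.

#' @rdname ConstellationGraph-class
#' @param x a `ConstellationGraph`
#' @export
constellationNodes <- function(x) x@nodes

#' @rdname ConstellationGraph-class
#' @export
constellationEdges <- function(x) x@edges

#' @rdname ConstellationGraph-class
#' @export
neighborFractions <- function(x) x@fractions

#' @rdname DensityGrid-class
#' @param x a `DensityGrid`
#' @export
densityBins <- function(x) x@bin_counts

#' @rdname DensityGrid-class
#' @export
densitySmoothed <- function(x) x@smoothed

#' @rdname DensityGrid-class
#' @export
densityBinPx <- function(x) x@bin_px

#' @rdname ReferenceTaxonomy-class
#' @param x a `ReferenceTaxonomy`
#' @export
refCentroids <- function(x) x@centroids

#' @rdname ReferenceTaxonomy-class
#' @export
refHierarchy <- function(x) x@hierarchy
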