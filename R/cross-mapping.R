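# Nearest-centroid label transfer between taxonomies, support filtering,
# and multi-level confusion matrices.

#' Select mapping genes from pairwise DE results
#'
#' Takes the union over all cluster pairs of the top `n_per_pair` genes
#' (ranked by adjusted p-value, ties by decreasing |logFC|) and
#' intersects it with the genes present in both datasets.
#'
#' @param pair_de list of DE tables (as from
#'   [differentialExpression()]), one per cluster pair.
#' @param query_genes,ref_genes gene universes of the two datasets.
#' @param n_per_pair genes taken per pair before the union (default 50).
#' @return character vector of mapping genes.
#' @export
selectMappingGenes <- function(pair_de, query_genes, ref_genes,
                               n_per_pair = 50) {
  shared <- intersect(query_genes, ref_genes)
  if (!length(shared)) stop("query and reference gene universes are disjoint")
  top <- unlist(lapply(pair_de, function(de) {
    de <- de[!is.na(de$p_value), , drop = FALSE]
    ord <- order(de$p_adjusted, -abs(de$log_fold_change))
    utils::head(de$gene[ord], n_per_pair)
  }))
  out <- intersect(unique(top), shared)
  if (!length(out)) stop("no selected gene present in both datasets")
  out
}

#' Map query cells to the nearest reference centroid
#'
#' Each query cell is assigned to the reference cluster whose centroid
#' maximizes Pearson correlation (default) or minimizes Euclidean
#' distance over the mapping gene set. Ties go to the lower centroid id
#' (stable, logged in the `tie` column). A query cell that is constant
#' over the mapping genes has no defined correlation and falls back to
#' Euclidean distance with a warning.
#'
#' @param query genes x cells expression matrix (normalized log scale).
#' @param ref a [ReferenceTaxonomy].
#' @param metric `"pearson"` (default) or `"euclidean"`.
#' @param query_clusters optional query cluster labels (enables support
#'   filtering and confusion matrices).
#' @param genes optional mapping gene set; default: all shared genes.
#' @return list of class `MappingResult`: `assignments` (`data.frame`
#'   with `cell`, `query_cluster`, `cluster`, `similarity`, `tie`),
#'   `metric`, `support_filtered`, `dropped` (empty until
#'   [filterLowSupport()]).
#' @export
mapToNearestCentroid <- function(query, ref, metric = c("pearson", "euclidean"),
                                 query_clusters = NULL, genes = NULL) {
  stopifnot(is(ref, "ReferenceTaxonomy"))
  metric <- match.arg(metric)
  cents <- refCentroids(ref)
  if (is.null(genes)) genes <- intersect(rownames(query), colnames(cents))
  genes <- intersect(intersect(genes, rownames(query)), colnames(cents))
  if (length(genes) < 10)
    stop("mapping gene set has fewer than 10 genes")
  q <- as.matrix(query[genes, , drop = FALSE])
  cm <- cents[, genes, drop = FALSE]
  ids <- rownames(cents)

  if (metric == "pearson") {
    sim <- suppressWarnings(stats::cor(q, t(cm)))   # cells x clusters
    const <- apply(q, 2, function(v) stats::sd(v) == 0)
    if (any(const)) {
      warning(sum(const), " constant query cell(s); falling back to Euclidean")
      dmat <- .centroidDist(q[, const, drop = FALSE], cm)
      sim[const, ] <- -dmat
    }
  } else {
    sim <- -.centroidDist(q, cm)
  }
  best <- apply(sim, 1, which.max)
  tie <- vapply(seq_len(nrow(sim)), function(i)
    sum(sim[i, ] == sim[i, best[i]]) > 1L, logical(1))
  assignments <- data.frame(
    cell = colnames(q),
    query_cluster = if (is.null(query_clusters)) NA_character_
                    else as.character(query_clusters),
    cluster = ids[best],
    similarity = sim[cbind(seq_len(nrow(sim)), best)],
    tie = tie, stringsAsFactors = FALSE)
  structure(list(assignments = assignments, metric = metric,
                 support_filtered = FALSE,
                 dropped = list(query = character(), ref = character())),
            class = "MappingResult")
}

.centroidDist <- function(q, cm) {
  # cells x clusters Euclidean distances; q genes x cells, cm clusters x genes
  qs <- colSums(q^2)
  cs <- rowSums(cm^2)
  d2 <- outer(qs, cs, "+") - 2 * t(q) %*% t(cm)
  sqrt(pmax(d2, 0))
}

#' @export
print.MappingResult <- function(x, ...) {
  cat(sprintf("MappingResult: %d cells -> %d reference clusters (%s)%s\n",
              nrow(x$assignments), length(unique(x$assignments$cluster)),
              x$metric,
              if (x$support_filtered) ", support-filtered" else ""))
  invisible(x)
}

#' Remove clusters with low mapped-cell support
#'
#' Reference clusters with fewer than `min_cells` mapped cells and query
#' clusters with fewer than `min_cells` cells remaining are dropped from
#' the correspondence, in both directions, iterating to a fixed point so
#' the operation is idempotent.
#'
#' @param result a `MappingResult` (mapped with `query_clusters`).
#' @param min_cells support threshold (default 3; a cluster with exactly
#'   `min_cells` cells is retained).
#' @return the filtered `MappingResult` with `support_filtered = TRUE`
#'   and dropped cluster ids recorded.
#' @export
filterLowSupport <- function(result, min_cells = 3) {
  a <- result$assignments
  dropped_q <- character(); dropped_r <- character()
  repeat {
    rc <- table(a$cluster)
    bad_r <- names(rc)[rc < min_cells]
    qc <- table(a$query_cluster)
    bad_q <- names(qc)[qc < min_cells]
    if (!length(bad_r) && !length(bad_q)) break
    dropped_r <- union(dropped_r, bad_r)
    dropped_q <- union(dropped_q, bad_q)
    a <- a[!(a$cluster %in% bad_r) & !(a$query_cluster %in% bad_q), ,
           drop = FALSE]
    if (!nrow(a)) break
  }
  result$assignments <- a
  result$support_filtered <- TRUE
  result$dropped <- list(query = dropped_q, ref = dropped_r)
  result
}

#' Confusion matrices at multiple hierarchy levels
#'
#' Tabulates mapped-cell counts of query clusters against the reference
#' hierarchy, aggregated at the requested levels. Row sums equal the
#' mapped-cell counts at every level (aggregation conserves counts).
#'
#' @param result a `MappingResult` mapped with `query_clusters`.
#' @param ref a [ReferenceTaxonomy] providing the cluster -> supertype ->
#'   subclass map.
#' @param levels character subset of `c("cluster","supertype","subclass")`.
#' @return named list of confusion matrices (query clusters x reference
#'   groups).
#' @export
buildConfusion <- function(result, ref,
                           levels = c("cluster", "supertype", "subclass")) {
  a <- result$assignments
  if (all(is.na(a$query_cluster)))
    stop("mapping was run without query_clusters")
  hier <- refHierarchy(ref)
  miss <- setdiff(unique(a$cluster), hier$cluster)
  if (length(miss))
    stop("mapped cluster absent from hierarchy: ",
         paste(miss, collapse = ", "))
  idx <- match(a$cluster, hier$cluster)
  out <- lapply(levels, function(lv) {
    grp <- hier[[lv]][idx]
    as.matrix(table(query = a$query_cluster, reference = grp))
  })
  names(out) <- levels
  out
}
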