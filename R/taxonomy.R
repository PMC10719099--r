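# Type centroids, taxonomy tree, gene-module scores, LIM-group
# assignment and the division/subclass/type hierarchy.

#' Average expression per type over a marker-gene panel
#'
#' @param norm log-normalized genes x nuclei matrix.
#' @param types type assignment (factor or vector), one per nucleus.
#' @param marker_genes character vector of genes to average (default all
#'   rows).
#' @return types x marker-genes matrix of arithmetic means.
#' @export
computeTypeCentroids <- function(norm, types, marker_genes = rownames(norm)) {
  types <- as.factor(types)
  if (any(table(types) == 0L))
    stop("empty type: ",
         paste(names(which(table(types) == 0L)), collapse = ", "))
  marker_genes <- intersect(marker_genes, rownames(norm))
  x <- norm[marker_genes, , drop = FALSE]
  agg <- t(sapply(levels(types), function(tp)
    Matrix::rowMeans(x[, types == tp, drop = FALSE])))
  matrix(agg, nrow = nlevels(types),
         dimnames = list(levels(types), marker_genes))
}

#' Build the cell-type taxonomy tree
#'
#' Agglomerative clustering of type centroids, by default average linkage
#' on correlation distance (1 - Pearson) — the common choice for
#' transcriptomic dendrograms. Linkage and metric are pluggable.
#'
#' @param centroids types x genes centroid matrix with unique row names.
#' @param linkage linkage method for [stats::hclust()].
#' @param metric `"correlation"` (1 - Pearson across genes) or
#'   `"euclidean"`.
#' @return an `hclust` object with types as leaves.
#' @export
buildTaxonomyTree <- function(centroids, linkage = "average",
                              metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(centroids) < 2) stop("need at least two types")
  if (anyDuplicated(rownames(centroids)))
    stop("duplicate type ids in centroid matrix")
  d <- if (metric == "correlation")
    stats::as.dist(1 - stats::cor(t(centroids))) else stats::dist(centroids)
  stats::hclust(d, method = linkage)
}

#' Sequential type ids in taxonomy tree order
#'
#' @param tree an `hclust` from [buildTaxonomyTree()].
#' @return named integer vector: type name -> id, numbered left to right
#'   along the dendrogram.
#' @export
typeIdsFromTree <- function(tree) {
  stats::setNames(order(tree$order), tree$labels[tree$order])[tree$labels]
}

#' Export the taxonomy tree as Newick
#'
#' @param tree an `hclust`.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @export
exportNewick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(file)) ape::write.tree(phy) else ape::write.tree(phy, file)
}

#' Three-level hierarchy from the taxonomy tree
#'
#' Divisions come from the first split surface of the tree (`cutree` at
#' `n_divisions`); subclasses are nested cuts at `n_subclasses`. An
#' optional override table (type -> division) implements manual
#' fine-tuning, e.g. moving neuromodulatory types into the modulatory
#' division on neurotransmitter evidence.
#'
#' @param tree an `hclust` over types.
#' @param n_divisions number of divisions (default 3).
#' @param n_subclasses number of subclasses (must be >= `n_divisions`).
#' @param division_overrides optional named vector `type = division`.
#' @return `data.frame` with `type`, `type_id` (tree order), `subclass`,
#'   `division`.
#' @export
buildHierarchy <- function(tree, n_divisions = 3, n_subclasses = 6,
                           division_overrides = NULL) {
  stopifnot(n_subclasses >= n_divisions)
  div <- stats::cutree(tree, k = n_divisions)
  sub <- stats::cutree(tree, k = n_subclasses)
  ids <- typeIdsFromTree(tree)
  out <- data.frame(type = tree$labels, type_id = unname(ids),
                    subclass = paste0("subclass-", sub),
                    division = paste0("division-", div),
                    stringsAsFactors = FALSE)
  if (!is.null(division_overrides)) {
    hit <- out$type %in% names(division_overrides)
    out$division[hit] <- unname(division_overrides[out$type[hit]])
  }
  out[order(out$type_id), , drop = FALSE]
}

#' Score a gene module against expression-matched controls
#'
#' The per-nucleus score is the mean expression of the module genes minus
#' the mean expression of a control set drawn to match the module's
#' expression profile: all genes are binned into `n_control_bins` by
#' average expression and, for each module gene, up to
#' `n_control_per_gene` control genes are sampled from its bin. The
#' aggregated control set is the union of the samples.
#'
#' @param norm log-normalized genes x nuclei matrix.
#' @param gene_set character vector of module genes (must be present).
#' @param n_control_bins number of expression bins (default 25).
#' @param n_control_per_gene controls sampled per module gene
#'   (default 100).
#' @param seed RNG seed for control sampling.
#' @return named numeric vector of per-nucleus scores.
#' @export
scoreGeneModule <- function(norm, gene_set, n_control_bins = 25,
                            n_control_per_gene = 100, seed = 1L) {
  if (!length(gene_set)) stop("gene_set is empty")
  miss <- setdiff(gene_set, rownames(norm))
  if (length(miss))
    stop("gene_set not present in matrix: ", paste(head(miss, 5), collapse = ", "))
  if (length(gene_set) > nrow(norm))
    stop("gene_set larger than the available gene pool")
  avg <- Matrix::rowMeans(norm)
  brks <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_control_bins + 1)))
  bin <- cut(avg, breaks = brks, include.lowest = TRUE, labels = FALSE)
  set.seed(seed)
  ctrl <- unique(unlist(lapply(gene_set, function(g) {
    pool <- rownames(norm)[bin == bin[match(g, rownames(norm))]]
    sample(pool, min(n_control_per_gene, length(pool)))
  })))
  score <- Matrix::colMeans(norm[gene_set, , drop = FALSE]) -
    Matrix::colMeans(norm[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(score), colnames(norm))
}

#' Assign hindbrain types to LIM groups
#'
#' Each type gets the LIM group (`Lmx1b`, `Lhx2/9`, `Lhx3/4`, `Lhx1/5`)
#' with the highest median per-nucleus module score. A type whose
#' `Lhx1/5` and `Lhx3/4` medians are both positive and within
#' `combined_ratio` of each other is assigned the combined
#' `Lhx1/5+Lhx3/4` group (a documented heuristic — the combined group is
#' defined by co-expression, not by a published formula). Types whose
#' scores are all non-positive are left unassigned with a warning.
#'
#' @param scores nuclei x 4 matrix (or data.frame) of module scores with
#'   columns `Lmx1b`, `Lhx2/9`, `Lhx3/4`, `Lhx1/5`.
#' @param types type assignment per nucleus.
#' @param combined_ratio ratio of the smaller to the larger of the
#'   `Lhx1/5` and `Lhx3/4` medians above which the combined group is
#'   called (default 0.75).
#' @return `data.frame` with `type`, `group`, the four median scores and
#'   a `combined` flag.
#' @export
assignLIMGroup <- function(scores, types, combined_ratio = 0.75) {
  groups <- c("Lmx1b", "Lhx2/9", "Lhx3/4", "Lhx1/5")
  scores <- as.matrix(scores)
  stopifnot(all(groups %in% colnames(scores)),
            nrow(scores) == length(types))
  types <- as.factor(types)
  med <- t(sapply(levels(types), function(tp)
    apply(scores[types == tp, groups, drop = FALSE], 2, stats::median)))
  assigned <- character(nrow(med))
  combined <- logical(nrow(med))
  for (i in seq_len(nrow(med))) {
    m <- med[i, ]
    if (all(m <= 0)) {
      assigned[i] <- NA_character_
      next
    }
    pair <- sort(c(m["Lhx1/5"], m["Lhx3/4"]), decreasing = TRUE)
    if (all(pair > 0) && pair[2] / pair[1] >= combined_ratio &&
        max(m[c("Lhx1/5", "Lhx3/4")]) >= max(m[c("Lmx1b", "Lhx2/9")])) {
      assigned[i] <- "Lhx1/5+Lhx3/4"
      combined[i] <- TRUE
    } else {
      assigned[i] <- groups[which.max(m)]
    }
  }
  if (anyNA(assigned))
    warning("unassigned type(s): ",
            paste(levels(types)[is.na(assigned)], collapse = ", "))
  data.frame(type = levels(types), group = assigned, med,
             combined = combined, row.names = NULL, check.names = FALSE)
}
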