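# Constellation relatedness graph and per-nucleus KNN heterogeneity.

#' Pooled nearest-neighbour fractions between types
#'
#' For each nucleus the `k` nearest neighbours (self excluded) are found
#' in the reduced space and summarized by type: row `t` of the result is
#' the distribution over types of the pooled `k * n_t` neighbour slots of
#' type `t`'s nuclei. Rows sum to 1 exactly. Distance ties are broken by
#' the stable index order of the kd-tree search.
#'
#' @param coords nuclei x components matrix (PC space; the 2D embedding
#'   is for display only).
#' @param types type assignment per nucleus.
#' @param k neighbours per nucleus (default 15); must be < nuclei.
#' @return types x types fraction matrix (self-fractions on diagonal).
#' @export
computeNeighborFractions <- function(coords, types, k = 15) {
  types <- as.factor(types)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of nuclei")
  if (any(table(types) == 0L))
    stop("empty type: ",
         paste(names(which(table(types) == 0L)), collapse = ", "))
  nn <- RANN::nn2(coords, k = k + 1L)$nn.idx
  nn <- t(vapply(seq_len(n), function(i) {
    row <- nn[i, ]
    row <- row[row != i]
    row[seq_len(k)]
  }, integer(k)))
  src <- rep(types, times = k)
  tgt <- types[as.vector(nn)]
  tab <- table(src, tgt)
  frac <- tab / rowSums(tab)
  matrix(frac, nrow = nlevels(types),
         dimnames = list(levels(types), levels(types)))
}

#' Build a constellation graph
#'
#' Nodes sit at the mean 2D position of each type's nuclei with area
#' proportional to `log(n_nuclei)`. An undirected edge is drawn between
#' types `a` and `b` iff `max(fraction(a->b), fraction(b->a))` strictly
#' exceeds `edge_threshold`. The drawn width at each endpoint is that
#' endpoint's outgoing fraction divided by the global maximum
#' off-diagonal fraction (so the largest outside-neighbour fraction in
#' the graph is rendered at 100% of its node width), clipped to 1.
#'
#' @param fractions types x types matrix from
#'   [computeNeighborFractions()].
#' @param embedding_2d nuclei x 2 coordinates.
#' @param types type assignment per nucleus (levels must match
#'   `fractions`).
#' @param edge_threshold strict threshold in (0, 1), default 0.05.
#' @param k_neighbors recorded on the object (default 15).
#' @return a [ConstellationGraph].
#' @export
buildConstellation <- function(fractions, embedding_2d, types,
                               edge_threshold = 0.05, k_neighbors = 15) {
  if (edge_threshold <= 0 || edge_threshold >= 1)
    stop("edge_threshold must lie in (0, 1)")
  types <- factor(types, levels = rownames(fractions))
  stopifnot(!anyNA(types), nrow(embedding_2d) == length(types))
  lv <- levels(types)
  cx <- tapply(embedding_2d[, 1], types, mean)
  cy <- tapply(embedding_2d[, 2], types, mean)
  nn <- as.vector(table(types))
  nodes <- S4Vectors::DataFrame(type = lv, centroid_x = as.numeric(cx),
                                centroid_y = as.numeric(cy),
                                n_nuclei = nn, area = log(nn))
  off <- fractions
  diag(off) <- 0
  gmax <- max(off)
  from <- character(); to <- character()
  f_from <- numeric(); f_to <- numeric()
  for (a in seq_along(lv)) for (b in seq_along(lv)) {
    if (b <= a) next
    if (max(fractions[a, b], fractions[b, a]) > edge_threshold) {
      from <- c(from, lv[a]); to <- c(to, lv[b])
      f_from <- c(f_from, fractions[a, b]); f_to <- c(f_to, fractions[b, a])
    }
  }
  wid <- function(f) if (gmax > 0) pmin(f / gmax, 1) else rep(0, length(f))
  edges <- S4Vectors::DataFrame(from = from, to = to,
                                fraction_from = f_from, fraction_to = f_to,
                                width_from = wid(f_from), width_to = wid(f_to))
  new("ConstellationGraph", nodes = nodes, fractions = fractions,
      edges = edges, k_neighbors = as.integer(k_neighbors),
      edge_threshold = edge_threshold)
}

#' Per-nucleus KNN heterogeneity score
#'
#' Average Euclidean distance to the `k` nearest neighbours (self
#' excluded) in the reduced space — by convention a 100-dimensional PC
#' space — standardized over all nuclei to a Z-score. Nuclei in locally
#' heterogeneous neighbourhoods get high scores.
#'
#' @param coords nuclei x components matrix.
#' @param k neighbours (default 15); needs at least `k + 1` nuclei.
#' @return `data.frame` with `mean_knn_dist` and `z_score`; z-scores have
#'   sample mean 0 and sample SD 1.
#' @export
computeHeterogeneity <- function(coords, k = 15) {
  n <- nrow(coords)
  if (n < k + 1) stop("need at least k + 1 nuclei")
  nn <- RANN::nn2(coords, k = k + 1L)
  d <- vapply(seq_len(n), function(i) {
    di <- nn$nn.dists[i, ][nn$nn.idx[i, ] != i]
    mean(di[seq_len(k)])
  }, numeric(1))
  s <- stats::sd(d)
  if (s == 0) stop("degenerate data: zero variance of neighbour distances")
  data.frame(mean_knn_dist = d, z_score = (d - mean(d)) / s,
             row.names = rownames(coords))
}

#' Export a constellation graph
#'
#' @param x a [ConstellationGraph].
#' @param file output path; format by extension (`.graphml` or `.json`).
#' @export
exportConstellation <- function(x, file) {
  nodes <- as.data.frame(x@nodes)
  edges <- as.data.frame(x@edges)
  if (grepl("\\.graphml$", file)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, file, format = "graphml")
  } else {
    jsonlite::write_json(list(nodes = nodes, edges = edges,
                              k_neighbors = x@k_neighbors,
                              edge_threshold = x@edge_threshold),
                         file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
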