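# Normalization -> variable genes -> scaling -> PCA -> graph clustering
# -> 2D embedding, the sequence iterated when building the taxonomy.

#' Library-size normalize, select variable genes and scale
#'
#' Counts are scaled per nucleus to `scale_factor` total and
#' log1p-transformed. Variable genes are ranked by variance-stabilized
#' dispersion: a loess fit of log10 variance on log10 mean of the raw
#' counts predicts the expected standard deviation per gene; counts are
#' standardized against it (clipped at `sqrt(n)`) and genes are ranked by
#' the variance of the standardized values. The selected genes are then
#' centred and scaled to unit variance (values clipped at `scale_max`).
#'
#' @param spe an [SPNExperiment] (QC-filtered) or a counts matrix.
#' @param n_variable number of variable genes to select (default 2000;
#'   clamped with a warning if it exceeds the gene count).
#' @param scale_factor per-nucleus library target (default 10000).
#' @param scale_max clip for scaled values (default 10).
#' @return list with `norm` (sparse genes x nuclei log-normalized
#'   matrix), `var_genes` (character), `scaled` (dense var-genes x
#'   nuclei matrix), `dispersion` (per-gene standardized variance).
#' @export
normalizeSelectScale <- function(spe, n_variable = 2000, scale_factor = 1e4,
                                 scale_max = 10) {
  counts <- if (is(spe, "SummarizedExperiment"))
    SummarizedExperiment::assay(spe, "counts") else spe
  counts <- as(counts, "CsparseMatrix")
  if (n_variable > nrow(counts)) {
    warning("n_variable exceeds gene count; clamping")
    n_variable <- nrow(counts)
  }
  libsize <- Matrix::colSums(counts)
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / pmax(libsize, 1))
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)

  disp <- .vstDispersion(counts)
  var_genes <- names(sort(disp, decreasing = TRUE))[seq_len(n_variable)]

  x <- as.matrix(norm[var_genes, , drop = FALSE])
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  sd[sd == 0] <- 1
  scaled <- (x - mu) / sd
  scaled[scaled > scale_max] <- scale_max
  scaled[scaled < -scale_max] <- -scale_max
  list(norm = norm, var_genes = var_genes, scaled = scaled, dispersion = disp)
}

# standardized variance after a loess mean-variance trend fit on raw
# counts; constant genes get dispersion 0 so they are never selected
.vstDispersion <- function(counts, loess_span = 0.3) {
  n <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  ex2 <- Matrix::rowMeans(counts^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- stats::setNames(numeric(nrow(counts)), rownames(counts))
  ok <- v > 0 & mu > 0
  if (sum(ok) < 10) { disp[ok] <- v[ok]; return(disp) }
  fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span,
                      degree = 2)
  exp_sd <- sqrt(10^fit$fitted)
  clip <- sqrt(n)
  # variance of clipped standardized counts, computed sparsely:
  # contribution of implicit zeros is (0 - mu)/sd per cell
  cs <- counts[ok, , drop = FALSE]
  mu_ok <- mu[ok]
  z0 <- pmax(pmin((0 - mu_ok) / exp_sd, clip), -clip)
  sumz <- z0 * n
  sumz2 <- z0^2 * n
  idx <- Matrix::which(cs != 0, arr.ind = TRUE)
  zi <- pmax(pmin((cs[idx] - mu_ok[idx[, 1]]) / exp_sd[idx[, 1]], clip), -clip)
  sumz <- sumz + tapply(zi - z0[idx[, 1]], factor(idx[, 1], levels = seq_len(nrow(cs))), sum, default = 0)
  sumz2 <- sumz2 + tapply(zi^2 - z0[idx[, 1]]^2, factor(idx[, 1], levels = seq_len(nrow(cs))), sum, default = 0)
  disp[ok] <- (sumz2 - sumz^2 / n) / (n - 1)
  disp
}

#' Principal-component reduction
#'
#' Top principal components of the scaled matrix (nuclei are
#' observations). Component signs are canonicalized so the loading of
#' largest magnitude is positive, making results deterministic across
#' runs and solvers.
#'
#' @param scaled var-genes x nuclei scaled matrix (as from
#'   [normalizeSelectScale()]).
#' @param n_components number of components (default 30; 100 is used for
#'   heterogeneity scoring). Reduced with a warning if the matrix rank
#'   cannot support it.
#' @param seed RNG seed for the iterative solver.
#' @return list with `coords` (nuclei x k), `rotation` (genes x k),
#'   `sdev`, `var_explained`.
#' @export
reduceDimensions <- function(scaled, n_components = 30, seed = 42L) {
  x <- t(scaled)                       # nuclei x genes
  maxk <- min(dim(x)) - 1L
  if (n_components > maxk) {
    warning("rank supports only ", maxk, " components; reducing")
    n_components <- maxk
  }
  xc <- sweep(x, 2, colMeans(x))
  set.seed(seed)
  pc <- if (n_components < maxk / 3 && min(dim(x)) > 200) {
    sv <- irlba::irlba(xc, nv = n_components)
    list(x = sv$u %*% diag(sv$d, n_components), rotation = sv$v, d = sv$d)
  } else {
    sv <- svd(xc, nu = n_components, nv = n_components)
    list(x = sv$u %*% diag(sv$d[seq_len(n_components)], n_components),
         rotation = sv$v, d = sv$d[seq_len(n_components)])
  }
  # sign canonicalization
  for (j in seq_len(n_components)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  sdev <- pc$d / sqrt(nrow(x) - 1)
  total_var <- sum(apply(x, 2, stats::var))
  coords <- pc$x
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coords = coords, rotation = pc$rotation, sdev = sdev,
       var_explained = sdev^2 / total_var)
}

#' Multi-resolution graph clustering
#'
#' Builds a shared-nearest-neighbor graph (Jaccard weights over
#' `k_neighbors` KNN lists, pruned below 1/15) in PC space and runs
#' modularity community detection at each resolution. Default algorithm
#' is Leiden; Louvain is available. Cluster ids are dense per resolution
#' and relabelled by decreasing size.
#'
#' @param coords nuclei x components embedding (from
#'   [reduceDimensions()]).
#' @param k_neighbors KNN list length (default 15); must be < nuclei.
#' @param resolutions numeric vector (default `c(0.5, 1, 2, 3)`).
#' @param algorithm `"leiden"` (default) or `"louvain"`.
#' @param seed RNG seed.
#' @return named list of factors, one per resolution.
#' @export
clusterMultiresolution <- function(coords, k_neighbors = 15,
                                   resolutions = c(0.5, 1, 2, 3),
                                   algorithm = c("leiden", "louvain"),
                                   seed = 42L) {
  algorithm <- match.arg(algorithm)
  n <- nrow(coords)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of nuclei")
  g <- .snnGraph(coords, k_neighbors)
  out <- lapply(resolutions, function(r) {
    set.seed(seed)
    cl <- if (algorithm == "leiden")
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = r, n_iterations = 10)
    else igraph::cluster_louvain(g, resolution = r)
    mem <- igraph::membership(cl)
    sizes <- sort(table(mem), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes), names(sizes))
    factor(relab[as.character(mem)], levels = seq_along(sizes))
  })
  names(out) <- paste0("res.", resolutions)
  out
}

.snnGraph <- function(coords, k, prune = 1 / 15) {
  n <- nrow(coords)
  nn <- RANN::nn2(coords, k = min(k + 1L, n))$nn.idx
  # drop self from each row
  nn <- t(vapply(seq_len(n), function(i) {
    row <- nn[i, ]
    row <- row[row != i]
    row[seq_len(k)]
  }, integer(k)))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
}

#' 2D embedding for visualization
#'
#' UMAP of the PC coordinates, seed-deterministic (single-threaded SGD).
#' Used only for plotting and constellation node placement; all
#' quantitative neighbour computations stay in PC space.
#'
#' @param coords nuclei x components matrix.
#' @param seed RNG seed.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return nuclei x 2 coordinate matrix.
#' @export
embed2D <- function(coords, seed = 42L, n_neighbors = 30, min_dist = 0.3) {
  set.seed(seed)
  um <- uwot::umap(coords, n_neighbors = min(n_neighbors, nrow(coords) - 1),
                   min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
                   batch = TRUE)
  rownames(um) <- rownames(coords)
  colnames(um) <- c("UMAP1", "UMAP2")
  um
}

#' Flag clusters co-expressing incompatible marker sets
#'
#' A cluster is flagged as a putative doublet cluster when its mean
#' detection fraction exceeds `threshold` in two or more mutually
#' exclusive marker sets (for example neuronal and glial markers).
#'
#' @param norm log-normalized genes x nuclei matrix.
#' @param clusters cluster assignment.
#' @param marker_sets named list of >= 2 disjoint character vectors.
#' @param threshold detection-fraction threshold (default 0.5).
#' @return `data.frame` per cluster with one detection column per set and
#'   a logical `flagged` column.
#' @export
flagDoubletClusters <- function(norm, clusters, marker_sets, threshold = 0.5) {
  if (length(marker_sets) < 2) stop("need at least two marker sets")
  all_genes <- unlist(marker_sets)
  if (anyDuplicated(all_genes)) stop("marker sets must be disjoint")
  clusters <- as.factor(clusters)
  det <- sapply(marker_sets, function(gs) {
    gs <- intersect(gs, rownames(norm))
    d <- as.matrix(norm[gs, , drop = FALSE] > 0)
    # mean over set genes of per-gene within-cluster detection fraction
    sapply(levels(clusters), function(cl)
      mean(rowMeans(d[, clusters == cl, drop = FALSE])))
  })
  det <- matrix(det, nrow = nlevels(clusters),
                dimnames = list(levels(clusters), names(marker_sets)))
  out <- data.frame(cluster = levels(clusters), det,
                    flagged = rowSums(det > threshold) >= 2,
                    row.names = NULL, check.names = FALSE)
  out
}
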