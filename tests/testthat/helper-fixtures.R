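# Shared fixtures, built in code and cached for the duration of a run.

.fixture_env <- new.env(parent = emptyenv())

# small atlas for unit tests: 6 types x 120 nuclei, 800 genes
smallAtlas <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generateCountMatrix(
      AtlasSimConfig(n_types = 6, nuclei_per_type = 120, n_genes = 800,
                     n_marker_genes_per_type = 30, seed = 7L))
  }
  .fixture_env$small
}

# its clustering pipeline (no UMAP; cached)
smallPipeline <- function() {
  if (is.null(.fixture_env$small_pipe)) {
    sim <- smallAtlas()
    .fixture_env$small_pipe <- runAtlasPipeline(sim$spe, n_variable = 500,
                                                seed = 11L, umap = FALSE)
  }
  .fixture_env$small_pipe
}

# build a tiny SPNExperiment from an explicit dense count matrix
tinySPN <- function(counts, xfp = rep(0L, ncol(counts)),
                    channel = rep("GFP", ncol(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("n%03d", seq_len(ncol(counts)))
  SPNExperiment(counts, roi_label = rep("MB", ncol(counts)),
                sort_channel = channel, xfp_count = xfp)
}

# brute-force KNN neighbour-fraction oracle: all-pairs distances
bruteFractions <- function(coords, types, k) {
  types <- as.factor(types)
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  tab <- matrix(0, nlevels(types), nlevels(types),
                dimnames = list(levels(types), levels(types)))
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    for (j in nb) tab[types[i], types[j]] <- tab[types[i], types[j]] + 1
  }
  tab / rowSums(tab)
}

# brute-force average-linkage agglomeration (O(n^3)) used as tree oracle
bruteAverageLinkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  cl_d <- d
  while (length(active) > 1) {
    m <- Inf; pair <- NULL
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (j <= i) next
      dij <- mean(d[active[[i]], active[[j]]])
      if (dij < m) { m <- dij; pair <- c(i, j) }
    }
    heights <- c(heights, m)
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    active <- c(active[-pair], list(merged))
  }
  heights
}
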