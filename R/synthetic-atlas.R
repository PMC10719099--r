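#' Simulate a labelled count matrix with planted type structure
#'
#' Draws a gene-by-nucleus count matrix from a negative-binomial model with
#' gene-specific means and shared dispersion. Each planted type
#' up-regulates its own disjoint marker set by `marker_logfc` (natural
#' log). Thirteen mitochondrial genes (named with the mouse `mt-` prefix)
#' carry on average `mito_frac_mean` of each library. Per-nucleus XFP
#' transcript counts follow a zero-inflated Poisson whose detection rate
#' depends on the planted first-/second-order status of the nucleus' type:
#' second-order types (the last `ceiling(frac_second_order_types * n_types)`
#' types) use `xfp_rate_second_order`, all others
#' `xfp_rate_first_order`. A nucleus drawn positive always carries at
#' least one transcript, so the expected XFP-positive fraction of a type
#' equals its rate exactly.
#'
#' @param cfg an [AtlasSimConfig].
#' @return a list with elements
#'   \describe{
#'     \item{spe}{[SPNExperiment] with `true_type` and `true_order` in
#'       `colData`.}
#'     \item{truth}{list: `type` (factor per nucleus), `type_order`
#'       (named character per type, `"first"`/`"second"`),
#'       `marker_genes` (named list of marker ids per type), `config`.}
#'   }
#' @examples
#' sim <- generateCountMatrix(AtlasSimConfig(n_types = 3, nuclei_per_type = 50,
#'                                           n_genes = 200))
#' table(sim$truth$type)
#' @export
generateCountMatrix <- function(cfg) {
  stopifnot(is(cfg, "AtlasSimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)

  nt <- cfg@n_types
  npc <- cfg@nuclei_per_type
  ng <- cfg@n_genes
  n <- nt * npc
  mito_names <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6",
                                "Co3", "Nd3", "Nd4l", "Nd4", "Nd5", "Nd6",
                                "Cytb"))
  gene_ids <- c(sprintf("gene-%05d", seq_len(ng)), mito_names)

  # gene abundance profile: lognormal, scaled so mito genes carry
  # mito_frac_mean of the expected library
  base <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.5)
  base <- base / sum(base) * (1 - cfg@mito_frac_mean)
  mito_base <- stats::rlnorm(13, meanlog = 0, sdlog = 0.3)
  mito_base <- mito_base / sum(mito_base) * cfg@mito_frac_mean
  p_gene <- c(base, mito_base)

  m <- cfg@n_marker_genes_per_type
  marker_genes <- lapply(seq_len(nt), function(t)
    gene_ids[((t - 1L) * m + 1L):(t * m)])
  names(marker_genes) <- sprintf("type-%02d", seq_len(nt))

  n_second <- if (cfg@frac_second_order_types > 0)
    ceiling(cfg@frac_second_order_types * nt) else 0L
  type_order <- rep("first", nt)
  if (n_second > 0) type_order[(nt - n_second + 1L):nt] <- "second"
  names(type_order) <- names(marker_genes)

  type <- factor(rep(names(marker_genes), each = npc),
                 levels = names(marker_genes))
  libsize <- stats::rlnorm(n, meanlog = log(cfg@library_size_mean) - 0.045,
                           sdlog = 0.3)

  fc <- exp(cfg@marker_logfc)
  counts <- matrix(0L, nrow = length(gene_ids), ncol = n)
  for (t in seq_len(nt)) {
    idx <- ((t - 1L) * m + 1L):(t * m)
    p <- p_gene
    p[idx] <- p[idx] * fc
    p <- p / sum(p)
    cols <- which(as.integer(type) == t)
    mu <- outer(p, libsize[cols])
    counts[, cols] <- stats::rnbinom(length(mu), size = 2, mu = mu)
  }
  dimnames(counts) <- list(gene_ids, sprintf("nucleus-%05d", seq_len(n)))

  rate <- ifelse(type_order[as.integer(type)] == "first",
                 cfg@xfp_rate_first_order, cfg@xfp_rate_second_order)
  xfp <- stats::rbinom(n, 1L, rate) * (1L + stats::rpois(n, 2))

  rois <- c("RFA", "M1M2S1", "S2", "HY", "MB", "CB", "PONS", "MED")
  roi_by_type <- rois[((seq_len(nt) - 1L) %% length(rois)) + 1L]
  channel <- sample(c("GFP", "mScarlet", "dual"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))

  spe <- SPNExperiment(Matrix::Matrix(counts, sparse = TRUE),
                       roi_label = roi_by_type[as.integer(type)],
                       sort_channel = channel, xfp_count = xfp,
                       extra_coldata = S4Vectors::DataFrame(
                         true_type = type,
                         true_order = type_order[as.integer(type)]))
  list(spe = spe,
       truth = list(type = type, type_order = type_order,
                    marker_genes = marker_genes, config = cfg))
}
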