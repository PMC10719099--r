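# Quality-control gating and first-/second-order cluster classification
# from XFP (fluorophore) transcript detection.

#' Quality-control thresholds
#'
#' @param max_mito_fraction nuclei must have mitochondrial fraction
#'   strictly below this (default 0.05).
#' @param min_genes nuclei must have strictly more genes detected than
#'   this (default 2000).
#' @param xfp_cluster_cutoff clusters with an XFP-positive fraction
#'   strictly below this are called second-order (default 0.10).
#' @return a validated `QCThresholds` list.
#' @export
QCThresholds <- function(max_mito_fraction = 0.05, min_genes = 2000,
                         xfp_cluster_cutoff = 0.10) {
  stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_genes >= 0,
            xfp_cluster_cutoff > 0, xfp_cluster_cutoff < 1)
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes = as.integer(min_genes),
                 xfp_cluster_cutoff = xfp_cluster_cutoff),
            class = "QCThresholds")
}

#' Filter nuclei on mitochondrial fraction and genes detected
#'
#' Keeps nuclei with `mito_fraction < max_mito_fraction` AND
#' `genes_detected > min_genes` — both strict, so a nucleus sitting
#' exactly on either boundary is removed.
#'
#' @param spe an [SPNExperiment].
#' @param thresholds a [QCThresholds()] list.
#' @return list with `spe` (the filtered object) and `report`, a one-row
#'   `data.frame` of per-reason removal counts (`removed_mito`,
#'   `removed_genes` count every nucleus failing that gate, so a nucleus
#'   failing both is counted in each and once in `removed_both`).
#' @export
applyQCFilter <- function(spe, thresholds = QCThresholds()) {
  stopifnot(is(spe, "SPNExperiment"), inherits(thresholds, "QCThresholds"))
  cd <- SummarizedExperiment::colData(spe)
  if (anyNA(cd$mito_fraction) || anyNA(cd$genes_detected))
    stop("metadata incomplete: NA in mito_fraction or genes_detected")
  fail_mito <- !(cd$mito_fraction < thresholds$max_mito_fraction)
  fail_genes <- !(cd$genes_detected > thresholds$min_genes)
  keep <- !fail_mito & !fail_genes
  report <- data.frame(n_input = ncol(spe),
                       removed_mito = sum(fail_mito),
                       removed_genes = sum(fail_genes),
                       removed_both = sum(fail_mito & fail_genes),
                       n_kept = sum(keep))
  if (!any(keep)) warning("QC filter removed every nucleus")
  list(spe = spe[, keep], report = report)
}

#' Flag XFP-positive nuclei
#'
#' A nucleus is XFP-positive if it carries at least one GFP or mScarlet
#' transcript in the raw (pre-cleanup) count matrix; the raw XFP count is
#' carried in `colData(spe)$xfp_count`.
#'
#' @param spe an [SPNExperiment].
#' @return named logical vector, one flag per nucleus.
#' @export
callXFPPositive <- function(spe) {
  stopifnot(is(spe, "SPNExperiment"))
  xfp <- SummarizedExperiment::colData(spe)$xfp_count
  if (anyNA(xfp))
    stop("missing xfp_count for nucleus: ",
         paste(head(colnames(spe)[is.na(xfp)], 5), collapse = ", "))
  stats::setNames(xfp >= 1L, colnames(spe))
}

#' Classify clusters as first- or second-order labelled
#'
#' Computes the XFP-positive fraction per cluster and calls a cluster
#' second-order when that fraction is strictly below
#' `xfp_cluster_cutoff` (a cluster at exactly the cutoff is first-order).
#' Clusters listed in `overrides` are kept first-order regardless of
#' their fraction — this mirrors curation of populations with external
#' evidence of direct projection — and require a justification string,
#' which is recorded on the result.
#'
#' @param flags logical XFP-positive flags, as from [callXFPPositive()].
#' @param clusters cluster assignment (factor or vector), same length.
#' @param thresholds a [QCThresholds()] list.
#' @param overrides character vector of cluster ids to keep first-order.
#' @param justification character; required when `overrides` is non-empty.
#' @return `data.frame` with `cluster_id`, `n_nuclei`, `n_xfp_pos`,
#'   `xfp_fraction`, `order` (`"first"`/`"second"`) and
#'   `override_applied`; the justification is attached as attribute
#'   `"override_justification"`.
#' @export
classifyClusterOrder <- function(flags, clusters, thresholds = QCThresholds(),
                                 overrides = character(),
                                 justification = NULL) {
  stopifnot(length(flags) == length(clusters))
  clusters <- as.factor(clusters)
  if (any(table(clusters) == 0L))
    stop("empty cluster: ",
         paste(names(which(table(clusters) == 0L)), collapse = ", "))
  if (length(overrides) && is.null(justification))
    stop("overrides require a justification string")
  n <- as.vector(table(clusters))
  npos <- as.vector(tapply(flags, clusters, sum))
  frac <- npos / n
  ids <- levels(clusters)
  ov <- ids %in% overrides
  order <- ifelse(frac < thresholds$xfp_cluster_cutoff & !ov,
                  "second", "first")
  out <- data.frame(cluster_id = ids, n_nuclei = n, n_xfp_pos = npos,
                    xfp_fraction = frac, order = order,
                    override_applied = ov & frac < thresholds$xfp_cluster_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "override_justification") <- justification
  out
}

#' Pool region-of-interest labels before order classification
#'
#' Some bordering dissections are analysed together (for example PONS and
#' MED pooled as hindbrain); the mapping is explicit configuration, not
#' inferred.
#'
#' @param roi character vector of dissection labels.
#' @param mapping named character vector, `old = new`.
#' @return character vector with mapped labels.
#' @export
poolROIs <- function(roi, mapping = c(PONS = "hindbrain", MED = "hindbrain")) {
  hit <- roi %in% names(mapping)
  roi[hit] <- unname(mapping[roi[hit]])
  roi
}

#' Drop nuclei belonging to second-order clusters
#'
#' @param spe an [SPNExperiment].
#' @param calls result of [classifyClusterOrder()].
#' @param clusters the cluster assignment used for the calls.
#' @return the filtered [SPNExperiment].
#' @export
removeSecondOrder <- function(spe, calls, clusters) {
  second <- calls$cluster_id[calls$order == "second"]
  spe[, !(as.character(clusters) %in% second)]
}
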