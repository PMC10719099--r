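# Gated differential expression, one-vs-rest marker calling and
# projection-target / region proportion tables.

#' Two-group differential expression with detection and fold-change gates
#'
#' Genes are tested only if (a) they are detected in at least `min_pct`
#' of the nuclei of at least one group, and (b) the absolute natural-log
#' fold change (computed on log1p-normalized means with a pseudo-count of
#' 1) is at least `logfc_threshold`. The default test is a two-part
#' hurdle: a z-test on detection proportions combined with a Wilcoxon
#' rank-sum z on the detected (positive) values via Stouffer's method;
#' a plain Wilcoxon on all values is available. Benjamini-Hochberg
#' correction is applied over tested genes only; `significant` requires
#' adjusted p < `alpha` and the gates.
#'
#' @param norm log-normalized genes x nuclei matrix.
#' @param group1,group2 disjoint, non-empty column selections (names or
#'   indices).
#' @param min_pct detection gate (default 0.25).
#' @param logfc_threshold fold-change gate in natural-log units
#'   (default 0.25).
#' @param test `"hurdle"` (default) or `"wilcox"`.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return `data.frame` per gene: `gene`, `log_fold_change`, `pct_group1`,
#'   `pct_group2`, `tested`, `p_value`, `p_adjusted`, `significant`.
#'   Untested genes keep NA p-values.
#' @export
differentialExpression <- function(norm, group1, group2, min_pct = 0.25,
                                   logfc_threshold = 0.25,
                                   test = c("hurdle", "wilcox"),
                                   alpha = 0.05) {
  test <- match.arg(test)
  i1 <- .resolveCols(norm, group1)
  i2 <- .resolveCols(norm, group2)
  if (!length(i1) || !length(i2)) stop("both groups must be non-empty")
  if (length(intersect(i1, i2))) stop("groups overlap")
  x1 <- as.matrix(norm[, i1, drop = FALSE])
  x2 <- as.matrix(norm[, i2, drop = FALSE])
  n1 <- ncol(x1); n2 <- ncol(x2)
  pct1 <- rowMeans(x1 > 0); pct2 <- rowMeans(x2 > 0)
  lfc <- log(rowMeans(expm1(x1)) + 1) - log(rowMeans(expm1(x2)) + 1)
  tested <- (pct1 >= min_pct | pct2 >= min_pct) & abs(lfc) >= logfc_threshold
  p <- rep(NA_real_, nrow(norm))
  for (g in which(tested)) {
    p[g] <- if (test == "hurdle") .hurdleP(x1[g, ], x2[g, ])
            else .wilcoxP(x1[g, ], x2[g, ])
  }
  padj <- rep(NA_real_, nrow(norm))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(gene = rownames(norm), log_fold_change = lfc,
             pct_group1 = pct1, pct_group2 = pct2, tested = tested,
             p_value = p, p_adjusted = padj,
             significant = tested & !is.na(padj) & padj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

.resolveCols <- function(norm, g) {
  if (is.character(g)) match(g, colnames(norm)) else as.integer(g)
}

# signed z for a two-sample Wilcoxon rank-sum with tie correction;
# positive when a tends to exceed b
.wilcoxZ <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
          sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(0)
  (w - mu) / sqrt(sig2)
}

.wilcoxP <- function(a, b) {
  z <- .wilcoxZ(a, b)
  2 * stats::pnorm(-abs(z))
}

# two-proportion z on detection; positive when a is detected more
.detectionZ <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  p1 <- mean(a > 0); p2 <- mean(b > 0)
  pp <- (sum(a > 0) + sum(b > 0)) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(0)
  (p1 - p2) / se
}

# Stouffer combination of the detection z and the positive-part rank z;
# falls back to detection alone when either group has too few positives
.hurdleP <- function(a, b) {
  zd <- .detectionZ(a, b)
  ap <- a[a > 0]; bp <- b[b > 0]
  if (length(ap) < 3 || length(bp) < 3) {
    z <- zd
  } else {
    z <- (zd + .wilcoxZ(ap, bp)) / sqrt(2)
  }
  if (z == 0 && stats::sd(c(a, b)) == 0) return(1)
  2 * stats::pnorm(-abs(z))
}

#' One-vs-rest marker genes for every type
#'
#' Runs [differentialExpression()] for each type against all other
#' nuclei; BH correction is applied within each comparison separately.
#' Singleton types are skipped with a warning.
#'
#' @param norm log-normalized genes x nuclei matrix.
#' @param types type assignment per nucleus (>= 2 types).
#' @param ... gates and test passed to [differentialExpression()].
#' @return `data.frame` of concatenated results with a leading `type`
#'   column.
#' @export
findAllMarkers <- function(norm, types, ...) {
  types <- as.factor(types)
  if (nlevels(types) < 2) stop("need at least two types")
  out <- lapply(levels(types), function(tp) {
    idx <- which(types == tp)
    if (length(idx) < 2) {
      warning("singleton type skipped: ", tp)
      return(NULL)
    }
    de <- differentialExpression(norm, idx, which(types != tp), ...)
    cbind(type = tp, de)
  })
  do.call(rbind, out)
}

#' Per-type projection-target proportions
#'
#' Tabulates cervical- (GFP), dual- (GFP+/mScarlet+) and lumbar-
#' (mScarlet) projecting nuclei per type. Both groupings of the
#' non-cervical classes are emitted: separate dual and lumbar
#' proportions, and pooled `dual_or_lumbar`.
#'
#' @param sort_channel character vector in `{"GFP","mScarlet","dual"}`.
#' @param types type assignment per nucleus.
#' @return `data.frame` per type: counts `n_cervical`, `n_dual`,
#'   `n_lumbar`; proportions `p_cervical`, `p_dual`, `p_lumbar`,
#'   `p_dual_or_lumbar`. Proportions sum to 1 per type.
#' @export
projectionProportions <- function(sort_channel, types) {
  if (!length(sort_channel)) stop("empty sort channel")
  bad <- !sort_channel %in% c("GFP", "mScarlet", "dual")
  if (any(bad))
    stop("unknown sort channel label(s): ",
         paste(unique(sort_channel[bad]), collapse = ", "))
  types <- as.factor(types)
  tab <- table(types, factor(sort_channel,
                             levels = c("GFP", "dual", "mScarlet")))
  n <- rowSums(tab)
  data.frame(type = levels(types),
             n_cervical = as.vector(tab[, "GFP"]),
             n_dual = as.vector(tab[, "dual"]),
             n_lumbar = as.vector(tab[, "mScarlet"]),
             p_cervical = as.vector(tab[, "GFP"]) / n,
             p_dual = as.vector(tab[, "dual"]) / n,
             p_lumbar = as.vector(tab[, "mScarlet"]) / n,
             p_dual_or_lumbar = as.vector(tab[, "dual"] + tab[, "mScarlet"]) / n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scale per-region counts quantified from one of several series
#'
#' When only one of `series_multiplier` section series is quantified,
#' raw region counts are multiplied up to whole-brain totals and
#' expressed as percentages of the brain-wide total.
#'
#' @param region_counts named non-negative numeric vector.
#' @param series_multiplier sections series factor (default 4; >= 1).
#' @return `data.frame` with `region`, `raw_count`, `scaled_total`,
#'   `percent` (sums to 100).
#' @export
scaleSeriesCounts <- function(region_counts, series_multiplier = 4) {
  if (series_multiplier < 1) stop("series_multiplier must be >= 1")
  if (any(region_counts < 0)) stop("negative region counts")
  scaled <- region_counts * series_multiplier
  data.frame(region = names(region_counts),
             raw_count = as.numeric(region_counts),
             scaled_total = as.numeric(scaled),
             percent = as.numeric(100 * scaled / sum(scaled)),
             row.names = NULL, stringsAsFactors = FALSE)
}
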