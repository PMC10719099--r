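#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index, used to score recovered clusters
#' against planted type labels.
#'
#' @param a,b two partitions of the same objects.
#' @return ARI in \[-1, 1\]; 1 means identical partitions up to labels.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_idx <- si * sj / choose(n, 2)
  max_idx <- (si + sj) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}
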