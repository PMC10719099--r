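# Axon-density contours from 8-bit images and mask-based
# colocalization / soma-size calls. Images are numeric matrices with
# values in [0, 255].

#' Top-hat background subtraction
#'
#' Subtracts the morphological opening of the image (disk structuring
#' element of the given radius) from the image itself, removing smooth
#' background while preserving structures smaller than the element.
#' Output is clipped to \[0, 255\] and rounded.
#'
#' @param img numeric matrix, values in \[0, 255\].
#' @param radius disk radius in pixels (>= 1, < min(dim)/2).
#' @return integer matrix of the same size.
#' @export
subtractBackground <- function(img, radius = 15) {
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= min(dim(img)) / 2)
    stop("structuring element does not fit in the image")
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  opened <- EBImage::opening(img / 255, brush) * 255
  out <- pmin(255, pmax(0, round(img - opened)))
  matrix(as.integer(out), nrow(img), ncol(img))
}

#' Binarize and remove small components
#'
#' Pixels strictly above `threshold` are kept; connected components with
#' `min_component_pixels` or fewer... precisely: only components with
#' strictly more than `min_component_pixels - 1` pixels survive, i.e.
#' with the defaults only signals of more than two connected pixels are
#' kept. Connectivity is 8 (diagonals connect) by default, 4 optionally.
#'
#' @param img numeric matrix in \[0, 255\].
#' @param threshold strict intensity threshold (default 120).
#' @param min_component_pixels minimum surviving component size
#'   (default 3).
#' @param connectivity 8 (default) or 4.
#' @return logical matrix.
#' @export
binarizeAndClean <- function(img, threshold = 120, min_component_pixels = 3,
                             connectivity = 8) {
  mask <- img > threshold
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_pixels)
  matrix(lab %in% keep, nrow(img), ncol(img))
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation over the 4- or 8-neighbourhood
#' until a fixed point, then densification of the surviving labels.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix; 0 is background, components numbered from 1.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  pad <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    okr <- rs >= 1 & rs <= h; okc <- cs >= 1 & cs <= w
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  repeat {
    nb <- lab
    for (s in shifts) {
      sh <- pad(lab, s[1], s[2])
      upd <- mask & sh > 0L & (nb == 0L | sh < nb)
      nb[upd] <- sh[upd]
    }
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Bin a mask and smooth the counts
#'
#' Above-threshold pixels are counted in `bin_px` x `bin_px` bins
#' (partial edge bins included, so the grid total equals the mask total
#' exactly). Smoothing is a normalized moving average: by the default
#' pixel interpretation the window spans `smooth_px` pixels (5 x 5 bins
#' with the defaults); the alternative bin interpretation uses a
#' `smooth_window` x `smooth_window` window of bins. Edge bins are
#' padded by reflection.
#'
#' @param mask logical matrix.
#' @param bin_px bin edge length (default 20); mask must be at least one
#'   bin wide.
#' @param smooth_px smoothing window in pixels (default 100; pixel
#'   interpretation).
#' @param mode `"pixel"` (default) or `"bin"`.
#' @param smooth_window window in bins for the bin interpretation.
#' @return a [DensityGrid].
#' @export
binAndSmooth <- function(mask, bin_px = 20, smooth_px = 100,
                         mode = c("pixel", "bin"), smooth_window = 100) {
  mode <- match.arg(mode)
  if (min(dim(mask)) < bin_px) stop("mask smaller than one bin")
  h <- nrow(mask); w <- ncol(mask)
  ri <- ceiling(seq_len(h) / bin_px)
  ci <- ceiling(seq_len(w) / bin_px)
  counts <- rowsum(t(rowsum(mask + 0, ri)), ci)
  counts <- t(counts)   # rows follow image rows
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL
  win <- if (mode == "pixel") max(1L, round(smooth_px / bin_px))
         else as.integer(smooth_window)
  smoothed <- .reflectMovingAverage(counts, win)
  new("DensityGrid", bin_counts = counts, smoothed = smoothed,
      bin_px = as.integer(bin_px),
      smooth_px = as.integer(if (mode == "pixel") smooth_px
                             else smooth_window * bin_px))
}

# normalized win x win moving average with symmetric (reflection)
# padding; separable box filter via cumulative sums
.reflectMovingAverage <- function(m, win) {
  if (win <= 1L) return(m)
  win <- min(win, 2L * min(dim(m)) - 1L)
  half <- (win - 1L) %/% 2L
  h2 <- win - 1L - half
  padIdx <- function(n) c(rev(seq_len(half)), seq_len(n),
                          seq(n, by = -1L, length.out = h2))
  boxPass <- function(P) {   # along rows; nrow(P) = n + win - 1
    C <- rbind(0, apply(P, 2, cumsum))
    (C[(win + 1L):nrow(C), , drop = FALSE] -
       C[seq_len(nrow(C) - win), , drop = FALSE]) / win
  }
  out <- boxPass(m[padIdx(nrow(m)), , drop = FALSE])
  out <- t(boxPass(t(out)[padIdx(ncol(m)), , drop = FALSE]))
  unname(out)
}

#' Contours from a smoothed density grid
#'
#' Iso-level polylines at evenly spaced levels between 0 and the grid
#' maximum (exclusive), or at explicit levels, with coordinates in image
#' pixel space (bin centres).
#'
#' @param grid a [DensityGrid].
#' @param n_levels number of evenly spaced levels (default 10).
#' @param levels optional explicit level values.
#' @return list of contours, each with `level`, `x` (column px), `y`
#'   (row px); empty (with a warning) for a flat grid.
#' @export
contourFromDensity <- function(grid, n_levels = 10, levels = NULL) {
  z <- densitySmoothed(grid)
  if (max(z) == min(z)) {
    warning("flat density grid: no contours")
    return(list())
  }
  if (is.null(levels))
    levels <- seq(0, max(z), length.out = n_levels + 2)[-c(1, n_levels + 2)]
  bp <- densityBinPx(grid)
  y <- (seq_len(nrow(z)) - 0.5) * bp
  x <- (seq_len(ncol(z)) - 0.5) * bp
  cl <- grDevices::contourLines(x = y, y = x, z = z, levels = levels)
  lapply(cl, function(ct) list(level = ct$level, y = ct$x, x = ct$y))
}

#' Colocalization and soma-size calls over segmentation masks
#'
#' A pixel is co-intense when both channels strictly exceed their
#' per-channel thresholds (Otsu by default, fixed values optionally). A
#' mask is called positive when at least `min_fraction` (default 0.65,
#' inclusive) of its pixels are co-intense. Soma area is the mask pixel
#' count times the pixel area.
#'
#' @param ch1,ch2 numeric matrices in \[0, 255\].
#' @param masks integer label matrix (0 = background).
#' @param thresholds optional `c(t1, t2)` fixed intensity cutoffs;
#'   default per-channel Otsu.
#' @param min_fraction positive-call fraction (default 0.65).
#' @param pixel_size_um pixel edge length in µm (default 1).
#' @return `data.frame` per mask: `mask_id`, `n_pixels`, `n_co_intense`,
#'   `fraction`, `positive`, `soma_area_px`, `soma_area_um2`.
#' @export
callColocalization <- function(ch1, ch2, masks, thresholds = NULL,
                               min_fraction = 0.65, pixel_size_um = 1) {
  stopifnot(all(dim(ch1) == dim(ch2)), all(dim(ch1) == dim(masks)))
  ids <- sort(unique(masks[masks > 0L]))
  if (!length(ids)) stop("no masks supplied")
  if (is.null(thresholds))
    thresholds <- c(otsuThreshold(ch1), otsuThreshold(ch2))
  co <- ch1 > thresholds[1] & ch2 > thresholds[2]
  out <- lapply(ids, function(id) {
    px <- masks == id
    n <- sum(px)
    if (n == 0L) stop("empty mask: ", id)
    nc <- sum(co[px])
    data.frame(mask_id = id, n_pixels = n, n_co_intense = nc,
               fraction = nc / n, positive = nc / n >= min_fraction,
               soma_area_px = n, soma_area_um2 = n * pixel_size_um^2)
  })
  do.call(rbind, out)
}

#' Otsu intensity threshold for an 8-bit image
#'
#' @param img numeric matrix in \[0, 255\].
#' @return threshold on the 0-255 scale.
#' @export
otsuThreshold <- function(img) {
  EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1), levels = 256) * 255
}
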