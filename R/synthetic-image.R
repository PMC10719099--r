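#' Simulate 8-bit axon/soma images with planted signal
#'
#' Single-channel mode (`two_channel = FALSE`) plants `n_blobs` disk-shaped
#' patches of supra-threshold intensity on a Gaussian noise background
#' (mean 10, sd `background_sd`, clipped to \[0, 255\] and rounded), as a
#' stand-in for axon signal in a spinal-cord section. Two-channel mode
#' plants non-overlapping circular somata, returns an integer label mask
#' per soma, makes channel 1 bright inside every mask, and makes channel 2
#' co-intense in 90% of the pixels of a planted fraction
#' (`coloc_fraction_true`) of masks and in only 30% of the pixels of the
#' rest, so downstream colocalization calls with a 65% rule recover the
#' planted positives.
#'
#' @param cfg an [ImageSimConfig].
#' @param two_channel logical; see Details.
#' @return single-channel: list with `image` (integer matrix, 0-255) and
#'   `blob_mask` (logical matrix of planted pixels). Two-channel: list
#'   with `ch1`, `ch2`, `masks` (integer label matrix, 0 = background)
#'   and `truth` (logical vector: planted colocalization per mask).
#' @export
generateAxonImage <- function(cfg, two_channel = FALSE) {
  stopifnot(is(cfg, "ImageSimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  h <- cfg@height; w <- cfg@width
  bg <- function(mean = 10) {
    m <- matrix(stats::rnorm(h * w, mean, cfg@background_sd), h, w)
    matrix(as.integer(pmin(255, pmax(0, round(m)))), h, w)
  }
  disk <- function(cy, cx, r) {
    rows <- max(1L, cy - r):min(h, cy + r)
    cols <- max(1L, cx - r):min(w, cx + r)
    sub <- expand.grid(row = rows, col = cols)
    sub[(sub$row - cy)^2 + (sub$col - cx)^2 <= r^2, ]
  }

  if (!two_channel) {
    img <- if (cfg@background_sd == 0 && cfg@n_blobs == 0L)
      matrix(0L, h, w) else bg()
    mask <- matrix(FALSE, h, w)
    if (cfg@n_blobs > 0L) {
      for (b in seq_len(cfg@n_blobs)) {
        r <- sample(3:8, 1)
        px <- disk(sample(seq_len(h), 1), sample(seq_len(w), 1), r)
        idx <- cbind(px$row, px$col)
        img[idx] <- as.integer(round(cfg@blob_intensity))
        mask[idx] <- TRUE
      }
    }
    return(list(image = img, blob_mask = mask))
  }

  ch1 <- bg(); ch2 <- bg()
  masks <- matrix(0L, h, w)
  n_masks <- cfg@n_blobs
  r <- 6L
  # place non-overlapping somata on a jittered grid
  grid_step <- 2L * r + 6L
  centers <- expand.grid(
    row = seq(r + 4L, h - r - 4L, by = grid_step),
    col = seq(r + 4L, w - r - 4L, by = grid_step))
  if (nrow(centers) < n_masks)
    stop("image too small for the requested number of masks")
  centers <- centers[sample(nrow(centers), n_masks), , drop = FALSE]
  is_pos <- rep(FALSE, n_masks)
  if (n_masks > 0L) {
    n_pos <- round(cfg@coloc_fraction_true * n_masks)
    is_pos[sample(n_masks, n_pos)] <- TRUE
    for (b in seq_len(n_masks)) {
      px <- disk(centers$row[b], centers$col[b], r)
      idx <- cbind(px$row, px$col)
      masks[idx] <- b
      ch1[idx] <- as.integer(round(cfg@blob_intensity))
      frac <- if (is_pos[b]) 0.9 else 0.3
      on <- seq_len(nrow(idx)) %in% sample(nrow(idx), round(frac * nrow(idx)))
      ch2[idx[on, , drop = FALSE]] <- as.integer(round(cfg@blob_intensity))
    }
  }
  list(ch1 = ch1, ch2 = ch2, masks = masks, truth = is_pos)
}
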