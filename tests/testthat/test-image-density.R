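# brute-force grayscale morphology oracle (min/max filter over a disk)
bruteTopHat <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  filt <- function(m, fun, pad) {
    out <- matrix(NA_real_, h, w)
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      rr <- r + offs$dr; ccs <- cc + offs$dc
      ok <- rr >= 1 & rr <= h & ccs >= 1 & ccs <= w
      vals <- m[cbind(rr[ok], ccs[ok])]
      if (any(!ok)) vals <- c(vals, pad)
      out[r, cc] <- fun(vals)
    }
    out
  }
  er <- filt(img, min, pad = max(img))
  op <- filt(er, max, pad = min(er))
  matrix(pmin(255, pmax(0, round(img - op))), h, w)
}

# brute-force connected components by flood fill
floodLabel <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!mask[r, cc] || lab[r, cc] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r, cc)); lab[r, cc] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(nb))) {
        rr <- p[1] + nb$dr[i]; c2 <- p[2] + nb$dc[i]
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w &&
            mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- cur
          queue <- c(queue, list(c(rr, c2)))
        }
      }
    }
  }
  lab
}

test_that("top-hat subtraction removes smooth background, keeps small peaks", {
  const <- matrix(77, 30, 30)
  expect_true(all(subtractBackground(const, 4) == 0))
  spot <- matrix(0, 30, 30); spot[15, 15] <- 200
  out <- subtractBackground(spot, 5)
  expect_equal(out[15, 15], 200L)
  expect_error(subtractBackground(const, 20), "fit")
  expect_error(subtractBackground(const, 0), ">= 1")
})

test_that("top-hat agrees with a brute-force min/max filter oracle", {
  set.seed(35)
  img <- outer(seq_len(40), seq_len(40), function(r, cc) 2 * r + 1.5 * cc)
  img[18:21, 18:21] <- img[18:21, 18:21] + 150
  img <- matrix(pmin(255, round(img)), 40, 40)
  ours <- subtractBackground(img, 3)
  oracle <- bruteTopHat(img, 3)
  # compare away from the border so padding conventions cannot differ
  core <- 8:33
  expect_equal(ours[core, core], matrix(as.integer(oracle[core, core]),
                                        length(core)), tolerance = 1)
})

test_that("binarization is strict at 120 and keeps only >2-pixel components", {
  img <- matrix(119, 20, 20)
  expect_equal(sum(binarizeAndClean(img)), 0)
  img2 <- matrix(0, 20, 20)
  img2[5, 5:6] <- 200                      # 2-pixel component: removed
  img2[10, 10] <- 200; img2[11, 10] <- 200; img2[11, 11] <- 200  # L-shape
  m <- binarizeAndClean(img2)
  expect_false(any(m[5, ]))
  expect_equal(sum(m), 3)
  expect_true(all(m[cbind(c(10, 11, 11), c(10, 10, 11))]))
})

test_that("component labelling matches flood fill at both connectivities", {
  set.seed(36)
  mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
  for (conn in c(8, 4)) {
    ours <- labelComponents(mask, conn)
    oracle <- floodLabel(mask, conn)
    # same partition: label maps are a bijection
    expect_equal(max(ours), max(oracle))
    expect_true(all((ours > 0) == (oracle > 0)))
    key <- paste(ours[ours > 0], oracle[oracle > 0])
    expect_equal(length(unique(key)), max(ours))
  }
  # diagonal pixels: one component under 8, two under 4
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(max(labelComponents(d, 8)), 1)
  expect_equal(max(labelComponents(d, 4)), 2)
})

test_that("binning conserves pixel counts exactly and smoothing preserves mass", {
  set.seed(37)
  mask <- matrix(runif(200 * 180) < 0.2, 200, 180)
  g <- binAndSmooth(mask, bin_px = 20, smooth_px = 100)
  expect_identical(sum(densityBins(g)), sum(mask))
  # one fully-true bin counts 400 before smoothing
  m2 <- matrix(FALSE, 100, 100); m2[21:40, 41:60] <- TRUE
  g2 <- binAndSmooth(m2)
  expect_equal(densityBins(g2)[2, 3], 400)
  expect_equal(sum(densityBins(g2)), 400L)
  # empty mask -> zero grids
  g0 <- binAndSmooth(matrix(FALSE, 100, 100))
  expect_true(all(densityBins(g0) == 0) && all(densitySmoothed(g0) == 0))
  # normalized kernel preserves interior mass
  big <- matrix(FALSE, 400, 400); big[181:220, 181:220] <- TRUE
  gb <- binAndSmooth(big)
  expect_equal(sum(densitySmoothed(gb)), sum(densityBins(gb)),
               tolerance = 1e-9)
  # the two smoothing interpretations are both available
  ga <- binAndSmooth(mask, mode = "bin", smooth_window = 3)
  expect_equal(dim(densitySmoothed(ga)), dim(densityBins(ga)))
})

test_that("contours are nested for a single peak and match Gaussian area", {
  # single central peak: all contours closed and nested
  m <- matrix(FALSE, 200, 200); m[81:120, 81:120] <- TRUE
  g <- binAndSmooth(m)
  ct <- contourFromDensity(g, n_levels = 4)
  expect_gt(length(ct), 0)
  flat <- binAndSmooth(matrix(FALSE, 100, 100))
  expect_warning(expect_length(contourFromDensity(flat), 0), "flat")

  # discrete Gaussian bump: half-max contour area vs closed form
  sigma <- 150
  grid_n <- 52
  bp <- 20L
  centers <- (seq_len(grid_n) - 0.5) * bp
  mid <- grid_n / 2 * bp
  z <- outer(centers, centers, function(y, x)
    exp(-((y - mid)^2 + (x - mid)^2) / (2 * sigma^2)))
  dg <- new("DensityGrid", bin_counts = z, smoothed = z,
            bin_px = bp, smooth_px = bp)
  ct2 <- contourFromDensity(dg, levels = 0.5)
  expect_equal(length(ct2), 1)
  # shoelace area of the polygon
  xs <- ct2[[1]]$x; ys <- ct2[[1]]$y
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  fwhm <- 2 * sigma * sqrt(2 * log(2))
  expect_lt(abs(area - pi * (fwhm / 2)^2) / (pi * (fwhm / 2)^2), 0.1)
})

test_that("colocalization boundary is inclusive at 65% and order-invariant", {
  ch1 <- matrix(0, 40, 40); ch2 <- matrix(0, 40, 40)
  masks <- matrix(0L, 40, 40)
  masks[1:10, 1:10] <- 1L    # 100 px
  masks[20:29, 20:29] <- 2L  # 100 px
  ch1[masks > 0] <- 200
  ch2[masks == 1][1:65] <- 200   # 65 co-intense -> positive
  ch2[masks == 2][1:64] <- 200   # 64 -> negative
  cc <- callColocalization(ch1, ch2, masks, thresholds = c(120, 120))
  expect_identical(cc$positive, c(TRUE, FALSE))
  expect_equal(cc$fraction, c(0.65, 0.64))
  expect_equal(cc$soma_area_px, c(100, 100))
  expect_equal(callColocalization(ch1, ch2, masks, thresholds = c(120, 120),
                                  pixel_size_um = 0.5)$soma_area_um2,
               c(25, 25))
  expect_error(callColocalization(ch1, ch2, matrix(0L, 40, 40)), "no masks")
})

test_that("planted colocalization fractions are recovered with Otsu thresholds", {
  tc <- generateAxonImage(ImageSimConfig(n_blobs = 100, height = 1500,
                                         width = 1500,
                                         coloc_fraction_true = 0.5,
                                         seed = 38L), two_channel = TRUE)
  cc <- callColocalization(tc$ch1, tc$ch2, tc$masks)
  expect_equal(sum(cc$positive), 50)
  expect_true(all(cc$positive == tc$truth[cc$mask_id]))
})

test_that("single-channel generator obeys its degenerate contracts", {
  z <- generateAxonImage(ImageSimConfig(n_blobs = 0, background_sd = 0))
  expect_true(all(z$image == 0))
  im <- generateAxonImage(ImageSimConfig(n_blobs = 8, blob_intensity = 200,
                                         background_sd = 5, seed = 39L))
  # background max far below threshold: binarization keeps the blobs
  m <- binarizeAndClean(im$image, threshold = 120)
  expect_identical(m, im$blob_mask)
  # TIFF round trip
  f <- withr::local_tempfile(fileext = ".tif")
  writeImageTIFF(im$image, f)
  expect_equal(readImageTIFF(f), im$image, ignore_attr = TRUE)
})
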