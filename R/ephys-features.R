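# Spike-shape analysis of cell-attached recordings and AP/passive
# feature extraction from whole-cell sweeps. Traces are plain numeric
# vectors in mV (or mV-like units) with an explicit sampling rate; all
# ms/µs constants are converted to samples at run time.

#' Detect isolated negative-peak spikes in a cell-attached trace
#'
#' Candidate spikes are local minima below `median - mad_k * MAD` of the
#' analysis window. A candidate is kept only if no other candidate lies
#' within ±5 ms (single-spike isolation); for every kept spike a ±5 ms
#' waveform window is extracted. Spikes whose window would extend past
#' the trace are dropped and recorded in the `dropped` attribute.
#'
#' @param trace numeric vector.
#' @param sampling_rate Hz.
#' @param analysis_start start of the analysis window in seconds
#'   (default 0; classically 10 min into the recording).
#' @param duration analysis window length in seconds (default 10).
#' @param mad_k amplitude criterion in MADs below the median (default 5).
#' @return list with `spike_times` (s, relative to trace start),
#'   `windows` (spikes x samples matrix, ±5 ms around each peak) and
#'   `threshold` (the amplitude criterion used).
#' @export
detectSpikesCellAttached <- function(trace, sampling_rate,
                                     analysis_start = 0, duration = 10,
                                     mad_k = 5) {
  i0 <- round(analysis_start * sampling_rate) + 1L
  i1 <- round((analysis_start + duration) * sampling_rate)
  if (i0 < 1L || i1 > length(trace))
    stop("analysis window extends past the trace")
  seg <- trace[i0:i1]
  crit <- stats::median(seg) - mad_k * stats::mad(seg)
  # light running-mean smoothing for candidate search only (noise
  # wiggles would split one spike into several sub-minima); windows are
  # cut from the raw trace
  ks <- max(1L, round(0.00025 * sampling_rate))
  sm <- if (ks > 1L)
    as.numeric(stats::filter(seg, rep(1 / (2 * ks + 1), 2 * ks + 1)))
  else seg
  sm[is.na(sm)] <- seg[is.na(sm)]
  below <- which(seg < crit)
  cand <- below[vapply(below, function(i) {
    lo <- max(1L, i - ks); hi <- min(length(seg), i + ks)
    sm[i] <= min(sm[lo:hi])
  }, logical(1))]
  # collapse chained candidates within 2 ms to the deepest sample
  if (length(cand)) {
    grp <- cumsum(c(1L, diff(cand) > round(0.002 * sampling_rate)))
    cand <- vapply(split(cand, grp), function(ix) ix[which.min(seg[ix])],
                   integer(1))
  }
  iso <- round(0.005 * sampling_rate)
  keep <- vapply(seq_along(cand), function(j) {
    others <- cand[-j]
    !any(abs(others - cand[j]) <= iso)
  }, logical(1))
  peaks <- cand[keep]
  half_n <- iso
  abs_pk <- peaks + i0 - 1L
  in_bounds <- abs_pk - half_n >= 1L & abs_pk + half_n <= length(trace)
  dropped <- abs_pk[!in_bounds]
  abs_pk <- abs_pk[in_bounds]
  windows <- if (length(abs_pk))
    t(vapply(abs_pk, function(pkk) trace[(pkk - half_n):(pkk + half_n)],
             numeric(2L * half_n + 1L)))
  else matrix(numeric(0), 0, 2L * half_n + 1L)
  structure(list(spike_times = (abs_pk - 1L) / sampling_rate,
                 windows = windows, threshold = crit),
            dropped = (dropped - 1L) / sampling_rate)
}

#' Normalize spike waveforms and average them
#'
#' Each waveform has the mean of its first 3.75 ms subtracted (baseline
#' 0) and is divided by the magnitude of its most negative value (peak
#' exactly -1). Waveforms with zero peak after baseline subtraction are
#' excluded (recorded in attribute `excluded`). The per-cell average is
#' the pointwise mean.
#'
#' @param windows spikes x samples matrix (±5 ms windows).
#' @param sampling_rate Hz.
#' @return numeric averaged normalized waveform.
#' @export
normalizeAndAverage <- function(windows, sampling_rate) {
  if (!nrow(windows)) stop("need at least one waveform")
  nb <- round(0.00375 * sampling_rate)
  excluded <- integer(0)
  norm <- matrix(NA_real_, nrow(windows), ncol(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ] - mean(windows[i, seq_len(nb)])
    pk <- min(w)
    if (pk == 0) { excluded <- c(excluded, i); next }
    norm[i, ] <- w / abs(pk)
  }
  norm <- norm[setdiff(seq_len(nrow(windows)), excluded), , drop = FALSE]
  if (!nrow(norm)) stop("all waveforms degenerate (zero peak)")
  structure(colMeans(norm), excluded = excluded)
}

#' Half-peak width of an averaged normalized waveform
#'
#' Width at amplitude -0.5: the first down-crossing before the -1 peak
#' and the next up-crossing after it are located by linear interpolation
#' between adjacent samples; the width is their time difference in ms.
#'
#' @param wave normalized waveform (baseline 0, peak -1).
#' @param sampling_rate Hz.
#' @return width in ms.
#' @export
halfPeakWidth <- function(wave, sampling_rate) {
  ipk <- which.min(wave)
  if (ipk < 2L || ipk >= length(wave))
    stop("waveform peak lies on the window boundary")
  level <- -0.5
  left <- NULL
  for (i in seq(ipk - 1L, 1L)) {
    if (wave[i] > level && wave[i + 1L] <= level) {
      left <- i + (wave[i] - level) / (wave[i] - wave[i + 1L]); break
    }
  }
  right <- NULL
  if (ipk < length(wave)) for (i in seq(ipk, length(wave) - 1L)) {
    if (wave[i] <= level && wave[i + 1L] > level) {
      right <- i + (level - wave[i]) / (wave[i + 1L] - wave[i]); break
    }
  }
  if (is.null(left) || is.null(right))
    stop("waveform does not cross the half-amplitude level on both flanks")
  (right - left) / sampling_rate * 1000
}

#' Action-potential threshold by the dV/dt criterion
#'
#' Scans per-sample forward differences and returns the voltage at the
#' last sample before the first difference at or above the dV/dt
#' criterion of 12 V/s (0.6 mV per 50 µs sample at 20 kHz; converted for
#' other rates).
#'
#' @param sweep membrane potential (mV).
#' @param sampling_rate Hz.
#' @param dvdt_threshold criterion in V/s (default 12).
#' @return list with `threshold` (mV) and `index` (sample).
#' @export
apThreshold <- function(sweep, sampling_rate, dvdt_threshold = 12) {
  per_sample <- dvdt_threshold * 1000 / sampling_rate   # mV per sample
  d <- diff(sweep)
  i <- which(d >= per_sample)
  if (!length(i)) stop("no AP found (dV/dt criterion never reached)")
  list(threshold = sweep[i[1L]], index = i[1L])
}

#' AP waveform features from a whole-cell sweep
#'
#' Given the dV/dt threshold, computes the peak (maximum potential after
#' the threshold crossing), amplitude (peak - threshold), half width at
#' threshold + amplitude/2 via linear interpolation (reported in µs) and
#' the fast afterhyperpolarization — threshold minus the potential
#' trough within 4 ms after the peak, reported as a signed difference
#' that is positive when the trough lies below threshold.
#'
#' @param sweep membrane potential (mV).
#' @param sampling_rate Hz.
#' @param threshold optional precomputed [apThreshold()] result.
#' @return list with `threshold`, `peak`, `amplitude`, `half_width_us`,
#'   `fahp` (all mV except the width).
#' @export
apFeatures <- function(sweep, sampling_rate, threshold = NULL) {
  if (is.null(threshold)) threshold <- apThreshold(sweep, sampling_rate)
  i0 <- threshold$index
  seg <- sweep[i0:length(sweep)]
  ipk <- which.max(seg) + i0 - 1L
  if (ipk >= length(sweep)) stop("AP peak at sweep end")
  peak <- sweep[ipk]
  amplitude <- peak - threshold$threshold
  level <- threshold$threshold + amplitude / 2
  up <- NULL
  if (ipk > i0) for (i in seq(ipk - 1L, i0)) {
    if (sweep[i] < level && sweep[i + 1L] >= level) {
      up <- i + (level - sweep[i]) / (sweep[i + 1L] - sweep[i]); break
    }
  }
  down <- NULL
  for (i in seq(ipk, length(sweep) - 1L)) {
    if (sweep[i] >= level && sweep[i + 1L] < level) {
      down <- i + (sweep[i] - level) / (sweep[i] - sweep[i + 1L]); break
    }
  }
  if (is.null(up) || is.null(down)) stop("half-amplitude level not crossed")
  w4 <- min(length(sweep), ipk + round(0.004 * sampling_rate))
  trough <- min(sweep[(ipk + 1L):w4])
  list(threshold = threshold$threshold, peak = peak, amplitude = amplitude,
       half_width_us = (down - up) / sampling_rate * 1e6,
       fahp = threshold$threshold - trough)
}

# count APs in a voltage segment by dV/dt crossings with a refractory
# separation (default 2 ms)
.countAPs <- function(sweep, sampling_rate, dvdt_threshold = 12,
                      refractory_ms = 2) {
  per_sample <- dvdt_threshold * 1000 / sampling_rate
  idx <- which(diff(sweep) >= per_sample)
  if (!length(idx)) return(0L)
  sep <- round(refractory_ms / 1000 * sampling_rate)
  keep <- c(TRUE, diff(idx) > sep)
  sum(keep)
}

#' Spontaneous firing rate in a fixed window
#'
#' @param sweep membrane potential trace (mV).
#' @param sampling_rate Hz.
#' @param window_start window start (s).
#' @param window_len window length (s, default 10).
#' @return rate in Hz (AP count / window length).
#' @export
spontaneousRate <- function(sweep, sampling_rate, window_start = 0,
                            window_len = 10) {
  i0 <- round(window_start * sampling_rate) + 1L
  i1 <- round((window_start + window_len) * sampling_rate)
  if (i0 < 1L || i1 > length(sweep)) stop("window exceeds the trace")
  .countAPs(sweep[i0:i1], sampling_rate) / window_len
}

#' Input resistance from current-step deflections
#'
#' Ordinary least-squares slope of steady-state voltage deflection (mV)
#' against injected current (pA), converted to megaohm (mV/pA x 1000).
#'
#' @param deflections `data.frame` with columns `current_pA` and
#'   `delta_mV` (>= 3 step points including 0 pA).
#' @return input resistance in megaohm.
#' @export
inputResistance <- function(deflections) {
  if (nrow(deflections) < 3) stop("need at least three step points")
  fit <- stats::lm(delta_mV ~ current_pA, data = deflections)
  unname(stats::coef(fit)["current_pA"]) * 1000
}

#' Frequency-current (F-I) curve
#'
#' Counts APs during each current step using the dV/dt crossing rule
#' with a 2 ms refractory separation. Missing steps are recorded as NA,
#' not zero.
#'
#' @param sweeps list of voltage traces (mV), one per step, or `NULL`
#'   entries for missing steps.
#' @param currents_pA injected current per sweep.
#' @param sampling_rate Hz.
#' @param step_start,step_duration location of the step within each
#'   sweep (s).
#' @return `data.frame` with `current_pA` and `n_spikes`.
#' @export
fiCurve <- function(sweeps, currents_pA, sampling_rate,
                    step_start = 0.2, step_duration = 1) {
  stopifnot(length(sweeps) == length(currents_pA))
  i0 <- round(step_start * sampling_rate) + 1L
  i1 <- round((step_start + step_duration) * sampling_rate)
  n <- vapply(sweeps, function(s) {
    if (is.null(s)) return(NA_integer_)
    as.integer(.countAPs(s[i0:min(i1, length(s))], sampling_rate))
  }, integer(1))
  data.frame(current_pA = currents_pA, n_spikes = n)
}

#' Two-sided Mann-Whitney comparison of two feature groups
#'
#' Exact for small samples without ties, normal approximation with tie
#' correction otherwise; completely tied data yield p = 1.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @return list with `statistic` (U for group a) and `p_value`.
#' @export
compareGroups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  if (length(unique(c(values_a, values_b))) == 1L)
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1))
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value))
}
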