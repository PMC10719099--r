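# Synthetic electrophysiology: cell-attached traces with a
# difference-of-exponentials negative spike template, and whole-cell
# current-step sweeps from a leaky integrate-and-fire cell with ohmic
# passive response.

#' Negative spike template with a prescribed half width
#'
#' Difference-of-exponentials transient \eqn{e^{-t/\tau_d} - e^{-t/\tau_r}}
#' (with \eqn{\tau_r = \tau_d/4}) scaled to peak amplitude `-amplitude`,
#' with the decay constant calibrated numerically so the full width at
#' half amplitude equals `half_width_ms`. Sampled over a ±5 ms window with
#' the peak at the centre sample.
#'
#' @param half_width_ms target full width at half amplitude (ms).
#' @param amplitude peak magnitude (positive number; template is negative).
#' @param sampling_rate Hz.
#' @return numeric vector of length `10 ms * sampling_rate + 1`.
#' @export
spikeTemplate <- function(half_width_ms, amplitude = 1, sampling_rate = 20000) {
  stopifnot(half_width_ms > 0, half_width_ms < 5)
  doe_fwhm <- function(tau_d) {
    tau_r <- tau_d / 4
    g <- function(t) exp(-t / tau_d) - exp(-t / tau_r)
    t_pk <- tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
    pk <- g(t_pk)
    half <- function(t) g(t) - pk / 2
    t1 <- stats::uniroot(half, c(1e-9, t_pk))$root
    t2 <- stats::uniroot(half, c(t_pk, 100 * tau_d))$root
    t2 - t1
  }
  tau_d <- stats::uniroot(function(x) doe_fwhm(x) - half_width_ms,
                          c(half_width_ms / 20, half_width_ms * 20))$root
  tau_r <- tau_d / 4
  t_pk <- tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
  half_n <- round(0.005 * sampling_rate)
  tt <- (seq(-half_n, half_n) / sampling_rate) * 1000 + t_pk  # ms, peak centred
  g <- ifelse(tt > 0, exp(-tt / tau_d) - exp(-tt / tau_r), 0)
  -amplitude * g / max(g)
}

#' Simulate a cell-attached recording with known spike times
#'
#' Spontaneous spikes occur at homogeneous Poisson times at
#' `firing_rate_true`; any spike falling within 10 ms of the previously
#' kept spike is discarded so every planted spike is isolated (the
#' downstream detector requires ±5 ms isolation). Gaussian noise of
#' `noise_sd` is added throughout.
#'
#' @param cfg an [EphysSimConfig].
#' @param duration_s trace length in seconds (>= 10).
#' @return list with `trace` (numeric, arbitrary mV-like units),
#'   `spike_times` (s, the planted truth), `sampling_rate`, `template`.
#' @export
generateCellAttachedTrace <- function(cfg, duration_s = 12) {
  stopifnot(is(cfg, "EphysSimConfig"))
  validObject(cfg)
  if (duration_s < 10) stop("trace must be at least 10 s")
  if (cfg@firing_rate_true >= 100)
    stop("firing_rate_true >= 100 Hz: ±5 ms isolation windows must overlap")
  set.seed(cfg@seed)
  rate <- cfg@sampling_rate
  n <- round(duration_s * rate)
  trace <- stats::rnorm(n, 0, cfg@noise_sd)
  times <- numeric(0)
  if (cfg@firing_rate_true > 0) {
    k <- stats::rpois(1, cfg@firing_rate_true * duration_s)
    raw <- sort(stats::runif(k, 0, duration_s))
    keep <- logical(length(raw))
    last <- -Inf
    for (i in seq_along(raw)) {
      if (raw[i] - last >= 0.010) { keep[i] <- TRUE; last <- raw[i] }
    }
    times <- raw[keep]
    tmpl <- spikeTemplate(cfg@spike_half_width_true, cfg@spike_amplitude, rate)
    half_n <- (length(tmpl) - 1L) %/% 2L
    times <- times[round(times * rate) > half_n &
                   round(times * rate) <= n - half_n - 1L]
    for (tm in times) {
      c0 <- round(tm * rate)
      idx <- (c0 - half_n):(c0 + half_n) + 1L
      trace[idx] <- trace[idx] + tmpl
    }
  }
  list(trace = trace, spike_times = times, sampling_rate = rate,
       template = if (cfg@firing_rate_true > 0)
         spikeTemplate(cfg@spike_half_width_true, cfg@spike_amplitude, rate)
       else NULL)
}

#' Simulate whole-cell current-step sweeps
#'
#' Hyperpolarizing and subthreshold steps produce an ohmic response
#' \eqn{V = V_{rest} + I R (1 - e^{-t/\tau})} (pA x megaohm / 1000 = mV);
#' suprathreshold steps drive a leaky integrate-and-fire cell
#' (\eqn{\tau} = 20 ms, threshold -45 mV, reset -58 mV) whose crossings
#' insert a stylized action potential (0.3 ms rise to +20 mV, 0.7 ms fall
#' to the reset). Each sweep has 0.2 s of baseline before and after the
#' step. Spike times are recorded as ground truth.
#'
#' @param cfg an [EphysSimConfig].
#' @param protocol `data.frame` with columns `current_pA` and
#'   `duration_s`, one row per sweep.
#' @return list with `sweeps` (list of numeric traces, mV),
#'   `protocol`, `sampling_rate`, `truth` (LIF parameters, per-sweep
#'   spike times and steady-state deflections), `step_window`
#'   (start/end sample of the step).
#' @export
generateWholeCellSweeps <- function(cfg, protocol) {
  stopifnot(is(cfg, "EphysSimConfig"))
  validObject(cfg)
  if (!is.data.frame(protocol) || nrow(protocol) == 0L)
    stop("protocol must be a non-empty data.frame(current_pA, duration_s)")
  set.seed(cfg@seed)
  rate <- cfg@sampling_rate
  dt <- 1 / rate
  v_rest <- -65; tau <- 0.020; v_th <- -45; v_reset <- -58
  ap_peak <- 20
  rise_n <- max(2L, round(0.0003 * rate))
  fall_n <- max(2L, round(0.0007 * rate))
  R <- cfg@input_resistance_true
  pre_n <- round(0.2 * rate); post_n <- round(0.2 * rate)

  sweeps <- vector("list", nrow(protocol))
  spike_times <- vector("list", nrow(protocol))
  deflection <- numeric(nrow(protocol))
  for (s in seq_len(nrow(protocol))) {
    I <- protocol$current_pA[s]
    dur_n <- round(protocol$duration_s[s] * rate)
    n <- pre_n + dur_n + post_n
    v <- numeric(n)
    v[seq_len(pre_n)] <- v_rest
    vinf <- v_rest + I * R / 1000
    deflection[s] <- vinf - v_rest
    # exact integrate-and-fire solution: spike times from the closed
    # form, exponential segments in between
    dur_s <- dur_n * dt
    ap_n <- rise_n + fall_n
    ap_shape <- c(seq(v_th, ap_peak, length.out = rise_n),
                  seq(ap_peak, v_reset, length.out = fall_n + 1L)[-1L])
    st <- numeric(0)
    if (vinf > v_th) {
      t1 <- tau * log((vinf - v_rest) / (vinf - v_th))
      isi <- ap_n * dt + tau * log((vinf - v_reset) / (vinf - v_th))
      if (t1 <= dur_s) st <- seq(t1, dur_s, by = isi)
    }
    seg_start <- c(0, st + ap_n * dt)          # segment onsets (s)
    seg_v0 <- c(v_rest, rep(v_reset, length(st)))
    seg_end <- c(st, dur_s)
    tvec <- (seq_len(dur_n) - 0.5) * dt
    vstep <- numeric(dur_n)
    for (sg in seq_along(seg_start)) {
      inseg <- tvec >= seg_start[sg] & tvec < seg_end[sg]
      vstep[inseg] <- vinf + (seg_v0[sg] - vinf) *
        exp(-(tvec[inseg] - seg_start[sg]) / tau)
    }
    for (tm in st) {
      j0 <- pmin(round(tm / dt) + 1L, dur_n)
      take <- min(ap_n, dur_n - j0 + 1L)
      vstep[j0:(j0 + take - 1L)] <- ap_shape[seq_len(take)]
    }
    v[(pre_n + 1L):(pre_n + dur_n)] <- vstep
    # relaxation back to rest after the step
    vcur <- v[pre_n + dur_n]
    for (j in seq_len(post_n)) {
      vcur <- vcur + dt / tau * (v_rest - vcur)
      v[pre_n + dur_n + j] <- vcur
    }
    if (cfg@noise_sd > 0) v <- v + stats::rnorm(n, 0, cfg@noise_sd)
    sweeps[[s]] <- v
    spike_times[[s]] <- st
  }
  list(sweeps = sweeps, protocol = protocol, sampling_rate = rate,
       step_window = c(start = pre_n + 1L, end_offset = post_n),
       truth = list(v_rest = v_rest, tau_s = tau, v_th = v_th,
                    v_reset = v_reset, ap_peak = ap_peak,
                    ap_samples = rise_n + fall_n,
                    input_resistance = R,
                    spike_times = spike_times, deflection = deflection))
}

#' Analytic spike count of the simulated integrate-and-fire cell
#'
#' Closed-form number of threshold crossings during a constant current
#' step, used as an independent check of the simulated F-I relationship.
#'
#' @param current_pA injected current.
#' @param duration_s step duration.
#' @param R input resistance (megaohm).
#' @param tau_s,v_rest,v_th,v_reset,ap_s LIF parameters; defaults match
#'   [generateWholeCellSweeps()] (`ap_s` is the 1 ms stylized AP).
#' @return expected spike count (integer).
#' @export
lifSpikeCount <- function(current_pA, duration_s = 1, R = 100,
                          tau_s = 0.020, v_rest = -65, v_th = -45,
                          v_reset = -58, ap_s = 0.001) {
  vinf <- v_rest + current_pA * R / 1000
  if (vinf <= v_th) return(0L)
  t1 <- tau_s * log((vinf - v_rest) / (vinf - v_th))
  isi <- ap_s + tau_s * log((vinf - v_reset) / (vinf - v_th))
  if (t1 > duration_s) return(0L)
  as.integer(1L + floor((duration_s - t1) / isi))
}
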