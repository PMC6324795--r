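# Trace feature extraction and the in-vivo-like (IVL) metric -----------------
#
# All scalar features are computed over an analysis window (1,000-10,000 ms
# by default, i.e. the last 9 s of a 10 s run): spikes are detected by an
# upward threshold crossing, their begin/end located by derivative criteria,
# and the samples they span are cut before subthreshold statistics are taken.
# The IVL metric scores a trace as
#
#   (mean Vm > -66.7 mV) + (sigma_Vm > 2.2 mV) + (ISICV > 0.8)
#     - 4 * (mean spike amplitude < 40 mV)
#
# so 3 = in-vivo-like (IVL), 0 = non-in-vivo-like (NIVL), negative values =
# nearing depolarization block (DB), and 1-2 = partially satisfied.

IVL_THRESH_MEAN_VM <- -66.7 # mV
IVL_THRESH_SIGMA_VM <- 2.2 # mV
IVL_THRESH_ISICV <- 0.8
IVL_THRESH_SPIKE_AMP <- 40 # mV

SPIKE_DETECT_THRESHOLD <- -20 # mV, upward crossing
SPIKE_ONSET_DVDT <- 20 # mV/ms

ANALYSIS_WINDOW <- c(1000, 10000) # ms

#' Detect spikes and cut them from a voltage trace
#'
#' Spikes are upward crossings of -20 mV. Each spike's begin is the start of
#' the last contiguous run of dV/dt >= 20 mV/ms before its peak (falling
#' back to the threshold crossing), its end the first return of Vm to at or
#' below the begin voltage; amplitude is peak minus begin voltage. Samples
#' between begin and end are removed from the subthreshold trace.
#'
#' @param trace An `ivl_trace` (or tibble with `time`, `vm`).
#' @param threshold Detection threshold (mV); spikes whose peak stays below
#'   it are not detected.
#' @return List with `spikes` (tibble: `time` of peak, `begin`, `end`,
#'   `amplitude` mV) and `subthreshold` (tibble `time`, `vm` with spike
#'   samples removed).
#' @export
detect_and_cut_spikes <- function(trace, threshold = SPIKE_DETECT_THRESHOLD) {
  t <- trace$time
  v <- trace$vm
  n <- length(v)
  dtr <- if (n > 1) t[2] - t[1] else 1
  dvdt <- c(0, diff(v)) / dtr

  up <- which(v[-1] >= threshold & v[-n] < threshold) + 1L
  spikes <- list()
  cut <- logical(n)
  last_end <- 0L
  for (i in up) {
    if (i <= last_end) next # still inside the previous spike
    # peak: local maximum while above threshold
    j <- i
    while (j < n && v[j + 1] >= v[j]) j <- j + 1L
    peak <- j
    # begin: walk back through the dV/dt >= onset run preceding the peak
    b <- peak
    while (b > 1 && dvdt[b] >= SPIKE_ONSET_DVDT) b <- b - 1L
    if (b == peak) b <- max(i - 1L, 1L) # no steep run: use the crossing
    # end: first return to at or below the begin voltage
    e <- peak
    while (e < n && v[e] > v[b]) e <- e + 1L
    cut[b:e] <- TRUE
    last_end <- e
    spikes[[length(spikes) + 1L]] <- tibble::tibble(
      time = t[peak], begin = t[b], end = t[e],
      amplitude = v[peak] - v[b]
    )
  }
  spikes <- if (length(spikes)) {
    dplyr::bind_rows(spikes)
  } else {
    tibble::tibble(
      time = numeric(), begin = numeric(), end = numeric(),
      amplitude = numeric()
    )
  }
  list(
    spikes = spikes,
    subthreshold = tibble::tibble(time = t[!cut], vm = v[!cut])
  )
}

#' Summarize a voltage trace into IVL-metric measurements
#'
#' Computes the mean and standard deviation of the subthreshold membrane
#' potential (after spike cutting), the inter-spike-interval coefficient of
#' variation (`sd(ISI)/mean(ISI)`; defined as 0 with fewer than 3 spikes),
#' the mean spike amplitude, and spike counts, all over the analysis window.
#'
#' @param trace An `ivl_trace`.
#' @param window Analysis window `c(start, end)` in ms.
#' @return One-row tibble of class `trace_measurements`: `mean_sub_vm`,
#'   `sigma_sub_vm`, `isi_cv`, `mean_spike_amp`, `n_spikes`, `spike_rate`
#'   (Hz over the window) and list-column `spike_times`.
#' @export
summarize_trace <- function(trace, window = ANALYSIS_WINDOW) {
  cutres <- detect_and_cut_spikes(trace)
  sub <- cutres$subthreshold
  in_win <- sub$time >= window[1] & sub$time <= window[2]
  sp <- cutres$spikes
  sp_in <- sp[sp$time >= window[1] & sp$time <= window[2], ]

  isis <- diff(sp_in$time)
  isi_cv <- if (nrow(sp_in) >= 3) sd(isis) / mean(isis) else 0
  vm <- sub$vm[in_win]
  out <- tibble::tibble(
    mean_sub_vm = if (length(vm)) mean(vm) else NA_real_,
    sigma_sub_vm = if (length(vm) > 1) sd(vm) else 0,
    isi_cv = isi_cv,
    mean_spike_amp = if (nrow(sp_in)) mean(sp_in$amplitude) else NA_real_,
    n_spikes = nrow(sp_in),
    spike_rate = nrow(sp_in) / (diff(window) / 1000),
    spike_times = list(sp_in$time)
  )
  class(out) <- c("trace_measurements", class(out))
  out
}

#' The in-vivo-like (IVL) metric and state classification
#'
#' Scores a set of trace measurements with the conditional metric
#' `(mean_sub_vm > -66.7) + (sigma_sub_vm > 2.2) + (isi_cv > 0.8) -
#' 4 * (mean_spike_amp < 40)` and maps the score to a state: `IVL` (3),
#' `NIVL` (0), `DB` (negative), otherwise `PARTIAL`. A trace without spikes
#' has `isi_cv = 0` (the irregularity criterion fails) and its amplitude
#' term is treated as *not* below threshold: silence is not depolarization
#' block.
#'
#' @param meas A `trace_measurements` row (or any list with the four
#'   fields), or an `ivl_trace` (summarized first).
#' @param window Analysis window when `meas` is a trace.
#' @return One-row tibble of class `ivl_assessment`: `ivl_metric` (integer in
#'   -4..3) and `state`.
#' @examples
#' ivl_metric(list(
#'   mean_sub_vm = -60, sigma_sub_vm = 3,
#'   isi_cv = 1, mean_spike_amp = 55
#' ))
#' @export
ivl_metric <- function(meas, window = ANALYSIS_WINDOW) {
  if (inherits(meas, "ivl_trace")) meas <- summarize_trace(meas, window)
  amp_term <- if (is.na(meas$mean_spike_amp)) {
    0L # no spikes: not in depolarization block by convention
  } else {
    as.integer(meas$mean_spike_amp < IVL_THRESH_SPIKE_AMP)
  }
  metric <- as.integer(meas$mean_sub_vm > IVL_THRESH_MEAN_VM) +
    as.integer(meas$sigma_sub_vm > IVL_THRESH_SIGMA_VM) +
    as.integer(meas$isi_cv > IVL_THRESH_ISICV) -
    4L * amp_term
  state <- dplyr::case_when(
    metric == 3L ~ "IVL",
    metric == 0L ~ "NIVL",
    metric < 0L ~ "DB",
    TRUE ~ "PARTIAL"
  )
  out <- tibble::tibble(ivl_metric = metric, state = state)
  class(out) <- c("ivl_assessment", class(out))
  out
}

#' Measure somatic input resistance with the -100 pA step protocol
#'
#' Runs a 10 s noise-free simulation with a -100 pA somatic step from 4.5 to
#' 5.5 s, averages the (spike-cut) membrane potential over the baseline
#' windows (0-4.5 s and 5.5-10 s) and over the settled part of the step
#' (4.7-5.5 s, skipping 200 ms), and reports
#' `Ri = (V_hyper - V_baseline) / I_inj` in MOhm.
#'
#' @param model An `is3_model`.
#' @param inputs Optional `input_assignment` present during the protocol.
#' @param i_inj Step amplitude (nA); must be nonzero.
#' @param noise Inject intrinsic noise during the protocol? Off by default.
#' @param noise_seed Noise seed when enabled.
#' @param dt,record_dt Solver/recording steps (ms).
#' @return One-row tibble of class `input_resistance_result`: `r_in` (MOhm),
#'   `v_baseline`, `v_hyper` (mV), `i_inj` (nA).
#' @export
input_resistance <- function(model, inputs = NULL, i_inj = -0.1,
                             noise = FALSE, noise_seed = 1L,
                             dt = 0.025, record_dt = 0.1) {
  if (i_inj == 0) abort("`i_inj` must be nonzero")
  step <- tibble::tibble(start = 4500, end = 5500, amp_nA = i_inj)
  tr <- simulate_model(model, inputs,
    duration = 10000, dt = dt,
    record_dt = record_dt, stim = step, noise = noise,
    noise_seed = noise_seed
  )
  sub <- detect_and_cut_spikes(tr)$subthreshold
  base <- sub$vm[sub$time < 4500 | sub$time >= 5500]
  hyper <- sub$vm[sub$time >= 4700 & sub$time < 5500]
  v_b <- mean(base)
  v_h <- mean(hyper)
  out <- tibble::tibble(
    r_in = (v_h - v_b) / i_inj, # mV / nA = MOhm
    v_baseline = v_b, v_hyper = v_h, i_inj = i_inj
  )
  class(out) <- c("input_resistance_result", class(out))
  out
}

# Welch power spectral density ------------------------------------------------

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-detrended, 50%-overlapping segments averaged into a
#' one-sided density estimate (units `x^2/Hz`). The default segment length
#' of 2000 samples at 1 kHz gives a 0.5 Hz grid, putting 8 Hz exactly on a
#' frequency bin (16 theta cycles per segment).
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency (Hz).
#' @param nperseg Segment length (samples); shortened to `length(x)` when
#'   the signal is shorter.
#' @param overlap Fractional segment overlap.
#' @return Tibble with `frequency` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs = 1000, nperseg = 2000, overlap = 0.5) {
  n <- length(x)
  nseg <- min(nperseg, n)
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  k <- seq_len(nseg) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / nseg)) # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg)[seq_len(nf)])^2 * scale
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)] # one-sided
    acc <- acc + p
  }
  tibble::tibble(
    frequency = (seq_len(nf) - 1L) * fs / nseg,
    power = acc / length(starts)
  )
}

#' Power spectral density of a spike train at theta frequency
#'
#' Bins spike times in the analysis window into a 1 ms instantaneous-rate
#' signal (counts per bin divided by the bin width, spikes/s) and applies
#' [welch_psd()]; `value_at_8hz` is the power at the frequency bin nearest
#' 8 Hz, in the spikes^2/Hz units of the recruitment criteria.
#'
#' @param spike_times Spike times (ms), or a `trace_measurements` row.
#' @param window Analysis window `c(start, end)` in ms.
#' @param bin_ms Bin width (ms).
#' @return List of class `psd_result`: `psd` (tibble `frequency`, `power`
#'   in spikes^2/Hz), `value_at_8hz`, `n_spikes`.
#' @export
spike_psd <- function(spike_times, window = ANALYSIS_WINDOW, bin_ms = 1) {
  if (inherits(spike_times, "trace_measurements")) {
    spike_times <- spike_times$spike_times[[1]]
  }
  st <- spike_times[spike_times >= window[1] & spike_times < window[2]]
  n_bins <- round(diff(window) / bin_ms)
  counts <- tabulate(
    pmin(floor((st - window[1]) / bin_ms) + 1L, n_bins),
    nbins = n_bins
  )
  fs <- 1000 / bin_ms
  # rate signal in spikes/s; all-zero counts give a zero spectrum
  psd <- welch_psd(counts * fs, fs = fs)
  i8 <- which.min(abs(psd$frequency - 8))
  structure(
    list(
      psd = psd, value_at_8hz = psd$power[i8],
      frequency_at_8hz = psd$frequency[i8], n_spikes = length(st)
    ),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %d spikes, PSD(%.4g Hz) = %.4g spikes^2/Hz\n",
    x$n_spikes, x$frequency_at_8hz, x$value_at_8hz
  ))
  invisible(x)
}
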