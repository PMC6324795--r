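# Conductance isolation, E/I ratios, theta-cycle analyses --------------------
#
# Conductance isolation mimics the stated protocol exactly: all active
# channel conductances are removed, the leak reversal in every compartment
# is set to the holding potential (so leak current vanishes at the clamp),
# and an ideal somatic voltage clamp records the electrode current, which is
# converted to a conductance via G = I / (V_hold - E_R). Method 1 removes
# the opposite input class entirely; Method 2 (the "experiment-like"
# variant) leaves both classes active, exposing the space-clamp artifact.

#' Clamp configuration for isolating one synaptic conductance class
#'
#' @param target `"excitatory"` or `"inhibitory"` - the class being
#'   recorded.
#' @param method `"method1"` (opposite class removed) or `"method2"`
#'   (both classes active, experiment-like).
#' @param v_hold Holding potential (mV). Defaults to the opposite class's
#'   reversal: -70 mV when recording excitatory currents, 0 mV when
#'   recording inhibitory currents.
#' @return A `clamp_config` list.
#' @export
clamp_config <- function(target = c("excitatory", "inhibitory"),
                         method = c("method1", "method2"),
                         v_hold = NULL) {
  target <- match.arg(target)
  method <- match.arg(method)
  v_hold <- v_hold %||% if (target == "excitatory") -70 else 0
  e_rev <- if (target == "excitatory") E_REV_EXC else E_REV_INH
  if (abs(v_hold - e_rev) < 1e-9) {
    abort("holding potential equals the recorded class's reversal (zero driving force)")
  }
  structure(
    list(target = target, method = method, v_hold = v_hold, e_rev = e_rev),
    class = "clamp_config"
  )
}

#' Isolate one synaptic conductance class by somatic voltage clamp
#'
#' @param model An `is3_model`.
#' @param inputs The scenario's `input_assignment`.
#' @param clamp A [clamp_config()].
#' @param duration Simulation length (ms).
#' @param dt,record_dt Solver steps (ms).
#' @return Tibble of class `conductance_trace` with `time` (ms) and `g`
#'   (nS), the recorded class's conductance seen from the soma.
#' @export
isolate_conductance <- function(model, inputs, clamp,
                                duration = 10000, dt = 0.025,
                                record_dt = 0.1) {
  use <- inputs
  if (clamp$method == "method1") {
    keep <- inputs$actives$kind == clamp$target
    use <- inputs
    use$actives <- inputs$actives[keep, ]
  }
  tr <- simulate_model(model, use,
    duration = duration, dt = dt,
    record_dt = record_dt, noise = FALSE,
    v_clamp = clamp$v_hold, passive_only = TRUE,
    e_leak = clamp$v_hold
  )
  g <- tr$i_clamp / (clamp$v_hold - clamp$e_rev) * 1e3 # nA/mV -> uS -> nS
  out <- tibble::tibble(time = tr$time, g = g)
  attr(out, "clamp") <- clamp
  class(out) <- c("conductance_trace", class(out))
  out
}

#' Excitatory and inhibitory conductance traces of one scenario
#'
#' Runs the isolation protocol twice (holding at -70 mV for the excitatory
#' class, 0 mV for the inhibitory class) with the chosen method.
#'
#' @inheritParams isolate_conductance
#' @param method `"method1"` or `"method2"`.
#' @return Tibble with `time`, `g_exc`, `g_inh` (nS).
#' @export
conductance_traces <- function(model, inputs, method = "method1",
                               duration = 10000, dt = 0.025,
                               record_dt = 0.1) {
  ge <- isolate_conductance(model, inputs,
    clamp_config("excitatory", method),
    duration = duration, dt = dt, record_dt = record_dt
  )
  gi <- isolate_conductance(model, inputs,
    clamp_config("inhibitory", method),
    duration = duration, dt = dt, record_dt = record_dt
  )
  tibble::tibble(time = ge$time, g_exc = ge$g, g_inh = gi$g)
}

#' Temporally averaged element-wise E/I conductance ratio
#'
#' Mean over time of `g_exc(t) / g_inh(t)` within the analysis window,
#' computed only at samples where the inhibitory conductance exceeds a small
#' floor (the element-wise ratio is undefined at zeros); the excluded
#' fraction is reported alongside.
#'
#' @param g Tibble with `time`, `g_exc`, `g_inh` from
#'   [conductance_traces()].
#' @param floor_nS Inclusion floor on `g_inh` (nS).
#' @param window Analysis window (ms).
#' @return One-row tibble: `ei_ratio` (NA when no sample passes the floor),
#'   `excluded_fraction`, `n_used`.
#' @export
ei_ratio <- function(g, floor_nS = 1e-3, window = ANALYSIS_WINDOW) {
  gw <- g[g$time >= window[1] & g$time <= window[2], ]
  ok <- gw$g_inh > floor_nS
  tibble::tibble(
    ei_ratio = if (any(ok)) mean(gw$g_exc[ok] / gw$g_inh[ok]) else NA_real_,
    excluded_fraction = mean(!ok),
    n_used = sum(ok)
  )
}

#' Average a trace over theta cycles
#'
#' Splits the analysis window into consecutive cycles of the theta period
#' (72 cycles of 125 ms for the default 9 s window) and returns the mean and
#' standard deviation at each within-cycle sample.
#'
#' @param trace Tibble with `time` plus the value column (a voltage or
#'   conductance trace on a regular grid).
#' @param value Name of the value column (default: `"vm"`, or `"g"` if
#'   present and `vm` is not).
#' @param period Cycle length (ms).
#' @param window Analysis window (ms); must span a whole number of cycles.
#' @return Tibble of class `cycle_average` with `phase_ms`, `mean`, `sd`;
#'   attribute `n_cycles`.
#' @export
theta_cycle_average <- function(trace, value = NULL, period = 125,
                                window = ANALYSIS_WINDOW) {
  value <- value %||% if ("vm" %in% names(trace)) "vm" else "g"
  n_cycles <- diff(window) / period
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    abort("analysis window must span a whole number of theta cycles")
  }
  n_cycles <- round(n_cycles)
  w <- trace[trace$time >= window[1] & trace$time < window[2], ]
  spc <- nrow(w) / n_cycles # samples per cycle
  if (abs(spc - round(spc)) > 1e-9) {
    abort("recording grid does not divide the theta period evenly")
  }
  spc <- round(spc)
  m <- matrix(w[[value]], nrow = spc, ncol = n_cycles)
  out <- tibble::tibble(
    phase_ms = (seq_len(spc) - 1) * period / spc,
    mean = rowMeans(m),
    sd = apply(m, 1, sd)
  )
  attr(out, "n_cycles") <- n_cycles
  class(out) <- c("cycle_average", class(out))
  out
}

# Theta synapse-number estimation ---------------------------------------------

#' Find the holding current recruiting sustained firing
#'
#' Increases a somatic depolarizing step until the model fires at least
#' `target_rate` Hz over a 10 s simulation (the comparability step before
#' inhibitory theta-input estimation).
#'
#' @param model An `is3_model`.
#' @param target_rate Minimum firing rate (Hz; 35 Hz = 350 spikes / 10 s).
#' @param amps Candidate amplitudes to scan, in nA, ascending.
#' @param noise Intrinsic noise on during the search?
#' @return The smallest amplitude (nA) meeting the target.
#' @export
find_holding_current <- function(model, target_rate = 35,
                                 amps = seq(0.02, 0.6, by = 0.02),
                                 noise = model$noise$enabled) {
  for (a in amps) {
    tr <- simulate_model(model,
      duration = 10000,
      stim = tibble::tibble(start = 0, end = 10000, amp_nA = a),
      noise = noise, noise_seed = derive_seed(1L, "holding", round(a * 1e4))
    )
    n <- summarize_trace(tr)$n_spikes
    if (n >= target_rate * 9) {
      return(a)
    } # window is the last 9 s
  }
  abort(sprintf(
    "no holding current up to %g nA reaches %g Hz", max(amps),
    target_rate
  ))
}

#' Estimate the theta-timed synapse count needed to recruit theta spiking
#'
#' Starting from one synapse, adds 8 Hz theta-timed synapses of the given
#' class in the given dendritic zone (deterministic trains, lowest slot ids)
#' until the model's spike-train power at 8 Hz and spike count meet the
#' stopping criteria: excitatory inputs require PSD(8 Hz) > 50 spikes^2/Hz
#' and more than 10 spikes; inhibitory inputs (applied against a holding
#' current that keeps the cell firing >= 35 Hz) require PSD(8 Hz) >
#' 80 spikes^2/Hz and fewer than 240 spikes.
#'
#' @param model An `is3_model` in its "in vitro" condition (no background
#'   bombardment).
#' @param zone `"proximal"` or `"distal"`.
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param cap Maximum count searched; exceeding it is an error naming the
#'   unmet criterion.
#' @param holding_nA Holding current for inhibitory estimation; found via
#'   [find_holding_current()] when `NULL`.
#' @param noise Intrinsic noise on?
#' @param eval_fun Optional hook `(n) -> list(psd8, n_spikes)` replacing the
#'   simulation (used for fast contract tests).
#' @return List: `count`, `psd8`, `n_spikes`, `holding_nA`.
#' @export
estimate_theta_inputs <- function(model, zone = c("proximal", "distal"),
                                  kind = c("excitatory", "inhibitory"),
                                  cap = 60, holding_nA = NULL,
                                  noise = model$noise$enabled,
                                  eval_fun = NULL) {
  zone <- match.arg(zone)
  kind <- match.arg(kind)
  if (is.null(eval_fun)) {
    if (kind == "inhibitory" && is.null(holding_nA)) {
      holding_nA <- find_holding_current(model, noise = noise)
    }
    stim <- if (kind == "inhibitory") {
      tibble::tibble(start = 0, end = 10000, amp_nA = holding_nA)
    } else {
      NULL
    }
    eval_fun <- function(n) {
      pops <- tibble::tibble(
        name = "probe", kind = kind, zone = zone,
        phase_deg = 0, n_synapses = n
      )
      proto <- build_theta_protocol(model$bank, pops)
      tr <- simulate_model(model, proto,
        duration = 10000, stim = stim,
        noise = noise, noise_seed = derive_seed(1L, "theta-est", n)
      )
      meas <- summarize_trace(tr)
      list(
        psd8 = spike_psd(meas)$value_at_8hz,
        n_spikes = meas$n_spikes
      )
    }
  }
  ok <- if (kind == "excitatory") {
    function(r) r$psd8 > 50 && r$n_spikes > 10
  } else {
    function(r) r$psd8 > 80 && r$n_spikes < 240
  }
  for (n in seq_len(cap)) {
    r <- eval_fun(n)
    if (ok(r)) {
      return(list(
        count = n, psd8 = r$psd8, n_spikes = r$n_spikes,
        holding_nA = holding_nA
      ))
    }
  }
  crit <- if (kind == "excitatory") {
    "PSD(8 Hz) > 50 spikes^2/Hz and > 10 spikes"
  } else {
    "PSD(8 Hz) > 80 spikes^2/Hz and < 240 spikes"
  }
  abort(sprintf("no count up to %d met the criterion: %s", cap, crit))
}

#' Spike-train theta power before and after adding theta-timed inputs
#'
#' Simulates a background scenario with and without the theta protocol
#' layered on top, holding all background seeds identical within each
#' repeat, and reports the spike-train PSD at 8 Hz before and after plus the
#' change. Repeats with re-randomized background seeds quantify robustness.
#'
#' @param model A calibrated `is3_model`.
#' @param scenario One scenario row (with `f_exc`, `f_inh`, `n_exc`,
#'   `n_inh`, `k_exc`, `k_inh`, `seed`).
#' @param protocol A `theta_protocol`; defaults to the standard populations.
#' @param n_reseeds Number of re-randomized repeats.
#' @param duration Simulation length (ms).
#' @return Tibble of class `theta_response`: one row per repeat with
#'   `psd8_before`, `psd8_after`, `delta_psd8`, `rate_before`,
#'   `rate_after`.
#' @export
theta_response <- function(model, scenario,
                           protocol = build_theta_protocol(model$bank),
                           n_reseeds = 5, duration = 10000) {
  rows <- purrr::map(seq_len(n_reseeds), function(r) {
    seeds <- scenario_seeds(scenario$seed, replicate = r)
    bg <- scenario_inputs(model, scenario$f_exc, scenario$f_inh,
      scenario$n_exc, scenario$n_inh, scenario$k_exc, scenario$k_inh,
      seeds = seeds, duration = duration
    )
    run_one <- function(inputs) {
      tr <- simulate_model(model, inputs,
        duration = duration,
        noise = TRUE, noise_seed = seeds$noise
      )
      meas <- summarize_trace(tr, window = c(1000, duration))
      list(
        psd8 = spike_psd(meas, window = c(1000, duration))$value_at_8hz,
        rate = meas$spike_rate
      )
    }
    before <- run_one(bg)
    after <- run_one(combine_inputs(bg, protocol))
    tibble::tibble(
      replicate = r,
      psd8_before = before$psd8, psd8_after = after$psd8,
      delta_psd8 = after$psd8 - before$psd8,
      rate_before = before$rate, rate_after = after$rate
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("theta_response", class(out))
  out
}
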