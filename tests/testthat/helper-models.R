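# Shared fixtures, built once per test run ----------------------------------

.fixtures <- new.env(parent = emptyenv())

# fully calibrated model (passive Ri target + noise sigma target); cached
# because calibration runs a few dozen 10 s simulations
calibrated_model <- function(variant = "AType+") {
  key <- paste0("model_", variant)
  if (is.null(.fixtures[[key]])) {
    mod <- build_model(variant)
    mod <- calibrate_passive(mod)
    mod <- calibrate_noise(mod)
    .fixtures[[key]] <- mod
  }
  .fixtures[[key]]
}

fixture_morphology <- function() {
  if (is.null(.fixtures$morph)) .fixtures$morph <- build_fixture_morphology()
  .fixtures$morph
}

fixture_bank <- function() {
  if (is.null(.fixtures$bank)) {
    .fixtures$bank <- build_synapse_bank(fixture_morphology())
  }
  .fixtures$bank
}

# passive single-compartment cell with a chosen total leak conductance
passive_toy <- function(g_total_nS = 2.5, e_leak = -70) {
  m <- single_compartment_morphology()
  area_cm2 <- pi * 10 * 10 * 1e-8
  g_dens <- g_total_nS * 1e-6 / area_cm2 # nS -> mS, over cm^2
  mod <- build_model("AType+",
    morphology = m, g_leak = g_dens,
    e_leak = e_leak
  )
  mod$channels[, c("g_nat", "g_nap", "g_ka", "g_kdrf")] <- 0
  mod
}

# unbranched passive chain (soma + n-1 dendritic compartments)
passive_chain <- function(n = 3, g_leak = 0.05, diam = 2, len = 50) {
  stopifnot(n >= 2)
  morph <- tibble::tibble(
    id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1)),
    length = c(10, rep(len, n - 1)),
    diam = c(10, rep(diam, n - 1)),
    path_distance = c(0, (seq_len(n - 1) - 0.5) * len),
    region = c("soma", rep("dendrite", n - 1))
  )
  mod <- build_model("AType+", morphology = ivlsim:::new_morphology(morph),
    g_leak = g_leak)
  mod$channels[, c("g_nat", "g_nap", "g_ka", "g_kdrf")] <- 0
  mod
}

# an input_assignment wiring the given spike train to one synapse slot row
single_synapse_input <- function(slot, times) {
  structure(
    list(
      actives = dplyr::mutate(slot, train_id = 1L, group_id = 1L),
      trains = list(times)
    ),
    class = "input_assignment"
  )
}

# synthetic voltage trace with triangular spikes riding a baseline
triangular_spike_trace <- function(baseline = -70, peak = 10,
                                   spike_times = c(300, 600),
                                   half_width = 1.5,
                                   duration = 1000, dt = 0.1) {
  t <- seq(0, duration, by = dt)
  v <- rep(baseline, length(t))
  for (t0 in spike_times) {
    idx <- abs(t - t0) <= half_width
    v[idx] <- baseline + (peak - baseline) * (1 - abs(t[idx] - t0) / half_width)
  }
  structure(tibble::tibble(time = t, vm = v), class = c("ivl_trace", class(tibble::tibble())))
}
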