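test_that("a flat trace yields no spikes and an unchanged subthreshold trace", {
  tr <- tibble::tibble(time = seq(0, 1000, 0.1), vm = -70)
  out <- detect_and_cut_spikes(tr)
  expect_equal(nrow(out$spikes), 0)
  expect_equal(nrow(out$subthreshold), nrow(tr))
})

test_that("triangular test spikes are detected, measured, and cut", {
  tr <- triangular_spike_trace(baseline = -70, peak = 10, spike_times = c(300, 600))
  out <- detect_and_cut_spikes(tr)
  expect_equal(nrow(out$spikes), 2)
  expect_equal(out$spikes$amplitude, c(80, 80), tolerance = 1e-6)
  expect_equal(out$spikes$time, c(300, 600), tolerance = 0.11)
  expect_equal(mean(out$subthreshold$vm), -70)
})

test_that("shrunken spikes measure amplitude from the onset voltage", {
  # a depolarization-block-like spikelet: -60 mV baseline, -35 mV peak
  # steep enough (50 mV/ms) for the derivative onset criterion
  tr <- triangular_spike_trace(
    baseline = -60, peak = -35, spike_times = 500,
    half_width = 0.5
  )
  out <- detect_and_cut_spikes(tr, threshold = -45)
  expect_equal(nrow(out$spikes), 1)
  expect_equal(out$spikes$amplitude, 25, tolerance = 1e-6)
  expect_lt(out$spikes$amplitude, 40) # would count toward the DB term
})

test_that("subthreshold statistics match analytic references", {
  t <- seq(1000, 10000, 0.1)
  flat <- structure(tibble::tibble(time = t, vm = -70),
    class = c("ivl_trace", "tbl_df", "tbl", "data.frame")
  )
  m <- summarize_trace(flat)
  expect_equal(m$mean_sub_vm, -70)
  expect_equal(m$sigma_sub_vm, 0)
  expect_equal(m$isi_cv, 0)
  expect_equal(m$n_spikes, 0)
  sine <- structure(
    tibble::tibble(time = t, vm = -65 + 2 * sin(2 * pi * 5 * t / 1000)),
    class = c("ivl_trace", "tbl_df", "tbl", "data.frame")
  )
  ms <- summarize_trace(sine)
  expect_equal(ms$mean_sub_vm, -65, tolerance = 1e-3)
  expect_equal(ms$sigma_sub_vm, 2 / sqrt(2), tolerance = 1e-3)
})

test_that("ISI coefficient of variation separates periodic from Poisson", {
  periodic <- triangular_spike_trace(
    spike_times = seq(1200, 9800, by = 100),
    duration = 10000
  )
  mp <- summarize_trace(periodic)
  expect_equal(mp$isi_cv, 0, tolerance = 1e-6)
  set.seed(123)
  times <- 1000 + cumsum(stats::rexp(1000, rate = 1))
  # spike train alone: feed times through the cv definition used internally
  isis <- diff(times)
  expect_equal(sd(isis) / mean(isis), 1.0, tolerance = 0.1)
  # fewer than 3 spikes: cv defined as 0
  two <- triangular_spike_trace(spike_times = c(2000, 3000), duration = 10000)
  expect_equal(summarize_trace(two)$isi_cv, 0)
})

test_that("cutting spikes does not inflate the subthreshold spread", {
  tr <- triangular_spike_trace(
    baseline = -65, peak = 15,
    spike_times = seq(1500, 9500, by = 500), duration = 10000
  )
  cut_sd <- summarize_trace(tr)$sigma_sub_vm
  raw_sd <- sd(tr$vm[tr$time >= 1000])
  expect_lte(cut_sd, raw_sd)
})

test_that("the IVL conditional matches its full truth table", {
  combos <- expand.grid(vm = c(-60, -70), sd = c(3, 1), cv = c(1, 0.3),
    amp = c(55, 30))
  for (i in seq_len(nrow(combos))) {
    cs <- combos[i, ]
    expected <- (cs$vm > -66.7) + (cs$sd > 2.2) + (cs$cv > 0.8) - 4 * (cs$amp < 40)
    got <- ivl_metric(list(
      mean_sub_vm = cs$vm, sigma_sub_vm = cs$sd,
      isi_cv = cs$cv, mean_spike_amp = cs$amp
    ))
    expect_equal(got$ivl_metric, expected)
    expect_equal(
      got$state,
      if (expected == 3) "IVL" else if (expected == 0) "NIVL"
      else if (expected < 0) "DB" else "PARTIAL"
    )
  }
})

test_that("printed IVL anchors and the no-spike convention hold", {
  expect_equal(ivl_metric(list(
    mean_sub_vm = -60, sigma_sub_vm = 3, isi_cv = 1,
    mean_spike_amp = 55
  ))$state, "IVL")
  expect_equal(ivl_metric(list(
    mean_sub_vm = -70, sigma_sub_vm = 1, isi_cv = 0.3,
    mean_spike_amp = 55
  ))$state, "NIVL")
  db <- ivl_metric(list(
    mean_sub_vm = -55, sigma_sub_vm = 4, isi_cv = 1.2,
    mean_spike_amp = 30
  ))
  expect_equal(db$ivl_metric, -1)
  expect_equal(db$state, "DB")
  # a spikeless trace is never DB and cannot be IVL
  silent <- ivl_metric(list(
    mean_sub_vm = -60, sigma_sub_vm = 3, isi_cv = 0,
    mean_spike_amp = NA_real_
  ))
  expect_equal(silent$ivl_metric, 2)
  expect_equal(silent$state, "PARTIAL")
})

test_that("input resistance of a passive toy matches 1/G", {
  toy <- passive_toy(g_total_nS = 2.5)
  r <- input_resistance(toy)
  expect_equal(r$r_in, 400, tolerance = 0.01)
  r2 <- input_resistance(toy, i_inj = -0.2)
  expect_equal(r2$r_in, r$r_in, tolerance = 1e-6) # linearity
  expect_error(input_resistance(toy, i_inj = 0), "nonzero")
})

test_that("spike-train PSD concentrates power at the drive frequency", {
  st <- seq(1000, 9999, by = 125) # perfectly periodic 8 Hz train
  p <- spike_psd(st)
  expect_equal(p$n_spikes, 72)
  expect_lt(abs(p$frequency_at_8hz - 8), 0.5)
  band <- p$psd[p$psd$frequency >= 1 & p$psd$frequency <= 50, ]
  expect_gte(p$value_at_8hz, max(band$power) - 1e-9)
  expect_true(all(p$psd$power >= 0))
})

test_that("empty and homogeneous trains give flat spectra", {
  p0 <- spike_psd(numeric(0))
  expect_true(all(p0$psd$power == 0))
  flat_ok <- vapply(1:100, function(s) {
    st <- sample_spike_train(20, 10000, seed = derive_seed(99, s))
    p <- spike_psd(st)
    band <- p$psd[p$psd$frequency >= 1 & p$psd$frequency <= 50, ]
    p$value_at_8hz <= 3 * stats::median(band$power)
  }, logical(1))
  expect_gte(sum(flat_ok), 95)
})
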