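test_that("clamp configurations enforce the holding-potential conventions", {
  ce <- clamp_config("excitatory", "method1")
  expect_equal(ce$v_hold, -70)
  expect_equal(ce$e_rev, 0)
  ci <- clamp_config("inhibitory", "method2")
  expect_equal(ci$v_hold, 0)
  expect_equal(ci$e_rev, -70)
  expect_error(clamp_config("excitatory", v_hold = 0), "driving force")
})

test_that("somatic clamp recovers the synaptic kernel on one compartment", {
  toy <- passive_toy()
  slot <- tibble::tibble(
    slot_id = 1L, compartment_id = 1L, kind = "excitatory",
    zone = "proximal", distance = 0, weight = 0.5,
    tau_r = 2.9936e-4, tau_d = 2.4216, e_rev = 0
  )
  inp <- single_synapse_input(slot, times = c(100, 140))
  g1 <- isolate_conductance(toy, inp, clamp_config("excitatory", "method1"),
    duration = 300
  )
  g2 <- isolate_conductance(toy, inp, clamp_config("excitatory", "method2"),
    duration = 300
  )
  k <- conductance_kernel(slot, c(100, 140), g1$time)
  expect_lt(abs(max(g1$g) - max(k$g)) / max(k$g), 0.02)
  # no cable: the two isolation methods agree exactly
  expect_equal(g1$g, g2$g, tolerance = 1e-12)
})

test_that("without inputs the isolated conductance is zero", {
  toy <- passive_toy()
  empty <- structure(
    list(actives = fixture_bank()[0, ], trains = list()),
    class = "input_assignment"
  )
  g <- isolate_conductance(toy, empty, clamp_config("excitatory", "method1"),
    duration = 200
  )
  expect_lt(max(abs(g$g)), 1e-9)
})

test_that("space clamp depresses method-2 excitatory conductance on a cable", {
  mod <- calibrated_model("AType+")
  seeds <- scenario_seeds(314L)
  inputs <- scenario_inputs(mod, 10, 60, 144, 120,
    k_exc = 9, k_inh = 4,
    seeds = seeds, duration = 2000
  )
  g1 <- isolate_conductance(mod, inputs, clamp_config("excitatory", "method1"),
    duration = 2000
  )
  g2 <- isolate_conductance(mod, inputs, clamp_config("excitatory", "method2"),
    duration = 2000
  )
  w <- g1$time >= 500
  expect_lt(mean(g2$g[w]), mean(g1$g[w]))
})

test_that("element-wise E/I ratio behaves like a conditioned mean", {
  t <- seq(1000, 10000, 0.1)
  g <- tibble::tibble(time = t, g_exc = 2, g_inh = 2)
  expect_equal(ei_ratio(g)$ei_ratio, 1)
  g$g_exc <- 0
  expect_equal(ei_ratio(g)$ei_ratio, 0)
  g$g_inh <- 1 + 0.5 * sin(t / 50)
  g$g_exc <- 2 * g$g_inh
  expect_equal(ei_ratio(g)$ei_ratio, 2)
  # scale equivariance
  g3 <- g
  g3$g_exc <- 3 * g$g_exc
  expect_equal(ei_ratio(g3)$ei_ratio, 3 * ei_ratio(g)$ei_ratio)
  # floor exclusion and the all-below-floor case
  g$g_inh[seq(1, nrow(g), by = 2)] <- 0
  r <- ei_ratio(g)
  expect_equal(r$excluded_fraction, 0.5, tolerance = 1e-3)
  g$g_inh <- 0
  expect_true(is.na(ei_ratio(g)$ei_ratio))
})

test_that("theta-cycle averaging stacks exactly 72 cycles of 125 ms", {
  t <- seq(0, 10000, 0.1)
  tr <- tibble::tibble(time = t, vm = sin(2 * pi * 8 * t / 1000))
  ca <- theta_cycle_average(tr)
  expect_equal(attr(ca, "n_cycles"), 72)
  expect_equal(nrow(ca), 1250) # 125 ms at 0.1 ms sampling
  expect_lt(max(ca$sd), 1e-9) # exact periodicity
  expect_equal(max(ca$mean), 1, tolerance = 1e-4)
  const <- tibble::tibble(time = t, vm = -63)
  cc <- theta_cycle_average(const)
  expect_true(all(cc$mean == -63) && all(cc$sd == 0))
  expect_error(
    theta_cycle_average(tr, window = c(1000, 9990)),
    "whole number"
  )
})

test_that("theta input estimation returns the minimal passing count", {
  mod <- calibrated_model("AType+")
  # contract check through the evaluation hook: criteria met from n = 7
  evals <- integer(0)
  res <- estimate_theta_inputs(mod,
    zone = "proximal", kind = "excitatory",
    eval_fun = function(n) {
      evals <<- c(evals, n)
      list(psd8 = if (n >= 7) 80 else 10, n_spikes = 5 * n)
    }
  )
  expect_equal(res$count, 7)
  expect_equal(evals, 1:7) # incremented one synapse at a time
  # inhibitory criteria: needs power above 80 and spikes below 240
  res_i <- estimate_theta_inputs(mod,
    zone = "distal", kind = "inhibitory",
    holding_nA = 0.1,
    eval_fun = function(n) list(psd8 = 30 * n, n_spikes = 300 - 30 * n)
  )
  expect_equal(res_i$count, 3)
  expect_error(
    estimate_theta_inputs(mod,
      zone = "proximal", kind = "excitatory",
      cap = 5, eval_fun = function(n) list(psd8 = 0, n_spikes = 0)
    ),
    "50 spikes"
  )
})

test_that("an empty theta protocol leaves the response unchanged", {
  mod <- calibrated_model("AType+")
  pops <- theta_populations()[0, ]
  proto <- build_theta_protocol(mod$bank, pops)
  scen <- tibble::tibble(
    f_exc = 5, f_inh = 10, n_exc = 72, n_inh = 8,
    k_exc = 9, k_inh = 4, seed = 11L
  )
  resp <- theta_response(mod, scen, protocol = proto, n_reseeds = 1,
    duration = 2000)
  expect_equal(resp$psd8_before, resp$psd8_after)
  expect_equal(resp$delta_psd8, 0)
})
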