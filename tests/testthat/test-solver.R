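test_that("passive single compartment follows the closed-form RC relaxation", {
  toy <- passive_toy(g_total_nS = 0.5)
  area <- pi * 10 * 10 * 1e-8 # cm^2
  tau <- 1 * area * 1e-6 / (0.5e-9) * 1000 # C/g in ms (~6.3 ms)
  tr <- simulate_model(toy,
    duration = 100, dt = 0.025, record_dt = 0.025,
    stim = tibble::tibble(start = 0, end = 100, amp_nA = 0.0025)
  )
  r_in <- 1 / 0.5 * 1000 # MOhm
  v_inf <- -70 + 0.0025 * r_in
  v_an <- v_inf + (-70 - v_inf) * exp(-tr$time / tau)
  expect_lt(max(abs(tr$vm - v_an)), 0.01)
})

test_that("with no inputs the membrane sits at the leak reversal", {
  toy <- passive_toy()
  tr <- simulate_model(toy, duration = 200)
  expect_equal(max(abs(tr$vm - (-70))), 0, tolerance = 1e-9)
})

test_that("time stepping converges at first order (Richardson)", {
  toy <- passive_toy(g_total_nS = 0.5)
  stim <- tibble::tibble(start = 0, end = 100, amp_nA = 0.005)
  final_vm <- function(dt) {
    tr <- simulate_model(toy,
      duration = 50, dt = dt, record_dt = 0.1,
      stim = stim
    )
    tail(tr$vm, 1)
  }
  v1 <- final_vm(0.1)
  v2 <- final_vm(0.05)
  v3 <- final_vm(0.025)
  # first order: successive differences shrink by ~2
  expect_lt(abs(v2 - v3), abs(v1 - v2))
  expect_equal(abs(v1 - v2) / abs(v2 - v3), 2, tolerance = 0.5)
})

test_that("steady state of a passive chain matches the direct linear solve", {
  mod <- passive_chain(n = 3)
  geom <- mod$geometry
  g_leak <- mod$g_leak * geom$area_cm2 # mS per compartment
  i_inj <- 0.01 # nA at soma
  # brute-force oracle: solve G v = b for the steady state
  g12 <- geom$g_ax_mS[2]
  g23 <- geom$g_ax_mS[3]
  G <- rbind(
    c(g_leak[1] + g12, -g12, 0),
    c(-g12, g_leak[2] + g12 + g23, -g23),
    c(0, -g23, g_leak[3] + g23)
  )
  b <- g_leak * (-70)
  b[1] <- b[1] + i_inj * 1e-3
  v_oracle <- solve(G, b)
  tr <- simulate_model(mod,
    duration = 2000, record = "all",
    stim = tibble::tibble(start = 0, end = 2000, amp_nA = i_inj)
  )
  v_end <- attr(tr, "vm_all")[nrow(tr), ]
  expect_equal(v_end, v_oracle, tolerance = 2e-4)
  # implied input resistance within 2%
  ri_sim <- (tail(tr$vm, 1) - (-70)) / i_inj
  ri_oracle <- (v_oracle[1] - (-70)) / i_inj
  expect_lt(abs(ri_sim - ri_oracle) / ri_oracle, 0.02)
})

test_that("membrane + axial currents balance the injected current", {
  mod <- passive_chain(n = 4)
  geom <- mod$geometry
  dt <- 0.025
  tr <- simulate_model(mod,
    duration = 5, dt = dt, record_dt = dt, record = "all",
    stim = tibble::tibble(start = 0, end = 5, amp_nA = 0.02)
  )
  v <- attr(tr, "vm_all")
  cap <- mod$cm * geom$area_cm2
  g_leak <- mod$g_leak * geom$area_cm2
  parent <- c(NA, 1, 2, 3)
  for (k in 2:nrow(v)) {
    vn <- v[k, ]
    vo <- v[k - 1, ]
    resid <- cap / dt * (vn - vo) + g_leak * (vn - (-70))
    for (i in 2:4) {
      ax <- geom$g_ax_mS[i] * (vn[i] - vn[parent[i]])
      resid[i] <- resid[i] + ax
      resid[parent[i]] <- resid[parent[i]] - ax
    }
    resid[1] <- resid[1] - 0.02e-3 # injected current, uA
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("identical seeds give bit-identical noisy traces", {
  toy <- passive_toy()
  t1 <- simulate_model(toy, duration = 500, noise = TRUE, noise_sigma = 5, noise_seed = 11)
  t2 <- simulate_model(toy, duration = 500, noise = TRUE, noise_sigma = 5, noise_seed = 11)
  t3 <- simulate_model(toy, duration = 500, noise = TRUE, noise_sigma = 5, noise_seed = 12)
  expect_identical(t1$vm, t2$vm)
  expect_false(identical(t1$vm, t3$vm))
})

test_that("solver guards against inconsistent step configuration", {
  toy <- passive_toy()
  expect_error(simulate_model(toy, duration = 100.01, dt = 0.025), "multiple")
  expect_error(simulate_model(toy, duration = 100, record_dt = 0.03), "multiple")
  expect_error(simulate_model(toy, duration = 100, dt = -1), "positive")
})
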