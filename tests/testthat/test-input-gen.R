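test_that("spike count equals rate x duration exactly", {
  expect_length(sample_spike_train(100, 10000, seed = 1), 1000)
  expect_length(sample_spike_train(5, 10000, seed = 1), 50)
  expect_length(sample_spike_train(0, 10000, seed = 1), 0)
  st <- sample_spike_train(30, 10000, seed = 7)
  expect_true(!is.unsorted(st))
  expect_true(all(st >= 0 & st <= 10000))
  expect_error(sample_spike_train(-1), "non-negative")
})

test_that("trains are reproducible per seed and differ across seeds", {
  expect_identical(
    sample_spike_train(20, 10000, seed = 42),
    sample_spike_train(20, 10000, seed = 42)
  )
  expect_false(identical(
    sample_spike_train(20, 10000, seed = 42),
    sample_spike_train(20, 10000, seed = 43)
  ))
})

test_that("sorted-uniform inter-spike intervals are exponential-like", {
  # Kolmogorov-Smirnov against a fitted exponential at alpha = 0.01
  pass <- vapply(1:100, function(s) {
    isis <- diff(sample_spike_train(100, 10000, seed = s))
    suppressWarnings(
      stats::ks.test(isis, "pexp", rate = 1 / mean(isis))$p.value
    ) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 95)
})

test_that("active-synapse selection splits excitatory actives across zones", {
  bank <- fixture_bank()
  a <- select_active(bank, 144, 8, seed = 1)
  act <- a$actives
  expect_equal(sum(act$kind == "excitatory" & act$zone == "proximal"), 72)
  expect_equal(sum(act$kind == "excitatory" & act$zone == "distal"), 72)
  expect_equal(sum(act$kind == "inhibitory"), 8)
  expect_false(any(duplicated(act$slot_id)))
})

test_that("exhaustive selection activates every slot exactly once", {
  bank <- fixture_bank()
  a <- select_active(bank, 1530, 344, seed = 3)
  expect_setequal(a$actives$slot_id, bank$slot_id)
})

test_that("selection is seed-reproducible and rejects invalid requests", {
  bank <- fixture_bank()
  a1 <- select_active(bank, 90, 12, seed = 5)
  a2 <- select_active(bank, 90, 12, seed = 5)
  a3 <- select_active(bank, 90, 12, seed = 6)
  expect_identical(a1$actives$slot_id, a2$actives$slot_id)
  expect_false(identical(a1$actives$slot_id, a3$actives$slot_id))
  expect_error(select_active(bank, 143, 8), "even")
  expect_error(select_active(bank, 1532, 8), "capacity")
  expect_error(select_active(bank, 144, 400), "capacity")
})

test_that("common-input grouping yields k-sized groups plus a remainder", {
  expect_equal(common_group_sizes(20, 8), c(8L, 8L, 4L))
  expect_equal(common_group_sizes(3, 10), 3L)
  expect_equal(common_group_sizes(12, 1), rep(1L, 12))
  expect_equal(common_group_sizes(0, 4), integer(0))

  bank <- fixture_bank()
  a <- select_active(bank, 40, 20, seed = 2) |>
    group_common(f_exc = 10, f_inh = 20, k_exc = 9, k_inh = 8, seed = 2)
  inh <- a$actives[a$actives$kind == "inhibitory", ]
  expect_equal(sort(as.integer(table(inh$group_id)), decreasing = TRUE),
    c(8L, 8L, 4L))
  exc <- a$actives[a$actives$kind == "excitatory", ]
  expect_equal(length(unique(exc$train_id)), ceiling(40 / 9))
  # group members reference the identical train object
  g1 <- inh$train_id[inh$group_id == inh$group_id[1]]
  expect_equal(length(unique(g1)), 1)
})

test_that("independent inputs (k = 1) give every synapse its own train", {
  bank <- fixture_bank()
  a <- select_active(bank, 18, 4, seed = 9) |>
    group_common(f_exc = 5, f_inh = 10, k_exc = 1, k_inh = 1, seed = 9)
  expect_equal(length(unique(a$actives$train_id)), 22)
  lens <- lengths(a$trains[unlist(unique(
    a$actives$train_id[a$actives$kind == "excitatory"]
  ))])
  expect_true(all(lens == 50)) # 5 Hz x 10 s
})

test_that("theta trains are deterministic quarter-cycle combs", {
  t0 <- theta_spike_times(0, 10000)
  expect_length(t0, 80)
  expect_equal(t0[1:3], c(0, 125, 250))
  t90 <- theta_spike_times(90, 10000)
  expect_equal(t90, t0 + 31.25)
  expect_error(theta_spike_times(0, 10030), "multiple")
})

test_that("theta protocol wires populations to zone-matched slots", {
  bank <- fixture_bank()
  proto <- build_theta_protocol(bank)
  pops <- theta_populations()
  expect_equal(nrow(proto$actives), sum(pops$n_synapses)) # 27*2 + 8*5
  ca3 <- proto$actives[proto$actives$population == "CA3", ]
  expect_equal(nrow(ca3), 27)
  expect_true(all(ca3$kind == "excitatory" & ca3$zone == "proximal"))
  ec3 <- proto$actives[proto$actives$population == "EC3", ]
  expect_true(all(ec3$zone == "distal"))
  expect_equal(proto$trains[[which(pops$name == "EC3")]][1], 62.5) # 180 deg
  # deterministic: identical on rebuild
  proto2 <- build_theta_protocol(bank)
  expect_identical(proto$actives$slot_id, proto2$actives$slot_id)
})

test_that("variant-specific theta counts and impossible populations", {
  bank <- fixture_bank()
  pops <- theta_populations()
  pops$n_synapses[pops$name == "EC3"] <- 18L # AType- distal excitatory count
  proto <- build_theta_protocol(bank, pops)
  expect_equal(sum(proto$actives$population == "EC3"), 18)
  pops$n_synapses[1] <- 10000L
  expect_error(build_theta_protocol(bank, pops), "slots")
})

test_that("assignments can be layered and exported as a raster", {
  bank <- fixture_bank()
  bg <- select_active(bank, 18, 4, seed = 1) |>
    group_common(5, 10, seed = 1)
  both <- combine_inputs(bg, build_theta_protocol(bank))
  expect_equal(nrow(both$actives), 22 + 94)
  expect_equal(length(both$trains), 22 + 7)
  r <- raster_export(bg)
  expect_named(r, c("slot_id", "spike_time_ms"))
  expect_equal(nrow(r), sum(lengths(bg$trains)[bg$actives$train_id]))
})
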