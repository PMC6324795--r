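# 4-D input-grid sweeps, pool division, and CBDR images ----------------------
#
# The production grid crosses excitatory rate (0-30 Hz by 5), inhibitory
# rate (0-100 Hz by 10), excitatory synapse count (18-1530 by 18) and
# inhibitory synapse count (4-344 by 4): 7 x 11 x 85 x 86 = 562,870 core
# combinations, times 2 model variants and 4 common-input modes =
# 4,502,960 ten-second simulations. Desk-scale work runs the same machinery
# on coarsened grids.

.grid_max <- c(f_exc = 30, f_inh = 100, n_exc = 1530, n_inh = 344)

#' The full production sweep grid
#'
#' @param variants Model variants included.
#' @param common_modes List of `c(k_exc, k_inh)` common-input modes.
#' @return A `sweep_grid` list with the four axis value vectors, the
#'   variants, the common modes, and the axis maxima used for
#'   normalization.
#' @export
default_sweep_grid <- function(variants = c("AType+", "AType-"),
                               common_modes = list(
                                 c(1, 1), c(9, 1), c(1, 4), c(9, 4)
                               )) {
  sweep_grid(
    f_exc = seq(0, 30, by = 5),
    f_inh = seq(0, 100, by = 10),
    n_exc = seq(18, 1530, by = 18),
    n_inh = seq(4, 344, by = 4),
    variants = variants,
    common_modes = common_modes
  )
}

#' Construct a sweep grid
#'
#' @param f_exc,f_inh Rate axes (Hz).
#' @param n_exc,n_inh Synapse-count axes.
#' @param variants Model variants.
#' @param common_modes List of `c(k_exc, k_inh)` pairs.
#' @param maxima Normalization maxima for [ei_metric_1()]; defaults to the
#'   production-grid maxima.
#' @return A `sweep_grid` object.
#' @export
sweep_grid <- function(f_exc, f_inh, n_exc, n_inh,
                       variants = "AType+",
                       common_modes = list(c(1, 1)),
                       maxima = .grid_max) {
  if (any(vapply(list(f_exc, f_inh, n_exc, n_inh), length, 1L) == 0)) {
    abort("all four grid axes need at least one value")
  }
  if (any(n_exc %% 2 != 0)) abort("`n_exc` values must be even")
  structure(
    list(
      f_exc = sort(f_exc), f_inh = sort(f_inh),
      n_exc = sort(n_exc), n_inh = sort(n_inh),
      variants = variants, common_modes = common_modes,
      maxima = maxima
    ),
    class = "sweep_grid"
  )
}

#' Number of scenarios in a grid
#'
#' @param grid A `sweep_grid`.
#' @return Scenario count (core combinations x variants x common modes).
#' @examples
#' grid_size(default_sweep_grid()) # 4502960
#' @export
grid_size <- function(grid) {
  length(grid$f_exc) * length(grid$f_inh) * length(grid$n_exc) *
    length(grid$n_inh) * length(grid$variants) * length(grid$common_modes)
}

#' Enumerate a sweep grid into an ordered scenario table
#'
#' Scenarios are ordered with the excitatory rate as the outermost key, then
#' inhibitory rate, excitatory count, inhibitory count (the representative
#' search order), within each variant and common mode. Each scenario carries
#' a deterministic seed derived from its coordinates.
#'
#' @param grid A `sweep_grid`.
#' @param seed Base seed folded into every scenario seed.
#' @return Tibble with `variant`, `k_exc`, `k_inh`, `f_exc`, `f_inh`,
#'   `n_exc`, `n_inh`, `seed`.
#' @export
enumerate_grid <- function(grid, seed = 1L) {
  modes <- tibble::tibble(
    k_exc = vapply(grid$common_modes, `[`, numeric(1), 1),
    k_inh = vapply(grid$common_modes, `[`, numeric(1), 2),
    mode_idx = seq_along(grid$common_modes)
  )
  out <- tidyr::expand_grid(
    variant = grid$variants,
    mode_idx = modes$mode_idx,
    f_exc = grid$f_exc,
    f_inh = grid$f_inh,
    n_exc = grid$n_exc,
    n_inh = grid$n_inh
  ) |>
    dplyr::left_join(modes, by = "mode_idx")
  # vectorized seed folding (same scheme as derive_seed) so the full
  # 4.5M-scenario grid enumerates in seconds
  h <- rep(as.double(seed) %% .SEED_MOD, nrow(out))
  for (x in list(
    match(out$variant, unique(grid$variants)), out$k_exc, out$k_inh,
    out$f_exc * 10, out$f_inh * 10, out$n_exc, out$n_inh
  )) {
    h <- (h * 69069 + (as.double(x) %% .SEED_MOD) + 1) %% .SEED_MOD
  }
  out$seed <- as.integer(h + 1)
  out[, c(
    "variant", "k_exc", "k_inh", "f_exc", "f_inh", "n_exc", "n_inh",
    "seed"
  )]
}

# E/I balance metrics ---------------------------------------------------------

#' Normalized excitation-inhibition balance metric
#'
#' `0.5 * (n_exc/n_max_exc + f_exc/f_max_exc - n_inh/n_max_inh -
#' f_inh/f_max_inh)`: -1 is purely inhibitory-dominant, +1 purely
#' excitatory-dominant.
#'
#' @param scenarios Data frame with `f_exc`, `f_inh`, `n_exc`, `n_inh`.
#' @param maxima Named axis maxima (defaults: production grid).
#' @return Numeric vector in `[-1, 1]`.
#' @export
ei_metric_1 <- function(scenarios, maxima = .grid_max) {
  0.5 * (scenarios$n_exc / maxima[["n_exc"]] +
    scenarios$f_exc / maxima[["f_exc"]] -
    scenarios$n_inh / maxima[["n_inh"]] -
    scenarios$f_inh / maxima[["f_inh"]])
}

#' Cumulative-rate excitation-inhibition balance metric
#'
#' `f_exc * n_exc - f_inh * n_inh` (Hz x synapses); negative values are
#' inhibitory-dominant.
#'
#' @param scenarios Data frame with `f_exc`, `f_inh`, `n_exc`, `n_inh`.
#' @return Numeric vector.
#' @export
ei_metric_2 <- function(scenarios) {
  scenarios$f_exc * scenarios$n_exc - scenarios$f_inh * scenarios$n_inh
}

# Pool division ---------------------------------------------------------------

.pool_ranges <- list(
  f_exc = list(low = c(0, 15), high = c(20, 30)),
  f_inh = list(low = c(0, 50), high = c(60, 100)),
  n_exc = list(low = c(18, 765), high = c(783, 1530)),
  n_inh = list(low = c(4, 172), high = c(176, 344))
)

pool_letter <- function(x, param) {
  r <- .pool_ranges[[param]]
  dplyr::case_when(
    x >= r$low[1] & x <= r$low[2] ~ "L",
    x >= r$high[1] & x <= r$high[2] ~ "H",
    TRUE ~ NA_character_
  )
}

#' Assign scenarios to the 16 low/high parameter pools
#'
#' Each of the four input parameters is split into a low and a high range
#' (rates: 0-15 / 20-30 Hz excitatory, 0-50 / 60-100 Hz inhibitory; counts:
#' 18-765 / 783-1530 excitatory, 4-172 / 176-344 inhibitory). The label
#' orders the letters as (inhibitory count, excitatory count, inhibitory
#' rate, excitatory rate), e.g. `"LLLL"` or `"HHLL"`.
#'
#' @param scenarios Data frame with `f_exc`, `f_inh`, `n_exc`, `n_inh`.
#' @return Character vector of pool labels.
#' @examples
#' assign_pool(data.frame(f_exc = 10, f_inh = 30, n_exc = 400, n_inh = 100))
#' @export
assign_pool <- function(scenarios) {
  l <- lapply(
    c("n_inh", "n_exc", "f_inh", "f_exc"),
    function(p) pool_letter(scenarios[[p]], p)
  )
  if (anyNA(unlist(l))) {
    abort("scenario value falls in neither the low nor the high pool range")
  }
  paste0(l[[1]], l[[2]], l[[3]], l[[4]])
}

# Scenario execution ----------------------------------------------------------

#' Realize and simulate one input scenario
#'
#' Draws the scenario's synapse placement and spike trains from its seed
#' streams, simulates the model, and summarizes the trace into measurements,
#' IVL metric/state, and E/I balance metrics.
#'
#' @param model A calibrated `is3_model`.
#' @param f_exc,f_inh Presynaptic rates (Hz).
#' @param n_exc,n_inh Active synapse counts.
#' @param k_exc,k_inh Common-input group sizes.
#' @param seed Scenario base seed (placement/spikes/noise streams derive
#'   from it).
#' @param replicate Replicate index for re-seeded repeats.
#' @param duration Simulation length (ms).
#' @param noise Intrinsic noise on? Defaults to the model's setting.
#' @param window Analysis window; defaults to 1000 ms to `duration`.
#' @param keep_trace Attach the voltage trace as an attribute?
#' @param dt,record_dt Solver steps (ms).
#' @return One-row tibble: scenario coordinates, measurements, `ivl_metric`,
#'   `state`, `ei1`, `ei2`.
#' @export
run_scenario <- function(model, f_exc, f_inh, n_exc, n_inh,
                         k_exc = 1, k_inh = 1, seed = 1L, replicate = 1L,
                         duration = 10000, noise = model$noise$enabled,
                         window = c(1000, duration), keep_trace = FALSE,
                         dt = 0.025, record_dt = 0.1) {
  seeds <- scenario_seeds(seed, replicate)
  inputs <- scenario_inputs(model, f_exc, f_inh, n_exc, n_inh,
    k_exc, k_inh,
    seeds = seeds, duration = duration
  )
  tr <- simulate_model(model, inputs,
    duration = duration, dt = dt,
    record_dt = record_dt, noise = noise, noise_seed = seeds$noise
  )
  meas <- summarize_trace(tr, window = window)
  assess <- ivl_metric(meas)
  coords <- tibble::tibble(
    f_exc = f_exc, f_inh = f_inh, n_exc = n_exc, n_inh = n_inh,
    k_exc = k_exc, k_inh = k_inh, seed = seed, replicate = replicate,
    variant = model$variant
  )
  out <- dplyr::bind_cols(coords, meas, assess)
  out$ei1 <- ei_metric_1(out)
  out$ei2 <- ei_metric_2(out)
  if (keep_trace) attr(out, "trace") <- tr
  out
}

#' Build the synaptic input realization of a scenario
#'
#' @inheritParams run_scenario
#' @param seeds Named seed streams from [scenario_seeds()].
#' @return An `input_assignment`.
#' @export
scenario_inputs <- function(model, f_exc, f_inh, n_exc, n_inh,
                            k_exc = 1, k_inh = 1,
                            seeds = scenario_seeds(1L), duration = 10000) {
  select_active(model$bank, n_exc, n_inh, seed = seeds$placement) |>
    group_common(f_exc, f_inh, k_exc, k_inh,
      duration = duration,
      seed = seeds$spikes
    )
}

#' Run a sweep over an enumerated scenario table
#'
#' @param model A calibrated `is3_model` (its variant must match the
#'   scenario rows, or pass a named list of models keyed by variant).
#' @param scenarios Tibble from [enumerate_grid()] (or any tibble with the
#'   scenario columns).
#' @param duration Simulation length per scenario (ms).
#' @param noise Intrinsic noise on?
#' @param progress Print a progress line every `progress` scenarios
#'   (0 = quiet).
#' @param ... Passed on to [run_scenario()].
#' @return Tibble of class `sweep_result`: one row per scenario.
#' @export
run_sweep <- function(model, scenarios, duration = 10000, noise = TRUE,
                      progress = 0, ...) {
  models <- if (inherits(model, "is3_model")) {
    setNames(list(model), model$variant)
  } else {
    model
  }
  rows <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    s <- scenarios[i, ]
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("sweep: %d / %d", i, nrow(scenarios)))
    }
    run_scenario(models[[s$variant]],
      f_exc = s$f_exc, f_inh = s$f_inh,
      n_exc = s$n_exc, n_inh = s$n_inh, k_exc = s$k_exc, k_inh = s$k_inh,
      seed = s$seed, duration = duration, noise = noise, ...
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Find a pool's representative scenario
#'
#' Walks the pool's IVL scenarios in the canonical order (excitatory rate,
#' then inhibitory rate, excitatory count, inhibitory count, ascending; seed
#' as the final tie-break) and re-simulates each candidate up to `n_repeats`
#' times with fresh placement and spike-time seeds. The first candidate that
#' is IVL on every repeat is the representative; a candidate that fails any
#' repeat is skipped. Returns `NULL` when the pool has no passing candidate.
#'
#' @param pool_records A `sweep_result` subset (one pool).
#' @param runner Function `(scenario_row, replicate) -> logical` deciding
#'   whether a re-seeded repeat is IVL. Defaults to re-running the scenario
#'   on `model`.
#' @param model Model used by the default runner.
#' @param n_repeats Consecutive IVL repeats required (10, as in the
#'   representative-selection procedure).
#' @param duration Simulation length for the default runner (ms).
#' @return The representative scenario row, or `NULL`.
#' @export
find_representative <- function(pool_records, runner = NULL, model = NULL,
                                n_repeats = 10, duration = 10000) {
  if (is.null(runner)) {
    if (is.null(model)) abort("supply either `runner` or `model`")
    runner <- function(s, rep) {
      res <- run_scenario(model,
        f_exc = s$f_exc, f_inh = s$f_inh,
        n_exc = s$n_exc, n_inh = s$n_inh, k_exc = s$k_exc,
        k_inh = s$k_inh, seed = s$seed, replicate = rep + 1L,
        duration = duration
      )
      res$state == "IVL"
    }
  }
  cand <- pool_records[pool_records$state == "IVL", ]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  cand <- cand[order(
    cand$f_exc, cand$f_inh, cand$n_exc, cand$n_inh,
    cand$seed
  ), ]
  for (i in seq_len(nrow(cand))) {
    s <- cand[i, ]
    ok <- TRUE
    for (rep in seq_len(n_repeats)) {
      if (!isTRUE(runner(s, rep))) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      return(s)
    }
  }
  NULL
}

# CBDR: clutter-based dimensional reordering ----------------------------------

#' Nest a 4-D sweep into a 2-D CBDR image matrix
#'
#' Rows stack the excitatory rate (outer) over the excitatory synapse count
#' (inner); columns stack the inhibitory rate (outer) over the inhibitory
#' count (inner). Pixel values are the IVL metric. The grid must be complete
#' (one record per combination).
#'
#' @param results A `sweep_result` for one variant and common mode.
#' @param value Column to paint (default `"ivl_metric"`).
#' @return A matrix of class `cbdr_matrix` with axis attributes; use
#'   [cbdr_pixel_to_params()] / [cbdr_params_to_pixel()] to map pixels to
#'   parameters, and [autoplot.cbdr_matrix()] to render it.
#' @export
cbdr_matrix <- function(results, value = "ivl_metric") {
  ax <- list(
    f_exc = sort(unique(results$f_exc)),
    n_exc = sort(unique(results$n_exc)),
    f_inh = sort(unique(results$f_inh)),
    n_inh = sort(unique(results$n_inh))
  )
  expected <- prod(lengths(ax))
  key <- paste(results$f_exc, results$n_exc, results$f_inh, results$n_inh)
  full <- tidyr::expand_grid(
    f_exc = ax$f_exc, n_exc = ax$n_exc,
    f_inh = ax$f_inh, n_inh = ax$n_inh
  )
  full_key <- paste(full$f_exc, full$n_exc, full$f_inh, full$n_inh)
  missing <- setdiff(full_key, key)
  if (nrow(results) != expected || length(missing) > 0) {
    abort(paste0(
      "results do not cover the full rectangular grid; missing ",
      length(missing), " points, e.g. ", paste(head(missing, 3), collapse = "; ")
    ))
  }
  nr <- length(ax$f_exc) * length(ax$n_exc)
  nc <- length(ax$f_inh) * length(ax$n_inh)
  row <- (match(results$f_exc, ax$f_exc) - 1L) * length(ax$n_exc) +
    match(results$n_exc, ax$n_exc)
  col <- (match(results$f_inh, ax$f_inh) - 1L) * length(ax$n_inh) +
    match(results$n_inh, ax$n_inh)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(row, col)] <- results[[value]]
  structure(m, axes = ax, value = value, class = "cbdr_matrix")
}

#' Map a CBDR pixel to its four input parameters
#'
#' @param m A `cbdr_matrix`.
#' @param row,col Pixel coordinates (1-based).
#' @return One-row tibble with `f_exc`, `n_exc`, `f_inh`, `n_inh`.
#' @export
cbdr_pixel_to_params <- function(m, row, col) {
  ax <- attr(m, "axes")
  tibble::tibble(
    f_exc = ax$f_exc[(row - 1L) %/% length(ax$n_exc) + 1L],
    n_exc = ax$n_exc[(row - 1L) %% length(ax$n_exc) + 1L],
    f_inh = ax$f_inh[(col - 1L) %/% length(ax$n_inh) + 1L],
    n_inh = ax$n_inh[(col - 1L) %% length(ax$n_inh) + 1L]
  )
}

#' Map input parameters to their CBDR pixel
#'
#' @param m A `cbdr_matrix`.
#' @param f_exc,f_inh,n_exc,n_inh Grid parameter values.
#' @return One-row tibble with `row`, `col`.
#' @export
cbdr_params_to_pixel <- function(m, f_exc, f_inh, n_exc, n_inh) {
  ax <- attr(m, "axes")
  tibble::tibble(
    row = (match(f_exc, ax$f_exc) - 1L) * length(ax$n_exc) +
      match(n_exc, ax$n_exc),
    col = (match(f_inh, ax$f_inh) - 1L) * length(ax$n_inh) +
      match(n_inh, ax$n_inh)
  )
}

#' Write the CBDR scale-bar sidecar
#'
#' Emits the axis nesting as JSON so any pixel of an exported image can be
#' mapped back to its four parameters.
#'
#' @param m A `cbdr_matrix`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cbdr_sidecar <- function(m, path) {
  ax <- attr(m, "axes")
  jsonlite::write_json(
    list(
      nesting = list(
        rows = c("f_exc (outer)", "n_exc (inner)"),
        cols = c("f_inh (outer)", "n_inh (inner)")
      ),
      axes = ax, value = attr(m, "value"),
      dim = dim(m)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
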