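# Simulation front end -------------------------------------------------------

#' Simulate the model under synaptic input, current steps, noise, or clamp
#'
#' Integrates the branched cable equation with backward-Euler time stepping
#' (Hines-ordered direct solve per step, exponential gate integration,
#' event-driven double-exponential synapses). The same (seed, configuration)
#' always yields a bit-identical trace.
#'
#' @param model An `is3_model`.
#' @param inputs An `input_assignment` (see [select_active()],
#'   [group_common()], [build_theta_protocol()]), or `NULL` for no synaptic
#'   input.
#' @param duration Simulation length (ms); must be a multiple of `dt`.
#' @param dt Time step (ms).
#' @param record_dt Recording interval (ms); must be a multiple of `dt`.
#' @param stim Optional tibble of current steps with columns `start`, `end`
#'   (ms) and `amp_nA`, plus optionally `compartment_id` (default: soma).
#' @param noise Inject somatic Gaussian current noise? Defaults to the
#'   model's noise configuration.
#' @param noise_sigma Noise amplitude (pA, per-step scaled by `1/sqrt(dt)`).
#' @param noise_seed Integer seed for the noise stream.
#' @param v_clamp If non-`NULL`, hold the soma at this potential (mV) with an
#'   ideal voltage clamp and record the electrode current.
#' @param passive_only If `TRUE`, zero all active conductances for this run.
#' @param e_leak Optional override of the leak reversal (mV) in all
#'   compartments (used by the conductance-isolation protocol).
#' @param record `"soma"` (default) or `"all"` (per-compartment matrix in
#'   attribute `vm_all`).
#' @param v0 Initial potential (mV); defaults to the (possibly overridden)
#'   leak reversal everywhere.
#' @return A tibble of class `ivl_trace` with columns `time` (ms) and `vm`
#'   (mV, somatic), plus `i_clamp` (nA) when clamped. Attributes: `dt`,
#'   `record_dt`, `duration`, and optionally `vm_all`.
#' @examples
#' mod <- build_model("AType+")
#' tr <- simulate_model(mod, duration = 200)
#' @export
simulate_model <- function(model, inputs = NULL,
                           duration = 10000, dt = 0.025, record_dt = 0.1,
                           stim = NULL,
                           noise = model$noise$enabled,
                           noise_sigma = model$noise$sigma_current,
                           noise_seed = model$noise$seed,
                           v_clamp = NULL,
                           passive_only = FALSE,
                           e_leak = NULL,
                           record = c("soma", "all"),
                           v0 = NULL) {
  record <- match.arg(record)
  stopifnot_scalar(duration, "duration")
  stopifnot_scalar(dt, "dt")
  if (dt <= 0) abort("`dt` must be positive")
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-9) {
    abort("`duration` must be a multiple of `dt`")
  }
  record_every <- round(record_dt / dt)
  if (abs(record_every * dt - record_dt) > 1e-9 || record_every < 1) {
    abort("`record_dt` must be a positive multiple of `dt`")
  }

  m <- model$morphology
  geom <- model$geometry %||% build_geometry(model)
  n <- nrow(m)
  e_leak_vec <- rep(e_leak %||% model$e_leak, n)
  g_leak_mS <- model$g_leak * geom$area_cm2 # mS/cm^2 * cm^2 = mS
  cap_uF <- model$cm * geom$area_cm2

  dens <- model$channels
  scale <- if (passive_only) 0 else 1
  gbar <- function(col) scale * dens[[col]] * geom$area_cm2

  syn <- build_syn_states(model, inputs, dt, n_steps)

  if (is.null(stim)) {
    stim <- tibble::tibble(
      start = numeric(), end = numeric(),
      amp_nA = numeric(), compartment_id = integer()
    )
  }
  if (!"compartment_id" %in% names(stim)) stim$compartment_id <- 1L
  stim_comp0 <- match(stim$compartment_id, m$id) - 1L

  clamp_on <- !is.null(v_clamp)
  v0_vec <- rep(v0 %||% (e_leak %||% model$e_leak), n)
  if (clamp_on) v0_vec[1] <- v_clamp

  out <- .simulate_cable(
    parent = geom$parent0,
    cap_uF = cap_uF,
    g_ax_mS = geom$g_ax_mS,
    g_leak_mS = g_leak_mS,
    e_leak_mV = e_leak_vec,
    g_nat_mS = gbar("g_nat"),
    g_nap_mS = gbar("g_nap"),
    g_ka_mS = gbar("g_ka"),
    g_kdrf_mS = gbar("g_kdrf"),
    e_na = model$e_na,
    e_k = model$e_k,
    syn_comp = syn$comp0,
    syn_tau_r = syn$tau_r,
    syn_tau_d = syn$tau_d,
    syn_e_rev = syn$e_rev,
    ev_step = syn$ev_step,
    ev_state = syn$ev_state,
    ev_amount_nS = syn$ev_amount,
    stim_comp = stim_comp0,
    stim_start = as.double(stim$start),
    stim_end = as.double(stim$end),
    stim_amp_nA = as.double(stim$amp_nA),
    noise_on = isTRUE(noise) && noise_sigma > 0,
    noise_sigma_pA = noise_sigma,
    noise_seed = as.double(noise_seed),
    noise_comp = 0L,
    clamp_on = clamp_on,
    clamp_vhold = if (clamp_on) v_clamp else 0,
    clamp_comp = 0L,
    dt = dt,
    n_steps = n_steps,
    record_every = record_every,
    v0 = v0_vec,
    record_all = record == "all",
    record_clamp = clamp_on
  )

  tr <- tibble::tibble(time = out$time, vm = out$vm)
  if (clamp_on) tr$i_clamp <- out$i_clamp
  attr(tr, "dt") <- dt
  attr(tr, "record_dt") <- record_dt
  attr(tr, "duration") <- duration
  if (record == "all") attr(tr, "vm_all") <- out$vm_all
  class(tr) <- c("ivl_trace", class(tr))
  tr
}

# Aggregate active synapses into per-(compartment, kinetics, reversal)
# conductance states and a sorted event list. Synapses sharing a compartment
# and kinetics class share a state, since their double-exponential dynamics
# are identical and conductances add linearly.
build_syn_states <- function(model, inputs, dt, n_steps) {
  empty <- list(
    comp0 = integer(), tau_r = numeric(), tau_d = numeric(),
    e_rev = numeric(), ev_step = integer(), ev_state = integer(),
    ev_amount = numeric()
  )
  if (is.null(inputs)) return(empty)
  actives <- inputs$actives
  if (is.null(actives) || nrow(actives) == 0) return(empty)

  key <- paste(actives$compartment_id, actives$tau_r, actives$tau_d,
    actives$e_rev,
    sep = "/"
  )
  states <- !duplicated(key)
  state_of <- match(key, key[states])
  st <- actives[states, ]

  fac <- kernel_factor(actives$tau_r, actives$tau_d)
  trains <- inputs$trains[actives$train_id]
  n_per <- lengths(trains)
  times <- unlist(trains, use.names = FALSE)
  idx <- rep.int(seq_len(nrow(actives)), n_per)
  keep <- times >= 0 & times < n_steps * dt
  times <- times[keep]
  idx <- idx[keep]
  step <- pmin(as.integer(round(times / dt)), n_steps - 1L)
  ord <- order(step)
  list(
    comp0 = match(st$compartment_id, model$morphology$id) - 1L,
    tau_r = st$tau_r,
    tau_d = st$tau_d,
    e_rev = st$e_rev,
    ev_step = step[ord],
    ev_state = (state_of[idx] - 1L)[ord],
    ev_amount = (actives$weight[idx] * fac[idx])[ord]
  )
}

#' @export
print.ivl_trace <- function(x, ...) {
  cat(sprintf(
    "<ivl_trace> %d samples, %.4g ms at record_dt %.4g ms\n",
    nrow(x), attr(x, "duration"), attr(x, "record_dt")
  ))
  NextMethod()
}

#' Write a recorded trace to CSV
#'
#' @param trace An `ivl_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
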