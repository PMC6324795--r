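# Double-exponential synapses and the full synapse bank ----------------------
#
# Each synapse is a two-state kinetic scheme: a presynaptic spike at time t0
# adds a conductance transient
#
#   g(t) = weight * factor * (exp(-(t - t0)/tau_d) - exp(-(t - t0)/tau_r))
#
# where `factor` normalizes the single-event peak to `weight`. Synaptic
# current follows i = g (V - E_R) (positive outward). Weights grow linearly
# with path distance (separate excitatory/inhibitory rules fitted to
# layer-specific recordings); kinetics are fixed per class and zone.

.exc_weight_slope <- 0.00230814 # nS/um
.exc_weight_intercept <- 0.22016666 # nS
.inh_weight_slope <- 0.00469125 # nS/um
.inh_weight_intercept <- 0.2695779 # nS

.kinetics <- tibble::tibble(
  kind = c("excitatory", "excitatory", "inhibitory"),
  zone = c("proximal", "distal", NA),
  tau_r = c(2.9936e-4, 6.1871e-4, 0.1013),
  tau_d = c(2.4216, 3.1975, 4.8216)
)

E_REV_EXC <- 0 # mV
E_REV_INH <- -70 # mV

EXC_PER_COMPARTMENT <- 9L
INH_TOTAL <- 344L

#' Distance-dependent excitatory synaptic weight
#'
#' @param path_distance Path distance from the soma (um), vectorized.
#' @return Weight in nS: `0.00230814 * d + 0.22016666`.
#' @examples
#' excitatory_weight(c(0, 100))
#' @export
excitatory_weight <- function(path_distance) {
  if (any(path_distance < 0)) abort("path_distance must be non-negative")
  .exc_weight_slope * path_distance + .exc_weight_intercept
}

#' Distance-dependent inhibitory synaptic weight
#'
#' @param path_distance Path distance from the soma (um), vectorized.
#' @return Weight in nS: `0.00469125 * d + 0.2695779`.
#' @examples
#' inhibitory_weight(c(0, 100))
#' @export
inhibitory_weight <- function(path_distance) {
  if (any(path_distance < 0)) abort("path_distance must be non-negative")
  .inh_weight_slope * path_distance + .inh_weight_intercept
}

#' Attach rise/decay time constants to synapse specifications
#'
#' Proximal excitatory synapses get (tau_r, tau_d) = (2.9936e-4, 2.4216) ms,
#' distal excitatory (6.1871e-4, 3.1975) ms, and inhibitory synapses
#' (0.1013, 4.8216) ms at every location.
#'
#' @param spec Tibble with columns `kind` and (for excitatory rows) `zone`.
#' @return `spec` with `tau_r` and `tau_d` columns filled.
#' @export
assign_kinetics <- function(spec) {
  spec$tau_r <- NULL
  spec$tau_d <- NULL
  exc <- .kinetics[!is.na(.kinetics$zone), ]
  inh <- .kinetics[is.na(.kinetics$zone), c("kind", "tau_r", "tau_d")]
  out <- dplyr::bind_rows(
    dplyr::inner_join(spec[spec$kind == "excitatory", ], exc,
      by = c("kind", "zone")
    ),
    dplyr::inner_join(spec[spec$kind == "inhibitory", ], inh, by = "kind")
  )
  out[order(out$slot_id), ]
}

# peak-normalization factor of the double exponential
kernel_factor <- function(tau_r, tau_d) {
  if (any(tau_d <= tau_r)) abort("tau_d must exceed tau_r")
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

#' Evaluate the summed conductance kernel of one synapse
#'
#' Closed-form evaluation of the double-exponential conductance generated by
#' a spike train, normalized so a single event peaks at `weight`. Serves as
#' the analytic reference for the event-driven solver states.
#'
#' @param spec One-row tibble (or list) with `weight`, `tau_r`, `tau_d`.
#' @param spike_times Sorted spike times (ms).
#' @param t_grid Evaluation times (ms).
#' @return Tibble of class `conductance_kernel` with `time` and `g` (nS).
#' @examples
#' k <- conductance_kernel(
#'   list(weight = 0.5, tau_r = 0.1, tau_d = 2),
#'   spike_times = 0, t_grid = seq(0, 20, 0.01)
#' )
#' max(k$g) # ~0.5
#' @export
conductance_kernel <- function(spec, spike_times, t_grid) {
  fac <- kernel_factor(spec$tau_r, spec$tau_d)
  g <- numeric(length(t_grid))
  for (t0 in spike_times) {
    dt <- t_grid - t0
    on <- dt >= 0
    g[on] <- g[on] + spec$weight * fac *
      (exp(-dt[on] / spec$tau_d) - exp(-dt[on] / spec$tau_r))
  }
  structure(
    tibble::tibble(time = t_grid, g = g),
    class = c("conductance_kernel", class(tibble::tibble())),
    peak = max(g)
  )
}

#' Synaptic current from conductance and driving force
#'
#' @param g Conductance (nS).
#' @param v Membrane potential (mV).
#' @param e_rev Reversal potential (mV).
#' @return Current in nA, positive outward: `g * (v - e_rev) * 1e-3`.
#' @examples
#' synaptic_current(1, -70, 0) # -0.07 nA (inward)
#' @export
synaptic_current <- function(g, v, e_rev) {
  g * (v - e_rev) * 1e-3
}

#' Build the full synapse bank on a morphology
#'
#' Places the complete complement of synapse slots on the dendritic tree:
#' 9 excitatory slots per dendritic compartment (1530 on the default
#' fixture, split 765 proximal / 765 distal) and 344 inhibitory slots spread
#' as evenly as possible (2 per compartment plus a third slot on the first 4
#' dendritic compartments). Weights follow the distance rules, kinetics the
#' per-class constants; construction is fully deterministic.
#'
#' @param morphology An `ivl_morphology`.
#' @return Tibble of class `synapse_bank`: `slot_id`, `compartment_id`,
#'   `kind`, `zone`, `distance` (um), `weight` (nS), `tau_r`, `tau_d` (ms),
#'   `e_rev` (mV).
#' @examples
#' bank <- build_synapse_bank(build_fixture_morphology())
#' table(bank$kind)
#' @export
build_synapse_bank <- function(morphology) {
  dend <- morphology[morphology$region == "dendrite", ]
  if (nrow(dend) == 0) abort("morphology has no dendritic compartments")
  n_dend <- nrow(dend)

  exc <- tibble::tibble(
    compartment_id = rep(dend$id, each = EXC_PER_COMPARTMENT),
    distance = rep(dend$path_distance, each = EXC_PER_COMPARTMENT),
    kind = "excitatory"
  )
  exc$zone <- dendrite_zone(exc$distance)
  exc$weight <- excitatory_weight(exc$distance)
  exc$e_rev <- E_REV_EXC

  inh_per_comp <- INH_TOTAL %/% n_dend
  n_extra <- INH_TOTAL - inh_per_comp * n_dend
  counts <- rep(inh_per_comp, n_dend) + c(
    rep(1L, n_extra),
    rep(0L, n_dend - n_extra)
  )
  inh <- tibble::tibble(
    compartment_id = rep(dend$id, times = counts),
    distance = rep(dend$path_distance, times = counts),
    kind = "inhibitory"
  )
  inh$zone <- dendrite_zone(inh$distance)
  inh$weight <- inhibitory_weight(inh$distance)
  inh$e_rev <- E_REV_INH

  bank <- dplyr::bind_rows(exc, inh)
  bank$slot_id <- seq_len(nrow(bank))
  bank <- assign_kinetics(bank)
  bank <- bank[, c(
    "slot_id", "compartment_id", "kind", "zone", "distance",
    "weight", "tau_r", "tau_d", "e_rev"
  )]
  class(bank) <- c("synapse_bank", class(bank))
  bank
}

#' Write a synapse bank to CSV
#'
#' @param bank A `synapse_bank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synapse_bank_csv <- function(bank, path) {
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE)
  invisible(path)
}
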