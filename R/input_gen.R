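# Synthetic presynaptic input generation -------------------------------------
#
# Background bombardment: each presynaptic train has exactly
# round(rate * duration) spikes drawn uniformly over the simulation window
# and sorted (sorted-uniform sampling; the resulting inter-spike intervals
# are near-exponential, i.e. Poisson-like irregular). Active synapses are
# chosen by unique uniform-integer sampling with the excitatory actives
# split equally between proximal and distal zones. Common-input grouping
# partitions the actives of each class into groups that share one train.
# The theta protocol adds deterministic 8 Hz population trains at
# quarter-cycle phase offsets.

#' Sample a background presynaptic spike train
#'
#' Draws exactly `round(rate * duration / 1000)` spike times uniformly over
#' `[0, duration)` and sorts them, so the realized mean rate equals the
#' requested rate by construction.
#'
#' @param rate Mean rate (Hz).
#' @param duration Window length (ms).
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times (ms).
#' @examples
#' length(sample_spike_train(100, 10000, seed = 1)) # 1000
#' @export
sample_spike_train <- function(rate, duration = 10000, seed = 1L) {
  if (rate < 0) abort("`rate` must be non-negative")
  n <- round(rate * duration / 1000)
  if (n == 0) {
    return(numeric(0))
  }
  with_seed(seed, sort(stats::runif(n, 0, duration)))
}

#' Select the active synapses of a scenario
#'
#' Chooses `n_exc / 2` proximal plus `n_exc / 2` distal excitatory slots and
#' `n_inh` inhibitory slots from the bank by unique uniform-integer sampling
#' (no slot is selected twice).
#'
#' @param bank A `synapse_bank`.
#' @param n_exc Number of active excitatory synapses (must be even).
#' @param n_inh Number of active inhibitory synapses.
#' @param seed Integer placement seed.
#' @return An object of class `input_assignment`: a list with `actives`
#'   (bank rows of the selected slots, plus `group_id`/`train_id` columns
#'   once trains are attached) and `trains` (empty until [group_common()]).
#' @export
select_active <- function(bank, n_exc, n_inh, seed = 1L) {
  if (n_exc %% 2 != 0) abort("`n_exc` must be even (equal proximal/distal split)")
  pools <- list(
    proximal = bank[bank$kind == "excitatory" & bank$zone == "proximal", ],
    distal = bank[bank$kind == "excitatory" & bank$zone == "distal", ],
    inhibitory = bank[bank$kind == "inhibitory", ]
  )
  need <- c(n_exc / 2, n_exc / 2, n_inh)
  avail <- vapply(pools, nrow, integer(1))
  if (any(need > avail)) {
    abort(sprintf(
      "requested actives exceed capacity (proximal %d/%d, distal %d/%d, inhibitory %d/%d)",
      need[1], avail[1], need[2], avail[2], need[3], avail[3]
    ))
  }
  actives <- with_seed(seed, {
    dplyr::bind_rows(purrr::map2(pools, need, function(p, k) {
      p[sort(sample.int(nrow(p), k)), ]
    }))
  })
  structure(
    list(actives = tibble::as_tibble(actives), trains = list()),
    class = "input_assignment"
  )
}

#' Partition actives into common-input groups and attach spike trains
#'
#' Splits the active synapses of each class (excitatory, inhibitory) into
#' `floor(n / k)` groups of size `k` plus one remainder group of size
#' `n %% k` (if nonzero). All members of a group receive the *same* freshly
#' sampled train at the class rate; `k = 1` gives every synapse its own
#' independent train.
#'
#' @param assignment An `input_assignment` from [select_active()].
#' @param f_exc,f_inh Presynaptic rates (Hz) for the two classes.
#' @param k_exc,k_inh Common-input group sizes (1 = independent).
#' @param duration Train window (ms).
#' @param seed Spike-time seed (one sub-seed per group).
#' @return The assignment with `group_id`/`train_id` columns on `actives`
#'   and the shared `trains` list filled.
#' @export
group_common <- function(assignment, f_exc, f_inh, k_exc = 1L, k_inh = 1L,
                         duration = 10000, seed = 1L) {
  if (k_exc < 1 || k_inh < 1) abort("group sizes must be >= 1")
  actives <- assignment$actives
  actives$group_id <- NA_integer_
  trains <- list()
  next_group <- 1L

  for (cls in c("excitatory", "inhibitory")) {
    idx <- which(actives$kind == cls)
    n <- length(idx)
    if (n == 0) next
    k <- if (cls == "excitatory") k_exc else k_inh
    rate <- if (cls == "excitatory") f_exc else f_inh
    gid <- ceiling(seq_len(n) / k) # sizes k, k, ..., remainder
    for (g in unique(gid)) {
      train_seed <- derive_seed(seed, cls, g)
      trains[[next_group]] <- sample_spike_train(rate, duration, train_seed)
      actives$group_id[idx[gid == g]] <- next_group
      next_group <- next_group + 1L
    }
  }
  actives$train_id <- actives$group_id
  assignment$actives <- actives
  assignment$trains <- trains
  assignment
}

#' Sizes of the common-input groups of one class
#'
#' @param n Number of active synapses of the class.
#' @param k Group size.
#' @return Integer vector of group sizes (`k` repeated, plus remainder).
#' @examples
#' common_group_sizes(20, 8) # 8 8 4
#' @export
common_group_sizes <- function(n, k) {
  if (n == 0) {
    return(integer(0))
  }
  as.integer(table(ceiling(seq_len(n) / k)))
}

# Theta protocol --------------------------------------------------------------

.theta_populations <- tibble::tibble(
  name = c(
    "CA3", "EC3", "bistratified", "IS1", "IS2", "neurogliaform", "OLM"
  ),
  kind = c(
    "excitatory", "excitatory", rep("inhibitory", 5)
  ),
  zone = c(
    "proximal", "distal", "proximal", "proximal", "proximal",
    "distal", "distal"
  ),
  phase_deg = c(0, 180, 90, 90, 90, 270, 270),
  n_synapses = c(27L, 27L, 8L, 8L, 8L, 8L, 8L)
)

#' Default theta-timed input populations
#'
#' One spike per population per 125 ms cycle: the proximally targeting
#' excitatory population (CA3) fires at 0 deg, its driven inhibitory
#' populations (bistratified, IS1, IS2) a quarter cycle later at 90 deg, the
#' distal excitatory population (EC3) at 180 deg, and its driven inhibitory
#' populations (neurogliaform, OLM) at 270 deg. Excitatory populations carry
#' 27 synapses each and inhibitory populations 8 each by default.
#'
#' @return Tibble with `name`, `kind`, `zone`, `phase_deg`, `n_synapses`.
#' @export
theta_populations <- function() {
  .theta_populations
}

#' Deterministic spike times of one theta-timed population
#'
#' @param phase_deg Phase within the cycle (degrees).
#' @param duration Simulation length (ms); a multiple of the period.
#' @param frequency Oscillation frequency (Hz), 8 by default.
#' @return Spike times `cycle * period + phase_deg / 360 * period` (ms).
#' @examples
#' head(theta_spike_times(90, 1000))
#' @export
theta_spike_times <- function(phase_deg, duration = 10000, frequency = 8) {
  period <- 1000 / frequency
  n_cycles <- round(duration / period)
  if (abs(n_cycles * period - duration) > 1e-9) {
    abort("`duration` must be a multiple of the theta period")
  }
  (seq_len(n_cycles) - 1) * period + phase_deg / 360 * period
}

#' Build the theta-timed input protocol
#'
#' Attaches each population's deterministic 8 Hz train to `n_synapses` bank
#' slots of the matching kind and zone. Slots are taken deterministically -
#' round-robin across the zone's compartments (first slot of each
#' compartment in id order, then second slots, and so on) - so the protocol
#' adds no randomness beyond the background scenario it is layered onto,
#' while spreading the population over the arbor instead of saturating a
#' single thin branch.
#'
#' @param bank A `synapse_bank`.
#' @param populations Population table as in [theta_populations()]; pass a
#'   modified copy for variant-specific synapse counts.
#' @param duration Simulation length (ms); a multiple of the period.
#' @param frequency Oscillation frequency (Hz).
#' @return An `input_assignment` holding the theta synapses and their
#'   deterministic trains.
#' @export
build_theta_protocol <- function(bank, populations = theta_populations(),
                                 duration = 10000, frequency = 8) {
  parts <- purrr::map(seq_len(nrow(populations)), function(i) {
    p <- populations[i, ]
    slots <- bank[bank$kind == p$kind & bank$zone == p$zone, ]
    if (nrow(slots) < p$n_synapses) {
      abort(sprintf(
        "population %s needs %d %s/%s slots but the bank has %d",
        p$name, p$n_synapses, p$kind, p$zone, nrow(slots)
      ))
    }
    slots <- slots[order(slots$slot_id), ]
    rank_in_comp <- stats::ave(
      seq_len(nrow(slots)), slots$compartment_id,
      FUN = seq_along
    )
    slots <- slots[order(rank_in_comp, slots$compartment_id), ]
    slots <- slots[seq_len(p$n_synapses), ]
    slots$population <- p$name
    slots
  })
  actives <- dplyr::bind_rows(parts)
  trains <- purrr::map(
    seq_len(nrow(populations)),
    function(i) {
      theta_spike_times(populations$phase_deg[i], duration, frequency)
    }
  )
  actives$train_id <- rep(
    seq_len(nrow(populations)),
    times = populations$n_synapses
  )
  actives$group_id <- actives$train_id
  structure(
    list(
      actives = actives, trains = trains,
      frequency = frequency, period = 1000 / frequency,
      populations = populations
    ),
    class = c("theta_protocol", "input_assignment")
  )
}

#' Combine two input assignments
#'
#' Concatenates actives and trains (e.g. layering the theta protocol on top
#' of a background scenario).
#'
#' @param a,b `input_assignment` objects.
#' @return Combined `input_assignment`.
#' @export
combine_inputs <- function(a, b) {
  offset <- length(a$trains)
  bb <- b$actives
  bb$train_id <- bb$train_id + offset
  bb$group_id <- bb$group_id + offset
  structure(
    list(
      actives = dplyr::bind_rows(a$actives, bb),
      trains = c(a$trains, b$trains)
    ),
    class = "input_assignment"
  )
}

#' Export an assignment's spike raster as a two-column table
#'
#' @param assignment An `input_assignment` with trains attached.
#' @param path Optional CSV path; if `NULL` the tibble is returned only.
#' @return Tibble with `slot_id`, `spike_time_ms`.
#' @export
raster_export <- function(assignment, path = NULL) {
  out <- purrr::map_dfr(seq_len(nrow(assignment$actives)), function(i) {
    tibble::tibble(
      slot_id = assignment$actives$slot_id[i],
      spike_time_ms = assignment$trains[[assignment$actives$train_id[i]]]
    )
  })
  if (!is.null(path)) utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  out
}
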