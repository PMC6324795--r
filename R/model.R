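# Model assembly: channel densities, passive properties, calibration --------

.variant_densities <- list(
  "AType+" = c(g_nat = 70, g_nap = 0.075, g_ka = 70, g_kdrf = 250),
  "AType-" = c(g_nat = 55, g_nap = 0.15, g_ka = 30, g_kdrf = 295)
)

.ri_targets <- c("AType+" = 388.71, "AType-" = 406.57) # MOhm, no-input
.sigma_vm_target <- 0.22 # mV, no-synapse subthreshold fluctuation

ACTIVE_DENDRITE_UM <- 70 # active conductances end here on dendrites

#' Assign channel densities to a morphology
#'
#' Distributes the four active conductances over the tree according to the
#' model variant: `G_Na,t` and `G_Kdrf` are uniform over the soma and the
#' first 70 um of dendrite in both variants; `G_Na,p` is somatic only; the
#' A-type conductance `G_Ka` extends into the proximal 70 um of dendrite in
#' the `"AType+"` variant but is somatic-only in `"AType-"`. The AIS carries
#' no active conductances unless `ais_active` is set.
#'
#' @param morphology An `ivl_morphology`.
#' @param variant `"AType+"` or `"AType-"`.
#' @param densities Optional named vector overriding the per-variant maxima
#'   (`g_nat`, `g_nap`, `g_ka`, `g_kdrf`, mS/cm^2).
#' @param ais_active If `TRUE`, the AIS gets the same densities as the soma.
#' @return Tibble with `id` and per-compartment `g_nat`, `g_nap`, `g_ka`,
#'   `g_kdrf` (mS/cm^2).
#' @examples
#' m <- build_fixture_morphology()
#' ch <- assign_channels(m, "AType+")
#' @export
assign_channels <- function(morphology, variant = c("AType+", "AType-"),
                            densities = NULL, ais_active = FALSE) {
  variant <- match.arg(variant)
  dens <- .variant_densities[[variant]]
  if (!is.null(densities)) dens[names(densities)] <- densities
  if (any(dens < 0)) abort("channel densities must be non-negative")
  in_active <- morphology$region == "soma" |
    (morphology$region == "dendrite" &
      morphology$path_distance <= ACTIVE_DENDRITE_UM) |
    (ais_active & morphology$region == "AIS")
  soma_only_ka <- variant == "AType-"
  tibble::tibble(
    id = morphology$id,
    g_nat = ifelse(in_active, dens[["g_nat"]], 0),
    g_nap = ifelse(morphology$region == "soma", dens[["g_nap"]], 0),
    g_ka = ifelse(
      if (soma_only_ka) morphology$region == "soma" else in_active,
      dens[["g_ka"]], 0
    ),
    g_kdrf = ifelse(in_active, dens[["g_kdrf"]], 0)
  )
}

#' Build a simulatable IS3-like cell model
#'
#' Bundles a morphology, its channel-density layout, the full synapse bank,
#' passive parameters, and the intrinsic-noise configuration into one object.
#' The returned model is *uncalibrated*: run [calibrate_passive()] (leak
#' conductance to the measured input-resistance target) and
#' [calibrate_noise()] (noise amplitude to the no-synapse voltage-fluctuation
#' target) before quantitative use.
#'
#' @param variant `"AType+"` or `"AType-"`.
#' @param morphology An `ivl_morphology`; defaults to the 221-compartment
#'   synthetic fixture.
#' @param densities Optional channel-density overrides, see
#'   [assign_channels()].
#' @param e_leak Leak reversal (mV).
#' @param g_leak Initial leak conductance density (mS/cm^2); replaced by
#'   [calibrate_passive()].
#' @param cm Specific capacitance (uF/cm^2).
#' @param Ra Axial resistivity (Ohm cm).
#' @param e_na,e_k Sodium / potassium reversal potentials (mV).
#' @return An object of class `is3_model`.
#' @examples
#' mod <- build_model("AType+")
#' @export
build_model <- function(variant = c("AType+", "AType-"),
                        morphology = build_fixture_morphology(),
                        densities = NULL,
                        e_leak = -70, g_leak = 0.0156,
                        cm = 1, Ra = 150,
                        e_na = 50, e_k = -85) {
  variant <- match.arg(variant)
  channels <- assign_channels(morphology, variant, densities)
  model <- structure(
    list(
      variant = variant,
      morphology = morphology,
      channels = channels,
      bank = if (any(morphology$region == "dendrite")) {
        build_synapse_bank(morphology)
      } else {
        build_synapse_bank(build_fixture_morphology())[0, ]
      },
      e_leak = e_leak, g_leak = g_leak, cm = cm, Ra = Ra,
      e_na = e_na, e_k = e_k,
      noise = list(
        enabled = FALSE, sigma_current = 0,
        target_sigma_vm = .sigma_vm_target, seed = 1L
      ),
      calibration = list(passive = FALSE, noise = FALSE)
    ),
    class = "is3_model"
  )
  model$geometry <- build_geometry(model)
  model
}

# solver-ready geometry: parents (0-based), areas, capacitances, couplings
build_geometry <- function(model) {
  m <- model$morphology
  area_cm2 <- pi * m$diam * m$length * 1e-8 # um^2 -> cm^2
  pidx <- match(m$parent_id, m$id)
  # axial resistance of a half-compartment, Ohm (lengths/diams um -> cm)
  r_half <- 4 * model$Ra * (m$length * 1e-4 / 2) / (pi * (m$diam * 1e-4)^2)
  g_ax <- numeric(nrow(m))
  child <- which(!is.na(pidx))
  g_ax[child] <- 1000 / (r_half[child] + r_half[pidx[child]]) # S -> mS
  list(
    parent0 = ifelse(is.na(pidx), -1L, pidx - 1L),
    area_cm2 = area_cm2,
    g_ax_mS = g_ax
  )
}

#' @export
print.is3_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<is3_model> variant %s, %d compartments\n",
      "  g_leak %.5g mS/cm^2 (passive calibration: %s)\n",
      "  noise sigma %.4g pA (noise calibration: %s)\n",
      "  synapse bank: %d excitatory + %d inhibitory slots\n"
    ),
    x$variant, nrow(x$morphology),
    x$g_leak, if (x$calibration$passive) "done" else "pending",
    x$noise$sigma_current, if (x$calibration$noise) "done" else "pending",
    sum(x$bank$kind == "excitatory"), sum(x$bank$kind == "inhibitory")
  ))
  invisible(x)
}

#' Calibrate the leak conductance to the no-input input-resistance target
#'
#' Scales the uniform leak density until the somatic input resistance
#' measured by the standard protocol (-100 pA step over 4.5-5.5 s of a 10 s
#' noise-free simulation, see [input_resistance()]) matches the variant's
#' target: 388.71 MOhm for `"AType+"`, 406.57 MOhm for `"AType-"`.
#'
#' @param model An `is3_model`.
#' @param target Target input resistance (MOhm); defaults per variant.
#' @param tol Convergence tolerance on the measured Ri (MOhm).
#' @param interval Search interval for the leak density (mS/cm^2).
#' @return The model with calibrated `g_leak`.
#' @export
calibrate_passive <- function(model, target = NULL, tol = 0.05,
                              interval = c(5e-4, 0.5)) {
  target <- target %||% .ri_targets[[model$variant]]
  f <- function(log_g) {
    model$g_leak <- 10^log_g
    input_resistance(model)$r_in - target
  }
  lo <- log10(interval[1])
  hi <- log10(interval[2])
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi)) {
    abort(sprintf(
      "leak search interval [%g, %g] mS/cm^2 does not bracket Ri = %g MOhm",
      interval[1], interval[2], target
    ))
  }
  root <- stats::uniroot(f, c(lo, hi),
    f.lower = f_lo, f.upper = f_hi,
    tol = 1e-5
  )
  model$g_leak <- 10^root$root
  achieved <- input_resistance(model)$r_in
  if (abs(achieved - target) > tol) {
    abort(sprintf(
      "passive calibration did not converge: Ri = %.3f MOhm (target %.2f)",
      achieved, target
    ))
  }
  model$calibration$passive <- TRUE
  model
}

#' Calibrate the somatic noise amplitude to the voltage-fluctuation target
#'
#' Sets the Gaussian noise-current amplitude so that the subthreshold
#' standard deviation of the somatic membrane potential over the last 9 s of
#' a 10 s no-synapse simulation, averaged over `n_seeds` independent noise
#' seeds, equals `target` (0.22 mV by default). The per-step noise current is
#' scaled by `1/sqrt(dt)` so its statistics are step-size invariant, and the
#' subthreshold response is linear in the amplitude to high accuracy, so a
#' scaled secant iteration converges in a few steps.
#'
#' @param model An `is3_model` with passive calibration done.
#' @param target Target subthreshold sigma_Vm (mV).
#' @param n_seeds Number of noise seeds averaged per evaluation.
#' @param tol Tolerance on the achieved mean sigma_Vm (mV).
#' @param sigma_max Upper bound on the amplitude (pA).
#' @param base_seed Base seed from which the evaluation noise seeds derive.
#' @return The model with calibrated `noise$sigma_current` and noise enabled.
#' @export
calibrate_noise <- function(model, target = .sigma_vm_target, n_seeds = 5,
                            tol = 0.005, sigma_max = 200, base_seed = 1L) {
  if (!model$calibration$passive) {
    abort("run calibrate_passive() before calibrate_noise()")
  }
  seeds <- vapply(
    seq_len(n_seeds), function(i) derive_seed(base_seed, "noise-cal", i),
    integer(1)
  )
  sigma <- 10
  meas <- measure_sigma_vm(model, sigma, seeds)
  for (iter in seq_len(8)) {
    if (meas <= 0) abort("noise produced no voltage fluctuation")
    sigma <- sigma * target / meas
    if (sigma > sigma_max) {
      abort(sprintf(
        "sigma_Vm target %g mV unreachable below %g pA", target, sigma_max
      ))
    }
    meas <- measure_sigma_vm(model, sigma, seeds)
    if (abs(meas - target) <= tol) break
  }
  if (abs(meas - target) > tol) {
    abort(sprintf(
      "noise calibration did not converge: sigma_Vm = %.4f mV (target %g)",
      meas, target
    ))
  }
  model$noise$enabled <- TRUE
  model$noise$sigma_current <- sigma
  model$noise$target_sigma_vm <- target
  model$calibration$noise <- TRUE
  model
}

#' Measure the no-synapse subthreshold voltage fluctuation
#'
#' @param model An `is3_model`.
#' @param sigma Noise amplitude to use (pA); defaults to the model's.
#' @param seeds Noise seeds; one 10 s simulation per seed.
#' @return Mean subthreshold sigma_Vm (mV) across seeds.
#' @export
measure_sigma_vm <- function(model, sigma = NULL,
                             seeds = 1:5) {
  sigma <- sigma %||% model$noise$sigma_current
  vals <- vapply(seeds, function(s) {
    tr <- simulate_model(model,
      noise = TRUE, noise_sigma = sigma,
      noise_seed = s
    )
    summarize_trace(tr)$sigma_sub_vm
  }, numeric(1))
  mean(vals)
}
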