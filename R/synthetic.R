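#' Noise model for synthetic data
#'
#' Gaussian noise, either additive (scale in signal units) or relative
#' (scale dimensionless, standard deviation `scale * |signal|`). Identical
#' seed and parameters always reproduce identical samples.
#'
#' @param kind `"relative_gaussian"` or `"additive_gaussian"`.
#' @param scale noise scale (>= 0). Default 0.05 relative, the repeatability
#'   of careful swelling-pressure measurements.
#' @param seed integer RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(kind = c("relative_gaussian", "additive_gaussian"),
                        scale = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(kind = kind, scale = scale, seed = as.integer(seed)),
            class = "noise_model")
}

#' Sampled noise and its per-point standard deviation
#' @keywords internal
.apply_noise <- function(signal, noise, stream = 0L) {
  n <- length(signal)
  sd_vec <- switch(noise$kind,
                   relative_gaussian = noise$scale * abs(signal),
                   additive_gaussian = rep(noise$scale, n))
  if (noise$scale == 0) {
    return(list(values = signal, sd = sd_vec))
  }
  eps <- withr::with_seed(stream_seed(noise$seed, stream),
                          stats::rnorm(n, sd = sd_vec))
  list(values = signal + eps, sd = sd_vec)
}

#' Derive a per-operation RNG stream seed
#'
#' Splitting rule for random streams: each generator operation draws from its
#' own stream `seed_i = (seed * 1009 + stream) mod (2^31 - 1)`, so adding a
#' generator call never perturbs the samples of another.
#'
#' @param seed base integer seed.
#' @param stream small non-negative integer identifying the operation/stream.
#' @return derived integer seed in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, stream = 0L) {
  as.integer((abs(as.double(seed)) * 1009 + as.double(stream)) %% 2147483647)
}

# stream ids per generator operation
.STREAM <- c(stress_strain = 1L, deswelling = 2L, salt_sweep = 3L, sans = 4L)

#' Generate a synthetic uniaxial compression series
#'
#' \eqn{\sigma_i = G_s(\Lambda_i - \Lambda_i^{-2}) + \epsilon_i}. The
#' ground-truth modulus is stored in the condition metadata.
#'
#' @param G_s true shear modulus (Pa), > 0.
#' @param lambda_grid deformation ratios in (0, 1].
#' @param noise a [noise_model()].
#' @return a [stress_strain_series()]; `condition$G_s_true` holds the truth.
#' @export
generate_stress_strain <- function(G_s,
                                   lambda_grid = seq(0.72, 0.98, by = 0.02),
                                   noise = noise_model()) {
  stopifnot(is.numeric(G_s), G_s > 0, inherits(noise, "noise_model"))
  if (any(lambda_grid <= 0) || any(lambda_grid > 1)) {
    stop("deformation ratios must lie in (0, 1]", call. = FALSE)
  }
  sig0 <- G_s * (lambda_grid - lambda_grid^-2)
  ns <- .apply_noise(sig0, noise, .STREAM[["stress_strain"]])
  stress_strain_series(lambda_grid, ns$values,
                       condition = list(G_s_true = G_s, sigma_true = sig0,
                                        noise = noise))
}

#' Generate a synthetic osmotic deswelling series
#'
#' Evaluates the forward gel model \eqn{\Pi_{tot}(\phi)} on a phi grid and
#' adds noise. The noiseless total and mixing pressures are retained in the
#' condition metadata as ground truth, and the per-point noise standard
#' deviation is stored in the curve's uncertainty column.
#'
#' @param model a [gel_model()].
#' @param phi_grid volume fractions in (0,1). Default 15 log-spaced points
#'   over the experimentally probed range 0.01-0.2.
#' @param noise a [noise_model()].
#' @return an [osmotic_curve()] of kind `"total"`.
#' @export
generate_deswelling_series <- function(model,
                                       phi_grid = exp(seq(log(0.01), log(0.2),
                                                          length.out = 15)),
                                       noise = noise_model()) {
  stopifnot(inherits(model, "gel_model"), inherits(noise, "noise_model"))
  .check_phi(phi_grid)
  p_tot <- swelling_pressure(phi_grid, model)
  p_mix <- mixing_pressure_virial(phi_grid, model$A2, model$A3, model$solvent)
  ns <- .apply_noise(p_tot, noise, .STREAM[["deswelling"]])
  osmotic_curve(phi_grid, ns$values, pressure_kind = "total",
                condition = list(model = model, Pi_tot_true = p_tot,
                                 Pi_mix_true = p_mix, noise = noise),
                uncertainty = if (noise$scale > 0) ns$sd else NULL)
}

#' Scenario recipe for synthetic salt/temperature sweeps
#'
#' Defines how the virial coefficients vary with a control variable (divalent
#' salt concentration in mol/m^3, or temperature in K), via affine laws
#' `A(x) = intercept + slope * x`. Three presets reproduce the qualitative
#' signatures seen in gel osmometry:
#' \describe{
#'   \item{`polyelectrolyte_salt_sweep`}{A2 weakly decreasing but positive
#'     across the CaCl2 grid while A3 strongly decreases and changes sign
#'     inside the grid — the many-body (virial sign inversion) pattern.}
#'   \item{`neutral_temperature_sweep`}{A2 nearly linear in temperature and
#'     changing sign, A3 small, positive and constant — the simple-fluid
#'     pattern of uncharged gels.}
#'   \item{`bottlebrush_salt_sweep`}{side-chain grafting suppresses the A3
#'     sign change: both coefficients stay positive over the same salt range.}
#' }
#'
#' @param scenario_kind one of the three presets.
#' @param A2_law,A3_law length-2 numeric `c(intercept, slope)` of the affine
#'   laws versus the control variable. Defaults depend on the preset.
#' @param control_grid strictly increasing control values (mol/m^3 CaCl2 for
#'   the salt sweeps, K for the temperature sweep).
#' @param C elastic prefactor (Pa) at `phi_ref`.
#' @param phi_ref reference volume fraction.
#' @param background_NaCl background monovalent salt (mol/m^3) for the salt
#'   sweeps (ionic Donnan term); ignored by the neutral preset.
#' @param fixed_charge_per_monomer effective charge per monomer for the
#'   charged presets (0 for the neutral preset).
#' @param solvent a [solvent_spec()].
#' @param noise_rel relative noise standard deviation.
#' @param seed integer seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario_kind = c("polyelectrolyte_salt_sweep",
                                              "neutral_temperature_sweep",
                                              "bottlebrush_salt_sweep"),
                            A2_law = NULL, A3_law = NULL, control_grid = NULL,
                            C = 2e4, phi_ref = 0.05,
                            background_NaCl = 40,
                            fixed_charge_per_monomer = NULL,
                            solvent = solvent_spec(),
                            noise_rel = 0.05, seed = 1L) {
  scenario_kind <- match.arg(scenario_kind)
  defaults <- switch(scenario_kind,
    polyelectrolyte_salt_sweep = list(
      A2_law = c(0.10, -0.02), A3_law = c(0.40, -1.2),
      control_grid = seq(0, 1.5, by = 0.25), f = 0.02),
    neutral_temperature_sweep = list(
      A2_law = c(-0.62, 0.002), A3_law = c(0.30, 0),
      control_grid = seq(280, 340, by = 10), f = 0),
    bottlebrush_salt_sweep = list(
      A2_law = c(0.10, -0.02), A3_law = c(0.40, -0.10),
      control_grid = seq(0, 1.5, by = 0.25), f = 0.02))
  if (is.null(A2_law)) A2_law <- defaults$A2_law
  if (is.null(A3_law)) A3_law <- defaults$A3_law
  if (is.null(control_grid)) control_grid <- defaults$control_grid
  if (is.null(fixed_charge_per_monomer)) fixed_charge_per_monomer <- defaults$f
  stopifnot(length(A2_law) == 2L, length(A3_law) == 2L,
            all(is.finite(A2_law)), all(is.finite(A3_law)),
            length(control_grid) >= 2L)
  if (any(diff(control_grid) <= 0)) {
    stop("control_grid must be strictly increasing", call. = FALSE)
  }
  stopifnot(noise_rel >= 0, phi_ref > 0, phi_ref < 1, C >= 0,
            fixed_charge_per_monomer >= 0)
  A2 <- A2_law[1] + A2_law[2] * control_grid
  A3 <- A3_law[1] + A3_law[2] * control_grid
  n_sign <- function(x) sum(diff(sign(x[x != 0])) != 0)
  bad <- switch(scenario_kind,
    polyelectrolyte_salt_sweep =
      if (any(A2 <= 0)) "polyelectrolyte preset requires A2 > 0 across the grid"
      else if (n_sign(A3) != 1) "polyelectrolyte preset requires exactly one A3 sign change inside the grid",
    neutral_temperature_sweep =
      if (any(A3 <= 0)) "neutral preset requires A3 > 0 across the grid"
      else if (n_sign(A3) != 0) "neutral preset requires constant-sign A3",
    bottlebrush_salt_sweep =
      if (any(A3 <= 0) || any(A2 <= 0)) "bottlebrush preset requires A2 > 0 and A3 > 0 across the grid")
  if (!is.null(bad)) {
    stop("scenario configuration error: ", bad, call. = FALSE)
  }
  structure(
    list(scenario_kind = scenario_kind, A2_law = A2_law, A3_law = A3_law,
         control_grid = control_grid, C = C, phi_ref = phi_ref,
         background_NaCl = background_NaCl,
         fixed_charge_per_monomer = fixed_charge_per_monomer,
         solvent = solvent, noise_rel = noise_rel, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s, %d control values in [%g, %g], noise %.3g\n",
              x$scenario_kind, length(x$control_grid), min(x$control_grid),
              max(x$control_grid), x$noise_rel))
  invisible(x)
}

#' Ground-truth virial coefficients of a scenario
#' @param config a [scenario_config()].
#' @return data.frame with columns `control`, `A2`, `A3`.
#' @export
scenario_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  data.frame(control = config$control_grid,
             A2 = config$A2_law[1] + config$A2_law[2] * config$control_grid,
             A3 = config$A3_law[1] + config$A3_law[2] * config$control_grid)
}

#' Gel model at one control value of a scenario
#' @param config a [scenario_config()].
#' @param control control value (need not lie on the grid).
#' @return a [gel_model()].
#' @export
scenario_model <- function(config, control) {
  stopifnot(inherits(config, "scenario_config"))
  ions <- if (config$fixed_charge_per_monomer > 0) {
    is_salt <- config$scenario_kind != "neutral_temperature_sweep"
    ca <- if (is_salt) control else 0
    salts <- data.frame(
      species = c("Na", "Cl", "Ca"),
      z = c(1, -1, 2),
      conc = c(config$background_NaCl, config$background_NaCl + 2 * ca, ca))
    ionic_condition(salts, config$fixed_charge_per_monomer)
  } else NULL
  sv <- if (config$scenario_kind == "neutral_temperature_sweep") {
    solvent_spec(V1 = config$solvent$V1, temperature = control)
  } else {
    config$solvent
  }
  gel_model(A2 = config$A2_law[1] + config$A2_law[2] * control,
            A3 = config$A3_law[1] + config$A3_law[2] * control,
            C = config$C, phi_ref = config$phi_ref, ions = ions, solvent = sv)
}

#' Generate a full synthetic sweep of deswelling curves
#'
#' One deswelling curve per control value, each generated from the scenario's
#' gel model with the configured noise, plus the per-condition shear modulus.
#'
#' @param config a [scenario_config()].
#' @param phi_grid phi grid passed to [generate_deswelling_series()].
#' @return list of class `salt_sweep`; each element is a list with `control`,
#'   `curve` (an [osmotic_curve()]), `G_s` (Pa), `model` (ground truth).
#' @export
generate_salt_sweep <- function(config,
                                phi_grid = exp(seq(log(0.01), log(0.2),
                                                   length.out = 15))) {
  stopifnot(inherits(config, "scenario_config"))
  out <- lapply(seq_along(config$control_grid), function(i) {
    ctrl <- config$control_grid[i]
    model <- scenario_model(config, ctrl)
    nm <- noise_model("relative_gaussian", config$noise_rel,
                      seed = stream_seed(config$seed,
                                         .STREAM[["salt_sweep"]] * 100L + i))
    curve <- generate_deswelling_series(model, phi_grid, nm)
    curve$condition$control <- ctrl
    list(control = ctrl, curve = curve,
         G_s = shear_modulus_scaling(phi_grid, config$C, config$phi_ref),
         model = model)
  })
  class(out) <- "salt_sweep"
  out
}

#' Generate a synthetic reduced SANS profile
#'
#' Evaluates the two-component intensity model on a q grid and adds noise;
#' the uncertainty column is filled with the per-point noise standard
#' deviation and the ground-truth parameters are kept in the condition
#' metadata. Default parameters emulate a swollen synthetic-polymer gel on
#' a pinhole SANS q range.
#'
#' @param params named list of ground-truth parameters: `dyn_amplitude`,
#'   `A`, `m`, plus `L`, `R` (rod variant) or `xi` (oz variant).
#' @param q_grid scattering vectors (1/Angstrom), > 0, increasing. Default 60
#'   log-spaced points over 0.003-0.15.
#' @param noise a [noise_model()].
#' @param variant `"rod"` or `"oz"`.
#' @param contrast contrast factor (1/cm^4) stored with the profile.
#' @return a [sans_profile()].
#' @export
generate_sans_profile <- function(params = list(dyn_amplitude = 1.2, L = 40,
                                                R = 8, A = 8e-9, m = 3.7),
                                  q_grid = exp(seq(log(0.003), log(0.15),
                                                   length.out = 60)),
                                  noise = noise_model(),
                                  variant = c("rod", "oz"),
                                  contrast = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(noise, "noise_model"))
  if (any(q_grid <= 0)) {
    stop("q must be positive: the static power law diverges at q = 0",
         call. = FALSE)
  }
  need <- if (variant == "rod") c("dyn_amplitude", "L", "R", "A", "m")
          else c("dyn_amplitude", "xi", "A", "m")
  if (!all(need %in% names(params))) {
    stop("params must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(unlist(params[need]) < 0)) {
    stop("all intensity-model parameters must be >= 0", call. = FALSE)
  }
  I0 <- total_intensity(q_grid, params, variant)
  ns <- .apply_noise(I0, noise, .STREAM[["sans"]])
  sans_profile(q_grid, ns$values,
               dI = if (noise$scale > 0) ns$sd else NULL,
               contrast = contrast,
               condition = list(truth = params, variant = variant,
                                noise = noise))
}
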