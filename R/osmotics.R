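#' Osmotic pressure curve of one gel series
#'
#' (phi, pressure) points of a single gel under one condition. `pressure_kind`
#' records which pressure the points are: `"total"`/`"swelling"` for the raw
#' swelling pressure Pi_tot, `"mixing"` after the elastic and ionic parts have
#' been removed.
#'
#' @param phi polymer volume fractions in (0,1).
#' @param pressure pressures in Pa, same length as `phi`.
#' @param pressure_kind one of `"total"`, `"swelling"`, `"mixing"`.
#' @param condition named list of condition metadata (salt in mol/m^3,
#'   temperature, ...).
#' @param uncertainty optional per-point 1-sigma pressure uncertainty (Pa).
#' @return object of class `osmotic_curve`.
#' @export
osmotic_curve <- function(phi, pressure,
                          pressure_kind = c("total", "swelling", "mixing"),
                          condition = list(), uncertainty = NULL) {
  pressure_kind <- match.arg(pressure_kind)
  .check_phi(phi)
  if (!is.numeric(pressure) || length(pressure) != length(phi)) {
    stop("pressure must be numeric with the same length as phi", call. = FALSE)
  }
  if (!is.null(uncertainty)) {
    if (!is.numeric(uncertainty) || length(uncertainty) != length(phi) ||
        any(uncertainty < 0)) {
      stop("uncertainty must be non-negative, same length as phi", call. = FALSE)
    }
  }
  structure(
    list(phi = as.numeric(phi), pressure = as.numeric(pressure),
         pressure_kind = pressure_kind, condition = condition,
         uncertainty = if (is.null(uncertainty)) NULL else as.numeric(uncertainty)),
    class = "osmotic_curve"
  )
}

#' @export
print.osmotic_curve <- function(x, ...) {
  cat(sprintf("<osmotic_curve> %d points (%s pressure), phi in [%.4g, %.4g]\n",
              length(x$phi), x$pressure_kind, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Ionic condition of a gel in a salt bath
#'
#' Describes the external electrolyte and the fixed charge carried by the
#' network. The external solution must be electroneutral. The fixed-charge
#' concentration inside the gel follows the swelling,
#' `c_f(phi) = fixed_charge_per_monomer * phi / monomer_molar_volume`
#' (mol/m^3); fixed charges are taken anionic (carboxylate, sulfonate,
#' phosphate backbones), balanced by mobile cations.
#'
#' @param salts data.frame with columns `species` (character), `z` (integer
#'   valence, sign included) and `conc` (external concentration, mol/m^3).
#'   E.g. 40 mM NaCl: `data.frame(species=c("Na","Cl"), z=c(1,-1), conc=c(40,40))`.
#' @param fixed_charge_per_monomer effective charges per monomer (>= 0,
#'   dimensionless). Effective, not chemical: counter-ion condensation lowers
#'   it well below the degree of neutralisation.
#' @param monomer_molar_volume molar volume of the monomer (m^3/mol),
#'   converting phi to monomer concentration.
#' @return object of class `ionic_condition`.
#' @export
ionic_condition <- function(salts, fixed_charge_per_monomer,
                            monomer_molar_volume = 6e-5) {
  stopifnot(is.data.frame(salts),
            all(c("species", "z", "conc") %in% names(salts)))
  if (any(salts$conc < 0)) stop("ion concentrations must be >= 0", call. = FALSE)
  if (any(salts$z == 0)) stop("ion valences must be non-zero", call. = FALSE)
  net <- sum(salts$z * salts$conc)
  tot <- sum(abs(salts$z) * salts$conc)
  if (tot > 0 && abs(net) > 1e-9 * tot) {
    stop("external solution is not electroneutral: sum z_j c_j != 0",
         call. = FALSE)
  }
  stopifnot(fixed_charge_per_monomer >= 0, monomer_molar_volume > 0)
  structure(
    list(salts = salts,
         fixed_charge_per_monomer = fixed_charge_per_monomer,
         monomer_molar_volume = monomer_molar_volume),
    class = "ionic_condition"
  )
}

#' @export
print.ionic_condition <- function(x, ...) {
  cat(sprintf("<ionic_condition> %d ion species, f_eff = %.3g per monomer\n",
              nrow(x$salts), x$fixed_charge_per_monomer))
  invisible(x)
}

#' Fixed-charge concentration at a given swelling
#' @param phi polymer volume fraction.
#' @param ions an [ionic_condition()].
#' @return fixed charge concentration in mol/m^3.
#' @export
fixed_charge_concentration <- function(phi, ions) {
  stopifnot(inherits(ions, "ionic_condition"))
  .check_phi(phi)
  ions$fixed_charge_per_monomer * phi / ions$monomer_molar_volume
}

#' Full gel model Pi_tot(phi)
#'
#' Assembles the additive swelling-pressure model
#' \eqn{\Pi_{tot}(\phi) = \Pi_{mix}(\phi) + \Pi_{elast}(\phi) + \Pi_{ion}(\phi)}
#' with the virial mixing pressure (coefficients `A2`, `A3`), the classical
#' elastic term \eqn{-C (\phi/\phi_{ref})^{1/3}}, and an optional ideal-Donnan
#' ionic term.
#'
#' @param A2,A3 dimensionless second/third osmotic virial coefficients.
#' @param C elastic prefactor in Pa: shear modulus at `phi_ref`. `C = 0`
#'   switches the elastic term off (solution rather than network).
#' @param phi_ref reference volume fraction of the elastic scaling.
#' @param ions an [ionic_condition()] or `NULL` for a neutral gel.
#' @param solvent a [solvent_spec()].
#' @return object of class `gel_model`.
#' @export
gel_model <- function(A2, A3, C = 0, phi_ref = 0.05, ions = NULL,
                      solvent = solvent_spec()) {
  stopifnot(is.numeric(A2), is.numeric(A3), is.finite(A2), is.finite(A3),
            is.numeric(C), C >= 0, phi_ref > 0, phi_ref < 1,
            inherits(solvent, "solvent_spec"))
  if (!is.null(ions)) stopifnot(inherits(ions, "ionic_condition"))
  structure(
    list(A2 = A2, A3 = A3, C = C, phi_ref = phi_ref, ions = ions,
         solvent = solvent),
    class = "gel_model"
  )
}

#' @export
print.gel_model <- function(x, ...) {
  cat(sprintf("<gel_model> A2 = %.4g, A3 = %.4g, C = %.4g Pa at phi_ref = %.3g, ions %s\n",
              x$A2, x$A3, x$C, x$phi_ref,
              if (is.null(x$ions)) "off" else "on"))
  invisible(x)
}

# ---- mixing pressure ---------------------------------------------------

#' Mixing pressure, virial form
#'
#' \eqn{\Pi_{mix} = (RT/V_1)(A_2 \phi^2 + A_3 \phi^3)}, the truncated osmotic
#' virial expansion whose coefficients measure pairwise (A2) and effective
#' three-body (A3) polymer-polymer interactions.
#'
#' @param phi volume fraction(s) in (0,1).
#' @param A2,A3 dimensionless virial coefficients.
#' @param solvent a [solvent_spec()].
#' @return mixing pressure in Pa.
#' @export
mixing_pressure_virial <- function(phi, A2, A3, solvent = solvent_spec()) {
  .check_phi(phi)
  pressure_scale(solvent) * (A2 * phi^2 + A3 * phi^3)
}

#' Mixing pressure, Flory-Huggins form
#'
#' \eqn{\Pi_{mix} = -(RT/V_1)[\ln(1-\phi) + \phi + \chi_0 \phi^2 + \chi_1 \phi^3]}
#' for a cross-linked network (infinite chains: no 1/N translational term).
#'
#' @param phi volume fraction(s) in (0,1).
#' @param chi0,chi1 Flory interaction parameters.
#' @inheritParams mixing_pressure_virial
#' @return mixing pressure in Pa.
#' @export
mixing_pressure_flory_huggins <- function(phi, chi0, chi1,
                                          solvent = solvent_spec()) {
  .check_phi(phi)
  stopifnot(is.finite(chi0), is.finite(chi1))
  -pressure_scale(solvent) * (log1p(-phi) + phi + chi0 * phi^2 + chi1 * phi^3)
}

#' Map Flory-Huggins parameters to virial coefficients and back
#'
#' Expanding \eqn{-\ln(1-\phi) - \phi = \phi^2/2 + \phi^3/3 + O(\phi^4)} and
#' matching powers gives \eqn{A_2 = 1/2 - \chi_0} and \eqn{A_3 = 1/3 - \chi_1}.
#' The theta condition chi0 = 1/2 maps to A2 = 0.
#'
#' @param chi0,chi1 Flory interaction parameters.
#' @return named list with `A2`, `A3`.
#' @export
chi_to_virial <- function(chi0, chi1) {
  stopifnot(is.finite(chi0), is.finite(chi1))
  list(A2 = 0.5 - chi0, A3 = 1 / 3 - chi1)
}

#' @rdname chi_to_virial
#' @param A2,A3 virial coefficients.
#' @return for `virial_to_chi`, named list with `chi0`, `chi1`.
#' @export
virial_to_chi <- function(A2, A3) {
  stopifnot(is.finite(A2), is.finite(A3))
  list(chi0 = 0.5 - A2, chi1 = 1 / 3 - A3)
}

# ---- Donnan ------------------------------------------------------------

#' Ideal Donnan ionic pressure
#'
#' Solves the ideal Donnan equilibrium between a gel carrying anionic fixed
#' charges and an electroneutral external electrolyte. A single Donnan ratio
#' \eqn{y = \exp(-F\psi/RT)} partitions every species,
#' \eqn{c_j^{gel} = c_j^{sol} y^{z_j}}; `y` is fixed by gel electroneutrality
#' \eqn{\sum_j z_j c_j^{gel} = c_f(\phi)}. The ionic pressure is the ideal
#' van't Hoff difference \eqn{\Pi_{ion} = RT \sum_j (c_j^{gel} - c_j^{sol})}.
#'
#' @param phi volume fraction (scalar or vector) in (0,1).
#' @param ions an [ionic_condition()].
#' @param solvent a [solvent_spec()].
#' @param tol relative tolerance of the Donnan-ratio root.
#' @return ionic pressure in Pa (>= 0 for anionic gels), same length as `phi`.
#' @examples
#' nacl <- data.frame(species = c("Na", "Cl"), z = c(1, -1), conc = c(40, 40))
#' ic <- ionic_condition(nacl, fixed_charge_per_monomer = 0.02)
#' donnan_pressure(0.05, ic)
#' @export
donnan_pressure <- function(phi, ions, solvent = solvent_spec(),
                            tol = 1e-13) {
  stopifnot(inherits(ions, "ionic_condition"))
  .check_phi(phi)
  RT <- solvent$R * solvent$T
  z <- ions$salts$z
  cs <- ions$salts$conc
  vapply(phi, function(p) {
    cf <- fixed_charge_concentration(p, ions)
    if (cf == 0 || all(cs == 0)) {
      if (cf > 0 && all(cs == 0)) {
        # counter-ion only limit: monovalent counter-ions at concentration cf
        return(RT * cf)
      }
      return(0)
    }
    # g(y) = sum z_j c_j y^{z_j} - cf is strictly increasing in y > 0.
    # With external electroneutrality sum z_j c_j = 0, the expm1 form avoids
    # catastrophic cancellation at small Donnan ratios (salt excess):
    g <- function(u) sum(z * cs * expm1(u * z)) - cf  # u = log(y)
    lo <- 0; hi <- 0
    while (g(lo) > 0) lo <- lo - 1
    while (g(hi) < 0) hi <- hi + 1
    if (lo == hi) { lo <- lo - 1e-8; hi <- hi + 1e-8 }
    root <- stats::uniroot(g, c(lo, hi), tol = tol)
    # polish to machine precision: Newton on u (g is smooth and monotone)
    u <- root$root
    for (it in 1:5) {
      gu <- g(u)
      dgu <- sum(z^2 * cs * exp(u * z))
      if (dgu == 0) break
      step <- gu / dgu
      u <- u - step
      if (abs(step) < 1e-15 * max(1, abs(u))) break
    }
    if (abs(g(u)) > 1e-6 * (abs(cf) + sum(abs(z) * cs))) {
      stop("Donnan ratio solve failed: residual ", g(u), call. = FALSE)
    }
    RT * sum(cs * expm1(u * z))
  }, numeric(1))
}

#' Closed-form Donnan pressure for a single 1:1 salt
#'
#' For one monovalent salt at external concentration `c_s` and fixed-charge
#' concentration `c_f` the two-equation Donnan system has the closed form
#' \eqn{\Pi_{ion} = RT(\sqrt{c_f^2 + 4 c_s^2} - 2 c_s)}; serves as an exact
#' cross-check of the numerical solver and exposes the limits
#' \eqn{\Pi_{ion} \to RT c_f} (no salt) and \eqn{\to 0} (salt excess).
#'
#' @param c_f fixed charge concentration (mol/m^3, >= 0).
#' @param c_s external salt concentration (mol/m^3, >= 0).
#' @param solvent a [solvent_spec()].
#' @return ionic pressure in Pa.
#' @export
donnan_pressure_closed_form_1_1 <- function(c_f, c_s,
                                            solvent = solvent_spec()) {
  stopifnot(all(c_f >= 0), all(c_s >= 0))
  RT <- solvent$R * solvent$T
  # rationalized form of RT*(sqrt(c_f^2 + 4 c_s^2) - 2 c_s): algebraically
  # identical but free of cancellation when c_s >> c_f
  RT * c_f^2 / (sqrt(c_f^2 + 4 * c_s^2) + 2 * c_s)
}

# ---- decomposition and virial fit --------------------------------------

#' Ionic pressure helper honouring a missing ionic condition
#' @keywords internal
.ionic_pressure <- function(phi, ions, solvent) {
  if (is.null(ions)) rep(0, length(phi)) else donnan_pressure(phi, ions, solvent)
}

#' Decompose a measured swelling pressure into its mixing part
#'
#' Inverts the additivity of the swelling pressure,
#' \eqn{\Pi_{mix}(\phi_i) = \Pi_{tot}(\phi_i) + G_s(\phi_i) - \Pi_{ion}(\phi_i)},
#' using a per-point shear modulus (measured, or extrapolated with the
#' phi^(1/3) scaling) and an optional Donnan term.
#'
#' @param curve an [osmotic_curve()] with `pressure_kind` `"total"` or
#'   `"swelling"`.
#' @param G_s shear modulus: a scalar or vector (Pa, recycled/per point), a
#'   function of phi, or a list `list(C = , phi_ref = )` using
#'   [shear_modulus_scaling()].
#' @param ions an [ionic_condition()] or `NULL`.
#' @param solvent a [solvent_spec()].
#' @return an [osmotic_curve()] with `pressure_kind = "mixing"`; attribute
#'   `"provenance"` records the subtracted elastic and ionic pressures.
#' @export
decompose_swelling_pressure <- function(curve, G_s, ions = NULL,
                                        solvent = solvent_spec()) {
  stopifnot(inherits(curve, "osmotic_curve"))
  if (!curve$pressure_kind %in% c("total", "swelling")) {
    stop("curve must carry total/swelling pressure, got kind '",
         curve$pressure_kind, "'", call. = FALSE)
  }
  if (missing(G_s) || is.null(G_s)) {
    stop("shear modulus G_s is required to remove the elastic term",
         call. = FALSE)
  }
  phi <- curve$phi
  g <- if (is.function(G_s)) {
    G_s(phi)
  } else if (is.list(G_s)) {
    shear_modulus_scaling(phi, G_s$C, G_s$phi_ref)
  } else {
    rep_len(as.numeric(G_s), length(phi))
  }
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("G_s must evaluate to finite non-negative moduli", call. = FALSE)
  }
  pion <- .ionic_pressure(phi, ions, solvent)
  mix <- curve$pressure + g - pion
  out <- osmotic_curve(phi, mix, pressure_kind = "mixing",
                       condition = curve$condition,
                       uncertainty = curve$uncertainty)
  attr(out, "provenance") <- list(G_s = g, Pi_ion = pion,
                                  source_kind = curve$pressure_kind)
  out
}

#' Fit osmotic virial coefficients to a mixing-pressure curve
#'
#' Weighted linear least squares of the reduced pressure
#' \eqn{\Pi_{mix} V_1 / (RT)} on the zero-intercept basis
#' \eqn{(\phi^2, \phi^3)}. Weights are \eqn{1/\sigma_i^2} from the curve's
#' uncertainty column when present, else unweighted. The covariance is the
#' exact linear-model covariance scaled by the residual variance.
#'
#' @param curve an [osmotic_curve()] of kind `"mixing"` with >= 3 points.
#' @param solvent a [solvent_spec()].
#' @return object of class `virial_fit`: `A2`, `A3`, `covariance` (2x2),
#'   `scale` (RT/V1, Pa), `n_points`, `residual_rms` (Pa), `df`, standard
#'   errors `A2_se`, `A3_se`.
#' @export
fit_virial_coefficients <- function(curve, solvent = solvent_spec()) {
  stopifnot(inherits(curve, "osmotic_curve"))
  if (curve$pressure_kind != "mixing") {
    stop("virial fit expects a mixing-pressure curve; decompose first",
         call. = FALSE)
  }
  phi <- curve$phi
  if (length(phi) < 3L) stop("need >= 3 points for a 2-parameter fit",
                             call. = FALSE)
  if (length(unique(phi)) < 2L) {
    stop("rank-deficient design: all phi equal", call. = FALSE)
  }
  scl <- pressure_scale(solvent)
  y <- curve$pressure / scl
  X <- cbind(phi2 = phi^2, phi3 = phi^3)
  w <- if (!is.null(curve$uncertainty) && all(curve$uncertainty > 0)) {
    (scl / curve$uncertainty)^2
  } else {
    rep(1, length(y))
  }
  fit <- stats::lm.wfit(X, y, w)
  if (fit$rank < 2L) stop("rank-deficient design in (phi^2, phi^3) basis",
                          call. = FALSE)
  cf <- fit$coefficients
  dof <- length(y) - 2L
  rss_w <- sum(w * fit$residuals^2)
  s2 <- if (dof > 0) rss_w / dof else 0
  XtWX <- crossprod(X * sqrt(w))
  covm <- s2 * solve(XtWX)
  dimnames(covm) <- list(c("A2", "A3"), c("A2", "A3"))
  structure(
    list(A2 = unname(cf[1]), A3 = unname(cf[2]),
         covariance = covm,
         A2_se = sqrt(covm[1, 1]), A3_se = sqrt(covm[2, 2]),
         scale = scl,
         n_points = length(y),
         df = dof,
         residual_rms = sqrt(mean(fit$residuals^2)) * scl),
    class = "virial_fit"
  )
}

#' @export
print.virial_fit <- function(x, ...) {
  cat(sprintf("<virial_fit> A2 = %.5g (se %.2g), A3 = %.5g (se %.2g), n = %d\n",
              x$A2, x$A2_se, x$A3, x$A3_se, x$n_points))
  invisible(x)
}

# ---- swelling pressure, equilibrium, transition ------------------------

#' Total swelling pressure of a gel model
#'
#' \eqn{\Pi_{tot}(\phi) = (RT/V_1)(A_2\phi^2 + A_3\phi^3)
#'   - C(\phi/\phi_{ref})^{1/3} + \Pi_{ion}(\phi)}.
#'
#' @param phi volume fraction(s) in (0,1).
#' @param model a [gel_model()].
#' @return pressure in Pa, same length as `phi`.
#' @export
swelling_pressure <- function(phi, model) {
  stopifnot(inherits(model, "gel_model"))
  .check_phi(phi)
  mix <- mixing_pressure_virial(phi, model$A2, model$A3, model$solvent)
  el <- if (model$C > 0) {
    -shear_modulus_scaling(phi, model$C, model$phi_ref)
  } else {
    rep(0, length(phi))
  }
  mix + el + .ionic_pressure(phi, model$ions, model$solvent)
}

#' Equilibrium swelling: roots of Pi_tot(phi) = 0
#'
#' Scans a log-spaced grid for sign changes of the swelling pressure and
#' refines each bracket by bisection/Brent to high relative precision. Roots
#' are classified stable where \eqn{d\Pi_{tot}/d\phi > 0}: compressing the gel
#' beyond such a root makes the swelling pressure positive, driving solvent
#' uptake back toward equilibrium (equivalently, the free energy F(V) is
#' convex there).
#'
#' @param model a [gel_model()].
#' @param interval search interval in phi, default `c(1e-4, 0.99)`.
#' @param n_grid number of log-spaced scan nodes (default 400).
#' @param tol_rel relative tolerance on each root.
#' @return data.frame with columns `phi` and `stable` (logical); zero rows
#'   with attribute `status = "no-equilibrium"` when Pi_tot has no root
#'   (fully swollen or fully collapsed over the interval).
#' @export
solve_equilibrium_swelling <- function(model, interval = c(1e-4, 0.99),
                                       n_grid = 400, tol_rel = 1e-10) {
  stopifnot(inherits(model, "gel_model"),
            length(interval) == 2L, interval[1] > 0, interval[2] < 1,
            interval[1] < interval[2], n_grid >= 10)
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = n_grid))
  f <- swelling_pressure(grid, model)
  roots <- numeric(0)
  sgn <- sign(f)
  for (i in seq_len(n_grid - 1L)) {
    if (sgn[i] == 0) { roots <- c(roots, grid[i]); next }
    if (sgn[i] * sgn[i + 1L] < 0) {
      r <- stats::uniroot(function(p) swelling_pressure(p, model),
                          c(grid[i], grid[i + 1L]),
                          f.lower = f[i], f.upper = f[i + 1L],
                          tol = tol_rel * grid[i])
      roots <- c(roots, r$root)
    }
  }
  if (sgn[n_grid] == 0) roots <- c(roots, grid[n_grid])
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    out <- data.frame(phi = numeric(0), stable = logical(0))
    attr(out, "status") <- "no-equilibrium"
    return(out)
  }
  stable <- vapply(roots, function(p) {
    h <- 1e-6 * p
    dP <- (swelling_pressure(min(p + h, interval[2]), model) -
             swelling_pressure(max(p - h, interval[1]), model)) / (2 * h)
    dP > 0
  }, logical(1))
  out <- data.frame(phi = roots, stable = stable)
  attr(out, "status") <- "ok"
  out
}

#' Longitudinal osmotic modulus
#'
#' \eqn{M_{os} = \phi \, \partial\Pi_{mix}/\partial\phi + (4/3) G_s
#'   = (RT/V_1)(2 A_2 \phi^2 + 3 A_3 \phi^3) + (4/3) G_s},
#' evaluated with the exact analytic derivative of the virial mixing
#' pressure. `M_os` controls the amplitude of thermal concentration
#' fluctuations seen by scattering. With
#' `include_elastic_derivative = TRUE`, the phi-derivative of the elastic
#' pressure is also included, contributing an extra \eqn{-G_s/3} (i.e.
#' \eqn{\phi\,\partial\Pi_{sw}/\partial\phi} rather than only the mixing
#' derivative); the default keeps the mixing-derivative convention.
#'
#' @param phi volume fraction(s).
#' @param A2,A3 virial coefficients.
#' @param G_s shear modulus in Pa (scalar or per-phi vector, >= 0).
#' @param solvent a [solvent_spec()].
#' @param include_elastic_derivative logical, see Details.
#' @return modulus in Pa.
#' @export
longitudinal_modulus <- function(phi, A2, A3, G_s,
                                 solvent = solvent_spec(),
                                 include_elastic_derivative = FALSE) {
  .check_phi(phi)
  stopifnot(all(G_s >= 0))
  m <- pressure_scale(solvent) * (2 * A2 * phi^2 + 3 * A3 * phi^3) +
    (4 / 3) * G_s
  if (include_elastic_derivative) m <- m - G_s / 3
  m
}

#' Detect a salt- or temperature-induced volume transition
#'
#' Follows the swollen equilibrium branch along a control variable by
#' continuation: at each control value the stable root of
#' \eqn{\Pi_{tot}(\phi)=0} nearest (in log phi) to the previous branch point
#' is taken. A volume transition is declared where the branch disappears (no
#' stable root survives near it) or where the swelling degree \eqn{1/\phi}
#' drops by more than `jump_threshold` between adjacent grid points; the
#' critical control value is then refined by bisection on the
#' branch-survival condition. When no stable root exists beyond the
#' transition (truncated virial models with A3 < 0 collapse without a second
#' minimum), the collapsed state is recorded at the scan upper bound `phi_max`.
#'
#' @param model_fun function mapping a control value to a [gel_model()].
#' @param control_grid numeric vector of >= 4 strictly increasing control
#'   values (salt concentration in mol/m^3, or temperature in K).
#' @param jump_threshold factor drop of 1/phi declaring a transition
#'   (default 2).
#' @param tol_rel relative tolerance of the bisection on the critical control
#'   value (default 1e-3).
#' @param interval,n_grid passed to [solve_equilibrium_swelling()].
#' @return object of class `transition_result`: `control_grid`, `phi_eq`
#'   (swollen-branch phi per grid point, NA after collapse), `transition`
#'   (logical), `c_critical`, `jump_ratio`.
#' @export
detect_volume_transition <- function(model_fun, control_grid,
                                     jump_threshold = 2, tol_rel = 1e-3,
                                     interval = c(1e-4, 0.99), n_grid = 400) {
  stopifnot(is.function(model_fun), length(control_grid) >= 4L,
            all(diff(control_grid) > 0), jump_threshold >= 1)
  branch_phi <- function(ctrl, phi_prev) {
    eq <- solve_equilibrium_swelling(model_fun(ctrl), interval = interval,
                                     n_grid = n_grid)
    st <- eq$phi[eq$stable]
    if (length(st) == 0L) return(NA_real_)
    if (is.na(phi_prev)) return(min(st))  # most swollen stable root
    st[which.min(abs(log(st) - log(phi_prev)))]
  }
  n <- length(control_grid)
  phi_eq <- rep(NA_real_, n)
  phi_prev <- NA_real_
  idx_break <- NA_integer_
  for (i in seq_len(n)) {
    p <- branch_phi(control_grid[i], phi_prev)
    if (i == 1L && is.na(p)) {
      stop("no stable equilibrium at the first control value ",
           control_grid[1], call. = FALSE)
    }
    phi_eq[i] <- p
    if (!is.na(p)) {
      if (!is.na(phi_prev) && (1 / phi_prev) / (1 / p) >= jump_threshold) {
        idx_break <- i
        break
      }
      phi_prev <- p
    } else {
      idx_break <- i
      break
    }
  }
  if (is.na(idx_break)) {
    out <- list(control_grid = control_grid, phi_eq = phi_eq,
                transition = FALSE, c_critical = NA_real_,
                jump_ratio = NA_real_)
    class(out) <- "transition_result"
    return(out)
  }
  # refine c_critical in (control[idx-1], control[idx]) by bisection on
  # branch survival relative to the last swollen point
  lo <- control_grid[idx_break - 1L]
  hi <- control_grid[idx_break]
  phi_before <- phi_prev
  survives <- function(ctrl) {
    p <- branch_phi(ctrl, phi_before)
    !is.na(p) && (1 / phi_before) / (1 / p) < jump_threshold
  }
  while ((hi - lo) > tol_rel * max(abs(hi), abs(lo), tol_rel)) {
    mid <- (lo + hi) / 2
    if (survives(mid)) lo <- mid else hi <- mid
  }
  c_crit <- (lo + hi) / 2
  phi_after <- branch_phi(hi, phi_before)
  if (is.na(phi_after)) phi_after <- interval[2]  # collapsed to scan bound
  out <- list(control_grid = control_grid, phi_eq = phi_eq,
              transition = TRUE, c_critical = c_crit,
              jump_ratio = (1 / phi_before) / (1 / phi_after))
  class(out) <- "transition_result"
  out
}

#' @export
print.transition_result <- function(x, ...) {
  if (x$transition) {
    cat(sprintf("<transition_result> volume transition at control = %.5g (jump ratio %.3g)\n",
                x$c_critical, x$jump_ratio))
  } else {
    cat("<transition_result> no volume transition over the control grid\n")
  }
  invisible(x)
}
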