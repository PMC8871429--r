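#' Reduced SANS profile
#'
#' Fully reduced small-angle neutron scattering data: scattering vector
#' magnitude q (1/Angstrom), absolute intensity I (1/cm) and optional
#' uncertainty dI (1/cm). q must be strictly increasing and positive.
#'
#' @param q scattering vectors (1/Angstrom), strictly increasing, > 0.
#' @param I intensities (1/cm).
#' @param dI optional 1-sigma uncertainties (1/cm), same length.
#' @param contrast optional neutron contrast factor Delta-rho^2 (1/cm^4).
#' @param condition optional named list (phi, salt, temperature, ...).
#' @return object of class `sans_profile`.
#' @export
sans_profile <- function(q, I, dI = NULL, contrast = NULL, condition = list()) {
  if (!is.numeric(q) || !is.numeric(I) || length(q) != length(I)) {
    stop("q and I must be numeric vectors of equal length", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("q must be positive and finite", call. = FALSE)
  }
  if (any(diff(q) <= 0)) {
    stop("q must be strictly increasing", call. = FALSE)
  }
  if (!is.null(dI)) {
    if (length(dI) != length(q) || any(dI < 0)) {
      stop("dI must be non-negative, same length as q", call. = FALSE)
    }
    if (any(I[dI == 0] < 0)) {
      stop("negative intensity with zero uncertainty", call. = FALSE)
    }
  }
  structure(
    list(q = as.numeric(q), I = as.numeric(I),
         dI = if (is.null(dI)) NULL else as.numeric(dI),
         contrast = contrast, condition = condition),
    class = "sans_profile"
  )
}

#' @export
print.sans_profile <- function(x, ...) {
  cat(sprintf("<sans_profile> %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

# ---- intensity kernels ---------------------------------------------------

#' Ornstein-Zernike intensity
#'
#' \eqn{I(q) = I_0 (1 + q^2 \xi^2)^{-1}}: the Lorentzian line shape of random
#' thermal concentration fluctuations with correlation length xi.
#'
#' @param q scattering vector (1/Angstrom), >= 0.
#' @param amplitude forward intensity I(0) (1/cm), >= 0.
#' @param xi correlation length (Angstrom), >= 0.
#' @return intensity (1/cm).
#' @export
oz_intensity <- function(q, amplitude, xi) {
  stopifnot(all(q >= 0), amplitude >= 0, xi >= 0)
  amplitude / (1 + q^2 * xi^2)
}

#' Rod-like Ornstein-Zernike intensity
#'
#' \eqn{I(q) = I_0 (1 + qL)^{-1} (1 + q^2R^2)^{-1}} for networks containing
#' linear segments of length L and effective cross-sectional dimension R
#' (Guinier regime q*xi < 1). Decays as q^-3 at large q.
#'
#' @param q scattering vector (1/Angstrom), >= 0.
#' @param amplitude forward intensity I(0) (1/cm), >= 0.
#' @param L segment length (Angstrom), >= 0.
#' @param R cross-sectional dimension (Angstrom), >= 0.
#' @return intensity (1/cm).
#' @export
rod_oz_intensity <- function(q, amplitude, L, R) {
  stopifnot(all(q >= 0), amplitude >= 0, L >= 0, R >= 0)
  amplitude / ((1 + q * L) * (1 + q^2 * R^2))
}

#' Power-law (static/excess) intensity
#'
#' \eqn{I_x(q) = A q^{-m}}: low-q excess scattering from large-scale static
#' structures; m = 4 for smooth interfaces (Porod), lower for rough ones.
#'
#' @param q scattering vector (1/Angstrom), > 0.
#' @param A prefactor (1/cm * Angstrom^-m), >= 0.
#' @param m exponent in `[2, 5]`.
#' @return intensity (1/cm).
#' @export
power_law_intensity <- function(q, A, m) {
  stopifnot(A >= 0, m >= 2, m <= 5)
  if (any(q <= 0)) stop("power law diverges: q must be > 0", call. = FALSE)
  A * q^(-m)
}

#' Two-component total SANS intensity
#'
#' Dynamic (thermal-fluctuation) component plus static power law:
#' rod variant \eqn{I(q) = I_0(1+qL)^{-1}(1+q^2R^2)^{-1} + Aq^{-m}}, or the
#' plain Ornstein-Zernike variant with correlation length xi in place of the
#' rod factor.
#'
#' @param q scattering vector (1/Angstrom), > 0.
#' @param params named list/`sans_fit_result`: `dyn_amplitude`, `A`, `m`, and
#'   either (`L`, `R`) for the rod variant or `xi` for the OZ variant.
#' @param variant `"rod"` or `"oz"`.
#' @return intensity (1/cm).
#' @export
total_intensity <- function(q, params, variant = c("rod", "oz")) {
  variant <- match.arg(variant)
  dyn <- if (variant == "rod") {
    rod_oz_intensity(q, params$dyn_amplitude, params$L, params$R)
  } else {
    oz_intensity(q, params$dyn_amplitude, params$xi)
  }
  stat <- if (params$A > 0) power_law_intensity(q, params$A, params$m) else 0
  dyn + stat
}

# ---- fitting -------------------------------------------------------------

#' Fit the two-component intensity model to a SANS profile
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt with box bounds) of
#' the dynamic-plus-static model. Weights are `1/dI^2` when an uncertainty
#' column is present; otherwise residuals are taken in log intensity, which
#' weights points by relative error. A small deterministic grid of
#' data-derived initial guesses (plateau level, low-q slope, crossover q) is
#' tried and the best converged start returned, so fits are reproducible
#' without randomness.
#'
#' @param profile a [sans_profile()] with >= 8 points spanning >= 1 decade in q.
#' @param variant `"rod"` (default) or `"oz"`.
#' @param q_range optional length-2 mask; only points inside are fitted.
#' @return object of class `sans_fit_result`: `dyn_amplitude`, `L`, `R` (rod)
#'   or `xi` (oz), `A`, `m`, `covariance`, `chi2_reduced`, `variant`,
#'   `n_points`, `converged`.
#' @export
fit_sans_profile <- function(profile, variant = c("rod", "oz"),
                             q_range = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(profile, "sans_profile"))
  q <- profile$q
  I <- profile$I
  dI <- profile$dI
  if (!is.null(q_range)) {
    keep <- q >= q_range[1] & q <= q_range[2]
    q <- q[keep]; I <- I[keep]
    if (!is.null(dI)) dI <- dI[keep]
  }
  if (length(q) < 8L) stop("need >= 8 points to fit", call. = FALSE)
  if (max(q) / min(q) < 10) {
    stop("q range must span at least one decade", call. = FALSE)
  }
  use_w <- !is.null(dI) && all(dI > 0)
  log_ok <- all(I > 0)

  unpack <- function(p) {
    if (variant == "rod") {
      list(dyn_amplitude = p[1], L = p[2], R = p[3], A = p[4], m = p[5])
    } else {
      list(dyn_amplitude = p[1], xi = p[2], A = p[3], m = p[4])
    }
  }
  resid_fn <- function(p) {
    mod <- total_intensity(q, unpack(p), variant)
    if (use_w) {
      (mod - I) / dI
    } else if (log_ok) {
      log(pmax(mod, 1e-300)) - log(I)
    } else {
      (mod - I) / pmax(abs(I), stats::median(abs(I)))
    }
  }

  # data-derived deterministic starts
  n <- length(q)
  hi <- q >= stats::quantile(q, 0.5)
  plateau <- stats::median(I[hi])
  plateau <- max(plateau, 1e-12)
  # low-q apparent power-law slope from the first few points
  k <- max(3L, min(5L, n %/% 4L))
  sl <- stats::coef(stats::lm(log(pmax(I[1:k], 1e-300)) ~ log(q[1:k])))[[2]]
  m0 <- min(max(-sl, 2), 5)
  A0 <- max((I[1] - plateau), I[1] * 1e-3) * q[1]^m0
  q_mid <- exp(mean(log(range(q))))
  starts <- list()
  for (fL in c(0.3, 1, 3)) {
    for (fA in c(0.2, 1)) {
      if (variant == "rod") {
        starts[[length(starts) + 1L]] <-
          c(plateau, fL / q_mid, 0.2 * fL / q_mid, fA * A0, m0)
      } else {
        starts[[length(starts) + 1L]] <-
          c(plateau, fL / q_mid, fA * A0, m0)
      }
    }
  }
  npar <- if (variant == "rod") 5L else 4L
  lower <- rep(0, npar); lower[npar] <- 2
  upper <- rep(Inf, npar); upper[npar] <- 5

  best <- NULL
  diags <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diags <- c(diags, conditionMessage(fit))
      next
    }
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) {
    stop("SANS fit failed from all starts: ", paste(diags, collapse = "; "),
         call. = FALSE)
  }
  fit <- best$fit
  p <- fit$par
  dof <- max(n - npar, 1L)
  covm <- tryCatch({
    h <- fit$hessian  # J'J at the optimum
    s2 <- best$ss / dof
    d <- sqrt(diag(h))  # precondition: amplitude scales differ by ~1e9
    s2 * (solve(h / (d %o% d)) / (d %o% d))
  }, error = function(e) matrix(NA_real_, npar, npar))
  res <- c(unpack(p),
           list(covariance = covm,
                chi2_reduced = best$ss / dof,
                variant = variant,
                n_points = n,
                converged = fit$info %in% 1:4))
  class(res) <- "sans_fit_result"
  res
}

#' @export
print.sans_fit_result <- function(x, ...) {
  if (x$variant == "rod") {
    cat(sprintf("<sans_fit_result rod> I0 = %.4g, L = %.4g A, R = %.4g A, A = %.3g, m = %.3f (chi2_red %.3g)\n",
                x$dyn_amplitude, x$L, x$R, x$A, x$m, x$chi2_reduced))
  } else {
    cat(sprintf("<sans_fit_result oz> I0 = %.4g, xi = %.4g A, A = %.3g, m = %.3f (chi2_red %.3g)\n",
                x$dyn_amplitude, x$xi, x$A, x$m, x$chi2_reduced))
  }
  invisible(x)
}

#' Fit a pure power law to (q, I) data
#'
#' Log-log least squares `log I = log A - m log q`. Used for Porod-regime
#' envelopes where the static component is isolated.
#'
#' @param q scattering vectors (> 0).
#' @param I intensities (> 0).
#' @return list with `A`, `m`, `m_se`.
#' @export
fit_power_law <- function(q, I) {
  stopifnot(length(q) == length(I), all(q > 0), all(I > 0))
  fit <- stats::lm(log(I) ~ log(q))
  cf <- stats::coef(fit)
  list(A = exp(cf[[1]]), m = -cf[[2]],
       m_se = sqrt(stats::vcov(fit)[2, 2]))
}

# ---- osmotic amplitude and consistency ----------------------------------

#' Forward intensity predicted from osmotic measurements
#'
#' The intensity scattered by thermodynamic concentration fluctuations at
#' q -> 0 is \eqn{I_{os}(0) = \Delta\rho^2 k_B T \phi^2 / M_{os}}. With the
#' contrast in 1/cm^4, k_B T in J = Pa m^3 and M_os in Pa, the ratio
#' k_B T / M_os is a volume in m^3 and is converted to cm^3 (factor 1e6),
#' giving the amplitude in 1/cm — the same absolute unit as reduced SANS data.
#'
#' @param phi polymer volume fraction.
#' @param M_os longitudinal osmotic modulus (Pa), > 0.
#' @param contrast neutron contrast factor Delta-rho^2 (1/cm^4).
#' @param solvent a [solvent_spec()].
#' @return forward intensity (1/cm).
#' @export
osmotic_amplitude <- function(phi, M_os, contrast, solvent = solvent_spec()) {
  .check_phi(phi)
  stopifnot(contrast > 0)
  if (any(M_os <= 0)) {
    stop("M_os <= 0: thermodynamically unstable state, amplitude undefined",
         call. = FALSE)
  }
  contrast * (solvent$kB * solvent$T / M_os) * 1e6 * phi^2
}

#' Osmotic vs scattering consistency check
#'
#' Compares the dynamic amplitude fitted from a SANS profile with the
#' amplitude predicted from macroscopic osmotic and elastic measurements.
#' Agreement within a multiplicative tolerance indicates that the molecular
#' interactions governing the gel are independent of observational length
#' scale.
#'
#' @param sans_amplitude fitted dynamic forward intensity (1/cm), > 0.
#' @param osmotic_amplitude_value predicted forward intensity (1/cm), > 0.
#' @param tolerance multiplicative tolerance: pass iff
#'   `|log(ratio)| <= log(1 + tolerance)`. Default 0.5 (factor 1.5).
#' @return object of class `consistency_report`: `sans_amplitude`,
#'   `osmotic_amplitude`, `ratio`, `tolerance`, `pass`.
#' @export
consistency_check <- function(sans_amplitude, osmotic_amplitude_value,
                              tolerance = 0.5) {
  if (sans_amplitude <= 0 || osmotic_amplitude_value <= 0) {
    stop("both amplitudes must be positive for a consistency check",
         call. = FALSE)
  }
  stopifnot(tolerance > 0)
  ratio <- sans_amplitude / osmotic_amplitude_value
  structure(
    list(sans_amplitude = sans_amplitude,
         osmotic_amplitude = osmotic_amplitude_value,
         ratio = ratio,
         tolerance = tolerance,
         pass = abs(log(ratio)) <= log1p(tolerance)),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> SANS/osmotic amplitude ratio = %.4g (tolerance factor %.3g): %s\n",
              x$ratio, 1 + x$tolerance, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
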