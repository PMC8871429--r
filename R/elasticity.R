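#' Uniaxial stress-strain series
#'
#' Container for a uniaxial compression experiment on a gel cylinder:
#' deformation ratios \eqn{\Lambda = L/L_0} and nominal stress \eqn{\sigma}
#' (force per undeformed cross-section, Pa). In the classical theory of
#' rubber elasticity \eqn{\sigma = G_s(\Lambda - \Lambda^{-2})}.
#'
#' @param lambda deformation ratios, all > 0 (compression: Lambda < 1).
#' @param sigma nominal stress in Pa, same length as `lambda`.
#' @param condition optional named list of condition metadata (salt, T, ...).
#' @return object of class `stress_strain_series`.
#' @export
stress_strain_series <- function(lambda, sigma, condition = list()) {
  if (!is.numeric(lambda) || !is.numeric(sigma)) {
    stop("lambda and sigma must be numeric", call. = FALSE)
  }
  if (length(lambda) != length(sigma) || length(lambda) < 1L) {
    stop("lambda and sigma must have equal length >= 1", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("deformation ratio Lambda must be positive and finite", call. = FALSE)
  }
  structure(
    list(lambda = as.numeric(lambda), sigma = as.numeric(sigma),
         condition = condition),
    class = "stress_strain_series"
  )
}

#' @export
print.stress_strain_series <- function(x, ...) {
  cat(sprintf("<stress_strain_series> %d points, Lambda in [%.3f, %.3f]\n",
              length(x$lambda), min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Fit the shear modulus from uniaxial compression data
#'
#' No-intercept least squares of nominal stress on the strain function
#' \eqn{\Lambda - \Lambda^{-2}}: the model passes exactly through the
#' undeformed state (\eqn{\Lambda = 1, \sigma = 0}), so no intercept is
#' estimated. Points outside `lambda_range` are discarded before fitting;
#' the default range reflects the regime where gels deform affinely without
#' barrel distortion.
#'
#' @param series a [stress_strain_series()].
#' @param lambda_range length-2 numeric, points with
#'   `lambda_range[1] <= Lambda <= lambda_range[2]` are kept. Use `NULL` to
#'   keep all points.
#' @return object of class `shear_modulus_fit`: `G_s` (Pa), `stderr` (Pa,
#'   heteroscedasticity-robust), `n_points`, `residual_rms` (Pa).
#' @examples
#' s <- stress_strain_series(c(0.8, 0.9), 5000 * (c(0.8, 0.9) - c(0.8, 0.9)^-2))
#' fit_shear_modulus(s)$G_s  # 5000
#' @export
fit_shear_modulus <- function(series, lambda_range = c(0.7, 1)) {
  stopifnot(inherits(series, "stress_strain_series"))
  lam <- series$lambda
  sig <- series$sigma
  if (!is.null(lambda_range)) {
    stopifnot(length(lambda_range) == 2L)
    keep <- lam >= lambda_range[1] & lam <= lambda_range[2]
    if (!any(keep)) {
      stop("no points inside lambda_range; pass lambda_range = NULL to keep all",
           call. = FALSE)
    }
    lam <- lam[keep]
    sig <- sig[keep]
  }
  x <- lam - lam^-2
  if (all(abs(x) < .Machine$double.eps * 8)) {
    stop("degenerate design: all Lambda equal 1, shear modulus unidentifiable",
         call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need >= 2 points to fit a modulus", call. = FALSE)
  sxx <- sum(x * x)
  G <- sum(x * sig) / sxx
  res <- sig - G * x
  dof <- max(n - 1L, 1L)
  s2 <- sum(res^2) / dof
  # heteroscedasticity-robust (HC1) standard error: stress noise typically
  # scales with |sigma|, so the homoscedastic formula is anti-conservative
  se_robust <- sqrt(sum(x^2 * res^2) * n / dof) / sxx
  structure(
    list(G_s = G,
         stderr = se_robust,
         n_points = n,
         residual_rms = sqrt(mean(res^2)),
         df = dof),
    class = "shear_modulus_fit"
  )
}

#' @export
print.shear_modulus_fit <- function(x, ...) {
  cat(sprintf("<shear_modulus_fit> G_s = %.6g Pa (se %.3g Pa, n = %d, rms %.3g Pa)\n",
              x$G_s, x$stderr, x$n_points, x$residual_rms))
  invisible(x)
}

#' Elastic contribution to the swelling pressure
#'
#' In the classical affine-network theory the elastic pressure equals minus
#' the shear modulus: \eqn{\Pi_{elast} = -A RT \nu \phi^{1/3} = -G_s}.
#'
#' @param G_s shear modulus in Pa, >= 0.
#' @return elastic pressure in Pa (non-positive).
#' @export
elastic_pressure <- function(G_s) {
  stopifnot(is.numeric(G_s), all(is.finite(G_s)))
  if (any(G_s < 0)) stop("shear modulus must be non-negative", call. = FALSE)
  -G_s
}

#' Shear modulus at arbitrary swelling via the phi^(1/3) scaling
#'
#' `G(phi) = C * (phi/phi_ref)^(1/3)`, the classical-theory concentration
#' dependence used when a modulus measured at `phi_ref` must be extrapolated
#' along a deswelling curve.
#'
#' @param phi polymer volume fraction(s) in (0,1).
#' @param C modulus at the reference volume fraction (Pa), > 0.
#' @param phi_ref reference volume fraction in (0,1).
#' @return modulus in Pa, same length as `phi`.
#' @export
shear_modulus_scaling <- function(phi, C, phi_ref) {
  .check_phi(phi)
  stopifnot(is.numeric(C), C >= 0, phi_ref > 0, phi_ref < 1)
  C * (phi / phi_ref)^(1 / 3)
}

#' Fit the concentration scaling of the shear modulus
#'
#' Log-log least squares `log G = log(prefactor) + exponent * log(phi)`.
#' The classical rubber-elasticity exponent is 1/3; the fit reports whether
#' that value is rejected at the 95% level, as a diagnostic rather than a
#' constraint (finite chain extensibility bends the scaling at high swelling).
#'
#' @param phi volume fractions (> 0), length >= 3.
#' @param G_s shear moduli in Pa (> 0), same length.
#' @return object of class `elastic_scaling_fit`: `prefactor` (Pa, value at
#'   phi = 1), `exponent`, `covariance` (2x2, log-prefactor and exponent),
#'   `exponent_se`, `classical_rejected` (logical, two-sided 95% t-test of
#'   exponent = 1/3).
#' @export
fit_elasticity_scaling <- function(phi, G_s) {
  if (length(phi) != length(G_s) || length(phi) < 3L) {
    stop("need >= 3 (phi, G_s) pairs of equal length", call. = FALSE)
  }
  if (any(phi <= 0) || any(G_s <= 0)) {
    stop("phi and G_s must be strictly positive for log-log fitting",
         call. = FALSE)
  }
  fit <- stats::lm(log(G_s) ~ log(phi))
  cf <- stats::coef(fit)
  # noiseless data give an exact fit; vcov's perfect-fit warning is expected
  vc <- suppressWarnings(stats::vcov(fit))
  se <- sqrt(vc[2, 2])
  tstat <- (cf[[2]] - 1 / 3) / se
  crit <- stats::qt(0.975, df = fit$df.residual)
  structure(
    list(prefactor = exp(cf[[1]]),
         exponent = cf[[2]],
         covariance = vc,
         exponent_se = se,
         classical_rejected = is.finite(tstat) && abs(tstat) > crit,
         n_points = length(phi)),
    class = "elastic_scaling_fit"
  )
}

#' @export
print.elastic_scaling_fit <- function(x, ...) {
  cat(sprintf("<elastic_scaling_fit> G = %.4g * phi^%.4f (se %.3g); classical 1/3 %s\n",
              x$prefactor, x$exponent, x$exponent_se,
              if (x$classical_rejected) "rejected at 95%" else "not rejected"))
  invisible(x)
}

#' Elastic pressure from the Gaussian affine-network free energy
#'
#' Independent route to the phi^(1/3) law: build the Gaussian affine-network
#' elastic free energy of an isotropically swollen network,
#' \eqn{F_{el}(V) = (3/2) A R T n_c (\lambda^2 - 1)} with
#' \eqn{\lambda = (V/V_{ref})^{1/3}}, and differentiate numerically,
#' \eqn{\Pi_{elast} = -\partial F_{el}/\partial V}. Used to verify that the
#' closed form \eqn{\Pi_{elast} \propto -\phi^{1/3}} follows from the free
#' energy rather than being assumed.
#'
#' @param phi volume fractions at which to evaluate the pressure.
#' @param prefactor `A * R * T * nu_ref` in Pa (modulus at `phi_ref`), > 0.
#' @param phi_ref reference volume fraction (network as prepared).
#' @param rel_step relative step of the central difference in V.
#' @return elastic pressure in Pa (negative), numerically differentiated.
#' @export
gaussian_network_pressure <- function(phi, prefactor = 2e4, phi_ref = 0.05,
                                      rel_step = 1e-6) {
  .check_phi(phi)
  stopifnot(prefactor > 0, phi_ref > 0, phi_ref < 1, rel_step > 0)
  # Work per unit moles of chains scaled so that -dF/dV at phi_ref equals
  # -prefactor. With lambda = (V/V_ref)^{1/3} and V = V_ref * phi_ref / phi:
  # F(V) = (prefactor * V_ref / 2) * 3 * (lambda^2 - 1); V_ref = 1 wlog.
  Fel <- function(V) 1.5 * prefactor * (V^(2 / 3) - 1)
  V <- phi_ref / phi
  h <- rel_step * V
  -(Fel(V + h) - Fel(V - h)) / (2 * h)
}
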