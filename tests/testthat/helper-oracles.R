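# Independent oracles used across tests. These deliberately avoid the
# package's own solvers: dense scans, quadrature and closed forms only.

# all sign-change brackets of Pi_tot on a dense log grid (midpoints)
brute_force_equilibria <- function(model, n = 1e6,
                                   interval = c(1e-4, 0.99)) {
  g <- exp(seq(log(interval[1]), log(interval[2]), length.out = n))
  f <- swelling_pressure(g, model)
  idx <- which(f[-1] * f[-n] < 0)
  list(phi = (g[idx] + g[idx + 1]) / 2,
       spacing_rel = log(interval[2] / interval[1]) / (n - 1))
}

# orientationally averaged smooth-sphere form factor (Rayleigh)
sphere_form_factor <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# local maxima (envelope points) of a positive oscillating series
local_maxima <- function(y) which(diff(sign(diff(y))) == -2) + 1L

# 3D Fourier transform of the exponential correlation exp(-r/xi)/r by
# quadrature (up to a q-independent constant)
oz_by_quadrature <- function(q, xi) {
  # 4 pi int r^2 [exp(-r/xi)/r] sinc(qr) dr = (4 pi / q) int exp(-r/xi) sin(qr) dr
  vapply(q, function(qq) {
    4 * pi / qq * stats::integrate(function(r) exp(-r / xi) * sin(qq * r),
                                   0, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

# number of sign changes in a numeric vector (zeros dropped)
n_sign_changes <- function(x) {
  s <- sign(x[x != 0])
  sum(diff(s) != 0)
}

default_water <- solvent_spec()
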