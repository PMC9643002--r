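#' Number of coefficients of the real even-order SH basis
#' @param lmax even, non-negative maximum harmonic order.
#' @return integer number of basis functions.
#' @export
sh_ncoef <- function(lmax) {
  check_lmax(lmax)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

check_lmax <- function(lmax) {
  if (length(lmax) != 1L || lmax < 0 || lmax %% 2 != 0)
    stop("lmax must be a single non-negative even integer")
  invisible(lmax)
}

#' Evaluate the real symmetric spherical-harmonic basis
#'
#' Returns the matrix of basis-function values for the real, even-order,
#' antipodally symmetric spherical-harmonic basis (orthonormal on the
#' sphere, MRtrix coefficient ordering: l = 0, 2, ..., lmax; m = -l..l
#' within each l).
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param lmax even maximum order.
#' @return n x `sh_ncoef(lmax)` numeric matrix.
#' @export
sh_basis <- function(dirs, lmax) {
  check_lmax(lmax)
  dirs <- rbind_pts(dirs)
  cpp_sh_basis(dirs, as.integer(lmax))
}

#' Deterministic quasi-uniform sphere sampling (spherical Fibonacci set)
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Synthesize a fibre-orientation distribution from discrete fibre lobes
#'
#' Builds the spherical-harmonic coefficients of a sum of antipodally
#' symmetric Watson-like lobes, one per fibre population:
#' `sum_i density_i * exp(kappa * ((d . u_i)^2 - 1))`.
#' Coefficients are obtained by least squares against the basis on a
#' deterministic sphere sampling (>= 300 points).  Sharp lobes truncated
#' at finite order ring below zero; when the synthesized amplitude dips
#' below `-0.01 * max` anywhere on the sampling, the smallest
#' Laplace-Beltrami apodization (per-band taper `exp(-s l (l+1))`, `s`
#' found by bisection) restoring that bound is applied.  The taper is
#' scale-free, so coefficients remain exactly linear in the population
#' densities.
#'
#' @param populations list of `list(direction = unit 3-vector,
#'   density = non-negative scalar)`; may be empty.
#' @param kappa lobe sharpness (> 0), default 20.
#' @param lmax even maximum order, default 8.
#' @param n_points sphere sampling size for the fit (>= 300).
#' @param apodize enforce the near-non-negativity bound (default TRUE);
#'   `FALSE` returns the raw least-squares fit.
#' @return numeric coefficient vector of length `sh_ncoef(lmax)`.
#' @export
synthesize_fod <- function(populations, kappa = 20, lmax = 8, n_points = 500,
                           apodize = TRUE) {
  check_lmax(lmax)
  stopifnot(kappa > 0, n_points >= 300)
  nc <- sh_ncoef(lmax)
  if (length(populations) == 0L) return(numeric(nc))
  dirs <- sphere_points(n_points)
  B <- sh_basis(dirs, lmax)
  f <- lobe_amplitudes(dirs, populations, kappa)
  coef <- qr.solve(B, f)
  if (apodize) coef <- apodize_nonneg(coef, B, lmax)
  coef
}

# per-coefficient harmonic order l for the even basis
sh_band_l <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

# smallest exp(-s l(l+1)) band taper keeping amplitude >= -0.01 * max
apodize_nonneg <- function(coef, B, lmax, bound = 0.01) {
  ll <- sh_band_l(lmax)
  ok <- function(s) {
    a <- drop(B %*% (coef * exp(-s * ll * (ll + 1))))
    min(a) >= -bound * max(a)
  }
  if (ok(0)) return(coef)
  hi <- 0.01
  while (!ok(hi)) hi <- hi * 2
  lo <- 0
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  coef * exp(-hi * ll * (ll + 1))
}

lobe_amplitudes <- function(dirs, populations, kappa) {
  f <- numeric(nrow(dirs))
  for (pop in populations) {
    u <- as.numeric(pop$direction)
    if (abs(sqrt(sum(u^2)) - 1) > 1e-6)
      stop("fibre population directions must be unit vectors")
    dens <- as.numeric(pop$density)
    if (dens < 0) stop("fibre population densities must be >= 0")
    ct2 <- drop(dirs %*% u)^2
    f <- f + dens * exp(kappa * (ct2 - 1))
  }
  f
}

#' FOD amplitude along directions
#'
#' Real spherical-harmonic synthesis of the coefficient vector at one or
#' more unit directions; negative synthesized values are clamped to zero.
#'
#' @param coefficients SH coefficient vector (length must match a valid
#'   even lmax).
#' @param direction unit 3-vector or n x 3 matrix of unit vectors.
#' @return numeric amplitude(s), >= 0.
#' @export
fod_amplitude <- function(coefficients, direction) {
  lmax <- lmax_for_ncoef(length(coefficients))
  B <- sh_basis(direction, lmax)
  pmax(drop(B %*% coefficients), 0)
}

lmax_for_ncoef <- function(nc) {
  lmax <- (-3 + sqrt(1 + 8 * nc)) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop("coefficient length does not correspond to a valid even lmax")
  as.integer(round(lmax))
}
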