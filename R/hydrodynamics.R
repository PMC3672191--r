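#' Stokes-Einstein hydrodynamic radius
#'
#' Radius of the sphere whose translational diffusion coefficient equals the
#' measured one: `R = kT / (6 pi eta D)`. Input D in um^2/s, viscosity in
#' cP; the result is returned in angstroms.
#'
#' @param D_um2_s Diffusion coefficient(s), um^2/s; vectorised.
#' @param cond A [physical_conditions()]; default water at 25 C.
#' @return Hydrodynamic radius (angstrom).
#' @examples
#' stokes_einstein_radius(84)   # ~29 A
#' stokes_einstein_radius(300)  # ~8.2 A
#' @export
stokes_einstein_radius <- function(D_um2_s, cond = physical_conditions()) {
  stopifnot(inherits(cond, "physical_conditions"))
  if (any(!is.finite(D_um2_s)) || any(D_um2_s <= 0))
    abort("Diffusion coefficients must be positive.")
  eta <- cond$viscosity_cP * 1e-3                    # Pa s
  R_m <- .kB * cond$temperature_K / (6 * pi * eta * D_um2_s * 1e-12)
  R_m * 1e10
}

#' Stokes-Einstein diffusion coefficient of a sphere
#'
#' Inverse of [stokes_einstein_radius()]: `D = kT / (6 pi eta R)`.
#'
#' @param R_A Sphere radius, angstrom; vectorised.
#' @param cond A [physical_conditions()].
#' @return Diffusion coefficient, um^2/s.
#' @export
stokes_einstein_D <- function(R_A, cond = physical_conditions()) {
  stopifnot(inherits(cond, "physical_conditions"))
  if (any(!is.finite(R_A)) || any(R_A <= 0))
    abort("Radii must be positive.")
  eta <- cond$viscosity_cP * 1e-3
  D_m2 <- .kB * cond$temperature_K / (6 * pi * eta * R_A * 1e-10)
  D_m2 * 1e12
}

#' Empirical native-protein hydrodynamic radius (Wilkins scaling)
#'
#' The empirical power law relating the hydrodynamic radius of folded
#' proteins to their residue count, `R_N = c0 * N^nu` with published central
#' values c0 = 4.75 A and nu = 0.29.
#'
#' @param n_residues Residue count(s), integer >= 1; vectorised.
#' @param c0 Prefactor, angstrom.
#' @param nu Scaling exponent.
#' @return Predicted radius, angstrom.
#' @examples
#' wilkins_native_radius(375)  # ~26.5 A
#' @export
wilkins_native_radius <- function(n_residues, c0 = 4.75, nu = 0.29) {
  if (any(n_residues < 1) || any(n_residues != round(n_residues)))
    abort("`n_residues` must be integers >= 1.")
  c0 * n_residues^nu
}

#' Volume of a sphere
#'
#' @param R_A Radius, angstrom; vectorised.
#' @return Volume, cubic angstrom.
#' @examples
#' sphere_volume(29)  # ~1.02e5 A^3
#' @export
sphere_volume <- function(R_A) {
  if (any(!is.finite(R_A)) || any(R_A <= 0))
    abort("Radii must be positive.")
  4 / 3 * pi * R_A^3
}

#' Perrin translational friction factor of a prolate ellipsoid
#'
#' Ratio of the translational friction of a prolate spheroid with axial
#' ratio `p = b/a` to that of the sphere of equal volume:
#' `F(p) = sqrt(1 - p^2) / (p^(2/3) * log((1 + sqrt(1 - p^2)) / p))`,
#' with `F(1) = 1` by continuous extension. `F > 1` for any aspherical
#' shape, so an ellipsoid always diffuses more slowly than the equal-volume
#' sphere.
#'
#' @param p Axial ratio(s) in (0, 1]; vectorised.
#' @return Friction factor(s), dimensionless, >= 1.
#' @examples
#' perrin_factor(c(1, 0.6, 0.1))
#' @export
perrin_factor <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    abort("Axial ratios must lie in (0, 1].")
  out <- rep(1, length(p))
  lt1 <- p < 1
  if (any(lt1)) {
    q <- p[lt1]
    xi <- sqrt(1 - q^2)
    out[lt1] <- xi / (q^(2 / 3) * log((1 + xi) / q))
  }
  out
}

#' Prolate ellipsoid shape
#'
#' Semi-axes of a prolate spheroid (`a >= b > 0`), with derived axial ratio
#' `p = b/a` and volume `(4/3) pi a b^2`.
#'
#' @param a_A Long semi-axis, angstrom.
#' @param b_A Short semi-axis, angstrom.
#' @return An object of class `prolate_shape` with fields `a_A`, `b_A`, `p`
#'   and `volume_A3`.
#' @examples
#' prolate_shape(35.3, 21.2)
#' @export
prolate_shape <- function(a_A, b_A) {
  if (!is.numeric(a_A) || !is.numeric(b_A) || length(a_A) != 1L || length(b_A) != 1L)
    abort("`a_A` and `b_A` must be single numbers.")
  if (b_A <= 0 || a_A < b_A)
    abort("Prolate semi-axes require a >= b > 0.")
  structure(
    list(a_A = a_A, b_A = b_A, p = b_A / a_A,
         volume_A3 = 4 / 3 * pi * a_A * b_A^2),
    class = "prolate_shape"
  )
}

#' @export
print.prolate_shape <- function(x, ...) {
  cat(sprintf("<prolate_shape> a = %.4g A, b = %.4g A (p = %.4g, V = %.4g A^3)\n",
              x$a_A, x$b_A, x$p, x$volume_A3))
  invisible(x)
}

#' Translational diffusion coefficient of a prolate ellipsoid
#'
#' Diffusion coefficient implied by the Perrin model: the Stokes-Einstein
#' coefficient of the equal-volume sphere (radius `(a b^2)^(1/3)`), divided
#' by the friction factor [perrin_factor()].
#'
#' @param shape A [prolate_shape()].
#' @param cond A [physical_conditions()].
#' @return Diffusion coefficient, um^2/s.
#' @examples
#' prolate_diffusion(prolate_shape(35.3, 21.2))
#' @export
prolate_diffusion <- function(shape, cond = physical_conditions()) {
  stopifnot(inherits(shape, "prolate_shape"))
  r_eq <- (shape$a_A * shape$b_A^2)^(1 / 3)
  stokes_einstein_D(r_eq, cond) / perrin_factor(shape$p)
}

#' Invert the Perrin model at fixed volume
#'
#' Finds the prolate ellipsoid of the given volume whose Perrin diffusion
#' coefficient equals a measured value. Because `F(p)` is strictly
#' decreasing on (0, 1], the axial ratio solving
#' `F(p) = D_sphere / D_meas` (with `D_sphere` the Stokes-Einstein value of
#' the equal-volume sphere) is unique and is found by bisection to a
#' relative diffusion tolerance of 1e-10. The semi-axes follow as
#' `a = R_eq * p^(-2/3)`, `b = p * a`, which conserves the volume exactly.
#'
#' @param D_meas_um2_s Measured diffusion coefficient, um^2/s; must be below
#'   the equal-volume sphere's Stokes-Einstein coefficient.
#' @param volume_A3 Imposed ellipsoid volume, cubic angstrom.
#' @param cond A [physical_conditions()].
#' @param tol Relative tolerance on the reproduced diffusion coefficient.
#' @param max_iter Bisection iteration cap.
#' @return A [prolate_shape()]; `prolate_diffusion()` of the result
#'   reproduces `D_meas_um2_s` to within `tol`.
#' @examples
#' invert_prolate(44, volume_A3 = 1e5)
#' @export
invert_prolate <- function(D_meas_um2_s, volume_A3,
                           cond = physical_conditions(),
                           tol = 1e-10, max_iter = 200L) {
  if (!is.numeric(D_meas_um2_s) || length(D_meas_um2_s) != 1L || D_meas_um2_s <= 0)
    abort("`D_meas_um2_s` must be a single positive number.")
  if (!is.numeric(volume_A3) || length(volume_A3) != 1L || volume_A3 <= 0)
    abort("`volume_A3` must be a single positive number.")
  r_eq <- (3 * volume_A3 / (4 * pi))^(1 / 3)
  d_sph <- stokes_einstein_D(r_eq, cond)
  if (D_meas_um2_s >= d_sph * (1 - 1e-12)) {
    if (D_meas_um2_s <= d_sph * (1 + 1e-9))
      return(prolate_shape(r_eq, r_eq))  # sphere boundary
    abort(sprintf(
      "No prolate solution: D = %.4g um^2/s exceeds the equal-volume sphere value %.4g um^2/s.",
      D_meas_um2_s, d_sph))
  }
  target <- d_sph / D_meas_um2_s  # required friction factor, > 1
  lo <- 1e-4
  hi <- 1
  if (perrin_factor(lo) < target)
    abort("Out of model range: required axial ratio is below 1e-4.")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (perrin_factor(mid) > target) lo <- mid else hi <- mid
    if (abs(perrin_factor((lo + hi) / 2) - target) <= tol * target &&
        (hi - lo) < 1e-14 * hi + 1e-15) break
  }
  p <- (lo + hi) / 2
  a <- r_eq * p^(-2 / 3)
  prolate_shape(a, p * a)
}

#' Hydrodynamic summary of a measured diffusion coefficient
#'
#' Convenience wrapper combining the spherical and ellipsoidal
#' interpretations of a diffusion coefficient into one tibble row: the
#' Stokes-Einstein radius always, and — when a constraint volume is given
#' and the coefficient lies below the equal-volume sphere bound — the
#' prolate semi-axes, axial ratio and model-implied diffusion coefficient.
#'
#' @param D_um2_s Measured diffusion coefficient(s), um^2/s; vectorised.
#' @param volume_A3 Optional imposed ellipsoid volume, cubic angstrom.
#' @param cond A [physical_conditions()].
#' @return A tibble with columns `D_um2_s`, `R_sph_A`, `a_A`, `b_A`, `p`,
#'   `D_model_um2_s` (shape columns `NA` where no prolate solution applies).
#' @examples
#' hydro_shape(c(84, 44, 31), volume_A3 = 1.02e5)
#' @export
hydro_shape <- function(D_um2_s, volume_A3 = NULL, cond = physical_conditions()) {
  rows <- purrr::map(D_um2_s, function(D) {
    R_sph <- stokes_einstein_radius(D, cond)
    out <- tibble(D_um2_s = D, R_sph_A = R_sph,
                  a_A = NA_real_, b_A = NA_real_, p = NA_real_,
                  D_model_um2_s = NA_real_)
    if (!is.null(volume_A3)) {
      r_eq <- (3 * volume_A3 / (4 * pi))^(1 / 3)
      if (D <= stokes_einstein_D(r_eq, cond)) {
        sh <- invert_prolate(D, volume_A3, cond)
        out$a_A <- sh$a_A
        out$b_A <- sh$b_A
        out$p <- sh$p
        out$D_model_um2_s <- prolate_diffusion(sh, cond)
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}
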