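#' Observation-volume beam geometry
#'
#' Describes the 3D Gaussian observation volume of a confocal FCS instrument
#' by its radial and axial 1/e^2 radii and the excitation mode. Two-photon
#' excitation squares the illumination profile, which halves the effective
#' residence time for a given beam waist; this is folded into the
#' diffusion-time prefactor (see [diffusion_time()]).
#'
#' @param omega0_um Radial 1/e^2 beam radius, micrometres. Must be positive.
#' @param z0_um Axial 1/e^2 radius, micrometres. Must be positive and at
#'   least `omega0_um` (structure parameter `s = z0/omega0 >= 1`).
#' @param photon_mode `"two-photon"` (default, matching a two-photon
#'   instrument) or `"one-photon"`.
#' @return An object of class `beam_geometry` with fields `omega0_um`,
#'   `z0_um`, `photon_mode` and the structure parameter `s`.
#' @examples
#' beam_geometry(0.4, 2.0)
#' @export
beam_geometry <- function(omega0_um, z0_um,
                          photon_mode = c("two-photon", "one-photon")) {
  photon_mode <- match.arg(photon_mode)
  if (!is.numeric(omega0_um) || length(omega0_um) != 1L || omega0_um <= 0)
    abort("`omega0_um` must be a single positive number.")
  if (!is.numeric(z0_um) || length(z0_um) != 1L || z0_um <= 0)
    abort("`z0_um` must be a single positive number.")
  s <- z0_um / omega0_um
  if (s < 1)
    abort("Structure parameter z0/omega0 must be >= 1.")
  structure(
    list(omega0_um = omega0_um, z0_um = z0_um,
         photon_mode = photon_mode, s = s),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> omega0 = %g um, z0 = %g um (s = %.3g), %s\n",
              x$omega0_um, x$z0_um, x$s, x$photon_mode))
  invisible(x)
}

#' Physical conditions of the solvent
#'
#' Temperature and viscosity used by the Stokes-Einstein and Perrin
#' relations. Defaults are water at 25 degrees C.
#'
#' @param temperature_K Absolute temperature, kelvin.
#' @param viscosity_cP Dynamic viscosity, centipoise (1 cP = 1e-3 Pa s).
#' @return An object of class `physical_conditions`.
#' @examples
#' physical_conditions()  # water at 25 C
#' @export
physical_conditions <- function(temperature_K = 298.15, viscosity_cP = 0.89) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L || temperature_K <= 0)
    abort("`temperature_K` must be a single positive number.")
  if (!is.numeric(viscosity_cP) || length(viscosity_cP) != 1L || viscosity_cP <= 0)
    abort("`viscosity_cP` must be a single positive number.")
  structure(
    list(temperature_K = temperature_K, viscosity_cP = viscosity_cP),
    class = "physical_conditions"
  )
}

#' One- or two-species FCS model
#'
#' Bundles the diffusing species (diffusion coefficient and amplitude
#' fraction each), the mean occupancy of the observation volume and an
#' additive baseline into the forward model evaluated by
#' [autocorrelation()]. Fractions are amplitude fractions under the
#' equal-brightness assumption and must sum to 1.
#'
#' @param D_um2_s Diffusion coefficient(s), um^2/s; length 1 or 2.
#' @param fraction Amplitude fraction(s), same length as `D_um2_s`, summing
#'   to 1 (within 1e-12). Defaults to a single species.
#' @param occupancy Mean number of molecules in the observation volume
#'   (`G(0) = baseline + 1/occupancy`). Must be positive.
#' @param baseline Additive offset of G; default 0.
#' @return An object of class `fcs_model`; `$species` is a tibble with
#'   columns `D_um2_s` and `fraction`, sorted by descending D.
#' @examples
#' fcs_model(84, occupancy = 5)
#' fcs_model(c(43, 14), fraction = c(0.97, 0.03), occupancy = 5)
#' @export
fcs_model <- function(D_um2_s, fraction = NULL, occupancy = 1, baseline = 0) {
  n <- length(D_um2_s)
  if (n < 1L || n > 2L)
    abort("An FCS model must have one or two species.")
  if (any(!is.finite(D_um2_s)) || any(D_um2_s <= 0))
    abort("All diffusion coefficients must be positive.")
  if (is.null(fraction)) {
    if (n != 1L) abort("`fraction` is required for a two-species model.")
    fraction <- 1
  }
  if (length(fraction) != n)
    abort("`fraction` must have one entry per species.")
  if (any(fraction < 0) || abs(sum(fraction) - 1) > 1e-12)
    abort("Fractions must be non-negative and sum to 1 (within 1e-12).")
  if (!is.numeric(occupancy) || length(occupancy) != 1L || occupancy <= 0)
    abort("`occupancy` must be a single positive number.")
  ord <- order(D_um2_s, decreasing = TRUE)
  structure(
    list(
      species = tibble(D_um2_s = D_um2_s[ord], fraction = fraction[ord]),
      occupancy = occupancy,
      baseline = baseline
    ),
    class = "fcs_model"
  )
}

#' @export
print.fcs_model <- function(x, ...) {
  cat(sprintf("<fcs_model> %d species, occupancy %.4g, baseline %g\n",
              nrow(x$species), x$occupancy, x$baseline))
  print(x$species)
  invisible(x)
}

#' Correlation curve constructor
#'
#' A correlation curve is a tibble with columns `lag_s` (strictly increasing
#' positive lag times, seconds), `g` (correlation values) and optionally
#' `sigma` (positive per-point standard deviations). This constructor
#' validates the invariants and attaches the `fcs_curve` class so that
#' [autoplot()] and the fitting functions recognise it.
#'
#' @param lag_s Strictly increasing positive lag times, s.
#' @param g Correlation values, same length.
#' @param sigma Optional positive per-point standard deviations.
#' @return A tibble of class `fcs_curve`.
#' @examples
#' fcs_curve(c(1e-5, 1e-4, 1e-3), c(0.19, 0.15, 0.05))
#' @export
fcs_curve <- function(lag_s, g, sigma = NULL) {
  if (length(lag_s) != length(g))
    abort("`lag_s` and `g` must have the same length.")
  if (any(!is.finite(lag_s)) || any(!is.finite(g)))
    abort("Lag times and correlation values must be finite.")
  if (any(lag_s <= 0))
    abort("Lag times must be positive.")
  if (any(diff(lag_s) <= 0))
    abort("Lag times must be strictly increasing.")
  tb <- tibble(lag_s = as.numeric(lag_s), g = as.numeric(g))
  if (!is.null(sigma)) {
    if (length(sigma) != length(g))
      abort("`sigma` must have the same length as `g`.")
    if (any(sigma <= 0))
      abort("`sigma` values must be positive.")
    tb$sigma <- as.numeric(sigma)
  }
  class(tb) <- c("fcs_curve", class(tb))
  tb
}

as_fcs_curve <- function(x) {
  if (inherits(x, "fcs_curve")) return(x)
  if (!is.data.frame(x) || !all(c("lag_s", "g") %in% names(x)))
    abort("A correlation curve needs columns `lag_s` and `g`.")
  fcs_curve(x$lag_s, x$g, sigma = x[["sigma"]])
}

#' Characteristic diffusion time of a species in the observation volume
#'
#' The lag time at which the autocorrelation of a freely diffusing species
#' has decayed to half of its amplitude. For one-photon excitation
#' `tau_D = omega0^2 / (4 D)`; two-photon excitation squares the detection
#' profile, giving `tau_D = omega0^2 / (8 D)`.
#'
#' @param D_um2_s Diffusion coefficient(s), um^2/s; vectorised.
#' @param beam A [beam_geometry()].
#' @return Diffusion time(s) in seconds.
#' @examples
#' diffusion_time(300, beam_geometry(0.4, 2.0))            # 66.7 us
#' diffusion_time(300, beam_geometry(0.4, 2.0, "one-photon"))  # 133.3 us
#' @export
diffusion_time <- function(D_um2_s, beam) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (any(!is.finite(D_um2_s)) || any(D_um2_s <= 0))
    abort("Diffusion coefficients must be positive.")
  k <- if (beam$photon_mode == "two-photon") 8 else 4
  beam$omega0_um^2 / (k * D_um2_s)
}

#' Diffusion coefficient from a measured diffusion time
#'
#' Exact inverse of [diffusion_time()].
#'
#' @param tau_d_s Diffusion time(s), seconds; vectorised.
#' @param beam A [beam_geometry()].
#' @return Diffusion coefficient(s), um^2/s.
#' @export
diffusion_from_time <- function(tau_d_s, beam) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (any(!is.finite(tau_d_s)) || any(tau_d_s <= 0))
    abort("Diffusion times must be positive.")
  k <- if (beam$photon_mode == "two-photon") 8 else 4
  beam$omega0_um^2 / (k * tau_d_s)
}

#' Calibrate the beam waist from a reference fluorophore
#'
#' The radial beam radius is obtained from the fitted diffusion time of a
#' fluorophore of known diffusion coefficient (the classic calibration uses
#' rhodamine 110 with D = 300 um^2/s): `omega0 = sqrt(k * D_ref * tau_D)`,
#' with `k = 8` for two-photon and `k = 4` for one-photon excitation.
#'
#' @param tau_d_ref_s Fitted diffusion time of the reference, seconds.
#' @param D_ref_um2_s Known diffusion coefficient of the reference, um^2/s;
#'   default 300 (rhodamine 110).
#' @param z0_um Axial radius to attach to the returned geometry; default
#'   keeps the common 5:1 aspect (`5 * omega0`).
#' @param photon_mode Excitation mode, as in [beam_geometry()].
#' @return A calibrated [beam_geometry()].
#' @examples
#' calibrate_beam(66.7e-6)  # omega0 very close to 0.4 um
#' @export
calibrate_beam <- function(tau_d_ref_s, D_ref_um2_s = 300, z0_um = NULL,
                           photon_mode = c("two-photon", "one-photon")) {
  photon_mode <- match.arg(photon_mode)
  if (!is.numeric(tau_d_ref_s) || length(tau_d_ref_s) != 1L || tau_d_ref_s <= 0)
    abort("`tau_d_ref_s` must be a single positive number.")
  if (!is.numeric(D_ref_um2_s) || length(D_ref_um2_s) != 1L || D_ref_um2_s <= 0)
    abort("`D_ref_um2_s` must be a single positive number.")
  k <- if (photon_mode == "two-photon") 8 else 4
  omega0 <- sqrt(k * D_ref_um2_s * tau_d_ref_s)
  beam_geometry(omega0, z0_um %||% (5 * omega0), photon_mode)
}

#' Autocorrelation of an FCS model
#'
#' Evaluates the analytic autocorrelation function of free 3D diffusion
#' through a 3D Gaussian observation volume,
#' `G(tau) = baseline + (1/N) * sum_i f_i * (1 + tau/tau_Di)^-1 *
#' (1 + tau/(s^2 tau_Di))^-1/2`, where `N` is the occupancy, `f_i` the
#' amplitude fractions and `s = z0/omega0` the structure parameter. The
#' two-species curve is the amplitude-weighted sum of the single-species
#' curves.
#'
#' @param model An [fcs_model()].
#' @param beam A [beam_geometry()].
#' @param lag_s Positive lag times, seconds.
#' @return An [fcs_curve()] tibble with columns `lag_s` and `g`.
#' @examples
#' beam <- beam_geometry(0.4, 2.0)
#' autocorrelation(fcs_model(84, occupancy = 5), beam, 10^seq(-6, 0, 0.5))
#' @export
autocorrelation <- function(model, beam, lag_s) {
  stopifnot(inherits(model, "fcs_model"), inherits(beam, "beam_geometry"))
  if (length(lag_s) == 0L || any(!is.finite(lag_s)) || any(lag_s <= 0))
    abort("Lag times must be positive and finite.")
  g <- g_model(lag_s, model$species$D_um2_s, model$species$fraction,
               model$occupancy, model$baseline, beam)
  fcs_curve(lag_s, g)
}

# vectorised model kernel; used by fitting without tibble overhead
g_model <- function(lag_s, D, fraction, occupancy, baseline, beam) {
  tau_d <- diffusion_time(D, beam)
  s2 <- beam$s^2
  acc <- 0
  for (i in seq_along(D)) {
    x <- lag_s / tau_d[i]
    acc <- acc + fraction[i] / ((1 + x) * sqrt(1 + x / s2))
  }
  baseline + acc / occupancy
}

#' Effective observation volume and concentration
#'
#' `effective_volume()` reports the conventional 3D Gaussian effective
#' volume `V_eff = pi^(3/2) * omega0^2 * z0` in femtolitres;
#' `occupancy_to_concentration()` converts a fitted occupancy to a molar
#' concentration `C = N / (N_A * V_eff)`. Only concentration reporting
#' depends on this convention, never the diffusion coefficients.
#'
#' @param beam A [beam_geometry()].
#' @return Effective volume in fL.
#' @examples
#' effective_volume(beam_geometry(0.4, 2.0))  # 1.78 fL
#' @export
effective_volume <- function(beam) {
  stopifnot(inherits(beam, "beam_geometry"))
  pi^1.5 * beam$omega0_um^2 * beam$z0_um  # um^3 == fL
}

#' @rdname effective_volume
#' @param occupancy Mean molecule number in the observation volume.
#' @param v_eff_fL Effective volume in femtolitres.
#' @return `occupancy_to_concentration()`: molar concentration (mol/L).
#' @export
occupancy_to_concentration <- function(occupancy, v_eff_fL) {
  if (any(occupancy <= 0)) abort("`occupancy` must be positive.")
  if (any(v_eff_fL <= 0)) abort("`v_eff_fL` must be positive.")
  occupancy / (.NA_const * v_eff_fL * 1e-15)
}
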