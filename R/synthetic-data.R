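#' Simulate a noisy correlation curve
#'
#' Evaluates the analytic autocorrelation of a model and applies
#' multiplicative Gaussian noise with a constant coefficient of variation:
#' `g = G(tau) * (1 + noise_cv * zeta)` with `zeta` i.i.d. standard normal.
#' The `sigma` column is set to the true per-point standard deviation
#' `noise_cv * G(tau)` (omitted when `noise_cv = 0`). Deterministic under a
#' fixed seed.
#'
#' @param model An [fcs_model()].
#' @param beam A [beam_geometry()].
#' @param noise_cv Relative noise level, >= 0.
#' @param lag_s Lag grid, seconds; default 96 log-spaced points spanning
#'   1e-6 s to 1 s.
#' @param seed Integer RNG seed.
#' @return An [fcs_curve()].
#' @examples
#' beam <- beam_geometry(0.4, 2.0)
#' simulate_curve(fcs_model(84, occupancy = 5), beam, noise_cv = 0.02, seed = 7)
#' @export
simulate_curve <- function(model, beam, noise_cv = 0,
                           lag_s = lag_grid(), seed = 1) {
  stopifnot(inherits(model, "fcs_model"), inherits(beam, "beam_geometry"))
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  g0 <- autocorrelation(model, beam, lag_s)$g
  if (noise_cv == 0) return(fcs_curve(lag_s, g0))
  g <- withr::with_seed(seed, g0 * (1 + noise_cv * rnorm(length(g0))))
  fcs_curve(lag_s, g, sigma = noise_cv * g0)
}

#' Logarithmic lag grid
#'
#' @param from,to Grid limits, seconds.
#' @param n Number of points.
#' @return Strictly increasing lag times, seconds.
#' @export
lag_grid <- function(from = 1e-6, to = 1, n = 96) {
  if (from <= 0 || to <= from || n < 2) abort("Invalid lag grid.")
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate a photon-count trace from Brownian emitters
#'
#' Point emitters perform 3D Brownian motion (per-axis step variance
#' `2 D dt`) in a periodic box centred on the focus. The expected count of
#' an emitter per bin is `brightness * dt * W(r)`, with detection profile
#' `W = exp(-4 (x^2+y^2)/omega0^2 - 4 z^2/z0^2)` for two-photon excitation
#' (the square of the 3D Gaussian illumination; exponent 2 instead of 4 for
#' one-photon), and realised counts are Poisson. The per-bin loop runs in
#' compiled code using R's RNG, so the trace is deterministic under a seed.
#'
#' @param species A data frame with columns `D_um2_s`, `brightness_cps`
#'   (counts/s at focus centre) and `n` (number of emitters).
#' @param beam A [beam_geometry()].
#' @param dt_s Bin width, seconds; must satisfy `dt <= tau_D/20` of the
#'   fastest species.
#' @param duration_s Trace duration, seconds.
#' @param box_um Periodic box edge (scalar or length-3), micrometres; must
#'   be at least `10 * omega0`. Default `max(10*omega0, 4*z0)`.
#' @param init_positions Optional matrix (total emitters x 3) of initial
#'   positions, micrometres, focus at the origin; default uniform in the box.
#' @param seed Integer RNG seed.
#' @return An object of class `photon_trace`: list with `bin_width_s` and
#'   integer `counts`.
#' @examples
#' beam <- beam_geometry(0.4, 2.0)
#' sp <- tibble::tibble(D_um2_s = 300, brightness_cps = 1e5, n = 20)
#' tr <- simulate_photon_trace(sp, beam, dt_s = 2e-6, duration_s = 0.05, seed = 1)
#' @export
simulate_photon_trace <- function(species, beam, dt_s, duration_s,
                                  box_um = NULL, init_positions = NULL,
                                  seed = 1) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (!is.data.frame(species) ||
      !all(c("D_um2_s", "brightness_cps", "n") %in% names(species)))
    abort("`species` needs columns `D_um2_s`, `brightness_cps`, `n`.")
  if (any(species$D_um2_s < 0) || any(species$brightness_cps < 0) ||
      any(species$n < 0))
    abort("Species parameters must be non-negative.")
  if (dt_s <= 0 || duration_s <= dt_s)
    abort("Need `0 < dt_s < duration_s`.")
  mobile <- species$D_um2_s[species$D_um2_s > 0]
  if (length(mobile) > 0) {
    tau_min <- min(diffusion_time(mobile, beam))
    if (dt_s > tau_min / 20)
      abort(sprintf(
        "Bin width too coarse: dt must be <= tau_D/20 of the fastest species (%.3g s).",
        tau_min / 20))
  }
  box_um <- box_um %||% max(10 * beam$omega0_um, 4 * beam$z0_um)
  if (length(box_um) == 1L) box_um <- rep(box_um, 3L)
  if (any(box_um < 10 * beam$omega0_um))
    abort("Box must be at least 10 * omega0 in every dimension.")

  n_tot <- sum(species$n)
  D <- rep(species$D_um2_s, species$n)
  beta <- rep(species$brightness_cps, species$n)
  n_bins <- floor(duration_s / dt_s)
  profile_k <- if (beam$photon_mode == "two-photon") 4 else 2

  counts <- withr::with_seed(seed, {
    pos0 <- init_positions %||%
      cbind(stats::runif(n_tot, -box_um[1] / 2, box_um[1] / 2),
            stats::runif(n_tot, -box_um[2] / 2, box_um[2] / 2),
            stats::runif(n_tot, -box_um[3] / 2, box_um[3] / 2))
    if (n_tot == 0L) pos0 <- matrix(0, 0, 3)
    if (nrow(pos0) != n_tot || ncol(pos0) != 3L)
      abort("`init_positions` must be a (total emitters) x 3 matrix.")
    bd_photon_trace_cpp(pos0, D, beta, beam$omega0_um, beam$z0_um,
                        box_um, dt_s, n_bins, profile_k)
  })
  structure(list(bin_width_s = dt_s, counts = counts), class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> %d bins of %.3g s, mean %.3g counts/bin\n",
              length(x$counts), x$bin_width_s, mean(x$counts)))
  invisible(x)
}

#' Tidy a photon trace into a time/counts table
#'
#' @param x A `photon_trace`.
#' @param ... Unused.
#' @return A tibble with `time_s` (bin start) and `counts`.
#' @method tidy photon_trace
#' @export
tidy.photon_trace <- function(x, ...) {
  tibble(time_s = (seq_along(x$counts) - 1) * x$bin_width_s,
         counts = as.numeric(x$counts))
}

#' Multi-tau autocorrelation of a photon trace
#'
#' Computes the normalised fluctuation autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2` on a quasi-logarithmic lag grid:
#' the first cascade level evaluates lags `1..m` bins directly, then the
#' trace is coarsened by summing pairs of bins and lags `m/2+1..m` of each
#' subsequent level are evaluated at the doubled bin width, until fewer
#' than `2 m` coarse bins remain (so the grid spans up to about a quarter
#' of the trace duration). Symmetric normalisation (separate left/right
#' monitor means) suppresses the finite-length bias.
#'
#' @param trace A `photon_trace`.
#' @param m Channels per cascade level; even, default 16.
#' @return An [fcs_curve()] with columns `lag_s` and `g`.
#' @export
multitau_correlate <- function(trace, m = 16) {
  stopifnot(inherits(trace, "photon_trace"))
  if (m < 2 || m %% 2 != 0) abort("`m` must be an even integer >= 2.")
  x <- as.numeric(trace$counts)
  if (length(x) < 4 * m)
    abort("Trace must contain at least 4*m bins.")
  if (all(x == 0))
    abort("Normalisation undefined: the trace is identically zero.")

  lag_s <- numeric(0)
  g <- numeric(0)
  width <- trace$bin_width_s
  level <- 0L
  while (length(x) >= 2 * m) {
    ks <- if (level == 0L) seq_len(m) else seq(m / 2 + 1, m)
    n <- length(x)
    for (k in ks) {
      left <- x[seq_len(n - k)]
      right <- x[seq(k + 1, n)]
      ml <- mean(left)
      mr <- mean(right)
      gk <- if (ml == 0 || mr == 0) NA_real_
            else mean(left * right) / (ml * mr) - 1
      lag_s <- c(lag_s, k * width)
      g <- c(g, gk)
    }
    # coarsen: sum adjacent bins
    n2 <- floor(length(x) / 2)
    x <- x[seq(1, 2 * n2, 2)] + x[seq(2, 2 * n2, 2)]
    width <- width * 2
    level <- level + 1L
  }
  keep <- !is.na(g)
  fcs_curve(lag_s[keep], g[keep])
}

#' pH-titration scenario generator
#'
#' Emulates a pH-unfolding titration of a two-domain protein followed by
#' FCS: the dominant-species diffusion coefficient follows a
#' piecewise-linear template rising from 25 um^2/s at pH 2 to ~50 um^2/s at
#' pH 4.5, holding a plateau to pH 6, peaking at 84 um^2/s at pH 7 (compact
#' native state) and declining to ~31 um^2/s by pH 10; a minor slowly
#' diffusing species (aggregates, D = 15 um^2/s) carries 2-10% of the
#' amplitude, peaking at the pH extremes and dropping to 0.5% at pH 7. One
#' noisy correlation curve is generated per pH, together with the
#' generating truth for recovery scoring.
#'
#' @param ph_values Numeric pH values in `[2, 11]`.
#' @param beam A [beam_geometry()].
#' @param occupancy Occupancy of every generated curve.
#' @param noise_cv Relative noise of each curve (see [simulate_curve()]).
#' @param lag_s Lag grid passed to [simulate_curve()].
#' @param slow_D_um2_s Diffusion coefficient of the minor slow species.
#' @param seed Integer RNG seed; per-pH curves use `seed + index`.
#' @return A tibble of class `fcs_titration` with columns `ph`,
#'   `true_D1`, `true_slow_fraction`, `true_D2` and a `curve` list-column
#'   of [fcs_curve()] objects.
#' @examples
#' beam <- beam_geometry(0.4, 2.0)
#' titration_scenario(c(4, 7, 10), beam, seed = 1)
#' @export
titration_scenario <- function(ph_values, beam, occupancy = 5,
                               noise_cv = 0.02, lag_s = lag_grid(),
                               slow_D_um2_s = 15, seed = 1) {
  stopifnot(inherits(beam, "beam_geometry"))
  if (any(ph_values < 2) || any(ph_values > 11))
    abort("pH values must lie in [2, 11].")
  d1 <- titration_D_template(ph_values)
  fr_slow <- titration_slow_fraction_template(ph_values)
  curves <- purrr::map(seq_along(ph_values), function(i) {
    f <- fr_slow[i]
    model <- if (f > 0)
      fcs_model(c(d1[i], slow_D_um2_s), fraction = c(1 - f, f),
                occupancy = occupancy)
    else fcs_model(d1[i], occupancy = occupancy)
    simulate_curve(model, beam, noise_cv = noise_cv, lag_s = lag_s,
                   seed = seed + i)
  })
  out <- tibble(ph = ph_values, true_D1 = d1, true_slow_fraction = fr_slow,
                true_D2 = slow_D_um2_s, curve = curves)
  class(out) <- c("fcs_titration", class(out))
  out
}

# piecewise-linear D1(pH) template, um^2/s
titration_D_template <- function(ph) {
  knots_ph <- c(2, 4, 4.5, 6, 7, 10, 11)
  knots_D <- c(25, 44, 50, 50, 84, 31, 31)
  approx(knots_ph, knots_D, xout = ph, rule = 2)$y
}

# slow (aggregate) amplitude fraction template
titration_slow_fraction_template <- function(ph) {
  knots_ph <- c(2, 4, 6, 7, 8, 10, 11)
  knots_f <- c(0.10, 0.03, 0.02, 0, 0.02, 0.08, 0.10)
  approx(knots_ph, knots_f, xout = ph, rule = 2)$y
}

#' Toy molecular trajectories with known structure
#'
#' Generates small labelled trajectories for exercising the
#' trajectory-statistics operations: `"diffusive"` moves a rigid random
#' conformation by centre-of-mass Brownian motion with a known diffusion
#' coefficient; `"two-state"` alternates deterministically between two
#' reference conformations (every `1/fraction`-th frame is the minor state)
#' plus isotropic Gaussian jitter, planting recoverable clusters;
#' `"static"` repeats one conformation.
#'
#' @param n_frames Number of frames, >= 2.
#' @param n_atoms Number of atoms, >= 1.
#' @param mode `"diffusive"`, `"two-state"` or `"static"`.
#' @param params Named list of mode parameters: `D_um2_s` (diffusive;
#'   default 80), `dt_ps` (frame spacing, default 1), `jitter_nm`
#'   (two-state noise sd, default 0.01), `fraction` (two-state minor-state
#'   share, default 0.1), `separation_nm` (two-state displacement scale,
#'   default 1).
#' @param seed Integer RNG seed.
#' @return An [md_trajectory()] with all atoms labelled `"CA"`.
#' @examples
#' toy_trajectory(100, 5, "two-state", seed = 3)
#' @export
toy_trajectory <- function(n_frames, n_atoms,
                           mode = c("diffusive", "two-state", "static"),
                           params = list(), seed = 1) {
  mode <- match.arg(mode)
  if (n_frames < 2 || n_atoms < 1)
    abort("Need `n_frames >= 2` and `n_atoms >= 1`.")
  p <- list(D_um2_s = 80, dt_ps = 1, jitter_nm = 0.01, fraction = 0.1,
            separation_nm = 1)
  p[names(params)] <- params
  withr::with_seed(seed, {
    base <- matrix(rnorm(n_atoms * 3, sd = 0.5), n_atoms, 3)  # nm
    coords <- array(0, c(n_frames, n_atoms, 3))
    if (mode == "static") {
      for (f in seq_len(n_frames)) coords[f, , ] <- base
    } else if (mode == "diffusive") {
      D_nm2_ps <- p$D_um2_s * 1e-6  # 1 um^2/s = 1e-6 nm^2/ps
      step_sd <- sqrt(2 * D_nm2_ps * p$dt_ps)
      com <- apply(rbind(0, matrix(rnorm((n_frames - 1) * 3, sd = step_sd),
                                   n_frames - 1, 3)), 2, cumsum)
      for (f in seq_len(n_frames))
        coords[f, , ] <- sweep(base, 2, com[f, ], "+")
    } else {
      shift <- matrix(rnorm(n_atoms * 3), n_atoms, 3)
      shift <- shift / sqrt(mean(rowSums(shift^2))) * p$separation_nm
      ref2 <- base + shift
      period <- max(2L, round(1 / p$fraction))
      for (f in seq_len(n_frames)) {
        ref <- if (f %% period == 0L) ref2 else base
        coords[f, , ] <- ref + matrix(rnorm(n_atoms * 3, sd = p$jitter_nm),
                                      n_atoms, 3)
      }
    }
    md_trajectory((seq_len(n_frames) - 1) * p$dt_ps, coords,
                  rep("CA", n_atoms))
  })
}
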