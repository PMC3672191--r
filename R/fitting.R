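#' Fit an FCS model to a correlation curve
#'
#' Weighted nonlinear least squares of the one- or two-species 3D Gaussian
#' autocorrelation model to a measured curve, minimising
#' `sum(((g_obs - g_model)/sigma)^2)` (unit weights when no `sigma` column
#' is present). The optimiser is bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) restarted from several log-spaced diffusion-time
#' initialisations, because the two-species objective is multimodal.
#' Species are reported sorted by descending diffusion coefficient, so
#' `F1` always refers to the faster species.
#'
#' @param curve An [fcs_curve()] (or data frame with columns `lag_s`, `g`
#'   and optionally `sigma`). At least 8 points for one species, 12 for two.
#' @param n_species 1 or 2.
#' @param beam A calibrated [beam_geometry()].
#' @param init Optional starting [fcs_model()] (adds one start).
#' @param bounds Optional named list overriding defaults
#'   `list(D = c(0.1, 1000), occupancy = c(1e-6, 1e4))`.
#' @param fit_baseline If `TRUE`, the additive baseline is a free parameter;
#'   default fixed at 0.
#' @param n_starts Number of log-spaced multi-start initialisations.
#' @return An object of class `fcs_fit`: the fitted model, reduced
#'   chi-square, per-parameter standard deviations, convergence flag and the
#'   data. Use [tidy()] / [glance()] to extract tables.
#' @examples
#' beam <- beam_geometry(0.4, 2.0)
#' crv <- simulate_curve(fcs_model(84, occupancy = 5), beam,
#'                       noise_cv = 0.02, seed = 1)
#' fit <- fit_correlation(crv, 1, beam)
#' glance(fit)
#' @export
fit_correlation <- function(curve, n_species = 1, beam, init = NULL,
                            bounds = NULL, fit_baseline = FALSE,
                            n_starts = 3) {
  if (is.data.frame(curve) && "lag_s" %in% names(curve) &&
      !anyNA(curve$lag_s) && is.unsorted(curve$lag_s, strictly = TRUE)) {
    curve <- curve[order(curve$lag_s), , drop = FALSE]  # point order is irrelevant
  }
  curve <- as_fcs_curve(curve)
  stopifnot(inherits(beam, "beam_geometry"), n_species %in% c(1, 2))
  n <- nrow(curve)
  min_pts <- if (n_species == 1) 8L else 12L
  if (n < min_pts)
    abort(sprintf("Need at least %d points to fit %d species.", min_pts, n_species))
  if (sd(curve$g) == 0 || diff(range(curve$g)) < 1e-15)
    abort("Degenerate curve: `g` is constant; nothing to fit.")

  w <- if ("sigma" %in% names(curve)) 1 / curve$sigma else rep(1, n)
  weighted <- "sigma" %in% names(curve)
  b <- list(D = c(0.1, 1000), occupancy = c(1e-6, 1e4))
  b[names(bounds)] <- bounds

  # data-driven initial guesses: amplitude -> occupancy, half-decay -> tau_D
  g0 <- max(curve$g)
  base0 <- min(curve$g)
  amp0 <- max(g0 - if (fit_baseline) base0 else 0, 1e-6)
  occ0 <- min(max(1 / amp0, b$occupancy[1]), b$occupancy[2])
  half <- if (fit_baseline) base0 + amp0 / 2 else amp0 / 2
  i_half <- which(curve$g <= half)[1]
  tau_half <- if (is.na(i_half)) median(curve$lag_s) else curve$lag_s[i_half]
  D_half <- diffusion_from_time(tau_half, beam)
  clampD <- function(D) pmin(pmax(D, b$D[1] * 1.01), b$D[2] * 0.99)

  starts <- list()
  if (n_species == 1) {
    for (f in 10^seq(-0.7, 0.7, length.out = n_starts))
      starts[[length(starts) + 1L]] <- list(occ = occ0, D = clampD(D_half * f))
  } else {
    ratios <- list(c(4, 1 / 4), c(10, 1), c(1, 1 / 10))
    f1s <- c(0.7, 0.9, 0.5)
    for (i in seq_len(max(n_starts, 3L))) {
      r <- ratios[[(i - 1L) %% 3L + 1L]]
      starts[[length(starts) + 1L]] <-
        list(occ = occ0, D = clampD(D_half * r), f1 = f1s[(i - 1L) %% 3L + 1L])
    }
  }
  if (n_species == 2) {
    # start from the nested one-species solution at the f1 = 1 boundary, so
    # the two-species minimum can never be worse than the one-species one
    f1 <- tryCatch(fit_correlation(curve, 1, beam, bounds = bounds,
                                   fit_baseline = fit_baseline,
                                   n_starts = n_starts),
                   error = function(e) NULL)
    if (!is.null(f1)) {
      D1 <- f1$model$species$D_um2_s
      starts[[length(starts) + 1L]] <-
        list(occ = f1$model$occupancy, D = clampD(c(D1, D1 / 8)), f1 = 1)
    }
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "fcs_model"))
    if (nrow(init$species) != n_species)
      abort("`init` must have `n_species` species.")
    starts[[length(starts) + 1L]] <-
      list(occ = init$occupancy, D = clampD(init$species$D_um2_s),
           f1 = init$species$fraction[1])
  }

  # parameter packing: (occupancy, D1[, D2, f1][, baseline])
  unpack <- function(par) {
    occ <- par[1]
    if (n_species == 1) {
      D <- par[2]; fr <- 1
      base <- if (fit_baseline) par[3] else 0
    } else {
      D <- par[2:3]; fr <- c(par[4], 1 - par[4])
      base <- if (fit_baseline) par[5] else 0
    }
    list(occ = occ, D = D, fr = fr, base = base)
  }
  resid_fn <- function(par) {
    u <- unpack(par)
    w * (curve$g - g_model(curve$lag_s, u$D, u$fr, u$occ, u$base, beam))
  }
  lower <- c(b$occupancy[1], rep(b$D[1], n_species),
             if (n_species == 2) 0, if (fit_baseline) -1)
  upper <- c(b$occupancy[2], rep(b$D[2], n_species),
             if (n_species == 2) 1, if (fit_baseline) 1)

  best <- NULL
  for (st in starts) {
    par0 <- c(st$occ, st$D,
              if (n_species == 2) st$f1 %||% 0.7,
              if (fit_baseline) 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    abort("All optimiser starts failed.")

  u <- unpack(best$par)
  n_free <- length(best$par)
  chi2 <- best$deviance
  chi2_red <- chi2 / (n - n_free)
  converged <- best$info %in% 1:4

  # standard errors from the weighted-Jacobian normal matrix, scaled by
  # the reduced chi-square (standard practice when sigma is only relative)
  J <- jacobian_fd(resid_fn, best$par)
  param_sd <- rep(NA_real_, n_free)
  cv <- tryCatch(chol2inv(chol(crossprod(J))) * chi2_red, error = function(e) NULL)
  if (!is.null(cv)) param_sd <- sqrt(pmax(diag(cv), 0))

  nm <- param_names(n_species, fit_baseline)
  # sort species by descending D, carrying fractions and SDs along
  if (n_species == 2 && u$D[1] < u$D[2]) {
    u$D <- u$D[2:1]
    u$fr <- u$fr[2:1]
    param_sd[2:3] <- param_sd[3:2]
    # fraction SD is shared: sd(1 - f1) = sd(f1)
  }
  model <- fcs_model(u$D, fraction = u$fr, occupancy = u$occ, baseline = u$base)

  structure(
    list(model = model, beam = beam,
         chi2 = chi2, chi2_red = chi2_red,
         param_sd = setNames(param_sd, nm),
         n_points = n, n_free = n_free,
         weighted = weighted, converged = converged,
         curve = curve,
         fitted = g_model(curve$lag_s, u$D, u$fr, u$occ, u$base, beam),
         info = best$info, message = best$message),
    class = "fcs_fit"
  )
}

param_names <- function(n_species, fit_baseline) {
  c("occupancy",
    if (n_species == 1) "D1" else c("D1", "D2", "F1"),
    if (fit_baseline) "baseline")
}

# forward-difference jacobian of a residual function
jacobian_fd <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1e-8)
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> %d species, %d points, chi2_red = %.4g%s\n",
              nrow(x$model$species), x$n_points, x$chi2_red,
              if (x$converged) "" else " (NOT converged)"))
  print(tidy(x))
  invisible(x)
}

#' Tidy an FCS fit into a parameter table
#'
#' @param x An `fcs_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy fcs_fit
#' @export
tidy.fcs_fit <- function(x, ...) {
  sp <- x$model$species
  est <- c(x$model$occupancy, sp$D_um2_s,
           if (nrow(sp) == 2) sp$fraction[1],
           if ("baseline" %in% names(x$param_sd)) x$model$baseline)
  tibble(term = names(x$param_sd), estimate = est,
         std.error = unname(x$param_sd))
}

#' One-row summary of an FCS fit
#'
#' @param x An `fcs_fit`.
#' @param ... Unused.
#' @return A tibble with `n_species`, `chi2_red`, `n_points`, `n_free`,
#'   `weighted`, `converged`.
#' @method glance fcs_fit
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble(n_species = nrow(x$model$species), chi2_red = x$chi2_red,
         n_points = x$n_points, n_free = x$n_free,
         weighted = x$weighted, converged = x$converged)
}

#' Per-point fitted values and residuals
#'
#' @param x An `fcs_fit`.
#' @param ... Unused.
#' @return The fitted curve with `.fitted`, `.resid` and (for weighted
#'   fits) `.std.resid` columns.
#' @method augment fcs_fit
#' @export
augment.fcs_fit <- function(x, ...) {
  out <- as_tibble(x$curve)
  out$.fitted <- x$fitted
  out$.resid <- out$g - out$.fitted
  if (x$weighted) out$.std.resid <- out$.resid / out$sigma
  out
}

#' Choose between nested one- and two-species fits
#'
#' Parsimony-first model selection mirroring visual practice: the
#' two-species model is preferred only when it both improves the reduced
#' chi-square by more than a relative threshold and assigns the minor
#' species more than a floor fraction; otherwise the one-species model is
#' kept.
#'
#' @param fit1 One-species `fcs_fit`.
#' @param fit2 Two-species `fcs_fit` on the same curve.
#' @param chi2_improvement Minimum relative reduction of `chi2_red`
#'   (default 0.10).
#' @param fraction_floor Minimum minor-species fraction (default 0.005).
#' @return A one-row tibble: `selected` ("one-species"/"two-species"),
#'   `chi2_red_1`, `chi2_red_2`, `improvement`, `minor_fraction`.
#' @export
compare_models <- function(fit1, fit2, chi2_improvement = 0.10,
                           fraction_floor = 0.005) {
  stopifnot(inherits(fit1, "fcs_fit"), inherits(fit2, "fcs_fit"))
  if (nrow(fit1$model$species) != 1L || nrow(fit2$model$species) != 2L)
    abort("`fit1` must be the one-species fit and `fit2` the two-species fit.")
  if (fit1$n_points != fit2$n_points ||
      !isTRUE(all.equal(fit1$curve$g, fit2$curve$g)) ||
      !isTRUE(all.equal(fit1$curve$lag_s, fit2$curve$lag_s)))
    abort("The two fits are not on the same curve.")
  improvement <- (fit1$chi2_red - fit2$chi2_red) / fit1$chi2_red
  minor <- min(fit2$model$species$fraction)
  selected <- if (improvement > chi2_improvement && minor > fraction_floor)
    "two-species" else "one-species"
  tibble(selected = selected,
         chi2_red_1 = fit1$chi2_red, chi2_red_2 = fit2$chi2_red,
         improvement = improvement, minor_fraction = minor)
}

#' Residual-resampling bootstrap confidence intervals
#'
#' Refits the model to `n_boot` pseudo-curves built by adding resampled
#' (with replacement) fit residuals to the fitted curve, and reports the
#' 16th/84th percentile interval of each parameter (approximately +/- 1 sd
#' for a Gaussian sampling distribution). Deterministic under a fixed seed.
#'
#' @param curve The curve that was fitted.
#' @param fit The converged `fcs_fit` to perturb.
#' @param n_boot Number of bootstrap replicates, >= 100.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`
#'   (16/84 percentiles).
#' @export
bootstrap_uncertainty <- function(curve, fit, n_boot = 500, seed = 1) {
  curve <- as_fcs_curve(curve)
  stopifnot(inherits(fit, "fcs_fit"))
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  if (!fit$converged) abort("Bootstrap requires a converged fit.")
  n_species <- nrow(fit$model$species)
  resid <- curve$g - fit$fitted
  ests <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(i) {
      gb <- fit$fitted + sample(resid, length(resid), replace = TRUE)
      cb <- curve
      cb$g <- gb
      fb <- tryCatch(
        fit_correlation(cb, n_species, fit$beam, init = fit$model,
                        n_starts = 1),
        error = function(e) NULL)
      if (is.null(fb)) return(NULL)
      setNames(tidy(fb)$estimate, tidy(fb)$term)
    })
  })
  ests <- ests[!vapply(ests, is.null, logical(1))]
  if (length(ests) < n_boot * 0.5)
    abort("Too many bootstrap refits failed.")
  mat <- do.call(rbind, ests)
  td <- tidy(fit)
  tibble(
    term = td$term,
    estimate = td$estimate,
    lower = apply(mat[, td$term, drop = FALSE], 2, quantile, probs = 0.16),
    upper = apply(mat[, td$term, drop = FALSE], 2, quantile, probs = 0.84)
  )
}
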