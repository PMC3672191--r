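#' Run configuration for a titration analysis
#'
#' Gathers physical conditions, beam geometry (or a calibration reference),
#' model-selection thresholds and seeds into one validated list used by
#' [run_titration()].
#'
#' @param temperature_K,viscosity_cP Solvent conditions.
#' @param omega0_um,z0_um,photon_mode Beam geometry (omega0 may be `NULL`
#'   when a calibration reference curve will supply it).
#' @param D_ref_um2_s Reference diffusion coefficient for calibration,
#'   um^2/s (default 300, rhodamine 110).
#' @param chi2_improvement,fraction_floor Model-selection thresholds, see
#'   [compare_models()].
#' @param volume_A3 Imposed prolate volume; `NULL` derives it from the
#'   largest fitted D across the titration (the compact reference state).
#' @param seed Integer seed recorded in the provenance and used for any
#'   stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(temperature_K = 298.15, viscosity_cP = 0.89,
                       omega0_um = NULL, z0_um = NULL,
                       photon_mode = c("two-photon", "one-photon"),
                       D_ref_um2_s = 300,
                       chi2_improvement = 0.10, fraction_floor = 0.005,
                       volume_A3 = NULL, seed = 1L) {
  photon_mode <- match.arg(photon_mode)
  cfg <- list(temperature_K = temperature_K, viscosity_cP = viscosity_cP,
              omega0_um = omega0_um, z0_um = z0_um,
              photon_mode = photon_mode, D_ref_um2_s = D_ref_um2_s,
              chi2_improvement = chi2_improvement,
              fraction_floor = fraction_floor,
              volume_A3 = volume_A3, seed = as.integer(seed))
  physical_conditions(temperature_K, viscosity_cP)  # validates
  structure(cfg, class = "run_config")
}

config_beam <- function(config) {
  if (is.null(config$omega0_um))
    abort("Config has no beam geometry; supply `omega0_um` or calibrate first.")
  beam_geometry(config$omega0_um,
                config$z0_um %||% (5 * config$omega0_um),
                config$photon_mode)
}

#' Fit, select and shape-convert a set of per-pH correlation curves
#'
#' For every pH the curve is fitted with one and with two species, the
#' parsimony rule of [compare_models()] picks the model, the selected fast
#' diffusion coefficient is converted to a Stokes-Einstein radius, and —
#' when it falls below the equal-volume spherical bound — a prolate
#' ellipsoid of the configured volume is solved for. Per-pH failures are
#' recorded in the report and do not abort the run. With fixed seeds the
#' report is deterministic.
#'
#' @param curves A tibble with columns `ph` and `curve` (list of
#'   [fcs_curve()]), e.g. from [titration_scenario()]; extra columns are
#'   ignored.
#' @param config A [run_config()] with beam geometry set.
#' @return A tibble of class `titration_report` with one row per pH:
#'   fitted `D1`, `F1`, `D2`, both reduced chi-squares, the `selected`
#'   model, `R_sph_A`, prolate `a_A`, `b_A`, `p`, the slow fraction and an
#'   `error` column (`NA` on success). Provenance (config, seeds) is kept
#'   in the `"provenance"` attribute.
#' @export
run_titration <- function(curves, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.data.frame(curves) || !all(c("ph", "curve") %in% names(curves))) {
    if (is.data.frame(curves) && nrow(curves) == 0)
      curves <- tibble(ph = numeric(0), curve = list())
    else
      abort("`curves` needs columns `ph` and `curve`.")
  }
  beam <- if (nrow(curves) > 0) config_beam(config) else NULL
  cond <- physical_conditions(config$temperature_K, config$viscosity_cP)

  rows <- purrr::map(seq_len(nrow(curves)), function(i) {
    out <- tibble(ph = curves$ph[i], D1 = NA_real_, F1 = NA_real_,
                  D2 = NA_real_, chi2_red_1 = NA_real_, chi2_red_2 = NA_real_,
                  selected = NA_character_, slow_fraction = NA_real_,
                  R_sph_A = NA_real_, a_A = NA_real_, b_A = NA_real_,
                  p = NA_real_, D_model_um2_s = NA_real_,
                  error = NA_character_)
    tryCatch({
      crv <- as_fcs_curve(curves$curve[[i]])
      fit1 <- fit_correlation(crv, 1, beam)
      fit2 <- fit_correlation(crv, 2, beam)
      cmp <- compare_models(fit1, fit2,
                            chi2_improvement = config$chi2_improvement,
                            fraction_floor = config$fraction_floor)
      sel <- if (cmp$selected == "two-species") fit2 else fit1
      sp <- sel$model$species
      out$D1 <- sp$D_um2_s[1]
      out$F1 <- sp$fraction[1]
      out$D2 <- if (nrow(sp) == 2) sp$D_um2_s[2] else NA_real_
      out$chi2_red_1 <- fit1$chi2_red
      out$chi2_red_2 <- fit2$chi2_red
      out$selected <- cmp$selected
      out$slow_fraction <- if (nrow(sp) == 2) sp$fraction[2] else 0
      out$R_sph_A <- stokes_einstein_radius(out$D1, cond)
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  report <- dplyr::bind_rows(rows)

  # prolate inversion against the configured (or native-state) volume
  if (nrow(report) > 0 && any(!is.na(report$D1))) {
    volume <- config$volume_A3 %||%
      sphere_volume(stokes_einstein_radius(max(report$D1, na.rm = TRUE), cond))
    for (i in seq_len(nrow(report))) {
      D1 <- report$D1[i]
      if (is.na(D1)) next
      r_eq <- (3 * volume / (4 * pi))^(1 / 3)
      if (D1 <= stokes_einstein_D(r_eq, cond)) {
        sh <- invert_prolate(D1, volume, cond)
        report$a_A[i] <- sh$a_A
        report$b_A[i] <- sh$b_A
        report$p[i] <- sh$p
        report$D_model_um2_s[i] <- prolate_diffusion(sh, cond)
      }
    }
    attr(report, "volume_A3") <- volume
  }
  if (nrow(report) == 0)
    warn("Empty curve set: returning an empty report.")
  attr(report, "provenance") <- list(
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fcshydro")),
    n_curves = nrow(report)
  )
  class(report) <- c("titration_report", class(report))
  report
}

#' Write and re-read a titration report
#'
#' `write_titration_report()` writes the table as CSV and the provenance
#' (full config, seeds, package version, imposed volume) as JSON with
#' sorted keys, so identical runs produce byte-identical files.
#' `read_titration_report()` restores both losslessly.
#'
#' @param report A `titration_report`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; writes `<stem>.csv` and `<stem>_provenance.json`.
#' @return `write_titration_report()`: the two file paths, invisibly.
#' @export
write_titration_report <- function(report, dir, stem = "titration_report") {
  stopifnot(inherits(report, "titration_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, "_provenance.json"))
  write.table(as.data.frame(report), csv, sep = ",", row.names = FALSE,
              quote = TRUE, qmethod = "double")
  prov <- attr(report, "provenance")
  prov$volume_A3 <- attr(report, "volume_A3")
  jsonlite::write_json(prov, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(csv = csv, provenance = js))
}

#' @rdname write_titration_report
#' @return `read_titration_report()`: the restored `titration_report`.
#' @export
read_titration_report <- function(dir, stem = "titration_report") {
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, "_provenance.json"))
  if (!file.exists(csv)) abort(paste("No such report:", csv))
  tb <- as_tibble(read.table(csv, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE))
  tb$selected <- as.character(tb$selected)
  tb$error <- as.character(tb$error)
  if (file.exists(js)) {
    prov <- jsonlite::read_json(js, simplifyVector = TRUE)
    attr(tb, "volume_A3") <- prov$volume_A3
    prov$volume_A3 <- NULL
    attr(tb, "provenance") <- prov
  }
  class(tb) <- c("titration_report", class(tb))
  tb
}

#' Read and write correlation curves as delimited text
#'
#' Curves are stored as whitespace- or comma-delimited text with a header
#' row naming `lag_s`, `g` and optionally `sigma`, decimal point `.`.
#'
#' @param path File path.
#' @return `read_curve()`: an [fcs_curve()].
#' @export
read_curve <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "", dec = ".")
  if (!all(c("lag_s", "g") %in% names(tb))) {
    tb <- read.table(path, header = TRUE, sep = ",", dec = ".")
  }
  as_fcs_curve(tb)
}

#' @rdname read_curve
#' @param curve An [fcs_curve()].
#' @export
write_curve <- function(curve, path) {
  curve <- as_fcs_curve(curve)
  write.table(as.data.frame(curve), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read and write photon traces as delimited text
#'
#' Traces are stored as a two-column table (`bin`, `counts`) with the bin
#' width on a `# bin_width_s` comment line.
#'
#' @param path File path.
#' @return `read_photon_trace()`: a `photon_trace`.
#' @export
read_photon_trace <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# bin_width_s", first))
    abort("Missing `# bin_width_s` header line.")
  bw <- as.numeric(sub("^# bin_width_s\\s*=?\\s*", "", first))
  tb <- read.table(path, header = TRUE, skip = 1L)
  structure(list(bin_width_s = bw, counts = as.integer(tb$counts)),
            class = "photon_trace")
}

#' @rdname read_photon_trace
#' @param trace A `photon_trace`.
#' @export
write_photon_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_s = %.17g", trace$bin_width_s), con)
  write.table(data.frame(bin = seq_along(trace$counts),
                         counts = trace$counts),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write run configurations as JSON
#'
#' @param path File path.
#' @return `read_config()`: a [run_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
}

#' @rdname read_config
#' @param config A [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read and write trajectories in XYZ format
#'
#' Plain-text multi-frame XYZ: per frame an atom-count line, a comment
#' line carrying the timestamp (`t= <ps>`), then one `label x y z` line
#' per atom. Coordinates are nanometres by default; pass `unit = "angstrom"`
#' to convert on the way in or out.
#'
#' @param path File path.
#' @param unit `"nm"` (default) or `"angstrom"`.
#' @return `read_xyz()`: an [md_trajectory()].
#' @export
read_xyz <- function(path, unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  labels <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- as.integer(trimws(lines[i]))
    if (is.na(na)) abort(sprintf("Bad atom-count line at line %d.", i))
    cmt <- lines[i + 1L]
    tm <- regmatches(cmt, regexpr("t\\s*=\\s*[-0-9.eE+]+", cmt))
    times <- c(times, if (length(tm)) as.numeric(sub("t\\s*=\\s*", "", tm))
                      else length(frames))
    block <- lines[seq(i + 2L, i + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    lab <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(labels)) labels <- lab
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  co <- array(0, c(length(frames), length(labels), 3))
  for (f in seq_along(frames)) co[f, , ] <- frames[[f]]
  if (unit == "angstrom") co <- co / 10
  md_trajectory(times, co, labels)
}

#' @rdname read_xyz
#' @param traj An [md_trajectory()].
#' @export
write_xyz <- function(traj, path, unit = c("nm", "angstrom")) {
  stopifnot(inherits(traj, "md_trajectory"))
  unit <- match.arg(unit)
  fac <- if (unit == "angstrom") 10 else 1
  na <- dim(traj$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(na), con)
    writeLines(sprintf("t= %.10g", traj$times_ps[f]), con)
    m <- frame_coords(traj, f, seq_len(na)) * fac
    writeLines(sprintf("%s %.10g %.10g %.10g", traj$atom_labels,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
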