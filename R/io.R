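# Spectrum file format, dataset manifests, run configuration, and the
# end-to-end pipeline (simulate -> fit -> dispersion -> report).

MANDATORY_HEADER_KEYS <- c("q_nm_inv", "temperature_C", "rf_fwhm_meV", "rf_eta")

#' Write an IXS spectrum to a plain-text file
#'
#' Header block of `# key: value` lines (`q_nm_inv`, `temperature_C`,
#' `rf_fwhm_meV`, `rf_eta`, `units`) followed by a CSV block with columns
#' `energy_meV`, `intensity_counts`, `error_counts`. Values are written with
#' 17 significant digits so `read_spectrum(write_spectrum(x))` round-trips
#' bit-exactly.
#'
#' @param spectrum An [ixs_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  check_spectrum(spectrum)
  rf <- spectrum_rf(spectrum)
  num <- function(x) sprintf("%.17g", x)
  header <- c(
    paste0("# q_nm_inv: ", num(spectrum_q(spectrum))),
    paste0("# temperature_C: ", num(attr(spectrum, "temperature_C"))),
    paste0("# rf_fwhm_meV: ", num(rf$fwhm)),
    paste0("# rf_eta: ", num(rf$eta)),
    "# units: energy_meV,intensity_counts,error_counts")
  body <- paste(num(spectrum$energy), num(spectrum$intensity),
                num(spectrum$error), sep = ",")
  writeLines(c(header, "energy_meV,intensity_counts,error_counts", body), path)
  invisible(path)
}

#' Read an IXS spectrum file
#'
#' Parses the format written by [write_spectrum()]. Malformed headers,
#' missing mandatory keys, non-increasing energy grids, NaN values or
#' non-positive errors raise a parse error naming the offence.
#'
#' @param path File path.
#' @return An [ixs_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  header_lines <- lines[is_header]
  kv <- regmatches(header_lines,
                   regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", header_lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad) > 0L) {
    stop("malformed header line: '", header_lines[bad[1L]], "'", call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  missing_keys <- setdiff(MANDATORY_HEADER_KEYS, keys)
  if (length(missing_keys) > 0L) {
    stop("missing mandatory header key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  header <- stats::setNames(as.list(vals), keys)

  body <- lines[!is_header]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows found.", call. = FALSE)
  if (!identical(trimws(body[1L]), "energy_meV,intensity_counts,error_counts")) {
    stop("unexpected column header line: '", body[1L], "'", call. = FALSE)
  }
  fields <- strsplit(body[-1L], ",", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf != 3L)) {
    stop("expected 3 columns on data line ", which(nf != 3L)[1L] + 1L,
         call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
  if (anyNA(mat)) {
    stop("non-numeric or NaN value on data line ",
         which(rowSums(is.na(mat)) > 0)[1L] + 1L, call. = FALSE)
  }
  if (any(diff(mat[, 1L]) <= 0)) {
    stop("energy grid not strictly increasing at data line ",
         which(diff(mat[, 1L]) <= 0)[1L] + 2L, call. = FALSE)
  }
  if (any(mat[, 3L] <= 0)) {
    stop("non-positive error value on data line ",
         which(mat[, 3L] <= 0)[1L] + 1L, call. = FALSE)
  }
  ixs_spectrum(mat[, 1L], mat[, 2L], mat[, 3L],
               q = as.numeric(header$q_nm_inv),
               temperature_C = as.numeric(header$temperature_C),
               rf = resolution_function(as.numeric(header$rf_fwhm_meV),
                                        as.numeric(header$rf_eta)))
}

#' Write a simulated dataset to disk
#'
#' One spectrum file per Q plus a JSON manifest listing the files and the
#' generator truth.
#'
#' @param dataset An `ixs_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ixs_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(dataset$spectra, function(sp) {
    fname <- sprintf("spectrum_q%07.3f.txt", spectrum_q(sp))
    write_spectrum(sp, file.path(dir, fname))
    fname
  }, character(1))
  manifest <- list(
    scenario = dataset$scenario$name,
    seed = dataset$seed,
    files = files,
    truth = dataset$manifest)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest and its spectra
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_dataset()].
#' @return A list: `spectra` (list of [ixs_spectrum()]), `truth` (tibble or
#'   `NULL`), `scenario`, `seed`.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(manifest$files)) {
    stop("manifest has no `files` entry.", call. = FALSE)
  }
  dir <- dirname(manifest_path)
  spectra <- lapply(file.path(dir, manifest$files), read_spectrum)
  truth <- if (!is.null(manifest$truth)) tibble::as_tibble(manifest$truth) else NULL
  list(spectra = spectra, truth = truth,
       scenario = manifest$scenario, seed = manifest$seed)
}

default_run_config <- function() {
  list(
    manifest = NULL,
    outdir = NULL,
    seed = 1L,
    rel_improvement = 0.15,
    vanish_k = 2,
    n_restarts = 5L,
    q_linear_max_long = 8,
    q_linear_max_trans = 10,
    q_min_window = c(10, 20))
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with keys `manifest`, `outdir`, `seed`, `rel_improvement`,
#' `vanish_k`, `n_restarts`, `q_linear_max_long`, `q_linear_max_trans`,
#' `q_min_window`. Unknown keys are rejected; thresholds must be positive.
#'
#' @param path YAML file path.
#' @return A validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  for (key in c("rel_improvement", "vanish_k", "q_linear_max_long",
                "q_linear_max_trans")) {
    if (!is.numeric(out[[key]]) || length(out[[key]]) != 1L || out[[key]] <= 0) {
      stop("config key `", key, "` must be a single positive number.",
           call. = FALSE)
    }
  }
  if (length(out$q_min_window) != 2L || out$q_min_window[1] >= out$q_min_window[2]) {
    stop("config key `q_min_window` must be c(lo, hi) with lo < hi.",
         call. = FALSE)
  }
  out
}

#' Analyze a set of spectra end to end (in memory)
#'
#' Per-Q fitting with automatic mode-count selection, branch assembly,
#' damping ratios, and derived quantities. The core of [run_pipeline()]
#' without any file io.
#'
#' @param spectra List of [ixs_spectrum()] objects.
#' @param seed Integer master seed.
#' @param config Optional (partial) config list; see [read_run_config()].
#' @return A list: `fits` (per-Q selection/fit table), `branches`
#'   (with damping ratios), `derived` (one-row tibble).
#' @export
analyze_dataset <- function(spectra, seed = 1L, config = list()) {
  cfg <- validate_run_config(config[setdiff(names(config), c("manifest", "outdir", "seed"))])
  fits <- fit_dataset(spectra, seed = seed,
                      rel_improvement = cfg$rel_improvement,
                      vanish_k = cfg$vanish_k, n_restarts = cfg$n_restarts)
  branches <- damping_ratio(assemble_branches(fits))
  derived <- derived_quantities(
    branches, q_linear_max_long = cfg$q_linear_max_long,
    q_linear_max_trans = cfg$q_linear_max_trans,
    q_min_window = cfg$q_min_window)
  list(fits = fits, branches = branches, derived = derived)
}

#' Run the full pipeline from a configuration
#'
#' Reads the dataset named by the config's `manifest`, fits every spectrum,
#' assembles dispersion branches and derived quantities, and writes the
#' report bundle to `outdir`: `mode_selection.csv`, `dispersion.csv`,
#' `derived.json`, `summary.txt` and `log.txt` (per-Q convergence, restart
#' seeds and chi-squared values). Idempotent for identical inputs and seed;
#' no timestamps are written. Per-Q failures are logged and skipped; an
#' empty surviving set is fatal.
#'
#' @param config A config list or path to a YAML config file; must provide
#'   `manifest` and `outdir`.
#' @return Invisibly, the [analyze_dataset()] result list plus `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  if (is.null(cfg$manifest) || is.null(cfg$outdir)) {
    stop("config must provide `manifest` and `outdir`.", call. = FALSE)
  }
  ds <- read_dataset(cfg$manifest)
  res <- analyze_dataset(ds$spectra, seed = cfg$seed, config = cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  sel <- res$fits
  sel_tbl <- tibble::tibble(
    q = sel$q, chosen_n_modes = sel$chosen_n_modes, chi2_one = sel$chi2_one,
    chi2_two = sel$chi2_two, vanished = sel$vanished, two_hump = sel$two_hump,
    ok = sel$ok, note = sel$note)
  utils::write.csv(sel_tbl, file.path(cfg$outdir, "mode_selection.csv"),
                   row.names = FALSE)

  disp <- res$branches
  disp_out <- tibble::tibble(
    Q_nm_inv = disp$q, branch = disp$branch, omega_meV = disp$omega,
    omega_err = disp$omega_err, gamma_meV = disp$gamma,
    gamma_err = disp$gamma_err, R = disp$R, present = disp$present)
  utils::write.csv(disp_out, file.path(cfg$outdir, "dispersion.csv"),
                   row.names = FALSE)

  jsonlite::write_json(as.list(res$derived),
                       file.path(cfg$outdir, "derived.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  log_lines <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("rel_improvement: %g  vanish_k: %g  n_restarts: %d",
            cfg$rel_improvement, cfg$vanish_k, cfg$n_restarts),
    vapply(seq_len(nrow(sel)), function(i) {
      if (!sel$ok[i]) {
        sprintf("Q = %7.3f  FAILED: %s", sel$q[i], sel$note[i])
      } else {
        fit <- sel$fit[[i]]
        sprintf("Q = %7.3f  modes = %d  chi2_1 = %.4f  chi2_2 = %.4f  converged = %s",
                sel$q[i], sel$chosen_n_modes[i], sel$chi2_one[i],
                sel$chi2_two[i], fit$converged)
      }
    }, character(1)))
  writeLines(log_lines, file.path(cfg$outdir, "log.txt"))

  d <- res$derived
  summary_lines <- c(
    "IXS phonon pipeline summary",
    sprintf("spectra analyzed: %d of %d", sum(sel$ok), nrow(sel)),
    sprintf("longitudinal sound speed: %.0f +/- %.0f m/s", d$v_long, d$v_long_err),
    if (is.finite(d$v_trans))
      sprintf("transverse sound speed: %.0f +/- %.0f m/s", d$v_trans, d$v_trans_err),
    if (is.finite(d$q_min))
      sprintf("dispersion minimum Q_min: %.2f +/- %.2f nm^-1", d$q_min, d$q_min_err),
    if (is.finite(d$area_A2))
      sprintf("area per lipid: %.1f A^2 (chain spacing %.2f A)", d$area_A2, d$d_A),
    if (isTRUE(d$gap_found))
      sprintf("transverse phonon gap: Q_gap = %.2f nm^-1 (%.2f-%.2f), d_gap = %.2f nm (%.2f-%.2f)",
              d$q_gap, d$q_gap_lo, d$q_gap_hi, d$d_gap_nm, d$d_gap_lo_nm,
              d$d_gap_hi_nm)
    else "transverse phonon gap: none detected")
  writeLines(summary_lines, file.path(cfg$outdir, "summary.txt"))

  invisible(c(res, list(outdir = cfg$outdir)))
}
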