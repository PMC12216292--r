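# readers/writers for the plain-text artifact formats, acquisition
# bookkeeping, and the built-in material table

#' Acquisition plan and its duration
#'
#' Bookkeeping for the two acquisition modes: spectroscopy (n interferogram
#' points x integration time x averages; 1200 x 35 ms x 20 = 14 min) and
#' imaging (pixels x per-pixel time; 150 x 100 px at 3.3 ms ~ 50 s).
#'
#' @param n_points Interferogram points per scan (spectroscopy mode).
#' @param integration_time_t_p Per-point/per-pixel integration time in s.
#' @param n_averages Number of averaged scans (spectroscopy mode).
#' @param pixels_x,pixels_y Image size in pixels (imaging mode).
#' @return Object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(n_points = NULL, integration_time_t_p = NULL,
                             n_averages = NULL, pixels_x = NULL,
                             pixels_y = NULL) {
  vals <- list(n_points = n_points, integration_time_t_p = integration_time_t_p,
               n_averages = n_averages, pixels_x = pixels_x,
               pixels_y = pixels_y)
  for (nm in names(vals))
    if (!is.null(vals[[nm]]) && vals[[nm]] <= 0)
      stop(nm, " must be positive")
  structure(vals, class = "acquisition_plan")
}

#' @rdname acquisition_plan
#' @param plan An `acquisition_plan`.
#' @return `plan_duration`: total duration in seconds, with attribute
#'   `minutes`.
#' @examples
#' plan_duration(acquisition_plan(n_points = 1200,
#'   integration_time_t_p = 0.035, n_averages = 20))  # 840 s = 14 min
#' @export
plan_duration <- function(plan) {
  stopifnot(inherits(plan, "acquisition_plan"))
  if (is.null(plan$integration_time_t_p))
    stop("integration_time_t_p is required")
  if (!is.null(plan$n_points) && !is.null(plan$n_averages)) {
    secs <- plan$n_points * plan$integration_time_t_p * plan$n_averages
  } else if (!is.null(plan$pixels_x) && !is.null(plan$pixels_y)) {
    secs <- plan$pixels_x * plan$pixels_y * plan$integration_time_t_p
  } else {
    stop("set either (n_points, n_averages) or (pixels_x, pixels_y)")
  }
  structure(secs, minutes = secs / 60)
}

#' Illumination irradiance
#'
#' \eqn{E} = power / area, in mW/cm^2. The reported switching illumination,
#' 30 mW over 0.5 x 0.5 mm^2, gives 12000 mW/cm^2.
#'
#' @param power_mW Optical power in mW, >= 0.
#' @param area_mm2 Illuminated area in mm^2, > 0.
#' @return Irradiance in mW/cm^2.
#' @examples
#' irradiance(30, 0.25)  # 12000
#' @export
irradiance <- function(power_mW, area_mm2) {
  if (power_mW < 0) stop("power must be >= 0")
  if (area_mm2 <= 0) stop("area must be > 0")
  power_mW / (area_mm2 / 100)   # 1 cm^2 = 100 mm^2
}

# ---- image I/O: text matrix per channel + JSON sidecar ----------------------

write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(ncol(m)))
    writeLines(paste(sprintf("%.17g", m[, j]), collapse = " "), con)
  invisible(path)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v))
      stop(sprintf("parse error in %s at line %d: non-numeric field", path, i))
    v
  })
  nc <- lengths(rows)
  if (length(unique(nc)) != 1)
    stop(sprintf("parse error in %s at line %d: expected %d fields, got %d",
                 path, which(nc != nc[1])[1], nc[1], nc[nc != nc[1]][1]))
  do.call(cbind, rows)   # each text line is one image column
}

#' Read and write near-field images
#'
#' A `nearfield_image` is stored as two whitespace-delimited text matrices
#' (`<stem>_amplitude.txt`, `<stem>_phase.txt`; one text line per image
#' column) plus a JSON sidecar `<stem>_meta.json` with pixel size and
#' channel metadata. The round trip is bit-exact for the rasters.
#'
#' @param image A [nearfield_image()].
#' @param stem Path stem (no extension).
#' @return `write_nearfield_image`: the stem, invisibly.
#'   `read_nearfield_image`: the image.
#' @export
write_nearfield_image <- function(image, stem) {
  stopifnot(inherits(image, "nearfield_image"))
  write_matrix_txt(image$amplitude, paste0(stem, "_amplitude.txt"))
  write_matrix_txt(image$phase, paste0(stem, "_phase.txt"))
  meta <- list(pixel_size_nm = image$pixel_size,
               wavenumber_cm1 = image$wavenumber,
               harmonic = image$harmonic,
               normalization = image$normalization,
               nx = nrow(image$amplitude), ny = ncol(image$amplitude))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_nearfield_image
#' @export
read_nearfield_image <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  a <- read_matrix_txt(paste0(stem, "_amplitude.txt"))
  p <- read_matrix_txt(paste0(stem, "_phase.txt"))
  nearfield_image(a, p, pixel_size = meta$pixel_size_nm,
                  wavenumber = if (is.null(meta$wavenumber_cm1)) NA_real_
                               else meta$wavenumber_cm1,
                  harmonic = meta$harmonic,
                  normalization = meta$normalization)
}

# ---- trace I/O --------------------------------------------------------------

#' Read and write signal traces
#'
#' CSV with columns `time_s`, `s2`, `phi2_deg`, `illumination_nm`, preceded
#' by `#`-comment header lines recording the sampling time, e.g.
#' `# t_p_s=0.5`.
#'
#' @param trace A [signal_trace()].
#' @param path File path.
#' @export
write_signal_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_p_s=%.17g", attr(trace, "t_p")), con)
  writeLines("time_s,s2,phi2_deg,illumination_nm", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%s", trace$time, trace$s2,
                     trace$phi2, trace$illumination), con)
  invisible(path)
}

#' @rdname write_signal_trace
#' @export
read_signal_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  tp <- NA_real_
  m <- regmatches(hdr, regexec("t_p_s=([0-9.eE+-]+)", hdr))
  for (mm in m) if (length(mm) == 2) tp <- as.numeric(mm[2])
  if (is.na(tp)) stop("trace file lacks a '# t_p_s=' header: ", path)
  body <- lines[!grepl("^#", lines)]
  first <- which(!grepl("^#", lines))[1]
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  need <- c("time_s", "s2", "phi2_deg", "illumination_nm")
  if (!all(need %in% names(df)))
    stop(sprintf("parse error in %s at line %d: expected columns %s",
                 path, first, paste(need, collapse = ", ")))
  for (cn in c("time_s", "s2", "phi2_deg")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v))
      stop(sprintf("parse error in %s at line %d: missing or non-numeric %s",
                   path, first + which(is.na(v))[1], cn))
    df[[cn]] <- v
  }
  if (anyNA(df$illumination_nm))
    stop(sprintf("parse error in %s at line %d: missing illumination label",
                 path, first + which(is.na(df$illumination_nm))[1]))
  signal_trace(df$time_s, df$s2, df$phi2_deg,
               as.character(df$illumination_nm), tp)
}

# ---- interferogram / spectrum I/O -------------------------------------------

#' Read and write interferograms
#'
#' CSV with columns `position_um` (mirror travel), `detector`.
#' @param ig An [interferogram()].
#' @param path File path.
#' @export
write_interferogram <- function(ig, path) {
  stopifnot(inherits(ig, "interferogram"))
  utils::write.csv(data.frame(position_um = sprintf("%.17g", ig$position_um),
                              detector = sprintf("%.17g", ig$detector)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_interferogram
#' @export
read_interferogram <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("position_um", "detector") %in% names(df)))
    stop("parse error in ", path, ": expected columns position_um, detector")
  interferogram(df$position_um, df$detector)
}

#' Write a spectrum to CSV
#'
#' Columns `wavenumber_cm1`, `s_n`, `phi_deg`.
#' @param spectrum A `complex_spectrum` or the data frame returned by
#'   [normalized_spectrum()].
#' @param path File path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  if (inherits(spectrum, "complex_spectrum")) {
    df <- data.frame(wavenumber_cm1 = spectrum$wavenumber,
                     s_n = spectrum$s_n, phi_deg = spectrum$phi_n)
  } else {
    df <- data.frame(wavenumber_cm1 = spectrum$wavenumber,
                     s_n = spectrum$s_ratio, phi_deg = spectrum$phi_diff_deg)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- material table ---------------------------------------------------------

#' Built-in permittivity surrogates
#'
#' Loads the editable oscillator table shipped in
#' `inst/extdata/materials.csv` (columns `material`, `center_cm1`,
#' `strength`, `damping_cm1`, `eps_inf_real`, `eps_inf_imag`; constant
#' media have no oscillator rows). These are illustrative fixtures that
#' place the lipid bands at 1466/1496/1603/1740 cm-1, a SiN phonon in the
#' 800--1150 cm-1 window and a flat lossy D2O -- not literature fits.
#'
#' @param path Optional path to an alternative table.
#' @param grid Wavenumber grid on which dispersive materials are evaluated.
#' @return Named list: constant media as complex scalars, dispersive media
#'   as [lorentz_permittivity()] spectra.
#' @export
builtin_materials <- function(path = NULL,
                              grid = seq(800, 2000, by = 2)) {
  if (is.null(path))
    path <- system.file("extdata", "materials.csv", package = "nanoswitch")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (mat in unique(df$material)) {
    rows <- df[df$material == mat, ]
    eps_inf <- complex(real = rows$eps_inf_real[1],
                       imaginary = rows$eps_inf_imag[1])
    osc <- rows[!is.na(rows$center_cm1), c("center_cm1", "strength",
                                           "damping_cm1")]
    out[[mat]] <- if (nrow(osc) == 0) eps_inf
                  else lorentz_permittivity(osc, eps_inf, grid)
  }
  out
}

# ---- ground truth JSON ------------------------------------------------------

#' Serialize generator ground truth beside an artifact
#'
#' @param truth Ground-truth list from a generator (`render_image`,
#'   `render_trace`, ...); closures are dropped.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  drop_fn <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, drop_fn)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  jsonlite::write_json(drop_fn(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
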