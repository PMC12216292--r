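# ---- seeded RNG helper ------------------------------------------------------

# run code with a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- scene specification ----------------------------------------------------

#' Specification of a synthetic near-field vesicle scene
#'
#' Describes a membrane-adhered vesicle field the way it appears in
#' second-harmonic s-SNOM rasters: flat-top discs with near-uniform interior
#' phase (> 25 deg by default) and amplitude, a smooth boundary fringe of
#' ~100 nm width rendered as a raised-cosine ramp, i.i.d. Gaussian pixel
#' noise, and an optional topography channel with nm-scale membrane bumps.
#'
#' @param image_size `c(nx, ny)` in pixels.
#' @param pixel_size Pixel edge in nm.
#' @param vesicles Data frame, one row per vesicle: `x`, `y` (center, nm),
#'   `radius` (nm), `interior_phase` (deg), `interior_amplitude` (arb.units),
#'   `fringe_width` (nm). Optional columns `harmonic_order`, `harmonic_amp`,
#'   `harmonic_phase` define a radial boundary perturbation
#'   \eqn{r(\varphi) = R (1 + A \cos(k\varphi - \varphi_0))}, and
#'   `bump_height_nm` a Gaussian membrane bump for the topography channel.
#' @param background_amplitude,background_phase Background levels (surrounding
#'   medium), arb.units and deg.
#' @param noise_sigma Gaussian noise sd added to both channels
#'   (amplitude channel in arb.units; the phase channel uses
#'   `noise_sigma_phase` if given, else the same number in deg).
#' @param noise_sigma_phase Optional separate phase-noise sd (deg).
#' @param seed Integer seed stored with the spec.
#' @return Object of class `scene_spec`.
#' @examples
#' sc <- scene_spec(vesicles = data.frame(x = 640, y = 640, radius = 330,
#'   interior_phase = 28, interior_amplitude = 21.2, fringe_width = 100))
#' @export
scene_spec <- function(image_size = c(128, 128), pixel_size = 10,
                       vesicles,
                       background_amplitude = 7, background_phase = 10,
                       noise_sigma = 0.3, noise_sigma_phase = NULL,
                       seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8), pixel_size > 0,
            is.data.frame(vesicles), noise_sigma >= 0)
  need <- c("x", "y", "radius", "interior_phase", "interior_amplitude",
            "fringe_width")
  if (!all(need %in% names(vesicles)))
    stop("vesicles must have columns ", paste(need, collapse = ", "))
  if (any(vesicles$fringe_width <= 0)) stop("fringe_width must be > 0")
  if (any(vesicles$radius <= pixel_size))
    stop("vesicle radius must exceed pixel_size")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 vesicles = vesicles,
                 background_amplitude = background_amplitude,
                 background_phase = background_phase,
                 noise_sigma = noise_sigma,
                 noise_sigma_phase = if (is.null(noise_sigma_phase))
                   noise_sigma else noise_sigma_phase,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# analytic boundary radius r(phi) of one vesicle row
vesicle_radius_fun <- function(v) {
  k <- if (!is.null(v$harmonic_order) && !is.na(v$harmonic_order))
    v$harmonic_order else 0
  A <- if (!is.null(v$harmonic_amp) && !is.na(v$harmonic_amp))
    v$harmonic_amp else 0
  p0 <- if (!is.null(v$harmonic_phase) && !is.na(v$harmonic_phase))
    v$harmonic_phase else 0
  function(phi) v$radius * (1 + A * cos(k * phi - p0))
}

# analytic area/perimeter/circularity of r(phi), by dense quadrature of the
# continuous boundary (truth is never taken from the raster)
boundary_truth <- function(v, n = 20000) {
  rf <- vesicle_radius_fun(v)
  phi <- seq(0, 2 * pi, length.out = n + 1)
  r <- rf(phi)
  dr <- (rf(phi + 1e-6) - rf(phi - 1e-6)) / 2e-6
  dphi <- diff(phi)
  area <- sum(0.5 * r[-1]^2 * dphi)
  per <- sum(sqrt(r^2 + dr^2)[-1] * dphi)
  list(area = area, perimeter = per, circularity = 4 * pi * area / per^2)
}

# raised-cosine profile across the boundary: 1 well inside, 0 well outside
fringe_ramp <- function(d, w) {
  out <- numeric(length(d))
  out[d <= -w / 2] <- 1
  mid <- d > -w / 2 & d < w / 2
  out[mid] <- 0.5 * (1 + cos(pi * (d[mid] + w / 2) / w))
  out
}

#' Render a synthetic near-field image with ground truth
#'
#' Draws every vesicle of the scene as a flat-top disc (optionally with a
#' low-order radial boundary perturbation) in the amplitude and phase
#' channels, with a raised-cosine fringe of the stated width centered on the
#' continuous boundary, then adds i.i.d. Gaussian noise. Pure function of
#' (spec, seed): identical inputs give bit-identical images.
#'
#' @param scene A [scene_spec()].
#' @param seed Overrides `scene$seed` when given.
#' @return List with elements `image` (a [nearfield_image()]) and `truth`
#'   (per-vesicle analytic area/perimeter/circularity from the continuous
#'   boundary, generator parameters, overlap warnings).
#' @export
render_image <- function(scene, seed = NULL) {
  stopifnot(inherits(scene, "scene_spec"))
  if (is.null(seed)) seed <- scene$seed
  nx <- scene$image_size[1]; ny <- scene$image_size[2]
  px <- scene$pixel_size
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  amp <- matrix(scene$background_amplitude, nx, ny)
  ph <- matrix(scene$background_phase, nx, ny)
  topo <- matrix(0, nx, ny)
  cover <- matrix(0, nx, ny)
  truth_ves <- vector("list", nrow(scene$vesicles))
  for (i in seq_len(nrow(scene$vesicles))) {
    v <- as.list(scene$vesicles[i, , drop = FALSE])
    rf <- vesicle_radius_fun(v)
    dx <- X - v$x; dy <- Y - v$y
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    d <- rho - rf(phi)                      # signed distance (radial approx.)
    ramp <- fringe_ramp(d, v$fringe_width)
    amp <- amp + (v$interior_amplitude - scene$background_amplitude) * ramp
    ph <- ph + (v$interior_phase - scene$background_phase) * ramp
    if (!is.null(v$bump_height_nm) && !is.na(v$bump_height_nm))
      topo <- topo + v$bump_height_nm * exp(-rho^2 / (2 * (v$radius / 2)^2))
    cover <- cover + (ramp > 0)
    truth_ves[[i]] <- c(v, boundary_truth(v))
  }
  overlap <- any(cover > 1)
  img <- with_seed(seed, {
    a <- amp + matrix(stats::rnorm(nx * ny, 0, scene$noise_sigma), nx, ny)
    p <- ph + matrix(stats::rnorm(nx * ny, 0, scene$noise_sigma_phase), nx, ny)
    nearfield_image(a, p, pixel_size = px)
  })
  attr(img, "topography_nm") <- topo
  truth <- list(vesicles = truth_ves, seed = seed,
                background_amplitude = scene$background_amplitude,
                background_phase = scene$background_phase,
                noise_sigma = scene$noise_sigma,
                noise_sigma_phase = scene$noise_sigma_phase,
                overlap_warning = overlap)
  if (overlap) warning("overlapping vesicles; recorded in truth")
  list(image = img, truth = truth)
}

# circularity of the unit shape 1 + A cos(k phi), scale-invariant in R
harmonic_circularity <- function(A, k, n = 4096) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-1]
  r <- 1 + A * cos(k * phi)
  dr <- -A * k * sin(k * phi)
  dphi <- 2 * pi / n
  area <- sum(0.5 * r^2) * dphi
  per <- sum(sqrt(r^2 + dr^2)) * dphi
  4 * pi * area / per^2
}

#' Render a trans/cis image pair with prescribed shape-change factors
#'
#' The trans state is the plain disc of the (single-vesicle) scene. The cis
#' state scales the disc to `area_factor` times the trans area and adds a
#' low-order radial harmonic whose amplitude is found by bisection so the
#' analytic circularity equals `circularity_factor` times the trans value
#' (a disc has circularity 1). Defaults mirror the reported trans-to-cis
#' change: +10% area, -8% circularity.
#'
#' @param scene A single-vesicle [scene_spec()].
#' @param area_factor Cis/trans area ratio, > 0. Default 1.10.
#' @param circularity_factor Cis/trans circularity ratio in (0, 1].
#'   Default 0.92.
#' @param seed Base seed; the two noise fields use `seed` and `seed + 1`.
#' @param harmonic_order Radial perturbation order k. Default 3 (gentle
#'   three-lobed deformation).
#' @return List with `image_trans`, `image_cis` (each a [nearfield_image()])
#'   and `truth` carrying the analytic areas/circularities and both target
#'   factors.
#' @export
render_state_pair <- function(scene, area_factor = 1.10,
                              circularity_factor = 0.92, seed = NULL,
                              harmonic_order = 3) {
  stopifnot(inherits(scene, "scene_spec"), area_factor > 0,
            circularity_factor > 0, circularity_factor <= 1)
  if (nrow(scene$vesicles) != 1)
    stop("render_state_pair expects a single-vesicle scene")
  if (is.null(seed)) seed <- scene$seed
  k <- harmonic_order
  # feasible range of the bisection: A in [0, 0.5]
  c_min <- harmonic_circularity(0.5, k)
  if (circularity_factor < c_min)
    stop(sprintf(
      "circularity_factor %.3f unreachable with harmonic order %d (feasible range [%.3f, 1])",
      circularity_factor, k, c_min))
  if (circularity_factor == 1) {
    A <- 0
  } else {
    lo <- 0; hi <- 0.5
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (harmonic_circularity(mid, k) > circularity_factor) lo <- mid
      else hi <- mid
    }
    A <- (lo + hi) / 2
  }
  v <- scene$vesicles[1, , drop = FALSE]
  # area of r = Rc (1 + A cos k phi) is pi Rc^2 (1 + A^2/2)
  Rc <- v$radius * sqrt(area_factor / (1 + A^2 / 2))
  ves_cis <- v
  ves_cis$radius <- Rc
  ves_cis$harmonic_order <- k
  ves_cis$harmonic_amp <- A
  ves_cis$harmonic_phase <- 0
  scene_cis <- scene
  scene_cis$vesicles <- ves_cis
  rt <- render_image(scene, seed = seed)
  rc <- render_image(scene_cis, seed = seed + 1L)
  tt <- rt$truth$vesicles[[1]]; tc <- rc$truth$vesicles[[1]]
  truth <- list(
    area_factor_target = area_factor,
    circularity_factor_target = circularity_factor,
    harmonic_order = k, harmonic_amp = A,
    trans = list(area = tt$area, perimeter = tt$perimeter,
                 circularity = tt$circularity),
    cis = list(area = tc$area, perimeter = tc$perimeter,
               circularity = tc$circularity),
    area_ratio = tc$area / tt$area,
    circularity_ratio = tc$circularity / tt$circularity,
    seed = seed)
  list(image_trans = rt$image, image_cis = rc$image, truth = truth)
}

# ---- switching traces -------------------------------------------------------

#' Specification of a synthetic photoswitching signal trace
#'
#' Epochs of constant illumination (alternating 365/465 nm), each carrying a
#' delayed sigmoidal step \eqn{f(t) = C + L / (1 + e^{-(t - t_d)/\tau})} in
#' both channels. Samples are boxcar averages of the continuous model over
#' windows of the sampling time t_p (the acquisition convolution the fits
#' inherit), plus Gaussian noise and optional linear drift.
#'
#' @param epochs Data frame, one row per epoch: `illumination` ("365" or
#'   "465"), `duration` (s), `step_s2` and `step_phi2` (signed step sizes L),
#'   `delay_t_d` (s, from epoch start), `growth_tau` (s).
#' @param t_p Sampling/integration time in s.
#' @param s2_baseline,phi2_baseline Channel values at the start of the trace
#'   (s2 conventionally normalized to the surrounding D2O).
#' @param noise_sigma_s2,noise_sigma_phi2 Per-sample Gaussian noise sd.
#' @param drift_slope_s2,drift_slope_phi2 Linear drift per second.
#' @param seed Integer seed.
#' @return Object of class `trace_spec`.
#' @export
trace_spec <- function(epochs = default_epochs(), t_p = 0.5,
                       s2_baseline = 1.0, phi2_baseline = 28,
                       noise_sigma_s2 = 0.01, noise_sigma_phi2 = 0.2,
                       drift_slope_s2 = 0, drift_slope_phi2 = 0,
                       seed = 1L) {
  stopifnot(is.data.frame(epochs), t_p > 0)
  need <- c("illumination", "duration", "step_s2", "step_phi2",
            "delay_t_d", "growth_tau")
  if (!all(need %in% names(epochs)))
    stop("epochs must have columns ", paste(need, collapse = ", "))
  if (any(epochs$duration <= epochs$delay_t_d))
    stop("epoch duration must exceed delay_t_d")
  if (any(epochs$duration < t_p)) stop("t_p longer than an epoch")
  if (nrow(epochs) > 1 &&
      any(epochs$illumination[-1] == epochs$illumination[-nrow(epochs)]))
    stop("illumination labels must alternate between epochs")
  structure(list(epochs = epochs, t_p = t_p,
                 s2_baseline = s2_baseline, phi2_baseline = phi2_baseline,
                 noise_sigma_s2 = noise_sigma_s2,
                 noise_sigma_phi2 = noise_sigma_phi2,
                 drift_slope_s2 = drift_slope_s2,
                 drift_slope_phi2 = drift_slope_phi2,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Default switching schedule: eight alternating 1-minute epochs
#'
#' Mirrors the reported experiment: illumination toggled once per minute
#' between 365 nm and 465 nm over eight epochs, an 8% amplitude step and a
#' 1.6 deg phase step (down under 365 nm, back up under 465 nm), delays
#' within 10.3--15.7 s and growth times within 0.7--3.9 s.
#'
#' @param n_epochs Number of epochs.
#' @param duration Epoch duration in s.
#' @return Data frame suitable for [trace_spec()].
#' @export
default_epochs <- function(n_epochs = 8, duration = 60) {
  to_cis <- rep(c(TRUE, FALSE), length.out = n_epochs)  # 365 first
  td <- rep(c(12.0, 10.3, 15.7, 13.5), length.out = n_epochs)
  tau <- rep(c(2.0, 0.7, 3.9, 1.5), length.out = n_epochs)
  data.frame(illumination = ifelse(to_cis, "365", "465"),
             duration = duration,
             step_s2 = ifelse(to_cis, -0.08, +0.08),
             step_phi2 = ifelse(to_cis, -1.6, +1.6),
             delay_t_d = td, growth_tau = tau)
}

# continuous two-channel model of a trace_spec, vectorized over absolute time
trace_model <- function(spec) {
  starts <- cumsum(c(0, spec$epochs$duration))[seq_len(nrow(spec$epochs))]
  function(t) {
    s2 <- rep(spec$s2_baseline, length(t))
    p2 <- rep(spec$phi2_baseline, length(t))
    for (i in seq_len(nrow(spec$epochs))) {
      e <- spec$epochs[i, ]
      tl <- t - starts[i]
      sig <- ifelse(tl < 0, 0, 1 / (1 + exp(-(tl - e$delay_t_d) / e$growth_tau)))
      s2 <- s2 + e$step_s2 * sig
      p2 <- p2 + e$step_phi2 * sig
    }
    list(s2 = s2 + spec$drift_slope_s2 * t,
         phi2 = p2 + spec$drift_slope_phi2 * t)
  }
}

#' Render a synthetic switching trace with ground truth
#'
#' Evaluates the continuous epoch model as its boxcar average over each
#' sampling window of width t_p (>= 32 sub-samples per window), attaches
#' epoch labels, and adds per-channel Gaussian noise.
#'
#' @param spec A [trace_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List with `trace` (a [signal_trace()]) and `truth` (epoch
#'   parameters, absolute switch times, noiseless windowed samples and the
#'   continuous model function).
#' @export
render_trace <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "trace_spec"))
  if (is.null(seed)) seed <- spec$seed
  tp <- spec$t_p
  total <- sum(spec$epochs$duration)
  n <- floor(total / tp + 1e-9)
  mid <- (seq_len(n) - 0.5) * tp
  model <- trace_model(spec)
  # boxcar average over each window with 32 sub-samples
  nsub <- 32
  off <- ((seq_len(nsub) - 0.5) / nsub - 0.5) * tp
  s2m <- numeric(n); p2m <- numeric(n)
  for (o in off) {
    v <- model(mid + o)
    s2m <- s2m + v$s2 / nsub
    p2m <- p2m + v$phi2 / nsub
  }
  starts <- cumsum(c(0, spec$epochs$duration))
  lab <- as.character(cut(mid, breaks = starts, labels = spec$epochs$illumination,
                          include.lowest = TRUE, right = TRUE))
  tr <- with_seed(seed, {
    s2 <- s2m + stats::rnorm(n, 0, spec$noise_sigma_s2)
    p2 <- p2m + stats::rnorm(n, 0, spec$noise_sigma_phi2)
    signal_trace(time = mid, s2 = s2, phi2 = p2, illumination = lab, t_p = tp)
  })
  truth <- list(epochs = spec$epochs, switch_times = starts,
                s2_baseline = spec$s2_baseline,
                phi2_baseline = spec$phi2_baseline,
                s2_noiseless = s2m, phi2_noiseless = p2m,
                model = model, seed = seed)
  list(trace = tr, truth = truth)
}

# ---- interferograms ---------------------------------------------------------

#' Render a synthetic asymmetric-Michelson interferogram
#'
#' The detector value at mirror position x (optical path difference 2x) for
#' a discrete spectral source is
#' \eqn{I(x) = \mathrm{Re} \sum_k A_k e^{i (2\pi \nu_k \cdot 2x + \phi_k)}},
#' sampled uniformly over the scan. The factor 2 reflects that mirror travel
#' doubles the optical path, so a scan of length s gives a nominal spectral
#' resolution of 1/(2s).
#'
#' @param components Data frame with columns `wavenumber` (cm-1),
#'   `amplitude`, and optionally `phase_deg`.
#' @param scan_length_um Mirror travel in micrometres.
#' @param n_points Number of samples, >= 64.
#' @param noise_sigma Optional Gaussian detector noise sd.
#' @param seed Seed for the noise.
#' @return An `interferogram` object: fields `position_um` (mirror grid),
#'   `detector`, `scan_length_um`, `n_points`.
#' @export
render_interferogram <- function(components, scan_length_um, n_points = 1200,
                                 noise_sigma = 0, seed = 1L) {
  stopifnot(is.data.frame(components), scan_length_um > 0, n_points >= 64)
  if (!all(c("wavenumber", "amplitude") %in% names(components)))
    stop("components needs columns wavenumber, amplitude")
  ph <- if ("phase_deg" %in% names(components))
    components$phase_deg * pi / 180 else rep(0, nrow(components))
  x_um <- seq(0, scan_length_um, length.out = n_points)
  dx_cm <- (x_um[2] - x_um[1]) * 1e-4
  nyq <- 1 / (2 * 2 * dx_cm)     # OPD step is twice the mirror step
  if (any(components$wavenumber >= nyq))
    stop(sprintf("aliasing: max wavenumber %.1f cm-1 exceeds Nyquist %.1f cm-1",
                 max(components$wavenumber), nyq))
  x_cm <- x_um * 1e-4
  det <- rep(0, n_points)
  for (k in seq_len(nrow(components)))
    det <- det + components$amplitude[k] *
      cos(2 * pi * components$wavenumber[k] * 2 * x_cm + ph[k])
  if (noise_sigma > 0)
    det <- det + with_seed(seed, stats::rnorm(n_points, 0, noise_sigma))
  structure(list(position_um = x_um, detector = det,
                 scan_length_um = scan_length_um, n_points = n_points),
            class = "interferogram")
}
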