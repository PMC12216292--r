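#' Co-registered near-field amplitude/phase rasters
#'
#' @param amplitude,phase Numeric matrices of identical shape (amplitude in
#'   arb.units, phase in degrees). Rows index x, columns y.
#' @param pixel_size Pixel edge in nm.
#' @param wavenumber Wavenumber of the recording in cm-1 (metadata).
#' @param harmonic Demodulation harmonic (metadata). Default 2.
#' @param normalization Free-text normalization label (e.g. "D2O", "Si").
#' @return Object of class `nearfield_image`.
#' @export
nearfield_image <- function(amplitude, phase, pixel_size,
                            wavenumber = NA_real_, harmonic = 2L,
                            normalization = "none") {
  stopifnot(is.matrix(amplitude), is.matrix(phase),
            all(dim(amplitude) == dim(phase)), pixel_size > 0)
  structure(list(amplitude = amplitude, phase = phase,
                 pixel_size = pixel_size, wavenumber = wavenumber,
                 harmonic = as.integer(harmonic),
                 normalization = normalization),
            class = "nearfield_image")
}

#' @export
print.nearfield_image <- function(x, ...) {
  cat(sprintf("Near-field image %d x %d px, %g nm/px (harmonic %d, %s cm-1, norm %s)\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_size, x$harmonic,
              format(x$wavenumber), x$normalization))
  invisible(x)
}

#' Border-frame background subtraction
#'
#' Estimates the background as the median amplitude of the border frame of
#' the stated fraction of the image and subtracts it from the amplitude
#' channel; the phase channel is left untouched.
#'
#' @param image A [nearfield_image()].
#' @param border_fraction Width of the border frame as a fraction of the
#'   image size, in (0, 0.5).
#' @param seed_box Optional `c(x0, y0, x1, y1)` (nm) bounding box of the
#'   object of interest; a warning is raised if it overlaps the border frame.
#' @return List with `image` (background-subtracted) and
#'   `background_estimate`.
#' @export
background_subtract <- function(image, border_fraction = 0.15,
                                seed_box = NULL) {
  stopifnot(inherits(image, "nearfield_image"),
            border_fraction > 0, border_fraction < 0.5)
  a <- image$amplitude
  bx <- max(1L, floor(nrow(a) * border_fraction))
  by <- max(1L, floor(ncol(a) * border_fraction))
  border <- matrix(FALSE, nrow(a), ncol(a))
  border[c(seq_len(bx), seq(nrow(a) - bx + 1, nrow(a))), ] <- TRUE
  border[, c(seq_len(by), seq(ncol(a) - by + 1, ncol(a)))] <- TRUE
  if (!is.null(seed_box)) {
    px <- image$pixel_size
    ix <- pmax(1L, pmin(nrow(a), ceiling(c(seed_box[1], seed_box[3]) / px)))
    iy <- pmax(1L, pmin(ncol(a), ceiling(c(seed_box[2], seed_box[4]) / px)))
    if (any(border[seq(ix[1], ix[2]), seq(iy[1], iy[2])]))
      warning("seed_box overlaps the background border frame")
  }
  bg <- stats::median(a[border])
  out <- image
  out$amplitude <- a - bg
  list(image = out, background_estimate = bg,
       n_border = sum(border))
}

# ---- contour machinery ------------------------------------------------------

# closed-polygon area (shoelace) and perimeter
polygon_metrics <- function(px, py) {
  x <- c(px, px[1]); y <- c(py, py[1])
  per <- sum(sqrt(diff(x)^2 + diff(y)^2))
  area <- abs(sum(x[-1] * y[-length(y)] - x[-length(x)] * y[-1])) / 2
  list(area = area, perimeter = per,
       circularity = 4 * pi * area / per^2)
}

# resample a closed polygon to ~uniform vertex spacing (arclength param.)
resample_polygon <- function(px, py, spacing = 0.5) {
  x <- c(px, px[1]); y <- c(py, py[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, seg > 0)           # drop duplicate vertices
  x <- x[keep]; y <- y[keep]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n <- max(32L, round(L / spacing))
  si <- seq(0, L, length.out = n + 1)[-(n + 1)]
  list(x = stats::approx(s, x, xout = si)$y,
       y = stats::approx(s, y, xout = si)$y)
}

# flag vertices where the boundary turns sharply at a coarse (multi-pixel)
# scale; these are genuine corners, not rasterization staircase
corner_pins <- function(px, py, spacing = 0.5, scale_px = 3, thresh_deg = 50) {
  n <- length(px)
  k <- max(1L, round(scale_px / spacing))
  idx <- function(v) ((v - 1) %% n) + 1
  i <- seq_len(n)
  bx <- px[i] - px[idx(i - k)]; by <- py[i] - py[idx(i - k)]
  ax <- px[idx(i + k)] - px[i]; ay <- py[idx(i + k)] - py[i]
  ang <- abs(atan2(bx * ay - by * ax, bx * ax + by * ay)) * 180 / pi
  ang > thresh_deg
}

# staircase removal: iterative neighbor averaging, every vertex clamped to
# within `clamp` pixels of its original position, corners pinned
relax_polygon <- function(px, py, clamp = 0.35, iters = 50, pins = NULL) {
  n <- length(px)
  ox <- px; oy <- py
  if (is.null(pins)) pins <- rep(FALSE, n)
  prev <- c(n, seq_len(n - 1)); nxt <- c(seq(2, n), 1)
  for (it in seq_len(iters)) {
    mx <- (px[prev] + px + px[nxt]) / 3
    my <- (py[prev] + py + py[nxt]) / 3
    dx <- mx - ox; dy <- my - oy
    d <- sqrt(dx^2 + dy^2)
    f <- ifelse(d > clamp, clamp / d, 1)
    f[pins] <- 0
    px <- ox + dx * f; py <- oy + dy * f
  }
  list(x = px, y = py)
}

# sub-pixel iso-contour polygons of matrix z at `level`; coordinates in
# pixel units (pixel centers at i - 0.5)
iso_contours <- function(z, level) {
  xs <- seq_len(nrow(z)) - 0.5
  ys <- seq_len(ncol(z)) - 0.5
  grDevices::contourLines(xs, ys, z, levels = level)
}

point_in_polygon <- function(x0, y0, px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  cross <- (py > y0) != (py[j] > y0)
  xi <- px[j] + (y0 - py[j]) * (px - px[j]) / (py - py[j])
  sum(cross & x0 < xi) %% 2 == 1
}

# choose the contour polygon enclosing the point (in pixel units)
pick_contour <- function(contours, x0, y0) {
  for (cc in contours)
    if (point_in_polygon(x0, y0, cc$x, cc$y)) return(cc)
  NULL
}

# one 3x3 box-filter pass with edge replication (noise suppression before
# thresholding/contouring; preserves linear ramps to first order)
box_smooth <- function(z, passes = 1) {
  for (p in seq_len(passes)) {
    n <- nrow(z); m <- ncol(z)
    z <- (z[c(1, 1:(n - 1)), ] + z + z[c(2:n, n), ]) / 3
    z <- (z[, c(1, 1:(m - 1))] + z + z[, c(2:m, m)]) / 3
  }
  z
}

# connected component of `mask` (logical matrix) containing (i, j), grown by
# vectorized frontier dilation (4-neighborhood)
connected_component <- function(mask, i, j) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[i, j]) return(comp)
  comp[i, j] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
    grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
    grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
    grown <- grown & mask
    if (all(grown == comp)) break
    comp <- grown
  }
  comp
}

# fill interior holes: everything not reachable from the border through the
# complement belongs to the component
fill_holes <- function(comp) {
  outside <- !comp
  reach <- matrix(FALSE, nrow(comp), ncol(comp))
  reach[1, ] <- outside[1, ]; reach[nrow(comp), ] <- outside[nrow(comp), ]
  reach[, 1] <- reach[, 1] | outside[, 1]
  reach[, ncol(comp)] <- reach[, ncol(comp)] | outside[, ncol(comp)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & outside
    if (all(grown == reach)) break
    reach <- grown
  }
  !reach
}

#' Area, perimeter and circularity of a binary mask
#'
#' Extracts the 0.5-level iso-contour of the mask (marching-squares style,
#' sub-pixel), removes the rasterization staircase by clamped relaxation
#' with coarse-scale corners pinned, and measures the polygon: shoelace
#' area, polyline perimeter, circularity \eqn{4\pi A/p^2}. A finely
#' rasterized disc scores ~1, an axis-aligned square ~\eqn{\pi/4}.
#'
#' @param mask Logical (or 0/1) matrix, a single connected component.
#' @param pixel_size Pixel edge in nm.
#' @return List with `area_A` (nm^2), `perimeter_p` (nm), `circularity` and
#'   the measurement `polygon` (nm coordinates).
#' @export
shape_metrics <- function(mask, pixel_size = 1) {
  mask <- mask != 0
  if (!any(mask)) stop("mask has zero pixels")
  z <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ccs <- iso_contours(z, 0.5)
  if (length(ccs) == 0) stop("no contour found (mask touches entire image?)")
  # largest contour by bounding box (holes were filled upstream)
  sizes <- vapply(ccs, function(cc) diff(range(cc$x)) * diff(range(cc$y)),
                  numeric(1))
  cc <- ccs[[which.max(sizes)]]
  rs <- resample_polygon(cc$x, cc$y)
  pins <- corner_pins(rs$x, rs$y)
  rl <- relax_polygon(rs$x, rs$y, pins = pins)
  m <- polygon_metrics(rl$x * pixel_size, rl$y * pixel_size)
  list(area_A = m$area, perimeter_p = m$perimeter,
       circularity = m$circularity,
       polygon = list(x = rl$x * pixel_size, y = rl$y * pixel_size))
}

#' Segment a vesicle around a seed point
#'
#' Background-subtracts the amplitude channel, hill-climbs from the seed to
#' the nearby local maximum (the particle center), thresholds at either the
#' stated fraction of that maximum (default 1/e, the reported boundary
#' rule) or an absolute level (e.g. the reported s2 = 7.8 arb.units),
#' keeps the connected component containing the maximum with holes filled,
#' and measures area/perimeter/circularity on the sub-pixel iso-contour of
#' the smooth amplitude raster at the threshold level.
#'
#' @param image A [nearfield_image()].
#' @param seed_point `c(x, y)` in nm.
#' @param criterion Either `"efold"` (threshold = max/e), a list
#'   `list(type = "fraction", value = f)`, or `list(type = "absolute",
#'   value = s)` in the raw (not background-subtracted) amplitude units.
#' @param border_fraction Passed to [background_subtract()].
#' @param presmooth Number of 3x3 box-filter passes applied to the
#'   background-subtracted amplitude before peak search and contouring
#'   (noise suppression; a symmetric kernel preserves the boundary
#'   position on the locally linear fringe ramp). Default 1.
#' @return Object of class `segmentation_result`: `mask`, `threshold_used`
#'   (background-subtracted units), `area_A` (nm^2), `perimeter_p` (nm),
#'   `circularity`, `centroid` (nm), `edge_touch` flag, `polygon`.
#' @export
segment_vesicle <- function(image, seed_point, criterion = "efold",
                            border_fraction = 0.15, presmooth = 1) {
  stopifnot(inherits(image, "nearfield_image"), length(seed_point) == 2)
  px <- image$pixel_size
  bs <- background_subtract(image, border_fraction)
  a <- box_smooth(bs$image$amplitude, presmooth)
  i <- max(1L, min(nrow(a), ceiling(seed_point[1] / px)))
  j <- max(1L, min(ncol(a), ceiling(seed_point[2] / px)))
  # greedy hill-climb to the local maximum nearest the seed
  repeat {
    ii <- max(1L, i - 1L):min(nrow(a), i + 1L)
    jj <- max(1L, j - 1L):min(ncol(a), j + 1L)
    win <- a[ii, jj, drop = FALSE]
    if (max(win) <= a[i, j]) break   # strict ascent only (plateaus terminate)
    w <- which(win == max(win), arr.ind = TRUE)[1, ]
    i <- ii[w[1]]; j <- jj[w[2]]
  }
  peak <- a[i, j]
  if (identical(criterion, "efold"))
    criterion <- list(type = "fraction", value = exp(-1))
  thr <- switch(criterion$type,
                fraction = peak * criterion$value,
                absolute = criterion$value - bs$background_estimate,
                stop("criterion type must be 'fraction' or 'absolute'"))
  above <- a >= thr
  if (!above[i, j] || !any(above))
    stop("empty segmentation: no pixel above threshold at the seed maximum")
  comp <- connected_component(above, i, j)
  edge_touch <- any(comp[1, ]) || any(comp[nrow(comp), ]) ||
    any(comp[, 1]) || any(comp[, ncol(comp)])
  if (edge_touch) warning("segmented component touches the image edge")
  comp <- fill_holes(comp)
  # sub-pixel boundary from the smooth raster at the threshold level
  cc <- pick_contour(iso_contours(a, thr), i - 0.5, j - 0.5)
  if (is.null(cc)) {            # peak sits on the contour grid: fall back
    sm <- shape_metrics(comp, px)
    poly <- sm$polygon
    m <- list(area = sm$area_A, perimeter = sm$perimeter_p,
              circularity = sm$circularity)
  } else {
    rs <- resample_polygon(cc$x, cc$y)
    rl <- relax_polygon(rs$x, rs$y, pins = corner_pins(rs$x, rs$y))
    m <- polygon_metrics(rl$x * px, rl$y * px)
    poly <- list(x = rl$x * px, y = rl$y * px)
  }
  centroid <- c(x = mean(poly$x), y = mean(poly$y))
  structure(list(mask = comp, threshold_used = thr,
                 background_estimate = bs$background_estimate,
                 area_A = m$area, perimeter_p = m$perimeter,
                 circularity = m$circularity, centroid = centroid,
                 edge_touch = edge_touch, polygon = poly,
                 pixel_size = px),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation: A = %.4g nm^2, p = %.4g nm, circularity %.3f (threshold %.3g)\n",
              x$area_A, x$perimeter_p, x$circularity, x$threshold_used))
  invisible(x)
}

# bilinear interpolation of matrix z (pixel centers at i - 0.5) at pixel
# coordinates (x, y)
bilinear <- function(z, x, y) {
  x <- pmin(pmax(x, 0.5), nrow(z) - 0.5)
  y <- pmin(pmax(y, 0.5), ncol(z) - 0.5)
  i0 <- pmin(pmax(floor(x - 0.5) + 1, 1), nrow(z) - 1)
  j0 <- pmin(pmax(floor(y - 0.5) + 1, 1), ncol(z) - 1)
  fx <- x - (i0 - 0.5); fy <- y - (j0 - 0.5)
  z[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    z[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    z[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    z[cbind(i0 + 1, j0 + 1)] * fx * fy
}

#' Gaussian-fit FWHM of a line profile
#'
#' Samples a channel along a line with bilinear interpolation and fits a
#' Gaussian plus constant offset by nonlinear least squares. The apparent
#' object width is FWHM \eqn{= 2\sqrt{2\ln 2}\,\sigma}; its standard error
#' comes from the fit covariance. Initial guesses: offset = profile min,
#' amplitude = max - min, center = argmax, sigma = line length / 6.
#'
#' @param image A [nearfield_image()].
#' @param line_endpoints `c(x0, y0, x1, y1)` in nm.
#' @param channel `"phase"` or `"amplitude"`.
#' @param n_samples Number of samples along the line (default: one per
#'   half-pixel).
#' @return Object of class `profile_fit`: `fwhm`, `fwhm_error` (nm), the
#'   fitted `parameters` (amplitude, center, sigma, offset), `covariance`,
#'   and the sampled `profile`.
#' @export
profile_fwhm <- function(image, line_endpoints, channel = c("phase", "amplitude"),
                         n_samples = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(image, "nearfield_image"), length(line_endpoints) == 4)
  px <- image$pixel_size
  p0 <- line_endpoints[1:2] / px; p1 <- line_endpoints[3:4] / px
  len_px <- sqrt(sum((p1 - p0)^2))
  if (len_px <= 5) stop("line length must exceed 5 pixels")
  if (is.null(n_samples)) n_samples <- max(32L, ceiling(len_px * 2))
  tseq <- seq(0, 1, length.out = n_samples)
  xs <- p0[1] + tseq * (p1[1] - p0[1])
  ys <- p0[2] + tseq * (p1[2] - p0[2])
  z <- if (channel == "phase") image$phase else image$amplitude
  prof <- bilinear(z, xs, ys)
  s <- tseq * len_px * px                       # nm along the line
  init <- c(A = max(prof) - min(prof), mu = s[which.max(prof)],
            sigma = (max(s) - min(s)) / 6, off = min(prof))
  model <- function(p, s) p[4] + p[1] * exp(-(s - p[2])^2 / (2 * p[3]^2))
  jac <- function(p, s) {
    g <- exp(-(s - p[2])^2 / (2 * p[3]^2))
    cbind(A = g,
          mu = p[1] * g * (s - p[2]) / p[3]^2,
          sigma = p[1] * g * (s - p[2])^2 / p[3]^3,
          off = 1)
  }
  fit <- lm_nls(function(p) prof - model(p, s),
                function(p) -jac(p, s), init,
                lower = c(-Inf, min(s), 1e-6 * max(s), -Inf),
                upper = c(Inf, max(s), max(s), Inf))
  if (!fit$converged)
    stop(sprintf("Gaussian profile fit did not converge (init A=%.3g mu=%.3g sigma=%.3g off=%.3g)",
                 init[1], init[2], init[3], init[4]))
  k <- 2 * sqrt(2 * log(2))
  sig_se <- sqrt(fit$cov["sigma", "sigma"])
  structure(list(fwhm = k * fit$par[["sigma"]], fwhm_error = k * sig_se,
                 parameters = fit$par, covariance = fit$cov,
                 rmse = fit$rmse,
                 profile = data.frame(s_nm = s, value = prof)),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("Gaussian profile fit: FWHM = %.1f +/- %.1f nm\n",
              x$fwhm, x$fwhm_error))
  invisible(x)
}

#' Per-state shape series over a switching image sequence
#'
#' Segments each image of an alternating trans/cis sequence, tabulates area
#' and circularity, the relative change across every transition, and a
#' reversibility summary (largest relative deviation between revisits of
#' the same illumination state and its first visit).
#'
#' @param images List of [nearfield_image()] objects, ordered in time.
#' @param labels Character vector of illumination labels (e.g. "365"/"465"),
#'   alternating, one per image.
#' @param seed_point,criterion,border_fraction Passed to
#'   [segment_vesicle()].
#' @return List with `table` (per image: label, area, circularity, ok flag),
#'   `transitions` (per consecutive pair: percent changes) and
#'   `reversibility` (per metric).
#' @export
state_series <- function(images, labels, seed_point, criterion = "efold",
                         border_fraction = 0.15) {
  stopifnot(length(images) >= 2, length(labels) == length(images))
  if (any(labels[-1] == labels[-length(labels)]))
    stop("illumination labels must alternate")
  rows <- lapply(seq_along(images), function(i) {
    r <- tryCatch(segment_vesicle(images[[i]], seed_point, criterion,
                                  border_fraction),
                  error = function(e) NULL)
    if (is.null(r))
      data.frame(index = i, label = labels[i], area_A = NA_real_,
                 circularity = NA_real_, ok = FALSE)
    else
      data.frame(index = i, label = labels[i], area_A = r$area_A,
                 circularity = r$circularity, ok = TRUE)
  })
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  trans <- data.frame(
    from = tab$label[-n], to = tab$label[-1],
    delta_area_pct = 100 * (tab$area_A[-1] - tab$area_A[-n]) / tab$area_A[-n],
    delta_circularity_pct =
      100 * (tab$circularity[-1] - tab$circularity[-n]) / tab$circularity[-n])
  revers <- vapply(c("area_A", "circularity"), function(m) {
    v <- tab[[m]]
    out <- 0
    for (lb in unique(tab$label)) {
      vv <- v[tab$label == lb & tab$ok]
      if (length(vv) > 1)
        out <- max(out, max(abs(vv[-1] - vv[1]) / abs(vv[1])))
    }
    out
  }, numeric(1))
  list(table = tab, transitions = trans, reversibility = revers)
}
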