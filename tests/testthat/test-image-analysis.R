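# segmentation, shape metrics, profiles, state series

test_that("background_subtract: constant, disc scene, sampling-error bound", {
  m <- matrix(3.7, 64, 64)
  img <- nearfield_image(m, m * 0, 10)
  bs <- background_subtract(img)
  expect_equal(bs$background_estimate, 3.7)
  expect_true(all(bs$image$amplitude == 0))

  r0 <- render_image(disc_scene(noise_sigma = 0))
  bs0 <- background_subtract(r0$image)
  far <- abs(bs0$image$amplitude) < 1e-12
  expect_gt(mean(far), 0.5)     # far field sits at exactly zero

  sc <- disc_scene(noise_sigma = 0.3, seed = 21L)
  r <- render_image(sc)
  bs1 <- background_subtract(r$image)
  # median of N border samples: sd ~ 1.25 sigma/sqrt(N); allow 3 sigma
  bound <- 3 * 1.25 * sc$noise_sigma / sqrt(bs1$n_border)
  expect_lt(abs(bs1$background_estimate - 0), bound + 1e-12)

  expect_warning(background_subtract(r$image, seed_box = c(10, 10, 300, 300)),
                 "border")
  expect_error(background_subtract(r$image, border_fraction = 0.6),
               "border_fraction")
})

test_that("segment_vesicle: flat-top disc, Gaussian level set, absolute threshold", {
  r <- render_image(disc_scene(noise_sigma = 0, fringe_width = 20))
  seg <- segment_vesicle(r$image, c(640, 640))
  expect_rel(seg$area_A, pi * 330^2, 0.015)
  expect_false(seg$edge_touch)
  expect_equal(unname(seg$centroid), c(640, 640), tolerance = 0.01)

  # 2-D Gaussian spot: the 1/e level set of exp(-rho^2 / (2 s^2)) is the
  # circle rho = sqrt(2) s, area 2 pi s^2 (field wide enough that the
  # border frame sees no Gaussian tail)
  n <- 192; px <- 10; sg <- 150; c0 <- 960
  xs <- (seq_len(n) - 0.5) * px
  g <- outer(xs, xs, function(x, y) exp(-((x - c0)^2 + (y - c0)^2) / (2 * sg^2)))
  img <- nearfield_image(5 * g, g * 0, px)
  sgauss <- segment_vesicle(img, c(c0, c0))
  expect_rel(sgauss$area_A, 2 * pi * sg^2, 0.02)

  # scene built so that absolute 7.8 equals max/e exactly: identical masks
  r2 <- render_image(disc_scene(noise_sigma = 0))   # interior 7.8 e
  seg_f <- segment_vesicle(r2$image, c(640, 640))
  seg_a <- segment_vesicle(r2$image, c(640, 640),
                           criterion = list(type = "absolute", value = 7.8))
  expect_identical(seg_f$mask, seg_a$mask)
  expect_equal(seg_f$area_A, seg_a$area_A, tolerance = 1e-9)

  # empty segmentation
  dark <- nearfield_image(matrix(0, 64, 64), matrix(0, 64, 64), 10)
  expect_error(segment_vesicle(dark, c(320, 320),
                               criterion = list(type = "absolute", value = 5)),
               "empty segmentation")
})

test_that("shape_metrics: disc scores ~1, square ~pi/4, perimeter oracle", {
  md <- shape_metrics(disc_mask(R = 50.3), pixel_size = 1)
  expect_equal(md$circularity, 1, tolerance = 0.02)
  expect_rel(md$perimeter_p, 2 * pi * 50.3, 0.01)

  ms <- shape_metrics(square_mask(40), pixel_size = 1)
  expect_rel(ms$circularity, pi / 4, 0.02)

  expect_error(shape_metrics(matrix(FALSE, 8, 8)), "zero pixels")
})

test_that("circularity is scale-invariant and bounded by 1 + delta_disc", {
  m <- disc_mask(R = 33.7)
  a <- shape_metrics(m, pixel_size = 1)
  b <- shape_metrics(m, pixel_size = 12.5)
  expect_equal(a$circularity, b$circularity, tolerance = 1e-12)
  expect_equal(b$area_A, a$area_A * 12.5^2, tolerance = 1e-9)

  set.seed(4)
  for (i in 1:8) {
    R <- stats::runif(1, 15, 45)
    k <- sample(2:5, 1)
    A <- stats::runif(1, 0, 0.2)
    xs <- seq_len(128) - 0.5
    m <- outer(xs, xs, function(x, y) {
      rho <- sqrt((x - 64)^2 + (y - 64)^2)
      th <- atan2(y - 64, x - 64)
      rho <= R * (1 + A * cos(k * th))
    })
    cm <- shape_metrics(m)$circularity
    expect_lte(cm, 1 + 0.02)
    expect_gt(cm, 0)
  }
})

test_that("segmentation is idempotent on the masked-and-padded crop", {
  r <- render_image(disc_scene(noise_sigma = 0))
  seg <- segment_vesicle(r$image, c(640, 640))
  idx <- which(seg$mask, arr.ind = TRUE)
  pad <- 20L
  ir <- range(idx[, 1]); jr <- range(idx[, 2])
  ii <- max(1, ir[1] - pad):min(nrow(seg$mask), ir[2] + pad)
  jj <- max(1, jr[1] - pad):min(ncol(seg$mask), jr[2] + pad)
  crop <- nearfield_image(r$image$amplitude[ii, jj], r$image$phase[ii, jj],
                          r$image$pixel_size)
  seed_crop <- (c(640, 640) / r$image$pixel_size - c(ii[1], jj[1]) + 1) *
    r$image$pixel_size
  seg2 <- segment_vesicle(crop, seed_crop)
  expect_equal(seg2$area_A, seg$area_A, tolerance = 1e-9)
  expect_equal(seg2$perimeter_p, seg$perimeter_p, tolerance = 1e-9)
  expect_equal(seg2$circularity, seg$circularity, tolerance = 1e-9)
})

test_that("area error on disc fixtures shrinks with observed order >= 1", {
  # same physical disc rasterized at decreasing pixel size; error averaged
  # over sub-pixel center shifts to tame discretization oscillation
  err_at <- function(h) {
    shifts <- c(0, 0.23, 0.41, 0.68)
    mean(vapply(shifts, function(s) {
      n <- round(1280 / h)
      xs <- (seq_len(n) - 0.5) * h
      m <- outer(xs, xs, function(x, y)
        (x - 640 - s * h)^2 + (y - 640)^2 <= 330^2)
      abs(shape_metrics(m, pixel_size = h)$area_A - pi * 330^2) / (pi * 330^2)
    }, numeric(1)))
  }
  e20 <- err_at(20); e10 <- err_at(10); e5 <- err_at(5)
  expect_lt(e10, e20)
  expect_lt(e5, e10)
  order_est <- log(e20 / e5) / log(4)
  expect_gte(order_est, 1)
})

test_that("profile_fwhm: exact Gaussian, vesicle recovery at SNR 10, error scaling", {
  # noiseless Gaussian with sigma = 75 nm -> FWHM = 2 sqrt(2 ln 2) * 75
  n <- 128; px <- 10
  xs <- (seq_len(n) - 0.5) * px
  sg <- 75
  g <- outer(xs, xs, function(x, y) 20 * exp(-((x - 640)^2) / (2 * sg^2)) + 5)
  img <- nearfield_image(g, g, px)
  # sample exactly at pixel centers so interpolation is exact
  pf <- profile_fwhm(img, c(305, 635, 975, 635), "phase", n_samples = 68)
  expect_equal(pf$fwhm, 2 * sqrt(2 * log(2)) * 75, tolerance = 1e-6)
  expect_lt(pf$fwhm_error, 1e-4)

  # apparent width 176 nm at SNR 10: recovered within 5%
  fw_true <- 176
  sg2 <- fw_true / (2 * sqrt(2 * log(2)))
  peak <- 10
  base <- outer(xs, xs, function(x, y)
    peak * exp(-((x - 640)^2 + (y - 640)^2) / (2 * sg2^2)))
  fw_rec <- with(list(), {
    set.seed(11)
    noisy <- base + matrix(stats::rnorm(n * n, 0, peak / 10), n, n)
    img2 <- nearfield_image(noisy, noisy, px)
    profile_fwhm(img2, c(340, 640, 940, 640), "phase")$fwhm
  })
  expect_rel(fw_rec, fw_true, 0.05)

  # doubling the noise raises the reported fwhm_error (Monte Carlo)
  err_at_noise <- function(sd_noise, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      noisy <- base + matrix(stats::rnorm(n * n, 0, sd_noise), n, n)
      img2 <- nearfield_image(noisy, noisy, px)
      profile_fwhm(img2, c(340, 640, 940, 640), "phase")$fwhm_error
    }, numeric(1)))
  }
  expect_gt(err_at_noise(peak / 5, 1:100), err_at_noise(peak / 10, 1:100))

  expect_error(profile_fwhm(img, c(300, 640, 330, 640)), "line length")
})

test_that("state_series: identical images give zero change; failures are flagged", {
  r <- render_image(disc_scene(noise_sigma = 0))
  ss <- state_series(list(r$image, r$image), c("465", "365"), c(640, 640))
  expect_equal(ss$transitions$delta_area_pct, 0, tolerance = 1e-12)
  expect_equal(ss$transitions$delta_circularity_pct, 0, tolerance = 1e-12)
  expect_equal(unname(ss$reversibility), c(0, 0))

  dark <- nearfield_image(matrix(0, 128, 128), matrix(0, 128, 128), 10)
  ss2 <- state_series(list(r$image, dark, r$image), c("465", "365", "465"),
                      c(640, 640),
                      criterion = list(type = "absolute", value = 5))
  expect_false(ss2$table$ok[2])
  expect_true(all(ss2$table$ok[c(1, 3)]))

  expect_error(state_series(list(r$image, r$image), c("465", "465"),
                            c(640, 640)), "alternate")
})

test_that("state_series recovers the generated area/circularity factors", {
  sc <- disc_scene(noise_sigma = 0, interior_amplitude = 20)
  rp <- render_state_pair(sc, area_factor = 1.10, circularity_factor = 0.92,
                          seed = 2)
  ss <- state_series(list(rp$image_trans, rp$image_cis), c("465", "365"),
                     c(640, 640))
  expect_equal(ss$transitions$delta_area_pct, 10, tolerance = 0.15)
  expect_equal(ss$transitions$delta_circularity_pct, -8, tolerance = 0.15)
})
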