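#' Fixed-position s2/phi2 signal trace
#'
#' @param time Sample times in s, strictly increasing, spacing ~ `t_p`.
#' @param s2 Second-harmonic amplitude (arb.units, optionally normalized to
#'   the surrounding D2O).
#' @param phi2 Second-harmonic phase in degrees.
#' @param illumination Character label per sample (e.g. "365"/"465"),
#'   piecewise constant.
#' @param t_p Sampling/integration time in s.
#' @return Object of class `signal_trace` (also a data frame).
#' @export
signal_trace <- function(time, s2, phi2, illumination, t_p) {
  stopifnot(length(time) == length(s2), length(time) == length(phi2),
            length(time) == length(illumination), t_p > 0)
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  out <- data.frame(time = time, s2 = s2, phi2 = phi2,
                    illumination = as.character(illumination))
  attr(out, "t_p") <- t_p
  class(out) <- c("signal_trace", "data.frame")
  out
}

#' Split a trace into constant-illumination epochs
#'
#' One epoch per maximal run of a constant illumination label. Each epoch's
#' local time origin is the switch instant (the boundary between the last
#' sample of the previous run and the first of this one); the original
#' absolute times are kept in column `time`.
#'
#' @param trace A [signal_trace()].
#' @return List of `signal_trace` objects; each has attributes
#'   `epoch_start` (absolute switch time, s) and `local_time` column `t`.
#' @export
split_epochs <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  lab <- trace$illumination
  drop <- is.na(lab) | lab == ""
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) with empty illumination label",
                    sum(drop)))
    trace <- trace[!drop, ]
    lab <- trace$illumination
  }
  r <- rle(lab)
  if (length(r$lengths) == 1)
    warning("trace has a single illumination label; returning one epoch")
  ends <- cumsum(r$lengths)
  starts_idx <- c(1, utils::head(ends, -1) + 1)
  tp <- attr(trace, "t_p")
  out <- vector("list", length(r$lengths))
  for (k in seq_along(r$lengths)) {
    idx <- starts_idx[k]:ends[k]
    # switch instant: midpoint between runs (start of recording for the first)
    t0 <- if (k == 1) trace$time[1] - tp / 2
          else (trace$time[starts_idx[k]] + trace$time[ends[k - 1]]) / 2
    ep <- trace[idx, ]
    ep$t <- ep$time - t0
    attr(ep, "t_p") <- tp
    attr(ep, "epoch_start") <- t0
    attr(ep, "label") <- r$values[k]
    class(ep) <- c("signal_trace", "data.frame")
    out[[k]] <- ep
  }
  out
}

#' Centered moving average of a trace
#'
#' Boxcar mean per channel with an odd window; near the edges the window
#' shrinks symmetrically. The window is recorded as an attribute.
#'
#' @param trace A [signal_trace()].
#' @param window_samples Odd integer >= 1.
#' @return Smoothed `signal_trace` with attribute `ma_window`.
#' @export
moving_average <- function(trace, window_samples) {
  stopifnot(inherits(trace, "signal_trace"))
  w <- as.integer(window_samples)
  if (w < 1 || w %% 2 == 0) stop("window_samples must be odd and >= 1")
  n <- nrow(trace)
  if (w > n) stop("window longer than trace")
  k <- (w - 1L) %/% 2L
  smooth1 <- function(x) {
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(i - k, 1L); hi <- pmin(i + k, n)
    # shrink symmetrically at the edges
    half <- pmin(i - lo, hi - i)
    lo <- i - half; hi <- i + half
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out <- trace
  out$s2 <- smooth1(trace$s2)
  out$phi2 <- smooth1(trace$phi2)
  attr(out, "ma_window") <- w
  out
}

# sigmoid model and analytic Jacobian; par = (L, t_d, tau, C)
sigmoid_f <- function(par, t) {
  s <- 1 / (1 + exp(-(t - par[2]) / par[3]))
  par[4] + par[1] * s
}
sigmoid_jac <- function(par, t) {
  s <- 1 / (1 + exp(-(t - par[2]) / par[3]))
  d <- s * (1 - s)
  cbind(L = s,
        t_d = -par[1] * d / par[3],
        tau = -par[1] * d * (t - par[2]) / par[3]^2,
        C = 1)
}

#' Fit the delayed-sigmoid switching model to one epoch
#'
#' Nonlinear least squares of \eqn{f(t) = C + L/(1 + e^{-(t - t_d)/\tau})}
#' on the epoch-local time axis, sign of L free. Initialization: C = mean of
#' the first quartile of samples, L = mean of the last quartile minus C,
#' t_d = first crossing of a 5-sample moving average through C + L/2,
#' tau = (time from the 25% to the 75% crossing) / ln 9; multi-start over
#' tau scalings 1/3, 1, 3 if the first attempt does not converge. Fitted
#' values are reported as-is: when tau is comparable to the sampling time
#' t_p, the boxcar acquisition biases tau upward (the true dynamics are
#' faster); no deconvolution is attempted.
#'
#' @param epoch_trace One element of [split_epochs()] (needs column `t`),
#'   or any `signal_trace` (then `t = time`).
#' @param channel `"s2"` or `"phi2"`.
#' @return Object of class `epoch_fit`: `L`, `t_d`, `tau`, `C`, standard
#'   errors, `covariance`, `rmse`, `converged`, plus the channel and t_p.
#' @export
fit_sigmoid <- function(epoch_trace, channel = c("s2", "phi2")) {
  channel <- match.arg(channel)
  stopifnot(inherits(epoch_trace, "signal_trace"))
  t <- if (!is.null(epoch_trace$t)) epoch_trace$t else epoch_trace$time
  y <- epoch_trace[[channel]]
  if (length(t) < 10) stop("need at least 10 samples to fit")
  tp <- attr(epoch_trace, "t_p")
  if (is.null(tp)) tp <- stats::median(diff(t))
  n <- length(y)
  q <- max(2L, floor(n / 4))
  C0 <- mean(y[seq_len(q)])
  L0 <- mean(y[seq(n - q + 1, n)]) - C0
  if (L0 == 0) L0 <- stats::sd(y) + 1e-12
  w <- min(5L, if (n %% 2 == 0) n - 1 else n)
  ym <- {
    tr <- epoch_trace
    if (is.null(tr$t)) tr$t <- t
    ma <- moving_average(tr, w)
    ma[[channel]]
  }
  crossing <- function(level) {
    s <- sign(L0) * (ym - level)
    for (i in seq_len(n - 1))
      if (s[i] < 0 && s[i + 1] >= 0) {
        f <- if (s[i + 1] == s[i]) 0 else -s[i] / (s[i + 1] - s[i])
        return(t[i] + f * (t[i + 1] - t[i]))
      }
    NA_real_
  }
  td0 <- crossing(C0 + L0 / 2)
  if (is.na(td0)) td0 <- t[which.min(abs(ym - (C0 + L0 / 2)))]
  t25 <- crossing(C0 + 0.25 * L0)
  t75 <- crossing(C0 + 0.75 * L0)
  tau0 <- if (!is.na(t25) && !is.na(t75) && t75 > t25)
    (t75 - t25) / log(9) else max(tp, (max(t) - min(t)) / 20)
  lower <- c(-Inf, min(t), max(1e-4 * (max(t) - min(t)), 1e-6), -Inf)
  upper <- c(Inf, max(t), (max(t) - min(t)), Inf)
  best <- NULL
  for (scal in c(1, 1 / 3, 3)) {
    fit <- lm_nls(function(p) y - sigmoid_f(p, t),
                  function(p) -sigmoid_jac(p, t),
                  c(L = L0, t_d = td0, tau = tau0 * scal, C = C0),
                  lower = lower, upper = upper)
    if (is.null(best) || sum(fit$residual^2) < sum(best$residual^2))
      best <- fit
    if (fit$converged) { best <- fit; break }
  }
  if (!best$converged)
    stop(sprintf("sigmoid fit did not converge (best rmse %.4g, init t_d=%.3g tau=%.3g)",
                 best$rmse, td0, tau0))
  se <- sqrt(pmax(diag(best$cov), 0))
  structure(list(L = best$par[["L"]], t_d = best$par[["t_d"]],
                 tau = best$par[["tau"]], C = best$par[["C"]],
                 se = se, covariance = best$cov, rmse = best$rmse,
                 converged = best$converged, channel = channel, t_p = tp),
            class = "epoch_fit")
}

#' @export
print.epoch_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit (%s): L = %.4g, t_d = %.3g s, tau = %.3g s, C = %.4g (rmse %.3g)\n",
              x$channel, x$L, x$t_d, x$tau, x$C, x$rmse))
  if (x$tau < 2 * x$t_p)
    cat(sprintf("  note: tau < 2 t_p (%.3g s); value is convolved with the sampling window\n",
                x$t_p))
  invisible(x)
}

#' Plateau step statistics around a switching transition
#'
#' Pre/post plateau means and standard deviations are computed outside a
#' guard interval around the transition. Reported per channel:
#' the relative amplitude change in percent (relative to the pre mean), the
#' absolute phase change in degrees, the step signal-to-noise ratio
#' SNR = |step| / pooled per-sample sd, and the two-sample significance
#' \eqn{z = |\mu_{post} - \mu_{pre}| / \sqrt{s_{pre}^2/n_{pre} +
#' s_{post}^2/n_{post}}}. SNR and z are distinct conventions of this
#' package (the underlying study prints both kinds of number without
#' defining them).
#'
#' @param trace A [signal_trace()] (column `t` used if present).
#' @param transition_time Transition time on the trace's time axis.
#' @param guard_interval Half-width of the excluded interval around the
#'   transition, s.
#' @return Object of class `step_stats` with per-channel fields.
#' @export
step_stats <- function(trace, transition_time, guard_interval) {
  stopifnot(inherits(trace, "signal_trace"), guard_interval >= 0)
  t <- if (!is.null(trace$t)) trace$t else trace$time
  pre <- t < transition_time - guard_interval
  post <- t > transition_time + guard_interval
  if (sum(pre) < 5 || sum(post) < 5)
    stop("need at least 5 plateau samples on each side of the guard interval")
  one <- function(x) {
    m1 <- mean(x[pre]); m2 <- mean(x[post])
    s1 <- stats::sd(x[pre]); s2 <- stats::sd(x[post])
    n1 <- sum(pre); n2 <- sum(post)
    pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    list(mu_pre = m1, mu_post = m2, delta = m2 - m1,
         snr = if (pooled > 0) abs(m2 - m1) / pooled else Inf,
         z = {
           den <- sqrt(s1^2 / n1 + s2^2 / n2)
           if (den > 0) abs(m2 - m1) / den else Inf
         },
         sd_pre = s1, sd_post = s2, n_pre = n1, n_post = n2)
  }
  a <- one(trace$s2); p <- one(trace$phi2)
  structure(list(
    delta_amplitude_pct = 100 * a$delta / a$mu_pre,
    delta_amplitude = a$delta,
    delta_phase_deg = p$delta,
    snr_amplitude = a$snr, snr_phase = p$snr,
    significance_z_amplitude = a$z, significance_z_phase = p$z,
    noise_sigma_amplitude = sqrt((a$sd_pre^2 + a$sd_post^2) / 2),
    noise_sigma_phase = sqrt((p$sd_pre^2 + p$sd_post^2) / 2),
    n_pre = a$n_pre, n_post = a$n_post,
    amplitude = a, phase = p),
    class = "step_stats")
}

#' @export
print.step_stats <- function(x, ...) {
  cat(sprintf("Step: amplitude %+.2f%% (SNR %.2f, %.2f sigma), phase %+.2f deg (SNR %.2f, %.2f sigma); n = %d/%d\n",
              x$delta_amplitude_pct, x$snr_amplitude,
              x$significance_z_amplitude, x$delta_phase_deg, x$snr_phase,
              x$significance_z_phase, x$n_pre, x$n_post))
  invisible(x)
}

#' Detection power versus sampling time
#'
#' Monte-Carlo study of step detectability as a function of the sampling
#' time t_p. Per-sample noise scales as \eqn{\sigma \propto 1/\sqrt{t_p}}
#' (integration averaging), calibrated so the per-sample step SNR equals
#' `snr_ref` at `t_p_ref`. Each simulated trace has a fixed number of
#' plateau samples on each side of an instantaneous step (so the plateau
#' duration grows with t_p and the significance grows like
#' \eqn{\sqrt{t_p}}); [step_stats()] supplies the per-trace statistics.
#'
#' @param step Step size in the amplitude channel (signed; relative units).
#' @param t_p_grid Sampling times in s.
#' @param n_seeds Number of Monte-Carlo repetitions per t_p.
#' @param snr_ref,t_p_ref Noise calibration: per-sample SNR at the
#'   reference sampling time (defaults 4 at 30 ms, the reported operating
#'   point).
#' @param n_plateau Plateau samples per side.
#' @param z_threshold Detection threshold in sigma units. Default 3.
#' @param seed Base seed; repetition i uses `seed + i`.
#' @return Data frame with columns `t_p`, `mean_snr`, `mean_z`,
#'   `detection_rate`.
#' @export
detection_power_study <- function(step = -0.08, t_p_grid = c(0.03, 0.1, 0.5),
                                  n_seeds = 500, snr_ref = 4, t_p_ref = 0.03,
                                  n_plateau = 100, z_threshold = 3,
                                  seed = 1L) {
  stopifnot(all(t_p_grid > 0), n_seeds >= 1, n_plateau >= 5)
  baseline <- 1
  out <- lapply(t_p_grid, function(tp) {
    sigma <- abs(step) / snr_ref * sqrt(t_p_ref / tp)
    snrs <- numeric(n_seeds); zs <- numeric(n_seeds)
    for (i in seq_len(n_seeds)) {
      st <- with_seed(seed + i, {
        n <- 2L * n_plateau
        tt <- (seq_len(n) - 0.5) * tp
        mid <- n_plateau * tp
        y <- baseline + ifelse(tt > mid, step, 0) +
          stats::rnorm(n, 0, sigma)
        tr <- signal_trace(tt, y, rep(0, n),
                           rep(c("465", "365"), each = n_plateau), tp)
        step_stats(tr, mid, guard_interval = 0)
      })
      snrs[i] <- st$snr_amplitude
      zs[i] <- st$significance_z_amplitude
    }
    data.frame(t_p = tp, mean_snr = mean(snrs), mean_z = mean(zs),
               detection_rate = mean(zs >= z_threshold))
  })
  do.call(rbind, out)
}
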