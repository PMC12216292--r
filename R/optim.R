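# Small dense Levenberg-Marquardt least-squares solver with analytic
# Jacobian and box constraints (projection). Used for the sigmoid and
# Gaussian fits: unlike stats::nls it converges cleanly on zero-noise data
# and lets us tighten parameters to machine precision, which the
# equivariance invariants require.
#
# resid_fn(par) -> residual vector; jac_fn(par) -> d(resid)/d(par) matrix.
lm_nls <- function(resid_fn, jac_fn, par0, lower = NULL, upper = NULL,
                   max_iter = 200, ftol = 1e-14, ptol = 1e-12) {
  p <- as.numeric(par0)
  nm <- names(par0)
  if (is.null(lower)) lower <- rep(-Inf, length(p))
  if (is.null(upper)) upper <- rep(Inf, length(p))
  clip <- function(x) pmin(pmax(x, lower), upper)
  p <- clip(p)
  r <- resid_fn(p)
  cost <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- jac_fn(p)
    g <- crossprod(J, r)
    A <- crossprod(J)
    dscale <- pmax(diag(A), 1e-12)
    ok_step <- FALSE
    for (trial in 1:30) {
      Ad <- A + lambda * diag(dscale, nrow(A))
      step <- tryCatch(-solve(Ad, g), error = function(e) NULL)
      if (!is.null(step)) {
        pn <- clip(p + as.numeric(step))
        rn <- resid_fn(pn)
        costn <- sum(rn^2)
        if (is.finite(costn) && costn <= cost) {
          rel_f <- (cost - costn) / max(cost, 1e-300)
          rel_p <- max(abs(pn - p) / pmax(abs(p), 1e-12))
          p <- pn; r <- rn; cost <- costn
          lambda <- max(lambda / 4, 1e-12)
          ok_step <- TRUE
          if (rel_f < ftol || rel_p < ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 8
    }
    if (!ok_step) {
      # no descent direction left: at a stationary point if gradient ~ 0
      converged <- max(abs(g)) <= 1e-8 * max(1, sqrt(cost)) || cost < 1e-20
      break
    }
    if (converged) break
  }
  names(p) <- nm
  J <- jac_fn(p)
  dof <- max(1L, length(r) - length(p))
  s2 <- sum(r^2) / dof
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) {
    matrix(NA_real_, length(p), length(p))
  })
  dimnames(cov) <- list(nm, nm)
  list(par = p, cov = cov, rmse = sqrt(mean(r^2)), residual = r,
       converged = converged || sum(r^2) < 1e-18, iterations = it)
}
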