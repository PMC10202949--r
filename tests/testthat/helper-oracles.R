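# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Fixed-step classical Runge-Kutta integration of the two-site exchange
# model with a boxcar input. Returns a matrix with columns P, L, U on the
# grid seq(0, t_end, by = dt).
rk4_two_site <- function(kPL, R1_pyr, R1_lac, R1_urea, amp_p, amp_u,
                         t_on, t_off, lambda_rf, t_end, dt, kLP = 0) {
  deriv <- function(t, y) {
    u <- if (t >= t_on && t < t_off) 1 else 0
    c(u * amp_p - (R1_pyr + lambda_rf + kPL) * y[1] + kLP * y[2],
      kPL * y[1] - (R1_lac + lambda_rf + kLP) * y[2],
      u * amp_u - (R1_urea + lambda_rf) * y[3])
  }
  tt <- seq(0, t_end, by = dt)
  out <- matrix(0, length(tt), 3, dimnames = list(NULL, c("P", "L", "U")))
  y <- c(0, 0, 0)
  for (i in seq_along(tt)[-1]) {
    t <- tt[i - 1]
    k1 <- deriv(t, y)
    k2 <- deriv(t + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i, ] <- y
  }
  out
}

# Literal enumeration of the two-stage step-up FDR procedure: stage one is
# a step-up pass at q/(1+q); stage two re-runs the step-up at level
# q/(1+q) * m/m0 with m0 estimated from stage one.
bky_oracle <- function(p, q) {
  m <- length(p)
  qp <- q / (1 + q)
  step_up <- function(pv, alpha) {
    o <- order(pv)
    ps <- pv[o]
    k <- 0
    for (i in m:1) {
      if (ps[i] <= i * alpha / m) { k <- i; break }
    }
    rej <- rep(FALSE, m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  r1 <- sum(step_up(p, qp))
  if (r1 == 0) return(rep(FALSE, m))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  step_up(p, qp * m / m0)
}

# Closed-form Pearson correlation between kPL = k0 * exp(lam * B) and a
# marker M = c + d * B + eps, with B ~ N(mu, s2) and eps ~ N(0, e2):
# cov = d * lam * s2 * E[exp(lam B)]; var(kPL) from the lognormal moments.
corr_lognormal_linear <- function(lam, s, d, e) {
  s2 <- s^2
  Eexp <- exp(lam^2 * s2 / 2)           # up to the exp(lam*mu) factor
  cov <- d * lam * s2 * Eexp
  vx <- exp(lam^2 * s2) * (exp(lam^2 * s2) - 1)
  vy <- d^2 * s2 + e^2
  cov / sqrt(vx * vy)
}

# Small helpers shared by the pipeline tests
frame_midpoints <- function(acq) (seq_len(acq$n_frames) - 0.5) *
  acq$frame_interval

three_peak_spectrum <- function(acq, res, amps, gammas, baseline = 0) {
  f <- spectrum_frequencies(acq)
  ctr <- ppm_to_offset_hz(res$ppm, acq)
  y <- rep(baseline, length(f))
  for (i in seq_along(amps)) y <- y + lorentzian(f, ctr[i], gammas[i], amps[i])
  y
}
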