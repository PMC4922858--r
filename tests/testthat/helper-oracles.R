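# Independent oracle implementations used to cross-check the package's
# density, sampling and simulation code.  These deliberately re-derive each
# quantity with different code paths (term-by-term formulas, quadrature,
# brute-force Monte Carlo) and must stay independent of the package
# internals.

# term-by-term censored mixture density, written directly from the printed
# normalization: [sum_i A_i (e^{-tm/ti} - e^{-tmax/ti})]^{-1} * sum_i (A_i/ti) e^{-t/ti}
oracle_mix_pdf <- function(t, A, tau, t_m, t_max) {
  norm <- 0
  for (i in seq_along(tau))
    norm <- norm + A[i] * (exp(-t_m / tau[i]) - exp(-t_max / tau[i]))
  val <- 0
  for (i in seq_along(tau))
    val <- val + (A[i] / tau[i]) * exp(-t / tau[i])
  val / norm
}

# convolution-of-two-exponentials density truncated to the window, obtained
# by numerical normalization of the raw convolution integrand
oracle_conv_pdf <- function(t, tau1, tau2, t_m, t_max) {
  raw <- function(u) {
    if (abs(tau1 - tau2) < 1e-12 * tau2) u * exp(-u / tau1)
    else exp(-u / max(tau1, tau2)) - exp(-u / min(tau1, tau2))
  }
  Z <- stats::integrate(Vectorize(raw), t_m, t_max, rel.tol = 1e-12)$value
  vapply(t, raw, numeric(1)) / Z
}

# quadrature CDF of any density function over [t_m, t]
oracle_cdf <- function(pdf_fun, t, t_m) {
  vapply(t, function(u)
    stats::integrate(pdf_fun, t_m, u, rel.tol = 1e-10)$value, numeric(1))
}

# brute-force Monte Carlo sampler for a single exponential arrival process
oracle_exp_arrivals <- function(n, rate, t_max, seed) {
  set.seed(seed)
  x <- stats::rexp(n, rate)
  x[x < t_max]
}

# direct sampler from the censored single-exponential law (inverse CDF),
# independent of sample_dwells
oracle_censored_exp <- function(n, tau, t_m, t_max, seed) {
  set.seed(seed)
  u <- stats::runif(n)
  lo <- exp(-t_m / tau); hi <- exp(-t_max / tau)
  -tau * log(lo - u * (lo - hi))
}

# noiseless trace for a set of bound intervals (frame-midpoint convention),
# independent of render_traces
oracle_trace <- function(intervals, frame_duration, frame_spacing, t_max,
                         baseline, amplitude) {
  n <- floor((t_max - frame_duration) / frame_spacing) + 1
  fs <- (seq_len(n) - 1) * frame_spacing
  occ <- numeric(n)
  for (r in seq_len(nrow(intervals))) {
    ov <- pmax(0, pmin(intervals$t1[r], fs + frame_duration) -
                  pmax(intervals$t0[r], fs)) / frame_duration
    occ <- occ + ov
  }
  baseline + amplitude * occ
}
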