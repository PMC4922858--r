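#' Censored exponential-mixture dwell-time model
#'
#' Constructs a dwell-time density model consisting of a mixture of 1--3
#' exponential components, renormalized over the observable window
#' \eqn{[t_m, t_{max}]}.  Dwell times shorter than the minimum detectable
#' dwell \code{t_m} (set by the frame spacing) or longer than the recording
#' length \code{t_max} cannot be observed, so the density conditions on
#' observation within the window:
#' \deqn{f(t) = \frac{\sum_i (A_i/\tau_i) e^{-t/\tau_i}}
#'                   {\sum_i A_i (e^{-t_m/\tau_i} - e^{-t_{max}/\tau_i})},
#'       \quad t \in [t_m, t_{max}].}
#'
#' @param tau numeric vector of 1--3 time constants (seconds), all positive.
#' @param A mixture amplitudes; a vector of the same length as \code{tau}
#'   summing to 1 (a single component may omit it).  Components are stored in
#'   ascending order of \code{tau}.
#' @param t_m minimum detectable dwell time (s).
#' @param t_max recording duration (s); must exceed \code{t_m}.
#' @return an object of class \code{"mixture_model"}.
#' @seealso [convolution_model()], [ddwell()], [sample_dwells()]
#' @examples
#' m <- mixture_model(tau = c(52, 780), A = c(0.5, 0.5), t_m = 3, t_max = 3600)
#' integrate(ddwell, 3, 3600, model = m)  # unit mass over the window
#' @export
mixture_model <- function(tau, A = NULL, t_m = 3, t_max = 3600) {
  tau <- as.numeric(tau)
  k <- length(tau)
  if (k < 1L || k > 3L) stop("mixture_model supports 1 to 3 components")
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("time constants must be positive")
  if (is.null(A)) A <- rep(1 / k, k)
  A <- as.numeric(A)
  if (length(A) != k) stop("length(A) must equal length(tau)")
  if (any(A < 0) || any(A > 1) || abs(sum(A) - 1) > 1e-8)
    stop("amplitudes must lie in [0,1] and sum to 1")
  if (!is.finite(t_m) || t_m < 0 || t_m >= t_max) stop("require 0 <= t_m < t_max")
  ord <- order(tau)
  structure(list(tau = tau[ord], A = A[ord], t_m = t_m, t_max = t_max),
            class = c("mixture_model", "dwell_model"))
}

#' Censored two-step convolution dwell-time model
#'
#' Waiting-time density for two sequential exponential steps with time
#' constants \code{tau1} and \code{tau2}, renormalized over the observable
#' window \eqn{[t_m, t_{max}]}:
#' \deqn{f(t) = \frac{e^{-t/\tau_1} - e^{-t/\tau_2}}
#'   {\tau_1(e^{-t_m/\tau_1} - e^{-t_{max}/\tau_1}) -
#'    \tau_2(e^{-t_m/\tau_2} - e^{-t_{max}/\tau_2})}.}
#' The normalizer is the exact window mass of the convolution, so the density
#' integrates to 1 over the window by construction.  The \eqn{\tau_1 = \tau_2}
#' case is handled by the Erlang-2 limit \eqn{t e^{-t/\tau}/\tau^2}
#' (renormalized), reached continuously.
#'
#' @param tau1,tau2 time constants of the two steps (s); order is immaterial.
#' @inheritParams mixture_model
#' @return an object of class \code{"convolution_model"}.
#' @export
convolution_model <- function(tau1, tau2, t_m = 3, t_max = 3600) {
  if (!is.finite(tau1) || !is.finite(tau2) || tau1 <= 0 || tau2 <= 0)
    stop("time constants must be positive")
  if (!is.finite(t_m) || t_m < 0 || t_m >= t_max) stop("require 0 <= t_m < t_max")
  structure(list(tau = sort(c(tau1, tau2)), t_m = t_m, t_max = t_max),
            class = c("convolution_model", "dwell_model"))
}

# window mass of one exponential component: integral of e^{-t/tau}/tau
.exp_window_mass <- function(tau, t_m, t_max) {
  exp(-t_m / tau) - exp(-t_max / tau)
}

# relative closeness at which the convolution switches to the Erlang branch
.CONV_EQ_TOL <- 1e-9

#' Dwell-time density, distribution and sampling
#'
#' \code{ddwell} evaluates the censored dwell-time density of a
#' \code{mixture_model} or \code{convolution_model} at times \code{t};
#' \code{pdwell} evaluates the corresponding CDF (mass accumulated from
#' \code{t_m}); \code{sample_dwells} draws from the model.  Outside the
#' censoring window the density is 0 (with a warning from \code{ddwell}).
#'
#' @param t vector of times (s).
#' @param model a \code{mixture_model} or \code{convolution_model}.
#' @return \code{ddwell}/\code{pdwell}: numeric vector along \code{t}.
#' @export
ddwell <- function(t, model) UseMethod("ddwell", model)

#' @export
ddwell.mixture_model <- function(t, model) {
  out <- numeric(length(t))
  inside <- t >= model$t_m & t <= model$t_max
  if (any(!inside & is.finite(t)))
    warning("density evaluated outside [t_m, t_max]; returning 0 there")
  Z <- sum(model$A * .exp_window_mass(model$tau, model$t_m, model$t_max))
  ti <- t[inside]
  num <- 0
  for (i in seq_along(model$tau))
    num <- num + model$A[i] / model$tau[i] * exp(-ti / model$tau[i])
  out[inside] <- num / Z
  out
}

#' @export
ddwell.convolution_model <- function(t, model) {
  out <- numeric(length(t))
  inside <- t >= model$t_m & t <= model$t_max
  if (any(!inside & is.finite(t)))
    warning("density evaluated outside [t_m, t_max]; returning 0 there")
  tau1 <- model$tau[1]; tau2 <- model$tau[2]
  ti <- t[inside]
  if (abs(tau1 - tau2) <= .CONV_EQ_TOL * tau2) {
    tau <- tau2
    # Erlang-2 numerator t e^{-t/tau}; window mass by closed form
    Z <- tau * ((1 + model$t_m / tau) * exp(-model$t_m / tau) -
                (1 + model$t_max / tau) * exp(-model$t_max / tau))
    out[inside] <- ti * exp(-ti / tau) / (tau * Z)
    return(out)
  }
  # expm1-stable difference of exponentials (tau2 > tau1 after sorting)
  d <- 1 / tau1 - 1 / tau2
  num <- exp(-ti / tau2) * (-expm1(-ti * d))          # e^{-t/tau2} - e^{-t/tau1}
  Z <- tau2 * .exp_window_mass(tau2, model$t_m, model$t_max) -
       tau1 * .exp_window_mass(tau1, model$t_m, model$t_max)
  out[inside] <- num / Z
  out
}

#' @rdname ddwell
#' @export
pdwell <- function(t, model) UseMethod("pdwell", model)

#' @export
pdwell.mixture_model <- function(t, model) {
  t <- pmin(pmax(t, model$t_m), model$t_max)
  Z <- sum(model$A * .exp_window_mass(model$tau, model$t_m, model$t_max))
  acc <- 0
  for (i in seq_along(model$tau))
    acc <- acc + model$A[i] *
      (exp(-model$t_m / model$tau[i]) - exp(-t / model$tau[i]))
  acc / Z
}

#' @export
pdwell.convolution_model <- function(t, model) {
  t <- pmin(pmax(t, model$t_m), model$t_max)
  tau1 <- model$tau[1]; tau2 <- model$tau[2]
  if (abs(tau1 - tau2) <= .CONV_EQ_TOL * tau2) {
    tau <- tau2
    mass <- function(a, b) (1 + a / tau) * exp(-a / tau) -
                           (1 + b / tau) * exp(-b / tau)
    return(mass(model$t_m, t) / mass(model$t_m, model$t_max))
  }
  mass <- function(a, b) {
    tau2 * (exp(-a / tau2) - exp(-b / tau2)) -
    tau1 * (exp(-a / tau1) - exp(-b / tau1))
  }
  mass(model$t_m, t) / mass(model$t_m, model$t_max)
}

#' @param n number of dwell times to draw.
#' @param seed optional integer seed; when given, sampling is reproducible.
#' @return \code{sample_dwells}: numeric vector of \code{n} dwell times in
#'   \eqn{[t_m, t_{max}]}.
#' @rdname ddwell
#' @examples
#' m <- mixture_model(tau = 617, t_m = 3, t_max = 3600)
#' x <- sample_dwells(m, 500, seed = 1)
#' @export
sample_dwells <- function(model, n, seed = NULL) UseMethod("sample_dwells", model)

#' @export
sample_dwells.mixture_model <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- model$A * .exp_window_mass(model$tau, model$t_m, model$t_max)
  comp <- sample.int(length(model$tau), n, replace = TRUE, prob = w)
  tau <- model$tau[comp]
  lo <- exp(-model$t_m / tau)
  hi <- exp(-model$t_max / tau)
  u <- stats::runif(n)
  # inverse-CDF draw from each component's window-truncated exponential
  -tau * log(lo - u * (lo - hi))
}

#' @export
sample_dwells.convolution_model <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tau1 <- model$tau[1]; tau2 <- model$tau[2]
  out <- numeric(0)
  # rejection from the untruncated two-step sum; window acceptance is the
  # convolution's window mass, well away from 0 for realistic parameters
  for (it in 1:10000) {
    need <- n - length(out)
    if (need <= 0) break
    m <- max(need * 2L, 32L)
    cand <- stats::rexp(m, 1 / tau1) + stats::rexp(m, 1 / tau2)
    cand <- cand[cand >= model$t_m & cand <= model$t_max]
    out <- c(out, cand)
  }
  if (length(out) < n)
    stop("rejection sampling failed; window mass too small for these parameters")
  out[seq_len(n)]
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Censored exponential mixture (k = %d) on [%g, %g] s\n",
              length(x$tau), x$t_m, x$t_max))
  cat("  tau:", paste(signif(x$tau, 4), collapse = ", "), "s\n")
  cat("  A:  ", paste(signif(x$A, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.convolution_model <- function(x, ...) {
  cat(sprintf("Censored two-step convolution on [%g, %g] s\n", x$t_m, x$t_max))
  cat("  tau:", paste(signif(x$tau, 4), collapse = ", "), "s\n")
  invisible(x)
}
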