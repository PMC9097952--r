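#' Arterial input function models
#'
#' Construct an arterial plasma activity model \eqn{C_p(t)} for FDG.
#' Three model families are supported:
#' \describe{
#'   \item{`feng4`}{the classic four-parameter Feng bolus form
#'     \eqn{C_p(u) = (A_1 u - A_2 - A_3) e^{-\lambda_1 u} + A_2 e^{-\lambda_2 u}
#'     + A_3 e^{-\lambda_3 u}} with \eqn{u = t - t_{peak\_offset}} and
#'     \eqn{C_p = 0} before tracer arrival. It rises sharply to an early peak
#'     and decays with a slow late washout, and admits closed-form integrals
#'     and convolutions.}
#'   \item{`tri_exponential`}{a sum of three decaying exponentials
#'     \eqn{\sum_j A_j e^{-\lambda_j t}} (an idealized instantaneously mixed
#'     bolus; non-zero at \eqn{t = 0}).}
#'   \item{`tabulated`}{a sampled curve interpolated linearly; integrals use
#'     the trapezoid rule over the tabulated support.}
#' }
#'
#' Default `feng4` coefficients are representative of an adult FDG bolus with
#' activities in kBq/ml and rate constants in 1/min.
#'
#' @param model one of `"feng4"`, `"tri_exponential"`, `"tabulated"`.
#' @param amplitudes numeric amplitudes, kBq/ml (for `feng4`, `A1` is in
#'   kBq/ml/min); length 3.
#' @param rates positive rate constants, 1/min; length 3.
#' @param t_peak_offset tracer arrival delay in minutes (`feng4` only):
#'   the curve is identically zero before this time.
#' @param times,values sample times (min) and activities (kBq/ml) for
#'   `model = "tabulated"`.
#' @return an object of class `input_function`.
#' @examples
#' f <- input_function("feng4")
#' evaluate_input(f, c(0, 1, 5, 60))
#' @export
input_function <- function(model = c("feng4", "tri_exponential", "tabulated"),
                           amplitudes = NULL, rates = NULL,
                           t_peak_offset = 0.4,
                           times = NULL, values = NULL) {
  model <- match.arg(model)
  if (model == "tabulated") {
    stopifnot(is.numeric(times), is.numeric(values),
              length(times) == length(values), length(times) >= 2)
    if (is.unsorted(times, strictly = TRUE)) stop("tabulated times must be strictly increasing")
    if (any(values < 0)) stop("tabulated activities must be non-negative")
    obj <- list(model_id = model, times = as.numeric(times),
                values = as.numeric(values), delay = 0, terms = NULL,
                coefficients = NULL)
    class(obj) <- "input_function"
    return(obj)
  }
  if (is.null(amplitudes)) {
    amplitudes <- if (model == "feng4") c(851.1, 21.88, 20.81) else c(60, 15, 8)
  }
  if (is.null(rates)) {
    rates <- if (model == "feng4") c(4.1339, 0.01043, 0.1191) else c(2.5, 0.012, 0.12)
  }
  stopifnot(length(amplitudes) == 3, length(rates) == 3)
  if (any(!is.finite(amplitudes)) || any(!is.finite(rates))) {
    stop("input-function coefficients must be finite")
  }
  if (any(rates <= 0)) stop("rate constants must be positive")
  if (model == "feng4") {
    if (any(amplitudes < 0)) stop("feng4 amplitudes must be non-negative")
    if (t_peak_offset < 0) stop("t_peak_offset must be non-negative")
    terms <- es_new(
      a = c(amplitudes[1], -(amplitudes[2] + amplitudes[3]), amplitudes[2], amplitudes[3]),
      l = c(rates[1], rates[1], rates[2], rates[3]),
      p = c(1L, 0L, 0L, 0L))
    delay <- t_peak_offset
  } else {
    if (any(amplitudes < 0)) stop("tri_exponential amplitudes must be non-negative")
    terms <- es_new(a = amplitudes, l = rates, p = c(0L, 0L, 0L))
    delay <- 0
  }
  obj <- list(model_id = model,
              coefficients = list(amplitudes = amplitudes, rates = rates),
              delay = delay, terms = es_compact(terms))
  class(obj) <- "input_function"
  obj
}

#' @export
print.input_function <- function(x, ...) {
  cat("<input_function>", x$model_id, "\n")
  if (x$model_id == "tabulated") {
    cat("  ", length(x$times), "samples on [",
        min(x$times), ",", max(x$times), "] min\n")
  } else {
    cat("  amplitudes:", signif(x$coefficients$amplitudes, 4), "kBq/ml\n")
    cat("  rates:     ", signif(x$coefficients$rates, 4), "1/min\n")
    if (x$delay > 0) cat("  arrival delay:", x$delay, "min\n")
  }
  invisible(x)
}

#' Evaluate an input function
#'
#' Plasma activity \eqn{C_p(t)} in kBq/ml at times `t` (minutes).
#'
#' @param f an [input_function()].
#' @param t non-negative times in minutes.
#' @return numeric vector of activities, kBq/ml.
#' @export
evaluate_input <- function(f, t) {
  stopifnot(inherits(f, "input_function"), is.numeric(t))
  if (any(t < 0)) stop("times must be non-negative")
  if (f$model_id == "tabulated") {
    if (any(t < min(f$times)) || any(t > max(f$times))) {
      stop("tabulated input function does not cover the requested times")
    }
    return(stats::approx(f$times, f$values, xout = t)$y)
  }
  u <- t - f$delay
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- es_eval(f$terms, u[pos])
  pmax(out, 0)
}

#' Cumulative integral of an input function
#'
#' \eqn{\int_0^t C_p(\tau)\,d\tau} in kBq·min/ml, exact (closed-form) for the
#' exponential-family models and trapezoidal for tabulated curves.
#'
#' @inheritParams evaluate_input
#' @return numeric vector of integrals, kBq·min/ml.
#' @export
integrate_input <- function(f, t) {
  stopifnot(inherits(f, "input_function"), is.numeric(t))
  if (any(t < 0)) stop("times must be non-negative")
  if (f$model_id == "tabulated") {
    if (min(f$times) > 0) stop("tabulated input function must cover [0, t]")
    if (any(t > max(f$times))) stop("tabulated input function does not cover [0, t]")
    cumint <- c(0, cumsum(diff(f$times) * (utils::head(f$values, -1) + utils::tail(f$values, -1)) / 2))
    base <- stats::approx(f$times, cumint, xout = pmax(t, min(f$times)))$y
    return(base - stats::approx(f$times, cumint, xout = 0)$y)
  }
  u <- pmax(t - f$delay, 0)
  es_eval(es_int(f$terms), u)
}

# internal generics used by frame averaging -------------------------------

curve_value <- function(x, t) UseMethod("curve_value")
curve_integral <- function(x, t) UseMethod("curve_integral")

#' @export
curve_value.input_function <- function(x, t) evaluate_input(x, t)
#' @export
curve_integral.input_function <- function(x, t) integrate_input(x, t)
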