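#' Irreversible two-tissue-compartment kinetic parameters
#'
#' Micro-parameters of the irreversible (k4 = 0) two-tissue-compartment FDG
#' model: plasma-to-tissue transport `K1` (ml/min/ml), tissue-to-plasma
#' clearance `k2` (1/min), phosphorylation (trapping) rate `k3` (1/min) and
#' fractional blood volume `vb`. The Patlak macro-parameters are derived:
#' the net influx rate \eqn{K_i = K_1 k_3 / (k_2 + k_3)} and the apparent
#' distribution volume of free tracer
#' \eqn{V = v_b + K_1 k_2 / (k_2 + k_3)^2}.
#'
#' @param K1 plasma-to-tissue rate, ml/min/ml.
#' @param k2 efflux rate, 1/min.
#' @param k3 trapping rate, 1/min.
#' @param vb fractional blood volume in `[0, 1)`.
#' @return an object of class `kinetic_params` with derived `ki_true`
#'   and `v_true`.
#' @examples
#' p <- kinetic_params(K1 = 0.1, k2 = 0.15, k3 = 0.05, vb = 0.05)
#' patlak_asymptote(p)
#' @export
kinetic_params <- function(K1, k2, k3, vb = 0) {
  stopifnot(is.numeric(K1), is.numeric(k2), is.numeric(k3), is.numeric(vb))
  if (K1 < 0 || k2 < 0 || k3 < 0) stop("rate constants must be non-negative")
  if (k2 + k3 <= 0) stop("k2 + k3 must be positive")
  if (vb < 0 || vb >= 1) stop("vb must lie in [0, 1)")
  obj <- list(K1 = K1, k2 = k2, k3 = k3, vb = vb,
              ki_true = K1 * k3 / (k2 + k3),
              v_true = vb + K1 * k2 / (k2 + k3)^2)
  class(obj) <- "kinetic_params"
  obj
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> K1=%.4g k2=%.4g k3=%.4g vb=%.3g  (Ki=%.4g /min, V=%.4g)\n",
              x$K1, x$k2, x$k3, x$vb, x$ki_true, x$v_true))
  invisible(x)
}

#' Patlak macro-parameters implied by micro-parameters
#'
#' @param p a [kinetic_params()] object.
#' @return list with `ki_true` (1/min) and `v_true` (unitless).
#' @export
patlak_asymptote <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  list(ki_true = p$ki_true, v_true = p$v_true)
}

#' Closed-form tissue time-activity curve
#'
#' The measured activity of a voxel holding tissue with kinetics `p` fed by
#' the plasma curve `f` is
#' \deqn{C(t) = \frac{K_1 k_3}{k_2+k_3}\int_0^t C_p
#'   + \frac{K_1 k_2}{k_2+k_3}\int_0^t e^{-(k_2+k_3)(t-s)} C_p(s)\,ds
#'   + v_b\,C_p(t),}
#' the exact solution of the irreversible two-tissue system plus the blood
#' contribution. For exponential-family inputs every term is closed-form.
#'
#' @param p a [kinetic_params()] object.
#' @param f an [input_function()] of the exponential family (`feng4` or
#'   `tri_exponential`).
#' @return an object of class `tissue_curve`; evaluate with
#'   [evaluate_tissue()] or frame-average with [frame_average()].
#' @export
tissue_curve <- function(p, f) {
  stopifnot(inherits(p, "kinetic_params"), inherits(f, "input_function"))
  if (f$model_id == "tabulated") {
    stop("closed-form tissue curves require an exponential-family input function")
  }
  beta <- p$k2 + p$k3
  terms <- es_add(
    es_scale(es_int(f$terms), p$K1 * p$k3 / beta),
    es_scale(es_conv(f$terms, beta), p$K1 * p$k2 / beta),
    es_scale(f$terms, p$vb))
  obj <- list(terms = terms, delay = f$delay, params = p, input = f)
  class(obj) <- "tissue_curve"
  obj
}

#' Evaluate a tissue curve
#'
#' @param tc a [tissue_curve()].
#' @param t non-negative times, minutes.
#' @return activities in kBq/ml.
#' @export
evaluate_tissue <- function(tc, t) {
  stopifnot(inherits(tc, "tissue_curve"))
  if (any(t < 0)) stop("times must be non-negative")
  u <- t - tc$delay
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- es_eval(tc$terms, u[pos])
  pmax(out, 0)
}

#' @export
curve_value.tissue_curve <- function(x, t) evaluate_tissue(x, t)

#' @export
curve_integral.tissue_curve <- function(x, t) {
  if (any(t < 0)) stop("times must be non-negative")
  u <- pmax(t - x$delay, 0)
  es_eval(es_int(x$terms), u)
}

#' Default organ kinetics for the whole-body digital phantom
#'
#' Representative FDG kinetic parameters for seven normal organs plus a
#' generic avid lesion. Each organ is parameterized from a target metabolic
#' rate `MR_FDG` (\eqn{K_i \times} glucose, µmol/min/ml) and a target Patlak
#' intercept `DV` (percent), values chosen inside the bands typically
#' reported for adult whole-body parametric FDG imaging. Micro-parameters
#' are then solved so the Patlak asymptote hits those targets exactly, with
#' an overall turnover \eqn{k_2 + k_3} of `beta` and a fractional blood
#' volume of one quarter of the intercept.
#'
#' @param glucose blood glucose used to convert MR targets to Ki, mmol/L.
#' @param beta assumed tissue turnover \eqn{k_2 + k_3}, 1/min.
#' @return data.frame with one row per region: targets (`mr_fdg`,
#'   `dv_percent`) and micro-parameters (`K1`, `k2`, `k3`, `vb`).
#' @export
organ_kinetic_defaults <- function(glucose = 5.5, beta = 0.35) {
  organs <- data.frame(
    organ = c("brain", "lung", "liver", "spleen", "heart_wall",
              "bone", "muscle", "lesion"),
    mr_fdg = c(0.17, 0.010, 0.040, 0.040, 0.12, 0.040, 0.010, 0.12),
    dv_percent = c(59, 4.1, 28, 22, 49, 15, 7.0, 35),
    stringsAsFactors = FALSE)
  organs$ki <- organs$mr_fdg / glucose
  v <- organs$dv_percent / 100
  organs$vb <- 0.25 * v
  # solve K1 k3 = ki * beta and K1 k2 = (v - vb) * beta^2 with k2 + k3 = beta
  organs$K1 <- organs$ki + (v - organs$vb) * beta
  organs$k3 <- organs$ki * beta / organs$K1
  organs$k2 <- beta - organs$k3
  organs
}

#' @rdname organ_kinetic_defaults
#' @param row one row of the table returned by [organ_kinetic_defaults()].
#' @export
kinetic_params_from_row <- function(row) {
  kinetic_params(K1 = row$K1, k2 = row$k2, k3 = row$k3, vb = row$vb)
}
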