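#' Extract an image-derived input function
#'
#' Per-frame mean over an aorta VOI, mirroring the automated
#' descending-aorta VOI placement of clinical multiparametric protocols.
#'
#' @param img a [render_phantom()] / [read_dynamic_image()] image.
#' @param voi logical array matching the image grid (or integer voxel
#'   indices) selecting the aorta voxels.
#' @return a [new_tac()] tagged `"aorta_idif"`.
#' @export
extract_idif <- function(img, voi) {
  stopifnot(inherits(img, "dynamic_image"))
  nvox <- prod(dim(img$data)[1:3])
  idx <- if (is.logical(voi)) which(voi) else as.integer(voi)
  if (length(idx) == 0) stop("aorta VOI is empty")
  if (any(idx < 1 | idx > nvox)) stop("aorta VOI lies outside the grid")
  mat <- matrix(img$data, nvox)[idx, , drop = FALSE]
  new_tac(img$schedule$start, img$schedule$end, colMeans(mat),
          source = "aorta_idif")
}

#' Merge early and late input-function TACs
#'
#' Concatenate the 0–6 min cardiac-bed TAC and the 60–75 min late-pass TAC
#' into the single merged curve used to derive the two-short-dynamic input
#' function (clinically exchanged as a CSV file; see [write_tac_csv()]).
#'
#' @param early TAC covering 0–6 min.
#' @param late TAC covering 60–75 min.
#' @return a [new_tac()] tagged `"merged"`.
#' @seealso [split_tac()] for the inverse.
#' @export
merge_tacs <- function(early, late) {
  stopifnot(inherits(early, "tac"), inherits(late, "tac"))
  if (max(early$end) > min(late$start) + 1e-9) {
    stop("early and late TACs overlap or are out of order")
  }
  new_tac(c(early$start, late$start), c(early$end, late$end),
          c(early$activity, late$activity), source = "merged")
}

#' @rdname merge_tacs
#' @param tac a merged TAC.
#' @param at split time in minutes (default 6).
#' @export
split_tac <- function(tac, at = 6) {
  stopifnot(inherits(tac, "tac"))
  e <- tac$end <= at + 1e-9
  list(early = new_tac(tac$start[e], tac$end[e], tac$activity[e],
                       source = tac_source(tac)),
       late = new_tac(tac$start[!e], tac$end[!e], tac$activity[!e],
                      source = tac_source(tac)))
}

#' TAC CSV dialect
#'
#' Fixed interchange dialect for TAC files: header
#' `frame_start_s,frame_end_s,activity_kBq_ml`, UTF-8, LF line endings,
#' `.` decimal point, no thousands separators. Values are written with 17
#' significant digits so a write/read round trip is bit-exact.
#'
#' @param tac a [new_tac()].
#' @param path file path.
#' @return `write_tac_csv`: the path, invisibly; `read_tac_csv`: a `tac`.
#' @export
write_tac_csv <- function(tac, path) {
  stopifnot(inherits(tac, "tac"))
  lines <- c("frame_start_s,frame_end_s,activity_kBq_ml",
             sprintf("%.17g,%.17g,%.17g",
                     tac$start * 60, tac$end * 60, tac$activity))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @param source source tag for the TAC read back.
#' @export
read_tac_csv <- function(path, source = "merged") {
  df <- utils::read.csv(path, colClasses = "numeric")
  expect <- c("frame_start_s", "frame_end_s", "activity_kBq_ml")
  if (!identical(names(df), expect)) {
    stop("not a TAC CSV (expected header ", paste(expect, collapse = ","), ")")
  }
  new_tac(df$frame_start_s / 60, df$frame_end_s / 60, df$activity_kBq_ml,
          source = source)
}

# closed-form value/integral representation shared by all gap families ----

gap_curve_es <- function(g) {
  switch(g$family,
    tri_exponential = list(terms = es_new(g$coefficients$amplitudes,
                                          g$coefficients$rates,
                                          rep(0L, length(g$coefficients$rates))),
                           delay = 0),
    input_model_refit = {
      cf <- g$coefficients
      list(terms = es_new(c(cf$amplitudes[1], -(cf$amplitudes[2] + cf$amplitudes[3]),
                            cf$amplitudes[2], cf$amplitudes[3]),
                          c(cf$rates[1], cf$rates[1], cf$rates[2], cf$rates[3]),
                          c(1L, 0L, 0L, 0L)),
           delay = cf$delay)
    },
    loglinear_bridge = {
      cf <- g$coefficients
      list(terms = es_new(cf$v0 * exp(cf$rate * cf$t0), cf$rate, 0L), delay = 0)
    },
    stop("unknown gap-model family: ", g$family))
}

#' Evaluate or integrate a fitted gap model
#'
#' @param g a [fit_gap_model()] object.
#' @param t times, minutes.
#' @return `gap_value`: modelled plasma activity (clamped at 0);
#'   `gap_integral`: \eqn{\int_{t0}^{t1}} of the modelled curve.
#' @export
gap_value <- function(g, t) {
  es <- gap_curve_es(g)
  u <- t - es$delay
  out <- numeric(length(t))
  out[u > 0] <- es_eval(es$terms, u[u > 0])
  if (any(out < 0)) {
    warning("gap model yielded negative activities; clamped at 0")
    out <- pmax(out, 0)
  }
  out
}

#' @rdname gap_value
#' @param t0,t1 integration bounds, minutes.
#' @export
gap_integral <- function(g, t0, t1) {
  es <- gap_curve_es(g)
  anti <- es_int(es$terms)
  es_eval(anti, pmax(t1 - es$delay, 0)) - es_eval(anti, pmax(t0 - es$delay, 0))
}

# Sum-of-positive-exponentials fit to frame-averaged samples.
# The model predicts the exact frame mean (a/l)(e^{-l t0} - e^{-l t1})/dt,
# and residuals are taken on the log scale so the late tail - which carries
# the 6-60 min bridge - is not swamped by the early peak. Starting values
# come from curve peeling: the 60-75 min window fixes the slowest term,
# successive early-window tails fix the faster ones.
fit_exp_sum <- function(t0, t1, v, k) {
  keep <- v > 0
  t0 <- t0[keep]; t1 <- t1[keep]; v <- v[keep]
  if (length(v) < k * 2) return(NULL)
  m <- (t0 + t1) / 2
  frame_mean <- function(a, l) {
    out <- numeric(length(t0))
    for (j in seq_along(a)) {
      out <- out + if (l[j] < 1e-8) rep(a[j], length(t0)) else
        a[j] * (exp(-l[j] * t0) - exp(-l[j] * t1)) / (l[j] * (t1 - t0))
    }
    out
  }
  peel_starts <- function() {
    amps <- numeric(0); rates <- numeric(0)
    resid <- v
    windows <- list(m >= 50, m < 50 & m >= stats::median(m[m < 50]),
                    m < stats::median(m[m < 50]))
    for (j in seq_len(min(k, 3))) {
      sel <- which(windows[[j]] & resid > max(resid) * 1e-8)
      if (length(sel) < 2) sel <- order(resid, decreasing = (j > 1))[1:3]
      ft <- stats::lm(log(resid[sel]) ~ m[sel])
      lam <- min(max(-stats::coef(ft)[2], 1e-4), 20)
      amp <- max(exp(stats::coef(ft)[1]), max(v) * 1e-8)
      amps <- c(amps, amp); rates <- c(rates, lam)
      resid <- pmax(resid - amp * exp(-lam * m), max(v) * 1e-9)
    }
    while (length(amps) < k) {
      amps <- c(amps, max(v) * 0.5)
      rates <- c(rates, max(rates) * 8)
    }
    list(amplitudes = amps, rates = rates)
  }
  st <- peel_starts()
  par0 <- c(log(st$amplitudes), log(st$rates))
  fit <- try(minpack.lm::nls.lm(
    par = par0,
    fn = function(par) {
      pred <- frame_mean(exp(par[seq_len(k)]), exp(par[k + seq_len(k)]))
      log(pmax(pred, max(v) * 1e-12)) - log(v)
    },
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  a <- exp(fit$par[seq_len(k)]); l <- exp(fit$par[k + seq_len(k)])
  ord <- order(l, decreasing = TRUE)
  list(amplitudes = unname(a[ord]), rates = unname(l[ord]),
       residual_norm = sqrt(sum(fit$fvec^2)), converged = fit$info %in% 1:4)
}

#' Fit a plasma model across the unsampled 6–60 min interval
#'
#' The two-short protocol samples the input function only on 0–6 min and
#' 60–75 min; the running plasma integral needed by the Patlak transform
#' requires a model of the curve in between. Families:
#' \describe{
#'   \item{`tri_exponential`}{(default) three positive decaying exponentials
#'     fitted by Levenberg–Marquardt least squares to the post-peak samples
#'     of both windows — the standard description of FDG plasma clearance,
#'     and identifiable from the two windows alone. Samples within
#'     `bolus_clearance` minutes of the peak are excluded: they are
#'     dominated by bolus transit, which the washout family cannot
#'     represent, and including them contaminates the components that
#'     carry the 6–60 min bridge.}
#'   \item{`input_model_refit`}{refit of the full Feng bolus shape
#'     (including the rise) to all samples.}
#'   \item{`loglinear_bridge`}{mono-exponential interpolation between the
#'     last early and first late sample.}
#' }
#' An essentially constant post-peak TAC yields a reduced single-term model
#' with rate ~0. Sample timestamps are frame midpoints.
#'
#' @param tac a merged (or fully sampled) [new_tac()].
#' @param family model family, see above.
#' @param bolus_clearance minutes after the peak excluded from the
#'   `tri_exponential` washout fit (default 1).
#' @return object of class `gap_model`: `family`, `coefficients`,
#'   `residual_norm`, `converged`, `t_peak`.
#' @export
fit_gap_model <- function(tac, family = c("tri_exponential", "input_model_refit",
                                          "loglinear_bridge"),
                          bolus_clearance = 1) {
  stopifnot(inherits(tac, "tac"))
  family <- match.arg(family)
  m <- tac_midpoints(tac)
  v <- tac$activity
  ipk <- which.max(v)
  post <- m > m[ipk] + bolus_clearance
  if (sum(post) < 3) post <- m > m[ipk]
  if (sum(post) < 3) stop("need at least 3 post-peak samples to fit a gap model")

  if (family == "loglinear_bridge") {
    early <- which(tac$end <= 6 + 1e-9)
    late <- which(tac$start >= 6 - 1e-9)
    if (!length(early) || !length(late)) stop("loglinear bridge needs samples on both sides of the gap")
    i0 <- early[length(early)]; i1 <- late[1]
    v0 <- max(v[i0], 1e-9); v1 <- max(v[i1], 1e-9)
    rate <- log(v0 / v1) / (m[i1] - m[i0])
    g <- list(family = family,
              coefficients = list(t0 = m[i0], v0 = v0, t1 = m[i1], v1 = v1, rate = rate),
              residual_norm = 0, converged = TRUE, t_peak = m[ipk])
    class(g) <- "gap_model"
    return(g)
  }

  if (family == "tri_exponential") {
    mp <- m[post]; vp <- v[post]
    if (stats::sd(vp) <= 1e-10 * max(abs(vp), 1e-12)) {
      g <- list(family = family,
                coefficients = list(amplitudes = mean(vp), rates = 1e-8),
                residual_norm = 0, converged = TRUE, t_peak = m[ipk],
                reduced = TRUE)
      class(g) <- "gap_model"
      return(g)
    }
    fit <- NULL
    for (k in c(3, 2, 1)) {
      fit <- fit_exp_sum(tac$start[post], tac$end[post], vp, k)
      if (!is.null(fit) && fit$converged) break
    }
    if (is.null(fit)) stop("gap-model fit failed to converge; residual diagnostics unavailable")
    if (!fit$converged) {
      stop(sprintf("gap-model fit did not converge (residual norm %.3g)", fit$residual_norm))
    }
    g <- list(family = family,
              coefficients = list(amplitudes = fit$amplitudes, rates = fit$rates),
              residual_norm = fit$residual_norm, converged = TRUE, t_peak = m[ipk])
    class(g) <- "gap_model"
    return(g)
  }

  # input_model_refit: full Feng shape including the rise
  delay0 <- max(m[ipk] - 0.3, 1e-3)
  par0 <- c(la1 = log(max(v) * 4), la2 = log(max(v[length(v)], 1e-3)),
            la3 = log(max(v) * 0.2), ll1 = log(4), ll2 = log(0.01),
            ll3 = log(0.12), ld = log(delay0))
  feng_fun <- function(par, t) {
    A <- exp(par[1:3]); L <- exp(par[4:6]); d <- exp(par[7])
    u <- pmax(t - d, 0)
    (A[1] * u - A[2] - A[3]) * exp(-L[1] * u) + A[2] * exp(-L[2] * u) +
      A[3] * exp(-L[3] * u)
  }
  fit <- try(minpack.lm::nls.lm(par0, fn = function(par) v - feng_fun(par, m),
                                control = minpack.lm::nls.lm.control(maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) {
    stop("input-model refit failed to converge")
  }
  g <- list(family = family,
            coefficients = list(amplitudes = unname(exp(fit$par[1:3])),
                                rates = unname(exp(fit$par[4:6])),
                                delay = unname(exp(fit$par[7]))),
            residual_norm = sqrt(sum(fit$fvec^2)), converged = TRUE,
            t_peak = m[ipk])
  class(g) <- "gap_model"
  g
}

#' @export
print.gap_model <- function(x, ...) {
  cat("<gap_model>", x$family, "| residual norm", signif(x$residual_norm, 4), "\n")
  invisible(x)
}

#' Serialize a gap model to JSON
#'
#' @param g a [fit_gap_model()] object.
#' @param path file path.
#' @export
write_gap_model <- function(g, path) {
  stopifnot(inherits(g, "gap_model"))
  jsonlite::write_json(unclass(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Running plasma integral of a sampled input function
#'
#' \eqn{\int_0^t C_p}, the x-axis numerator of the Patlak transform, from a
#' sampled TAC: trapezoid over the sampled segments (with a zero-anchored
#' rise over `[0, first midpoint]`), and the closed-form integral of the
#' fitted gap model across any sampling hole wider than `gap_tol` minutes.
#'
#' @param tac a [new_tac()] (e.g. the IDIF).
#' @param g a [fit_gap_model()] object, or `NULL` for fully sampled TACs.
#' @param t query times, minutes (at most the end of the last frame).
#' @param gap_tol midpoint spacings larger than this (minutes) are treated
#'   as unsampled and bridged with the gap model.
#' @return integral values, kBq·min/ml; monotone non-decreasing in `t`.
#' @export
cumulative_plasma_integral <- function(tac, g = NULL, t, gap_tol = 6) {
  stopifnot(inherits(tac, "tac"), is.numeric(t))
  m <- tac_midpoints(tac)
  v <- pmax(tac$activity, 0)
  if (any(t < 0) || any(t > max(tac$end) + 1e-9)) {
    stop("query times must lie within [0, last frame end]")
  }
  # first knot: the first frame's mean value held from the frame start --
  # for an IDIF whose first 5-s frame precedes tracer arrival this is the
  # zero-anchored rise, and a fully sampled constant TAC integrates to c*t
  knots <- c(tac$start[1], m, max(tac$end))
  vals <- c(v[1], v, v[length(v)])
  nseg <- length(knots) - 1
  seg_gap <- logical(nseg)
  seg_int <- numeric(nseg)
  for (i in seq_len(nseg)) {
    wid <- knots[i + 1] - knots[i]
    if (i > 1 && i <= length(m) && wid > gap_tol) {
      if (is.null(g)) {
        stop("TAC has an unsampled interval wider than gap_tol; a gap model is required")
      }
      seg_gap[i] <- TRUE
      seg_int[i] <- gap_integral(g, knots[i], knots[i + 1])
    } else {
      seg_int[i] <- wid * (vals[i] + vals[i + 1]) / 2
    }
  }
  cum <- c(0, cumsum(seg_int))
  out <- numeric(length(t))
  for (j in seq_along(t)) {
    tj <- min(t[j], knots[length(knots)])
    if (tj <= knots[1]) next  # no activity before the first frame
    i <- findInterval(tj, knots, rightmost.closed = TRUE)
    i <- min(max(i, 1), nseg)
    partial <- if (seg_gap[i]) {
      gap_integral(g, knots[i], tj)
    } else {
      frac_v <- vals[i] + (vals[i + 1] - vals[i]) *
        (tj - knots[i]) / (knots[i + 1] - knots[i])
      (tj - knots[i]) * (vals[i] + frac_v) / 2
    }
    out[j] <- cum[i] + partial
  }
  out
}
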