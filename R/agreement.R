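#' Passing–Bablok regression
#'
#' Nonparametric method-comparison regression. The slope is the shifted
#' median of all pairwise slopes \eqn{S_{ij} = (y_j - y_i)/(x_j - x_i)}:
#' slopes of exactly −1 are excluded, ties between \eqn{x_i} and \eqn{x_j}
#' with differing \eqn{y} contribute \eqn{\pm\infty}, 0/0 pairs are dropped,
#' and the median index is offset by \eqn{K}, the number of slopes below −1,
#' which makes the estimate equivariant under exchange of the axes. The
#' intercept is \eqn{A = \mathrm{median}(y - Bx)}. Confidence bounds use the
#' rank-based normal approximation with
#' \eqn{C_\gamma = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}}.
#'
#' @param x,y paired measurements (method 1 and method 2).
#' @param ci_level two-sided confidence level (default 0.95).
#' @return list with `intercept`, `slope`, `intercept_ci`, `slope_ci`,
#'   `n`, `n_slopes`, `K`, and the residual standard deviation `rsd` with
#'   its ±1.96 band (`random_differences`).
#' @references Passing H, Bablok W. A new biometrical procedure for testing
#'   the equality of measurements from two different analytical methods.
#'   J Clin Chem Clin Biochem 1983;21:709-720.
#' @export
passing_bablok <- function(x, y, ci_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Passing-Bablok regression needs at least 3 pairs")
  if (length(unique(x)) == 1) stop("all x values are equal; slope undefined")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  S <- ifelse(dx == 0 & dy == 0, NA_real_, dy / dx)  # 0/0 pairs dropped
  S <- S[!is.na(S)]
  S <- S[S != -1]
  if (!length(S)) stop("no valid pairwise slopes")
  S <- sort(S)             # sorts -Inf/Inf to the ends
  N <- length(S)
  K <- sum(S < -1)
  B <- if (N %% 2 == 1) {
    S[(N + 1) / 2 + K]
  } else {
    mean(S[c(N / 2 + K, N / 2 + 1 + K)])
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  Cg <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - Cg) / 2)
  M2 <- N - M1 + 1
  B_lo <- if (M1 + K >= 1 && M1 + K <= N) S[M1 + K] else -Inf
  B_hi <- if (M2 + K >= 1 && M2 + K <= N) S[M2 + K] else Inf
  A <- stats::median(y - B * x)
  A_lo <- stats::median(y - B_hi * x)
  A_hi <- stats::median(y - B_lo * x)
  resid <- y - (A + B * x)
  rsd <- stats::sd(resid)
  list(intercept = A, slope = B,
       intercept_ci = c(A_lo, A_hi), slope_ci = c(B_lo, B_hi),
       n = n, n_slopes = N, K = K, rsd = rsd,
       random_differences = c(-1.96 * rsd, 1.96 * rsd),
       ci_level = ci_level, x = x, y = y)
}

#' Cusum test for linearity of a Passing–Bablok fit
#'
#' Residual-sign cumulative-sum test. Points are ranked by increasing
#' \eqn{x}; points above the fitted line score \eqn{+\sqrt{n_2/n_1}}, below
#' \eqn{-\sqrt{n_1/n_2}} (with \eqn{n_1}, \eqn{n_2} the counts above and
#' below). The partial-sum path returns to 0 by construction, so under
#' linearity its maximum absolute excursion (with a small continuity
#' correction) scaled by
#' \eqn{\sqrt{n_1 + n_2}} follows the Kolmogorov–Smirnov distribution,
#' from which a two-sided p-value is taken. A large cusum excursion (small
#' p) indicates systematic deviation from linearity.
#'
#' @param x,y paired measurements.
#' @param fit a [passing_bablok()] fit for the same data.
#' @return p-value in `[0, 1]`; degenerate all-zero residuals give 1 with a
#'   warning.
#' @export
cusum_linearity <- function(x, y, fit) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  r <- y - (fit$intercept + fit$slope * x)
  eps <- 1e-12 * max(abs(y), 1)
  pos <- r > eps
  neg <- r < -eps
  n1 <- sum(pos); n2 <- sum(neg)
  if (n1 + n2 == 0) {
    warning("all residuals are zero; linearity test degenerate")
    return(1)
  }
  if (n1 == 0 || n2 == 0) return(1)
  ord <- order(x, y)
  score <- numeric(length(x))
  score[pos] <- sqrt(n2 / n1)
  score[neg] <- -sqrt(n1 / n2)
  cusum <- cumsum(score[ord])
  # +0.3 is a small-sample continuity correction: the discrete walk's
  # maximum undershoots the Brownian-bridge supremum, which would make the
  # asymptotic test conservative at n of a few dozen
  stat <- (max(abs(cusum)) + 0.3) / sqrt(n1 + n2)
  # Kolmogorov survival function
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * stat^2))
  min(max(p, 0), 1)
}

#' Bland–Altman agreement analysis
#'
#' Differences `d = y - x` (second method minus first); reports the mean
#' bias, the 95% limits of agreement `bias ± 1.96 sd(d)`, and additionally
#' a confidence interval of the bias itself (the two are often conflated;
#' both are returned under unambiguous names).
#'
#' @param x,y paired measurements (reference method first).
#' @param ci_level confidence level for the bias CI.
#' @return list with `bias`, `lower_limit`, `upper_limit` (limits of
#'   agreement), `sd`, `bias_ci`, `n`.
#' @export
bland_altman <- function(x, y, ci_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  d <- y[ok] - x[ok]
  n <- length(d)
  if (n < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - ci_level) / 2, n - 1)
  list(bias = bias, sd = s,
       lower_limit = bias - 1.96 * s, upper_limit = bias + 1.96 * s,
       bias_ci = c(bias - tq * s / sqrt(n), bias + tq * s / sqrt(n)),
       n = n)
}

#' Spearman rank correlation with confidence interval
#'
#' Rank correlation with average ranks for ties, computed directly as the
#' Pearson correlation of the rank vectors. The confidence interval uses
#' the Fisher z transform with Fieller's standard error
#' \eqn{\sqrt{1.06/(n-3)}}; the p-value uses the t approximation with
#' \eqn{n - 2} degrees of freedom.
#'
#' @param x,y paired measurements.
#' @param ci_level confidence level (default 0.95).
#' @return list with `rho`, `ci`, `p`, `n`; zero rank variance yields `NA`
#'   estimates with a warning.
#' @export
spearman_ci <- function(x, y, ci_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_, n = n))
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (n > 3 && abs(rho) < 1) {
    se <- sqrt(1.06 / (n - 3))
    ci <- tanh(atanh(rho) + c(-1, 1) * z * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  p <- if (abs(rho) < 1) {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  } else 0
  list(rho = rho, ci = ci, p = p, n = n)
}

#' Full method-comparison battery over paired samples
#'
#' Runs Passing–Bablok regression (with the cusum linearity test),
#' Bland–Altman analysis and Spearman correlation for each metric of a
#' paired-sample table, producing one report row per metric — the layout
#' used to compare standard against two-short-dynamic parametric values.
#'
#' @param pairs data.frame with columns `metric`, `std`, `tsd` (and
#'   optionally `region`, `group`).
#' @param ci_level confidence level.
#' @return data.frame of class `agreement_report`: per metric the PB
#'   intercept/slope with CIs, residual-SD band, cusum p, BA bias and
#'   limits of agreement, Spearman rho with CI and p, and `n`.
#' @export
agreement_battery <- function(pairs, ci_level = 0.95) {
  stopifnot(all(c("metric", "std", "tsd") %in% names(pairs)))
  metrics <- unique(pairs$metric)
  rows <- lapply(metrics, function(mt) {
    d <- pairs[pairs$metric == mt, ]
    pb <- passing_bablok(d$std, d$tsd, ci_level)
    cu <- cusum_linearity(d$std, d$tsd, pb)
    ba <- bland_altman(d$std, d$tsd, ci_level)
    sp <- spearman_ci(d$std, d$tsd, ci_level)
    data.frame(metric = mt, n = pb$n,
               intercept_A = pb$intercept,
               intercept_lo = pb$intercept_ci[1], intercept_hi = pb$intercept_ci[2],
               slope_B = pb$slope,
               slope_lo = pb$slope_ci[1], slope_hi = pb$slope_ci[2],
               rsd = pb$rsd,
               random_diff_lo = pb$random_differences[1],
               random_diff_hi = pb$random_differences[2],
               cusum_p = cu,
               ba_bias = ba$bias, ba_lower = ba$lower_limit, ba_upper = ba$upper_limit,
               spearman_rho = sp$rho, spearman_lo = sp$ci[1], spearman_hi = sp$ci[2],
               spearman_p = sp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", class(out))
  out
}

#' Plot helpers for the agreement battery
#'
#' `plot_passing_bablok` draws the scatter with the identity and fitted
#' lines; `plot_bland_altman` draws differences against means with the bias
#' and limits of agreement.
#'
#' @param x,y paired measurements (std, tsd).
#' @param fit a [passing_bablok()] fit (for the regression plot).
#' @param main plot title.
#' @export
plot_passing_bablok <- function(x, y, fit, main = "Passing-Bablok regression") {
  graphics::plot(x, y, pch = 19, cex = 0.6, xlab = "standard", ylab = "two short dynamic",
                 main = main)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  graphics::abline(fit$intercept, fit$slope, col = "firebrick")
  invisible(NULL)
}

#' @rdname plot_passing_bablok
#' @param ba a [bland_altman()] result.
#' @export
plot_bland_altman <- function(x, y, ba, main = "Bland-Altman") {
  m <- (x + y) / 2
  d <- y - x
  graphics::plot(m, d, pch = 19, cex = 0.6, xlab = "mean of methods",
                 ylab = "difference (tsd - std)", main = main)
  graphics::abline(h = ba$bias, col = "firebrick")
  graphics::abline(h = c(ba$lower_limit, ba$upper_limit), col = "firebrick", lty = 2)
  invisible(NULL)
}
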