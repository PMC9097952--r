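# Internal algebra over finite sums of  a * t^p * exp(-l * t)  terms
# (p in 0:2, l >= 0). The family is closed under definite integration from 0
# and under convolution with exp(-beta * t), so arterial input curves,
# two-tissue-compartment tissue curves, their running integrals and exact
# frame averages all stay closed-form. Not exported.

es_new <- function(a = numeric(), l = numeric(), p = integer()) {
  stopifnot(length(a) == length(l), length(l) == length(p))
  data.frame(a = as.numeric(a), l = as.numeric(l), p = as.integer(p))
}

es_compact <- function(es) {
  es <- es[es$a != 0, , drop = FALSE]
  rownames(es) <- NULL
  es
}

es_scale <- function(es, c) {
  es$a <- es$a * c
  es
}

es_add <- function(...) {
  es_compact(do.call(rbind, list(...)))
}

# evaluate sum_i a_i t^p_i exp(-l_i t) at (non-negative) t
es_eval <- function(es, t) {
  out <- numeric(length(t))
  for (i in seq_len(nrow(es))) {
    out <- out + es$a[i] * t^es$p[i] * exp(-es$l[i] * t)
  }
  out
}

# running integral from 0, returned as a new term sum in t
es_int <- function(es) {
  if (nrow(es) == 0L) return(es)
  rows <- vector("list", nrow(es))
  for (i in seq_len(nrow(es))) {
    a <- es$a[i]; l <- es$l[i]; p <- es$p[i]
    rows[[i]] <- if (l == 0) {
      es_new(a / (p + 1), 0, p + 1L)
    } else if (p == 0L) {
      es_new(c(a / l, -a / l), c(0, l), c(0L, 0L))
    } else if (p == 1L) {
      es_new(c(a / l^2, -a / l^2, -a / l), c(0, l, l), c(0L, 0L, 1L))
    } else if (p == 2L) {
      es_new(c(2 * a / l^3, -2 * a / l^3, -2 * a / l^2, -a / l),
             c(0, l, l, l), c(0L, 0L, 1L, 2L))
    } else {
      stop("polynomial degree above 2 not supported in term sums")
    }
  }
  es_compact(do.call(rbind, rows))
}

# convolution integral  int_0^t exp(-beta (t - s)) f(s) ds  for beta > 0
es_conv <- function(es, beta) {
  stopifnot(beta > 0)
  if (nrow(es) == 0L) return(es)
  rows <- vector("list", nrow(es))
  for (i in seq_len(nrow(es))) {
    a <- es$a[i]; l <- es$l[i]; p <- es$p[i]
    rows[[i]] <- if (l == beta) {
      if (p == 0L) {
        es_new(a, beta, 1L)
      } else if (p == 1L) {
        es_new(a / 2, beta, 2L)
      } else {
        stop("degree-2 resonant convolution not supported")
      }
    } else {
      d <- beta - l
      if (p == 0L) {
        es_new(c(a / d, -a / d), c(l, beta), c(0L, 0L))
      } else if (p == 1L) {
        es_new(c(a / d, -a / d^2, a / d^2), c(l, l, beta), c(1L, 0L, 0L))
      } else {
        stop("degree-2 convolution not needed and not supported")
      }
    }
  }
  es_compact(do.call(rbind, rows))
}
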