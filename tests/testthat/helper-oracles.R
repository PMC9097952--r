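# Independent oracles and fixture builders used across the suite.

# Stiff-ODE integration of the irreversible two-tissue system (deSolve),
# independent of the package's closed-form convolution path. Returns the
# measured activity C1 + C2 + vb * Cp at `times`.
ode_tissue_oracle <- function(p, f, times) {
  rhs <- function(t, y, parms) {
    cp <- evaluate_input(f, t)
    list(c(p$K1 * cp - (p$k2 + p$k3) * y[1], p$k3 * y[1]))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(c(0, 0), times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  idx <- match(times, tt)
  rowSums(sol[idx, 2:3, drop = FALSE]) + p$vb * evaluate_input(f, times)
}

# direct evaluation of the Feng bolus form, written out independently of
# the package's internal term-sum representation
feng_direct <- function(t, A, L, delay) {
  u <- t - delay
  out <- numeric(length(t))
  pos <- u > 0
  up <- u[pos]
  out[pos] <- (A[1] * up - A[2] - A[3]) * exp(-L[1] * up) +
    A[2] * exp(-L[2] * up) + A[3] * exp(-L[3] * up)
  pmax(out, 0)
}

# adaptive-quadrature frame mean
quad_frame_mean <- function(f, t0, t1) {
  stats::integrate(function(s) evaluate_input(f, s), t0, t1,
                   rel.tol = 1e-12, subdivisions = 2000L)$value / (t1 - t0)
}

# brute-force Passing-Bablok slope/intercept straight from the definition:
# explicit double loop, explicit shifted-median indexing
pb_brute <- function(x, y) {
  n <- length(x)
  S <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- dy / dx
      if (identical(s, -1)) next
      if (s == -1) next
      S <- c(S, s)
    }
  }
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  B <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else (S[N / 2 + K] + S[N / 2 + 1 + K]) / 2
  A <- median(y - B * x)
  list(A = A, B = B)
}

random_kinetics <- function() {
  K1 <- runif(1, 0.02, 0.4)
  k2 <- runif(1, 0.05, 0.5)
  k3 <- runif(1, 0.01, 0.2)
  vb <- runif(1, 0, 0.3)
  kinetic_params(K1, k2, k3, vb)
}

# isotropic Gaussian blob on a cubic grid
gaussian_blob <- function(n = 41, sd_vox = 3) {
  ctr <- (n + 1) / 2
  d2 <- outer(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"),
              (seq_len(n) - ctr)^2, "+")
  exp(-d2 / (2 * sd_vox^2))
}

# small single-organ phantom for fast image-level tests
tiny_phantom <- function(glucose = 5.5) {
  organs <- organ_kinetic_defaults(glucose = glucose)
  regions <- list(
    tissue = list(geometry = list(type = "box", lo_mm = c(10, 10, 10),
                                  hi_mm = c(50, 50, 50)),
                  params = kinetic_params_from_row(organs[organs$organ == "liver", ])),
    aorta = list(geometry = list(type = "box", lo_mm = c(60, 60, 10),
                                 hi_mm = c(70, 70, 60)), params = "blood"))
  phantom_spec(shape = c(20L, 20L, 20L), voxel_mm = 4, regions = regions,
               blood_glucose = glucose)
}
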