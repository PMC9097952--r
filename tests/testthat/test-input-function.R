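test_that("IDIF extraction equals the frame-averaged plasma curve on noiseless data", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  s <- build_schedule("standard")
  img <- render_phantom(spec, f, s, noise_model(0, 1L))
  amask <- img$labels == match("aorta", img$region_names)
  idif <- extract_idif(img, amask)
  expect_equal(idif$activity, frame_average(f, s)$activity)
  expect_identical(attr(idif, "source"), "aorta_idif")
  # one-voxel VOI returns that voxel's series
  one <- which(amask)[1]
  idif1 <- extract_idif(img, one)
  expect_equal(idif1$activity, matrix(img$data, prod(dim(img$labels)))[one, ])
  expect_error(extract_idif(img, integer(0)), "empty")
})

test_that("VOI averaging shrinks IDIF noise roughly as 1/sqrt(n voxels)", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  s <- build_schedule("two_short")
  truth <- frame_average(f, s)$activity
  amask <- NULL
  err_mean <- c(); err_one <- c()
  for (seed in 1:12) {
    img <- render_phantom(spec, f, s, noise_model(0.5, seed))
    if (is.null(amask)) amask <- img$labels == match("aorta", img$region_names)
    voi100 <- which(amask)[1:100]
    e_m <- extract_idif(img, voi100)$activity - truth
    e_1 <- extract_idif(img, which(amask)[1])$activity - truth
    err_mean <- c(err_mean, e_m)
    err_one <- c(err_one, e_1)
  }
  ratio <- stats::sd(err_one) / stats::sd(err_mean)
  expect_gt(ratio, 7)
  expect_lt(ratio, 13)
})

test_that("merge and split are inverses and validate their inputs", {
  f <- input_function("feng4")
  s <- build_schedule("two_short")
  full <- frame_average(f, s, source = "merged")
  halves <- split_tac(full, at = 6)
  back <- merge_tacs(halves$early, halves$late)
  expect_equal(back$start, full$start)
  expect_equal(back$activity, full$activity)
  expect_identical(attr(back, "source"), "merged")
  expect_error(merge_tacs(halves$late, halves$early), "overlap|order")
  # merging the standard sub-curves reproduces the standard IDIF restricted
  std <- frame_average(f, build_schedule("standard"), source = "aorta_idif")
  keep <- std$end <= 6 + 1e-9 | std$start >= 60 - 1e-9
  restricted <- new_tac(std$start[keep], std$end[keep], std$activity[keep])
  expect_equal(back$activity, restricted$activity)
})

test_that("the TAC CSV dialect round-trips bit-exactly", {
  f <- input_function("feng4")
  tac <- frame_average(f, build_schedule("two_short"), source = "merged")
  path <- file.path(tempdir(), "tac_roundtrip.csv")
  write_tac_csv(tac, path)
  raw <- readLines(path)
  expect_identical(raw[1], "frame_start_s,frame_end_s,activity_kBq_ml")
  expect_false(any(grepl(",,|;", raw)))
  back <- read_tac_csv(path)
  expect_identical(back$start, tac$start)
  expect_identical(back$end, tac$end)
  expect_identical(back$activity, tac$activity)
  unlink(path)
  bad <- file.path(tempdir(), "bad.csv")
  utils::write.csv(data.frame(a = 1, b = 2), bad, row.names = FALSE)
  expect_error(read_tac_csv(bad), "TAC CSV")
  unlink(bad)
})

test_that("gap model recovers tri-exponential truth from the two windows alone", {
  truth_A <- c(60, 15, 8)
  truth_L <- c(2.5, 0.12, 0.012)
  f <- input_function("tri_exponential", amplitudes = truth_A, rates = truth_L)
  tac <- frame_average(f, build_schedule("two_short"), source = "merged")
  g <- fit_gap_model(tac, family = "tri_exponential")
  expect_true(g$converged)
  expect_lt(max(abs(g$coefficients$rates / truth_L - 1)), 0.01)
  expect_lt(max(abs(g$coefficients$amplitudes / truth_A - 1)), 0.01)
})

test_that("degenerate and noisy gap fits behave sensibly", {
  # constant tac: reduced model with rate ~ 0 and the constant value
  ct <- new_tac(c(0:5, 60:74), c(1:6, 61:75), c(7, rep(5, 20)))
  g <- fit_gap_model(ct, family = "tri_exponential")
  expect_equal(gap_value(g, 30), 5, tolerance = 1e-6)
  # two noise seeds: coefficients differ, fitted late curve agrees to noise scale
  f <- input_function("feng4")
  s <- build_schedule("two_short")
  base <- frame_average(f, s, source = "merged")
  fits <- lapply(c(101, 202), function(seed) {
    set.seed(seed)
    noisy <- new_tac(base$start, base$end,
                     pmax(base$activity + rnorm(nrow(base), 0, 0.15), 0),
                     source = "merged")
    fit_gap_model(noisy)
  })
  late <- seq(60, 75, by = 1)
  expect_lt(max(abs(gap_value(fits[[1]], late) - gap_value(fits[[2]], late))), 0.5)
})

test_that("all three gap families bridge a noiseless merged TAC", {
  f <- input_function("feng4")
  tac <- frame_average(f, build_schedule("two_short"), source = "merged")
  exact <- integrate_input(f, 67.5)
  for (fam in c("tri_exponential", "input_model_refit")) {
    g <- fit_gap_model(tac, family = fam)
    got <- cumulative_plasma_integral(tac, g, 67.5)
    expect_lt(abs(got - exact) / exact, 0.02)
  }
  g <- fit_gap_model(tac, family = "loglinear_bridge")
  got <- cumulative_plasma_integral(tac, g, 67.5)
  expect_lt(abs(got - exact) / exact, 0.15)  # crude bridge, order-of-magnitude only
})

test_that("cumulative plasma integral: trapezoid limits, monotonicity, gap continuity", {
  # fully sampled constant TAC integrates to c * t
  ct <- new_tac(0:74, 1:75, rep(2, 75))
  expect_equal(cumulative_plasma_integral(ct, NULL, c(0, 7.25, 75)),
               2 * c(0, 7.25, 75))
  expect_identical(cumulative_plasma_integral(ct, NULL, 0), 0)
  # two-short TAC without a model cannot be integrated across the gap
  f <- input_function("feng4")
  tac <- frame_average(f, build_schedule("two_short"), source = "merged")
  expect_error(cumulative_plasma_integral(tac, NULL, 67.5), "gap model")
  # with a model: monotone, and continuous at the gap boundaries
  g <- fit_gap_model(tac)
  tt <- seq(0, 75, by = 0.25)
  vv <- cumulative_plasma_integral(tac, g, tt)
  expect_true(all(diff(vv) >= -1e-9))
  m <- tac_midpoints(tac)
  b0 <- max(m[m < 50]); b1 <- min(m[m > 50])
  for (b in c(b0, b1)) {
    lo <- cumulative_plasma_integral(tac, g, b - 1e-6)
    hi <- cumulative_plasma_integral(tac, g, b + 1e-6)
    expect_lt(abs(hi - lo), 1e-3)
  }
})

test_that("gap models serialize to JSON with family, coefficients and diagnostics", {
  f <- input_function("feng4")
  tac <- frame_average(f, build_schedule("two_short"), source = "merged")
  g <- fit_gap_model(tac)
  path <- file.path(tempdir(), "gap.json")
  write_gap_model(g, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$family, "tri_exponential")
  expect_equal(back$coefficients$amplitudes, g$coefficients$amplitudes)
  expect_true(is.numeric(back$residual_norm))
  unlink(path)
})
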