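test_that("Patlak coordinates behave as ratio identities", {
  f <- input_function("feng4")
  s <- build_schedule("standard")
  idif <- frame_average(f, s, source = "aorta_idif")
  # tissue identical to plasma: y = 1 for every late frame
  pts <- patlak_points(idif, idif)
  expect_equal(pts$y, rep(1, 3))
  # zero tissue: y = 0
  zero <- new_tac(idif$start, idif$end, rep(0, nrow(idif)))
  expect_equal(patlak_points(zero, idif)$y, rep(0, 3))
  # mismatched frames rejected
  short <- new_tac(idif$start[1:10], idif$end[1:10], idif$activity[1:10])
  expect_error(patlak_points(short, idif), "share")
})

test_that("noiseless two-tissue curves give Patlak slope near the asymptote", {
  f <- input_function("feng4")
  s <- build_schedule("standard")
  idif <- frame_average(f, s, source = "aorta_idif")
  p <- kinetic_params(0.1, 0.15, 0.05, 0.05)
  tt <- frame_average(tissue_curve(p, f), s)
  pts <- patlak_points(tt, idif)
  fit <- fit_line(pts, glucose = 5.5)
  expect_lt(abs(fit$ki - 0.025) / 0.025, 0.02)
  # the three points are nearly collinear
  resid <- pts$y - (fit$v + fit$ki * pts$x)
  expect_lt(max(abs(resid)), 1e-3 * max(pts$y))
  expect_equal(fit$mr_fdg, fit$ki * 5.5)
})

test_that("line fitting matches closed-form OLS and flags degenerate input", {
  pts <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6))
  fit <- fit_line(pts)
  expect_equal(fit$ki, 2)
  expect_equal(fit$v, 0)
  flat <- fit_line(data.frame(x = c(1, 2, 3), y = c(4, 4, 4)))
  expect_equal(flat$ki, 0)
  expect_equal(flat$v, 4)
  set.seed(9)
  for (rep in 1:10) {
    pts <- data.frame(x = runif(3, 1, 100), y = runif(3))
    fit <- fit_line(pts)
    ref <- stats::coef(stats::lm(y ~ x, data = pts))
    expect_equal(fit$v, unname(ref[1]), tolerance = 1e-10)
    expect_equal(fit$ki, unname(ref[2]), tolerance = 1e-10)
  }
  bad <- fit_line(data.frame(x = c(1, NA, NA), y = c(1, NA, NA)))
  expect_false(bad$valid)
  expect_true(is.na(bad$ki))
})

test_that("parametric maps recover regional truth on a noiseless phantom", {
  spec <- default_phantom_spec()
  f <- input_function("feng4")
  s <- build_schedule("standard")
  img <- render_phantom(spec, f, s, noise_model(0, 1L))
  idif <- extract_idif(img, img$labels == match("aorta", img$region_names))
  expect_warning(maps <- make_maps(img, idif, glucose = 5.5), "SUV")
  organs <- organ_kinetic_defaults(glucose = 5.5)
  for (i in seq_len(nrow(organs))) {
    nm <- organs$organ[i]
    if (!nm %in% img$region_names) next
    mask <- img$labels == match(nm, img$region_names)
    p <- kinetic_params_from_row(organs[i, ])
    mr_true <- 5.5 * p$ki_true
    expect_lt(abs(mean(maps$mr[mask]) - mr_true), 0.02 * mr_true + 1e-9)
  }
  # aorta voxels: pure blood, y ~ 1 and slope ~ 0, so DV ~ 100%
  amask <- img$labels == match("aorta", img$region_names)
  expect_equal(mean(maps$dv[amask]), 100, tolerance = 0.02)
  expect_lt(max(abs(maps$ki[amask])), 1e-4)
})

test_that("maps scale linearly with glucose and support SUV output", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  s <- build_schedule("standard")
  img <- render_phantom(spec, f, s, noise_model(0, 1L))
  idif <- extract_idif(img, img$labels == match("aorta", img$region_names))
  m1 <- make_maps(img, idif, glucose = 5, dose_MBq = 260, weight_kg = 70)
  m2 <- make_maps(img, idif, glucose = 10, dose_MBq = 260, weight_kg = 70)
  expect_equal(m2$mr, 2 * m1$mr)
  expect_equal(m2$dv, m1$dv)
  expect_true(all(m1$suv >= 0))
  # SUV from the last three frames: mean activity * weight / dose
  last3 <- dim(img$data)[4] - 2:0
  ref <- apply(img$data[, , , last3], 1:3, mean) * 70 / 260
  expect_equal(m1$suv, ref, tolerance = 1e-12)
})

test_that("standard and two-short maps agree voxel-wise on noiseless data", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  full <- render_phantom(spec, f, build_schedule("standard"), noise_model(0, 1L))
  short <- subset_frames(full, build_schedule("two_short"))
  amask <- full$labels == match("aorta", full$region_names)
  idif_std <- extract_idif(full, amask)
  idif_tsd <- extract_idif(short, amask)
  gap <- fit_gap_model(idif_tsd)
  m_std <- suppressWarnings(make_maps(full, idif_std, glucose = 5.5))
  m_tsd <- suppressWarnings(make_maps(short, idif_tsd, g = gap, glucose = 5.5))
  tmask <- full$labels == match("tissue", full$region_names)
  rel <- abs(m_tsd$ki[tmask] - m_std$ki[tmask]) / abs(m_std$ki[tmask])
  expect_lt(max(rel), 0.02)
})

test_that("parametric maps persist as NIfTI with provenance", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  img <- render_phantom(spec, f, build_schedule("standard"), noise_model(0, 1L))
  idif <- extract_idif(img, img$labels == match("aorta", img$region_names))
  maps <- make_maps(img, idif, glucose = 5.5, dose_MBq = 260, weight_kg = 70)
  prefix <- file.path(tempdir(), "maps_test")
  write_maps(maps, prefix)
  mr_back <- RNifti::readNifti(paste0(prefix, "_mr.nii.gz"))
  expect_equal(array(as.numeric(mr_back), dim(maps$mr)), maps$mr, tolerance = 1e-12)
  prov <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_identical(prov$protocol, "standard")
  unlink(paste0(prefix, c("_mr.nii.gz", "_dv.nii.gz", "_suv.nii.gz", ".json")))
})
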