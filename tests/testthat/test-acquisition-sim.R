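test_that("standard schedule reproduces the published protocol structure", {
  s <- build_schedule("standard")
  durs <- s$end - s$start
  expect_equal(sum(durs == 2), 5)    # five 2-min passes
  expect_equal(sum(durs == 5), 11)   # eleven 5-min passes
  last3 <- utils::tail(s, 3)
  expect_equal(last3$start, c(60, 65, 70))
  expect_equal(last3$end, c(65, 70, 75))
  # cardiac sub-frames tile [0, 6)
  cardiac <- s[s$end <= 6 + 1e-9, ]
  expect_equal(cardiac$start[1], 0)
  expect_equal(max(cardiac$end), 6)
  expect_true(all(abs(utils::tail(cardiac$start, -1) - utils::head(cardiac$end, -1)) < 1e-12))
  # frames strictly increasing, non-overlapping
  expect_true(all(diff(s$start) > 0))
  expect_true(all(utils::tail(s$start, -1) >= utils::head(s$end, -1) - 1e-12))
})

test_that("two-short schedule is the standard subset covering 0-6 and 60-75 min", {
  s <- build_schedule("two_short")
  std <- build_schedule("standard")
  expect_true(all(s$end <= 6 + 1e-9 | s$start >= 60 - 1e-9))
  expect_equal(sum((s$end - s$start)[s$end <= 6 + 1e-9]), 6)
  expect_equal(sum((s$end - s$start)[s$start >= 60 - 1e-9]), 15)
  key <- function(d) paste(d$start, d$end)
  expect_true(all(key(s) %in% key(std)))
  expect_error(build_schedule("standard", cardiac_subframes = rep(5, 10)), "tile")
})

test_that("frame averages equal adaptive quadrature of the continuous curve", {
  f <- input_function("feng4")
  s <- build_schedule("standard")
  fa <- frame_average(f, s)
  check <- c(1, 5, 13, 21, 29, nrow(s))   # spread over sub-frames and passes
  for (k in check) {
    expect_lt(abs(fa$activity[k] - quad_frame_mean(f, s$start[k], s$end[k])) /
                max(fa$activity[k], 1e-12), 1e-8)
  }
  # near-constant curve: every frame equals the constant
  const <- input_function("tri_exponential", amplitudes = c(3, 0, 0),
                          rates = c(1e-9, 1, 1))
  fc <- frame_average(const, s)
  expect_equal(fc$activity, rep(3, nrow(s)), tolerance = 1e-6)
})

test_that("noiseless phantom rendering is exact and reproducible", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  s <- build_schedule("two_short")
  img <- render_phantom(spec, f, s, noise_model(0, 1L))
  img2 <- render_phantom(spec, f, s, noise_model(0, 99L))
  expect_identical(img$data, img2$data)  # sigma0 = 0 ignores the seed
  # aorta voxels carry the frame-averaged plasma curve exactly
  amask <- img$labels == match("aorta", img$region_names)
  fa <- frame_average(f, s)
  for (k in c(1, 10, nrow(s))) {
    vox <- img$data[, , , k][amask]
    expect_equal(unique(vox), fa$activity[k])
  }
  # zero-kinetics region renders to zero
  spec0 <- spec
  spec0$regions$tissue$params <- kinetic_params(0, 0.1, 0.05, 0)
  img0 <- render_phantom(spec0, f, s, noise_model(0, 1L))
  tmask <- img0$labels == match("tissue", img0$region_names)
  expect_true(all(img0$data[, , , 5][tmask] == 0))
})

test_that("noisy rendering is seed-deterministic and rejects overlapping regions", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  s <- build_schedule("two_short")
  a <- render_phantom(spec, f, s, noise_model(0.5, 11L))
  b <- render_phantom(spec, f, s, noise_model(0.5, 11L))
  expect_identical(a$data, b$data)
  c2 <- render_phantom(spec, f, s, noise_model(0.5, 12L))
  expect_false(identical(a$data, c2$data))
  bad <- spec
  bad$regions$tissue$geometry$hi_mm <- c(70, 70, 70)  # now covers the aorta
  expect_error(render_phantom(bad, f, s, noise_model(0, 1L)), "overlap")
})

test_that("restricting a standard acquisition equals simulating two-short directly", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  nm <- noise_model(0.4, 21L)
  full <- render_phantom(spec, f, build_schedule("standard"), nm)
  direct <- render_phantom(spec, f, build_schedule("two_short"), nm)
  sub <- subset_frames(full, build_schedule("two_short"))
  expect_identical(sub$data, direct$data)
})

test_that("noise standard deviation scales as 1/sqrt(frame duration)", {
  # one uniform-activity region observed under 1-min and 4-min frames;
  # thousands of voxels give the empirical sd to well under 5%
  organs <- organ_kinetic_defaults()
  regions <- list(
    tissue = list(geometry = list(type = "box", lo_mm = c(2, 2, 2),
                                  hi_mm = c(78, 78, 78)),
                  params = kinetic_params_from_row(organs[organs$organ == "liver", ])),
    aorta = list(geometry = list(type = "box", lo_mm = c(90, 90, 2),
                                 hi_mm = c(94, 94, 78)), params = "blood"))
  spec <- phantom_spec(shape = c(24L, 24L, 24L), voxel_mm = 4, regions = regions)
  f <- input_function("feng4")
  s <- structure(data.frame(start = c(60, 61), end = c(61, 65)),
                 protocol = "standard", class = c("frame_schedule", "data.frame"))
  img <- render_phantom(spec, f, s, noise_model(0.6, 5L))
  img0 <- render_phantom(spec, f, s, noise_model(0, 5L))
  tmask <- img$labels == match("tissue", img$region_names)
  sd1 <- stats::sd((img$data[, , , 1] - img0$data[, , , 1])[tmask])
  sd4 <- stats::sd((img$data[, , , 2] - img0$data[, , , 2])[tmask])
  expect_equal(sd1 / sd4, 2, tolerance = 0.05)
})

test_that("dynamic images round-trip through NIfTI plus JSON sidecar", {
  spec <- tiny_phantom()
  f <- input_function("feng4")
  s <- build_schedule("two_short")
  img <- render_phantom(spec, f, s, noise_model(0.3, 2L))
  prefix <- file.path(tempdir(), "dynimg_test")
  write_dynamic_image(img, prefix)
  back <- read_dynamic_image(prefix)
  expect_equal(back$data, img$data, tolerance = 1e-12)
  expect_equal(back$schedule$start, img$schedule$start)
  expect_equal(back$schedule$end, img$schedule$end)
  expect_identical(schedule_protocol <- attr(back$schedule, "protocol"), "two_short")
  expect_equal(back$voxel_mm, img$voxel_mm)
  unlink(paste0(prefix, c(".nii.gz", ".json")))
})
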