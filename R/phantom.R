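#' Noise model for framed PET images
#'
#' Zero-mean Gaussian image-space noise whose standard deviation per voxel
#' and frame is \eqn{\sigma_0 \sqrt{\bar A / \Delta t}}, where \eqn{\bar A}
#' is the voxel's noiseless frame activity (kBq/ml) and \eqn{\Delta t} the
#' frame duration (min). This reproduces the count-statistics scaling of
#' reconstructed PET: variance proportional to activity and inversely
#' proportional to frame duration.
#'
#' @param sigma0 noise scale at 1 kBq/ml and a 1-min frame, kBq/ml.
#' @param seed integer seed; noise is drawn per frame from a seed derived
#'   from `seed` and the frame start time, so restricting a standard-protocol
#'   simulation to the two-short frames is bit-identical to simulating the
#'   two-short protocol directly.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma0 = 0.4, seed = 1L) {
  stopifnot(is.numeric(sigma0), sigma0 >= 0, is.numeric(seed))
  structure(list(sigma0 = sigma0, seed = as.integer(seed)), class = "noise_model")
}

frame_noise_seed <- function(seed, start_s) {
  as.integer((abs(as.integer(seed)) %% 1000000L) * 2011L + as.integer(round(start_s)))
}

#' Digital whole-body phantom specification
#'
#' A voxel grid plus labelled regions, each a sphere or box carrying its own
#' [kinetic_params()]; exactly one region is flagged as the aorta
#' (input-function source) and holds pure arterial blood (its activity is
#' \eqn{C_p(t)} itself).
#'
#' @param shape integer grid dimensions (voxels), length 3.
#' @param voxel_mm isotropic voxel size, mm.
#' @param regions named list; each element is a list with `geometry`
#'   (`list(type = "sphere", center_mm =, diameter_mm =)` or
#'   `list(type = "box", lo_mm =, hi_mm =)`) and `params` (a
#'   [kinetic_params()], or the string `"blood"` for the aorta).
#' @param aorta name of the aorta region.
#' @param blood_glucose blood glucose, mmol/L.
#' @return object of class `phantom_spec`.
#' @seealso [default_phantom_spec()] for a ready-made whole-body layout.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), voxel_mm = 4,
                         regions, aorta = "aorta", blood_glucose = 5.5) {
  stopifnot(length(shape) == 3, all(shape >= 1), voxel_mm > 0,
            is.list(regions), length(regions) >= 1)
  if (is.null(names(regions)) || anyDuplicated(names(regions))) {
    stop("regions must be uniquely named")
  }
  if (!aorta %in% names(regions)) stop("aorta region not found among regions")
  n_blood <- sum(vapply(regions, function(r) identical(r$params, "blood"), logical(1)))
  if (n_blood != 1 || !identical(regions[[aorta]]$params, "blood")) {
    stop("exactly one region (the aorta) must carry blood kinetics")
  }
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 regions = regions, aorta = aorta,
                 blood_glucose = blood_glucose),
            class = "phantom_spec")
}

# voxel-center coordinates (mm) along one axis
voxel_centers <- function(n, voxel_mm) (seq_len(n) - 0.5) * voxel_mm

region_mask <- function(geometry, shape, voxel_mm) {
  cx <- voxel_centers(shape[1], voxel_mm)
  cy <- voxel_centers(shape[2], voxel_mm)
  cz <- voxel_centers(shape[3], voxel_mm)
  if (geometry$type == "sphere") {
    ctr <- geometry$center_mm
    r <- geometry$diameter_mm / 2
    dx2 <- (cx - ctr[1])^2
    dy2 <- (cy - ctr[2])^2
    dz2 <- (cz - ctr[3])^2
    arr <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
  } else if (geometry$type == "box") {
    inx <- cx >= geometry$lo_mm[1] & cx <= geometry$hi_mm[1]
    iny <- cy >= geometry$lo_mm[2] & cy <= geometry$hi_mm[2]
    inz <- cz >= geometry$lo_mm[3] & cz <= geometry$hi_mm[3]
    arr <- outer(outer(inx, iny, "&"), inz, "&")
  } else {
    stop("unknown geometry type: ", geometry$type)
  }
  arr
}

#' Default whole-body phantom layout
#'
#' Seven normal organs (brain, lungs, liver, spleen, heart wall, bone,
#' muscle), a descending-aorta blood column and optional spherical lesions
#' on a 48×48×48 grid of 4-mm voxels. Organ kinetics default to
#' [organ_kinetic_defaults()]; pass `organ_table` to override per-subject
#' values.
#'
#' @param organ_table data.frame in the format of [organ_kinetic_defaults()]
#'   (rows `brain` ... `muscle` are used).
#' @param lesions optional list; each element
#'   `list(center_mm =, diameter_mm =, params = kinetic_params)`.
#' @param shape,voxel_mm grid geometry.
#' @param blood_glucose blood glucose, mmol/L.
#' @return a [phantom_spec()].
#' @export
default_phantom_spec <- function(organ_table = organ_kinetic_defaults(),
                                 lesions = list(),
                                 shape = c(48L, 48L, 48L), voxel_mm = 4,
                                 blood_glucose = 5.5) {
  kp <- function(organ) {
    row <- organ_table[organ_table$organ == organ, ]
    if (nrow(row) != 1) stop("organ_table is missing organ: ", organ)
    kinetic_params_from_row(row)
  }
  regions <- list(
    brain = list(geometry = list(type = "sphere", center_mm = c(96, 96, 164),
                                 diameter_mm = 48), params = kp("brain")),
    lung = list(geometry = list(type = "box", lo_mm = c(104, 60, 92),
                                hi_mm = c(152, 132, 128)), params = kp("lung")),
    heart_wall = list(geometry = list(type = "sphere", center_mm = c(68, 96, 110),
                                      diameter_mm = 36), params = kp("heart_wall")),
    liver = list(geometry = list(type = "sphere", center_mm = c(70, 70, 56),
                                 diameter_mm = 52), params = kp("liver")),
    spleen = list(geometry = list(type = "sphere", center_mm = c(144, 144, 56),
                                  diameter_mm = 30), params = kp("spleen")),
    bone = list(geometry = list(type = "box", lo_mm = c(24, 20, 8),
                                hi_mm = c(168, 40, 28)), params = kp("bone")),
    muscle = list(geometry = list(type = "box", lo_mm = c(148, 148, 140),
                                  hi_mm = c(184, 184, 184)), params = kp("muscle")),
    aorta = list(geometry = list(type = "box", lo_mm = c(90, 142, 40),
                                 hi_mm = c(98, 150, 140)), params = "blood")
  )
  if (length(lesions)) {
    for (i in seq_along(lesions)) {
      les <- lesions[[i]]
      regions[[paste0("lesion", i)]] <-
        list(geometry = list(type = "sphere", center_mm = les$center_mm,
                             diameter_mm = les$diameter_mm),
             params = les$params)
    }
  }
  phantom_spec(shape = shape, voxel_mm = voxel_mm, regions = regions,
               aorta = "aorta", blood_glucose = blood_glucose)
}

# spots known to be clear of the default organ layout, for placing lesions
lesion_candidate_centers <- function() {
  list(c(40, 150, 150), c(150, 40, 156), c(40, 40, 150),
       c(160, 96, 24), c(28, 96, 130), c(96, 30, 96))
}

#' Render a framed, noisy dynamic PET volume
#'
#' Every voxel of a region carries the exact frame-averaged activity of the
#' region's tissue curve (the aorta carries the frame-averaged plasma
#' curve); Gaussian noise per the [noise_model()] is then added frame by
#' frame. Regions may not overlap.
#'
#' @param spec a [phantom_spec()].
#' @param f an [input_function()].
#' @param s a [build_schedule()] schedule.
#' @param noise a [noise_model()]; use `sigma0 = 0` for noiseless volumes.
#' @return a `dynamic_image`: list with 4D `data` (x, y, z, frame; kBq/ml),
#'   `schedule`, `voxel_mm`, `glucose`, integer `labels` volume and
#'   `region_names`.
#' @export
render_phantom <- function(spec, f, s, noise = noise_model(0, 1L)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(f, "input_function"),
            inherits(s, "frame_schedule"), inherits(noise, "noise_model"))
  shape <- spec$shape
  nvox <- prod(shape)
  nf <- nrow(s)
  lab <- array(0L, dim = shape)
  region_names <- names(spec$regions)
  for (i in seq_along(spec$regions)) {
    m <- region_mask(spec$regions[[i]]$geometry, shape, spec$voxel_mm)
    if (!any(m)) stop("region lies outside the grid: ", region_names[i])
    if (any(lab[m] != 0L)) {
      stop("overlapping regions: ", region_names[i], " and ",
           region_names[lab[m][lab[m] != 0L][1]])
    }
    lab[m] <- i
  }
  truth <- matrix(0, nvox, nf)
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    tac <- if (identical(r$params, "blood")) {
      frame_average(f, s, source = "aorta_idif")
    } else {
      frame_average(tissue_curve(r$params, f), s)
    }
    idx <- which(lab == i)
    truth[idx, ] <- rep(tac$activity, each = length(idx))
  }
  data <- truth
  if (noise$sigma0 > 0) {
    dt <- s$end - s$start
    start_s <- round(s$start * 60)
    for (j in seq_len(nf)) {
      sd_j <- noise$sigma0 * sqrt(pmax(truth[, j], 0) / dt[j])
      rng <- local({
        set.seed(frame_noise_seed(noise$seed, start_s[j]))
        stats::rnorm(nvox)
      })
      data[, j] <- truth[, j] + rng * sd_j
    }
  }
  structure(list(data = array(data, dim = c(shape, nf)), schedule = s,
                 voxel_mm = spec$voxel_mm, glucose = spec$blood_glucose,
                 labels = lab, region_names = region_names,
                 aorta = spec$aorta, seed = noise$seed, sigma0 = noise$sigma0),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat("<dynamic_image>", paste(dim(x$data), collapse = " x "),
      sprintf("@ %g mm, protocol %s\n", x$voxel_mm, schedule_protocol(x$schedule)))
  invisible(x)
}

#' Restrict a dynamic image to another protocol's frames
#'
#' Selects the frames of `img` whose intervals appear in `s`. Because both
#' study arms come from one 75-min session, the two-short-dynamic dataset is
#' exactly the standard dataset restricted to the 0–6 min and 60–75 min
#' frames.
#'
#' @param img a [render_phantom()] image.
#' @param s the target [build_schedule()] schedule (a subset of the image's).
#' @return a `dynamic_image` over the frames of `s`.
#' @export
subset_frames <- function(img, s) {
  stopifnot(inherits(img, "dynamic_image"), inherits(s, "frame_schedule"))
  key <- function(df) paste(round(df$start * 60), round(df$end * 60))
  idx <- match(key(s), key(img$schedule))
  if (anyNA(idx)) stop("target schedule contains frames absent from the image")
  out <- img
  out$data <- img$data[, , , idx, drop = FALSE]
  out$schedule <- s
  out
}

#' Write / read a dynamic image as NIfTI plus a JSON timing sidecar
#'
#' The 4D volume is stored as NIfTI-1 (`<prefix>.nii.gz`) and the frame
#' schedule, voxel size, protocol and noise seed in `<prefix>.json`.
#'
#' @param img a `dynamic_image`.
#' @param prefix output path without extension.
#' @return `write_dynamic_image`: the prefix, invisibly;
#'   `read_dynamic_image`: a `dynamic_image` (without phantom labels).
#' @export
write_dynamic_image <- function(img, prefix) {
  stopifnot(inherits(img, "dynamic_image"))
  vol <- RNifti::asNifti(img$data, pixdim = c(rep(img$voxel_mm, 3), 1))
  RNifti::writeNifti(vol, paste0(prefix, ".nii.gz"))
  sidecar <- list(frame_start_s = round(img$schedule$start * 60),
                  frame_end_s = round(img$schedule$end * 60),
                  protocol = schedule_protocol(img$schedule),
                  voxel_mm = img$voxel_mm, glucose = img$glucose,
                  seed = img$seed, sigma0 = img$sigma0)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(prefix) {
  vol <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  frames <- data.frame(start = meta$frame_start_s / 60, end = meta$frame_end_s / 60)
  s <- structure(frames, protocol = meta$protocol,
                 class = c("frame_schedule", "data.frame"))
  structure(list(data = array(as.numeric(vol), dim = dim(vol)), schedule = s,
                 voxel_mm = meta$voxel_mm, glucose = meta$glucose,
                 labels = NULL, region_names = NULL, aorta = NULL,
                 seed = meta$seed, sigma0 = meta$sigma0),
            class = "dynamic_image")
}
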