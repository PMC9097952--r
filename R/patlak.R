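#' Patlak transformation of a tissue TAC
#'
#' For each of the last `n_frames` frames (midpoint \eqn{t_k}) compute the
#' Patlak coordinates
#' \deqn{x_k = \int_0^{t_k} C_p\,d\tau \;/\; C_p(t_k), \qquad
#'       y_k = C_t(t_k) / C_p(t_k).}
#' After equilibration the points lie on a line with slope \eqn{K_i} and
#' intercept \eqn{V}. Frames with non-positive plasma activity yield `NA`
#' coordinates.
#'
#' @param tissue tissue [new_tac()]; its last `n_frames` frames must match
#'   the input function's.
#' @param input the IDIF [new_tac()].
#' @param g optional [fit_gap_model()] for TACs with an unsampled interval.
#' @param n_frames number of late frames used (default 3).
#' @return data.frame with columns `t`, `x`, `y`, `cp`.
#' @export
patlak_points <- function(tissue, input, g = NULL, n_frames = 3) {
  stopifnot(inherits(tissue, "tac"), inherits(input, "tac"))
  kt <- nrow(tissue) - n_frames + seq_len(n_frames)
  ki <- nrow(input) - n_frames + seq_len(n_frames)
  if (kt[1] < 1 || ki[1] < 1) stop("not enough frames for the Patlak fit")
  if (max(abs(tissue$start[kt] - input$start[ki])) > 1e-9 ||
      max(abs(tissue$end[kt] - input$end[ki])) > 1e-9) {
    stop("tissue and input TACs must share the late frames")
  }
  tk <- tac_midpoints(input)[ki]
  cp <- input$activity[ki]
  xint <- cumulative_plasma_integral(input, g, tk)
  ok <- cp > 0
  x <- ifelse(ok, xint / cp, NA_real_)
  y <- ifelse(ok, tissue$activity[kt] / cp, NA_real_)
  data.frame(t = tk, x = x, y = y, cp = cp)
}

#' Ordinary least-squares line through Patlak points
#'
#' @param points data.frame from [patlak_points()] (columns `x`, `y`).
#' @param glucose blood glucose, mmol/L; scales `ki` to the metabolic rate
#'   `mr_fdg` = `ki` × glucose (µmol/min/ml).
#' @return object of class `patlak_fit`: `ki` (1/min, slope), `v`
#'   (unitless intercept), `mr_fdg`, `dv_percent` (= 100 `v`), `n_points`
#'   and the points used. With fewer than 2 valid points the fit is marked
#'   invalid (`NA` estimates).
#' @export
fit_line <- function(points, glucose = NA_real_) {
  ok <- is.finite(points$x) & is.finite(points$y)
  out <- list(ki = NA_real_, v = NA_real_, mr_fdg = NA_real_,
              dv_percent = NA_real_, n_points = sum(ok), points = points,
              glucose = glucose, valid = FALSE)
  class(out) <- "patlak_fit"
  if (sum(ok) < 2) return(out)
  x <- points$x[ok]; y <- points$y[ok]
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) return(out)
  out$ki <- sum((x - xb) * (y - yb)) / sxx
  out$v <- yb - out$ki * xb
  out$mr_fdg <- out$ki * glucose
  out$dv_percent <- 100 * out$v
  out$valid <- TRUE
  out
}

#' @export
print.patlak_fit <- function(x, ...) {
  if (!x$valid) {
    cat("<patlak_fit> invalid (", x$n_points, "valid points )\n")
  } else {
    cat(sprintf("<patlak_fit> Ki = %.5g /min, V = %.4g (MR_FDG = %.4g, DV = %.4g%%)\n",
                x$ki, x$v, x$mr_fdg, x$dv_percent))
  }
  invisible(x)
}

#' Voxel-wise parametric maps from the last three frames
#'
#' Applies the Patlak transform and line fit to every voxel of a dynamic
#' image, producing the metabolic-rate map `mr` (= Ki × glucose,
#' µmol/min/ml), the distribution-volume map `dv` (percent) and, when the
#' injected dose and body weight are supplied, the static SUV map from the
#' mean of the last three frames. Both acquisition protocols run through
#' this identical code path; only the input-function integral differs.
#'
#' @param img a [render_phantom()] / [read_dynamic_image()] image covering
#'   the last three frames.
#' @param input the IDIF [new_tac()] for the corresponding protocol.
#' @param g optional [fit_gap_model()] (two-short protocol).
#' @param glucose blood glucose, mmol/L.
#' @param dose_MBq,weight_kg injected activity and body weight for SUV
#'   scaling; if missing the SUV map is omitted with a warning.
#' @param n_frames number of late frames used (default 3).
#' @return object of class `parametric_maps`: 3D arrays `mr`, `dv`,
#'   `ki`, `v`, optionally `suv`, plus `provenance`. Invalid voxels are
#'   `NaN`.
#' @export
make_maps <- function(img, input, g = NULL, glucose = img$glucose,
                      dose_MBq = NULL, weight_kg = NULL, n_frames = 3) {
  stopifnot(inherits(img, "dynamic_image"), inherits(input, "tac"))
  s <- img$schedule
  nf <- nrow(s)
  kt <- nf - n_frames + seq_len(n_frames)
  ki_idx <- nrow(input) - n_frames + seq_len(n_frames)
  if (max(abs(s$start[kt] - input$start[ki_idx])) > 1e-9) {
    stop("image and input function do not share the late frames")
  }
  tk <- tac_midpoints(input)[ki_idx]
  cp <- input$activity[ki_idx]
  if (any(cp <= 0)) stop("non-positive plasma activity in the fit frames")
  x <- cumulative_plasma_integral(input, g, tk) / cp
  xb <- mean(x)
  sxx <- sum((x - xb)^2)
  shape <- dim(img$data)[1:3]
  frames <- matrix(img$data[, , , kt], prod(shape), n_frames)
  y <- sweep(frames, 2, cp, "/")
  yb <- rowMeans(y)
  ki_map <- as.vector(y %*% (x - xb)) / sxx
  v_map <- yb - ki_map * xb
  bad <- !is.finite(ki_map) | !is.finite(v_map)
  ki_map[bad] <- NaN
  v_map[bad] <- NaN
  out <- list(
    ki = array(ki_map, shape),
    v = array(v_map, shape),
    mr = array(ki_map * glucose, shape),
    dv = array(100 * v_map, shape),
    suv = NULL,
    voxel_mm = img$voxel_mm,
    provenance = list(protocol = schedule_protocol(s),
                      gap_family = if (is.null(g)) NA_character_ else g$family,
                      glucose = glucose, seed = img$seed, sigma0 = img$sigma0))
  if (is.null(dose_MBq) || is.null(weight_kg)) {
    warning("injected dose/body weight not supplied; SUV map omitted")
  } else {
    suv <- rowMeans(frames) * weight_kg / dose_MBq
    suv[!is.finite(suv)] <- NaN
    out$suv <- array(pmax(suv, 0), shape)
  }
  class(out) <- "parametric_maps"
  out
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat("<parametric_maps>", paste(dim(x$mr), collapse = " x "),
      "| protocol:", x$provenance$protocol,
      "| gap family:", x$provenance$gap_family, "\n")
  invisible(x)
}

#' Write parametric maps as NIfTI with a provenance sidecar
#'
#' @param maps a [make_maps()] object.
#' @param prefix output path prefix; writes `<prefix>_mr.nii.gz`,
#'   `<prefix>_dv.nii.gz`, optionally `<prefix>_suv.nii.gz`, and
#'   `<prefix>.json`.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "parametric_maps"))
  pd <- c(rep(maps$voxel_mm, 3))
  RNifti::writeNifti(RNifti::asNifti(maps$mr, pixdim = pd), paste0(prefix, "_mr.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$dv, pixdim = pd), paste0(prefix, "_dv.nii.gz"))
  if (!is.null(maps$suv)) {
    RNifti::writeNifti(RNifti::asNifti(maps$suv, pixdim = pd), paste0(prefix, "_suv.nii.gz"))
  }
  jsonlite::write_json(maps$provenance, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
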