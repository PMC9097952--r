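#' Acquisition frame schedules
#'
#' Build the frame schedule for one of the two acquisition protocols:
#' \describe{
#'   \item{`standard`}{a 6-min single-bed dynamic acquisition over the
#'     cardiac region (sub-framed, by default 12×5 s + 8×15 s + 6×30 s),
#'     a short dead time while whole-body passes are set up, then 16
#'     whole-body continuous-bed-motion passes: 5 passes of 2 min followed
#'     by 11 passes of 5 min. The last three frames cover 60–75 min p.i.}
#'   \item{`two_short`}{the subset of the standard schedule covering
#'     0–6 min and 60–75 min only.}
#' }
#'
#' The printed pass durations (6 + 5×2 + 11×5 min) total 71 min; a dead
#' time (default 4 min) after the cardiac bed reconciles this with the
#' 75-min total and places the last three frames at exactly
#' \[60,65), \[65,70), \[70,75) min.
#'
#' @param protocol `"standard"` or `"two_short"`.
#' @param cardiac_subframes sub-frame durations of the 0–6 min acquisition,
#'   in seconds; must total 360 s.
#' @param dead_time_min dead time between the cardiac bed and the first
#'   whole-body pass, minutes.
#' @return a `frame_schedule`: data.frame with `start`, `end` (minutes,
#'   half-open intervals) and attribute `protocol`.
#' @examples
#' s <- build_schedule("standard")
#' tail(s, 3)   # the three 60-75 min frames
#' @export
build_schedule <- function(protocol = c("standard", "two_short"),
                           cardiac_subframes = c(rep(5, 12), rep(15, 8), rep(30, 6)),
                           dead_time_min = 4) {
  protocol <- match.arg(protocol)
  stopifnot(all(cardiac_subframes > 0))
  if (sum(cardiac_subframes) != 360) {
    stop("cardiac sub-frames must tile the 6-min single-bed acquisition (360 s)")
  }
  edges_s <- c(0, cumsum(cardiac_subframes))
  cardiac <- data.frame(start = utils::head(edges_s, -1) / 60,
                        end = utils::tail(edges_s, -1) / 60)
  wb_start <- 6 + dead_time_min
  wb_durs <- c(rep(2, 5), rep(5, 11))
  wb_edges <- wb_start + c(0, cumsum(wb_durs))
  wb <- data.frame(start = utils::head(wb_edges, -1),
                   end = utils::tail(wb_edges, -1))
  if (abs(max(wb$end) - 75) > 1e-9) {
    stop("schedule does not end at 75 min; adjust dead_time_min")
  }
  frames <- rbind(cardiac, wb)
  if (protocol == "two_short") {
    keep <- frames$end <= 6 + 1e-9 | frames$start >= 60 - 1e-9
    frames <- frames[keep, , drop = FALSE]
  }
  rownames(frames) <- NULL
  structure(frames, protocol = protocol, class = c("frame_schedule", "data.frame"))
}

schedule_protocol <- function(s) attr(s, "protocol")

#' Time-activity curves
#'
#' A TAC is a per-frame activity record: columns `start`, `end` (minutes)
#' and `activity` (kBq/ml), plus a `source` tag (`"aorta_idif"`, `"tissue"`
#' or `"merged"`). Frame midpoints serve as the sample timestamps for
#' fitting and integration.
#'
#' @param start,end frame boundaries, minutes; sorted, non-overlapping.
#' @param activity frame-mean activities, kBq/ml.
#' @param source provenance tag.
#' @return object of class `tac` (a data.frame).
#' @export
new_tac <- function(start, end, activity, source = "tissue") {
  stopifnot(length(start) == length(end), length(end) == length(activity))
  if (any(end <= start)) stop("frame intervals must have positive duration")
  if (is.unsorted(start, strictly = TRUE)) stop("frames must be strictly increasing")
  if (any(utils::tail(start, -1) < utils::head(end, -1) - 1e-9)) {
    stop("frame intervals must not overlap")
  }
  if (any(!is.finite(activity))) stop("activities must be finite")
  structure(data.frame(start = start, end = end, activity = activity),
            source = source, class = c("tac", "data.frame"))
}

#' @rdname new_tac
#' @param tac a `tac` object.
#' @export
tac_midpoints <- function(tac) (tac$start + tac$end) / 2

tac_source <- function(tac) attr(tac, "source")

#' Exact frame averaging of a continuous curve
#'
#' The scanner reports, per frame \[t0, t1), the time-averaged activity
#' \eqn{\frac{1}{t_1-t_0}\int_{t_0}^{t_1} C(t)\,dt}. For the closed-form
#' input and tissue curves this integral is evaluated exactly.
#'
#' @param curve an [input_function()] or [tissue_curve()].
#' @param s a [build_schedule()] frame schedule.
#' @param source source tag for the resulting TAC.
#' @return a [new_tac()] with one activity per frame.
#' @export
frame_average <- function(curve, s, source = NULL) {
  stopifnot(inherits(s, "frame_schedule"))
  if (is.null(source)) {
    source <- if (inherits(curve, "input_function")) "aorta_idif" else "tissue"
  }
  F1 <- curve_integral(curve, s$end)
  F0 <- curve_integral(curve, s$start)
  new_tac(s$start, s$end, (F1 - F0) / (s$end - s$start), source = source)
}
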