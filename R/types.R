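#' Trajectory set
#'
#' Container for single-particle trajectories: a long-format table of
#' detections plus acquisition metadata. Each trajectory occupies strictly
#' consecutive frames (the linker does no gap closing).
#'
#' @param tracks Data frame with columns `track` (integer id), `frame`
#'   (0-based integer), `x`, `y` (um). Extra columns (e.g. `intensity`,
#'   `quality`) are kept.
#' @param frame_interval Frame interval (s).
#' @param n_frames Total number of frames in the source movie, if known;
#'   needed by the first/last-frame track filters.
#' @param field Optional named vector `c(width =, height =)` in um; needed
#'   by the edge filter.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(tracks, frame_interval, n_frames = NULL,
                           field = NULL) {
  stopifnot(is.data.frame(tracks),
            all(c("track", "frame", "x", "y") %in% names(tracks)),
            frame_interval > 0)
  tracks <- tracks[order(tracks$track, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, frame_interval = frame_interval,
                 n_frames = if (is.null(n_frames)) NULL else
                   as.integer(n_frames),
                 field = field),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d tracks, %d detections, dt = %g s\n",
              length(unique(x$tracks$track)), nrow(x$tracks),
              x$frame_interval))
  invisible(x)
}

#' Number of tracks in a trajectory set
#' @param set A [trajectory_set()].
#' @return Integer count of distinct track ids.
#' @export
n_tracks <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  length(unique(set$tracks$track))
}

#' Binding-event log
#'
#' Times of single-molecule membrane association events observed over a
#' known membrane area and duration at a known solution concentration.
#'
#' @param times Event times (s), within `[0, duration]`.
#' @param area Observation area (um^2).
#' @param duration Observation time (s).
#' @param concentration Solution concentration (uM).
#' @return An object of class `binding_event_log`.
#' @export
binding_event_log <- function(times, area, duration, concentration = NA) {
  stopifnot(area > 0, duration > 0)
  times <- sort(as.numeric(times))
  if (length(times) > 0 &&
      (times[1] < 0 || times[length(times)] > duration))
    stop("event times must lie within [0, duration]")
  structure(list(times = times, area = area, duration = duration,
                 concentration = concentration),
            class = "binding_event_log")
}

#' @export
print.binding_event_log <- function(x, ...) {
  cat(sprintf(
    "<binding_event_log> %d events over %g um^2 x %g s (C = %g uM)\n",
    length(x$times), x$area, x$duration, x$concentration))
  invisible(x)
}

#' Lipid composition
#'
#' Molar fractions of the lipid species making up a supported bilayer,
#' together with the per-lipid membrane footprint used to convert molar
#' fraction to surface density.
#'
#' @param fractions Named numeric vector of molar fractions summing to 1.
#' @param footprint_nm2 Area per lipid (nm^2); 0.72 nm^2 is the standard
#'   value for DOPC.
#' @return An object of class `lipid_composition`.
#' @examples
#' lipid_composition(c(DOPC = 0.96, `PI(4,5)P2` = 0.04))
#' @export
lipid_composition <- function(fractions, footprint_nm2 = 0.72) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)),
            all(fractions >= 0), footprint_nm2 > 0)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("molar fractions must sum to 1")
  structure(list(fractions = fractions, footprint_nm2 = footprint_nm2),
            class = "lipid_composition")
}
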