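#' Read and write trajectory tables in TrackMate CSV dialect
#'
#' Trajectories are exchanged as CSV with columns `TRACK_ID`,
#' `POSITION_X`, `POSITION_Y` (um) and `FRAME` (0-based integer), the
#' column subset of a TrackMate spot export. `read_tracks_csv` tolerates
#' the extra non-numeric header rows that TrackMate (v7+) inserts below
#' the column names, and ignores additional columns.
#'
#' @param set A [trajectory_set()].
#' @param path File path.
#' @param frame_interval Frame interval (s) of the source movie.
#' @param n_frames,field Optional movie metadata attached to the returned
#'   set (see [trajectory_set()]).
#' @return `read_tracks_csv` returns a [trajectory_set()];
#'   `write_tracks_csv` returns `path` invisibly.
#' @export
write_tracks_csv <- function(set, path) {
  stopifnot(inherits(set, "trajectory_set"))
  out <- data.frame(TRACK_ID = set$tracks$track,
                    POSITION_X = set$tracks$x,
                    POSITION_Y = set$tracks$y,
                    FRAME = as.integer(set$tracks$frame))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, frame_interval, n_frames = NULL,
                            field = NULL) {
  df <- read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "POSITION_X", "POSITION_Y", "FRAME")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[, need]
  # TrackMate inserts units/description rows below the header
  suppressWarnings({
    num <- data.frame(track = as.numeric(df$TRACK_ID),
                      x = as.numeric(df$POSITION_X),
                      y = as.numeric(df$POSITION_Y),
                      frame = as.numeric(df$FRAME))
  })
  num <- num[complete.cases(num), , drop = FALSE]
  num$track <- as.integer(num$track)
  num$frame <- as.integer(num$frame)
  trajectory_set(num, frame_interval = frame_interval,
                 n_frames = n_frames, field = field)
}

#' Write and read simulation ground truth as JSON
#'
#' @param ground_truth The `ground_truth` component returned by
#'   [simulate_trajectories()].
#' @param path File path.
#' @return `read_ground_truth_json` returns the ground-truth list;
#'   `write_ground_truth_json` returns `path` invisibly.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write and read synthetic movies as 16-bit multi-page TIFF
#'
#' Photon-count stacks from [render_movie()] are stored as 16-bit TIFF,
#' one page per frame. Counts are clipped to 65535.
#'
#' @param stack Numeric array `c(rows, cols, frames)` of counts.
#' @param path File path.
#' @return `read_movie_tiff` returns the stack as a numeric array of
#'   counts; `write_movie_tiff` returns `path` invisibly.
#' @export
write_movie_tiff <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(round(stack[, , f]), 0), 65535)
    m / 65535  # tiff stores [0,1] scaled to the sample depth
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- round(pages[[f]] * 65535)
  stack
}

#' Write a filter audit (counts removed per rule) as JSON
#'
#' @param filtered Result of [filter_trajectories()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_filter_audit_json <- function(filtered, path) {
  jsonlite::write_json(as.list(attr(filtered, "removed_counts")), path,
                       auto_unbox = TRUE)
  invisible(path)
}
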