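#' Membrane-binding frequency from an event log
#'
#' The slope of the cumulative event count versus time, obtained by
#' ordinary least-squares regression, divided by the observation area.
#' For a homogeneous Poisson event stream this estimates the per-area
#' event intensity.
#'
#' @param log A [binding_event_log()]. Fewer than 10 events gives an
#'   estimate with `warning = TRUE`; zero events gives frequency 0.
#' @return List with `frequency` (events / (um^2 * s)), `slope`
#'   (events/s), `n_events`, `concentration` and `warning` (logical).
#' @export
binding_frequency <- function(log) {
  stopifnot(inherits(log, "binding_event_log"))
  n <- length(log$times)
  warn <- n < 10
  if (warn)
    warning(sprintf("only %d events; frequency estimate is unreliable", n))
  slope <- if (n == 0) {
    0
  } else if (n == 1) {
    1 / log$times[1]
  } else {
    unname(coef(lm(count ~ time,
                   data = data.frame(count = seq_len(n),
                                     time = log$times)))["time"])
  }
  list(frequency = slope / log$area, slope = slope, n_events = n,
       concentration = log$concentration, warning = warn)
}

#' Estimate the association rate constant kON
#'
#' Regresses the per-area binding frequency against solution
#' concentration with the intercept fixed at zero (the frequency must
#' vanish at zero concentration); kON is the slope. A free-intercept fit
#' is also returned as a diagnostic. With a single concentration kON is
#' computed as frequency / concentration and flagged.
#'
#' @param logs List of [binding_event_log()]s spanning >= 2 distinct
#'   concentrations (each log must carry its concentration, uM).
#' @return Object of class `kon_estimate`: `kon` (events per
#'   (uM * um^2 * s)), `kon_per_nM` (same per nM, i.e. `kon / 1000`),
#'   `se`, `frequencies` (data frame concentration/frequency/n_events),
#'   `single_concentration` flag, and `free_intercept_fit` (lm or NULL).
#' @export
estimate_kon <- function(logs) {
  stopifnot(is.list(logs), length(logs) >= 1,
            all(vapply(logs, inherits, TRUE, "binding_event_log")))
  freqs <- do.call(rbind, lapply(logs, function(l) {
    bf <- suppressWarnings(binding_frequency(l))
    data.frame(concentration = l$concentration, frequency = bf$frequency,
               n_events = bf$n_events)
  }))
  if (any(is.na(freqs$concentration)))
    stop("every event log must carry its concentration")
  single <- length(unique(freqs$concentration)) < 2
  if (single) {
    warning("single concentration: kon = frequency / concentration")
    kon <- mean(freqs$frequency / freqs$concentration)
    se <- NA_real_
    free_fit <- NULL
  } else {
    fit <- lm(frequency ~ 0 + concentration, data = freqs)
    kon <- unname(coef(fit)["concentration"])
    se <- sqrt(diag(vcov(fit)))[["concentration"]]
    free_fit <- lm(frequency ~ concentration, data = freqs)
  }
  structure(list(kon = kon, kon_per_nM = kon / 1000, se = se,
                 frequencies = freqs, single_concentration = single,
                 free_intercept_fit = free_fit),
            class = "kon_estimate")
}

#' @export
print.kon_estimate <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<kon_estimate> kON = %.*g /(uM um^2 s) = %.*g /(nM um^2 s)  [SE %.2g, %d concentrations]\n",
    digits, x$kon, digits, x$kon_per_nM, x$se, nrow(x$frequencies)))
  invisible(x)
}

#' Extract binding events from a trajectory set
#'
#' A binding event is the first frame of a trajectory that survives the
#' movie-limit filters (tracks starting in the first frame or reaching
#' the last are censored and dropped). The immobile-displacement filter
#' is NOT applied by default -- immobile nonspecific particles still bind
#' -- but can be enabled.
#'
#' @param set A [trajectory_set()] with known `n_frames`.
#' @param area Observation area (um^2); defaults to the set's field area.
#' @param concentration Solution concentration (uM).
#' @param apply_immobile_filter Also drop tracks below the displacement
#'   threshold (default `FALSE`).
#' @param min_total_displacement Threshold used when
#'   `apply_immobile_filter` is `TRUE` (um).
#' @return A [binding_event_log()].
#' @export
events_from_trajectories <- function(set, area = NULL, concentration = NA,
                                     apply_immobile_filter = FALSE,
                                     min_total_displacement = 0.1) {
  stopifnot(inherits(set, "trajectory_set"), !is.null(set$n_frames))
  if (is.null(area)) {
    if (is.null(set$field)) stop("supply `area` or a set with field size")
    area <- set$field[["width"]] * set$field[["height"]]
  }
  rules <- filter_rules(
    drop_first_frame_starts = TRUE, drop_last_frame_ends = TRUE,
    min_frames = 1,
    min_total_displacement = if (apply_immobile_filter)
      min_total_displacement else 0,
    edge_margin = 0, max_duration = Inf)
  kept <- filter_trajectories(set, rules)
  starts <- vapply(split(kept$tracks$frame, kept$tracks$track), min,
                   numeric(1))
  binding_event_log(starts * set$frame_interval,
                    area = area,
                    duration = set$n_frames * set$frame_interval,
                    concentration = concentration)
}
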