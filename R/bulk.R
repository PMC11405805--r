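#' Fold change in membrane recruitment
#'
#' Equilibrium intensity (mean over the final plateau) divided by a
#' reference level. The plateau is detected as the longest terminal
#' window (at least 10% of the trace) over which the linear trend changes
#' the signal by less than 2% of the signal range; if none is found the
#' final 10% of points is used with a warning.
#'
#' @param series A `membrane_time_series` (data frame with `time`,
#'   `intensity`) or any such data frame.
#' @param reference_level Reference intensity (> 0), e.g. the density in
#'   the absence of the recruiting lipid.
#' @param plateau_window Optional explicit window `c(t_start, t_end)` (s)
#'   over which to average.
#' @return Fold change (dimensionless), with attribute `plateau` (the
#'   plateau level used).
#' @export
fold_change <- function(series, reference_level, plateau_window = NULL) {
  stopifnot(is.data.frame(series), all(c("time", "intensity") %in%
                                         names(series)),
            reference_level > 0)
  if (!is.null(plateau_window)) {
    sel <- series$time >= plateau_window[1] & series$time <= plateau_window[2]
    if (!any(sel)) stop("plateau window contains no samples")
    plateau <- mean(series$intensity[sel])
  } else {
    plateau <- detect_plateau(series)
    if (is.na(plateau)) {
      warning("no plateau detected; using final 10% of points")
      n <- nrow(series)
      plateau <- mean(series$intensity[seq.int(ceiling(0.9 * n), n)])
    }
  }
  structure(plateau / reference_level, plateau = plateau)
}

# mean of the longest terminal window with negligible trend, or NA
detect_plateau <- function(series) {
  n <- nrow(series)
  rng <- diff(range(series$intensity))
  if (rng == 0) return(mean(series$intensity))
  for (frac in seq(0.5, 0.1, by = -0.1)) {
    i0 <- ceiling((1 - frac) * n)
    idx <- i0:n
    if (length(idx) < 3) next
    fit <- lm(intensity ~ time, data = series[idx, ])
    drift <- abs(coef(fit)[["time"]]) *
      (series$time[n] - series$time[i0])
    if (drift < 0.02 * rng)
      return(mean(series$intensity[idx]))
  }
  NA_real_
}

#' Reaction half-time of a membrane kinetic trace
#'
#' Earliest time at which the smoothed signal crosses the midpoint
#' between its initial and final plateau levels, with linear
#' interpolation between samples. The result is invariant to affine
#' rescaling of the intensity. Multiple crossings (non-monotone traces)
#' are flagged; the first is reported.
#'
#' @param series Data frame with `time` (strictly increasing, s) and
#'   `intensity`.
#' @param smooth_width Width (samples) of the centered moving average
#'   applied before crossing detection (default 5; 1 disables).
#' @param plateau_frac Fraction of points defining the initial and final
#'   levels (default 0.1).
#' @return Half-time (s) with attributes `n_crossings` and `levels`
#'   (initial, final). Errors if the trace shows no completion (flat).
#' @export
reaction_half_time <- function(series, smooth_width = 5,
                               plateau_frac = 0.1) {
  stopifnot(is.data.frame(series),
            all(c("time", "intensity") %in% names(series)),
            all(diff(series$time) > 0), smooth_width >= 1)
  n <- nrow(series)
  y <- series$intensity
  if (smooth_width > 1) {
    w <- min(as.integer(smooth_width), n)
    if (w %% 2 == 0) w <- w - 1L
    if (w >= 3) {
      sm <- stats::filter(y, rep(1 / w, w), sides = 2)
      y <- ifelse(is.na(sm), y, as.numeric(sm))
    }
  }
  k <- max(1L, ceiling(plateau_frac * n))
  lev0 <- mean(y[seq_len(k)])
  lev1 <- mean(y[seq.int(n - k + 1L, n)])
  if (abs(lev1 - lev0) <= 1e-12 * max(abs(lev1), abs(lev0), 1))
    stop("trace shows no reaction completion (flat)")
  mid <- (lev0 + lev1) / 2
  z <- y - mid
  strict <- which(z[-n] * z[-1] < 0)          # crossing between i and i+1
  exact <- which(z == 0)                      # sample exactly at midpoint
  exact <- exact[c(TRUE, diff(exact) > 1)]    # collapse runs at the midpoint
  cross <- sort(c(strict, exact))
  if (length(cross) == 0)
    stop("signal never crosses the midpoint")
  i <- cross[1]
  t_half <- if (z[i] == 0) series$time[i] else {
    # linear interpolation between samples i and i+1
    series$time[i] + (mid - y[i]) / (y[i + 1] - y[i]) *
      (series$time[i + 1] - series$time[i])
  }
  n_cross <- length(cross)
  if (n_cross > 1)
    warning(sprintf("%d midpoint crossings; reporting the first", n_cross))
  structure(t_half, n_crossings = n_cross, levels = c(initial = lev0,
                                                      final = lev1))
}

#' Lipid surface density from molar fraction
#'
#' Converts the molar fraction of a lipid species into a surface density
#' (lipids per um^2, one leaflet) assuming a fixed per-lipid footprint
#' (0.72 nm^2, the standard DOPC value). The conversion is linear in the
#' molar fraction: `density = fraction / (footprint_nm2 * 1e-6)`.
#'
#' @param composition A [lipid_composition()].
#' @param species Name of the lipid species.
#' @return Density (lipids/um^2, one leaflet).
#' @examples
#' comp <- lipid_composition(c(DOPC = 0.96, `PI(4,5)P2` = 0.04))
#' lipid_density(comp, "PI(4,5)P2")  # ~55,556 lipids/um^2
#' @export
lipid_density <- function(composition, species) {
  stopifnot(inherits(composition, "lipid_composition"))
  if (!species %in% names(composition$fractions))
    stop("unknown lipid species: ", species)
  unname(composition$fractions[[species]] /
           (composition$footprint_nm2 * 1e-6))
}

#' Read a bulk membrane-intensity time series from two-column CSV
#'
#' @param path CSV file with columns time (s) and intensity (any header
#'   names; the first two columns are used).
#' @param condition Optional condition label attached as attribute.
#' @return A `membrane_time_series` data frame (`time`, `intensity`).
#' @export
read_bulk_csv <- function(path, condition = NULL) {
  df <- read.csv(path)
  if (ncol(df) < 2) stop("expected two columns (time, intensity)")
  out <- data.frame(time = as.numeric(df[[1]]),
                    intensity = as.numeric(df[[2]]))
  if (any(diff(out$time) <= 0)) stop("time must be strictly increasing")
  structure(out, class = c("membrane_time_series", "data.frame"),
            condition = condition)
}
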