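#' Simulation configuration
#'
#' Describes the imaging geometry and acquisition settings of a synthetic
#' TIRF movie: field size in micrometers, pixel size, frame interval and
#' number of frames, plus the localization error and point-spread-function
#' parameters used when rendering and perturbing positions.
#'
#' @param field_width,field_height Field size (um).
#' @param pixel_size Pixel size (um/pixel).
#' @param frame_interval Time between frames (s). 0.052 s (19 fps) and
#'   0.102 s (10 fps) are typical single-molecule acquisition settings.
#' @param n_frames Number of frames (>= 2).
#' @param localization_sigma Gaussian localization error added to true
#'   positions (um).
#' @param psf_sigma Gaussian PSF standard deviation (pixels), used by
#'   [render_movie()].
#' @param photons_per_spot Expected integrated counts per rendered spot.
#' @param background_mean Mean Poisson background per pixel.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(field_width = 20, field_height = 20,
                       pixel_size = 0.1, frame_interval = 0.052,
                       n_frames = 200, localization_sigma = 0.02,
                       psf_sigma = 1.3, photons_per_spot = 500,
                       background_mean = 10, seed = 1L) {
  stopifnot(field_width > 0, field_height > 0, pixel_size > 0,
            frame_interval > 0, n_frames >= 2, localization_sigma >= 0,
            psf_sigma > 0, photons_per_spot >= 0, background_mean >= 0)
  structure(list(field_width = field_width, field_height = field_height,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 localization_sigma = localization_sigma,
                 psf_sigma = psf_sigma, photons_per_spot = photons_per_spot,
                 background_mean = background_mean, seed = as.integer(seed)),
            class = "sim_config")
}

#' Membrane-binding model
#'
#' Generative model of membrane association and dissociation. Molecules
#' arrive as a homogeneous Poisson process with intensity
#' `kon * concentration * area` and dwell on the membrane for a time drawn
#' from the exponential mixture `alpha_fast * Exp(tau_fast) +
#' (1 - alpha_fast) * Exp(tau_slow)`. Photobleaching competes as an
#' independent exponential with rate `bleach_rate`, censoring the observed
#' dwell.
#'
#' @param kon Association rate constant, events per (uM * um^2 * s).
#' @param concentration Solution concentration (uM).
#' @param alpha_fast Fraction of the fast-dissociating population, in
#'   `[0, 1]`. `alpha_fast = 1` gives single-exponential dwells with mean
#'   `tau_fast`.
#' @param tau_fast,tau_slow Mean dwell times of the fast and slow
#'   populations (s); `tau_fast <= tau_slow`.
#' @param bleach_rate Photobleaching rate (per s); 0 disables bleaching.
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(kon = 184, concentration = 5e-5,
                          alpha_fast = 0.95, tau_fast = 0.815,
                          tau_slow = 3.09, bleach_rate = 0) {
  stopifnot(kon >= 0, concentration >= 0,
            alpha_fast >= 0, alpha_fast <= 1,
            tau_fast > 0, tau_slow > 0, bleach_rate >= 0)
  if (tau_fast > tau_slow)
    stop("`tau_fast` must not exceed `tau_slow`")
  structure(list(kon = kon, concentration = concentration,
                 alpha_fast = alpha_fast, tau_fast = tau_fast,
                 tau_slow = tau_slow, bleach_rate = bleach_rate),
            class = "binding_model")
}

#' Lateral diffusion model
#'
#' Two-species 2D Brownian diffusion with an optional immobile fraction.
#' Each step of a mobile molecule over a lag `tau` has independent Gaussian
#' x and y increments with variance `2 * D * tau`.
#'
#' @param frac_species1 Fraction of mobile molecules belonging to species 1
#'   (diffusivity `D1`).
#' @param D1,D2 Diffusion coefficients (um^2/s), `D1 <= D2`.
#' @param immobile_frac Fraction of molecules that do not move.
#' @return An object of class `diffusion_model`.
#' @export
diffusion_model <- function(frac_species1 = 1, D1 = 0.16, D2 = 0.16,
                            immobile_frac = 0) {
  stopifnot(frac_species1 >= 0, frac_species1 <= 1,
            immobile_frac >= 0, immobile_frac <= 1,
            D1 >= 0, D2 >= 0)
  if (D1 > D2) stop("`D1` must not exceed `D2`")
  structure(list(frac_species1 = frac_species1, D1 = D1, D2 = D2,
                 immobile_frac = immobile_frac),
            class = "diffusion_model")
}

#' Simulate membrane dwell times
#'
#' Draws `n` dwell times from the exponential mixture of a
#' [binding_model()]: with probability `alpha_fast` a molecule belongs to
#' the fast population (mean `tau_fast`), otherwise to the slow one (mean
#' `tau_slow`). If `bleach_rate > 0` each dwell is censored by an
#' independent exponential bleaching time. Dwells are additionally
#' quantized to the acquisition grid as `ceiling(dwell / frame_interval) *
#' frame_interval`, the value a tracker would report for a movie with that
#' frame interval.
#'
#' @param n Number of molecules (>= 1).
#' @param model A [binding_model()].
#' @param frame_interval Frame interval (s) used for quantization.
#' @return A data frame with columns `dwell` (continuous, s), `quantized`
#'   (s), `species` (`"fast"`/`"slow"`) and `bleached` (logical).
#' @examples
#' m <- binding_model(alpha_fast = 0.95, tau_fast = 0.815, tau_slow = 3.09)
#' set.seed(1)
#' d <- simulate_dwell_times(1e4, m, frame_interval = 0.052)
#' mean(d$dwell)  # ~ 0.95 * 0.815 + 0.05 * 3.09
#' @export
simulate_dwell_times <- function(n, model, frame_interval) {
  if (length(n) != 1 || n < 1)
    stop("`n` must be a single count >= 1")
  if (frame_interval <= 0)
    stop("`frame_interval` must be positive")
  stopifnot(inherits(model, "binding_model"))
  n <- as.integer(n)
  fast <- runif(n) < model$alpha_fast
  dwell <- ifelse(fast,
                  rexp(n, rate = 1 / model$tau_fast),
                  rexp(n, rate = 1 / model$tau_slow))
  bleached <- rep(FALSE, n)
  if (model$bleach_rate > 0) {
    tb <- rexp(n, rate = model$bleach_rate)
    bleached <- tb < dwell
    dwell <- pmin(dwell, tb)
  }
  quantized <- ceiling(dwell / frame_interval - 1e-12) * frame_interval
  data.frame(dwell = dwell, quantized = quantized,
             species = ifelse(fast, "fast", "slow"),
             bleached = bleached)
}

#' Simulate membrane-binding arrival times
#'
#' Homogeneous Poisson process of membrane association events with
#' intensity `kon * concentration * area`; the event count over `duration`
#' has mean `kon * concentration * area * duration`.
#'
#' @param kon Association rate constant, events per (uM * um^2 * s).
#' @param concentration Solution concentration (uM); 0 gives no events.
#' @param area Observation area (um^2).
#' @param duration Observation time (s).
#' @param seed Optional integer seed set before drawing.
#' @return A [binding_event_log()] holding the sorted event times together
#'   with `area`, `duration` and `concentration`.
#' @export
simulate_arrivals <- function(kon, concentration, area, duration,
                              seed = NULL) {
  stopifnot(kon >= 0, concentration >= 0, area > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, kon * concentration * area * duration)
  times <- sort(runif(n, 0, duration))
  binding_event_log(times, area = area, duration = duration,
                    concentration = concentration)
}

#' Simulate single-molecule trajectories with ground truth
#'
#' Composes Poisson arrivals, exponential-mixture dwell times with optional
#' photobleaching, and two-species 2D Brownian motion into a set of
#' trajectories over a rectangular field. Each molecule appears at a
#' uniform random position at its arrival time, is detected in every frame
#' at whose midpoint it is membrane-bound, moves between frames with
#' Gaussian increments of variance `2 * D * frame_interval` per axis
#' (reflecting boundaries), and its reported positions are perturbed by
#' `localization_sigma`. Molecules present in the first or last frame are
#' flagged in the ground truth: the standard track filters must remove them
#' because their dwell is censored by the movie limits.
#'
#' @param config A [sim_config()]; `config$seed` seeds the simulation.
#' @param binding A [binding_model()].
#' @param diffusion A [diffusion_model()].
#' @return A list with components `trajectories` (a [trajectory_set()] of
#'   noisy detections, one track per detected molecule) and `ground_truth`
#'   (see Details).
#' @details `ground_truth` is a list with `molecules`, a data frame of
#'   per-molecule records (arrival time, true and bleach-censored dwell,
#'   species, number of detected frames, first/last-frame flags), and
#'   `positions`, the noiseless per-frame positions in the same layout as
#'   the trajectory table.
#' @export
simulate_trajectories <- function(config, binding, diffusion) {
  stopifnot(inherits(config, "sim_config"),
            inherits(binding, "binding_model"),
            inherits(diffusion, "diffusion_model"))
  W <- config$field_width; H <- config$field_height
  if (W * H <= 0) stop("field area must be positive")
  dt <- config$frame_interval
  Tdur <- config$n_frames * dt
  set.seed(config$seed)

  n_mol <- rpois(1, binding$kon * binding$concentration * W * H * Tdur)
  arrivals <- sort(runif(n_mol, 0, Tdur))
  dw <- if (n_mol > 0)
    simulate_dwell_times(n_mol, binding, dt) else
    data.frame(dwell = numeric(), quantized = numeric(),
               species = character(), bleached = logical())

  # species: immobile, else species 1 (D1) vs species 2 (D2)
  u <- runif(n_mol)
  mobile <- u >= diffusion$immobile_frac
  sp1 <- runif(n_mol) < diffusion$frac_species1
  D <- ifelse(!mobile, 0, ifelse(sp1, diffusion$D1, diffusion$D2))
  species <- ifelse(!mobile, "immobile", ifelse(sp1, "species1", "species2"))

  mids <- (seq_len(config$n_frames) - 0.5) * dt  # frame midpoints
  rows <- vector("list", n_mol)
  mol <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    t0 <- arrivals[i]; t1 <- t0 + dw$dwell[i]
    frames <- which(mids >= t0 & mids < t1) - 1L  # 0-based
    nf <- length(frames)
    if (nf > 0) {
      x <- numeric(nf); y <- numeric(nf)
      x[1] <- runif(1, 0, W); y[1] <- runif(1, 0, H)
      if (nf > 1) {
        s <- sqrt(2 * D[i] * dt)
        dx <- rnorm(nf - 1, 0, s); dy <- rnorm(nf - 1, 0, s)
        for (k in 2:nf) {
          x[k] <- reflect(x[k - 1] + dx[k - 1], W)
          y[k] <- reflect(y[k - 1] + dy[k - 1], H)
        }
      }
      rows[[i]] <- data.frame(track = i, frame = frames, x = x, y = y)
    }
    mol[[i]] <- data.frame(
      molecule = i, arrival = t0, true_dwell = dw$dwell[i],
      observed_dwell = dw$dwell[i], bleached = dw$bleached[i],
      dwell_species = dw$species[i], diffusion_species = species[i],
      n_detected = nf,
      in_first_frame = nf > 0 && frames[1] == 0L,
      in_last_frame = nf > 0 && frames[nf] == config$n_frames - 1L)
  }
  positions <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(positions))
    positions <- data.frame(track = integer(), frame = integer(),
                            x = numeric(), y = numeric())
  molecules <- do.call(rbind, mol)
  if (is.null(molecules))
    molecules <- data.frame(molecule = integer(), arrival = numeric(),
                            true_dwell = numeric(), observed_dwell = numeric(),
                            bleached = logical(), dwell_species = character(),
                            diffusion_species = character(),
                            n_detected = integer(), in_first_frame = logical(),
                            in_last_frame = logical())

  noisy <- positions
  if (nrow(noisy) > 0 && config$localization_sigma > 0) {
    noisy$x <- pmin(pmax(noisy$x + rnorm(nrow(noisy), 0,
                                         config$localization_sigma), 0), W)
    noisy$y <- pmin(pmax(noisy$y + rnorm(nrow(noisy), 0,
                                         config$localization_sigma), 0), H)
  }
  trajectories <- trajectory_set(noisy, frame_interval = dt,
                                 n_frames = config$n_frames,
                                 field = c(width = W, height = H))
  list(trajectories = trajectories,
       ground_truth = list(molecules = molecules, positions = positions))
}

# reflect a coordinate into [0, L] (reflecting boundary)
reflect <- function(z, L) {
  z <- z %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}

#' Render a trajectory set as a synthetic TIRF image stack
#'
#' Each detection is drawn as an integrated 2D Gaussian of standard
#' deviation `psf_sigma` (pixels) carrying `photons_per_spot` expected
#' counts, on a Poisson background of mean `background_mean` per pixel.
#' Spots falling off the field are clipped, not wrapped.
#'
#' @param trajectories A [trajectory_set()] (coordinates in um).
#' @param config A [sim_config()]; pixel grid is
#'   `field_height/pixel_size` rows by `field_width/pixel_size` columns.
#' @param noise If `TRUE` (default) pixel values are Poisson draws around
#'   the expected image; if `FALSE` the noiseless expected image is
#'   returned.
#' @return A numeric array of dimension `c(n_rows, n_cols, n_frames)`
#'   (photon counts).
#' @export
render_movie <- function(trajectories, config, noise = TRUE) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(config, "sim_config"))
  px <- config$pixel_size
  nc <- ceiling(config$field_width / px)
  nr <- ceiling(config$field_height / px)
  nf <- config$n_frames
  stack <- array(config$background_mean, dim = c(nr, nc, nf))
  tr <- trajectories$tracks
  half <- ceiling(5 * config$psf_sigma)
  for (i in seq_len(nrow(tr))) {
    f <- tr$frame[i] + 1L
    if (f < 1 || f > nf) next
    cx <- tr$x[i] / px  # column coordinate, pixels
    cy <- tr$y[i] / px
    j0 <- max(1L, floor(cx) - half + 1L); j1 <- min(nc, floor(cx) + half + 1L)
    i0 <- max(1L, floor(cy) - half + 1L); i1 <- min(nr, floor(cy) + half + 1L)
    if (j0 > j1 || i0 > i1) next
    # integrate the Gaussian over pixel boundaries
    fx <- diff(pnorm(seq(j0 - 1, j1), mean = cx, sd = config$psf_sigma))
    fy <- diff(pnorm(seq(i0 - 1, i1), mean = cy, sd = config$psf_sigma))
    stack[i0:i1, j0:j1, f] <- stack[i0:i1, j0:j1, f] +
      config$photons_per_spot * outer(fy, fx)
  }
  if (noise) {
    stack[] <- rpois(length(stack), stack)
  }
  stack
}

#' Simulate a bulk membrane-recruitment time series
#'
#' Phenomenological sigmoid (Hill curve) rising from 0 to `plateau` and
#' crossing `plateau / 2` at `t_half`, with additive Gaussian noise. This
#' reproduces the shape of bulk recruitment or lipid-phosphorylation
#' traces without any mechanistic reaction model.
#'
#' @param t_half Half-completion time (s); must lie inside `[0, t_max]`.
#' @param plateau Final intensity level (arbitrary units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_points Number of samples.
#' @param t_max Total duration (s); default `4 * t_half`.
#' @param hill Hill coefficient controlling steepness.
#' @return A data frame of class `membrane_time_series` with columns
#'   `time` (s) and `intensity`.
#' @export
simulate_bulk_trace <- function(t_half, plateau, noise_sd = 0,
                                n_points = 200, t_max = 4 * t_half,
                                hill = 4) {
  stopifnot(t_half >= 0, noise_sd >= 0, n_points >= 2, hill > 0)
  if (t_half > t_max) stop("`t_half` must lie within the time range")
  time <- seq(0, t_max, length.out = n_points)
  intensity <- if (plateau == 0) {
    rep(0, n_points)
  } else if (t_half == 0) {
    c(0, rep(plateau, n_points - 1))
  } else {
    plateau * time^hill / (time^hill + t_half^hill)
  }
  if (noise_sd > 0) intensity <- intensity + rnorm(n_points, 0, noise_sd)
  structure(data.frame(time = time, intensity = intensity),
            class = c("membrane_time_series", "data.frame"))
}
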