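test_that("dwell-time simulation matches the mixture mean and guards inputs", {
  m <- binding_model(alpha_fast = 0.95, tau_fast = 0.815, tau_slow = 3.09,
                     bleach_rate = 0)
  set.seed(11)
  d <- simulate_dwell_times(1e6, m, frame_interval = 0.052)
  expect_equal(mean(d$dwell), 0.95 * 0.815 + 0.05 * 3.09, tolerance = 0.01)
  # quantization rounds up to the acquisition grid
  expect_true(all(d$quantized >= d$dwell - 1e-9))
  k <- d$quantized / 0.052
  expect_true(all(abs(k - round(k)) < 1e-9))   # on the acquisition grid
  expect_gte(min(round(k)), 1)

  # degenerate mixture is a plain exponential
  m1 <- binding_model(alpha_fast = 1, tau_fast = 1, tau_slow = 1)
  set.seed(12)
  d1 <- simulate_dwell_times(2e5, m1, 0.05)
  expect_equal(mean(d1$dwell), 1.0, tolerance = 0.01)

  expect_error(simulate_dwell_times(0, m, 0.05), "n")
  expect_error(simulate_dwell_times(10, m, 0), "frame_interval")
  expect_error(binding_model(tau_fast = 2, tau_slow = 1), "tau_fast")
})

test_that("dwell sample mean stays within 2 SE of the mixture mean", {
  m <- binding_model(alpha_fast = 0.8, tau_fast = 0.3, tau_slow = 2.0)
  mu <- 0.8 * 0.3 + 0.2 * 2.0
  v <- 0.8 * 2 * 0.3^2 + 0.2 * 2 * 2^2 - mu^2  # mixture variance
  set.seed(21)
  fails <- 0
  for (r in 1:20) {
    d <- simulate_dwell_times(5000, m, 0.05)
    if (abs(mean(d$dwell) - mu) > 2 * sqrt(v / 5000)) fails <- fails + 1
  }
  # ~5% of replicates may fall outside a 2 SE band
  expect_lte(fails, 4)
})

test_that("photobleaching censors dwells to an exponential with summed rate", {
  # single-exponential dwell 1/tau plus bleaching b => Exp(1/tau + b)
  m <- binding_model(alpha_fast = 1, tau_fast = 2, tau_slow = 2,
                     bleach_rate = 0.75)
  set.seed(31)
  d <- simulate_dwell_times(1e5, m, 0.05)
  rate <- 1 / 2 + 0.75
  expect_equal(mean(d$dwell), 1 / rate, tolerance = 0.02)
  ks <- suppressWarnings(ks.test(d$dwell, "pexp", rate))
  expect_gt(ks$p.value, 0.01)
  expect_true(any(d$bleached))
})

test_that("arrival streams are Poisson with intensity kon*C*A", {
  el <- simulate_arrivals(184, 5e-5, 1000, 100, seed = 5)
  expect_s3_class(el, "binding_event_log")
  expect_true(all(el$times >= 0 & el$times <= 100))
  expect_equal(length(el$times), 920, tolerance = 0.15)

  expect_length(simulate_arrivals(184, 0, 1000, 100, seed = 1)$times, 0)

  # empirical rate over 100 replicates within 2 SE of kon*C*A
  set.seed(42)
  lambda <- 9.68 * 5e-5 * 1000          # events per second
  counts <- replicate(100, length(simulate_arrivals(9.68, 5e-5, 1000,
                                                    100)$times))
  se <- sqrt(lambda * 100 / 100)        # SE of the mean count, 100 reps
  expect_lt(abs(mean(counts) - lambda * 100), 2 * se)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_frames = 50, seed = 99)
  bm <- binding_model(kon = 5, concentration = 0.001)
  dm <- diffusion_model(frac_species1 = 0.6, D1 = 0.05, D2 = 0.5)
  a <- simulate_trajectories(cfg, bm, dm)
  b <- simulate_trajectories(cfg, bm, dm)
  expect_identical(a$trajectories$tracks, b$trajectories$tracks)
  expect_identical(a$ground_truth$molecules, b$ground_truth$molecules)
})

test_that("trajectories respect dwell, boundary and noise settings", {
  # D = 0, sigma = 0: static track
  cfg <- sim_config(field_width = 10, field_height = 10, n_frames = 60,
                    localization_sigma = 0, seed = 3)
  bm <- binding_model(kon = 20, concentration = 0.005, alpha_fast = 1,
                      tau_fast = 0.4, tau_slow = 0.4)
  dm0 <- diffusion_model(D1 = 0, D2 = 0)
  sim <- simulate_trajectories(cfg, bm, dm0)
  tr <- sim$trajectories$tracks
  expect_gt(nrow(tr), 0)
  for (id in unique(tr$track)) {
    g <- tr[tr$track == id, ]
    expect_equal(diff(range(g$x)), 0)
    expect_equal(diff(range(g$y)), 0)
    expect_equal(g$frame, g$frame[1] + seq_len(nrow(g)) - 1)
  }
  # positions inside the field
  expect_true(all(tr$x >= 0 & tr$x <= 10 & tr$y >= 0 & tr$y <= 10))

  # immobile_frac = 1: zero total displacement
  dmi <- diffusion_model(D1 = 0.2, D2 = 0.5, immobile_frac = 1)
  simi <- simulate_trajectories(cfg, bm, dmi)
  tri <- simi$trajectories$tracks
  for (id in unique(tri$track)) {
    g <- tri[tri$track == id, ]
    expect_lt(max(sqrt((g$x - g$x[1])^2 + (g$y - g$y[1])^2)), 1e-12)
  }

  # first/last frame flags match the detection table
  gt <- sim$ground_truth
  for (i in seq_len(nrow(gt$molecules))) {
    mrec <- gt$molecules[i, ]
    if (mrec$n_detected == 0) next
    g <- gt$positions[gt$positions$track == mrec$molecule, ]
    expect_identical(mrec$in_first_frame, min(g$frame) == 0)
    expect_identical(mrec$in_last_frame, max(g$frame) == cfg$n_frames - 1)
  }
})

test_that("mean step length of a mobile simulation follows sqrt(pi*D*tau)", {
  cfg <- sim_config(field_width = 50, field_height = 50, n_frames = 400,
                    frame_interval = 0.052, localization_sigma = 0,
                    seed = 17)
  bm <- binding_model(kon = 3, concentration = 0.001, alpha_fast = 1,
                      tau_fast = 1.5, tau_slow = 1.5)
  dm <- diffusion_model(D1 = 0.16, D2 = 0.16)
  sim <- simulate_trajectories(cfg, bm, dm)
  steps <- compute_steps(sim$trajectories)
  expect_gt(length(steps), 2000)
  expect_equal(mean(steps), sqrt(pi * 0.16 * 0.052), tolerance = 0.03)
})

test_that("single-species step lengths pass a Rayleigh KS check at n = 1e5", {
  D <- 0.1; tau <- 0.052
  set.seed(23)
  # direct increments, the generative rule the trajectory engine uses
  dx <- rnorm(1e5, 0, sqrt(2 * D * tau))
  dy <- rnorm(1e5, 0, sqrt(2 * D * tau))
  r <- sqrt(dx^2 + dy^2)
  prayleigh <- function(q) 1 - exp(-q^2 / (4 * D * tau))
  ks <- suppressWarnings(ks.test(r, prayleigh))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("rendering places integrated Gaussian spots on the pixel grid", {
  cfg <- sim_config(field_width = 8, field_height = 8, pixel_size = 0.1,
                    n_frames = 3, background_mean = 0, psf_sigma = 1.3,
                    photons_per_spot = 400, seed = 1)
  empty <- trajectory_set(data.frame(track = integer(), frame = integer(),
                                     x = numeric(), y = numeric()),
                          frame_interval = cfg$frame_interval)
  stack0 <- render_movie(empty, cfg, noise = FALSE)
  expect_equal(dim(stack0), c(80, 80, 3))
  expect_true(all(stack0 == 0))

  one <- trajectory_set(data.frame(track = 1L, frame = 0:2, x = 4.26,
                                   y = 3.74), frame_interval = 0.052)
  st <- render_movie(one, cfg, noise = FALSE)
  for (f in 1:3) {
    am <- which(st[, , f] == max(st[, , f]), arr.ind = TRUE)
    expect_equal(unname(am[1, "col"]), 43)  # x = 4.26 um -> pixel col 43
    expect_equal(unname(am[1, "row"]), 38)  # y = 3.74 um -> pixel row 38
  }
  # photons integrate to the configured count (spot well inside field)
  expect_equal(sum(st[, , 1]), 400, tolerance = 1e-6)

  # off-field spot is clipped, not wrapped
  off <- trajectory_set(data.frame(track = 1L, frame = 0L, x = -0.05,
                                   y = 4), frame_interval = 0.052)
  sto <- render_movie(off, cfg, noise = FALSE)
  expect_lt(sum(sto[, , 1]), 400 * 0.6)
  expect_equal(sum(sto[, , 2]), 0)
})

test_that("rendered then re-detected spot center is within 0.1 pixel", {
  cfg <- sim_config(field_width = 10, field_height = 10, pixel_size = 0.1,
                    n_frames = 2, background_mean = 0, psf_sigma = 1.5,
                    photons_per_spot = 1000, seed = 1)
  truth <- data.frame(track = 1L, frame = 0:1, x = c(5.03, 6.44),
                      y = c(4.87, 2.19))
  st <- render_movie(trajectory_set(truth, 0.052), cfg, noise = FALSE)
  sp <- detect_spots(st, radius = 0.21, quality_threshold = 1,
                     pixel_size = 0.1)
  expect_equal(nrow(sp), 2)
  expect_lt(max(abs(sp$x - truth$x)), 0.1 * cfg$pixel_size)
  expect_lt(max(abs(sp$y - truth$y)), 0.1 * cfg$pixel_size)
})

test_that("bulk trace generator hits its half-time and plateau", {
  tr <- simulate_bulk_trace(t_half = 100, plateau = 50, noise_sd = 0,
                            n_points = 401)
  expect_s3_class(tr, "membrane_time_series")
  expect_true(all(diff(tr$intensity) >= -1e-12))    # monotone before noise
  expect_equal(tr$intensity[tr$time == 100], 25)
  flat <- simulate_bulk_trace(t_half = 10, plateau = 0, noise_sd = 0,
                              n_points = 50)
  expect_true(all(flat$intensity == 0))
  # round trip through the half-time estimator
  est <- reaction_half_time(tr, smooth_width = 1)
  expect_equal(as.numeric(est), 100, tolerance = diff(tr$time[1:2]) / 100)
})
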