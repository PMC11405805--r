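# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation.

# Maximum-likelihood fit of a one- or two-component exponential mixture to
# continuous dwell times (direct likelihood optimization, no binning).
mle_exp_mixture <- function(dwells, order = 2) {
  if (order == 1) {
    tau <- mean(dwells)                       # closed-form MLE
    return(list(tau1 = tau, se = c(tau1 = tau / sqrt(length(dwells)))))
  }
  nll <- function(p) {
    tau1 <- exp(p[1]); tau2 <- exp(p[2]); a <- plogis(p[3])
    -sum(log(a / tau1 * exp(-dwells / tau1) +
               (1 - a) / tau2 * exp(-dwells / tau2)))
  }
  m <- mean(dwells)
  starts <- list(c(log(m / 2), log(3 * m), qlogis(0.8)),
                 c(log(m / 4), log(2 * m), qlogis(0.5)),
                 c(log(m), log(10 * m), qlogis(0.9)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, nll, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  tau1 <- exp(best$par[1]); tau2 <- exp(best$par[2]); a <- plogis(best$par[3])
  # delta-method SEs on the natural scale
  vc <- tryCatch(solve(best$hessian), error = function(e)
    matrix(NA, 3, 3))
  grad <- c(tau1, tau2, a * (1 - a))
  se <- sqrt(pmax(diag(vc), 0)) * grad
  if (tau1 > tau2) {
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    a <- 1 - a
    se <- se[c(2, 1, 3)]
  }
  list(tau1 = tau1, tau2 = tau2, alpha = a,
       se = c(tau1 = se[1], tau2 = se[2], alpha = se[3]))
}

# Rule-by-rule brute-force trajectory filter: returns ids of surviving
# tracks given the raw detection table.
brute_force_filter <- function(tracks, frame_interval, n_frames, field,
                               min_frames = 3, min_disp = 0.1,
                               edge_margin = 1, max_duration = Inf) {
  keep <- c()
  for (id in unique(tracks$track)) {
    g <- tracks[tracks$track == id, ]
    g <- g[order(g$frame), ]
    ok <- TRUE
    if (g$frame[1] == 0) ok <- FALSE
    if (g$frame[nrow(g)] == n_frames - 1) ok <- FALSE
    if (nrow(g) < min_frames) ok <- FALSE
    disp <- 0
    for (i in seq_len(nrow(g)))
      disp <- max(disp, sqrt((g$x[i] - g$x[1])^2 + (g$y[i] - g$y[1])^2))
    if (disp < min_disp) ok <- FALSE
    for (i in seq_len(nrow(g))) {
      if (g$x[i] < edge_margin || g$x[i] > field[1] - edge_margin ||
          g$y[i] < edge_margin || g$y[i] > field[2] - edge_margin)
        ok <- FALSE
    }
    if ((nrow(g) - 1) * frame_interval > max_duration) ok <- FALSE
    if (ok) keep <- c(keep, id)
  }
  keep
}

# Brute-force optimal assignment by permutation enumeration (n <= 7).
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

# total cost of the assignment returned by tirfkin's LAP solver
lap_solution_cost <- function(cost) {
  sol <- tirfkin:::solve_lap(cost)
  sum(cost[cbind(seq_along(sol), sol)])
}

# simple two-group pooled-variance t statistic, computed by hand
hand_t_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# canonical generating parameter sets used across tests (reference fit
# parameters of the study proteins, used here as simulation ground truth)
wt_pip5k_params <- list(tau1 = 0.815, tau2 = 3.09, alpha = 0.95,
                        n = 14950, dt = 0.052)
pip4k_params <- list(tau1 = 0.248, tau2 = 1.82, alpha = 0.81,
                     n = 13117, dt = 0.052)
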