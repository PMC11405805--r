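#' Frame-to-frame step sizes of a trajectory set
#'
#' Euclidean displacements between detections `lag` frames apart, pooled
#' over all tracks. The lag time is `lag * frame_interval`.
#'
#' @param set A [trajectory_set()].
#' @param lag Lag in frames (default 1, the interval the step-size
#'   distributions are built at).
#' @return Numeric vector of step lengths (um) with attribute `tau`
#'   (lag time, s).
#' @export
compute_steps <- function(set, lag = 1) {
  stopifnot(inherits(set, "trajectory_set"), lag >= 1)
  lag <- as.integer(lag)
  tr <- set$tracks
  steps <- unlist(lapply(split(tr, tr$track), function(g) {
    n <- nrow(g)
    if (n <= lag) return(numeric(0))
    i <- seq_len(n - lag)
    sqrt((g$x[i + lag] - g$x[i])^2 + (g$y[i + lag] - g$y[i])^2)
  }), use.names = FALSE)
  attr(steps, "tau") <- lag * set$frame_interval
  steps
}

#' Step-size probability density
#'
#' Histogram of step lengths with fixed bin width (0.01 um by default),
#' normalized to a probability density (counts divided by `n * bin_width`)
#' so it can be fit directly against the Rayleigh mixture models.
#'
#' @param steps Step lengths (um), e.g. from [compute_steps()]; at least
#'   100.
#' @param bin_width Bin width (um, default 0.01).
#' @param tau Lag time (s); taken from `attr(steps, "tau")` if absent.
#' @return Object of class `step_density`: list with `bin_centers`,
#'   `density` (per um), `counts`, `bin_width`, `tau`, `n`.
#' @export
build_step_density <- function(steps, bin_width = 0.01, tau = NULL) {
  stopifnot(bin_width > 0)
  if (length(steps) < 100)
    stop("need at least 100 steps")
  if (is.null(tau)) tau <- attr(steps, "tau")
  if (is.null(tau)) stop("lag time `tau` must be supplied")
  nbin <- max(1L, ceiling(max(steps) / bin_width + 1e-9))
  edges <- seq(0, nbin * bin_width, by = bin_width)
  counts <- tabulate(pmin(pmax(ceiling(steps / bin_width - 1e-12), 1L),
                          nbin), nbins = nbin)
  structure(list(bin_centers = edges[-1] - bin_width / 2,
                 density = counts / (length(steps) * bin_width),
                 counts = counts, bin_width = bin_width, tau = tau,
                 n = length(steps)),
            class = "step_density")
}

#' @export
print.step_density <- function(x, ...) {
  cat(sprintf("<step_density> n = %d steps, %d bins of %g um, tau = %g s\n",
              x$n, length(x$bin_centers), x$bin_width, x$tau))
  invisible(x)
}

#' Fit one- or two-species Brownian models to a step-size density
#'
#' Fits the 2D Brownian step-size (Rayleigh) models
#' `f(r) = r / (2 D tau) * exp(-r^2 / (4 D tau))` (one species) or
#' `f(r) = alpha * r / (2 D1 tau) * exp(-r^2 / (4 D1 tau)) + (1 - alpha) *
#' r / (2 D2 tau) * exp(-r^2 / (4 D2 tau))` (two species) to the binned
#' probability density by constrained nonlinear least squares with
#' multi-start initialization. Zero-count bins participate with density 0.
#'
#' @param density A [build_step_density()] object; order 1 needs >= 1e3
#'   underlying steps, order 2 >= 1e4.
#' @param order 1 or 2.
#' @return Object of class `diffusion_fit`: `order`, `D1`, `D2` (um^2/s,
#'   `D1 <= D2`), `alpha` (fraction of species 1), `se`, `rss`, `n`,
#'   `converged`. Degenerate two-species fits (`alpha` outside
#'   `[0.01, 0.99]` or `D2/D1 < 1.2`) are flagged in `degenerate`.
#' @export
fit_step_density <- function(density, order = 1) {
  stopifnot(inherits(density, "step_density"), order %in% c(1, 2))
  if (order == 1 && density$n < 1e3)
    stop("order-1 fit needs a density built from >= 1000 steps")
  if (order == 2 && density$n < 1e4)
    stop("order-2 fit needs a density built from >= 10000 steps")
  r <- density$bin_centers
  y <- density$density
  tau <- density$tau
  # moment start: mean step of a single Rayleigh is sqrt(pi * D * tau)
  mstep <- sum(r * y) * density$bin_width
  D0 <- max(mstep^2 / (pi * tau), 1e-6)

  if (order == 1) {
    form <- y ~ r / (2 * D1 * tau) * exp(-r^2 / (4 * D1 * tau))
    starts <- lapply(c(1, 0.3, 3), function(f) list(D1 = D0 * f))
    lower <- c(D1 = 1e-8); upper <- c(D1 = Inf)
  } else {
    form <- y ~ alpha * r / (2 * D1 * tau) * exp(-r^2 / (4 * D1 * tau)) +
      (1 - alpha) * r / (2 * D2 * tau) * exp(-r^2 / (4 * D2 * tau))
    starts <- list(list(D1 = 0.3 * D0, D2 = 3 * D0, alpha = 0.5),
                   list(D1 = 0.1 * D0, D2 = 2 * D0, alpha = 0.7),
                   list(D1 = 0.5 * D0, D2 = 10 * D0, alpha = 0.3),
                   list(D1 = D0, D2 = D0, alpha = 0.5))
    lower <- c(D1 = 1e-8, D2 = 1e-8, alpha = 0)
    upper <- c(D1 = Inf, D2 = Inf, alpha = 1)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(y = y, r = r, tau = tau),
                        start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-15)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(structure(list(order = order, D1 = NA_real_, D2 = NA_real_,
                          alpha = NA_real_, se = NULL, rss = NA_real_,
                          n = density$n, converged = FALSE,
                          degenerate = NA),
                     class = c("fit_failure", "diffusion_fit")))
  p <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    setNames(rep(NA_real_, length(p)), names(p)))
  if (order == 1) {
    out <- list(order = 1, D1 = unname(p["D1"]), D2 = NA_real_,
                alpha = NA_real_, se = c(D1 = unname(se["D1"])),
                degenerate = FALSE)
  } else {
    D1 <- unname(p["D1"]); D2 <- unname(p["D2"]); alpha <- unname(p["alpha"])
    se2 <- c(D1 = unname(se["D1"]), D2 = unname(se["D2"]),
             alpha = unname(se["alpha"]))
    if (D1 > D2) {  # alpha stays the fraction of the slower species 1
      tmp <- D1; D1 <- D2; D2 <- tmp
      alpha <- 1 - alpha
      se2 <- c(D1 = se2[["D2"]], D2 = se2[["D1"]], alpha = se2[["alpha"]])
    }
    out <- list(order = 2, D1 = D1, D2 = D2, alpha = alpha, se = se2,
                degenerate = alpha < 0.01 || alpha > 0.99 ||
                  D2 / D1 < 1.2)
  }
  out$rss <- best$rss
  out$n <- density$n
  out$converged <- TRUE
  out$model <- best$fit
  structure(out, class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, digits = 4, ...) {
  if (!x$converged) {
    cat("<diffusion_fit> FAILED to converge\n")
    return(invisible(x))
  }
  if (x$order == 1) {
    cat(sprintf("<diffusion_fit> single species: D = %.*g um^2/s (n = %d)\n",
                digits, x$D1, x$n))
  } else {
    cat(sprintf(
      "<diffusion_fit> two species: D1 = %.*g, D2 = %.*g um^2/s, alpha = %.*g (n = %d)%s\n",
      digits, x$D1, digits, x$D2, digits, x$alpha, x$n,
      if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Mean single-molecule displacement
#'
#' Arithmetic mean (and SD) of step lengths; for pure 2D Brownian motion
#' with diffusivity D and lag tau the expectation is `sqrt(pi * D * tau)`.
#'
#' @param steps Step lengths (um), nonempty.
#' @return Named vector `c(mean, sd, n)`.
#' @export
mean_displacement <- function(steps) {
  stopifnot(length(steps) > 0)
  c(mean = mean(steps), sd = sd(steps), n = length(steps))
}

#' Per-cell mean displacements and two-group comparison
#'
#' One mean step length per cell, plus group statistics and the unpaired
#' two-tailed Student's t-test between the two groups.
#'
#' @param groups Named list of two groups; each group a list of per-cell
#'   step-length vectors (um).
#' @return List with `table` (group, cell, mean_step, n), `group_stats`,
#'   `t_test`, `p_value`.
#' @export
per_cell_displacement <- function(groups) {
  stopifnot(is.list(groups), length(groups) == 2, !is.null(names(groups)))
  tab <- do.call(rbind, lapply(names(groups), function(g) {
    cells <- groups[[g]]
    if (length(cells) < 2) stop("need at least 2 cells per group")
    do.call(rbind, lapply(seq_along(cells), function(i)
      data.frame(group = g, cell = i, mean_step = mean(cells[[i]]),
                 n = length(cells[[i]]))))
  }))
  gs <- do.call(rbind, lapply(names(groups), function(g) {
    v <- tab$mean_step[tab$group == g]
    data.frame(group = g, mean = mean(v), sd = sd(v), n_cells = length(v))
  }))
  tt <- t.test(tab$mean_step[tab$group == names(groups)[1]],
               tab$mean_step[tab$group == names(groups)[2]],
               var.equal = TRUE, alternative = "two.sided")
  list(table = tab, group_stats = gs, t_test = tt, p_value = tt$p.value)
}
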