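#' Compute membrane dwell times from trajectories
#'
#' The dwell time of a track is `(number of detections - 1) *
#' frame_interval`. Tracks are expected to be pre-filtered (see
#' [filter_trajectories()]); single-detection tracks are rejected.
#'
#' @param set A [trajectory_set()].
#' @return Numeric vector of dwell times (s), one per track.
#' @export
compute_dwell_times <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  n_det <- table(set$tracks$track)
  if (any(n_det < 2))
    stop("single-frame tracks present; filter trajectories first")
  as.numeric(n_det - 1) * set$frame_interval
}

#' Build a dwell-time survival curve
#'
#' Computes the empirical survival function `1 - CDF` of the dwell times
#' on the acquisition grid (bin edges at integer multiples of the frame
#' interval, the frame interval being the bin size) and its log10, the
#' form in which dwell-time distributions are plotted and fitted.
#'
#' @param dwells Dwell times (s); at least 10.
#' @param frame_interval Frame interval (s).
#' @return An object of class `dwell_survival`: list with `dwell_times`,
#'   `frame_interval`, `bin_edges` (s; starts at 0), `survival`,
#'   `log10_survival` (`NA` where survival is 0), `n`, and a `fittable`
#'   flag (`FALSE` when the curve has fewer than two usable points, e.g.
#'   all dwells identical).
#' @examples
#' s <- build_survival(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), frame_interval = 1)
#' s$log10_survival[s$bin_edges == 1]  # log10(0.8)
#' @export
build_survival <- function(dwells, frame_interval) {
  stopifnot(frame_interval > 0)
  if (length(dwells) < 10)
    stop("need at least 10 dwell times")
  n <- length(dwells)
  # frame counts; dwells already on the grid map exactly
  k <- ceiling(dwells / frame_interval - 1e-9)
  kmax <- max(k)
  edges_k <- 0:kmax
  surv <- vapply(edges_k, function(e) sum(k > e), numeric(1)) / n
  structure(list(dwell_times = as.numeric(dwells),
                 frame_interval = frame_interval,
                 bin_edges = edges_k * frame_interval,
                 survival = surv,
                 log10_survival = ifelse(surv > 0, log10(surv), NA_real_),
                 n = n,
                 # informative points are those with 0 < survival < 1;
                 # all-identical dwells give none and cannot be fit
                 fittable = sum(surv > 0 & surv < 1) >= 1),
            class = "dwell_survival")
}

#' @export
print.dwell_survival <- function(x, ...) {
  cat(sprintf("<dwell_survival> n = %d, dt = %g s, %d bin edges\n",
              x$n, x$frame_interval, length(x$bin_edges)))
  invisible(x)
}

#' Fit one- or two-exponential models to a survival curve
#'
#' Fits the survival models `S(t) = exp(-t / tau)` (order 1) or
#' `S(t) = alpha * exp(-t / tau1) + (1 - alpha) * exp(-t / tau2)`
#' (order 2) by constrained nonlinear least squares
#' ([minpack.lm::nlsLM()]) with multi-start initialization. `alpha` is
#' always the fraction of the fast-dissociating population: the fit is
#' re-ordered so that `tau1 <= tau2`. By default the objective is the
#' survival curve on the linear scale; `objective = "log"` fits the
#' log10 curve instead (the scale on which it is plotted). Fitting on the
#' linear scale avoids over-weighting the sparse tail.
#'
#' @param curve A [build_survival()] curve.
#' @param order 1 or 2.
#' @param objective `"linear"` (default) or `"log"`.
#' @return An object of class `exp_mixture_fit`: list with `order`,
#'   `tau1`, `tau2`, `alpha`, standard errors (`se`, named), `rss`
#'   (residual sum of squares on the fit scale), `n` (number of dwell
#'   times), `n_points` (fitted curve points), `converged`, and the
#'   fitted model object. On non-convergence a failure object
#'   (`converged = FALSE`, parameters `NA`) is returned -- never silent
#'   `NaN`s.
#' @export
fit_survival <- function(curve, order = 2,
                         objective = c("linear", "log")) {
  stopifnot(inherits(curve, "dwell_survival"), order %in% c(1, 2))
  objective <- match.arg(objective)
  usable <- curve$survival > 0
  t <- curve$bin_edges[usable]
  S <- curve$survival[usable]
  if (sum(usable) < 2 * order + 1)
    stop("survival curve has too few usable points for order ", order)
  y <- if (objective == "log") log10(S) else S
  med <- median(curve$dwell_times)
  tau0 <- max(med / log(2), curve$frame_interval)

  rhs <- if (order == 1) "exp(-t / tau1)" else
    "alpha * exp(-t / tau1) + (1 - alpha) * exp(-t / tau2)"
  if (objective == "log")
    rhs <- sprintf("log10(pmax(%s, 1e-300))", rhs)
  form <- stats::as.formula(paste("y ~", rhs))

  starts <- if (order == 1) {
    lapply(c(1, 0.5, 2, 5), function(f) list(tau1 = tau0 * f))
  } else {
    list(list(tau1 = tau0, tau2 = 5 * tau0, alpha = 0.8),
         list(tau1 = 0.5 * tau0, tau2 = 3 * tau0, alpha = 0.6),
         list(tau1 = 0.3 * tau0, tau2 = 10 * tau0, alpha = 0.9),
         list(tau1 = 2 * tau0, tau2 = 20 * tau0, alpha = 0.5))
  }
  lower <- if (order == 1) c(tau1 = curve$frame_interval / 100) else
    c(tau1 = curve$frame_interval / 100,
      tau2 = curve$frame_interval / 100, alpha = 0)
  upper <- if (order == 1) c(tau1 = Inf) else
    c(tau1 = Inf, tau2 = Inf, alpha = 1)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, data = data.frame(y = y, t = t),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(order = order, tau1 = NA_real_, tau2 = NA_real_,
                          alpha = NA_real_, se = NULL, rss = NA_real_,
                          n = curve$n, n_points = length(t),
                          objective = objective, converged = FALSE,
                          model = NULL),
                     class = c("fit_failure", "exp_mixture_fit")))
  }
  p <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    setNames(rep(NA_real_, length(p)), names(p)))
  if (order == 1) {
    out <- list(order = 1, tau1 = unname(p["tau1"]), tau2 = NA_real_,
                alpha = NA_real_,
                se = c(tau1 = unname(se["tau1"])))
  } else {
    tau1 <- unname(p["tau1"]); tau2 <- unname(p["tau2"])
    alpha <- unname(p["alpha"])
    se2 <- c(tau1 = unname(se["tau1"]), tau2 = unname(se["tau2"]),
             alpha = unname(se["alpha"]))
    if (tau1 > tau2) {  # enforce tau1 <= tau2; alpha stays the fast fraction
      tmp <- tau1; tau1 <- tau2; tau2 <- tmp
      alpha <- 1 - alpha
      se2 <- c(tau1 = se2[["tau2"]], tau2 = se2[["tau1"]],
               alpha = se2[["alpha"]])
    }
    out <- list(order = 2, tau1 = tau1, tau2 = tau2, alpha = alpha, se = se2)
  }
  out$rss <- best$rss
  out$n <- curve$n
  out$n_points <- length(t)
  out$objective <- objective
  out$converged <- TRUE
  out$model <- best$fit
  structure(out, class = "exp_mixture_fit")
}

#' @export
print.exp_mixture_fit <- function(x, digits = 4, ...) {
  if (!x$converged) {
    cat("<exp_mixture_fit> FAILED to converge\n")
    return(invisible(x))
  }
  if (x$order == 1) {
    cat(sprintf("<exp_mixture_fit> single exponential: tau = %.*g +/- %.*g s (n = %d)\n",
                digits, x$tau1, 2, x$se[["tau1"]], x$n))
  } else {
    cat(sprintf(
      "<exp_mixture_fit> two exponentials: tau1 = %.*g s, tau2 = %.*g s, alpha = %.*g (n = %d)\n",
      digits, x$tau1, digits, x$tau2, digits, x$alpha, x$n))
  }
  invisible(x)
}

#' Select the exponential model order for a survival curve
#'
#' Fits both the single- and the two-exponential model and keeps the
#' second component only when it is statistically justified: a
#' likelihood-ratio test on the binned dwell counts must reject the
#' single-exponential model at `p < alpha_level` AND the two-component
#' fit must be non-degenerate (`tau2 / tau1 >= 2` and the fast fraction
#' inside `[0.01, 0.99]`). Never more than two components.
#'
#' The test statistic is `G2 = 2 (ll2 - ll1)`, where `ll` is the
#' multinomial log-likelihood of each fitted survival model evaluated on
#' the per-frame dwell counts, referred to a chi-square with 2 degrees of
#' freedom. Because dwell times are independent, this test is calibrated;
#' the extra-sum-of-squares F-statistic on the curve points, which badly
#' overstates significance on serially correlated survival values, is
#' still reported as a diagnostic (`f_statistic`).
#'
#' @param curve A [build_survival()] curve.
#' @param alpha_level Significance level of the likelihood-ratio test
#'   (default 0.01).
#' @param objective Fit scale, see [fit_survival()].
#' @return List with `order` (1 or 2), the chosen `fit`, both candidate
#'   fits, the likelihood-ratio `p_value`, and `f_statistic`.
#' @export
select_model <- function(curve, alpha_level = 0.01,
                         objective = c("linear", "log")) {
  objective <- match.arg(objective)
  f1 <- fit_survival(curve, order = 1, objective = objective)
  f2 <- tryCatch(fit_survival(curve, order = 2, objective = objective),
                 error = function(e) structure(list(converged = FALSE),
                                               class = "fit_failure"))
  p_value <- NA_real_
  fstat <- NA_real_
  order <- 1L
  if (f1$converged && isTRUE(f2$converged)) {
    g2 <- 2 * (binned_loglik(curve, f2) - binned_loglik(curve, f1))
    p_value <- stats::pchisq(g2, df = 2, lower.tail = FALSE)
    df2 <- f2$n_points - 3
    if (df2 > 0 && f2$rss > 0)
      fstat <- ((f1$rss - f2$rss) / 2) / (f2$rss / df2)
    nondegenerate <- f2$tau2 / f2$tau1 >= 2 &&
      f2$alpha >= 0.01 && f2$alpha <= 0.99
    if (!is.na(p_value) && p_value < alpha_level && nondegenerate)
      order <- 2L
  } else if (!f1$converged && isTRUE(f2$converged)) {
    order <- 2L
  }
  list(order = order, fit = if (order == 1) f1 else f2,
       fit1 = f1, fit2 = f2, p_value = p_value, f_statistic = fstat)
}

# multinomial log-likelihood of a fitted survival model on the per-frame
# dwell counts of the curve's sample
binned_loglik <- function(curve, fit) {
  dt <- curve$frame_interval
  k <- pmax(1L, ceiling(curve$dwell_times / dt - 1e-9))
  kmax <- max(k)
  S <- function(t) {
    if (fit$order == 1) exp(-t / fit$tau1) else
      fit$alpha * exp(-t / fit$tau1) + (1 - fit$alpha) * exp(-t / fit$tau2)
  }
  Sv <- S((0:kmax) * dt)
  p <- Sv[1:kmax] - Sv[2:(kmax + 1)]   # P(dwell in frame bin j)
  cnt <- tabulate(k, nbins = kmax)
  sum(cnt * log(pmax(p, 1e-300)))
}

#' Fraction of transient membrane-binding events
#'
#' Fraction of dwell times strictly below a threshold; the default
#' 0.104 s corresponds to two frames at a 52 ms frame interval.
#'
#' @param dwells Dwell times (s), nonempty.
#' @param threshold Transience threshold (s).
#' @return Fraction in `[0, 1]`.
#' @export
classify_transient <- function(dwells, threshold = 0.104) {
  stopifnot(length(dwells) > 0, threshold > 0)
  mean(dwells < threshold)
}

#' Per-cell dwell-time fits and two-group comparison
#'
#' Fits one exponential model per cell's dwell-time sample, tabulates the
#' cell-level time constants, and compares two groups of cells with the
#' standard unpaired two-tailed Student's t-test (pooled variance).
#' Cells whose curve cannot be built or fit are excluded with a message.
#'
#' @param groups Named list of two groups; each group is a list of
#'   per-cell dwell-time vectors (s).
#' @param frame_interval Frame interval (s).
#' @param order Model order per cell (default 1, the usual choice for
#'   per-cell samples).
#' @param objective Fit scale, see [fit_survival()].
#' @return List with `table` (data frame: group, cell, tau1, n),
#'   `group_stats` (mean, sd, n cells per group) and `t_test` (the
#'   `htest` object), plus `p_value`.
#' @export
per_cell_summary <- function(groups, frame_interval, order = 1,
                             objective = c("linear", "log")) {
  stopifnot(is.list(groups), length(groups) == 2, !is.null(names(groups)))
  objective <- match.arg(objective)
  rows <- list()
  for (g in names(groups)) {
    cells <- groups[[g]]
    if (length(cells) < 2)
      stop("need at least 2 cells per group")
    for (i in seq_along(cells)) {
      fit <- tryCatch({
        crv <- build_survival(cells[[i]], frame_interval)
        if (!crv$fittable) stop("unfittable curve")
        fit_survival(crv, order = order, objective = objective)
      }, error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        message(sprintf("cell %d of group '%s' excluded (unfittable)", i, g))
        next
      }
      rows[[length(rows) + 1]] <-
        data.frame(group = g, cell = i, tau1 = fit$tau1,
                   n = length(cells[[i]]))
    }
  }
  tab <- do.call(rbind, rows)
  gs <- do.call(rbind, lapply(names(groups), function(g) {
    v <- tab$tau1[tab$group == g]
    data.frame(group = g, mean = mean(v), sd = sd(v), n_cells = length(v))
  }))
  tt <- t.test(tab$tau1[tab$group == names(groups)[1]],
               tab$tau1[tab$group == names(groups)[2]],
               var.equal = TRUE, alternative = "two.sided")
  list(table = tab, group_stats = gs, t_test = tt, p_value = tt$p.value)
}
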