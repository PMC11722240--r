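#' Time derivatives of the lateral-inhibition circuit
#'
#' Evaluates the right-hand side of the dimensionless Notch-Delta system
#' for an arbitrary number of cells. The neighbour Delta input of cell *i*
#' is the arithmetic mean of its neighbours' Delta levels, which for a
#' two-cell pair is simply the partner's Delta.
#'
#' @param notch,delta Numeric vectors of per-cell activated-Notch and Delta
#'   levels (non-negative, one entry per cell).
#' @param params A [circuit_params()] object.
#' @param topology Neighbour map as returned by [make_topology()]; defaults
#'   to all-mutual coupling.
#' @return A list with components `dnotch` and `ddelta`.
#' @examples
#' p <- circuit_params(kn = 0.5, kd = 0.25)
#' nd_derivatives(c(0, 0), c(0, 0), p)  # dN = 0, dD = v
#' @export
nd_derivatives <- function(notch, delta, params,
                           topology = make_topology(length(notch))) {
  stopifnot(inherits(params, "circuit_params"))
  n <- length(notch)
  if (length(delta) != n) stop("`notch` and `delta` must have the same length", call. = FALSE)
  if (length(topology) != n) stop("topology size does not match number of cells", call. = FALSE)
  if (any(lengths(topology) == 0L)) stop("every cell needs at least one neighbour", call. = FALSE)
  if (any(notch < 0) || any(delta < 0)) stop("state values must be >= 0", call. = FALSE)
  dbar <- vapply(topology, function(nb) mean(delta[nb]), numeric(1))
  dn <- dbar^params$r / (params$kn^params$r + dbar^params$r) - notch
  dd <- params$v * (1 / (1 + (notch / params$kd)^params$h) - delta)
  list(dnotch = dn, ddelta = dd)
}

# deSolve-compatible RHS; state packed as c(N_1..N_n, D_1..D_n)
nd_rhs <- function(t, y, parms) {
  n <- parms$n_cells
  d <- nd_derivatives(y[seq_len(n)], y[n + seq_len(n)], parms$params, parms$topology)
  list(c(d$dnotch, d$ddelta))
}

#' Simulate the lateral-inhibition circuit
#'
#' Integrates the dimensionless Notch-Delta equations for a group of
#' coupled cells with an adaptive solver (`deSolve::ode`, method `lsoda`,
#' rtol 1e-8 / atol 1e-10) and samples the solution on a dense regular
#' grid. Reporter accumulation is computed alongside via
#' [reporter_accumulation()].
#'
#' `simulate_pair()` reproduces the canonical two-cell set-up: both cells
#' start with high Delta and low Notch, with the symmetry broken by a
#' slightly higher initial Notch in cell 2 (0.011 versus 0.010).
#' `simulate_triplet()` runs three mutually coupled cells, mimicking the
#' cell clusters that form after injury, with the same style of
#' symmetry-breaking initial condition on the last cell.
#'
#' @param params A [circuit_params()] object.
#' @param init_notch,init_delta Initial per-cell Notch and Delta levels.
#' @param topology Neighbour map (list of neighbour index vectors).
#' @param t_end End of the integration window (dimensionless time,
#'   default 10).
#' @param dt_out Output grid spacing (default 0.01).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `nd_trajectory`: a list with `times`
#'   (output grid), `notch`, `delta`, `reporter` (time-by-cell matrices),
#'   `params` and `topology`.
#' @examples
#' tr <- simulate_pair(circuit_params(kn = 0.5, kd = 0.25))
#' tail(tr$delta, 1)  # cell 2 has won the fate competition: low Delta
#' @export
simulate_cells <- function(params, init_notch, init_delta,
                           topology = make_topology(length(init_notch)),
                           t_end = 10, dt_out = 0.01,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "circuit_params"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  n <- length(init_notch)
  if (length(init_delta) != n) stop("initial Notch and Delta must have the same length", call. = FALSE)
  if (any(init_notch < 0) || any(init_delta < 0)) stop("initial state must be >= 0", call. = FALSE)
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  y0 <- c(init_notch, init_delta)
  sol <- deSolve::ode(
    y = y0, times = times, func = nd_rhs,
    parms = list(params = params, topology = topology, n_cells = n),
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (anyNA(sol) || any(!is.finite(sol))) {
    stop("integration produced non-finite state; check parameters", call. = FALSE)
  }
  notch <- unname(sol[, 1 + seq_len(n), drop = FALSE])
  delta <- unname(sol[, 1 + n + seq_len(n), drop = FALSE])
  traj <- structure(
    list(times = unname(sol[, 1]), notch = notch, delta = delta,
         reporter = NULL, params = params, topology = topology,
         n_cells = n),
    class = "nd_trajectory"
  )
  traj$reporter <- reporter_accumulation(traj, beta = params$beta)
  traj
}

#' @rdname simulate_cells
#' @export
simulate_pair <- function(params, init_notch = c(0.010, 0.011),
                          init_delta = c(1, 1), t_end = 10, ...) {
  stopifnot(length(init_notch) == 2L, length(init_delta) == 2L)
  simulate_cells(params, init_notch, init_delta,
                 topology = make_topology(2), t_end = t_end, ...)
}

#' @rdname simulate_cells
#' @export
simulate_triplet <- function(params, init_notch = c(0.010, 0.010, 0.011),
                             init_delta = c(1, 1, 1),
                             topology = make_topology(3), t_end = 10, ...) {
  stopifnot(length(init_notch) == 3L, length(init_delta) == 3L)
  simulate_cells(params, init_notch, init_delta,
                 topology = topology, t_end = t_end, ...)
}

#' @export
print.nd_trajectory <- function(x, ...) {
  cat(sprintf("Notch-Delta trajectory: %d cells, t in [0, %g], %d time points\n",
              x$n_cells, max(x$times), length(x$times)))
  nf <- x$notch[nrow(x$notch), ]
  df <- x$delta[nrow(x$delta), ]
  cat(sprintf("  final Notch: %s\n", paste(signif(nf, 3), collapse = ", ")))
  cat(sprintf("  final Delta: %s\n", paste(signif(df, 3), collapse = ", ")))
  invisible(x)
}

#' Convert a trajectory to a long data frame
#'
#' @param x An `nd_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `cell`, `notch`, `delta`,
#'   `reporter`.
#' @export
as.data.frame.nd_trajectory <- function(x, ...) {
  n <- x$n_cells
  tibble::tibble(
    time = rep(x$times, times = n),
    cell = rep(seq_len(n), each = length(x$times)),
    notch = as.vector(x$notch),
    delta = as.vector(x$delta),
    reporter = as.vector(x$reporter)
  )
}

# cumulative trapezoid of y over grid t (both vectors)
cumtrapz1 <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Downstream reporter accumulation
#'
#' Computes per-cell reporter levels from a trajectory. The default
#' (`mode = "integral"`) treats the reporter as the running integral of
#' activated Notch scaled by the maximal production rate `beta`
#' (\eqn{R_i(t) = \beta \int_0^t N_i \, dt}), which is the
#' early-time approximation in which production dominates turnover. The
#' full mode (`mode = "ode"`) solves
#' \eqn{dR_i/dt = \beta N_i - \alpha R_i} exactly on the output grid
#' (piecewise-linear Notch), and reduces to the integral mode as
#' \eqn{\alpha \to 0}.
#'
#' @param traj An `nd_trajectory`.
#' @param beta Maximal reporter production rate (>= 0).
#' @param alpha Reporter degradation rate, used by `mode = "ode"`.
#' @param mode `"integral"` (default) or `"ode"`.
#' @return A time-by-cell matrix of reporter levels, monotone
#'   non-decreasing in the integral mode.
#' @export
reporter_accumulation <- function(traj, beta = 1, alpha = traj$params$alpha,
                                  mode = c("integral", "ode")) {
  mode <- match.arg(mode)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (length(traj$times) < 2L) stop("trajectory needs at least 2 time points", call. = FALSE)
  if (mode == "integral") {
    return(apply(traj$notch, 2, function(nser) beta * cumtrapz1(traj$times, nser)))
  }
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  apply(traj$notch, 2, function(nser) reporter_ode1(traj$times, nser, beta, alpha))
}

# Exact update of dR/dt = beta*N(t) - alpha*R with N linear on each output
# interval. The convolution integral has a closed form; for alpha*h below
# 1e-4 a second-order series avoids catastrophic cancellation and limits
# exactly to the trapezoid rule at alpha = 0.
reporter_ode1 <- function(t, nser, beta, alpha) {
  n <- length(t)
  out <- numeric(n)
  for (k in seq_len(n - 1L)) {
    h <- t[k + 1L] - t[k]
    n0 <- nser[k]; n1 <- nser[k + 1L]
    ah <- alpha * h
    if (ah < 1e-4) {
      j <- h * (n0 + n1) / 2 - alpha * h^2 * (2 * n0 + n1) / 6
    } else {
      m <- (n1 - n0) / h
      e <- exp(-ah)
      j <- n0 * (1 - e) / alpha + m * (h / alpha - (1 - e) / alpha^2)
    }
    out[k + 1L] <- out[k] * exp(-ah) + beta * j
  }
  out
}

# index of the cell with the highest Notch at the final time point;
# ties broken toward the lowest index
high_notch_cell <- function(traj) {
  which.max(traj$notch[nrow(traj$notch), ])
}

#' Steady-state Delta of the winning (high-Notch) cell
#'
#' Runs the default two-cell simulation to `t_end` and returns the Delta
#' level of the high-Notch cell at the end of the window. In the healthy
#' regime (low `kd`) lateral inhibition drives this value towards zero; in
#' the injury regime (high `kd`) the winning cell keeps expressing Delta.
#'
#' @param params A [circuit_params()] object.
#' @param t_end Evaluation time (default 10).
#' @param ... Passed to [simulate_pair()].
#' @return The Delta level of the high-Notch cell at `t_end`.
#' @examples
#' steady_state_delta(circuit_params(kn = 0.5, kd = 0.25))  # ~0: healthy
#' steady_state_delta(circuit_params(kn = 0.5, kd = 1))     # >0.5: injury
#' @export
steady_state_delta <- function(params, t_end = 10, ...) {
  traj <- simulate_pair(params, t_end = t_end, ...)
  traj$delta[nrow(traj$delta), high_notch_cell(traj)]
}

#' Notch signalling speed
#'
#' Mean rate of reporter accumulation of the high-Notch cell over the
#' window `t_from` to `t_to` (defaults 4 to 10), with `beta = 1`. Reporter
#' values at the window endpoints are obtained by linear interpolation on
#' the dense output grid. Raising `kd` at fixed `kn` increases this speed:
#' the losing neighbour keeps presenting Delta, so the winner's Notch
#' output builds faster.
#'
#' @param params A [circuit_params()] object.
#' @param t_from,t_to Averaging window (dimensionless time).
#' @param ... Passed to [simulate_pair()].
#' @return Mean reporter accumulation rate (scalar).
#' @export
signaling_speed <- function(params, t_from = 4, t_to = 10, ...) {
  stopifnot(t_to > t_from)
  traj <- simulate_pair(params, t_end = max(10, t_to), ...)
  rep_hi <- reporter_accumulation(traj, beta = 1)[, high_notch_cell(traj)]
  r4 <- stats::approx(traj$times, rep_hi, xout = t_from)$y
  r10 <- stats::approx(traj$times, rep_hi, xout = t_to)$y
  (r10 - r4) / (t_to - t_from)
}

#' Phase map over the (KN, KD) parameter plane
#'
#' Evaluates a scalar circuit metric (steady-state Delta of the winning
#' cell, or signalling speed) at every combination of `kn` and `kd`. The
#' default grid follows the experimentally plausible ranges for healthy
#' midgut cells: `kn` log-spaced over 0.1-10 and `kd` spanning 0.1-2.
#'
#' @param kn_values,kd_values Positive grid axes.
#' @param metric `"steady_state_delta"` or `"signaling_speed"`.
#' @param v,r,h,beta Circuit constants shared across the grid.
#' @param ... Passed to the underlying simulation.
#' @return An object of class `phase_map`: list with `kn_values`,
#'   `kd_values`, `metric` and a `values` matrix (rows = kn, cols = kd).
#' @examples
#' pm <- phase_map(kn_values = c(0.5, 1), kd_values = c(0.25, 1),
#'                 metric = "steady_state_delta")
#' as.data.frame(pm)
#' @export
phase_map <- function(kn_values = 10^seq(-1, 1, length.out = 21),
                      kd_values = seq(0.1, 2, length.out = 20),
                      metric = c("steady_state_delta", "signaling_speed"),
                      v = 1, r = 2L, h = 2L, beta = 1, ...) {
  metric <- match.arg(metric)
  if (length(kn_values) == 0L || length(kd_values) == 0L)
    stop("grid axes must be non-empty", call. = FALSE)
  if (any(kn_values <= 0) || any(kd_values <= 0))
    stop("grid values must be positive", call. = FALSE)
  fn <- switch(metric, steady_state_delta = steady_state_delta,
               signaling_speed = signaling_speed)
  vals <- matrix(NA_real_, length(kn_values), length(kd_values))
  for (i in seq_along(kn_values)) {
    for (j in seq_along(kd_values)) {
      vals[i, j] <- tryCatch(
        fn(circuit_params(kn = kn_values[i], kd = kd_values[j],
                          v = v, r = r, h = h, beta = beta), ...),
        error = function(e) stop(sprintf("phase map failed at kn=%g, kd=%g: %s",
                                         kn_values[i], kd_values[j],
                                         conditionMessage(e)), call. = FALSE)
      )
    }
  }
  structure(list(kn_values = kn_values, kd_values = kd_values,
                 metric = metric, values = vals),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Phase map of %s: %d kn x %d kd values in [%.3g, %.3g]\n",
              x$metric, length(x$kn_values), length(x$kd_values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname phase_map
#' @param x A `phase_map`.
#' @export
as.data.frame.phase_map <- function(x, ...) {
  tibble::tibble(
    kn = rep(x$kn_values, times = length(x$kd_values)),
    kd = rep(x$kd_values, each = length(x$kn_values)),
    value = as.vector(x$values)
  )
}
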