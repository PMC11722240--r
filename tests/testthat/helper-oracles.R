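# Independent numerical oracles, deliberately kept apart from the package's
# implementation paths (fixed-step RK4 vs deSolve/lsoda; explicit loops vs
# vectorised code).

# Fixed-step classical RK4 for the n-cell lateral-inhibition system with
# all-mutual coupling (neighbour input = mean of the other cells' Delta).
rk4_nd_oracle <- function(kn, kd, v = 1, r = 2, h = 2, n0, d0,
                          t_end = 10, dt = 1e-4, save_every = 100L) {
  nc <- length(n0)
  rhs <- function(nn, dd) {
    dbar <- (sum(dd) - dd) / (nc - 1)
    list(dn = dbar^r / (kn^r + dbar^r) - nn,
         dd = v * (1 / (1 + (nn / kd)^h) - dd))
  }
  steps <- round(t_end / dt)
  keep <- seq(0L, steps, by = save_every)
  out_n <- matrix(NA_real_, length(keep), nc)
  out_d <- matrix(NA_real_, length(keep), nc)
  nn <- n0; dd <- d0; ki <- 1L
  for (s in 0:steps) {
    if (ki <= length(keep) && s == keep[ki]) {
      out_n[ki, ] <- nn; out_d[ki, ] <- dd; ki <- ki + 1L
    }
    if (s == steps) break
    k1 <- rhs(nn, dd)
    k2 <- rhs(nn + dt / 2 * k1$dn, dd + dt / 2 * k1$dd)
    k3 <- rhs(nn + dt / 2 * k2$dn, dd + dt / 2 * k2$dd)
    k4 <- rhs(nn + dt * k3$dn, dd + dt * k3$dd)
    nn <- nn + dt / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn)
    dd <- dd + dt / 6 * (k1$dd + 2 * k2$dd + 2 * k3$dd + k4$dd)
  }
  list(times = keep * dt, notch = out_n, delta = out_d)
}

# memoised oracle runs for the two reference parameter points (used by
# several tests; each full-resolution run takes about a second)
.oracle_cache <- new.env(parent = emptyenv())
oracle_point <- function(kd, cells = 2L, dt = 1e-4) {
  key <- sprintf("kd%g_c%d_dt%g", kd, cells, dt)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  n0 <- if (cells == 2L) c(0.010, 0.011) else c(0.010, 0.010, 0.011)
  res <- rk4_nd_oracle(kn = 0.5, kd = kd, n0 = n0, d0 = rep(1, cells), dt = dt)
  .oracle_cache[[key]] <- res
  res
}

# plain-loop cumulative trapezoid, independent of the package's version
trapz_oracle <- function(t, y) {
  out <- numeric(length(t))
  for (i in 2:length(t)) {
    out[i] <- out[i - 1] + (t[i] - t[i - 1]) * (y[i] + y[i - 1]) / 2
  }
  out
}

# brute-force fine-grid search for the equal-posterior crossing of a
# two-component Gaussian mixture
boundary_grid_oracle <- function(w, mu, sd, step = 1e-5) {
  xs <- seq(mu[1], mu[2], by = step)
  diffs <- w[1] * dnorm(xs, mu[1], sd[1]) - w[2] * dnorm(xs, mu[2], sd[2])
  i <- which(diffs <= 0)[1]
  (xs[i - 1] + xs[i]) / 2
}

# brute-force two-sample KS distance over the pooled sample points
ks_d_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}

# build a gmm_fit object directly (bypassing EM) for boundary tests
make_gmm_fit <- function(w, mu, sd) {
  fit <- structure(
    list(weights = w, means = mu, sds = sd, boundary = NA_real_,
         loglik = NA_real_, n = 0L, seed = NA_integer_, n_restarts = 0L,
         log_scale = TRUE, iterations = 0L, degenerate = FALSE),
    class = "gmm_fit"
  )
  fit$boundary <- decision_boundary(fit)
  fit
}

# minimal trajectory object with prescribed Notch series (time x cells)
make_traj <- function(times, notch) {
  structure(
    list(times = times, notch = notch, delta = notch * 0,
         reporter = NULL, params = circuit_params(0.5, 0.25),
         n_cells = ncol(notch), topology = make_topology(max(2, ncol(notch)))),
    class = "nd_trajectory"
  )
}

# noiseless triangle track: rises `up` per frame for n_up frames from 0,
# then falls `down` per frame for n_down frames
triangle_track <- function(up = 0.02, n_up = 40, down = 0.03, n_down = 40) {
  peak <- up * n_up
  c(seq(0, peak, by = up), peak - down * seq_len(n_down))
}
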