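#' Specification of a synthetic bimodal intensity population
#'
#' Describes the generative model for fixed-tissue reporter intensities:
#' a two-component mixture on the log10 scale whose low and high modes
#' stand for the stem-like (NRE-low) and enteroblast-like (NRE-high)
#' progenitor states, with marker probabilities attached per component
#' (Delta marks stem cells, so P(Delta+ | low) is high in healthy tissue;
#' PH3 marks mitoses, which are almost exclusively NRE-low).
#'
#' @param n_cells Number of cells to draw.
#' @param means,sds Component means and SDs on the log10-intensity scale
#'   (component 1 = low mode).
#' @param weight_high Mixing weight of the high component, in \[0, 1\].
#' @param p_delta,p_ph3 Length-2 vectors `c(low, high)` of marker
#'   probabilities conditional on the component.
#' @param condition Condition label attached to every record.
#' @param n_guts Number of gut identifiers cells are spread over.
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @seealso [population_preset()] for study-like healthy/injured settings.
#' @export
population_spec <- function(n_cells, means = c(1.0, 2.5), sds = c(0.2, 0.2),
                            weight_high = 0.3,
                            p_delta = c(low = 0.45, high = 0.3),
                            p_ph3 = c(low = 0.05, high = 0.001),
                            condition = "synthetic", n_guts = 5L, seed = 1L) {
  stopifnot(n_cells >= 1, length(means) == 2L, length(sds) == 2L)
  if (any(sds <= 0)) stop("component SDs must be positive", call. = FALSE)
  probs <- c(weight_high, p_delta, p_ph3)
  if (any(probs < 0 | probs > 1))
    stop("weights and marker probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), means = means, sds = sds,
                 weight_high = weight_high, p_delta = unname(p_delta),
                 p_ph3 = unname(p_ph3), condition = condition,
                 n_guts = as.integer(n_guts), seed = as.integer(seed)),
            class = "population_spec")
}

#' Study-like population presets
#'
#' Returns a [population_spec()] parameterised to mimic the two tissue
#' states: healthy tissue has a mostly NRE-low progenitor pool whose
#' Delta+ cells are rarely NRE-high, while injured tissue has an expanded
#' NRE-high fraction and many Delta+ cells that are simultaneously
#' NRE-high (the hallmark of disrupted lateral-inhibition feedback).
#'
#' @param condition `"healthy"` or `"injured"`.
#' @param n_cells Number of cells (default 2000, the order of a typical
#'   per-condition pooled cell count).
#' @param seed Integer seed.
#' @return A `population_spec`.
#' @export
population_preset <- function(condition = c("healthy", "injured"),
                              n_cells = 2000L, seed = 1L) {
  condition <- match.arg(condition)
  if (condition == "healthy") {
    population_spec(n_cells, weight_high = 0.15,
                    p_delta = c(low = 0.45, high = 0.3),
                    p_ph3 = c(low = 0.05, high = 0.001),
                    condition = "healthy", seed = seed)
  } else {
    population_spec(n_cells, weight_high = 0.55,
                    p_delta = c(low = 0.4, high = 0.5),
                    p_ph3 = c(low = 0.05, high = 0.004),
                    condition = "injured", seed = seed)
  }
}

#' Draw a synthetic cell population
#'
#' Samples cell records from a [population_spec()]: each cell's component
#' is Bernoulli(`weight_high`), its log10 intensity is normal within the
#' component, and its marker flags are Bernoulli with the component's
#' marker probabilities. The generating component is retained in
#' `true_component`, so downstream classification can be scored against
#' ground truth. Deterministic given the spec's seed.
#'
#' @param spec A `population_spec`.
#' @return A tibble with columns `cell_id`, `gut_id`, `condition`,
#'   `intensity`, `esg_pos`, `delta_pos`, `ph3_pos`, `true_component`.
#' @export
gen_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_cells
  out <- with_preserved_seed(spec$seed, {
    comp <- stats::rbinom(n, 1L, spec$weight_high) + 1L  # 1 = low, 2 = high
    lx <- stats::rnorm(n, spec$means[comp], spec$sds[comp])
    delta <- stats::runif(n) < spec$p_delta[comp]
    ph3 <- stats::runif(n) < spec$p_ph3[comp]
    list(comp = comp, lx = lx, delta = delta, ph3 = ph3)
  })
  tibble::tibble(
    cell_id = sprintf("cell_%05d", seq_len(n)),
    gut_id = sprintf("gut_%02d", 1L + (seq_len(n) - 1L) %% spec$n_guts),
    condition = spec$condition,
    intensity = 10^out$lx,
    esg_pos = TRUE,
    delta_pos = out$delta,
    ph3_pos = out$ph3,
    true_component = c("low", "high")[out$comp]
  )
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Kinetic constants of the dual-fluorophore timer reporter
#'
#' Holds the maturation and degradation kinetics of the timer's two
#' fluorophores: a fast-folding, destabilized GFP (maturation ~0.1 h,
#' half-life ~2 h) that tracks promoter activity closely, and a
#' slow-folding, long-lived RFP (maturation ~1.5 h, half-life ~20 h) that
#' integrates signalling history. Rate constants use the half-time
#' convention k = ln(2)/t; treating the reported maturation times as
#' half-times is an approximation. Sampling matches the imaging protocol:
#' one frame every 7.5 minutes for 20.5 hours.
#'
#' @param gfp_maturation_h,gfp_halflife_h,rfp_maturation_h,rfp_halflife_h
#'   Fluorophore kinetics, in hours.
#' @param noise_sd Additive Gaussian measurement noise SD on the
#'   normalized intensity scale (default 0.02).
#' @param sampling_interval_min Frame interval in minutes (default 7.5).
#' @param duration_h Imaging duration in hours (default 20.5).
#' @return An object of class `timer_kinetics`.
#' @export
timer_kinetics <- function(gfp_maturation_h = 0.1, gfp_halflife_h = 2,
                           rfp_maturation_h = 1.5, rfp_halflife_h = 20,
                           noise_sd = 0.02, sampling_interval_min = 7.5,
                           duration_h = 20.5) {
  times <- c(gfp_maturation_h, gfp_halflife_h, rfp_maturation_h,
             rfp_halflife_h, sampling_interval_min, duration_h)
  if (any(times <= 0)) stop("all times must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(
    gfp_maturation_h = gfp_maturation_h, gfp_halflife_h = gfp_halflife_h,
    rfp_maturation_h = rfp_maturation_h, rfp_halflife_h = rfp_halflife_h,
    gfp_km = log(2) / gfp_maturation_h, gfp_kd = log(2) / gfp_halflife_h,
    rfp_km = log(2) / rfp_maturation_h, rfp_kd = log(2) / rfp_halflife_h,
    noise_sd = noise_sd, sampling_interval_min = sampling_interval_min,
    duration_h = duration_h
  ), class = "timer_kinetics")
}

#' Piecewise-linear promoter-activity profile
#'
#' Describes the underlying Notch-driven promoter activity of one cell as
#' a piecewise-linear function bounded in \[0, 1\] over the imaging
#' window. Patterns: `up_only` (off, then rises to 1 and stays),
#' `down_only` (on since before the window, falls from `onset_h`),
#' `up_down` (rise, plateau, fall) and `sustained` (constant 1).
#'
#' @param pattern One of `"up_only"`, `"down_only"`, `"up_down"`,
#'   `"sustained"`.
#' @param onset_h Time (h) at which the first transition starts.
#' @param rise_rate,fall_rate Activity change rates in fraction per hour
#'   (a rate of 0.25/h means a full 0-to-1 rise takes 4 h).
#' @param plateau_h Plateau duration between rise and fall (h), `up_down`
#'   only.
#' @param duration_h Window length (h, default 20.5).
#' @return An object of class `activity_profile` with breakpoints `t`,
#'   values `a`, and the generating fields.
#' @export
activity_profile <- function(pattern = c("up_down", "up_only", "down_only",
                                         "sustained"),
                             onset_h = 2, rise_rate = 0.25, fall_rate = 0.15,
                             plateau_h = 4, duration_h = 20.5) {
  pattern <- match.arg(pattern)
  stopifnot(onset_h >= 0, rise_rate > 0, fall_rate > 0, plateau_h >= 0)
  rise_d <- 1 / rise_rate
  fall_d <- 1 / fall_rate
  # breakpoints may extend past the window; evaluation extends the last
  # value constantly in either direction
  bp <- switch(pattern,
    sustained = list(t = c(0, duration_h), a = c(1, 1)),
    up_only = list(t = c(0, onset_h, onset_h + rise_d), a = c(0, 0, 1)),
    down_only = list(t = c(0, onset_h, onset_h + fall_d), a = c(1, 1, 0)),
    up_down = list(t = c(0, onset_h, onset_h + rise_d,
                         onset_h + rise_d + plateau_h,
                         onset_h + rise_d + plateau_h + fall_d),
                   a = c(0, 0, 1, 1, 0))
  )
  t <- bp$t; a <- bp$a
  dup <- duplicated(t)
  structure(list(t = t[!dup], a = a[!dup], pattern = pattern,
                 onset_h = onset_h, rise_rate = rise_rate,
                 fall_rate = fall_rate, plateau_h = plateau_h,
                 duration_h = duration_h),
            class = "activity_profile")
}

#' Evaluate an activity profile
#'
#' @param profile An `activity_profile` (or a plain function of time in
#'   hours).
#' @param t_h Times in hours.
#' @return Activity values in \[0, 1\].
#' @export
activity_at <- function(profile, t_h) {
  if (is.function(profile)) return(profile(t_h))
  stopifnot(inherits(profile, "activity_profile"))
  stats::approx(profile$t, profile$a, xout = t_h, rule = 2)$y
}

#' Use a simulated Notch trajectory as a promoter-activity profile
#'
#' Bridges the circuit model to trace generation: the activated-Notch
#' series of one simulated cell, rescaled from dimensionless model time to
#' hours, becomes the promoter activity driving the timer forward model.
#'
#' @param traj An `nd_trajectory`.
#' @param cell Cell index within the trajectory.
#' @param time_scale_h Hours of real time per unit of dimensionless model
#'   time.
#' @return A function of time (hours) clamped to \[0, 1\], with the
#'   rescaled grid attached as attribute `"breakpoints"`.
#' @export
activity_from_trajectory <- function(traj, cell = 2L, time_scale_h = 2) {
  stopifnot(inherits(traj, "nd_trajectory"), cell >= 1, cell <= traj$n_cells)
  t_h <- traj$times * time_scale_h
  a <- pmin(1, pmax(0, traj$notch[, cell]))
  f <- stats::approxfun(t_h, a, rule = 2)
  attr(f, "breakpoints") <- t_h
  f
}

# Exact update of one fluorophore's two-compartment system over a step of
# length dt during which the forcing is linear, A(s) = c0 + m s:
#   I' = A(s) - a I   (a = k_m + k_d),   M' = k_m I - d M   (d = k_d).
# The solution is I(s) = P + Q s + R exp(-a s) with P = c0/a - m/a^2,
# Q = m/a, R = I0 - P, and M integrates I against exp(-d (dt - s)).
# a > d always (a = k_m + d), so the resonant denominator never vanishes.
lin2_step <- function(i0, m0, c0, m, dt, km, kd) {
  a <- km + kd; d <- kd
  p <- c0 / a - m / a^2
  q <- m / a
  r <- i0 - p
  ea <- exp(-a * dt); ed <- exp(-d * dt)
  i1 <- p + q * dt + r * ea
  j <- p * (-expm1(-d * dt)) / d +
    q * (d * dt + expm1(-d * dt)) / d^2 +
    r * (ea - ed) / (d - a)
  m1 <- m0 * ed + km * j
  c(i1, m1)
}

#' Forward model of the dual-fluorophore timer
#'
#' Produces noiseless GFP and RFP traces from a promoter-activity profile
#' through a two-compartment linear kinetic model per fluorophore:
#' \deqn{I' = A(t) - (k_m + k_d) I, \qquad M' = k_m I - k_d M}
#' with maturation rate \eqn{k_m = \ln 2 / t_{mat}} and degradation rate
#' \eqn{k_d = \ln 2 / t_{1/2}}. The observable signal is the mature pool
#' `M`, sampled at the kinetics' frame interval. Because the system is
#' linear and the profile piecewise linear, it is integrated exactly
#' (closed-form update on every interval between sample points and profile
#' breakpoints); plain-function profiles are treated as piecewise linear
#' on a grid refined to `substep_h`.
#'
#' When the profile is active at time zero (e.g. `down_only`), the
#' fluorophore pools start at the steady state for `A(0)`, representing a
#' cell already expressing before imaging began; otherwise they start
#' empty. Pass `init` to override.
#'
#' @param profile An `activity_profile` or a function of time (hours).
#' @param kinetics A [timer_kinetics()].
#' @param init Optional initial state `c(I_gfp, M_gfp, I_rfp, M_rfp)`.
#' @param substep_h Grid refinement for plain-function profiles (hours,
#'   default 0.01); piecewise-linear profiles are integrated exactly.
#' @return A tibble with `frame` (0-based), `time_min`, `time_h`,
#'   `activity`, `gfp`, `rfp` (raw mature-pool levels).
#' @examples
#' kin <- timer_kinetics()
#' tf <- timer_forward(activity_profile("up_down", onset_h = 1,
#'                                      rise_rate = 0.5, plateau_h = 2,
#'                                      fall_rate = 0.5), kin)
#' # slow RFP peaks later than fast GFP:
#' tf$time_h[which.max(tf$rfp)] > tf$time_h[which.max(tf$gfp)]
#' @export
timer_forward <- function(profile, kinetics = timer_kinetics(), init = NULL,
                          substep_h = 0.01) {
  kin <- kinetics
  stopifnot(inherits(kin, "timer_kinetics"))
  dt_h <- kin$sampling_interval_min / 60
  samples <- seq(0, kin$duration_h, by = dt_h)
  bp <- if (is.function(profile)) attr(profile, "breakpoints") else profile$t
  grid <- c(samples, bp[bp > 0 & bp < kin$duration_h])
  if (is.function(profile)) {
    grid <- c(grid, seq(0, kin$duration_h, by = substep_h))
  }
  grid <- sort(unique(grid))
  a0 <- activity_at(profile, 0)
  if (is.null(init)) {
    init <- if (a0 > 0) {
      c(a0 / (kin$gfp_km + kin$gfp_kd),
        a0 * kin$gfp_km / ((kin$gfp_km + kin$gfp_kd) * kin$gfp_kd),
        a0 / (kin$rfp_km + kin$rfp_kd),
        a0 * kin$rfp_km / ((kin$rfp_km + kin$rfp_kd) * kin$rfp_kd))
    } else rep(0, 4)
  }
  y <- init
  state <- matrix(NA_real_, length(grid), 4L)
  state[1, ] <- y
  a_grid <- activity_at(profile, grid)
  for (i in seq_len(length(grid) - 1L)) {
    dt <- grid[i + 1L] - grid[i]
    slope <- (a_grid[i + 1L] - a_grid[i]) / dt
    g <- lin2_step(y[1], y[2], a_grid[i], slope, dt, kin$gfp_km, kin$gfp_kd)
    r <- lin2_step(y[3], y[4], a_grid[i], slope, dt, kin$rfp_km, kin$rfp_kd)
    y <- c(g, r)
    state[i + 1L, ] <- y
  }
  at_samples <- match(samples, grid)
  tibble::tibble(
    frame = seq_along(samples) - 1L,
    time_min = samples * 60,
    time_h = samples,
    activity = activity_at(profile, samples),
    gfp = state[at_samples, 2L],
    rfp = state[at_samples, 4L]
  )
}

#' Closed-form steady state of the timer forward model
#'
#' For constant promoter activity `a`, the mature fluorophore pool
#' converges to `a * k_m / ((k_m + k_d) * k_d)`; used as an analytic check
#' of [timer_forward()].
#'
#' @param a Constant activity level.
#' @param k_m,k_d Maturation and degradation rates (per hour).
#' @return Steady-state mature-pool level.
#' @export
timer_steady_state <- function(a, k_m, k_d) {
  a * k_m / ((k_m + k_d) * k_d)
}

# condition presets for movie generation: pattern frequencies from the
# tracked-cell counts (healthy 25% up_down, injured 57%), activity rates
# chosen so the measured per-frame dGFP slopes land near the reported
# medians (healthy ~0.02/frame rising, injured ~0.034/frame)
movie_presets <- list(
  healthy = list(
    pattern_probs = c(up_only = 0.16, down_only = 0.59, up_down = 0.25),
    rise_meanlog = log(0.16), rise_sdlog = 0.3,
    fall_meanlog = log(0.11), fall_sdlog = 0.3,
    plateau_range_h = c(2, 6)
  ),
  injured = list(
    pattern_probs = c(up_only = 0.05, down_only = 0.38, up_down = 0.57),
    rise_meanlog = log(0.28), rise_sdlog = 0.3,
    fall_meanlog = log(0.17), fall_sdlog = 0.3,
    plateau_range_h = c(1, 3)
  )
)

# which activity phases fall inside the observed window with at least
# `min_frames` sampled frames each; returns the realized pattern label
realized_pattern <- function(profile, window_start_h, window_end_h,
                             interval_min = 7.5, min_frames = 3L) {
  need_h <- (min_frames - 1L) * interval_min / 60
  overlap <- function(a, b) {
    max(0, min(b[2], window_end_h) - max(b[1], window_start_h)) >= need_h &&
      a > 0
  }
  p <- profile
  rise <- switch(p$pattern,
    up_only = , up_down = overlap(1, c(p$onset_h, p$onset_h + 1 / p$rise_rate)),
    FALSE)
  fall_start <- switch(p$pattern,
    down_only = p$onset_h,
    up_down = p$onset_h + 1 / p$rise_rate + p$plateau_h,
    NA_real_)
  fall <- if (is.na(fall_start)) FALSE else
    overlap(1, c(fall_start, fall_start + 1 / p$fall_rate))
  if (rise && fall) "up_down" else if (rise) "up_only"
  else if (fall) "down_only" else "indeterminate"
}

#' Generate a synthetic timer movie with known ground truth
#'
#' Draws per-cell activity profiles from a condition preset, runs each
#' through the timer forward model, scales cells by a lognormal
#' brightness factor, normalizes each channel to the movie-wide maximum,
#' adds Gaussian measurement noise, and optionally truncates each cell to
#' a random observation sub-window (cells enter and leave the imaged
#' field). The generating profile parameters and the phase pattern
#' realized within each cell's observed window are returned as ground
#' truth.
#'
#' The `healthy` preset has slow activity rates and long plateaus, so most
#' cells display a single signalling phase within the 20.5-h window and
#' about a quarter complete both up- and downregulation; the `injured`
#' preset has roughly 1.75-fold faster rates, so most cells complete both
#' phases - matching the pattern frequencies and rate medians observed in
#' the tracked-cell data.
#'
#' @param n_cells Total number of cells (ignored when `n_per_pattern`
#'   given).
#' @param preset `"healthy"` or `"injured"`.
#' @param kinetics A [timer_kinetics()].
#' @param seed Integer seed.
#' @param noise_sd Measurement noise SD on the normalized scale (defaults
#'   to the kinetics' value).
#' @param truncate Randomly trim up to 10 frames from each end of each
#'   cell's track (default `TRUE`).
#' @param n_per_pattern Optional named counts, e.g.
#'   `c(up_down = 50, down_only = 30)`, overriding the preset frequencies.
#' @param movie_id Movie identifier.
#' @return A list with `tracks` (long tibble: `movie_id`, `cell_id`,
#'   `condition`, `frame`, `time_min`, `gfp`, `rfp`) and `truth` (per
#'   cell: drawn pattern, realized pattern within the observed window,
#'   rates, onset, plateau, window).
#' @export
gen_movie <- function(n_cells = 100L, preset = c("healthy", "injured"),
                      kinetics = timer_kinetics(), seed = 1L,
                      noise_sd = kinetics$noise_sd, truncate = TRUE,
                      n_per_pattern = NULL, movie_id = NULL) {
  preset <- match.arg(preset)
  ps <- movie_presets[[preset]]
  kin <- kinetics
  if (is.null(movie_id)) movie_id <- paste0(preset, "_movie")
  dt_h <- kin$sampling_interval_min / 60
  n_frames <- length(seq(0, kin$duration_h, by = dt_h))

  patterns <- if (is.null(n_per_pattern)) NULL else
    rep(names(n_per_pattern), times = n_per_pattern)
  out <- with_preserved_seed(seed, {
    if (is.null(patterns)) {
      patterns <- sample(names(ps$pattern_probs), n_cells, replace = TRUE,
                         prob = ps$pattern_probs)
    }
    n_cells <- length(patterns)
    gfp_mat <- matrix(NA_real_, n_frames, n_cells)
    rfp_mat <- matrix(NA_real_, n_frames, n_cells)
    truth <- vector("list", n_cells)
    windows <- matrix(NA_integer_, n_cells, 2L)
    dur <- kin$duration_h
    for (i in seq_len(n_cells)) {
      pat <- patterns[i]
      rise <- stats::rlnorm(1, ps$rise_meanlog, ps$rise_sdlog)
      fall <- stats::rlnorm(1, ps$fall_meanlog, ps$fall_sdlog)
      plateau <- stats::runif(1, ps$plateau_range_h[1], ps$plateau_range_h[2])
      # [t_on, t_off] is the period the cell is visibly active (the timer
      # GFP persists ~2 h past promoter shut-off); observation windows are
      # anchored to it because segmentation follows cells with signal
      if (pat == "up_down") {
        onset <- stats::runif(1, 0.5, 2)
        # keep the rise and the start of the fall inside the window
        rise <- max(rise, 1 / (12 - onset))
        plateau <- min(plateau, 18 - (onset + 1 / rise))
        t_on <- onset
        t_off <- min(dur, onset + 1 / rise + plateau + 1 / fall + 2)
      } else if (pat == "up_only") {
        rise <- max(rise, 1 / 14)
        onset <- stats::runif(1, 2, dur - 1 / rise - 1.5)
        t_on <- onset; t_off <- dur
      } else if (pat == "down_only") {
        onset <- stats::runif(1, 1, 4)
        t_on <- 0; t_off <- min(dur, onset + 1 / fall + 2)
      } else {  # sustained
        onset <- 0
        t_on <- 0; t_off <- dur
      }
      prof <- activity_profile(pat, onset_h = onset, rise_rate = rise,
                               fall_rate = fall, plateau_h = plateau,
                               duration_h = dur)
      tf <- timer_forward(prof, kin)
      bright <- stats::rlnorm(1, 0, 0.2)
      gfp_mat[, i] <- tf$gfp * bright
      rfp_mat[, i] <- tf$rfp * bright
      w <- if (truncate) {
        ws <- max(0, t_on - stats::runif(1, 0.5, 2.5))
        we <- min(dur, t_off + stats::runif(1, 0, 1))
        lo <- max(1L, 1L + floor(ws / dt_h))
        hi <- min(n_frames, 1L + ceiling(we / dt_h))
        if (hi - lo + 1L < 20L) { lo <- max(1L, hi - 19L); hi <- min(n_frames, lo + 19L) }
        c(lo, hi)
      } else c(1L, n_frames)
      windows[i, ] <- w
      truth[[i]] <- tibble::tibble(
        movie_id = movie_id, cell_id = sprintf("cell_%03d", i),
        condition = preset, pattern_drawn = pat,
        pattern = realized_pattern(prof, (w[1] - 1L) * dt_h, (w[2] - 1L) * dt_h,
                                   kin$sampling_interval_min),
        rise_rate = rise, fall_rate = fall, onset_h = onset,
        plateau_h = plateau, first_frame = w[1] - 1L, last_frame = w[2] - 1L
      )
    }
    # movie-wide per-channel normalization, then additive measurement noise
    gfp_mat <- gfp_mat / max(gfp_mat)
    rfp_mat <- rfp_mat / max(rfp_mat)
    if (noise_sd > 0) {
      # negative measurements are physically impossible; clamp at zero
      gfp_mat <- pmax(gfp_mat + stats::rnorm(length(gfp_mat), 0, noise_sd), 0)
      rfp_mat <- pmax(rfp_mat + stats::rnorm(length(rfp_mat), 0, noise_sd), 0)
    }
    rows <- lapply(seq_len(n_cells), function(i) {
      fr <- windows[i, 1L]:windows[i, 2L]
      tibble::tibble(
        movie_id = movie_id, cell_id = sprintf("cell_%03d", i),
        condition = preset, frame = fr - 1L,
        time_min = (fr - 1L) * kin$sampling_interval_min,
        gfp = gfp_mat[fr, i], rfp = rfp_mat[fr, i]
      )
    })
    list(tracks = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
  out
}
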