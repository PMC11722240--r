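#' Per-movie 0-1 normalization of channel intensities
#'
#' For each channel within each movie, divides every mean-intensity value
#' by the movie-wide maximum of that channel, so the brightest measurement
#' in the movie maps to exactly 1. Movies are normalized independently of
#' one another; the operation is idempotent.
#'
#' @param tracks A long-format tibble with columns `movie_id`, `cell_id`,
#'   `frame` and the channel columns (default `gfp` and `rfp`).
#' @param channels Channel column names to normalize.
#' @return The input with added `<channel>_norm` columns.
#' @export
normalize_movie <- function(tracks, channels = c("gfp", "rfp")) {
  stopifnot(is.data.frame(tracks), "movie_id" %in% names(tracks))
  missing_ch <- setdiff(channels, names(tracks))
  if (length(missing_ch) > 0)
    stop("missing channel column(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  tracks <- tibble::as_tibble(tracks)
  for (ch in channels) {
    vals <- tracks[[ch]]
    if (any(!is.finite(vals))) stop(sprintf("non-finite values in `%s`", ch), call. = FALSE)
    if (any(vals < 0)) stop(sprintf("negative intensities in `%s`", ch), call. = FALSE)
    norm <- numeric(nrow(tracks))
    for (mv in unique(tracks$movie_id)) {
      sel <- tracks$movie_id == mv
      mx <- max(vals[sel])
      if (mx <= 0)
        stop(sprintf("channel `%s` is all zero in movie `%s`", ch, mv), call. = FALSE)
      norm[sel] <- vals[sel] / mx
    }
    tracks[[paste0(ch, "_norm")]] <- norm
  }
  tracks
}

#' Robust locally weighted smoothing of a single-cell trace
#'
#' Smooths a time series with a centred robust locally weighted linear
#' regression (lowess-style): each point is replaced by the value at that
#' point of a tricube-weighted linear fit over the `window` nearest
#' points, with `iterations` bisquare re-weighting passes that downweight
#' outliers (weights derived from 6 times the median absolute residual).
#' Constant and exactly linear series are reproduced unchanged; isolated
#' spikes are suppressed more strongly than by a plain moving average.
#'
#' @param values Numeric series (one value per frame).
#' @param window Odd span, in points (default 5).
#' @param iterations Number of robustness iterations (default 2).
#' @return Smoothed series, same length as the input.
#' @export
smooth_track <- function(values, window = 5L, iterations = 2L) {
  n <- length(values)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  if (n < window) stop(sprintf("need at least %d points", window), call. = FALSE)
  x <- seq_len(n)
  rw <- rep(1, n)  # robustness weights, one per data point
  fitted <- values
  for (it in seq_len(iterations + 1L)) {
    fitted <- local_linear_pass(x, values, window, rw)
    if (it > iterations) break
    r <- abs(values - fitted)
    s <- 6 * stats::median(r)
    # a mostly-flat series (median residual ~0) still needs a usable scale,
    # or an isolated spike would never be downweighted
    if (s <= 0) s <- 0.5 * max(r)
    if (s <= 0) break
    u <- r / s
    rw <- ifelse(u >= 1, 0, (1 - u^2)^2)
  }
  fitted
}

# one pass of tricube-weighted local linear regression at every point
local_linear_pass <- function(x, y, window, rw) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - window + 1L))
    idx <- lo:(lo + window - 1L)
    d <- abs(x[idx] - x[i])
    dmax <- max(d)
    wt <- if (dmax > 0) (1 - (d / dmax)^3)^3 else rep(1, length(idx))
    wt <- wt * rw[idx]
    if (sum(wt > 0) < 2L) wt <- wt + 1e-8  # guard: refit with near-uniform weights
    xi <- x[idx]; yi <- y[idx]
    sw <- sum(wt)
    xb <- sum(wt * xi) / sw
    yb <- sum(wt * yi) / sw
    sxx <- sum(wt * (xi - xb)^2)
    b <- if (sxx > 0) sum(wt * (xi - xb) * (yi - yb)) / sxx else 0
    out[i] <- yb + b * (x[i] - xb)
  }
  out
}

#' Quality control of a single-cell timer track
#'
#' Assigns each normalized track exactly one QC status, checking rules in
#' this order:
#' \enumerate{
#'   \item `excluded_short`: fewer than `min_points` frames;
#'   \item `notch_off`: visible RFP (mean >= `rfp_present`) while GFP
#'     stays below `off_gfp` for the whole track - the cell has recently
#'     switched Notch off and is excluded from slope analysis;
#'   \item `excluded_low_signal`: mean GFP over the first half of the
#'     track (first `ceiling(n/2)` points) below `first_half_floor`;
#'   \item `excluded_noisy`: residual noise score above `noise_cap`,
#'     where the score is `sd(raw - smoothed) / diff(range(smoothed))`, a
#'     scale-free stand-in for the judgement that raw measurements are too
#'     noisy for meaningful analysis;
#'   \item otherwise `included`.
#' }
#'
#' @param gfp_norm,rfp_norm Normalized channel series for one cell.
#' @param first_half_floor,min_points,off_gfp,rfp_present,noise_cap QC
#'   thresholds (defaults 0.1, 8, 0.1, 0.1, 0.15).
#' @param window Smoothing span used for the noise score.
#' @return A one-row tibble: `status` (factor), `n_points`,
#'   `first_half_mean`, `noise_score`.
#' @export
qc_track <- function(gfp_norm, rfp_norm = NULL, first_half_floor = 0.1,
                     min_points = 8L, off_gfp = 0.1, rfp_present = 0.1,
                     noise_cap = 0.15, window = 5L) {
  statuses <- c("included", "excluded_short", "notch_off",
                "excluded_low_signal", "excluded_noisy")
  n <- length(gfp_norm)
  first_half_mean <- mean(gfp_norm[seq_len(ceiling(n / 2))])
  res <- function(status, noise = NA_real_) {
    tibble::tibble(status = factor(status, levels = statuses),
                   n_points = n, first_half_mean = first_half_mean,
                   noise_score = noise)
  }
  if (n < min_points) return(res("excluded_short"))
  if (!is.null(rfp_norm) && max(gfp_norm) < off_gfp &&
      mean(rfp_norm) >= rfp_present) {
    return(res("notch_off"))
  }
  if (first_half_mean < first_half_floor) return(res("excluded_low_signal"))
  sm <- smooth_track(gfp_norm, window = window)
  rng <- diff(range(sm))
  resid_sd <- stats::sd(gfp_norm - sm)
  noise <- if (rng > 0) resid_sd / rng else if (resid_sd > 0) Inf else 0
  if (noise > noise_cap) return(res("excluded_noisy", noise))
  res("included", noise)
}

#' Split a smoothed track at its maximum and fit segment slopes
#'
#' Splits a smoothed trace into a rising and a falling part at the maximum
#' of the smoothed data (earliest index on ties; the maximum point belongs
#' to both segments) and fits an ordinary least-squares line `y = m x + b`
#' to each segment, with `x` the frame index starting at 0 within the
#' track. A maximum at the first or last frame yields a single-segment
#' (falling or rising) result; segments with fewer than `min_seg` points
#' are not fitted.
#'
#' @param smoothed Smoothed series for one included track.
#' @param min_seg Minimum points per fitted segment (default 3).
#' @return A tibble with one row per fitted segment: `segment`
#'   (`"rising"`/`"falling"`), `m`, `b`, `n_points`, `peak_index`. Zero
#'   rows (with attribute `unfittable = TRUE`) if no segment is fittable.
#' @examples
#' tri <- c(seq(0, 0.8, by = 0.02), seq(0.77, 0, by = -0.03))
#' split_and_fit(tri)
#' @export
split_and_fit <- function(smoothed, min_seg = 3L) {
  n <- length(smoothed)
  x <- seq_len(n) - 1L
  k <- which.max(smoothed)
  rows <- list()
  if (k >= 2L && k >= min_seg) {
    idx <- 1:k
    f <- stats::lm.fit(cbind(1, x[idx]), smoothed[idx])
    rows$rising <- tibble::tibble(segment = "rising",
                                  m = unname(f$coefficients[2]),
                                  b = unname(f$coefficients[1]), n_points = k,
                                  peak_index = k - 1L)
  }
  if (k <= n - 1L && (n - k + 1L) >= min_seg) {
    idx <- k:n
    f <- stats::lm.fit(cbind(1, x[idx]), smoothed[idx])
    rows$falling <- tibble::tibble(segment = "falling",
                                   m = unname(f$coefficients[2]),
                                   b = unname(f$coefficients[1]),
                                   n_points = n - k + 1L,
                                   peak_index = k - 1L)
  }
  out <- if (length(rows) > 0) do.call(rbind, unname(rows)) else
    tibble::tibble(segment = character(), m = numeric(), b = numeric(),
                   n_points = integer(), peak_index = integer())
  if (nrow(out) == 0L) attr(out, "unfittable") <- TRUE
  out
}

#' Classify the signalling phase pattern of a track
#'
#' A track is `up_down` when it carries both a qualifying rising segment
#' and a qualifying falling segment; otherwise it is `up_only` or
#' `down_only` according to the single qualifying segment, or
#' `indeterminate` if none qualifies. A segment qualifies when its slope
#' clears the directional floor (`m > rise_floor`, `m < -fall_floor`) and
#' its fitted net change over the segment (`|m| * (n_points - 1)`)
#' exceeds `min_change`. The slope floors reject flat segments; the
#' net-change requirement rejects the short spurious counter-segment that
#' measurement noise creates next to the maximum of a monotone trace,
#' while keeping slow-but-deep real phases (e.g. a long shallow decay).
#'
#' @param slopes Output of [split_and_fit()] for one track.
#' @param rise_floor,fall_floor Minimum signed slope for a segment to
#'   count as a real phase (normalized intensity per frame, default
#'   0.001).
#' @param min_change Minimum fitted net intensity change over a segment
#'   (normalized units, default 0.08, i.e. several noise SDs).
#' @return One of `"up_down"`, `"up_only"`, `"down_only"`,
#'   `"indeterminate"`.
#' @export
classify_pattern <- function(slopes, rise_floor = 0.001, fall_floor = 0.001,
                             min_change = 0.08) {
  q <- qualify_segments(slopes, rise_floor, fall_floor, min_change)
  has_rise <- any(q & slopes$segment == "rising")
  has_fall <- any(q & slopes$segment == "falling")
  if (has_rise && has_fall) return("up_down")
  if (has_rise) return("up_only")
  if (has_fall) return("down_only")
  "indeterminate"
}

#' Segment qualification used by pattern and rate analyses
#'
#' @param slopes Output of [split_and_fit()].
#' @param rise_floor,fall_floor,min_change See [classify_pattern()].
#' @return Logical vector marking segments that represent a real
#'   signalling phase.
#' @export
qualify_segments <- function(slopes, rise_floor = 0.001, fall_floor = 0.001,
                             min_change = 0.08) {
  change <- abs(slopes$m) * (slopes$n_points - 1)
  (slopes$segment == "rising" & slopes$m > rise_floor & change > min_change) |
    (slopes$segment == "falling" & slopes$m < -fall_floor & change > min_change)
}

#' Run the full track pipeline over a long-format table
#'
#' Normalizes each movie, then per cell: smooths the GFP channel, applies
#' QC, splits included tracks at the smoothed maximum, fits segment
#' slopes and classifies the phase pattern.
#'
#' @param tracks Long tibble with columns `movie_id`, `cell_id`,
#'   `condition`, `frame`, `gfp`, `rfp` (e.g. from [read_track_table()] or
#'   [gen_movie()]).
#' @param window Smoothing span.
#' @param min_seg Minimum points per fitted segment.
#' @param rise_floor,fall_floor,min_change Pattern qualification
#'   thresholds, see [classify_pattern()].
#' @param ... QC thresholds passed to [qc_track()].
#' @return A list of tibbles: `qc` (one row per track), `slopes` (one row
#'   per fitted segment of included tracks) and `patterns` (one row per
#'   included track).
#' @export
analyze_tracks <- function(tracks, window = 5L, min_seg = 3L,
                           rise_floor = 0.001, fall_floor = 0.001,
                           min_change = 0.08, ...) {
  stopifnot(all(c("movie_id", "cell_id", "frame", "gfp", "rfp") %in% names(tracks)))
  if (!"condition" %in% names(tracks)) tracks$condition <- "unspecified"
  tracks <- normalize_movie(tracks)
  key <- interaction(tracks$movie_id, tracks$cell_id, drop = TRUE)
  qc_rows <- list(); slope_rows <- list(); pattern_rows <- list()
  for (k in levels(key)) {
    tr <- tracks[key == k, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    meta <- tibble::tibble(movie_id = tr$movie_id[1], cell_id = tr$cell_id[1],
                           condition = tr$condition[1])
    qc <- qc_track(tr$gfp_norm, tr$rfp_norm, window = window, ...)
    qc_rows[[k]] <- cbind(meta, qc)
    if (qc$status != "included") next
    sm <- smooth_track(tr$gfp_norm, window = window)
    sl <- split_and_fit(sm, min_seg = min_seg)
    if (nrow(sl) > 0) {
      sl$qualifies <- qualify_segments(sl, rise_floor, fall_floor, min_change)
      slope_rows[[k]] <- cbind(meta, sl)
    }
    pattern_rows[[k]] <- cbind(
      meta,
      tibble::tibble(pattern = classify_pattern(sl, rise_floor, fall_floor,
                                                min_change))
    )
  }
  bind0 <- function(rows, proto) {
    if (length(rows) > 0) tibble::as_tibble(do.call(rbind, unname(rows))) else proto
  }
  list(
    qc = bind0(qc_rows, tibble::tibble()),
    slopes = bind0(slope_rows, tibble::tibble(
      movie_id = character(), cell_id = character(), condition = character(),
      segment = character(), m = numeric(), b = numeric(),
      n_points = integer(), peak_index = integer(), qualifies = logical())),
    patterns = bind0(pattern_rows, tibble::tibble(
      movie_id = character(), cell_id = character(), condition = character(),
      pattern = character()))
  )
}

#' Summarise signalling rates per condition and direction
#'
#' For every (condition, segment direction) group, reports the number of
#' segments, the median slope, and the fraction of cells changing rapidly
#' (rising slope above `rapid_threshold`, falling slope below its
#' negative; no separate deactivation threshold is defined, so it is
#' taken symmetric to the activation one). When exactly two conditions are present, the
#' rising and falling slope distributions are compared between them with
#' an unpaired two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' Only segments representing a real signalling phase enter the summary:
#' if the slope table carries a `qualifies` column (as produced by
#' [analyze_tracks()]), non-qualifying segments - the near-flat residue a
#' split leaves on a one-phase track - are dropped first, mirroring how
#' measured rates are reported only for cells that exhibit the
#' corresponding phase.
#'
#' @param slopes Slope tibble from [analyze_tracks()] (columns
#'   `condition`, `segment`, `m`, optionally `qualifies`).
#' @param rapid_threshold Rapid-change threshold in normalized intensity
#'   per frame (default 0.025).
#' @return A list with `summary` (per-group tibble: `condition`,
#'   `segment`, `n`, `median_slope`, `rapid_fraction`) and `tests`
#'   (per-direction Mann-Whitney p-values, or an empty tibble).
#' @export
rate_summary <- function(slopes, rapid_threshold = 0.025) {
  stopifnot(all(c("condition", "segment", "m") %in% names(slopes)))
  if ("qualifies" %in% names(slopes)) slopes <- slopes[slopes$qualifies, ]
  groups <- unique(slopes[, c("condition", "segment")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- slopes$condition == groups$condition[i] &
      slopes$segment == groups$segment[i]
    m <- slopes$m[sel]
    rapid <- if (groups$segment[i] == "rising") m > rapid_threshold
             else m < -rapid_threshold
    tibble::tibble(condition = groups$condition[i], segment = groups$segment[i],
                   n = sum(sel),
                   median_slope = if (sum(sel) > 0) stats::median(m) else NA_real_,
                   rapid_fraction = if (sum(sel) > 0) mean(rapid) else NA_real_)
  })
  summary <- do.call(rbind, rows)
  conds <- unique(slopes$condition)
  tests <- tibble::tibble(segment = character(), p_value = numeric())
  if (length(conds) == 2L) {
    for (seg in unique(slopes$segment)) {
      a <- slopes$m[slopes$condition == conds[1] & slopes$segment == seg]
      b <- slopes$m[slopes$condition == conds[2] & slopes$segment == seg]
      if (length(a) > 0 && length(b) > 0) {
        p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
        tests <- rbind(tests, tibble::tibble(segment = seg, p_value = p))
      }
    }
  }
  list(summary = tibble::as_tibble(summary), tests = tests)
}

#' Proportion of cells completing the full signalling program
#'
#' Tabulates phase patterns per condition and reports the proportion of
#' included cells that show both up- and downregulation (`up_down`)
#' within the imaging window - the readout by which injured tissue shows
#' an increased fraction of cells completing the whole Notch program in
#' under a day.
#'
#' @param patterns Pattern tibble from [analyze_tracks()] (columns
#'   `condition`, `pattern`).
#' @return A tibble per condition: `n`, `n_up_down`, `prop_up_down`,
#'   `percent_up_down`.
#' @export
pattern_summary <- function(patterns) {
  stopifnot(all(c("condition", "pattern") %in% names(patterns)))
  conds <- unique(patterns$condition)
  rows <- lapply(conds, function(cd) {
    pat <- patterns$pattern[patterns$condition == cd]
    n <- length(pat)
    k <- sum(pat == "up_down")
    tibble::tibble(condition = cd, n = n, n_up_down = k,
                   prop_up_down = if (n > 0) k / n else NA_real_,
                   percent_up_down = if (n > 0) 100 * k / n else NA_real_)
  })
  do.call(rbind, rows)
}
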