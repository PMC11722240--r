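make_tracks <- function(gfp_by_cell, movie_id = "m1", condition = "healthy",
                        rfp = 0.5) {
  rows <- lapply(names(gfp_by_cell), function(cid) {
    g <- gfp_by_cell[[cid]]
    tibble::tibble(movie_id = movie_id, cell_id = cid, condition = condition,
                   frame = seq_along(g) - 1L, time_min = (seq_along(g) - 1L) * 7.5,
                   gfp = g, rfp = rfp)
  })
  do.call(rbind, rows)
}

test_that("per-movie normalization scales each channel to a unit maximum", {
  tr <- make_tracks(list(a = c(50, 100, 200), b = c(10, 20, 30)))
  out <- normalize_movie(tr)
  expect_equal(out$gfp_norm[1], 0.25)
  expect_equal(max(out$gfp_norm), 1)

  # two movies are normalized independently
  tr2 <- rbind(tr, make_tracks(list(c = c(5, 10)), movie_id = "m2"))
  out2 <- normalize_movie(tr2)
  expect_equal(max(out2$gfp_norm[out2$movie_id == "m1"]), 1)
  expect_equal(max(out2$gfp_norm[out2$movie_id == "m2"]), 1)

  # idempotence: renormalizing normalized values changes nothing
  renorm <- normalize_movie(
    tibble::tibble(out[, c("movie_id", "cell_id", "frame")],
                   gfp = out$gfp_norm, rfp = out$rfp_norm))
  expect_equal(renorm$gfp_norm, out$gfp_norm)

  expect_error(normalize_movie(make_tracks(list(a = c(-1, 2)))), "negative")
  expect_error(normalize_movie(make_tracks(list(a = c(0, 0)), rfp = 0)), "zero")
})

test_that("robust smoothing reproduces constants and lines exactly", {
  expect_equal(smooth_track(rep(0.4, 20)), rep(0.4, 20), tolerance = 1e-12)
  lin <- 0.1 + 0.03 * (0:30)
  expect_equal(smooth_track(lin), lin, tolerance = 1e-9)
  expect_error(smooth_track(1:10, window = 4), "odd")
  expect_error(smooth_track(1:3, window = 5), "at least")
})

test_that("robust smoothing suppresses an isolated spike below the moving average", {
  y <- rep(0, 21); y[11] <- 1
  sm <- smooth_track(y, window = 5)
  ma <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))  # oracle
  expect_lt(max(sm), max(ma, na.rm = TRUE))
})

test_that("QC assigns statuses by the documented rule order", {
  # too few points
  expect_equal(as.character(qc_track(rep(0.5, 6))$status), "excluded_short")
  # recently Notch-OFF: visible RFP, GFP below 0.1 throughout
  qc_off <- qc_track(rep(0.05, 40), rep(0.3, 40))
  expect_equal(as.character(qc_off$status), "notch_off")
  # weak first half without RFP context is a low-signal exclusion
  low <- c(rep(0.04, 20), rep(0.6, 20))
  expect_equal(as.character(qc_track(low, rep(0.05, 40))$status),
               "excluded_low_signal")
  expect_lt(qc_track(low)$first_half_mean, 0.1)
  # clean ramp passes
  ramp <- seq(0.2, 0.9, length.out = 40)
  qc_ok <- qc_track(ramp, rep(0.5, 40))
  expect_equal(as.character(qc_ok$status), "included")
  # heavy raw noise on a shallow trace trips the noise score
  set.seed(4)
  noisy <- pmax(0, 0.4 + rnorm(40, 0, 0.2))
  expect_equal(as.character(qc_track(noisy, rep(0.5, 40))$status),
               "excluded_noisy")
})

test_that("split-at-maximum fits recover constructed slopes exactly", {
  # monotone ramp: maximum at the last index, single rising segment
  ramp <- 0.03 * (0:40)
  sl <- split_and_fit(ramp)
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$segment, "rising")
  expect_equal(sl$m, 0.03, tolerance = 1e-10)

  # triangle: both segments, slopes exact, shared maximum point
  tri <- triangle_track(up = 0.02, n_up = 40, down = 0.03, n_down = 40)
  sl2 <- split_and_fit(tri)
  expect_equal(sort(sl2$segment), c("falling", "rising"))
  expect_equal(sl2$m[sl2$segment == "rising"], 0.02, tolerance = 1e-10)
  expect_equal(sl2$m[sl2$segment == "falling"], -0.03, tolerance = 1e-10)
  expect_equal(sum(sl2$n_points), length(tri) + 1L)

  # monotone falling: single falling segment
  sl3 <- split_and_fit(rev(ramp))
  expect_equal(sl3$segment, "falling")
  expect_equal(sl3$m, -0.03, tolerance = 1e-10)

  # argmax ties resolve to the earliest index
  flat_top <- c(0, 1, 1, 1, 0.5, 0.2)
  expect_equal(unique(split_and_fit(flat_top)$peak_index), 1L)

  # too short on both sides -> unfittable
  un <- split_and_fit(c(0, 1, 0))
  expect_equal(nrow(un), 0L)
  expect_true(isTRUE(attr(un, "unfittable")))
})

test_that("phase patterns follow the fitted segments and slope floors", {
  expect_equal(classify_pattern(split_and_fit(0.03 * (0:40))), "up_only")
  expect_equal(classify_pattern(split_and_fit(triangle_track())), "up_down")
  expect_equal(classify_pattern(split_and_fit(rev(0.03 * (0:40)))), "down_only")
  # shallow segments with negligible net change are not real phases
  tiny <- split_and_fit(c(seq(0, 0.02, length.out = 10),
                          seq(0.02, 0, length.out = 10)))
  expect_equal(classify_pattern(tiny), "indeterminate")
})

test_that("slopes are recovered within 15% under measurement noise", {
  true_m <- 0.02
  err <- vapply(1:100, function(seed) {
    set.seed(seed)
    y <- pmin(1, pmax(0, 0.1 + true_m * (0:59) + rnorm(60, 0, 0.02)))
    sl <- split_and_fit(smooth_track(y))
    m <- sl$m[sl$segment == "rising"]
    abs(m - true_m) / true_m
  }, numeric(1))
  expect_lt(max(err), 0.15)
  # and the estimates are unbiased to within 5% of the true slope
  expect_lt(abs(mean(err * sign(err))), 0.05)
})

test_that("the end-to-end track pipeline handles QC, fits and patterns together", {
  tri <- triangle_track(up = 0.02, n_up = 40, down = 0.03, n_down = 25)
  tracks <- make_tracks(list(
    tri_cell = tri * 100,                     # raw units; max defines the scale
    ramp_cell = seq(20, 84, length.out = 50),
    short_cell = rep(50, 5),
    dim_cell = c(rep(2, 20), rep(60, 20))
  ))
  res <- analyze_tracks(tracks)
  status <- setNames(as.character(res$qc$status), res$qc$cell_id)
  expect_equal(status[["short_cell"]], "excluded_short")
  expect_equal(status[["dim_cell"]], "excluded_low_signal")
  expect_equal(status[["tri_cell"]], "included")
  expect_equal(status[["ramp_cell"]], "included")
  pat <- setNames(res$patterns$pattern, res$patterns$cell_id)
  expect_equal(pat[["tri_cell"]], "up_down")
  expect_equal(pat[["ramp_cell"]], "up_only")
  # QC judges each track alone: dropping one cell leaves the others unchanged
  res2 <- analyze_tracks(tracks[tracks$cell_id != "short_cell", ])
  expect_equal(res2$qc$status[res2$qc$cell_id == "tri_cell"],
               res$qc$status[res$qc$cell_id == "tri_cell"])
})

test_that("rate summaries report medians, rapid fractions and group tests", {
  slopes <- tibble::tibble(
    condition = rep(c("healthy", "injured"), each = 3),
    segment = "rising",
    m = c(0.01, 0.02, 0.03, 0.02, 0.03, 0.04)
  )
  rs <- rate_summary(slopes, rapid_threshold = 0.025)
  h <- rs$summary[rs$summary$condition == "healthy", ]
  expect_equal(h$median_slope, 0.02)
  expect_equal(h$rapid_fraction, 1 / 3)
  expect_equal(rs$summary$rapid_fraction[rs$summary$condition == "injured"], 2 / 3)
  expect_equal(nrow(rs$tests), 1L)

  all_slow <- rate_summary(tibble::tibble(condition = "c", segment = "rising",
                                          m = c(0.01, 0.02)))
  expect_equal(all_slow$summary$rapid_fraction, 0)

  # falling slopes use the sign-appropriate threshold
  fall <- rate_summary(tibble::tibble(condition = "c", segment = "falling",
                                      m = c(-0.01, -0.03)))
  expect_equal(fall$summary$rapid_fraction, 0.5)
})

test_that("pattern summaries reproduce count-based proportions", {
  patterns <- tibble::tibble(
    condition = rep(c("healthy", "injured"), times = c(32, 93)),
    pattern = c(rep("up_down", 8), rep("up_only", 24),
                rep("up_down", 53), rep("down_only", 40))
  )
  ps <- pattern_summary(patterns)
  expect_equal(ps$percent_up_down[ps$condition == "healthy"], 25)
  expect_equal(round(ps$percent_up_down[ps$condition == "injured"]), 57)
  expect_equal(ps$n_up_down, c(8L, 53L))
})
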