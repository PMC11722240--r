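#' Fit a two-component Gaussian mixture to reporter intensities
#'
#' Notch-reporter intensity distributions of intestinal progenitor cells
#' are bimodal, with a low-Notch (stem-like) and a high-Notch
#' (enteroblast-like) mode. This function fits a two-component univariate
#' Gaussian mixture to `log10(intensity)` by expectation-maximisation,
#' taking the best of `n_restarts` k-means-seeded starts by log-likelihood.
#' Components are ordered so that component 1 is the lower-mean (NRE-low)
#' mode, and the equal-posterior decision boundary between the modes is
#' located by [decision_boundary()].
#'
#' The fit is deterministic given `seed`: the RNG state is saved and
#' restored, so fitting does not perturb the caller's random stream.
#'
#' @param intensities Positive intensity values (arbitrary units).
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of EM restarts (default 20).
#' @param min_n Minimum number of cells required (default 20).
#' @param var_floor Lower bound on component variance, in (log10 units)^2,
#'   preventing component collapse (default 1e-4).
#' @param log_scale Fit on `log10(intensity)` (default) or, if `FALSE`, on
#'   the raw linear scale.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `gmm_fit` with elements `weights`, `means`,
#'   `sds` (component 1 = lower mean), `boundary`, `loglik`, `n`, `seed`,
#'   `n_restarts`, `log_scale` and a `degenerate` flag.
#' @examples
#' set.seed(1)
#' x <- 10^c(rnorm(300, 1.0, 0.2), rnorm(150, 2.5, 0.2))
#' fit_bimodal_gmm(x, seed = 1)
#' @export
fit_bimodal_gmm <- function(intensities, seed = 1L, n_restarts = 20L,
                            min_n = 20L, var_floor = 1e-4, log_scale = TRUE,
                            max_iter = 500L, tol = 1e-10) {
  if (length(intensities) < min_n)
    stop(sprintf("need at least %d values to fit a mixture (got %d)",
                 min_n, length(intensities)), call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and > 0", call. = FALSE)
  x <- if (log_scale) log10(intensities) else intensities

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    km <- tryCatch(stats::kmeans(x, centers = 2L, iter.max = 50L),
                   error = function(e) NULL)
    init <- if (is.null(km)) {
      mu <- sample(x, 2L)
      list(w = c(0.5, 0.5), mu = mu, sd = rep(stats::sd(x), 2L))
    } else {
      list(w = km$size / length(x), mu = as.vector(km$centers),
           sd = pmax(sqrt(var_floor),
                     vapply(1:2, function(k) {
                       xs <- x[km$cluster == k]
                       if (length(xs) > 1) stats::sd(xs) else stats::sd(x) / 2
                     }, numeric(1))))
    }
    em <- em_gmm2(x, init$w, init$mu, init$sd, var_floor, max_iter, tol)
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }

  ord <- order(best$mu)
  weights <- best$w[ord]; means <- best$mu[ord]; sds <- best$sd[ord]
  degenerate <- any(sds^2 <= var_floor * (1 + 1e-12)) ||
    any(weights < 1e-3) || !(means[1] < means[2])
  if (degenerate)
    warning("degenerate mixture fit (component collapse or vanishing weight); ",
            "boundary may be unreliable", call. = FALSE)

  fit <- structure(
    list(weights = weights, means = means, sds = sds, boundary = NA_real_,
         loglik = best$loglik, n = length(x), seed = seed,
         n_restarts = n_restarts, log_scale = log_scale,
         iterations = best$iter, degenerate = degenerate),
    class = "gmm_fit"
  )
  fit$boundary <- tryCatch(decision_boundary(fit), error = function(e) NA_real_)
  fit
}

# 2-component univariate EM on x from a given start
em_gmm2 <- function(x, w, mu, sd, var_floor, max_iter, tol) {
  n <- length(x)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    v1 <- sum(g1 * (x - mu[1])^2) / n1
    v2 <- sum((1 - g1) * (x - mu[2])^2) / n2
    sd <- sqrt(pmax(c(v1, v2), var_floor))
    w <- c(n1, n2) / n
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd, loglik = ll, iter = iter)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Two-component Gaussian mixture (n = %d, %s scale)\n",
              x$n, if (x$log_scale) "log10" else "linear"))
  cat(sprintf("  NRE-low : weight %.3f, mean %.4f, sd %.4f\n",
              x$weights[1], x$means[1], x$sds[1]))
  cat(sprintf("  NRE-hi  : weight %.3f, mean %.4f, sd %.4f\n",
              x$weights[2], x$means[2], x$sds[2]))
  cat(sprintf("  decision boundary: %.5f   log-likelihood: %.2f\n",
              x$boundary, x$loglik))
  if (x$degenerate) cat("  (flagged degenerate)\n")
  invisible(x)
}

#' Equal-posterior decision boundary of a two-component mixture
#'
#' Finds the intensity (on the fitting scale, log10 by default) at which
#' the posterior probabilities of the two components are equal, i.e. the
#' root of \eqn{w_1 \phi(x; \mu_1, \sigma_1) = w_2 \phi(x; \mu_2,
#' \sigma_2)} between the two component means, by bisection to 1e-8.
#' Cells above this threshold are classified as NRE-high.
#'
#' @param fit A `gmm_fit`.
#' @param tol Bisection tolerance (default 1e-8).
#' @return The boundary on the fitting scale.
#' @export
decision_boundary <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "gmm_fit"))
  w <- fit$weights; mu <- fit$means; s <- fit$sds
  f <- function(x) w[1] * stats::dnorm(x, mu[1], s[1]) -
    w[2] * stats::dnorm(x, mu[2], s[2])
  lo <- mu[1]; hi <- mu[2]
  flo <- f(lo); fhi <- f(hi)
  if (!(flo > 0 && fhi < 0))
    stop("no equal-posterior boundary between the component means ",
         "(components overlap too strongly)", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify cells into NRE-low / NRE-high states
#'
#' Applies a fitted mixture to a table of cell records: each cell receives
#' the posterior probability of each component and a hard label, NRE-high
#' if and only if its `log10(intensity)` exceeds the decision boundary
#' strictly (a cell exactly at the boundary is NRE-low). Any fit may be
#' applied to any record set, which supports classifying marker subsets
#' (e.g. mitotic PH3+ cells) or perturbation genotypes against their
#' control condition's fit.
#'
#' @param records A data frame with at least an `intensity` column
#'   (e.g. from [read_cell_table()] or [gen_population()]).
#' @param fit A `gmm_fit`.
#' @return A tibble of the accepted records with added columns
#'   `post_low`, `post_hi` and `label` (factor, `NRE_low`/`NRE_hi`),
#'   carrying the fit in attribute `"gmm_fit"`. Records with non-positive
#'   intensity are dropped with a warning and reported in attribute
#'   `"rejected"`.
#' @export
classify_cells <- function(records, fit) {
  stopifnot(inherits(fit, "gmm_fit"), is.data.frame(records))
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  if (!"intensity" %in% names(records))
    stop("`records` must have an `intensity` column", call. = FALSE)
  bad <- !is.finite(records$intensity) | records$intensity <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with non-positive intensity", sum(bad)),
            call. = FALSE)
  }
  rejected <- which(bad)
  records <- tibble::as_tibble(records[!bad, , drop = FALSE])
  x <- if (fit$log_scale) log10(records$intensity) else records$intensity
  d1 <- fit$weights[1] * stats::dnorm(x, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * stats::dnorm(x, fit$means[2], fit$sds[2])
  tot <- d1 + d2
  tot[tot == 0] <- .Machine$double.xmin
  records$post_low <- d1 / tot
  records$post_hi <- d2 / tot
  if (is.na(fit$boundary))
    stop("fit has no decision boundary; cannot assign hard labels", call. = FALSE)
  records$label <- factor(ifelse(x > fit$boundary, "NRE_hi", "NRE_low"),
                          levels = c("NRE_low", "NRE_hi"))
  attr(records, "gmm_fit") <- fit
  attr(records, "rejected") <- rejected
  records
}

#' Marker-by-state cross-tabulation
#'
#' Cross-tabulates a classified population against a boolean marker column
#' (e.g. `delta_pos` or `ph3_pos`), reporting both directions of
#' conditioning: the fraction of marker-positive cells that are NRE-high,
#' and the fraction of NRE-high cells that are marker-positive. Integer
#' counts are retained so proportions can be reproduced exactly.
#'
#' @param classified Output of [classify_cells()].
#' @param marker Name of a logical column in `classified`.
#' @return A one-row tibble with counts (`n_total`, `n_marker`,
#'   `n_marker_hi`, `n_hi`, `n_hi_marker`) and proportions
#'   (`prop_hi_given_marker`, `prop_low_given_marker`,
#'   `prop_marker_given_hi`); proportions with a zero denominator are `NA`.
#' @examples
#' counts <- count_proportion(8, 32)  # 25% of tracked healthy cells
#' @export
subpopulation_proportions <- function(classified, marker) {
  stopifnot(is.data.frame(classified), "label" %in% names(classified))
  if (!marker %in% names(classified))
    stop(sprintf("marker column `%s` not found", marker), call. = FALSE)
  mk <- as.logical(classified[[marker]])
  hi <- classified$label == "NRE_hi"
  n_marker <- sum(mk)
  n_hi <- sum(hi)
  tibble::tibble(
    marker = marker,
    n_total = length(mk),
    n_marker = n_marker,
    n_marker_hi = sum(mk & hi),
    n_hi = n_hi,
    n_hi_marker = sum(hi & mk),
    prop_hi_given_marker = if (n_marker > 0) sum(mk & hi) / n_marker else NA_real_,
    prop_low_given_marker = if (n_marker > 0) sum(mk & !hi) / n_marker else NA_real_,
    prop_marker_given_hi = if (n_hi > 0) sum(hi & mk) / n_hi else NA_real_
  )
}

#' Simple count-based proportion
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return A list with `k`, `n`, `prop` (k/n, `NA` if n = 0) and
#'   `percent`.
#' @export
count_proportion <- function(k, n) {
  stopifnot(k >= 0, n >= 0, k <= n || n == 0)
  p <- if (n > 0) k / n else NA_real_
  list(k = as.integer(k), n = as.integer(n), prop = p, percent = 100 * p)
}

#' Log-scale histogram of intensities
#'
#' Bins positive intensities into intervals of uniform width on the log10
#' scale (the field convention for displaying reporter-intensity
#' distributions uses bins of width 0.04 or 0.05 log10 units, i.e.
#' 10^0.04-fold). Bin edges fall on integer multiples of the width and the
#' bins are left-closed.
#'
#' @param intensities Positive values.
#' @param width Bin width in log10 units (default 0.05).
#' @return A tibble with `log10_lo`, `log10_hi`, `mid` (linear-scale bin
#'   centre), `count` and `prop` (sums to 1).
#' @export
log_histogram <- function(intensities, width = 0.05) {
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and > 0", call. = FALSE)
  lx <- log10(intensities)
  lo <- floor(min(lx) / width) * width
  hi <- ceiling(max(lx) / width) * width
  if (hi <= max(lx)) hi <- hi + width
  edges <- seq(lo, hi, by = width)
  if (edges[length(edges)] <= max(lx)) edges <- c(edges, edges[length(edges)] + width)
  counts <- graphics::hist(lx, breaks = edges, right = FALSE, plot = FALSE)$counts
  tibble::tibble(
    log10_lo = edges[-length(edges)],
    log10_hi = edges[-1],
    mid = 10^((edges[-length(edges)] + edges[-1]) / 2),
    count = counts,
    prop = counts / sum(counts)
  )
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two intensity distributions with the two-sample K-S test
#' (the convention for assessing shifts between reporter-intensity
#' distributions across conditions), returning the D statistic (sup
#' distance between the two empirical CDFs) and the asymptotic p-value.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A list with `d`, `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(d = unname(kt$statistic), p_value = unname(kt$p.value),
       n_a = length(sample_a), n_b = length(sample_b))
}
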