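#' Parameters of the dimensionless Notch-Delta lateral-inhibition circuit
#'
#' Constructs and validates the parameter set of the dimensionless
#' lateral-inhibition model. Activated Notch in each cell is driven by the
#' Delta ligand of its neighbours through a Hill function with threshold
#' `kn`, and Delta in each cell is repressed by that cell's own activated
#' Notch through a Hill function with threshold `kd`:
#'
#' \deqn{dN_i/dt = \bar{D}_i^r / (kn^r + \bar{D}_i^r) - N_i}
#' \deqn{dD_i/dt = v \left( 1/(1 + (N_i/kd)^h) - D_i \right)}
#'
#' where \eqn{\bar{D}_i} is the neighbour Delta input of cell *i*. `kn`
#' sets the intercellular leg of the circuit (it is inversely related to
#' cell-cell contact area), while `kd` sets the intracellular leg; raising
#' `kd` weakens Notch's ability to shut off its neighbour-facing ligand and
#' models the injury state in which high-Notch cells keep expressing Delta.
#'
#' @param kn Dimensionless threshold of Notch activation by neighbour
#'   Delta. Must be positive.
#' @param kd Dimensionless threshold of Delta inhibition by same-cell
#'   activated Notch. Must be positive.
#' @param v Ratio of Notch to Delta degradation rates (default 1).
#' @param r Hill coefficient for Notch activation (integer, default 2).
#' @param h Hill coefficient for Delta inhibition (integer, default 2).
#' @param beta Maximal reporter production rate (default 1).
#' @param alpha Reporter degradation rate; only used by the full reporter
#'   ODE mode (default 0, i.e. pure accumulation).
#' @return An object of class `circuit_params`.
#' @examples
#' circuit_params(kn = 0.5, kd = 0.25)
#' @export
circuit_params <- function(kn, kd, v = 1, r = 2L, h = 2L, beta = 1, alpha = 0) {
  stopifnot(is.numeric(kn), is.numeric(kd), length(kn) == 1L, length(kd) == 1L)
  if (!is.finite(kn) || kn <= 0) stop("`kn` must be a positive finite number", call. = FALSE)
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be a positive finite number", call. = FALSE)
  if (!is.finite(v) || v <= 0) stop("`v` must be a positive finite number", call. = FALSE)
  if (r < 1 || r != round(r)) stop("`r` must be an integer >= 1", call. = FALSE)
  if (h < 1 || h != round(h)) stop("`h` must be an integer >= 1", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  structure(
    list(kn = kn, kd = kd, v = v, r = as.integer(r), h = as.integer(h),
         beta = beta, alpha = alpha),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Notch-Delta circuit parameters\n")
  cat(sprintf("  kn = %g, kd = %g, v = %g, r = %d, h = %d\n", x$kn, x$kd, x$v, x$r, x$h))
  cat(sprintf("  reporter: beta = %g, alpha = %g\n", x$beta, x$alpha))
  invisible(x)
}

#' Cell neighbourhood topologies
#'
#' Builds the neighbour map used by the circuit simulators. Each cell must
#' have at least one neighbour; the neighbour Delta input of a cell is the
#' arithmetic mean of its neighbours' Delta levels, so a two-cell pair
#' reduces exactly to the classical mutual-signalling model.
#'
#' @param n_cells Number of cells (>= 2).
#' @param type `"complete"` (all cells mutually connected, the default) or
#'   `"chain"` (cell i connected to i-1 and i+1).
#' @return A list of integer vectors, one per cell, giving neighbour indices.
#' @export
make_topology <- function(n_cells, type = c("complete", "chain")) {
  type <- match.arg(type)
  stopifnot(n_cells >= 2)
  idx <- seq_len(n_cells)
  nb <- switch(type,
    complete = lapply(idx, function(i) idx[idx != i]),
    chain = lapply(idx, function(i) idx[abs(idx - i) == 1L])
  )
  if (any(lengths(nb) == 0L)) stop("every cell needs at least one neighbour", call. = FALSE)
  nb
}
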