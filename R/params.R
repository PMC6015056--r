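#' Dimensionless parameters of the lateral inhibition model
#'
#' Collects the dimensionless parameter vector that governs one model
#' variant on one periodic lattice. Three variants are distinguished by
#' `W` and `h`:
#'
#' * `W = Inf`, `h = 0`: the classical model with a single well-mixed pool
#'   of activated Notch per cell.
#' * finite `W`, `h = 0`: intracellular Notch heterogeneity — each cell
#'   carries left and right activated-Notch pools exchanged at rate `W`.
#' * `h > 0`: the Delta-Notch binding rate additionally depends on the
#'   intercellular distance through a Dembo-type exponential law with
#'   optimum distance `lambda` and sensitivity `h`.
#'
#' @param b0 Maximum dimensionless Delta production rate (> 0).
#' @param K Dimensionless inhibitory coefficient: the mean activated-Notch
#'   fraction giving half-maximal repression of Delta production (> 0).
#' @param kd Dimensionless activated-Notch decay rate (> 0).
#' @param kf0 Baseline dimensionless Delta-Notch binding rate constant (> 0).
#' @param h Tension-sensitivity coefficient of the binding rate (>= 0).
#'   `h = 0` switches the tension dependence off.
#' @param lambda Optimum dimensionless intercellular distance in the Dembo
#'   law. Ignored when `h = 0`.
#' @param W Dimensionless intracellular Notch diffusion rate. A finite
#'   non-negative number, or `Inf` for the fast-diffusion (single-pool)
#'   limit.
#' @param n_cells Number of cells on the periodic lattice (integer >= 2).
#' @param hill Hill coefficient of Notch-mediated repression of Delta
#'   (default 2).
#'
#' @return An object of class `li_params`: a named list with the fields
#'   above plus `variant`, one of `"heterogeneous"` (finite `W`) or
#'   `"pooled"` (`W = Inf`).
#' @examples
#' li_params(b0 = 0.8, K = 0.01, kd = 1, kf0 = 0.1, W = 0)
#' @export
li_params <- function(b0, K, kd, kf0, h = 0, lambda = 0, W = Inf,
                      n_cells = 12L, hill = 2) {
  p <- list(
    b0 = as.numeric(b0), K = as.numeric(K), kd = as.numeric(kd),
    kf0 = as.numeric(kf0), h = as.numeric(h), lambda = as.numeric(lambda),
    W = as.numeric(W), n_cells = as.integer(n_cells), hill = as.numeric(hill)
  )
  validate_li_params(p)
  p$variant <- if (is.infinite(p$W)) "pooled" else "heterogeneous"
  structure(p, class = "li_params")
}

validate_li_params <- function(p) {
  scalar_pos <- c("b0", "K", "kd", "kf0")
  for (f in scalar_pos) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      abort_invalid_parameter(f, "must be a single strictly positive finite number")
    }
  }
  if (length(p$h) != 1L || !is.finite(p$h) || p$h < 0) {
    abort_invalid_parameter("h", "must be a single finite number >= 0")
  }
  if (length(p$lambda) != 1L || !is.finite(p$lambda)) {
    abort_invalid_parameter("lambda", "must be a single finite number")
  }
  if (length(p$W) != 1L || is.na(p$W) || p$W < 0) {
    abort_invalid_parameter("W", "must be >= 0 (possibly Inf)")
  }
  if (length(p$n_cells) != 1L || is.na(p$n_cells) || p$n_cells < 2L) {
    abort_invalid_parameter("n_cells", "must be an integer >= 2")
  }
  if (length(p$hill) != 1L || !is.finite(p$hill) || p$hill < 1) {
    abort_invalid_parameter("hill", "must be >= 1")
  }
  invisible(p)
}

abort_invalid_parameter <- function(field, msg) {
  rlang::abort(
    paste0("invalid parameter `", field, "`: ", msg),
    class = "tipstalk_error_invalid_parameter",
    field = field
  )
}

#' @export
print.li_params <- function(x, ...) {
  cat("<li_params> ", x$variant,
      if (x$h > 0) " + tension-dependent binding" else "", "\n", sep = "")
  cat(sprintf("  b0 = %g, K = %g, kd = %g, kf0 = %g, hill = %g\n",
              x$b0, x$K, x$kd, x$kf0, x$hill))
  cat(sprintf("  h = %g, lambda = %g, W = %s, n_cells = %d\n",
              x$h, x$lambda, format(x$W), x$n_cells))
  invisible(x)
}

#' Dimensional parameters of the lateral inhibition model
#'
#' Container for the dimensional rate constants; see
#' [nondimensionalize()] for the mapping to the dimensionless system.
#'
#' @param B0 Maximum Delta expression rate (concentration/time).
#' @param k_D Delta decay rate (1/time).
#' @param k_N Notch decay rate (1/time).
#' @param k Delta inhibitory coefficient (concentration of activated Notch
#'   at half-maximal repression).
#' @param K_F Delta-Notch binding rate constant (1/(concentration x time)).
#' @param N0_total Total Notch per cell side (concentration).
#' @param F_Notch Intracellular Notch diffusion coefficient (length^2/time).
#' @param L Cell length (length).
#' @return An object of class `li_dimensional`.
#' @export
dimensional_params <- function(B0, k_D, k_N, k, K_F, N0_total, F_Notch, L) {
  d <- list(B0 = B0, k_D = k_D, k_N = k_N, k = k, K_F = K_F,
            N0_total = N0_total, F_Notch = F_Notch, L = L)
  for (f in names(d)) {
    v <- d[[f]]
    ok <- length(v) == 1L && is.finite(v) &&
      (v > 0 || (f == "F_Notch" && v >= 0))
    if (!ok) abort_invalid_parameter(f, "must be a single positive finite number")
  }
  structure(lapply(d, as.numeric), class = "li_dimensional")
}

#' Map dimensional parameters onto the dimensionless model
#'
#' Applies the nondimensionalization conventions of the model: time is
#' rescaled by the Delta decay rate and Delta by its reference scale
#' `D_0 = kd / B0` (with `kd = k_N / k_D` the dimensionless Notch decay),
#' giving `b0 = B0 / (k_D * D_0)`, `K = k / N0_total`,
#' `kf0 = K_F * D_0 / (2 * k_D)` and `W = F_Notch / (L^2 * k_D * N0_total)`.
#' The tension parameters `h` and `lambda` are dimensionless bundles of the
#' Dembo constants and are passed through unchanged.
#'
#' @param dim An [dimensional_params()] object.
#' @param h,lambda,n_cells,hill Passed through to [li_params()].
#' @return An `li_params` object.
#' @export
nondimensionalize <- function(dim, h = 0, lambda = 0, n_cells = 12L, hill = 2) {
  stopifnot(inherits(dim, "li_dimensional"))
  kd <- dim$k_N / dim$k_D
  D0 <- kd / dim$B0
  li_params(
    b0 = dim$B0 / (dim$k_D * D0),
    K = dim$k / dim$N0_total,
    kd = kd,
    kf0 = dim$K_F * D0 / (2 * dim$k_D),
    h = h, lambda = lambda,
    W = dim$F_Notch / (dim$L^2 * dim$k_D * dim$N0_total),
    n_cells = n_cells, hill = hill
  )
}
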