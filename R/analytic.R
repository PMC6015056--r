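#' The steady-state matching function M
#'
#' In the fast-diffusion (`W = Inf`) tension model, eliminating Delta from
#' the steady-state equations of two stalk cells flanked by tips reduces
#' the matching condition to `M(N1) = M(N2)` with
#' `M(x) = (1 - x)/x * (1 + (x/K)^2)`. Non-trivial (unequal) stalk pairs
#' therefore require `M` to be many-to-one.
#'
#' @param x Activated-Notch fraction(s) in (0, 1].
#' @param K Inhibitory coefficient (> 0).
#' @return `M(x)` (vectorized).
#' @examples
#' m_function(0.5, 1) # 1.25
#' @export
m_function <- function(x, K) {
  stopifnot(K > 0)
  if (any(x <= 0)) {
    rlang::abort("m_function requires x > 0", class = "tipstalk_error_domain")
  }
  (1 - x) / x * (1 + (x / K)^2)
}

#' Positive stationary points of M
#'
#' `M'(x) = -1/x^2 + 1/K^2 - 2x/K^2 = 0` clears to `x^2 - 2x^3 = K^2`.
#' The left side peaks at `1/27` (at `x = 1/3`), so there are two distinct
#' positive stationary points when `K^2 < 1/27`, one double point at the
#' threshold, and none above it. Roots are found by bracketed bisection on
#' the cleared cubic, which is well behaved near `x = 0`.
#'
#' @param K Inhibitory coefficient (> 0).
#' @return Numeric vector of stationary points (length 0, 1 or 2), all in
#'   `(0, 1/2)`.
#' @export
m_prime_roots <- function(K) {
  stopifnot(length(K) == 1L, is.finite(K), K > 0)
  g <- function(x) x^2 - 2 * x^3 - K^2
  peak <- g(1 / 3)
  if (abs(peak) <= 1e-14) return(1 / 3)
  if (peak < 0) return(numeric(0))
  lo <- stats::uniroot(g, c(1e-12, 1 / 3), tol = 1e-14)$root
  hi <- stats::uniroot(g, c(1 / 3, 1 / 2), tol = 1e-14)$root
  c(lo, hi)
}

#' Critical inhibition coefficient for non-trivial stalk pairs
#'
#' The largest `K` at which `M'` still has two distinct positive roots:
#' `K* = sqrt(max(x^2 - 2x^3)) = sqrt(1/27) = 1/(3 sqrt(3)) = 0.19245...`.
#' Above this threshold `M` is monotone on `(0, 1]` and only the trivial
#' equal-Notch solution exists, so two-cell (and larger) spacings of the
#' pooled tension model require `K < K*`.
#'
#' @return The threshold `1/(3 * sqrt(3))`.
#' @export
critical_K <- function() 1 / (3 * sqrt(3))

#' Stationary-point analysis of M at a given K
#'
#' @param K Inhibitory coefficient (> 0).
#' @return An object of class `li_mfun`: `K`, `stationary_points` and the
#'   `many_to_one` flag (two distinct stationary points).
#' @export
m_function_analysis <- function(K) {
  sp <- m_prime_roots(K)
  structure(list(K = K, stationary_points = sp,
                 many_to_one = length(sp) == 2L),
            class = "li_mfun")
}

#' @export
print.li_mfun <- function(x, ...) {
  cat(sprintf("<li_mfun> K = %g: %d stationary point(s)%s\n", x$K,
              length(x$stationary_points),
              if (x$many_to_one) " (many-to-one)" else ""))
  if (length(x$stationary_points)) {
    cat("  at x =", paste(signif(x$stationary_points, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Residual of the stalk-pair matching condition
#'
#' @param N1,N2 Activated-Notch fractions of the two stalk cells, in
#'   (0, 1].
#' @param K Inhibitory coefficient (> 0).
#' @return `|M(N1) - M(N2)|`; zero at any admissible stalk pair
#'   (trivially when `N1 = N2`).
#' @export
equality_residual <- function(N1, N2, K) {
  abs(m_function(N1, K) - m_function(N2, K))
}

#' Symmetry residual of a three-cell-spacing root
#'
#' With distance-independent binding (`h = 0`) the two outer stalk cells
#' of a three-cell spacing see identical activation (both their inner
#' sides face the middle stalk's Delta and both outer sides face a tip),
#' so their Notch and Delta levels must coincide and the pattern collapses
#' to a one-cell spacing. Tension-dependent binding (`h > 0`) breaks this
#' symmetry. Returns the largest deviation between the two outer stalk
#' cells (Delta, plus mirror-paired Notch sides for finite `W`).
#'
#' @param result A found `li_steady` result from a three-cell ansatz.
#' @return The symmetry residual (<= 1e-8 at any converged `h = 0` root).
#' @export
three_cell_symmetry_check <- function(result) {
  stopifnot(inherits(result, "li_steady"), isTRUE(result$found))
  if (result$spacing_claimed != 3L) {
    abort_unsupported_variant("symmetry check requires a three-cell ansatz result")
  }
  st <- result$state
  n <- nrow(st)
  tip <- which.max(st$D) # a period-4 tiling: tip, stalk1, stalk2, stalk3
  at <- function(k) ((tip - 1L + k) %% n) + 1L
  c1 <- at(1L); c3 <- at(3L)
  if (result$params$variant == "pooled") {
    max(abs(st$D[c1] - st$D[c3]),
        abs(st$N_left[c1] - st$N_left[c3]))
  } else {
    # mirror symmetry about the middle stalk swaps left and right sides
    max(abs(st$D[c1] - st$D[c3]),
        abs(st$N_left[c1] - st$N_right[c3]),
        abs(st$N_right[c1] - st$N_left[c3]))
  }
}
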