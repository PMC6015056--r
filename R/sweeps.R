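#' Define a (K, kf0) sweep grid
#'
#' @param K_values Strictly increasing positive grid of the inhibition
#'   coefficient `K` (log-spaced by convention).
#' @param kf0_values Strictly increasing positive grid of the baseline
#'   binding rate `kf0`.
#' @param base An [li_params()] object supplying every non-swept field.
#' @param spacings Integer vector of candidate spacings to test at each
#'   grid point.
#' @return An object of class `li_grid`.
#' @export
sweep_grid <- function(K_values, kf0_values, base, spacings) {
  stopifnot(inherits(base, "li_params"))
  chk <- function(v, nm) {
    if (length(v) == 0 || any(v <= 0) || is.unsorted(v, strictly = TRUE)) {
      abort_invalid_parameter(nm, "must be non-empty, positive and strictly increasing")
    }
  }
  chk(K_values, "K_values")
  chk(kf0_values, "kf0_values")
  spacings <- as.integer(spacings)
  structure(list(K_values = as.numeric(K_values),
                 kf0_values = as.numeric(kf0_values),
                 base = base, spacings = spacings),
            class = "li_grid")
}

#' Log-spaced grid helper
#'
#' @param from,to Positive range endpoints.
#' @param n Number of points.
#' @return `n` log-spaced values from `from` to `to`.
#' @export
log_space <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Map pattern existence and stability over a (K, kf0) grid
#'
#' Runs [solve_pattern()] at every grid point for every candidate spacing
#' and records one verdict per (point, spacing): `"stable"` (a root exists
#' and is linearly stable), `"unstable-only"` (a root exists but none of
#' the converged attempts is stable) or `"not-found"`. Coexisting stable
#' spacings at one point are all recorded. Deterministic given `seed`.
#'
#' @param grid An [sweep_grid()] object.
#' @param seed Restart seed passed to [solve_pattern()].
#' @return A tibble of class `li_map` with columns `K`, `kf0`, `spacing`,
#'   `verdict`, sorted by (K, kf0, spacing); attributes carry the base
#'   parameters, grid and seed.
#' @export
sweep_existence <- function(grid, seed = 20180622) {
  stopifnot(inherits(grid, "li_grid"))
  cases <- tidyr::expand_grid(K = grid$K_values, kf0 = grid$kf0_values,
                              spacing = grid$spacings)
  verdict <- purrr::pmap_chr(cases, function(K, kf0, spacing) {
    p <- grid$base
    p$K <- K
    p$kf0 <- kf0
    res <- tryCatch(solve_pattern(p, spacing, seed = seed),
                    error = function(e) NULL)
    if (is.null(res) || !res$found) "not-found"
    else if (res$verdict == "stable" && !res$collapsed) "stable"
    else if (!res$collapsed) "unstable-only"
    else "not-found"
  })
  out <- dplyr::arrange(dplyr::mutate(cases, verdict = verdict),
                        .data$K, .data$kf0, .data$spacing)
  structure(out, base = grid$base, seed = seed,
            K_values = grid$K_values, kf0_values = grid$kf0_values,
            class = c("li_map", class(out)))
}

#' Summarise stable spacings across the four model regimes
#'
#' Runs a fixed reference sweep in each requested quadrant of the
#' (diffusion, tension) plane — classical (`W = Inf`, `h = 0`),
#' heterogeneity only (finite `W`, `h = 0`), tension only (`W = Inf`,
#' `h > 0`) and both mechanisms — and reports the set of spacings ever
#' found stable. The reference grids are small and anchored on parameter
#' regions where each variant's patterns are known to live; the
#' tension-only quadrant pools two reference sweeps because its stable
#' windows for different spacings occur at different decay rates.
#'
#' @param quadrants Character vector among `"classical"`,
#'   `"heterogeneity"`, `"tension"`, `"both"`.
#' @param seed Restart seed.
#' @return A tibble with columns `quadrant`, `W_regime`, `h_regime`,
#'   `stable_spacings` (list column of integer vectors) and `spacings`
#'   (comma-separated string).
#' @export
regime_summary <- function(quadrants = c("classical", "heterogeneity",
                                         "tension", "both"),
                           seed = 20180622) {
  quadrants <- match.arg(quadrants, several.ok = TRUE)
  sweeps_for <- function(q) {
    switch(q,
      classical = list(sweep_grid(
        K_values = log_space(1e-3, 1, 5),
        kf0_values = log_space(1e-2, 1e2, 5),
        base = li_params(b0 = 0.8, K = 1, kd = 1, kf0 = 1, h = 0, W = Inf),
        spacings = 0:3)),
      heterogeneity = list(sweep_grid(
        K_values = c(0.005, 0.01, 0.025, 0.05, 0.1, 1),
        kf0_values = c(0.05, 0.1, 0.3, 1, 10),
        base = li_params(b0 = 0.9, K = 1, kd = 0.2, kf0 = 1, h = 0, W = 0),
        spacings = 0:3)),
      tension = list(
        sweep_grid(
          K_values = c(0.02, 0.05, 0.1, 0.15),
          kf0_values = c(1, 3.719, 10),
          base = li_params(b0 = 0.9, K = 1, kd = 0.0225, kf0 = 1,
                           h = 0.0052, lambda = 30, W = Inf),
          spacings = 0:2),
        sweep_grid(
          K_values = c(0.02, 0.05, 0.1),
          kf0_values = c(10, 38.6324, 60),
          base = li_params(b0 = 0.9, K = 1, kd = 0.4021, kf0 = 1,
                           h = 0.0761, lambda = 10, W = Inf),
          spacings = 0:3)),
      both = list(sweep_grid(
        K_values = c(0.001, 0.005, 0.01, 0.05, 0.1),
        kf0_values = c(1, 5, 10, 35, 60),
        base = li_params(b0 = 0.9, K = 1, kd = 0.4, kf0 = 1,
                         h = 0.076, lambda = 10, W = 0),
        spacings = 0:3))
    )
  }
  rows <- lapply(quadrants, function(q) {
    maps <- lapply(sweeps_for(q), sweep_existence, seed = seed)
    stable <- sort(unique(unlist(lapply(maps, function(m) {
      m$spacing[m$verdict == "stable"]
    }))))
    tibble::tibble(
      quadrant = q,
      W_regime = if (q %in% c("classical", "tension")) "infinite" else "finite",
      h_regime = if (q %in% c("classical", "heterogeneity")) "zero" else "positive",
      stable_spacings = list(as.integer(stable)),
      spacings = paste(stable, collapse = ",")
    )
  })
  dplyr::bind_rows(rows)
}
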