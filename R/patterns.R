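#' Classify the spacing of a lattice state
#'
#' Tip cells are the cells with the highest Delta level; an n-cell spacing
#' has n stalk cells between consecutive tips. A state whose Delta profile
#' is flat (to `rel_tol`) is the uniform pattern, reported as spacing 0.
#' If consecutive tips are not equally spaced the pattern is irregular.
#'
#' @param state An [lattice_state()] tibble.
#' @param rel_tol Relative tolerance grouping cells with the maximal Delta
#'   level into the tip class (default 1e-3).
#' @return An object of class `li_pattern`: `spacing` (integer, `NA` if
#'   irregular), `irregular` flag, `period` (`NA` if irregular), `tips`
#'   (0-based tip cell indices) and `uniform` flag.
#' @examples
#' s <- lattice_state(D = rep(c(0.8, 0.01), 3), N_left = rep(c(0.1, 0.9), 3))
#' classify_spacing(s)$spacing # 1
#' @export
classify_spacing <- function(state, rel_tol = 1e-3) {
  validate_li_state(state)
  D <- state$D
  n <- length(D)
  Dmax <- max(D)
  # floor guards the all-zero state in the uniformity test
  if (max(D) - min(D) <= rel_tol * max(Dmax, 1e-12)) {
    return(new_li_pattern(spacing = 0L, period = 1L, tips = state$cell,
                          uniform = TRUE))
  }
  tips <- which(D >= (1 - rel_tol) * Dmax)
  if (length(tips) == n) {
    return(new_li_pattern(spacing = 0L, period = 1L, tips = state$cell,
                          uniform = TRUE))
  }
  gaps <- diff(c(tips, tips[1] + n)) # cyclic gaps between consecutive tips
  if (length(unique(gaps)) == 1L) {
    new_li_pattern(spacing = gaps[1] - 1L, period = gaps[1],
                   tips = state$cell[tips], uniform = FALSE)
  } else {
    new_li_pattern(spacing = NA_integer_, period = NA_integer_,
                   tips = state$cell[tips], uniform = FALSE,
                   irregular = TRUE)
  }
}

new_li_pattern <- function(spacing, period, tips, uniform, irregular = FALSE) {
  structure(list(spacing = spacing, period = period, tips = tips,
                 uniform = uniform, irregular = irregular),
            class = "li_pattern")
}

#' @export
print.li_pattern <- function(x, ...) {
  if (x$irregular) cat("<li_pattern> irregular\n")
  else cat(sprintf("<li_pattern> spacing %d (period %d)%s\n", x$spacing,
                   x$period, if (x$uniform) ", uniform" else ""))
  invisible(x)
}

#' Label cells as tip, stalk or hybrid
#'
#' Cells near the maximal Delta level are tips, cells near zero Delta are
#' stalks, and cells with moderate Delta — the intermediate phenotype with
#' asymmetric left/right Notch that larger spacings are built from — are
#' labelled hybrid.
#'
#' @param state An [lattice_state()] tibble.
#' @param tip_frac Fraction of the maximal Delta above which a cell is a
#'   tip (default 0.9).
#' @param stalk_frac Fraction below which a cell is a stalk (default 0.1).
#' @return A tibble with columns `cell`, `D`, `label`.
#' @export
label_cells <- function(state, tip_frac = 0.9, stalk_frac = 0.1) {
  validate_li_state(state)
  if (!(stalk_frac > 0 && stalk_frac < tip_frac && tip_frac < 1)) {
    abort_invalid_parameter("tip_frac/stalk_frac",
                            "need 0 < stalk_frac < tip_frac < 1")
  }
  Dmax <- max(state$D)
  cls <- classify_spacing(state)
  label <- if (cls$uniform) {
    rep("uniform", nrow(state))
  } else {
    dplyr::case_when(
      state$D >= tip_frac * Dmax ~ "tip",
      state$D <= stalk_frac * Dmax ~ "stalk",
      TRUE ~ "hybrid"
    )
  }
  tibble::tibble(cell = state$cell, D = state$D, label = label)
}

#' Left/right activated-Notch asymmetry per cell
#'
#' @param state An [lattice_state()] tibble from the heterogeneous
#'   (finite `W`) variant.
#' @return A tibble with columns `cell`, `asymmetry` =
#'   `|N_left - N_right|`.
#' @export
notch_asymmetry <- function(state) {
  validate_li_state(state)
  tibble::tibble(cell = state$cell,
                 asymmetry = abs(state$N_left - state$N_right))
}
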