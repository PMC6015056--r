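#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a steady-state result
#'
#' @param x An `li_steady` result with `found = TRUE`.
#' @param ... Unused.
#' @return A tibble with one row per cell: the state columns plus the
#'   tip/stalk/hybrid `label` and the left/right Notch `asymmetry`.
#' @method tidy li_steady
#' @export
tidy.li_steady <- function(x, ...) {
  stopifnot(isTRUE(x$found))
  dplyr::left_join(
    dplyr::left_join(tibble::as_tibble(x$state),
                     label_cells(x$state)[, c("cell", "label")], by = "cell"),
    notch_asymmetry(x$state), by = "cell")
}

#' One-row summary of a steady-state result
#'
#' @param x An `li_steady` result.
#' @param ... Unused.
#' @return A tibble with `found`, claimed/observed spacing, `collapsed`,
#'   `residual_norm`, `max_re_eigenvalue` and the stability `verdict`.
#' @method glance li_steady
#' @export
glance.li_steady <- function(x, ...) {
  tibble::tibble(
    found = x$found,
    spacing_claimed = x$spacing_claimed,
    spacing_observed = x$spacing_observed,
    collapsed = x$collapsed,
    residual_norm = x$residual_norm,
    max_re_eigenvalue = if (is.null(x$eigenvalues)) NA_real_
                        else max(Re(x$eigenvalues)),
    verdict = x$verdict
  )
}

#' One-row summary of a trajectory
#'
#' @param x An `li_trajectory`.
#' @param ... Unused.
#' @return A tibble with `t_end`, `final_residual` and `converged`.
#' @method glance li_trajectory
#' @export
glance.li_trajectory <- function(x, ...) {
  tibble::tibble(
    t_end = max(x$time),
    final_residual = attr(x, "final_residual"),
    converged = attr(x, "converged")
  )
}

#' Plot the per-cell profile of a lattice state
#'
#' Bar panels of Delta, Notch-left and Notch-right against cell number,
#' the standard way one inspects a tip-stalk pattern.
#'
#' @param object An `li_state` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot li_state
#' @export
autoplot.li_state <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("D", "N_left", "N_right"),
                              names_to = "variable", values_to = "level")
  long$variable <- factor(long$variable, levels = c("D", "N_left", "N_right"),
                          labels = c("Delta", "Notch left", "Notch right"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$level)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "cell", y = "dimensionless level") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.li_state
#' @method autoplot li_steady
#' @export
autoplot.li_steady <- function(object, ...) {
  stopifnot(isTRUE(object$found))
  autoplot(object$state) +
    ggplot2::ggtitle(sprintf("spacing %s (%s)",
                             object$spacing_observed, object$verdict))
}

#' Plot a pattern-existence map
#'
#' Tile map of the verdict over the (K, kf0) grid, faceted by candidate
#' spacing (log axes).
#'
#' @param object An `li_map` from [sweep_existence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot li_map
#' @export
autoplot.li_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$kf0,
                                   fill = .data$verdict)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~spacing, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(
      "stable" = "#1b7837", "unstable-only" = "#fdb863",
      "not-found" = "grey85")) +
    ggplot2::labs(x = "K", y = "kf0") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory
#'
#' Delta levels of every cell against time.
#'
#' @param object An `li_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot li_trajectory
#' @export
autoplot.li_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$D,
                                   group = .data$cell,
                                   colour = factor(.data$cell))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (dimensionless)", y = "Delta",
                  colour = "cell") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
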