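abort_config <- function(key, msg) {
  rlang::abort(paste0("config error at `", key, "`: ", msg),
               class = "tipstalk_error_config", key = key)
}

config_keys <- c("b0", "K", "kd", "kf0", "h", "lambda", "W", "n_cells", "hill")

#' Load model parameters from a YAML config file
#'
#' Recognised keys: `b0`, `K`, `kd`, `kf0`, `h`, `lambda`, `W`,
#' `n_cells`, `hill`. `W` accepts the literal string `"inf"`. Unknown keys
#' are rejected; omitted optional keys take the defaults `h = 0`,
#' `lambda = 0`, `W = "inf"`, `n_cells = 12`, `hill = 2`.
#'
#' @param path Path to a YAML file.
#' @return An [li_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_config(path, "file does not exist")
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_config(path, conditionMessage(e)))
  if (!is.list(cfg)) abort_config(path, "top level must be a mapping")
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) abort_config(unknown[1], "unknown key")
  for (req in c("b0", "K", "kd", "kf0")) {
    if (is.null(cfg[[req]])) abort_config(req, "required key missing")
  }
  W <- cfg$W %||% "inf"
  if (is.character(W)) {
    if (!identical(tolower(W), "inf")) abort_config("W", "must be a number or \"inf\"")
    W <- Inf
  }
  for (key in setdiff(config_keys, "W")) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L)) {
      abort_config(key, "must be a single number")
    }
  }
  tryCatch(
    li_params(b0 = cfg$b0, K = cfg$K, kd = cfg$kd, kf0 = cfg$kf0,
              h = cfg$h %||% 0, lambda = cfg$lambda %||% 0, W = W,
              n_cells = cfg$n_cells %||% 12L, hill = cfg$hill %||% 2),
    tipstalk_error_invalid_parameter = function(e) {
      abort_config(e$field %||% "?", conditionMessage(e))
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a lattice state as CSV
#'
#' The on-disk format has one row per cell with header
#' `cell,D,N_left,N_right` and 0-based cell indices.
#'
#' @param state An [lattice_state()] tibble.
#' @param path Output path.
#' @return `write_state` returns `path` invisibly; `read_state` returns
#'   an `li_state` tibble.
#' @export
write_state <- function(state, path) {
  validate_li_state(state)
  readr::write_csv(state[, c("cell", "D", "N_left", "N_right")], path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  lattice_state(D = df$D, N_left = df$N_left, N_right = df$N_right)
}

#' Write a solver or sweep result with a JSON metadata sidecar
#'
#' Steady states are written as a state CSV plus `<path>.json` carrying
#' parameters, seed, residual, eigenvalue extremes and the verdict;
#' pattern maps as tidy `K,kf0,spacing,verdict` CSV plus metadata;
#' trajectories as long `time,cell,D,N_left,N_right` CSV. Numbers in
#' sidecars keep 12 significant digits.
#'
#' @param result An `li_steady`, `li_map` or `li_trajectory` object.
#' @param path Output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  sidecar <- function(meta) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = 12, pretty = TRUE)
  }
  params_meta <- function(p) {
    m <- unclass(p)
    m$W <- if (is.infinite(m$W)) "inf" else m$W
    m
  }
  if (inherits(result, "li_steady")) {
    if (!result$found) {
      rlang::abort("cannot write a not-found steady-state result",
                   class = "tipstalk_error_invalid_state")
    }
    write_state(result$state, path)
    sidecar(list(
      type = "steady_state", version = pkg_version(),
      params = params_meta(result$params),
      spacing_claimed = result$spacing_claimed,
      spacing_observed = result$spacing_observed,
      collapsed = result$collapsed,
      residual_norm = result$residual_norm,
      max_re_eigenvalue = max(Re(result$eigenvalues)),
      min_re_eigenvalue = min(Re(result$eigenvalues)),
      verdict = result$verdict, seed = result$seed,
      restarts_used = result$restarts_used))
  } else if (inherits(result, "li_map")) {
    readr::write_csv(tibble::as_tibble(result), path)
    sidecar(list(
      type = "pattern_map", version = pkg_version(),
      params = params_meta(attr(result, "base")),
      K_values = attr(result, "K_values"),
      kf0_values = attr(result, "kf0_values"),
      seed = attr(result, "seed")))
  } else if (inherits(result, "li_trajectory")) {
    readr::write_csv(tibble::as_tibble(result), path)
    sidecar(list(
      type = "trajectory", version = pkg_version(),
      params = params_meta(attr(result, "params")),
      final_residual = attr(result, "final_residual"),
      converged = attr(result, "converged")))
  } else {
    rlang::abort("unsupported result type", class = "tipstalk_error_config")
  }
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("tipstalk"))
}

#' Reference parameter sets for each model regime
#'
#' The parameter sets at which the documented example patterns of every
#' variant live: uniform and salt-and-pepper states of the heterogeneous
#' model, its two-cell spacings at three diffusion rates, the narrow
#' two- and three-cell windows of the pooled tension model, and the four
#' spacings of the combined model.
#'
#' @return A tibble with one row per set: `name`, `spacing` (the spacing
#'   whose root exists and is stable there) and all model parameters.
#' @export
reference_parameter_sets <- function() {
  tibble::tribble(
    ~name, ~spacing, ~b0, ~K, ~kd, ~kf0, ~h, ~lambda, ~W,
    "het_zerocell",       0L, 0.5, 1,     1,      0.1,     0,      0,  0,
    "het_onecell",        1L, 0.8, 0.01,  1,      0.1,     0,      0,  0,
    "het_twocell",        2L, 0.8, 0.01,  1,      0.3,     0,      0,  0,
    "het_twocell_slow",   2L, 0.9, 0.025, 0.2,    0.3,     0,      0,  0,
    "het_twocell_W3",     2L, 0.9, 0.025, 0.2,    0.3,     0,      0,  3,
    "het_twocell_W50",    2L, 0.9, 0.025, 0.2,    0.3,     0,      0,  50,
    "tension_twocell",    2L, 0.9, 0.1,   0.0225, 3.719,   0.0052, 30, Inf,
    "tension_threecell",  3L, 0.9, 0.05,  0.4021, 38.6324, 0.0761, 10, Inf,
    "combined_zerocell",  0L, 0.9, 0.1,   0.4,    40,      0.076,  10, 0,
    "combined_onecell",   1L, 0.9, 0.07,  0.4,    40,      0.076,  10, 0,
    "combined_twocell",   2L, 0.9, 0.01,  0.4,    40,      0.076,  10, 0,
    "combined_threecell", 3L, 0.9, 0.01,  0.4,    35,      0.076,  10, 0
  )
}

#' Parameters of one reference set
#'
#' @param name A `name` from [reference_parameter_sets()].
#' @param n_cells Lattice size (default 12).
#' @return An [li_params()] object.
#' @export
reference_params <- function(name, n_cells = 12L) {
  sets <- reference_parameter_sets()
  row <- sets[sets$name == name, ]
  if (nrow(row) != 1L) abort_invalid_parameter("name", "unknown reference set")
  li_params(b0 = row$b0, K = row$K, kd = row$kd, kf0 = row$kf0, h = row$h,
            lambda = row$lambda, W = row$W, n_cells = n_cells)
}

#' Deterministic fixtures for testing and exploration
#'
#' Produces (a) synthetic lattice states with known spacings 0-3, (b)
#' random admissible states, and (c) the reference parameter sets, all
#' reproducible from `seed`.
#'
#' @param seed Integer seed.
#' @param n_cells Lattice size of the synthetic states (default 12).
#' @param n_random Number of random admissible states (default 4).
#' @return A list with elements `spacing_states` (named list of
#'   `li_state`, names `"spacing0"` to `"spacing3"`), `random_states` and
#'   `param_sets`.
#' @export
generate_fixtures <- function(seed = 1L, n_cells = 12L, n_random = 4L) {
  spacing_state <- function(spacing) {
    period <- spacing + 1L
    Dp <- c(0.8, rep(0.05, spacing))
    if (spacing >= 2L) Dp[2:period] <- seq(0.3, 0.05, length.out = spacing)
    D <- rep(Dp, length.out = n_cells)
    Np <- 0.9 - Dp # stalks high Notch, tips low
    lattice_state(D = D, N_left = rep(Np, length.out = n_cells))
  }
  spacing_states <- stats::setNames(
    lapply(0:3, spacing_state), paste0("spacing", 0:3))
  # spacing 0 fixture must actually be uniform
  spacing_states$spacing0 <- lattice_state(
    D = rep(0.4, n_cells), N_left = rep(0.3, n_cells))
  random_states <- withr::with_seed(seed, {
    lapply(seq_len(n_random), function(i) {
      lattice_state(D = stats::runif(n_cells, 0, 1),
                    N_left = stats::runif(n_cells),
                    N_right = stats::runif(n_cells))
    })
  })
  list(spacing_states = spacing_states, random_states = random_states,
       param_sets = reference_parameter_sets())
}
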