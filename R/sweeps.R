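#' Sweep axis specification
#'
#' One axis of a two-parameter phase-diagram sweep. Any field of
#' [drive_params()] or [induction_settings()] (plus \code{initial_q_D}) can
#' be swept.
#'
#' @param parameter Name of the parameter to vary: one of \code{"e_W"},
#'   \code{"f"}, \code{"h"}, \code{"e_W_induced"}, \code{"f_induced"},
#'   \code{"e_D"}, \code{"e_D_induced"}, \code{"alpha"},
#'   \code{"start_generation"}, \code{"initial_q_D"}.
#' @param from,to Axis bounds, within the parameter's legal range.
#' @param n Number of grid points (>= 2). Default 101.
#' @return An object of class \code{"axis_spec"}.
#' @examples
#' axis_spec("e_W", 0, 1, n = 21)
#' @export
axis_spec <- function(parameter, from, to, n = 101L) {
  parameter <- match.arg(parameter, .sweepable_params())
  if (!is.numeric(from) || !is.numeric(to) || from >= to) {
    stop("axis bounds must satisfy `from` < `to`", call. = FALSE)
  }
  if (n < 2) stop("an axis needs at least 2 grid points", call. = FALSE)
  structure(list(parameter = parameter, from = from, to = to,
                 n = as.integer(n),
                 values = seq(from, to, length.out = n)),
            class = "axis_spec")
}

.sweepable_params <- function() {
  c("e_W", "f", "h", "e_W_induced", "f_induced", "e_D", "e_D_induced",
    "alpha", "start_generation", "initial_q_D")
}

# return base config with one named parameter overridden
.override_config <- function(config, parameter, value) {
  p <- config$params
  ind <- config$induction
  if (parameter %in% names(unclass(p))) {
    p[[parameter]] <- value
  } else if (parameter == "alpha") {
    ind <- induction_settings(value, ind$start_generation, ind$enabled)
  } else if (parameter == "start_generation") {
    ind <- induction_settings(ind$alpha, value, ind$enabled)
  } else if (parameter == "initial_q_D") {
    return(simulation_config(p, config$variant, ind, value,
                             config$max_generations,
                             config$fixation_threshold))
  } else {
    stop(sprintf("unknown sweep parameter `%s`", parameter), call. = FALSE)
  }
  simulation_config(p, config$variant, ind, config$initial_q_D,
                    config$max_generations, config$fixation_threshold)
}

#' Two-parameter outcome grid sweep
#'
#' Runs one trajectory per grid cell with the cell's two parameter values
#' overriding the base configuration, all other parameters held fixed.
#' Produces the data behind outcome phase diagrams: which region of
#' parameter space drives the gene drive to fixation, which reverts to wild
#' type, and how long fixation takes.
#'
#' Cells in which the population mean fitness collapses to zero are
#' recorded with outcome \code{"DEGENERATE"}; the sweep never aborts.
#' When induction is enabled, cells where the drive is already lost before
#' the signal fires carry \code{pre_induction_loss = TRUE}.
#'
#' @param x,y [axis_spec()] objects naming two distinct parameters.
#' @param base_config A [simulation_config()] supplying every other value.
#' @return An object of class \code{"gd_outcome_grid"}: a list with the
#'   axis specs, the base config, and \code{cells} — a long-format data
#'   frame with columns \code{x_param}, \code{x_value}, \code{y_param},
#'   \code{y_value}, \code{outcome}, \code{fixation_generation},
#'   \code{pre_induction_loss}.
#' @examples
#' cfg <- simulation_config(drive_params(e_W = 0.5, f = 0.8),
#'                          max_generations = 200)
#' g <- grid_sweep(axis_spec("e_W", 0, 1, 5), axis_spec("f", 0, 1, 5), cfg)
#' table(g$cells$outcome)
#' @export
grid_sweep <- function(x, y, base_config) {
  stopifnot(inherits(x, "axis_spec"), inherits(y, "axis_spec"),
            inherits(base_config, "simulation_config"))
  if (x$parameter == y$parameter) {
    stop("the two axes must name distinct parameters", call. = FALSE)
  }
  grid <- expand.grid(x_value = x$values, y_value = y$values,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  outcome <- character(n)
  fix_gen <- rep(NA_integer_, n)
  pre_loss <- logical(n)
  for (i in seq_len(n)) {
    cfg <- .override_config(base_config, x$parameter, grid$x_value[i])
    cfg <- .override_config(cfg, y$parameter, grid$y_value[i])
    tr <- run_simulation(cfg, on_degenerate = "label")
    outcome[i] <- tr$outcome
    fix_gen[i] <- tr$fixation_generation
    ind <- cfg$induction
    pre_loss[i] <- ind$enabled && ind$alpha > 0 &&
      tr$outcome == "WT_FIXATION" &&
      !is.na(tr$fixation_generation) &&
      tr$fixation_generation <= ind$start_generation
  }
  cells <- data.frame(x_param = x$parameter, x_value = grid$x_value,
                      y_param = y$parameter, y_value = grid$y_value,
                      outcome = outcome, fixation_generation = fix_gen,
                      pre_induction_loss = pre_loss)
  structure(list(x_axis = x, y_axis = y, base_config = base_config,
                 cells = cells),
            class = "gd_outcome_grid")
}

#' @export
print.gd_outcome_grid <- function(x, ...) {
  cat(sprintf("Outcome grid: %s (%d) x %s (%d), %s model\n",
              x$x_axis$parameter, x$x_axis$n,
              x$y_axis$parameter, x$y_axis$n, x$base_config$variant))
  print(table(x$cells$outcome))
  invisible(x)
}

#' @export
plot.gd_outcome_grid <- function(x, ...) {
  lev <- c("WT_FIXATION", "NO_FIXATION", "GD_FIXATION", "DEGENERATE")
  z <- matrix(as.integer(factor(x$cells$outcome, levels = lev)),
              nrow = x$x_axis$n)
  graphics::image(x$x_axis$values, x$y_axis$values, z,
                  col = c("#2166ac", "#f7f7f7", "#b2182b", "grey30"),
                  zlim = c(1, 4),
                  xlab = x$x_axis$parameter, ylab = x$y_axis$parameter, ...)
  invisible(x)
}

#' Locate an outcome threshold along one parameter
#'
#' Bisection for the critical parameter value at which the run outcome
#' flips, e.g. the smallest drive fitness at which the drive still invades.
#' A coarse pre-scan first verifies that the predicate changes exactly once
#' over the bracket (a warning is issued if it is non-monotone); bisection
#' then narrows the bracket to the requested tolerance.
#'
#' @param parameter A sweepable parameter name (see [axis_spec()]).
#' @param bracket Numeric length-2 vector \code{c(low, high)}; the predicate
#'   must differ at the two ends.
#' @param base_config A [simulation_config()].
#' @param predicate Function of a trajectory returning \code{TRUE}/\code{FALSE};
#'   defaults to "drive reached fixation".
#' @param tolerance Final bracket width. Default \code{1e-4}.
#' @param prescan_n Number of pre-scan points used for the monotonicity
#'   check (set to 0 to skip).
#' @return A list with \code{value} (the final bracket midpoint),
#'   \code{bracket} (the final bracketing pair), \code{parameter} and
#'   \code{predicate_at_upper}.
#' @examples
#' cfg <- simulation_config(drive_params(e_W = 1, f = 0.5))
#' find_threshold("f", c(0.3, 0.7), cfg)$value  # ~0.5
#' @export
find_threshold <- function(parameter, bracket, base_config,
                           predicate = function(tr) tr$outcome == "GD_FIXATION",
                           tolerance = 1e-4, prescan_n = 21L) {
  parameter <- match.arg(parameter, .sweepable_params())
  stopifnot(inherits(base_config, "simulation_config"),
            length(bracket) == 2L, bracket[1] < bracket[2])
  eval_at <- function(v) {
    cfg <- .override_config(base_config, parameter, v)
    isTRUE(predicate(run_simulation(cfg, on_degenerate = "label")))
  }
  p_lo <- eval_at(bracket[1])
  p_hi <- eval_at(bracket[2])
  if (p_lo == p_hi) {
    stop("predicate does not change over the bracket; no threshold to find",
         call. = FALSE)
  }
  if (prescan_n >= 3L) {
    scan <- vapply(seq(bracket[1], bracket[2], length.out = prescan_n),
                   eval_at, logical(1L))
    if (sum(diff(scan) != 0) > 1L) {
      warning("predicate is non-monotone on the bracket; ",
              "bisection returns one of several crossings", call. = FALSE)
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (eval_at(mid) == p_lo) lo <- mid else hi <- mid
  }
  list(value = (lo + hi) / 2, bracket = c(lo, hi),
       parameter = parameter, predicate_at_upper = p_hi)
}
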