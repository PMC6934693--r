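#' Simulation configuration
#'
#' Bundles a model variant, its parameters, the induction schedule and the
#' run controls. Defaults follow the study conditions used throughout the
#' package: the drive is introduced at 0.1% allele frequency, an allele is
#' declared fixed when its frequency exceeds 0.99999, and runs are capped at
#' 1,000 generations.
#'
#' @param params A [drive_params()] object.
#' @param variant One of [model_variants()].
#' @param induction An [induction_settings()] object; default no induction.
#' @param initial_q_D Starting drive allele frequency, in (0, 1).
#' @param max_generations Generation cap (positive integer).
#' @param fixation_threshold Frequency above which (strictly) an allele is
#'   declared fixed; must lie in (0.5, 1).
#' @return An object of class \code{"simulation_config"}.
#' @examples
#' simulation_config(drive_params(e_W = 0.8, f = 0.7))
#' @export
simulation_config <- function(params, variant = "standard",
                              induction = no_induction(),
                              initial_q_D = 0.001,
                              max_generations = 1000L,
                              fixation_threshold = 0.99999) {
  stopifnot(inherits(params, "drive_params"),
            inherits(induction, "induction_settings"))
  variant <- .match_variant(variant)
  if (!is.numeric(initial_q_D) || initial_q_D <= 0 || initial_q_D >= 1) {
    stop("`initial_q_D` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(max_generations) || max_generations < 1) {
    stop("`max_generations` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(fixation_threshold) || fixation_threshold <= 0.5 ||
      fixation_threshold >= 1) {
    stop("`fixation_threshold` must lie strictly between 0.5 and 1",
         call. = FALSE)
  }
  structure(list(params = params, variant = variant, induction = induction,
                 initial_q_D = initial_q_D,
                 max_generations = as.integer(max_generations),
                 fixation_threshold = fixation_threshold),
            class = "simulation_config")
}

#' Run a multi-generation trajectory
#'
#' Iterates the variant's single-generation update from
#' \code{initial_q_D}, switching to the induced effective parameters from
#' the induction start generation onward (the transition producing
#' generation \code{start_generation + 1} is the first induced one). The run
#' stops at the first generation — including generation 0 — at which either
#' allele's frequency strictly exceeds the fixation threshold, or at the
#' generation cap.
#'
#' @param config A [simulation_config()] object.
#' @param on_degenerate What to do if the population mean fitness hits zero
#'   (the frequency model cannot represent this extinction): \code{"error"}
#'   signals a \code{"gd_degenerate_error"} carrying the generation at which
#'   it occurred; \code{"label"} terminates the trajectory with outcome
#'   \code{"DEGENERATE"} instead.
#' @return An object of class \code{"gd_trajectory"}: a list with
#'   \code{states} (data frame \code{generation}, \code{q_D}, \code{q_W},
#'   \code{induced}), \code{outcome} (one of \code{"GD_FIXATION"},
#'   \code{"WT_FIXATION"}, \code{"NO_FIXATION"}, \code{"DEGENERATE"}),
#'   \code{fixation_generation} (\code{NA} unless fixed),
#'   \code{induction_applied_from} (\code{NA} if the signal never fired
#'   before the run ended) and the \code{config}.
#' @examples
#' cfg <- simulation_config(drive_params(e_W = 1, f = 1))
#' run_simulation(cfg)  # drive fixes at generation 14
#' @export
run_simulation <- function(config, on_degenerate = c("error", "label")) {
  stopifnot(inherits(config, "simulation_config"))
  on_degenerate <- match.arg(on_degenerate)

  n_max <- config$max_generations
  q <- numeric(n_max + 1L)
  induced <- integer(n_max + 1L)
  q[1L] <- config$initial_q_D
  thr <- config$fixation_threshold

  outcome <- "NO_FIXATION"
  fix_gen <- NA_integer_
  last <- 0L
  degenerate_at <- NA_integer_

  fixed <- function(qd) qd > thr || (1 - qd) > thr

  if (fixed(q[1L])) {
    outcome <- if (q[1L] > thr) "GD_FIXATION" else "WT_FIXATION"
    fix_gen <- 0L
  } else {
    for (g in seq_len(n_max) - 1L) {      # parent generation index
      eff <- effective_params(config$params, config$induction, g)
      induced[g + 2L] <- as.integer(eff$alpha > 0)
      q_next <- tryCatch(drive_step(q[g + 1L], config$params,
                                    config$variant, eff),
                         gd_degenerate_error = function(e) e)
      if (inherits(q_next, "gd_degenerate_error")) {
        if (on_degenerate == "error") .degenerate_error(g + 1L)
        degenerate_at <- g + 1L
        outcome <- "DEGENERATE"
        last <- g
        break
      }
      q[g + 2L] <- q_next
      last <- g + 1L
      if (fixed(q_next)) {
        outcome <- if (q_next > thr) "GD_FIXATION" else "WT_FIXATION"
        fix_gen <- g + 1L
        break
      }
    }
  }

  states <- data.frame(generation = 0:last,
                       q_D = q[1:(last + 1L)],
                       q_W = 1 - q[1:(last + 1L)],
                       induced = induced[1:(last + 1L)])
  ind <- config$induction
  applied_from <- if (ind$enabled && ind$alpha > 0 &&
                      last >= ind$start_generation + 1L) {
    ind$start_generation
  } else NA_integer_

  structure(list(states = states, outcome = outcome,
                 fixation_generation = fix_gen,
                 induction_applied_from = applied_from,
                 degenerate_generation = degenerate_at,
                 config = config),
            class = "gd_trajectory")
}

#' @export
print.gd_trajectory <- function(x, ...) {
  cat(sprintf("Gene drive trajectory (%s model)\n", x$config$variant))
  cat(sprintf("  generations simulated: %d\n", nrow(x$states) - 1L))
  cat(sprintf("  outcome: %s", x$outcome))
  if (!is.na(x$fixation_generation)) {
    cat(sprintf(" at generation %d", x$fixation_generation))
  }
  cat("\n")
  cat(sprintf("  final q_D = %.6g\n", x$states$q_D[nrow(x$states)]))
  if (!is.na(x$induction_applied_from)) {
    cat(sprintf("  induction applied from generation %d\n",
                x$induction_applied_from))
  }
  invisible(x)
}

#' @export
plot.gd_trajectory <- function(x, ...) {
  graphics::plot(x$states$generation, x$states$q_D, type = "l", col = "red",
                 xlab = "generation", ylab = expression(q[D]),
                 ylim = c(0, 1), ...)
  ind <- x$config$induction
  if (ind$enabled && ind$alpha > 0) {
    graphics::abline(v = ind$start_generation, lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Classify the terminal state of a run
#'
#' @param trajectory A [run_simulation()] result, or a bare final
#'   drive-allele frequency.
#' @param fixation_threshold Threshold used for classification; defaults to
#'   the trajectory's own configured value.
#' @return \code{"GD_FIXATION"} if the final drive frequency strictly
#'   exceeds the threshold, \code{"WT_FIXATION"} if the wild-type frequency
#'   does, else \code{"NO_FIXATION"}.
#' @export
classify_outcome <- function(trajectory, fixation_threshold = NULL) {
  if (inherits(trajectory, "gd_trajectory")) {
    q <- trajectory$states$q_D[nrow(trajectory$states)]
    if (is.null(fixation_threshold)) {
      fixation_threshold <- trajectory$config$fixation_threshold
    }
  } else {
    q <- trajectory
    if (is.null(fixation_threshold)) fixation_threshold <- 0.99999
  }
  if (q > fixation_threshold) "GD_FIXATION"
  else if (1 - q > fixation_threshold) "WT_FIXATION"
  else "NO_FIXATION"
}

#' Generations until fixation
#'
#' @param trajectory A [run_simulation()] result.
#' @return The first generation index at which an allele exceeded the
#'   fixation threshold, or \code{NA} if the run ended without fixation.
#' @export
time_to_fixation <- function(trajectory) {
  stopifnot(inherits(trajectory, "gd_trajectory"))
  trajectory$fixation_generation
}
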