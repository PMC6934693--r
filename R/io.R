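#' Build a simulation configuration from a JSON file and/or overrides
#'
#' The JSON schema mirrors [simulation_config()]: top-level keys
#' \code{variant}, \code{params} (with \code{e_W}, \code{f} and optionally
#' \code{h}, \code{e_W_induced}, \code{f_induced}, \code{e_D},
#' \code{e_D_induced}), \code{induction} (with \code{alpha},
#' \code{start_generation}, optional \code{enabled}), and optional
#' \code{initial_q_D}, \code{max_generations}, \code{fixation_threshold}.
#' Values in \code{overrides} (same structure, flat names such as
#' \code{"params.e_W"} or nested lists both accepted) take precedence over
#' the file. Defaults are applied for everything else: \code{h = 0.5},
#' \code{initial_q_D = 0.001}, threshold \code{0.99999}, cap 1,000
#' generations. Validation failures report the offending field path.
#'
#' @param path Path to a JSON config file, or \code{NULL} to build purely
#'   from \code{overrides}.
#' @param overrides Named list of values overriding the file.
#' @return A [simulation_config()] object.
#' @examples
#' load_config(overrides = list(variant = "standard",
#'                              params = list(e_W = 0.8, f = 0.7)))
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  raw <- .merge_config(raw, .unflatten(overrides))

  pr <- raw$params
  if (is.null(pr) || is.null(pr$e_W) || is.null(pr$f)) {
    stop("config: `params.e_W` and `params.f` are required", call. = FALSE)
  }
  params <- tryCatch(
    drive_params(e_W = pr$e_W, f = pr$f,
                 h = pr$h %||% 0.5,
                 e_W_induced = pr$e_W_induced %||% pr$e_W,
                 f_induced = pr$f_induced %||% pr$f,
                 e_D = pr$e_D %||% 0,
                 e_D_induced = pr$e_D_induced %||% 0),
    error = function(e) stop(sprintf("config: params.%s", conditionMessage(e)),
                             call. = FALSE))

  ind <- raw$induction
  induction <- if (is.null(ind)) {
    no_induction()
  } else {
    if (!is.null(ind$alpha) && is.null(ind$start_generation)) {
      stop("config: `induction.start_generation` is required when ",
           "`induction.alpha` is given", call. = FALSE)
    }
    tryCatch(
      induction_settings(alpha = ind$alpha %||% 0,
                         start_generation = ind$start_generation %||% 0L,
                         enabled = ind$enabled %||% TRUE),
      error = function(e) stop(sprintf("config: induction.%s",
                                       conditionMessage(e)), call. = FALSE))
  }

  tryCatch(
    simulation_config(params = params,
                      variant = raw$variant %||% "standard",
                      induction = induction,
                      initial_q_D = raw$initial_q_D %||% 0.001,
                      max_generations = raw$max_generations %||% 1000L,
                      fixation_threshold = raw$fixation_threshold %||% 0.99999),
    error = function(e) stop(sprintf("config: %s", conditionMessage(e)),
                             call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "params.e_W" = 0.8 -> list(params = list(e_W = 0.8))
.unflatten <- function(x) {
  out <- list()
  for (nm in names(x)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) {
      out[[nm]] <- x[[nm]]
    } else {
      out[[parts[1L]]] <- out[[parts[1L]]] %||% list()
      out[[parts[1L]]][[parts[2L]]] <- x[[nm]]
    }
  }
  out
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

.config_as_list <- function(config) {
  list(variant = config$variant,
       params = unclass(config$params),
       induction = unclass(config$induction),
       initial_q_D = config$initial_q_D,
       max_generations = config$max_generations,
       fixation_threshold = config$fixation_threshold)
}

.write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(tool = "revdrive",
                     version = as.character(utils::packageVersion("revdrive")),
                     config = .config_as_list(config)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# fixed-format numeric printing: 12 significant digits, byte-stable
.fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.12g", x))
}

#' Write a trajectory to CSV with a JSON manifest sidecar
#'
#' The CSV holds one row per generation with columns
#' \code{generation,q_D,q_W,induced}; frequencies are printed with 12
#' significant digits so round-trips preserve oracle-level comparisons.
#' A sidecar \code{<path>.json} records the full resolved configuration,
#' the outcome and the fixation generation, sufficient to reproduce the
#' file exactly.
#'
#' @param trajectory A [run_simulation()] result.
#' @param path Output CSV path.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "gd_trajectory"))
  df <- trajectory$states
  lines <- c("generation,q_D,q_W,induced",
             sprintf("%d,%s,%s,%d", df$generation,
                     .fmt_num(df$q_D), .fmt_num(df$q_W), df$induced))
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write %s: %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
  .write_manifest(trajectory$config, paste0(path, ".json"),
                  list(outcome = trajectory$outcome,
                       fixation_generation = trajectory$fixation_generation,
                       output = path))
  invisible(path)
}

#' Write an outcome grid to long-format CSV with a JSON manifest
#'
#' Columns:
#' \code{x_param,x_value,y_param,y_value,outcome,fixation_generation,pre_induction_loss}.
#' One row per grid cell; \code{fixation_generation} is empty for cells
#' that did not fix. The manifest \code{<path>.json} records the base
#' configuration and both axis specifications.
#'
#' @param grid A [grid_sweep()] result.
#' @param path Output CSV path.
#' @return Invisibly, the CSV path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "gd_outcome_grid"))
  df <- grid$cells
  lines <- c(
    "x_param,x_value,y_param,y_value,outcome,fixation_generation,pre_induction_loss",
    sprintf("%s,%s,%s,%s,%s,%s,%d", df$x_param, .fmt_num(df$x_value),
            df$y_param, .fmt_num(df$y_value), df$outcome,
            ifelse(is.na(df$fixation_generation), "",
                   as.character(df$fixation_generation)),
            as.integer(df$pre_induction_loss)))
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write %s: %s", path,
                                            conditionMessage(e)),
                                    call. = FALSE))
  axes <- function(a) list(parameter = a$parameter, from = a$from,
                           to = a$to, n = a$n)
  .write_manifest(grid$base_config, paste0(path, ".json"),
                  list(x_axis = axes(grid$x_axis),
                       y_axis = axes(grid$y_axis), output = path))
  invisible(path)
}
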