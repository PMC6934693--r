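#' Gene drive model parameters
#'
#' Bundles every parameter of the frequency-based gene drive model for one
#' scenario. The baseline parameters are the homing efficiency \code{e_W}
#' (probability that the drive both cleaves the wild-type target and is
#' copied across by homology-directed repair), the relative fitness \code{f}
#' of the drive homozygote (wild type = 1), and the degree of dominance
#' \code{h} used to form the heterozygote fitness \code{(1 - h) + f * h}.
#' The induced parameters take effect once an external signal is applied
#' (see [induction_settings()]): \code{e_W_induced} and \code{f_induced}
#' replace their baseline counterparts in the responding fraction of the
#' population, while \code{e_D} (basal, "leaky") and \code{e_D_induced}
#' (post-signal) are the self-cleavage rates of the self-excising drive.
#'
#' @param e_W Drive conversion efficiency, in \[0, 1\].
#' @param f Relative fitness of the drive homozygote, in \[0, 1\].
#' @param h Degree of dominance, in \[0, 1\]. Default 0.5 (codominance).
#' @param e_W_induced Post-induction drive efficiency. Defaults to \code{e_W}.
#' @param f_induced Post-induction drive-homozygote fitness. Defaults to \code{f}.
#' @param e_D Basal (pre-induction) self-cleavage probability. Default 0.
#' @param e_D_induced Post-induction self-cleavage probability. Default 0.
#' @return An object of class \code{"drive_params"} (a named list).
#' @examples
#' drive_params(e_W = 0.8, f = 0.7)
#' @export
drive_params <- function(e_W, f, h = 0.5,
                         e_W_induced = e_W, f_induced = f,
                         e_D = 0, e_D_induced = 0) {
  p <- list(e_W = e_W, f = f, h = h,
            e_W_induced = e_W_induced, f_induced = f_induced,
            e_D = e_D, e_D_induced = e_D_induced)
  for (nm in names(p)) .check_prob(p[[nm]], nm)
  structure(p, class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat("Gene drive parameters:\n")
  cat(sprintf("  e_W = %g, f = %g, h = %g\n", x$e_W, x$f, x$h))
  cat(sprintf("  induced: e_W' = %g, f' = %g\n", x$e_W_induced, x$f_induced))
  cat(sprintf("  self-cleavage: e_D = %g, e_D' = %g\n", x$e_D, x$e_D_induced))
  invisible(x)
}

#' External induction signal settings
#'
#' Describes the external inducing signal: \code{alpha} is the fraction of
#' individuals that respond to the signal in each generation once it is
#' applied, and \code{start_generation} the generation at which it is first
#' applied. Before \code{start_generation} the effective response fraction is
#' exactly 0; from \code{start_generation} onward the signal is applied
#' continuously at the same level, so the effective fraction is exactly
#' \code{alpha} (the shift completes within one generation). The transition
#' producing generation \code{start_generation + 1} is the first induced one.
#'
#' @param alpha Fraction of responding individuals, in \[0, 1\].
#' @param start_generation Non-negative integer generation at which the
#'   signal is first applied.
#' @param enabled Logical; set \code{FALSE} to model the uninduced system
#'   regardless of \code{alpha}.
#' @return An object of class \code{"induction_settings"}.
#' @examples
#' induction_settings(alpha = 0.9, start_generation = 10)
#' no_induction()
#' @export
induction_settings <- function(alpha, start_generation, enabled = TRUE) {
  .check_prob(alpha, "alpha")
  if (!is.numeric(start_generation) || length(start_generation) != 1L ||
      is.na(start_generation) || start_generation < 0 ||
      start_generation != floor(start_generation)) {
    stop("`start_generation` must be a single non-negative integer",
         call. = FALSE)
  }
  structure(list(alpha = alpha,
                 start_generation = as.integer(start_generation),
                 enabled = isTRUE(enabled)),
            class = "induction_settings")
}

#' @rdname induction_settings
#' @export
no_induction <- function() {
  induction_settings(alpha = 0, start_generation = 0L, enabled = FALSE)
}

#' @export
print.induction_settings <- function(x, ...) {
  if (!x$enabled) {
    cat("Induction: disabled\n")
  } else {
    cat(sprintf("Induction: alpha = %g from generation %d onward\n",
                x$alpha, x$start_generation))
  }
  invisible(x)
}

#' Model variant tags
#'
#' The four single-generation update rules the package implements. Each tag
#' selects one recursion and the subset of [drive_params()] it reads.
#'
#' @return Character vector of valid variant tags.
#' @export
model_variants <- function() {
  c("standard", "inducible_efficiency", "inducible_fitness", "self_cleaving")
}

.match_variant <- function(variant) {
  match.arg(variant, model_variants())
}

#' Heterozygote fitness under partial dominance
#'
#' The drive homozygote has relative fitness \code{f}; a drive/wild-type
#' heterozygote whose drive failed to convert has fitness
#' \code{(1 - h) + f * h}, interpolating between wild type (\code{h = 0})
#' and the drive homozygote (\code{h = 1}). With the default \code{h = 0.5}
#' the fitness effect is codominant.
#'
#' @param f Relative fitness of the drive homozygote, in \[0, 1\].
#' @param h Degree of dominance, in \[0, 1\].
#' @return The heterozygote relative fitness, between \code{min(f, 1)} and 1.
#' @examples
#' het_fitness(0.7, 0.5)  # 0.85
#' @export
het_fitness <- function(f, h) {
  .check_prob(f, "f")
  .check_prob(h, "h")
  (1 - h) + f * h
}

#' Effective parameters under a partially responding population
#'
#' Once the external signal is applied, a fraction \code{alpha} of the
#' population carries the induced parameter values and the remaining
#' \code{1 - alpha} the baseline ones; the population-level recursion uses
#' the mixture values. Before \code{start_generation} (or when induction is
#' disabled) the effective mixing fraction is exactly 0.
#'
#' @param params A [drive_params()] object.
#' @param induction An [induction_settings()] object (or \code{NULL} for no
#'   induction).
#' @param generation The generation index of the parental population; the
#'   transition it parameterises produces generation \code{generation + 1}.
#' @return A list with components \code{alpha} (the effective mixing
#'   fraction), \code{e_eff} = alpha * e_W' + (1 - alpha) * e_W,
#'   \code{f_eff} = alpha * f' + (1 - alpha) * f, and
#'   \code{E} = (1 - alpha) * e_D + alpha * e_D'.
#' @examples
#' p <- drive_params(e_W = 0.8, f = 0.7, e_W_induced = 0.1)
#' effective_params(p, induction_settings(0.9, 10), generation = 9)$e_eff  # 0.8
#' effective_params(p, induction_settings(0.9, 10), generation = 10)$e_eff # 0.17
#' @export
effective_params <- function(params, induction = NULL, generation = 0L) {
  stopifnot(inherits(params, "drive_params"))
  if (generation < 0) stop("`generation` must be non-negative", call. = FALSE)
  a <- 0
  if (!is.null(induction) && inherits(induction, "induction_settings") &&
      induction$enabled && generation >= induction$start_generation) {
    a <- induction$alpha
  }
  list(alpha = a,
       e_eff = a * params$e_W_induced + (1 - a) * params$e_W,
       f_eff = a * params$f_induced + (1 - a) * params$f,
       E = (1 - a) * params$e_D + a * params$e_D_induced)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# classed condition for the all-lethal / zero-mean-fitness corner
.degenerate_error <- function(generation = NA_integer_) {
  stop(structure(class = c("gd_degenerate_error", "error", "condition"),
                 list(message = paste0(
                        "degenerate population: mean fitness is zero",
                        if (!is.na(generation))
                          sprintf(" (at generation %d)", generation)),
                      call = NULL,
                      generation = generation)))
}

.MEAN_FITNESS_TOL <- 1e-12
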