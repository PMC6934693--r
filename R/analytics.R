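#' Invasion growth factor of a rare drive allele
#'
#' Linearising the recursion at \code{q_D -> 0} gives the per-generation
#' multiplication factor of rare drive alleles,
#' \deqn{\lambda = 2 f_{eff} e_{eff} + ((1-h) + f_{eff} h)(1 - e_{eff})}
#' for the standard and inducible variants (with the variant's effective
#' parameters), and
#' \deqn{\lambda = (1 - E)\,[\,2 f e_W + ((1-h) + f h)(1 - e_W)\,]}
#' for the self-cleaving variant, where the leading factor removes the
#' drive-allele mass lost to self-excision. \eqn{\lambda > 1} predicts that
#' the drive invades; \eqn{\lambda < 1} that it is lost. This linearisation
#' is a diagnostic derived here from the recursions; it is distinct from the
#' simpler favorability heuristic (see [heuristic_favorability()]), with
#' which it coincides on the boundary only at \code{e_W = 1}, \code{h = 0.5}.
#'
#' @inheritParams mean_fitness
#' @return The scalar growth factor \eqn{\lambda \ge 0}.
#' @examples
#' invasion_growth_factor(drive_params(e_W = 0.8, f = 0.7))  # 1.29
#' @export
invasion_growth_factor <- function(params, variant = "standard", eff = NULL) {
  stopifnot(inherits(params, "drive_params"))
  variant <- .match_variant(variant)
  if (is.null(eff)) eff <- effective_params(params, NULL, 0L)
  if (variant == "self_cleaving") {
    fh <- (1 - params$h) + params$f * params$h
    (1 - eff$E) * (2 * params$f * params$e_W + fh * (1 - params$e_W))
  } else {
    e <- if (variant == "inducible_efficiency") eff$e_eff else params$e_W
    f <- if (variant == "inducible_fitness") eff$f_eff else params$f
    fh <- (1 - params$h) + f * params$h
    2 * f * e + fh * (1 - e)
  }
}

#' Drive favorability heuristic f(e_W + 1) > 1
#'
#' A rule of thumb from earlier individual-based drive modeling: the drive
#' is favored to take over the population when the product of its
#' homozygote fitness and \code{e_W + 1} exceeds 1. Exactly 1 is reported
#' as the boundary rather than assigned to either side.
#'
#' @param f Relative fitness of the drive homozygote.
#' @param e_W Drive conversion efficiency.
#' @return A list with \code{value} = \code{f * (e_W + 1)} and
#'   \code{status} in \code{c("favored", "boundary", "not_favored")}.
#' @examples
#' heuristic_favorability(0.95, 1)  # value 1.9, favored
#' @export
heuristic_favorability <- function(f, e_W) {
  .check_prob(f, "f")
  .check_prob(e_W, "e_W")
  v <- f * (e_W + 1)
  list(value = v,
       status = if (v > 1) "favored" else if (v < 1) "not_favored" else "boundary")
}

#' Invasion report for one parameter set
#'
#' Combines the linearised growth factor and the favorability heuristic
#' into one diagnostic record. The two are reported side by side, never
#' conflated: the growth factor is derived from this package's recursions,
#' the heuristic is the classic \code{f(e_W + 1) > 1} rule.
#'
#' @inheritParams invasion_growth_factor
#' @return An object of class \code{"invasion_report"}: a list with
#'   \code{growth_factor}, \code{favored} (growth factor > 1),
#'   \code{heuristic_value}, \code{heuristic_status}, plus the variant and
#'   a parameter echo.
#' @examples
#' invasion_report(drive_params(e_W = 0.8, f = 0.7))
#' @export
invasion_report <- function(params, variant = "standard", eff = NULL) {
  lambda <- invasion_growth_factor(params, variant, eff)
  heur <- heuristic_favorability(params$f, params$e_W)
  structure(list(growth_factor = lambda,
                 favored = lambda > 1,
                 heuristic_value = heur$value,
                 heuristic_status = heur$status,
                 variant = .match_variant(variant),
                 params = params),
            class = "invasion_report")
}

#' @export
print.invasion_report <- function(x, ...) {
  cat(sprintf("Invasion report (%s model)\n", x$variant))
  cat(sprintf("  linearised growth factor lambda = %.6g (%s)\n",
              x$growth_factor,
              if (x$favored) "drive invades" else "drive is lost"))
  cat(sprintf("  heuristic f(e_W + 1) = %.6g (%s)\n",
              x$heuristic_value, x$heuristic_status))
  invisible(x)
}
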