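#' Single-generation allele-frequency updates
#'
#' Deterministic recursions for the drive allele frequency \code{q_D} under
#' random mating, non-overlapping generations and an infinite population,
#' with no resistance alleles of any kind. Heterozygotes are converted to
#' drive homozygotes with probability \code{e_W} (immediate conversion);
#' failed conversion leaves a heterozygote with fitness
#' \code{(1 - h) + f * h}. Writing \code{q_W = 1 - q_D}, the standard
#' recursion is
#' \deqn{q_D' = \frac{f (q_D^2 + 2 q_W q_D e_W) + ((1-h)+fh)\, q_W q_D (1-e_W)}
#'             {1 - (1-f)(q_D^2 + 2 q_W q_D e_W) - (h - fh)\, 2 q_W q_D (1-e_W)}}
#' whose denominator is the population mean fitness.
#'
#' \code{step_inducible_efficiency()} is the same recursion with \code{e_W}
#' replaced everywhere by the effective efficiency \code{e_eff};
#' \code{step_inducible_fitness()} replaces \code{f} everywhere (including
#' inside the heterozygote fitness) by \code{f_eff}. Both collapse to
#' \code{step_standard()} when the effective value equals the baseline.
#'
#' \code{step_self_cleaving()} adds self-excision of the drive cassette at
#' rate \code{E} per allele-carrying cleavage opportunity. In a heterozygote
#' the drive and the wild-type target are attacked independently: dual
#' cleavage is lethal (probability \code{E * e_W}), cleavage of only the
#' drive restores a wild-type homozygote (\code{E * (1 - e_W)}), cleavage of
#' only the target converts to a drive homozygote (\code{(1 - E) * e_W}),
#' and no cleavage leaves the heterozygote (\code{(1 - E) * (1 - e_W)}).
#' A drive homozygote is lethal when both alleles self-cleave
#' (\code{E^2}), and otherwise remains a drive homozygote (repair uses the
#' homologous drive allele as template). With \code{E = 0} the update equals
#' \code{step_standard()} exactly.
#'
#' All four functions are vectorised over \code{q_D}.
#'
#' @param q_D Drive allele frequency (numeric vector in \[0, 1\]).
#' @param params A [drive_params()] object.
#' @param e_eff Effective drive efficiency (mixture of \code{e_W} and
#'   \code{e_W_induced}; see [effective_params()]).
#' @param f_eff Effective drive-homozygote fitness.
#' @param E Effective self-cleavage probability.
#' @return The next-generation drive allele frequency, in \[0, 1\].
#'   An error of class \code{"gd_degenerate_error"} is signalled when the
#'   mean fitness is zero (to numerical tolerance), e.g. the all-lethal
#'   corner \code{q_D = 1}, \code{E = 1} of the self-cleaving model.
#' @examples
#' p <- drive_params(e_W = 0.8, f = 0.7)
#' step_standard(0.001, p)
#' step_self_cleaving(0.5, p, E = 0.6)
#' @name drive_step_rules
NULL

# shared core: standard-form recursion with arbitrary (e, f) values
.step_efh <- function(q_D, e, f, h) {
  q_W <- 1 - q_D
  conv <- q_D^2 + 2 * q_W * q_D * e          # drive homozygotes after conversion
  het  <- q_W * q_D * (1 - e)                 # surviving heterozygotes (one orientation)
  fh   <- (1 - h) + f * h
  num <- f * conv + fh * het
  den <- 1 - (1 - f) * conv - (h - f * h) * 2 * het
  if (any(den <= .MEAN_FITNESS_TOL)) .degenerate_error()
  # the ratio is in [0, 1] exactly; clamp away 1-ulp round-off
  pmin(pmax(num / den, 0), 1)
}

#' @rdname drive_step_rules
#' @export
step_standard <- function(q_D, params) {
  stopifnot(inherits(params, "drive_params"))
  .step_efh(q_D, params$e_W, params$f, params$h)
}

#' @rdname drive_step_rules
#' @export
step_inducible_efficiency <- function(q_D, params, e_eff) {
  stopifnot(inherits(params, "drive_params"))
  .check_prob(e_eff, "e_eff")
  .step_efh(q_D, e_eff, params$f, params$h)
}

#' @rdname drive_step_rules
#' @export
step_inducible_fitness <- function(q_D, params, f_eff) {
  stopifnot(inherits(params, "drive_params"))
  .check_prob(f_eff, "f_eff")
  .step_efh(q_D, params$e_W, f_eff, params$h)
}

# surviving genotype pools of the self-cleaving model; also used by mean_fitness
.self_cleaving_pools <- function(q_D, e_W, E) {
  q_W <- 1 - q_D
  list(
    DD = q_D^2 * (1 - E^2) + 2 * q_W * q_D * (1 - E) * e_W,
    DW = 2 * q_W * q_D * (1 - E) * (1 - e_W),
    WW = q_W^2 + 2 * q_W * q_D * E * (1 - e_W),
    lethal = q_D^2 * E^2 + 2 * q_W * q_D * E * e_W
  )
}

#' @rdname drive_step_rules
#' @export
step_self_cleaving <- function(q_D, params, E) {
  stopifnot(inherits(params, "drive_params"))
  .check_prob(E, "E")
  if (E == 0) return(.step_efh(q_D, params$e_W, params$f, params$h))
  pools <- .self_cleaving_pools(q_D, params$e_W, E)
  fh <- (1 - params$h) + params$f * params$h
  den <- params$f * pools$DD + fh * pools$DW + pools$WW
  if (any(den <= .MEAN_FITNESS_TOL)) .degenerate_error()
  pmin(pmax((params$f * pools$DD + fh * pools$DW / 2) / den, 0), 1)
}

#' Mean fitness of the parental generation
#'
#' The denominator of the selected variant's recursion: the fitness-weighted
#' mass of surviving post-drive-action genotypes. Equals 1 when the drive
#' carries no fitness cost and no lethality occurs; equals 0 in the
#' all-lethal corner of the self-cleaving model. Unlike the step functions,
#' this does not signal on zero — callers decide how to treat it.
#'
#' @inheritParams drive_step_rules
#' @param variant One of [model_variants()].
#' @param eff Effective parameter bundle from [effective_params()]; only the
#'   component the variant reads is used. Defaults to the uninduced bundle.
#' @return Non-negative scalar (vectorised over \code{q_D}).
#' @examples
#' p <- drive_params(e_W = 0.8, f = 0.7)
#' mean_fitness(0.001, p, "standard")
#' @export
mean_fitness <- function(q_D, params, variant = "standard", eff = NULL) {
  stopifnot(inherits(params, "drive_params"))
  variant <- .match_variant(variant)
  if (is.null(eff)) eff <- effective_params(params, NULL, 0L)
  e <- switch(variant, inducible_efficiency = eff$e_eff, params$e_W)
  f <- switch(variant, inducible_fitness = eff$f_eff, params$f)
  E <- switch(variant, self_cleaving = eff$E, 0)
  pools <- .self_cleaving_pools(q_D, e, E)
  fh <- (1 - params$h) + f * params$h
  f * pools$DD + fh * pools$DW + pools$WW
}

#' Dispatch one generation of the selected model variant
#'
#' Applies the variant's update rule using the effective parameters for the
#' current generation. This is the transition used by [run_simulation()].
#'
#' @inheritParams mean_fitness
#' @return Next-generation drive allele frequency.
#' @examples
#' p <- drive_params(e_W = 0.8, f = 0.7, e_W_induced = 0.1)
#' ind <- induction_settings(alpha = 0.9, start_generation = 10)
#' drive_step(0.013, p, "inducible_efficiency", effective_params(p, ind, 10))
#' @export
drive_step <- function(q_D, params, variant = "standard", eff = NULL) {
  variant <- .match_variant(variant)
  if (is.null(eff)) eff <- effective_params(params, NULL, 0L)
  switch(variant,
         standard = step_standard(q_D, params),
         inducible_efficiency = step_inducible_efficiency(q_D, params, eff$e_eff),
         inducible_fitness = step_inducible_fitness(q_D, params, eff$f_eff),
         self_cleaving = step_self_cleaving(q_D, params, eff$E))
}
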