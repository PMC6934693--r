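#' Genotype-enumeration oracle
#'
#' Independent brute-force re-derivation of each recursion. Starting from
#' random-union genotype frequencies (q_D^2, 2 q_W q_D, q_W^2), drive action
#' is applied per genotype as an explicit probability tree rather than
#' through the closed-form algebra, so the result can serve as a
#' ground-truth cross-check of the step functions.
#'
#' In a heterozygote the self-cleavage module (rate \code{E}) and the
#' homing reaction (rate \code{e}) act independently, giving four fates:
#' both cleaved — lethal (\code{E * e}); only the drive cleaved — repaired
#' to a wild-type homozygote (\code{E * (1 - e)}); only the target cleaved —
#' converted to a drive homozygote (\code{(1 - E) * e}); neither —
#' heterozygote retained (\code{(1 - E) * (1 - e)}). A drive homozygote is
#' lethal when both its alleles self-cleave (\code{E^2}) and otherwise
#' remains a drive homozygote. For the non-self-cleaving variants
#' \code{E = 0}. Fitness weights are \code{f} for the drive homozygote,
#' \code{(1 - h) + f h} for the heterozygote and 1 for wild type.
#'
#' @param q_D Drive allele frequency (single value).
#' @param params A [drive_params()] object.
#' @param variant One of [model_variants()].
#' @param eff Effective parameter bundle from [effective_params()];
#'   defaults to the uninduced bundle.
#' @return An object of class \code{"genotype_pool"}: a list with masses
#'   \code{DD}, \code{DW}, \code{WW}, \code{lethal} (summing to 1) and
#'   fitness weights \code{fitness_DD}, \code{fitness_DW},
#'   \code{fitness_WW}.
#' @examples
#' p <- drive_params(e_W = 1, f = 1)
#' enumerate_pool(0.5, p)  # all heterozygotes converted: DD = 0.75
#' @export
enumerate_pool <- function(q_D, params, variant = "standard", eff = NULL) {
  stopifnot(inherits(params, "drive_params"))
  .check_prob(q_D, "q_D")
  variant <- .match_variant(variant)
  if (is.null(eff)) eff <- effective_params(params, NULL, 0L)
  e <- switch(variant, inducible_efficiency = eff$e_eff, params$e_W)
  f <- switch(variant, inducible_fitness = eff$f_eff, params$f)
  E <- switch(variant, self_cleaving = eff$E, 0)
  q_W <- 1 - q_D

  # random union of gametes
  g_DD <- q_D^2
  g_DW <- 2 * q_W * q_D
  g_WW <- q_W^2

  # per-genotype fate tree
  DD <- g_DD * (1 - E^2) +        # homozygote survives unless both alleles excised
        g_DW * (1 - E) * e        # target cleaved, drive intact: converted
  DW <- g_DW * (1 - E) * (1 - e)  # neither reaction fired
  WW <- g_WW +
        g_DW * E * (1 - e)        # drive excised, target intact: repaired to WT
  lethal <- g_DD * E^2 +
            g_DW * E * e          # dual cleavage

  structure(list(DD = DD, DW = DW, WW = WW, lethal = lethal,
                 fitness_DD = f,
                 fitness_DW = (1 - params$h) + f * params$h,
                 fitness_WW = 1),
            class = "genotype_pool")
}

#' @export
print.genotype_pool <- function(x, ...) {
  cat("Post-drive-action genotype pool:\n")
  cat(sprintf("  DD: %.6g (fitness %g)\n", x$DD, x$fitness_DD))
  cat(sprintf("  DW: %.6g (fitness %g)\n", x$DW, x$fitness_DW))
  cat(sprintf("  WW: %.6g (fitness %g)\n", x$WW, x$fitness_WW))
  cat(sprintf("  lethal: %.6g\n", x$lethal))
  invisible(x)
}

#' Next-generation drive frequency from an enumerated pool
#'
#' Fitness-weighted allele count over the surviving genotypes:
#' \code{(w_DD * DD + w_DW * DW / 2) / (w_DD * DD + w_DW * DW + w_WW * WW)}.
#' Reproduces the closed-form recursions by construction.
#'
#' @param pool A [enumerate_pool()] result.
#' @return Drive allele frequency after selection, in \[0, 1\]. Signals a
#'   \code{"gd_degenerate_error"} when no surviving fitness-weighted mass
#'   remains.
#' @export
oracle_next_frequency <- function(pool) {
  stopifnot(inherits(pool, "genotype_pool"))
  den <- pool$fitness_DD * pool$DD + pool$fitness_DW * pool$DW +
         pool$fitness_WW * pool$WW
  if (den <= .MEAN_FITNESS_TOL) .degenerate_error()
  (pool$fitness_DD * pool$DD + pool$fitness_DW * pool$DW / 2) / den
}

#' One Wright-Fisher generation around the deterministic step
#'
#' Finite-population check of the infinite-population recursions: computes
#' the deterministic next-generation frequency via the enumeration oracle,
#' then binomially samples \code{2 * population_size} alleles at that
#' frequency. The mean over replicates converges to the deterministic value
#' as the population grows.
#'
#' @inheritParams enumerate_pool
#' @param population_size Number of diploid individuals (>= 2).
#' @param seed Optional integer seed for reproducibility; when supplied the
#'   RNG state is restored afterwards.
#' @return Sampled drive allele frequency.
#' @examples
#' p <- drive_params(e_W = 0.8, f = 0.7)
#' wright_fisher_step(0.5, 1e4, p, seed = 1)
#' @export
wright_fisher_step <- function(q_D, population_size, params,
                               variant = "standard", eff = NULL,
                               seed = NULL) {
  if (!is.numeric(population_size) || population_size < 2) {
    stop("`population_size` must be >= 2", call. = FALSE)
  }
  q_next <- oracle_next_frequency(enumerate_pool(q_D, params, variant, eff))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_alleles <- 2 * floor(population_size)
  stats::rbinom(1L, n_alleles, q_next) / n_alleles
}
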