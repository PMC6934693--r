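# shared helpers for the revdrive test suite

# one random parameter set spanning the full legal ranges
random_params <- function() {
  drive_params(e_W = runif(1), f = runif(1), h = runif(1),
               e_W_induced = runif(1), f_induced = runif(1),
               e_D = runif(1), e_D_induced = runif(1))
}

# effective bundle at a random induction level, already switched on
random_eff <- function(params) {
  effective_params(params, induction_settings(runif(1), 0L), generation = 0L)
}

# trajectory shortcut used throughout
run_scenario <- function(e_W, f, variant = "standard", e_W_induced = e_W,
                         f_induced = f, e_D = 0, e_D_induced = 0,
                         alpha = NULL, start_generation = 10L, ...) {
  params <- drive_params(e_W = e_W, f = f, e_W_induced = e_W_induced,
                         f_induced = f_induced, e_D = e_D,
                         e_D_induced = e_D_induced)
  induction <- if (is.null(alpha)) no_induction() else
    induction_settings(alpha, start_generation)
  run_simulation(simulation_config(params, variant, induction, ...))
}
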