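# single-generation update rules and their algebraic properties

test_that("heterozygote fitness interpolates between wild type and homozygote", {
  expect_equal(het_fitness(1, 0.5), 1)
  expect_equal(het_fitness(0, 0.5), 0.5)
  expect_equal(het_fitness(0.7, 0.5), 0.85)
  expect_equal(het_fitness(0.3, 0), 1)    # fully recessive cost
  expect_equal(het_fitness(0.3, 1), 0.3)  # fully dominant cost
  expect_error(het_fitness(1.2, 0.5), "must be a single number")
})

test_that("effective parameters mix baseline and induced values by alpha", {
  p <- drive_params(e_W = 0.8, f = 0.7, e_W_induced = 0.1, f_induced = 0.4,
                    e_D = 0.05, e_D_induced = 0.9)
  ind <- induction_settings(alpha = 0.9, start_generation = 10)

  pre <- effective_params(p, ind, generation = 9)
  expect_identical(pre$alpha, 0)
  expect_identical(pre$e_eff, p$e_W)
  expect_identical(pre$f_eff, p$f)
  expect_identical(pre$E, p$e_D)

  post <- effective_params(p, ind, generation = 10)
  expect_equal(post$e_eff, 0.9 * 0.1 + 0.1 * 0.8)  # 0.17
  expect_equal(post$f_eff, 0.9 * 0.4 + 0.1 * 0.7)  # 0.43
  expect_equal(post$E, 0.1 * 0.05 + 0.9 * 0.9)

  # full response and disabled induction
  full <- effective_params(p, induction_settings(1, 0), 0)
  expect_equal(full$e_eff, 0.1)
  off <- effective_params(p, induction_settings(0.9, 0, enabled = FALSE), 50)
  expect_identical(off$alpha, 0)
})

test_that("standard step reproduces hand-derived values", {
  # exact values computed independently by genotype enumeration in rational
  # arithmetic
  p <- drive_params(e_W = 0.8, f = 0.7)
  expect_equal(step_standard(0.001, p), 0.0012901063478022899, tolerance = 1e-14)
  expect_equal(mean_fitness(0.001, p), 0.99946024, tolerance = 1e-14)

  # perfect drive, no cost: all heterozygotes converted
  expect_equal(step_standard(0.5, drive_params(e_W = 1, f = 1)), 0.75)

  # absent allele stays absent; fixed allele stays fixed
  expect_equal(step_standard(0, p), 0)
  expect_equal(step_standard(1, p), 1)
})

test_that("neutral parameter choices are fixed points", {
  p_neutral <- drive_params(e_W = 0, f = 1)
  for (q in c(0.001, 0.1, 0.5, 0.9)) {
    expect_equal(step_standard(q, p_neutral), q)
    expect_equal(step_inducible_efficiency(q, drive_params(1, 1), e_eff = 0), q)
    expect_equal(step_inducible_fitness(q, drive_params(0, 0.2), f_eff = 1), q)
  }
  expect_equal(mean_fitness(0.3, drive_params(e_W = 0.6, f = 1)), 1)
})

test_that("inducible variants collapse to the standard model when uninduced", {
  qs <- c(0, 0.001, 0.01, 0.1, 0.5, 0.9, 0.99, 1)
  p <- drive_params(e_W = 0.8, f = 0.7, e_W_induced = 0.1, f_induced = 0.4,
                    e_D = 0, e_D_induced = 0)
  std <- step_standard(qs, p)
  # alpha = 0 routes
  eff0 <- effective_params(p, no_induction(), 0)
  expect_identical(step_inducible_efficiency(qs, p, eff0$e_eff), std)
  expect_identical(step_inducible_fitness(qs, p, eff0$f_eff), std)
  expect_identical(step_self_cleaving(qs, p, eff0$E), std)
  # induced value equal to the baseline
  p_same <- drive_params(e_W = 0.8, f = 0.7, e_W_induced = 0.8, f_induced = 0.7)
  eff1 <- effective_params(p_same, induction_settings(0.9, 0), 0)
  expect_identical(step_inducible_efficiency(qs, p_same, eff1$e_eff), std)
  expect_identical(step_inducible_fitness(qs, p_same, eff1$f_eff), std)
})

test_that("self-cleaving step matches exact genotype bookkeeping", {
  p <- drive_params(e_W = 0.8, f = 0.7)
  # exact rational-arithmetic value at q_D = 0.5, E = 0.6
  expect_equal(step_self_cleaving(0.5, p, E = 0.6), 0.4242957746478873,
               tolerance = 1e-14)
  # all-lethal corner: every individual carries two excised drive alleles
  expect_error(step_self_cleaving(1, p, E = 1), class = "gd_degenerate_error")
  expect_equal(mean_fitness(1, p, "self_cleaving",
                            list(e_eff = 0.8, f_eff = 0.7, E = 1)), 0)
})

test_that("every step maps the unit interval into itself", {
  set.seed(42)
  qs <- c(0, 10^seq(-3, 0, length.out = 20), 1)
  for (rep in 1:50) {
    p <- random_params()
    eff <- random_eff(p)
    for (v in model_variants()) {
      q2 <- tryCatch(drive_step(qs, p, v, eff),
                     gd_degenerate_error = function(e) NULL)
      if (!is.null(q2)) {
        expect_true(all(q2 >= 0 & q2 <= 1),
                    info = sprintf("variant %s", v))
      }
    }
  }
})

test_that("closed-form limit holds at e_W = 1, f = 1: 1 - q' = (1 - q)^2", {
  p <- drive_params(e_W = 1, f = 1)
  q <- 0.001
  for (g in 1:13) {
    q <- step_standard(q, p)
    expect_equal(1 - q, (1 - 0.001)^(2^g), tolerance = 1e-12)
  }
})

test_that("drive frequency gain is monotone in e_W when drive is cost-free", {
  e_grid <- seq(0, 1, by = 0.05)
  for (q in c(0.01, 0.3, 0.7)) {
    vals <- vapply(e_grid,
                   function(e) step_standard(q, drive_params(e_W = e, f = 1)),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-15))
    # analytic slope dq'/de_W = q_W q_D at f = 1
    expect_equal((vals[2] - vals[1]) / 0.05, q * (1 - q), tolerance = 1e-2)
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(drive_params(e_W = 1.5, f = 0.7), "e_W")
  expect_error(drive_params(e_W = 0.8, f = -0.1), "f")
  expect_error(drive_params(e_W = 0.8, f = 0.7, h = 2), "h")
  expect_error(induction_settings(alpha = 1.1, start_generation = 10), "alpha")
  expect_error(induction_settings(alpha = 0.5, start_generation = -1),
               "start_generation")
  expect_error(induction_settings(alpha = 0.5, start_generation = 2.5),
               "start_generation")
})
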