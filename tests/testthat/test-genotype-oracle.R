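# enumeration oracle and finite-population cross-checks

test_that("enumerated pools match the drive-action probability tree", {
  p <- drive_params(e_W = 1, f = 1)
  pool <- enumerate_pool(0.5, p)
  expect_equal(pool$DD, 0.75)  # all heterozygotes converted
  expect_equal(pool$DW, 0)
  expect_equal(pool$WW, 0.25)
  expect_equal(pool$lethal, 0)

  # full self-cleavage with perfect homing: heterozygotes and homozygotes
  # all carry a cleaved drive plus a cleaved target -> lethal
  pool2 <- enumerate_pool(0.5, p, "self_cleaving",
                          list(e_eff = 1, f_eff = 1, E = 1))
  expect_equal(pool2$DD, 0)
  expect_equal(pool2$WW, 0.25)
  expect_equal(pool2$lethal, 0.75)

  # exact rational-arithmetic pool at q = 0.5, e_W = 0.8, E = 0.6
  p3 <- drive_params(e_W = 0.8, f = 0.7)
  pool3 <- enumerate_pool(0.5, p3, "self_cleaving",
                          list(e_eff = 0.8, f_eff = 0.7, E = 0.6))
  expect_equal(pool3$DD, 0.32, tolerance = 1e-14)
  expect_equal(pool3$DW, 0.04, tolerance = 1e-14)
  expect_equal(pool3$WW, 0.31, tolerance = 1e-14)
  expect_equal(pool3$lethal, 0.33, tolerance = 1e-14)
})

test_that("pool masses always sum to one", {
  set.seed(7)
  for (rep in 1:200) {
    p <- random_params()
    eff <- random_eff(p)
    v <- sample(model_variants(), 1)
    pool <- enumerate_pool(runif(1), p, v, eff)
    expect_equal(pool$DD + pool$DW + pool$WW + pool$lethal, 1,
                 tolerance = 1e-12)
    expect_true(all(c(pool$DD, pool$DW, pool$WW, pool$lethal) >= 0))
  }
})

test_that("oracle agrees with every closed-form step across random draws", {
  set.seed(20240901)
  n_draws <- 10000L
  worst <- 0
  degenerate <- 0L
  for (k in seq_len(n_draws)) {
    p <- random_params()
    eff <- random_eff(p)
    v <- model_variants()[(k %% 4L) + 1L]
    q <- runif(1)
    closed <- tryCatch(drive_step(q, p, v, eff),
                       gd_degenerate_error = function(e) NA_real_)
    oracle <- tryCatch(oracle_next_frequency(enumerate_pool(q, p, v, eff)),
                       gd_degenerate_error = function(e) NA_real_)
    expect_identical(is.na(closed), is.na(oracle))
    if (is.na(closed)) degenerate <- degenerate + 1L
    else worst <- max(worst, abs(closed - oracle))
  }
  expect_lte(worst, 1e-12)
  expect_lt(degenerate, n_draws / 10)  # degeneracy is a rare corner
})

test_that("oracle signals degeneracy when no surviving mass remains", {
  p <- drive_params(e_W = 1, f = 1)
  pool <- enumerate_pool(1, p, "self_cleaving",
                         list(e_eff = 1, f_eff = 1, E = 1))
  expect_equal(pool$lethal, 1)
  expect_error(oracle_next_frequency(pool), class = "gd_degenerate_error")
})

test_that("Wright-Fisher sampling is absorbing at 0, seeded, and unbiased", {
  p <- drive_params(e_W = 0.8, f = 0.7)
  expect_equal(wright_fisher_step(0, 1000, p, seed = 1), 0)

  # reproducibility under a fixed seed
  a <- wright_fisher_step(0.5, 1e4, p, seed = 99)
  b <- wright_fisher_step(0.5, 1e4, p, seed = 99)
  expect_identical(a, b)

  # neutral parameters, huge population: stays within 5 SE of 0.5
  pn <- drive_params(e_W = 0, f = 1)
  se <- sqrt(0.5 * 0.5 / (2 * 1e6))
  expect_lt(abs(wright_fisher_step(0.5, 1e6, pn, seed = 3) - 0.5), 5 * se)
})

test_that("Wright-Fisher means converge to the deterministic step", {
  p <- drive_params(e_W = 0.8, f = 0.7)
  det <- oracle_next_frequency(enumerate_pool(0.001, p))
  set.seed(11)
  # replicate means at growing population sizes approach the deterministic
  # value with shrinking deviation
  devs <- vapply(c(1e3, 1e4, 1e5), function(N) {
    qs <- replicate(400, wright_fisher_step(0.001, N, p))
    abs(mean(qs) - det)
  }, numeric(1))
  se5 <- 5 * sqrt(det * (1 - det) / (2 * c(1e3, 1e4, 1e5) * 400))
  expect_true(all(devs < se5))
  expect_lt(devs[3], devs[1])
})
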