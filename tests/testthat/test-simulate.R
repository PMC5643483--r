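test_that("generators are fully deterministic under a seed", {
  db <- metabolite_db()
  a <- simulate_spectrum(db, n_true = 10, n_decoys = 5, ppm_sigma = 0.1,
                         blank_contaminants = 3, low_snr_frac = 0.2,
                         seed = 99)
  b <- simulate_spectrum(db, n_true = 10, n_decoys = 5, ppm_sigma = 0.1,
                         blank_contaminants = 3, low_snr_frac = 0.2,
                         seed = 99)
  expect_identical(a, b)
  g1 <- simulate_batch_growth(noise_cv = 0.05, seed = 7)
  g2 <- simulate_batch_growth(noise_cv = 0.05, seed = 7)
  expect_identical(g1, g2)
  d1 <- simulate_diatom_experiment(noise_cv = 0.02, seed = 3)
  d2 <- simulate_diatom_experiment(noise_cv = 0.02, seed = 3)
  expect_identical(d1, d2)
})

test_that("an empty spectrum configuration yields empty peak lists", {
  sim <- simulate_spectrum(n_true = 0, n_decoys = 0, seed = 1)
  expect_equal(nrow(sim$sample), 0)
  expect_equal(nrow(sim$blank), 0)
  expect_equal(nrow(sim$manifest), 0)
})

test_that("decoy formulas pass the plausibility filters and avoid the
          database", {
  db <- metabolite_db()
  set.seed(17)
  decoys <- simulate_decoy_formulas(30, exclude = db$formula)
  expect_equal(anyDuplicated(decoys), 0)
  expect_false(any(decoys %in% db$formula))
  dbe <- formula_dbe(decoys)
  counts <- parse_formula(decoys)
  expect_true(all(abs(dbe - round(dbe)) < 1e-9))
  expect_true(all(counts$H / counts$C >= 0.3 & counts$H / counts$C <= 2.5))
  expect_true(all(counts$O / counts$C <= 1.2))
  m <- formula_mass(decoys)
  expect_true(all(m >= 92 & m <= 2000))
})

test_that("the blank shares exactly the configured contaminants", {
  db <- metabolite_db()
  sim <- simulate_spectrum(db, n_true = 8, n_decoys = 4,
                           blank_contaminants = 3, ppm_sigma = 0, seed = 12)
  expect_equal(nrow(sim$blank), 3)
  expect_equal(sum(sim$manifest$role == "contaminant"), 3)
  # contaminant peaks appear in the sample at the same theoretical masses
  cont <- sim$manifest[sim$manifest$role == "contaminant", ]
  expect_true(all(vapply(cont$mz, function(z) {
    any(abs(sim$sample$mz - z) < 1e-9)
  }, TRUE)))
})

test_that("the low-S/N fraction lands below the filter threshold", {
  db <- metabolite_db()
  sim <- simulate_spectrum(db, n_true = 40, low_snr_frac = 0.25, seed = 5)
  expect_equal(sum(sim$manifest$snr < 5), round(0.25 * 40))
  expect_false(any(sim$manifest$expected_detectable & sim$manifest$snr < 5))
})

test_that("Monod batch growth conserves carbon and is monotone", {
  sim <- simulate_batch_growth(mu_max = 0.25, ks = 0.2, yield_coeff = 0.15,
                               s0 = 8, x0 = 0.02, dt = 0.04, t_end = 60)
  # biomass non-decreasing, substrate non-increasing in the noise-free signal
  expect_true(all(diff(sim$biomass) >= -1e-12))
  expect_true(all(diff(sim$substrate) <= 1e-12))
  # conservation: x - x0 = Y (s0 - s) along the whole trajectory
  lhs <- sim$biomass - 0.02
  rhs <- 0.15 * (8 - sim$substrate)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("in the low-Ks limit early growth is pure exponential", {
  mu <- 0.3
  sim <- simulate_batch_growth(mu_max = mu, ks = 1e-6, yield_coeff = 0.2,
                               s0 = 5, x0 = 0.01, dt = 0.02, t_end = 20)
  early <- sim[sim$substrate > 2.5, ] # S >> Ks throughout
  expect_equal(early$biomass, 0.01 * exp(mu * early$time_h),
               tolerance = 1e-3)
})

test_that("parameter guards reject impossible growth configurations", {
  expect_error(simulate_batch_growth(mu_max = -1), "positive")
  expect_error(simulate_batch_growth(mu_max = 0.5, dt = 0.05), "stability")
  expect_error(simulate_diatom_experiment(n_replicates = 1), "replicates")
})

test_that("noise-free simulated curves return the generating rate", {
  sim <- simulate_batch_growth(mu_max = 0.2, ks = 0.05, dt = 0.05,
                               t_end = 40)
  obs <- sim[seq(1, nrow(sim), by = 20), ]
  fit <- fit_growth_rate(obs, time_h, biomass_obs)
  expect_lt(abs(fit$rate - 0.2) / 0.2, 0.05)
})

test_that("a noise-free diatom experiment reproduces its stimulation factor
          exactly", {
  sim <- simulate_diatom_experiment(stimulation_factor = 1.22, noise_cv = 0,
                                    seed = 4)
  rates <- fit_replicate_rates(sim$curves, time_h, fluorescence,
                               arm, replicate)
  s <- stimulation(rates$rate[rates$arm == "treated"],
                   rates$rate[rates$arm == "control"])
  expect_equal(s$percent_enhancement, 22, tolerance = 1e-9)
  # the manifest carries the generating truth
  expect_equal(unique(sim$manifest$stimulation_factor), 1.22)
})

test_that("a null diatom experiment is centered on zero enhancement", {
  set.seed(31)
  est <- replicate(60, {
    sim <- simulate_diatom_experiment(stimulation_factor = 1,
                                      noise_cv = 0.05)
    rates <- fit_replicate_rates(sim$curves, time_h, fluorescence,
                                 arm, replicate)
    stimulation(rates$rate[rates$arm == "treated"],
                rates$rate[rates$arm == "control"])$percent_enhancement
  })
  # mean within 3 standard errors of zero
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
})
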