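test_that("ground-truth models honour scales, symmetry and determinism", {
  z <- make_ising_model(7, 0, 0, seed = 99)
  expect_equal(z$h, rep(0, 7))
  expect_true(all(z$J == 0))
  m1 <- make_ising_model(2, 0.5, 0.5, seed = 1)
  m2 <- make_ising_model(2, 0.5, 0.5, seed = 1)
  expect_equal(m1$h, m2$h)
  expect_equal(m1$J, m2$J)
  m <- make_ising_model(7, 0.3, 0.3, seed = 7)
  expect_equal(m$J, t(m$J))
  expect_true(all(diag(m$J) == 0))
  expect_true(all(abs(m$h) <= 0.3), all(abs(m$J) <= 0.3))
  p <- boltzmann_distribution(m)$probabilities
  expect_length(p, 128)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(make_ising_model(1, 0.3, 0.3), "n_nodes")
})

test_that("model scaling multiplies energies without moving the minima", {
  m <- make_ising_model(6, 0.3, 0.4, seed = 3)
  s <- scale_model(m, 1.7)
  expect_equal(enumerate_energies(s)$energies, 1.7 * enumerate_energies(m)$energies)
  expect_equal(find_local_minima(enumerate_energies(s))$code,
               find_local_minima(enumerate_energies(m))$code)
})

test_that("exact sampler reproduces the Boltzmann distribution", {
  u <- mem_parameters(rep(0, 7))
  x <- sample_patterns_exact(u, 1e5, seed = 1)
  freq <- tabulate(pattern_to_code(x) + 1L, nbins = 128) / 1e5
  se <- sqrt((1 / 128) * (127 / 128) / 1e5)
  expect_true(all(abs(freq - 1 / 128) < 5 * se))
  expect_equal(nrow(sample_patterns_exact(u, 0, seed = 1)), 0)
  m <- make_ising_model(7, 0.3, 0.3, seed = 7)
  x2 <- sample_patterns_exact(m, 5e4, seed = 2)
  emp <- compute_empirical_moments(x2)
  exact <- compute_model_moments(m)
  expect_lt(max(abs(emp$mean_activity - exact$mean_activity)), 0.02)
  expect_lt(max(abs(emp$pairwise - exact$pairwise)), 0.02)
  # total-variation convergence of the empirical pattern distribution
  x3 <- sample_patterns_exact(m, 1e5, seed = 3)
  freq3 <- tabulate(pattern_to_code(x3) + 1L, nbins = 128) / 1e5
  tv <- 0.5 * sum(abs(freq3 - boltzmann_distribution(m)$probabilities))
  expect_lt(tv, 0.02)
})

test_that("continuous conversion adds calibrated noise and is invertible at high snr", {
  m <- make_ising_model(7, 0.3, 0.3, seed = 5)
  p <- sample_patterns_exact(m, 1e4, seed = 6)
  x <- binary_to_continuous(p, snr = 5, seed = 7)
  expect_equal(dim(x), dim(p))
  expect_lt(abs(sd(x - p) - 1 / 5), 0.01)
  # recovery rate above 95% at snr 5
  b <- binarize(x)
  expect_gt(mean(b$values == p), 0.95)
  expect_error(binary_to_continuous(p, snr = 0), "snr")
})

test_that("AR(1) generator matches its theoretical autocorrelation", {
  x <- generate_ar1_series(0.8, 1e4, seed = 1)
  expect_lt(abs(acf(x, plot = FALSE, lag.max = 1)$acf[2] - 0.8), 0.03)
  w <- generate_ar1_series(0, 1e4, seed = 2)
  expect_lt(abs(acf(w, plot = FALSE, lag.max = 1)$acf[2]), 0.05)
  expect_identical(generate_ar1_series(0.5, 100, seed = 9),
                   generate_ar1_series(0.5, 100, seed = 9))
  expect_error(generate_ar1_series(1, 100), "stationarity")
})

test_that("cohort generation is reproducible with a complete manifest", {
  spec <- default_study_spec(seed = 5, n_subjects_per_group = 3,
                             n_timepoints = 60)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$manifest), 12)
  expect_setequal(unique(coh$manifest$group), c("TD", "ASD", "ADHD", "ASD_ADHD"))
  expect_setequal(names(coh$series), coh$manifest$subject_id)
  expect_true(all(vapply(coh$series, function(s) all(dim(s) == c(60, 7)), TRUE)))
  coh2 <- generate_cohort(spec)
  expect_identical(coh$series, coh2$series)
  expect_identical(coh$manifest, coh2$manifest)
  # symptom scores present only in the planted groups
  expect_true(all(is.na(coh$manifest$cprs_hyper[coh$manifest$group == "ASD"])))
  expect_true(all(!is.na(coh$manifest$cprs_hyper[coh$manifest$group == "ADHD"])))
})

test_that("unknown planted feature names are a configuration error", {
  spec <- default_study_spec(seed = 1, n_subjects_per_group = 2, n_timepoints = 20)
  spec$symptom_slopes$bad <- list(feature = "nope", slope = 1, noise_sd = 1)
  expect_error(generate_cohort(spec), "unknown planted feature")
})

test_that("zero-slope symptoms stay uncorrelated with their feature", {
  base <- base_study_model()
  spec <- effect_spec(list(G = base), n_subjects_per_group = 40,
                      n_timepoints = 120, snr = 8, steps_per_tr = 3,
                      speed_jitter_sd = 0.4,
                      symptom_slopes = list(s0 = list(feature = "freq_ACDB",
                                                      slope = 0, noise_sd = 1)),
                      seed = 31)
  hits <- 0
  for (r in 1:10) {
    spec$seed <- 31 + r
    coh <- generate_cohort(spec)
    f <- coh$truth$features$freq_ACDB
    if (sd(f) > 0 && abs(cor(f, coh$manifest$s0)) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("planted slopes are recovered by least squares on large cohorts", {
  base <- base_study_model()
  spec <- effect_spec(list(G = base), n_subjects_per_group = 120,
                      n_timepoints = 150, snr = 8, steps_per_tr = 3,
                      speed_jitter_sd = 0.5,
                      symptom_slopes = list(sym = list(feature = "freq_ACDB",
                                                       slope = 300,
                                                       noise_sd = 2,
                                                       intercept = 10)),
                      seed = 77)
  coh <- generate_cohort(spec)
  fit <- lm(coh$manifest$sym ~ coh$truth$features$freq_ACDB)
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 300), 2 * est["Std. Error"])
})

test_that("identical group models keep the group test at its nominal level", {
  base <- base_study_model()
  pvals <- sapply(1:25, function(r) {
    spec <- effect_spec(list(G1 = base, G2 = base), n_subjects_per_group = 12,
                        n_timepoints = 100, snr = 8, steps_per_tr = 2,
                        speed_jitter_sd = 0.3, seed = 400 + r)
    coh <- generate_cohort(spec)
    f <- coh$truth$features
    two_sample_t(f$freq_ACDB[f$group == "G1"], f$freq_ACDB[f$group == "G2"])$p
  })
  # 25 null replicates at alpha = .05: P(>= 5 rejections) < 1e-3
  expect_lte(sum(pvals < 0.05), 4)
})

test_that("planted mediation chains carry the requested coefficients", {
  base <- base_study_model()
  spec <- effect_spec(list(G = base), n_subjects_per_group = 200,
                      n_timepoints = 30, snr = 8,
                      mediation_plant = list(alpha = 0.8, beta = 0.7,
                                             gamma_prime = 0),
                      seed = 21)
  coh <- generate_cohort(spec)
  man <- coh$manifest
  res <- mediation_bootstrap(man$med_x, man$med_m, man$med_y,
                             n_boot = 1000, seed = 5)
  expect_lt(abs(res$alpha - 0.8), 0.2)
  expect_lt(abs(res$beta - 0.7), 0.15)
  expect_gt(res$ci["indirect", "lower"], 0)
  expect_lte(res$ci["gamma_prime", "lower"], 0)
})

test_that("cohort directories round-trip through write/read", {
  spec <- default_study_spec(seed = 3, n_subjects_per_group = 2,
                             n_timepoints = 30)
  coh <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_cohort(dir)
  expect_equal(back$manifest$subject_id, coh$manifest$subject_id)
  id <- coh$manifest$subject_id[1]
  expect_equal(unname(back$series[[id]]), unname(coh$series[[id]]),
               tolerance = 1e-6)
  expect_equal(back$truth$seed, 3)
})
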