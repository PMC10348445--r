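test_that("binarize thresholds at the per-timepoint mean with ties to -1", {
  b <- binarize(matrix(1:7, nrow = 1))
  expect_equal(b$values[1, ], c(-1L, -1L, -1L, -1L, 1L, 1L, 1L))
  # all-constant row: every signal ties with the mean -> all -1
  expect_equal(binarize(matrix(2, 1, 4))$values[1, ], rep(-1L, 4))
  expect_error(binarize(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
})

test_that("per-node-temporal-mean mode thresholds each column at its own mean", {
  x <- cbind(c(0, 10), c(5, 5.5))
  b <- binarize(x, mode = "per-node-temporal-mean")
  expect_equal(b$values, rbind(c(-1L, -1L), c(1L, 1L)))
})

test_that("binarization inverts binary_to_continuous at high snr", {
  m <- make_ising_model(7, 0.3, 0.3, seed = 3)
  p <- sample_patterns_exact(m, 500, seed = 9)
  x <- binary_to_continuous(p, snr = 1e6, seed = 1)
  b <- binarize(x)
  mixed <- apply(p, 1, function(r) length(unique(r)) > 1)
  expect_true(all(b$values[mixed, ] == p[mixed, ]))
})

test_that("empirical moments equal a brute-force double loop", {
  set.seed(42)
  x <- matrix(sample(c(-1L, 1L), 50 * 4, replace = TRUE), 50, 4)
  mom <- compute_empirical_moments(x)
  expect_equal(mom$mean_activity, sapply(1:4, function(i) mean(x[, i])))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(mom$pairwise[i, j], mean(x[, i] * x[, j]))
  }
  expect_equal(mom$n_samples, 50)
  # concatenation across subjects is plain row stacking
  mom2 <- compute_empirical_moments(list(x[1:20, ], x[21:50, ]))
  expect_equal(mom2$mean_activity, mom$mean_activity)
  expect_equal(mom2$pairwise, mom$pairwise)
  expect_error(compute_empirical_moments(list(x, x[, 1:3])), "node counts")
})

test_that("pattern energy matches the double-sum definition and hand values", {
  expect_equal(pattern_energy(c(1, 1), mem_parameters(c(1, -1), matrix(c(0, .5, .5, 0), 2))),
               -0.5)
  m0 <- mem_parameters(rep(0, 3))
  expect_equal(pattern_energy(all_patterns(3), m0), rep(0, 8))
  m <- make_ising_model(5, 0.4, 0.4, seed = 11)
  s <- all_patterns(5)
  for (k in c(1, 7, 19, 32)) {
    expect_equal(pattern_energy(s[k, ], m), oracle_energy(s[k, ], m$h, m$J))
  }
  # spin-flip symmetry at h = 0
  mj <- mem_parameters(rep(0, 4), m$J[1:4, 1:4] - diag(diag(m$J[1:4, 1:4])))
  e <- pattern_energy(all_patterns(4), mj)
  expect_equal(e, rev(e))
})

test_that("Boltzmann distribution is exact, normalized and stable", {
  u <- boltzmann_distribution(mem_parameters(rep(0, 7)))
  expect_equal(u$probabilities, rep(1 / 128, 128))
  m <- make_ising_model(3, 1, 1, seed = 5)
  p <- boltzmann_distribution(m)$probabilities
  # naive unstabilized computation as oracle
  e <- apply(all_patterns(3), 1, oracle_energy, h = m$h, J = m$J)
  expect_equal(p, exp(-e) / sum(exp(-e)), tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("model moments match closed forms and Monte-Carlo sampling", {
  mom0 <- compute_model_moments(mem_parameters(rep(0, 4)))
  expect_equal(mom0$mean_activity, rep(0, 4))
  expect_equal(mom0$pairwise, diag(4))
  # independent spins: <sigma_i> = tanh(h_i)
  mh <- compute_model_moments(mem_parameters(rep(0.5, 3)))
  expect_equal(mh$mean_activity, rep(tanh(0.5), 3), tolerance = 1e-12)
  m <- make_ising_model(6, 0.3, 0.3, seed = 21)
  exact <- compute_model_moments(m)
  x <- sample_patterns_exact(m, 2e5, seed = 22)
  emp <- compute_empirical_moments(x)
  expect_lt(max(abs(emp$mean_activity - exact$mean_activity)), 0.01)
  expect_lt(max(abs(emp$pairwise - exact$pairwise)), 0.01)
})

test_that("independent fit inverts tanh and reproduces its input means", {
  mom <- moment_set(c(0, tanh(0.5), -tanh(1.2)), diag(3))
  fit <- fit_independent_mem(mom)
  expect_equal(fit$h, c(0, 0.5, -1.2), tolerance = 1e-10)
  expect_true(all(fit$J == 0))
  back <- compute_model_moments(fit)
  expect_equal(back$mean_activity, mom$mean_activity, tolerance = 1e-10)
})

test_that("gradient ascent recovers known parameters from exact moments", {
  worst <- 0
  for (s in 1:6) {
    n <- 3 + (s %% 5)
    m <- make_ising_model(n, 0.3, 0.3, seed = s)
    fit <- fit_pairwise_mem(compute_model_moments(m), tol = 1e-8)
    expect_true(fit$diagnostics$converged)
    worst <- max(worst, abs(fit$params$h - m$h), abs(fit$params$J - m$J))
  }
  expect_lt(worst, 1e-4)
  # zero moments are a fixed point of the zero-initialized ascent
  z <- fit_pairwise_mem(moment_set(rep(0, 3), diag(3)))
  expect_equal(z$params$h, rep(0, 3))
  expect_equal(z$diagnostics$n_iterations, 1)
})

test_that("fit warns when the series is shorter than 2^(N-1) timepoints", {
  mom <- moment_set(rep(0.1, 7), diag(7) + 0.05 - diag(0.05, 7), n_samples = 30)
  expect_warning(fit_pairwise_mem(mom, max_iter = 10), "timepoints")
})

test_that("empirical pattern distribution matches a hash-count oracle", {
  set.seed(8)
  x <- matrix(sample(c(-1L, 1L), 200 * 3, replace = TRUE), 200, 3)
  d <- empirical_pattern_distribution(x)
  counts <- table(factor(apply(x, 1, function(r) sum((r == 1) * c(1, 2, 4))),
                         levels = 0:7))
  expect_equal(d$probabilities, as.numeric(counts) / 200)
  one <- empirical_pattern_distribution(matrix(c(1, -1, 1), 1))
  expect_equal(one$probabilities[6], 1)
  expect_equal(sum(one$probabilities), 1)
})

test_that("KL divergence obeys closed forms and Gibbs' inequality", {
  p <- pattern_distribution(c(1, 0))
  q <- pattern_distribution(c(0.5, 0.5))
  expect_equal(kl_divergence(p, q), log(2))
  expect_equal(kl_divergence(q, q), 0)
  expect_error(kl_divergence(q, p), "positive")
  withr::with_seed(31, {
    for (i in 1:20) {
      a <- runif(8); a <- a / sum(a)
      b <- runif(8) + 0.01; b <- b / sum(b)
      expect_gte(kl_divergence(pattern_distribution(a), pattern_distribution(b)), 0)
    }
  })
})

test_that("fit accuracy is 1 for a realizable distribution and flagged when degenerate", {
  m <- make_ising_model(4, 0.4, 0.4, seed = 17)
  emp <- boltzmann_distribution(m)
  first <- fit_independent_mem(compute_model_moments(m))
  acc <- fit_accuracy(emp, first, m)
  expect_true(acc$defined)
  expect_equal(acc$accuracy, 1, tolerance = 1e-9)
  # uniform empirical distribution: both models fit perfectly -> undefined
  u <- boltzmann_distribution(mem_parameters(rep(0, 4)))
  z <- mem_parameters(rep(0, 4))
  degen <- fit_accuracy(u, mem_parameters(rep(0, 4), order = "first"), z)
  expect_false(degen$defined)
  expect_true(is.na(degen$accuracy))
})

test_that("pairwise fit beats the independent fit on structured data (D2 <= D1)", {
  m <- make_ising_model(5, 0.3, 0.5, seed = 29)
  x <- sample_patterns_exact(m, 2e4, seed = 30)
  mom <- compute_empirical_moments(x)
  fit <- fit_pairwise_mem(mom, tol = 1e-8)
  acc <- fit_accuracy(empirical_pattern_distribution(x),
                      fit_independent_mem(mom), fit$params)
  expect_lte(acc$d2, acc$d1 + 1e-12)
  expect_gt(acc$accuracy, 0.9)
})

test_that("model JSON round-trips through export/import", {
  m <- make_ising_model(4, 0.3, 0.3, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_mem_json(m, path, fit = list(accuracy = 0.99))
  back <- read_mem_json(path)
  expect_equal(back$h, m$h)
  expect_equal(back$J, m$J)
  expect_equal(back$order, "pairwise")
})
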