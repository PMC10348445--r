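test_that("walk length, burn-in and neighbour structure behave as specified", {
  m <- mem_parameters(rep(0, 7))
  traj <- metropolis_random_walk(m, n_steps = 1e5, burn_in = 100, seed = 5)
  expect_length(traj$codes, 99900)
  # flat landscape: every proposal accepted, consecutive codes differ by 1 bit
  d <- bitwXor(traj$codes[-1], traj$codes[-length(traj$codes)])
  expect_true(all(d %in% 2^(0:6)))
  # reproducibility
  traj2 <- metropolis_random_walk(m, n_steps = 1e5, burn_in = 100, seed = 5)
  expect_identical(traj$codes, traj2$codes)
})

test_that("downhill proposals are always accepted", {
  # two-node chain with a strong field: from the high-energy pattern the
  # walk must always step downhill when that flip is proposed
  m <- mem_parameters(c(5, 5))
  traj <- metropolis_random_walk(m, n_steps = 2000, burn_in = 0, seed = 2,
                                 start_code = 0L)
  first_leave <- which(traj$codes != 0L)[1]
  expect_false(is.na(first_leave))
  # after reaching the all-plus ground state it should essentially stay
  expect_gt(mean(traj$codes[500:2000] == 3L), 0.95)
})

test_that("Metropolis kernel satisfies detailed balance on every neighbour pair", {
  m <- make_ising_model(7, 0.3, 0.3, seed = 47)
  p <- boltzmann_distribution(m)$probabilities
  e <- enumerate_energies(m)$energies
  nb <- energyscape:::neighbor_codes(7)
  worst <- 0
  for (i in 0:127) {
    for (j in nb[i + 1, ]) {
      pij <- (1 / 7) * min(1, exp(e[i + 1] - e[j + 1]))
      pji <- (1 / 7) * min(1, exp(e[j + 1] - e[i + 1]))
      worst <- max(worst, abs(p[i + 1] * pij - p[j + 1] * pji))
    }
  }
  expect_lt(worst, 1e-14)
})

test_that("long-run visit frequencies converge to the Boltzmann distribution", {
  m <- make_ising_model(7, 0.3, 0.3, seed = 47)
  p <- boltzmann_distribution(m)$probabilities
  traj <- metropolis_random_walk(m, n_steps = 1e6, burn_in = 100, seed = 11)
  freq <- tabulate(traj$codes + 1L, nbins = 128) / length(traj$codes)
  tv <- 0.5 * sum(abs(freq - p))
  expect_lt(tv, 0.01)
})

test_that("MCMC pattern sampler thins correctly and visits all flat-landscape patterns", {
  m <- mem_parameters(rep(0, 7))
  raw <- metropolis_random_walk(m, n_steps = 600, burn_in = 100, seed = 9)
  thin1 <- sample_patterns_mcmc(m, 500, burn_in = 100, thin = 1, seed = 9)
  expect_equal(pattern_to_code(thin1), raw$codes)
  all_seen <- sample_patterns_mcmc(m, 2e4, burn_in = 100, thin = 1, seed = 10)
  expect_setequal(unique(pattern_to_code(all_seen)), 0:127)
  expect_equal(nrow(sample_patterns_mcmc(m, 0, seed = 1)), 0)
})

test_that("patterns map to their basin states with ambiguity dropped", {
  m <- make_ising_model(5, 0.4, 0.4, seed = 12)
  land <- enumerate_energies(m)
  mm <- find_local_minima(land)
  basins <- assign_basins(land, mm)
  # local minima map to their own labels
  st <- patterns_to_states(mm$code, basins)
  expect_equal(as.character(st), toupper(mm$label))
  # per-element lookup oracle on a random code sequence
  codes <- withr::with_seed(3, sample(0:31, 300, replace = TRUE))
  st2 <- patterns_to_states(codes, basins, drop_ambiguous = FALSE)
  expect_equal(as.character(st2), toupper(basins$assignment[codes + 1]))
})

test_that("run compression conserves duration and merges runs", {
  r <- compress_runs(c("A", "A", "A", "B", "B"))
  expect_equal(r, data.frame(state = c("A", "B"), duration = c(3L, 2L)))
  expect_equal(nrow(compress_runs("A")), 1)
  x <- random_state_seq(500, LETTERS[1:4], seed = 6)
  expect_equal(sum(compress_runs(x)$duration), 500)
  expect_error(compress_runs(character(0)), "empty")
})

test_that("transition statistics match a pair-counting oracle", {
  s <- state_sequence(c("A", "B", "A", "B"), states = c("A", "B"))
  ts <- transition_statistics(s)
  expect_equal(ts$transition_counts["A", "B"], 2)
  expect_equal(ts$transition_counts["B", "A"], 1)
  expect_equal(ts$transition_freq["A", "B"], 2 / 3)
  const <- transition_statistics(state_sequence(rep("A", 10), states = c("A", "B")))
  expect_true(all(const$transition_counts == 0))
  expect_equal(const$dwell$mean_dwell[const$dwell$state == "A"], 10)
  x <- random_state_seq(400, LETTERS[1:5], seed = 8)
  ts2 <- transition_statistics(state_sequence(x))
  for (a in LETTERS[1:5]) for (b in LETTERS[1:5]) {
    if (a == b) next
    want <- sum(x[-length(x)] == a & x[-1] == b)
    expect_equal(unname(ts2$transition_counts[a, b]), want)
  }
  # transitions plus within-run steps account for every step
  expect_equal(sum(ts2$transition_counts) + sum(compress_runs(x)$duration - 1),
               length(x) - 1)
})

test_that("path templates count indirect transitions in both directions", {
  states <- LETTERS[1:6]
  tpl <- canonical_templates()
  seq1 <- state_sequence(c("A", "A", "C", "B"), states = states)
  expect_equal(count_path_transitions(seq1, tpl$freq_ACDB)$count, 1)
  expect_equal(count_path_transitions(seq1, tpl$freq_ACDB)$frequency, 1 / 3)
  seq2 <- state_sequence(c("A", "E", "B"), states = states)
  expect_equal(count_path_transitions(seq2, tpl$freq_ACDB)$count, 0)
  expect_equal(count_path_transitions(seq2, tpl$freq_ACDEFB)$count, 0)
  seq3 <- state_sequence(c("A", "C", "F", "B"), states = states)
  expect_equal(count_path_transitions(seq3, path_template(c("A", "B"), list("C", "F")))$count, 1)
  expect_equal(count_path_transitions(seq3, tpl$freq_ACDEFB)$count, 1)
  seq4 <- state_sequence(c("B", "F", "C", "A"), states = states)
  expect_equal(count_path_transitions(seq4, path_template(c("A", "B"), list("C", "F")))$count, 1)
  expect_equal(count_path_transitions(seq4, tpl$freq_ACDEFB)$count, 1)
  expect_equal(count_path_transitions(seq4, tpl$freq_ACDEFB,
                                      directions = "forward")$count, 0)
})

test_that("template matching handles runs, excursions and unknown states", {
  states <- LETTERS[1:6]
  tpl <- canonical_templates()
  # repeated interior runs from one block still match
  s <- state_sequence(c("A", "C", "D", "C", "B"), states = states)
  expect_equal(count_path_transitions(s, tpl$freq_ACDB)$count, 1)
  # an excursion returning to the same endpoint is not a transition
  s2 <- state_sequence(c("A", "C", "A"), states = states)
  expect_equal(count_path_transitions(s2, tpl$freq_ACDB)$count, 0)
  # direct A-B steps never match (blocks must be nonempty)
  s3 <- state_sequence(c("A", "B", "A", "B"), states = states)
  expect_equal(count_path_transitions(s3, tpl$freq_ACDB)$count, 0)
  # ordered blocks: E/F before C/D does not match the C/D-then-E/F template
  s4 <- state_sequence(c("A", "E", "C", "B"), states = states)
  expect_equal(count_path_transitions(s4, tpl$freq_ACDEFB)$count, 0)
  expect_error(count_path_transitions(s4, path_template(c("A", "Z"), list("C"))),
               "unknown states")
  expect_error(path_template(c("A", "B"), list(c("A", "C"))), "endpoint")
})

test_that("path counts are invariant under relabeling respecting the template sets", {
  x <- random_state_seq(2000, LETTERS[1:6], seed = 14)
  tpl <- canonical_templates()$freq_ACDEFB
  n1 <- count_path_transitions(state_sequence(x), tpl)$count
  swap <- c(A = "A", B = "B", C = "D", D = "C", E = "F", F = "E")
  n2 <- count_path_transitions(state_sequence(unname(swap[x])), tpl)$count
  expect_equal(n1, n2)
})

test_that("subject dynamics chain produces the features used downstream", {
  m <- make_ising_model(7, 0.3, 0.6, seed = 135)
  land <- enumerate_energies(m)
  mm <- find_local_minima(land)
  basins <- assign_basins(land, mm)
  # hand-built series visiting minima a -> c -> b
  codes <- c(rep(mm$code[1], 3), rep(mm$code[3], 2), rep(mm$code[2], 3))
  series <- binary_time_series(code_to_pattern(codes, 7))
  dyn <- subject_dynamics(series, basins)
  expect_equal(unname(dyn$path_freq["freq_ACDB"]), 1 / 7)
  expect_equal(unname(dyn$path_freq["freq_ACFB"]), 0)
  # a trajectory stuck in one basin yields zero path counts
  stuck <- binary_time_series(code_to_pattern(rep(mm$code[1], 5), 7))
  expect_true(all(subject_dynamics(stuck, basins)$path_freq == 0))
})

test_that("cohort-mean simulated and empirical path frequencies correlate", {
  base <- base_study_model()
  specs <- seq(0.7, 1.4, length.out = 8)
  sim <- emp <- matrix(NA_real_, length(specs), 3)
  land0 <- enumerate_energies(base)
  basins0 <- assign_basins(land0, find_local_minima(land0))
  for (i in seq_along(specs)) {
    m <- scale_model(base, specs[i])
    traj <- metropolis_random_walk(m, 3e4, 100, seed = 100 + i)
    st <- patterns_to_states(traj, basins0)
    sim[i, ] <- vapply(canonical_templates(), function(tp)
      count_path_transitions(st, tp)$frequency, numeric(1))
    emp_i <- rowMeans(vapply(1:12, function(r) {
      pats <- sample_patterns_mcmc(m, 175, burn_in = 100, seed = 7000 + 20 * i + r)
      st_s <- patterns_to_states(pats, basins0)
      vapply(canonical_templates(), function(tp)
        count_path_transitions(st_s, tp)$frequency, numeric(1))
    }, numeric(3)))
    emp[i, ] <- emp_i
  }
  expect_gt(cor(as.vector(sim), as.vector(emp)), 0.5)
})
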