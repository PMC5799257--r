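test_that("negative log-likelihood matches brute-force marginalization", {
  inst <- small_instance(n_signs = 8, n_diseases = 3, seed = 61)
  m <- fit_from_true_marginals(inst)
  state <- random_state(8, 4, seed = 62)
  D <- diagsim:::enumerate_binary(3)
  # -H differs from log sum_{S^u} P(S|D)P0(D) by a D-independent constant
  negH <- -apply(D, 1, function(d) neg_log_likelihood(m, state, d))
  brute <- log(apply(D, 1, function(d) enum_likelihood(m, state, d)))
  shifts <- negH - brute
  expect_lt(diff(range(shifts)), 1e-10)
})

test_that("empty observation set leaves only the prior term", {
  m <- small_model()
  st <- observation_state(m$n_signs)
  d <- c(1L, 1L, 0L)
  expect_equal(neg_log_likelihood(m, st, d), -sum(m$prior_fields * d),
               tolerance = 1e-12)
})

test_that("field-aligned observations add the least possible energy", {
  # each new observed sign i adds -S_i h_i + ln 2cosh h_i to the energy;
  # the term x*h - ln 2cosh h is maximized at x = sign(h), so the aligned
  # value gives the smaller increase, bounded by log(1 + e^{-2|h|}) <= ln 2
  m <- random_model(8, 3, seed = 63)
  st <- random_state(8, 3, seed = 64)
  for (d in list(c(0L, 1L, 0L), c(1L, 1L, 1L))) {
    u <- unobserved_signs(st)[1]
    h <- local_fields(m, d)[u]
    e0 <- neg_log_likelihood(m, st, d)
    aligned <- observe_sign(st, u, if (h >= 0) 1L else -1L)
    opposed <- observe_sign(st, u, if (h >= 0) -1L else 1L)
    e_al <- neg_log_likelihood(m, aligned, d)
    e_op <- neg_log_likelihood(m, opposed, d)
    expect_lte(e_al, e_op + 1e-12)
    expect_gte(e_al, e0 - 1e-12)
    expect_lte(e_al, e0 + log(2) + 1e-12)
    expect_equal(e_al - e0, log1p(exp(-2 * abs(h))), tolerance = 1e-10)
  }
})

test_that("exact inference with no observations returns the prior", {
  inst <- generate_instance(20, 5, seed = 65)
  m <- fit_from_true_marginals(inst, prior = calibrate_prior(5, 2))
  r <- exact_infer(m, observation_state(20))
  expect_equal(r$disease_marginals, rep(0.4, 5), tolerance = 1e-10)
})

test_that("exact sign marginals match full joint enumeration", {
  inst <- small_instance(n_signs = 7, n_diseases = 2, seed = 66)
  m <- fit_from_true_marginals(inst)
  state <- random_state(7, 3, seed = 67)
  r <- exact_infer(m, state)
  # brute force over (S^u, D)
  u <- unobserved_signs(state)
  Su <- diagsim:::enumerate_signs(length(u))
  D <- diagsim:::enumerate_binary(2)
  joint <- matrix(0, nrow(Su), nrow(D))
  for (rd in seq_len(nrow(D))) {
    prior <- sum(m$prior_fields * D[rd, ]) - sum(log1p(exp(m$prior_fields)))
    for (rs in seq_len(nrow(Su))) {
      s <- integer(7)
      s[state$observed_idx] <- state$observed_val
      s[u] <- Su[rs, ]
      joint[rs, rd] <- exp(prior + conditional_log_prob(m, s, D[rd, ]))
    }
  }
  joint <- joint / sum(joint)
  for (k in seq_along(u)) {
    p_brute <- sum(joint[Su[, k] == 1, ])
    expect_equal(r$sign_marginals[u[k]], p_brute, tolerance = 1e-10)
  }
  for (a in 1:2) {
    expect_equal(r$disease_marginals[a], sum(joint[, D[, a] == 1]),
                 tolerance = 1e-10)
  }
  expect_true(all(is.na(r$sign_marginals[state$observed_idx])))
})

test_that("exact ML hypothesis is the global likelihood maximum", {
  inst <- small_instance(n_signs = 9, n_diseases = 3, seed = 68)
  m <- fit_from_true_marginals(inst)
  state <- random_state(9, 5, seed = 69)
  r <- exact_infer(m, state)
  D <- diagsim:::enumerate_binary(3)
  energies <- apply(D, 1, function(d) neg_log_likelihood(m, state, d))
  expect_equal(r$ml_log_likelihood, -min(energies), tolerance = 1e-12)
  expect_equal(as.integer(r$ml_hypothesis), D[which.min(energies), ])
})

test_that("sign-marginal bookkeeping is consistent when a sign is removed", {
  inst <- small_instance(n_signs = 8, n_diseases = 3, seed = 70)
  m <- fit_from_true_marginals(inst)
  state <- random_state(8, 4, seed = 71)
  k <- length(state$observed_idx)
  reduced <- observation_state(8, state$observed_idx[-k],
                               state$observed_val[-k])
  r <- exact_infer(m, reduced)
  expect_false(is.na(r$sign_marginals[state$observed_idx[k]]))
  expect_true(all(r$sign_marginals[unobserved_signs(reduced)] >= 0 &
                  r$sign_marginals[unobserved_signs(reduced)] <= 1))
})

test_that("MC marginals agree with exact enumeration at the default budget", {
  inst <- generate_instance(20, 5, seed = 72)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 2, seed = 73)
  state <- initial_observations(inst, truth, 6, seed = 74)
  ex <- exact_infer(m, state)
  mc <- mc_infer(m, state, mc_config(seed = 75))
  expect_lt(max(abs(mc$disease_marginals - ex$disease_marginals)), 0.02)
  u <- unobserved_signs(state)
  expect_lt(max(abs(mc$sign_marginals[u] - ex$sign_marginals[u])), 0.02)
})

test_that("MC inference is deterministic given the seed", {
  inst <- generate_instance(15, 4, seed = 76)
  m <- fit_from_true_marginals(inst)
  state <- random_state(15, 5, seed = 77)
  cfg <- mc_config(n_total = 4000, n_eq = 400, seed = 99)
  a <- mc_infer(m, state, cfg)
  b <- mc_infer(m, state, cfg)
  expect_identical(a, b)
})

test_that("MC error shrinks as the sweep budget grows", {
  inst <- generate_instance(15, 4, seed = 78)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 1, seed = 79)
  state <- initial_observations(inst, truth, 5, seed = 80)
  ex <- exact_infer(m, state)
  err <- vapply(c(2000, 20000, 200000), function(n) {
    r <- mc_infer(m, state, mc_config(n_total = n, n_eq = n / 10, seed = 81))
    max(abs(r$disease_marginals - ex$disease_marginals))
  }, 0)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.01)
})

test_that("zero-coupling model sampling recovers the prior", {
  m <- random_model(6, 3, seed = 82)
  m$leak_fields[] <- 0
  m$one_couplings <- lapply(m$one_couplings, function(f) { f$K[] <- 0; f })
  m$two_couplings <- lapply(m$two_couplings, function(f) { f$K[] <- 0; f })
  m$prior_fields <- rep(log(0.4 / 0.6), 3)
  r <- mc_infer(m, observation_state(6), mc_config(seed = 83))
  expect_lt(max(abs(r$disease_marginals - 0.4)), 0.02)
})

test_that("simulated annealing recovers the exhaustive ML hypothesis", {
  inst <- generate_instance(20, 5, seed = 84)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 2, seed = 85)
  state <- initial_observations(inst, truth, 8, seed = 86)
  ex <- exact_infer(m, state)
  hits <- 0L
  for (k in 1:40) {
    sa <- sa_max_likelihood(m, state, mc_config(seed = 1000 + k))
    expect_lte(sa$log_likelihood, ex$ml_log_likelihood + 1e-9)
    # ties at the optimum are possible (half-integer couplings); reaching
    # the optimal likelihood value counts as recovery
    if (sa$log_likelihood >= ex$ml_log_likelihood - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("enumeration guard directs large models to Monte Carlo", {
  inst <- generate_instance(30, 25, list(M_a = 25, M_ab = 10, k_a = 10,
                                         k_ab = 10), seed = 87)
  m <- fit_from_true_marginals(inst, prior = calibrate_prior(25, 2))
  expect_error(exact_infer(m, observation_state(30)), "mc_infer")
})
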