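test_that("initial observations reveal true values on a random subset", {
  inst <- small_instance(n_signs = 10, n_diseases = 3, seed = 101)
  truth <- sample_hypothesis(inst, 1, seed = 102)
  s_true <- most_probable_true_signs(inst, truth)
  st0 <- initial_observations(inst, truth, 0, seed = 103)
  expect_length(st0$observed_idx, 0)
  st_all <- initial_observations(inst, truth, 10, seed = 103)
  expect_identical(sort(st_all$observed_idx), 1:10)
  expect_identical(st_all$observed_val[order(st_all$observed_idx)], s_true)
  a <- initial_observations(inst, truth, 4, seed = 104)
  b <- initial_observations(inst, truth, 4, seed = 104)
  expect_identical(a, b)
  expect_error(initial_observations(inst, truth, 11), "n_initial")
})

test_that("most positive sign and imputation follow the declared tie rules", {
  st <- observation_state(6, c(1L, 4L), c(1L, 1L))
  sm <- c(NA, 0.2, 0.9, NA, 0.9, 0.5)
  r <- structure(list(sign_marginals = sm), class = "inference_result")
  expect_identical(most_positive_sign(r, st), 3L)  # tie 3 vs 5 -> lowest
  expect_identical(impute_value(r, 3), 1L)
  expect_identical(impute_value(r, 2), -1L)
  expect_identical(impute_value(r, 6), 1L)  # exactly 1/2 -> +1
  expect_error(impute_value(r, 1), "observed")
  r_one <- structure(list(sign_marginals = c(NA, 0.1, rep(NA, 4))),
                     class = "inference_result")
  st_one <- observation_state(6, c(1L, 3L, 4L, 5L, 6L),
                              c(1L, 1L, 1L, 1L, 1L))
  expect_identical(most_positive_sign(r_one, st_one), 2L)
})

test_that("greedy choice maximizes the per-step objective", {
  inst <- small_instance(n_signs = 8, n_diseases = 3, seed = 105)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 1, seed = 106)
  state <- initial_observations(inst, truth, 3, seed = 107)
  infer <- inference_backend(m)
  params <- objective_params(1, 0.1)
  ch <- greedy_choose(m, state, params, inst$weights, inst$costs, infer)
  # exhaustive check over all candidates
  result <- infer(state)
  totals <- vapply(unobserved_signs(state), function(j) {
    st2 <- observe_sign(state, j, impute_value(result, j))
    step_objective(infer(st2), st2, inst$costs[j], params, inst$weights)$total
  }, 0)
  expect_equal(ch$breakdown$total, max(totals), tolerance = 1e-12)
  expect_identical(ch$sign, unobserved_signs(state)[which.max(totals)])
})

test_that("a dominant cost penalty sends greedy to the cheapest sign", {
  inst <- small_instance(n_signs = 8, n_diseases = 3, seed = 108)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 1, seed = 109)
  state <- initial_observations(inst, truth, 2, seed = 110)
  ch <- greedy_choose(m, state, objective_params(0, 1e6), inst$weights,
                      inst$costs, inference_backend(m))
  u <- unobserved_signs(state)
  expect_identical(ch$sign, u[which.min(inst$costs[u])])
})

test_that("trajectories observe each sign at most once and grow by one per step", {
  inst <- small_instance(n_signs = 10, n_diseases = 3, seed = 111)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 2, seed = 112)
  for (strat in c("greedy", "random")) {
    traj <- run_diagnosis(inst, m, truth, "diags2", strat, n_steps = 6,
                          n_initial = 2, seed = 113)
    expect_identical(nrow(traj$steps), 6L)
    all_obs <- traj$initial_state$observed_idx
    expect_false(anyDuplicated(all_obs) > 0)
    expect_length(all_obs, 8)
    expect_identical(traj$steps$sign, all_obs[3:8])
  }
})

test_that("full Diags-I observation recovers every true sign value", {
  inst <- small_instance(n_signs = 8, n_diseases = 2, seed = 114)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 1, seed = 115)
  traj <- run_diagnosis(inst, m, truth, "diags1", "greedy",
                        n_steps = 6, n_initial = 2, seed = 116)
  s_true <- most_probable_true_signs(inst, truth)
  st <- traj$initial_state
  expect_identical(st$observed_val, s_true[st$observed_idx])
  expect_identical(traj$steps$value, traj$steps$true_value)
})

test_that("Diags-II matches Diags-I when imputation is forced correct", {
  # with all but n_steps signs initially observed, the posterior pins the
  # remaining signs to their true values, so both processes coincide
  inst <- small_instance(n_signs = 9, n_diseases = 2, seed = 117)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 1, seed = 118)
  t1 <- run_diagnosis(inst, m, truth, "diags1", "greedy", n_steps = 2,
                      n_initial = 7, seed = 119)
  t2 <- run_diagnosis(inst, m, truth, "diags2", "greedy", n_steps = 2,
                      n_initial = 7, seed = 119)
  expect_identical(t1$steps$sign, t2$steps$sign)
  expect_equal(t1$steps$dl, t2$steps$dl, tolerance = 1e-9)
})

test_that("random-strategy trajectories are reproducible", {
  inst <- small_instance(n_signs = 10, n_diseases = 3, seed = 120)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 1, seed = 121)
  a <- run_diagnosis(inst, m, truth, "diags2", "random", n_steps = 5,
                     n_initial = 2, seed = 122)
  b <- run_diagnosis(inst, m, truth, "diags2", "random", n_steps = 5,
                     n_initial = 2, seed = 122)
  expect_identical(a$steps, b$steps)
  c <- run_diagnosis(inst, m, truth, "diags2", "random", n_steps = 5,
                     n_initial = 2, seed = 123)
  expect_false(identical(a$steps$sign, c$steps$sign))
})

test_that("mean DL(t) is non-decreasing in Diags-I over many realizations", {
  out <- replicate_diagnosis(n_signs = 12, n_diseases = 4,
                             expected_present = 2, n_present = 2,
                             mode = "diags1", strategy = "greedy",
                             n_steps = 8, n_initial = 2,
                             params = objective_params(1, 0),
                             n_realizations = 200, seed = 124)
  cv <- out$curves$curves
  d <- diff(cv$mean_dl)
  se <- pmax(cv$se_dl[-1], cv$se_dl[-nrow(cv)])
  expect_true(all(d >= -2 * se))
  expect_gt(cv$mean_dl[nrow(cv)], cv$mean_dl[1])
})
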