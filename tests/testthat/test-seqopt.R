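make_opt_problem <- function(n_signs = 6, n_diseases = 2, n_initial = 2,
                             seed = 131) {
  inst <- generate_instance(n_signs, n_diseases, seed = seed)
  m <- fit_from_true_marginals(inst)
  truth <- sample_hypothesis(inst, 1, seed = seed + 1)
  st <- initial_observations(inst, truth, n_initial, seed = seed + 2)
  list(inst = inst, m = m, st = st, infer = inference_backend(m))
}

# Exhaustive search over all ordered sequences of length n_steps.
exhaustive_best <- function(p, n_steps, params) {
  u <- unobserved_signs(p$st)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (x in v) {
      for (tail in perms(setdiff(v, x), k - 1)) {
        out[[length(out) + 1]] <- c(x, tail)
      }
    }
    out
  }
  seqs <- perms(u, n_steps)
  vals <- vapply(seqs, function(s) {
    evaluate_sequence(p$m, p$st, s, params, p$inst$weights, p$inst$costs,
                      p$infer)$objective
  }, 0)
  list(best = max(vals), seqs = seqs, vals = vals)
}

test_that("a length-one sequence reduces to the step objective", {
  p <- make_opt_problem()
  params <- objective_params(1, 0.1)
  u <- unobserved_signs(p$st)[1]
  ev <- evaluate_sequence(p$m, p$st, u, params, p$inst$weights, p$inst$costs,
                          p$infer)
  expect_equal(ev$objective, ev$trajectory$steps$total[1], tolerance = 1e-12)
})

test_that("sequence order matters through posterior conditioning", {
  p <- make_opt_problem(n_signs = 5, n_diseases = 2, n_initial = 1,
                        seed = 133)
  params <- objective_params(1, 0)
  u <- unobserved_signs(p$st)[1:3]
  orders <- list(u, u[c(1, 3, 2)], u[c(2, 1, 3)], u[c(2, 3, 1)],
                 u[c(3, 1, 2)], u[c(3, 2, 1)])
  vals <- vapply(orders, function(s) {
    evaluate_sequence(p$m, p$st, s, params, p$inst$weights, p$inst$costs,
                      p$infer)$objective
  }, 0)
  expect_gt(diff(range(vals)), 1e-8)
  # re-evaluation is deterministic
  v2 <- evaluate_sequence(p$m, p$st, u, params, p$inst$weights, p$inst$costs,
                          p$infer)$objective
  expect_identical(vals[1], v2)
})

test_that("invalid sequences are rejected", {
  p <- make_opt_problem()
  params <- objective_params()
  expect_error(evaluate_sequence(p$m, p$st, integer(0), params,
                                 p$inst$weights, p$inst$costs, p$infer),
               "empty")
  u <- unobserved_signs(p$st)
  expect_error(evaluate_sequence(p$m, p$st, c(u[1], u[1]), params,
                                 p$inst$weights, p$inst$costs, p$infer),
               "repeated")
  expect_error(evaluate_sequence(p$m, p$st, p$st$observed_idx[1], params,
                                 p$inst$weights, p$inst$costs, p$infer),
               "initial")
})

test_that("guided proposals keep the prefix and draw by positivity", {
  p <- make_opt_problem(n_signs = 7, n_diseases = 2, n_initial = 1,
                        seed = 135)
  current <- unobserved_signs(p$st)[1:4]
  for (k in 1:20) {
    prop <- propose_sequence(current, p$m, p$st, p$infer, seed = 200 + k)
    s <- prop$sequence
    expect_length(s, 4)
    expect_false(anyDuplicated(s) > 0)
    expect_false(any(s %in% p$st$observed_idx))
  }
  # frequency of the first drawn sign under full resampling (tau = 1) must
  # follow the initial positivity weights
  r0 <- p$infer(p$st)
  u <- unobserved_signs(p$st)
  w <- r0$sign_marginals[u]
  w <- w / sum(w)
  n_draw <- 4000
  # a length-1 sequence forces tau = 1, so the (single) element is always
  # freshly drawn from the initial-state positivity weights
  firsts <- vapply(seq_len(n_draw), function(k) {
    propose_sequence(u[1], p$m, p$st, p$infer, seed = 5000 + k)$sequence[1]
  }, 0L)
  emp <- as.vector(table(factor(firsts, levels = u))) / n_draw
  for (j in seq_along(u)) {
    se <- sqrt(w[j] * (1 - w[j]) / n_draw)
    expect_lt(abs(emp[j] - w[j]), 3 * se + 1e-9)
  }
})

test_that("accepted-objective trace is non-decreasing", {
  p <- make_opt_problem(n_signs = 8, n_diseases = 3, n_initial = 2,
                        seed = 137)
  cfg <- optimizer_config(n_max = 60, n_steps = 3,
                          params = objective_params(1, 0.1), seed = 138)
  out <- optimize_sequence(p$m, p$st, p$inst$weights, p$inst$costs, cfg,
                           p$infer)
  expect_true(all(diff(out$trace) >= 0))
  expect_gte(out$acceptance_rate, 0)
  expect_lte(out$acceptance_rate, 1)
  expect_equal(out$objective, out$trace[length(out$trace)])
})

test_that("optimizer finds the exhaustive optimum on tiny problems", {
  params <- objective_params(1, 0)
  hits <- 0L
  n_seeds <- 20L
  for (k in seq_len(n_seeds)) {
    p <- make_opt_problem(n_signs = 4, n_diseases = 2, n_initial = 0,
                          seed = 140 + k)
    ex <- exhaustive_best(p, 2, params)
    cfg <- optimizer_config(n_max = 200, n_steps = 2, params = params,
                            seed = 300 + k)
    out <- optimize_sequence(p$m, p$st, p$inst$weights, p$inst$costs, cfg,
                             p$infer)
    if (abs(out$objective - ex$best) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("optimized sequences beat random sequences on matched problems", {
  params <- objective_params(1, 0)
  wins <- 0L
  n_pairs <- 25L
  for (k in seq_len(n_pairs)) {
    p <- make_opt_problem(n_signs = 8, n_diseases = 2, n_initial = 2,
                          seed = 400 + k)
    cfg <- optimizer_config(n_max = 25, n_steps = 3, params = params,
                            seed = 500 + k)
    out <- optimize_sequence(p$m, p$st, p$inst$weights, p$inst$costs, cfg,
                             p$infer)
    rnd <- diagsim:::with_seed(600 + k, sample(unobserved_signs(p$st), 3))
    v_rnd <- evaluate_sequence(p$m, p$st, rnd, params, p$inst$weights,
                               p$inst$costs, p$infer)$objective
    if (out$objective >= v_rnd - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins / n_pairs, 0.9)
})
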