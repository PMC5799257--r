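#' Optimizer configuration
#'
#' @param n_max Number of propose/evaluate iterations.
#' @param n_steps Sequence length T.
#' @param params An [objective_params()].
#' @param seed Integer master seed for the optimizer.
#' @return List of class `optimizer_config`.
#' @export
optimizer_config <- function(n_max, n_steps, params = objective_params(),
                             seed = 1L) {
  if (!is_count(n_max) || n_max < 1L) stopf("n_max must be a positive count")
  structure(list(n_max = as.integer(n_max), n_steps = as.integer(n_steps),
                 params = params, seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Evaluate a fixed observation sequence
#'
#' Simulates the imputed diagnostic process (Diags-II) along a fixed
#' sequence of signs: each sign is observed at its most probable value
#' under the current posterior, inference is updated, and the per-step
#' objective terms are accumulated into the sequence objective
#' `sum_t ML(t) + lambda_P sum_t DP(t) - lambda_C sum_t SC(t)`.
#'
#' @param model A `maxent_model`.
#' @param initial_state `observation_state` holding the initial findings.
#' @param sequence Ordered distinct sign indices disjoint from the initial
#'   observations.
#' @param params An [objective_params()].
#' @param weights Per-disease weights.
#' @param costs Per-sign costs.
#' @param infer Inference backend; defaults to exhaustive enumeration.
#' @return List with `objective` and `trajectory` (a `trajectory` with
#'   `strategy = "sequence"`, no truth attached).
#' @export
evaluate_sequence <- function(model, initial_state, sequence, params,
                              weights, costs, infer = NULL) {
  if (is.null(infer)) infer <- inference_backend(model)
  sequence <- as.integer(sequence)
  if (anyDuplicated(sequence)) stopf("sequence contains repeated signs")
  if (any(sequence %in% initial_state$observed_idx)) {
    stopf("sequence overlaps the initial observations")
  }
  n_steps <- length(sequence)
  if (n_steps == 0L) stopf("sequence is empty")
  state <- initial_state
  result <- infer(state)
  steps <- data.frame(t = seq_len(n_steps), sign = sequence,
                      value = integer(n_steps), ml = numeric(n_steps),
                      dp = numeric(n_steps), sc = numeric(n_steps),
                      total = numeric(n_steps))
  marginals <- matrix(NA_real_, nrow = n_steps + 1L, ncol = model$n_diseases)
  marginals[1L, ] <- result$disease_marginals
  for (t in seq_len(n_steps)) {
    j <- sequence[t]
    v <- impute_value(result, j)
    state <- observe_sign(state, j, v)
    result <- infer(state)
    br <- step_objective(result, state, costs[j], params, weights)
    steps$value[t] <- v
    steps$ml[t] <- br$ml
    steps$dp[t] <- br$dp
    steps$sc[t] <- br$sc
    steps$total[t] <- br$total
    marginals[t + 1L, ] <- result$disease_marginals
  }
  traj <- structure(list(mode = "diags2", strategy = "sequence",
                         params = params, true_hypothesis = NULL,
                         initial_state = state, steps = steps,
                         marginals = marginals, dl0 = NA_real_),
                    class = "trajectory")
  list(objective = sequence_objective(traj, params), trajectory = traj)
}

#' Marginal-guided sequence proposal
#'
#' Proposes a new observation sequence from the current one: a time step
#' `tau` is chosen uniformly, the prefix before `tau` is kept, and from
#' `tau` onward each new sign is drawn from the still-unobserved signs with
#' probability proportional to `P(S_i = +1 | S^o(t - 1))`, the state being
#' advanced with imputed values as the suffix is built. Signs already used
#' are excluded and the weights renormalized; if the positive-probability
#' mass vanishes the draw falls back to uniform (flagged in the result).
#'
#' @param current Current sequence (ordered sign indices).
#' @param model A `maxent_model`.
#' @param initial_state `observation_state` of initial findings.
#' @param infer Inference backend.
#' @param seed Integer seed for the proposal draws.
#' @return List with `sequence` and `used_fallback`.
#' @export
propose_sequence <- function(current, model, initial_state, infer = NULL,
                             seed = 1L) {
  if (is.null(infer)) infer <- inference_backend(model)
  n_steps <- length(current)
  if (n_steps < 1L) stopf("current sequence is empty")
  with_seed(seed, {
    tau <- sample.int(n_steps, 1L)
    state <- initial_state
    result <- infer(state)
    new_seq <- integer(n_steps)
    if (tau > 1L) {
      for (t in seq_len(tau - 1L)) {
        j <- current[t]
        state <- observe_sign(state, j, impute_value(result, j))
        result <- infer(state)
        new_seq[t] <- j
      }
    }
    used_fallback <- FALSE
    for (t in tau:n_steps) {
      cand <- unobserved_signs(state)
      w <- result$sign_marginals[cand]
      if (!any(w > 0)) {
        used_fallback <- TRUE
        w <- rep(1, length(cand))
      }
      j <- if (length(cand) == 1L) cand else {
        cand[sample.int(length(cand), 1L, prob = w)]
      }
      state <- observe_sign(state, j, impute_value(result, j))
      result <- infer(state)
      new_seq[t] <- j
    }
    list(sequence = new_seq, used_fallback = used_fallback)
  })
}

#' Zero-temperature sequence optimization
#'
#' Optimizes a whole Diags-II observation sequence by stochastic local
#' search: starting from a uniformly drawn sequence, `n_max`
#' marginal-guided proposals are generated and each is accepted only if it
#' strictly increases the sequence objective. The accepted-objective trace
#' is therefore non-decreasing.
#'
#' @param model A `maxent_model`.
#' @param initial_state `observation_state` of initial findings.
#' @param weights Per-disease weights.
#' @param costs Per-sign costs.
#' @param cfg An [optimizer_config()].
#' @param infer Inference backend; defaults to exhaustive enumeration.
#' @return List with `sequence`, `objective`, `trajectory`,
#'   `acceptance_rate`, `n_accepted`, and `trace` (objective after each
#'   iteration).
#' @export
optimize_sequence <- function(model, initial_state, weights, costs, cfg,
                              infer = NULL) {
  if (is.null(infer)) infer <- inference_backend(model)
  n_free <- length(unobserved_signs(initial_state))
  if (n_free < cfg$n_steps) {
    stopf("sequence length exceeds the number of unobserved signs")
  }
  current <- with_seed(child_seed(cfg$seed, 1L), {
    sample(unobserved_signs(initial_state), cfg$n_steps)
  })
  ev <- evaluate_sequence(model, initial_state, current, cfg$params,
                          weights, costs, infer)
  trace <- numeric(cfg$n_max)
  n_acc <- 0L
  for (n in seq_len(cfg$n_max)) {
    prop <- propose_sequence(current, model, initial_state, infer,
                             seed = child_seed(cfg$seed, 100L + n))
    ev2 <- evaluate_sequence(model, initial_state, prop$sequence, cfg$params,
                             weights, costs, infer)
    if (ev2$objective - ev$objective > 0) {
      current <- prop$sequence
      ev <- ev2
      n_acc <- n_acc + 1L
    }
    trace[n] <- ev$objective
  }
  list(sequence = current, objective = ev$objective,
       trajectory = ev$trajectory, acceptance_rate = n_acc / cfg$n_max,
       n_accepted = n_acc, trace = trace)
}
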