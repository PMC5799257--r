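#' Most positive unobserved sign
#'
#' The unobserved sign with the largest probability of being positive,
#' `argmax_(i in U) P(S_i = +1 | S^o)`; ties go to the lowest index.
#'
#' @param result An `inference_result`.
#' @param state The matching `observation_state`.
#' @return A sign index.
#' @export
most_positive_sign <- function(result, state) {
  u <- unobserved_signs(state)
  if (length(u) == 0L) stopf("no unobserved signs left")
  u[which.max(result$sign_marginals[u])]
}

#' Impute the outcome of an unobserved sign
#'
#' The most probable value under the current posterior: `+1` if
#' `P(S_i = +1 | S^o) >= 1/2`, else `-1`.
#'
#' @param result An `inference_result`.
#' @param sign An unobserved sign index.
#' @return -1 or +1.
#' @export
impute_value <- function(result, sign) {
  p <- result$sign_marginals[sign]
  if (is.na(p)) stopf("sign %d is already observed", sign)
  if (p >= 0.5) 1L else -1L
}

#' Greedy one-step test selection
#'
#' Evaluates every unobserved sign as the next test: the candidate is
#' tentatively observed at its imputed (most probable) value, inference is
#' recomputed, and the per-step objective
#' `ML + lambda_P * DP - lambda_C * C_j` is evaluated. Returns the
#' candidate with the largest objective; ties go to the lowest sign index.
#'
#' @param model A `maxent_model` (used only through `infer`).
#' @param state Current `observation_state`.
#' @param params An [objective_params()].
#' @param weights Per-disease weights.
#' @param costs Per-sign observation costs.
#' @param infer Inference backend, `function(state) -> inference_result`.
#' @param result Optional current `inference_result` (recomputed if
#'   missing); supplies the imputation marginals.
#' @return List with `sign`, `value` (the imputed outcome), `breakdown`
#'   (an `objective_breakdown`) and `result` (inference after tentatively
#'   observing the chosen sign).
#' @export
greedy_choose <- function(model, state, params, weights, costs, infer,
                          result = NULL) {
  u <- unobserved_signs(state)
  if (length(u) == 0L) stopf("no unobserved signs left")
  if (is.null(result)) result <- infer(state)
  best <- NULL
  for (j in u) {
    v <- impute_value(result, j)
    st2 <- observe_sign(state, j, v)
    r2 <- infer(st2)
    br <- step_objective(r2, st2, costs[j], params, weights)
    if (is.null(best) || br$total > best$breakdown$total) {
      best <- list(sign = j, value = v, breakdown = br, result = r2)
    }
  }
  best
}

#' Simulate a sequential diagnostic process
#'
#' Runs the step-by-step diagnosis of a simulated patient with hidden
#' hypothesis `true_hypothesis`. At each of `n_steps` steps a previously
#' unobserved sign is selected (`"greedy"`: maximize the per-step
#' objective; `"random"`: uniformly at random) and observed:
#'
#' * `mode = "diags1"`: the recorded value is the patient's true sign (the
#'   most probable configuration of the true distribution), as if a real
#'   medical test were performed;
#' * `mode = "diags2"`: the recorded value is the model-imputed most
#'   probable value, so the whole process is a simulation requiring no new
#'   real observations.
#'
#' Posterior disease marginals (including the pre-sequential state, step 0)
#' and the per-step objective terms and posterior-truth overlap `DL(t)` are
#' recorded.
#'
#' @param instance A `problem_instance` (weights, costs, true signs).
#' @param model The fitted `maxent_model` used for inference.
#' @param true_hypothesis 0/1 disease vector of the simulated patient.
#' @param mode `"diags1"` or `"diags2"`.
#' @param strategy `"greedy"` or `"random"`.
#' @param n_steps Number of sequential observations T.
#' @param params An [objective_params()].
#' @param infer Inference backend; defaults to exhaustive enumeration.
#' @param n_initial Number of initial observations `N_O(0)` (ignored when
#'   `state` is given).
#' @param state Optional pre-built initial `observation_state`.
#' @param seed Integer seed controlling the initial-observation subset and
#'   any random sign choices.
#' @return An object of class `trajectory`: list with `mode`, `strategy`,
#'   `params`, `true_hypothesis`, `initial_state`, `steps` (data frame with
#'   columns `t`, `sign`, `value`, `true_value`, `ml`, `dp`, `sc`, `total`,
#'   `dl`), `marginals` (matrix of disease posteriors, rows t = 0..T) and
#'   `dl0`.
#' @export
run_diagnosis <- function(instance, model, true_hypothesis,
                          mode = c("diags1", "diags2"),
                          strategy = c("greedy", "random"),
                          n_steps, params = objective_params(),
                          infer = NULL, n_initial = 0L, state = NULL,
                          seed = 1L) {
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  if (is.null(infer)) infer <- inference_backend(model)
  if (is.null(state)) {
    state <- initial_observations(instance, true_hypothesis, n_initial,
                                  child_seed(seed, 1L))
  }
  if (n_steps > instance$n_signs - length(state$observed_idx)) {
    stopf("n_steps exceeds the number of unobserved signs")
  }
  weights <- instance$weights
  costs <- instance$costs
  s_true <- most_probable_true_signs(instance, true_hypothesis)

  # Uniform selection without replacement == a random permutation of the
  # initially unobserved signs, drawn once for reproducibility.
  random_order <- if (strategy == "random") {
    with_seed(child_seed(seed, 2L), sample(unobserved_signs(state)))
  } else NULL

  result <- infer(state)
  n_d <- model$n_diseases
  marginals <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n_d)
  marginals[1L, ] <- result$disease_marginals
  dl0 <- dl_overlap(result$disease_marginals, weights, true_hypothesis)

  steps <- data.frame(t = integer(n_steps), sign = integer(n_steps),
                      value = integer(n_steps), true_value = integer(n_steps),
                      ml = numeric(n_steps), dp = numeric(n_steps),
                      sc = numeric(n_steps), total = numeric(n_steps),
                      dl = numeric(n_steps))

  for (t in seq_len(n_steps)) {
    if (strategy == "greedy") {
      ch <- greedy_choose(model, state, params, weights, costs, infer, result)
      j <- ch$sign
      v_imp <- ch$value
    } else {
      j <- random_order[t]
      v_imp <- impute_value(result, j)
    }
    value <- if (mode == "diags1") s_true[j] else v_imp
    state <- observe_sign(state, j, value)
    result <- if (strategy == "greedy" && value == v_imp) ch$result else {
      infer(state)
    }
    br <- step_objective(result, state, costs[j], params, weights)
    marginals[t + 1L, ] <- result$disease_marginals
    steps$t[t] <- t
    steps$sign[t] <- j
    steps$value[t] <- value
    steps$true_value[t] <- s_true[j]
    steps$ml[t] <- br$ml
    steps$dp[t] <- br$dp
    steps$sc[t] <- br$sc
    steps$total[t] <- br$total
    steps$dl[t] <- dl_overlap(result$disease_marginals, weights,
                              true_hypothesis)
  }

  structure(list(mode = mode, strategy = strategy, params = params,
                 true_hypothesis = as.integer(true_hypothesis),
                 initial_state = state, steps = steps, marginals = marginals,
                 dl0 = dl0, seed = as.integer(seed)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory (%s strategy): %d steps, true hypothesis {%s}\n",
              x$mode, x$strategy, nrow(x$steps),
              hypothesis_key(x$true_hypothesis)))
  cat(sprintf("  DL: %.3f (t = 0) -> %.3f (t = %d)\n", x$dl0,
              if (nrow(x$steps) > 0) x$steps$dl[nrow(x$steps)] else x$dl0,
              nrow(x$steps)))
  invisible(x)
}
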