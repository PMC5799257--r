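#' Objective-function parameters
#'
#' Weights of the two auxiliary terms in the test-selection objective:
#' `lambda_P` scales the disease-polarization reward and `lambda_C` the
#' observation-cost penalty.
#'
#' @param lambda_P Non-negative polarization weight.
#' @param lambda_C Non-negative cost weight.
#' @return List of class `objective_params`.
#' @export
objective_params <- function(lambda_P = 0, lambda_C = 0) {
  if (lambda_P < 0 || lambda_C < 0) stopf("lambda weights must be non-negative")
  structure(list(lambda_P = lambda_P, lambda_C = lambda_C),
            class = "objective_params")
}

#' Normalized maximum log-likelihood term
#'
#' `ML(t) = log L(D^ML | S^o(t)) / |O(t)|`, the maximum of the disease
#' log-likelihood normalized by the number of observed signs (initial
#' findings included). The average over observation outcomes is realized by
#' the single most-probable-outcome branch of the simulation.
#'
#' @param result An `inference_result`.
#' @param state The `observation_state` the result was computed from.
#' @return Scalar.
#' @export
ml_term <- function(result, state) {
  n_obs <- length(state$observed_idx)
  if (n_obs == 0L) stopf("ML(t) is undefined with no observed signs")
  result$ml_log_likelihood / n_obs
}

#' Weighted disease-polarization term
#'
#' `DP(t) = sum_a W_a |P(D_a = 1 | S^o) - 1/2| / sum_a W_a`, in `[0, 1/2]`:
#' zero when every posterior sits at 1/2, maximal when all posteriors are
#' decisive (0 or 1). Disease weights emphasize e.g. life-threatening
#' conditions.
#'
#' @param result An `inference_result` (or a bare vector of disease
#'   marginals).
#' @param weights Strictly positive per-disease weights.
#' @return Scalar in `[0, 1/2]`.
#' @export
dp_term <- function(result, weights) {
  p <- if (inherits(result, "inference_result")) result$disease_marginals else result
  if (any(weights <= 0)) stopf("disease weights must be strictly positive")
  if (length(p) != length(weights)) stopf("marginals and weights differ in length")
  sum(weights * abs(p - 0.5)) / sum(weights)
}

#' Per-step test-selection objective
#'
#' `E(t) = ML(t) + lambda_P * DP(t) - lambda_C * SC(t)`, where `SC(t)` is
#' the cost of the sign chosen at step t.
#'
#' @inheritParams ml_term
#' @param cost_of_chosen Cost `C_j` of the chosen sign.
#' @param params An [objective_params()].
#' @param weights Per-disease weights for the polarization term.
#' @return List of class `objective_breakdown` with elements `ml`, `dp`,
#'   `sc` and `total`.
#' @export
step_objective <- function(result, state, cost_of_chosen, params, weights) {
  ml <- ml_term(result, state)
  dp <- dp_term(result, weights)
  structure(list(ml = ml, dp = dp, sc = cost_of_chosen,
                 total = ml + params$lambda_P * dp -
                   params$lambda_C * cost_of_chosen),
            class = "objective_breakdown")
}

#' Whole-sequence objective
#'
#' `E[O(T)] = sum_t ML(t) + lambda_P sum_t DP(t) - lambda_C sum_t SC(t)`,
#' the sum of the per-step objectives along a trajectory.
#'
#' @param trajectory A `trajectory` (see [run_diagnosis()]), or any object
#'   with a `steps` data frame holding columns `ml`, `dp`, `sc`.
#' @param params An [objective_params()].
#' @return Scalar objective value.
#' @export
sequence_objective <- function(trajectory, params) {
  st <- trajectory$steps
  if (is.null(st) || nrow(st) == 0L) stopf("trajectory has no steps")
  sum(st$ml) + params$lambda_P * sum(st$dp) - params$lambda_C * sum(st$sc)
}
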