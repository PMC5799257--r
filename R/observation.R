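#' Construct an observation state
#'
#' Tracks the ordered list of observed signs with their values, beginning
#' with the initial findings, and the set of still-unobserved signs. The
#' step counter `t` counts post-initial observations only.
#'
#' @param n_signs Total number of signs.
#' @param observed_idx Integer vector of observed sign indices, in
#'   observation order. The first `n_initial` are the initial findings.
#' @param observed_val -1/+1 values aligned with `observed_idx`.
#' @param n_initial Number of initial observations (defaults to all of
#'   `observed_idx`).
#' @return An object of class `observation_state`.
#' @export
observation_state <- function(n_signs, observed_idx = integer(0),
                              observed_val = integer(0),
                              n_initial = length(observed_idx)) {
  observed_idx <- as.integer(observed_idx)
  if (length(observed_idx) != length(observed_val)) {
    stopf("observed_idx and observed_val differ in length")
  }
  if (anyDuplicated(observed_idx)) stopf("a sign cannot be observed twice")
  if (length(observed_idx) > 0 &&
      (min(observed_idx) < 1L || max(observed_idx) > n_signs)) {
    stopf("observed sign index out of range")
  }
  if (length(observed_val) > 0) assert_sign_config(observed_val)
  if (n_initial > length(observed_idx)) {
    stopf("n_initial exceeds the number of observed signs")
  }
  structure(list(n_signs = as.integer(n_signs), observed_idx = observed_idx,
                 observed_val = as.integer(observed_val),
                 n_initial = as.integer(n_initial)),
            class = "observation_state")
}

#' @export
print.observation_state <- function(x, ...) {
  cat(sprintf("Observation state: %d/%d signs observed (%d initial, t = %d)\n",
              length(x$observed_idx), x$n_signs, x$n_initial,
              observation_step(x)))
  invisible(x)
}

#' @rdname observation_state
#' @param state An `observation_state`.
#' @export
unobserved_signs <- function(state) {
  setdiff(seq_len(state$n_signs), state$observed_idx)
}

#' @rdname observation_state
#' @export
observation_step <- function(state) {
  length(state$observed_idx) - state$n_initial
}

#' @rdname observation_state
#' @param sign Sign index to observe.
#' @param value Observed value, -1 or +1.
#' @export
observe_sign <- function(state, sign, value) {
  if (sign %in% state$observed_idx) stopf("sign %d already observed", sign)
  if (sign < 1L || sign > state$n_signs) stopf("sign index out of range")
  if (!value %in% c(-1L, 1L)) stopf("value must be -1 or +1")
  state$observed_idx <- c(state$observed_idx, as.integer(sign))
  state$observed_val <- c(state$observed_val, as.integer(value))
  state
}

#' Draw initial observations for a simulated patient
#'
#' Picks a uniformly random subset of signs of the requested size and
#' assigns each its true value under the patient's hypothesis (the most
#' probable sign from the true distribution).
#'
#' @param instance A `problem_instance`.
#' @param true_hypothesis 0/1 disease vector of the simulated patient.
#' @param n_initial Number of initial observations, between 0 and `n_signs`.
#' @param seed Integer seed.
#' @return An `observation_state` with `t = 0`.
#' @export
initial_observations <- function(instance, true_hypothesis, n_initial,
                                 seed = NULL) {
  if (!is_count(n_initial) || n_initial > instance$n_signs) {
    stopf("n_initial must be a count between 0 and n_signs")
  }
  s_true <- most_probable_true_signs(instance, true_hypothesis)
  with_seed(seed, {
    idx <- if (n_initial == 0L) integer(0) else {
      sort(sample.int(instance$n_signs, n_initial))
    }
    observation_state(instance$n_signs, idx, s_true[idx])
  })
}
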