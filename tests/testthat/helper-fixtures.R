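# Shared fixtures, built in code at test time.

small_instance <- function(n_signs = 10, n_diseases = 3, seed = 11) {
  generate_instance(n_signs, n_diseases, seed = seed)
}

small_model <- function(instance = small_instance(), order = "D2S1") {
  fit_from_true_marginals(instance, order = order)
}

# Brute-force log partition function by summing over all sign configs.
enum_log_partition <- function(model, hypothesis) {
  S <- diagsim:::enumerate_signs(model$n_signs)
  h <- local_fields(model, hypothesis)
  log(sum(exp(S %*% h)))
}

# Brute-force disease likelihood sum_{S^u} P(S|D) P0(D), fully normalized.
enum_likelihood <- function(model, state, hypothesis) {
  u <- unobserved_signs(state)
  prior <- sum(model$prior_fields * hypothesis) -
    sum(log1p(exp(model$prior_fields)))
  if (length(u) == 0) {
    s <- integer(model$n_signs)
    s[state$observed_idx] <- state$observed_val
    return(exp(prior + conditional_log_prob(model, s, hypothesis)))
  }
  Su <- diagsim:::enumerate_signs(length(u))
  tot <- 0
  for (r in seq_len(nrow(Su))) {
    s <- integer(model$n_signs)
    s[state$observed_idx] <- state$observed_val
    s[u] <- Su[r, ]
    tot <- tot + exp(conditional_log_prob(model, s, hypothesis))
  }
  tot * exp(prior)
}

# A random model with arbitrary (non-fitted) couplings on a full graph.
random_model <- function(n_signs, n_diseases, seed) {
  inst <- generate_instance(n_signs, n_diseases, seed = seed)
  m <- fit_from_true_marginals(inst)
  set.seed(seed + 1)
  m$leak_fields <- rnorm(n_signs, sd = 0.7)
  m$one_couplings <- lapply(m$one_couplings, function(f) {
    f$K <- rnorm(length(f$K), sd = 0.7); f
  })
  m$two_couplings <- lapply(m$two_couplings, function(f) {
    f$K <- rnorm(length(f$K), sd = 0.7); f
  })
  m$prior_fields <- rnorm(n_diseases, sd = 0.5)
  m
}

# Random observation state over a model's signs.
random_state <- function(n_signs, n_obs, seed) {
  set.seed(seed)
  idx <- sort(sample.int(n_signs, n_obs))
  observation_state(n_signs, idx, sample(c(-1L, 1L), n_obs, replace = TRUE))
}
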