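#' Negative log-likelihood of a disease hypothesis
#'
#' Energy of hypothesis D given the observed signs:
#' `H(D | S^o) = -sum_a Ka0 D_a - sum_(i in O) S_i h_i(D)
#'   + sum_(i in O) ln(2 cosh h_i(D))`.
#' Unobserved signs marginalize to one and contribute nothing. Up to an
#' additive constant independent of D, `-H` is the log of the disease
#' likelihood `L(D | S^o) = sum_(S^u) P(S | D) P0(D)`.
#'
#' @param model A `maxent_model`.
#' @param state An `observation_state`.
#' @param hypothesis 0/1 disease vector.
#' @return Scalar energy (negative log-likelihood).
#' @export
neg_log_likelihood <- function(model, state, hypothesis) {
  hypothesis <- assert_disease_config(hypothesis, model$n_diseases)
  e <- -sum(model$prior_fields * hypothesis)
  o <- state$observed_idx
  if (length(o) > 0) {
    h <- local_fields(model, hypothesis)[o]
    e <- e - sum(state$observed_val * h) + sum(log2cosh(h))
  }
  e
}

#' Precompute the exhaustive-enumeration inference engine
#'
#' Tabulates, for all `2^n_diseases` hypotheses, the local fields on every
#' sign, their `ln 2cosh`, the implied per-sign probabilities
#' `(1 + tanh h) / 2` and the prior energy term. Posterior computations for
#' any observation state then reduce to a few small matrix products, which
#' makes repeated inference inside diagnostic simulations cheap.
#'
#' @param model A `maxent_model` with `n_diseases <= 20`.
#' @return An object of class `exact_engine`.
#' @export
exact_engine <- function(model) {
  nd <- model$n_diseases
  if (nd > 20L) {
    stopf(paste("exhaustive enumeration is limited to 20 diseases;",
                "use mc_infer() for larger models"))
  }
  dmat <- enumerate_binary(nd)
  nh <- nrow(dmat)
  hmat <- matrix(model$leak_fields, nrow = nh, ncol = model$n_signs,
                 byrow = TRUE)
  for (f in model$one_couplings) {
    rows <- dmat[, f$disease] == 1L
    hmat[rows, f$signs] <- hmat[rows, f$signs] +
      matrix(f$K, nrow = sum(rows), ncol = length(f$K), byrow = TRUE)
  }
  for (f in model$two_couplings) {
    rows <- dmat[, f$pair[1]] == 1L & dmat[, f$pair[2]] == 1L
    hmat[rows, f$signs] <- hmat[rows, f$signs] +
      matrix(f$K, nrow = sum(rows), ncol = length(f$K), byrow = TRUE)
  }
  structure(list(dmat = dmat, hmat = hmat, l2c = log2cosh(hmat),
                 tmat = (1 + tanh(hmat)) / 2,
                 prior_term = as.vector(dmat %*% model$prior_fields),
                 n_signs = model$n_signs, n_diseases = nd),
            class = "exact_engine")
}

# Hypothesis energies for an observation state, vectorized over all
# enumerated hypotheses.
engine_energies <- function(engine, state) {
  o <- state$observed_idx
  e <- -engine$prior_term
  if (length(o) > 0) {
    e <- e - as.vector(engine$hmat[, o, drop = FALSE] %*% state$observed_val) +
      rowSums(engine$l2c[, o, drop = FALSE])
  }
  e
}

inference_result <- function(disease_marginals, sign_marginals, ml_hypothesis,
                             ml_log_likelihood, method) {
  structure(list(disease_marginals = disease_marginals,
                 sign_marginals = sign_marginals,
                 ml_hypothesis = ml_hypothesis,
                 ml_log_likelihood = ml_log_likelihood, method = method),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("Inference result (%s):\n", x$method))
  cat("  disease marginals:",
      paste(format(x$disease_marginals, digits = 3), collapse = " "), "\n")
  cat(sprintf("  ML hypothesis {%s}, log-likelihood %.4f\n",
              hypothesis_key(x$ml_hypothesis), x$ml_log_likelihood))
  invisible(x)
}

#' Exact posterior inference by exhaustive enumeration
#'
#' Enumerates all `2^n_diseases` hypotheses to compute the disease
#' posterior marginals `P(D_a = 1 | S^o)`, the marginals of unobserved
#' signs `P(S_i = +1 | S^o)` (a posterior-weighted mixture of
#' `(1 + tanh h_i(D)) / 2`), and the global maximum-likelihood hypothesis
#' with its log-likelihood `-H`.
#'
#' @param model A `maxent_model`.
#' @param state An `observation_state`.
#' @param engine Optional precomputed [exact_engine()] for `model`.
#' @return An `inference_result`; `sign_marginals` is a full-length vector
#'   with `NA` at observed positions.
#' @export
exact_infer <- function(model, state, engine = NULL) {
  if (is.null(engine)) engine <- exact_engine(model)
  e <- engine_energies(engine, state)
  logw <- -e - max(-e)
  w <- exp(logw)
  w <- w / sum(w)
  dmarg <- as.vector(crossprod(engine$dmat, w))
  smarg <- as.vector(crossprod(engine$tmat, w))
  smarg[state$observed_idx] <- NA_real_
  iml <- which.min(e)
  inference_result(dmarg, smarg, engine$dmat[iml, ], -e[iml], "exact")
}

#' Monte Carlo inference configuration
#'
#' Settings for Metropolis marginal estimation and simulated-annealing
#' maximum-likelihood search. Defaults follow the reference protocol:
#' 20000 sweeps with 2000 for equilibration and samples every 20 sweeps at
#' inverse temperature 1; annealing raises beta linearly from 1 to 10 over
#' 5000 sweeps. One sweep attempts `n_diseases` single-disease flips.
#'
#' @param n_total Total Metropolis sweeps.
#' @param n_eq Equilibration sweeps discarded before sampling.
#' @param n_sample Sampling stride in sweeps.
#' @param beta Inverse temperature for marginal estimation.
#' @param beta_start,beta_end Annealing schedule endpoints.
#' @param n_annealing Annealing sweeps.
#' @param seed Integer seed for the sampler.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_total = 20000L, n_eq = 2000L, n_sample = 20L,
                      beta = 1, beta_start = 1, beta_end = 10,
                      n_annealing = 5000L, seed = 1L) {
  if (n_eq >= n_total) stopf("n_eq must be smaller than n_total")
  if (n_sample < 1L) stopf("n_sample must be at least 1")
  if (beta_end <= beta_start) stopf("beta_end must exceed beta_start")
  structure(list(n_total = as.integer(n_total), n_eq = as.integer(n_eq),
                 n_sample = as.integer(n_sample), beta = beta,
                 beta_start = beta_start, beta_end = beta_end,
                 n_annealing = as.integer(n_annealing),
                 seed = as.integer(seed)),
            class = "mc_config")
}

# Flatten a maxent_model into the plain vectors the C++ sampler expects
# (0-based indices).
model_cdata <- function(model) {
  list(ns = model$n_signs, nd = model$n_diseases,
       k0 = as.numeric(model$leak_fields),
       kprior = as.numeric(model$prior_fields),
       one_d = vapply(model$one_couplings, function(f) f$disease - 1L, 0L),
       one_signs = lapply(model$one_couplings, function(f) f$signs - 1L),
       one_k = lapply(model$one_couplings, function(f) as.numeric(f$K)),
       two_a = vapply(model$two_couplings, function(f) f$pair[1] - 1L, 0L),
       two_b = vapply(model$two_couplings, function(f) f$pair[2] - 1L, 0L),
       two_signs = lapply(model$two_couplings, function(f) f$signs - 1L),
       two_k = lapply(model$two_couplings, function(f) as.numeric(f$K)))
}

#' Monte Carlo posterior inference
#'
#' Metropolis sampling over disease configurations with energy
#' `H(D | S^o)` at inverse temperature `cfg$beta` estimates the disease and
#' unobserved-sign marginals; a subsequent simulated-annealing run supplies
#' the maximum-likelihood hypothesis. Estimates converge to the
#' [exact_infer()] values as the sweep budget grows, and runs are
#' reproducible given `cfg$seed`.
#'
#' @inheritParams exact_infer
#' @param cfg An [mc_config()].
#' @return An `inference_result` with `method = "mc"`.
#' @export
mc_infer <- function(model, state, cfg = mc_config()) {
  cd <- model_cdata(model)
  res <- cpp_mc_marginals(cd$ns, cd$nd, cd$k0, cd$kprior, cd$one_d,
                          cd$one_signs, cd$one_k, cd$two_a, cd$two_b,
                          cd$two_signs, cd$two_k,
                          state$observed_idx - 1L, state$observed_val,
                          cfg$n_total, cfg$n_eq, cfg$n_sample, cfg$beta,
                          cfg$seed)
  ml <- sa_max_likelihood(model, state, cfg)
  smarg <- res$sign_marginals
  smarg[state$observed_idx] <- NA_real_
  inference_result(res$disease_marginals, smarg, ml$hypothesis,
                   ml$log_likelihood, "mc")
}

#' Maximum-likelihood hypothesis by simulated annealing
#'
#' Anneals the Metropolis sampler on `H(D | S^o)` with inverse temperature
#' raised linearly from `cfg$beta_start` to `cfg$beta_end` over
#' `cfg$n_annealing` sweeps, returning the best-energy configuration ever
#' visited and its log-likelihood `-H`.
#'
#' @inheritParams mc_infer
#' @return List with `hypothesis` (0/1 vector) and `log_likelihood`.
#' @export
sa_max_likelihood <- function(model, state, cfg = mc_config()) {
  cd <- model_cdata(model)
  res <- cpp_sa_ml(cd$ns, cd$nd, cd$k0, cd$kprior, cd$one_d, cd$one_signs,
                   cd$one_k, cd$two_a, cd$two_b, cd$two_signs, cd$two_k,
                   state$observed_idx - 1L, state$observed_val,
                   cfg$n_annealing, cfg$beta_start, cfg$beta_end,
                   child_seed(cfg$seed, 77L))
  list(hypothesis = as.integer(res$best_d), log_likelihood = res$best_loglik)
}

#' Build a reusable inference backend
#'
#' Returns a closure `function(state)` performing inference with a fixed
#' model: exhaustive enumeration (with the engine precomputed once) or
#' Monte Carlo. Diagnosis simulations and the sequence optimizer are
#' backend-agnostic and accept any such closure.
#'
#' @param model A `maxent_model`.
#' @param method `"exact"` or `"mc"`.
#' @param cfg [mc_config()] used when `method = "mc"`.
#' @return A function mapping an `observation_state` to an
#'   `inference_result`.
#' @export
inference_backend <- function(model, method = c("exact", "mc"),
                              cfg = mc_config()) {
  method <- match.arg(method)
  if (method == "exact") {
    engine <- exact_engine(model)
    function(state) exact_infer(model, state, engine)
  } else {
    function(state) mc_infer(model, state, cfg)
  }
}
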