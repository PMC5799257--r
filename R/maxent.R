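#' Calibrate the factorized disease prior
#'
#' The prior over diseases is factorized,
#' `P0(D_a) = exp(Ka0 * D_a) / (1 + exp(Ka0))`, with a common field chosen so
#' that the expected number of present diseases matches a target:
#' `n_diseases * P0(D_a = 1) = expected_present`.
#'
#' @param n_diseases Number of diseases.
#' @param expected_present Target expected number of present diseases,
#'   strictly between 0 and `n_diseases`.
#' @return List with `per_disease_prob` and `prior_fields` (the log-odds
#'   `ln(p / (1 - p))`, recycled to length `n_diseases`).
#' @examples
#' calibrate_prior(5, 2)$per_disease_prob  # 0.4
#' @export
calibrate_prior <- function(n_diseases, expected_present) {
  if (!is_count(n_diseases) || n_diseases < 1L) {
    stopf("n_diseases must be a positive count")
  }
  if (!is.numeric(expected_present) || expected_present <= 0 ||
      expected_present >= n_diseases) {
    stopf("expected_present must lie strictly between 0 and n_diseases")
  }
  p <- expected_present / n_diseases
  list(per_disease_prob = rep(p, n_diseases),
       prior_fields = rep(log(p / (1 - p)), n_diseases))
}

# Half log-odds of a +1 observation; the elementary fitting step.
half_logodds <- function(p_plus) {
  if (any(p_plus <= 0) || any(p_plus >= 1)) {
    stopf("degenerate true marginal (0 or 1) implies an infinite coupling")
  }
  0.5 * log(p_plus / (1 - p_plus))
}

#' Fit a maximum-entropy disease-sign model from true conditional marginals
#'
#' Computes the model parameters exactly from single-sign conditional
#' marginals of the true distribution: the leak fields from
#' `P_true(S_i | no disease)`, single-disease couplings from
#' `P_true(S_i | only D_a)` and (for order `"D2S1"`) two-disease couplings
#' from `P_true(S_i | only D_a, D_b)`, each as half log-odds with the
#' lower-order terms subtracted. Couplings are stored only for signs
#' connected to the corresponding factor in the interaction graph;
#' unconnected signs implicitly carry zero coupling.
#'
#' Under the exponential benchmark truth the fit reduces to
#' `Ki0 = S_i(empty)/2`, `Kia = S_i(a)/2 - Ki0` and
#' `Kiab = S_i(ab)/2 - Ki0 - Kia - Kib`.
#'
#' @param instance A `problem_instance` providing the true marginals.
#' @param order `"D2S1"` (default) or `"D1S1"` (no two-disease couplings).
#' @param prior Prior specification as returned by [calibrate_prior()];
#'   defaults to an expected two present diseases.
#' @return An object of class `maxent_model`.
#' @export
fit_from_true_marginals <- function(instance, order = c("D2S1", "D1S1"),
                                    prior = calibrate_prior(instance$n_diseases,
                                                            min(2, instance$n_diseases / 2))) {
  order <- match.arg(order)
  ns <- instance$n_signs
  graph <- instance$graph

  p0 <- vapply(seq_len(ns), function(i) {
    true_sign_prob(instance, i, integer(instance$n_diseases), 1L)
  }, 0)
  leak <- half_logodds(p0)

  one <- lapply(graph$one_factors, function(f) {
    d <- integer(instance$n_diseases); d[f$disease] <- 1L
    p <- vapply(f$signs, function(i) true_sign_prob(instance, i, d, 1L), 0)
    list(disease = f$disease, signs = f$signs,
         K = half_logodds(p) - leak[f$signs])
  })

  two <- list()
  if (order == "D2S1" && length(graph$two_factors) > 0L) {
    # Single-disease coupling lookup: Kia is zero off-factor.
    ka_of <- function(a, signs) {
      out <- numeric(length(signs))
      for (f in one) {
        if (f$disease == a) {
          m <- match(signs, f$signs)
          hit <- !is.na(m)
          out[hit] <- f$K[m[hit]]
        }
      }
      out
    }
    two <- lapply(graph$two_factors, function(f) {
      d <- integer(instance$n_diseases); d[f$pair] <- 1L
      p <- vapply(f$signs, function(i) true_sign_prob(instance, i, d, 1L), 0)
      list(pair = f$pair, signs = f$signs,
           K = half_logodds(p) - leak[f$signs] -
             ka_of(f$pair[1], f$signs) - ka_of(f$pair[2], f$signs))
    })
  }

  structure(list(order = order, n_signs = ns,
                 n_diseases = instance$n_diseases, graph = graph,
                 leak_fields = leak, one_couplings = one, two_couplings = two,
                 prior_fields = prior$prior_fields,
                 prior_prob = prior$per_disease_prob),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("%s maximum-entropy model: %d signs, %d diseases\n",
              x$order, x$n_signs, x$n_diseases))
  cat(sprintf("  %d single-disease factors, %d two-disease factors\n",
              length(x$one_couplings), length(x$two_couplings)))
  cat(sprintf("  prior P(D_a = 1) = %s\n",
              paste(format(unique(x$prior_prob), digits = 3), collapse = ", ")))
  invisible(x)
}

#' Local fields on all signs under a disease hypothesis
#'
#' The effective bias on sign i is
#' `h_i(D) = Ki0 + sum_a Kia D_a + sum_(a<b) Kiab D_a D_b`,
#' with sums running over factors connected to sign i.
#'
#' @param model A `maxent_model`.
#' @param hypothesis 0/1 disease vector.
#' @return Numeric vector of length `n_signs`.
#' @export
local_fields <- function(model, hypothesis) {
  hypothesis <- assert_disease_config(hypothesis, model$n_diseases)
  h <- model$leak_fields
  for (f in model$one_couplings) {
    if (hypothesis[f$disease] == 1L) h[f$signs] <- h[f$signs] + f$K
  }
  for (f in model$two_couplings) {
    if (hypothesis[f$pair[1]] == 1L && hypothesis[f$pair[2]] == 1L) {
      h[f$signs] <- h[f$signs] + f$K
    }
  }
  h
}

#' @rdname local_fields
#' @param sign Single sign index.
#' @export
local_field <- function(model, sign, hypothesis) {
  if (!is_count(sign) || sign < 1L || sign > model$n_signs) {
    stopf("sign index out of range")
  }
  local_fields(model, hypothesis)[sign]
}

#' Log partition function of the sign distribution
#'
#' With only single-sign couplings the partition function factorizes over
#' signs: `ln Z(D) = sum_i ln(2 cosh h_i(D))`, evaluated in the
#' overflow-safe form `|h| + ln(1 + exp(-2|h|))`.
#'
#' @inheritParams local_fields
#' @return Scalar `ln Z(D)`.
#' @export
log_partition <- function(model, hypothesis) {
  sum(log2cosh(local_fields(model, hypothesis)))
}

#' Conditional log-probability of a full sign configuration
#'
#' `ln P(S | D) = sum_i S_i h_i(D) - ln Z(D)`.
#'
#' @inheritParams local_fields
#' @param signs -1/+1 configuration of length `n_signs`.
#' @return Scalar log probability.
#' @export
conditional_log_prob <- function(model, signs, hypothesis) {
  signs <- assert_sign_config(signs, model$n_signs)
  h <- local_fields(model, hypothesis)
  sum(signs * h) - sum(log2cosh(h))
}
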