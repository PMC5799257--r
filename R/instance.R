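#' Generate a synthetic diagnostic benchmark problem
#'
#' Creates a complete synthetic "true world" for diagnostic simulations: a
#' bipartite interaction graph between diseases and signs, per-disease
#' weights and per-sign observation costs drawn i.i.d. uniform on (0, 1),
#' and, for the all-healthy hypothesis and every factored disease subset, a
#' sign configuration attributed uniformly at random from \{-1, +1\}^NS.
#' The attributed configurations define the true exponential sign
#' distribution evaluated by [true_sign_prob()].
#'
#' The default graph is fully connected: one single-disease factor per
#' disease and one two-disease factor per disease pair, every factor touching
#' all signs. Sparse graphs are obtained by passing `graph_params` with
#' `M_a` single-disease factors, `M_ab` two-disease factors (distinct pairs
#' drawn uniformly) and factor connectivities `k_a`, `k_ab` (sign subsets
#' drawn uniformly without replacement).
#'
#' @param n_signs Number of binary sign variables (clinical findings).
#' @param n_diseases Number of binary disease variables.
#' @param graph_params Optional list with elements `M_a`, `M_ab`, `k_a`,
#'   `k_ab`. Defaults to the fully connected graph.
#' @param seed Integer seed; the instance is a deterministic function of it.
#' @return An object of class `problem_instance`: a list with elements
#'   `n_signs`, `n_diseases`, `graph`, `weights`, `costs`,
#'   `attributed_signs` (named list keyed by disease subset) and `seed`.
#' @examples
#' inst <- generate_instance(20, 5, seed = 1)
#' length(inst$graph$one_factors)
#' @export
generate_instance <- function(n_signs, n_diseases, graph_params = NULL,
                              seed = 1L) {
  if (!is_count(n_signs) || n_signs < 1L) stopf("n_signs must be a positive count")
  if (!is_count(n_diseases) || n_diseases < 1L) {
    stopf("n_diseases must be a positive count")
  }
  n_pairs_max <- n_diseases * (n_diseases - 1) / 2
  if (is.null(graph_params)) {
    graph_params <- list(M_a = n_diseases, M_ab = n_pairs_max,
                         k_a = n_signs, k_ab = n_signs)
  }
  gp <- graph_params
  for (nm in c("M_a", "M_ab", "k_a", "k_ab")) {
    if (is.null(gp[[nm]]) || !is_count(gp[[nm]])) {
      stopf("graph_params$%s must be a non-negative count", nm)
    }
  }
  if (gp$M_a > n_diseases) stopf("M_a exceeds the number of diseases")
  if (gp$M_ab > n_pairs_max) stopf("M_ab exceeds the number of disease pairs")
  if (gp$k_a > n_signs || gp$k_ab > n_signs) {
    stopf("factor connectivity exceeds the number of signs")
  }

  with_seed(seed, {
    # Which diseases own a single-disease factor.
    fac_diseases <- if (gp$M_a == n_diseases) seq_len(n_diseases) else {
      sort(sample.int(n_diseases, gp$M_a))
    }
    one_factors <- lapply(fac_diseases, function(a) {
      signs <- if (gp$k_a == n_signs) seq_len(n_signs) else {
        sort(sample.int(n_signs, gp$k_a))
      }
      list(disease = a, signs = signs)
    })

    # Distinct disease pairs for two-disease factors.
    two_factors <- list()
    if (gp$M_ab > 0L) {
      all_pairs <- which(upper.tri(matrix(0, n_diseases, n_diseases)),
                         arr.ind = TRUE)
      pick <- if (gp$M_ab == nrow(all_pairs)) seq_len(nrow(all_pairs)) else {
        sort(sample.int(nrow(all_pairs), gp$M_ab))
      }
      two_factors <- lapply(pick, function(r) {
        signs <- if (gp$k_ab == n_signs) seq_len(n_signs) else {
          sort(sample.int(n_signs, gp$k_ab))
        }
        list(pair = as.integer(c(all_pairs[r, 1L], all_pairs[r, 2L])),
             signs = signs)
      })
    }

    graph <- list(n_signs = n_signs, n_diseases = n_diseases,
                  M_a = gp$M_a, M_ab = gp$M_ab, k_a = gp$k_a, k_ab = gp$k_ab,
                  one_factors = one_factors, two_factors = two_factors)

    weights <- stats::runif(n_diseases)
    costs <- stats::runif(n_signs)

    # Attributed sign configurations for the all-healthy hypothesis and
    # every factored subset, each uniform over {-1,+1}^NS.
    keys <- c("",
              vapply(one_factors, function(f) as.character(f$disease), ""),
              vapply(two_factors, function(f) paste(f$pair, collapse = ","), ""))
    attributed <- lapply(keys, function(k) {
      sample(c(-1L, 1L), n_signs, replace = TRUE)
    })
    names(attributed) <- keys

    structure(list(n_signs = n_signs, n_diseases = n_diseases, graph = graph,
                   weights = weights, costs = costs,
                   attributed_signs = attributed, seed = as.integer(seed)),
              class = "problem_instance")
  })
}

#' @export
print.problem_instance <- function(x, ...) {
  cat(sprintf("Synthetic diagnostic problem: %d signs, %d diseases\n",
              x$n_signs, x$n_diseases))
  cat(sprintf("  factors: %d single-disease (k=%d), %d two-disease (k=%d)\n",
              x$graph$M_a, x$graph$k_a, x$graph$M_ab, x$graph$k_ab))
  cat(sprintf("  attributed hypotheses: %d, seed: %d\n",
              length(x$attributed_signs), x$seed))
  invisible(x)
}

attributed_for <- function(instance, hypothesis) {
  key <- hypothesis_key(hypothesis)
  # match() rather than [[ ]]: the all-healthy key is the empty string,
  # which [[ ]] never matches.
  idx <- match(key, names(instance$attributed_signs))
  if (is.na(idx)) {
    stopf("no attributed sign configuration for hypothesis {%s}", key)
  }
  instance$attributed_signs[[idx]]
}

#' True per-sign observation probability
#'
#' The synthetic benchmark assumes signs are distributed, given a disease
#' hypothesis D, as `P(S|D) = exp(-H(S, S(D))) / Z`, where `H` is the
#' Hamming distance to the attributed configuration `S(D)` and
#' `Z = (1 + e^-1)^NS`. Because the Hamming distance is a sum over signs,
#' the distribution factorizes; this function returns the single-sign factor
#' `P(S_i = value | D)`, which is `e/(1+e)` when `value` matches the
#' attributed sign and `1/(1+e)` otherwise.
#'
#' @param instance A `problem_instance`.
#' @param sign Sign index (1-based).
#' @param hypothesis 0/1 disease vector whose subset has an attribution.
#' @param value Sign value, -1 or +1.
#' @return Probability in (0, 1).
#' @export
true_sign_prob <- function(instance, sign, hypothesis, value) {
  if (!is_count(sign) || sign < 1L || sign > instance$n_signs) {
    stopf("sign index out of range")
  }
  if (!value %in% c(-1, 1)) stopf("value must be -1 or +1")
  s_attr <- attributed_for(instance, hypothesis)
  exp(-(value != s_attr[sign])) / (1 + exp(-1))
}

#' Most probable sign configuration under the true model
#'
#' The mode of the true exponential distribution given hypothesis D is the
#' attributed configuration S(D) itself (zero Hamming distance). These are
#' the values a real medical test would reveal in simulated diagnoses.
#'
#' @inheritParams true_sign_prob
#' @return Integer vector of -1/+1 of length `n_signs`.
#' @export
most_probable_true_signs <- function(instance, hypothesis) {
  attributed_for(instance, hypothesis)
}

#' Draw a true disease hypothesis for simulation
#'
#' Samples the hypothesis a simulated patient actually has. With one present
#' disease, disease a is drawn with probability proportional to its weight
#' W_a. With two present diseases, eligible pairs are those owning a
#' two-disease factor in the graph, drawn with probability proportional to
#' W_a + W_b.
#'
#' @param instance A `problem_instance`.
#' @param n_present Number of present diseases, 1 or 2.
#' @param seed Integer seed.
#' @return 0/1 disease vector of length `n_diseases`.
#' @export
sample_hypothesis <- function(instance, n_present, seed = NULL) {
  nd <- instance$n_diseases
  if (!n_present %in% c(1L, 2L)) stopf("n_present must be 1 or 2")
  with_seed(seed, {
    d <- integer(nd)
    if (n_present == 1L) {
      eligible <- vapply(instance$graph$one_factors, `[[`, 0L, "disease")
      if (length(eligible) == 0L) stopf("no factored single-disease hypothesis")
      w <- instance$weights[eligible]
      d[eligible[sample.int(length(eligible), 1L, prob = w)]] <- 1L
    } else {
      pairs <- instance$graph$two_factors
      if (length(pairs) == 0L) {
        stopf("no two-disease factor: cannot sample a two-disease hypothesis")
      }
      w <- vapply(pairs, function(f) sum(instance$weights[f$pair]), 0)
      d[pairs[[sample.int(length(pairs), 1L, prob = w)]]$pair] <- 1L
    }
    d
  })
}

#' Hamming distance between two sign configurations
#'
#' Number of positions at which two -1/+1 configurations differ, computed as
#' `sum((a - b)^2) / 4`.
#'
#' @param a,b Sign vectors of equal length with entries -1/+1.
#' @return Integer count in `[0, length(a)]`.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stopf("sign configurations differ in length")
  as.integer(sum((a - b)^2) / 4)
}

#' Evaluate the true joint sign distribution
#'
#' Full-configuration probability `exp(-H(S, S(D))) / (1 + e^-1)^NS` of the
#' benchmark model; used mainly as an enumeration oracle in tests.
#'
#' @param instance A `problem_instance`.
#' @param signs -1/+1 configuration of length `n_signs`.
#' @param hypothesis 0/1 disease vector.
#' @return Probability.
#' @export
true_config_prob <- function(instance, signs, hypothesis) {
  s_attr <- attributed_for(instance, hypothesis)
  assert_sign_config(signs, instance$n_signs)
  h <- hamming_distance(signs, s_attr)
  exp(-h) / (1 + exp(-1))^instance$n_signs
}
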