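#' Overlap of the disease posterior with the truth
#'
#' `DL(t) = sum_a W_a (2 D_a^true - 1)(P(D_a = 1 | S^o) - 1/2) / sum_a W_a`,
#' in `[-1/2, 1/2]`: +1/2 when every posterior matches the true
#' presence/absence exactly, 0 when posteriors are uninformative, negative
#' when they point the wrong way.
#'
#' @param disease_marginals Posterior `P(D_a = 1 | S^o)` per disease.
#' @param weights Strictly positive disease weights.
#' @param true_hypothesis 0/1 disease vector.
#' @return Scalar in `[-1/2, 1/2]`.
#' @export
dl_overlap <- function(disease_marginals, weights, true_hypothesis) {
  if (any(weights <= 0)) stopf("disease weights must be strictly positive")
  sum(weights * (2 * true_hypothesis - 1) * (disease_marginals - 0.5)) /
    sum(weights)
}

#' First right and wrong diagnosis times
#'
#' Scans the recorded disease posteriors of a trajectory in step order
#' (step 0, the post-initial-observation state, included). `T_R` is the
#' first step at which some truly present disease satisfies
#' `P(D_a = 1 | S^o(t)) >= p_th`; `T_W` the first step at which some absent
#' disease does. A process that never crosses the threshold gets the
#' sentinel value `T + 1`.
#'
#' @param trajectory A `trajectory` with a `marginals` matrix (rows
#'   t = 0..T).
#' @param true_set Indices of the truly present diseases (defaults to the
#'   trajectory's `true_hypothesis`).
#' @param p_th Threshold probability in (1/2, 1).
#' @return List of class `diagnosis_times` with `T_R`, `T_W` and `T_max`.
#' @export
first_diagnosis_times <- function(trajectory, true_set = NULL, p_th = 0.9) {
  if (p_th <= 0.5 || p_th >= 1) stopf("p_th must lie in (1/2, 1)")
  if (is.null(true_set)) {
    if (is.null(trajectory$true_hypothesis)) {
      stopf("true_set is required when the trajectory carries no truth")
    }
    true_set <- which(trajectory$true_hypothesis == 1L)
  }
  m <- trajectory$marginals
  t_max <- nrow(m) - 1L
  n_d <- ncol(m)
  false_set <- setdiff(seq_len(n_d), true_set)
  t_r <- t_w <- t_max + 1L
  for (t in 0:t_max) {
    row <- m[t + 1L, ]
    if (t_r > t_max && length(true_set) > 0 && any(row[true_set] >= p_th)) {
      t_r <- t
    }
    if (t_w > t_max && length(false_set) > 0 && any(row[false_set] >= p_th)) {
      t_w <- t
    }
    if (t_r <= t_max && t_w <= t_max) break
  }
  structure(list(T_R = t_r, T_W = t_w, T_max = t_max),
            class = "diagnosis_times")
}

#' Aggregate diagnosis-time and overlap curves over realizations
#'
#' Builds, over a set of simulated realizations, the empirical cumulative
#' probabilities `P(T_R <= t)` and `P(T_W <= t)` for t = 0..T_max (sentinel
#' realizations never count), their difference
#' `deltaP(t) = P(T_R <= t) - P(T_W <= t)`, and the mean `DL(t)` and mean
#' cumulative observation cost curves with standard errors.
#'
#' @param times List of `diagnosis_times` (one per realization).
#' @param trajectories Optional list of matching `trajectory` objects, used
#'   for the DL and cost curves.
#' @param t_max Largest step; defaults to the common `T_max` of `times`.
#' @return A list of class `curve_set` with data frame `curves` (columns
#'   `t`, `p_right`, `p_wrong`, `delta_p`, and when trajectories are given
#'   `mean_dl`, `se_dl`, `mean_cost`) and `n_realizations`.
#' @export
aggregate_curves <- function(times, trajectories = NULL, t_max = NULL) {
  if (length(times) == 0L) stopf("at least one realization is required")
  if (is.null(t_max)) t_max <- times[[1]]$T_max
  tr <- vapply(times, `[[`, 0L, "T_R")
  tw <- vapply(times, `[[`, 0L, "T_W")
  n <- length(times)
  ts <- 0:t_max
  p_right <- vapply(ts, function(t) mean(tr <= t), 0)
  p_wrong <- vapply(ts, function(t) mean(tw <= t), 0)
  curves <- data.frame(t = ts, p_right = p_right, p_wrong = p_wrong,
                       delta_p = p_right - p_wrong)
  if (!is.null(trajectories)) {
    dl <- vapply(trajectories, function(x) c(x$dl0, x$steps$dl), numeric(t_max + 1L))
    cost <- vapply(trajectories, function(x) c(0, cumsum(x$steps$sc)),
                   numeric(t_max + 1L))
    dl <- matrix(dl, nrow = t_max + 1L)
    cost <- matrix(cost, nrow = t_max + 1L)
    curves$mean_dl <- rowMeans(dl)
    curves$se_dl <- apply(dl, 1L, stats::sd) / sqrt(n)
    curves$mean_cost <- rowMeans(cost)
  }
  structure(list(curves = curves, n_realizations = n), class = "curve_set")
}

#' Characteristic times and the critical number of initial observations
#'
#' From difference curves `deltaP(t)` computed at several values of the
#' initial-observation count `N_O(0)`: `t*` is, per curve, the last step at
#' which `deltaP(t) > 0` (`NA` when the curve is never positive); the
#' critical count `N_O*` is the linear-interpolation zero of the final
#' difference `deltaP(T_max)` as a function of `N_O(0)`, i.e. the initial
#' information needed before the imputed process favors a right over a
#' wrong diagnosis.
#'
#' @param curve_sets Named or unnamed list of `curve_set` objects, one per
#'   `N_O(0)` value.
#' @param n_initial Numeric vector of the matching `N_O(0)` values.
#' @return List with `t_star` (per `N_O(0)`), `delta_p_final`, `n_o_star`
#'   (`NA` when the sign change is not bracketed) and `bracketed`.
#' @export
estimate_crossings <- function(curve_sets, n_initial) {
  if (length(curve_sets) < 2L) stopf("need curves for at least two N_O(0) values")
  if (length(curve_sets) != length(n_initial)) {
    stopf("curve_sets and n_initial differ in length")
  }
  t_star <- vapply(curve_sets, function(cs) {
    pos <- cs$curves$t[cs$curves$delta_p > 0]
    if (length(pos) == 0L) NA_real_ else max(pos)
  }, 0)
  dpf <- vapply(curve_sets, function(cs) {
    cs$curves$delta_p[nrow(cs$curves)]
  }, 0)
  ord <- order(n_initial)
  x <- n_initial[ord]
  y <- dpf[ord]
  n_o_star <- NA_real_
  bracketed <- FALSE
  for (k in seq_len(length(x) - 1L)) {
    if (y[k] <= 0 && y[k + 1L] > 0) {
      bracketed <- TRUE
      n_o_star <- if (y[k] == 0) x[k] else {
        x[k] + (0 - y[k]) * (x[k + 1L] - x[k]) / (y[k + 1L] - y[k])
      }
      break
    }
  }
  list(t_star = t_star, delta_p_final = dpf, n_o_star = n_o_star,
       bracketed = bracketed)
}
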