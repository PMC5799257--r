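---
title: "Simulating sequential clinical diagnosis: models, inference and test selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sequential clinical diagnosis: models, inference and test selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagsim)
```

## The problem

A clinician observing a patient faces a sequential decision problem: which
medical test to order next, given everything observed so far, so that the
diagnosis becomes decisive quickly and cheaply. `diagsim` studies this
problem *in silico*. It builds a probabilistic model connecting binary
disease variables $D_a \in \{0,1\}$, $a = 1,\dots,N_D$, to binary sign
variables $S_i \in \{-1,+1\}$, $i = 1,\dots,N_S$ (clinical and laboratory
findings), simulates step-by-step diagnostic processes under different
test-selection strategies, and measures how quickly and how reliably the
posterior over diseases concentrates on the truth.

Every disease $a$ carries a weight $W_a \in (0,1)$ (its importance, e.g.
severity) and every sign $i$ a cost $C_i \in (0,1)$ (the cost of the test
revealing it). Both are drawn i.i.d. uniform in the synthetic benchmark.

## The model

The joint distribution is $P(\mathbf S; \mathbf D) = P(\mathbf S \mid
\mathbf D)\, P_0(\mathbf D)$. The conditional sign distribution is a
maximum-entropy model with interaction factors attached to single diseases
and to disease pairs, each factor acting on individual signs only (no
sign–sign couplings):

$$
P(\mathbf S \mid \mathbf D) = \frac{1}{Z(\mathbf D)}
\exp\Big(\sum_i S_i\, h_i(\mathbf D)\Big),
\qquad
h_i(\mathbf D) = K_i^0 + \sum_a K_i^a D_a + \sum_{a<b} K_i^{ab} D_a D_b .
$$

The *leak field* $K_i^0$ captures the effect of unknown or ignored
diseases on sign $i$; $K_i^a$ and $K_i^{ab}$ are the one- and two-disease
couplings, present only for (factor, sign) pairs in the interaction graph.
The model with only $K_i^0, K_i^a$ is called D1S1; adding $K_i^{ab}$ gives
D2S1. Because all factors act on single signs, the partition function
factorizes exactly:

$$
\ln Z(\mathbf D) = \sum_i \ln\!\big(2 \cosh h_i(\mathbf D)\big).
$$

The disease prior is factorized, $P_0(D_a = 1) = p_a$ with field
$K_a^0 = \ln\!\big(p_a/(1-p_a)\big)$. `calibrate_prior(n_diseases, k)`
chooses a common $p$ so that the expected number of present diseases is
$k$; all small-system studies in this package use $p = 2/N_D$
(two expected diseases).

### The synthetic truth and exact fitting

The benchmark "true world" (a `problem_instance`) attributes to the
all-healthy state and to every factored disease subset $\mathbf D$ a sign
configuration $\mathbf S(\mathbf D)$ drawn uniformly from
$\{-1,+1\}^{N_S}$, and defines the true sign distribution as an
exponential decay in the Hamming distance to it:

$$
P_{\mathrm{true}}(\mathbf S \mid \mathbf D) \propto
e^{-H(\mathbf S,\, \mathbf S(\mathbf D))}.
$$

This factorizes over signs, each sign agreeing with its attributed value
with probability $e/(1+e) \approx 0.731$. Because the model class can
represent any set of single-sign conditional marginals with
$|\mathbf D| \le 2$, the D2S1 parameters are computed *exactly* from the
true conditionals as half log-odds with lower-order terms subtracted:

$$
K_i^0 = \tfrac12 \ln
\frac{P_{\mathrm{true}}(S_i = +1 \mid \text{no disease})}
     {P_{\mathrm{true}}(S_i = -1 \mid \text{no disease})},
\qquad
K_i^a = \tfrac12 \ln
\frac{P_{\mathrm{true}}(S_i = +1 \mid \text{only } a)}
     {P_{\mathrm{true}}(S_i = -1 \mid \text{only } a)} - K_i^0,
$$

and analogously for $K_i^{ab}$ with $K_i^0 + K_i^a + K_i^b$ subtracted.
Under the exponential truth this reduces to
$K_i^0 = S_i(\varnothing)/2$, $K_i^a = S_i(a)/2 - K_i^0$, etc., so all
fitted couplings are half-integers. One practical consequence worth
knowing: hypothesis energies then lie on a lattice and *exact ties* in the
maximum likelihood are not rare; any routine comparing optimizer output to
an enumerated argmax must compare likelihood values, not configurations.

`fit_from_true_marginals()` raises an error on degenerate marginals
(probability exactly 0 or 1, implying an infinite coupling) rather than
clipping; the exponential truth never produces them.

## Inference

Given observed signs $\mathbf S^o$ the disease posterior is governed by
the energy (negative log-likelihood)

$$
\mathcal H(\mathbf D \mid \mathbf S^o) =
-\sum_a K_a^0 D_a
-\sum_{i \in O} S_i^o\, h_i(\mathbf D)
+\sum_{i \in O} \ln\!\big(2\cosh h_i(\mathbf D)\big),
$$

unobserved signs marginalizing away exactly. Marginals of unobserved signs
are posterior mixtures of $\big(1 + \tanh h_i(\mathbf D)\big)/2$.

Two backends implement the same interface:

* **Exhaustive enumeration** (`exact_infer`) sums over all $2^{N_D}$
  hypotheses. An `exact_engine` pre-tabulates the local fields of every
  hypothesis once per model, reducing each inference call to a few small
  matrix products; this is what makes simulation studies with hundreds of
  thousands of inference calls practical. Guarded at $N_D \le 20$.
* **Metropolis Monte Carlo** (`mc_infer`, compiled code) for larger
  models: single-disease flips, one sweep = $N_D$ attempted flips, energy
  maintained incrementally. Defaults follow the reference protocol of
  20000 sweeps, 2000 discarded for equilibration, samples every 20 sweeps
  at $\beta = 1$. Per sample the estimators are conditional
  (Rao–Blackwellized): $P(D_a = 1 \mid \mathbf D_{-a}, \mathbf S^o)$ for
  diseases — the exact analogue of the $\tanh$ form used for signs —
  which materially lowers the variance at no extra sweep cost. At these
  budgets on fully connected 20-sign/5-disease problems, marginal errors
  stay at the level of a few hundredths (empirically $\lesssim 0.02$,
  about three Monte Carlo standard errors).
* **Simulated annealing** (`sa_max_likelihood`) finds the
  maximum-likelihood hypothesis by raising $\beta$ linearly from 1 to 10
  over 5000 sweeps, tracking the best configuration ever visited (costs
  nothing, tightens the estimate). Annealing runs independently after
  marginal estimation rather than reusing its equilibration, so the two
  estimates are independently reproducible.

All probability computations are done in log space;
$\ln 2\cosh h$ uses the overflow-safe form $|h| + \ln(1 + e^{-2|h|})$.

## The diagnostic processes

Starting from $N_O(0)$ initial observations (a uniform subset of signs at
their true values), at each step $t = 1, \dots, T$ an unobserved sign
$j_t$ is selected and "observed". Two processes differ in what value is
recorded:

* **Diags-I**: the true value — as if the medical test were actually
  performed. True values are the most probable signs of the true
  distribution, i.e. $\mathbf S(\mathbf D^{\mathrm{true}})$ itself.
* **Diags-II**: the model-imputed most probable value
  $\arg\max P(S_j \mid \mathbf S^o)$ — a pure simulation, requiring no new
  real observation. This is the package's single-branch simplification of
  averaging over outcomes; the exact two-branch average is available in
  principle only through the exhaustive backend and is not used in the
  shipped studies.

The greedy strategy selects the sign maximizing the per-step objective

$$
\mathcal E(t) = \mathrm{ML}(t) + \lambda_P\, \mathrm{DP}(t)
- \lambda_C\, \mathrm{SC}(t),
$$

with $\mathrm{ML}(t)$ the maximum log-likelihood normalized by the number
of observed signs $|O(t)|$ (initial findings included — $O(t)$ is defined
as their union with the chosen signs), $\mathrm{DP}(t) = \sum_a W_a
\lvert P(D_a = 1 \mid \mathbf S^o) - \tfrac12 \rvert / \sum_a W_a \in
[0, \tfrac12]$ the weighted disease polarization *after* incorporating the
$t$-th value, and $\mathrm{SC}(t) = C_{j_t}$ the cost of the chosen test.
The random strategy draws $j_t$ uniformly among unobserved signs and gives
an upper bound for how much initial information is needed.

Tunable parameters that matter:

| parameter | meaning | default / studied values |
|---|---|---|
| $\lambda_P$ | weight of polarization reward (unitless) | 0 or 1 |
| $\lambda_C$ | weight of cost penalty (unitless) | 0 or 0.1 |
| $N_O(0)$ | initial observations | 0–8 (of 20) |
| $P_{\mathrm{th}}$ | diagnosis threshold probability | 0.9 |
| prior $p$ | $P_0(D_a = 1)$ | $2/N_D$ |

## Whole-sequence optimization

For Diags-II the whole sequence $\{j_1,\dots,j_T\}$ can be optimized
directly against the sequence objective $\mathcal E[O(T)] = \sum_t
\mathrm{ML}(t) + \lambda_P \sum_t \mathrm{DP}(t) - \lambda_C \sum_t
\mathrm{SC}(t)$. `optimize_sequence()` runs a zero-temperature Monte
Carlo: from a random sequence, repeatedly propose a new one and accept
only if the objective strictly increases ($\Delta\mathcal E = 0$ is
rejected). Proposals keep a random prefix and rebuild the suffix by
drawing each next sign with probability proportional to
$P(S_i = +1 \mid \mathbf S^o(t-1))$ — signs likely to be positive are the
informative ones to impute — with the state advanced by imputed values as
the suffix grows, already-used signs excluded and weights renormalized
(uniform fallback if all weights vanish, flagged). Evaluating one
candidate sequence costs $T$ inference calls.

## Performance measures

* **Overlap** $DL(t) = \sum_a W_a (2D_a^{\mathrm{true}} - 1)
  \big(P(D_a = 1 \mid \mathbf S^o(t)) - \tfrac12\big) / \sum_a W_a \in
  [-\tfrac12, \tfrac12]$: how well the posterior points at the truth.
* **First diagnosis times**: $T_R$ ($T_W$) is the first step at which some
  truly present (absent) disease crosses $P_{\mathrm{th}}$. Step $t = 0$
  (after the initial observations, before any sequential test) is included
  in the scan, so initial findings alone can trigger a diagnosis; a
  process that never crosses gets the sentinel $T+1$, which never counts
  in cumulative curves but keeps joint histograms constructible.
* **Cumulative curves** $P(T_R \le t)$, $P(T_W \le t)$, their difference
  $\delta P(t)$, mean $DL(t)$ and mean cumulative cost, over independent
  realizations of the *model and process* (a fresh instance per
  realization).
* **Characteristic quantities**: $t^*$, the last step with
  $\delta P(t) > 0$ (how many imputed tests one can afford before the
  initial information is squandered); and $N_O^*$, the
  linear-interpolation zero of $\delta P(T)$ against $N_O(0)$ — below it
  the imputed process is more likely to reach a wrong diagnosis than a
  right one.

## What the generator emulates — and what it does not

The synthetic benchmark reproduces the *structure* of the diagnostic
problem: sparse or dense disease–sign association, disease interactions in
pairs, noisy sign expression, heterogeneous disease importance and test
costs, and partial observability. It does not attempt realistic disease
prevalences, correlated sign noise (the truth factorizes over signs),
sign–sign interactions, or real co-morbidity statistics; attributed sign
configurations are drawn independently for each disease subset, including
over signs outside a factor's neighborhood, so the fitted sparse model is
deliberately mismatched there. Passing tests therefore demonstrate the
correctness of the machinery and the qualitative phenomenology
(information monotonicity under revealed values, the $N_O^*$ transition,
cost control), not clinical validity on real data.

## Numerical and design choices

* Ties are broken deterministically: lowest sign index in argmax
  selections, $+1$ at an imputation probability of exactly $\tfrac12$.
* Hypothesis sampling for simulated patients: one present disease with
  probability $\propto W_a$; two present diseases restricted to pairs
  owning a two-disease factor, with probability $\propto W_a + W_b$ (the
  additive reading of weight-proportionality; configurable by editing the
  instance weights). Unfactored pairs are excluded because the fitted
  model carries no information about them.
* If fewer single-disease factors than diseases are requested
  ($M_a < N_D$), a uniform random subset of diseases receives factors.
* Seeds: every stochastic component takes its own seed, derived from a
  master seed through a fixed integer mix, so instance generation,
  hypothesis draws, initial observations, MC inference and sequence
  optimization are independently reproducible. The random strategy
  pre-draws a permutation of the unobserved signs (distributionally
  identical to uniform selection without replacement) so trajectories do
  not depend on the inference backend's internal RNG.
* Problem sizes in the shipped studies: correctness oracles run at
  $N_S \le 12$, $N_D \le 5$ (exhaustive enumeration over signs);
  simulation studies at $N_S = 20$, $N_D = 5$, $T = 12$ with 250–600
  realizations per condition and exact inference; the sequence-optimizer
  smoke study at $N_S = 60$, $N_D = 10$, $T = 10$ on a sparse graph
  ($M_a = 10$, $M_{ab} = 20$, $k = 18$). These sizes keep every study
  deterministic-oracle-checkable or statistically well-resolved while the
  full suite runs in minutes.

## Known limitations

* No sign–sign couplings (D2S2) and no belief-propagation or mean-field
  inference; exhaustive enumeration or Metropolis sampling only.
* The outcome average over possible test results is everywhere replaced by
  the single most-probable-outcome branch.
* Hypotheses with three or more present diseases can be simulated against
  the fitted model, but the model is only exact for $|\mathbf D| \le 2$
  conditionals, and the generator does not attribute sign configurations
  to larger subsets.
* $N_O^*$ is estimated by linear interpolation between simulated $N_O(0)$
  grid points; it is a bracketing estimate, not a root-finding procedure.

## A minimal session

```{r example, eval = FALSE}
inst <- generate_instance(n_signs = 20, n_diseases = 5, seed = 1)
model <- fit_from_true_marginals(inst, prior = calibrate_prior(5, 2))
truth <- sample_hypothesis(inst, n_present = 2, seed = 2)

traj <- run_diagnosis(inst, model, truth, mode = "diags2",
                      strategy = "greedy", n_steps = 12, n_initial = 4,
                      params = objective_params(lambda_P = 1, lambda_C = 0.1),
                      seed = 3)
first_diagnosis_times(traj, p_th = 0.9)
```
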