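---
title: "Models and methods in salmodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in salmodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmodiv)
```

`salmodiv` implements, from first principles, the statistical machinery
needed to study lineage diversification in a clade descended from a
whole-genome duplication (WGD): curation of WGD paralogue gene trees by
their diploidization outcome, construction of paralogue concatenations and
orthologue supermatrices, molecular-clock diagnostics, and diversification
inference (lineage-through-time curves, the gamma statistic, survival
models of branching times, and the binary-state speciation-extinction
model, BiSSE). This vignette records the model definitions, the default
choices and their rationale, the numerical strategy, and the known
limitations.

## 1. Trees, branching times and alignments

Trees are `ape::phylo` objects. `read_newick()` / `write_newick()` provide
strict Newick IO with character-offset error messages; `branching_times()`
extracts, from an ultrametric tree, the sorted node ages $x_1 \ge \dots
\ge x_{n-1}$, the internode intervals $g_k$ (time spent with exactly $k$
reconstructed lineages) and the cumulative lineage-times
$T_i = \sum_{k=2}^{i} k\,g_k$. Alignments are in-frame codon matrices
(`codon_alignment`) with FASTA IO and codon-position extraction
(`codon_partition()`), which preserves the position offset so partitioning
and concatenation commute.

## 2. Synthetic data generators

All statistics in the package are exercised on synthetic data, so the
generators are part of the package rather than test scaffolding.

* `simulate_bd_tree()` and `simulate_bisse()` are Gillespie simulations of
  the constant-rate birth-death and BiSSE processes, conditioned on a tip
  count $n$ by forward simulation with rejection (extinct or overshooting
  runs are discarded) and stopped at the $n$-th birth plus an additional
  exponential waiting time. This conditioning is simple and transparent
  but is not the generalized-sampling-algorithm draw from the exact
  conditioned distribution; the small bias this induces is accepted and
  the pure-birth case, where the construction is exact, is used for null
  calibrations.
* `simulate_wgd_gene_tree()` builds paralogue gene trees under three
  diploidization scenarios on a species tree with outgroups: ancestral
  resolution (two dated paralogue clades splitting at the duplication
  depth), lineage-specific resolution (independent resolutions inside
  crown lineages), and unresolved tetrasomy with gene conversion pulling
  paralogue pairs into species-level sister pairs. The geometry is
  deterministic given the requested depths.
* `simulate_alignment()` evolves in-frame codon sequences under HKY with
  per-codon-position rate multipliers (default third position fastest),
  using the exact eigendecomposition of the rate matrix.
* `make_sealevel_fixture()` produces a noisy long-term sea-level-like
  series for the climate overlay.

## 3. Paralogue curation

`classify_diploidization()` screens a WGD paralogue gene tree into
`resolved_ancestral`, `lineage_specific`, `unresolved_tetrasomic` or
`ambiguous`, keeping only the first: the configuration in which the
paralogue split predates the crown radiation, the two paralogue clades are
each monophyletic, and each is represented by multiple subfamilies, so the
split is a clean, datable event shared by all lineages. Decisions the
underlying study design leaves open are exposed as parameters rather than
guessed: `min_support` compares against per-node support annotations when
present in the Newick (absent annotations with a threshold set yield
`ambiguous`), and the minimum subfamily representation per clade is an
argument with a documented default.

`enumerate_concatenations()` indexes the $2^k$ ways of concatenating $k$
paralogue pairs (little-endian bit coding; the $2^{k-1}$ assignments with
the first bit 0 are the swap-deduplicated "canonical" half), and
`sample_concatenations()` draws distinct assignments uniformly.
`concat_orthologs()` builds the species-level supermatrix with one
pseudo-taxon row per species and paralogue; outgroup species, which carry
a single copy, are duplicated across both paralogue block sets so they
serve as outgroups to both paralogues. Missing sequences are always
gap-filled with a message, never silently dropped, so matrix dimensions
are reproducible.

## 4. Clock diagnostics

`tajima_rrt()` is Tajima's relative-rate test: over sites ungapped and
unambiguous in all three sequences, $m_1$ and $m_2$ count changes unique
to each ingroup taxon and $(m_1 - m_2)^2/(m_1 + m_2)$ is referred to
$\chi^2_1$ ($p = 1$ by convention when $m_1 + m_2 = 0$).
`saturation_scan()` reports, per sequence pair, transition and
transversion proportions and the closed-form Kimura two-parameter
distance $d = -\tfrac12\ln\big((1-2P-Q)\sqrt{1-2Q}\big)$; pairs beyond the
K2P domain are flagged as saturated and excluded from the
differences-vs-distance slope. The closed-form K2P distance is used in
place of tool-specific composite-likelihood distances; this deviation is
deliberate, since only the closed form is a published formula.

## 5. Diversification inference

**LTT and gamma.** `ltt()` is the step curve of reconstructed lineage
counts against age. `gamma_test()` computes
$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} T_i - T/2}
{T\sqrt{1/(12(n-2))}},$$
asymptotically standard normal under constant rates, with a two-tailed
normal p-value. Positive $\gamma$ means node ages crowd toward the
present.

**Survival models.** `fit_survival()` treats the $n-1$ node ages as
uncensored waiting times measured backwards from the present (complete
tree, no censoring — the exact censoring scheme of the originating method
description is ambiguous, and the uncensored reading is the one
implemented) and fits: (A) constant hazard, closed-form
$\hat\delta = N/\sum x_i$; (B) Weibull hazard
$h(x) = \delta\beta(\delta x)^{\beta-1}$, with $\beta < 1$ concentrating
events near the present; (C) piecewise-constant hazard with shift age
$T_c$ either fixed or profiled over the midpoints of the observed
branching times. B and C are compared to A by likelihood-ratio tests
(df 1 for A-vs-B; df 1 for A-vs-C with fixed $T_c$, df 2 when profiled,
with the usual caveat that a profiled changepoint is not a regular
parameter) and to each other by Akaike weights.

**BiSSE.** `bisse_loglik()` integrates, along each branch and for each
state $i$ with $j = 1-i$,
$$\frac{dE_i}{dt} = \mu_i - (\lambda_i+\mu_i+q_{ij})E_i +
\lambda_i E_i^2 + q_{ij}E_j, \qquad
\frac{dD_i}{dt} = -(\lambda_i+\mu_i+q_{ij})D_i + q_{ij}D_j +
2\lambda_i E_i D_i,$$
with tip conditions $D_i = \mathbf 1\{\text{state}=i\}$, $E_i = 0$
(complete sampling), node combination
$D_i \leftarrow D_i^{\text{left}} D_i^{\text{right}} \lambda_i$, and root
weighting by default proportional to the root $D$ values (`root_mode =
"obs"`, the convention of the model's reference implementation; equal
weights and fixed-state options are provided). Survival conditioning is
off by default and available behind a flag.

## 6. Numerical choices

* The E/D system is integrated in C++ with an adaptive Cash-Karp
  Runge-Kutta 4(5) scheme at relative tolerance `1e-8`, with per-branch
  renormalisation of $D$ and accumulation of the log scaler, so deep trees
  do not underflow. The production integrator is verified in the tests
  against a brute-force fixed-step RK4 oracle on small trees and against
  the closed-form birth-death $\times$ Mk2 factorization when rates are
  state-independent.
* `bisse_ml()` optimizes on the log-rate scale with bounds
  $[10^{-8}, 10^3]$ and multi-start (default 5; first start from a
  Yule-style heuristic, the rest jittered), because BiSSE surfaces are
  multimodal. Ties are broken by highest log-likelihood, then lowest
  parameter norm.
* `bisse_mcmc()` is an adaptive random-walk Metropolis sampler on the six
  log-rates with independent exponential priors (default mean twice a
  Yule-style speciation estimate); the proposal scale is adapted toward
  23% acceptance during burn-in and then frozen, so the retained chain is
  a valid Metropolis sampler. Non-mixing is screened by a crude
  effective-sample-size estimate, raising a warning below `ess_warn`.

## 7. Design decisions and open questions

* **LRT degrees of freedom.** The constrained BiSSE model forces
  $\lambda_0=\lambda_1$ and $\mu_0=\mu_1$ while leaving the transition
  rates free, so the free-vs-constrained LRT has df = 2. Reported
  analyses of this kind sometimes quote p-values consistent with df = 1;
  `bisse_lrt()` reports the parameter-count df and leaves the convention
  visible rather than guessing.
* **Root treatment.** Default `"obs"` weighting; alternatives exposed.
* **Breakpoint profiling.** Profiling $T_c$ over branching-time midpoints
  is a discrete search, and the df = 2 reference distribution for the
  A-vs-C LRT is approximate.
* **Known limitation: BiSSE rate estimation on small asymmetric trees.**
  On 65-tip trees simulated with a strongly asymmetric process (high
  state-1 speciation, slow transitions), replicates occasionally contain
  very few or zero state-0 tips. On zero-state-0 trees the BiSSE
  likelihood increases without bound along $\lambda_0 = q_{01} \to
  \infty$, $q_{10} = 0$ (a transient super-speciating hidden state), so a
  finite MLE for the state-0 rates does not exist and batch means of
  $\hat\lambda_0$ are fragile across seed batches. This is a property of
  the likelihood, verified against an independent integrator, not an
  optimizer artifact. $\hat\lambda_1$, the rate of the well-represented
  state, is stable.

## 8. Worked example

```{r example, eval = FALSE}
truth <- bisse_params(lambda0 = 0.09, lambda1 = 0.31,
                      mu0 = 0.04, mu1 = 0.14, q01 = 0.01, q10 = 0.01)
sim <- simulate_bisse(truth, n_tips = 65, root_state = 1, seed = 1)

gamma_test(sim$tree)
fit_survival(sim$tree)

free <- bisse_ml(sim$tree, sim$states, seed = 1)
eq <- bisse_ml(sim$tree, sim$states, constrained = TRUE, seed = 1)
bisse_lrt(free, eq)
```

The numbered scripts under `analysis/` run the full workflow — data
generation, paralogue screening, concatenation, clock diagnostics,
diversification inference and the climate overlay — end to end on
synthetic data.
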