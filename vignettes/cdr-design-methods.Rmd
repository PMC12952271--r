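---
title: "Energy-based multi-objective design of antibody CDR variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based multi-objective design of antibody CDR variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdropt)
```

## The design problem

Antibody lead optimization asks for variants of a starting ("wild-type")
antibody that bind the target more tightly while remaining developable —
soluble, stable, human-like. `cdropt` operates on a concatenation of the
three heavy-chain complementarity-determining regions (CDRH1/H2/H3; 33
residues for the shipped default wild type) and restricts the search to
sequences at most `d_lim = 6` substitutions away. Even so the space holds
`choose(33, 6) * 20^6 ≈ 7.09e13` candidates under the position-choice
counting convention, far beyond what any affinity assay can cover, so the
package couples predictive surrogates to generative samplers.

## The model

Candidates are drawn from a Boltzmann distribution over sequence space,

$$ p(x) = \frac{1}{Z}\, p_{\mathrm{HUM}}(x)\, e^{-E(x)/T}, \qquad
   E(x) = -\sum_i w_i f_i(x), \quad \sum_i w_i = 1 , $$

which is the exact solution of "minimize the mean energy while staying
KL-close to the humanness prior". The canonical two-objective energy is
$E(x) = -w\,\hat f_{\mathrm{aff}}(x;\beta) - (1-w)\,\hat f_{\mathrm{sol}}(x)$.

* **Affinity** $\hat f_{\mathrm{aff}}$ is a Gaussian-process regression over
  sequence embeddings (one-hot by default; external protein-language-model
  embeddings enter through a file-backed encoder). The RBF kernel
  $k(x,x') = \delta \exp(-\lVert x-x'\rVert^2 / 2\lambda^2)$, a constant
  prior mean $C$ and the observation noise $\sigma_n$ are fitted by
  gradient ascent of the log marginal likelihood. The sampler consumes the
  confidence-bound acquisition $\mu(x) + \beta\,\sigma(x)$: $\beta > 0$
  explores high-uncertainty sequences, $\beta < 0$ is pessimistic.
  Affinities are expressed as $f_{\mathrm{aff}} = \log_{10}(1\,\mathrm{nM}/K_d)$.
* **Solubility** $\hat f_{\mathrm{sol}}(x) = -\sum_j \mathrm{SASA}(j, x_j)\,
  \mathrm{HW}(x_j) + \mathrm{const}$ penalizes exposed hydrophobic residues.
  Per-residue relative solvent accessibility comes from a pluggable
  provider (constant 1, per-amino-acid table, or per-sequence file).
* **Humanness** $p_{\mathrm{HUM}}$ is any autoregressive sequence prior with
  $\ln p(x) = \sum_i \ln p(x_i \mid x_{<i})$. The package ships trainable
  categorical stand-ins (position-specific or k-mer) and a file-backed
  adapter with the identical contract for scores precomputed by an external
  immunoglobulin language model; with a uniform prior the target reduces to
  the maximum-entropy Boltzmann form.

## Samplers

**Metropolis–Hastings.** Proposals are uniform over the set of sequences one
substitution from the current state and at most `d_lim` from the wild type;
acceptance is `min(1, p(x')/p(x))` times an optional proposal correction.
Eight chains of 20,000 steps (defaults) start from the wild type; burn-in is
the smallest point on a 5%-spaced grid at which the Gelman–Rubin statistic
of the log target density falls below 1.1, and non-converged runs are
extended by 20,000 steps. Two deliberate choices:

* The *Hastings correction* for the shrinking boundary neighborhood
  (`log |N(x)| - log |N(x')|`) is on by default because it makes the chain's
  stationary law exactly the Boltzmann target — verified in the tests
  against full enumeration on a 27-state space (total variation < 0.02).
  The plain-ratio variant remains available (`hastings = FALSE`) for
  protocol-faithful replication; it is exact only away from the `d_lim`
  boundary, where the proposal is symmetric.
* The monitored scalar for Gelman–Rubin is the log unnormalized density,
  the one scalar every target provides.

**GFlowNet-style amortized sampler.** An autoregressive policy builds
sequences left to right and is trained with the trajectory-balance loss
$(\log Z_\theta + \log P_F(x) - \log R(x))^2$ with reward
$R(x) = p_{\mathrm{HUM}}(x) e^{-E(x)/T}$, a 20,000-record FIFO replay
buffer, 16 fresh + 16 replayed sequences per step, learning-rate halving at
the midpoint, and a 10× higher rate for $\log Z_\theta$. Convergence is
tracked as the Spearman correlation between held-out log rewards and policy
log-probabilities. Two policy parameterizations are provided, both with
hand-derived gradients: a fully expressive tabular prefix-conditioned
policy (exact on enumerable spaces; used by the validation suite, where it
reaches total variation ≤ 0.1 against enumeration and Spearman > 0.9) and a
compact linear policy over position and mutation-count features. The
mutation constraint is enforced by hard masking — once `d_lim` mutations are
spent only the wild-type letter remains available — which is stricter than
letting the policy learn the constraint and guarantees zero mass outside
the ball. The trajectory-balance learning rate is a per-architecture
tunable: the desk-scale tabular policy trains with `lr = 5e-2`, while the
shipped default (`1e-3`) matches the convention for neural policies.

## Candidate selection

All generated sequences are placed in the (acquisition, solubility) plane.
The Pareto front is the maximal non-dominated subset; each candidate gets a
variance-normalized distance to the front,

$$ d_P(x) = \min_{x' \in \mathrm{PO}}
   \sqrt{ \frac{(\hat f_{\mathrm{aff}}(x)-\hat f_{\mathrm{aff}}(x'))^2}{\sigma^2_{\mathrm{aff}}}
        + \frac{(\hat f_{\mathrm{sol}}(x)-\hat f_{\mathrm{sol}}(x'))^2}{\sigma^2_{\mathrm{sol}}} }, $$

with variances computed over the full generated pool before any filtering.
The square root is taken so `d_P` has the units of normalized objective
space; the raw squared form is available by configuration. The top-`B`
selection takes the `B` smallest `d_P` with lexicographic tie-breaks for
determinism. The benchmark protocol (`threshold_count_eval`) instead
filters by predicted solubility (strictly above `f_sol_min`), ranks by
acquisition, truncates to the budget `B` and counts sequences whose *true*
affinity exceeds each threshold of a grid.

Developability is additionally audited with a net-charge score (+1 for R/K,
+0.1 for H, −1 for D/E; acceptable band [−2, 2]) and the dipeptide-weight
instability index ((10/L)·Σ weights; values above 40 flag instability —
note that convention is adopted here deliberately: higher index = less
stable, threshold 40).

## The synthetic landscape: what it emulates and what it does not

Ground truth for validation is a pairwise-epistatic affinity function
$f(x) = f_{\mathrm{WT}} + \sum_i h_i(x_i) + \sum_{i<j} J_{ij}(x_i, x_j)$
with i.i.d. Gaussian tables and all wild-type entries zeroed. Two
parameterizations (mean, sd): *simple* has $h \sim N(-0.5, 0.5)$,
$J \sim N(0, 0.5)$ — most single mutations mildly deleterious, weak
epistasis — and *hard* has $h \sim N(0, 0.5)$, $J \sim N(-0.5, 0.5)$, where
coupling penalties make random multi-mutants far more deleterious. The
baseline $f_{\mathrm{WT}}$ defaults to 0 since only differences matter for
ranking. The library generator mirrors a deep-mutational-scan composition:
every (position, amino-acid) single-substitution record — 33 × 20 = 660 for
the canonical wild type, identity substitutions kept as wild-type-affinity
records to match that enumeration — plus 2,100 distinct random doubles and
11,900 distinct random triples, each observation perturbed by N(0, 1)
measurement noise. Out-of-distribution negatives (fully random CDRs pinned
at the weak affinity implied by $K_a = 10^7\,\mathrm{M}^{-1}$, i.e.
$f_{\mathrm{aff}} = -2$) are available but not used by default. The field
and coupling tables are materialized eagerly (about 1.7 MB at L = 33),
which keeps seed-reproducibility trivial.

This landscape emulates *measurement noise, sparse library coverage and
second-order epistasis*; it does not emulate structural constraints,
higher-order epistasis, assay-specific biases or the sequence composition
of natural repertoires. Passing the synthetic end-to-end checks therefore
demonstrates that the machinery optimizes what its surrogates know about —
not that the surrogates are accurate for any particular real antigen.

## Numerical choices

* Kernel hyperparameters are optimized on the log scale; the marginal
  likelihood is evaluated on mean-centered targets (the constant mean `C`
  is trainable, initialized to the training mean). Factorizations use
  Cholesky with escalating jitter (0 → 1e-8 → 1e-6 → 1e-4); failure after
  escalation is an error, never silent.
* The default optimizer is plain gradient ascent for a fixed budget of 600
  steps at learning rate 1e-3 (adam is available by configuration). The
  noise scale is initialized to half the target standard deviation: small
  noise initializations reliably fall into the well-known
  length-scale-collapse local optimum of the marginal likelihood, which
  flattens the acquisition surface and stalls generation.
* The acquisition uses the latent (noise-free) posterior variance; the
  noisy predictive variance is a flagged variant.
* Posterior variances are clipped at zero; `d_P` errors out on degenerate
  (zero-variance) objectives rather than dividing by zero.
* All randomness flows from explicit master seeds through one documented
  splitting scheme (`derive_seeds`), so chains, replicates and datasets are
  exactly reproducible; MCMC traces store sequences as strings.
* Candidate pools are de-duplicated by sequence before Pareto analysis;
  diversity/novelty metrics operate on the records they are given.

## Problem sizes used by the validation suite

The shipped tests exercise the full protocol at desk scale, chosen so the
whole suite completes comfortably on one CPU: exact-distribution checks on
3–4-letter alphabets with full enumeration (27–256 states, 1e5–2e5 MCMC
steps, 3,000 trajectory-balance steps); GP oracles at n = 30 and parameter
recovery at n = 200; and an end-to-end benchmark on a 16-residue wild-type
prefix with a 2,020-record simple-mode library (GP trained on half),
6 × 3,000 MCMC steps, budget B = 500. At that scale the sampler's top-500
exceed the best library records in mean true affinity and dominate the
constrained local-search and random-mutant baselines under identical
budgets, reproducing the method's qualitative claims; the full-scale
printed compositions (14,660-row library) are reproduced exactly where they
are cheap to check.

## Known limitations

* The hydrophobicity weight table behind the published solubility score is
  not public; the package ships the Kyte–Doolittle scale as a documented
  placeholder, so absolute solubility magnitudes (and thresholds such as
  `f_sol_min = 4`) are calibration-dependent.
* No shipped language-model weights: humanness and PLM embeddings beyond
  one-hot enter only through file-backed adapters or user-registered
  callables.
* The GFlowNet policies are deliberately small; they match the training
  protocol, not the convolutional architecture, of production-scale
  samplers.
* Pareto machinery is two-objective; scans over more objectives grow
  exponentially and are out of scope.
* On *hard*-mode landscapes at desk scale the surrogate-guided samplers do
  not reliably beat the best library records: with couplings dominating and
  a small noisy library, the GP cannot identify the rare beneficial
  multi-mutants. This mirrors the regime-dependence of acquisition
  optimism/pessimism rather than a defect of the samplers (the exactness
  checks pass regardless of mode).
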