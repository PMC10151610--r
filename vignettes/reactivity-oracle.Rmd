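---
title: "A Bayesian oracle for combinatorial reactivity data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian oracle for combinatorial reactivity data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

reactoracle interprets the outcomes of combinatorial chemistry campaigns: a
roster of 6-20 starting materials is combined 2-4 at a time, each mixture is
assayed for reactivity (a single reactive/nonreactive flag, or a fixed-width
bit vector derived from chromatogram regions showing new product peaks), and
the system maintains a posterior over an explicit generative theory of which
latent traits drive the observed reactions. On top of the posterior it
quantifies how surprising each observation was before and after learning,
proposes the next most informative experiment, shortlists anomalies for
expert follow-up, and compares rival theories deposited in a registry.

## The generative model

**Latent structure.** Each entity $e$ (a compound, or a fingerprint bit in
structural theories) possesses each of $K$ abstract properties to a degree
$M_{eI} \in [0,1]$. Property combinations carry mutual reactivity: for each
modelled arity $k \in \{2,3,4\}$ a symmetric tensor $R^{(k)}$ over property
indices gives the probability that entities holding those properties react
through that channel. For a pair $(\alpha, \beta)$ the component matrix

$$P_{\alpha\beta IJ} = M_{\alpha I}\, M_{\beta J}\, R^{(2)}_{IJ}$$

is the probability that $\alpha$ and $\beta$ react by virtue of $\alpha$
holding $I$ and $\beta$ holding $J$ (`component_matrix()`).

**Noisy-OR aggregation.** Every ordered assignment of properties to the
participating compounds is an independent potential cause, and a combination
reacts if any cause fires:

$$p_{\text{react}} = 1 - \prod_{I_1 \ldots I_k}
  \Bigl(1 - R^{(k)}_{I_1 \ldots I_k} \prod_j M_{c_j I_j}\Bigr).$$

This is algebraically identical to a noisy-OR over unordered index multisets
in which each multiset combines its distinct ordered assignments by noisy-OR
(the test suite holds the vectorized product against an explicit
multiset-enumeration oracle). Because $R$ is symmetric the result is
invariant under any permutation of the compounds.

**Sub-combination closure.** A ternary or quaternary mixture contains its
pairs and triples, so its outcome aggregates the causes of *every*
sub-combination whose size is among the modelled arities. This is what lets
the model answer whether `A + B + C: reactive` signifies a genuine
three-component mode given that `A + B` alone already reacts: the pair cause
explains the triple observation, and the arity-3 tensor is only pulled up by
reactivity that no pair accounts for.

**Multi-bit outcomes.** When outcomes are $B$-bit reactivity vectors, each
cause (a sub-combination together with a property multiset, i.e. a
*reactivity mode*) emits bit $b$ with probability $E_{mb}$ from a
modes-by-$B$ emission map, again aggregated by noisy-OR. Whether the
connection between modes and observable events is a hard assignment or a
soft matrix is an open design point; the soft matrix was chosen to keep all
latents continuous. Binary (width-1) theories bypass the emission map: the
event is reactivity itself.

**Observation noise.** Every bit passes through
$p = \varepsilon_{fp} + (1 - \varepsilon_{fp} - \varepsilon_{fn})\, s$.
The defaults are $\varepsilon = 0.01$; analyses of noise-free synthetic
fixtures use $\varepsilon = 10^{-3}$, because an exact zero turns the
log-likelihood into a cliff (probability 0 against an observed 1) that
breaks gradient-based sampling, while $10^{-3}$ leaves a one-off positive
costing $-\ln 10^{-3} \approx 6.9$ nats to dismiss as noise — enough to
force a structural explanation. Probabilities are clamped to
$[10^{-9}, 1 - 10^{-9}]$ before logs are taken.

## Priors: the `"conservative-v1"` configuration

Memberships, heterotypic tensor entries and emission entries are i.i.d.
Beta(0.5, 2.5): sparse, favoring few active properties, so a fitted theory
uses the minimum structure the data demand. Homotypic (repeated-index)
tensor entries such as $R_{II}$ get a more skeptical Beta(0.5, 10):
chemically, reactivity typically arises between complementary roles
(nucleophile/electrophile, diene/dienophile, acid/base), and statistically
the skepticism breaks an exact tie in the Diels-Alder fixture between the
intended heterotypic explanation (cyclopentadiene carrying mutually reactive
diene and dienophile characters) and a same-cost homotypic one
(cyclopentadiene with a single self-reactive property), which single-pair
data cannot distinguish. All shapes are overridable through
`prior_config()`.

**Choosing the truncation $K$.** $K$ is a fixed truncation with sparsity
induced by the prior, not an inferred dimension (keeping all latents
continuous for Hamiltonian Monte Carlo). One consequence deserves emphasis:
the prior predictive reactivity of the noisy-OR grows with $K$, since
$K^k$ index tuples each contribute prior mass. At $K = 8$ a ternary mixture
is a priori reactive with probability above one half — the opposite of the
conservative stance — while at $K = 3$ it sits near 0.1. The package
therefore treats $K$ as a per-study choice: $K = 8$ for the Diels-Alder
space (whose point is that only 4 of 8 offered properties end up used),
$K = 3$ for the Passerini space (two planted modes plus one spare
dimension), $K = 4$ for the 11-compound named-reaction space (whose 629
free parameters also set the practical sampling budget).

## Inference

`fit_posterior()` samples the joint posterior with Hamiltonian Monte Carlo
in the unconstrained logit parameterization (the Beta prior and the Jacobian
combine to $a \log \sigma(x) + b \log \sigma(-x)$, smooth everywhere), with
analytic gradients implemented in compiled code. Step size is adapted by
dual averaging toward a 0.9 acceptance target with a diagonal mass matrix
estimated from the middle half of warmup; trajectory lengths are jittered
uniformly up to 32 leapfrog steps. Chains run sequentially from a single
seeded RNG stream, so identical inputs give bit-identical draws. Divergent
trajectories (energy error above 1000) and split-$\hat R > 1.05$ raise
warnings, never errors.

The posterior is exchangeable over property labels, so raw parameter draws
are subject to label switching (a high $\hat R$ on raw entries across chains
is expected, not a defect); all quantitative comparisons in the package and
its tests use label-invariant functionals — predictive probabilities,
likelihoods, property *counts*.

**Independent oracle.** `grid_posterior()` integrates
prior $\times$ likelihood over the unit hypercube for theories with at most
6 free parameters, by the midpoint rule (the Beta(0.5, $\cdot$) density
diverges at 0; the singularity is integrable and midpoints never touch it).
The test suite requires MCMC posterior means to match grid means within
three combined standard errors on several toys, including a
self-contradictory log whose posterior must land at the noise-determined
value.

## Surprise, anomalies, exploration

The surprise of an observation is the negative log predictive likelihood of
its recorded outcome vector. `surprise_trace()` reports it under three
distributions: *a priori* (parameters from the prior), *online* (a posterior
conditioned on earlier observations only — the state of belief at the point
of observation), and *a posteriori* (the full-log posterior). Online traces
refit every `refit_every` observations and importance-reweight in between;
with reweighting only, the per-step predictives telescope exactly to the
joint predictive likelihood, a property the tests check to $10^{-6}$.
Observations whose final surprise exceeds $-\ln 0.05$ (a 5%-likely outcome;
configurable) form the anomaly shortlist handed to the expert.

`select_disruptive()` operationalizes "the experiment whose outcome would
most change expected reactivity over the unexplored space" as an expected
total-variation change of predictive probabilities, estimated by importance
reweighting of posterior draws rather than refitting — computable at every
iteration at desk scale. Candidates' multi-bit outcomes are collapsed to
binary (any bit set) for the outcome branching; $2^B$ branches would be
intractable. Ties are broken by canonical experiment order so rankings are
deterministic.

`replay_exploration()` closes the loop: choose (randomly or by disruption
ranking), observe, update, periodically refit. An observation whose online
surprise exceeds the anomaly threshold is scheduled once more before being
accepted, mirroring good laboratory practice of repeating a surprising
result; both attempts enter the log.

## Theory registry and comparison

`register_theory()` assigns content-addressed identifiers (MD5 of the
canonical JSON definition), so identical definitions collide by construction
and refinements record their parent. `compare_theories()` embeds two rival
theories as components of a per-observation mixture,
$p(\text{obs}) = w\, p_a + (1-w)\, p_b$ with $w \sim \text{Beta}(1,1)$ and
both theories' latents sampled jointly; the posterior of $w$ measures
relative support. Per-observation (rather than per-dataset) mixing follows
the standard mixture-based model-comparison construction. `reinterpret()`
runs the same log under every deposited theory side by side; theories
declaring `outcome_coding = "count"` see the log thermometer-recoded to peak
counts (a count of $c$ sets bits $1..c$), which reuses the Bernoulli
machinery unchanged.

## Synthetic fixtures

The generators plant known rules and are the package's study conditions:

- `make_diels_alder_space()`: acid, base, two inert fillers, a
  dienophile-only partner, and self-reactive cyclopentadiene; reactive
  pairs: acid+base, cyclopentadiene+itself, cyclopentadiene+dienophile. The
  construction makes "4 properties in total, 2 on cyclopentadiene" the
  unique minimal explanation under the homotypic-skeptical prior.
- `make_passerini_space()`: 9 compounds with real SMILES (one isocyanide,
  two acids, two carbonyls, two amines, two inert solvents); planted
  acid+amine pairs and the ternary acid+carbonyl+isocyanide mode; rules are
  subset-closed, so a ternary mixture containing an acid-amine pair is
  reactive through it. 36 binary and 84 ternary experiments.
- `make_named_reaction_space()`: 11 compounds (representative stand-in
  structures) spanning eight landmark named reactions with 8-bit detected
  reactivity vectors; 550 experiments over arities 2-4. Bits unique to a
  full reagent set (bold in the panel) are never emitted by
  sub-combinations; the remaining bits are attributed, at fixture build
  time, to the largest proper reagent subsets consistent with every row of
  the panel, which keeps outcomes monotone under reagent addition and
  reproduces all eight printed vectors exactly.
- `reactivity_vector_from_chromatograms()` bins product retention times into
  8 equal regions over the chromatogram window (default 0-8 min) and flags
  regions holding a product peak with no reactant peak within 0.1 min.

What the generators deliberately do not emulate: reaction conditions,
stoichiometry and concentration; yields and kinetics; chromatogram peak
shapes, baselines and detector wavelength structure; and real assay noise
beyond independent bit flips. Passing tests on these fixtures therefore
demonstrate that the inferential machinery recovers planted relational
structure and calibrated surprise — not that any particular laboratory assay
meets the model's independence assumptions.

## Minimal-explanation readout

`active_properties()` reports how much latent structure a fitted binary
pairwise theory actually uses: per posterior draw, each reactive observation
is attributed to its maximal cause $(I, J) = \arg\max M_{aI} M_{bJ} R_{IJ}$
(ignored below a 0.01 relevance floor), the union of participating
properties is counted, and the per-draw counts are summarized by their
median — a label-invariant statistic. An absolute threshold on posterior
parameter magnitudes would not work here: a rule witnessed by a single
Bernoulli observation constrains the *product* of three latents only weakly,
so no prior in this family concentrates individual entries near 1, yet the
identity of the best-supported cause is stable across draws.

## Problem sizes and numerical choices

The test suite and the acceptance script run, per analysis, 2 chains of
800-900 warmup and as many kept draws (500 for mixtures, 600 for the
recovery study), sizes at which every stochastic check passed with margin on
repeated seeds during development. Likelihood floor $10^{-9}$; activity
floor $0.01$; anomaly threshold $-\ln 0.05$; chromatogram match tolerance
0.1 min; grid resolution chosen so the total grid stays near $2 \times 10^6$
points (hard cap $10^7$). Externally recorded campaigns can be replayed by
loading their space and observation files (`load_observations()`) and using
the recorded outcomes as the replay's outcome source (the `explore`
subcommand does exactly this), but nothing in the package requires external
data.

## Known limitations

- Static HMC with jittered path length, not a dynamic no-U-turn sampler;
  for the ~600-parameter named-reaction theory, mixing of raw latents is
  slow and only label-invariant predictive summaries should be trusted.
- The mixture weight of compare_theories() relaxes on the timescale of the
  joint latent posterior; for near-equivalent theories its effective sample
  size is small and summaries should be read together with the reported
  `ess_w`.
- Disruption scores rely on importance reweighting from the current
  posterior; after many un-refitted steps the effective sample size of the
  weights degrades.
- The emission map scales as (number of modes) × (width); large $K$ with
  arity 4 and wide outcome vectors is outside the intended desk scale.
- Reaction conditions are carried as metadata but do not enter the
  likelihood.
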