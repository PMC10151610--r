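# reactoracle

Bayesian interpretation of combinatorial chemical-reactivity data.

Autonomous and semi-autonomous chemistry platforms can run hundreds of
combinatorial experiments — mix 2–4 reagents from a roster, assay the result —
but turning those outcomes into *chemistry* (which latent traits of which
reagents drive the observed reactions? which result is a discovery and which
an anomaly? what should be tried next?) is usually left to a human expert,
with all the hidden bias that entails. `reactoracle` is for chemists and
cheminformaticians who want that interpretation step to be an explicit,
quantitative, reproducible model: expert knowledge goes in as priors, every
observation updates a posterior, and "surprise" and "discovery" become
numbers.

## The model

Each entity $e$ (a compound, or a fingerprint bit in structural theories)
carries each of $K$ abstract properties to a degree $M_{eI}\in[0,1]$.
Symmetric reactivity tensors $R^{(k)}$ over property indices ($k = 2,3,4$
components) say which property combinations react. For a pair
$(\alpha,\beta)$ the component matrix

$$P_{\alpha\beta IJ} = M_{\alpha I}\,M_{\beta J}\,R^{(2)}_{IJ}$$

gives the probability of reaction via properties $(I,J)$; causes combine by
noisy-OR over all property assignments and over all sub-combinations of the
mixture, pass through an optional emission map onto the bits of a
chromatogram-derived reactivity vector, and finally through a false
positive/negative noise channel. Posteriors are sampled by Hamiltonian Monte
Carlo with analytic gradients (compiled core); a brute-force grid integrator
acts as an independent oracle on small instances. On top of the posterior
the package computes per-observation surprise ($-\log$ predictive
likelihood; a priori, online, and a posteriori), ranks unexplored
experiments by expected disruption, shortlists anomalies, and compares rival
theories through posterior mixture weights under content-addressed
identifiers. Synthetic chemical spaces with planted rules (acid–base,
Diels–Alder, Passerini, and an 8-reaction named-reaction panel with 8-bit
reactivity vectors) generate every dataset used in the tests. See the
methods vignette (`vignettes/reactivity-oracle.Rmd`) for the full model and
the design choices.

## Worked example

Fit the structure-free theory to the Diels–Alder toy space — six compounds,
three reactive pairs, cyclopentadiene allowed to react with itself — and ask
how much latent structure the posterior actually uses:

```r
library(reactoracle)

da  <- make_diels_alder_space()
log <- simulate_log(da$space, da$outcome_source, experiments = da$experiments)
th  <- reactivity_theory(da$space, K = 8, width = 1,
                         noise = noise_model(1e-3, 1e-3))
post <- fit_posterior(th, log, mcmc_config(seed = 1, chains = 2,
                                           warmup = 800, draws = 800))
post
#> <reactivity_posterior> 1600 draws (2 chains), 84 parameters; max split-Rhat 1.005, 0 divergences

act <- active_properties(post, log, compound = "cpd")
act$total        # 4  -- properties used of the 8 offered
act$on_compound  # 2  -- carried by cyclopentadiene (diene + dienophile roles)
```

Although eight abstract properties are available, the fitted theory explains
all sixteen observations with four — two of them on cyclopentadiene, whose
self-reactivity forces two *mutually reactive* characters. The surprise
trace tells the discovery story per observation:

```r
tr <- surprise_trace(th, log, mcmc_config(seed = 1, chains = 2,
                                          warmup = 800, draws = 800),
                     components = c("prior", "final"))
tr[rowSums(log$outcomes) > 0, c("experiment", "a_priori", "a_posteriori")]
#>        experiment a_priori a_posteriori
#>         acid+base     1.47         1.49
#>           cpd+cpd     1.50         1.14
#>    cpd+dienophile     1.49         1.29
nrow(anomaly_shortlist(tr))
#> 0
```

The two cyclopentadiene reactions corroborate each other (their final
surprise drops below the prior), and at the end no observation exceeds the
anomaly threshold: the fitted theory explains everything it saw. The same
machinery drives `replay_exploration()` (closed-loop random or
most-disruptive experiment selection with a repeat-attempt policy for
surprising outcomes) and `compare_theories()` (mixture-weight comparison of
rival theories). A thin command-line wrapper with `fit / explore / compare /
simulate / vectorize` subcommands is installed at `inst/cli/reactoracle`.

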