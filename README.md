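# kinetix

Simulation and gradient-based training of kinetic metabolic models in R.

## What it does, and for whom

Systems biologists describe metabolism with ODE models
`dm/dt = S v(t, m, θ)`: the stoichiometric matrix `S` maps reaction fluxes
`v` to concentration changes of the metabolites `m`. Writing such a model is
the easy half; *parameterizing* it against sparse, noisy time-series
concentration data is the hard one — parameters span orders of magnitude,
the systems are stiff, and the fitting landscapes are sloppy and
multimodal. kinetix brings the training toolbox of neural ODEs to this
problem:

* **SBML in, SBML out** — parse Level 2/3 models (species, compartments,
  global/local parameters, MathML kinetic laws, assignment rules, initial
  assignments, function definitions) into executable ODE systems, and
  export parameterized models back (`parse_sbml()`, `export_sbml()`).
* **Rate-law registry** — build models by hand from reusable kinetic
  mechanisms (mass action, Michaelis–Menten irreversible and
  Haldane-reversible, Hill, inhibition laws, ordered bi-bi, facilitated
  diffusion, ...), freely extensible (`instantiate_law()`,
  `register_law()`).
* **Stiff simulation** — 5th-order implicit adaptive integration (Radau
  IIA) with tight tolerances; integration failure is a counted result, not
  a crash (`simulate_model()`).
* **Training loop** — mean-centered loss
  `J = (1/N) Σ ((pred − obs)/⟨obs⟩)²`, gradients obtained by a reverse-mode
  discrete adjoint through the integrator, log-space parameter updates with
  AdaBelief, gradient global-norm clipping at 4, early stopping, and
  multi-dataset gradient averaging (`train()`, `train_multi()`).
* **Multi-start screening** — log-space Latin hypercube initialization
  within `[θ_true/X, X·θ_true]`, initialization- and training-success
  percentages, relative improvement, seeded replicates (`lhs_sample()`,
  `screen_model()`).
* **Hybrid models** — mask a reaction and learn it with a neural flux term,
  `dm/dt = S₍₋ᵢ₎ v₍₋ᵢ₎ + NN(t, m, w, b)`, trained jointly with the
  mechanistic parameters (`mask_reaction()`, `hybridize()`,
  `masking_experiment()`).

## A worked example

Fit a two-rate mass-action chain A → B → C (true rates 0.7 and 0.3) from
ten noiseless observations per species, starting at parameters drawn up to
10× off:

```r
library(kinetix)

fx <- fixture_model("chain")
ds <- generate_synthetic_dataset(fx$model, t_end = fx$t_end)  # 3 x 10 points
theta0 <- c(v1_k = 2.1, v2_k = 0.06)                          # 3x and 1/5x off
fit <- train(fx$model, theta0, ds)
fit
#> <kx_train_result> status=converged-early, 807 updates, final loss 9.825e-07 (best 9.825e-07)
round(fit$theta, 4)
#>   v1_k   v2_k
#> 0.7002 0.2995
```

The run stops as soon as the mean-centered loss drops below the
early-stopping threshold `1e-6`; both rate constants come back within a
fraction of a percent of their true values. The same loop scales to a
multi-start screen:

```r
samples <- lhs_sample(fx$theta_true, X = 10, n = 20, seed = 1)
sc <- training_screen(fx$model, ds, samples)
sc
#> <kx_screen_result> 20 runs: init 100.0%, trained 100.0%, median r 1.000
```

All 20 Latin-hypercube starts integrate at iteration 0 (100% initialization
success) and every one trains below the success threshold `1e-3` (100%
training success), with a median relative improvement of 1.0 — i.e. the
loss is reduced by essentially its whole initial value.

A command-line front end over the same functions ships in
`inst/cli/kinetix.R` (subcommands `simulate`, `train`, `screen`,
`hybrid-mask`).

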