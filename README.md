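# islandbrains

Comparative-phylogenetic tools for testing whether birds endemic to oceanic
islands evolved relatively larger brains *in situ* — or whether big-brained
lineages simply colonize islands more often.

The package is aimed at comparative biologists with a species trait table
(brain volume, body mass, an insularity flag, life-history and ecological
covariates) and one or more dated phylogenies. It implements the full
analytical chain for the island–brain question:

* **Bayesian phylogenetic mixed models (BPMMs).** Gibbs sampling for
  Gaussian, binary (probit latent liability) and binomial-count responses
  with a tree-structured random effect realized through its sparse
  precision, so ancestral nodes carry posterior effects. Inverse-Wishart
  (V = 1, ν = 0.002) variance priors; 2,100,000 / 100,000 / 2,000
  iteration–burn-in–thinning reference schedule (1,000 retained draws);
  posterior modes, 95% HPD intervals and two-tailed pMCMC.
* **Relative brain size** as the residual of a log–log phylogenetic GLS of
  brain volume on body mass: `log(brain) = a + b·log(body) + ε`,
  `ε ~ N(0, σ²V)` with V the shared branch-length matrix.
* **Sister-taxa comparisons**: each island endemic paired with its closest
  continental relatives by patristic distance, pair identity as random
  effect, including the island-rule interaction (insularity × body-size
  category).
* **Two-step ancestral transition analysis**: reconstruct island/mainland
  states at every node, classify at posterior probability > 0.90, and
  contrast ancestral relative brain size across transition categories —
  continent→continent (α), continent→island (β), island→island (γ) — so
  that γ − β > 0 indicates in-situ evolution and β − α > 0 indicates
  colonization sorting.
* **Phylogenetic path analysis**: d-separation basis sets, Fisher's
  C = −2Σln pᵢ ~ χ²₂ₖ, and model ranking by CICc = C + 2qn/(n − q − 1)
  over causal scenarios linking insularity, environmental variation, diet
  breadth, developmental period and relative brain size.
* **A synthetic-data generator** (birth–death trees, two-state island
  histories, Brownian traits, a known structural-equation model) providing
  ground truth for every recovery experiment.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic dataset
with a known in-situ island effect of 0.06 log units (400 species, 59
island endemics over 10 independent colonizations):

```sh
Rscript analysis/01_simulate.R 1         # tree + trait table + manifest
Rscript analysis/02_global_models.R 1    # global insularity BPMMs
Rscript analysis/03_sister_comparisons.R 1
Rscript analysis/04_ancestral_transitions.R 1
Rscript analysis/05_path_analysis.R 1
```

Output of the run above (seed 1):

```
Model 1 (N = 400): insularity beta mode = 0.069, HPD [0.028, 0.105], pMCMC = 0.002
59 pairs (154 species). Paired insularity beta = 0.140 [0.100, 0.179], pMCMC = 0.002
Classified ancestor-child links: alpha=676, beta=7, gamma=71
beta_minus_alpha: mode = -0.002 [-0.030, 0.034], pMCMC = 0.906
gamma_minus_beta: mode = 0.068 [-0.023, 0.158], pMCMC = 0.154
Best model: full (C = 8.32, df = 6, p = 0.216, CICc = 24.68)
  ...
  INS DVP  0.38307   DVP RBS  0.16847
  INS IVE  0.49050   IVE RBS  0.09244
```

Reading these numbers: the global model finds island endemics with
relatively larger brains after allometric and phylogenetic control (β mode
0.069, interval excluding zero — the generator planted 0.06 plus small
mediated environmental effects); the paired sister-taxa contrast agrees
(and is larger, because deep island clades accrue more in-situ change than
the species-wide average); the transition contrasts point toward in-situ
evolution (γ − β = 0.068) rather than colonization sorting (β − α ≈ 0);
and the top two causal scenarios are the full mediation model and the
environment + life-history structure that generated the data (ΔCICc =
0.15), with the recovered edge coefficients close to the generating values
(island → environmental variation 0.49 vs 0.449 planted; developmental
period → brain 0.168 vs 0.155). Result tables land under `results/`.

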