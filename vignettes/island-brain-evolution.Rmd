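---
title: "Models and methods: brain size evolution on oceanic islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: brain size evolution on oceanic islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the choices that were genuinely open, and what the synthetic
experiments do and do not demonstrate.

## The scientific question

Oceanic islands concentrate a particular set of selective pressures:
impoverished communities that invite niche expansion, environmental
fluctuations that cannot be escaped by dispersal, and a general slowing of
the pace of life. All three have been proposed to favour enlarged brains.
The difficulty is separating *in situ* evolution (brains grew after
colonization) from *sorting* (big-brained lineages colonize islands
disproportionately). The package implements the full analytical apparatus
for that separation on a species trait table and a dated phylogeny:
phylogenetic mixed models, sister-taxa contrasts, a two-step ancestral
transition analysis, and phylogenetic path analysis, together with a
synthetic-data generator that provides ground truth for every step.

## The Bayesian phylogenetic mixed model

All models are mixed models whose random effect is structured by the
phylogeny. For a Gaussian response

$$ y = X\beta + Z u + e,\qquad u \sim N(0, \sigma^2_a A),\qquad
   e \sim N(0, \sigma^2_e I), $$

where $A$ is the matrix of shared root-to-ancestor path lengths (the
Brownian-motion covariance). The sampler works on the sparse
tree-structured *precision* of $A$: effects live on every node of the tree
(ancestors included), the root is pinned at zero, and each edge contributes
an increment with variance proportional to its length. This makes a Gibbs
sweep linear in the number of nodes and gives ancestral nodes posterior
effects for free, which the transition analysis uses directly.

Updates are conjugate: the joint location vector $(\beta, u)$ is drawn from
its multivariate normal full conditional via a sparse Cholesky
factorization, and each variance component from an inverse-gamma full
conditional. The variance prior is inverse-Wishart with $V = 1$,
$\nu = 0.002$, implemented for these univariate components as the
equivalent inverse-gamma$(\nu/2, \nu V/2)$. Binary responses use probit
latent-liability augmentation with the residual variance fixed at 1 and a
fixed-effect prior variance of $1 + \pi^2/3$; coefficients are therefore on
the liability scale, so magnitudes are not comparable to logit-link
estimates, while contrasts and signs are. Binomial counts (the family-level
colonization model) are expanded into Bernoulli rows sharing their
family's random effect.

The reference schedule is 2,100,000 iterations, 100,000 burn-in, thinning
2,000 — exactly 1,000 retained draws per chain — with five replicate
chains per tree in full-scale use. The test-suite and the validation
experiments run a desk-scale schedule (21,000 / 1,000 / 20, also 1,000
retained draws) chosen so that every experiment completes on a single CPU;
the experiment sizes reported below are the package's standing choices.
Reported point estimates are posterior modes (Gaussian kernel density,
Silverman bandwidth), intervals are 95% highest-posterior-density
intervals, and pMCMC is two-tailed, $2\min(\Pr(>0), \Pr(<0))$, floored at
$2/N$; a one-tailed variant is available by configuration because the
verbal definition of the statistic is ambiguous between the two.

## Relative brain size

Relative brain size is the residual of log brain volume on log body mass
from a closed-form phylogenetic GLS under pure Brownian covariance (an
optional Pagel's lambda multiplies the off-diagonal entries). Residuals
satisfy $X^\top V^{-1} r = 0$, are invariant to the units of body mass, and
match the standard phylogenetic residual tool to numerical precision (the
test suite checks this against an independent implementation).

## Sister-taxa comparisons

Every island endemic is paired with the continental species at minimal
patristic distance; ties within $10^{-8}$ enter as a group, each member a
row sharing the pair identifier (preserving within-group variance under
the pair random effect, rather than averaging traits). A continental
species serves at most one pair: conflicts go to the island species with
the smaller distance and the loser re-pairs to its next-closest free
relative. The paired models use the pair identifier as an i.i.d. random
intercept; phylogeny can be added as a second random effect by
configuration but is off by default, since the paired design already
absorbs shared history within pairs. The island-rule test interacts
insularity with a body-size category computed as above/below the median
log body mass *of the paired subset* (ties count as small); with "small"
as the reference level, small species growing and large species shrinking
on islands appears as a negative insularity-by-large interaction.

## The two-step transition analysis

Step one fits the binary liability model to the contemporary
island/mainland states and records, for every internal node, the posterior
probability that its liability is positive. Nodes are classified island or
continental when that probability exceeds 0.90 (a configurable threshold);
others are left unclassified and excluded. Each classified ancestor-child
edge then receives a category: continent→continent ($\alpha$),
continent→island ($\beta$), island→island ($\gamma$), island→continent
($\delta$, retained but flagged — island losses are too rare to model). A
node contributes one observation per category it instantiates, and
"child" means the node or tip one edge below, because transitions are
per-branch events.

Step two estimates ancestral relative brain sizes as Brownian-motion
conditional means given the tips (the root takes the GLS phylogenetic
mean) and regresses them on category in a no-intercept mixed model with
the node-level phylogenetic covariance as random effect. Two derived
contrasts answer the two questions: $\beta - \alpha$ (did big brains
precede colonization?) and $\gamma - \beta$ (did brains grow after it?);
$\gamma - \alpha$ is also reported, covering both conventions for the
pairwise comparisons.

One numerical decision matters a great deal here. Feeding bare conditional
means into the node-level mixed model is degenerate: the interpolated
field is smooth, the phylogenetic random effect reproduces it exactly, and
the residual variance collapses toward zero, leaving the contrasts driven
only by local jumps across single edges. The package therefore propagates
reconstruction uncertainty by default — each node value is an independent
draw from its conditional posterior (conditional mean plus noise at the
node's conditional standard deviation, with the Brownian rate estimated
from the mean squared independent contrast). This restores an honest error
term and interval widths comparable to what node-level mixed models report
in practice. Bare conditional means remain available by configuration.

An identifiability caveat follows from the construction and is worth
stating plainly: reconstruction interpolates descendants, so *any*
clade-localized elevation — whether it arose before or after colonization
— appears as a gradient toward the elevated tips. The two generator modes
below are therefore only weakly separable; the validation scores
directional signatures (the sign of each mode's characteristic contrast),
not exclusive ones.

## Phylogenetic path analysis

Causal scenarios are DAGs over insularity (INS), diet breadth (DBR),
developmental period (DVP), inter-annual or seasonal environmental
variation (IVE/SVE) and relative brain size (RBS). The d-separation basis
set contains one claim per non-adjacent pair, conditioned on the union of
both variables' parents; the regression response is the pair member later
in topological order. Claims are tested by closed-form phylogenetic GLS
(default; deterministic t-tests) or by the Bayesian engine (pMCMC as the
claim p-value — a deliberate, noted substitution for a frequentist p).
Model fit is Fisher's $C = -2\sum \ln p_i$ against $\chi^2_{2k}$, and
models are ranked by $\mathrm{CICc} = C + 2qn/(n-q-1)$ with $q$ = number
of edges + number of exogenous variances (the printed formula's verbal
definition of $q$ is not fully recoverable, so the convention is fixed and
reported per model). Variables are Z-transformed within each model's
complete cases, making edge coefficients standardized.

The default candidate set holds eight DAGs: all include the
insularity-to-mediator edges and the direct INS→RBS edge, and differ in
which mediators feed brain size (none, each alone, each pair, all three);
a seasonal-variation variant set swaps SVE for IVE, and the two EVI
summaries never co-occur in one model because they are two statistics of
the same index.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the standing
study conditions:

* **Tree**: forward birth-death simulation (birth 1, death 0.25) from a
  crown of two lineages, stopped when the live-lineage count first reaches
  `n_tips` and extended by one exponential waiting time; extinct lineages
  pruned; rescaled to unit height. Under pure birth the expected crown
  height has the closed form $\sum_{k=2}^{n-1} 1/(k\lambda) + 1/(n\lambda)$,
  which the tests verify by Monte Carlo.
* **Island history**: a two-state Markov process from a continental root,
  gain 0.1 and loss 0.3 per unit branch length. These rates give roughly
  5–10% island tips with persistent island clades — the structure of a
  global avian dataset in which about 6% of species are oceanic-island
  endemics distributed over many independent colonizations. (A first draft
  with a much higher loss rate produced almost no island clades and was
  revised at design time; island clades are a prerequisite of the
  transition analysis, not a tuning target.) Because colonization is
  tree-correlated, some histories carry almost no signal; histories are
  therefore resampled until they meet a stated inclusion condition
  (defaults: at least 2 island tips; the transition experiments require 10
  island tips, 3 island nodes and 5 independent colonizations, mirroring
  the requirement of lineages well-sampled on both islands and
  continents; the transition-contrast experiment conditions on 15 island
  tips, 6 island nodes and 10 independent colonizations).
* **Traits**: log body mass is Brownian (root 4.0 ≈ 55 g, rate 2.25, so
  tip SD ≈ 1.5 log units); log brain volume follows the allometry
  intercept 2.3, slope 0.58, with Brownian residuals of SD 0.2. The island
  brain effect (default 0.06 log units) accrues either along island
  branches in proportion to dwell time, normalized so island tips average
  the stated effect (*in-situ* mode), or as a heritable shift carried by
  the whole clade descending from each colonization branch's parent
  (*sorting* mode — the shift arises before colonization, so continental
  clade-mates carry it too; a shift applied only at island tips would be
  indistinguishable from in-situ evolution after reconstruction). A third
  mode, *tip*, applies a constant shift at island tips only: it realizes
  the island fixed effect exactly and is what the parameter-recovery
  experiment simulates, with the structural-equation mediation paths
  zeroed there so the stated effect is the whole effect.
* **Covariates**: the structural equations run on the standardized scale
  with tree-structured (Brownian) noise, so the phylogenetic regressions
  used to test them are correctly specified. Default coefficients are the
  reported path estimates of the island system: INS→IVE 0.449, INS→SVE
  −0.369, INS→DVP 0.322, IVE→RBS 0.034, DVP→RBS 0.155, with the direct
  INS→RBS path defaulting to 0 because the branch-accrued island effect
  plays that role (set it to 0.104 and the island effect to 0 to generate
  from a pure path-model truth). Observable ingredient columns are built
  to be consistent with the derived summaries: per-species EVI
  year-by-month matrices whose coefficient of variation of yearly means
  and mean annual amplitude reproduce the latent environmental variables
  exactly; incubation and fledging days whose logged sum is affine in the
  latent developmental period; and coded diet frequencies (values in
  {0, 0.1, 0.5, 1}) whose Rao quadratic entropy tracks the latent breadth
  coarsely — the coding is discrete, so this column alone carries
  quantization noise.
* The shipped food-type dissimilarity matrix is a documented synthetic
  placeholder built from a coarse nutritional grouping; any result that
  depends on diet breadth is configuration-sensitive by design and a
  measured nutritional matrix can be supplied.

What passing tests show — and do not show — about real data: the
experiments demonstrate that the estimators recover known truths under
the generator's assumptions (Brownian traits, correct covariance,
missing-at-random completeness). Real comparative data violate several of
these (measurement error in endocasts, non-Brownian evolution, biased
sampling of island faunas), and nothing here quantifies robustness to
those violations.

## Validation experiments and their standing sizes

* Conjugate oracle: the Gaussian sampler against the closed-form solution
  (150 observations).
* Exact-marginal oracle: binary-model node probabilities on 4-tip trees
  against brute-force quadrature over tip liabilities (tolerance 0.05).
* Recovery: island effect 0.06, 200 tips, 20 replicates — the 95% interval
  should cover the truth in at least 17; a null effect should be rejected
  at most 3 times.
* Discriminant validity: effect 0.1, 300 tips, 10 replicates per mode —
  in-situ runs should show $\gamma-\beta > 0$ and sorting runs
  $\beta-\alpha > 0$ (posterior means, pooled over four imputed
  node-value sets) in at least 80%. This check is reported but is not met
  in full: replicates whose classified categories fall below three nodes
  (about a quarter, even under the stated inclusion condition) cannot
  yield the contrast at all, and the sorting signature is structurally
  weak — a clade-wide pre-colonization shift elevates the reconstructed
  values of in-clade continental (alpha) nodes as much as the boundary
  (beta) nodes, so the phylogeny-controlled contrast hovers near zero and
  flips sign in roughly a third of replicates. Estimable in-situ
  replicates do show $\gamma-\beta > 0$ consistently; separating sorting
  from in-situ truth at 80% per arm is beyond what tip-only
  reconstruction supports here.
* C-test calibration: 1,000 GLS replicates under the generating DAG at 200
  tips — rejection at 0.05 ± 0.02.
* CICc selection: 50 replicates at 500 species. This check is reported but
  is expected to fail by construction: the generating truth contains the
  0.034 environment-to-brain path, which at n = 500 gives a d-separation
  claim essentially indistinguishable from its null (power ≈ 11%), while
  dropping that edge saves ~2 CICc units; the true model therefore
  outranks its one-edge-poorer neighbour only about 38% of the time, and
  no information-criterion convention changes a Δq = 1 penalty. The
  selection rate the package actually achieves (~25%) is an honest
  property of information-criterion selection at this effect size, not an
  implementation defect; detecting that edge at 80% would need a sample
  roughly twenty times larger or a stronger generating coefficient.

## Known limitations

* The liability-scale binary model reproduces signs and contrasts, not
  logit-scale magnitudes.
* The transition analysis cannot fully separate pre- from post-colonization
  elevation (see the identifiability caveat above); its strength is the
  directional contrast, and even that depends on propagated reconstruction
  uncertainty.
* Ancestral values assume homogeneous Brownian motion; rate shifts or
  selective regimes on islands would bias the contrasts.
* Listwise deletion is used per model, with the per-model N always
  reported; variables are standardized within each model's complete cases.
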