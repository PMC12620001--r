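---
title: "Differentiable breeding schemes and gradient-based mate allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable breeding schemes and gradient-based mate allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedgrad)
```

## The problem

Recurrent selection improves a breeding population by cycling through
selection and intermating.  Beyond *which* parents to select, a breeder
must decide *how many progeny to allocate to each cross*.  `breedgrad`
treats that allocation as a parametric policy and optimizes it with
gradients: the entire multi-generation scheme — meiosis included — is
expressed as a differentiable computational graph, so the sensitivity of
the final population's merit to the allocation weights of every
generation is available by reverse-mode automatic differentiation.

## Model

A population holds $N$ diploid individuals genotyped at $m$ biallelic
markers, each individual a phased binary vector $w_i \in \{0,1\}^{2m}$
(maternal haplotype first).  All markers are QTLs with additive effects
$\beta \in \mathbb{R}^m$, duplicated over haplotypes into
$\alpha \in \mathbb{R}^{2m}$, so the genotypic value is
$\alpha^\top w_i$.  The merit of a population is the mean genotypic value
of its top-$K$ individuals, and genetic gain is the difference in merit
between a later generation and the founders.

Each generation:

1. **Selection.**  One of three truncation strategies of decreasing
   intensity ranks individuals by *weighted breeding value*
   $\mathrm{WBV}_i = \sum_j \alpha_j\, p_j^{-1/2} w_{ij}$, where $p_j$ is
   the minor allele frequency — rare alleles are up-weighted to protect
   long-term gain.  SI1 takes the best $n=15$; SI2 clusters marker
   dosages (Ward linkage, Euclidean distance) into 25 groups and takes
   each group's best; SI3 takes the best 50.
2. **Pair scoring.**  The $n$ parents form all $P = n(n+1)/2$ diallel
   pairs (selfing included).  Each pair $k$ gets a feature vector
   $\omega_k$: the mean parental WBV, and the *expected genetic variance
   of progeny* (GVP)
   $\omega_{k2} = \sum_{j,j'} \sigma_{kjj'} \beta_j \beta_{j'}$ with
   $\sigma_{kjj'} = \tfrac14 (1 - 2 r_{jj'}) \sum_{i \in \{M,P\}}
   (w_{kij} - w_{kij+m})(w_{kij'} - w_{kij'+m})$,
   a closed-form variance implied by the parents' phase and the pairwise
   recombination rates $r_{jj'}$.
3. **Allocation.**  Progeny are assigned to pairs by the softmax
   $\pi_k \propto \exp(\omega_k^\top \theta^{(\tau)})$; the per-generation
   weights $\theta^{(\tau)} \in [0.5, 3.5]^d$ are the optimized policy.
   $\theta = 0$ is the non-optimized equal-allocation baseline (EQ).
4. **Meiosis.**  A gamete inherits marker $j$ from haplotype
   $1 + (\sum_{j' \le j} \eta_{j'} \bmod 2)$, where
   $\eta_j \sim \mathrm{Bernoulli}(r_{j-1,j})$ are crossover indicators
   and the first marker of every chromosome uses the virtual rate $1/2$
   (chromosomes segregate independently).  Two independent gametes are
   concatenated into a progeny.

### Making it differentiable

Sampling a pair per progeny slot is discrete.  The graph replaces it
with the Gumbel-Softmax relaxation
$y_{ik} = \mathrm{softmax}_k\!\big((\log \pi_k + g_{ik})/c\big)$,
$g_{ik} \sim \mathrm{Gumbel}(0,1)$: every slot generates one candidate
offspring from *every* pair (the segregation draws $\eta$ fixed per
slot-pair) and takes the $y$-weighted convex combination, giving soft
allele scores in $[0,1]$.  As $c \to 0$ the weights become one-hot and
the hard simulator is recovered.  Merit, WBV, GVP and allele frequencies
are all smooth in the soft scores, so with the noise $(g, \eta)$ fixed
and discrete index sets (parent rankings, clusters, the top-$K$ set,
clamp branches) frozen at their forward values, the map from the weights
$\theta^{(\tau)}$ of every generation to the final merit $F$ is smooth
and is differentiated in reverse.  The objective is the expectation
$F(\theta) = E_\eta[E_g[F(\theta, g, \eta)]]$, estimated by Monte Carlo.

Gradients flow only through the allocation path; selection rankings are
treated as constants of the graph.  Differentiable *selection* of
individuals is possible under the same relaxation but is deliberately
out of scope: the evaluated schemes use the fixed strategies above.

### Optimization

The weights are optimized in an unconstrained pre-image:
$\theta = 0.5 + 3 \cdot \mathrm{logistic}(\nu)$.  Plain stochastic
gradient ascent updates $\nu^{(\tau)}$ with fresh noise every epoch.
Two presets differ only in the initial GVP weight — GORA1 starts high
($\nu_{\mathrm{GVP}} = +1$), GORA2 low ($\nu_{\mathrm{GVP}} = -2$) —
since that initial value materially changes both the optimized policy
and the diversity trajectory.  Optimized policies are then evaluated by
the *hard* simulator: allocation probabilities become integer counts by
largest-remainder rounding and progeny are generated discretely, with
paired meiosis seeds across strategies to cut comparison variance.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `generations` (T) | 4 | breeding cycles |
| `K` | 5 | top-K defining merit |
| `selection` | SI2 | SI1/SI2/SI3, decreasing intensity |
| `temperature` (c) | 0.5 | Gumbel-Softmax sharpness; smaller is closer to discrete sampling but noisier gradients; no annealing |
| `maf_floor` | 0.01 | lower clamp on $p_j$ so $p^{-1/2}$ stays finite at monomorphic markers |
| `standardize` | TRUE | z-score $\omega$ columns across pairs; WBV and GVP have incomparable natural scales, and a shared $\theta$ domain presumes comparable features |
| `lr`, schedule | 0.1, ×0.5 / 50 epochs | SGD ascent step; mild decay, since aggressive schedules can halt the search early |
| `epochs` × `n_mc` | 200 × 100 (study scale) | function evaluations; desk-scale work uses 30 × 20 |

Minor allele frequencies are recomputed from the current (soft)
population each generation — "minor allele frequency" naturally refers
to the population being allocated, and the frequency spectrum drifts
over cycles.

## The founder generator

Founders emulate a diploid crop with 10 chromosomes, $N = 250$
individuals and $m = 30$ or $m = 500$ QTLs of known effect (scaled-down
geometries are used throughout the tests).  Haplotypes are drawn marker
by marker: target alternative-allele frequencies $f_j \sim U(0.05, 0.5)$,
and within a chromosome each haplotype copies its previous allele with
probability $\exp(-0.1\, d)$ ($d$ the gap in cM) or redraws from
$\mathrm{Bernoulli}(f_j)$.  QTL effects are i.i.d. $N(0, 1)$.  Genetic
distances convert to recombination rates by the Haldane map function
$r = \tfrac12(1 - e^{-2d/100})$, and markers on different chromosomes
recombine at $r = 1/2$.

This generator reproduces the first-order structure the method feeds on
— a realistic frequency spectrum, LD that decays with genetic distance,
independent chromosomes — but not coalescent genealogy, mutation,
population structure, dominance or epistasis, nor estimated (rather than
known) marker effects.  Passing tests therefore demonstrate the
correctness of the machinery and the behavior of the optimizer under
these idealized conditions, not performance on real germplasm.

## Numerical choices

* $\pi$ is floored at $10^{-12}$ before the log inside the
  Gumbel-Softmax; softmaxes subtract the row maximum.
* WBV ranking ties break toward the lower row index, making selection
  fully deterministic; zero-variance feature columns standardize to 0.
* The bounded transform keeps every optimized $\theta$ strictly inside
  $(0.5, 3.5)$; the EQ baseline's $\theta = 0$ deliberately bypasses the
  transform (it is a reference policy, not an optimizable point).
* Largest-remainder rounding of $N\pi$ breaks remainder ties by pair
  index, so hard allocation is deterministic given $\pi$.
* One master seed expands into per-component seeds by a hash of the
  component tag (`child_seed`), so founders, trait, optimization noise
  and evaluation meiosis draw from decoupled reproducible streams.
* Gradient validation uses common random numbers: one frozen noise bank
  serves the base and all perturbed evaluations, so central differences
  at $h = 10^{-3}$ in $\nu$ compare the same deterministic function.
  The grid diagnostic freezes one bank across all lattice nodes for the
  same reason.  Fresh noise per epoch is used for SGD itself.

## Design choices where the design was open

* **Per-chromosome parity reset.**  The crossover-parity recursion is
  defined along one marker sequence; with multiple chromosomes each
  chromosome's first marker re-randomizes the source haplotype at rate
  $1/2$, which is exactly independent assortment.
* **SI2 clustering.**  "Hierarchical clustering on marker genotypes"
  leaves the metric open; Ward linkage on Euclidean dosage distances is
  the standard genomic choice and gives compact, balanced clusters.
* **Candidate-per-pair construction.**  Every progeny slot builds one
  offspring from every pair, at $O(N P m)$ cost per generation, keeping
  the relaxation exact w.r.t. the pair-sampling formulation rather than
  approximating with a subsample.  Desk-scale geometries keep this
  affordable (the Rcpp kernels process one slot-pair-marker entry in a
  few ns).
* **In-graph rankings as constants.**  Merit's top-$K$ set, parent
  rankings and cluster memberships are piecewise constant in $\theta$;
  differentiating through them is neither possible nor necessary for
  the allocation path.  The finite-difference checks confirm the frozen
  graph's gradients are the correct derivatives between ranking
  switches.

## Problem sizes used in the tests

The shipped tests and the acceptance script run scaled-down versions of
the study conditions, chosen to exercise every code path with
comfortable statistical margins: gradient checks on $N = 20$, $m = 12$,
$T = 2$ schemes; meiosis and GVP oracles with $10^5$ and
$5 \times 10^4$ draws; convergence on ten seeded one-generation runs
(30 epochs × 20 simulations); and the headline comparison on $N = 60$,
$m = 200$ over 10 chromosomes, 10 clusters, $T = 4$, with 200
paired-seed evaluation replicates.  Study-scale settings
($N = 250$, 10,000 replicates, 200 × 100 SGD) remain available through
the same configuration objects.

## Known limitations

* Gradient fidelity degrades as the trait becomes coarse (few QTLs):
  merit is then nearly piecewise constant and ranking switches dominate
  the landscape.  Many-QTL settings behave much better.
* SGD is local; the optimized weights depend visibly on initialization
  (hence the two presets), and a mild step-decay schedule can stop
  short of the best achievable policy.
* The hard evaluator allocates deterministically (largest remainder);
  multinomial allocation would add between-replicate variance but not
  change means appreciably.
* No crossover interference, sex-specific maps, polyploidy, mutation,
  or non-additive trait architecture.

## A worked example

```{r example, eval = FALSE}
map <- build_marker_map(rep(10, 5), spacing_cM = 8)
founders <- simulate_founders(map, N = 40, seed = child_seed(7, "founders"))
trait <- sample_trait(map, child_seed(7, "trait"))
cfg <- scheme_config(generations = 3, K = 5, selection = "SI2",
                     n_clusters = 8)

opt <- sgd_optimize(founders, trait, map, strategy_preset("GORA2", 3),
                    epochs = 20, n_mc = 10, seed = child_seed(7, "sgd"),
                    cfg = cfg)
opt$trace

res <- run_experiment(founders, trait, map,
                      list(EQ = eq_params(3), GORA2 = opt$params),
                      cfg, n_reps = 100, seed = child_seed(7, "eval"))
res$summary
```
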