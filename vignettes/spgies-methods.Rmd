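---
title: "Methods: skeleton-primed interventional structure learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton-primed interventional structure learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spgies)
```

## The problem

A gene regulatory network is modelled as a causal Bayesian network: a DAG
$G$ over genes $X_1,\dots,X_p$ with the Markov factorization
$P(X)=\prod_i P(X_i \mid \mathrm{Pa}(X_i))$.  From observational
expression data alone, $G$ is identifiable only up to its Markov
equivalence class (MEC), represented by the essential graph (CPDAG): edges
take a direction only where every member of the class agrees.  Hard
interventions — clamping a gene to a fixed value, the idealization of a
knockout — cut the clamped gene's incoming edges and shrink the class to
an interventional MEC, whose I-essential graph orients every edge cut by
some intervention plus the consequences propagated by Meek's rules.

`spgies` implements this machinery end to end: equivalence-class
computation with a brute-force enumeration oracle for testing
(`essential_graph()`, `i_essential_graph()`, `enumerate_mec()`), a
simulation benchmark, observational skeleton estimators, the greedy
interventional search itself, evaluation metrics, and an
experimental-design loop that chooses the next knockout.

## The learner

`fit_gies()` is a greedy score-based search over DAGs with the
interventional Gaussian BIC.  The local score of gene $v$ with parent set
$P$ is computed over the *usable rows* $m$ — those whose intervention
targets exclude $v$, since a knockout of $v$ severs $v$'s structural
equation:

$$ s(v, P) = -\frac{m}{2}\left(1 + \log 2\pi\hat\sigma^2\right)
   - \frac{\log m}{2}\,(|P| + 1), $$

with $\hat\sigma^2$ the maximum-likelihood residual variance of the
(intercept-free) regression of $v$ on $P$.  The search alternates a
forward phase (single-edge insertions), a backward phase (deletions) and a
turning phase (reversals), each run to a local optimum, cycling until no
move improves the score; every accepted move must strictly increase the
score, which guarantees termination.  The result is reported as the
I-essential graph of the final DAG together with the member DAG itself.

Design choices made where the field leaves room:

* **DAG-space moves.**  The search walks DAGs rather than equivalence
  classes.  With the benchmark's design — every gene receives a knockout —
  the I-essential graphs are fully directed and the two walks coincide;
  the score-equivalence test (equal scores across enumerated I-MECs)
  keeps the simplification honest on observational data.
* **Tie-breaking** among equal-gain moves is lexicographic in
  (source, target), making every fit reproducible.
* **Degenerate designs** (rank-deficient regressions, zero-variance
  genes, fewer usable rows than $|P|+2$) score $-\infty$ and therefore
  reject the move.

`sp_gies()` is the two-step variant: an observational skeleton estimator
is run on the observational rows only, and its adjacencies become the
only pairs the greedy search may connect.  When PC supplies a CPDAG, only
its skeleton is used — orientations are left to the interventional score.
The restriction shrinks the search space (the source of the method's
speed at scale) and empirically also its error: restricted fits dominate
unrestricted ones on sparse benchmarks.

## Skeleton estimators

* `pc_estimate()`: order-independent ("stable") PC with Fisher-z partial
  correlation tests.  `alpha` defaults to 0.01; it is the main knob
  trading recall for precision, and at the benchmark's $n = 100$ it is
  deliberately conservative.
* `clr_scores()` on a `mutual_information_matrix()`: CLR standardizes
  each pairwise MI against both genes' background distributions
  ($z$-scores clipped at zero, combined as $\sqrt{z_i^2+z_j^2}$);
  `threshold_top_fraction()` keeps the top 10% of pairs by default.
* `aracne_prune()`: MI threshold plus the data-processing inequality,
  which deletes the weakest edge of every triangle as an indirect
  interaction.  The MI threshold for a target p-value (default $10^{-8}$)
  comes from `mi_null_threshold()`, a permutation null with an
  exponential tail fit — $10^{-8}$ is far beyond any feasible permutation
  count, so the tail above the 95th percentile is extrapolated
  exponentially.
* The default MI estimator is the Gaussian closed form
  $-\tfrac12\log(1-\rho^2)$, appropriate for the linear-Gaussian
  benchmark; an 8-bin equal-width histogram estimator stands in for
  spline/adaptive-partitioning estimators on non-Gaussian data.
* `deviation_matrix()` gives the knockout-deviation baseline: gene $j$'s
  standardized deviation under the knockout of gene $i$.

## The simulated world

`make_benchmark()` draws a random topology (Erdős–Rényi $p=0.5$,
Barabási–Albert $k=2$, or Watts–Strogatz $k=2,\ p=0.5$ rewiring), orients
it by a uniformly random node permutation, attaches a linear-Gaussian SEM,
and samples 100 observational rows plus **one** knockout row per gene.
Values the benchmark description leaves open were fixed once:

* **Weights**: magnitudes uniform on $[0.25, 1]$ with random sign —
  bounded away from zero so that no edge is unfaithful by construction —
  and unit noise variance everywhere.
* **Knockout clamp**: 0, the observational mean of every gene; this is
  what a clean knockout of a mean-centred expression value looks like.
  It is also the *least informative* clamp value for orientation: a
  single mean-valued interventional row shifts the BIC by only a fraction
  of a nat, so orientation accuracy from one knockout per gene saturates
  well below 100% no matter how many observational rows exist.  This is a
  property of the stated design, not of the implementation.
* The Barabási–Albert generator starts from $k$ edgeless seed nodes and
  attaches each arrival to $k$ distinct nodes preferentially, so the edge
  count is exactly $k(n-k)$; Watts–Strogatz rewiring preserves exactly
  $nk/2$ edges.  These identities pin the NULL-baseline SHD values of the
  benchmark tables.

What a green test on this world does *not* establish: robustness to
nonlinear mechanisms, non-Gaussian noise, hidden confounders, or hub-heavy
real regulatory networks — on real expression data the Gaussian ML score
is known to dissolve hubs that MI-based methods keep.

Random-sign weights routinely produce *strong-faithfulness violations*
(a collider's induced partial correlation cancelling a direct edge), so
the consistency tests construct their own comfortably faithful fixtures:
triangle-free DAGs with same-sign weights in $[0.6, 1]$.  On such data PC
recovers the exact essential graph in 50/50 seeds and the greedy search
the exact DAG in 46/50; on random-sign SEMs both rates drop to 50–75%
for any learner of this type.

## Metrics

* `shd()`: the L1 distance between binary adjacency matrices.  A reversed
  edge costs 2; undirected estimated edges are expanded to both ordered
  entries before comparison.  This follows the literal L1 definition even
  though part of the literature counts reversals as 1.
* `sid()`: the structural intervention distance — the number of ordered
  pairs $(i,j)$ for which parent adjustment in the estimated graph yields
  a wrong interventional distribution in the true one, computed with the
  adjustment criterion (proper back-door graph + d-separation) and
  verified in the tests against a numeric linear-SEM oracle on all
  3-node DAG pairs.
* `aucpr()`: area under the precision-recall curve over ordered pairs.
  The default interpolation is **trapezoidal with a (recall 0,
  precision 1) anchor**, under which an edgeless predictor scores
  $(1+\text{prevalence})/2$ — exactly the 0.50–0.61 NULL-baseline values
  the benchmark tables print, which is how the convention was identified;
  step interpolation (average precision) is available as an option.

## Experimental design

`run_oed_loop()` follows the acquisition protocol: per round, approximate
the graph posterior by `bootstrap_posterior()` (stratified resampling
within intervention strata, uniform weights — the weighted importance
sampling of the ABCD lineage is deliberately simplified away), score all
candidate knockouts with a utility, acquire **one** new interventional
sample at the argmax, refit, and record SHD/AUC-PR against the truth.

Two utilities are provided plus a uniform-random baseline:

* `utility_edge_orientation()`: the posterior-expected number of edges
  that the enlarged target family newly orients — computed exactly via
  `i_essential_graph()` per bootstrap DAG.
* `utility_information_gain()`: an edge-state entropy surrogate.  Define
  $H(\mathcal I)$ as the posterior-weighted, per-pair Shannon entropy of
  edge states (absent / $i\to j$ / $j\to i$) *within* groups of bootstrap
  DAGs sharing the same I-essential graph under family $\mathcal I$; the
  utility is $H(\mathcal I)-H(\mathcal I\cup\{c\})$.  Because adding a
  target only refines the grouping, the utility is nonnegative, and it
  vanishes on concentrated or fully-oriented posteriors.  This surrogate
  replaces the full entropy over DAGs, which is neither stated in closed
  form in the source literature nor tractable.

Defaults: $B = 20$ bootstrap replicates (a compromise between posterior
resolution and the cost of refitting the learner $B$ times per round; the
acceptance tests use $B = 10$ to stay inside their runtime budget),
knockout clamp 0, candidates = all genes with repeats allowed.

## Numerical notes and limitations

* All randomness flows from one integer seed through deterministic
  per-stage substreams; every fit is bit-reproducible.
* Score improvements below $10^{-9}$ are treated as ties and rejected,
  preventing cycling on equivalent-score moves.
* The greedy search can lodge in genuine local optima when the data
  barely separate orientations (one mean-valued knockout row per gene);
  a stronger reversal-with-reoptimization move was evaluated and escapes
  none of them, confirming a data rather than search limitation.
* `sid()` is quadratic-to-cubic in $p$ and warns above 2,000 nodes.
* Latent variables, cyclic graphs, soft interventions and
  environmental-condition covariates are out of scope throughout.
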