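---
title: "Methods: linking metabolic repertoire, phenotype, and phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking metabolic repertoire, phenotype, and phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microrep)
```

`microrep` asks how three views of a microbial community relate to one
another: the **metabolic repertoire** (which reactions a genome-scale model
contains), the **predicted phenotype** (which nutrients are essential under
flux balance analysis), and **phylogeny** (cophenetic distance on a rooted
tree). This vignette documents the models and procedures behind each stage,
the parameters that matter, and the design decisions taken where the design
was genuinely open. It states no empirical result beyond what the package's
tests and acceptance script compute themselves.

## Growth simulation

A metabolic model is a stoichiometric matrix $S$ (metabolites $\times$
reactions) with flux bounds. Growth is the solution of

$$\max v_b \quad \text{s.t.} \quad S v = 0, \qquad
v_{i,\min} \le v_i \le v_{i,\max},$$

where $v_b$ is the flux through the single biomass reaction, interpreted as
the growth rate in $h^{-1}$. Media act only on exchange reactions. An
exchange moves one extracellular metabolite out of the system
(`1 M_ext -> nothing`), so positive flux secretes and negative flux takes
up; "maximal uptake $u$" therefore means a lower bound of $-u$. Defaults
follow convention: uptake limit 10 mmol/gDW/h for every exchange in the rich
medium, and irreversible/reversible default bounds of $[0, 1000]$ and
$[-1000, 1000]$ mmol/gDW/h when a file omits them.

The LP is solved by a bounded-variable two-phase simplex (`lp_bounded()`)
written for this package: box bounds are handled natively rather than as
slack rows, Bland's smallest-index rule guards against cycling under the
heavy degeneracy typical of metabolic networks, and basis systems are
re-solved densely every pivot, which is cheap at these problem sizes and
avoids update drift. Before the LP is built, dead-end pruning removes
reactions that can never carry flux (a metabolite appearing in exactly one
reaction cannot be balanced), iterated to a fixed point; this leaves optima
untouched while keeping screen LPs small. The solver is validated against
an exhaustive vertex-enumeration oracle on random networks of up to eight
reactions (agreement to $10^{-6}$; observed error is at machine precision).

Only the LP *optimum* is contract-stable. Optimal flux vectors are
frequently degenerate, so the package reports one optimal vertex as-is and
no test ever asserts on individual fluxes.

## Nutrient essentiality

Each exchanged metabolite is removed from the rich medium individually by
forcing both bounds of its exchange reaction to 0 — the literal protocol,
which also blocks secretion of that metabolite; a config switch
(`removal = "uptake_only"`) closes only the uptake direction for users who
prefer that semantics. A nutrient is **essential** when growth after its
removal falls below 0.05 $h^{-1}$, an estimate of doubling requirements in
the mammalian gut. Removal problems that are infeasible count as growth 0.
Growth values are compared with an absolute tolerance of $10^{-6}$
$h^{-1}$ before the cutoff is applied; the screen iterates over exchanged
metabolites (not over transporters, which can be many-to-one).

A screen on a model that does not itself grow on the rich medium is
meaningless and raises a "baseline infeasible" error rather than returning
an all-essential answer.

## Distances

Binary profiles (reaction presence, essential nutrients, or external
annotation matrices) are always assessed against the union of features over
the whole collection. Dissimilarity is one minus the Jaccard index,
$d(i,j) = 1 - |b_i \cap b_j| / |b_i \cup b_j|$; two all-zero profiles get
distance 0 (they are identical; this avoids 0/0). Phylogenetic distance is
the cophenetic — i.e. patristic — distance: the sum of branch lengths along
the leaf-to-leaf path. Path length is used rather than a merge-height
definition because empirical trees are generally not ultrametric, where
merge heights are ill-posed. Trees must be rooted (a basal bifurcation)
with branch lengths on every edge; internal polytomies are accepted.
Distance matrices are exchanged as TSV at 12 significant digits so repeated
runs are diff-stable.

## Ordination, embedding, clustering

PCoA is classical scaling: double-center $-\tfrac12 D^2$, eigendecompose,
scale eigenvectors by the square root of their positive eigenvalues.
Jaccard matrices are usually near-Euclidean but not exactly so; axes with
nonpositive eigenvalues are dropped and their total magnitude is reported
as `negative_eigenvalue_mass` — no Cailliez or Lingoes correction, favoring
transparency over smoothing. Explained fractions are taken over the sum of
positive eigenvalues.

Discriminative reactions are found by Pearson-correlating each 0/1 feature
column with the first two coordinate axes (point-biserial correlation). The
relevance score is the $L_2$ norm of the two correlations — the two axes
are ranked jointly, since per-axis ranking would double-count features
loading diagonally — with ties broken lexicographically for determinism and
the top 200 flagged by default. Constant features get relevance 0.

t-SNE (via Rtsne, exact $\theta = 0$ on the precomputed distance matrix)
captures local structure. Defaults: perplexity
$\min(30, \lfloor (n-1)/3 \rfloor)$, seed 42; the same input and seed
reproduce the same embedding bit-for-bit. Sub-types are complete-linkage
hierarchical clusters cut at a user-chosen $k$ — choosing $k$ is
deliberately left to inspection of the dendrogram, as no automatic rule
matches how sub-types are defined in practice. Cluster ids are assigned by
size then lexicographically smallest member, so labels are stable across
runs. A contrast between clusters A and B lists features present in at
least 90% of one cluster and at most 10% of the other (`hi`/`lo`
thresholds), sorted by the presence-fraction gap.

Note that complete-linkage merges are only well-defined up to ties:
Jaccard distances of binary data are heavily tied, so two correct
implementations can produce different (equally valid) dendrograms. The
package's oracle tests therefore use continuous dissimilarities, where the
merge sequence is unambiguous.

## Cross-distance regressions

Over one aligned organism set, every unordered pair contributes a row
$(x, y, z)$: metabolic, phylogenetic and essential-nutrient distance
($N(N-1)/2$ rows). Two models are fitted:

$$y = 10^{\alpha + \beta x} \qquad\text{and}\qquad z = \alpha + \beta x.$$

The exponential model is fitted as a linear regression of the semi-log
transformed data ($\log_{10} y$ on $x$) and paired with the Spearman rank
correlation of $(x, y)$; the linear model is ordinary least squares paired
with the Pearson correlation. $R^2$ and RMSE of the exponential model are
reported on the $\log_{10}$ scale, consistent with the semi-log regression;
`rmse_scale = "original"` back-transforms the fitted values first. Pairs
with $y = 0$ (identical leaves) cannot enter the log fit; they are excluded
and accounted for via `n_used`. Rank correlations are invariant to the
monotone transform, so the Spearman value does not depend on which scale it
is computed on. A zero-variance response is assigned correlation 0 by
convention.

Per-taxon summaries restrict the pair set to organisms sharing a class or
genus label (at least 3 members) and tabulate both fits per subset, with
associations and $R^2$ above 0.5 flagged. A moving average (window 5% of
pairs, step 1, sorted by $x$) provides the diagnostic trend curve; it is
cosmetic and enters no fit.

## The synthetic community generator

The generator produces data with the statistical structure the analysis
assumes, plus ground truth that is exact by construction:

* **Tree** — a pure-birth (Yule) process: while $k$ lineages are alive the
  next split waits $\mathrm{Exp}(k \lambda_b)$; after the $n$-th lineage one
  more epoch elapses and all tips extend to the present, so trees are
  ultrametric with expected depth $\sum_{k=2}^{n} 1/(k\lambda_b)$. No
  extinction: the tree is an input elsewhere, so realism demands are low.
* **Repertoires** — each of 300 features evolves independently as a
  two-state Markov chain (gain $\lambda$, loss $\mu$, both 1 per unit
  branch length; root state stationary). This induces the saturating,
  exponential-like relation between phylogenetic and repertoire distance.
  Horizontal transfer is deliberately absent — a documented limitation.
* **Models** — per nutrient $k$ (15 by default): exchange, transporter, and
  a core pathway to biomass precursor $k$; when the $k$-th evolved feature
  is present, an alternative pathway feeds precursor $k$ from the
  neighboring nutrient. Nutrient $k$ is essential exactly when that
  alternative route is absent, so truth is wired structurally, never tuned
  numerically. Every other present feature becomes an inert dead-end
  reaction, so the model's reaction set mirrors its evolved profile. No
  reaction touches oxygen; all models grow anaerobically.
* **Taxonomy** — the tree is cut at the two depths yielding exactly 5
  "class" and 15 "genus" clades (defaults; genera nest in classes by
  construction), mirroring a 5-class/3-genus subset analysis at one third
  of the 301-organism scale.

Scale choices, made once at design time: `birth_rate = 5` puts the expected
depth of a 100-tip tree near 0.84, i.e. about 1.7 expected gain/loss events
per feature along a typical tip-to-tip path — a mixture of unsaturated pairs
(which carry phylogenetic signal) and saturating pairs (the plateau of the
exponential relation). Much deeper trees saturate almost every pair and the
repertoire–phylogeny association collapses toward zero; much shallower
trees make the relation nearly linear. `p_alternative_route = 1` means the
essentiality phenotype is fully encoded by the repertoire (the hypothesis
under study); lowering it decouples the two. The default community is 100
organisms — large enough for stable rank correlations over 4,950 pairs,
small enough that a full FBA screen (1,600 LPs) runs in well under a minute.

What passing tests on this generator do **not** show: real annotation
pipelines introduce correlated, taxon-biased errors; real repertoires
evolve with horizontal transfer and selection; real biomass compositions
vary across taxa (the generator uses one biomass shape). Results on
synthetic data validate the machinery, not any biological claim.

## Numerical and degenerate-input conventions

* LP tolerances: reduced-cost optimality $10^{-9}$, pivot threshold
  $10^{-11}$, feasibility check on $|S v|$ at $10^{-9}$ (hard failure above
  $10^{-7}$).
* Growth comparisons use an absolute tolerance of $10^{-6}$ $h^{-1}$
  before the essentiality cutoff.
* PCoA eigenvalues within $10^{-9}$ (relative) of zero count as zero.
* Monotone-trend checks on pair data use quintile (5 equal-count) bins of
  roughly a thousand pairs each: coarse enough to average the saturation
  plateau's sampling noise, fine enough to resolve the rise.
* Empty-vs-empty Jaccard profiles: distance 0. Zero-variance responses:
  correlation 0. Pairs with $y = 0$: excluded from log fits, reported.
* All TSV numbers at 12 significant digits; identical configurations
  reproduce byte-identical output bundles (seeds govern all randomness).

## Problem sizes used in validation

The test and acceptance suites run: 200 random networks (up to 8 reactions)
against the vertex-enumeration oracle; the default 100-organism community
for the essentiality screen (1,600 LPs) and the distance-structure checks;
a 301-organism tree/repertoire collection for pair-table counting; 20
replicates of $n = 2000$ semi-log regressions for parameter recovery; and
complete-linkage oracles on all instances up to 12 organisms. These sizes
were chosen to make every oracle exhaustive or statistically decisive while
keeping a full run in the minutes range.

## Known limitations

* The simplex is dense and single-threaded; genome-scale models with many
  thousands of reactions will be slow (minutes per screen). The analyses
  here never need that scale, but an interior-point or sparse revised
  simplex would be the natural upgrade path.
* SBML support is read-only and minimal (species, reactions, fbc bounds and
  objective); anything else is ignored with a warning. The package JSON
  schema is the canonical interchange format.
* Two compartments only; models with periplasm or organelle compartments
  are rejected at validation.
* t-SNE coordinates are deterministic per seed but, like all t-SNE output,
  not comparable across perplexities or seeds; cluster membership, not
  geometry, is the supported reading.
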