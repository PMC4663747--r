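# microrep

Tools for asking how much of a microbe's *phenotype* is explained by its
*metabolic repertoire* rather than by its *phylogeny* — the question behind
comparative analyses of gut microbial communities, where members of the same
genus can differ sharply in what they can eat and make.

`microrep` takes a collection of genome-scale metabolic models (a compact
JSON schema, with a minimal SBML reader), a rooted phylogenetic tree, and a
taxonomy table, and computes three pairwise views of the community:

* **metabolic distance** — one minus the Jaccard index of reaction sets,
  `d(i,j) = 1 − |b_i ∩ b_j| / |b_i ∪ b_j|`, over the union of reactions in
  the whole collection;
* **phenotypic distance** — the same Jaccard dissimilarity over *essential
  nutrients*, predicted by flux balance analysis: maximize biomass flux
  `v_b` subject to `S·v = 0` and flux bounds, on a rich medium (uptake
  ≤ 10 mmol/gDW/h on every exchange), removing each exchanged metabolite in
  turn and calling it essential when growth drops below 0.05 h⁻¹;
* **phylogenetic distance** — the cophenetic (patristic) distance on the
  rooted tree.

On top of these it provides principal coordinate analysis with
discriminative-reaction loadings (point-biserial correlation of each
reaction with the first two axes), t-SNE embeddings, complete-linkage
sub-type clustering with differential reaction sets, and the two
cross-distance regressions

```
y = 10^(α + βx)        (phylogenetic y on metabolic x; Spearman correlation)
z = α + βx             (essential-nutrient z on metabolic x; Pearson correlation)
```

fitted per taxon subset as well as globally. A synthetic community
generator (Yule tree, two-state gain/loss repertoire evolution, FBA-ready
models with structurally wired nutrient essentiality) provides ground truth
for end-to-end validation. The linear programs behind FBA are solved by a
bounded-variable two-phase simplex written for this package and validated
against an exhaustive vertex-enumeration oracle.

## Worked example

A bundled two-substrate toy model (glucose or fructose each feed the single
biomass precursor):

```r
library(microrep)
m <- read_model(system.file("extdata", "example_model.json", package = "microrep"))
solve_fba(m)
#> <flux_result> status = optimal, growth_rate = 20

scr <- essential_nutrients(m)
scr$growth
#> fru_e glc_e
#>    10    10
scr$essential
#> character(0)
```

Growth on the rich medium is 20 h⁻¹ (both sugars taken up at the 10
mmol/gDW/h cap feed the same precursor). Removing either sugar alone leaves
growth at 10 h⁻¹ — far above the 0.05 h⁻¹ cutoff — so *neither* nutrient is
essential: the alternative route buys phenotypic robustness. Deleting the
`ALT_fru` reaction from the model would make glucose essential; this
repertoire→phenotype wiring is exactly what the community-scale regressions
quantify.

A full synthetic study in one call:

```r
cfg <- read_pipeline_config(system.file("extdata", "default_config.yaml",
                                        package = "microrep"))
bundle <- run_pipeline(cfg, "out/")
#> [microrep] simulated community: 100 organisms, seed 42
#> [microrep] essentiality screen: 100 organisms x 15 nutrients
#> [microrep] PCoA: axis 1+2 explain 21.3% (negative mass 0.34)
#> [microrep] regressions: Spearman(x, y) = 0.354, Pearson(x, z) = 0.397 over 4950 pairs
```

`out/` then contains the models, tree, presence and essentiality matrices,
the three distance matrices, PCoA/t-SNE coordinates and loadings, cluster
labels, the 4,950-row pair table, the per-taxon fit summary and moving
averages — all TSV/JSON, byte-identical across reruns of the same
configuration. The same stages are scriptable individually
(`simulate_community()`, `essential_nutrients()`, `jaccard_distance()`,
`pcoa()`, `hcluster()`, `fit_exponential()`, ...) and exposed through a thin
command-line wrapper in `exec/microrep`.

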