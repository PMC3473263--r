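# regulonkit

Qualitative regulatory network analysis for microbial genomes.

Curated collections of bacterial regulation — transcription-factor
binding, transcriptional attenuation, translational regulation by
proteins, small RNAs and riboswitches, and substrate-level enzyme
modulation — are qualitative: they record who regulates what, by which
mechanism and in which direction, without rate constants. regulonkit
gives bioinformaticians and curators a validated data model for such
collections plus the analyses that make them useful:

* a declarative **regulatory model** (genes, transcription units,
  promoters, terminators, products, compounds, reactions, regulation
  records) with referential validation and content statistics;
* the **gene-level signed network**: operon-aware expansion of every
  interaction to gene–gene edges labelled activation / inhibition /
  dual / unknown, with optional sigma-factor edges, plus clustering,
  subnetworks, elliptical and layered overview layouts, and XGMML
  export for Cytoscape;
* **influence ranking**: the dominant eigenvector of the regulation
  adjacency matrix (a simplified PageRank computed by the power
  method), so global regulators rise to the top;
* **gene-group algebra** and **regulation-enrichment analysis**: is a
  gene set over-represented for targets of particular regulators?
  One-sided hypergeometric test with Benjamini–Hochberg correction;
* **parity inference**: propagate regulation signs through a
  signed entity graph — including complex formation and
  irreversible metabolic reactions — to classify every upstream entity
  as a net activator, net inhibitor, or unknown influence on a target,
  with the signed paths behind each call;
* a seeded **synthetic-model generator** with a ground-truth ledger,
  so the whole stack is testable without any external database;
* a **command-line interface** over all of the above.

## The core computations

**Influence.** With `A[i,j] = 1` iff gene *i* regulates gene *j* and
`r(j)` the number of distinct regulators of *j*, scores solve
`s = (1-α)(M + I)s + αu` with `M[i,j] = A[i,j]/r(j)` (regulator-count
normalisation), iterated with L1 normalisation until convergence
(default α = 0.001, tolerance 1e-12). The top score is rescaled to
100. The `+I` shift suppresses period-two oscillation on cycles
without changing eigenvectors.

**Enrichment.** For a regulator with `K` targets in an `N`-gene
universe, `k` of which fall in an `n`-gene group, the raw p-value is
the hypergeometric upper tail `P(X ≥ k)`; candidates are all genes
with ≥ 1 target in the universe, and adjusted p-values are compared
against α = 0.05 by default.

**Parity.** Signs multiply along paths (an inhibitor of an inhibitor
activates). An entity's classification is the set of sign products
over simple paths to the target (depth ≤ 6 by default) whose
intermediate nodes are themselves unambiguous; entities with
conflicting paths are unknown and block further propagation. Hub
metabolites (> 10 reactions) are excluded; reversible reactions carry
no directional signal and are ignored.

## Worked example

```r
library(regulonkit)

gen   <- generate_model(synth_params(n_genes = 120), seed = 4)
model <- gen$model
model
#> <regulatory_model 'synth-seed4-n120'>
#>   genes                120
#>   transcription_units  73
#>   promoters            73
#>   terminators          2
#>   products             123
#>   compounds            22
#>   reactions            14
#>   regulations          53

head(model_stats(model), 12)
#>    category                        value
#>  1 transcriptional_regulation       40
#>  2 transcription_factor_binding     37
#>  3 allosteric_regulation_of_rnap     1
#>  4 attenuation                       2
#>  5 translational_regulation          3
#> ...
#> 11 genes_with_regulator             51
#> 12 percent_of_genome                42.5
```

51 of the 120 genes (42.5%) have at least one transcriptional or
translational regulator. Build the gene network and rank by influence:

```r
net <- build_gene_network(model)   # transcriptional+translational+sigma
res <- influence_scores(net)
rank_table(res, top_n = 5, model = model)
#>    rank gene  product_role            score score_printed direct_targets
#> 1     1 g0108 polypeptide p-g0108 100       100                      120
#> 2     2 g0078 polypeptide p-g0078  50.0     50                         9
#> 3     3 g0005 polypeptide p-g0005   0.0104  0.01                      12
#> 4     4 g0098 polypeptide p-g0098   0.00906 0.0091                    13
#> 5     5 g0066 polypeptide p-g0066   0.00828 0.0083                    10
```

The top gene (g0108) is the model's sigma factor — it transcribes all
120 genes, the analogue of a housekeeping sigma factor dominating a
real ranking. g0078 scores far above TFs with similar target counts
because its targets include other regulators. Normalisation is a
visible knob: without regulator-count weighting the same network gives
g0078 a score of 62 instead of 50, because sole-regulator edges lose
their extra weight (`influence_scores(net, normalization = "none")`).

Enrichment recovers the regulator of a regulon from its gene set
alone:

```r
grp <- regulatees_of(gene_group("g0078", "regulon"), net)
regulation_enrichment(grp, net)
#>   regulator     k     K     n     N    p_raw    p_adj significant
#> 1 g0078         9     9     9   120 9.56e-14 8.61e-13 TRUE
#> 2 g0005         0    12     9   120 1        1        FALSE
#> ...
```

And parity inference explains *how* a gene is controlled, through
entities rather than genes:

```r
pg  <- build_parity_graph(model)
cls <- classify_influences(pg, "g0002", depth = 6)
tidy(cls)
#>   entity     class
#> 1 g0078      activator
#> 2 mf-p-g0078 activator
```

g0002 is activated both by the TF gene g0078 and by the ligand-bound
modified form `mf-p-g0078` through which it acts. `influence_paths(pg,
"g0078", "g0002")` lists the signed paths behind the call.

All result objects have `tidy()`/`glance()` methods and `autoplot()`
plots; `write_xgmml(net, "net.xgmml", layout = elliptical_layout(net,
model))` produces a Cytoscape-ready file.

## Command line

```sh
inst/cli/regulonkit synth --seed 4 --genes 120 -o model.json
inst/cli/regulonkit validate model.json
inst/cli/regulonkit stats model.json
inst/cli/regulonkit network model.json -o net.xgmml --layout elliptical
inst/cli/regulonkit rank model.json --top 10
inst/cli/regulonkit enrich model.json --genes regulon.txt
inst/cli/regulonkit parity model.json --target g0002 --depth 6
```

Exit codes: 0 success, 1 validation failure, 2 usage error.

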