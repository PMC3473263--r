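---
title: "Methods: qualitative regulatory network analysis with regulonkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qualitative regulatory network analysis with regulonkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonkit)
```

# The data model

regulonkit represents bacterial regulation qualitatively: who regulates
what, by which mechanism, and with which sign — never with rate
constants or binding affinities. A `regulatory_model` holds eight
tibbles: genes, transcription units (TUs), promoters, terminators, gene
products, compounds, reactions, and regulation records. A regulation
record names a regulator entity (a product or a small molecule), a
regulated entity, a class, and a mode from `{+, -, dual, unknown}`.

The class determines what kind of entity may be regulated, and that in
turn fixes the *gene-level expansion* of the interaction:

* **Transcription-factor binding** and **allosteric regulation of RNA
  polymerase** target a promoter; regulating a promoter regulates every
  gene of the promoter's TU.
* **Attenuation** targets a terminator; only the genes downstream of
  the terminator are affected. We index terminators by the number of TU
  genes upstream of them (`site_index`), not by base-pair coordinate:
  the TU's gene order is authoritative and no sequence is required.
* **Translational regulation** targets a TU or a single gene. When a TU
  is targeted we expand to *all* of its genes; the alternative (only
  genes downstream of the regulator's mRNA site) would require binding
  coordinates that the qualitative model deliberately omits.
* **Enzyme modulation** targets an enzyme or a reaction and expands to
  no genes at all — it acts on protein activity, not expression.

Regulator entities resolve to encoding genes recursively: a polypeptide
or RNA to its genes, a modified form through its unmodified form, a
complex through the union of its product components. Small molecules
(e.g. riboswitch ligands) encode no gene and resolve to nothing.
Post-translational events (covalent modification, sequestration) are
modelled as explicit reaction records, never as regulation records.
A regulation class for protein degradation is reserved but rejected by
`validate_model()` as unsupported.

`validate_model()` checks every referential and structural invariant
and returns violations as data (a tibble), so a curator can fix a file
instead of chasing exceptions. `model_stats()` produces the standard
content-statistics table (regulation counts per class and sub-class,
gene coverage, regulator tallies split protein/RNA/small-molecule,
enzyme-modulation tallies with a physiological-relevance filter). Our
typing rule for regulator entities: compounds are small molecules, RNA
products are RNAs, everything else — polypeptides, complexes, modified
forms — counts as protein (a complex counts as RNA only if it has RNA
components and no polypeptide). The "transcriptional regulation" row is
computed as the count of all transcriptional-class records, which in
published tables equals the sum of its sub-rows.

# The gene network

`build_gene_network()` projects the model onto a directed gene-to-gene
graph: an edge A → B means gene A's product (possibly via a complex or
modified form) regulates gene B's expression. Enzyme modulation never
contributes; sigma-factor preference is optionally added as activation
edges from the sigma gene to each TU it transcribes. Compound
regulators contribute no edge here — the graph is gene-to-gene by
definition; their influence is handled by the parity layer.

Parallel labels for one ordered pair are merged on the lattice
`unknown < activation/inhibition < dual`: a conflicting
activation/inhibition pair becomes `dual` (genuinely context-dependent
regulation is information, not noise), and `unknown` is dominated by
any informative label. The merge is order-independent, which the tests
check by permuting the regulation table.

## Layouts

Two overview layouts are computed as pure coordinate assignments.
The *elliptical* layout places sigma-factor genes on an inner ellipse,
all other regulators (out-degree > 0) on a second, and the remaining
genes on an outer ellipse grouped contiguously by regulator cluster
(two genes cluster together iff their direct regulator sets are
identical). A dual-role gene (sigma factor that is also a TF) is drawn
on the sigma ring only. The concrete geometry — 2:1 axis ratio, radii
1, 2, 4 — is our choice; nothing downstream depends on it. The
*layered* layout stacks regulators by one plus the longest path through
regulator-only nodes, computed on the strongly-connected-component
condensation so mutually regulating genes share a layer; non-regulators
form the bottom layer, ordered cluster-contiguously. Both layouts are
deterministic and injective on coordinates.

# Influence ranking

The influence of a gene should grow with the number of genes it
regulates, directly and (with decay) indirectly, and a sole regulator
of a gene should weigh more than one of many co-regulators. Both ideas
are captured by the dominant eigenvector of the regulation adjacency
matrix, a simplified PageRank. With \(A_{ij} = 1\) iff gene *i*
regulates gene *j* and \(r(j)\) the number of distinct regulators of
*j*, the iteration matrix under the default regulator-count
normalisation is \(M_{ij} = A_{ij} / r(j)\), and the power method
iterates

\[ s \leftarrow (1 - \alpha)\,(M + I)\,s + \alpha u , \]

normalising \(\|s\|_1 = 1\) each step, with \(u\) uniform. The \(+I\)
shift maps every eigenvalue \(\lambda\) to \(\lambda + 1\) without
changing eigenvectors, which kills the period-two oscillation that pure
power iteration exhibits on cycles; the damping term \(\alpha\)
(default 0.001) guarantees a unique fixed point on disconnected
graphs. Signs are deliberately ignored — repressors are as influential
as activators. Autoregulatory self-loops are kept. Defaults: tolerance
`1e-12` on the L1 step change, at most `1e5` iterations; at
\(\alpha = 0\) failure to converge is an error advising a positive
damping. Scores are rescaled so the top gene scores exactly 100, and
display formatting follows the published convention: integers at and
above 10, two significant figures below.

Both normalisation and damping are open choices in the qualitative
setting, so both are arguments; the README shows how each changes a
small example. Correctness is established by oracle equivalence — the
power-method scores match a dense eigendecomposition of the explicit
iteration matrix to an L1 gap below 1e-8 on random 20–50-node graphs —
because reproducing published organism-specific rankings would require
the underlying curated database content.

# Gene groups and regulation enrichment

Gene groups are sets with provenance: every operation appends to the
group's history. Supported algebra: direct or indirect (bounded-depth
reverse/forward reachability) regulators and regulatees, operon
expansion, union/intersection/difference, mapping to products with
optional closure over complexes and modified forms, and compound-side
queries (which enzymes does a metabolite modulate; which proteins bind
it, via ligand lists and regulator complexes containing it).

Regulation enrichment asks whether a gene group is over-represented
for targets of particular regulators. For each candidate regulator
with \(K\) targets in an \(N\)-gene universe, of which \(k\) fall in
the \(n\)-gene group, the raw p-value is the hypergeometric upper tail

\[ p = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}
       {\binom{N}{n}}, \]

a one-sided Fisher exact test in the enrichment direction, computed via
`stats::phyper` (log-gamma based, exact to machine precision — verified
against exhaustive subset enumeration for \(N \le 20\)). The candidate
family is every gene with at least one regulatee in the universe under
the chosen mode, so the multiple-testing family is model-dependent and
reported (`n_tests` attribute). Correction defaults to
Benjamini–Hochberg at \(\alpha = 0.05\); both are arguments. A gene
counts as regulated by r only through network edges — operon expansion
happens at network construction, not silently inside the test.

# Parity inference

To decide whether an entity is a net activator or inhibitor of a
target, the expression-level graph is not enough: ligands, complexes
and metabolism matter. `build_parity_graph()` therefore works at the
entity level. A gene and its single-gene polypeptide/RNA product are
one node; complexes, modified forms and compounds are their own nodes.
Edges come from regulation records (signed by mode; unknown-mode
records carry no information and are omitted, while dual-mode records
contribute both signs — ambiguity *is* information), from complex
formation and covalent modification (components and unmodified forms
activate what they form), and from irreversible reactions: reactants
and enzymes activate each reaction product, and the enzyme plus the
other reactants inhibit each reactant, because they promote its
consumption. Reversible reactions are ignored — they carry no
directional signal — and compounds participating in more than
`hub_threshold` reactions (default 10) are excluded outright: hub
metabolites such as currency cofactors are unlikely to carry specific
regulatory signal.

Effects are multiplicative in sign along a path: an inhibitor of an
inhibitor is an indirect activator. `classify_influences()` assigns
each upstream entity the set of path-sign products over *simple* paths
(no node revisited, so autoregulatory loops do not feed a node's own
sign back) of length at most `depth` (default 6) whose intermediate
nodes all have an unambiguous sign. An entity with both a positive and
a negative admissible path has unknown net effect; it is pruned and
regulatory effects through it are ignored. Because pruning can
invalidate previously admissible paths, the procedure recomputes from
scratch after each newly discovered conflict, committing conflicts
permanently; each round adds one node to the pruned set, so at most
|V| rounds run (asserted by an iteration counter). The schedule is
deterministic: candidates are swept in lexicographic order and the
first conflict found in a sweep is pruned. Alternative disambiguation
rules — shortest path wins, majority vote — are deliberately not
implemented. The implementation's depth-first path search is validated
against an independent igraph-based exhaustive path enumeration on 200
random signed graphs, and `influence_paths()` reports the admissible
signed paths behind any classification.

# The synthetic-model generator

`generate_model()` exists so that every analysis is testable without
external database content. Its defaults are the study conditions used
throughout the tests and are chosen to look like a small bacterium:
geometric operon sizes with mean 1.7 genes (most TUs are mono- or
di-cistronic); 5% of genes encoding transcription factors and 0.5%
sigma factors, echoing the regulator fraction and sigma-factor counts
of well-curated genomes; Poisson TF out-degree with mean 5; activation
and inhibition equally likely at 45% each with 3% dual and the rest
unknown; attenuation and translational interactions at 5% and 8% of
the TF interaction count; a metabolic layer (15% compounds, 12%
reactions, 30% reversible, 8% enzyme modulations with 80%
physiologically relevant) and one deliberately hub-like compound wired
into exactly 12 reactions to exercise hub pruning. A quarter of TFs
act as ligand-bound modified forms and another quarter as TF–ligand
complexes, so regulator resolution and parity component edges are
exercised by default.

All randomness flows from one master seed through named per-phase
substreams (a hash of the phase name mixed into the seed), so adding a
generation phase never perturbs earlier ones and output is
byte-reproducible per seed. During construction the generator records a
ground-truth ledger — per-class counts, per-regulator target-gene
lists derived directly from the TU partition, per-gene regulator
lists, the full content-statistics vector, hub compound ids — against
which `model_stats()`, network out-degrees and in-neighbourhoods are
tested for exact equality.

What the generator does not emulate: genomic coordinates and binding
site sequences, condition-dependent regulation, combinatorial promoter
logic, realistic degree distributions (TF out-degree is Poisson, not
heavy-tailed), and cross-regulation structure between the metabolic
and transcriptional layers beyond random wiring. Passing tests on
generated models therefore establishes algorithmic correctness, not
biological calibration.

# Numerical and design choices

* IDs are case-sensitive opaque strings; derived gene lists are sorted
  for determinism (TU expansions keep TU order, which is meaningful).
* The RegJSON writer is canonical — arrays sorted by id, fixed key
  order, absent optionals omitted — so equal models are byte-equal,
  which the round-trip and determinism tests exploit.
* XGMML export uses one directed graph per file, numeric node ids in
  sorted gene-id order, the gene id as the node label (Cytoscape keys
  on labels), and a string attribute `mode` for the edge effect with a
  list attribute `provenance` of regulation ids.
* Ties in the influence ranking break lexicographically; cluster
  ordering is size-descending with lexicographic representatives;
  every layout is deterministic.
* Degenerate inputs: an empty model yields all-zero statistics; an
  empty network refuses to lay out or rank; an unreachable
  regulator/target pair yields zero paths, not an error.
* Problem sizes in the test suite: oracle equivalence uses 50 random
  networks of 20–50 nodes (influence) and 200 random signed graphs of
  up to 30 nodes (parity); enrichment enumeration covers universes up
  to 20 genes; round-trip and ledger checks use 20 generated models;
  the end-to-end pipeline runs once at 2,000 genes.

# Limitations

The model is qualitative and does not compose co-acting regulators: if
a gene has both an activator and an inhibitor, regulonkit reports both
and decides nothing. Environmental regulators (temperature, pH) and
protein-degradation control are not representable. Influence scores
depend on curation density — a richly annotated regulator outranks an
equally influential but sparsely annotated one. Parity inference
treats reaction stoichiometry as unweighted and ignores reversible
reactions entirely, and its depth bound trades completeness for
interpretability.
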