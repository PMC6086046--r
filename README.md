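# ontropy

Entropy-aware path-based (EAPB) quality metrics for biomedical ontologies.

## The problem

Ontology engineers need a quantitative handle on *redundancy*: duplicated
classes, near-copied definitions and loosely connected hierarchies inflate an
ontology without adding meaning. Treating the ontology as an undirected
simple graph of classes, Shannon entropy over a per-concept probability
distribution is a natural redundancy/complexity measure — but the classical
formulation only looks at single-point (adjacency) connectivity and gives
every edge the same weight, ignoring both multi-hop paths and the textual
definitions attached to classes.

`ontropy` implements an entropy metric that repairs both omissions. For a
class graph with `n` concepts and connectivity matrix `C` (`C_uv ∈ {0, 1}`),
the unweighted baseline distribution is

    P_k = Σ_u C_uk / Σ_{u,v} C_uv ,     S = −Σ_k P_k log2 P_k .

Each vertex pair is then weighted by an **information gain**

    O_uv = rel(u, v) / D_uv ,

where `rel` is the cosine similarity of the two vertices' embeddings mapped
onto [0, 1] and `D_uv` is their shortest-path hop count, giving the
path-and-text-aware distribution and entropy

    P′_k = Σ_{u≠k} C_uk · O_uk / Σ_{u,v} C_uv · O_uv ,
    S′  = −Σ_k P′_k log2 P′_k   (bits).

The embeddings are learned jointly from two channels:

* **structure**: skip-gram over biased (node2vec-style) random walks, with
  negative sampling;
* **text**: a single-layer CNN over each class description, pooled with
  *mutual attention* — for an interacting pair the correlation matrix
  `C = tanh(UᵀAV)` (with a trainable attentive matrix `A`) yields a pair of
  softmax attention vectors, so each class emphasises the words its
  neighbour cares about.

Four per-edge log-likelihood terms (`structure|structure`, `text|text`,
`text|structure`, `structure|text`) share one softmax form and one
representation space; the final vertex embedding concatenates the structure
vector with the neighbour-averaged text vector. A text-ablated mode
(`structure-only` similarities) isolates what the text channel contributes.

Everything is testable offline: a seed-deterministic synthetic-ontology
generator produces class hierarchies with controllable redundancy
(duplicated classes with near-copied definitions) and missing-definition
fractions that exercise the description fallback cascade
(definition → injected external text source → superclass copy → label).

## Worked example

```r
library(ontropy)

g <- synth_ontology(synth_config(n_classes = 30, redundancy = 0.3, seed = 42))
g
#> <ontology_graph> 30 classes, 37 edges (texts resolved)

model <- train_embeddings(g, joint_config(seed = 42))
model
#> <ontropy_model> 30 vertices, dim 32, vocab 95, 10 epoch(s)
#>   objective: -10.8131 -> -10.811

report <- eapb_entropy(g, model)
report
#> <entropy_report> S' = 4.88684 bits over 30 concepts
#>   connectivity: reachability; similarity: full-embedding; baseline entropy: 4.90689 bits

ablate_text(g, model)$s_prime   # structure-only ablation
#> [1] 4.886858

head(tidy(report), 3)           # per-concept contributions -P'_k log2 P'_k
#> # A tibble: 3 × 3
#>   id                                 p_prime contribution_bits
#> 1 http://example.org/synthetic#C0001  0.0445             0.200
#> 2 http://example.org/synthetic#C0002  0.0451             0.202
#> 3 http://example.org/synthetic#C0003  0.0387             0.181
```

`S′` sits below both the baseline entropy and the `log2(30) ≈ 4.907` ceiling:
the gain weighting concentrates probability mass on well-connected,
textually similar regions (here, the 30% duplicated classes), which is
exactly the redundancy signal the metric is built to expose. `glance()`
summarises a report in one row; `autoplot()` draws the contribution profile
of a report or the objective trajectory of a model.

Real ontologies enter through `read_ontology()` (OWL RDF/XML, OWL Turtle,
OBO 1.4) followed by `as_ontology_graph()` and `resolve_texts()`;
`ontology_stats()` and `ontology_granularity()` give the summary counts and
property-label granularity profile used by `compare_ontologies()`, which
softmax-scores ontologies on triples/classes/relations, aggregates by
geometric mean, and correlates aggregate scores with entropies (Pearson and
Spearman).

A thin command-line wrapper ships in `inst/cli/ontropy.R`:

```sh
Rscript inst/cli/ontropy.R synth   --out demo.ttl --seed 2 --n-classes 15 --redundancy 0.3
Rscript inst/cli/ontropy.R stats   --input demo.ttl --out stats.tsv
Rscript inst/cli/ontropy.R entropy --input demo.ttl --out report.json --seed 1
```

Each run writes a `.manifest.json` (command, options, seed, version) that
makes its outputs reproducible bit for bit.

## Package layout

* `R/read-ontology.R`, `R/graph-build.R`, `R/stats.R` — parsing (RDF/XML via
  xml2; restricted Turtle and OBO 1.4 readers), class-graph projection,
  text fallback, summary statistics, granularity.
* `R/graph-core.R`, `R/eapb.R` — connectivity/shortest-path machinery,
  information gain, weighted distribution, entropy reports.
* `R/walks.R`, `R/text-encoder.R`, `R/model.R`, `R/model-api.R` — biased
  walks, CNN + mutual-attention text encoder, joint training (hand-derived
  analytic gradients, verified against finite differences in the tests),
  checkpoints.
* `R/synthetic.R` — the synthetic-ontology generator and Turtle writer.
* `R/compare.R`, `R/cli.R`, `R/tidiers.R` — comparison scoring, CLI,
  broom-style `tidy()`/`glance()` and `autoplot()` methods.
* `vignettes/ontropy-methods.Rmd` — the model, its assumptions, parameter
  choices and limitations.
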