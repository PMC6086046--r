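---
title: "Entropy-aware path-based ontology quality: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-aware path-based ontology quality: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model, the assumptions behind it, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where a
genuinely open design choice had to be made.

## The model

An ontology is reduced to a **simple undirected graph** of classes:
`rdfs:subClassOf` axioms and object-property assertions between declared
classes become edges; self-loops and parallel edges are dropped. This
throws away edge direction and annotation structure deliberately — the
metric asks how evenly *connectivity mass* is spread over concepts, not
what the axioms assert.

Every class also carries a **text description**, resolved by a fixed
cascade: its own textual definition; otherwise an injected external text
source queried with the class label (capped at 5 sentences); otherwise the
resolved description of its described superclass(es), propagated bottom-up
until a described ancestor is found; otherwise the label itself. The
cascade is recomputed from the stored definitions each time, which makes
`resolve_texts()` idempotent. The external source is an injectable function
rather than a live web call: a metric whose value depends on the state of
an external website at run time is not reproducible.

### Embeddings

Two vertex representations are learned jointly and live in one space:

* **Structure.** Biased second-order random walks (return bias `1/p`,
  in-out bias `1/q`) generate a context corpus; skip-gram pairs within a
  window feed a log-likelihood of softmax form,
  `log p(v|u) = u·v − log Σ_k exp(u·k)`, estimated by negative sampling.
* **Text.** The token sequence is mapped through a word table to a
  `d × L` matrix, convolved with a window-3 filter bank (linear output —
  the only squashing is the `tanh` inside the attention), and pooled with
  **mutual attention**: for an ordered pair the correlation matrix
  `C = tanh(UᵀAV)` is mean-pooled along rows and columns, softmaxed into a
  pair of attention vectors, and the attention-weighted column sums give
  one context-dependent text vector per side. The attentive matrix `A` is
  trainable, so the model can learn which word interactions matter.

The per-edge objective is `L_s + α·L_tt + β·L_ts + γ·L_st`, four log
conditional probabilities of the same softmax form that condition structure
on structure, text on text, and each on the other. Candidate text vectors
inside a softmax are always contextualised against the *source* vertex of
the edge (the column side of the attention pair), a convention the exact
and sampled modes share. Gradients through the attention and convolution
are derived analytically; the test suite checks every parameter block
against central finite differences at tolerance `1e-6`.

The final embedding of a vertex concatenates its structure vector with the
mean of its per-neighbour context text vectors. Attention only defines text
vectors *per pair*; the information-gain matrix needs one vector per vertex
for arbitrary, possibly non-adjacent pairs, and the neighbour mean is the
simplest order-independent aggregate. An isolated vertex uses its
self-conditioned text vector.

### The metric

With shortest-path hop counts `D` and embedding relevancy
`rel(u,v) = (1 + cos)/2`, the information gain is `O_uv = rel(u,v)/D_uv`
(zero on the diagonal and for unreachable pairs), the weighted concept
distribution is `P′_k = Σ_{u≠k} C_uk O_uk / Σ C_uv O_uv`, and the metric is
`S′ = −Σ P′_k log2 P′_k` in bits. Two exact reductions anchor the
implementation: `O ≡ 1` reproduces the unweighted baseline entropy to
machine precision, and scaling `O` by any positive constant changes
nothing.

## Parameters and defaults

| parameter | default | why |
|---|---|---|
| `dim` | 32 | One shared width for structure, word and text vectors. The cross-space terms dot a text vector with a structure vector, which forces equal widths; 32 is a desk-scale choice that keeps a full training run on a 50-class ontology in seconds while leaving the similarity geometry expressive. |
| `conv_window` | 3 | Trigram-scale local features; the standard smallest non-trivial choice. |
| `alpha, beta, gamma` | 1, 0.3, 0.3 | The text-text term keeps full weight; the two mutual-generation terms are down-weighted as secondary alignment pressure. |
| `epochs` | 10 | Enough for the objective to ascend reliably on the synthetic fixtures. |
| `learning_rate` | 0.025 | The conventional skip-gram starting step, decayed linearly to a tenth. |
| `negatives` | 5 | Standard negative-sampling count. |
| `walk_length`, `walks_per_vertex`, `walk_window` | 40, 10, 5 | Conventional biased-walk corpus settings; `return_param = inout_param = 1` makes the walk unbiased unless the user opts into bias. |
| `max_text_len` | 100 tokens | Bounds attention cost quadratically; a deviation knob, not a modelling claim. |
| `exact_softmax_cutoff` | 200 | Exact softmax over all vertices is kept available for oracle tests on small graphs; beyond this size only the sampled estimate is allowed. |
| `connectivity` | `"reachability"` | The point of a path-based measure is that non-adjacent but connected concepts interact; adjacency mode is retained as a flag for comparison with single-point formulations. |

The per-epoch objective recorded in `loss_history` uses negatives drawn
once before training, so successive epochs are evaluated against the same
yardstick; an exact text softmax would cost one attention forward per
vertex per edge and is reserved for `edge_objective(exact = TRUE)` on
small toys.

## Numerical choices

* **Cosine to [0, 1].** `P′` must be non-negative, and cosine can be
  negative. The default affine map `(1 + cos)/2` preserves the similarity
  ordering; a clamp-at-zero alternative sits behind `map = "clamp"`.
* **`0 · log 0 := 0`**, entropy in bits (base-2 logarithm).
* **Unreachable pairs contribute zero** to all weighted sums: an infinite
  path length has no defined gain.
* **Hop-count division.** "Divide by the shortest path" is read as
  division by the shortest-path *length* (an integer ≥ 1), which prevents a
  long path's weight from being counted once per hop. Division by the
  *number* of shortest paths is a conceivable alternative reading and was
  not adopted.
* **Diagonal excluded everywhere**: both `C` and `O` have zero diagonals,
  so the `u ≠ k` restriction applies to numerator and denominator alike.
* **Superclass-copy ties** (several described parents) concatenate parent
  texts in lexicographic id order — deterministic and order-independent.
* **Zero vectors** have undefined cosine; their relevancy is defined as 0
  with a warning rather than an error, since an untrained or ablated model
  can legitimately produce them.
* **Softmax inputs are log-transformed** (`log1p`) in the comparison
  scores: raw ontology counts span orders of magnitude, and a raw-count
  softmax over a set that includes a million-class ontology is a one-hot
  vector, which would make every aggregate degenerate.
* **Seeding.** Every stochastic entry point takes a seed and restores the
  caller's RNG state (`withr::with_seed`); identical config + seed gives
  bit-identical models, reports and CLI outputs.

## What the synthetic generator emulates — and what it does not

`synth_ontology()` produces a `subClassOf` backbone (random recursive tree,
preferential attachment, or clustered trees), a handful of object-property
cross edges, and per-class definitions drawn from topic vocabularies tied
to the subtrees under the root — so text carries genuine signal about graph
position, which is what gives the text channel something to learn.
Redundancy is injected exactly the way the metric is meant to detect it:
duplicated classes attached beside their originals with near-copied
definitions (per-token replacement noise), plus an optional fraction of
classes with no definition at all to exercise the fallback cascade.
Ground truth (duplicate pairs, topic assignments) travels with the graph.

It does **not** emulate: medical vocabulary or real token frequency
distributions, polysemy, multi-parent (DAG) hierarchies, annotation or
data properties, or OBO-specific constructs. Passing tests on these
fixtures therefore show that the pipeline's *mechanics* behave as specified
(reductions, bounds, invariances, duplicate-pair separation), not that the
metric's absolute values on any real ontology are recovered — those depend
on the ontology downloads and training settings of the original study and
are out of scope here.

## Problem sizes used by the tests

The suite runs entirely on generated fixtures: oracle tests on 3–20-vertex
graphs, property sweeps over 100 random synthetic ontologies of 8–30
classes, training checks on 25–50-class ontologies with 10 seeds, and the
acceptance script's standard condition of 50 classes at redundancy 0.4
with the default configuration. These sizes were chosen so a full check of
every property completes in minutes on one CPU while still being large
enough for the separation properties to be non-trivial.

## Known limitations

* The Turtle reader is a restricted parser (no blank nodes, collections or
  `@base`); it covers the package's own output and typical class/property
  serializations, and rejects what it cannot parse with a line-numbered
  error. The RDF/XML reader handles the striped syntax Protégé-style
  exports use, not `rdf:parseType` or reification.
* "Triples with/without annotation" is counted by a documented rule
  (object-is-literal); other tools may draw that line elsewhere.
* No OWL reasoning: only asserted axioms enter the graph, never inferred
  ones.
* Training is plain SGD in R — appropriate for the hundreds-of-classes
  scale the tests target, not for million-class ontologies.
* Entropy values are comparable between ontologies of similar size;
  `log2(n)` growth means raw values should not be compared across very
  different sizes without the per-aspect normalisations in
  `compare_ontologies()`.
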