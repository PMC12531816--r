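---
title: "Hierarchical classification of fungal ITS sequences with k-mer embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical classification of fungal ITS sequences with k-mer embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hftc)
```

## The problem

The internal transcribed spacer (ITS) is the universal DNA barcode for
fungi: it is variable enough to separate closely related species yet
conserved enough to amplify across the kingdom. Reference collections
such as UNITE cluster ITS sequences into *species hypotheses* (SHs) at a
fixed similarity radius and attach a seven-rank lineage
(kingdom, phylum, class, order, family, genus, species) to each.
Assigning a lineage to a query amplicon is then a very large, very
imbalanced multi-class problem, and flat classifiers that predict each
rank independently can return biologically impossible combinations — a
sequence placed in one phylum at the phylum rank and in another phylum's
class one rank below.

`hftc` addresses both problems at once:

* **compact features** — sequences are represented by pooled skip-gram
  embeddings of their k-mers instead of the classical
  $4^k$-dimensional k-mer frequency vector (KFV), compressing 16,384+
  dimensions to 200;
* **structural consistency** — classification proceeds through a tree
  of per-node random forests that mirrors the taxonomy, so every
  returned lineage is, by construction, an existing root-to-species
  path of the reference.

## Feature model

A sequence of length $\ell$ is tokenized with a sliding window of
length $k$ and stride $L$ (default $L = 1$), in **both orientations**:
the sequence as given, and its reverse complement. Each orientation
yields $\lfloor(\ell-k)/L\rfloor + 1$ tokens. Treating each token list
as a sentence, a skip-gram model with negative sampling is trained over
the corpus of all training sequences (two sentences per record), giving
every k-mer in the vocabulary an $N$-dimensional vector ($N = 100$ by
default). A sequence vector is the mean of its in-vocabulary forward
token vectors concatenated with the mean of its reverse token vectors —
$2N = 200$ numbers regardless of $k$ or sequence length. Out-of-vocabulary
tokens are dropped and counted; a direction that is entirely
out-of-vocabulary contributes a zero half-vector.

Choices worth knowing about:

* *"Reverse direction" means reverse complement.* The literature this
  design follows does not pin the definition down; plain string
  reversal is available (`reverse = "string"` in `tokenize_bikmer()`)
  but the biological orientation is the default.
* *One embedding per k, shared by all nodes.* Embeddings are trained
  once per distinct $k$ on the full training corpus rather than
  per sub-classifier; this keeps vocabulary and geometry shared, and
  training cost proportional to the number of distinct $k$ values (two,
  by default). Per-node `k_overrides` can express any other layout.
* *Skip-gram hyperparameters* default to the canonical word2vec
  settings (window 5, 5 negative samples, 5 epochs, starting learning
  rate 0.025 with linear decay, `min_count = 1`), trained
  single-threaded with a fixed seed so runs are bit-reproducible. No
  frequent-word subsampling is applied: k-mer frequency spectra are far
  flatter than natural-language word frequencies and determinism is
  worth more here than a marginal speed-up.
* The KFV baseline (`kfv()`) is kept as a first-class operation so the
  embedding can always be compared against the representation it
  replaces.

## The classifier tree

The hierarchy is built from the training lineages alone (counts of
distinct species, by default), with a single grouping threshold $T$
(1000 species by default, matching reference-scale data):

1. the root splits the kingdom into phyla;
2. a child taxon with $\ge T$ species becomes its own class and is
   expanded one rank deeper;
3. the children with $< T$ species are merged into one `Other` class
   that is classified **directly to species** (a leaf);
4. taxa at the family rank are always species leaves — genus is never a
   routing rank, because congeneric species are exactly what the
   species-level classifier with small $k$ separates best;
5. a node whose every child falls below $T$ collapses into a single
   direct species classifier for its whole subtree (`<taxon>_<r>2s`),
   and a routing node with a single class routes deterministically
   without training a forest.

Node names follow the `<taxon>_<from>2<to>` convention (`Fungi2p`,
`Ascomycota_p2c`, `Cortinariaceae_f2s`, `other_p2s`,
`Ascomycota_p_other_c2s`), so a model summary can be read against the
taxonomy directly. An optional `max_leaf_classes` splits an oversized
`Other` leaf into alphabetical chunks (`Other1`, `Other2`, ...).

Routing nodes embed with $k = 10$, species leaves with $k = 7$
(defaults; both overridable per node). These are the two regimes the
level-dependent feature design exploits: longer k-mers give sparser,
more distinctive representations that separate anciently diverged
groups, while shorter k-mers densely overlap and resolve the point
mutations and short indels that distinguish congeneric species.
`select_k()` reproduces the selection procedure — five-fold stratified
cross-validation over candidate $k$ (7–11 by default) at any node, ties
broken toward the smaller $k$.

Each non-degenerate node trains a probability random forest (`ranger`,
100 trees, `sqrt` feature sampling, single-threaded with a fixed seed)
on the sequence vectors of the records under it. At prediction time a
query descends from the root taking the argmax-probability class at
each node (ties break to the lexicographically smallest label), and the
species decision is resolved through the species-to-lineage map — which
is what guarantees consistency. There is no confidence-based early
stopping by default; an optional `min_confidence` stops the descent
when a node's top probability falls below it, leaving deeper ranks
absent.

## Evaluation metrics

`evaluate()` reports, per rank: plain accuracy (ACC), hierarchical
accuracy (HA — a record counts only if **every** rank from phylum down
to the evaluated rank is correct), one-vs-rest precision/recall/F1, and
the multi-class Matthews correlation coefficient. HA $\le$ ACC at every
rank and is non-increasing with depth; for a consistent classifier over
systematic (globally unique) names the two coincide, and they can only
separate through rank-name homonyms or refused predictions.

Two aggregation decisions are deliberate and configurable:

* Precision/recall/F1 are **weighted** one-vs-rest by default (macro
  and micro are available). The binary definitions do not pin down a
  multi-class aggregation, and with thousands of classes the choice
  matters; weighted averaging is the least surprising default for
  heavily imbalanced supports.
* The **genus row mirrors the species row** by default. The classifier
  never makes a genus decision — genus is read off the species map —
  so the species decision's metrics are reported at both ranks.
  `genus = "derived"` instead scores the derived genus *names*, under
  which a sibling-species confusion still counts as a correct genus;
  both readings are defensible, so both are implemented.

Refused or failed queries keep their rows and count as errors at every
rank: denominators never shrink.

## The simulator

`simulate_dataset()` generates fully labelled ITS-like data whose
divergence tracks the taxonomy: a random kingdom ancestor is mutated at
rate 0.30 to found each phylum, 0.15 for classes, 0.10 orders, 0.06
families, 0.04 genera, 0.02 species, and 0.005 within species, with
single-base indels at 0.001 per position throughout (defaults; all
configurable). Default counts give 32 species x 12 records of ~600 bp.
Twelve records per species against a per-SH subsample of 10 means
curation always exercises its sampling step, and the two surplus
records per species double as natural held-out queries. Optional noise
records (ambiguous labels, injected non-ACGT characters) exercise the
curation filters, and a homonym option duplicates a class name across
phyla to test path-aware metrics.

What the simulator does **not** model: ITS secondary structure,
chimeras, length heterogeneity between clades, rank-dependent
taxon-size imbalance, or the label noise of real reference databases.
Passing the recovery tests therefore demonstrates that the pipeline's
machinery is sound — not that real-data accuracies carry over.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run a scaled-down study:
simulator defaults (32 species, 384 records before curation, 320
after), embedding and forest defaults, and grouping threshold $T = 3$
species so that the full routing chain (phylum through family, plus
degenerate single-child nodes) is exercised at this scale; with the
reference-scale default $T = 1000$ such a small study would collapse to
one flat leaf. Held-out species-level accuracy on this configuration is
expected at or above 0.90, and per-rank accuracy non-increasing from
phylum to species. Curation arithmetic is checked at reference scale
(25,163 SHs x 10 = 251,630 records) on a synthetic manifest, where only
bookkeeping, not sequence content, matters.

Other numerical details: k-mers are coded in base 4 (A<C<G<T,
lexicographic), capping $k$ at 15 (and 12 for explicit KFVs); per-SH
subsampling sorts records by id within SH and SHs alphabetically before
drawing, so the retained set is independent of file order; argmax ties
break lexicographically; probability forests use `ranger` with
`num.threads = 1` everywhere, which together with the seeded
single-threaded skip-gram trainer makes retraining byte-reproducible.

## Limitations

* Average pooling discards positional information; two sequences with
  the same k-mer bag embed identically.
* The fixed seven-rank scheme is assumed; rank-flexible taxonomies and
  intermediate ranks are out of scope.
* Species names must be globally unique (UNITE-style binomials and SH
  ids are); homonyms at intermediate ranks are handled path-wise.
* Probabilities from the forests are not calibrated; `min_confidence`
  thresholds should be chosen empirically for the task at hand.
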