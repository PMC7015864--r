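---
title: "Heterogeneous-network lncRNA similarity: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous-network lncRNA similarity: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetlncsim)
```

## The problem and the model

Functionally similar lncRNAs tend to (i) bind overlapping miRNA sets,
(ii) be implicated in related diseases, and (iii) be co-expressed across
tissues. Each of those signals is partial: interaction catalogs cover a
few hundred lncRNAs, disease associations another partly overlapping set,
expression atlases yet another. `hetlncsim` therefore scores lncRNA pairs
in four independent evidence layers and combines them by a weighted
average, with each layer weighted by how well it predicts an external
proxy for shared function — lncRNA pairs that share a target mRNA.

### miRNA layer

For a pair of lncRNAs, let `A` and `B` be their miRNA partner sets and
`U = A ∪ B` the ordered union. lncRNA `k`'s feature vector over `U` has
entry `max_{m' ∈ partners(k)} MISIM(m, m')` at miRNA `m`, where MISIM is a
precomputed miRNA functional-similarity matrix with unit diagonal. The
pair's score is the cosine of the two vectors.

The *max-to-own-set* replacement is a deliberate reading of the
construction "start from the 0/1 union indicator, then substitute
similarity values": it reduces exactly to the 0/1 indicator when MISIM is
the identity (giving the closed form `|A∩B| / √(|A||B|)`, which the tests
exploit), it keeps every entry in [0, 1], and it rewards a miRNA that is
absent from one partner set but functionally close to it. miRNAs missing
from MISIM contribute 0 (logged), except the trivial self-similarity of 1.

### Disease layer

Disease similarity follows Wang-style semantics on the disease hierarchy
DAG. For a term `i`, `T_i` is `i` plus its ancestors; the contribution of
`s ∈ T_i` is

    D_i(i) = 1,   D_i(s) = max { Δ · D_i(s') : s' child of s within T_i }

i.e. `Δ` raised to the shortest downward path length from `s` to `i`. The
semantic value is `DV(i) = Σ_{s∈T_i} D_i(s)` and pairwise similarity is

    DS(i1, i2) = Σ_{s ∈ T_1 ∩ T_2} (D_i1(s) + D_i2(s)) / (DV(i1) + DV(i2)).

`Δ` defaults to 0.5, the customary decay for this family of measures; it
is exposed as `delta` everywhere (`--delta` on the CLI) and contributions
increase strictly with it, which is property-tested. The memoized
recursion is verified against an independent path-enumeration oracle on
random DAGs. Multiple roots are allowed; terms sharing no ancestor get
`DS = 0`. Cycles are a hard construction error (one offending node set is
reported), since the recursion diverges on them. A disease id appearing in
several places of the hierarchy is modeled as one node with several
parents, not duplicated nodes.

Per-lncRNA vectors over the pair's disease union come in two modes:

* `ds-max` (default): entry at disease `d` is the maximum `DS(d, d')` over
  the lncRNA's own diseases — the analogue of the miRNA construction, and
  the reason the full `DS` matrix is computed up front. Identical
  association sets give all-ones vectors and cosine 1.
* `dv-literal`: entry is `DV(d)` if `d` is associated, else 0 — the
  literal "vector of semantic values" definition, kept because the two
  readings genuinely differ (disjoint association sets score 0 here even
  when the diseases are near-identical siblings). Vectors in both modes
  are padded to the pair's union key list; comparing on shared diseases
  only would make cosine blind to how much the two sets differ.

### Expression layers

Spearman rank correlation (average ranks on ties, Pearson on the ranks)
over pairwise-complete tissues, requiring at least 3. Blank cells in the
input are *missing*, never zero: an unmeasured tissue and a silent gene
must not be conflated. Two atlases with different normalization units
(TPM/FPKM) are handled strictly separately — rank correlation is invariant
to monotone per-profile transforms (property-tested), but mixing columns
across atlases is not meaningful. Negative correlations are kept by
default; `clamp-zero` floors them at 0 for users who want a non-negative
layer. Pairs with undefined correlation (constant profile) are omitted
from the layer rather than scored 0, because 0 is a meaningful
"uncorrelated" value.

### Fusion

    S̄ = Σ_i AUC_i · S_i / n

The literal form divides by the layer count `n`, not `Σ AUC`, which
deflates fused scores below the per-layer scale; it is kept as the default
for fidelity to the weighted-average schema, with the normalized
`sum-weights` variant (a convex combination) behind a flag. Coverage
overlap between layers is heavy but partial, and the schema does not say
how a pair absent from some layers enters the average; `available` mode
(the default) averages over the layers that score the pair, because strict
intersection would leave few pairs. Both choices are recorded in the run
manifest. Input order of layers never affects output (pairs are merged on
canonical keys and sorted), and a single layer with weight 1 is reproduced
exactly — both property-tested.

### Evaluation protocol

Positives are all lncRNA pairs sharing ≥ 1 target mRNA. Negatives are
sampled uniformly without replacement from pairs of lncRNAs that *both
appear in the lncRNA–mRNA table* (so "no shared target" is verifiable
rather than merely unknown), intersected with the evaluated layer's scored
pairs. Each layer's AUC on its own positives and an equal number of seeded
negatives becomes its fusion weight. If a degenerate input leaves fewer
verifiable non-sharing pairs than positives, the benchmark uses all of
them and logs a warning rather than failing.

For the integrated benchmark, layers differ hugely in sample size, so a
balanced subset takes from every layer the same number of positives and
negatives (the minimum positive count over layers), preferring pairs
scored by more layers; remaining ties break on the canonical pair id, a
deterministic rule chosen so the subset is reproducible without hidden
state. Per-layer selections are merged with duplicates removed.

AUC is computed by the rank (Mann–Whitney) formulation with ties counted
½; the threshold-sweep curve's trapezoidal area equals it to 1e-12, and
both equal an exhaustive concordant-pair count on random tied score sets
(tested). The positive/negative score split is additionally tested with a
two-sided Wilcoxon rank-sum test — exact enumeration when both classes
have under 20 observations, tie-corrected normal approximation otherwise.

## The synthetic generator

`generate_fixture()` emulates the full input suite with planted
co-function clusters: each cluster owns a pool of miRNAs, sibling-leaf
diseases under a cluster-specific DAG branch, target mRNAs, and a mean
expression profile per atlas. Each lncRNA picks each own-pool partner with
probability 0.9 (`within_cluster_partner_overlap`) and each foreign-pool
partner with probability 0.05 (`cross_cluster_leak`); expression is the
cluster mean profile (uniform on 0.5–3 per tissue) plus Gaussian noise of
SD 0.25, floored at 0. MISIM-like entries are drawn on 0.6–1.0 within a
pool and 0.0–0.3 across. Diseases sit as sibling leaves so that `ds-max`
similarity is high within clusters while exercising nontrivial DAG
structure (default depth 3, branching 2).

Defaults: 60 lncRNAs in 3 clusters, 30 miRNAs (≈ 10 partners per lncRNA),
18 diseases (≈ 5 associations per lncRNA), 24 and 12 tissues — partner
densities in line with curated interaction and association catalogs. The
target-mRNA pool is deliberately small (6, i.e. 2 per cluster, one of
which every cluster member carries so that same-cluster pairs share a
target by construction): validated lncRNA–mRNA interactomes are sparse,
and a denser pool would make shared-target positives the majority of all
pairs, which would invert the class balance of the benchmark. These sizes
also keep the full pipeline (all-pairs over 1770 pairs × 4 layers plus
evaluation) to a few seconds, which is the problem size used throughout
the test suite.

All randomness flows from one master seed through fixed numbered
substreams (one per sub-generator), so adding a generator never perturbs
earlier draws and two runs with the same seed serialize byte-identically.

What the fixture does *not* emulate: realistic TPM/FPKM distributions
(expression is Gaussian around a uniform mean, not log-normal and
zero-inflated), real MeSH topology (thousands of terms, multi-position
ids), scale (real layers cover 10³–10⁴ lncRNAs), and realistic
non-overlap between layers (fixture coverage is complete). Passing tests
therefore demonstrate correctness of the computations and recoverability
of a known planted signal — not performance on real catalogs, whose
published benchmark AUCs depend on specific database snapshots.

## Numerical and interface choices

* All pairs are unordered and stored with the lexicographically smaller id
  first (C collation, locale-independent); every similarity here is
  symmetric.
* Scores are serialized with `%.15g` and "." decimal, so files round-trip
  to 1e-12 and are byte-stable across locales; manifests record base
  names, not absolute paths, so reruns in different directories compare
  byte-identical.
* Asymmetric input similarity matrices are reconciled by arithmetic
  average by default (`max`/`error` available): the source databases
  publish both `Sim(A,B)` and `Sim(B,A)` without a reconciliation rule.
  Out-of-range values are clamped to [0, 1] with a logged count rather
  than rejected, to tolerate real-world exports.
* Diseases present in associations but absent from the DAG are dropped
  with a logged count, mirroring the name-normalization step users perform
  against the hierarchy's glossary.
* Undefined similarities (zero-norm vectors, constant profiles) raise a
  typed condition; network builders skip the pair and log a count.
* The CLI parses subcommand-style flags with a small built-in parser
  (flag > YAML config > default precedence) and returns exit codes
  (0 success, 2 validation, 1 computation) instead of quitting, so it is
  testable in-process.

## Known limitations

* Id harmonization across naming schemes (gene symbol, Ensembl, RefSeq,
  database-specific ids, chromosomal coordinates) is out of scope; inputs
  must already use one consistent id space.
* All-pairs construction is O(n²); builders accept a `subset` argument to
  bound cost on large catalogs.
* Fusion weights are in-sample: the same benchmark that produces the
  weights evaluates the integrated network, as in the original protocol;
  a held-out split would be needed for unbiased absolute numbers.
* The `n`-denominator fusion deflates scores of partially covered pairs;
  use `sum-weights` when score comparability across pairs with different
  layer support matters.
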