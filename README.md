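# hetlncsim

Functional similarity between long non-coding RNAs (lncRNAs), computed by
integrating four heterogeneous evidence networks.

Most experimentally characterized lncRNAs are annotated through what they
interact with, not what they do. A practical route to function prediction
is therefore a good similarity measure between lncRNAs: if an
uncharacterized lncRNA is highly similar to well-studied ones, their
functions are candidate annotations for it. No single data source captures
lncRNA biology on its own, so `hetlncsim` scores every lncRNA pair in four
independent evidence layers and fuses them:

1. **miRNA layer** — lncRNAs binding similar miRNA sets are assumed
   functionally similar. Each pair's miRNA partner sets are merged into a
   union key list; the entry of lncRNA *k*'s profile at miRNA *m* is
   `max_{m' ∈ partners(k)} MISIM(m, m')`, where MISIM is a precomputed
   miRNA functional-similarity matrix (so own partners score 1 and foreign
   miRNAs score their best surrogate). The pair's similarity is the cosine
   of the two profiles.
2. **Disease layer** — lncRNAs associated with similar diseases are assumed
   functionally similar. Disease similarity uses Wang-style semantic values
   on the disease-hierarchy DAG: each ancestor `s` of a term `i`
   contributes `D_i(s) = Δ^(shortest path s→i)` (decay `Δ = 0.5` by
   default), the semantic value is `DV(i) = Σ_s D_i(s)`, and
   `DS(i₁, i₂) = Σ_{s ∈ T₁∩T₂} (D_{i₁}(s) + D_{i₂}(s)) / (DV(i₁) + DV(i₂))`.
   Per-lncRNA semantic feature vectors over the pair's disease union are
   compared by cosine.
3. & 4. **Expression layers** — co-expressed genes tend to share function.
   Spearman rank correlation of tissue expression profiles, computed
   separately in two atlases (TPM and FPKM units are never mixed).

**Fusion** uses each layer's benchmark AUC as its weight:
`S̄ = Σᵢ AUCᵢ·Sᵢ / n`, averaging over the layers that score a pair. The AUC
comes from a built-in evaluator: lncRNA pairs sharing a target mRNA are
positives, sampled non-sharing pairs negatives, and each layer is scored by
how well it separates them (rank/Mann-Whitney AUC with ties counted ½).

The package also ships a seeded synthetic-data generator that plants
co-function clusters across all inputs (interaction tables, a MISIM-like
matrix, a disease DAG, two expression atlases), so the whole pipeline runs
and is testable without any downloads.

## Worked example

```r
library(hetlncsim)

bundle <- generate_fixture(fixture_params(seed = 7))   # 60 lncRNAs, 3 clusters
dag <- disease_dag(bundle$dag)
ds  <- disease_similarity_matrix(dag, sort(unique(bundle$lnc_disease$pairs$partner)))

nets <- list(mirna_network(bundle$lnc_mirna, bundle$misim),
             disease_network(bundle$lnc_disease, ds),
             expression_network(bundle$expr_A, "GTEx"),
             expression_network(bundle$expr_B, "NONCODE"))
ev <- evaluate_networks(nets, bundle$lnc_mrna, seed = 7)

print(nets[[1]])
#> similarity_network 'mirna': 60 lncRNAs covered, 1770 scored pairs
round(ev$weights, 3)
#>   mirna disease    GTEx NONCODE
#>   0.803   0.863   0.883   0.822
ev$integrated_roc
#> roc_result: AUC 0.8372 (777 positives, 777 negatives)
head(ev$integrated$scores, 3)
#>     lncA   lncB     score n_networks
#> 1 LNC001 LNC002 0.1941825          4
#> 2 LNC001 LNC003 0.1819614          4
#> 3 LNC001 LNC004 0.7698089          4
```

Each layer separates the planted clusters well on its own (AUC weights
0.80–0.88); the integrated network, fusing all four with those AUCs as
weights, discriminates shared-target pairs with AUC 0.84 on the balanced
benchmark, and the positive/negative score distributions separate at
rank-sum p ≈ 3e-117. `LNC001`/`LNC004` sit in the same planted cluster
(high fused score, 0.77); `LNC001`/`LNC002` do not (0.19).

## Command line

A `hetlncsim` launcher is installed under `exec/`; it wires the same
functions into subcommands:

```sh
hetlncsim fixtures --out data/ --seed 7
hetlncsim sim-mirna --interactions data/lnc_mirna.tsv --misim data/misim.tsv --out net_mirna.tsv
hetlncsim sim-disease --associations data/lnc_disease.tsv --dag data/dag.tsv --out net_disease.tsv
hetlncsim sim-expression --expr data/expr_atlas_a.tsv --unit TPM --name GTEx --out net_gtex.tsv
hetlncsim evaluate --net mirna=net_mirna.tsv --net disease=net_disease.tsv \
  --net GTEx=net_gtex.tsv --lnc-mrna data/lnc_mrna.tsv --seed 7 --out report.json
hetlncsim integrate --net mirna=net_mirna.tsv --net disease=net_disease.tsv \
  --net GTEx=net_gtex.tsv --weights report.json.weights.tsv --out integrated.tsv
hetlncsim query --net integrated.tsv --one LNC001
hetlncsim export-graph --net mirna=net_mirna.tsv --net GTEx=net_gtex.tsv \
  --threshold 0.7 --format graphml --out net.graphml
```

Every run writes a manifest (inputs with checksums, effective
configuration, seed) sufficient to re-run bit-identically; options can also
come from a YAML file via `--config`.

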