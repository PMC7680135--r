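---
title: "litmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{litmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model litmap implements, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic validation does and does not establish.

## 1. The relatedness model

Document relatedness is a convex combination of a citation signal and a
text signal:

$$ r^{HYB}_{ij} = \alpha\, r^{DC}_{ij} + (1-\alpha)\, r^{SA}_{ij}. $$

*Direct citation (DC).* A citation from $i$ to $j$ contributes
$c_{ij} = 1/\mathrm{nref}(i)$, where $\mathrm{nref}(i)$ counts only
references inside the corpus; the pair value is
$\max(c_{ij}, c_{ji})$, and the map is divided by its observed maximum. In
realistic corpora some document has a single in-set reference, so the
divisor is 1 and $1/\mathrm{nref}$ values pass through unscaled.

*Text similarity (SA).* Raw pairwise scores $S_{ij}$ arrive precomputed
(litmap never computes them from text). Each document keeps its top-20
partners — a pair survives if it is in the top-20 of *either* endpoint, and
ties at the 20th score are all kept, which makes truncation deterministic
without an arbitrary ordering. Retained scores are divided by the global
maximum.

*Imputation.* Most citation pairs have no retained similarity score, but
citation-linked documents almost always share topical content, so assuming
zero text relatedness would be wrong. Pairs with a known raw score outside
the top-20 get that score normalized; the rest get half the smaller of the
two endpoints' minimum retained scores, which keeps every imputed value
strictly below anything observed for either endpoint (the conservative
reading of "half the minimum score for either document"). Endpoints with no
retained score at all fall back to a global floor (half the corpus-wide
minimum) and are logged.

*Calibration.* $\alpha = \Sigma r^{SA} / (\Sigma r^{DC} + \Sigma r^{SA})$
solves the balance condition $\alpha \Sigma r^{DC} = (1-\alpha) \Sigma
r^{SA}$. Whether the sums are taken before or after imputation is not
determined by the balance idea itself; litmap defaults to *after* (the
stated goal is equal weight across the entire set of pairs that enter
clustering) and exposes `calibrate_before_imputation` for the other order.
Sums are accumulated over pairs sorted by key so totals are reproducible
bit-for-bit on a platform.

## 2. Clustering

The document network is clustered with the Leiden algorithm
(`igraph::cluster_leiden`) under a constant-Potts quality — the
resolution-parameterized objective of the Leiden University methodology
lineage — with modularity available as a config alternative. Three nested
levels (PM5 finest, PM4, PM3) are built bottom-up: each coarser level
clusters the *aggregated* graph of the level below, whose edge weights are
the size-normalized cluster relatedness (Section 3) and whose node weights
are document counts. Re-clustering the aggregate guarantees the nesting the
PM5→PM4→PM3 columns promise; three independent runs would not.

*Minimum sizes.* How the published model enforced its 75/750/7500 minimums
is not stated; litmap merges each undersized cluster into the neighbour
with the highest summed edge weight, smallest cluster first, recomputing
after every merge. Undersized clusters with no external edges pool into a
designated residual cluster rather than being deleted — removal of
documents is never implicit.

*Resolutions.* Constant-Potts resolutions are scale-dependent (the
published full-corpus value 7.75e-5 balances ~18M documents with weights
summing to millions). For the 2,000-document synthetic corpus the defaults
are 0.02 / 0.002 / 0.0002, fixed once from a weight-density argument: a
100-document planted topic has ≈25 internal edges per document with mean
hybrid weight ≈0.08, so internal weight density ≈0.02 per pair-slot, and
the CPM threshold separating "merge" from "split" must sit below that but
above the (≈100× sparser) cross-topic density. The decade steps between
levels mirror the published model's coarsening ratio.

*Degenerate clusters.* The published model removed clusters by manual
review; litmap replaces this with rules (fraction of erratum-type titles
> 0.5; or missing-abstract fraction > 0.8 together with mean reference
count < 1), applied to whole clusters only, with counts reported.

## 3. Cluster graph and map

Cluster relatedness is $R_{mn} = \sum r^{HYB}_{ij} / \sqrt{N_m N_n}$ over
cross-pairs, size-normalized so large clusters are not automatically
central. Edges are filtered to each cluster's top-15 by $R$ (either
endpoint suffices; ties kept — the same union reading as the SA
truncation). The 2-D layout is a seeded Fruchterman–Reingold embedding
followed by cutting the longest `edge_cut` fraction of edges (default 0.7)
and refining from the previous coordinates. This reproduces the *contract*
of the OpenOrd-style layout — seeded determinism, an edge-cutting knob,
linked clusters proximate — not its simulated-annealing schedule; the
algorithm used is recorded in the layout metadata. Fields are assigned per
cluster by journal plurality with alphabetical tie-break; the default
vocabulary is the conventional twelve high-level fields.

## 4. Characterization

*Phrases.* The chunk grammar `(JJ.*|VBG)* (NN.*)+ (VBG)?` (zero or more
adjectives/gerunds, one or more nouns, at most one trailing gerund) is
applied greedily left-to-right to pre-tagged tokens; title and abstract are
chunked separately so no phrase spans the boundary. POS tagging sits behind
an interface — the generator emits tagged tokens, and a minimal rule tagger
exists for untagged text — so grammar behaviour is tagger-independent.

*Bootstrap scores.* Counts are summed over 20 samples of
$\lceil np/3 \rceil$ documents drawn without replacement, then scaled to
$sc = count/(20\,np/3)$, an estimate of occurrences per paper. Counts are
raw occurrences, not document frequency (the per-paper gloss of $sc$
requires this).

*Idio scores.* $idio = 10 \log(1 + sc/nptot) \cdot sc/sctot$, where
$sctot$ sums the phrase's scores over all clusters and $nptot$ counts the
papers of all clusters in which the phrase appears. The log base is not
determined by the formula's source; natural log is the default with a
base-10 switch, declared in output metadata. Both readings order phrases
identically within a cluster (the base is a positive scalar on the log
factor); only absolute magnitudes differ.

*Central papers.* Document centrality is the summed within-cluster hybrid
relatedness; reported scores are normalized to the cluster maximum (the
sheet's "relative score" normalization is not specified upstream;
max-normalization makes the top paper's score exactly 1). Reviews are
listed separately; ties break by document id.

*Indicators.* Windowed means/fractions of per-document metrics and flags
(the window defaults to the last five years of the corpus span), author
counts at ≥2 and ≥5 papers, mean paper age, vitality = 1 / mean reference
age with a one-year floor on reference age (preventing division blow-up for
same-year citations), and the annualized growth
$((n_{last}+1)/(n_{first}+1))^{1/3} - 1$. The +1 smoothing keeps growth
finite when a cluster has an empty first year — common at synthetic scale —
at the cost of a small downward bias for large counts. Percentiles are
$100 \cdot \mathrm{midrank}/n$ over non-missing cluster values: ties share
a midrank, the maximum maps to 100, missing values propagate.

*Overlays.* An external ID list is projected to per-cluster counts and
concentrations; a passing set applies joint count/fraction thresholds
(defaults 25 and 10%).

## 5. The synthetic generator

The generator emits the statistical structure the pipeline assumes, not
realistic text: `K = 20` topics × 100 documents over 2010–2019, Poisson(8)
references per document targeting the same topic with probability 0.9 and
only earlier-or-equal years; 20 within-topic and 5 cross-topic similarity
partners per document with exponential scores at scales 30 vs 3 (so top-20
lists are predominantly within-topic); titles/abstracts mixing shared and
topic-specific vocabulary with tags emitted alongside; topic-pooled
authors; review/trial types at 10%/5%; topic-tilted metric draws.
Similarity scores are *sampled*, not computed from the generated text, so
relatedness tests do not depend on any text model. All draws flow from one
seed; identical config+seed gives byte-identical artifacts.

A green synthetic run establishes that the pipeline recovers planted
block structure (ARI ≥ 0.9), that the hierarchy nests, and that idio
scoring surfaces planted vocabulary. It does **not** establish performance
on real literatures: real citation networks have hubs, skewed topic sizes,
temporal drift and noisy similarity scores the generator deliberately
omits, and cluster counts/resolutions do not transfer across corpus scales.

## 6. Numerical contracts and degenerate inputs

- Unordered pairs are stored once under a canonical (sorted) key; all sums
  run in sorted-key order.
- Equal similarity scores normalize to 1 and survive truncation together.
- A document citing zero in-set references simply contributes no DC edges.
- Empty characterization windows yield null indicators (logged), never
  zeros masquerading as measurements.
- Cluster ids are dense positive integers per level; the residual cluster,
  when present, is a regular id flagged in the level's metadata.
- The pipeline manifest records config hash, seed, α, edge counts, cluster
  counts and removals, so any stage can be re-run and compared.

## 7. Known limitations

- Exact-string matching for journals and authors (no normalization or
  disambiguation).
- One journal → one field; no fractional field assignment.
- The full OpenOrd schedule is not implemented; layouts are comparable in
  contract, not in visual detail.
- Raw similarity computation, citation-source merging by DOI, and the
  classifier-derived per-document flags are inputs, not computations.
- Full-corpus scale (10^7 documents, 10^8 edges) is out of desk-scale
  reach; published cluster counts are context, not test targets.
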