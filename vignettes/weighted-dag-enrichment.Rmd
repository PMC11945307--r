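---
title: "Weighted DAG-aware enrichment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted DAG-aware enrichment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichdag)
```

## The problem: inheritance makes ancestors look enriched

Over-representation analysis (ORA) asks, term by term, whether an
interesting gene list overlaps a term's annotated gene set more often than
chance. With ontology-structured annotation (Disease Ontology, Gene
Ontology, any rooted is_a DAG) the true-path rule makes term gene sets
nested: a gene annotated to *Alzheimer's disease* is implicitly annotated
to *tauopathy*, *nervous system disease*, and every other ancestor up to
the root. A term that is genuinely enriched therefore drags its whole
ancestor chain into significance — the *inheritance problem*. The result
table fills with general terms that carry no independent evidence, and the
specific term that actually explains the signal may not even rank first.

`enrichdag` implements a double-weighted hypergeometric model that tackles
this globally. Every (term, gene) annotation carries a weight in (0, 1];
the per-term statistic is the classical hypergeometric upper tail,

$$p = 1 - \sum_{k=0}^{r-1} \frac{\binom{m}{k}\binom{N-m}{n-k}}{\binom{N}{n}},$$

with the annotated count $m$ and the overlap count $r$ replaced by the
floor of the corresponding weight sums ($m_w$, $r_w$). $N$ is the number
of genes annotated anywhere in the ontology and $n$ the number of
interesting genes among them; both stay unweighted.

## The two weighting mechanisms

**Initial weights.** A direct annotation starts at weight 1. An annotation
inherited upward loses 0.1 per level of inheritance, floored at 0.5:
$w = \max(1 - 0.1\,d,\ 0.5)$, where $d$ is the difference between the
term's level and the level of the shallowest directly annotated descendant
contributing the gene. Levels are longest-path depths from the root (root
= level 1), so $d$ measures how far the evidence travelled. The floor
keeps indirect evidence alive: this is a moderate correction, not an
elimination scheme.

**Dynamic weights and penalties.** Terms are processed bottom-up, deepest
level first, so every term is scored after all of its children (nodes on
one level never share an edge and are processed in lexicographic id
order). For a term $t$ with score $p(t)$ within the significance threshold
(default 0.01), each already-scored child $c$ with $p(c)$ within the
threshold is compared through the dynamic weight

$$w_d = \frac{\log p(c)}{\log p(t)},$$

natural logs throughout. $w_d > 1$ means the child is locally more
significant. Two cases:

* **Child wins** ($w_d > 1$): the genes annotated to $c$ have their
  weights at $t$ *and every ancestor of* $t$ divided by $w_d$ times a
  penalty factor. The child leaves the comparison permanently, $p(t)$ is
  recomputed, and the comparison repeats until no child outranks $t$ (a
  safety cap, default 50 passes, guards the loop; the floors of shrinking
  weight sums stabilize long before it in practice).
* **Parent wins** (no remaining child has $w_d > 1$): each remaining
  child's weights at the child itself are multiplied by $w_d \le 1$ and
  divided by the penalty; the child's score is recomputed and overwrites
  its earlier value.

The penalty factor,

$$\mathrm{penal} = \max\!\left(\frac{1}{10}\cdot
  \frac{\log(\mathrm{xmin})}{\log p(t) + \log p(c)},\ 1\right),$$

uses the smallest positive normalized double
($\mathrm{xmin} \approx 2.225\times10^{-308}$, so
$\log(\mathrm{xmin}) \approx -708.4$). When parent and child are similarly
but only moderately significant, the denominator is small and the penalty
is large — it, rather than $w_d$, does the down-weighting. When both
p-values are extreme the ratio falls below 1 and is clamped: the dynamic
weight alone decides. Scores of exactly 1 are nudged to $1 - 10^{-16}$
before taking logs (only inside the weight formulas; reported p-values are
untouched), and every computed score is clamped below at xmin so logs stay
finite.

Weights only ever decrease after initialization — both update factors are
$\ge 1$ divisors or $\le 1$ multipliers, and the implementation asserts
this on every update. After the traversal a single Benjamini–Hochberg
step-up adjustment is applied across all recorded terms; the traversal
threshold always uses raw p.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.01 | raw-p cutoff steering the traversal and defining "significant" |
| `weight_step` | 0.1 | initial-weight decay per inherited level |
| `min_init_weight` | 0.5 | floor of initial weights |
| `penalty_scale` | 0.1 | scale factor of the penalty formula |
| `min_genes`, `max_genes` | 0 (off) | skip terms with too few/many annotated genes; 10 and 2000 are sensible for genome-scale runs — terms below ~10 genes are rarely informative and terms above ~2000 are so general that they add noise |
| `max_refine_iters` | 50 | safety cap on the per-term refinement loop |

Setting `weight_step = 0`, `min_init_weight = 1` and `decorrelate = FALSE`
(or simply `method = "classic"`) reduces the model exactly to term-for-term
ORA; the test suite verifies the reduction to 1e-12 on dozens of fixtures.

## Interpretation choices the description leaves open

A few points of the procedure admit more than one literal reading; the
package fixes them as follows.

* **Origin distance under multiple inheritance** is the *level
  difference* between the term and the shallowest directly annotated
  descendant carrying the gene, not the edge count of any particular
  path — levels are the model's only distance notion, and the minimum
  (strongest-evidence) distance wins when several descendants contribute
  the same gene.
* **Step order.** The threshold check on $p(t)$ is re-applied on every
  refinement pass; $w_d$ and the penalty are computed from the scores at
  the start of a pass and the winning children are applied sequentially.
* **Scope of the child-wins update** is the term and its ancestors only,
  never the term's other descendants.
* **Once penalized, a child never re-enters** the comparison, and the
  parent-wins update overwrites the child's recorded p-value; the final
  table holds one row per term.
* **Floors** of the weighted counts $m_w$ and $r_w$ are taken
  independently.
* **Ties** ($w_d = 1$ exactly) favor the parent.
* Terms skipped by the gene-count bounds receive no score and are
  invisible to their parents' comparisons.
* Interesting genes absent from the annotated background are dropped (with
  a message) before $n$ is counted.

## The synthetic fixtures: what they emulate, and what not

All tests and studies run on seeded synthetic data built by
`generate_ontology()`, `generate_annotations()` and `implant_interest()`.

* The **ontology generator** guarantees the target depth with a backbone
  chain, draws the remaining terms' levels from a mid-peaked law (few
  terms just below the root, a bulge at intermediate levels, thinning
  toward the deepest levels — the census shape real disease ontologies
  show), and adds a second, strictly shallower parent with probability 0.3,
  producing the diamonds of multiple inheritance.
* The **annotation generator** draws each term's direct gene count from a
  discrete power law truncated at 300 with exponent 1.3, which puts about
  68% of terms below 10 direct genes while letting a few terms reach
  hundreds — the right-skewed shape of genome-scale disease annotation.
  Counts are drawn independently per term; real annotation is correlated
  along the DAG (sibling diseases share genes), which the generator does
  not model.
* `implant_interest()` plants ground truth: each signal term contributes
  its direct genes independently with probability $1 - 1/\mathrm{strength}$
  (so the infinite-strength limit contributes everything, and strengths
  just above 1 contribute almost nothing), plus background genes at a
  configurable rate. This simple law was chosen because it maps strength
  monotonically onto inclusion probability with the right limits; nothing
  downstream depends on its exact form.

Passing recovery and robustness tests on these fixtures demonstrates the
algorithm's behavior under controlled signal — it does not certify
performance on real annotation corpora, whose gene–term correlation
structure, annotation bias (well-studied diseases carry far more genes)
and literature redundancy the generators deliberately do not reproduce.

## The simulation studies

**Recovery (accuracy).** Each repetition selects k "known" terms at random
from the middle 50% of the annotation-size ordering (terms with very few
genes are hard for any method; terms with very many are trivially
general), builds the interest set from their genes, and counts how many
known terms appear among the top-k significant results of the weighted
model and of plain ORA. Two details matter:

* the size ordering uses **expanded** counts by default — after true-path
  expansion, "genes annotated to a term" means the expanded set, and
  middle-of-the-ordering terms then carry enough direct genes to build a
  realistic interest list (`by = "direct"` is available);
* the promiscuity filter (drop genes annotated to ≥ 30 terms) counts
  annotations **in the same space as the interest set**: direct counts for
  direct-mode lists, expanded counts for expansion-derived lists. An
  expansion-derived list loses many more genes to the filter — every
  direct annotation inherits to the whole ancestor chain — which is
  precisely why expansion-derived interest sets recover implanted terms
  less accurately than directly annotated ones. Counting only direct
  annotations in both modes would leave expansion-derived lists with full
  coverage of the known terms and erase that contrast entirely.

**Perturbation (robustness).** Starting from an unperturbed run's top-100
significant terms, the interest list is degraded — a fraction removed, or
noise genes added from the background — at 0–30% in 5% steps, many
repetitions per level, and the surviving overlap is averaged per level.
Per-repetition seeds derive deterministically from the master seed, so
every reported number reproduces bit-for-bit.

**Problem sizes.** The packaged studies run on a 500-term / 2,000-gene
ontology with 10 implanted terms and 20 repetitions for recovery, and a
150-term / 600-gene ontology with 100 repetitions per noise level for
perturbation — large enough for the directional effects to be stable,
small enough to iterate on comfortably.

## Numerical and degenerate-input notes

* `hyper_test()` evaluates the tail through the hypergeometric survival
  function (log-space internally); $r = 0$ returns exactly 1, and the
  weighted variant clamps at xmin so downstream logs are finite.
* A weighted count can floor to zero when penalties shrink a small term's
  weights; the term's score is then 1 — heavily penalized small terms
  drop out rather than error out.
* A single-node ontology gives the degenerate test $m = N$, $r = n$ and
  p = 1; an interest list disjoint from the background is an error.
* Node order is deterministic everywhere (lexicographic ids within a
  level), so identical inputs give bit-identical outputs; the core has no
  randomness.
* Dictionary collisions (two terms sharing a surface string) resolve to
  the lexicographically smallest term id, with a warning.

## Known limitations

* Only is_a edges build the DAG; part_of and other relations are ignored.
* The free-text annotator is an exact-phrase, longest-match scanner meant
  for short functional descriptions; it is not a tokenizing concept
  recognizer and will miss inflected or rearranged disease names.
* p-values recorded for deep terms early in the traversal are not globally
  recomputed when later sibling processing changes shared weights (except
  where the parent-wins step explicitly does so); the table reflects the
  bottom-up pass, not a fixed point.
* The BH adjustment is applied to the traversal's final p-values; because
  the weighting couples tests across terms, the adjusted values control
  the FDR only in the same approximate sense as in other weighted
  enrichment schemes.
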