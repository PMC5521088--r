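---
title: "Predicting noisy GO annotations: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting noisy GO annotations: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goanoise)
```

## The problem

Gene Ontology annotation files accumulate errors: electronically inferred
annotations are never individually reviewed, and even curated ones are
revised as evidence accumulates. Operationally, a *noisy* annotation is
one present in a historical GOA release but absent from a recent one,
after restricting both releases to the ontology terms they share (so that
ontology restructuring is not mistaken for curation). This package scores
every annotation of every gene for how likely it is to be noisy, and flags
the lowest-scoring ones.

## The model

Work within one branch (BP, CC or MF). Let `A` be the N × |T| binary
gene–term matrix after true-path propagation: `A(i,t) = 1` iff gene *i* is
directly annotated with *t* or with a descendant of *t*. Branch roots are
excluded — every annotated gene hits them trivially, and a root can never
be a meaningful noisy annotation.

**Semantic similarity by sparse representation.** Annotation profiles are
sparse (well under 2% nonzero on real data) and contaminated; sparse
coding is robust to exactly this regime. Each profile is reconstructed
from the other genes' profiles under a nonnegative l1 penalty:

$$\hat\gamma_i = \arg\min_{\gamma \ge 0}
  \tfrac12\,\lVert A(i,\cdot) - \gamma^{\top}\bar A^{i}\rVert_2^2
  + \lambda \lVert\gamma\rVert_1 .$$

The coefficients populate row *i* of the similarity matrix `S` (with an
index shift across the removed row); the diagonal is zero — a gene must
not vote on its own annotations — and `S ← (S + Sᵀ)/2` symmetrises.
Aggregated votes `V_SR = S·A` then act as a weighted nearest-neighbour
tally: the neighbourhood is whatever the sparse code left nonzero. A gene
with no similar genes has a numerically zero similarity row, and its
annotations receive uniformly low votes; ranking only *within* a gene's
own annotations (below) keeps such genes comparable.

**Evidence-code weights.** From a pair of archived releases, a direct
(gene, term) pair carrying code *c* in the older release is noisy iff the
pair is absent from the newer release's direct pairs — deliberately
code-agnostic, so re-curation (the same pair under a new code) does not
inflate the ratio. Ratios `r(c) = N̄(c)/N(c)` can be averaged over the
last *l* release pairs (default *l* = 1, one prior pair). Codes with
`r̃(c) ≥ τ`, where τ is the mean ratio over codes actually observed in
the branch, are down-weighted to θ; ties fall on the down-weighted side,
so if every code behaves alike all are treated as equally unstable.
Unobserved codes keep weight 1 (no evidence against them) with a warning.
Direct entries take the **max** weight over their codes (corroboration by
one stable source suffices), and weights propagate to ancestors by a max
rule, so an ancestor is never weighted below a descendant that supports
it.

**Fusion and selection.** `V = α·V_SR + (1−α)·A_ec`. Per gene, only
annotated terms compete; the *q* smallest scores are flagged
(evaluation protocol, ties broken lexicographically by term id for
determinism), or every score below 0.45 is flagged (production protocol).
Either way, annotated descendants of flagged terms are flagged too, as
`inherited`: by the true path rule, a term that should not be annotated
invalidates its whole annotated subtree.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `lambda` | 0.5 | l1 weight of the sparse code (unitless). Behaviour is stable across 0.1–1 on both real and synthetic data; 0.5 is the midpoint. Above the largest profile correlation the code collapses to zero. |
| `alpha` | 0.2 | fusion weight in [0, 1]. 0 = evidence-only (EC), 1 = vote-only (SR). Small α lets neighbourhood disagreement reorder annotations within an evidence-weight level without overturning the evidence signal. |
| `theta` | 0.5 | down-weight in (0, 1) for unstable codes. At 0.5 the two evidence levels (1 vs 0.5) map, through `(1−α)`, to fused-score bands [0.8, 1] and [0.4, 0.6] that a 0.45 cut separates cleanly. |
| `l` | 1 | release pairs averaged for the ratios; one four-month window balances sample size against drift in curation practice. |
| `v_cut` | 0.45 | production cutoff. With the defaults it is equivalent to flagging entries at the gene's lowest evidence weight whose vote component satisfies `V_SR < 0.25`; for other (α, θ) the V-cut is primary. |
| bootstrap | 85%, 500 reps | gene resampling for mean ± sd reporting. |

## The synthetic generator

`sim_config()` emulates the archived-release setting end to end: a layered
`is_a` DAG (root plus evenly filled layers, 1–2 parents drawn from the
layer above); genes grouped in functional clusters, each owning a coherent
term subset, so sparse codes have neighbours to find; per-record evidence
codes; and a recent release obtained by deleting records independently
with per-code probabilities. Injected noise is *off-profile* annotation:
with probability `profile_noise` a gene's direct term is swapped for
another cluster's term. Off-profile records carry a code mix biased toward
IEA and an elevated removal probability, coupling the two noise notions
the way unstable real annotations couple provenance and churn.

Defaults — the study conditions for all shipped experiments — are 300
genes × 400 terms in 5 layers, 10 clusters, 8 direct annotations per gene,
10% off-profile noise, code mix IEA/IDA/TAS/IMP = .5/.2/.15/.15
(off-profile: .8/.05/.1/.05), removal rates .2/.05/.1/.05 and .8 for
off-profile records. These sizes keep a full
generate → fit → predict → evaluate cycle at a few seconds, so the
acceptance experiment averages 20 independent seeds comfortably; ratio-
recovery checks use ≥ 2000 annotations per code so the binomial 3σ band is
tight.

What the generator does **not** emulate: GO's term-depth and information-
content distributions, species- and literature-driven annotation bias,
annotation additions (only removals define noise), and correlated removal
of whole publication batches. Passing the synthetic study therefore shows
the machinery ranks coupled, cluster-violating noise correctly — not that
real GOA noise has exactly this structure.

## Numerical choices

* The nonnegative lasso is solved by cyclic coordinate descent on the Gram
  form (compiled); all N leave-one-out subproblems share one N × N Gram
  matrix, computed once. Convergence is declared when the largest
  coordinate move in a sweep falls below 1e−10; the contract is the KKT
  condition (residual ≤ 1e−4), not a particular solver. Coefficients below
  1e−10 are reported as zeros. A zero Gram diagonal (all-zero profile)
  pins its coefficient at zero.
* Selection ties (equal fused scores) break lexicographically by term id;
  baseline frequency ties break uniformly at random under the caller's
  seed. All randomness everywhere flows from explicit integer seeds.
* Degenerate inputs: an empty record list is an error (there is nothing to
  fit); a gene absent from the recent release has all its historical
  annotations labelled noisy; `q` larger than a gene's annotation count
  selects all of them; genes with no true noisy labels are excluded from
  precision/recall/F1 averages (under the q protocol they make no
  predictions, so their ratios are undefined); per-gene F1 is 0 when
  p + r = 0.
* Fmax and Smin follow the standard CAFA conventions (protein-centric
  F-measure over a threshold grid; information content −log of term
  frequency in the truth), since no alternative definitions ship with the
  package's inputs.

## Open design points, resolved

* **`part_of` edges** are treated as containment and propagated along with
  `is_a` (annotation to a part implies annotation to the whole);
  regulates-type relations are not containment and are ignored. The
  relation set is an argument of `parse_obo()` for users who disagree.
* **NOT-qualified and ND records** are dropped by default (negative
  annotations are not annotations; ND marks absence of data and only ever
  annotates roots). Both filters are switchable in `parse_gaf()`.
* **τ per branch**, over observed codes only: reliability profiles differ
  across branches, and a code never seen in a branch contributes no
  information there.
* **Noisiness is decided on direct pairs only**; inherited annotations
  never enter the ratio counts, though both labels and predictions live in
  propagated space during evaluation.

## Known limitations

* A noisy annotation that persists across releases *and* is common among a
  gene's neighbours is invisible to both signals by construction.
* The operational label (removed between releases) conflates curation
  noise with other churn; headline scores should be read against that
  label, not against biological truth.
* On synthetic data, threshold-mode cleanup before majority-vote function
  prediction raises Fmax slightly but can lower term-averaged AUROC: the
  synthetic truth is the recent release itself, so removing down-weighted
  annotations that happen to survive is penalised. The acceptance script
  reports both directions honestly.
* Similarity is O(N²) memory and one lasso per gene; tens of thousands of
  genes call for blockwise or approximate solving, which is out of scope
  here.
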