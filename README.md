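# goanoise

Predicting **noisy Gene Ontology annotations** — annotations of a gene
that are likely incorrect and destined to be removed in later curation —
from two complementary signals:

1. **Sparse-representation semantic similarity.** Each gene's true-path-
   propagated annotation profile `A(i,·)` is reconstructed as a nonnegative
   sparse combination of the other genes' profiles,

   ```
   γ̂ᵢ = argmin_{γ ≥ 0}  ½‖A(i,·) − γᵀĀⁱ‖² + λ‖γ‖₁
   ```

   The nonzero coefficients pick out a small semantic neighbourhood and
   double as similarity weights `S(i,j)` (symmetrised, zero diagonal).
   A weighted vote `V_SR(i,t) = Σⱼ S(i,j)·A(j,t)` counts how strongly the
   neighbourhood supports each annotated term — terms the neighbours rarely
   carry are suspect.

2. **Evidence-code reliability.** Comparing archived annotation releases
   restricted to their shared ontology, the per-code noisy-annotation ratio
   `r(c) = N̄(c)/N(c)` measures how often code-`c` annotations disappear.
   Codes at or above the branch-mean ratio τ are down-weighted to θ < 1;
   weights attach to direct annotations (max over codes for a pair) and
   propagate to ancestors by a max rule, giving `A_ec`.

The two signals fuse into a per-annotation score

```
V(i,t) = α·V_SR(i,t) + (1 − α)·A_ec(i,t),        α = 0.2 by default
```

and, per gene, the annotated terms with the smallest `V` are flagged noisy
(with their annotated descendant terms, by the true path rule). `α = 0`
reduces to the evidence-only ranking (EC), `α = 1` to the vote-only ranking
(SR).

The package is aimed at anyone curating or consuming GOA files — it parses
OBO ontologies and GAF 2.x annotation files, ships random and
lowest-frequency baselines, bootstrap precision/recall/F1 evaluation, a
majority-vote function-prediction assessment, and a synthetic
ontology/annotation generator with known ground truth so the whole method
is testable without downloads.

## Worked example

Simulate a release pair with injected noise, fit, predict, evaluate:

```r
library(goanoise)
cfg <- sim_config(n_genes = 120, n_terms = 150, n_clusters = 6)
dag <- generate_dag(cfg, seed = 11)
ann <- generate_annotations(dag, cfg, seed = 12)
pair_est  <- make_release_pair(ann$records, cfg, seed = 13)  # ratio estimation
pair_eval <- make_release_pair(ann$records, cfg, seed = 14)  # evaluation

fit <- goanoise(pair_eval$historical, dag,
                history = list(list(old = pair_est$historical,
                                    new = pair_est$recent)))
fit
#> Noisy-annotation model (BP branch)
#>   genes: 120   terms: 149  (roots excluded)
#>   alpha = 0.2  theta = 0.5  lambda = 0.5
#>   down-weighted evidence codes: IEA
```

The fitted object holds the propagated matrix `A`, the similarity `S`
(`coef(fit)`), the votes `V_sr`, the evidence-weighted matrix `A_ec` and
the fused scores `V`. Labels and predictions:

```r
A_recent <- propagate_annotations(
  annotation_matrix(pair_eval$recent, term_order = dag$terms), dag)
labels <- noise_labels(fit$A, A_recent)
labels
#> noise_labels: 575 noisy annotation(s) on 94 of 120 gene(s)

pred <- predict(fit, mode = "q", q = attr(labels, "q_true"))
pred
#> noise_prediction: 586 flagged annotation(s) on 94 gene(s) (11 inherited)
#>     gene       term     score rank inherited
#> 1  G0004 GO:9000074 0.4333140    1     FALSE
#> 2  G0005 GO:9000036 0.4329721    1     FALSE
#> ...

evaluate_predictions(pred, labels, fraction = 0.85, reps = 500, seed = 15)
#> Evaluation over 94 gene(s), 500 bootstrap replicate(s) of 85%:
#>   precision  45.77 +/- 1.51 %
#>   recall     46.31 +/- 1.51 %
#>   f1         46.01 +/- 1.51 %
```

So with the per-gene true noisy counts as `q`, the fused score recovers
about 46% of the injected noisy annotations (F1, bootstrap mean ± sd) on
this instance — roughly double the random baseline on the same data.
`rank_annotations(fit, "G0001")` shows one gene's annotations ordered by
score (most suspect first), and `predict(fit, mode = "threshold")` flags
every annotation scoring below 0.45 for production-style cleanup.

Real data go through the same surface: `parse_obo()` two contemporaneous
ontology releases, `shared_terms()` them, `parse_gaf()` the archived
annotation releases, then fit as above. A command-line wrapper lives at
`inst/scripts/goanoise`.

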