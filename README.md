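# mclcomplex

Detection of protein complexes from protein–protein interaction (PPI)
networks, for computational biologists who have an interaction edge list
(DIP/MIPS-style TSV), optionally a gene-expression time course, and want
ranked, quality-filtered complex predictions plus the standard evaluation
metrics against a curated catalogue such as CYC2008.

## Method

The pipeline has three stages:

1. **Edge weighting.** The PPI network `G = (V, E)` is weighted by the
   Jaccard similarity of neighbourhoods,
   `A(i,j) = |N(v_i) ∩ N(v_j)| / |N(v_i) ∪ N(v_j)|` for `(v_i,v_j) ∈ E`,
   with each diagonal entry set to the row's maximum off-diagonal weight.
   Column-normalizing `A` gives the flow matrix
   `M(i,j) = A(i,j) / Σ_k A(k,j)` of a random walk on the network.

2. **Markov clustering (MCL).** `M` is iterated with
   *Expand* (`M ← M × M`), *Inflate*
   (`M(i,j) ← M(i,j)^r / Σ_k M(k,j)^r`, default `r = 2`) and *Prune*
   (per column, entries below `thd(j) = avg(j) − w·var(j)` over the
   support are zeroed and the column renormalized, default `w = 1`)
   until convergence. Vertices flowing to the same attractor form one
   cluster.

3. **Filtering and modification.** Each candidate complex `C` is scored on
   `Den(C,2)` (2-connection density), `E_co(C)` (mean pairwise
   co-expression, `E_co(u,v) = Σ_l ln((T'_u(l)+T'_v(l)) / |T'_u(l)−T'_v(l)|)`
   over max-normalized time courses) and `CoRatio(C)` (fraction of member
   pairs co-expressed above the network average). Complexes above the
   upper bounds (defaults `0.18 / 80 / 0.75`) are reserved, below the
   lower bounds (`0.06 / 50 / 0.20`) discarded, and median complexes are
   modified: members and neighbouring proteins are scored with a logistic
   function `P(v,C) = 1/(1+e^{−Σ w_i·Feature_i(v,C)})` of seven
   topology/co-expression features (shipped weights
   `0.01, 0.02, 0.01, 0.24, 0.36, 0.03, 0.33`), deleting weak members
   (`P < 0.5`) and adding strong neighbours (`P > 0.8`).

Evaluation implements the overlap score
`O(C_p, C_b) = |C_p ∩ C_b|² / (|C_p|·|C_b|)` with match threshold
`ω = 0.2` (Precision / Recall / F-Measure) and the clustering-wise
`Sn` / `PPV` / `Acc = √(Sn·PPV)`.

## Worked example

A synthetic data set with eight planted complexes (sizes 4–10, intra-edge
probability 0.85, background 0.01) and matching noisy periodic expression
profiles over 36 time points:

```r
library(mclcomplex)

d   <- simulate_dataset(synthetic_spec(seed = 11))
det <- detect_complexes(d$graph, d$expression)
det
#> complex_detection: 8 complexes (from 39 MCL clusters, 5 iterations)

evaluate_complexes(det$complexes, d$truth, omega = 0.2)
#> EvalReport (omega = 0.2)
#>   |P| = 8  Ncp = 8    |B| = 8  Ncb = 8
#>   Sn = 1.0000  PPV = 0.6667  Acc = 0.8165
#>   Precision = 1.0000  Recall = 1.0000  F-Measure = 1.0000
```

All eight planted complexes are recovered (every prediction matches a
true complex at `ω = 0.2` and vice versa, so Precision, Recall and
F-Measure are all 1); `PPV < 1` reflects a few extra members attached to
otherwise correct complexes. The same run from the shell:

```sh
Rscript inst/cli/mclcomplex.R simulate --out-dir sim --seed 11
Rscript inst/cli/mclcomplex.R pipeline --network sim/network.tsv \
    --expression sim/expression.tsv --benchmark sim/truth.txt --out-dir run
```

Real networks are run the same way: `--network` takes any two-column
edge list, `--expression` a TSV of per-gene time courses, `--benchmark` a
catalogue with one complex per line.

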