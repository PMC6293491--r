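# micnet

Infers **directed gene regulatory networks** from time-series expression
data. The intended users are computational biologists with short
multi-perturbation time courses (e.g. DREAM4-style benchmarks: a handful
of independent series, ~20 time points each) who want a directed,
binary network rather than a ranked edge list.

## Method

Two phases:

1. **Skeleton.** Every gene pair is scored with the maximal information
   coefficient,

   `MIC(X,Y) = max_{nx ny < B(n)} I*(X,Y; nx, ny) / log(min(nx, ny))`,
   `B(n) = n^0.6`,

   where `I*` is the largest mutual information over rank-based
   `nx x ny` grids. Pairs with `MIC >= theta` form an undirected graph;
   inside every triangle X-Y-Z the Gaussian-covariance conditional
   mutual information `I(Y,Z | X)` is evaluated on the raw profiles and
   a vanishing value deletes the indirect edge.

2. **Orientation.** Expression is binarized by the absolute Z-score
   rule (`1` iff `|x - mu|/sigma >= k`, default `k = 1.2`). Each edge
   is directed by comparing
   `CRAE(X->Y) + I_T(X->Y)` against `CRAE(Y->X) + I_T(Y->X)`, where
   `CRAE(X->Y) = H(Y|X) / (H(Y) |Y|)` and
   `I_T(X->Y) = I(X[1..T-d], Y[1+d..T])` is the time-lagged mutual
   information (lag `d = 1` by default); the larger sum wins, ties go
   to the larger `I_T`.

Evaluation against a gold standard uses precision, recall, accuracy,
F-score and Matthews correlation over the `N(N-1)` ordered non-self
gene pairs. A seeded synthetic module (random DAG + lagged saturating
kinetics) makes the whole pipeline testable offline.

## Worked example

```r
library(micnet)

truth <- sim_network(10, 15, seed = 4)      # ground-truth DAG
ds    <- sim_expression(truth, seed = 4)    # 5 series x 21 points
fit   <- micnet(ds)                         # theta defaults to 0.43
fit
#> Inferred gene regulatory network (MIC skeleton + entropy orientation)
#>   10 genes, 5 series, 105 time points
#>   theta = 0.43, k = 1.2, tdelay = 1
#>   skeleton: 16 edges, 3 pruned as indirect
#>   network:  13 directed edges

evaluate_network(fit$network, truth)$metrics
#> precision    recall       acc   f_score       mcc
#> 0.4615385 0.4000000 0.8222222 0.4285714 0.3251066
```

Reading: 45 gene pairs were MIC-scored; 16 crossed `theta = 0.43`; 3
were deleted as indirect by the triangle CMI test; the 13 survivors
were each given a direction. Of those 13 directed edges 6 match the
15-edge ground truth exactly (direction included), giving precision
0.46, recall 0.40 and MCC 0.33 over the 90 ordered gene pairs — the
order of magnitude binary directed inference achieves on noisy 10-gene
benchmark systems. `fit$orientation` holds the per-edge audit (CRAE,
lagged MI, rule used); `fit$pruned` the deleted edges with their CMI.

File-based use (DREAM4 layouts) goes through `read_timeseries()`,
`write_network()`, `run_infer()`, `run_evaluate()`, `run_simulate()`,
or the thin CLI at `inst/cli/micnet.R`.

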