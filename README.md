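# mixdag

Structure learning of directed acyclic graphs (DAGs) from **mixed**
continuous and categorical observational data.

Molecular and epidemiological studies rarely produce variables of one
type: gene or cytokine expression is continuous, while disease phenotypes
and SNP genotypes are categorical. Classical DAG learners (PC-style
constraint methods, gaussian score methods) assume a single distribution
family and force the categorical variables to be dropped or miscast as
continuous. `mixdag` is for analysts who want causal-direction hypotheses
— which upstream factors regulate which downstream effectors — from such
mixed cross-sectional data, with SNPs optionally constrained to act only
as sources.

## The method

The joint distribution is modeled as a pairwise Markov random field, so
every node's full conditional is either gaussian or multinomial. Three
stages recover the DAG:

1. **Markov blankets** — for every node $j$, an L1-penalized GLM
   $\hat\beta_j = \arg\min_\beta\, -\ell_j(\beta) + \lambda_j\lVert\beta\rVert_1$
   (gaussian lasso or multinomial-logit lasso), with $\lambda_j$ chosen by
   the extended BIC
   $\mathrm{EBIC}_\gamma = -2\ell_j + \lVert\beta\rVert_0\log n + 2\gamma\lVert\beta\rVert_0\log(d{-}1)$.
   Nonzero coefficients define the mixed graphical model (MGM), a superset
   of the DAG skeleton.
2. **Skeleton** — a PC-stable loop over MGM edges removes the spurious
   co-parent (moralization) edges using a permutation test of conditional
   independence for mixed pairs: regress both variables on the
   conditioning set, correlate the GLM residuals (ordinary residuals for
   continuous targets, summed Pearson residuals from a multinomial logit
   for categorical ones), and compare against $B$ permutations of one
   residual vector. Each removal records its d-separation set.
3. **Orientation** — greedy hill climbing from the empty graph over
   add/delete/reverse moves restricted to skeleton edges, minimizing the
   decomposable $\mathrm{BIC} = \sum_j [-2\log L^{(j)} + \lVert\hat\beta\rVert_0\log n]$,
   with cycle and direction-constraint checks at every move.

A structural-equation simulator (random DAGs, mixed node types, the
generative model above) and sensitivity/specificity/FDR edge-recovery
metrics round out the package. See `vignettes/mixed-dag-learning.Rmd` for
the full model account and design decisions.

## Worked example

Simulate an 8-node mixed DAG (25% categorical nodes), learn it back, and
score the recovery:

```r
library(mixdag)

cfg  <- scenario_config("custom", n = 500, d = 8, n_edges = 8,
                        frac_categorical = 0.25, seed = 7)
inst <- simulate_scenario(cfg)   # $truth (DAG), $data (mixed_data)
fit  <- mixdag(inst$data, seed = 7)
print(fit)
#> Mixed-data DAG fit
#>   data:     500 samples x 8 variables
#>   MGM:      20 edge(s)
#>   skeleton: 8 edge(s) (12 removed by CI tests)
#>   DAG:      8 directed edge(s), overall BIC = 10648.563

skeleton_metrics(fit$skeleton$graph, inst$truth)
#> skeleton-level recovery: sensitivity 1.000, specificity 1.000, FDR 0.000
dag_metrics(fit$dag$graph, inst$truth)
#> dag-level recovery: sensitivity 0.750, specificity 1.000, FDR 0.250
```

The first stage over-connects (20 MGM edges for 8 true ones — Markov
blankets include co-parents), the permutation tests prune it back to the
exact true skeleton here, and hill climbing orients the edges: 6 of 8
directions match the truth (DAG-level sensitivity 0.75; the 2
wrongly-directed edges count against DAG FDR but not against the perfect
skeleton). `summary(fit)` lists every directed edge and each removed
edge's separation set; `write_mixdag(fit, dir)` exports all artifacts as
TSV edge lists and logs.

Real data enter through `read_mixed_data("data.csv", types)` with a
declared type per column, plus optional
`direction_constraints(source_only = c("rs123", ...))` to force SNPs to
emit edges only.

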