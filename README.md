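# multifold

Integrative RNA secondary structure prediction from chemical probing
data. `multifold` takes an RNA sequence together with one or more
per-nucleotide reactivity profiles (SHAPE, DMS, CMCT — each profile one
*probing condition*), samples the pseudo-Boltzmann ensemble of every
condition, clusters the pooled samples across conditions, and returns
the dominant conformations supported by the data. It is aimed at RNA
structural biologists and bioinformaticians who have probing profiles
from several reagents, technologies or ionic conditions and want a
consensus structure model (or a small ranked set of candidate models)
rather than one profile's single prediction.

## Method

Reactivities enter the thermodynamic model as per-position
pseudo-energies (Deigan-style soft constraints),

> ΔG_d(i) = m · ln(r_i + 1) + b,  with m = 1.3, b = −0.4 kcal/mol,

added once per paired position, so that pairing unreactive bases is
rewarded. For each condition *d* the package draws M = 1000 structures
from the pseudo-Boltzmann distribution exp(−E_d(S)/RT)/Z_d by stochastic
backtracking through a McCaskill-type partition function (exact dynamic
programming over a bundled nearest-neighbor model; compiled core). The
pooled samples are clustered by base-pair distance (k-means over binary
pair-indicator vectors, whose squared Euclidean distance *is* the
base-pair distance), with the number of clusters chosen by an iterative
splitting criterion. Each cluster C is scored by

* **Stability(C)** — its accumulated Boltzmann condition probability
  Σ_d Σ_{S∈C∩S_d} P_d(S), and
* **Support(C)** — the number of conditions with probability mass ≥
  τ = 1/(k+1) inside C,

and the maximum expected accuracy (MEA) centroids of the Pareto-optimal
clusters under (Stability, Support) are returned, ranked by stability.
The package also compares conditions by the squared-Euclidean *ensemble
distance* between their base-pair probability dot plots (with 2-D maps
and condition grouping), ships MCC / sensitivity / PPV / geometric-mean
evaluation against reference structures (with pseudoknot removal by
maximum non-crossing subset), box-plot reactivity normalization, reagent
masking, and a synthetic reactivity generator for controlled
experiments. See the methods vignette
(`vignettes/multifold-methods.Rmd`) for the full model description and
design rationale.

## Worked example

Simulate three probing conditions from a known two-hairpin reference and
predict from them:

```r
library(multifold)

seq <- rna_sequence("GGCAGGCAAAAGCCUGCCAAAGCGGCCGAAAACGGCCGC", id = "demo")
ref <- parse_dotbracket("(((((((....)))))))...(((((((....)))))))")

panel <- simulate_condition_panel(ref, seq, n_conditions = 3,
                                  params = sim_params(flip_prob = 0.1),
                                  seed = 42)
pred <- predict_structures(seq, panel, config = run_config(seed = 1))
pred
#> # A tibble: 1 × 6
#>    rank structure                               stability support cluster  size
#>   <int> <chr>                                       <dbl>   <int>   <int> <dbl>
#> 1     1 (((((((....)))))))...(((((((....)))))))      3.00       3       1  2983

evaluate_predictions(pred, ref)
#> # A tibble: 1 × 9
#>   prediction    TP    FP    TN    FN   mcc  sens   ppv    gm
#>        <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1          1    14     0   727     0     1     1     1     1
```

One cluster absorbs 2983 of the 3000 pooled samples; its stability 3.00
(out of a maximum of 3, one unit per condition) and support 3 (all three
conditions place ≥ τ of their mass in it) make it the whole Pareto
front, and its MEA centroid reproduces the reference exactly (MCC = 1:
14 of 14 reference pairs recovered, no false pairs among the 741
position pairs).

Conditions can also be compared directly through their ensembles:

```r
cd <- distance_matrix(seq, panel, include_probing_free = TRUE)
signif(cd$D, 3)
#>           cond1    cond2    cond3   thermo
#> cond1  0.00e+00 0.000323 3.88e-07 1.54e-05
#> cond2  3.23e-04 0.000000 3.15e-04 2.40e-04
#> cond3  3.88e-07 0.000315 0.00e+00 1.49e-05
#> thermo 1.54e-05 0.000240 1.49e-05 0.00e+00
```

All four ensembles (three probing-directed, one probing-free) agree on
this easy fold, so the ensemble distances are tiny; `embed_2d()` and
`cluster_conditions()` turn larger matrices into 2-D condition maps and
condition groups.

A command-line interface wraps the same functions for file-based use:

```sh
multifold predict sequence.fa cond1.shape cond2.shape --seed 4 --out pred
multifold compare sequence.fa cond*.shape --probing-free --k 2 --out cmp
multifold evaluate pred.db reference.ct --out metrics.tsv
multifold simulate sequence.fa structure.db --conditions 3 --out panel/
```

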