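---
title: "Methods: multi-condition probing-directed structure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-condition probing-directed structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multifold)
```

## The problem

Chemical probing reagents (SHAPE acylators such as 1M7 or NMIA, DMS, CMCT)
react preferentially with flexible — typically unpaired — nucleotides.
After normalization, a probing experiment yields one reactivity value per
position: a *reactivity profile*. A *condition* is the combination of
reagent, read-out technology and ionic context that produced one profile.
Different conditions probe the same molecule through different systematic
biases, so no single profile is reliable on its own; the premise of this
package is that conformations supported across several conditions are more
likely to be native.

## The pipeline

For each condition $d$, per-position reactivities $r_i$ are converted into
pseudo-energies

$$\Delta G_d(i) = m \ln(r_i + 1) + b, \qquad m = 1.3,\; b = -0.4
\text{ kcal/mol},$$

and the thermodynamic energy of a structure is supplemented with those
terms, giving the pseudo free energy $E_d(S)$. In the default
`deigan_paired` mode, $\Delta G_d(i)$ is added once for each *paired*
position of $S$: an unreactive base ($r_i \approx 0$) receives the bonus
$b < 0$ when paired, while pairing a highly reactive base is penalized.
The package also implements a `literal_unpaired` mode in which the term
attaches to unpaired positions. We made `deigan_paired` the default
because, with $m > 0$ and $b < 0$, attaching the term to unpaired
positions *rewards* leaving unreactive bases unpaired — the opposite of
what reactivity means chemically; the paired-position convention restores
the intended directionality. Positions that are masked (missing data,
or nucleotides the reagent cannot probe: DMS reports only A/C, CMCT only
G/U) contribute exactly 0.

The package then:

1. draws $M = 1000$ structures per condition from the pseudo-Boltzmann
   ensemble $\Pr(S \mid d) = e^{-E_d(S)/RT}/Z_d$ by stochastic
   backtracking through a McCaskill-type partition function;
2. pools the samples across conditions, keeping each structure's
   condition of origin;
3. clusters the pool by **base-pair distance** (the size of the symmetric
   difference of pair sets), using k-means on binary pair-indicator
   vectors — an embedding in which squared Euclidean distance *equals*
   base-pair distance, so the clustering metric is exactly the structural
   one;
4. picks the number of clusters $k$ by scanning $k = 2, 3, \dots$ until a
   stopping criterion fires (see below);
5. scores each cluster $C$ by
   $\mathrm{Stability}(C) = \sum_d \sum_{S \in C \cap \mathcal S_d} \Pr_d(S)$
   (its accumulated Boltzmann condition probability, where $\Pr_d$ is
   normalized over the sampled multiset of $d$) and by
   $\mathrm{Support}(C)$, the number of conditions whose probability mass
   inside $C$ reaches $\tau = 1/(k+1)$;
6. discards clusters dominated on both metrics, and returns the **maximum
   expected accuracy (MEA) centroids** of the Pareto-optimal clusters,
   ranked by stability.

Cluster feature probabilities (used for centroids) weight the
*deduplicated* member structures by their thermodynamic Boltzmann factors
$e^{-E(S)/RT}$ — pseudo-energies influence which structures get sampled,
not how the members of a cluster are averaged. The MEA centroid maximizes
$\sum_{(i,j) \in S} 2\gamma\, \mathbb P_C(i,j) + \sum_{i \text{ unpaired}}
\mathbb P_C(i \text{ unpaired})$ with $\gamma = 1$ by default.

### Choice of k and its edge cases

A cluster is *significantly populated* when its stability strictly
exceeds $\varepsilon = |\mathcal D| / 3$ — a threshold that caps the
number of significant clusters at three, since stabilities sum to
$|\mathcal D|$. Two clusters are *highly similar* when their centroids
differ by at most $\delta = 1$ base pair. The scan stops when (i) two
significant clusters of the current iteration are highly similar, or
(ii) every significant cluster of the previous iteration is highly
similar to some cluster of the current one; both signal that further
splitting only fragments stable conformations. On a trigger at $k$, the
clustering for $k - 1$ — the last stable one — is returned. Two
under-specified corners needed decisions:

* a trigger at the very first $k = 2$ returns the trivial single-cluster
  clustering (the pool never supported a split);
* criterion (ii) requires *all* previous significant centroids to be
  matched, and is skipped when the previous iteration had no significant
  cluster (a vacuous match would otherwise stop the scan immediately).

If no criterion fires by $k_{\max} = 10$, the $k_{\max}$ clustering is
returned with a warning.

With no probing data at all, the package runs in probing-free mode: the
purely thermodynamic ensemble is treated as a single pseudo-condition
($\varepsilon = 1/3$). With a single condition the Pareto front is always
a single cluster, so mono-probing predictions return one structure.

## The energy model

The folding engine is a compact nearest-neighbor model: 36 tabulated
stacking terms (one per ordered pair of adjacent helix pair types over
AU/UA/CG/GC/GU/UG) plus linear loop penalties — hairpin
$a_H + b_H u$, internal/bulge $a_I + b_I u$, multiloop
$a_M + b_M(\text{branches}) + c_M u$ — shipped as a versioned TSV under
`inst/extdata/`. It is loop-decomposable, so the partition function, exact
base-pair probabilities (outside algorithm) and stochastic sampling are
computed by dynamic programming in compiled code; hairpins enclose at
least 3 unpaired positions, internal loops are not size-capped (keeping
the DP in exact agreement with the standalone loop-decomposition energy
function on *every* structure), and `N` never pairs. It is intentionally
not a full Turner 2004 parameter set (no dangles, no coaxial stacking, no
sequence-dependent loop terms). Every ensemble-level result in the test
suite is validated against exhaustive enumeration *under the same model*,
so the correctness of the sampling, clustering and selection machinery
does not rest on the table's biological fidelity. An external
thermodynamic engine can be substituted by passing a different
`energy_model()` table.

`RT` defaults to $0.0019872 \times 310.15 = 0.61633$ kcal/mol (37&nbsp;°C,
the probing temperature).

### Numerical choices

* Partition tables are kept on the linear scale in doubles; the deepest
  realistic stack (200-nt all-GC duplex) reaches $Z \sim 10^{232}$, well
  inside double range, and the engine fails loudly rather than silently
  overflowing.
* Stochastic backtracking consumes R's RNG, so a single `set.seed` makes
  sampling exactly reproducible; roulette-wheel selections carry a
  fall-back branch for the $\le 10^{-15}$ rounding slack at the end of a
  scan.
* MEA and pseudoknot-removal tracebacks resolve ties deterministically:
  MEA prefers leaving positions unpaired (zero-probability pairs are
  never introduced), pseudoknot removal prefers the lexicographically
  smallest maximum pair set.
* k-means runs with 3 restarts, all seeded from one master seed via the
  fan-out `seed_stage = (seed \cdot 2654435761 + stage) \bmod (2^{31}-1)`,
  so every stage is independently reproducible.

## Reactivity normalization

Raw reactivities are normalized by the box-plot rule: values above
$Q_3 + 1.5\,\mathrm{IQR}$ are set aside as outliers, the remaining values
are divided by the mean of their top 10%, and outliers are capped at the
maximum retained normalized value. A `literal_iqr` switch instead uses
$1.5\,\mathrm{IQR}$ itself as the cut-off; we kept the standard box-plot
reading as the default because the bare cut-off degenerates (discards
nearly everything) whenever the IQR is small relative to the median. When
the IQR is exactly 0 the outlier step is skipped entirely. Missing values
are any negative inputs (the community's −999 sentinel included).

## The synthetic generator

Real probing data are noisy in ways that are only partially understood,
so the package ships a generator with *controlled* statistical structure:
paired positions draw reactivities from an exponential distribution
(mean 0.08), unpaired positions from a gamma (shape 2, scale 0.45, mean
0.9), 5% of positions drop out as missing, and a `flip_prob` dial swaps a
position's class with the given probability — the generator's noise knob.
These defaults are package choices (normalized probing data typically
show low-reactivity paired positions and a broad unpaired tail around 1);
they are not fitted to any laboratory dataset, and every parameter is
configurable. Mutant panels emulate mutate-and-map experiments by
flipping a small fraction of pairing statuses per mutant rather than
refolding mutated sequences, which keeps tests independent of the energy
model.

What passing the recovery tests shows: under profile noise of this
family, the pipeline concentrates sampled mass into the generating
structure's cluster and its MEA centroid reproduces that structure, and
pooling several conditions is never worse than single conditions on
average. What it does not show: performance under real reagent-specific
biases (correlated errors along helices, primer shadows, sequence-driven
reactivity), which no synthetic family of this simplicity reproduces.

## Comparing probing conditions

Each condition's ensemble is summarized by its dot plot — the matrix of
pair probabilities $\mathbb P(i,j \mid d)$ — and conditions are compared
by the squared Euclidean ensemble distance
$\mathrm{Dist}(d,d') = \sum_{i<j} (\mathbb P(i,j|d) - \mathbb P(i,j|d'))^2$.
The 2-D condition map is classical multidimensional scaling on
$\sqrt{\mathrm{Dist}}$; because dot plots are points of a Euclidean space
under this metric, the embedding coincides with a principal-component
projection of the vectorized dot plots and is exact whenever two
dimensions suffice. Conditions are grouped by k-means on the embedding
coordinates.

## Evaluation metrics

Predictions are scored against a reference by classifying all
$n(n-1)/2$ unordered position pairs (strict pair identity, no one-off
slippage credit): MCC and the geometric mean
$\mathrm{GM} = \sqrt{\mathrm{Sens} \times \mathrm{PPV}}$, with
zero-denominator cases defined as 0. Crossing reference pair sets (e.g.
crystallographic models with pseudoknots) are first reduced to their
maximum non-crossing subset by cardinality — maximum *weight* would need
per-pair confidences that pair lists do not carry. Note that the MCC of a
random predictor is mean-zero only asymptotically; at realistic lengths
its finite-sample expectation is a few tenths of a percent away from 0.

## Problem sizes in the test suite

The suite validates ensembles by exhaustive enumeration on sequences up
to 20 nt (hundreds to tens of thousands of structures), sampling
calibration at 50 000 draws, MEA and pseudoknot removal against
brute-force search up to 12 positions/pairs, and parameter recovery on a
60-nt three-hairpin reference with 3 simulated conditions and the default
$M = 1000$, across 20 seeds. These sizes were chosen so the full suite
exercises every code path with exact oracles while remaining quick enough
to run on every change.

## Known limitations

* The bundled energy model is deliberately small; absolute free energies
  are not comparable to laboratory calorimetry, and predictions on real
  sequences should use it as a demonstration engine, not a Turner-model
  replacement.
* Pseudoknots are out of scope for prediction (they are handled only on
  the reference side, by removal).
* No replicate merging or raw-read processing: inputs are already
  normalized per-position reactivities.
* Mini-batch k-means is not implemented; pools at the default
  $M = 1000$ per condition stay well below the size where plain k-means
  becomes a bottleneck.
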