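---
title: "Differential coexpression networks: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential coexpression networks: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcenet)
```

## The problem

Two time-course expression experiments measure the same genes under two
conditions — for instance a yeast culture pulsed with low versus high
glucose, or a wild-type versus a transcription-factor-deletion strain
sampled through the cell cycle. Genes whose *co*-expression changes
between the conditions point at rewired regulation even when neither
gene is differentially expressed on its own. `dcenet` identifies such
differentially coexpressed links (DCELs), assembles them into a signed
differential coexpression network (DCEN), characterizes the network's
strikingly tree-like topology against null models, organizes its
components into functional clusters with Gene Ontology semantic
similarity, and infers which transcription factors changed activity
between the conditions.

## The differential link score

For genes $u, v$ with Spearman correlations $r^a_{uv}$ and $r^b_{uv}$ in
conditions $a$ and $b$, the package scores the change as

$$s_{uv} = \Delta_{uv}\left(1 + w\,\frac{|r^a_{uv}| + |r^b_{uv}|}{2}\right),
\qquad \Delta_{uv} = r^b_{uv} - r^a_{uv},$$

with `tieWeight` $w = 1$ by default. The first factor is the plain
correlation difference; the second separates pairs with identical
differences by how strongly correlated they are at all: a pair moving
from 1.0 to 0.5 is more informative than one moving from 0.5 to 0.0,
and the score orders them accordingly (−0.875 vs −0.625). Positive
scores mark links whose correlation is higher in condition $b$
("positive DCELs"), negative scores the reverse. The plain $\Delta$ is
also returned so users can rank on it alone (`tieWeight = 0`).

Spearman rather than Pearson correlation is used throughout: time-course
responses are typically monotone but rarely linear, and rank correlation
is robust to single-timepoint spikes.

## Significance: a shared permutation null

Significance is assessed by randomizing the assignment of sample columns
to conditions and recomputing all scores. One shared pool of `nPerm`
permutations serves every gene pair (at $10^5$–$10^6$ pairs a per-pair
pool is impractical, and under the null the statistic is exchangeable
per pair regardless). The empirical p-value of a pair is the proportion
of permutations whose absolute permuted score is at least the observed
one — a two-sided test, since links of both signs are biologically
meaningful and retained. Two schemes are provided:

* **pooled** (default): columns are reassigned to conditions at random,
  preserving each condition's sample count; works with unequal time
  grids (e.g. 12 vs 14 timepoints).
* **paired**: condition labels are swapped independently at each shared
  timepoint; requires matching grids and respects strong between-series
  dependence.

P-values are Benjamini–Hochberg adjusted and pairs with adjusted
$p < 10^{-4}$ become DCELs (both thresholds are parameters; a flag
thresholds the raw p instead). With the default count/`nPerm` estimator
the attainable minimum p is $1/\texttt{nPerm}$; `callDcels` warns when
`alpha` is below that resolution. An `(count+1)/(nPerm+1)` estimator is
available for users who prefer a never-zero p.

Constitutive links (CCELs) are pairs with Spearman correlation strictly
above 0.95 in *both* conditions; they form the constitutive network
(CCEN) used as a stable-coexpression reference.

## Preprocessing

`preprocessExpression` applies, in fixed order: quantile normalization
(per condition by default — the two conditions are separate array
series; a flag pools them), removal of probes missing more than 20% of
timepoints in either condition, k-nearest-neighbour imputation
(`k = 10`; Euclidean distance over mutually observed columns, unweighted
neighbour mean, neighbour pool restricted to the same condition),
collapsing of probes to genes by averaging, and a variance filter that
drops genes whose standard deviation is outside the top 25% in *both*
conditions (ties at the quantile cut are kept, reading "top 25%"
inclusively). The missing-value policy for quantile normalization is
explicit: ranks are computed per column over observed entries, the
reference distribution is the row-wise mean of per-column sorted values
(interpolated for columns with fewer observations), and ties get the
average reference value; on complete matrices this reproduces
`limma::normalizeQuantiles`, which the test suite verifies.

## Topology and the tree-likeness nulls

Table-style summaries (`topologySummary`) treat the DCEN as an unsigned
simple graph: average/maximum degree, power-law exponent of the degree
distribution (discrete maximum likelihood with the lower cutoff chosen
by Kolmogorov–Smirnov minimization, via igraph's `plfit`), average
clustering coefficient, and — on the largest connected component, where
they are defined — diameter and mean shortest path. Edge signs enter
only the triad census: each triangle is classified by its number of
positive edges. Because correlation is transitive, a coexpression
network admits only triangles with an odd number of positive edges, so
differences between two conditions' networks concentrate on at most two
edges of any triangle — the structural reason differential networks are
nearly triangle-free.

Two null models probe this:

* `degreePreservingNullC`: double-edge-swap randomizations (10 attempted
  swaps per edge per sample) preserve the degree sequence exactly; the
  p-value is the fraction of samples whose average clustering is at or
  below the observed one. Analyses in this vignette's scale use 1,000
  samples; $10^5$ is the production setting.
* `randomDcenTriadNull`: condition labels of the expression columns are
  shuffled, scores recomputed, and the top-$|s|$ pairs (matching the
  observed edge count) form a chance differential network whose
  triads-per-edge is recorded. Re-running the full permutation test
  inside this null would be quadratically expensive; rank-matching the
  edge count preserves network size and is the documented deviation
  made for tractability.

## GO semantics and functional clustering

Only the biological_process namespace is used, and annotations with
evidence codes IEP (inferred from expression pattern — circular for a
coexpression analysis) and IGI are discarded. Annotation frequencies
$p(t)$ are computed from the loaded, filtered corpus itself after
propagating annotations to ancestors over `is_a` links; $p$ is 1 at the
root and non-increasing toward the leaves. Term similarity is
Schlicker's relevance measure — Lin's ratio weighted by $1 - p(c)$ of
the best common ancestor — and gene similarity is the best-match
average (funSim) over the two genes' *direct* term sets, the standard
funSim convention (propagation stays inside the information content).
Enrichment is the upper-tail hypergeometric test with BH adjustment
across the tested terms of one run.

Genes are clustered by average-linkage hierarchical clustering of their
functional-similarity profiles with 1 − Pearson correlation as the
distance. The cluster count is a *user* decision made by inspecting the
heatmap and tree (7 and 9 were used in the analyses this package
replicates); the tool never auto-selects it. Link densities between
clusters $i, j$ are normalized by pair counts ($n_i n_j$ between,
$\binom{n_i}{2}$ within — the only convention that makes the quantity a
density in [0, 1]), and standardized against a gene-cluster label
shuffling null; $z > 1.5$ flags enriched cluster pairs. The
between/within ratio test reuses the same shuffling pool within a run.

## TF activity inference

For each transcription factor the co-occurrence count is the number of
DCELs with both endpoints among its targets. The null replaces every
network gene by a random gene regulated by the same number of TFs
(pools widened ±1, ±2, … until they hold at least 50 genes — "same or
similar" needs a concrete tolerance and adaptive widening keeps sparse
count bins feasible), keeping the edge topology fixed; draws are
without repetition within a permutation and a node may draw itself, so
the observed configuration lies in the null's support. Calls use the
empirical p at 0.05 (the BH-adjusted q is also reported, and a flag
switches the call to it — published tables are ambiguous about which
they threshold, so both are emitted). The common-TF index of a gene
pair is the mean of the Jaccard and overlap coefficients of their
regulator sets, and `targetCorrelationShift` compares a TF's
target-target correlation distributions between conditions with a
two-sample Kolmogorov–Smirnov test (the original analysis reports the
distributions "differed significantly" without naming a test; KS is the
assumption-light default).

## What the synthetic data emulates — and what it does not

`generateExpressionPair` plants modules that share a sinusoidal latent
time course (cell-cycle-like periodicity), one frequency per module so
distinct modules are uncorrelated, plus iid Gaussian noise. The
standard benchmark is 200 genes, 14 timepoints per condition, latent
amplitude 5 against unit noise. Differential links are planted by
*sign rewiring*: half a module's genes follow the sign-flipped latent
in exactly one condition, so cross-half pairs jump between $r \approx
+0.9$ and $-0.9$ while each half stays constitutively coexpressed.
Both DCEL sign classes are populated symmetrically (flip in $a$ →
positive links, flip in $b$ → negative), mirroring the near-balanced
sign counts real DCENs show.

A deliberate design point: modules that simply *lose* coexpression
($r: 0.9 \to 0$) are supported and exercised in the tests, but they are
not the benchmark's planted truth. At 14 timepoints the observed score
of such a pair ($|\Delta| \lesssim 1$, further shrunk by chance
correlation in the noise condition) overlaps the extreme tail of the
pooled permutation null — unbalanced column reassignments partially
reconstruct the differential signal — so no implementation can recover
them reliably at $p < 10^{-4}$. This is a statement about power at
small sample sizes, not about the caller; users should expect
real lost-coexpression links to need more timepoints or laxer
thresholds. Sign-rewired links are detected with a wide margin.

`generateRotationalPair` serves the topology benchmarks: every gene
gets its own phase on the latent circle (correlation ≈ cosine of the
phase difference — a coexpression *continuum*, which is what makes real
coexpression networks geometric and sign-transitive), and a few "mover"
genes jump phase by π in condition b. True differential links then form
bipartite stars around the movers (triangle-free, clustering 0), while
label-shuffled data yields angular-band chance networks rich in
triads — reproducing both directions the tree-likeness analysis tests.

Neither generator models dye bias, spatial artifacts, heteroscedastic
array noise, or missing-data mechanisms beyond missing-completely-at-
random; passing the benchmarks shows the statistics behave as designed,
not that any particular biological dataset will.

The toy ontology generator builds a small rooted DAG with genes
annotated at the deepest terms and a fraction of annotations tagged
IEP/IGI to exercise evidence filtering; the TF-table generator plants
one "deactivated" TF whose targets cover ≥ 90% of the genes incident to
planted DCELs, with all other TFs drawing uniform random target sets.

## Numerical choices and degenerate inputs

* Zero-variance genes have undefined correlations; their pairs are
  dropped before scoring, with a logged count.
* Permuted scores that are undefined (a constant pseudo-condition
  slice) are treated as 0 — no evidence against the null.
* Thresholds are strict as specified: DCELs need $p < \alpha$, CCELs
  $r > 0.95$ in both conditions; a pair at the boundary is excluded.
* Component ordering breaks size ties by the lexicographically smallest
  member, so outputs are deterministic.
* Singleton clusters have undefined within-density (reported 0 with a
  flag); zero null SD makes a z-score undefined (reported NA with a
  flag); a zero within-cluster link count makes the ratio test fall
  back to the between-link count, logged.
* All pipeline randomness derives from one master seed via
  `stageSeed(master, stage)`, so adding a stage never shifts another
  stage's random stream and repeated runs are bit-identical.

## Scale of the bundled analyses

The test-suite and acceptance benchmarks run at desk scale by design:
10,000 permutations for the recovery benchmark, 1,000–2,000 for
calibration and topology, 1,000 degree-preserving samples, 200
randomized-data replicates, and 20 seeds for the planted-TF study. The
corresponding production settings ($10^5$ randomizations throughout)
are plain parameter changes documented on each function.

## Known limitations

* The aggregated score's second term uses the package's documented
  form with a configurable weight; ranking is insensitive to the weight
  for equal-difference pairs, but absolute score values should not be
  compared across different `tieWeight` settings.
* The shared permutation pool makes extreme p-values across pairs
  positively correlated; family-wise error is controlled by BH on the
  empirical p-values, as in the replicated analysis, not by a
  max-statistic correction.
* `powerlawGamma` fits the degree distribution but does not test
  power-law against alternatives (log-normal, truncated laws).
* GO similarity traverses `is_a` only; `part_of` edges are ignored (a
  constructor flag away for users who need them).
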