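---
title: "Methods: scoring, resampling and clustering of pathway crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, resampling and clustering of pathway crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaycrosstalk)
```

## The model

The package quantifies *dysfunctional crosstalk* between gene pathways in a
case/control expression study, region by region, on a protein-protein
interaction (PPI) scaffold. The analysis has five stages.

**1. Voting-ensemble network.** Interaction evidence from several source
databases is merged by majority voting: an undirected interaction is kept
when at least `min_votes` distinct databases report it (default 3 of 5,
the common rule for integrating curated human interactomes). Duplicates
within one database carry a single vote, self-loops are dropped, and edges
are stored in canonical low/high orientation.

**2. Mapping pathways onto the network.** The focal (disease) pathway and
its *neighbor pathways* — those sharing at least one gene with it — are
intersected with the network nodes and the measured genes; the surviving
genes induce each pathway's edge set, and genes left without any induced
interaction (isolated proteins) are pruned. The deduplicated union of all
induced edge sets is the *sampling frame* for every permutation test below.

**3. Edge dysfunction scores.** For an interaction $e=(x,y)$ in one region,
three p-values are combined by Fisher's method:

* $p_1, p_2$ — two-sided Welch (unequal-variance) t-tests of differential
  expression of $x$ and of $y$ between control and disease samples;
* $p_3$ — the two-sided Pearson correlation test of the pair over
  *disease samples only* (disease-state co-expression).

The edge score is the Fisher statistic
$S(e) = -2\left(\ln p_1 + \ln p_2 + \ln p_3\right)$, referred to
$\chi^2_6$ for the reported combined p-value. Throughout the package the
score used in all summations is the *statistic* (larger = more
dysfunctional); the combined p-value is carried alongside for reporting.
The three p-values are treated as independent, as the meta-analytic scheme
assumes; no dependence correction is applied, and no multiple-testing
correction is applied across edges.

**4. Crosstalk and dysregulation by edge-set resampling.** The crosstalk
score of pathways $P_i, P_j$ is $C(P_i,P_j)=\sum_{e \in O_{ij}} S(e)$ over
their overlapping induced edges $O_{ij}$; the dysregulation score of one
pathway is $S_P=\sum_{e \in P} S(e)$ over all its induced edges. Both are
tested against the same null: random edge subsets of the observed sizes
drawn uniformly, without replacement and without any connectivity or
degree constraint, from the frame. The p-value is the fraction of
`n_perm` random scores *strictly exceeding* the observed score; strict
exceedance is the default because it admits exact 0 and 1, matching the
reporting convention of the original analysis, while `smoothed = TRUE`
switches to the add-one estimator $(b+1)/(B+1)$ for statistical hygiene.
Per region, pathways are ranked by p-value, ties broken by descending
$S_P$, then pathway id, for determinism.

**5. Clustering and enrichment.** Crosstalk p-values define a pathway
distance matrix (distance = p-value, non-overlapping pairs = 1, diagonal
= 0) which is clustered by average-linkage agglomeration. The tree is cut
dynamically in style: at a height fraction (`cut_height`, default 0.5) of
the maximum merge height, and clusters smaller than `min_cluster_size`
(default 3) are relabelled *unassigned* — the pathways that cannot be
clearly grouped. Functional enrichment of each pathway uses the
accumulative hypergeometric tail
$p=\sum_{i=k}^{\min(f,m)} \binom{f}{i}\binom{n-f}{m-i}/\binom{n}{m}$
with $n$ the nodes of the assembled network of pathways (configurable to
any universe), $f$ the term's annotated proteins, $m$ the pathway's
proteins and $k$ their intersection, computed in log space. Raw p-values
are ranked (top 3 by default); a Benjamini–Hochberg column is emitted as a
convenience extra only.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_votes` | 3 | databases that must support an interaction |
| `n_perm` | 10^4 | resampling iterations (10^6 for publication precision) |
| `strict` | TRUE | strict `>` exceedance; `FALSE` gives `>=` |
| `smoothed` | FALSE | add-one smoothing of permutation p-values |
| `p_floor` | 1e-300 | clamp keeping $\ln p$ finite; does not affect ranks |
| `linkage` | average | agglomeration method |
| `cut_height` | 0.5 | cut position, fraction of maximum merge height |
| `min_cluster_size` | 3 | smaller clusters become "unassigned" |
| `top_n`, `top_t` | 5, 3 | ranked pathways per region, terms per pathway |

The default `n_perm` of 10^4 is a desk-scale compromise: permutation
p-values have Monte-Carlo SE $\sqrt{p(1-p)/B}$, so 10^4 resolves p around
0.05 to about 0.002.

## The synthetic world

`simulate_crosstalk_data()` emits everything the pipeline reads, with the
statistical structure the analysis assumes:

* a gene universe (default 300 genes) with a true interaction set —
  background Erdős–Rényi edges (density 0.01) plus denser subgraphs inside
  pathways (pair probability 0.35), mimicking curated pathway maps;
* five databases, each holding a true edge with probability
  `db_coverage = 0.7` plus spurious non-edges at 5% of the true count, so
  the 3-of-5 vote filter does real work;
* 12 pathways of 10–30 genes; every non-focal pathway shares 1–5 genes
  with the focal pathway, so all are neighbors by construction;
* per-region control/disease expression, i.i.d. standard normal baseline
  (the continuous, roughly Gaussian scale of normalized log-intensity
  data). Disease samples add a `de_effect = 1.5` SD mean shift on the
  focal pathway's genes, and a gene-disjoint matching of the focal
  pathway's internal edges receives disease-only correlation via a shared
  latent factor $x=\sqrt{\rho}\,z+\sqrt{1-\rho}\,\varepsilon$ with
  $\rho = 0.6$ — exact population correlation, trivially vectorized.
  Sample sizes default to 15 per condition per region (chosen for test
  power; the original study does not state per-region sizes);
* optional multi-probe emission (duplicated gene rows plus probe noise)
  that downstream readers must average, matching the probe-averaging rule;
* 50 annotation terms, with one planted term covering 80% of the focal
  pathway plus a 1% background rate.

All randomness flows from one seed through `derive_seed(seed, stage_label)`
(a string-salted hash below $2^{31}$), so stages re-run independently still
reproduce a pipeline run, and identical configurations give byte-identical
outputs.

What the generator does **not** emulate: microarray probe-level artifacts
(no RMA, no CEL files), realistic expression moments of any particular
dataset, gene-length or GC biases, or annotation hierarchies. A green test
therefore establishes algorithmic correctness and statistical calibration
under the stated Gaussian world, not fidelity to any real cohort.

## Numerical choices and degenerate inputs

* P-values are clamped to `[p_floor, 1]`; zero-variance Welch inputs give
  p = 1 when means agree and `p_floor` otherwise; constant series in the
  correlation test give p = 1 with a warning.
* The hypergeometric tail is accumulated in log space with `lchoose` and a
  max-shifted log-sum-exp, exact to ~1e-14 relative against rational
  arithmetic for $n \le 60$ and stable for universes of tens of thousands.
* Empty mapped pathways are flagged, excluded from ranking and from the
  frame, never raised as errors; an empty frame aborts the run.
* Ranking and all file outputs use deterministic orderings (lexicographic
  edge keys, pathway-id tie-breaks) so fixed seeds give byte-identical
  tables.

## Design choices where the design was open

* **Score vs p-value as the summand.** The edge quantity summed into
  $C(P_i,P_j)$ and $S_P$ is the Fisher *statistic*, the natural additive
  quantity with "larger = more extreme" exceedance; the combined p-value
  is reported alongside.
* **"Same size" null pathways** preserve the *induced edge count*, because
  the scores are edge sums and the stated sampling frame is the edge union;
  the two subsets of a crosstalk pair are drawn independently (not
  disjointly), and null subsets need not be connected.
* **Distance = p-value.** Cluster input is the crosstalk significance
  (small p = close), which makes clusters groups of significantly
  interacting pathways.
* **Tree cut.** A full dynamic tree cut implementation is out of scope;
  the height-fraction cut with minimum-size unassignment reproduces the
  observable behavior (clusters plus a grey "unassigned" remainder) and is
  pluggable via the clustering parameters.
* **Enrichment universe** defaults to the network-of-pathways node set and
  is configurable; term hierarchies are not traversed.

## Known limitations

* **Pathway-level permutation p-values are anti-conservative.** The
  resampling null draws unconstrained edge sets, but a real pathway's
  induced edges share endpoint genes: each gene's Welch $-2\ln p$ enters
  $S_P$ once per incident edge, so the observed score is overdispersed
  relative to the null. Measured on 200 global-null replicates of the
  default world, about 21% of focal-pathway p-values fall at or below
  0.05 (the engine itself is calibrated: on a gene-disjoint frame the null
  p-values are uniform). This is a property of the published resampling
  scheme; rankings — the primary output — are unaffected by the common
  inflation, but the p-values should be read as scores, not as calibrated
  tail probabilities.
* **Edge-level dependence.** Scores of edges sharing an endpoint are
  dependent; calibration checks (KS uniformity, mean-score checks) are
  therefore run on a gene-disjoint edge subsample
  (`gene_disjoint_edges()`), where independence holds under the global
  null.
* Crosstalk p-values across pairs are mutually dependent (shared edges and
  shared null frame); no multiple-testing correction is applied anywhere,
  matching the original analysis.
* Real-data headline numbers from the original study depend on 2008
  snapshots of the source databases and are not reproducible here; the
  package validates by properties (oracles, calibration, planted-signal
  recovery, determinism) instead.
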