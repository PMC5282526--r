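---
title: "Methods: rank-based signature reversal and network pharmacology"
author: "sigrev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based signature reversal and network pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

## The problem

A multi-component drug (here motivated by herbal extracts profiled in a
type 2 diabetes model) rarely acts through one target. A practical way to
ask "does this treatment oppose this disease?" at the whole-transcriptome
level is signature reversal: summarize the disease as up- and
down-regulated gene lists, summarize each drug treatment in a reference
library as a full gene ranking, and test whether the disease's up genes
sink to the bottom of the drug's ranking while its down genes rise to the
top. sigrev implements that chain end to end — preprocessing,
rank-based connectivity scoring, repressor-weighted pathway activity,
degree-weighted network efficacy, functional-module detection, and a
literature-association check — together with a synthetic-data generator
that plants known structure in every input, so each stage can be
validated offline against ground truth.

## Connectivity scoring

For a tag set with sorted ranks $V_{(1)} < \dots < V_{(t)}$ inside a
ranking of $n$ genes (rank 1 = most up-regulated by the treatment), the
enrichment score is the classic two-sided Kolmogorov–Smirnov-type
statistic

$$a = \max_j\left(\frac{j}{t} - \frac{V_{(j)}}{n}\right), \qquad
  b = \max_j\left(\frac{V_{(j)}}{n} - \frac{j-1}{t}\right),$$

with $ES = a$ if $a \ge b$ and $ES = -b$ otherwise. The combined
instance score is $c = ES_{up} - ES_{down}$ when the two sub-scores
disagree in sign (concordant with either mimicry or reversal) and $0$
otherwise; scores are scaled into $[-1, 1]$ by dividing positives by the
largest positive and negatives by the largest negative magnitude.

Two numerical points discovered during development are worth recording.
First, on the discrete rank lattice the mirror relation is
$a(n{+}1{-}V) = b(V) - 1/n$ and $b(n{+}1{-}V) = a(V) + 1/n$ — reversing
a ranking does *not* exactly negate $ES$, and for tag sets symmetric
about the center the sign can even be preserved. The tests assert the
exact exchange relation rather than a naive antisymmetry. Second,
drug-level scoring orders all $N$ instances by $c$ and summarizes a
drug's $k$ positions with the same $a/b$ statistic; discordant instances
pile up at $c = 0$, and any fixed tie order would park one drug's tied
instances at fixed positions and bias its permutation p. Ties are
therefore broken uniformly at random under the run's seed, which keeps
the position-set permutation null calibrated while remaining
reproducible.

Drug significance uses the add-one estimator
$p = (1 + \#\{|ES^*| \ge |ES|\})/(1 + B)$ over $B$ random position sets
of size $k$ (default $B = 1000$), one shared null per distinct $k$.
Note the p-value floor this implies: a drug whose $k$ instances sit in a
planted extreme block of $m$ instances cannot beat
$\approx \binom{m}{k}/\binom{N}{k}$, so per-drug significance of planted
drugs depends on library size, not only on effect strength.

The reversal statistic itself is the Pearson correlation between two
queries' drug enrichment-score profiles over the drugs passing a
permutation-p filter (default $p < 0.05$ in either query; the
either/both rule is configurable because both readings are defensible).

## Pathway activity

Activity of pathway $P$ in a condition is
$A_P = \frac{1}{|P|}\sum_{g \in P} w_g\, r_g$ with $r_g$ the log2 ratio
to control and $w_g = -1$ for genes curated as repressors. The divisor
is the full membership size even when members are unmeasured (the
literal reading of size normalization); a measured-only divisor is
available. Significance is two-sided on $|A|$ against random gene sets
of the same size with the role-weight multiset reshuffled (1000
permutations), and q-values are Benjamini–Hochberg across the pathways
of the run. Enrichment of annotated terms uses the standard one-sided
Fisher/hypergeometric tail; the more conservative EASE variant (one hit
removed) is behind a flag and off by default.

## Network efficacy

Differential genes are mapped onto an undirected interaction network,
the largest connected induced component is isolated (ties broken toward
the component containing the lexicographically smallest gene id), and
the efficacy statistic is $W = \sum_g d_g r_g$ over the cluster, with
$d_g$ the node degree — full-network degree by default, since degree is
read as global positional importance; within-cluster degree is a flag.
$W$ is deliberately not normalized by cluster size (a normalized variant
exists for cross-study comparison). Significance is two-sided against
random gene sets of cluster size drawn from measured network genes. In
noise-free synthetic data $W$ shrinks exactly geometrically along the
dose series, which the tests assert.

## Functional modules

Genes are connected when the Pearson correlation of their log-ratio
trajectories over at least three ordered conditions reaches 0.8 — the
threshold applies to the *signed* correlation by default, with an
absolute-value mode behind a flag — optionally intersected with an
interaction backbone. Modules come from a classic Markov Cluster
iteration: column-stochastic matrix with unit self-loops (a standard
regularization against bipartite oscillation), expansion by matrix
square, inflation with exponent 2, pruning at $10^{-5}$, convergence at
$10^{-8}$ or 100 iterations. Clusters are read from the limit matrix's
attractor systems; a node attracted to several systems joins the
lowest-labelled one, groups below 3 genes are discarded and counted.
Term overlap between module sets uses the upper hypergeometric tail, and
enrichment-map edges use the overlap coefficient
$|A \cap B| / \min(|A|, |B|)$ with an inclusive 0.5 cutoff.

## Literature association

An item-by-keyword count matrix is binarized (any positive count becomes
1) so that a few heavily referred items cannot dominate; the sum of a
query set's binary entries is compared with 1000 equal-sized random item
sets, one-sided with the add-one correction, which makes the statistic
exactly invariant to inflating any single count — a property the tests
verify literally. An incremental curve repeats the test on every prefix
of the items ordered by total raw count (ties broken by item id). The
seeded null draws use a canonical (sorted) item order so the p-value is
invariant to input row order.

## The synthetic study

The generator is the package's study design, not a tuning knob. Defaults:
2000 genes; intensities $2^{\mu_g + e + \varepsilon}$ with per-gene
baseline $\mu_g \sim N(9, 1)$ (5% of genes are generated dim, near the
simulated local background of $\sim 100$, to exercise the 1.4-fold
background filter); 200 disease genes shifted by $\pm 2$ log2 units
(half up, half down) — a 4-fold planted effect, chosen so that the
partially restored treatment response still clears the standard 2-fold
selection; Gaussian log2 noise with sd 0.1; one control and one disease
column (mirroring pooled single-array designs) plus three dose
conditions that remove half of the remaining effect each
(residual $= 2 \cdot 0.5^s$). The reference library holds 50 drugs
$\times$ 2 instances: 5 mimic drugs with planted up genes at the top, 5
reversal drugs with them at the bottom, 40 neutral uniform permutations;
planted rankings are roughened by `round(0.5 * n)` random adjacent
transpositions. Twenty pathways of ~15 genes include a planted
activated pathway, a planted repressed one, and a role-flipped duplicate
whose activity must be the exact negation. The network realizes two
8-gene modules (drawn from the up and down gene sets) with edge
probability 0.9 inside and 0.02 elsewhere over ~100 background nodes.
The literature matrix covers ten diabetes-related keywords with nonzero
probability 0.9 for the planted (reversal-drug) items and 0.15
otherwise, plus a few 500-fold inflated entries for the binarization to
neutralize. Each generator draws from its own stream derived from the
master seed by a fixed offset, so stages reproduce in isolation.

What the generator does not emulate: probe-level microarray structure,
array-specific intensity distributions, correlated biological replicate
noise, pooling variance across animals, ortholog mapping loss, or the
cell-line/tissue context differences that dominate real cross-system
comparisons. Passing the planted-truth tests shows the statistics
recover the structure they are designed for; it does not certify
performance on real arrays, where effect sizes are smaller and noise is
structured.

## Pipeline and determinism

`run_pipeline()` chains background filtering (1.4-fold), quantile
normalization, log ratios (pseudo-count 1), 2-fold signatures for the
disease contrast and for the treatment response (treated vs disease
reference — in the synthetic design this is the reversal query),
connectivity for both queries, their profile correlation, pathway
activity, network efficacy across the dose series, Markov modules on the
differential genes, and the literature test of the significantly
reversing drugs. All permutation counts default to 1000; every stage's
randomness derives from the master seed; per-stage runtimes are kept in
the in-memory bundle but excluded from written artifacts so reruns are
bit-identical. Configuration validation reports every problem at once.

Problem sizes in the shipped tests (hundreds of genes, tens of drugs,
200-trial calibrations at 200 permutations) were chosen as the smallest
sets on which the planted structure is unambiguous and permutation
floors (add-one p at $B$ permutations is at least $1/(B+1)$; a BH
q-value across $m$ pathways is at least $m/(B+1)$ divided by the
significant rank) remain below the thresholds being asserted — that is
why truth-recovery assertions run at the full 1000 permutations while
calibration sweeps use 200.

## Known limitations

- The profile-template stage is a deliberate simplification of
  short-time-series profile mining: unit-slope templates, correlation
  assignment, label-permutation FDR. It reproduces the logic, not the
  original tool's exact template set.
- The two-class statistic is a single regularized d-score with a
  quantile fudge factor; no exchangeability-grid calibration of $s_0$,
  no resampling-based FDR. Thresholds are user-supplied.
- Ratio-only 2-fold selection on pooled single arrays carries no
  replicate variance and hence no significance; this mirrors the pooled
  design it emulates and is flagged rather than silently "fixed".
- Pathway activity treats a pathway as a weighted gene list; topology
  beyond activator/repressor roles is ignored.
- Functional-interaction backbones from curated databases are richer
  than anything the generator plants; module results on real data will
  differ from the synthetic benchmark.
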