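---
title: "Predicting nitrotyrosine sites from evolutionary sequence profiles"
author: "nitroRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nitrotyrosine sites from evolutionary sequence profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroRF)
```

## The problem

Tyrosine nitration (3-nitrotyrosine) is a post-translational modification
produced by reactive nitrogen species, a marker of nitrosative and
oxidative stress. Experimentally mapping which tyrosines of a protein are
nitrated is slow and biased toward abundant proteins, so sequence-based
prediction is attractive: given a protein, score every tyrosine for its
propensity to be nitrated.

`nitroRF` frames this as binary classification of fixed-length peptide
windows. Each candidate site is represented by the 41-mer
(&minus;20..+20) centered on the tyrosine; windows extending past a
protein terminus are padded with `-`, and padding contributes zero to
every encoding (gap neutralization). Experimentally verified sites are
positives; all remaining tyrosines of the same proteins are negatives.
Because negatives vastly outnumber positives, training uses a balanced
1:1 subsample by default (1:2, 1:3 and keep-all ratios are available; as
the negative pool grows, precision falls while accuracy rises, so the
balanced ratio is the default for the final model).

## Feature encodings

The core encoding is the **profile-weighted composition of k-spaced
amino-acid pairs** (pbCKSAAP). For a window of length $L = 2w+1$ with a
PSI-BLAST position-specific scoring matrix (PSSM) aligned to it, the
feature for the ordered residue pair $(q_i, q_j)$ at spacing $k$ is

$$
S_{ij}(k) \;=\; \frac{1}{L-k-1}
\sum_{v\,:\,\text{pep}[v]=q_i,\;\text{pep}[v+k+1]=q_j}
\max\!\bigl(\min\{\mathrm{PSSM}(v,q_i),\,\mathrm{PSSM}(v+k+1,q_j)\},\,0\bigr),
$$

i.e. each literal occurrence of the pair contributes the clipped minimum
of the two positions' log-odds scores. With $k = 0..4$ this yields
$20 \times 5 \times 20 = 2000$ features. The summation in the source
formula is ambiguous about whether it runs over literal occurrences or
over all position pairs; we implement the occurrence-gated reading (the
normalizing count $N$ is defined as the number of occurrences of the
pair, and gaps are explicitly "not counted"), and expose a dense variant
(`encoderConfig(dense = TRUE)`) that sums the clipped minimum over every
position pair, for sensitivity analysis. The denominator uses the full
padded window length, keeping the scaling constant across windows.

Three reference encodings are included for comparison: plain k-spaced
pair counts (KSAAP, 2000 features), one-hot binary encoding (BE,
$41 \times 20 = 820$), and AAindex physicochemical profiles
($41 \times 8 = 328$) using eight curated indices (LIFS790101,
TSAJ990101, NAKH920108, MAXF760101, BLAM930101, BIOV880101, CEDJ970104,
MIYS990104), taken from the AAindex release 9.1 tables shipped with
`seqinr`; `NA` table entries and gap positions encode as 0, and raw
(unstandardized) values are used by default since the pair encodings are
likewise unscaled. A useful identity links the two pair encoders: with a
unit one-hot pseudo-profile, every occurrence contributes
$\min(1,1) = 1$, so pbCKSAAP reduces exactly to KSAAP — this is enforced
as a test invariant.

PSSMs are parsed from the standard PSI-BLAST ASCII layout (the first 20
log-odds columns; the weighted-percentage columns are ignored, as the
clipping in the formula only makes sense on log-odds). Running PSI-BLAST
itself is out of scope: the pipeline accepts a directory of pre-computed
`<id>.pssm` files and otherwise falls back, with a warning, to a
database-free pseudo-profile (BLOSUM62 rows, or scaled one-hot).

## Feature selection

Each feature is scored by a two-sided Wilcoxon rank-sum (Mann–Whitney)
test between classes. Small untied samples ($n+m \le 10$) use the exact
null distribution; otherwise a normal approximation with midranks, tie
correction and continuity correction is used (matching `wilcox.test`'s
conventions, against which the approximation path is cross-checked;
small-sample p-values are validated against full enumeration of rank
partitions). Features are ranked by ascending p-value — the source
protocol does not state the ranking key, so we chose the p-value with a
deterministic tie-break chain (|standardized statistic| descending, then
name) — and the top 200 are kept.

Information gain (binarizing each feature at its gain-maximizing
threshold — the simplest scheme consistent with continuous features) and
mRMR (three-bin discretization at mean ± sd, mutual-information
difference scheme, as in the original method's defaults) are provided as
comparison rankers.

Selection can leak: ranking features on the full training set and then
cross-validating overstates performance. `kfoldCV` therefore recomputes
the ranking inside each training partition by default
(`nestedSelection = TRUE`); the whole-set protocol is available as
`globalSelection` in the pipeline for comparability, and the leakage
implication is the reason it is not the default.

## Classifier, threshold and evaluation

A random forest (the `randomForest` package: 500 trees,
`mtry = floor(sqrt(p))`, nodes grown to purity — the package defaults,
since the source protocol states none) votes on each window; the score
is the positive vote fraction. The decision threshold is not 0.5: it is
anchored at a target specificity of 90%, as the smallest cutoff $t$ such
that $Sp \ge 0.90$ under the strict `score > t` rule (ties at the
threshold are negative, for a deterministic boundary). Within
cross-validation the anchor is computed on the training partition's
out-of-bag votes, never on the held-out fold. A feature matrix in which
every column is constant cannot grow a forest; `trainRF` then returns a
degenerate model whose score is the training class prior for every
sample.

Evaluation reports accuracy, sensitivity, specificity, precision and
MCC from the standard confusion-count formulas (zero denominators yield
0 with a warning, the usual MCC convention), plus ROC/AUC where AUC is
computed as the normalized Mann–Whitney statistic (ties count ½).
Stratified k-fold cross-validation (default 10) reports both the
per-fold means and the pooled out-of-fold metrics, since protocols
differ on which to quote.

## Rule extraction

To make the forest interpretable, every root-to-leaf path ending in a
positive leaf is read as a conjunctive rule (per-feature conditions
merged to their tightest bounds), and a covering subset is assembled
greedily: repeatedly take the rule covering the most not-yet-covered
positive windows (ties: fewer conditions, then discovery order). The
source description of this loop is self-contradictory (it speaks of
deleting negatives until none remain); the standard positive set-cover
reading reproduces the published rule-table structure, and the
negative-deletion variant is available behind
`greedyCover(negativeDeletion = TRUE)`. Rules render in pair-frequency
notation, e.g. `I(A××××K) > 0.118 & I(H××××A) ≤ 0.013`, and round-trip
through `parseRule`. Both newly-covered and absolute coverage counts are
reported, since either reading of a published coverage column is
possible.

## Positional statistics

Two complementary contrasts compare positive and negative windows:

* **Residue enrichment (two-sample-logo style).** Per (position,
  residue) cell, a two-proportion z-test on class frequencies (gaps
  excluded from denominators), uncorrected $\alpha = 0.05$ by default to
  match typical two-sample-logo settings. We implement the statistic
  rather than wrap the external logo tool, for self-containedness.
* **Conservation (APV).** The average PSSM value of a window position is
  the mean of its 20 profile scores; per position, a Kruskal–Wallis test
  compares per-window APVs between classes, Bonferroni-corrected by the
  number of positions (41). For two untied groups KW's $H$ equals the
  squared standardized rank-sum statistic, which ties the two test
  modules together and is checked in the suite. Upstream/downstream
  flank summaries average offsets $[-20,-1]$ and $[+1,+20]$.

## The synthetic benchmark

Real curated nitration datasets and database-derived PSSMs cannot be
bundled, so the package generates a fully seeded synthetic benchmark
that every stage runs against:

* 500 proteins of length 80–160, residues i.i.d. uniform over the 20
  amino acids (a natural-frequency mode exists); 2–4 tyrosine sites per
  protein, each positive with probability 0.5. Sites are spaced at least
  `w + motif reach + 1` residues apart so that no window contains another
  site's planted residues (or another tyrosine) — without this, negative
  windows pick up neighboring positives' motifs through the composition
  features and the benchmark stops being background-vs-signal;
* a planted motif around positive sites — G at &minus;2 (probability
  0.85), K at &minus;1 (0.90), V at +1 (0.85) — emulating the reported
  enrichment of K, V and G near genuine sites;
* PSSMs written in PSI-BLAST ASCII layout as scaled one-hot profiles
  plus rounded Gaussian noise (sd 2), clipped to $[-8, 12]$ to mimic the
  log-odds range; background positions use scale 4 and planted/center
  positions scale 8, so conservation is elevated exactly where the
  signal is.

`truthTable()` enumerates the pair features the motif implies (e.g. K at
&minus;1 with the central Y gives the $k=0$ pair K·Y), which makes
selection-recovery measurable. Property runs use 500 windows per class.
These fixtures are separable by construction: they validate the
machinery (recovery of planted features, CV AUC ≥ 0.9, monotone response
to motif strength), not real-data performance. Real nitration data have
homology structure, compositional bias and much weaker signal, so
published-scale metrics cannot be reproduced from the synthetic
benchmark and no such claim is made.

## Numerical and design choices

* Coordinates are 1-based inclusive in all I/O; the canonical residue
  column order is the PSI-BLAST ASCII order `ARNDCQEGHILKMFPSTWYV`.
* Non-standard residues (B, J, O, U, Z, …) collapse to `X` and behave
  like gaps (zero contribution) — the conservative analogue of the gap
  rule, on which the source is silent.
* The 40% peptide-identity redundancy filter is a greedy first-seen scan
  comparing windows within the same label class (cross-class behavior is
  unstated in the source; within-class filtering never removes a
  positive in favor of a negative and is deterministic). Identity counts
  matching characters over the full window, padding included.
* Raw integer log-odds are used directly — no sigmoid or
  z-normalization; the $\max(\cdot,0)$ clip is the only transformation.
* All stochastic steps (balancing, fold assignment, forest training,
  fixture generation) are controlled by explicit integer seeds, and
  reruns are byte-identical.
* Rule mining defaults to the first 25 trees of the forest: rule counts
  grow linearly with trees while the covering set stabilizes early; the
  cap is a pipeline parameter (`ruleTrees`), not a limit of the
  extractor.

## Known limitations

* The pseudo-profile fallback is a stand-in, not a substitute for real
  PSI-BLAST profiles; pbCKSAAP scores computed from it carry no
  evolutionary information beyond the substitution matrix.
* The two-proportion z-test is asymptotic; at very small per-position
  counts its calibration degrades (the suite checks calibration at
  n = 400 per class).
* mRMR is quadratic in the number of features and intended for the
  selected subset or comparisons at moderate dimensionality, not for
  the full 2000-feature matrix at scale.
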