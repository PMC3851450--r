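---
title: "Two-phase SVM classification of plastid proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase SVM classification of plastid proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plastids — chloroplasts, chromoplasts, etioplasts, amyloplasts and their
relatives — are the plant and algal organelles responsible for
photosynthesis, pigment storage and starch metabolism. Genome-scale
annotation needs a predictor that, given only an amino-acid sequence,
decides (phase I) whether the protein is plastid-localized and (phase II)
which functional plastid type an identified plastid protein belongs to.
Transit-peptide-based predictors miss plastid proteins that use alternative
targeting routes and cannot distinguish plastid types at all, which
motivates classifiers built on whole-sequence features.

`plastidclass` implements this two-phase design: a binary radial-basis
SVM for plastid vs non-plastid, chained into a one-vs-one (OVO) multiclass
SVM over the four plastid types, each trainable on any of five sequence
encodings.

## Feature encodings

All encodings operate on sanitized sequences over the 20 canonical residues
in fixed alphabetical one-letter order (`AA_ALPHABET20`). Sanitization maps
U→C, B→N, Z→Q, J→L and removes X, stops, gaps and other symbols; the
encodings are defined only over the canonical alphabet, so this is a
precondition, not a convenience.

* **AAC** (20): relative frequency of each residue,
  $P_i = f_i / \sum_{k=1}^{20} f_k$.
* **DIPEP** (400): relative frequency of each ordered adjacent pair,
  $P_{ij} = f_{ij} / (L-1)$. Captures first-order sequence order
  information beyond composition.
* **PseAAC** ($20+2\lambda$, default 30): Chou-style pseudo amino-acid
  composition. For tiers $\tau = 1..\lambda$ two amphiphilic correlation
  factors are computed,
  $\theta^{(s)}_\tau = \frac{1}{L-\tau}\sum_{i=1}^{L-\tau} H_s(P_i)\,H_s(P_{i+\tau})$,
  one per physicochemical scale $s$ (hydrophobicity, hydrophilicity). The
  vector is $p_u = f_u / D$ for $u \le 20$ and $p_u = w\theta_u / D$ for the
  tail, with $D = \sum f_i + w \sum \theta$; the tail interleaves
  $\theta^{(1)}_1, \theta^{(2)}_1, \theta^{(1)}_2, \ldots$. Defaults
  $w = 0.1$, $\lambda = 5$; the encoding requires $L > \lambda$.
* **NCC** (60): concatenated AAC of the N-terminal segment, the central
  region and the C-terminal segment. Terminal segments are 25 residues — an
  empirically good compromise for this problem — when $L \ge 51$.
* **PHYSCHEM** (20): fractions of residues in 19 (overlapping)
  physicochemical classes — charged, polar-neutral, basic, acidic,
  aliphatic, aromatic, small, tiny, large, hydrophobic-aromatic,
  hydrophobic-neutral, amidic, cyclic (P), hydroxylic, sulfur-containing,
  hydrogen-bonding, acidic-and-amide, ionizable, cross-link-forming (C) —
  plus the theoretical isoelectric point.

### Design choices in the encodings

**PseAAC scales.** The formulation requires a hydrophobicity and a
hydrophilicity scale but no specific tables are mandated; we use the
classic amphiphilic pair (Tanford hydrophobicity, Hopp–Woods
hydrophilicity), standardized to mean 0 / unit variance over the 20
residues (population denominator 20) before computing the correlation
factors — the established convention for this encoding. Both scales are
injectable through `pseaac_params()` so alternatives can be evaluated; the
chosen tables are a documented substitution, not a claim about the original
models.

**Two correlation series.** The tier formula prints a single product
$H(P_i) H(P_{i+\tau})$ while the vector needs $2\lambda$ order terms; the
only consistent reading is two parallel correlation series, one per scale,
and that is what `pseaac()` computes (interleaved by tier).

**NCC short sequences.** For $L < 2 \cdot 25 + 1$ the sequence is split
into contiguous near-equal thirds (first segment $\lceil L/3 \rceil$, the
remainder balanced) instead of being rejected, so genome-scale scans never
abort; this preserves the N/Center/C semantics at reduced resolution.
Sequences shorter than 3 residues cannot form three non-empty segments and
are excluded (and reported) by `extract()`.

**Theoretical pI.** Henderson–Hasselbalch net charge over the free termini
and the D, E, C, Y, H, K, R side chains with the EMBOSS pKa set, solved by
bisection on pH 0–14 to 0.001 pH units. The feature is divided by 14 so it
lies on the same $[0,1]$ scale as the composition fractions; an unscaled pI
would dominate RBF distances.

## Classifiers

Binary machines are soft-margin SVMs with kernel
$K(x,y) = \exp(-\gamma \lVert x-y \rVert^2)$ fit by libsvm (`e1071`) on the
raw $[0,1]$-scale features (no internal rescaling). The cost factor $j$
multiplies the penalty on positive-class training errors, implemented as a
per-class weight — useful when the positive class is the one whose recall
matters. Phase II trains one machine per unordered class pair
($k(k-1)/2$ machines) and predicts by majority vote; ties are broken by the
largest summed absolute margin among the tied classes, then by fixed class
order (a tie rule must be fixed somewhere; this one is deterministic and
auditable, and `predict_ovo()` returns the full vote and margin tallies).

The per-scheme default $(\gamma, C, j)$ triples recorded in
`default_svm_params()` (e.g. DIPEP phase I $\gamma=265, C=6, j=1$; DIPEP
phase II $\gamma=210, C=1, j=2$) were selected on the original curated
training corpus. On other data they are sensible starting points on
$[0,1]$-scale features, not guaranteed optima; every training function
accepts explicit parameters. Phase-II machines share one triple per scheme
rather than per-pair tuning.

Decision thresholds: `predict_binary(model, x, threshold)` thresholds the
signed margin, so `threshold_scan()` (default grid $-1.2$ to $1.2$ in steps
of $0.1$, 25 rows) traces the sensitivity/specificity trade-off;
sensitivity is non-increasing and specificity non-decreasing in the
threshold.

## Evaluation

`metrics()` derives the seven standard parameters from confusion counts:
sensitivity, specificity, accuracy, precision, rate of false prediction
(RFP $= 100 -$ precision), error rate ($= 100 -$ accuracy) and the Matthews
correlation coefficient
$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$.
When an MCC marginal factor is zero the coefficient is reported as 0, the
random-prediction value — the common convention for the degenerate case.
MCC equals the Pearson correlation of the binary truth/prediction vectors,
which the test suite verifies on random instances.

`roc()` sweeps all distinct scores; the trapezoidal AUC equals the
Mann–Whitney rank statistic (ties one half), cross-checked in the tests
against an independent rank computation and against `pROC`.

`kfold_cv()` uses class-stratified folds (fold sizes differ by at most one
per class, seeded assignment). The pooled report is computed from the
summed confusion counts (micro pooling); per-fold reports are also
returned, since the two aggregations differ in general.
`multiclass_metrics()` reports one-vs-rest metrics per class and an
unweighted macro average; macro was chosen for the overall line and is
deliberately documented, because published overall numbers for multiclass
problems do not always state their aggregation rule and a macro average
should not be read as a reproduction of any specific one.

## Dataset preparation

Benchmark evaluation is inflated by near-duplicate sequences, so sets are
reduced to below 30% pairwise identity within and across classes.
`pairwise_identity()` aligns globally (BLOSUM62, affine gaps open 10 /
extend 0.5) and reports identical positions over alignment columns
(including gaps; a shorter-sequence denominator is selectable). Because
co-optimal alignments can place gaps differently depending on argument
order, the pair is canonicalized before aligning so identity is exactly
symmetric. `greedy_reduce()` processes sequences longest-first (ties by id)
and absorbs each into the first representative at $\ge$ cutoff identity —
a greedy, alignment-based approximation of k-mer clustering tools; cluster
counts will differ from theirs, but the guarantee that matters (no two
representatives at or above the cutoff) holds by construction and
`audit_identity()` verifies it exhaustively. In the cross-class step the
first (anchor) class is kept intact and conflicts are removed from the
second — which side loses sequences is otherwise arbitrary, so a
deterministic convention is documented instead. `split_independent()`
carves a seeded uniform holdout of `round(n * fraction)` sequences
(3160 at 10% → 316 independent / 2844 training).

## The synthetic benchmark

No public accession list exists for the original curated corpus, so the
package ships a generator that emulates the statistical structure the
classifiers exploit, making every stage testable offline:

* **Compositions.** A Swiss-Prot-like background; the plastid and
  non-plastid profiles differ in exactly the 11 residues A, C, I, M, P, V,
  D, H, K, S, W (enrichment factor 1.3 / depletion 0.7, renormalized within
  the shifted subset so the other nine residues are untouched). The four
  plastid-type profiles share the plastid composition and differ in
  smaller, pairwise-distinct four-residue subsets (factors 1.2/0.8) —
  phase II is deliberately the harder problem.
* **Dipeptide coupling.** Each class emits residues from a first-order
  Markov chain: a mixture (weight 0.25) of independent draws and a
  class-specific biased transition. The bias is a seeded log-normal
  perturbation of the product joint $f \otimes f$, Sinkhorn-balanced so
  both marginals equal the class composition; the chain's stationary
  distribution is therefore exactly the profile, so dipeptide structure is
  added without distorting composition. This gives DIPEP information beyond
  AAC, mirroring the observation that dipeptide features outperform plain
  composition.
* **Transit-peptide-like prefix.** Plastid-family sequences start with an
  S/T/A-rich, D/E-poor prefix (length uniform on 30–60, capped at a third
  of the sequence). The body composition is compensated for the expected
  prefix fraction so pooled class composition still converges to the
  profile; the prefix is what makes the NCC encoding more informative than
  whole-sequence composition, a directional property the tests check.
* **Lengths.** Log-normal with median 300 and $\sigma = 0.4$, floored at 80
  residues so both the full NCC segmentation ($L \ge 51$) and every PseAAC
  precondition hold; the short-sequence thirds path is exercised by
  dedicated tests instead.
* **Effect size.** A single knob $\delta$ interpolates every deviation
  (composition shifts, prefix enrichment, transition bias) between the
  shared background ($\delta = 0$, the null configuration in which all
  classes are statistically identical) and the default study setting
  ($\delta = 1$).

`make_benchmark()` builds the standard problem sizes used throughout the
acceptance checks: 400 sequences per phase-I class with a 100-per-class
independent set, and 150 per plastid type with 40 per class independent.
These sizes are an order of magnitude below the original corpus — chosen so
a full benchmark run completes in about a minute on one core while keeping
the binomial noise on a 5-fold CV accuracy below about two percentage
points — and the expected behavior at these sizes (phase-I CV accuracy
$\ge 90\%$, phase-II OVO accuracy $\ge 55\%$ against a 25% chance level,
null accuracy in 45–55%) was verified by oracle runs before being frozen
into the tests.

**What passing these tests does and does not show.** The generator
produces i.i.d. sequences from clean class-conditional distributions. Real
proteins carry homology structure, domain architecture, length–class
correlations and annotation noise, none of which are emulated — so
synthetic accuracies characterize the correctness of the pipeline (feature
math, fold hygiene, vote aggregation), not the accuracy achievable on real
proteomes. The null configuration guards specifically against information
leakage: any pipeline defect that leaks labels shows up as
above-chance null accuracy.

## Numerical conventions

* Residue order is alphabetical one-letter code everywhere; model files
  embed it along with a format version and checksum.
* Composition blocks sum to 1 within $10^{-9}$; PseAAC is normalized as a
  whole vector (it sums to 1 only when all correlation factors are
  non-negative, which standardized scales do not guarantee).
* pI bisection tolerance 0.001 pH; degenerate Welch comparisons
  (zero variance in both sets) report $p = 1$.
* Training is deterministic given data, parameters and seed; any internal
  shuffling is seeded. CV fold assignment is a pure function of the seed.

## Known limitations

* The greedy identity reduction is quadratic in set size and alignment
  cost; it is meant for benchmark curation at thousands of sequences, not
  metagenome scale.
* Default hyperparameters transfer to new corpora only as starting points;
  no tuning search is included by design.
* The physicochemical encoding's classes overlap, so its features are
  correlated; no decorrelation is attempted (the RBF kernel tolerates it).
* PSI-BLAST-style similarity search against a live database is outside the
  package's scope.
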