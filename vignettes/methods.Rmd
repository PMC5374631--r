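---
title: "Predicting protein-binding regions in RNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-binding regions in RNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpbindr)
```

## Overview

`rbpbindr` classifies fixed-length windows of mRNA as protein-binding or
non-binding.  The discriminative signal comes from three sources:
position-specific log-odds profiles of mono-nucleotides (mPWM) and of
di-nucleotides (dPWM) contrasting binding against non-binding training
sequences, and global k-mer compositions (k = 1, 2, 3) of the sequence.
An RBF-kernel support vector machine separates the encoded vectors.
This vignette records the model, its assumptions, and every numerical
and design choice a maintainer would want to know about.

## The log-odds profiles

For a training set of positives and negatives, all of length $n$, the
mono-nucleotide matrix is

$$\mathrm{mPWM}(i, j) \;=\; \ln\frac{f^{+}(i,j)}{f^{-}(i,j)},$$

with $i$ ranging over A, C, G, U and $j = 1,\dots,n$, and analogously
for the $16 \times (n-1)$ di-nucleotide matrix.  Natural logarithms are
used throughout.  The underlying assumption is positional independence
*given the class*: each column contributes additively to the evidence.
The di-nucleotide matrix relaxes this by one order, capturing adjacent
dependencies the mono profile misses.

**Smoothing.**  Raw per-position frequencies can be zero, which would
make the log-odds infinite.  Counts are therefore additively smoothed:

$$f(s, j) = \frac{c(s,j) + \alpha}{N + 4^{k}\alpha},$$

with the same pseudocount $\alpha$ (default 1.0) for the positive and
negative matrices.  This keeps every entry finite and preserves the
antisymmetry $\mathrm{PWM}(\mathrm{pos},\mathrm{neg}) =
-\mathrm{PWM}(\mathrm{neg},\mathrm{pos})$, which the test suite checks
as an invariant.  As $\alpha \to 0$ on nowhere-zero data the scores
converge to the raw log ratios, so both readings of "frequency" are
reachable through one exposed parameter.  `build_pwm()` refuses
$\alpha = 0$ whenever it would produce a zero denominator, with an
error telling the user to raise $\alpha$, rather than emitting
infinities.

**Row order.**  All $4^k$ blocks are ordered lexicographically
A < C < G < U.  Nothing depends on this beyond reproducibility of the
vector layout, but everything assumes it consistently.

## The feature vector

For the canonical window $w = 25$ the layout is
`mPWM[25] | dPWM[24] | composition[84]`, 133 elements; an optional
protein block extends it to 196.  Three length regimes are handled:

* $|s| = w$: profile terms are read off position by position.
* $|s| > w$: the window with the maximum mono log-odds sum is located
  by an exhaustive ungapped scan (`best_offset()`); both profile blocks
  come from that window, while compositions cover the *entire*
  sequence.  The scan ties are broken toward the smallest offset so
  output is deterministic.
* $|s| < w$: the whole sequence is slid along the matrix columns under
  full containment (offsets $0..w-|s|$); profile cells with no covered
  nucleotide are zero-filled.  A di-nucleotide cell is zero-filled
  unless *both* of its positions are covered — the conservative reading
  of "no corresponding nucleotide".  Zero is the natural fill value
  because a log-odds of zero is exactly "no evidence".  Overhanging
  placements are not considered; allowing them would add partially
  covered columns without adding evidence.

Compositions are normalized by the number of k-mer windows
$|s| - k + 1$, so each sub-block (4, 16, 64) sums to one independently;
normalizing by $|s|$ instead would break this closure property, which
the tests rely on.  Sequences shorter than 3 nt are rejected because the
tri-nucleotide block is undefined.

**Protein CTD block.**  When the binding protein's sequence is
available, a 63-element composition/transition/distribution descriptor
over 7 physicochemical amino-acid groups ({A,G,V}, {C}, {M,S,T,Y},
{F,I,L,P}, {H,N,Q,W}, {K,R}, {D,E}) is appended.  Transitions count
unordered adjacent group pairs ($\binom{7}{2} = 21$; same-group
adjacencies are counted nowhere), normalized by $\mathrm{length} - 1$.
Distributions record, per group, the normalized residue positions of
occurrence ranks $1$ and $\lceil q c\rceil$ for $q \in
\{0.25, 0.5, 0.75, 1\}$ ($c$ = group count), clamped to rank $\ge 1$;
the 100% point is the last *occurrence*, not the last residue.  Absent
groups contribute five zeros.  These are the standard CTD conventions;
they make each 5-tuple nondecreasing in $[0,1]$, a tested invariant.

## The classifier

A C-classification SVM (libsvm, via e1071) with the Gaussian kernel
$\exp(-\gamma\lVert x - y\rVert^2)$.  Defaults $C = 32$ and
$\gamma = 2^{-7} = 0.0078125$ are the grid-search optimum for this
feature family; `grid_search()` re-derives them on new data over the
usual powers-of-two grids ($C \in 2^{-5}..2^{15}$,
$\gamma \in 2^{-15}..2^{3}$, exponent step 2), breaking accuracy ties
toward the smaller $C$ then the smaller $\gamma$.  A linear kernel is
reachable through `svm_config(kernel = "linear")` for sensitivity
checks but is not the default.

Features are linearly rescaled to $[-1, 1]$ using minima and maxima
learned on the training data only; the scaling state is part of the
trained model and is re-applied verbatim at prediction time, so
training is invariant to any per-feature affine transformation of the
raw inputs (a tested property).  Scaling can be disabled
(`scale = FALSE`) to probe its effect.  No class weighting is applied:
unbalanced 1:$n$ datasets are trained as-is, which is what produces the
characteristic PPV/MCC decay as $n$ grows.

Constant features map to 0 under scaling.  Models refuse prediction
inputs whose feature count or block layout differs from the training
layout.

## Evaluation machinery

Six measures are computed from confusion counts: sensitivity,
specificity, accuracy, PPV, NPV and MCC.  Any measure whose denominator
is zero is reported as 0 and the situation flagged, keeping batch runs
alive on degenerate groups.

**10-fold CV.**  Folds are stratified by class under a recorded seed;
fold ids continue cyclically across classes so the $k = n$ limit is
exact leave-one-out.  Within every fold the PWMs are rebuilt from that
fold's training portion only, all sequences re-encoded, and the SVM
retrained — the leakage-safe reading of "profiles built from a training
dataset".  Confusion counts are pooled over folds and the metric set
computed from the pooled counts; fold-averaged metrics are returned
alongside for comparison, since either convention appears in the
literature.

**LOPO CV.**  All sequences of one RBP (binding and non-binding) are
held out per run.  The weighted average is computed from the summed
TP/TN/FP/FN of all runs — never by averaging per-group metrics, which
would weight a 10-sequence RBP equally with a 5,000-sequence one.
Negatives carry the RBP tag of the group they were generated for; any
untagged negatives are distributed round-robin across groups, the least
informative assignment.  Groups containing a single class are evaluated
and flagged rather than dropped.

**ROC.**  Thresholds sweep the unique decision values; AUC is the
trapezoid-rule area.  The implementation is cross-checked against an
independent reference (pROC) in the test suite.

## Dataset construction

Region tables use 0-based half-open coordinates internally (BED
convention); the reader accepts a `one_based` flag for 1-based
inclusive input rather than guessing a source's convention.  Candidate
filtering keeps regions of exactly the target length on the requested
strand with affinity *strictly* above the threshold (default > 0.9).
Slices containing N are skipped with a warning — no profile feature is
defined for ambiguous bases.

Random negatives are drawn uniformly over admissible start positions,
rejecting overlaps with known binding regions and N-containing slices;
upstream negatives sit a fixed distance (1–1001 nt) before each
positive on its own strand, probing how similar near-site background
is.  Redundancy removal is a greedy identity clustering in input order:
a sequence is dropped when its global-alignment identity (match +1,
mismatch 0, gaps free including end gaps; identity = matches /
alignment length) to any retained representative — or to a reference
set, in two-set mode — reaches the threshold (default 0.8).  This plays
the role an external clustering tool (CD-HIT-EST) plays on real data;
it preserves the filtering semantics without the word-filter heuristics
of that tool, and is documented as an approximation.  It is idempotent,
which the suite tests.

Ratio datasets (1:1 through 1:10) reuse all positives and nest their
negative samples, so datasets differ only by added negatives.  Real
curated datasets drew negatives independently per ratio; nesting is a
deliberate deviation chosen for experimental cleanliness (ablations
across ratios are not confounded by resampling noise).  Train/test
splits are stratified by label and RBP group with largest-remainder
rounding so per-label totals hit `round(fraction * n)` exactly;
one-sequence strata go wholly to training with a warning.

## The synthetic generator

`synth_generate()` draws positives column-wise from a positional
probability table and negatives i.i.d. from a background distribution,
tagging records round-robin with synthetic RBP names.  The default
conditions, chosen once: 25-nt sequences, an 8-nt core with consensus
UGUAUAUA at columns 9–16 (a PUF-family-like recognition element —
short, U/A-rich, moderately degenerate), per-column consensus
probability 0.85 with the remainder split equally, uniform flanks and
background, 14 groups mirroring a realistic RBP panel, and 2,000
sequences per class at desk scale.

What this emulates: positional preference concentrated in a short core,
degenerate positions, group structure for LOPO.  What it does *not*
emulate: genomic background composition bias (real non-binding regions
are not uniform), shared motifs between RBPs, sequence redundancy,
affinity-score noise, or secondary-structure effects.  Passing the
desk-scale pipeline checks therefore demonstrates that the machinery is
correct and that profile features dominate composition features under
positional signal — it does not certify real-data accuracy figures,
which depend on the curated CLIP-derived datasets.

With these defaults the mutual information per core column is high
enough that the Bayes error of the generative model is a few percent,
so the pipeline-level acceptance thresholds (pooled accuracy ≥ 85%,
MCC ≥ 0.7, compositions strictly below the full set) test the
implementation, not luck.  A uniform model (`motif_model_null()`)
provides the matching negative control: chance-level MCC and AUC.

## Problem sizes and determinism

Desk-scale runs use 2,000 sequences per class for the pipeline checks,
5,000 per class for log-odds recovery, and a few hundred for the
remaining properties — sizes at which every check completes in minutes
on one CPU while keeping binomial noise well inside the asserted
margins.  All sampling (generation, fold assignment, splits, negative
draws) goes through explicit integer seeds via `withr::with_seed`, so
no call disturbs the session RNG and any two runs with equal manifests
are bit-identical, a property the CLI tests assert on serialized
reports.

## Known limitations

* The identity clustering is $O(n^2)$ in pairwise alignments; for
  datasets beyond ~10⁴ sequences an external clustering tool is the
  practical choice.
* Only ungapped alignment against the profile is supported, and
  short-sequence placement requires full containment (no overhangs).
* Profile matrices are first- and second-order only (no $k \ge 3$
  profiles), and no secondary-structure or physicochemical nucleotide
  features are included.
* Probability calibration of decision values is out of scope; decision
  values are suitable for ranking (ROC) but are not probabilities.
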