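---
title: "Predicting binding regions from motifs and modified nucleosomes"
author: "epimotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binding regions from motifs and modified nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`epimotif` predicts which 1-kb genomic bins contain transcription-factor
binding sites by combining two independent sources of evidence.

**Sequence evidence.** Aligned binding-site sequences are summarized as a
position weight matrix. Counts $c_{b,i}$ of base $b$ at motif position $i$
over $N$ sites are smoothed with pseudocounts distributed proportionally to
a zero-order background $q_b$ — total pseudocount $P = \sqrt{N}$, per-base
$p_b = P\,q_b$ — giving frequencies and log-odds

$$f_{b,i} = \frac{c_{b,i} + p_b}{N + P}, \qquad
  m_{b,i} = \log_2\!\frac{f_{b,i}}{q_b}.$$

A window of length $L$ scores $\sum_i m_{w_i,i}$; the score is mapped to a
*relative unit scale* by anchoring at $s_{\min}$ and $s_{\max}$, the sums of
the per-column minimum and maximum matrix entries:
$\mathrm{rel} = (raw - s_{\min})/(s_{\max} - s_{\min}) \in [0,1]$. The
relative score is invariant to the logarithm base (the base cancels in the
ratio), which the test suite verifies. A 1-kb bin's PWM score is the
maximum relative score over every window fully inside the bin, on the
forward strand and as its reverse complement.

**Epigenetic evidence.** Nucleosomes carrying a histone modification are
represented by their center coordinates (one sorted set per chromosome —
positions, not coverage; duplicates collapse). Two features are computed at
an anchor position:

- *MNN*, the absolute distance to the nearest center of a given mark, one
  value per mark;
- *MNO*, the number of centers in the closed window ±`flank` (default
  1000 bp, i.e. a 2-kb window), one count per mark.

**Classifier.** A logistic regression classifier maps the feature vector to
a binding probability, $h_\theta(x) = (1 + e^{-\theta^\top x})^{-1}$, fit by
minimizing the average cross-entropy
$J(\theta) = -\tfrac1m \sum_i [y_i \ln h_\theta(x_i) +
(1-y_i)\ln(1-h_\theta(x_i))]$ with the analytic gradient
$\tfrac1m X^\top(h-y)$ under BFGS, initialized at $\theta = 0$ (the cost is
convex, so initialization is immaterial — tested by random restarts, not
assumed). Since raw distances reach megabases, features are z-scored with
training statistics that are stored on the model and re-applied verbatim at
prediction; this standardization is a numerical-conditioning choice and
leaves the fitted probabilities equivalent to a fit on raw features.
Zero-variance features are dropped with a warning rather than inverting a
singular scale. An optional L2 penalty (default off) is available for
ill-conditioned mark combinations. `stats::glm(..., binomial)` serves as an
independent cross-check in the tests, never as the implementation.

**Training and test sets.** Training positives are feature vectors at
binding-*site* centers on the training chromosome; negatives are vectors at
exactly two random positions per positive, drawn uniformly from non-gapped
regions (maximal A/C/G/T runs of ≥1 kb, so a full flanking window of real
sequence exists). No exclusion zone around true sites is applied to the
negative sample — sampling is plainly uniform, so a negative can fall near
a site. Test chromosomes are binned into non-overlapping 1-kb half-open
intervals; a bin is labeled positive when it *contains the center* of a
reported site, and features are computed at the *bin* center. The
site-center/bin-center asymmetry between training and test anchors is a
deliberate part of the method's design and is preserved.

**Fusion and transfer.** Each test bin's final score is the product
$h_\theta(x) \cdot \mathrm{rel}_{\mathrm{PWM}}$. Both factors lie in
$[0,1]$; the product preserves ranking dominance in each factor and needs
no extra parameters. A weighted log-linear (geometric-mean) fusion is
available behind `combine = "loglinear"` for sensitivity analysis. Because
active-mark architecture around bound regions is largely factor-agnostic, a
classifier trained on one factor's sites is made specific to another factor
by fusing with that factor's PWM (`transfer_predict()`).

**Evaluation.** ROC curves sweep descending score thresholds with ties
grouped at one step; AUC is the trapezoidal area, equal to the Mann–Whitney
pairwise statistic with half credit for ties (asserted against a pairwise
oracle and against pROC). "Averaged over the test set" is ambiguous between
pooling all intervals into one ranking and averaging per-chromosome AUCs;
`averaged_roc()` computes both and reports the pooled curve as primary,
since it corresponds to a single genome-wide ranking.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bin_size` | 1000 | bp | the method's region granularity; uniform width keeps MNO comparable across bins (trailing partial bins are dropped) |
| `flank` | 1000 | bp | MNO window half-width; ±1 kb matches the profiling window |
| `footprint` | 15 | bp | half-width of the plotted nucleosome footprint; profile offsets span −1015..+1015 |
| `pseudocount_total` | `"sqrt_n"` | counts | $P=\sqrt N$ grows sublinearly so informative columns stay sharp; overridable with any positive number |
| `negative_ratio` | 2 | — | two sampled negatives per positive |
| `combine` | `"product"` | — | parameter-free fusion of two $[0,1]$ factors |
| `lambda` | 0 | — | unregularized cross-entropy; L2 available for collinear mark sets |
| optimizer | BFGS, ≤500 iter | — | any quasi-Newton method meeting a 1e-6 gradient tolerance is acceptable; the specific routine is an implementation detail |

Conventions fixed for determinism: internal coordinates are 0-based
half-open (GFF converts on read); an interval's center is
`start + floor(length/2)`; equidistant nearest neighbors share the minimal
distance by definition; MNO windows are closed at both edges.

## The synthetic benchmark

`synthetic_spec()` / `generate_dataset()` emulate the three inputs the
method consumes. Defaults — the package's study conditions — are 3
chromosomes × 2 Mb, GC 0.41, 500 sites per chromosome planted as a 12-bp
consensus mutated at 15% per position on a random strand, one 20-kb
assembly gap per chromosome, and four marks (three active, one repressive).

Active marks place 6 nucleosomes per site at offsets
$\pm\mu + \mathcal N(0,\sigma)$ ($\mu = 150$, $\sigma = 50$), truncated to
$|{\rm offset}| \le \mu + 4\sigma$ and resampled out of the central
exclusion zone $\pm 40$ bp — the simplest generative model reproducing the
observed bimodal enrichment with a nucleosome-free region — plus a uniform
background of 0.1 centers/kb. Repressive (and moderate) marks are uniform
background only, at 5/kb (1/kb): active-methylation nucleosomes are sparse
outside regulatory neighborhoods, while repressive marks blanket
heterochromatin at near-full nucleosome density. These density choices were
fixed from a design-space simulation before the test suite existed.

`profile_roundtrip_check()` closes the loop: the profiler recovers two
peaks within ±20 bp of ±150 and a central minimum at 0 from active tracks,
and flatness (max/min < 1.5) from repressive ones. Two estimator details
matter. First, peak and minimum locations are read from the profile
smoothed at the footprint scale (31 bp), and the minimum is located as the
median of the near-minimal plateau — the depleted center is a plateau of
near-zero values whose raw argmin is a coin flip among tied offsets.
Second, flatness is computed on the smoothed profile over the fully
supported interior $|{\rm offset}| \le 1000$: offsets beyond ±1000 lose
part of their footprint support at the window edge (only nucleosomes with
$|c - s| \le 1015$ enter the profile), a windowing artifact that would
otherwise depress the edges of even a perfectly uniform track by up to
half.

**What passing does and does not show.** The generator reproduces the
*statistical shape* the method assumes — bimodal active enrichment,
depleted centers, uniform repressive background, assembly gaps, motif
degeneracy. It does not simulate read-level artifacts (mappability,
duplicates, tag-shift), nucleosome-calling errors upstream of the center
positions, correlated mark co-occurrence, CpG-island composition around
real promoters, or the extreme class imbalance of a 3-Gb genome. Synthetic
AUCs (≈0.92 PWM-only, ≈0.99 MNN at these conditions) therefore validate
the machinery and the ordering of methods, not the absolute accuracies
reachable on real chromatin data, which depend on external datasets.

## Numerical choices and degenerate inputs

- The sigmoid and cost are computed branch-wise
  ($\log(1+e^z) = z + \log(1+e^{-z})$ for $z>0$), so $J(0) = \ln 2$ exactly
  and huge $|z|$ cannot overflow; perfectly separable data simply drive
  $J \to 0$ within the iteration cap.
- Windows containing non-ACGT characters are unscorable and skipped rather
  than scored against the background; a bin with no scorable window gets
  the worst relative score 0 and an `unscorable` flag.
- A mark with no nucleosome on a chromosome is an error at the feature
  layer; the pipeline substitutes the chromosome length as a sentinel
  distance, warns, and flags the affected intervals — distances are never
  silently fabricated.
- Model and PWM JSON are written with 17 significant digits, so a reloaded
  model reproduces probabilities bit-identically.
- Score TSVs fix floats at 6 decimals and row order at (chrom, start); the
  run log records package version, seed, config and input checksums but no
  timestamp, so two runs of the same configuration are byte-identical.

## Open design points resolved here

- The binding-site "center" of an even-length interval is
  `start + floor(length/2)` everywhere (sites and bins alike); the
  convention is arbitrary but fixed.
- MNO counts nucleosome *centers* in the window, not footprint overlap —
  the feature is a discrete count of nucleosomes "in" the flanking region.
- Heterogeneous-length site sets are rejected when building a PWM rather
  than silently re-aligned.
- Training chromosomes with no eligible non-gapped run of ≥1 kb abort
  negative sampling with an error instead of relaxing the run-length rule.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
default study conditions (3 × 2 Mb, 1500 sites, four marks: ~6000 scored
bins, PWM scan of ~4 M windows per strand per chromosome) in well under a
minute each on a single core; the miniature fixtures used by unit tests
(2 × 200 kb) run in seconds. These sizes were chosen so that the complete
analysis is comfortably reproducible on a laptop.
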