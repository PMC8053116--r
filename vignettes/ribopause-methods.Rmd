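---
title: "Methods: codon-level pause detection, site occupancy, and co-IP enrichment"
author: "ribopause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-level pause detection, site occupancy, and co-IP enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ribopause)
```

This vignette is the package's account of its models and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. The measurement model

A translating ribosome protects a ~26–34 nt mRNA fragment from nuclease
digestion. After size selection, alignment of these footprints to the
transcriptome places each read's 5′ end at a known distance — the *P-site
offset*, dependent on read length — from the first nucleotide of the codon
occupied by the ribosome's P-site. The A-site (decoding) codon is one codon
downstream, the E-site one upstream. Everything downstream of alignment is
arithmetic on this coordinate system, which is why the package works in
transcript space with 0-based, half-open coordinates throughout and converts
SAM's 1-based positions only at the I/O boundary.

Two analyses read this signal in complementary ways:

* **Pause scoring** asks, per transcript and per codon, whether one codon's
  P-site read count towers over its local neighborhood.
* **Site occupancy** asks, transcriptome-wide, whether a codon *identity*
  attracts more ribosome dwell than its abundance in the translated
  transcriptome predicts.

A codon-specific supply problem (say, scarce charged tRNA-Arg) should move
both: excess pause calls on Arg codons, and an A-site observed/expected
ratio above 1 for Arg codons. Their joint null — ratios ≈ 1 and no
codon-group excess among calls — is the package's synthetic analogue of a
negative stalling result, and is exactly what the acceptance suite
calibrates.

## 2. Pause score

For codon $i$ with P-site count $d_i$, flanking window $W_i$ (up to `window`
codons on each side, focal excluded, truncated at CDS edges):

$$ z_i = \frac{d_i - \max(bg_i)}{\max(bg_i) \times 0.5}, \qquad
   bg_i = \{d_j : j \in W_i\} $$

with calls at $z \ge 10$, on transcripts with mean density $\ge 0.5$
reads/codon. Both comparisons are inclusive, and both thresholds are
parameters (`threshold`, `min_density`) with those defaults.

Numerical choices:

* **Background window.** The background definition is not canonical; we use
  symmetric flanks of `window = 25` codons each side, excluding the focal
  codon, truncated at CDS edges. A window wider than the CDS degenerates to
  full-CDS-minus-focal, which is defined and tested. The window is reported
  in output metadata rather than asserted as anyone's "true" value.
* **Zero-background floor.** $\max(bg)$ is floored at 1 read, so a codon
  with reads but a weak live flank cannot divide by zero; codons whose
  *entire* flanking window is empty are marked not-scorable (`z = NA`)
  rather than infinite.
* **Scale behaviour.** The ratio form makes $z$ invariant to scaling all
  counts by a common factor (verified numerically in the property tests,
  floor not engaged). It is *not* a classical Poisson z-score — a
  $(d-\mu)/\sqrt{\mu}$ statistic would grow with depth — so the $z \ge 10$
  cut is a fixed fold-over-background criterion, conservative at the depths
  the density filter admits: under the uniform-dwell null the acceptance
  suite measures $\le 0.1\%$ of scorable codons at $z \ge 10$.
* **Edges.** Start and stop codons are scorable but flagged (`is_edge`);
  initiation and termination peaks are not elongation pauses. Stop-codon
  calls are excluded from identity rankings, which normalize over the 61
  sense codons.
* **Ties in rankings** break alphabetically after descending count, making
  output order deterministic.

The density filter applies to replicate-merged alignments (merge first,
then map P-sites); whether it should apply per replicate is unstated
upstream, and post-merge matches the merge-then-map order of operations.

## 3. P-site offsets

For read length $L$, the offset is estimated as the mode of
$\text{cds\_start} - \text{read 5′ end}$ over start-proximal reads,
restricted to the plausible window $[9, L-9]$; a tie on the mode breaks
toward the value closest to the fallback. Lengths with fewer than
`min_support = 50` candidate reads use the fallback of 12 nt (the canonical
eukaryotic 5′-to-P-site distance). This is the global, start-anchored core
of offset estimation; per-length refinement passes used by full
implementations are deliberately simplified away and the simplification is
the reason `min_support` and `fallback` are exposed rather than fixed.

The estimator's identifiability rests on initiation enrichment: reads with
the start codon in the P-site yield the candidate equal to the true offset,
while reads one codon downstream yield offset − 3, also inside the
plausible window. With no initiation peak the two candidates are equally
frequent in expectation and the mode is a coin flip. Real libraries have a
strong initiation peak, so the footprint simulator models one
(`start_peak`, default 5× dwell on the start codon); with it, exact
recovery of length-specific offsets at ≥ 1000 reads/length is a property
the acceptance suite verifies. Setting `start_peak = 1` produces the
strictly uniform-dwell world used for null calibration.

Frame is recorded but not forced: an out-of-frame P-site still bins into
its containing codon by floor division, and per-length frame fractions are
emitted as QC.

## 4. Site occupancy

Observed counts: codons at the requested site (E/P/A) over *all* reads on
*all* transcripts with reads — deliberately no coverage filter, unlike
pause scoring. Expected frequencies: codon composition of the CDSs of those
same transcripts. Choices that were genuinely open:

* **Weighting.** Whether the expectation should weight each transcript's
  codons by its read count is unsettled; both modes are implemented
  (`unweighted` default, `read-weighted` optional) and labeled, neither
  asserted as the original analysis's choice.
* **Stops.** Stop codons are excluded from both observed and expected by
  default (A-site dwell on a stop is termination, not decoding);
  `include_stops` reverses this.
* **Edges.** First and last CDS codons are excluded from observed and
  expected by default to keep initiation/termination out of the elongation
  statistic; configurable.
* **Degenerate ratios.** Expected 0 with observed > 0 yields a flagged
  `Inf`, never an error.

Group summaries (Arg, Gln by default) are read-weighted means of member
codon ratios.

## 5. Synthetic footprints: what the generator states

The generator is a first-class module, and its defaults are the stated
world of the tests:

* per-transcript read counts Poisson with mean ∝ abundance (the simplest
  model consistent with the pause score's Poisson framing);
* P-site codon drawn ∝ per-codon dwell weights (61 sense codons, mean 1),
  times injected fold elevations; an `"A"` mode applies dwell to the A-site
  codon instead, to exercise the occupancy analyses' site resolution;
* read length uniform on 26–34 nt, offsets 12 nt at all lengths unless
  told otherwise; reads are placed exactly, so frame is pure by
  construction and recovered counts can be compared to truth *exactly*;
* reads never truncate at transcript ends — invalid placements are
  resampled; UTRs default to 50 nt so edge codons stay mappable;
* `start_peak = 5` initiation enrichment (section 3), switched off for
  uniform-dwell nulls.

For the occupancy null calibration, abundances are set proportional to CDS
length (equal expected reads per codon everywhere), which makes observed
site-codon counts exactly multinomial against the composition expectation;
with equal per-transcript abundances, shorter transcripts carry higher
per-codon rates and the comparison inherits extra variance that is
generator mismatch, not analysis error.

What the generator does **not** emulate — hence what a green test does not
establish: sequencing error, adapters, rRNA contamination, non-uniform
ligation bias, multimapping, or spliced genome-space alignment. It
validates the analysis arithmetic and its statistical calibration, not
robustness to upstream artifacts.

## 6. Quantitative proteomics model

The enrichment workflow is fixed in order: QC flag filter → log2 +
validity filter (≥ `min_valid = 2` quantified replicates in at least one
group) → per-sample imputation from
$\mathcal{N}(\bar{x}_j - 1.8\,s_j,\ (0.3\,s_j)^2)$ → per-protein two-sided
Student's $t$. Reordering imputation before the validity filter changes
results and is not expressible through these interfaces.

* Width 0.3 and downshift 1.8 (in units of the sample SD) are the
  established defaults for left-censored LFQ imputation and are the
  package defaults; both are parameters.
* Imputation is per sample (column); a whole-matrix mode exists for sparse
  columns. A column with fewer than two observed values is a hard error —
  its SD is undefined and silently guessing one would manufacture data.
* Equal-variance Student's *t* matches the described workflow; Welch is a
  flag. No multiple-testing correction by default; Benjamini–Hochberg is a
  flag. Zero variance in both groups with equal means returns $t = 0$,
  $p = 1$, flagged.
* Proteins quantified in only one group survive filtering, and imputation
  fills the other group: this is precisely the mechanism by which
  presence/absence interactors become significant, and the synthetic
  presence/absence scenario states a full-intensity bait signal over an
  undetectable control (an IP of a true complex member is orders of
  magnitude enrichment, not a subtle fold change).

The quant generator draws per-protein baselines
$\mathcal{N}(25, 2^2)$ on the log2 scale (typical LFQ range), replicate
noise $\sigma = 0.3$, and missingness by a logistic
missing-not-at-random model in the *true* intensity — non-increasing in
intensity, the regime downshifted imputation presumes. Null calibration
(uniform p-values, type-I error at nominal level) is run with dropout off,
because the t-test's calibration is a property of the test, not of the
imputation; recovery scenarios turn dropout on.

## 7. Determinism

One global seed fans out deterministically to per-stage seeds
(`fan_seed`), every stochastic function takes an explicit seed, and
`run_pipeline()` writes a manifest with parameters and per-file MD5
checksums but no timestamps — identical configuration, identical bytes.
This is tested end to end.

## 8. Known limitations

* Transcript-space, forward-strand alignments only; no spliced genome
  alignment handling, no per-transcript offsets, no 3′-anchored offset
  mode.
* The pause score's fixed threshold is a heuristic fold criterion; it is
  calibrated (conservative under the null) but carries no p-value.
* The occupancy analysis is descriptive; no cross-condition test is
  attached to the group fractions, matching its role as a comparison
  surface rather than an inference.
* The enrichment t-test is unmoderated; with 3 vs 3 replicates,
  background proteins with accidentally tiny variance can reach small
  p-values, which is why rankings — not a significance cut — are the
  reported output, and the choice of cut is left to the user.
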