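---
title: "Methods: differential acetylation at SINEs, B-box scanning and factory colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential acetylation at SINEs, B-box scanning and factory colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sineac)
```

`sineac` reimplements, as a tested and reusable pipeline, the chain of
bespoke computations needed to connect three observations about
activity-dependent transcription in neurons: histone H3K9K14
acetylation changes at short interspersed elements (SINEs) near
inducible genes, TFIIIC recognition (B-box) motifs inside those
elements, and the relocation of gene loci to RNA polymerase II
transcription factories. Every stage can be exercised on seeded
synthetic data with known ground truth, so the statistical behaviour of
the whole chain is testable without any external download.

## 1. Differential acetylation scan

Two ChIP-seq tag libraries (condition A and control B) are reduced to
deduplicated 5' mapping positions: reads below mapping quality 10 are
discarded, and at most one tag is kept per (chromosome, position,
strand) so that every retained tag derives from an independent
molecule. The deduplication key includes the strand — the weaker of the
two defensible readings of "one mapping per position" — because two
reads at the same base on opposite strands cannot be clonal copies of
each other.

Windows of $w = 2000$ bp slide at a stride of $s = 500$ bp. The stride
is a package choice: region widths quantized near 0.5 kbp are
consistent with it, and it is exposed in `scan_windows()` and the
configuration. For a window containing $k_A$ and $k_B$ tags, the null
hypothesis of no differential enrichment makes

$$k_A \mid n \sim \mathrm{Binomial}\!\left(n,\; p_0\right),
\qquad n = k_A + k_B,\quad p_0 = \frac{N_A}{N_A + N_B},$$

with $N_A, N_B$ the total library sizes. Both one-sided tails are
computed, each including the observed count:
$p_\mathrm{inc} = P(X \ge k_A)$ and $p_\mathrm{dec} = P(X \le k_A)$.
Windows with a tail below $\alpha = 10^{-3}$ (strict) are significant;
overlapping-or-abutting significant windows of the same direction merge
into differential regions whose `peak_score` is the maximum
$-\log_{10} p$ over members. Scores are computed in log space
(`pbinom(..., log.p = TRUE)`), so extreme windows never collapse to
`-log10(0)`. A chromosome's final partial window is emitted truncated
and flagged, and excluded from region calling; windows with $n = 0$ can
never be significant and are skipped by the FDR accounting.

### False discovery rate

The estimator is one of several defensible choices and is documented as
such: for every tested window the exact probability mass of the
discrete critical region,
$P_{n,p_0}(p_\mathrm{inc} < \alpha \text{ or } p_\mathrm{dec} < \alpha)$,
is accumulated over windows (grouped by $n$), giving the expected
number of false discoveries; dividing by the observed number of calls
and capping at 1 gives the estimate. On null simulations it sits at 1;
on spiked simulations with strong true windows it drops far below.

### Discreteness and calibration

Because the binomial test is discrete, its attainable size is below the
nominal level. Summing the critical-region mass over the Poisson
mixture of window counts at 15 tags/window/library gives an expected
per-direction significant fraction of $0.60\alpha$ at
$\alpha = 10^{-2}$ and $0.51\alpha$ at $10^{-3}$; the either-direction
fraction is the sum of two one-sided sizes ($1.20\alpha$ and
$1.03\alpha$). The calibration tests therefore assert two things: the
per-direction fraction never exceeds $\alpha$ (conservativeness), and
the observed significant fraction agrees with the exact attainable size
within binomial sampling error. Asserting "fraction $\approx \alpha$"
directly would be wrong for a discrete test.

### Detection power at 3x enrichment

A single 2-kb window spiked at 3x over a 15-tag background yields
counts $k_A \sim \mathrm{Pois}(45)$ versus
$k_B \sim \mathrm{Pois}(15)$; summing the binomial tail over this joint
distribution gives an exact detection probability of 0.778 at
$\alpha = 10^{-3}$. Recovery of such spikes therefore plateaus near
78%, not above 90%, and windows that overlap a spike by 1000-1500 bp
carry genuine partial signal that extends recovered region boundaries
by one or two strides about a quarter of the time. The spike-recovery
test states the stronger bounds and is expected to fail them; the
power computation above is the reference for what these study
conditions can actually deliver.

### Changes track

Regions serialize to a browser-loadable wiggle track
(`track type=wiggle_0` with BED-style data lines): height
$-\log_{10} p$ for increases, $+\log_{10} p$ (negative) for decreases,
base 10 chosen to match genome-browser conventions since no base is
forced by the track description. The reader (`read_changes_track()`)
accepts bedGraph, fixedStep and variableStep dialects via
`rtracklayer`, merges same-sign spans and refuses tracks with
overlapping spans of opposite sign.

## 2. Genomic context and density profiles

Gene grouping follows the expression table: induced (NI) means fold
change $\ge 1.24$ (inclusive — "at least") with adjusted $p < 0.05$;
repressed (NR) the reciprocal; constitutively expressed (CE) means
detected in both conditions without qualifying as NI/NR; constitutively
silent (CS) detected in neither. Genes detected in exactly one
condition with no differential call have no defined group and are
labelled `unassigned` with a warning.

Region context is an exclusive three-way classification with TSS
precedence: `tss` if the region overlaps any transcription start site,
else `gene_body`, else `extragenic`; the three counts always partition
the region set.

Repeat-family enrichment counts regions containing at least one element
of a family against a size-matched random background
(`sample_background()`, seeded; optionally constrained to intervals
containing a TSS) and tests the 2x2 table with a two-sided Fisher's
exact test. Frequencies are reported per 1000 regions. The odds ratio
is the sample odds ratio with a Haldane-Anscombe 0.5 correction on zero
cells, so identical sets give exactly 1 (the conditional-MLE estimate
of `fisher.test` degenerates to 0/Inf there).

TSS metaprofiles bin tags in 100-bp bins on strand-oriented
TSS-relative coordinates (downstream positive; minus-strand genes
coordinate-flipped). Bins crossing a chromosome end are masked from the
group average rather than zero-filled. The per-gene promoter statistic
summarized in the box-plot style output is the mean count per 100-bp
bin within [0, +500) — a per-bin mean rather than a sum, documented
here because either is consistent with "tag density".

The acetylated-SINE density profile counts, per gene and per offset $o$
in $\{-100, \dots, +100\}$ kbp at 5-kbp spacing, the de novo acetylated
SINEs (SINE-class elements overlapping a region of increased
acetylation by at least 1 bp) whose midpoint lies within a 50-kbp
window centered on $o$. Midpoint membership avoids double counting an
element across the offsets sharing a boundary; windows are closed at
both edges so an element midpoint exactly on an edge contributes to
both flanking offsets, which is what makes a single element at +30 kbp
span offsets +5 to +55 kbp inclusive. Per offset, group means are
compared (induced vs constitutive by default) with a two-tailed
Mann-Whitney test; `wilcox.test` provides exact enumeration for small
untied samples and the tie-corrected normal approximation otherwise.
Because adjacent offsets share 90% of their window, significance flags
arrive in runs: a single chance excursion can flag several contiguous
null offsets, which is visible in seed-to-seed variability of the
out-of-band flag rate.

## 3. B-box motif scanning

Scores are standard log-odds in bits, $\sum_j \log_2
(p_j(b_j)/q(b_j))$, with `N` scoring zero (background-neutral) and both
strands scanned (reverse-strand hits are scored on the reverse
complement and reported at the forward-strand coordinate of the hit's
left edge). The default hit threshold is 80% of the maximal score.

The published B-box-like position-weight matrix is not redistributable
in numeric form, so the package ships a clearly labelled synthetic
stand-in: the canonical RNA polymerase III B-box internal-promoter
consensus `GTTCGAANNC` centered in 16 columns with uninformative `N`
flanks, pseudocount 0.25. Any measured matrix can be swapped in through
`read_pwm()` (plain-text, one header line plus L rows of A/C/G/T
probabilities). Ordinal categories for tabulating element calls use
four cut points (80/87.5/95/99% of the maximal score), right-closed
upward so an on-edge score takes the higher bin; a perfect consensus
lands in `++++` and scores below the lowest edge are `no call`.

Region-set over-representation reduces each sequence to a binary
"contains a hit" indicator and applies the two-sided Fisher's exact
test to target versus background sets; `split_half()` reproduces a
seeded 50/50 test/validation split of a region set.

## 4. 3D immuno-DNA FISH analysis

Stacks are `[y, x, z]` arrays with anisotropic voxel sizes, default
100 x 100 x 200 nm (0.2-µm confocal z-spacing). The nucleus is
segmented from the DAPI channel by a single global Otsu threshold
(computed on the flattened stack, not per slice), keeping the largest
26-connected component and filling holes per slice; fields with several
nuclei return the largest (single-cell contract — crop upstream).

RNAPII-ser5P "positive" voxels are those inside the nucleus whose
intensity strictly exceeds the nuclear mean plus $k$ standard
deviations, $k = 1$ by default. The SD is the population ($n$) formula,
and the strict `>` at the boundary is deliberate and tested; both
choices are documented because the description of the original rule
fixes neither. The per-cell adaptive threshold absorbs
staining-intensity differences between cells and experiments.

FISH signals are detected as 26-connected components above a
mean + $k$SD threshold on the FISH channel ($k = 2$ by default — the
original tool's rule for this channel is not specified, so this is a
documented stand-in), discarding components under 2 voxels, with
intensity-weighted centroids at physical voxel-center coordinates
$((i - 0.5)\,d)$. The locus-to-factory distance is the minimum
Euclidean distance, under anisotropic scaling, from the centroid to the
center of any positive voxel — in all directions, not only within one
confocal plane — and a locus colocalizes when that distance is at most
225 nm (inclusive), the distance at which the two smallest detectable
objects overlap. The 225-nm rule is a single scalar, not axially
rescaled. Transcription factories are counted as positive-voxel
components of at least 2 voxels; condition comparisons of colocalized
fractions use the two-sided Fisher's exact test. RNA-FISH
ribonucleoparticle analysis reuses the object detector inside a cell
mask and reports per-particle integrated intensities plus the per-cell
total.

Distances are measured to positive-voxel *centers*, so a measured
locus-to-factory distance underestimates the planted center-to-center
distance by up to the supra-threshold radius of a focus; with the
synthetic focus width below (sigma 80/80/110 nm) that bias stays below one
voxel diagonal (245 nm), which is the tolerance the recovery tests use.

## 5. Synthetic study conditions

All generators take one integer seed and are byte-deterministic per
seed (verified by digesting serialized outputs).

* **Tag libraries.** Uniform background at 0.0075 tags/bp/library — a
  mean of 15 tags per 2-kb window, the background the recovery analyses
  specify — with Poisson counts, random strands and clonal-duplicate
  collapse. Spiked intervals multiply the rate by $r$ in library A
  only. The uniform background matches the count-based null; a hotspot
  option is unnecessary for the properties under test.
* **Annotation.** Genes on a 300-kbp pitch (so +/-125-kbp neighborhoods
  never interleave) with random strands; a genome-wide background of
  acetylated SINEs at $6 \times 10^{-6}$/bp (about 0.3 per 50-kbp
  window, a realistic genome-wide density of differentially acetylated
  elements) common to all groups; and a Poisson(2) surplus per induced
  gene placed uniformly in the strand-oriented +20 to +75-kbp band.
  The expression table is generated consistently with the labels, so
  classification round-trips exactly. Band-recovery tallies count
  offsets inside the planted band as "in band" and offsets whose 50-kbp
  window is disjoint from the band as "out of band"; partially
  overlapping boundary offsets carry genuine partial signal and belong
  to neither tally.
* **Sequences.** I.i.d. uniform ACGT with a maximal-scoring consensus
  realization planted at a recorded offset in a designated fraction.
* **Image stacks.** Ellipsoidal nucleus (DAPI 0.75), RNAPII foci as
  anisotropic Gaussians (amplitude 0.7, sigma 80/80/110 nm) at
  grid-jittered voxel centers with a minimum separation chosen so that
  supra-threshold blobs of neighbouring foci can never touch (hence 200
  planted foci are counted exactly), a low nuclear RNAPII baseline
  (0.06), and one FISH spot per requested distance placed at exactly
  that distance from its verified-nearest focus, mutually separated
  from other spots. Gaussian read noise (SD 0.004) is kept below the
  level at which single noise voxels would cross the adaptive mean+1SD
  threshold, because spurious positive voxels would break the
  controlled-distance contract the generator guarantees. The point
  spread is a Gaussian approximation; no Airy model, chromatic shift or
  depth-dependent aberration is simulated, so passing tests demonstrate
  the correctness of the measurement chain, not robustness to every
  optical artifact of real confocal data.

Problem sizes in the shipped tests and acceptance script — $10^4$ null
windows, 50 spikes on a 12-Mb chromosome, 270 genes, 200 sequences, 50
synthetic cells of 48 x 48 x 16 voxels and one 80 x 80 x 30 stack with
200 foci — were chosen as the smallest sizes at which the tested
fractions have tight enough sampling error to be meaningful.

## 6. Known limitations

* The scan assumes libraries differ only by the condition; no
  cross-sample normalization is attempted (the underlying design
  deliberately avoids it), and input/IgG subtraction is out of scope.
* The discrete binomial test is conservative; at low coverage many
  windows cannot reach significance at all.
* The default B-box matrix is a consensus-derived stand-in, not the
  published measured matrix.
* The imaging chain analyses one nucleus per field and measures
  distances to voxel centers; sub-voxel Gaussian spot fitting and
  deconvolution are out of scope.
* Synthetic data are simplified by design: uniform tag background,
  Gaussian PSF, rigid gene spacing. They validate algorithmic
  correctness and statistical calibration, not performance on every
  pathology of real data.
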