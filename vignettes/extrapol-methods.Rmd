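---
title: "Methods: discovering and classifying extragenic Pol II transcription sites"
author: "extrapol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and classifying extragenic Pol II transcription sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide Pol II ChIP-seq in stimulated cells shows substantial
occupancy outside annotated genes. Two biological entities hide in that
signal: transcribed *enhancers* — regulatory elements over which Pol II
elongates, producing unstable nuclear non-coding RNAs — and promoters/TSSs
of unannotated RNA genes. `extrapol` separates them using the canonical
chromatin asymmetry: enhancers are H3K4me1-high/H3K4me3-low over several
kilobases, while active or poised TSSs carry a sharp, locally confined
H3K4me3 peak flanked by H3K4me1. Everything downstream — regulation
classes, CpG and transcription-factor association, conservation, motif
content — is a characterisation of those two classes.

All coordinates are 0-based half-open (BED convention) throughout;
gene-table dialects with other conventions are converted on read. A single
convention end to end removes the classic off-by-one drift between
components.

## Extragenic peak curation

Peak calling proper is expected from a dedicated caller on real data; the
package accepts pre-called intervals through the `peaks` manifest role.
For self-contained runs a minimal caller is included: fixed windows
(default 200 bp, step 50 bp) are tested against a global Poisson rate
(library size / genome length) at p < 10⁻⁵, significant windows merged
(`peak_merge_gap_bp`, default 500 bp — broad, low enhancer domains show
local dips that would otherwise fragment them), and regions shorter than
200 bp dropped. A global background is adequate on the synthetic genome;
on real data, with its copy-number and mappability structure, a local
background model is preferable — that is one reason external callers
remain first-class inputs.

Three filters then produce the extragenic set:

* any overlap with an annotated gene body removes the peak;
* a strand-aware 10 kb flank past each 3′ end removes peaks created by
  Pol II running past termination sites (`flank3_bp`);
* a peak whose gap to the nearest gene 3′ end *transcribing towards it* is
  continuously covered by Pol II signal — no zero-tag window of
  `continuity_gap_bp` (default 500 bp) — is discarded as gene run-on. The
  500 bp window operationalises "visual discontinuity"; it is the smallest
  scale at which a genuine gap is distinguishable from local tag sparsity
  at typical library depths.

Summits are the midpoint of the leftmost plateau of the sliding-window tag
maximum. The window (`summit_smooth_bp`) defaults to 500 bp in the
pipeline: enhancer Pol II is broad and low, and a 50 bp window (the
`find_summit()` function default, appropriate for sharp TSS peaks) merely
finds the highest noise spike within the domain.

## Regulation classes

For a peak with x_ut and x_stim tags and library sizes N_ut, N_stim, the
no-change null says x_stim ~ Binomial(x_ut + x_stim, N_stim/(N_ut +
N_stim)); the two-sided exact test (`binom.test`) gives p. Direction comes
from the library-normalised fold with pseudocount 1. Defaults `fold_min =
2`, `p_max = 1e-3` define *inducible* / *repressed* / *constitutive*. The
rule is anti-symmetric under swapping conditions by construction. The
thresholds are declared configuration, not an attempt to reproduce any
particular published three-way split, whose exact statistical recipe is
not restated here.

## The chromatin-signature classifier

Each peak is represented by H3K4me1 and H3K4me3 tag counts in fifty 100 bp
bins spanning ±2.5 kb around the summit, scaled to tags-per-million and
then to unit sum *per mark*. The signature is the *pattern* — broad
bimodal me1 versus sharp central me3 — not the amplitude, and unit-sum
normalisation makes predictions invariant to sequencing depth (doubling
every tag changes nothing). Two optional scalar amplitude features (log
total tags per mark) exist but are off by default. A mark with no tags in
the window stays all-zero and is flagged; a peak with both marks empty is
never classified.

Training exemplars: the enhancer class uses "informative" p300 peaks —
at least 2.5 kb from any annotated TSS, so the window cannot touch
promoter chromatin; the promoter class uses an equal number of annotated
TSSs sampled uniformly under the run seed. The decision function is a
linear-kernel soft-margin SVM (e1071/libsvm) on the 100 concatenated bins.
A linear kernel keeps the model deterministic and the me1/me3 weight
pattern directly interpretable. The cost parameter defaults to 100:
unit-sum features have per-bin magnitude of order 1/50, and a cost of 1 at
that feature scale lets the margin penalty dominate the loss (observed as
chance-level held-out accuracy); any cost ≳ 5 separates cleanly, and 100
leaves headroom for noisier profiles.

The third class is produced by an abstention band: profiles whose decision
score lies in (−band, +band) are *unpredictable*. The band is the 5th
percentile of the absolute scores of correctly classified training
profiles, with the scores taken **out-of-fold** — each training profile is
scored by the model of the cross-validation split that did not see it.
In-sample scores of a near-separable max-margin fit pile up at ±1 (every
point is at or outside the margin), which makes the in-sample 5th
percentile a knife-edge exactly where noisy test profiles concentrate;
out-of-fold scores estimate the spread that held-out data actually have.
Five-fold cross-validation accuracies (seeded fold assignment) are stored
in the model and reported.

Models serialise to a plain TSV (one weight per feature, bias, band,
metadata) and reload bit-exactly.

## Clustering and downstream statistics

Peaks within `cluster_gap_bp` (default 2 kb; enhancer sub-peaks typically
lie within a kilobase or two of each other) merge into clusters; the
cluster takes the majority regulation label (tie → constitutive) and
majority signature class (tie → unpredictable), and clusters overlapping
protein-coding gene bodies are discarded. Both tie-breaks are stated so
the pipeline is deterministic.

**Randomisation nulls.** Overlap fractions (CpG islands, PU.1 ±500 bp,
ncRNA catalogues) and set-level conservation are compared against
`n_random` (default 1000) sets of length-matched intervals placed
uniformly on the same chromosomes, excluding gene bodies when the query
set is extragenic. Random sets are matched on length and extragenic
placement only — no GC or repeat matching — and the output records this.
Empirical p-values use +1 smoothing, p = (1 + #{null ≥ obs})/(1 +
n_random), which is never exactly zero and is super-uniform under the
null; the test suite verifies self-null uniformity by Kolmogorov–Smirnov
over 200 seeded repetitions for all three null-based statistics.

**Gene association.** Enhancer-type clusters are assigned to the nearest
protein-coding gene at boundary distance strictly below 20 kb (ties: nearer
TSS, then lexicographically smaller id — determinism again). Gene
regulation labels come from the same binomial rule applied to Pol II tags
in TSS ± 500 bp; "Pol II-positive" means at least `gene_polii_min`
(default 20) pooled tags there. Class enrichment among assigned genes is
an exact binomial test of the observed class count against the class
frequency in all Pol II-positive genes; per-class raw p-values are
reported as such, with a Benjamini–Hochberg column added for transparency.
The choice of a binomial rather than hypergeometric form treats
assignments as independent draws; at the observed assignment counts the
difference is negligible.

**Active-transcription evidence.** CAGE clusters overlapping a region
yield the median of consecutive midpoint spacings (regions with one
cluster report "single", none "none") — tight spacing is promoter-like,
dispersed spacing enhancer-like. Distances from clusters to the nearest
Ser5-P Pol II peak use boundary gaps (0 on overlap). RNA-seq support is
≥ 1 nuclear RNA-seq tag in the cluster; the report compares median Pol II
tags-per-million between supported and unsupported clusters as a log10
ratio.

**Conservation.** Per-base profiles around summits average only defined
bases (conservation tracks have gaps; missing is missing, not zero).
Set-level significance uses the mean score over all defined region bases
versus the same length-matched extragenic null, p < 0.01 by default.

## Motif enrichment

Scoring is Clover-style: a window scores the likelihood ratio
∏ p_pwm(base)/p_background(base) (N contributes 1); a sequence scores the
arithmetic mean over all windows on both strands (reverse-complement
scanning, so scores are strand-invariant); a group of sequences scores the
mean of log sequence scores (geometric-mean aggregation). A matrix equal
to the background scores exactly 0 on any group. The full published
statistic averages over sequence subsets as well; the per-sequence
averaging used here keeps the statistic deterministic and checkable
against exhaustive enumeration at test scale, and is labelled
"Clover-style" rather than claimed as an exact reimplementation. The
inner scan is a small compiled (Rcpp) kernel; a pure-R reference
implementation is kept and the two are asserted equal in the tests.

Group-level significance draws `n_draws` null sets of per-target
length-matched fragments from a background pool (two pools mirror the
published design: whole-chromosome sequence cut into 5 kb pieces, and the
5 kb upstream of every coding TSS). Per-region match probabilities
(the heat-table companion) compare the region's score with
mononucleotide-composition-preserving shuffles, counting ties as one half
so a background-equal matrix sits near 0.5. Dinucleotide-preserving
shuffling is deliberately not offered: a correct Eulerian-path shuffler is
out of proportion to its role here, and an approximate one silently
changes the null. JASPAR count matrices are converted to probabilities
with a 0.01 pseudocount per cell (avoids log 0 at zero counts while
shifting a count-100 column by < 10⁻³).

## The synthetic genome

`synthetic_spec()` fixes the study conditions; the defaults describe the
system the pipeline is designed around: 2 chromosomes × 5 Mb, 60
protein-coding genes, 120 enhancers, 40 ncRNA promoters;
constitutive/inducible/repressed fractions 0.20/0.32/0.48 (the reported
composition of extragenic Pol II peaks in stimulated macrophages); mean
enhancer Pol II 60 tags in the low condition with a 4-fold change at
regulated elements, against tag-dense gene bodies (mean 400); H3K4me1 at
enhancers as a two-mode Gaussian mixture (modes ±1 kb, σ 500 bp) with
H3K4me3 at 15% of it, and the inverse at promoters/TSSs (σ 300 bp central
me3, flanking me1); CpG islands at 72% of coding TSSs, 21% of ncRNA
promoters, 0.5% of enhancers; p300 at 80% and PU.1 at 85%/70% of
enhancers/promoters; tight CAGE clusters at promoters, dispersed ones at
enhancers; RNA-seq tags proportional to Pol II occupancy; conservation
0.60 ± 0.08 at element cores over a 0.10 background with 3% of the track
missing; and three NF-kB-like motif instances planted in each inducible
enhancer, alongside ten decoy matrices screened to be insensitive to the
planted motif (an unscreened random matrix sharing a G-run with the
consensus responds to the planted sites themselves and is then not a decoy).

Two generator details matter for correctness of the benchmark itself.
First, sequencing depth is matched between conditions: the condition with
less planted signal mass receives compensating uniform background tags
(bulk transcription unchanged by stimulation), because the regulation test
works on library-normalised counts and an unbalanced depth would silently
rescale every planted fold. Second, tag counts are Poisson around the
planted means and every element is recoverable from the emitted files
alone; a truth table (coordinates, class, regulation, CpG flag, planted
motifs) accompanies each dataset.

What the generator does **not** emulate: mappability and repeat structure,
duplicate-read artefacts, copy-number variation, non-uniform fragment-size
effects, realistic base composition (the genome is uniform random), or
correlated replicate structure (one library per condition, as in the
motivating datasets). Passing the recovery benchmarks therefore
demonstrates that the statistical machinery is implemented correctly under
its own assumptions, not that those assumptions survive contact with real
chromatin — the usual caveat for simulation-validated pipelines.

## Problem sizes and runtime

The default end-to-end run (10 Mb genome, ~160 elements, 1000-set nulls,
eleven matrices × three enhancer groups × two backgrounds at 199 draws)
completes in well under a minute on one CPU; the full test suite, which
additionally runs 200-repetition null calibrations and several hundred
brute-force oracle comparisons, takes about two minutes. Null-set counts
in the examples are chosen so the minimal attainable p-value (1/(n+1))
sits below the significance thresholds being tested.

## Known limitations

* The global-background Poisson caller is for synthetic-scale data;
  real data should come with externally called peaks.
* Signature classification assumes exactly two marks; multi-mark
  extensions would need a different feature layout.
* Empirical p-values are bounded below by 1/(n_random + 1); claims below
  that resolution require raising `n_random`.
* The enhancer/promoter training set is balanced by construction; heavily
  skewed real class priors shift the decision boundary and are not
  recalibrated.
* Motif enrichment inherits the composition sensitivity of
  likelihood-ratio scoring: backgrounds should match the targets'
  large-scale composition, as the two provided pools do only approximately.
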