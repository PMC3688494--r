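---
title: "Methods: detecting and comparing C-to-U editing in organelle amplicon sequencing"
author: "orgedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing C-to-U editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgedit)
library(data.table)
```

## The measurement problem

Plant mitochondrial and chloroplast mRNAs are edited post-transcriptionally by
C-to-U deamination. In cDNA sequencing an edited molecule reads as T where the
genomic template has C, so the *editing extent* of a site — the fraction of
transcripts edited — is estimable as the `T/(C+T)` read-count fraction at that
template position. Deep sequencing of pooled, strand- and transcript-specific
RT-PCR amplicons yields per-site depths of order 10^3–10^4, which makes extents
measurable to a few tenths of a percent — but also means that raw sequencing
and polymerase errors (~10^-4–10^-3 per base) produce T reads at *every* C
site. Separating low-level genuine editing from error is therefore a
statistical problem, and `orgedit` implements a complete treatment: an
empirical error model, a likelihood-ratio site caller, explicit candidate
filters, and a differential-editing framework for mutant and silenced
genotypes of editing factors.

## Read preprocessing and pileups

Reads are cleaned the way amplicon Illumina data of this design are:
the first 3 (low-quality) bases are trimmed from the 5' end, the 3' tail is
clipped from the first base with quality below Q20, and reads shorter than
60 nt after these operations are discarded (`preprocess_reads()`; the
defaults are the constants just quoted). Alignment records are kept only when
they have a unique top hit, are not secondary, and contain no indels
(`filter_alignments()`); the aligner itself is outside the package — plain
SAM is consumed.

`build_pileup()` records, for every covered template position, each aligned
base together with its *position on the processed read as sequenced*. Two
conventions matter:

* Only C→T on the transcript strand is editing. Reads aligned to the reverse
  strand (rare under a strand-specific protocol) are counted after
  complementing into template orientation — SAM already stores SEQ that way —
  while their read positions are mapped back to the sequenced 5' index, since
  sequencing error depends on the machine cycle, not the template.
* `N` bases are recorded but excluded from all counts and likelihoods.

## The empirical error model

`estimate_mismatch_rates()` estimates `P_i(o|r)`, the probability of observing
base `o` at read position `i` over a template base `r`, from the alignments of
a library — either to spike-in control templates or to the full template set.
Because genuine editing inflates the apparent C→T rate, obvious editing sites
are masked first; `auto_mask()` formalizes "obvious" as a pooled T fraction
≥ 0.02 across libraries. The threshold is deliberately aggressive: residual
low-level editing left in the estimate only inflates the C→T error rate and
thus makes site calls *more* conservative, which is the safe direction.

Two numerical choices are not forced by the data and are documented here as
package decisions:

* **Pseudocount.** Each off-diagonal count receives +0.5 (the diagonal takes
  the complementary mass), so `P_i(o|r) = (n_i(o|r) + 0.5·[o≠r]) / (N_i(r) + 1.5)`.
  A rate of exactly 0 would make the likelihood-ratio test degenerate.
* **Stratum floor.** A per-position stratum is trusted only with ≥ 1000
  observations of its reference base; sparser strata (and positions beyond
  the table) fall back to the position-marginal pooled rate. This trades a
  little positional resolution for variance control.

## The likelihood-ratio site caller

At a template C with editing fraction θ, each read is edited with probability
θ, and the error channel applies either way, so an observation of base `o` at
read position `i` has probability

    (1 − θ) · P_i(o|C) + θ · P_i(o|T).

`call_editing_site()` maximizes the column log-likelihood over θ ∈ [0, 1]
(Brent's method, absolute tolerance 1e-8 — deterministic), forms the statistic
`LRT = 2(L(θ̂) − L(0))`, and converts it to a p-value with the χ²(1 df) upper
tail. Because θ = 0 lies on the boundary of the parameter space, the exact
null is the mixture `0.5·χ²₀ + 0.5·χ²₁`; using plain χ²₁ instead doubles
p-values, i.e. the caller is deliberately conservative (about half the nominal
type-I error in our calibration simulations, slightly less at typical depths
because the T count is discrete). Per-observation mixture likelihoods — rather
than a collapsed binomial on C/T counts alone — let non-C/T observations
contribute through their own channel probabilities, although with
position-uniform rates the two formulations coincide; this functional form is
the package's own reconstruction of the published test's description.

Candidate sites across an experiment must pass three filters
(`select_candidates()`, strict inequalities): p < 1e-6 in at least one
library, editing fraction > 0.05 in at least one library, and mean depth
across all libraries > 100.

## Differential editing

For a mutant versus its wild-type sibling (and a silenced plant versus its
controls), biological replicates are pooled by summing C and T counts, and
each site is tested with the plain Pearson chi-square on the 2×2 table —
no continuity correction, matching the statistic's printed definition. The
familywise error rate is held at 1e-3 by Bonferroni division across the
analyzed sites of the organelle partition (619 mitochondrial sites → nominal
1.6e-6; 37 plastid sites → 2.7e-5).

The effect metric is the relative drop of editing extent,
`ΔEE = (wt − mut)/wt`: a site poorly edited in the wild type can still show a
near-complete loss in the mutant (e.g. extent 0.04 → 0.005 is ΔEE = 0.875), which
an absolute difference would miss. The classification rule is applied
verbatim: not significant → independent; significant and ΔEE < 0.1 →
independent; significant and ΔEE ≥ 0.1 → dependent. Editing *increases*
(negative ΔEE) are reported but never classified dependent. Sites with zero
wild-type extent, or with a degenerate 2×2 marginal, are excluded with a
reason code rather than silently dropped.

Silenced genotypes use a dual-control design: the site must show the
significant reduction against *both* the uninoculated control and the
GFP-silenced (vector-only) control, and sites where the GFP control itself is
reduced versus the uninoculated plants are excluded from the silenced-analysis
universe. Reported extents and ΔEE anchor on the uninoculated control — the
published account does not say which control anchors the reported numbers, and
this choice follows the thresholds' reference to the uninoculated comparison.
The Bonferroni denominator is the number of sites actually supplied to a
comparison, so the silenced universe (after GFP exclusions) yields its own
nominal threshold.

## Overlap between editing factors

`classification_matrix()` collects per-factor dependent/independent/excluded
labels; sites excluded for any factor of a comparison are dropped listwise for
that comparison. `venn_counts()` partitions the analyzed sites over up to
three factors' dependent sets, `overlap_percentage()` reports round-half-up
integer percentages (the reporting style of the source tables), and
`factor_independence_test()` applies the same 2×2 chi-square to the joint
dependent/independent table, returning observed and expected-under-independence
cells so that an excess of doubly-controlled sites is directly visible.

## Cis-element similarity

Editing specificity factors recognize a cis element of roughly 30 nt, mostly
upstream of the target C. `extract_window()` takes the −20..+5 window around a
site (truncated and flagged at template edges), and `best_identity_match()`
scans a query window against known-site windows. Similarity in the source
analysis was assessed by eye with ad-hoc gaps, which no fixed algorithm can
reproduce; the package therefore *formalizes* the criterion as a local
alignment scored match +1 / mismatch −1 / gap −2, reporting as "identity" the
number of identical aligned positions, maximized over score-optimal alignments
(this tie-break makes the count well-defined). Hits require ≥ 10 identical
nucleotides by default. Windows are compared in transcript orientation only,
because editing cis elements are strand-specific.

## The simulator and what it does (not) emulate

`simulate_truth_set()` / `simulate_reads()` generate random templates,
editing sites placed only on Cs with configurable true θ, and pre-aligned
strand-specific reads with per-read-position substitution errors; reads are
emitted as FASTA + FASTQ + truth SAM so no external aligner is needed.
Defaults mirror the study conditions: processed read length 97 (100 nt minus
the 5' trim), per-site depth 5500 (the reported mean per editing site when
pooling 24 libraries), per-pair substitution rates 1e-3 (PCR/RT-PCR-like;
plasmid-spike-like runs use 1e-4), and flat, mid-dip, or end-peak coverage
shapes after the depth profiles amplicon fragmentation produces.
`simulate_pileup()` is a count-level fast path that draws the sufficient
statistics directly (all observations of a site share one read position,
cycling across sites) — exact for position-uniform channels and used for the
large calibration runs; `simulate_error_pileup()` generates the error-only
alignments used for rate estimation.

The simulator draws editing events independently per read, applies
independent per-base errors, and uses constant base qualities. Real data add
polymerase context effects, quality degradation along the read, linked edits
on the same molecule, and PCR duplicates — none of which are emulated.
Passing the closed-loop tests therefore shows the statistics are implemented
correctly and calibrated under the stated model, not that the model captures
every artifact of real libraries.

## Problem sizes used in the checks

The shipped tests and the acceptance script run, among others: null
calibration on 1e5 simulated sites at depth 5500 and error 1e-3; recovery of
θ ∈ {0.05, 0.1, 0.5, 0.9} over 400 sites at depth 5500; candidate selection
on 50 edited plus 5000 null sites at depth 2000; mismatch-rate recovery over
1e7 observations; oracle agreement on 1000 random 2×2 tables and ~200 random
window pairs; and a read-level end-to-end pipeline run on two 400-nt templates
with four libraries. These sizes were chosen as the smallest at which the
binomial error bars make the assertions sharp.

## Known limitations

* The error model conditions on read position only — not on quality scores,
  sequence context, or strand — matching the published description.
* The χ²₁ boundary convention is conservative by about a factor of two at the
  p-values where calls are made; users wanting exact calibration can halve
  p-values, at the cost of departing from the reference behavior.
* Plain SAM only; no paired-end-specific logic; indel-containing alignments
  are discarded rather than realigned.
* The cis-similarity identity is a reproducible formalization of a visual
  criterion, and its site counts are not expected to match hand-curated ones.
* U-to-C editing and non-organellar editing are out of scope.
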