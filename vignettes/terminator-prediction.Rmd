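---
title: "Predicting Rho-dependent transcription terminators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Rho-dependent transcription terminators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoterm)
```

## The biological model

Bacteria terminate transcription by two routes. Intrinsic terminators are
GC-rich RNA hairpins followed by a uridine run that destabilise the
elongation complex on their own. Rho-dependent terminators instead rely on
Rho, a hexameric RNA/DNA helicase. Rho loads on a *Rho utilization* (RUT)
site — an unstructured, ribosome-free stretch of roughly 70–80 nt of
nascent RNA that is cytosine-rich, guanine-poor, and carries regularly
spaced C residues — then translocates 5'→3' until it catches RNA
polymerase dwelling at a pause site, where it dissociates the complex.

`rhoterm` operationalises this picture as a two-step sequence scan:

1. **RUT site.** A 78-nt window slides one nucleotide at a time until its
   C/G ratio exceeds 1 *and* its cytosines are regularly spaced. From
   that seed, a 128-nt block (78 + 50 nt of slack) is examined and the
   qualifying 78-nt window with the maximal C/G ratio becomes the RUT
   site.
2. **Pause site.** The 150 nt downstream of the RUT 3' end are searched
   for stem-loop hairpins (perfect Watson–Crick stem of ≥ 4 bp, loop of
   4–8 nt, GC-rich stem) and for the 12-nt pause consensus element
   G₋₁₁G₋₁₀(C/T)₋₁G₊₁. A candidate with neither feature is discarded.

Each retained prediction receives a score between 6 and 15: 3 base points
for each mandatory element, plus exclusive tiers of +1/+2/+3 for C/G
ratios above 1.25/1.5/2, +1/+2 for stem GC above genome GC + 10/+ 20,
independent half points for a loop shorter than 6 nt and a stem longer
than 4 bp, and +3 when a consensus element lies within the hairpin span
extended by 5 nt on each side. All threshold comparisons are strict, so a
C/G ratio of exactly 1.25 earns nothing. The maximum 15 = 3 + 3 + 3 + 2 +
0.5 + 0.5 + 3 is attainable only if the two half points are independent,
which fixes that reading of the schedule.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| window length | 78 nt | RUT extent; matches the footprint of the Rho hexamer's primary RNA-binding surface |
| refinement block | 128 nt | 78 + 50 nt of slack to maximise C/G locally |
| C/G threshold | > 1 | the scalar reading of "C > G content" |
| max C gap | ≤ 13 nt | boundary-inclusive spacing bound (see below) |
| pause region | 150 nt | downstream search space for the pause site |
| stem / loop | ≥ 4 bp / 4–8 nt | hairpin geometry; stem pairs are strict Watson–Crick |
| GC-rich stem | ≥ genome GC% | entry requirement; bonuses at +10 / +20 above genome GC |
| proximity margin | 5 nt | consensus-near-hairpin window for the +3 bonus |

### Cytosine spacing: upper bound, with the band as a switch

"Regularly spaced cytosines (every 11–13 nt)" is operationalised as a
*boundary-inclusive maximum gap of 13 nt*: the distances from the window
start to the first C, between consecutive Cs, and from the last C to the
window end must all be ≤ 13. This enforces cytosines distributed across
the entire window (at least 6 of them) while accepting denser spacing,
because additional cytosines can only favour Rho loading. The strict band
reading — consecutive gaps must also be ≥ 11 nt — is available via
`spacing_band = TRUE` in the scanning functions, but is not the default:
it rejects windows that are unambiguously C-over-G rich merely for having
*extra* cytosines, which has no biological rationale.

### Degenerate compositions

A window with cytosines but no guanine at all has C/G = ∞ and qualifies
(its C content strictly exceeds its G content); a window with neither C
nor G reports a ratio of 0 and never qualifies. `N` counts as neither C
nor G, never pairs in a stem, and never matches the consensus element.

## Determinism, tie-breaks, resumption

The scanner contains no randomness. Ties in the refinement block
(several qualifying windows with the same maximal ratio, e.g. several
all-C, no-G windows) resolve to the smallest start, favouring the
earliest Rho loading point. Among hairpins, the one maximising the final
prediction score wins (its stem-GC tier, half points and consensus
proximity); ties again resolve to the smallest start. After a successful
prediction, scanning resumes immediately after the RUT 3' end, which
permits densely packed adjacent terminators; after a discarded candidate
(no pause site) it resumes one position past the seed so that no sequence
is skipped. Near the sequence end the pause region is truncated, never
wrapped: circular genomes are not modelled.

Minus-strand scanning reverse-complements the record, runs the identical
forward procedure, and maps coordinates back, so minus-strand output is
by construction the exact mirror of a plus-strand scan of the reverse
complement — a property the test suite checks exactly.

## Coordinates

The R API uses 1-based inclusive coordinates throughout, the convention
of the Bioconductor ranges infrastructure and of GFF3; the TSV report is
likewise 1-based inclusive. BED output is converted to the standard
0-based half-open convention on export, and bedGraph input is converted
on import. Interval lengths are preserved by both conversions.

## The hairpin model is combinatorial, not thermodynamic

Stems are perfect Watson–Crick pairings (A·T, G·C): no G·U/G·T wobble, no
bulges, and no free-energy minimisation. The structural requirement in
the underlying model is purely combinatorial, and a thermodynamic folder
would predict different (often larger, bulged) structures that the
scoring schedule has no vocabulary for. For each loop position and loop
length only the maximal stem is reported; inner truncations of the same
stem are suppressed to keep candidate lists non-redundant. Note that the
same physical inverted repeat can still surface once per compatible loop
length (e.g. a stem-5/loop-4 repeat also admits a stem-4/loop-6 reading);
the pause-site selector resolves these through the score-then-position
tie-break.

## The evaluation protocol

`build_positive_set()` extracts the 300 nt immediately upstream
(strand-aware) of regions known to harbour a terminator at their 5'
boundary. `build_negative_set()` collects intergenic gaps of 200–300 nt
between *divergently oriented* (head-to-head, −/+) coding sequences: the
only configuration in which the gap is downstream of neither gene's 3'
end, so no terminator is expected. `evaluate_balanced()` subsamples the
larger set to the smaller set's size, without replacement, `n_repeats`
times under a caller-supplied seed; each positive sequence contributes at
most one true positive regardless of how many predictions it contains.
Precision, recall, specificity, accuracy and F1 are computed per repeat
and averaged; mean counts are reported alongside. Averaging per repeat
rather than deriving metrics from mean counts is a deliberate choice —
the two differ only in rounding, and the per-repeat average is the one
that treats each repeat as an experiment.

`validate_with_coverage()` implements the expression-aware read-gradient
rule: a prediction is considered only when coverage at its RUT 5'-end
point is ≥ 10 reads (otherwise a silent region would masquerade as a
false positive), and is validated when that value is ≥ 1.5-fold the
coverage 150 nt past the RUT 3' end. A zero downstream value with an
expressed upstream is the strongest possible gradient and validates.
`overlap_count()` counts intervals of one predictor within 50 nt
(edge-to-edge) of another's, each counted once.

## What the synthetic generator emulates — and what it does not

`generate_genome()` plants RUT + gap + hairpin constructs, on random
strands, into an i.i.d. background of tunable GC, separated by ≥ 300 nt;
`generate_coverage()` lays a piecewise-constant track at the expressed
level with a multiplicative step-down after each planted pause site
(window sized to contain the validator's downstream measurement point but
never the next element), plus optional zero-truncated Gaussian noise. The
defaults — GC-40% background, C/G ratio 2, cytosines every 12 nt, a
perfect 6-bp/4-nt hairpin 20 nt downstream — describe strong, clearly
detectable signals.

These fixtures exercise every decision threshold in the scanner and
validator, which is their job. They do **not** model real genomes: no
codon structure, no compositional skew, no transcription units, no read
noise model beyond the additive Gaussian. Consequently, passing the
planted-recovery tests demonstrates that the implementation detects the
motif it defines, not that the motif captures all real Rho-dependent
terminators. One property of real backgrounds carries over clearly: the
motif is permissive, and random or genomic sequence of ordinary GC
content yields a substantial density of predictions (the test suite
tracks this false-positive density on background-only genomes as a
stability regression across seeds). On balanced benchmarks with *random*
negatives this density caps precision well below what curated genomic
negative sets (AT-rich divergent intergenic regions) give; the package
therefore treats random-negative F1 as a determinism regression, not as
a performance claim.

## Problem sizes used in the checks

The shipped checks run entirely on generated data: 20 synthetic genomes
of 20 kb (5 planted terminators each) for recovery and coverage
validation, 1000 scans of 320-nt sequences for the per-prediction RUT
invariants, 100 random 1-kb sequences for the brute-force oracle
equivalence of seeding and refinement, 60 random 150-mers for the
detector oracles, and 50 random 600-mers for exact strand symmetry.
These sizes were chosen to exercise each guarantee at meaningful
multiplicity while keeping the default check quick on a laptop.

## Known limitations

* Scores are ordinal, not calibrated probabilities; no threshold
  optimisation is attempted.
* Whole-genome prediction totals depend mildly on the resumption policy
  (after the RUT 3' end on success, seed + 1 on discard) and on whether
  overlapping same-strand predictions are deduplicated downstream; the
  package emits them all and leaves deduplication to the caller.
* No circular-genome wraparound; elements spanning the origin are
  missed.
* The comparison-predictor overlap analysis consumes interval files; the
  package does not run any intrinsic-terminator predictor itself.
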