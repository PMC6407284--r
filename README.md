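# rhoterm

Prediction of Rho-dependent transcription terminators in bacterial
genomes, with the evaluation protocol to measure how well the predictions
hold up against annotation and RNA-seq coverage.

## The problem

Rho-dependent termination accounts for a large share of transcription
stops in bacteria, yet it is much harder to predict than intrinsic
(hairpin + U-run) termination because the signal is diffuse: Rho loads on
a **RUT site** — roughly 78 nt of unstructured, C-rich/G-poor RNA with
regularly spaced cytosines — and then releases the polymerase at a
downstream **pause site**, either an RNA hairpin or the pause consensus
element G₋₁₁G₋₁₀(C/T)₋₁G₊₁. `rhoterm` is for microbial genomicists who
want genome-wide candidate lists of such terminators, with scores,
standard-format output (TSV/BED6/GFF3), and the tooling to evaluate the
candidates against coverage data.

## The method

Two deterministic steps per strand:

1. **RUT search.** Slide a 78-nt window one nt at a time until
   C/G > 1 and the boundary-inclusive maximum cytosine gap is ≤ 13 nt;
   within the following 128-nt block pick the qualifying window with
   maximal C/G (ties → earliest).
2. **Pause search.** In the 150 nt downstream of the RUT 3′ end, find
   hairpins (perfect Watson–Crick stem ≥ 4 bp, loop 4–8 nt, stem
   GC ≥ genome GC) and consensus elements; keep the configuration that
   maximises the score, discard the candidate if neither feature exists.

Scores span [6, 15]: 3 + 3 base points, +1/+2/+3 for C/G > 1.25/1.5/2
(exclusive tiers), +1/+2 for stem GC > genome GC + 10/+20, +0.5 each for
loop < 6 nt and stem > 4 bp, +3 for a consensus element within the
hairpin span ± 5 nt. All comparisons strict.

The evaluation module reproduces the standard protocol: 300-nt upstream
positives, 200–300-nt divergent-intergenic negatives, balanced repeated
subsampling (one TP per sequence at most) with precision / recall /
specificity / accuracy / F1, RNA-seq validation via a ≥ 1.5-fold coverage
drop across the terminator (upstream coverage ≥ 10 reads), and 50-nt
overlap counting against another predictor's intervals. A seeded
synthetic-genome generator (planted RUTs, hairpins, coverage step-downs
with truth tables) makes the whole package testable offline.

## Worked example

```r
library(rhoterm)
g <- generate_genome(fixture_spec(seed = 42, length = 6000L, n_terminators = 2L))
g$record
#> <genome_record> synthetic: 6000 nt, GC% = 39.70
pred <- scan_genome(g$record, min_score = 9)
pred
#> <rhoterm_predictions> 28 prediction(s)
#>    record_id strand rut_start rut_end cg_ratio        pause_type pause_start
#> 1  synthetic      -        46     123    2.200 hairpin+consensus           7
#> 2  synthetic      -       136     213    2.000 hairpin+consensus           7
#> 3  synthetic      +       855     932    1.917           hairpin        1028
#> ...
```

Each row is one candidate: the 78-nt RUT interval (1-based inclusive,
forward coordinates), its C/G ratio, the pause-site type and span, and
the score. The two planted terminators are recovered (e.g. row 2 with
C/G 2.000 and a proximal consensus scoring 13); the remaining rows are
the background hits expected at this GC content — scores grade them.
`write_predictions(pred, "out", c("tsv", "bed", "gff3"))` exports the
table; a thin CLI wraps the same functions:

```sh
rhoterm scan --fasta genome.fasta --out pred --bed --gff
rhoterm validate --fasta genome.fasta --predictions pred.tsv --coverage cov.wig --out validated.tsv
rhoterm overlap --a other.bed --b pred.bed --window 50
```

Feeding the reference balanced-test confusion counts through the metric
formulas:

```r
m <- metrics_from_counts(tp = 128, fn = 67, fp = 46, tn = 149)
#> precision 73.6%, recall 65.6%, specificity 76.4%, accuracy 71.0%, F1 0.69
```

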