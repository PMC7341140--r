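---
title: "Models and conventions behind ddGBStools"
author: "ddGBStools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind ddGBStools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddGBStools)
```

# Scope

ddGBStools implements the bespoke computational stages of a double-digest
genotyping-by-sequencing (ddGBS) workflow: in silico digestion and library
design, in-line-barcode demultiplexing, and post-genotyping quality
control. Read alignment, genotype-likelihood models and imputation are the
territory of dedicated external tools and are deliberately out of scope;
this package produces the quantities needed *before* sequencing (which
enzymes, which size window, how many reads) and *after* genotyping (which
sites and samples to trust).

# In silico digestion

## Coordinates

All digestion arithmetic is done in 0-based half-open coordinates. A *cut
coordinate* is a between-base index on the top strand: a plus-strand
recognition site starting at `s` for an enzyme with cut offset `c` cuts at
`s + c`, and a fragment boundary at `k` splits a sequence into `[0, k)` and
`[k, len)`. Overhangs affect fragment end *labels* (and hence ligatability)
but not fragment lengths: length bookkeeping uses top-strand cut positions
only, which is the convention of standard restriction-mapping tools and is
strand-symmetric for the palindromic enzymes in the shipped catalog.
Fragments returned to the user ride in a `GRanges` (1-based, closed), with
the conversion confined to that boundary; BED output converts back to
0-based half-open.

## N handling and ambiguity codes

Recognition sites never match across an `N`: an assembly gap cannot be cut.
Fragments *containing* Ns still count toward the digested total, because
the denominator of a capture fraction is the full genome length. IUPAC
ambiguity codes in a recognition sequence are honoured (each code matches
its base set); non-palindromic enzymes are scanned on both strands with
minus-strand cuts mirrored to top-strand coordinates. A coordinate cut
identically by both enzymes of a double digest is labelled `AMBIGUOUS` —
the overhang that would remain is undeterminable, so such fragments are
excluded from the amplifiable class. These events are vanishingly rare in
real genomes but are handled deterministically.

## End classes and capture

Each fragment's class derives from its two end labels: `PP` (both ends cut
by the primary enzyme), `PS` (one primary, one secondary), `SS` (both
secondary), `END` (touching a sequence terminus) and `AMBIGUOUS`. Standard
ddGBS adapter/primer chemistry amplifies only `PS` fragments, so the
default qualifying class for capture accounting is `PS`; single-enzyme
designs use `PP`.

Size selection operates on library molecules (insert + adapters + primers),
so windows are specified on the library scale and converted with an
`adapterOffset` (default 125 bp, the combined length of a typical
barcode-adapter/Y-adapter/primer set). A fragment is captured when its
length falls inclusively within the insert-scale window. The capture
fraction divides captured bp by total digested bp; multi-sequence genomes
are pooled, and whether unplaced scaffolds are included is the caller's
choice of input sequences, not a hidden default.

## Coverage budgeting

Reduced representation concentrates each sample's reads onto the captured
fraction `f` of the genome, giving the expected fold coverage
`R L / (f G)`. The model assumes uniform amplification and mapping; PCR
bias, gel-migration shifts and read pile-up in repeats make real coverage
overdispersed, so the output should be read as a budgeting estimate, not a
guarantee. The inverse `readsNeeded()` answers the multiplexing question
("how many samples per lane at a target depth").

## Enzyme selection

`rankSecondaryEnzymes()` applies the conventional hard criteria for a
secondary enzyme — 4 bp unambiguous recognition sequence, buffer
compatibility with the primary digest, 37 °C incubation, sticky ends
(adapters cannot be ligated selectively to blunt ends, which random shear
also produces), and no methylation sensitivity (a methylation-sensitive
digest would restrict capture to an epigenotype-dependent subset) — then
ranks the survivors by capture fraction. Criteria are flags, not dogma:
each can be relaxed per call.

# Demultiplexing

Reads have the layout `[barcode][cut-site residual][insert]`. Assignment
minimises the Hamming distance between each barcode and the read prefix of
that barcode's length, with at most one mismatch by default; among
equal-distance candidates the longer barcode wins (a deterministic,
conservative rule for variable-length barcode sets), and remaining ties are
discarded as ambiguous. The residual (default `TGCAG`, the PstI site minus
the first base) must match exactly: it certifies that the molecule really
is a cut-and-ligated ddGBS fragment, and tolerating mismatches there would
admit chimeras. Barcode tables are validated at load against the
ambiguity in which a short barcode plus the residual's leading bases spells
out a longer barcode. Emitted reads are barcode-trimmed with the residual
retained, matching what downstream aligner-facing trimmers expect to
remove.

Quality trimming implements the running-sum 3' rule used by the standard
trimmers: walking in from the 3' end, the cumulative sum of
`threshold − quality` is tracked, the read is cut before the suffix
maximising that sum (the longest such suffix when several tie), and reads
shorter than 25 bp after trimming are dropped. The per-sample threshold of
two million assigned reads (inclusive) reflects the empirical missingness
cliff below that depth; both thresholds are arguments, not constants.

# Genotype QC

## Trio Mendelian errors

`mendelCheckTrio()` classifies each offspring/sire/dam genotype triple at
an autosomal biallelic site against the full 27-configuration transmission
table (any missing member is uninformative). X-chromosome trio logic is
deliberately not implemented.

The expected fraction of trios able to reveal an error at minor allele
frequency $p$ is modelled as

$$f(p) = 1 - (1 - 2p(1-p))^3,$$

the probability that at least one of three *independent* Hardy–Weinberg
genotypes is heterozygous ($f(0)=0$, $f(0.5)=0.875$, monotone between).
Treating trio members as independent is an approximation: under true
Mendelian transmission the three genotypes are correlated and the
probability of observing a heterozygote in the trio differs from $f(p)$
except at $p = 0.5$, where both equal 0.875. The package therefore reports
$f(\hat p)$ as a model reference curve next to the *observed* informative
fraction rather than using it as a denominator. Operationally, a trio-site
is counted informative when all three members are called and either some
member is heterozygous or the configuration itself is a Mendelian error
(the second clause keeps the invariant errors ≤ informative; all-homozygous
error configurations such as hom-alt offspring of two hom-ref parents are
errors a het-only definition would miss). Site error rates divide errors by
informative trios; per-sample totals attribute each trio error to the
offspring, the member whose genotype is constrained.

Removal thresholds follow the conventional printed values — site error
rate strictly above 0.005, sample error count strictly above 10× the
per-sample mean — with `suggestSiteThreshold()` available as an advisory
data-driven alternative: the sorted per-site error-rate curve is averaged
in fixed-width rank bins (50 by default), the bend is located at the
maximum discrete second difference, and the threshold is placed midway
between the bend bin and the next, i.e. inside the gap separating the
clean mass from the outlier tail. The estimator is reported, never applied
automatically.

## Sex inference

The X-chromosome read fraction (X-mapped / total mapped) separates sexes
cleanly in mammals because males carry one X: samples strictly above the
3 % threshold are called female, others male. Samples with zero mapped
reads are flagged undefined rather than erroring, and recorded-sex
mismatches are flagged for follow-up (swaps, contamination, mislabelled
pedigree entries).

## Concordance

Callsets are matched on (chrom, pos). Identical ref/alt pairs are compared
directly; swapped pairs have the second callset's codes flipped 0 ↔ 2.
A/T and C/G sites that would need a swap are excluded and counted instead:
for those alleles a swap is indistinguishable from a strand flip, and
within-platform data sharing one reference strand should never need it.
Discordance is computed per genotype call (not per allele), over jointly
non-missing calls only, and is reported overall, per sample, per site, and
as a site-count curve over a discordance-threshold grid.

## Hardy–Weinberg exact test

The two-sided exact test conditions on the observed allele counts and
enumerates the heterozygote-count distribution with the standard
recurrence; the p-value sums all outcomes no more probable than the
observed one. Probabilities are compared with a relative tolerance of
1e-7 so that exact ties (symmetric distributions) are included
consistently under floating-point arithmetic; mid-p variants are not used,
matching the conventional implementations behind hard HWE filters.
Monomorphic sites give p = 1.

## Site filtering

`filterSites()` applies known-site membership, biallelic-SNV shape,
minimum called individuals (2), MAF (< 0.005 removed — a site exactly at
the threshold survives), call rate (< 0.90 removed) and HWE (p < 1e-10
removed), in that fixed order, attributing each removed site to the first
rule it fails. The fixed order is what makes per-rule removal counts
reproducible and comparable across runs.

# The simulators

The fixture generators exist to make every claim above testable with known
ground truth, and their defaults mirror the study conditions the package
is built around: 500 trios × 2,000 sites with a uniform MAF spectrum on
[0.05, 0.5] and a 1 % planted error rate for the Mendel scanner; 96-sample
cohorts with female/male X-fraction means of 5 %/1 % (sd 0.002) straddling
the 3 % threshold; 200 bp planted inserts inside a 250–400 bp library
window; reads of `barcode + TGCAG + insert` at constant Q40.

`makeGenome()` interleaves motif-free background (rejection-sampled
against every involved recognition site and its reverse complement) with
planted cassettes whose two cut sites delimit an insert of exactly the
requested length. Cassette orientation alternates so fragments *between*
cassettes are PP or SS, never PS — the planted fragments are therefore
exactly the PS fragments of the digest and capture fractions are exact by
construction (spacers of ≥ 500 bp keep everything else out of realistic
windows). Junction-spanning accidental sites are repaired by point
mutation and verified. This construction intentionally does not emulate
repeat structure, GC heterogeneity, assembly gaps, PCR duplicates or
realistic error profiles: a passing test certifies the *accounting*, not
robustness to genomic complexity.

`simulateTrioGenotypes()` draws parents from Hardy–Weinberg proportions,
transmits one allele per parent, and plants errors only among informative
trio-sites, always as a genuine rule violation (for het × het parent
pairs, where any offspring is consistent, the sire is set hom-ref and the
offspring hom-alt). Every planted perturbation is thus detectable and the
truth table is exhaustive, which the tests exploit by requiring *exact*
recovery of the planted error count.

All generators take a `seed` and restore the caller's RNG state; identical
arguments and seed give byte-identical output.

# Numerical and scale choices

Test and acceptance problem sizes (100 random 1–10 kb oracle digests,
100 kb planted genomes, 500 × 2,000 trio matrices, exhaustive HWE
enumeration to n = 25) were chosen so the full suite exercises every code
path in about a minute on a laptop-class core while keeping binomial
standard errors small enough for 3-SE recovery checks to be meaningful.
The rn6-scale digest benchmark is the exception: it needs the 2.87 Gb
assembly on disk and roughly an hour, so it runs only when the FASTA is
supplied (`options(ddgbs.rn6 = ...)` or `scratch/rn6.fa`).

# Known limitations

* Coverage is a uniform-sampling expectation; no attempt is made to model
  PCR amplification bias, size-selector migration shifts or repeat
  pile-up.
* Demultiplexing is single-end, single-barcode; combinatorial dual
  barcodes and error-correcting barcode design are out of scope.
* Mendelian checks are autosomal only; sex-chromosome transmission logic
  is not implemented.
* Concordance harmonisation is limited to ref/alt swaps; cross-platform
  strand flips are excluded rather than resolved.
* The informative-trio model is an independence approximation, exact only
  at MAF 0.5 (see above); it is reported as a reference curve, not used as
  a test statistic.
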