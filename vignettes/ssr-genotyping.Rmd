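---
title: "Genotyping perfect microsatellites from spanning reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping perfect microsatellites from spanning reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpoly)
```

## The model

A perfect microsatellite is an uninterrupted head-to-tail tandem of a 1–6 nt
motif. Its allele is the number of whole repeat units, and alleles differ
between genotypes because unit counts mutate rapidly. `ssrpoly` estimates
the allele(s) present in each genotype from the subset of aligned reads that
measure the run unambiguously, then compares genotypes.

The central measurement rule is geometric. A read of length $L$ can report
the length of a run of a $k$-nt motif only when the run *and* a phase-breaking
flank on each side lie inside the read. We require one full motif of flank
per side, so the longest measurable run is

$$\mathrm{maxlen}(L, k) = L - 2k \quad\text{nt},\qquad
  \mathrm{maxunits}(L, k) = \left\lfloor \frac{L - 2k}{k} \right\rfloor,$$

e.g. 96 nt of dinucleotide repeat (48 units) or 14 hexanucleotide units for
$L = 100$. Reads failing the rule fall into two classes that the package
tallies separately: *partial span* (the alignment does not cover the whole
reference interval of the locus) and *border uncertainty* (the repeat run in
the read touches a read edge, or has less than the required flank, so the
allele could extend beyond what is visible). The loose reading "one or more
flank bases" is available via `filter_params(flank_len = 1)`; the default of
one motif per side is what makes the filter consistent with the
detectability arithmetic above.

Two further filters remove alignment artefacts before counting:

* **multi-mapped reads** — secondary/supplementary records always; under the
  default `"tag"` policy also reads whose hit-count tag exceeds 1 or whose
  secondary alignment score (`XS`) reaches the primary score (`AS`), i.e.
  another placement is as good as the reported one. For aligners without
  such tags, `multimap_policy = "mapq"` with a MAPQ cutoff is the fallback.
* **mate pairs at one locus** — overlapping mates that agree are one
  molecule and are collapsed to a single observation (counting both would
  double-weight it); overlapping mates that disagree are internally
  inconsistent and both are dropped; mates that do not overlap each other
  yet both claim the same run indicate a misalignment and both are dropped.
  Only the last rule is forced by first principles; the deduplication of
  concordant overlapping mates is this package's choice, made so that read
  support approximates molecule support.

Counting is done **in read space**: after projecting the locus interval
through the CIGAR onto read coordinates (`project_ref_interval()`), the
maximal tandem run of any rotation of the motif covering the interval
midpoint is measured in the read sequence itself
(`count_repeat_units()`). The reference is only used to anchor the locus;
a read carrying a two-unit insertion reports two units more than the
reference, whatever the aligner did with the indel placement. This matters
in practice: the modal read-space count can legitimately disagree with the
unit count annotated on a consensus reference.

## Allele calling

Per locus and genotype the accepted reads form a histogram of unit counts.
Two inclusive thresholds govern the call:

* $t$ (`min_reads`, default 10): with fewer than $t$ spanning reads the
  locus is `insufficient_coverage` — reported as `NA`, never dropped.
* $p$ (`min_percent`, default 30): every unit count supported by at least
  $p\%$ of the spanning reads is an allele. One qualifying count is a
  homozygote, two a heterozygote, three or more a multi-allelic (polyploid)
  call; lowering $p$ (e.g. to 25 for a triploid) admits more alleles, and
  raising it is monotone — it can only remove alleles.

The denominator of $p$ is the total spanning-read count at the locus, not
the top-two-allele total. Two degenerate rules are fixed deliberately: when
$p > 50$ no bin may qualify, and the major allele is still reported (a
covered locus should never yield an empty call; the default parameters
never reach this branch); ties for the major allele break toward the larger
unit count, deterministically. Allele strings list alleles by support,
major first ("`6; 5`").

Across genotypes, a locus is `polymorphic` when at least two genotypes are
called and their allele *sets* differ, `monomorphic` when they all agree,
and `not_comparable` otherwise (fewer than two genotypes called). The join
is an in-memory full outer join on the locus key over all catalog loci.
Compound ("c"-type) catalog entries are carried through uncalled so output
row counts match the input catalog; they are not genotyped because a
compound repeat has no single unit count.

## What the simulator emulates — and what it does not

`simulate_reference()` plants perfect runs inside rejection-sampled random
background: the bases adjacent to each run are drawn to break the repeat
phase, and a candidate background is accepted only when detection recovers
exactly the planted catalog, so no accidental repeat shadows a locus.
`simulate_genotype_reads()` then draws error-free or noisy reads from
haplotypes (the reference with each run replaced by the allele's run),
encoding the length difference as a single insertion/deletion left-aligned
at the run's left edge — the SAM convention for repeat indels; because
counting is read-space, indel placement does not affect calls.

Two sampling modes are provided. *Tiling* mode emits one read per start
position and assigns haplotypes by a largest-deficit cycle over the allele
fractions, so every contiguous window of positions realises the planted
fractions to within one read; this is stratified sampling, chosen so that
exact-recovery experiments (e.g. a 65/35 heterozygote against the 30%
threshold) measure the filter and the caller rather than sampling noise.
*Random* mode draws start positions uniformly and haplotypes multinomially
at a chosen fold coverage, which is what the noisy-recovery experiments
use. The error model is substitution-only.

The simulator deliberately does **not** model PCR stutter (unit-slippage
products), quality-score profiles, platform-specific error spectra,
alignment errors, or reference mis-assembly. Passing the simulation-based
tests therefore shows that the selection/counting/calling chain is correct
on reads whose only defects are substitutions; on real data, stutter —
especially at homopolymers — and alignment quality around long runs remain
the dominant error sources, and residual miscalls of that kind are expected.

## Numerical and design choices

* Coordinates: MISA-like tables are 1-based inclusive
  (`end - start + 1 = length`); all internal interval arithmetic is 0-based
  half-open with conversion at the I/O boundary, avoiding off-by-one drift
  against SAM.
* Detection reports each maximal run once, anchored at its left edge with
  the motif read verbatim from that phase, and only at its shortest period
  (an `(AT)8` run is never also `(ATAT)4`); runs break at `N`; annotated
  intervals contain whole units only.
* A run's *extent* for flanking purposes includes partial-unit bases that
  continue the period, so the bases immediately beyond the extent break the
  phase by construction; a run whose extent touches the read edge is
  border-uncertain.
* Reads whose CIGAR places a reference skip (`N`) across a locus are
  rejected as partial span; internal deletions are allowed (they encode
  shorter alleles) and project to zero read bases.
* The anchor for read-space counting is the midpoint of the projected
  interval, which stays inside the run for both insertion and deletion
  alleles of any size the spanning filter can accept.
* Degenerate inputs: an empty alignment file yields an empty table (not an
  error); an empty histogram is `insufficient_coverage` with zero reads; a
  catalog sequence missing from the alignment header is an error naming the
  sequence.

## Problem sizes used in the packaged experiments

The test suite validates detection, projection and counting against
brute-force oracles on sequences up to 100 nt (hundreds of randomized
cases under fixed seeds), and runs the full pipeline on simulated
genotypes: six loci covering motif lengths 1–6 with homozygous, 50/50 and
65/35 heterozygous and 34/33/33 triploid designs under tiling coverage,
plus noisy runs at 0.5% per-base error and 50× coverage. These sizes give
per-locus spanning depths of 40–90 reads, comfortably above the default
$t = 10$, and complete in well under a minute each; they are study-scale
choices, not limits of the method.

## Known limitations

* Only perfect repeats are genotyped; imperfect and compound SSRs are
  carried through uncalled.
* Allele lengths are reported in repeat units, not amplicon base pairs;
  converting to fragment sizes needs primer coordinates, which are out of
  scope.
* No stutter correction: at homopolymer loci with real data, the modal
  allele is usually right but minor stutter bins can inflate heterozygote
  calls at permissive `p`.
* One alignment file per genotype is assumed; pooled or barcoded BAMs must
  be split upstream.
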