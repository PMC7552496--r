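---
title: "Calling methylation haplotype blocks: model, choices and validation"
author: "asmphaser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling methylation haplotype blocks: model, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmphaser)
```

## The model

Bisulfite sequencing reads report the methylation state of every cytosine
they cover: an unconverted C is methylated (M), a converted C (read as T)
is unmethylated (U). When the two alleles of a locus are differentially
methylated, a read covering two nearby cytosines tends to show the *same
allele pattern at both* — either the methylated-allele pattern or the
unmethylated-allele pattern — so the per-read joint distribution over the
four state combinations (MM, MU, UM, UU) concentrates on two complementary
cells. That co-segregation is the phase signal this package exploits. The
same reads carry the alleles of heterozygous SNPs, so SNPs falling inside
or near a methylation block are phased onto the same two haplotypes for
free, and Hi-C-derived phased blocks can then stitch distant blocks
together.

The procedure, per chromosome and bisulfite strand (the two strands carry
independent cytosines and are processed separately throughout):

1. **Effective sites.** Per-cytosine M/U tallies are computed and sites
   that are essentially fully methylated (level > `meth_high`, default
   0.9) or fully unmethylated (level < `meth_low`, default 0.1) are
   removed — a site at level 0 or 1 is identical on both alleles and
   carries no phase information. A minimum coverage (`min_cov`, default 4
   reads) is required. Heterozygous SNP sites get the analogous
   *effective-SNP* filter: both alleles must actually be observed, with
   minor-allele fraction at least `meth_low` and coverage at least
   `min_cov`. This matters because bisulfite conversion destroys one
   allele of some SNP classes (a C allele on the original-top strand reads
   as T; a G allele on the original-bottom strand reads as A): such a
   half-callable site can never link or be phased, and without the filter
   it would only sever the chain it sits in.
2. **Pair test.** For each consecutive pair of effective sites sharing at
   least `min_cov` reads, the 2x2 co-occurrence table over the co-covering
   reads is tested with a two-sided Fisher exact test (minimum-likelihood
   rule, computed by direct hypergeometric enumeration). All pairs of the
   run — cytosine–cytosine, cytosine–SNP and SNP–SNP, across all
   chromosomes and strands, including the non-adjacent cytosine-by-SNP
   pairs used for phasing votes — form a single Benjamini–Hochberg family.
   A genome-wide family is the one coherent multiple-testing universe for
   a genome-wide scan; it is also why votes are counted up front rather
   than after block construction, which would make the family depend on
   its own test outcomes.
3. **Classification.** A tested pair is an ASM pair when (i) its adjusted
   p-value is below `fdr` (default 0.05), (ii) the two largest cells
   together exceed `top2_frac` (default 90%) of the covering reads, and
   (iii) the ratio of the largest to the second-largest cell is below
   `max_ratio` (default 2). The inequalities are strict, so ties at the
   printed thresholds fail. A second-largest cell of zero is treated as
   ratio +Inf and fails criterion (iii): a table where only one
   combination occurs is a fully concordant, non-heterozygous pattern, not
   evidence for two alleles.
4. **Chaining.** Accepted pairs are chained greedily left to right; a
   rejected, under-covered or orientation-ambiguous pair closes the open
   block. Orientation comes from the dominant diagonal
   (`n11 + n22` versus `n12 + n21`); a tie between the diagonals carries
   no orientation and also closes the block. Blocks need at least two
   member sites; the ASMR output table lists blocks with at least two
   member cytosines, since its columns are defined over cytosines.
5. **Phasing.** Within a block, haplotype A is anchored at the first
   member site as the haplotype carrying the lexicographically smaller
   status there (M for a cytosine, the reference allele for a SNP) — a
   deterministic labelling that needs no external truth. Each SNP with
   accepted pairs against member cytosines receives one vote per pair for
   the allele riding on haplotype A; the majority wins and ties stay
   unphased. A SNP chained only through another SNP (no cytosine votes)
   keeps the phase propagated along the chain.
6. **Hi-C merging.** Phase vectors from WGBS blocks and Hi-C blocks are
   compared over shared SNPs: per SNP the score is +k on agreement, -k on
   disagreement, 0 when either phase is missing, and the HapScore is the
   absolute score sum. A WGBS/Hi-C pair with at least `min_shared`
   (default 2) shared SNPs merges when the HapScore exceeds
   `min_score_frac * k * n_shared` (default fraction 0.9); the sign of the
   sum orients the Hi-C block. Since the threshold is a fraction of
   `k * n_shared`, `k` cancels; it is retained (default 1) for fidelity to
   the score definition. Links close transitively via union-find with
   orientation parity, so one Hi-C block can chain several WGBS blocks; a
   parity conflict (a block required to both flip and not flip along two
   paths) aborts that component's merge rather than breaking the tie
   arbitrarily. On a SNP phased by both sources the WGBS assignment wins:
   it is read-local evidence, while the Hi-C phase has passed through an
   upstream phaser.

## Numerical and degenerate-input choices

* The exact test sums hypergeometric point probabilities no larger than
  the observed table's, with a relative tolerance of 1e-7 guarding ties
  broken only by floating-point rounding (the same guard `fisher.test`
  uses). A table with an all-zero row or column admits a single
  configuration and returns p = 1. A zero-total table has no p-value and
  is an error (or, for a conversion-confounded SNP pair, a signaled
  zero-total table).
* BH adjustment is delegated to `stats::p.adjust`; the test suite checks
  it against a hand-written step-up oracle.
* Merging is deterministic and independent of input block order: blocks
  and components are processed in (chromosome, start) order.

## Input conventions

Coordinates are 1-based inclusive everywhere. Bisulfite strand is taken
from the aligner's `XG` tag when present (`CT` = original top, `GA` =
original bottom, the Bismark convention); otherwise it is inferred for a
directional library from FLAG orientation (single-end/first mate: forward
= "+", reverse = "-"; second mate: the opposite of its own orientation).
Overlapping mates are counted once per position, first mate winning on
conflict. The cytosine context default is CpG only — that is where
mammalian ASM signal lives — with CHG/CHH/all selectable for plant-style
analyses.

## What the simulator emulates — and what it does not

`make_truth()` plants non-overlapping ASM regions (default 10 regions of
2 kb in a 100 kb genome) with CpGs at controlled spacing (default 25 bp,
well under the 100 bp read length, so adjacent planted sites always share
reads), heterozygous SNPs with known phase (half inside regions), and a
background of ordinary CpGs. Methylation is modelled at the *site* level:
each region CpG's state per allele is drawn once (Bernoulli 0.95 on the
methylated allele, 0.05 on the other), and reads copy the state exactly,
corrupted only by the conversion-failure and sequencing-error rates. With
both rates at zero the data are genuinely noiseless, which is what makes
exact recovery a meaningful test. Background CpGs share a common state
across alleles (methylated with probability 0.7, the typical mammalian
methylome), except for a 10% fraction fluctuating at per-read level 0.5 on
both alleles — these pass the effective-site filter and exercise the
rejection path and the FDR family.

`simulate_bisulfite()` tiles each strand with fragment starts on a regular
lattice and emits one fragment per allele per start, so both alleles are
observed at equal, near-deterministic depth (`depth` is therefore *per
allele per strand*). This is deliberate: the generator's purpose is
validating the algorithm against exact planted truth, and coverage
fluctuation or allele-sampling noise is a property of data, not of the
method under test. Real data differ in exactly these ways — random
fragment starts, allele imbalance, overdispersion, PCR duplicates,
mapping errors, platform-specific error profiles — so passing these tests
shows algorithmic correctness, not expected performance on a given
library. Reads are emitted already aligned (alignment is out of scope,
and deterministic placement keeps the truth exact).

`simulate_hic()` plants phased blocks as connected components of drawn
within-allele SNP pairs, each block's phase equal to truth up to a random
global flip, with configurable per-SNP error and missing rates. It stands
in for an external Hi-C phasing workflow; it does not model contact
matrices or distance-dependent ligation frequencies.

Evaluation conditions on the *testable* planted set: a planted pair
counts toward recall only when both its sites pass the effective-site
filter and the connecting pairs meet the coverage floor — a pair the test
never saw cannot count against the classifier. The realized (not the
nominal) per-site allele states define the truth, since a region CpG
whose two alleles happened to draw the same state is not
allele-informative.

## Validation problem sizes

The test suite and the acceptance script validate at three scales, chosen
to exercise every code path while keeping a full run comfortable on a
laptop: a 20 kb / 3-region / depth-10 simulation for fast integration
tests; the 100 kb / 10-region / 50-SNP / depth-20 noiseless reference
condition for exact-recovery checks (recall, precision and region
recovery all 1.0, switch error 0); and five replicate 30 kb / 4-region /
depth-30 simulations with conversion-failure 0.01 and sequencing-error
0.001 for the noisy condition (recall and precision at or above 0.95).
The exact-test implementation is checked against an integer-arithmetic
enumeration oracle on every 2x2 table with total up to 20.

## Known limitations

* Only consecutive effective-site pairs are tested for chaining (plus
  cytosine-by-SNP pairs for phasing); co-covered but non-adjacent
  cytosine pairs are not used as additional links.
* Single-site ASM (allele inference without a linkable neighbour) is out
  of scope, as are differential methylation between samples, indel
  phasing and population-based phasing.
* The two strands are never merged: a region supported on both strands
  yields two blocks, one per strand (they can be joined downstream
  through shared SNPs by the Hi-C merge machinery).
* The phased fraction is bounded by read length: only SNPs within a read
  length of an effective cytosine can be phased from WGBS alone — which
  is precisely the motivation for the Hi-C merge step.
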