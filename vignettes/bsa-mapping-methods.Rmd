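---
title: "Mapping a recessive locus from pooled allele depths: models and design"
author: "bsamapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus from pooled allele depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

# The problem

A monogenic recessive trait segregating in a biparental F2 population can
be mapped cheaply by bulked segregant analysis with sequencing (BSA-seq):
pool DNA from the two phenotypic extremes, sequence each pool, and scan
the genome for positions where the pools' allele frequencies diverge. At
a locus unlinked to the trait both bulks are random draws from the F2 and
carry the two parental alleles at frequency 1/2 each. At the causal locus
the recessive bulk is fixed for the causal allele, while the dominant
bulk carries it at frequency 1/3 (its members are a 1:2 mixture of
homozygous and heterozygous individuals). The package implements the full
desk-side analysis around this signal: segregation testing, SNP-index
mapping, marker-based fine mapping, coding-indel effect prediction and
relative expression — together with a seeded generator producing
synthetic data with exactly the statistical structure the analysis
assumes.

# The SNP index and its null distribution

For one bulk at one biallelic SNP with `ref`/`alt` read depths, the SNP
index is `alt / (ref + alt)`: 0 when every read matches the reference
genome, 1 when the bulk is fixed for the alternate allele. The delta SNP
index is the dominant-bulk (L) index minus the recessive-bulk (S) index.
With the short-parent allele polarized as the alternate, the expectation
at the causal locus is `1/3 - 1 = -2/3`; far from it, 0.

Windows of 1 Mb advancing in 10 kb steps (the defaults) average the
member SNP indices per pool; the window statistic is the unweighted mean
(a depth-weighted mean is available behind `weighted = TRUE`, but with
roughly uniform Poisson depths the two are nearly identical). Windows are
anchored at position 1 and are half-open, `[start, start + 1 Mb)`.

Significance comes from a two-stage binomial null, simulated rather than
asymptotic:

1. each pool's alternate-allele count is drawn
   `Binomial(2 * bulkSize, 1/2)` — the bulk is a random sample of F2
   individuals under no linkage;
2. the pool's alternate-read count is drawn `Binomial(depth, k / (2 *
   bulkSize))` — reads sample the pooled chromosomes.

The difference of the two pools' indices is tabulated for 10,000
replicates per read depth, and the empirical 2.5%/97.5% (and 0.5%/99.5%)
quantiles give the per-depth confidence bounds. A window's bound is
looked up at the tabulated depth nearest its mean per-SNP total depth.
Both stages matter: read sampling alone understates the variance because
the bulk's composition itself fluctuates (variance `1/(8 * bulkSize)` on
the allele frequency).

Candidate regions are maximal runs of at least `minConsecutive = 3`
consecutive windows whose delta exceeds the bound with a consistent sign;
the run's extreme-|delta| window is reported as the peak. Three
consecutive windows 10 kb apart share almost all their SNPs, so this
suppresses single-window noise without costing real peaks, which span
hundreds of windows under 1 Mb smoothing.

# The synthetic F2 generator

The generator is first-class, tested code, not a fixture. Its default
design reproduces the study conditions the analysis is meant for:

* three chromosomes of 30 Mb and 1.2 Morgans each, SNPs every 50 kb, a
  recessive causal locus at chr3:15,000,000 — a desk-scale stand-in for a
  cucurbit-sized genome that keeps runtimes in seconds while leaving two
  full chromosomes unlinked as negative controls;
* F2 individuals built from two independent gametes; per chromosome the
  crossover count is Poisson(genetic length) with breakpoints uniform on
  the physical length (Haldane's model, no interference) — the simplest
  standard meiosis model, adequate because the analysis never exploits
  interference;
* phenotype strictly recessive at the causal locus, no phenocopies;
* bulks of 30 long and 30 short individuals (the first of each phenotype,
  so bulk membership carries no hidden randomness beyond the population
  seed), depths Poisson(30) per pool per SNP, alternate reads binomial in
  the pool's true allele frequency;
* the long parent is written as the reference allele, so the causal peak
  is negative; polarization is a convention, not an assumption.

What the generator does **not** emulate: sequencing error, alignment
artefacts, reference bias, variable marker informativeness, segregation
distortion, and phenotyping error. Passing the recovery tests therefore
shows the statistical machinery is correct under the stated model — not
that any particular real dataset will behave as cleanly.

All randomness flows from a single integer seed; pipeline stages derive
their seeds by fixed offsets from it, so `runPipeline()` is reproducible
file for file.

# SNP filtering

The depth-and-index filter (`filterSnps`) retains SNPs with total depth
of at least 7 in both pools and a maximum per-pool index of at least 0.3.
Low-depth SNPs carry indices too noisy to average; SNPs where neither
bulk shows the alternate allele appreciably are typically
reference-genome artefacts rather than segregating sites. Both thresholds
follow common QTL-seq practice and are plain arguments; removal counts
per rule are kept in the result's metadata.

# Fine mapping from recombinants

Genotype codes are `A` (homozygous dominant parent), `H`, `B` (homozygous
recessive parent). Under the recessive model a short-phenotype individual
must be `B` at the causal position and a long one must not. A marker
contradicted by an individual is therefore separated from the causal
locus by a crossover in that individual.

`narrowInterval` distinguishes two situations:

* some marker is consistent with every individual — the interval runs
  from the nearest contradicted marker on the left of the consistent
  block to the nearest on the right (outermost markers when a side has no
  contradiction);
* no marker is fully consistent, i.e. the causal locus sits strictly
  between two markers with recombinants on both sides. The interval is
  then the adjacent marker pair contradicted by the fewest distinct
  individuals. Violator counts grow with distance from the causal locus,
  so the true gap minimizes this; requiring the two flanks' violator sets
  to be exactly disjoint was considered and rejected because occasional
  double crossovers make shared violators legitimate.

If even the best adjacent pair is contradicted by more than a quarter of
the individuals, the trait is declared unlinked: a linked locus can only
be contradicted by gap recombinants (a few percent), while an unlinked
trait contradicts every marker in roughly 3/8 of individuals.

Interval length is reported as `end - start` (no `+1`): the causal locus
lies strictly between the flanking marker positions, and this convention
reproduces published flanking-coordinate arithmetic exactly. Individuals
missing a genotype at a decision marker are excluded there, never
imputed; violations are attributed to recombination, never to phenotyping
error (no error-tolerance parameter in this version).

CAPS assays are digested in silico on the forward strand only (CAPS
enzymes typically have palindromic sites); all occurrences of the
recognition sequence are cut on the uncut coordinate frame, and a marker
is polymorphic when the parents' fragment-length multisets differ.

# Coding-effect prediction

Deletions are specified 1-based inclusive on the CDS, so a span of
502–514 removes 13 bases; a deleted length not divisible by 3 is a
frameshift. Proteins are translated with the standard genetic code from
position 1, stopping before the first stop codon; a domain is lost when
its last residue exceeds the mutant protein length, with a partial flag
when the domain starts before the truncation point. Ambiguity codes are
rejected rather than guessed. The CDS fixture generator engineers, by
rejection sampling over downstream codons (capped at 10,000 iterations),
a reference/mutant pair whose frameshifted stop lands exactly at a
requested residue count — by default 173 residues after a 13 bp deletion
at position 502, with one annotated domain upstream of the truncation
(retained) and one downstream (lost), mimicking the
DIOX_N / 2OG-FeII_Oxy layout of a GA 3beta-hydroxylase.

# Relative expression

`relativeExpression` implements the Livak 2^-ddCt estimator: replicate
Ct values are averaged on the cycle scale per gene, ΔCt is target minus
reference, ΔΔCt subtracts the calibrator sample, and the fold change is
2^-ΔΔCt with the amplification efficiency fixed at 2 (the method's
defining assumption; efficiency-corrected models are out of scope). The
calibrator's fold is exactly 1 by construction. Spread is propagated as
`sqrt(sd_target^2 + sd_reference^2)` on the Ct scale and reported as a
fold range. Note the estimator is slightly biased upward under Ct noise
(it is the exponential of a Gaussian); the generator tests account for
this with the lognormal mean rather than pretending the bias away.

# Numerical and testing choices

* Chi-square goodness of fit uses the uncorrected Pearson statistic —
  continuity correction would not reproduce published two-class
  statistics — with the upper-tail p from the chi-square distribution
  function; p-values are validated against numerical tail integrals to
  1e-6.
* Window/CI simulations in the test suite run at the design the package
  defaults encode: populations of 400, 30/30 bulks, 30x depth, 10,000
  null replicates, 40 recovery seeds. At that size the whole recovery
  property runs in a few minutes on one core.
* Null-bound quantiles are empirical (type-7 interpolation) over a
  discrete replicate distribution; inclusive comparisons at the bounds
  keep the realized coverage within a percent of nominal at 30x.
* Internal coordinates are 1-based closed everywhere; the single
  exception is BED output, converted at the boundary (`start - 1`).
* Degenerate inputs: zero-depth SNPs yield a missing index and are
  excluded from window means; windows without SNPs carry missing values;
  empty marker lists produce a phenotype-only table; a CDS shorter than
  one codon translates to an empty protein with a warning.

# Known limitations

The mapping model is strictly biallelic, monogenic and recessive; there
is no support for quantitative traits, dominance at the mapped locus, or
tricube-smoothed statistics. Read alignment and variant calling are
upstream of the package: input is an allele-depth table (TSV or a
two-sample VCF with AD fields). Genome-to-CDS coordinate lifting is not
implemented; deletions are analyzed on the CDS. The unlinked-trait
threshold in `narrowInterval` (a quarter of individuals) is a heuristic
separating two well-separated regimes, not a calibrated test.
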