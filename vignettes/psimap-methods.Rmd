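---
title: "Mapping GWAS variants into primate-specific genomic regions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping GWAS variants into primate-specific genomic regions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`psimap` implements a colocalization analysis between catalogs of
primate-specific genomic information (PSI) and genome-wide association
study (GWAS) results. Nine heterogeneous element classes — human
accelerated regions (HAR), human gained enhancers (HGE), human-biased and
primate-specific cis-regulatory elements (hbCRE, psCRE), de novo mutation
hotspots in neurodevelopmental regulatory elements (DNM), human-specific
insertions (hsInsert), primate-specific transcriptional units (psTU),
human accelerated DNase I hypersensitive sites (haDHS), and hominin-specific
gene regulatory elements (hsGRE) — are merged into non-overlapping *PSI
regions*. Genome-wide significant GWAS variants are then mapped into those
regions by position, collapsed into independent loci through lead-variant
linkage-disequilibrium (LD) blocks, and contrasted with chi-square tests:
disease vs quantitative traits, one focal element type vs the rest, and
regulatory vs non-regulatory regions.

The pipeline is exercised end to end on synthetic data with known ground
truth, because the real element catalogs and summary-statistic sets are not
bundled with the package.

## Region construction

Elements are stored 0-based half-open (the BED convention). Merging takes
the connected components of overlapping intervals per chromosome: two
elements share a region iff a chain of pairwise overlaps of at least one
base links them.

Three boundary decisions matter and are fixed throughout:

* **Abutting intervals are not merged.** Under half-open semantics,
  `[a, b)` and `[b, c)` share no base and therefore remain separate
  regions. The test oracle (a base array with two slots per coordinate)
  honors the same rule.
* **Duplicate intervals are retained.** The same interval contributed by
  two source catalogs yields one region with two constituent elements,
  which is what makes the multi-element region count meaningful.
* **A region is non-regulatory** iff its type set is contained in
  {hsInsert, psTU}, the two classes without direct regulatory evidence.
  Regions mixing a regulatory and a non-regulatory type count as
  regulatory, but the regulatory-contrast table excludes every multi-type
  region anyway (they are a small minority — about 1% in the motivating
  catalog — and their classification would otherwise be arbitrary).

Region summaries report the mean length both to one decimal and truncated
toward zero to an integer, because published summary tables of this kind
truncate (24,708,805 bp over 19,473 regions prints as 1,268 bp, not
1,268.9). Genome coverage is reported against whatever chromosome-sizes
table the user supplies; the package does not assume a particular genome
build's total length.

The chromosome-distribution test is a goodness-of-fit chi-square on region
*counts* per chromosome with expectations proportional to chromosome
length, `E_c = N * L_c / sum(L)`. Counts (rather than covered bp) give a
valid multinomial chi-square; coverage per chromosome is still reported
alongside.

## Significance filtering and mapping

Each trait declares its significance mode. The thresholds are strict, with
the boundary excluded on both scales: `p < 5e-8` and `log10 BF > 6`. A
variant's identity is its id when present, else `chrom:pos`; duplicate
(variant, trait) rows collapse to the most significant with a warning.

Variant positions are 1-based (GWAS convention) and regions 0-based
half-open, so position `p` falls in `[s, e)` iff `s <= p - 1 < e`. Both
boundaries are unit-tested: position `s` is outside, `s + 1` and `e` are
inside, `e + 1` is outside.

A variant mapped into a multi-type region credits *every* type in the
region's type set in the per-type tallies (the alternative — dropping such
events — is available as `multi_type = "exclude"`). Pleiotropy is counted
over distinct mapped variant identities appearing significant and mapped
in two or more traits.

## LD-block loci

Loci come from reported lead variants, not from re-clumping: a significant
variant joins lead L's block iff `r2 > 0.8` (strict; exactly 0.8 joins
nothing). With several qualifying leads the variant joins the highest-r2
lead, ties broken toward the lead at the smaller genomic position. Every
lead belongs to its own block with r2 = 1 by convention. Loci are
trait-specific: the same genomic lead reported for two traits is two loci,
consistent with summing input loci across studies.

Significant variants with no lead above the threshold are reported
separately as *unassigned* and excluded from locus counts. The package
cannot know how such variants were handled in any given source analysis,
so a `singleton = TRUE` switch promotes them to single-variant loci
instead; the default excludes them because loci are defined only through
reported leads.

The locus mapping rate is `100 * mapped loci / input loci` (a locus is
mapped when any member maps); the variant-level rate is
`100 * mapped records / significant records`. Percentages round half away
from zero to one decimal in display fields, with raw ratios retained in
the report JSON, and every displayed percentage is re-derived from its
numerator and denominator at report-build time (an internal consistency
assertion).

## Contingency tests

`chisq_independence()` wraps the standard Pearson test. Continuity
correction defaults ON for 2x2 tables — matching the default behavior of
the statistical environment such analyses are usually run in — with a flag
to disable; both corrected and uncorrected statistics are easy to obtain.
A zero expected cell is an error (the table is degenerate); an expected
cell below 5 is a warning only. P-values keep their raw double value in
machine output and are floored at 2.2e-16 only in display strings.

For the regulatory contrast, the counting unit is *regions* (regions with
at least one mapped variant vs none), matching the figure-caption
formulation of the motivating analysis; a locus-level variant of that
contrast is ambiguous between text and figure in the source and was not
made primary.

## The synthetic generator

`sim_config()` / `end_to_end_fixture()` emit everything the pipeline
reads: chrom.sizes, nine element BEDs, per-trait GWAS TSVs, an LD table, a
YAML manifest and a ground-truth JSON. Everything is a pure function of
the seed; reruns are byte-identical.

Defaults were chosen once to make a desk-scale analogue of the motivating
catalog and are not tuned per test:

* **Genome**: five chromosomes of 2 Mb. Small enough that every stage runs
  in seconds, large enough that regions stay sparse.
* **Elements**: ~600 across the nine types, with per-type counts
  (83, 2, 30, 45, 1, 360, 4, 16, 58) scaled down ~33x from the real
  catalog's (2737, 63, 1000, 1488, 31, 11874, 131, 524, 1919), and
  log-normal lengths (sdlog 0.6, floor 10 bp) whose medians (250–4,200 bp)
  reproduce each type's per-element length scale implied by the catalog's
  per-type share of total region length. The resulting toy coverage
  (~8% of the toy genome) is deliberately denser than the real 0.81%:
  at 10 Mb a realistic density would leave mapping counts too small to
  test against.
* **Placement** is length-proportional across chromosomes by default
  (the null of the chromosome-distribution test); per-type weight vectors
  can make it arbitrarily uneven.
* **Traits**: two quantitative and two disease traits, one disease trait
  scored by log10 Bayes factor so both significance modes are exercised;
  40 loci each, Poisson(3) block members within +/-25 kb of the lead,
  member r2 ~ Uniform(0.81, 1), plus 10% decoy significant variants with
  r2 ~ Uniform(0, 0.8) to the nearest lead. Block half-width and decoy
  rate are arbitrary but exposed in the config.
* **Enrichment**: disease leads land inside a region with probability
  `theta*c / (theta*c + 1 - c)` where `c` is realized coverage, so `theta`
  is exactly the in-region odds multiplier; quantitative leads use
  probability `c`. The default `theta = 2` is a moderate enrichment.
  Enrichment is injected at the lead (locus) level because the headline
  contrast of the motivating analysis is locus-level.
* **Block members of an out-of-region lead are placed outside the
  regions** (rejection sampling, falling back to the lead's own position).
  This makes a locus map iff its lead was placed in-region, so the
  locus-category odds ratio estimates `theta` directly and the generator's
  ground-truth flags round-trip exactly through `map_variants()`. It is a
  simplification: in real data an LD block can straddle an annotation
  boundary, which would attenuate the observed odds ratio relative to the
  generating mechanism.
* r2 values are drawn directly rather than derived from simulated
  genotypes; the pipeline only ever consumes r2 tables, so genotype-level
  simulation would add nothing testable.

What passing tests on this generator do **not** show: robustness to real
summary-statistic dialects (alleles, effect sizes, build mismatches),
realistic LD structure or allele frequencies, or the behavior of the
chi-square approximations at the very small per-cell counts a sparse real
annotation can produce.

## Test and verification scale

Property tests compare the merger against an independent base-array union
oracle (1,000 random fixtures of up to 60 intervals on a 20 kb toy
chromosome) and against `IRanges::reduce()` as a cross-check; mapping is
compared against an all-pairs scan; block assignment against an
argmax-over-leads oracle; chi-square statistics against the textbook 2x2
closed forms with and without Yates correction. Calibration uses 1,000
null replicates (type-I error within the 99% binomial interval around
0.05, correction off, since Yates is deliberately conservative).
Enrichment recovery uses 2,000 loci per category at `theta = 3`
(tolerance +/-20% on the odds ratio); the power check uses 150 loci per
category at `theta = 4` over 200 draws, a size chosen by a two-proportion
power calculation to put rejection power well above 95% before any test
was run. These sizes keep the full suite around a minute on one core.

## Known limitations

* Positional overlap only: no posterior-probability colocalization of
  association signals.
* No liftover; all inputs must share one genome build. Elements are
  unstranded.
* The published headline p-values of the motivating analysis
  (1.6e-5, 9.3e-12, 1.4e-66) are not reproducible because the underlying
  per-cell counts were published only graphically; the package reproduces
  the *structure* of those contrasts and the arithmetic of every printed
  aggregate instead.
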