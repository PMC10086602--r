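# psimap

Colocalization of GWAS variants with primate-specific genomic regions.

## The problem

Genomic changes specific to higher primates — human accelerated regions
(HAR), human-specific insertions (hsInsert), primate-specific regulatory
elements and half a dozen further classes, collectively *primate-specific
genomic information* (PSI) — are candidate substrates for human-specific
regulation of complex traits. The catalogs describing them are
heterogeneous: different studies, counts from dozens to tens of thousands,
element lengths from tens of bases to multi-kilobase insertions. `psimap`
is for researchers who want to ask, reproducibly: *once these catalogs are
unified into non-overlapping regions, do genome-wide significant GWAS
variants land in them more often than chance — and does that differ between
disease and quantitative traits, between element types, and between
regulatory and non-regulatory elements?*

## What it computes

1. **PSI regions** — the nine typed element sets (BED, 0-based half-open)
   are merged into the connected components of overlapping intervals per
   chromosome. Abutting intervals stay separate; each region keeps its
   constituent element ids and type set. Summaries: counts, multi-element
   share, total/mean length, genome coverage, and a chi-square
   goodness-of-fit of region counts against chromosome-length-proportional
   expectations, `E_c = N L_c / Σ L_c`.
2. **Significant variants** — per-trait summary statistics filtered at
   strict genome-wide significance, `p < 5×10⁻⁸` or `log₁₀BF > 6`.
3. **Positional mapping** — a 1-based variant position `p` maps into
   region `[s, e)` iff `s ≤ p−1 < e`; mapped variants inherit the region's
   type set; pleiotropic = mapped and significant in ≥ 2 traits.
4. **LD loci** — variants collapse onto reported lead variants via
   `r² > 0.8` blocks (highest-r² lead wins; exactly 0.8 joins nothing);
   mapping rates are reported at the variant level
   (`100 × mapped records / significant records`) and locus level
   (`100 × mapped loci / input loci`).
5. **Contrasts** — Pearson chi-square (Yates correction on by default for
   2×2): disease vs quantitative loci by mapped status, one focal element
   type vs the rest by trait category, regulatory vs non-regulatory
   single-type regions by hit status.
6. **Synthetic data** — a seeded generator emits a toy genome, element
   sets, LD structure and GWAS tables with a controllable disease-locus
   enrichment θ (the in-region odds multiplier), so every stage is
   testable end to end with known ground truth.

## Worked example

The analysis is organized as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate.R        # seeded synthetic bundle -> results/bundle
Rscript analysis/02_build_regions.R   # merge + profile regions
Rscript analysis/03_map_and_clump.R   # filter, map, LD-clump
Rscript analysis/04_enrichment_tests.R# contingency contrasts + report
```

Step 2 prints, for the default bundle:

```
599 elements merged into 562 regions
PSI region summary: 562 regions (35 multi-element, 6.2%)
  total 851344 bp, mean 1514.8 bp (truncated 1514), genome coverage 8.51%
Chromosome distribution: X2 = 6.02 (df 4), p = 0.197
```

i.e. the ~600 simulated elements merge into 562 non-overlapping regions
covering 8.5% of the 10 Mb toy genome, and their spread across chromosomes
is consistent with length-proportional placement (the generator's default
null). Step 3 then reports

```
variant-level mapping: 45 / 681 records (6.6%)
locus-level mapping: 26 / 160 loci (16.3%)
unassigned significant variants (decoys, r2 <= 0.8): 61
```

and step 4 the disease-vs-quantitative contrast (simulated at θ = 2, i.e.
disease loci land in regions at twice the odds of quantitative loci):

```
             mapped unmapped
disease          19       61
quantitative      7       73
X2 = 5.557, df = 1, p = 0.0184 (Yates)
```

The same machinery is callable directly: `run_pipeline(bundle_dir)` returns
the full report as a list and can write `report.json`, `regions.bed`,
`mapped_variants.tsv`, `loci.tsv` and per-test TSV tables.

## Scope

Positional overlap only (no posterior-probability colocalization), no
liftover, no strand handling, no re-clumping of loci from genotype panels:
leads and r² values are inputs. See `vignettes/psimap-methods.Rmd` for the
model, parameter and design details.
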