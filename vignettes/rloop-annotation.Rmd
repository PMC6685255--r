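---
title: "Expression-aware annotation of R-loop peaks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-aware annotation of R-loop peaks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopann)
```

## The problem

R-loops are three-stranded structures — a DNA:RNA hybrid plus the displaced
single DNA strand — that form co-transcriptionally when the nascent RNA
anneals back to the DNA template strand. The workhorse mapping assay,
DRIP-seq, immunoprecipitates the hybrid without retaining its strand, and
its peaks are kilobase-scale: much longer than transcription-factor ChIP
peaks, long enough to span several gene features or several genes. Tools
that annotate a peak by its nearest TSS, or by its midpoint, routinely
misassign such peaks.

Two observations fix both problems. First, because R-loop formation is
co-transcriptional, among several candidate genes the one actually being
transcribed is overwhelmingly the likelier source — so gene expression
data, when available, should arbitrate. Second, assigning the peak to a
gene immediately determines the strand of the hybrid: the RNA is annealed
to the gene's *template* strand, the complement of its annotated strand.
This package implements that logic, together with multi-feature
decomposition (a peak may legitimately cover upstream flank, 5'UTR, exons,
introns, 3'UTR and downstream flank at once) and a shuffle-based
per-feature enrichment test.

## The annotation procedure

For each query peak, in order:

1. **Overlap** (`find_overlaps()`): candidate genes are all BED12 records
   whose span, extended by strand-aware upstream/downstream flanks, shares
   at least 1 bp with the peak's full `[start, end)` extent. The peak
   midpoint is never used; this is what keeps kilobase peaks whose centre
   falls between genes from being called intergenic. Peaks with no
   candidate are intergenic. The search is indexed through
   `GenomicRanges::findOverlaps()`; its contract is exact agreement with a
   brute-force all-pairs scan, which the test suite enforces on randomized
   instances.
2. **Selection** (`select_gene()`): a single candidate wins outright.
   Otherwise the candidate with the highest above-threshold expression
   wins; if none is above threshold, the expressed candidates tie, or no
   expression table was given, the largest overlap (with the extended
   span) wins. Remaining ties fall to the lexicographically smallest gene
   name. Selection is therefore a total order: annotation is deterministic
   byte-for-byte.
3. **Template strand** (`template_strand()`): the complement of the
   selected gene's strand.
4. **Features** (`assign_features()`): six non-exclusive flags, one per
   feature of the *selected* gene, each true on >= 1 bp overlap. Exons come
   from the BED12 blocks, introns are the gaps between them (so exon +
   intron lengths tile the gene span exactly), UTRs are the exonic
   complement of the CDS ("thick") region on the appropriate side, and the
   flanks abut the 5'/3' gene boundaries strand-awarely.
5. **Warning** (`warn_flag()`): a record is flagged when the peak touches
   only the flanks of its gene (no gene-body feature), or when it overlaps
   two or more genes that are all expressed above threshold. Both are the
   geometries where an antisense R-loop — transcription on the opposite
   strand near gene ends, or from the overlapping neighbour — could
   masquerade as the assigned gene's signal. Warned peaks are also listed
   in a dedicated table, with their expressed rival genes, so a user can
   drop or inspect them.

The output splits three ways: `expressed` (assigned gene above threshold),
`unexpressed`, and `merged`, plus the intergenic BED.

## Parameters that matter

* `up_size`, `down_size` (bp, default 5000 each): flank extent. 5 kb is
  the conventional promoter/terminator neighbourhood in R-loop annotation
  work; R-loops form kilobases from gene ends, so 1 kb-scale values lose
  genuinely genic peaks and very large values dilute the intergenic class.
* `expression_threshold` (same unit as the expression table, default 0):
  a gene is "expressed" when its value is *strictly* above the threshold.
  0 is the least-assuming default — any positive signal counts. The
  comparison is on raw values; the table is never rescaled or
  log-transformed, so any two metrics (TPM, FPKM, ...) that agree on
  threshold classes and on value ordering give identical annotations.
  This metric invariance is a tested property, not an aspiration.
* `n_shuffles` (default 10): shuffle replicates for enrichment. More than
  one is required for the dispersion estimate; 10 gives stable SD bars at
  interactive runtimes, and the value is user-settable for tighter nulls.

Genes absent from the expression table count as expression 0; duplicate
names in the table resolve to their maximum value (conservative for
"is this gene expressed at all" decisions), with a warning.

## The shuffle null and the enrichment test

`shuffle_peaks()` re-implements genome-wide, length-preserving shuffling
with the standard semantics: each peak keeps its length, lands on a
chromosome drawn with probability proportional to chromosome length
(restricted to chromosomes that can hold it), at a start uniform on
`[0, chrom_len - peak_len]`; shuffled peaks may overlap each other and no
exclusion regions are applied. Keeping the shuffler internal makes the
whole analysis seedable and free of external binaries. Each replicate is
annotated with *exactly* the query's reference, expression table and
parameters, so observed and null counts are like-for-like.

Per feature, the report gives the observed count, the null mean and
sample SD (n − 1) across replicates, the fold `observed / rand_mean`, and
a Pearson chi-squared p-value (1 df, no continuity correction) on the
2×2 table `[[obs_in, obs_out], [round(rand_in), round(rand_out)]]` — the
minimal contingency construction that yields one p-value per feature.
Conventions for edge cases: null mean 0 with a positive observation
reports an infinite fold; both zero reports fold 1 (no signal, no
enrichment); a zero marginal makes the table degenerate and the p-value 1,
with a flag. The chi-squared statistic uses the closed form
`n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`, cross-checked in the tests against
`chisq.test(correct = FALSE)` to 1e-10.

Because the second row of the table is a *mean* of many replicates, its
sampling noise is far below a single draw's; the test consequently runs
conservative for null queries (its p-values are super-uniform), which is
the safe direction for an enrichment screen.

**Calibration check.** The suite draws query sets from the shuffle null
itself and requires every feature's fold to lie within three null standard
deviations of 1 — that is `|fold − 1| <= 3·rand_sd/rand_mean`. The null SD
(not the SD of the null mean) is the right yardstick because the observed
count is a single draw from that null, not an average.

## The synthetic fixture generator

`generate_fixture()` builds, from a seed, a small genome with everything a
test needs and the expected answer for every peak. What it emulates:

* multi-exon gene models (1–6 blocks, 2–15 kb) with CDS bounds placed so
  both UTRs exist, a fraction of non-coding genes, on 2 × 1 Mb
  chromosomes by default, 40 genes;
* expression with a realistic TPM-like dynamic range — log-uniform on
  [0.1, 1000] for expressed genes (70% of singles by default), exactly 0
  for silent ones so the strict-threshold rule is exercised;
* four peak placement classes (default 120/30/20/30 of 200 peaks):
  `gene_body` (unambiguous), `flank_only` (warning rule a),
  `two_gene_overlap` (a peak across two overlapping genes, both expressed
  with distinct values, so expression must arbitrate — warning rule b),
  and `intergenic` (placed in zones no extended gene span reaches).
  Single genes are laid out with disjoint flank territories, so their
  truth is unambiguous by construction.

What it deliberately does not emulate: read-level noise and peak-calling
artefacts (peaks are exact intervals), genuine antisense transcription,
GC/chromatin-matched backgrounds, realistic gene density or isoform
structure, and chromosome-scale heterogeneity. Passing tests therefore
demonstrate *algorithmic* fidelity — the decision rules behave exactly as
specified on data where the right answer is known — not biological
accuracy on any particular genome. The ambiguous classes' truth is defined
by the package's own decision rules, so they test implementation
stability, not biology.

Problem sizes used across the suite — 100+ random overlap instances (up
to 1,000 peaks × 200 genes), 1,000 random gene models for the feature
invariants, 500 unambiguous peaks for strand recovery, and 20 calibration
trials at 100 shuffles each — were chosen as the smallest sets that
exercise every branch with comfortable statistical margins.

## Design choices where the design was open

* **Annotation table layout**: columns follow the natural reading order
  of one record — coordinates, peak name, gene, strand, expression, the
  six feature flags, warning — 14 columns, flags as 0/1.
* **Per-feature BED files vs BED12 derivation**: a reference folder may
  ship explicit `5UTR.bed`/`3UTR.bed`/`exon.bed`/`intron.bed`; when all
  four are present they take precedence (they are the more explicit
  statement of intent), and `derive = TRUE` forces BED12 derivation.
* **Several BED12 records sharing a name** are kept as independent models;
  a peak overlapping several records of one gene still counts as a
  single-gene case (dedup by name at selection), and the winning record is
  the one with the largest overlap.
* **Warned multi-gene peaks** report the selected gene in the main table;
  the rivals appear in the warned-peaks table rather than as extra rows,
  keeping the main table one-row-per-peak.
* **Shuffling is genome-wide**, not source-chromosome-restricted: the
  null asks "where would length-matched peaks fall anywhere in the
  genome", which matches the chromosome-weighted placement model.
* **Pie-chart collapse**: the pie needs one label per peak, so flags
  collapse by the priority 5'UTR > 3'UTR > Exon > Intron > Upstream >
  Downstream > Intergenic — transcribed gene-body features first, since
  they are the informative annotation for a co-transcriptional structure.
  The bar plot and upset-style plot keep the full multi-feature counts;
  every figure's numbers are also written as TSV, so figures carry no
  unique information.
* **Figures** are emitted as PNG and SVG with antialiasing off and a
  discarded warm-up render per figure; both steps remove cairo
  glyph-cache state from the output so that seeded reruns are
  byte-identical, which the determinism test asserts over whole output
  folders.

## Degenerate inputs and numerical corner cases

Zero-size flanks return empty intervals rather than zero-length ones;
flanks are clamped at chromosome edges, but never into the gene body even
if a stated chromosome size contradicts a gene record. Half-open
adjacency (`a.end == b.start`) is not an overlap. Non-coding genes
(`thick_start == thick_end`) and CDS-covering-span genes have empty UTRs.
A peak on a chromosome absent from `chrom.sizes` is reported in a
mismatch list and classed intergenic instead of being silently dropped —
chromosome-naming mismatches are the dominant real-world failure mode, so
names are compared as exact strings with no "chr" normalization. Peaks
longer than every chromosome make shuffling impossible and raise an error
naming the peak.

## Known limitations

The fundamental one is shared with the assay: a peak caused by an
antisense R-loop near a gene end, or over two co-expressed overlapping
genes, cannot be resolved from unstranded DRIP data — such peaks are
flagged, not resolved, and the warned-peaks table exists precisely so they
can be excluded downstream. Beyond that: no isoform-level reasoning (each
BED12 record is independent), no GTF/GFF ingestion, no blacklist/gap
exclusion in the shuffle null, and no GC- or chromatin-matched background
models.
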