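---
title: "Methods: junction landscapes and strain-specific splicing calls"
author: "SpliceScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction landscapes and strain-specific splicing calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceScape)
```

# The unit of analysis

SpliceScape works at the resolution of individual exon–exon junctions,
not transcripts. A junction is identified by its intron: the chromosome
and the 1-based positions of the first and last intronic base, which is
the native coordinate convention of the tabular junction files that
spliced aligners emit. Keeping that convention internally means ingest is
a pure decode and every export (BED, TSV) performs exactly one coordinate
conversion at the boundary.

Two representational decisions matter downstream:

* **Junction keys are strandless.** For unannotated junctions the strand
  is inferred from the splice motif and can be undefined in one strain
  while called in another; requiring strand identity would split what is
  biologically one intron. Strand is instead *reconciled* at merge time:
  the unique non-undefined strand across strains, `undefined` if no
  strain called one, and `conflict` if both orientations were reported.
  Conflicting junctions are kept and flagged rather than dropped, so the
  user decides their fate.
* **"Read coverage" means uniquely mapped reads.** The multi-mapping
  count is carried through all containers but never enters a threshold,
  matching a uniquely-mapped-only alignment policy. Where the choice
  between "reads" and "read pairs" is ambiguous in common usage, the
  package fixes coverage as the unique-count column of the junction
  table.

Ingest is deliberately permissive: no row is dropped for motif class,
annotation status or low coverage, because the strain-specific caller
needs the unfiltered landscape (a junction absent from a table is read as
zero coverage, which is evidence of absence for the specificity
criterion). Malformed rows, out-of-range dialect codes, inverted
coordinates and duplicate keys are hard errors that name the offending
line numbers — silent repair would corrupt cross-strain comparisons.

# Motif classification and annotation

The splice-site motif is re-derived from the genome rather than trusted
from the aligner's code: the first two and last two intronic bases are
read on the plus strand, and the pair is tested as (donor, acceptor) in
the forward orientation and, failing that, reverse-complemented in the
opposite orientation. The canonical set is GT/AG plus the minor GC/AG and
AT/AC classes; everything else — including any ambiguity character — is
non-canonical, and the junction's own strand call is passed through
unchanged. Re-deriving makes the high-confidence filter independent of
aligner versions; a flag (`useTableMotif`) restores the table codes for
users without the genome at hand.

The annotated-junction database is the set of introns implied by
consecutive exon pairs of each transcript in a GTF, deduplicated across
transcripts. Annotation lookup is an exact, strand-blind coordinate
match: the key is strandless (above), and a motif-inferred strand
disagreement should not demote a coordinate-exact match. Both a strict
(strand-matched) and lenient count are computable from the stored
annotated strand; the package reports the lenient one. Transcripts whose
exons overlap or abut are skipped with a warning, since they imply a
non-positive intron length.

Gene overlap intersects the *intron interval* with gene spans (min/max
over each gene's exons) and requires at least 1 bp of intersection, with
strand agreement enforced only when the junction strand is known. The
intron interval is used because it is the only interval the junction
record itself defines; no minimum-overlap fraction is imposed. Ties are
broken by longest overlap, then lexicographic gene id, making the result
invariant to annotation input order.

# Conservation and the splicing phylogeny

At threshold *t*, the junction universe is every key with coverage ≥ *t*
in at least one strain. Conservation is reported as the fraction of the
universe present in ≥ 2 strains and in all strains. Two thresholding
modes exist because the natural-language phrasing "junctions with ≥ *t*
coverage conserved in *k* strains" is ambiguous: the default
(`per-strain`) counts a strain only when its own coverage reaches *t* —
the symmetric reading — while `focal` requires *t* somewhere and mere
presence elsewhere. Both are one argument apart so users can compare.

The phylogeny clusters strains on the Euclidean distance between rows of
the pairwise shared-junction-count matrix (diagonal = per-strain totals)
with average linkage by default; complete and single linkage are options
because no linkage is canonical for this purpose. The sharing matrix
defaults to *t* = 1 — all identified junctions included. Rows are sorted
by strain label before clustering, so the dendrogram is deterministic and
invariant to input order up to label-ordered tie-breaks. Branch lengths
follow the usual ultrametric convention (leaf depth = merge height / 2).
No bootstrap support is computed: the matrix has one observation per
strain pair, so resampling would have to be over junctions, which is out
of scope.

# The three criteria for high-confidence strain-specific splicing

A high-confidence SSS event is a junction that

1. is detected in exactly one strain — by default *zero* unique reads in
   every other strain, the strictest reading of "absent". A tolerance
   (`requireAbsentReads`) exists for noisy panels but is 0 by default;
2. has coverage ≥ `minCoverage` (default 10) in the focal strain. The
   floor is a parameter, not a constant: the helper `coverageMedian()`
   reports the pooled unique-read median (~7.5 under the default
   synthetic landscape) so users can re-derive a floor for their own
   depth the same way — low-coverage singletons are dominated by
   sequencing errors and alignment artifacts, and a floor comfortably
   above the pooled median suppresses them;
3. is defined by a canonical splice site. The canonical set includes
   GC/AG and AT/AC, not GT/AG alone, because genuine minor-class introns
   would otherwise be discarded wholesale; the set is configurable.

The filter chain is monotone by construction: high-confidence calls are
a subset of potential calls for every configuration, and counts can only
fall as the floor rises or the canonical set shrinks. These invariants
are asserted in the test suite.

Calls can be intersected with user-supplied genomic intervals (1-based
closed; BED input is shifted at the boundary), which supports questions
like whether SSS events concentrate in regions known to be over- or
under-represented in derived populations. Only the intersection is
provided; selection-bias analysis itself is out of scope, as are
event-type classification (exon skip vs alternative last exon),
primer design and any wet-lab validation bookkeeping.

# The synthetic landscape generator

The generator exists so every stage is testable against known ground
truth without sequencing data. It emulates, at desk scale, the shape of
a deep brain-tissue RNA-seq panel across 8 inbred strains:

* **Structure.** 3400 core junctions present in all strains, 7750
  partially shared junctions over subset sizes 2–7 (weights 0.25, 0.20,
  0.17, 0.14, 0.13, 0.11), 500 private junctions per strain, and ~250
  noise junctions per strain (Poisson). These counts were fixed once, at
  design time, so that 65% of distinct junctions are present in ≥ 2
  strains and ~20% in all 8 — the qualitative landscape shape of such
  panels — while keeping full-pipeline runs in seconds.
* **Coverage.** Negative binomial around a shared per-junction
  expression level: core junctions draw their mean from
  9·lognormal(log 3, 0.4) with NB size 12 (highly expressed, tight);
  partial junctions from 9·lognormal(log 0.19, 0.7) with size 2; private
  junctions are floored at coverage 10 (they model the strain-specific
  events that survive the coverage criterion); noise coverage is
  1 + geometric(0.55), so 1–3 reads dominate. Sharing the expression
  level across strains is what makes well-expressed junctions conserved
  everywhere — under these defaults the all-strain conservation fraction
  *increases* with the threshold (≈0.20 → 0.27 → 0.33 at t = 1, 3, 10)
  as it does in real panels, and the pooled coverage median lands at
  7–8. The magnitudes of real deep libraries (hundreds of thousands of
  junctions, all-strain conservation of 50–71% at high thresholds) are
  not reproducible at this scale and are not claimed.
* **Motifs and genome.** True junctions are 95% GT/AG, 3.5% GC/AG, 0.5%
  AT/AC, 1% non-canonical; noise junctions are non-canonical with
  probability 0.5. Each junction owns a 400 bp genome block, and its
  donor/acceptor dinucleotides are overwritten in a copy of the simulated
  genome (reverse-complemented for minus-strand junctions; non-canonical
  junctions get dinucleotide pairs that are canonical in neither
  orientation). Half of the true junctions — drawn from the
  canonical-motif ones, so annotated implies canonical here — are emitted
  as two-exon transcripts of a synthetic GTF with 50 bp exon flanks.
* **Determinism.** Identical spec and seed give byte-identical files;
  the test suite hash-compares complete output directories.

What the generator does *not* emulate: read-level error processes,
alignment artifacts with positional structure, coverage correlation
along transcripts, shared-but-shifted junctions from indel divergence,
or genuine biological divergence of wild-derived strains (which is
approximated simply by raising their private-junction load). Passing
tests on synthetic data therefore demonstrate the correctness of the
bookkeeping and the calling logic under the stated model — not that the
thresholds are optimal for any particular real dataset.

# Numerical and engineering choices

* Coordinates are 1-based closed internally; BED export subtracts one
  from the start only at the boundary. The BED round trip preserves keys;
  the TSV dump preserves every field.
* Degenerate inputs fail loudly: introns shorter than 4 bases cannot
  carry two dinucleotides and are an error in motif classification;
  empty threshold universes yield `NA` fractions, not errors; an empty
  junction file is a valid, empty strain set.
* Table percentages are rounded half-even to 2 decimals at write time
  only; all in-memory statistics stay unrounded.
* Pipeline outputs carry a provenance header (package version, config
  hash, parameters) with no timestamps, so re-runs are byte-identical
  and can be hash-verified.
* Problem sizes in the test suite were chosen to keep the default run
  around a minute: the full-size default landscape (~17,000 junction
  keys, ~65,000 junction records) is generated once and reused across
  test files; structural unit tests use landscapes of a few hundred
  junctions.

# Reproducing published-scale results

The per-strain summary layer accepts any table of per-strain counts, so
panel-wide statistics of published junction surveys can be recomputed
from their printed per-strain numbers (the package ships one such table
for the 8 Collaborative Cross founder strains; see the README's worked
example). Re-running the full pipeline on real junction tables from deep
libraries (e.g. aligned against mm9 with an Ensembl 66 junction
database) is supported by the same entry points but is not part of the
test suite: results at that scale depend on the aligner version and
reference, and the raw data are not desk-scale inputs.
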