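---
title: "Characterizing quadripartite plastomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing quadripartite plastomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastchar)
```

`plastchar` bundles the computations behind a standard comparative
plastome characterization: quadripartite structure and IR junctions,
repeat content, nucleotide diversity, and codon-usage bias.  This
vignette explains each model and the choices behind it — what is
assumed, which knobs matter, how degenerate inputs are handled, and what
the synthetic data generator does and does not emulate.

## Coordinates and containers

All coordinates are 1-based inclusive, the GenBank convention, both
internally and in every report.  A single convention end to end removes
a whole class of off-by-one translation errors, round-trips GenBank
locations losslessly, and matches what R users expect from IRanges-style
tooling.  A `genome_record` holds the uppercase A/C/G/T/N sequence, a
circularity flag and a feature table whose `intervals` list-column keeps
multi-exon features in annotation order; minus-strand features are
spliced by concatenating intervals as annotated and reverse-complementing
the result, which is the GenBank `complement(join(...))` semantics.
Ambiguity codes other than N are rejected at parse time: the codon and
repeat mathematics downstream assume a concrete base at every position,
and silently coercing an R or Y would corrupt counts rather than fail
loudly.

## Quadripartite structure

The IR pair is defined as the longest pair of disjoint intervals on the
circle whose sequences are exact reverse complements, with both gaps
nonempty; the longer gap is LSC.  Exactness is the right default because
assembled plastomes carry two literally identical IR copies — the
assembler collapses them — so a mismatch-tolerant definition would only
blur the boundary.  The default minimum IR length of 1000 bp is far
below real plastid IRs (≈10–25 kb) but far above the longest chance
palindromes in a ~10² kb AT-rich sequence, so it excludes noise without
risking the target.  Detection runs on the doubled sequence so that it
is rotation-invariant: a genome linearized at any point yields the same
region lengths.  Ties (multiple maximal pairs) are broken by the
smallest IRb start in the frame where LSC begins at position 1; the
canonical report order is LSC–IRb–SSC–IRa with junctions JLB, JSB, JSA,
JLA at the last base of each region.

Junction distances are signed: positive is the gap in bp between the
nearer gene end and the junction (zero when flush), negative means the
gene crosses the junction, with magnitude equal to the bp falling in the
region that holds the smaller part of the gene.  Genes absent from a
genome are reported as `absent` rather than dropped, since absences at
junctions (e.g. *rpl23*) are themselves findings.

## Repeat mining

SSRs are perfect tandem repeats of primitive 1–6 nt motifs with MISA's
minimum unit counts (10, 6, 4, 3, 3, 3).  Each maximal run is assigned
its smallest primitive period, so `(AT)6` is a single dinucleotide locus
rather than a non-primitive tetranucleotide or twelve mononucleotide
positions, and runs contained in a reported run of smaller period are
not double-reported.  Motifs are tallied as read on the forward strand
without canonical collapsing (A-runs and T-runs stay separate), the
layout used in published SSR tables.  Compound-SSR merging is not
implemented; counts on real genomes may differ slightly from tools that
merge adjacent loci.

Dispersed repeats are maximal pairs under a Hamming budget: a pair
(pos1, pos2, L) of the four types F/P/R/C qualifies when the first copy
and the transformed second copy differ at ≤ 3 positions over L ≥ 30 bp,
and no one-base extension stays within budget.  The finder is
seed-and-extend: m mismatches cut a qualifying window into m+1 exact
runs totalling ≥ L−m, so the longest run has ≥ ⌈(L−m)/(m+1)⌉ = 7
positions, and exact 7-mer seeds find every window; windows are then
enumerated from the mismatch positions collected around each seed and
deduplicated on (diagonal, start).  Each unordered pair is reported
once; a self-centered palindrome once.  The IRa/IRb pair itself is a
giant palindromic repeat — it is reported, tagged `is_ir_pair`
(containment test, since a mismatch-budget window extends slightly past
the exact copies), and excluded from summary totals by default, because
published dispersed-repeat counts conventionally describe repeats
*within* the single-copy architecture.  No E-value or containment
filtering is applied beyond maximality: overlapping maximal windows
around a mismatch cluster are all legitimate output under this
definition, which is worth remembering when comparing counts across
tools.  The test suite checks the finder against an independent
brute-force enumeration that walks every diagonal.

## Nucleotide diversity

π is the mean number of pairwise differences per site: columns holding
any gap or ambiguity are removed first (complete deletion), then
π = Σ<sub>i&lt;j</sub> d<sub>ij</sub> / C(n,2) / L′ over the L′ retained
columns.  No Jukes–Cantor correction is applied — the headline π in
DnaSP-style gene screens is the uncorrected sample statistic.  The
windowed variant advances by a fixed step (default 25 columns); after
the last full window one trailing partial window is added only when at
least one step of columns follows it and some columns are uncovered, so
a window that already ends exactly at the alignment end produces no
redundant tail.  Whole-gene values use a single window spanning the
gene; both modes exist because a gene-length window admits only one
placement, making "window = gene, step = 25" meaningful only as the
whole-gene mode plus a separate windowed profile.  Hypervariable
ranking uses strict π &gt; threshold (default 0.08), descending, ties
alphabetical.

## Codon usage

CDSs enter the analysis only if they pass the standard filter: spliced
length strictly greater than 300 nt, ATG start, TAA/TAG/TGA stop, no
internal stop, and removal of IR duplicates (identical gene name and
identical spliced sequence keep exactly one copy).  Failing records are
flagged, never silently dropped.

Positional statistics exclude the terminal stop codon and include the
start.  GC1, GC2 and GCall run over all remaining codons.  All
third-position statistics — A3, T3, G3, C3, GC3 and GC3s — are computed
over the synonymously variable codons only (ATG and TGG excluded): the
third position of a nondegenerate codon cannot vary, so including it
would mix a fixed constant into a statistic meant to measure usage
freedom.  Under this convention GC3 and GC3s coincide; both columns are
kept so the report layout matches the field's standard tables.

ENC follows Wright's estimator with the CodonW conventions: per-family
homozygosity F = (nΣp²−1)/(n−1) for families with n ≥ 2, class means
over 2-, 3-, 4- and 6-fold families (Leu, Ser and Arg stay six-fold),
ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ capped at 61.  A missing
3-fold mean (Ile unobserved) is imputed as the mean of F̄₂ and F̄₄;
families with F ≤ 0 (all observed codons distinct — no information) are
dropped from their class mean; if any other class mean is missing the
gene's ENC is `NA`.  The mutation-pressure null curve is
ENC* = 2 + GC3 + 29/(GC3² + (1−GC3)²), which evaluates to 31, 60.5 and
32 at GC3 = 0, 0.5, 1.

RSCU is observed count over family mean; unobserved families are
missing, not zero, so a gene that never uses alanine does not appear to
avoid every alanine codon equally.  The neutrality plot regresses GC12
on GC3 by ordinary least squares and reports both the correlation-test
and slope-test p-values (identical in simple regression, but both are
conventionally quoted); a constant response is reported as slope 0 with
r² = 0 and missing p rather than a warning-laden degenerate fit.  PR2
uses all synonymously variable codons, consistent with the
third-position convention above; a `fourfold`-restricted variant was
considered and rejected because the positional statistics feeding it are
already restricted to variable codons.

Optimal codons: genes sorted by ascending ENC (ties by name), the first
⌈0.1 n⌉ form the high-expression (most biased) pool and the last
⌈0.1 n⌉ the low-expression pool; ceiling guarantees nonempty pools at
any n ≥ 10.  RSCU is recomputed on pooled counts per pool;
ΔRSCU ≥ 0.08 marks high-expression codons, pooled all-gene RSCU &gt; 1
marks high-frequency codons, and optimal means both.  The 0.08 default
is the conventional Methods-section threshold; it is an argument
(`delta_threshold`) for sensitivity analysis.

## The synthetic generator

`generate_plastome()` emulates the study conditions of a moss plastome:
124,264 bp total (LSC 85,572, SSC 18,608, IRs 10,042), AT-rich
single-copy backgrounds (GC 0.260/0.251) and GC-rich IRs (0.433), with
planted SSRs covering all six motif classes, planted F/P/R/C repeats at
0 and 3 mismatches, genes sampled from a third-position A/T-biased codon
profile (default bias 0.85, giving the low-GC3s, mid-ENC signature of
real plastid genes), IR-duplicated and intron-split genes, and
junction-straddling markers.  Three constructions make recovery exact
rather than approximate: SSR flanks are chosen to break the tandem
period on both sides; each planted dispersed repeat gets one blocking
mismatch immediately outside each end, so a 3-mismatch plant is itself a
maximal window; and the four IR boundaries are blocked the same way so
layout detection returns the planted intervals to the base.  Everything
derives from one integer seed; the manifest records ground-truth
coordinates for every planted element.

What the generator does **not** emulate: i.i.d. backgrounds have no
codon structure, isochores or compositional autocorrelation outside
planted genes; alignments evolve by independent per-site mutation from a
star ancestor (no substitution-model rate variation, no indels unless
planted); gene content and order are a convenient subset, not a real
gene map.  Passing the recovery tests therefore demonstrates
correctness of the detectors' definitions, not robustness to every
artifact of real assemblies (annotation errors, heteroplasmy, collapsed
repeats).

`generate_alignment()` solves 2p(1−p) + (2/3)p² = π for the per-site
mutation probability p, so expected pairwise diversity equals the
target; at the regime used in the tests (9 taxa × 1500 columns,
π = 0.09) the mean recovered π over 50 seeds sits within ±0.01 of the
target, and the tests assert exactly that.

## Problem sizes and determinism

The test suite and the acceptance script run at the full default genome
scale (124 kb) for structure, SSR and dispersed-repeat recovery; oracle
equality for the repeat finder uses 100 random 2 kb instances with
planted repeats of all four types; codon-pool recovery uses 2 × 25 genes
of ~300 codons; diversity recovery uses 50 seeded alignments.  These
sizes keep each property statistically decisive while the whole suite
completes in a couple of minutes.  All randomness flows through
explicit integer seeds (base R RNG); the same seed reproduces every
sequence byte for byte.

## Known limitations

GenBank parsing covers the feature-table subset that organelle records
use (join/complement locations, gene/product/note qualifiers); exotic
location operators (`one-of`, remote accession references) are rejected
with an error naming the location.  Trans-spliced genes are spliced in
annotation order without reordering — the annotation is treated as
authoritative.  Genes whose annotation spans the circular origin are
supported, but the generator never plants one by default.  The
dispersed-repeat definition reports all maximal windows, so totals are
not directly comparable to tools that apply containment or E-value
filters; when comparing, use the `is_ir_pair`-excluded total for
single-copy repeat content and the inclusive total otherwise.
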