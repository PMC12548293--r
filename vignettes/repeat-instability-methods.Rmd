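---
title: "Methods: quantifying microsatellite instability and repeat mutation spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying microsatellite instability and repeat mutation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msirep)
```

`msirep` measures replication-slippage-driven instability of short tandem
repeats (microsatellites) in mismatch-repair-deficient tissue from three
directions: read-level allele diversity at cataloged loci, reporter-gene
mutation spectra, and SBS/ID classification of somatic variants. This
vignette documents the models, the parameters that matter, the numerical
conventions, and the places where the design was genuinely open and a
choice had to be made.

## Microsatellite cataloging

A locus is a **maximal perfect tandem repeat** of a primitive 1–3 bp motif.
"Perfect" means no interruptions: the stratified entropy summaries below
group loci by exact unit count, which is only well-defined for perfect
tracts. Ambiguous bases terminate runs. Motifs must be primitive (not a
power of a shorter unit), so a homopolymer is cataloged once at motif size
1, never as "AA"; a mononucleotide run inside a longer dinucleotide context
is reported independently at both sizes.

Minimum unit counts default to **mono ≥ 5, di ≥ 3, tri ≥ 3** — a
conventional lower bound below which slippage is rare and "instability" is
not meaningfully measurable; they are configurable arguments of
`scan_reference()`.

Two conventions resolve corner cases deterministically:

* **Phase.** The reported motif is the unit starting at the leftmost base
  of the maximal run ("ACACACA" is (AC)₃, not (CA)₃). Canonicalization
  merges a motif with its reverse complement only (TG → CA), never with
  its rotations, so GA/TC and AG/CT remain distinct motif classes — they
  behave differently and are compared separately.
* **Overlaps.** Maximal periodic runs of the same motif size can overlap
  by up to k−1 bases (e.g. "ACACACGCGCGC"). The scanner resolves this
  greedily left to right: a later run whose tract overlaps an already
  reported locus has its start advanced to the first base past that locus
  and its motif and unit count recomputed. Same-size loci therefore never
  overlap; cross-size overlaps are allowed.

Coordinates are 0-based half-open internally and in BED output; 1-based
coordinates appear only in VCF-facing code.

## Allele spectra from reads

The repeat length a read supports is measured by **sequence pattern
matching between flank anchors**, not from the CIGAR: aligners place indels
within repeats ambiguously, so the CIGAR encodes an arbitrary left- or
right-shifted representation. A read yields an observation only if it
contains, in order, `min_flank` (default 5 bp) of reference sequence on
both sides of the tract, with consecutive motif copies between the located
anchors running exactly into the right anchor. Reads with ambiguity (N) in
the tract or anchors fail those exact matches and are discarded, as are
unmapped, secondary, supplementary, duplicate-marked, and low-mapping-
quality records (`min_mapq`, default 20).

Loci with fewer than `min_depth` (default 10) spanning observations are
flagged insufficient and excluded from statistics. This per-locus read
floor is a separate guard from the per-stratum locus-count exclusion
below; both are explicit, named parameters.

Spectra serialize to a documented ".dis-like" TSV dialect (one line per
locus; `spectrum` column of comma-separated `units:count` pairs sorted by
units) so that cohorts can be stored and re-read bit-exactly.

## The entropy statistic

For read proportions \(p_i\) over distinct observed unit counts at one
locus,

\[ SE = -\sum_i p_i \log_2 p_i. \]

**Base 2 (bits)** is used and stated in the outputs; the choice of base
rescales every SE by a constant and does not affect orderings, stratified
comparisons, or the sign of trends. SE = 0 iff the spectrum is a point
mass; SE ≤ log₂(k) for k distinct lengths; SE is invariant to relabeling
lengths and to merging spectra with identical length distributions.

Stratification groups loci by (canonical motif, unit count) per sample.
For exome (WES) input, strata with **fewer than 10 loci** are excluded
(and logged with a reason): sparse exome strata produce noisy means. The
exclusion is read as a *locus-count* rule, not a read-depth rule — read
depth has its own explicit floor upstream — and it is applied to WES only;
genome-wide data keep all strata.

Per-motif trends are ordinary least squares of per-locus SE on unit count,
with a 95% confidence interval on the slope from the standard error and
the t quantile. At least three distinct unit counts are required; fewer is
an error, not a silent degenerate fit.

## Tumor-only MSI scoring

The per-locus instability call is deliberately simple and fully declared,
since tumor-only calling requires a normal-cohort reference:

1. **Baseline.** Pool the allele proportions of all normal samples per
   locus (loci missing or under-covered in any normal are dropped and
   logged). For each locus, compute each normal's total variation distance
   d to the pool of the *other* normals (leave-one-out), and set
   τ = mean(d) + 3·SD(d).
2. **Score.** For each locus shared between sample and baseline,
   d = ½ Σ |p_sample − p_baseline|. The locus is unstable iff
   d > max(τ, τ_floor) with **τ_floor = 0.05**; ties are stable (strict
   inequality). The MSI score is the unstable fraction of evaluated loci.

The floor guards against degenerate τ when normals are identical or few
(with a single normal sample, τ falls back to a global default of 0.1).
Per-locus d values are emitted for audit. Total variation distance was
chosen because it is bounded on [0, 1], symmetric, and directly
interpretable as the redistributed read mass; the mean + 3·SD threshold
mirrors common outlier calibration against an empirical null. These
choices are *not* those of any external MSI caller, so absolute scores are
not comparable to scores produced by other tools — within-study contrasts
(genotype, tissue) are the intended use.

## Reporter-gene calculus

The reporter assay counts mutant (Km/Sm-resistant) colonies among screened
(Km-resistant) colonies; MF = n_mutant / n_screened. Per-class MF
apportions the overall MF by the class proportions among classified
mutations. Eleven classes are used: the six Watson–Crick substitution
pairs (C>T and G>A both count as G:C>A:T), 1-bp indels in A/T homopolymer
runs of length ≥ 2 ("1-indel_(A)n", with the run length recorded), 2-bp
indels removing/adding two bases of an A/T run, other 1-bp indels, indels
larger than 2 bp, and "other".

Conventions:

* A runs and T runs are both "(A)n" context — the assay reads one strand
  of a double-stranded tract.
* Run length ≥ 2 qualifies as (A)n; an isolated base yields plain 1-indel.
* Indel positions are normalized to the run's leftmost coordinate
  (placement within a homopolymer is ambiguous), which makes positional
  hotspot profiles well-defined.
* Group summaries are **per-mouse means** by default (each animal is the
  biological replicate); a pooled mode (all colonies of a group combined)
  is provided as an option. Two-group comparisons use the Mann–Whitney U
  test on per-mouse overall MFs — a named standard test, called from
  `stats`, not re-derived.
* Multi-mutation colonies contribute each mutation once; no colony-level
  deduplication is applied.

Class-MF conservation (Σ per-class MF = overall MF; run-length buckets sum
to the (A)n total) holds exactly in both modes and is asserted in tests.

## Somatic filtering and SBS96/ID83

The filter retains variants with tumor and normal depth ≥ 10, ≥ 3 tumor
alt reads, 0 normal alt reads, autosomal location, no dbSNP membership,
and no sharing across two or more tumors. dbSNP membership and shared-
tumor counts are consumed as precomputed input flags; rules commute, and
the per-rule rejection tally attributes each rejected variant to the first
rule it fails in the fixed order above. Chromosome dialects ("chrX", "MT")
are normalized on ingest.

SBS96 follows the pyrimidine convention: a purine reference base
reverse-complements the trinucleotide and the substitution before
classification, so complementing every record leaves the matrix invariant
(each of the 96 classes is hit by exactly two of the 192 strand-explicit
combinations — asserted exhaustively in tests).

ID83 classifies left-aligned indels: 1-bp events by base (A/T events as T,
C/G as C) and homopolymer run length (deletions count the run *including*
the deleted base, categories 1…5, 6+; insertions count the adjacent run,
0…4, 5+); longer deletions by the tandem-copy count of the deleted
sequence including the deleted copy (1…5, 6+) when a tandem copy exists,
else by the longest flanking microhomology; insertions analogously without
a microhomology branch. The top deletion-repeat category is "6+",
matching the display convention under which the hallmark multi-unit
repeat-deletion pattern sits in the more-than-six-units bucket.
Left-alignment before classification makes equivalent right-shifted
representations classify identically (property-tested).

## Integration-site detection

Only read pairs with exactly one host-mapped mate (mapping quality ≥ 20)
and one unmapped mate are informative for a plasmid-into-genome junction.
Unmapped mates are re-aligned to the plasmid with a gapped local aligner —
`Biostrings::pairwiseAlignment` with match +1, mismatch −2, gap −3,
declared constants — and kept at ≥ 80% of the maximum attainable score
(read length × match score). Host positions are single-linkage clustered
with a 1 kb gap window; clusters with ≥ 3 supporting pairs become calls.
Because the transgene is a multi-copy tandem array, pairs internal to the
array are both-unmapped and carry no host signal; the simulator generates
both kinds so the finder's selection logic is exercised. Split-read
(soft-clip) mining is available conceptually but off by default; mate-pair
evidence alone locates the junction to within a fragment length.

## The synthetic-data generators

The generators define the conditions under which every property in the
test suite is evaluated; they emulate the statistical *structure* the
analysis assumes, not the full messiness of real sequencing data.

**Slippage model.** Per-read slippage probability
p(n) = min(0.5, p0 · (n − n_min + 1)^γ · genotype_multiplier), with
defaults p0 = 0.002, γ = 1.5, n_min = 5: per-read length-change rates are
fractions of a percent at short tracts and rise steeply with length,
giving near-zero entropy at 5–8 units and visibly diversified spectra
beyond ~15 units at the MMR-deficient multiplier of 5 — the qualitative
regime in which length-dependent destabilization is observable at
ordinary depths. A slipped read steps −1 unit with probability d1 = 0.7,
+1 with i1 = 0.2, and otherwise takes a geometrically decaying larger
step with the sign drawn in the d1:i1 ratio: contraction dominates,
reflecting deletion-dominated repeat mutation spectra in MMR deficiency.
PCR-stutter-like jitter is a separate, default-off concern: instability
and noise stay independently testable.

**Reference backgrounds** are random but repeat-free by construction (a
base may not extend any 1–3 bp periodicity beyond small caps, and may
never continue a periodicity across a planted-repeat junction), so
`scan_reference` provably recovers exactly the planted loci — verified at
generation time. The stress tests of the scanner use unconstrained i.i.d.
sequence instead, where incidental repeats are expected and checked
against an exhaustive oracle.

**Reporter colonies.** Mutant counts are binomial per mouse at the
generating MF; classes are drawn from a weight table whose default is
proportional to the class spectrum of untreated MMR-deficient small
intestine (dominated by 1-indel_(A)n); adenine-run events choose their
run ∝ (run length)⁴ and are deletions with probability 0.9. The synthetic
reporter sequence plants one A-run per length 2–6 — emulating a reporter
whose longest adenine tract is (A)₆ — in a background whose homopolymers
are capped at a single base, so the planted runs are the only (A)n sites.

**Integration read sets** sample ~N(300, 30) fragments over the modified
genome at a chosen depth, lift host-side coordinates back to host space,
and emit plasmid-touching mates as unmapped.

All generators are pure functions of (parameters, seed); the RNG stream is
split hierarchically per sample and locus (a hash of seed and labels), so
adding a locus or sample does not perturb other draws, and the caller's
RNG state is restored afterwards.

**What the generators do not emulate** — and what passing tests therefore
do not show about real data: base-call errors and quality scores, PCR
stutter, mapping ambiguity in repetitive genomes, tumor purity and
subclonality, coverage biases, and genome-scale catalogs. Conclusions
about real samples still require the usual upstream QC.

## Problem sizes and numerical conventions

The property suites run at desk scale, chosen to give the statistics room
to separate while keeping the full test run in minutes: scanner-oracle
identity on 100 independent 10-kb sequences; slope and MSI-score contrasts
over 100 seeded replicates (400 loci × depth 50, and 60 loci with a
20-normal baseline — the latter sized like a realistic normal cohort for
tumor-only baselines); reporter trends over 100 replicates of 5 mice ×
200,000 colonies; integration recovery over 20 replicates of a 20-kb host
at 20× depth. Replicate seeds are fixed offsets from a base seed, so every
run is reproducible.

Numerical conventions: proportions are validated to sum to 1 within 1e−12;
entropy of a point mass is exactly 0 (signed zero normalized); ties at
d = τ are stable; zero-mutation mice contribute zero per-class MF with a
warning when mutant colonies exist but classifications are absent; empty
inputs yield empty outputs (scan of an empty sequence, clustering of empty
evidence) rather than errors, while contract violations (unknown locus
ids, ref-allele mismatches, missing depth fields, zero normals) are hard
errors.

## Known limitations

* Absolute MSI scores depend on the declared TV-distance/τ calibration and
  are not comparable across tools; use within-study contrasts.
* Perfect repeats only: interrupted repeats are neither cataloged nor
  scored.
* The anchor-based length measurement discards reads whose flanks mutate
  or end near the tract, biasing depth slightly downward at long tracts
  (longer tracts leave less room for anchors within a read).
* The scanner is written for desk-scale references (tests use ≤ 100 kb);
  genome-scale cataloging is out of scope.
* The integration-site finder assumes a single-locus insertion and
  mate-pair evidence; it does not assemble the insertion structure or
  estimate copy number.
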