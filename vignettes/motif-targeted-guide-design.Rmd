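---
title: "Motif-targeted sgRNA design: models, rules, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-targeted sgRNA design: models, rules, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifguides)
```

## The problem

CRISPR experiments on regulatory sequence differ from gene knockouts in one
crucial way: the target is not a reading frame but a short motif — an E-box
bound by MYC-family factors, an ETS site, a miRNA seed match. A guide is
useful only if its molecular consequence lands *on the motif*: for active
Cas9 the repair indels must overlap the binding site; for dCas9 the bound
ribonucleoprotein must physically cover it. `motifguides` encodes these
geometric requirements explicitly and scales them from a single promoter to
thousands of ChIP-seq peaks.

This vignette explains the models and conventions; it states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## Coordinates

All internal coordinates are 0-based half-open, identical to BED; conversion
to 1-based inclusive happens only when tables are exported. This removes the
usual off-by-one ambiguity between scan positions, cut bonds and browser
tracks: a cut *bond* `b` is the phosphodiester bond between plus-strand
positions `b-1` and `b`.

## Motif model

Motifs are positional base-set patterns derived from IUPAC strings. Two
conventions matter:

* **Genomic `N` never matches.** Ambiguity in the *pattern* widens
  acceptance; ambiguity in the *genome* (assembly gaps, masked bases) does
  not. Without this rule a gap of a few hundred `N`s would "contain" every
  motif at every offset.
* **Palindrome collapsing.** A motif equal to its own reverse complement
  (CACGTG) matches the same molecular site on both strands; reporting both
  would double every downstream guide count. Identical-interval +/− pairs
  of self-complementary motifs collapse onto the `+` record. Non-palindromic
  overlapping hits are all kept.

Count matrices (JASPAR, TRANSFAC) are collapsed to an IUPAC consensus rather
than scanned as weight matrices — the design target is a concrete editable
site, not a log-odds threshold. Two collapse rules are offered, per column
with frequencies `f_b = count_b / total`:

* `min_frequency` (default, threshold 0.25): include every base with
  `f_b >= t`; if nothing qualifies, fall back to the most frequent base.
* `cumulative`: include bases in decreasing-frequency order (alphabetical
  tie-break, so the result is deterministic) until the running sum reaches
  `t`.

The default threshold 0.25 is the natural "above uniform background" cutoff
for a 4-letter alphabet; both rule and threshold are exposed in
`run_config()` because matrix sharpness varies between databases.

## Guide geometry

For PAM pattern `NGG`/`NGA`/`NGCG`, every matching window on either strand
anchors a candidate 20-nt protospacer immediately 5′ of it (on the PAM's
strand). Geometry rules:

* **cas9** — the blunt cut lies 3 nt 5′ of the PAM. We require the bond to
  lie *strictly inside* the motif: both flanking bases are motif bases
  (`rel_start + 1 <= b <= rel_end - 1`). Bonds at the motif border touch
  only one motif base, so an indel could spare the site entirely; they are
  excluded.
* **dcas9** — occupancy blocking: the protospacer (the 20-nt duplex the
  ribonucleoprotein engages, PAM excluded) must overlap the motif by at
  least 1 nt. Whether the PAM should count toward overlap is genuinely open;
  we chose the conservative protospacer-only reading and document it, since
  the R-loop footprint is what occludes the factor.
* **custom** — the gap between the PAM interval and the motif interval
  (0 when touching or overlapping, else the count of bases strictly
  between) must not exceed a user distance. The distance is unsigned:
  "PAM within X nt of the motif" is symmetric and strand-agnostic.

These choices give two provable relations exercised by the tests: every
cas9 guide is also a dcas9 guide, and custom-mode guide counts are
non-decreasing in the distance parameter.

BED targets are extended by 30 nt per side (clamped at chromosome ends,
with the actual extension recorded per region) before scanning, so motifs
at — or just beyond — a peak border still receive guides whose protospacers
need flanking sequence. Raw/FASTA targets cannot be extended; the tests
confirm a motif 10 nt outside a BED interval is designed for under BED
input and invisible under the equivalent FASTA input.

## Off-target model

Off-target search is an in-process PAM-anchored mismatch scan: all
PAM-adjacent 20-mers in the genome (both strands) are collected and
Hamming-compared to each guide, keeping sites within 4 (standard) or
3 (rapid) mismatches. No DNA/RNA bulges are modeled. The test suite pins
this search to an independent every-window brute-force scan at every
mismatch level.

Each site is scored with a CFD-style model: the product over mismatched
positions of a penalty indexed by (guide base, site base, position 1–20
from the PAM-distal end), times a PAM penalty indexed by the PAM's last two
bases. Identity entries are 1; a perfect canonical site scores exactly 1.
The bundled table (`inst/extdata/cfd_*_synthetic.tsv`) is **synthetic**: it
preserves the published model's structure — mismatches near the PAM are
most disruptive, transition-like mispairs are better tolerated than
transversions, non-canonical PAMs are strongly penalized — via the
documented formula in the file headers, but its numbers are not the
published measurements. Any table in the same two-file TSV layout can be
passed to `load_cfd_table()`; absent a table, the pipeline degrades to
mismatch-count-only reporting with a warning.

Per guide, specificity is aggregated as

$$\mathrm{off\_score} = \frac{100}{1 + \sum_i \mathrm{CFD}_i}$$

over all sites except the design locus. This maps an empty off-target set
to 100, one perfect-equivalent competitor to 50, and is strictly decreasing
in every added positive-CFD site — a 0–100, higher-is-better scale on which
a "score < 30" exclusion filter is meaningful. The design locus is excluded
by exact coordinates when the target carried them; for sequence-only
targets the first perfect-match canonical-PAM site (chromosome/position
order) is taken as the presumed design locus, and *additional* perfect
matches count as off-targets with CFD 1 — a deliberate, conservative
convention.

## On-target scoring

Trained efficiency predictors (gradient-boosted 30-mer models and kin) are
out of scope; the package instead defines a scorer *contract* — input: 4 nt
context + 20 nt protospacer + PAM + 3 nt context on the guide strand;
output: 0–100 — plus a registry (`register_on_target_scorer()`) so such a
model can be plugged in unchanged. The built-in `surrogate` scorer is a
transparent deterministic heuristic: 50, +25 if protospacer GC is within
40–60%, −25 if it contains a homopolymer run ≥ 5 nt, clamped to [0, 100].
It encodes two uncontroversial design preferences and nothing more; its
scores order guides coarsely and should not be read as cutting-efficiency
predictions. Guides too close to a sequence end to form the full context
window remain unscored.

## Localization and TSS context

Gene models (refGene-style dumps) decompose into per-transcript interval
sets: coding exon = exon ∩ CDS, non-coding exon = exon \ CDS, intron =
transcript \ exons — the three sets tile the transcript exactly (a tested
invariant). A motif interval is classified by *any-overlap* against all
transcripts with the hierarchy coding exon > non-coding exon > intron >
intergenic, which resolves both boundary-spanning motifs and disagreeing
transcript variants toward the most consequential call. Midpoint
classification was rejected: a motif half inside a coding exon is a
coding-exon edit regardless of where its midpoint falls.

TSS positions are `tx_start` (+ strand) or `tx_end − 1` (− strand), every
transcript contributing its own. Closest up- and downstream TSS are
reported with genomic signed distances (negative: TSS left of motif start;
positive: TSS right of motif end; a TSS inside the motif fills both slots
at distance 0). The TSS *exclusion filter*, however, is strand-aware by
default (`tss_strand_aware`): a window like −200…+100 nt around a TSS is
conventionally meant in the gene's direction of transcription (the CRISPRi
promoter window), so the motif's genomic offset is sign-flipped for minus
strand genes. The flag restores purely genomic windows.

## Filter composition

Filters compose in a fixed, documented order: motif-level (allowed
localizations, then TSS window — removing a motif removes its guides) →
guide-level score thresholds → optional pruning of motifs without guides →
`top_x` best guides per motif. Ranking for `top_x` is off-score descending,
then on-score descending, then leftmost position: specificity is the
primary quality axis, and the positional tie-break makes results
deterministic. Order matters (a `top_x` applied before a score threshold
would keep different guides), so the composition is pinned and filtering is
contractive and idempotent — both tested properties.

## Synthetic fixtures: what they do and do not show

All tests run on generated data: random genomes of specified GC, planted
motif instances (half per strand, with guaranteed adjacent NGGs for half
the sites so cas9 guides provably exist), planted protospacer near-copies
with exactly *k* substitutions outside the PAM, and random non-overlapping
gene models with per-base painted truth labels. Everything is
seed-deterministic, and fixtures are emitted in the pipeline's real input
formats (FASTA, refGene-style TSV, BED) so tests exercise the actual
parsers.

The default study conditions used by the acceptance script are a 60 kb
single-chromosome genome with 50 planted E-boxes inside ±40 nt "peaks" and
8 genes — large enough for chance motif hits and full annotation variety,
small enough that the whole pipeline runs in seconds. i.i.d. random
sequence has no repeats, segmental duplications or biased k-mer
composition, so passing tests demonstrate *algorithmic correctness*
(recovery, geometry, oracle equivalence, determinism), not real-genome
off-target burden: on a mammalian genome the same guide would meet far more
near-matches, and specificity scores would spread far below the ~100 seen
on toy data.

## Degenerate inputs and tie-breaks

* Zero-total matrix columns, ragged matrices, non-IUPAC symbols, malformed
  BED lines and inconsistent exon lists are rejected with the offending
  column/position/row named.
* Motifs longer than their target, regions with no PAM, and empty result
  sets propagate as empty tables; summary statistics of an empty run are
  all-zero without division errors.
* Duplicate region names get numeric suffixes (warning); unnamed regions
  get `target{k}` in input order.
* Identical guides from overlapping motifs merge in "unique guides" mode on
  the key (protospacer, PAM, strand, position) — the same spacer text at
  two loci stays two records.
* Score histograms bin at [0,10), …, [90,100]; 100 belongs to the top bin.

## Known limitations

* Mismatch-only off-target search (no bulges), single-guide designs only,
  3′-PAM Cas enzymes only.
* The CFD table shipped is synthetic (see above); absolute off-scores
  should be recalibrated with a measured table before being compared to
  published specificity values.
* The surrogate on-target scorer is a placeholder contract implementation,
  not a trained predictor.
* Matrix motifs are reduced to an IUPAC consensus; position-weight-matrix
  log-odds scanning is intentionally out of scope.
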