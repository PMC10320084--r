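# motifguides

Design CRISPR sgRNAs that target **sequence motifs** — transcription-factor
binding sites, miRNA seed matches, any pattern expressible in IUPAC codes —
inside user-supplied genomic regions. General-purpose guide designers pick
sgRNAs for a gene or an interval; `motifguides` is for experiments where the
*motif itself* is the target: disrupting an E-box with Cas9 so indels destroy
the binding site, or parking dCas9 on top of it to block the factor
sterically.

It is aimed at regulatory-genomics labs designing anything from a handful of
guides against one promoter up to library-scale designs across thousands of
ChIP-seq peaks, entirely in-process (plain R, no external aligners, no web
services).

## What it computes

1. **Motif scan.** Motifs come as plain/IUPAC sequences (inline, FASTA, CSV)
   or as JASPAR/TRANSFAC count matrices collapsed to an IUPAC consensus
   (per column, either every base with frequency ≥ *t*, or the smallest
   frequency-sorted set reaching a cumulative *t*). Both strands of every
   target are scanned; targets given as BED coordinates are extended by
   30 nt on each side so border motifs still receive guides. An `N` in the
   genome never matches any motif position.
2. **Guide geometry.** For each motif occurrence, every NGG/NGA/NGCG PAM
   site defines a candidate 20-nt protospacer. Three acceptance rules:
   - `cas9` — the blunt cut (3 nt 5′ of the PAM) must fall strictly inside
     the motif, so repair indels disrupt it;
   - `dcas9` — the protospacer must overlap the motif by ≥ 1 nt;
   - `custom` — the PAM-to-motif gap must be ≤ a chosen distance.
3. **Off-target specificity.** Every genomic site within 4 (standard) or
   3 (rapid) mismatches of a guide, with a matching PAM, is enumerated by a
   PAM-anchored in-process search. Each site gets a CFD-style score
   `∏ penalty(guide base, site base, position) × penalty(PAM)`, and the
   guide's specificity is aggregated as

   `off_score = 100 / (1 + Σ site CFD)` (design locus excluded),

   i.e. 100 = no off-targets, 50 = off-target burden equivalent to one
   perfect site. The bundled penalty table is a clearly-labelled synthetic
   stand-in with the published model's structure; drop-in replacement by a
   measured table is supported.
4. **On-target efficiency.** A pluggable scorer interface; the built-in
   deterministic surrogate rewards 40–60% GC and penalizes homopolymer runs
   ≥ 5 (50 ± 25, clamped to [0, 100]). External predictors can be
   registered without touching the pipeline.
5. **Annotation, summaries, filters.** Motifs are classified against
   refGene-style gene models with the hierarchy coding exon > non-coding
   exon > intron > intergenic, and the closest up/downstream TSS is
   reported. Results can be filtered by localization, TSS window
   (strand-aware), score thresholds, and per-motif top-x ranking, and are
   summarized with score histograms and guides-per-motif distributions.

Everything is testable without downloads: the `fixtures` module generates
seed-deterministic toy genomes, planted motifs, planted off-target sites and
toy gene annotations with complete ground truth.

## Worked example

```r
library(motifguides)

# seed-deterministic fixture: 60 kb genome with 12 planted E-boxes
g   <- make_toy_genome(1, 60000, seed = 7, path = tempfile(fileext = ".fa"))
g   <- plant_motifs(g, "CACGTG", 12, seed = 8)
ann <- make_toy_annotation(g, n_genes = 5, seed = 9)
bed <- tempfile(fileext = ".bed")
writeLines(sprintf("chr1\t%d\t%d\tpeak%d", g$truth$start - 50,
                   g$truth$end + 50, 1:12), bed)

cfg <- run_config(motifs = "CACGTG", targets = bed, target_format = "bed",
                  genome_path = g$path, annotation_path = ann$path,
                  mode = "cas9", output_dir = "ebox_run")
res <- run_pipeline(cfg)
res$summary
#> motifs: 12 | guides: 24 | motifs with guides: 66.7%
#> guides per motif: 2.00 | avg on-score: 59.4 | avg off-score: 100.0
#> localization: coding_exon=0 noncoding_exon=0 intron=1 intergenic=11

head(res$guides[, c("guide_id", "protospacer", "pam", "strand", "cut_bond",
                    "off_score", "on_score")], 3)
#>              guide_id          protospacer pam strand cut_bond off_score on_score
#> 1 peak1_motif1_guide1 GCTAGGAGCTTCCAAGCACG TGG      +       81       100       75
#> 2 peak1_motif1_guide2 CTAGGAGCTTCCAAGCACGT GGG      +       82       100       75
#> 3 peak1_motif1_guide3 TAGGAGCTTCCAAGCACGTG GGG      +       83       100       75
```

Reading the output: all 12 planted E-boxes are found; 24 Cas9 guides cut
strictly inside a motif (8 of the 12 motifs have at least one, the planted
half with guaranteed PAMs plus chance PAM neighborhoods). `off_score = 100`
means the 60 kb toy genome holds no near-matches beyond each design locus;
`on_score` is the surrogate efficiency heuristic. The run directory contains `motifs.tsv`, `guides.tsv`,
`unique_guides.tsv`, `offtargets.tsv`, `summary.json`, a color-coded
`tracks.bed` for the UCSC Genome Browser, and a `manifest.json` recording
every parameter.

The same pipeline is scriptable from a shell via the installed CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/motifguides", package="motifguides"))')" \
  design --motifs CACGTG --targets targets.bed --target-format bed \
  --genome genome.fa --mode cas9 --out ebox_run
```

(subcommands: `design`, `find-motifs`, `offtargets`, `annotate`,
`fixtures`).

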