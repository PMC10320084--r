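# Genomic-context annotation: label motif intervals against gene models
# under the coding exon > non-coding exon > intron > intergenic hierarchy,
# and find the closest upstream/downstream TSS.

# 0-based half-open <-> IRanges (1-based closed) conversion helpers.
to_iranges <- function(starts, ends) IRanges::IRanges(start = starts + 1L, end = ends)
from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Build an annotation index from gene models
#'
#' Per transcript: `coding_exon` = exon intersected with the CDS,
#' `noncoding_exon` = exon minus CDS (UTRs and all exons of non-coding
#' transcripts), `intron` = transcript span minus exons. The three sets
#' tile the transcript exactly. The TSS is `tx_start` for plus-strand and
#' `tx_end - 1` for minus-strand transcripts. Every transcript contributes
#' its own intervals and TSS; overlapping transcripts are resolved at query
#' time by the classification hierarchy.
#'
#' @param gene_models Data frame from [read_gene_annotation()].
#' @return An `annotation_index`: `labels`, a per-chromosome list of data
#'   frames (`start`, `end` 0-based half-open, `category`, `gene_name`)
#'   sorted by start; `tss`, a per-chromosome list of data frames
#'   (`position`, `strand`, `gene_name`) sorted by position.
#' @export
build_annotation_index <- function(gene_models) {
  label_rows <- list()
  tss_rows <- list()
  for (i in seq_len(nrow(gene_models))) {
    gm <- gene_models[i, , drop = FALSE]
    ex_s <- gm$exon_starts[[1L]]
    ex_e <- gm$exon_ends[[1L]]
    if (any(ex_s >= ex_e) || is.unsorted(ex_s) ||
        any(ex_s < gm$tx_start) || any(ex_e > gm$tx_end)) {
      stop(sprintf("transcript '%s': exon intervals must be sorted and within the transcript",
                   gm$transcript_id), call. = FALSE)
    }
    exons <- to_iranges(ex_s, ex_e)
    tx <- to_iranges(gm$tx_start, gm$tx_end)
    cds <- if (gm$cds_start < gm$cds_end) to_iranges(gm$cds_start, gm$cds_end)
           else IRanges::IRanges()
    coding <- IRanges::intersect(exons, cds)
    noncoding <- IRanges::setdiff(exons, cds)
    introns <- IRanges::setdiff(tx, exons)
    add <- function(ir, category) {
      if (length(ir) == 0L) return(NULL)
      df <- from_iranges(ir)
      df$category <- category
      df$gene_name <- gm$gene_name
      df$chrom <- gm$chrom
      df
    }
    label_rows[[length(label_rows) + 1L]] <- do.call(rbind, Filter(Negate(is.null), list(
      add(coding, "coding_exon"), add(noncoding, "noncoding_exon"),
      add(introns, "intron")
    )))
    tss_rows[[length(tss_rows) + 1L]] <- data.frame(
      chrom = gm$chrom,
      position = if (gm$strand == "+") gm$tx_start else gm$tx_end - 1L,
      strand = gm$strand, gene_name = gm$gene_name,
      stringsAsFactors = FALSE
    )
  }
  labels_all <- do.call(rbind, label_rows)
  tss_all <- do.call(rbind, tss_rows)
  labels <- lapply(split(labels_all, labels_all$chrom), function(df) {
    df <- df[order(df$start, df$end), c("start", "end", "category", "gene_name")]
    rownames(df) <- NULL
    df
  })
  tss <- lapply(split(tss_all, tss_all$chrom), function(df) {
    df <- df[order(df$position, df$gene_name), c("position", "strand", "gene_name")]
    rownames(df) <- NULL
    df
  })
  structure(list(labels = labels, tss = tss), class = "annotation_index")
}

CATEGORY_PRIORITY <- c(coding_exon = 3L, noncoding_exon = 2L, intron = 1L,
                       intergenic = 0L)

#' Classify an interval against the annotation hierarchy
#'
#' Among all annotation labels overlapping the interval by at least one
#' nucleotide (across all transcripts), returns the highest-priority
#' category: coding exon > non-coding exon > intron; `intergenic` when
#' nothing overlaps. Boundary-spanning motifs and transcript-variant
#' conflicts therefore resolve to the most exonic/coding call.
#'
#' @param start,end 0-based half-open interval.
#' @param chrom Chromosome name.
#' @param index An [build_annotation_index()] object.
#' @return One of `"coding_exon"`, `"noncoding_exon"`, `"intron"`,
#'   `"intergenic"`.
#' @export
classify_interval <- function(start, end, chrom, index) {
  labels <- index$labels[[chrom]]
  if (is.null(labels)) {
    warning(sprintf("chromosome '%s' absent from annotation index; intergenic",
                    chrom), call. = FALSE)
    return("intergenic")
  }
  ov <- labels$start < end & labels$end > start
  if (!any(ov)) return("intergenic")
  cats <- labels$category[ov]
  names(CATEGORY_PRIORITY)[match(max(CATEGORY_PRIORITY[cats]), CATEGORY_PRIORITY)]
}

#' Closest upstream and downstream TSS for an interval
#'
#' Upstream = TSS with the largest position at or left of the interval
#' start (signed distance `tss - start`, non-positive); downstream = TSS
#' with the smallest position at or right of the interval end (distance
#' `tss - end`, non-negative). A TSS strictly inside the interval is
#' reported in both slots with distance 0. Distances are genomic
#' (browser-orientation), not gene-strand-relative. Slots are `NULL` when
#' no such TSS exists on the chromosome.
#'
#' @param start,end 0-based half-open interval.
#' @param chrom Chromosome name.
#' @param index An [build_annotation_index()] object.
#' @return List with `upstream` and `downstream`, each `NULL` or a list
#'   `gene`, `position`, `strand`, `distance`.
#' @export
closest_tss <- function(start, end, chrom, index) {
  tss <- index$tss[[chrom]]
  if (is.null(tss) || nrow(tss) == 0L) return(list(upstream = NULL, downstream = NULL))
  inside <- which(tss$position > start & tss$position < end)
  if (length(inside) > 0L) {
    i <- inside[1L]  # deterministic: smallest position, then gene name
    rec <- list(gene = tss$gene_name[i], position = tss$position[i],
                strand = tss$strand[i], distance = 0L)
    return(list(upstream = rec, downstream = rec))
  }
  up_i <- which(tss$position <= start)
  down_i <- which(tss$position >= end)
  upstream <- if (length(up_i) > 0L) {
    i <- up_i[length(up_i)]  # positions sorted ascending
    list(gene = tss$gene_name[i], position = tss$position[i],
         strand = tss$strand[i], distance = as.integer(tss$position[i] - start))
  } else NULL
  downstream <- if (length(down_i) > 0L) {
    i <- down_i[1L]
    list(gene = tss$gene_name[i], position = tss$position[i],
         strand = tss$strand[i], distance = as.integer(tss$position[i] - end))
  } else NULL
  list(upstream = upstream, downstream = downstream)
}

#' Annotate motif hits with localization and closest-TSS context
#'
#' Adds `localization`, `upstream_tss_*` and `downstream_tss_*` columns.
#' Only hits with genomic coordinates can be annotated; for others the
#' columns stay `NA`.
#'
#' @param motif_hits Motif-hit data frame.
#' @param index An [build_annotation_index()] object.
#' @return The decorated motif-hit data frame.
#' @export
annotate_motif_hits <- function(motif_hits, index) {
  n <- nrow(motif_hits)
  motif_hits$localization <- NA_character_
  for (col in c("upstream_tss_gene", "downstream_tss_gene")) {
    motif_hits[[col]] <- NA_character_
  }
  for (col in c("upstream_tss_pos", "upstream_tss_dist",
                "downstream_tss_pos", "downstream_tss_dist")) {
    motif_hits[[col]] <- NA_integer_
  }
  motif_hits$upstream_tss_strand <- NA_character_
  motif_hits$downstream_tss_strand <- NA_character_
  if (n == 0L) return(motif_hits)
  for (i in seq_len(n)) {
    if (is.na(motif_hits$chrom[i])) next
    motif_hits$localization[i] <- classify_interval(
      motif_hits$g_start[i], motif_hits$g_end[i], motif_hits$chrom[i], index)
    ct <- closest_tss(motif_hits$g_start[i], motif_hits$g_end[i],
                      motif_hits$chrom[i], index)
    if (!is.null(ct$upstream)) {
      motif_hits$upstream_tss_gene[i] <- ct$upstream$gene
      motif_hits$upstream_tss_pos[i] <- ct$upstream$position
      motif_hits$upstream_tss_dist[i] <- ct$upstream$distance
      motif_hits$upstream_tss_strand[i] <- ct$upstream$strand
    }
    if (!is.null(ct$downstream)) {
      motif_hits$downstream_tss_gene[i] <- ct$downstream$gene
      motif_hits$downstream_tss_pos[i] <- ct$downstream$position
      motif_hits$downstream_tss_dist[i] <- ct$downstream$distance
      motif_hits$downstream_tss_strand[i] <- ct$downstream$strand
    }
  }
  motif_hits
}
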