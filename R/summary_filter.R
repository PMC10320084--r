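# Result-page statistics and the documented filter/ranking pipeline.

score_histogram <- function(scores) {
  scores <- scores[!is.na(scores)]
  # bins [0,10), [10,20), ..., [90,100]
  bin <- pmin(floor(scores / 10), 9) + 1L
  counts <- tabulate(bin, nbins = 10L)
  stats::setNames(as.integer(counts),
                  paste0("[", seq(0, 90, 10), ",", seq(10, 100, 10), ")"))
}

#' Summary statistics over motif hits and guides
#'
#' Counts, percentage of motifs with at least one guide, average guides
#' per motif, average on-/off-target scores (over scored guides only),
#' 10-wide score histograms over \[0,100\], a guides-per-motif histogram,
#' and localization counts when annotation was run.
#'
#' @param motif_hits Motif-hit data frame.
#' @param guides Guide data frame (motif view: one row per motif-guide
#'   association).
#' @return A `summary_stats` list.
#' @export
summarize_results <- function(motif_hits, guides) {
  n_motifs <- nrow(motif_hits)
  n_guides <- nrow(guides)
  guides_per_motif <- if (n_motifs > 0L) {
    counts <- table(factor(guides$hit_id, levels = motif_hits$hit_id))
    as.integer(counts)
  } else integer(0)
  with_guides <- sum(guides_per_motif > 0L)
  on_sc <- guides$on_score
  off_sc <- guides$off_score
  loc <- if ("localization" %in% names(motif_hits)) {
    tab <- table(factor(motif_hits$localization,
                        levels = c("coding_exon", "noncoding_exon", "intron",
                                   "intergenic")))
    stats::setNames(as.integer(tab), names(tab))
  } else NULL
  structure(list(
    n_motifs = n_motifs,
    n_guides = n_guides,
    pct_motifs_with_guides = if (n_motifs > 0L) 100 * with_guides / n_motifs else 0,
    avg_guides_per_motif = if (n_motifs > 0L) mean(guides_per_motif) else 0,
    avg_on_score = if (any(!is.na(on_sc))) mean(on_sc, na.rm = TRUE) else NA_real_,
    avg_off_score = if (any(!is.na(off_sc))) mean(off_sc, na.rm = TRUE) else NA_real_,
    guides_per_motif_histogram = if (length(guides_per_motif) > 0L) {
      tab <- table(guides_per_motif)
      stats::setNames(as.integer(tab), names(tab))
    } else integer(0),
    on_score_histogram = score_histogram(on_sc),
    off_score_histogram = score_histogram(off_sc),
    localization_counts = loc
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("motifs: %d | guides: %d | motifs with guides: %.1f%%\n",
              x$n_motifs, x$n_guides, x$pct_motifs_with_guides))
  cat(sprintf("guides per motif: %.2f | avg on-score: %s | avg off-score: %s\n",
              x$avg_guides_per_motif,
              if (is.na(x$avg_on_score)) "-" else sprintf("%.1f", x$avg_on_score),
              if (is.na(x$avg_off_score)) "-" else sprintf("%.1f", x$avg_off_score)))
  if (!is.null(x$localization_counts)) {
    cat("localization:", paste(names(x$localization_counts),
                               x$localization_counts, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Build a filter specification
#'
#' All fields optional. Filters compose in a fixed, documented order:
#' motif-level (allowed localizations, then TSS exclusion window), then
#' guide-level score thresholds, then pruning of motifs without guides,
#' then `top_x` best guides per motif (ranked by off-score descending,
#' on-score descending, leftmost position).
#'
#' @param localizations Keep only motifs in these categories.
#' @param tss_window `c(lo, hi)`: exclude motifs whose position relative to
#'   a closest TSS falls inside `[lo, hi]` (e.g. `c(-200, 100)` for the
#'   usual CRISPRi promoter window).
#' @param tss_strand_aware If `TRUE` (default), the relative position is
#'   measured in the TSS gene's transcription direction; if `FALSE`,
#'   in genomic orientation.
#' @param min_on_score,min_off_score Guide-level score thresholds.
#' @param drop_motifs_without_guides Prune motifs left with no guides.
#' @param top_x Keep at most this many best-ranked guides per motif.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(localizations = NULL, tss_window = NULL,
                        tss_strand_aware = TRUE, min_on_score = NULL,
                        min_off_score = NULL, drop_motifs_without_guides = FALSE,
                        top_x = NULL) {
  if (!is.null(tss_window) && (length(tss_window) != 2L ||
                               tss_window[1L] > tss_window[2L])) {
    stop("tss_window must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (!is.null(localizations) &&
      !all(localizations %in% names(CATEGORY_PRIORITY))) {
    stop("localizations must be among coding_exon, noncoding_exon, intron, intergenic",
         call. = FALSE)
  }
  structure(list(
    localizations = localizations, tss_window = tss_window,
    tss_strand_aware = isTRUE(tss_strand_aware),
    min_on_score = min_on_score, min_off_score = min_off_score,
    drop_motifs_without_guides = isTRUE(drop_motifs_without_guides),
    top_x = if (is.null(top_x)) NULL else as.integer(top_x)
  ), class = "filter_spec")
}

# Position of the motif relative to a TSS, in the transcription direction
# when strand-aware. Stored distances are TSS-minus-motif-edge, so the
# motif sits at minus that value for a plus-strand gene.
motif_rel_to_tss <- function(dist, tss_strand, strand_aware) {
  sign <- if (strand_aware && !is.na(tss_strand) && tss_strand == "-") 1 else -1
  sign * dist
}

#' Apply filters to motif hits and guides
#'
#' See [filter_spec()] for the fields and the fixed composition order.
#' Motif-level filters remove motifs and their now-orphaned guides;
#' guide-level filters remove guides only. Filtering is contractive and
#' idempotent.
#'
#' @param motif_hits Motif-hit data frame.
#' @param guides Guide data frame (motif view).
#' @param spec A [filter_spec()].
#' @return List with filtered `motif_hits` and `guides`.
#' @export
apply_filters <- function(motif_hits, guides, spec) {
  stopifnot(inherits(spec, "filter_spec"))

  # 1. motif-level: localization
  if (!is.null(spec$localizations)) {
    if (!"localization" %in% names(motif_hits)) {
      stop("localization filter requires annotated motifs (coordinates + gene models)",
           call. = FALSE)
    }
    motif_hits <- motif_hits[!is.na(motif_hits$localization) &
                               motif_hits$localization %in% spec$localizations, ,
                             drop = FALSE]
  }
  # 2. motif-level: TSS exclusion window
  if (!is.null(spec$tss_window)) {
    if (!"upstream_tss_dist" %in% names(motif_hits)) {
      stop("TSS-window filter requires annotated motifs (coordinates + gene models)",
           call. = FALSE)
    }
    in_window <- vapply(seq_len(nrow(motif_hits)), function(i) {
      rels <- c(
        motif_rel_to_tss(motif_hits$upstream_tss_dist[i],
                         motif_hits$upstream_tss_strand[i], spec$tss_strand_aware),
        motif_rel_to_tss(motif_hits$downstream_tss_dist[i],
                         motif_hits$downstream_tss_strand[i], spec$tss_strand_aware)
      )
      rels <- rels[!is.na(rels)]
      any(rels >= spec$tss_window[1L] & rels <= spec$tss_window[2L])
    }, logical(1))
    if (length(in_window) > 0L) motif_hits <- motif_hits[!in_window, , drop = FALSE]
  }
  guides <- guides[guides$hit_id %in% motif_hits$hit_id, , drop = FALSE]

  # 3. guide-level score thresholds
  if (!is.null(spec$min_on_score)) {
    guides <- guides[!is.na(guides$on_score) &
                       guides$on_score >= spec$min_on_score, , drop = FALSE]
  }
  if (!is.null(spec$min_off_score)) {
    guides <- guides[!is.na(guides$off_score) &
                       guides$off_score >= spec$min_off_score, , drop = FALSE]
  }
  # 4. prune motifs with no surviving guides
  if (spec$drop_motifs_without_guides) {
    motif_hits <- motif_hits[motif_hits$hit_id %in% guides$hit_id, , drop = FALSE]
  }
  # 5. top_x best guides per motif
  if (!is.null(spec$top_x) && nrow(guides) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(guides)), guides$hit_id), function(ix) {
      ord <- order(-replace_na(guides$off_score[ix], -Inf),
                   -replace_na(guides$on_score[ix], -Inf),
                   guides$proto_start[ix])
      ix[ord][seq_len(min(spec$top_x, length(ix)))]
    }))
    guides <- guides[sort(keep), , drop = FALSE]
  }
  rownames(motif_hits) <- NULL
  rownames(guides) <- NULL
  list(motif_hits = motif_hits, guides = guides)
}

replace_na <- function(x, value) {
  x[is.na(x)] <- value
  x
}
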