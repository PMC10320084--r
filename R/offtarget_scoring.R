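# Genome-wide near-match enumeration for guides, CFD-style scoring of each
# off-target, aggregation into a 0-100 specificity score, and the pluggable
# on-target scorer.

#' Load the bundled CFD-style penalty table
#'
#' The packaged table is a synthetic stand-in with the same structure and
#' algebra as the published CFD model (per-position mismatch penalties in
#' \[0,1\], identity = 1, multiplied across mismatches and by a PAM
#' penalty); it is generated from a documented deterministic formula, not
#' the published values. A user-supplied table in the same two-file TSV
#' layout can be passed instead.
#'
#' @param mismatch_path TSV with columns `guide_base`, `site_base`,
#'   `position` (1..20 from the PAM-distal end), `penalty`.
#' @param pam_path TSV with columns `pam_suffix` (last two PAM bases),
#'   `penalty`.
#' @return A `cfd_table` list: `mismatch` (named numeric,
#'   names `"G>T@12"`-style), `pam` (named numeric by suffix),
#'   `provenance`.
#' @export
load_cfd_table <- function(mismatch_path = NULL, pam_path = NULL) {
  mismatch_path <- mismatch_path %||%
    system.file("extdata", "cfd_mismatch_synthetic.tsv", package = "motifguides")
  pam_path <- pam_path %||%
    system.file("extdata", "cfd_pam_synthetic.tsv", package = "motifguides")
  mm <- utils::read.delim(mismatch_path, comment.char = "#", stringsAsFactors = FALSE)
  pam <- utils::read.delim(pam_path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(mm$penalty < 0 | mm$penalty > 1) || any(pam$penalty < 0 | pam$penalty > 1)) {
    stop("CFD penalties must lie in [0, 1]", call. = FALSE)
  }
  ident <- mm$guide_base == mm$site_base
  if (any(mm$penalty[ident] != 1)) {
    stop("CFD identity entries must have penalty 1.0", call. = FALSE)
  }
  structure(list(
    mismatch = stats::setNames(mm$penalty,
                               paste0(mm$guide_base, ">", mm$site_base, "@", mm$position)),
    pam = stats::setNames(pam$penalty, pam$pam_suffix),
    provenance = paste("loaded from", basename(mismatch_path))
  ), class = "cfd_table")
}

#' CFD-style activity score for one off-target site
#'
#' Product over mismatched positions of the mismatch penalty
#' `(guide_base, site_base, position)`, multiplied by the PAM penalty of
#' the observed PAM (keyed on its last two bases). A perfect match at a
#' canonical-PAM site scores exactly 1.
#'
#' @param protospacer 20-nt guide sequence, 5'->3' (PAM-distal first).
#' @param site_sequence 20-nt genomic site aligned to the guide, same
#'   orientation.
#' @param pam_observed Observed PAM sequence at the site (>= 2 nt).
#' @param table A [load_cfd_table()] object.
#' @return Numeric in \[0, 1\].
#' @export
cfd_score <- function(protospacer, site_sequence, pam_observed,
                      table = load_cfd_table()) {
  g <- strsplit(toupper(protospacer), "", fixed = TRUE)[[1L]]
  s <- strsplit(toupper(site_sequence), "", fixed = TRUE)[[1L]]
  if (length(g) != 20L || length(s) != 20L) {
    stop("protospacer and site must both be 20 nt (gap-free alignment)",
         call. = FALSE)
  }
  mm <- which(g != s)
  score <- 1.0
  if (length(mm) > 0L) {
    keys <- paste0(g[mm], ">", s[mm], "@", mm)
    pen <- table$mismatch[keys]
    if (anyNA(pen)) {
      bad <- keys[which(is.na(pen))[1L]]
      stop(sprintf("CFD table has no entry for mismatch %s", bad), call. = FALSE)
    }
    score <- prod(pen)
  }
  suffix <- toupper(substr(pam_observed, nchar(pam_observed) - 1L, nchar(pam_observed)))
  pam_pen <- table$pam[suffix]
  if (is.na(pam_pen)) {
    stop(sprintf("CFD table has no PAM penalty for suffix '%s'", suffix),
         call. = FALSE)
  }
  unname(score * pam_pen)
}

#' Aggregate off-target CFD values into a 0-100 specificity score
#'
#' `score = 100 / (1 + sum(cfd))` over all off-target hits, excluding the
#' guide's own design locus: 100 with no off-targets, 50 when the CFD sum
#' reaches 1, strictly decreasing as positive-CFD hits accumulate. The
#' exact value is returned; round only for display.
#'
#' @param cfd Numeric vector of per-off-target CFD values.
#' @return Numeric in (0, 100].
#' @export
cumulative_specificity <- function(cfd) {
  if (length(cfd) == 0L) return(100)
  100 / (1 + sum(cfd))
}

# PAM-site positions (0-based starts) on the plus strand of `seq_txt` using
# an overlap-tolerant regex compiled from the IUPAC pattern.
regex_pam_starts <- function(seq_txt, pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  rx <- paste0("(?=", paste(vapply(chars, iupac_regex_class, character(1)),
                            collapse = ""), ")")
  m <- gregexpr(rx, seq_txt, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Enumerate genomic near-matches of a protospacer
#'
#' Finds every PAM-adjacent 20-mer on both strands of the genome that
#' differs from the protospacer at no more than `max_mismatches` positions
#' and whose PAM matches `pam_pattern`. Sites containing `N` are skipped.
#' The guide's own design locus (exact coordinate match, when supplied) is
#' flagged `is_on_target`; for guides without coordinates, the first
#' perfect-match site in chromosome/position order is flagged as the
#' presumed design locus. On-target rows are excluded from specificity
#' aggregation by [score_offtargets()] but additional perfect matches count
#' as off-targets with CFD computed like any other site.
#'
#' @param protospacer 20-nt guide sequence.
#' @param genome Named character vector from [read_genome()].
#' @param pam_pattern PAM IUPAC pattern.
#' @param max_mismatches 0..4 (4 = standard mode, 3 = rapid mode).
#' @param on_target Optional list/one-row data frame with `chrom`,
#'   `g_start` (0-based start of the 20-nt site) and `strand` of the design
#'   locus.
#' @param table CFD table, or `NULL` to skip CFD and report mismatch counts
#'   only.
#' @param guide_id Label carried into the report.
#' @return Off-target data frame: `guide_id`, `chrom`, `g_start`, `strand`,
#'   `site_sequence` (guide-aligned 5'->3'), `pam_observed`,
#'   `mismatch_count`, `mismatch_positions` (comma-joined, 1..20 from the
#'   PAM-distal end), `cfd`, `is_on_target`.
#' @export
enumerate_offtargets <- function(protospacer, genome, pam_pattern = "NGG",
                                 max_mismatches = 4L, on_target = NULL,
                                 table = load_cfd_table(), guide_id = "guide") {
  protospacer <- validate_dna(protospacer, "protospacer", allow_n = FALSE)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt", call. = FALSE)
  if (!max_mismatches %in% 0:4) stop("max_mismatches must be in 0..4", call. = FALSE)
  if (is.null(genome) || length(genome) == 0L) {
    stop("genome missing: off-target search needs genome sequences", call. = FALSE)
  }
  pam_pattern <- validate_iupac(pam_pattern, "PAM pattern")
  L <- nchar(pam_pattern)
  g_chars <- strsplit(protospacer, "", fixed = TRUE)[[1L]]
  rc_chars <- strsplit(reverse_complement(protospacer), "", fixed = TRUE)[[1L]]

  per_chrom <- lapply(names(genome), function(chrom) {
    seq_txt <- toupper(genome[[chrom]])
    n <- nchar(seq_txt)
    res <- list()

    # plus strand: protospacer at [p-20, p), PAM at [p, p+L)
    p <- regex_pam_starts(seq_txt, pam_pattern)
    p <- p[p >= 20L & p + L <= n]
    if (length(p) > 0L) {
      sites <- substring(seq_txt, p - 19L, p)
      pams <- substring(seq_txt, p + 1L, p + L)
      mmc <- hamming_to_guide(sites, g_chars)
      ok <- !is.na(mmc) & mmc <= max_mismatches
      if (any(ok)) {
        res[["+"]] <- data.frame(
          chrom = chrom, g_start = p[ok] - 20L, strand = "+",
          site_sequence = sites[ok], pam_observed = pams[ok],
          mismatch_count = mmc[ok], stringsAsFactors = FALSE
        )
      }
    }
    # minus strand: revcomp(PAM) at [q, q+L), protospacer (plus coords) at
    # [q+L, q+L+20); guide-aligned site = revcomp of that span
    q <- regex_pam_starts(seq_txt, reverse_complement(pam_pattern))
    q <- q[q + L + 20L <= n]
    if (length(q) > 0L) {
      span <- substring(seq_txt, q + L + 1L, q + L + 20L)
      pam_span <- substring(seq_txt, q + 1L, q + L)
      # compare plus-strand span against revcomp(guide): mismatch positions
      # then mirror to guide coordinates
      mm_pos_plus <- mismatch_positions_to(span, rc_chars)
      mmc <- vapply(mm_pos_plus, function(v) if (is.null(v)) NA_integer_ else length(v),
                    integer(1))
      ok <- !is.na(mmc) & mmc <= max_mismatches
      if (any(ok)) {
        res[["-"]] <- data.frame(
          chrom = chrom, g_start = q[ok] + L, strand = "-",
          site_sequence = vapply(span[ok], reverse_complement, character(1),
                                 USE.NAMES = FALSE),
          pam_observed = vapply(pam_span[ok], reverse_complement, character(1),
                                USE.NAMES = FALSE),
          mismatch_count = mmc[ok], stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, res)
  })
  hits <- do.call(rbind, per_chrom)
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- empty_offtargets()
    return(out)
  }
  hits <- hits[order(hits$chrom, hits$g_start, hits$strand), , drop = FALSE]

  hits$mismatch_positions <- vapply(hits$site_sequence, function(site) {
    s <- strsplit(site, "", fixed = TRUE)[[1L]]
    paste(which(s != g_chars), collapse = ",")
  }, character(1), USE.NAMES = FALSE)

  hits$cfd <- if (is.null(table)) {
    NA_real_
  } else {
    vapply(seq_len(nrow(hits)), function(i) {
      cfd_score(protospacer, hits$site_sequence[i], hits$pam_observed[i], table)
    }, numeric(1))
  }

  hits$is_on_target <- FALSE
  if (!is.null(on_target) && !is.na(on_target$chrom %||% NA)) {
    hits$is_on_target <- hits$chrom == on_target$chrom &
      hits$g_start == on_target$g_start & hits$strand == on_target$strand
  } else {
    perfect <- which(hits$mismatch_count == 0L)
    if (length(perfect) > 0L) hits$is_on_target[perfect[1L]] <- TRUE
  }
  hits$guide_id <- guide_id
  rownames(hits) <- NULL
  hits[, names(empty_offtargets()), drop = FALSE]
}

# Hamming distance of each site string to the guide; NA when the site
# contains a non-ACGT character (assembly gaps etc. are skipped).
hamming_to_guide <- function(sites, g_chars) {
  if (length(sites) == 0L) return(integer(0))
  M <- matrix(unlist(strsplit(sites, "", fixed = TRUE), use.names = FALSE),
              nrow = 20L)
  has_n <- colSums(matrix(!M %in% c("A", "C", "G", "T"), nrow = 20L)) > 0L
  d <- colSums(M != g_chars)
  d[has_n] <- NA_integer_
  as.integer(d)
}

mismatch_positions_to <- function(sites, ref_chars) {
  lapply(strsplit(sites, "", fixed = TRUE), function(s) {
    if (any(!s %in% c("A", "C", "G", "T"))) return(NULL)
    which(s != ref_chars)
  })
}

#' Score a guide set against a genome
#'
#' Runs [enumerate_offtargets()] for each distinct protospacer, computes
#' the per-mismatch-class census and the cumulative specificity score
#' (excluding the on-target locus), and writes them back onto the guide
#' records.
#'
#' @param guides Guide data frame.
#' @param genome Named character vector.
#' @param config A [design_config()].
#' @param table CFD table or `NULL` (mismatch-count-only reporting, with a
#'   warning).
#' @return List: `guides` (scored), `offtargets` (combined report).
#' @export
score_offtargets <- function(guides, genome, config, table = load_cfd_table()) {
  if (is.null(table)) {
    warning("no CFD table: reporting mismatch counts only, no specificity score",
            call. = FALSE)
  }
  if (nrow(guides) == 0L) return(list(guides = guides, offtargets = empty_offtargets()))
  key <- paste(guides$protospacer, guides$chrom, guides$g_proto_start, guides$strand,
               sep = "|")
  first_idx <- which(!duplicated(key))
  reports <- lapply(first_idx, function(i) {
    on <- if (!is.na(guides$chrom[i])) {
      list(chrom = guides$chrom[i], g_start = guides$g_proto_start[i],
           strand = guides$strand[i])
    } else NULL
    enumerate_offtargets(guides$protospacer[i], genome,
                         pam_pattern = config$pam_pattern,
                         max_mismatches = config$max_mismatches,
                         on_target = on, table = table,
                         guide_id = guides$guide_id[i])
  })
  names(reports) <- key[first_idx]
  for (r in seq_len(nrow(guides))) {
    rep_r <- reports[[key[r]]]
    off <- rep_r[!rep_r$is_on_target, , drop = FALSE]
    for (k in 0:4) {
      guides[[paste0("off_mm", k)]][r] <- sum(off$mismatch_count == k)
    }
    guides$off_score[r] <- if (is.null(table)) NA_real_ else
      cumulative_specificity(off$cfd)
  }
  offtargets <- do.call(rbind, unname(reports))
  rownames(offtargets) <- NULL
  list(guides = guides, offtargets = offtargets)
}

# ---- on-target scoring --------------------------------------------------

.scorers <- new.env(parent = emptyenv())

#' Register an on-target scorer
#'
#' A scorer is a function taking the extended context sequence (4 nt
#' context + 20 nt protospacer + PAM + 3 nt context, 5'->3' on the guide
#' strand) and returning a score in \[0, 100\]. Registering under an
#' existing name replaces it; external models (e.g. an Azimuth wrapper) can
#' be plugged in this way without touching the pipeline.
#'
#' @param name Scorer name.
#' @param fun Scoring function.
#' @export
register_on_target_scorer <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .scorers)
  invisible(name)
}

# Deterministic built-in scorer:
# 50 + 25*(protospacer GC% in [40, 60]) - 25*(homopolymer run >= 5 in the
# protospacer), clamped to [0, 100]. A transparent heuristic encoding two
# well-known design preferences (moderate GC, no long homopolymers); not a
# trained efficiency model.
surrogate_scorer <- function(context) {
  proto <- substr(toupper(context), 5L, 24L)
  chars <- strsplit(proto, "", fixed = TRUE)[[1L]]
  gc <- 100 * mean(chars %in% c("G", "C"))
  runs <- rle(chars)
  homopoly <- any(runs$lengths >= 5L)
  score <- 50 + 25 * (gc >= 40 && gc <= 60) - 25 * homopoly
  min(100, max(0, score))
}

#' On-target efficiency score via a registered scorer
#'
#' @param context The extended context sequence (see
#'   [register_on_target_scorer()]), or `NA` when the guide sits too close
#'   to the sequence end to provide context.
#' @param scorer Name of a registered scorer; `"surrogate"` is the built-in
#'   deterministic heuristic.
#' @return Score in \[0, 100\], or `NA` (unscored) when context is missing.
#' @export
on_target_score <- function(context, scorer = "surrogate") {
  if (is.na(context)) return(NA_real_)
  fun <- get0(scorer, envir = .scorers)
  if (is.null(fun)) stop(sprintf("no registered on-target scorer '%s'", scorer),
                         call. = FALSE)
  fun(context)
}

#' Extract a guide's extended scoring context from its target sequence
#'
#' 4 nt upstream context + 20 nt protospacer + observed PAM + 3 nt
#' downstream context, on the guide strand. `NA` when the target sequence
#' cannot provide the full window.
#'
#' @param guide One-row guide data frame.
#' @param sequence The target-region sequence the guide was designed on.
#' @return Context string or `NA`.
#' @export
guide_context <- function(guide, sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (guide$strand == "+") {
    s <- guide$proto_start - 4L
    e <- guide$pam_end + 3L
    if (s < 0L || e > n) return(NA_character_)
    substr(sequence, s + 1L, e)
  } else {
    s <- guide$pam_start - 3L
    e <- guide$proto_end + 4L
    if (s < 0L || e > n) return(NA_character_)
    reverse_complement(substr(sequence, s + 1L, e))
  }
}
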