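# Motif engine: matrix -> IUPAC consensus, IUPAC pattern matching, and
# both-strand motif location in target sequences.

#' Reverse complement of a DNA or IUPAC string
#'
#' IUPAC-aware: ambiguity codes are complemented as sets (R<->Y, K<->M,
#' B<->V, D<->H; S, W and N are their own complements).
#'
#' @param x A single IUPAC/DNA string.
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("CACGTG")  # palindromic E-box
#' reverse_complement("GGATA")
#' @export
reverse_complement <- function(x) {
  x <- validate_iupac(x, "sequence")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Compile an IUPAC motif into a positional base-set matcher
#'
#' Each motif position becomes the set of unambiguous bases it accepts.
#' Matching is case-insensitive on the target side. A genomic `N` (assembly
#' gap / unknown base) never satisfies any motif position, including motif
#' `N`: ambiguity in the pattern widens acceptance, ambiguity in the genome
#' does not.
#'
#' @param iupac A single IUPAC string.
#' @return A list of character vectors (allowed bases per position), with
#'   attribute `iupac` carrying the normalized pattern.
#' @export
iupac_to_matcher <- function(iupac) {
  iupac <- validate_iupac(iupac, "motif")
  chars <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  matcher <- IUPAC_BASES[chars]
  attr(matcher, "iupac") <- iupac
  matcher
}

#' Does a sequence window match an IUPAC pattern?
#'
#' @param sequence DNA string of the same length as the pattern.
#' @param iupac IUPAC pattern.
#' @return Logical scalar.
#' @export
matches_iupac <- function(sequence, iupac) {
  m <- iupac_to_matcher(iupac)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(chars) != length(m)) return(FALSE)
  all(vapply(seq_along(m), function(i) chars[i] %in% m[[i]], logical(1)))
}

#' Convert a count matrix to an IUPAC consensus motif
#'
#' Per column, base frequencies are `f_b = count_b / column_total`. Rule
#' `min_frequency` includes every base with `f_b >= threshold` (falling back
#' to the most frequent base when nothing qualifies). Rule `cumulative`
#' sorts bases by descending frequency (ties broken alphabetically A<C<G<T)
#' and includes them until the running sum first reaches the threshold. The
#' included set maps to its unique IUPAC code.
#'
#' @param matrix A count matrix as returned by [read_motif_input()]: a list
#'   with `motif_id`, `counts` (4 x L numeric matrix, rows A,C,G,T) and
#'   `dialect`.
#' @param rule `"min_frequency"` or `"cumulative"`.
#' @param threshold Frequency threshold in (0, 1]. Default 0.25.
#' @return A one-row motif data frame (see [read_motif_input()]).
#' @export
matrix_to_iupac <- function(matrix, rule = c("min_frequency", "cumulative"),
                            threshold = 0.25) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  counts <- matrix$counts
  if (is.null(counts) || nrow(counts) != 4L) {
    stop("count matrix must have 4 rows (A, C, G, T)", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  codes <- vapply(seq_len(ncol(counts)), function(j) {
    col <- counts[, j]
    total <- sum(col)
    if (total <= 0) {
      stop(sprintf("column %d of matrix '%s' has zero total count",
                   j, matrix$motif_id), call. = FALSE)
    }
    f <- col / total
    included <- if (rule == "min_frequency") {
      inc <- bases[f >= threshold]
      if (length(inc) == 0L) bases[which.max(f)] else inc
    } else {
      ord <- order(-f, bases)  # descending frequency, alphabetical ties
      csum <- cumsum(f[ord])
      k <- which(csum >= threshold - 1e-12)[1L]
      sort(bases[ord[seq_len(k)]])
    }
    SET_TO_CODE[[paste(sort(included), collapse = "")]]
  }, character(1))
  motif_spec(
    motif_id = matrix$motif_id,
    name = matrix$motif_id,
    iupac = paste(codes, collapse = ""),
    source = "matrix",
    matrix_ref = matrix$motif_id
  )
}

# One-row MotifSpec data frame.
motif_spec <- function(motif_id, name, iupac, source = "sequence",
                       matrix_ref = NA_character_) {
  data.frame(
    motif_id = motif_id, name = name,
    iupac = validate_iupac(iupac, "motif"),
    source = source, matrix_ref = matrix_ref,
    stringsAsFactors = FALSE
  )
}

# Core scan: all start positions (0-based) where `matcher` matches `chars`.
# Genomic N never matches (IUPAC_BASES sets contain only A/C/G/T).
scan_positions <- function(chars, matcher) {
  L <- length(matcher)
  n <- length(chars)
  if (L > n) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & chars[j:(n - L + j)] %in% matcher[[j]]
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

#' Locate all occurrences of a motif on both strands of a sequence
#'
#' Every position where the motif pattern matches the plus strand yields a
#' `+` hit; every position where its reverse complement matches yields a `-`
#' hit. Overlapping matches are all reported. When the motif is its own
#' reverse complement (e.g. the CACGTG E-box), the `+` and `-` hits at one
#' interval are the same molecular site, so only the `+` record is kept.
#' Hits are sorted by start position, then strand.
#'
#' @param motif IUPAC string, or a one-row motif data frame.
#' @param region Target sequence string, or a one-row target-region data
#'   frame as returned by [read_targets()].
#' @return A motif-hit data frame with columns `motif_id`, `region_name`,
#'   `rel_start`, `rel_end` (0-based half-open in the supplied sequence),
#'   `strand`, `matched_sequence` (always the plus-strand text), and genomic
#'   `chrom`, `g_start`, `g_end` when the region carries coordinates.
#' @export
find_motifs <- function(motif, region) {
  if (is.data.frame(motif)) {
    stopifnot(nrow(motif) == 1L)
    iupac <- motif$iupac
    motif_id <- motif$motif_id
  } else {
    iupac <- motif
    motif_id <- "motif"
  }
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    sequence <- region$sequence
    region_name <- region$name
    has_coords <- !is.na(region$chrom)
    g_origin <- if (has_coords) region$start - region$extended_left else NA_integer_
    chrom <- region$chrom
  } else {
    sequence <- region
    region_name <- "region"
    has_coords <- FALSE
    g_origin <- NA_integer_
    chrom <- NA_character_
  }
  iupac <- validate_iupac(iupac, "motif")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  L <- nchar(iupac)

  fwd <- scan_positions(chars, iupac_to_matcher(iupac))
  rc <- reverse_complement(iupac)
  rev <- scan_positions(chars, iupac_to_matcher(rc))
  if (identical(rc, iupac)) {
    # palindrome: identical-interval +/- duplicates collapse onto +
    rev <- setdiff(rev, fwd)
  }

  starts <- c(fwd, rev)
  strands <- c(rep("+", length(fwd)), rep("-", length(rev)))
  if (length(starts) == 0L) return(empty_motif_hits())
  ord <- order(starts, strands)
  starts <- starts[ord]
  strands <- strands[ord]

  hits <- data.frame(
    hit_id = NA_character_,
    motif_id = motif_id,
    region_name = region_name,
    rel_start = as.integer(starts),
    rel_end = as.integer(starts + L),
    strand = strands,
    matched_sequence = substring(paste(chars, collapse = ""),
                                 starts + 1L, starts + L),
    chrom = chrom,
    g_start = if (has_coords) as.integer(g_origin + starts) else NA_integer_,
    g_end = if (has_coords) as.integer(g_origin + starts + L) else NA_integer_,
    stringsAsFactors = FALSE
  )
  hits
}

#' Scan a set of motifs across a set of target regions
#'
#' Applies [find_motifs()] to every motif/region pair and assigns hit names
#' (`{region}_motif{i}`, `i` 1-based in coordinate order within a region).
#'
#' @param motifs Motif data frame (one or more rows).
#' @param targets Target-region data frame from [read_targets()].
#' @return Combined motif-hit data frame.
#' @export
scan_motifs <- function(motifs, targets) {
  out <- lapply(seq_len(nrow(targets)), function(r) {
    region <- targets[r, , drop = FALSE]
    per_motif <- lapply(seq_len(nrow(motifs)), function(m) {
      find_motifs(motifs[m, , drop = FALSE], region)
    })
    hits <- do.call(rbind, per_motif)
    if (nrow(hits) == 0L) return(hits)
    hits <- hits[order(hits$rel_start, hits$rel_end, hits$strand,
                       hits$motif_id), , drop = FALSE]
    hits$hit_id <- paste0(region$name, "_motif", seq_len(nrow(hits)))
    hits
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res)) empty_motif_hits() else res
}
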