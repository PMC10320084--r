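# Independent brute-force oracles. These deliberately re-derive IUPAC
# semantics, motif matching, off-target enumeration and interval
# classification through different routes (regex engine, all-window
# matrices, per-base painting) than the package implementation.

ORACLE_IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

ORACLE_COMP <- c(A = "T", T = "A", C = "G", G = "C", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_rc <- function(x) {
  paste(rev(unname(ORACLE_COMP[strsplit(x, "")[[1L]]])), collapse = "")
}

oracle_iupac_regex <- function(iupac) {
  paste(sprintf("[%s]", unname(ORACLE_IUPAC[strsplit(iupac, "")[[1L]]])),
        collapse = "")
}

# All 0-based start positions where the IUPAC pattern matches the plus
# strand, via an overlap-tolerant regex. Genomic N never matches because
# the character classes only contain A/C/G/T.
oracle_scan <- function(sequence, iupac) {
  rx <- paste0("(?=", oracle_iupac_regex(iupac), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# Both-strand position checker with palindrome collapsing; returns a data
# frame comparable to find_motifs() output (rel_start, strand).
oracle_find_motifs <- function(iupac, sequence) {
  fwd <- oracle_scan(sequence, iupac)
  rc <- oracle_rc(iupac)
  rev <- oracle_scan(sequence, rc)
  if (identical(rc, iupac)) rev <- setdiff(rev, fwd)
  df <- rbind(
    data.frame(rel_start = fwd, strand = rep("+", length(fwd))),
    data.frame(rel_start = rev, strand = rep("-", length(rev)))
  )
  df[order(df$rel_start, df$strand), , drop = FALSE]
}

# Literal per-window checker (slow path) for small sequences: double-checks
# the regex oracle through yet another route.
oracle_find_motifs_literal <- function(iupac, sequence) {
  L <- nchar(iupac)
  n <- nchar(sequence)
  ok_window <- function(window, pat) {
    w <- strsplit(window, "")[[1L]]
    p <- strsplit(pat, "")[[1L]]
    all(vapply(seq_len(L), function(j) {
      grepl(w[j], ORACLE_IUPAC[[p[j]]], fixed = TRUE) && w[j] %in% c("A","C","G","T")
    }, logical(1)))
  }
  rc <- oracle_rc(iupac)
  rows <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      win <- substr(sequence, s + 1L, s + L)
      f <- ok_window(win, iupac)
      r <- ok_window(win, rc)
      if (identical(rc, iupac) && f) r <- FALSE
      if (f) rows[[length(rows) + 1L]] <- data.frame(rel_start = s, strand = "+")
      if (r) rows[[length(rows) + 1L]] <- data.frame(rel_start = s, strand = "-")
    }
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(rel_start = integer(0), strand = character(0))
  df[order(df$rel_start, df$strand), , drop = FALSE]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_iupac <- function(n) {
  # mostly concrete bases with occasional ambiguity codes
  codes <- names(ORACLE_IUPAC)
  probs <- c(rep(5, 4), rep(1, 11))
  paste(sample(codes, n, replace = TRUE, prob = probs), collapse = "")
}

# Naive every-window Hamming scan over both strands of a genome. Scans the
# reverse complement of each chromosome for minus-strand sites and maps
# coordinates back, so it shares no code with the PAM-anchored search.
# Returns (chrom, g_start, strand, mismatch_count) for sites with a
# pattern-matching PAM; windows containing N are skipped.
oracle_offtargets <- function(spacer, genome, pam_pattern = "NGG",
                              max_mm = 4L) {
  g <- strsplit(spacer, "")[[1L]]
  L <- nchar(pam_pattern)
  pam_rx <- paste0("^", oracle_iupac_regex(pam_pattern), "$")
  scan_strand <- function(seq_txt) {
    n <- nchar(seq_txt)
    if (n < 20L + L) return(NULL)
    chars <- strsplit(seq_txt, "")[[1L]]
    starts <- 0:(n - 20L - L)
    idx <- outer(1:20, starts, "+")  # 1-based index of window chars
    M <- matrix(chars[idx], nrow = 20L)
    mm <- colSums(M != g)
    bad <- colSums(matrix(!(M %in% c("A", "C", "G", "T")), nrow = 20L)) > 0L
    pam_txt <- substring(seq_txt, starts + 21L, starts + 20L + L)
    keep <- !bad & mm <= max_mm & grepl(pam_rx, pam_txt, perl = TRUE)
    if (!any(keep)) return(NULL)
    data.frame(start = starts[keep], mismatch_count = as.integer(mm[keep]))
  }
  out <- list()
  for (chrom in names(genome)) {
    seq_txt <- genome[[chrom]]
    n <- nchar(seq_txt)
    plus <- scan_strand(seq_txt)
    if (!is.null(plus)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, g_start = plus$start, strand = "+",
        mismatch_count = plus$mismatch_count, stringsAsFactors = FALSE)
    }
    minus <- scan_strand(oracle_rc(seq_txt))
    if (!is.null(minus)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, g_start = n - minus$start - 20L, strand = "-",
        mismatch_count = minus$mismatch_count, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(chrom = character(0), g_start = integer(0),
               strand = character(0), mismatch_count = integer(0))
  df <- df[order(df$chrom, df$g_start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Per-base painting oracle for interval classification: paints every base
# of each transcript with increasing priority, then reduces an interval to
# its highest-priority label.
oracle_paint_labels <- function(gene_models, chrom_lengths) {
  prio <- c(intergenic = 0L, intron = 1L, noncoding_exon = 2L, coding_exon = 3L)
  labs <- lapply(chrom_lengths, function(n) rep("intergenic", n))
  for (i in seq_len(nrow(gene_models))) {
    gm <- gene_models[i, , drop = FALSE]
    la <- labs[[gm$chrom]]
    put <- function(la, s, e, cat) {
      if (e <= s) return(la)
      sel <- (s + 1L):e
      la[sel][prio[la[sel]] < prio[[cat]]] <- cat
      la
    }
    la <- put(la, gm$tx_start, gm$tx_end, "intron")
    es <- gm$exon_starts[[1L]]; ee <- gm$exon_ends[[1L]]
    for (j in seq_along(es)) la <- put(la, es[j], ee[j], "noncoding_exon")
    if (gm$cds_start < gm$cds_end) {
      for (j in seq_along(es)) {
        la <- put(la, max(es[j], gm$cds_start), min(ee[j], gm$cds_end),
                  "coding_exon")
      }
    }
    labs[[gm$chrom]] <- la
  }
  labs
}

oracle_classify <- function(start, end, chrom, labs) {
  prio <- c(intergenic = 0L, intron = 1L, noncoding_exon = 2L, coding_exon = 3L)
  if (!chrom %in% names(labs)) return("intergenic")
  seen <- labs[[chrom]][(start + 1L):end]
  names(prio)[prio == max(prio[seen])]
}

# Small helper: write a named character vector of sequences as FASTA.
write_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  close(con)
  path
}
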