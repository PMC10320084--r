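# Readers and writers for every external format the pipeline touches:
# motifs (inline/FASTA/csv/JASPAR/TRANSFAC), targets (raw/FASTA/BED +
# genome), refGene-style gene annotation, and result tables/tracks.

#' Read a genome from a multi-record FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop(sprintf("genome file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read motifs from inline text, FASTA, csv, or matrix formats
#'
#' Sequence dialects (`inline`, `fasta`, `csv`) return IUPAC motif records;
#' matrix dialects (`jaspar`, `transfac`) return count matrices to be
#' collapsed with [matrix_to_iupac()]. `inline` also accepts comma- or
#' newline-separated lists.
#'
#' @param text_or_path Motif text, or a path to a file holding it.
#' @param declared_format One of `inline`, `fasta`, `csv`, `jaspar`,
#'   `transfac`.
#' @return For sequence dialects, a motif data frame (columns `motif_id`,
#'   `name`, `iupac`, `source`, `matrix_ref`); for matrix dialects, a list
#'   of count matrices, each a list with `motif_id`, `counts` (4 x L, rows
#'   A,C,G,T) and `dialect`.
#' @export
read_motif_input <- function(text_or_path,
                             declared_format = c("inline", "fasta", "csv",
                                                 "jaspar", "transfac")) {
  declared_format <- match.arg(declared_format)
  txt <- slurp(text_or_path)
  switch(declared_format,
    inline = ,
    csv = {
      pieces <- unlist(strsplit(txt, "[,\r\n]+"))
      pieces <- trimws(pieces)
      pieces <- pieces[nzchar(pieces)]
      if (length(pieces) == 0L) stop("no motifs found in input", call. = FALSE)
      do.call(rbind, lapply(seq_along(pieces), function(i) {
        motif_spec(paste0("motif", i), paste0("motif", i), pieces[i])
      }))
    },
    fasta = {
      recs <- parse_fasta_text(txt)
      do.call(rbind, lapply(seq_along(recs), function(i) {
        motif_spec(names(recs)[i], names(recs)[i], recs[[i]])
      }))
    },
    jaspar = parse_jaspar(txt),
    transfac = parse_transfac(txt)
  )
}

slurp <- function(text_or_path) {
  is_path <- length(text_or_path) == 1L && !grepl("[\r\n>]", text_or_path) &&
    file.exists(text_or_path)
  if (is_path) {
    paste(readLines(text_or_path, warn = FALSE), collapse = "\n")
  } else {
    paste(text_or_path, collapse = "\n")
  }
}

parse_fasta_text <- function(txt) {
  lines <- strsplit(txt, "\r?\n")[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers ('>') found", call. = FALSE)
  idx <- cumsum(hdr)
  if (idx[1L] == 0L) stop("sequence data before first FASTA header", call. = FALSE)
  headers <- sub("^>\\s*", "", lines[hdr])
  headers <- sub("\\s.*$", "", headers)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1), collapse = "")
  out <- as.list(toupper(gsub("\\s", "", seqs)))
  names(out) <- headers[as.integer(names(seqs))]
  out
}

# JASPAR dialect:  optional ">ID name" header, then 4 rows like
#   A  [ 4 19  0  0 ]     (brackets optional)
parse_jaspar <- function(txt) {
  lines <- strsplit(txt, "\r?\n")[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  blocks <- split(lines, cumsum(grepl("^>", lines)))
  lapply(unname(blocks), function(bl) {
    id <- "matrix1"
    if (grepl("^>", bl[1L])) {
      id <- sub("\\s.*$", "", sub("^>\\s*", "", bl[1L]))
      bl <- bl[-1L]
    }
    rows <- lapply(bl, function(ln) {
      ln <- gsub("[][]", " ", ln)
      toks <- strsplit(trimws(ln), "\\s+")[[1L]]
      list(base = toupper(toks[1L]), counts = suppressWarnings(as.numeric(toks[-1L])))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stop(sprintf("JASPAR block '%s' must have exactly the rows A, C, G, T", id),
           call. = FALSE)
    }
    lens <- vapply(rows, function(r) length(r$counts), integer(1))
    if (length(unique(lens)) != 1L) {
      stop(sprintf("ragged JASPAR matrix '%s': row lengths %s", id,
                   paste(lens, collapse = ",")), call. = FALSE)
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    check_matrix_columns(counts, id)
    list(motif_id = id, counts = counts, dialect = "jaspar")
  })
}

# TRANSFAC dialect: ID/NA line names the matrix; P0 line gives column order;
# numbered rows are per-position counts; '//' separates records.
parse_transfac <- function(txt) {
  lines <- strsplit(txt, "\r?\n")[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  blocks <- split(lines, cumsum(c(0, utils::head(grepl("^//", lines), -1))))
  out <- lapply(unname(blocks), function(bl) {
    bl <- bl[!grepl("^//", bl)]
    if (length(bl) == 0L) return(NULL)
    id_line <- grep("^(ID|NA)\\s", bl, value = TRUE)
    id <- if (length(id_line) > 0L) {
      strsplit(trimws(id_line[1L]), "\\s+")[[1L]][2L]
    } else "matrix1"
    p0 <- grep("^P0|^PO", bl, value = TRUE)
    order_bases <- if (length(p0) > 0L) {
      toupper(strsplit(trimws(p0[1L]), "\\s+")[[1L]][-1L])[1:4]
    } else c("A", "C", "G", "T")
    pos_lines <- grep("^[0-9]+\\s", bl, value = TRUE)
    if (length(pos_lines) == 0L) {
      stop(sprintf("TRANSFAC block '%s' has no position rows", id), call. = FALSE)
    }
    vals <- lapply(pos_lines, function(ln) {
      toks <- strsplit(trimws(ln), "\\s+")[[1L]][-1L]
      suppressWarnings(as.numeric(toks[1:4]))
    })
    bad <- which(vapply(vals, function(v) anyNA(v), logical(1)))
    if (length(bad) > 0L) {
      stop(sprintf("TRANSFAC matrix '%s': column %d does not have 4 numeric counts",
                   id, bad[1L]), call. = FALSE)
    }
    counts <- do.call(cbind, vals)
    rownames(counts) <- order_bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    check_matrix_columns(counts, id)
    list(motif_id = id, counts = counts, dialect = "transfac")
  })
  out[!vapply(out, is.null, logical(1))]
}

check_matrix_columns <- function(counts, id) {
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop(sprintf("matrix '%s' contains negative or missing counts", id),
         call. = FALSE)
  }
  zero <- which(colSums(counts) == 0)
  if (length(zero) > 0L) {
    stop(sprintf("matrix '%s': column %d has no positive count", id, zero[1L]),
         call. = FALSE)
  }
  invisible(counts)
}

#' Read a BED file into a data frame
#'
#' Skips `track` and comment lines. Columns beyond the first six are
#' ignored.
#'
#' @param path BED file path.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand` (`NA` where absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed BED line %d: fewer than 3 fields", line_no[i]),
           call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("malformed BED line %d: non-numeric coordinates", line_no[i]),
           call. = FALSE)
    }
    if (start >= end) {
      stop(sprintf("malformed BED line %d: start (%d) must be < end (%d)",
                   line_no[i], start, end), call. = FALSE)
    }
    data.frame(
      chrom = f[1L], start = start, end = end,
      name = if (length(f) >= 4L) f[4L] else NA_character_,
      score = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else NA_real_,
      strand = if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read target regions from raw text, FASTA, or BED coordinates
#'
#' BED targets are extended by `extension` nucleotides on each side (clamped
#' at chromosome bounds) before the sequence is fetched from the genome, so
#' that guides can be designed for motifs at the border of the region. Raw
#' and FASTA targets are taken verbatim and carry no genomic coordinates.
#' Both strands are always searched downstream, so any BED strand column is
#' ignored here.
#'
#' @param text_or_path Target text or file path.
#' @param declared_format One of `raw`, `fasta`, `bed`.
#' @param genome Named character vector from [read_genome()]; required for
#'   `bed` input.
#' @param extension Nucleotides added at each border of BED targets
#'   (default 30).
#' @return Target-region data frame: `name`, `chrom`, `start`, `end`
#'   (0-based half-open, `NA` for sequence input), `sequence`,
#'   `extended_left`, `extended_right`, `origin`.
#' @export
read_targets <- function(text_or_path, declared_format = c("raw", "fasta", "bed"),
                         genome = NULL, extension = 30L) {
  declared_format <- match.arg(declared_format)
  if (declared_format == "bed" && is.null(genome)) {
    stop("BED targets require a genome to fetch sequence from", call. = FALSE)
  }
  if (extension < 0) stop("extension must be non-negative", call. = FALSE)

  targets <- switch(declared_format,
    raw = {
      txt <- slurp(text_or_path)
      pieces <- trimws(unlist(strsplit(txt, "[,\r\n]+")))
      pieces <- pieces[nzchar(pieces)]
      do.call(rbind, lapply(seq_along(pieces), function(i) {
        data.frame(
          name = NA_character_, chrom = NA_character_,
          start = NA_integer_, end = NA_integer_,
          sequence = validate_dna(pieces[i], sprintf("target %d", i)),
          extended_left = 0L, extended_right = 0L, origin = "raw",
          stringsAsFactors = FALSE
        )
      }))
    },
    fasta = {
      recs <- parse_fasta_text(slurp(text_or_path))
      do.call(rbind, lapply(seq_along(recs), function(i) {
        data.frame(
          name = names(recs)[i], chrom = NA_character_,
          start = NA_integer_, end = NA_integer_,
          sequence = validate_dna(recs[[i]], sprintf("target '%s'", names(recs)[i])),
          extended_left = 0L, extended_right = 0L, origin = "fasta",
          stringsAsFactors = FALSE
        )
      }))
    },
    bed = {
      bed <- if (is.data.frame(text_or_path)) text_or_path else {
        path <- text_or_path
        if (!file.exists(path)) {
          tf <- tempfile(fileext = ".bed")
          writeLines(strsplit(slurp(text_or_path), "\r?\n")[[1L]], tf)
          path <- tf
        }
        read_bed(path)
      }
      do.call(rbind, lapply(seq_len(nrow(bed)), function(i) {
        chrom <- bed$chrom[i]
        if (!chrom %in% names(genome)) {
          stop(sprintf("chromosome '%s' (BED row %d) not present in genome",
                       chrom, i), call. = FALSE)
        }
        chrom_len <- nchar(genome[[chrom]])
        if (bed$end[i] > chrom_len) {
          stop(sprintf("BED row %d: end %d beyond chromosome '%s' length %d",
                       i, bed$end[i], chrom, chrom_len), call. = FALSE)
        }
        ext_l <- min(extension, bed$start[i])
        ext_r <- min(extension, chrom_len - bed$end[i])
        fetch_start <- bed$start[i] - ext_l  # 0-based
        fetch_end <- bed$end[i] + ext_r
        data.frame(
          name = bed$name[i], chrom = chrom,
          start = bed$start[i], end = bed$end[i],
          sequence = substr(genome[[chrom]], fetch_start + 1L, fetch_end),
          extended_left = as.integer(ext_l), extended_right = as.integer(ext_r),
          origin = "bed", stringsAsFactors = FALSE
        )
      }))
    }
  )
  assign_region_names(targets)
}

# Fill in generic names ("target{k}") and disambiguate duplicates.
assign_region_names <- function(targets) {
  nm <- targets$name
  generic <- is.na(nm) | !nzchar(nm)
  nm[generic] <- paste0("target", which(generic))
  dup <- duplicated(nm)
  if (any(dup)) {
    warning("duplicate region names disambiguated with numeric suffixes",
            call. = FALSE)
    for (i in which(dup)) {
      k <- 2L
      while (paste0(nm[i], "_", k) %in% nm) k <- k + 1L
      nm[i] <- paste0(nm[i], "_", k)
    }
  }
  targets$name <- nm
  rownames(targets) <- NULL
  targets
}

#' Read gene models from a refGene-style dump
#'
#' Accepts UCSC `ncbiRefSeqCurated`-style tab-separated rows (with or
#' without the leading `bin` column, with or without a header line);
#' comma-terminated exon coordinate lists are tolerated. All coordinates
#' are 0-based half-open as stored by UCSC.
#'
#' @param path File path.
#' @return Gene-model data frame with columns `gene_name`, `transcript_id`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, and
#'   list-columns `exon_starts`, `exon_ends`. Non-coding transcripts have
#'   `cds_start == cds_end`.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    # with bin column strand is field 4, without it field 3
    off <- if (length(f) >= 4L && f[4L] %in% c("+", "-")) 1L
           else if (length(f) >= 3L && f[3L] %in% c("+", "-")) 0L
           else return(NULL)  # header or junk line
    if (length(f) < off + 10L) {
      stop(sprintf("annotation row %d: too few columns", i), call. = FALSE)
    }
    ex_s <- parse_coord_list(f[off + 9L])
    ex_e <- parse_coord_list(f[off + 10L])
    if (length(ex_s) != length(ex_e)) {
      stop(sprintf("annotation row %d (%s): exonStarts/exonEnds lengths differ (%d vs %d)",
                   i, f[off + 1L], length(ex_s), length(ex_e)), call. = FALSE)
    }
    n_exon <- suppressWarnings(as.integer(f[off + 8L]))
    if (!is.na(n_exon) && n_exon != length(ex_s)) {
      stop(sprintf("annotation row %d (%s): exonCount %d but %d exons listed",
                   i, f[off + 1L], n_exon, length(ex_s)), call. = FALSE)
    }
    gene <- if (length(f) >= off + 12L && nzchar(f[off + 12L])) f[off + 12L]
            else f[off + 1L]
    data.frame(
      gene_name = gene, transcript_id = f[off + 1L],
      chrom = f[off + 2L], strand = f[off + 3L],
      tx_start = as.integer(f[off + 4L]), tx_end = as.integer(f[off + 5L]),
      cds_start = as.integer(f[off + 6L]), cds_end = as.integer(f[off + 7L]),
      exon_starts = I(list(ex_s)), exon_ends = I(list(ex_e)),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no gene-model rows found", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

parse_coord_list <- function(x) {
  toks <- strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1L]]
  as.integer(toks)
}

# ---- result export ------------------------------------------------------

# Score bin -> itemRgb color for browser tracks.
SCORE_COLORS <- data.frame(
  lo = c(0, 30, 50, 80),
  hi = c(30, 50, 80, 100.01),
  rgb = c("255,0,0", "255,165,0", "255,255,0", "0,200,0"),  # red/orange/yellow/green
  stringsAsFactors = FALSE
)

#' Map a 0-100 score to a browser-track color
#'
#' Bins `[0,30)` red, `[30,50)` orange, `[50,80)` yellow, `[80,100]` green;
#' unscored guides are gray.
#'
#' @param score Numeric vector of scores (NA allowed).
#' @return Character vector of `"r,g,b"` strings.
#' @export
score_color <- function(score) {
  vapply(score, function(s) {
    if (is.na(s)) return("128,128,128")
    i <- which(s >= SCORE_COLORS$lo & s < SCORE_COLORS$hi)[1L]
    if (is.na(i)) "128,128,128" else SCORE_COLORS$rgb[i]
  }, character(1))
}

motif_table <- function(motif_hits) {
  data.frame(
    motif_name = motif_hits$hit_id,
    motif_id = motif_hits$motif_id,
    region = motif_hits$region_name,
    matched_sequence = motif_hits$matched_sequence,
    chrom = motif_hits$chrom,
    # tables are 1-based inclusive; internal storage 0-based half-open
    start = motif_hits$g_start + 1L,
    end = motif_hits$g_end,
    rel_start = motif_hits$rel_start + 1L,
    rel_end = motif_hits$rel_end,
    strand = motif_hits$strand,
    localization = if ("localization" %in% names(motif_hits))
      motif_hits$localization else NA_character_,
    upstream_tss_gene = pick_col(motif_hits, "upstream_tss_gene"),
    upstream_tss_pos = pick_num(motif_hits, "upstream_tss_pos") + 1L,
    upstream_tss_distance = pick_num(motif_hits, "upstream_tss_dist"),
    downstream_tss_gene = pick_col(motif_hits, "downstream_tss_gene"),
    downstream_tss_pos = pick_num(motif_hits, "downstream_tss_pos") + 1L,
    downstream_tss_distance = pick_num(motif_hits, "downstream_tss_dist"),
    stringsAsFactors = FALSE
  )
}

pick_col <- function(df, col) if (col %in% names(df)) df[[col]] else rep(NA_character_, nrow(df))
pick_num <- function(df, col) if (col %in% names(df)) df[[col]] else rep(NA_integer_, nrow(df))

guide_table <- function(guides) {
  data.frame(
    guide_name = guides$guide_id,
    motifs = guides$motif_ids,
    region = guides$region_name,
    protospacer = guides$protospacer,
    pam = guides$pam,
    chrom = guides$chrom,
    start = guides$g_proto_start + 1L,
    end = guides$g_proto_end,
    rel_start = guides$proto_start + 1L,
    rel_end = guides$proto_end,
    strand = guides$strand,
    cut_bond = guides$cut_bond,
    on_score = guides$on_score,
    off_score = guides$off_score,
    off_mm0 = guides$off_mm0, off_mm1 = guides$off_mm1, off_mm2 = guides$off_mm2,
    off_mm3 = guides$off_mm3, off_mm4 = guides$off_mm4,
    stringsAsFactors = FALSE
  )
}

#' Write motif and guide results as tables or browser tracks
#'
#' Tabular formats (`tsv`, `csv`) write a per-motif table and a
#' per-unique-guide table as two files (`<stem>_motifs.<ext>`,
#' `<stem>_guides.<ext>`); `xlsx` places them on two sheets of one file
#' (requires the writexl or openxlsx package at run time); `bed` writes one
#' file with two track blocks (motifs, guides), guide color encoding the
#' chosen score via `itemRgb`. Table coordinates are 1-based inclusive; BED
#' coordinates 0-based half-open.
#'
#' @param motif_hits Motif-hit data frame.
#' @param guides Guide data frame (typically [unique_guides()] output).
#' @param format One of `tsv`, `csv`, `xlsx`, `bed`.
#' @param destination Output stem (without extension).
#' @param color_by Which score drives BED guide colors: `off_score`
#'   (default) or `on_score`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(motif_hits, guides, format = c("tsv", "csv", "xlsx", "bed"),
                          destination, color_by = c("off_score", "on_score")) {
  format <- match.arg(format)
  color_by <- match.arg(color_by)
  mt <- motif_table(motif_hits)
  gt <- guide_table(guides)
  paths <- switch(format,
    tsv = ,
    csv = {
      sepc <- if (format == "tsv") "\t" else ","
      p1 <- paste0(destination, "_motifs.", format)
      p2 <- paste0(destination, "_guides.", format)
      utils::write.table(mt, p1, sep = sepc, quote = FALSE, row.names = FALSE, na = "")
      utils::write.table(gt, p2, sep = sepc, quote = FALSE, row.names = FALSE, na = "")
      c(p1, p2)
    },
    xlsx = {
      p <- paste0(destination, ".xlsx")
      if (requireNamespace("writexl", quietly = TRUE)) {
        writexl::write_xlsx(list(motifs = mt, unique_guides = gt), p)
      } else if (requireNamespace("openxlsx", quietly = TRUE)) {
        openxlsx::write.xlsx(list(motifs = mt, unique_guides = gt), p)
      } else {
        stop("xlsx export needs the 'writexl' or 'openxlsx' package; ",
             "use tsv/csv/bed instead", call. = FALSE)
      }
      p
    },
    bed = {
      p <- paste0(destination, ".bed")
      write_tracks_bed(motif_hits, guides, p, color_by)
      p
    }
  )
  invisible(paths)
}

write_tracks_bed <- function(motif_hits, guides, path, color_by = "off_score") {
  if ((nrow(motif_hits) > 0L && anyNA(motif_hits$chrom)) ||
      (nrow(guides) > 0L && anyNA(guides$chrom))) {
    stop("BED export requires genomic coordinates; raw/FASTA targets have none",
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track name="motifs" description="motif occurrences" itemRgb="On"', con)
  if (nrow(motif_hits) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0,0,255",
                       motif_hits$chrom, motif_hits$g_start, motif_hits$g_end,
                       motif_hits$hit_id, motif_hits$strand,
                       motif_hits$g_start, motif_hits$g_end), con)
  }
  writeLines(sprintf('track name="guides" description="sgRNAs colored by %s" itemRgb="On"',
                     color_by), con)
  if (nrow(guides) > 0L) {
    score <- guides[[color_by]]
    shown <- ifelse(is.na(score), 0, round(score))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t%s",
                       guides$chrom, guides$g_proto_start, guides$g_proto_end,
                       guides$guide_id, shown, guides$strand,
                       guides$g_proto_start, guides$g_proto_end,
                       score_color(score)), con)
  }
  invisible(path)
}

#' Write an annotation index to per-chromosome BED files
#'
#' One BED file per chromosome, label (coding_exon / noncoding_exon /
#' intron) in the name column, plus a `<chrom>_tss.bed` of TSS positions.
#'
#' @param index Annotation index from [build_annotation_index()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_annotation_bed <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (chrom in names(index$labels)) {
    df <- index$labels[[chrom]]
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, df$start, df$end, df$category),
               file.path(dir, paste0(chrom, ".bed")))
  }
  for (chrom in names(index$tss)) {
    df <- index$tss[[chrom]]
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, df$position, df$position + 1L,
                       df$gene_name, df$strand),
               file.path(dir, paste0(chrom, "_tss.bed")))
  }
  invisible(dir)
}
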