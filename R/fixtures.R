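# Seed-deterministic synthetic genomes, planted motifs/off-targets and toy
# gene annotations with full ground truth, emitted in the same external
# formats the pipeline consumes (FASTA, refGene-style TSV), so tests
# exercise the real parsers.

write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate a reproducible random toy genome
#'
#' @param n_chroms Number of chromosomes.
#' @param length Length of each chromosome (>= 1000).
#' @param gc Target GC fraction.
#' @param seed RNG seed; the same seed always yields an identical file.
#' @param path Output FASTA path (default: tempfile).
#' @return List: `path`, `sequences` (named character vector), `index`
#'   (data frame of chromosome lengths), `seed`.
#' @export
make_toy_genome <- function(n_chroms = 1L, length = 10000L, gc = 0.5,
                            seed = 1L, path = tempfile(fileext = ".fa")) {
  if (length < 1000L) stop("chromosome length must be >= 1000", call. = FALSE)
  seqs <- with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    out <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    stats::setNames(out, paste0("chr", seq_len(n_chroms)))
  })
  write_fasta(seqs, path)
  list(path = path, sequences = seqs,
       index = data.frame(chrom = names(seqs), length = nchar(seqs),
                          row.names = NULL, stringsAsFactors = FALSE),
       seed = seed)
}

instantiate_iupac <- function(iupac) {
  chars <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(c) {
    opts <- IUPAC_BASES[[c]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

splice <- function(seq, start0, text) {
  # overwrite seq at 0-based position start0 with text
  paste0(substr(seq, 1L, start0), text,
         substr(seq, start0 + nchar(text) + 1L, nchar(seq)))
}

#' Plant concrete motif instances into a genome at recorded loci
#'
#' Writes `n` instantiations of the IUPAC motif (random choice per
#' ambiguity code) at non-overlapping loci, half on each strand
#' (minus-strand plantings write the reverse complement). For at least
#' half of the sites an `NGG` PAM is written immediately so that a
#' Cas9-mode guide cutting inside the motif exists, and 20 nt of
#' protospacer room is kept on each side.
#'
#' @param genome A [make_toy_genome()] result (or compatible list with
#'   `sequences` and `path`).
#' @param motif_iupac Motif to plant.
#' @param n Number of placements.
#' @param seed RNG seed.
#' @param rewrite If `TRUE` (default) the modified genome is rewritten to
#'   `genome$path`.
#' @return The genome list with updated `sequences`, plus `truth`: a data
#'   frame of planted occurrences (`chrom`, `start`, `end`, `strand`,
#'   `sequence` as plus-strand text, `pam_guaranteed`).
#' @export
plant_motifs <- function(genome, motif_iupac, n, seed = 1L, rewrite = TRUE) {
  motif_iupac <- validate_iupac(motif_iupac, "motif")
  L <- nchar(motif_iupac)
  seqs <- genome$sequences
  res <- with_seed(seed, {
    chroms <- names(seqs)
    margin <- 30L  # room for protospacers/PAMs around each site
    slot <- L + 10L
    placements <- list()
    occupied <- lapply(seqs, function(s) integer(0))
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in 1:200) {
        chrom <- sample(chroms, 1L)
        max_start <- nchar(seqs[[chrom]]) - L - margin
        if (max_start <= margin) next
        start <- sample(margin:max_start, 1L)
        clash <- any(abs(occupied[[chrom]] - start) < slot + 10L)
        if (!clash) {
          occupied[[chrom]] <- c(occupied[[chrom]], start)
          placements[[i]] <- list(chrom = chrom, start = start)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("insufficient space to plant all motifs", call. = FALSE)
    }
    truth <- list()
    for (i in seq_len(n)) {
      chrom <- placements[[i]]$chrom
      start <- placements[[i]]$start
      strand <- if (i %% 2L == 1L) "+" else "-"
      inst <- instantiate_iupac(motif_iupac)
      plus_text <- if (strand == "+") inst else reverse_complement(inst)
      seqs[[chrom]] <- splice(seqs[[chrom]], start, plus_text)
      pam_guaranteed <- i <= ceiling(n / 2)
      if (pam_guaranteed) {
        # a +-strand NGG with pam_start = motif_end - 1 puts the cut bond at
        # motif_end - 4, strictly inside any motif of length >= 5
        pam_start <- start + L - 1L
        seqs[[chrom]] <- splice(seqs[[chrom]], pam_start + 1L, "GG")
      }
      truth[[i]] <- data.frame(
        chrom = chrom, start = start, end = start + L, strand = strand,
        sequence = substr(seqs[[chrom]], start + 1L, start + L),
        pam_guaranteed = pam_guaranteed, stringsAsFactors = FALSE
      )
    }
    list(seqs = seqs, truth = do.call(rbind, truth))
  })
  genome$sequences <- res$seqs
  genome$truth <- res$truth
  if (rewrite) write_fasta(genome$sequences, genome$path)
  genome
}

#' Plant near-copies of a protospacer as controlled off-target sites
#'
#' For each requested mismatch count `k`, writes one copy of
#' `spacer + "TGG"` with exactly `k` substitutions confined to the
#' protospacer (never the PAM) at a recorded locus on the plus strand.
#'
#' @param genome A [make_toy_genome()] result.
#' @param spacer 20-nt protospacer.
#' @param mismatch_counts Integer vector, each in 0..4.
#' @param seed RNG seed.
#' @param rewrite Rewrite `genome$path` (default `TRUE`).
#' @return The genome list with `offtarget_truth`: data frame `chrom`,
#'   `start` (0-based start of the 20-nt site), `mismatches`,
#'   `site_sequence`.
#' @export
plant_offtargets <- function(genome, spacer, mismatch_counts, seed = 1L,
                             rewrite = TRUE) {
  spacer <- validate_dna(spacer, "spacer", allow_n = FALSE)
  if (nchar(spacer) != 20L) stop("spacer must be 20 nt", call. = FALSE)
  seqs <- genome$sequences
  res <- with_seed(seed, {
    chroms <- names(seqs)
    bases <- c("A", "C", "G", "T")
    used <- lapply(seqs, function(s) integer(0))
    truth <- list()
    for (j in seq_along(mismatch_counts)) {
      k <- mismatch_counts[j]
      stopifnot(k %in% 0:4)
      repeat {
        chrom <- sample(chroms, 1L)
        max_start <- nchar(seqs[[chrom]]) - 23L - 10L
        start <- sample(10L:max_start, 1L)
        if (!any(abs(used[[chrom]] - start) < 40L)) break
      }
      used[[chrom]] <- c(used[[chrom]], start)
      site <- strsplit(spacer, "", fixed = TRUE)[[1L]]
      if (k > 0L) {
        pos <- sample(1:20, k)
        for (p in pos) site[p] <- sample(setdiff(bases, site[p]), 1L)
      }
      site_txt <- paste(site, collapse = "")
      seqs[[chrom]] <- splice(seqs[[chrom]], start, paste0(site_txt, "TGG"))
      truth[[j]] <- data.frame(
        chrom = chrom, start = start, mismatches = as.integer(k),
        site_sequence = site_txt, stringsAsFactors = FALSE
      )
    }
    list(seqs = seqs, truth = do.call(rbind, truth))
  })
  genome$sequences <- res$seqs
  genome$offtarget_truth <- res$truth
  if (rewrite) write_fasta(genome$sequences, genome$path)
  genome
}

#' Generate a toy gene annotation with per-base ground truth
#'
#' Random non-overlapping transcripts (1-4 exons each, both strands, a mix
#' of coding and non-coding) written as a refGene-style tab-separated dump.
#' The ground-truth labels are painted base by base with the
#' coding > non-coding > intron priority — an independent construction of
#' the categories the interval index derives by set algebra.
#'
#' @param genome A [make_toy_genome()] result.
#' @param n_genes Number of transcripts.
#' @param seed RNG seed.
#' @param path Output annotation path (default: tempfile).
#' @return List: `path`, `gene_models` (the written models re-read through
#'   [read_gene_annotation()] would equal these), `truth_labels`
#'   (per-chromosome character vector labeling every base), `tss_truth`
#'   (data frame `chrom`, `position`, `strand`, `gene_name`), `seed`.
#' @export
make_toy_annotation <- function(genome, n_genes = 5L, seed = 1L,
                                path = tempfile(fileext = ".txt")) {
  res <- with_seed(seed, {
    chroms <- names(genome$sequences)
    lens <- nchar(genome$sequences)
    rows <- list()
    occupied <- lapply(genome$sequences, function(s) cbind(start = integer(0), end = integer(0)))
    for (g in seq_len(n_genes)) {
      placed <- FALSE
      for (attempt in 1:300) {
        chrom <- sample(chroms, 1L)
        span <- sample(300:900, 1L)
        if (lens[[chrom]] < span + 20L) next
        tx_start <- sample(0:(lens[[chrom]] - span), 1L)
        tx_end <- tx_start + span
        occ <- occupied[[chrom]]
        if (nrow(occ) > 0L && any(occ[, "start"] < tx_end & occ[, "end"] > tx_start)) next
        occupied[[chrom]] <- rbind(occ, cbind(start = tx_start, end = tx_end))
        placed <- TRUE
        break
      }
      if (!placed) stop("genes do not fit in the genome", call. = FALSE)
      n_exon <- sample(1:4, 1L)
      # split the span into exons separated by introns
      cuts <- sort(sample(seq(tx_start + 20L, tx_end - 20L, by = 10L),
                          2L * (n_exon - 1L)))
      bounds <- c(tx_start, cuts, tx_end)
      ex_s <- bounds[seq(1L, length(bounds), by = 2L)]
      ex_e <- bounds[seq(2L, length(bounds), by = 2L)]
      strand <- sample(c("+", "-"), 1L)
      coding <- stats::runif(1) < 0.7
      if (coding) {
        # CDS starts inside the first exon and ends inside the last
        cds_start <- ex_s[1L] + sample(1:(ex_e[1L] - ex_s[1L] - 1L), 1L)
        cds_end <- ex_s[n_exon] + sample(1:(ex_e[n_exon] - ex_s[n_exon] - 1L), 1L)
        if (cds_end <= cds_start) { tmp <- cds_start; cds_start <- cds_end; cds_end <- tmp + 1L }
      } else {
        cds_start <- cds_end <- tx_start
      }
      rows[[g]] <- data.frame(
        gene_name = paste0("gene", g), transcript_id = paste0("tx", g),
        chrom = chrom, strand = strand,
        tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
        cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
        exon_starts = I(list(as.integer(ex_s))), exon_ends = I(list(as.integer(ex_e))),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
  gene_models <- res
  rownames(gene_models) <- NULL

  # per-base truth, painted independently with increasing priority
  truth_labels <- lapply(genome$sequences, function(s) {
    rep("intergenic", nchar(s))
  })
  for (i in seq_len(nrow(gene_models))) {
    gm <- gene_models[i, , drop = FALSE]
    lab <- truth_labels[[gm$chrom]]
    paint <- function(lab, s, e, category) {
      if (e <= s) return(lab)
      idx <- (s + 1L):e
      pr <- CATEGORY_PRIORITY[lab[idx]]
      upgrade <- CATEGORY_PRIORITY[[category]] > pr
      lab[idx[upgrade]] <- category
      lab
    }
    lab <- paint(lab, gm$tx_start, gm$tx_end, "intron")
    for (j in seq_along(gm$exon_starts[[1L]])) {
      lab <- paint(lab, gm$exon_starts[[1L]][j], gm$exon_ends[[1L]][j],
                   "noncoding_exon")
    }
    if (gm$cds_start < gm$cds_end) {
      for (j in seq_along(gm$exon_starts[[1L]])) {
        s <- max(gm$exon_starts[[1L]][j], gm$cds_start)
        e <- min(gm$exon_ends[[1L]][j], gm$cds_end)
        lab <- paint(lab, s, e, "coding_exon")
      }
    }
    truth_labels[[gm$chrom]] <- lab
  }
  tss_truth <- data.frame(
    chrom = gene_models$chrom,
    position = ifelse(gene_models$strand == "+", gene_models$tx_start,
                      gene_models$tx_end - 1L),
    strand = gene_models$strand, gene_name = gene_models$gene_name,
    stringsAsFactors = FALSE
  )

  # refGene-style dump (with bin column, comma-terminated exon lists)
  lines <- vapply(seq_len(nrow(gene_models)), function(i) {
    gm <- gene_models[i, , drop = FALSE]
    paste(c(
      0L, gm$transcript_id, gm$chrom, gm$strand, gm$tx_start, gm$tx_end,
      gm$cds_start, gm$cds_end, length(gm$exon_starts[[1L]]),
      paste0(paste(gm$exon_starts[[1L]], collapse = ","), ","),
      paste0(paste(gm$exon_ends[[1L]], collapse = ","), ","),
      0L, gm$gene_name, "cmpl", "cmpl",
      paste0(paste(rep(0L, length(gm$exon_starts[[1L]])), collapse = ","), ",")
    ), collapse = "\t")
  }, character(1))
  writeLines(lines, path)

  list(path = path, gene_models = gene_models, truth_labels = truth_labels,
       tss_truth = tss_truth, seed = seed)
}
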