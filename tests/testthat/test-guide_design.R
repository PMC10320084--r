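# Exhaustive geometry oracle: enumerate every PAM window on both strands
# by regex and apply the mode rule arithmetically.
oracle_design <- function(sequence, ms, me, mode, pam_pattern = "NGG",
                          max_dist = NULL) {
  n <- nchar(sequence)
  L <- nchar(pam_pattern)
  rows <- list()
  for (p in 0:(n - L)) {
    win <- substr(sequence, p + 1, p + L)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pam_pattern else oracle_rc(pam_pattern)
      if (!grepl(paste0("^", oracle_iupac_regex(pat), "$"), win, perl = TRUE)) next
      proto_s <- if (strand == "+") p - 20L else p + L
      proto_e <- proto_s + 20L
      if (proto_s < 0L || proto_e > n) next
      bond <- if (strand == "+") p - 3L else p + L + 3L
      keep <- switch(mode,
        cas9 = bond >= ms + 1L && bond <= me - 1L,
        dcas9 = proto_s < me && proto_e > ms,
        custom = {
          gap <- if (p + L <= ms) ms - (p + L) else if (me <= p) p - me else 0L
          gap <= max_dist
        })
      if (keep) rows[[length(rows) + 1L]] <-
          data.frame(proto_start = proto_s, strand = strand)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(proto_start = integer(0), strand = character(0))
  df[order(df$proto_start, df$strand), , drop = FALSE]
}

# write fixed text into a random background at given 0-based offsets
random_dna_with <- function(inserts, n) {
  s <- strsplit(random_dna(n), "")[[1]]
  for (ins in inserts) {
    at <- as.integer(ins[1]); txt <- strsplit(ins[2], "")[[1]]
    s[(at + 1):(at + length(txt))] <- txt
  }
  paste(s, collapse = "")
}

mk_hit <- function(ms, me, region = "r") {
  data.frame(hit_id = paste0(region, "_motif1"), motif_id = "m",
             region_name = region, rel_start = ms, rel_end = me,
             strand = "+", matched_sequence = "NNNNNN", chrom = NA_character_,
             g_start = NA_integer_, g_end = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("scan_pams finds both strands and discards truncated protospacers", {
  # both candidate PAMs on this 11-mer lack protospacer room
  expect_equal(nrow(scan_pams("ACGTAGGACCT", "NGG")), 0L)
  # with room, the same windows are retained
  seq <- paste0(strrep("A", 20), "TAGGACCT", strrep("A", 20))
  pams <- scan_pams(seq, "NGG")
  expect_true(any(pams$strand == "+" & pams$pam_start == 21L))  # AGG
  expect_true(any(pams$strand == "-" & pams$pam_start == 25L))  # CCT = rc(AGG)
  # NGCG: only 4-nt windows ending GCG qualify
  seq2 <- paste0(strrep("T", 25), "AGCG", strrep("T", 25))
  p2 <- scan_pams(seq2, "NGCG")
  expect_equal(p2$pam_start[p2$strand == "+"], 25L)
  expect_equal(p2$pam_end[p2$strand == "+"], 29L)
})

test_that("cas9 cut-bond rule and dcas9 overlap rule resolve the worked geometries", {
  seq <- random_dna_with(list(c(30, "AGG"), c(35, "TGG")), 80)
  cfg9 <- design_config("NGG", "cas9")
  cfgd <- design_config("NGG", "dcas9")
  # + PAM at [29,32): cut bond 26, inside motif [25,31)
  hit <- mk_hit(25L, 31L)
  pam <- data.frame(pam_start = 29L, pam_end = 32L, strand = "+")
  g <- design_guides(hit, pam, cfg9, seq)
  expect_equal(nrow(g), 1L)
  expect_equal(g$cut_bond, 26L)
  expect_equal(g$proto_start, 9L)
  # + PAM at [34,37): cut bond 31 = motif end -> rejected by cas9,
  # accepted by dcas9 (protospacer [14,34) overlaps by 6)
  pam2 <- data.frame(pam_start = 34L, pam_end = 37L, strand = "+")
  expect_equal(nrow(design_guides(hit, pam2, cfg9, seq)), 0L)
  gd <- design_guides(hit, pam2, cfgd, seq)
  expect_equal(nrow(gd), 1L)
  expect_true(is.na(gd$cut_bond))
  # minimal 1-nt dcas9 overlap: motif [24,30), protospacer [5,25)
  hit2 <- mk_hit(24L, 30L)
  pam3 <- data.frame(pam_start = 25L, pam_end = 28L, strand = "+")
  expect_equal(nrow(design_guides(hit2, pam3, cfgd, seq)), 1L)
})

test_that("custom mode measures the PAM-to-motif gap and is monotone in distance", {
  seq <- random_dna(120)
  hit <- mk_hit(50L, 56L)
  pam_sites <- scan_pams(seq, "NGG")
  counts <- vapply(c(0L, 2L, 5L, 10L, 25L), function(d) {
    nrow(design_guides(hit, pam_sites, design_config("NGG", "custom",
                                                     custom_max_distance = d), seq))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  # spot-check the gap rule: PAM touching the motif edge has gap 0
  pam <- data.frame(pam_start = 56L, pam_end = 59L, strand = "+")
  expect_equal(nrow(design_guides(hit, pam, design_config("NGG", "custom",
                                                          custom_max_distance = 0L), seq)), 1L)
  # 3 bases strictly between -> needs distance >= 3
  pam2 <- data.frame(pam_start = 59L, pam_end = 62L, strand = "+")
  expect_equal(nrow(design_guides(hit, pam2, design_config("NGG", "custom",
                                                           custom_max_distance = 2L), seq)), 0L)
  expect_equal(nrow(design_guides(hit, pam2, design_config("NGG", "custom",
                                                           custom_max_distance = 3L), seq)), 1L)
})

test_that("design matches the exhaustive position/strand oracle on random sequences", {
  set.seed(61)
  for (i in 1:25) {
    seq <- random_dna(sample(150:400, 1))
    ms <- sample(40:(nchar(seq) - 60), 1)
    me <- ms + sample(5:10, 1)
    hit <- mk_hit(ms, me)
    pams <- scan_pams(seq, "NGG")
    for (mode in c("cas9", "dcas9", "custom")) {
      cfg <- design_config("NGG", mode,
                           custom_max_distance = if (mode == "custom") 7L else NULL)
      got <- design_guides(hit, pams, cfg, seq)[, c("proto_start", "strand")]
      want <- oracle_design(seq, ms, me, mode, max_dist = 7L)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = paste(mode, i))
    }
  }
})

test_that("protospacer and PAM text are extracted strand-correctly", {
  set.seed(71)
  seq <- random_dna(200)
  hit <- mk_hit(80L, 88L)
  pams <- scan_pams(seq, "NGG")
  g <- design_guides(hit, pams, design_config("NGG", "dcas9"), seq)
  for (r in seq_len(nrow(g))) {
    if (g$strand[r] == "+") {
      expect_identical(g$protospacer[r],
                       substr(seq, g$proto_start[r] + 1, g$proto_end[r]))
      expect_match(g$pam[r], "^.GG$")
    } else {
      expect_identical(g$protospacer[r],
                       oracle_rc(substr(seq, g$proto_start[r] + 1, g$proto_end[r])))
      expect_match(g$pam[r], "^.GG$")
      expect_identical(g$pam[r],
                       oracle_rc(substr(seq, g$pam_start[r] + 1, g$pam_end[r])))
    }
    expect_equal(nchar(g$protospacer[r]), 20L)
  }
})

test_that("dcas9 guides are a superset of cas9 guides on identical inputs", {
  set.seed(81)
  for (i in 1:10) {
    seq <- random_dna(300)
    ms <- sample(60:220, 1); me <- ms + 6L
    hit <- mk_hit(ms, me)
    pams <- scan_pams(seq, "NGG")
    key <- function(g) paste(g$proto_start, g$strand)
    k9 <- key(design_guides(hit, pams, design_config("NGG", "cas9"), seq))
    kd <- key(design_guides(hit, pams, design_config("NGG", "dcas9"), seq))
    expect_true(all(k9 %in% kd))
  }
})

test_that("naming follows the region/motif/guide scheme with 1-based coordinate order", {
  seqs <- c(peakA = paste0(strrep("T", 30), "CACGTGCGG", strrep("T", 30),
                           "CACGTGAGG", strrep("T", 30)))
  targets <- data.frame(name = "peakA", chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, sequence = seqs[[1]],
                        extended_left = 0L, extended_right = 0L, origin = "fasta",
                        stringsAsFactors = FALSE)
  motifs <- read_motif_input("CACGTG", "inline")
  hits <- scan_motifs(motifs, targets)
  expect_identical(hits$hit_id, c("peakA_motif1", "peakA_motif2"))
  guides <- design_all_guides(hits, targets, design_config("NGG", "cas9"))
  expect_true(all(grepl("^peakA_motif[12]_guide[0-9]+$", guides$guide_id)))
  # guide numbering restarts per motif and follows coordinate order
  g1 <- guides[guides$hit_id == "peakA_motif1", ]
  expect_identical(g1$guide_id, paste0("peakA_motif1_guide", seq_len(nrow(g1))))
  expect_true(all(diff(g1$proto_start) >= 0))
})

test_that("unique_guides merges only identical-position duplicates and unions motif ids", {
  base <- design_all_guides(
    scan_motifs(read_motif_input("AACGTT", "inline"),
                data.frame(name = "r", chrom = NA_character_, start = NA_integer_,
                           end = NA_integer_,
                           sequence = paste0(strrep("G", 25), "AACGTTAACGTT", strrep("G", 25)),
                           extended_left = 0L, extended_right = 0L, origin = "raw",
                           stringsAsFactors = FALSE)),
    data.frame(name = "r",
               sequence = paste0(strrep("G", 25), "AACGTTAACGTT", strrep("G", 25)),
               stringsAsFactors = FALSE),
    design_config("NGG", "dcas9"))
  uq <- unique_guides(base)
  expect_lte(nrow(uq), nrow(base))
  # overlapping motifs share guides -> merged records carry both motif ids
  shared <- uq[grepl(",", uq$motif_ids), ]
  expect_gt(nrow(shared), 0L)
  # all-distinct input is a no-op
  distinct <- base[!duplicated(paste(base$protospacer, base$proto_start, base$strand)), ]
  expect_equal(nrow(unique_guides(distinct)), nrow(distinct))
  # same protospacer text at different positions stays separate
  a <- base[1, ]; b <- base[1, ]
  b$proto_start <- b$proto_start + 50L
  b$hit_id <- b$motif_ids <- "r_motif9"
  expect_equal(nrow(unique_guides(rbind(a, b))), 2L)
})

test_that("design_config validates custom-mode distance", {
  expect_error(design_config("NGG", "custom"), "custom_max_distance")
  expect_error(design_config("NGG", "cas9", custom_max_distance = 5),
               "only meaningful")
  expect_equal(design_config(offtarget_mode = "rapid")$max_mismatches, 3L)
})
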