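cfd_tab <- load_cfd_table()

test_that("bundled CFD-style table satisfies its structural contract", {
  expect_true(all(cfd_tab$mismatch >= 0 & cfd_tab$mismatch <= 1))
  expect_true(all(cfd_tab$pam >= 0 & cfd_tab$pam <= 1))
  # identity entries are exactly 1, mismatch entries strictly below 1
  keys <- names(cfd_tab$mismatch)
  ident <- substr(keys, 1, 1) == substr(keys, 3, 3)
  expect_true(all(cfd_tab$mismatch[ident] == 1))
  expect_true(all(cfd_tab$mismatch[!ident] < 1))
  expect_equal(unname(cfd_tab$pam["GG"]), 1)
  expect_true(all(cfd_tab$pam[names(cfd_tab$pam) != "GG"] < 1))
})

test_that("cfd_score is 1 only for the perfect canonical site and multiplies penalties", {
  g <- strrep("A", 20)
  expect_equal(cfd_score(g, g, "TGG", cfd_tab), 1.0)
  # single mismatch: exactly the table entry times the PAM penalty
  s1 <- paste0(strrep("A", 11), "C", strrep("A", 8))
  expect_equal(cfd_score(g, s1, "TGG", cfd_tab),
               unname(cfd_tab$mismatch["A>C@12"]))
  expect_equal(cfd_score(g, s1, "TAG", cfd_tab),
               unname(cfd_tab$mismatch["A>C@12"] * cfd_tab$pam["AG"]))
  # two mismatches: product of entries
  s2 <- paste0("G", strrep("A", 10), "C", strrep("A", 8))
  expect_equal(cfd_score(g, s2, "TGG", cfd_tab),
               unname(cfd_tab$mismatch["A>G@1"] * cfd_tab$mismatch["A>C@12"]))
  # non-canonical PAM alone pushes a perfect site below 1
  expect_lt(cfd_score(g, g, "TAG", cfd_tab), 1.0)
})

test_that("cfd_score equals brute-force recomputation and is order-invariant", {
  set.seed(91)
  for (i in 1:50) {
    g <- random_dna(20)
    s <- strsplit(g, "")[[1]]
    k <- sample(0:4, 1)
    pos <- sample(1:20, k)
    for (p in pos) s[p] <- sample(setdiff(c("A","C","G","T"), s[p]), 1)
    site <- paste(s, collapse = "")
    pam <- paste0(sample(c("A","C","G","T"), 1), sample(c("GG", "AG", "GA", "TT"), 1))
    # brute force: walk all 20 positions, multiply penalties by lookup
    want <- cfd_tab$pam[substr(pam, 2, 3)]
    gs <- strsplit(g, "")[[1]]
    for (p in 1:20) {
      if (gs[p] != s[p]) {
        want <- want * cfd_tab$mismatch[paste0(gs[p], ">", s[p], "@", p)]
      }
    }
    expect_equal(cfd_score(g, site, pam, cfd_tab), unname(want))
  }
})

test_that("cumulative specificity follows 100/(1+sum) and its monotonicity", {
  expect_equal(cumulative_specificity(numeric(0)), 100)
  expect_equal(cumulative_specificity(1.0), 50)
  expect_equal(cumulative_specificity(0.25), 80)
  expect_equal(cumulative_specificity(c(0.1, 0.15)), 80)  # reorder-invariant
  expect_equal(cumulative_specificity(c(0.15, 0.1)), 80)
  # strictly decreasing per added positive-CFD hit
  set.seed(101)
  cfds <- runif(10, 0.01, 1)
  scores <- vapply(seq_along(cfds), function(k) cumulative_specificity(cfds[1:k]),
                   numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("planted off-targets are recovered exactly by construction", {
  spacer <- "GACGTCAATGGCTAGCTAGC"
  genome <- make_toy_genome(1, 20000, seed = 5, path = tempfile(fileext = ".fa"))
  genome <- plant_offtargets(genome, spacer, c(0, 1, 2, 3, 4), seed = 6)
  truth <- genome$offtarget_truth
  for (max_mm in 0:4) {
    hits <- enumerate_offtargets(spacer, genome$sequences, "NGG", max_mm,
                                 table = cfd_tab)
    expected <- truth[truth$mismatches <= max_mm, ]
    for (r in seq_len(nrow(expected))) {
      m <- hits[hits$g_start == expected$start[r] & hits$strand == "+", ]
      expect_equal(nrow(m), 1L)
      expect_equal(m$mismatch_count, expected$mismatches[r])
      expect_identical(m$site_sequence, expected$site_sequence[r])
    }
  }
  # the planted perfect copy scores CFD 1.0 at a canonical PAM
  h0 <- enumerate_offtargets(spacer, genome$sequences, "NGG", 0, table = cfd_tab)
  exact <- h0[h0$g_start == truth$start[truth$mismatches == 0], ]
  expect_equal(exact$cfd, 1.0)
})

test_that("PAM gate excludes near-copies without a matching PAM", {
  spacer <- "ACGTACGTACGTACGTACGT"
  seqs <- c(chr1 = paste0(strrep("T", 30), spacer, "ATT", strrep("T", 30)))
  hits <- enumerate_offtargets(spacer, seqs, "NGG", 4, table = cfd_tab)
  expect_false(any(hits$g_start == 30 & hits$strand == "+"))
})

test_that("sites containing N are skipped", {
  spacer <- "ACGTACGTACGTACGTACGT"
  site <- sub("^A", "N", spacer)
  seqs <- c(chr1 = paste0(strrep("T", 30), site, "TGG", strrep("T", 30)))
  hits <- enumerate_offtargets(spacer, seqs, "NGG", 4, table = cfd_tab)
  expect_equal(nrow(hits), 0L)
})

test_that("enumeration matches the all-window Hamming oracle incl. minus strand", {
  set.seed(111)
  genome <- make_toy_genome(2, 3000, seed = 12, path = tempfile(fileext = ".fa"))
  for (i in 1:5) {
    spacer <- random_dna(20)
    for (max_mm in c(2, 4)) {
      got <- enumerate_offtargets(spacer, genome$sequences, "NGG", max_mm,
                                  table = NULL)
      want <- oracle_offtargets(spacer, genome$sequences, "NGG", max_mm)
      got_key <- paste(got$chrom, got$g_start, got$strand, got$mismatch_count)
      want_key <- paste(want$chrom, want$g_start, want$strand, want$mismatch_count)
      expect_identical(sort(got_key), sort(want_key))
    }
  }
})

test_that("the design locus is flagged on-target and excluded from the score", {
  spacer <- "GATTACAGATTACAGATTAC"
  # two identical perfect sites; one is the design locus
  seqs <- c(chr1 = paste0(strrep("T", 25), spacer, "AGG", strrep("T", 25),
                          spacer, "CGG", strrep("T", 25)))
  on <- list(chrom = "chr1", g_start = 25L, strand = "+")
  hits <- enumerate_offtargets(spacer, seqs, "NGG", 1, on_target = on,
                               table = cfd_tab)
  expect_equal(sum(hits$is_on_target), 1L)
  expect_equal(hits$g_start[hits$is_on_target], 25L)
  off <- hits[!hits$is_on_target, ]
  # the second perfect copy counts as an off-target with cfd = 1
  expect_true(any(off$mismatch_count == 0 & off$cfd == 1))
  expect_lte(cumulative_specificity(off$cfd), 50)
  # without coordinates, the first perfect site is the presumed design locus
  hits2 <- enumerate_offtargets(spacer, seqs, "NGG", 1, table = cfd_tab)
  expect_equal(hits2$g_start[hits2$is_on_target], 25L)
})

test_that("mismatch-level hit sets are nested (monotone in max_mismatches)", {
  set.seed(121)
  genome <- make_toy_genome(1, 5000, seed = 13, path = tempfile(fileext = ".fa"))
  spacer <- random_dna(20)
  prev <- character(0)
  for (k in 0:4) {
    h <- enumerate_offtargets(spacer, genome$sequences, "NGG", k, table = NULL)
    key <- paste(h$chrom, h$g_start, h$strand)
    expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("surrogate on-target scorer follows its documented formula", {
  # 50% GC, no homopolymer -> 50 + 25
  ctx <- paste0("AAAA", strrep("ACGT", 5), "TGG", "AAA")
  expect_equal(on_target_score(ctx), 75)
  # low GC, no homopolymer -> 50
  ctx2 <- paste0("AAAA", paste(rep(c("A","T","A","T"), 5), collapse = ""), "TGG", "AAA")
  expect_equal(on_target_score(ctx2), 50)
  # homopolymer >= 5 and GC in range -> 50
  ctx3 <- paste0("AAAA", "GGGGG", strrep("AC", 7), "A", "TGG", "AAA")
  expect_equal(nchar(ctx3), 30 - 0)  # 4 + 20 + 3 + 3
  expect_equal(on_target_score(ctx3), 50)
  # missing context -> unscored
  expect_true(is.na(on_target_score(NA_character_)))
})

test_that("external scorers plug in through the registry", {
  register_on_target_scorer("const42", function(context) 42)
  expect_equal(on_target_score("ACGT", scorer = "const42"), 42)
  expect_error(on_target_score("ACGT", scorer = "nope"), "no registered")
})

test_that("guide_context builds the 4+20+PAM+3 window and refuses truncation", {
  seq <- random_dna(60)
  g <- data.frame(proto_start = 10L, proto_end = 30L, pam_start = 30L,
                  pam_end = 33L, strand = "+")
  ctx <- guide_context(g, seq)
  expect_equal(nchar(ctx), 30L)
  expect_identical(substr(ctx, 5, 24), substr(seq, 11, 30))
  # guide 2 nt from the sequence start cannot form the window
  g2 <- data.frame(proto_start = 2L, proto_end = 22L, pam_start = 22L,
                   pam_end = 25L, strand = "+")
  expect_true(is.na(guide_context(g2, seq)))
  # minus strand: context is reverse-complemented
  g3 <- data.frame(proto_start = 23L, proto_end = 43L, pam_start = 20L,
                   pam_end = 23L, strand = "-")
  ctx3 <- guide_context(g3, seq)
  expect_identical(substr(ctx3, 5, 24), oracle_rc(substr(seq, 24, 43)))
})

test_that("missing CFD table degrades to mismatch-count-only with a warning", {
  guides <- data.frame(guide_id = "g1", hit_id = "h", motif_ids = "h",
                       region_name = "r", protospacer = "GATTACAGATTACAGATTAC",
                       pam = "TGG", strand = "+", proto_start = 0L, proto_end = 20L,
                       pam_start = 20L, pam_end = 23L, cut_bond = 17L,
                       chrom = NA_character_, g_proto_start = NA_integer_,
                       g_proto_end = NA_integer_, g_pam_start = NA_integer_,
                       g_pam_end = NA_integer_, on_score = NA_real_,
                       off_score = NA_real_, off_mm0 = NA_integer_,
                       off_mm1 = NA_integer_, off_mm2 = NA_integer_,
                       off_mm3 = NA_integer_, off_mm4 = NA_integer_,
                       stringsAsFactors = FALSE)
  seqs <- c(chr1 = paste0(strrep("T", 25), "GATTACAGATTACAGATTAC", "AGG",
                          strrep("T", 25)))
  expect_warning(res <- score_offtargets(guides, seqs,
                                         design_config("NGG", "cas9"),
                                         table = NULL),
                 "mismatch counts only")
  expect_true(is.na(res$guides$off_score))
  expect_equal(res$guides$off_mm0, 0L)  # the single perfect site is the presumed on-target
})
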