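# PAM scanning and sgRNA candidate generation under the Cas9, dCas9 or
# custom geometry rule, plus deterministic naming and deduplication.

#' Build a guide-design configuration
#'
#' @param pam_pattern PAM IUPAC pattern: `NGG` (canonical S. pyogenes),
#'   `NGA`, or `NGCG`.
#' @param mode `cas9` (blunt cut, 3 nt 5' of the PAM, must fall strictly
#'   inside the motif), `dcas9` (protospacer must overlap the motif by at
#'   least 1 nt; the PAM itself does not count), or `custom` (PAM-to-motif
#'   interval gap at most `custom_max_distance`).
#' @param custom_max_distance Non-negative integer; required (and only
#'   allowed) in `custom` mode.
#' @param offtarget_mode `standard` (up to 4 mismatches) or `rapid` (up to
#'   3 mismatches).
#' @return A `design_config` list.
#' @export
design_config <- function(pam_pattern = c("NGG", "NGA", "NGCG"),
                          mode = c("cas9", "dcas9", "custom"),
                          custom_max_distance = NULL,
                          offtarget_mode = c("standard", "rapid")) {
  pam_pattern <- match.arg(pam_pattern)
  mode <- match.arg(mode)
  offtarget_mode <- match.arg(offtarget_mode)
  if (mode == "custom") {
    if (is.null(custom_max_distance) || !is.numeric(custom_max_distance) ||
        length(custom_max_distance) != 1L || custom_max_distance < 0) {
      stop("custom mode requires a single non-negative custom_max_distance",
           call. = FALSE)
    }
    custom_max_distance <- as.integer(custom_max_distance)
  } else if (!is.null(custom_max_distance)) {
    stop("custom_max_distance is only meaningful in custom mode", call. = FALSE)
  }
  structure(list(
    pam_pattern = pam_pattern, mode = mode,
    custom_max_distance = custom_max_distance,
    offtarget_mode = offtarget_mode,
    max_mismatches = if (offtarget_mode == "rapid") 3L else 4L
  ), class = "design_config")
}

#' Find all PAM sites on both strands of a sequence
#'
#' A plus-strand site is a window matching the PAM pattern whose 20-nt
#' protospacer lies immediately 5' (to the left); a minus-strand site is a
#' window matching the reverse-complement pattern with the protospacer to
#' its right. Sites whose protospacer would run past either sequence end
#' are discarded.
#'
#' @param sequence Target sequence (uppercase DNA).
#' @param pam_pattern PAM IUPAC pattern (`NGG`, `NGA`, `NGCG`).
#' @return Data frame `pam_start`, `pam_end` (0-based half-open), `strand`.
#' @export
scan_pams <- function(sequence, pam_pattern = "NGG") {
  pam_pattern <- validate_iupac(pam_pattern, "PAM pattern")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  L <- nchar(pam_pattern)
  n <- length(chars)
  plus <- scan_positions(chars, iupac_to_matcher(pam_pattern))
  minus <- scan_positions(chars, iupac_to_matcher(reverse_complement(pam_pattern)))
  plus <- plus[plus >= 20L]                 # room for protospacer upstream
  minus <- minus[minus + L + 20L <= n]      # room downstream
  out <- data.frame(
    pam_start = as.integer(c(plus, minus)),
    pam_end = as.integer(c(plus, minus) + L),
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    stringsAsFactors = FALSE
  )
  out[order(out$pam_start, out$strand), , drop = FALSE]
}

#' Design candidate sgRNAs for one motif occurrence
#'
#' Geometry per mode: `cas9` keeps a guide iff its blunt-cut bond `b` (3 nt
#' 5' of the PAM) lies strictly inside the motif, i.e. both bases flanking
#' the bond are motif bases (`rel_start + 1 <= b <= rel_end - 1`); `dcas9`
#' keeps a guide iff its 20-nt protospacer overlaps the motif by >= 1 nt;
#' `custom` keeps a guide iff the gap between the PAM interval and the
#' motif interval is at most `custom_max_distance` (0 for touching or
#' overlapping intervals). Protospacer and PAM text are extracted
#' strand-correctly (reverse-complemented for minus-strand guides).
#'
#' @param motif_hit One-row motif-hit data frame.
#' @param pam_sites Data frame from [scan_pams()] on the same sequence.
#' @param config A [design_config()].
#' @param sequence The target sequence the hit and PAM sites refer to.
#' @return Guide data frame (possibly empty).
#' @export
design_guides <- function(motif_hit, pam_sites, config, sequence) {
  stopifnot(is.data.frame(motif_hit), nrow(motif_hit) == 1L,
            inherits(config, "design_config"))
  if (nrow(pam_sites) == 0L) return(empty_guides())
  sequence <- toupper(sequence)
  ms <- motif_hit$rel_start
  me <- motif_hit$rel_end

  plus <- pam_sites$strand == "+"
  proto_start <- ifelse(plus, pam_sites$pam_start - 20L, pam_sites$pam_end)
  proto_end <- proto_start + 20L
  cut_bond <- ifelse(plus, pam_sites$pam_start - 3L, pam_sites$pam_end + 3L)

  keep <- switch(config$mode,
    cas9 = cut_bond >= ms + 1L & cut_bond <= me - 1L,
    dcas9 = proto_start < me & proto_end > ms,
    custom = interval_gap(pam_sites$pam_start, pam_sites$pam_end, ms, me) <=
      config$custom_max_distance
  )
  keep <- which(keep)
  if (length(keep) == 0L) return(empty_guides())

  rows <- lapply(keep, function(i) {
    p_s <- proto_start[i]; p_e <- proto_end[i]
    pam_s <- pam_sites$pam_start[i]; pam_e <- pam_sites$pam_end[i]
    strand <- pam_sites$strand[i]
    proto_txt <- substr(sequence, p_s + 1L, p_e)
    pam_txt <- substr(sequence, pam_s + 1L, pam_e)
    if (strand == "-") {
      proto_txt <- reverse_complement(proto_txt)
      pam_txt <- reverse_complement(pam_txt)
    }
    has_coords <- !is.na(motif_hit$chrom)
    g_origin <- if (has_coords) motif_hit$g_start - motif_hit$rel_start else NA_integer_
    data.frame(
      guide_id = NA_character_, hit_id = motif_hit$hit_id,
      motif_ids = motif_hit$hit_id, region_name = motif_hit$region_name,
      protospacer = proto_txt, pam = pam_txt, strand = strand,
      proto_start = p_s, proto_end = p_e,
      pam_start = pam_s, pam_end = pam_e,
      cut_bond = if (config$mode == "cas9") as.integer(cut_bond[i]) else NA_integer_,
      chrom = motif_hit$chrom,
      g_proto_start = if (has_coords) as.integer(g_origin + p_s) else NA_integer_,
      g_proto_end = if (has_coords) as.integer(g_origin + p_e) else NA_integer_,
      g_pam_start = if (has_coords) as.integer(g_origin + pam_s) else NA_integer_,
      g_pam_end = if (has_coords) as.integer(g_origin + pam_e) else NA_integer_,
      on_score = NA_real_, off_score = NA_real_,
      off_mm0 = NA_integer_, off_mm1 = NA_integer_, off_mm2 = NA_integer_,
      off_mm3 = NA_integer_, off_mm4 = NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$proto_start, out$strand), , drop = FALSE]
}

#' Design guides for every motif hit in every target region
#'
#' Scans each region's sequence for PAM sites once, applies
#' [design_guides()] per hit, and assigns deterministic names:
#' motif hits are already `{region}_motif{i}`; guides become
#' `{region}_motif{i}_guide{j}` with `j` 1-based in coordinate order.
#'
#' @param motif_hits Motif-hit data frame from [scan_motifs()].
#' @param targets Target-region data frame.
#' @param config A [design_config()].
#' @return Guide data frame.
#' @export
design_all_guides <- function(motif_hits, targets, config) {
  if (nrow(motif_hits) == 0L) return(empty_guides())
  out <- lapply(seq_len(nrow(targets)), function(r) {
    region <- targets[r, , drop = FALSE]
    hits <- motif_hits[motif_hits$region_name == region$name, , drop = FALSE]
    if (nrow(hits) == 0L) return(empty_guides())
    pam_sites <- scan_pams(region$sequence, config$pam_pattern)
    per_hit <- lapply(seq_len(nrow(hits)), function(h) {
      g <- design_guides(hits[h, , drop = FALSE], pam_sites, config, region$sequence)
      if (nrow(g) > 0L) g$guide_id <- paste0(g$hit_id, "_guide", seq_len(nrow(g)))
      g
    })
    do.call(rbind, per_hit)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res)) empty_guides() else res
}

#' Collapse duplicated guides across overlapping motif hits
#'
#' Guides identical in protospacer, PAM, strand and position (genomic when
#' available, else region + relative position) are merged into one record
#' whose `motif_ids` is the comma-joined union of contributing motif hits.
#' Output is sorted by position.
#'
#' @param guides Guide data frame.
#' @return Deduplicated guide data frame.
#' @export
unique_guides <- function(guides) {
  if (nrow(guides) == 0L) return(guides)
  pos_key <- ifelse(is.na(guides$chrom),
                    paste(guides$region_name, guides$proto_start, sep = "@"),
                    paste(guides$chrom, guides$g_proto_start, sep = "@"))
  key <- paste(guides$protospacer, guides$pam, guides$strand, pos_key, sep = "|")
  groups <- split(seq_len(nrow(guides)), key)
  rows <- lapply(groups, function(ix) {
    rec <- guides[ix[1L], , drop = FALSE]
    rec$motif_ids <- paste(sort(unique(unlist(
      strsplit(guides$motif_ids[ix], ",", fixed = TRUE)))), collapse = ",")
    rec
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region_name,
                   ifelse(is.na(out$g_proto_start), out$proto_start, out$g_proto_start),
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
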