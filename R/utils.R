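# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# IUPAC nucleotide ambiguity codes -> allowed unambiguous bases.
IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Base-set (sorted, concatenated) -> IUPAC code.
SET_TO_CODE <- stats::setNames(
  names(IUPAC_BASES),
  vapply(IUPAC_BASES, function(b) paste(sort(b), collapse = ""), character(1))
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# Character class per IUPAC code, for regex construction.
iupac_regex_class <- function(code) {
  b <- IUPAC_BASES[[code]]
  if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
}

#' @noRd
validate_iupac <- function(x, what = "motif") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  }
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_BASES))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC symbol '%s' at position %d in %s '%s'",
                 chars[bad[1L]], bad[1L], what, x), call. = FALSE)
  }
  paste(chars, collapse = "")
}

validate_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("%s must be a single string", what), call. = FALSE)
  }
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  paste(chars, collapse = "")
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gap between two 0-based half-open intervals: 0 when touching/overlapping,
# else the number of bases strictly between them.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

# Empty prototypes keep column schemas in one place.
empty_motif_hits <- function() {
  data.frame(
    hit_id = character(0), motif_id = character(0), region_name = character(0),
    rel_start = integer(0), rel_end = integer(0), strand = character(0),
    matched_sequence = character(0), chrom = character(0),
    g_start = integer(0), g_end = integer(0),
    stringsAsFactors = FALSE
  )
}

empty_guides <- function() {
  data.frame(
    guide_id = character(0), hit_id = character(0), motif_ids = character(0),
    region_name = character(0), protospacer = character(0), pam = character(0),
    strand = character(0),
    proto_start = integer(0), proto_end = integer(0),
    pam_start = integer(0), pam_end = integer(0), cut_bond = integer(0),
    chrom = character(0), g_proto_start = integer(0), g_proto_end = integer(0),
    g_pam_start = integer(0), g_pam_end = integer(0),
    on_score = numeric(0), off_score = numeric(0),
    off_mm0 = integer(0), off_mm1 = integer(0), off_mm2 = integer(0),
    off_mm3 = integer(0), off_mm4 = integer(0),
    stringsAsFactors = FALSE
  )
}

empty_offtargets <- function() {
  data.frame(
    guide_id = character(0), chrom = character(0), g_start = integer(0),
    strand = character(0), site_sequence = character(0),
    pam_observed = character(0), mismatch_count = integer(0),
    mismatch_positions = character(0), cfd = numeric(0),
    is_on_target = logical(0),
    stringsAsFactors = FALSE
  )
}
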