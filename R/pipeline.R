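# End-to-end pipeline: read inputs -> find motifs -> design guides ->
# off-target scoring -> annotation -> filter/summarize -> write a result
# bundle with a machine-readable manifest.

#' Build a validated run configuration
#'
#' @param motifs Motif input text or path.
#' @param motif_format `inline`, `fasta`, `csv`, `jaspar` or `transfac`.
#' @param targets Target input text or path.
#' @param target_format `raw`, `fasta` or `bed`.
#' @param genome_path Genome FASTA; required for BED targets and for
#'   off-target scoring.
#' @param annotation_path Optional refGene-style gene-model dump.
#' @param matrix_rule,matrix_threshold Matrix-to-IUPAC collapse rule (see
#'   [matrix_to_iupac()]).
#' @param pam_pattern,mode,custom_max_distance,offtarget_mode See
#'   [design_config()].
#' @param extension Border extension for BED targets (default 30).
#' @param filters Optional [filter_spec()].
#' @param skip_offtargets Skip the genome-wide off-target search even when
#'   a genome is available.
#' @param on_target_scorer Registered scorer name (default `"surrogate"`).
#' @param output_dir Directory for the result bundle.
#' @param output_formats Subset of `tsv`, `csv`, `xlsx`; BED tracks are
#'   always written when coordinates exist.
#' @param color_by Score used for BED track colors.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters only for fixture generation).
#' @return A `run_config` list.
#' @export
run_config <- function(motifs, motif_format = "inline",
                       targets, target_format = "raw",
                       genome_path = NULL, annotation_path = NULL,
                       matrix_rule = "min_frequency", matrix_threshold = 0.25,
                       pam_pattern = "NGG", mode = "cas9",
                       custom_max_distance = NULL,
                       offtarget_mode = "standard", extension = 30L,
                       filters = NULL, skip_offtargets = FALSE,
                       on_target_scorer = "surrogate",
                       output_dir = tempfile("motifguides_run_"),
                       output_formats = "tsv", color_by = "off_score",
                       seed = 1L) {
  design <- design_config(pam_pattern, mode, custom_max_distance, offtarget_mode)
  if (target_format == "bed" && is.null(genome_path)) {
    stop("BED targets require genome_path", call. = FALSE)
  }
  if (!is.null(filters) && !inherits(filters, "filter_spec")) {
    stop("filters must be a filter_spec()", call. = FALSE)
  }
  stopifnot(all(output_formats %in% c("tsv", "csv", "xlsx")))
  structure(list(
    motifs = motifs, motif_format = motif_format,
    targets = targets, target_format = target_format,
    genome_path = genome_path, annotation_path = annotation_path,
    matrix_rule = matrix_rule, matrix_threshold = matrix_threshold,
    design = design, extension = as.integer(extension),
    filters = filters, skip_offtargets = isTRUE(skip_offtargets),
    on_target_scorer = on_target_scorer,
    output_dir = output_dir, output_formats = output_formats,
    color_by = color_by, seed = as.integer(seed)
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full motif-to-guides pipeline
#'
#' Stages: read motifs and targets -> scan motifs on both strands ->
#' design guides under the configured geometry -> off-target scoring
#' (when a genome is available) -> on-target scoring -> localization and
#' closest-TSS annotation (when coordinates and gene models are
#' available) -> filters -> summary -> write `motifs.tsv`, `guides.tsv`,
#' `unique_guides.tsv`, `offtargets.tsv`, `summary.json`, `tracks.bed`
#' (coordinate inputs only) and `manifest.json` into the output
#' directory. Outputs are deterministic: identical config and inputs give
#' byte-identical tabular files.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the in-memory results (`targets`,
#'   `motifs`, `motif_hits`, `guides`, `unique_guides`, `offtargets`,
#'   `summary`, `manifest`, `paths`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(list.files(config$output_dir, full.names = TRUE))
  })

  say("reading inputs")
  genome <- if (!is.null(config$genome_path)) {
    stage("read_genome", read_genome(config$genome_path))
  } else NULL
  motif_in <- stage("read_motifs",
                    read_motif_input(config$motifs, config$motif_format))
  motifs <- if (is.data.frame(motif_in)) motif_in else {
    do.call(rbind, lapply(motif_in, matrix_to_iupac,
                          rule = config$matrix_rule,
                          threshold = config$matrix_threshold))
  }
  targets <- stage("read_targets",
                   read_targets(config$targets, config$target_format,
                                genome = genome, extension = config$extension))

  say("scanning %d motif(s) across %d region(s)", nrow(motifs), nrow(targets))
  motif_hits <- stage("find_motifs", scan_motifs(motifs, targets))

  say("designing guides (%s mode, PAM %s)", config$design$mode,
      config$design$pam_pattern)
  guides <- stage("design_guides",
                  design_all_guides(motif_hits, targets, config$design))

  offtargets <- empty_offtargets()
  if (!is.null(genome) && !config$skip_offtargets && nrow(guides) > 0L) {
    say("off-target search (max %d mismatches) for %d guide record(s)",
        config$design$max_mismatches, nrow(guides))
    scored <- stage("offtargets",
                    score_offtargets(guides, genome, config$design))
    guides <- scored$guides
    offtargets <- scored$offtargets
  }

  if (nrow(guides) > 0L) {
    say("on-target scoring")
    seq_by_region <- stats::setNames(targets$sequence, targets$name)
    guides$on_score <- vapply(seq_len(nrow(guides)), function(i) {
      ctx <- guide_context(guides[i, , drop = FALSE],
                           seq_by_region[[guides$region_name[i]]])
      on_target_score(ctx, config$on_target_scorer)
    }, numeric(1))
  }

  annotated <- FALSE
  if (!is.null(config$annotation_path) && any(!is.na(motif_hits$chrom))) {
    say("annotating localization and closest TSS")
    gene_models <- stage("read_annotation",
                         read_gene_annotation(config$annotation_path))
    index <- stage("annotation_index", build_annotation_index(gene_models))
    motif_hits <- stage("annotate", annotate_motif_hits(motif_hits, index))
    annotated <- TRUE
  } else if (!is.null(config$annotation_path)) {
    warning("annotation supplied but targets carry no genomic coordinates; ",
            "localization columns unavailable", call. = FALSE)
  }

  if (!is.null(config$filters)) {
    say("applying filters")
    filtered <- stage("filters",
                      apply_filters(motif_hits, guides, config$filters))
    motif_hits <- filtered$motif_hits
    guides <- filtered$guides
    offtargets <- offtargets[offtargets$guide_id %in% guides$guide_id, ,
                             drop = FALSE]
  }

  uniq <- unique_guides(guides)
  summary <- summarize_results(motif_hits, guides)

  say("writing results to %s", config$output_dir)
  paths <- write_bundle(config, targets, motifs, motif_hits, guides, uniq,
                        offtargets, summary, annotated)
  ok <- TRUE
  invisible(list(targets = targets, motifs = motifs, motif_hits = motif_hits,
                 guides = guides, unique_guides = uniq, offtargets = offtargets,
                 summary = summary, manifest = paths$manifest,
                 paths = paths$files))
}

write_bundle <- function(config, targets, motifs, motif_hits, guides, uniq,
                         offtargets, summary, annotated) {
  out <- config$output_dir
  files <- character(0)
  tab <- function(df, name) {
    p <- file.path(out, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    p
  }
  files <- c(files,
             tab(motif_table(motif_hits), "motifs.tsv"),
             tab(guide_table(guides), "guides.tsv"),
             tab(guide_table(uniq), "unique_guides.tsv"),
             tab(offtargets[!offtargets$is_on_target, , drop = FALSE],
                 "offtargets.tsv"))
  for (fmt in setdiff(config$output_formats, "tsv")) {
    files <- c(files, write_results(motif_hits, uniq, fmt,
                                    file.path(out, "results"),
                                    color_by = config$color_by))
  }
  if (all(!is.na(motif_hits$chrom)) &&
      (nrow(motif_hits) > 0L || nrow(uniq) > 0L) &&
      !anyNA(uniq$chrom)) {
    p <- file.path(out, "tracks.bed")
    write_tracks_bed(motif_hits, uniq, p, config$color_by)
    files <- c(files, p)
  }
  sj <- file.path(out, "summary.json")
  jsonlite::write_json(unclass(summary), sj, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, sj)

  manifest <- list(
    package = "motifguides",
    version = as.character(utils::packageVersion("motifguides")),
    parameters = list(
      motif_format = config$motif_format,
      target_format = config$target_format,
      matrix_rule = config$matrix_rule,
      matrix_threshold = config$matrix_threshold,
      pam_pattern = config$design$pam_pattern,
      mode = config$design$mode,
      custom_max_distance = config$design$custom_max_distance,
      offtarget_mode = config$design$offtarget_mode,
      max_mismatches = config$design$max_mismatches,
      extension = config$extension,
      on_target_scorer = config$on_target_scorer,
      color_by = config$color_by,
      filters = if (is.null(config$filters)) NULL else unclass(config$filters),
      annotation_used = annotated,
      genome = if (is.null(config$genome_path)) NULL else basename(config$genome_path),
      seed = config$seed
    ),
    counts = list(
      targets = nrow(targets),
      motif_specs = nrow(motifs),
      motif_hits = nrow(motif_hits),
      guides = nrow(guides),
      unique_guides = nrow(uniq),
      offtargets = sum(!offtargets$is_on_target)
    )
  )
  mj <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mj, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, mj)
  list(files = files, manifest = manifest)
}
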