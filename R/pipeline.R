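# End-to-end orchestration: scan (per-sample contigs), call (consensus +
# internal classification), motif (upstream scanning + enrichment).

#' Default run configuration
#'
#' All pipeline tunables with their standard values: smoothing sigma 50 nt
#' at 99.5% kernel mass; 150-nt windows at 5-nt steps; RMSD floor at the
#' 50th percentile; coverage-sum band between the 50th and 95th
#' percentiles; contig-defining difference threshold at the 90th
#' percentile; TES flank 150 nt; merging below 1 kb boundary distance and
#' 3-fold expression variation; consensus filters at 4 kb maximum span,
#' 2-sample minimum support, 75-nt internality margin, rank cutoff 800;
#' motif scanning over 300-nt upstream windows at a 0.85 relative-score
#' threshold.
#'
#' @param ... overrides for any field (input paths, `outdir`, `seed`, or a
#'   tunable).
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    sigma = 50, kernel_mass = 0.995, window = 150L, step = 5L,
    rmsd_percentile = 0.5, cov_band = c(0.5, 0.95), diff_percentile = 0.9,
    tes_flank = 150L, merge_gap = 1000L, merge_fold = 3,
    max_span = 4000L, min_support = 2L, internal_margin = 75L,
    rank_cutoff = 800, upstream_window = 300L, motif_threshold = 0.85,
    gene_feature = "gene",
    genome = NULL, annotation = NULL, exclusions = NULL, control = NULL,
    tests = NULL, motifs = NULL, outdir = NULL, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys are [default_config()] fields.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_config, y)
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

require_inputs <- function(config, fields) {
  for (f in fields) {
    v <- config[[f]]
    if (is.null(v)) stop("config field '", f, "' is required here")
    if (f != "motifs" && !all(file.exists(unlist(v)))) {
      missing <- unlist(v)[!file.exists(unlist(v))]
      stop("input file not found (", f, "): ", paste(missing, collapse = ", "))
    }
  }
}

sample_names_of <- function(paths) {
  nm <- names(paths)
  fallback <- sub("\\.[^.]*$", "", basename(paths))
  if (is.null(nm)) return(fallback)
  ifelse(nzchar(nm), nm, fallback)
}

#' Write a per-sample contig table
#' @param contigs ranked `transcript_contigs`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_contig_table <- function(contigs, path) {
  cols <- c("seqname", "start", "end", "tss", "strand", "avg_diff", "size",
            "score", "rank", "sample", "flags")
  utils::write.table(contigs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scan stage: per-sample ranked contigs
#'
#' Reads the inputs, masks excluded features, smooths and depth-normalizes
#' every sample, and calls ranked contigs for each test sample against the
#' control. With `outdir` set, per-sample contig tables and a stage-count
#' log are written.
#'
#' @param config a `run_config` with at least `genome`, `annotation`,
#'   `control` and `tests` set.
#' @return an `itss_scan` list: `samples` (per-sample [call_contigs()]
#'   results), `ctrl`, `annot`, `layout`, `config`, `stage_counts`.
#' @export
pipeline_scan <- function(config) {
  require_inputs(config, c("genome", "annotation", "control", "tests"))
  genome <- read_genome(config$genome)
  layout <- layout_from_genome(genome)
  annot <- read_gff3(config$annotation, config$gene_feature, layout)
  excl <- if (!is.null(config$exclusions)) {
    read_exclusions(config$exclusions, layout)
  } else {
    NULL
  }
  ctrl_raw <- apply_exclusions(
    read_bedgraph(config$control, layout, sample = "control"), excl
  )
  ctrl_n <- normalize_depth(
    smooth_coverage(ctrl_raw, config$sigma, config$kernel_mass),
    total_signal(ctrl_raw)
  )
  rm(ctrl_raw)
  test_paths <- unlist(config$tests)
  snames <- sample_names_of(test_paths)
  samples <- list()
  for (i in seq_along(test_paths)) {
    raw <- apply_exclusions(
      read_bedgraph(test_paths[i], layout, sample = snames[i]), excl
    )
    test_n <- normalize_depth(
      smooth_coverage(raw, config$sigma, config$kernel_mass),
      total_signal(raw)
    )
    rm(raw)
    samples[[snames[i]]] <- call_contigs(
      ctrl_n, test_n, annot,
      window = config$window, step = config$step,
      tes_flank = config$tes_flank, rmsd_p = config$rmsd_percentile,
      cov_band = config$cov_band, diff_p = config$diff_percentile,
      merge_gap = config$merge_gap, merge_fold = config$merge_fold
    )
  }
  stage_counts <- lapply(samples, `[[`, "stage_counts")
  res <- structure(
    list(samples = samples, ctrl = ctrl_n, annot = annot, layout = layout,
         config = config, stage_counts = stage_counts),
    class = "itss_scan"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(samples)) {
      write_contig_table(
        samples[[nm]]$contigs,
        file.path(config$outdir, sprintf("contigs_%s.tsv", nm))
      )
    }
    jsonlite::write_json(
      stage_counts, file.path(config$outdir, "stage_counts.json"),
      auto_unbox = TRUE
    )
  }
  res
}

#' Call stage: consensus and internal-TSS classification
#'
#' Combines per-sample contigs into consensus calls (>= 2 supporting
#' samples, span <= 4 kb) and classifies them as ORF-internal. With
#' `outdir` set, writes the internal-TSS report, a consensus BED, and
#' run metadata (parameters + input checksums).
#'
#' @param scan an `itss_scan` from [pipeline_scan()].
#' @param config a `run_config` (defaults to the scan's).
#' @return an `itss_calls` list: `consensus`, `internal`, `counts`.
#' @export
pipeline_call <- function(scan, config = scan$config) {
  if (length(scan$samples) < 2L) {
    stop(
      "at least two test samples are required: contigs identified in ",
      "only one sample are discarded"
    )
  }
  all_contigs <- do.call(rbind, lapply(scan$samples, `[[`, "contigs"))
  rownames(all_contigs) <- NULL
  clustered <- match_across_samples(all_contigs, max_gap = config$merge_gap)
  consensus <- consensus_calls(
    clustered, min_support = config$min_support, max_span = config$max_span
  )
  internal <- classify_internal(
    consensus, scan$annot,
    min_dist = config$internal_margin, rank_cutoff = config$rank_cutoff
  )
  res <- structure(
    list(consensus = consensus, internal = internal,
         counts = attr(consensus, "counts")),
    class = "itss_calls"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_internal_report(
      internal, file.path(config$outdir, "internal_tss.tsv")
    )
    write_contigs_bed(
      consensus, file.path(config$outdir, "consensus_contigs.bed")
    )
    write_run_metadata(config, file.path(config$outdir, "run_metadata.json"))
  }
  res
}

#' Write run metadata (parameters and input checksums)
#' @param config a `run_config`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  inputs <- c(config$genome, config$annotation, config$exclusions,
              config$control, unlist(config$tests), unlist(config$motifs))
  inputs <- inputs[!is.null(inputs)]
  md <- list(
    package = "itss",
    version = as.character(utils::packageVersion("itss")),
    parameters = unclass(config)[!vapply(unclass(config), is.null,
                                         logical(1))],
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(md, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Motif stage: upstream scanning and enrichment
#'
#' Flags each internal-TSS call whose 300-nt upstream window contains a
#' motif site and tests enrichment of flagged genes against the
#' all-ORF-upstream background with the exact test, separately per motif.
#' With `outdir` set, rewrites the internal-TSS report with the flags and
#' writes an enrichment summary JSON.
#'
#' @param calls an `itss_calls` from [pipeline_call()].
#' @param scan the `itss_scan` the calls came from.
#' @param config a `run_config` with `motifs` set: a named list/vector of
#'   PWM file paths (names become flag prefixes, e.g. `MSE`, `URS1`).
#' @return an `itss_motif` list: `internal` (flagged calls), `enrichment`
#'   (per-motif `enrichment_result`s), `motifs`.
#' @export
pipeline_motif <- function(calls, scan, config = scan$config) {
  require_inputs(config, "motifs")
  motif_paths <- unlist(config$motifs)
  if (!all(file.exists(motif_paths))) {
    stop("motif file not found: ",
         paste(motif_paths[!file.exists(motif_paths)], collapse = ", "))
  }
  genome <- read_genome(config$genome)
  internal <- calls$internal
  enrichment <- list()
  for (nm in sample_names_of(motif_paths)) {
    motif <- load_pwm(motif_paths[[which(sample_names_of(motif_paths) == nm)[1]]],
                      name = nm)
    prefix <- tolower(nm)
    internal <- flag_upstream_sites(
      internal, genome, motif,
      window = config$upstream_window, threshold = config$motif_threshold,
      prefix = prefix
    )
    bg <- upstream_orf_hits(
      scan$annot, genome, motif,
      window = config$upstream_window, threshold = config$motif_threshold
    )
    fg_genes <- unique(internal$gene_id)
    fg_hit <- vapply(
      fg_genes,
      function(g) any(internal[[paste0(prefix, "_hit")]][internal$gene_id == g]),
      logical(1)
    )
    enrichment[[nm]] <- exact_enrichment(
      k = sum(fg_hit), n = length(fg_genes), K = sum(bg), N = length(bg)
    )
  }
  res <- structure(
    list(internal = internal, enrichment = enrichment,
         motifs = motif_paths),
    class = "itss_motif"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_internal_report(
      internal, file.path(config$outdir, "internal_tss.tsv")
    )
    jsonlite::write_json(
      lapply(enrichment, function(e) {
        list(p = e$p, p_over = e$p_over, k = e$k, n = e$n, K = e$K, N = e$N)
      }),
      file.path(config$outdir, "enrichment.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  res
}

#' Run the full pipeline
#'
#' Scan, call, and (when `config$motifs` is set) motif stages in sequence.
#'
#' @param config a `run_config`.
#' @return an `itss_run` list: `scan`, `calls`, `motif` (NULL without
#'   motifs), `internal` (the final flagged internal-TSS calls).
#' @export
run_pipeline <- function(config) {
  scan <- pipeline_scan(config)
  calls <- pipeline_call(scan, config)
  motif <- NULL
  internal <- calls$internal
  if (!is.null(config$motifs)) {
    motif <- pipeline_motif(calls, scan, config)
    internal <- motif$internal
  }
  structure(
    list(scan = scan, calls = calls, motif = motif, internal = internal,
         config = config),
    class = "itss_run"
  )
}

#' @export
print.itss_run <- function(x, ...) {
  cat("<itss_run>\n")
  for (nm in names(x$scan$samples)) {
    sc <- x$scan$samples[[nm]]$stage_counts
    cat(
      "  ", nm, ": ", sc[["peaks"]], " peaks -> ", sc[["after_tes"]],
      " after TES filter -> ", sc[["after_criteria"]],
      " after criteria -> ", sc[["after_merge"]], " contigs\n",
      sep = ""
    )
  }
  cat(
    "  consensus: ", nrow(x$calls$consensus), " calls; internal: ",
    nrow(x$internal), "\n",
    sep = ""
  )
  if (!is.null(x$motif)) {
    for (nm in names(x$motif$enrichment)) {
      e <- x$motif$enrichment[[nm]]
      cat(
        "  ", nm, ": ", e$k, "/", e$n, " foreground vs ", e$K, "/", e$N,
        " background, p = ", format(e$p, digits = 3), "\n",
        sep = ""
      )
    }
  }
  invisible(x)
}
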