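load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (!file.exists(genome)) stop("genome FASTA not found: ", genome, call. = FALSE)
  g <- Biostrings::readDNAStringSet(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full cryptic-splicing pipeline
#'
#' Executes event detection, PSI quantification, differential testing and
#' cryptic-site characterization on a cohort, writing a report bundle of
#' TSVs (events, PSI matrix, test results, event-type summary, distance
#' histogram, site annotations, canonical and cryptic motif matrices) plus a
#' JSON run manifest recording the package version, seed, effective
#' parameters and MD5 hashes of every output file. When an ortholog map and
#' a second cohort's significant gene set are supplied, the gene-level
#' overlap is added; when an amplicon assay and reads are supplied, the
#' isoform summary is added.
#'
#' @param sample_sheet Sample-sheet tibble or path (see
#'   [read_sample_sheet()]).
#' @param genome Reference FASTA path or [Biostrings::DNAStringSet-class].
#' @param annotation GTF path or gene-model tibble.
#' @param out_dir Output directory for the report bundle.
#' @param config A [diff_config()].
#' @param dialect Junction-table dialect of the sample-sheet paths.
#' @param window_offsets Motif window (transcript-sense offsets, 0 = last
#'   intronic base).
#' @param ppt_offsets,bp_offsets Composition-score windows.
#' @param ortholog_map Optional ortholog map tibble (`gene_a`, `gene_b`).
#' @param cohort_b_genes Optional character vector of significant A3SS genes
#'   of a second cohort.
#' @param amplicon Optional [amplicon_assay()].
#' @param amplicon_reads Optional reads for `amplicon` (see
#'   [classify_reads()]).
#' @param seed Integer seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A list of class `cryptsplice_report` with all result tables and
#'   the bundle file paths.
#' @export
run_pipeline <- function(sample_sheet, genome, annotation, out_dir,
                         config = diff_config(),
                         dialect = "simple_tsv",
                         window_offsets = c(-30L, 9L),
                         ppt_offsets = c(-20L, -5L),
                         bp_offsets = c(-40L, -10L),
                         ortholog_map = NULL,
                         cohort_b_genes = NULL,
                         amplicon = NULL,
                         amplicon_reads = NULL,
                         seed = 1L) {
  sheet <- stage("sample_sheet", {
    if (is.character(sample_sheet)) read_sample_sheet(sample_sheet) else sample_sheet
  })
  genome <- stage("genome", load_genome(genome))
  models <- stage("annotation", {
    if (is.character(annotation)) read_annotation(annotation) else annotation
  })
  junctions <- stage("junctions", {
    dplyr::bind_rows(lapply(seq_len(nrow(sheet)), function(i) {
      read_junction_table(sheet$path[i], dialect = dialect,
                          sample_id = sheet$sample_id[i])
    }))
  })

  events <- stage("detect", detect_events(junctions, models))
  psi <- stage("psi", compute_psi(events, junctions,
                                  samples = sheet$sample_id,
                                  min_coverage = config$min_coverage))
  mat <- psi_matrix(psi)
  fit <- stage("diffsplice", differential_test(mat, sheet, config))
  results <- dplyr::left_join(
    fit$results,
    events[, c("event_id", "gene_id", "event_type", "strand")],
    by = "event_id"
  )
  sig_ids <- results$event_id[results$significant]
  type_summary <- summarize_event_types(events, sig_ids)

  sig_a3ss <- events[events$event_id %in% sig_ids &
                       events$event_type == "A3SS", , drop = FALSE]
  char <- stage("characterize", {
    if (nrow(sig_a3ss) > 0) {
      characterize_sites(sig_a3ss, genome, models,
                         ppt_offsets = ppt_offsets, bp_offsets = bp_offsets)
    } else {
      NULL
    }
  })
  dist_hist <- if (nrow(sig_a3ss) > 0) distance_histogram(sig_a3ss) else distance_histogram(integer(0))
  motifs <- stage("motifs", {
    if (nrow(sig_a3ss) > 0) {
      offs <- seq(window_offsets[1], window_offsets[2])
      list(
        canonical = motif_profile(
          extract_ss_windows(sig_a3ss, "canonical", genome, window_offsets),
          offsets = offs),
        cryptic = motif_profile(
          extract_ss_windows(sig_a3ss, "cryptic", genome, window_offsets),
          offsets = offs)
      )
    } else {
      NULL
    }
  })

  overlap <- NULL
  if (!is.null(ortholog_map) && !is.null(cohort_b_genes)) {
    overlap <- stage("overlap", {
      overlap_events(unique(sig_a3ss$gene_id), cohort_b_genes, ortholog_map)
    })
  }
  amplicon_summary <- NULL
  if (!is.null(amplicon) && !is.null(amplicon_reads)) {
    amplicon_summary <- stage("amplicon", classify_reads(amplicon_reads, amplicon))
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    events = file.path(out_dir, "events.tsv"),
    psi_matrix = file.path(out_dir, "psi_matrix.tsv"),
    results = file.path(out_dir, "diff_splice_results.tsv"),
    event_types = file.path(out_dir, "event_type_summary.tsv"),
    distance_histogram = file.path(out_dir, "distance_histogram.tsv"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  readr::write_tsv(events, paths$events, progress = FALSE)
  write_psi_matrix(mat, paths$psi_matrix)
  readr::write_tsv(results, paths$results, progress = FALSE)
  readr::write_tsv(type_summary, paths$event_types, progress = FALSE)
  readr::write_tsv(dist_hist, paths$distance_histogram, progress = FALSE)
  if (!is.null(char)) {
    paths$site_annotations <- file.path(out_dir, "site_annotations.tsv")
    readr::write_tsv(char, paths$site_annotations, progress = FALSE)
  }
  if (!is.null(motifs)) {
    paths$motif_canonical <- file.path(out_dir, "motif_canonical.tsv")
    paths$motif_cryptic <- file.path(out_dir, "motif_cryptic.tsv")
    readr::write_tsv(motifs$canonical, paths$motif_canonical, progress = FALSE)
    readr::write_tsv(motifs$cryptic, paths$motif_cryptic, progress = FALSE)
  }
  if (!is.null(overlap)) {
    paths$overlap_counts <- file.path(out_dir, "overlap_counts.tsv")
    paths$overlap_shared <- file.path(out_dir, "overlap_shared_genes.tsv")
    readr::write_tsv(overlap$counts, paths$overlap_counts, progress = FALSE)
    readr::write_tsv(overlap$shared, paths$overlap_shared, progress = FALSE)
  }
  if (!is.null(amplicon_summary)) {
    paths$amplicon_summary <- file.path(out_dir, "amplicon_summary.tsv")
    readr::write_tsv(amplicon_summary, paths$amplicon_summary, progress = FALSE)
  }

  tsv_paths <- unlist(paths[names(paths) != "manifest"])
  manifest <- list(
    package = "cryptsplice",
    version = as.character(utils::packageVersion("cryptsplice")),
    seed = as.integer(seed),
    n_samples = nrow(sheet),
    samples = sheet$sample_id,
    parameters = list(
      pseudocount = config$pseudocount,
      min_coverage = config$min_coverage,
      delta_psi_min = config$delta_psi_min,
      p_max = config$p_max,
      test = config$test,
      adjust = config$adjust,
      preset = config$preset,
      window_offsets = window_offsets,
      ppt_offsets = ppt_offsets,
      bp_offsets = bp_offsets
    ),
    files = as.list(unname(tools::md5sum(tsv_paths)))
  )
  names(manifest$files) <- basename(tsv_paths)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  structure(list(
    samples = sheet, events = events, psi = psi, psi_matrix = mat, fit = fit,
    results = results, event_type_summary = type_summary,
    distance_histogram = dist_hist, site_annotations = char, motifs = motifs,
    overlap = overlap, amplicon_summary = amplicon_summary, paths = paths
  ), class = "cryptsplice_report")
}

#' @export
print.cryptsplice_report <- function(x, ...) {
  cat("<cryptsplice pipeline report>\n")
  cat(sprintf("  %d samples, %d events, %d significant\n",
              nrow(x$samples), nrow(x$events), sum(x$results$significant)))
  cat("  bundle:", dirname(x$paths$events), "\n")
  invisible(x)
}
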