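#' Detect alternative splicing events from junctions and annotation
#'
#' Builds donor/acceptor indices per gene from the pooled junction evidence
#' of all samples and calls pairwise events against the annotation:
#'
#' * **A3SS** — two junctions sharing a donor, one ending at an annotated
#'   acceptor (the canonical 3'ss) and one at an unannotated acceptor (the
#'   alternative, typically cryptic, 3'ss). One event is emitted per
#'   unannotated acceptor.
#' * **A5SS** — the symmetric call on a shared acceptor with an unannotated
#'   donor.
#' * **exon_skip** — a junction exactly bridging the two annotated flanking
#'   introns of an annotated internal exon.
#'
#' Junctions with undefined strand are dropped (3'ss identity is
#' strand-dependent) and junctions outside every gene span are ignored; both
#' are reported via a message. Events are deduplicated across samples and
#' identifiers are deterministic functions of gene and coordinates.
#'
#' If several annotated acceptors share a donor, the acceptor used by the
#' longest annotated transcript is taken as canonical (ties broken by the
#' most-upstream acceptor in transcript sense); likewise for donors.
#'
#' @param junctions Junction tibble pooled over samples
#'   (see [read_junction_table()]).
#' @param models Gene-model tibble (see [read_annotation()]).
#' @return A tibble with one row per event: `event_id`, `gene_id`, `chrom`,
#'   `strand`, `event_type`, `shared_site`, `canonical_site`,
#'   `alternative_site`, the defining junction intervals
#'   (`canonical_start/end`, `alt_start/end`) and, for exon skips, the
#'   skipped exon interval (`skip_start/end`).
#' @export
detect_events <- function(junctions, models) {
  undefined <- junctions$strand == "*"
  if (any(undefined)) {
    message("dropping ", sum(undefined), " junction record(s) with undefined strand")
    junctions <- junctions[!undefined, , drop = FALSE]
  }
  jx <- junctions |>
    dplyr::group_by(.data$chrom, .data$strand, .data$intron_start,
                    .data$intron_end) |>
    dplyr::summarise(total_reads = sum(.data$unique_reads), .groups = "drop") |>
    dplyr::filter(.data$total_reads >= 1)

  spans <- gene_spans(models)
  assigned <- dplyr::inner_join(
    jx, spans,
    by = dplyr::join_by("chrom", "strand", "intron_start" >= "start",
                        "intron_end" <= "end")
  )
  n_orphan <- nrow(jx) - dplyr::n_distinct(
    assigned[, c("chrom", "strand", "intron_start", "intron_end")]
  )
  if (n_orphan > 0) {
    message(n_orphan, " junction(s) not attributable to any gene; ignored")
  }
  assigned <- dplyr::mutate(
    assigned,
    donor = ifelse(.data$strand == "+", .data$intron_start, .data$intron_end),
    acceptor = ifelse(.data$strand == "+", .data$intron_end, .data$intron_start)
  )

  introns <- transcript_introns(models)
  tx_len <- models |>
    dplyr::filter(.data$feature == "exon") |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(tx_length = sum(.data$end - .data$start + 1L),
                     .groups = "drop")
  introns <- dplyr::left_join(introns, tx_len, by = "transcript_id")

  events <- dplyr::bind_rows(
    call_alt_site_events(assigned, introns, type = "A3SS"),
    call_alt_site_events(assigned, introns, type = "A5SS"),
    call_exon_skip_events(assigned, introns, models)
  )
  if (nrow(events) == 0) return(empty_events())
  dplyr::arrange(events, .data$gene_id, .data$event_id)
}

empty_events <- function() {
  tibble::tibble(
    event_id = character(), gene_id = character(), chrom = character(),
    strand = character(), event_type = character(),
    shared_site = integer(), canonical_site = integer(),
    alternative_site = integer(),
    canonical_start = integer(), canonical_end = integer(),
    alt_start = integer(), alt_end = integer(),
    skip_start = integer(), skip_end = integer()
  )
}

# shared logic for A3SS (shared donor, variable acceptor) and A5SS
# (shared acceptor, variable donor)
call_alt_site_events <- function(assigned, introns, type) {
  shared_col <- if (type == "A3SS") "donor" else "acceptor"
  var_col <- if (type == "A3SS") "acceptor" else "donor"

  annotated_sites <- introns |>
    dplyr::group_by(.data$gene_id, site = .data[[var_col]],
                    shared = .data[[shared_col]]) |>
    dplyr::summarise(best_tx_length = max(.data$tx_length), .groups = "drop")

  jx <- assigned |>
    dplyr::mutate(shared = .data[[shared_col]], site = .data[[var_col]])
  ann <- dplyr::distinct(introns[, c("gene_id", var_col)])
  names(ann)[2] <- "site"
  ann$is_annotated <- TRUE
  jx <- dplyr::left_join(jx, ann, by = c("gene_id", "site"))
  jx$is_annotated <- !is.na(jx$is_annotated)

  grp <- jx |> dplyr::group_by(.data$gene_id, .data$shared)
  has_both <- grp |>
    dplyr::summarise(any_ann = any(.data$is_annotated),
                     any_novel = any(!.data$is_annotated), .groups = "drop") |>
    dplyr::filter(.data$any_ann & .data$any_novel)
  if (nrow(has_both) == 0) return(NULL)

  jx <- dplyr::semi_join(jx, has_both, by = c("gene_id", "shared"))

  # canonical site per (gene, shared site): annotated site of the longest
  # transcript using it; tie -> most upstream in transcript sense
  upstream_rank <- function(site, strand) ifelse(strand == "+", site, -site)
  canon <- jx |>
    dplyr::filter(.data$is_annotated) |>
    dplyr::left_join(annotated_sites, by = c("gene_id", "site", "shared")) |>
    dplyr::mutate(best_tx_length = dplyr::coalesce(.data$best_tx_length, 0L)) |>
    dplyr::group_by(.data$gene_id, .data$shared) |>
    dplyr::arrange(dplyr::desc(.data$best_tx_length),
                   upstream_rank(.data$site, .data$strand), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "shared", "chrom", "strand",
                  canonical_site = "site",
                  canonical_start = "intron_start",
                  canonical_end = "intron_end")

  novel <- jx |>
    dplyr::filter(!.data$is_annotated) |>
    dplyr::select("gene_id", "shared",
                  alternative_site = "site",
                  alt_start = "intron_start", alt_end = "intron_end")

  ev <- dplyr::inner_join(canon, novel, by = c("gene_id", "shared"))
  if (nrow(ev) == 0) return(NULL)
  tibble::tibble(
    event_id = sprintf("%s:%s:%d>%d", ev$gene_id, type, ev$canonical_site,
                       ev$alternative_site),
    gene_id = ev$gene_id,
    chrom = ev$chrom,
    strand = ev$strand,
    event_type = type,
    shared_site = as.integer(ev$shared),
    canonical_site = as.integer(ev$canonical_site),
    alternative_site = as.integer(ev$alternative_site),
    canonical_start = as.integer(ev$canonical_start),
    canonical_end = as.integer(ev$canonical_end),
    alt_start = as.integer(ev$alt_start),
    alt_end = as.integer(ev$alt_end),
    skip_start = NA_integer_,
    skip_end = NA_integer_
  )
}

call_exon_skip_events <- function(assigned, introns, models) {
  # candidate skip junctions: bridge the outer boundaries of two consecutive
  # (transcript-sense) introns flanking an annotated internal exon
  introns <- dplyr::arrange(introns, .data$transcript_id, .data$intron_rank)
  by_tx <- introns |>
    dplyr::group_by(.data$chrom, .data$gene_id, .data$transcript_id,
                    .data$strand) |>
    dplyr::reframe(
      # genomic extent of the skip junction over two transcript-consecutive
      # introns (works on both strands)
      first_start = pmin(.data$intron_start[-dplyr::n()], .data$intron_start[-1]),
      last_end = pmax(.data$intron_end[-dplyr::n()], .data$intron_end[-1]),
      exon_start = pmin(.data$intron_end[-dplyr::n()], .data$intron_end[-1]) + 1L,
      exon_end = pmax(.data$intron_start[-dplyr::n()], .data$intron_start[-1]) - 1L,
      # transcript-sense first flanking intron (inclusion junction)
      inc_start = .data$intron_start[-dplyr::n()],
      inc_end = .data$intron_end[-dplyr::n()]
    )
  if (nrow(by_tx) == 0) return(NULL)

  cand <- dplyr::distinct(
    by_tx, .data$chrom, .data$gene_id, .data$strand,
    .data$first_start, .data$last_end, .data$exon_start, .data$exon_end,
    .data$inc_start, .data$inc_end
  )
  hits <- dplyr::inner_join(
    assigned, cand,
    by = dplyr::join_by("chrom", "strand", "gene_id",
                        "intron_start" == "first_start",
                        "intron_end" == "last_end")
  )
  if (nrow(hits) == 0) return(NULL)
  hits <- dplyr::distinct(hits, .data$gene_id, .data$chrom, .data$strand,
                          .data$intron_start, .data$intron_end,
                          .data$exon_start, .data$exon_end,
                          .data$inc_start, .data$inc_end)
  tibble::tibble(
    event_id = sprintf("%s:exon_skip:%d-%d", hits$gene_id, hits$intron_start,
                       hits$intron_end),
    gene_id = hits$gene_id,
    chrom = hits$chrom,
    strand = hits$strand,
    event_type = "exon_skip",
    shared_site = NA_integer_,
    canonical_site = NA_integer_,
    alternative_site = NA_integer_,
    canonical_start = as.integer(hits$inc_start),
    canonical_end = as.integer(hits$inc_end),
    alt_start = as.integer(hits$intron_start),
    alt_end = as.integer(hits$intron_end),
    skip_start = as.integer(hits$exon_start),
    skip_end = as.integer(hits$exon_end)
  )
}

#' Quantify percent spliced in (PSI) per event and sample
#'
#' PSI is the bounded two-way ratio `alt / (alt + canonical)` of uniquely
#' mapping reads supporting the alternative junction over the total support
#' of the event's two junctions. When the total support is below
#' `min_coverage` the PSI value is reported missing. The literal unbounded
#' ratio `alt / canonical` is exposed alongside as `alt_canonical_ratio`.
#'
#' @param events Event tibble from [detect_events()].
#' @param junctions Junction tibble covering all samples.
#' @param samples Character vector of sample identifiers defining the matrix
#'   columns; defaults to the samples present in `junctions`.
#' @param min_coverage Total-read floor below which PSI is missing
#'   (default 10).
#' @return A long tibble: `event_id`, `sample_id`, `alt_reads`,
#'   `canonical_reads`, `total_reads`, `psi`, `alt_canonical_ratio`.
#' @export
compute_psi <- function(events, junctions, samples = NULL, min_coverage = 10) {
  if (any(junctions$unique_reads < 0)) {
    stop("negative junction read counts", call. = FALSE)
  }
  samples <- samples %||% sort(unique(junctions$sample_id))
  key <- function(chrom, start, end, strand, sample) {
    paste(chrom, start, end, strand, sample, sep = "\r")
  }
  counts <- junctions |>
    dplyr::group_by(.data$chrom, .data$intron_start, .data$intron_end,
                    .data$strand, .data$sample_id) |>
    dplyr::summarise(unique_reads = sum(.data$unique_reads), .groups = "drop")
  lookup <- stats::setNames(
    counts$unique_reads,
    key(counts$chrom, counts$intron_start, counts$intron_end, counts$strand,
        counts$sample_id)
  )
  grid <- tidyr::expand_grid(
    events[, c("event_id", "chrom", "strand", "canonical_start",
               "canonical_end", "alt_start", "alt_end")],
    sample_id = samples
  )
  alt <- lookup[key(grid$chrom, grid$alt_start, grid$alt_end, grid$strand,
                    grid$sample_id)]
  can <- lookup[key(grid$chrom, grid$canonical_start, grid$canonical_end,
                    grid$strand, grid$sample_id)]
  alt <- unname(alt); can <- unname(can)
  alt[is.na(alt)] <- 0L
  can[is.na(can)] <- 0L
  total <- alt + can
  psi <- ifelse(total >= min_coverage, alt / total, NA_real_)
  tibble::tibble(
    event_id = grid$event_id,
    sample_id = grid$sample_id,
    alt_reads = as.integer(alt),
    canonical_reads = as.integer(can),
    total_reads = as.integer(total),
    psi = psi,
    alt_canonical_ratio = ifelse(total >= min_coverage & can > 0, alt / can,
                                 NA_real_)
  )
}

#' Pivot long PSI values into an events-by-samples matrix
#'
#' @param psi Long PSI tibble from [compute_psi()].
#' @return A wide tibble: `event_id` plus one numeric column per sample.
#' @export
psi_matrix <- function(psi) {
  tidyr::pivot_wider(psi[, c("event_id", "sample_id", "psi")],
                     names_from = "sample_id", values_from = "psi")
}

#' Tabulate detected events by type
#'
#' Counts events per class, overall and among significant events, in the
#' style of an event-type summary panel.
#'
#' @param events Event tibble from [detect_events()].
#' @param significant Optional character vector of significant `event_id`s
#'   (or a logical vector along `events`).
#' @return A tibble with columns `event_type`, `n_events`, `n_significant`.
#' @export
summarize_event_types <- function(events, significant = NULL) {
  types <- c("A3SS", "A5SS", "exon_skip")
  if (is.null(significant)) {
    sig <- rep(FALSE, nrow(events))
  } else if (is.logical(significant)) {
    stopifnot(length(significant) == nrow(events))
    sig <- significant
  } else {
    sig <- events$event_id %in% significant
  }
  tibble::tibble(event_type = types) |>
    dplyr::left_join(
      tibble::tibble(event_type = events$event_type, sig = sig) |>
        dplyr::group_by(.data$event_type) |>
        dplyr::summarise(n_events = dplyr::n(), n_significant = sum(.data$sig),
                         .groups = "drop"),
      by = "event_type"
    ) |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L),
                  n_significant = dplyr::coalesce(.data$n_significant, 0L))
}
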