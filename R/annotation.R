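#' Read gene models from a GTF file
#'
#' Imports `exon` (and, when present, `CDS`) features and returns them as a
#' tidy gene-model table. Exons are sorted in genomic order within each
#' transcript. Every feature must carry `gene_id` and `transcript_id`
#' attributes.
#'
#' @param source Path to a GTF file.
#' @return A tibble with columns `chrom`, `gene_id`, `transcript_id`,
#'   `strand`, `feature` (`"exon"` or `"CDS"`), `start`, `end`
#'   (1-based inclusive).
#' @seealso [write_annotation()], [transcript_introns()]
#' @export
read_annotation <- function(source) {
  if (!file.exists(source)) {
    stop("annotation not found: ", source, call. = FALSE)
  }
  gr <- rtracklayer::import(source, format = "gtf")
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) {
    stop("GTF ", source, " has no feature type column", call. = FALSE)
  }
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (!any(df$type == "exon")) {
    stop("annotation ", source, " contains no exon features", call. = FALSE)
  }
  if (!"gene_id" %in% names(df) || anyNA(df$gene_id)) {
    stop("GTF ", source, " has exon features without a gene_id attribute",
         call. = FALSE)
  }
  if (!"transcript_id" %in% names(df) || anyNA(df$transcript_id)) {
    stop("GTF ", source, " has exon features without a transcript_id attribute",
         call. = FALSE)
  }
  models <- tibble::tibble(
    chrom = as.character(df$seqnames),
    gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    strand = as.character(df$strand),
    feature = as.character(df$type),
    start = as.integer(df$start),
    end = as.integer(df$end)
  )
  models <- dplyr::arrange(models, .data$gene_id, .data$transcript_id,
                           .data$feature, .data$start)
  validate_gene_models(models)
}

validate_gene_models <- function(models) {
  exons <- models[models$feature == "exon", , drop = FALSE]
  by_tx <- split(exons, exons$transcript_id)
  for (tx in by_tx) {
    o <- order(tx$start)
    if (any(tx$end[o][-nrow(tx)] >= tx$start[o][-1])) {
      stop("overlapping exons in transcript ", tx$transcript_id[1],
           call. = FALSE)
    }
  }
  models
}

cds_phases <- function(feature, strand, start, end) {
  n <- length(start)
  if (feature != "CDS") return(rep(NA_integer_, n))
  tx_order <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  len <- (end - start + 1L)[tx_order]
  ph <- integer(n)
  ph[tx_order] <- (3L - cumsum(c(0L, len[-n])) %% 3L) %% 3L
  ph
}

#' Write gene models to a GTF file
#'
#' @param models A gene-model tibble as returned by [read_annotation()].
#' @param sink Output path.
#' @return The input, invisibly.
#' @export
write_annotation <- function(models, sink) {
  # reading-frame phase for CDS features: first CDS segment of a transcript
  # starts in phase 0, later segments carry the carry-over
  models <- models |>
    dplyr::group_by(.data$transcript_id, .data$feature) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(phase = cds_phases(.data$feature[1], .data$strand[1],
                                     .data$start, .data$end)) |>
    dplyr::ungroup()
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand,
    type = models$feature,
    source = "cryptsplice",
    gene_id = models$gene_id,
    transcript_id = models$transcript_id,
    phase = models$phase
  )
  rtracklayer::export(gr, sink, format = "gtf")
  invisible(models[, setdiff(names(models), "phase")])
}

#' Derive introns and annotated splice sites from gene models
#'
#' Introns are the gaps between consecutive exons of a transcript. The donor
#' (5' splice site) is the intron boundary adjacent to the upstream exon in
#' transcript sense and the acceptor (3' splice site) the boundary adjacent
#' to the downstream exon: on `+` the acceptor is `intron_end`, on `-` it is
#' `intron_start`.
#'
#' @param models A gene-model tibble.
#' @return A tibble with one row per intron: `chrom`, `gene_id`,
#'   `transcript_id`, `strand`, `intron_start`, `intron_end`, `donor`,
#'   `acceptor`, `intron_rank` (transcript-sense order, 1-based).
#' @export
transcript_introns <- function(models) {
  exons <- models[models$feature == "exon", , drop = FALSE]
  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  out <- exons |>
    dplyr::group_by(.data$chrom, .data$gene_id, .data$transcript_id,
                    .data$strand) |>
    dplyr::reframe(
      intron_start = .data$end[-dplyr::n()] + 1L,
      intron_end = .data$start[-1] - 1L
    ) |>
    dplyr::filter(.data$intron_start <= .data$intron_end)
  out <- dplyr::mutate(
    out,
    donor = ifelse(.data$strand == "+", .data$intron_start, .data$intron_end),
    acceptor = ifelse(.data$strand == "+", .data$intron_end, .data$intron_start)
  )
  out |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(intron_rank = if (.data$strand[1] == "+") {
      rank(.data$intron_start)
    } else {
      rank(-.data$intron_start)
    }) |>
    dplyr::ungroup()
}

#' @rdname transcript_introns
#' @return `gene_spans()` returns one row per gene with its genomic extent.
#' @export
gene_spans <- function(models) {
  models[models$feature == "exon", , drop = FALSE] |>
    dplyr::group_by(.data$chrom, .data$gene_id, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
}
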