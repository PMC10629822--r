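#' Read a two-column ortholog map
#'
#' A headered TSV with columns `gene_a` and `gene_b` pairing gene
#' identifiers of two cohorts (e.g. mouse and human). Duplicate pairs are
#' dropped; one-to-many mappings are allowed but reported via a message.
#'
#' @param source Path to the TSV.
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_map <- function(source) {
  if (!file.exists(source)) {
    stop("ortholog map not found: ", source, call. = FALSE)
  }
  tbl <- read_tsv_quiet(source, col_types = "cc", progress = FALSE)
  stop_on_parse_problems(tbl, source)
  if (!all(c("gene_a", "gene_b") %in% names(tbl))) {
    stop("ortholog map must have columns gene_a and gene_b", call. = FALSE)
  }
  validate_ortholog_map(tbl[, c("gene_a", "gene_b")])
}

validate_ortholog_map <- function(map) {
  map <- dplyr::distinct(map)
  n_multi <- sum(duplicated(map$gene_a)) + sum(duplicated(map$gene_b))
  if (n_multi > 0) {
    message("ortholog map contains ", n_multi, " one-to-many mapping(s)")
  }
  map
}

#' Gene-level overlap of significant alternative-3'ss events across cohorts
#'
#' Translates cohort A's significant gene set through the ortholog map and
#' intersects it with cohort B's at the gene level (cross-species event
#' coordinates are not comparable). Genes absent from the map are counted as
#' cohort-private and reported via a message.
#'
#' @param genes_a,genes_b Character vectors of gene identifiers with a
#'   significant A3SS event in each cohort (already thresholded per cohort).
#' @param map Ortholog map tibble with columns `gene_a`, `gene_b`.
#' @return A list with `counts` (tibble: `a_only`, `shared`, `b_only`) and
#'   `shared` (tibble of `gene_a`, `gene_b` pairs, sorted).
#' @export
overlap_events <- function(genes_a, genes_b, map) {
  map <- validate_ortholog_map(map[, c("gene_a", "gene_b")])
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  unmapped_a <- setdiff(genes_a, map$gene_a)
  unmapped_b <- setdiff(genes_b, map$gene_b)
  if (length(unmapped_a) + length(unmapped_b) > 0) {
    message(length(unmapped_a), " cohort-A and ", length(unmapped_b),
            " cohort-B gene(s) absent from the ortholog map; counted as private")
  }
  shared_pairs <- map[map$gene_a %in% genes_a & map$gene_b %in% genes_b, ,
                      drop = FALSE]
  shared_a <- unique(shared_pairs$gene_a)
  shared_b <- unique(shared_pairs$gene_b)
  # shared is counted as ortholog pairs, which keeps the tally symmetric
  # under cohort swap even for one-to-many maps (equal to shared genes for
  # one-to-one maps)
  counts <- tibble::tibble(
    a_only = length(setdiff(genes_a, shared_a)),
    shared = nrow(shared_pairs),
    b_only = length(setdiff(genes_b, shared_b))
  )
  shared_pairs <- dplyr::arrange(shared_pairs, .data$gene_a, .data$gene_b)
  list(counts = counts, shared = shared_pairs)
}
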