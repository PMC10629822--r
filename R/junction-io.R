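# readr warnings about parse problems are redundant here: problems() is
# inspected explicitly and converted to errors with line numbers
read_tsv_quiet <- function(...) suppressWarnings(readr::read_tsv(...))

#' Read a splice-junction table
#'
#' Reads per-sample splice-junction read counts in one of two dialects:
#'
#' * `"sj_tab"` — the STAR `SJ.out.tab` format: nine unnamed, tab-separated
#'   columns (chromosome, intron start, intron end, strand code, splice motif,
#'   annotation flag, uniquely mapping reads, multi-mapping reads, maximum
#'   overhang). Strand codes 0/1/2 map to `"*"` (undefined), `"+"`, `"-"`.
#'   Multi-mapping read counts are discarded: only uniquely mapping reads
#'   support junction quantification.
#' * `"simple_tsv"` — a headered TSV with columns `chrom`, `intron_start`,
#'   `intron_end`, `strand` (`+`, `-` or `*`), `unique_reads` and optionally
#'   `sample_id`.
#'
#' Coordinates are 1-based inclusive intron intervals: `intron_start` is the
#' first intronic base and `intron_end` the last (the G of the acceptor AG on
#' the plus strand).
#'
#' @param source Path to the junction file.
#' @param dialect `"simple_tsv"` or `"sj_tab"`.
#' @param sample_id Sample identifier attached to every junction. Defaults to
#'   the file name without extension (or the file's `sample_id` column for
#'   `simple_tsv` when present).
#' @return A tibble with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `unique_reads`, `sample_id`.
#' @seealso [write_junction_table()], [read_sample_sheet()]
#' @export
read_junction_table <- function(source,
                                dialect = c("simple_tsv", "sj_tab"),
                                sample_id = NULL) {
  if (!is.character(dialect) || !all(dialect %in% c("simple_tsv", "sj_tab"))) {
    stop("unknown junction dialect: ", paste(setdiff(dialect, c("simple_tsv", "sj_tab")), collapse = ", "),
         call. = FALSE)
  }
  dialect <- match.arg(dialect)
  if (!file.exists(source)) {
    stop("junction table not found: ", source, call. = FALSE)
  }
  default_id <- sub("\\.[^.]*$", "", basename(source))

  if (dialect == "sj_tab") {
    tbl <- read_tsv_quiet(
      source,
      col_names = c("chrom", "intron_start", "intron_end", "strand_code",
                    "motif", "annotated", "unique_reads", "multi_reads",
                    "max_overhang"),
      col_types = "ciiiiiiii",
      progress = FALSE
    )
    stop_on_parse_problems(tbl, source)
    jx <- tibble::tibble(
      chrom = tbl$chrom,
      intron_start = tbl$intron_start,
      intron_end = tbl$intron_end,
      strand = c("*", "+", "-")[tbl$strand_code + 1L],
      unique_reads = tbl$unique_reads,
      sample_id = sample_id %||% default_id
    )
    if (anyNA(jx$strand)) {
      bad <- which(is.na(jx$strand))[1]
      stop("malformed sj_tab line ", bad, " in ", source,
           ": strand code must be 0, 1 or 2", call. = FALSE)
    }
  } else {
    tbl <- read_tsv_quiet(source, col_types = readr::cols(
      chrom = readr::col_character(),
      intron_start = readr::col_integer(),
      intron_end = readr::col_integer(),
      strand = readr::col_character(),
      .default = readr::col_guess()
    ), progress = FALSE)
    stop_on_parse_problems(tbl, source)
    required <- c("chrom", "intron_start", "intron_end", "strand", "unique_reads")
    missing_cols <- setdiff(required, names(tbl))
    if (length(missing_cols)) {
      stop("simple_tsv junction table ", source, " lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    jx <- tibble::tibble(
      chrom = tbl$chrom,
      intron_start = tbl$intron_start,
      intron_end = tbl$intron_end,
      strand = tbl$strand,
      unique_reads = as.integer(tbl$unique_reads),
      sample_id = sample_id %||% (if ("sample_id" %in% names(tbl)) tbl$sample_id else default_id)
    )
  }
  validate_junctions(jx, source)
}

stop_on_parse_problems <- function(tbl, source) {
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop("malformed line ", probs$row[1], " in ", source, ": ",
         probs$expected[1], " expected, got '", probs$actual[1], "'",
         call. = FALSE)
  }
  invisible(tbl)
}

validate_junctions <- function(jx, source = "junction table") {
  if (nrow(jx) == 0) return(jx)
  if (!all(jx$strand %in% c("+", "-", "*"))) {
    stop("invalid strand value in ", source,
         " (expected '+', '-' or '*')", call. = FALSE)
  }
  bad <- which(jx$intron_start > jx$intron_end | jx$intron_start < 1 |
                 jx$unique_reads < 0 | is.na(jx$unique_reads))
  if (length(bad)) {
    stop("malformed line ", bad[1], " in ", source,
         ": need 1 <= intron_start <= intron_end and unique_reads >= 0",
         call. = FALSE)
  }
  jx
}

#' Write a junction table in the simple TSV dialect
#'
#' @param junctions A junction tibble as returned by [read_junction_table()].
#' @param sink Output path.
#' @return The input, invisibly.
#' @export
write_junction_table <- function(junctions, sink) {
  validate_junctions(junctions)
  readr::write_tsv(
    junctions[, c("chrom", "intron_start", "intron_end", "strand",
                  "unique_reads", "sample_id")],
    sink, progress = FALSE
  )
  invisible(junctions)
}

#' Read a sample sheet
#'
#' The sample sheet is a headered TSV with columns `sample_id`, `group`
#' (`WT` or `MUT`) and `path` (junction table location, resolved relative to
#' the sheet's directory when not absolute).
#'
#' @param source Path to the sample sheet.
#' @return A tibble with columns `sample_id`, `group`, `path`.
#' @export
read_sample_sheet <- function(source) {
  if (!file.exists(source)) {
    stop("sample sheet not found: ", source, call. = FALSE)
  }
  tbl <- read_tsv_quiet(source, col_types = "ccc", progress = FALSE)
  stop_on_parse_problems(tbl, source)
  required <- c("sample_id", "group", "path")
  if (!all(required %in% names(tbl))) {
    stop("sample sheet must have columns sample_id, group, path", call. = FALSE)
  }
  if (anyDuplicated(tbl$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         tbl$sample_id[duplicated(tbl$sample_id)][1], call. = FALSE)
  }
  if (!all(tbl$group %in% c("WT", "MUT"))) {
    stop("sample sheet group must be 'WT' or 'MUT'", call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", tbl$path)
  tbl$path[rel] <- file.path(dirname(source), tbl$path[rel])
  tbl[, required]
}

#' @rdname read_sample_sheet
#' @param samples A sample-sheet tibble.
#' @param sink Output path.
#' @export
write_sample_sheet <- function(samples, sink) {
  readr::write_tsv(samples[, c("sample_id", "group", "path")], sink,
                   progress = FALSE)
  invisible(samples)
}

#' Read and write PSI matrices
#'
#' A PSI matrix is stored as a TSV whose first column `event_id` holds event
#' identifiers and whose remaining columns hold per-sample PSI values in
#' \[0, 1\]; missing values (events below the coverage floor in a sample) are
#' encoded as `NA`. Values survive a round trip to at least six decimals and
#' the missingness pattern is preserved exactly.
#'
#' @param source,sink File path.
#' @param matrix A wide tibble: `event_id` plus one numeric column per sample.
#' @return `read_psi_matrix()` returns the wide tibble; `write_psi_matrix()`
#'   returns its input invisibly.
#' @export
read_psi_matrix <- function(source) {
  if (!file.exists(source)) {
    stop("PSI matrix not found: ", source, call. = FALSE)
  }
  tbl <- read_tsv_quiet(source, col_types = readr::cols(
    event_id = readr::col_character(),
    .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop("PSI matrix ", source, " is not rectangular or not numeric (line ",
         probs$row[1], ")", call. = FALSE)
  }
  if (!"event_id" %in% names(tbl)) {
    stop("PSI matrix must have an event_id column", call. = FALSE)
  }
  if (anyDuplicated(tbl$event_id)) {
    stop("duplicate event_id in PSI matrix: ",
         tbl$event_id[duplicated(tbl$event_id)][1], call. = FALSE)
  }
  tbl
}

#' @rdname read_psi_matrix
#' @export
write_psi_matrix <- function(matrix, sink) {
  if (!"event_id" %in% names(matrix)) {
    stop("PSI matrix must have an event_id column", call. = FALSE)
  }
  if (anyDuplicated(matrix$event_id)) {
    stop("duplicate event_id in PSI matrix: ",
         matrix$event_id[duplicated(matrix$event_id)][1], call. = FALSE)
  }
  readr::write_tsv(matrix, sink, na = "NA", progress = FALSE)
  invisible(matrix)
}
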