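revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Define a two-isoform amplicon assay
#'
#' Models a targeted RT-PCR assay over a splice junction with two possible
#' products: the canonical amplicon and a non-canonical amplicon carrying an
#' intronic insertion (the sequence included by a cryptic 3'ss) at the exon
#' junction. Each isoform gets a diagnostic string: the `k`-mer centered on
#' its junction (exon-exon for the canonical isoform, exon-intron for the
#' non-canonical one), which must not occur in the other isoform's template
#' in either orientation.
#'
#' @param canonical Canonical template sequence (the amplicon region).
#' @param insertion Intronic sequence included in the non-canonical isoform;
#'   must be non-empty.
#' @param fwd_primer,rev_primer Primer sequences; the forward primer must
#'   occur exactly once in each template, the reverse primer exactly once as
#'   its reverse complement.
#' @param junction_pos 1-based position of the last base of the upstream
#'   exon within `canonical`; the insertion sits immediately after it.
#' @param k Diagnostic string length (even, default 16).
#' @return A list of class `cryptsplice_amplicon_assay` with the two
#'   templates, primers, insertion and diagnostic strings.
#' @export
amplicon_assay <- function(canonical, insertion, fwd_primer, rev_primer,
                           junction_pos, k = 16L) {
  if (nchar(insertion) < 1) {
    stop("insertion must be non-empty (a zero-length insertion is not an assay)",
         call. = FALSE)
  }
  if (k %% 2 != 0 || k < 4) stop("k must be an even number >= 4", call. = FALSE)
  non_canonical <- paste0(
    substr(canonical, 1, junction_pos), insertion,
    substr(canonical, junction_pos + 1, nchar(canonical))
  )
  count_hits <- function(pattern, subject) {
    length(gregexpr(pattern, subject, fixed = TRUE)[[1]][
      gregexpr(pattern, subject, fixed = TRUE)[[1]] > 0])
  }
  for (tmpl in c(canonical = canonical, non_canonical = non_canonical)) {
    if (count_hits(fwd_primer, tmpl) != 1) {
      stop("forward primer must occur exactly once in each template",
           call. = FALSE)
    }
    if (count_hits(revcomp_str(rev_primer), tmpl) != 1) {
      stop("reverse primer must occur exactly once (as reverse complement) in each template",
           call. = FALSE)
    }
  }
  half <- k %/% 2
  diag_canonical <- substr(canonical, junction_pos - half + 1, junction_pos + half)
  diag_non_canonical <- substr(non_canonical, junction_pos - half + 1,
                               junction_pos + half)
  occurs <- function(s, tmpl) {
    grepl(s, tmpl, fixed = TRUE) || grepl(revcomp_str(s), tmpl, fixed = TRUE)
  }
  if (occurs(diag_canonical, non_canonical) ||
      occurs(diag_non_canonical, canonical)) {
    stop("diagnostic junction strings are not unique to their isoform; ",
         "increase k or adjust the templates", call. = FALSE)
  }
  structure(list(
    canonical = canonical,
    non_canonical = non_canonical,
    insertion = insertion,
    fwd_primer = fwd_primer,
    rev_primer = rev_primer,
    junction_pos = as.integer(junction_pos),
    k = as.integer(k),
    diag_canonical = diag_canonical,
    diag_non_canonical = diag_non_canonical
  ), class = "cryptsplice_amplicon_assay")
}

#' Bundled synthetic amplicon fixtures
#'
#' Deterministic synthetic assays reproducing the printed geometries of the
#' MAP3K7 exon 4/5 junction amplicons: `"human"` gives a 94 bp canonical and
#' 114 bp non-canonical product (20 nt insertion), `"mouse"` a 114 bp
#' canonical and 137 bp non-canonical product (23 nt insertion). The
#' template sequences themselves are synthetic (generated from a fixed
#' internal seed, insertion ending in AG); only the geometry follows the
#' published assays.
#'
#' @param geometry `"human"` or `"mouse"`.
#' @return A `cryptsplice_amplicon_assay`.
#' @export
amplicon_fixture <- function(geometry = c("human", "mouse")) {
  geometry <- match.arg(geometry)
  geom <- switch(geometry,
                 human = list(canonical_len = 94L, insertion_len = 20L,
                              junction_pos = 47L, seed = 104729L),
                 mouse = list(canonical_len = 114L, insertion_len = 23L,
                              junction_pos = 57L, seed = 224737L))
  withr::with_seed(geom$seed, {
    canonical <- paste(sample(BASES, geom$canonical_len, replace = TRUE),
                       collapse = "")
    insertion <- paste0(
      paste(sample(BASES, geom$insertion_len - 2L, replace = TRUE),
            collapse = ""),
      "AG"
    )
    amplicon_assay(
      canonical = canonical,
      insertion = insertion,
      fwd_primer = substr(canonical, 1, 20),
      rev_primer = revcomp_str(substr(canonical, geom$canonical_len - 19L,
                                      geom$canonical_len)),
      junction_pos = geom$junction_pos
    )
  })
}

#' Predict amplicon lengths for both isoforms
#'
#' Lengths are measured from the forward primer's 5' end to the reverse
#' primer's 5' end, inclusive, on each template.
#'
#' @param assay A [amplicon_assay()].
#' @return A tibble with columns `isoform` (`canonical`, `non_canonical`)
#'   and `length_bp`.
#' @export
predict_amplicons <- function(assay) {
  stopifnot(inherits(assay, "cryptsplice_amplicon_assay"))
  one <- function(tmpl) {
    fwd_start <- regexpr(assay$fwd_primer, tmpl, fixed = TRUE)[1]
    rev_rc <- revcomp_str(assay$rev_primer)
    rev_start <- regexpr(rev_rc, tmpl, fixed = TRUE)[1]
    rev_end <- rev_start + nchar(rev_rc) - 1L
    as.integer(rev_end - fwd_start + 1L)
  }
  tibble::tibble(
    isoform = c("canonical", "non_canonical"),
    length_bp = c(one(assay$canonical), one(assay$non_canonical))
  )
}

#' Classify amplicon reads by diagnostic junction strings
#'
#' A read is assigned to the isoform whose diagnostic junction `k`-mer it
#' contains (in either orientation); reads matching both or neither are
#' unassigned. This exact-match rule assumes error-free reads.
#'
#' @param reads Character vector of read sequences, a
#'   [Biostrings::DNAStringSet-class], or the path to a FASTA/FASTQ file.
#' @param assay A [amplicon_assay()].
#' @return A one-row tibble of class `cryptsplice_isoform_summary`:
#'   `n_canonical`, `n_non_canonical`, `n_unassigned`, `n_total`,
#'   `misspliced_fraction` (= non-canonical / (canonical + non-canonical)).
#' @export
classify_reads <- function(reads, assay) {
  stopifnot(inherits(assay, "cryptsplice_amplicon_assay"))
  if (inherits(reads, "XStringSet")) {
    reads <- as.character(reads)
  } else if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
             grepl("\\.(fastq|fq|fasta|fa)$", reads)) {
    fmt <- if (grepl("\\.(fastq|fq)$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  detect <- function(s) {
    stringr::str_detect(reads, stringr::fixed(s)) |
      stringr::str_detect(reads, stringr::fixed(revcomp_str(s)))
  }
  hit_can <- detect(assay$diag_canonical)
  hit_non <- detect(assay$diag_non_canonical)
  n_can <- sum(hit_can & !hit_non)
  n_non <- sum(hit_non & !hit_can)
  n_un <- length(reads) - n_can - n_non
  tibble::new_tibble(
    tibble::tibble(
      n_canonical = n_can,
      n_non_canonical = n_non,
      n_unassigned = n_un,
      n_total = length(reads),
      misspliced_fraction = if (n_can + n_non > 0) n_non / (n_can + n_non) else NA_real_
    ),
    class = "cryptsplice_isoform_summary"
  )
}

#' Simulate error-free amplicon reads
#'
#' Draws each read's isoform from a Bernoulli with the given non-canonical
#' fraction and emits the full template sequence, reverse-complementing each
#' read with probability one half.
#'
#' @param assay A [amplicon_assay()].
#' @param n Number of reads.
#' @param non_canonical_fraction True misspliced fraction.
#' @param seed Integer seed.
#' @return Character vector of `n` read sequences.
#' @export
simulate_amplicon_reads <- function(assay, n, non_canonical_fraction,
                                    seed = 1L) {
  stopifnot(inherits(assay, "cryptsplice_amplicon_assay"))
  withr::with_seed(as.integer(seed), {
    is_non <- stats::runif(n) < non_canonical_fraction
    reads <- ifelse(is_non, assay$non_canonical, assay$canonical)
    flip <- stats::runif(n) < 0.5
    reads[flip] <- vapply(reads[flip], revcomp_str, character(1),
                          USE.NAMES = FALSE)
    reads
  })
}
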