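#' Distance from the cryptic to the canonical 3' splice site
#'
#' Positive distances mean the cryptic acceptor lies upstream of the
#' canonical one (inside the intron), so the distance equals the length of
#' the intronic sequence included in the mature transcript. On the plus
#' strand `d = canonical - alternative`; on the minus strand
#' `d = alternative - canonical`.
#'
#' @param events A3SS event tibble (rows of [detect_events()] output).
#' @return Integer vector of signed distances, one per event.
#' @export
cryptic_distance <- function(events) {
  if (!all(events$event_type == "A3SS")) {
    stop("cryptic_distance() is defined for A3SS events only", call. = FALSE)
  }
  d <- ifelse(events$strand == "+",
              events$canonical_site - events$alternative_site,
              events$alternative_site - events$canonical_site)
  if (any(d == 0)) {
    stop("event with identical canonical and alternative acceptor", call. = FALSE)
  }
  as.integer(d)
}

#' Histogram of cryptic-site distances on log2 bins
#'
#' Positive (intron-internal, upstream) distances are tabulated in log2 bins
#' `[1,2), [2,4), [4,8), ...`; negative distances (downstream shifts) are
#' collected in a single `downstream` bin.
#'
#' @param events A3SS event tibble, or an integer vector of signed distances.
#' @return A tibble with `bin` (label), `lower`, `upper`, `count` and
#'   `is_mode` (TRUE for the modal bin among positive distances).
#' @export
distance_histogram <- function(events) {
  d <- if (is.numeric(events)) as.integer(events) else cryptic_distance(events)
  if (length(d) == 0) {
    return(tibble::tibble(bin = character(), lower = integer(),
                          upper = integer(), count = integer(),
                          is_mode = logical()))
  }
  pos <- d[d >= 1]
  neg <- d[d < 1]
  out <- NULL
  if (length(pos)) {
    k <- floor(log2(pos))
    counts <- table(factor(k, levels = 0:max(k)))
    out <- tibble::tibble(
      bin = sprintf("[%d,%d)", 2^(as.integer(names(counts))),
                    2^(as.integer(names(counts)) + 1L)),
      lower = 2^(as.integer(names(counts))),
      upper = 2^(as.integer(names(counts)) + 1L),
      count = as.integer(counts)
    )
    out$is_mode <- out$count == max(out$count) &
      seq_len(nrow(out)) == which.max(out$count)
  }
  if (length(neg)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      bin = "downstream", lower = NA_integer_, upper = NA_integer_,
      count = length(neg), is_mode = FALSE
    ))
  }
  out
}

#' Extract transcript-sense sequence windows around 3' splice sites
#'
#' Offsets are relative to the splice site with 0 at the last intronic base
#' (the G of the acceptor AG) and +1 at the first exonic base; negative
#' offsets are intronic. Minus-strand windows are reverse-complemented so
#' all sequences read in transcript sense and align at the splice site. The
#' default window (-30..+9, 40 nt) spans the branchpoint-distal PPT through
#' the exon start.
#'
#' @param events A3SS event tibble.
#' @param site `"canonical"` or `"cryptic"` (the alternative acceptor).
#' @param genome A [Biostrings::DNAStringSet-class] covering the events'
#'   chromosomes.
#' @param offsets Length-2 integer vector `c(from, to)`.
#' @return A tibble with `event_id` and `sequence`; events whose window
#'   falls off the contig are skipped with a message.
#' @export
extract_ss_windows <- function(events, site = c("canonical", "cryptic"),
                               genome, offsets = c(-30L, 9L)) {
  site <- match.arg(site)
  stopifnot(length(offsets) == 2, offsets[1] <= offsets[2])
  coord <- if (site == "canonical") events$canonical_site else events$alternative_site
  seqs <- character(nrow(events))
  keep <- logical(nrow(events))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(events))) {
    chrom <- events$chrom[i]
    if (events$strand[i] == "+") {
      start <- coord[i] + offsets[1]; end <- coord[i] + offsets[2]
    } else {
      start <- coord[i] - offsets[2]; end <- coord[i] - offsets[1]
    }
    if (!chrom %in% names(lens) || start < 1 || end > lens[[chrom]]) {
      message("window off contig for event ", events$event_id[i], "; skipped")
      next
    }
    s <- Biostrings::subseq(genome[[chrom]], start, end)
    if (events$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
    keep[i] <- TRUE
  }
  tibble::tibble(event_id = events$event_id[keep], sequence = seqs[keep])
}

#' Position frequency matrix and information content of aligned sequences
#'
#' Computes per-position A/C/G/T counts, relative frequencies and Shannon
#' information content `IC = 2 - H` (bits, log2) for a set of equal-length
#' aligned sequences. `N` bases are excluded position-wise. No small-sample
#' correction is applied by default (matching logo tools run on small event
#' sets); enable `small_sample_correction` to subtract the approximation
#' `3 / (2 ln(2) n)`.
#'
#' @param sequences Character vector of equal-length sequences over
#'   `A`, `C`, `G`, `T`, `N` (or a tibble from [extract_ss_windows()]).
#' @param offsets Optional integer offsets labelling the positions.
#' @param small_sample_correction Apply the small-sample entropy correction.
#' @return A tibble with one row per position: `offset`, counts `A`, `C`,
#'   `G`, `T`, frequencies `freq_A` .. `freq_T`, `ic` (bits) and `n_obs`.
#' @export
motif_profile <- function(sequences, offsets = NULL,
                          small_sample_correction = FALSE) {
  if (inherits(sequences, "data.frame")) sequences <- sequences$sequence
  if (length(sequences) == 0) {
    stop("motif_profile() needs at least one sequence", call. = FALSE)
  }
  w <- unique(nchar(sequences))
  if (length(w) != 1) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(toupper(sequences), "")), ncol = w,
                  byrow = TRUE)
  if (!all(chars %in% c(BASES, "N"))) {
    stop("sequences may only contain A, C, G, T or N", call. = FALSE)
  }
  counts <- vapply(seq_len(w), function(j) {
    tabulate(factor(chars[, j], levels = BASES), nbins = 4)
  }, integer(4))
  n_obs <- colSums(counts)
  freq <- sweep(counts, 2, pmax(n_obs, 1L), "/")
  h <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- 2 - h
  if (small_sample_correction) {
    ic <- pmax(0, ic - 3 / (2 * log(2) * pmax(n_obs, 1L)))
  }
  ic[n_obs == 0] <- NA_real_
  tibble::tibble(
    offset = offsets %||% seq_len(w),
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    freq_A = freq[1, ], freq_C = freq[2, ], freq_G = freq[3, ],
    freq_T = freq[4, ],
    ic = ic,
    n_obs = as.integer(n_obs)
  )
}

count_fraction <- function(x, alphabet) {
  vapply(strsplit(toupper(as.character(x)), ""), function(ch) {
    ch <- ch[!is.na(ch) & ch != "N"]
    if (length(ch) == 0) return(NA_real_)
    mean(ch %in% alphabet)
  }, numeric(1))
}

#' Polypyrimidine-tract and branchpoint-window composition scores
#'
#' `ppt_score()` returns the fraction of pyrimidines (C/T) and
#' `branchpoint_a_fraction()` the fraction of adenosines among non-N bases
#' of a window sequence. The conventional windows are offsets -20..-5
#' (PPT) and -40..-10 (branchpoint search region) from the 3'ss.
#'
#' @param window Character vector of window sequences.
#' @return Numeric fraction in \[0, 1\], `NA` for empty/all-N windows.
#' @export
ppt_score <- function(window) count_fraction(window, PYRIMIDINES)

#' @rdname ppt_score
#' @export
branchpoint_a_fraction <- function(window) count_fraction(window, "A")

#' Flag likely nonsense-mediated-decay outcomes of intronic inclusions
#'
#' A cryptic acceptor `d` nt upstream of the canonical one includes `d` nt of
#' intronic sequence in the transcript. If `d` is not a multiple of 3 the
#' inclusion shifts the reading frame (`frameshift`). Otherwise the included
#' sequence is read in the annotated CDS frame at the insertion point: an
#' in-frame stop codon gives `ptc_in_frame`, none gives `none`. Genes without
#' CDS annotation are flagged `unknown_frame`. Codons spanning the insertion
#' boundaries are not scanned.
#'
#' @param events A3SS event tibble.
#' @param models Gene-model tibble with CDS features where available.
#' @param genome A [Biostrings::DNAStringSet-class].
#' @return Character vector along events with values `frameshift`,
#'   `ptc_in_frame`, `none` or `unknown_frame`.
#' @export
flag_nmd <- function(events, models, genome) {
  d <- cryptic_distance(events)
  if (any(d < 1)) {
    stop("flag_nmd() expects intron-internal (positive-distance) cryptic sites",
         call. = FALSE)
  }
  cds <- models[models$feature == "CDS", , drop = FALSE]
  out <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (d[i] %% 3 != 0) { out[i] <- "frameshift"; next }
    gene_cds <- cds[cds$gene_id == events$gene_id[i], , drop = FALSE]
    if (nrow(gene_cds) == 0) { out[i] <- "unknown_frame"; next }
    # CDS bases transcript-sense upstream of the canonical acceptor
    if (events$strand[i] == "+") {
      up <- pmin(gene_cds$end, events$canonical_site[i]) - gene_cds$start + 1L
    } else {
      up <- gene_cds$end - pmax(gene_cds$start, events$canonical_site[i]) + 1L
    }
    phase <- sum(pmax(up, 0L)) %% 3L
    inc <- included_sequence(events[i, , drop = FALSE], genome)
    first_codon <- (3L - phase) %% 3L + 1L
    if (first_codon > d[i] - 2L) { out[i] <- "none"; next }
    starts <- seq(first_codon, d[i] - 2L, by = 3L)
    codons <- substring(inc, starts, starts + 2L)
    out[i] <- if (any(codons %in% c("TAA", "TAG", "TGA"))) "ptc_in_frame" else "none"
  }
  out
}

# transcript-sense intronic sequence included by using the cryptic acceptor
included_sequence <- function(events, genome) {
  vapply(seq_len(nrow(events)), function(i) {
    if (events$strand[i] == "+") {
      s <- Biostrings::subseq(genome[[events$chrom[i]]],
                              events$alternative_site[i] + 1L,
                              events$canonical_site[i])
    } else {
      s <- Biostrings::reverseComplement(Biostrings::subseq(
        genome[[events$chrom[i]]],
        events$canonical_site[i],
        events$alternative_site[i] - 1L
      ))
    }
    as.character(s)
  }, character(1))
}

#' Characterize cryptic 3' splice sites
#'
#' Per-event annotation of significant (or all) A3SS events: signed cryptic
#' distance, included intronic sequence, PPT pyrimidine fraction and
#' branchpoint-window adenosine fraction at the canonical and cryptic sites,
#' and the NMD flag.
#'
#' @param events A3SS event tibble.
#' @param genome A [Biostrings::DNAStringSet-class].
#' @param models Gene-model tibble (CDS features used for the NMD flag; pass
#'   `NULL` to flag all events `unknown_frame`).
#' @param ppt_offsets,bp_offsets Scoring windows relative to each 3'ss.
#' @return A tibble with one row per event: `event_id`, `gene_id`,
#'   `distance`, `included_sequence`, `ppt_canonical`, `ppt_cryptic`,
#'   `bp_a_canonical`, `bp_a_cryptic`, `nmd_flag`.
#' @export
characterize_sites <- function(events, genome, models = NULL,
                               ppt_offsets = c(-20L, -5L),
                               bp_offsets = c(-40L, -10L)) {
  events <- events[events$event_type == "A3SS", , drop = FALSE]
  d <- cryptic_distance(events)
  win <- function(site, offs) {
    w <- extract_ss_windows(events, site, genome, offs)
    w$sequence[match(events$event_id, w$event_id)]
  }
  ppt_can <- win("canonical", ppt_offsets)
  ppt_cry <- win("cryptic", ppt_offsets)
  bp_can <- win("canonical", bp_offsets)
  bp_cry <- win("cryptic", bp_offsets)
  nmd <- if (!is.null(models) && any(models$feature == "CDS") && all(d >= 1)) {
    flag_nmd(events, models, genome)
  } else {
    rep("unknown_frame", nrow(events))
  }
  tibble::tibble(
    event_id = events$event_id,
    gene_id = events$gene_id,
    distance = d,
    included_sequence = ifelse(d >= 1, included_sequence(events, genome),
                               NA_character_),
    ppt_canonical = ppt_score(ppt_can),
    ppt_cryptic = ppt_score(ppt_cry),
    bp_a_canonical = branchpoint_a_fraction(bp_can),
    bp_a_cryptic = branchpoint_a_fraction(bp_cry),
    nmd_flag = nmd
  )
}
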