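#' Simulation configuration for a cryptic-splicing cohort
#'
#' Defines the study conditions emulated by the cohort simulator: a two-group
#' genotype contrast (wild-type vs SF3B1-mutant, default 3 vs 4 replicates as
#' in the murine tumor cohort), mostly alternative-3'ss events whose cryptic
#' acceptors sit a short log-normally distributed distance (mode inside
#' 8--14 nt) upstream of the canonical acceptor, a weakened polypyrimidine
#' tract (PPT) and enriched upstream adenosines at cryptic sites, and
#' negative-binomial junction coverage with binomial allocation of reads
#' between the cryptic and canonical acceptor.
#'
#' The configured PPT pyrimidine fractions are targets for the *measured*
#' content of the default scoring windows (offsets -20..-5 from each site):
#' windows are filled with a binomially drawn pyrimidine quota so that
#' canonical and cryptic windows read back their configured fractions even
#' where the two windows overlap geometrically (they do whenever the cryptic
#' distance is below ~21 nt).
#'
#' @param n_genes Number of simulated genes; one splice event per gene.
#' @param intron_length_range Integer range (nt) for intron lengths.
#' @param exon_length_range Integer range (nt) for exon lengths.
#' @param n_wt,n_mut Replicates per genotype group (defaults 3 and 4).
#' @param fraction_responsive Fraction of events with a genotype-dependent
#'   PSI shift.
#' @param delta_psi_effect True PSI increase in mutant samples at responsive
#'   events; `delta_psi_effect + baseline_psi_wt` must be at most 1.
#' @param baseline_psi_wt Baseline PSI of the alternative junction in
#'   wild-type samples (cryptic acceptors are nearly silent without the
#'   mutation).
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size
#'   for the per-event, per-sample junction coverage.
#' @param cryptic_distance_mode Mode (nt) of the discretized log-normal
#'   cryptic-to-canonical distance distribution; must lie in \[8, 14\] to
#'   match the mutant signature.
#' @param cryptic_distance_sdlog Log-scale SD of the distance distribution.
#' @param canonical_ppt_pyrimidine_fraction,cryptic_ppt_pyrimidine_fraction
#'   Target pyrimidine content of the canonical and cryptic PPT windows.
#' @param branchpoint_a_enrichment Per-base adenosine probability in the
#'   branchpoint-proximal window upstream of cryptic sites (background 0.25).
#' @param background_event_mix Named proportions of `A5SS` and `exon_skip`
#'   decoy events; the remainder are A3SS events.
#' @param missing_min_coverage Total-read floor below which PSI is missing.
#' @param mut_penetrance Multiplier in \[0, 1\] attenuating the mutant PSI
#'   shift (models partial allelic expression of the mutation; default 1,
#'   i.e. off).
#' @param seed Default seed used by the simulation functions.
#' @return A list of class `cryptsplice_sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       intron_length_range = c(150L, 600L),
                       exon_length_range = c(80L, 200L),
                       n_wt = 3,
                       n_mut = 4,
                       fraction_responsive = 0.25,
                       delta_psi_effect = 0.3,
                       baseline_psi_wt = 0.05,
                       coverage_mean = 50,
                       coverage_dispersion = 8,
                       cryptic_distance_mode = 11,
                       cryptic_distance_sdlog = 0.45,
                       canonical_ppt_pyrimidine_fraction = 0.85,
                       cryptic_ppt_pyrimidine_fraction = 0.55,
                       branchpoint_a_enrichment = 0.5,
                       background_event_mix = c(A5SS = 0.1, exon_skip = 0.1),
                       missing_min_coverage = 10,
                       mut_penetrance = 1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    intron_length_range = as.integer(intron_length_range),
    exon_length_range = as.integer(exon_length_range),
    n_wt = as.integer(n_wt),
    n_mut = as.integer(n_mut),
    fraction_responsive = fraction_responsive,
    delta_psi_effect = delta_psi_effect,
    baseline_psi_wt = baseline_psi_wt,
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    cryptic_distance_mode = cryptic_distance_mode,
    cryptic_distance_sdlog = cryptic_distance_sdlog,
    canonical_ppt_pyrimidine_fraction = canonical_ppt_pyrimidine_fraction,
    cryptic_ppt_pyrimidine_fraction = cryptic_ppt_pyrimidine_fraction,
    branchpoint_a_enrichment = branchpoint_a_enrichment,
    background_event_mix = background_event_mix,
    missing_min_coverage = as.integer(missing_min_coverage),
    mut_penetrance = mut_penetrance,
    seed = as.integer(seed)
  )
  probs <- c(cfg$fraction_responsive, cfg$delta_psi_effect, cfg$baseline_psi_wt,
             cfg$canonical_ppt_pyrimidine_fraction,
             cfg$cryptic_ppt_pyrimidine_fraction, cfg$branchpoint_a_enrichment,
             cfg$mut_penetrance, cfg$background_event_mix)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_wt < 2 || cfg$n_mut < 2) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (cfg$delta_psi_effect + cfg$baseline_psi_wt > 1) {
    stop("delta_psi_effect + baseline_psi_wt must not exceed 1", call. = FALSE)
  }
  if (sum(cfg$background_event_mix) > 1) {
    stop("background_event_mix proportions must sum to at most 1", call. = FALSE)
  }
  if (cfg$cryptic_distance_mode < 8 || cfg$cryptic_distance_mode > 14) {
    stop("cryptic_distance_mode must lie in [8, 14]", call. = FALSE)
  }
  structure(cfg, class = "cryptsplice_sim_config")
}

#' @export
print.cryptsplice_sim_config <- function(x, ...) {
  cat("<cryptsplice simulation config>\n")
  cat(sprintf("  %d genes, %d WT vs %d MUT samples\n", x$n_genes, x$n_wt, x$n_mut))
  cat(sprintf("  responsive fraction %.2f, delta PSI %.2f on baseline %.2f\n",
              x$fraction_responsive, x$delta_psi_effect, x$baseline_psi_wt))
  cat(sprintf("  coverage NB(mu = %.0f, size = %.0f), PSI missing below %d reads\n",
              x$coverage_mean, x$coverage_dispersion, x$missing_min_coverage))
  cat(sprintf("  cryptic distance lognormal mode %g nt, PPT pyrimidine %0.2f (canonical) vs %0.2f (cryptic)\n",
              x$cryptic_distance_mode, x$canonical_ppt_pyrimidine_fraction,
              x$cryptic_ppt_pyrimidine_fraction))
  invisible(x)
}

# sequence alphabet helpers -------------------------------------------------

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

rand_bases <- function(n) sample(BASES, n, replace = TRUE)

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

#' Sample cryptic-acceptor distances
#'
#' Distances are drawn from a log-normal distribution parameterized by its
#' mode, rounded to integers and truncated at 3 nt (a cryptic AG closer than
#' that would fuse with the canonical acceptor).
#'
#' @param n Number of draws.
#' @param mode Modal distance in nt.
#' @param sdlog Log-scale standard deviation.
#' @return Integer vector of distances (>= 3).
#' @keywords internal
sample_cryptic_distance <- function(n, mode, sdlog) {
  meanlog <- log(mode) + sdlog^2
  pmax(3L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

# fill `k` randomly chosen positions with pyrimidines, the rest with purines
fill_ppt_window <- function(seq_chars, positions, k) {
  n <- length(positions)
  k <- max(0L, min(n, k))
  pyr_at <- positions[sample.int(n, k)]
  pur_at <- setdiff(positions, pyr_at)
  seq_chars[pyr_at] <- sample(PYRIMIDINES, length(pyr_at), replace = TRUE)
  seq_chars[pur_at] <- sample(PURINES, length(pur_at), replace = TRUE)
  seq_chars
}

PPT_OFFSETS <- -20:-5     # scoring window relative to a 3'ss (0 = last intronic base)
BP_OFFSETS <- -40:-21     # adenosine-enriched region written upstream of cryptic sites

#' Simulate a toy genome with a cryptic 3'ss signature
#'
#' Generates `n_genes` three-exon genes on a single chromosome, each hosting
#' one splice event (A3SS, A5SS or exon skip per the configured mix). Every
#' intron starts GT and ends AG. Genes carrying an A3SS event additionally
#' receive a cryptic AG inside the first intron at a sampled distance upstream
#' of the canonical acceptor, a weakened PPT over the cryptic scoring window,
#' and an adenosine-enriched branchpoint-proximal region upstream of it. Genes
#' are placed on either strand; minus-strand gene blocks are stored
#' reverse-complemented so all sequence signatures are transcript-sense.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet-class]
#'   of one chromosome), `models` (gene-model tibble, exons plus CDS), and
#'   `truth` (one row per event: `event_id`, `gene_id`, `chrom`, `strand`,
#'   `event_type`, `responsive`, `true_distance`, `true_delta_psi`, and the
#'   genomic coordinates of the canonical, alternative and downstream
#'   constitutive junctions).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cryptsplice_sim_config"))
  withr::with_seed(as.integer(seed), simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  n <- cfg$n_genes
  mix <- cfg$background_event_mix
  p_decoy <- c(A5SS = unname(mix["A5SS"]), exon_skip = unname(mix["exon_skip"]))
  p_a3ss <- 1 - sum(p_decoy)
  event_type <- sample(c("A3SS", "A5SS", "exon_skip"), n, replace = TRUE,
                       prob = c(p_a3ss, p_decoy))
  responsive <- stats::runif(n) < cfg$fraction_responsive
  strand <- sample(c("+", "-"), n, replace = TRUE)

  chrom_chunks <- vector("list", 2 * n + 1)
  chrom_chunks[[1]] <- rand_bases(100L)
  cursor <- 100L

  models <- vector("list", n)
  truth <- vector("list", n)

  for (g in seq_len(n)) {
    gene_id <- sprintf("gene%04d", g)
    exon_len <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]), 3,
                       replace = TRUE)
    intron_len <- sample(seq(cfg$intron_length_range[1], cfg$intron_length_range[2]),
                         2, replace = TRUE)
    L <- sum(exon_len) + sum(intron_len)
    s <- rand_bases(L)

    # transcript-sense local coordinates
    e1 <- c(1L, exon_len[1])
    i1 <- c(e1[2] + 1L, e1[2] + intron_len[1])
    e2 <- c(i1[2] + 1L, i1[2] + exon_len[2])
    i2 <- c(e2[2] + 1L, e2[2] + intron_len[2])
    e3 <- c(i2[2] + 1L, i2[2] + exon_len[3])

    for (intr in list(i1, i2)) {
      s[intr[1]:(intr[1] + 1L)] <- c("G", "T")
      s[(intr[2] - 1L):intr[2]] <- c("A", "G")
    }

    a0 <- i1[2]           # canonical acceptor of intron 1 (last intronic base)
    d <- NA_integer_
    alt_local <- NULL

    if (event_type[g] == "A3SS") {
      ok <- FALSE
      for (try in 1:20) {
        d <- sample_cryptic_distance(1, cfg$cryptic_distance_mode,
                                     cfg$cryptic_distance_sdlog)
        if (d + 45L <= intron_len[1]) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("intron of gene ", gene_id,
             " too short to host the sampled cryptic distance", call. = FALSE)
      }
      ac <- a0 - d
      s[(ac - 1L):ac] <- c("A", "G")
      # adenosine-enriched branchpoint-proximal region upstream of the cryptic AG
      bp_pos <- ac + BP_OFFSETS
      s[bp_pos] <- sample(BASES, length(bp_pos), replace = TRUE,
                          prob = c(cfg$branchpoint_a_enrichment,
                                   rep((1 - cfg$branchpoint_a_enrichment) / 3, 3)))
      # canonical PPT window: binomial pyrimidine quota over non-AG positions
      can_win <- a0 + PPT_OFFSETS
      can_free <- setdiff(can_win, c(ac - 1L, ac))
      k_can <- stats::rbinom(1, length(can_win), cfg$canonical_ppt_pyrimidine_fraction)
      s <- fill_ppt_window(s, can_free, k_can)
      # cryptic PPT window: quota discounted by pyrimidines contributed by the
      # already-written canonical overlap
      cry_win <- ac + PPT_OFFSETS
      cry_free <- setdiff(cry_win, c(can_win, ac - 1L, ac))
      overlap <- intersect(cry_win, can_win)
      k_cry <- stats::rbinom(1, length(cry_win), cfg$cryptic_ppt_pyrimidine_fraction) -
        sum(s[overlap] %in% PYRIMIDINES)
      s <- fill_ppt_window(s, cry_free, k_cry)
      s[(ac - 1L):ac] <- c("A", "G")      # quota fill never overwrites the AGs
      s[(a0 - 1L):a0] <- c("A", "G")
      alt_local <- c(i1[1], ac)           # alternative (cryptic) intron
    } else if (event_type[g] == "A5SS") {
      d5 <- sample(10:30, 1)
      s[(i1[1] + d5):(i1[1] + d5 + 1L)] <- c("G", "T")
      alt_local <- c(i1[1] + d5, i1[2])   # alternative intron, shifted donor
    } else {
      alt_local <- c(i1[1], i2[2])        # exon-skipping junction
    }

    # place the gene block on the chromosome (minus-strand blocks are stored
    # reverse-complemented; local position p maps to cursor + L - p + 1)
    gstart <- cursor + 1L
    if (strand[g] == "+") {
      block <- s
      loc2gen <- function(p) gstart + p - 1L
    } else {
      block <- revcomp_chars(s)
      loc2gen <- function(p) gstart + L - p
    }
    map_iv <- function(iv) sort(c(loc2gen(iv[1]), loc2gen(iv[2])))
    chrom_chunks[[2 * g]] <- block
    chrom_chunks[[2 * g + 1]] <- rand_bases(100L)
    cursor <- cursor + L + 100L

    exon_iv <- lapply(list(e1, e2, e3), map_iv)
    cds_iv <- lapply(list(e2, e3), map_iv)
    tx_id <- sprintf("tx%04d", g)
    models[[g]] <- tibble::tibble(
      chrom = "chrSim1",
      gene_id = gene_id,
      transcript_id = tx_id,
      strand = strand[g],
      feature = rep(c("exon", "CDS"), c(3, 2)),
      start = vapply(c(exon_iv, cds_iv), `[`, integer(1), 1),
      end = vapply(c(exon_iv, cds_iv), `[`, integer(1), 2)
    )

    can_iv <- map_iv(i1)
    alt_iv <- map_iv(alt_local)
    j2_iv <- map_iv(i2)
    site_of <- function(iv) if (strand[g] == "+") iv[2] else iv[1]   # acceptor
    donor_of <- function(iv) if (strand[g] == "+") iv[1] else iv[2]
    event_id <- switch(
      event_type[g],
      A3SS = sprintf("%s:A3SS:%d>%d", gene_id, site_of(can_iv), site_of(alt_iv)),
      A5SS = sprintf("%s:A5SS:%d>%d", gene_id, donor_of(can_iv), donor_of(alt_iv)),
      exon_skip = sprintf("%s:exon_skip:%d-%d", gene_id, alt_iv[1], alt_iv[2])
    )
    this_type <- event_type[g]
    this_responsive <- responsive[g]
    truth[[g]] <- tibble::tibble(
      event_id = event_id,
      gene_id = gene_id,
      chrom = "chrSim1",
      strand = strand[g],
      event_type = this_type,
      responsive = this_responsive,
      true_distance = if (this_type == "A3SS") d else NA_integer_,
      true_delta_psi = if (this_responsive) cfg$delta_psi_effect * cfg$mut_penetrance else 0,
      canonical_start = can_iv[1], canonical_end = can_iv[2],
      alt_start = alt_iv[1], alt_end = alt_iv[2],
      j2_start = j2_iv[1], j2_end = j2_iv[2]
    )
  }

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(unlist(chrom_chunks), collapse = ""), "chrSim1")
  )
  models <- dplyr::bind_rows(models)
  models <- dplyr::arrange(models, .data$gene_id, .data$transcript_id,
                           .data$feature, .data$start)
  list(genome = genome, models = models, truth = dplyr::bind_rows(truth))
}

#' Simulate junction counts for a cohort
#'
#' For every sample and event, total event coverage is drawn from a negative
#' binomial with the configured mean and size; reads supporting the
#' alternative junction are binomial with success probability equal to the
#' sample's true PSI (baseline in WT; baseline plus the attenuated effect in
#' responsive mutant samples), the canonical junction receiving the
#' remainder. The downstream constitutive junction of each gene gets an
#' independent negative-binomial count. Zero-count junctions are not emitted,
#' mirroring aligner junction tables.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param config The [sim_config()] used to generate it.
#' @param seed Integer seed (defaults to `config$seed + 1` so genome and
#'   counts use distinct streams).
#' @return A list with `junctions` (long tibble over all samples) and
#'   `samples` (sample sheet with `sample_id`, `group`, `path` holding the
#'   file names [write_cohort()] will use).
#' @export
simulate_junction_counts <- function(truth, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "cryptsplice_sim_config"))
  withr::with_seed(as.integer(seed), simulate_counts_impl(truth, config))
}

simulate_counts_impl <- function(truth, cfg) {
  samples <- tibble::tibble(
    sample_id = c(sprintf("wt_%d", seq_len(cfg$n_wt)),
                  sprintf("mut_%d", seq_len(cfg$n_mut))),
    group = rep(c("WT", "MUT"), c(cfg$n_wt, cfg$n_mut))
  )
  samples$path <- paste0("junctions_", samples$sample_id, ".tsv")

  grid <- tidyr::expand_grid(truth, sample_id = samples$sample_id)
  grid <- dplyr::left_join(grid, samples[, c("sample_id", "group")],
                           by = "sample_id")
  m <- nrow(grid)
  total <- stats::rnbinom(m, mu = cfg$coverage_mean, size = cfg$coverage_dispersion)
  psi_true <- cfg$baseline_psi_wt +
    ifelse(grid$group == "MUT", grid$true_delta_psi, 0)
  alt <- stats::rbinom(m, total, psi_true)
  canonical <- total - alt
  j2 <- stats::rnbinom(m, mu = cfg$coverage_mean, size = cfg$coverage_dispersion)

  one <- function(start, end, reads) {
    tibble::tibble(chrom = grid$chrom, intron_start = start, intron_end = end,
                   strand = grid$strand, unique_reads = as.integer(reads),
                   sample_id = grid$sample_id)
  }
  junctions <- dplyr::bind_rows(
    one(grid$canonical_start, grid$canonical_end, canonical),
    one(grid$alt_start, grid$alt_end, alt),
    one(grid$j2_start, grid$j2_end, j2)
  )
  junctions <- junctions[junctions$unique_reads > 0, , drop = FALSE]
  junctions <- dplyr::arrange(junctions, .data$sample_id, .data$intron_start,
                              .data$intron_end)
  list(junctions = junctions, samples = samples)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genome()] and
#' [simulate_junction_counts()].
#'
#' @inheritParams simulate_genome
#' @return A list of class `cryptsplice_cohort` with elements `genome`,
#'   `models`, `truth`, `junctions`, `samples` and `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  gen <- simulate_genome(config, seed = seed)
  cnt <- simulate_junction_counts(gen$truth, config, seed = as.integer(seed) + 1L)
  structure(c(gen, cnt, list(config = config)), class = "cryptsplice_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the reference FASTA, GTF annotation, one junction table per sample
#' (simple TSV dialect), the sample sheet and the truth table, all re-readable
#' with the package's readers.
#'
#' @param cohort A `cryptsplice_cohort` from [simulate_cohort()].
#' @param directory Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cryptsplice_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create cohort directory: ", directory, call. = FALSE)
  }
  paths <- list(
    genome = file.path(directory, "genome.fa"),
    annotation = file.path(directory, "annotation.gtf"),
    sample_sheet = file.path(directory, "samples.tsv"),
    truth = file.path(directory, "truth.tsv")
  )
  Biostrings::writeXStringSet(cohort$genome, paths$genome)
  write_annotation(cohort$models, paths$annotation)
  sheet <- cohort$samples
  paths$junctions <- file.path(directory, sheet$path)
  for (i in seq_len(nrow(sheet))) {
    jx <- cohort$junctions[cohort$junctions$sample_id == sheet$sample_id[i], ,
                           drop = FALSE]
    write_junction_table(jx, paths$junctions[i])
  }
  write_sample_sheet(sheet, paths$sample_sheet)
  readr::write_tsv(cohort$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
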