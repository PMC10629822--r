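a3_event <- function(strand = "+", canonical = 2000L, alternative = 1980L,
                     chrom = "chrT", gene = "g1") {
  tibble::tibble(
    event_id = sprintf("%s:A3SS:%d>%d", gene, canonical, alternative),
    gene_id = gene, chrom = chrom, strand = strand, event_type = "A3SS",
    canonical_site = canonical, alternative_site = alternative
  )
}

test_that("cryptic distance is strand-symmetric and positive for upstream sites", {
  expect_equal(cryptic_distance(a3_event("+", 2000L, 1980L)), 20L)
  expect_equal(cryptic_distance(a3_event("-", 1001L, 1021L)), 20L)
  # a downstream shift is negative
  expect_equal(cryptic_distance(a3_event("+", 2000L, 2012L)), -12L)
  expect_error(cryptic_distance(a3_event("+", 2000L, 2000L)), "identical")
  ev <- a3_event(); ev$event_type <- "A5SS"
  expect_error(cryptic_distance(ev), "A3SS")
})

test_that("distance histogram uses log2 bins and flags the mode", {
  h <- distance_histogram(c(9L, 10L, 12L, 13L, 40L))
  expect_equal(h$count[h$bin == "[8,16)"], 4L)
  expect_equal(h$bin[h$is_mode], "[8,16)")

  h1 <- distance_histogram(1L)
  expect_equal(h1$bin, "[1,2)")
  expect_equal(h1$count, 1L)

  expect_equal(nrow(distance_histogram(integer(0))), 0)

  hneg <- distance_histogram(c(5L, -3L))
  expect_equal(hneg$count[hneg$bin == "downstream"], 1L)
})

test_that("splice-site windows are transcript-sense and end in AG", {
  # plus-strand gene with acceptor at 2000 and a mirrored minus-strand copy
  set.seed(99)
  fwd <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  fwd <- paste0(substr(fwd, 1, 1998), "AG", substr(fwd, 2001, 3000))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  genome <- Biostrings::DNAStringSet(c(chrF = fwd, chrR = rc))

  ev_f <- a3_event("+", 2000L, 1980L, chrom = "chrF")
  w <- extract_ss_windows(ev_f, "canonical", genome, c(-3L, 2L))
  expect_equal(nchar(w$sequence), 6)
  expect_equal(w$sequence, substr(fwd, 1997, 2002))
  expect_equal(substr(w$sequence, 3, 4), "AG")

  # the same site on the reverse-complemented contig reads identically
  ev_r <- a3_event("-", 3000L - 2000L + 1L, 3000L - 1980L + 1L, chrom = "chrR")
  w_r <- extract_ss_windows(ev_r, "canonical", genome, c(-3L, 2L))
  expect_equal(w_r$sequence, w$sequence)

  # off-contig windows are skipped with a message
  ev_edge <- a3_event("+", 10L, 5L, chrom = "chrF")
  expect_message(w_e <- extract_ss_windows(ev_edge, "canonical", genome,
                                           c(-30L, 9L)), "off contig")
  expect_equal(nrow(w_e), 0)
})

test_that("canonical windows from the simulator all end in AG", {
  co <- tiny_cohort()
  ev <- suppressMessages(detect_events(co$junctions, co$models))
  a3 <- ev[ev$event_type == "A3SS", ]
  w <- extract_ss_windows(a3, "canonical", co$genome, c(-1L, 0L))
  expect_true(all(w$sequence == "AG"))
  w_cry <- extract_ss_windows(a3, "cryptic", co$genome, c(-1L, 0L))
  expect_true(all(w_cry$sequence == "AG"))
})

test_that("information content follows the Shannon definition", {
  prof <- motif_profile(c("ACA", "ACC", "AGG", "AGT"))
  # position 1 all A -> 2 bits
  expect_equal(prof$ic[1], 2)
  # position 2: C,C,G,G -> (0, 1/2, 1/2, 0) -> 1 bit
  expect_equal(prof$ic[2], 1)
  # position 3: A,C,G,T -> uniform -> 0 bits
  expect_equal(prof$ic[3], 0)
  expect_true(all(abs(rowSums(as.matrix(
    prof[, c("freq_A", "freq_C", "freq_G", "freq_T")])) - 1) < 1e-12))
  expect_true(all(prof$ic >= 0 & prof$ic <= 2))

  expect_error(motif_profile(c("AAA", "AAAA")), "same length")
  expect_error(motif_profile(c("AAXA")), "A, C, G, T or N")

  # N bases are excluded position-wise
  profN <- motif_profile(c("AN", "AN", "AC"))
  expect_equal(profN$n_obs, c(3L, 1L))
  expect_equal(profN$ic[2], 2)

  # the small-sample correction only lowers IC
  prof_c <- motif_profile(c("ACA", "ACC", "AGG", "AGT"),
                          small_sample_correction = TRUE)
  expect_true(all(prof_c$ic <= prof$ic))
})

test_that("composition scores count pyrimidines and adenosines", {
  expect_equal(ppt_score("TTTTCCTTTTCCTTTT"), 1)
  expect_equal(ppt_score("AAAAAAAA"), 0)
  expect_equal(branchpoint_a_fraction("AAAAAAAA"), 1)
  expect_equal(branchpoint_a_fraction("TTTTCCTT"), 0)
  expect_equal(ppt_score("ACGT"), 0.5)
  expect_true(is.na(ppt_score("NNN")))
  expect_true(is.na(ppt_score("")))
})

test_that("NMD flags follow frame arithmetic on the included sequence", {
  # gene: exon [1,100], intron [101,400], exon [401,500]; CDS = second exon
  # cryptic acceptor 21 nt upstream of 400 includes intron bases 380..400
  inc <- paste0("TAA", paste(rep("C", 16), collapse = ""), "AG")  # 21 nt
  seqs <- paste0(
    paste(rep("G", 100), collapse = ""),
    paste(rep("C", 279), collapse = ""), inc,
    paste(rep("G", 100), collapse = "")
  )
  genome <- Biostrings::DNAStringSet(c(chrT = seqs))
  models <- tibble::tibble(
    chrom = "chrT", gene_id = "g1", transcript_id = "t1", strand = "+",
    feature = c("exon", "exon", "CDS"),
    start = c(1L, 401L, 401L), end = c(100L, 500L, 500L)
  )
  ev21 <- a3_event("+", 400L, 379L)   # d = 21, in-frame, TAA at codon 1
  expect_equal(flag_nmd(ev21, models, genome), "ptc_in_frame")

  ev20 <- a3_event("+", 400L, 380L)   # d = 20 -> frameshift
  expect_equal(flag_nmd(ev20, models, genome), "frameshift")

  no_cds <- models[models$feature == "exon", ]
  expect_equal(flag_nmd(ev21, no_cds, genome), "unknown_frame")

  # in-frame inclusion whose codon phase splits the TAA -> no stop read
  ev_none <- a3_event("+", 399L, 378L)
  expect_equal(flag_nmd(ev_none, models, genome), "none")
})

test_that("site characterization contrasts cryptic and canonical composition", {
  co <- tiny_cohort()
  ev <- suppressMessages(detect_events(co$junctions, co$models))
  a3 <- ev[ev$event_type == "A3SS", ]
  ch <- characterize_sites(a3, co$genome, co$models)
  expect_equal(nrow(ch), nrow(a3))
  expect_true(all(nchar(ch$included_sequence) == ch$distance))
  expect_lt(mean(ch$ppt_cryptic), mean(ch$ppt_canonical))
  expect_gt(mean(ch$bp_a_cryptic), mean(ch$bp_a_canonical))
  expect_true(all(ch$nmd_flag %in%
                    c("frameshift", "ptc_in_frame", "none", "unknown_frame")))
  # frame rule: non-multiples of 3 are always frameshift
  expect_true(all(ch$nmd_flag[ch$distance %% 3 != 0] == "frameshift"))
})
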