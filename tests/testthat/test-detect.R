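test_that("a shared donor with one novel acceptor yields one A3SS event", {
  models <- toy_models()
  jx <- toy_junctions(list(
    intron_start = c(1001L, 1001L),
    intron_end = c(2000L, 1980L),
    strand = c("+", "+")
  ))
  ev <- detect_events(jx, models)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "A3SS")
  expect_equal(ev$canonical_site, 2000L)
  expect_equal(ev$alternative_site, 1980L)
  expect_equal(ev$shared_site, 1001L)
  expect_equal(ev$gene_id, "gplus")
})

test_that("the same junction pair on the minus strand is an A5SS event", {
  # on '-' the transcript-sense acceptor is the shared intron start, so the
  # varying boundary is the donor
  models <- toy_models()
  jx <- toy_junctions(list(
    intron_start = c(7001L, 7001L),
    intron_end = c(8000L, 7980L),
    strand = c("-", "-")
  ))
  ev <- detect_events(jx, models)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "A5SS")
  expect_equal(ev$canonical_site, 8000L)
  expect_equal(ev$alternative_site, 7980L)
  expect_equal(ev$shared_site, 7001L)
})

test_that("a junction bridging two annotated introns is an exon skip", {
  models <- toy_models()
  jx <- toy_junctions(list(
    intron_start = c(1001L, 3001L, 1001L),
    intron_end = c(2000L, 4000L, 4000L),
    strand = c("+", "+", "+")
  ))
  ev <- detect_events(jx, models)
  skip <- ev[ev$event_type == "exon_skip", ]
  expect_equal(nrow(skip), 1)
  expect_equal(skip$skip_start, 2001L)
  expect_equal(skip$skip_end, 3000L)
  expect_equal(skip$alt_start, 1001L)
  expect_equal(skip$alt_end, 4000L)
  expect_equal(skip$canonical_start, 1001L)  # first flanking inclusion junction
  expect_equal(skip$canonical_end, 2000L)
})

test_that("undefined-strand and orphan junctions are dropped with a message", {
  models <- toy_models()
  jx <- toy_junctions(list(
    intron_start = c(1001L, 1001L, 90001L),
    intron_end = c(2000L, 1980L, 95000L),
    strand = c("*", "+", "+")
  ))
  msgs <- capture_messages(ev <- detect_events(jx, models))
  expect_true(any(grepl("undefined strand", msgs)))
  expect_true(any(grepl("not attributable", msgs)))
  expect_equal(nrow(ev), 0)   # canonical junction lost its only read
})

test_that("PSI follows the bounded two-way ratio with a coverage floor", {
  ev <- tibble::tibble(
    event_id = "e", chrom = "chrT", strand = "+",
    canonical_start = 1001L, canonical_end = 2000L,
    alt_start = 1001L, alt_end = 1980L
  )
  mk <- function(alt, can) toy_junctions(list(
    intron_start = c(1001L, 1001L), intron_end = c(2000L, 1980L),
    strand = c("+", "+"), unique_reads = c(can, alt)
  ))
  expect_equal(compute_psi(ev, mk(0L, 50L))$psi, 0)
  expect_equal(compute_psi(ev, mk(3L, 7L))$psi, 0.3)
  expect_true(is.na(compute_psi(ev, mk(2L, 3L))$psi))
  expect_equal(compute_psi(ev, mk(2L, 3L), min_coverage = 5)$psi, 0.4)
  # literal unbounded ratio is exposed alongside
  expect_equal(compute_psi(ev, mk(3L, 7L))$alt_canonical_ratio, 3 / 7)
  expect_error(compute_psi(ev, mk(-1L, 7L)), "negative")
})

test_that("PSI is monotone in alternative reads and bounded", {
  ev <- tibble::tibble(
    event_id = "e", chrom = "chrT", strand = "+",
    canonical_start = 1001L, canonical_end = 2000L,
    alt_start = 1001L, alt_end = 1980L
  )
  for (can in c(5L, 20L)) {
    psis <- vapply(0:30, function(alt) {
      jx <- toy_junctions(list(
        intron_start = c(1001L, 1001L), intron_end = c(2000L, 1980L),
        strand = c("+", "+"), unique_reads = c(can, alt)
      ))
      compute_psi(ev, jx, min_coverage = 1)$psi
    }, numeric(1))
    expect_true(all(diff(psis) >= 0))
    expect_true(all(psis >= 0 & psis <= 1))
  }
})

test_that("detection recovers exactly the simulated truth events", {
  co <- tiny_cohort()
  ev <- suppressMessages(detect_events(co$junctions, co$models))
  # completeness: every truth event whose alternative junction was observed
  observed_alt <- co$truth$event_id %in% co$truth$event_id[
    paste(co$truth$alt_start, co$truth$alt_end) %in%
      paste(co$junctions$intron_start, co$junctions$intron_end)]
  expect_true(all(co$truth$event_id[observed_alt] %in% ev$event_id))
  # soundness: nothing beyond the simulated events
  expect_true(all(ev$event_id %in% co$truth$event_id))
})

test_that("event calls are invariant under genome mirroring", {
  co <- tiny_cohort()
  L <- Biostrings::width(co$genome)[1]
  mirror_iv <- function(start, end) list(start = L + 1L - end, end = L + 1L - start)
  flip <- c(`+` = "-", `-` = "+", `*` = "*")

  jx <- co$junctions
  miv <- mirror_iv(jx$intron_start, jx$intron_end)
  jx$intron_start <- miv$start; jx$intron_end <- miv$end
  jx$strand <- unname(flip[jx$strand])

  models <- co$models
  miv <- mirror_iv(models$start, models$end)
  models$start <- miv$start; models$end <- miv$end
  models$strand <- unname(flip[models$strand])

  ev <- suppressMessages(detect_events(co$junctions, co$models))
  ev_m <- suppressMessages(detect_events(jx, models))
  expect_equal(nrow(ev), nrow(ev_m))
  # mirrored A3SS sites map back onto the original ones
  a3 <- ev[ev$event_type == "A3SS", ]
  a3m <- ev_m[ev_m$event_type == "A3SS", ]
  expect_setequal(paste(a3$gene_id, a3$canonical_site, a3$alternative_site),
                  paste(a3m$gene_id, L + 1L - a3m$canonical_site,
                        L + 1L - a3m$alternative_site))
})

test_that("event-type summaries count overall and significant events", {
  ev <- tibble::tibble(
    event_id = c("a", "b", "c", "d"),
    event_type = c("A3SS", "A3SS", "A3SS", "A5SS")
  )
  tab <- summarize_event_types(ev, c("a", "b", "c", "d"))
  expect_equal(tab$n_events, c(3L, 1L, 0L))
  expect_equal(tab$n_significant, c(3L, 1L, 0L))
  expect_equal(tab$event_type, c("A3SS", "A5SS", "exon_skip"))

  empty <- summarize_event_types(ev[0, ])
  expect_true(all(empty$n_events == 0))
})
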