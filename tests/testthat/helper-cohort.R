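# small simulated cohort shared across test files (built once per run)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 60, seed = 20260920 %% 1000L)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

# hand-built two-transcript annotation on both strands
toy_models <- function() {
  tibble::tibble(
    chrom = "chrT",
    gene_id = c(rep("gplus", 3), rep("gminus", 3)),
    transcript_id = c(rep("tplus", 3), rep("tminus", 3)),
    strand = rep(c("+", "-"), each = 3),
    feature = "exon",
    start = c(1L, 2001L, 4001L, 6001L, 8001L, 10001L),
    end = c(1000L, 3000L, 5000L, 7000L, 9000L, 11000L)
  )
}

toy_junctions <- function(rows) {
  tibble::tibble(
    chrom = rows$chrom %||% "chrT",
    intron_start = rows$intron_start,
    intron_end = rows$intron_end,
    strand = rows$strand,
    unique_reads = rows$unique_reads %||% rep(10L, length(rows$intron_start)),
    sample_id = rows$sample_id %||% rep("s1", length(rows$intron_start))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
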