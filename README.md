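# cryptsplice

Hotspot mutations in the splicing factor SF3B1 (most prominently K700E)
change how the U2 snRNP recognizes the branchpoint, activating normally
silent *cryptic 3' splice sites* — acceptors that sit a short distance
(typically 8–14 nt) inside the intron, carry a weaker polypyrimidine tract
(PPT) and an adenosine-enriched region upstream, and splice a short intronic
fragment into the mature mRNA. Because those fragments frequently shift the
reading frame, the misspliced transcripts are often degraded by
nonsense-mediated decay (NMD), silencing the affected gene (e.g. *MAP3K7*
in SF3B1-mutant pancreatic cancer).

`cryptsplice` is an R package for detecting and characterizing this
signature from splice-junction read counts in a two-genotype cohort
(wild-type vs SF3B1-mutant). It provides:

* **I/O** for STAR `SJ.out.tab` (and a simple TSV dialect), GTF annotation,
  FASTA references, sample sheets and PSI matrices;
* **event detection**: alternative 3'ss (A3SS), alternative 5'ss (A5SS) and
  exon-skipping calls from pooled junction evidence against the annotation;
* **PSI quantification**: for an event with alternative-junction reads *a*
  and canonical-junction reads *c* in one sample,
  `PSI = a / (a + c)`, missing when `a + c < 10`;
* **differential splicing**, the transform–test pipeline:
  `log(PSI + x)` (default `x = 0.01`) → removal of zero-variability events →
  event-wise mean imputation of missing values → per-event standardization →
  two-sided two-sample *t*-test (WT vs MUT), with significance gates
  `|ΔPSI| > 0.1` and `p < 0.01` (murine preset) or `|ΔPSI| > 0.05`,
  `p < 1e-10` (pan-cancer preset), plus optional Benjamini–Hochberg
  adjustment;
* **cryptic-site characterization**: distance to the canonical acceptor
  (log2-binned histogram), position frequency matrices with Shannon
  information content `IC = 2 − H` (bits), PPT pyrimidine and
  branchpoint-window adenosine fractions, and an NMD flag
  (frameshift / in-frame PTC / none);
* **cross-cohort overlap** of significant A3SS gene sets through an ortholog
  map;
* **amplicon isoform quantification**: predicted canonical/non-canonical
  RT-PCR product lengths and exact diagnostic-*k*-mer read classification,
  yielding the misspliced fraction;
* a **cohort simulator** (`sim_config()`, `simulate_cohort()`) that
  generates toy genomes, annotations and junction counts carrying a
  configurable cryptic-3'ss signature together with a machine-readable
  truth table — the basis for all calibration and power tests.

## Worked example

Simulate the default cohort (200 genes, 3 wild-type vs 4 mutant replicates)
and run the analysis:

```r
library(cryptsplice)

cfg <- sim_config(seed = 1L)
co  <- simulate_cohort(cfg)
ev  <- detect_events(co$junctions, co$models)
psi <- compute_psi(ev, co$junctions, samples = co$samples$sample_id)
fit <- differential_test(psi_matrix(psi), co$samples)
fit
#> <cryptsplice differential splicing result>
#>   200 events tested, 45 significant (|dPSI| > 0.1, p < 0.01, pooled t-test)

sig <- tidy(fit)$event_id[tidy(fit)$significant]
summarize_event_types(ev, sig)
#> # A tibble: 3 × 3
#>   event_type n_events n_significant
#>   <chr>         <int>         <int>
#> 1 A3SS            165            38
#> 2 A5SS             15             4
#> 3 exon_skip        20             3
```

A3SS events dominate the significant calls, as expected for an
SF3B1-mutant signature. Their cryptic acceptors cluster 8–16 nt upstream
of the canonical acceptor:

```r
a3 <- ev[ev$event_id %in% sig & ev$event_type == "A3SS", ]
distance_histogram(a3)
#>   bin     lower upper count is_mode
#> 1 [1,2)       1     2     0 FALSE
#> 2 [2,4)       2     4     0 FALSE
#> 3 [4,8)       4     8     5 FALSE
#> 4 [8,16)      8    16    16 TRUE
#> 5 [16,32)    16    32    16 FALSE
#> 6 [32,64)    32    64     1 FALSE

ch <- characterize_sites(a3, co$genome, co$models)
round(colMeans(ch[, c("ppt_canonical", "ppt_cryptic",
                      "bp_a_canonical", "bp_a_cryptic")]), 2)
#>  ppt_canonical    ppt_cryptic bp_a_canonical   bp_a_cryptic
#>           0.83           0.57           0.25           0.41
table(ch$nmd_flag)
#> frameshift       none
#>         28         10
```

The cryptic sites show the weaker PPT (0.57 vs 0.83 pyrimidine fraction)
and upstream adenosine enrichment (0.41 vs 0.25) typical of mutant-SF3B1
acceptor choice, and most inclusions frameshift the transcript. The
amplicon module reproduces a targeted assay over such a junction:

```r
predict_amplicons(amplicon_fixture("human"))
#>   isoform       length_bp
#> 1 canonical            94
#> 2 non_canonical       114

reads <- simulate_amplicon_reads(amplicon_fixture("human"), 3000, 1/3, seed = 1L)
classify_reads(reads, amplicon_fixture("human"))
#>   n_canonical n_non_canonical n_unassigned n_total misspliced_fraction
#> 1        1987            1013            0    3000               0.338
```

`run_pipeline()` chains all stages and writes a report bundle (TSV tables
plus a JSON run manifest with parameters and file hashes); `plot_*()`
functions and `autoplot()` render the event-type summary, distance
histogram, motif logos and a volcano plot.

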