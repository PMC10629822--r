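---
title: "Detecting cryptic 3' splice sites from junction counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic 3' splice sites from junction counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsplice)
```

# The analysis problem

Mutant SF3B1 perturbs branchpoint recognition by the U2 snRNP and thereby
activates cryptic 3' splice sites (3'ss): acceptors located a short
distance inside the intron, upstream of the canonical AG. Their use splices
a short intronic fragment into the mRNA; when the fragment length is not a
multiple of three the reading frame shifts and the transcript becomes a
nonsense-mediated decay (NMD) substrate. The observable footprint in
short-read RNA-seq is a set of unannotated splice junctions that share a
donor with an annotated junction but end at a nearby unannotated acceptor,
used substantially more in mutant than in wild-type samples.

`cryptsplice` works entirely from per-sample junction read counts plus a
GTF annotation and reference FASTA. It does not realign reads and does not
use exonic coverage, which bounds what it can call (see *Limitations*).

# Event detection and PSI

Junction evidence is pooled across samples; a junction participates in
detection if it has at least one uniquely mapping read in at least one
sample. Multi-mapping reads are never counted, and junctions with undefined
strand are dropped because acceptor/donor identity is strand-dependent.

For each gene, an **A3SS** event is called for every triple (shared donor,
annotated acceptor, unannotated acceptor) observed in the data; **A5SS** is
the mirror call on a shared acceptor; an **exon_skip** is called when a
junction exactly bridges the two annotated flanking introns of an annotated
internal exon. Each unannotated acceptor yields its own pairwise event
against the canonical acceptor because the PSI below is a two-way ratio.
If several annotated acceptors share a donor, the one used by the longest
annotated transcript is canonical, ties going to the most upstream site in
transcript sense; the annotation defines canonicality, since junction data
alone cannot.

Per event and sample, with `a` reads on the alternative junction and `c`
on the canonical one,

$$\mathrm{PSI} = \frac{a}{a + c},$$

reported missing when `a + c` is below `min_coverage` (default 10 reads; a
ratio of a handful of reads is noise, and 10 is the conventional floor for
junction-level PSI). The literal unbounded ratio `a / c` is exposed as
`alt_canonical_ratio` for users who want it, but all downstream statistics
use the bounded PSI. For exon skips the denominator junction is the
transcript-sense first flanking (inclusion) junction; using one inclusion
junction keeps every event a two-junction ratio.

# The differential-splicing statistic

The pipeline applies, in order:

1. `log(PSI + x)` with pseudocount `x > 0` (default 0.01). The transform
   spreads the mass near 0 where cryptic PSI values live; the pseudocount
   keeps `PSI = 0` finite. `x` is a real tuning knob: small `x` emphasizes
   differences among near-zero PSI values, large `x` makes the transform
   nearly affine (and the statistic then approaches a plain t-test on PSI).
   Because the transform is nonlinear, changing `x` can move borderline
   events across the significance threshold; what *is* exactly invariant is
   step 4 — standardization is affine and leaves every t statistic
   unchanged, which the test suite asserts.
2. Removal of events with no variability (all observed values equal) or no
   observations at all.
3. Event-wise mean imputation of the remaining missing values, using the
   mean over *all* samples, not per group. Group-wise imputation would
   build the tested contrast into the imputed values; all-sample imputation
   is conservative (it shrinks the group difference) and matches the
   stated order transform → filter → impute → standardize → test.
4. Per-event standardization to mean 0, *population* SD 1.
5. A two-sided two-sample t-test per event, pooled-variance by default
   (the plainest reading of "t-test" for a 3-vs-4 design); Welch is
   available via `diff_config(test = "welch")`.

The effect size `delta_psi` is deliberately computed on the raw PSI scale
from observed (non-imputed) values — it is the quantity with biological
units (ΔPSI = mean mutant PSI − mean wild-type PSI). Significance requires
both `|ΔPSI| > delta_psi_min` and `p < p_max`; the `mouse_kpc` preset uses
(0.1, 0.01) and the `pan_cancer` preset (0.05, 1e-10), the two published
threshold pairs. Raw p-values gate significance by default, replicating
the original analysis; BH-adjusted values are always reported and can gate
instead (`adjust = "BH"`). Events with fewer than two observed values in
either group get a missing p-value and are never called significant.

# Coordinate and window conventions

All intron coordinates are 1-based inclusive: `intron_start` is the first
intronic base, `intron_end` the last (the G of the acceptor AG on the plus
strand). This matches the STAR `SJ.out.tab` dialect, so junction tables can
be used without shifting; conversion happens only at sequence-extraction
time.

Sequence windows around a 3'ss use transcript-sense offsets with **0 at the
last intronic base** and +1 at the first exonic base, so the acceptor AG
sits at offsets −1, 0. Defaults:

| window | offsets | length | role |
|---|---|---|---|
| motif window | −30..+9 | 40 nt | position frequency matrix / logo |
| PPT window | −20..−5 | 16 nt | pyrimidine fraction |
| branchpoint window | −40..−10 | 31 nt | adenosine fraction |

The motif window length sits inside the conventional 30–40 nt range for
3'ss logos; the PPT and branchpoint windows follow standard splicing
literature. All are configurable. Minus-strand windows are
reverse-complemented so every extracted sequence reads in transcript sense.

Information content per motif position is Shannon `IC = 2 − H(p)` bits on
A/C/G/T frequencies, with N excluded position-wise. No small-sample
correction is applied by default because the published logos are built from
a handful of events and standard logo tools apply none; the correction
`3/(2 \ln(2) n)` is available as an option and only lowers IC.

The cryptic distance `d` is positive when the alternative acceptor lies
upstream (inside the intron) — then `d` equals the length of the included
intronic sequence — and negative for downstream shifts. The histogram uses
log2 bins `[1,2), [2,4), …` because the distance distribution is
heavy-tailed with a short-distance mode; ties between bins are broken
toward the smaller-distance bin when flagging the mode, and downstream
shifts are tabulated in their own bin rather than forced onto the log
scale.

The NMD flag is rule-based: `d %% 3 != 0` is a frameshift; otherwise the
included sequence is scanned for stop codons in the annotated reading
frame at the insertion point (phase derived from the CDS upstream of the
canonical acceptor). Codons spanning the insertion boundaries are not
scanned — with a phase-0 insertion there are none, and for other phases
the boundary codons depend on exonic context the flag deliberately ignores.
Genes without CDS annotation give `unknown_frame`.

# The cohort simulator

The simulator is the package's test bed: it emulates the statistical
structure of a sorted two-genotype tumor cohort (default 3 wild-type vs 4
mutant replicates, the sequenced replicate layout of the murine study) and
writes a truth table, so detection completeness, test calibration, power,
FDR and signature recovery can all be measured against known ground truth.

Each simulated gene has three exons and two introns on a random strand
(minus-strand gene blocks are stored reverse-complemented, so the whole
strand-handling path is exercised). Every intron starts GT and ends AG.
One splice event is planted per gene: 80% A3SS and 10% each A5SS /
exon-skip decoys by default. A fraction of events (default 0.25) is
*responsive*: its true PSI is `baseline_psi_wt` (default 0.05 — cryptic
acceptors are nearly silent without the mutation) in wild-type samples and
`baseline_psi_wt + delta_psi_effect` (default +0.3, consistent with about
a third of transcripts misspliced at a strongly affected locus) in mutant
samples. A `mut_penetrance` knob in [0, 1] can attenuate the effect to
mimic partial allelic expression of the mutation; it defaults to 1 (off)
because genotype is taken to act directly on the splicing ratio.

**Counts.** Per sample and event, total event coverage is negative
binomial (`mu = 50`, `size = 8` by default — overdispersed junction
coverage typical of replicate tumor RNA-seq); alternative-junction reads
are binomial with the sample's true PSI, the canonical junction gets the
remainder, and each gene's downstream constitutive junction receives an
independent NB count. No count model is implied by the original analysis;
NB-total with binomial allocation is the standard overdispersed junction
model and is sufficient for type-I/power evaluation. Zero-count junctions
are not written, and low totals fall under the PSI missingness floor, so
missing data arise naturally.

**Cryptic distances** are drawn from a log-normal parameterized by its
mode (default 11 nt, inside the mutant-typical 8–14 nt range; `sdlog`
0.45), rounded and truncated at 3 nt. If an intron cannot host a sampled
distance plus the sequence-signature windows, the distance is resampled a
bounded number of times before a sizing error is raised.

**Sequence signature.** Responsive-gene introns carry a cryptic AG at
distance `d`, an adenosine-enriched region (P(A) = 0.5 vs background 0.25)
upstream of the cryptic site, and polypyrimidine content written as
per-window quotas: the canonical PPT window receives a
`Binomial(16, 0.85)` pyrimidine quota and the cryptic window a
`Binomial(16, 0.55)` quota. The configured fractions are targets for the
*measured* content of the default scoring windows. This matters because
the two windows overlap geometrically whenever `d < 21` nt and the cryptic
AG itself sits inside the canonical window: with naive per-region i.i.d.
base drawing the overlap and the AG dilute the measured contrast to a
fraction of the configured difference. Writing canonical-first with the
cryptic quota discounted by the pyrimidines already contributed in the
overlap makes the windows read back close to their configured fractions,
so the canonical-vs-cryptic contrast in the output reflects the
configuration rather than window-geometry artifacts.

All simulator outputs are pure functions of `(config, seed)`; genome and
counts use distinct derived seeds so the same genome can carry independent
count replicates.

**What the simulator does not emulate**: expression-level differences
between genotypes, alignment and mapping artifacts, intron retention,
multi-isoform genes, GC or mappability bias, allele-specific coverage, and
real branchpoint motifs (the adenosine enrichment is compositional, not a
positioned heptamer). Tests passing on simulated cohorts therefore
validate the pipeline's arithmetic, calibration and recovery behavior
under its stated model — not performance on the full messiness of real
RNA-seq.

# Cohort overlap and amplicon quantification

Cross-cohort comparison is done at the gene level through a two-column
ortholog map, because event coordinates are not comparable across genomes.
The shared count is tallied as ortholog pairs, which keeps the Venn counts
symmetric under cohort swap even for one-to-many maps; genes absent from
the map count as cohort-private.

The amplicon module models a targeted RT-PCR over a misspliced junction.
Product lengths are measured 5'-primer-end to 5'-primer-end on each
template. Reads are classified by exact containment of a diagnostic 16-mer
centered on each isoform's junction (orientation-insensitive); reads
matching both or neither diagnostic are left unassigned, and the
misspliced fraction is non-canonical / (canonical + non-canonical).
Exact matching assumes error-free reads — adequate for desk-scale
validation and for simulated reads; a mismatch-tolerant mode is out of
scope. The bundled `amplicon_fixture()` templates are synthetic sequences
built from fixed internal seeds; only their geometries (94 bp canonical +
20 nt insertion; 114 bp canonical + 23 nt insertion) follow the published
assays. The two geometries are shipped side by side without adjudicating
which applies to which murine tissue, mirroring the two published gel
layouts.

# Problem sizes and determinism

The bundled analyses run at desk scale by choice: default cohorts use 200
genes and 7 samples; calibration and recovery checks use 1000 events
(3 vs 4 and 8 vs 8 samples at coverages 50 and 100). These sizes give
binomial standard errors small enough to resolve the tested tolerances
(e.g. ±0.003 on a 0.01 rejection rate at 1000 events) while keeping each
check in seconds. Every pipeline output is deterministic given the inputs
and seed; the run manifest records the package version, seed, effective
parameters and MD5 hashes of all written tables.

# Limitations

* Intron retention and mutually exclusive exons are not called: both need
  exonic read coverage, which junction tables do not contain.
* The t-test operates on 3–8 samples per group; calibration holds under
  the simulator's count model, but heavy-tailed real data may deviate.
* The NMD flag is sequence-rule-based (frame and PTC), not a full NMD
  model (no 50-nt rule, no last-exon logic).
* Gene assignment of junctions is by span containment and strand;
  overlapping genes on the same strand would both claim a junction.
* `classify_reads()` requires exact diagnostic matches; sequencing errors
  inside the 16-mer leave reads unassigned, which is unbiased for the
  fraction only when errors hit both isoforms equally.
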