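---
title: "circflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circflow)
```

# Scope

Circular RNAs (circRNAs) arise when a downstream 5' splice site is joined
back to an upstream 3' splice site, producing a covalently closed RNA whose
only direct sequencing evidence is the read that spans the back-splice
junction (BSJ). circflow implements the junction-level computational
pipeline used to characterise circRNA biogenesis and its dependence on an
intron-binding RNA-binding protein (the ELAV/Hu family case is the
motivating system): BSJ calling and quantification, a circRNA-centric
intron database, differential circRNA expression and classification,
exon–intron split analysis (EISA) of IP versus input libraries,
cotranscriptional splicing efficiency from nascent RNA-seq, reverse
complementary match (RCM) detection in flanking introns, cross-link
(iCLIP) enrichment statistics, positional motif enrichment at the BSJ, and
a repeat-overlap permutation test.

Everything operates on plain data frames with 0-based half-open
coordinates; conversion to GTF (1-based inclusive) and BED happens only in
the I/O functions. A seeded synthetic-data generator emulates all inputs
so the full pipeline is testable end to end without external data.

# The models and procedures

## BSJ calling and the junction ratio

A split read whose second segment maps genomically upstream of its first
defines a candidate back-splice: acceptor = second segment start, donor =
first segment end. Candidates must carry canonical splice signals, read on
the transcribed strand of the adjoining introns: intronic `GT` just
downstream of the donor and intronic `AG` just upstream of the acceptor
(their reverse complements `AC`/`CT` on the genomic forward strand of `-`
genes). Calling merges identical coordinates exactly — no tolerance — so
counts stay auditable; the 10-nt clustering used for intron assignment
happens later, in the annotation module.

Circular-to-linear expression is the junction ratio

$$\mathrm{JR} = \frac{2\,\mathrm{bsj}}{2\,\mathrm{bsj} + \mathrm{fsj}},$$

where `fsj` counts reads colinearly spanning either circle boundary,
deduplicated per read. The forward-junction definition is an explicit,
documented approximation: the published quantifiers do not print their
read-admission rules, so circflow counts any colinear read whose extent
crosses the acceptor or donor position.

A circRNA enters the reference set when it reaches five back-splice reads
in at least one cell population (replicates pooled per population); the
saturation analysis subsamples accepted BSJ reads without replacement at
fractions of the library and reports the recovered fraction of the full
detection set, averaged over replicates (3 by default).

## The intron database

Protein-coding genes are kept; a transcript's first/last exon is treated
as an alternative TSS/TES exon — and excluded — when its outer boundary
differs from the gene-level outermost boundary. This is the minimal
operational reading of "alternative"; the source procedure does not define
it further. Optionally, exons absent from a caller-supplied expressed-exon
whitelist are dropped (expression estimation itself is upstream tooling's
job). The union of retained exons is subtracted from the gene span and
gaps shorter than 10 nt are discarded.

CircRNAs are collapsed by single linkage when both their 5' and 3' ends
lie within 10 nt ("within" read inclusively, distance ≤ 10). An intron
whose end lies within 10 nt of a cluster's genomic start is the
transcription-upstream flanking intron on `+` genes; labels swap on `-`
genes. Single-intron circle geometry can make one intron flank both
boundaries; it is kept with class `flank_both` and flagged. Remaining
introns of circRNA-hosting genes are `nonflanking`; introns of other
genes are `other_gene`.

## Differential circRNA expression

The published pipelines delegate testing to a count-model GLM stack; as a
deliberately self-contained substitute, circflow tests each circRNA with a
conditional binomial exact test: given $n = c_A + c_B$, under the null
$c_A \sim \mathrm{Binomial}(n,\ \ell_A/(\ell_A+\ell_B))$ with library
sizes $\ell$, and the two-sided p-value sums outcome probabilities no
larger than the observed one. Fold changes use 0.5 prior counts;
$\log\mathrm{CPM} = \log_2((c+0.5)/(\ell+1)\times 10^6)$. Replicates are
summed within groups before testing, so biological dispersion is not
modelled — a stated limitation, adequate at BSJ-scale counts and exactly
oracle-verifiable. No multiple-testing correction is applied in
classification, mirroring the printed raw-P thresholds.

Classification presets: the population contrast labels a circRNA
`neuronal` when logCPM > −5, p < 0.1 and log2FC > 0 (`nonneuronal` for
the negative side); a stricter display preset (p < 0.05, logCPM > −5.4,
|log2FC| ≥ 1) is exposed separately since the two threshold sets coexist
in the source material and are best kept as named presets rather than
reconciled. Mutant contrasts label `elav_down`/`elav_up` at |log2FC| ≥
0.5 (single mutant) or ≥ 0.3 (double mutant) with logCPM > −5.4.

## EISA

Reads are classified as exon–exon junction (EEJ; gapped exactly across an
annotated intron — mature mRNA evidence) or exon–intron boundary (EIB;
CIGAR containing only M operations, overlapping exonic and intronic
sequence of one gene by at least 1 nt on each side — pre-mRNA evidence).
The two classes are mutually exclusive by construction. Genes with mean
EEJ below 10 are filtered. Per gene, enrichment of IP over input is the
library-normalised log2 ratio with 0.5 prior counts, computed separately
on EEJ (total transcript) and EIB (pre-mRNA) counts; a gene is called
pre-mRNA-enriched when its boundary enrichment exceeds 1 and a one-sided
conditional binomial test is significant at 0.05. Both thresholds are
arguments: the original call threshold behind the published
pre-mRNA-enriched gene fraction is not printed, so the substitute's knobs
are explicit configuration, not a reconstruction.

## Splicing efficiency

For each intron, quantification windows are the transcribed-strand last
30% of the intron and the first 30% of the downstream exon (genomically
mirrored on `-` genes). Window lengths use round-half-up and must be at
least 1 nt. Efficiency is one minus the intron-to-exon per-nt read
density ratio, clamped to [0, 1] because sampling noise can push the raw
ratio outside; values near 1 mean fast cotranscriptional splicing. The
density ratio cancels library normalisation, so the elaborate
exon-usage normalisation of the original quantification is replaced by
per-window per-nt densities with optional library scaling. Group
comparisons bin introns by length (five log-spaced bins by default; a cap
at 10 kb can be imposed through the bin edges) and use a one-tailed
Welch t-test per bin, matching the direction the analysis asks about
(bound introns splicing more slowly).

## RCM detection

The default, exact mode reports all maximal spans where the upstream
intron sequence equals the reverse complement of a downstream span,
found by 7-mer seeding against the reverse-complemented downstream
sequence and bidirectional extension, deduplicated so a match contained
(in both spans) within a longer one is suppressed while staggered
overlaps are kept, and filtered to > 20 nt (`min_len = 21`). Exact mode
is a deliberate replacement of the minus-strand BLAST alignment of the
original procedure: it is fully oracle-verifiable against an $O(n^2)$
enumeration, and it sidesteps the question of whether alignment length
counts gaps. A greedy mode approximates BLAST's tolerance of mismatches
with X-drop extension (match +1, mismatch −2, drop 6) and reports aligned
columns and mismatch counts. `N` never matches. Downstream-span
coordinates are reported on the genomic forward strand for BED
compatibility. Per-circRNA RCM density groups all pairs of one circRNA
as a single unit per length bin and normalises per kb of flanking
intron; conservation scoring is accepted as an optional per-base score
input rather than computed (it requires external score tracks).

## Cross-link enrichment and metaprofiles

Enrichment across intron classes compares observed cross-link counts per
group against a length-proportional expectation with a chi-squared
goodness-of-fit test (k − 1 df). The published description — a
contingency table of length-normalised counts — is implemented on the
expectation side: scaling the observed counts would make the chi-squared
statistic ill-defined on non-integers, while testing raw counts against
length-share expectations preserves exactly the same null. The
construction is config-switchable via the `groups` argument.
Metaprofiles map intron positions to 100 transcribed-strand bins
(`floor`-based integer binning, so short introns share bins
deterministically), and RCM profiles accumulate signal in nt-resolution
flanks (±1 kb) around length-normalised RCM interiors, separately for
the upstream- and downstream-intron sides.

## BSJ motif statistics

Junction windows take ±25 nt across the BSJ on the spliced circle
sequence — the RNA that physically spans the junction is exonic — with
circular wrap for circles shorter than 50 nt; a genomic-window fallback
can be emulated by passing genomic sequence. PWM scanning is explicit
log2-odds scoring at every offset with a configurable threshold
(default 0); MEME-format motif files are parsed by a small built-in
reader with a pseudocount so zero probabilities stay finite. Enrichment
against control windows (circRNAs neither enriched nor depleted are the
natural control set) is a Fisher exact test on the per-sequence
hit/no-hit table with a Haldane-corrected odds ratio. Positional
enrichment classifies each hit's centre (motif midpoint, rounded down)
as central within a 20-nt band around the window midpoint and tests the
central count with an upper-tail binomial against the fraction of
available centre positions that are central.

## Repeat-overlap permutation test

The observed number of query regions (RCMs) overlapping at least one
repeat is compared to a null built by uniformly re-placing
length-preserved query regions within a placement space 500 times
(lengths preserved, no overlap constraints — the default behaviour of the
standard genomic randomisation tools). The empirical p-value is
$(1 + \#\{null \ge obs\})/(ntimes + 1)$ and a z-score standardises the
observation. Region count (not base pairs) is the overlap unit.

# The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are the
conditions exercised by the test suite and the acceptance script:

* 20 protein-coding genes with 4–6 exons (120–250 nt) and introns of
  80–400 nt on a single chromosome, strands random, `GT..AG` written at
  every intron boundary on the transcribed strand. These sizes are
  Drosophila-like at toy scale: most fly introns are well under 400 nt.
* 10 genes host one circRNA each over 1–3 consecutive internal exons, so
  every planted circle has canonical splice signals by construction.
* Each circRNA's transcription-upstream flanking intron receives a
  random 30–60 nt span whose exact reverse complement is written into
  the downstream flanking intron; a U-rich consensus (`TTTTTTT` on DNA),
  the ELAV-family binding preference, is embedded in each planted RCM.
* BSJ reads average 50 per circRNA per sample (Poisson), emitted as two
  30 nt segments in reversed genomic order; forward-junction reads are
  colinear spliced records whose expected depth follows the circular
  fraction (0.5 by default, giving a junction ratio near 2/3). Two
  non-canonical decoy junctions are planted to exercise caller
  specificity. Reads are idealised: no mismatches, fixed `30M,30M`
  CIGARs, so the all-M EIB rule is exercisable — the statistics, not
  aligner behaviour, are the target.
* Cross-link sites are placed uniformly at 0.05 sites/nt in introns,
  multiplied by 3 in flanking introns; nascent reads fill the
  splicing-efficiency windows so the per-nt density ratio estimates
  1 − spliced fraction (0.8 by default).

One master seed drives everything; each generator derives its own stream
by a fixed offset, so stages are independently reproducible and
identical configs give byte-identical FASTA/GTF/TSV outputs.

What the generator does *not* emulate — sequencing errors, fragment-length
distributions, paired-end inserts, isoform diversity beyond an optional
alternative-TSS/TES transcript, multi-mapping — bounds what green tests
show about real data: they demonstrate that the statistics and the
bookkeeping are correct under the stated read model, not that the caller
is robust to alignment artefacts.

# Numerical choices

* Window rounding is round-half-up with a hard error when a window rounds
  to zero nt.
* Metaprofile binning uses integer arithmetic (`(rel * n_bins) %/% len`)
  to avoid floating-point drift at bin boundaries.
* The junction ratio and splicing efficiency return `NA` on empty
  denominators rather than erroring.
* Efficiency clamping to [0, 1] is applied after the ratio, matching the
  "closer to 1 / closer to 0" semantics of the readout.
* `find_rcms` treats `N` as never matching; ties in containment dedup
  resolve longest-first, then leftmost.
* The exact test's two-sided p sums outcome probabilities ≤ observed
  with the conventional `1 + 1e-7` relative tolerance.

# Problem sizes

The test suite and the acceptance script run the study conditions above:
20 genes / 10 circRNAs at depth 50, a 500-circRNA null and a 100-circRNA
4-fold panel for calibration and power, 5000 nascent reads per intron for
efficiency recovery, 1000 null and 100 planted simulations for the
chi-squared checks, 200 random intron pairs (≤ 400 nt) for the RCM
oracle, and 200 seeded permutation runs at 100 randomisations for
p-value uniformity. These sizes give tight Monte-Carlo tolerances while
keeping the whole suite interactive.

# A worked run

```{r worked}
cfg <- sim_config(seed = 1)
truth <- plant_circrnas(sim_genome(cfg))
reads <- simulate_reads(truth, rep = 1)
circs <- count_fsj(reads, call_bsj(reads, truth$genome))
head(circs[, c("circ_id", "bsj", "fsj", "junction_ratio")])

introns <- build_intron_db(truth$exons, truth$genes)
introns <- assign_flanking_introns(introns, collapse_circrnas(truth$circrnas))
table(introns$class)

track <- simulate_crosslinks(truth, cfg, introns = introns)
group_enrichment(track, introns)

rcms <- flanking_rcms(truth$circrnas, truth$genome)
summary(rcms$length)
```

# Known limitations

* The DE substitute has no dispersion model: with many biological
  replicates it will be anticonservative relative to a GLM with
  empirical-Bayes dispersion.
* FSJ counting is an approximation of the unpublished read-admission
  rules of the reference quantifiers.
* Exact-mode RCMs underestimate BLAST alignments that tolerate
  mismatches/gaps; greedy mode approximates but does not reproduce BLAST
  scoring.
* The permutation test's empirical p is discrete; at small query sets it
  is conservative.
* Single-chromosome, single-isoform synthetic data cannot probe
  multi-locus ambiguity or isoform-specific exon signal removal.
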