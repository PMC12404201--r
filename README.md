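# circflow

Junction-level analysis of circular RNA (circRNA) biogenesis in R.

Circular RNAs form when a downstream 5' splice site is ligated back to an
upstream 3' splice site; the only direct sequencing evidence is a read
spanning the back-splice junction (BSJ). circflow implements the
computational pipeline by which circRNA biogenesis and its dependence on
an intron-binding RNA-binding protein (the neuronal ELAV/Hu family being
the motivating case) is characterised from junction-level evidence:

* **BSJ calling & quantification** — split-read geometry with a canonical
  GT/AG splice-signal filter, the circular-to-linear junction ratio
  `2·bsj/(2·bsj+fsj)`, a ≥5-BSJ-per-population reference filter, and a
  read-subsampling saturation analysis.
* **Intron database** — protein-coding introns after alternative-TSS/TES
  exon exclusion and exon subtraction (<10 nt gaps dropped), circRNA
  collapsing at 10 nt tolerance, and flanking / nonflanking / other-gene
  intron classes.
* **Differential circRNA expression** — a conditional binomial exact test
  on pooled group counts with logCPM and prior-count fold changes, plus
  the threshold presets that define neuronal / nonneuronal and
  mutant-affected (ELAV-dependent) circRNA classes.
* **Exon–intron split analysis (EISA)** — exon–exon-junction vs
  exon–intron-boundary read classification (all-M CIGAR rule) and
  per-gene pre-mRNA enrichment of IP over input libraries.
* **Splicing efficiency** — nascent-read densities in the intron 3' 30%
  window vs the downstream-exon 5' 30% window, `1 − ratio` clamped to
  [0,1], with length-binned group comparisons.
* **RCM detection** — exact maximal reverse-complementary matches (>20 nt)
  between flanking introns by 7-mer seed-and-extend, a mismatch-tolerant
  greedy mode, per-circRNA densities, GC content, and a repeat-overlap
  permutation test (length-preserving randomisation, empirical p).
* **Cross-link enrichment** — chi-squared test of iCLIP site counts
  against length-proportional expectations across intron classes, plus
  normalised-intron and RCM-centred metaprofiles.
* **BSJ motif statistics** — ±25 nt junction windows on the spliced
  circle (with circular wrap), PWM log-odds scanning (MEME-format reader
  included), Fisher enrichment vs control windows and central positional
  enrichment.

A seeded synthetic-data generator plants circRNAs, RCM pairs, motif sites,
cross-link enrichment and nascent-read fractions so every stage is
testable end to end without external data.

## Worked example

```r
library(circflow)

cfg   <- sim_config(seed = 1)                 # 20 genes, 10 circRNAs
truth <- plant_circrnas(sim_genome(cfg))
reads <- simulate_reads(truth, rep = 1)

circs <- count_fsj(reads, call_bsj(reads, truth$genome))
head(circs[, c("circ_id", "bsj", "fsj", "junction_ratio")], 3)
#>            circ_id bsj fsj junction_ratio
#> 1 chrS:-:7036:7627  45  48      0.6521739
#> 2 chrS:-:9149:9873  64  68      0.6530612
#> 3 chrS:+:14138:14847 59  48     0.7108434
```

All 10 planted circRNAs are recovered at their exact coordinates; with a
circular fraction of 0.5 the junction ratio sits near 2/3, as the formula
predicts when BSJ and FSJ depths are equal. Building the intron database
and testing cross-link enrichment:

```r
introns <- build_intron_db(truth$exons, truth$genes)
introns <- assign_flanking_introns(introns, collapse_circrnas(truth$circrnas))
track   <- simulate_crosslinks(truth, cfg, introns = introns)
group_enrichment(track, introns)
#> Cross-link enrichment across intron groups
#>   flank         1921 sites /    12395 nt  (154.98 per kb)
#>   nonflanking    442 sites /     8995 nt  (49.14 per kb)
#>   chi-squared = 275.734 (df 1), p = 5.9e-62
```

The planted 3× flanking enrichment is recovered (155 vs 49 sites per kb).
RCM detection on the flanking introns returns one exact
reverse-complementary match per circRNA covering each planted span:

```r
rcms <- flanking_rcms(truth$circrnas, truth$genome)
nrow(rcms)        # 10
range(rcms$length)  # 35 56 — planted lengths, possibly chance-extended
```

A command-line front end over the same functions is installed at
`inst/scripts/circflow.R` (`simulate`, `quantify`, `build-introns`,
`rcm`).

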