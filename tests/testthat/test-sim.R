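# Synthetic-data generator: construction audits, determinism, planted truth.

test_that("genome construction places GT/AG at every intron boundary and is deterministic", {
  cfg <- sim_config(seed = 7, n_genes = 20)
  tr1 <- sim_genome(cfg)
  tr2 <- sim_genome(cfg)
  expect_identical(tr1$genome, tr2$genome)
  expect_identical(tr1$exons, tr2$exons)
  # byte-identical FASTA + GTF
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_genome_fasta(tr1$genome, f1); write_genome_fasta(tr2$genome, f2)
  write_gtf(tr1$genes, tr1$exons, g1); write_gtf(tr2$genes, tr2$exons, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))

  expect_equal(nrow(tr1$genes), 20L)
  # intron count by construction audit: sum(exons - 1) per transcript
  n_introns <- sum(tr1$genes$n_exons - 1L)
  found <- 0L
  for (gid in tr1$genes$gene_id) {
    ex <- tr1$exons[tr1$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    st <- ex$strand[1]
    for (k in seq_len(nrow(ex) - 1L)) {
      is <- ex$end[k]; ie <- ex$start[k + 1L]
      donor <- substr(tr1$genome[["chrS"]], is + 1L, is + 2L)
      accept <- substr(tr1$genome[["chrS"]], ie - 1L, ie)
      if (st == "+") {
        expect_identical(donor, "GT"); expect_identical(accept, "AG")
      } else {
        expect_identical(donor, "CT"); expect_identical(accept, "AC")
      }
      found <- found + 1L
    }
  }
  expect_equal(found, n_introns)
})

test_that("a 3-exon single-gene config yields 2 canonical introns", {
  cfg <- sim_config(seed = 2, n_genes = 1, exons_per_gene = c(3, 3),
                    n_circ_genes = 1)
  tr <- sim_genome(cfg)
  expect_equal(tr$genes$n_exons, 3L)
  introns <- build_intron_db(tr$exons, tr$genes)
  expect_equal(nrow(introns), 2L)
})

test_that("planted circRNAs are canonical and RCM pairs are exact reverse complements", {
  tr <- default_truth()
  cfg <- tr$config
  expect_equal(nrow(tr$circrnas), cfg$n_circ_genes)
  for (i in seq_len(nrow(tr$circrnas))) {
    ci <- tr$circrnas[i, ]
    expect_true(circflow:::is_canonical_bsj(tr$genome, ci$chrom, ci$start,
                                            ci$end, ci$strand))
  }
  for (i in seq_len(nrow(tr$rcm_pairs))) {
    r <- tr$rcm_pairs[i, ]
    up <- substr(tr$genome[[r$chrom]], r$up_start + 1L, r$up_end)
    down <- substr(tr$genome[[r$chrom]], r$down_start + 1L, r$down_end)
    expect_identical(up, revcomp(down))
    expect_gte(r$length, cfg$rcm_len[1])
    expect_lte(r$length, cfg$rcm_len[2])
    expect_true(grepl(cfg$motif, up, fixed = TRUE))
  }
  # decoys planted and non-canonical
  for (i in seq_len(nrow(tr$decoys))) {
    d <- tr$decoys[i, ]
    expect_false(circflow:::is_canonical_bsj(tr$genome, d$chrom, d$start,
                                             d$end, d$strand))
  }
})

test_that("circRNA placement in 2-exon genes is rejected", {
  cfg <- sim_config(seed = 3, n_genes = 2, exons_per_gene = c(2, 2),
                    n_circ_genes = 1)
  tr <- sim_genome(cfg)
  expect_error(plant_circrnas(tr), "placement")
})

test_that("read simulation honours the circular fraction at its limits", {
  cfg1 <- sim_config(seed = 4, circular_fraction = 1)
  tr1 <- plant_circrnas(sim_genome(cfg1))
  r1 <- simulate_reads(tr1)
  expect_equal(sum(r1$junction_type == "FSJ"), 0L)

  cfg0 <- sim_config(seed = 4, circular_fraction = 0)
  tr0 <- plant_circrnas(sim_genome(cfg0))
  r0 <- simulate_reads(tr0)
  expect_equal(sum(r0$junction_type == "BSJ"), 0L)
  expect_gt(sum(r0$junction_type == "FSJ"), 0L)
  # downstream junction ratio is 0 at every planted circle
  called <- call_bsj(r0, tr0$genome)
  expect_equal(nrow(called), 0L)
})

test_that("total BSJ reads are Poisson around depth x circRNAs", {
  tr <- default_truth()  # bsj_depth 50, 10 circRNAs
  reads <- simulate_reads(tr, rep = 1)
  nb <- sum(reads$junction_type == "BSJ")
  expect_lt(abs(nb - 500), 3 * sqrt(500))
})

test_that("read simulation is deterministic per group/replicate and warns on zero depth", {
  tr <- default_truth()
  expect_identical(simulate_reads(tr, rep = 2), simulate_reads(tr, rep = 2))
  cfg0 <- sim_config(seed = 5, bsj_depth = 0)
  tr0 <- plant_circrnas(sim_genome(cfg0))
  expect_warning(simulate_reads(tr0), "zero depth")
})

test_that("cross-link simulation respects the enrichment multiplier", {
  cfg <- sim_config(seed = 6, clip_density = 1, clip_enrichment = 3)
  tr <- plant_circrnas(sim_genome(cfg))
  introns <- build_intron_db(tr$exons, tr$genes)
  introns <- assign_flanking_introns(introns, collapse_circrnas(tr$circrnas))
  track <- simulate_crosslinks(tr, cfg, introns = introns)
  dens <- function(classes) {
    sel <- introns[introns$class %in% classes, ]
    tot <- sum(vapply(seq_len(nrow(sel)), function(i) {
      sum(track$count[track$chrom == sel$chrom[i] &
                        track$strand == sel$strand[i] &
                        track$pos >= sel$start[i] & track$pos < sel$end[i]])
    }, numeric(1)))
    tot / sum(sel$end - sel$start)
  }
  ratio <- dens(c("flank_up", "flank_down", "flank_both")) / dens("nonflanking")
  expect_lt(abs(ratio - 3), 0.5)

  # null construction: equal densities across classes in expectation
  cfg1 <- sim_config(seed = 6, clip_density = 1, clip_enrichment = 1)
  tr1 <- plant_circrnas(sim_genome(cfg1))
  introns1 <- build_intron_db(tr1$exons, tr1$genes)
  introns1 <- assign_flanking_introns(introns1, collapse_circrnas(tr1$circrnas))
  track1 <- simulate_crosslinks(tr1, cfg1, introns = introns1)
  track <- track1; introns <- introns1
  ratio1 <- dens(c("flank_up", "flank_down", "flank_both")) / dens("nonflanking")
  expect_lt(abs(ratio1 - 1), 0.2)

  # empty intron set gives an empty track
  empty <- simulate_crosslinks(tr, cfg, introns = introns[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("nascent simulation hits its spliced-fraction limits", {
  cfg1 <- sim_config(seed = 8, spliced_fraction = 1)
  tr <- plant_circrnas(sim_genome(cfg1))
  w1 <- simulate_nascent(tr, cfg1)
  expect_true(all(w1$intron_count == 0L))
  eff1 <- splice_efficiency_table(w1)
  expect_true(all(eff1$efficiency == 1))

  cfg0 <- sim_config(seed = 8, spliced_fraction = 0, nascent_depth = 5000)
  w0 <- simulate_nascent(tr, cfg0)
  eff0 <- splice_efficiency_table(w0)
  expect_lt(max(eff0$efficiency), 0.06)
})
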