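# RCM detection (exact + greedy), density/GC summaries, permutation test.

test_that("a planted 30-nt RCM is recovered at its coordinates", {
  set.seed(41)
  up <- rand_dna(300)
  down <- rand_dna(300)
  s <- rand_dna(30)
  substr(up, 101, 130) <- s
  substr(down, 201, 230) <- revcomp(s)
  out <- find_rcms(up, down)
  expect_equal(nrow(out), 1L)
  expect_lte(out$up_start, 100)
  expect_gte(out$up_end, 130)
  expect_lte(out$down_start, 200)
  expect_gte(out$down_end, 230)
  expect_gte(out$length, 30)
  expect_equal(out$n_mismatches, 0L)
})

test_that("A/C-only sequence pairs cannot carry an RCM", {
  up <- paste(rep(c("A", "C"), 200), collapse = "")
  down <- paste(rep(c("C", "A"), 200), collapse = "")
  expect_equal(nrow(find_rcms(up, down)), 0L)
})

test_that("every reported RCM satisfies its own invariants", {
  tr <- default_truth()
  rcms <- flanking_rcms(tr$circrnas, tr$genome)
  expect_gt(nrow(rcms), 0L)
  for (i in seq_len(nrow(rcms))) {
    r <- rcms[i, ]
    up <- substr(tr$genome[[r$chrom]], r$up_start + 1L, r$up_end)
    down <- substr(tr$genome[[r$chrom]], r$down_start + 1L, r$down_end)
    expect_identical(up, revcomp(down))
    expect_gt(r$length, 20)
  }
  # planted-RCM recall: each planted span is covered by a reported match
  for (i in seq_len(nrow(tr$rcm_pairs))) {
    p <- tr$rcm_pairs[i, ]
    hit <- rcms$circ_id == p$circ_id &
      rcms$up_start <= p$up_start & rcms$up_end >= p$up_end &
      rcms$down_start <= p$down_start & rcms$down_end >= p$down_end
    expect_true(any(hit))
  }
})

test_that("exact mode equals the brute-force enumeration on random pairs", {
  set.seed(43)
  for (rep in 1:30) {
    n1 <- sample(80:400, 1); n2 <- sample(80:400, 1)
    up <- rand_dna(n1); down <- rand_dna(n2)
    if (rep %% 3 == 0) {  # plant a match in a third of the cases
      L <- sample(21:40, 1)
      s <- rand_dna(L)
      o1 <- sample(0:(n1 - L), 1); o2 <- sample(0:(n2 - L), 1)
      substr(up, o1 + 1, o1 + L) <- s
      substr(down, o2 + 1, o2 + L) <- revcomp(s)
    }
    got <- find_rcms(up, down)[, c("up_start", "up_end", "down_start",
                                   "down_end", "length")]
    want <- brute_force_rcms(up, down)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("N is tolerated but never matches", {
  up <- paste0(rand_dna(50), strrep("N", 30), rand_dna(50))
  down <- paste0(rand_dna(50), strrep("N", 30), rand_dna(50))
  expect_equal(nrow(find_rcms(up, down)), 0L)
  expect_error(find_rcms("ACGTX", "ACGT"), "alphabet")
})

test_that("find_rcms is symmetric under swapping the intron pair", {
  set.seed(44)
  up <- rand_dna(300); down <- rand_dna(300)
  s <- rand_dna(25)
  substr(up, 51, 75) <- s
  substr(down, 101, 125) <- revcomp(s)
  a <- find_rcms(up, down)
  b <- find_rcms(down, up)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(paste(a$up_start, a$up_end), paste(b$down_start, b$down_end))
  expect_setequal(paste(a$down_start, a$down_end), paste(b$up_start, b$up_end))
})

test_that("greedy mode bridges a single mismatch that exact mode splits", {
  set.seed(45)
  up <- rand_dna(200)
  down <- rand_dna(200)
  s <- rand_dna(41)
  rc <- revcomp(s)
  substr(rc, 21, 21) <- if (substr(rc, 21, 21) == "A") "C" else "A"
  substr(up, 51, 91) <- s
  substr(down, 101, 141) <- rc
  exact <- find_rcms(up, down, min_len = 15)
  greedy <- find_rcms(up, down, min_len = 21, mode = "greedy")
  expect_true(all(exact$length < 41))
  expect_gte(max(greedy$length), 41)
  expect_gte(max(greedy$n_mismatches), 1L)
})

test_that("RCM density groups pairs per circRNA and normalises per kb", {
  rcms <- data.frame(circ_id = c("c1", "c1", "c1"),
                     length = c(25, 27, 29), stringsAsFactors = FALSE)
  flank <- data.frame(circ_id = "c1", total_flank_nt = 2000)
  d <- rcm_density(rcms, flank, bins = c(20, 30, 50))
  expect_equal(d$n_circ, c(1L, 0L))
  expect_equal(d$density[1], 1 / 2)
  # doubling intron length halves per-kb density
  flank2 <- data.frame(circ_id = "c1", total_flank_nt = 4000)
  d2 <- rcm_density(rcms, flank2, bins = c(20, 30, 50))
  expect_equal(d2$density[1], d$density[1] / 2)
  # no RCMs: all densities zero
  d0 <- rcm_density(rcms[0, ], flank, bins = c(20, 30, 50))
  expect_true(all(d0$density == 0))
})

test_that("GC content excludes N from both numerator and denominator", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GCGCN"), 1)
  expect_true(is.na(gc_content("NNN")))
  expect_error(gc_content(""), "empty")
})

test_that("permutation overlap handles the degenerate cases", {
  regions <- data.frame(chrom = "chr1",
                        start = seq(0, 19000, by = 1000),
                        end = seq(0, 19000, by = 1000) + 50)
  space <- data.frame(chrom = "chr1", start = 0, end = 100000)
  # identical query and repeat sets: maximal observed overlap, minimal p
  pt <- permutation_overlap(regions, regions, space, ntimes = 100, seed = 2)
  expect_equal(pt$observed, nrow(regions))
  expect_lte(pt$p_empirical, 2 / 101)
  # empty repeats: observed 0, all null 0, p = 1
  pt0 <- permutation_overlap(regions, regions[0, ], space, ntimes = 50,
                             seed = 2)
  expect_equal(pt0$observed, 0L)
  expect_true(all(pt0$null_overlaps == 0L))
  expect_equal(pt0$p_empirical, 1)
  # region longer than every placement interval
  long <- data.frame(chrom = "chr1", start = 0, end = 200000)
  expect_error(permutation_overlap(long, regions, space), "placement")
})

test_that("planted repeat enrichment is detected by the permutation test", {
  set.seed(46)
  repeats <- data.frame(chrom = "chr1",
                        start = seq(0, 99000, by = 2000),
                        end = seq(0, 99000, by = 2000) + 100)
  # queries placed inside repeats
  query <- repeats[1:25, ]
  query$start <- query$start + 20; query$end <- query$start + 40
  space <- data.frame(chrom = "chr1", start = 0, end = 100000)
  pt <- permutation_overlap(query, repeats, space, ntimes = 200, seed = 3)
  expect_equal(pt$observed, 25L)
  expect_lt(pt$p_empirical, 0.01)
  expect_gt(pt$z_score, 3)
})
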