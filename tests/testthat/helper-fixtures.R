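# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# default study-condition truth set (20 genes, 10 planted circRNAs)
default_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    cfg <- sim_config(seed = 1)
    tr <- sim_genome(cfg)
    .fixture_env$truth <- plant_circrnas(tr)
  }
  .fixture_env$truth
}

default_introns <- function() {
  if (is.null(.fixture_env$introns)) {
    tr <- default_truth()
    introns <- build_intron_db(tr$exons, tr$genes)
    clusters <- collapse_circrnas(tr$circrnas)
    .fixture_env$introns <- assign_flanking_introns(introns, clusters)
  }
  .fixture_env$introns
}

# a tiny single-gene annotation used by hand-audited tests:
# + strand, exons [0,100) [200,300) [400,500)
toy_exons <- function(strand = "+", gene_id = "gA") {
  data.frame(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
    chrom = "chr1", strand = strand,
    start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
    exon_rank = 1:3, stringsAsFactors = FALSE
  )
}

toy_genes <- function(strand = "+", gene_id = "gA") {
  data.frame(gene_id = gene_id, chrom = "chr1", strand = strand,
             start = 0L, end = 500L, biotype = "protein_coding",
             n_exons = 3L, stringsAsFactors = FALSE)
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# genome with a single canonical BSJ planted at (start, end) on `strand`
planted_bsj_genome <- function(n = 700L, start = 100L, end = 560L,
                               strand = "+", chrom = "chr1") {
  g <- setNames(rand_dna(n), chrom)
  if (strand == "+") {
    substr(g[[chrom]], start - 1L, start) <- "AG"
    substr(g[[chrom]], end + 1L, end + 2L) <- "GT"
  } else {
    substr(g[[chrom]], start - 1L, start) <- "AC"
    substr(g[[chrom]], end + 1L, end + 2L) <- "CT"
  }
  g
}

# split-read row constructor
read_row <- function(id, chrom, strand, s1, e1, s2 = NA, e2 = NA,
                     cigar = "30M,30M", type = "BSJ") {
  data.frame(read_id = id, chrom = chrom, strand = strand,
             seg1_start = s1, seg1_end = e1, seg2_start = s2, seg2_end = e2,
             cigar = cigar, junction_type = type, stringsAsFactors = FALSE)
}

# independent O(n^2) enumeration of maximal exact reverse-complement
# matches >= min_len between two sequences, via the full comparison matrix
# and per-diagonal run-length encoding (used as the find_rcms oracle)
brute_force_rcms <- function(up, down, min_len = 21L) {
  u <- strsplit(up, "")[[1]]
  d <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(down))), "")[[1]]
  d[d == "N"] <- "#"
  n_u <- length(u); n_d <- length(d)
  eq <- outer(u, d, "==")
  rows <- list(); k <- 0L
  for (diag in (1L - n_d):(n_u - 1L)) {
    i0 <- max(1L, diag + 1L)
    i1 <- min(n_u, diag + n_d)
    if (i1 < i0) next
    v <- eq[cbind(i0:i1, (i0:i1) - diag)]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (m in which(r$values & r$lengths >= min_len)) {
      i_s <- i0 + starts[m] - 1L
      i_e <- i0 + ends[m] - 1L
      k_s <- i_s - diag; k_e <- i_e - diag
      k <- k + 1L
      rows[[k]] <- data.frame(
        up_start = i_s - 1L, up_end = i_e,
        down_start = n_d - k_e, down_end = n_d - k_s + 1L,
        length = i_e - i_s + 1L, stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    return(data.frame(up_start = integer(), up_end = integer(),
                      down_start = integer(), down_end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # same containment rule as the implementation, coded independently
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[i]) next
      if (out$length[j] > out$length[i] &&
          out$up_start[j] <= out$up_start[i] &&
          out$up_end[i] <= out$up_end[j] &&
          out$down_start[j] <= out$down_start[i] &&
          out$down_end[i] <= out$down_end[j]) {
        keep[i] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$up_start, out$down_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
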