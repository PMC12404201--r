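# Synthetic-data generator: toy genome + annotation, planted circRNAs with
# RCM pairs and motif sites, split-read samples, cross-link tracks and
# nascent-read window counts. One top-level seed; each generator derives its
# own stream by a fixed offset so stages are independently reproducible.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions exercised throughout the test
#' suite: 20 multi-exon protein-coding genes on both strands, 10 of which
#' host a circRNA whose flanking introns carry an exact reverse-complementary
#' match (RCM) with a U-rich motif (written as T on DNA) embedded in it.
#'
#' @param seed integer; master seed. Child streams are derived by fixed
#'   offsets per generator.
#' @param n_genes number of genes.
#' @param exons_per_gene inclusive range (length-2) of exons per gene.
#' @param exon_len,intron_len inclusive ranges of exon and intron lengths (nt).
#' @param n_circ_genes number of genes hosting one planted circRNA each.
#' @param circ_exon_span inclusive range of internal exons per circle.
#' @param bsj_depth mean back-splice-junction reads per circRNA per sample.
#' @param circular_fraction fraction of junction-spanning reads at a circle
#'   boundary that are back-spliced; expected FSJ depth is
#'   `bsj_depth * (1 - cf) / cf` (with the `cf = 0` limit giving zero BSJ
#'   reads and `bsj_depth` FSJ reads).
#' @param fold_change group-B over group-A abundance multiplier applied to
#'   every planted circRNA.
#' @param rcm_len inclusive range of planted RCM lengths (nt); must be able
#'   to contain `motif`.
#' @param motif consensus string (over ACGT) embedded in each planted RCM.
#' @param clip_enrichment cross-link density multiplier in flanking introns.
#' @param clip_density baseline cross-link sites per nt in introns.
#' @param spliced_fraction per-intron probability that a nascent read is
#'   spliced (so intron-window reads appear with probability `1 - sf`).
#' @param nascent_depth nascent reads per intron's downstream-exon window.
#' @param intergenic intergenic spacer length (nt).
#' @param read_seg_len length of each read segment (nt); reads are two
#'   segments with CIGAR `"30M,30M"` by default.
#' @param n_decoys number of planted non-canonical back-splice decoy
#'   junctions (their reads must be rejected by the caller).
#' @param decoy_depth mean reads per decoy junction per sample.
#' @param alt_tss if `TRUE`, a second transcript with an alternative first
#'   and last exon is added to each gene, exercising the TSS/TES exclusion
#'   rule of [build_intron_db()].
#' @param max_chrom_len chromosome budget (nt); exceeding it is a sizing
#'   error.
#' @return a validated list of class `circflow_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(4L, 6L),
                       exon_len = c(120L, 250L),
                       intron_len = c(80L, 400L),
                       n_circ_genes = 10L,
                       circ_exon_span = c(1L, 3L),
                       bsj_depth = 50,
                       circular_fraction = 0.5,
                       fold_change = 1,
                       rcm_len = c(30L, 60L),
                       motif = "TTTTTTT",
                       clip_enrichment = 3,
                       clip_density = 0.05,
                       spliced_fraction = 0.8,
                       nascent_depth = 500L,
                       intergenic = 300L,
                       read_seg_len = 30L,
                       n_decoys = 2L,
                       decoy_depth = 10,
                       alt_tss = FALSE,
                       max_chrom_len = 2e6) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    exons_per_gene = check_range(exons_per_gene, "exons_per_gene"),
    exon_len = check_range(exon_len, "exon_len"),
    intron_len = check_range(intron_len, "intron_len"),
    n_circ_genes = as.integer(n_circ_genes),
    circ_exon_span = check_range(circ_exon_span, "circ_exon_span"),
    bsj_depth = bsj_depth,
    circular_fraction = check_fraction(circular_fraction, "circular_fraction"),
    fold_change = fold_change,
    rcm_len = check_range(rcm_len, "rcm_len"),
    motif = toupper(motif),
    clip_enrichment = clip_enrichment,
    clip_density = clip_density,
    spliced_fraction = check_fraction(spliced_fraction, "spliced_fraction"),
    nascent_depth = as.integer(nascent_depth),
    intergenic = as.integer(intergenic),
    read_seg_len = as.integer(read_seg_len),
    n_decoys = as.integer(n_decoys),
    decoy_depth = decoy_depth,
    alt_tss = isTRUE(alt_tss),
    max_chrom_len = max_chrom_len
  )
  if (is.na(cfg$seed)) stop("seed must be an integer")
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$bsj_depth < 0 || cfg$fold_change < 0) stop("depths must be nonnegative")
  if (!grepl("^[ACGT]+$", cfg$motif)) stop("motif must be over the ACGT alphabet")
  if (cfg$rcm_len[1] < nchar(cfg$motif)) {
    stop("rcm_len minimum must accommodate the motif")
  }
  if (cfg$intron_len[1] < cfg$rcm_len[2] + 6L) {
    stop("intron_len minimum too short to host the longest RCM")
  }
  if (cfg$exon_len[1] < cfg$read_seg_len) {
    stop("exon_len minimum shorter than a read segment")
  }
  class(cfg) <- "circflow_config"
  cfg
}

#' Generate a toy genome and gene annotation
#'
#' Lays out `n_genes` multi-exon genes on a single chromosome, strands drawn
#' at random, with GT..AG dinucleotides written at every intron's
#' transcribed-strand boundaries (on `-` genes the genomic forward strand
#' carries CT..AC). Deterministic under the config seed.
#'
#' @param config a [sim_config()] object.
#' @return a `circflow_truth` list with elements `genome` (named character
#'   vector), `genes`, `exons` (0-based half-open data frames) and `config`.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "circflow_config"))
  set.seed(config$seed + 1L)
  chrom <- "chrS"
  margin <- 200L
  cursor <- margin
  gene_rows <- vector("list", config$n_genes)
  exon_rows <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    n_ex <- draw_range(config$exons_per_gene)
    ex_len <- draw_range(config$exon_len, n_ex)
    in_len <- draw_range(config$intron_len, max(n_ex - 1L, 0L))
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("g%03d", g)
    pos <- cursor
    es <- integer(n_ex); ee <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      es[k] <- pos; ee[k] <- pos + ex_len[k]
      pos <- ee[k]
      if (k < n_ex) pos <- pos + in_len[k]
    }
    gene_rows[[g]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand,
      start = es[1], end = ee[n_ex], biotype = "protein_coding",
      n_exons = n_ex, stringsAsFactors = FALSE
    )
    exon_rows[[g]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      chrom = chrom, strand = strand, start = es, end = ee,
      exon_rank = seq_len(n_ex), stringsAsFactors = FALSE
    )
    cursor <- ee[n_ex] + config$intergenic
  }
  genes <- do.call(rbind, gene_rows)
  exons <- do.call(rbind, exon_rows)
  chrom_len <- cursor + margin
  if (chrom_len > config$max_chrom_len) {
    stop("sizing error: requested geometry exceeds the chromosome budget")
  }
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
  genome <- setNames(seq, chrom)
  # write splice signals at every intron boundary (transcribed strand)
  for (g in seq_len(config$n_genes)) {
    ex <- exon_rows[[g]]
    st <- ex$strand[1]
    if (nrow(ex) < 2L) next
    for (k in seq_len(nrow(ex) - 1L)) {
      is <- ex$end[k]; ie <- ex$start[k + 1L]  # intron [is, ie)
      if (st == "+") {
        genome <- set_seq(genome, chrom, is, "GT")
        genome <- set_seq(genome, chrom, ie - 2L, "AG")
      } else {
        genome <- set_seq(genome, chrom, is, "CT")
        genome <- set_seq(genome, chrom, ie - 2L, "AC")
      }
    }
  }
  if (config$alt_tss) {
    alt <- exons
    alt$transcript_id <- paste0(alt$gene_id, ".t2")
    # trim the outer boundary of the first/last exon to create an
    # alternative TSS/TES (40 nt inboard)
    for (gid in unique(alt$gene_id)) {
      i <- which(alt$gene_id == gid)
      first <- i[which.min(alt$start[i])]
      last <- i[which.max(alt$end[i])]
      alt$start[first] <- alt$start[first] + 40L
      alt$end[last] <- alt$end[last] - 40L
    }
    exons <- rbind(exons, alt)
  }
  truth <- list(genome = genome, genes = genes, exons = exons,
                config = config, circrnas = NULL, rcm_pairs = NULL,
                decoys = NULL)
  class(truth) <- "circflow_truth"
  truth
}

#' @export
print.circflow_truth <- function(x, ...) {
  cat("circflow synthetic truth set\n")
  cat(sprintf("  genome: %d chromosome(s), %s nt\n", length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  genes: %d (%d exons)\n", nrow(x$genes), nrow(x$exons)))
  if (!is.null(x$circrnas)) {
    cat(sprintf("  circRNAs: %d planted, %d RCM pairs, %d decoys\n",
                nrow(x$circrnas), nrow(x$rcm_pairs),
                if (is.null(x$decoys)) 0L else nrow(x$decoys)))
  }
  invisible(x)
}

#' Plant circRNAs, RCM pairs and motif sites into a truth set
#'
#' For each selected multi-exon gene, one circRNA spanning consecutive
#' internal exons is recorded (its boundaries are existing exon boundaries,
#' so the canonical GT/AG signals written by [sim_genome()] hold by
#' construction). In the transcription-upstream flanking intron a random
#' span carrying the configured motif is written; its exact reverse
#' complement is written into the downstream flanking intron. Non-canonical
#' decoy junctions are also planted for caller specificity tests.
#'
#' @param truth a `circflow_truth` from [sim_genome()].
#' @param config a [sim_config()]; defaults to the one inside `truth`.
#' @return `truth` with `circrnas`, `rcm_pairs` and `decoys` filled in and
#'   the genome updated with planted sequence.
#' @export
plant_circrnas <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "circflow_truth"))
  set.seed(config$seed + 2L)
  eligible <- which(truth$genes$n_exons >= 3L)
  if (length(eligible) < config$n_circ_genes) {
    stop("placement error: not enough genes with internal exons")
  }
  chosen <- sort(sample(eligible, config$n_circ_genes))
  nm <- nchar(config$motif)
  circ_rows <- vector("list", length(chosen))
  rcm_rows <- vector("list", length(chosen))
  for (i in seq_along(chosen)) {
    gene <- truth$genes[chosen[i], ]
    ex <- truth$exons[truth$exons$gene_id == gene$gene_id &
                        grepl("\\.t1$", truth$exons$transcript_id), ]
    ex <- ex[order(ex$start), ]
    n_ex <- nrow(ex)
    k <- min(draw_range(config$circ_exon_span), n_ex - 2L)
    first <- 2L + draw_range(c(0L, n_ex - 1L - k - 1L)) # internal window
    last <- first + k - 1L
    cstart <- ex$start[first]
    cend <- ex$end[last]
    # flanking introns in genomic coordinates
    left <- c(ex$end[first - 1L], ex$start[first])
    right <- c(ex$end[last], ex$start[last + 1L])
    if (gene$strand == "+") { up <- left; down <- right } else { up <- right; down <- left }
    # plant one exact RCM pair with the motif embedded on the upstream side
    L <- draw_range(config$rcm_len)
    s_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    m_off <- draw_range(c(0L, L - nm))
    s <- paste(s_chars, collapse = "")
    substr(s, m_off + 1L, m_off + nm) <- config$motif
    up_len <- up[2] - up[1]; down_len <- down[2] - down[1]
    if (up_len < L + 6L || down_len < L + 6L) {
      stop("placement error: flanking intron too short for the RCM")
    }
    up_off <- 3L + draw_range(c(0L, up_len - 6L - L))
    down_off <- 3L + draw_range(c(0L, down_len - 6L - L))
    truth$genome <- set_seq(truth$genome, gene$chrom, up[1] + up_off, s)
    truth$genome <- set_seq(truth$genome, gene$chrom, down[1] + down_off,
                            revcomp(s))
    circ_rows[[i]] <- data.frame(
      circ_id = sprintf("circ%02d", i), chrom = gene$chrom,
      strand = gene$strand, start = cstart, end = cend,
      gene_id = gene$gene_id,
      up_intron_start = up[1], up_intron_end = up[2],
      down_intron_start = down[1], down_intron_end = down[2],
      prev_exon_end = ex$end[first - 1L],
      next_exon_start = ex$start[last + 1L],
      stringsAsFactors = FALSE
    )
    rcm_rows[[i]] <- data.frame(
      circ_id = sprintf("circ%02d", i), chrom = gene$chrom,
      strand = gene$strand,
      up_start = up[1] + up_off, up_end = up[1] + up_off + L,
      down_start = down[1] + down_off, down_end = down[1] + down_off + L,
      length = L, seq = s, stringsAsFactors = FALSE
    )
  }
  truth$circrnas <- do.call(rbind, circ_rows)
  truth$rcm_pairs <- do.call(rbind, rcm_rows)
  # decoy junctions whose flanks fail the canonical check
  if (config$n_decoys > 0L) {
    decoys <- vector("list", config$n_decoys)
    for (d in seq_len(config$n_decoys)) {
      for (try in 1:200) {
        gene <- truth$genes[sample_int(nrow(truth$genes), 1L), ]
        a <- gene$start + 50L + draw_range(c(0L, max(gene$end - gene$start - 400L, 1L)))
        b <- a + draw_range(c(100L, 250L))
        if (b + 2L >= nchar(truth$genome[[gene$chrom]])) next
        if (is_canonical_bsj(truth$genome, gene$chrom, a, b, gene$strand)) next
        if (any(truth$circrnas$start == a & truth$circrnas$end == b)) next
        decoys[[d]] <- data.frame(
          decoy_id = sprintf("decoy%02d", d), chrom = gene$chrom,
          strand = gene$strand, start = a, end = b,
          gene_id = gene$gene_id, stringsAsFactors = FALSE
        )
        break
      }
      if (is.null(decoys[[d]])) stop("placement error: could not place decoy")
    }
    truth$decoys <- do.call(rbind, decoys)
  }
  truth
}

#' Construct back-splice read records for given junctions
#'
#' Emits idealised two-segment split reads in reversed genomic order across
#' the back-splice: segment 1 ends at the donor, segment 2 starts at the
#' acceptor (genomically upstream of segment 1).
#'
#' @param circs data frame with `chrom`, `strand`, `start`, `end`.
#' @param n_per_circ integer vector (recycled) of reads per junction.
#' @param seg_len segment length in nt.
#' @param prefix read-id prefix.
#' @param junction_type label stored in the `junction_type` column.
#' @return a split-read data frame (see [simulate_reads()] for columns).
#' @export
make_bsj_reads <- function(circs, n_per_circ, seg_len = 30L,
                           prefix = "bsj", junction_type = "BSJ") {
  n_per_circ <- rep_len(n_per_circ, nrow(circs))
  idx <- rep(seq_len(nrow(circs)), n_per_circ)
  if (length(idx) == 0L) return(empty_reads())
  data.frame(
    read_id = sprintf("%s_%05d", prefix, seq_along(idx)),
    chrom = circs$chrom[idx], strand = circs$strand[idx],
    seg1_start = circs$end[idx] - seg_len, seg1_end = circs$end[idx],
    seg2_start = circs$start[idx], seg2_end = circs$start[idx] + seg_len,
    cigar = sprintf("%dM,%dM", seg_len, seg_len),
    junction_type = junction_type, stringsAsFactors = FALSE
  )
}

empty_reads <- function() {
  data.frame(read_id = character(), chrom = character(), strand = character(),
             seg1_start = integer(), seg1_end = integer(),
             seg2_start = integer(), seg2_end = integer(),
             cigar = character(), junction_type = character(),
             stringsAsFactors = FALSE)
}

#' Simulate split-read records for one sample
#'
#' Per circRNA, BSJ read counts are Poisson around `bsj_depth` (times
#' `fold_change` in group B) and forward-junction (FSJ) reads are Poisson
#' around `bsj_depth * (1 - cf) / cf` where `cf` is the circular fraction.
#' FSJ reads are colinear spliced records across one of the two circle
#' boundaries into the neighbouring exon. Decoy junction reads (non-canonical
#' flanks) are included with `junction_type = "BSJ_decoy"`.
#'
#' @param truth a planted `circflow_truth`.
#' @param config a [sim_config()].
#' @param group `"A"` or `"B"`; group B applies `fold_change`.
#' @param rep replicate index; together with `group` it fixes the RNG stream.
#' @param exact_counts if `TRUE`, use rounded expectations instead of
#'   Poisson draws.
#' @return data frame of reads: `read_id, chrom, strand, seg1_start,
#'   seg1_end, seg2_start, seg2_end, cigar, junction_type` plus `sample_id`.
#' @export
simulate_reads <- function(truth, config = truth$config, group = "A",
                           rep = 1L, exact_counts = FALSE) {
  stopifnot(inherits(truth, "circflow_truth"), !is.null(truth$circrnas))
  group <- match.arg(group, c("A", "B"))
  set.seed(config$seed + 1000L * as.integer(rep) +
             500L * (group == "B") + 3L)
  circs <- truth$circrnas
  mult <- if (group == "B") config$fold_change else 1
  cf <- config$circular_fraction
  mu_b <- rep(config$bsj_depth * mult, nrow(circs))
  mu_f <- if (cf == 0) rep(config$bsj_depth * mult, nrow(circs))
          else mu_b * (1 - cf) / cf
  if (cf == 0) mu_b <- rep(0, nrow(circs))
  if (config$bsj_depth == 0) warning("zero depth: empty sample")
  nb <- if (exact_counts) round(mu_b) else rpois(nrow(circs), mu_b)
  nf <- if (exact_counts) round(mu_f) else rpois(nrow(circs), mu_f)
  L <- config$read_seg_len
  bsj <- make_bsj_reads(circs, nb, seg_len = L,
                        prefix = sprintf("%s%d_bsj", group, rep))
  # FSJ reads: colinear across a randomly chosen circle boundary
  fsj_rows <- vector("list", nrow(circs))
  for (i in seq_len(nrow(circs))) {
    if (nf[i] == 0L) next
    side <- sample(c("L", "R"), nf[i], replace = TRUE)
    s1s <- ifelse(side == "L", circs$prev_exon_end[i] - L, circs$end[i] - L)
    s1e <- s1s + L
    s2s <- ifelse(side == "L", circs$start[i], circs$next_exon_start[i])
    fsj_rows[[i]] <- data.frame(
      read_id = sprintf("%s%d_fsj%02d_%05d", group, rep, i, seq_len(nf[i])),
      chrom = circs$chrom[i], strand = circs$strand[i],
      seg1_start = s1s, seg1_end = s1e,
      seg2_start = s2s, seg2_end = s2s + L,
      cigar = sprintf("%dM,%dM", L, L),
      junction_type = "FSJ", stringsAsFactors = FALSE
    )
  }
  out <- rbind(bsj, do.call(rbind, fsj_rows))
  if (!is.null(truth$decoys) && nrow(truth$decoys) > 0L) {
    nd <- if (exact_counts) rep(round(config$decoy_depth), nrow(truth$decoys))
          else rpois(nrow(truth$decoys), config$decoy_depth)
    out <- rbind(out, make_bsj_reads(truth$decoys, nd, seg_len = L,
                                     prefix = sprintf("%s%d_dec", group, rep),
                                     junction_type = "BSJ_decoy"))
  }
  if (nrow(out) > 0L) out$sample_id <- paste0(group, rep)
  out
}

# Intron database with flanking classes derived from the truth set.
truth_introns <- function(truth) {
  introns <- build_intron_db(truth$exons, truth$genes)
  clusters <- collapse_circrnas(truth$circrnas)
  assign_flanking_introns(introns, clusters)
}

#' Simulate a cross-link track over the intron database
#'
#' Cross-link sites are placed uniformly within each intron at
#' `clip_density` sites per nt; in circRNA-flanking introns the density is
#' multiplied by `clip_enrichment`. Counts at coinciding positions are
#' aggregated.
#'
#' @param truth planted `circflow_truth`.
#' @param config a [sim_config()].
#' @param introns optional pre-built intron table (with `class`); computed
#'   from the truth set when omitted.
#' @return data frame `chrom, strand, pos, count` (0-based positions).
#' @export
simulate_crosslinks <- function(truth, config = truth$config, introns = NULL) {
  if (is.null(introns)) introns <- truth_introns(truth)
  set.seed(config$seed + 4L)
  if (nrow(introns) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- vector("list", nrow(introns))
  for (i in seq_len(nrow(introns))) {
    len <- introns$end[i] - introns$start[i]
    mult <- if (startsWith(introns$class[i], "flank")) config$clip_enrichment else 1
    nsite <- rpois(1L, len * config$clip_density * mult)
    if (nsite == 0L) next
    pos <- introns$start[i] + sample_int(len, nsite, replace = TRUE) - 1L
    tab <- table(pos)
    rows[[i]] <- data.frame(chrom = introns$chrom[i],
                            strand = introns$strand[i],
                            pos = as.integer(names(tab)),
                            count = as.integer(tab),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), strand = character(),
                      pos = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$strand, out$pos), , drop = FALSE]
}

#' Simulate nascent-read counts over splicing-efficiency windows
#'
#' For every intron with an identifiable downstream exon, the downstream-exon
#' window (first 30 percent of the exon) receives `nascent_depth` reads; the
#' intron window (last 30 percent of the intron) receives
#' `Binomial(round(n * L_intron_window / L_exon_window), 1 - spliced_fraction)`
#' reads, so the per-nt density ratio estimates `1 - spliced_fraction`.
#'
#' @param truth planted `circflow_truth`.
#' @param config a [sim_config()].
#' @param spliced_fractions optional named (by `intron_id`) vector of
#'   per-intron spliced fractions overriding the scalar config value.
#' @param introns optional pre-built intron table.
#' @return data frame with window coordinates, counts and the true spliced
#'   fraction per intron.
#' @export
simulate_nascent <- function(truth, config = truth$config,
                             spliced_fractions = NULL, introns = NULL) {
  if (is.null(introns)) introns <- truth_introns(truth)
  set.seed(config$seed + 5L)
  rows <- vector("list", nrow(introns))
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    ex <- truth$exons[truth$exons$gene_id == it$gene_id, ]
    dn <- if (it$strand == "+") ex[ex$start == it$end, , drop = FALSE]
          else ex[ex$end == it$start, , drop = FALSE]
    if (nrow(dn) == 0L) next
    dn <- dn[1L, ]
    w <- make_windows(c(it$start, it$end), c(dn$start, dn$end), it$strand)
    sf <- if (!is.null(spliced_fractions) && it$intron_id %in% names(spliced_fractions)) {
      spliced_fractions[[it$intron_id]]
    } else config$spliced_fraction
    n <- config$nascent_depth
    wi <- w$intron_window[2] - w$intron_window[1]
    we <- w$exon_window[2] - w$exon_window[1]
    icount <- rbinom(1L, round(n * wi / we), 1 - sf)
    rows[[i]] <- data.frame(
      intron_id = it$intron_id, gene_id = it$gene_id,
      chrom = it$chrom, strand = it$strand,
      intron_win_start = w$intron_window[1], intron_win_end = w$intron_window[2],
      exon_win_start = w$exon_window[1], exon_win_end = w$exon_window[2],
      intron_count = icount, exon_count = n,
      true_spliced_fraction = sf, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
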