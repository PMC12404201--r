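# Reverse-complementary-match detection between circRNA-flanking introns,
# RCM density / GC summaries, and a region-overlap permutation test.

chars_of <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_alphabet <- function(x, name) {
  if (!nzchar(x)) stop(name, " must be nonempty")
  if (grepl("[^ACGTN]", x)) stop("alphabet error: non-ACGTN symbol in ", name)
}

# suppress matches whose up AND down spans are contained in a longer kept
# match; overlapping staggered matches are both kept
dedup_contained <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(-df$length, df$up_start, df$down_start), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    contained <- FALSE
    for (j in which(keep)) {
      if (df$up_start[j] <= df$up_start[i] && df$up_end[i] <= df$up_end[j] &&
          df$down_start[j] <= df$down_start[i] &&
          df$down_end[i] <= df$down_end[j]) {
        contained <- TRUE
        break
      }
    }
    keep[i] <- !contained
  }
  out <- df[keep, , drop = FALSE]
  out[order(out$up_start, out$down_start), , drop = FALSE]
}

empty_rcms <- function() {
  data.frame(up_start = integer(), up_end = integer(),
             down_start = integer(), down_end = integer(),
             length = integer(), n_mismatches = integer(),
             gc_content = numeric(), stringsAsFactors = FALSE)
}

#' Find reverse complementary matches between two intron sequences
#'
#' In exact mode (default), reports all maximal spans where the upstream
#' sequence equals the reverse complement of a downstream span, found by
#' k-mer seeding against the reverse-complemented downstream sequence and
#' bidirectional exact extension; matches contained in a longer match are
#' suppressed and only matches of at least `min_len` nt are kept. Greedy
#' mode tolerates mismatches via X-drop extension (match +1, mismatch -2,
#' drop 6 by default). `N` never matches.
#'
#' Coordinates are 0-based half-open within each input sequence; the
#' downstream span is reported on the genomic forward strand of the
#' downstream sequence.
#'
#' @param up_seq,down_seq DNA strings (upstream / downstream flanking
#'   intron, genomic forward strand).
#' @param word_size seed k-mer length.
#' @param min_len minimum reported match length (nt); the field-standard
#'   filter keeps matches longer than 20 nt, i.e. `min_len = 21`.
#' @param mode `"exact"` or `"greedy"`.
#' @param xdrop,match_score,mismatch_score greedy-mode extension scoring.
#' @return data frame `up_start, up_end, down_start, down_end, length,
#'   n_mismatches, gc_content`.
#' @export
find_rcms <- function(up_seq, down_seq, word_size = 7L, min_len = 21L,
                      mode = c("exact", "greedy"), xdrop = 6,
                      match_score = 1, mismatch_score = -2) {
  mode <- match.arg(mode)
  check_alphabet(up_seq, "up_seq")
  check_alphabet(down_seq, "down_seq")
  u <- chars_of(up_seq)
  d <- chars_of(revcomp(down_seq))
  # make N never match anything, including another N
  d[d == "N"] <- "#"
  n_u <- length(u); n_d <- length(d)
  if (n_u < word_size || n_d < word_size) return(empty_rcms())
  # k-mer index of the reverse-complemented downstream sequence
  dk <- substring(paste(d, collapse = ""), seq_len(n_d - word_size + 1L),
                  word_size:n_d)
  idx <- split(seq_along(dk), dk)
  uk <- substring(up_seq, seq_len(n_u - word_size + 1L), word_size:n_u)
  hits <- list()
  hn <- 0L
  covered <- list()  # per-diagonal intervals already emitted (1-based in u)
  for (i in seq_along(uk)) {
    if (grepl("N", uk[i], fixed = TRUE)) next
    ks <- idx[[uk[i]]]
    if (is.null(ks)) next
    for (k in ks) {
      diag <- i - k
      dkey <- as.character(diag)
      cov <- covered[[dkey]]
      if (!is.null(cov) &&
          any(cov[, 1] <= i & i + word_size - 1L <= cov[, 2])) next
      if (mode == "exact") {
        l <- i; r <- i + word_size - 1L
        while (l > 1L && l - diag > 1L && u[l - 1L] == d[l - diag - 1L]) l <- l - 1L
        while (r < n_u && r - diag < n_d && u[r + 1L] == d[r - diag + 1L]) r <- r + 1L
        mm <- 0L
      } else {
        ext <- xdrop_extend(u, d, i, i + word_size - 1L, diag, xdrop,
                            match_score, mismatch_score)
        l <- ext$l; r <- ext$r; mm <- ext$mm
      }
      covered[[dkey]] <- rbind(cov, c(l, r))
      len <- r - l + 1L
      if (len < min_len) next
      hn <- hn + 1L
      k_l <- l - diag; k_r <- r - diag
      hits[[hn]] <- data.frame(
        up_start = l - 1L, up_end = r,
        down_start = n_d - k_r, down_end = n_d - k_l + 1L,
        length = len, n_mismatches = mm, stringsAsFactors = FALSE
      )
    }
  }
  if (hn == 0L) return(empty_rcms())
  out <- unique(do.call(rbind, hits))
  out <- dedup_contained(out)
  out$gc_content <- vapply(seq_len(nrow(out)), function(i) {
    gc_content(substr(up_seq, out$up_start[i] + 1L, out$up_end[i]))
  }, numeric(1))
  rownames(out) <- NULL
  out
}

# X-drop extension with match/mismatch scoring from a seeded exact match;
# returns the maximal-score extents and mismatch count.
xdrop_extend <- function(u, d, l0, r0, diag, xdrop, ms, xs) {
  n_u <- length(u); n_d <- length(d)
  best <- (r0 - l0 + 1L) * ms
  # rightward
  score <- best; best_r <- r0; r <- r0
  while (r < n_u && r - diag < n_d) {
    r <- r + 1L
    score <- score + if (u[r] == d[r - diag]) ms else xs
    if (score > best) { best <- score; best_r <- r }
    if (best - score >= xdrop) break
  }
  # leftward from the best right extent
  score <- best; best_l <- l0; l <- l0
  while (l > 1L && l - diag > 1L) {
    l <- l - 1L
    score <- score + if (u[l] == d[l - diag]) ms else xs
    if (score > best) { best <- score; best_l <- l }
    if (best - score >= xdrop) break
  }
  mm <- sum(u[best_l:best_r] != d[(best_l - diag):(best_r - diag)])
  list(l = best_l, r = best_r, mm = mm)
}

#' RCMs for every circRNA's flanking intron pair
#'
#' Runs [find_rcms()] on the upstream/downstream flanking intron sequences
#' of each planted or clustered circRNA and reports genomic coordinates.
#'
#' @param circs data frame with `circ_id, chrom, strand` and flanking
#'   intron coordinates (`up_intron_start/end`, `down_intron_start/end`),
#'   e.g. the truth table of [plant_circrnas()].
#' @param genome named character vector of chromosome sequences.
#' @param ... passed to [find_rcms()].
#' @return data frame of RCM pairs with genomic `up_start, up_end,
#'   down_start, down_end` plus `circ_id, chrom, strand, length,
#'   n_mismatches, gc_content`.
#' @export
flanking_rcms <- function(circs, genome, ...) {
  rows <- lapply(seq_len(nrow(circs)), function(i) {
    ci <- circs[i, ]
    up <- get_seq(genome, ci$chrom, ci$up_intron_start, ci$up_intron_end)
    down <- get_seq(genome, ci$chrom, ci$down_intron_start, ci$down_intron_end)
    r <- find_rcms(up, down, ...)
    if (nrow(r) == 0L) return(NULL)
    r$up_start <- r$up_start + ci$up_intron_start
    r$up_end <- r$up_end + ci$up_intron_start
    r$down_start <- r$down_start + ci$down_intron_start
    r$down_end <- r$down_end + ci$down_intron_start
    cbind(data.frame(circ_id = ci$circ_id, chrom = ci$chrom,
                     strand = ci$strand, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(data.frame(circ_id = character(), chrom = character(),
                            strand = character(), stringsAsFactors = FALSE),
                 empty_rcms())
  }
  rownames(out) <- NULL
  out
}

#' RCM density per pairing-length bin
#'
#' Within each RCM-length bin, a circRNA contributes at most one unit
#' (RCM pairs flanking the same circRNA are grouped); the count of
#' contributing circRNAs is normalised per kb of flanking-intron sequence.
#'
#' @param rcms data frame with `circ_id` and `length`.
#' @param flank_nt data frame with `circ_id, total_flank_nt` (summed length
#'   of both flanking introns).
#' @param bins length-bin edges (nt).
#' @return data frame `bin, n_circ, total_kb, density`.
#' @export
rcm_density <- function(rcms, flank_nt,
                        bins = c(20, 30, 50, 100, 200, Inf)) {
  total_kb <- sum(flank_nt$total_flank_nt) / 1000
  labels <- levels(cut(numeric(), bins, include.lowest = TRUE))
  n_circ <- integer(length(labels))
  if (nrow(rcms) > 0L) {
    rcms$bin <- cut(rcms$length, bins, include.lowest = TRUE)
    tab <- unique(rcms[!is.na(rcms$bin), c("circ_id", "bin")])
    t2 <- table(tab$bin)
    n_circ <- as.integer(t2[labels])
    n_circ[is.na(n_circ)] <- 0L
  }
  data.frame(bin = labels, n_circ = n_circ, total_kb = total_kb,
             density = n_circ / total_kb, stringsAsFactors = FALSE)
}

#' GC content of a DNA sequence
#'
#' `(#G + #C) / length`, with `N` excluded from both numerator and
#' denominator. All-`N` input gives `NA`.
#'
#' @param x character vector of DNA sequences.
#' @return numeric fractions.
#' @export
#' @examples
#' gc_content("ACGT")  # 0.5
gc_content <- function(x) {
  if (any(!nzchar(x))) stop("empty sequence")
  vapply(x, function(s) {
    ch <- chars_of(toupper(s))
    ch <- ch[ch != "N"]
    if (length(ch) == 0L) return(NA_real_)
    sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

# number of query regions overlapping >= 1 merged repeat interval
# (reps must be a per-chrom list of matrices with sorted, merged rows)
count_overlaps0 <- function(qs, qe, qchrom, reps) {
  n <- 0L
  for (cr in unique(qchrom)) {
    m <- reps[[cr]]
    i <- which(qchrom == cr)
    if (is.null(m) || nrow(m) == 0L) next
    # region [s,e) overlaps iff some repeat has r.start < e and r.end > s
    pos <- findInterval(qs[i], m[, 1])
    hit <- (pos >= 1L & m[pmax(pos, 1L), 2] > qs[i]) |
      (pos < nrow(m) & m[pmin(pos + 1L, nrow(m)), 1] < qe[i])
    n <- n + sum(hit)
  }
  n
}

merge_regions <- function(df) {
  out <- list()
  for (cr in unique(df$chrom)) {
    x <- df[df$chrom == cr, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))
    out[[cr]] <- cbind(IRanges::start(ir) - 1L, IRanges::end(ir))
  }
  out
}

#' Region-overlap permutation test
#'
#' Tests whether the observed number of query regions overlapping a repeat
#' set exceeds chance, by re-placing length-preserved query regions
#' uniformly within a placement space `ntimes` times (no overlap
#' constraints). The empirical p-value is
#' `(1 + #\{null >= observed\}) / (ntimes + 1)`; the z-score standardises
#' the observation against the null mean and sd.
#'
#' @param query,repeats,space data frames with `chrom, start, end`
#'   (0-based half-open). `space` is the set of intervals regions may be
#'   placed into (e.g. all flanking introns, or the gene space).
#' @param ntimes number of randomisations.
#' @param seed RNG seed.
#' @return list of class `circflow_permtest`: `observed, null_overlaps,
#'   p_empirical, z_score, ntimes`.
#' @export
permutation_overlap <- function(query, repeats, space, ntimes = 500L,
                                seed = 1L) {
  if (ntimes < 1L) stop("ntimes must be >= 1")
  set.seed(seed)
  reps <- merge_regions(repeats)
  lens <- query$end - query$start
  observed <- count_overlaps0(query$start, query$end, query$chrom, reps)
  # eligible start positions per space interval for each query length
  sp_len <- space$end - space$start
  null <- integer(ntimes)
  ulens <- unique(lens)
  elig <- lapply(ulens, function(L) pmax(0L, sp_len - L + 1L))
  names(elig) <- as.character(ulens)
  if (any(vapply(elig, sum, numeric(1)) == 0)) {
    stop("placement error: query region longer than any placement interval")
  }
  nq <- length(lens)
  for (t in seq_len(ntimes)) {
    ns <- integer(nq); ne <- integer(nq); ch <- character(nq)
    for (L in ulens) {
      q <- which(lens == L)
      w <- elig[[as.character(L)]]
      j <- sample.int(length(w), length(q), replace = TRUE, prob = w)
      off <- floor(runif(length(q)) * w[j])
      ns[q] <- space$start[j] + off
      ne[q] <- ns[q] + L
      ch[q] <- space$chrom[j]
    }
    null[t] <- count_overlaps0(ns, ne, ch, reps)
  }
  mu <- mean(null); s <- sd(null)
  structure(list(
    observed = observed, null_overlaps = null,
    p_empirical = (1 + sum(null >= observed)) / (ntimes + 1),
    z_score = if (isTRUE(s > 0)) (observed - mu) / s else NA_real_,
    ntimes = ntimes
  ), class = "circflow_permtest")
}

#' @export
print.circflow_permtest <- function(x, ...) {
  cat("Region-overlap permutation test\n")
  cat(sprintf("  observed overlaps: %d\n", x$observed))
  cat(sprintf("  null mean (sd): %.2f (%.2f) over %d randomisations\n",
              mean(x$null_overlaps), sd(x$null_overlaps), x$ntimes))
  cat(sprintf("  empirical p: %.4g   z: %.2f\n", x$p_empirical, x$z_score))
  invisible(x)
}
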