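# BSJ motif analysis: +/-25 nt junction windows with circular wrap,
# position-weight-matrix scanning, Fisher enrichment against control
# windows and central positional enrichment.

#' Construct a position weight matrix object
#'
#' @param mat 4-row numeric matrix of per-position probabilities, rows
#'   named A, C, G, T; columns sum to 1.
#' @param background named nucleotide background frequencies (sum 1).
#' @param id motif identifier.
#' @return list of class `circflow_pwm`.
#' @export
pwm <- function(mat, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                id = "motif") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(abs(colSums(mat) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  structure(list(id = id, mat = mat, background = background[c("A", "C", "G", "T")]),
            class = "circflow_pwm")
}

#' PWM from a consensus string
#'
#' @param consensus string over ACGT.
#' @param p probability assigned to the consensus base at each position
#'   (the rest is split evenly).
#' @param id motif identifier.
#' @return a [pwm()] object.
#' @export
pwm_from_consensus <- function(consensus, p = 0.91, id = consensus) {
  ch <- chars_of(toupper(consensus))
  if (any(!ch %in% c("A", "C", "G", "T"))) stop("consensus must be over ACGT")
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(ch),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(ch)) m[ch[j], j] <- p
  pwm(m, id = id)
}

#' Read motifs from a MEME-format file
#'
#' Parses the minimal MEME motif format (version line, optional background
#' frequencies, `MOTIF` blocks with `letter-probability matrix` sections).
#' A small pseudocount is mixed in so zero probabilities do not produce
#' infinite log-odds.
#'
#' @param path file path.
#' @param pseudo pseudocount weight mixed with the background.
#' @return list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudo = 0.01) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) && bgi[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    if (length(tok) >= 8L) {
      vals <- as.numeric(tok[seq(2, 8, by = 2)])
      names(vals) <- tok[seq(1, 7, by = 2)]
      bg <- vals[c("A", "C", "G", "T")]
    }
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines[s:length(lines)])[1] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    m <- t(vapply(rows, function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]]),
                  numeric(4), USE.NAMES = FALSE))
    m <- t(m)  # 4 x w
    m <- (m + pseudo * bg) / (1 + pseudo)
    m <- sweep(m, 2, colSums(m), "/")
    out[[id]] <- pwm(m, background = bg, id = id)
  }
  out
}

#' Exonic sequence of a circRNA
#'
#' Concatenates the host gene's exon sequences inside the circle in
#' transcript orientation (reverse complemented for `-` genes).
#'
#' @param circ one-row data frame with `chrom, strand, start, end,
#'   gene_id`.
#' @param exons exon table.
#' @param genome named character vector of chromosome sequences.
#' @return DNA string.
#' @export
circ_exon_seq <- function(circ, exons, genome) {
  ex <- exons[exons$gene_id == circ$gene_id & exons$start >= circ$start &
                exons$end <= circ$end, , drop = FALSE]
  ex <- unique(ex[order(ex$start), c("start", "end")])
  if (nrow(ex) == 0L) stop("no exons inside the circle")
  s <- paste(vapply(seq_len(nrow(ex)), function(i) {
    get_seq(genome, circ$chrom, ex$start[i], ex$end[i])
  }, character(1)), collapse = "")
  if (circ$strand == "-") s <- revcomp(s)
  s
}

#' Sequence window across the back-splice junction
#'
#' Returns the `2 * half_width` nt read across the junction: the last
#' `half_width` nt of the circle's (spliced) sequence followed by its
#' first `half_width` nt. Circles shorter than the window wrap around
#' circularly.
#'
#' @param circ_seq the circle's spliced sequence (transcript orientation).
#' @param half_width nt on each side of the junction.
#' @return DNA string of length `2 * half_width`.
#' @export
#' @examples
#' bsj_window("AAACCCGGGTTT", half_width = 3)  # "TTTAAA"
bsj_window <- function(circ_seq, half_width = 25L) {
  n <- nchar(circ_seq)
  if (n == 0L) stop("circle of length 0")
  ch <- chars_of(circ_seq)
  idx <- ((n - half_width):(n + half_width - 1L)) %% n
  paste(ch[idx + 1L], collapse = "")
}

#' Scan a sequence with a PWM
#'
#' Computes the log2-odds score (PWM vs background) at every offset and
#' reports hits scoring at least `threshold`; overlapping hits are
#' allowed.
#'
#' @param seqs named character vector of equal-purpose sequences (names
#'   become `sequence_id`; defaults to indices).
#' @param pwm a [pwm()] object.
#' @param threshold minimum log2-odds score.
#' @return data frame `sequence_id, offset, score` (0-based offsets).
#' @export
scan_pwm <- function(seqs, pwm, threshold = 0) {
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  w <- ncol(pwm$mat)
  lodds <- log2(pwm$mat / pwm$background)
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    if (grepl("[^ACGT]", s)) stop("alphabet mismatch in sequence ", id)
    if (nchar(s) < w) stop("sequence shorter than the motif")
    x <- match(chars_of(s), c("A", "C", "G", "T"))
    offs <- 0:(nchar(s) - w)
    score <- vapply(offs, function(o) {
      sum(lodds[cbind(x[(o + 1):(o + w)], seq_len(w))])
    }, numeric(1))
    keep <- score >= threshold
    if (!any(keep)) return(NULL)
    data.frame(sequence_id = id, offset = offs[keep], score = score[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(), offset = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Motif enrichment in target vs control windows
#'
#' Builds the 2x2 table of sequences with vs without at least one PWM hit
#' in the target and control sets; reports the Haldane-corrected odds
#' ratio and the Fisher exact p-value.
#'
#' @param target,control character vectors of windows.
#' @param pwm a [pwm()] object.
#' @param threshold scan threshold.
#' @return list `odds_ratio, p, table`.
#' @export
motif_enrichment <- function(target, control, pwm, threshold = 0) {
  if (length(target) == 0L || length(control) == 0L) {
    stop("both sequence sets must be nonempty")
  }
  if (any(nchar(c(target, control)) < ncol(pwm$mat))) {
    stop("motif longer than the windows")
  }
  has_hit <- function(seqs) {
    h <- scan_pwm(setNames(seqs, seq_along(seqs)), pwm, threshold)
    length(unique(h$sequence_id))
  }
  a <- has_hit(target); b <- length(target) - a
  c_ <- has_hit(control); d <- length(control) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(hit = c("yes", "no"),
                                set = c("target", "control")))
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  list(odds_ratio = or, p = fisher.test(tab)$p.value, table = tab)
}

#' Central positional enrichment of motif hits
#'
#' Classifies each hit's centre (motif midpoint, rounded down) as central
#' when it falls within `central_width` positions around the window
#' midpoint, and tests the central count against the fraction of
#' available centre positions that are central with an upper-tail
#' binomial test.
#'
#' @param hits data frame from [scan_pwm()] over equal-length windows.
#' @param motif_len motif width (nt).
#' @param window_len window length (nt).
#' @param central_width width of the central band (nt).
#' @return list `p, n_hits, n_central, p0`.
#' @export
central_enrichment <- function(hits, motif_len, window_len = 50L,
                               central_width = 20L) {
  if (central_width >= window_len) stop("central_width must be < window_len")
  mid <- window_len / 2
  band <- c(mid - central_width / 2, mid + central_width / 2)
  center_of <- function(off) off + (motif_len - 1L) %/% 2L
  avail <- center_of(0:(window_len - motif_len))
  p0 <- sum(avail >= band[1] & avail < band[2]) / length(avail)
  n <- nrow(hits)
  if (n == 0L) return(list(p = 1, n_hits = 0L, n_central = 0L, p0 = p0))
  centers <- center_of(hits$offset)
  k <- sum(centers >= band[1] & centers < band[2])
  list(p = pbinom(k - 1, n, p0, lower.tail = FALSE),
       n_hits = n, n_central = k, p0 = p0)
}
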