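# Exon-intron split analysis: classify reads as exon-exon-junction (EEJ,
# mature mRNA evidence) or exon-intron-boundary (EIB, pre-mRNA evidence)
# and compute per-gene IP-vs-input enrichment.

#' Classify alignment records as EEJ, EIB or other
#'
#' EEJ: a gapped read whose gap matches an annotated intron of a transcript
#' (segment 1 ends at the intron start, segment 2 starts at the intron
#' end). EIB: an ungapped read whose CIGAR contains only M operations and
#' whose span overlaps both exonic and intronic sequence of one gene by at
#' least 1 nt on each side of a boundary. Everything else is `other`.
#'
#' @param reads split-read data frame (single-segment reads have `NA` in
#'   `seg2_start`/`seg2_end`).
#' @param exons exon table (`gene_id, transcript_id, chrom, strand, start,
#'   end`).
#' @return data frame `read_id, class, gene_id` (`gene_id` is `NA` for
#'   class `other`).
#' @export
classify_read <- function(reads, exons) {
  if (any(!grepl("^([0-9]+[MIDNSHP=X],?)+$", reads$cigar))) {
    stop("CIGAR parse failure")
  }
  # annotated exon-exon junctions per transcript
  jx <- list()
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1L) {
      jx[[tx]] <- data.frame(
        gene_id = ex$gene_id[1], chrom = ex$chrom[1], strand = ex$strand[1],
        gap_start = ex$end[-nrow(ex)], gap_end = ex$start[-1],
        stringsAsFactors = FALSE
      )
    }
  }
  jx <- do.call(rbind, jx)
  # per-gene exon unions and intronic gaps
  gene_feats <- list()
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, ]
    ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    gaps <- IRanges::gaps(ir, start = min(ex$start) + 1L, end = max(ex$end))
    gene_feats[[gid]] <- list(
      chrom = ex$chrom[1], strand = ex$strand[1],
      span = c(min(ex$start), max(ex$end)),
      exons = cbind(IRanges::start(ir) - 1L, IRanges::end(ir)),
      introns = if (length(gaps)) cbind(IRanges::start(gaps) - 1L,
                                        IRanges::end(gaps))
                else matrix(integer(), ncol = 2)
    )
  }
  cls <- rep("other", nrow(reads))
  gene <- rep(NA_character_, nrow(reads))
  only_m <- grepl("^([0-9]+M,?)+$", reads$cigar)
  spliced <- !is.na(reads$seg2_start) & reads$seg2_start >= reads$seg1_end
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (spliced[i] && !is.null(jx)) {
      hit <- jx$chrom == r$chrom & jx$strand == r$strand &
        jx$gap_start == r$seg1_end & jx$gap_end == r$seg2_start
      if (any(hit)) {
        cls[i] <- "EEJ"
        gene[i] <- jx$gene_id[which(hit)[1]]
        next
      }
    }
    if (!spliced[i] && is.na(r$seg2_start) && only_m[i]) {
      for (gid in names(gene_feats)) {
        gf <- gene_feats[[gid]]
        if (gf$chrom != r$chrom || gf$strand != r$strand) next
        ov <- function(m) {
          if (nrow(m) == 0L) return(0L)
          sum(pmax(0L, pmin(m[, 2], r$seg1_end) - pmax(m[, 1], r$seg1_start)))
        }
        if (ov(gf$exons) >= 1L && ov(gf$introns) >= 1L) {
          cls[i] <- "EIB"
          gene[i] <- gid
          break
        }
      }
    }
  }
  data.frame(read_id = reads$read_id, class = cls, gene_id = gene,
             stringsAsFactors = FALSE)
}

#' Per-gene EEJ/EIB counts from classified reads
#'
#' @param classified output of [classify_read()].
#' @return data frame `gene_id, eej, eib`.
#' @export
eisa_counts <- function(classified) {
  keep <- classified$class %in% c("EEJ", "EIB")
  x <- classified[keep, , drop = FALSE]
  genes <- sort(unique(x$gene_id))
  data.frame(
    gene_id = genes,
    eej = vapply(genes, function(g) sum(x$gene_id == g & x$class == "EEJ"),
                 integer(1)),
    eib = vapply(genes, function(g) sum(x$gene_id == g & x$class == "EIB"),
                 integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Exon and exon-intron-boundary enrichment (IP vs input) per gene
#'
#' Exon (total-transcript) enrichment is the library-normalised log2 ratio
#' of EEJ counts with 0.5 prior counts; boundary (pre-mRNA) enrichment is
#' the analogue on EIB counts. Genes whose mean EEJ count across the two
#' libraries is below `min_eej` are `filtered`. A gene is
#' `pre_mRNA_enriched` when its boundary enrichment exceeds
#' `enr_threshold` and the one-sided conditional binomial p-value of the
#' EIB contrast is below `alpha`; otherwise `not_enriched`.
#'
#' @param tab data frame with `gene_id, eej_ip, eej_input, eib_ip,
#'   eib_input`.
#' @param lib_ip,lib_input library sizes; default to the column totals.
#' @param min_eej mean-EEJ filter threshold.
#' @param enr_threshold log2 boundary-enrichment call threshold.
#' @param alpha significance level of the binomial check.
#' @return data frame with enrichments, p-values and a `class` column.
#' @export
eisa_enrichment <- function(tab, lib_ip = NULL, lib_input = NULL,
                            min_eej = 10, enr_threshold = 1, alpha = 0.05) {
  req <- c("gene_id", "eej_ip", "eej_input", "eib_ip", "eib_input")
  if (!all(req %in% names(tab))) stop("design error: missing count columns")
  if (is.null(lib_ip)) lib_ip <- sum(tab$eej_ip) + sum(tab$eib_ip)
  if (is.null(lib_input)) lib_input <- sum(tab$eej_input) + sum(tab$eib_input)
  sf <- lib_input / lib_ip  # scales IP counts onto the input library
  exon_enr <- log2((tab$eej_ip + 0.5) / (tab$eej_input + 0.5) * sf)
  boundary_enr <- log2((tab$eib_ip + 0.5) / (tab$eib_input + 0.5) * sf)
  p0 <- lib_ip / (lib_ip + lib_input)
  p <- mapply(function(a, b) {
    n <- a + b
    if (n == 0) return(1)
    binom.test(a, n, p0, alternative = "greater")$p.value
  }, tab$eib_ip, tab$eib_input)
  mean_eej <- (tab$eej_ip + tab$eej_input) / 2
  filtered <- mean_eej < min_eej
  class <- ifelse(filtered, "filtered",
                  ifelse(boundary_enr > enr_threshold & p < alpha,
                         "pre_mRNA_enriched", "not_enriched"))
  data.frame(
    gene_id = tab$gene_id,
    eej_ip = tab$eej_ip, eej_input = tab$eej_input,
    eib_ip = tab$eib_ip, eib_input = tab$eib_input,
    exon_enrichment = ifelse(filtered, NA_real_, exon_enr),
    boundary_enrichment = ifelse(filtered, NA_real_, boundary_enr),
    p = ifelse(filtered, NA_real_, p),
    class = class, stringsAsFactors = FALSE
  )
}
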