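# Back-splice junction calling and quantification: canonical-signal
# filtering, forward-junction counting, the junction ratio, the >=5-BSJ
# reference filter and the saturation analysis.

#' Call back-splice junctions from split-read records
#'
#' A read whose two segments map to the same chromosome and strand with the
#' second segment genomically upstream of the first defines a candidate
#' back-splice junction: acceptor = second segment start, donor = first
#' segment end. Candidates failing the canonical GT/AG check (read on the
#' transcribed strand of the adjoining introns) are dropped; identical
#' coordinates are merged and counted.
#'
#' @param reads split-read data frame (see [simulate_reads()]).
#' @param genome named character vector of chromosome sequences.
#' @param detail if `TRUE`, also return the per-read junction assignment of
#'   accepted back-splice reads (needed by [saturation_curve()]).
#' @return data frame of circRNAs (`circ_id, chrom, strand, start, end,
#'   bsj, canonical`), or, with `detail = TRUE`, a list with elements
#'   `circs` and `assignments` (`read_id, circ_id`).
#' @export
call_bsj <- function(reads, genome, detail = FALSE) {
  cand <- !is.na(reads$seg2_start) & reads$seg2_start < reads$seg1_start
  r <- reads[cand, , drop = FALSE]
  empty <- data.frame(circ_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), bsj = integer(),
                      canonical = logical(), stringsAsFactors = FALSE)
  if (nrow(r) == 0L) {
    return(if (detail) list(circs = empty,
                            assignments = data.frame(read_id = character(),
                                                     circ_id = character()))
           else empty)
  }
  if (!all(r$chrom %in% names(genome))) stop("unknown chromosome in reads")
  lens <- nchar(genome)[r$chrom]
  if (any(r$seg1_end > lens) || any(r$seg2_start < 0L)) {
    stop("read segment beyond chromosome end")
  }
  acceptor <- r$seg2_start
  donor <- r$seg1_end
  key <- paste(r$chrom, r$strand, acceptor, donor, sep = ":")
  uk <- !duplicated(key)
  ok <- is_canonical_bsj(genome, r$chrom[uk], acceptor[uk], donor[uk],
                         r$strand[uk])
  canon_keys <- key[uk][ok]
  accept <- key %in% canon_keys
  tab <- table(key[accept])
  if (length(tab) == 0L) {
    return(if (detail) list(circs = empty,
                            assignments = data.frame(read_id = character(),
                                                     circ_id = character()))
           else empty)
  }
  parts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  circs <- data.frame(
    circ_id = names(tab), chrom = parts[, 1], strand = parts[, 2],
    start = as.integer(parts[, 3]), end = as.integer(parts[, 4]),
    bsj = as.integer(tab), canonical = TRUE, stringsAsFactors = FALSE
  )
  circs <- circs[order(circs$chrom, circs$start, circs$end), , drop = FALSE]
  rownames(circs) <- NULL
  if (!detail) return(circs)
  list(circs = circs,
       assignments = data.frame(read_id = r$read_id[accept],
                                circ_id = key[accept],
                                stringsAsFactors = FALSE))
}

#' Count forward-junction (linear) reads per circRNA
#'
#' A colinear read (single segment, or second segment genomically
#' downstream) supports the linear transcript at a circle when its extent
#' spans the acceptor or the donor boundary; each read is counted at most
#' once per circRNA.
#'
#' @param reads split-read data frame.
#' @param circs circRNA table from [call_bsj()].
#' @return `circs` with `fsj` and `junction_ratio` columns added.
#' @export
count_fsj <- function(reads, circs) {
  colinear <- is.na(reads$seg2_start) | reads$seg2_start >= reads$seg1_end
  r <- reads[colinear, , drop = FALSE]
  ext_min <- r$seg1_start
  ext_max <- ifelse(is.na(r$seg2_end), r$seg1_end, r$seg2_end)
  fsj <- integer(nrow(circs))
  for (i in seq_len(nrow(circs))) {
    hit <- r$chrom == circs$chrom[i] & r$strand == circs$strand[i] &
      ((ext_min < circs$start[i] & circs$start[i] < ext_max) |
         (ext_min < circs$end[i] & circs$end[i] < ext_max))
    fsj[i] <- length(unique(r$read_id[hit]))
  }
  circs$fsj <- fsj
  circs$junction_ratio <- junction_ratio(circs$bsj, circs$fsj)
  circs
}

#' Circular-to-linear junction ratio
#'
#' Computes `2 * bsj / (2 * bsj + fsj)`; `NA` when both counts are zero.
#'
#' @param bsj,fsj nonnegative read counts (vectorised).
#' @return numeric vector of ratios in `[0, 1]`.
#' @export
#' @examples
#' junction_ratio(5, 10)  # 0.5
junction_ratio <- function(bsj, fsj) {
  if (any(bsj < 0, na.rm = TRUE) || any(fsj < 0, na.rm = TRUE)) {
    stop("counts must be nonnegative")
  }
  out <- 2 * bsj / (2 * bsj + fsj)
  out[bsj + fsj == 0] <- NA_real_
  out
}

#' Reference filter: minimum BSJ support per population
#'
#' Retains a circRNA when its pooled back-splice read count reaches
#' `min_bsj` in at least one population, recording which populations
#' qualified.
#'
#' @param counts data frame with `circ_id, population, bsj` (replicates
#'   already pooled per population).
#' @param min_bsj minimum BSJ reads per circRNA per population.
#' @return data frame `circ_id, populations` (comma-joined qualifying
#'   populations) for retained circRNAs.
#' @export
filter_reference <- function(counts, min_bsj = 5L) {
  ok <- counts[counts$bsj >= min_bsj, , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(data.frame(circ_id = character(), populations = character(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(population ~ circ_id, data = ok,
                   FUN = function(p) paste(sort(unique(p)), collapse = ","))
  names(agg)[2] <- "populations"
  agg[order(agg$circ_id), , drop = FALSE]
}

#' Saturation analysis by read subsampling
#'
#' Subsamples the accepted back-splice reads without replacement at each
#' fraction, recomputes detection at the `min_bsj` threshold, and reports
#' the recovered fraction relative to the full set, averaged over
#' replicates. Deterministic under `seed`.
#'
#' @param assignments per-read junction assignments (`circ_id` per accepted
#'   BSJ read), as returned by `call_bsj(..., detail = TRUE)$assignments`.
#' @param fractions percentages in `(0, 100]`.
#' @param n_reps subsampling replicates per fraction.
#' @param seed RNG seed.
#' @param min_bsj detection threshold.
#' @return data frame `fraction, n_detected, recovery`.
#' @export
saturation_curve <- function(assignments, fractions = c(1, 5, 10, 25, 50, 75, 100),
                             n_reps = 3L, seed = 1L, min_bsj = 5L) {
  if (any(fractions <= 0) || any(fractions > 100)) {
    stop("fractions must lie in (0, 100]")
  }
  if (nrow(assignments) == 0L) stop("no back-splice reads to subsample")
  set.seed(seed)
  ids <- assignments$circ_id
  N <- length(ids)
  full <- names(which(table(ids) >= min_bsj))
  if (length(full) == 0L) stop("no circRNA reaches the detection threshold")
  out <- lapply(fractions, function(f) {
    det <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      k <- max(1L, round(f / 100 * N))
      sub <- ids[sample_int(N, k)]
      det[r] <- sum(table(sub)[full] >= min_bsj, na.rm = TRUE)
    }
    data.frame(fraction = f, n_detected = mean(det),
               recovery = mean(det) / length(full))
  })
  do.call(rbind, out)
}

#' Assign host genes to called circRNAs
#'
#' A circRNA is assigned to the gene whose span contains it on the same
#' strand and chromosome (first match in gene order when several do).
#'
#' @param circs circRNA table.
#' @param genes gene table (`gene_id, chrom, strand, start, end`).
#' @return `circs` with a `gene_id` column (`NA` when unassigned).
#' @export
assign_host_genes <- function(circs, genes) {
  circs$gene_id <- NA_character_
  for (i in seq_len(nrow(circs))) {
    hit <- which(genes$chrom == circs$chrom[i] &
                   genes$strand == circs$strand[i] &
                   genes$start <= circs$start[i] &
                   genes$end >= circs$end[i])
    if (length(hit) > 0L) circs$gene_id[i] <- genes$gene_id[hit[1]]
  }
  circs
}
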