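# Cross-link (iCLIP) enrichment across intron classes and metaprofiles
# over normalised introns and around RCMs.

# total track counts within [start,end) on matching chrom/strand
track_counts_in <- function(track, chrom, strand, start, end) {
  hit <- track$chrom == chrom & track$strand == strand &
    track$pos >= start & track$pos < end
  sum(track$count[hit])
}

#' Cross-link enrichment across intron classes
#'
#' Tests whether cross-link sites distribute across intron groups in
#' proportion to their total lengths: observed counts per group are
#' compared to a length-proportional expectation with a chi-squared
#' goodness-of-fit test (k-1 degrees of freedom). This keeps the counts
#' integral while performing the length normalisation on the expectation
#' side. Per-group per-kb densities are also reported.
#'
#' @param track cross-link track (`chrom, strand, pos, count`).
#' @param introns intron table with `class` (from
#'   [assign_flanking_introns()]).
#' @param groups named list mapping group labels to intron classes;
#'   default contrasts flanking vs nonflanking introns.
#' @return list of class `circflow_enrichment`: per-group `counts`,
#'   `lengths`, `density_per_kb`, plus `chi2`, `df`, `p`.
#' @export
group_enrichment <- function(track, introns,
                             groups = list(
                               flank = c("flank_up", "flank_down", "flank_both"),
                               nonflanking = "nonflanking")) {
  if (length(groups) < 2L) stop("need at least two groups")
  counts <- numeric(length(groups))
  lens <- numeric(length(groups))
  for (g in seq_along(groups)) {
    sel <- introns[introns$class %in% groups[[g]], , drop = FALSE]
    lens[g] <- sum(sel$end - sel$start)
    counts[g] <- sum(vapply(seq_len(nrow(sel)), function(i) {
      track_counts_in(track, sel$chrom[i], sel$strand[i],
                      sel$start[i], sel$end[i])
    }, numeric(1)))
  }
  names(counts) <- names(lens) <- names(groups)
  if (any(lens == 0)) stop("each group needs total length > 0")
  if (sum(counts) == 0) {
    warning("zero cross-links in all groups")
    return(structure(list(counts = counts, lengths = lens,
                          density_per_kb = counts / (lens / 1000),
                          chi2 = NA_real_, df = length(groups) - 1L,
                          p = NA_real_), class = "circflow_enrichment"))
  }
  test <- suppressWarnings(chisq.test(counts, p = lens / sum(lens)))
  structure(list(counts = counts, lengths = lens,
                 density_per_kb = counts / (lens / 1000),
                 chi2 = unname(test$statistic), df = unname(test$parameter),
                 p = test$p.value), class = "circflow_enrichment")
}

#' @export
print.circflow_enrichment <- function(x, ...) {
  cat("Cross-link enrichment across intron groups\n")
  for (g in names(x$counts)) {
    cat(sprintf("  %-12s %8.0f sites / %8.0f nt  (%.2f per kb)\n", g,
                x$counts[g], x$lengths[g], x$density_per_kb[g]))
  }
  cat(sprintf("  chi-squared = %.3f (df %d), p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Metaprofile of cross-link signal over length-normalised introns
#'
#' Positions within each intron are mapped to `n_bins` equal-width bins in
#' transcribed-strand orientation (`floor(fraction * n_bins)`; on `-`
#' introns the genomic right end maps to bin 1). Counts are summed across
#' introns, optionally after per-intron total normalisation.
#'
#' @param track cross-link track.
#' @param introns intron table.
#' @param n_bins number of bins.
#' @param normalize if `TRUE`, each intron's counts are scaled to sum to 1
#'   before summation.
#' @return data frame `bin, count`.
#' @export
intron_metaprofile <- function(track, introns, n_bins = 100L,
                               normalize = FALSE) {
  if (nrow(introns) == 0L) stop("introns must be nonempty")
  prof <- numeric(n_bins)
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    hit <- track$chrom == it$chrom & track$strand == it$strand &
      track$pos >= it$start & track$pos < it$end
    if (!any(hit)) next
    pos <- track$pos[hit]
    cnt <- track$count[hit]
    len <- it$end - it$start
    rel <- if (it$strand == "+") pos - it$start else it$end - 1 - pos
    # integer arithmetic avoids floating-point drift at bin boundaries
    bin <- pmin((rel * n_bins) %/% len, n_bins - 1L) + 1L
    if (normalize) cnt <- cnt / sum(cnt)
    prof <- prof + vapply(seq_len(n_bins),
                          function(b) sum(cnt[bin == b]), numeric(1))
  }
  data.frame(bin = seq_len(n_bins), count = prof)
}

#' Metaprofile of cross-link signal at RCMs and their surroundings
#'
#' Accumulates cross-link counts in nt-resolution flank bins on either
#' side of each RCM span and in `interior_bins` length-normalised bins
#' inside the span, separately for upstream-intron and downstream-intron
#' RCM sides. Flanks extending past chromosome bounds are truncated and
#' flagged in the `truncated` attribute.
#'
#' @param track cross-link track.
#' @param rcms RCM table from [flanking_rcms()].
#' @param flank flank width in nt.
#' @param interior_bins number of interior bins.
#' @param chrom_len optional named vector of chromosome lengths.
#' @return data frame `side, region, offset, count`; `region` is
#'   `flank_left`, `interior` or `flank_right` (genomic orientation).
#' @export
rcm_metaprofile <- function(track, rcms, flank = 1000L, interior_bins = 50L,
                            chrom_len = NULL) {
  truncated <- FALSE
  sides <- list(up = c("up_start", "up_end"),
                down = c("down_start", "down_end"))
  out <- list()
  for (sd in names(sides)) {
    left <- numeric(flank); interior <- numeric(interior_bins)
    right <- numeric(flank)
    for (i in seq_len(nrow(rcms))) {
      s <- rcms[[sides[[sd]][1]]][i]
      e <- rcms[[sides[[sd]][2]]][i]
      cr <- rcms$chrom[i]; st <- rcms$strand[i]
      cl <- if (!is.null(chrom_len)) chrom_len[[cr]] else Inf
      if (s - flank < 0 || e + flank > cl) truncated <- TRUE
      hit <- track$chrom == cr & track$strand == st &
        track$pos >= max(0, s - flank) & track$pos < min(cl, e + flank)
      if (!any(hit)) next
      pos <- track$pos[hit]; cnt <- track$count[hit]
      for (j in seq_along(pos)) {
        if (pos[j] < s) {
          left[flank - (s - pos[j]) + 1L] <-
            left[flank - (s - pos[j]) + 1L] + cnt[j]
        } else if (pos[j] >= e) {
          right[pos[j] - e + 1L] <- right[pos[j] - e + 1L] + cnt[j]
        } else {
          b <- pmin(((pos[j] - s) * interior_bins) %/% (e - s),
                    interior_bins - 1L) + 1L
          interior[b] <- interior[b] + cnt[j]
        }
      }
    }
    out[[sd]] <- rbind(
      data.frame(side = sd, region = "flank_left",
                 offset = -(flank:1), count = left),
      data.frame(side = sd, region = "interior",
                 offset = seq_len(interior_bins), count = interior),
      data.frame(side = sd, region = "flank_right",
                 offset = seq_len(flank), count = right)
    )
  }
  res <- do.call(rbind, out)
  attr(res, "truncated") <- truncated
  res
}
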