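# Cotranscriptional splicing efficiency from nascent reads: 30%-of-length
# windows at the intron 3' end and the downstream exon 5' end, efficiency
# = 1 - intron/exon read-density ratio, clamped to [0,1].

#' Build the intron/exon quantification windows
#'
#' The intron window covers the transcribed-strand last 30 percent of the
#' intron; the exon window the first 30 percent of the downstream exon. On
#' the `-` strand these are the genomically leftmost and rightmost
#' segments respectively. Window lengths use round-half-up; a window that
#' rounds to zero nt is an error.
#'
#' @param intron,exon length-2 vectors `c(start, end)` (0-based half-open);
#'   the exon is the transcription-downstream exon.
#' @param strand `"+"` or `"-"`.
#' @param window_fraction fraction of the feature length per window.
#' @return list with `intron_window` and `exon_window` (each `c(start,
#'   end)`).
#' @export
#' @examples
#' make_windows(c(100, 200), c(200, 300), "+")
make_windows <- function(intron, exon, strand, window_fraction = 0.3) {
  il <- intron[2] - intron[1]
  el <- exon[2] - exon[1]
  wi <- round_half_up(window_fraction * il)
  we <- round_half_up(window_fraction * el)
  if (wi < 1 || we < 1) stop("feature too short: window rounds to 0 nt")
  if (strand == "+") {
    list(intron_window = c(intron[2] - wi, intron[2]),
         exon_window = c(exon[1], exon[1] + we))
  } else {
    list(intron_window = c(intron[1], intron[1] + wi),
         exon_window = c(exon[2] - we, exon[2]))
  }
}

#' Splicing efficiency from window counts
#'
#' Per-nt, library-normalised densities are formed for each window and the
#' efficiency is `1 - intron_density / exon_density`, clamped to `[0, 1]`
#' (sampling noise can push the raw ratio outside). `NA` when the exon
#' density is zero. Values near 1 indicate efficient cotranscriptional
#' splicing.
#'
#' @param intron_count,exon_count nonnegative read counts (vectorised).
#' @param intron_win_len,exon_win_len window lengths (nt).
#' @param lib_size library size (cancels in the ratio; kept for interface
#'   symmetry).
#' @return numeric efficiencies in `[0, 1]` (or `NA`).
#' @export
splicing_efficiency <- function(intron_count, exon_count,
                                intron_win_len, exon_win_len,
                                lib_size = 1) {
  if (any(intron_count < 0) || any(exon_count < 0)) {
    stop("counts must be nonnegative")
  }
  di <- intron_count / lib_size / intron_win_len
  de <- exon_count / lib_size / exon_win_len
  eff <- 1 - di / de
  eff[de == 0] <- NA_real_
  pmin(1, pmax(0, eff))
}

#' Per-intron splicing efficiencies from nascent window counts
#'
#' Convenience wrapper applying [splicing_efficiency()] to the output of
#' [simulate_nascent()] or an equivalent window-count table.
#'
#' @param windows data frame with `intron_id, intron_win_start,
#'   intron_win_end, exon_win_start, exon_win_end, intron_count,
#'   exon_count`.
#' @param lib_size library size.
#' @return `windows` with `efficiency` and `length` (full intron length
#'   when available, else window-derived) columns.
#' @export
splice_efficiency_table <- function(windows, lib_size = 1) {
  wi <- windows$intron_win_end - windows$intron_win_start
  we <- windows$exon_win_end - windows$exon_win_start
  windows$efficiency <- splicing_efficiency(windows$intron_count,
                                            windows$exon_count, wi, we,
                                            lib_size)
  windows
}

#' Compare splicing efficiency between two intron groups, binned by length
#'
#' Introns are binned by length (log-spaced edges by default); per bin the
#' group medians and a one-tailed Welch two-sample t-test are reported.
#'
#' @param records data frame with `efficiency`, `length`, `group` (exactly
#'   two groups; the first level is the reference "A").
#' @param bins numeric vector of bin edges, or `NULL` for five log-spaced
#'   bins over the observed length range.
#' @param alternative passed to [stats::t.test()]; the default `"less"`
#'   tests whether group B efficiencies are lower than group A's.
#' @return data frame per bin: group sizes, medians, difference and
#'   p-value (`NA` for underpopulated bins).
#' @export
compare_splice_eff <- function(records, bins = NULL, alternative = "less") {
  groups <- if (is.factor(records$group)) levels(records$group)
            else sort(unique(records$group))
  if (length(groups) != 2L) stop("exactly two groups required")
  if (is.null(bins)) {
    rng <- range(records$length)
    bins <- exp(seq(log(rng[1] * 0.999), log(rng[2] * 1.001),
                    length.out = 6L))
  }
  records$bin <- cut(records$length, bins, include.lowest = TRUE)
  out <- lapply(levels(records$bin), function(b) {
    a <- records$efficiency[records$bin == b & records$group == groups[1]]
    bb <- records$efficiency[records$bin == b & records$group == groups[2]]
    a <- a[!is.na(a)]; bb <- bb[!is.na(bb)]
    p <- if (length(a) >= 2L && length(bb) >= 2L) {
      t.test(bb, a, alternative = alternative)$p.value
    } else NA_real_
    data.frame(bin = b, n_A = length(a), n_B = length(bb),
               median_A = if (length(a)) median(a) else NA_real_,
               median_B = if (length(bb)) median(bb) else NA_real_,
               delta = (if (length(bb)) median(bb) else NA_real_) -
                 (if (length(a)) median(a) else NA_real_),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
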