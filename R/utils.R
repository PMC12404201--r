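# Shared low-level helpers. All coordinates 0-based half-open unless noted.

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GATTACA")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round half up; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

# Extract genome[chrom][start, end) from a named character vector genome.
# Errors on unknown chromosome or out-of-bounds coordinates.
get_seq <- function(genome, chrom, start, end) {
  if (!all(chrom %in% names(genome))) {
    stop("unknown chromosome: ", paste(setdiff(chrom, names(genome)), collapse = ", "))
  }
  n <- nchar(genome[chrom])
  if (any(start < 0) || any(end > n) || any(start > end)) {
    stop("coordinates outside chromosome bounds")
  }
  unname(substr(genome[chrom], start + 1L, end))
}

# In-place substring replacement in a genome sequence (0-based half-open).
set_seq <- function(genome, chrom, start, replacement) {
  substr(genome[[chrom]], start + 1L, start + nchar(replacement)) <- replacement
  genome
}

# Canonical splice-signal check for a back-splice junction (start = acceptor,
# end = donor; 0-based half-open). The GT (donor) / AG (acceptor) dinucleotides
# are read on the transcribed strand of the adjoining introns: on '-' the
# genomic forward sequence carries their reverse complements.
is_canonical_bsj <- function(genome, chrom, start, end, strand) {
  n <- length(start)
  ok <- logical(n)
  for (i in seq_len(n)) {
    len <- nchar(genome[[chrom[i]]])
    if (start[i] < 2L || end[i] + 2L > len) {
      ok[i] <- FALSE
      next
    }
    left <- get_seq(genome, chrom[i], start[i] - 2L, start[i])
    right <- get_seq(genome, chrom[i], end[i], end[i] + 2L)
    ok[i] <- if (strand[i] == "+") {
      left == "AG" && right == "GT"
    } else {
      left == "AC" && right == "CT"
    }
  }
  ok
}

# sample() without its length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}

# draw one integer uniformly from an inclusive range c(lo, hi)
draw_range <- function(range, n = 1L) {
  if (length(range) == 1L) range <- c(range, range)
  as.integer(range[1] + floor(runif(n) * (range[2] - range[1] + 1L)))
}

check_range <- function(x, name) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2] || x[1] <= 0) {
    stop("invalid range for ", name)
  }
  x
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a fraction in [0,1]")
  }
  x
}

# split comma-joined id strings, dropping empties
split_ids <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
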