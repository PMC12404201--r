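# I/O boundaries. Internal coordinates are 0-based half-open; GTF is
# written/read 1-based inclusive and BED 0-based half-open.

#' Write a genome to FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene models as GTF
#'
#' Emits gene, transcript and exon features with
#' `gene_biotype "protein_coding"`, converting to 1-based inclusive
#' coordinates. Output is deterministic (byte-identical for identical
#' input).
#'
#' @param genes,exons annotation tables (0-based half-open).
#' @param path output path.
#' @export
write_gtf <- function(genes, exons, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf(
      '%s\tcircflow\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
      if ("biotype" %in% names(g)) g$biotype else "protein_coding"))
    gex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (tx in unique(gex$transcript_id)) {
      te <- gex[gex$transcript_id == tx, , drop = FALSE]
      te <- te[order(te$start), ]
      lines <- c(lines, sprintf(
        '%s\tcircflow\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
        g$chrom, min(te$start) + 1L, max(te$end), g$strand, g$gene_id, tx,
        if ("biotype" %in% names(g)) g$biotype else "protein_coding"))
      lines <- c(lines, sprintf(
        '%s\tcircflow\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_number "%d"; gene_biotype "%s";',
        g$chrom, te$start + 1L, te$end, g$strand, g$gene_id, tx,
        seq_len(nrow(te)),
        if ("biotype" %in% names(g)) g$biotype else "protein_coding"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Uses rtracklayer and returns 0-based half-open tables.
#'
#' @param path GTF path.
#' @return list with `genes` and `exons` data frames.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  ex <- df[df$type == "exon", , drop = FALSE]
  exons <- data.frame(
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    chrom = as.character(ex$seqnames), strand = as.character(ex$strand),
    start = ex$start - 1L, end = ex$end, stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
  rownames(exons) <- NULL
  gn <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = gn$gene_id, chrom = as.character(gn$seqnames),
    strand = as.character(gn$strand), start = gn$start - 1L, end = gn$end,
    biotype = if ("gene_biotype" %in% names(gn)) gn$gene_biotype
              else "protein_coding",
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}

#' Write/read the split-read TSV format
#'
#' Columns: `read_id, chrom, strand, seg1_start, seg1_end, seg2_start,
#' seg2_end, cigar, junction_type` (0-based half-open; single-segment
#' reads leave segment 2 empty).
#'
#' @param reads split-read data frame.
#' @param path file path.
#' @export
write_reads_tsv <- function(reads, path) {
  cols <- c("read_id", "chrom", "strand", "seg1_start", "seg1_end",
            "seg2_start", "seg2_end", "cigar", "junction_type")
  write.table(reads[, intersect(cols, names(reads)), drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write an intron database as TSV (BED-like plus class columns)
#' @param introns intron table.
#' @param path file path.
#' @export
write_introns_tsv <- function(introns, path) {
  write.table(introns, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_introns_tsv
#' @export
read_introns_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if ("circ_ids" %in% names(x)) x$circ_ids[is.na(x$circ_ids)] <- ""
  x
}

#' Write/read a cross-link track as 6-column BED
#'
#' One-nt intervals with the count in the score column.
#'
#' @param track cross-link track (`chrom, strand, pos, count`).
#' @param path file path.
#' @export
write_crosslinks_bed <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\txl%d\t%d\t%s", track$chrom, track$pos,
                   track$pos + 1L, seq_len(nrow(track)), track$count,
                   track$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_crosslinks_bed
#' @export
read_crosslinks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             pos = GenomicRanges::start(gr) - 1L,
             count = as.integer(gr$score), stringsAsFactors = FALSE)
}

#' Write a simulation truth set to a directory
#'
#' Writes `genome.fa`, `annotation.gtf` and TSV truth tables
#' (`circrnas.tsv`, `rcm_pairs.tsv`, `decoys.tsv`).
#'
#' @param truth a planted `circflow_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_gtf(truth$genes, truth$exons, file.path(dir, "annotation.gtf"))
  for (nm in c("circrnas", "rcm_pairs", "decoys")) {
    if (!is.null(truth[[nm]])) {
      write.table(truth[[nm]], file.path(dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
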