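# Intron database construction, circRNA collapsing and flanking-intron
# assignment. Coordinates 0-based half-open; "within a 10 nt window" is read
# as distance <= 10 nt inclusive.

#' Build the intron database from gene models
#'
#' Restricts to protein-coding genes, drops a transcript's first/last exon
#' when its outer boundary differs from the gene-level outermost boundary
#' (alternative TSS/TES), optionally drops exons absent from an
#' expressed-exon whitelist, subtracts the union of retained exons from the
#' gene span, and discards resulting gaps shorter than `min_len` nt.
#' Classes are initialised to `other_gene`; use
#' [assign_flanking_introns()] to classify relative to circRNAs.
#'
#' @param exons data frame with `gene_id, transcript_id, chrom, strand,
#'   start, end` (0-based half-open).
#' @param genes optional data frame with `gene_id`, `biotype` and
#'   (optionally) `start`, `end` giving gene spans; when absent all genes
#'   are kept and spans are taken from the exon extent.
#' @param expressed_exons optional data frame with `chrom, start, end`;
#'   exons not matching a row exactly are discarded before subtraction.
#' @param min_len minimum intron length retained (nt).
#' @return data frame of introns: `intron_id, gene_id, chrom, strand,
#'   start, end, length, class, circ_ids`.
#' @export
build_intron_db <- function(exons, genes = NULL, expressed_exons = NULL,
                            min_len = 10L) {
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(exons))) stop("malformed annotation: missing columns")
  if (nrow(exons) == 0L) stop("malformed annotation: no exons")
  keep_genes <- unique(exons$gene_id)
  if (!is.null(genes) && "biotype" %in% names(genes)) {
    keep_genes <- intersect(keep_genes,
                            genes$gene_id[genes$biotype == "protein_coding"])
  }
  out <- list()
  for (gid in keep_genes) {
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    if (any(ex$end <= ex$start)) stop("malformed annotation: empty exon")
    gspan <- if (!is.null(genes) && all(c("start", "end") %in% names(genes)) &&
                 gid %in% genes$gene_id) {
      g <- genes[genes$gene_id == gid, ][1L, ]
      c(g$start, g$end)
    } else {
      c(min(ex$start), max(ex$end))
    }
    outer_start <- min(ex$start); outer_end <- max(ex$end)
    retained <- rep(TRUE, nrow(ex))
    for (tx in unique(ex$transcript_id)) {
      i <- which(ex$transcript_id == tx)
      if (length(i) < 1L) stop("malformed annotation: transcript without exons")
      first <- i[which.min(ex$start[i])]
      last <- i[which.max(ex$end[i])]
      if (ex$start[first] != outer_start) retained[first] <- FALSE
      if (ex$end[last] != outer_end) retained[last] <- FALSE
    }
    if (!is.null(expressed_exons)) {
      key <- paste(ex$chrom, ex$start, ex$end)
      wl <- paste(expressed_exons$chrom, expressed_exons$start,
                  expressed_exons$end)
      retained <- retained & key %in% wl
    }
    exk <- ex[retained, , drop = FALSE]
    if (nrow(exk) > 0L) {
      ex_ir <- IRanges::reduce(IRanges::IRanges(start = exk$start + 1L,
                                                end = exk$end))
      gaps <- IRanges::gaps(ex_ir, start = gspan[1] + 1L, end = gspan[2])
    } else {
      gaps <- IRanges::IRanges(start = gspan[1] + 1L, end = gspan[2])
    }
    if (length(gaps) == 0L) next
    gs <- IRanges::start(gaps) - 1L
    ge <- IRanges::end(gaps)
    len <- ge - gs
    keep <- len >= min_len
    if (!any(keep)) next
    gs <- gs[keep]; ge <- ge[keep]
    out[[gid]] <- data.frame(
      intron_id = sprintf("%s.I%02d", gid, seq_along(gs)),
      gene_id = gid, chrom = ex$chrom[1], strand = ex$strand[1],
      start = gs, end = ge, length = ge - gs,
      class = "other_gene", circ_ids = "", stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(intron_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      class = character(), circ_ids = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse circRNAs whose ends lie within a tolerance of each other
#'
#' Single-linkage clustering: two circRNAs on the same chromosome and strand
#' link when both their 5' (start) and 3' (end) coordinates differ by at
#' most `tol` nt. Clusters partition the input; the representative span is
#' the leftmost start / rightmost end over members.
#'
#' @param circs data frame with `circ_id, chrom, strand, start, end` and
#'   optionally `gene_id`.
#' @param tol linkage tolerance in nt (inclusive).
#' @return data frame of clusters: `cluster_id, chrom, strand, start, end,
#'   n_members, circ_ids, gene_ids`.
#' @export
collapse_circrnas <- function(circs, tol = 10L) {
  n <- nrow(circs)
  if (n == 0L) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      circ_ids = character(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (circs$chrom[i] == circs$chrom[j] &&
          circs$strand[i] == circs$strand[j] &&
          abs(circs$start[i] - circs$start[j]) <= tol &&
          abs(circs$end[i] - circs$end[j]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  ids <- split(seq_len(n), root)
  rows <- lapply(seq_along(ids), function(k) {
    m <- ids[[k]]
    data.frame(
      cluster_id = sprintf("CC%03d", k),
      chrom = circs$chrom[m[1]], strand = circs$strand[m[1]],
      start = min(circs$start[m]), end = max(circs$end[m]),
      n_members = length(m),
      circ_ids = paste(circs$circ_id[m], collapse = ","),
      gene_ids = if ("gene_id" %in% names(circs)) {
        paste(unique(circs$gene_id[m]), collapse = ",")
      } else "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Assign flanking/nonflanking classes to introns
#'
#' An intron whose end lies within `tol` nt of a cluster's 5' back-splice
#' boundary (genomic start) is transcription-upstream on `+` genes; one
#' whose start lies within `tol` of the 3' boundary (genomic end) is
#' downstream. On `-` strand the labels swap. Introns flanking on both
#' sides (single-intron circle geometry) get class `flank_both` and are
#' flagged. Remaining introns of circRNA-hosting genes are `nonflanking`;
#' introns of non-hosting genes are `other_gene`.
#'
#' @param introns intron table from [build_intron_db()].
#' @param clusters cluster table from [collapse_circrnas()].
#' @param tol assignment window in nt (inclusive).
#' @return the intron table with `class`, `circ_ids` and `flank_flag`
#'   columns filled.
#' @export
assign_flanking_introns <- function(introns, clusters, tol = 10L) {
  host_genes <- unique(unlist(split_ids(clusters$gene_ids)))
  introns$class <- ifelse(introns$gene_id %in% host_genes,
                          "nonflanking", "other_gene")
  introns$circ_ids <- ""
  introns$flank_flag <- FALSE
  if (nrow(clusters) == 0L || nrow(introns) == 0L) return(introns)
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    cl <- clusters[clusters$chrom == it$chrom & clusters$strand == it$strand, ,
                   drop = FALSE]
    if (nrow(cl) == 0L) next
    left_hit <- abs(it$end - cl$start) <= tol   # intron genomically left
    right_hit <- abs(it$start - cl$end) <= tol  # intron genomically right
    if (!any(left_hit | right_hit)) next
    # transcription-direction labels: '+' left = upstream; '-' swapped
    up_hit <- if (it$strand == "+") left_hit else right_hit
    down_hit <- if (it$strand == "+") right_hit else left_hit
    linked <- cl[left_hit | right_hit, , drop = FALSE]
    introns$circ_ids[i] <- paste(unique(unlist(split_ids(linked$circ_ids))),
                                 collapse = ",")
    if (any(up_hit) && any(down_hit)) {
      introns$class[i] <- "flank_both"
      introns$flank_flag[i] <- TRUE
    } else if (any(up_hit)) {
      introns$class[i] <- "flank_up"
    } else {
      introns$class[i] <- "flank_down"
    }
  }
  introns
}
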