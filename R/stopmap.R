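## Gene-level positional analyses at stop codons: per-gene cumulative
## distributions of read 3' ends in a 100-nt window, half-point ordering
## for the heatmap, and reading-frame analysis downstream of stop codons.

#' Select genes for the 3'-end CDF heatmap
#'
#' A gene passes iff it has at least `min_reads` reads with 3' ends inside
#' the window AND carries a single annotated stop codon across its isoforms
#' (multi-stop genes are removed to avoid misclassifying footprints
#' downstream of a stop codon).
#'
#' @param reads Deduplicated read-ends table (filter to the size class of
#'   interest, e.g. short 15-18 nt, before calling).
#' @param transcripts Transcript table (one row per gene, with
#'   `n_annotated_stops`).
#' @param min_reads Window read-count threshold (default 50).
#' @param window The 100-nt window centred on the stop codon, as stop-
#'   relative positions; default c(-50, 49), i.e. 100 positions with
#'   position 0 the stop codon's first nt.
#' @return Character vector of passing gene ids.
#' @export
select_heatmap_genes <- function(reads, transcripts, min_reads = 50,
                                 window = c(-50, 49)) {
  reads <- as.data.table(reads)
  tx <- as.data.table(transcripts)
  rr <- reads[gene_id %in% tx$gene_id]
  rr[, rel3 := to_stop_relative(rr, tx, anchor = "3p")]
  cnt <- rr[rel3 >= window[1] & rel3 <= window[2], .N, by = gene_id]
  ok <- cnt[N >= min_reads, gene_id]
  single <- tx[n_annotated_stops == 1L, gene_id]
  sort(intersect(ok, single))
}

#' Per-gene cumulative distribution of read 3' ends
#'
#' For each selected gene, `cdf(p)` is the fraction of in-window read 3'
#' ends at positions <= p; `half_point` is the smallest position with
#' cdf >= 0.5 ("the position at which 50% of all reads were at or
#' upstream").
#'
#' @param reads Deduplicated read-ends table.
#' @param transcripts Transcript table (one row per gene).
#' @param genes Gene ids (typically from [select_heatmap_genes()]).
#' @param window Stop-relative window; default c(-50, 49).
#' @return A classed list (`nmd_cdfs`) with `cdf` (gene x position matrix),
#'   `half_point` (data.table gene_id, half_point, n_reads) and `window`.
#' @export
gene_cdf <- function(reads, transcripts, genes, window = c(-50, 49)) {
  reads <- as.data.table(reads)
  tx <- as.data.table(transcripts)
  rr <- reads[gene_id %in% genes]
  rr[, rel3 := to_stop_relative(rr, tx, anchor = "3p")]
  rr <- rr[rel3 >= window[1] & rel3 <= window[2]]
  if (!all(genes %in% rr$gene_id))
    stop("gene(s) with zero in-window reads: ",
         paste(setdiff(genes, rr$gene_id), collapse = ", "))
  positions <- seq(window[1], window[2])
  cnt <- rr[, .N, by = .(gene_id, rel3)]
  m <- matrix(0, nrow = length(genes), ncol = length(positions),
              dimnames = list(genes, positions))
  m[cbind(match(cnt$gene_id, genes), match(cnt$rel3, positions))] <- cnt$N
  n_reads <- rowSums(m)
  cdf <- t(apply(m, 1, cumsum)) / n_reads
  hp <- apply(cdf, 1, function(row) positions[which(row >= 0.5)[1]])
  structure(list(cdf = cdf,
                 half_point = data.table(gene_id = genes,
                                         half_point = as.integer(hp),
                                         n_reads = as.integer(n_reads)),
                 window = as.integer(window)),
            class = "nmd_cdfs")
}

#' Order genes by CDF half-point
#'
#' Ascending half-point (the position at which 50% of reads are at or
#' upstream); ties broken lexicographically by gene id so the ordering is
#' deterministic.
#'
#' @param cdfs From [gene_cdf()].
#' @return Character vector of gene ids in heatmap order.
#' @export
order_genes <- function(cdfs) {
  stopifnot(inherits(cdfs, "nmd_cdfs"))
  hp <- copy(cdfs$half_point)
  setorder(hp, half_point, gene_id)
  hp$gene_id
}

#' Reading-frame fractions of reads downstream of the stop codon
#'
#' Restricts to reads whose 3' end lies strictly downstream of the stop
#' codon (relative position > 2) and computes the fraction in each frame
#' {0, +1, +2}, where frame is the 5'-end offset modulo 3 relative to the
#' CDS reading frame (frame 0 = in-frame with the CDS).
#'
#' @param reads Deduplicated read-ends table (filter to a size class
#'   first if desired).
#' @param transcripts Transcript table (one row per gene).
#' @return A `data.table` with columns frame (0,1,2), fraction, n. With no
#'   downstream reads, fractions are NA and n = 0 (flagged, not an error).
#' @export
frame_fractions <- function(reads, transcripts) {
  reads <- as.data.table(reads)
  tx <- as.data.table(transcripts)
  rr <- reads[gene_id %in% tx$gene_id]
  rr[, rel3 := to_stop_relative(rr, tx, anchor = "3p")]
  rr <- rr[rel3 > 2L]
  if (!nrow(rr))
    return(data.table(frame = 0:2, fraction = NA_real_, n = 0L))
  cds0 <- setNames(tx$cds_start, tx$gene_id)
  fr <- (rr$end5 - cds0[rr$gene_id]) %% 3L
  tab <- tabulate(fr + 1L, nbins = 3L)
  data.table(frame = 0:2, fraction = tab / sum(tab), n = as.integer(tab))
}

#' Write the CDF heatmap matrix and half-point table
#'
#' `<prefix>_cdf.tsv` holds the per-gene CDF rows in heatmap order;
#' `<prefix>_half_point.tsv` the ordering table.
#'
#' @param cdfs From [gene_cdf()].
#' @param prefix Output path prefix.
#' @param meta Named character vector of header metadata.
#' @export
write_cdf_heatmap <- function(cdfs, prefix, meta = NULL) {
  ord <- order_genes(cdfs)
  m <- cdfs$cdf[ord, , drop = FALSE]
  dt <- cbind(data.table(gene_id = rownames(m)), as.data.table(m))
  meta <- c(meta, window = paste(cdfs$window, collapse = ".."))
  write_read_ends(dt, paste0(prefix, "_cdf.tsv"), meta = meta)
  hp <- copy(cdfs$half_point)
  hp <- hp[match(ord, gene_id)]
  write_read_ends(hp, paste0(prefix, "_half_point.tsv"), meta = meta)
  invisible(c(paste0(prefix, "_cdf.tsv"), paste0(prefix, "_half_point.tsv")))
}
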