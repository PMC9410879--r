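## Stop-codon-anchored metagene profiles of normalised read density.

#' Per-gene normalised read density
#'
#' Divides per-position counts by the gene's length-normalised CDS read
#' count (`cds_total / cds_length`), so a gene with perfectly uniform
#' coverage has density 1.0 at every position and differently expressed
#' genes contribute on a common scale.
#'
#' @param counts Numeric vector of per-position read counts.
#' @param cds_total Total read count inside the gene's CDS.
#' @param cds_length CDS length in nt.
#' @return Numeric vector of normalised densities.
#' @export
gene_density <- function(counts, cds_total, cds_length) {
  stopifnot(cds_length > 0)
  if (cds_total <= 0) stop("cds_total must be positive (exclude the gene)")
  counts / (cds_total / cds_length)
}

#' Stop-codon metagene profile
#'
#' Averages per-gene normalised densities ([gene_density()]) across genes
#' at each stop-codon-relative position. Normalisation denominators use
#' CDS-contained counts of `norm_reads` (default: all reads supplied, any
#' size class), while the numerator counts only `size_class` reads at the
#' chosen anchor. Genes whose transcript does not span the full window
#' contribute only at covered positions; the mean at each position is over
#' genes covering it.
#'
#' @param reads Deduplicated read-ends table.
#' @param transcripts Transcript table (one row per gene).
#' @param size_class "short", "mid", "long", "other" or "all".
#' @param anchor Read end used for positioning: "3p" or "5p".
#' @param window Integer c(lo, hi) of stop-relative positions.
#' @param gene_set Optional character vector restricting genes; its name
#'   (deparsed or via `gene_set_label`) is carried in the output.
#' @param gene_set_label Label stored in the output.
#' @param min_reads Minimum CDS read count for a gene to be included.
#' @param norm_reads Optional read table used only for the normalisation
#'   denominator (defaults to `reads`).
#' @return A `data.table` (class `MetageneProfile`) with columns position,
#'   density, n_genes, size_class, gene_set, anchor.
#' @export
metagene <- function(reads, transcripts, size_class = "short",
                     anchor = c("3p", "5p"), window = c(-50, 50),
                     gene_set = NULL, gene_set_label = NULL,
                     min_reads = 5, norm_reads = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(length(window) == 2, window[1] <= window[2])
  reads <- as.data.table(reads)
  tx <- as.data.table(transcripts)
  if (is.null(norm_reads)) norm_reads <- reads
  norm_reads <- as.data.table(norm_reads)
  label <- if (!is.null(gene_set_label)) gene_set_label
           else if (is.null(gene_set)) "all" else "subset"
  if (!is.null(gene_set)) {
    tx <- tx[gene_id %in% gene_set]
    if (!nrow(tx)) stop("empty gene set: ", label)
  }

  # denominator: reads anchored inside the CDS, any position
  nr <- copy(norm_reads)[gene_id %in% tx$gene_id]
  nr[, pos := if (anchor == "3p") end3 else end5]
  nr <- merge(nr, tx[, .(gene_id, cds_start, cds_length, stop_codon_pos,
                         spliced_length)],
              by = "gene_id")
  cds_tot <- nr[pos >= cds_start & pos <= cds_start + cds_length - 1L,
                .(cds_total = .N), by = gene_id]
  keep <- merge(tx, cds_tot, by = "gene_id")[cds_total >= min_reads]
  if (!nrow(keep)) stop("no gene passes the min_reads filter (set: ",
                        label, ")")

  sel <- reads[gene_id %in% keep$gene_id]
  if (size_class != "all") {
    sc <- size_class
    sel <- sel[sel$size_class == sc]
  }
  sel[, rel := to_stop_relative(sel, keep, anchor = anchor)]
  sel <- sel[rel >= window[1] & rel <= window[2]]
  cnt <- sel[, .N, by = .(gene_id, rel)]

  positions <- seq(window[1], window[2])
  # per-gene covered relative range (transcript bounds)
  cov <- keep[, .(gene_id,
                  lo = pmax(window[1], -stop_codon_pos),
                  hi = pmin(window[2], spliced_length - 1L - stop_codon_pos),
                  cds_total, cds_length)]
  grid <- cov[, .(rel = seq(lo, hi)), by = .(gene_id, cds_total, cds_length)]
  grid <- merge(grid, cnt, by = c("gene_id", "rel"), all.x = TRUE)
  grid[is.na(N), N := 0L]
  grid[, density := N / (cds_total / cds_length)]
  prof <- grid[, .(density = mean(density), n_genes = .N), by = rel]
  out <- data.table(position = positions)
  out <- merge(out, prof, by.x = "position", by.y = "rel", all.x = TRUE)
  out[is.na(n_genes), `:=`(density = NA_real_, n_genes = 0L)]
  out[, `:=`(size_class = size_class, gene_set = label, anchor = anchor)]
  setattr(out, "class", c("MetageneProfile", class(out)))
  out[]
}

#' Write a metagene profile as TSV
#'
#' @param profile From [metagene()].
#' @param path Output path.
#' @param meta Named character vector of `# key: value` header lines.
#' @export
write_metagene <- function(profile, path, meta = NULL) {
  write_read_ends(profile, path, meta = meta)
}
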