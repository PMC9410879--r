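library(data.table)

# Write a GFF3 fixture; `rows` is a list of character vectors
# (seqid, source, type, start, end, score, strand, phase, attributes).
write_gff3_fixture <- function(rows, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

gff_row <- function(type, start, end, strand, id, parent = NULL) {
  attrs <- paste0("ID=", id)
  if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
  c("chrI", "test", type, start, end, ".", strand,
    if (type == "CDS") "0" else ".", attrs)
}

# Single-exon gene: exon spans [tx_start, tx_end], CDS [cds_start, cds_end]
# (all 1-based inclusive genomic).
single_tx_gff3 <- function(tx_start, tx_end, cds_start, cds_end,
                           strand = "+", gene = "geneA", tx = "geneA.t1") {
  write_gff3_fixture(list(
    gff_row("gene", tx_start, tx_end, strand, gene),
    gff_row("mRNA", tx_start, tx_end, strand, tx, gene),
    gff_row("exon", tx_start, tx_end, strand, paste0(tx, ".e1"), tx),
    gff_row("CDS", cds_start, cds_end, strand, paste0(tx, ".c1"), tx)
  ))
}

# Minimal transcript table for analyses that do not need annotation files.
tiny_transcripts <- function(gene_id, stop_codon_pos, spliced_length,
                             cds_start = 0L, cds_length = NULL,
                             n_annotated_stops = 1L) {
  if (is.null(cds_length)) cds_length <- stop_codon_pos - cds_start + 3L
  data.table(gene_id = gene_id,
             transcript_id = paste0(gene_id, ".1"),
             strand = "+",
             spliced_length = as.integer(spliced_length),
             cds_start = as.integer(cds_start),
             cds_length = as.integer(cds_length),
             stop_codon_pos = as.integer(stop_codon_pos),
             n_annotated_stops = as.integer(n_annotated_stops))
}

# Read table shorthand: positions given stop-relative for `tx` row 1.
rel_reads <- function(tx, rel5, length, gene_id = tx$gene_id[1], ...) {
  stop0 <- tx$stop_codon_pos[match(gene_id, tx$gene_id)]
  read_ends_table(gene_id, stop0 + rel5, length, ...)
}
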