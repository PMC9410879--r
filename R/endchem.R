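## 3'-end chemistry and base-composition analyses.
##
## The +/-PNK 3' RACE pair distinguishes nuclease chemistries: fragments
## with a 3' hydroxyl (left by metal-dependent nucleases such as SMG-6 and
## the exosome) ligate in both protocols, whereas 3'-phosphate ends (left
## by metal-independent nucleases such as IRE-1) require the PNK
## phosphatase treatment and appear only in the +PNK library.

#' Compare +/-PNK libraries at candidate cleavage sites
#'
#' For each site, counts reads whose 3' end falls on the site in the -PNK
#' (3'OH-only) and +PNK (3'OH + 3'P) libraries, normalises by library depth
#' (total deduplicated reads, a counts-per-million-equivalent), and calls
#' the site's chemistry from the depth-normalised ratio
#' `(count_oh/depth_oh) / (count_ohp/depth_ohp)`: OH-dominant at >= 0.5,
#' P-dominant at <= 0.25, otherwise indeterminate. Sites with fewer than
#' `min_site_reads` combined reads are always indeterminate. The default
#' thresholds are heuristics chosen to separate pure-OH from pure-P
#' regimes with margin; they are not taken from any measured dataset.
#'
#' @param oh_reads -PNK library read-ends table (deduplicated).
#' @param ohp_reads +PNK library read-ends table (deduplicated).
#' @param sites Optional `data.frame(gene_id, end3)` of candidate sites in
#'   transcript coordinates; if NULL, sites are discovered as 3'-end
#'   positions with at least `min_site_reads` reads in the +PNK library.
#' @param min_site_reads Minimum combined reads for a confident call.
#' @param oh_threshold,p_threshold Ratio thresholds for the call.
#' @return A `data.table` (one row per site): gene_id, end3, count_oh,
#'   count_ohp, ratio, call.
#' @export
compare_libraries <- function(oh_reads, ohp_reads, sites = NULL,
                              min_site_reads = 10,
                              oh_threshold = 0.5, p_threshold = 0.25) {
  oh <- as.data.table(oh_reads)
  ohp <- as.data.table(ohp_reads)
  depth_oh <- nrow(oh)
  depth_ohp <- nrow(ohp)
  if (depth_oh == 0 || depth_ohp == 0)
    stop("zero total depth in one of the libraries")
  if (is.null(sites)) {
    sites <- ohp[, .N, by = .(gene_id, end3)][N >= min_site_reads,
                                              .(gene_id, end3)]
  }
  sites <- as.data.table(sites)[, .(gene_id, end3)]
  c_oh <- oh[, .(count_oh = .N), by = .(gene_id, end3)]
  c_ohp <- ohp[, .(count_ohp = .N), by = .(gene_id, end3)]
  out <- merge(sites, c_oh, by = c("gene_id", "end3"), all.x = TRUE)
  out <- merge(out, c_ohp, by = c("gene_id", "end3"), all.x = TRUE)
  out[is.na(count_oh), count_oh := 0L]
  out[is.na(count_ohp), count_ohp := 0L]
  out[, ratio := (count_oh / depth_oh) / (count_ohp / depth_ohp)]
  out[count_ohp == 0, ratio := Inf]
  out[, call := fifelse(ratio >= oh_threshold, "OH-dominant",
                        fifelse(ratio <= p_threshold, "P-dominant",
                                "indeterminate"))]
  out[count_oh + count_ohp < min_site_reads, call := "indeterminate"]
  setorder(out, gene_id, end3)
  out[]
}

#' Nucleotide composition at read 3' ends near stop codons
#'
#' Frequencies of A/C/G/T at the transcript position of each read's 3' end,
#' restricted to reads whose 3' end is within `max_distance` nt of the stop
#' codon (first nt). An exosome stalled preferentially at guanosines leaves
#' an excess of 3'-terminal G relative to the local base content.
#'
#' @param reads Deduplicated read-ends table.
#' @param transcripts Transcript table (one row per gene).
#' @param sequences Named character vector (or `DNAStringSet`) of spliced
#'   transcript sequences, named by gene_id or transcript_id.
#' @param max_distance Maximum |3'-end - stop| distance in nt (default 10).
#' @return A `data.table` with columns base (A,C,G,T), frequency, n. Reads
#'   whose end falls outside the available sequence are skipped (count
#'   reported via attribute `n_skipped`).
#' @export
end_base_composition <- function(reads, transcripts, sequences,
                                 max_distance = 10) {
  reads <- as.data.table(reads)
  tx <- as.data.table(transcripts)
  if (inherits(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  # accept sequences named by transcript_id as well as gene_id
  nm <- names(sequences)
  if (!all(tx$gene_id %in% nm) && all(tx$transcript_id %in% nm))
    names(sequences) <- tx$gene_id[match(nm, tx$transcript_id)]
  rr <- reads[gene_id %in% tx$gene_id]
  rr[, rel3 := to_stop_relative(rr, tx, anchor = "3p")]
  rr <- rr[abs(rel3) <= max_distance]
  seqlen <- nchar(sequences)[rr$gene_id]
  skip <- rr$end3 < 0 | rr$end3 >= seqlen | is.na(seqlen)
  n_skipped <- sum(skip)
  rr <- rr[!skip]
  bases <- substr(sequences[rr$gene_id], rr$end3 + 1L, rr$end3 + 1L)
  tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
  out <- data.table(base = c("A", "C", "G", "T"),
                    frequency = if (sum(tab) > 0) as.numeric(tab / sum(tab))
                                else NA_real_,
                    n = as.integer(tab))
  setattr(out, "n_skipped", n_skipped)
  out[]
}

#' Positional base content of the transcriptome near stop codons
#'
#' Background base frequencies over the same stop-relative positions used
#' by [end_base_composition()], for contrast with observed 3'-end
#' composition.
#'
#' @inheritParams end_base_composition
#' @return A `data.table` with columns base, frequency.
#' @export
background_base_composition <- function(transcripts, sequences,
                                        max_distance = 10) {
  tx <- as.data.table(transcripts)
  if (inherits(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  nm <- names(sequences)
  if (!all(tx$gene_id %in% nm) && all(tx$transcript_id %in% nm))
    names(sequences) <- tx$gene_id[match(nm, tx$transcript_id)]
  pieces <- vapply(seq_len(nrow(tx)), function(i) {
    s <- sequences[[tx$gene_id[i]]]
    lo <- max(0L, tx$stop_codon_pos[i] - max_distance)
    hi <- min(nchar(s) - 1L, tx$stop_codon_pos[i] + max_distance)
    substr(s, lo + 1L, hi + 1L)
  }, character(1))
  bases <- strsplit(paste(pieces, collapse = ""), "")[[1]]
  tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
  data.table(base = c("A", "C", "G", "T"),
             frequency = as.numeric(tab / sum(tab)))
}
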