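## Transcript models, read records and stop-codon-relative coordinates.
##
## Conventions used throughout the package:
##   * transcript-space positions are 0-based; position 0 is the first nt of
##     the spliced transcript (5' end), irrespective of genomic strand;
##   * a read occupies [end5, end3] inclusive, length = end3 - end5 + 1;
##   * relative position 0 is the FIRST nt of the annotated stop codon, so
##     the stop codon occupies relative positions 0, 1, 2;
##   * annotation files are GFF3/GTF with the usual 1-based inclusive
##     coordinates; CDS features are assumed to include the stop codon
##     (Ensembl GFF3 convention).

#' Ribo-seq footprint size classes
#'
#' Classify footprint lengths into the three gel-size-selected classes used
#' for ribosome-state profiling: 15-18 nt ("short", ribosomes stalled on
#' truncated mRNA 3' ends), 19-26 nt ("mid", which contains the predicted
#' 25/22/19 nt decay intermediates), 28-30 nt ("long", elongating
#' ribosomes). Anything else (including 27 nt) is "other".
#'
#' @param length Integer vector of read lengths in nt.
#' @return Character vector with values "short", "mid", "long" or "other".
#' @examples
#' classify_size(c(15, 18, 21, 27, 28, 30, 31))
#' @export
classify_size <- function(length) {
  stopifnot(is.numeric(length), all(length >= 1))
  out <- rep("other", length(length))
  out[length >= 15 & length <= 18] <- "short"
  out[length >= 19 & length <= 26] <- "mid"
  out[length >= 28 & length <= 30] <- "long"
  out
}

#' Build a read-ends table
#'
#' Canonical tabular form of deduplicated footprints / 3' RACE fragments:
#' one row per read with transcript-space end coordinates. `size_class` is
#' always recomputed from `length` and `end3` from `end5 + length - 1`.
#'
#' @param gene_id,end5,length Character / integer vectors (recycled by
#'   data.table rules).
#' @param chemistry 3' end chemistry: "OH", "P" or "unknown".
#' @param umi Unique molecular identifier string ("" if absent).
#' @return A `data.table` with columns gene_id, end5, end3, length,
#'   size_class, chemistry, umi.
#' @export
read_ends_table <- function(gene_id, end5, length, chemistry = "unknown",
                            umi = "") {
  stopifnot(all(length >= 1), all(end5 >= 0))
  dt <- data.table(
    gene_id = as.character(gene_id),
    end5 = as.integer(end5),
    length = as.integer(length),
    chemistry = as.character(chemistry),
    umi = as.character(umi)
  )
  dt[, end3 := end5 + length - 1L]
  dt[, size_class := classify_size(length)]
  setcolorder(dt, c("gene_id", "end5", "end3", "length", "size_class",
                    "chemistry", "umi"))
  dt[]
}

#' Collapse PCR duplicates by UMI
#'
#' Reads identical in (gene_id, end5, length, umi) are collapsed to a single
#' record; collapse is exact-match on the UMI string (no mismatch
#' tolerance). Output is sorted by gene, end5, length, umi so repeated runs
#' are byte-identical. Records with an empty UMI are retained as their own
#' class with a warning.
#'
#' @param reads A read-ends table (see [read_ends_table()]).
#' @return Deduplicated read-ends table.
#' @export
collapse_umis <- function(reads) {
  stopifnot(is.data.frame(reads))
  reads <- as.data.table(reads)
  if (any(!nzchar(reads$umi))) {
    warning(sum(!nzchar(reads$umi)),
            " read(s) with empty UMI retained as singleton classes")
  }
  out <- unique(reads, by = c("gene_id", "end5", "length", "umi"))
  out <- copy(out)
  out[, end3 := end5 + length - 1L]
  out[, size_class := classify_size(length)]
  setorder(out, gene_id, end5, length, umi)
  out[]
}

#' Project a read end into stop-codon-relative coordinates
#'
#' @param reads Read-ends table.
#' @param transcripts Transcript table from [parse_annotation()] (one row
#'   per gene; see [canonical_transcripts()]).
#' @param anchor Which read end to anchor: "5p" or "3p".
#' @return Integer vector: (anchored end) - stop_codon_pos. 0 means the
#'   anchored end sits on the first nt of the stop codon; negative is
#'   upstream. Reads whose gene is absent from `transcripts` get NA.
#' @export
to_stop_relative <- function(reads, transcripts, anchor = c("3p", "5p")) {
  anchor <- match.arg(anchor)
  stopifnot(is.data.frame(reads), is.data.frame(transcripts))
  stop_pos <- setNames(as.integer(transcripts$stop_codon_pos),
                       transcripts$gene_id)
  end <- if (anchor == "3p") reads$end3 else reads$end5
  unname(as.integer(end) - stop_pos[reads$gene_id])
}

#' Reduce a transcript table to one representative isoform per gene
#'
#' Keeps, per gene, the transcript with the longest CDS (ties broken by
#' lexicographic transcript_id). `n_annotated_stops` (computed across all of
#' the gene's isoforms) is preserved, so multi-stop genes can still be
#' excluded downstream.
#'
#' @param transcripts Transcript table from [parse_annotation()].
#' @return Transcript table with one row per gene.
#' @export
canonical_transcripts <- function(transcripts) {
  tx <- as.data.table(transcripts)
  setorder(tx, gene_id, -cds_length, transcript_id)
  tx[, .SD[1L], by = gene_id]
}

#' Parse a GFF3/GTF annotation into transcript models
#'
#' Reads gene/mRNA/exon/CDS features through `rtracklayer` and builds one
#' transcript model per mRNA: exon segments ordered 5'->3' in transcript
#' orientation (minus-strand features flipped), the CDS projected into
#' transcript space, and the stop codon taken as the last 3 nt of the
#' spliced CDS (CDS includes the stop codon, as in Ensembl GFF3).
#' `n_annotated_stops` counts, per gene, the distinct genomic positions of
#' the stop codon's first nt across isoforms.
#'
#' @param path Path to a GFF3 (or GTF) file; gzip is handled transparently.
#' @return A `data.table` with one row per transcript: gene_id,
#'   transcript_id, strand, spliced_length, cds_start, cds_length,
#'   stop_codon_pos, stop_genomic, n_annotated_stops, and a list-column
#'   `cds_segments` of genomic (start, end) 1-based inclusive matrices
#'   ordered 5'->3'.
#' @export
parse_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ft <- as.data.table(as.data.frame(gr))
  if (!"type" %in% names(ft)) stop("annotation has no feature types")
  ft[, type := as.character(type)]

  first_chr <- function(x) {
    # Parent/ID columns come back as CharacterList from GFF3
    vapply(as.list(x), function(v)
      if (length(v)) as.character(v[[1]]) else NA_character_, character(1))
  }
  if ("Parent" %in% names(ft)) ft[, Parent := first_chr(Parent)]
  if ("ID" %in% names(ft)) ft[, ID := as.character(ID)]

  mrna <- ft[type %in% c("mRNA", "transcript")]
  if (!nrow(mrna)) stop("annotation contains no mRNA/transcript features")
  tx_gene <- setNames(mrna$Parent, mrna$ID)

  sub_feats <- ft[type %in% c("exon", "CDS")]
  orphan <- is.na(sub_feats$Parent) | !(sub_feats$Parent %in% mrna$ID)
  if (any(orphan)) {
    warning(sum(orphan), " exon/CDS feature(s) without a known mRNA parent",
            " were skipped")
    sub_feats <- sub_feats[!orphan]
  }

  build_one <- function(tid) {
    fx <- sub_feats[Parent == tid]
    ex <- fx[type == "exon"]
    cd <- fx[type == "CDS"]
    if (!nrow(ex)) ex <- cd  # CDS-only annotations
    if (!nrow(cd)) return(NULL)
    str <- as.character(ex$strand[1])
    setorder(ex, start)
    setorder(cd, start)
    if (any(head(ex$end, -1L) >= tail(ex$start, -1L)))
      stop("overlapping exons in transcript ", tid)
    # transcript-space offset of each exon's 5'-most nt
    widths <- ex$end - ex$start + 1L
    if (str == "-") {
      ex <- ex[rev(seq_len(nrow(ex)))]
      cd <- cd[rev(seq_len(nrow(cd)))]
      widths <- rev(widths)
    }
    offs <- cumsum(c(0L, head(widths, -1L)))
    g2t <- function(gpos) {
      # map genomic position (1-based) to transcript space (0-based)
      for (i in seq_len(nrow(ex))) {
        if (gpos >= ex$start[i] && gpos <= ex$end[i]) {
          return(if (str == "-") offs[i] + (ex$end[i] - gpos)
                 else offs[i] + (gpos - ex$start[i]))
        }
      }
      NA_integer_
    }
    cds_t5 <- g2t(if (str == "-") cd$end[1] else cd$start[1])
    g_last <- if (str == "-") cd$start[nrow(cd)] else cd$end[nrow(cd)]
    cds_t3 <- g2t(g_last)
    cds_len <- sum(cd$end - cd$start + 1L)
    # genomic position of the first nt of the stop codon (last 3 nt of CDS)
    stop_gen <- if (str == "-") g_last + 2L else g_last - 2L
    data.table(
      gene_id = tx_gene[[tid]], transcript_id = tid, strand = str,
      spliced_length = sum(widths),
      cds_start = as.integer(cds_t5),
      cds_length = as.integer(cds_len),
      stop_codon_pos = as.integer(cds_t3 - 2L),
      stop_genomic = as.integer(stop_gen),
      cds_segments = list(as.matrix(cd[, .(start, end)]))
    )
  }

  tx <- rbindlist(Filter(Negate(is.null), lapply(mrna$ID, build_one)))
  if (!nrow(tx)) stop("no transcript with CDS features found")
  tx[, n_annotated_stops := uniqueN(stop_genomic), by = gene_id]
  stopifnot(all(tx$stop_codon_pos >= 0),
            all(tx$stop_codon_pos <= tx$spliced_length - 3L))
  setorder(tx, gene_id, transcript_id)
  tx[]
}

#' Read / write the deduplicated read-ends table
#'
#' TSV with `#`-prefixed metadata header lines; `.gz` paths are handled
#' transparently.
#'
#' @param path File path.
#' @param x Read-ends table.
#' @param meta Named character vector written as `# key: value` lines.
#' @return `read_read_ends()` returns a read-ends `data.table`.
#' @export
read_read_ends <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body <- lines[!startsWith(lines, "#")]
  dt <- fread(text = paste(body, collapse = "\n"), sep = "\t",
              colClasses = list(character = c("gene_id", "chemistry", "umi")))
  dt[, `:=`(end5 = as.integer(end5), end3 = as.integer(end3),
            length = as.integer(length))]
  dt[]
}

#' @rdname read_read_ends
#' @export
write_read_ends <- function(x, path, meta = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", meta), con)
  hdr <- paste(names(x), collapse = "\t")
  body <- do.call(paste, c(as.list(as.data.frame(x)), sep = "\t"))
  writeLines(c(hdr, body), con)
  invisible(path)
}
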