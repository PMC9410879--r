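test_that("size classes follow the gel size-selection bounds", {
  expect_equal(classify_size(c(15, 16, 17, 18)), rep("short", 4))
  expect_equal(classify_size(c(19, 21, 26)), rep("mid", 3))
  expect_equal(classify_size(c(28, 29, 30)), rep("long", 3))
  expect_equal(classify_size(c(1, 14, 27, 31, 50)), rep("other", 5))
})

test_that("plus-strand CDS projects to transcript-space stop position", {
  # exon/CDS at genomic 100-199 (0-based) = 101..200 (1-based inclusive);
  # stop codon occupies the last 3 CDS nt, first nt at genomic 197 (0-based)
  path <- single_tx_gff3(101, 200, 101, 200, strand = "+")
  tx <- parse_annotation(path)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$spliced_length, 100L)
  expect_equal(tx$cds_start, 0L)
  expect_equal(tx$cds_length, 100L)
  expect_equal(tx$stop_codon_pos, 97L)
  expect_equal(tx$n_annotated_stops, 1L)
})

test_that("minus-strand transcripts flip to identical transcript space", {
  plus <- parse_annotation(single_tx_gff3(101, 200, 101, 200, "+"))
  minus <- parse_annotation(single_tx_gff3(101, 200, 101, 200, "-"))
  expect_equal(minus$stop_codon_pos, plus$stop_codon_pos)
  expect_equal(minus$spliced_length, plus$spliced_length)
  expect_equal(minus$cds_start, plus$cds_start)
})

test_that("multi-exon minus-strand CDS maps through spliced coordinates", {
  # two exons 101..150 and 201..260 on '-': transcript runs 260 -> 101,
  # spliced length 110; CDS = exon2 only (60 nt), so in transcript space
  # CDS occupies [0, 59] and the stop codon's first nt sits at 57
  path <- write_gff3_fixture(list(
    gff_row("gene", 101, 260, "-", "gB"),
    gff_row("mRNA", 101, 260, "-", "gB.t1", "gB"),
    gff_row("exon", 101, 150, "-", "gB.t1.e2", "gB.t1"),
    gff_row("exon", 201, 260, "-", "gB.t1.e1", "gB.t1"),
    gff_row("CDS", 201, 260, "-", "gB.t1.c1", "gB.t1")
  ))
  tx <- parse_annotation(path)
  expect_equal(tx$spliced_length, 110L)
  expect_equal(tx$cds_start, 0L)
  expect_equal(tx$stop_codon_pos, 57L)
})

test_that("isoforms ending at different genomic stops are counted per gene", {
  path <- write_gff3_fixture(list(
    gff_row("gene", 101, 400, "+", "gC"),
    gff_row("mRNA", 101, 300, "+", "gC.t1", "gC"),
    gff_row("exon", 101, 300, "+", "gC.t1.e1", "gC.t1"),
    gff_row("CDS", 101, 250, "+", "gC.t1.c1", "gC.t1"),
    gff_row("mRNA", 101, 400, "+", "gC.t2", "gC"),
    gff_row("exon", 101, 400, "+", "gC.t2.e1", "gC.t2"),
    gff_row("CDS", 101, 340, "+", "gC.t2.c1", "gC.t2")
  ))
  tx <- parse_annotation(path)
  expect_equal(nrow(tx), 2L)
  expect_equal(unique(tx$n_annotated_stops), 2L)
  # canonical reduction keeps the longer CDS and the multi-stop flag
  can <- canonical_transcripts(tx)
  expect_equal(nrow(can), 1L)
  expect_equal(can$transcript_id, "gC.t2")
  expect_equal(can$n_annotated_stops, 2L)
})

test_that("orphan CDS features are skipped with a warning", {
  path <- write_gff3_fixture(list(
    gff_row("gene", 101, 200, "+", "gD"),
    gff_row("mRNA", 101, 200, "+", "gD.t1", "gD"),
    gff_row("exon", 101, 200, "+", "gD.t1.e1", "gD.t1"),
    gff_row("CDS", 101, 200, "+", "gD.t1.c1", "gD.t1"),
    gff_row("CDS", 301, 400, "+", "orphan.c1", "no.such.mRNA")
  ))
  expect_warning(tx <- parse_annotation(path), "skipped")
  expect_equal(nrow(tx), 1L)
})

test_that("malformed annotation raises a parse error naming the file", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chrI\tonly\tthree"), bad)
  expect_error(parse_annotation(bad), "failed to parse annotation")
})

test_that("UMI collapse keeps one record per (gene, end5, length, umi)", {
  r <- read_ends_table(rep("g1", 2), c(10, 10), c(20, 20), umi = "ACGTAA")
  expect_equal(nrow(collapse_umis(r)), 1L)
  r2 <- read_ends_table(rep("g1", 2), c(10, 10), c(20, 20),
                        umi = c("ACGTAA", "ACGTAT"))
  expect_equal(nrow(collapse_umis(r2)), 2L)
  # 10 reads over 3 distinct keys
  keys <- data.table(end5 = c(5L, 5L, 9L), length = c(20L, 21L, 20L),
                     umi = c("AAAAAA", "AAAAAA", "CCCCCC"))
  picks <- keys[c(1, 1, 1, 2, 2, 3, 3, 3, 3, 3)]
  r3 <- read_ends_table("g1", picks$end5, picks$length, umi = picks$umi)
  expect_equal(nrow(collapse_umis(r3)), 3L)
})

test_that("UMI collapse is idempotent and deterministic in order", {
  set.seed(11)
  r <- read_ends_table("g1", sample(1:30, 200, TRUE), sample(15:30, 200, TRUE),
                       umi = sample(c("AC", "GT", "CA"), 200, TRUE))
  once <- collapse_umis(r)
  twice <- collapse_umis(once)
  expect_identical(once, twice)
  shuffled <- collapse_umis(r[sample(nrow(r))])
  expect_identical(once, shuffled)
})

test_that("empty UMIs are retained as singletons with a warning", {
  r <- read_ends_table(rep("g1", 3), c(10, 10, 10), c(20, 20, 20), umi = "")
  expect_warning(out <- collapse_umis(r), "empty UMI")
  expect_equal(nrow(out), 1L)  # identical empty-UMI keys still collapse
})

test_that("stop-relative projection anchors either read end", {
  tx <- tiny_transcripts("g1", stop_codon_pos = 100L, spliced_length = 200L)
  r <- read_ends_table("g1", end5 = c(83L, 85L, 100L),
                       length = c(18L, 18L, 21L))
  rel3 <- to_stop_relative(r, tx, anchor = "3p")
  rel5 <- to_stop_relative(r, tx, anchor = "5p")
  expect_equal(rel3, c(0L, 2L, 20L))   # 3' end on stop first / last nt
  expect_equal(rel5, c(-17L, -15L, 0L))  # 18-nt read ending at stop: 5p -17
  # anchor identity holds for arbitrary records
  set.seed(4)
  rr <- read_ends_table("g1", sample(0:150, 100, TRUE), sample(15:30, 100, TRUE))
  expect_equal(to_stop_relative(rr, tx, "3p") - to_stop_relative(rr, tx, "5p"),
               rr$length - 1L)
})

test_that("read-ends tables round-trip through TSV, gzip included", {
  set.seed(9)
  r <- read_ends_table(sample(c("g1", "g2"), 50, TRUE), sample(0:99, 50, TRUE),
                       sample(15:30, 50, TRUE),
                       chemistry = sample(c("OH", "P"), 50, TRUE),
                       umi = replicate(50, paste(sample(c("A", "C", "G", "T"),
                                                        6, TRUE), collapse = "")))
  for (ext in c(".tsv", ".tsv.gz")) {
    path <- tempfile(fileext = ext)
    write_read_ends(r, path, meta = c(seed = "9"))
    back <- read_read_ends(path)
    expect_equal(as.data.frame(back), as.data.frame(r))
  }
})
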