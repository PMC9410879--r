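test_that("protection geometry reproduces the footprint series", {
  cfg <- sim_config()
  expect_equal(footprint_length(10, cfg), 28L)  # full footprint
  expect_equal(footprint_length(7, cfg), 25L)   # intermediates step by codon
  expect_equal(footprint_length(4, cfg), 22L)
  expect_equal(footprint_length(1, cfg), 19L)
  expect_equal(footprint_length(0, cfg), 18L)   # stalled maximum
  expect_error(footprint_length(-1, cfg), "non-negative")
})

test_that("footprint_length is non-decreasing and clamps at full length", {
  cfg <- sim_config()
  lens <- footprint_length(0:40, cfg)
  expect_true(all(diff(lens) >= 0))
  expect_true(all(lens <= cfg$full_footprint))
  expect_equal(lens[11:41], rep(28L, 31))
  # codon-stepped distances give lengths differing by exactly 3
  expect_equal(diff(footprint_length(c(1, 4, 7), cfg)), c(3L, 3L))
  # human preset shifts the series up by 3 at the full-length end
  hcfg <- sim_config_human()
  expect_equal(footprint_length(13, hcfg), 31L)
  expect_equal(footprint_length(c(1, 4, 7, 10), hcfg), c(19L, 22L, 25L, 28L))
})

test_that("config validation enforces geometry and probability bounds", {
  expect_error(sim_config(full_footprint = 30), "geometry")
  expect_error(sim_config(cleavage_rate = 1.5), "probabilities")
  expect_error(sim_config(cds_length_range = c(40, 100)),
               "2x full_footprint")
})

test_that("a fixed seed makes the transcriptome byte-identical", {
  cfg <- sim_config(n_genes = 40, seed = 7)
  t1 <- simulate_transcriptome(cfg)
  t2 <- simulate_transcriptome(cfg)
  expect_identical(t1$transcripts, t2$transcripts)
  # CDS lengths in range and codon-multiple, stop codon canonical
  cl <- t1$transcripts$cds_length
  expect_true(all(cl >= 300 & cl <= 900))
  expect_true(all(cl %% 3 == 0))
  stops <- substr(t1$transcripts$sequence,
                  t1$transcripts$stop_codon_pos + 1L,
                  t1$transcripts$stop_codon_pos + 3L)
  expect_true(all(stops %in% c("TAA", "TGA", "TAG")))
})

test_that("uniform expression allocates reads near-equally at depth 1e5", {
  cfg <- sim_config(n_genes = 50, expression_law = "uniform", seed = 5,
                    pcr_duplicate_rate = 0)
  tr <- simulate_transcriptome(cfg)
  rd <- simulate_reads(tr, n_ribo = 1e5, n_race = 0)
  counts <- rd$ribo[, .N, by = gene_id]$N
  p <- 1 / 50
  sd_bin <- sqrt(1e5 * p * (1 - p))
  z <- abs(counts - 1e5 * p) / sd_bin
  expect_true(mean(z <= 3) >= 0.95)  # ~99.7% expected within 3 sd
})

test_that("direct A-site cleavage puts all short 3' ends in the stop codon", {
  cfg <- sim_config(n_genes = 20, model = "model1_Asite", cleavage_rate = 1,
                    ire1_rate = 0, pcr_duplicate_rate = 0, seed = 2)
  tr <- simulate_transcriptome(cfg)
  rd <- simulate_reads(tr, n_ribo = 2e4, n_race = 0)
  short <- rd$ribo[size_class == "short"]
  rel3 <- to_stop_relative(short, tr$transcripts, "3p")
  expect_gt(nrow(short), 0)
  expect_true(all(rel3 >= 0 & rel3 <= 2))
})

test_that("the endonuclease-null mode emits no short footprints outside the IRE-1-like site", {
  cfg <- sim_config(n_genes = 20, model = "none", cleavage_rate = 0,
                    pcr_duplicate_rate = 0, seed = 2)
  tr <- simulate_transcriptome(cfg)
  rd <- simulate_reads(tr, n_ribo = 2e4, n_race = 0)
  short <- rd$ribo[size_class == "short"]
  ire_gene <- tr$transcripts[!is.na(ire1_site), gene_id]
  expect_true(all(short$gene_id == ire_gene))
  site <- tr$transcripts[!is.na(ire1_site), ire1_site]
  expect_true(all(short$end3 == site))
})

test_that("the trimming automaton stalls at guanosines as designed", {
  # designed sequence: single G at stop-relative +4, cut at +8
  seq <- paste(rep("A", 60), collapse = "")
  stop0 <- 40L
  substr(seq, stop0 + 4 + 1, stop0 + 4 + 1) <- "G"
  e_all <- nmdtrace:::trim_ends(rep(8L, 50), seq, stop0, g_stall_prob = 1)
  expect_true(all(e_all == 4L))      # always stalls at the only G
  e_none <- nmdtrace:::trim_ends(rep(8L, 50), seq, stop0, g_stall_prob = 0)
  expect_true(all(e_none == 2L))     # runs to the ribosome boundary
  expect_equal(nmdtrace:::trim_ends(1L, seq, stop0, 1), 1L)  # below floor
})

test_that("captured intermediates share the 3' end and step 3 nt at the 5' end", {
  cfg <- sim_config(n_genes = 30, model = "model2_runon", cleavage_rate = 0.8,
                    intermediate_capture_prob = 0.2, ire1_rate = 0,
                    g_stall_prob = 0, pcr_duplicate_rate = 0, seed = 8)
  tr <- simulate_transcriptome(cfg)
  rd <- simulate_reads(tr, n_ribo = 3e4, n_race = 0)
  mids <- rd$ribo[length %in% c(19L, 22L, 25L)]
  expect_gt(nrow(mids), 100)
  rel3 <- to_stop_relative(mids, tr$transcripts, "3p")
  expect_true(all(rel3 >= 0 & rel3 <= 2))   # same (truncated) 3' ends
  expect_setequal(unique(mids$length), c(19L, 22L, 25L))
  # within one gene and one truncated end, 5' ends differ by multiples of 3
  one <- mids[rel3 == 0]
  one[, rel5 := to_stop_relative(one, tr$transcripts, "5p")]
  expect_true(all(one$rel5 %% 3 == (-18L) %% 3))
})

test_that("reads are seed-deterministic; chemistry only relabels libraries", {
  cfg <- sim_config(n_genes = 15, seed = 12)
  tr <- simulate_transcriptome(cfg)
  r1 <- simulate_reads(tr, n_ribo = 5e3, n_race = 2e3)
  r2 <- simulate_reads(tr, n_ribo = 5e3, n_race = 2e3)
  expect_identical(r1$ribo, r2$ribo)
  expect_identical(r1$race, r2$race)
  # all-OH chemistry: same fragment positions, different library membership
  cfg_oh <- sim_config(n_genes = 15, seed = 12,
                       chemistry_map = c(smg6 = "OH", exosome = "OH",
                                         ire1 = "OH"))
  tr_oh <- simulate_transcriptome(cfg_oh)
  r3 <- simulate_reads(tr_oh, n_ribo = 5e3, n_race = 2e3)
  expect_identical(r3$race[, .(gene_id, end5, end3, length, umi)],
                   r1$race[, .(gene_id, end5, end3, length, umi)])
  expect_equal(nrow(r3$race_minus_pnk), nrow(r3$race))
  expect_lt(nrow(r1$race_minus_pnk), nrow(r1$race))
})

test_that("simulated annotation and sequences round-trip through GFF3/FASTA", {
  cfg <- sim_config(n_genes = 8, seed = 21)
  tr <- simulate_transcriptome(cfg)
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  write_sim_gff3(tr, gff)
  write_sim_fasta(tr, fa)
  parsed <- canonical_transcripts(parse_annotation(gff))
  orig <- tr$transcripts
  expect_equal(parsed$gene_id, orig$gene_id)
  expect_equal(parsed$spliced_length, orig$spliced_length)
  expect_equal(parsed$cds_start, orig$cds_start)
  expect_equal(parsed$stop_codon_pos, orig$stop_codon_pos)
  expect_equal(parsed$n_annotated_stops, rep(1L, nrow(orig)))
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(seqs), orig$transcript_id)
  expect_equal(as.character(seqs), setNames(orig$sequence, orig$transcript_id))
  # the stop codon read out of the FASTA matches the annotation coordinate
  s1 <- as.character(seqs[[1]])
  expect_true(substr(s1, parsed$stop_codon_pos[1] + 1,
                     parsed$stop_codon_pos[1] + 3) %in% c("TAA", "TGA", "TAG"))
})
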