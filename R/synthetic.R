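## Mechanistic simulator of NMD decay intermediates.
##
## Two competing models for the short (15-18 nt) footprints that accumulate
## at premature stop codons:
##   model1_Asite  - the endonuclease cuts directly in the ribosomal A-site
##                   over the stop codon; the stalled ribosome's footprint 3'
##                   end falls within the stop codon.
##   model2_runon  - the endonuclease cuts downstream near the stop; the
##                   3'>5' exosome trims the fragment back (stalling at
##                   guanosines with probability g_stall_prob, and
##                   unconditionally at the boundary protected by the
##                   trailing ribosome); the trailing ribosome then runs on
##                   to the truncated end and stalls there. While it
##                   approaches, partially protected "intermediate"
##                   footprints (25/22/19 nt with default geometry) share
##                   the truncated 3' end and step 3 nt at the 5' end.
## model = "none" with cleavage_rate = 0 emulates an endonuclease-null
## (smg-6 PIN-dead) condition.

#' Simulation configuration
#'
#' Geometry, cleavage model, rates, chemistry and seed for the synthetic
#' generator. Defaults encode the study conditions: a 28-nt full footprint
#' with 10 nt protected between the A-site first nt and the mRNA entry
#' tunnel, stalled footprints of 15-18 nt, a cleavage-offset law
#' concentrated on the stop codon with a geometric downstream tail, and a
#' modest exosome guanosine-stall probability.
#'
#' @param n_genes Number of simulated genes.
#' @param cds_length_range CDS length bounds in nt (rounded to codons).
#' @param utr5_length,utr3_length Fixed UTR lengths in nt.
#' @param expression_law "uniform" or "lognormal".
#' @param lognormal_meanlog,lognormal_sdlog Log-normal expression params.
#' @param gc GC content of simulated sequences.
#' @param full_footprint Elongating footprint length (nt).
#' @param downstream_protect nt protected between the A-site first nt and
#'   the mRNA entry tunnel. Must satisfy
#'   `full_footprint == max(stalled_range) + downstream_protect`.
#' @param stalled_range Length bounds of stalled footprints (5' jitter from
#'   RNase digestion heterogeneity).
#' @param model "model1_Asite", "model2_runon" or "none".
#' @param cleavage_rate Probability an mRNA molecule is cleaved by the
#'   endonuclease.
#' @param cleavage_offset_law Law of the cut site (fragment 3'-end position
#'   relative to the stop codon's first nt): either
#'   `list(type="stop_geometric", p=0.5)` (mass 0.5 at 0 with a geometric
#'   downstream tail), `list(type="per_gene", offsets=<named int>, jitter=0)`
#'   (gene-specific offsets, uniform +/- jitter), or a `function(n, gene)`
#'   returning integer offsets.
#' @param g_stall_prob Probability the exosome halts at each guanosine it
#'   exposes while trimming 3'->5'.
#' @param intermediate_capture_prob Probability a cleaved molecule is
#'   captured as a pre-stall intermediate (ribosome still approaching the
#'   truncated end) rather than as the final stalled footprint.
#' @param readthrough_prob Probability the trailing ribosome bypasses the
#'   stop codon and elongates downstream.
#' @param readthrough_frame Reading frame of readthrough: 0 or -1.
#' @param frame_noise Probability a readthrough footprint's 5' end is
#'   displaced off-frame by 1 nt (digestion imprecision).
#' @param term_rate Fraction of intact-molecule footprints that are 21-nt
#'   empty-A-site termination footprints at the stop (emitted regardless of
#'   model).
#' @param ire1_rate Probability a molecule of the designated IRE-1-like
#'   gene is cleaved at its fixed internal site (endonuclease-independent;
#'   leaves a 3' phosphate).
#' @param chemistry_map Named map nuclease -> 3' end chemistry.
#' @param pcr_duplicate_rate Fraction of additional PCR-duplicate reads
#'   appended to each library (same UMI and coordinates).
#' @param umi_length_ribo,umi_length_race UMI randomer lengths.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A `SimulationConfig` (classed list).
#' @export
sim_config <- function(n_genes = 300,
                       cds_length_range = c(300, 900),
                       utr5_length = 30,
                       utr3_length = 150,
                       expression_law = c("lognormal", "uniform"),
                       lognormal_meanlog = 0, lognormal_sdlog = 1,
                       gc = 0.43,
                       full_footprint = 28,
                       downstream_protect = 10,
                       stalled_range = c(15, 18),
                       model = c("model2_runon", "model1_Asite", "none"),
                       cleavage_rate = 0.5,
                       cleavage_offset_law = list(type = "stop_geometric",
                                                  p = 0.5),
                       g_stall_prob = 0.3,
                       intermediate_capture_prob = 0.02,
                       readthrough_prob = 0,
                       readthrough_frame = 0,
                       frame_noise = 0.05,
                       term_rate = 0.05,
                       ire1_rate = 0.3,
                       chemistry_map = c(smg6 = "OH", exosome = "OH",
                                         ire1 = "P"),
                       pcr_duplicate_rate = 0.15,
                       umi_length_ribo = 8,
                       umi_length_race = 6,
                       seed = 1L) {
  expression_law <- match.arg(expression_law)
  model <- match.arg(model)
  cfg <- list(
    n_genes = as.integer(n_genes),
    cds_length_range = as.integer(cds_length_range),
    utr5_length = as.integer(utr5_length),
    utr3_length = as.integer(utr3_length),
    expression_law = expression_law,
    lognormal_meanlog = lognormal_meanlog,
    lognormal_sdlog = lognormal_sdlog,
    gc = gc,
    full_footprint = as.integer(full_footprint),
    downstream_protect = as.integer(downstream_protect),
    stalled_range = as.integer(stalled_range),
    model = model,
    cleavage_rate = cleavage_rate,
    cleavage_offset_law = cleavage_offset_law,
    g_stall_prob = g_stall_prob,
    intermediate_capture_prob = intermediate_capture_prob,
    readthrough_prob = readthrough_prob,
    readthrough_frame = as.integer(readthrough_frame),
    frame_noise = frame_noise,
    term_rate = term_rate,
    ire1_rate = ire1_rate,
    chemistry_map = chemistry_map,
    pcr_duplicate_rate = pcr_duplicate_rate,
    umi_length_ribo = as.integer(umi_length_ribo),
    umi_length_race = as.integer(umi_length_race),
    seed = as.integer(seed)
  )
  probs <- c(cleavage_rate, g_stall_prob, intermediate_capture_prob,
             readthrough_prob, frame_noise, term_rate, ire1_rate,
             pcr_duplicate_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]")
  if (cfg$full_footprint != max(cfg$stalled_range) + cfg$downstream_protect)
    stop("geometry inconsistent: full_footprint must equal ",
         "max(stalled_range) + downstream_protect")
  if (!cfg$readthrough_frame %in% c(0L, -1L))
    stop("readthrough_frame must be 0 or -1")
  if (cfg$cds_length_range[1] < 2L * cfg$full_footprint)
    stop("cds_length_range lower bound must be at least 2x full_footprint")
  structure(cfg, class = "SimulationConfig")
}

#' Human-geometry preset
#'
#' Mammalian ribosomes protect a slightly larger footprint; with a 31-nt
#' full footprint and the same 18-nt stalled maximum, the intermediate
#' series sits 3 nt upstream (at the 5' end) of the nematode series.
#'
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_human <- function(...) {
  sim_config(full_footprint = 31, downstream_protect = 13, ...)
}

#' Protected fragment length of a ribosome near a truncated 3' end
#'
#' A ribosome whose A-site first nt lies `a_site_to_end` nt upstream of the
#' fragment 3' end protects `min(full_footprint,
#' max(stalled_range) + a_site_to_end)` nt: the mRNA entry tunnel shields
#' the 3' end, so footprints shrink only at their 5' side as the ribosome
#' approaches the end. With default geometry distances >= 10 give 28 nt;
#' 7/4/1 give the intermediate 25/22/19 nt; 0 gives the stalled maximum of
#' 18 nt (downstream jitter to 15-18 is applied separately at emission).
#'
#' @param a_site_to_end Non-negative integer distance(s) in nt from the
#'   A-site first nt to the fragment 3' end.
#' @param config A [sim_config()].
#' @return Integer vector of protected fragment lengths (nt).
#' @export
footprint_length <- function(a_site_to_end, config = sim_config()) {
  if (any(a_site_to_end < 0))
    stop("a_site_to_end must be non-negative")
  pmin(config$full_footprint,
       max(config$stalled_range) + as.integer(a_site_to_end))
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_umis <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Simulate a transcriptome
#'
#' Generates `n_genes` single-isoform transcripts (5'UTR + CDS + 3'UTR) with
#' random sequences at the configured GC content, CDS lengths divisible by
#' 3 and ending in a canonical stop codon, and per-gene expression weights.
#' The first gene is designated "IRE-1-like": it carries a fixed internal
#' cleavage site (mid-CDS) whose fragments bear a 3' phosphate, providing
#' an endonuclease-independent control locus.
#'
#' @param config A [sim_config()].
#' @return A classed list with elements `transcripts` (transcript table with
#'   sequence, expression weight `wt` and `ire1_site` columns) and `config`.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  cds_len <- sample(seq(config$cds_length_range[1],
                        config$cds_length_range[2]), n, replace = TRUE)
  cds_len <- as.integer(3L * floor(cds_len / 3))
  spliced <- config$utr5_length + cds_len + config$utr3_length
  seqs <- vapply(spliced, rand_seq, character(1), gc = config$gc)
  # place a canonical stop codon as the last CDS codon
  stops <- sample(c("TAA", "TGA", "TAG"), n, replace = TRUE)
  stop_pos <- config$utr5_length + cds_len - 3L
  substr(seqs, stop_pos + 1L, stop_pos + 3L) <- stops
  wt <- switch(config$expression_law,
               uniform = rep(1, n),
               lognormal = rlnorm(n, config$lognormal_meanlog,
                                  config$lognormal_sdlog))
  tx <- data.table(
    gene_id = ids,
    transcript_id = paste0(ids, ".1"),
    strand = rep_len(c("+", "-"), n),
    spliced_length = as.integer(spliced),
    cds_start = config$utr5_length,
    cds_length = cds_len,
    stop_codon_pos = as.integer(stop_pos),
    n_annotated_stops = 1L,
    wt = wt / sum(wt),
    sequence = seqs,
    ire1_site = NA_integer_
  )
  # IRE-1-like control: fixed internal cleavage site mid-CDS (codon boundary)
  tx$ire1_site[1] <- as.integer(config$utr5_length +
                                  3L * floor(cds_len[1] / 6))
  structure(list(transcripts = tx, config = config),
            class = "nmd_transcriptome")
}

## Trimming automaton: from cut end3 `cut` (stop-relative), the exosome
## removes nucleotides 3'->5', halting at each exposed guanosine with
## probability g_stall_prob and unconditionally at the trailing-ribosome
## boundary (last nt of the stop codon, rel +2). Cuts at or upstream of the
## boundary are returned unchanged. Vectorised over reads of one gene.
trim_ends <- function(cut_rel, seq, stop_codon_pos, g_stall_prob,
                      floor_rel = 2L) {
  out <- cut_rel
  todo <- which(cut_rel > floor_rel)
  if (!length(todo) || g_stall_prob <= 0) {
    out[todo] <- floor_rel
    return(out)
  }
  bases <- strsplit(seq, "")[[1]]
  for (i in todo) {
    # positions exposed as new 3' ends, in trimming order
    p <- seq(cut_rel[i] - 1L, floor_rel)
    isg <- bases[stop_codon_pos + p + 1L] == "G"
    gpos <- p[isg]
    stalled <- gpos[runif(length(gpos)) < g_stall_prob]
    out[i] <- if (length(stalled)) stalled[1] else floor_rel
  }
  out
}

draw_offsets <- function(law, n, gene) {
  if (is.function(law)) return(as.integer(law(n, gene)))
  switch(law$type,
    stop_geometric = as.integer(rgeom(n, law$p)),
    per_gene = {
      off <- law$offsets[[gene]]
      if (is.null(off)) stop("no per-gene offset for ", gene)
      j <- if (is.null(law$jitter)) 0L else as.integer(law$jitter)
      as.integer(off + if (j > 0) sample(seq(-j, j), n, TRUE) else 0L)
    },
    stop("unknown cleavage_offset_law type: ", law$type)
  )
}

#' Simulate Ribo-seq and 3' RACE reads
#'
#' Emits reads gene-by-gene according to the configured cleavage model (see
#' the module header). Background elongating ribosomes yield 28-30 nt
#' footprints uniform over the CDS; terminating ribosomes yield 21-nt
#' empty-A-site footprints at the stop codon regardless of model. Cleaved
#' molecules yield stalled short footprints whose 3' end is the (possibly
#' exosome-trimmed) fragment end, pre-stall intermediates with probability
#' `intermediate_capture_prob`, and, with `readthrough_prob`, frame-locked
#' elongating footprints downstream of the stop. 3' RACE fragments mirror
#' the fragment 3' ends with their nuclease's chemistry; intact molecules
#' contribute their mature 3' end. Cut sites falling beyond the transcript
#' end are resampled (count reported via attribute `n_resampled`).
#'
#' @param transcriptome From [simulate_transcriptome()].
#' @param n_ribo,n_race Total Ribo-seq / 3' RACE read counts (allocated to
#'   genes by expression weight).
#' @param seed Optional seed overriding `config$seed` (so several read sets
#'   can be drawn from one transcriptome).
#' @return A classed list with read-ends tables `ribo`, `race` (all
#'   fragments, with chemistry), `race_plus_pnk` (identical to `race`: +PNK
#'   captures 3'OH and 3'P) and `race_minus_pnk` (3'OH only). PCR
#'   duplicates are appended at `pcr_duplicate_rate`; collapse with
#'   [collapse_umis()].
#' @export
simulate_reads <- function(transcriptome, n_ribo = 2e5, n_race = 5e4,
                           seed = NULL) {
  stopifnot(inherits(transcriptome, "nmd_transcriptome"))
  cfg <- transcriptome$config
  tx <- transcriptome$transcripts
  set.seed(if (is.null(seed)) cfg$seed + 1L else as.integer(seed))
  n_resampled <- 0L

  alloc <- function(total) {
    as.integer(rmultinom(1, total, prob = tx$wt))
  }

  gene_reads <- function(g, n_g, race = FALSE) {
    if (n_g == 0) return(NULL)
    row <- tx[g]
    stop_rel0 <- row$stop_codon_pos
    max_rel <- row$spliced_length - 1L - stop_rel0  # last valid rel position
    cleaved <- runif(n_g) < cfg$cleavage_rate & cfg$model != "none"
    ire1 <- !is.na(row$ire1_site) & runif(n_g) < cfg$ire1_rate
    # IRE-1-like cleavage preempts (site-specific, endonuclease-independent)
    cleaved <- cleaved & !ire1

    res <- vector("list", 4)

    ## fragment 3' ends of cleaved molecules (stop-relative)
    nc <- sum(cleaved)
    ends <- integer(0)
    if (nc > 0) {
      if (cfg$model == "model1_Asite") {
        # direct A-site cleavage: 3' end within the stop codon
        law <- cfg$cleavage_offset_law
        ends <- if (!is.function(law) && identical(law$type, "stop_geometric"))
          sample(0:2, nc, replace = TRUE) else draw_offsets(law, nc, row$gene_id)
      } else {
        cut <- draw_offsets(cfg$cleavage_offset_law, nc, row$gene_id)
        bad <- cut > max_rel
        while (any(bad)) {
          n_resampled <<- n_resampled + sum(bad)
          cut[bad] <- draw_offsets(cfg$cleavage_offset_law, sum(bad),
                                   row$gene_id)
          bad <- cut > max_rel
        }
        ends <- trim_ends(cut, row$sequence, stop_rel0, cfg$g_stall_prob)
      }
      ends <- pmax(ends, -(stop_rel0 - max(cfg$stalled_range)))  # stay on tx
    }

    if (race) {
      e3 <- integer(n_g); chem <- character(n_g)
      e3[cleaved] <- stop_rel0 + ends
      chem[cleaved] <- if (cfg$model == "model1_Asite")
        cfg$chemistry_map[["smg6"]] else cfg$chemistry_map[["exosome"]]
      # direct (untrimmed) endonuclease ends keep the endonuclease chemistry
      if (nc > 0 && cfg$model == "model2_runon")
        chem[cleaved][ends <= 2L] <- cfg$chemistry_map[["smg6"]]
      e3[ire1] <- row$ire1_site
      chem[ire1] <- cfg$chemistry_map[["ire1"]]
      intact <- !cleaved & !ire1
      e3[intact] <- row$spliced_length - 1L
      chem[intact] <- "OH"
      len <- pmin(sample(20:50, n_g, replace = TRUE), e3 + 1L)
      return(read_ends_table(row$gene_id, e3 - len + 1L, len,
                             chemistry = chem,
                             umi = rand_umis(n_g, cfg$umi_length_race)))
    }

    ## --- Ribo-seq ---
    out <- list()
    # intact molecules: elongating + terminating footprints
    ni <- sum(!cleaved & !ire1)
    if (ni > 0) {
      term <- runif(ni) < cfg$term_rate
      ne <- sum(!term)
      if (ne > 0) {
        len <- sample(28:30, ne, replace = TRUE)
        # elongating: 5' ends uniform over the CDS (footprint within tx)
        lo <- row$cds_start
        hi <- pmin(row$cds_start + row$cds_length - 1L,
                   row$spliced_length - len)
        e5 <- lo + floor(runif(ne) * (hi - lo + 1L))
        out$elong <- data.table(end5 = as.integer(e5), length = len)
      }
      if (any(term)) {
        # empty-A-site termination footprint: end3 at stop last nt (rel +2)
        e3 <- stop_rel0 + 2L
        out$term <- data.table(end5 = rep(e3 - 20L, sum(term)),
                               length = rep(21L, sum(term)))
      }
    }
    # IRE-1-like site: ribosomes stall on that truncated end too
    if (any(ire1)) {
      len <- sample(cfg$stalled_range[1]:cfg$stalled_range[2], sum(ire1),
                    replace = TRUE)
      out$ire1 <- data.table(end5 = row$ire1_site - len + 1L, length = len)
    }
    if (nc > 0) {
      u <- runif(nc)
      rt <- u < cfg$readthrough_prob
      # pre-stall intermediates exist only under the run-on model: with
      # direct A-site cleavage there is no approach phase to capture
      interm <- cfg$model == "model2_runon" & !rt &
        (u < cfg$readthrough_prob + cfg$intermediate_capture_prob)
      stall <- !rt & !interm
      if (any(stall)) {
        len <- sample(cfg$stalled_range[1]:cfg$stalled_range[2], sum(stall),
                      replace = TRUE)
        e3 <- stop_rel0 + ends[stall]
        out$stall <- data.table(end5 = as.integer(e3 - len + 1L),
                                length = len)
      }
      if (any(interm)) {
        # pre-stall snapshot: ribosome a codon-multiple short of the end
        dset <- seq(1L, cfg$downstream_protect - 1L, by = 3L)
        d <- sample(dset, sum(interm), replace = TRUE)
        len <- footprint_length(d, cfg)
        e3 <- stop_rel0 + ends[interm]
        out$interm <- data.table(end5 = as.integer(e3 - len + 1L),
                                 length = as.integer(len))
      }
      if (any(rt)) {
        # readthrough: frame-locked elongating footprints downstream
        nrt <- sum(rt)
        kmax <- max(1L, (cfg$utr3_length - 6L) %/% 3L)
        k <- pmin(1L + rgeom(nrt, 0.3), kmax)
        e5 <- stop_rel0 + 3L * k + cfg$readthrough_frame
        off <- runif(nrt) < cfg$frame_noise
        e5[off] <- e5[off] + sample(c(-1L, 1L), sum(off), replace = TRUE)
        len <- sample(cfg$stalled_range[1]:cfg$stalled_range[2], nrt,
                      replace = TRUE)
        out$rt <- data.table(end5 = as.integer(e5), length = len)
      }
    }
    dt <- rbindlist(out, use.names = TRUE)
    if (!nrow(dt)) return(NULL)
    dt <- dt[end5 >= 0 & end5 + length <= row$spliced_length]
    read_ends_table(row$gene_id, dt$end5, dt$length, chemistry = "unknown",
                    umi = rand_umis(nrow(dt), cfg$umi_length_ribo))
  }

  empty <- read_ends_table(character(0), integer(0), integer(0))
  nr <- if (n_ribo > 0) alloc(n_ribo) else integer(nrow(tx))
  ribo <- rbindlist(c(list(empty), lapply(seq_len(nrow(tx)),
                      function(g) gene_reads(g, nr[g], race = FALSE))))
  na <- if (n_race > 0) alloc(n_race) else integer(nrow(tx))
  race <- rbindlist(c(list(empty), lapply(seq_len(nrow(tx)),
                      function(g) gene_reads(g, na[g], race = TRUE))))

  add_dups <- function(dt) {
    if (cfg$pcr_duplicate_rate <= 0 || !nrow(dt)) return(dt)
    ndup <- as.integer(round(nrow(dt) * cfg$pcr_duplicate_rate))
    if (ndup == 0) return(dt)
    rbind(dt, dt[sample(nrow(dt), ndup, replace = TRUE)])
  }
  ribo <- add_dups(ribo)
  race <- add_dups(race)
  setorder(ribo, gene_id, end5, length, umi)
  setorder(race, gene_id, end5, length, umi)

  out <- list(ribo = ribo,
              race = race,
              race_plus_pnk = race,
              race_minus_pnk = race[chemistry != "P"],
              config = cfg)
  attr(out, "n_resampled") <- n_resampled
  structure(out, class = "nmd_reads")
}

#' Write simulated annotation and sequences
#'
#' `write_sim_gff3()` lays the single-isoform transcripts head-to-tail on
#' one synthetic chromosome (alternating strands, 100-nt spacers) and
#' exports gene/mRNA/exon/CDS features; `write_sim_fasta()` writes the
#' spliced transcript sequences (named by transcript_id). Both stamp the
#' simulation seed in a header comment.
#'
#' @param transcriptome From [simulate_transcriptome()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sim_gff3 <- function(transcriptome, path) {
  tx <- transcriptome$transcripts
  gap <- 100L
  starts <- cumsum(c(1L, head(tx$spliced_length + gap, -1L)))
  feats <- lapply(seq_len(nrow(tx)), function(i) {
    r <- tx[i]
    s <- starts[i]; e <- s + r$spliced_length - 1L
    minus <- r$strand == "-"
    # transcript-space [a,b] (0-based incl.) -> genomic 1-based incl.
    t2g <- function(a, b) {
      if (minus) c(e - b, e - a) else c(s + a, s + b)
    }
    cds <- t2g(r$cds_start, r$cds_start + r$cds_length - 1L)
    data.table(
      seqid = "synthI",
      start = c(s, s, s, cds[1]),
      end = c(e, e, e, cds[2]),
      strand = r$strand,
      type = c("gene", "mRNA", "exon", "CDS"),
      ID = c(r$gene_id, r$transcript_id,
             paste0(r$transcript_id, ".e1"), paste0(r$transcript_id, ".c1")),
      Parent = c(NA, r$gene_id, r$transcript_id, r$transcript_id),
      phase = c(NA, NA, NA, 0L)
    )
  })
  ft <- rbindlist(feats)
  gr <- GenomicRanges::GRanges(
    seqnames = ft$seqid,
    ranges = IRanges::IRanges(ft$start, ft$end),
    strand = ft$strand,
    type = ft$type,
    ID = ft$ID,
    Parent = ifelse(is.na(ft$Parent), NA_character_, ft$Parent),
    phase = ft$phase
  )
  rtracklayer::export(gr, path, format = "gff3")
  lines <- readLines(path)
  writeLines(c(lines[1],
               paste0("# nmdtrace simulation seed: ",
                      transcriptome$config$seed),
               lines[-1]), path)
  invisible(path)
}

#' @rdname write_sim_gff3
#' @export
write_sim_fasta <- function(transcriptome, path) {
  tx <- transcriptome$transcripts
  ss <- Biostrings::DNAStringSet(setNames(tx$sequence, tx$transcript_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
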