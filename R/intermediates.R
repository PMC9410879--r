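## Intermediate-footprint detection: per-length positional tallies, average
## footprint density across genes, and a permutation z-score / p-value
## significance map. Under the run-on model, a ribosome approaching a
## truncated 3' end leaves a series of footprints that share a 3' end and
## shrink by one codon (3 nt) at the 5' end; in (length x 5'-position)
## space this series is the diagonal the significance map should light up.

#' Build per-gene (length, position) tallies
#'
#' Restricts to genes with at least `min_reads` reads (counted over ALL the
#' gene's reads, before windowing), then tallies reads by their 5' end
#' position relative to the stop codon, keeping lengths separate. Reads
#' whose 5' ends fall outside the window are excluded from the entries but
#' still count toward the gene total.
#'
#' @param reads Deduplicated read-ends table.
#' @param transcripts Transcript table (one row per gene).
#' @param min_reads Minimum total reads per gene (default 5).
#' @param window Integer c(lo, hi) of stop-relative 5'-end positions.
#' @return A classed list (`nmd_tallies`) with `entries` (gene_id, length,
#'   pos, count), `genes` (gene_id, total_reads), `window`, `n_genes`.
#' @export
build_tallies <- function(reads, transcripts, min_reads = 5,
                          window = c(-40, 20)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  reads <- as.data.table(reads)
  tx <- as.data.table(transcripts)
  reads <- reads[gene_id %in% tx$gene_id]
  totals <- reads[, .(total_reads = .N), by = gene_id]
  keep <- totals[total_reads >= min_reads]
  rr <- reads[gene_id %in% keep$gene_id]
  rr[, rel5 := to_stop_relative(rr, tx, anchor = "5p")]
  entries <- rr[rel5 >= window[1] & rel5 <= window[2],
                .(count = .N), by = .(gene_id, length, pos = rel5)]
  setorder(entries, gene_id, length, pos)
  structure(list(entries = entries, genes = keep,
                 window = as.integer(window), n_genes = nrow(keep)),
            class = "nmd_tallies")
}

#' Average footprint density across genes
#'
#' For each (length, position) cell, the mean read count over all included
#' genes (genes without an entry contribute 0).
#'
#' @param tallies From [build_tallies()].
#' @param lengths Integer vector of footprint lengths to report (rows);
#'   default: the full range observed in the tallies.
#' @return Numeric matrix (lengths x positions) with dimnames.
#' @export
average_density <- function(tallies, lengths = NULL) {
  stopifnot(inherits(tallies, "nmd_tallies"), tallies$n_genes >= 1)
  en <- tallies$entries
  if (is.null(lengths))
    lengths <- if (nrow(en)) seq(min(en$length), max(en$length)) else integer(0)
  positions <- seq(tallies$window[1], tallies$window[2])
  m <- matrix(0, nrow = length(lengths), ncol = length(positions),
              dimnames = list(lengths, positions))
  if (nrow(en)) {
    agg <- en[length %in% lengths & pos %in% positions,
              .(s = sum(count)), by = .(length, pos)]
    m[cbind(match(agg$length, lengths), match(agg$pos, positions))] <-
      agg$s / tallies$n_genes
  }
  m
}

#' Permutation significance of average footprint density
#'
#' For each permutation, the observed counts within every (gene, length)
#' stratum are reassigned to uniformly random distinct positions (mode
#' "window": drawn from the full analysis window, the default; mode
#' "occupied": permuted among that stratum's own occupied positions), and
#' the average footprint density is recomputed. The permutations yield a
#' per-cell z-score of the observed density,
#' `z = (observed - perm_mean) / perm_sd` (sample sd), and a one-sided
#' upper-tail p-value from the standard normal. Cells with `perm_sd = 0`
#' and observed equal to the permutation mean get z = 0, p = 1; p-values
#' are clamped into (0, 1].
#'
#' @param tallies From [build_tallies()].
#' @param n_perm Number of permutations (>= 2; default 30).
#' @param seed Integer seed for the permutation RNG.
#' @param mode "window" or "occupied" (see above).
#' @param lengths Lengths (matrix rows), as in [average_density()].
#' @return A classed list (`nmd_density`) with matrices `mean_density`
#'   (observed), `perm_mean`, `perm_sd`, `z`, `p`, plus `lengths`,
#'   `positions`, `n_perm`, `seed`, `mode`, `n_genes`.
#' @export
permutation_significance <- function(tallies, n_perm = 30, seed = NULL,
                                     mode = c("window", "occupied"),
                                     lengths = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tallies, "nmd_tallies"))
  if (n_perm < 2) stop("n_perm must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  en <- tallies$entries
  if (is.null(lengths))
    lengths <- if (nrow(en)) seq(min(en$length), max(en$length)) else integer(0)
  positions <- seq(tallies$window[1], tallies$window[2])
  W <- length(positions)
  if (mode == "window") {
    sizes <- en[, .N, by = .(gene_id, length)]
    if (nrow(sizes) && any(sizes$N > W))
      stop("window (", W, " positions) smaller than the number of distinct ",
           "entries in some (gene, length) stratum; cannot place counts ",
           "injectively")
  }
  obs <- average_density(tallies, lengths = lengths)

  nL <- length(lengths)
  S <- matrix(0, nL, W)
  S2 <- matrix(0, nL, W)
  en_use <- en[length %in% lengths]
  for (b in seq_len(n_perm)) {
    perm <- copy(en_use)
    if (mode == "window") {
      perm[, newpos := positions[sample.int(W, .N)], by = .(gene_id, length)]
    } else {
      perm[, newpos := pos[sample.int(.N)], by = .(gene_id, length)]
    }
    agg <- perm[, .(s = sum(count)), by = .(length, newpos)]
    m <- matrix(0, nL, W)
    m[cbind(match(agg$length, lengths), match(agg$newpos, positions))] <-
      agg$s / tallies$n_genes
    S <- S + m
    S2 <- S2 + m * m
  }
  mu <- S / n_perm
  v <- (S2 - n_perm * mu * mu) / (n_perm - 1)
  sdv <- sqrt(pmax(v, 0))
  z <- (obs - mu) / sdv
  degenerate <- sdv == 0 & abs(obs - mu) < 1e-12
  z[degenerate] <- 0
  p <- pnorm(z, lower.tail = FALSE)
  p[degenerate] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  dimnames(mu) <- dimnames(sdv) <- dimnames(z) <- dimnames(p) <- dimnames(obs)
  structure(list(mean_density = obs, perm_mean = mu, perm_sd = sdv,
                 z = z, p = p, lengths = as.integer(lengths),
                 positions = positions, n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 mode = mode, n_genes = tallies$n_genes),
            class = "nmd_density")
}

#' Write the density / z / p matrices as TSV
#'
#' Three files `<prefix>_{density,z,p}.tsv` with length rows and position
#' columns; run metadata (seed, n_perm, window, mode) embedded as `#`
#' header comments.
#'
#' @param dm From [permutation_significance()].
#' @param prefix Output path prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_density_matrices <- function(dm, prefix) {
  stopifnot(inherits(dm, "nmd_density"))
  meta <- c(n_perm = dm$n_perm, seed = dm$seed,
            window = paste(range(dm$positions), collapse = ".."),
            mode = dm$mode, n_genes = dm$n_genes)
  paths <- character(0)
  for (what in c("mean_density", "z", "p")) {
    tag <- if (what == "mean_density") "density" else what
    path <- paste0(prefix, "_", tag, ".tsv")
    m <- dm[[what]]
    dt <- data.table(length = rownames(m))
    dt <- cbind(dt, as.data.table(m))
    write_read_ends(dt, path, meta = meta)
    paths <- c(paths, path)
  }
  invisible(paths)
}
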