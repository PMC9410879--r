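## Pipeline surface: a validated run configuration and one entry point,
## nmd_run(subcommand, config), that reads inputs, executes a stage and
## writes TSV outputs plus a machine-readable manifest (resolved
## parameters and input checksums). A thin command-line wrapper over this
## function ships in inst/scripts/nmdtrace.R.

#' Pipeline run configuration
#'
#' Collects paths, windows, thresholds, anchors and the seed for
#' [nmd_run()]. Validation reports all violations in one pass.
#'
#' @param annotation,reads,norm_reads,oh_reads,ohp_reads,sequences Input
#'   file paths (which stages need which is documented per subcommand in
#'   [nmd_run()]).
#' @param out_dir Output directory (created if missing).
#' @param min_reads Gene inclusion threshold for tallies/metagene.
#' @param heatmap_min_reads Window read threshold for the CDF heatmap.
#' @param n_perm Number of permutations (>= 2).
#' @param window Stop-relative window c(lo, hi) for metagene/intermediates.
#' @param heatmap_window 100-nt heatmap window.
#' @param size_class Size class analysed ("short", "mid", "long", "all").
#' @param anchor Read-end anchor ("3p" or "5p").
#' @param shuffle_mode Permutation mode ("window" or "occupied").
#' @param seed Integer seed.
#' @param sim A [sim_config()] for the simulate subcommand.
#' @param n_ribo,n_race Simulated library depths.
#' @return A classed list (`RunConfig`).
#' @export
run_config <- function(annotation = NULL, reads = NULL, norm_reads = NULL,
                       oh_reads = NULL, ohp_reads = NULL, sequences = NULL,
                       out_dir = ".", min_reads = 5, heatmap_min_reads = 50,
                       n_perm = 30, window = c(-40, 20),
                       heatmap_window = c(-50, 49), size_class = "short",
                       anchor = "3p", shuffle_mode = "window", seed = 1L,
                       sim = NULL, n_ribo = 2e5, n_race = 5e4) {
  cfg <- list(annotation = annotation, reads = reads,
              norm_reads = norm_reads, oh_reads = oh_reads,
              ohp_reads = ohp_reads, sequences = sequences,
              out_dir = out_dir, min_reads = min_reads,
              heatmap_min_reads = heatmap_min_reads, n_perm = n_perm,
              window = as.integer(window),
              heatmap_window = as.integer(heatmap_window),
              size_class = size_class, anchor = anchor,
              shuffle_mode = shuffle_mode, seed = as.integer(seed),
              sim = sim, n_ribo = n_ribo, n_race = n_race)
  problems <- character(0)
  if (cfg$n_perm < 2) problems <- c(problems, "n_perm must be >= 2")
  if (cfg$min_reads < 1) problems <- c(problems, "min_reads must be >= 1")
  if (length(cfg$window) != 2 || cfg$window[1] > cfg$window[2])
    problems <- c(problems, "window must be c(lo, hi) with lo <= hi")
  if (!cfg$size_class %in% c("short", "mid", "long", "other", "all"))
    problems <- c(problems, "size_class must be short/mid/long/other/all")
  if (!cfg$anchor %in% c("3p", "5p"))
    problems <- c(problems, "anchor must be 3p or 5p")
  if (!cfg$shuffle_mode %in% c("window", "occupied"))
    problems <- c(problems, "shuffle_mode must be window or occupied")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "RunConfig")
}

manifest_write <- function(config, subcommand, inputs, outputs) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  checksums <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  resolved <- config[!vapply(config, is.null, logical(1))]
  resolved$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  man <- list(subcommand = subcommand,
              parameters = resolved,
              input_checksums = checksums,
              outputs = outputs)
  path <- file.path(config$out_dir,
                    paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

require_inputs <- function(config, fields) {
  missing <- fields[vapply(fields, function(f)
    is.null(config[[f]]) || !file.exists(config[[f]]), logical(1))]
  if (length(missing))
    stop("missing input(s) for this subcommand: ",
         paste(missing, collapse = ", "), call. = FALSE)
}

load_gene_models <- function(config) {
  canonical_transcripts(parse_annotation(config$annotation))
}

#' Run one pipeline stage
#'
#' Subcommands and their inputs (all read tables are read-ends TSVs; UMIs
#' are collapsed on load):
#' \describe{
#'   \item{simulate}{`config$sim`; writes annotation GFF3, transcript
#'     FASTA, and ribo / race_plus_pnk / race_minus_pnk read tables.}
#'   \item{metagene}{annotation + reads (+ optional norm_reads); writes a
#'     metagene profile TSV.}
#'   \item{intermediates}{annotation + reads; writes density/z/p matrices.}
#'   \item{heatmap}{annotation + reads; writes the CDF matrix and
#'     half-point table (short-class reads).}
#'   \item{endchem}{annotation + oh_reads + ohp_reads (+ sequences for base
#'     composition); writes chemistry-call and base-composition TSVs.}
#'   \item{frames}{annotation + reads; writes the frame-fraction table.}
#' }
#' Outputs are deterministic given identical config + seed; per-stage gene
#' filter counts are reported via `message()`.
#'
#' @param subcommand One of simulate, metagene, intermediates, heatmap,
#'   endchem, frames.
#' @param config A [run_config()].
#' @return Invisibly, a character vector of output paths (manifest last).
#' @export
nmd_run <- function(subcommand = c("simulate", "metagene", "intermediates",
                                   "heatmap", "endchem", "frames"),
                    config = run_config()) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)
  inputs <- list()
  outputs <- character(0)

  load_reads <- function(path) {
    collapse_umis(read_read_ends(path))
  }

  if (subcommand == "simulate") {
    sim <- if (is.null(config$sim)) sim_config(seed = config$seed)
           else config$sim
    trans <- simulate_transcriptome(sim)
    reads <- simulate_reads(trans, n_ribo = config$n_ribo,
                            n_race = config$n_race)
    meta <- c(seed = sim$seed, model = sim$model)
    write_sim_gff3(trans, od("annotation.gff3"))
    write_sim_fasta(trans, od("transcripts.fa"))
    write_read_ends(reads$ribo, od("ribo_reads.tsv"), meta = meta)
    write_read_ends(reads$race_plus_pnk, od("race_plus_pnk.tsv"), meta = meta)
    write_read_ends(reads$race_minus_pnk, od("race_minus_pnk.tsv"),
                    meta = meta)
    outputs <- od(c("annotation.gff3", "transcripts.fa", "ribo_reads.tsv",
                    "race_plus_pnk.tsv", "race_minus_pnk.tsv"))
    message("simulate: ", sim$n_genes, " genes, ", nrow(reads$ribo),
            " ribo reads, ", nrow(reads$race), " race fragments")
  } else if (subcommand == "metagene") {
    require_inputs(config, c("annotation", "reads"))
    inputs <- list(annotation = config$annotation, reads = config$reads)
    tx <- load_gene_models(config)
    reads <- load_reads(config$reads)
    norm <- if (!is.null(config$norm_reads)) load_reads(config$norm_reads)
    prof <- metagene(reads, tx, size_class = config$size_class,
                     anchor = config$anchor,
                     window = c(config$window[1],
                                max(config$window[2], config$window[1])),
                     min_reads = config$min_reads, norm_reads = norm)
    write_metagene(prof, od("metagene.tsv"),
                   meta = c(size_class = config$size_class,
                            anchor = config$anchor))
    outputs <- od("metagene.tsv")
    message("metagene: ", max(prof$n_genes), " genes included")
  } else if (subcommand == "intermediates") {
    require_inputs(config, c("annotation", "reads"))
    inputs <- list(annotation = config$annotation, reads = config$reads)
    tx <- load_gene_models(config)
    reads <- load_reads(config$reads)
    tal <- build_tallies(reads, tx, min_reads = config$min_reads,
                         window = config$window)
    message("intermediates: ", tal$n_genes, " genes pass min_reads=",
            config$min_reads)
    dm <- permutation_significance(tal, n_perm = config$n_perm,
                                   seed = config$seed,
                                   mode = config$shuffle_mode)
    outputs <- write_density_matrices(dm, od("intermediates"))
  } else if (subcommand == "heatmap") {
    require_inputs(config, c("annotation", "reads"))
    inputs <- list(annotation = config$annotation, reads = config$reads)
    tx <- load_gene_models(config)
    reads <- load_reads(config$reads)
    short <- reads[size_class == "short"]
    genes <- select_heatmap_genes(short, tx,
                                  min_reads = config$heatmap_min_reads,
                                  window = config$heatmap_window)
    message("heatmap: ", length(genes), " genes pass (min ",
            config$heatmap_min_reads, " in-window reads, single stop)")
    if (!length(genes)) stop("no gene passes the heatmap filters")
    cdfs <- gene_cdf(short, tx, genes, window = config$heatmap_window)
    outputs <- write_cdf_heatmap(cdfs, od("heatmap"),
                                 meta = c(min_reads =
                                            config$heatmap_min_reads))
  } else if (subcommand == "endchem") {
    require_inputs(config, c("annotation", "oh_reads", "ohp_reads"))
    inputs <- list(annotation = config$annotation,
                   oh_reads = config$oh_reads, ohp_reads = config$ohp_reads,
                   sequences = config$sequences)
    tx <- load_gene_models(config)
    oh <- load_reads(config$oh_reads)
    ohp <- load_reads(config$ohp_reads)
    calls <- compare_libraries(oh, ohp)
    write_read_ends(calls, od("chemistry_calls.tsv"))
    outputs <- od("chemistry_calls.tsv")
    if (!is.null(config$sequences)) {
      seqs <- Biostrings::readDNAStringSet(config$sequences)
      comp <- end_base_composition(ohp, tx, seqs)
      write_read_ends(comp, od("end_base_composition.tsv"))
      outputs <- c(outputs, od("end_base_composition.tsv"))
    }
    message("endchem: ", nrow(calls), " sites called")
  } else if (subcommand == "frames") {
    require_inputs(config, c("annotation", "reads"))
    inputs <- list(annotation = config$annotation, reads = config$reads)
    tx <- load_gene_models(config)
    reads <- load_reads(config$reads)
    fr <- frame_fractions(reads[size_class == "short"], tx)
    write_read_ends(fr, od("frame_fractions.tsv"))
    outputs <- od("frame_fractions.tsv")
    message("frames: ", sum(fr$n), " downstream short-class reads")
  }

  man <- manifest_write(config, subcommand, inputs, outputs)
  invisible(c(outputs, man))
}
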