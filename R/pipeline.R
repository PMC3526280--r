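#' Pipeline configuration
#'
#' Resolves and validates every tunable of the simulate -> detect ->
#' discover -> summarize workflow into one plain list that can be echoed to
#' a manifest and replayed. Exactly one input source must be given: a
#' fixture name, or a genome FASTA plus kinetics TSV (with an unmethylated
#' reference kinetics TSV for the context model).
#'
#' @param fixture fixture name (see [fixture_motifs()]), or `NULL`.
#' @param genome_path,kinetics_path,ref_kinetics_path external input files
#'   (used when `fixture` is `NULL`).
#' @param out_dir output directory for [run_pipeline()] artifacts.
#' @param seed integer seed for every stochastic stage.
#' @param n_top number of top kinetic hits fed to motif discovery.
#' @param flank window half-width around each hit.
#' @param min_coverage,score_floor detection parameters
#'   (see [detect_modifications()]).
#' @param target_unassigned threshold rule target; defaults to 0.05 for the
#'   m4C-dominated `bce` fixture and 0.01 otherwise.
#' @param min_gap_len minimum zero-coverage gap length to report.
#' @param discovery a [discovery_params()] list.
#' @param genome_length,gc_fraction,min_sites fixture generation knobs.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(fixture = NULL, genome_path = NULL,
                            kinetics_path = NULL, ref_kinetics_path = NULL,
                            out_dir = "methylmotif_out", seed = 1L,
                            n_top = 1000L, flank = 20L, min_coverage = 10L,
                            score_floor = 20,
                            target_unassigned = NULL, min_gap_len = 1000L,
                            discovery = discovery_params(),
                            genome_length = 200000L, gc_fraction = 0.5,
                            min_sites = 150L) {
  if (is.null(fixture) && (is.null(genome_path) || is.null(kinetics_path))) {
    stop("either a fixture name or genome_path + kinetics_path is required",
         call. = FALSE)
  }
  if (is.null(target_unassigned)) {
    target_unassigned <- if (identical(fixture, "bce")) 0.05 else 0.01
  }
  stopifnot(target_unassigned >= 0, target_unassigned < 1,
            n_top >= 1, flank >= 1, min_coverage >= 0, score_floor >= 0,
            min_gap_len >= 1)
  cfg <- list(fixture = fixture, genome_path = genome_path,
              kinetics_path = kinetics_path,
              ref_kinetics_path = ref_kinetics_path,
              out_dir = out_dir, seed = as.integer(seed),
              n_top = as.integer(n_top), flank = as.integer(flank),
              min_coverage = as.integer(min_coverage),
              score_floor = score_floor,
              target_unassigned = target_unassigned,
              min_gap_len = as.integer(min_gap_len),
              discovery = unclass(discovery),
              genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction, min_sites = as.integer(min_sites))
  structure(cfg, class = "pipeline_config")
}

#' Fit the methylome model to a genome and its kinetics
#'
#' The in-memory workflow behind [run_pipeline()]: detect modified
#' positions against the context reference, discover motifs from the top
#' hits, assign all hits, choose the reporting threshold by the
#' unassigned-fraction rule, pair complementary-strand motifs, classify RM
#' types, summarize per-motif extent of methylation, and re-screen the
#' residual unassigned hits.
#'
#' @param genome a `DNAStringSet` genome.
#' @param tracks kinetics tracks of the sample.
#' @param ref_tracks kinetics tracks of unmethylated DNA (context model
#'   training data).
#' @param config a [pipeline_config()].
#' @return an object of class `methylome_fit`; see [tidy.methylome_fit()]
#'   and [glance.methylome_fit()].
#' @export
methylome_pipeline <- function(genome, tracks, ref_tracks,
                               config = pipeline_config(fixture = "gmet")) {
  dp <- do.call(discovery_params, config$discovery)
  model <- build_context_model(genome, ref_tracks)
  records <- detect_modifications(tracks, genome, model,
                                  min_coverage = config$min_coverage,
                                  score_floor = config$score_floor)
  hits <- top_hits(records, config$n_top)
  windows <- extract_windows(hits, genome, flank = config$flank)
  candidates <- discover_motifs(windows, genome, dp)
  records <- assign_hits(records, candidates, genome)
  threshold <- if (nrow(records) > 0) {
    select_threshold(records, config$target_unassigned)
  } else {
    warning("no positions detected above the score floor", call. = FALSE)
    Inf
  }
  motifs <- pair_motifs(candidates)
  summary <- build_summary(genome, motifs, records, threshold)
  residual_rec <- dplyr::filter(records, .data$score >= threshold,
                                !.data$assigned)
  residual <- residual_motif_check(
    extract_windows(residual_rec, genome, flank = config$flank), genome, dp)
  gaps <- find_coverage_gaps(tracks, genome, min_len = config$min_gap_len)
  structure(list(
    genome = genome, config = config, context_model = model,
    records = records, n_hits = nrow(records), threshold = threshold,
    motifs = dplyr::mutate(
      motifs, rm_type = classify_rm_type(motifs$pattern, motifs$double_strand)),
    summary = summary, residual = residual,
    residual_n_hits = nrow(residual_rec), gaps = gaps,
    clean = nrow(residual) == 0 && is.finite(threshold)
  ), class = "methylome_fit")
}

resolve_inputs <- function(config) {
  if (!is.null(config$fixture)) {
    fx <- make_fixture(config$fixture, seed = config$seed,
                       genome_length = config$genome_length,
                       gc_fraction = config$gc_fraction,
                       min_sites = config$min_sites)
    list(genome = fx$genome, tracks = fx$tracks, ref_tracks = fx$ref_tracks,
         fixture = fx)
  } else {
    genome <- read_genome_fasta(config$genome_path)
    tracks <- read_kinetics_tsv(config$kinetics_path)
    if (is.null(config$ref_kinetics_path)) {
      stop("external runs need ref_kinetics_path (unmethylated control ",
           "kinetics) to train the context model", call. = FALSE)
    }
    list(genome = genome, tracks = tracks,
         ref_tracks = read_kinetics_tsv(config$ref_kinetics_path),
         fixture = NULL)
  }
}

#' Run the full pipeline and write its artifacts
#'
#' Resolves inputs (fixture simulation or external files), fits the
#' methylome, and writes to `config$out_dir`: `modifications.gff3` (all
#' detected positions at or above the reporting threshold),
#' `motifs.csv` (discovered candidates with pairing and RM-type calls),
#' `summary.csv` (per-motif extent of methylation), `residual.csv`
#' (re-screen of unassigned hits; empty on a clean run),
#' `coverage_gaps.bed`, and `manifest.yaml` (the resolved configuration;
#' [run_from_manifest()] reproduces all artifacts byte-identically).
#' All writes are atomic.
#'
#' @param config a [pipeline_config()].
#' @return the `methylome_fit`, invisibly, with attribute `status`: 0 for
#'   a clean run, 1 if the residual check found motifs or the threshold
#'   target was unattainable.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  inputs <- resolve_inputs(config)
  fit <- methylome_pipeline(inputs$genome, inputs$tracks, inputs$ref_tracks,
                            config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  retained <- dplyr::filter(fit$records, .data$score >= fit$threshold) |>
    extract_windows(inputs$genome, flank = config$flank) |>
    dplyr::left_join(fit$motifs[c("pattern", "mod_type")],
                     by = c(motif = "pattern"))
  write_modifications_gff3(retained, out("modifications.gff3"))
  write_csv_atomic(fit$motifs, out("motifs.csv"))
  write_csv_atomic(fit$summary, out("summary.csv"))
  write_csv_atomic(fit$residual, out("residual.csv"))
  gaps_bed <- tibble::tibble(
    chrom = fit$gaps$contig, start = fit$gaps$start - 1L, end = fit$gaps$end,
    name = "zero_coverage_gap", score = 0L, strand = ".")
  atomic_write(out("coverage_gaps.bed"), function(tmp) {
    readr::write_tsv(gaps_bed, tmp, col_names = FALSE, progress = FALSE)
  })
  manifest <- list(package = "methylmotif",
                   version = as.character(utils::packageVersion("methylmotif")),
                   config = unclass(config))
  atomic_write(out("manifest.yaml"), function(tmp) {
    yaml::write_yaml(manifest, tmp)
  })
  status <- if (isTRUE(fit$clean)) 0L else 1L
  attr(fit, "status") <- status
  invisible(fit)
}

#' @rdname run_pipeline
#' @param path path to a `manifest.yaml` written by a previous run.
#' @param out_dir optional new output directory (defaults to the one in the
#'   manifest).
#' @export
run_from_manifest <- function(path, out_dir = NULL) {
  manifest <- yaml::read_yaml(path)
  cfg <- manifest$config
  cfg$discovery <- do.call(discovery_params, cfg$discovery)
  cfg[lengths(cfg) == 0] <- list(NULL)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(do.call(pipeline_config, cfg))
}

write_csv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    readr::write_csv(df, tmp, progress = FALSE)
  })
  invisible(path)
}

#' Write detected modifications as GFF3
#'
#' One feature per modified position, following community base-modification
#' conventions: `type` is the modification type of the assigned motif (or
#' `modified_DNA_base` when unassigned), `start == end` is the 1-based
#' position, `score` the kinetic score (2 decimals), and attributes carry
#' `coverage`, `IPDRatio`, the strand-oriented sequence `context`, and the
#' assigned `motif` (or `unassigned`).
#'
#' @param records retained records with `window`, `motif`, `mod_type`
#'   columns (see [run_pipeline()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_modifications_gff3 <- function(records, path) {
  type <- ifelse(is.na(records$mod_type), "modified_DNA_base",
                 records$mod_type)
  lines <- sprintf(
    "%s\tmethylmotif\t%s\t%d\t%d\t%.2f\t%s\t.\tcoverage=%d;IPDRatio=%.4f;context=%s;motif=%s",
    records$contig, type, records$position, records$position, records$score,
    records$strand, records$n_obs, records$ipd_ratio, records$window,
    ifelse(is.na(records$motif), "unassigned", records$motif))
  atomic_write(path, function(tmp) {
    readr::write_lines(c("##gff-version 3", lines), tmp)
  })
  invisible(path)
}

#' @export
print.methylome_fit <- function(x, ...) {
  cat("<methylome_fit>\n")
  cat("  contigs:", length(x$genome), " total bp:",
      sum(Biostrings::width(x$genome)), "\n")
  cat("  detected positions (score floor):", x$n_hits, "\n")
  cat("  reporting threshold:", format(x$threshold, digits = 4),
      " (target unassigned <=", x$config$target_unassigned, ")\n")
  cat("  motifs:", nrow(x$motifs), "in",
      length(unique(x$motifs$group)), "duplex group(s)\n")
  if (nrow(x$summary) > 0) {
    cat("  extent of methylation:\n")
    s <- x$summary
    cat(sprintf("    %-16s %-6s %-14s %5d/%5d  %5.1f%%\n", s$pattern,
                s$mod_type, s$rm_type, s$n_detected, s$n_sites,
                100 * s$fraction), sep = "")
  }
  cat("  residual motifs:", nrow(x$residual),
      if (isTRUE(x$clean)) "(clean)" else "(ATTENTION)", "\n")
  invisible(x)
}

#' Tidy a fitted methylome
#'
#' `tidy()` returns the per-motif summary table; `glance()` a one-row
#' model-level summary.
#'
#' @param x a `methylome_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.methylome_fit <- function(x, ...) {
  x$summary
}

#' @rdname tidy.methylome_fit
#' @export
glance.methylome_fit <- function(x, ...) {
  retained <- dplyr::filter(x$records, .data$score >= x$threshold)
  tibble::tibble(
    n_detected = nrow(x$records),
    n_retained = nrow(retained),
    threshold = x$threshold,
    unassigned_fraction = if (nrow(retained) > 0) {
      mean(!retained$assigned)
    } else NA_real_,
    n_motifs = nrow(x$motifs),
    n_groups = length(unique(x$motifs$group)),
    n_residual_motifs = nrow(x$residual),
    n_coverage_gaps = nrow(x$gaps),
    clean = x$clean
  )
}
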