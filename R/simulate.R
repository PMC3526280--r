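#' Simulation configuration for synthetic sequencing kinetics
#'
#' The generative model for per-position interpulse-duration (IPD)
#' summaries. IPDs are modelled log-normally: at an unmodified position the
#' log-IPD of a single pulse is Normal with a sequence-context-dependent mean
#' and common standard deviation `sigma`. Methylation shifts the mean by a
#' modification-type-dependent `delta`, ordered `m6A > m4C > m5C` to mirror
#' the observed signal strengths (strong m6A, weaker m4C, weak and diffuse
#' m5C); m5C additionally leaks half its shift into the two adjacent
#' positions on the same strand. Only the per-position summary (read count,
#' mean, SD of log-IPD) is retained, as produced by real kinetics pipelines.
#'
#' @param coverage_mean mean per-strand read coverage (Poisson).
#' @param sigma per-read log-IPD standard deviation.
#' @param delta named mean log-IPD shifts for `m6A`, `m4C`, `m5C`
#'   (defaults `log(4)`, `log(2)`, `log(1.2)`).
#' @param context_order centered k-mer order of the baseline mean model.
#' @param context_sd spread of per-context baseline means around 0.
#' @param context_seed seed of the per-context baseline draw. The baseline
#'   is polymerase chemistry, a property of the configuration and not of a
#'   run: two runs with the same config (e.g. a sample and its unmethylated
#'   control) share identical context baselines.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(coverage_mean = 60, sigma = 0.6,
                       delta = c(m6A = log(4), m4C = log(2), m5C = log(1.2)),
                       context_order = 3L, context_sd = 0.3,
                       context_seed = 20121002L) {
  stopifnot(coverage_mean >= 0, sigma > 0, context_order %% 2 == 1,
            all(c("m6A", "m4C", "m5C") %in% names(delta)))
  if (!(delta[["m6A"]] > delta[["m4C"]] && delta[["m4C"]] > delta[["m5C"]] &&
        delta[["m5C"]] >= 0)) {
    stop("signal shifts must satisfy delta(m6A) > delta(m4C) > delta(m5C) >= 0",
         call. = FALSE)
  }
  structure(list(coverage_mean = coverage_mean, sigma = sigma,
                 delta = delta[c("m6A", "m4C", "m5C")],
                 context_order = as.integer(context_order),
                 context_sd = context_sd,
                 context_seed = as.integer(context_seed)),
            class = "sim_config")
}

#' Plant a methylome onto a genome
#'
#' Scans each motif and includes every site independently with its
#' `fraction` (per-motif extent of methylation; methylation need not be
#' complete in vivo). The returned truth set is the per-strand ground truth
#' the detection stage is measured against.
#'
#' @param genome a `DNAStringSet` genome.
#' @param motifs a motif table; an optional `fraction` column gives each
#'   motif's methylated fraction (default 1).
#' @param seed integer seed; inclusion draws are reproducible and do not
#'   disturb the caller's RNG.
#' @return a tibble `(contig, position, strand, mod_type, pattern)` of
#'   methylated positions.
#' @export
plant_methylation <- function(genome, motifs, seed = 1L) {
  validate_motifs(motifs)
  if (!"fraction" %in% names(motifs)) motifs$fraction <- 1
  stopifnot(all(motifs$fraction >= 0 & motifs$fraction <= 1))
  sites <- scan_motifs(genome, motifs) |>
    dplyr::left_join(motifs[c("pattern", "offset", "mod_type", "fraction")],
                     by = c("pattern", "offset", "mod_type"))
  keep <- withr::with_seed(seed, stats::runif(nrow(sites)) < sites$fraction)
  sites[keep, c("contig", "position", "strand", "mod_type", "pattern")] |>
    dplyr::distinct(.data$contig, .data$position, .data$strand, .keep_all = TRUE)
}

# per-context baseline mean log-IPDs: one draw per k-mer over A/C/G/T,
# deterministic in the config (NOT the run seed -- see sim_config docs)
context_baseline <- function(config) {
  k <- config$context_order
  kmers <- expand_iupac(strrep("N", k), max_size = 4^k)
  mu <- withr::with_seed(derive_seed(config$context_seed, "context_baseline"),
                         stats::rnorm(length(kmers), 0, config$context_sd))
  stats::setNames(mu, kmers)
}

# strand-aware centered k-mer context for every (position, strand); NA at
# contig edges where the full k-mer is unavailable
position_contexts <- function(genome, contig, position, strand, k) {
  flank <- (k - 1L) %/% 2L
  seqs <- as.character(genome)
  lens <- stats::setNames(nchar(seqs), names(genome))
  ctx <- rep(NA_character_, length(position))
  for (id in unique(contig)) {
    idx <- which(contig == id)
    p <- position[idx]
    ok <- p - flank >= 1L & p + flank <= lens[[id]]
    ctx[idx[ok]] <- substring(seqs[[id]], p[ok] - flank, p[ok] + flank)
  }
  minus <- strand == "-" & !is.na(ctx)
  if (any(minus)) ctx[minus] <- revcomp_concrete(ctx[minus])
  ctx
}

# fast reverse complement for concrete A/C/G/T(/N) strings of equal length
revcomp_concrete <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Simulate per-position kinetics summaries
#'
#' For every position on both strands: coverage `n_obs ~ Poisson(mean)`, and
#' the sufficient statistics of `n_obs` log-IPD draws from
#' `Normal(mu(context) + shift, sigma)` -- the sample mean is drawn as
#' `Normal(mu + shift, sigma/sqrt(n))` and the sample SD from the exact
#' scaled chi-square law, so no per-read data is ever materialized. `shift`
#' is the modification delta at methylated truth positions, plus the m5C
#' adjacency leak. Positions with `n_obs < 2` carry `NA` summaries.
#'
#' @param genome a `DNAStringSet` genome.
#' @param truth a truth tibble from [plant_methylation()] (may be empty for
#'   an unmethylated control run).
#' @param config a [sim_config()].
#' @param seed integer seed; output is bit-reproducible given
#'   `(genome, truth, config, seed)`.
#' @return a kinetics track tibble `(contig, position, strand, base, n_obs,
#'   mean_logipd, sd_logipd)`, one row per position and strand.
#' @export
simulate_kinetics <- function(genome, truth = NULL, config = sim_config(),
                              seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  baseline <- context_baseline(config)
  seqs <- as.character(genome)

  tracks <- purrr::imap(seqs, function(seq, id) {
    len <- nchar(seq)
    plus_bases <- substring(seq, seq_len(len), seq_len(len))
    tibble::tibble(
      contig = id,
      position = rep(seq_len(len), 2L),
      strand = rep(c("+", "-"), each = len),
      base = c(plus_bases, chartr("ACGT", "TGCA", plus_bases))
    )
  }) |> dplyr::bind_rows()

  ctx <- position_contexts(genome, tracks$contig, tracks$position,
                           tracks$strand, config$context_order)
  mu <- unname(baseline[ctx])
  mu[is.na(mu)] <- 0

  shift <- numeric(nrow(tracks))
  if (!is.null(truth) && nrow(truth) > 0) {
    key <- paste(tracks$contig, tracks$position, tracks$strand)
    shift <- shift + config$delta[truth$mod_type][
      match(key, paste(truth$contig, truth$position, truth$strand))]
    shift[is.na(shift)] <- 0
    m5 <- truth[truth$mod_type == "m5C", ]
    if (nrow(m5) > 0) {
      # diffuse m5C signal: half the shift leaks to the flanking positions
      leak <- dplyr::bind_rows(
        dplyr::mutate(m5, position = .data$position - 1L),
        dplyr::mutate(m5, position = .data$position + 1L)
      )
      leak_n <- table(paste(leak$contig, leak$position, leak$strand))
      hit <- match(key, names(leak_n))
      shift <- shift + ifelse(is.na(hit), 0,
                              as.vector(leak_n)[hit] * config$delta[["m5C"]] / 2)
    }
  }

  withr::with_seed(derive_seed(seed, "kinetics"), {
    n <- stats::rpois(nrow(tracks), config$coverage_mean)
    mean_ipd <- ifelse(n >= 1,
                       stats::rnorm(nrow(tracks), mu + shift,
                                    config$sigma / sqrt(pmax(n, 1))),
                       NA_real_)
    sd_ipd <- ifelse(n >= 2,
                     config$sigma * sqrt(stats::rchisq(
                       nrow(tracks), df = pmax(n - 1L, 1L)) / pmax(n - 1L, 1L)),
                     NA_real_)
    tracks |>
      dplyr::mutate(n_obs = n,
                    mean_logipd = ifelse(n >= 2, mean_ipd, NA_real_),
                    sd_logipd = sd_ipd)
  })
}

#' Read/write kinetics tracks as TSV
#'
#' Plain-text interchange format: columns `contig, position, strand, base,
#' n_obs, mean_logipd, sd_logipd` with 1-based positions.
#'
#' @param tracks a kinetics track tibble.
#' @param path file path.
#' @return the tracks tibble (reader) or `path` invisibly (writer).
#' @export
write_kinetics_tsv <- function(tracks, path) {
  atomic_write(path, function(tmp) {
    readr::write_tsv(tracks, tmp, progress = FALSE)
  })
  invisible(path)
}

#' @rdname write_kinetics_tsv
#' @export
read_kinetics_tsv <- function(path) {
  if (!file.exists(path)) stop("kinetics table not found: ", path, call. = FALSE)
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("contig", "position", "strand", "base", "n_obs",
           "mean_logipd", "sd_logipd")
  miss <- setdiff(req, names(tr))
  if (length(miss) > 0) {
    stop("kinetics table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!tr$strand %in% c("+", "-") | is.na(tr$position) | tr$n_obs < 0)
  if (length(bad) > 0) {
    stop("malformed kinetics table '", path, "' at row ", bad[1], call. = FALSE)
  }
  tr
}
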