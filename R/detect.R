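#' Build an in-silico kinetic reference (sequence-context model)
#'
#' Trains the per-context expected log-IPD from kinetics tracks of
#' unmethylated DNA (a whole-genome amplified control or a simulated null
#' run): for every centered k-mer on the read strand, the mean of the
#' per-position mean log-IPDs and the pooled within-position SD. Contexts
#' never seen in training fall back to the global values.
#'
#' @param genome a `DNAStringSet` genome.
#' @param tracks unmethylated kinetics tracks.
#' @param k centered k-mer order (odd).
#' @return a tibble of class `context_model` with columns `context`,
#'   `ref_mean`, `ref_sd`, `n_positions`, plus attributes `k`,
#'   `fallback_mean`, `fallback_sd`.
#' @export
build_context_model <- function(genome, tracks, k = 3L) {
  stopifnot(k %% 2 == 1)
  usable <- dplyr::filter(tracks, .data$n_obs >= 2, !is.na(.data$mean_logipd))
  if (nrow(usable) == 0) stop("no usable track rows to train on", call. = FALSE)
  usable$context <- position_contexts(genome, usable$contig, usable$position,
                                      usable$strand, k)
  usable <- dplyr::filter(usable, !is.na(.data$context))
  model <- usable |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(ref_mean = mean(.data$mean_logipd),
                     ref_sd = sqrt(mean(.data$sd_logipd^2)),
                     n_positions = dplyr::n(), .groups = "drop")
  structure(model,
            k = k,
            fallback_mean = mean(usable$mean_logipd),
            fallback_sd = sqrt(mean(usable$sd_logipd^2)),
            class = c("context_model", class(model)))
}

# reference means for arbitrary contexts, falling back for unseen/NA
context_ref_mean <- function(model, contexts) {
  out <- model$ref_mean[match(contexts, model$context)]
  out[is.na(out)] <- attr(model, "fallback_mean")
  out
}

#' Phred-scaled kinetic modification score
#'
#' One-sided one-sample t test of the observed per-position log-IPDs
#' against the context reference mean: `t = (mean_logipd - ref_mean) /
#' (sd_logipd / sqrt(n_obs))`, upper-tail p under Student t with
#' `n_obs - 1` df, reported as `-10 log10(p)` and capped (p can underflow
#' far below double precision at strong m6A signals). Reference uncertainty
#' is ignored; the reference is trained on orders of magnitude more
#' positions than any single test. Positions with `n_obs < 2` get `NA`.
#'
#' @param n_obs,mean_logipd,sd_logipd per-position summaries (vectorized).
#' @param ref_mean context reference mean(s).
#' @param cap maximum score.
#' @return numeric score vector, `0 <= score <= cap`.
#' @examples
#' kinetic_score(25, 0, 1, 0) # p = 0.5 -> 3.0103
#' @export
kinetic_score <- function(n_obs, mean_logipd, sd_logipd, ref_mean, cap = 1000) {
  n <- max(length(n_obs), length(mean_logipd), length(sd_logipd),
           length(ref_mean))
  n_obs <- rep_len(n_obs, n); mean_logipd <- rep_len(mean_logipd, n)
  sd_logipd <- rep_len(sd_logipd, n); ref_mean <- rep_len(ref_mean, n)
  t_stat <- (mean_logipd - ref_mean) / (sd_logipd / sqrt(n_obs))
  ok <- n_obs >= 2 & !is.na(t_stat)
  score <- rep(NA_real_, n)
  score[ok] <- pmin(-10 * stats::pt(t_stat[ok], df = n_obs[ok] - 1,
                                    lower.tail = FALSE, log.p = TRUE) /
                      log(10), cap)
  score
}

#' Genome-wide detection of modified positions
#'
#' Scores every sufficiently covered A/C position on both strands against
#' the context model and returns those at or above the score floor, sorted
#' by descending score with deterministic ties (contig, position, strand).
#' Scoring is restricted to A and C because the target chemistries (m6A,
#' m4C, m5C) modify those bases; set `bases` to score everything.
#'
#' @param tracks kinetics tracks of the sample.
#' @param genome a `DNAStringSet` genome.
#' @param model a [build_context_model()] reference.
#' @param min_coverage minimum `n_obs` per strand for a position to be
#'   scored (positions with `n_obs < 2` are never scored).
#' @param score_floor minimum reported score; the default 20 corresponds
#'   to p = 0.01, before refinement by [select_threshold()].
#' @param bases bases (on the read strand) eligible for scoring.
#' @return a tibble `(contig, position, strand, base, score, n_obs,
#'   ipd_ratio)`; `ipd_ratio = exp(mean_logipd - ref_mean)`.
#' @export
detect_modifications <- function(tracks, genome, model, min_coverage = 10L,
                                 score_floor = 20, bases = c("A", "C")) {
  cand <- dplyr::filter(tracks, .data$n_obs >= max(2L, min_coverage),
                        .data$base %in% bases, !is.na(.data$mean_logipd),
                        !is.na(.data$sd_logipd), .data$sd_logipd > 0)
  if (nrow(cand) == 0) {
    return(tibble::tibble(contig = character(), position = integer(),
                          strand = character(), base = character(),
                          score = double(), n_obs = integer(),
                          ipd_ratio = double()))
  }
  ctx <- position_contexts(genome, cand$contig, cand$position, cand$strand,
                           attr(model, "k"))
  ref <- context_ref_mean(model, ctx)
  cand |>
    dplyr::mutate(score = kinetic_score(.data$n_obs, .data$mean_logipd,
                                        .data$sd_logipd, ref),
                  ipd_ratio = exp(.data$mean_logipd - ref)) |>
    dplyr::filter(!is.na(.data$score), .data$score >= score_floor) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$contig, .data$position,
                   .data$strand == "-") |>
    dplyr::select("contig", "position", "strand", "base", "score",
                  "n_obs", "ipd_ratio")
}

#' Select the top-scoring kinetic hits
#'
#' The motif-discovery input: the first `n` records of the (already sorted)
#' detection output; fewer if fewer exist. Tie order is the deterministic
#' detection order.
#'
#' @param records detection records from [detect_modifications()].
#' @param n number of hits to keep (1000 in the standard workflow).
#' @return the top records, same columns.
#' @export
top_hits <- function(records, n = 1000L) {
  records |>
    dplyr::arrange(dplyr::desc(.data$score), .data$contig, .data$position,
                   .data$strand == "-") |>
    dplyr::slice_head(n = n)
}

#' Find zero-coverage gaps
#'
#' Maximal runs of positions with no reads on either strand, at least
#' `min_len` long -- deletions relative to the reference, or assembly gaps,
#' show up this way. Positions absent from the track table count as zero
#' coverage.
#'
#' @param tracks kinetics tracks.
#' @param genome a `DNAStringSet` genome (supplies contig lengths).
#' @param min_len minimum gap length to report.
#' @return a tibble `(contig, start, end, length)` with 1-based closed
#'   intervals, sorted by contig then start.
#' @export
find_coverage_gaps <- function(tracks, genome, min_len = 100L) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  purrr::imap(lens, function(len, id) {
    cov <- numeric(len)
    tr <- dplyr::filter(tracks, .data$contig == id, .data$n_obs > 0)
    if (nrow(tr) > 0) {
      agg <- tapply(tr$n_obs, tr$position, sum)
      cov[as.integer(names(agg))] <- agg
    }
    r <- rle(cov == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    tibble::tibble(contig = id, start = starts[keep], end = ends[keep],
                   length = r$lengths[keep])
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$contig, .data$start)
}
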