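#' Select the kinetic-score threshold by the unassigned-fraction rule
#'
#' The reporting threshold is the minimal score (i.e. the largest retained
#' hit set) such that among hits scoring at or above it, the fraction not
#' assigned to any recognition motif is at most `target_unassigned` -- 1%
#' in the standard workflow, relaxed to 5% for m4C-dominated methylomes
#' whose weaker signals blur into the noise floor. The target is an
#' inequality: exact equality is generally unattainable on a discrete score
#' set. If no cut satisfies it, `Inf` is returned with a warning and
#' downstream summaries are empty rather than wrong.
#'
#' @param records detection records carrying an `assigned` logical column
#'   (see [assign_hits()]).
#' @param target_unassigned maximum tolerated unassigned fraction.
#' @return the score threshold (scalar; `Inf` if unattainable).
#' @examples
#' rec <- tibble::tibble(score = c(100, 90, 80, 70, 60, 50),
#'                       assigned = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
#' select_threshold(rec, 0.2) # 50: 1/6 unassigned
#' @export
select_threshold <- function(records, target_unassigned = 0.01) {
  if (nrow(records) == 0) stop("no detection records", call. = FALSE)
  stopifnot("assigned" %in% names(records))
  ord <- order(-records$score)
  score <- records$score[ord]
  unassigned <- !records$assigned[ord]
  n <- length(score)
  cum_un <- cumsum(unassigned)
  # valid cut points: after the last record of each distinct score
  boundary <- c(score[-n] > score[-1], TRUE)
  feasible <- boundary & (cum_un / seq_len(n) <= target_unassigned)
  if (!any(feasible)) {
    warning("no threshold attains unassigned fraction <= ",
            target_unassigned, "; returning Inf", call. = FALSE)
    return(Inf)
  }
  score[max(which(feasible))]
}

#' Per-motif extent of methylation
#'
#' For each motif: how many of its genomic positions carry a detected call
#' at or above the threshold. Denominators are per-strand methylatable
#' positions (both strands of a palindromic site count separately, matching
#' the strand-resolved kinetic calls); duplex placement counts are also
#' returned for the alternative convention.
#'
#' @param genome a `DNAStringSet` genome.
#' @param motifs a motif table.
#' @param records detection records.
#' @param threshold reporting score threshold (from [select_threshold()]).
#' @return a tibble `(pattern, offset, mod_type, n_detected, n_sites,
#'   n_duplex, fraction, mean_score)`.
#' @export
methylation_extent <- function(genome, motifs, records, threshold = -Inf) {
  retained <- dplyr::filter(records, .data$score >= threshold)
  key <- paste(retained$contig, retained$position, retained$strand)
  purrr::pmap(motifs[c("pattern", "offset", "mod_type")],
              function(pattern, offset, mod_type) {
    sites <- scan_pattern(genome, pattern, offset)
    counts <- count_motif_sites(genome, pattern, offset)
    hit <- paste(sites$contig, sites$position, sites$strand) %in% key
    det <- retained[key %in% paste(sites$contig, sites$position, sites$strand), ]
    tibble::tibble(
      pattern = pattern, offset = offset, mod_type = mod_type,
      n_detected = sum(hit), n_sites = nrow(sites),
      n_duplex = counts$n_duplex,
      fraction = if (nrow(sites) > 0) sum(hit) / nrow(sites) else NA_real_,
      mean_score = if (nrow(det) > 0) mean(det$score) else NA_real_)
  }) |> dplyr::bind_rows()
}

#' Group complementary-strand motifs into duplex specificities
#'
#' Two motifs describe the two strands of one double-strand specificity
#' when one's pattern is the reverse complement of the other's (they then
#' cover the same duplex placements, each methylating its own strand), as
#' in GG**A**TC / G**A**TCC. A self-reverse-complementary motif (e.g.
#' RG**A**TCY) is its own partner: every duplex occurrence is methylated on
#' both strands. Anything else is a single-strand (hemimethylating)
#' specificity. The partition is invariant under motif order.
#'
#' @param motifs a motif table.
#' @return `motifs` with columns `group`, `partner` (partner pattern or
#'   `NA`) and `double_strand` appended.
#' @export
pair_motifs <- function(motifs) {
  if (nrow(motifs) == 0) {
    return(dplyr::mutate(motifs, group = integer(), partner = character(),
                         double_strand = logical()))
  }
  rc <- revcomp_iupac(motifs$pattern)
  canon <- paste(pmin(motifs$pattern, rc), motifs$mod_type)
  group <- match(canon, unique(canon))
  partner <- rep(NA_character_, nrow(motifs))
  double_strand <- logical(nrow(motifs))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) >= 2L) {
      # complementary pair (first two; duplicates beyond that stay grouped)
      i <- idx[1]
      j <- idx[which(motifs$pattern[idx] == rc[i])[1]]
      if (!is.na(j)) {
        partner[i] <- motifs$pattern[j]
        partner[j] <- motifs$pattern[i]
        double_strand[idx] <- TRUE
      }
    } else if (motifs$pattern[idx] == rc[idx]) {
      partner[idx] <- motifs$pattern[idx] # self-complementary
      double_strand[idx] <- TRUE
    }
  }
  dplyr::mutate(motifs, group = group, partner = partner,
                double_strand = double_strand)
}

#' Heuristic restriction-modification system type call
#'
#' Structure-based rules: bipartite recognition sequences methylated on
#' both strands are the signature of Type I systems; contiguous
#' double-strand sites of Type II; contiguous single-strand
#' (hemimethylating) sites of Type III or Type IIG MTases; a bipartite
#' single-strand site fits no canonical class and is flagged. The rules are
#' heuristics -- e.g. a Type IIG enzyme that methylates both strands of a
#' bipartite-looking site will be labelled Type I.
#'
#' @param pattern motif pattern(s).
#' @param double_strand logical, methylated on both strands (vectorized).
#' @return character vector of calls: `"TypeI"`, `"TypeII"`,
#'   `"TypeIII_or_IIG"`, `"unclassified"`.
#' @export
classify_rm_type <- function(pattern, double_strand) {
  bip <- is_bipartite(pattern)
  dplyr::case_when(
    bip & double_strand ~ "TypeI",
    !bip & double_strand ~ "TypeII",
    !bip & !double_strand ~ "TypeIII_or_IIG",
    .default = "unclassified"
  )
}

#' Build the methylome summary table
#'
#' One row per motif: genome-wide site counts, detected counts and extent
#' of methylation at the reporting threshold, strand partner, and the RM
#' system type call of its duplex group. Rows are ordered by descending
#' per-strand site count (ties by pattern), so reruns on identical inputs
#' are byte-identical.
#'
#' @param genome a `DNAStringSet` genome.
#' @param motifs a motif table (candidates from [discover_motifs()] or
#'   known motifs); paired columns are added if absent.
#' @param records detection records.
#' @param threshold reporting score threshold.
#' @return a `MotifSummary` tibble: `(pattern, offset, mod_type, group,
#'   partner, double_strand, rm_type, n_sites, n_duplex, n_detected,
#'   fraction, mean_score)`.
#' @export
build_summary <- function(genome, motifs, records, threshold = -Inf) {
  if (!"double_strand" %in% names(motifs)) motifs <- pair_motifs(motifs)
  ext <- methylation_extent(genome, motifs, records, threshold)
  motifs |>
    dplyr::select(dplyr::any_of(c("pattern", "offset", "mod_type", "group",
                                  "partner", "double_strand"))) |>
    dplyr::left_join(ext, by = c("pattern", "offset", "mod_type")) |>
    dplyr::mutate(rm_type = classify_rm_type(.data$pattern,
                                             .data$double_strand)) |>
    dplyr::arrange(dplyr::desc(.data$n_sites), .data$pattern) |>
    dplyr::select("pattern", "offset", "mod_type", "group", "partner",
                  "double_strand", "rm_type", "n_sites", "n_duplex",
                  "n_detected", "fraction", "mean_score")
}
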