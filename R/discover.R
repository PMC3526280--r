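#' Tuning parameters for motif discovery
#'
#' @param min_support minimum number of windows a candidate must explain.
#' @param enrich_floor minimum observed/expected enrichment of a candidate.
#' @param gain_floor minimum fraction of newly explained windows for a
#'   single-position IUPAC generalization to be accepted.
#' @param alpha familywise significance level for seed acceptance
#'   (Bonferroni-corrected over every enumerated seed).
#' @param k_range lengths of contiguous seed words.
#' @param half_range half-site lengths for spaced-dyad (bipartite) seeds.
#' @param spacer_range nonspecific spacer lengths for dyad seeds; chosen as
#'   a superset of the 5-8 nt typical of Type I sites so short half-sites
#'   next to the spacer remain reachable.
#' @param cover_frac a flanking column is absorbed into the motif with the
#'   minimal IUPAC code whose bases cover at least this fraction of
#'   supporting windows (never N).
#' @param split_freq if no small code covers the column, a single base this
#'   frequent (and at least twice its background frequency) extends the
#'   motif and splits off the non-matching windows -- this is what separates
#'   the two strand-specific motifs of an asymmetric double-strand site.
#' @param max_iter cap on refinement steps per candidate.
#' @param max_motifs cap on emitted candidates per run.
#' @return a list of class `discovery_params`.
#' @export
discovery_params <- function(min_support = 20L, enrich_floor = 10,
                             gain_floor = 0.05, alpha = 0.01,
                             k_range = 4:8, half_range = 2:5,
                             spacer_range = 4:9, cover_frac = 0.9,
                             split_freq = 0.4, max_iter = 40L,
                             max_motifs = 12L) {
  structure(as.list(environment()), class = "discovery_params")
}

BASES <- c("A", "C", "G", "T")

# genome order-0 background base probabilities
genome_base_freq <- function(genome) {
  counts <- colSums(Biostrings::letterFrequency(genome, BASES))
  counts / sum(counts)
}

# membership lookup with an explicit N *observation* column that matches
# nothing (window padding)
.mem5 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      mm <- iupac_membership_matrix()
      m <<- cbind(mm, N = FALSE)
    }
    m
  }
})

# log10 upper-tail binomial probability P(X >= obs), X ~ Bin(n, p)
log10_binom_tail <- function(obs, n, p) {
  stats::pbinom(obs - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# probability that a random window matches the non-N columns of a motif:
# product of per-column code mass under the genome background, except the
# center column which uses the empirical center-base distribution of the
# windows (windows are centered on called bases by construction)
motif_null_prob <- function(codes, offs, q, pc) {
  p <- 1
  for (j in seq_along(codes)) {
    if (codes[j] == "N") next
    dist <- if (offs[j] == 0) pc else q
    p <- p * sum(dist[IUPAC_SETS[[codes[j]]]])
  }
  p
}

# logical match of every row of char matrix Wa against (offs, codes)
match_windows <- function(Wa, cc, offs, codes) {
  mem <- .mem5()
  ok <- rep(TRUE, nrow(Wa))
  for (j in seq_along(codes)) {
    if (codes[j] == "N") next
    ok <- ok & mem[codes[j], Wa[, cc + offs[j]]]
  }
  ok
}

# enumerate contiguous-word and spaced-dyad seeds among the active windows;
# returns one row per distinct (pattern, start offset) with its window count
enumerate_seeds <- function(Wa, cc, params) {
  n_act <- nrow(Wa)
  width <- ncol(Wa)
  res <- list()
  add <- function(cols, start_off, spacer_at = NULL, spacer_len = 0L) {
    str <- do.call(paste0, lapply(cols, function(j) Wa[, j]))
    valid <- !grepl("N", str, fixed = TRUE) # contig-edge padding in a half-site
    if (spacer_len > 0L) {
      # insert the N-run between the two half-sites
      str <- paste0(substr(str, 1L, spacer_at), strrep("N", spacer_len),
                    substring(str, spacer_at + 1L))
    }
    tab <- table(str[valid])
    if (length(tab) == 0) return()
    res[[length(res) + 1L]] <<- tibble::tibble(
      pattern = names(tab), start_off = start_off, obs = as.integer(tab))
  }
  for (k in params$k_range) {
    for (ca in seq_len(k)) {
      cols <- (cc - ca + 1L):(cc - ca + k)
      if (cols[1] < 1L || cols[k] > width) next
      add(cols, start_off = 1L - ca)
    }
  }
  for (la in params$half_range) for (lb in params$half_range) {
    for (sp in params$spacer_range) {
      span <- la + sp + lb
      for (ca in seq_len(la)) { # center inside half-site A
        startA <- 1L - ca
        colsA <- (cc + startA):(cc + startA + la - 1L)
        colsB <- (cc + startA + la + sp):(cc + startA + span - 1L)
        if (colsA[1] < 1L || colsB[lb] > width) next
        add(c(colsA, colsB), start_off = startA,
            spacer_at = la, spacer_len = sp)
      }
      for (cb in seq_len(lb)) { # center inside half-site B
        startB <- 1L - cb
        startA <- startB - sp - la
        colsA <- (cc + startA):(cc + startA + la - 1L)
        colsB <- (cc + startB):(cc + startB + lb - 1L)
        if (colsA[1] < 1L || colsB[lb] > width) next
        add(c(colsA, colsB), start_off = startA,
            spacer_at = la, spacer_len = sp)
      }
    }
  }
  dplyr::bind_rows(res) |>
    dplyr::distinct(.data$pattern, .data$start_off, .keep_all = TRUE)
}

# Greedy refinement of a seed into a degenerate motif (see vignette).
# Moves, tried in priority order each step until none applies:
#   1. extension -- absorb an informative flanking column (at most 2-fold
#      degenerate, or a single-base "split" that specializes away an
#      unrelated window family sharing the seed core);
#   2. tighten -- specialize an informative interior spacer column (a coarse
#      dyad seed can win with part of a half-site inside its N-run);
#   3. generalization -- widen one position by one base, accepted while it
#      gains >= gain_floor new windows, stays >= enrich_floor enriched, and
#      the base shows at least background-level evidence in the freed
#      column (which stops remerging of families a split separated).
# Extension precedes generalization so that shared cores (e.g. the AA of
# RAATTY / GKAAYG / TAAY...) are specialized into full-length motifs before
# any widening can fuse the families.
refine_motif <- function(Wa, cc, seed, q, pc, params) {
  chars <- iupac_chars(seed$pattern)
  offs <- seed$start_off + seq_along(chars) - 1L
  codes <- chars
  n_act <- nrow(Wa)
  width <- ncol(Wa)
  center_j <- which(offs == 0L)
  stopifnot(length(center_j) == 1L)

  support <- match_windows(Wa, cc, offs, codes)
  cnt <- sum(support)

  col_freq <- function(j_col, rows) {
    chs <- Wa[rows, j_col]
    chs <- chs[chs %in% BASES]
    if (length(chs) < params$min_support) return(NULL)
    stats::setNames(
      as.numeric(table(factor(chs, levels = BASES))) / length(chs), BASES)
  }

  try_extend <- function(off_new) {
    col <- cc + off_new
    if (col < 1L || col > width) return(NULL)
    freq <- col_freq(col, support)
    if (is.null(freq)) return(NULL)
    # extension admits at most 2-fold degeneracy; broader codes only ever
    # arise through the tighten/generalization passes, which keeps
    # mask-induced composition bias from fabricating near-N flank columns
    inc <- BASES[freq >= 0.2]
    code <- NULL
    if (length(inc) %in% 1:2 && sum(freq[inc]) >= params$cover_frac) {
      code <- iupac_code_for(inc)
    } else {
      top <- BASES[which.max(freq)]
      if (freq[top] >= max(params$split_freq, 2 * q[top])) {
        code <- top # specialize: split off the non-matching windows
      }
    }
    if (is.null(code)) return(NULL)
    if (off_new < min(offs)) {
      offs2 <- c(off_new, offs); codes2 <- c(code, codes)
    } else {
      offs2 <- c(offs, off_new); codes2 <- c(codes, code)
    }
    cnt2 <- sum(match_windows(Wa, cc, offs2, codes2))
    if (cnt2 < params$min_support) return(NULL)
    p0 <- motif_null_prob(codes2, offs2, q, pc)
    if (cnt2 / (n_act * p0) < params$enrich_floor) return(NULL)
    list(offs = offs2, codes = codes2, cnt = cnt2,
         log10p = log10_binom_tail(cnt2, n_act, p0))
  }

  tighten_move <- function() {
    best <- NULL
    for (j in which(codes == "N")) {
      freq <- col_freq(cc + offs[j], support)
      if (is.null(freq)) next
      inc <- BASES[freq >= 0.8 * q]
      if (!length(inc) %in% 1:3) next
      cov <- sum(freq[inc])
      # a genuine 3-base column excludes its fourth base almost entirely;
      # a random spacer column can reach ~90% cover by sampling noise but
      # not ~97%, so 3-base codes carry a stricter bar
      need <- if (length(inc) == 3L) max(params$cover_frac, 0.97) else params$cover_frac
      if (cov < need) next
      if (is.null(best) || cov > best$cov + 1e-12) {
        best <- list(j = j, code = iupac_code_for(inc), cov = cov)
      }
    }
    if (is.null(best)) return(NULL)
    new_codes <- codes
    new_codes[best$j] <- best$code
    new_sup <- match_windows(Wa, cc, offs, new_codes)
    if (sum(new_sup) < params$min_support) return(NULL)
    list(codes = new_codes, cnt = sum(new_sup))
  }

  generalize_move <- function() {
    best <- NULL
    for (j in seq_along(codes)) {
      if (codes[j] == "N" || j == center_j) next
      cur_set <- IUPAC_SETS[[codes[j]]]
      if (length(cur_set) >= 3L) next # N is never reached by widening
      # evidence for each candidate base: free position j and look at its
      # column among the remaining matches -- a base that truly belongs to
      # a degenerate position is ~background-frequent or better there,
      # while bases that would merely merge an unrelated family are rare
      free_codes <- codes
      free_codes[j] <- "N"
      free_sup <- match_windows(Wa, cc, offs, free_codes)
      colc <- Wa[free_sup, cc + offs[j]]
      colc <- colc[colc %in% BASES]
      if (length(colc) == 0) next
      for (b in setdiff(BASES, cur_set)) {
        if (mean(colc == b) < 0.8 * q[b]) next
        new_codes <- codes
        new_codes[j] <- iupac_code_for(c(cur_set, b))
        new_cnt <- sum(match_windows(Wa, cc, offs, new_codes))
        gain <- (new_cnt - cnt) / cnt
        if (gain < params$gain_floor) next
        enr <- new_cnt / (n_act * motif_null_prob(new_codes, offs, q, pc))
        if (enr < params$enrich_floor) next
        if (is.null(best) || gain > best$gain + 1e-12) {
          best <- list(codes = new_codes, cnt = new_cnt, gain = gain)
        }
      }
    }
    best
  }

  for (iter in seq_len(params$max_iter)) {
    ext <- purrr::compact(list(try_extend(min(offs) - 1L),
                               try_extend(max(offs) + 1L)))
    if (length(ext) > 0) {
      pick <- ext[[which.min(vapply(ext, `[[`, 0, "log10p"))]]
      offs <- pick$offs; codes <- pick$codes; cnt <- pick$cnt
      support <- match_windows(Wa, cc, offs, codes)
      next
    }
    tight <- tighten_move()
    if (!is.null(tight)) {
      codes <- tight$codes
      cnt <- tight$cnt
      support <- match_windows(Wa, cc, offs, codes)
      next
    }
    gen <- generalize_move()
    if (!is.null(gen)) {
      codes <- gen$codes
      cnt <- gen$cnt
      support <- match_windows(Wa, cc, offs, codes)
      next
    }
    break
  }

  # trim uninformative (N) edge positions
  keep <- which(codes != "N")
  if (length(keep) > 0) {
    rng <- keep[1]:keep[length(keep)]
    codes <- codes[rng]
    offs <- offs[rng]
    support <- match_windows(Wa, cc, offs, codes)
    cnt <- sum(support)
  }

  p0 <- motif_null_prob(codes, offs, q, pc)
  list(pattern = paste(codes, collapse = ""),
       offset = which(offs == 0L),
       support = cnt,
       p0 = p0,
       enrichment = cnt / (n_act * p0),
       log10p = log10_binom_tail(cnt, n_act, p0),
       mask = support)
}

#' Discover IUPAC recognition motifs from hit windows
#'
#' The consensus-motif engine: iteratively (1) enumerate candidate seeds --
#' every contiguous 4-8-mer covering the center and every spaced dyad
#' (half-sites 2-5 nt, spacer 4-9 nt, center inside a half-site) observed
#' in the windows; (2) score each seed by the upper-tail binomial
#' probability of its window count against the genome-composition
#' background (the center column is scored against the empirical
#' center-base distribution, since windows are centered on called bases by
#' construction); (3) refine the most significant seed by greedy IUPAC
#' generalization and flank extension; (4) emit the candidate, mask the
#' windows it explains, and repeat until no seed survives the
#' Bonferroni-corrected significance test, the support floor and the
#' enrichment floor. The methylated offset is the center position within
#' the emitted pattern; the modification type follows the center base (A ->
#' m6A, C -> m4C; m5C is not kinetically called genome-wide).
#'
#' Complementary-strand motifs of one double-strand specificity (e.g.
#' GGATC / GATCC) are emitted separately here -- kinetic signals are
#' per-strand -- and collapsed later by [pair_motifs()].
#'
#' @param windows a tibble with a `window` column ([extract_windows()]) or
#'   a character vector of equal-width odd-length windows.
#' @param genome a `DNAStringSet` genome (background composition).
#' @param params a [discovery_params()] list.
#' @return a candidate tibble `(pattern, offset, mod_type, name, support,
#'   n_windows, p0, enrichment, log10p)` -- `n_windows` and `p0` are the
#'   active-window count and per-window null probability the binomial
#'   p-value was computed against -- in discovery order; zero rows (with a
#'   warning if
#'   fewer than `min_support` windows were supplied) when nothing is found.
#' @export
discover_motifs <- function(windows, genome, params = discovery_params()) {
  win <- if (is.data.frame(windows)) windows$window else as.character(windows)
  empty <- tibble::tibble(pattern = character(), offset = integer(),
                          mod_type = character(), name = character(),
                          support = integer(), n_windows = integer(),
                          p0 = double(), enrichment = double(),
                          log10p = double())
  if (length(win) < params$min_support) {
    if (length(win) > 0) {
      warning("only ", length(win), " windows supplied (min_support = ",
              params$min_support, "); no motifs searched", call. = FALSE)
    }
    return(empty)
  }
  widths <- unique(nchar(win))
  stopifnot(length(widths) == 1L, widths %% 2 == 1)
  W <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
              nrow = length(win), byrow = TRUE)
  cc <- (widths + 1L) %/% 2L
  q <- genome_base_freq(genome)

  active <- rep(TRUE, length(win))
  out <- list()
  for (round in seq_len(params$max_motifs)) {
    if (sum(active) < params$min_support) break
    Wa <- W[active, , drop = FALSE]
    n_act <- nrow(Wa)
    pc_tab <- table(factor(Wa[, cc], levels = BASES)) / n_act
    pc <- stats::setNames(as.numeric(pc_tab), BASES)

    seeds <- enumerate_seeds(Wa, cc, params)
    if (nrow(seeds) == 0) break
    m_tests <- nrow(seeds)
    seeds$p0 <- vapply(seq_len(m_tests), function(i) {
      chars <- iupac_chars(seeds$pattern[i])
      motif_null_prob(chars, seeds$start_off[i] + seq_along(chars) - 1L, q, pc)
    }, 0)
    seeds$enrichment <- seeds$obs / (n_act * seeds$p0)
    cand <- seeds[seeds$obs >= params$min_support &
                    seeds$enrichment >= params$enrich_floor, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand$log10p <- log10_binom_tail(cand$obs, n_act, cand$p0)
    thresh <- log10(params$alpha) - log10(m_tests)
    cand <- cand[cand$log10p <= thresh, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- cand[order(cand$log10p, cand$pattern), , drop = FALSE]

    ref <- refine_motif(Wa, cc, cand[1, ], q, pc, params)
    if (ref$support < params$min_support) break
    center_base <- substr(ref$pattern, ref$offset, ref$offset)
    out[[length(out) + 1L]] <- tibble::tibble(
      pattern = ref$pattern, offset = ref$offset,
      mod_type = if (center_base == "A") "m6A" else "m4C",
      name = ref$pattern, support = as.integer(ref$support),
      n_windows = n_act, p0 = ref$p0,
      enrichment = ref$enrichment, log10p = ref$log10p)
    active[active] <- !ref$mask
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out) |>
    dplyr::distinct(.data$pattern, .data$offset, .keep_all = TRUE)
}

#' Assign kinetic hits to motifs
#'
#' A hit is assigned to the first motif (table order) whose pattern,
#' placed with its methylated offset on the hit's position and strand,
#' matches the genome. The remainder is the unassigned population whose
#' fraction drives [select_threshold()] and which is re-screened by
#' [residual_motif_check()].
#'
#' @param records detection records.
#' @param motifs a motif table (discovered candidates or known motifs).
#' @param genome a `DNAStringSet` genome.
#' @return `records` with columns `motif` (pattern or `NA`) and `assigned`.
#' @export
assign_hits <- function(records, motifs, genome) {
  assigned <- rep(NA_character_, nrow(records))
  if (!is.null(motifs) && nrow(motifs) > 0) {
    key <- paste(records$contig, records$position, records$strand)
    for (i in seq_len(nrow(motifs))) {
      todo <- is.na(assigned)
      if (!any(todo)) break
      sites <- scan_pattern(genome, motifs$pattern[i], motifs$offset[i])
      hit <- key %in% paste(sites$contig, sites$position, sites$strand)
      assigned[todo & hit] <- motifs$pattern[i]
    }
  }
  dplyr::mutate(records, motif = assigned, assigned = !is.na(assigned))
}

#' Re-screen unassigned hits for additional motifs
#'
#' The confirmation step on the residual population left unassigned at the
#' chosen threshold: the same discovery algorithm is run on those windows
#' alone. A clean methylome analysis returns zero rows; anything found
#' indicates an active specificity that the main pass missed.
#'
#' @param windows windows of the unassigned, above-threshold hits.
#' @inheritParams discover_motifs
#' @return a candidate tibble as in [discover_motifs()].
#' @export
residual_motif_check <- function(windows, genome, params = discovery_params()) {
  n <- if (is.data.frame(windows)) nrow(windows) else length(windows)
  if (n == 0) {
    return(discover_motifs(character(0), genome, params))
  }
  discover_motifs(windows, genome, params)
}
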