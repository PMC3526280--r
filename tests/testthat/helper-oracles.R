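# Independent brute-force oracles, deliberately naive.

# all (1-based) start positions of any expansion of `pattern` in `seq`,
# overlapping occurrences included
oracle_find_starts <- function(seq, pattern) {
  words <- expand_iupac(pattern)
  L <- nchar(pattern)
  n <- nchar(seq)
  if (n < L) return(integer(0))
  starts <- integer(0)
  for (s in seq_len(n - L + 1L)) {
    if (substr(seq, s, s + L - 1L) %in% words) starts <- c(starts, s)
  }
  starts
}

# naive both-strand site scan: returns tibble(position, strand) of the
# methylated base for a single linear contig
oracle_scan <- function(seq, pattern, offset) {
  L <- nchar(pattern)
  plus <- oracle_find_starts(seq, pattern) + offset - 1L
  minus <- oracle_find_starts(seq, revcomp_iupac(pattern)) + (L - offset)
  dplyr::arrange(
    tibble::tibble(position = as.integer(c(plus, minus)),
                   strand = rep(c("+", "-"), c(length(plus), length(minus)))),
    position, strand == "-")
}

# log10 of the upper-tail binomial probability by direct summation of
# dbinom terms in log space (log-sum-exp)
oracle_log10_binom_tail <- function(obs, n, p) {
  k <- obs:n
  lp <- stats::dbinom(k, n, p, log = TRUE)
  m <- max(lp)
  (m + log(sum(exp(lp - m)))) / log(10)
}

# uniform random A/C/G/T windows of odd width centered on a fixed base
random_windows <- function(n, width = 41L, center_base = "A", seed = 1L) {
  withr::with_seed(seed, {
    w <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, "")
    substr(w, (width + 1L) %/% 2L, (width + 1L) %/% 2L) <- center_base
    w
  })
}

tiny_genome <- function(seq, id = "c1", circular = FALSE) {
  if (is.null(names(seq))) seq <- stats::setNames(seq, rep_len(id, length(seq)))
  g <- Biostrings::DNAStringSet(seq)
  set_genome_circular(g, circular)
}
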