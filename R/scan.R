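#' Scan a genome for occurrences of an IUPAC pattern
#'
#' Finds every position whose strand carries the methylated base of the
#' pattern. A site's strand is the strand of the methylated base and the
#' pattern is always read 5'->3' on that strand, matching the per-strand
#' nature of sequencing kinetic signals. Minus-strand matching is performed
#' by locating the reverse-complement pattern on the plus strand and mapping
#' the offset back: a minus-strand site at plus-coordinate `p` means the
#' pattern, read 5'->3' on the minus strand, has its methylated base opposite
#' `p`. All overlapping occurrences are reported; circular contigs wrap
#' across the origin.
#'
#' @param genome a `DNAStringSet` genome.
#' @param pattern IUPAC pattern.
#' @param offset 1-based offset of the methylated base within `pattern`.
#' @return a tibble `(contig, position, strand)` sorted by contig, position,
#'   then strand (`+` before `-`); positions are 1-based.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "AAGATCAA"))
#' scan_pattern(g, "GATC", 2) # + site at 4, - site at 5
#' @export
scan_pattern <- function(genome, pattern, offset) {
  chars <- iupac_chars(pattern)
  L <- length(chars)
  offset <- as.integer(offset)
  stopifnot(offset >= 1, offset <= L)
  rc <- revcomp_iupac(pattern)
  circ <- genome_circular(genome)

  per_contig <- purrr::imap(as.character(genome), function(seq, id) {
    len <- nchar(seq)
    subject <- if (isTRUE(circ[[id]]) && len > 1L) {
      paste0(seq, substr(seq, 1L, min(L - 1L, len)))
    } else {
      seq
    }
    find_starts <- function(pat) {
      if (L > nchar(subject)) return(integer(0))
      s <- Biostrings::start(Biostrings::matchPattern(
        pat, Biostrings::DNAString(subject), fixed = FALSE))
      s[s <= len] # a start beyond len duplicates a wrap already seen
    }
    plus <- find_starts(pattern) + offset - 1L
    minus <- find_starts(rc) + (L - offset)
    tibble::tibble(
      contig = id,
      position = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus)))
    ) |>
      dplyr::mutate(position = ((.data$position - 1L) %% len) + 1L) |>
      dplyr::distinct()
  })

  dplyr::bind_rows(per_contig) |>
    dplyr::arrange(.data$contig, .data$position, .data$strand == "-")
}

#' Scan a genome for a table of motifs
#'
#' @param genome a `DNAStringSet` genome.
#' @param motifs a motif table (see [motif_tbl()]).
#' @return a tibble of sites `(contig, position, strand, pattern, offset,
#'   mod_type, name)`, all overlapping occurrences of all motifs.
#' @export
scan_motifs <- function(genome, motifs) {
  validate_motifs(motifs)
  purrr::pmap(motifs[c("pattern", "offset", "mod_type", "name")],
              function(pattern, offset, mod_type, name) {
    scan_pattern(genome, pattern, offset) |>
      dplyr::mutate(pattern = pattern, offset = offset,
                    mod_type = mod_type, name = name)
  }) |>
    dplyr::bind_rows()
}

#' Does a pattern match at a given position and strand?
#'
#' True iff placing `pattern` so that its `offset`-th base lands on
#' `(position, strand)` matches the genome, reading the pattern 5'->3' on
#' that strand. Placements running off a linear contig end are `FALSE`;
#' circular contigs wrap. This is the predicate used to assign kinetic hits
#' to discovered motifs. Vectorized over `contig`/`position`/`strand`.
#'
#' @param genome a `DNAStringSet` genome.
#' @param contig,position,strand site coordinates (1-based position; strand
#'   `"+"` or `"-"`).
#' @param pattern,offset the motif.
#' @return logical vector.
#' @export
matches_at <- function(genome, contig, position, strand, pattern, offset) {
  chars <- iupac_chars(pattern)
  L <- length(chars)
  stopifnot(offset >= 1, offset <= L)
  rc_chars <- iupac_chars(revcomp_iupac(pattern))
  circ <- genome_circular(genome)
  seqs <- as.character(genome)
  lens <- stats::setNames(nchar(seqs), names(genome))

  n <- max(length(contig), length(position), length(strand))
  contig <- rep_len(contig, n); position <- rep_len(as.integer(position), n)
  strand <- rep_len(strand, n)

  vapply(seq_len(n), function(i) {
    seq <- seqs[[contig[i]]]
    len <- lens[[contig[i]]]
    if (is.na(position[i]) || position[i] < 1L || position[i] > len) return(FALSE)
    # plus-strand projection of the placement
    if (strand[i] == "+") {
      start <- position[i] - offset + 1L
      want <- chars
    } else {
      start <- position[i] - (L - offset)
      want <- rc_chars
    }
    idx <- start:(start + L - 1L)
    if (isTRUE(circ[[contig[i]]])) {
      idx <- ((idx - 1L) %% len) + 1L
    } else if (idx[1] < 1L || idx[L] > len) {
      return(FALSE)
    }
    got <- strsplit(paste(substring(seq, idx, idx), collapse = ""), "")[[1]]
    all(mapply(iupac_contains, want, got))
  }, NA)
}

#' Per-strand and duplex site counts for a motif
#'
#' Genome-wide denominators for extent-of-methylation. `n_strand` counts
#' methylatable positions per strand (both strands of a palindromic site
#' count as two); `n_duplex` counts distinct duplex placements of the
#' recognition sequence irrespective of strand. Both conventions are exposed
#' because published per-motif totals do not always state which was used.
#'
#' @inheritParams scan_pattern
#' @return a one-row tibble `(pattern, n_strand, n_duplex)`.
#' @export
count_motif_sites <- function(genome, pattern, offset) {
  sites <- scan_pattern(genome, pattern, offset)
  rc <- revcomp_iupac(pattern)
  L <- nchar(pattern)
  # duplex placements: union of forward placements of the pattern and of its
  # reverse complement on the plus strand
  starts_plus <- dplyr::filter(sites, .data$strand == "+") |>
    dplyr::mutate(start = .data$position - offset + 1L)
  starts_minus <- dplyr::filter(sites, .data$strand == "-") |>
    dplyr::mutate(start = .data$position - (L - offset))
  duplex <- dplyr::bind_rows(
    starts_plus[c("contig", "start")], starts_minus[c("contig", "start")]
  ) |> dplyr::distinct()
  tibble::tibble(pattern = pattern, n_strand = nrow(sites), n_duplex = nrow(duplex))
}

#' Write motif sites as BED6
#'
#' One line per site: `chrom, start (0-based), end, name = pattern, score =
#' 0, strand`. The only place the package emits 0-based coordinates, per the
#' BED convention.
#'
#' @param sites a site tibble from [scan_motifs()] (columns `contig`,
#'   `position`, `strand`, and optionally `pattern`).
#' @param path output file.
#' @param extra_cols names of additional columns to append after strand
#'   (e.g. `"mod_type"` for truth sets).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, extra_cols = character(0)) {
  name <- if ("pattern" %in% names(sites)) sites$pattern else "."
  bed <- tibble::tibble(
    chrom = sites$contig,
    start = sites$position - 1L,
    end = sites$position,
    name = name,
    score = 0L,
    strand = sites$strand
  )
  for (col in extra_cols) bed[[col]] <- sites[[col]]
  atomic_write(path, function(tmp) {
    readr::write_tsv(bed, tmp, col_names = FALSE, progress = FALSE)
  })
  invisible(path)
}
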