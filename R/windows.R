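#' Extract strand-oriented sequence windows around kinetic hits
#'
#' For each detected position, the `2*flank + 1`-mer centered on the called
#' base, read 5'->3' on the called strand (minus-strand windows are
#' reverse-complemented), with N-padding where the window overhangs a
#' linear contig end. Motif discovery operates on these windows, so the
#' methylated base is always the center character.
#'
#' @param records detection records (`contig`, `position`, `strand`, ...).
#' @param genome a `DNAStringSet` genome.
#' @param flank half-width of the window (default 20, i.e. 41-mers).
#' @return `records` with a `window` column appended.
#' @export
extract_windows <- function(records, genome, flank = 20L) {
  seqs <- as.character(genome)
  padded <- stats::setNames(
    paste0(strrep("N", flank), seqs, strrep("N", flank)), names(seqs))
  win <- character(nrow(records))
  for (id in unique(records$contig)) {
    idx <- which(records$contig == id)
    p <- records$position[idx] # center sits at p + flank in padded coords
    win[idx] <- substring(padded[[id]], p, p + 2L * flank)
  }
  minus <- records$strand == "-"
  if (any(minus)) win[minus] <- revcomp_concrete(win[minus])
  dplyr::mutate(records, window = win)
}

#' Read/write hit windows as FASTA
#'
#' Interchange with external motif tools: one record per window, the
#' description line recording `contig:position:strand:score` of the
#' centered hit.
#'
#' @param windows a tibble with `window` plus the hit coordinates.
#' @param path file path.
#' @return `path` invisibly (writer); a windows tibble (reader).
#' @export
write_windows_fasta <- function(windows, path) {
  ids <- sprintf("%s:%d:%s:%.2f", windows$contig, windows$position,
                 windows$strand, windows$score)
  atomic_write(path, function(tmp) {
    readr::write_lines(paste0(">", ids, "\n", windows$window), tmp)
  })
  invisible(path)
}

#' @rdname write_windows_fasta
#' @export
read_windows_fasta <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  heads <- grepl("^>", lines)
  ids <- sub("^>", "", lines[heads])
  seq_idx <- cumsum(heads)
  seqs <- tapply(lines[!heads], seq_idx[!heads], paste, collapse = "")
  parts <- stringr::str_match(ids, "^(.*):(\\d+):([+-]):([0-9.]+)$")
  tibble::tibble(contig = parts[, 2], position = as.integer(parts[, 3]),
                 strand = parts[, 4], score = as.numeric(parts[, 5]),
                 window = unname(as.character(seqs)))
}
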