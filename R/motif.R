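#' Construct a table of methyltransferase recognition motifs
#'
#' A motif is a degenerate IUPAC pattern together with the 1-based offset of
#' the methylated base within it and the modification chemistry. Bipartite
#' (Type I style) recognition sequences are written as a single pattern with
#' an internal run of four or more N's separating the two half-sites, e.g.
#' `"CCACNNNNNNCTC"`.
#'
#' @param pattern IUPAC pattern(s), length >= 2.
#' @param offset 1-based position of the methylated base within `pattern`.
#'   Must be an `A` for `m6A` and a `C` for `m4C`/`m5C`.
#' @param mod_type one of `"m6A"`, `"m4C"`, `"m5C"` (recycled).
#' @param name optional motif label (defaults to the pattern).
#' @return a tibble with columns `pattern`, `offset`, `mod_type`, `name`,
#'   one row per motif. All motif-set arguments in this package take this
#'   shape, so motif tables pipe directly into [scan_motifs()] and
#'   [plant_methylation()].
#' @examples
#' motif_tbl(c("GGATC", "GATCC"), c(3, 2), "m6A")
#' @export
motif_tbl <- function(pattern, offset, mod_type = "m6A", name = pattern) {
  tbl <- tibble::tibble(
    pattern = toupper(as.character(pattern)),
    offset = as.integer(offset),
    mod_type = as.character(mod_type),
    name = as.character(name)
  )
  validate_motifs(tbl)
  tbl
}

#' Validate a motif table
#'
#' Checks the invariants every motif must satisfy: a valid IUPAC pattern of
#' length >= 2, an offset inside the pattern whose code is exactly the
#' methylatable base for the stated chemistry, and -- for bipartite patterns
#' (internal N-run of >= 4) -- half-sites of length >= 2 on both sides.
#'
#' @param motifs a data frame with columns `pattern`, `offset`, `mod_type`.
#' @return `motifs`, invisibly; errors describe the offending row.
#' @export
validate_motifs <- function(motifs) {
  stopifnot(is.data.frame(motifs))
  req <- c("pattern", "offset", "mod_type")
  missing_cols <- setdiff(req, names(motifs))
  if (length(missing_cols) > 0) {
    stop("motif table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(motifs))) {
    p <- motifs$pattern[i]
    off <- motifs$offset[i]
    mt <- motifs$mod_type[i]
    chars <- iupac_chars(p)
    if (length(chars) < 2L) stop("motif '", p, "': pattern length must be >= 2", call. = FALSE)
    if (is.na(off) || off < 1L || off > length(chars)) {
      stop("motif '", p, "': offset ", off, " outside pattern", call. = FALSE)
    }
    if (!mt %in% c("m6A", "m4C", "m5C")) {
      stop("motif '", p, "': unknown mod_type '", mt, "'", call. = FALSE)
    }
    want <- if (mt == "m6A") "A" else "C"
    if (chars[off] != want) {
      stop("motif '", p, "': base at offset ", off, " is '", chars[off],
           "' but mod_type ", mt, " requires '", want, "'", call. = FALSE)
    }
    bp <- bipartite_parts(p)
    if (!is.null(bp)) {
      if (nchar(bp$left) < 2L || nchar(bp$right) < 2L) {
        stop("motif '", p, "': bipartite half-sites must each be >= 2 nt", call. = FALSE)
      }
    }
  }
  invisible(motifs)
}

#' Decompose a bipartite pattern into half-sites and spacer
#'
#' A pattern is bipartite iff it contains an internal maximal run of four or
#' more N's; the half-sites are the flanks of that run. Contiguous patterns
#' return `NULL`.
#'
#' @param pattern a single IUPAC pattern.
#' @return `NULL`, or a list with `left`, `right` (half-site patterns) and
#'   `spacer` (N-run length).
#' @examples
#' bipartite_parts("CCACNNNNNNCTC")
#' @export
bipartite_parts <- function(pattern) {
  chars <- iupac_chars(pattern)
  runs <- rle(chars == "N")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  internal <- which(runs$values & runs$lengths >= 4L &
                      starts > 1L & ends < length(chars))
  if (length(internal) == 0L) return(NULL)
  # the maximal internal N-run (first if tied)
  k <- internal[which.max(runs$lengths[internal])]
  list(
    left = paste(chars[seq_len(starts[k] - 1L)], collapse = ""),
    right = paste(chars[(ends[k] + 1L):length(chars)], collapse = ""),
    spacer = runs$lengths[k]
  )
}

#' @rdname bipartite_parts
#' @return `is_bipartite()`: logical, vectorized over patterns.
#' @export
is_bipartite <- function(pattern) {
  vapply(pattern, function(p) !is.null(bipartite_parts(p)), NA, USE.NAMES = FALSE)
}
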