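#' IUPAC nucleotide ambiguity algebra
#'
#' The degenerate alphabet used to write methyltransferase recognition
#' sequences: each code denotes a set of bases (R = A/G, Y = C/T, W = A/T,
#' S = G/C, M = A/C, K = G/T, B/D/H/V = "not A/C/G/T", N = any).
#' These helpers are the algebraic core every scanner and the motif
#' discovery stage build on.
#'
#' @name iupac
NULL

# code -> character vector of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", M = "K", K = "M", S = "S", W = "W",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# reverse lookup: sorted concrete-base set (collapsed string) -> code
IUPAC_FROM_SET <- {
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(IUPAC_SETS), keys)
}

#' @param pattern a single IUPAC string.
#' @return `iupac_chars()`: the pattern split into single codes, with an
#'   informative error on any character outside the alphabet.
#' @rdname iupac
#' @keywords internal
iupac_chars <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, IUPAC_CODES)
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  chars
}

#' Reverse complement of an IUPAC pattern
#'
#' Base-wise IUPAC complement, then reversal, so the result reads 5'->3' on
#' the opposite strand. An involution: `revcomp_iupac(revcomp_iupac(p)) == p`.
#' Self-reverse-complementary patterns (e.g. `"RGATCY"`) are fixed points and
#' mark recognition sites methylatable on both strands by one specificity.
#'
#' @param pattern IUPAC string (vectorized).
#' @return character vector of reverse-complemented patterns.
#' @examples
#' revcomp_iupac("GGATC")  # "GATCC"
#' revcomp_iupac("RGATCY") # itself
#' @export
revcomp_iupac <- function(pattern) {
  vapply(pattern, function(p) {
    chars <- iupac_chars(p)
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Expand an IUPAC pattern into its concrete sequences
#'
#' The Cartesian product of the per-position base sets. Used as the
#' brute-force matching oracle and to instantiate degenerate sites in the
#' synthetic genome generator.
#'
#' @param pattern IUPAC string.
#' @param max_size guard on the expansion cardinality; exceeding it is an
#'   error (degenerate patterns grow as the product of set sizes).
#' @return character vector of concrete A/C/G/T strings.
#' @examples
#' expand_iupac("GCWGC") # GCAGC, GCTGC
#' @export
expand_iupac <- function(pattern, max_size = 4096L) {
  chars <- iupac_chars(pattern)
  sets <- IUPAC_SETS[chars]
  card <- prod(lengths(sets))
  if (card > max_size) {
    stop("expansion of '", pattern, "' has ", card,
         " sequences, exceeding max_size = ", max_size, call. = FALSE)
  }
  if (length(sets) == 0L) return(character(0))
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = ""))
}

#' @return `iupac_code_for()`: the single code denoting a set of concrete
#'   bases (e.g. `c("A","G")` -> `"R"`).
#' @param bases character vector of concrete bases.
#' @rdname iupac
#' @keywords internal
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_FROM_SET[[key]]
  if (is.null(code)) stop("no IUPAC code for base set {", key, "}", call. = FALSE)
  code
}

# logical: is each base of `bases` contained in the set of `code`? vectorized
# over bases for a single code.
iupac_contains <- function(code, bases) {
  bases %in% IUPAC_SETS[[code]]
}

# 15 x 4 membership matrix, rows = codes, cols = A,C,G,T.  Used for fast
# window-vs-motif matching in the discovery stage.
iupac_membership_matrix <- function() {
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = 4,
              dimnames = list(IUPAC_CODES, c("A", "C", "G", "T")))
  for (code in IUPAC_CODES) m[code, IUPAC_SETS[[code]]] <- TRUE
  m
}
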