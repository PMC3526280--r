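#' Genome I/O and simulation
#'
#' Genomes are held as [Biostrings::DNAStringSet] objects restricted to the
#' concrete alphabet A/C/G/T (ambiguity codes are rejected in genomes -- they
#' belong in motifs). Per-contig circularity is carried in the object's
#' metadata and honoured by the scanners.
#'
#' @name genome-io
NULL

#' @param genome a `DNAStringSet`.
#' @return `genome_circular()`: named logical, one flag per contig.
#' @rdname genome-io
#' @export
genome_circular <- function(genome) {
  circ <- S4Vectors::metadata(genome)$circular
  if (is.null(circ)) circ <- stats::setNames(rep(FALSE, length(genome)), names(genome))
  circ[names(genome)]
}

#' @param circular logical, one per contig (recycled).
#' @return `set_genome_circular()`: the genome with updated flags.
#' @rdname genome-io
#' @export
set_genome_circular <- function(genome, circular) {
  circular <- rep_len(circular, length(genome))
  S4Vectors::metadata(genome)$circular <- stats::setNames(circular, names(genome))
  genome
}

validate_genome <- function(genome) {
  ids <- names(genome)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all contigs must have non-empty ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(genome) < 1L)) {
    stop("contigs must have length >= 1", call. = FALSE)
  }
  seqs <- as.character(genome)
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("contig '", ids[i], "' contains disallowed character '",
         substr(seqs[i], bad[i], bad[i]), "' at position ", bad[i],
         " (genomes must be A/C/G/T only)", call. = FALSE)
  }
  invisible(genome)
}

#' Read a genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] and enforces the genome invariants:
#' unique non-empty contig ids and a strict A/C/G/T alphabet (lowercase is
#' uppercased; any ambiguity code is an error naming the contig and offset).
#' Only the first whitespace-delimited word of each header is kept as the id.
#'
#' @param path FASTA file.
#' @param circular logical circularity flag(s), recycled over contigs.
#' @return a `DNAStringSet` genome.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  validate_genome(genome)
  set_genome_circular(genome, circular)
}

#' Write a genome to FASTA
#'
#' @param genome a `DNAStringSet` genome.
#' @param path output file; written atomically (temp file + rename).
#' @param width line width for the sequence body.
#' @return `path`, invisibly. Round-trips with [read_genome_fasta()].
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  validate_genome(genome)
  atomic_write(path, function(tmp) {
    Biostrings::writeXStringSet(genome, tmp, width = width)
  })
  invisible(path)
}

#' Simulate a random genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc_fraction / 2`, the null background the
#' motif-discovery enrichment model assumes. Reproducible given `seed`
#' without touching the caller's RNG state.
#'
#' @param length contig length(s) in bp; one contig per element.
#' @param gc_fraction genomic G+C fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param ids contig ids (default `sim_1`, `sim_2`, ...).
#' @return a `DNAStringSet` genome (linear contigs).
#' @examples
#' simulate_genome(1000, 0.5, seed = 1)
#' @export
simulate_genome <- function(length, gc_fraction = 0.5, seed = 1L, ids = NULL) {
  stopifnot(all(length >= 1), gc_fraction >= 0, gc_fraction <= 1)
  if (is.null(ids)) ids <- paste0("sim_", seq_along(length))
  prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
            G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- withr::with_seed(seed, {
    vapply(length, function(L) {
      paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
    }, "")
  })
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  set_genome_circular(genome, FALSE)
}
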