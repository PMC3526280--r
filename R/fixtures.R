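#' Planted motif complements for the six emulated methylomes
#'
#' Each fixture emulates the active methyltransferase complement of one of
#' six well-characterized bacteria, scaled to a desk-size genome:
#'
#' * `gmet` (*G. metallireducens*-like): the fused-MTase pair methylating
#'   GG**A**TC / G**A**TCC on opposite strands, and a Type III-style
#'   single-strand TCC**A**GG.
#' * `csal` (*C. salexigens*-like): the degenerate palindrome RG**A**TCY
#'   (both strands, incomplete methylation) and the bipartite Type I site
#'   CC**A**C N6 CTC with its complementary-strand partner.
#' * `vbr` (*V. breoganii*-like): Dam-style G**A**TC plus two Type I
#'   bipartite specificities (AGH**A** N7 TGAC, CT**A**G N6 RTAA) with
#'   their partners.
#' * `cje81` (*C. jejuni* 81-176-like): RA**A**TTY, single-strand Type IIG
#'   GGRC**A** and GCA**A**GG, and two Type I sites (CA**A**Y N6 ACT,
#'   TA**A**Y N5 TGC) with partners.
#' * `cje11168` (*C. jejuni* NCTC 11168-like): RA**A**TTY, the
#'   double-strand G**A**G N5 GT specificity with partner, single-strand
#'   GKA**A**YG, and TA**A**Y N5 TGC with partner.
#' * `bce` (*B. cereus*-like): Type I TA**A**G N7 TGG with partner, the
#'   m4C pair **A**CGGC / G**C**CGT methylating opposite strands, and two
#'   weak m5C nuisance specificities (G**C**WGC, GGWC**C**) that exercise
#'   robustness to diffuse low-intensity signal.
#'
#' @param name fixture name, one of `"gmet"`, `"csal"`, `"vbr"`, `"cje81"`,
#'   `"cje11168"`, `"bce"`.
#' @return a motif table with `fraction` (planted methylated fraction) and
#'   `nuisance` (TRUE for the weak m5C specificities, which the detection
#'   stage is not expected to recover).
#' @export
fixture_motifs <- function(name) {
  defs <- list(
    gmet = tibble::tribble(
      ~pattern, ~offset, ~mod_type, ~fraction,
      "GGATC", 3L, "m6A", 1,
      "GATCC", 2L, "m6A", 1,
      "TCCAGG", 4L, "m6A", 1
    ),
    csal = tibble::tribble(
      ~pattern, ~offset, ~mod_type, ~fraction,
      "RGATCY", 3L, "m6A", 0.9,
      "CCACNNNNNNCTC", 3L, "m6A", 1,
      "GAGNNNNNNGTGG", 2L, "m6A", 1
    ),
    vbr = tibble::tribble(
      ~pattern, ~offset, ~mod_type, ~fraction,
      "GATC", 2L, "m6A", 1,
      "AGHANNNNNNNTGAC", 4L, "m6A", 1,
      "GTCANNNNNNNTDCT", 4L, "m6A", 1,
      "CTAGNNNNNNRTAA", 3L, "m6A", 1,
      "TTAYNNNNNNCTAG", 3L, "m6A", 1
    ),
    cje81 = tibble::tribble(
      ~pattern, ~offset, ~mod_type, ~fraction,
      "RAATTY", 3L, "m6A", 1,
      "GGRCA", 5L, "m6A", 1,
      "GCAAGG", 4L, "m6A", 1,
      "CAAYNNNNNNACT", 3L, "m6A", 1,
      "AGTNNNNNNRTTG", 1L, "m6A", 1,
      "TAAYNNNNNTGC", 3L, "m6A", 1,
      "GCANNNNNRTTA", 3L, "m6A", 1
    ),
    cje11168 = tibble::tribble(
      ~pattern, ~offset, ~mod_type, ~fraction,
      "RAATTY", 3L, "m6A", 1,
      "GAGNNNNNGT", 2L, "m6A", 1,
      "ACNNNNNCTC", 1L, "m6A", 1,
      "GKAAYG", 4L, "m6A", 1,
      "TAAYNNNNNTGC", 3L, "m6A", 1,
      "GCANNNNNRTTA", 3L, "m6A", 1
    ),
    bce = tibble::tribble(
      ~pattern, ~offset, ~mod_type, ~fraction,
      "TAAGNNNNNNNTGG", 3L, "m6A", 1,
      "CCANNNNNNNCTTA", 3L, "m6A", 1,
      "ACGGC", 2L, "m4C", 1,
      "GCCGT", 2L, "m4C", 1,
      "GCWGC", 2L, "m5C", 1,
      "GGWCC", 5L, "m5C", 1
    )
  )
  if (!name %in% names(defs)) {
    stop("unknown fixture '", name, "'; choose one of: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  out <- defs[[name]]
  out$name <- out$pattern
  out$nuisance <- out$mod_type == "m5C"
  validate_motifs(out)
  out
}

# Ensure each duplex recognition-site family occurs at least `min_sites`
# times by writing concrete instances into the genome at random,
# non-overlapping slots.  A 200 kb random genome under-represents long
# bipartite sites relative to the multi-Mb genomes being emulated; spiking
# restores realistic per-genome site counts.  Orientation and degenerate /
# spacer bases are drawn uniformly.  Truth is scanned *after* spiking, so
# any site destroyed or created as a side effect is accounted for.
spike_motif_sites <- function(genome, motifs, min_sites = 150L, seed = 1L) {
  seqs <- as.character(genome)
  occupied <- lapply(seqs, function(s) logical(nchar(s)))
  canon <- pmin(motifs$pattern, revcomp_iupac(motifs$pattern))
  fams <- motifs[!duplicated(canon) & !motifs$nuisance, ]

  withr::with_seed(derive_seed(seed, "spike"), {
    for (i in seq_len(nrow(fams))) {
      pat <- fams$pattern[i]
      off <- fams$offset[i]
      L <- nchar(pat)
      have <- sum(vapply(names(seqs), function(id) {
        g1 <- Biostrings::DNAStringSet(stats::setNames(seqs[id], id))
        count_motif_sites(g1, pat, off)$n_duplex
      }, 0L))
      need <- max(0L, min_sites - have)
      placed <- 0L
      guard <- 0L
      while (placed < need && guard < 50L * need) {
        guard <- guard + 1L
        id <- sample(names(seqs), 1L,
                     prob = nchar(seqs) / sum(nchar(seqs)))
        len <- nchar(seqs[[id]])
        if (len < L) next
        start <- sample.int(len - L + 1L, 1L)
        span <- start:(start + L - 1L)
        if (any(occupied[[id]][span])) next
        inst_pat <- if (stats::runif(1) < 0.5) pat else revcomp_iupac(pat)
        inst <- paste(vapply(iupac_chars(inst_pat),
                             function(code) sample(IUPAC_SETS[[code]], 1L), ""),
                      collapse = "")
        substr(seqs[[id]], start, start + L - 1L) <- inst
        occupied[[id]][span] <- TRUE
        placed <- placed + 1L
      }
      if (placed < need) {
        warning("could only spike ", placed, " of ", need,
                " extra sites for ", pat, call. = FALSE)
      }
    }
  })
  out <- Biostrings::DNAStringSet(seqs)
  set_genome_circular(out, genome_circular(genome))
}

#' Build a complete synthetic methylome fixture
#'
#' Simulates a random genome, guarantees a realistic number of recognition
#' sites for each planted specificity, plants the methylome, and simulates
#' both the methylated kinetics tracks and an unmethylated control run of
#' the same genome (the in-silico kinetic reference the detection stage
#' trains on). Fully deterministic given `(name, seed)`.
#'
#' @param name fixture name (see [fixture_motifs()]).
#' @param seed integer seed.
#' @param genome_length genome size in bp.
#' @param gc_fraction genomic G+C content.
#' @param config a [sim_config()].
#' @param min_sites minimum duplex occurrences per planted site family.
#' @return a list with elements `genome`, `motifs` (the planted table),
#'   `truth`, `tracks` (methylated run), `ref_tracks` (unmethylated
#'   control), `config`, `seed`, `name`.
#' @examples
#' \donttest{
#' fx <- make_fixture("gmet", seed = 1)
#' dplyr::count(fx$truth, pattern)
#' }
#' @export
make_fixture <- function(name, seed = 1234L, genome_length = 200000L,
                         gc_fraction = 0.5, config = sim_config(),
                         min_sites = 150L) {
  motifs <- fixture_motifs(name)
  genome <- simulate_genome(genome_length, gc_fraction,
                            seed = derive_seed(seed, paste0("genome_", name)),
                            ids = paste0(name, "_chr"))
  genome <- spike_motif_sites(genome, motifs, min_sites = min_sites,
                              seed = derive_seed(seed, paste0("spike_", name)))
  truth <- plant_methylation(genome, motifs,
                             seed = derive_seed(seed, paste0("plant_", name)))
  tracks <- simulate_kinetics(genome, truth, config,
                              seed = derive_seed(seed, paste0("ipd_", name)))
  ref_tracks <- simulate_kinetics(genome, NULL, config,
                                  seed = derive_seed(seed, paste0("ref_", name)))
  list(genome = genome, motifs = motifs, truth = truth, tracks = tracks,
       ref_tracks = ref_tracks, config = config, seed = seed, name = name)
}
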