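test_that("FASTA round trip preserves ids and sequence", {
  g <- tiny_genome(c(c1 = "ACGT", c2 = "GGGATCCC"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(g, path)
  g2 <- read_genome_fasta(path)
  expect_identical(as.character(g2), as.character(g))
  expect_identical(names(g2), names(g))
})

test_that("genome validation rejects ambiguity codes with coordinates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description", "ACGNT"), path)
  expect_error(read_genome_fasta(path), "contig 'c1'.*'N' at position 4")
  expect_error(read_genome_fasta(withr::local_tempfile()), "not found")
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), dup)
  expect_error(read_genome_fasta(dup), "duplicate contig")
})

test_that("pattern scanning reports the methylated base per strand", {
  g <- tiny_genome("AAGATCAA")
  sites <- scan_pattern(g, "GATC", 2)
  expect_identical(sites$position, c(4L, 5L))
  expect_identical(sites$strand, c("+", "-"))
  expect_identical(nrow(scan_pattern(g, "TCCAGG", 4)), 0L)
  # one bipartite instance planted in a 30-mer
  seq30 <- paste0("AAAAA", "CCACTTTTTTCTC", "GGGGGGGGGGGG")
  gb <- tiny_genome(seq30)
  plus <- scan_pattern(gb, "CCACNNNNNNCTC", 3)
  expect_identical(plus$position, 8L)
  expect_identical(plus$strand, "+")
  minus <- scan_pattern(gb, "GAGNNNNNNGTGG", 2)
  expect_identical(minus$strand, "-")
  expect_identical(minus$position, 17L) # the A opposite the duplex T
})

test_that("scanning agrees with the brute-force expansion oracle", {
  motifs <- list(c("GATC", 2), c("RGATCY", 3), c("GCWGC", 2),
                 c("CCACNNNNNNCTC", 3), c("TCCAGG", 4), c("GGRCA", 5))
  for (i in 1:6) {
    g <- simulate_genome(1500, gc_fraction = 0.5, seed = 100 + i)
    seq <- as.character(g)[[1]]
    for (m in motifs) {
      got <- scan_pattern(g, m[[1]], as.integer(m[[2]]))
      want <- oracle_scan(seq, m[[1]], as.integer(m[[2]]))
      expect_identical(got$position, want$position,
                       label = paste("positions of", m[[1]], "genome", i))
      expect_identical(got$strand, want$strand,
                       label = paste("strands of", m[[1]], "genome", i))
    }
  }
})

test_that("palindromic motifs hit both strands equally and symmetry holds", {
  g <- simulate_genome(20000, seed = 7)
  sites <- scan_pattern(g, "RGATCY", 3)
  expect_identical(sum(sites$strand == "+"), sum(sites$strand == "-"))
  # strand symmetry: revcomp pattern with mirrored offset scans the same
  # duplexes from the other side
  for (m in list(c("GGATC", 3), c("GGRCA", 5), c("TCCAGG", 4))) {
    pat <- m[[1]]; off <- as.integer(m[[2]]); L <- nchar(pat)
    a <- scan_pattern(g, pat, off)
    b <- scan_pattern(g, revcomp_iupac(pat), L - off + 1L)
    expect_identical(nrow(a), nrow(b), label = paste("site count", pat))
  }
})

test_that("circular contigs wrap across the origin", {
  # GATC split across the origin: ...GA | TC...
  g_lin <- tiny_genome("TCAAAAGA")
  g_circ <- tiny_genome("TCAAAAGA", circular = TRUE)
  expect_identical(nrow(scan_pattern(g_lin, "GATC", 2)), 0L)
  sites <- scan_pattern(g_circ, "GATC", 2)
  expect_identical(sites$position, c(1L, 8L)) # + A at wrapped pos 1...
  expect_setequal(sites$strand, c("+", "-"))
  expect_true(matches_at(g_circ, "c1", 8L, "+", "GATC", 2))
  expect_false(matches_at(g_lin, "c1", 8L, "+", "GATC", 2)) # clipped
})

test_that("matches_at places patterns on either strand with clipping", {
  g <- tiny_genome("AAGATCAA")
  expect_true(matches_at(g, "c1", 4, "+", "GATC", 2))
  expect_false(matches_at(g, "c1", 4, "-", "GATC", 2))
  expect_true(matches_at(g, "c1", 5, "-", "GATC", 2))
  expect_false(matches_at(g, "c1", 1, "+", "GATC", 2)) # runs off the start
  expect_false(matches_at(g, "c1", 8, "+", "GATC", 2)) # runs off the end
  expect_true(matches_at(g, "c1", 4, "+", "NGATCN", 3))
})

test_that("per-strand and duplex site counts follow their conventions", {
  g <- tiny_genome("AAGATCAAGGATCC")
  # GATC at 3..6; GGATCC at 9..14 contains GGATC and GATCC
  counts <- count_motif_sites(g, "GATC", 2)
  expect_identical(counts$n_strand, 4L) # two duplexes x two strands
  expect_identical(counts$n_duplex, 2L)
  gg <- count_motif_sites(g, "GGATC", 3)
  expect_identical(gg$n_strand, 2L) # one strand of GGATCC + revcomp match
  expect_identical(gg$n_duplex, 2L)
})

test_that("BED output is 0-based half-open with strand and name", {
  g <- tiny_genome("AAGATCAA")
  sites <- scan_motifs(g, motif_tbl("GATC", 2, "m6A"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_identical(bed$X2, c(3, 4)) # 0-based starts
  expect_identical(bed$X3, c(4, 5))
  expect_identical(bed$X4, c("GATC", "GATC"))
  expect_identical(bed$X6, c("+", "-"))
})
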