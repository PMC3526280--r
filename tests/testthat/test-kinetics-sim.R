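test_that("simulated genomes respect length, composition and seed", {
  g <- simulate_genome(1000, 0.5, seed = 3)
  expect_identical(Biostrings::width(g), 1000L)
  gc1 <- simulate_genome(500, 1.0, seed = 3)
  expect_identical(as.integer(Biostrings::letterFrequency(gc1, "AT")[[1]]), 0L)
  at1 <- simulate_genome(500, 0.0, seed = 3)
  expect_identical(as.integer(Biostrings::letterFrequency(at1, "GC")[[1]]), 0L)
  expect_identical(as.character(simulate_genome(800, 0.4, seed = 9)),
                   as.character(simulate_genome(800, 0.4, seed = 9)))
  expect_false(identical(as.character(simulate_genome(800, 0.4, seed = 9)),
                         as.character(simulate_genome(800, 0.4, seed = 10))))
})

test_that("methylation planting is an independent per-site Bernoulli draw", {
  g <- simulate_genome(30000, seed = 21)
  m_full <- motif_tbl("GATC", 2, "m6A")
  sites <- scan_motifs(g, m_full)
  full <- plant_methylation(g, dplyr::mutate(m_full, fraction = 1), seed = 5)
  expect_identical(nrow(full), nrow(sites))
  none <- plant_methylation(g, dplyr::mutate(m_full, fraction = 0), seed = 5)
  expect_identical(nrow(none), 0L)
  half <- plant_methylation(g, dplyr::mutate(m_full, fraction = 0.5), seed = 5)
  # replay of the seeded inclusion draw gives the same count
  keep <- withr::with_seed(5, stats::runif(nrow(sites)) < 0.5)
  expect_identical(nrow(half), sum(keep))
  expect_identical(half, plant_methylation(
    g, dplyr::mutate(m_full, fraction = 0.5), seed = 5))
})

test_that("kinetics summaries recover the configured signal shifts", {
  g <- simulate_genome(3000, seed = 31)
  cfg <- sim_config(coverage_mean = 100)
  truth <- plant_methylation(g, motif_tbl("GATC", 2, "m6A"), seed = 1)
  tr <- simulate_kinetics(g, truth, cfg, seed = 2)
  expect_identical(nrow(tr), 6000L)
  key <- paste(tr$contig, tr$position, tr$strand)
  tkey <- paste(truth$contig, truth$position, truth$strand)
  met <- tr[key %in% tkey, ]
  unmet <- tr[!key %in% tkey & tr$n_obs >= 2, ]
  base <- methylmotif:::context_baseline(cfg)
  ctx_met <- methylmotif:::position_contexts(g, met$contig, met$position,
                                             met$strand, 3L)
  ctx_un <- methylmotif:::position_contexts(g, unmet$contig, unmet$position,
                                            unmet$strand, 3L)
  # methylated positions sit delta(m6A) above their context baseline
  shift_met <- mean(met$mean_logipd - base[ctx_met])
  se_met <- cfg$sigma / sqrt(sum(met$n_obs))
  expect_lt(abs(shift_met - log(4)), 4 * se_met + 1e-9)
  shift_un <- mean(unmet$mean_logipd - base[ctx_un], na.rm = TRUE)
  se_un <- cfg$sigma / sqrt(sum(unmet$n_obs))
  expect_lt(abs(shift_un), 4 * se_un + 1e-3)
})

test_that("zero coverage produces empty summaries, not fake data", {
  g <- simulate_genome(500, seed = 41)
  tr <- simulate_kinetics(g, NULL, sim_config(coverage_mean = 0), seed = 1)
  expect_true(all(tr$n_obs == 0))
  expect_true(all(is.na(tr$mean_logipd)))
})

test_that("kinetics tracks are bit-reproducible and round-trip as TSV", {
  g <- simulate_genome(2000, seed = 51)
  t1 <- simulate_kinetics(g, NULL, seed = 7)
  t2 <- simulate_kinetics(g, NULL, seed = 7)
  expect_identical(t1, t2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kinetics_tsv(t1, path)
  back <- read_kinetics_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(t1), tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::mutate(t1[1:5, ], strand = "x"), bad)
  expect_error(read_kinetics_tsv(bad), "row 1")
})

test_that("fixtures plant exactly their printed motif complements", {
  run <- fixture_run("gmet")
  expect_setequal(unique(run$truth$pattern),
                  c("GGATC", "GATCC", "TCCAGG"))
  # every truth position carries the planted base on its strand
  expect_true(all(run$truth$mod_type == "m6A"))
  # csal: methylated GATC cores all conform to RGATCY
  cs <- fixture_run("csal")
  gatc_truth <- cs$truth[cs$truth$pattern == "RGATCY", ]
  conforms <- matches_at(cs$genome, gatc_truth$contig, gatc_truth$position,
                         gatc_truth$strand, "RGATCY", 3)
  expect_true(all(conforms))
  core <- scan_pattern(cs$genome, "NGATCN", 3)
  in_truth <- paste(core$contig, core$position, core$strand) %in%
    paste(cs$truth$contig, cs$truth$position, cs$truth$strand)
  rg <- matches_at(cs$genome, core$contig, core$position, core$strand,
                   "RGATCY", 3)
  expect_identical(sum(in_truth & !rg), 0L)
})

test_that("fixture generation is deterministic in (name, seed)", {
  a <- make_fixture("gmet", seed = 77, genome_length = 20000L)
  b <- make_fixture("gmet", seed = 77, genome_length = 20000L)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$tracks, b$tracks)
  c <- make_fixture("gmet", seed = 78, genome_length = 20000L)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("spiked fixtures reach the minimum duplex site count", {
  fx <- fixture_run("csal")
  n <- count_motif_sites(fx$genome, "CCACNNNNNNCTC", 3)
  expect_gte(n$n_duplex, 150L)
})
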