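test_that("windows are strand-oriented, centered and N-padded", {
  g <- tiny_genome("AAGATCAA")
  rec <- tibble::tibble(contig = "c1", position = c(4L, 5L, 1L),
                        strand = c("+", "-", "+"), score = 100)
  win <- extract_windows(rec, g, flank = 2)
  expect_identical(win$window[1], "AGATC") # + strand, read as-is
  expect_identical(win$window[2], "TGATC") # - strand, 5'->3' on minus
  expect_identical(win$window[3], "NNAAG") # padded at the contig start
  # center character is the called base on the called strand
  expect_identical(substr(win$window, 3, 3), c("A", "A", "A"))
})

test_that("window FASTA round-trips with hit coordinates", {
  run <- fixture_run("gmet")
  w <- run$windows[1:25, ]
  path <- withr::local_tempfile(fileext = ".fasta")
  write_windows_fasta(w, path)
  back <- read_windows_fasta(path)
  expect_identical(back$window, w$window)
  expect_identical(back$position, w$position)
  expect_identical(back$strand, w$strand)
})

test_that("discovery recovers the planted motif complement exactly", {
  for (nm in c("gmet", "csal", "vbr", "cje81", "cje11168", "bce")) {
    run <- fixture_run(nm)
    expect_identical(motif_key(run$candidates),
                     motif_key(planted_nonnuisance(run)),
                     label = paste("discovered motifs for", nm))
  }
})

test_that("candidate significance matches a brute-force binomial oracle", {
  run <- fixture_run("gmet")
  cand <- run$candidates
  expect_gt(nrow(cand), 0)
  for (i in seq_len(nrow(cand))) {
    oracle <- oracle_log10_binom_tail(cand$support[i], cand$n_windows[i],
                                      cand$p0[i])
    expect_equal(cand$log10p[i], oracle, tolerance = 1e-6,
                 label = paste("log10 p of", cand$pattern[i]))
  }
})

test_that("uniform random windows yield no motifs", {
  g <- simulate_genome(50000, seed = 101)
  emitted <- 0L
  for (trial in 1:20) {
    win <- random_windows(300, center_base = if (trial %% 2) "A" else "C",
                          seed = 1000 + trial)
    suppressWarnings(cand <- discover_motifs(win, g))
    emitted <- emitted + nrow(cand)
  }
  expect_identical(emitted, 0L)
})

test_that("discovery warns and returns nothing below minimum support", {
  g <- simulate_genome(1000, seed = 103)
  expect_warning(out <- discover_motifs(random_windows(5, seed = 1), g),
                 "min_support")
  expect_identical(nrow(out), 0L)
  expect_identical(nrow(residual_motif_check(character(0), g)), 0L)
})

test_that("discovery is idempotent on explained windows", {
  run <- fixture_run("gmet")
  W <- run$windows$window
  explained <- rep(FALSE, length(W))
  for (i in seq_len(nrow(run$candidates))) {
    chars <- strsplit(run$candidates$pattern[i], "")[[1]]
    offs <- seq_along(chars) - run$candidates$offset[i]
    hit <- vapply(W, function(w) {
      ch <- strsplit(w, "")[[1]]
      all(mapply(function(code, o) {
        x <- ch[21 + o]
        x %in% c("A", "C", "G", "T") &&
          x %in% methylmotif:::IUPAC_SETS[[code]]
      }, chars, offs))
    }, NA, USE.NAMES = FALSE)
    explained <- explained | hit
  }
  again <- discover_motifs(W[explained], run$genome)
  expect_true(all(paste(again$pattern, again$offset) %in%
                    paste(run$candidates$pattern, run$candidates$offset)))
})

test_that("hits are assigned first-match and the remainder left over", {
  g <- tiny_genome("AAGATCAATTGATCAA")
  rec <- tibble::tibble(contig = "c1",
                        position = c(4L, 12L, 2L, 8L),
                        strand = c("+", "+", "+", "+"),
                        score = c(100, 90, 80, 70))
  motifs <- motif_tbl("GATC", 2, "m6A")
  out <- assign_hits(rec, motifs, g)
  expect_identical(out$assigned, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$motif, c("GATC", "GATC", NA, NA))
  none <- assign_hits(rec, motifs[0, ], g)
  expect_true(all(!none$assigned))
  # first-match by motif table order
  two <- motif_tbl(c("NGATCN", "GATC"), c(3, 2), "m6A")
  both <- assign_hits(rec, two, g)
  expect_identical(both$motif[1], "NGATCN")
})

test_that("the residual check finds a deliberately unexplained motif", {
  run <- fixture_run("gmet")
  retained <- dplyr::filter(run$records, score >= run$threshold, !assigned)
  suppressWarnings(resid <- residual_motif_check(
    extract_windows(retained, run$genome), run$genome))
  expect_identical(nrow(resid), 0L) # clean methylome
  # seed the residual pool with windows of an unplanted specificity
  planted <- random_windows(60, seed = 77)
  substr(planted, 16, 21) <- "TGCGCA" # its A lands on the window center
  resid2 <- discover_motifs(c(planted, random_windows(100, seed = 78)),
                            run$genome)
  expect_true("TGCGCA" %in% resid2$pattern)
  expect_identical(resid2$offset[resid2$pattern == "TGCGCA"], 6L)
})
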