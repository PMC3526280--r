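test_that("threshold selection follows the unassigned-fraction rule", {
  rec <- tibble::tibble(score = c(100, 90, 80, 70, 60, 50),
                        assigned = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(select_threshold(rec, 0.2), 50)
  # all assigned: keep everything
  all_ok <- tibble::tibble(score = c(30, 20, 10), assigned = TRUE)
  expect_identical(select_threshold(all_ok, 0.01), 10)
  # target 0 with an unassigned record: cut above it
  expect_identical(select_threshold(rec, 0), 70)
  rec2 <- tibble::tibble(score = c(100, 90, 80), assigned = c(TRUE, FALSE, TRUE))
  expect_identical(select_threshold(rec2, 0), 100)
  expect_warning(thr <- select_threshold(
    tibble::tibble(score = 10, assigned = FALSE), 0.5), "Inf")
  expect_identical(thr, Inf)
  expect_error(select_threshold(rec[0, ], 0.01), "no detection records")
})

test_that("threshold selection agrees with an exhaustive sweep", {
  brute <- function(rec, target) {
    ord <- order(-rec$score)
    s <- rec$score[ord]; a <- rec$assigned[ord]
    best <- Inf
    for (cut in unique(s)) {
      keep <- s >= cut
      if (sum(!a & keep) / sum(keep) <= target) best <- min(best, cut)
    }
    best
  }
  withr::with_seed(202, {
    for (rep in 1:30) {
      n <- sample(20:400, 1)
      rec <- tibble::tibble(
        score = sample(seq(10, 200, by = 5), n, replace = TRUE), # many ties
        assigned = stats::runif(n) < 0.8)
      for (target in c(0, 0.01, 0.05, 0.2, 0.5)) {
        got <- suppressWarnings(select_threshold(rec, target))
        expect_identical(got, brute(rec, target))
      }
      # monotonicity: stricter target never lowers the threshold
      thr <- vapply(c(0.5, 0.2, 0.05, 0.01, 0),
                    function(t) suppressWarnings(select_threshold(rec, t)), 0)
      d <- diff(thr)
      expect_true(all(d >= 0 | is.nan(d))) # Inf - Inf when unattainable
    }
  })
})

test_that("wrong threshold example from sweep matches hand computation", {
  # the largest retained set with unassigned fraction <= target wins even
  # when a smaller set also qualifies
  rec <- tibble::tibble(score = c(9, 8, 7, 6, 5),
                        assigned = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(select_threshold(rec, 0.2), 5) # 1/5 unassigned
})

test_that("extent of methylation counts detected sites per strand", {
  g <- tiny_genome("AAGATCAA")
  motifs <- motif_tbl("GATC", 2, "m6A")
  no_rec <- tibble::tibble(contig = character(), position = integer(),
                           strand = character(), score = double())
  ext0 <- methylation_extent(g, motifs, no_rec, 0)
  expect_identical(ext0$n_detected, 0L)
  expect_identical(ext0$n_sites, 2L)
  expect_identical(ext0$fraction, 0)
  rec <- tibble::tibble(contig = "c1", position = c(4L, 5L),
                        strand = c("+", "-"), score = c(90, 40))
  ext <- methylation_extent(g, motifs, rec, 50)
  expect_identical(ext$n_detected, 1L) # the 40 falls below threshold
  expect_identical(ext$fraction, 0.5)
})

test_that("planted methylated fractions are recovered within binomial CI", {
  g <- simulate_genome(60000, seed = 111)
  cfg <- sim_config()
  ref <- simulate_kinetics(g, NULL, cfg, seed = 12)
  model <- build_context_model(g, ref)
  for (f in c(0.25, 0.5, 0.75, 1.0)) {
    motifs <- dplyr::mutate(motif_tbl("GATC", 2, "m6A"), fraction = f)
    truth <- plant_methylation(g, motifs, seed = round(100 * f))
    tr <- simulate_kinetics(g, truth, cfg, seed = round(100 * f) + 1)
    rec <- detect_modifications(tr, g, model, score_floor = 60)
    ext <- methylation_extent(g, motifs, rec, 60)
    ci <- 2.58 * sqrt(f * (1 - f) / ext$n_sites)
    expect_lt(abs(ext$fraction - f), ci + 0.01,
              label = paste("recovered extent at f =", f))
  }
})

test_that("complementary-strand motifs pair into duplex groups", {
  m <- motif_tbl(c("GGATC", "GATCC", "RGATCY", "TCCAGG"),
                 c(3, 2, 3, 4), "m6A")
  p <- pair_motifs(m)
  expect_identical(p$partner[1], "GATCC")
  expect_identical(p$partner[2], "GGATC")
  expect_identical(p$group[1], p$group[2])
  expect_identical(p$partner[3], "RGATCY") # self-complementary
  expect_true(p$double_strand[3])
  expect_true(is.na(p$partner[4])) # lone single-strand motif
  expect_false(p$double_strand[4])
  # the partition is invariant under motif order
  p2 <- pair_motifs(m[c(4, 2, 3, 1), ])
  key <- function(p) {
    split(paste(p$pattern), p$group) |> lapply(sort) |> unname() |>
      (\(x) x[order(vapply(x, paste, "", collapse = ","))])()
  }
  expect_identical(key(p), key(p2))
  expect_identical(anyDuplicated(paste(p$pattern, p$offset)), 0L)
})

test_that("RM-type calls follow the structural rules", {
  expect_identical(classify_rm_type("CCACNNNNNNCTC", TRUE), "TypeI")
  expect_identical(classify_rm_type("RGATCY", TRUE), "TypeII")
  expect_identical(classify_rm_type("GGRCA", FALSE), "TypeIII_or_IIG")
  expect_identical(classify_rm_type("CCACNNNNNNCTC", FALSE), "unclassified")
})

test_that("the summary table is complete, bounded and byte-deterministic", {
  run <- fixture_run("gmet")
  s <- build_summary(run$genome, run$candidates, run$records, run$threshold)
  expect_identical(nrow(s), 3L)
  expect_identical(length(unique(s$group)), 2L)
  expect_true(all(s$fraction >= 0 & s$fraction <= 1))
  expect_true(all(s$n_detected <= s$n_sites))
  expect_identical(s$rm_type[s$pattern == "TCCAGG"], "TypeIII_or_IIG")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(s, p1)
  readr::write_csv(build_summary(run$genome, run$candidates, run$records,
                                 run$threshold), p2)
  expect_identical(readLines(p1), readLines(p2))
})
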