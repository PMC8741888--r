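test_that("perfect-repeat detection: homopolymers, primitivity, spans", {
  hits <- find_perfect_ssrs(c(a = strrep("A", 12)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit, "A")
  expect_equal(hits$repeats, 12L)
  expect_equal(hits$type, "p1")
  expect_equal(c(hits$start, hits$end), c(0L, 12L))

  # (AC)6 is one p2 hit, never additionally a p4 (ACAC) hit
  hits <- find_perfect_ssrs(c(a = strrep("AC", 6)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit, "AC")
  expect_equal(hits$unit_len, 2L)
  expect_equal(hits$repeats, 6L)

  # flank lengths are derived from the span (flanks chosen so they cannot
  # extend the run or shift its phase)
  hits <- find_perfect_ssrs(c(a = paste0("TTGGG", strrep("AC", 6), "GTTAG")))
  expect_equal(hits$left_flank_len, 5L)
  expect_equal(hits$right_flank_len, 5L)

  # N breaks runs
  broken <- paste0(strrep("AC", 3), "N", strrep("AC", 3))
  expect_equal(nrow(find_perfect_ssrs(c(a = broken),
                                      min_repeats = c(10, 3, 5, 5, 5, 5))), 2L)
  expect_equal(nrow(find_perfect_ssrs(c(a = broken))), 0L)
})

test_that("miner equals the exhaustive position-by-position oracle", {
  set.seed(41)
  for (i in 1:150) {
    s <- plant_repeats(300)
    got <- find_perfect_ssrs(c(x = s))
    want <- oracle_find_ssrs(s)
    expect_equal(nrow(got), nrow(want), info = s)
    if (nrow(want)) {
      expect_equal(got$unit, want$unit, info = s)
      expect_equal(got$repeats, want$repeats, info = s)
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$end, want$end, info = s)
    }
  }
})

test_that("compound joining follows the gap rule and matches the scan oracle", {
  set.seed(45)
  fl <- rand_flank(30, "AC")
  fr <- rand_flank(30, "AG", left = FALSE)
  seq0 <- paste0(fl, strrep("AC", 6), strrep("AG", 6), fr)
  h <- find_perfect_ssrs(c(a = seq0))
  joined <- join_compound(h, max_gap = 100)
  expect_equal(nrow(joined), 1L)
  expect_equal(joined$type, "c")
  expect_equal(joined$unit, "AC-AG")
  expect_equal(c(joined$start, joined$end), c(30L, 54L))
  expect_equal(joined$right_flank_len, 30L)

  seq1 <- paste0(fl, strrep("AC", 6), "TTT", strrep("AG", 6), fr)
  joined <- join_compound(find_perfect_ssrs(c(a = seq1)), max_gap = 100)
  expect_equal(joined$type, "c*")
  expect_equal(c(joined$start, joined$end), c(30L, 57L))

  seq2 <- paste0(rand_flank(5, "AC"), strrep("AC", 6), rand_seq(150),
                 strrep("AG", 6), rand_flank(5, "AG", left = FALSE))
  h2 <- find_perfect_ssrs(c(a = seq2))
  if (nrow(h2) == 2L) {
    joined <- join_compound(h2, max_gap = 100)
    expect_equal(joined$type, h2$type)
  }

  # random multi-hit sequences against the definition-based oracle
  set.seed(42)
  for (i in 1:40) {
    parts <- replicate(sample(2:4, 1), strrep(rand_seq(2), sample(6:9, 1)))
    gaps <- replicate(length(parts) - 1,
                      strrep("T", sample(c(0, 0, 2, 5, 120), 1)))
    s <- paste0("GGGGG", paste0(parts, c(gaps, ""), collapse = ""), "GGGGG")
    h <- find_perfect_ssrs(c(x = s), min_repeats = c(10, 6, 5, 5, 5, 5))
    if (nrow(h) < 2) next
    got <- join_compound(h, max_gap = 100)
    want <- oracle_join_compound(as.data.frame(h), 100)
    expect_equal(got$unit, want$unit, info = s)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
    expect_equal(got$type, want$type, info = s)
  }
})

test_that("Filter 2 keeps single-SSR sequences with long enough flanks", {
  set.seed(44)
  seq220 <- paste0(rand_flank(60, "AC"), strrep("AC", 8),
                   rand_flank(144, "AC", left = FALSE))
  stopifnot(nchar(seq220) == 220)
  reads <- tibble::tibble(id = "x", seq = seq220)
  hits <- find_perfect_ssrs(reads)
  expect_equal(c(hits$start, hits$end), c(60L, 76L))

  out <- filter_candidates(reads, hits, pipeline_config(min_flank_len = 50))
  expect_equal(nrow(out), 1L)
  expect_equal(out$unit, "AC")

  out <- filter_candidates(reads, hits, pipeline_config(min_flank_len = 75))
  expect_equal(nrow(out), 0L)
  expect_equal(stage_info(out)$reasons[["no_ssr"]], 1L)

  # two independent qualifying repeats: rejected as multi_ssr
  seq2 <- paste0(rand_flank(60, "AC"), strrep("AC", 8),
                 rand_flank(60, "AC", left = FALSE), rand_flank(0, "AG"),
                 strrep("AG", 7), rand_flank(60, "AG", left = FALSE))
  reads2 <- tibble::tibble(id = "y", seq = seq2)
  hits2 <- find_perfect_ssrs(reads2)
  expect_equal(nrow(hits2), 2L)
  out <- filter_candidates(reads2, hits2, pipeline_config())
  expect_equal(nrow(out), 0L)
  expect_equal(stage_info(out)$reasons[["multi_ssr"]], 1L)

  # excluded types are ignored
  out <- filter_candidates(reads, hits,
                           pipeline_config(excluded_ssr_types = "p2"))
  expect_equal(nrow(out), 0L)
})

test_that("raising the flank threshold never admits more sequences", {
  set.seed(43)
  reads <- tibble::tibble(id = sprintf("s%03d", 1:60),
                          seq = replicate(60, plant_repeats(250)))
  hits <- join_compound(find_perfect_ssrs(reads), 100)
  counts <- vapply(c(10, 25, 50, 75, 100), function(mfl) {
    nrow(filter_candidates(reads, hits, pipeline_config(min_flank_len = mfl)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
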