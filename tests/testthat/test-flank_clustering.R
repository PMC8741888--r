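test_that("repeat excision concatenates the flanks and is invertible", {
  seq <- "AAACACACACACAGG"
  cand <- tibble::tibble(id = "x", seq = seq, start = 3L, end = 13L,
                         unit = "CA", unit_len = 2L, repeats = 5L)
  sig <- excise_ssr(cand)
  expect_equal(sig$signature, "AAAGG")
  expect_equal(sig$full_length, 15L)
  expect_equal(nchar(sig$signature), sig$full_length - 10L)

  # re-inserting unit x repeats at the span start reproduces the original
  rebuilt <- paste0(substr(seq, 1, 3), strrep("CA", 5), substr(sig$signature, 4, 5))
  expect_equal(rebuilt, seq)

  # whole-sequence span gives an empty (legal) signature
  whole <- tibble::tibble(id = "y", seq = strrep("AC", 6), start = 0L,
                          end = 12L)
  expect_equal(excise_ssr(whole)$signature, "")

  # out-of-bounds span is fatal
  oob <- tibble::tibble(id = "z", seq = "ACGT", start = 0L, end = 9L)
  expect_error(excise_ssr(oob), "out of bounds")
})

test_that("identity is 1 - edit distance over the shorter length", {
  expect_equal(seq_identity(strrep("ACGT", 25), strrep("ACGT", 25)), 1.0)

  set.seed(51)
  a <- rand_seq(100)
  b <- a
  pos <- sample(100, 10)
  for (p in pos) {
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, p, p))[sample(3, 1)]
  }
  # 10 substitutions can only lower identity to exactly 0.90 unless gaps
  # re-create a cheaper path, which utils::adist would also find
  expect_equal(seq_identity(a, b), oracle_identity(a, b))

  for (i in 1:25) {
    x <- rand_seq(sample(30:150, 1))
    y <- rand_seq(sample(30:150, 1))
    expect_equal(seq_identity(x, y), oracle_identity(x, y))
  }
  expect_error(seq_identity("", "ACGT"), "empty")
})

test_that("greedy clustering groups copies and splits distant signatures", {
  sigs <- tibble::tibble(signature = rep(rand_seq(120), 5),
                         full_length = rep(140L, 5))
  out <- greedy_cluster(sigs)
  expect_equal(out$cluster_id, rep(1L, 5))
  expect_equal(sum(out$is_seed), 1L)

  # identity 0.85 < 0.90: two singletons
  set.seed(52)
  a <- rand_seq(100)
  b <- a
  for (p in sample(100, 15)) {
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  }
  stopifnot(oracle_identity(a, b) < 0.9)
  out <- greedy_cluster(tibble::tibble(signature = c(a, b),
                                       full_length = c(100L, 100L)))
  expect_equal(length(unique(out$cluster_id)), 2L)
})

test_that("word-filtered clustering equals the no-filter and adist references", {
  set.seed(53)
  base <- replicate(25, rand_seq(sample(80:160, 1)))
  sigs <- character(0)
  for (s in base) {
    sigs <- c(sigs, s)
    for (j in seq_len(sample(2:6, 1))) {
      m <- s
      for (p in sample(nchar(s), sample(0:12, 1))) {
        substr(m, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      sigs <- c(sigs, m)
    }
  }
  tbl <- tibble::tibble(signature = sigs, full_length = nchar(sigs) + 20L)

  with_filter <- greedy_cluster(tbl, word_filter = TRUE)
  without <- greedy_cluster(tbl, word_filter = FALSE)
  expect_equal(with_filter$cluster_id, without$cluster_id)

  # processing order: length descending, ties input order
  ord <- order(-nchar(sigs), seq_along(sigs))
  want <- integer(length(sigs))
  want[ord] <- oracle_greedy(sigs[ord], 0.90)
  expect_true(same_partition(with_filter$cluster_id, want))

  # partition and member-to-seed identity invariants
  expect_true(all(table(with_filter$cluster_id) >= 1))
  expect_equal(length(with_filter$cluster_id), length(sigs))
  seeds <- with_filter$signature[with_filter$is_seed]
  seed_of <- seeds[match(with_filter$cluster_id,
                         with_filter$cluster_id[with_filter$is_seed])]
  expect_true(all(seq_identity(with_filter$signature, seed_of) >= 0.90))
})

test_that("Filter 3 drops singletons and optionally motif-mixed clusters", {
  tbl <- tibble::tibble(
    signature = c("S1", "S2", "S3", "P1", "P1b"),
    full_length = rep(100L, 5),
    cluster_id = c(1L, 2L, 3L, 4L, 4L),
    unit = c("AC", "AC", "AC", "AC", "CA"),
    is_seed = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- filter_clusters(tbl, min_members = 2)
  expect_equal(unique(out$cluster_id), 4L)
  expect_equal(stage_info(out), list(input = 4L, kept = 1L, dropped = 3L,
                                     reasons = NULL))

  # AC and CA are the same motif up to rotation; AG is not
  tbl$unit[5] <- "AG"
  out <- filter_clusters(tbl, min_members = 2, require_motif_consistency = TRUE)
  expect_equal(nrow(out), 0L)
  tbl$unit[5] <- "CA"
  out <- filter_clusters(tbl, min_members = 2, require_motif_consistency = TRUE)
  expect_equal(unique(out$cluster_id), 4L)

  # min_members = 1, consistency off: identity transformation
  out <- filter_clusters(tbl, min_members = 1)
  expect_equal(nrow(out), nrow(tbl))
})
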