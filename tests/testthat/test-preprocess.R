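mk_reads <- function(seqs, q = 40L) {
  tibble::tibble(id = paste0("r", seq_along(seqs)), seq = seqs,
                 qual = vapply(nchar(seqs),
                               function(n) strrep(intToUtf8(q + 33L), n),
                               character(1)))
}

test_that("adapter removal: exact, mismatched, and oracle-equivalent cuts", {
  adapter <- "AGATCGGAAGAGCACACGTC"
  insert <- "TTGACCAGTTGGCCAATTGGCCAATGGTTCACAGTGGAAC"  # 40 nt
  reads <- mk_reads(paste0(insert, adapter))
  out <- trim_reads(reads, adapter)
  expect_equal(out$seq, insert)

  # one mismatch in a 20-nt adapter: error rate 0.05 <= 0.10
  ad_mut <- paste0(substr(adapter, 1, 9), "T", substr(adapter, 11, 20))
  stopifnot(ad_mut != adapter)
  out <- trim_reads(mk_reads(paste0(insert, ad_mut)), adapter)
  expect_equal(out$seq, insert)

  # random reads with adapter planted at random positions: leftmost
  # acceptable cut must equal the brute-force semi-global oracle
  set.seed(31)
  for (i in 1:40) {
    pos <- sample(36:80, 1)
    s <- paste0(rand_seq(pos), substr(adapter, 1, sample(5:20, 1)))
    s <- substr(s, 1, min(nchar(s), 90))
    got <- trim_reads(mk_reads(s), adapter, min_len = 1L)
    expect_equal(nchar(got$seq),
                 oracle_adapter_cut(s, adapter, 0.10, 3), info = s)
  }
})

test_that("quality trimming cuts at the first bad window and drops short reads", {
  # all-Q2 read: first window fails, read dropped
  bad <- tibble::tibble(id = "r1", seq = rand_seq(50),
                        qual = strrep(intToUtf8(2L + 33L), 50))
  out <- trim_reads(bad)
  expect_equal(nrow(out), 0L)
  expect_equal(stage_info(out), list(input = 1L, kept = 0L, dropped = 1L,
                                     reasons = NULL))

  # quality drops at position 41; the first window whose mean falls below
  # 15 starts at position 40, so the kept prefix is 39 bases
  q <- c(rep(40L, 40), rep(2L, 20))
  rd <- tibble::tibble(id = "r1", seq = rand_seq(60),
                       qual = intToUtf8(q + 33L))
  out <- trim_reads(rd)
  expect_equal(nchar(out$seq), 39L)
  expect_equal(out$seq, substr(rd$seq, 1, 39))
})

test_that("trimming never lengthens a read and conserves counts", {
  set.seed(32)
  reads <- mk_reads(vapply(sample(20:120, 30, TRUE), rand_seq, character(1)))
  reads$qual <- vapply(nchar(reads$seq),
                       function(n) intToUtf8(sample(2:40, n, TRUE) + 33L),
                       character(1))
  out <- trim_reads(reads, adapters = "AGATCGGAAGAGC")
  info <- stage_info(out)
  expect_equal(info$kept + info$dropped, info$input)
  orig <- reads$seq[match(out$id, reads$id)]
  expect_true(all(nchar(out$seq) <= nchar(orig)))
  expect_true(all(substr(orig, 1, nchar(out$seq)) == out$seq))
})

test_that("merging reconstructs fragments exactly from error-free pairs", {
  set.seed(33)
  frag <- rand_seq(300)
  r1 <- mk_reads(substr(frag, 1, 250))
  r2 <- mk_reads(revcomp(substr(frag, 51, 300)))
  out <- merge_pairs(r1, r2)
  expect_equal(out$seq, frag)

  # completeness over random fragment sizes up to 2*readlen - min_overlap
  for (i in 1:30) {
    n <- sample(60:490, 1)
    frag <- rand_seq(n)
    r1 <- mk_reads(substr(frag, 1, min(250, n)))
    r2 <- mk_reads(revcomp(substr(frag, max(1, n - 249), n)))
    out <- merge_pairs(r1, r2)
    expect_equal(out$seq, frag, info = paste("fragment length", n))
  }
})

test_that("unrelated reads stay unmerged, matching the exhaustive-offset oracle", {
  set.seed(34)
  for (i in 1:15) {
    a <- rand_seq(250)
    b <- rand_seq(250)
    out <- merge_pairs(mk_reads(a), mk_reads(b))
    best <- oracle_best_overlap(a, revcomp(b), 10)
    expect_equal(nrow(out), as.integer(best$density <= 0.25))
  }
})

test_that("identical mates pass through unchanged (single-end mode)", {
  rd <- mk_reads(rand_seq(120))
  out <- merge_pairs(rd, rd)
  expect_equal(out$seq, rd$seq)
  expect_equal(out$qual, rd$qual)
})

test_that("merge consensus takes the higher-quality base and quality rules", {
  frag <- rand_seq(200)
  r1s <- substr(frag, 1, 150)
  r2s <- substr(frag, 51, 200)
  # plant a disagreement at fragment position 100 (overlap region 51..150)
  ch <- c("A", "C", "G", "T")
  pos <- 100
  old <- substr(r2s, pos - 50, pos - 50)
  substr(r2s, pos - 50, pos - 50) <- setdiff(ch, old)[1]
  r1 <- mk_reads(r1s, q = 20L)
  r2 <- mk_reads(revcomp(r2s), q = 30L)
  out <- merge_pairs(r1, r2)
  expect_equal(nchar(out$seq), 200L)
  # disagreeing position takes the r2 (higher-quality) base
  expect_equal(substr(out$seq, pos, pos), substr(r2s, pos - 50, pos - 50))
  # consensus quality at disagreement = |q1 - q2| = 10
  expect_equal(phred_decode(out$qual)[pos], 10L)
  # agreeing overlap positions carry max(q1, q2) = 30
  expect_equal(phred_decode(out$qual)[pos + 1], 30L)
})

test_that("restriction filter honours every anchor and can be disabled", {
  seqs <- c("GATCACGTTT", "ACGTTTGATC", "ACGGATCGTT", "ACGTACGTAC")
  expect_equal(has_restriction_site(seqs, "GATC", "start"),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(has_restriction_site(seqs, "GATC", "end"),
               c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(has_restriction_site(seqs, "GATC", "either"),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(has_restriction_site(seqs, "GATC", "anywhere"),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(has_restriction_site(seqs, "")))

  reads <- mk_reads(seqs)
  out <- filter_restriction(reads, "GATC", "either")
  expect_equal(nrow(out), 2L)
  info <- stage_info(out)
  expect_equal(info$kept + info$dropped, info$input)
})
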