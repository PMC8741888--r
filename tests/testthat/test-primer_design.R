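test_that("melting temperature matches the frozen reference panel and orderings", {
  ref <- read.csv(test_path("tm-reference.csv"), stringsAsFactors = FALSE)
  tm <- melting_temperature(ref$oligo)
  expect_true(all(abs(tm - ref$tm) < 0.5))

  # AT-rich melts below GC-rich at equal length and conditions
  expect_lt(melting_temperature(strrep("AT", 10)),
            melting_temperature(strrep("GC", 10)))

  # adding stabilising GC stacks monotonically raises Tm
  tms <- melting_temperature(strrep("GC", 6:14))
  expect_true(all(diff(tms) > 0))

  expect_error(melting_temperature("ACGT"), "length")
  expect_error(melting_temperature(strrep("A", 40)), "length")
  expect_error(melting_temperature("ACGTNACGTNACGT"), "ambiguous")
})

test_that("candidate enumeration equals the brute-force predicate oracle", {
  expect_equal(nrow(enumerate_candidates(strrep("A", 80))), 0L)

  set.seed(71)
  for (i in 1:12) {
    template <- rand_seq(90)
    for (orient in c("forward", "reverse")) {
      got <- enumerate_candidates(template, orientation = orient)
      want <- oracle_enumerate(template, c(0, 90), orient, primer_params())
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        key <- function(d) paste(d$seq, d$tstart, d$tend)
        expect_setequal(key(got), key(want))
      }
    }
  }

  # avoid_in_ssr: no candidate intersects the repeat span
  template <- paste0(rand_seq(80), strrep("AC", 10), rand_seq(80))
  got <- enumerate_candidates(template, ssr_span = c(80, 100),
                              avoid_in_ssr = TRUE)
  expect_true(all(got$tend <= 80 | got$tstart >= 100))
})

test_that("pairing and ranking follow the penalty and hard constraints", {
  fwd <- tibble::tibble(seq = "F", tstart = 10L, tend = 30L, length = 20L,
                        tm = 60, gc = 50, orientation = "forward")
  rev <- tibble::tibble(seq = "R", tstart = 150L, tend = 170L, length = 20L,
                        tm = 60.4, gc = 50, orientation = "reverse")
  pairs <- pair_and_rank(fwd, rev, ssr_span = c(60, 100))
  expect_equal(nrow(pairs), 1L)
  expect_true(pairs$is_best)
  expect_equal(pairs$product_size, 160L)

  # no reverse within max_diff_tm: empty result
  rev$tm <- 61.5
  expect_equal(nrow(pair_and_rank(fwd, rev, ssr_span = c(60, 100))), 0L)

  # exhaustive-oracle ranking on random candidate sets
  set.seed(72)
  params <- primer_params()
  for (rep in 1:15) {
    nf <- sample(5:20, 1); nr <- sample(5:20, 1)
    fwd <- tibble::tibble(
      seq = sprintf("F%d", 1:nf),
      tstart = sample(0:50, nf, TRUE), length = sample(18:27, nf, TRUE),
      tm = round(runif(nf, 57, 63), 3), gc = 50, orientation = "forward")
    fwd$tend <- fwd$tstart + fwd$length
    rev <- tibble::tibble(
      seq = sprintf("R%d", 1:nr),
      tend = sample(150:220, nr, TRUE), length = sample(18:27, nr, TRUE),
      tm = round(runif(nr, 57, 63), 3), gc = 50, orientation = "reverse")
    rev$tstart <- rev$tend - rev$length
    span <- c(80, 120)
    got <- pair_and_rank(fwd, rev, span, max_diff_tm = 1.0,
                         num_return = 1000L)

    # oracle: enumerate all combinations, apply constraints, sort
    cand <- expand.grid(f = 1:nf, r = 1:nr)
    rows <- list()
    for (j in seq_len(nrow(cand))) {
      f <- fwd[cand$f[j], ]; r <- rev[cand$r[j], ]
      product <- r$tend - f$tstart
      if (f$tend > r$tstart) next
      if (product < 100 || product > 300) next
      if (f$tstart > span[1] || r$tend < span[2]) next
      if (abs(f$tm - r$tm) > 1.0 + 1e-9) next
      pen <- abs(f$tm - 60) + 0.25 * abs(f$length - 20) +
        abs(r$tm - 60) + 0.25 * abs(r$length - 20) + 2 * abs(f$tm - r$tm)
      rows[[length(rows) + 1]] <- data.frame(
        fs = f$seq, rs = r$seq, pen = pen, product = product,
        fstart = f$tstart, rstart = r$tstart)
    }
    if (!length(rows)) {
      expect_equal(nrow(got), 0L)
      next
    }
    want <- do.call(rbind, rows)
    want <- want[order(want$pen, want$product, want$fstart, want$rstart), ]
    expect_equal(got$fwd_seq, want$fs)
    expect_equal(got$rev_seq, want$rs)
    expect_equal(got$penalty, want$pen, tolerance = 1e-12)
  }
})

test_that("widening max_diff_tm never shrinks the feasible pair set", {
  set.seed(73)
  template <- paste0(rand_seq(110), strrep("AC", 12), rand_seq(110))
  fwd <- enumerate_candidates(template, orientation = "forward")
  rev <- enumerate_candidates(template, orientation = "reverse")
  span <- c(110, 134)
  key <- function(p) paste(p$fwd_tstart, p$fwd_length, p$rev_tstart, p$rev_length)
  tight <- pair_and_rank(fwd, rev, span, max_diff_tm = 0.5, num_return = 1000000L)
  loose <- pair_and_rank(fwd, rev, span, max_diff_tm = 2.0, num_return = 1000000L)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("records carry ids, flags and locus fields correctly", {
  locus <- tibble::tibble(locus_number = 8L, motif_unit = "AC", unit_len = 2L,
                          observed = 5L, potential = 12L, range_min = 180L,
                          range_max = 202L, representative = "ACGT")
  pairs <- tibble::tibble(
    fwd_seq = c("F1", "F2"), fwd_tstart = c(0L, 2L), fwd_tend = c(20L, 22L),
    fwd_length = 20L, fwd_tm = c(59.123, 59.456),
    rev_seq = c("R1", "R2"), rev_tstart = c(150L, 150L),
    rev_tend = c(170L, 170L), rev_length = 20L, rev_tm = c(59.2, 59.5),
    product_size = c(170L, 168L), penalty = c(1.2, 1.5),
    pair_number = 1:2, is_best = c(TRUE, FALSE))
  hit <- tibble::tibble(unit = "AC", repeats = 11L, start = 60L, end = 82L)
  rec <- render_records(locus, pairs, "Bats", hit)
  expect_equal(rec$id, c("Bats8-1", "Bats8-2"))
  expect_equal(rec$best_flag, c("|BEST|", ""))
  expect_equal(rec$motif, rep("(AC)11", 2))
  expect_equal(rec$range, rep("180-202", 2))
  expect_equal(rec$alleles_observed, rep(5L, 2))
  expect_equal(rec$fwd_tm, c(59.12, 59.46))
  expect_equal(nrow(render_records(locus, pairs[0, ], "Bats", hit)), 0L)
})

test_that("every emitted record passes the post-hoc constraint validator", {
  sim <- simulate_library(sim_config(n_loci = 4, n_individuals = 10,
                                     coverage = 2, error_rate = 0, seed = 17))
  for (avoid in c(FALSE, TRUE)) {
    cfg <- pipeline_config(min_allele_cnt = 2, avoid_primer_in_ssr = avoid)
    run <- run_pipeline(sim$r1, sim$r2, cfg)
    expect_gt(nrow(run$results), 0)
    checks <- validate_primer_records(run$results, cfg)
    expect_true(attr(checks, "ok"))
  }
})
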