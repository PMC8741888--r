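#' Detect perfect microsatellites
#'
#' Scans each sequence for maximal perfect tandem repeats of primitive units
#' of 1-6 nt. Semantics, fixed so that results are reproducible and
#' oracle-checkable:
#' \itemize{
#'   \item a candidate run is the leftmost whole-unit repeat inside a maximal
#'     periodic stretch (the stretch cannot be extended by even one base on
#'     either side), so `end - start == unit_len * repeats` and trailing
#'     partial units are not included;
#'   \item units must be primitive (a `(ACAC)` run is reported once as
#'     `(AC)`, never additionally under the longer unit);
#'   \item `N` bases break runs: units containing `N` are never reported;
#'   \item a run must reach the per-unit-length minimum repeat count in
#'     `min_repeats` (positions 1-6; the conventional defaults
#'     10/6/5/5/5/5);
#'   \item overlapping candidates of different unit lengths are resolved
#'     left to right, shortest unit first: a candidate overlapping an
#'     already accepted run is discarded.
#' }
#'
#' @param x a reads tibble (columns `id`, `seq`) or a character vector of
#'   sequences (names become ids).
#' @param min_repeats integer vector of length 6: minimum repeat count for
#'   unit lengths 1-6.
#' @return a tibble of hits with columns `id`, `unit` (first observed
#'   phase), `unit_len`, `repeats`, `start`, `end` (0-based half-open span),
#'   `type` (`p1`-`p6`), `left_flank_len`, `right_flank_len`.
#' @export
#' @examples
#' find_perfect_ssrs(c(r1 = "TTGGCACACACACACACGTTAG"))
find_perfect_ssrs <- function(x, min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    if (is.null(names(x))) names(x) <- ids
    x <- tibble(id = ids, seq = unname(toupper(x)))
  }
  assert_reads(x, arg = "x")
  stopifnot(length(min_repeats) == 6L)
  out <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    out[[i]] <- scan_one_seq(x$seq[i], min_repeats)
    if (nrow(out[[i]])) out[[i]]$id <- x$id[i]
  }
  hits <- bind_rows(out)
  if (nrow(hits) == 0L) {
    return(tibble(id = character(), unit = character(), unit_len = integer(),
                  repeats = integer(), start = integer(), end = integer(),
                  type = character(), left_flank_len = integer(),
                  right_flank_len = integer()))
  }
  hits[, c("id", "unit", "unit_len", "repeats", "start", "end", "type",
           "left_flank_len", "right_flank_len")]
}

## Candidate runs for one sequence via shifted-match run-length encoding:
## positions where s[i] == s[i+k] form runs; a run of length L corresponds to
## a periodic stretch of length L + k, holding floor((L + k) / k) full units.
scan_one_seq <- function(seq, min_repeats) {
  n <- nchar(seq)
  empty <- tibble(id = character(0), unit = character(0),
                  unit_len = integer(0), repeats = integer(0),
                  start = integer(0), end = integer(0), type = character(0),
                  left_flank_len = integer(0), right_flank_len = integer(0))
  if (n < 2L) return(empty)
  r <- charToRaw(seq)
  cand <- list()
  ci <- 0L
  for (k in 1:6) {
    if (n < 2L * k) next
    m <- r[1:(n - k)] == r[(k + 1L):n]
    rl <- rle(m)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    sel <- which(rl$values & rl$lengths >= k)
    for (j in sel) {
      i0 <- starts[j]                       # 1-based stretch start
      reps <- (rl$lengths[j] + k) %/% k
      if (reps < min_repeats[k]) next
      unit <- substr(seq, i0, i0 + k - 1L)
      if (grepl("[^ACGT]", unit)) next
      if (!is_primitive_unit(unit)) next
      ci <- ci + 1L
      cand[[ci]] <- list(unit = unit, unit_len = k, repeats = reps,
                         start = i0 - 1L, end = i0 - 1L + reps * k)
    }
  }
  if (ci == 0L) return(empty)
  cand <- bind_rows(lapply(cand, as_tibble))
  cand <- cand[order(cand$start, cand$unit_len), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- 0L
  for (j in seq_len(nrow(cand))) {
    if (cand$start[j] >= last_end) {
      keep[j] <- TRUE
      last_end <- cand$end[j]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(id = NA_character_, unit = cand$unit, unit_len = cand$unit_len,
         repeats = cand$repeats, start = cand$start, end = cand$end,
         type = paste0("p", cand$unit_len),
         left_flank_len = cand$start, right_flank_len = n - cand$end)
}

#' Join adjacent repeats into compound hits
#'
#' Consecutive hits on the same sequence merge into a compound when their
#' gap is zero (`type = "c"`) or between 1 and `max_gap` bases
#' (`type = "c*"`, compound with imperfection); chains of three or more
#' join the same way. The merged span covers all constituent runs plus
#' gaps; the `unit` field lists constituent units joined by `-`;
#' `unit_len` is the smallest constituent unit length (the step of the
#' allele-length lattice) and `repeats` the largest constituent run count.
#' Hits further apart than `max_gap` are left unchanged.
#'
#' @param hits hit tibble from [find_perfect_ssrs()] (per sequence: sorted
#'   by start, non-overlapping).
#' @param max_gap largest imperfection, in bp, still joined as `c*`.
#' @return hit tibble of the same shape.
#' @export
join_compound <- function(hits, max_gap = 100L) {
  if (nrow(hits) == 0L) return(hits)
  out <- lapply(split(hits, factor(hits$id, levels = unique(hits$id))),
                join_compound_one, max_gap = max_gap)
  bind_rows(out)
}

join_compound_one <- function(h, max_gap) {
  h <- h[order(h$start), , drop = FALSE]
  if (nrow(h) < 2L) return(h)
  seqlen <- h$end[nrow(h)] + h$right_flank_len[nrow(h)]
  groups <- cumsum(c(TRUE, h$start[-1] - h$end[-nrow(h)] > max_gap))
  res <- lapply(split(seq_len(nrow(h)), groups), function(idx) {
    g <- h[idx, , drop = FALSE]
    if (nrow(g) == 1L) return(g)
    gaps <- g$start[-1] - g$end[-nrow(g)]
    tibble(
      id = g$id[1],
      unit = paste(g$unit, collapse = "-"),
      unit_len = min(g$unit_len),
      repeats = max(g$repeats),
      start = g$start[1],
      end = g$end[nrow(g)],
      type = if (all(gaps == 0L)) "c" else "c*",
      left_flank_len = g$start[1],
      right_flank_len = seqlen - g$end[nrow(g)]
    )
  })
  bind_rows(res)
}

#' Select repeat-bearing candidate sequences (Filter 2)
#'
#' Hits whose type is excluded or whose repeat count is below
#' `min_motif_repetition` are ignored. A surviving hit qualifies when both
#' flanking regions are at least `min_flank_len` long. Sequences with
#' exactly one qualifying hit pass; sequences with none are rejected with
#' reason `"no_ssr"`, and sequences carrying several independent qualifying
#' repeats are rejected as `"multi_ssr"` (downstream clustering excises one
#' repeat region per sequence).
#'
#' @param reads merged-read tibble (columns `id`, `seq`, optionally `qual`).
#' @param hits hit tibble from [find_perfect_ssrs()] / [join_compound()].
#' @param config an [pipeline_config()] list (fields `excluded_ssr_types`,
#'   `min_motif_repetition`, `min_flank_len`).
#' @return tibble of passing sequences: read columns plus the chosen hit's
#'   columns (`unit`, `unit_len`, `repeats`, `start`, `end`, `type`). Stage
#'   counts, with a reason histogram, in [stage_info()].
#' @export
filter_candidates <- function(reads, hits, config = pipeline_config()) {
  assert_reads(reads)
  n_in <- nrow(reads)
  ok <- !(hits$type %in% config$excluded_ssr_types) &
    hits$repeats >= config$min_motif_repetition &
    hits$left_flank_len >= config$min_flank_len &
    hits$right_flank_len >= config$min_flank_len
  qual_hits <- hits[ok, , drop = FALSE]
  n_per_id <- table(qual_hits$id)
  n_qual <- as.integer(n_per_id[reads$id])
  n_qual[is.na(n_qual)] <- 0L
  pass <- n_qual == 1L
  chosen <- qual_hits[match(reads$id[pass], qual_hits$id), , drop = FALSE]
  out <- reads[pass, , drop = FALSE]
  out$unit <- chosen$unit
  out$unit_len <- chosen$unit_len
  out$repeats <- chosen$repeats
  out$start <- chosen$start
  out$end <- chosen$end
  out$type <- chosen$type
  reasons <- c(no_ssr = sum(n_qual == 0L), multi_ssr = sum(n_qual > 1L))
  stage_attr(out, n_in, sum(pass), reasons = reasons)
}
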