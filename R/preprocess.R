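#' Adapter removal and quality trimming
#'
#' For each read, the 3' adapter is located by a substitution-only
#' semi-global scan over every start position (error rate at most
#' `adapter_max_error_rate` of the matched length, matched length at least
#' `adapter_min_overlap`); the leftmost acceptable hit and everything
#' downstream of it are removed. A 5'-to-3' sliding window of `window` bases
#' then cuts the read at the first window whose mean Phred quality falls
#' below `min_mean_q`. Reads shorter than `min_len` after both steps are
#' dropped; dropping is a counted, normal outcome (see [stage_info()]).
#'
#' The output is never longer than the input and is always a prefix of the
#' adapter-clipped read.
#'
#' @param reads tibble with columns `id`, `seq`, `qual`.
#' @param adapters character vector of 3' adapter sequences (may be empty).
#' @param window sliding-window width in bases.
#' @param min_mean_q minimum mean Phred quality of a window.
#' @param min_len minimum read length kept.
#' @param adapter_max_error_rate maximum mismatch fraction of an adapter match.
#' @param adapter_min_overlap minimum matched adapter length at the read end.
#' @return tibble of kept (trimmed) reads; stage counts in [stage_info()].
#' @export
trim_reads <- function(reads, adapters = character(), window = 4L,
                       min_mean_q = 15, min_len = 36L,
                       adapter_max_error_rate = 0.10,
                       adapter_min_overlap = 3L) {
  assert_reads(reads, need_qual = TRUE)
  n_in <- nrow(reads)
  if (n_in == 0L) {
    return(stage_attr(reads, 0L, 0L))
  }
  adapters <- toupper(adapters[nzchar(adapters)])
  seqs <- reads$seq
  quals <- reads$qual
  keep_len <- integer(n_in)
  for (i in seq_len(n_in)) {
    s <- seqs[i]
    cut <- nchar(s)
    for (ad in adapters) {
      cut <- min(cut, cpp_adapter_cut(s, ad, adapter_max_error_rate,
                                      as.integer(adapter_min_overlap)))
    }
    if (cut >= window) {
      q <- phred_decode(substr(quals[i], 1L, cut))
      cs <- c(0, cumsum(q))
      nw <- cut - window + 1L
      means <- (cs[(window + 1L):(cut + 1L)] - cs[1:nw]) / window
      bad <- which(means < min_mean_q)
      if (length(bad)) cut <- bad[1] - 1L
    }
    keep_len[i] <- cut
  }
  kept <- keep_len >= min_len
  out <- tibble(
    id = reads$id[kept],
    seq = substr(seqs[kept], 1L, keep_len[kept]),
    qual = substr(quals[kept], 1L, keep_len[kept])
  )
  stage_attr(out, n_in, sum(kept))
}

#' Merge overlapping read pairs
#'
#' The mate (`r2`) is reverse-complemented (qualities reversed) and every
#' overlap length from `min_overlap` up to the shorter read length is
#' scored by mismatch density; the candidate with the lowest density wins,
#' ties going to the longer overlap, and is accepted when its density is at
#' most `max_mismatch_density`. Consensus bases at disagreeing positions take
#' the higher-quality base; consensus qualities are the maximum of the two at
#' agreements and their absolute difference at disagreements.
#'
#' Pairs whose two mates are byte-identical are treated as single-end input
#' supplied twice and pass through unchanged, so a run started with the same
#' FASTQ as forward and reverse reduces each pair to the original read.
#'
#' @param r1,r2 read tibbles of equal length (columns `id`, `seq`, `qual`).
#' @param min_overlap minimum overlap length considered, in bp.
#' @param max_mismatch_density maximum mismatch fraction of the overlap.
#' @return tibble of merged reads (`id` from `r1`); unmerged pairs are
#'   dropped and counted (see [stage_info()]).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_density = 0.25) {
  assert_reads(r1, need_qual = TRUE, arg = "r1")
  assert_reads(r2, need_qual = TRUE, arg = "r2")
  if (nrow(r1) != nrow(r2)) abort("r1 and r2 must have the same number of reads")
  n_in <- nrow(r1)
  ids <- character(0); seqs <- character(0); quals <- character(0)
  if (n_in > 0L) {
    rc2 <- revcomp(r2$seq)
    qr2 <- vapply(strsplit(r2$qual, "", fixed = TRUE),
                  function(ch) paste(rev(ch), collapse = ""), character(1))
    res <- vector("list", n_in)
    for (i in seq_len(n_in)) {
      if (r1$seq[i] == r2$seq[i]) {
        res[[i]] <- list(merged = TRUE, seq = r1$seq[i], qual = r1$qual[i])
      } else {
        res[[i]] <- cpp_merge_pair(r1$seq[i], r1$qual[i], rc2[i], qr2[i],
                                   as.integer(min_overlap),
                                   max_mismatch_density)
      }
    }
    ok <- vapply(res, function(x) isTRUE(x$merged), logical(1))
    ids <- r1$id[ok]
    seqs <- vapply(res[ok], `[[`, character(1), "seq")
    quals <- vapply(res[ok], `[[`, character(1), "qual")
  }
  out <- tibble(id = ids, seq = seqs, qual = quals)
  stage_attr(out, n_in, nrow(out))
}

#' Restriction-site presence test
#'
#' `has_restriction_site()` is the vectorised predicate; an empty pattern
#' disables the filter (every sequence passes), for libraries not produced
#' by enzymatic digestion. `filter_restriction()` applies it to a read table
#' and records stage counts (the stage logged as "Filter 1").
#'
#' @param seqs character vector of sequences.
#' @param pattern residual restriction-site sequence (may be empty).
#' @param anchor where the pattern must occur: a prefix (`"start"`), a
#'   suffix (`"end"`), either terminus (`"either"`, the default: digestion
#'   leaves the residual site at fragment ends) or any position
#'   (`"anywhere"`).
#' @return logical vector.
#' @export
has_restriction_site <- function(seqs, pattern,
                                 anchor = c("either", "start", "end", "anywhere")) {
  anchor <- match.arg(anchor)
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) return(rep(TRUE, length(seqs)))
  switch(anchor,
    start = startsWith(seqs, pattern),
    end = endsWith(seqs, pattern),
    either = startsWith(seqs, pattern) | endsWith(seqs, pattern),
    anywhere = str_detect(seqs, fixed(pattern))
  )
}

#' @rdname has_restriction_site
#' @param reads tibble with columns `id`, `seq`.
#' @export
filter_restriction <- function(reads, pattern,
                               anchor = c("either", "start", "end", "anywhere")) {
  assert_reads(reads)
  keep <- has_restriction_site(reads$seq, pattern, anchor)
  stage_attr(reads[keep, , drop = FALSE], nrow(reads), sum(keep))
}
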