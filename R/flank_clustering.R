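#' Excise the repeat and form flank signatures
#'
#' Removes the repeat span from each candidate sequence and concatenates the
#' two flanking regions into a locus signature: reads from the same genomic
#' locus share (near-)identical flanks whatever their allele length, so the
#' signature is what gets clustered.
#'
#' @param candidates tibble from [filter_candidates()]: columns `id`, `seq`
#'   and the chosen hit's `start`/`end` span (0-based half-open).
#' @return the input with columns `source_id`, `signature`
#'   (`seq[0,start) ++ seq[end,len)`) and `full_length` (length of the
#'   original merged sequence) added.
#' @export
excise_ssr <- function(candidates) {
  assert_reads(candidates, arg = "candidates")
  if (!all(c("start", "end") %in% names(candidates))) {
    abort("`candidates` must carry hit columns start/end (see filter_candidates())")
  }
  n <- nchar(candidates$seq)
  if (nrow(candidates) &&
      any(candidates$start < 0L | candidates$end > n |
          candidates$start > candidates$end)) {
    abort("repeat span out of bounds for its sequence")
  }
  candidates$source_id <- candidates$id
  candidates$signature <- paste0(
    substr(candidates$seq, 1L, candidates$start),
    substr(candidates$seq, candidates$end + 1L, n)
  )
  candidates$full_length <- n
  candidates
}

#' Alignment identity between two sequences
#'
#' One minus the unit-cost global alignment (Levenshtein) distance divided
#' by the length of the shorter sequence, floored at zero: aligned matches
#' per shorter-sequence position. A 100-mer differing by 10 substitutions
#' scores exactly 0.90. This is the identity measure the greedy clustering
#' thresholds at 0.90.
#'
#' @param a,b character vectors of DNA sequences (recycled to equal length).
#' @return numeric vector of identities in `[0, 1]`.
#' @export
#' @examples
#' seq_identity("ACGTACGT", "ACGTACGT")
seq_identity <- function(a, b) {
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
  }
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    abort("identity of an empty sequence is undefined")
  }
  mapply(cpp_identity, a, b, USE.NAMES = FALSE)
}

#' Greedy incremental clustering of flank signatures
#'
#' Signatures are processed by length, longest first (ties keep input
#' order). Each one is compared against existing cluster seeds in
#' seed-creation order and joins the first seed with identity at least
#' `threshold`; otherwise it founds a new cluster. A shared-word prefilter
#' of word length `word_size` (a q-gram lower bound on the edit distance,
#' plus the length-difference bound) skips seed comparisons that provably
#' cannot reach the threshold; it never changes the resulting partition
#' relative to `word_filter = FALSE`.
#'
#' @param signatures tibble from [excise_ssr()] (columns `signature`,
#'   `full_length`).
#' @param threshold minimum member-to-seed identity.
#' @param word_size prefilter word length.
#' @param word_filter set to `FALSE` to disable the prefilter (reference
#'   mode; slower, identical result).
#' @return the input tibble with `cluster_id` (1-based, in seed-creation
#'   order) and `is_seed` columns added; row order is preserved.
#' @export
greedy_cluster <- function(signatures, threshold = 0.90, word_size = 10L,
                           word_filter = TRUE) {
  if (!is.data.frame(signatures) || !"signature" %in% names(signatures)) {
    abort("`signatures` must be a tibble with a signature column (see excise_ssr())")
  }
  n <- nrow(signatures)
  if (n == 0L) {
    signatures$cluster_id <- integer(0)
    signatures$is_seed <- logical(0)
    return(signatures)
  }
  len <- nchar(signatures$signature)
  ord <- order(-len, seq_len(n))
  cl_ord <- cpp_greedy_cluster(signatures$signature[ord], threshold,
                               as.integer(word_size), isTRUE(word_filter))
  cluster_id <- integer(n)
  cluster_id[ord] <- cl_ord
  is_seed <- logical(n)
  is_seed[ord[!duplicated(cl_ord)]] <- TRUE
  signatures$cluster_id <- cluster_id
  signatures$is_seed <- is_seed
  signatures
}

#' Cluster-level selection (Filter 3)
#'
#' Keeps clusters with at least `min_members` members (singleton clusters
#' cannot show polymorphism) and, when `require_motif_consistency` is on,
#' whose members all share one canonical repeat unit (units compared up to
#' rotation, so reads of the same run detected in different phases agree).
#'
#' @param clustered tibble from [greedy_cluster()].
#' @param min_members minimum cluster size kept.
#' @param require_motif_consistency drop clusters mixing repeat units.
#' @return the surviving rows; cluster-level stage counts in [stage_info()].
#' @export
filter_clusters <- function(clustered, min_members = 2L,
                            require_motif_consistency = FALSE) {
  if (nrow(clustered) == 0L) return(stage_attr(clustered, 0L, 0L))
  sizes <- table(clustered$cluster_id)
  ok_ids <- as.integer(names(sizes)[sizes >= min_members])
  if (require_motif_consistency) {
    canon <- canonical_unit(clustered$unit)
    n_units <- tapply(canon, clustered$cluster_id,
                      function(u) length(unique(u)))
    ok_ids <- intersect(ok_ids, as.integer(names(n_units)[n_units == 1L]))
  }
  out <- clustered[clustered$cluster_id %in% ok_ids, , drop = FALSE]
  stage_attr(out, length(sizes), length(ok_ids))
}
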