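#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows desc filter group_by left_join mutate
#'   n row_number select slice summarise ungroup distinct
#' @importFrom stringr str_count str_detect str_sub fixed
#' @importFrom Rcpp sourceCpp
#' @useDynLib ssrmarkers, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. IUPAC ambiguity codes other than `N` are not handled;
#' `N` complements to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("GATTACA")
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## Phred+33 helpers -----------------------------------------------------------

phred_decode <- function(qual) utf8ToInt(qual) - 33L

phred_encode <- function(q) intToUtf8(q + 33L)

## A motif unit is primitive when it is not a whole-number repetition of a
## shorter unit (e.g. "ACAC" is not primitive, "AC" is).
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(unit, 1L, d), k %/% d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical rotation of a repeat unit
#'
#' The lexicographically smallest rotation of the unit, used when comparing
#' motifs across reads of the same locus (the observed phase of a repeat is
#' arbitrary). Compound units (joined by `-`) canonicalise constituent-wise.
#'
#' @param unit character vector of motif units.
#' @return character vector of canonical units.
#' @export
canonical_unit <- function(unit) {
  one <- function(u) {
    if (grepl("-", u, fixed = TRUE)) {
      parts <- strsplit(u, "-", fixed = TRUE)[[1]]
      return(paste(vapply(parts, one, character(1)), collapse = "-"))
    }
    k <- nchar(u)
    if (k <= 1L) return(u)
    rot <- vapply(seq_len(k), function(i) {
      paste0(substr(u, i, k), substr(u, 1L, i - 1L))
    }, character(1))
    min(rot)
  }
  vapply(unit, one, character(1), USE.NAMES = FALSE)
}

## Run `code` under a fixed RNG seed without disturbing the caller's RNG
## stream.
with_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Stage bookkeeping: every filtering stage records input = kept + dropped.
stage_attr <- function(x, input, kept, reasons = NULL) {
  attr(x, "stage") <- list(input = as.integer(input), kept = as.integer(kept),
                           dropped = as.integer(input - kept),
                           reasons = reasons)
  x
}

#' Per-stage bookkeeping of a filtering step
#'
#' Stage-aware functions (trimming, merging, the three filters) attach the
#' number of records in, kept and dropped to their result; this retrieves it.
#'
#' @param x a tibble returned by a stage function.
#' @return a list with elements `input`, `kept`, `dropped` and (optionally)
#'   `reasons`, a named drop-reason histogram.
#' @export
stage_info <- function(x) attr(x, "stage")

assert_reads <- function(reads, need_qual = FALSE, arg = "reads") {
  if (!is.data.frame(reads) || !all(c("id", "seq") %in% names(reads))) {
    abort(sprintf("`%s` must be a data frame with columns id, seq", arg))
  }
  if (need_qual && (!"qual" %in% names(reads) || anyNA(reads$qual))) {
    abort(sprintf("`%s` must carry per-base qualities (column qual)", arg))
  }
  invisible(TRUE)
}
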