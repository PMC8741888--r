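#' Read a FASTQ file into a tibble
#'
#' Strict 4-line-record FASTQ with Phred+33 qualities. Records are returned
#' in file order. Malformed records (missing `+` separator, sequence/quality
#' length mismatch, truncated final record) raise an error naming the
#' offending line.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a tibble with columns `id` (header without the leading `@`),
#'   `seq` and `qual` (Phred+33 string, same length as `seq`).
#' @seealso [write_fastq()], [phred_scores()]
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  if (n %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record at line %d of '%s'", n, path))
  }
  idx <- seq(1L, n, by = 4L)
  heads <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) {
    abort(sprintf("expected '@' header at line %d of '%s'",
                  idx[bad[1]], path))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("expected '+' separator at line %d of '%s'",
                  idx[bad[1]] + 2L, path))
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    abort(sprintf("sequence/quality length mismatch at line %d of '%s'",
                  idx[bad[1]] + 3L, path))
  }
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) {
    abort(sprintf("empty sequence at line %d of '%s'", idx[bad[1]] + 1L, path))
  }
  tibble(id = sub("^@", "", heads), seq = toupper(seqs), qual = quals)
}

#' @rdname read_fastq
#' @param reads a tibble with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  assert_reads(reads, need_qual = TRUE)
  out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of quality strings.
#' @return a list of integer vectors.
#' @export
phred_scores <- function(qual) lapply(qual, phred_decode)

#' Read/write FASTA (used for intermediate dumps)
#'
#' @param path file path.
#' @return `read_fasta()` returns a tibble with columns `id`, `seq` and an
#'   all-`NA` `qual` column so the result drops into the same verbs as FASTQ
#'   input.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  is_head <- startsWith(lines, ">")
  if (!is_head[1]) abort(sprintf("'%s' does not start with a FASTA header", path))
  grp <- cumsum(is_head)
  ids <- sub("^>", "", lines[is_head])
  seqs <- vapply(split(lines[!is_head], grp[!is_head]),
                 paste, character(1), collapse = "")
  seqs <- seqs[as.character(seq_along(ids))]
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(seqs))) abort(sprintf("record without sequence in '%s'", path))
  tibble(id = ids, seq = toupper(unname(seqs)), qual = NA_character_)
}

#' @rdname read_fasta
#' @param seqs a tibble with columns `id` and `seq`.
#' @export
write_fasta <- function(seqs, path) {
  assert_reads(seqs, arg = "seqs")
  writeLines(as.vector(rbind(paste0(">", seqs$id), seqs$seq)), path)
  invisible(path)
}

## ----------------------------------------------------------------------------
## Pipeline configuration

#' Pipeline configuration
#'
#' Builds the full parameter set of the pipeline with its documented
#' defaults. Any parameter can be overridden by name; [read_config()] layers
#' a `KEY=value` file on top of these defaults.
#'
#' Key parameters (file-key spelling in parentheses):
#' \describe{
#'   \item{min_allele_cnt (MIN_ALLEL_CNT)}{minimum observed alleles for a
#'     locus to be selected; default 5.}
#'   \item{special_search / special_min_potential (SPECIAL_SEARCH,
#'     SPECIAL_DIF)}{when Special Search is on, selection is instead based on
#'     the potential allele count; default threshold 8.}
#'   \item{min_flank_len (MIN_FLANK_LEN)}{minimum length of each flanking
#'     region for a repeat-bearing sequence to pass Filter 2; default 50.}
#'   \item{max_diff_tm (MAX_DIFF_TM)}{maximum melting-temperature difference
#'     between the two primers of a pair, in deg C; default 0.5.}
#' }
#'
#' @param ... named overrides of any configuration field.
#' @return a list of class `ssr_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(min_flank_len = 75, special_search = TRUE)
#' cfg$min_allele_cnt
pipeline_config <- function(...) {
  cfg <- list(
    # preprocessing
    adapters = "AGATCGGAAGAGC",
    restriction_pattern = "GATC",
    restriction_anchor = "either",
    trim_window = 4L,
    trim_min_q = 15,
    trim_min_len = 36L,
    adapter_max_error_rate = 0.10,
    adapter_min_overlap = 3L,
    merge_min_overlap = 10L,
    merge_max_mismatch_density = 0.25,
    # SSR mining / Filter 2
    min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
    compound_max_gap = 100L,
    excluded_ssr_types = character(),
    min_motif_repetition = 5L,
    min_flank_len = 50L,
    # clustering / Filter 3
    cluster_identity = 0.90,
    cluster_word_size = 10L,
    cluster_min_members = 2L,
    cluster_motif_consistency = FALSE,
    # locus selection
    min_allele_cnt = 5L,
    special_search = FALSE,
    special_min_potential = 8L,
    # primer design
    max_diff_tm = 0.5,
    product_size_range = c(100L, 300L),
    primer_min_size = 18L,
    primer_max_size = 27L,
    primer_opt_size = 20L,
    primer_min_tm = 57,
    primer_max_tm = 63,
    primer_opt_tm = 60,
    primer_min_gc = 20,
    primer_max_gc = 80,
    primer_max_poly_x = 4L,
    primer_max_self_comp = 8L,
    primer_num_return = 5L,
    avoid_primer_in_ssr = FALSE,
    oligo_conc = 5e-8,
    monovalent = 0.05,
    # output / reproducibility
    prefix = "SSR",
    rng_seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    length(cfg$product_size_range) == 2L,
    cfg$product_size_range[1] <= cfg$product_size_range[2],
    cfg$min_allele_cnt >= 1, cfg$special_min_potential >= 2,
    cfg$min_flank_len >= 0, cfg$max_diff_tm >= 0,
    cfg$min_motif_repetition >= 2,
    cfg$cluster_identity > 0, cfg$cluster_identity <= 1,
    length(cfg$min_repeats) == 6L, all(cfg$min_repeats >= 2),
    cfg$restriction_anchor %in% c("start", "end", "either", "anywhere"),
    all(cfg$excluded_ssr_types %in% c(paste0("p", 1:6), "c", "c*"))
  )
  structure(cfg, class = "ssr_config")
}

## KEY=value file keys -> config fields, with a parser per key.
config_key_map <- function() {
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("not a number", call. = FALSE)
    v
  }
  int <- function(x) as.integer(num(x))
  lgl <- function(x) {
    x <- toupper(trimws(x))
    if (x %in% c("ON", "TRUE", "YES", "1")) return(TRUE)
    if (x %in% c("OFF", "FALSE", "NO", "0")) return(FALSE)
    stop("not a logical (use ON/OFF)", call. = FALSE)
  }
  csv <- function(x) {
    out <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    out[nzchar(out)]
  }
  rng <- function(x) {
    v <- suppressWarnings(as.integer(strsplit(x, "-", fixed = TRUE)[[1]]))
    if (length(v) != 2L || anyNA(v)) stop("expected 'min-max'", call. = FALSE)
    v
  }
  ints <- function(x) {
    v <- suppressWarnings(as.integer(csv(x)))
    if (anyNA(v)) stop("expected comma-separated integers", call. = FALSE)
    v
  }
  list(
    ADAPTERS = list(field = "adapters", parse = csv),
    RESTRICTION_PATTERN = list(field = "restriction_pattern", parse = toupper),
    RESTRICTION_ANCHOR = list(field = "restriction_anchor", parse = tolower),
    TRIM_WINDOW = list(field = "trim_window", parse = int),
    TRIM_MIN_QUALITY = list(field = "trim_min_q", parse = num),
    TRIM_MIN_LEN = list(field = "trim_min_len", parse = int),
    ADAPTER_MAX_ERROR_RATE = list(field = "adapter_max_error_rate", parse = num),
    MERGE_MIN_OVERLAP = list(field = "merge_min_overlap", parse = int),
    MERGE_MAX_MISMATCH_DENSITY = list(field = "merge_max_mismatch_density", parse = num),
    MIN_REPEATS = list(field = "min_repeats", parse = ints),
    COMPOUND_MAX_GAP = list(field = "compound_max_gap", parse = int),
    EXCLUDED_SSR_TYPES = list(field = "excluded_ssr_types", parse = csv),
    MIN_MOTIF_REPETITION = list(field = "min_motif_repetition", parse = int),
    MIN_FLANK_LEN = list(field = "min_flank_len", parse = int),
    CLUSTER_IDENTITY = list(field = "cluster_identity", parse = num),
    CLUSTER_WORD_SIZE = list(field = "cluster_word_size", parse = int),
    CLUSTER_MIN_MEMBERS = list(field = "cluster_min_members", parse = int),
    CLUSTER_MOTIF_CONSISTENCY = list(field = "cluster_motif_consistency", parse = lgl),
    MIN_ALLEL_CNT = list(field = "min_allele_cnt", parse = int),
    SPECIAL_SEARCH = list(field = "special_search", parse = lgl),
    SPECIAL_DIF = list(field = "special_min_potential", parse = int),
    MAX_DIFF_TM = list(field = "max_diff_tm", parse = num),
    PRODUCT_SIZE_RANGE = list(field = "product_size_range", parse = rng),
    PRIMER_MIN_SIZE = list(field = "primer_min_size", parse = int),
    PRIMER_MAX_SIZE = list(field = "primer_max_size", parse = int),
    PRIMER_OPT_SIZE = list(field = "primer_opt_size", parse = int),
    PRIMER_MIN_TM = list(field = "primer_min_tm", parse = num),
    PRIMER_MAX_TM = list(field = "primer_max_tm", parse = num),
    PRIMER_OPT_TM = list(field = "primer_opt_tm", parse = num),
    PRIMER_MIN_GC = list(field = "primer_min_gc", parse = num),
    PRIMER_MAX_GC = list(field = "primer_max_gc", parse = num),
    PRIMER_MAX_POLY_X = list(field = "primer_max_poly_x", parse = int),
    PRIMER_MAX_SELF_COMP = list(field = "primer_max_self_comp", parse = int),
    PRIMER_NUM_RETURN = list(field = "primer_num_return", parse = int),
    AVOID_PRIMER_IN_SSR = list(field = "avoid_primer_in_ssr", parse = lgl),
    OLIGO_CONC = list(field = "oligo_conc", parse = num),
    MONOVALENT = list(field = "monovalent", parse = num),
    PREFIX = list(field = "prefix", parse = identity),
    SEED = list(field = "rng_seed", parse = int)
  )
}

#' Read a KEY=value configuration file
#'
#' Lines of the form `KEY=value`; `#` starts a comment; blank lines are
#' ignored. Missing keys take the defaults of [pipeline_config()]; unknown
#' keys produce a warning; an unparseable value for a known key is fatal.
#'
#' @param path path to the configuration file.
#' @param base configuration to layer the file onto.
#' @return an `ssr_config` list.
#' @export
read_config <- function(path, base = pipeline_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  map <- config_key_map()
  cfg <- unclass(base)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      warn(sprintf("ignoring malformed config line: '%s'", ln))
      next
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    entry <- map[[toupper(key)]]
    if (is.null(entry)) {
      warn(sprintf("unknown configuration key '%s' ignored", key))
      next
    }
    parsed <- tryCatch(entry$parse(val), error = function(e) {
      abort(sprintf("invalid value '%s' for configuration key '%s': %s",
                    val, key, conditionMessage(e)))
    })
    cfg[[entry$field]] <- parsed
  }
  validate_config(cfg)
}

## ----------------------------------------------------------------------------
## Twelve-column results table

output_columns <- c("ID", "Size", "Forward_Primer", "Forward_Tm",
                    "Reverse_Primer", "Reverse_Tm", "Motif", "Range",
                    "Alleles", "Potential_Alleles", "Flag", "Sequence")

#' Write / read the twelve-column results table
#'
#' One header line, then one tab-separated line per designed primer pair with
#' exactly twelve fields: locus/pair id, product size, forward primer and its
#' melting temperature, reverse primer and its melting temperature, motif as
#' `(UNIT)count`, allele length range as `min-max`, observed and potential
#' allele counts, the `|BEST|` flag (empty for non-best pairs), and the locus
#' representative sequence. Melting temperatures are printed with two
#' decimals.
#'
#' @param records tibble of output records ordered by locus then pair number
#'   (as produced by [design_primers()] / [run_pipeline()]).
#' @param path output file path.
#' @return `write_output_table()` returns `path` invisibly;
#'   `read_output_table()` returns the records tibble.
#' @export
write_output_table <- function(records, path) {
  out <- tibble(
    ID = records$id,
    Size = as.integer(records$size),
    Forward_Primer = records$fwd_seq,
    Forward_Tm = sprintf("%.2f", records$fwd_tm),
    Reverse_Primer = records$rev_seq,
    Reverse_Tm = sprintf("%.2f", records$rev_tm),
    Motif = records$motif,
    Range = records$range,
    Alleles = as.integer(records$alleles_observed),
    Potential_Alleles = as.integer(records$alleles_potential),
    Flag = records$best_flag,
    Sequence = records$sequence
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_output_table
#' @export
read_output_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    ID = "c", Size = "i", Forward_Primer = "c", Forward_Tm = "d",
    Reverse_Primer = "c", Reverse_Tm = "d", Motif = "c", Range = "c",
    Alleles = "i", Potential_Alleles = "i", Flag = "c", Sequence = "c"
  ), progress = FALSE)
  tibble(
    id = tab$ID, size = tab$Size,
    fwd_seq = tab$Forward_Primer, fwd_tm = tab$Forward_Tm,
    rev_seq = tab$Reverse_Primer, rev_tm = tab$Reverse_Tm,
    motif = tab$Motif, range = tab$Range,
    alleles_observed = tab$Alleles, alleles_potential = tab$Potential_Alleles,
    best_flag = ifelse(is.na(tab$Flag), "", tab$Flag),
    sequence = tab$Sequence
  )
}
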