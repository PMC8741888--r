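## Unified nearest-neighbor thermodynamic parameters for DNA/DNA duplexes:
## per-stack enthalpy (kcal/mol) and entropy (cal/(mol*K)), plus duplex
## initiation terms per terminal base pair and the symmetry correction for
## self-complementary oligos.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
NN_SYM_DS <- -1.4
GAS_R <- 1.987  # cal/(mol*K)

#' Oligonucleotide melting temperature
#'
#' Nearest-neighbor thermodynamics with the unified DNA parameter set:
#' `Tm = 1000 * dH / (dS + R * ln(C/4)) - 273.15`, where `dH`/`dS` sum the
#' per-stack terms plus the terminal initiation terms, `C` is the total
#' oligo concentration (`C/1` for self-complementary oligos, which also get
#' the symmetry entropy correction), and the monovalent-salt correction
#' `0.368 * (N - 1) * ln([Na+])` is added to the entropy.
#'
#' @param oligo character vector of primer sequences (10-36 nt, `ACGT` only).
#' @param oligo_conc total oligo concentration in mol/L (default 50 nM).
#' @param monovalent monovalent cation concentration in mol/L (default 50 mM).
#' @return numeric vector of melting temperatures in deg C.
#' @export
#' @examples
#' melting_temperature("AGCGTCCAAGTTCGGGATAG")
melting_temperature <- function(oligo, oligo_conc = 5e-8, monovalent = 0.05) {
  n <- nchar(oligo)
  if (any(n < 10L | n > 36L)) {
    abort("oligo length must be between 10 and 36 nt")
  }
  if (any(grepl("[^ACGT]", oligo))) {
    abort("oligo contains ambiguous bases (only A/C/G/T supported)")
  }
  chars <- strsplit(oligo, "", fixed = TRUE)
  vapply(seq_along(oligo), function(i) {
    ch <- chars[[i]]
    len <- length(ch)
    stacks <- paste0(ch[-len], ch[-1])
    dh <- sum(NN_DH[stacks])
    ds <- sum(NN_DS[stacks])
    term <- ifelse(ch[c(1L, len)] %in% c("G", "C"), "GC", "AT")
    dh <- dh + sum(NN_INIT_DH[term])
    ds <- ds + sum(NN_INIT_DS[term])
    selfcomp <- oligo[i] == revcomp(oligo[i])
    conc_div <- 4
    if (selfcomp) {
      ds <- ds + NN_SYM_DS
      conc_div <- 1
    }
    ds_salt <- 0.368 * (len - 1) * log(monovalent)
    1000 * dh / (ds + ds_salt + GAS_R * log(oligo_conc / conc_div)) - 273.15
  }, numeric(1))
}

#' Primer constraint block
#'
#' Conventional design defaults: length 18-27 (optimum 20), melting
#' temperature 57-63 deg C (optimum 60), GC content 20-80%, homopolymers of
#' at most 4, internal complementary stretches of at most 8, and up to 5
#' returned pairs per locus.
#'
#' @param ... named overrides of any field.
#' @return a list of primer constraints.
#' @export
primer_params <- function(...) {
  p <- list(min_size = 18L, max_size = 27L, opt_size = 20L,
            min_tm = 57, max_tm = 63, opt_tm = 60,
            min_gc = 20, max_gc = 80,
            max_poly_x = 4L, max_self_comp = 8L, num_return = 5L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    abort(paste0("unknown primer parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  p
}

config_primer_params <- function(cfg) {
  primer_params(min_size = cfg$primer_min_size, max_size = cfg$primer_max_size,
                opt_size = cfg$primer_opt_size, min_tm = cfg$primer_min_tm,
                max_tm = cfg$primer_max_tm, opt_tm = cfg$primer_opt_tm,
                min_gc = cfg$primer_min_gc, max_gc = cfg$primer_max_gc,
                max_poly_x = cfg$primer_max_poly_x,
                max_self_comp = cfg$primer_max_self_comp,
                num_return = cfg$primer_num_return)
}

## TRUE when the primer contains a complementary internal stretch longer
## than max_len (some k-mer and its reverse complement both occur).
has_self_comp <- function(primer, max_len) {
  k <- max_len + 1L
  n <- nchar(primer)
  if (n < k) return(FALSE)
  kmers <- substring(primer, 1:(n - k + 1L), k:n)
  any(revcomp(unique(kmers)) %in% kmers)
}

#' Enumerate primer candidates on a template
#'
#' All template substrings (reverse complements, for reverse primers) lying
#' entirely inside `region` whose length, GC content, homopolymer runs,
#' internal self-complementarity and melting temperature satisfy `params`.
#' With `avoid_in_ssr`, candidates overlapping `ssr_span` are excluded.
#'
#' @param template the locus representative sequence.
#' @param region 0-based half-open span the primer must lie within
#'   (default: the whole template).
#' @param orientation `"forward"` or `"reverse"`.
#' @param params a [primer_params()] list.
#' @param ssr_span 0-based half-open repeat span on the template.
#' @param avoid_in_ssr exclude candidates intersecting `ssr_span`.
#' @param oligo_conc,monovalent passed to [melting_temperature()].
#' @return tibble of candidates: `seq` (5'->3'), `tstart`, `tend` (template
#'   span, 0-based half-open), `length`, `tm`, `gc`, `orientation`.
#' @export
enumerate_candidates <- function(template, region = NULL,
                                 orientation = c("forward", "reverse"),
                                 params = primer_params(), ssr_span = NULL,
                                 avoid_in_ssr = FALSE, oligo_conc = 5e-8,
                                 monovalent = 0.05) {
  orientation <- match.arg(orientation)
  n <- nchar(template)
  if (is.null(region)) region <- c(0L, n)
  if (region[1] < 0L || region[2] > n || region[1] > region[2]) {
    abort("`region` must be a 0-based half-open span within the template")
  }
  empty <- tibble(seq = character(), tstart = integer(), tend = integer(),
                  length = integer(), tm = numeric(), gc = numeric(),
                  orientation = character())
  grid <- do.call(rbind, lapply(params$min_size:params$max_size, function(len) {
    if (region[2] - region[1] < len) return(NULL)
    tstart <- region[1]:(region[2] - len)
    cbind(tstart = tstart, len = len)
  }))
  if (is.null(grid) || nrow(grid) == 0L) return(empty)
  tstart <- as.integer(grid[, "tstart"])
  len <- as.integer(grid[, "len"])
  tend <- tstart + len
  sub <- substring(template, tstart + 1L, tend)
  primer <- if (orientation == "forward") sub else revcomp(sub)
  ok <- !grepl("[^ACGT]", primer)
  gc <- (str_count(primer, "G") + str_count(primer, "C")) / len * 100
  ok <- ok & gc >= params$min_gc & gc <= params$max_gc
  poly <- sprintf("A{%1$d}|C{%1$d}|G{%1$d}|T{%1$d}", params$max_poly_x + 1L)
  ok <- ok & !grepl(poly, primer)
  if (isTRUE(avoid_in_ssr) && !is.null(ssr_span)) {
    ok <- ok & (tend <= ssr_span[1] | tstart >= ssr_span[2])
  }
  idx <- which(ok)
  idx <- idx[!vapply(primer[idx], has_self_comp, logical(1),
                     max_len = params$max_self_comp)]
  if (length(idx) == 0L) return(empty)
  tm <- melting_temperature(primer[idx], oligo_conc, monovalent)
  keep <- tm >= params$min_tm & tm <= params$max_tm
  idx <- idx[keep]
  if (length(idx) == 0L) return(empty)
  tibble(seq = primer[idx], tstart = tstart[idx], tend = tend[idx],
         length = len[idx], tm = tm[keep], gc = gc[idx],
         orientation = orientation)
}

#' Pair and rank primer candidates
#'
#' Every forward/reverse combination whose primers do not overlap each
#' other, whose product (forward 5' end to reverse 5' end on the template)
#' lies within `product_size_range` and spans the whole repeat, and whose
#' melting-temperature difference is at most `max_diff_tm`, is scored
#' `penalty = sum over both primers of (|tm - opt_tm| + 0.25 * |length -
#' opt_size|) + 2 * |tm_fwd - tm_rev|` and sorted by ascending penalty (ties:
#' smaller product, then leftmost forward start, then leftmost reverse
#' start). The top `num_return` pairs are returned and the first is flagged
#' best.
#'
#' @param fwd,rev candidate tibbles from [enumerate_candidates()].
#' @param ssr_span 0-based half-open repeat span the product must cover.
#' @param max_diff_tm maximum melting-temperature difference, deg C.
#' @param product_size_range allowed product length range, bp.
#' @param params a [primer_params()] list (optimum size/Tm, `num_return`).
#' @param num_return maximum pairs returned.
#' @return tibble of ranked pairs: forward and reverse columns (prefixed
#'   `fwd_`/`rev_`), `product_size`, `penalty`, `pair_number`, `is_best`.
#'   An empty result means the locus yields no acceptable pair and is
#'   dropped from the output (a counted outcome).
#' @export
pair_and_rank <- function(fwd, rev, ssr_span, max_diff_tm = 0.5,
                          product_size_range = c(100L, 300L),
                          params = primer_params(),
                          num_return = params$num_return) {
  empty <- tibble(fwd_seq = character(), fwd_tstart = integer(),
                  fwd_tend = integer(), fwd_length = integer(),
                  fwd_tm = numeric(), rev_seq = character(),
                  rev_tstart = integer(), rev_tend = integer(),
                  rev_length = integer(), rev_tm = numeric(),
                  product_size = integer(), penalty = numeric(),
                  pair_number = integer(), is_best = logical())
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  g <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  f <- fwd[g$f, ]; r <- rev[g$r, ]
  product <- r$tend - f$tstart
  dtm <- abs(f$tm - r$tm)
  ok <- f$tend <= r$tstart &
    product >= product_size_range[1] & product <= product_size_range[2] &
    f$tstart <= ssr_span[1] & r$tend >= ssr_span[2] &
    dtm <= max_diff_tm + 1e-9
  if (!any(ok)) return(empty)
  f <- f[ok, ]; r <- r[ok, ]
  product <- product[ok]; dtm <- dtm[ok]
  penalty <- abs(f$tm - params$opt_tm) + 0.25 * abs(f$length - params$opt_size) +
    abs(r$tm - params$opt_tm) + 0.25 * abs(r$length - params$opt_size) +
    2 * dtm
  ord <- order(penalty, product, f$tstart, r$tstart)
  ord <- ord[seq_len(min(num_return, length(ord)))]
  tibble(
    fwd_seq = f$seq[ord], fwd_tstart = f$tstart[ord], fwd_tend = f$tend[ord],
    fwd_length = f$length[ord], fwd_tm = f$tm[ord],
    rev_seq = r$seq[ord], rev_tstart = r$tstart[ord], rev_tend = r$tend[ord],
    rev_length = r$length[ord], rev_tm = r$tm[ord],
    product_size = as.integer(product[ord]), penalty = penalty[ord],
    pair_number = seq_along(ord), is_best = seq_along(ord) == 1L
  )
}

## Re-detect the repeat span on a representative rather than trusting the
## span carried over from its read: upstream spans can be mis-anchored
## (e.g. placed within the repetitive region) relative to the sequence the
## primers are actually designed on.
locate_ssr_on_rep <- function(rep_seq, motif_unit, config) {
  hits <- find_perfect_ssrs(c(rep = rep_seq), config$min_repeats)
  hits <- join_compound(hits, config$compound_max_gap)
  hits <- hits[!(hits$type %in% config$excluded_ssr_types) &
                 hits$repeats >= config$min_motif_repetition, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  same <- canonical_unit(hits$unit) == canonical_unit(motif_unit)
  if (any(same)) hits <- hits[same, , drop = FALSE]
  hits[which.max(hits$repeats), , drop = FALSE]
}

#' Design ranked primer pairs for selected loci
#'
#' For each locus the repeat span is re-detected on the representative
#' sequence, forward and reverse candidates are enumerated on the regions
#' compatible with spanning the repeat, and candidates are paired and
#' ranked under the configured constraints. Loci yielding no acceptable
#' pair are dropped and counted.
#'
#' @param loci selected loci tibble ([select_loci()]) carrying a
#'   `representative` sequence column.
#' @param config an [pipeline_config()] list.
#' @return twelve-column records tibble (see [write_output_table()]);
#'   locus-level stage counts in [stage_info()].
#' @export
design_primers <- function(loci, config = pipeline_config()) {
  params <- config_primer_params(config)
  records <- vector("list", nrow(loci))
  n_with_pairs <- 0L
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    rep_seq <- locus$representative
    n <- nchar(rep_seq)
    hit <- locate_ssr_on_rep(rep_seq, locus$motif_unit, config)
    if (is.null(hit)) next
    span <- c(hit$start, hit$end)
    fwd <- enumerate_candidates(
      rep_seq, region = c(0L, min(n, span[1] + params$max_size)),
      orientation = "forward", params = params, ssr_span = span,
      avoid_in_ssr = config$avoid_primer_in_ssr,
      oligo_conc = config$oligo_conc, monovalent = config$monovalent)
    fwd <- fwd[fwd$tstart <= span[1], , drop = FALSE]
    rev <- enumerate_candidates(
      rep_seq, region = c(max(0L, span[2] - params$max_size), n),
      orientation = "reverse", params = params, ssr_span = span,
      avoid_in_ssr = config$avoid_primer_in_ssr,
      oligo_conc = config$oligo_conc, monovalent = config$monovalent)
    rev <- rev[rev$tend >= span[2], , drop = FALSE]
    pairs <- pair_and_rank(fwd, rev, span, config$max_diff_tm,
                           config$product_size_range, params)
    if (nrow(pairs) == 0L) next
    n_with_pairs <- n_with_pairs + 1L
    records[[i]] <- render_records(locus, pairs, config$prefix, hit)
  }
  out <- bind_rows(records)
  if (nrow(out) == 0L) {
    out <- tibble(id = character(), size = integer(), fwd_seq = character(),
                  fwd_tm = numeric(), rev_seq = character(),
                  rev_tm = numeric(), motif = character(), range = character(),
                  alleles_observed = integer(), alleles_potential = integer(),
                  best_flag = character(), sequence = character())
  }
  stage_attr(out, nrow(loci), n_with_pairs)
}

#' Render ranked pairs as twelve-column output records
#'
#' Ids are `<prefix><locus_number>-<pair_number>`; the motif cell is
#' `(UNIT)count` from the repeat as located on the representative; the
#' range cell is `min-max` of the allele lengths; only the rank-1 pair
#' carries the `|BEST|` flag. Melting temperatures are rounded to two
#' decimals (the precision of the output table).
#'
#' @param locus one-row loci tibble.
#' @param pairs ranked pairs from [pair_and_rank()].
#' @param prefix id prefix.
#' @param hit one-row hit tibble for the repeat on the representative.
#' @return records tibble, one row per pair.
#' @export
render_records <- function(locus, pairs, prefix, hit) {
  tibble(
    id = sprintf("%s%d-%d", prefix, locus$locus_number, pairs$pair_number),
    size = pairs$product_size,
    fwd_seq = pairs$fwd_seq,
    fwd_tm = round(pairs$fwd_tm, 2),
    rev_seq = pairs$rev_seq,
    rev_tm = round(pairs$rev_tm, 2),
    motif = sprintf("(%s)%d", hit$unit, hit$repeats),
    range = sprintf("%d-%d", locus$range_min, locus$range_max),
    alleles_observed = locus$observed,
    alleles_potential = locus$potential,
    best_flag = ifelse(pairs$is_best, "|BEST|", ""),
    sequence = locus$representative
  )
}

#' Post-hoc validation of emitted primer records
#'
#' Re-derives every hard constraint from the records themselves: the
#' primers must occur on the representative at positions reproducing the
#' stated product size, the product must lie within the configured range
#' and span the re-detected repeat, the pair melting-temperature difference
#' must respect `max_diff_tm`, and, when the in-repeat post-filter is on,
#' neither primer may intersect the repeat span.
#'
#' @param records records tibble ([design_primers()] output).
#' @param config the configuration the records were produced under.
#' @return tibble with one row per record and logical check columns;
#'   attribute `ok` is `TRUE` when every check passed.
#' @export
validate_primer_records <- function(records, config = pipeline_config()) {
  checks <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    template <- rec$sequence
    unit <- sub("^\\(([^)]*)\\).*$", "\\1", rec$motif)
    hit <- locate_ssr_on_rep(template, unit, config)
    fpos <- as.integer(regexpr(rec$fwd_seq, template, fixed = TRUE)) - 1L
    rpos <- as.integer(regexpr(revcomp(rec$rev_seq), template, fixed = TRUE)) - 1L
    rend <- rpos + nchar(rec$rev_seq)
    product_ok <- fpos >= 0L && rpos >= 0L &&
      (rend - fpos) == rec$size &&
      rec$size >= config$product_size_range[1] &&
      rec$size <= config$product_size_range[2]
    span_ok <- !is.null(hit) && fpos >= 0L && rpos >= 0L &&
      fpos <= hit$start && rend >= hit$end
    tm_ok <- abs(rec$fwd_tm - rec$rev_tm) <= config$max_diff_tm + 0.011
    in_ssr_ok <- TRUE
    if (isTRUE(config$avoid_primer_in_ssr) && !is.null(hit)) {
      in_ssr_ok <- (fpos + nchar(rec$fwd_seq) <= hit$start || fpos >= hit$end) &&
        (rend <= hit$start || rpos >= hit$end)
    }
    checks[[i]] <- tibble(id = rec$id, product_ok = product_ok,
                          span_ok = span_ok, tm_ok = tm_ok,
                          in_ssr_ok = in_ssr_ok)
  }
  out <- bind_rows(checks)
  attr(out, "ok") <- nrow(out) == 0L ||
    all(out$product_ok & out$span_ok & out$tm_ok & out$in_ssr_ok)
  out
}
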