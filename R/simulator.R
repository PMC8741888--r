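#' Simulated multi-individual SSR library configuration
#'
#' Defaults emulate the kind of library the pipeline targets: a pooled,
#' untagged sample of 36 diploid individuals, restriction-digested
#' (residual `GATC` at both fragment ends), adapter-ligated, enriched for
#' di-/tetranucleotide repeats and sequenced 250 bp paired-end, with
#' fragment sizes small enough that the mates overlap across the repeat.
#' Every fragment carries one repeat flanked by two locus-unique regions.
#'
#' @param n_individuals pooled individuals (each contributes `ploidy`
#'   alleles per locus).
#' @param n_loci planted loci.
#' @param ploidy chromosome copies per individual.
#' @param read_len read length, bp.
#' @param coverage read pairs per allele copy per individual.
#' @param error_rate i.i.d. per-base substitution probability.
#' @param flank_len length of each unique flanking region, bp.
#' @param restriction_pattern residual site placed at both fragment ends.
#' @param adapter 3' adapter ligated after the fragment.
#' @param motif_units repeat units sampled for loci.
#' @param alleles_range range of distinct planted alleles per locus.
#' @param repeats_range_di,repeats_range_tetra repeat-count ranges for
#'   units of length <= 2 and > 2.
#' @param min_overlap mate overlap the fragment sizes must allow.
#' @param seed RNG seed; the same seed gives byte-identical libraries.
#' @return a list of class `ssr_sim_config`.
#' @export
sim_config <- function(n_individuals = 36L, n_loci = 20L, ploidy = 2L,
                       read_len = 250L, coverage = 3L, error_rate = 0.001,
                       flank_len = 120L, restriction_pattern = "GATC",
                       adapter = "AGATCGGAAGAGC",
                       motif_units = c("AC", "AG", "GT", "CT",
                                       "ATCT", "AGAT", "ACAG", "AAGG"),
                       alleles_range = c(3L, 8L),
                       repeats_range_di = c(7L, 24L),
                       repeats_range_tetra = c(5L, 14L),
                       min_overlap = 10L, seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_loci = as.integer(n_loci), ploidy = as.integer(ploidy),
              read_len = as.integer(read_len), coverage = as.integer(coverage),
              error_rate = error_rate, flank_len = as.integer(flank_len),
              restriction_pattern = toupper(restriction_pattern),
              adapter = toupper(adapter), motif_units = toupper(motif_units),
              alleles_range = as.integer(alleles_range),
              repeats_range_di = as.integer(repeats_range_di),
              repeats_range_tetra = as.integer(repeats_range_tetra),
              min_overlap = as.integer(min_overlap), seed = as.integer(seed))
  max_ssr <- max(c(repeats_range_di[2] * 2L,
                   repeats_range_tetra[2] * 4L))
  max_frag <- 2L * nchar(cfg$restriction_pattern) + 2L * cfg$flank_len + max_ssr
  if (max_frag > 2L * cfg$read_len - cfg$min_overlap) {
    abort(sprintf(paste0("fragments up to %d bp cannot guarantee a %d bp mate",
                         " overlap at read length %d"),
                  max_frag, cfg$min_overlap, cfg$read_len))
  }
  structure(cfg, class = "ssr_sim_config")
}

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Flanks are rejection-sampled so that simulation artefacts cannot confound
## the pipeline: no incidental repeat above detection thresholds, no
## single-base extension of the planted repeat across the junctions, and
## every cross-locus signature pair below 0.78 identity (well under the 0.90
## clustering threshold).
sample_flanks <- function(cfg, unit, prev_signatures) {
  k <- nchar(unit)
  u_first <- substr(unit, 1L, 1L)
  u_last <- substr(unit, k, k)
  repeat {
    left <- rand_dna(cfg$flank_len)
    right <- rand_dna(cfg$flank_len)
    if (substr(left, cfg$flank_len, cfg$flank_len) == u_last) next
    if (substr(right, 1L, 1L) == u_first) next
    left_part <- paste0(cfg$restriction_pattern, left)
    right_part <- paste0(right, cfg$restriction_pattern)
    if (nrow(find_perfect_ssrs(c(l = left_part, r = right_part))) > 0L) next
    sig <- paste0(left_part, right_part)
    clash <- FALSE
    for (s in prev_signatures) {
      if (cpp_identity(sig, s) >= 0.78) { clash <- TRUE; break }
    }
    if (clash) next
    return(list(left = left, right = right, signature = sig))
  }
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    pos <- which(stats::runif(n) < rate)
    if (length(pos)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  seqs
}

rand_quals <- function(lens) {
  vapply(lens, function(n) intToUtf8(sample(68:73, n, replace = TRUE)),
         character(1))
}

#' Simulate a pooled multi-individual SSR library
#'
#' For each planted locus, each individual draws `ploidy` alleles uniformly
#' from the locus's planted allele list; every allele copy yields `coverage`
#' read pairs from the fragment `pattern ++ left_flank ++ unit x repeats ++
#' right_flank ++ pattern` (adapter appended, so short fragments read into
#' it), with i.i.d. substitution errors and plausible qualities. The
#' ground-truth manifest is sufficient to recompute every expected pipeline
#' output without re-running the simulator.
#'
#' @param cfg a [sim_config()] list.
#' @param dir optional directory; when given, `r1.fastq`, `r2.fastq`,
#'   `truth_loci.tsv` and `truth_reads.tsv` are written there.
#' @return a list of class `ssr_sim`: read tibbles `r1` and `r2`, the
#'   per-locus manifest `loci` (motif, flanks, planted and realised repeat
#'   counts, realised allele lengths, expected observed and potential
#'   counts), the per-read manifest `reads` (source locus and allele) and
#'   the `config`.
#' @export
simulate_library <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "ssr_sim_config"))
  sim <- with_rng(cfg$seed, {
    loci <- vector("list", cfg$n_loci)
    sigs <- character(0)
    frag_of <- vector("list", cfg$n_loci)   # repeat count -> fragment
    for (l in seq_len(cfg$n_loci)) {
      unit <- sample(cfg$motif_units, 1L)
      k <- nchar(unit)
      rng <- if (k <= 2L) cfg$repeats_range_di else cfg$repeats_range_tetra
      n_all <- sample(cfg$alleles_range[1]:cfg$alleles_range[2], 1L)
      planted <- sort(sample(rng[1]:rng[2], min(n_all, diff(rng) + 1L)))
      fl <- sample_flanks(cfg, unit, sigs)
      sigs <- c(sigs, fl$signature)
      # index-based draw: sample(planted, ...) would misbehave when only one
      # allele is planted (scalar x samples from 1:x)
      geno <- matrix(planted[sample.int(length(planted),
                                        cfg$n_individuals * cfg$ploidy,
                                        replace = TRUE)],
                     nrow = cfg$n_individuals)
      realized <- sort(unique(as.vector(geno)))
      frags <- stats::setNames(
        paste0(cfg$restriction_pattern, fl$left, strrep(unit, realized),
               fl$right, cfg$restriction_pattern),
        realized)
      frag_of[[l]] <- frags
      lens <- nchar(frags)
      loci[[l]] <- list(
        locus = l, unit = unit, unit_len = k,
        flank_left = fl$left, flank_right = fl$right,
        planted_repeats = paste(planted, collapse = ","),
        realized_repeats = paste(realized, collapse = ","),
        realized_lengths = paste(lens, collapse = ","),
        observed = length(realized),
        potential = (max(lens) - min(lens)) %/% k + 1L,
        genotypes = geno
      )
    }
    # reads
    rows <- list(); ri <- 0L
    for (l in seq_len(cfg$n_loci)) {
      geno <- loci[[l]]$genotypes
      for (ind in seq_len(cfg$n_individuals)) {
        for (copy in seq_len(cfg$ploidy)) {
          reps <- geno[ind, copy]
          frag <- frag_of[[l]][[as.character(reps)]]
          for (cv in seq_len(cfg$coverage)) {
            ri <- ri + 1L
            rows[[ri]] <- list(
              id = sprintf("sim_L%03d_I%03d_c%d_v%d", l, ind, copy, cv),
              locus = l, repeats = reps, allele_length = nchar(frag),
              frag = frag)
          }
        }
      }
    }
    frag_seq <- vapply(rows, `[[`, character(1), "frag")
    ids <- vapply(rows, `[[`, character(1), "id")
    r1_seq <- substr(paste0(frag_seq, cfg$adapter), 1L, cfg$read_len)
    r2_seq <- substr(paste0(revcomp(frag_seq), cfg$adapter), 1L, cfg$read_len)
    r1_seq <- apply_errors(r1_seq, cfg$error_rate)
    r2_seq <- apply_errors(r2_seq, cfg$error_rate)
    r1 <- tibble(id = ids, seq = r1_seq, qual = rand_quals(nchar(r1_seq)))
    r2 <- tibble(id = ids, seq = r2_seq, qual = rand_quals(nchar(r2_seq)))
    truth_loci <- bind_rows(lapply(loci, function(x) {
      as_tibble(x[setdiff(names(x), "genotypes")])
    }))
    truth_reads <- tibble(
      id = ids,
      locus = vapply(rows, `[[`, integer(1), "locus"),
      repeats = vapply(rows, function(x) as.integer(x$repeats), integer(1)),
      allele_length = vapply(rows, function(x) as.integer(x$allele_length),
                             integer(1)))
    list(r1 = r1, r2 = r2, loci = truth_loci, reads = truth_reads)
  })
  sim$config <- cfg
  class(sim) <- "ssr_sim"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fastq(sim$r1, file.path(dir, "r1.fastq"))
    write_fastq(sim$r2, file.path(dir, "r2.fastq"))
    readr::write_tsv(sim$loci, file.path(dir, "truth_loci.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$reads, file.path(dir, "truth_reads.tsv"),
                     progress = FALSE)
    sim$dir <- dir
  }
  sim
}

#' @export
print.ssr_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated SSR library: %d loci x %d individuals (ploidy %d), %d read pairs\n",
    x$config$n_loci, x$config$n_individuals, x$config$ploidy, nrow(x$r1)))
  invisible(x)
}

#' Score pipeline output against a simulation manifest
#'
#' Matches each planted locus to the results table through probe windows
#' drawn from its two flanks (30-mers, unique per locus by construction; a
#' locus matches when any probe occurs in a record's representative, so a
#' stray sequencing error inside one window cannot hide a recovered locus)
#' and reports, per locus, whether it was recovered and whether the
#' observed and potential allele counts equal the manifest values. A planted locus whose allele
#' counts fall below the selection thresholds is reported as
#' `below_threshold`, not as missed; recall is computed over loci meeting
#' the thresholds.
#'
#' @param results records tibble (from [run_pipeline()] or
#'   [read_output_table()]).
#' @param truth the `loci` manifest of [simulate_library()].
#' @param min_allele_cnt,special_search,special_min_potential the selection
#'   rule the pipeline ran with.
#' @return a list of class `ssr_recovery`: per-locus tibble `loci` and a
#'   one-row `summary` (recall, precision, exactness fractions).
#' @export
score_recovery <- function(results, truth, min_allele_cnt = 5L,
                           special_search = FALSE,
                           special_min_potential = 8L) {
  meets <- if (isTRUE(special_search)) {
    truth$potential >= special_min_potential
  } else {
    truth$observed >= min_allele_cnt
  }
  n_rec <- nrow(results)
  per <- vector("list", nrow(truth))
  matched_ids <- character(0)
  for (i in seq_len(nrow(truth))) {
    fl <- truth$flank_left[i]
    fr <- truth$flank_right[i]
    probes <- unique(c(str_sub(fl, -30L),
                       substr(fl, 1L, 30L),
                       substr(fr, 1L, 30L),
                       str_sub(fr, -30L)))
    probes <- probes[nchar(probes) >= 15L]
    hit_rows <- integer(0)
    if (n_rec) {
      hit <- rep(FALSE, n_rec)
      for (p in probes) hit <- hit | str_detect(results$sequence, fixed(p))
      hit_rows <- which(hit)
    }
    found <- length(hit_rows) > 0L
    obs_ok <- pot_ok <- NA
    if (found) {
      rec <- results[hit_rows[1], ]
      obs_ok <- rec$alleles_observed == truth$observed[i]
      pot_ok <- rec$alleles_potential == truth$potential[i]
      matched_ids <- c(matched_ids,
                       unique(sub("-\\d+$", "", results$id[hit_rows])))
    }
    per[[i]] <- tibble(
      locus = truth$locus[i], meets_threshold = meets[i], found = found,
      status = if (found) "found" else if (meets[i]) "missed" else "below_threshold",
      observed_exact = obs_ok, potential_exact = pot_ok)
  }
  per <- bind_rows(per)
  found_meet <- per$found & per$meets_threshold
  all_locus_ids <- unique(sub("-\\d+$", "", results$id))
  summary <- tibble(
    n_planted = nrow(truth),
    n_meeting = sum(meets),
    n_found = sum(found_meet),
    recall = if (sum(meets)) sum(found_meet) / sum(meets) else NA_real_,
    precision = if (length(all_locus_ids))
      length(intersect(all_locus_ids, matched_ids)) / length(all_locus_ids)
      else NA_real_,
    observed_exact = if (any(per$found))
      mean(per$observed_exact[per$found]) else NA_real_,
    potential_exact = if (any(per$found))
      mean(per$potential_exact[per$found]) else NA_real_)
  structure(list(loci = per, summary = summary), class = "ssr_recovery")
}

#' @export
print.ssr_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("Recovery: %d/%d threshold-meeting loci found (recall %.3f)\n",
           "observed-allele exactness %.3f, potential-allele exactness %.3f\n"),
    s$n_found, s$n_meeting, s$recall, s$observed_exact, s$potential_exact))
  invisible(x)
}
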