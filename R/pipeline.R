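STAGE_LABELS <- c("Original FASTQ file", "Trimming", "Pair-end merge",
                  "Filter 1", "Filter 2", "Clusters", "Filter 3",
                  "Unique loci", "Primers selected")

#' Run the full SSR discovery and primer design pipeline
#'
#' Stages execute in order: adapter/quality trimming, pair merging,
#' restriction filter (Filter 1), repeat mining and candidate selection
#' (Filter 2), repeat excision and greedy flank clustering, cluster
#' selection (Filter 3), allele tabulation and locus selection,
#' representative choice and primer design. Per-stage sequence counts are
#' recorded throughout; with a fixed configuration (including `rng_seed`)
#' the output is deterministic.
#'
#' Supplying the same file (or tibble) as `r1` and `r2` runs the pipeline
#' in single-end mode: identical mates pass the merge stage unchanged.
#'
#' @param r1,r2 FASTQ paths or read tibbles for the two ends.
#' @param config an [pipeline_config()] list.
#' @return an object of class `ssr_run`: `results` (twelve-column records
#'   tibble), `counts` (stage-count tibble), `loci` (selected loci),
#'   `clusters` (clustered member table), `config`. Zero loci is a normal
#'   completion with an empty results table.
#' @export
#' @examples
#' sim <- simulate_library(sim_config(n_loci = 2, n_individuals = 6,
#'                                    coverage = 1, error_rate = 0, seed = 42))
#' run <- run_pipeline(sim$r1, sim$r2, pipeline_config(min_allele_cnt = 2))
#' stage_counts(run)
run_pipeline <- function(r1, r2, config = pipeline_config()) {
  stopifnot(inherits(config, "ssr_config"))
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  assert_reads(r1, need_qual = TRUE, arg = "r1")
  assert_reads(r2, need_qual = TRUE, arg = "r2")
  counts <- integer(length(STAGE_LABELS))
  names(counts) <- STAGE_LABELS
  counts["Original FASTQ file"] <- nrow(r1)

  t1 <- trim_reads(r1, config$adapters, config$trim_window, config$trim_min_q,
                   config$trim_min_len, config$adapter_max_error_rate,
                   config$adapter_min_overlap)
  t2 <- trim_reads(r2, config$adapters, config$trim_window, config$trim_min_q,
                   config$trim_min_len, config$adapter_max_error_rate,
                   config$adapter_min_overlap)
  keep_ids <- intersect(t1$id, t2$id)
  t1 <- t1[match(keep_ids, t1$id), , drop = FALSE]
  t2 <- t2[match(keep_ids, t2$id), , drop = FALSE]
  counts["Trimming"] <- length(keep_ids)

  merged <- merge_pairs(t1, t2, config$merge_min_overlap,
                        config$merge_max_mismatch_density)
  counts["Pair-end merge"] <- nrow(merged)

  kept <- filter_restriction(merged, config$restriction_pattern,
                             config$restriction_anchor)
  counts["Filter 1"] <- nrow(kept)

  hits <- find_perfect_ssrs(kept, config$min_repeats)
  hits <- join_compound(hits, config$compound_max_gap)
  candidates <- filter_candidates(kept, hits, config)
  counts["Filter 2"] <- nrow(candidates)

  signatures <- excise_ssr(candidates)
  signatures <- signatures[nzchar(signatures$signature), , drop = FALSE]
  clustered <- greedy_cluster(signatures, config$cluster_identity,
                              config$cluster_word_size)
  counts["Clusters"] <- length(unique(clustered$cluster_id))

  surviving <- filter_clusters(clustered, config$cluster_min_members,
                               config$cluster_motif_consistency)
  counts["Filter 3"] <- length(unique(surviving$cluster_id))

  loci <- tabulate_alleles(surviving)
  loci <- select_loci(loci, config$min_allele_cnt, config$special_search,
                      config$special_min_potential)
  counts["Unique loci"] <- nrow(loci)

  reps <- choose_representative(surviving, config$rng_seed)
  loci <- left_join(loci, reps[, c("cluster_id", "seq")], by = "cluster_id")
  names(loci)[names(loci) == "seq"] <- "representative"

  records <- design_primers(loci, config)
  counts["Primers selected"] <- stage_info(records)$kept

  structure(list(results = as_tibble(records), counts = tibble(
    stage = factor(STAGE_LABELS, levels = STAGE_LABELS),
    count = unname(counts)
  ), loci = loci, clusters = clustered, config = config), class = "ssr_run")
}

#' Stage counts of a pipeline run
#'
#' @param run an `ssr_run` object.
#' @return a tibble with columns `stage` and `count`, one row per stage in
#'   pipeline order.
#' @export
stage_counts <- function(run) {
  stopifnot(inherits(run, "ssr_run"))
  run$counts
}

#' @export
print.ssr_run <- function(x, ...) {
  cat("SSR marker discovery run\n")
  cnt <- x$counts
  for (i in seq_len(nrow(cnt))) {
    cat(sprintf("  %-20s %d\n", as.character(cnt$stage[i]), cnt$count[i]))
  }
  cat(sprintf("  primer pairs emitted  %d\n", nrow(x$results)))
  invisible(x)
}

#' Tidy the results of a pipeline run
#'
#' @param x an `ssr_run` object.
#' @param ... unused.
#' @return the twelve-column records tibble, one row per designed primer
#'   pair.
#' @export
tidy.ssr_run <- function(x, ...) x$results

#' One-row summary of a pipeline run
#'
#' @param x an `ssr_run` object.
#' @param ... unused.
#' @return a one-row tibble: the stage counts in wide form plus the number
#'   of emitted primer pairs.
#' @export
glance.ssr_run <- function(x, ...) {
  wide <- as.list(x$counts$count)
  names(wide) <- gsub("[ -]", "_", tolower(as.character(x$counts$stage)))
  as_tibble(c(wide, list(primer_pairs = nrow(x$results))))
}

#' Stage-count funnel plot of a pipeline run
#'
#' @param object an `ssr_run` object.
#' @param ... unused.
#' @return a ggplot: sequences (or clusters/loci) surviving each stage.
#' @export
autoplot.ssr_run <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.1))) +
    ggplot2::labs(x = NULL, y = "records surviving",
                  title = "Pipeline stage counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Allele-count overview of selected loci
#'
#' @param run an `ssr_run` object.
#' @return a ggplot comparing observed and potential allele counts per
#'   selected locus.
#' @export
plot_locus_alleles <- function(run) {
  stopifnot(inherits(run, "ssr_run"))
  loci <- run$loci
  long <- tidyr::pivot_longer(
    loci[, c("locus_number", "observed", "potential")],
    cols = c("observed", "potential"),
    names_to = "measure", values_to = "alleles")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$locus_number),
                                     y = .data$alleles,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "locus", y = "alleles", fill = NULL,
                  title = "Observed vs potential alleles per locus") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
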