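#' Tabulate alleles per cluster
#'
#' Within a cluster, an allele is a distinct full merged-sequence length:
#' flank-length variation inside a 90%-identity cluster is negligible, so
#' length differences reflect repeat-number differences. For each cluster
#' this computes the sorted distinct lengths, the observed allele count, the
#' length range, and the potential allele count
#' `floor((range_max - range_min) / unit_len) + 1` - the number of lattice
#' positions of step `unit_len` between the extreme alleles, i.e. the
#' alleles one could expect in the wider population given the extremes seen
#' in the pool.
#'
#' @param clustered tibble from [greedy_cluster()] / [filter_clusters()]
#'   (columns `cluster_id`, `full_length`, `unit`, `unit_len`, `is_seed`).
#' @return a loci tibble, one row per cluster: `cluster_id`, `motif_unit`
#'   (seed's unit), `unit_len`, `allele_lengths` (list column),
#'   `observed`, `range_min`, `range_max`, `potential`, `n_members`.
#' @export
tabulate_alleles <- function(clustered) {
  need <- c("cluster_id", "full_length", "unit", "unit_len", "is_seed")
  if (!all(need %in% names(clustered))) {
    abort("`clustered` must come from greedy_cluster() on excised candidates")
  }
  if (nrow(clustered) == 0L) {
    return(tibble(cluster_id = integer(), motif_unit = character(),
                  unit_len = integer(), allele_lengths = list(),
                  observed = integer(), range_min = integer(),
                  range_max = integer(), potential = integer(),
                  n_members = integer()))
  }
  clustered |>
    group_by(.data$cluster_id) |>
    summarise(
      motif_unit = .data$unit[.data$is_seed][1],
      unit_len = .data$unit_len[.data$is_seed][1],
      allele_lengths = list(sort(unique(.data$full_length))),
      observed = length(.data$allele_lengths[[1]]),
      range_min = min(.data$full_length),
      range_max = max(.data$full_length),
      potential = (max(.data$full_length) - min(.data$full_length)) %/%
        .data$unit_len[.data$is_seed][1] + 1L,
      n_members = dplyr::n(),
      .groups = "drop"
    )
}

#' Locus selection
#'
#' With Special Search off (default), a locus is kept when its observed
#' allele count reaches `min_allele_cnt`. Switching Special Search on
#' replaces that criterion: loci are instead kept when their potential
#' allele count reaches `special_min_potential`, admitting loci whose
#' sampled alleles are few but widely spread - candidates for unsampled
#' polymorphism in the wider population.
#'
#' Surviving loci are numbered 1..n in input order (`locus_number`).
#'
#' @param loci loci tibble from [tabulate_alleles()].
#' @param min_allele_cnt minimum observed alleles (Special Search off).
#' @param special_search replace the observed-count criterion with the
#'   potential-count criterion.
#' @param special_min_potential minimum potential alleles (Special Search on).
#' @return the selected loci with a `locus_number` column.
#' @export
select_loci <- function(loci, min_allele_cnt = 5L, special_search = FALSE,
                        special_min_potential = 8L) {
  keep <- if (isTRUE(special_search)) {
    loci$potential >= special_min_potential
  } else {
    loci$observed >= min_allele_cnt
  }
  out <- loci[keep, , drop = FALSE]
  out$locus_number <- seq_len(nrow(out))
  out
}

#' Choose a locus representative
#'
#' One sequence is drawn uniformly among the cluster's distinct sequence
#' variants (deduplicated, so abundant alleles carry no extra weight) with a
#' seeded generator: the same seed and input always give the same choice.
#' Clusters are processed in ascending `cluster_id` order.
#'
#' @param clustered member tibble (columns `cluster_id`, `source_id`, `seq`).
#' @param seed integer seed for the draw.
#' @return tibble with one row per cluster: `cluster_id`, `source_id` and
#'   `seq` of the chosen representative.
#' @export
choose_representative <- function(clustered, seed = 1L) {
  if (nrow(clustered) == 0L) {
    return(tibble(cluster_id = integer(), source_id = character(),
                  seq = character()))
  }
  ids <- sort(unique(clustered$cluster_id))
  with_rng(seed, {
    rows <- lapply(ids, function(cl) {
      m <- clustered[clustered$cluster_id == cl, , drop = FALSE]
      variants <- sort(unique(m$seq))
      pick <- variants[[sample.int(length(variants), 1L)]]
      first <- which(m$seq == pick)[1]
      tibble(cluster_id = cl, source_id = m$source_id[first], seq = pick)
    })
    bind_rows(rows)
  })
}

#' Maximum distinct alleles a pooled sample can show
#'
#' An untagged pool of `n_individuals` individuals of ploidy `ploidy`
#' contributes at most `ploidy * n_individuals` distinct alleles per locus
#' (e.g. 72 for 36 diploid individuals); observed counts above this cap in a
#' run indicate artefacts and are flagged in the log.
#'
#' @param n_individuals number of pooled individuals.
#' @param ploidy chromosome copies per individual.
#' @return integer allele cap.
#' @export
#' @examples
#' max_pool_alleles(36, 2)
max_pool_alleles <- function(n_individuals, ploidy = 2L) {
  stopifnot(n_individuals >= 1, ploidy >= 1)
  as.integer(ploidy) * as.integer(n_individuals)
}
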