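# Brute-force / first-principles oracles, kept deliberately independent of
# the package's implementation paths: position-by-position scans, exhaustive
# enumeration, and base R's utils::adist for alignment distance.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

oracle_primitive <- function(unit) {
  k <- nchar(unit)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 && strrep(substr(unit, 1, d), k / d) == unit) return(FALSE)
  }
  TRUE
}

# Scans every position and unit length against the definition predicate:
# a hit is the leftmost whole-unit run of a primitive, N-free unit inside a
# maximal periodic stretch (the base just before the run must break the
# period), reaching the per-unit-length repeat threshold; overlapping
# candidates are resolved left-to-right, shortest unit first.
oracle_find_ssrs <- function(seq, min_repeats = c(10, 6, 5, 5, 5, 5)) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (k in 1:6) {
    if (n < 2 * k) next
    for (i in 1:(n - 2 * k + 1)) {
      unit <- ch[i:(i + k - 1)]
      if (any(!unit %in% c("A", "C", "G", "T"))) next
      if (i > 1 && ch[i - 1] == ch[i - 1 + k]) next  # stretch extends left
      r <- 1
      while (i + (r + 1) * k - 1 <= n &&
             all(ch[(i + r * k):(i + (r + 1) * k - 1)] == unit)) {
        r <- r + 1
      }
      if (r < min_repeats[k]) next
      u <- paste(unit, collapse = "")
      if (!oracle_primitive(u)) next
      rows[[length(rows) + 1]] <-
        data.frame(unit = u, unit_len = k, repeats = r,
                   start = i - 1, end = i - 1 + r * k,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(unit = character(), unit_len = integer(),
                      repeats = integer(), start = integer(),
                      end = integer()))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$start, cand$unit_len), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- 0
  for (j in seq_len(nrow(cand))) {
    if (cand$start[j] >= last_end) {
      keep[j] <- TRUE
      last_end <- cand$end[j]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Definition-based compound scan on one sequence's sorted hits.
oracle_join_compound <- function(h, max_gap) {
  h <- h[order(h$start), , drop = FALSE]
  if (nrow(h) < 2) return(h[, c("unit", "start", "end", "type")])
  out <- list()
  i <- 1
  while (i <= nrow(h)) {
    j <- i
    gaps <- integer(0)
    while (j < nrow(h) && h$start[j + 1] - h$end[j] <= max_gap) {
      gaps <- c(gaps, h$start[j + 1] - h$end[j])
      j <- j + 1
    }
    if (j == i) {
      out[[length(out) + 1]] <- data.frame(
        unit = h$unit[i], start = h$start[i], end = h$end[i],
        type = h$type[i], stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1]] <- data.frame(
        unit = paste(h$unit[i:j], collapse = "-"),
        start = h$start[i], end = h$end[j],
        type = if (all(gaps == 0)) "c" else "c*", stringsAsFactors = FALSE)
    }
    i <- j + 1
  }
  do.call(rbind, out)
}

oracle_identity <- function(a, b) {
  d <- utils::adist(a, b)[1, 1]
  max(0, 1 - d / min(nchar(a), nchar(b)))
}

# The same greedy first-fit loop, run with the adist-based identity and no
# word prefilter; sigs must already be in processing order.
oracle_greedy <- function(sigs, threshold) {
  seeds <- character(0)
  cl <- integer(length(sigs))
  for (i in seq_along(sigs)) {
    assigned <- 0
    for (ci in seq_along(seeds)) {
      if (oracle_identity(sigs[i], seeds[ci]) >= threshold - 1e-12) {
        assigned <- ci
        break
      }
    }
    if (!assigned) {
      seeds <- c(seeds, sigs[i])
      assigned <- length(seeds)
    }
    cl[i] <- assigned
  }
  cl
}

same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, paste, collapse = ",") %in%
          tapply(seq_along(b), b, paste, collapse = ",")) &&
    length(unique(a)) == length(unique(b))
}

# Semi-global 3' adapter scan, substitution-only, leftmost acceptable start.
oracle_adapter_cut <- function(seq, adapter, max_err, min_olap) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (p in seq_len(n)) {
    mlen <- min(alen, n - p + 1)
    if (mlen < min_olap) break
    mism <- sum(s[p:(p + mlen - 1)] != a[1:mlen])
    if (mism <= max_err * mlen + 1e-12) return(p - 1)
  }
  n
}

# Exhaustive-offset overlap oracle: best (density, larger L on ties).
oracle_best_overlap <- function(s1, s2rc, min_overlap) {
  n1 <- nchar(s1); n2 <- nchar(s2rc)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2rc, "", fixed = TRUE)[[1]]
  best <- list(L = -1L, density = Inf)
  for (L in seq(min_overlap, min(n1, n2))) {
    m <- sum(c1[(n1 - L + 1):n1] != c2[1:L])
    d <- m / L
    if (d < best$density - 1e-12 ||
        (d < best$density + 1e-12 && L > best$L)) {
      best <- list(L = L, density = d)
    }
  }
  best
}

# Brute-force candidate enumeration applying each predicate literally.
oracle_enumerate <- function(template, region, orientation, params,
                             ssr_span = NULL, avoid_in_ssr = FALSE) {
  rows <- list()
  for (len in params$min_size:params$max_size) {
    if (region[2] - region[1] < len) next
    for (tstart in region[1]:(region[2] - len)) {
      tend <- tstart + len
      sub <- substr(template, tstart + 1, tend)
      primer <- if (orientation == "forward") sub else revcomp(sub)
      if (grepl("[^ACGT]", primer)) next
      gc <- sum(strsplit(primer, "", fixed = TRUE)[[1]] %in% c("G", "C")) /
        len * 100
      if (gc < params$min_gc || gc > params$max_gc) next
      runs <- rle(strsplit(primer, "", fixed = TRUE)[[1]])
      if (max(runs$lengths) > params$max_poly_x) next
      if (avoid_in_ssr && !is.null(ssr_span) &&
          !(tend <= ssr_span[1] || tstart >= ssr_span[2])) next
      k <- params$max_self_comp + 1
      if (nchar(primer) >= k) {
        kmers <- substring(primer, 1:(nchar(primer) - k + 1), k:nchar(primer))
        if (any(revcomp(kmers) %in% kmers)) next
      }
      tm <- melting_temperature(primer)
      if (tm < params$min_tm || tm > params$max_tm) next
      rows[[length(rows) + 1]] <- data.frame(
        seq = primer, tstart = tstart, tend = tend, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq = character(), tstart = integer(),
                      tend = integer()))
  }
  do.call(rbind, rows)
}

# Random flank with no detectable repeat and a junction base that cannot
# extend a run of `unit` (left flank: last base differs from the unit's
# last base; right flank: first base differs from the unit's first base).
rand_flank <- function(n, unit, left = TRUE) {
  if (n == 0) return("")
  k <- nchar(unit)
  repeat {
    s <- rand_seq(n)
    if (left && substr(s, n, n) == substr(unit, k, k)) next
    if (!left && substr(s, 1, 1) == substr(unit, 1, 1)) next
    if (nrow(find_perfect_ssrs(c(f = s))) > 0) next
    return(s)
  }
}

# Random 300-mer with 0-2 planted repeat runs at non-overlapping positions.
plant_repeats <- function(n = 300) {
  seq <- rand_seq(n)
  n_plants <- sample(0:2, 1)
  pos <- 1
  for (p in seq_len(n_plants)) {
    k <- sample(1:6, 1)
    reps <- sample(c(10, 6, 5, 5, 5, 5)[k] + (-2:4), 1)
    unit <- rand_seq(k)
    run <- strrep(unit, reps)
    start <- pos + sample(0:30, 1)
    if (start + nchar(run) > n) break
    substr(seq, start, start + nchar(run) - 1) <- run
    pos <- start + nchar(run) + sample(5:20, 1)
  }
  seq
}
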