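# Per-base boolean-array oracles for the interval algebra, deliberately
# written base-by-base so they share no code path with the implementation.

cover_vec <- function(x, chrom, glen) {
  v <- logical(glen)
  xi <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(xi))) {
    v[seq(xi$start[[i]] + 1L, xi$end[[i]])] <- TRUE
  }
  v
}

runs_to_intervals <- function(v, chrom) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = as.numeric(starts[keep]),
                 end = as.numeric(ends[keep]))
}

oracle_per_chrom <- function(fun, chroms, glen) {
  dplyr::arrange(dplyr::bind_rows(lapply(chroms, fun)), chrom, start)
}

oracle_merge_gap <- function(x, max_gap, glen) {
  oracle_per_chrom(function(cm) {
    v <- cover_vec(x, cm, glen)
    # close interior uncovered runs shorter than max_gap (book-ended
    # intervals are already contiguous in the coverage vector)
    r <- rle(v)
    n <- length(r$values)
    for (i in seq_len(n)) {
      if (!r$values[i] && i > 1L && i < n && r$lengths[i] < max_gap) {
        r$values[i] <- TRUE
      }
    }
    runs_to_intervals(inverse.rle(r), cm)
  }, unique(x$chrom), glen)
}

oracle_intersect <- function(a, b, glen) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  oracle_per_chrom(function(cm) {
    runs_to_intervals(cover_vec(a, cm, glen) & cover_vec(b, cm, glen), cm)
  }, chroms, glen)
}

oracle_exclusive <- function(a, b, glen) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    v <- cover_vec(b, a$chrom[[i]], glen)
    keep[i] <- !any(v[seq(a$start[[i]] + 1L, a$end[[i]])])
  }
  a[keep, , drop = FALSE]
}

oracle_reciprocal_pairs <- function(a, b, frac) {
  hits <- 0L
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[[i]] != b$chrom[[j]]) next
      ov <- min(a$end[[i]], b$end[[j]]) - max(a$start[[i]], b$start[[j]])
      if (ov >= frac * (a$end[[i]] - a$start[[i]]) &&
          ov >= frac * (b$end[[j]] - b$start[[j]])) {
        hits <- hits + 1L
        rows[[hits]] <- c(i, j, ov)
      }
    }
  }
  if (hits == 0L) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer(),
                          overlap_bp = numeric()))
  }
  m <- do.call(rbind, rows)
  tibble::tibble(a_idx = m[, 1], b_idx = m[, 2], overlap_bp = m[, 3])
}

random_interval_set <- function(n_max = 50, glen = 1e5,
                                chroms = c("chrA", "chrB")) {
  n <- sample.int(n_max, 1L)
  cm <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, glen - 2))
  width <- pmin(floor(rexp(n, 1 / 500)) + 1, glen - start)
  tibble::tibble(chrom = cm, start = start, end = start + width)
}
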