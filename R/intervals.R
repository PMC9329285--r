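#' Genomic interval tibbles
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval covers bases `start, start+1, ..., end-1` and has length
#' `end - start >= 1`. Interval sets are plain tibbles with at least the
#' columns `chrom`, `start`, `end`; extra columns (name, score, strand,
#' narrowPeak statistics, ...) are carried through untouched by the
#' record-level operations and dropped by the base-level ones
#' ([merge_with_gap()], [intersect_intervals()]), which construct new
#' intervals.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors of 0-based half-open coordinates.
#' @param ... Further columns, recycled as in [tibble::tibble()].
#' @return A tibble with columns `chrom`, `start`, `end` and any extras.
#' @examples
#' intervals("chr1", c(100, 900), c(200, 1000))
#' @export
intervals <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = as.character(chrom),
                 start = as.numeric(start),
                 end = as.numeric(end), ...)
}

#' Describe a genome as chromosome lengths
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Numeric vector of chromosome lengths in bp (positive).
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_info(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_info <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom) > 0L) {
    rlang::abort("duplicated chromosome names in genome definition",
                 class = "ceatlas_config_error")
  }
  if (any(!is.finite(length)) || any(length < 1)) {
    rlang::abort("chromosome lengths must be positive and finite",
                 class = "ceatlas_config_error")
  }
  tibble::tibble(chrom = chrom, length = length)
}

empty_intervals <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric())
}

#' Validate an interval tibble
#'
#' Checks the column contract (`chrom`, `start`, `end`), the half-open
#' invariants (`start >= 0`, `end > start`) and, when a genome is supplied,
#' that every interval lies on a known chromosome and within its bounds.
#' Out-of-bounds intervals are rejected, not clipped, so that annotation /
#' genome-build mismatches surface immediately.
#'
#' @param x Interval tibble.
#' @param genome Optional genome tibble from [genome_info()].
#' @return `x`, invisibly, normalised to character `chrom` and numeric
#'   coordinates.
#' @export
validate_intervals <- function(x, genome = NULL) {
  if (!is.data.frame(x)) {
    rlang::abort("interval set must be a data frame",
                 class = "ceatlas_schema_error")
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("interval set is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "ceatlas_schema_error")
  }
  x <- tibble::as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$end <= x$start)
  if (length(bad) > 0L) {
    i <- bad[[1L]]
    rlang::abort(sprintf(
      "invalid interval at row %d: %s:%s-%s (need 0 <= start < end)",
      i, x$chrom[[i]], format(x$start[[i]], scientific = FALSE),
      format(x$end[[i]], scientific = FALSE)),
      class = "ceatlas_coord_error")
  }
  if (!is.null(genome)) {
    len <- stats::setNames(genome$length, genome$chrom)
    unknown <- which(!(x$chrom %in% genome$chrom))
    if (length(unknown) > 0L) {
      i <- unknown[[1L]]
      rlang::abort(sprintf("chromosome '%s' (row %d) is not in the genome",
                           x$chrom[[i]], i),
                   class = "ceatlas_coord_error")
    }
    over <- which(x$end > len[x$chrom])
    if (length(over) > 0L) {
      i <- over[[1L]]
      rlang::abort(sprintf(
        "interval %s:%s-%s (row %d) extends beyond chromosome end (%s)",
        x$chrom[[i]], format(x$start[[i]], scientific = FALSE),
        format(x$end[[i]], scientific = FALSE), i,
        format(len[[x$chrom[[i]]]], scientific = FALSE)),
        class = "ceatlas_coord_error")
    }
  }
  invisible(x)
}

#' Merge intervals separated by less than a gap
#'
#' Sorts intervals within each chromosome and merges every run of intervals
#' in which consecutive members overlap, are book-ended, or are separated by
#' a gap strictly smaller than `max_gap` (the `< 1 kb` merge rule of peak
#' post-processing corresponds to `max_gap = 1000`). Book-ended intervals
#' (gap 0 under half-open coordinates) always merge, including at
#' `max_gap = 0`. The result is a normalized set: sorted, non-overlapping,
#' non-adjacent. Metadata columns are dropped. Idempotent.
#'
#' @param x Interval tibble.
#' @param max_gap Non-negative gap threshold in bp; gaps `< max_gap` close.
#' @param genome Optional genome tibble; enables bounds checking.
#' @return A normalized interval tibble (`chrom`, `start`, `end`).
#' @examples
#' merge_with_gap(intervals("chr1", c(100, 900), c(200, 1000)), 1000)
#' @export
merge_with_gap <- function(x, max_gap, genome = NULL) {
  if (!is.numeric(max_gap) || length(max_gap) != 1L || is.na(max_gap) ||
      max_gap < 0) {
    rlang::abort("max_gap must be a single non-negative number",
                 class = "ceatlas_param_error")
  }
  x <- validate_intervals(x, genome)
  if (nrow(x) == 0L) return(empty_intervals())
  # merge iff gap < max_gap OR gap <= 0; for integral gaps this is
  # gap < max(max_gap, 1)
  thr <- max(max_gap, 1)
  x |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .prev_end = dplyr::lag(cummax(.data$end), default = -Inf),
      .run = cumsum(.data$start - .data$.prev_end >= thr)
    ) |>
    dplyr::group_by(.data$chrom, .data$.run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Normalize an interval set
#'
#' Equivalent to [merge_with_gap()] with `max_gap = 0`: overlapping and
#' book-ended intervals are unioned, output is sorted and disjoint.
#'
#' @inheritParams merge_with_gap
#' @return A normalized interval tibble.
#' @export
normalize_intervals <- function(x, genome = NULL) {
  merge_with_gap(x, 0, genome = genome)
}

# For each interval of `q` (rows on one chromosome), the index range
# [lo, hi] of intervals in the normalized, sorted set (ns, ne) it overlaps
# by >= 1 bp. Relies on ns and ne both being sorted (true for normalized
# sets). Returns a list(lo = , hi = ) of integer vectors.
norm_overlap_range <- function(q_start, q_end, ns, ne) {
  hi <- findInterval(q_end - 0.5, ns)        # b.start < q.end
  lo <- findInterval(q_start + 0.5, ne) + 1L # b.end > q.start
  list(lo = lo, hi = hi)
}

#' Per-base intersection of two interval sets
#'
#' Returns the maximal sub-intervals covered by both `a` and `b`
#' (base-by-base AND). Both inputs are normalized internally first, so
#' metadata is not propagated.
#'
#' @param a,b Interval tibbles.
#' @param genome Optional genome tibble applied to both inputs.
#' @return A normalized interval tibble covering `coverage(a) AND
#'   coverage(b)`.
#' @examples
#' intersect_intervals(intervals("chr1", 0, 1000),
#'                     intervals("chr1", c(100, 800), c(200, 900)))
#' @export
intersect_intervals <- function(a, b, genome = NULL) {
  a <- normalize_intervals(a, genome)
  b <- normalize_intervals(b, genome)
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty_intervals())
  pieces <- lapply(intersect(unique(a$chrom), unique(b$chrom)), function(cm) {
    ac <- a[a$chrom == cm, ]
    bc <- b[b$chrom == cm, ]
    rng <- norm_overlap_range(ac$start, ac$end, bc$start, bc$end)
    n_hit <- pmax(rng$hi - rng$lo + 1L, 0L)
    if (sum(n_hit) == 0L) return(NULL)
    ai <- rep(seq_len(nrow(ac)), times = n_hit)
    bi <- sequence(n_hit, from = rng$lo)
    tibble::tibble(chrom = cm,
                   start = pmax(ac$start[ai], bc$start[bi]),
                   end = pmin(ac$end[ai], bc$end[bi]))
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) return(empty_intervals())
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Intervals of one set with zero overlap against another
#'
#' Keeps every `a` record (metadata included) that shares no base with any
#' `b` interval — the `bedtools intersect -v` semantics used for
#' tissue-exclusive enhancer calls. Book-ended intervals do not overlap
#' under half-open coordinates and are therefore kept.
#'
#' @param a Interval tibble whose records are filtered.
#' @param b Interval tibble acting as the exclusion set.
#' @param genome Optional genome tibble.
#' @return The subset of `a` rows with zero overlap with `b`.
#' @export
exclusive_intervals <- function(a, b, genome = NULL) {
  a <- validate_intervals(a, genome)
  bn <- normalize_intervals(b, genome)
  if (nrow(a) == 0L || nrow(bn) == 0L) return(a)
  keep <- rep(TRUE, nrow(a))
  for (cm in intersect(unique(a$chrom), unique(bn$chrom))) {
    ia <- which(a$chrom == cm)
    bc <- bn[bn$chrom == cm, ]
    rng <- norm_overlap_range(a$start[ia], a$end[ia], bc$start, bc$end)
    keep[ia] <- rng$hi < rng$lo
  }
  a[keep, , drop = FALSE]
}

# All (a-row, b-row) pairs overlapping by >= 1 bp, by global row index.
# Neither input needs to be normalized. Desk-scale: candidate filtering is
# vectorized per chromosome via sorted b-starts, then trimmed on b-ends.
overlap_join <- function(a, b) {
  out <- list()
  for (cm in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == cm)
    ib <- which(b$chrom == cm)
    ord <- order(b$start[ib], b$end[ib])
    ib <- ib[ord]
    bs <- b$start[ib]
    be <- b$end[ib]
    hi <- findInterval(a$end[ia] - 0.5, bs)  # b.start < a.end
    n_cand <- hi
    if (sum(n_cand) == 0L) next
    ai <- rep(ia, times = n_cand)
    bj <- sequence(n_cand, from = 1L)
    ok <- be[bj] > a$start[ai]               # b.end > a.start
    ai <- ai[ok]
    bj <- bj[ok]
    if (length(ai) == 0L) next
    out[[cm]] <- tibble::tibble(
      a_idx = ai, b_idx = ib[bj],
      overlap_bp = pmin(a$end[ai], b$end[ib[bj]]) -
        pmax(a$start[ai], b$start[ib[bj]]))
  }
  if (length(out) == 0L) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer(),
                          overlap_bp = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Pairs of intervals with reciprocal overlap above a fraction
#'
#' Reports every pair `(x in a, y in b)` whose overlap length is at least
#' `frac * length(x)` *and* `frac * length(y)` — the
#' `bedtools intersect -f frac -r` criterion used for cross-tissue
#' consensus enhancers.
#'
#' @param a,b Interval tibbles (need not be normalized).
#' @param frac Required reciprocal fraction, in `(0, 1]`.
#' @param genome Optional genome tibble.
#' @return A tibble with one row per qualifying pair: `chrom`, the `a` and
#'   `b` coordinates (`start_a`/`end_a`, `start_b`/`end_b`), `overlap_bp`,
#'   `frac_a`, `frac_b`, plus `name_a`/`name_b` when the inputs carry a
#'   `name` column, and the originating row indices `a_idx`/`b_idx`.
#' @examples
#' reciprocal_overlap_pairs(intervals("chr1", 0, 100),
#'                          intervals("chr1", 5, 100), frac = 0.9)
#' @export
reciprocal_overlap_pairs <- function(a, b, frac, genome = NULL) {
  if (!is.numeric(frac) || length(frac) != 1L || is.na(frac) ||
      frac <= 0 || frac > 1) {
    rlang::abort("frac must be a single number in (0, 1]",
                 class = "ceatlas_param_error")
  }
  a <- validate_intervals(a, genome)
  b <- validate_intervals(b, genome)
  hits <- overlap_join(a, b)
  len_a <- a$end[hits$a_idx] - a$start[hits$a_idx]
  len_b <- b$end[hits$b_idx] - b$start[hits$b_idx]
  keep <- hits$overlap_bp >= frac * len_a & hits$overlap_bp >= frac * len_b
  hits <- hits[keep, , drop = FALSE]
  out <- tibble::tibble(
    chrom = a$chrom[hits$a_idx],
    start_a = a$start[hits$a_idx], end_a = a$end[hits$a_idx],
    start_b = b$start[hits$b_idx], end_b = b$end[hits$b_idx],
    overlap_bp = hits$overlap_bp,
    frac_a = hits$overlap_bp / (a$end[hits$a_idx] - a$start[hits$a_idx]),
    frac_b = hits$overlap_bp / (b$end[hits$b_idx] - b$start[hits$b_idx]),
    a_idx = hits$a_idx, b_idx = hits$b_idx)
  if ("name" %in% names(a)) out$name_a <- a$name[hits$a_idx]
  if ("name" %in% names(b)) out$name_b <- b$name[hits$b_idx]
  dplyr::arrange(out, .data$chrom, .data$start_a, .data$start_b)
}

#' Distance from interval midpoints to the nearest TSS
#'
#' For each interval, computes `|midpoint - nearest TSS|` where the
#' midpoint is `floor((start + end) / 2)`, and labels it with a distance
#' bin. Ties between equidistant TSSs resolve to the smaller coordinate.
#' Intervals on chromosomes with no TSS get `NA` distance and the bin
#' `"unassigned"` rather than an error.
#'
#' @param x Interval tibble.
#' @param tss Tibble of TSS positions with columns `chrom` and `pos`
#'   (0-based base offsets), e.g. from [read_tss()].
#' @param edges Increasing bin edges in bp; the defaults give the bins
#'   0–5 kb, 5–50 kb, 50–500 kb and >500 kb (right-closed).
#' @return `x` with added columns `midpoint`, `tss_pos`, `distance` and
#'   `bin` (factor; the last level is `"unassigned"`).
#' @export
nearest_tss_distance <- function(x, tss, edges = c(5e3, 5e4, 5e5)) {
  x <- validate_intervals(x)
  if (!is.data.frame(tss) || !all(c("chrom", "pos") %in% names(tss))) {
    rlang::abort("tss must be a data frame with columns chrom, pos",
                 class = "ceatlas_schema_error")
  }
  edges <- sort(as.numeric(edges))
  labs <- c(paste0(format(c(0, edges[-length(edges)]) / 1e3, trim = TRUE,
                          scientific = FALSE), "-",
                   format(edges / 1e3, trim = TRUE, scientific = FALSE),
                   " kb"),
            paste0(">", format(edges[length(edges)] / 1e3, trim = TRUE,
                               scientific = FALSE), " kb"))
  mid <- floor((x$start + x$end) / 2)
  tss_pos <- rep(NA_real_, nrow(x))
  for (cm in intersect(unique(x$chrom), unique(tss$chrom))) {
    pos <- sort(unique(tss$pos[tss$chrom == cm]))
    ix <- which(x$chrom == cm)
    i <- findInterval(mid[ix], pos)
    left <- ifelse(i >= 1L, pos[pmax(i, 1L)], NA_real_)
    right <- ifelse(i < length(pos), pos[pmin(i + 1L, length(pos))], NA_real_)
    d_left <- abs(mid[ix] - left)
    d_right <- abs(mid[ix] - right)
    # ties -> smaller coordinate, i.e. the left neighbour
    use_left <- !is.na(d_left) & (is.na(d_right) | d_left <= d_right)
    tss_pos[ix] <- ifelse(use_left, left, right)
  }
  distance <- abs(mid - tss_pos)
  bin <- cut(distance, breaks = c(-1, edges, Inf), labels = labs)
  bin <- factor(ifelse(is.na(distance), "unassigned", as.character(bin)),
                levels = c(labs, "unassigned"))
  x$midpoint <- mid
  x$tss_pos <- tss_pos
  x$distance <- distance
  x$bin <- bin
  x
}

#' Harmonise chromosome-name style across inputs
#'
#' Chromosome names are otherwise matched as exact strings, and public
#' annotation sources mix `chr1` and `1` conventions; apply this to every
#' input (including the genome table) before combining them.
#'
#' @param x Interval tibble, TSS/SNP tibble (any data frame with a `chrom`
#'   column), or genome tibble.
#' @param style `"chr"` to ensure a `chr` prefix, `"plain"` to strip it.
#' @return `x` with rewritten `chrom`.
#' @export
normalize_chrom_names <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  if (!"chrom" %in% names(x)) {
    rlang::abort("no 'chrom' column to normalize",
                 class = "ceatlas_schema_error")
  }
  bare <- sub("^chr", "", x$chrom)
  x$chrom <- if (style == "chr") paste0("chr", bare) else bare
  x
}

#' Total number of bases covered by an interval set
#'
#' Overlapping intervals are counted once (the set is normalized first).
#'
#' @param x Interval tibble.
#' @return A single number of covered bases.
#' @export
covered_bp <- function(x) {
  n <- normalize_intervals(x)
  sum(n$end - n$start)
}
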