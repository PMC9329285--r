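#' Parameters of candidate-enhancer atlas construction
#'
#' The four constants of the CE-calling recipe: promoter exclusion windows
#' of `promoter_flank` bp on each side of a TSS, gap-merging of nearby
#' peaks/conserved fragments at `merge_gap` bp, the reciprocal-overlap
#' fraction used for cross-tissue consensus calls, and the fixed width of
#' regions prepared for motif scanning.
#'
#' @param promoter_flank Promoter half-width in bp (default 1000: 1 kb on
#'   each side of the TSS).
#' @param merge_gap Merge gap in bp; intervals separated by less than this
#'   are unioned (default 1000).
#' @param consensus_frac Reciprocal overlap fraction for consensus calls
#'   (default 0.9).
#' @param motif_width Width in bp of recentred motif-scanning regions
#'   (default 1000).
#' @return A list with class `ce_atlas_params`.
#' @export
atlas_params <- function(promoter_flank = 1000, merge_gap = 1000,
                         consensus_frac = 0.9, motif_width = 1000) {
  if (promoter_flank <= 0 || merge_gap < 0 || motif_width <= 0) {
    rlang::abort("promoter_flank and motif_width must be positive; merge_gap non-negative",
                 class = "ceatlas_param_error")
  }
  if (consensus_frac <= 0 || consensus_frac > 1) {
    rlang::abort("consensus_frac must be in (0, 1]",
                 class = "ceatlas_param_error")
  }
  structure(list(promoter_flank = promoter_flank, merge_gap = merge_gap,
                 consensus_frac = consensus_frac,
                 motif_width = motif_width),
            class = "ce_atlas_params")
}

#' Promoter exclusion mask around TSSs
#'
#' Builds `[tss - flank, tss + flank)` windows, clamps them to chromosome
#' bounds, and merges overlaps into a normalized mask.
#'
#' @param tss Tibble with columns `chrom`, `pos`.
#' @param flank Half-width in bp (positive).
#' @param genome Genome tibble from [genome_info()]; used for clamping and
#'   to reject TSSs beyond chromosome ends.
#' @return A normalized interval tibble.
#' @export
promoter_mask <- function(tss, flank, genome = NULL) {
  if (flank <= 0) {
    rlang::abort("flank must be positive", class = "ceatlas_param_error")
  }
  if (nrow(tss) == 0L) return(empty_intervals())
  win <- tibble::tibble(chrom = as.character(tss$chrom),
                        start = pmax(tss$pos - flank, 0),
                        end = tss$pos + flank)
  if (!is.null(genome)) {
    len <- stats::setNames(genome$length, genome$chrom)
    bad <- which(!(win$chrom %in% genome$chrom) | tss$pos >= len[win$chrom])
    if (length(bad) > 0L) {
      i <- bad[[1L]]
      rlang::abort(sprintf("TSS %s:%s (row %d) is beyond the chromosome bounds",
                           win$chrom[[i]],
                           format(tss$pos[[i]], scientific = FALSE), i),
                   class = "ceatlas_coord_error")
    }
    win$end <- pmin(win$end, len[win$chrom])
  }
  normalize_intervals(win)
}

#' Remove peaks overlapping a promoter mask
#'
#' Whole-record removal: a peak overlapping the mask by even 1 bp is
#' dropped entirely (not trimmed); all other peaks pass unchanged. Set
#' `trim = TRUE` to instead subtract the masked span and keep the
#' promoter-distal remainder of each peak.
#'
#' @param peaks Interval tibble of peaks.
#' @param mask Normalized mask from [promoter_mask()].
#' @param trim Subtract instead of drop (default `FALSE`).
#' @return Filtered peak tibble.
#' @export
filter_promoter_peaks <- function(peaks, mask, trim = FALSE) {
  if (!trim) return(exclusive_intervals(peaks, mask))
  peaks <- validate_intervals(peaks)
  maskn <- normalize_intervals(mask)
  if (nrow(maskn) == 0L || nrow(peaks) == 0L) return(peaks)
  # complement of the mask within each peak = peak AND NOT mask
  kept <- exclusive_intervals(peaks, maskn)
  cut <- intersect_intervals(peaks, maskn)
  residual <- subtract_cover(peaks[!rownames_in(peaks, kept), , drop = FALSE],
                             cut)
  dplyr::arrange(dplyr::bind_rows(kept[, c("chrom", "start", "end")],
                                  residual),
                 .data$chrom, .data$start)
}

rownames_in <- function(x, subset) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  key(x) %in% key(subset)
}

# base-level subtraction: pieces of x not covered by the normalized set y
subtract_cover <- function(x, y) {
  x <- normalize_intervals(x)
  y <- normalize_intervals(y)
  if (nrow(x) == 0L) return(empty_intervals())
  if (nrow(y) == 0L) return(x)
  out <- list()
  for (cm in unique(x$chrom)) {
    xc <- x[x$chrom == cm, ]
    yc <- y[y$chrom == cm, ]
    if (nrow(yc) == 0L) { out[[cm]] <- xc; next }
    pieces <- lapply(seq_len(nrow(xc)), function(i) {
      s <- xc$start[[i]]; e <- xc$end[[i]]
      hit <- yc[yc$start < e & yc$end > s, , drop = FALSE]
      if (nrow(hit) == 0L) return(tibble::tibble(chrom = cm, start = s, end = e))
      starts <- c(s, pmin(hit$end, e))
      ends <- c(pmax(hit$start, s), e)
      keep <- ends > starts
      tibble::tibble(chrom = cm, start = starts[keep], end = ends[keep])
    })
    out[[cm]] <- dplyr::bind_rows(pieces)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Conservation-filtered, gap-merged regions from a peak set
#'
#' Intersects peaks with conservation blocks (per-base AND) and merges the
#' resulting conserved fragments separated by less than `merge_gap`. A peak
#' without a single conserved base contributes nothing; conversely a peak
#' spanning several conserved blocks less than `merge_gap` apart yields one
#' region that may include non-conserved spacer sequence.
#'
#' @param peaks Interval tibble (promoter-filtered, replicate-merged peaks).
#' @param conservation Interval tibble of conservation blocks in the same
#'   coordinate system.
#' @param merge_gap Merge gap in bp.
#' @param genome Optional genome tibble.
#' @return Normalized interval tibble of conserved merged regions.
#' @export
conserved_merged_regions <- function(peaks, conservation, merge_gap,
                                     genome = NULL) {
  conservation <- validate_intervals(conservation, genome)
  if (nrow(conservation) == 0L) {
    rlang::warn("conservation set is empty: no conserved regions can be called")
    return(empty_intervals())
  }
  merge_with_gap(intersect_intervals(peaks, conservation, genome), merge_gap)
}

#' Classify enhancer states from the two conserved mark sets of one tissue
#'
#' Builds the >= 1 bp overlap graph between the H3K27ac and H3K4me1
#' conserved merged regions. Each connected component containing intervals
#' of both marks becomes one strongly-active enhancer spanning the
#' component's union; components made of a single H3K27ac interval become
#' active enhancers, and single H3K4me1 components poised enhancers. With
#' `geometry = "intersection"`, strongly-active regions take the
#' intersected span of the two marks within the component instead of the
#' union.
#'
#' @param k27 Normalized interval tibble of conserved merged H3K27ac
#'   regions.
#' @param k4 Likewise for H3K4me1.
#' @param tissue Tissue label recorded on every output row.
#' @param geometry `"union"` (default) or `"intersection"` span for
#'   strongly-active calls.
#' @return A tibble of candidate enhancers: `tissue`, `chrom`, `start`,
#'   `end`, `state`, `source_marks`, `id`.
#' @export
classify_states <- function(k27, k4, tissue,
                            geometry = c("union", "intersection")) {
  geometry <- match.arg(geometry)
  k27 <- normalize_intervals(k27)
  k4 <- normalize_intervals(k4)
  pool <- dplyr::bind_rows(
    dplyr::mutate(k27, mark = "H3K27ac"),
    dplyr::mutate(k4, mark = "H3K4me1"))
  if (nrow(pool) == 0L) {
    return(tibble::tibble(tissue = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          state = character(), source_marks = character(),
                          id = character()))
  }
  pool <- pool |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .prev_end = dplyr::lag(cummax(.data$end), default = -Inf),
      # strict >= 1 bp overlap chains a component; book-ended does not
      .comp = cumsum(.data$start >= .data$.prev_end)
    ) |>
    dplyr::ungroup()
  out <- pool |>
    dplyr::group_by(.data$chrom, .data$.comp) |>
    dplyr::group_map(function(g, key) {
      marks <- unique(g$mark)
      if (length(marks) == 2L) {
        span <- if (geometry == "union") {
          c(min(g$start), max(g$end))
        } else {
          ik <- intersect_intervals(g[g$mark == "H3K27ac", ],
                                    g[g$mark == "H3K4me1", ])
          c(min(ik$start), max(ik$end))
        }
        tibble::tibble(chrom = key$chrom, start = span[[1L]],
                       end = span[[2L]], state = "strongly_active",
                       source_marks = "H3K27ac,H3K4me1")
      } else {
        tibble::tibble(chrom = key$chrom, start = g$start, end = g$end,
                       state = ifelse(marks == "H3K27ac", "active",
                                      "poised"),
                       source_marks = marks)
      }
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  out$tissue <- tissue
  out$id <- sprintf("%s:%s:%s-%s", tissue, out$chrom,
                    format(out$start, scientific = FALSE, trim = TRUE),
                    format(out$end, scientific = FALSE, trim = TRUE))
  dplyr::select(out, "tissue", "chrom", "start", "end", "state",
                "source_marks", "id")
}

ce_states <- c("strongly_active", "active", "poised")

new_ce_atlas <- function(ces, params, genome, provenance) {
  structure(list(ces = ces, params = params, genome = genome,
                 provenance = provenance),
            class = "ce_atlas")
}

#' Build a two-tissue candidate-enhancer atlas
#'
#' Runs the full CE-calling recipe per tissue and mark: remove peaks
#' overlapping promoter windows, merge nearby peaks (`< merge_gap`),
#' intersect with conservation blocks and re-merge, then combine the two
#' marks' region sets into strongly-active / active / poised enhancer
#' calls.
#'
#' @param peaks A tibble of replicate-merged peak calls with columns
#'   `tissue`, `mark` (values `H3K27ac` / `H3K4me1`), `chrom`, `start`,
#'   `end`. Exactly two tissues and both marks per tissue are required.
#' @param tss Tibble of TSS positions (`chrom`, `pos`).
#' @param conservation Interval tibble of conservation blocks.
#' @param genome Genome tibble from [genome_info()].
#' @param params [atlas_params()] object.
#' @param geometry Strongly-active span geometry, see [classify_states()].
#' @return A `ce_atlas` object: `$ces` (tibble of CEs), `$params`,
#'   `$genome`, `$provenance` (per-stage record counts, parameters,
#'   timestamp). Use [tidy()][generics::tidy] for the CE tibble and
#'   [glance()][generics::glance] for per-(tissue, state) counts.
#' @export
build_atlas <- function(peaks, tss, conservation, genome,
                        params = atlas_params(),
                        geometry = c("union", "intersection")) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(params, "ce_atlas_params"))
  if (!all(c("tissue", "mark") %in% names(peaks))) {
    rlang::abort("peaks must carry 'tissue' and 'mark' columns",
                 class = "ceatlas_schema_error")
  }
  combos <- dplyr::distinct(peaks[, c("tissue", "mark")])
  tissues <- sort(unique(combos$tissue))
  marks <- c("H3K27ac", "H3K4me1")
  want <- tidyr::expand_grid(tissue = tissues, mark = marks)
  if (length(tissues) != 2L ||
      nrow(dplyr::anti_join(want, combos, by = c("tissue", "mark"))) > 0L) {
    rlang::abort(paste0(
      "need exactly two tissues with both H3K27ac and H3K4me1 peak sets; found: ",
      paste(sprintf("%s/%s", combos$tissue, combos$mark), collapse = ", ")),
      class = "ceatlas_config_error")
  }
  validate_intervals(peaks, genome)
  mask <- promoter_mask(tss, params$promoter_flank, genome)
  stage_counts <- list()
  ces <- list()
  for (ti in tissues) {
    per_mark <- list()
    for (mk in marks) {
      p <- peaks[peaks$tissue == ti & peaks$mark == mk,
                 c("chrom", "start", "end")]
      p_filt <- filter_promoter_peaks(p, mask)
      p_merged <- merge_with_gap(p_filt, params$merge_gap)
      p_cons <- conserved_merged_regions(p_merged, conservation,
                                         params$merge_gap, genome)
      per_mark[[mk]] <- p_cons
      stage_counts[[paste(ti, mk, sep = "/")]] <- list(
        peaks_in = nrow(p), post_promoter = nrow(p_filt),
        post_merge = nrow(p_merged), post_conservation = nrow(p_cons))
    }
    ces[[ti]] <- classify_states(per_mark[["H3K27ac"]],
                                 per_mark[["H3K4me1"]], ti,
                                 geometry = geometry)
  }
  ces <- dplyr::bind_rows(ces)
  if (nrow(ces) == 0L) {
    rlang::warn("atlas is empty: no peaks survived promoter and conservation filtering")
  }
  new_ce_atlas(
    ces = ces,
    params = params,
    genome = genome,
    provenance = list(stage_counts = stage_counts,
                      geometry = geometry,
                      n_tss = nrow(tss),
                      n_conservation_blocks = nrow(conservation),
                      timestamp = format(Sys.time(), tz = "UTC",
                                         usetz = TRUE)))
}

#' @export
print.ce_atlas <- function(x, ...) {
  cat("Candidate-enhancer atlas\n")
  cat("  tissues:", paste(unique(x$ces$tissue), collapse = ", "), "\n")
  cat("  enhancers:", nrow(x$ces), "\n")
  print(glance_counts(x$ces))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CE atlas into its enhancer tibble
#'
#' @param x A `ce_atlas`.
#' @param tissue,state Optional filters.
#' @param ... Unused.
#' @return The CE tibble (`tissue`, `chrom`, `start`, `end`, `state`,
#'   `source_marks`, `id`).
#' @method tidy ce_atlas
#' @export
tidy.ce_atlas <- function(x, tissue = NULL, state = NULL, ...) {
  ces <- x$ces
  if (!is.null(tissue)) ces <- ces[ces$tissue %in% tissue, , drop = FALSE]
  if (!is.null(state)) {
    if (!all(state %in% ce_states)) {
      rlang::abort(paste0("unknown state label: ",
                          paste(setdiff(state, ce_states), collapse = ", ")),
                   class = "ceatlas_param_error")
    }
    ces <- ces[ces$state %in% state, , drop = FALSE]
  }
  ces
}

#' One-row-per-(tissue, state) summary of a CE atlas
#'
#' @param x A `ce_atlas`.
#' @param ... Unused.
#' @return Tibble with `tissue`, `state`, `count`, `total_bp`.
#' @method glance ce_atlas
#' @export
glance.ce_atlas <- function(x, ...) {
  glance_counts(x$ces)
}

#' Fixed-width regions centred on candidate enhancers for motif scanning
#'
#' Replaces each CE by a `width`-bp window centred on its midpoint
#' (`floor((start + end) / 2)`), clamped to chromosome bounds (clamping
#' shortens the window rather than shifting it).
#'
#' @param ces CE tibble (e.g. from [tidy.ce_atlas()]) or any interval
#'   tibble.
#' @param width Window width in bp (positive).
#' @param genome Optional genome tibble for end clamping.
#' @return Interval tibble of recentred windows, with `id` carried through
#'   when present.
#' @export
prepare_motif_regions <- function(ces, width, genome = NULL) {
  if (width <= 0) {
    rlang::abort("width must be positive", class = "ceatlas_param_error")
  }
  ces <- validate_intervals(ces)
  if (nrow(ces) == 0L) return(empty_intervals())
  mid <- floor((ces$start + ces$end) / 2)
  start <- mid - width %/% 2
  end <- start + width
  start <- pmax(start, 0)
  if (!is.null(genome)) {
    len <- stats::setNames(genome$length, genome$chrom)
    end <- pmin(end, len[ces$chrom])
  }
  out <- tibble::tibble(chrom = ces$chrom, start = start, end = end)
  if ("id" %in% names(ces)) out$id <- ces$id
  out
}

#' Sample random fixed-width background regions from a genome
#'
#' Draws `n` `width`-bp regions uniformly over all valid start positions
#' (chromosomes weighted by their number of valid starts), optionally
#' rejecting regions that overlap an exclusion set. Used to build the
#' random background for motif enrichment.
#'
#' @param genome Genome tibble.
#' @param n Number of regions.
#' @param width Region width in bp.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   regions.
#' @param exclude Optional interval tibble; sampled regions overlapping it
#'   are rejected and redrawn.
#' @param max_tries Total draw budget (default `50 * n`); exceeding it
#'   raises an error stating how many regions were placed.
#' @return Interval tibble of `n` sampled regions.
#' @export
sample_background_regions <- function(genome, n, width, seed = NULL,
                                      exclude = NULL, max_tries = NULL) {
  stopifnot(n >= 0, width >= 1)
  valid <- genome$length - width + 1
  usable <- valid >= 1
  if (n > 0 && !any(usable)) {
    rlang::abort("no chromosome can hold a region of the requested width",
                 class = "ceatlas_param_error")
  }
  if (n == 0L) return(empty_intervals())
  if (is.null(max_tries)) max_tries <- 50L * n
  excl <- if (is.null(exclude)) NULL else normalize_intervals(exclude)
  draw <- function() {
    placed <- empty_intervals()
    tries <- 0L
    batch <- n
    while (nrow(placed) < n && tries < max_tries) {
      m <- min(batch, max_tries - tries)
      tries <- tries + m
      cm <- sample(genome$chrom[usable], m, replace = TRUE,
                   prob = valid[usable])
      st <- floor(stats::runif(m, 0, valid[match(cm, genome$chrom)]))
      cand <- tibble::tibble(chrom = cm, start = st, end = st + width)
      if (!is.null(excl) && nrow(excl) > 0L) {
        cand <- exclusive_intervals(cand, excl)
      }
      placed <- utils::head(dplyr::bind_rows(placed, cand), n)
    }
    if (nrow(placed) < n) {
      rlang::abort(sprintf(
        "placed only %d of %d background regions within the retry budget",
        nrow(placed), n), class = "ceatlas_runtime_error")
    }
    placed
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Bar chart of enhancer-state counts per tissue
#'
#' @param object A `ce_atlas`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ce_atlas
#' @export
autoplot.ce_atlas <- function(object, ...) {
  counts <- glance_counts(object$ces)
  counts$state <- factor(counts$state, levels = ce_states)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$state, y = .data$count,
                               fill = .data$tissue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "enhancer state", y = "candidate enhancers",
                  fill = "tissue") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
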