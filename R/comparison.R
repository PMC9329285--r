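atlas_two_tissues <- function(atlas) {
  stopifnot(inherits(atlas, "ce_atlas"))
  tissues <- sort(unique(atlas$ces$tissue))
  if (length(tissues) != 2L) {
    rlang::abort(paste0("comparison needs an atlas with exactly two tissues; found: ",
                        paste(tissues, collapse = ", ")),
                 class = "ceatlas_config_error")
  }
  tissues
}

check_state <- function(state) {
  if (!is.character(state) || length(state) != 1L || !(state %in% ce_states)) {
    rlang::abort(paste0("unknown state label: ", paste(state, collapse = ", "),
                        " (expected one of ", paste(ce_states, collapse = ", "),
                        ")"),
                 class = "ceatlas_param_error")
  }
  state
}

#' Cross-tissue consensus enhancers at a reciprocal overlap fraction
#'
#' Pairs same-state candidate enhancers of the two tissues whose overlap
#' covers at least `frac` of both members (`bedtools intersect -f frac -r`
#' semantics).
#'
#' @param atlas A two-tissue `ce_atlas`.
#' @param state One of `"strongly_active"`, `"active"`, `"poised"`.
#' @param frac Reciprocal fraction in `(0, 1]`; defaults to the atlas
#'   `consensus_frac` parameter (0.9).
#' @return Tibble with one row per consensus pair: `id_a`, `id_b`,
#'   `chrom`, coordinates of both members, `overlap_bp`, `frac_a`,
#'   `frac_b`. Tissue "a" is the alphabetically first tissue.
#' @export
consensus_ces <- function(atlas, state = "strongly_active",
                          frac = atlas$params$consensus_frac) {
  tissues <- atlas_two_tissues(atlas)
  check_state(state)
  a <- tidy(atlas, tissue = tissues[[1L]], state = state)
  b <- tidy(atlas, tissue = tissues[[2L]], state = state)
  pairs <- reciprocal_overlap_pairs(dplyr::rename(a, name = "id"),
                                    dplyr::rename(b, name = "id"),
                                    frac = frac)
  tibble::tibble(
    tissue_a = tissues[[1L]], tissue_b = tissues[[2L]],
    id_a = pairs$name_a, id_b = pairs$name_b,
    chrom = pairs$chrom,
    start_a = pairs$start_a, end_a = pairs$end_a,
    start_b = pairs$start_b, end_b = pairs$end_b,
    overlap_bp = pairs$overlap_bp,
    frac_a = pairs$frac_a, frac_b = pairs$frac_b)
}

#' Tissue-exclusive candidate enhancers
#'
#' Returns the CEs of `tissue` in `state` that share no base with any
#' same-state CE of the other tissue (zero-overlap criterion). With
#' `any_state = TRUE` the exclusion set is the other tissue's entire CE
#' set regardless of state (a stricter definition of "unique").
#'
#' @param atlas A two-tissue `ce_atlas`.
#' @param tissue Tissue whose CEs are tested.
#' @param state State class (default strongly-active, the class used for
#'   tissue-specific enhancer analysis).
#' @param any_state Exclude against all states of the other tissue.
#' @return CE tibble (subset of the tissue's state set).
#' @export
exclusive_ces <- function(atlas, tissue, state = "strongly_active",
                          any_state = FALSE) {
  tissues <- atlas_two_tissues(atlas)
  if (!(tissue %in% tissues)) {
    rlang::abort(paste0("tissue '", tissue, "' is not in the atlas"),
                 class = "ceatlas_param_error")
  }
  check_state(state)
  other <- setdiff(tissues, tissue)
  mine <- tidy(atlas, tissue = tissue, state = state)
  theirs <- if (any_state) tidy(atlas, tissue = other)
            else tidy(atlas, tissue = other, state = state)
  exclusive_intervals(mine, theirs)
}

#' Enhancers switching from strongly-active to poised between tissues
#'
#' Reports the strongly-active CEs of `from_tissue` that overlap (by at
#' least 1 bp, or reciprocally at `frac` when given) at least one poised
#' CE of `to_tissue`. Each row carries the ids of its poised partners.
#'
#' @param atlas A two-tissue `ce_atlas`.
#' @param from_tissue Tissue providing the strongly-active set.
#' @param to_tissue Tissue providing the poised set.
#' @param frac Optional reciprocal fraction; `NULL` (default) means any
#'   >= 1 bp overlap.
#' @return Tibble of switching CEs with columns of the CE record plus
#'   `partners` (comma-joined poised CE ids) and `n_partners`.
#' @export
state_switch_ces <- function(atlas, from_tissue, to_tissue, frac = NULL) {
  tissues <- atlas_two_tissues(atlas)
  if (!all(c(from_tissue, to_tissue) %in% tissues) ||
      from_tissue == to_tissue) {
    rlang::abort("from_tissue and to_tissue must be the two distinct atlas tissues",
                 class = "ceatlas_param_error")
  }
  strong <- tidy(atlas, tissue = from_tissue, state = "strongly_active")
  poised <- tidy(atlas, tissue = to_tissue, state = "poised")
  if (nrow(strong) == 0L || nrow(poised) == 0L) {
    return(dplyr::mutate(strong[0, ], partners = character(),
                         n_partners = integer()))
  }
  hits <- if (is.null(frac)) {
    overlap_join(strong, poised)
  } else {
    p <- reciprocal_overlap_pairs(strong, poised, frac = frac)
    tibble::tibble(a_idx = p$a_idx, b_idx = p$b_idx)
  }
  if (nrow(hits) == 0L) {
    return(dplyr::mutate(strong[0, ], partners = character(),
                         n_partners = integer()))
  }
  ann <- hits |>
    dplyr::group_by(.data$a_idx) |>
    dplyr::summarise(
      partners = paste(poised$id[sort(.data$b_idx)], collapse = ","),
      n_partners = dplyr::n(), .groups = "drop")
  out <- strong[ann$a_idx, , drop = FALSE]
  out$partners <- ann$partners
  out$n_partners <- ann$n_partners
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' TSS-distance profile of a CE atlas
#'
#' Computes the distance of every CE midpoint to its nearest TSS and
#' tabulates the counts per (tissue, state) over the distance bins
#' (default 0–5, 5–50, 50–500, >500 kb), with CEs on chromosomes lacking a
#' TSS counted as `"unassigned"`.
#'
#' @param atlas A `ce_atlas`.
#' @param tss Tibble of TSS positions (`chrom`, `pos`).
#' @param edges Bin edges in bp, see [nearest_tss_distance()].
#' @return Tibble with `tissue`, `state`, `bin`, `n` (all bins present,
#'   zero-filled).
#' @export
tss_distance_profile <- function(atlas, tss, edges = c(5e3, 5e4, 5e5)) {
  stopifnot(inherits(atlas, "ce_atlas"))
  if (nrow(tss) == 0L) {
    rlang::abort("TSS list is empty", class = "ceatlas_param_error")
  }
  d <- nearest_tss_distance(atlas$ces, tss, edges = edges)
  d$tissue <- factor(d$tissue)
  d$state <- factor(d$state,
                    levels = intersect(ce_states, unique(d$state)))
  out <- dplyr::count(d, .data$tissue, .data$state, .data$bin,
                      .drop = FALSE, name = "n")
  out$tissue <- as.character(out$tissue)
  out$state <- as.character(out$state)
  dplyr::arrange(out, .data$tissue, .data$state, .data$bin)
}

#' Full cross-tissue comparison report
#'
#' Convenience wrapper running [consensus_ces()], [exclusive_ces()] (both
#' tissues), [state_switch_ces()] (both directions, any-overlap and, for
#' transparency, reciprocal at the consensus fraction) and
#' [tss_distance_profile()].
#'
#' @param atlas A two-tissue `ce_atlas`.
#' @param tss Tibble of TSS positions.
#' @param state State class for the consensus/exclusive analysis.
#' @param frac Reciprocal fraction for consensus calls.
#' @return A list of class `ce_comparison` with elements `consensus`,
#'   `exclusive` (named by tissue), `switches` (named `A_to_B`), and
#'   `tss_profile`, plus a `summary` tibble of headline counts.
#' @export
compare_tissues <- function(atlas, tss, state = "strongly_active",
                            frac = atlas$params$consensus_frac) {
  tissues <- atlas_two_tissues(atlas)
  a <- tissues[[1L]]; b <- tissues[[2L]]
  consensus <- consensus_ces(atlas, state = state, frac = frac)
  excl <- stats::setNames(
    lapply(tissues, function(ti) exclusive_ces(atlas, ti, state = state)),
    tissues)
  sw <- list(state_switch_ces(atlas, a, b), state_switch_ces(atlas, b, a))
  names(sw) <- c(paste0(a, "_to_", b), paste0(b, "_to_", a))
  sw_recip <- list(
    state_switch_ces(atlas, a, b, frac = frac),
    state_switch_ces(atlas, b, a, frac = frac))
  summary <- tibble::tibble(
    quantity = c("consensus_pairs",
                 paste0("exclusive_", tissues),
                 paste0("switch_", names(sw)),
                 paste0("switch_reciprocal_", names(sw))),
    state = state,
    n = c(nrow(consensus), vapply(excl, nrow, integer(1)),
          vapply(sw, nrow, integer(1)),
          vapply(sw_recip, nrow, integer(1))))
  structure(list(consensus = consensus, exclusive = excl, switches = sw,
                 tss_profile = tss_distance_profile(atlas, tss),
                 summary = summary, tissues = tissues, state = state,
                 frac = frac),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat("Cross-tissue CE comparison (", paste(x$tissues, collapse = " vs "),
      "; state ", x$state, ", reciprocal frac ", x$frac, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname compare_tissues
#' @param x A `ce_comparison`.
#' @param ... Unused.
#' @method tidy ce_comparison
#' @export
tidy.ce_comparison <- function(x, ...) {
  x$summary
}

#' Bar chart of the TSS-distance profile
#'
#' @param profile Tibble from [tss_distance_profile()].
#' @return A ggplot object, faceted by tissue.
#' @export
plot_tss_distance_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data$n,
                               fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "distance to nearest TSS", y = "candidate enhancers",
                  fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
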