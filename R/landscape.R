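#' Select differentially expressed genes at strict thresholds
#'
#' Adds a `direction` column to a differential-expression table:
#' `up_a` for rows with `log2fc > lfc_min` and `padj < padj_max`, `up_b`
#' for `log2fc < -lfc_min` and `padj < padj_max`, and `ns` otherwise. Both
#' inequalities are strict, so a gene at exactly `log2fc = lfc_min` or
#' `padj = padj_max` is not selected. `log2fc` is oriented as tissue A
#' over tissue B.
#'
#' @param de Tibble with at least `gene_id`, `log2fc`, `padj` columns.
#' @param lfc_min Minimum absolute log2 fold-change (default 0.5).
#' @param padj_max Maximum adjusted p (default 0.05).
#' @return `de` with the added `direction` column.
#' @export
select_degs <- function(de, lfc_min = 0.5, padj_max = 0.05) {
  if (lfc_min <= 0 || padj_max <= 0) {
    rlang::abort("lfc_min and padj_max must be positive",
                 class = "ceatlas_param_error")
  }
  missing_cols <- setdiff(c("gene_id", "log2fc", "padj"), names(de))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("DE table is missing column(s): ",
                        paste(missing_cols, collapse = ", "),
                        " (expected gene_id, log2fc, padj)"),
                 class = "ceatlas_schema_error")
  }
  dplyr::mutate(
    tibble::as_tibble(de),
    direction = dplyr::case_when(
      .data$log2fc > lfc_min & .data$padj < padj_max ~ "up_a",
      .data$log2fc < -lfc_min & .data$padj < padj_max ~ "up_b",
      TRUE ~ "ns"))
}

#' Assign candidate enhancers to differentially expressed genes
#'
#' Implements the regulatory-landscape pairing: a DEG whose TSS lies in
#' one or more TADs is paired with every CE overlapping (>= 1 bp, or fully
#' contained with `containment = TRUE`) any of those TADs (nested and
#' overlapping TADs contribute the union of their CEs); a DEG whose TSS
#' lies in no TAD is instead paired with every CE overlapping the window
#' `[tss - window, tss + window)`. A CE may be paired with several genes
#' and vice versa.
#'
#' @param ces CE tibble (typically a tissue-exclusive strongly-active set
#'   from [exclusive_ces()]) with an `id` column.
#' @param degs DEG tibble with `gene_id`, `chrom`, `tss` (0-based TSS
#'   position) columns, already restricted to the direction matching the
#'   CE tissue; rows with a missing TSS are skipped with a warning.
#' @param tads Interval tibble of TADs; a `tad_id` (or `name`) column is
#'   used when present, else ids are generated.
#' @param window Fallback half-window in bp around TSSs outside all TADs
#'   (default 1 Mb).
#' @param containment Require CEs to be fully contained in a TAD rather
#'   than merely overlapping it (default `FALSE`).
#' @return Tibble of assignments: `ce_id`, `gene_id`, `mechanism`
#'   (`"tad"` or `"window"`), `tad_id` (`NA` for window pairs),
#'   `distance_bp` (CE midpoint to TSS). Sorted by (gene_id, ce_id);
#'   independent of input row order.
#' @export
assign_ces_to_degs <- function(ces, degs, tads, window = 1e6,
                               containment = FALSE) {
  ces <- validate_intervals(ces)
  if (!"id" %in% names(ces)) {
    ces$id <- sprintf("%s:%s-%s", ces$chrom,
                      format(ces$start, scientific = FALSE, trim = TRUE),
                      format(ces$end, scientific = FALSE, trim = TRUE))
  }
  needed <- c("gene_id", "chrom", "tss")
  missing_cols <- setdiff(needed, names(degs))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("DEG table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "ceatlas_schema_error")
  }
  no_tss <- is.na(degs$tss) | is.na(degs$chrom)
  if (any(no_tss)) {
    rlang::warn(sprintf("skipping %d DEG(s) without TSS coordinates (%s)",
                        sum(no_tss),
                        paste(utils::head(degs$gene_id[no_tss], 5L),
                              collapse = ", ")))
    degs <- degs[!no_tss, , drop = FALSE]
  }
  tads <- validate_intervals(tads)
  if (!"tad_id" %in% names(tads)) {
    tads$tad_id <- if ("name" %in% names(tads)) tads$name else
      sprintf("tad_%s:%s-%s", tads$chrom,
              format(tads$start, scientific = FALSE, trim = TRUE),
              format(tads$end, scientific = FALSE, trim = TRUE))
  }
  if (nrow(degs) == 0L || nrow(ces) == 0L) {
    return(tibble::tibble(ce_id = character(), gene_id = character(),
                          mechanism = character(), tad_id = character(),
                          distance_bp = numeric()))
  }
  tss_iv <- tibble::tibble(chrom = degs$chrom, start = degs$tss,
                           end = degs$tss + 1)
  in_tad <- overlap_join(tss_iv, tads)  # gene rows containing TSS-in-TAD
  ce_mid <- floor((ces$start + ces$end) / 2)
  rows <- list()
  tad_genes <- unique(in_tad$a_idx)
  if (length(tad_genes) > 0L) {
    ce_tad <- overlap_join(ces, tads)
    if (containment && nrow(ce_tad) > 0L) {
      ok <- ces$start[ce_tad$a_idx] >= tads$start[ce_tad$b_idx] &
        ces$end[ce_tad$a_idx] <= tads$end[ce_tad$b_idx]
      ce_tad <- ce_tad[ok, , drop = FALSE]
    }
    pairs <- dplyr::inner_join(
      tibble::tibble(gene_row = in_tad$a_idx, tad_row = in_tad$b_idx),
      tibble::tibble(ce_row = ce_tad$a_idx, tad_row = ce_tad$b_idx),
      by = "tad_row", relationship = "many-to-many")
    if (nrow(pairs) > 0L) {
      rows$tad <- tibble::tibble(
        ce_id = ces$id[pairs$ce_row],
        gene_id = degs$gene_id[pairs$gene_row],
        mechanism = "tad",
        tad_id = tads$tad_id[pairs$tad_row],
        distance_bp = abs(ce_mid[pairs$ce_row] - degs$tss[pairs$gene_row]))
    }
  }
  win_genes <- setdiff(seq_len(nrow(degs)), tad_genes)
  if (length(win_genes) > 0L) {
    win <- tibble::tibble(chrom = degs$chrom[win_genes],
                          start = pmax(degs$tss[win_genes] - window, 0),
                          end = degs$tss[win_genes] + window)
    hits <- overlap_join(win, ces)
    if (nrow(hits) > 0L) {
      g <- win_genes[hits$a_idx]
      rows$window <- tibble::tibble(
        ce_id = ces$id[hits$b_idx],
        gene_id = degs$gene_id[g],
        mechanism = "window",
        tad_id = NA_character_,
        distance_bp = abs(ce_mid[hits$b_idx] - degs$tss[g]))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(ce_id = character(), gene_id = character(),
                          mechanism = character(), tad_id = character(),
                          distance_bp = numeric()))
  }
  out |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_id, .data$ce_id, .data$tad_id)
}

#' SNPs located inside candidate enhancers
#'
#' Reports every (SNP, CE) pair with `start <= pos < end` (half-open
#' membership: a SNP at exactly `end` is outside). Annotation columns of
#' the SNP table pass through.
#'
#' @param snps Tibble with `rsid`, `chrom`, `pos` (0-based) plus free-form
#'   annotation columns (trait, p-value text, ...).
#' @param ces CE tibble; `id`, `state`, `tissue` columns are carried into
#'   the output when present.
#' @return Tibble with one row per overlap: `rsid`, `chrom`, `pos`,
#'   `ce_id`, CE coordinates, `state`/`tissue` when available, and the
#'   SNP annotations.
#' @export
snps_in_ces <- function(snps, ces) {
  missing_cols <- setdiff(c("rsid", "chrom", "pos"), names(snps))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("SNP table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "ceatlas_schema_error")
  }
  ces <- validate_intervals(ces)
  if (!"id" %in% names(ces)) {
    ces$id <- sprintf("%s:%s-%s", ces$chrom,
                      format(ces$start, scientific = FALSE, trim = TRUE),
                      format(ces$end, scientific = FALSE, trim = TRUE))
  }
  snp_iv <- tibble::tibble(chrom = as.character(snps$chrom),
                           start = snps$pos, end = snps$pos + 1)
  hits <- overlap_join(snp_iv, ces)
  out <- tibble::tibble(
    rsid = snps$rsid[hits$a_idx],
    chrom = snps$chrom[hits$a_idx],
    pos = snps$pos[hits$a_idx],
    ce_id = ces$id[hits$b_idx],
    ce_start = ces$start[hits$b_idx],
    ce_end = ces$end[hits$b_idx])
  if ("state" %in% names(ces)) out$state <- ces$state[hits$b_idx]
  if ("tissue" %in% names(ces)) out$tissue <- ces$tissue[hits$b_idx]
  extra <- setdiff(names(snps), c("rsid", "chrom", "pos"))
  for (col in extra) out[[col]] <- snps[[col]][hits$a_idx]
  dplyr::arrange(out, .data$chrom, .data$pos, .data$ce_id)
}
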