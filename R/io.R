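#' Read a BED-family file into an interval tibble
#'
#' Parses BED3+ (tab-separated, 0-based half-open). `track`, `browser` and
#' `#` comment lines are skipped. Standard column names are applied up to
#' BED6 (`name`, `score`, `strand`); with `min_cols = 10` the ENCODE
#' narrowPeak schema is used (`signalValue`, `pValue`, `qValue`, `summit`).
#' Parse and coordinate errors report the offending file line number.
#'
#' @param path Path to the file.
#' @param min_cols Minimum number of columns required (default 3).
#' @return An interval tibble; columns beyond 3 are kept as metadata.
#' @export
read_bed <- function(path, min_cols = 3) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "ceatlas_io_error")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < min_cols)) {
    i <- which(ncols < min_cols)[[1L]]
    rlang::abort(sprintf("line %d of %s has %d column(s); expected >= %d",
                         line_no[[i]], path, ncols[[i]], min_cols),
                 class = "ceatlas_parse_error")
  }
  ncol_use <- min(ncols)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)],
                  character(ncol_use)))
  np_names <- c("chrom", "start", "end", "name", "score", "strand",
                "signalValue", "pValue", "qValue", "summit")
  cn <- np_names[seq_len(min(ncol_use, 10L))]
  if (ncol_use > 10L) cn <- c(cn, paste0("extra", seq_len(ncol_use - 10L)))
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  names(out) <- cn
  for (col in intersect(c("start", "end", "score", "signalValue", "pValue",
                          "qValue", "summit"), cn)) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    if (col %in% c("start", "end") && anyNA(val)) {
      i <- which(is.na(val))[[1L]]
      rlang::abort(sprintf("line %d of %s: non-numeric %s '%s'",
                           line_no[[i]], path, col, out[[col]][[i]]),
                   class = "ceatlas_parse_error")
    }
    out[[col]] <- val
  }
  bad <- which(out$start < 0 | out$end <= out$start)
  if (length(bad) > 0L) {
    i <- bad[[1L]]
    rlang::abort(sprintf(
      "line %d of %s: invalid interval %s:%s-%s (need 0 <= start < end)",
      line_no[[i]], path, out$chrom[[i]],
      format(out$start[[i]], scientific = FALSE),
      format(out$end[[i]], scientific = FALSE)),
      class = "ceatlas_parse_error")
  }
  out
}

#' @rdname read_bed
#' @export
read_narrowpeak <- function(path) {
  read_bed(path, min_cols = 10)
}

#' Read TSS positions from a GTF/GFF3 or BED file
#'
#' From GTF/GFF3, the TSS of a `+` feature is its (1-based) start converted
#' to a 0-based offset, and of a `-` feature its end converted likewise;
#' records without a usable strand are skipped with a warning. From BED,
#' each interval's `start` is taken as the TSS. Positions are deduplicated
#' per chromosome (several transcripts sharing a start yield one TSS).
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` (also GFF3) or `"bed"`.
#' @param feature GTF feature type(s) to use (default `"gene"`; use
#'   `"transcript"` for per-transcript TSSs).
#' @return A tibble with columns `chrom`, `pos` (0-based TSS offset) and,
#'   for GTF input, `gene_id` and `strand`.
#' @export
read_tss <- function(path, format = c("gtf", "bed"), feature = "gene") {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- read_bed(path, min_cols = 3)
    out <- tibble::tibble(chrom = bed$chrom, pos = bed$start)
    return(dplyr::distinct(dplyr::arrange(out, .data$chrom, .data$pos)))
  }
  gtf <- readr::read_tsv(
    path, comment = "#",
    col_names = c("chrom", "source", "feature", "start", "end", "score",
                  "strand", "frame", "attributes"),
    col_types = readr::cols(
      chrom = "c", source = "c", feature = "c", start = "d", end = "d",
      score = "c", strand = "c", frame = "c", attributes = "c"),
    progress = FALSE)
  gtf <- gtf[gtf$feature %in% feature, , drop = FALSE]
  usable <- gtf$strand %in% c("+", "-")
  if (any(!usable)) {
    rlang::warn(sprintf("skipping %d %s record(s) without '+'/'-' strand",
                        sum(!usable), paste(feature, collapse = "/")))
    gtf <- gtf[usable, , drop = FALSE]
  }
  gene_id <- stringr::str_match(gtf$attributes,
                                'gene_id[ =]"?([^";]+)"?')[, 2L]
  out <- tibble::tibble(
    chrom = gtf$chrom,
    # GTF is 1-based inclusive; 0-based TSS = start-1 on '+', end-1 on '-'
    pos = ifelse(gtf$strand == "+", gtf$start - 1, gtf$end - 1),
    gene_id = gene_id,
    strand = gtf$strand)
  dplyr::distinct(dplyr::arrange(out, .data$chrom, .data$pos),
                  .data$chrom, .data$pos, .keep_all = TRUE)
}

#' Read a differential-expression results table
#'
#' Expects a TSV with at least `gene_id`, `log2fc` and `padj`; TSS
#' coordinates may be present as `chrom` + `tss` columns or joined later
#' from an annotation. Extra columns pass through.
#'
#' @param path Path to the TSV.
#' @return A tibble with the table contents.
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  missing_cols <- setdiff(c("gene_id", "log2fc", "padj"), names(de))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("DE table is missing column(s): ",
                        paste(missing_cols, collapse = ", "),
                        " (expected gene_id, log2fc, padj)"),
                 class = "ceatlas_schema_error")
  }
  de
}

#' Read SNP records
#'
#' Accepts a TSV with columns `rsid`, `chrom`, `pos` (plus free-form
#' annotation columns). The coordinate convention of `pos` is never
#' guessed: state it explicitly via `coords`.
#'
#' @param path Path to the TSV.
#' @param coords `"zero_based"` for BED-like offsets or `"one_based"` for
#'   conventional variant positions (converted to 0-based on read).
#' @return A tibble with 0-based `pos`; malformed positions are dropped
#'   with a warning naming their lines.
#' @export
read_snps <- function(path, coords = c("zero_based", "one_based")) {
  coords <- match.arg(coords)
  snps <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  missing_cols <- setdiff(c("rsid", "chrom", "pos"), names(snps))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("SNP table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "ceatlas_schema_error")
  }
  pos <- suppressWarnings(as.numeric(snps$pos))
  bad <- is.na(pos) | pos < ifelse(coords == "one_based", 1, 0)
  if (any(bad)) {
    rlang::warn(sprintf("dropping %d SNP record(s) with malformed positions (rows %s)",
                        sum(bad),
                        paste(utils::head(which(bad), 5L), collapse = ", ")))
    snps <- snps[!bad, , drop = FALSE]
    pos <- pos[!bad]
  }
  snps$pos <- if (coords == "one_based") pos - 1 else pos
  snps
}

#' Write an interval tibble as BED
#'
#' Writes BED3 or BED6 depending on the presence of `name`; rows are sorted
#' by (chrom, start, end) and coordinates are printed as plain integers so
#' reruns are byte-identical.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  df <- data.frame(chrom = x$chrom,
                   start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) {
    df$name <- x$name
    df$score <- if ("score" %in% names(x)) x$score else 0
    df$strand <- if ("strand" %in% names(x)) x$strand else "."
  }
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a candidate-enhancer atlas to a directory
#'
#' Emits one BED6 file per tissue (`<tissue>.ces.bed`, name field
#' `tissue|state|id`) plus `atlas.json` with the per-(tissue, state) counts
#' and total bp, the parameters, and the provenance block. Output is
#' deterministic except for the `timestamp` field in the JSON.
#'
#' @param atlas A `ce_atlas` object from [build_atlas()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "ce_atlas"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ces <- dplyr::arrange(atlas$ces, .data$tissue, .data$chrom, .data$start,
                        .data$end)
  for (ti in unique(ces$tissue)) {
    x <- ces[ces$tissue == ti, , drop = FALSE]
    bed <- tibble::tibble(
      chrom = x$chrom, start = x$start, end = x$end,
      name = paste(x$tissue, x$state, x$id, sep = "|"),
      score = 0, strand = ".")
    write_bed(bed, file.path(dir, paste0(ti, ".ces.bed")))
  }
  summary <- list(
    tissues = unique(ces$tissue),
    counts = glance_counts(ces),
    genome = atlas$genome,
    parameters = unclass(atlas$params),
    provenance = atlas$provenance)
  jsonlite::write_json(summary, file.path(dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

glance_counts <- function(ces) {
  ces |>
    dplyr::group_by(.data$tissue, .data$state) |>
    dplyr::summarise(count = dplyr::n(),
                     total_bp = sum(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::arrange(.data$tissue, .data$state)
}

#' Read a candidate-enhancer atlas written by [write_atlas()]
#'
#' @param dir Directory containing `atlas.json` and the per-tissue BED
#'   files.
#' @return A `ce_atlas` object.
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  tissues <- unlist(meta$tissues)
  empty <- tibble::tibble(tissue = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          state = character(), id = character())
  ces <- dplyr::bind_rows(empty, lapply(tissues, function(ti) {
    bed <- read_bed(file.path(dir, paste0(ti, ".ces.bed")), min_cols = 6)
    parts <- stringr::str_split_fixed(bed$name, stringr::fixed("|"), 3L)
    tibble::tibble(tissue = parts[, 1L], chrom = bed$chrom,
                   start = bed$start, end = bed$end,
                   state = parts[, 2L], id = parts[, 3L])
  }))
  genome <- tibble::as_tibble(meta$genome)
  new_ce_atlas(ces = ces,
               params = do.call(atlas_params, meta$parameters),
               genome = genome,
               provenance = meta$provenance)
}

#' Write a tibble report as TSV with deterministic ordering
#'
#' @param x A tibble (assignments, pairs, histograms, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
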