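#' Parameters of the synthetic two-tissue epigenome
#'
#' The generator plants enhancers of known state in two tissues on a small
#' genome, together with the annotation the CE pipeline consumes: TSSs,
#' TADs, a differential-expression table and SNPs. Seven planting
#' categories are used: `shared_strongly_active`, `shared_active`,
#' `shared_poised` (same state in both tissues), `unique_a` / `unique_b`
#' (strongly-active in one tissue, absent in the other),
#' `switch_a_strong_b_poised` / `switch_b_strong_a_poised`
#' (strongly-active in one tissue, poised in the other).
#'
#' Structural guarantees that make the ground truth unambiguous under the
#' pipeline's merge rule: planted enhancers are pairwise more than
#' `2 * merge_gap` apart, and every enhancer keeps at least
#' `promoter_flank + 500` bp clear of every TSS.
#'
#' A fraction `pairing_frac` of the unique enhancers of each tissue is
#' placed in a dedicated TAD shared with exactly one matched DEG
#' (upregulated in the same tissue); `n_extra_degs` further DEGs per
#' tissue sit in TADs containing no tissue-exclusive enhancer, and
#' `n_ns_genes` non-significant genes are scattered outside the TAD
#' blocks.
#'
#' @param genome Genome tibble (default two chromosomes totalling 20 Mb).
#' @param tissues Two tissue labels (default `interzone`, `phalange`;
#'   `log2fc` in the emitted DE table is oriented first over second).
#' @param n_per_category Enhancers planted per category (default 50).
#' @param enhancer_width Width range in bp (default 400–1500).
#' @param merge_gap,promoter_flank Pipeline constants the layout must
#'   respect (defaults as in [atlas_params()]).
#' @param pairing_frac Fraction of unique enhancers paired with a DEG in a
#'   shared TAD (default 0.6).
#' @param n_extra_degs DEGs per tissue planted in enhancer-free TADs
#'   (default 20).
#' @param n_ns_genes Non-significant genes (default 200).
#' @param n_snps_inside,n_snps_outside SNPs planted inside planted
#'   enhancers / in enhancer-free background (defaults 100 / 200).
#' @param tad_width,tad_gap TAD block width and inter-block gap ranges in
#'   bp.
#' @return A list of class `ce_sim_params`.
#' @export
sim_params <- function(genome = genome_info(c("chrSim1", "chrSim2"),
                                            c(12e6, 8e6)),
                       tissues = c("interzone", "phalange"),
                       n_per_category = 50,
                       enhancer_width = c(400, 1500),
                       merge_gap = 1000,
                       promoter_flank = 1000,
                       pairing_frac = 0.6,
                       n_extra_degs = 20,
                       n_ns_genes = 200,
                       n_snps_inside = 100,
                       n_snps_outside = 200,
                       tad_width = c(5e4, 1e5),
                       tad_gap = c(1e4, 4e4)) {
  stopifnot(length(tissues) == 2L, n_per_category >= 0,
            pairing_frac >= 0, pairing_frac <= 1)
  structure(list(genome = genome, tissues = tissues,
                 n_per_category = n_per_category,
                 enhancer_width = enhancer_width, merge_gap = merge_gap,
                 promoter_flank = promoter_flank,
                 pairing_frac = pairing_frac, n_extra_degs = n_extra_degs,
                 n_ns_genes = n_ns_genes, n_snps_inside = n_snps_inside,
                 n_snps_outside = n_snps_outside, tad_width = tad_width,
                 tad_gap = tad_gap),
            class = "ce_sim_params")
}

#' Noise model of the synthetic observation process
#'
#' @param jitter_sd Peak endpoint jitter, Normal(0, `jitter_sd`) bp
#'   (default 20).
#' @param fn_rate Probability that an emitted peak is dropped (default
#'   0.05).
#' @param spurious_per_mb Spurious peaks per Mb per (tissue, mark) set
#'   (default 0.1).
#' @param conservation_coverage Fraction of each planted enhancer covered
#'   by its conservation block (default 0.9).
#' @param split_prob Probability that an enhancer-mark emits two
#'   overlapping peaks (each spanning ~70% of the region) instead of one
#'   full-span peak (default 0.5).
#' @param background_cons_per_mb Background conservation blocks per Mb
#'   (default 10).
#' @param background_cons_width Width range of background blocks in bp.
#' @return A list of class `ce_noise_params`.
#' @export
noise_params <- function(jitter_sd = 20, fn_rate = 0.05,
                         spurious_per_mb = 0.1,
                         conservation_coverage = 0.9, split_prob = 0.5,
                         background_cons_per_mb = 10,
                         background_cons_width = c(100, 300)) {
  stopifnot(jitter_sd >= 0, fn_rate >= 0, fn_rate <= 1,
            conservation_coverage > 0, conservation_coverage <= 1,
            split_prob >= 0, split_prob <= 1)
  structure(list(jitter_sd = jitter_sd, fn_rate = fn_rate,
                 spurious_per_mb = spurious_per_mb,
                 conservation_coverage = conservation_coverage,
                 split_prob = split_prob,
                 background_cons_per_mb = background_cons_per_mb,
                 background_cons_width = background_cons_width),
            class = "ce_noise_params")
}

#' Noise-free observation parameters
#'
#' In this limit the emitted peak sets equal the planted regions exactly
#' and conservation covers every enhancer completely, so the pipeline must
#' reproduce the truth identically.
#'
#' @return A `ce_noise_params` object with all noise switched off.
#' @export
no_noise <- function() {
  noise_params(jitter_sd = 0, fn_rate = 0, spurious_per_mb = 0,
               conservation_coverage = 1, split_prob = 0,
               background_cons_per_mb = 0)
}

sim_categories <- function() {
  c("shared_strongly_active", "shared_active", "shared_poised",
    "unique_a", "unique_b",
    "switch_a_strong_b_poised", "switch_b_strong_a_poised")
}

category_states <- function(category) {
  map <- list(
    shared_strongly_active = c("strongly_active", "strongly_active"),
    shared_active = c("active", "active"),
    shared_poised = c("poised", "poised"),
    unique_a = c("strongly_active", "absent"),
    unique_b = c("absent", "strongly_active"),
    switch_a_strong_b_poised = c("strongly_active", "poised"),
    switch_b_strong_a_poised = c("poised", "strongly_active"))
  do.call(rbind, map[category])
}

#' Simulate the ground truth of a two-tissue synthetic epigenome
#'
#' Lays out TAD blocks (CE–DEG pair blocks and enhancer-free DEG blocks)
#' along the chromosomes, then plants the remaining enhancers, the
#' non-significant genes and the SNPs in the TAD-free background by
#' rejection sampling under the spacing and promoter-clearance
#' constraints. Deterministic under `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A list of class `ce_sim_truth` with tibbles `enhancers`
#'   (`enh_id`, `chrom`, `start`, `end`, `category`, per-tissue states),
#'   `genes` (`gene_id`, `chrom`, `tss`, `direction`, `paired_enh`),
#'   `tads` (`tad_id`, `chrom`, `start`, `end`, `kind`), `snps`
#'   (`rsid`, `chrom`, `pos`, `inside`, `enh_id`), plus `genome`,
#'   `tissues`, `params` and `seed`.
#' @export
simulate_truth <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "ce_sim_params"))
  withr::with_seed(seed, simulate_truth_impl(params, seed))
}

simulate_truth_impl <- function(params, seed) {
  g <- params$genome
  n_cat <- params$n_per_category
  spacing <- 2 * params$merge_gap
  tss_clear <- params$promoter_flank + 500
  n_pair <- round(params$pairing_frac * n_cat)

  # ---- block plan: pair TADs and enhancer-free DEG TADs -----------------
  blocks <- tibble::tibble(
    kind = c(rep("pair_a", n_pair), rep("pair_b", n_pair),
             rep("extra_a", params$n_extra_degs),
             rep("extra_b", params$n_extra_degs)))
  if (nrow(blocks) > 0L) blocks <- blocks[sample.int(nrow(blocks)), ,
                                          drop = FALSE]
  margin <- 1e4
  cursor <- stats::setNames(rep(margin, nrow(g)), g$chrom)
  placed_blocks <- list()
  for (i in seq_len(nrow(blocks))) {
    w_tad <- stats::runif(1, params$tad_width[1], params$tad_width[2])
    gap <- stats::runif(1, params$tad_gap[1], params$tad_gap[2])
    placed <- FALSE
    for (cm in g$chrom) {
      if (cursor[[cm]] + w_tad + gap <= g$length[g$chrom == cm] - margin) {
        placed_blocks[[i]] <- tibble::tibble(
          kind = blocks$kind[[i]], chrom = cm,
          start = floor(cursor[[cm]]), end = floor(cursor[[cm]] + w_tad))
        cursor[[cm]] <- cursor[[cm]] + w_tad + gap
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rlang::abort(sprintf(
        "infeasible packing: placed %d of %d TAD blocks on the genome",
        i - 1L, nrow(blocks)), class = "ceatlas_runtime_error")
    }
  }
  tads <- dplyr::bind_rows(placed_blocks)
  if (nrow(tads) == 0L) {
    tads <- tibble::tibble(kind = character(), chrom = character(),
                           start = numeric(), end = numeric())
  }
  tads$tad_id <- if (nrow(tads) > 0L) sprintf("tad%03d", seq_len(nrow(tads)))
                 else character()

  # background zones: TAD-free space after the last block of each chrom
  zones <- tibble::tibble(
    chrom = g$chrom,
    start = pmin(unname(cursor[g$chrom]) + spacing, g$length - margin),
    end = g$length - margin)
  zones <- zones[zones$end - zones$start > 1e4, , drop = FALSE]

  enh_start <- list(); enh_end <- list(); tss_pos <- list()
  for (cm in g$chrom) {
    enh_start[[cm]] <- numeric(); enh_end[[cm]] <- numeric()
    tss_pos[[cm]] <- numeric()
  }
  enh_ok <- function(cm, s, e) {
    !any(enh_start[[cm]] - spacing < e & enh_end[[cm]] + spacing > s) &&
      !any(tss_pos[[cm]] - tss_clear < e & tss_pos[[cm]] + tss_clear > s)
  }
  tss_ok <- function(cm, p) {
    !any(enh_start[[cm]] - tss_clear < p + 1 & enh_end[[cm]] + tss_clear > p) &&
      !any(abs(tss_pos[[cm]] - p) < 50)
  }
  rand_width <- function() {
    floor(stats::runif(1, params$enhancer_width[1],
                       params$enhancer_width[2] + 1))
  }

  enh_rows <- list()
  gene_rows <- list()
  gene_n <- 0L
  enh_n <- 0L
  add_enh <- function(cm, s, e, category) {
    enh_n <<- enh_n + 1L
    enh_start[[cm]] <<- c(enh_start[[cm]], s)
    enh_end[[cm]] <<- c(enh_end[[cm]], e)
    st <- category_states(category)
    enh_rows[[enh_n]] <<- tibble::tibble(
      enh_id = sprintf("enh%04d", enh_n), chrom = cm, start = s, end = e,
      category = category, state_a = st[1L], state_b = st[2L])
    enh_rows[[enh_n]]$enh_id
  }
  add_gene <- function(cm, p, direction, paired_enh = NA_character_) {
    gene_n <<- gene_n + 1L
    tss_pos[[cm]] <<- c(tss_pos[[cm]], p)
    gene_rows[[gene_n]] <<- tibble::tibble(
      gene_id = sprintf("gene%04d", gene_n), chrom = cm, tss = p,
      direction = direction, paired_enh = paired_enh)
  }

  # ---- populate blocks --------------------------------------------------
  for (i in seq_len(nrow(tads))) {
    cm <- tads$chrom[[i]]; ts <- tads$start[[i]]; te <- tads$end[[i]]
    kind <- tads$kind[[i]]
    p <- floor(stats::runif(1, ts + 5e3, te - 5e3))
    if (kind %in% c("pair_a", "pair_b")) {
      w <- rand_width()
      right <- stats::runif(1) < 0.5
      s <- if (right && p + 2500 + w <= te - 1000) {
        floor(stats::runif(1, p + 2500, te - 1000 - w))
      } else if (ts + 1000 + w <= p - 2500) {
        floor(stats::runif(1, ts + 1000, p - 2500 - w))
      } else {
        floor(stats::runif(1, p + 2500, te - 1000 - w))
      }
      cat <- if (kind == "pair_a") "unique_a" else "unique_b"
      eid <- add_enh(cm, s, s + w, cat)
      add_gene(cm, p, if (kind == "pair_a") "up_a" else "up_b",
               paired_enh = eid)
    } else {
      add_gene(cm, p, if (kind == "extra_a") "up_a" else "up_b")
    }
  }

  # ---- background placements by rejection sampling ----------------------
  sample_in_zones <- function(width) {
    wts <- pmax(zones$end - zones$start - width, 0)
    zi <- sample.int(nrow(zones), 1L, prob = wts)
    s <- floor(stats::runif(1, zones$start[[zi]],
                            zones$end[[zi]] - width))
    list(chrom = zones$chrom[[zi]], start = s)
  }
  place_background <- function(n, what, category = NULL, direction = NULL) {
    tries <- 0L
    budget <- max(200L * n, 1000L)
    placed <- 0L
    while (placed < n && tries < budget) {
      tries <- tries + 1L
      if (what == "enh") {
        w <- rand_width()
        cand <- sample_in_zones(w)
        if (enh_ok(cand$chrom, cand$start, cand$start + w)) {
          add_enh(cand$chrom, cand$start, cand$start + w, category)
          placed <- placed + 1L
        }
      } else {
        cand <- sample_in_zones(1)
        if (tss_ok(cand$chrom, cand$start)) {
          add_gene(cand$chrom, cand$start, direction)
          placed <- placed + 1L
        }
      }
    }
    if (placed < n) {
      rlang::abort(sprintf(
        "infeasible packing: placed %d of %d background %s items after %d tries",
        placed, n, what, tries), class = "ceatlas_runtime_error")
    }
  }
  if (nrow(zones) == 0L && n_cat > 0L) {
    rlang::abort("no background space left on the genome for enhancer placement",
                 class = "ceatlas_runtime_error")
  }
  for (cat in c("shared_strongly_active", "shared_active", "shared_poised",
                "switch_a_strong_b_poised", "switch_b_strong_a_poised")) {
    if (n_cat > 0L) place_background(n_cat, "enh", category = cat)
  }
  if (n_cat - n_pair > 0L) {
    place_background(n_cat - n_pair, "enh", category = "unique_a")
    place_background(n_cat - n_pair, "enh", category = "unique_b")
  }
  if (params$n_ns_genes > 0L) {
    place_background(params$n_ns_genes, "gene", direction = "ns")
  }

  enhancers <- if (enh_n > 0L) dplyr::bind_rows(enh_rows) else
    tibble::tibble(enh_id = character(), chrom = character(),
                   start = numeric(), end = numeric(),
                   category = character(), state_a = character(),
                   state_b = character())
  genes <- if (gene_n > 0L) dplyr::bind_rows(gene_rows) else
    tibble::tibble(gene_id = character(), chrom = character(),
                   tss = numeric(), direction = character(),
                   paired_enh = character())

  # ---- SNPs -------------------------------------------------------------
  snp_rows <- list()
  if (params$n_snps_inside > 0L && enh_n > 0L) {
    host <- sample.int(enh_n, params$n_snps_inside, replace = TRUE)
    snp_rows$inside <- tibble::tibble(
      chrom = enhancers$chrom[host],
      pos = floor(stats::runif(params$n_snps_inside,
                               enhancers$start[host],
                               enhancers$end[host])),
      inside = TRUE, enh_id = enhancers$enh_id[host])
  }
  if (params$n_snps_outside > 0L) {
    got <- 0L; tries <- 0L; acc <- list()
    while (got < params$n_snps_outside && tries < 200L * params$n_snps_outside) {
      tries <- tries + 1L
      cand <- sample_in_zones(1)
      cm <- cand$chrom; p <- cand$start
      if (!any(enh_start[[cm]] - 1000 <= p & enh_end[[cm]] + 1000 > p)) {
        got <- got + 1L
        acc[[got]] <- tibble::tibble(chrom = cm, pos = p, inside = FALSE,
                                     enh_id = NA_character_)
      }
    }
    if (got < params$n_snps_outside) {
      rlang::abort(sprintf("placed %d of %d background SNPs", got,
                           params$n_snps_outside),
                   class = "ceatlas_runtime_error")
    }
    snp_rows$outside <- dplyr::bind_rows(acc)
  }
  snps <- dplyr::bind_rows(snp_rows)
  if (nrow(snps) == 0L) {
    snps <- tibble::tibble(chrom = character(), pos = numeric(),
                           inside = logical(), enh_id = character())
  }
  snps <- dplyr::mutate(snps, rsid = sprintf("rs%06d", dplyr::row_number()),
                        .before = 1L)

  structure(list(enhancers = enhancers, genes = genes,
                 tads = dplyr::select(tads, "tad_id", "chrom", "start",
                                      "end", "kind"),
                 snps = snps, genome = g, tissues = params$tissues,
                 params = params, seed = seed),
            class = "ce_sim_truth")
}

#' @export
print.ce_sim_truth <- function(x, ...) {
  cat("Synthetic two-tissue epigenome truth (seed ", x$seed, ")\n", sep = "")
  cat("  genome:", sum(x$genome$length) / 1e6, "Mb on", nrow(x$genome),
      "chromosome(s)\n")
  cat("  enhancers:", nrow(x$enhancers), " genes:", nrow(x$genes),
      " TADs:", nrow(x$tads), " SNPs:", nrow(x$snps), "\n")
  print(dplyr::count(x$enhancers, .data$category))
  invisible(x)
}

#' Emit the observable inputs implied by a synthetic truth
#'
#' Produces everything the CE pipeline consumes: per-(tissue, mark) peak
#' sets, conservation blocks, TSS positions, TADs, a DE results table and
#' SNP records. Each enhancer-mark emits one full-span peak or (with
#' probability `split_prob`) two overlapping peaks covering ~70% of the
#' region each; peak endpoints are jittered by Normal(0, `jitter_sd`),
#' peaks are dropped at `fn_rate`, and spurious peaks are added at
#' `spurious_per_mb`. Conservation blocks cover a `conservation_coverage`
#' fraction of each planted enhancer (uniformly offset), plus background
#' blocks. DE values: upregulated genes draw
#' `log2fc = +/-(1 + |Normal(0, 0.5)|)` with `padj = 10^-U(5, 30)`;
#' non-significant genes draw `log2fc ~ Normal(0, 0.2)` with
#' `padj ~ U(0.2, 1)`.
#'
#' @param truth A `ce_sim_truth` from [simulate_truth()].
#' @param noise A [noise_params()] object (use [no_noise()] for the exact
#'   limit).
#' @param seed Integer seed for the observation noise.
#' @return A list of class `ce_sim_inputs` with `peaks` (tibble with
#'   `tissue`, `mark`, `chrom`, `start`, `end`), `conservation`, `tss`,
#'   `tads`, `de` (with `chrom` and `tss` columns), `snps`, `genome`,
#'   `tissues`.
#' @export
emit_observed_inputs <- function(truth, noise = noise_params(), seed = 1) {
  stopifnot(inherits(truth, "ce_sim_truth"),
            inherits(noise, "ce_noise_params"))
  withr::with_seed(seed, emit_impl(truth, noise))
}

emit_impl <- function(truth, noise) {
  g <- truth$genome
  len <- stats::setNames(g$length, g$chrom)
  genome_mb <- sum(g$length) / 1e6
  enh <- truth$enhancers

  state_marks <- function(state) {
    switch(state,
           strongly_active = c("H3K27ac", "H3K4me1"),
           active = "H3K27ac",
           poised = "H3K4me1",
           absent = character())
  }
  jitter <- function(x) round(x + stats::rnorm(length(x), 0, noise$jitter_sd))

  peak_rows <- list()
  for (ti_idx in 1:2) {
    ti <- truth$tissues[[ti_idx]]
    states <- if (ti_idx == 1L) enh$state_a else enh$state_b
    for (i in seq_len(nrow(enh))) {
      for (mk in state_marks(states[[i]])) {
        s <- enh$start[[i]]; e <- enh$end[[i]]; w <- e - s
        raw <- if (stats::runif(1) < noise$split_prob) {
          tibble::tibble(start = c(s, s + floor(0.3 * w)),
                         end = c(s + ceiling(0.7 * w), e))
        } else {
          tibble::tibble(start = s, end = e)
        }
        raw$start <- pmax(jitter(raw$start), 0)
        raw$end <- pmin(jitter(raw$end), len[[enh$chrom[[i]]]])
        raw <- raw[raw$end > raw$start, , drop = FALSE]
        raw <- raw[stats::runif(nrow(raw)) >= noise$fn_rate, , drop = FALSE]
        if (nrow(raw) > 0L) {
          peak_rows[[length(peak_rows) + 1L]] <- tibble::tibble(
            tissue = ti, mark = mk, chrom = enh$chrom[[i]],
            start = raw$start, end = raw$end)
        }
      }
    }
    for (mk in c("H3K27ac", "H3K4me1")) {
      n_spur <- stats::rpois(1, noise$spurious_per_mb * genome_mb)
      if (n_spur > 0L) {
        wd <- floor(stats::runif(n_spur, 200, 800))
        cm <- sample(g$chrom, n_spur, replace = TRUE, prob = g$length)
        st <- floor(stats::runif(n_spur, 0, len[cm] - wd))
        peak_rows[[length(peak_rows) + 1L]] <- tibble::tibble(
          tissue = ti, mark = mk, chrom = cm, start = st, end = st + wd)
      }
    }
  }
  peaks <- dplyr::bind_rows(peak_rows)
  if (nrow(peaks) == 0L) {
    peaks <- tibble::tibble(tissue = character(), mark = character(),
                            chrom = character(), start = numeric(),
                            end = numeric())
  }
  peaks <- dplyr::arrange(peaks, .data$tissue, .data$mark, .data$chrom,
                          .data$start)

  cons_rows <- list()
  if (nrow(enh) > 0L) {
    w <- enh$end - enh$start
    cov_w <- round(noise$conservation_coverage * w)
    off <- floor(stats::runif(nrow(enh), 0, w - cov_w + 1))
    cons_rows$planted <- tibble::tibble(chrom = enh$chrom,
                                        start = enh$start + off,
                                        end = enh$start + off + cov_w)
  }
  n_bg <- stats::rpois(1, noise$background_cons_per_mb * genome_mb)
  if (n_bg > 0L) {
    wd <- floor(stats::runif(n_bg, noise$background_cons_width[1],
                             noise$background_cons_width[2]))
    cm <- sample(g$chrom, n_bg, replace = TRUE, prob = g$length)
    st <- floor(stats::runif(n_bg, 0, len[cm] - wd))
    cons_rows$background <- tibble::tibble(chrom = cm, start = st,
                                           end = st + wd)
  }
  conservation <- dplyr::bind_rows(cons_rows)
  if (nrow(conservation) == 0L) conservation <- empty_intervals()
  conservation <- dplyr::arrange(conservation, .data$chrom, .data$start)

  genes <- truth$genes
  n_genes <- nrow(genes)
  lfc <- numeric(n_genes); padj <- numeric(n_genes)
  up_a <- genes$direction == "up_a"
  up_b <- genes$direction == "up_b"
  ns <- genes$direction == "ns"
  lfc[up_a] <- 1 + abs(stats::rnorm(sum(up_a), 0, 0.5))
  lfc[up_b] <- -(1 + abs(stats::rnorm(sum(up_b), 0, 0.5)))
  lfc[ns] <- stats::rnorm(sum(ns), 0, 0.2)
  padj[up_a | up_b] <- 10^-stats::runif(sum(up_a | up_b), 5, 30)
  padj[ns] <- stats::runif(sum(ns), 0.2, 1)
  de <- tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                       tss = genes$tss, log2fc = lfc, padj = padj)

  snps <- tibble::tibble(
    rsid = truth$snps$rsid, chrom = truth$snps$chrom,
    pos = truth$snps$pos,
    trait = sample(c("osteoarthritis", "height", "bone_density", "none"),
                   nrow(truth$snps), replace = TRUE),
    pvalue_text = sprintf("%.0fe-%d",
                          stats::runif(nrow(truth$snps), 1, 9),
                          floor(stats::runif(nrow(truth$snps), 8, 20))))

  structure(list(peaks = peaks, conservation = conservation,
                 tss = tibble::tibble(chrom = genes$chrom,
                                      pos = genes$tss,
                                      gene_id = genes$gene_id),
                 tads = truth$tads, de = de, snps = snps,
                 genome = g, tissues = truth$tissues, noise = noise),
            class = "ce_sim_inputs")
}

#' Write a synthetic input bundle as plain-text files
#'
#' Emits per-(tissue, mark) peak BEDs, `conservation.bed`, `tss.bed`,
#' `tads.bed`, `de_table.tsv` and `snps.tsv` (0-based positions), plus
#' `genome.tsv`, all readable by the package's readers.
#'
#' @param inputs A `ce_sim_inputs` from [emit_observed_inputs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(inputs, dir) {
  stopifnot(inherits(inputs, "ce_sim_inputs"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ti in inputs$tissues) {
    for (mk in c("H3K27ac", "H3K4me1")) {
      p <- inputs$peaks[inputs$peaks$tissue == ti & inputs$peaks$mark == mk,
                        c("chrom", "start", "end")]
      write_bed(p, file.path(dir, paste0(ti, ".", mk, ".peaks.bed")))
    }
  }
  write_bed(inputs$conservation, file.path(dir, "conservation.bed"))
  write_bed(tibble::tibble(chrom = inputs$tss$chrom,
                           start = inputs$tss$pos,
                           end = inputs$tss$pos + 1,
                           name = inputs$tss$gene_id),
            file.path(dir, "tss.bed"))
  write_bed(tibble::tibble(chrom = inputs$tads$chrom,
                           start = inputs$tads$start,
                           end = inputs$tads$end,
                           name = inputs$tads$tad_id),
            file.path(dir, "tads.bed"))
  readr::write_tsv(inputs$de, file.path(dir, "de_table.tsv"),
                   progress = FALSE)
  readr::write_tsv(inputs$snps, file.path(dir, "snps.tsv"),
                   progress = FALSE)
  readr::write_tsv(inputs$genome, file.path(dir, "genome.tsv"),
                   progress = FALSE)
  invisible(dir)
}

truth_state_sets <- function(truth) {
  long <- dplyr::bind_rows(
    dplyr::transmute(truth$enhancers, tissue = truth$tissues[[1L]],
                     .data$chrom, .data$start, .data$end,
                     state = .data$state_a, enh_id = .data$enh_id,
                     category = .data$category),
    dplyr::transmute(truth$enhancers, tissue = truth$tissues[[2L]],
                     .data$chrom, .data$start, .data$end,
                     state = .data$state_b, enh_id = .data$enh_id,
                     category = .data$category))
  long[long$state != "absent", , drop = FALSE]
}

#' Score pipeline recovery of a planted synthetic truth
#'
#' A planted enhancer counts as recovered when a same-tissue, same-state
#' atlas CE overlaps it reciprocally at >= 0.5. Per-(tissue, state)
#' precision, recall and F1 are reported, together with observed vs
#' expected counts for the tissue-exclusive and state-switch sets (the
#' expected exclusive set of a tissue is its planted unique *plus* switch
#' enhancers, both being strongly-active there and not in the other
#' tissue), and, when assignments are supplied, planted CE–gene pair
#' recall/precision (an assignment matches a planted pair when its gene
#' matches and its CE reciprocally overlaps the planted enhancer at
#' >= 0.5).
#'
#' @param truth A `ce_sim_truth`.
#' @param atlas The `ce_atlas` built from the emitted inputs.
#' @param comparison Optional `ce_comparison` from [compare_tissues()].
#' @param assignments Optional named list (by tissue) of assignment
#'   tibbles from [assign_ces_to_degs()].
#' @return A list with `states` (tibble: tissue, state, n_truth, n_atlas,
#'   matched, precision, recall, f1), `state_f1` (pooled per state),
#'   `counts` (observed vs expected exclusive/switch counts) and `pairs`
#'   (pair recall/precision, or `NULL`).
#' @export
score_recovery <- function(truth, atlas, comparison = NULL,
                           assignments = NULL) {
  stopifnot(inherits(truth, "ce_sim_truth"), inherits(atlas, "ce_atlas"))
  tstates <- truth_state_sets(truth)
  grid <- tidyr::expand_grid(tissue = truth$tissues, state = ce_states)
  states <- purrr::pmap(grid, function(tissue, state) {
    tr <- tstates[tstates$tissue == tissue & tstates$state == state, ]
    at <- atlas$ces[atlas$ces$tissue == tissue & atlas$ces$state == state, ]
    matched_truth <- 0L; matched_atlas <- 0L
    if (nrow(tr) > 0L && nrow(at) > 0L) {
      pairs <- reciprocal_overlap_pairs(tr, at, frac = 0.5)
      matched_truth <- length(unique(pairs$a_idx))
      matched_atlas <- length(unique(pairs$b_idx))
    }
    precision <- if (nrow(at) > 0L) matched_atlas / nrow(at) else NA_real_
    recall <- if (nrow(tr) > 0L) matched_truth / nrow(tr) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else if (nrow(tr) > 0L) 0 else NA_real_
    tibble::tibble(tissue = tissue, state = state, n_truth = nrow(tr),
                   n_atlas = nrow(at), matched_truth = matched_truth,
                   matched_atlas = matched_atlas, precision = precision,
                   recall = recall, f1 = f1)
  }) |> dplyr::bind_rows()

  state_f1 <- states |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      n_truth = sum(.data$n_truth), n_atlas = sum(.data$n_atlas),
      precision = ifelse(sum(.data$n_atlas) > 0,
                         sum(.data$matched_atlas) / sum(.data$n_atlas),
                         NA_real_),
      recall = ifelse(sum(.data$n_truth) > 0,
                      sum(.data$matched_truth) / sum(.data$n_truth),
                      NA_real_),
      .groups = "drop") |>
    dplyr::mutate(f1 = ifelse(!is.na(.data$precision) &
                                !is.na(.data$recall) &
                                .data$precision + .data$recall > 0,
                              2 * .data$precision * .data$recall /
                                (.data$precision + .data$recall),
                              ifelse(.data$n_truth > 0, 0, NA_real_)))

  counts <- NULL
  if (!is.null(comparison)) {
    a <- truth$tissues[[1L]]; b <- truth$tissues[[2L]]
    enh <- truth$enhancers
    expected <- c(
      sum(enh$category %in% c("unique_a", "switch_a_strong_b_poised")),
      sum(enh$category %in% c("unique_b", "switch_b_strong_a_poised")),
      sum(enh$category == "switch_a_strong_b_poised"),
      sum(enh$category == "switch_b_strong_a_poised"))
    observed <- c(nrow(comparison$exclusive[[a]]),
                  nrow(comparison$exclusive[[b]]),
                  nrow(comparison$switches[[paste0(a, "_to_", b)]]),
                  nrow(comparison$switches[[paste0(b, "_to_", a)]]))
    counts <- tibble::tibble(
      quantity = c(paste0("exclusive_", c(a, b)),
                   paste0("switch_", c(paste0(a, "_to_", b),
                                       paste0(b, "_to_", a)))),
      expected = expected, observed = observed,
      rel_error = ifelse(expected > 0, abs(observed - expected) / expected,
                         NA_real_))
  }

  pairs <- NULL
  if (!is.null(assignments)) {
    planted <- truth$genes[!is.na(truth$genes$paired_enh), , drop = FALSE]
    asg <- dplyr::bind_rows(assignments)
    n_matched <- 0L
    matched_asg <- rep(FALSE, nrow(asg))
    if (nrow(planted) > 0L && nrow(asg) > 0L) {
      enh <- truth$enhancers
      for (i in seq_len(nrow(planted))) {
        cand <- asg[asg$gene_id == planted$gene_id[[i]], , drop = FALSE]
        if (nrow(cand) == 0L) next
        pe <- enh[enh$enh_id == planted$paired_enh[[i]], , drop = FALSE]
        ce <- atlas$ces[match(cand$ce_id, atlas$ces$id), , drop = FALSE]
        ro <- reciprocal_overlap_pairs(pe, ce, frac = 0.5)
        if (nrow(ro) > 0L) {
          n_matched <- n_matched + 1L
          matched_asg[asg$gene_id == planted$gene_id[[i]] &
                        asg$ce_id %in% cand$ce_id[ro$b_idx]] <- TRUE
        }
      }
    }
    pairs <- tibble::tibble(
      n_planted = nrow(planted), n_assignments = nrow(asg),
      pair_recall = if (nrow(planted) > 0L) n_matched / nrow(planted)
                    else NA_real_,
      pair_precision = if (nrow(asg) > 0L) mean(matched_asg) else NA_real_)
  }

  list(states = states, state_f1 = state_f1, counts = counts, pairs = pairs)
}

#' Run the full synthetic study end to end
#'
#' Simulates a truth, emits observed inputs under the given noise model,
#' builds the atlas, compares the tissues, assigns tissue-exclusive
#' strongly-active CEs to matching-direction DEGs, overlays the SNPs and
#' scores recovery against the truth.
#'
#' @param params [sim_params()] object.
#' @param noise [noise_params()] object.
#' @param seed Integer seed; the observation noise uses `seed + 1000`.
#' @param atlas_parameters [atlas_params()] object used for the pipeline.
#' @return A list with `truth`, `inputs`, `atlas`, `comparison`,
#'   `degs`, `assignments` (named by tissue), `snp_overlaps` and
#'   `recovery`.
#' @export
run_synthetic_study <- function(params = sim_params(),
                                noise = noise_params(), seed = 1,
                                atlas_parameters = atlas_params(
                                  promoter_flank = params$promoter_flank,
                                  merge_gap = params$merge_gap)) {
  truth <- simulate_truth(params, seed = seed)
  inputs <- emit_observed_inputs(truth, noise = noise, seed = seed + 1000)
  atlas <- build_atlas(inputs$peaks, inputs$tss, inputs$conservation,
                       inputs$genome, params = atlas_parameters)
  comparison <- compare_tissues(atlas, inputs$tss)
  degs <- select_degs(inputs$de)
  dirs <- stats::setNames(c("up_a", "up_b"), truth$tissues)
  assignments <- lapply(truth$tissues, function(ti) {
    assign_ces_to_degs(
      exclusive_ces(atlas, ti, state = "strongly_active"),
      degs[degs$direction == dirs[[ti]], , drop = FALSE],
      inputs$tads)
  })
  names(assignments) <- truth$tissues
  snp_overlaps <- snps_in_ces(inputs$snps, atlas$ces)
  recovery <- score_recovery(truth, atlas, comparison, assignments)
  list(truth = truth, inputs = inputs, atlas = atlas,
       comparison = comparison, degs = degs, assignments = assignments,
       snp_overlaps = snp_overlaps, recovery = recovery)
}
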