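#' Default pipeline configuration
#'
#' All tunables of the pipeline stages with their defaults: sub-exon
#' coverage cutoffs (covered > 0.6, skipped <= 0.2), the dynamic-threshold
#' cap (80 bp) and step (10 bp), the novel-read graph batch size (1500),
#' the novel-isoform support rule (> 20 reads at pseudo-bulk), the
#' rare-isoform fraction (0.05), the gene read floor (> 20), enhancement
#' thresholds, FDR alpha and seeds.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "enhanced",        # enhanced | annotation_only
    covered_min = 0.6, skipped_max = 0.2,
    threshold_cap = 80, threshold_step = 10,
    batch_size = 1500L, novel_min_support = 20L,
    rare_fraction = 0.05, gene_min_reads = 20L,
    cov_floor = 5, fold_change = 5, window = 10L, junction_min_reads = 2L,
    min_junction_gap = 30L,   # block gaps below this are deletions, not introns
    fdr_alpha = 0.01, louvain_seed = 42L)
  utils::modifyList(cfg, list(...))
}

#' Run the full isoform-assignment pipeline
#'
#' Orchestrates annotate, map, novel discovery and counting on an in-memory
#' read table: builds (optionally coverage-enhanced) sub-exon partitions,
#' encodes each read against its overlapping genes, assigns reads to known
#' isoforms with dynamic thresholding, pools known-incompatible reads per
#' gene and discovers novel isoforms at pseudo-bulk level, resolves
#' multi-gene ambiguity by priority class and mapping score, and emits
#' gene- and transcript-level count matrices with full read-fate
#' accounting.
#'
#' @param reads Read tibble with columns `read_id`, `cell_barcode`,
#'   `chrom`, and a `blocks` list-column of aligned-block tibbles
#'   (see [emit_reads()] or [read_tagged_bam()]).
#' @param annotation Exon tibble of the known annotation
#'   (see [read_gtf_exons()]).
#' @param config A [pipeline_config()] list.
#' @param barcodes Optional barcode whitelist (defaults to the barcodes
#'   present in `reads`).
#' @return A `pipeline_result` list: `assignments` (tibble `read_id`,
#'   `cell_barcode`, `gene_id`, `isoform_id`, `mapping_score`,
#'   `priority_class`, `threshold_used`), `counts` (a `count_matrices`),
#'   `novel_isoforms` (tibble with membership list-column and footprints),
#'   `partitions`, `meta_genes`, `read_fate` (named counts summing to
#'   `nrow(reads)`) and `config`.
#' @export
run_pipeline <- function(reads, annotation, config = pipeline_config(),
                         barcodes = NULL) {
  reads <- tibble::as_tibble(reads)
  partitions <- partition_genes(annotation)

  read_spans <- tibble::tibble(
    idx = seq_len(nrow(reads)), chrom = reads$chrom,
    start = purrr::map_int(reads$blocks, ~ as.integer(min(.x$start))),
    end = purrr::map_int(reads$blocks, ~ as.integer(max(.x$end))))

  if (config$mode == "enhanced") {
    partitions <- purrr::map(partitions, function(p) {
      enhance_from_reads(p, reads, read_spans, config)
    })
  }
  meta <- group_meta_genes(partitions)
  gene_spans <- purrr::map_dfr(partitions, function(p) {
    sp <- partition_span(p)
    tibble::tibble(gene_id = p$gene_id, chrom = p$chrom,
                   start = sp[1], end = sp[2])
  })

  # --- per-gene encoding + known-isoform assignment --------------------------
  hit_chunks <- list()   # per gene: data frame of (read, gene) known hits
  novel_pool <- list()   # per gene: encodings of known-incompatible reads
  pool_score <- list()   # exonic mapping score of those reads, for gene choice
  umis <- reads$umi %||% rep(NA_character_, nrow(reads))
  for (g in names(partitions)) {
    p <- partitions[[g]]
    sp <- gene_spans[gene_spans$gene_id == g, ]
    hit <- which(read_spans$chrom == sp$chrom &
                   read_spans$start < sp$end & read_spans$end > sp$start)
    if (!length(hit)) next
    footprint_all <- merge_intervals(p$sub_exons)
    pool_encs <- list(); pool_sc <- numeric(0)
    g_idx <- integer(0); g_iso <- character(0)
    g_score <- numeric(0); g_thr <- numeric(0)
    for (i in hit) {
      enc <- encode_read(reads$blocks[[i]], p, read_id = reads$read_id[i],
                         cell_barcode = reads$cell_barcode[i],
                         umi = umis[i],
                         covered_min = config$covered_min,
                         skipped_max = config$skipped_max)
      cs <- assign_with_dynamic_threshold(enc, p, step = config$threshold_step,
                                          cap_bp = config$threshold_cap)
      if (length(cs$compatible_isoforms)) {
        iso <- if (cs$unique) cs$compatible_isoforms else break_ties(cs, enc, p)
        g_idx <- c(g_idx, i); g_iso <- c(g_iso, iso)
        g_score <- c(g_score, mapping_score(reads$blocks[[i]],
                                            transcript_footprint(p, iso)))
        g_thr <- c(g_thr, cs$threshold_used)
      } else {
        pool_encs[[length(pool_encs) + 1L]] <- enc
        pool_sc <- c(pool_sc, stats::setNames(
          mapping_score(reads$blocks[[i]], footprint_all), reads$read_id[i]))
      }
    }
    if (length(pool_encs)) {
      novel_pool[[g]] <- pool_encs
      pool_score[[g]] <- pool_sc
    }
    if (length(g_idx)) {
      hit_chunks[[g]] <- tibble::tibble(
        idx = g_idx, gene_id = g, isoform_id = g_iso,
        mapping_score = g_score, priority_class = "known",
        threshold_used = g_thr)
    }
  }
  known_hits <- dplyr::bind_rows(hit_chunks)

  # reads hitting several genes: keep the best (known class only here, so
  # max mapping score, ties to the lexicographically smaller gene)
  resolved_known <- if (nrow(known_hits)) {
    known_hits |>
      dplyr::mutate(read_id = reads$read_id[.data$idx],
                    cell_barcode = reads$cell_barcode[.data$idx]) |>
      dplyr::arrange(.data$idx, dplyr::desc(.data$mapping_score),
                     .data$gene_id) |>
      dplyr::distinct(.data$idx, .keep_all = TRUE)
  } else tibble::tibble()
  known_read_ids <- if (nrow(resolved_known)) resolved_known$read_id else character(0)

  # --- novel discovery per gene (reads with no known-compatible gene) --------
  novel_assign <- list(); novel_iso_tbl <- list()
  for (g in names(novel_pool)) {
    encs <- novel_pool[[g]]
    ids <- purrr::map_chr(encs, "read_id")
    keep <- !ids %in% known_read_ids
    # a read pooled under several genes goes to its best-scoring gene
    best_gene <- best_pool_gene(pool_score)
    keep <- keep & (best_gene[ids] == g)
    encs <- encs[keep]
    if (!length(encs)) next
    disc <- discover_novel_isoforms(encs, partitions[[g]],
                                    batch_size = config$batch_size,
                                    seed = config$louvain_seed,
                                    min_support = config$novel_min_support)
    novel_iso_tbl[[g]] <- dplyr::mutate(disc$isoforms, gene_id = g)
    assigned <- disc$assignments
    pending_ids <- purrr::map_chr(encs, "read_id")
    unhit <- setdiff(pending_ids, assigned$read_id)
    novel_assign[[g]] <- dplyr::bind_rows(
      dplyr::mutate(assigned, gene_id = g),
      tibble::tibble(read_id = unhit, isoform_id = NA_character_, gene_id = g))
  }
  novel_iso_tbl <- dplyr::bind_rows(novel_iso_tbl)
  novel_assign <- dplyr::bind_rows(novel_assign)

  # uncategorized novel isoforms: reads fall back to the gene's
  # uncategorized row (they still count toward the gene)
  if (nrow(novel_assign)) {
    categorized <- novel_iso_tbl$isoform_id[novel_iso_tbl$category == "novel"]
    novel_assign <- novel_assign |>
      dplyr::left_join(tibble::tibble(read_id = reads$read_id,
                                      cell_barcode = reads$cell_barcode),
                       by = "read_id") |>
      dplyr::mutate(
        priority_class = dplyr::if_else(
          !is.na(.data$isoform_id) & .data$isoform_id %in% categorized,
          "novel", "exon_only"),
        isoform_id = dplyr::if_else(.data$priority_class == "novel",
                                    .data$isoform_id, NA_character_),
        mapping_score = NA_real_, threshold_used = NA_real_)
  }

  assignments <- dplyr::bind_rows(resolved_known, novel_assign)
  if (nrow(assignments))
    assignments <- dplyr::select(assignments, "read_id", "cell_barcode",
                                 "gene_id", "isoform_id", "mapping_score",
                                 "priority_class",
                                 dplyr::any_of("threshold_used"))

  barcodes <- barcodes %||% sort(unique(reads$cell_barcode))
  counts <- build_matrices(assignments, barcodes,
                           genes = sort(names(partitions)))

  fate <- c(
    assigned_known = sum(assignments$priority_class == "known"),
    assigned_novel = sum(assignments$priority_class == "novel"),
    uncategorized = sum(assignments$priority_class == "exon_only"),
    dropped_no_gene = nrow(reads) - nrow(assignments))
  if (nrow(novel_iso_tbl)) {
    novel_iso_tbl$footprint <- purrr::map2(
      novel_iso_tbl$membership, novel_iso_tbl$gene_id,
      function(v, g) merge_intervals(
        partitions[[g]]$sub_exons[v == 1L, , drop = FALSE]))
  }
  structure(
    list(assignments = assignments, counts = counts,
         novel_isoforms = novel_iso_tbl, partitions = partitions,
         meta_genes = meta, read_fate = fate, config = config),
    class = "pipeline_result")
}

# which gene claims each pooled read (highest exonic mapping score,
# ties to the lexicographically smaller gene id)
best_pool_gene <- function(pool_score) {
  if (!length(pool_score)) return(character(0))
  df <- purrr::imap_dfr(pool_score, function(sc, g) {
    tibble::tibble(read_id = names(sc), gene_id = g, score = unname(sc))
  })
  df |>
    dplyr::arrange(.data$read_id, dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE) |>
    (\(d) stats::setNames(d$gene_id, d$read_id))()
}

# build a coverage track + junction table for one gene from the reads and
# refine its partition
enhance_from_reads <- function(p, reads, read_spans, config) {
  sp <- partition_span(p)
  hit <- which(read_spans$chrom == p$chrom &
                 read_spans$start < sp[2] & read_spans$end > sp[1])
  if (!length(hit)) return(p)
  region_s <- min(sp[1], min(read_spans$start[hit]))
  region_e <- max(sp[2], max(read_spans$end[hit]))
  width <- region_e - region_s
  delta <- numeric(width + 1L)
  jx_d <- numeric(0); jx_a <- numeric(0)
  for (i in hit) {
    b <- reads$blocks[[i]]
    i0 <- b$start - region_s + 1L
    i1 <- b$end - region_s + 1L
    for (r in seq_along(i0)) {          # +1 at block start, -1 past its end
      delta[i0[r]] <- delta[i0[r]] + 1
      delta[i1[r]] <- delta[i1[r]] - 1
    }
    nb <- length(i0)
    if (nb > 1L) {
      gap_d <- b$end[-nb]; gap_a <- b$start[-1]
      big <- (gap_a - gap_d) >= config$min_junction_gap
      jx_d <- c(jx_d, gap_d[big]); jx_a <- c(jx_a, gap_a[big])
    }
  }
  cov <- cumsum(delta)[seq_len(width)]
  junctions <- if (length(jx_d)) {
    key <- paste(jx_d, jx_a)
    tab <- table(key)
    first <- !duplicated(key)
    tibble::tibble(donor = jx_d[first], acceptor = jx_a[first],
                   reads = as.integer(tab[paste(jx_d, jx_a)[first]]))
  } else NULL
  enhance_partition(p, cov, junctions, cov_start = region_s,
                    cov_floor = config$cov_floor,
                    fold_change = config$fold_change,
                    window = config$window,
                    junction_min_reads = config$junction_min_reads)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  read fate:",
      paste(names(x$read_fate), x$read_fate, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  %d novel isoforms (%d categorized)\n",
              nrow(x$novel_isoforms),
              sum(x$novel_isoforms$category == "novel")))
  invisible(x)
}
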