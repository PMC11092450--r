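#' Refine a sub-exon partition with read coverage evidence
#'
#' Enhanced-annotation mode: keeps every annotation-derived boundary and adds
#' new sub-exon boundaries where the reads argue for them — (i) splice
#' positions observed in the data but absent from the annotation, and (ii)
#' positions where read depth changes sharply between adjacent windows.
#' Unannotated regions with depth at or above `cov_floor` become candidate
#' novel sub-exons (assigned to no annotated transcript); low-coverage
#' regions are never promoted.
#'
#' @param partition A `subexon_partition` from [build_partition()].
#' @param coverage Integer vector of per-base read depth. Its first element
#'   corresponds to genomic position `cov_start`.
#' @param junctions Data frame of observed splice junctions with columns
#'   `donor`, `acceptor` (0-based positions of the intron's half-open ends)
#'   and `reads` (supporting read count). May be `NULL`.
#' @param cov_start Genomic position of `coverage[1]` (0-based). Defaults to
#'   the partition span start.
#' @param cov_floor Minimum depth for a base to count as expressed
#'   (default 5 reads).
#' @param fold_change Depth ratio between adjacent windows that defines a
#'   "sharp" coverage change (default 5).
#' @param window Window width in bp for depth-change detection (default 10).
#' @param junction_min_reads Minimum read support for a novel splice
#'   boundary (default 2).
#' @return A refined `subexon_partition` with `source = "enhanced"`. With an
#'   empty coverage track the input is returned unchanged with a message.
#' @export
enhance_partition <- function(partition, coverage, junctions = NULL,
                              cov_start = NULL, cov_floor = 5,
                              fold_change = 5, window = 10L,
                              junction_min_reads = 2L) {
  if (is.null(coverage) || length(coverage) == 0L) {
    inform(paste0("empty coverage track for ", partition$gene_id,
                  "; returning the annotation-only partition"))
    return(partition)
  }
  span <- partition_span(partition)
  if (is.null(cov_start)) cov_start <- span[1]

  ann_bounds <- sort(unique(c(partition$sub_exons$start, partition$sub_exons$end)))
  jx_bounds <- junction_boundaries(junctions, junction_min_reads)
  step_bounds <- coverage_change_points(coverage, cov_start, fold_change, window)

  region_s <- min(span[1], cov_start)
  region_e <- max(span[2], cov_start + length(coverage))
  bounds <- sort(unique(c(ann_bounds, jx_bounds, step_bounds, region_s, region_e)))
  bounds <- bounds[bounds >= region_s & bounds <= region_e]

  cand <- tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1])
  in_annot <- purrr::map2_lgl(cand$start, cand$end, function(s, e) {
    any(partition$sub_exons$start <= s & partition$sub_exons$end >= e)
  })
  # outside the annotation, keep only intervals whose mean depth clears the floor
  expressed <- purrr::map2_lgl(cand$start, cand$end, function(s, e) {
    i0 <- max(s - cov_start + 1, 1); i1 <- min(e - cov_start, length(coverage))
    i0 <= i1 && mean(coverage[i0:i1]) >= cov_floor
  })
  keep <- cand[in_annot | expressed, , drop = FALSE]

  transcripts <- purrr::map(partition$transcripts, function(vec) {
    old <- partition$sub_exons[vec == 1L, , drop = FALSE]
    purrr::map2_int(keep$start, keep$end, function(s, e) {
      as.integer(any(old$start <= s & old$end >= e))
    })
  })

  new_partition(partition$gene_id, partition$chrom, partition$strand,
                keep, transcripts, source = "enhanced")
}

junction_boundaries <- function(junctions, min_reads) {
  if (is.null(junctions) || nrow(junctions) == 0L) return(integer(0))
  junctions <- tibble::as_tibble(junctions)
  if (!"reads" %in% names(junctions)) junctions$reads <- 1L
  ok <- junctions$reads >= min_reads
  sort(unique(c(junctions$donor[ok], junctions$acceptor[ok])))
}

# positions where mean depth of adjacent windows differs by >= fold_change;
# returns 0-based genomic positions of the change points
coverage_change_points <- function(coverage, cov_start, fold_change, window) {
  n <- length(coverage)
  if (n < 2L * window) return(integer(0))
  cs <- c(0, cumsum(as.numeric(coverage)))
  i <- seq_len(n - 2L * window + 1L)
  left <- (cs[i + window] - cs[i]) / window
  right <- (cs[i + 2L * window] - cs[i + window]) / window
  hi <- pmax(left, right)
  lo <- pmax(pmin(left, right), 0.5)
  pts <- cov_start + i[hi >= fold_change * lo] + window - 1L
  if (!length(pts)) return(integer(0))
  # collapse runs of adjacent candidate points to the steepest single base
  grp <- cumsum(c(1L, diff(pts) > 1L))
  vapply(split(pts, grp), function(run) {
    rel <- as.integer(run - cov_start)  # depth[rel] is left of the boundary
    jumps <- abs(log((coverage[pmin(rel + 1L, length(coverage))] + 0.5) /
                       (coverage[pmax(rel, 1L)] + 0.5)))
    as.integer(run[which.max(jumps)])
  }, integer(1), USE.NAMES = FALSE)
}

#' Infer a sub-exon partition from coverage alone
#'
#' Annotation-free mode: contiguous blocks of depth at or above `cov_floor`
#' become exons; observed splice junctions and sharp depth changes split
#' them into sub-exons. Blocks connected by junctions are assembled into one
#' inferred transcript; isolated blocks get their own. A synthetic gene
#' identifier is assigned.
#'
#' @inheritParams enhance_partition
#' @param chrom,strand Chromosome name and strand for the region.
#' @param gene_id Synthetic gene identifier (default derives from position).
#' @return A `subexon_partition` with `source = "annotation_free"`.
#' @export
build_partition_annotation_free <- function(coverage, cov_start = 0L,
                                            junctions = NULL,
                                            chrom = "chr?", strand = "+",
                                            gene_id = NULL,
                                            cov_floor = 5, fold_change = 5,
                                            window = 10L,
                                            junction_min_reads = 2L) {
  expressed <- coverage >= cov_floor
  if (!any(expressed)) abort("no expressed region", class = "isousage_no_signal")
  r <- rle(expressed)
  ends_rel <- cumsum(r$lengths)
  starts_rel <- ends_rel - r$lengths + 1L
  blocks <- tibble::tibble(
    start = cov_start + starts_rel[r$values] - 1L,
    end = cov_start + ends_rel[r$values])
  if (is.null(gene_id))
    gene_id <- sprintf("novelgene-%s-%d", chrom, blocks$start[1])

  jx <- junction_boundaries(junctions, junction_min_reads)
  steps <- coverage_change_points(coverage, cov_start, fold_change, window)
  bounds <- sort(unique(c(blocks$start, blocks$end, jx, steps)))
  cand <- tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1])
  inside <- purrr::map2_lgl(cand$start, cand$end, function(s, e) {
    any(blocks$start <= s & blocks$end >= e)
  })
  sub_exons <- cand[inside, , drop = FALSE]

  # connect blocks through junction (donor in block i, acceptor in block j)
  comp <- block_components(blocks, junctions, junction_min_reads)
  transcripts <- purrr::imap(split(seq_len(nrow(blocks)), comp), function(idx, key) {
    covered <- blocks[idx, , drop = FALSE]
    purrr::map2_int(sub_exons$start, sub_exons$end, function(s, e) {
      as.integer(any(covered$start <= s & covered$end >= e))
    })
  })
  names(transcripts) <- sprintf("%s-tx%s", gene_id, seq_along(transcripts))

  new_partition(gene_id, chrom, strand, sub_exons, transcripts,
                source = "annotation_free")
}

block_components <- function(blocks, junctions, min_reads) {
  n <- nrow(blocks)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    junctions <- tibble::as_tibble(junctions)
    if (!"reads" %in% names(junctions)) junctions$reads <- 1L
    junctions <- junctions[junctions$reads >= min_reads, , drop = FALSE]
    for (k in seq_len(nrow(junctions))) {
      i <- which(blocks$start < junctions$donor[k] & blocks$end >= junctions$donor[k])
      j <- which(blocks$start <= junctions$acceptor[k] & blocks$end > junctions$acceptor[k])
      if (length(i) == 1L && length(j) == 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}
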