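#' Build a sub-exon partition from annotated exons
#'
#' Decomposes all exons of one gene into non-overlapping sub-exons: maximal
#' intervals bounded by any two adjacent exon boundaries across the gene's
#' transcripts. Every annotated isoform is then an exact union of sub-exons,
#' recorded as a binary membership vector, so reads can be compared to
#' isoforms through a compatibility matrix rather than base-level overlap.
#'
#' Coordinates are 0-based half-open internally; [from_gtf()] converts the
#' 1-based inclusive GTF convention at the I/O boundary.
#'
#' @param exons A data frame with one row per exon and columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end` (0-based half-open).
#'   All rows must share one `gene_id`.
#' @return A `subexon_partition` object: a list with `gene_id`, `chrom`,
#'   `strand`, `sub_exons` (tibble with `start`, `end`), `transcripts`
#'   (named list of binary membership vectors over sub-exons) and `source`.
#' @examples
#' exons <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1", strand = "+",
#'   transcript_id = c("t1", "t2"),
#'   start = c(100, 100), end = c(200, 300))
#' build_partition(exons)
#' @export
build_partition <- function(exons) {
  exons <- as_exon_tbl(exons)
  if (nrow(exons) == 0L) abort("gene has zero exon records", class = "isousage_no_exons")
  if (length(unique(exons$gene_id)) != 1L)
    abort("all exon records must share one gene_id")
  if (any(exons$end <= exons$start))
    abort("malformed interval: end <= start", class = "isousage_bad_interval")

  # sub-exon boundaries = union of all distinct exon start/end positions
  bounds <- sort(unique(c(exons$start, exons$end)))
  cand <- tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1])
  # keep only intervals inside at least one exon (drop introns shared by all)
  inside <- purrr::map2_lgl(cand$start, cand$end, function(s, e) {
    any(exons$start <= s & exons$end >= e)
  })
  sub_exons <- cand[inside, ]

  transcripts <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::group_map(function(df, key) {
      member <- purrr::map2_int(sub_exons$start, sub_exons$end, function(s, e) {
        as.integer(any(df$start <= s & df$end >= e))
      })
      stats::setNames(list(member), key$transcript_id)
    }) |>
    purrr::flatten()
  transcripts <- transcripts[order(names(transcripts))]

  new_partition(
    gene_id = exons$gene_id[[1]],
    chrom = exons$chrom[[1]],
    strand = exons$strand[[1]],
    sub_exons = sub_exons,
    transcripts = transcripts,
    source = "annotation_only"
  )
}

new_partition <- function(gene_id, chrom, strand, sub_exons, transcripts, source) {
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         sub_exons = tibble::as_tibble(sub_exons[c("start", "end")]),
         transcripts = transcripts, source = source),
    class = "subexon_partition")
}

as_exon_tbl <- function(exons) {
  exons <- tibble::as_tibble(exons)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss)) abort(paste("missing exon columns:", paste(miss, collapse = ", ")))
  exons
}

#' @export
print.subexon_partition <- function(x, ...) {
  cat(sprintf("<subexon_partition> %s (%s%s) [%s]\n", x$gene_id, x$chrom,
              x$strand, x$source))
  cat(sprintf("  %d sub-exons spanning [%d, %d); %d transcripts\n",
              nrow(x$sub_exons), min(x$sub_exons$start), max(x$sub_exons$end),
              length(x$transcripts)))
  invisible(x)
}

#' Tidy a sub-exon partition into a long tibble
#'
#' @param x A `subexon_partition`.
#' @param ... Unused.
#' @return A tibble with one row per (sub-exon, transcript) pair and columns
#'   `gene_id`, `subexon`, `start`, `end`, `length`, `transcript_id`, `member`.
#' @export
tidy.subexon_partition <- function(x, ...) {
  base <- tibble::tibble(
    gene_id = x$gene_id, subexon = seq_len(nrow(x$sub_exons)),
    start = x$sub_exons$start, end = x$sub_exons$end,
    length = x$sub_exons$end - x$sub_exons$start)
  if (!length(x$transcripts)) return(dplyr::mutate(base, transcript_id = NA_character_, member = NA_integer_))
  purrr::imap_dfr(x$transcripts, function(vec, tx) {
    dplyr::mutate(base, transcript_id = tx, member = as.integer(vec))
  })
}

# sub-exon lengths (bp)
subexon_lengths <- function(partition) {
  partition$sub_exons$end - partition$sub_exons$start
}

# genomic span of a partition, 0-based half-open
partition_span <- function(partition) {
  c(min(partition$sub_exons$start), max(partition$sub_exons$end))
}

# exonic footprint of one transcript as an interval tibble
transcript_footprint <- function(partition, transcript_id) {
  vec <- partition$transcripts[[transcript_id]]
  if (is.null(vec)) abort(paste("unknown transcript:", transcript_id))
  partition$sub_exons[vec == 1L, ]
}
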