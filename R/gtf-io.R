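#' Read exon records from a GTF annotation
#'
#' Imports `exon` features and converts them to the internal 0-based
#' half-open convention. Parsing goes through rtracklayer; only the
#' `gene_id`/`transcript_id` attributes are retained.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), one row per exon.
#' @export
read_gtf_exons <- function(path) {
  need_pkg("rtracklayer")
  gr <- rtracklayer::import(path, format = "gtf", feature.type = "exon")
  tibble::tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,  # GTF is 1-based inclusive
    end = BiocGenerics::end(gr)
  )
}

#' Write exon records to a GTF file
#'
#' Inverse of [read_gtf_exons()]: emits gene/transcript/exon features with
#' 1-based inclusive coordinates. Used to export enhanced, annotation-free
#' and novel isoform models.
#'
#' @param exons Exon tibble as returned by [read_gtf_exons()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf_exons <- function(exons, path) {
  exons <- as_exon_tbl(exons)
  lines <- exons |>
    dplyr::arrange(.data$chrom, .data$gene_id, .data$transcript_id, .data$start) |>
    dplyr::mutate(
      line = sprintf(
        "%s\tisousage\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        .data$chrom, .data$start + 1L, .data$end, .data$strand,
        .data$gene_id, .data$transcript_id)) |>
    dplyr::pull("line")
  writeLines(lines, path)
  invisible(path)
}

#' Convert an exon tibble to per-gene sub-exon partitions
#'
#' @param exons Exon tibble ([read_gtf_exons()] output or equivalent).
#' @return Named list of `subexon_partition`, one per gene.
#' @export
partition_genes <- function(exons) {
  exons <- as_exon_tbl(exons)
  parts <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(~ build_partition(.x |> dplyr::mutate(gene_id = .y$gene_id)))
  stats::setNames(parts, purrr::map_chr(parts, "gene_id"))
}

# partition -> exon tibble (merging consecutive member sub-exons per transcript)
partition_to_exons <- function(partition) {
  purrr::imap_dfr(partition$transcripts, function(vec, tx) {
    se <- partition$sub_exons[vec == 1L, , drop = FALSE]
    if (nrow(se) == 0L) return(NULL)
    merged <- merge_intervals(se)
    tibble::tibble(gene_id = partition$gene_id, transcript_id = tx,
                   chrom = partition$chrom, strand = partition$strand,
                   start = merged$start, end = merged$end)
  })
}

# merge touching/overlapping intervals; accepts anything with $start/$end
merge_intervals <- function(iv) {
  s <- iv$start; e <- iv$end
  n <- length(s)
  if (n <= 1L)
    return(tibble::new_tibble(list(start = s, end = e), nrow = n))
  o <- order(s)
  s <- s[o]; e <- e[o]
  run_max <- cummax(e)
  new_run <- c(TRUE, s[-1] > run_max[-n])
  grp <- cumsum(new_run)
  tibble::new_tibble(
    list(start = s[new_run],
         end = as.vector(tapply(e, grp, max))),
    nrow = sum(new_run))
}
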