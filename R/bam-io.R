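#' Read a barcode-tagged BAM into the pipeline's read table
#'
#' Loads primary alignments (secondary and supplementary records are
#' skipped) together with their cell-barcode and UMI tags, and converts
#' each record's CIGAR into aligned blocks on the reference. Tag names
#' default to the CB/UB convention of 10x-style pipelines and are
#' configurable for other vendors.
#'
#' @param path Path to an indexed, coordinate-sorted BAM file.
#' @param cb_tag,umi_tag BAM tag names for cell barcode and UMI
#'   (defaults `"CB"`, `"UB"`).
#' @return Tibble with columns `read_id`, `cell_barcode`, `umi`, `chrom`,
#'   `strand` and a `blocks` list-column (0-based half-open intervals),
#'   ready for [run_pipeline()].
#' @export
read_tagged_bam <- function(path, cb_tag = "CB", umi_tag = "UB") {
  need_pkg("GenomicAlignments")
  need_pkg("Rsamtools")
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = "qname",
                                   tag = c(cb_tag, umi_tag))
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  mc <- S4Vectors::mcols(ga)
  blocks <- GenomicAlignments::grglist(ga, order.as.in.query = FALSE)
  starts <- BiocGenerics::start(blocks)
  ends <- BiocGenerics::end(blocks)
  tibble::tibble(
    read_id = as.character(mc$qname),
    cell_barcode = as.character(mc[[cb_tag]]),
    umi = as.character(mc[[umi_tag]]),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(BiocGenerics::strand(ga)),
    blocks = purrr::map2(as.list(starts), as.list(ends), function(s, e) {
      tibble::tibble(start = as.integer(s) - 1L, end = as.integer(e))
    }))
}

#' Write a read table as a SAM file
#'
#' Emits valid spliced alignments (blocks joined by `N` CIGAR operations,
#' `*` sequence) with CB/UB tags, so simulated read tables can round-trip
#' through samtools/Rsamtools as tagged BAMs.
#'
#' @param reads Read tibble with `read_id`, `cell_barcode`, `umi`, `chrom`,
#'   `strand` and a `blocks` list-column.
#' @param path Output SAM path.
#' @param seqlengths Optional named vector of reference lengths for the
#'   header (derived from the reads when absent).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, seqlengths = NULL) {
  reads <- tibble::as_tibble(reads)
  if (is.null(seqlengths)) {
    seqlengths <- reads |>
      dplyr::mutate(mx = purrr::map_int(.data$blocks, ~ as.integer(max(.x$end)))) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(len = max(.data$mx) + 1000L) |>
      (\(d) stats::setNames(d$len, d$chrom))()
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                      as.integer(seqlengths)))
  ord <- order(reads$chrom, purrr::map_int(reads$blocks,
                                           ~ as.integer(min(.x$start))))
  reads <- reads[ord, ]
  recs <- purrr::pmap_chr(
    list(reads$read_id, reads$cell_barcode, reads$umi, reads$chrom,
         reads$strand, reads$blocks),
    function(id, cb, umi, chrom, strand, blocks) {
      lens <- blocks$end - blocks$start
      gaps <- if (nrow(blocks) > 1) blocks$start[-1] - blocks$end[-nrow(blocks)]
      else integer(0)
      cigar <- paste0(paste0(lens[1], "M"),
                      if (length(gaps))
                        paste0(gaps, "N", lens[-1], "M", collapse = "")
                      else "", collapse = "")
      flag <- if (strand == "-") 16L else 0L
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tCB:Z:%s\tUB:Z:%s",
              id, flag, chrom, blocks$start[1] + 1L, cigar, cb, umi)
    })
  writeLines(c(header, recs), path)
  invisible(path)
}
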