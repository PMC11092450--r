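#' Encode a read's spliced alignment against a gene's sub-exons
#'
#' For each sub-exon the fraction of its bases covered by the read's aligned
#' blocks is computed and discretized: `covered` if the fraction exceeds
#' 0.6, `skipped` if it does not exceed 0.2 while the sub-exon lies inside
#' the read's aligned genomic span, `ambiguous` in between, and `unobserved`
#' for sub-exons outside the span (truncation/degradation tolerance: they
#' are never treated as skipped).
#'
#' @param blocks Data frame of the read's aligned blocks with columns
#'   `start`, `end` (0-based half-open, sorted, on the partition's
#'   chromosome).
#' @param partition A `subexon_partition`.
#' @param read_id,cell_barcode,umi Read metadata carried through.
#' @param covered_min Coverage fraction above which a sub-exon is covered
#'   (default 0.6).
#' @param skipped_max Coverage fraction at or below which an in-span
#'   sub-exon is skipped (default 0.2).
#' @return A `read_encoding` object: list with `read_id`, `cell_barcode`,
#'   `umi`, `gene_id`, `states` (character vector), `coverage_fractions`,
#'   `aligned_span`, `aligned_bases`.
#' @export
encode_read <- function(blocks, partition, read_id = NA_character_,
                        cell_barcode = NA_character_, umi = NA_character_,
                        covered_min = 0.6, skipped_max = 0.2) {
  bs <- blocks$start; be <- blocks$end
  stopifnot(!is.null(bs), !is.null(be))
  span <- c(min(bs), max(be))
  gspan <- partition_span(partition)
  if (span[2] <= gspan[1] || span[1] >= gspan[2])
    abort("read does not overlap the gene span", class = "isousage_no_overlap")

  se <- partition$sub_exons
  len <- se$end - se$start
  overlap <- colSums(pmax(outer(be, se$end, pmin) - outer(bs, se$start, pmax), 0))
  frac <- overlap / len
  in_span <- se$start >= span[1] & se$end <= span[2]
  states <- rep("ambiguous", length(frac))
  states[frac > covered_min] <- "covered"
  low <- frac <= skipped_max & !(frac > covered_min)
  states[low & in_span] <- "skipped"
  states[low & !in_span] <- "unobserved"  # span-edge truncation stays neutral

  structure(
    list(read_id = read_id, cell_barcode = cell_barcode, umi = umi,
         gene_id = partition$gene_id, states = states,
         coverage_fractions = frac, aligned_span = span,
         aligned_bases = sum(be - bs)),
    class = "read_encoding")
}

#' @export
print.read_encoding <- function(x, ...) {
  code <- c(covered = "1", skipped = "0", ambiguous = "?", unobserved = ".")
  cat(sprintf("<read_encoding> %s on %s: %s\n", x$read_id, x$gene_id,
              paste(code[x$states], collapse = "")))
  invisible(x)
}

#' Filter isoforms compatible with a read encoding
#'
#' An isoform is excluded iff, restricted to sub-exons of length at least
#' `min_subexon_len`, the read covers a sub-exon the isoform lacks or skips
#' a sub-exon the isoform contains. Ambiguous and unobserved sub-exons never
#' exclude.
#'
#' @param encoding A `read_encoding`.
#' @param partition The matching `subexon_partition`.
#' @param min_subexon_len Sub-exons shorter than this (bp) are ignored in
#'   the compatibility decision (default 0: all sub-exons are informative).
#' @param transcripts Optional named list of membership vectors to filter
#'   against (defaults to the partition's annotated transcripts).
#' @return Character vector of compatible transcript ids (possibly empty,
#'   in which case the read is a candidate novel read).
#' @export
filter_compatible <- function(encoding, partition, min_subexon_len = 0,
                              transcripts = NULL) {
  stopifnot(min_subexon_len >= 0)
  transcripts <- transcripts %||% partition$transcripts
  tm <- transcript_matrix(transcripts)
  keep <- compat_fast(encoding$states, subexon_lengths(partition), tm,
                      min_subexon_len)
  rownames(tm)[keep]
}

# transcripts as a K x m binary matrix (rows named)
transcript_matrix <- function(transcripts) {
  matrix(unlist(transcripts, use.names = FALSE),
         nrow = length(transcripts), byrow = TRUE,
         dimnames = list(names(transcripts), NULL))
}

# vectorized exclusion rule over all transcripts at once
compat_fast <- function(states, lens, tm, min_len) {
  use <- lens >= min_len
  covered <- use & states == "covered"
  skipped <- use & states == "skipped"
  viol <- ((1 - tm) %*% covered) + (tm %*% skipped)
  as.vector(viol == 0)
}

#' Assign a read to isoforms with gene-specific dynamic thresholding
#'
#' Starting from a minimum informative sub-exon length of 0 bp, the
#' compatibility filter is applied; if more than one isoform survives the
#' threshold is raised in 10 bp steps up to `min(80, mean sub-exon length)`
#' so that small, error-prone sub-exons stop vetoing, stopping at the first
#' unique mapping. If no threshold gives a unique mapping the first
#' non-empty (multiple) mapping encountered is returned.
#'
#' @inheritParams filter_compatible
#' @param step Threshold increment in bp (default 10).
#' @param cap_bp Hard cap on the threshold in bp (default 80).
#' @return A `compatibility_set`: list with `read_id`,
#'   `compatible_isoforms` (character, possibly empty), `threshold_used`,
#'   and `unique` (logical).
#' @export
assign_with_dynamic_threshold <- function(encoding, partition,
                                          transcripts = NULL,
                                          step = 10, cap_bp = 80) {
  lens <- subexon_lengths(partition)
  cap <- min(cap_bp, mean(lens))
  thresholds <- seq(0, cap, by = step)
  tm <- transcript_matrix(transcripts %||% partition$transcripts)
  first_nonempty <- NULL
  for (thr in thresholds) {
    compat <- rownames(tm)[compat_fast(encoding$states, lens, tm, thr)]
    if (length(compat) == 1L) {
      return(new_compat(encoding$read_id, compat, thr, TRUE))
    }
    if (length(compat) > 1L && is.null(first_nonempty)) {
      first_nonempty <- list(compat = compat, thr = thr)
    }
  }
  if (!is.null(first_nonempty)) {
    return(new_compat(encoding$read_id, first_nonempty$compat,
                      first_nonempty$thr, FALSE))
  }
  new_compat(encoding$read_id, character(0), max(thresholds), FALSE)
}

new_compat <- function(read_id, isoforms, threshold, unique) {
  structure(list(read_id = read_id, compatible_isoforms = isoforms,
                 threshold_used = threshold, unique = unique),
            class = "compatibility_set")
}

#' Break ties among multiple compatible isoforms
#'
#' Picks the isoform with the fewest unmapped exons — member sub-exons the
#' read does not cover — with remaining ties broken by lexicographic
#' transcript id.
#'
#' @param compatible Character vector of candidate transcript ids
#'   (length at least 2), or a `compatibility_set`.
#' @inheritParams filter_compatible
#' @return A single transcript id.
#' @export
break_ties <- function(compatible, encoding, partition, transcripts = NULL) {
  if (inherits(compatible, "compatibility_set"))
    compatible <- compatible$compatible_isoforms
  transcripts <- transcripts %||% partition$transcripts
  covered <- encoding$states == "covered"
  unmapped <- vapply(transcripts[compatible],
                     function(vec) sum(vec == 1L & !covered), numeric(1))
  ord <- order(unmapped, names(unmapped))
  names(unmapped)[ord[1]]
}
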