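#' Mapping score of a read against an isoform footprint
#'
#' The fraction of the read's aligned bases that fall inside the isoform's
#' exonic footprint, used to rank competing gene assignments for ambiguous
#' (overlapping-gene or chimeric) reads.
#'
#' @param blocks Data frame of the read's aligned blocks (`start`, `end`,
#'   0-based half-open).
#' @param footprint Data frame of the isoform's exonic intervals (`start`,
#'   `end`), e.g. from the member sub-exons of a partition.
#' @return A fraction in \[0, 1\].
#' @export
mapping_score <- function(blocks, footprint) {
  bs <- blocks$start; be <- blocks$end
  total <- sum(be - bs)
  if (total <= 0) abort("read has zero aligned bases")
  footprint <- merge_intervals(footprint)   # tolerate overlapping intervals
  inside <- sum(pmax(outer(be, footprint$end, pmin) -
                       outer(bs, footprint$start, pmax), 0))
  inside / total
}

#' Resolve a read mapped to several genes
#'
#' Candidates are ranked first by priority class (`known` over `novel` over
#' `exon_only`), then by mapping score, then by lexicographic gene id.
#'
#' @param candidates Tibble with one row per candidate gene and columns
#'   `read_id`, `cell_barcode`, `gene_id`, `isoform_id`, `mapping_score`,
#'   `priority_class`.
#' @return The single winning row.
#' @export
resolve_multi_gene <- function(candidates) {
  stopifnot(nrow(candidates) >= 1L)
  rank <- c(known = 1L, novel = 2L, exon_only = 3L)
  candidates |>
    dplyr::arrange(rank[.data$priority_class], dplyr::desc(.data$mapping_score),
                   .data$gene_id) |>
    dplyr::slice(1)
}

#' Build gene- and transcript-level count matrices
#'
#' One increment per resolved read at (feature, barcode). Reads assigned to
#' an uncategorized or exon-only feature count toward the gene total and the
#' gene's `<gene>-uncategorized` transcript row, so transcript counts
#' conserve gene counts exactly.
#'
#' @param assignments Tibble with columns `read_id`, `cell_barcode`,
#'   `gene_id`, `isoform_id` (use `NA` or `"uncategorized"` for reads with
#'   no categorized isoform).
#' @param barcodes Character vector: the barcode whitelist (column order of
#'   the matrices). Reads with other barcodes are dropped and counted.
#' @param genes Optional character vector fixing gene row order.
#' @return A `count_matrices` object: list with sparse `gene_counts`
#'   (genes x cells), `transcript_counts` (transcripts x cells), a
#'   `features` tibble (`feature_id`, `gene_id`, `feature_type`), `barcodes`
#'   and `dropped` (number of non-whitelist reads).
#' @export
build_matrices <- function(assignments, barcodes, genes = NULL) {
  stopifnot(length(barcodes) > 0L)
  assignments <- tibble::as_tibble(assignments)
  ok <- assignments$cell_barcode %in% barcodes
  dropped <- sum(!ok)
  if (dropped > 0)
    inform(sprintf("%d reads dropped: barcode not in whitelist", dropped))
  assignments <- assignments[ok, , drop = FALSE]
  if (nrow(assignments) == 0L) {
    genes <- genes %||% character(0)
    zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(length(genes), length(barcodes)),
                                 dimnames = list(genes, barcodes))
    return(structure(
      list(gene_counts = zero,
           transcript_counts = zero[integer(0), , drop = FALSE],
           features = tibble::tibble(gene_id = character(),
                                     feature_id = character(),
                                     feature_type = character()),
           barcodes = barcodes, dropped = dropped),
      class = "count_matrices"))
  }
  assignments$isoform_id <- dplyr::if_else(
    is.na(assignments$isoform_id) |
      assignments$isoform_id %in% c("uncategorized", "exon-only"),
    paste0(assignments$gene_id, "-uncategorized"), assignments$isoform_id)

  genes <- genes %||% sort(unique(assignments$gene_id))
  feats <- assignments |>
    dplyr::distinct(.data$gene_id, .data$isoform_id) |>
    dplyr::mutate(feature_type = dplyr::case_when(
      grepl("-uncategorized$", .data$isoform_id) ~ "uncategorized",
      grepl("-novel-\\d+$", .data$isoform_id) ~ "novel",
      TRUE ~ "known")) |>
    dplyr::arrange(.data$gene_id, .data$feature_type, .data$isoform_id) |>
    dplyr::rename(feature_id = "isoform_id")

  tally <- function(rows, ids) {
    i <- match(rows, ids)
    j <- match(assignments$cell_barcode, barcodes)
    Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                         dims = c(length(ids), length(barcodes)),
                         dimnames = list(ids, barcodes))
  }
  structure(
    list(gene_counts = tally(assignments$gene_id, genes),
         transcript_counts = tally(assignments$isoform_id, feats$feature_id),
         features = feats, barcodes = barcodes, dropped = dropped),
    class = "count_matrices")
}

#' @export
print.count_matrices <- function(x, ...) {
  cat(sprintf("<count_matrices> %d genes x %d cells; %d transcript rows (%d reads, %d dropped)\n",
              nrow(x$gene_counts), length(x$barcodes),
              nrow(x$transcript_counts), sum(x$gene_counts), x$dropped))
  invisible(x)
}

#' Write count matrices as MatrixMarket triplets
#'
#' Emits the 10x-style triplet (`matrix.mtx.gz`, `barcodes.tsv.gz`,
#' `features.tsv.gz`) under `<dir>/gene/` and `<dir>/transcript/`.
#'
#' @param counts A `count_matrices` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrices <- function(counts, dir) {
  write_level <- function(mat, feats, sub) {
    d <- file.path(dir, sub)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    mm <- file.path(d, "matrix.mtx")
    Matrix::writeMM(mat, mm)
    gz_move(mm)
    con <- gzfile(file.path(d, "barcodes.tsv.gz"), "w")
    writeLines(counts$barcodes, con); close(con)
    con <- gzfile(file.path(d, "features.tsv.gz"), "w")
    writeLines(feats, con); close(con)
  }
  write_level(counts$gene_counts, rownames(counts$gene_counts), "gene")
  write_level(counts$transcript_counts,
              paste(counts$features$feature_id, counts$features$gene_id,
                    counts$features$feature_type, sep = "\t"),
              "transcript")
  invisible(dir)
}

gz_move <- function(path) {
  raw_lines <- readLines(path)
  con <- gzfile(paste0(path, ".gz"), "w")
  writeLines(raw_lines, con); close(con)
  unlink(path)
}

#' Read count matrices written by [write_count_matrices()]
#'
#' @param dir Directory holding `gene/` and `transcript/` triplets.
#' @return A `count_matrices` object.
#' @export
read_count_matrices <- function(dir) {
  read_level <- function(sub) {
    d <- file.path(dir, sub)
    mat <- Matrix::readMM(gzfile(file.path(d, "matrix.mtx.gz")))
    barcodes <- readLines(gzfile(file.path(d, "barcodes.tsv.gz")))
    feats <- readLines(gzfile(file.path(d, "features.tsv.gz")))
    list(mat = mat, barcodes = barcodes, feats = feats)
  }
  g <- read_level("gene")
  t <- read_level("transcript")
  fparts <- strsplit(t$feats, "\t", fixed = TRUE)
  feats <- tibble::tibble(
    feature_id = purrr::map_chr(fparts, 1),
    gene_id = purrr::map_chr(fparts, 2),
    feature_type = purrr::map_chr(fparts, 3))
  norm_mat <- function(m) {  # undo writeMM's symmetric/pattern encodings
    m <- methods::as(m, "generalMatrix")
    m <- methods::as(m, "dMatrix")
    methods::as(m, "CsparseMatrix")
  }
  gm <- norm_mat(g$mat)
  tm <- norm_mat(t$mat)
  dimnames(gm) <- list(g$feats, g$barcodes)
  dimnames(tm) <- list(feats$feature_id, t$barcodes)
  structure(list(gene_counts = gm, transcript_counts = tm, features = feats,
                 barcodes = g$barcodes, dropped = NA_integer_),
            class = "count_matrices")
}

#' Local relative junction abundance (LRJA)
#'
#' Reads supporting a specific splice junction divided by reads supporting
#' any junction involving the same upstream exon; used to corroborate a
#' novel junction across platforms.
#'
#' @param junction_reads Reads supporting the junction of interest.
#' @param upstream_exon_junction_reads Reads supporting any junction that
#'   involves the upstream exon (must be at least `junction_reads`).
#' @return The ratio, or `NA` for 0/0.
#' @export
lrja <- function(junction_reads, upstream_exon_junction_reads) {
  stopifnot(junction_reads >= 0, upstream_exon_junction_reads >= 0)
  if (upstream_exon_junction_reads < junction_reads)
    abort("denominator smaller than numerator")
  if (upstream_exon_junction_reads == 0) return(NA_real_)
  junction_reads / upstream_exon_junction_reads
}
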