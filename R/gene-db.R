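#' Group overlapping genes into meta-genes
#'
#' Genes whose genomic spans overlap (transitively, regardless of strand)
#' are grouped into one meta-gene, the unit within which reads compete for
#' gene assignment. Singleton genes form singleton meta-genes.
#'
#' @param partitions Named list of `subexon_partition` objects.
#' @return A tibble with one row per gene: `meta_id`, `gene_id`, `chrom`,
#'   `span_start`, `span_end` (the meta-gene's merged span).
#' @export
group_meta_genes <- function(partitions) {
  if (!length(partitions)) {
    return(tibble::tibble(meta_id = character(), gene_id = character(),
                          chrom = character(), span_start = integer(),
                          span_end = integer()))
  }
  spans <- purrr::map_dfr(partitions, function(p) {
    sp <- partition_span(p)
    tibble::tibble(gene_id = p$gene_id, chrom = p$chrom,
                   start = sp[1], end = sp[2])
  })
  spans |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(component = cumsum(.data$start >= dplyr::lag(
      cummax(as.numeric(.data$end)), default = -Inf))) |>
    dplyr::group_by(.data$chrom, .data$component) |>
    dplyr::mutate(meta_id = sprintf("meta-%s-%d", .data$chrom[1], min(.data$start)),
                  span_start = min(.data$start), span_end = max(.data$end)) |>
    dplyr::ungroup() |>
    dplyr::select("meta_id", "gene_id", "chrom", "span_start", "span_end") |>
    dplyr::arrange(.data$chrom, .data$span_start, .data$gene_id)
}

#' Build a gene database
#'
#' Bundles per-gene sub-exon partitions, the meta-gene grouping, and the
#' build parameters into one serializable object.
#'
#' @param partitions Named list of `subexon_partition` objects (see
#'   [partition_genes()]).
#' @param build_params Named list of the thresholds used to build the
#'   partitions (recorded verbatim).
#' @return A `gene_database` object.
#' @export
gene_database <- function(partitions, build_params = list()) {
  partitions <- partitions[order(names(partitions))]
  structure(
    list(version = 1L, partitions = partitions,
         meta_genes = group_meta_genes(partitions),
         build_params = build_params),
    class = "gene_database")
}

#' @export
print.gene_database <- function(x, ...) {
  cat(sprintf("<gene_database> v%d: %d genes, %d meta-genes\n", x$version,
              length(x$partitions), length(unique(x$meta_genes$meta_id))))
  invisible(x)
}

#' Serialize / restore a gene database
#'
#' The database round-trips losslessly through a versioned JSON container
#' with deterministic key order, so identical inputs produce byte-identical
#' files.
#'
#' @param db A `gene_database`.
#' @param path Output (or input) file path.
#' @return `write_gene_database()` returns `path` invisibly;
#'   `read_gene_database()` returns the restored `gene_database`.
#' @export
write_gene_database <- function(db, path) {
  stopifnot(inherits(db, "gene_database"))
  payload <- list(
    version = db$version,
    build_params = db$build_params,
    meta_genes = as.data.frame(db$meta_genes),
    partitions = purrr::map(db$partitions, function(p) {
      list(gene_id = p$gene_id, chrom = p$chrom, strand = p$strand,
           source = p$source,
           sub_exons = as.data.frame(p$sub_exons),
           transcripts = purrr::map(p$transcripts, as.integer))
    }))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_gene_database
#' @export
read_gene_database <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  partitions <- purrr::map(payload$partitions, function(p) {
    new_partition(p$gene_id, p$chrom, p$strand,
                  tibble::as_tibble(p$sub_exons),
                  purrr::map(p$transcripts, as.integer),
                  source = p$source)
  })
  db <- gene_database(partitions,
                      build_params = payload$build_params %||% list())
  db$version <- payload$version
  db
}
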