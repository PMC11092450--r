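#' Build a read-read similarity graph for novel reads
#'
#' Nodes are novel reads (at most `batch_size`, taken in order of aligned
#' start position); the edge weight between two reads is the fraction of
#' jointly informative sub-exons (covered or skipped in both reads) on
#' which their states agree. Pairs with no jointly informative sub-exon get
#' no edge.
#'
#' @param encodings List of `read_encoding` objects for one gene's novel
#'   reads.
#' @param batch_size Maximum number of reads per graph (default 1500).
#' @return A list with `graph` (an igraph object, possibly with 0 nodes),
#'   `read_ids` (nodes, in batch order) and `remaining` (encodings left for
#'   later batches).
#' @export
build_read_graph <- function(encodings, batch_size = 1500L) {
  ord <- order(purrr::map_dbl(encodings, ~ .x$aligned_span[1]))
  encodings <- encodings[ord]
  batch <- utils::head(encodings, batch_size)
  remaining <- if (length(encodings) > batch_size)
    encodings[-seq_len(batch_size)] else list()
  if (length(batch) < 2L) {
    return(list(graph = igraph::make_empty_graph(n = 0, directed = FALSE),
                read_ids = character(0), remaining = remaining))
  }
  ids <- purrr::map_chr(batch, "read_id")
  states <- do.call(rbind, purrr::map(batch, "states"))
  n <- length(batch)
  cov <- (states == "covered") * 1
  skp <- (states == "skipped") * 1
  inf <- cov + skp
  joint <- tcrossprod(inf)                    # jointly informative counts
  agree <- tcrossprod(cov) + tcrossprod(skp)  # agreements among those
  w <- ifelse(joint > 0, agree / joint, NA_real_)
  w[lower.tri(w, diag = TRUE)] <- NA_real_
  keep <- which(!is.na(w) & w > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(keep)) {
    g <- igraph::add_edges(g, as.vector(t(keep)))
    igraph::E(g)$weight <- w[keep]
  }
  list(graph = g, read_ids = ids, remaining = remaining)
}

#' Detect read communities with the Louvain method
#'
#' Weighted-modularity Louvain clustering at resolution 1 under a fixed
#' RNG seed, so identical graphs give identical partitions.
#'
#' @param graph An igraph object (from [build_read_graph()]).
#' @param seed Integer RNG seed (default 42).
#' @param resolution Modularity resolution parameter (default 1).
#' @return Integer vector of community ids, named by read id.
#' @export
detect_communities <- function(graph, seed = 42L, resolution = 1) {
  stopifnot(igraph::vcount(graph) > 0L)
  comm <- withr_seed(seed, igraph::cluster_louvain(graph, resolution = resolution))
  stats::setNames(igraph::membership(comm), igraph::V(graph)$name)
}

# run expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Consensus sub-exon membership of a read community
#'
#' Per sub-exon, membership is 1 when `covered` is at least as frequent as
#' `skipped` among the community's informative reads (ties go to
#' inclusion, since skips are more often truncation/under-alignment
#' artifacts than real exclusions); sub-exons informative in no read take
#' membership 0.
#'
#' @param community List of `read_encoding` objects.
#' @return Integer membership vector over the gene's sub-exons.
#' @export
consensus_annotation <- function(community) {
  stopifnot(length(community) > 0L)
  states <- do.call(rbind, purrr::map(community, "states"))
  n_cov <- colSums(states == "covered")
  n_skip <- colSums(states == "skipped")
  as.integer(n_cov > 0 & n_cov >= n_skip)
}

#' Remap novel reads to candidate isoforms and prune redundancy
#'
#' Candidates identical to an annotated isoform or to each other are
#' dropped, novel reads are remapped to the remaining candidates with the
#' relaxed small-sub-exon threshold `min(80, mean sub-exon length)`
#' (encouraging multiple mappings), and candidates are scanned in ascending
#' support order, removing any whose every read also maps to another
#' retained candidate or to an annotated isoform.
#'
#' @param novel_reads List of `read_encoding` objects (novel reads).
#' @param candidates Named list of candidate membership vectors.
#' @param partition The gene's `subexon_partition`.
#' @return List with `isoforms` (named list of retained membership
#'   vectors), `assignments` (tibble `read_id`, `isoform_id`) and
#'   `unassigned` (encodings mapping to no retained candidate).
#' @export
remap_and_prune <- function(novel_reads, candidates, partition) {
  ann <- partition$transcripts
  # drop duplicates of annotated isoforms, then duplicates among candidates
  is_dup_ann <- purrr::map_lgl(candidates, function(v) {
    any(purrr::map_lgl(ann, ~ identical(as.integer(.x), as.integer(v))))
  })
  candidates <- candidates[!is_dup_ann]
  if (length(candidates)) {
    keys <- purrr::map_chr(candidates, paste, collapse = "")
    candidates <- candidates[!duplicated(keys)]
  }
  if (!length(candidates)) {
    return(list(isoforms = list(),
                assignments = tibble::tibble(read_id = character(),
                                             isoform_id = character()),
                unassigned = novel_reads))
  }
  relaxed <- min(80, mean(subexon_lengths(partition)))
  hits <- purrr::map(novel_reads, function(enc) {
    filter_compatible(enc, partition, min_subexon_len = relaxed,
                      transcripts = candidates)
  })
  ann_hits <- purrr::map(novel_reads, function(enc) {
    filter_compatible(enc, partition, min_subexon_len = relaxed,
                      transcripts = ann)
  })
  support <- purrr::map_int(names(candidates), function(id) {
    sum(purrr::map_lgl(hits, ~ id %in% .x))
  })
  names(support) <- names(candidates)

  retained <- names(candidates)
  for (id in names(sort(support))) {  # ascending support
    others <- setdiff(retained, id)
    idx <- which(purrr::map_lgl(hits, ~ id %in% .x))
    if (!length(idx)) { retained <- others; next }
    redundant <- all(purrr::map_lgl(idx, function(i) {
      length(intersect(hits[[i]], others)) > 0L || length(ann_hits[[i]]) > 0L
    }))
    if (redundant) retained <- others
  }

  isoforms <- candidates[retained]
  assign_one <- function(i) {
    compat <- intersect(hits[[i]], retained)
    if (!length(compat)) return(NA_character_)
    if (length(compat) == 1L) return(compat)
    break_ties(compat, novel_reads[[i]], partition, transcripts = isoforms)
  }
  calls <- purrr::map_chr(seq_along(novel_reads), assign_one)
  list(
    isoforms = isoforms,
    assignments = tibble::tibble(
      read_id = purrr::map_chr(novel_reads, "read_id"),
      isoform_id = calls)[!is.na(calls), ],
    unassigned = novel_reads[is.na(calls)])
}

#' Categorize a novel isoform by pseudo-bulk read support
#'
#' @param support_reads Read count supporting the isoform with all cells
#'   pooled.
#' @param min_reads Support strictly above this is required to call the
#'   isoform novel (default 20).
#' @return `"novel"` or `"uncategorized"`.
#' @export
categorize_support <- function(support_reads, min_reads = 20L) {
  ifelse(support_reads > min_reads, "novel", "uncategorized")
}

#' Discover novel isoforms for one gene
#'
#' Full pseudo-bulk novel-isoform stage: batches novel reads (ordered by
#' aligned start) into similarity graphs, Louvain-clusters each batch,
#' derives consensus membership vectors, remaps and prunes, and repeats on
#' still-unassigned reads until no further graph can be built. Isoform ids
#' are `<gene>-novel-N` in decreasing support order.
#'
#' @param novel_reads List of `read_encoding` objects classified as novel.
#' @param partition The gene's `subexon_partition`.
#' @param batch_size Reads per graph (default 1500).
#' @param seed Louvain RNG seed (default 42).
#' @param min_support Support above which an isoform is `novel` rather than
#'   `uncategorized` (default 20).
#' @return List with `isoforms` (tibble `isoform_id`, `support_reads`,
#'   `category`, plus a `membership` list-column) and `assignments` (tibble
#'   `read_id`, `isoform_id`).
#' @export
discover_novel_isoforms <- function(novel_reads, partition,
                                    batch_size = 1500L, seed = 42L,
                                    min_support = 20L) {
  all_iso <- list()
  all_assign <- list()
  pending <- novel_reads
  batch_i <- 0L
  repeat {
    n_before <- length(pending)
    batch_i <- batch_i + 1L
    gb <- build_read_graph(pending, batch_size)
    if (igraph::vcount(gb$graph) < 2L) break
    membership <- detect_communities(gb$graph, seed = seed)
    batch <- pending[match(gb$read_ids, purrr::map_chr(pending, "read_id"))]
    cands <- purrr::map(split(seq_along(batch), membership[gb$read_ids]),
                        ~ consensus_annotation(batch[.x]))
    names(cands) <- sprintf("b%d.cand%d", batch_i, seq_along(cands))
    res <- remap_and_prune(batch, cands, partition)
    all_iso <- c(all_iso, res$isoforms)
    all_assign <- c(all_assign, list(res$assignments))
    pending <- c(res$unassigned, gb$remaining)
    if (!length(pending) || length(pending) >= n_before) break
  }
  assignments <- dplyr::bind_rows(all_assign)
  if (!length(all_iso)) {
    return(list(isoforms = tibble::tibble(isoform_id = character(),
                                          support_reads = integer(),
                                          category = character(),
                                          membership = list()),
                assignments = tibble::tibble(read_id = character(),
                                             isoform_id = character())))
  }
  # merge duplicate vectors across batches and rename by support
  keys <- purrr::map_chr(all_iso, paste, collapse = "")
  canonical <- stats::setNames(names(all_iso)[!duplicated(keys)],
                               keys[!duplicated(keys)])
  remap_id <- stats::setNames(canonical[keys], names(all_iso))
  assignments$isoform_id <- unname(remap_id[assignments$isoform_id])
  uniq <- all_iso[!duplicated(keys)]

  support <- assignments |> dplyr::count(.data$isoform_id)
  support_n <- stats::setNames(rep(0L, length(uniq)), names(uniq))
  support_n[support$isoform_id] <- support$n
  ord <- order(-support_n, names(uniq))
  final_ids <- stats::setNames(
    sprintf("%s-novel-%d", partition$gene_id, seq_along(ord)),
    names(uniq)[ord])
  assignments$isoform_id <- unname(final_ids[assignments$isoform_id])
  iso_tbl <- tibble::tibble(
    isoform_id = unname(final_ids[names(uniq)[ord]]),
    support_reads = as.integer(unname(support_n[ord])),
    category = categorize_support(unname(support_n[ord]), min_support),
    membership = purrr::map(uniq[ord], as.integer))
  list(isoforms = iso_tbl, assignments = assignments)
}
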