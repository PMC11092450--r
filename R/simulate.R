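#' Simulate a multi-isoform gene annotation with held-out novel isoforms
#'
#' Generates synthetic multi-exon gene models (shared and distinct exons
#' across isoforms), then removes a stated fraction of isoforms at random
#' into a held-out set that plays the role of ground-truth novel isoforms:
#' absent from the emitted "known" annotation but present in the truth.
#' Every gene retains at least one known isoform, and all isoforms of a
#' gene share its first and last exon (a common TSS/TES simplification)
#' so that isoform differences are internal splicing differences.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Integer range (length 2) of isoforms per gene
#'   (default 2 to 5; every gene gets at least 2).
#' @param holdout_fraction Fraction of all isoforms moved to the held-out
#'   novel set (default 0.3).
#' @param exon_count_range,exon_len_range,intron_len_range Structural
#'   ranges (defaults 3-10 exons of 50-500 bp with 100-2000 bp introns).
#' @param seed Optional RNG seed.
#' @return List with `known` (exon tibble of the emitted annotation),
#'   `holdout` (exon tibble of ground-truth novel isoforms), `all` (both)
#'   and `isoforms` (tibble `gene_id`, `transcript_id`, `novel`).
#' @export
simulate_annotation <- function(n_genes, isoforms_per_gene = c(2L, 5L),
                                holdout_fraction = 0.3,
                                exon_count_range = c(3L, 10L),
                                exon_len_range = c(50L, 500L),
                                intron_len_range = c(100L, 2000L),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- function(rng) {  # guard sample()'s length-one expansion
    if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  }
  pos <- 10000L
  genes <- purrr::map_dfr(seq_len(n_genes), function(g) {
    n_ex <- pick(exon_count_range)
    lens <- sample(exon_len_range[1]:exon_len_range[2], n_ex, replace = TRUE)
    gaps <- sample(intron_len_range[1]:intron_len_range[2], n_ex - 1L,
                   replace = TRUE)
    starts <- pos + cumsum(c(0L, lens[-n_ex] + gaps))
    ends <- starts + lens
    pos <<- ends[n_ex] + sample(5000:10000, 1L)
    gene_id <- sprintf("gene%03d", g)
    strand <- sample(c("+", "-"), 1L)
    k <- pick(isoforms_per_gene)
    vecs <- distinct_isoform_vectors(n_ex, k)
    purrr::imap_dfr(vecs, function(v, i) {
      tibble::tibble(gene_id = gene_id,
                     transcript_id = sprintf("%s-tx%d", gene_id, i),
                     chrom = "chrS", strand = strand,
                     start = starts[v == 1L], end = ends[v == 1L])
    })
  })
  iso <- genes |> dplyr::distinct(.data$gene_id, .data$transcript_id)
  n_hold <- round(holdout_fraction * nrow(iso))
  held <- character(0)
  known_per_gene <- table(iso$gene_id)
  for (tx in sample(iso$transcript_id)) {
    if (length(held) >= n_hold) break
    g <- iso$gene_id[iso$transcript_id == tx]
    if (known_per_gene[[g]] > 1L) {
      held <- c(held, tx)
      known_per_gene[[g]] <- known_per_gene[[g]] - 1L
    }
  }
  iso$novel <- iso$transcript_id %in% held
  list(known = genes[!genes$transcript_id %in% held, ],
       holdout = genes[genes$transcript_id %in% held, ],
       all = genes, isoforms = iso)
}

# k distinct binary exon-membership vectors of length n_ex, all including
# the first and last exon and >= 2 exons
distinct_isoform_vectors <- function(n_ex, k) {
  seen <- character(0)
  out <- list()
  tries <- 0L
  while (length(out) < k && tries < 200L) {
    tries <- tries + 1L
    v <- integer(n_ex)
    v[c(1L, n_ex)] <- 1L
    if (n_ex > 2L)
      v[2:(n_ex - 1L)] <- stats::rbinom(n_ex - 2L, 1L, 0.5)
    key <- paste(v, collapse = "")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out <- c(out, list(v))
    }
  }
  out
}

#' Simulate per-cell transcript counts for one gene
#'
#' The generative model of per-cell transcript usage: concentration
#' parameters alpha_k ~ Gamma(shape 2, scale 2); per cell a sequencing
#' depth rate lambda_c ~ Uniform(0, 15) and total n_c ~ Poisson(lambda_c);
#' usage pi_c ~ Dirichlet(alpha); counts x_c ~ Multinomial(n_c, pi_c).
#'
#' @param K Number of isoforms.
#' @param n_cells Number of cells.
#' @param alpha Optional fixed concentration vector (drawn if `NULL`).
#' @param gamma_shape,gamma_scale Gamma parameters for alpha (defaults 2, 2).
#' @param lambda_max Upper end of the uniform depth-rate range (default 15).
#' @param seed Optional RNG seed.
#' @return List with `alpha`, `pi` (cells x K usage draws), `n` (per-cell
#'   totals) and `X` (cells x K count matrix).
#' @export
simulate_cell_counts <- function(K, n_cells, alpha = NULL, gamma_shape = 2,
                                 gamma_scale = 2, lambda_max = 15,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- alpha %||% stats::rgamma(K, shape = gamma_shape, scale = gamma_scale)
  lambda <- stats::runif(n_cells, 0, lambda_max)
  n <- stats::rpois(n_cells, lambda)
  pi_c <- matrix(stats::rgamma(n_cells * K, shape = rep(alpha, each = n_cells)),
                 nrow = n_cells)
  pi_c <- pi_c / rowSums(pi_c)
  X <- t(vapply(seq_len(n_cells), function(c) {
    if (n[c] == 0L) return(integer(K))
    as.integer(stats::rmultinom(1, n[c], pi_c[c, ]))
  }, integer(K)))
  list(alpha = alpha, pi = pi_c, n = n, X = X)
}

#' Emit aligned reads for a simulated truth table
#'
#' Each (cell, transcript) truth count becomes that many reads tracing the
#' transcript's exon chain, with optional 5' truncation (probability
#' `truncation_prob`, exponential truncated length with mean
#' `truncation_mean`) and nanopore-like alignment noise: small deletions
#' within blocks at a rate proportional to the base error rate
#' (substitutions leave alignment geometry unchanged and are not modelled
#' explicitly).
#'
#' @param truth Tibble with columns `cell_barcode`, `population`,
#'   `transcript_id`, `count`.
#' @param exons Exon tibble covering every truth transcript (known plus
#'   held-out).
#' @param error_rate Total per-base error rate (default 0.01, R10-like);
#'   deletions are modelled at 30% of it.
#' @param truncation_prob Probability a read is 5'-truncated (default 0).
#' @param truncation_mean Mean truncated length in bp (default 150).
#' @param seed Optional RNG seed.
#' @return Tibble with one row per read: `read_id`, `cell_barcode`, `umi`,
#'   `population`, `chrom`, `strand`, `truth_gene`, `truth_transcript`,
#'   `truth_novel` and a `blocks` list-column of aligned-block tibbles.
#' @export
emit_reads <- function(truth, exons, error_rate = 0.01, truncation_prob = 0,
                       truncation_mean = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exons <- as_exon_tbl(exons)
  tx_tbl <- exons |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(gene_id = .data$gene_id[1], chrom = .data$chrom[1],
                     strand = .data$strand[1],
                     starts = list(.data$start), ends = list(.data$end))
  tx_idx <- match(truth$transcript_id, tx_tbl$transcript_id)
  if (anyNA(tx_idx)) abort("truth references transcripts absent from exons")
  del_rate <- error_rate * 0.3

  # expand truth rows to one entry per read, then perturb blocks per read
  rows <- which(truth$count > 0)
  reps <- truth$count[rows]
  src <- rep(rows, reps)
  ti <- tx_idx[src]
  n_total <- length(src)
  blocks <- vector("list", n_total)
  for (r in seq_len(n_total)) {
    b <- list(start = as.numeric(tx_tbl$starts[[ti[r]]]),
              end = as.numeric(tx_tbl$ends[[ti[r]]]))
    if (truncation_prob > 0 && stats::runif(1) < truncation_prob) {
      cut <- ceiling(stats::rexp(1, 1 / truncation_mean))
      b <- truncate_blocks(b, cut, tx_tbl$strand[ti[r]])
    }
    if (del_rate > 0) b <- jitter_deletions(b, del_rate)
    blocks[[r]] <- tibble::new_tibble(b, nrow = length(b$start))
  }
  tibble::tibble(
    read_id = sprintf("read%07d", seq_len(n_total)),
    cell_barcode = truth$cell_barcode[src],
    umi = sprintf("UMI%07d", seq_len(n_total)),
    population = truth$population[src],
    chrom = tx_tbl$chrom[ti], strand = tx_tbl$strand[ti],
    truth_gene = tx_tbl$gene_id[ti],
    truth_transcript = truth$transcript_id[src],
    blocks = blocks)
}

# remove `cut` exonic bases from the 5' end (strand-aware); blocks is a
# plain list(start = numeric, end = numeric)
truncate_blocks <- function(blocks, cut, strand) {
  lens <- blocks$end - blocks$start
  total <- sum(lens)
  cut <- min(cut, total - 50L)  # keep >= 50 aligned bases
  if (cut <= 0) return(blocks)
  nb <- length(lens)
  if (strand == "+") {
    consumed <- cumsum(lens)
    first_keep <- which(consumed > cut)[1]
    prior <- if (first_keep > 1) consumed[first_keep - 1] else 0
    blocks <- list(start = blocks$start[first_keep:nb],
                   end = blocks$end[first_keep:nb])
    blocks$start[1] <- blocks$start[1] + (cut - prior)
  } else {
    consumed <- rev(cumsum(rev(lens)))
    last_keep <- max(which(consumed > cut))
    after <- if (last_keep < nb) consumed[last_keep + 1] else 0
    blocks <- list(start = blocks$start[1:last_keep],
                   end = blocks$end[1:last_keep])
    blocks$end[last_keep] <- blocks$end[last_keep] - (cut - after)
  }
  blocks
}

# sprinkle small alignment deletions (1-5 bp gaps) into blocks
jitter_deletions <- function(blocks, del_rate) {
  total <- sum(blocks$end - blocks$start)
  n_del <- stats::rpois(1, del_rate * total)
  if (n_del == 0L) return(blocks)
  for (d in seq_len(n_del)) {
    lens <- blocks$end - blocks$start
    bi <- sample.int(length(lens), 1, prob = lens)
    gap <- sample(1:5, 1)
    if (lens[bi] <= gap + 2L) next
    at <- blocks$start[bi] + sample.int(lens[bi] - gap - 1L, 1)
    blocks <- list(
      start = append(blocks$start, at + gap, after = bi),
      end = append(blocks$end, at, after = bi - 1L))
  }
  blocks
}

#' Simulate a full two-population long-read single-cell dataset
#'
#' End-to-end generator: synthetic annotation with held-out novel isoforms,
#' per-gene Dirichlet-multinomial cell counts for two cell populations (a
#' stated fraction of genes gets independent alpha vectors in the second
#' population, planting true differential transcript usage), and aligned
#' reads with errors and truncation. Gene expression is simulated
#' independently per gene, so no gene-gene correlation is present.
#'
#' @param n_genes Number of genes (default 20).
#' @param n_cells Cells per population (default 50).
#' @param dtu_fraction Fraction of genes with population-specific alpha
#'   (default 0.5).
#' @param holdout_fraction Fraction of isoforms held out as ground-truth
#'   novel (default 0.3).
#' @param error_rate,truncation_prob,truncation_mean See [emit_reads()].
#' @param isoforms_per_gene Passed to [simulate_annotation()].
#' @param seed RNG seed for the whole dataset.
#' @return A `sim_dataset` list: `reads` (see [emit_reads()]), `annotation`
#'   (known exon tibble), `holdout` (held-out exon tibble), `truth_counts`
#'   (tibble `population`, `cell_barcode`, `gene_id`, `transcript_id`,
#'   `count`), `truth_usage` (tibble `gene_id`, `population`, `transcript_id`,
#'   `alpha`, `pi_bar`, `phi`), `dtu_genes` (character), `cells` (tibble
#'   `cell_barcode`, `population`).
#' @export
simulate_dataset <- function(n_genes = 20L, n_cells = 50L,
                             dtu_fraction = 0.5, holdout_fraction = 0.3,
                             error_rate = 0.01, truncation_prob = 0,
                             truncation_mean = 150,
                             isoforms_per_gene = c(2L, 5L), seed = 1L) {
  set.seed(seed)
  ann <- simulate_annotation(n_genes, isoforms_per_gene, holdout_fraction)
  gene_ids <- unique(ann$isoforms$gene_id)
  dtu_genes <- sample(gene_ids, round(dtu_fraction * length(gene_ids)))
  cells <- tibble::tibble(
    cell_barcode = c(sprintf("cellA%04d", seq_len(n_cells)),
                     sprintf("cellB%04d", seq_len(n_cells))),
    population = rep(c("A", "B"), each = n_cells))

  truth_counts <- list(); truth_usage <- list()
  for (g in gene_ids) {
    txs <- sort(ann$isoforms$transcript_id[ann$isoforms$gene_id == g])
    K <- length(txs)
    simA <- simulate_cell_counts(K, n_cells)
    alphaB <- if (g %in% dtu_genes) NULL else simA$alpha
    simB <- simulate_cell_counts(K, n_cells, alpha = alphaB)
    for (pop in c("A", "B")) {
      sim <- if (pop == "A") simA else simB
      bc <- cells$cell_barcode[cells$population == pop]
      nz <- which(sim$X > 0, arr.ind = TRUE)
      if (nrow(nz)) {
        truth_counts[[paste(g, pop)]] <- tibble::tibble(
          population = pop, cell_barcode = bc[nz[, 1]], gene_id = g,
          transcript_id = txs[nz[, 2]], count = sim$X[nz])
      }
      truth_usage[[paste(g, pop)]] <- tibble::tibble(
        gene_id = g, population = pop, transcript_id = txs,
        alpha = sim$alpha, pi_bar = sim$alpha / sum(sim$alpha),
        phi = 1 / (1 + sum(sim$alpha)))
    }
  }
  truth_counts <- dplyr::bind_rows(truth_counts)
  reads <- emit_reads(truth_counts, ann$all, error_rate = error_rate,
                      truncation_prob = truncation_prob,
                      truncation_mean = truncation_mean)
  novel_tx <- ann$isoforms$transcript_id[ann$isoforms$novel]
  reads$truth_novel <- reads$truth_transcript %in% novel_tx
  structure(
    list(reads = reads, annotation = ann$known, holdout = ann$holdout,
         truth_counts = truth_counts,
         truth_usage = dplyr::bind_rows(truth_usage),
         dtu_genes = sort(dtu_genes), cells = cells),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes (%d DTU), %d cells, %d reads (%d from held-out isoforms)\n",
              length(unique(x$truth_counts$gene_id)), length(x$dtu_genes),
              nrow(x$cells), nrow(x$reads), sum(x$truth_novel %||% x$reads$truth_novel)))
  invisible(x)
}
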