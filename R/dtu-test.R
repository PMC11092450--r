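#' Aggregate rare isoforms and apply the gene read floor
#'
#' Isoform columns whose pooled count (over all cells of both populations)
#' is at most `rare_fraction` of the gene's pooled total are summed into a
#' single `rare` column, and genes with a pooled total of `min_reads` reads
#' or fewer are flagged as excluded from testing.
#'
#' @param X Cells x isoforms count matrix (both populations stacked).
#' @param rare_fraction Pooled-count fraction at or below which an isoform
#'   is rare (default 0.05).
#' @param min_reads Genes need strictly more than this many pooled reads to
#'   be testable (default 20).
#' @return List with `X` (aggregated matrix; rare column named `"rare"`),
#'   `rare_isoforms` (names of the merged columns), `excluded` (logical)
#'   and `reason` (`NA`, `"low_count"` or `"single_isoform"`).
#' @export
aggregate_rare <- function(X, rare_fraction = 0.05, min_reads = 20L) {
  X <- as.matrix(X)
  stopifnot(all(X >= 0))
  total <- sum(X)
  pooled <- colSums(X)
  rare <- pooled <= rare_fraction * total
  nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
  if (any(rare)) {
    keep <- X[, !rare, drop = FALSE]
    agg <- cbind(keep, rare = rowSums(X[, rare, drop = FALSE]))
    colnames(agg) <- c(nm[!rare], "rare")
  } else {
    agg <- X
    colnames(agg) <- nm
  }
  excluded <- FALSE; reason <- NA_character_
  if (total <= min_reads) { excluded <- TRUE; reason <- "low_count" }
  else if (ncol(agg) < 2L) { excluded <- TRUE; reason <- "single_isoform" }
  list(X = agg, rare_isoforms = nm[rare], excluded = excluded, reason = reason)
}

#' Gene-level likelihood-ratio test for differential transcript usage
#'
#' Tests H0: pi_bar identical across populations A and B (each population
#' keeping its own over-dispersion phi) against H1: free (pi_bar, phi) per
#' population. The statistic 2(l_H1 - l_H0) is referred to a chi-squared
#' distribution with K - 1 degrees of freedom.
#'
#' @param XA,XB Cells x isoforms count matrices for the two populations
#'   (same isoform columns, after [aggregate_rare()]).
#' @return List with `statistic`, `df`, `p_value`, `fit_A`, `fit_B`
#'   (`dm_fit` objects) and `fit_null`.
#' @export
lrt_gene <- function(XA, XB) {
  fits <- dtu_fits(XA, XB)
  if (is.null(fits)) return(list(statistic = NA_real_, df = NA_integer_,
                                 p_value = NA_real_, fit_A = NULL,
                                 fit_B = NULL, fit_null = NULL))
  K <- ncol(fits$XA)
  h0 <- fit_dm_shared_pi(fits$XA, fits$XB)
  stat <- 2 * (fits$fit_A$loglik + fits$fit_B$loglik - h0$loglik)
  if (stat < 0) {  # re-anchor H1 at the null optimum and keep the better fit
    fa <- fit_dm(fits$XA, init = pmax(h0$pi_bar * (1 / h0$phi_A - 1), 1e-6))
    fb <- fit_dm(fits$XB, init = pmax(h0$pi_bar * (1 / h0$phi_B - 1), 1e-6))
    if (fa$loglik > fits$fit_A$loglik) fits$fit_A <- fa
    if (fb$loglik > fits$fit_B$loglik) fits$fit_B <- fb
    stat <- max(0, 2 * (fits$fit_A$loglik + fits$fit_B$loglik - h0$loglik))
  }
  df <- K - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       fit_A = fits$fit_A, fit_B = fits$fit_B, fit_null = h0)
}

#' Transcript-level likelihood-ratio test
#'
#' Tests H0: pi_bar_k equal across the two populations for one isoform k,
#' leaving the composition of the remaining isoforms (and each population's
#' over-dispersion) free, against the fully free H1; chi-squared with 1
#' degree of freedom. For K = 2 this coincides with the gene-level test.
#'
#' @inheritParams lrt_gene
#' @param k Isoform column index to test.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_transcript <- function(XA, XB, k) {
  fits <- dtu_fits(XA, XB)
  if (is.null(fits)) return(list(statistic = NA_real_, df = NA_integer_,
                                 p_value = NA_real_))
  h0 <- fit_dm_shared_component(fits$XA, fits$XB, k)
  stat <- max(0, 2 * (fits$fit_A$loglik + fits$fit_B$loglik - h0$loglik))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

# shared prep for the LRTs: drop empty cells, fit H1 per group
dtu_fits <- function(XA, XB) {
  XA <- as.matrix(XA); XB <- as.matrix(XB)
  XA <- XA[rowSums(XA) > 0, , drop = FALSE]
  XB <- XB[rowSums(XB) > 0, , drop = FALSE]
  if (nrow(XA) < 2L || nrow(XB) < 2L || ncol(XA) < 2L) return(NULL)
  fit_A <- try(fit_dm(XA), silent = TRUE)
  fit_B <- try(fit_dm(XB), silent = TRUE)
  if (inherits(fit_A, "try-error") || inherits(fit_B, "try-error")) return(NULL)
  list(XA = XA, XB = XB, fit_A = fit_A, fit_B = fit_B)
}

#' Detect isoform switching between two fitted populations
#'
#' The dominant isoform of each population is the argmax of pi_bar over the
#' non-rare columns; switching means the dominants differ. The effect size
#' is the absolute sum of the differences in the two dominant isoforms'
#' proportions, |pi_a^A - pi_a^B| + |pi_b^A - pi_b^B| where a and b are the
#' dominants of A and B — in \[0, 2\].
#'
#' @param fit_A,fit_B `dm_fit` objects with identical isoform indexing.
#' @param rare_col Name or index of the aggregated rare column to exclude
#'   from dominance (default `"rare"`; ignored if absent).
#' @return List with `switching` (logical), `effect_size` (`NA` unless
#'   switching), `dominant_A`, `dominant_B`.
#' @export
detect_switching <- function(fit_A, fit_B, rare_col = "rare") {
  nm <- names(fit_A$alpha) %||% as.character(seq_along(fit_A$alpha))
  use <- nm != rare_col
  pa <- fit_A$pi_bar[use]; pb <- fit_B$pi_bar[use]
  cand <- nm[use]
  a <- cand[which.max(pa)]
  b <- cand[which.max(pb)]
  switching <- a != b
  effect <- if (switching) {
    abs(fit_A$pi_bar[nm == a] - fit_B$pi_bar[nm == a]) +
      abs(fit_B$pi_bar[nm == b] - fit_A$pi_bar[nm == b])
  } else NA_real_
  list(switching = switching, effect_size = unname(effect),
       dominant_A = a, dominant_B = b)
}

#' Benjamini-Hochberg adjustment within a testing scope
#'
#' Gene-level p-values are adjusted across all genes tested; transcript-
#' level p-values across all gene-by-transcript tests.
#'
#' @param p Numeric vector of p-values (NAs preserved).
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Test differential transcript usage across all genes
#'
#' Runs the full statistics stage: per gene, rare-isoform aggregation and
#' the read floor, gene-level and per-transcript likelihood-ratio tests,
#' BH adjustment (genes across genes; transcripts across all
#' gene-by-transcript tests), isoform-switching detection and effect size,
#' and bootstrap standard errors for the usage estimates.
#'
#' @param counts A `count_matrices` object, or a transcripts x cells matrix
#'   with a matching `features` tibble passed separately.
#' @param groups Data frame with columns `cell_barcode` and `population`
#'   (exactly two populations).
#' @param features Optional features tibble (`feature_id`, `gene_id`) if
#'   `counts` is a bare matrix.
#' @param rare_fraction,min_reads See [aggregate_rare()].
#' @param boot Number of bootstrap resamples for the usage standard errors
#'   (default 0: no bootstrap).
#' @return A `dtu_results` object: list of tibbles `genes` (gene_id,
#'   statistic, df, p_gene, padj_gene, phi_A, phi_B, switching,
#'   effect_size, dominant_A, dominant_B, excluded, reason) and
#'   `transcripts` (gene_id, isoform, pi_A, pi_B, sd_A, sd_B, statistic,
#'   p_transcript, padj_transcript).
#' @export
dtu_test <- function(counts, groups, features = NULL, rare_fraction = 0.05,
                     min_reads = 20L, boot = 0L) {
  if (inherits(counts, "count_matrices")) {
    features <- counts$features
    mat <- counts$transcript_counts
  } else {
    stopifnot(!is.null(features))
    mat <- counts
  }
  groups <- tibble::as_tibble(groups)
  pops <- sort(unique(groups$population))
  if (length(pops) != 2L) abort("exactly two populations are required")
  cells_A <- groups$cell_barcode[groups$population == pops[1]]
  cells_B <- groups$cell_barcode[groups$population == pops[2]]
  cells_A <- intersect(cells_A, colnames(mat))
  cells_B <- intersect(cells_B, colnames(mat))

  gene_rows <- split(features$feature_id, features$gene_id)
  gene_res <- list(); tx_res <- list()
  for (g in names(gene_rows)) {
    rows <- gene_rows[[g]]
    XA <- t(as.matrix(mat[rows, cells_A, drop = FALSE]))
    XB <- t(as.matrix(mat[rows, cells_B, drop = FALSE]))
    colnames(XA) <- colnames(XB) <- rows
    agg <- aggregate_rare(rbind(XA, XB), rare_fraction, min_reads)
    if (agg$excluded) {
      gene_res[[g]] <- tibble::tibble(
        gene_id = g, statistic = NA_real_, df = NA_integer_,
        p_gene = NA_real_, phi_A = NA_real_, phi_B = NA_real_,
        switching = NA, effect_size = NA_real_, dominant_A = NA_character_,
        dominant_B = NA_character_, excluded = TRUE, reason = agg$reason)
      next
    }
    XA2 <- agg$X[seq_len(nrow(XA)), , drop = FALSE]
    XB2 <- agg$X[nrow(XA) + seq_len(nrow(XB)), , drop = FALSE]
    gt <- lrt_gene(XA2, XB2)
    if (is.null(gt$fit_A)) {
      gene_res[[g]] <- tibble::tibble(
        gene_id = g, statistic = NA_real_, df = NA_integer_,
        p_gene = NA_real_, phi_A = NA_real_, phi_B = NA_real_,
        switching = NA, effect_size = NA_real_, dominant_A = NA_character_,
        dominant_B = NA_character_, excluded = TRUE, reason = "unfittable")
      next
    }
    sw <- detect_switching(gt$fit_A, gt$fit_B)
    gene_res[[g]] <- tibble::tibble(
      gene_id = g, statistic = gt$statistic, df = gt$df, p_gene = gt$p_value,
      phi_A = gt$fit_A$phi, phi_B = gt$fit_B$phi, switching = sw$switching,
      effect_size = sw$effect_size, dominant_A = sw$dominant_A,
      dominant_B = sw$dominant_B, excluded = FALSE, reason = NA_character_)

    sds <- if (boot > 0L) boot_pi_sd(XA2, XB2, boot) else NULL
    K <- ncol(XA2)
    tx_res[[g]] <- purrr::map_dfr(seq_len(K), function(k) {
      tt <- lrt_transcript(XA2, XB2, k)
      tibble::tibble(
        gene_id = g, isoform = colnames(XA2)[k],
        pi_A = unname(gt$fit_A$pi_bar[k]), pi_B = unname(gt$fit_B$pi_bar[k]),
        sd_A = if (is.null(sds)) NA_real_ else sds$A[k],
        sd_B = if (is.null(sds)) NA_real_ else sds$B[k],
        statistic = tt$statistic, p_transcript = tt$p_value)
    })
  }
  genes <- dplyr::bind_rows(gene_res)
  genes$padj_gene <- adjust_fdr(genes$p_gene)
  transcripts <- dplyr::bind_rows(tx_res)
  if (nrow(transcripts))
    transcripts$padj_transcript <- adjust_fdr(transcripts$p_transcript)
  structure(list(genes = genes, transcripts = transcripts,
                 populations = pops),
            class = "dtu_results")
}

# nonparametric bootstrap over cells for pi_bar standard errors
boot_pi_sd <- function(XA, XB, boot) {
  one <- function(X) {
    reps <- replicate(boot, {
      idx <- sample.int(nrow(X), replace = TRUE)
      f <- try(fit_dm(X[idx, , drop = FALSE]), silent = TRUE)
      if (inherits(f, "try-error")) rep(NA_real_, ncol(X)) else f$pi_bar
    })
    apply(reps, 1, stats::sd, na.rm = TRUE)
  }
  list(A = one(XA), B = one(XB))
}

#' @export
print.dtu_results <- function(x, ...) {
  tested <- sum(!x$genes$excluded)
  cat(sprintf("<dtu_results> %s vs %s: %d genes tested (%d excluded), %d with padj <= 0.01\n",
              x$populations[1], x$populations[2], tested,
              sum(x$genes$excluded),
              sum(x$genes$padj_gene <= 0.01, na.rm = TRUE)))
  invisible(x)
}

#' @rdname dtu_test
#' @param x A `dtu_results` object.
#' @param ... Unused.
#' @export
tidy.dtu_results <- function(x, ...) x$genes

#' @rdname dtu_test
#' @export
glance.dtu_results <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes), n_tested = sum(!x$genes$excluded),
    n_dtu_001 = sum(x$genes$padj_gene <= 0.01, na.rm = TRUE),
    n_switching = sum(x$genes$switching, na.rm = TRUE))
}
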