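#' Evaluate pipeline output against simulation ground truth
#'
#' Computes the simulation-study metrics: (i) read-isoform mapping accuracy
#' over known and novel isoforms, where a novel-read call is correct iff
#' the read was assigned to a discovered isoform whose exonic chain matches
#' its truth held-out isoform; (ii) precision/recall/F1 of per-read
#' novel-vs-known classification; (iii) the novel isoform annotation rate
#' (reported novel isoforms / expressed ground-truth novel isoforms);
#' (iv) Spearman correlation and median absolute percentage error of
#' pseudo-bulk gene and known-transcript counts against truth; and (v)
#' precision/recall of differential-transcript-usage calls against the
#' planted DTU gene set, when a `dtu_results` object is supplied.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dtu Optional `dtu_results` from [dtu_test()].
#' @param padj_threshold Adjusted-p cutoff for a DTU call (default 0.01).
#' @return A one-row tibble of metrics.
#' @export
evaluate_pipeline <- function(sim, result, dtu = NULL,
                              padj_threshold = 0.01) {
  reads <- sim$reads
  asg <- result$assignments
  if (!all(asg$read_id %in% reads$read_id))
    abort("assignments contain read ids absent from the truth")
  m <- dplyr::left_join(
    reads[, c("read_id", "truth_gene", "truth_transcript", "truth_novel")],
    asg[, c("read_id", "gene_id", "isoform_id", "priority_class")],
    by = "read_id")

  # match each discovered novel isoform to a held-out transcript by footprint
  novel_match <- match_novel_isoforms(result$novel_isoforms, sim$holdout)

  pred_iso <- m$isoform_id
  matched_truth <- novel_match$truth_transcript[match(pred_iso, novel_match$isoform_id)]
  correct <- dplyr::case_when(
    is.na(pred_iso) ~ FALSE,
    !m$truth_novel ~ pred_iso == m$truth_transcript,
    TRUE ~ !is.na(matched_truth) & matched_truth == m$truth_transcript)
  mapping_accuracy <- mean(correct)

  # per-read novel-vs-known classification
  pred_novel <- !is.na(m$priority_class) & m$priority_class == "novel"
  tp <- sum(pred_novel & m$truth_novel)
  novel_precision <- if (sum(pred_novel)) tp / sum(pred_novel) else NA_real_
  novel_recall <- if (sum(m$truth_novel)) tp / sum(m$truth_novel) else NA_real_
  novel_f1 <- if (!is.na(novel_precision) && !is.na(novel_recall) &&
                  novel_precision + novel_recall > 0)
    2 * novel_precision * novel_recall / (novel_precision + novel_recall)
  else NA_real_

  expressed_novel <- unique(reads$truth_transcript[reads$truth_novel])
  n_reported <- sum(result$novel_isoforms$category == "novel")
  annotation_rate <- if (length(expressed_novel))
    n_reported / length(expressed_novel) else NA_real_

  # pseudo-bulk quantification vs truth
  gene_truth <- sim$truth_counts |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(truth = sum(.data$count))
  gene_est <- tibble::tibble(gene_id = rownames(result$counts$gene_counts),
                             est = Matrix::rowSums(result$counts$gene_counts))
  gq <- dplyr::left_join(gene_truth, gene_est, by = "gene_id") |>
    tidyr::replace_na(list(est = 0))
  tx_truth <- sim$truth_counts |>
    dplyr::filter(!.data$transcript_id %in% unique(sim$holdout$transcript_id)) |>
    dplyr::group_by(transcript_id = .data$transcript_id) |>
    dplyr::summarise(truth = sum(.data$count))
  tx_est <- tibble::tibble(
    transcript_id = rownames(result$counts$transcript_counts),
    est = Matrix::rowSums(result$counts$transcript_counts))
  tq <- dplyr::left_join(tx_truth, tx_est, by = "transcript_id") |>
    tidyr::replace_na(list(est = 0))

  spearman <- function(d) stats::cor(d$truth, d$est, method = "spearman")
  mape <- function(d) stats::median(abs(d$est - d$truth) / d$truth)

  out <- tibble::tibble(
    n_reads = nrow(reads),
    mapping_accuracy = mapping_accuracy,
    novel_precision = novel_precision, novel_recall = novel_recall,
    novel_f1 = novel_f1, annotation_rate = annotation_rate,
    gene_spearman = spearman(gq), gene_mape = mape(gq),
    transcript_spearman = spearman(tq), transcript_mape = mape(tq))

  if (!is.null(dtu)) {
    called <- dtu$genes$gene_id[!is.na(dtu$genes$padj_gene) &
                                  dtu$genes$padj_gene <= padj_threshold]
    tested <- dtu$genes$gene_id[!dtu$genes$excluded]
    truth_pos <- intersect(sim$dtu_genes, tested)
    tp_d <- length(intersect(called, truth_pos))
    out$dtu_precision <- if (length(called)) tp_d / length(called) else NA_real_
    out$dtu_recall <- if (length(truth_pos)) tp_d / length(truth_pos) else NA_real_
  }
  out
}

# footprint-match discovered novel isoforms to held-out transcripts
match_novel_isoforms <- function(novel_isoforms, holdout) {
  if (is.null(novel_isoforms) || nrow(novel_isoforms) == 0L)
    return(tibble::tibble(isoform_id = character(),
                          truth_transcript = character()))
  truth_keys <- purrr::map_chr(split(holdout, holdout$transcript_id),
                               ~ footprint_key(merge_intervals(.x[c("start", "end")])))
  keys <- purrr::map_chr(novel_isoforms$footprint, footprint_key)
  tibble::tibble(
    isoform_id = novel_isoforms$isoform_id,
    truth_transcript = names(truth_keys)[match(keys, truth_keys)])
}

footprint_key <- function(iv) paste(iv$start, iv$end, sep = "-", collapse = ";")

#' Precision/recall helpers for matched novel annotations
#'
#' Fraction of reported (categorized) novel isoforms whose exonic chain
#' exactly matches a held-out isoform, and the fraction of expressed
#' held-out isoforms recovered exactly.
#'
#' @inheritParams evaluate_pipeline
#' @return Tibble with `annotation_precision`, `annotation_recall`.
#' @export
evaluate_novel_annotation <- function(sim, result) {
  iso <- result$novel_isoforms
  iso <- iso[iso$category == "novel", , drop = FALSE]
  nm <- match_novel_isoforms(iso, sim$holdout)
  expressed <- unique(sim$reads$truth_transcript[sim$reads$truth_novel])
  tibble::tibble(
    annotation_precision = if (nrow(nm)) mean(!is.na(nm$truth_transcript))
    else NA_real_,
    annotation_recall = if (length(expressed))
      length(intersect(nm$truth_transcript, expressed)) / length(expressed)
    else NA_real_)
}
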