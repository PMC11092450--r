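test_that("phi follows its closed form and pi_bar normalizes alpha", {
  f <- isousage:::new_dm_fit(c(1, 1), loglik = 0, converged = TRUE,
                             boundary = FALSE, n_cells = 10)
  expect_equal(f$phi, 1 / 3)
  expect_equal(f$pi_bar, c(0.5, 0.5))
  f2 <- isousage:::new_dm_fit(c(4, 2, 2), 0, TRUE, FALSE, 10)
  expect_equal(f2$phi, 1 / 9)
  expect_equal(f2$pi_bar, c(0.5, 0.25, 0.25))
})

test_that("cells expressing a single isoform push pi_bar to the boundary", {
  X <- cbind(rpois(40, 8), 0)
  X[X[, 1] == 0, 1] <- 1
  f <- fit_dm(X)
  expect_gt(f$pi_bar[1], 0.97)
  expect_lt(f$pi_bar[2], 0.03)
})

test_that("the MLE beats a 3-D grid-search oracle and recovers pi_bar", {
  set.seed(101)
  sim <- simulate_cell_counts(3, 200, alpha = c(4, 2, 2))
  X <- sim$X[rowSums(sim$X) > 0, ]
  f <- fit_dm(X)
  expect_gte(f$loglik, oracle_dm_grid(X) - 1e-6)
  expect_lt(max(abs(f$pi_bar - c(0.5, 0.25, 0.25))), 0.03)
})

test_that("degenerate inputs raise errors", {
  expect_error(fit_dm(matrix(0, 5, 2)), "cells")
  expect_error(fit_dm(matrix(1:10, ncol = 1)), "isoform")
})

test_that("pi_bar is invariant to scaling alpha while phi is not", {
  set.seed(5)
  f1 <- fit_dm(simulate_cell_counts(3, 500, alpha = c(4, 2, 2))$X)
  f4 <- fit_dm(simulate_cell_counts(3, 500, alpha = 4 * c(4, 2, 2))$X)
  expect_lt(max(abs(f1$pi_bar - f4$pi_bar)), 0.05)
  expect_gt(f1$phi, f4$phi)   # larger total concentration -> smaller phi
  expect_lt(abs(f1$phi - 1 / 9), 0.05)
  expect_lt(abs(f4$phi - 1 / 33), 0.03)
})

test_that("tidy() and glance() summarize a fit", {
  X <- t(rmultinom(30, 20, c(0.7, 0.3)))
  colnames(X) <- c("tx1", "tx2")
  f <- fit_dm(X)
  td <- tidy(f)
  expect_equal(td$isoform, c("tx1", "tx2"))
  expect_equal(sum(td$pi_bar), 1)
  gl <- glance(f)
  expect_equal(gl$K, 2L)
  expect_true(gl$converged)
})

test_that("identical groups give a near-zero statistic and p near 1", {
  set.seed(3)
  X <- simulate_cell_counts(3, 80, alpha = c(3, 2, 1))$X
  g <- lrt_gene(X, X)
  expect_lt(g$statistic, 1e-3)
  expect_gt(g$p_value, 0.99)
  tt <- lrt_transcript(X, X, 2)
  expect_gt(tt$p_value, 0.99)
})

test_that("well-separated groups are detected with extreme significance", {
  set.seed(4)
  XA <- simulate_cell_counts(2, 500, alpha = c(0.8, 0.2) * 5)$X
  XB <- simulate_cell_counts(2, 500, alpha = c(0.2, 0.8) * 5)$X
  g <- lrt_gene(XA, XB)
  expect_lt(g$p_value, 1e-6)
})

test_that("nested-model log-likelihood ordering holds on random fixtures", {
  set.seed(6)
  for (rep in 1:15) {
    K <- sample(2:4, 1)
    a <- rgamma(K, 2, scale = 2)
    XA <- simulate_cell_counts(K, 60, alpha = a)$X
    XB <- simulate_cell_counts(K, 60, alpha = a)$X
    if (min(sum(XA), sum(XB)) < 10) next
    g <- lrt_gene(XA, XB)
    if (is.na(g$statistic)) next
    expect_gte(g$statistic, 0)
    # free fits dominate the constrained fit
    expect_gte(g$fit_A$loglik + g$fit_B$loglik, g$fit_null$loglik - 1e-6)
    k <- sample(K, 1)
    tt <- lrt_transcript(XA, XB, k)
    expect_gte(tt$statistic, 0)
  }
})

test_that("only the perturbed component is flagged by the transcript test", {
  set.seed(8)
  aA <- c(4, 3, 3); aB <- c(7, 3, 3) * (10 / 13)  # component 1 shifts, 2:3 ratio kept
  XA <- simulate_cell_counts(3, 600, alpha = aA)$X
  XB <- simulate_cell_counts(3, 600, alpha = aB)$X
  p1 <- lrt_transcript(XA, XB, 1)$p_value
  expect_lt(p1, 0.01)
})

test_that("for K = 2 the transcript test equals the gene test", {
  set.seed(9)
  XA <- simulate_cell_counts(2, 150, alpha = c(2, 1))$X
  XB <- simulate_cell_counts(2, 150, alpha = c(1.5, 1.5))$X
  g <- lrt_gene(XA, XB)
  t1 <- lrt_transcript(XA, XB, 1)
  t2 <- lrt_transcript(XA, XB, 2)
  expect_equal(t1$statistic, g$statistic, tolerance = 1e-4)
  expect_equal(t2$statistic, g$statistic, tolerance = 1e-4)
  expect_equal(g$df, 1L)
})

test_that("parameter recovery across replicates tracks truth", {
  set.seed(10)
  res <- t(replicate(50, {
    a <- rgamma(3, 2, scale = 2)
    X <- simulate_cell_counts(3, 300, alpha = a)$X
    f <- fit_dm(X[rowSums(X) > 0, ])
    c(err = mean(abs(f$pi_bar - a / sum(a))),
      phi_true = 1 / (1 + sum(a)), phi_est = f$phi)
  }))
  expect_lt(mean(res[, "err"]), 0.03)
  expect_gt(cor(res[, "phi_true"], res[, "phi_est"], method = "spearman"), 0.8)
})

test_that("rare isoforms are pooled at the 5% rule and the read floor applies", {
  # totals (900, 60, 40) of 1000: the 40-read isoform is <= 5% -> rare
  X <- rbind(c(450, 30, 20), c(450, 30, 20))
  agg <- aggregate_rare(X)
  expect_equal(colnames(agg$X), c("1", "2", "rare"))
  expect_equal(unname(colSums(agg$X)), c(900, 60, 40))
  expect_equal(agg$rare_isoforms, "3")
  expect_false(agg$excluded)

  # exactly 5% is aggregated (<= rule)
  X2 <- rbind(c(475, 475, 25), c(475, 475, 25))   # 50 of 1000 = 5%
  expect_equal(aggregate_rare(X2)$rare_isoforms, "3")
  # just above 5% is kept
  X3 <- rbind(c(235, 235, 26), c(235, 235, 26))   # 52 of 992 > 5%
  expect_length(aggregate_rare(X3)$rare_isoforms, 0)

  # gene with 15 reads total -> excluded
  X4 <- rbind(c(5, 3), c(4, 3))
  expect_true(aggregate_rare(X4)$excluded)
  expect_equal(aggregate_rare(X4)$reason, "low_count")
  # unchanged when nothing is rare
  X5 <- rbind(c(250, 250), c(250, 250))
  expect_equal(aggregate_rare(X5)$X, X5, ignore_attr = TRUE)
})

test_that("switching requires a change of dominant isoform, rare excluded", {
  fA <- isousage:::new_dm_fit(c(9, 1), 0, TRUE, FALSE, 10, names = c("t1", "t2"))
  fB <- isousage:::new_dm_fit(c(1, 9), 0, TRUE, FALSE, 10, names = c("t1", "t2"))
  sw <- detect_switching(fA, fB)
  expect_true(sw$switching)
  expect_equal(sw$effect_size, 1.6)
  expect_equal(sw$dominant_A, "t1")
  expect_equal(sw$dominant_B, "t2")

  same <- detect_switching(fA, fA)
  expect_false(same$switching)
  expect_true(is.na(same$effect_size))

  # dominance via the rare column is ignored
  fC <- isousage:::new_dm_fit(c(2, 1, 7), 0, TRUE, FALSE, 10,
                              names = c("t1", "t2", "rare"))
  fD <- isousage:::new_dm_fit(c(1, 2, 7), 0, TRUE, FALSE, 10,
                              names = c("t1", "t2", "rare"))
  sw2 <- detect_switching(fC, fD)
  expect_equal(sw2$dominant_A, "t1")
  expect_equal(sw2$dominant_B, "t2")
  expect_true(sw2$switching)
})

test_that("BH adjustment is applied within scope", {
  expect_equal(adjust_fdr(0.04), 0.04)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
})

test_that("dtu_test produces a coherent table over a small dataset", {
  set.seed(12)
  n_cells <- 60
  cells <- tibble::tibble(
    cell_barcode = c(sprintf("a%02d", 1:n_cells), sprintf("b%02d", 1:n_cells)),
    population = rep(c("A", "B"), each = n_cells))
  # gene1: planted DTU; gene2: shared alpha
  XA1 <- simulate_cell_counts(2, n_cells, alpha = c(6, 1))$X
  XB1 <- simulate_cell_counts(2, n_cells, alpha = c(1, 6))$X
  a2 <- c(2, 3)
  XA2 <- simulate_cell_counts(2, n_cells, alpha = a2)$X
  XB2 <- simulate_cell_counts(2, n_cells, alpha = a2)$X
  mat <- rbind(t(rbind(XA1, XB1)), t(rbind(XA2, XB2)))
  rownames(mat) <- c("g1-t1", "g1-t2", "g2-t1", "g2-t2")
  colnames(mat) <- cells$cell_barcode
  feats <- tibble::tibble(feature_id = rownames(mat),
                          gene_id = rep(c("g1", "g2"), each = 2))
  out <- dtu_test(mat, cells, features = feats, boot = 20)
  expect_s3_class(out, "dtu_results")
  g1 <- out$genes[out$genes$gene_id == "g1", ]
  g2 <- out$genes[out$genes$gene_id == "g2", ]
  expect_lt(g1$padj_gene, 0.01)
  expect_gt(g2$p_gene, 0.01)
  expect_true(g1$switching)
  expect_true(all(out$genes$padj_gene >= out$genes$p_gene, na.rm = TRUE))
  expect_true(all(out$transcripts$padj_transcript >=
                    out$transcripts$p_transcript, na.rm = TRUE))
  expect_true(all(is.finite(out$transcripts$sd_A)))
  # usage estimates sum to one within gene and population
  sums <- tapply(out$transcripts$pi_A, out$transcripts$gene_id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-6)
  expect_equal(glance(out)$n_tested, 2L)
  expect_s3_class(autoplot(out), "gg")
  expect_s3_class(plot_transcript_usage(out, "g1"), "gg")
})
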