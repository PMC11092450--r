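# minimal encoding constructor for graph tests
mk_enc <- function(id, states, start = 0) {
  structure(list(read_id = id, cell_barcode = "bc", umi = "u", gene_id = "g",
                 states = states, coverage_fractions = as.numeric(states == "covered"),
                 aligned_span = c(start, start + 1000), aligned_bases = 100L),
            class = "read_encoding")
}

test_that("edge weights are the agreement fraction over jointly informative sub-exons", {
  e1 <- mk_enc("r1", c("covered", "skipped", "covered", "covered"))
  e2 <- mk_enc("r2", c("covered", "skipped", "covered", "covered"))
  g <- build_read_graph(list(e1, e2))
  expect_equal(igraph::E(g$graph)$weight, 1.0)

  e3 <- mk_enc("r3", c("covered", "covered", "covered", "covered"))
  g2 <- build_read_graph(list(e1, e3))  # agree on 3 of 4
  expect_equal(igraph::E(g2$graph)$weight, 0.75)

  # ambiguous/unobserved are not informative
  e4 <- mk_enc("r4", c("covered", "ambiguous", "unobserved", "covered"))
  g3 <- build_read_graph(list(e1, e4))  # joint informative: 1 and 4, agree both
  expect_equal(igraph::E(g3$graph)$weight, 1.0)

  # no jointly informative sub-exons -> no edge
  e5 <- mk_enc("r5", c("ambiguous", "ambiguous", "unobserved", "unobserved"))
  g4 <- build_read_graph(list(e1, e5))
  expect_equal(igraph::ecount(g4$graph), 0L)
})

test_that("pairwise weights match brute-force computation on random encodings", {
  set.seed(5)
  encs <- lapply(1:20, function(i) {
    mk_enc(sprintf("r%02d", i),
           sample(c("covered", "skipped", "ambiguous", "unobserved"), 6,
                  replace = TRUE))
  })
  g <- build_read_graph(encs)
  el <- igraph::as_data_frame(g$graph)
  for (i in 1:19) for (j in (i + 1):20) {
    si <- encs[[i]]$states; sj <- encs[[j]]$states
    joint <- si %in% c("covered", "skipped") & sj %in% c("covered", "skipped")
    w <- if (any(joint)) mean(si[joint] == sj[joint]) else NA
    row <- el[(el$from == encs[[i]]$read_id & el$to == encs[[j]]$read_id) |
                (el$from == encs[[j]]$read_id & el$to == encs[[i]]$read_id), ]
    if (is.na(w) || w == 0) expect_equal(nrow(row), 0L)
    else expect_equal(row$weight, w)
  }
})

test_that("fewer than two novel reads yields an empty graph", {
  g <- build_read_graph(list(mk_enc("r1", c("covered", "covered"))))
  expect_equal(igraph::vcount(g$graph), 0L)
})

test_that("batching takes reads in aligned-start order", {
  encs <- list(mk_enc("late", c("covered", "covered"), start = 500),
               mk_enc("early", c("covered", "skipped"), start = 10),
               mk_enc("mid", c("skipped", "covered"), start = 100))
  g <- build_read_graph(encs, batch_size = 2L)
  expect_equal(g$read_ids, c("early", "mid"))
  expect_equal(purrr::map_chr(g$remaining, "read_id"), "late")
})

test_that("Louvain separates disconnected cliques and keeps one clique together", {
  a <- lapply(1:6, function(i) mk_enc(paste0("a", i),
                                      c("covered", "covered", "skipped", "skipped")))
  b <- lapply(1:6, function(i) mk_enc(paste0("b", i),
                                      c("skipped", "skipped", "covered", "covered")))
  g <- build_read_graph(c(a, b))
  comm <- detect_communities(g$graph, seed = 1)
  expect_equal(length(unique(comm)), 2L)
  expect_equal(length(unique(comm[paste0("a", 1:6)])), 1L)

  ga <- build_read_graph(a)
  expect_equal(length(unique(detect_communities(ga$graph, seed = 1))), 1L)
})

test_that("a planted 3-community graph is recovered", {
  pats <- list(c("covered", "covered", "skipped", "skipped", "skipped", "skipped"),
               c("skipped", "skipped", "covered", "covered", "skipped", "skipped"),
               c("skipped", "skipped", "skipped", "skipped", "covered", "covered"))
  encs <- purrr::imap(rep(pats, each = 8), function(p, i) {
    mk_enc(sprintf("r%02d", i), p)
  })
  g <- build_read_graph(encs)
  comm <- detect_communities(g$graph, seed = 42)
  planted <- rep(1:3, each = 8)
  expect_equal(length(unique(comm)), 3L)
  # identical planted pattern -> identical community
  for (k in 1:3) {
    ids <- sprintf("r%02d", which(planted == k))
    expect_equal(length(unique(comm[ids])), 1L)
  }
})

test_that("community detection is deterministic under a fixed seed", {
  set.seed(123)
  encs <- lapply(1:30, function(i) {
    mk_enc(sprintf("r%02d", i),
           sample(c("covered", "skipped"), 6, replace = TRUE))
  })
  g <- build_read_graph(encs)
  c1 <- detect_communities(g$graph, seed = 7)
  c2 <- detect_communities(g$graph, seed = 7)
  expect_identical(c1, c2)
})

test_that("consensus membership is the per-sub-exon mode, ties toward inclusion", {
  ten <- lapply(1:10, function(i) mk_enc(paste0("r", i),
                                         c("covered", "covered", "skipped", "skipped")))
  expect_equal(consensus_annotation(ten), c(1L, 1L, 0L, 0L))

  mixed <- c(lapply(1:6, function(i) mk_enc(paste0("c", i),
                                            c("covered", "covered", "covered", "skipped"))),
             lapply(1:4, function(i) mk_enc(paste0("s", i),
                                            c("covered", "covered", "skipped", "skipped"))))
  expect_equal(consensus_annotation(mixed)[3], 1L)  # 6 covered vs 4 skipped

  tie <- c(lapply(1:5, function(i) mk_enc(paste0("c", i),
                                          c("covered", "covered"))),
           lapply(1:5, function(i) mk_enc(paste0("s", i),
                                          c("covered", "skipped"))))
  expect_equal(consensus_annotation(tie)[2], 1L)    # 5/5 tie -> inclusion

  none <- lapply(1:3, function(i) mk_enc(paste0("r", i),
                                         c("covered", "ambiguous")))
  expect_equal(consensus_annotation(none)[2], 0L)   # informative in no read
})

test_that("support categorization uses a strict > 20 rule", {
  expect_equal(categorize_support(25), "novel")
  expect_equal(categorize_support(15), "uncategorized")
  expect_equal(categorize_support(20), "uncategorized")
  expect_equal(categorize_support(21), "novel")
})

test_that("candidates duplicating annotated isoforms are removed before remapping", {
  p <- build_partition(toy_exons("g", "chr1", "+", list(
    t1 = rbind(c(0, 100), c(200, 300)), t2 = cbind(0, 100))))
  reads <- lapply(1:5, function(i) mk_enc(paste0("r", i), c("covered", "covered")))
  out <- remap_and_prune(reads, list(cand1 = c(1L, 1L)), p)
  expect_length(out$isoforms, 0L)
  expect_equal(length(out$unassigned), 5L)
})

test_that("a candidate whose reads all map elsewhere is pruned", {
  p <- build_partition(toy_exons("g", "chr1", "+", list(
    t1 = rbind(c(0, 100), c(200, 300), c(400, 500)))))
  # candidate A = (1,0,0) is a truncation-shadow of B = (1,1,0):
  # its reads (unobserved tail) also map to B under the relaxed threshold
  a_reads <- lapply(1:3, function(i) {
    mk_enc(paste0("a", i), c("covered", "unobserved", "unobserved"))
  })
  b_reads <- lapply(1:8, function(i) {
    mk_enc(paste0("b", i), c("covered", "covered", "skipped"))
  })
  out <- remap_and_prune(c(a_reads, b_reads),
                         list(A = c(1L, 0L, 0L), B = c(1L, 1L, 0L)), p)
  expect_equal(names(out$isoforms), "B")
  expect_true(all(out$assignments$isoform_id == "B"))

  # disjoint-support candidates are all retained
  c_reads <- lapply(1:4, function(i) {
    mk_enc(paste0("c", i), c("skipped", "skipped", "covered"))
  })
  out2 <- remap_and_prune(c(b_reads, c_reads),
                          list(B = c(1L, 1L, 0L), C = c(0L, 0L, 1L)), p)
  expect_setequal(names(out2$isoforms), c("B", "C"))
})

test_that("discovery recovers a held-out isoform from clean reads", {
  p <- build_partition(toy_exons("g", "chr1", "+", list(
    t1 = rbind(c(0, 100), c(200, 300), c(400, 500)))))
  # 26 identical reads following membership (1,0,1): unknown to annotation
  reads <- lapply(1:26, function(i) {
    mk_enc(paste0("r", i), c("covered", "skipped", "covered"))
  })
  out <- discover_novel_isoforms(reads, p)
  expect_equal(nrow(out$isoforms), 1L)
  expect_equal(out$isoforms$membership[[1]], c(1L, 0L, 1L))
  expect_equal(out$isoforms$support_reads, 26L)
  expect_equal(out$isoforms$category, "novel")
  expect_equal(out$isoforms$isoform_id, "g-novel-1")
  expect_equal(nrow(out$assignments), 26L)
})

test_that("emitted novel isoforms never duplicate annotated membership vectors", {
  set.seed(21)
  for (rep in 1:10) {
    p <- random_toy_gene(max_subexons = 5, max_isoforms = 3)
    reads <- lapply(1:30, function(i) {
      mk_enc(paste0("r", i),
             sample(c("covered", "skipped"), nrow(p$sub_exons), replace = TRUE))
    })
    out <- discover_novel_isoforms(reads, p)
    for (v in out$isoforms$membership) {
      for (ann in p$transcripts) expect_false(identical(v, as.integer(ann)))
    }
  }
})
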