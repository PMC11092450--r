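# a 4-sub-exon gene used across the encoding tests: lengths 100, 100, 100, 100
enc_gene <- function() {
  build_partition(toy_exons("g1", "chr1", "+", list(
    t1 = rbind(c(0, 100), c(200, 300), c(400, 500), c(600, 700)),
    t2 = rbind(c(0, 100), c(400, 500), c(600, 700)),
    t3 = rbind(c(0, 100), c(200, 300), c(600, 700)))))
}

test_that("coverage fractions discretize into the four states", {
  p <- enc_gene()
  # full first sub-exon, 15% of second, 40% of third, none of fourth (in span)
  blocks <- tibble::tibble(start = c(0, 200, 400, 680),
                           end = c(100, 215, 440, 700))
  e <- encode_read(blocks, p, read_id = "r1")
  expect_equal(e$coverage_fractions, c(1, 0.15, 0.40, 0.20))
  expect_equal(e$states, c("covered", "skipped", "ambiguous", "skipped"))
})

test_that("sub-exons outside the aligned span are unobserved, not skipped", {
  p <- enc_gene()
  blocks <- tibble::tibble(start = c(400, 600), end = c(500, 700))  # 5' truncated
  e <- encode_read(blocks, p)
  expect_equal(e$states, c("unobserved", "unobserved", "covered", "covered"))
  expect_equal(e$aligned_span, c(400, 700))
})

test_that("exact boundary fractions respect > 0.6 and <= 0.2", {
  p <- build_partition(toy_exons("g", "chr1", "+",
                                 list(t1 = rbind(c(0, 100), c(200, 300)))))
  at60 <- encode_read(tibble::tibble(start = c(0, 200), end = c(60, 300)), p)
  expect_equal(at60$states[1], "ambiguous")   # exactly 0.6 is not covered
  at20 <- encode_read(tibble::tibble(start = c(0, 200), end = c(20, 300)), p)
  expect_equal(at20$states[1], "skipped")     # exactly 0.2 is skipped
})

test_that("reads outside the gene span raise a structured error", {
  p <- enc_gene()
  expect_error(encode_read(tibble::tibble(start = 5000, end = 5100), p),
               class = "isousage_no_overlap")
})

test_that("compatibility excludes on covered-absent and skipped-present", {
  p <- enc_gene()
  # read covers sub-exons 1 and 3, skips 2, beyond span for 4
  e <- structure(list(read_id = "r", states = c("covered", "skipped",
                                                "covered", "unobserved"),
                      coverage_fractions = c(1, 0, 1, 0),
                      aligned_span = c(0, 500), aligned_bases = 200L,
                      gene_id = "g1"),
                 class = "read_encoding")
  compat <- filter_compatible(e, p)
  # t1 has sub-exon 2 (skipped) -> excluded; t3 lacks 3 (covered) -> excluded
  expect_equal(compat, "t2")
})

test_that("truncation tolerance: unobserved sub-exons never exclude", {
  p <- enc_gene()
  e <- structure(list(read_id = "r",
                      states = c("unobserved", "covered", "covered", "covered"),
                      coverage_fractions = c(0, 1, 1, 1),
                      aligned_span = c(200, 700), aligned_bases = 300L,
                      gene_id = "g1"),
                 class = "read_encoding")
  expect_true("t1" %in% filter_compatible(e, p))
})

test_that("raising the sub-exon length threshold never shrinks the compatible set", {
  set.seed(31)
  for (rep in 1:40) {
    p <- random_toy_gene()
    e <- random_encoding(p)
    prev <- filter_compatible(e, p, 0)
    for (thr in c(10, 20, 40, 80, 200)) {
      cur <- filter_compatible(e, p, thr)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("the dynamic threshold cap is min(80, mean sub-exon length)", {
  # sub-exon lengths (50, 10, 200): mean 86.7 -> cap 80
  p <- build_partition(toy_exons("g", "chr1", "+", list(
    t1 = rbind(c(0, 50), c(100, 110), c(200, 400)),
    t2 = rbind(c(0, 50), c(200, 400)))))
  expect_equal(isousage:::subexon_lengths(p), c(50, 10, 200))
  # a read covering only sub-exon 2 stays incompatible with both isoforms at
  # every threshold; the recorded threshold is the cap
  e <- structure(list(read_id = "r",
                      states = c("skipped", "covered", "skipped"),
                      coverage_fractions = c(0, 1, 0),
                      aligned_span = c(0, 400), aligned_bases = 10L,
                      gene_id = "g"),
                 class = "read_encoding")
  cs <- assign_with_dynamic_threshold(e, p)
  expect_equal(cs$threshold_used, 80)
  # mean sub-exon length below 80 caps at the mean instead
  p2 <- build_partition(toy_exons("g", "chr1", "+", list(
    t1 = rbind(c(0, 30), c(100, 130)), t2 = cbind(0, 30))))
  e2 <- structure(list(read_id = "r", states = c("skipped", "skipped"),
                       coverage_fractions = c(0, 0),
                       aligned_span = c(0, 130), aligned_bases = 5L,
                       gene_id = "g"),
                  class = "read_encoding")
  cs2 <- assign_with_dynamic_threshold(e2, p2)
  expect_equal(cs2$threshold_used, 30)
})

test_that("a read compatible with one isoform stops at threshold 0", {
  p <- enc_gene()
  e <- structure(list(read_id = "r", states = c("covered", "skipped",
                                                "covered", "covered"),
                      coverage_fractions = c(1, 0, 1, 1),
                      aligned_span = c(0, 700), aligned_bases = 300L,
                      gene_id = "g1"),
                 class = "read_encoding")
  cs <- assign_with_dynamic_threshold(e, p)
  expect_true(cs$unique)
  expect_equal(cs$compatible_isoforms, "t2")
  expect_equal(cs$threshold_used, 0)
})

test_that("a small-sub-exon mismatch is forgiven once the threshold passes it", {
  # 12 bp middle sub-exon: a read skipping it conflicts with t1 (which has
  # it) at thresholds 0 and 10, and becomes uniquely t1 at 20 once the
  # 12 bp sub-exon stops being informative
  p <- build_partition(toy_exons("g", "chr1", "+", list(
    t1 = rbind(c(0, 150), c(300, 312), c(400, 550)),
    t2 = rbind(c(0, 150), c(400, 550), c(600, 750)))))
  e <- structure(list(read_id = "r",
                      states = c("covered", "skipped", "covered", "skipped"),
                      coverage_fractions = c(1, 0, 1, 0),
                      aligned_span = c(0, 750), aligned_bases = 300L,
                      gene_id = "g"),
                 class = "read_encoding")
  expect_length(filter_compatible(e, p, 0), 0)   # both vetoed
  expect_length(filter_compatible(e, p, 10), 0)
  expect_equal(filter_compatible(e, p, 20), "t1")
  cs <- assign_with_dynamic_threshold(e, p)
  expect_true(cs$unique)
  expect_equal(cs$compatible_isoforms, "t1")
  expect_equal(cs$threshold_used, 20)
})

test_that("ties break on fewest unmapped exons, then transcript id", {
  p <- enc_gene()
  e <- structure(list(read_id = "r", states = c("covered", "covered",
                                                "unobserved", "unobserved"),
                      coverage_fractions = c(1, 1, 0, 0),
                      aligned_span = c(0, 300), aligned_bases = 200L,
                      gene_id = "g1"),
                 class = "read_encoding")
  # t1 (1,1,1,1): 2 unmapped; t3 (1,1,0,1): 1 unmapped -> t3
  expect_equal(break_ties(c("t1", "t3"), e, p), "t3")
  # equal unmapped counts -> lexicographic
  trans <- list(za = c(1L, 1L, 0L, 0L), ab = c(1L, 1L, 0L, 0L))
  expect_equal(break_ties(c("za", "ab"), e, p, transcripts = trans), "ab")
})

test_that("tie-breaking matches exhaustive counting on random fixtures", {
  set.seed(13)
  for (rep in 1:30) {
    p <- random_toy_gene(max_isoforms = 5)
    e <- random_encoding(p)
    compat <- names(p$transcripts)
    if (length(compat) < 2) next
    got <- break_ties(compat, e, p)
    counts <- sapply(p$transcripts, function(v) {
      sum(v == 1L & e$states != "covered")
    })
    best <- min(counts)
    want <- sort(names(counts)[counts == best])[1]
    expect_equal(got, want)
  }
})

test_that("dynamic thresholding agrees with brute-force enumeration", {
  set.seed(17)
  for (rep in 1:200) {
    p <- random_toy_gene()
    e <- random_encoding(p)
    got <- assign_with_dynamic_threshold(e, p)
    want <- oracle_dynamic(e, p)
    expect_setequal(got$compatible_isoforms, want$isoforms)
    expect_equal(got$threshold_used, want$threshold)
    expect_equal(got$unique, want$unique)
  }
})
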