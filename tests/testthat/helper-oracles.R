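# Independent brute-force oracles and random fixture generators.
# These deliberately re-derive results from first principles, without
# reusing the package's internal code paths.

# ---- random toy genes -------------------------------------------------------

# a random gene: <= max_subexons sub-exons, <= max_isoforms distinct isoforms
random_toy_gene <- function(max_subexons = 6, max_isoforms = 5,
                            min_subexons = 2) {
  n_se <- sample(min_subexons:max_subexons, 1)
  lens <- sample(c(5, 12, 30, 60, 120, 250), n_se, replace = TRUE)
  starts <- cumsum(c(100, head(lens, -1) + sample(50:300, n_se - 1, replace = TRUE)))
  sub_exons <- tibble::tibble(start = starts, end = starts + lens)
  k <- sample(1:max_isoforms, 1)
  vecs <- unique(lapply(seq_len(k + 3), function(i) {
    v <- rbinom(n_se, 1, 0.6)
    if (!any(v == 1)) v[sample(n_se, 1)] <- 1L
    as.integer(v)
  }))
  vecs <- vecs[seq_len(min(k, length(vecs)))]
  transcripts <- setNames(vecs, sprintf("t%02d", seq_along(vecs)))
  isousage:::new_partition("toy", "chrT", "+", sub_exons, transcripts,
                           "annotation_only")
}

# a random encoding consistent with a partition (arbitrary states)
random_encoding <- function(partition) {
  n <- nrow(partition$sub_exons)
  states <- sample(c("covered", "skipped", "ambiguous", "unobserved"), n,
                   replace = TRUE, prob = c(0.45, 0.25, 0.15, 0.15))
  structure(
    list(read_id = paste0("r", sample.int(1e6, 1)), cell_barcode = "bc1",
         umi = "u", gene_id = partition$gene_id, states = states,
         coverage_fractions = ifelse(states == "covered", 1,
                                     ifelse(states == "skipped", 0, 0.4)),
         aligned_span = c(min(partition$sub_exons$start),
                          max(partition$sub_exons$end)),
         aligned_bases = 100L),
    class = "read_encoding")
}

# ---- brute-force compatibility / dynamic threshold --------------------------

oracle_compatible <- function(encoding, partition, min_len) {
  lens <- partition$sub_exons$end - partition$sub_exons$start
  keep <- character(0)
  for (tx in names(partition$transcripts)) {
    v <- partition$transcripts[[tx]]
    ok <- TRUE
    for (i in seq_along(v)) {
      if (lens[i] < min_len) next
      if (encoding$states[i] == "covered" && v[i] == 0) ok <- FALSE
      if (encoding$states[i] == "skipped" && v[i] == 1) ok <- FALSE
    }
    if (ok) keep <- c(keep, tx)
  }
  keep
}

# enumerate every threshold exactly as specified and return the stop point
oracle_dynamic <- function(encoding, partition, step = 10, cap_bp = 80) {
  cap <- min(cap_bp, mean(partition$sub_exons$end - partition$sub_exons$start))
  thresholds <- seq(0, cap, by = step)
  first_multi <- NULL
  for (thr in thresholds) {
    compat <- oracle_compatible(encoding, partition, thr)
    if (length(compat) == 1) {
      return(list(isoforms = compat, threshold = thr, unique = TRUE))
    }
    if (length(compat) > 1 && is.null(first_multi)) {
      first_multi <- list(isoforms = compat, threshold = thr, unique = FALSE)
    }
  }
  if (!is.null(first_multi)) return(first_multi)
  list(isoforms = character(0), threshold = max(thresholds), unique = FALSE)
}

# ---- brute-force interval components (meta-genes) ---------------------------

oracle_components <- function(spans) {
  n <- nrow(spans)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && spans$chrom[i] == spans$chrom[j] &&
        spans$start[i] < spans$end[j] && spans$start[j] < spans$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# ---- Dirichlet-multinomial grid oracle --------------------------------------

# best log-likelihood on a 3-D alpha lattice, computed from scratch via
# per-component tables (exact same likelihood definition, independent code)
oracle_dm_grid <- function(X, grid = seq(0.2, 8, by = 0.1)) {
  stopifnot(ncol(X) == 3)
  nvec <- rowSums(X)
  step <- grid[2] - grid[1]
  fk <- sapply(grid, function(a) colSums(lgamma(X + a) - lgamma(a)))
  # the S-term depends only on sum(alpha); tabulate it on the induced lattice
  svals <- seq(3 * grid[1], 3 * max(grid), by = step)
  sterm <- vapply(svals, function(S) sum(lgamma(S) - lgamma(nvec + S)),
                  numeric(1))
  pair_f <- outer(fk[1, ], fk[2, ], "+")
  pair_s <- outer(grid, grid, "+")
  best <- -Inf
  for (k in seq_along(grid)) {
    idx <- round((pair_s + grid[k] - svals[1]) / step) + 1L
    tot <- pair_f + fk[3, k] + sterm[idx]
    best <- max(best, max(tot))
  }
  best
}

# ---- misc -------------------------------------------------------------------

# exon tibble for a toy gene defined by a list of (start, end) exon matrices
toy_exons <- function(gene_id, chrom, strand, tx_list) {
  purrr::imap_dfr(tx_list, function(m, tx) {
    tibble::tibble(gene_id = gene_id, transcript_id = tx, chrom = chrom,
                   strand = strand, start = m[, 1], end = m[, 2])
  })
}
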