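# isousage

Isoform-level quantification and differential transcript usage (DTU)
testing for long-read single-cell RNA-seq.

Long reads span whole transcripts, so a single-cell long-read experiment
can, in principle, resolve *which isoform* each molecule came from — not
just which gene. In practice this is hard: nanopore reads carry alignment
noise and 5' truncations, isoforms share most of their exons, genes
overlap, and per-cell counts are tiny. `isousage` addresses the full chain
for users of tagged-BAM output from vendor single-cell pipelines
(wf-single-cell, Iso-Seq, Parse):

1. **Sub-exon gene models.** Each gene's exons are partitioned into
   non-overlapping sub-exons bounded by every annotated exon boundary, so
   each isoform is a binary vector over sub-exons. Read coverage can
   refine the model (novel junctions, sharp coverage changes, candidate
   novel exons) or define it from scratch.
2. **Read-isoform assignment.** A read covers a sub-exon at > 60% of its
   length, skips it at ≤ 20%; sub-exons beyond the read's aligned span are
   neutral (truncation tolerance). Isoforms conflicting with covered or
   skipped sub-exons are excluded, with a gene-specific *dynamic
   threshold* (0 → min(80 bp, mean sub-exon length) in 10 bp steps) that
   ignores small, error-prone sub-exons until the mapping becomes unique.
3. **Novel isoform discovery.** Reads compatible with no known isoform are
   clustered at pseudo-bulk level in batches of ≤ 1500 via a weighted
   read-read agreement graph and Louvain communities; community consensus
   vectors become novel isoforms, pruned for redundancy, and must exceed
   20 supporting reads to be reported.
4. **Counting.** Gene × cell and transcript × cell sparse matrices
   (10x-style MatrixMarket triplets) with exact read-count conservation
   and per-read fate accounting.
5. **DTU statistics.** Per gene, transcript counts per cell follow a
   Dirichlet-multinomial: X<sub>c</sub> ~ Multinomial(n<sub>c</sub>,
   π<sub>c</sub>), π<sub>c</sub> ~ Dirichlet(α), with average usage
   π̄<sub>k</sub> = α<sub>k</sub>/Σα<sub>i</sub> and mean-invariant
   over-dispersion φ = 1/(1+Σα<sub>i</sub>) capturing whether cells
   co-express isoforms (small φ) or each commit to one (large φ).
   Likelihood-ratio tests compare populations at the gene level
   (H<sub>0</sub>: shared π̄, group-specific φ; χ² with K−1 df) and per
   transcript (only component k constrained; χ² with 1 df), with
   Benjamini-Hochberg correction, rare-isoform (≤ 5%) aggregation,
   isoform-switching calls and effect sizes.

A ground-truth simulator (per-gene Gamma-drawn Dirichlet concentrations,
Uniform(0,15)-Poisson per-cell depth, configurable error and 5'-truncation
models, held-out "novel" isoforms, planted DTU genes) plus an evaluation
module make every stage testable end to end with no external data.

## Worked example

Simulate a small two-population dataset, run the pipeline, and test DTU:

```r
library(isousage)

sim <- simulate_dataset(n_genes = 12, n_cells = 30, error_rate = 0.01,
                        truncation_prob = 0.3, seed = 42)
sim
#> <sim_dataset> 12 genes (6 DTU), 60 cells, 5573 reads (1587 from held-out isoforms)

res <- run_pipeline(sim$reads, sim$annotation)
res
#> <pipeline_result>
#>   read fate: assigned_known=4045, assigned_novel=1528, uncategorized=0, dropped_no_gene=0
#>   11 novel isoforms (11 categorized)

dtu <- dtu_test(res$counts, sim$cells)
dtu
#> <dtu_results> A vs B: 12 genes tested (0 excluded), 3 with padj <= 0.01

head(tidy(dtu)[, c("gene_id", "statistic", "p_gene", "padj_gene",
                   "switching", "effect_size")], 5)
#> # A tibble: 5 × 6
#>   gene_id statistic  p_gene padj_gene switching effect_size
#>   <chr>       <dbl>   <dbl>     <dbl> <lgl>           <dbl>
#> 1 gene001     2.42  0.120      0.180  TRUE            0.219
#> 2 gene002     3.92  0.0478     0.0819 TRUE            0.264
#> 3 gene003     8.61  0.00335    0.0100 FALSE          NA
#> 4 gene004     0.785 0.376      0.451  FALSE          NA
#> 5 gene005     1.00  0.317      0.423  FALSE          NA

evaluate_pipeline(sim, res, dtu = dtu)
#> mapping_accuracy 0.982, novel_precision 1.000, novel_recall 0.963,
#> annotation_rate 1.000, transcript_spearman 0.997, dtu_precision 1.000, ...
```

Reading it: all 5,573 simulated reads were assigned (fate accounting always
sums to the input); 11 novel isoforms were discovered and all passed the
20-read support rule; 3 of 12 genes show significant DTU at padj ≤ 0.01
(the planted effect sizes vary, so not every DTU gene is detectable at 30
cells per population); the per-read mapping accuracy against ground truth
is 0.982. `autoplot(dtu)` draws the effect-size vs significance overview
and `plot_transcript_usage(dtu, "gene003")` the per-isoform usage bars.
`fit_dm()` fits a single gene's Dirichlet-multinomial directly and has
`tidy()`/`glance()` methods.

Real data enters through `read_tagged_bam("sample.bam")` (CB/UB tags,
configurable) and `read_gtf_exons("annotation.gtf")`; a command-line
wrapper for the annotate / run / dtu / simulate steps ships in
`inst/cli/isousage.R`.

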