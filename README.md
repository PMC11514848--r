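# ernatools

Offline identification and functional annotation of enhancer RNAs (eRNAs).

Active enhancers are transcribed, and the resulting eRNAs are useful handles
on enhancer activity — but they are short-lived, weakly expressed, and
absent from standard gene annotation, so they must be called from de novo
assembled transcriptomes and annotated indirectly, through the
protein-coding genes (PCGs) they are wired to. `ernatools` implements that
whole path as composable R functions plus a thin command-line wrapper, for
genomics researchers who have a de novo assembly (RNA-seq or GRO-seq
derived GTF) and enhancer evidence (marker peak BEDs) in hand and no wish
to depend on a web service or hosted datasets.

## What it computes

**Identification.** Transcripts are filtered out when their span overlaps
(>= 1 bp, strand-agnostic) an annotated PCG, a simple repeat, or a
blacklisted region; survivors are gated by coding potential (an external
label table, or a built-in longest-ORF rule: coding iff the longest
ATG..stop run over the three forward frames is >= 100 aa). Enhancer regions
come from a "marker buffet": each marker interval (H3K27ac, H3K4me1,
accessibility, RNAPII, curated enhancer catalogs, ...) is expanded to the
±3 kb window around its center, then the windowed sets are either merged
(comprehensive) or multi-intersected so only positions covered by >=
*k* distinct marker sets survive (high-confidence). A noncoding transcript
whose TSS lies inside an enhancer region is an eRNA; adjacent genes within
±1 Mb (closest-edge distance) are reported as putative targets.

**Quantification.** Expression is computed from coverage tracks
(bedGraph) rather than read counting:

    FPKM = Σ(Cov) · 10⁹ / (R · L · T)

where Σ(Cov) is the summed per-base read coverage over the feature, *R*
the read length, *L* the feature length (exonic length for transcripts),
and *T* the library's total mapped reads. For reads fully contained in the
feature this equals count-based FPKM exactly.

**Networks and function.** For every (eRNA, PCG) pair the Spearman
correlation ρ (Pearson correlation of mid-ranks) is tested with the
two-sided t approximation t = ρ√((n−2)/(1−ρ²)) on n−2 df (exact
permutation p available for n ≤ 9) and Benjamini–Hochberg adjusted; edges
with |ρ| ≥ 0.3 and q ≤ 0.05 (user-tunable) form the co-expression network.
A regulatory network adds TF/RBP edges (peaks overlapping the eRNA span)
and enhancer–promoter loop edges (one anchor on the eRNA, the other on a
gene's ±2 kb promoter window); networks can be intersected node- and
edge-wise. Dense modules are extracted by an unweighted greedy
seed-and-expand (SPICi-style; density and support thresholds 0.5), hubs by
a degree-quantile rule, and function is transferred to an eRNA by
hypergeometric enrichment of its connected PCGs against GMT gene sets:

    P(X ≥ k) = Σ_{i≥k} C(K,i) C(N−K, n−i) / C(N,n)

**Synthetic fixtures.** `fixture_spec()` / `write_fixtures()` generate
every input format the toolkit reads — toy genome GTFs, marker/repeat/
blacklist BEDs, sequences, coverage bedGraphs with known read placements,
expression matrices with planted rank correlation, GMT sets — together
with truth tables, so the full pipeline runs and is testable offline.

## Worked example

```r
library(ernatools)

dir <- "demo"
write_fixtures(dir, fixture_spec(seed = 1, preset = "tiny"))

tx  <- read_gtf_transcripts(file.path(dir, "transcripts.gtf"))
enh <- combine_markers(
  list(H3K27ac = read_bed(file.path(dir, "marker_H3K27ac.bed")),
       ATAC    = read_bed(file.path(dir, "marker_ATAC.bed"))),
  mode = "overlap", min_support = 2)
enh
#>   chrom  start    end         name score strand
#> 1  chrS 417200 423000 ATAC,H3K27ac     2      .
#> 2  chrS 457200 463000 ATAC,H3K27ac     2      .
#> 3  chrS 497200 503000 ATAC,H3K27ac     2      .
```

Three enhancer regions: positions covered by both windowed marker sets,
with the supporting labels in `name`. Running identification:

```r
res <- run_erna_id(
  tx, enh,
  pcg       = transcript_spans(read_gtf_transcripts(file.path(dir, "pcg.gtf"))),
  repeats   = read_bed(file.path(dir, "repeats.bed")),
  blacklist = read_bed(file.path(dir, "blacklist.bed")),
  coding    = classify_coding(tx, method = "external_table",
                              table = file.path(dir, "coding_table.tsv")),
  genes     = read_bed(file.path(dir, "genes.bed")))
res$calls[, c("transcript_id", "chrom", "start", "end", "strand", "markers")]
#>   transcript_id chrom  start    end strand      markers
#> 1        ERNA01  chrS 420446 421246      + ATAC,H3K27ac
#> 2        ERNA02  chrS 459348 460148      - ATAC,H3K27ac
#> 3        ERNA03  chrS 500945 501745      + ATAC,H3K27ac
```

Of the 14 transcripts in the assembly, the 5 PCG copies and 4 of the 6
decoys are removed by the overlap filters, one intergenic coding decoy
falls to the coding gate, one intergenic noncoding decoy survives both
gates but starts outside every enhancer, and exactly the three transcripts
transcribed from enhancer regions are called. Their co-expression interactome:

```r
edges <- spearman_edges(read_expression(file.path(dir, "erna_expr.tsv")),
                        read_expression(file.path(dir, "pcg_expr.tsv")))
net <- build_coexpression_network(edges)   # |rho| >= 0.3, q <= 0.05
net$edges[, c("source", "target", "rho", "p", "q")]
#>   source target       rho           p           q
#> 1 ERNA01 GENE01 0.8111888 0.001363315 0.009501839
#> 2 ERNA02 GENE02 0.7972028 0.001900368 0.009501839
#> 3 ERNA03 GENE03 0.7972028 0.001900368 0.009501839

fpkm(1e6, read_length = 100, total_reads = 1e7, length = 1000)
#> [1] 1000
```

Each planted eRNA recovers its planted PCG partner (target rank
correlation 0.8) and nothing else. `extract_modules(net)`,
`extract_hubs(net)` and `annotate_erna("ERNA01", net, collection = ...)`
continue to module extraction and enrichment; `?annotate_erna` shows the
three query strategies.

The same pipeline is available from a shell via `inst/scripts/erna`
(`erna fixtures | buffet | id | quantify | coexpr | annotate`).

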