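---
title: "Identifying and annotating enhancer RNAs with ernatools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and annotating enhancer RNAs with ernatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernatools)
```

# The problem

Enhancer RNAs (eRNAs) are noncoding transcripts produced from active
enhancers. They mark enhancer activity and often correlate with, or
participate in, the regulation of nearby and distal protein-coding genes
(PCGs). Because eRNAs are unannotated, unstable and lowly expressed, they
are recovered from de novo transcriptome assemblies, and their functions
cannot be read off directly — they are inferred from the company an eRNA
keeps: co-expressed PCGs, transcription factors (TFs) and RNA-binding
proteins (RBPs) with binding peaks on the eRNA locus, and
enhancer–promoter (E–P) chromatin loops anchored on it.

`ernatools` implements this workflow in two arms: identification (filter,
coding gate, enhancer intersection) and annotation (quantification,
networks, modules, enrichment), plus a synthetic-fixture generator that
makes the whole pipeline runnable and testable offline.

# Coordinate model

Every interval in the package is 0-based half-open (`start` inclusive,
`end` exclusive), the native BED convention. GTF input (1-based inclusive)
is converted on read and restored on write. A single convention everywhere
removes the usual off-by-one hazards at BED/GTF boundaries; the trade-off
is that printed coordinates differ by one from what a GTF-centric tool
would show for the same feature. Overlap is strand-agnostic throughout —
strand is carried but never used for intersection — and any shared base
(>= 1 bp) counts as an overlap; no minimum overlap fraction is applied
anywhere. Chromosome names match by exact string equality (no "chr"
aliasing); a preflight warning fires when two inputs share no chromosome
names, which catches mismatched naming styles early instead of silently
returning empty results.

# Identification

## Enhancer regions from the marker buffet

Users supply one or more marker interval sets — histone marks, chromatin
accessibility, polymerase binding, curated enhancer catalogs. Each marker
interval is reduced to its integer center `floor((start + end) / 2)`
(deterministic for even-length intervals) and expanded to a ±`flank`
window, 3000 bp by default: enhancer-scale resolution around the evidence
summit. Windows clamp at zero on the left; no right clamp is applied
because assembly bounds are not part of the marker files.

Two combination modes exist. *Merge* unions all windowed intervals
(book-ended pieces merge, matching the default behavior of the standard
interval toolkits) — the comprehensive catalog. *Overlap* keeps only
positions covered by at least `min_support` distinct marker sets
(default 2) — the high-confidence catalog. The overlap product keeps
fragment boundaries where the supporting label set changes
(multi-intersection semantics); each emitted region carries its supporting
labels. Windowing precedes combination, i.e. the ±3 kb expansion applies
to each marker before any intersection, and uniformly to every marker
class; the alternative order (combine, then window) shifts boundaries by
at most one flank and is not offered, to keep the semantics single-valued.
Both mode and `min_support` are exposed on the API and the CLI because the
"right" stringency is a property of the user's marker panel, not of the
method.

## Filtering and the coding gate

A de novo assembly contains mostly things that are not eRNAs. Transcripts
whose span overlaps an annotated PCG, a simple repeat, or a blacklisted
region are removed; span-level overlap is the default (conservative
removal — an intronic repeat removes the transcript), with `level =
"exon"` available when exon-level precision is wanted. The removal log
records one reason per transcript with fixed precedence PCG → repeats →
blacklist; precedence affects only the log, never the retained set.

The coding-potential gate is pluggable. The expected production path is an
external classifier run outside the toolkit, delivered as a two-column
transcript/label table. The built-in fallback labels a transcript coding
when its longest ATG-to-stop open reading frame, scanned over the three
forward frames of the transcript sequence, reaches `orf_min` = 100 amino
acids — the conventional lncRNA/mRNA discrimination threshold. The
fallback is a deliberately simple, fully specified rule, not a
reimplementation of any published classifier, and its threshold is a flag.

## Calling

A noncoding transcript is an eRNA when it is transcribed from an enhancer:
by default its TSS (span start on `+`/`.`, `end − 1` on `−`) must lie
inside an enhancer region. The laxer `any_overlap` rule (>= 1 bp span
overlap) is offered as a flag and provably calls a superset of the TSS
rule. Putative targets are genes within ±1 Mb by closest-edge distance
(`max(0, max(starts) − min(ends))`, 0 for overlap or abutment) — edges
rather than centers, so a 100-kb gene body is not penalized for its
length.

# Quantification

Expression is computed from coverage tracks rather than read counting:

$$\mathrm{FPKM} = \frac{\Sigma(\mathrm{Cov}) \times 10^9}{R \cdot L \cdot T}$$

with Σ(Cov) the summed per-base coverage over the feature (exons only for
transcripts, with L the exonic length), R the read length, T the library's
total mapped reads. Since a read contributes exactly its in-feature bases
to Σ(Cov), fully contained reads give Σ(Cov) = count × R and the formula
reduces to count-based FPKM exactly; reads straddling a feature edge lose
up to R − 1 bases each, bounding the relative deviation for uniform
placements by (R − 1)/L. Both properties are tested against simulated read
placements with known counts. bedGraph is the required track format
because it is plain text and encodes the step function exactly. For
paired-end libraries R should be the mean mapped read length and T counts
mapped reads, not fragments. No normalization beyond FPKM and no
multimapping correction is attempted.

# Networks

## Co-expression

For every (eRNA, PCG) pair — deliberately not PCG × PCG; the object of
interest is the eRNA interactome — the Spearman correlation is the Pearson
correlation of mid-ranks (average ranks on ties). The two-sided p-value
uses the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on n − 2
degrees of freedom, the standard choice for n beyond ~10; an exact
permutation p (proportion of the n! permutations reaching the observed
|ρ|) is available for n ≤ 9, where the approximation is visibly off: at
n = 4 and ρ = 0.8 the t approximation gives p = 0.2 while the exact
two-sided p is 1/3. Zero-variance features yield NaN and are excluded from
every downstream step, including the adjustment family.

"Adjusted p" is Benjamini–Hochberg by default (the field's default FDR
control; Bonferroni available), applied globally across all computed pairs
rather than per eRNA — one family, one error rate; a per-eRNA scope would
make an edge's q depend on how many partners its eRNA was tested against.
Edges pass at |ρ| ≥ `rho_min` (0.3) and q ≤ `q_max` (0.05); both are
conventional, overridable defaults for what is inherently a user-defined
cutoff.

## Regulatory edges and intersection

TFs and RBPs become regulators of an eRNA when at least one of their peaks
overlaps the eRNA span; multiple peaks collapse to one edge with the peak
count as evidence. A loop links an eRNA to a gene when one anchor overlaps
the eRNA span and the other overlaps the gene's promoter window, ±2 kb of
the TSS — a promoter-scale default for resolving which gene a loop anchor
serves, exposed as `promoter_flank`. Loops anchored on an eRNA that
resolve to no promoter are still reported (as eRNA-mediated loops) but
contribute no edge. Network intersection takes the node-id intersection
and the unordered node-pair intersection of edges, regardless of edge
kind, recording both kinds in the evidence column — so a co-expression
edge and a loop edge over the same pair corroborate each other.

# Modules, hubs and enrichment

Dense modules are extracted by a greedy seed-and-expand in unweighted
mode: seed on the unclustered node of highest remaining degree, pair it
with its best unclustered neighbor, then repeatedly add the candidate of
highest support (fraction of current members it touches), accepting while
support ≥ 0.5 and density `2e/(k(k−1))` ≥ 0.5, both thresholds from the
published defaults of the SPICi algorithm this procedure follows, both exposed as flags. Emitted
clusters are removed and the process repeats until no edges remain;
singletons are discarded. In unweighted mode all neighbors weigh equally,
so "best" is resolved purely by the deterministic lexicographic tie-break
used everywhere in the procedure; this resolves a pair of 4-cliques joined
by a bridge edge into exactly the two cliques. Hubs have no agreed
definition; the package's rule — degree at or above
`max(min_degree, (1 − top_fraction))` degree quantile, defaults 5 and
0.05 — is documented as this package's own convention.

Function transfers to an eRNA by hypergeometric enrichment
$P(X \ge k) = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$
of three query lists: direct PCG neighbors, PCG members of each module
containing the eRNA, and PCG hubs adjacent to it. BH adjustment runs
within each collection (GO, KEGG and hallmark-style collections form
separate families, mirroring how such panels are reported separately).
The default universe is the GMT universe united with the network's PCGs —
a network-restricted background would inflate significance for queries
drawn from the network itself; `universe` overrides it. No ontology-graph
propagation is performed: sets are used exactly as supplied.

# The synthetic fixtures

The generator emulates the study conditions the toolkit is designed for,
at desk scale, and is itself first-class, tested code. One toy chromosome
is laid out in fixed 40-kb slots: two-exon 3-kb PCGs; repeat and blacklist
regions; enhancer slots whose center carries a peak in each of two marker
sets (H3K27ac-like and ATAC-like, so both overlap and merge combination
cover them); planted eRNAs (two exons, 800-bp span, alternating strand)
with TSS jittered uniformly within ±2 kb of an enhancer center — inside
the ±3 kb windows under either combination mode; and decoys cycling
through five failure modes (PCG/repeat/blacklist overlap, intergenic
noncoding, intergenic coding). Coding fixture sequences carry an ATG..stop
ORF far above threshold; noncoding sequences are drawn from the A/C/T
alphabet — no G means no ATG and an ORF length of exactly 0, so the
coding-gate ground truth holds by construction rather than by filtering
candidates through the very classifier under test.

Expression matrices plant each non-null eRNA–PCG pair on a shared latent
Gaussian with independent noise; the noise scale is calibrated per pair by
grid search on the realized vectors so the empirical Spearman correlation
lands on the target (0.8 by default) — an empirical, distribution-free
calibration rather than an analytic attenuation formula. `noise_sd`
governs the null features. A monotone `2^x` transform makes values
positive and expression-like without touching any rank statistic. Read
simulation places uniform reads per region (Poisson counts) and emits the
exact per-base coverage as bedGraph together with the true counts, so the
coverage and counting FPKM routes can be cross-validated; the library T is
the sample's simulated read count. Every generator is a pure function of
the `fixture_spec` — the same seed reproduces every output byte, and the
caller's RNG stream is left untouched.

The presets state the standard conditions: `tiny` (5 PCGs, 3 planted
eRNAs, 6 decoys, 12 samples) for end-to-end identification;
`default` (20/8/12/50); `network-heavy` (20 PCGs, 26 eRNAs of which 20
carry planted partners — 20 planted among 500 null pairs — 50 samples)
for co-expression recovery, where the planted signal at ρ = 0.8 and
n = 50 should be recovered essentially completely at default thresholds
with empirical FDR near the nominal 0.05. Oracle sweeps in the tests use
50 random 10 × 12 matrix pairs (correlation), 1000 random p-vectors
(adjustment), 200 random 12-node graphs (modules), all (N ≤ 25, K, n, k)
configurations (enrichment) and 100 simulated regions (quantification) —
sizes chosen to exercise the combinatorics densely while keeping the whole
suite under a minute per module.

What passing these fixtures does *not* show: the generator has no read
errors, GC or mappability structure, no overdispersion or batch structure
in expression, no correlated marker noise, and its decoys are
unambiguous. Results on real assemblies depend on assembly quality, the
marker panel's cell-type match, and the coding classifier used — none of
which the fixtures emulate.

# Degenerate inputs and numerical notes

Empty marker intersections, empty networks and empty enrichment queries
return empty, well-typed results with a warning rather than erroring, so
pipelines degrade visibly but gracefully. `ρ = ±1` maps to p = 0 before
the t statistic would divide by zero; exact-permutation comparisons use a
1e-12 slack on |ρ| so floating-point ties count as ties. BH excludes
NaN/NA from the family size. The hypergeometric tail is computed as an
upper-tail survival value, not `1 − CDF`, avoiding cancellation for small
p. All tie-breaks (module seeding and expansion, hub ordering, adjacency)
are lexicographic, making every procedure deterministic for a given
input.

# Limitations

The toolkit does not assemble transcripts, call peaks, or run any coding
classifier beyond the ORF fallback; it consumes their outputs. BigWig
tracks are not read directly — convert to bedGraph. No liftover, GFF3 or
tabix support. Hub extraction and the loop-promoter assignment rules are
reasonable conventions, not community standards, and are flagged as such
in their documentation.
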