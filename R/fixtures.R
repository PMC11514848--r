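#' Specification of a synthetic fixture set
#'
#' The fixture generator emulates, at toy scale, every input the toolkit
#' consumes: a single-chromosome annotation with protein-coding genes,
#' repeats, blacklist regions and marker-supported enhancers; planted eRNA
#' transcripts whose TSS falls inside an enhancer window; decoy transcripts
#' that must be filtered out; expression matrices with planted rank
#' correlation; and read placements with exact coverage tracks. The seed
#' fully determines every output byte.
#'
#' @param seed integer RNG seed.
#' @param preset `"tiny"` (5 PCGs, 3 planted eRNAs, 6 decoys, 12 samples),
#'   `"default"` (20/8/12/50) or `"network-heavy"` (20 PCGs, 26 planted
#'   eRNAs of which 20 carry a planted expression partner, 50 samples);
#'   individual arguments override preset values.
#' @param n_pcg number of protein-coding genes.
#' @param n_noncoding number of decoy transcripts (cycling through
#'   PCG-overlapping, repeat-overlapping, blacklist-overlapping, intergenic
#'   noncoding and intergenic coding types).
#' @param n_planted_ernas number of planted enhancer-derived transcripts.
#' @param n_samples samples in expression matrices (>= 10).
#' @param planted_rho target Spearman correlation of planted pairs, in
#'   (-1, 1).
#' @param noise_sd noise scale of null expression features.
#' @param fraction_null fraction of planted eRNAs given no expression
#'   partner.
#' @param read_length simulated read length in bp.
#' @param chrom chromosome name of the toy genome.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, preset = c("tiny", "default",
                                               "network-heavy"),
                         n_pcg = NULL, n_noncoding = NULL,
                         n_planted_ernas = NULL, n_samples = NULL,
                         planted_rho = 0.8, noise_sd = 0.5,
                         fraction_null = 0, read_length = 100L,
                         chrom = "chrS") {
  preset <- match.arg(preset)
  base <- switch(preset,
    tiny = list(n_pcg = 5L, n_noncoding = 6L, n_planted_ernas = 3L,
                n_samples = 12L),
    default = list(n_pcg = 20L, n_noncoding = 12L, n_planted_ernas = 8L,
                   n_samples = 50L),
    `network-heavy` = list(n_pcg = 20L, n_noncoding = 10L,
                           n_planted_ernas = 26L, n_samples = 50L)
  )
  if (preset == "network-heavy" && missing(fraction_null))
    fraction_null <- 6 / 26
  spec <- list(
    seed = as.integer(seed), preset = preset,
    n_pcg = as.integer(n_pcg %||% base$n_pcg),
    n_noncoding = as.integer(n_noncoding %||% base$n_noncoding),
    n_planted_ernas = as.integer(n_planted_ernas %||% base$n_planted_ernas),
    n_samples = as.integer(n_samples %||% base$n_samples),
    planted_rho = planted_rho, noise_sd = noise_sd,
    fraction_null = fraction_null, read_length = as.integer(read_length),
    chrom = chrom, slot = 40000L
  )
  stopifnot(spec$n_pcg >= 0, spec$n_noncoding >= 0,
            spec$n_planted_ernas >= 0, spec$n_samples >= 0,
            abs(spec$planted_rho) < 1, spec$fraction_null >= 0,
            spec$fraction_null <= 1)
  structure(spec, class = "fixture_spec")
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Generate the toy genome annotation and marker fixtures
#'
#' Lays out one chromosome in fixed 40-kb slots: protein-coding genes,
#' repeat and blacklist regions, enhancer slots whose center carries a peak
#' in each of two marker sets (H3K27ac and ATAC), planted eRNA transcripts
#' with TSS jittered within +/- 2 kb of an enhancer center (inside the
#' +/- 3 kb marker windows under both overlap and merge combination), and
#' decoy transcripts that the pipeline must reject. The truth table labels
#' every transcript.
#'
#' Noncoding transcript sequences are drawn from the A/C/T alphabet (no G,
#' hence no ATG, hence ORF length 0) so the coding-gate ground truth is
#' guaranteed by construction; coding sequences carry an ATG..stop ORF well
#' above the 100-aa default threshold.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, all fixture files are written
#'   there (transcripts.gtf, pcg.gtf, repeats.bed, blacklist.bed,
#'   marker_H3K27ac.bed, marker_ATAC.bed, genes.bed, coding_table.tsv,
#'   sequences.fa, truth.tsv).
#' @return A list with `transcripts` (transcript table of the de novo
#'   assembly: PCG copies + planted eRNAs + decoys), `pcg_spans`,
#'   `repeats`, `blacklist`, `markers` (buffet list), `genes` (gene spans,
#'   ids in `name`), `sequences` (named character), `coding_table`,
#'   `truth` (`transcript_id`, `class`, `decoy_type`) and `chrom_size`.
#' @export
make_annotation <- function(spec, dir = NULL) {
  with_seed(spec$seed + 1L, make_annotation_impl(spec, dir))
}

make_annotation_impl <- function(spec, dir) {
  W <- spec$slot
  n_rep <- 3L
  n_bl <- 2L
  n_slots <- spec$n_pcg + n_rep + n_bl + spec$n_planted_ernas +
    spec$n_noncoding
  chrom_size <- (n_slots + 1L) * W
  slot_start <- function(i) (i - 1L) * W
  cursor <- 0L
  txs <- list()
  seqs <- character(0)
  truth <- list()
  add_truth <- function(id, class, type = NA_character_)
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = id, class = class, decoy_type = type,
      stringsAsFactors = FALSE)

  # protein-coding genes: 3-kb two-exon genes, alternating strand
  pcg_rows <- list()
  for (i in seq_len(spec$n_pcg)) {
    gs <- slot_start(cursor + i) + 10000L
    strand <- if (i %% 2L) "+" else "-"
    exons <- data.frame(start = c(gs, gs + 2000L), end = c(gs + 1000L,
                                                           gs + 3000L))
    gene_id <- sprintf("GENE%02d", i)
    pcg_rows[[i]] <- make_transcript(gene_id, gene_id, spec$chrom, strand,
                                     exons)
    tx_id <- sprintf("NOV_PCG%02d", i)
    txs[[tx_id]] <- make_transcript(tx_id, tx_id, spec$chrom, strand, exons)
    seqs[tx_id] <- make_coding_seq(2000L)
    add_truth(tx_id, "pcg")
  }
  cursor <- cursor + spec$n_pcg
  pcg_tab <- transcript_table(pcg_rows)
  pcg_spans <- transcript_spans(pcg_tab)
  pcg_spans$name <- pcg_tab$gene_id
  genes <- pcg_spans

  repeats <- genomic_intervals(
    spec$chrom,
    vapply(seq_len(n_rep), function(i) slot_start(cursor + i) + 15000L, 0L),
    vapply(seq_len(n_rep), function(i) slot_start(cursor + i) + 16500L, 0L),
    name = sprintf("rpt%d", seq_len(n_rep)))
  cursor <- cursor + n_rep
  blacklist <- genomic_intervals(
    spec$chrom,
    vapply(seq_len(n_bl), function(i) slot_start(cursor + i) + 15000L, 0L),
    vapply(seq_len(n_bl), function(i) slot_start(cursor + i) + 17000L, 0L),
    name = sprintf("bl%d", seq_len(n_bl)))
  cursor <- cursor + n_bl

  # enhancer slots: both marker sets peak at the slot center
  centers <- integer(0)
  for (j in seq_len(spec$n_planted_ernas)) {
    c0 <- slot_start(cursor + j) + 20000L
    centers <- c(centers, c0)
    tss <- c0 + sample(-2000:2000, 1L)
    strand <- if (j %% 2L) "+" else "-"
    span <- if (strand == "+") c(tss, tss + 800L) else c(tss - 799L,
                                                         tss + 1L)
    exons <- data.frame(start = span[1] + c(0L, 500L),
                        end = span[1] + c(300L, 800L))
    tx_id <- sprintf("ERNA%02d", j)
    txs[[tx_id]] <- make_transcript(tx_id, tx_id, spec$chrom, strand, exons)
    seqs[tx_id] <- make_noncoding_seq(600L)
    add_truth(tx_id, "planted_erna")
  }
  cursor <- cursor + spec$n_planted_ernas
  markers <- if (length(centers)) list(
    H3K27ac = genomic_intervals(spec$chrom, centers - 500L, centers + 500L,
                                name = sprintf("k27_%d", seq_along(centers))),
    ATAC = genomic_intervals(spec$chrom, centers - 300L, centers + 700L,
                             name = sprintf("atac_%d", seq_along(centers)))
  ) else list(H3K27ac = empty_intervals(), ATAC = empty_intervals())

  # decoys: transcripts the pipeline must reject
  types <- c("overlap_pcg", "overlap_repeat", "overlap_blacklist",
             "intergenic_noncoding", "intergenic_coding")
  for (d in seq_len(spec$n_noncoding)) {
    type <- types[((d - 1L) %% length(types)) + 1L]
    tx_id <- sprintf("DECOY%02d", d)
    own <- slot_start(cursor + d)
    span_start <- switch(type,
      overlap_pcg = if (spec$n_pcg)
        pcg_tab$start[((d - 1L) %% spec$n_pcg) + 1L] + 500L else own + 5000L,
      overlap_repeat = repeats$start[((d - 1L) %% n_rep) + 1L] - 200L,
      overlap_blacklist = blacklist$start[((d - 1L) %% n_bl) + 1L] - 200L,
      own + 5000L)
    exons <- data.frame(start = span_start, end = span_start + 800L)
    strand <- if (d %% 2L) "+" else "-"
    txs[[tx_id]] <- make_transcript(tx_id, tx_id, spec$chrom, strand, exons)
    seqs[tx_id] <- if (type == "intergenic_coding") make_coding_seq(800L)
    else make_noncoding_seq(800L)
    add_truth(tx_id, type)
  }
  truth <- do.call(rbind, truth)
  is_decoy <- truth$class %in% types
  truth$decoy_type[is_decoy] <- truth$class[is_decoy]
  truth$class[is_decoy] <- "decoy"
  transcripts <- transcript_table(txs)
  coding_table <- data.frame(
    transcript_id = transcripts$transcript_id,
    label = ifelse(vapply(seqs[transcripts$transcript_id], longest_orf_aa,
                          0L) >= 100L, "coding", "noncoding"),
    stringsAsFactors = FALSE
  )
  out <- list(transcripts = transcripts, pcg_spans = pcg_spans,
              repeats = repeats, blacklist = blacklist, markers = markers,
              genes = genes, sequences = seqs, coding_table = coding_table,
              truth = truth, chrom_size = chrom_size)
  if (!is.null(dir)) write_annotation_fixtures(out, dir)
  out
}

#' @keywords internal
write_annotation_fixtures <- function(ann, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf_transcripts(ann$transcripts, p("transcripts.gtf"))
  pcg_tx <- ann$pcg_spans
  # pcg annotation as single-exon GTF over gene spans
  pcg_tab <- transcript_table(lapply(seq_len(nrow(pcg_tx)), function(i)
    make_transcript(pcg_tx$name[i], pcg_tx$name[i], pcg_tx$chrom[i],
                    pcg_tx$strand[i],
                    data.frame(start = pcg_tx$start[i], end = pcg_tx$end[i]))))
  write_gtf_transcripts(pcg_tab, p("pcg.gtf"))
  write_bed(ann$repeats, p("repeats.bed"))
  write_bed(ann$blacklist, p("blacklist.bed"))
  for (lab in names(ann$markers))
    write_bed(ann$markers[[lab]], p(sprintf("marker_%s.bed", lab)))
  write_bed(ann$genes, p("genes.bed"))
  utils::write.table(ann$coding_table, p("coding_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(p("sequences.fa"), "w")
  for (id in names(ann$sequences))
    writeLines(c(paste0(">", id), ann$sequences[[id]]), con)
  close(con)
  invisible(dir)
}

#' @keywords internal
make_coding_seq <- function(len) {
  stopifnot(len >= 303L)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste0,
                  collapse = "")
  sense <- setdiff(codons, stops)
  n_cod <- (len - 6L) %/% 3L
  body <- paste(sample(sense, n_cod, replace = TRUE), collapse = "")
  core <- paste0("ATG", body, "TGA")
  paste0(core, paste(rep("A", len - nchar(core)), collapse = ""))
}

#' @keywords internal
make_noncoding_seq <- function(len) {
  # A/C/T alphabet: no G, hence no ATG, hence no ORF
  paste(sample(c("A", "C", "T"), len, replace = TRUE), collapse = "")
}

#' Generate expression matrices with planted co-expressed pairs
#'
#' Planted (eRNA, PCG) pairs share a latent standard-normal variable with
#' independent Gaussian noise added to each partner; the noise scale of
#' each pair is calibrated empirically (grid search on the realized
#' vectors) so the pair's Spearman correlation lands on `planted_rho`.
#' Null features are independent noise. Matrices are exponentiated
#' (`2^x`) to resemble positive expression values; ranks, and hence every
#' Spearman statistic, are unaffected.
#'
#' @param spec a [fixture_spec()]; uses `n_samples`, `planted_rho`,
#'   `noise_sd` and `fraction_null`.
#' @param ernas,pcgs character vectors of feature ids for the two matrices.
#' @param dir optional output directory (erna_expr.tsv, pcg_expr.tsv,
#'   planted_pairs.tsv).
#' @return A list with `erna` and `pcg` matrices (features x samples) and
#'   `planted` (data.frame `erna`, `pcg`, `target_rho`, `achieved_rho`).
#' @export
make_expression <- function(spec, ernas, pcgs, dir = NULL) {
  if (spec$n_samples < 10L) stop("need n_samples >= 10", call. = FALSE)
  with_seed(spec$seed + 2L, make_expression_impl(spec, ernas, pcgs, dir))
}

make_expression_impl <- function(spec, ernas, pcgs, dir) {
  n <- spec$n_samples
  samples <- sprintf("S%02d", seq_len(n))
  em <- matrix(stats::rnorm(length(ernas) * n, sd = spec$noise_sd),
               nrow = length(ernas), dimnames = list(ernas, samples))
  pm <- matrix(stats::rnorm(length(pcgs) * n, sd = spec$noise_sd),
               nrow = length(pcgs), dimnames = list(pcgs, samples))
  n_planted <- round((1 - spec$fraction_null) * length(ernas))
  n_planted <- min(n_planted, length(ernas))
  planted <- NULL
  if (n_planted > 0L && length(pcgs)) {
    rows <- lapply(seq_len(n_planted), function(i) {
      z <- stats::rnorm(n)
      e1 <- stats::rnorm(n)
      e2 <- stats::rnorm(n)
      target <- spec$planted_rho
      grid <- seq(0.01, 3, by = 0.01)
      ach <- vapply(grid, function(s)
        stats::cor(z + s * e1, sign(target) * (z + s * e2),
                   method = "spearman"), 0)
      s <- grid[which.min(abs(ach - target))]
      x <- z + s * e1
      y <- sign(target) * (z + s * e2)
      pj <- ((i - 1L) %% length(pcgs)) + 1L
      em[ernas[i], ] <<- x
      pm[pcgs[pj], ] <<- y
      data.frame(erna = ernas[i], pcg = pcgs[pj], target_rho = target,
                 achieved_rho = stats::cor(x, y, method = "spearman"),
                 stringsAsFactors = FALSE)
    })
    planted <- do.call(rbind, rows)
  }
  if (is.null(planted))
    planted <- data.frame(erna = character(0), pcg = character(0),
                          target_rho = numeric(0), achieved_rho = numeric(0))
  em <- 2^em
  pm <- 2^pm
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(em, file.path(dir, "erna_expr.tsv"))
    write_expression(pm, file.path(dir, "pcg_expr.tsv"))
    utils::write.table(planted, file.path(dir, "planted_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(erna = em, pcg = pm, planted = planted)
}

#' Simulate reads over regions and emit exact coverage tracks
#'
#' Places reads of fixed length uniformly within each region (or, with
#' `placement = "straddle"`, starting anywhere inside the region so that
#' reads near the right edge extend past it) and emits the exact per-base
#' coverage as a bedGraph-style track, plus the true read counts so a
#' count-based FPKM oracle can be computed. The library total-mapped-reads
#' T of each sample is its simulated read count (floored at 1 so T > 0
#' holds for empty libraries).
#'
#' @param spec a [fixture_spec()]; uses `read_length`.
#' @param regions an interval data frame with region ids in `name`.
#' @param mean_count Poisson mean read count per region.
#' @param samples sample names (one track per sample).
#' @param placement `"contained"` (reads fully inside the region) or
#'   `"straddle"`.
#' @param dir optional output directory (`<sample>.bedgraph`, stats.tsv,
#'   counts.tsv).
#' @return A list with `tracks` (named list of coverage tracks), `stats`
#'   (named list of [library_stats()]), `counts` (regions x samples
#'   matrix) and `reads` (named list of read interval tables).
#' @export
make_tracks_and_reads <- function(spec, regions, mean_count = 200,
                                  samples = "S01",
                                  placement = c("contained", "straddle"),
                                  dir = NULL) {
  placement <- match.arg(placement)
  regions <- validate_intervals(regions)
  R <- spec$read_length
  if (any(regions$end - regions$start <= R))
    stop("read length must be smaller than every region", call. = FALSE)
  with_seed(spec$seed + 3L,
            make_tracks_impl(spec, regions, mean_count, samples, placement,
                             dir))
}

make_tracks_impl <- function(spec, regions, mean_count, samples, placement,
                             dir) {
  R <- spec$read_length
  ids <- ifelse(is.na(regions$name), sprintf("region%d",
                                             seq_len(nrow(regions))),
                regions$name)
  counts <- matrix(0L, nrow(regions), length(samples),
                   dimnames = list(ids, samples))
  tracks <- list()
  stats <- list()
  reads_out <- list()
  for (s in samples) {
    reads <- list()
    for (i in seq_len(nrow(regions))) {
      cnt <- stats::rpois(1L, mean_count)
      counts[i, s] <- cnt
      if (!cnt) next
      lo <- regions$start[i]
      hi <- if (placement == "contained") regions$end[i] - R
      else regions$end[i] - 1L
      starts <- sample(lo:hi, cnt, replace = TRUE)
      reads[[length(reads) + 1L]] <-
        data.frame(chrom = regions$chrom[i], start = starts,
                   end = starts + R, stringsAsFactors = FALSE)
    }
    reads <- if (length(reads)) do.call(rbind, reads)
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
    tracks[[s]] <- reads_to_track(reads)
    stats[[s]] <- library_stats(R, max(1L, nrow(reads)))
    reads_out[[s]] <- reads
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in samples)
      write_bedgraph(tracks[[s]], file.path(dir, paste0(s, ".bedgraph")))
    st <- data.frame(sample = samples,
                     read_length = R,
                     total_reads = vapply(stats, `[[`, 0, "total_reads"))
    utils::write.table(st, file.path(dir, "stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(region = rownames(counts), counts),
                       file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(tracks = tracks, stats = stats, counts = counts, reads = reads_out)
}

#' Exact per-base coverage of a read set
#' @param reads data.frame `chrom`, `start`, `end` (0-based half-open).
#' @return A coverage track data frame.
#' @export
reads_to_track <- function(reads) {
  if (!nrow(reads))
    return(coverage_track(data.frame(chrom = character(0),
                                     start = integer(0), end = integer(0),
                                     depth = numeric(0))))
  parts <- lapply(split(reads, reads$chrom), function(r) {
    cov <- IRanges::coverage(IRanges::IRanges(r$start + 1L, r$end))
    rl <- S4Vectors::runLength(cov)
    rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl)
    starts <- ends - rl  # already 0-based half-open starts
    keep <- rv > 0
    data.frame(chrom = r$chrom[1], start = starts[keep], end = ends[keep],
               depth = rv[keep], stringsAsFactors = FALSE)
  })
  coverage_track(do.call(rbind, parts))
}

#' Generate a gene-set collection fixture
#'
#' Builds a GMT-style collection over the fixture's PCG ids: one set
#' holding the planted expression partners (a coherent "program" an eRNA's
#' neighborhood should enrich for) plus random sets of comparable size.
#'
#' @param spec a [fixture_spec()].
#' @param pcg_ids universe of gene ids.
#' @param partner_ids gene ids of planted partners (may be empty).
#' @param n_random number of random decoy sets.
#' @param dir optional directory; writes `sets.gmt`.
#' @return A `gene_set_collection`.
#' @export
make_gene_sets <- function(spec, pcg_ids, partner_ids = character(0),
                           n_random = 3L, dir = NULL) {
  with_seed(spec$seed + 4L, {
    sets <- list()
    if (length(partner_ids))
      sets$target_program <- sort(unique(partner_ids))
    size <- max(3L, min(length(pcg_ids),
                        max(1L, length(unique(partner_ids)))))
    for (i in seq_len(n_random))
      sets[[sprintf("random_set_%d", i)]] <-
        sort(sample(pcg_ids, min(size, length(pcg_ids))))
    coll <- gene_set_collection(sets, universe = pcg_ids)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      lines <- vapply(names(coll$sets), function(nm)
        paste(c(nm, "synthetic fixture set", coll$sets[[nm]]),
              collapse = "\t"), "")
      writeLines(lines, file.path(dir, "sets.gmt"))
    }
    coll
  })
}

#' Write a complete fixture directory
#'
#' Convenience wrapper generating annotation, expression, coverage and
#' gene-set fixtures into one directory.
#'
#' @param dir output directory.
#' @param spec a [fixture_spec()].
#' @return Invisibly, a list with all generated objects.
#' @export
write_fixtures <- function(dir, spec = fixture_spec()) {
  ann <- make_annotation(spec, dir = dir)
  planted_ids <- ann$truth$transcript_id[ann$truth$class == "planted_erna"]
  expr <- make_expression(spec, planted_ids, ann$genes$name, dir = dir)
  erna_tx <- ann$transcripts[ann$transcripts$transcript_id %in% planted_ids,
                             , drop = FALSE]
  regions <- transcript_spans(erna_tx)
  trk <- if (nrow(regions))
    make_tracks_and_reads(spec, regions, samples = "S01", dir = dir)
  else NULL
  coll <- make_gene_sets(spec, ann$genes$name, expr$planted$pcg, dir = dir)
  invisible(list(annotation = ann, expression = expr, tracks = trk,
                 gene_sets = coll, spec = spec))
}
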