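#' Filter de novo transcripts against exclusion regions
#'
#' Removes every transcript whose span (or, with `level = "exon"`, any exon)
#' overlaps by >= 1 bp, strand-agnostically, an annotated protein-coding
#' gene, a simple repeat, or a blacklisted region. The removal log records
#' the first matching exclusion set in the fixed precedence
#' pcg -> repeats -> blacklist (precedence affects the logged reason only,
#' never the retained set).
#'
#' @param transcripts a transcript table ([read_gtf_transcripts()]).
#' @param pcg,repeats,blacklist interval data frames of exclusion regions;
#'   any of them may be empty.
#' @param level `"span"` (default) tests the transcript span;
#'   `"exon"` tests individual exons.
#' @return A list with `retained` (transcript table) and `removal_log`
#'   (data.frame of `transcript_id`, `reason`).
#' @export
filter_transcripts <- function(transcripts, pcg = NULL, repeats = NULL,
                               blacklist = NULL,
                               level = c("span", "exon")) {
  level <- match.arg(level)
  spans <- transcript_spans(transcripts)
  test_iv <- if (level == "span") spans else exon_intervals(transcripts)
  sets <- list(pcg = pcg, repeats = repeats, blacklist = blacklist)
  reason <- rep(NA_character_, nrow(transcripts))
  for (nm in names(sets)) {  # precedence order
    s <- sets[[nm]]
    if (is.null(s) || !nrow(s)) next
    s <- validate_intervals(s, nm)
    if (nrow(spans)) check_shared_chroms(spans, s, c("transcripts", nm))
    hits <- find_interval_overlaps(test_iv, s)
    hit_tx <- unique(test_iv$name[hits$query])
    idx <- match(hit_tx, transcripts$transcript_id)
    reason[idx[is.na(reason[idx])]] <- nm
  }
  removed <- !is.na(reason)
  list(
    retained = transcripts[!removed, , drop = FALSE],
    removal_log = data.frame(transcript_id = transcripts$transcript_id[removed],
                             reason = reason[removed],
                             stringsAsFactors = FALSE)
  )
}

#' @keywords internal
exon_intervals <- function(transcripts) {
  if (!nrow(transcripts)) return(empty_intervals())
  per_tx <- lapply(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    genomic_intervals(transcripts$chrom[i], ex$start, ex$end,
                      name = transcripts$transcript_id[i],
                      strand = transcripts$strand[i])
  })
  validate_intervals(do.call(rbind, per_tx))
}

#' Classify transcripts as coding or noncoding
#'
#' The coding-potential gate is pluggable. `method = "external_table"` reads
#' labels produced by an external coding-potential tool (a two-column
#' transcript_id/label table, as one would export from CPC2 run outside the
#' toolkit). `method = "orf_fallback"` is a built-in gate that labels a
#' transcript coding when its longest open reading frame — ATG through the
#' next in-frame stop, scanned over the three forward frames of the supplied
#' transcript sequence — is at least `orf_min` amino acids (default 100 aa,
#' counting the initial Met and excluding the stop).
#'
#' @param transcripts a transcript table.
#' @param method `"orf_fallback"` or `"external_table"`.
#' @param sequences named character vector of transcript sequences
#'   (orf_fallback; each must have `nchar` equal to the transcript's
#'   `exonic_length`).
#' @param table data.frame or TSV path with columns `transcript_id`,
#'   `label` (external_table; label in `coding`/`noncoding`).
#' @param orf_min minimum ORF length in amino acids for a coding call.
#' @return A data.frame of coding calls: `transcript_id`, `label`
#'   (`"coding"`/`"noncoding"`), `score` (ORF length in aa, or `NA` for
#'   external labels) and `method`.
#' @export
classify_coding <- function(transcripts,
                            method = c("orf_fallback", "external_table"),
                            sequences = NULL, table = NULL, orf_min = 100L) {
  method <- match.arg(method)
  ids <- transcripts$transcript_id
  if (method == "external_table") {
    if (is.character(table) && length(table) == 1L)
      table <- utils::read.delim(table, stringsAsFactors = FALSE)
    if (is.null(table) || !all(c("transcript_id", "label") %in% names(table)))
      stop("external_table requires a table with columns transcript_id, label",
           call. = FALSE)
    miss <- setdiff(ids, table$transcript_id)
    if (length(miss))
      stop("coding table is missing transcript ids: ",
           paste(miss, collapse = ", "), call. = FALSE)
    lab <- table$label[match(ids, table$transcript_id)]
    bad <- !lab %in% c("coding", "noncoding")
    if (any(bad))
      stop("coding labels must be 'coding' or 'noncoding'", call. = FALSE)
    return(data.frame(transcript_id = ids, label = lab, score = NA_real_,
                      method = "external_table", stringsAsFactors = FALSE))
  }
  if (is.null(sequences))
    stop("orf_fallback requires transcript sequences", call. = FALSE)
  miss <- setdiff(ids, names(sequences))
  if (length(miss))
    stop("sequences missing for transcript ids: ",
         paste(miss, collapse = ", "), call. = FALSE)
  seqs <- sequences[ids]
  len_bad <- nchar(seqs) != transcripts$exonic_length
  if (any(len_bad))
    stop("sequence length != exonic_length for: ",
         paste(ids[len_bad], collapse = ", "), call. = FALSE)
  orf <- vapply(seqs, longest_orf_aa, 0L)
  data.frame(transcript_id = ids,
             label = ifelse(orf >= orf_min, "coding", "noncoding"),
             score = as.numeric(orf), method = "orf_fallback",
             stringsAsFactors = FALSE)
}

#' Longest ORF length in amino acids
#'
#' Scans the three forward frames of a nucleotide sequence for ATG..stop
#' runs; returns the longest run in codons counted from the ATG up to (not
#' including) the stop. 0 when no complete ORF exists.
#'
#' @param seq a nucleotide string.
#' @return Integer ORF length in amino acids.
#' @export
longest_orf_aa <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3L
    if (n_cod < 2L) next
    starts <- frame + 3L * (seq_len(n_cod) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    atg_at <- -1L
    for (i in seq_len(n_cod)) {
      if (atg_at < 0L && codons[i] == "ATG") {
        atg_at <- i
      } else if (atg_at > 0L && codons[i] %in% stops) {
        best <- max(best, i - atg_at)
        atg_at <- -1L
      }
    }
  }
  as.integer(best)
}

#' Call eRNAs from noncoding transcripts and enhancer regions
#'
#' Identifies transcripts transcribed from enhancer regions. Under the
#' default rule `"tss_in_enhancer"` a transcript is an eRNA when its TSS
#' position lies inside at least one enhancer interval (origin of
#' transcription within the enhancer); `"any_overlap"` relaxes this to a
#' >= 1 bp span overlap. Every satisfying enhancer is attached, with its
#' supporting marker labels.
#'
#' @param noncoding a transcript table of noncoding transcripts.
#' @param enhancers an enhancer interval table ([combine_markers()] output,
#'   or any BED-derived interval table).
#' @param rule `"tss_in_enhancer"` (default) or `"any_overlap"`.
#' @return An eRNA call table: a data.frame with the transcript columns of
#'   the called rows plus list-column `enhancers` (per-call enhancer
#'   sub-table) and `markers` (comma-joined union of supporting labels).
#' @export
call_ernas <- function(noncoding, enhancers,
                       rule = c("tss_in_enhancer", "any_overlap")) {
  rule <- match.arg(rule)
  enhancers <- validate_intervals(enhancers, "enhancers")
  empty <- noncoding[0, , drop = FALSE]
  empty$enhancers <- list()
  empty$markers <- character(0)
  class(empty) <- unique(c("erna_calls", class(empty)))
  if (!nrow(noncoding) || !nrow(enhancers)) return(empty)
  probe <- if (rule == "tss_in_enhancer") {
    genomic_intervals(noncoding$chrom, noncoding$tss, noncoding$tss + 1L,
                      name = noncoding$transcript_id)
  } else {
    transcript_spans(noncoding)
  }
  hits <- find_interval_overlaps(probe, enhancers)
  if (!nrow(hits)) return(empty)
  called_idx <- sort(unique(hits$query))
  out <- noncoding[called_idx, , drop = FALSE]
  marker_lists <- enhancer_marker_list(enhancers)
  out$enhancers <- lapply(called_idx, function(i)
    enhancers[hits$subject[hits$query == i], , drop = FALSE])
  out$markers <- vapply(called_idx, function(i) {
    labs <- unlist(marker_lists[hits$subject[hits$query == i]])
    paste(sort(unique(labs[nzchar(labs)])), collapse = ",")
  }, "")
  rownames(out) <- NULL
  class(out) <- unique(c("erna_calls", class(out)))
  out
}

#' Report genes adjacent to called eRNAs
#'
#' Genes on the same chromosome whose span lies within `window` bp of the
#' eRNA span, by closest-edge distance (0 when overlapping or abutting);
#' these are the putative targets reported alongside each call. Default
#' window +/- 1 Mb.
#'
#' @param ernas an eRNA call table ([call_ernas()]) or any interval table
#'   with a `name` column of ids.
#' @param genes an interval data frame of gene spans with gene ids in
#'   `name`.
#' @param window maximum closest-edge distance in bp (default 1e6).
#' @return A data.frame `erna_id`, `gene_id`, `distance`, sorted per eRNA by
#'   ascending distance, ties broken by gene id.
#' @export
adjacent_genes <- function(ernas, genes, window = 1000000L) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  genes <- validate_intervals(genes, "genes")
  id <- if ("transcript_id" %in% names(ernas)) ernas$transcript_id
  else ernas$name
  none <- data.frame(erna_id = character(0), gene_id = character(0),
                     distance = numeric(0))
  if (!nrow(ernas) || !nrow(genes)) return(none)
  rows <- lapply(seq_len(nrow(ernas)), function(i) {
    same <- genes$chrom == ernas$chrom[i]
    if (!any(same)) return(NULL)
    g <- genes[same, , drop = FALSE]
    d <- edge_distance(ernas$chrom[i], ernas$start[i], ernas$end[i],
                       g$chrom, g$start, g$end)
    keep <- d <= window
    if (!any(keep)) return(NULL)
    g <- g[keep, , drop = FALSE]
    d <- d[keep]
    ord <- order(d, g$name)
    data.frame(erna_id = id[i], gene_id = g$name[ord], distance = d[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(none)
  rownames(out) <- NULL
  out
}

#' Annotate eRNA regions against arbitrary interval sets
#'
#' Generic interval annotation of eRNA spans: for each eRNA and each
#' annotation set (for example clinically relevant mutations, histone-mark
#' peaks, accessibility peaks), the number of overlapping records (>= 1 bp)
#' and their names. A row is emitted for every eRNA x set combination,
#' including zero counts.
#'
#' @param ernas an eRNA call table or interval table with ids in
#'   `transcript_id`/`name`.
#' @param annotations a named list of interval data frames
#'   ([marker_buffet()] accepts the same structure).
#' @return A data.frame `erna_id`, `annotation`, `count`, `names`.
#' @export
annotate_regions <- function(ernas, annotations) {
  annotations <- marker_buffet(annotations)
  id <- if ("transcript_id" %in% names(ernas)) ernas$transcript_id
  else ernas$name
  spans <- genomic_intervals(ernas$chrom, ernas$start, ernas$end, name = id)
  rows <- lapply(names(annotations), function(lab) {
    ann <- annotations[[lab]]
    hits <- find_interval_overlaps(spans, ann)
    data.frame(
      erna_id = id,
      annotation = lab,
      count = vapply(seq_along(id), function(i)
        sum(hits$query == i), 0L),
      names = vapply(seq_along(id), function(i) {
        nm <- ann$name[hits$subject[hits$query == i]]
        paste(nm[!is.na(nm)], collapse = ",")
      }, ""),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$erna_id, out$annotation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full eRNA identification pipeline
#'
#' Filters de novo transcripts against protein-coding genes, simple repeats
#' and blacklisted regions; gates the survivors by coding potential; calls
#' eRNAs against enhancer regions; and reports adjacent genes within the
#' +/- 1 Mb window when gene spans are supplied.
#'
#' @param transcripts a transcript table of the de novo assembly.
#' @param enhancers an enhancer interval table.
#' @param pcg,repeats,blacklist exclusion interval tables (any may be NULL).
#' @param coding a coding-call data.frame ([classify_coding()]), or NULL to
#'   skip the gate (all transcripts treated as noncoding).
#' @param genes optional gene-span interval table for adjacency reporting.
#' @param rule eRNA call rule, see [call_ernas()].
#' @param level filtering level, see [filter_transcripts()].
#' @param window adjacency window in bp.
#' @return A list with `calls` (eRNA call table), `removal_log`,
#'   `noncoding` (transcript table surviving both filters) and `adjacent`
#'   (adjacency table, or NULL).
#' @export
run_erna_id <- function(transcripts, enhancers, pcg = NULL, repeats = NULL,
                        blacklist = NULL, coding = NULL, genes = NULL,
                        rule = c("tss_in_enhancer", "any_overlap"),
                        level = c("span", "exon"), window = 1000000L) {
  rule <- match.arg(rule)
  level <- match.arg(level)
  filt <- filter_transcripts(transcripts, pcg, repeats, blacklist,
                             level = level)
  kept <- filt$retained
  if (!is.null(coding)) {
    lab <- coding$label[match(kept$transcript_id, coding$transcript_id)]
    if (anyNA(lab))
      stop("coding calls missing for: ",
           paste(kept$transcript_id[is.na(lab)], collapse = ", "),
           call. = FALSE)
    kept <- kept[lab == "noncoding", , drop = FALSE]
  }
  calls <- call_ernas(kept, enhancers, rule = rule)
  adjacent <- if (!is.null(genes) && nrow(calls))
    adjacent_genes(calls, genes, window = window) else NULL
  list(calls = calls, removal_log = filt$removal_log, noncoding = kept,
       adjacent = adjacent)
}

#' Write eRNA calls as BED6 and TSV
#'
#' @param result a [run_erna_id()] result.
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @return Invisibly, a summary data.frame (one row per call).
#' @export
write_erna_calls <- function(result, bed_path = NULL, tsv_path = NULL) {
  calls <- result$calls
  enh_str <- vapply(seq_len(nrow(calls)), function(i) {
    e <- calls$enhancers[[i]]
    paste(sprintf("%s:%d-%d", e$chrom, e$start, e$end), collapse = ";")
  }, "")
  adj_str <- rep("", nrow(calls))
  if (!is.null(result$adjacent) && nrow(result$adjacent)) {
    sp <- split(result$adjacent, result$adjacent$erna_id)
    for (i in seq_len(nrow(calls))) {
      a <- sp[[calls$transcript_id[i]]]
      if (!is.null(a))
        adj_str[i] <- paste(sprintf("%s(%d)", a$gene_id, as.integer(a$distance)),
                            collapse = ";")
    }
  }
  tab <- data.frame(
    transcript_id = calls$transcript_id, chrom = calls$chrom,
    start = calls$start, end = calls$end, strand = calls$strand,
    enhancers = enh_str, markers = calls$markers,
    adjacent_genes = adj_str, stringsAsFactors = FALSE
  )
  if (!is.null(bed_path))
    write_bed(genomic_intervals(calls$chrom, calls$start, calls$end,
                                name = calls$transcript_id,
                                strand = calls$strand), bed_path)
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
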