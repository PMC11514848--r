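#' Read a BED file
#'
#' Reads BED3/BED6 records into an interval data frame. BED coordinates are
#' natively 0-based half-open and are taken as-is. Lines starting with
#' `#`, `track` or `browser` are skipped. Columns 4-6, when present,
#' populate `name`, `score` and `strand`.
#'
#' @param path path to a BED file.
#' @return An interval data frame (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_intervals())
  recs <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_one <- function(f, lineno) {
    if (length(f) < 3L)
      stop("BED parse error at line ", lineno, ": fewer than 3 columns",
           call. = FALSE)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop("BED parse error at line ", lineno, ": non-integer coordinates",
           call. = FALSE)
    if (end <= start)
      stop("BED parse error at line ", lineno, ": end <= start", call. = FALSE)
    list(chrom = f[1], start = start, end = end,
         name = if (length(f) >= 4L) f[4] else NA_character_,
         score = if (length(f) >= 5L)
           suppressWarnings(as.numeric(f[5])) else NA_real_,
         strand = if (length(f) >= 6L && f[6] %in% c("+", "-", ".")) f[6]
         else ".")
  }
  rows <- mapply(parse_one, recs, idx, SIMPLIFY = FALSE)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  validate_intervals(df, paste0("BED file ", path))
}

#' Write intervals as BED6
#'
#' @param intervals an interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  out <- data.frame(
    intervals$chrom, intervals$start, intervals$end,
    ifelse(is.na(intervals$name), ".", intervals$name),
    ifelse(is.na(intervals$score), 0, intervals$score),
    intervals$strand
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcripts from a GTF file
#'
#' Groups `exon` features by `transcript_id` into a transcript table. GTF
#' coordinates (1-based inclusive) are converted to the package's 0-based
#' half-open convention. The transcription start site (TSS) is the span
#' start on `+`/`.` strands and `end - 1` on `-`.
#'
#' @param path path to a GTF file with exon features carrying
#'   `transcript_id` (and optionally `gene_id`) attributes.
#' @return A transcript table: a data.frame with one row per transcript and
#'   columns `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (the span), `tss`, `exonic_length`, plus a list-column `exons` of
#'   per-transcript exon data frames (`start`, `end`, sorted, disjoint).
#'   Transcripts without exon features are skipped with a warning.
#' @export
read_gtf_transcripts <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  is_exon <- types == "exon"
  if (any(is_exon) &&
      (is.null(md$transcript_id) || anyNA(md$transcript_id[is_exon])))
    stop("GTF parse error: exon feature missing transcript_id attribute",
         call. = FALSE)
  n_tx_feats <- if (is.null(md$transcript_id)) character(0) else
    unique(stats::na.omit(md$transcript_id[types %in%
                                             c("transcript", "mRNA")]))
  if (!any(is_exon)) {
    if (length(n_tx_feats))
      warning("skipping ", length(n_tx_feats),
              " transcript(s) with no exon features", call. = FALSE)
    return(transcript_table(list()))
  }
  ex <- gr[is_exon]
  exd <- data.frame(
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    gene_id = if (is.null(S4Vectors::mcols(ex)$gene_id)) NA_character_
    else as.character(S4Vectors::mcols(ex)$gene_id),
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    strand = as.character(BiocGenerics::strand(ex)),
    start = BiocGenerics::start(ex) - 1L,  # GTF 1-based -> 0-based half-open
    end = BiocGenerics::end(ex),
    stringsAsFactors = FALSE
  )
  exd$strand[exd$strand == "*"] <- "."
  missing_exons <- setdiff(n_tx_feats, unique(exd$transcript_id))
  if (length(missing_exons))
    warning("skipping transcript(s) with no exon features: ",
            paste(missing_exons, collapse = ", "), call. = FALSE)
  txs <- lapply(split(exd, exd$transcript_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    make_transcript(d$transcript_id[1], d$gene_id[1], d$chrom[1],
                    d$strand[1], d[, c("start", "end")])
  })
  transcript_table(txs)
}

#' @keywords internal
make_transcript <- function(transcript_id, gene_id, chrom, strand, exons) {
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("transcript ", transcript_id, ": overlapping exons", call. = FALSE)
  span_start <- min(exons$start)
  span_end <- max(exons$end)
  list(
    transcript_id = transcript_id,
    gene_id = if (is.na(gene_id)) transcript_id else gene_id,
    chrom = chrom, strand = strand,
    start = span_start, end = span_end,
    tss = if (strand == "-") span_end - 1L else span_start,
    exonic_length = as.integer(sum(exons$end - exons$start)),
    exons = exons
  )
}

#' @keywords internal
transcript_table <- function(tx_list) {
  if (!length(tx_list)) {
    df <- data.frame(transcript_id = character(0), gene_id = character(0),
                     chrom = character(0), strand = character(0),
                     start = integer(0), end = integer(0), tss = integer(0),
                     exonic_length = integer(0))
    df$exons <- list()
  } else {
    df <- data.frame(
      transcript_id = vapply(tx_list, `[[`, "", "transcript_id"),
      gene_id = vapply(tx_list, `[[`, "", "gene_id"),
      chrom = vapply(tx_list, `[[`, "", "chrom"),
      strand = vapply(tx_list, `[[`, "", "strand"),
      start = vapply(tx_list, function(t) as.integer(t$start), 0L),
      end = vapply(tx_list, function(t) as.integer(t$end), 0L),
      tss = vapply(tx_list, function(t) as.integer(t$tss), 0L),
      exonic_length = vapply(tx_list, `[[`, 0L, "exonic_length"),
      stringsAsFactors = FALSE
    )
    df$exons <- lapply(tx_list, `[[`, "exons")
  }
  rownames(df) <- NULL
  class(df) <- unique(c("transcript_table", class(df)))
  df
}

#' Transcript spans as an interval table
#'
#' Collapses each transcript to its genomic span (min exon start to max
#' exon end), with the transcript id in `name`.
#'
#' @param tx a transcript table.
#' @return An interval data frame.
#' @export
transcript_spans <- function(tx) {
  genomic_intervals(tx$chrom, tx$start, tx$end, name = tx$transcript_id,
                    strand = tx$strand)
}

#' Write a transcript table as GTF exon features
#'
#' Restores 1-based inclusive GTF coordinates.
#' @param tx a transcript table.
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf_transcripts <- function(tx, path, source = "ernatools") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id[i], tx$transcript_id[i])
    lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                     tx$chrom[i], source, ex$start + 1L, ex$end,
                     tx$strand[i], attrs)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a paired-anchor loop file
#'
#' Six tab-separated columns `chrom1 start1 end1 chrom2 start2 end2` plus an
#' optional seventh score column (BEDPE-like), as produced by HiChIP-style
#' loop callers. Coordinates are 0-based half-open.
#'
#' @param path path to the loop file.
#' @return A data.frame with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `score`.
#' @export
read_loops <- function(path) {
  if (!file.exists(path)) stop("loop file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "score")
  if (!length(keep))
    return(stats::setNames(data.frame(character(0), integer(0), integer(0),
                                      character(0), integer(0), integer(0),
                                      numeric(0)), cols))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop("loop parse error at line ", i, ": fewer than 6 columns",
           call. = FALSE)
    co <- suppressWarnings(as.integer(f[c(2, 3, 5, 6)]))
    if (anyNA(co))
      stop("loop parse error at line ", i, ": non-integer coordinates",
           call. = FALSE)
    if (co[2] <= co[1] || co[4] <= co[3])
      stop("loop parse error at line ", i, ": end <= start", call. = FALSE)
    data.frame(chrom1 = f[1], start1 = co[1], end1 = co[2], chrom2 = f[4],
               start2 = co[3], end2 = co[4],
               score = if (length(f) >= 7L)
                 suppressWarnings(as.numeric(f[7])) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a bedGraph coverage track
#'
#' Four tab-separated columns `chrom start end depth`, 0-based half-open,
#' exactly encoding a per-base step function. Gaps mean depth 0. Intervals
#' must be disjoint within a chromosome.
#'
#' @param path path to a bedGraph file.
#' @return A coverage track: a data.frame with columns `chrom`, `start`,
#'   `end`, `depth`, sorted by (chrom, start).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path))
    stop("bedGraph file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (!length(keep))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), depth = numeric(0)))
  mat <- do.call(rbind, strsplit(lines[keep], "\t", fixed = TRUE))
  if (ncol(mat) < 4L)
    stop("bedGraph parse error: fewer than 4 columns", call. = FALSE)
  df <- data.frame(chrom = mat[, 1],
                   start = suppressWarnings(as.integer(mat[, 2])),
                   end = suppressWarnings(as.integer(mat[, 3])),
                   depth = suppressWarnings(as.numeric(mat[, 4])))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$depth))
    stop("bedGraph parse error: non-numeric fields", call. = FALSE)
  coverage_track(df)
}

#' @keywords internal
coverage_track <- function(df) {
  if (any(df$end <= df$start))
    stop("coverage track: end <= start", call. = FALSE)
  if (any(df$depth < 0))
    stop("coverage track: negative depth", call. = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  by_chrom <- split(seq_len(nrow(df)), df$chrom)
  for (idx in by_chrom) {
    if (length(idx) > 1L && any(df$start[idx][-1] < df$end[idx][-length(idx)]))
      stop("coverage track: overlapping intervals", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- unique(c("coverage_track", class(df)))
  df
}

#' Write a coverage track as bedGraph
#' @param track a coverage track data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then tab-separated gene ids.
#'
#' @param path path to a GMT file.
#' @return A gene-set collection: list with `sets` (named list of character
#'   vectors) and `universe` (union of all member ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i,
           ": need name, description and >= 1 gene", call. = FALSE)
    nm <- f[1]
    if (nm %in% names(sets))
      stop("GMT parse error: duplicate set name ", nm, call. = FALSE)
    sets[[nm]] <- unique(f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Build a gene-set collection from a named list
#' @param sets named list of character vectors of gene ids.
#' @param universe optional background universe; defaults to the union of
#'   all sets.
#' @return A `gene_set_collection` list.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  structure(list(sets = sets, universe = unique(universe)),
            class = "gene_set_collection")
}

#' Read an expression matrix from TSV
#'
#' First column: feature id; header row: sample ids.
#'
#' @param path path to a TSV file.
#' @return A numeric matrix, features x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix, features x samples.
#' @param path output path.
#' @param id_col name of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
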