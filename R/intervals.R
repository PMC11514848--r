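#' Construct a table of genomic intervals
#'
#' The toolkit represents genomic intervals as plain data frames with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand` in BED column order.
#' Coordinates are 0-based half-open (`start` inclusive, `end` exclusive)
#' everywhere inside the package; GTF input is converted on read.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end`.
#' @param name optional feature names (`NA` allowed).
#' @param score optional numeric scores (`NA` allowed).
#' @param strand strand characters, each one of `"+"`, `"-"`, `"."`.
#' @return A data.frame of class `c("genomic_intervals", "data.frame")`.
#' @export
#' @examples
#' genomic_intervals("chr1", c(100, 300), c(200, 400), name = c("a", "b"))
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
}

#' @keywords internal
validate_intervals <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  if (!"name" %in% names(df)) df$name <- NA_character_
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"strand" %in% names(df)) df$strand <- "."
  df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  if (nrow(df)) {
    if (anyNA(df$start) || anyNA(df$end))
      stop(what, ": non-integer coordinates", call. = FALSE)
    if (any(df$start < 0))
      stop(what, ": negative start coordinate", call. = FALSE)
    if (any(df$end <= df$start))
      stop(what, ": end <= start", call. = FALSE)
    if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
      stop(what, ": empty chromosome name", call. = FALSE)
    bad <- !df$strand %in% c("+", "-", ".")
    if (any(bad))
      stop(what, ": strand must be one of +, -, .", call. = FALSE)
  }
  class(df) <- unique(c("genomic_intervals", class(df)))
  rownames(df) <- NULL
  df
}

#' @keywords internal
empty_intervals <- function() {
  genomic_intervals(character(0), integer(0), integer(0),
                    character(0), numeric(0), character(0))
}

#' Overlap length of two genomic intervals
#'
#' Number of bases shared by two 0-based half-open intervals; 0 when they lie
#' on different chromosomes or do not intersect. Strand is ignored, as in
#' every overlap rule of the pipeline.
#'
#' @param a,b single intervals: one-row interval data frames or lists with
#'   elements `chrom`, `start`, `end`.
#' @return Integer overlap length (>= 0).
#' @export
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' b <- genomic_intervals("chr1", 150, 250)
#' overlap_length(a, b)  # 50
overlap_length <- function(a, b) {
  a <- as.list(a[c("chrom", "start", "end")])
  b <- as.list(b[c("chrom", "start", "end")])
  if (length(a$chrom) != 1L || length(b$chrom) != 1L)
    stop("overlap_length() takes single intervals", call. = FALSE)
  if (a$chrom != b$chrom) return(0L)
  as.integer(max(0L, min(a$end, b$end) - max(a$start, b$start)))
}

#' Merge overlapping and book-ended intervals
#'
#' Per chromosome, unites intervals that overlap or abut (book-ended
#' intervals merge, the BEDTools-merge default). Strand-agnostic; the output
#' carries strand `"."` and no name/score. Output is sorted by
#' (chrom, start) and its intervals are pairwise disjoint and non-abutting.
#'
#' @param intervals an interval data frame (see [genomic_intervals()]).
#' @return A merged interval data frame.
#' @export
merge_intervals <- function(intervals) {
  intervals <- validate_intervals(intervals)
  if (!nrow(intervals)) return(empty_intervals())
  parts <- split(intervals, intervals$chrom)
  out <- lapply(names(parts), function(ch) {
    p <- parts[[ch]]
    red <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  validate_intervals(out)
}

#' Find pairwise overlaps between two interval tables
#'
#' All (query, subject) index pairs whose intervals share at least one base
#' on the same chromosome. This is the single overlap query used by every
#' filtering/calling rule in the pipeline (strand-agnostic, >= 1 bp).
#'
#' @param query,subject interval data frames.
#' @return A data.frame with columns `query`, `subject` (row indices) and
#'   `width` (overlap length in bp).
#' @export
find_interval_overlaps <- function(query, subject) {
  query <- validate_intervals(query, "query")
  subject <- validate_intervals(subject, "subject")
  none <- data.frame(query = integer(0), subject = integer(0),
                     width = integer(0))
  if (!nrow(query) || !nrow(subject)) return(none)
  chroms <- intersect(unique(query$chrom), unique(subject$chrom))
  if (!length(chroms)) return(none)
  res <- lapply(chroms, function(ch) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- pmin(query$end[qi][qh], subject$end[si][sh]) -
      pmax(query$start[qi][qh], subject$start[si][sh])
    data.frame(query = qi[qh], subject = si[sh], width = as.integer(w))
  })
  out <- do.call(rbind, res)
  out[order(out$query, out$subject), , drop = FALSE]
}

#' Closest-edge distance between intervals
#'
#' 0 when the intervals overlap or abut; otherwise the number of bases
#' separating their closest edges. `Inf` across chromosomes.
#'
#' @keywords internal
edge_distance <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  d <- pmax(0L, pmax(start_a, start_b) - pmin(end_a, end_b))
  d[chrom_a != chrom_b] <- Inf
  d
}

#' Warn when two inputs share no chromosome names
#'
#' Chromosome matching is exact string equality (no "chr" aliasing); this
#' preflight catches fixtures or inputs written in different naming styles.
#'
#' @keywords internal
check_shared_chroms <- function(a, b, what = c("first input", "second input")) {
  if (nrow(a) && nrow(b) &&
      !length(intersect(unique(a$chrom), unique(b$chrom))))
    warning("no chromosome names shared between ", what[1], " and ", what[2],
            "; chromosome matching is exact (no 'chr' aliasing)",
            call. = FALSE)
  invisible(NULL)
}
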