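#' Expand intervals to fixed windows around their centers
#'
#' Each interval is replaced by the +/- `flank` bp window around its integer
#' center `floor((start + end) / 2)`; enhancer-marker peaks are expanded this
#' way (default +/- 3 kb) before being combined into enhancer regions.
#' Windows are clamped at 0 on the left; no right clamp is applied (assembly
#' bounds are optional input the marker files do not carry).
#'
#' @param intervals an interval data frame.
#' @param flank window half-width in bp (default 3000).
#' @return An interval data frame of windows; `name` and `strand` preserved.
#' @export
#' @examples
#' center_window(genomic_intervals("chr1", 10000, 10001), flank = 3000)
center_window <- function(intervals, flank = 3000L) {
  intervals <- validate_intervals(intervals)
  if (flank <= 0) stop("flank must be > 0", call. = FALSE)
  flank <- as.integer(flank)
  centers <- (intervals$start + intervals$end) %/% 2L
  out <- intervals
  out$start <- pmax(0L, centers - flank)
  out$end <- centers + flank
  validate_intervals(out)
}

#' Build a marker buffet
#'
#' A buffet is a named list of enhancer-marker interval sets (for example
#' H3K27ac peaks, H3K4me1 peaks, ATAC/DNase accessibility, RNA polymerase II
#' binding, or curated enhancer catalogs). Labels must be unique.
#'
#' @param ... named interval data frames, or a single named list of them.
#' @return A named list of validated interval tables.
#' @export
marker_buffet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) &&
      !is.data.frame(args[[1]]))
    args <- args[[1]]
  if (is.null(names(args)) || any(!nzchar(names(args))))
    stop("every marker set needs a label (named argument)", call. = FALSE)
  if (anyDuplicated(names(args)))
    stop("marker labels must be unique", call. = FALSE)
  lapply(args, validate_intervals, what = "marker set")
}

#' Combine enhancer markers into enhancer regions
#'
#' Each marker interval is first expanded to the +/- `flank` window around
#' its center ([center_window()]), then the windowed sets are combined:
#'
#' * `mode = "merge"` (comprehensive): the union of all windowed intervals,
#'   with overlapping/book-ended pieces merged; each region is supported by
#'   every marker set that intersects it.
#' * `mode = "overlap"` (high-confidence): genomic positions covered by at
#'   least `min_support` distinct marker sets; maximal runs of such
#'   positions are emitted, keeping fragment boundaries where the supporting
#'   label set changes (multi-intersection semantics) and merging adjacent
#'   fragments whose label sets are identical.
#'
#' @param buffet a named list of marker interval sets ([marker_buffet()]).
#' @param mode `"overlap"` or `"merge"`.
#' @param min_support minimum number of distinct marker sets covering a
#'   position (overlap mode; default 2).
#' @param flank center-window half-width in bp (default 3000).
#' @return An interval data frame of enhancer regions with the supporting
#'   marker labels comma-joined in `name` and their count in `score`.
#'   An empty buffet intersection yields an empty table with a warning.
#' @export
combine_markers <- function(buffet, mode = c("overlap", "merge"),
                            min_support = 2L, flank = 3000L) {
  mode <- match.arg(mode)
  buffet <- marker_buffet(buffet)
  if (!length(buffet)) stop("buffet is empty", call. = FALSE)
  min_support <- as.integer(min_support)
  if (min_support < 1L)
    stop("min_support must be >= 1", call. = FALSE)
  if (mode == "overlap" && length(buffet) < min_support)
    stop("overlap mode needs at least min_support (", min_support,
         ") marker sets; got ", length(buffet), call. = FALSE)
  windowed <- lapply(buffet, center_window, flank = flank)

  if (mode == "merge") {
    all_w <- do.call(rbind, lapply(windowed, function(d)
      d[, c("chrom", "start", "end", "name", "score", "strand")]))
    merged <- merge_intervals(all_w)
    if (!nrow(merged)) {
      warning("no enhancer regions produced", call. = FALSE)
      return(merged)
    }
    labels <- support_labels(merged, windowed)
    merged$name <- labels$labels
    merged$score <- labels$n
    return(validate_intervals(merged))
  }

  # overlap mode: per-set union first (a set counts once per base), then
  # disjoin all covered fragments and count distinct supporting sets.
  reduced <- lapply(windowed, merge_intervals)
  pooled <- do.call(rbind, Map(function(d, lab) {
    d$name <- lab
    d
  }, reduced, names(reduced)))
  frags_by_chrom <- lapply(split(pooled, pooled$chrom), function(p) {
    dj <- IRanges::disjoin(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(chrom = p$chrom[1], start = IRanges::start(dj) - 1L,
               end = IRanges::end(dj), stringsAsFactors = FALSE)
  })
  frags <- validate_intervals(do.call(rbind, frags_by_chrom))
  hits <- find_interval_overlaps(frags, pooled)
  lab_per_frag <- vapply(seq_len(nrow(frags)), function(i) {
    labs <- sort(unique(pooled$name[hits$subject[hits$query == i]]))
    paste(labs, collapse = ",")
  }, "")
  n_per_frag <- vapply(strsplit(lab_per_frag, ",", fixed = TRUE), length, 0L)
  keep <- n_per_frag >= min_support
  if (!any(keep)) {
    warning("no enhancer regions produced", call. = FALSE)
    return(empty_intervals())
  }
  frags <- frags[keep, , drop = FALSE]
  frags$name <- lab_per_frag[keep]
  frags$score <- n_per_frag[keep]
  frags <- frags[order(frags$chrom, frags$start), , drop = FALSE]
  # merge adjacent fragments carrying the identical supporting label set
  out <- frags[1, , drop = FALSE]
  if (nrow(frags) > 1L) {
    for (i in 2:nrow(frags)) {
      j <- nrow(out)
      if (frags$chrom[i] == out$chrom[j] && frags$start[i] <= out$end[j] &&
          frags$name[i] == out$name[j]) {
        out$end[j] <- max(out$end[j], frags$end[i])
      } else {
        out <- rbind(out, frags[i, , drop = FALSE])
      }
    }
  }
  validate_intervals(out)
}

#' @keywords internal
support_labels <- function(regions, windowed_sets) {
  per_set <- lapply(names(windowed_sets), function(lab) {
    hits <- find_interval_overlaps(regions, windowed_sets[[lab]])
    unique(hits$query)
  })
  labels <- vapply(seq_len(nrow(regions)), function(i) {
    labs <- names(windowed_sets)[vapply(per_set, function(q) i %in% q, TRUE)]
    paste(sort(labs), collapse = ",")
  }, "")
  list(labels = labels,
       n = vapply(strsplit(labels, ",", fixed = TRUE), length, 0L))
}

#' Marker labels supporting an enhancer table, split into a list
#' @keywords internal
enhancer_marker_list <- function(enhancers) {
  strsplit(ifelse(is.na(enhancers$name), "", enhancers$name), ",",
           fixed = TRUE)
}
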