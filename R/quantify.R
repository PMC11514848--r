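#' Total read coverage over a region
#'
#' Sums depth x overlap over a coverage track's step function within one
#' 0-based half-open region. This is the Sum(Cov) term of the coverage-based
#' FPKM: summing per-base depths is equivalent to summing, over reads, the
#' number of read bases falling inside the region.
#'
#' @param track a coverage track ([read_bedgraph()]).
#' @param region a single interval (one-row data frame or list with
#'   `chrom`, `start`, `end`).
#' @return Total coverage (numeric, >= 0); 0 when the track does not touch
#'   the region.
#' @export
coverage_sum <- function(track, region) {
  region <- as.list(region[c("chrom", "start", "end")])
  if (!nrow(track)) return(0)
  t <- track[track$chrom == region$chrom, , drop = FALSE]
  if (!nrow(t)) return(0)
  ov <- pmax(0, pmin(t$end, region$end) - pmax(t$start, region$start))
  sum(t$depth * ov)
}

#' Coverage-based FPKM
#'
#' `FPKM = Sum(Cov) * 1e9 / (R * L * T)`, where `Sum(Cov)` is the total read
#' coverage of the region ([coverage_sum()]), `R` the read length, `L` the
#' feature length in bp, and `T` the total mapped reads of the library.
#' For reads fully contained in the region, `Sum(Cov) = count * R`, so this
#' equals the count-based `count * 1e9 / (L * T)` exactly.
#'
#' @param cov_sum total read coverage (Sum(Cov)).
#' @param read_length read length R in bp (> 0). For paired-end libraries
#'   use the mean mapped read length; `T` counts mapped reads, not
#'   fragments.
#' @param total_reads total mapped reads T of the library (> 0).
#' @param length feature length L in bp (> 0).
#' @return FPKM value(s); vectorized over `cov_sum`/`length`.
#' @export
#' @examples
#' fpkm(1e6, read_length = 100, total_reads = 1e7, length = 1000)  # 1000
fpkm <- function(cov_sum, read_length, total_reads, length) {
  if (any(length <= 0)) stop("feature length L must be > 0", call. = FALSE)
  if (any(read_length <= 0)) stop("read length R must be > 0", call. = FALSE)
  if (any(total_reads <= 0)) stop("total reads T must be > 0", call. = FALSE)
  cov_sum * 1e9 / (read_length * length * total_reads)
}

#' Library statistics for coverage-based quantification
#' @param read_length read length R in bp.
#' @param total_reads total mapped reads T.
#' @return A list with class `library_stats`.
#' @export
library_stats <- function(read_length, total_reads) {
  if (read_length <= 0 || total_reads <= 0)
    stop("read_length and total_reads must be > 0", call. = FALSE)
  structure(list(read_length = read_length, total_reads = total_reads),
            class = "library_stats")
}

#' Quantify regions across samples as an FPKM matrix
#'
#' For plain intervals, `Sum(Cov)` is taken over the region and `L` is the
#' region length; for transcript-table input, coverage is summed over exons
#' only and `L` is the exonic length.
#'
#' @param tracks named list of coverage tracks, one per sample.
#' @param stats named list of [library_stats()] (or lists with
#'   `read_length`, `total_reads`), one per sample; names must match
#'   `tracks`.
#' @param regions an interval data frame (ids in `name`) or a transcript
#'   table (ids in `transcript_id`).
#' @return A numeric FPKM matrix, regions x samples, in input order.
#' @export
quantify_regions <- function(tracks, stats, regions) {
  samples <- names(tracks)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("tracks must be a named list (sample names)", call. = FALSE)
  miss <- setdiff(samples, names(stats))
  if (length(miss))
    stop("library stats missing for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  is_tx <- inherits(regions, "transcript_table") ||
    "exons" %in% names(regions)
  ids <- if (is_tx) regions$transcript_id else {
    v <- regions$name
    ifelse(is.na(v) | !nzchar(v),
           sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end), v)
  }
  lens <- if (is_tx) regions$exonic_length else regions$end - regions$start
  m <- matrix(0, nrow = nrow(regions), ncol = length(samples),
              dimnames = list(ids, samples))
  for (s in samples) {
    trk <- tracks[[s]]
    st <- stats[[s]]
    for (i in seq_len(nrow(regions))) {
      cs <- if (is_tx) {
        ex <- regions$exons[[i]]
        sum(vapply(seq_len(nrow(ex)), function(j)
          coverage_sum(trk, list(chrom = regions$chrom[i],
                                 start = ex$start[j], end = ex$end[j])),
          0))
      } else {
        coverage_sum(trk, regions[i, , drop = FALSE])
      }
      m[i, s] <- fpkm(cs, st$read_length, st$total_reads, lens[i])
    }
  }
  m
}
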