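#' Spearman co-expression edges between eRNAs and protein-coding genes
#'
#' Computes, for every (eRNA, PCG) pair, the Spearman correlation (Pearson
#' correlation of mid-ranks, average ranks for ties) across the shared
#' samples, a two-sided p-value, and a multiple-testing-adjusted q-value
#' across all computed pairs. Correlation is restricted to eRNA x PCG pairs
#' (never PCG x PCG): the network of interest links eRNAs to their putative
#' protein-coding interactome.
#'
#' P-values use the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom (two-sided; `rho = +/-1` gives `p = 0`), or an
#' exact permutation null (`p_method = "exact"`, n <= 9): the proportion of
#' the `n!` sample permutations whose |rho| reaches the observed |rho|.
#' Zero-variance features yield `rho = NaN`, `p = NaN` and are excluded from
#' the adjustment family.
#'
#' @param erna_expr,pcg_expr numeric matrices (features x samples) with
#'   identical, identically ordered sample columns; n >= 4 samples.
#' @param p_method `"approx_t"` (default) or `"exact"` (n <= 9).
#' @param adjust_method `"BH"` (default) or `"bonferroni"`.
#' @return An edge table: data.frame `source`, `target`, `kind = "coexpr"`,
#'   `rho`, `p`, `q`, `evidence`.
#' @export
spearman_edges <- function(erna_expr, pcg_expr,
                           p_method = c("approx_t", "exact"),
                           adjust_method = c("BH", "bonferroni")) {
  p_method <- match.arg(p_method)
  adjust_method <- match.arg(adjust_method)
  if (is.null(colnames(erna_expr)) || is.null(colnames(pcg_expr)) ||
      !identical(colnames(erna_expr), colnames(pcg_expr)))
    stop("expression matrices must share an identical ordered sample list",
         call. = FALSE)
  n <- ncol(erna_expr)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (p_method == "exact" && n > 9L)
    stop("exact permutation p is limited to n <= 9 samples", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(t(erna_expr), t(pcg_expr), method = "spearman"))
  rho[is.na(rho)] <- NaN
  if (p_method == "approx_t") {
    p <- spearman_p_t(rho, n)
  } else {
    p <- rho
    ra <- t(apply(erna_expr, 1L, rank))
    rb <- t(apply(pcg_expr, 1L, rank))
    for (i in seq_len(nrow(rho)))
      for (j in seq_len(ncol(rho)))
        p[i, j] <- if (is.nan(rho[i, j])) NaN else
          spearman_p_exact(ra[i, ], rb[j, ])
  }
  edges <- data.frame(
    source = rep(rownames(erna_expr), times = ncol(rho)),
    target = rep(colnames(rho), each = nrow(rho)),
    kind = "coexpr",
    rho = as.vector(rho), p = as.vector(p),
    stringsAsFactors = FALSE
  )
  edges$q <- adjust_bh(edges$p, method = adjust_method)
  edges$evidence <- sprintf("n=%d", n)
  edges
}

#' @keywords internal
spearman_p_t <- function(rho, n) {
  denom <- 1 - rho^2
  tstat <- rho * sqrt((n - 2) / pmax(denom, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 & !is.nan(rho)] <- 0
  p[is.nan(rho)] <- NaN
  p
}

#' @keywords internal
spearman_p_exact <- function(rank_x, rank_y, tol = 1e-12) {
  obs <- abs(stats::cor(rank_x, rank_y))
  perms <- permutations_of(length(rank_y))
  hits <- vapply(seq_len(nrow(perms)), function(k)
    abs(stats::cor(rank_x, rank_y[perms[k, ]])) >= obs - tol, TRUE)
  mean(hits)
}

#' @keywords internal
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[r + seq_len(nrow(sub)), 1L] <- i
    out[r + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg (or Bonferroni) adjusted p-values
#'
#' Step-up BH: for sorted p-values, `q_(i) = min_{j >= i} (m * p_(j) / j)`
#' clipped at 1, restored to input order. `NaN`/`NA` entries propagate and
#' are excluded from the family size m.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA/NaN allowed).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NaN, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = if (method == "BH") "BH"
                           else "bonferroni")
  q
}

#' Construct a network from an edge table
#'
#' @param edges an edge table (`source`, `target`, `kind`, optionally
#'   `rho`, `p`, `q`, `evidence`).
#' @param roles optional named character vector id -> role
#'   (`erna`/`pcg`/`tf`/`rbp`); defaults by edge kind: coexpr/loop sources
#'   are eRNAs and targets PCGs, tf/rbp targets take their kind as role.
#' @return An `erna_network`: list with `nodes` (data.frame `id`, `role`)
#'   and `edges`.
#' @export
as_network <- function(edges, roles = NULL) {
  for (col in c("rho", "p", "q"))
    if (!col %in% names(edges)) edges[[col]] <- rep(NA_real_, nrow(edges))
  if (!"evidence" %in% names(edges))
    edges$evidence <- rep("", nrow(edges))
  if (!"kind" %in% names(edges))
    edges$kind <- rep("coexpr", nrow(edges))
  key <- paste(edges$source, edges$target, edges$kind)
  if (anyDuplicated(key))
    stop("duplicate (source, target, kind) edges", call. = FALSE)
  ids <- unique(c(edges$source, edges$target))
  role <- rep("pcg", length(ids))
  names(role) <- ids
  role[unique(edges$source)] <- "erna"
  for (k in c("tf", "rbp")) {
    tgt <- unique(edges$target[edges$kind == k])
    role[tgt] <- k
  }
  if (!is.null(roles)) role[names(roles)] <- roles
  nodes <- data.frame(id = ids, role = unname(role[ids]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "erna_network")
}

#' @export
print.erna_network <- function(x, ...) {
  cat("erna_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tab <- table(x$nodes$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Threshold co-expression edges into a network
#'
#' Keeps edges with `|rho| >= rho_min` and `q <= q_max` (both user-defined
#' thresholds; conventional defaults 0.3 and 0.05). Nodes are the endpoints
#' of kept edges only. NaN rho/q rows (zero-variance features) are dropped.
#'
#' @param edges an edge table from [spearman_edges()].
#' @param rho_min minimum absolute Spearman rho (default 0.3).
#' @param q_max maximum adjusted p-value (default 0.05).
#' @return An `erna_network`. Empty networks are allowed (with a warning).
#' @export
build_coexpression_network <- function(edges, rho_min = 0.3, q_max = 0.05) {
  keep <- !is.na(edges$rho) & !is.na(edges$q) &
    abs(edges$rho) >= rho_min & edges$q <= q_max
  kept <- edges[keep, , drop = FALSE]
  if (!nrow(kept)) warning("no edges pass the thresholds", call. = FALSE)
  as_network(kept)
}

#' Regulator edges from TF/RBP peak overlap
#'
#' A transcription factor or RNA-binding protein whose peak set overlaps an
#' eRNA span by >= 1 bp is a potential regulator of that eRNA; multiple
#' overlapping peaks of one regulator are deduplicated into a single edge
#' whose evidence records the peak count.
#'
#' @param ernas an eRNA call table (or any interval table with ids in
#'   `transcript_id`/`name`).
#' @param peak_sets a list of regulator peak sets, each a list with
#'   `regulator_id`, `kind` (`"tf"`/`"rbp"`) and `intervals` (interval
#'   data frame).
#' @return An edge table `source` (eRNA), `target` (regulator), `kind`,
#'   `rho = NA`, `p = NA`, `q = NA`, `evidence` (overlapping peak count).
#' @export
regulatory_overlaps <- function(ernas, peak_sets) {
  id <- if ("transcript_id" %in% names(ernas)) ernas$transcript_id
  else ernas$name
  spans <- if (nrow(ernas))
    genomic_intervals(ernas$chrom, ernas$start, ernas$end, name = id)
  else empty_intervals()
  rows <- lapply(peak_sets, function(ps) {
    stopifnot(ps$kind %in% c("tf", "rbp"))
    hits <- find_interval_overlaps(spans, ps$intervals)
    if (!nrow(hits)) return(NULL)
    cnt <- table(hits$query)
    data.frame(source = id[as.integer(names(cnt))],
               target = ps$regulator_id, kind = ps$kind,
               rho = NA_real_, p = NA_real_, q = NA_real_,
               evidence = as.character(as.integer(cnt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source = character(0), target = character(0),
                      kind = character(0), rho = numeric(0), p = numeric(0),
                      q = numeric(0), evidence = character(0))
  rownames(out) <- NULL
  out
}

#' Enhancer-promoter loop edges
#'
#' A loop whose anchor overlaps an eRNA span (>= 1 bp) is an eRNA-mediated
#' loop; when its other anchor overlaps a gene promoter window
#' `[tss - flank, tss + flank)` the (eRNA, gene) pair becomes a loop edge.
#' Loops mediated by an eRNA but resolving to no promoter contribute no
#' edge and are reported in the `mediated_loops` attribute.
#'
#' @param ernas an eRNA call table or interval table.
#' @param loops a loop data.frame ([read_loops()]).
#' @param genes a data.frame `gene_id`, `chrom`, `tss` (0-based TSS
#'   positions).
#' @param promoter_flank promoter half-width in bp (default 2000).
#' @return An edge table (`kind = "loop"`, evidence = supporting loop
#'   count) with attribute `mediated_loops`: a data.frame of loop index,
#'   eRNA id and whether a promoter partner was found.
#' @export
loop_edges <- function(ernas, loops, genes, promoter_flank = 2000L) {
  if (promoter_flank < 0) stop("promoter_flank must be >= 0", call. = FALSE)
  id <- if ("transcript_id" %in% names(ernas)) ernas$transcript_id
  else ernas$name
  spans <- if (nrow(ernas))
    genomic_intervals(ernas$chrom, ernas$start, ernas$end, name = id)
  else empty_intervals()
  promoters <- if (nrow(genes))
    genomic_intervals(genes$chrom, pmax(0L, genes$tss - promoter_flank),
                      genes$tss + promoter_flank, name = genes$gene_id)
  else empty_intervals()
  anchors <- list(
    a1 = genomic_intervals(loops$chrom1, loops$start1, loops$end1),
    a2 = genomic_intervals(loops$chrom2, loops$start2, loops$end2)
  )
  hit_e <- lapply(anchors, find_interval_overlaps, subject = spans)
  hit_p <- lapply(anchors, find_interval_overlaps, subject = promoters)
  pairs <- list()
  mediated <- list()
  for (li in seq_len(nrow(loops))) {
    for (side in 1:2) {
      eh <- hit_e[[side]]
      ern <- unique(eh$subject[eh$query == li])
      if (!length(ern)) next
      other <- hit_p[[3L - side]]
      prom <- unique(other$subject[other$query == li])
      for (e in ern) {
        mediated[[length(mediated) + 1L]] <-
          data.frame(loop = li, erna_id = id[e],
                     has_promoter_partner = length(prom) > 0L)
        for (g in prom)
          pairs[[length(pairs) + 1L]] <-
            data.frame(source = id[e], target = promoters$name[g],
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs)) {
    pr <- do.call(rbind, pairs)
    key <- paste(pr$source, pr$target)
    cnt <- table(key)
    uq <- !duplicated(key)
    out <- data.frame(source = pr$source[uq], target = pr$target[uq],
                      kind = "loop", rho = NA_real_, p = NA_real_,
                      q = NA_real_,
                      evidence = as.character(as.integer(cnt[key[uq]])),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(source = character(0), target = character(0),
                      kind = character(0), rho = numeric(0), p = numeric(0),
                      q = numeric(0), evidence = character(0))
  }
  med <- if (length(mediated)) unique(do.call(rbind, mediated))
  else data.frame(loop = integer(0), erna_id = character(0),
                  has_promoter_partner = logical(0))
  rownames(out) <- NULL
  rownames(med) <- NULL
  attr(out, "mediated_loops") <- med
  out
}

#' Intersect two networks
#'
#' Nodes: the id intersection of both node sets. Edges: unordered node
#' pairs present in both edge sets, regardless of edge kind; the kinds from
#' both inputs are recorded in the evidence column. Numeric columns are
#' taken from the first network's edge.
#'
#' @param a,b `erna_network` objects.
#' @return An `erna_network` (possibly with zero nodes/edges).
#' @export
intersect_networks <- function(a, b) {
  ids <- intersect(a$nodes$id, b$nodes$id)
  pair_key <- function(e)
    paste(pmin(e$source, e$target), pmax(e$source, e$target))
  ka <- pair_key(a$edges)
  kb <- pair_key(b$edges)
  keep <- which(ka %in% kb & !duplicated(ka))
  edges <- a$edges[keep, , drop = FALSE]
  if (nrow(edges)) {
    kb_kind <- vapply(ka[keep], function(k)
      paste(sort(unique(b$edges$kind[kb == k])), collapse = "+"), "")
    edges$evidence <- sprintf("a:%s;b:%s", edges$kind, kb_kind)
  }
  nodes <- unique(rbind(a$nodes, b$nodes))
  nodes <- nodes[nodes$id %in% ids, , drop = FALSE]
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "erna_network")
}

#' Write a network as edge and node TSV files
#' @param net an `erna_network`.
#' @param edges_path,nodes_path output paths (either may be NULL).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edges_path = NULL, nodes_path = NULL) {
  if (!is.null(edges_path))
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(nodes_path))
    utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(net)
}
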