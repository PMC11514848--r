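#' Hypergeometric gene-set enrichment
#'
#' For a query gene list and a collection of named gene sets over a finite
#' universe of size N: with K the set size, n the query size and k the
#' overlap, the enrichment p-value is the upper hypergeometric tail
#' `P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K, n-i) / C(N,n)`.
#' q-values are Benjamini-Hochberg adjusted within the collection (each
#' collection — e.g. GO vs KEGG vs hallmark — forms its own adjustment
#' family).
#'
#' @param query character vector of gene ids; ids outside the universe are
#'   dropped with a warning.
#' @param collection a gene-set collection ([read_gmt()],
#'   [gene_set_collection()]).
#' @param universe optional background universe overriding the
#'   collection's; sets are restricted to it.
#' @return A data.frame `set_name`, `k`, `n`, `K`, `N`, `p`, `q`, `genes`
#'   (overlapping ids, comma-joined), sorted by ascending p.
#' @export
hypergeom_enrich <- function(query, collection, universe = NULL) {
  if (is.null(universe)) universe <- collection$universe
  universe <- unique(universe)
  N <- length(universe)
  if (!N) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query id(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    K <- length(set)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- hyper_tail_p(k, K, N, n)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_bh(out$p)
  out <- out[order(out$p, out$set_name),
             c("set_name", "k", "n", "K", "N", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X hypergeometric with `K` successes in a universe of
#' `N`, drawing `n`; the enrichment p-value of an overlap of size `k`.
#'
#' @param k observed overlap (>= 0).
#' @param K gene-set size.
#' @param N universe size.
#' @param n query size.
#' @return The tail probability (1 when `k = 0`).
#' @export
hyper_tail_p <- function(k, K, N, n) {
  if (k <= 0L) return(1)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Annotate an eRNA's function from its network context
#'
#' Transfers functional labels from protein-coding genes to an eRNA by
#' running hypergeometric enrichment over three query gene lists drawn from
#' the network: (i) the eRNA's direct PCG neighbors, (ii) the PCG members
#' of each module containing the eRNA, (iii) the PCG hubs adjacent to the
#' eRNA.
#'
#' @param erna_id a node id present in `net`.
#' @param net an `erna_network`.
#' @param modules a module list ([extract_modules()]); computed from `net`
#'   when NULL.
#' @param collection a gene-set collection.
#' @param hubs hub ids ([extract_hubs()]); computed from `net` at defaults
#'   when NULL.
#' @param universe optional enrichment universe; defaults to the collection
#'   universe united with the network's PCG ids.
#' @return A list with elements `neighbors`, `modules`, `hubs`; each holds
#'   `query` (the gene list) and `enrichment` (result table), with
#'   `modules` a list of one such entry per module containing the eRNA.
#' @export
annotate_erna <- function(erna_id, net, modules = NULL, collection,
                          hubs = NULL, universe = NULL) {
  if (!erna_id %in% net$nodes$id)
    stop("node not in network: ", erna_id, call. = FALSE)
  if (is.null(modules)) modules <- extract_modules(net)
  if (is.null(hubs)) hubs <- extract_hubs(net)
  if (is.null(universe))
    universe <- union(collection$universe,
                      net$nodes$id[net$nodes$role == "pcg"])
  pcg_ids <- net$nodes$id[net$nodes$role == "pcg"]
  adj <- adjacency_list(net)
  neighbors <- intersect(adj[[erna_id]], pcg_ids)
  run <- function(q) {
    if (!length(q))
      return(list(query = character(0),
                  enrichment = hypergeom_enrich(character(0), collection,
                                                universe)[0, , drop = FALSE]))
    list(query = q,
         enrichment = suppressWarnings(
           hypergeom_enrich(q, collection, universe)))
  }
  mod_hits <- Filter(function(m) erna_id %in% m$members, modules)
  res <- list(
    neighbors = run(neighbors),
    modules = lapply(mod_hits, function(m)
      run(intersect(m$members, pcg_ids))),
    hubs = run(intersect(intersect(hubs, neighbors), pcg_ids))
  )
  if (!length(neighbors))
    warning("eRNA ", erna_id, " has no PCG neighbors; queries are empty",
            call. = FALSE)
  res
}
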