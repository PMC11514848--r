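#' Extract dense modules by greedy seed-and-expand clustering
#'
#' Unweighted dense-module extraction in the style of fast local clustering
#' of biological networks: repeatedly seed on the unclustered node of
#' highest remaining degree, pair it with its best unclustered neighbor
#' (highest remaining degree), then greedily add the unclustered vertex of
#' highest support — the fraction of current members it connects to —
#' accepting while support >= `support_threshold` and the resulting module
#' density `2 * e / (k * (k - 1))` stays >= `density_threshold`. The module
#' is emitted when expansion stops (size >= 2 always holds), its members
#' are removed, and the process repeats until no edges remain among
#' unclustered nodes. Singletons are discarded. All ties break
#' lexicographically by node id, making the output deterministic.
#'
#' @param net an `erna_network` (edge weights, if any, are ignored:
#'   unweighted mode).
#' @param density_threshold minimum module density in (0, 1\] (default 0.5).
#' @param support_threshold minimum support fraction in (0, 1\] (default
#'   0.5).
#' @return A list of modules, each a list with `members` (sorted ids),
#'   `density`, and `ernas` (member ids with role `erna`).
#' @export
extract_modules <- function(net, density_threshold = 0.5,
                            support_threshold = 0.5) {
  if (density_threshold <= 0 || density_threshold > 1 ||
      support_threshold <= 0 || support_threshold > 1)
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  adj <- adjacency_list(net)
  unclustered <- sort(names(adj))
  erna_ids <- net$nodes$id[net$nodes$role == "erna"]
  modules <- list()
  repeat {
    deg <- vapply(unclustered, function(v)
      length(intersect(adj[[v]], unclustered)), 0L)
    if (!length(deg) || max(deg) == 0L) break
    seed <- unclustered[deg == max(deg)][1L]  # unclustered sorted -> lex tie
    # unweighted mode: all neighbors weigh equally, so the "best" neighbor
    # is resolved purely by the lexicographic tie-break
    partner <- sort(intersect(adj[[seed]], unclustered))[1L]
    members <- c(seed, partner)
    n_within <- 1L
    repeat {
      cand <- sort(setdiff(
        intersect(unique(unlist(adj[members])), unclustered), members))
      if (!length(cand)) break
      supp_edges <- vapply(cand, function(v)
        length(intersect(adj[[v]], members)), 0L)
      support <- supp_edges / length(members)
      best <- cand[support == max(support)][1L]
      k <- length(members) + 1L
      new_within <- n_within + unname(supp_edges[match(best, cand)])
      new_density <- 2 * new_within / (k * (k - 1L))
      if (max(support) < support_threshold ||
          new_density < density_threshold) break
      members <- c(members, best)
      n_within <- new_within
    }
    members <- sort(members)
    modules[[length(modules) + 1L]] <- list(
      members = members,
      density = 2 * n_within / (length(members) * (length(members) - 1L)),
      ernas = intersect(members, erna_ids)
    )
    unclustered <- setdiff(unclustered, members)
  }
  modules
}

#' @keywords internal
adjacency_list <- function(net) {
  e <- net$edges
  src <- pmin(e$source, e$target)
  tgt <- pmax(e$source, e$target)
  key <- paste(src, tgt)
  uq <- !duplicated(key) & src != tgt
  src <- src[uq]
  tgt <- tgt[uq]
  ids <- sort(unique(net$nodes$id))
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(src)) {
    adj[[src[i]]] <- c(adj[[src[i]]], tgt[i])
    adj[[tgt[i]]] <- c(adj[[tgt[i]]], src[i])
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Extract hub nodes by degree
#'
#' Hubs are nodes whose degree reaches
#' `max(min_degree, (1 - top_fraction) degree quantile)` over all network
#' nodes (isolated nodes count with degree 0). The degree-quantile-with-
#' floor criterion is this package's definition of a hub.
#'
#' @param net an `erna_network`.
#' @param top_fraction upper tail fraction of the degree distribution to
#'   admit (default 0.05).
#' @param min_degree hard floor on hub degree (default 5).
#' @return Character vector of hub ids, sorted by degree descending, ties
#'   by id.
#' @export
extract_hubs <- function(net, top_fraction = 0.05, min_degree = 5L) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]", call. = FALSE)
  adj <- adjacency_list(net)
  deg <- vapply(adj, length, 0L)
  if (!length(deg)) return(character(0))
  cutoff <- max(min_degree,
                stats::quantile(deg, 1 - top_fraction, names = FALSE))
  hubs <- names(deg)[deg >= cutoff]
  hubs[order(-deg[hubs], hubs)]
}

#' Module list as a data.frame
#' @param modules output of [extract_modules()].
#' @return A data.frame `module`, `size`, `density`, `members`
#'   (comma-joined), `ernas`.
#' @export
modules_table <- function(modules) {
  data.frame(
    module = sprintf("M%d", seq_along(modules)),
    size = vapply(modules, function(m) length(m$members), 0L),
    density = vapply(modules, `[[`, 0, "density"),
    members = vapply(modules, function(m)
      paste(m$members, collapse = ","), ""),
    ernas = vapply(modules, function(m)
      paste(m$ernas, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}
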