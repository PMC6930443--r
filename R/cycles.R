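#' Kill graph of an assembly
#'
#' The directed graph whose vertices are populations and whose edges are the
#' clicks, oriented killer to victim.
#'
#' @param a A `click_assembly`.
#' @return An [igraph::igraph] directed graph.
#' @export
kill_graph <- function(a) {
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(a$populations$id)
  if (nrow(a$kill_edges))
    g <- igraph::add_edges(g, rbind(a$kill_edges$killer, a$kill_edges$victim))
  g
}

# Adjacency list (named list of character vectors, killer -> victims).
kill_adjacency <- function(a) {
  ids <- a$populations$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) adj[[id]] <- character(0)
  for (i in seq_len(nrow(a$kill_edges)))
    adj[[a$kill_edges$killer[i]]] <-
      c(adj[[a$kill_edges$killer[i]]], a$kill_edges$victim[i])
  adj
}

# All simple directed cycles of length <= max_len, as vectors of node ids in
# edge orientation. Bounded DFS rooted at each node; a cycle is recorded only
# at its lexicographically smallest member, so each cycle appears once.
enumerate_cycles <- function(adj, max_len = Inf) {
  nodes <- sort(names(adj))
  out <- list()
  for (root in nodes) {
    path <- root
    dfs <- function(v) {
      for (w in adj[[v]]) {
        if (w < root) next            # only cycles rooted at their min node
        if (w == root) {
          if (length(path) >= 2L) out[[length(out) + 1L]] <<- path
        } else if (!(w %in% path) && length(path) < max_len) {
          path <<- c(path, w)
          dfs(w)
          path <<- path[-length(path)]
        }
      }
    }
    dfs(root)
  }
  out
}

#' Smallest directed kill cycle of an assembly
#'
#' Contextual cell death reduces an assembly to the smallest directed cycle
#' that can sustain a response; this returns that cycle in the kill graph.
#' Ties between equally short cycles are broken first by the lexicographic
#' order of the sorted member ids, then by the edge sequence after rotating
#' the cycle to start at its lexicographically smallest member.
#'
#' @param a A `click_assembly`.
#' @return Character vector of population ids in killer-to-victim order
#'   (starting at the smallest member), or `character(0)` if the kill graph
#'   is acyclic.
#' @export
smallest_directed_cycle <- function(a) {
  adj <- kill_adjacency(a)
  if (!nrow(a$kill_edges)) return(character(0))
  # Shortest cycle length via BFS: for every edge u->v, the shortest path
  # v ~> u closes a cycle of length dist(v, u) + 1.
  g <- kill_graph(a)
  d <- igraph::distances(g, mode = "out")
  ke <- a$kill_edges
  lens <- d[cbind(ke$victim, ke$killer)] + 1
  if (all(!is.finite(lens))) return(character(0))
  L <- min(lens)
  cands <- enumerate_cycles(adj, max_len = L)
  cands <- cands[lengths(cands) == L]
  rotate_min <- function(cyc) {
    k <- which(cyc == min(cyc))[1L]
    if (k > 1L) cyc <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
    cyc
  }
  cands <- lapply(cands, rotate_min)
  keys <- vapply(cands, function(cyc)
    paste(c(sort(cyc), cyc), collapse = "\r"), character(1))
  cands[[order(keys)[1L]]]
}
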