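# Independent oracles used across the suite.

# Brute-force enumeration of ALL simple directed cycles of a kill graph,
# as canonical strings (rotated to start at the smallest member). Depth-
# unbounded DFS over the edge list; independent of the package's bounded
# search and BFS length computation.
oracle_all_cycles <- function(edges_df) {
  nodes <- sort(unique(c(edges_df$killer, edges_df$victim)))
  succ <- lapply(stats::setNames(nodes, nodes), function(v)
    edges_df$victim[edges_df$killer == v])
  found <- character(0)
  visit <- function(path) {
    v <- path[length(path)]
    for (w in succ[[v]]) {
      if (w == path[1]) {
        if (length(path) >= 2) {
          k <- which(path == min(path))[1]
          rot <- c(path[k:length(path)], path[seq_len(k - 1)])
          found <<- unique(c(found, paste(rot, collapse = ">")))
        }
      } else if (!(w %in% path)) visit(c(path, w))
    }
  }
  for (v in nodes) visit(v)
  found
}

oracle_shortest_cycle <- function(edges_df) {
  cycles <- oracle_all_cycles(edges_df)
  if (!length(cycles)) return(character(0))
  parts <- strsplit(cycles, ">", fixed = TRUE)
  lens <- lengths(parts)
  parts <- parts[lens == min(lens)]
  keys <- vapply(parts, function(cyc)
    paste(c(sort(cyc), cyc), collapse = "\r"), character(1))
  parts[[order(keys)[1]]]
}

# Random directed graph with at most one edge per unordered pair (the click
# exclusivity rule), returned as a kill-edge data frame over letter ids.
random_kill_graph <- function(n_nodes, p_edge = 0.4) {
  ids <- letters[seq_len(n_nodes)]
  rows <- list()
  for (i in seq_len(n_nodes - 1)) for (j in seq(i + 1, n_nodes)) {
    if (stats::runif(1) < p_edge) {
      pair <- if (stats::runif(1) < 0.5) c(ids[i], ids[j]) else c(ids[j], ids[i])
      rows[[length(rows) + 1]] <- kill_edge(pair[1], pair[2])
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

assembly_from_edges <- function(edges_df, extra_ids = character(0)) {
  ids <- sort(unique(c(edges_df$killer, edges_df$victim, extra_ids)))
  pops <- do.call(rbind, lapply(ids, function(id)
    population(id, lineage = id, stage = "young")))
  assembly(pops, edges_df)
}

# Reference CA stepper: mirrors the compiled sweep draw-for-draw using R's
# RNG, written independently against the documented draw protocol.
reference_ca_sweep <- function(states, ids, kill_edge_m, kill_prob_m,
                               rep_prob, mat_prob, mat_target, death_prob) {
  H <- nrow(states); W <- ncol(states); N <- H * W
  g <- states
  for (k in seq_len(N)) {
    site <- floor(stats::runif(1) * N)
    if (site >= N) site <- N - 1
    focal <- g[site + 1]
    if (focal == 0) next
    r <- site %% H; cc <- site %/% H
    dir <- floor(stats::runif(1) * 4)
    if (dir >= 4) dir <- 3
    nr <- r; nc <- cc
    if (dir == 0) nr <- (r - 1) %% H
    else if (dir == 1) nr <- (r + 1) %% H
    else if (dir == 2) nc <- (cc - 1) %% W
    else nc <- (cc + 1) %% W
    nsite <- nc * H + nr
    nb <- g[nsite + 1]
    if (nb > 0 && kill_edge_m[focal, nb] == 1) {
      if (stats::runif(1) < kill_prob_m[focal, nb]) g[nsite + 1] <- 0L
    } else if (nb == 0) {
      if (stats::runif(1) < rep_prob[focal]) g[nsite + 1] <- focal
    }
  }
  for (site in seq_len(N)) {
    st <- g[site]
    if (st == 0) next
    um <- stats::runif(1)
    if (mat_target[st] > 0 && um < mat_prob[st]) {
      st <- as.integer(mat_target[st])
      g[site] <- st
    }
    ud <- stats::runif(1)
    if (ud < death_prob[st]) g[site] <- 0L
  }
  g
}

canonical_params <- function() ode_params(t_end = 400, n_samples = 1601)
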