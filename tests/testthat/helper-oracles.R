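# Brute-force oracles, independent of the package's algorithms.

# build a DAG from "A>B" edge strings
dag_from <- function(nodes, edges, types = NULL, categories = NULL) {
  g <- mixed_graph(nodes, types, categories)
  for (e in edges) {
    ab <- strsplit(e, ">", fixed = TRUE)[[1L]]
    g <- add_directed_edge(g, ab[1L], ab[2L])
  }
  g
}

# all subsets of a character vector
all_subsets <- function(v) {
  out <- list(character())
  for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
  out
}

# exhaustive DFS ancestor oracle (path enumeration over directed edges)
bf_is_ancestor <- function(g, a, b) {
  if (a == b) return(FALSE)
  paths_from <- function(v, visited) {
    if (v == b) return(TRUE)
    for (ch in children(g, v)) {
      if (ch %in% visited) next
      if (paths_from(ch, c(visited, ch))) return(TRUE)
    }
    FALSE
  }
  paths_from(a, a)
}

# enumerate all simple undirected paths between x and y
bf_all_paths <- function(g, x, y) {
  out <- list()
  dfs <- function(path) {
    cur <- path[length(path)]
    if (cur == y) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (nb in adjacencies(g, cur)) {
      if (nb %in% path) next
      dfs(c(path, nb))
    }
  }
  dfs(x)
  out
}

# brute-force d-separation: every path must be blocked, applying the
# per-path blocking rule (non-collider in s, or collider with no self/
# descendant in s)
bf_d_separated <- function(g, x, y, s) {
  anc <- if (length(edge_set(g))) ancestor_matrix(g) else
    matrix(FALSE, length(g$nodes), length(g$nodes),
           dimnames = list(g$nodes, g$nodes))
  for (path in bf_all_paths(g, x, y)) {
    if (length(path) == 2L) return(FALSE)  # direct edge never blocked
    open <- TRUE
    for (i in 2:(length(path) - 1L)) {
      prev <- path[i - 1L]; v <- path[i]; nxt <- path[i + 1L]
      collider <- endpoint(g, prev, v) == EP_ARROW &&
        endpoint(g, nxt, v) == EP_ARROW
      if (collider) {
        desc_in_s <- v %in% s || any(vapply(s, function(w) anc[v, w],
                                            logical(1L)))
        if (!desc_in_s) { open <- FALSE; break }
      } else {
        if (v %in% s) { open <- FALSE; break }
      }
    }
    if (open) return(FALSE)
  }
  TRUE
}

# brute-force Possible-D-Sep via simple-path enumeration with the
# collider-or-triangle rule on every interior vertex
bf_possible_dsep <- function(g, x, y = NULL) {
  reach <- character()
  for (v in setdiff(g$nodes, x)) {
    for (path in bf_all_paths(g, x, v)) {
      ok <- TRUE
      if (length(path) > 2L) {
        for (i in 2:(length(path) - 1L)) {
          prev <- path[i - 1L]; m <- path[i]; nxt <- path[i + 1L]
          collider <- endpoint(g, prev, m) == EP_ARROW &&
            endpoint(g, nxt, m) == EP_ARROW
          triangle <- is_adjacent(g, prev, nxt)
          if (!collider && !triangle) { ok <- FALSE; break }
        }
      }
      if (ok) { reach <- c(reach, v); break }
    }
  }
  setdiff(sort(unique(reach)), c(x, y))
}

# random small DAG for property tests (uniform pairs under a random
# topological order)
random_test_dag <- function(n_nodes, n_edges, types = NULL) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  g <- mixed_graph(nodes, types)
  ord <- sample(nodes)
  pairs <- utils::combn(n_nodes, 2L)
  pick <- sample(ncol(pairs), min(n_edges, ncol(pairs)))
  for (k in pick)
    g <- add_directed_edge(g, ord[pairs[1L, k]], ord[pairs[2L, k]])
  g
}

# draw a simulated study in a small world (shared by several test files)
small_study <- function(seed, n_nodes = 10L, edges = 12, sd = 3,
                        latents = 2L, n = 500L) {
  simulate_study(sim_config(n_nodes = n_nodes, edge_count_mean = edges,
                            edge_count_sd = sd, n_latents = latents,
                            n_samples = n), seed = seed)
}
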