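# The constraint-based search family over partial ancestral graphs:
# order-independent (stable) skeleton search, collider orientation in three
# modes (first recorded separating set, maximum-p-value separating set,
# conservative), the Possible-D-Sep phase needed for correctness under
# latent confounding, and the complete orientation-rule closure.

#' Search configuration for the FCI family
#'
#' @param mode one of `"FCI"` (first recorded separating set), `"FCI_MAX"`
#'   (maximum-p separating set) or `"CFCI"` (conservative collider
#'   classification).
#' @param alpha significance threshold of the independence test.
#' @param depth maximum conditioning-set size in the skeleton and collider
#'   searches (-1 = unlimited).
#' @param initial_graph optional undirected [mixed_graph()]; the skeleton
#'   search starts from it instead of the complete graph (used by the
#'   MGM-constrained hybrids).
#' @param cores number of processors assumed by the collider job scheduler.
#' @param chunk_beta chunk-size multiplier for job subdivision: a batch is
#'   split while its summed adjacency load exceeds `|E| * chunk_beta /
#'   cores`.
#' @param pdsep_depth maximum conditioning-set size in the Possible-D-Sep
#'   phase (-1 = unlimited).
#' @param cache_cap maximum number of cached independence-test results per
#'   run.
#' @export
search_config <- function(mode = c("FCI", "FCI_MAX", "CFCI"), alpha = 0.05,
                          depth = 3L, initial_graph = NULL, cores = 1L,
                          chunk_beta = 1, pdsep_depth = 3L,
                          cache_cap = 100000L) {
  mode <- match.arg(mode)
  stopifnot(depth >= -1L, cores >= 1L, chunk_beta > 0)
  structure(list(mode = mode, alpha = alpha, depth = as.integer(depth),
                 initial_graph = initial_graph, cores = as.integer(cores),
                 chunk_beta = chunk_beta, pdsep_depth = as.integer(pdsep_depth),
                 cache_cap = as.integer(cache_cap)),
            class = "search_config")
}

# canonical subset enumeration: sizes ascending, members in name order
subsets_of_size <- function(vars, k) {
  vars <- sort(vars)
  if (k == 0L) return(list(character()))
  if (length(vars) < k) return(list())
  cmb <- utils::combn(vars, k, simplify = FALSE)
  cmb
}

subsets_up_to <- function(vars, maxk) {
  maxk <- if (maxk < 0L) length(vars) else min(maxk, length(vars))
  out <- list()
  for (k in 0:maxk) out <- c(out, subsets_of_size(vars, k))
  out
}

# memoized test wrapper (per-run cache, flushed when the cap is reached;
# full caching is exponential in the number of nodes)
cached_test <- function(test, cap = 100000L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  function(x, y, s = character()) {
    key <- paste(pair_key(x, y), paste(sort(s), collapse = ","), sep = "||")
    if (exists(key, envir = env, inherits = FALSE))
      return(get(key, envir = env, inherits = FALSE))
    res <- test(x, y, s)
    if (env$n >= cap) {            # flush rather than track recency
      rm(list = ls(env)[ls(env) != "n"], envir = env)
      env$n <- 0L
    }
    assign(key, res, envir = env)
    env$n <- env$n + 1L
    res
  }
}

#' Order-independent (stable) skeleton search
#'
#' Level-wise PC-style search: at conditioning size k every surviving edge
#' is tested against all size-k subsets of the adjacencies of either
#' endpoint, with adjacency sets frozen at the start of the level and edges
#' deleted only after the level completes.  The first separating set found
#' per removed edge is recorded.
#'
#' @param nodes character vector of variable names (or NULL to take them
#'   from `cfg$initial_graph`).
#' @param cfg a [search_config()].
#' @param test a test closure `function(x, y, s)` returning a `ci_result`
#'   (see [make_data_test()], [make_oracle_test()]).
#' @return list with `graph` (undirected [mixed_graph()]) and `sepsets`
#'   (a [sepset_map()]).
#' @export
stable_skeleton <- function(nodes = NULL, cfg = search_config(), test) {
  if (is.null(nodes)) {
    if (is.null(cfg$initial_graph)) stop("need nodes or cfg$initial_graph")
    nodes <- cfg$initial_graph$nodes
  }
  nodes <- sort(nodes)
  if (!is.null(cfg$initial_graph)) {
    g <- induced_subgraph(skeleton_of(cfg$initial_graph), nodes)
  } else {
    g <- mixed_graph(nodes)
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
      if (i < j) g <- add_edge(g, nodes[i], nodes[j], EP_CIRCLE, EP_CIRCLE)
    }
  }
  sepsets <- sepset_map()
  maxk <- if (cfg$depth < 0L) length(nodes) - 2L else cfg$depth
  k <- 0L
  while (k <= maxk) {
    adj_frozen <- stats::setNames(lapply(nodes, function(v) adjacencies(g, v)),
                                  nodes)
    if (!any(lengths(adj_frozen) - 1L >= k)) break
    to_remove <- character()
    ep <- graph_edge_pairs(g)
    for (r in seq_len(nrow(ep))) {
      x <- ep[r, 1L]; y <- ep[r, 2L]
      found <- FALSE
      for (side in list(c(x, y), c(y, x))) {
        if (found) break
        cands <- setdiff(adj_frozen[[side[1L]]], side[2L])
        if (length(cands) < k) next
        for (S in subsets_of_size(cands, k)) {
          res <- test(x, y, S)
          if (isTRUE(res$independent)) {
            sepset_put(sepsets, x, y, S, res$pvalue)
            to_remove <- c(to_remove, pair_key(x, y))
            found <- TRUE
            break
          }
        }
      }
    }
    for (key in to_remove) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      g <- remove_edge(g, ab[1L], ab[2L])
    }
    k <- k + 1L
  }
  list(graph = g, sepsets = sepsets)
}

#' Maximum-p separating set for a non-adjacent pair
#'
#' Evaluates the independence test over every subset (up to `cfg$depth`) of
#' the adjacencies of `x` and of `z` (plus `extra` candidate sets, e.g. the
#' recorded first-found separating set) and returns the subset with the
#' largest p-value.  Ties are broken in favour of the smaller set, then by
#' lexicographic member order; both are implied by the canonical enumeration
#' order.
#'
#' @param x,z non-adjacent node names.
#' @param g the current [mixed_graph()].
#' @param cfg a [search_config()].
#' @param test a test closure.
#' @param extra optional list of extra candidate conditioning sets.
#' @return list with `set`, `pvalue` and `separates` (TRUE iff the best
#'   p-value exceeds `cfg$alpha`).
#' @export
max_p_sepset <- function(x, z, g, cfg = search_config(), test, extra = NULL) {
  cands <- c(subsets_up_to(setdiff(adjacencies(g, x), z), cfg$depth),
             subsets_up_to(setdiff(adjacencies(g, z), x), cfg$depth))
  if (!is.null(extra)) cands <- c(extra, cands)
  # canonical order: size ascending then lexicographic; first max wins
  keys <- vapply(cands, function(s) paste(sort(s), collapse = ","),
                 character(1L))
  ord <- order(lengths(cands), keys)
  cands <- cands[ord]; keys <- keys[ord]
  cands <- cands[!duplicated(keys)]
  best <- NULL; best_p <- -1
  for (S in cands) {
    S <- sort(S)
    res <- test(x, z, S)
    if (res$pvalue > best_p) { best_p <- res$pvalue; best <- S }
  }
  list(set = best, pvalue = best_p, separates = best_p > cfg$alpha)
}

# ---- collider classification -------------------------------------------

triple_key <- function(x, y, z) paste(x, y, z, sep = "|")

# unshielded triples (x, y, z), x < z by name, as a list
unshielded_triples <- function(g) {
  out <- list()
  for (y in sort(g$nodes)) {
    adj <- adjacencies(g, y)
    if (length(adj) < 2L) next
    cmb <- utils::combn(adj, 2L)
    for (k in seq_len(ncol(cmb))) {
      x <- cmb[1L, k]; z <- cmb[2L, k]
      if (!is_adjacent(g, x, z))
        out[[length(out) + 1L]] <- list(x = x, y = y, z = z)
    }
  }
  out
}

# classify one unshielded triple; returns "COLLIDER", "NONCOLLIDER" or
# "AMBIGUOUS"
classify_triple <- function(tr, g, mode, sepsets, cfg, test) {
  x <- tr$x; y <- tr$y; z <- tr$z
  rec <- sepset_get(sepsets, x, z)
  if (mode == "FCI") {
    if (is.null(rec)) return("AMBIGUOUS")  # no separation evidence recorded
    if (y %in% rec$set) "NONCOLLIDER" else "COLLIDER"
  } else if (mode == "FCI_MAX") {
    mp <- max_p_sepset(x, z, g, cfg, test,
                       extra = if (is.null(rec)) NULL else list(rec$set))
    sepset_put(sepsets, x, z, mp$set, mp$pvalue)
    if (y %in% mp$set) "NONCOLLIDER" else "COLLIDER"
  } else {  # CFCI
    cands <- c(subsets_up_to(setdiff(adjacencies(g, x), z), cfg$depth),
               subsets_up_to(setdiff(adjacencies(g, z), x), cfg$depth))
    if (!is.null(rec)) cands <- c(list(rec$set), cands)
    keys <- vapply(cands, function(s) paste(sort(s), collapse = ","),
                   character(1L))
    cands <- cands[!duplicated(keys)]
    seps <- Filter(function(S) isTRUE(test(x, z, S)$independent), cands)
    if (!length(seps)) return("AMBIGUOUS")
    inall <- all(vapply(seps, function(S) y %in% S, logical(1L)))
    innone <- !any(vapply(seps, function(S) y %in% S, logical(1L)))
    if (innone) "COLLIDER" else if (inall) "NONCOLLIDER" else "AMBIGUOUS"
  }
}

#' Subdivide collider-orientation work into balanced job batches
#'
#' A batch of unshielded triples is recursively bisected while its summed
#' load (the number of edges adjacent to the outer nodes of each triple)
#' exceeds `|E| * beta / cores`.  The batches partition the input exactly
#' and their evaluation order does not affect results: orientation decisions
#' are computed per triple and merged afterwards.
#'
#' @param triples list of unshielded triples (`list(x =, y =, z =)`).
#' @param g the current [mixed_graph()].
#' @param cores number of processors.
#' @param beta chunk-size multiplier.
#' @return list of batches, each a list of triples.
#' @export
partition_collider_jobs <- function(triples, g, cores = 1L, beta = 1) {
  stopifnot(cores >= 1L, beta > 0)
  if (!length(triples)) return(list())
  load <- vapply(triples, function(tr) {
    length(adjacencies(g, tr$x)) + length(adjacencies(g, tr$z))
  }, numeric(1L))
  chunk <- n_edges(g) * beta / cores
  subdivide <- function(idx) {
    if (length(idx) <= 1L || sum(load[idx]) <= chunk) return(list(idx))
    half <- length(idx) %/% 2L
    c(subdivide(idx[seq_len(half)]), subdivide(idx[-seq_len(half)]))
  }
  batches <- subdivide(seq_along(triples))
  lapply(batches, function(idx) triples[idx])
}

#' Orient unshielded colliders
#'
#' Classifies every unshielded triple of the skeleton in the configured
#' mode and adds the implied arrowheads.  Triple decisions are computed
#' independently (in scheduler batches) and merged afterwards, so batch
#' order cannot affect the result.  When `prior` decisions and a pre-phase
#' adjacency `snapshot` are supplied, a triple whose outer-node adjacency
#' sets are unchanged reuses its prior classification without retesting
#' (collider retention).
#'
#' @param g undirected or circle-reset [mixed_graph()].
#' @param sepsets a [sepset_map()]; updated in place in max-p mode.
#' @param cfg a [search_config()].
#' @param test a test closure.
#' @param prior optional named list of prior triple classifications.
#' @param snapshot optional named list of pre-phase adjacency sets.
#' @return list with `graph`, `decisions` (named classification list) and
#'   `ambiguous` (keys of unfaithful triples).
#' @export
orient_colliders <- function(g, sepsets, cfg = search_config(), test,
                             prior = NULL, snapshot = NULL) {
  triples <- unshielded_triples(g)
  batches <- partition_collider_jobs(triples, g, cfg$cores, cfg$chunk_beta)
  decisions <- list()
  for (batch in batches) {
    for (tr in batch) {
      key <- triple_key(tr$x, tr$y, tr$z)
      if (!is.null(prior) && !is.null(prior[[key]]) && !is.null(snapshot) &&
          identical(snapshot[[tr$x]], adjacencies(g, tr$x)) &&
          identical(snapshot[[tr$z]], adjacencies(g, tr$z))) {
        decisions[[key]] <- prior[[key]]
      } else {
        decisions[[key]] <- classify_triple(tr, g, cfg$mode, sepsets, cfg, test)
      }
    }
  }
  for (tr in triples) {
    if (identical(decisions[[triple_key(tr$x, tr$y, tr$z)]], "COLLIDER")) {
      g$marks[tr$x, tr$y] <- EP_ARROW
      g$marks[tr$z, tr$y] <- EP_ARROW
    }
  }
  amb <- names(decisions)[vapply(decisions, identical, logical(1L),
                                 "AMBIGUOUS")]
  list(graph = g, decisions = decisions, ambiguous = amb)
}

#' Possible-D-Sep set of a node
#'
#' Nodes v reachable from `x` along a path on which every non-endpoint
#' vertex is either a collider on the path or part of a triangle with its
#' two path neighbours.
#'
#' @param g partially oriented [mixed_graph()].
#' @param x node name.
#' @param y optional node excluded from the returned set.
#' @export
possible_dsep <- function(g, x, y = NULL) {
  reached <- character()
  visited <- new.env(parent = emptyenv())
  queue <- list()
  for (v in adjacencies(g, x)) {
    queue[[length(queue) + 1L]] <- c(x, v)
    assign(paste(x, v), TRUE, envir = visited)
    reached <- c(reached, v)
  }
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    a <- st[1L]; b <- st[2L]
    for (cnode in adjacencies(g, b)) {
      if (cnode == a || cnode == x) next
      key <- paste(b, cnode)
      if (exists(key, envir = visited, inherits = FALSE)) next
      collider_at_b <- g$marks[a, b] == EP_ARROW && g$marks[cnode, b] == EP_ARROW
      triangle <- is_adjacent(g, a, cnode)
      if (collider_at_b || triangle) {
        assign(key, TRUE, envir = visited)
        queue[[length(queue) + 1L]] <- c(b, cnode)
        reached <- c(reached, cnode)
      }
    }
  }
  out <- sort(unique(reached))
  setdiff(out, c(x, y))
}

#' Possible-D-Sep edge-removal phase
#'
#' For each surviving edge (x, y), tests subsets (sizes 1..`pdsep_depth`)
#' of Possible-D-Sep(x) \\ {x, y} and symmetrically of Possible-D-Sep(y);
#' removes the edge and records the separating set on independence.  Nodes
#' whose adjacency changed are reported so downstream reorientation can
#' retain unaffected colliders.
#'
#' @param g [mixed_graph()] after the first collider orientation.
#' @param sepsets a [sepset_map()], updated in place.
#' @param cfg a [search_config()].
#' @param test a test closure.
#' @return list with `graph`, `sepsets` and `changed` (character vector of
#'   nodes with any adjacency change).
#' @export
pdsep_phase <- function(g, sepsets, cfg = search_config(), test) {
  changed <- character()
  ep <- graph_edge_pairs(g)
  for (r in seq_len(nrow(ep))) {
    x <- ep[r, 1L]; y <- ep[r, 2L]
    if (!is_adjacent(g, x, y)) next
    removed <- FALSE
    for (side in list(c(x, y), c(y, x))) {
      if (removed) break
      pds <- setdiff(possible_dsep(g, side[1L], side[2L]), c(x, y))
      maxk <- if (cfg$pdsep_depth < 0L) length(pds)
              else min(cfg$pdsep_depth, length(pds))
      if (maxk < 1L) next
      for (k in seq_len(maxk)) {
        if (removed) break
        for (S in subsets_of_size(pds, k)) {
          res <- test(x, y, S)
          if (isTRUE(res$independent)) {
            sepset_put(sepsets, x, y, S, res$pvalue)
            g <- remove_edge(g, x, y)
            changed <- c(changed, x, y)
            removed <- TRUE
            break
          }
        }
      }
    }
  }
  list(graph = g, sepsets = sepsets, changed = sort(unique(changed)))
}

# ---- orientation rules --------------------------------------------------

# potentially-directed edge u -> v: endpoint at u not an arrow, endpoint at
# v not a tail
pd_edge <- function(g, u, v) {
  g$marks[u, v] != EP_NULL && g$marks[v, u] != EP_ARROW &&
    g$marks[u, v] != EP_TAIL
}

# uncovered potentially-directed path from a to b; when `via` is given the
# path must start a -> via -> ...; when `first_nonadj_to` is given the first
# intermediate vertex must be non-adjacent to that node; `circle_only`
# restricts to circle-circle edges.  Returns the path (character vector) or
# NULL.  Simple-path DFS.
find_ucp_path <- function(g, a, b, via = NULL, first_nonadj_to = NULL,
                          circle_only = FALSE, max_steps = 20000L) {
  edge_ok <- function(u, v) {
    if (circle_only)
      g$marks[u, v] == EP_CIRCLE && g$marks[v, u] == EP_CIRCLE
    else pd_edge(g, u, v)
  }
  steps <- 0L
  dfs <- function(path) {
    steps <<- steps + 1L
    if (steps > max_steps) return(NULL)  # deterministic search budget
    cur <- path[length(path)]
    if (cur == b && length(path) >= 3L) return(path)
    for (nxt in adjacencies(g, cur)) {
      if (nxt %in% path) next
      if (!edge_ok(cur, nxt)) next
      if (length(path) >= 2L &&
          is_adjacent(g, path[length(path) - 1L], nxt)) next  # covered triple
      if (length(path) == 1L) {
        if (!is.null(via) && nxt != via) next
        if (!is.null(first_nonadj_to) &&
            (nxt == first_nonadj_to || is_adjacent(g, nxt, first_nonadj_to)))
          next
      }
      res <- dfs(c(path, nxt))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  dfs(a)
}

# discriminating path search: for edge b o-* c, find <d, ..., a, b, c> with
# every vertex between d and b a collider on the path and a parent of c,
# and d not adjacent to c.  Returns list(d =, a =) or NULL.
find_discriminating <- function(g, b, c) {
  is_parent <- function(u, v) g$marks[u, v] == EP_ARROW &&
    g$marks[v, u] == EP_TAIL
  visited <- character()
  queue <- list()
  for (a in adjacencies(g, b)) {
    if (a == c) next
    if (g$marks[b, a] != EP_ARROW) next       # arrow at a on a--b
    if (!is_parent(a, c)) next
    queue[[length(queue) + 1L]] <- c(a, a)    # (current, first 'a')
    visited <- c(visited, a)
  }
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    prev <- st[1L]; first_a <- st[2L]
    for (u in adjacencies(g, prev)) {
      if (u %in% c(b, c) || u %in% visited) next
      if (g$marks[u, prev] != EP_ARROW) next  # arrow at prev on u--prev
      if (!is_adjacent(g, u, c)) {
        return(list(d = u, a = first_a))
      }
      if (is_parent(u, c) && g$marks[prev, u] == EP_ARROW) {
        visited <- c(visited, u)
        queue[[length(queue) + 1L]] <- c(u, first_a)
      }
    }
  }
  NULL
}

# One pass of the orientation rules; only circle endpoints are ever
# modified.  Returns list(graph, changed).
zhang_rule_pass <- function(g, sepsets, cfg, lookup_sepset) {
  changed <- FALSE
  ns <- sort(g$nodes)
  set_mark <- function(a, b, mark) {
    # mark at b on edge a--b, only upgrading circles
    if (g$marks[a, b] == EP_CIRCLE && g$marks[a, b] != mark) {
      g$marks[a, b] <<- mark
      changed <<- TRUE
    }
  }
  # R1 and R2
  for (b in ns) for (a in ns) {
    if (a == b || !is_adjacent(g, a, b)) next
    for (cn in ns) {
      if (cn == a || cn == b) next
      # R1: a *-> b o-* c, a and c non-adjacent  =>  b -> c
      if (is_adjacent(g, b, cn) && !is_adjacent(g, a, cn) &&
          g$marks[a, b] == EP_ARROW && g$marks[cn, b] == EP_CIRCLE) {
        set_mark(cn, b, EP_TAIL)
        set_mark(b, cn, EP_ARROW)
      }
      # R2: (a -> b *-> c) or (a *-> b -> c), a *-o c  =>  arrow at c
      if (is_adjacent(g, a, cn) && g$marks[a, cn] == EP_CIRCLE &&
          is_adjacent(g, b, cn)) {
        case1 <- g$marks[a, b] == EP_ARROW && g$marks[b, a] == EP_TAIL &&
          g$marks[b, cn] == EP_ARROW
        case2 <- g$marks[a, b] == EP_ARROW && g$marks[b, cn] == EP_ARROW &&
          g$marks[cn, b] == EP_TAIL
        if (case1 || case2) set_mark(a, cn, EP_ARROW)
      }
    }
  }
  # R3: a *-> b <-* c, a *-o d o-* c, a,c non-adjacent, d *-o b  =>  d *-> b
  for (b in ns) for (d in ns) {
    if (b == d || !is_adjacent(g, b, d) || g$marks[d, b] != EP_CIRCLE) next
    adjb <- adjacencies(g, b); adjd <- adjacencies(g, d)
    for (a in intersect(adjb, adjd)) for (cn in intersect(adjb, adjd)) {
      if (a >= cn || a == b || cn == b) next
      if (is_adjacent(g, a, cn)) next
      if (g$marks[a, b] == EP_ARROW && g$marks[cn, b] == EP_ARROW &&
          g$marks[a, d] == EP_CIRCLE && g$marks[cn, d] == EP_CIRCLE) {
        set_mark(d, b, EP_ARROW)
      }
    }
  }
  # R4: discriminating paths
  for (b in ns) for (cn in ns) {
    if (b == cn || !is_adjacent(g, b, cn)) next
    if (g$marks[cn, b] != EP_CIRCLE) next
    dp <- find_discriminating(g, b, cn)
    if (is.null(dp)) next
    rec <- lookup_sepset(dp$d, cn)
    if (is.null(rec)) next
    if (b %in% rec$set) {
      set_mark(cn, b, EP_TAIL)
      set_mark(b, cn, EP_ARROW)
    } else {
      set_mark(b, dp$a, EP_ARROW)
      set_mark(dp$a, b, EP_ARROW)
      set_mark(b, cn, EP_ARROW)
      set_mark(cn, b, EP_ARROW)
    }
  }
  # R5: a o-o b with an uncovered circle path  =>  undirected edges
  for (a in ns) for (b in ns) {
    if (a >= b || !is_adjacent(g, a, b)) next
    if (g$marks[a, b] != EP_CIRCLE || g$marks[b, a] != EP_CIRCLE) next
    path <- NULL
    for (x in adjacencies(g, a)) {
      if (x == b || is_adjacent(g, x, b)) next
      if (g$marks[a, x] != EP_CIRCLE || g$marks[x, a] != EP_CIRCLE) next
      path <- find_ucp_path(g, a, b, via = x, first_nonadj_to = NULL,
                            circle_only = TRUE)
      if (!is.null(path)) {
        y <- path[length(path) - 1L]
        if (is_adjacent(g, a, y)) { path <- NULL; next }
        break
      }
    }
    if (!is.null(path)) {
      set_mark(a, b, EP_TAIL); set_mark(b, a, EP_TAIL)
      for (i in seq_len(length(path) - 1L)) {
        set_mark(path[i], path[i + 1L], EP_TAIL)
        set_mark(path[i + 1L], path[i], EP_TAIL)
      }
    }
  }
  # R6: a -- b (both tails) and b o-* c  =>  tail at b
  # R7: a -o b (tail at a, circle at b), b o-* c, a,c non-adjacent => tail at b
  for (b in ns) for (a in ns) {
    if (a == b || !is_adjacent(g, a, b)) next
    tt <- g$marks[a, b] == EP_TAIL && g$marks[b, a] == EP_TAIL
    to <- g$marks[b, a] == EP_TAIL && g$marks[a, b] == EP_CIRCLE
    if (!tt && !to) next
    for (cn in adjacencies(g, b)) {
      if (cn == a || g$marks[cn, b] != EP_CIRCLE) next
      if (tt) set_mark(cn, b, EP_TAIL)
      else if (to && !is_adjacent(g, a, cn)) set_mark(cn, b, EP_TAIL)
    }
  }
  # R8, R9, R10 act on a o-> c edges
  for (a in ns) for (cn in ns) {
    if (a == cn || !is_adjacent(g, a, cn)) next
    if (!(g$marks[a, cn] == EP_ARROW && g$marks[cn, a] == EP_CIRCLE)) next
    done <- FALSE
    # R8: a -> b -> c (or a -o b -> c)
    for (b in intersect(adjacencies(g, a), adjacencies(g, cn))) {
      b_to_c <- g$marks[b, cn] == EP_ARROW && g$marks[cn, b] == EP_TAIL
      a_to_b <- g$marks[a, b] == EP_ARROW && g$marks[b, a] == EP_TAIL
      a_tocirc_b <- g$marks[a, b] == EP_CIRCLE && g$marks[b, a] == EP_TAIL
      if (b_to_c && (a_to_b || a_tocirc_b)) {
        set_mark(cn, a, EP_TAIL); done <- TRUE; break
      }
    }
    if (done) next
    # R9: uncovered potentially-directed path from a to c avoiding the edge
    path <- find_ucp_path(g, a, cn, first_nonadj_to = cn)
    if (!is.null(path)) { set_mark(cn, a, EP_TAIL); next }
    # R10: b -> c <- d, uncovered potentially-directed paths a..b and a..d
    # whose first vertices differ and are non-adjacent  =>  tail at a
    first_steps <- function(from, target) {
      out <- character()
      for (w in adjacencies(g, from)) {
        if (!pd_edge(g, from, w)) next
        if (w == target) { out <- c(out, w); next }
        if (!is.null(find_ucp_path(g, from, target, via = w)))
          out <- c(out, w)
      }
      out
    }
    pars <- Filter(function(b) g$marks[b, cn] == EP_ARROW &&
                     g$marks[cn, b] == EP_TAIL, adjacencies(g, cn))
    pars <- setdiff(pars, a)
    if (length(pars) >= 2L) {
      cmb <- utils::combn(pars, 2L)
      for (k in seq_len(ncol(cmb))) {
        s1 <- first_steps(a, cmb[1L, k])
        s2 <- first_steps(a, cmb[2L, k])
        for (xx in s1) {
          for (yy in s2) {
            if (xx != yy && !is_adjacent(g, xx, yy)) {
              set_mark(cn, a, EP_TAIL); done <- TRUE; break
            }
          }
          if (done) break
        }
        if (done) break
      }
    }
  }
  list(graph = g, changed = changed)
}

apply_zhang_rules <- function(g, sepsets, cfg, lookup_sepset) {
  repeat {
    res <- zhang_rule_pass(g, sepsets, cfg, lookup_sepset)
    g <- res$graph
    if (!res$changed) break
  }
  g
}

#' Reorient after Possible-D-Sep and apply the complete rule closure
#'
#' All endpoints are reset to circles, unshielded colliders are re-oriented
#' in the configured mode (reusing pre-phase decisions for triples whose
#' outer-node adjacency sets were untouched by the Possible-D-Sep phase),
#' and the orientation rules are applied to closure.
#'
#' @param g [mixed_graph()] after [pdsep_phase()].
#' @param sepsets a [sepset_map()].
#' @param cfg a [search_config()].
#' @param test a test closure.
#' @param prior prior triple decisions from the first collider phase.
#' @param snapshot pre-phase adjacency snapshot (named list).
#' @return the final PAG with attribute `"ambiguous"` (CFCI unfaithful
#'   triples).
#' @export
reorient_and_finalize <- function(g, sepsets, cfg = search_config(), test,
                                  prior = NULL, snapshot = NULL) {
  g <- skeleton_of(g)
  oc <- orient_colliders(g, sepsets, cfg, test, prior = prior,
                         snapshot = snapshot)
  g <- oc$graph
  lookup <- function(a, b) {
    rec <- sepset_get(sepsets, a, b)
    if (!is.null(rec)) return(rec)
    if (is_adjacent(g, a, b)) return(NULL)
    # pair non-adjacent from the start (constrained search): find a
    # separating set on demand
    mp <- max_p_sepset(a, b, g, cfg, test)
    if (!mp$separates) return(NULL)
    sepset_put(sepsets, a, b, mp$set, mp$pvalue)
    sepset_get(sepsets, a, b)
  }
  g <- apply_zhang_rules(g, sepsets, cfg, lookup)
  attr(g, "ambiguous") <- oc$ambiguous
  g
}

#' Run an FCI-family search end to end
#'
#' Stable skeleton, first collider orientation, Possible-D-Sep edge
#' removal, circle reset with collider re-orientation (retaining unaffected
#' colliders), and the complete orientation-rule closure.
#'
#' @param nodes character vector of variable names (NULL to take them from
#'   `cfg$initial_graph` or from `d`).
#' @param cfg a [search_config()].
#' @param test a test closure; if NULL, built from `d` with
#'   [make_data_test()].
#' @param d optional [mixed_dataset()].
#' @return the estimated PAG ([mixed_graph()]) with attributes `"n_tests"`
#'   (independence tests performed), `"sepsets"` and `"ambiguous"`.
#' @export
fci_run <- function(nodes = NULL, cfg = search_config(), test = NULL,
                    d = NULL) {
  if (is.null(test)) {
    if (is.null(d)) stop("need a test closure or a dataset")
    test <- make_data_test(d, ci_config(cfg$alpha))
  }
  if (is.null(nodes)) {
    if (!is.null(d)) nodes <- names(d)
    else if (!is.null(cfg$initial_graph)) nodes <- cfg$initial_graph$nodes
    else stop("need nodes, a dataset or an initial graph")
  }
  counted <- counted_test(test)
  tcached <- cached_test(counted, cfg$cache_cap)
  sk <- stable_skeleton(nodes, cfg, tcached)
  g <- sk$graph
  sepsets <- sk$sepsets
  snapshot <- stats::setNames(lapply(sort(nodes), function(v)
    adjacencies(g, v)), sort(nodes))
  oc1 <- orient_colliders(g, sepsets, cfg, tcached)
  pd <- pdsep_phase(oc1$graph, sepsets, cfg, tcached)
  pag <- reorient_and_finalize(pd$graph, sepsets, cfg, tcached,
                               prior = oc1$decisions, snapshot = snapshot)
  # restore type metadata when a dataset was supplied
  if (!is.null(d)) {
    types <- variable_types(d)
    pag$types[names(types)] <- types
    for (v in names(d)) if (is.factor(d[[v]]))
      pag$categories[[v]] <- levels(d[[v]])
  }
  attr(pag, "n_tests") <- test_count(counted)
  attr(pag, "sepsets") <- sepsets
  attr(pag, "pdsep_changed") <- pd$changed
  pag
}
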