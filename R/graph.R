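# Endpoint-labelled mixed graphs: DAGs, undirected skeletons and PAGs share one
# container.  marks[a, b] is the endpoint mark AT node b on the edge a--b, so an
# edge a -> b is stored as marks[a, b] == EP_ARROW, marks[b, a] == EP_TAIL.

#' Endpoint mark codes
#'
#' Integer codes for the endpoint marks of a [mixed_graph()]: `EP_NULL` (no
#' edge), `EP_TAIL` (`-`), `EP_ARROW` (`>`), `EP_CIRCLE` (`o`).
#'
#' @name endpoints
#' @keywords internal
NULL

#' @rdname endpoints
#' @export
EP_NULL   <- 0L
#' @rdname endpoints
#' @export
EP_TAIL   <- 1L
#' @rdname endpoints
#' @export
EP_ARROW  <- 2L
#' @rdname endpoints
#' @export
EP_CIRCLE <- 3L

#' Create an endpoint-labelled mixed graph
#'
#' A `mixed_graph` holds a node set (optionally typed continuous/categorical)
#' and a square integer matrix of endpoint marks.  The same container
#' represents DAGs (all edges tail--arrow, acyclic), undirected skeletons
#' (circle--circle) and partial ancestral graphs (any mix of tail, arrow and
#' circle marks).
#'
#' @param nodes character vector of unique node names.
#' @param types optional character vector (`"continuous"`/`"categorical"`),
#'   recycled or named by node; default all continuous.
#' @param categories optional named list of category label vectors for the
#'   categorical nodes (each of length >= 2).
#' @return an object of class `mixed_graph`.
#' @export
mixed_graph <- function(nodes, types = NULL, categories = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  if (is.null(types)) types <- rep("continuous", length(nodes))
  if (!is.null(names(types))) types <- unname(types[nodes])
  types <- rep_len(as.character(types), length(nodes))
  if (!all(types %in% c("continuous", "categorical")))
    stop("types must be 'continuous' or 'categorical'")
  names(types) <- nodes
  if (is.null(categories)) categories <- list()
  for (v in names(categories)) {
    if (!identical(types[[v]], "categorical"))
      stop("categories given for non-categorical node: ", v)
    if (length(categories[[v]]) < 2)
      stop("categorical node needs >= 2 categories: ", v)
  }
  marks <- matrix(EP_NULL, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
  structure(list(nodes = nodes, types = types, categories = categories,
                 marks = marks),
            class = "mixed_graph")
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat("mixed_graph:", length(x$nodes), "nodes,", n_edges(x), "edges\n")
  ep <- graph_edge_pairs(x)
  if (nrow(ep)) {
    for (i in seq_len(nrow(ep)))
      cat(" ", format_edge(x, ep[i, 1L], ep[i, 2L]), "\n")
  }
  invisible(x)
}

#' Add or replace an edge
#'
#' @param g a [mixed_graph()].
#' @param a,b node names.
#' @param mark_a,mark_b endpoint marks at `a` and `b` (`EP_TAIL`, `EP_ARROW`,
#'   `EP_CIRCLE`).
#' @return the modified graph.
#' @export
add_edge <- function(g, a, b, mark_a = EP_CIRCLE, mark_b = EP_CIRCLE) {
  stopifnot(a %in% g$nodes, b %in% g$nodes, a != b)
  g$marks[b, a] <- as.integer(mark_a)
  g$marks[a, b] <- as.integer(mark_b)
  g
}

#' Add a directed edge a -> b
#' @inheritParams add_edge
#' @export
add_directed_edge <- function(g, a, b) add_edge(g, a, b, EP_TAIL, EP_ARROW)

#' Remove the edge between two nodes
#' @inheritParams add_edge
#' @export
remove_edge <- function(g, a, b) {
  g$marks[a, b] <- EP_NULL
  g$marks[b, a] <- EP_NULL
  g
}

#' Endpoint mark at `b` on the edge `a`--`b`
#' @inheritParams add_edge
#' @return integer endpoint code (`EP_NULL` if not adjacent).
#' @export
endpoint <- function(g, a, b) g$marks[a, b]

#' Set the endpoint mark at `b` on the edge `a`--`b`
#' @inheritParams add_edge
#' @param mark endpoint code.
#' @export
set_endpoint <- function(g, a, b, mark) {
  if (g$marks[a, b] == EP_NULL) stop("no edge ", a, " -- ", b)
  g$marks[a, b] <- as.integer(mark)
  g
}

#' Test adjacency
#' @inheritParams add_edge
#' @export
is_adjacent <- function(g, a, b) g$marks[a, b] != EP_NULL

#' Adjacent nodes, sorted by name
#'
#' All internal iteration in the search code uses name-sorted adjacency so
#' results are invariant to the column order of the input data.
#'
#' @param g a [mixed_graph()].
#' @param v node name.
#' @export
adjacencies <- function(g, v) {
  sort(g$nodes[g$marks[v, ] != EP_NULL])
}

#' Number of edges
#' @param g a [mixed_graph()].
#' @export
n_edges <- function(g) sum(g$marks != EP_NULL) %/% 2L

#' Unordered adjacent pairs as a two-column character matrix (name-sorted)
#' @param g a [mixed_graph()].
#' @keywords internal
graph_edge_pairs <- function(g) {
  ns <- sort(g$nodes)
  out <- list()
  k <- 0L
  for (i in seq_along(ns)) {
    for (j in seq_along(ns)) {
      if (j <= i) next
      if (g$marks[ns[i], ns[j]] != EP_NULL) {
        k <- k + 1L
        out[[k]] <- c(ns[i], ns[j])
      }
    }
  }
  if (!k) return(matrix(character(), 0L, 2L))
  do.call(rbind, out)
}

# ---- DAG view -----------------------------------------------------------

#' Parents of a node under the DAG view
#' @inheritParams adjacencies
#' @export
parents <- function(g, v) {
  sort(g$nodes[g$marks[, v][g$nodes] == EP_ARROW & g$marks[v, ] == EP_TAIL])
}

#' Children of a node under the DAG view
#' @inheritParams adjacencies
#' @export
children <- function(g, v) {
  sort(g$nodes[g$marks[v, ] == EP_ARROW & g$marks[, v][g$nodes] == EP_TAIL])
}

# parent index list for fast internal algorithms
parent_index_list <- function(g) {
  n <- length(g$nodes)
  m <- g$marks
  lapply(seq_len(n), function(j) which(m[, j] == EP_ARROW & m[j, ] == EP_TAIL))
}

#' Check the DAG view: every edge tail--arrow and the graph acyclic
#' @param g a [mixed_graph()].
#' @export
is_dag <- function(g) {
  m <- g$marks
  adj <- m != EP_NULL
  ok <- all((m[adj] == EP_TAIL & t(m)[adj] == EP_ARROW) |
            (m[adj] == EP_ARROW & t(m)[adj] == EP_TAIL))
  if (!ok) return(FALSE)
  !is.null(topological_order(g))
}

#' Topological order of a DAG (NULL if cyclic)
#' @param g a [mixed_graph()].
#' @export
topological_order <- function(g) {
  pl <- parent_index_list(g)
  n <- length(g$nodes)
  indeg <- lengths(pl)
  childl <- vector("list", n)
  for (j in seq_len(n)) for (p in pl[[j]]) childl[[p]] <- c(childl[[p]], j)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (c in childl[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != n) return(NULL)
  g$nodes[out]
}

#' Ancestor query on a DAG
#'
#' `TRUE` iff a directed path `a -> ... -> b` exists.  A node is not its own
#' ancestor (`is_ancestor(g, a, a)` is `FALSE`).
#'
#' @param g a [mixed_graph()] passing the DAG view.
#' @param a,b node names.
#' @export
is_ancestor <- function(g, a, b) {
  if (!is_dag(g)) stop("is_ancestor requires a DAG")
  if (a == b) return(FALSE)
  ai <- match(a, g$nodes); bi <- match(b, g$nodes)
  pl <- parent_index_list(g)
  # walk ancestors of b
  seen <- rep(FALSE, length(g$nodes))
  stack <- pl[[bi]]
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v == ai) return(TRUE)
    stack <- c(stack, pl[[v]])
  }
  FALSE
}

#' Boolean ancestor matrix of a DAG
#'
#' `anc[a, b]` is `TRUE` iff `a` is a (proper) ancestor of `b`.
#'
#' @param g a [mixed_graph()] passing the DAG view.
#' @export
ancestor_matrix <- function(g) {
  pl <- parent_index_list(g)
  n <- length(g$nodes)
  anc <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  ord <- topological_order(g)
  if (is.null(ord)) stop("ancestor_matrix requires a DAG")
  for (v in ord) {
    j <- match(v, g$nodes)
    for (p in pl[[j]]) {
      anc[p, j] <- TRUE
      anc[, j] <- anc[, j] | anc[, p]
    }
  }
  anc
}

# ---- d-separation -------------------------------------------------------

# Internal fast d-separation on a parent-index representation.
# Uses the ancestral moral graph: restrict to ancestors of {x, y} union s,
# moralize, delete s, and test undirected connectivity of x and y.
dsep_parentlist <- function(pl, n, x, y, s) {
  target <- c(x, y, s)
  inanc <- rep(FALSE, n)
  stack <- target
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (inanc[v]) next
    inanc[v] <- TRUE
    stack <- c(stack, pl[[v]])
  }
  ancs <- which(inanc)
  # moral adjacency among ancestors
  adj <- vector("list", n)
  for (v in ancs) {
    pa <- pl[[v]]
    for (p in pa) {
      adj[[v]] <- c(adj[[v]], p)
      adj[[p]] <- c(adj[[p]], v)
    }
    if (length(pa) > 1L) {
      for (i in seq_along(pa)) for (j in seq_along(pa)) {
        if (i < j) {
          adj[[pa[i]]] <- c(adj[[pa[i]]], pa[j])
          adj[[pa[j]]] <- c(adj[[pa[j]]], pa[i])
        }
      }
    }
  }
  blocked <- rep(FALSE, n)
  blocked[s] <- TRUE
  seen <- rep(FALSE, n)
  stack <- x
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v] || blocked[v]) next
    seen[v] <- TRUE
    if (v == y) return(FALSE)
    stack <- c(stack, adj[[v]])
  }
  TRUE
}

#' d-separation on a DAG
#'
#' Decides whether `s` blocks every path between `x` and `y` under the
#' standard d-separation criterion (a collider is open iff it or one of its
#' descendants is in `s`).  Implemented via the ancestral moral graph.
#'
#' @param g a [mixed_graph()] passing the DAG view (may include latent nodes).
#' @param x,y distinct node names not contained in `s`.
#' @param s character vector of conditioning node names (may be empty).
#' @export
d_separated <- function(g, x, y, s = character()) {
  stopifnot(x != y, !(x %in% s), !(y %in% s))
  pl <- parent_index_list(g)
  dsep_parentlist(pl, length(g$nodes),
                  match(x, g$nodes), match(y, g$nodes), match(s, g$nodes))
}

#' Moralize a DAG
#'
#' Returns the undirected graph over the same nodes whose edge set is the
#' DAG's adjacencies plus an edge between every pair of nodes sharing a
#' child.  All marks are circle--circle.
#'
#' @param g a [mixed_graph()] passing the DAG view.
#' @export
moralize <- function(g) {
  out <- mixed_graph(g$nodes, g$types, g$categories)
  for (v in g$nodes) {
    pa <- parents(g, v)
    for (p in pa) out <- add_edge(out, p, v, EP_CIRCLE, EP_CIRCLE)
    if (length(pa) > 1L) {
      cmb <- utils::combn(pa, 2L)
      for (k in seq_len(ncol(cmb)))
        out <- add_edge(out, cmb[1L, k], cmb[2L, k], EP_CIRCLE, EP_CIRCLE)
    }
  }
  out
}

#' Induced subgraph on a node subset
#' @param g a [mixed_graph()].
#' @param keep character vector of node names to keep.
#' @export
induced_subgraph <- function(g, keep) {
  keep <- g$nodes[g$nodes %in% keep]
  out <- mixed_graph(keep, g$types[keep],
                     g$categories[names(g$categories) %in% keep])
  out$marks <- g$marks[keep, keep, drop = FALSE]
  out
}

#' Undirected skeleton (all marks reset to circles)
#' @param g a [mixed_graph()].
#' @export
skeleton_of <- function(g) {
  g$marks[g$marks != EP_NULL] <- EP_CIRCLE
  g
}

#' Set of unordered adjacent pairs as "a|b" keys (a < b by name)
#' @param g a [mixed_graph()].
#' @export
edge_set <- function(g) {
  ep <- graph_edge_pairs(g)
  if (!nrow(ep)) return(character())
  paste(ep[, 1L], ep[, 2L], sep = "|")
}
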