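# Line-oriented graph files.  Layout:
#   nodes:
#   <name> <continuous|categorical> [comma-separated categories]
#   edges:
#   <a> <token> <b>
# with edge tokens ---, o-o, o->, <->, --> (and --o, required so every
# tail/arrow/circle mark combination is representable).  The writer
# normalizes edge
# direction so only those five tokens appear; reading a written file
# reproduces the marks matrix exactly.

edge_token_marks <- list(
  "---" = c(EP_TAIL,   EP_TAIL),
  "o-o" = c(EP_CIRCLE, EP_CIRCLE),
  "o->" = c(EP_CIRCLE, EP_ARROW),
  "<->" = c(EP_ARROW,  EP_ARROW),
  "-->" = c(EP_TAIL,   EP_ARROW),
  "--o" = c(EP_TAIL,   EP_CIRCLE)
)

format_edge <- function(g, a, b) {
  ma <- g$marks[b, a]  # mark at a
  mb <- g$marks[a, b]  # mark at b
  for (tok in names(edge_token_marks)) {
    tm <- edge_token_marks[[tok]]
    if (tm[1L] == ma && tm[2L] == mb) return(paste(a, tok, b))
    if (tm[1L] == mb && tm[2L] == ma) return(paste(b, tok, a))
  }
  stop("cannot format edge ", a, " -- ", b)
}

#' Write a graph to a text file
#'
#' @param g a [mixed_graph()].
#' @param path output file path.
#' @seealso [read_graph()]
#' @export
write_graph <- function(g, path) {
  lines <- c("nodes:")
  for (v in g$nodes) {
    ln <- paste(v, g$types[[v]])
    if (identical(g$types[[v]], "categorical") && !is.null(g$categories[[v]]))
      ln <- paste(ln, paste(g$categories[[v]], collapse = ","))
    lines <- c(lines, ln)
  }
  lines <- c(lines, "edges:")
  ep <- graph_edge_pairs(g)
  if (nrow(ep)) {
    for (i in seq_len(nrow(ep)))
      lines <- c(lines, format_edge(g, ep[i, 1L], ep[i, 2L]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph from a text file
#'
#' @param path file in the [write_graph()] dialect.
#' @return a [mixed_graph()].
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  sec <- ""
  nodes <- character(); types <- character(); categories <- list()
  edges <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "nodes:") { sec <- "nodes"; next }
    if (ln == "edges:") { sec <- "edges"; next }
    parts <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (sec == "nodes") {
      if (length(parts) < 2L)
        stop("line ", i, ": malformed node declaration: ", ln)
      nodes <- c(nodes, parts[1L])
      types <- c(types, parts[2L])
      if (length(parts) >= 3L)
        categories[[parts[1L]]] <- strsplit(parts[3L], ",")[[1L]]
    } else if (sec == "edges") {
      if (length(parts) != 3L || !parts[2L] %in% names(edge_token_marks))
        stop("line ", i, ": malformed edge (unknown endpoint token): ", ln)
      edges[[length(edges) + 1L]] <- parts
    } else {
      stop("line ", i, ": content before 'nodes:' header: ", ln)
    }
  }
  names(types) <- nodes
  g <- mixed_graph(nodes, types, categories)
  for (e in edges) {
    tm <- edge_token_marks[[e[2L]]]
    if (!e[1L] %in% nodes || !e[3L] %in% nodes)
      stop("edge references undeclared node: ", paste(e, collapse = " "))
    g <- add_edge(g, e[1L], e[3L], tm[1L], tm[2L])
  }
  g
}

# ---- datasets -----------------------------------------------------------

#' Construct a mixed dataset
#'
#' Thin wrapper around a data.frame: numeric columns are continuous
#' variables, factor columns are categorical variables (their levels are the
#' category labels).  No missing cells are allowed.
#'
#' @param df a data.frame of numeric and factor columns.
#' @return an object of class `mixed_dataset` (still a data.frame).
#' @export
mixed_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyNA(df)) stop("mixed_dataset does not allow missing cells")
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.character(col)) df[[nm]] <- factor(col)
    else if (is.logical(col)) df[[nm]] <- factor(col, levels = c(FALSE, TRUE))
    else if (!is.numeric(col) && !is.factor(col))
      stop("unsupported column type in ", nm)
    if (is.factor(df[[nm]]) && nlevels(df[[nm]]) < 2)
      warning("categorical column ", nm, " has a single category")
  }
  class(df) <- c("mixed_dataset", "data.frame")
  df
}

#' Variable types of a mixed dataset
#' @param d a [mixed_dataset()].
#' @return named character vector, `"continuous"` or `"categorical"`.
#' @export
variable_types <- function(d) {
  vapply(d, function(col) if (is.factor(col)) "categorical" else "continuous",
         character(1L))
}

#' Read a delimited mixed dataset
#'
#' Columns are typed categorical iff non-numeric, or integer-valued with at
#' most `max_discrete` distinct values; otherwise continuous.  A sidecar
#' type file (`name<TAB>continuous|categorical`, one row per variable)
#' overrides the heuristic.
#'
#' @param path delimited text file with a header row.
#' @param sep field separator (default tab).
#' @param max_discrete distinct-value threshold for the integer heuristic.
#' @param type_file optional sidecar file of per-column type overrides.
#' @return a [mixed_dataset()].
#' @export
read_dataset <- function(path, sep = "\t", max_discrete = 5L,
                         type_file = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fill = FALSE)
  if (any(raw == "" | is.na(as.matrix(raw))))
    stop("empty cells in ", path)
  overrides <- character()
  if (!is.null(type_file)) {
    tf <- utils::read.table(type_file, header = FALSE, sep = "\t",
                            colClasses = "character")
    overrides <- stats::setNames(tf[[2L]], tf[[1L]])
  }
  out <- raw
  for (nm in names(raw)) {
    col <- raw[[nm]]
    num <- suppressWarnings(as.numeric(col))
    numeric_ok <- !anyNA(num)
    if (nm %in% names(overrides)) {
      cat_col <- identical(overrides[[nm]], "categorical")
    } else if (!numeric_ok) {
      cat_col <- TRUE
    } else {
      cat_col <- all(num == round(num)) &&
        length(unique(num)) <= max_discrete
    }
    out[[nm]] <- if (cat_col) factor(col, levels = unique(col)[order(unique(col))])
                 else num
  }
  mixed_dataset(out)
}

#' Write a mixed dataset to a delimited text file
#' @param d a [mixed_dataset()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_dataset <- function(d, path, sep = "\t") {
  out <- as.data.frame(d)
  for (nm in names(out)) {
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
    else out[[nm]] <- sprintf("%.17g", out[[nm]])  # exact double round trip
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
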