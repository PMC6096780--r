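# Separating-set records, keyed by unordered node pair.

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Create an empty separating-set map
#'
#' Maps unordered variable pairs to the conditioning set that rendered them
#' independent together with the p-value of that test.
#'
#' @return an object of class `sepset_map`.
#' @export
sepset_map <- function() {
  structure(list(env = new.env(parent = emptyenv())), class = "sepset_map")
}

#' Record a separating set
#' @param m a [sepset_map()].
#' @param a,b the node pair.
#' @param set character vector conditioning set.
#' @param pvalue p-value of the independence test that removed the edge.
#' @export
sepset_put <- function(m, a, b, set, pvalue) {
  assign(pair_key(a, b), list(set = sort(set), pvalue = pvalue), envir = m$env)
  invisible(m)
}

#' Look up a separating set (NULL if absent)
#' @param m a [sepset_map()].
#' @param a,b the node pair.
#' @export
sepset_get <- function(m, a, b) {
  key <- pair_key(a, b)
  if (exists(key, envir = m$env, inherits = FALSE))
    get(key, envir = m$env, inherits = FALSE)
  else NULL
}

#' All recorded pairs
#' @param m a [sepset_map()].
#' @return character vector of "a|b" keys.
#' @export
sepset_pairs <- function(m) sort(ls(m$env))
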