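# PAG-versus-PAG scoring: adjacency precision/recall and an
# endpoint-orientation score, both stratified by edge type (CC, CD, DD).
# Orientation counts are computed only over edges shared by the two graphs;
# each shared edge contributes two endpoint judgments scored from the
# confusion grid below (rows = true endpoint, columns = predicted endpoint
# at B on an edge A *-x B):
#
#            pred o            pred >                    pred -
#   true o   1 TP              1 TP if !Anc(B,A) else    1 TP if Anc(B,A)
#                              1 FN                      else 1 FP
#   true >   1/2 FP            1 TP                      1 FP
#   true -   1/2 FN            1 FN                      1 TP
#
# When the true endpoint is a circle the data-generating DAG is consulted
# for the ancestral fact.

edge_stratum <- function(types, a, b) {
  ta <- types[[a]]; tb <- types[[b]]
  if (ta == "continuous" && tb == "continuous") "CC"
  else if (ta == "categorical" && tb == "categorical") "DD"
  else "CD"
}

#' Adjacency confusion counts per edge-type stratum
#'
#' A true positive is an edge present in both graphs regardless of
#' orientation; false positives are estimate-only edges and false negatives
#' truth-only edges.
#'
#' @param est,truth [mixed_graph()]s over the same node set.
#' @param types named character vector of variable types (defaults to the
#'   truth graph's).
#' @return data.frame with stratum, tp, fp, fn.
#' @export
adjacency_confusion <- function(est, truth, types = truth$types) {
  if (!setequal(est$nodes, truth$nodes))
    stop("estimated and true graphs have different node sets")
  ee <- edge_set(est); te <- edge_set(truth)
  strata <- c("CC", "CD", "DD")
  counts <- matrix(0, 3L, 3L, dimnames = list(strata, c("tp", "fp", "fn")))
  tally <- function(keys, col) {
    for (key in keys) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      s <- edge_stratum(types, ab[1L], ab[2L])
      counts[s, col] <<- counts[s, col] + 1
    }
  }
  tally(intersect(ee, te), "tp")
  tally(setdiff(ee, te), "fp")
  tally(setdiff(te, ee), "fn")
  data.frame(stratum = strata, tp = counts[, "tp"], fp = counts[, "fp"],
             fn = counts[, "fn"], row.names = NULL)
}

# score one endpoint; returns c(tp, fp, fn) with halves allowed
score_endpoint <- function(true_mark, pred_mark, anc_b_a) {
  tp <- 0; fp <- 0; fn <- 0
  if (true_mark == EP_CIRCLE) {
    if (pred_mark == EP_CIRCLE) tp <- 1
    else if (pred_mark == EP_ARROW) { if (!anc_b_a) tp <- 1 else fn <- 1 }
    else { if (anc_b_a) tp <- 1 else fp <- 1 }
  } else if (true_mark == EP_ARROW) {
    if (pred_mark == EP_CIRCLE) fp <- 0.5
    else if (pred_mark == EP_ARROW) tp <- 1
    else fp <- 1
  } else {  # true tail
    if (pred_mark == EP_CIRCLE) fn <- 0.5
    else if (pred_mark == EP_ARROW) fn <- 1
    else tp <- 1
  }
  c(tp = tp, fp = fp, fn = fn)
}

#' Orientation confusion counts per edge-type stratum
#'
#' Scores the two endpoints of every edge shared between the estimated and
#' true PAGs, consulting the data-generating DAG for ancestry whenever the
#' true endpoint is a circle.
#'
#' @param est,truth [mixed_graph()]s over the same node set.
#' @param dag the data-generating DAG (a [mixed_graph()] including any
#'   latent nodes).
#' @return data.frame with stratum, tp, fp, fn (fractions allowed).
#' @export
orientation_score <- function(est, truth, dag) {
  shared <- intersect(edge_set(est), edge_set(truth))
  anc <- ancestor_matrix(dag)
  strata <- c("CC", "CD", "DD")
  counts <- matrix(0, 3L, 3L, dimnames = list(strata, c("tp", "fp", "fn")))
  for (key in shared) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
    s <- edge_stratum(truth$types, ab[1L], ab[2L])
    for (ends in list(ab, rev(ab))) {
      a <- ends[1L]; b <- ends[2L]   # judging the endpoint at b
      tm <- truth$marks[a, b]; pm <- est$marks[a, b]
      if (tm == EP_NULL || pm == EP_NULL)
        stop("NULL endpoint on a shared edge")
      counts[s, ] <- counts[s, ] + score_endpoint(tm, pm, anc[b, a])
    }
  }
  data.frame(stratum = strata, tp = counts[, "tp"], fp = counts[, "fp"],
             fn = counts[, "fn"], row.names = NULL)
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

#' Full evaluation report
#'
#' Adjacency and orientation confusion counts with derived precision,
#' recall and F1 per stratum (CC, CD, DD) and over all edges (ALL).
#' Undefined ratios (zero denominators) are reported as NA, never as 0 or
#' 1, so cross-seed averages stay honest.
#'
#' @inheritParams orientation_score
#' @return long-format data.frame: stratum, metric (adjacency/orientation),
#'   tp, fp, fn, precision, recall, f1.
#' @export
eval_report <- function(est, truth, dag) {
  adj <- adjacency_confusion(est, truth)
  ori <- orientation_score(est, truth, dag)
  rows <- list()
  for (metric in c("adjacency", "orientation")) {
    cnt <- if (metric == "adjacency") adj else ori
    cnt <- rbind(cnt, data.frame(stratum = "ALL", tp = sum(cnt$tp),
                                 fp = sum(cnt$fp), fn = sum(cnt$fn)))
    for (r in seq_len(nrow(cnt))) {
      m <- prf(cnt$tp[r], cnt$fp[r], cnt$fn[r])
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = cnt$stratum[r], metric = metric,
        tp = cnt$tp[r], fp = cnt$fp[r], fn = cnt$fn[r],
        precision = m[["precision"]], recall = m[["recall"]],
        f1 = m[["f1"]])
    }
  }
  do.call(rbind, rows)
}
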