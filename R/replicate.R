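# End-to-end replication driver: simulate -> (MGM) -> search -> evaluate
# across seeds and parameter grids, emitting a long-format results table.

algorithm_ids <- c("fci", "fci-max", "cfci", "mgm-fci", "mgm-fci-max",
                   "mgm-cfci")

algo_mode <- function(algorithm) {
  switch(algorithm,
         "fci" = , "mgm-fci" = "FCI",
         "fci-max" = , "mgm-fci-max" = "FCI_MAX",
         "cfci" = , "mgm-cfci" = "CFCI",
         stop("unknown algorithm: ", algorithm))
}

algo_uses_mgm <- function(algorithm) startsWith(algorithm, "mgm-")

#' Run one algorithm on one dataset
#'
#' @param d a [mixed_dataset()].
#' @param algorithm one of `fci`, `fci-max`, `cfci`, `mgm-fci`,
#'   `mgm-fci-max`, `mgm-cfci`.
#' @param alpha independence-test threshold.
#' @param lambda MGM penalty (MGM-constrained algorithms only).
#' @param depth,pdsep_depth conditioning-depth limits.
#' @param cores,chunk_beta collider-scheduler parameters.
#' @param skeleton optional precomputed undirected [mixed_graph()]
#'   (overrides the internal MGM fit for `mgm-*` algorithms).
#' @return the estimated PAG with attributes `n_tests` and (for `mgm-*`)
#'   `mgm_graph`.
#' @export
learn_pag <- function(d, algorithm = "fci", alpha = 0.05, lambda = 0.15,
                      depth = 3L, pdsep_depth = 3L, cores = 1L,
                      chunk_beta = 1, skeleton = NULL) {
  algorithm <- match.arg(algorithm, algorithm_ids)
  init <- NULL
  mgm_graph <- NULL
  if (algo_uses_mgm(algorithm)) {
    if (is.null(skeleton)) {
      mgm_graph <- mgm_fit(d, mgm_config(lambda = lambda))$graph
    } else {
      mgm_graph <- skeleton
    }
    init <- mgm_graph
  } else if (!is.null(skeleton)) {
    init <- skeleton
  }
  cfg <- search_config(mode = algo_mode(algorithm), alpha = alpha,
                       depth = depth, initial_graph = init, cores = cores,
                       chunk_beta = chunk_beta, pdsep_depth = pdsep_depth)
  pag <- fci_run(nodes = names(d), cfg = cfg, d = d)
  if (!is.null(mgm_graph)) attr(pag, "mgm_graph") <- mgm_graph
  pag
}

#' Replicate a simulation comparison across seeds and grids
#'
#' For each seed: simulate a study, compute the true PAG, run every
#' requested algorithm at every grid point, and evaluate against the truth.
#' Returns a long-format table (seed, algorithm, alpha, lambda, stratum,
#' metric, tp, fp, fn, precision, recall, f1, n_tests).  Stage failures are
#' recorded as rows with NA metrics and the run continues.
#'
#' @param sim a [sim_config()].
#' @param algorithms character vector of algorithm ids.
#' @param alphas grid of independence thresholds.
#' @param lambdas grid of MGM penalties (used by `mgm-*` algorithms only).
#' @param seeds integer vector of seeds.
#' @param depth,pdsep_depth conditioning-depth limits.
#' @export
replicate_study <- function(sim = sim_config(), algorithms = c("fci",
                            "fci-max"), alphas = c(0.001, 0.01, 0.05, 0.1),
                            lambdas = c(0.1, 0.15, 0.25), seeds = 1:10,
                            depth = 3L, pdsep_depth = 3L) {
  rows <- list()
  for (seed in seeds) {
    study <- simulate_study(sim, seed = seed)
    for (algorithm in algorithms) {
      lam_grid <- if (algo_uses_mgm(algorithm)) lambdas else NA_real_
      for (lambda in lam_grid) {
        skel <- if (algo_uses_mgm(algorithm))
          mgm_fit(study$data, mgm_config(lambda = lambda))$graph else NULL
        for (alpha in alphas) {
          rec <- tryCatch({
            pag <- learn_pag(study$data, algorithm, alpha = alpha,
                             lambda = lambda, depth = depth,
                             pdsep_depth = pdsep_depth, skeleton = skel)
            rep <- eval_report(pag, study$truth, study$dag)
            rep$n_tests <- attr(pag, "n_tests")
            rep
          }, error = function(e) {
            data.frame(stratum = "ALL", metric = "error", tp = NA, fp = NA,
                       fn = NA, precision = NA, recall = NA, f1 = NA,
                       n_tests = NA, row.names = NULL)
          })
          rec$seed <- seed; rec$algorithm <- algorithm
          rec$alpha <- alpha; rec$lambda <- lambda
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("seed", "algorithm", "alpha", "lambda", "stratum", "metric",
          "tp", "fp", "fn", "precision", "recall", "f1", "n_tests")]
}
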