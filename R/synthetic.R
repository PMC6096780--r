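# Synthetic mixed-data worlds: random DAGs over half-continuous /
# half-discrete variables, linear / log-linear structural equations with
# deliberately non-monotonic categorical effects, latent-variable selection
# and removal, and ground-truth PAG construction by oracle search.

#' Simulation configuration
#'
#' Defaults state the 50-node simulation world: half continuous variables,
#' three categories per discrete variable, edge count drawn from
#' Normal(100, 30) and clamped to the connected/simple range, 5 latent
#' variables, edge weights of magnitude 0.5-1.5 with either sign, Gaussian
#' noise with standard deviation drawn uniformly from [1, 2].
#'
#' @param n_nodes number of nodes in the generating DAG.
#' @param frac_continuous fraction of continuous nodes.
#' @param n_categories categories per discrete node.
#' @param edge_count_mean,edge_count_sd Normal draw for the edge count.
#' @param n_latents nodes to hide (each must keep >= 2 observed children).
#' @param n_samples rows to simulate.
#' @param weight_low,weight_high edge-weight magnitude range.
#' @param noise_sd_low,noise_sd_high continuous noise-sd range.
#' @param topology `"random"` (uniform pairs under a random topological
#'   order) or `"scale_free"` (preferential attachment).
#' @export
sim_config <- function(n_nodes = 50L, frac_continuous = 0.5,
                       n_categories = 3L, edge_count_mean = 100,
                       edge_count_sd = 30, n_latents = 5L,
                       n_samples = 1000L, weight_low = 0.5,
                       weight_high = 1.5, noise_sd_low = 1,
                       noise_sd_high = 2,
                       topology = c("random", "scale_free")) {
  topology <- match.arg(topology)
  stopifnot(n_latents < n_nodes, n_categories >= 2L)
  structure(list(n_nodes = as.integer(n_nodes),
                 frac_continuous = frac_continuous,
                 n_categories = as.integer(n_categories),
                 edge_count_mean = edge_count_mean,
                 edge_count_sd = edge_count_sd,
                 n_latents = as.integer(n_latents),
                 n_samples = as.integer(n_samples),
                 weight_low = weight_low, weight_high = weight_high,
                 noise_sd_low = noise_sd_low, noise_sd_high = noise_sd_high,
                 topology = topology),
            class = "sim_config")
}

#' Draw a random mixed-type DAG
#'
#' The edge count is drawn from Normal(mean, sd) and clamped to
#' `[n - 1, n(n-1)/2]`; edges are placed under a random topological order,
#' either uniformly over pairs or by preferential attachment.  Node types
#' are assigned at random with exactly `round(n * frac_continuous)`
#' continuous nodes.
#'
#' @param cfg a [sim_config()].  Uses the current RNG state.
#' @return a [mixed_graph()] passing the DAG view.
#' @export
random_dag <- function(cfg = sim_config()) {
  n <- cfg$n_nodes
  nodes <- sprintf("V%03d", seq_len(n))
  n_cont <- round(n * cfg$frac_continuous)
  types <- rep("categorical", n)
  types[sample.int(n, n_cont)] <- "continuous"
  names(types) <- nodes
  cats <- paste0("c", seq_len(cfg$n_categories))
  categories <- stats::setNames(
    rep(list(cats), sum(types == "categorical")),
    nodes[types == "categorical"])
  g <- mixed_graph(nodes, types, categories)
  n_edges_target <- round(stats::rnorm(1, cfg$edge_count_mean,
                                       cfg$edge_count_sd))
  n_edges_target <- max(n - 1L, min(n_edges_target, n * (n - 1L) / 2L))
  ord <- sample(nodes)  # topological order
  if (cfg$topology == "random") {
    all_pairs <- utils::combn(seq_len(n), 2L)
    pick <- sample.int(ncol(all_pairs), n_edges_target)
    for (k in pick) {
      a <- ord[all_pairs[1L, k]]; b <- ord[all_pairs[2L, k]]
      g <- add_directed_edge(g, a, b)
    }
  } else {
    deg <- stats::setNames(rep(0L, n), nodes)
    placed <- 0L
    # spread the target count over the incoming nodes
    for (i in 2:n) {
      remaining_nodes <- n - i + 1L
      m <- max(1L, round((n_edges_target - placed) / remaining_nodes))
      m <- min(m, i - 1L)
      prob <- deg[ord[seq_len(i - 1L)]] + 1
      src <- sample(ord[seq_len(i - 1L)], m, prob = prob)
      for (a in src) {
        g <- add_directed_edge(g, a, ord[i])
        deg[a] <- deg[a] + 1L
        deg[ord[i]] <- deg[ord[i]] + 1L
        placed <- placed + 1L
      }
    }
  }
  g
}

# strictly ascending or strictly descending.  Strictness matters: the rows
# of a discrete-discrete block are permutations of one vector, so its
# columns necessarily contain ties, and under a weak definition no
# permutation-filled matrix could satisfy the no-monotone-row-or-column
# requirement at all.
is_monotone <- function(v) all(diff(v) > 0) || all(diff(v) < 0)

# a vector of k uniform draws, centered to sum 0 and rescaled so the
# largest element equals |w|, then sign-flipped when w < 0 and permuted
# until non-monotone in category index
draw_cat_vector <- function(k, w) {
  repeat {
    v <- stats::runif(k)
    v <- v - mean(v)
    if (max(v) <= 0) next  # all equal (probability zero); redraw
    v <- v * (abs(w) / max(v))
    if (w < 0) v <- -v
    for (i in seq_len(50L)) {
      if (!is_monotone(v)) return(v)
      v <- sample(v)
    }
  }
}

#' Assign structural-equation parameters to a DAG
#'
#' Each edge's base weight has magnitude drawn uniformly from
#' `[weight_low, weight_high]` with a random sign.  Continuous-continuous
#' edges keep the single weight; edges involving a discrete variable get a
#' per-category vector that sums to zero, has largest magnitude equal to the
#' weight, and is non-monotonic in category index; discrete-discrete edges
#' get a matrix whose rows are distinct permutations of one such vector,
#' with no monotone row or column.
#'
#' @param dag a [mixed_graph()] DAG.
#' @param cfg a [sim_config()].
#' @return an object of class `param_dag`.
#' @export
assign_parameters <- function(dag, cfg = sim_config()) {
  draw_weight <- function()
    sample(c(-1, 1), 1L) * stats::runif(1, cfg$weight_low, cfg$weight_high)
  cc <- list(); cd <- list(); dd <- list()
  for (child in sort(dag$nodes)) {
    for (parent in parents(dag, child)) {
      key <- paste(parent, child, sep = "->")
      w <- draw_weight()
      pt <- dag$types[[parent]]; ct <- dag$types[[child]]
      if (pt == "continuous" && ct == "continuous") {
        cc[[key]] <- w
      } else if (pt == "categorical" && ct == "categorical") {
        kp <- length(dag$categories[[parent]])
        kc <- length(dag$categories[[child]])
        stopifnot(kp == kc)  # rows are permutations of one base vector
        repeat {
          base <- draw_cat_vector(kc, w)
          perms <- list()
          seen <- character()
          guard <- 0L
          while (length(perms) < kp && guard < 200L) {
            guard <- guard + 1L
            cand <- sample(base)
            ck <- paste(cand, collapse = ",")
            if (ck %in% seen || is_monotone(cand)) next
            seen <- c(seen, ck)
            perms[[length(perms) + 1L]] <- cand
          }
          if (length(perms) < kp) next
          M <- do.call(rbind, perms)
          if (!any(apply(M, 2L, is_monotone))) break
        }
        dd[[key]] <- M
      } else {
        k <- if (pt == "categorical") length(dag$categories[[parent]])
             else length(dag$categories[[child]])
        cd[[key]] <- draw_cat_vector(k, w)
      }
    }
  }
  cont <- dag$nodes[dag$types == "continuous"]
  disc <- dag$nodes[dag$types == "categorical"]
  cont_node <- stats::setNames(
    lapply(cont, function(v) list(mean = 0,
      noise_sd = stats::runif(1, cfg$noise_sd_low, cfg$noise_sd_high))),
    cont)
  disc_node <- stats::setNames(
    lapply(disc, function(v)
      stats::runif(length(dag$categories[[v]]), -0.2, 0.2)),
    disc)
  structure(list(dag = dag, cc = cc, cd = cd, dd = dd,
                 cont_node = cont_node, disc_node = disc_node),
            class = "param_dag")
}

#' Sample a mixed dataset from a parameterized DAG
#'
#' Ancestral (topological-order) sampling: a continuous child is the sum of
#' its parents' linear contributions plus Gaussian noise with the node's
#' fixed standard deviation; a discrete child's category probabilities are
#' proportional to exp(baseline + parent contributions) and the category is
#' chosen by inverse CDF against a uniform error draw.  Logits are centered
#' before exponentiation.
#'
#' @param pd a `param_dag` from [assign_parameters()].
#' @param n number of samples.
#' @return a [mixed_dataset()] over all DAG nodes (latents included).
#' @export
simulate_mixed <- function(pd, n) {
  dag <- pd$dag
  ord <- topological_order(dag)
  vals <- list()   # numeric for continuous, integer category index for disc
  for (v in ord) {
    pa <- parents(dag, v)
    if (dag$types[[v]] == "continuous") {
      mu <- rep(pd$cont_node[[v]]$mean, n)
      for (p in pa) {
        key <- paste(p, v, sep = "->")
        if (dag$types[[p]] == "continuous") {
          mu <- mu + pd$cc[[key]] * vals[[p]]
        } else {
          mu <- mu + pd$cd[[key]][vals[[p]]]
        }
      }
      vals[[v]] <- mu + stats::rnorm(n, 0, pd$cont_node[[v]]$noise_sd)
    } else {
      k <- length(dag$categories[[v]])
      eta <- matrix(pd$disc_node[[v]], n, k, byrow = TRUE)
      for (p in pa) {
        key <- paste(p, v, sep = "->")
        if (dag$types[[p]] == "continuous") {
          eta <- eta + outer(vals[[p]], pd$cd[[key]])
        } else {
          eta <- eta + pd$dd[[key]][vals[[p]], , drop = FALSE]
        }
      }
      mx <- eta[, 1L]
      for (c in seq_len(k)[-1L]) mx <- pmax(mx, eta[, c])
      eta <- eta - mx  # overflow-safe
      P <- exp(eta) / rowSums(exp(eta))
      cum <- P %*% upper.tri(diag(k), diag = TRUE)
      u <- stats::runif(n)
      idx <- rep(1L, n)
      for (c in seq_len(k - 1L)) idx <- idx + (u > cum[, c])
      vals[[v]] <- idx
    }
  }
  df <- as.data.frame(lapply(stats::setNames(dag$nodes, dag$nodes),
    function(v) {
      if (dag$types[[v]] == "continuous") vals[[v]]
      else factor(dag$categories[[v]][vals[[v]]],
                  levels = dag$categories[[v]])
    }))
  mixed_dataset(df)
}

#' Select latent variables
#'
#' Iteratively picks `k` nodes uniformly among those with at least two
#' children that are not themselves already selected as latent, so every
#' latent truly confounds at least two observed variables.
#'
#' @param dag a [mixed_graph()] DAG.
#' @param k number of latents.
#' @return character vector of latent node names.
#' @export
select_latents <- function(dag, k) {
  latents <- character()
  for (i in seq_len(k)) {
    eligible <- Filter(function(v) {
      if (length(setdiff(children(dag, v), latents)) < 2L) return(FALSE)
      # picking v must not strip an earlier latent below two observed
      # children
      all(vapply(latents, function(l)
        length(setdiff(children(dag, l), c(latents, v))) >= 2L,
        logical(1L)))
    }, setdiff(dag$nodes, latents))
    if (!length(eligible))
      stop("fewer than k nodes with >= 2 observed children; resample the DAG")
    latents <- c(latents, if (length(eligible) == 1L) eligible
                 else sample(eligible, 1L))
  }
  sort(latents)
}

#' Ground-truth PAG of a DAG with latents
#'
#' Runs the FCI search with a d-separation oracle over the observed nodes
#' only (unlimited conditioning depth); the output is the best PAG
#' obtainable from correct conditional-independence information.
#'
#' @param dag a [mixed_graph()] DAG (latents included).
#' @param latents character vector of latent node names.
#' @return the true PAG over the observed nodes.
#' @export
true_pag <- function(dag, latents = character()) {
  observed <- setdiff(dag$nodes, latents)
  test <- make_oracle_test(dag)
  cfg <- search_config(mode = "FCI", alpha = 0.5, depth = -1L,
                       pdsep_depth = -1L)
  pag <- fci_run(nodes = observed, cfg = cfg, test = test)
  pag$types[observed] <- dag$types[observed]
  pag$categories <- dag$categories[names(dag$categories) %in% observed]
  pag
}

#' Simulate one complete study
#'
#' Draws a DAG, parameterizes it, selects latents (resampling the DAG when
#' too few nodes are eligible), simulates data, and computes the true PAG.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `dag`, `params`, `latents`, `truth` (true PAG),
#'   `data_full` and `data` (observed columns only).
#' @export
simulate_study <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    dag <- random_dag(cfg)
    latents <- tryCatch(select_latents(dag, cfg$n_latents),
                        error = function(e) NULL)
    if (!is.null(latents)) break
  }
  params <- assign_parameters(dag, cfg)
  data_full <- simulate_mixed(params, cfg$n_samples)
  observed <- setdiff(dag$nodes, latents)
  data_obs <- mixed_dataset(data_full[, observed, drop = FALSE])
  truth <- true_pag(dag, latents)
  list(dag = dag, params = params, latents = latents, truth = truth,
       data_full = data_full, data = data_obs)
}
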