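# Lee-Hastie mixed graphical model learned by proximal-gradient descent on
# the penalized negative log pseudolikelihood.  The pseudolikelihood is the
# sum of each variable's conditional: Gaussian linear regressions for
# continuous variables (unit conditional variance on standardized data) and
# multiclass logistic regressions for categorical variables.  The penalty is
# an l1 norm on continuous-continuous couplings, a group l2 norm on each
# continuous-discrete coupling vector and a Frobenius norm on each
# discrete-discrete coupling block; node potentials are unpenalized.
# Proximal shrinkage produces exactly-zero blocks, so the learned undirected
# skeleton is read off as the set of nonzero coupling blocks.

#' MGM fitting configuration
#'
#' @param lambda common penalty weight applied to all three edge classes
#'   unless a class-specific weight is given.
#' @param lambda_cc,lambda_cd,lambda_dd penalties for continuous-continuous,
#'   continuous-discrete and discrete-discrete couplings.
#' @param max_iter maximum proximal-gradient iterations.
#' @param edge_stability_window stop when the implied edge set has been
#'   identical for this many consecutive iterations (default 3).
#' @param min_iter iterations to run before the stability window is
#'   consulted, so an initially empty model is not mistaken for a converged
#'   one.
#' @param step0 initial step size for backtracking line search.
#' @export
mgm_config <- function(lambda = 0.15, lambda_cc = lambda, lambda_cd = lambda,
                       lambda_dd = lambda, max_iter = 500L,
                       edge_stability_window = 3L, min_iter = 10L,
                       step0 = 1) {
  stopifnot(lambda_cc >= 0, lambda_cd >= 0, lambda_dd >= 0,
            edge_stability_window >= 1L)
  structure(list(lambda_cc = lambda_cc, lambda_cd = lambda_cd,
                 lambda_dd = lambda_dd, max_iter = as.integer(max_iter),
                 edge_stability_window = as.integer(edge_stability_window),
                 min_iter = as.integer(min_iter), step0 = step0),
            class = "mgm_config")
}

row_max <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
  out
}

# Internal: split a dataset into standardized continuous matrix X and 0/1
# indicator matrix D with per-variable column blocks.
mgm_prepare <- function(d) {
  types <- variable_types(d)
  cont <- sort(names(types)[types == "continuous"])
  disc <- sort(names(types)[types == "categorical"])
  n <- nrow(d)
  X <- matrix(0, n, length(cont), dimnames = list(NULL, cont))
  center <- stats::setNames(numeric(length(cont)), cont)
  scale <- stats::setNames(numeric(length(cont)), cont)
  for (v in cont) {
    col <- as.numeric(d[[v]])
    center[v] <- mean(col)
    scale[v] <- stats::sd(col)
    if (!is.finite(scale[v]) || scale[v] == 0) scale[v] <- 1
    X[, v] <- (col - center[v]) / scale[v]
  }
  blocks <- list(); cols <- list(); K <- 0L
  for (v in disc) {
    f <- d[[v]]
    k <- nlevels(f)
    blocks[[v]] <- K + seq_len(k)
    K <- K + k
    ind <- matrix(0, n, k)
    ind[cbind(seq_len(n), as.integer(f))] <- 1
    cols[[v]] <- ind
  }
  D <- if (K) do.call(cbind, cols) else matrix(0, n, 0L)
  list(X = X, D = D, n = n, p = length(cont), K = K,
       cont = cont, disc = disc, blocks = blocks,
       center = center, scale = scale)
}

#' Zero-initialized MGM parameter set
#'
#' Holds every coupling and node-potential block of the model: `beta`
#' (continuous-continuous, symmetric, zero diagonal), `alpha` (continuous
#' node potentials), `rho` (category-by-continuous couplings), `phi`
#' (category-by-category couplings, symmetric, zero diagonal blocks), `psi`
#' (categorical node potentials) and `noise` (residual variances, filled in
#' after fitting).
#'
#' @param d a [mixed_dataset()].
#' @export
mgm_params <- function(d) {
  prep <- mgm_prepare(d)
  mgm_params_from_prep(prep)
}

mgm_params_from_prep <- function(prep) {
  ind_names <- unlist(lapply(prep$disc, function(v)
    paste0(v, ".", seq_along(prep$blocks[[v]]))), use.names = FALSE)
  if (is.null(ind_names)) ind_names <- character()
  structure(list(
    beta = matrix(0, prep$p, prep$p, dimnames = list(prep$cont, prep$cont)),
    alpha = stats::setNames(numeric(prep$p), prep$cont),
    rho = matrix(0, prep$K, prep$p, dimnames = list(ind_names, prep$cont)),
    phi = matrix(0, prep$K, prep$K, dimnames = list(ind_names, ind_names)),
    psi = stats::setNames(numeric(prep$K), ind_names),
    noise = stats::setNames(rep(1, prep$p), prep$cont)),
    class = "mgm_params")
}

# smooth part of the objective (sample-mean negative log pseudolikelihood);
# continuous conditionals are weighted by their learned noise variances
mgm_smooth_loss <- function(par, prep) {
  n <- prep$n
  loss <- 0
  if (prep$p) {
    M <- matrix(par$alpha, n, prep$p, byrow = TRUE) + prep$X %*% par$beta
    if (prep$K) M <- M + prep$D %*% par$rho
    res <- prep$X - M
    s2 <- pmax(par$noise, 1e-6)
    loss <- loss + 0.5 * sum(sweep(res * res, 2L, s2, "/")) / n +
      0.5 * sum(log(2 * pi * s2))
  }
  for (v in prep$disc) {
    b <- prep$blocks[[v]]
    eta <- matrix(par$psi[b], n, length(b), byrow = TRUE)
    if (prep$p) eta <- eta + prep$X %*% t(par$rho[b, , drop = FALSE])
    if (prep$K) eta <- eta + prep$D %*% par$phi[, b, drop = FALSE]
    mx <- row_max(eta)
    lse <- mx + log(rowSums(exp(eta - mx)))
    loss <- loss + (sum(lse) - sum(eta * prep$D[, b, drop = FALSE])) / n
  }
  loss
}

mgm_smooth_grad <- function(par, prep) {
  n <- prep$n
  g <- mgm_params_from_prep(prep)
  res <- NULL
  if (prep$p) {
    M <- matrix(par$alpha, n, prep$p, byrow = TRUE) + prep$X %*% par$beta
    if (prep$K) M <- M + prep$D %*% par$rho
    res <- prep$X - M
    resw <- sweep(res, 2L, pmax(par$noise, 1e-6), "/")
    g$alpha <- -colSums(resw) / n
    Gcc <- -crossprod(prep$X, resw) / n
    g$beta <- Gcc + t(Gcc)
    diag(g$beta) <- 0
  }
  if (prep$K) {
    U <- matrix(0, n, prep$K)
    for (v in prep$disc) {
      b <- prep$blocks[[v]]
      eta <- matrix(par$psi[b], n, length(b), byrow = TRUE)
      if (prep$p) eta <- eta + prep$X %*% t(par$rho[b, , drop = FALSE])
      eta <- eta + prep$D %*% par$phi[, b, drop = FALSE]
      mx <- row_max(eta)
      ee <- exp(eta - mx)
      P <- ee / rowSums(ee)
      U[, b] <- P - prep$D[, b, drop = FALSE]
    }
    g$psi <- colSums(U) / n
    if (prep$p) g$rho <- -crossprod(prep$D, resw) / n + crossprod(U, prep$X) / n
    Gdd <- crossprod(prep$D, U) / n
    g$phi <- Gdd + t(Gdd)
    for (v in prep$disc) {
      b <- prep$blocks[[v]]
      g$phi[b, b] <- 0
    }
  }
  g
}

mgm_penalty <- function(par, prep, cfg) {
  pen <- 0
  if (prep$p > 1)
    pen <- pen + cfg$lambda_cc * sum(abs(par$beta[upper.tri(par$beta)]))
  if (prep$p && prep$K) {
    for (v in prep$disc) {
      b <- prep$blocks[[v]]
      for (s in seq_len(prep$p))
        pen <- pen + cfg$lambda_cd * sqrt(sum(par$rho[b, s]^2))
    }
  }
  if (length(prep$disc) > 1) {
    dd <- prep$disc
    for (i in seq_along(dd)) for (j in seq_along(dd)) {
      if (i < j) {
        br <- prep$blocks[[dd[i]]]; bj <- prep$blocks[[dd[j]]]
        pen <- pen + cfg$lambda_dd * sqrt(sum(par$phi[br, bj]^2))
      }
    }
  }
  pen
}

mgm_prox <- function(par, prep, cfg, t) {
  if (prep$p > 1) {
    th <- t * cfg$lambda_cc
    par$beta <- sign(par$beta) * pmax(abs(par$beta) - th, 0)
    diag(par$beta) <- 0
  }
  if (prep$p && prep$K) {
    th <- t * cfg$lambda_cd
    for (v in prep$disc) {
      b <- prep$blocks[[v]]
      for (s in seq_len(prep$p)) {
        nv <- sqrt(sum(par$rho[b, s]^2))
        par$rho[b, s] <- if (nv <= th) 0 else par$rho[b, s] * (1 - th / nv)
      }
    }
  }
  if (length(prep$disc) > 1) {
    th <- t * cfg$lambda_dd
    dd <- prep$disc
    for (i in seq_along(dd)) for (j in seq_along(dd)) {
      if (i < j) {
        br <- prep$blocks[[dd[i]]]; bj <- prep$blocks[[dd[j]]]
        B <- par$phi[br, bj, drop = FALSE]
        nv <- sqrt(sum(B^2))
        B <- if (nv <= th) B * 0 else B * (1 - th / nv)
        par$phi[br, bj] <- B
        par$phi[bj, br] <- t(B)
      }
    }
  }
  par
}

param_fields <- c("beta", "alpha", "rho", "phi", "psi")

param_step <- function(par, grad, t) {
  for (f in param_fields) par[[f]] <- par[[f]] - t * grad[[f]]
  par
}

param_diff_sq <- function(a, b) {
  s <- 0
  for (f in param_fields) s <- s + sum((a[[f]] - b[[f]])^2)
  s
}

param_grad_dot <- function(g, a, b) {
  s <- 0
  for (f in param_fields) s <- s + sum(g[[f]] * (a[[f]] - b[[f]]))
  s
}

# implied undirected edge set: "a|b" keys of nonzero coupling blocks
mgm_edge_keys <- function(par, prep, tol = 0) {
  keys <- character()
  if (prep$p > 1) {
    for (i in seq_len(prep$p)) for (j in seq_len(prep$p)) {
      if (i < j && abs(par$beta[i, j]) > tol)
        keys <- c(keys, pair_key(prep$cont[i], prep$cont[j]))
    }
  }
  if (prep$p && prep$K) {
    for (v in prep$disc) {
      b <- prep$blocks[[v]]
      for (s in seq_len(prep$p)) {
        if (any(abs(par$rho[b, s]) > tol))
          keys <- c(keys, pair_key(prep$cont[s], v))
      }
    }
  }
  dd <- prep$disc
  if (length(dd) > 1) {
    for (i in seq_along(dd)) for (j in seq_along(dd)) {
      if (i < j && any(abs(par$phi[prep$blocks[[dd[i]]],
                                   prep$blocks[[dd[j]]]]) > tol))
        keys <- c(keys, pair_key(dd[i], dd[j]))
    }
  }
  sort(keys)
}

#' Negative log pseudolikelihood of an MGM
#'
#' The sample-mean of minus the log conditional density of every variable
#' given all others: Gaussian linear regressions (unit variance, data
#' standardized internally) for continuous variables, multiclass logistic
#' regressions for categorical variables.
#'
#' @param params an [mgm_params()] set dimensioned to `d`.
#' @param d a [mixed_dataset()].
#' @export
neg_log_pseudolikelihood <- function(params, d) {
  mgm_smooth_loss(params, mgm_prepare(d))
}

#' Penalized MGM objective
#'
#' [neg_log_pseudolikelihood()] plus the l1 / group-l2 / Frobenius penalty
#' on the coupling blocks (node potentials unpenalized).
#'
#' @inheritParams neg_log_pseudolikelihood
#' @param cfg an [mgm_config()].
#' @export
mgm_objective <- function(params, d, cfg = mgm_config()) {
  prep <- mgm_prepare(d)
  mgm_smooth_loss(params, prep) + mgm_penalty(params, prep, cfg)
}

#' Fit a mixed graphical model
#'
#' Proximal-gradient (ISTA with backtracking line search) minimization of
#' the penalized negative log pseudolikelihood, starting from zero coupling
#' parameters and marginally fitted node potentials.  Iteration stops when
#' the implied edge set is unchanged for `edge_stability_window` consecutive
#' iterations (after `min_iter` iterations) or at `max_iter`.
#'
#' @param d a [mixed_dataset()].
#' @param cfg an [mgm_config()].
#' @return list with `params` (an [mgm_params()]), `graph` (undirected
#'   [mixed_graph()] with circle-circle edges), `objective` (trace of
#'   accepted objective values) and `iterations`.
#' @export
mgm_fit <- function(d, cfg = mgm_config()) {
  if (nrow(d) < 2L) stop("mgm_fit needs n >= 2")
  prep <- mgm_prepare(d)
  par <- mgm_params_from_prep(prep)
  # marginal node potentials: standardized continuous means are 0 already;
  # categorical log-frequencies relative to nothing (softmax-invariant shift)
  for (v in prep$disc) {
    b <- prep$blocks[[v]]
    freq <- pmax(colMeans(prep$D[, b, drop = FALSE]), 1e-12)
    par$psi[b] <- log(freq)
  }
  t <- cfg$step0
  f_old <- mgm_smooth_loss(par, prep)
  trace <- mgm_smooth_loss(par, prep) + mgm_penalty(par, prep, cfg)
  prev_keys <- NULL
  stable <- 0L
  iters <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    iters <- iter
    grad <- mgm_smooth_grad(par, prep)
    repeat {
      cand <- mgm_prox(param_step(par, grad, t), prep, cfg, t)
      f_new <- mgm_smooth_loss(cand, prep)
      if (!is.finite(f_new)) { t <- t / 2; next }
      ub <- f_old + param_grad_dot(grad, cand, par) +
        param_diff_sq(cand, par) / (2 * t)
      if (f_new <= ub + 1e-12) break
      t <- t / 2
      if (t < 1e-12) stop("mgm_fit: step size underflow (non-finite objective)")
    }
    par <- cand
    # closed-form coordinate update of the noise variances (exact minimizer,
    # so the objective cannot increase)
    if (prep$p) {
      M <- matrix(par$alpha, prep$n, prep$p, byrow = TRUE) + prep$X %*% par$beta
      if (prep$K) M <- M + prep$D %*% par$rho
      par$noise <- pmax(colMeans((prep$X - M)^2), 1e-6)
    }
    f_old <- mgm_smooth_loss(par, prep)
    trace <- c(trace, f_old + mgm_penalty(par, prep, cfg))
    keys <- mgm_edge_keys(par, prep)
    if (!is.null(prev_keys) && identical(keys, prev_keys)) {
      stable <- stable + 1L
    } else {
      stable <- 0L
    }
    prev_keys <- keys
    if (iter >= cfg$min_iter && stable >= cfg$edge_stability_window) break
    t <- min(t * 2, cfg$step0)  # allow the step to recover between iterations
  }
  names(par$noise) <- prep$cont
  types <- variable_types(d)
  g <- mixed_graph(sort(names(d)), types[sort(names(d))],
                   categories = stats::setNames(
                     lapply(names(types)[types == "categorical"],
                            function(v) levels(d[[v]])),
                     names(types)[types == "categorical"]))
  for (key in mgm_edge_keys(par, prep)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
    g <- add_edge(g, ab[1L], ab[2L], EP_CIRCLE, EP_CIRCLE)
  }
  list(params = par, graph = g, objective = trace, iterations = iters)
}
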