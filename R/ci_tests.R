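# Conditional-independence tests for mixed data.
#
# Both continuous and categorical branches are regression-based: for a
# continuous target a linear model is fit and the candidate's coefficient
# (or indicator block) is tested; for a categorical target a multinomial
# logistic regression is fit and a likelihood-ratio test compares the model
# with and without the candidate variable, holding the conditioning set in
# both models.

#' Configuration for conditional-independence tests
#' @param alpha significance threshold in (0, 1); the null of independence is
#'   rejected when p < alpha.
#' @export
ci_config <- function(alpha = 0.05) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(alpha = alpha), class = "ci_config")
}

ci_result <- function(pvalue, alpha, dof = 0L, degenerate = FALSE) {
  pvalue <- unname(pvalue)
  independent <- if (degenerate) FALSE else (pvalue > alpha)
  structure(list(pvalue = pvalue, independent = independent,
                 dof = as.integer(dof), degenerate = degenerate),
            class = "ci_result")
}

#' Expand categorical variables into 0/1 indicator columns
#'
#' Each categorical variable with k categories becomes k indicator columns
#' (one per category); continuous variables pass through unchanged.
#'
#' @param d a [mixed_dataset()].
#' @param vars character vector of variable names to expand.
#' @return list with `design` (numeric matrix), `source` (character vector
#'   mapping output columns to source variables) and `degenerate` (TRUE if
#'   any categorical variable has a single observed category).
#' @export
expand_indicators <- function(d, vars) {
  cols <- list(); src <- character(); degenerate <- FALSE
  for (v in vars) {
    col <- d[[v]]
    if (is.factor(col)) {
      if (length(unique(col)) < 2L) degenerate <- TRUE
      for (lev in levels(col)) {
        cols[[paste0(v, ".", lev)]] <- as.numeric(col == lev)
        src <- c(src, v)
      }
    } else {
      cols[[v]] <- as.numeric(col)
      src <- c(src, v)
    }
  }
  design <- if (length(cols)) do.call(cbind, cols)
            else matrix(numeric(), nrow(d), 0L)
  list(design = design, source = src, degenerate = degenerate)
}

# Drop-reference design block for predictors: k-1 indicators per categorical
# variable (full indicator sets are exactly collinear with an intercept).
# All-constant columns are dropped.
predictor_block <- function(d, vars) {
  vars <- sort(vars)
  cols <- list(); src <- character()
  for (v in vars) {
    col <- d[[v]]
    if (is.factor(col)) {
      levs <- levels(col)
      for (lev in levs[-1L]) {
        cols[[paste0(v, ".", lev)]] <- as.numeric(col == lev)
        src <- c(src, v)
      }
    } else {
      cols[[v]] <- as.numeric(col)
      src <- c(src, v)
    }
  }
  if (length(cols)) {
    keep <- vapply(cols, function(x) stats::var(x) > 0, logical(1L))
    cols <- cols[keep]; src <- src[keep]
  }
  design <- if (length(cols)) do.call(cbind, cols)
            else matrix(numeric(), nrow(d), 0L)
  list(design = design, source = src)
}

# ---- linear branch ------------------------------------------------------

#' Linear-regression conditional-independence test (continuous target)
#'
#' Regresses continuous `x` on `y` and `s`.  For continuous `y` the p-value
#' is the two-sided t test on y's coefficient; for categorical `y` it is the
#' F test of the joint contribution of y's indicator block.
#'
#' @param d a [mixed_dataset()].
#' @param x name of a continuous variable (the regression target).
#' @param y name of the candidate variable.
#' @param s character vector of conditioning variable names.
#' @param cfg a [ci_config()].
#' @export
test_continuous <- function(d, x, y, s = character(), cfg = ci_config()) {
  n <- nrow(d)
  sy <- predictor_block(d, y)
  ss <- predictor_block(d, s)
  X1 <- cbind(`(Intercept)` = rep(1, n), sy$design, ss$design)
  ycols <- seq_len(ncol(sy$design)) + 1L
  if (ncol(sy$design) == 0L)  # single observed category: nothing to test
    return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
  qx <- qr(X1)
  if (qx$rank < ncol(X1))
    return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
  xv <- as.numeric(d[[x]])
  df2 <- n - ncol(X1)
  if (df2 <= 0) return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
  res1 <- qr.resid(qx, xv)
  rss1 <- sum(res1^2)
  if (!is.factor(d[[y]])) {
    coefs <- qr.coef(qx, xv)
    sigma2 <- rss1 / df2
    XtXinv <- chol2inv(qr.R(qx))
    k <- match(ycols[1L], qx$pivot)
    se <- sqrt(sigma2 * XtXinv[k, k])
    if (!is.finite(se) || se == 0)
      return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    tstat <- coefs[ycols[1L]] / se
    p <- 2 * stats::pt(-abs(tstat), df2)
    ci_result(p, cfg$alpha, 1L)
  } else {
    X0 <- cbind(rep(1, n), ss$design)
    res0 <- qr.resid(qr(X0), xv)
    rss0 <- sum(res0^2)
    d1 <- ncol(sy$design)
    fstat <- ((rss0 - rss1) / d1) / (rss1 / df2)
    if (!is.finite(fstat)) return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    p <- stats::pf(fstat, d1, df2, lower.tail = FALSE)
    ci_result(p, cfg$alpha, as.integer(d1))
  }
}

# ---- multinomial logistic branch ---------------------------------------

matrixStats_rowMax <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
  out
}

# Multinomial logistic regression with reference category 1, fitted by
# Newton-Raphson with step halving.  W is a d x (k-1) coefficient matrix;
# X includes the intercept column.
multinom_fit <- function(X, yidx, k, max_iter = 100L, tol = 1e-8) {
  n <- nrow(X); dcol <- ncol(X)
  if (k < 2L) return(list(loglik = 0, converged = TRUE, npar = 0L))
  if (dcol == 1L && all(X[, 1L] == 1)) {   # intercept only: closed form
    cnt <- tabulate(yidx, k)
    ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
    return(list(loglik = ll, converged = TRUE, npar = (k - 1L)))
  }
  res <- tryCatch(cpp_multinom_fit(X, as.integer(yidx), as.integer(k),
                                   as.integer(max_iter), tol),
                  error = function(e) NULL)
  if (!is.null(res)) {
    res$npar <- as.integer(res$npar)
    return(res)
  }
  # pure-R fallback (same algorithm)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), yidx)] <- 1
  km1 <- k - 1L
  nll_P <- function(W) {
    eta <- cbind(0, X %*% W)
    mx <- matrixStats_rowMax(eta)
    ee <- exp(eta - mx)
    rs <- rowSums(ee)
    P <- ee / rs
    list(nll = sum(mx + log(rs)) - sum(eta[cbind(seq_len(n), yidx)]), P = P)
  }
  W <- matrix(0, dcol, km1)
  cur <- nll_P(W)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    P <- cur$P
    G <- crossprod(X, P[, -1L, drop = FALSE] - Y[, -1L, drop = FALSE])
    # observed-information Newton step; H is (km1*dcol) square
    H <- matrix(0, km1 * dcol, km1 * dcol)
    for (c1 in seq_len(km1)) for (c2 in seq_len(km1)) {
      wgt <- if (c1 == c2) P[, c1 + 1L] * (1 - P[, c1 + 1L])
             else -P[, c1 + 1L] * P[, c2 + 1L]
      blk <- crossprod(X, X * wgt)
      ridx <- (c1 - 1L) * dcol + seq_len(dcol)
      cidx <- (c2 - 1L) * dcol + seq_len(dcol)
      H[ridx, cidx] <- blk
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), as.vector(G)),
                     error = function(e) NULL)
    if (is.null(step)) break
    stepm <- matrix(step, dcol, km1)
    t <- 1
    repeat {
      cand <- nll_P(W - t * stepm)
      if (is.finite(cand$nll) && cand$nll <= cur$nll + 1e-12) break
      t <- t / 2
      if (t < 1e-6) break
    }
    if (t < 1e-6) break
    W <- W - t * stepm
    if (abs(cur$nll - cand$nll) < tol * (abs(cur$nll) + 1)) {
      cur <- cand
      converged <- TRUE
      break
    }
    cur <- cand
  }
  list(loglik = -cur$nll, converged = converged, npar = dcol * km1)
}

#' Likelihood-ratio conditional-independence test (categorical target)
#'
#' Fits multinomial logistic regressions of categorical `x` on `s` plus `y`
#' (full model) and on `s` alone (null model); twice the log-likelihood
#' difference is compared to a chi-square with degrees of freedom equal to
#' the parameter-count difference.
#'
#' @inheritParams test_continuous
#' @param x name of a categorical variable (the regression target).
#' @export
test_categorical <- function(d, x, y, s = character(), cfg = ci_config()) {
  n <- nrow(d)
  xf <- d[[x]]
  k <- length(unique(xf))
  if (k < 2L) return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
  yidx <- as.integer(factor(xf))  # observed categories only
  sy <- predictor_block(d, y)
  ss <- predictor_block(d, s)
  if (ncol(sy$design) == 0L)
    return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
  X1 <- cbind(rep(1, n), ss$design, sy$design)
  X0 <- cbind(rep(1, n), ss$design)
  if (qr(X1)$rank < ncol(X1))
    return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
  full <- multinom_fit(X1, yidx, k)
  null <- multinom_fit(X0, yidx, k)
  stat <- 2 * (full$loglik - null$loglik)
  dof <- full$npar - null$npar
  if (!is.finite(stat) || dof <= 0L)
    return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, dof, lower.tail = FALSE)
  ci_result(p, cfg$alpha, dof, degenerate = !(full$converged && null$converged) &&
              p > cfg$alpha)
}

#' Mixed conditional-independence test (dispatch)
#'
#' Both continuous: linear branch.  Exactly one categorical: likelihood-ratio
#' branch with the categorical variable as the regression target.  Both
#' categorical: likelihood-ratio branch with the variable having fewer
#' categories as the target (ties broken by name order), which makes the
#' decision symmetric in (x, y).
#'
#' @inheritParams test_continuous
#' @export
ci_test <- function(d, x, y, s = character(), cfg = ci_config()) {
  stopifnot(x != y, !(x %in% s), !(y %in% s))
  xc <- is.factor(d[[x]]); yc <- is.factor(d[[y]])
  if (!xc && !yc) {
    # symmetric canonical order for exact reproducibility
    pr <- sort(c(x, y))
    test_continuous(d, pr[1L], pr[2L], s, cfg)
  } else if (xc && !yc) {
    test_categorical(d, x, y, s, cfg)
  } else if (!xc && yc) {
    test_categorical(d, y, x, s, cfg)
  } else {
    kx <- nlevels(d[[x]]); ky <- nlevels(d[[y]])
    target <- if (kx < ky) x else if (ky < kx) y else sort(c(x, y))[1L]
    other <- setdiff(c(x, y), target)
    test_categorical(d, target, other, s, cfg)
  }
}

#' Oracle conditional-independence test from a DAG
#'
#' Declares independence exactly when `x` and `y` are d-separated by `s` in
#' the data-generating DAG (which may include latent nodes); the p-value is
#' 1 under independence and 0 under dependence.
#'
#' @param g a [mixed_graph()] passing the DAG view.
#' @param x,y node names.
#' @param s conditioning node names.
#' @export
oracle_ci_test <- function(g, x, y, s = character()) {
  ind <- d_separated(g, x, y, s)
  structure(list(pvalue = as.numeric(ind), independent = ind, dof = 0L,
                 degenerate = FALSE), class = "ci_result")
}

#' Build a test closure over a dataset
#'
#' Returns `function(x, y, s)` suitable for the search functions.
#' Predictor design blocks are precomputed per variable and multinomial
#' log-likelihoods are memoized by (target, predictor set): the full model
#' of one test is the null model of many others, so searches share fits.
#' Decisions agree exactly with [ci_test()].
#'
#' @param d a [mixed_dataset()].
#' @param cfg a [ci_config()].
#' @export
make_data_test <- function(d, cfg = ci_config()) {
  n <- nrow(d)
  vars <- names(d)
  isfac <- vapply(d, is.factor, logical(1L))
  names(isfac) <- vars
  pred <- lapply(stats::setNames(vars, vars), function(v)
    predictor_block(d, v)$design)
  yidx <- lapply(stats::setNames(vars, vars), function(v)
    if (isfac[[v]]) as.integer(factor(d[[v]])) else NULL)
  kcat <- vapply(d, function(col) if (is.factor(col))
    length(unique(col)) else 0L, integer(1L))
  names(kcat) <- vars
  nlev <- vapply(d, function(col) if (is.factor(col)) nlevels(col) else 0L,
                 integer(1L))
  names(nlev) <- vars
  xnum <- lapply(stats::setNames(vars, vars), function(v)
    if (!isfac[[v]]) as.numeric(d[[v]]) else NULL)
  ones <- rep(1, n)
  fits <- new.env(parent = emptyenv())
  # fitted multinomial loglik of `target` on intercept + predictors
  mn_ll <- function(target, preds) {
    preds <- sort(preds)
    key <- paste(target, paste(preds, collapse = ","), sep = "~")
    if (exists(key, envir = fits, inherits = FALSE))
      return(get(key, envir = fits, inherits = FALSE))
    X <- do.call(cbind, c(list(ones), pred[preds]))
    val <- if (qr(X)$rank < ncol(X)) list(rankdef = TRUE)
           else c(multinom_fit(X, yidx[[target]], kcat[[target]]),
                  rankdef = FALSE)
    assign(key, val, envir = fits)
    val
  }
  cat_branch <- function(target, other, s) {
    if (kcat[[target]] < 2L || ncol(pred[[other]]) == 0L)
      return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    full <- mn_ll(target, c(s, other))
    null <- mn_ll(target, s)
    if (isTRUE(full$rankdef) || isTRUE(null$rankdef))
      return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    stat <- 2 * (full$loglik - null$loglik)
    dof <- full$npar - null$npar
    if (!is.finite(stat) || dof <= 0L)
      return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    p <- stats::pchisq(max(stat, 0), dof, lower.tail = FALSE)
    ci_result(p, cfg$alpha, dof,
              degenerate = !(full$converged && null$converged) &&
                p > cfg$alpha)
  }
  cont_branch <- function(x, y, s) {
    yb <- pred[[y]]
    if (ncol(yb) == 0L) return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    sb <- if (length(s)) do.call(cbind, pred[sort(s)])
          else matrix(numeric(), n, 0L)
    X1 <- cbind(ones, yb, sb)
    qx <- qr(X1)
    if (qx$rank < ncol(X1))
      return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    df2 <- n - ncol(X1)
    if (df2 <= 0) return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
    xv <- xnum[[x]]
    res1 <- qr.resid(qx, xv)
    rss1 <- sum(res1^2)
    if (!isfac[[y]]) {
      coefs <- qr.coef(qx, xv)
      sigma2 <- rss1 / df2
      XtXinv <- chol2inv(qr.R(qx))
      pos <- match(2L, qx$pivot)
      se <- sqrt(sigma2 * XtXinv[pos, pos])
      if (!is.finite(se) || se == 0)
        return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
      p <- 2 * stats::pt(-abs(coefs[2L] / se), df2)
      ci_result(p, cfg$alpha, 1L)
    } else {
      res0 <- qr.resid(qr(cbind(ones, sb)), xv)
      d1 <- ncol(yb)
      fstat <- ((sum(res0^2) - rss1) / d1) / (rss1 / df2)
      if (!is.finite(fstat))
        return(ci_result(0, cfg$alpha, 0L, degenerate = TRUE))
      ci_result(stats::pf(fstat, d1, df2, lower.tail = FALSE), cfg$alpha,
                as.integer(d1))
    }
  }
  function(x, y, s = character()) {
    s <- sort(s)
    xc <- isfac[[x]]; yc <- isfac[[y]]
    if (!xc && !yc) {
      pr <- sort(c(x, y))
      cont_branch(pr[1L], pr[2L], s)
    } else if (xc && !yc) {
      cat_branch(x, y, s)
    } else if (!xc && yc) {
      cat_branch(y, x, s)
    } else {
      kx <- nlev[[x]]; ky <- nlev[[y]]
      target <- if (kx < ky) x else if (ky < kx) y else sort(c(x, y))[1L]
      cat_branch(target, setdiff(c(x, y), target), s)
    }
  }
}

#' Build an oracle test closure over a DAG
#'
#' The parent structure is precomputed once, so repeated queries are fast.
#'
#' @param g a [mixed_graph()] passing the DAG view.
#' @export
make_oracle_test <- function(g) {
  pl <- parent_index_list(g)
  n <- length(g$nodes)
  nodes <- g$nodes
  function(x, y, s = character()) {
    ind <- dsep_parentlist(pl, n, match(x, nodes), match(y, nodes),
                           match(s, nodes))
    structure(list(pvalue = as.numeric(ind), independent = ind, dof = 0L,
                   degenerate = FALSE), class = "ci_result")
  }
}

#' Wrap a test closure with a call counter
#'
#' @param test a test closure (`function(x, y, s)`).
#' @return a closure with the same signature; read the count with
#'   [test_count()].
#' @export
counted_test <- function(test) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  f <- function(x, y, s = character()) {
    env$count <- env$count + 1L
    test(x, y, s)
  }
  attr(f, "counter") <- env
  f
}

#' Number of calls made through a [counted_test()] closure
#' @param test the counted closure.
#' @export
test_count <- function(test) {
  env <- attr(test, "counter")
  if (is.null(env)) stop("not a counted test")
  env$count
}
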