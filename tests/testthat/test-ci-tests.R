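test_that("indicator expansion follows the one-per-category rule", {
  d <- mixed_dataset(data.frame(
    f = factor(c("a", "b", "c", "a"), levels = c("a", "b", "c")),
    x = c(0.1, 0.2, 0.3, 0.4)))
  ex <- expand_indicators(d, c("f", "x"))
  expect_identical(ex$design[, 1:3],
                   cbind(f.a = c(1, 0, 0, 1), f.b = c(0, 1, 0, 0),
                         f.c = c(0, 0, 1, 0)))
  expect_identical(ex$design[, 4], d$x)
  expect_identical(ex$source, c("f", "f", "f", "x"))
  # continuous-only input is the identity
  ex2 <- expand_indicators(d, "x")
  expect_identical(drop(ex2$design), d$x)
  # indicator columns of each categorical source row-sum to 1
  set.seed(1)
  d3 <- mixed_dataset(data.frame(g = factor(sample(letters[1:4], 30, TRUE)),
                                 h = factor(sample(letters[1:3], 30, TRUE))))
  ex3 <- expand_indicators(d3, c("g", "h"))
  for (v in c("g", "h"))
    expect_true(all(rowSums(ex3$design[, ex3$source == v]) == 1))
  # single observed category flags degeneracy
  d4 <- mixed_dataset(suppressWarnings(
    data.frame(k = factor(rep("a", 5), levels = c("a", "b")), x = rnorm(5))))
  expect_true(expand_indicators(d4, "k")$degenerate)
})

test_that("linear branch matches lm and detects exact dependence", {
  set.seed(2)
  n <- 300
  d <- mixed_dataset(data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n),
                                f = factor(sample(letters[1:3], n, TRUE))))
  r <- test_continuous(d, "x", "y", c("z", "f"))
  fit <- stats::lm(d$x ~ d$y + d$z + d$f)
  expect_equal(r$pvalue, summary(fit)$coefficients[2, 4], tolerance = 1e-10)
  rf <- test_continuous(d, "x", "f", c("y", "z"))
  a <- stats::anova(stats::lm(d$x ~ d$y + d$z),
                    stats::lm(d$x ~ d$y + d$z + d$f))
  expect_equal(rf$pvalue, a[2, "Pr(>F)"], tolerance = 1e-10)
  expect_identical(rf$dof, 2L)

  d2 <- mixed_dataset(data.frame(x = rnorm(100), y = 0))
  d2$y <- d2$x
  r2 <- test_continuous(d2, "x", "y")
  expect_lt(r2$pvalue, 1e-10)
  expect_false(r2$independent)
})

test_that("likelihood-ratio branch: dof count, exact dependence, lm-free oracle", {
  set.seed(3)
  n <- 400
  d <- mixed_dataset(data.frame(x = factor(sample(letters[1:3], n, TRUE)),
                                y = rnorm(n)))
  r <- test_categorical(d, "x", "y")
  expect_identical(r$dof, 2L)  # (k-1) * one new predictor column
  # independent oracle: profile the same LRT with optim on the analytic NLL
  X1 <- cbind(1, d$y); yi <- as.integer(d$x)
  nll <- function(w, X) {
    W <- matrix(w, ncol(X), 2)
    eta <- cbind(0, X %*% W)
    sum(log(rowSums(exp(eta)))) - sum(eta[cbind(seq_len(n), yi)])
  }
  o1 <- stats::optim(rep(0, 4), nll, X = X1, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12))
  o0 <- stats::optim(rep(0, 2), nll, X = cbind(rep(1, n)), method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12))
  stat <- 2 * (o0$value - o1$value)
  expect_equal(r$pvalue, stats::pchisq(stat, 2, lower.tail = FALSE),
               tolerance = 1e-6)

  f <- factor(sample(letters[1:3], 300, TRUE))
  ddet <- mixed_dataset(data.frame(x = f, y = f))
  rdet <- ci_test(ddet, "x", "y")
  expect_false(rdet$independent)
  expect_lt(rdet$pvalue, 1e-10)
})

test_that("dispatch matches the type truth table and is decision-symmetric", {
  set.seed(4)
  n <- 250
  d <- mixed_dataset(data.frame(
    c1 = rnorm(n), c2 = rnorm(n),
    f3 = factor(sample(letters[1:3], n, TRUE)),
    f2 = factor(sample(letters[1:2], n, TRUE))))
  # both continuous -> t test (dof 1); mixed -> LRT with categorical target;
  # both categorical -> LRT with the smaller-arity target
  expect_identical(ci_test(d, "c1", "c2")$dof, 1L)
  expect_identical(ci_test(d, "f3", "c1")$dof,
                   test_categorical(d, "f3", "c1")$dof)
  expect_identical(ci_test(d, "c1", "f3")$dof,
                   test_categorical(d, "f3", "c1")$dof)
  expect_equal(ci_test(d, "f3", "f2")$pvalue,
               test_categorical(d, "f2", "f3")$pvalue)
  # symmetry of the full result for every type combination
  for (pair in list(c("c1", "c2"), c("c1", "f3"), c("f3", "f2"),
                    c("f2", "c2"))) {
    a <- ci_test(d, pair[1], pair[2], "c2"[pair[1] != "c2" & pair[2] != "c2"])
    b <- ci_test(d, pair[2], pair[1], "c2"[pair[1] != "c2" & pair[2] != "c2"])
    expect_identical(a$independent, b$independent)
    expect_equal(a$pvalue, b$pvalue)
  }
})

test_that("fast closure agrees exactly with ci_test on random queries", {
  set.seed(5)
  n <- 200
  d <- mixed_dataset(data.frame(a = rnorm(n),
                                b = factor(sample(letters[1:3], n, TRUE)),
                                c = rnorm(n),
                                e = factor(sample(letters[1:2], n, TRUE))))
  ft <- make_data_test(d)
  vars <- names(d)
  for (i in 1:60) {
    pick <- sample(vars, sample(2:4, 1))
    r1 <- ft(pick[1], pick[2], pick[-(1:2)])
    r2 <- ci_test(d, pick[1], pick[2], pick[-(1:2)])
    expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-9)
    expect_identical(r1$independent, r2$independent)
  }
})

test_that("null calibration and monotone power for both branches", {
  set.seed(6)
  n <- 400; reps <- 400
  pc <- replicate(reps, test_continuous(
    mixed_dataset(data.frame(x = rnorm(n), y = rnorm(n))), "x", "y")$pvalue)
  pk <- replicate(reps, test_categorical(
    mixed_dataset(data.frame(x = factor(sample(letters[1:3], n, TRUE)),
                             y = rnorm(n))), "x", "y")$pvalue)
  band <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(pc < 0.05) - 0.05), band)
  expect_lt(abs(mean(pk < 0.05) - 0.05), band)
  # p-values roughly uniform
  expect_lt(suppressWarnings(stats::ks.test(pc, "punif")$statistic), 0.08)
  expect_lt(suppressWarnings(stats::ks.test(pk, "punif")$statistic), 0.08)
  # larger effects give stochastically smaller p-values
  pv_at <- function(beta) median(replicate(60, {
    x <- rnorm(n); y <- beta * x + rnorm(n)
    test_continuous(mixed_dataset(data.frame(x = x, y = y)), "x", "y")$pvalue
  }))
  expect_lt(pv_at(0.2), pv_at(0.05))
})

test_that("conditioning removes confounded dependence (linear SEM)", {
  set.seed(7)
  n <- 1500
  z <- rnorm(n); x <- z + rnorm(n); y <- z + rnorm(n)
  d <- mixed_dataset(data.frame(x = x, y = y, z = z))
  expect_false(ci_test(d, "x", "y")$independent)
  expect_true(ci_test(d, "x", "y", "z")$independent)
})

test_that("oracle test delegates to d-separation with 0/1 p-values", {
  chain <- dag_from(c("A", "B", "C"), c("A>B", "B>C"))
  r <- oracle_ci_test(chain, "A", "C", "B")
  expect_true(r$independent); expect_identical(r$pvalue, 1)
  # latent confounder: no observed separator
  lat <- dag_from(c("L", "X", "Y"), c("L>X", "L>Y"))
  for (s in list(character())) {
    expect_false(oracle_ci_test(lat, "X", "Y", s)$independent)
  }
  set.seed(8)
  g <- random_test_dag(6, 8)
  fast <- make_oracle_test(g)
  ns <- g$nodes
  for (i in 1:20) {
    xy <- sample(ns, 2)
    s <- setdiff(sample(ns, sample(0:3, 1)), xy)
    expect_identical(fast(xy[1], xy[2], s)$independent,
                     d_separated(g, xy[1], xy[2], s))
  }
})

test_that("degenerate designs are reported dependent, not thrown", {
  set.seed(9)
  d <- mixed_dataset(suppressWarnings(data.frame(
    x = rnorm(30), y = rnorm(30),
    k = factor(rep("a", 30), levels = c("a", "b")))))
  r <- test_continuous(d, "x", "k")
  expect_true(r$degenerate)
  expect_false(r$independent)
  # exactly collinear conditioning column
  d2 <- mixed_dataset(data.frame(x = rnorm(30), y = rnorm(30), z = 0))
  d2$z <- d2$y
  r2 <- test_continuous(d2, "x", "y", "z")
  expect_true(r2$degenerate)
  expect_false(r2$independent)
})
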