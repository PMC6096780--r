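# a scripted independence oracle: `indep` is a list of character vectors
# "x|y|s1,s2" that are declared independent (p = 1); all else dependent
mock_test <- function(indep) {
  keys <- vapply(indep, identity, character(1))
  function(x, y, s = character()) {
    key <- paste(pagmix:::pair_key(x, y), paste(sort(s), collapse = ","),
                 sep = "|")
    ind <- key %in% keys
    structure(list(pvalue = as.numeric(ind), independent = ind, dof = 0L,
                   degenerate = FALSE), class = "ci_result")
  }
}

test_that("stable skeleton recovers oracle chains and colliders", {
  chain <- dag_from(c("A", "B", "C"), c("A>B", "B>C"))
  sk <- stable_skeleton(c("A", "B", "C"),
                        search_config("FCI", alpha = .5, depth = -1),
                        make_oracle_test(chain))
  expect_setequal(edge_set(sk$graph), c("A|B", "B|C"))
  expect_identical(sepset_get(sk$sepsets, "A", "C")$set, "B")

  coll <- dag_from(c("A", "B", "C"), c("A>B", "C>B"))
  sk2 <- stable_skeleton(c("A", "B", "C"),
                         search_config("FCI", alpha = .5, depth = -1),
                         make_oracle_test(coll))
  expect_setequal(edge_set(sk2$graph), c("A|B", "B|C"))
  expect_identical(sepset_get(sk2$sepsets, "A", "C")$set, character())
})

test_that("skeleton is invariant to dataset column permutations", {
  set.seed(21)
  study <- small_study(2, n_nodes = 5, edges = 6, sd = 1, latents = 0L,
                       n = 400)
  cfg <- search_config("FCI", alpha = 0.05, depth = 3)
  ref <- NULL
  for (p in 1:12) {
    dp <- mixed_dataset(as.data.frame(study$data)[, sample(names(study$data))])
    sk <- stable_skeleton(names(dp), cfg, make_data_test(dp, ci_config(0.05)))
    if (is.null(ref)) ref <- sk$graph$marks
    expect_identical(sk$graph$marks, ref)
  }
})

test_that("max-p separating set dominates and matches brute-force argmax", {
  set.seed(22)
  study <- small_study(4, n_nodes = 6, edges = 7, sd = 1, latents = 0L,
                       n = 400)
  cfg <- search_config("FCI_MAX", alpha = 0.05, depth = 3)
  test <- make_data_test(study$data, ci_config(0.05))
  sk <- stable_skeleton(names(study$data), cfg, test)
  g <- sk$graph
  for (key in sepset_pairs(sk$sepsets)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    rec <- sepset_get(sk$sepsets, ab[1], ab[2])
    mp <- max_p_sepset(ab[1], ab[2], g, cfg, test, extra = list(rec$set))
    # dominance over the first-found set
    expect_gte(mp$pvalue, rec$pvalue)
    # brute force over the same candidate lattice, written independently
    cands <- c(list(rec$set), all_subsets(setdiff(adjacencies(g, ab[1]), ab[2])),
               all_subsets(setdiff(adjacencies(g, ab[2]), ab[1])))
    cands <- Filter(function(s) length(s) <= 3, cands)
    best <- max(vapply(cands, function(s) test(ab[1], ab[2], sort(s))$pvalue,
                       numeric(1)))
    expect_equal(mp$pvalue, best, tolerance = 1e-12)
  }
  # with an oracle, a d-separating set (p = 1) is found whenever one exists
  dag <- dag_from(c("A", "B", "C"), c("A>B", "B>C"))
  mp <- max_p_sepset("A", "C", skeleton_of(dag),
                     search_config(depth = -1), make_oracle_test(dag))
  expect_identical(mp$pvalue, 1)
  expect_identical(mp$set, "B")
})

test_that("collider orientation honours the three modes", {
  coll <- dag_from(c("A", "B", "C"), c("A>B", "C>B"))
  cfg <- search_config("FCI", alpha = .5, depth = -1)
  test <- make_oracle_test(coll)
  sk <- stable_skeleton(coll$nodes, cfg, test)
  oc <- orient_colliders(sk$graph, sk$sepsets, cfg, test)
  expect_identical(endpoint(oc$graph, "A", "B"), EP_ARROW)
  expect_identical(endpoint(oc$graph, "C", "B"), EP_ARROW)
  expect_identical(endpoint(oc$graph, "B", "A"), EP_CIRCLE)

  chain <- dag_from(c("A", "B", "C"), c("A>B", "B>C"))
  test2 <- make_oracle_test(chain)
  sk2 <- stable_skeleton(chain$nodes, cfg, test2)
  oc2 <- orient_colliders(sk2$graph, sk2$sepsets, cfg, test2)
  expect_identical(endpoint(oc2$graph, "A", "B"), EP_CIRCLE)
  expect_identical(endpoint(oc2$graph, "C", "B"), EP_CIRCLE)

  # CFCI: B separates in one set but not another -> ambiguous, no arrows
  g <- mixed_graph(c("A", "B", "C", "D"))
  for (e in list(c("A", "B"), c("B", "C"), c("A", "D"), c("D", "C")))
    g <- add_edge(g, e[1], e[2], EP_CIRCLE, EP_CIRCLE)
  sep <- sepset_map(); sepset_put(sep, "A", "C", "D", 0.9)
  mtest <- mock_test(list("A|C|D", "A|C|B,D"))
  occ <- orient_colliders(g, sep, search_config("CFCI", alpha = .5, depth = -1),
                          mtest)
  expect_true("A|B|C" %in% occ$ambiguous)
  expect_identical(endpoint(occ$graph, "A", "B"), EP_CIRCLE)
  expect_identical(endpoint(occ$graph, "C", "B"), EP_CIRCLE)
})

test_that("possible-d-sep follows the collider-or-triangle rule", {
  g <- mixed_graph(c("A", "B", "C"))
  g <- add_edge(g, "A", "B", EP_CIRCLE, EP_ARROW)
  g <- add_edge(g, "C", "B", EP_CIRCLE, EP_ARROW)
  expect_true("B" %in% possible_dsep(g, "A"))
  expect_true("C" %in% possible_dsep(g, "A"))  # collider at B opens the path

  # definite noncollider and no triangle blocks the walk
  h <- mixed_graph(c("A", "B", "C"))
  h <- add_edge(h, "A", "B", EP_CIRCLE, EP_TAIL)
  h <- add_edge(h, "B", "C", EP_ARROW, EP_CIRCLE)  # A o-- B --> C? B end tail
  h$marks["A", "B"] <- EP_TAIL; h$marks["C", "B"] <- EP_TAIL
  expect_false("C" %in% possible_dsep(h, "A"))

  set.seed(23)
  for (rep in 1:6) {
    pg <- mixed_graph(sprintf("P%d", 1:7))
    marks <- c(EP_TAIL, EP_ARROW, EP_CIRCLE)
    for (k in 1:9) {
      ab <- sample(pg$nodes, 2)
      pg <- add_edge(pg, ab[1], ab[2], sample(marks, 1), sample(marks, 1))
    }
    for (x in pg$nodes)
      expect_identical(possible_dsep(pg, x), bf_possible_dsep(pg, x))
  }
})

test_that("possible-d-sep phase removes edges only separable outside adjacency", {
  # latent-free oracle worlds: the stable skeleton is already correct, so
  # the phase must remove nothing
  set.seed(24)
  for (rep in 1:8) {
    dag <- random_test_dag(8, 10)
    cfg <- search_config("FCI", alpha = .5, depth = -1, pdsep_depth = -1)
    test <- make_oracle_test(dag)
    sk <- stable_skeleton(dag$nodes, cfg, test)
    oc <- orient_colliders(sk$graph, sk$sepsets, cfg, test)
    pd <- pdsep_phase(oc$graph, sk$sepsets, cfg, test)
    expect_length(pd$changed, 0)
    expect_identical(edge_set(pd$graph), edge_set(sk$graph))
  }

  # constructed case: X--Y separable only by V, which sits outside both
  # adjacency sets but inside Possible-D-Sep(X) through the collider at C
  g <- mixed_graph(c("C", "V", "X", "Y"))
  g <- add_edge(g, "X", "C", EP_CIRCLE, EP_ARROW)
  g <- add_edge(g, "V", "C", EP_CIRCLE, EP_ARROW)
  g <- add_edge(g, "X", "Y", EP_CIRCLE, EP_CIRCLE)
  g <- add_edge(g, "C", "Y", EP_CIRCLE, EP_CIRCLE)
  sep <- sepset_map()
  mtest <- mock_test(list("X|Y|V"))
  cfg <- search_config("FCI", alpha = .5, depth = -1, pdsep_depth = -1)
  pd <- pdsep_phase(g, sep, cfg, mtest)
  expect_false(is_adjacent(pd$graph, "X", "Y"))
  expect_identical(sepset_get(sep, "X", "Y")$set, "V")
  expect_setequal(pd$changed, c("X", "Y"))
})

test_that("orientation rules fire on their defining configurations", {
  cfg <- search_config("FCI", alpha = .5, depth = -1)
  lookup_none <- function(a, b) NULL
  # R1: A *-> B o-* C with A, C non-adjacent  =>  B -> C
  g <- mixed_graph(c("A", "B", "C"))
  g <- add_edge(g, "A", "B", EP_CIRCLE, EP_ARROW)
  g <- add_edge(g, "B", "C", EP_CIRCLE, EP_CIRCLE)
  out <- pagmix:::apply_zhang_rules(g, sepset_map(), cfg, lookup_none)
  expect_identical(endpoint(out, "B", "C"), EP_ARROW)
  expect_identical(endpoint(out, "C", "B"), EP_TAIL)

  # R2: A -> B *-> C with A *-o C  =>  arrowhead at C on A's edge
  h <- mixed_graph(c("A", "B", "C"))
  h <- add_edge(h, "A", "B", EP_TAIL, EP_ARROW)
  h <- add_edge(h, "B", "C", EP_CIRCLE, EP_ARROW)
  h <- add_edge(h, "A", "C", EP_CIRCLE, EP_CIRCLE)
  out2 <- pagmix:::apply_zhang_rules(h, sepset_map(), cfg, lookup_none)
  expect_identical(endpoint(out2, "A", "C"), EP_ARROW)

  # R4: discriminating path <D, A, B, C>, B in sepset(D, C)  =>  B -> C
  k <- mixed_graph(c("D", "A", "B", "C"))
  k <- add_edge(k, "D", "A", EP_CIRCLE, EP_ARROW)
  k <- add_edge(k, "A", "B", EP_ARROW, EP_ARROW)
  k <- add_edge(k, "A", "C", EP_TAIL, EP_ARROW)   # A -> C (parent)
  k <- add_edge(k, "B", "C", EP_CIRCLE, EP_CIRCLE)
  sep <- sepset_map(); sepset_put(sep, "D", "C", "B", 0.8)
  out3 <- pagmix:::apply_zhang_rules(k, sep, cfg,
                                     function(a, b) sepset_get(sep, a, b))
  expect_identical(endpoint(out3, "C", "B"), EP_TAIL)
  expect_identical(endpoint(out3, "B", "C"), EP_ARROW)
})

test_that("full runs behave end to end", {
  # fully independent world -> edgeless output
  empty <- mixed_graph(c("A", "B", "C", "D"))
  pag <- fci_run(empty$nodes, search_config("FCI", alpha = .5, depth = -1),
                 make_oracle_test(empty))
  expect_length(edge_set(pag), 0)

  # latent confounder world: X <- L -> Y, X -> Z <- Y with L hidden
  dag <- dag_from(c("L", "X", "Y", "Z"),
                  c("L>X", "L>Y", "X>Z", "Y>Z"))
  pag2 <- fci_run(c("X", "Y", "Z"),
                  search_config("FCI", alpha = .5, depth = -1,
                                pdsep_depth = -1),
                  make_oracle_test(dag))
  # triangle with no unshielded triples: nothing is orientable
  expect_setequal(edge_set(pag2), c("X|Y", "X|Z", "Y|Z"))
  expect_true(all(pag2$marks[pag2$marks != 0] == EP_CIRCLE))

  # constrained search only deletes: output adjacencies within the skeleton
  set.seed(25)
  study <- small_study(5, n_nodes = 8, edges = 10, latents = 1L, n = 400)
  skel <- mgm_fit(study$data, mgm_config(lambda = 0.1))$graph
  pag3 <- learn_pag(study$data, "mgm-fci", alpha = 0.05, skeleton = skel)
  expect_true(all(edge_set(pag3) %in% edge_set(skel)))
})

test_that("collider job partitioning is an exact, load-bounded partition", {
  g <- mixed_graph(sprintf("V%d", 1:10))
  set.seed(26)
  for (k in 1:10) {
    ab <- sample(g$nodes, 2)
    g <- add_edge(g, ab[1], ab[2], EP_CIRCLE, EP_CIRCLE)
  }
  triples <- pagmix:::unshielded_triples(g)
  expect_gte(length(triples), 2)
  batches <- partition_collider_jobs(triples, g, cores = 2, beta = 1)
  got <- unlist(lapply(batches, function(b) vapply(b, function(tr)
    pagmix:::triple_key(tr$x, tr$y, tr$z), character(1))))
  want <- vapply(triples, function(tr)
    pagmix:::triple_key(tr$x, tr$y, tr$z), character(1))
  expect_identical(sort(got), sort(want))
  expect_identical(length(got), length(want))  # no loss, no duplication

  # single collider cannot be subdivided
  expect_length(partition_collider_jobs(triples[1], g, cores = 8,
                                        beta = 0.01), 1)

  # hand-traced subdivision: 4 triples of load 5 each, chunk = 10*1/2 = 5
  h <- mixed_graph(c(sprintf("X%d", 1:4), sprintf("Z%d", 1:4), "Y", "W"))
  # give every X_i and Z_i adjacency sets summing to 5 per triple
  edges <- list(c("X1","Y"), c("Z1","Y"), c("X2","Y"), c("Z2","Y"),
                c("X3","W"), c("Z3","W"), c("X4","W"), c("Z4","W"),
                c("X1","X2"), c("X3","X4"))
  for (e in edges) h <- add_edge(h, e[1], e[2], EP_CIRCLE, EP_CIRCLE)
  tr4 <- list(list(x="X1",y="Y",z="Z1"), list(x="X2",y="Y",z="Z2"),
              list(x="X3",y="W",z="Z3"), list(x="X4",y="W",z="Z4"))
  loads <- vapply(tr4, function(tr) length(adjacencies(h, tr$x)) +
                    length(adjacencies(h, tr$z)), numeric(1))
  expect_identical(loads, c(3, 3, 3, 3))
  # chunk = |E| * beta / cores = 10 * 1.2 / 4 = 3: every batch is a singleton
  b4 <- partition_collider_jobs(tr4, h, cores = 4, beta = 1.2)
  expect_length(b4, 4)
})

test_that("serial and multi-core configurations give identical PAGs", {
  set.seed(27)
  for (seed in 1:3) {
    study <- small_study(seed + 30, n_nodes = 9, edges = 11, latents = 2L,
                         n = 10)
    obs <- setdiff(study$dag$nodes, study$latents)
    test <- make_oracle_test(study$dag)
    p1 <- fci_run(obs, search_config("FCI_MAX", alpha = .5, depth = -1,
                                     pdsep_depth = -1, cores = 1), test)
    p4 <- fci_run(obs, search_config("FCI_MAX", alpha = .5, depth = -1,
                                     pdsep_depth = -1, cores = 4,
                                     chunk_beta = 0.5), test)
    expect_identical(p1$marks, p4$marks)
  }
})
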