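chain_net <- function() {
  signal_network(tibble::tibble(source = c("M", "X"),
                                target = c("X", "TF"),
                                relation = "activation"))
}

test_that("network TSV reading de-duplicates and annotates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    source = c("A", "B", "A", "C"),
    target = c("B", "C", "B", "C"),
    relation = "activation",
    source_genes = c("GA", "GB", "GA", "GC"),
    target_genes = c("GB", "GC", "GB", "GC")), f)
  net <- read_network(f)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)  # duplicate A->B collapsed
  expect_equal(sum(net$edges$source == net$edges$target), 1)  # self-loop kept
  expect_equal(net$nodes$genes[net$nodes$id == "A"], "GA")
})

test_that("upstream reach respects the radius and matches BFS", {
  net <- chain_net()
  expect_equal(upstream_reach(net, "M", 2), c(X = 1L, TF = 2L))
  expect_equal(upstream_reach(net, "M", 1), c(X = 1L))
  expect_error(upstream_reach(net, "Q", 2), "unknown")
  # oracle equivalence on random graphs
  withr::with_seed(24, {
    for (i in 1:10) {
      n <- 100
      ids <- sprintf("N%03d", 1:n)
      edges <- tibble::tibble(
        source = sample(ids, 250, replace = TRUE),
        target = sample(ids, 250, replace = TRUE),
        relation = "activation")
      edges <- dplyr::distinct(edges, source, target, .keep_all = TRUE)
      net2 <- signal_network(edges)
      start <- sample(ids, 1)
      radius <- sample(1:6, 1)
      got <- upstream_reach(net2, start, radius)
      want <- oracle_bfs(edges, start, radius)
      expect_equal(got[order(names(got))], want[order(names(want))])
    }
  })
})

test_that("candidate scores follow the coverage-proximity formula", {
  # direct regulator of every TF scores 1/2
  edges <- tibble::tibble(source = "M", target = sprintf("T%d", 1:4),
                          relation = "activation")
  net <- signal_network(edges)
  sc <- score_candidates(net, sprintf("T%d", 1:4), radius = 3)
  expect_equal(sc$score[sc$node_id == "M"], 0.5)
  # a TF itself contributes d = 0 only for itself
  edges2 <- tibble::tibble(source = sprintf("T%d", 1:10),
                           target = "sink", relation = "r")
  net2 <- signal_network(edges2)
  sc2 <- score_candidates(net2, sprintf("T%d", 1:10), radius = 2)
  expect_equal(unique(sc2$score[grepl("^T", sc2$node_id)]), 0.1)
  expect_false("sink" %in% sc2$node_id)  # reaches no TF
  # score bounds and radius contract
  expect_true(all(sc2$score > 0 & sc2$score <= 1))
  expect_error(score_candidates(net2, character(0)), "at least 2")
})

test_that("radius monotonicity: larger radius never lowers a score", {
  withr::with_seed(25, {
    for (i in 1:8) {
      tr <- plant_truth(regulator_tf_coverage = 0.8)
      net <- gen_network(80, edge_density = 1.5, tf_nodes = 6, truth = tr,
                         max_plant_depth = 3, seed = 100 + i)
      tfs <- net$truth$tf_node_ids
      for (r in 1:4) {
        s1 <- score_candidates(net$network, tfs, radius = r)
        s2 <- score_candidates(net$network, tfs, radius = r + 1)
        shared <- intersect(s1$node_id, s2$node_id)
        expect_true(all(s2$score[match(shared, s2$node_id)] >=
                          s1$score[match(shared, s1$node_id)] - 1e-12))
        # no reported TF beyond the radius
        expect_true(all(unlist(s1$reached_tfs) <= r))
      }
    }
  })
})

test_that("permutation z and fdr behave under degenerate and planted nulls", {
  net <- chain_net()
  # universe equal to the TF set: the null is the observation, z = 0
  res <- permutation_significance(net, c("X", "TF"), radius = 3,
                                  n_perm = 100, seed = 1,
                                  tf_universe = c("X", "TF"))
  expect_true(all(res$z_score == 0))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  # planted regulator stands out
  tr <- plant_truth(regulator_tf_coverage = 0.8)
  net2 <- gen_network(200, edge_density = 1.5, tf_nodes = 10, truth = tr,
                      max_plant_depth = 3, seed = 26)
  res2 <- permutation_significance(net2$network, net2$truth$tf_node_ids,
                                   radius = 6, n_perm = 300, seed = 26)
  planted <- res2[res2$node_id == net2$truth$planted_regulator, ]
  expect_gte(planted$z_score, 3)
  expect_lte(planted$fdr, 0.05)
  # determinism
  res3 <- permutation_significance(net2$network, net2$truth$tf_node_ids,
                                   radius = 6, n_perm = 300, seed = 26)
  expect_identical(res2, res3)
  expect_error(permutation_significance(net, c("X", "TF"), n_perm = 10),
               "n_perm")
})

test_that("regulator ranking combines score and z ranks with min-ties", {
  one <- tibble::tibble(node_id = "a", genes = "GA", score = 0.5,
                        n_reached = 1L, reached_tfs = list(c(t = 1L)),
                        z_score = 2, fdr = 0.1)
  expect_equal(rank_regulators(one)$ranks_sum, 2L)
  three <- tibble::tibble(
    node_id = c("best", "mid", "low"),
    genes = NA_character_, score = c(0.9, 0.5, 0.2), n_reached = 1L,
    reached_tfs = list(c(t = 1L)), z_score = c(5, 3, 1),
    fdr = c(0.01, 0.1, 0.5))
  rk <- rank_regulators(three)
  expect_equal(rk$node_id[1], "best")
  expect_equal(rk$ranks_sum[1], 2L)
  # input order does not matter
  rk2 <- rank_regulators(three[c(3, 1, 2), ])
  expect_equal(rk2$node_id, rk$node_id)
})

test_that("the feedback filter demands an up-regulated module carrier", {
  res <- tibble::tibble(
    node_id = c("r1", "r2", "r3", "cplx"),
    genes = c("GA", "GB", "GC", "GX,GA"),
    score = 0.5, n_reached = 1L, reached_tfs = list(c(t = 1L)),
    z_score = 3, fdr = 0.01)
  cs <- c(GA = 9.7, GB = 12, GC = 8.0, GX = 1)
  up <- c("GA", "GC")
  out <- feedback_filter(res, cs, critical_value = 8.77, deg_up = up)
  expect_setequal(out$node_id, c("r1", "cplx"))  # complex passes via GA
  # boundary: exactly at the critical value is retained
  out2 <- feedback_filter(res, c(GA = 8.77, GB = 1, GC = 1, GX = 1),
                          critical_value = 8.77, deg_up = "GA")
  expect_true("r1" %in% out2$node_id)
  # r2: high composite but not up-regulated -> dropped
  expect_false("r2" %in% out$node_id)
})
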