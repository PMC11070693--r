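test_that("degree-targeted skeleton generation is feasible and deterministic", {
  # degrees [2,2,2] admit exactly one simple graph: the triangle
  g <- generate_skeleton(p = 3, degree_sequence = c(2, 2, 2), jitter = 0,
                         seed = 5)
  expect_equal(igraph::ecount(g), 3L)
  expect_true(all(igraph::degree(g) == 2))
  g1 <- generate_skeleton(p = 20, seed = 9)
  g2 <- generate_skeleton(p = 20, seed = 9)
  expect_true(igraph::identical_graphs(g1, g2))
})

test_that("registry preset hits the target edge count on average", {
  ec <- sapply(1:40, function(s) igraph::ecount(generate_skeleton(seed = s)))
  expect_lt(abs(mean(ec) - 280) / 280, 0.1)
})

test_that("random-order orientation always yields a DAG covering the skeleton", {
  for (s in 1:10) {
    sk <- generate_skeleton(p = 12, seed = s)
    dag <- orient_to_dag(sk, seed = s)
    expect_true(igraph::is_dag(dag))
    expect_equal(igraph::ecount(dag), igraph::ecount(sk))
  }
  sk <- generate_skeleton(p = 12, seed = 3)
  expect_true(igraph::identical_graphs(orient_to_dag(sk, seed = 4),
                                       orient_to_dag(sk, seed = 4)))
})

test_that("SEM simulation is reproducible and respects types", {
  sk <- generate_skeleton(p = 10, seed = 2, mean_degree = 3)
  dag <- orient_to_dag(sk, seed = 3)
  specs <- make_benchmark_specs(10, 0.5, seed = 4)
  d1 <- simulate_sem(dag, specs, 300, seed = 5)
  d2 <- simulate_sem(dag, specs, 300, seed = 5)
  expect_identical(d1$df, d2$df)
  expect_equal(d1$n_samples, 300L)
  for (i in seq_len(nrow(specs))) {
    col <- d1$df[[specs$name[i]]]
    if (specs$vtype[i] == "continuous") {
      expect_true(is.numeric(col))
    } else {
      expect_lte(length(unique(col)), specs$n_levels[i])
    }
  }
  expect_error(simulate_sem(dag, specs, 0, seed = 1), "n must be")
})

test_that("a single continuous edge is recovered with the generating sign", {
  set.seed(8)
  n <- 1000
  a <- rnorm(n)
  b <- a + rnorm(n)
  d <- mindnet_data(data.frame(a = a, b = b))
  sk <- learn_skeleton(d)
  expect_equal(present_edges(sk$graph), "a-b")
  expect_equal(sk$graph$pairs$sign[mindnet:::g_idx(sk$graph, "a", "b")],
               "positive")
})

test_that("zero-effect simulations produce mutually independent columns", {
  # roots only: a DAG with no edges; at least 95% of pairs across seeds
  # must come out exactly independent (the regularized test keeps a small
  # finite-sample false-positive rate per pair)
  dag <- igraph::make_empty_graph(n = 0, directed = TRUE) +
    igraph::vertices(sprintf("V%02d", 1:4))
  specs <- make_benchmark_specs(4, 0.5, seed = 2)
  indep_pairs <- 0
  total_pairs <- 0
  for (s in 1:30) {
    d <- simulate_sem(dag, specs, 2000, seed = s)
    sk <- learn_skeleton(d)
    total_pairs <- total_pairs + choose(4, 2)
    indep_pairs <- indep_pairs + choose(4, 2) - length(present_edges(sk$graph))
  }
  expect_gte(indep_pairs / total_pairs, 0.95)
})

test_that("CPDAG construction matches Markov-equivalence facts", {
  # chain a -> b -> c is fully reversible
  dag <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                     directed = TRUE)
  cp <- dag_to_cpdag(dag)
  expect_equal(nrow(cp$directed), 0L)
  expect_equal(nrow(cp$undirected), 2L)
  # collider a -> b <- c keeps both arrows
  dag <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("c", "b")),
                                     directed = TRUE)
  cp <- dag_to_cpdag(dag)
  expect_equal(nrow(cp$directed), 2L)
  expect_equal(nrow(cp$undirected), 0L)
})

test_that("CPDAG equals exhaustive enumeration on random small DAGs", {
  for (p in 3:5) {
    for (s in 1:12) {
      dag <- random_dag(p, q = 0.5, seed = s * 10 + p)
      expect_true(cpdag_equal(dag_to_cpdag(dag), brute_cpdag(dag)),
                  info = sprintf("p=%d seed=%d", p, s))
    }
  }
})

test_that("precision, recall and F respect their defining identities", {
  r <- mindnet:::prf(9, 1, 3)
  expect_equal(unname(r["precision"]), 0.9)
  expect_equal(unname(r["recall"]), 0.75)
  expect_equal(unname(r["f_score"]), 2 * 0.9 * 0.75 / 1.65)
  r0 <- mindnet:::prf(0, 0, 5)
  expect_equal(unname(r0["precision"]), 0)
  expect_equal(unname(r0["f_score"]), 0)
})

test_that("scoring a graph against itself is perfect at all levels", {
  bm <- generate_benchmark(p = 10, discrete_prop = 0.5, n = 100, seed = 3,
                           mean_degree = 3)
  # build an inferred graph equal to the CPDAG
  specs <- bm$data$specs
  g <- mixed_graph(specs)
  cp <- bm$cpdag
  orient_pair <- function(g, from, to) {
    i <- mindnet:::g_idx(g, from, to)
    g$pairs$present[i] <- TRUE
    if (from < to) {
      g$pairs$mark_y[i] <- "head"
      g$pairs$mark_x[i] <- "tail"
      g$pairs$p_head_y[i] <- 0.9
      g$pairs$p_tail_x[i] <- 0.9
    } else {
      g$pairs$mark_x[i] <- "head"
      g$pairs$mark_y[i] <- "tail"
      g$pairs$p_head_x[i] <- 0.9
      g$pairs$p_tail_y[i] <- 0.9
    }
    g$pairs$status[i] <- "genuine"
    g
  }
  if (nrow(cp$directed)) {
    for (r in seq_len(nrow(cp$directed))) {
      g <- orient_pair(g, cp$directed[r, 1], cp$directed[r, 2])
    }
  }
  if (nrow(cp$undirected)) {
    for (r in seq_len(nrow(cp$undirected))) {
      i <- mindnet:::g_idx(g, cp$undirected[r, 1], cp$undirected[r, 2])
      g$pairs$present[i] <- TRUE
      g$pairs$status[i] <- "undirected"
    }
  }
  sc <- score_graphs(cp, g)
  expect_true(all(sc$precision == 1))
  expect_true(all(sc$recall == 1))
  expect_true(all(sc$f_score == 1))
  # empty inferred graph: zero recall, precision 0 by convention
  sc0 <- score_graphs(cp, mixed_graph(specs))
  expect_true(all(sc0$recall == 0))
  expect_true(all(sc0$precision == 0))
})

test_that("oriented precision improves with sample size on mostly discrete data", {
  ctl <- mindnet_control(propagate = TRUE)
  prec <- sapply(c(250L, 1000L, 4000L), function(n) {
    res <- run_benchmark(n_networks = 8, n_samples = n, discrete_prop = 0.8,
                         p = 24, ctl = ctl, seed = 11, mean_degree = 6)
    res[res$network == "mean" & res$level == "oriented_subgraph", "precision"]
  })
  expect_gt(prec[2], prec[1])
  expect_gt(prec[3], prec[2])
})

test_that("benchmark sweeps emit per-network and mean rows deterministically", {
  ctl <- mindnet_control(propagate = TRUE)
  r1 <- run_benchmark(n_networks = 2, n_samples = 150, discrete_prop = 1,
                      p = 8, ctl = ctl, seed = 3, mean_degree = 3)
  r2 <- run_benchmark(n_networks = 2, n_samples = 150, discrete_prop = 1,
                      p = 8, ctl = ctl, seed = 3, mean_degree = 3)
  expect_identical(r1, r2)
  expect_equal(sum(r1$network == "mean"), 3L)
  for (lv in unique(r1$level)) {
    rows <- r1[r1$level == lv & r1$network != "mean", ]
    m <- r1[r1$level == lv & r1$network == "mean", ]
    expect_gte(m$precision, min(rows$precision))
    expect_lte(m$precision, max(rows$precision))
  }
})
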