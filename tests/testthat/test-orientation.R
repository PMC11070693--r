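test_that("v-structure probability and score formulas agree everywhere", {
  # closed-form checkpoints
  expect_equal(v_structure_probability(-log(3)), 2 / 3)
  expect_equal(v_structure_score(-log(3)), log(2), tolerance = 1e-12)
  expect_equal(v_structure_probability(-1e-12), 0.5, tolerance = 1e-9)
  expect_equal(v_structure_score(-1e-12), 0, tolerance = 1e-9)
  expect_equal(v_structure_probability(-50), 1, tolerance = 1e-12)
  # no overflow for huge evidence, score stays ordered and finite
  s <- v_structure_score(-1000)
  expect_true(is.finite(s))
  expect_equal(s, 1000 - log(2), tolerance = 1e-9)
  expect_error(v_structure_probability(0.1), "negative")
  expect_error(v_structure_score(0), "negative")
  # probability-score identity to 1e-12 over 10^4 random inputs
  set.seed(42)
  n_i3 <- -exp(runif(1e4, -20, 3))
  p_direct <- v_structure_probability(n_i3)
  p_score <- 1 / (1 + exp(-v_structure_score(n_i3)))
  expect_lt(max(abs(p_direct - p_score)), 1e-12)
})

test_that("scores still order probabilities that saturate in floating point", {
  a <- v_structure_score(-5000)
  b <- v_structure_score(-6000)
  expect_identical(v_structure_probability(-5000), v_structure_probability(-6000))
  expect_lt(a, b)
})

test_that("induced score limits match the defining formula", {
  # m = M = log 2 collapses to zero confidence
  r <- induced_score(log(2), log(2))
  expect_equal(r$score, 0)
  expect_equal(r$p, 0.5)
  expect_equal(r$score,
               max(0, log(2) - log1p(exp(0) + exp(-log(2)))))
  # overwhelming three-point support: induced score approaches the source
  r <- induced_score(1e6, 3)
  expect_equal(r$score, 3, tolerance = 1e-6)
  # m = M = s -> infinity: score -> s - log 2
  r <- induced_score(40, 40)
  expect_equal(r$score, 40 - log(2), tolerance = 1e-9)
  expect_error(induced_score(-1, 2), "non-negative")
})

test_that("induced confidence never exceeds the source head confidence", {
  set.seed(7)
  for (i in 1:500) {
    sv <- exp(runif(1, -8, 8))
    n3 <- exp(runif(1, -8, 8))
    r <- induced_score(n3, sv)
    expect_lte(r$p, 1 / (1 + exp(-sv)) + 1e-12)
    expect_gte(r$score, 0)
  }
})

test_that("edge classification follows the head/tail significance rules", {
  ends <- function(ph, pt) list(p_head = ph, p_tail = pt)
  expect_equal(classify_edge(ends(0.2, 0.9), ends(0.9, 0.1), 0.5), "genuine")
  expect_equal(classify_edge(ends(0.2, 0.5), ends(0.9, 0.1), 0.5), "putative")
  expect_equal(classify_edge(ends(0.8, 0.1), ends(0.8, 0.1), 0.5), "bidirected")
  expect_equal(classify_edge(ends(0.5, 0.5), ends(0.5, 0.5), 0.5), "undirected")
  # raising beta demotes borderline calls
  expect_equal(classify_edge(ends(0.2, 0.7), ends(0.9, 0.1), 0.75), "putative")
})

test_that("collider data orients heads into the middle node", {
  hits <- 0
  for (s in 1:30) {
    d <- sim_collider(n = 2000, seed = s)
    g <- discover_network(d)
    i1 <- g_idx(g, "x", "z")
    i2 <- g_idx(g, "y", "z")
    if (g$pairs$present[i1] && g$pairs$present[i2] &&
        g$pairs$mark_y[i1] == "head" && g$pairs$mark_y[i2] == "head" &&
        g$pairs$p_head_y[i1] > 0.5 && g$pairs$p_head_y[i2] > 0.5) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 28)
})

test_that("chains stay unoriented without propagation (Markov equivalence)", {
  d <- sim_chain(n = 2000, seed = 4)
  g <- discover_network(d, mindnet_control(propagate = FALSE))
  p <- g$pairs[g$pairs$present, ]
  expect_setequal(present_edges(g), c("x-z", "y-z"))
  expect_true(all(p$mark_x == "undefined" & p$mark_y == "undefined"))
})

test_that("contextual forks orient outward with certain tails", {
  d <- sim_fork(n = 2000, seed = 6)
  d$specs$is_contextual[d$specs$name == "z"] <- TRUE
  g <- discover_network(d)
  for (v in c("x", "y")) {
    i <- g_idx(g, v, "z")
    expect_true(g$pairs$present[i])
    # z is the lexicographic y side of both pairs
    expect_equal(g$pairs$mark_y[i], "tail")
    expect_equal(g$pairs$p_tail_y[i], 1)
    expect_false(g$pairs$mark_y[i] == "head")
  }
})

test_that("no arrowhead ever points into a contextual variable", {
  for (s in 1:5) {
    set.seed(s)
    n <- 1500
    z <- sample(c("s", "d"), n, TRUE)
    x <- ifelse(runif(n) < 0.8, ifelse(z == "s", "a", "b"),
                sample(c("a", "b"), n, TRUE))
    y <- rbern_lab(0.15 + 0.35 * (x == "a") + 0.35 * (z == "s"))
    d <- mindnet_data(data.frame(x = x, y = y, z = z))
    d$specs$is_contextual[d$specs$name == "z"] <- TRUE
    g <- discover_network(d, mindnet_control(propagate = TRUE))
    p <- g$pairs[g$pairs$present, ]
    bad <- (p$y == "z" & p$mark_y == "head") | (p$x == "z" & p$mark_x == "head")
    expect_false(any(bad))
  }
})

test_that("a hidden common cause yields a bidirected edge", {
  hits <- 0
  n_try <- 40
  for (s in seq_len(n_try)) {
    set.seed(s)
    n <- 5000
    w <- sample(c("a", "b"), n, TRUE)
    v <- sample(c("a", "b"), n, TRUE)
    l <- sample(c("s", "d"), n, TRUE)  # latent
    x <- rbern_lab(0.05 + 0.45 * (w == "a") + 0.45 * (l == "s"))
    z <- rbern_lab(0.05 + 0.45 * (v == "a") + 0.45 * (l == "s"))
    d <- mindnet_data(data.frame(w = w, v = v, x = x, z = z))
    g <- discover_network(d)
    i <- g_idx(g, "x", "z")
    if (g$pairs$present[i] && g$pairs$status[i] == "bidirected") hits <- hits + 1
  }
  expect_gte(hits / n_try, 0.9)
})
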