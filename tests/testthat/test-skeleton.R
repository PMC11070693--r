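test_that("top contributor search finds the mediator and rejects noise", {
  # chain x -> a -> y: a is the unique d-separator
  set.seed(21)
  n <- 2000
  x <- sample(c("u", "v"), n, TRUE)
  a <- ifelse(runif(n) < 0.85, ifelse(x == "u", "s", "d"),
              sample(c("s", "d"), n, TRUE))
  y <- ifelse(runif(n) < 0.85, ifelse(a == "s", "p", "q"),
              sample(c("p", "q"), n, TRUE))
  b <- sample(c("e", "f"), n, TRUE)  # pure noise
  d <- mindnet_data(data.frame(x = x, a = a, y = y, b = b))
  top <- find_top_contributor("x", "y", character(0), c("a", "b"), d)
  expect_equal(top$variable, "a")
  expect_gt(top$contribution, 0)
  # three mutually independent variables: no positive contributor
  set.seed(22)
  d2 <- mindnet_data(data.frame(x = sample(letters[1:2], n, TRUE),
                                y = sample(letters[1:2], n, TRUE),
                                a = sample(letters[1:2], n, TRUE)))
  expect_null(find_top_contributor("x", "y", character(0), "a", d2))
})

test_that("independent variables produce the empty graph with empty sepsets", {
  set.seed(30)
  n <- 2000
  d <- mindnet_data(data.frame(x = sample(letters[1:2], n, TRUE),
                               y = sample(letters[1:3], n, TRUE),
                               z = rnorm(n)))
  sk <- learn_skeleton(d)
  expect_equal(length(present_edges(sk$graph)), 0L)
  for (r in sk$records) {
    expect_equal(length(r$contributors), 0L)
    expect_equal(r$residual, 0)
  }
})

test_that("collider and fork skeletons match the d-separation oracle", {
  coll_hits <- 0
  fork_hits <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    sk <- learn_skeleton(sim_collider(n = 2000, seed = s))
    rec <- sk$records[[pair_key("x", "y")]]
    if (identical(present_edges(sk$graph), c("x-z", "y-z")) &&
        !is.null(rec) && length(rec$contributors) == 0L) {
      coll_hits <- coll_hits + 1  # x-y removed marginally, z NOT in sepset
    }
    sk <- learn_skeleton(sim_fork(n = 2000, seed = s))
    rec <- sk$records[[pair_key("x", "y")]]
    if (identical(present_edges(sk$graph), c("x-z", "y-z")) &&
        !is.null(rec) && identical(rec$contributors, "z")) {
      fork_hits <- fork_hits + 1  # x-y removed with sepset {z}
    }
  }
  expect_gte(coll_hits, ceiling(0.95 * n_seeds))
  expect_gte(fork_hits, ceiling(0.95 * n_seeds))
})

test_that("removed edges record zero residual; retained edges keep positive residual", {
  d <- sim_chain(n = 1500, seed = 3)
  sk <- learn_skeleton(d)
  for (key in names(sk$records)) {
    r <- sk$records[[key]]
    i <- mindnet:::g_idx(sk$graph, r$pair[1], r$pair[2])
    if (sk$graph$pairs$present[i]) {
      expect_gt(sk$graph$pairs$residual_info[i], 0)
    } else {
      expect_equal(r$residual, 0)
    }
    # only positive contributions are ever collected
    if (length(r$contributions)) expect_true(all(r$contributions > 0))
  }
})

test_that("raising max_cond never adds edges", {
  set.seed(41)
  n <- 1200
  z1 <- sample(c("a", "b"), n, TRUE)
  z2 <- sample(c("a", "b"), n, TRUE)
  x <- rbern_lab(0.1 + 0.4 * (z1 == "a") + 0.4 * (z2 == "a"))
  y <- rbern_lab(0.1 + 0.4 * (z1 == "a") + 0.4 * (z2 == "a"))
  d <- mindnet_data(data.frame(x = x, y = y, z1 = z1, z2 = z2))
  e0 <- present_edges(learn_skeleton(d, mindnet_control(max_cond = 0))$graph)
  e1 <- present_edges(learn_skeleton(d, mindnet_control(max_cond = 1))$graph)
  e2 <- present_edges(learn_skeleton(d, mindnet_control(max_cond = 2))$graph)
  expect_true(all(e1 %in% e0))
  expect_true(all(e2 %in% e1))
})

test_that("equal-contribution candidates break ties lexicographically", {
  # two byte-identical mediator columns give exactly equal contributions
  set.seed(77)
  n <- 1500
  x <- sample(c("u", "v"), n, TRUE)
  m <- ifelse(runif(n) < 0.85, ifelse(x == "u", "s", "d"),
              sample(c("s", "d"), n, TRUE))
  y <- ifelse(runif(n) < 0.85, ifelse(m == "s", "p", "q"),
              sample(c("p", "q"), n, TRUE))
  d <- mindnet_data(data.frame(x = x, y = y, a1 = m, a2 = m))
  top <- find_top_contributor("x", "y", character(0), c("a2", "a1"), d)
  expect_equal(top$variable, "a1")
})

test_that("argument order does not change all-categorical estimates", {
  d <- sim_chain(n = 900, seed = 13)
  a <- conditional_mi_reg("x", "y", "z", d)
  b <- conditional_mi_reg("y", "x", "z", d)
  expect_lt(abs(a$reg_info_rect - b$reg_info_rect), 1e-9)
})

test_that("skeleton learning is deterministic", {
  d <- sim_fork(n = 800, seed = 9)
  a <- learn_skeleton(d)
  b <- learn_skeleton(d)
  expect_identical(a$graph$pairs, b$graph$pairs)
  expect_identical(a$records, b$records)
})

test_that("noiseless logical chains recover the true skeleton", {
  hits <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 5000
    a <- sample(c("t", "f"), n, TRUE)
    b <- ifelse(runif(n) < 0.9, a, sample(c("t", "f"), n, TRUE))
    c_ <- ifelse(runif(n) < 0.9, b, sample(c("t", "f"), n, TRUE))
    d_ <- ifelse(runif(n) < 0.9, c_, sample(c("t", "f"), n, TRUE))
    dt <- mindnet_data(data.frame(a = a, b = b, c = c_, d = d_))
    sk <- learn_skeleton(dt)
    if (identical(present_edges(sk$graph), c("a-b", "b-c", "c-d"))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 95)
})
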