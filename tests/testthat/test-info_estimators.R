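test_that("plug-in mutual information matches hand computation", {
  # perfect binary association: counts [[2,0],[0,2]] -> log 2
  expect_equal(discrete_mi(c("a", "a", "b", "b"), c("u", "u", "v", "v")),
               log(2))
  # exact independence: counts [[1,1],[1,1]] -> 0
  expect_equal(discrete_mi(c("a", "a", "b", "b"), c("u", "v", "u", "v")), 0)
  # counts [[3,1],[1,3]] against a brute-force sum over the 4 cells
  x <- rep(c("a", "b"), each = 4)
  y <- c("u", "u", "u", "v", "u", "v", "v", "v")
  expect_equal(discrete_mi(x, y), brute_mi(x, y), tolerance = 1e-12)
  expect_error(discrete_mi(character(0), character(0)), "zero usable rows")
})

test_that("plug-in MI equals exhaustive computation on random small tables", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:50, 1)
    x <- sample(letters[1:sample(2:3, 1)], n, TRUE)
    y <- sample(LETTERS[1:sample(2:3, 1)], n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_lt(abs(discrete_mi(x, y) - brute_mi(x, y)), 1e-12)
  }
})

test_that("complexity penalties follow their closed forms", {
  # single-level variables carry no cost
  expect_equal(complexity_term(1, 4, 1, 100, "bic"), 0)
  expect_equal(complexity_term(3, 1, 1, 100, "nml"), 0)
  # bic closed form
  expect_equal(complexity_term(2, 2, 1, 100, "bic"), 0.5 * log(100))
  expect_equal(complexity_term(3, 4, 2, 50, "bic"),
               0.5 * 2 * 3 * 2 * log(50))
  # nml for a 2x2 table at n = 4 against exhaustive enumeration of the
  # multinomial parametric complexity over all 4-sample tables
  expected <- brute_param_complexity(4, 4) - 2 * brute_param_complexity(2, 4)
  expect_equal(complexity_term(2, 2, 1, 4, "nml"), expected, tolerance = 1e-9)
})

test_that("complexity is nondecreasing in cardinalities and sample size", {
  for (mode in c("bic", "nml")) {
    ks <- sapply(2:6, function(cx) complexity_term(cx, 3, 1, 100, mode))
    expect_true(all(diff(ks) > 0))
    ks <- sapply(c(50, 100, 500, 1000), function(n)
      complexity_term(3, 3, 1, n, mode))
    expect_true(all(diff(ks) > 0))
    ks <- sapply(1:4, function(cc) complexity_term(2, 2, cc, 400, mode))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("rectification clamps at zero", {
  expect_equal(rectify(-0.3), 0)
  expect_equal(rectify(0.2), 0.2)
  expect_equal(rectify(0), 0)
  expect_equal(rectify(c(-1, 0.5, 0)), c(0, 0.5, 0))
})

test_that("independent continuous pairs yield exactly zero with single bins", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    r <- optimal_discretization_mi(runif(1000), runif(1000))
    if (r$reg_info_rect == 0 && r$partitions$x$n_bins == 1 &&
        r$partitions$y$n_bins == 1) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 95)
})

test_that("the bin cap is enforced and binds for deterministic pairs", {
  set.seed(1)
  x <- rnorm(100000)
  r <- optimal_discretization_mi(x, x, max_bins = 50)
  expect_equal(r$partitions$x$n_bins, 50L)
  expect_equal(r$partitions$y$n_bins, 50L)
  set.seed(2)
  x <- rnorm(5000)
  r <- optimal_discretization_mi(x, x, max_bins = 10)
  expect_equal(r$partitions$x$n_bins, 10L)
  r2 <- optimal_discretization_mi(x, x + rnorm(5000, 0, 0.1), max_bins = 50)
  expect_lte(r2$partitions$x$n_bins, 50L)
})

test_that("discretized MI estimate agrees with a kNN oracle on noisy linear data", {
  set.seed(7)
  x <- rnorm(500)
  y <- x + rnorm(500)
  r <- optimal_discretization_mi(x, y)
  expect_lt(abs(r$raw_info - ksg_mi(x, y)), 0.05)
})

test_that("optimal discretization validates its inputs", {
  expect_error(optimal_discretization_mi(rnorm(2), rnorm(2)),
               "fewer than 3 complete rows")
  expect_error(optimal_discretization_mi(c("a", "b", "a"), c("u", "v", "u")),
               "continuous")
})

test_that("conditional estimator reduces to the unconditional one", {
  set.seed(3)
  n <- 400
  d <- mindnet_data(data.frame(x = rnorm(n), y = rnorm(n),
                               z = sample(c("a", "b"), n, TRUE)))
  a <- conditional_mi_reg("x", "y", character(0), d)
  b <- optimal_discretization_mi(d$df$x, d$df$y)
  expect_equal(a$reg_info_rect, b$reg_info_rect, tolerance = 1e-12)
})

test_that("conditional independence by construction is detected as exact zero", {
  d <- sim_fork(n = 2000, seed = 5)
  r <- conditional_mi_reg("x", "y", "z", d)
  expect_identical(r$reg_info_rect, 0)
})

test_that("three-point information carries the causal signature sign", {
  # collider: negative; chain: positive; doubly-independent terms: exact zero
  expect_lt(three_point_info("x", "y", "z", character(0), sim_collider(seed = 2)), 0)
  expect_gt(three_point_info("x", "y", "z", character(0), sim_chain(seed = 2)), 0)
  set.seed(9)
  n <- 800
  d <- mindnet_data(data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n)))
  expect_identical(three_point_info("x", "y", "z", character(0), d), 0)
  expect_error(three_point_info("x", "y", "z", "z", d), "cond")
})

test_that("every rectified value the estimators return is non-negative", {
  for (s in 1:20) {
    set.seed(s)
    n <- 150
    d <- mindnet_data(data.frame(
      a = rnorm(n),
      b = sample(letters[1:3], n, TRUE),
      c = rnorm(n) + as.integer(factor(sample(letters[1:3], n, TRUE))),
      e = sample(letters[1:2], n, TRUE)))
    vars <- c("a", "b", "c", "e")
    pp <- utils::combn(vars, 2)
    for (j in seq_len(ncol(pp))) {
      cond <- sample(setdiff(vars, pp[, j]), sample(0:2, 1))
      r <- conditional_mi_reg(pp[1, j], pp[2, j], cond, d)
      expect_gte(r$reg_info_rect, 0)
    }
  }
})

test_that("discretization runtime grows sub-quadratically once the cap binds", {
  times <- sapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(1)
    x <- rnorm(n)
    y <- x + rnorm(n, 0, 0.5)
    st <- Sys.time()
    optimal_discretization_mi(x, y)
    as.numeric(Sys.time() - st, units = "secs")
  })
  slope <- stats::coef(stats::lm(log(pmax(times, 1e-4)) ~ log(c(1e3, 1e4, 1e5))))[2]
  expect_lt(slope, 1.3)
})
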