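# Small simulators for three-node structures and helpers shared by tests.

rbern_lab <- function(p, labels = c("s", "d")) {
  ifelse(stats::runif(length(p)) < p, labels[1L], labels[2L])
}

# binary collider x -> z <- y with additive main effects (faithful)
sim_collider <- function(n = 2000, seed = 1) {
  set.seed(seed)
  x <- sample(c("a", "b"), n, TRUE)
  y <- sample(c("a", "b"), n, TRUE)
  z <- rbern_lab(0.1 + 0.4 * (x == "a") + 0.4 * (y == "a"))
  mindnet_data(data.frame(x = x, y = y, z = z))
}

# fork x <- z -> y
sim_fork <- function(n = 2000, seed = 1, flip = 0.15) {
  set.seed(seed)
  z <- sample(c("s", "d"), n, TRUE)
  noisy <- function(v) ifelse(stats::runif(n) < 1 - flip,
                              ifelse(v == "s", "a", "b"),
                              sample(c("a", "b"), n, TRUE))
  mindnet_data(data.frame(x = noisy(z), y = noisy(z), z = z))
}

# chain x -> z -> y
sim_chain <- function(n = 2000, seed = 1, flip = 0.15) {
  set.seed(seed)
  x <- sample(c("a", "b"), n, TRUE)
  z <- ifelse(stats::runif(n) < 1 - flip, ifelse(x == "a", "s", "d"),
              sample(c("s", "d"), n, TRUE))
  y <- ifelse(stats::runif(n) < 1 - flip, ifelse(z == "s", "a", "b"),
              sample(c("a", "b"), n, TRUE))
  mindnet_data(data.frame(x = x, y = y, z = z))
}

present_edges <- function(g) {
  p <- g$pairs[g$pairs$present, c("x", "y"), drop = FALSE]
  sort(paste(p$x, p$y, sep = "-"))
}

# KSG (max-norm) k-nearest-neighbour mutual information estimate, used as an
# independent oracle for continuous pairs
ksg_mi <- function(x, y, k = 5L) {
  n <- length(x)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1L, function(r) sort(r)[k])
  nx <- vapply(seq_len(n), function(i) sum(dx[i, ] < eps[i]) - 1L, numeric(1))
  ny <- vapply(seq_len(n), function(i) sum(dy[i, ] < eps[i]) - 1L, numeric(1))
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

# brute-force plug-in MI over a contingency table (independent of package
# internals)
brute_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        s <- s + tab[i, j] / n *
          log(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  s
}

# exhaustive multinomial parametric complexity C(L, n) by enumerating
# compositions of n into L cells
brute_param_complexity <- function(L, n) {
  compositions <- function(n, L) {
    if (L == 1L) return(matrix(n, 1L, 1L))
    out <- NULL
    for (k in 0:n) {
      rest <- compositions(n - k, L - 1L)
      out <- rbind(out, cbind(k, rest))
    }
    out
  }
  cc <- compositions(n, L)
  tot <- 0
  for (r in seq_len(nrow(cc))) {
    cnt <- cc[r, ]
    ll <- prod((cnt / n) ^ cnt)
    tot <- tot + exp(lgamma(n + 1) - sum(lgamma(cnt + 1))) * ll
  }
  log(tot)
}

# random mixed graph for round-trip tests
random_mixed_graph <- function(p = 6L, seed = 1L) {
  set.seed(seed)
  specs <- data.frame(name = sprintf("n%02d", seq_len(p)),
                      vtype = sample(c("continuous", "categorical"), p, TRUE),
                      is_contextual = FALSE, stringsAsFactors = FALSE)
  g <- mixed_graph(specs)
  for (i in seq_len(nrow(g$pairs))) {
    if (stats::runif(1) < 0.5) next
    g$pairs$present[i] <- TRUE
    mk <- sample(c("undirected", "directed", "bidirected"), 1L)
    if (mk == "bidirected") {
      g$pairs$mark_x[i] <- "head"
      g$pairs$mark_y[i] <- "head"
      g$pairs$p_head_x[i] <- stats::runif(1, 0.6, 0.99)
      g$pairs$p_head_y[i] <- stats::runif(1, 0.6, 0.99)
      g$pairs$status[i] <- "bidirected"
    } else if (mk == "directed") {
      g$pairs$mark_y[i] <- "head"
      g$pairs$mark_x[i] <- "tail"
      g$pairs$p_head_y[i] <- stats::runif(1, 0.6, 0.99)
      g$pairs$p_tail_x[i] <- stats::runif(1, 0.6, 0.99)
      g$pairs$status[i] <- if (g$pairs$p_tail_x[i] > 0.5) "genuine" else "putative"
    } else {
      g$pairs$status[i] <- "undirected"
    }
    g$pairs$info_reg[i] <- stats::runif(1, 0.01, 1)
    g$pairs$sign[i] <- sample(c("positive", "negative", "na"), 1L)
  }
  for (i in which(!g$pairs$present)) {
    g$sepsets[[pair_key(g$pairs$x[i], g$pairs$y[i])]] <-
      list(pair = c(g$pairs$x[i], g$pairs$y[i]),
           contributors = sample(specs$name, sample(0:2, 1L)),
           contributions = numeric(0), residual = 0)
    g$pairs$info_reg[i] <- 0
    g$pairs$residual_info[i] <- 0
  }
  g
}

marks_equal <- function(a, b) {
  all(a$pairs$present == b$pairs$present) &&
    all(a$pairs$mark_x == b$pairs$mark_x) &&
    all(a$pairs$mark_y == b$pairs$mark_y)
}

# random DAG over p nodes with edge probability q
random_dag <- function(p, q = 0.4, seed = 1L) {
  set.seed(seed)
  nms <- sprintf("d%d", seq_len(p))
  el <- NULL
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      if (stats::runif(1) < q) el <- rbind(el, c(nms[i], nms[j]))
    }
  }
  if (is.null(el)) el <- matrix(character(0), 0L, 2L)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  g + igraph::vertices(setdiff(nms, igraph::V(g)$name))
}

# brute-force CPDAG: enumerate all acyclic orientations of the skeleton with
# the same v-structures as the DAG; an edge is compelled iff it has the same
# direction in all of them
brute_cpdag <- function(dag) {
  el <- igraph::as_edgelist(dag)
  nms <- igraph::V(dag)$name
  m <- nrow(el)
  if (m == 0L) {
    return(list(nodes = nms, directed = matrix(character(0), 0L, 2L),
                undirected = matrix(character(0), 0L, 2L)))
  }
  vstructs <- function(edges) {
    out <- character(0)
    for (z in nms) {
      par <- edges[edges[, 2L] == z, 1L, drop = TRUE]
      if (length(par) < 2L) next
      cmb <- utils::combn(sort(par), 2L)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1L, j]
        b <- cmb[2L, j]
        adj <- any((edges[, 1L] == a & edges[, 2L] == b) |
                   (edges[, 1L] == b & edges[, 2L] == a))
        if (!adj) out <- c(out, paste(a, z, b))
      }
    }
    sort(out)
  }
  target <- vstructs(el)
  same_dir <- rep(TRUE, m)
  seen_forward <- rep(FALSE, m)
  for (mask in 0:(2^m - 1)) {
    flip <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    edges <- el
    edges[flip, ] <- edges[flip, 2:1]
    gg <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(gg)) next
    if (!identical(vstructs(edges), target)) next
    seen_forward <- seen_forward | !flip
    same_dir <- same_dir & !flip
  }
  directed <- el[same_dir, , drop = FALSE]
  und <- el[!same_dir, , drop = FALSE]
  und <- t(apply(und, 1L, sort))
  if (length(und) == 0L) und <- matrix(character(0), 0L, 2L)
  list(nodes = nms, directed = directed, undirected = und)
}

cpdag_equal <- function(a, b) {
  fmt <- function(m) if (nrow(m)) sort(paste(m[, 1L], m[, 2L])) else character(0)
  identical(fmt(a$directed), fmt(b$directed)) &&
    identical(fmt(a$undirected), fmt(b$undirected))
}
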