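# Synthetic benchmark generation and scoring.
#
# Benchmarks emulate a nationwide cancer-registry network: 51 mixed-type
# variables whose skeleton follows a right-skewed degree distribution with
# mean degree about 11 (280 edges), jittered by +/-2 connections per node,
# realized by degree-sequence construction plus edge-swap rewiring, then
# oriented into a DAG by a random node ordering and sampled from mixed-type
# structural equation models with skewed categorical marginals and bimodal
# continuous root distributions.

#' Generate a random undirected skeleton with a registry-like degree profile
#'
#' Degrees are drawn from a right-skewed distribution (negative binomial plus
#' one) with the requested mean, jittered by `+/- jitter` connections per
#' node, made graphical, realized deterministically, then randomized by
#' degree-preserving edge swaps.
#'
#' @param p number of nodes (default 51).
#' @param degree_sequence optional explicit degree sequence (jitter still
#'   applies; use `jitter = 0` to keep it exact).
#' @param jitter per-node degree variability (default 2).
#' @param mean_degree target mean degree for drawn sequences (default 11).
#' @param seed integer seed.
#' @return an undirected [igraph::igraph] with vertex names `V01...`.
#' @export
generate_skeleton <- function(p = 51L, degree_sequence = NULL, jitter = 2L,
                              mean_degree = 11, seed = 1L) {
  set.seed(seed)
  for (attempt in seq_len(100L)) {
    deg <- if (is.null(degree_sequence)) {
      1L + stats::rnbinom(p, size = 6, mu = mean_degree - 1)
    } else {
      as.integer(degree_sequence)
    }
    if (jitter > 0L) deg <- deg + sample(seq(-jitter, jitter), p, replace = TRUE)
    deg <- pmin(pmax(deg, 1L), p - 1L)
    if (sum(deg) %% 2L == 1L) {
      j <- which.max(deg)
      deg[j] <- deg[j] - 1L
    }
    if (igraph::is_graphical(deg)) {
      g <- igraph::realize_degseq(deg, method = "smallest")
      g <- igraph::rewire(g, igraph::keeping_degseq(niter = 20L * igraph::ecount(g)))
      igraph::V(g)$name <- sprintf("V%02d", seq_len(p))
      return(g)
    }
  }
  stop("no graphical degree sequence after 100 jitter redraws")
}

#' Orient a skeleton into a DAG by a random node ordering
#'
#' @param skeleton undirected igraph.
#' @param seed integer seed.
#' @return directed acyclic [igraph::igraph]; the permutation is stored in
#'   the graph attribute `"order"`.
#' @export
orient_to_dag <- function(skeleton, seed = 1L) {
  set.seed(seed)
  nms <- igraph::V(skeleton)$name
  perm <- sample(nms)
  rank <- stats::setNames(seq_along(perm), perm)
  el <- igraph::as_edgelist(skeleton)
  flip <- rank[el[, 1L]] > rank[el[, 2L]]
  el[flip, ] <- el[flip, 2:1]
  dag <- igraph::graph_from_edgelist(el, directed = TRUE)
  dag <- dag + igraph::vertices(setdiff(nms, igraph::V(dag)$name))
  dag <- igraph::permute(dag, match(igraph::V(dag)$name, nms))
  igraph::graph_attr(dag, "order") <- perm
  dag
}

#' Assign mixed variable types to benchmark nodes
#'
#' @param p number of nodes.
#' @param discrete_prop fraction of categorical nodes (0 to 1).
#' @param seed integer seed.
#' @return spec data.frame (`name`, `vtype`, `is_contextual`, `n_levels`).
#' @export
make_benchmark_specs <- function(p = 51L, discrete_prop = 0.8, seed = 1L) {
  set.seed(seed)
  nms <- sprintf("V%02d", seq_len(p))
  ncat <- round(p * discrete_prop)
  cat_nodes <- if (ncat > 0L) sample(nms, ncat) else character(0)
  data.frame(
    name = nms,
    vtype = ifelse(nms %in% cat_nodes, "categorical", "continuous"),
    is_contextual = FALSE,
    n_levels = ifelse(nms %in% cat_nodes, sample(2:6, p, replace = TRUE), NA),
    stringsAsFactors = FALSE
  )
}

skewed_probs <- function(L) {
  top <- stats::runif(1, 0.4, 0.7)
  rest <- stats::runif(L - 1L)
  rest <- rest / sum(rest) * (1 - top)
  sample(c(top, rest))
}

#' Sample a mixed-type structural equation model on a DAG
#'
#' Nodes are sampled in topological order.  Continuous roots follow a
#' two-component location mixture, categorical roots a skewed multinomial
#' (largest level 40-70% mass).  Each parent contributes a standardized
#' effect with magnitude drawn in `[0.3, 1]`: a linear coefficient of
#' magnitude in `[0.4, 1.2]` (random sign) rescaled for continuous parents,
#' per-level effects for categorical parents.  Continuous children add unit
#' Gaussian noise; categorical children are drawn from a multinomial logit
#' on the same parent effects.
#'
#' @param dag directed acyclic igraph.
#' @param specs spec table from [make_benchmark_specs()].
#' @param n sample size (>= 1).
#' @param seed integer seed.
#' @return a [mindnet_data] with `n` rows.
#' @export
simulate_sem <- function(dag, specs, n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  nms <- igraph::V(dag)$name
  ord <- nms[as.integer(igraph::topo_sort(dag))]
  df <- as.data.frame(stats::setNames(rep(list(rep(NA_real_, n)), length(nms)), nms))
  lv <- function(name) specs$n_levels[specs$name == name]
  vt <- function(name) specs$vtype[specs$name == name]

  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }

  for (v in ord) {
    parents <- nms[igraph::neighbors(dag, v, mode = "in")]
    L <- lv(v)
    if (!length(parents)) {
      if (vt(v) == "continuous") {
        w <- stats::runif(1, 0.3, 0.7)
        delta <- stats::runif(1, 1.5, 3.5)
        comp <- stats::rbinom(n, 1L, w)
        df[[v]] <- stats::rnorm(n, mean = ifelse(comp == 1L, -delta / 2, delta / 2), sd = 1)
      } else {
        df[[v]] <- sample(letters[seq_len(L)], n, replace = TRUE,
                          prob = skewed_probs(L))
      }
      next
    }
    # standardized per-parent signal columns
    contrib <- matrix(0, n, length(parents))
    for (j in seq_along(parents)) {
      pvar <- parents[j]
      s_p <- stats::runif(1, 0.3, 1.0)
      if (vt(pvar) == "continuous") {
        coef <- stats::runif(1, 0.4, 1.2) * sample(c(-1, 1), 1L)
        contrib[, j] <- s_p * sign(coef) * std(coef * df[[pvar]])
      } else {
        eff <- stats::rnorm(lv(pvar))
        vals <- eff[match(df[[pvar]], letters[seq_len(lv(pvar))])]
        contrib[, j] <- s_p * std(vals)
      }
    }
    if (vt(v) == "continuous") {
      df[[v]] <- rowSums(contrib) + stats::rnorm(n)
    } else {
      # multinomial logit with ordered level scores: each parent acts
      # through one monotone linear predictor (guaranteed main effects, no
      # purely interactive, unfaithful mechanisms)
      alpha <- log(skewed_probs(L))
      tl <- seq(-1, 1, length.out = L)
      lin <- rowSums(contrib) * stats::runif(1, 1.5, 2.5)
      eta <- outer(lin, tl) + matrix(alpha, n, L, byrow = TRUE)
      eta <- eta - apply(eta, 1L, max)
      pr <- exp(eta)
      pr <- pr / rowSums(pr)
      u <- stats::runif(n)
      cum <- t(apply(pr, 1L, cumsum))
      idx <- rowSums(u > cum) + 1L
      df[[v]] <- letters[idx]
    }
  }
  sp <- specs[match(nms, specs$name), c("name", "vtype", "is_contextual")]
  mindnet_data(df, sp)
}

#' Generate a full benchmark instance
#'
#' Skeleton, DAG, variable types, CPDAG and sampled data, all derived
#' deterministically from one seed.
#'
#' @param p nodes; @param discrete_prop categorical fraction; @param n
#'   samples; @param seed integer seed; @param mean_degree target mean
#'   degree.
#' @return list with elements `dag`, `cpdag`, `specs`, `data`, `seed`.
#' @export
generate_benchmark <- function(p = 51L, discrete_prop = 0.8, n = 500L,
                               seed = 1L, mean_degree = 11) {
  sk <- generate_skeleton(p = p, mean_degree = mean_degree, seed = seed)
  dag <- orient_to_dag(sk, seed = seed + 1L)
  specs <- make_benchmark_specs(p, discrete_prop, seed = seed + 2L)
  data <- simulate_sem(dag, specs, n, seed = seed + 3L)
  list(dag = dag, cpdag = dag_to_cpdag(dag), specs = specs, data = data,
       seed = seed)
}

#' Completed partially directed acyclic graph of a DAG
#'
#' Identifies compelled edge directions: v-structure arrowheads plus the
#' standard orientation-propagation closure rules.  Reversible edges are
#' returned undirected.
#'
#' @param dag directed acyclic igraph.
#' @return list with `nodes`, `directed` (2-column from/to matrix) and
#'   `undirected` (2-column matrix, x < y).
#' @export
dag_to_cpdag <- function(dag) {
  nms <- igraph::V(dag)$name
  el <- igraph::as_edgelist(dag)
  adj <- function(a, b) {
    any((el[, 1L] == a & el[, 2L] == b) | (el[, 1L] == b & el[, 2L] == a))
  }
  # directed marks: start with v-structure arrowhead edges
  dirmat <- matrix(character(0), 0L, 2L)
  if (nrow(el)) {
    for (z in nms) {
      par <- el[el[, 2L] == z, 1L]
      if (length(par) < 2L) next
      cmb <- utils::combn(sort(par), 2L)
      for (j in seq_len(ncol(cmb))) {
        if (!adj(cmb[1L, j], cmb[2L, j])) {
          dirmat <- rbind(dirmat, c(cmb[1L, j], z), c(cmb[2L, j], z))
        }
      }
    }
  }
  dirmat <- unique(dirmat)
  meek_closure(nms, el, dirmat)
}

# orientation closure (propagation rules) over a skeleton `el` (rows carry
# the true direction, used only for adjacency) with compelled directed
# edges `dirmat`; returns the CPDAG edge partition
meek_closure <- function(nms, el, dirmat) {
  if (!nrow(el)) {
    return(list(nodes = nms,
                directed = matrix(character(0), 0L, 2L),
                undirected = matrix(character(0), 0L, 2L)))
  }
  skel <- unique(t(apply(el, 1L, sort)))
  has_dir <- function(a, b) {
    nrow(dirmat) > 0L && any(dirmat[, 1L] == a & dirmat[, 2L] == b)
  }
  oriented <- function(a, b) has_dir(a, b) || has_dir(b, a)
  adj <- function(a, b) any(skel[, 1L] == pmin(a, b) & skel[, 2L] == pmax(a, b))
  nbrs <- function(a) {
    c(skel[skel[, 1L] == a, 2L], skel[skel[, 2L] == a, 1L])
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(skel))) {
      for (swap in c(FALSE, TRUE)) {
        a <- if (swap) skel[r, 2L] else skel[r, 1L]
        b <- if (swap) skel[r, 1L] else skel[r, 2L]
        if (oriented(a, b)) next
        fire <- FALSE
        # R1: c -> a, c not adjacent to b  =>  a -> b
        for (cc in nbrs(a)) {
          if (has_dir(cc, a) && cc != b && !adj(cc, b)) { fire <- TRUE; break }
        }
        # R2: a -> c -> b  =>  a -> b
        if (!fire) {
          for (cc in intersect(nbrs(a), nbrs(b))) {
            if (has_dir(a, cc) && has_dir(cc, b)) { fire <- TRUE; break }
          }
        }
        # R3: a - c -> b, a - d -> b, c,d non-adjacent  =>  a -> b
        if (!fire) {
          cand <- intersect(nbrs(a), nbrs(b))
          cand <- cand[vapply(cand, function(cc) {
            !oriented(a, cc) && has_dir(cc, b)
          }, logical(1))]
          if (length(cand) >= 2L) {
            cmb <- utils::combn(cand, 2L)
            for (j in seq_len(ncol(cmb))) {
              if (!adj(cmb[1L, j], cmb[2L, j])) { fire <- TRUE; break }
            }
          }
        }
        # R4: a - d -> c -> b with d,b non-adjacent and a - c  =>  a -> b
        if (!fire) {
          for (cc in intersect(nbrs(a), nbrs(b))) {
            if (!has_dir(cc, b)) next
            for (dd in intersect(nbrs(a), nbrs(cc))) {
              if (dd != b && has_dir(dd, cc) && !oriented(a, dd) && !adj(dd, b)) {
                fire <- TRUE
                break
              }
            }
            if (fire) break
          }
        }
        if (fire) {
          dirmat <- rbind(dirmat, c(a, b))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  und <- skel[!vapply(seq_len(nrow(skel)), function(r) {
    oriented(skel[r, 1L], skel[r, 2L])
  }, logical(1)), , drop = FALSE]
  list(nodes = nms, directed = dirmat, undirected = und)
}

prf <- function(tp, fp, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f_score = f)
}

# inferred-edge orientation summary: for each present pair, the set of
# significant heads (a head mark whose probability clears 1/2; genuine,
# putative and bidirected edges are the oriented ones)
inferred_edge_table <- function(g) {
  p <- g$pairs[g$pairs$present, , drop = FALSE]
  if (!nrow(p)) {
    return(data.frame(x = character(0), y = character(0),
                      head_x = logical(0), head_y = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(x = p$x, y = p$y,
             head_x = p$mark_x == "head" & p$p_head_x > 0.5,
             head_y = p$mark_y == "head" & p$p_head_y > 0.5,
             stringsAsFactors = FALSE)
}

#' Score an inferred graph against a true CPDAG
#'
#' Three levels: skeleton (edge presence only); CPDAG (an edge found with
#' the wrong orientation state - an erroneously oriented reversible edge, or
#' a compelled edge left unoriented or reversed - counts as a false
#' positive); oriented-edge subgraph (precision/recall/F restricted to the
#' edges oriented in the true CPDAG versus those oriented in the inferred
#' graph; genuine and putative edges both count as oriented, and a
#' bidirected inferred edge matches only a compelled true edge).
#'
#' @param truth_cpdag output of [dag_to_cpdag()].
#' @param inferred a classified [mixed_graph] on the same nodes.
#' @return data.frame with one row per level and columns `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`.
#' @export
score_graphs <- function(truth_cpdag, inferred) {
  if (!setequal(truth_cpdag$nodes, inferred$nodes$name)) {
    stop("node sets differ between truth and inferred graph")
  }
  inf <- inferred_edge_table(inferred)
  inf_keys <- pair_key(inf$x, inf$y)
  tdir <- truth_cpdag$directed
  tund <- truth_cpdag$undirected
  tdir_keys <- if (nrow(tdir)) pair_key(tdir[, 1L], tdir[, 2L]) else character(0)
  tund_keys <- if (nrow(tund)) pair_key(tund[, 1L], tund[, 2L]) else character(0)
  truth_keys <- c(tdir_keys, tund_keys)

  # skeleton
  sk <- prf(tp = sum(inf_keys %in% truth_keys),
            fp = sum(!inf_keys %in% truth_keys),
            fn = sum(!truth_keys %in% inf_keys))

  # orientation state of each inferred edge
  n_heads <- inf$head_x + inf$head_y
  # head endpoint for singly-oriented inferred edges
  head_at <- ifelse(inf$head_y & !inf$head_x, inf$y,
                    ifelse(inf$head_x & !inf$head_y, inf$x, NA))
  truth_head <- stats::setNames(tdir[, 2L], tdir_keys)

  cp_tp <- 0L
  cp_fp <- 0L
  for (i in seq_along(inf_keys)) {
    k <- inf_keys[i]
    if (!(k %in% truth_keys)) { cp_fp <- cp_fp + 1L; next }
    if (k %in% tund_keys) {
      if (n_heads[i] == 0L) cp_tp <- cp_tp + 1L else cp_fp <- cp_fp + 1L
    } else {
      ok <- n_heads[i] == 1L && !is.na(head_at[i]) && head_at[i] == truth_head[[k]]
      if (ok) cp_tp <- cp_tp + 1L else cp_fp <- cp_fp + 1L
    }
  }
  cp <- prf(tp = cp_tp, fp = cp_fp, fn = sum(!truth_keys %in% inf_keys))

  # oriented-edge subgraph
  ori_inf <- which(n_heads >= 1L)
  or_tp <- 0L
  or_fp <- 0L
  for (i in ori_inf) {
    k <- inf_keys[i]
    if (n_heads[i] == 2L) {
      # bidirected: matches only a compelled true edge
      if (k %in% tdir_keys) or_tp <- or_tp + 1L else or_fp <- or_fp + 1L
    } else if (k %in% tdir_keys && head_at[i] == truth_head[[k]]) {
      or_tp <- or_tp + 1L
    } else {
      or_fp <- or_fp + 1L
    }
  }
  or <- prf(tp = or_tp, fp = or_fp, fn = length(tdir_keys) - or_tp)

  out <- as.data.frame(rbind(skeleton = sk, cpdag = cp, oriented_subgraph = or))
  out$level <- rownames(out)
  rownames(out) <- NULL
  out[c("level", "tp", "fp", "fn", "precision", "recall", "f_score")]
}

#' Run a benchmark sweep
#'
#' Generates `n_networks` benchmark instances, learns a network from each
#' sample with [discover_network()], scores all three levels and appends a
#' mean row per level.
#'
#' @param n_networks number of instances.
#' @param n_samples rows per sampled table.
#' @param discrete_prop categorical-node fraction.
#' @param p nodes per network.
#' @param ctl a [mindnet_control()]; benchmark runs conventionally use
#'   `propagate = TRUE`.
#' @param seed base seed; instance `i` uses `seed + 1000 * (i - 1)`.
#' @param mean_degree target mean degree.
#' @return data.frame of per-network scores (`network`, `level`, counts,
#'   precision/recall/F) with `network = "mean"` summary rows.
#' @export
run_benchmark <- function(n_networks = 10L, n_samples = 500L,
                          discrete_prop = 0.8, p = 51L,
                          ctl = mindnet_control(propagate = TRUE),
                          seed = 1L, mean_degree = 11) {
  rows <- list()
  for (i in seq_len(n_networks)) {
    bm <- generate_benchmark(p = p, discrete_prop = discrete_prop,
                             n = n_samples, seed = seed + 1000L * (i - 1L),
                             mean_degree = mean_degree)
    g <- discover_network(bm$data, ctl)
    sc <- score_graphs(bm$cpdag, g)
    sc$network <- as.character(i)
    rows[[i]] <- sc
  }
  res <- do.call(rbind, rows)
  means <- stats::aggregate(res[c("precision", "recall", "f_score")],
                            by = list(level = res$level), FUN = mean)
  means$network <- "mean"
  means$tp <- NA_real_
  means$fp <- NA_real_
  means$fn <- NA_real_
  rbind(res, means[names(res)])
}
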