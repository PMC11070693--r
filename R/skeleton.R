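# Step 1: edge removal by iterative collection of information contributors.
#
# Starting from the complete graph, pairs with zero rectified regularized
# mutual information are dropped immediately (empty separating set).  For
# the surviving edges, the most significant positive information
# contributors are collected one at a time; an edge is removed the moment
# its rectified residual I'(X;Y|{Ai}) reaches zero, and the collected
# contributors form its separating set.  Candidate contributors must carry a
# strictly positive *raw* three-point contribution I(X;Y;A|{Ai}) > 0 (a
# complexity-driven drop in regularized information alone does not qualify a
# contributor); among eligible candidates the one with the largest
# regularized contribution is collected.

#' Control parameters for network learning
#'
#' @param max_bins cap on the number of bins per continuous variable.
#' @param mode complexity penalty for categorical estimates, `"nml"` or `"bic"`.
#' @param max_cond maximum number of collected contributors per edge; an edge
#'   whose conditioning set reaches the cap is retained.
#' @param n_cand candidate cut-point grid size for unconditional estimates.
#' @param n_cand_cond grid size for conditional estimates (smaller: these
#'   dominate the run time and need less cut-point resolution).
#' @param beta orientation confidence threshold in `[0.5, 1)`.
#' @param propagate propagate induced tails as heads at the opposite end.
#' @param contextual_priors pin `p_tail = 1` at contextual endpoints and
#'   forbid arrowheads into contextual variables.
#' @param consistency `"none"`, `"skeleton"` or `"orientation"`.
#' @param max_iterations cap on consistency iterations.
#' @param scope candidate contributors are drawn from the `"union"` (default)
#'   or `"common"` part of the current neighborhoods of the two endpoints.
#' @param contributor_rule `"closure"` (default): a candidate whose addition
#'   drives the rectified residual to zero completes a separating set and is
#'   always admissible; `"significance"`: only candidates whose raw
#'   three-point contribution exceeds the complexity increase are collected.
#'   Closure removes more dispensable edges (higher skeleton precision),
#'   significance preserves more weak edges (higher recall).
#' @return a named list of settings.
#' @export
mindnet_control <- function(max_bins = 50L, mode = "nml", max_cond = 20L,
                            n_cand = 64L, n_cand_cond = 32L,
                            beta = 0.5, propagate = FALSE,
                            contextual_priors = TRUE,
                            consistency = "none", max_iterations = 100L,
                            scope = c("union", "common"),
                            contributor_rule = c("closure", "significance")) {
  stopifnot(beta >= 0.5, beta < 1, max_bins >= 1, max_cond >= 0,
            max_iterations >= 1)
  list(max_bins = as.integer(max_bins), mode = mode,
       max_cond = as.integer(max_cond), n_cand = as.integer(n_cand),
       n_cand_cond = as.integer(n_cand_cond), beta = beta,
       propagate = propagate, contextual_priors = contextual_priors,
       consistency = match.arg(consistency, c("none", "skeleton", "orientation")),
       max_iterations = as.integer(max_iterations),
       scope = match.arg(scope),
       contributor_rule = match.arg(contributor_rule))
}

# memoizing conditional-information session
new_session <- function(data, ctl) {
  env <- new.env(parent = emptyenv())
  env$data <- data
  env$ctl <- ctl
  env$cache <- new.env(parent = emptyenv())
  env
}

session_cmi <- function(ss, x, y, cond) {
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  key <- paste(c(x, y, sort(cond)), collapse = "\r")
  got <- ss$cache[[key]]
  if (!is.null(got)) return(got)
  prep_fast(ss)
  if (!ss$has_na) {
    val <- cmi_fast(ss, x, y, cond)
  } else {
    nc <- if (length(cond)) ss$ctl$n_cand_cond else ss$ctl$n_cand
    r <- conditional_mi_reg(x, y, cond, ss$data, ss$ctl$max_bins,
                            ss$ctl$mode, nc)
    val <- list(raw = r$raw_info, rect = r$reg_info_rect,
                kpn = r$complexity)  # penalty per sample, raw - reg
  }
  assign(key, val, envir = ss$cache)
  val
}

#' Find the most significant information contributor for a pair
#'
#' Among `candidates`, returns the variable with the largest regularized
#' three-point contribution `I'(X;Y;A|collected)` -- the raw contribution
#' minus the complexity increase of the extended conditioning set -- or
#' `NULL` if no candidate has a strictly positive one.  Ties are broken
#' toward the lexicographically smaller name.
#'
#' @param x,y the pair under examination.
#' @param collected contributors already collected, in order.
#' @param candidates eligible contributor names.
#' @param data a [mindnet_data].
#' @param ctl a [mindnet_control()] list.
#' @return `list(variable =, contribution =, raw_contribution =, residual =,
#'   raw_residual =)` or `NULL`.
#' @export
find_top_contributor <- function(x, y, collected, candidates, data,
                                 ctl = mindnet_control()) {
  ss <- new_session(data, ctl)
  res <- top_contributor(ss, x, y, collected, candidates)
  res$pick
}

top_contributor <- function(ss, x, y, collected, candidates,
                            closure_pool = NULL) {
  base <- session_cmi(ss, x, y, collected)
  cand <- sort(setdiff(candidates, c(x, y, collected)))
  best <- NULL
  best_sep <- NULL
  scores <- stats::setNames(numeric(0), character(0))
  for (a in cand) {
    r <- session_cmi(ss, x, y, c(collected, a))
    raw3 <- base$raw - r$raw
    # significance-penalized three-point contribution: the raw contribution
    # must exceed the complexity increase of the extended conditioning set
    sig3 <- raw3 - (r$kpn - base$kpn)
    rule <- ss$ctl$contributor_rule %||% "closure"
    removes <- r$rect <= 0 && raw3 > 0 && rule == "closure"
    if (!is.null(closure_pool)) removes <- removes && (a %in% closure_pool)
    if (sig3 > 0 || removes) {
      scores[a] <- sig3
      info <- list(variable = a, contribution = sig3,
                   raw_contribution = raw3,
                   rect_drop = base$rect - r$rect,
                   residual = r$rect, raw_residual = r$raw)
      if (removes && (is.null(best_sep) ||
                      sig3 > best_sep$contribution + 1e-15)) {
        best_sep <- info
      }
      if (is.null(best) || sig3 > best$contribution + 1e-15) {
        best <- info
      }
    }
  }
  # a candidate that completes a separating set (zero rectified residual)
  # takes precedence over merely significant partial contributors
  list(pick = if (!is.null(best_sep)) best_sep else best, scores = scores)
}

# rectified regularized information for one pair (unconditional)
pair_info <- function(ss, x, y) session_cmi(ss, x, y, character(0))

#' Learn the undirected skeleton
#'
#' Removes dispensable edges from the complete graph by iterative contributor
#' collection.  Edges are processed in order of confidence: at each step the
#' edge whose residual minus its next contribution is smallest (the most
#' confidently reducible one) collects its top contributor; the edge is
#' removed as soon as its rectified residual reaches zero.  Pairs with zero
#' marginal regularized information are removed first with empty separating
#' sets.
#'
#' @param data a [mindnet_data].
#' @param ctl a [mindnet_control()] list (`max_cond`, `scope`, estimator
#'   settings).
#' @param consistency_filter optional predicate `function(x, y, a)` ruling on
#'   contributor eligibility (used by the consistency iteration).
#' @param session optional estimator session to reuse cached information
#'   values across consistency iterations.
#' @return `list(graph = <mixed_graph>, records = <named list>)`; each record
#'   has fields `pair`, `contributors`, `contributions`, `raw_contributions`,
#'   `residual`, `info_reg` (the pair's marginal rectified information).
#' @export
learn_skeleton <- function(data, ctl = mindnet_control(),
                           consistency_filter = NULL, session = NULL) {
  ss <- if (is.null(session)) new_session(data, ctl) else session
  g <- mixed_graph(data$specs, complete = TRUE)
  nms <- g$nodes$name
  records <- list()

  st <- new.env(parent = emptyenv())
  active <- character(0)
  for (i in seq_len(nrow(g$pairs))) {
    x <- g$pairs$x[i]
    y <- g$pairs$y[i]
    key <- pair_key(x, y)
    r <- pair_info(ss, x, y)
    if (r$rect <= 0) {
      g$pairs$present[i] <- FALSE
      g$pairs$status[i] <- "absent"
      g$pairs$info_reg[i] <- 0
      g$pairs$residual_info[i] <- 0
      records[[key]] <- list(pair = c(x, y), contributors = character(0),
                             contributions = numeric(0),
                             raw_contributions = numeric(0),
                             residual = 0, info_reg = r$rect)
      g$sepsets[[key]] <- records[[key]]
    } else {
      g$pairs$info_reg[i] <- r$rect
      g$pairs$residual_info[i] <- r$rect
      st[[key]] <- list(x = x, y = y, collected = character(0),
                        contributions = numeric(0),
                        raw_contributions = numeric(0),
                        residual = r$rect, raw_residual = r$raw,
                        info_reg = r$rect, top = NULL, scores = NULL,
                        done = FALSE)
      active <- c(active, key)
    }
  }
  active <- sort(active)

  # adjacency lists of the evolving graph (kept in sync on removal)
  adj <- new.env(parent = emptyenv())
  for (v in nms) adj[[v]] <- character(0)
  pres <- g$pairs[g$pairs$present, c("x", "y"), drop = FALSE]
  for (i in seq_len(nrow(pres))) {
    adj[[pres$x[i]]] <- c(adj[[pres$x[i]]], pres$y[i])
    adj[[pres$y[i]]] <- c(adj[[pres$y[i]]], pres$x[i])
  }

  candidate_set <- function(e) {
    nb <- if (ctl$scope == "common") {
      intersect(adj[[e$x]], adj[[e$y]])
    } else {
      union(adj[[e$x]], adj[[e$y]])
    }
    nb <- setdiff(nb, c(e$x, e$y, e$collected))
    if (!is.null(consistency_filter) && length(nb)) {
      nb <- nb[vapply(nb, function(a) isTRUE(consistency_filter(e$x, e$y, a)),
                      logical(1))]
    }
    nb
  }


  repeat {
    # refresh stale top contributors
    for (key in active) {
      e <- st[[key]]
      if (e$done || !is.null(e$scores)) next
      tc <- top_contributor(ss, e$x, e$y, e$collected, candidate_set(e))
      e$top <- tc$pick
      e$scores <- tc$scores
      if (is.null(e$top)) e$done <- TRUE
      st[[key]] <- e
    }
    live <- Filter(function(k) !st[[k]]$done, active)
    if (!length(live)) break
    ranks <- vapply(live, function(k) {
      e <- st[[k]]
      e$residual - e$top$contribution
    }, numeric(1))
    key <- live[[which.min(ranks)]]
    e <- st[[key]]
    a <- e$top$variable
    e$collected <- c(e$collected, a)
    # record the rectified information drop (telescopes exactly from the
    # pair's marginal information down to its residual)
    e$contributions <- c(e$contributions, e$top$rect_drop)
    e$raw_contributions <- c(e$raw_contributions, e$top$raw_contribution)
    e$residual <- e$top$residual
    e$raw_residual <- e$top$raw_residual
    e$top <- NULL
    e$scores <- NULL
    if (e$residual <= 0) {
      e$done <- TRUE
      i <- g_idx(g, e$x, e$y)
      g$pairs$present[i] <- FALSE
      g$pairs$status[i] <- "absent"
      g$pairs$residual_info[i] <- 0
      adj[[e$x]] <- setdiff(adj[[e$x]], e$y)
      adj[[e$y]] <- setdiff(adj[[e$y]], e$x)
      rec <- list(pair = c(e$x, e$y), contributors = e$collected,
                  contributions = e$contributions,
                  raw_contributions = e$raw_contributions,
                  residual = 0, info_reg = e$info_reg)
      records[[key]] <- rec
      g$sepsets[[key]] <- rec
      # neighborhoods of the endpoints shrank: invalidate incident edges
      for (k2 in active) {
        e2 <- st[[k2]]
        if (e2$done || is.null(e2$scores)) next
        if (e2$x %in% c(e$x, e$y) || e2$y %in% c(e$x, e$y)) {
          # candidate pool changed; recompute lazily (estimates are cached)
          e2$top <- NULL
          e2$scores <- NULL
          st[[k2]] <- e2
        }
      }
    } else if (length(e$collected) >= ctl$max_cond) {
      e$done <- TRUE
    }
    st[[key]] <- e
  }

  for (key in active) {
    e <- st[[key]]
    i <- g_idx(g, e$x, e$y)
    if (g$pairs$present[i]) {
      g$pairs$residual_info[i] <- e$residual
      records[[key]] <- list(pair = c(e$x, e$y), contributors = e$collected,
                             contributions = e$contributions,
                             raw_contributions = e$raw_contributions,
                             residual = e$residual, info_reg = e$info_reg)
      g$contributors[[key]] <- records[[key]]
      g$pairs$sign[i] <- edge_sign(data, e$x, e$y)
    }
  }
  list(graph = g, records = records, session = ss)
}
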