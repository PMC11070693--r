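# Step 2/3: orientation of the skeleton.
#
# V-structures are scored from negative conditional three-point information
# via numerically stable orientation scores; induced tail/head orientations
# derive from existing arrowheads through a rectified induced score that can
# never exceed the confidence of its source head.  Marks are applied in
# strictly decreasing score order and never overwritten by a lower score.

sigmoid <- function(s) 1 / (1 + exp(-s))

#' Head probability of a v-structure
#'
#' For an unshielded triple X-Z-Y with negative `N * I'(X;Y;Z|\{Ai\})`, the
#' probability that both edges carry arrowheads into Z is
#' `(1 + exp(n_i3)) / (1 + 3 exp(n_i3))`, which lies in `[0.5, 1)`.
#'
#' @param n_i3 `N` times the conditional three-point information; must be
#'   negative.
#' @return head probability.
#' @export
v_structure_probability <- function(n_i3) {
  if (any(n_i3 >= 0)) stop("n_i3 must be negative (not a v-structure)")
  e <- exp(n_i3)
  (1 + e) / (1 + 3 * e)
}

#' Orientation score of a v-structure
#'
#' The score equivalent of [v_structure_probability()]:
#' `score_v = -n_i3 + log1p(exp(n_i3)) - log(2)`, with
#' `P = 1 / (1 + exp(-score_v))`.  Scores remain finitely ordered where the
#' probabilities saturate at 1 in floating point, which is what makes
#' confidence ranking possible at very large sample sizes.
#'
#' @inheritParams v_structure_probability
#' @return non-negative score.
#' @export
v_structure_score <- function(n_i3) {
  if (any(n_i3 >= 0)) stop("n_i3 must be negative (not a v-structure)")
  pmax(0, -n_i3 + log1p(exp(n_i3)) - log(2))
}

#' Rectified induced orientation score
#'
#' Confidence of a tail (or propagated head) induced by an existing
#' arrowhead of score `score_v`:
#' `score_i = max(0, m - log1p(exp(m - M) + exp(-M)))` with
#' `m = min(n_i3_abs, score_v)`, `M = max(n_i3_abs, score_v)`.  The induced
#' probability `1 / (1 + exp(-score_i))` can never exceed the source head's
#' probability.
#'
#' @param n_i3_abs `N * |I'(X;Y;Z|\{Ai\})|`, non-negative.
#' @param score_v score of the arrowhead the orientation derives from.
#' @return `list(score =, p =)`.
#' @export
induced_score <- function(n_i3_abs, score_v) {
  if (n_i3_abs < 0 || score_v < 0) stop("inputs must be non-negative")
  m <- min(n_i3_abs, score_v)
  M <- max(n_i3_abs, score_v)
  s <- max(0, m - log1p(exp(m - M) + exp(-M)))
  list(score = s, p = sigmoid(s))
}

#' Classify an edge from its endpoint marks
#'
#' @param end_x,end_y lists with elements `p_head` and `p_tail`.
#' @param beta confidence threshold in `[0.5, 1)`.
#' @return `"genuine"` (one significant head, significant tail at the other
#'   end), `"putative"` (significant head only), `"bidirected"` (two
#'   significant heads) or `"undirected"`.
#' @export
classify_edge <- function(end_x, end_y, beta = 0.5) {
  hx <- end_x$p_head > beta
  hy <- end_y$p_head > beta
  if (hx && hy) return("bidirected")
  if (hy) return(if (end_x$p_tail > beta) "genuine" else "putative")
  if (hx) return(if (end_y$p_tail > beta) "genuine" else "putative")
  "undirected"
}

# enumerate unshielded triples (x, z, y): x-z and z-y present, x-y absent,
# x < y; returns data.frame with the conditioning set taken from the removed
# pair's separating set (minus z) and the signed n_i3
unshielded_triples <- function(g, records, ss) {
  n <- ss$data$n_samples
  out <- list()
  for (z in g$nodes$name) {
    nb <- sort(g_neighbors(g, z))
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    for (j in seq_len(ncol(cmb))) {
      x <- cmb[1L, j]
      y <- cmb[2L, j]
      if (g_adjacent(g, x, y)) next
      rec <- records[[pair_key(x, y)]]
      ai <- setdiff(if (is.null(rec)) character(0) else rec$contributors, z)
      a <- session_cmi(ss, x, y, ai)
      b <- session_cmi(ss, x, y, c(ai, z))
      n_i3 <- n * (a$rect - b$rect)
      out[[length(out) + 1L]] <- data.frame(
        x = x, z = z, y = y, n_i3 = n_i3, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(x = character(0), z = character(0), y = character(0),
                      n_i3 = numeric(0), stringsAsFactors = FALSE))
  }
  tr <- do.call(rbind, out)
  tr[order(tr$x, tr$z, tr$y), , drop = FALSE]
}

#' Orient a learned skeleton
#'
#' Scores all unshielded triples, then applies v-structure arrowheads and
#' induced tail/head orientations in strictly decreasing score order; a mark
#' placed with a higher score is never overwritten.  Contextual variables,
#' when enabled, have `p_tail = 1` pinned at all their endpoints and never
#' receive arrowheads.  Finally each edge is classified as genuine,
#' putative, bidirected or undirected at threshold `beta`.
#'
#' @param skeleton a [mixed_graph] from [learn_skeleton()].
#' @param records separating-set records from [learn_skeleton()].
#' @param data the [mindnet_data] the skeleton was learned from.
#' @param ctl a [mindnet_control()] list (`beta`, `propagate`,
#'   `contextual_priors`).
#' @param session optional estimator session to reuse cached values.
#' @return the oriented, classified [mixed_graph]; triple scores are stored
#'   in `$meta$triples`.
#' @export
orient_graph <- function(skeleton, records, data, ctl = mindnet_control(),
                         session = NULL) {
  g <- skeleton
  ss <- if (is.null(session)) new_session(data, ctl) else session
  tr <- unshielded_triples(g, records, ss)
  tr$score_v <- rep(NA_real_, nrow(tr))
  neg <- which(tr$n_i3 < 0)
  if (length(neg)) tr$score_v[neg] <- v_structure_score(tr$n_i3[neg])
  tr$kind <- ifelse(tr$n_i3 < 0, "v_structure", "non_v")

  ctx <- g$nodes$name[g$nodes$is_contextual]
  use_ctx <- isTRUE(ctl$contextual_priors)

  # endpoint state: marks, probabilities and the score that placed them
  ends <- new.env(parent = emptyenv())
  end_key <- function(a, b) paste(a, b, sep = "\r")  # mark at the b end of a-b
  get_end <- function(a, b) {
    e <- ends[[end_key(a, b)]]
    if (is.null(e)) list(mark = "undefined", p_head = 0.5, p_tail = 0.5,
                         score = -Inf) else e
  }
  # returns TRUE if the mark was placed
  place <- function(a, b, mark, score, p) {
    if (use_ctx && mark == "head" && b %in% ctx) return(FALSE)
    cur <- get_end(a, b)
    if (cur$mark != "undefined") return(FALSE)
    e <- list(mark = mark, p_head = if (mark == "head") p else cur$p_head,
              p_tail = if (mark == "tail") p else cur$p_tail, score = score)
    ends[[end_key(a, b)]] <- e
    TRUE
  }

  if (use_ctx) {
    for (cvar in ctx) {
      for (nb in g_neighbors(g, cvar)) {
        ends[[end_key(nb, cvar)]] <- list(mark = "tail", p_head = 0,
                                          p_tail = 1, score = Inf)
      }
    }
  }

  # action queue: data.frame of pending orientations
  queue <- list()
  push <- function(type, a, b, score, p, ord) {
    queue[[length(queue) + 1L]] <<- list(type = type, a = a, b = b,
                                         score = score, p = p, ord = ord)
  }
  if (length(neg)) {
    for (j in neg) {
      ordkey <- paste(tr$x[j], tr$z[j], tr$y[j])
      p <- sigmoid(tr$score_v[j])
      push("head", tr$x[j], tr$z[j], tr$score_v[j], p, ordkey)
      push("head", tr$y[j], tr$z[j], tr$score_v[j], p, ordkey)
    }
  }

  # after a head lands at the z end of edge (w, z), every positive
  # unshielded triple with that arm induces a tail at z on its other arm
  on_head <- function(w, z, src_score) {
    hit <- which(tr$z == z & tr$n_i3 > 0 & (tr$x == w | tr$y == w))
    for (j in hit) {
      v <- if (tr$x[j] == w) tr$y[j] else tr$x[j]
      if (!g_adjacent(g, v, z)) next
      isc <- induced_score(abs(tr$n_i3[j]), src_score)
      push("induced", v, z, isc$score, isc$p,
           paste(tr$x[j], tr$z[j], tr$y[j]))
    }
  }

  repeat {
    if (!length(queue)) break
    scores <- vapply(queue, function(q) q$score, numeric(1))
    ords <- vapply(queue, function(q) q$ord, character(1))
    pick <- order(-scores, ords)[1L]
    q <- queue[[pick]]
    queue[[pick]] <- NULL
    if (q$type == "head") {
      if (place(q$a, q$b, "head", q$score, q$p)) on_head(q$a, q$b, q$score)
    } else {
      # induced tail at the q$b end of edge (q$a, q$b)
      placed_tail <- place(q$a, q$b, "tail", q$score, q$p)
      if (isTRUE(ctl$propagate) && placed_tail) {
        # the tail propagates as a head at the opposite (q$a) end
        if (place(q$b, q$a, "head", q$score, q$p)) {
          on_head(q$b, q$a, q$score)
        }
      }
    }
  }

  # write endpoint state back into the pair table and classify
  for (i in which(g$pairs$present)) {
    x <- g$pairs$x[i]
    y <- g$pairs$y[i]
    ex <- get_end(y, x)  # mark at the x end of edge x-y
    ey <- get_end(x, y)
    g$pairs$mark_x[i] <- ex$mark
    g$pairs$mark_y[i] <- ey$mark
    g$pairs$p_head_x[i] <- ex$p_head
    g$pairs$p_tail_x[i] <- ex$p_tail
    g$pairs$p_head_y[i] <- ey$p_head
    g$pairs$p_tail_y[i] <- ey$p_tail
    g$pairs$status[i] <- classify_edge(ex, ey, ctl$beta)
  }
  g$meta$triples <- tr
  g
}
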