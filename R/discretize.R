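# Optimal-discretization estimation of (conditional) mutual information for
# mixed continuous/categorical variables.
#
# Mutual information involving a continuous variable is defined as the
# supremum, over partitions of that variable, of the regularized mutual
# information between the partitioned variables.  The search is a
# dynamic-programming optimization over candidate cut-points (exact given the
# candidate grid), alternating between the two variables when both are
# continuous.  The partition penalty is an additive MDL scheme: each extra bin
# of a variable costs the corresponding degrees-of-freedom increment
# 0.5 * d(log-likelihood dof) * log(N) plus a cut-point coding cost log(K)
# where K is the number of candidate positions.  Additivity keeps the DP
# exact; the NML penalty (non-additive in the bin count) is reserved for
# all-categorical estimates.

default_n_cand <- function(max_bins) max(64L, 2L * as.integer(max_bins))

new_partition <- function(variable, cutpoints, n_bins) {
  list(variable = variable, cutpoints = cutpoints, n_bins = as.integer(n_bins))
}

# Segment continuous vector xv against opposite factor u (global margins) and
# co-factor cf (within-bin margins).  Returns bin codes (original order),
# cut-point values, n_bins, and the DP value T (total nats, penalties for
# this variable's bins already subtracted).
segment_numeric <- function(xv, u, nu, cf, nc, pen_bin, max_bins, n_cand) {
  n <- length(xv)
  ord <- order(xv)
  xs <- xv[ord]
  # candidate boundaries between distinct adjacent values
  distinct <- which(diff(xs) > 0)
  if (length(distinct) == 0L) {
    return(list(codes = rep(1L, n), cutpoints = numeric(0), n_bins = 1L,
                value = 0, K = 1L))
  }
  if (length(distinct) > n_cand) {
    pick <- unique(round(seq(1L, length(distinct), length.out = n_cand)))
    distinct <- distinct[pick]
  }
  K <- length(distinct)
  res <- dp_segment_cpp(u[ord] - 1L, cf[ord] - 1L, nu, nc,
                        as.integer(distinct),
                        pen_bin + log(K), as.integer(max_bins))
  ci <- res$cut_idx
  cutpoints <- if (length(ci)) (xs[ci] + xs[ci + 1L]) / 2 else numeric(0)
  codes <- findInterval(xv, cutpoints) + 1L
  list(codes = codes, cutpoints = cutpoints, n_bins = res$n_bins,
       value = res$value, K = K)
}

equal_freq_codes <- function(xv, nbins) {
  qs <- unique(stats::quantile(xv, probs = seq_len(nbins - 1L) / nbins,
                               type = 1, names = FALSE))
  codes <- findInterval(xv, qs, left.open = TRUE) + 1L
  as.integer(factor(codes))
}

# Merge conditioning columns (list of vectors + vtypes) into one integer
# factor.  Continuous conditioning variables are discretized into
# equal-frequency bins; bin counts shrink with the number of continuous
# conditioners so strata stay populated.
build_cond_factor <- function(cols, vtypes) {
  if (length(cols) == 0L) return(list(codes = NULL, nc = 1L))
  n <- length(cols[[1L]])
  ncont <- sum(vtypes == "continuous")
  bcont <- if (ncont > 0L) {
    max(2L, min(5L, floor((n / 25) ^ (1 / ncont))))
  } else 0L
  codes <- rep(1L, n)
  card <- 1L
  for (i in seq_along(cols)) {
    ci <- if (vtypes[i] == "continuous") {
      equal_freq_codes(cols[[i]], bcont)
    } else {
      as.integer(factor(cols[[i]]))
    }
    k <- max(ci)
    codes <- (codes - 1L) * k + ci
    card <- card * k
  }
  codes <- as.integer(factor(codes))  # drop empty combinations
  list(codes = codes, nc = max(codes))
}

# Regularized information I'(X ; {Y, C}) where C is an integer co-factor
# (possibly NULL) merged onto the Y side.  x/y are given as value vectors
# plus types; y may be NULL (information between X and the bare factor C).
joint_reg_info <- function(xv, xtype, yv, ytype, ccodes, nc,
                           max_bins = 50L, mode = "nml",
                           n_cand = default_n_cand(max_bins)) {
  n <- length(xv)
  logN <- log(n)
  if (is.null(ccodes)) {
    ccodes <- rep(1L, n)
    nc <- 1L
  }
  if (is.null(yv)) {
    # I'(X ; C)
    if (xtype == "categorical") {
      cx <- as.integer(factor(xv))
      rx <- max(cx)
      tab <- matrix(cross_tab_cpp(cx - 1L, ccodes - 1L, rx, nc), rx, nc)
      raw <- mi_from_counts(tab)
      k <- complexity_term_fast(rx, nc, 1L, n, mode)
      return(info_result(raw, raw - k / n))
    }
    seg <- segment_numeric(xv, ccodes, nc, rep(1L, n), 1L,
                           pen_bin = 0.5 * (nc - 1) * logN,
                           max_bins, n_cand)
    raw_T <- n_times_i(seg$codes, seg$n_bins, ccodes, nc)
    reg <- seg$value / n
    prt <- list(x = new_partition("x", seg$cutpoints, seg$n_bins))
    return(info_result(raw_T / n, reg, prt))
  }

  if (xtype == "categorical" && ytype == "categorical") {
    cx <- as.integer(factor(xv))
    cy <- as.integer(factor(yv))
    cyc <- merge_codes(cy, ccodes)
    rx <- max(cx)
    ryc <- max(cyc)
    tab <- matrix(cross_tab_cpp(cx - 1L, cyc - 1L, rx, ryc), rx, ryc)
    raw <- mi_from_counts(tab)
    out <- info_result(raw, raw - complexity_term_fast(rx, ryc, 1L, n, mode) / n)
    out$codes_x <- cx
    out$card_x <- rx
    out$K_x <- 1L
    out$codes_y <- cy
    out$card_y <- max(cy)
    out$K_y <- 1L
    return(out)
  }

  if (xtype == "continuous" && ytype == "categorical") {
    cy <- as.integer(factor(yv))
    cyc <- merge_codes(cy, ccodes)
    nf <- max(cyc)
    seg <- segment_numeric(xv, cyc, nf, rep(1L, n), 1L,
                           pen_bin = 0.5 * (nf - 1) * logN,
                           max_bins, n_cand)
    raw_T <- n_times_i(seg$codes, seg$n_bins, cyc, nf)
    prt <- list(x = new_partition("x", seg$cutpoints, seg$n_bins))
    out <- info_result(raw_T / n, seg$value / n, prt)
    out$codes_x <- seg$codes
    out$card_x <- seg$n_bins
    out$K_x <- seg$K
    out$codes_y <- cy
    out$card_y <- max(cy)
    out$K_y <- 1L
    return(out)
  }

  if (xtype == "categorical" && ytype == "continuous") {
    cx <- as.integer(factor(xv))
    rx <- max(cx)
    seg <- segment_numeric(yv, cx, rx, ccodes, nc,
                           pen_bin = 0.5 * (rx - 1) * nc * logN,
                           max_bins, n_cand)
    cyc <- merge_codes(seg$codes, ccodes)
    raw_T <- n_times_i(cx, rx, cyc, max(cyc))
    # constant baseline complexity of the X-vs-strata table
    const <- 0.5 * (rx - 1) * (nc - 1) * logN
    reg <- (seg$value - const) / n
    prt <- list(y = new_partition("y", seg$cutpoints, seg$n_bins))
    out <- info_result(raw_T / n, reg, prt)
    out$codes_x <- cx
    out$card_x <- rx
    out$K_x <- 1L
    out$codes_y <- seg$codes
    out$card_y <- seg$n_bins
    out$K_y <- seg$K
    return(out)
  }

  # both continuous: alternating optimization; started from a coarse
  # equal-frequency grid and (for unconditional pairs) also from the finest
  # allowed grid, keeping the run with the better final objective -- the
  # fine start lets near-deterministic pairs reach high-resolution optima
  # the coarse start cannot grow into
  run_alternation <- function(b0) {
    ycodes <- equal_freq_codes(yv, b0)
    best <- -Inf
    out <- NULL
    for (round in seq_len(20L)) {
      fy <- merge_codes(ycodes, ccodes)
      nf <- max(fy)
      segx <- segment_numeric(xv, fy, nf, rep(1L, n), 1L,
                              pen_bin = 0.5 * (nf - 1) * logN,
                              max_bins, n_cand)
      rx <- segx$n_bins
      segy <- segment_numeric(yv, segx$codes, rx, ccodes, nc,
                              pen_bin = 0.5 * (rx - 1) * nc * logN,
                              max_bins, n_cand)
      ycodes <- segy$codes
      obj <- full_objective(segx$codes, rx, segx$K, segy$codes, segy$n_bins,
                            segy$K, ccodes, nc, n, logN)
      if (obj <= best + 1e-9) break
      best <- obj
      out <- list(xcodes = segx$codes, xcuts = segx$cutpoints, rx = rx,
                  Kx = segx$K, ycodes = segy$codes, ycuts = segy$cutpoints,
                  ry = segy$n_bins, Ky = segy$K)
    }
    list(best = best, out = out)
  }
  inits <- min(max_bins, max(2L, floor(n ^ (1 / 3))))
  if (is.null(ccodes) || nc == 1L) inits <- unique(c(inits, max_bins))
  best <- -Inf
  out <- NULL
  for (b0 in inits) {
    r0 <- run_alternation(b0)
    if (r0$best > best + 1e-9) {
      best <- r0$best
      out <- r0$out
    }
  }
  if (is.null(out) || best <= 0) {
    prt <- list(x = new_partition("x", numeric(0), 1L),
                y = new_partition("y", numeric(0), 1L))
    res <- info_result(0, min(best, 0), prt)
    res$codes_x <- rep(1L, n)
    res$card_x <- 1L
    res$K_x <- 1L
    res$codes_y <- rep(1L, n)
    res$card_y <- 1L
    res$K_y <- 1L
    return(res)
  }
  fy <- merge_codes(out$ycodes, ccodes)
  raw_T <- n_times_i(out$xcodes, out$rx, fy, max(fy))
  prt <- list(x = new_partition("x", out$xcuts, out$rx),
              y = new_partition("y", out$ycuts, out$ry))
  res <- info_result(raw_T / n, best / n, prt)
  res$codes_x <- out$xcodes
  res$card_x <- out$rx
  res$K_x <- out$Kx
  res$codes_y <- out$ycodes
  res$card_y <- out$ry
  res$K_y <- out$Ky
  res
}

merge_codes <- function(a, b) {
  if (is.null(b)) return(a)
  as.integer(factor((a - 1L) * max(b) + b))
}

n_times_i <- function(a, na, b, nb) {
  tab <- matrix(cross_tab_cpp(a - 1L, b - 1L, na, nb), na, nb)
  length(a) * mi_from_counts(tab)
}

# full joint objective N*I' for the continuous-continuous case
full_objective <- function(xc, rx, Kx, yc, ry, Ky, ccodes, nc, n, logN) {
  fy <- merge_codes(yc, ccodes)
  raw_T <- n_times_i(xc, rx, fy, max(fy))
  raw_T - 0.5 * (rx - 1) * (ry * nc - 1) * logN -
    (rx - 1) * log(max(Kx, 1)) - (ry - 1) * log(max(Ky, 1))
}

#' Optimal-discretization mutual information
#'
#' Regularized mutual information between two variables, at least one of
#' which is continuous, obtained by maximizing the penalized plug-in mutual
#' information over partitions of the continuous variable(s).  The estimate
#' vanishes exactly (with single-bin partitions) when no partition achieves a
#' positive regularized value, providing a built-in independence test.
#'
#' @param x,y numeric vectors, or factors/character for a categorical side;
#'   complete cases, equal length, at least 3 rows.
#' @param max_bins cap on the number of bins per variable (default 50).
#' @param mode complexity mode for categorical sides, `"nml"` or `"bic"`.
#' @return an `info_result` with fields `raw_info`, `complexity`, `reg_info`,
#'   `reg_info_rect` (in nats per sample) and `partitions`.
#' @export
optimal_discretization_mi <- function(x, y, max_bins = 50L, mode = "nml") {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("fewer than 3 complete rows")
  xt <- if (is.numeric(x)) "continuous" else "categorical"
  yt <- if (is.numeric(y)) "continuous" else "categorical"
  if (xt == "categorical" && yt == "categorical") {
    stop("at least one of x, y must be continuous; use discrete_mi()")
  }
  a <- joint_reg_info(x, xt, y, yt, NULL, 1L, max_bins = max_bins, mode = mode)
  res <- stratified_reg_info(a, list(codes = NULL, nc = 1L), length(x), mode)
  info_result(res$raw, res$reg, a$partitions)
}

#' Regularized conditional mutual information
#'
#' Computes the rectified regularized conditional mutual information
#' I'(X;Y|cond) from a data table.  All-categorical tuples are computed
#' directly from stratified contingency tables; tuples involving continuous
#' variables use the difference of optimal joint-variable information terms
#' I'(X;\{Y,U\}) - I'(X;U), with the conditioning variables merged into a
#' joint factor.  Complete cases over exactly the involved variables are
#' used.
#'
#' @param x,y variable names.
#' @param cond character vector of conditioning variable names (may be empty).
#' @param data a [mindnet_data] table.
#' @param max_bins,mode see [optimal_discretization_mi()].
#' @return an `info_result`; `reg_info_rect` is the rectified estimate.
#' @export
conditional_mi_reg <- function(x, y, cond = character(0), data,
                               max_bins = 50L, mode = "nml",
                               n_cand = default_n_cand(max_bins)) {
  vars <- c(x, y, cond)
  sub <- complete_rows(data, vars)
  n <- nrow(sub)
  if (n == 0L) stop("empty complete-case intersection for ",
                    paste(vars, collapse = ", "))
  types <- vtype_of(data, vars)
  xt <- types[[x]]
  yt <- types[[y]]

  if (all(unlist(types) == "categorical")) {
    cx <- as.integer(factor(sub[[x]]))
    cy <- as.integer(factor(sub[[y]]))
    rx <- max(cx)
    ry <- max(cy)
    if (length(cond)) {
      cf <- build_cond_factor(sub[cond], unlist(types[cond]))
      res <- stratified_cat_cmi(cx, rx, cy, ry, cf$codes, cf$nc, n, mode)
      return(info_result(res$raw, res$raw - res$k / n))
    }
    tab <- matrix(cross_tab_cpp(cx - 1L, cy - 1L, rx, ry), rx, ry)
    raw <- mi_from_counts(tab)
    k <- complexity_term_fast(rx, ry, 1L, n, mode)
    return(info_result(raw, raw - k / n))
  }

  # mixed/continuous tuples: optimize the continuous partitions by the
  # supremum search (conditioning merged into a joint factor on the inner
  # side), then treat the discretized variables exactly like categorical
  # ones -- stratified plug-in CMI with the per-stratum complexity penalty
  # plus the cut-point coding costs.  The outer variable is the
  # lexicographically smaller name for determinism.
  if (x <= y) {
    ov <- x; ot <- xt; iv <- y; it <- yt
  } else {
    ov <- y; ot <- yt; iv <- x; it <- xt
  }
  cf <- if (length(cond)) {
    build_cond_factor(sub[cond], unlist(types[cond]))
  } else list(codes = NULL, nc = 1L)
  a <- joint_reg_info(sub[[ov]], ot, sub[[iv]], it, cf$codes, cf$nc,
                      max_bins = max_bins, mode = mode, n_cand = n_cand)
  res <- stratified_reg_info(a, cf, n, mode)
  info_result(res$raw, res$reg, a$partitions)
}

# stratified regularized CMI from selected codes (shared reporting for the
# general and fast paths)
stratified_reg_info <- function(a, cf, n, mode) {
  if (a$card_x == 1L || a$card_y == 1L) {
    # single-bin partition: information and penalty vanish exactly
    return(list(raw = 0, reg = 0))
  }
  sc <- if (is.null(cf$codes)) rep(1L, n) else cf$codes
  S <- if (is.null(cf$codes)) 1L else max(sc)
  sm <- strat_mi_cpp(a$codes_x, a$codes_y, sc, a$card_x, a$card_y, S)
  njs <- sm$n_s[sm$n_s > 0]
  k <- complexity_term_fast(a$card_x, a$card_y, length(njs),
                       if (mode == "nml") njs else n, mode)
  coding <- (a$card_x - 1) * log(max(a$K_x, 1)) +
    (a$card_y - 1) * log(max(a$K_y, 1))
  list(raw = sm$raw, reg = sm$raw - (k + coding) / n)
}

# vectorized stratified categorical CMI: raw (nats/sample) and penalty k
# (total nats) over the observed conditioning strata
stratified_cat_cmi <- function(cx, rx, cy, ry, scodes, S, n, mode) {
  idx <- ((scodes - 1L) * ry + (cy - 1L)) * rx + cx
  nxyz <- array(tabulate(idx, rx * ry * S), c(rx, ry, S))
  n_s <- colSums(colSums(nxyz))          # per-stratum totals, length S
  n_xs <- apply(nxyz, c(1L, 3L), sum)    # rx x S
  n_ys <- apply(nxyz, c(2L, 3L), sum)    # ry x S
  pos <- which(nxyz > 0)
  ai <- (pos - 1L) %% rx + 1L
  aj <- ((pos - 1L) %/% rx) %% ry + 1L
  as_ <- (pos - 1L) %/% (rx * ry) + 1L
  v <- nxyz[pos]
  raw <- sum(v / n * (log(v) + log(n_s[as_]) -
                      log(n_xs[cbind(ai, as_)]) - log(n_ys[cbind(aj, as_)])))
  k <- complexity_term_fast(rx, ry, S, if (mode == "nml") n_s else n, mode)
  list(raw = raw, k = k)
}

#' Conditional three-point information
#'
#' Difference of two rectified regularized conditional mutual information
#' terms, I'(X;Y|cond) - I'(X;Y|cond,Z), in nats per sample.  Negative values
#' are the signature of a v-structure X -> Z <- Y; positive values indicate a
#' non-collider.  When both terms are rectified to zero the result is exactly
#' zero, which prevents the orientation of inconsistent v-structures.
#'
#' @inheritParams conditional_mi_reg
#' @param z middle variable name; must not be in `cond`.
#' @return a signed scalar (nats per sample).
#' @export
three_point_info <- function(x, y, z, cond = character(0), data,
                             max_bins = 50L, mode = "nml",
                             n_cand = default_n_cand(max_bins)) {
  if (z %in% cond) stop("z must not be in cond")
  a <- conditional_mi_reg(x, y, cond, data, max_bins, mode, n_cand)
  b <- conditional_mi_reg(x, y, c(cond, z), data, max_bins, mode, n_cand)
  a$reg_info_rect - b$reg_info_rect
}
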