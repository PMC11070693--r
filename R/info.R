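#' Plug-in mutual information between two categorical samples
#'
#' Computes the maximum-likelihood ("plug-in") estimate of the mutual
#' information from the joint contingency table of two equal-length,
#' complete-case categorical samples, in nats.
#'
#' @param x,y vectors coercible to factors, same length, no missing values.
#' @return Mutual information in nats (per sample), a non-negative scalar.
#' @examples
#' discrete_mi(c("a", "a", "b", "b"), c("u", "u", "v", "v"))  # log(2)
#' @export
discrete_mi <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) == 0L) stop("zero usable rows")
  cx <- as.integer(factor(x))
  cy <- as.integer(factor(y))
  nx <- max(cx)
  ny <- max(cy)
  tab <- cross_tab_cpp(cx - 1L, cy - 1L, nx, ny)
  mi_from_counts(matrix(tab, nx, ny))
}

# MI in nats from a joint count matrix
mi_from_counts <- function(tab) {
  n <- sum(tab)
  if (n <= 0) stop("zero usable rows")
  if (nrow(tab) == 1L || ncol(tab) == 1L) return(0)
  rm <- rowSums(tab)
  cm <- colSums(tab)
  idx <- which(tab > 0)
  if (length(idx) == 0L) return(0)
  i <- (idx - 1L) %% nrow(tab) + 1L
  j <- (idx - 1L) %/% nrow(tab) + 1L
  v <- tab[idx]
  sum(v / n * (log(v) + log(n) - log(rm[i]) - log(cm[j])))
}

#' Rectify a regularized information value
#'
#' Negative regularized (conditional) mutual information signals
#' (conditional) independence; the supremum over partitions always admits the
#' single-bin partition with exactly zero regularized information, so any
#' negative value is replaced by 0.
#'
#' @param v numeric vector.
#' @return `pmax(0, v)`.
#' @export
rectify <- function(v) pmax(0, v)

# memoized log parametric complexity
.complexity_cache <- new.env(parent = emptyenv())

log_param_complexity <- function(L, n) {
  L <- as.integer(L)
  n <- as.integer(n)
  if (L <= 1L || n <= 0L) return(0)
  Ls <- as.character(L)
  v <- .complexity_cache[[Ls]]
  if (!is.null(v) && length(v) >= n && !is.na(v[n])) return(v[n])
  if (is.null(v) || length(v) < n) {
    v2 <- rep(NA_real_, max(n, 2L * length(v), 1024L))
    if (!is.null(v)) v2[seq_along(v)] <- v
    v <- v2
  }
  v[n] <- log_param_complexity_cpp(L, n)
  assign(Ls, v, envir = .complexity_cache)
  v[n]
}

#' Complexity penalty for a (conditional) mutual information test
#'
#' Returns the sample-size dependent complexity term `k(N)` (total nats, not
#' per sample) that regularizes the decision between dependence and
#' (conditional) independence of a pair of categorical variables.
#'
#' Two penalties are provided. `"bic"` is the classical degrees-of-freedom
#' penalty `0.5 * (card_x - 1) * (card_y - 1) * card_cond * log(n)`. `"nml"`
#' (the default) is a normalized-maximum-likelihood penalty: per conditioning
#' stratum, the difference between the log parametric complexity of the joint
#' `card_x * card_y` multinomial and those of the two marginal multinomials,
#' summed over strata. `n` may be a vector of per-stratum sample counts
#' (length `card_cond`); a scalar total is split evenly across strata.
#'
#' @param card_x,card_y level counts of the two tested variables (>= 1).
#' @param card_cond number of conditioning strata (1 = unconditional).
#' @param n total sample count, or vector of per-stratum counts.
#' @param mode `"nml"` or `"bic"`.
#' @return penalty in nats, >= 0.
#' @export
complexity_term <- function(card_x, card_y, card_cond = 1L, n,
                            mode = c("nml", "bic")) {
  mode <- match.arg(mode)
  stopifnot(card_x >= 1, card_y >= 1, card_cond >= 1, all(n >= 0))
  complexity_term_fast(card_x, card_y, card_cond, n, mode)
}

complexity_term_fast <- function(card_x, card_y, card_cond, n, mode) {
  if (card_x == 1L || card_y == 1L) return(0)
  if (mode == "bic") {
    ntot <- if (length(n) > 1L) sum(n) else n
    if (ntot < 1) return(0)
    return(0.5 * (card_x - 1) * (card_y - 1) * card_cond * log(ntot))
  }
  ns <- if (length(n) == 1L && card_cond > 1L) {
    rep(floor(n / card_cond), card_cond) +
      c(rep(1L, n %% card_cond), rep(0L, card_cond - n %% card_cond))
  } else n
  ns <- ns[ns > 0]
  if (!length(ns)) return(0)
  k <- 0
  for (nj in ns) {
    k <- k + log_param_complexity(card_x * card_y, nj) -
      log_param_complexity(card_x, nj) -
      log_param_complexity(card_y, nj)
  }
  max(0, k)
}

# construct an InfoResult
info_result <- function(raw, reg, partitions = list()) {
  structure(
    list(raw_info = raw, complexity = raw - reg, reg_info = reg,
         reg_info_rect = max(0, reg), partitions = partitions),
    class = "info_result"
  )
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("raw I = %.4f  k/N = %.4f  I' = %.4f  rect = %.4f nats\n",
              x$raw_info, x$complexity, x$reg_info, x$reg_info_rect))
  for (nm in names(x$partitions)) {
    p <- x$partitions[[nm]]
    cat(sprintf("  %s: %d bin(s)\n", nm, p$n_bins))
  }
  invisible(x)
}
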