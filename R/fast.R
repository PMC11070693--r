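# Fast estimation path for complete-case tables.
#
# Structure learning evaluates tens of thousands of conditional-information
# terms on the same columns; when the table has no missing values the
# per-call work of subsetting, factor coercion and sorting can all be hoisted
# into one per-variable preparation step.  This path computes exactly the
# same estimates as conditional_mi_reg() (guarded by tests); only the
# mechanics differ.

prep_fast <- function(ss) {
  if (!is.null(ss$fast_ready)) return()
  data <- ss$data
  ss$has_na <- anyNA(data$df)
  ss$fast_ready <- TRUE
  if (ss$has_na) return()
  n <- data$n_samples
  ss$n <- n
  vinfo <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(data$specs))) {
    nm <- data$specs$name[i]
    tp <- data$specs$vtype[i]
    col <- data$df[[nm]]
    v <- list(type = tp)
    if (tp == "categorical") {
      v$codes <- as.integer(factor(col))
      v$card <- max(v$codes)
    } else {
      v$values <- col
      v$ord <- order(col)
      xs <- col[v$ord]
      v$distinct <- which(diff(xs) > 0)
      v$xs <- xs
      # pre-binned versions used when the variable conditions others
      v$eqf <- lapply(2:5, function(b) equal_freq_codes(col, b))
      names(v$eqf) <- as.character(2:5)
    }
    assign(nm, v, envir = vinfo)
  }
  ss$vinfo <- vinfo
  ss$cand_cache <- new.env(parent = emptyenv())
  ss$eqf_cache <- new.env(parent = emptyenv())
  ss$pair_codes <- new.env(parent = emptyenv())
  ss$cf_cache <- new.env(parent = emptyenv())
}

fast_cand <- function(ss, vname, n_cand) {
  key <- paste0(vname, ".", n_cand)
  got <- ss$cand_cache[[key]]
  if (!is.null(got)) return(got)
  distinct <- ss$vinfo[[vname]]$distinct
  if (length(distinct) > n_cand) {
    pick <- unique(round(seq(1L, length(distinct), length.out = n_cand)))
    distinct <- distinct[pick]
  }
  assign(key, distinct, envir = ss$cand_cache)
  distinct
}

# combine integer code vectors into one compact factor
combine_codes <- function(a, ka, b, kb) {
  f <- (a - 1L) * kb + b
  tab <- tabulate(f, ka * kb)
  keep <- which(tab > 0L)
  map <- integer(ka * kb)
  map[keep] <- seq_along(keep)
  list(codes = map[f], card = length(keep))
}

fast_cond_factor <- function(ss, cond) {
  if (!length(cond)) return(list(codes = NULL, card = 1L))
  ckey <- paste(sort(cond), collapse = "\r")
  got <- ss$cf_cache[[ckey]]
  if (!is.null(got)) return(got)
  vinfo <- ss$vinfo
  types <- vapply(cond, function(v) vinfo[[v]]$type, character(1))
  ncont <- sum(types == "continuous")
  bcont <- if (ncont > 0L) {
    max(2L, min(5L, floor((ss$n / 25) ^ (1 / ncont))))
  } else 0L
  codes <- NULL
  card <- 1L
  for (v in cond) {
    vi <- vinfo[[v]]
    if (vi$type == "continuous") {
      ci <- vi$eqf[[as.character(bcont)]]
      k <- max(ci)
    } else {
      ci <- vi$codes
      k <- vi$card
    }
    if (is.null(codes)) {
      codes <- ci
      card <- k
    } else {
      cc <- combine_codes(codes, card, ci, k)
      codes <- cc$codes
      card <- cc$card
    }
  }
  out <- list(codes = codes, card = card)
  assign(ckey, out, envir = ss$cf_cache)
  out
}

# DP segmentation of a prepared continuous variable against factor u
# (global margins) with co-factor cf (within-bin margins)
fast_segment <- function(ss, vname, u, nu, cf, nc, pen_bin, max_bins, n_cand) {
  n <- ss$n
  vi <- ss$vinfo[[vname]]
  cand <- fast_cand(ss, vname, n_cand)
  if (!length(cand)) {
    return(list(codes = rep(1L, n), n_bins = 1L, value = 0, K = 1L))
  }
  K <- length(cand)
  ord <- vi$ord
  if (is.null(cf)) cf <- rep(1L, n)
  res <- dp_segment_cpp(u[ord] - 1L, cf[ord] - 1L, nu, nc,
                        as.integer(cand), pen_bin + log(K),
                        as.integer(max_bins))
  cuts <- res$cut_idx
  codes_sorted <- findInterval(seq_len(n) - 1L, cuts) + 1L
  codes <- integer(n)
  codes[ord] <- codes_sorted
  list(codes = codes, n_bins = res$n_bins, value = res$value, K = K)
}

# partition selection for I'(outer ; {inner, C}) on the fast path; returns
# the selected codes for both sides plus candidate-grid sizes
fast_joint <- function(ss, ov, iv, cf, max_bins, mode, n_cand) {
  n <- ss$n
  logN <- log(n)
  vinfo <- ss$vinfo
  ccodes <- cf$codes
  nc <- cf$card
  vo <- vinfo[[ov]]
  vi <- vinfo[[iv]]

  if (vo$type == "categorical" && vi$type == "categorical") {
    return(list(codes_x = vo$codes, card_x = vo$card, K_x = 1L,
                codes_y = vi$codes, card_y = vi$card, K_y = 1L))
  }

  if (vo$type == "continuous" && vi$type == "categorical") {
    yc <- if (is.null(ccodes)) list(codes = vi$codes, card = vi$card) else
      combine_codes(vi$codes, vi$card, ccodes, nc)
    seg <- fast_segment(ss, ov, yc$codes, yc$card, NULL, 1L,
                        pen_bin = 0.5 * (yc$card - 1) * logN, max_bins, n_cand)
    return(list(codes_x = seg$codes, card_x = seg$n_bins, K_x = seg$K,
                codes_y = vi$codes, card_y = vi$card, K_y = 1L))
  }

  if (vo$type == "categorical" && vi$type == "continuous") {
    seg <- fast_segment(ss, iv, vo$codes, vo$card, ccodes, nc,
                        pen_bin = 0.5 * (vo$card - 1) * nc * logN,
                        max_bins, n_cand)
    return(list(codes_x = vo$codes, card_x = vo$card, K_x = 1L,
                codes_y = seg$codes, card_y = seg$n_bins, K_y = seg$K))
  }

  # both continuous
  run_alt <- function(b0) {
    key <- paste0(iv, ".eqf.", b0)
    ycodes <- ss$eqf_cache[[key]]
    if (is.null(ycodes)) {
      ycodes <- equal_freq_codes(vi$values, b0)
      assign(key, ycodes, envir = ss$eqf_cache)
    }
    best <- -Inf
    out <- NULL
    for (round in seq_len(20L)) {
      fy <- if (is.null(ccodes)) list(codes = ycodes, card = max(ycodes)) else
        combine_codes(ycodes, max(ycodes), ccodes, nc)
      segx <- fast_segment(ss, ov, fy$codes, fy$card, NULL, 1L,
                           pen_bin = 0.5 * (fy$card - 1) * logN,
                           max_bins, n_cand)
      rx <- segx$n_bins
      segy <- fast_segment(ss, iv, segx$codes, rx, ccodes, nc,
                           pen_bin = 0.5 * (rx - 1) * nc * logN,
                           max_bins, n_cand)
      ycodes <- segy$codes
      obj <- fast_objective(segx$codes, rx, segx$K, segy$codes, segy$n_bins,
                            segy$K, ccodes, nc, n, logN)
      if (obj <= best + 1e-9) break
      best <- obj
      out <- list(xcodes = segx$codes, rx = rx, Kx = segx$K,
                  ycodes = segy$codes, ry = segy$n_bins, Ky = segy$K)
    }
    list(best = best, out = out)
  }
  inits <- min(max_bins, max(2L, floor(n ^ (1 / 3))))
  if (nc == 1L) inits <- unique(c(inits, max_bins))
  best <- -Inf
  out <- NULL
  for (b0 in inits) {
    r0 <- run_alt(b0)
    if (r0$best > best + 1e-9) {
      best <- r0$best
      out <- r0$out
    }
  }
  if (is.null(out) || best <= 0) {
    ones <- rep(1L, n)
    return(list(codes_x = ones, card_x = 1L, K_x = 1L,
                codes_y = ones, card_y = 1L, K_y = 1L))
  }
  list(codes_x = out$xcodes, card_x = out$rx, K_x = out$Kx,
       codes_y = out$ycodes, card_y = out$ry, K_y = out$Ky)
}

fast_objective <- function(xc, rx, Kx, yc, ry, Ky, ccodes, nc, n, logN) {
  fy <- if (is.null(ccodes)) list(codes = yc, card = max(yc)) else
    combine_codes(yc, max(yc), ccodes, nc)
  raw_T <- n_times_i(xc, rx, fy$codes, fy$card)
  raw_T - 0.5 * (rx - 1) * (ry * nc - 1) * logN -
    (rx - 1) * log(max(Kx, 1)) - (ry - 1) * log(max(Ky, 1))
}

# fast-path CMI; mirrors conditional_mi_reg() exactly for complete data
# when policy = "optimize".  Under the default session policy, a pair whose
# marginal supremum fixed a non-trivial partition keeps those codes for all
# of its conditional tests (the discretized pair is then treated exactly
# like a categorical one, keeping Eq-style telescoping on one partition);
# re-optimization under conditioning is used only for pairs whose marginal
# estimate vanished, as needed by the orientation terms.
cmi_fast <- function(ss, x, y, cond, policy = "pair_codes") {
  vinfo <- ss$vinfo
  n <- ss$n
  mode <- ss$ctl$mode
  max_bins <- ss$ctl$max_bins
  n_cand <- if (length(cond)) ss$ctl$n_cand_cond else ss$ctl$n_cand
  types <- vapply(c(x, y, cond), function(v) vinfo[[v]]$type, character(1))

  if (all(types == "categorical")) {
    vx <- vinfo[[x]]
    vy <- vinfo[[y]]
    if (length(cond)) {
      cf <- fast_cond_factor(ss, cond)
      sm <- strat_mi_cpp(vx$codes, vy$codes, cf$codes, vx$card, vy$card,
                         cf$card)
      njs <- sm$n_s[sm$n_s > 0]
      k <- complexity_term_fast(vx$card, vy$card, length(njs),
                           if (mode == "nml") njs else n, mode)
      raw <- sm$raw
    } else {
      tab <- matrix(cross_tab_cpp(vx$codes - 1L, vy$codes - 1L,
                                  vx$card, vy$card), vx$card, vy$card)
      raw <- mi_from_counts(tab)
      k <- complexity_term_fast(vx$card, vy$card, 1L, n, mode)
    }
    reg <- raw - k / n
    return(list(raw = raw, reg = reg, rect = max(0, reg), kpn = raw - reg))
  }

  if (x <= y) { ov <- x; iv <- y } else { ov <- y; iv <- x }
  cf <- fast_cond_factor(ss, cond)
  pkey <- paste(ov, iv, sep = "\r")
  a <- NULL
  if (length(cond) && policy == "pair_codes") {
    pc <- ss$pair_codes[[pkey]]
    if (is.null(pc)) {
      # ensure the marginal estimate (and its codes) exists
      session_cmi(ss, ov, iv, character(0))
      pc <- ss$pair_codes[[pkey]]
    }
    if (!is.null(pc) && pc$card_x > 1L && pc$card_y > 1L) a <- pc
  }
  if (is.null(a)) {
    a <- fast_joint(ss, ov, iv, cf, max_bins, mode, n_cand)
    if (!length(cond)) assign(pkey, a, envir = ss$pair_codes)
  }
  res <- stratified_reg_info(a, list(codes = cf$codes), n, mode)
  list(raw = res$raw, reg = res$reg, rect = max(0, res$reg),
       kpn = res$raw - res$reg)
}
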