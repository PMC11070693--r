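# Indirect information contributions: the fraction of a pair's regularized
# mutual information explained by each collected contributor, in collection
# order.  The rectified telescoping identity guarantees that, per pair, the
# contribution fractions sum to one minus the residual fraction.

#' Indirect contributions for one pair
#'
#' `IndC(Ak) = I'(X;Y;Ak|{Ai}_{k-1}) / I'(X;Y)` for each contributor in the
#' order it was collected, together with the pair's residual fraction
#' `I'(X;Y|{Ai}_n) / I'(X;Y)` (zero for removed edges).
#'
#' @param record a separating-set record from [learn_skeleton()].
#' @return data.frame with columns `x`, `y`, `contributor`, `rank`, `ind_c`,
#'   `residual_fraction`, `independent`.  Marginally independent pairs yield
#'   a single flagged row with no contributions.
#' @export
indirect_contributions <- function(record) {
  x <- record$pair[1L]
  y <- record$pair[2L]
  if (record$info_reg <= 0) {
    return(data.frame(x = x, y = y, contributor = NA_character_,
                      rank = NA_integer_, ind_c = NA_real_,
                      residual_fraction = NA_real_, independent = TRUE,
                      stringsAsFactors = FALSE))
  }
  k <- length(record$contributors)
  resid <- record$residual / record$info_reg
  if (k == 0L) {
    return(data.frame(x = x, y = y, contributor = NA_character_,
                      rank = NA_integer_, ind_c = NA_real_,
                      residual_fraction = resid, independent = FALSE,
                      stringsAsFactors = FALSE))
  }
  data.frame(x = x, y = y, contributor = record$contributors,
             rank = seq_len(k), ind_c = record$contributions / record$info_reg,
             residual_fraction = resid, independent = FALSE,
             stringsAsFactors = FALSE)
}

#' Indirect contributions for every non-independent pair
#'
#' @param records the record list returned by [learn_skeleton()] (covering
#'   removed pairs and retained pairs with collected contributors).
#' @return row-bound contribution table, ordered by pair.
#' @export
indirect_contributions_all <- function(records) {
  if (!length(records)) {
    return(data.frame(x = character(0), y = character(0),
                      contributor = character(0), rank = integer(0),
                      ind_c = numeric(0), residual_fraction = numeric(0),
                      independent = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(records[order(names(records))],
                               indirect_contributions))
  rownames(out) <- NULL
  out
}
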