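#' Learn a causal network from a mixed-type data table
#'
#' Full pipeline: skeleton learning by iterative contributor collection,
#' confidence-ordered orientation, edge classification, and (optionally)
#' indirect-path consistency iteration.
#'
#' @param data a [mindnet_data].
#' @param ctl a [mindnet_control()] list.
#' @return a classified [mixed_graph]; separating-set records are stored in
#'   `meta$records`.
#' @examples
#' set.seed(1)
#' n <- 600
#' z <- rnorm(n)
#' d <- data.frame(x = z + rnorm(n), y = z + rnorm(n), z = z)
#' g <- discover_network(mindnet_data(d))
#' g
#' @export
discover_network <- function(data, ctl = mindnet_control()) {
  if (ctl$consistency != "none") return(learn_consistent(data, ctl))
  ss <- new_session(data, ctl)
  sk <- learn_skeleton(data, ctl, session = ss)
  g <- orient_graph(sk$graph, sk$records, data, ctl, session = ss)
  g$meta$records <- sk$records
  g
}
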