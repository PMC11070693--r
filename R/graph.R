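# Mixed graph container: every unordered variable pair carries one edge
# state (presence, endpoint marks with head/tail probabilities, status,
# regularized information, association sign, separating set).

pair_key <- function(x, y) {
  ifelse(x < y, paste(x, y, sep = "\r"), paste(y, x, sep = "\r"))
}

#' Create an empty mixed graph over a set of variables
#'
#' @param specs data.frame with columns `name`, `vtype`, `is_contextual`
#'   (e.g. the `specs` element of a [mindnet_data]).
#' @param complete if `TRUE`, start from the complete graph (all edges
#'   present); otherwise the empty graph.
#' @return an object of class `mixed_graph`.
#' @export
mixed_graph <- function(specs, complete = FALSE) {
  nms <- sort(specs$name)
  specs <- specs[match(nms, specs$name), , drop = FALSE]
  rownames(specs) <- NULL
  if (length(nms) < 2L) stop("need at least two variables")
  cmb <- utils::combn(nms, 2L)
  pairs <- data.frame(
    x = cmb[1L, ], y = cmb[2L, ],
    present = complete,
    status = if (complete) "undirected" else "absent",
    info_reg = NA_real_, residual_info = NA_real_,
    sign = "na",
    mark_x = "undefined", mark_y = "undefined",
    p_head_x = 0.5, p_tail_x = 0.5, p_head_y = 0.5, p_tail_y = 0.5,
    stringsAsFactors = FALSE
  )
  idx <- seq_len(nrow(pairs))
  names(idx) <- pair_key(pairs$x, pairs$y)
  structure(
    list(nodes = specs, pairs = pairs, index = idx,
         sepsets = list(), contributors = list(), meta = list()),
    class = "mixed_graph"
  )
}

g_idx <- function(g, x, y) unname(g$index[pair_key(x, y)])

g_present <- function(g) g$pairs[g$pairs$present, c("x", "y"), drop = FALSE]

g_neighbors <- function(g, v) {
  p <- g$pairs[g$pairs$present, , drop = FALSE]
  c(p$y[p$x == v], p$x[p$y == v])
}

g_adjacent <- function(g, x, y) g$pairs$present[g_idx(g, x, y)]

#' @export
print.mixed_graph <- function(x, ...) {
  p <- x$pairs[x$pairs$present, , drop = FALSE]
  cat(sprintf("mixed_graph: %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(p),
              paste(sprintf("%s=%d", names(table(p$status)), table(p$status)),
                    collapse = ", ")))
  invisible(x)
}

# association sign of an edge: Spearman correlation when a continuous
# variable is involved; sign of the concordant-discordant (gamma) statistic
# on level codes for categorical pairs
edge_sign <- function(data, x, y) {
  sub <- complete_rows(data, c(x, y))
  if (nrow(sub) < 3L) return("na")
  tp <- vtype_of(data, c(x, y))
  if (any(unlist(tp) == "continuous")) {
    xv <- if (tp[[x]] == "continuous") sub[[x]] else as.integer(factor(sub[[x]]))
    yv <- if (tp[[y]] == "continuous") sub[[y]] else as.integer(factor(sub[[y]]))
    r <- suppressWarnings(stats::cor(xv, yv, method = "spearman"))
    if (is.na(r) || r == 0) return("na")
    return(if (r > 0) "positive" else "negative")
  }
  tab <- table(sub[[x]], sub[[y]])
  if (nrow(tab) < 2L || ncol(tab) < 2L) return("na")
  conc <- 0
  disc <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (i < nrow(tab) && j < ncol(tab)) {
        conc <- conc + tab[i, j] * sum(tab[(i + 1):nrow(tab), (j + 1):ncol(tab)])
      }
      if (i < nrow(tab) && j > 1L) {
        disc <- disc + tab[i, j] * sum(tab[(i + 1):nrow(tab), 1:(j - 1)])
      }
    }
  }
  if (conc == disc) return("na")
  if (conc > disc) "positive" else "negative"
}

fmt_num <- function(v) {
  ifelse(is.na(v), "NA", sprintf("%.12g", v))
}

#' Write a per-pair edge summary table
#'
#' One row per unordered variable pair (all P(P-1)/2 of them), listing edge
#' status, regularized information (nats), association sign, the four
#' endpoint head/tail probabilities, the separating set and the indirect
#' contributor percentages.  Row order is lexicographic in the pair.
#'
#' @param graph a classified [mixed_graph].
#' @param contributions optional contribution table from
#'   [indirect_contributions_all()].
#' @param path output TSV path.
#' @export
write_edge_summary <- function(graph, contributions = NULL, path) {
  p <- graph$pairs
  key <- pair_key(p$x, p$y)
  sepset <- vapply(key, function(k) {
    s <- graph$sepsets[[k]]
    if (is.null(s)) "" else paste(s$contributors, collapse = ";")
  }, character(1))
  contrib <- rep("", nrow(p))
  if (!is.null(contributions) && nrow(contributions)) {
    ck <- pair_key(contributions$x, contributions$y)
    for (k in unique(ck)) {
      rows <- contributions[ck == k, , drop = FALSE]
      contrib[key == k] <- paste(
        sprintf("%s:%s", rows$contributor, fmt_num(100 * rows$ind_c)),
        collapse = ";")
    }
  }
  out <- data.frame(
    x = p$x, y = p$y, status = p$status,
    info_reg = fmt_num(p$info_reg), sign = p$sign,
    mark_x = p$mark_x, mark_y = p$mark_y,
    p_head_x = fmt_num(p$p_head_x), p_tail_x = fmt_num(p$p_tail_x),
    p_head_y = fmt_num(p$p_head_y), p_tail_y = fmt_num(p$p_tail_y),
    residual_info = fmt_num(p$residual_info),
    sepset = sepset, contributions = contrib,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge summary written by [write_edge_summary()]
#'
#' @param path summary TSV path.
#' @param specs optional variable spec data.frame; reconstructed from the
#'   pair list (all variables categorical, non-contextual) when omitted.
#' @return a [mixed_graph].
#' @export
read_edge_summary <- function(path, specs = NULL) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  nms <- sort(unique(c(tb$x, tb$y)))
  if (is.null(specs)) {
    specs <- data.frame(name = nms, vtype = "categorical",
                        is_contextual = FALSE, stringsAsFactors = FALSE)
  }
  g <- mixed_graph(specs)
  for (i in seq_len(nrow(tb))) {
    j <- g_idx(g, tb$x[i], tb$y[i])
    g$pairs$present[j] <- tb$status[i] != "absent"
    g$pairs$status[j] <- tb$status[i]
    g$pairs$info_reg[j] <- tb$info_reg[i]
    g$pairs$sign[j] <- tb$sign[i]
    g$pairs$mark_x[j] <- tb$mark_x[i]
    g$pairs$mark_y[j] <- tb$mark_y[i]
    g$pairs$p_head_x[j] <- tb$p_head_x[i]
    g$pairs$p_tail_x[j] <- tb$p_tail_x[i]
    g$pairs$p_head_y[j] <- tb$p_head_y[i]
    g$pairs$p_tail_y[j] <- tb$p_tail_y[i]
    g$pairs$residual_info[j] <- tb$residual_info[i]
    if (tb$status[i] == "absent") {
      contr <- if (is.na(tb$sepset[i]) || tb$sepset[i] == "") character(0) else
        strsplit(tb$sepset[i], ";", fixed = TRUE)[[1L]]
      g$sepsets[[pair_key(tb$x[i], tb$y[i])]] <-
        list(pair = c(tb$x[i], tb$y[i]), contributors = contr,
             contributions = numeric(length(contr)), residual = 0)
    }
  }
  g
}

#' Write a mixed graph to disk
#'
#' `adjacency_tsv` encodes the mark seen at the column variable's end of
#' each edge: 0 absent, 1 present with undefined mark, 2 arrowhead into the
#' column variable, -2 tail at the column variable, 6 for a bidirected pair
#' (symmetric).  `graphml` and `dot` carry status and endpoint probabilities
#' as edge attributes.
#'
#' @param graph a [mixed_graph].
#' @param path output file.
#' @param format one of `"adjacency_tsv"`, `"graphml"`, `"dot"`.
#' @export
write_graph <- function(graph, path, format = c("adjacency_tsv", "graphml", "dot")) {
  format <- match.arg(format)
  switch(format,
         adjacency_tsv = write_adjacency(graph, path),
         graphml = write_graphml(graph, path),
         dot = write_dot(graph, path))
  invisible(path)
}

mark_code <- function(present, status, mark_at_col) {
  if (!present) return(0L)
  if (status == "bidirected") return(6L)
  switch(mark_at_col, head = 2L, tail = -2L, 1L)
}

write_adjacency <- function(graph, path) {
  nms <- graph$nodes$name
  a <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  p <- graph$pairs
  for (i in which(p$present)) {
    a[p$x[i], p$y[i]] <- mark_code(TRUE, p$status[i], p$mark_y[i])
    a[p$y[i], p$x[i]] <- mark_code(TRUE, p$status[i], p$mark_x[i])
  }
  utils::write.table(a, path, sep = "\t", quote = FALSE, col.names = NA)
}

#' Read an adjacency TSV written by [write_graph()]
#' @param path adjacency file.
#' @param specs optional variable specs.
#' @return a [mixed_graph] (presence and marks only).
#' @export
read_adjacency <- function(path, specs = NULL) {
  a <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  nms <- sort(rownames(a))
  if (is.null(specs)) {
    specs <- data.frame(name = nms, vtype = "categorical",
                        is_contextual = FALSE, stringsAsFactors = FALSE)
  }
  g <- mixed_graph(specs)
  for (i in seq_len(nrow(g$pairs))) {
    x <- g$pairs$x[i]
    y <- g$pairs$y[i]
    cxy <- a[x, y]
    cyx <- a[y, x]
    if (cxy == 0L && cyx == 0L) next
    g$pairs$present[i] <- TRUE
    if (cxy == 6L || cyx == 6L) {
      g$pairs$status[i] <- "bidirected"
      g$pairs$mark_x[i] <- "head"
      g$pairs$mark_y[i] <- "head"
    } else {
      g$pairs$mark_y[i] <- switch(as.character(cxy), `2` = "head", `-2` = "tail", "undefined")
      g$pairs$mark_x[i] <- switch(as.character(cyx), `2` = "head", `-2` = "tail", "undefined")
      g$pairs$status[i] <- "undirected"
    }
  }
  g
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

write_graphml <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  keys <- c(status = "string", sign = "string", info_reg = "double",
            mark_x = "string", mark_y = "string",
            p_head_x = "double", p_tail_x = "double",
            p_head_y = "double", p_tail_y = "double")
  for (k in names(keys)) {
    w('  <key id="%s" for="edge" attr.name="%s" attr.type="%s"/>', k, k, keys[[k]])
  }
  w('  <key id="vtype" for="node" attr.name="vtype" attr.type="string"/>')
  w('  <key id="contextual" for="node" attr.name="contextual" attr.type="boolean"/>')
  w('  <graph edgedefault="undirected">')
  for (i in seq_len(nrow(graph$nodes))) {
    w('    <node id="%s"><data key="vtype">%s</data><data key="contextual">%s</data></node>',
      xml_escape(graph$nodes$name[i]), graph$nodes$vtype[i],
      tolower(as.character(graph$nodes$is_contextual[i])))
  }
  p <- graph$pairs
  for (i in which(p$present)) {
    w('    <edge source="%s" target="%s">', xml_escape(p$x[i]), xml_escape(p$y[i]))
    w('      <data key="status">%s</data><data key="sign">%s</data><data key="info_reg">%s</data>',
      p$status[i], p$sign[i], fmt_num(p$info_reg[i]))
    w('      <data key="mark_x">%s</data><data key="mark_y">%s</data>',
      p$mark_x[i], p$mark_y[i])
    w('      <data key="p_head_x">%s</data><data key="p_tail_x">%s</data><data key="p_head_y">%s</data><data key="p_tail_y">%s</data>',
      fmt_num(p$p_head_x[i]), fmt_num(p$p_tail_x[i]),
      fmt_num(p$p_head_y[i]), fmt_num(p$p_tail_y[i]))
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
}

#' Read a GraphML file written by [write_graph()]
#' @param path graphml file.
#' @return a [mixed_graph].
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//node")
  specs <- data.frame(
    name = xml2::xml_attr(nodes, "id"),
    vtype = xml2::xml_text(xml2::xml_find_first(nodes, "./data[@key='vtype']")),
    is_contextual = xml2::xml_text(
      xml2::xml_find_first(nodes, "./data[@key='contextual']")) == "true",
    stringsAsFactors = FALSE
  )
  g <- mixed_graph(specs)
  edges <- xml2::xml_find_all(doc, ".//edge")
  getd <- function(e, k) xml2::xml_text(xml2::xml_find_first(e, sprintf("./data[@key='%s']", k)))
  for (e in edges) {
    x <- xml2::xml_attr(e, "source")
    y <- xml2::xml_attr(e, "target")
    i <- g_idx(g, x, y)
    flip <- x > y  # stored orientation vs canonical pair order
    g$pairs$present[i] <- TRUE
    g$pairs$status[i] <- getd(e, "status")
    g$pairs$sign[i] <- getd(e, "sign")
    g$pairs$info_reg[i] <- as.numeric(getd(e, "info_reg"))
    mx <- getd(e, "mark_x"); my <- getd(e, "mark_y")
    phx <- as.numeric(getd(e, "p_head_x")); ptx <- as.numeric(getd(e, "p_tail_x"))
    phy <- as.numeric(getd(e, "p_head_y")); pty <- as.numeric(getd(e, "p_tail_y"))
    if (flip) {
      tmp <- mx; mx <- my; my <- tmp
      tmp <- phx; phx <- phy; phy <- tmp
      tmp <- ptx; ptx <- pty; pty <- tmp
    }
    g$pairs$mark_x[i] <- mx; g$pairs$mark_y[i] <- my
    g$pairs$p_head_x[i] <- phx; g$pairs$p_tail_x[i] <- ptx
    g$pairs$p_head_y[i] <- phy; g$pairs$p_tail_y[i] <- pty
  }
  g
}

write_dot <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("graph mindnet {")
  for (i in seq_len(nrow(graph$nodes))) {
    w('  "%s" [vtype="%s", contextual="%s"];', graph$nodes$name[i],
      graph$nodes$vtype[i], tolower(as.character(graph$nodes$is_contextual[i])))
  }
  p <- graph$pairs
  for (i in which(p$present)) {
    w(paste0('  "%s" -- "%s" [status="%s", sign="%s", info_reg="%s", ',
             'mark_x="%s", mark_y="%s", p_head_x="%s", p_tail_x="%s", ',
             'p_head_y="%s", p_tail_y="%s"];'),
      p$x[i], p$y[i], p$status[i], p$sign[i], fmt_num(p$info_reg[i]),
      p$mark_x[i], p$mark_y[i], fmt_num(p$p_head_x[i]), fmt_num(p$p_tail_x[i]),
      fmt_num(p$p_head_y[i]), fmt_num(p$p_tail_y[i]))
  }
  w("}")
}

#' Read a DOT file written by [write_graph()]
#' @param path dot file.
#' @return a [mixed_graph].
#' @export
read_dot <- function(path) {
  ln <- readLines(path)
  nodeln <- grep('^  "[^"]+" \\[vtype=', ln, value = TRUE)
  attr1 <- function(s, k) sub(sprintf('.*%s="([^"]*)".*', k), "\\1", s)
  specs <- data.frame(
    name = sub('^  "([^"]+)" .*', "\\1", nodeln),
    vtype = attr1(nodeln, "vtype"),
    is_contextual = attr1(nodeln, "contextual") == "true",
    stringsAsFactors = FALSE
  )
  g <- mixed_graph(specs)
  edgeln <- grep(" -- ", ln, fixed = TRUE, value = TRUE)
  for (s in edgeln) {
    x <- sub('^  "([^"]+)" -- .*', "\\1", s)
    y <- sub('^  "[^"]+" -- "([^"]+)".*', "\\1", s)
    i <- g_idx(g, x, y)
    flip <- x > y
    g$pairs$present[i] <- TRUE
    g$pairs$status[i] <- attr1(s, "status")
    g$pairs$sign[i] <- attr1(s, "sign")
    g$pairs$info_reg[i] <- suppressWarnings(as.numeric(attr1(s, "info_reg")))
    mx <- attr1(s, "mark_x"); my <- attr1(s, "mark_y")
    phx <- as.numeric(attr1(s, "p_head_x")); ptx <- as.numeric(attr1(s, "p_tail_x"))
    phy <- as.numeric(attr1(s, "p_head_y")); pty <- as.numeric(attr1(s, "p_tail_y"))
    if (flip) {
      tmp <- mx; mx <- my; my <- tmp
      tmp <- phx; phx <- phy; phy <- tmp
      tmp <- ptx; ptx <- pty; pty <- tmp
    }
    g$pairs$mark_x[i] <- mx; g$pairs$mark_y[i] <- my
    g$pairs$p_head_x[i] <- phx; g$pairs$p_tail_x[i] <- ptx
    g$pairs$p_head_y[i] <- phy; g$pairs$p_tail_y[i] <- pty
  }
  g
}
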