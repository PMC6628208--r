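# independent iterative-pruning oracle built on igraph, plus a random
# directed-graph generator; shared by the module and acceptance suites
igraphPruneOracle <- function(net, minDegree = 2,
                              mode = c("total", "in_or_out")) {
  testthat::skip_if_not_installed("igraph")
  mode <- match.arg(mode)
  ed <- edges(net)
  ed <- ed[!duplicated(paste(ed$source, ed$target)), , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed[c("source", "target")],
                                     vertices = nodes(net)$primary)
  repeat {
    score <- if (mode == "total")
      igraph::degree(g, mode = "all")
    else
      pmax(igraph::degree(g, mode = "in"), igraph::degree(g, mode = "out"))
    drop <- names(score)[score < minDegree]
    if (!length(drop)) break
    g <- igraph::delete_vertices(g, drop)
  }
  sort(igraph::V(g)$name)
}

randomNet <- function(nNodes, nEdges) {
  ids <- paste0("n", seq_len(nNodes))
  src <- sample(ids, nEdges, replace = TRUE)
  tgt <- sample(ids, nEdges, replace = TRUE)
  edgeNet(paste0(src, "->", tgt)[src != tgt])
}
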