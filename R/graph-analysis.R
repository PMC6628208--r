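#' Remove duplicate edges
#'
#' Keeps at most one edge per (source, target, interaction type) triple —
#' first occurrence wins, so provenance follows dataset order. The same
#' gene pair under two different interaction types keeps both edges. The
#' node set is unchanged. Networks built by this package are already unique
#' on the triple; this is the explicit pre-step for [degreeFilter()] on
#' networks imported from elsewhere.
#'
#' @param net a [Network-class].
#' @return the de-duplicated [Network-class].
#' @export
removeDuplicateEdges <- function(net) {
  ed <- net@edges
  keep <- !duplicated(paste(ed$source, ed$target, ed$interaction_type,
                            sep = "\r"))
  newNetwork(net@nodes, ed[keep, , drop = FALSE], net@cores, net@organism)
}

nodeDegrees <- function(net, mode) {
  # parallel interaction-type edges count once per (source, target) pair
  ed <- net@edges
  pairs <- ed[!duplicated(paste(ed$source, ed$target, sep = "\r")), ,
              drop = FALSE]
  ids <- net@nodes$primary
  outd <- tabulate(match(pairs$source, ids), nbins = length(ids))
  ind <- tabulate(match(pairs$target, ids), nbins = length(ids))
  if (mode == "total") {
    list(keepScore = outd + ind)
  } else {
    list(keepScore = pmax(outd, ind))
  }
}

#' Terminal-node and linear-path filtration
#'
#' The pruning procedure applied after duplicate-edge removal: per pass,
#' node degrees are computed on the current network, nodes meeting the
#' degree criterion are kept, and the induced subgraph becomes the input of
#' the next pass. The first pass removes terminal nodes (degree 1); the
#' second removes nodes that linked a core to terminal nodes and had
#' themselves become terminal — two passes is the classical procedure, and
#' `fixpoint = TRUE` iterates until stable, which eliminates linear paths of
#' any length while preserving every cycle (a feedback 2-cycle gives both
#' its nodes degree 2, so it always survives). Cores receive no special
#' protection.
#'
#' @param net a [Network-class], duplicates already removed.
#' @param minDegree keep nodes with degree at least this (default 2).
#' @param passes number of filtration passes (default 2).
#' @param fixpoint iterate until the node set stops changing, ignoring
#'   `passes`.
#' @param mode `"total"` counts in-degree plus out-degree (default);
#'   `"in_or_out"` keeps a node when either its in-degree or its out-degree
#'   meets the threshold. Parallel edges of different interaction types
#'   count once per (source, target) pair in both modes.
#' @return the filtered [Network-class]; nodes that survive with no
#'   remaining edges are kept as isolates.
#' @export
degreeFilter <- function(net, minDegree = 2, passes = 2, fixpoint = FALSE,
                         mode = c("total", "in_or_out")) {
  mode <- match.arg(mode)
  stopifnot(minDegree >= 1, passes >= 1)
  cur <- net
  pass <- 0L
  repeat {
    pass <- pass + 1L
    score <- nodeDegrees(cur, mode)$keepScore
    keepIds <- cur@nodes$primary[score >= minDegree]
    changed <- length(keepIds) < nrow(cur@nodes)
    nd <- cur@nodes[cur@nodes$primary %in% keepIds, , drop = FALSE]
    ed <- cur@edges[cur@edges$source %in% keepIds &
                    cur@edges$target %in% keepIds, , drop = FALSE]
    cur <- newNetwork(nd, ed, intersect(cur@cores, keepIds),
                      cur@organism)
    if (fixpoint) { if (!changed) break } else if (pass >= passes) break
  }
  cur
}

#' Partition targets by the set of cores regulating them
#'
#' Assigns every non-core node that receives at least one inbound edge from
#' a core to the block keyed by the exact set of cores targeting it — the
#' mono-, di- and tri-regulated target clusters of a merged network. Nodes
#' with no inbound core edge are excluded; blocks are disjoint and together
#' cover all core-targeted nodes.
#'
#' @param net a [Network-class].
#' @param coreIds core primary identifiers; defaults to `cores(net)`.
#' @return a [CoTargetPartition-class]; block names are the sorted core
#'   identifiers joined with `"+"`.
#' @export
coTargetPartition <- function(net, coreIds = cores(net)) {
  stopifnot(all(coreIds %in% net@nodes$primary))
  ed <- net@edges[net@edges$source %in% coreIds &
                  !net@edges$target %in% coreIds, , drop = FALSE]
  ed <- ed[!duplicated(paste(ed$source, ed$target, sep = "\r")), ,
           drop = FALSE]
  if (nrow(ed) == 0L) return(new("CoTargetPartition", blocks = list()))
  keyOf <- vapply(split(ed$source, ed$target),
                  function(s) paste(sort(unique(s)), collapse = "+"),
                  character(1))
  blocks <- split(names(keyOf), keyOf)
  blocks <- lapply(blocks, function(b) unname(sort(b)))
  new("CoTargetPartition", blocks = blocks)
}

setMethod("blocks", "CoTargetPartition", function(x) x@blocks)

setMethod("show", "CoTargetPartition", function(object) {
  cat("CoTargetPartition with", length(object@blocks), "block(s)\n")
  for (k in names(object@blocks))
    cat(" ", k, ":", length(object@blocks[[k]]), "target(s)\n")
})

#' Summary counts of a network
#'
#' Node count, edge count and per-core target counts (distinct
#' out-neighbours of each core) — the sizes that parameterize the
#' enrichment tests.
#'
#' @param net a [Network-class].
#' @return list with `nodes`, `edges`, and `perCore` (named integer
#'   vector keyed by core primary identifier).
#' @export
networkCounts <- function(net) {
  perCore <- vapply(net@cores, function(c) {
    length(unique(net@edges$target[net@edges$source == c]))
  }, integer(1))
  list(nodes = nrow(net@nodes), edges = nrow(net@edges), perCore = perCore)
}
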