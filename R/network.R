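#' Describe one uploaded screen
#'
#' Packages a list of submitted identifiers together with the core gene
#' whose screen produced it. The `technique` label ("DamID", "RNAseq", ...)
#' becomes the `Interaction Type` of every edge of the wheel built from the
#' dataset.
#'
#' @param name dataset name, unique within a session.
#' @param organism organism binomial name.
#' @param coreSymbol core gene symbol (must resolve through the backend).
#' @param technique technique label.
#' @param identifiers submitted identifier texts.
#' @return a [Dataset-class].
#' @export
newDataset <- function(name, organism, coreSymbol, technique, identifiers) {
  new("Dataset", name = name, organism = organism, coreSymbol = coreSymbol,
      technique = technique, identifiers = as.character(identifiers))
}

newNetwork <- function(nodes, edges, cores, organism) {
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("Network", nodes = nodes, edges = edges, cores = cores,
      organism = organism)
}

#' Build a wheel network from one dataset
#'
#' Resolves the dataset's identifiers through the backend and builds the
#' star: the core gene at the hub, one node per resolved target on the rim,
#' and one directed edge core -> target per target, labelled with the
#' dataset's technique. A target equal to the core would be a self-loop; by
#' default it is dropped with a warning.
#'
#' @param dataset a [Dataset-class].
#' @param backend a [Resolver][Resolver-class].
#' @param selfLoops keep a core-to-itself edge when the core appears in its
#'   own target list.
#' @param passThrough keep unresolved identifiers as pass-through nodes
#'   (see [resolveIdentifiers()]).
#' @return a [Network-class] with a single core.
#' @export
buildWheel <- function(dataset, backend, selfLoops = FALSE,
                       passThrough = TRUE) {
  core <- validateCoreSymbol(backend, dataset@organism, dataset@coreSymbol)
  targets <- if (length(dataset@identifiers))
    resolveIdentifiers(backend, dataset@organism, dataset@identifiers,
                       passThrough = passThrough)$nodes
  else emptyNodes()
  self <- targets$primary == core$primary
  if (any(self) && !selfLoops) {
    warning("core gene \"", dataset@coreSymbol,
            "\" appears in its own target list; self-loop dropped")
    targets <- targets[!self, , drop = FALSE]
  }
  nodes <- rbind(core, targets)
  nodes <- nodes[!duplicated(nodes$primary), , drop = FALSE]
  edges <- if (nrow(targets))
    data.frame(source = core$primary, target = targets$primary,
               interaction_type = dataset@technique,
               dataset_name = dataset@name, stringsAsFactors = FALSE)
  else emptyEdges()
  newNetwork(nodes, edges, cores = core$primary,
             organism = dataset@organism)
}

#' Merge wheel networks into one combined network
#'
#' Takes the union of nodes (keyed by primary identifier, first occurrence
#' wins) and the union of edges (de-duplicated on source, target,
#' interaction type; the same gene pair reported by two datasets with
#' different techniques keeps both edges, so provenance is never lost).
#' Targets shared between wheels become the nodes that interconnect them.
#' Row order is canonical — dataset registration order, then input row order
#' — so the merge result is independent of input order up to that sort.
#'
#' @param wheels list of [Network-class] objects sharing one organism.
#' @return the merged [Network-class].
#' @export
mergeNetworks <- function(wheels) {
  stopifnot(length(wheels) >= 1L)
  orgs <- unique(vapply(wheels, function(w) w@organism, character(1)))
  if (length(orgs) != 1L)
    stop("cannot merge networks from different organisms: ",
         paste(orgs, collapse = ", "))
  nodes <- do.call(rbind, lapply(wheels, function(w) w@nodes))
  nodes <- nodes[!duplicated(nodes$primary), , drop = FALSE]
  edges <- do.call(rbind, lapply(wheels, function(w) w@edges))
  edges <- edges[!duplicated(paste(edges$source, edges$target,
                                   edges$interaction_type, sep = "\r")), ,
                 drop = FALSE]
  cores <- unique(unlist(lapply(wheels, function(w) w@cores)))
  newNetwork(nodes, edges, cores, orgs)
}

#' Fold curated interactions into a network
#'
#' Adds the genetic/physical interaction records returned by
#' [fetchInteractions()] to a network: partners not already present become
#' new nodes, and each record becomes a directed edge query gene -> partner
#' labelled `genetic` or `physical`. Existing nodes and edges are never
#' removed; records duplicating an existing edge leave the network
#' unchanged, so the operation is monotone.
#'
#' @param net a [Network-class].
#' @param records interaction data.frame from [fetchInteractions()].
#' @return the enriched [Network-class].
#' @export
integrateInteractions <- function(net, records) {
  if (is.null(records) || nrow(records) == 0L) return(net)
  newPartners <- !records$partner %in% net@nodes$primary
  addNodes <- data.frame(primary = records$partner[newPartners],
                         symbol = records$partner_symbol[newPartners],
                         secondary = records$partner_secondary[newPartners],
                         organism = rep(net@organism, sum(newPartners)),
                         stringsAsFactors = FALSE)
  nodes <- rbind(net@nodes, addNodes)
  nodes <- nodes[!duplicated(nodes$primary), , drop = FALSE]
  addEdges <- data.frame(source = records$query, target = records$partner,
                         interaction_type = records$kind,
                         dataset_name = records$provenance,
                         stringsAsFactors = FALSE)
  edges <- rbind(net@edges, addEdges)
  edges <- edges[!duplicated(paste(edges$source, edges$target,
                                   edges$interaction_type, sep = "\r")), ,
                 drop = FALSE]
  newNetwork(nodes, edges, net@cores, net@organism)
}

#' The seven Cytoscape network-table column names
#'
#' Header of the network CSV, in emission order. In Cytoscape's table
#' importer, `Source Symbol` is the source-node column, `Target Symbol` the
#' target-node column, `Interaction Type` the interaction column, and the
#' identifier columns are source/target node attributes.
#'
#' @return character vector of length 7.
#' @export
networkCsvHeader <- function() {
  c("Source Symbol", "Source Primary Identifier",
    "Source Secondary Identifier", "Interaction Type",
    "Target Symbol", "Target Primary Identifier",
    "Target Secondary Identifier")
}

#' Write the Cytoscape-ready network CSV
#'
#' One row per edge, in canonical order (dataset registration order, then
#' input row order), with the fixed seven-column header of
#' [networkCsvHeader()]. An empty network writes a header-only file.
#'
#' @param net a [Network-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNetworkCsv <- function(net, path) {
  nd <- net@nodes
  s <- match(net@edges$source, nd$primary)
  t <- match(net@edges$target, nd$primary)
  rows <- lapply(seq_len(nrow(net@edges)), function(i)
    c(nd$symbol[s[i]], nd$primary[s[i]], nd$secondary[s[i]],
      net@edges$interaction_type[i],
      nd$symbol[t[i]], nd$primary[t[i]], nd$secondary[t[i]]))
  writeCsvLines(c(list(networkCsvHeader()), rows), path)
}

#' Read a network CSV back into a Network
#'
#' Rebuilds a [Network-class] from a file written by [writeNetworkCsv()]
#' (or any CSV with the same seven columns). Cores are not stored in the
#' file; by default they are inferred as the source nodes of user-technique
#' edges (any interaction type other than `genetic`/`physical`), which
#' recovers the wheel hubs of a merged network. Pass `cores` explicitly to
#' override.
#'
#' @param path path to the network CSV.
#' @param cores optional character vector of core primary identifiers.
#' @param organism organism recorded on the rebuilt network.
#' @return a [Network-class].
#' @export
readNetworkCsv <- function(path, cores = NULL,
                           organism = "Drosophila melanogaster") {
  tab <- readTable(path, hasHeader = TRUE)
  if (!identical(tab@headers, networkCsvHeader()))
    stop("not a network CSV: header does not match the seven-column format")
  m <- tab@cells
  nodes <- data.frame(
    primary = c(m[, 2L], m[, 6L]),
    symbol = c(m[, 1L], m[, 5L]),
    secondary = c(m[, 3L], m[, 7L]),
    organism = organism, stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$primary), , drop = FALSE]
  edges <- if (nrow(m)) data.frame(
    source = m[, 2L], target = m[, 6L], interaction_type = m[, 4L],
    dataset_name = "", stringsAsFactors = FALSE) else emptyEdges()
  edges <- edges[!duplicated(paste(edges$source, edges$target,
                                   edges$interaction_type, sep = "\r")), ,
                 drop = FALSE]
  if (is.null(cores)) {
    user <- !edges$interaction_type %in% c("genetic", "physical")
    cores <- unique(edges$source[user])
  }
  newNetwork(nodes, edges, cores, organism)
}

setMethod("nodes", "Network", function(x) x@nodes)
setMethod("edges", "Network", function(x) x@edges)
setMethod("cores", "Network", function(x) x@cores)
setMethod("organism", "Network", function(x) x@organism)

setMethod("show", "Network", function(object) {
  cat("Network (", object@organism, "): ", nrow(object@nodes), " nodes, ",
      nrow(object@edges), " edges, ", length(object@cores), " core(s)\n",
      sep = "")
  if (length(object@cores)) {
    syms <- object@nodes$symbol[match(object@cores, object@nodes$primary)]
    cat("  cores:", paste(syms, collapse = ", "), "\n")
  }
  types <- table(object@edges$interaction_type)
  if (length(types))
    cat("  edge types:",
        paste(names(types), types, sep = "=", collapse = ", "), "\n")
})
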