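#' @import methods
NULL

#' RawTable: a delimited text table held as character cells
#'
#' Holds the cells of a delimited text file exactly as read: every cell is
#' text, every row has exactly `length(headers)` cells (short rows are padded
#' with empty strings on read), and headers are unique (duplicates suffixed
#' `_2`, `_3`, ...). Construct with [readTable()].
#'
#' @slot headers character vector of unique column names; synthesized
#'   (`col_1` .. `col_N`) when the file had no header row.
#' @slot cells character matrix, one row per data row, `length(headers)`
#'   columns.
#' @slot sourcePath path the table was read from (may be `""` for tables
#'   built in memory).
#'
#' @exportClass RawTable
setClass("RawTable",
  representation(headers = "character", cells = "matrix",
                 sourcePath = "character"),
  prototype(headers = character(0),
            cells = matrix(character(0), nrow = 0, ncol = 0),
            sourcePath = ""))

setValidity("RawTable", function(object) {
  msg <- character(0)
  if (!is.character(object@cells))
    msg <- c(msg, "cells must be a character matrix")
  if (ncol(object@cells) != length(object@headers))
    msg <- c(msg, "every row must have exactly length(headers) cells")
  if (anyDuplicated(object@headers))
    msg <- c(msg, "headers must be unique")
  if (length(msg)) msg else TRUE
})

#' Dataset: one uploaded screen
#'
#' A named list of submitted gene/protein identifiers produced by a screen
#' (DamID target list, differential-expression list, proteomic screen, ...),
#' together with the core gene whose manipulation or profiling produced it
#' and the technique label that becomes the interaction type of the wheel
#' edges. Construct with [newDataset()].
#'
#' @slot name dataset name, unique within a session.
#' @slot organism organism binomial name.
#' @slot coreSymbol gene symbol of the core gene/protein.
#' @slot technique technique label, e.g. `"DamID"` or `"RNAseq"`; becomes
#'   the `Interaction Type` of every wheel edge.
#' @slot identifiers submitted identifier texts, in input order.
#'
#' @exportClass Dataset
setClass("Dataset",
  representation(name = "character", organism = "character",
                 coreSymbol = "character", technique = "character",
                 identifiers = "character"))

setValidity("Dataset", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@technique) != 1L || !nzchar(object@technique))
    msg <- c(msg, "technique must be a single non-empty string")
  if (length(object@coreSymbol) != 1L || !nzchar(object@coreSymbol))
    msg <- c(msg, "coreSymbol must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' Network: nodes plus directed typed edges, Cytoscape-ready
#'
#' The central container: a set of node records plus a duplicate-free list of
#' directed edges carrying an interaction-type label. A single uploaded
#' dataset yields a wheel network (core at the hub, one edge core -> target
#' per target); [mergeNetworks()] unions wheels so that shared targets
#' interconnect them; [integrateInteractions()] folds in curated
#' genetic/physical interactions.
#'
#' @slot nodes data.frame with columns `primary`, `symbol`, `secondary`,
#'   `organism`; one row per node, `primary` unique and non-empty.
#' @slot edges data.frame with columns `source`, `target` (node primary
#'   identifiers), `interaction_type`, `dataset_name`; unique on
#'   (source, target, interaction_type).
#' @slot cores primary identifiers of the core genes, in dataset
#'   registration order.
#' @slot organism organism binomial name shared by all nodes.
#'
#' @exportClass Network
setClass("Network",
  representation(nodes = "data.frame", edges = "data.frame",
                 cores = "character", organism = "character"))

emptyNodes <- function() {
  data.frame(primary = character(0), symbol = character(0),
             secondary = character(0), organism = character(0),
             stringsAsFactors = FALSE)
}

emptyEdges <- function() {
  data.frame(source = character(0), target = character(0),
             interaction_type = character(0), dataset_name = character(0),
             stringsAsFactors = FALSE)
}

setValidity("Network", function(object) {
  msg <- character(0)
  nd <- object@nodes; ed <- object@edges
  if (!all(c("primary", "symbol", "secondary", "organism") %in% names(nd)))
    msg <- c(msg, "nodes must have columns primary, symbol, secondary, organism")
  if (!all(c("source", "target", "interaction_type", "dataset_name") %in% names(ed)))
    msg <- c(msg, "edges must have columns source, target, interaction_type, dataset_name")
  if (length(msg)) return(msg)
  if (anyDuplicated(nd$primary))
    msg <- c(msg, "node primary identifiers must be unique")
  if (any(!nzchar(nd$primary)))
    msg <- c(msg, "node primary identifiers must be non-empty")
  if (!all(ed$source %in% nd$primary) || !all(ed$target %in% nd$primary))
    msg <- c(msg, "every edge endpoint must be a network node")
  if (!all(object@cores %in% nd$primary))
    msg <- c(msg, "every core must be a network node")
  if (nrow(ed) &&
      anyDuplicated(paste(ed$source, ed$target, ed$interaction_type, sep = "\r")))
    msg <- c(msg, "edges must be unique on (source, target, interaction_type)")
  if (length(msg)) msg else TRUE
})

#' Resolver backends
#'
#' `Resolver` is the abstract contract for the identifier/interaction
#' service: validating a core gene symbol, updating submitted identifiers to
#' current primary identifiers, and retrieving curated genetic and physical
#' interactions. Two backends implement it: [localResolver()] (deterministic
#' CSV tables, for offline work and testing) and [interMineResolver()] (a
#' live InterMine web service).
#'
#' @name Resolver-class
#' @aliases Resolver LocalResolver-class InterMineResolver-class
#' @exportClass Resolver
setClass("Resolver", representation("VIRTUAL"))

#' @slot organism the organism the local tables describe.
#' @slot mapping data.frame `submitted_id`, `primary_identifier`, `symbol`,
#'   `secondary_identifier`.
#' @slot interactions data.frame `id_a`, `id_b` (primary identifiers),
#'   `kind` (`genetic` or `physical`).
#' @rdname Resolver-class
#' @exportClass LocalResolver
setClass("LocalResolver", contains = "Resolver",
  representation(organism = "character", mapping = "data.frame",
                 interactions = "data.frame"))

setValidity("LocalResolver", function(object) {
  msg <- character(0)
  if (!all(c("submitted_id", "primary_identifier", "symbol",
             "secondary_identifier") %in% names(object@mapping)))
    msg <- c(msg, paste("mapping must have columns submitted_id,",
                        "primary_identifier, symbol, secondary_identifier"))
  if (!all(c("id_a", "id_b", "kind") %in% names(object@interactions)))
    msg <- c(msg, "interactions must have columns id_a, id_b, kind")
  else if (nrow(object@interactions) &&
           !all(object@interactions$kind %in% c("genetic", "physical")))
    msg <- c(msg, "interaction kind must be 'genetic' or 'physical'")
  if (length(msg)) msg else TRUE
})

#' @slot registry named character vector mapping organism binomial name to
#'   an InterMine service base URL (e.g. Drosophila melanogaster to the
#'   FlyMine endpoint).
#' @slot batchSize number of identifiers per service query.
#' @rdname Resolver-class
#' @exportClass InterMineResolver
setClass("InterMineResolver", contains = "Resolver",
  representation(registry = "character", batchSize = "numeric"))

#' ExpressionClassification: genes split at an expression threshold
#'
#' Result of [classifyHighExpression()]: the input expression values, the
#' threshold, and the derived set of "highly expressed" identifiers (value
#' greater than or equal to the threshold, boundary included).
#'
#' @slot values named numeric vector of expression levels (e.g. RPKM),
#'   names are primary identifiers.
#' @slot threshold classification threshold (same units as `values`).
#' @slot highSet identifiers with `value >= threshold`.
#'
#' @exportClass ExpressionClassification
setClass("ExpressionClassification",
  representation(values = "numeric", threshold = "numeric",
                 highSet = "character"))

setValidity("ExpressionClassification", function(object) {
  ok <- names(object@values)[object@values >= object@threshold]
  if (!setequal(object@highSet, ok))
    "highSet must be exactly the identifiers with value >= threshold"
  else TRUE
})

#' CoTargetPartition: targets grouped by the set of cores regulating them
#'
#' Maps every non-core node that receives at least one inbound core edge to
#' the exact set of cores targeting it. Blocks are pairwise disjoint and
#' exhaustive over core-targeted nodes. Block names are the sorted core
#' primary identifiers joined with `"+"`.
#'
#' @slot blocks named list; each element a character vector of target
#'   primary identifiers.
#'
#' @exportClass CoTargetPartition
setClass("CoTargetPartition", representation(blocks = "list"))

setValidity("CoTargetPartition", function(object) {
  all_ids <- unlist(object@blocks, use.names = FALSE)
  if (anyDuplicated(all_ids))
    "blocks must be pairwise disjoint"
  else TRUE
})
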