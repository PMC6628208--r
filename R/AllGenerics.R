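#' Validate a core gene symbol against the resolver
#'
#' Looks the typed core gene symbol up in the backend and returns its node
#' record. An unknown symbol is a fatal error: the wheel cannot be built
#' without a resolvable hub. Matching is exact first; if that fails and
#' `caseInsensitive = TRUE` (the default), a case-insensitive match is
#' accepted with a warning, since symbols are often typed in lowercase
#' ("esg", "cic") while database symbols vary in case.
#'
#' @param backend a [Resolver][Resolver-class] backend.
#' @param organism organism binomial name, e.g. `"Drosophila melanogaster"`.
#' @param symbol the typed core gene symbol.
#' @param caseInsensitive fall back to case-insensitive matching (with a
#'   warning) when the exact match fails.
#' @return one-row node data.frame (`primary`, `symbol`, `secondary`,
#'   `organism`).
#' @export
setGeneric("validateCoreSymbol",
  function(backend, organism, symbol, caseInsensitive = TRUE)
    standardGeneric("validateCoreSymbol"))

#' Update submitted identifiers to current primary identifiers
#'
#' Resolves each submitted identifier through the backend, preserving input
#' order and de-duplicating on the resolved primary identifier (first
#' occurrence wins). Unresolvable inputs are always reported in the
#' `unresolved` component, never silently dropped; when `passThrough = TRUE`
#' (the default) they are additionally kept as pass-through node records
#' whose primary identifier is the submitted text, so network sizes stay
#' stable.
#'
#' @inheritParams validateCoreSymbol
#' @param ids character vector of submitted identifiers.
#' @param passThrough keep unresolved identifiers as pass-through nodes.
#' @return list with `nodes` (data.frame `primary`, `symbol`, `secondary`,
#'   `organism`) and `unresolved` (character vector of submitted texts).
#' @export
setGeneric("resolveIdentifiers",
  function(backend, organism, ids, passThrough = TRUE)
    standardGeneric("resolveIdentifiers"))

#' Retrieve curated genetic and physical interactions
#'
#' Fetches every curated interaction involving any of the queried nodes and
#' de-duplicates on (unordered pair, kind). Each record keeps the query gene
#' that retrieved it, so the emitted edge direction is query gene -> partner
#' (the curated data assert no biological direction).
#'
#' @inheritParams validateCoreSymbol
#' @param nodes data.frame of resolved node records (as returned by
#'   [resolveIdentifiers()]); the `primary` column is queried.
#' @return data.frame with columns `query`, `partner`, `partner_symbol`,
#'   `partner_secondary`, `kind` (`genetic`/`physical`), `provenance`.
#' @export
setGeneric("fetchInteractions",
  function(backend, organism, nodes) standardGeneric("fetchInteractions"))

#' @describeIn Network-class node table accessor.
#' @param x a `Network`.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @describeIn Network-class edge table accessor.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @describeIn Network-class core primary identifiers.
#' @export
setGeneric("cores", function(x) standardGeneric("cores"))

#' @describeIn Network-class organism binomial name.
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))

#' @describeIn CoTargetPartition-class named list of blocks.
#' @param x a `CoTargetPartition`.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @describeIn ExpressionClassification-class the derived high-expression set.
#' @param x an `ExpressionClassification`.
#' @export
setGeneric("highSet", function(x) standardGeneric("highSet"))
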