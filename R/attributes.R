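#' Load Discrete/Continuous attribute columns from a table
#'
#' Reads a valued attribute table (e.g. per-gene RPKM from an RNA-seq
#' study): one mapping column of gene/protein identifiers, plus any number
#' of value columns. Identifiers in the mapping column are updated through
#' the backend so they key onto the same primary identifiers the network
#' uses. Only the columns named in `keep` are retained — clearing a column's
#' name excludes it from processing. When the same identifier occurs twice,
#' the last value wins, with a warning.
#'
#' @param table a [RawTable-class].
#' @param mappingCol the identifier column (index or header name).
#' @param keep named vector of columns to retain: names are the attribute
#'   names under which the columns are emitted, values are column indices or
#'   header names. An unnamed entry keeps the column under its own header.
#' @param backend a [Resolver][Resolver-class].
#' @param organism organism binomial name.
#' @return named list of attribute value maps (named character vectors,
#'   names = primary identifiers), one per kept column, tagged with
#'   `type = "valued"`.
#' @export
loadValuedAttributes <- function(table, mappingCol, keep, backend,
                                 organism) {
  if (length(keep) == 0L)
    stop("at least one value column must be kept")
  kidx <- resolveColumns(table, keep)
  knames <- names(keep)
  if (is.null(knames)) knames <- rep("", length(keep))
  knames[!nzchar(knames)] <- table@headers[kidx[!nzchar(knames)]]
  midx <- resolveColumns(table, mappingCol)[1L]
  ids <- trimws(table@cells[, midx])
  rows <- which(nzchar(ids))
  if (length(rows) == 0L)
    stop("mapping column \"", table@headers[midx], "\" is empty")
  res <- resolveIdentifiers(backend, organism, ids[rows],
                            passThrough = TRUE)
  # per-row primary: re-map each row (resolveIdentifiers de-duplicates)
  prim <- mapSubmitted(backend, ids[rows], res)
  out <- vector("list", length(kidx))
  names(out) <- knames
  for (j in seq_along(kidx)) {
    vals <- table@cells[rows, kidx[j]]
    if (anyDuplicated(prim))
      warning("duplicate identifier rows in attribute table; last value wins")
    v <- vals
    names(v) <- prim
    v <- v[!duplicated(prim, fromLast = TRUE)]
    out[[j]] <- structure(v, type = "valued")
  }
  out
}

# row-wise submitted -> primary, using the resolver's mapping when the
# backend is local, otherwise falling back to the resolved record list
mapSubmitted <- function(backend, submitted, res) {
  if (is(backend, "LocalResolver")) {
    pos <- match(submitted, backend@mapping$submitted_id)
    ifelse(is.na(pos), submitted,
           backend@mapping$primary_identifier[pos])
  } else {
    pos <- match(submitted, res$nodes$primary)
    ifelse(is.na(pos), submitted, res$nodes$primary[pos])
  }
}

#' Load a List attribute from a membership table
#'
#' A List attribute is a gene list sharing some property (a GO category, a
#' gene family, genes with available reagents, ...). The named column is
#' read as the member list and resolved through the backend; the attribute
#' is emitted as literal `true`/`false` per network node. Members absent
#' from the network are retained in the attribute and simply unmatched at
#' emission time.
#'
#' @param table a [RawTable-class].
#' @param memberCol the column holding member identifiers.
#' @param attrName the user-typed attribute label (non-empty), e.g.
#'   `"ISC Homeostasis"`.
#' @inheritParams loadValuedAttributes
#' @return a named list of length one: a character vector of resolved member
#'   primary identifiers tagged with `type = "list"`.
#' @export
loadListAttribute <- function(table, memberCol, attrName, backend,
                              organism) {
  if (!nzchar(attrName)) stop("the attribute must be named")
  idx <- resolveColumns(table, memberCol)[1L]
  ids <- trimws(table@cells[, idx])
  ids <- ids[nzchar(ids)]   # an empty member column is a valid (empty) list
  members <- if (length(ids))
    resolveIdentifiers(backend, organism, ids, passThrough = TRUE)$nodes$primary
  else character(0)
  out <- list(structure(unique(members), type = "list"))
  names(out) <- attrName
  out
}

#' Write the all-in-one node attribute CSV
#'
#' Emits one row per network node — never more, never fewer — with the
#' node's primary identifier in the first column, `Mapping Key`, which is
#' the column Cytoscape joins on. List attributes are written as literal
#' `true`/`false`; valued attributes as the stored text, or an empty cell
#' for nodes absent from the attribute table (Cytoscape's default style
#' then applies to them).
#'
#' @param net a [Network-class] supplying the mapping-key nodes.
#' @param attributes named list of attributes in load order, as returned by
#'   [loadValuedAttributes()] / [loadListAttribute()] (concatenate with
#'   `c()`). Attribute names must be unique.
#' @param path output path.
#' @return the path, invisibly.
#' @export
emitAttributeCsv <- function(net, attributes, path) {
  if (anyDuplicated(names(attributes)))
    stop("duplicate attribute name: ",
         names(attributes)[duplicated(names(attributes))][1L])
  keys <- net@nodes$primary
  cols <- lapply(attributes, function(a) {
    if (identical(attr(a, "type"), "list"))
      ifelse(keys %in% a, "true", "false")
    else {
      v <- unname(a[keys])
      v[is.na(v)] <- ""
      v
    }
  })
  rows <- lapply(seq_along(keys), function(i)
    c(keys[i], vapply(cols, `[`, character(1), i)))
  writeCsvLines(c(list(c("Mapping Key", names(attributes))), rows), path)
}
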