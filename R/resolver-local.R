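#' Deterministic local resolver backend
#'
#' Builds a [Resolver][Resolver-class] backend from two local CSV tables, so
#' identifier updating and interaction retrieval work offline and are pure
#' functions of the table contents. The mapping table has columns
#' `submitted_id`, `primary_identifier`, `symbol`, `secondary_identifier`
#' (one row per submitted alias; a current identifier maps to itself). The
#' interaction table has columns `id_a`, `id_b`, `kind`, where identifiers
#' are primary identifiers and `kind` is `genetic` or `physical`.
#'
#' @param mapping data.frame, or path to the mapping CSV.
#' @param interactions data.frame, or path to the interaction CSV; may be
#'   omitted when only identifier resolution is needed.
#' @param organism organism binomial name the tables describe.
#' @return a `LocalResolver`.
#' @examples
#' map <- data.frame(submitted_id = c("OLD1", "FB2"),
#'                   primary_identifier = c("FB1", "FB2"),
#'                   symbol = c("esg", "cic"),
#'                   secondary_identifier = c("CG3758", ""))
#' be <- localResolver(map, organism = "Drosophila melanogaster")
#' resolveIdentifiers(be, "Drosophila melanogaster", c("OLD1", "FB2"))
#' @export
localResolver <- function(mapping, interactions = NULL,
                          organism = "Drosophila melanogaster") {
  if (is.character(mapping))
    mapping <- tableAsDf(readTable(mapping, hasHeader = TRUE))
  if (is.null(interactions)) {
    interactions <- data.frame(id_a = character(0), id_b = character(0),
                               kind = character(0), stringsAsFactors = FALSE)
  } else if (is.character(interactions)) {
    interactions <- tableAsDf(readTable(interactions, hasHeader = TRUE))
  }
  new("LocalResolver", organism = organism,
      mapping = as.data.frame(mapping, stringsAsFactors = FALSE),
      interactions = as.data.frame(interactions, stringsAsFactors = FALSE))
}

tableAsDf <- function(table) {
  df <- as.data.frame(table@cells, stringsAsFactors = FALSE)
  names(df) <- table@headers
  df
}

checkOrganism <- function(backend, organism) {
  if (!identical(organism, backend@organism))
    stop("unknown organism \"", organism, "\" (backend serves \"",
         backend@organism, "\")")
}

setMethod("validateCoreSymbol", "LocalResolver",
  function(backend, organism, symbol, caseInsensitive = TRUE) {
    checkOrganism(backend, organism)
    map <- backend@mapping
    hit <- which(map$symbol == symbol)
    if (!length(hit) && caseInsensitive) {
      hit <- which(tolower(map$symbol) == tolower(symbol))
      if (length(hit))
        warning("symbol \"", symbol, "\" matched \"",
                map$symbol[hit[1L]], "\" case-insensitively")
    }
    if (!length(hit))
      stop("unknown core gene symbol: \"", symbol, "\"")
    r <- map[hit[1L], ]
    data.frame(primary = r$primary_identifier, symbol = r$symbol,
               secondary = r$secondary_identifier, organism = organism,
               stringsAsFactors = FALSE)
  })

setMethod("resolveIdentifiers", "LocalResolver",
  function(backend, organism, ids, passThrough = TRUE) {
    checkOrganism(backend, organism)
    stopifnot(length(ids) > 0L)
    map <- backend@mapping
    pos <- match(ids, map$submitted_id)
    resolved <- !is.na(pos)
    unresolved <- unique(ids[!resolved])
    if (length(unresolved))
      warning(length(unresolved), " identifier(s) could not be resolved: ",
              paste(utils::head(unresolved, 5L), collapse = ", "),
              if (length(unresolved) > 5L) ", ..." else "")
    recs <- data.frame(
      primary = ifelse(resolved, map$primary_identifier[pos], ids),
      symbol = ifelse(resolved, map$symbol[pos], ids),
      secondary = ifelse(resolved, map$secondary_identifier[pos], ""),
      organism = organism, stringsAsFactors = FALSE)
    if (!passThrough) recs <- recs[resolved, , drop = FALSE]
    recs <- recs[!duplicated(recs$primary), , drop = FALSE]
    rownames(recs) <- NULL
    list(nodes = recs, unresolved = unresolved)
  })

setMethod("fetchInteractions", "LocalResolver",
  function(backend, organism, nodes) {
    checkOrganism(backend, organism)
    tab <- backend@interactions
    queried <- nodes$primary
    touch_a <- tab$id_a %in% queried
    touch_b <- tab$id_b %in% queried
    hit <- tab[touch_a | touch_b, , drop = FALSE]
    if (nrow(hit) == 0L) return(emptyInteractions())
    # query gene = the queried endpoint (id_a preferred when both queried)
    a_is_query <- hit$id_a %in% queried
    query <- ifelse(a_is_query, hit$id_a, hit$id_b)
    partner <- ifelse(a_is_query, hit$id_b, hit$id_a)
    lo <- pmin(hit$id_a, hit$id_b)
    hi <- pmax(hit$id_a, hit$id_b)
    keep <- !duplicated(paste(lo, hi, hit$kind, sep = "\r"))
    query <- query[keep]; partner <- partner[keep]; kind <- hit$kind[keep]
    map <- backend@mapping
    ppos <- match(partner, map$primary_identifier)
    data.frame(
      query = query, partner = partner,
      partner_symbol = ifelse(is.na(ppos), partner, map$symbol[ppos]),
      partner_secondary = ifelse(is.na(ppos), "",
                                 map$secondary_identifier[ppos]),
      kind = kind, provenance = "local", stringsAsFactors = FALSE)
  })

emptyInteractions <- function() {
  data.frame(query = character(0), partner = character(0),
             partner_symbol = character(0), partner_secondary = character(0),
             kind = character(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

setMethod("show", "LocalResolver", function(object) {
  cat("LocalResolver for", object@organism, "\n")
  cat("  mapping entries:", nrow(object@mapping), "\n")
  cat("  interactions:", nrow(object@interactions), "\n")
})
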