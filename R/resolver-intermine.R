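#' Live InterMine web-service backend
#'
#' A [Resolver][Resolver-class] backend that queries an InterMine data
#' warehouse (FlyMine and relatives) over its JSON web-service interface:
#' gene lookup for symbol validation and identifier updating, and the
#' curated genetic/physical interaction tables. Queries are batched and
#' retried once on failure; a service that stays unreachable raises an error
#' distinct from an unknown-symbol error, so callers can tell a spelling
#' mistake from an outage. Requires network access and the \pkg{jsonlite}
#' package; for offline or reproducible work use [localResolver()].
#'
#' @param registry named character vector mapping organism binomial name to
#'   a mine base URL; the default registers FlyMine for
#'   *Drosophila melanogaster*. Endpoints move, so the registry is plain
#'   data the caller can edit.
#' @param batchSize identifiers per LOOKUP query.
#' @return an `InterMineResolver`.
#' @export
interMineResolver <- function(
    registry = c("Drosophila melanogaster" =
                   "https://www.flymine.org/flymine/service"),
    batchSize = 200) {
  new("InterMineResolver", registry = registry, batchSize = batchSize)
}

mineUrl <- function(backend, organism) {
  if (!organism %in% names(backend@registry))
    stop("unknown organism \"", organism, "\": not in the mine registry")
  backend@registry[[organism]]
}

# POST a PathQuery XML, return the parsed results table; one retry.
mineQuery <- function(base, queryXml) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the live InterMine backend requires the 'jsonlite' package")
  u <- paste0(base, "/query/results?format=json&query=",
              utils::URLencode(queryXml, reserved = TRUE))
  fetch <- function() {
    con <- url(u, open = "rb")
    on.exit(close(con))
    jsonlite::fromJSON(rawToChar(readBin(con, "raw", 8e6)),
                       simplifyMatrix = TRUE)
  }
  res <- tryCatch(fetch(), error = function(e) {
    Sys.sleep(1)
    tryCatch(fetch(), error = function(e2)
      stop("InterMine service unreachable at ", base, ": ",
           conditionMessage(e2)))
  })
  res$results
}

geneViewXml <- function(organism, constraint) {
  paste0('<query model="genomic" view="Gene.primaryIdentifier ',
         'Gene.symbol Gene.secondaryIdentifier" constraintLogic="A and B">',
         '<constraint path="Gene.organism.name" op="=" code="B" value="',
         organism, '"/>', constraint, '</query>')
}

lookupGenes <- function(backend, organism, ids) {
  base <- mineUrl(backend, organism)
  out <- NULL
  for (chunk in split(ids, ceiling(seq_along(ids) / backend@batchSize))) {
    cons <- paste0('<constraint path="Gene" op="LOOKUP" code="A" value="',
                   paste(chunk, collapse = ","), '"/>')
    rows <- mineQuery(base, geneViewXml(organism, cons))
    if (length(rows)) out <- rbind(out, as.matrix(rows))
  }
  out
}

setMethod("validateCoreSymbol", "InterMineResolver",
  function(backend, organism, symbol, caseInsensitive = TRUE) {
    rows <- lookupGenes(backend, organism, symbol)
    if (is.null(rows) || nrow(rows) == 0L)
      stop("unknown core gene symbol: \"", symbol, "\"")
    if (!caseInsensitive) {
      exact <- rows[, 2L] == symbol
      if (!any(exact)) stop("unknown core gene symbol: \"", symbol, "\"")
      rows <- rows[exact, , drop = FALSE]
    } else if (!any(rows[, 2L] == symbol)) {
      warning("symbol \"", symbol, "\" matched \"", rows[1L, 2L],
              "\" case-insensitively")
    }
    data.frame(primary = rows[1L, 1L], symbol = rows[1L, 2L],
               secondary = naToEmpty(rows[1L, 3L]), organism = organism,
               stringsAsFactors = FALSE)
  })

setMethod("resolveIdentifiers", "InterMineResolver",
  function(backend, organism, ids, passThrough = TRUE) {
    stopifnot(length(ids) > 0L)
    rows <- lookupGenes(backend, organism, ids)
    found <- if (is.null(rows)) character(0) else rows[, 1L]
    # LOOKUP does not echo the submitted alias; treat inputs that match no
    # returned primary/symbol/secondary as unresolved
    known <- if (is.null(rows)) character(0) else as.vector(rows)
    unresolved <- unique(ids[!ids %in% known])
    recs <- if (is.null(rows)) emptyNodes() else
      data.frame(primary = rows[, 1L], symbol = rows[, 2L],
                 secondary = naToEmpty(rows[, 3L]), organism = organism,
                 stringsAsFactors = FALSE)
    if (passThrough && length(unresolved))
      recs <- rbind(recs, data.frame(primary = unresolved,
                                     symbol = unresolved, secondary = "",
                                     organism = organism,
                                     stringsAsFactors = FALSE))
    if (length(unresolved))
      warning(length(unresolved), " identifier(s) could not be resolved")
    recs <- recs[!duplicated(recs$primary), , drop = FALSE]
    rownames(recs) <- NULL
    list(nodes = recs, unresolved = unresolved)
  })

setMethod("fetchInteractions", "InterMineResolver",
  function(backend, organism, nodes) {
    base <- mineUrl(backend, organism)
    out <- emptyInteractions()
    for (chunk in split(nodes$primary,
                        ceiling(seq_len(nrow(nodes)) / backend@batchSize))) {
      xml <- paste0(
        '<query model="genomic" view="Gene.primaryIdentifier ',
        'Gene.interactions.participant2.primaryIdentifier ',
        'Gene.interactions.participant2.symbol ',
        'Gene.interactions.participant2.secondaryIdentifier ',
        'Gene.interactions.details.relationshipType" ',
        'constraintLogic="A and B">',
        '<constraint path="Gene.primaryIdentifier" op="ONE OF" code="A">',
        paste0('<value>', chunk, '</value>', collapse = ""),
        '</constraint>',
        '<constraint path="Gene.organism.name" op="=" code="B" value="',
        organism, '"/></query>')
      rows <- tryCatch(mineQuery(base, xml), error = function(e) {
        warning("interaction fetch failed for a batch: ",
                conditionMessage(e))
        NULL
      })
      if (length(rows)) {
        rows <- as.matrix(rows)
        kind <- tolower(rows[, 5L])
        ok <- kind %in% c("genetic", "physical")
        rows <- rows[ok, , drop = FALSE]; kind <- kind[ok]
        out <- rbind(out, data.frame(
          query = rows[, 1L], partner = rows[, 2L],
          partner_symbol = naToEmpty(rows[, 3L]),
          partner_secondary = naToEmpty(rows[, 4L]),
          kind = kind, provenance = "intermine",
          stringsAsFactors = FALSE))
      }
    }
    lo <- pmin(out$query, out$partner)
    hi <- pmax(out$query, out$partner)
    out <- out[!duplicated(paste(lo, hi, out$kind, sep = "\r")), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })

naToEmpty <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

setMethod("show", "InterMineResolver", function(object) {
  cat("InterMineResolver\n")
  for (org in names(object@registry))
    cat(" ", org, "->", object@registry[[org]], "\n")
})
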