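#' Read a delimited text table
#'
#' Reads a comma-separated file (RFC 4180; a UTF-8 byte-order mark is
#' tolerated) into a [RawTable-class]. All cells are kept as text. Rows
#' shorter than the header are padded with empty cells; rows longer than the
#' header are rejected. When the file has no header row, column names
#' `col_1` .. `col_N` are synthesized; duplicate header names get `_2`,
#' `_3`, ... suffixes so downstream column addressing is unambiguous.
#'
#' @param path path to a CSV file.
#' @param hasHeader `TRUE` if the values in the first row should be used as
#'   column headers and excluded from the data.
#' @return a [RawTable-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("GeneID,Score", "FBgn01,3.5", "FBgn02,1.2"), tf)
#' tab <- readTable(tf, hasHeader = TRUE)
#' headers(tab)
#' previewRows(tab)
#' @export
readTable <- function(path, hasHeader) {
  if (!file.exists(path)) stop("file not found: ", path)
  widths <- utils::count.fields(path, sep = ",", quote = "\"",
                                blank.lines.skip = TRUE)
  if (is.null(widths) || length(widths) == 0L)
    stop("empty file: ", path)
  ncol <- widths[1L]
  too_wide <- which(widths > ncol)
  if (length(too_wide))
    stop("row ", too_wide[1L], " of ", path, " has ", widths[too_wide[1L]],
         " cells but the first row has only ", ncol)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         fill = TRUE, blank.lines.skip = TRUE,
                         na.strings = character(0),
                         fileEncoding = "UTF-8-BOM",
                         check.names = FALSE, quote = "\"")
  raw <- as.matrix(raw)
  dimnames(raw) <- NULL
  raw[is.na(raw)] <- ""
  raw <- raw[, seq_len(ncol), drop = FALSE]
  if (hasHeader) {
    headers <- as.character(raw[1L, ])
    cells <- raw[-1L, , drop = FALSE]
  } else {
    headers <- paste0("col_", seq_len(ncol))
    cells <- raw
  }
  new("RawTable", headers = dedupHeaders(headers), cells = cells,
      sourcePath = path)
}

# "a","b","a" -> "a","b","a_2": suffix by occurrence count
dedupHeaders <- function(headers) {
  counts <- integer(0)
  vapply(headers, function(h) {
    k <- counts[h]
    if (is.na(k) || is.null(k)) k <- 0L
    counts[h] <<- k + 1L
    if (k == 0L) h else paste0(h, "_", k + 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' @describeIn readTable column names of a table.
#' @param table a [RawTable-class].
#' @export
headers <- function(table) table@headers

#' @describeIn readTable number of data rows.
#' @export
tableRowCount <- function(table) nrow(table@cells)

#' Preview the first rows of a table
#'
#' Returns a read-only copy of the first `min(n, rows)` data rows, the way
#' the upload preview shows column headers and the first five rows for the
#' user to pick the relevant column from.
#'
#' @param table a [RawTable-class].
#' @param n maximum number of rows (default 5).
#' @return character matrix with the table's headers as column names.
#' @export
previewRows <- function(table, n = 5) {
  stopifnot(n >= 1)
  k <- min(n, nrow(table@cells))
  out <- table@cells[seq_len(k), , drop = FALSE]
  colnames(out) <- table@headers
  out
}

resolveColumns <- function(table, cols) {
  if (is.character(cols)) {
    idx <- match(cols, table@headers)
    if (anyNA(idx))
      stop("unknown column(s): ", paste(cols[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(cols)
    if (any(idx < 1L) || any(idx > length(table@headers)))
      stop("column index out of range (table has ",
           length(table@headers), " columns)")
    idx
  }
}

#' Extract identifiers from selected columns
#'
#' Returns the cell values of the selected column(s) in row order (columns
#' concatenated in selection order), with surrounding whitespace stripped
#' and blank cells dropped.
#'
#' @param table a [RawTable-class].
#' @param columns column indices (1-based) or header names; at least one.
#' @return character vector of identifiers.
#' @export
extractIdentifiers <- function(table, columns) {
  if (length(columns) == 0L) stop("at least one column must be selected")
  idx <- resolveColumns(table, columns)
  out <- trimws(as.character(table@cells[, idx]))
  out <- out[nzchar(out)]
  if (length(out) == 0L && nrow(table@cells) > 0L)
    stop("selected column(s) ",
         paste(table@headers[idx], collapse = ", "), " contain no values")
  out
}

#' Keep only identifiers present in every technical replicate
#'
#' Screens often report putative targets per technical replicate; a common
#' pre-processing step keeps only targets identified in all replicates. A
#' replicate cell is "present" when non-blank. Output preserves input row
#' order and de-duplicates keeping the first occurrence.
#'
#' @param table a [RawTable-class].
#' @param replicateCols columns holding per-replicate presence marks or
#'   values (indices or header names).
#' @param idCol the identifier column.
#' @return character vector of identifiers present in every replicate.
#' @export
replicateIntersectionFilter <- function(table, replicateCols, idCol) {
  if (length(replicateCols) == 0L)
    stop("at least one replicate column is required")
  rep_idx <- resolveColumns(table, replicateCols)
  id_idx <- resolveColumns(table, idCol)[1L]
  if (nrow(table@cells) == 0L) return(character(0))
  present <- nzchar(trimws(table@cells[, rep_idx, drop = FALSE]))
  dim(present) <- c(nrow(table@cells), length(rep_idx))
  keep <- rowSums(present) == length(rep_idx)
  ids <- trimws(table@cells[keep, id_idx])
  ids <- ids[nzchar(ids)]
  unique(ids)
}

#' Top-n identifiers by mean value across replicates
#'
#' Computes the row mean over the value columns (e.g. signal-to-background
#' ratios across technical replicates), ranks rows by descending mean, and
#' returns the identifiers of the top `n` rows. Ties are broken by input row
#' order (earlier row wins).
#'
#' @param table a [RawTable-class].
#' @param valueCols numeric columns to average (indices or header names).
#' @param idCol the identifier column.
#' @param n number of identifiers to return; when `n` is at least the row
#'   count, all identifiers are returned sorted by mean.
#' @return character vector of identifiers, descending mean.
#' @export
topNByMean <- function(table, valueCols, idCol, n) {
  stopifnot(n >= 1)
  val_idx <- resolveColumns(table, valueCols)
  id_idx <- resolveColumns(table, idCol)[1L]
  if (nrow(table@cells) == 0L) return(character(0))
  vals <- matrix(NA_real_, nrow(table@cells), length(val_idx))
  for (j in seq_along(val_idx)) {
    raw <- trimws(table@cells[, val_idx[j]])
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw))
    if (length(bad))
      stop("non-numeric value \"", raw[bad[1L]], "\" in row ", bad[1L],
           ", column ", table@headers[val_idx[j]])
    vals[, j] <- v
  }
  means <- rowMeans(vals)
  ord <- order(-means, seq_along(means))
  ids <- trimws(table@cells[ord, id_idx])
  ids[seq_len(min(n, length(ids)))]
}

# RFC 4180: quote a field iff it contains a comma, quote or line break;
# embedded quotes doubled.
csvQuote <- function(x) {
  x <- as.character(x)
  needs <- grepl('[",\r\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

writeCsvLines <- function(cellRows, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(cellRows,
                  function(r) paste(csvQuote(r), collapse = ","),
                  character(1))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a table back to CSV
#'
#' Writes headers then rows, RFC 4180 quoting, UTF-8 without a byte-order
#' mark. `writeTable(readTable(p, TRUE), q)` round-trips headers and cells.
#'
#' @param table a [RawTable-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTable <- function(table, path) {
  rows <- c(list(table@headers),
            lapply(seq_len(nrow(table@cells)),
                   function(i) table@cells[i, ]))
  writeCsvLines(rows, path)
}

#' Build a RawTable in memory
#'
#' Mostly useful for tests and programmatic pipelines; equivalent to writing
#' a CSV and reading it back.
#'
#' @param cells character matrix (or something coercible).
#' @param headers column names; synthesized when `NULL`.
#' @return a [RawTable-class].
#' @export
rawTable <- function(cells, headers = NULL) {
  cells <- as.matrix(cells)
  mode(cells) <- "character"
  cells[is.na(cells)] <- ""
  if (is.null(headers)) headers <- paste0("col_", seq_len(ncol(cells)))
  dimnames(cells) <- NULL
  new("RawTable", headers = dedupHeaders(as.character(headers)),
      cells = cells, sourcePath = "")
}

setMethod("show", "RawTable", function(object) {
  cat("RawTable:", nrow(object@cells), "rows x",
      length(object@headers), "columns\n")
  cat("  headers:", paste(object@headers, collapse = ", "), "\n")
  if (nzchar(object@sourcePath))
    cat("  source:", object@sourcePath, "\n")
})
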