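# Small in-code fixtures shared across test files.

ORG <- "Drosophila melanogaster"

# deterministic local backend: cores A/B (+C) and plain targets t1..t9,
# one stale alias OLD_t1 -> t1
toyBackend <- function(interactions = NULL) {
  ids <- paste0("t", 1:9)
  mapping <- data.frame(
    submitted_id = c("OLD_t1", ids, "FBcoreA", "FBcoreB", "FBcoreC"),
    primary_identifier = c("t1", ids, "FBcoreA", "FBcoreB", "FBcoreC"),
    symbol = c("t1", ids, "esg", "cic", "tis11"),
    secondary_identifier = c("CG_t1", paste0("CG_", ids),
                             "CG_A", "CG_B", "CG_C"),
    stringsAsFactors = FALSE)
  localResolver(mapping, interactions, organism = ORG)
}

toyWheel <- function(core = "esg", targets = c("t1", "t2"),
                     technique = "DamID", name = paste0(core, "-ds"),
                     backend = toyBackend()) {
  buildWheel(newDataset(name, ORG, core, technique, targets), backend)
}

writeCsv <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

# build a Network directly from an edge list like c("a->b", "b->c")
edgeNet <- function(arrows, type = "DamID", cores = character(0)) {
  parts <- strsplit(unique(arrows), "->", fixed = TRUE)
  src <- vapply(parts, `[`, character(1), 1)
  tgt <- vapply(parts, `[`, character(1), 2)
  ids <- unique(c(src, tgt, cores))
  nodesDf <- data.frame(primary = ids, symbol = ids,
                        secondary = rep("", length(ids)),
                        organism = rep(ORG, length(ids)),
                        stringsAsFactors = FALSE)
  edgesDf <- data.frame(source = src, target = tgt,
                        interaction_type = rep(type, length(src)),
                        dataset_name = rep("test", length(src)),
                        stringsAsFactors = FALSE)
  new("Network", nodes = nodesDf, edges = edgesDf, cores = cores,
      organism = ORG)
}
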