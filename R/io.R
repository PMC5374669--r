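# Readers and writers for the interchange formats: the graph-spec format
# (JSON, a YAML subset; read back with the yaml parser so hand-written YAML
# parses too) and JASPAR flat PFM records.
#
# Graph-spec schema: top-level `variables` (list of {name, states}),
# `factors` (list of {name, scope, potential}), optional `scores` (list of
# {name, table}). Flat tables are row-major with the LAST scope variable
# varying fastest.

#' Read a graph specification
#'
#' Parses the structured-text interchange format (YAML or JSON) into a
#' [FactorGraph-class] and, when a `scores` block is present, a
#' [ScoreSpec-class]. Flat tables are row-major (last scope variable
#' fastest) and round-trip bit-exactly through [writeGraphSpec()].
#'
#' @param path file path.
#' @return a list with elements `graph` and `score` (`NULL` when the file
#'   carries no scores block).
#' @export
readGraphSpec <- function(path) {
  ## JSON first (bit-exact doubles); fall back to the YAML parser for
  ## hand-written YAML specs
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    tryCatch(yaml::read_yaml(path),
                             error = function(e2)
                               stopf("cannot parse '%s': %s", path,
                                     conditionMessage(e2))))
  if (is.null(doc$variables)) stopf("%s: missing top-level 'variables'", path)
  if (is.null(doc$factors)) stopf("%s: missing top-level 'factors'", path)
  cards <- integer(0)
  for (v in doc$variables) {
    if (is.null(v$name)) stopf("%s: variable entry without 'name'", path)
    if (is.null(v$states))
      stopf("%s: variable '%s' is missing 'states'", path, v$name)
    ## as.character guards against YAML 1.1 scalars (a variable named "y"
    ## parses as a boolean)
    cards[as.character(v$name)] <- as.integer(v$states)
  }
  facs <- list()
  for (fc in doc$factors) {
    if (is.null(fc$name)) stopf("%s: factor entry without 'name'", path)
    if (is.null(fc$scope) || is.null(fc$potential))
      stopf("%s: factor '%s' needs 'scope' and 'potential'", path, fc$name)
    sc <- as.character(unlist(fc$scope))
    if (anyNA(match(sc, names(cards))))
      stopf("%s: factor '%s' scope references undeclared variable", path, fc$name)
    d <- cards[sc]
    flat <- as.numeric(unlist(fc$potential))
    if (length(flat) != prod(d))
      stopf("%s: factor '%s' potential has %d entries, expected %d",
            path, fc$name, length(flat), prod(d))
    facs[[fc$name]] <- list(scope = sc, potential = unflattenRowMajor(flat, d))
  }
  g <- factorGraph(cards, facs)
  score <- NULL
  if (!is.null(doc$scores)) {
    tabs <- list()
    for (se in doc$scores) {
      if (is.null(se$name) || is.null(se$table))
        stopf("%s: score entry needs 'name' and 'table'", path)
      a <- match(se$name, g@facNames)
      if (is.na(a)) stopf("%s: scores reference unknown factor '%s'", path, se$name)
      d <- g@varCards[g@scopes[[a]]]
      flat <- as.numeric(unlist(se$table))
      if (length(flat) != prod(d))
        stopf("%s: score table '%s' has %d entries, expected %d",
              path, se$name, length(flat), prod(d))
      tabs[[se$name]] <- unflattenRowMajor(flat, d)
    }
    if (length(tabs) != length(g@facNames))
      stopf("%s: scores block must cover every factor", path)
    score <- scoreSpec(g, tabs)
  }
  list(graph = g, score = score)
}

#' Write a graph specification
#'
#' Serializes a graph (and optional score spec) to the interchange format
#' as JSON (which any YAML parser also reads). Doubles are written at full
#' precision so that `readGraphSpec(writeGraphSpec(...))` reproduces every
#' table bit-for-bit.
#'
#' @param graph a [FactorGraph-class].
#' @param score optional [ScoreSpec-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGraphSpec <- function(graph, score = NULL, path) {
  doc <- list(
    variables = lapply(seq_along(graph@varNames), function(v)
      list(name = graph@varNames[v], states = graph@varCards[v])),
    factors = lapply(seq_along(graph@facNames), function(a)
      list(name = graph@facNames[a],
           scope = as.list(graph@varNames[graph@scopes[[a]]]),
           potential = flattenRowMajor(graph@potentials[[a]]))))
  if (!is.null(score)) {
    checkScoreMatches(graph, score)
    doc$scores <- lapply(seq_along(graph@facNames), function(a)
      list(name = graph@facNames[a],
           table = flattenRowMajor(score@tables[[a]])))
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a JASPAR flat-format position frequency matrix
#'
#' Parses the JASPAR PFM text dialects: a `>ID name` header followed by
#' four rows in A,C,G,T order, each optionally labelled and optionally
#' bracketed, e.g. `A  [ 4380  20  0 ]` or plain `4380 20 0`.
#'
#' @param path file path.
#' @return a 4 x N numeric count matrix with rownames A,C,G,T and
#'   attributes `id` and `name` from the header (when present).
#' @export
readJasparPfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  id <- NA_character_; nm <- NA_character_
  if (length(lines) && startsWith(lines[1L], ">")) {
    hdr <- strsplit(sub("^>\\s*", "", lines[1L]), "\\s+")[[1L]]
    id <- hdr[1L]; nm <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else NA_character_
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stopf("%s: expected 4 matrix rows", path)
  rows <- vector("list", 4L)
  for (i in 1:4) {
    ln <- trimws(lines[i])
    lab <- sub("^([ACGTacgt])\\s*[:|]?\\s*\\[?.*$", "\\1", ln)
    if (grepl("^[ACGTacgt]\\b", ln) || grepl("^[ACGTacgt]\\s*\\[", ln)) {
      if (toupper(lab) != DNA_ALPHABET[i])
        stopf("%s: row %d labelled '%s', expected '%s' (rows must be A,C,G,T)",
              path, i, toupper(lab), DNA_ALPHABET[i])
      ln <- sub("^[ACGTacgt]", "", ln)
    }
    ln <- gsub("[][]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
    if (anyNA(vals) || !length(vals))
      stopf("%s: cannot parse numeric values on matrix row %d", path, i)
    if (any(vals < 0)) stopf("%s: negative count on row %d", path, i)
    rows[[i]] <- vals
  }
  n <- unique(lengths(rows))
  if (length(n) != 1L)
    stopf("%s: matrix rows have differing lengths (%s)", path,
          paste(lengths(rows), collapse = ", "))
  m <- do.call(rbind, rows)
  rownames(m) <- DNA_ALPHABET
  attr(m, "id") <- id
  attr(m, "name") <- nm
  m
}

#' Read a whitespace/TSV numeric table
#'
#' Utility for probability vectors and transition tables supplied as TSV:
#' plain numeric columns, optional comment lines starting with `#`.
#'
#' @param path file path.
#' @return a numeric matrix (a 1-column matrix for a vector file).
#' @export
readNumericTsv <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE, comment.char = "#"))
  storage.mode(m) <- "double"
  unname(m)
}
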