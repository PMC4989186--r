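#' @include AllClasses.R
NULL

## Read input as lines: accepts a connection, a path (plain or gzip; gzfile
## reads both transparently), or a character vector that is already text.
.readInputLines <- function(x) {
  if (inherits(x, "connection")) {
    on.exit(close(x), add = TRUE)
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    con <- gzfile(x, open = "rt")
    on.exit(close(con), add = TRUE)
    return(readLines(con, warn = FALSE))
  }
  if (is.character(x))
    return(unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE))
  stop("expected a file path, connection, or character text")
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Depth of each taxon below the root; NA signals a cycle.
.taxDepths <- function(nodes) {
  parent <- setNames(nodes$parent, nodes$taxon)
  depth <- setNames(rep(NA_integer_, nrow(nodes)), nodes$taxon)
  root <- nodes$taxon[is.na(nodes$parent)]
  depth[root] <- 0L
  n <- length(depth)
  for (tx in nodes$taxon) {
    if (!is.na(depth[tx])) next
    chain <- character()
    cur <- tx
    steps <- 0L
    while (is.na(depth[cur])) {
      chain <- c(chain, cur)
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (is.na(cur) || steps > n) break  # orphan chain or cycle
    }
    if (!is.na(cur) && !is.na(depth[cur]))
      depth[chain] <- depth[cur] + rev(seq_along(chain))
  }
  depth
}

## ---- ontology graph helpers --------------------------------------------

.buildTermGraph <- function(terms, edges) {
  igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges[, c("child", "parent"), drop = FALSE]
        else data.frame(child = character(), parent = character()),
    directed = TRUE,
    vertices = data.frame(name = terms))
}

#' Resolve term ids through the alt_id alias map
#'
#' @param x an [OntologyGraph-class].
#' @param ids character vector of term ids (canonical or alternative).
#' @return character vector of canonical ids; unknown ids become `NA`.
#' @export
resolveTermIds <- function(x, ids) {
  out <- ids
  isAlt <- ids %in% names(x@altMap)
  out[isAlt] <- x@altMap[ids[isAlt]]
  out[!(out %in% x@terms)] <- NA_character_
  out
}

## reachability over the child->parent graph; ids must be canonical
.termClosure <- function(x, ids, mode) {
  ids <- ids[!is.na(ids)]
  if (!length(ids)) return(character())
  res <- igraph::ego(x@graph, order = igraph::vcount(x@graph),
                     nodes = ids, mode = mode)
  unique(unlist(lapply(res, function(v) v$name), use.names = FALSE))
}

#' Ancestors / descendants of GO terms
#'
#' Closure over the `is_a`/`part_of` DAG. The query terms themselves are
#' included when `includeSelf = TRUE` (the default), matching the cumulative
#' "term or one of its children" counting semantics.
#'
#' @param x an [OntologyGraph-class].
#' @param ids character vector of term ids.
#' @param includeSelf include the query terms in the result.
#' @return character vector (the union over all query terms).
#' @export
termAncestors <- function(x, ids, includeSelf = TRUE) {
  ids <- resolveTermIds(x, ids)
  out <- .termClosure(x, ids, mode = "out")
  if (!includeSelf) out <- setdiff(out, ids)
  out
}

#' @rdname termAncestors
#' @export
termDescendants <- function(x, ids, includeSelf = TRUE) {
  ids <- resolveTermIds(x, ids)
  out <- .termClosure(x, ids, mode = "in")
  if (!includeSelf) out <- setdiff(out, ids)
  out
}

## per-term ancestor sets (self included) as a named list, for bulk closure
.ancestorList <- function(x, ids) {
  ids <- unique(ids)
  res <- igraph::ego(x@graph, order = igraph::vcount(x@graph),
                     nodes = ids, mode = "out")
  setNames(lapply(res, function(v) v$name), ids)
}

## ---- taxonomy helpers ---------------------------------------------------

#' Taxonomy navigation
#'
#' @param x a [TaxonomyTree-class].
#' @param ids character (or coercible) vector of taxon ids.
#' @param includeSelf include the query taxa in the result.
#' @return `taxParent`: parent ids (`NA` for the root); `taxRank` /
#'   `taxName`: rank or scientific-name strings; `taxChildren`: character
#'   vector of direct children; `taxAncestors` / `taxDescendants`: the
#'   closure as a character vector.
#' @export
taxParent <- function(x, ids) {
  p <- setNames(x@nodes$parent, x@nodes$taxon)
  unname(p[as.character(ids)])
}

#' @rdname taxParent
#' @export
taxRank <- function(x, ids) {
  r <- setNames(x@nodes$rank, x@nodes$taxon)
  unname(r[as.character(ids)])
}

#' @rdname taxParent
#' @export
taxName <- function(x, ids) {
  n <- setNames(x@nodes$name, x@nodes$taxon)
  unname(n[as.character(ids)])
}

#' @rdname taxParent
#' @export
taxChildren <- function(x, ids) {
  x@nodes$taxon[x@nodes$parent %in% as.character(ids)]
}

#' @rdname taxParent
#' @export
taxAncestors <- function(x, ids, includeSelf = TRUE) {
  p <- setNames(x@nodes$parent, x@nodes$taxon)
  ids <- as.character(ids)
  out <- if (includeSelf) ids else character()
  cur <- unique(unname(p[ids]))
  cur <- cur[!is.na(cur)]
  while (length(cur)) {
    new <- setdiff(cur, out)
    out <- c(out, new)
    cur <- unique(unname(p[new]))
    cur <- cur[!is.na(cur)]
  }
  unique(out)
}

#' @rdname taxParent
#' @export
taxDescendants <- function(x, ids, includeSelf = TRUE) {
  ids <- as.character(ids)
  out <- if (includeSelf) ids else character()
  cur <- taxChildren(x, ids)
  while (length(cur)) {
    new <- setdiff(cur, out)
    out <- c(out, new)
    cur <- taxChildren(x, new)
  }
  unique(out)
}

#' @rdname taxParent
#' @export
taxRoot <- function(x) x@nodes$taxon[is.na(x@nodes$parent)]
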