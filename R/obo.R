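#' @include AllClasses.R utils.R
NULL

#' Parse an OBO 1.2/1.4 ontology
#'
#' Reads `[Term]` stanzas into an [OntologyGraph-class]. Only `is_a` and
#' `part_of` (via `relationship: part_of`) edges are retained; `alt_id`
#' entries become aliases of the canonical id; obsolete terms are carried but
#' flagged and keep no edges. Cross-namespace integrity and acyclicity are
#' enforced by the class validity check.
#'
#' @param file path (plain or gzip), connection, or OBO text.
#' @return an [OntologyGraph-class].
#' @examples
#' obo <- c("format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: biological_process", "is_a: GO:0000001 ! root")
#' g <- parseOBO(paste(obo, collapse = "\n"))
#' goTerms(g)
#' @export
parseOBO <- function(file) {
  lines <- .readInputLines(file)
  ## locate stanza boundaries
  stanzaStart <- grep("^\\[", lines)
  if (!length(stanzaStart))
    stop("OBO format error: no stanzas found")
  stanzaType <- sub("^\\[([^]]*)\\].*$", "\\1", lines[stanzaStart])
  stanzaEnd <- c(stanzaStart[-1] - 1L, length(lines))

  ids <- character(); nms <- character(); nss <- character()
  obs <- logical(); alt <- list()
  edges <- vector("list", sum(stanzaType == "Term"))
  k <- 0L
  defaultNs <- sub("^default-namespace:\\s*", "",
                   grep("^default-namespace:", lines, value = TRUE)[1])

  for (i in which(stanzaType == "Term")) {
    body <- lines[(stanzaStart[i] + 1L):stanzaEnd[i]]
    body <- body[nzchar(body) & !grepl("^!", body)]
    tags <- sub(":.*$", "", body)
    vals <- sub("^[^:]*:\\s*", "", body)
    vals <- sub("\\s*!.*$", "", vals)        # trailing comments
    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id))
      stop("OBO format error: [Term] stanza without id near line ", stanzaStart[i])
    k <- k + 1L
    ids[k] <- id
    nm <- vals[tags == "name"][1]
    nms[k] <- if (is.na(nm)) "" else nm
    ns <- vals[tags == "namespace"][1]
    nss[k] <- if (is.na(ns)) defaultNs else ns
    obs[k] <- any(tags == "is_obsolete" & vals == "true")
    a <- vals[tags == "alt_id"]
    if (length(a)) alt[[id]] <- a
    if (!obs[k]) {
      isa <- vals[tags == "is_a"]
      rel <- vals[tags == "relationship"]
      po <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
      if (length(isa) || length(po))
        edges[[k]] <- data.frame(
          child = id,
          parent = c(isa, po),
          type = c(rep("is_a", length(isa)), rep("part_of", length(po))),
          stringsAsFactors = FALSE)
    }
  }
  length(ids) <- k; length(nms) <- k; length(nss) <- k; length(obs) <- k
  if (anyDuplicated(ids))
    stop("OBO format error: duplicated term id ",
         ids[duplicated(ids)][1])
  ed <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (is.null(ed))
    ed <- data.frame(child = character(), parent = character(),
                     type = character(), stringsAsFactors = FALSE)
  unknown <- setdiff(ed$parent, ids)
  if (length(unknown))
    stop("OBO integrity error: edges reference unknown terms: ",
         paste(head(unknown, 5), collapse = ", "))

  altMap <- if (length(alt))
    setNames(rep(names(alt), lengths(alt)), unlist(alt, use.names = FALSE))
  else setNames(character(), character())

  gr <- .buildTermGraph(ids, ed)
  isaGraph <- igraph::subgraph_from_edges(
    gr, igraph::E(gr)[seq_len(nrow(ed))][ed$type == "is_a"],
    delete.vertices = FALSE)
  if (!igraph::is_dag(isaGraph))
    stop("OBO integrity error: cyclic is_a relationship detected")
  new("OntologyGraph",
      terms = ids,
      termName = setNames(nms, ids),
      termNamespace = setNames(nss, ids),
      obsolete = setNames(obs, ids),
      edges = ed,
      altMap = altMap,
      graph = gr)
}

#' Write an ontology as OBO text
#'
#' Minimal OBO 1.2 serialisation of an [OntologyGraph-class]; round-trips
#' through [parseOBO()].
#'
#' @param x an [OntologyGraph-class].
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return character vector of OBO lines, invisibly.
#' @export
writeOBO <- function(x, file = NULL) {
  out <- c("format-version: 1.2", "")
  byAlt <- split(names(x@altMap), unname(x@altMap))
  for (id in x@terms) {
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", x@termName[[id]]),
                paste0("namespace: ", x@termNamespace[[id]]))
    if (!is.null(byAlt[[id]]))
      stanza <- c(stanza, paste0("alt_id: ", byAlt[[id]]))
    if (x@obsolete[[id]]) {
      stanza <- c(stanza, "is_obsolete: true")
    } else {
      e <- x@edges[x@edges$child == id, , drop = FALSE]
      if (nrow(e)) {
        isa <- e$parent[e$type == "is_a"]
        po <- e$parent[e$type == "part_of"]
        stanza <- c(stanza,
                    if (length(isa)) paste0("is_a: ", isa),
                    if (length(po)) paste0("relationship: part_of ", po))
      }
    }
    out <- c(out, stanza, "")
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
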