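#' Gene-sharing network thresholds
#'
#' The BLAST-style thresholds used for reciprocal protein similarity:
#' E-value at most 1e-10 (kept permissive so short proteins of < 100 aa
#' are not lost), query coverage of the HSP at least 75 percent, and
#' sequence identity at least 80 percent.
#'
#' @param evalueMax maximum E-value.
#' @param queryCoverageMin minimum HSP coverage of the query, percent.
#' @param identityMin minimum percent identity.
#' @return a named list of thresholds.
#' @export
geneSharingThresholds <- function(evalueMax = 1e-10, queryCoverageMin = 75,
                                  identityMin = 80) {
  stopifnot(evalueMax > 0, queryCoverageMin >= 0, queryCoverageMin <= 100,
            identityMin >= 0, identityMin <= 100)
  list(evalueMax = evalueMax, queryCoverageMin = queryCoverageMin,
       identityMin = identityMin)
}

# one Smith-Waterman per unordered protein pair; thresholds are then
# evaluated in both directions (coverage on the respective query, E-value
# against the respective database size)
.pairHit <- function(a, b, params) {
  localAlign(a, b, params)
}

#' Reciprocally similar protein pairs between two proteomes
#'
#' A pair (a, b) qualifies when the similarity passes all thresholds in
#' both directions: identity, coverage evaluated on each sequence in turn,
#' and the E-value computed against each proteome's total residue count
#' (database-style search space). Qualifying pairs are resolved to a
#' one-to-one matching greedily by descending bit score, so each protein
#' contributes to at most one pair.
#'
#' @param proteomeA,proteomeB named `AAStringSet` (or named character
#'   vectors).
#' @param thresholds from [geneSharingThresholds()].
#' @param params a protein [ScoringParams-class].
#' @return data.frame with columns `protein_a`, `protein_b`,
#'   `identity_percent`, `coverage_a`, `coverage_b`, `bit_score`,
#'   `evalue_ab`, `evalue_ba`.
#' @export
reciprocalPairs <- function(proteomeA, proteomeB,
                            thresholds = geneSharingThresholds(),
                            params = proteinScoringParams()) {
  a <- as.character(proteomeA); names(a) <- names(proteomeA)
  b <- as.character(proteomeB); names(b) <- names(proteomeB)
  stopifnot(length(a) > 0, length(b) > 0,
            !is.null(names(a)), !is.null(names(b)))
  nA <- sum(nchar(a)); nB <- sum(nchar(b))
  rows <- list(); k <- 0L
  for (i in seq_along(a)) for (j in seq_along(b)) {
    h <- .pairHit(a[[i]], b[[j]], params)
    if (nrow(h) == 0L) next
    lenA <- nchar(a[[i]]); lenB <- nchar(b[[j]])
    covA <- 100 * (h$query_end - h$query_start + 1) / lenA
    covB <- 100 * (h$subject_end - h$subject_start + 1) / lenB
    eAB <- karlinEvalue(h$bit_score, lenA, nB)
    eBA <- karlinEvalue(h$bit_score, lenB, nA)
    if (h$identity_percent >= thresholds$identityMin &&
        covA >= thresholds$queryCoverageMin &&
        covB >= thresholds$queryCoverageMin &&
        eAB <= thresholds$evalueMax && eBA <= thresholds$evalueMax) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        protein_a = names(a)[i], protein_b = names(b)[j],
        identity_percent = h$identity_percent, coverage_a = covA,
        coverage_b = covB, bit_score = h$bit_score,
        evalue_ab = eAB, evalue_ba = eBA, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      identity_percent = numeric(), coverage_a = numeric(),
                      coverage_b = numeric(), bit_score = numeric(),
                      evalue_ab = numeric(), evalue_ba = numeric(),
                      stringsAsFactors = FALSE)
  if (!k) return(empty)
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$bit_score, cand$protein_a, cand$protein_b), ,
               drop = FALSE]
  usedA <- character(); usedB <- character(); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$protein_a[i] %in% usedA) && !(cand$protein_b[i] %in% usedB)) {
      keep[i] <- TRUE
      usedA <- c(usedA, cand$protein_a[i])
      usedB <- c(usedB, cand$protein_b[i])
    }
  }
  cand[keep, , drop = FALSE]
}

.newNetwork <- function(nodes, edges) {
  new("PhageNetwork", nodes = nodes, edges = edges)
}

.emptyEdges <- function() {
  data.frame(from = character(), to = character(), weight = integer(),
             pairs = I(list()), stringsAsFactors = FALSE)
}

#' Build a gene-sharing network over whole proteomes
#'
#' Nodes are (pro)phages; an edge connects two phages when they share at
#' least one reciprocally similar protein, and its weight is the count of
#' one-to-one reciprocal pairs (the member pairs are retained on the
#' edge).
#'
#' @param proteomes named list of `AAStringSet`, one per phage.
#' @param thresholds from [geneSharingThresholds()].
#' @param params protein [ScoringParams-class].
#' @param nodeAttrs optional data.frame keyed by `name` with node
#'   attributes (family, host, lifestyle, ...).
#' @return a [PhageNetwork-class].
#' @export
buildPhageNetwork <- function(proteomes,
                              thresholds = geneSharingThresholds(),
                              params = proteinScoringParams(),
                              nodeAttrs = NULL) {
  stopifnot(length(proteomes) >= 2, !is.null(names(proteomes)))
  phages <- names(proteomes)
  edges <- .emptyEdges()
  for (i in seq_len(length(phages) - 1)) for (j in seq(i + 1, length(phages))) {
    rp <- reciprocalPairs(proteomes[[i]], proteomes[[j]], thresholds, params)
    if (nrow(rp)) {
      edges <- rbind(edges, data.frame(
        from = phages[i], to = phages[j], weight = nrow(rp),
        pairs = I(list(paste(rp$protein_a, rp$protein_b, sep = "|"))),
        stringsAsFactors = FALSE))
    }
  }
  nodes <- data.frame(name = phages, stringsAsFactors = FALSE)
  if (!is.null(nodeAttrs))
    nodes <- merge(nodes, nodeAttrs, by = "name", all.x = TRUE, sort = FALSE)
  .newNetwork(nodes, edges)
}

#' Build a marker-gene network
#'
#' One marker protein per phage (integrase, large terminase subunit, major
#' capsid protein, ...); an edge of weight 1 connects two phages whose
#' markers are reciprocally similar under the thresholds. Phages without
#' the marker stay in the network as flagged isolated nodes.
#'
#' @param markers named character vector or `AAStringSet`, at most one
#'   marker per phage; use `NA` for a missing marker.
#' @param thresholds from [geneSharingThresholds()].
#' @param params protein [ScoringParams-class].
#' @return a [PhageNetwork-class] with a `missing_marker` node attribute.
#' @export
buildMarkerNetwork <- function(markers,
                               thresholds = geneSharingThresholds(),
                               params = proteinScoringParams()) {
  m <- as.character(markers)
  names(m) <- names(markers)
  stopifnot(!is.null(names(m)))
  have <- !is.na(m) & nzchar(m)
  phages <- names(m)
  edges <- .emptyEdges()
  hv <- which(have)
  if (length(hv) >= 2) {
    for (ii in seq_len(length(hv) - 1)) for (jj in seq(ii + 1, length(hv))) {
      i <- hv[ii]; j <- hv[jj]
      seta <- stats::setNames(m[i], phages[i])
      setb <- stats::setNames(m[j], phages[j])
      rp <- reciprocalPairs(seta, setb, thresholds, params)
      if (nrow(rp))
        edges <- rbind(edges, data.frame(
          from = phages[i], to = phages[j], weight = 1L,
          pairs = I(list(paste(phages[i], phages[j], sep = "|"))),
          stringsAsFactors = FALSE))
    }
  }
  nodes <- data.frame(name = phages, missing_marker = !have,
                      stringsAsFactors = FALSE)
  .newNetwork(nodes, edges)
}

#' Build a protein-level identity network
#'
#' Nodes are individual proteins; an edge connects two proteins whose
#' pairwise local alignment reaches the identity threshold over at least
#' the coverage threshold of the shorter sequence (the convention for
#' marker-protein diversity networks such as MTase target-class maps).
#'
#' @param proteins named `AAStringSet` (or named character vector).
#' @param identityMin minimum percent identity (default 80).
#' @param coverageMin minimum coverage of the shorter sequence, percent
#'   (default 75).
#' @param params protein [ScoringParams-class].
#' @param nodeAttrs optional data.frame keyed by `name` (e.g. methylation
#'   target classes).
#' @return a [PhageNetwork-class] over proteins.
#' @export
buildProteinIdentityNetwork <- function(proteins, identityMin = 80,
                                        coverageMin = 75,
                                        params = proteinScoringParams(),
                                        nodeAttrs = NULL) {
  p <- as.character(proteins)
  names(p) <- names(proteins)
  stopifnot(length(p) >= 1, !is.null(names(p)))
  edges <- .emptyEdges()
  if (length(p) >= 2) {
    for (i in seq_len(length(p) - 1)) for (j in seq(i + 1, length(p))) {
      h <- localAlign(p[[i]], p[[j]], params)
      if (nrow(h) == 0L) next
      shorter <- min(nchar(p[[i]]), nchar(p[[j]]))
      covQ <- (h$query_end - h$query_start + 1)
      covS <- (h$subject_end - h$subject_start + 1)
      covShort <- 100 * (if (nchar(p[[i]]) <= nchar(p[[j]])) covQ else covS) /
        shorter
      if (h$identity_percent >= identityMin && covShort >= coverageMin)
        edges <- rbind(edges, data.frame(
          from = names(p)[i], to = names(p)[j], weight = 1L,
          pairs = I(list(paste(names(p)[i], names(p)[j], sep = "|"))),
          stringsAsFactors = FALSE))
    }
  }
  nodes <- data.frame(name = names(p), stringsAsFactors = FALSE)
  if (!is.null(nodeAttrs))
    nodes <- merge(nodes, nodeAttrs, by = "name", all.x = TRUE, sort = FALSE)
  .newNetwork(nodes, edges)
}

#' Convert a PhageNetwork to an igraph graph
#'
#' Member pair lists are serialised into a `pairs` edge attribute
#' (semicolon-separated) so every attribute survives file export.
#'
#' @param network a [PhageNetwork-class].
#' @return an undirected `igraph` graph.
#' @export
asIgraph <- function(network) {
  ed <- networkEdges(network)
  if (nrow(ed)) {
    ed$pairs <- vapply(ed$pairs, paste, character(1), collapse = ";")
  } else {
    ed$pairs <- character(0)
  }
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = networkNodes(network))
}

.fromIgraph <- function(g) {
  nodes <- igraph::as_data_frame(g, what = "vertices")
  nodes$id <- NULL  # file-format artifact, not a network attribute
  rownames(nodes) <- NULL
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed)) {
    ed$weight <- as.integer(ed$weight)
    ed$pairs <- I(strsplit(ed$pairs, ";", fixed = TRUE))
  } else {
    ed <- .emptyEdges()
  }
  .newNetwork(nodes, ed)
}

#' Connected components and orphan nodes
#'
#' Components by edge traversal; orphans are degree-0 nodes (components of
#' size one).
#'
#' @param network a [PhageNetwork-class].
#' @return list with `components` (list of character vectors, largest
#'   first) and `orphans` (character vector).
#' @export
componentsAndOrphans <- function(network) {
  g <- asIgraph(network)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[order(-vapply(members, length, integer(1)))]
  orphans <- names(igraph::degree(g))[igraph::degree(g) == 0]
  list(components = unname(members), orphans = orphans)
}

#' Export a network to GraphML, GEXF or edge-list TSV
#'
#' GraphML and GEXF round-trip nodes, edges, weights and attributes
#' losslessly through [importNetwork()]; the TSV holds one edge per row.
#'
#' @param network a [PhageNetwork-class].
#' @param path output file.
#' @param format `"graphml"`, `"gexf"` or `"tsv"`.
#' @export
exportNetwork <- function(network, path,
                          format = c("graphml", "gexf", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(asIgraph(network), path, format = "graphml")
  } else if (format == "gexf") {
    .writeGexf(network, path)
  } else {
    ed <- networkEdges(network)
    ed$pairs <- vapply(ed$pairs, paste, character(1), collapse = ";")
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import a network written by [exportNetwork()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"gexf"`.
#' @return a [PhageNetwork-class].
#' @export
importNetwork <- function(path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    .fromIgraph(g)
  } else {
    .readGexf(path)
  }
}

.gexfType <- function(x) {
  if (is.logical(x)) "boolean"
  else if (is.integer(x)) "integer"
  else if (is.numeric(x)) "double"
  else "string"
}

.writeGexf <- function(network, path) {
  nodes <- networkNodes(network)
  ed <- networkEdges(network)
  attrCols <- setdiff(names(nodes), "name")
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  if (length(attrCols)) {
    attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
    for (i in seq_along(attrCols))
      xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1L),
                          title = attrCols[i],
                          type = .gexfType(nodes[[attrCols[i]]]))
  }
  nn <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nn, "node", id = nodes$name[i],
                              label = nodes$name[i])
    if (length(attrCols)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (k in seq_along(attrCols)) {
        v <- nodes[[attrCols[k]]][i]
        xml2::xml_add_child(av, "attvalue", `for` = as.character(k - 1L),
                            value = if (is.na(v)) "NA" else as.character(v))
      }
    }
  }
  ee <- xml2::xml_add_child(graph, "edges")
  if (nrow(ed)) {
    pairsStr <- vapply(ed$pairs, paste, character(1), collapse = ";")
    for (i in seq_len(nrow(ed))) {
      xml2::xml_add_child(ee, "edge", id = as.character(i - 1L),
                          source = ed$from[i], target = ed$to[i],
                          weight = as.character(ed$weight[i]),
                          pairs = pairsStr[i])
    }
  }
  xml2::write_xml(doc, path)
}

.readGexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://www.gexf.net/1.2draft")
  attrNodes <- xml2::xml_find_all(
    doc, "//g:attributes[@class='node']/g:attribute", ns)
  attrTitle <- xml2::xml_attr(attrNodes, "title")
  attrType <- xml2::xml_attr(attrNodes, "type")
  names(attrType) <- xml2::xml_attr(attrNodes, "id")
  nodeEls <- xml2::xml_find_all(doc, "//g:nodes/g:node", ns)
  nodes <- data.frame(name = xml2::xml_attr(nodeEls, "id"),
                      stringsAsFactors = FALSE)
  for (k in seq_along(attrNodes)) {
    id <- xml2::xml_attr(attrNodes[k], "id")
    vals <- vapply(nodeEls, function(nd) {
      v <- xml2::xml_find_first(
        nd, sprintf(".//g:attvalue[@for='%s']", id), ns)
      xml2::xml_attr(v, "value")
    }, character(1))
    vals[vals == "NA"] <- NA
    vals <- switch(attrType[[id]],
                   boolean = as.logical(vals),
                   integer = as.integer(vals),
                   double = as.numeric(vals),
                   vals)
    nodes[[attrTitle[k]]] <- vals
  }
  edgeEls <- xml2::xml_find_all(doc, "//g:edges/g:edge", ns)
  if (length(edgeEls)) {
    ed <- data.frame(
      from = xml2::xml_attr(edgeEls, "source"),
      to = xml2::xml_attr(edgeEls, "target"),
      weight = as.integer(xml2::xml_attr(edgeEls, "weight")),
      pairs = I(strsplit(xml2::xml_attr(edgeEls, "pairs"), ";",
                         fixed = TRUE)),
      stringsAsFactors = FALSE)
  } else {
    ed <- .emptyEdges()
  }
  .newNetwork(nodes, ed)
}
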