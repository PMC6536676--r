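#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges IRanges
NULL

#' Scoring parameters for local alignment
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' statistical parameters (lambda, K) used to convert raw Smith-Waterman
#' scores into bit scores and E-values. Use [proteinScoringParams()] or
#' [nucleotideScoringParams()] to construct sensible defaults.
#'
#' @slot matrix numeric substitution matrix; row/column names define the
#'   alphabet.
#' @slot gapOpen,gapExtend positive gap penalties; a gap of length L costs
#'   `gapOpen + L * gapExtend`.
#' @slot lambda,K Karlin-Altschul parameters (both > 0).
#' @slot type `"protein"` or `"nucleotide"`.
#' @exportClass ScoringParams
setClass("ScoringParams", representation(
  matrix = "matrix", gapOpen = "numeric", gapExtend = "numeric",
  lambda = "numeric", K = "numeric", type = "character"))

setValidity("ScoringParams", function(object) {
  msg <- character()
  if (is.null(rownames(object@matrix)) ||
      !identical(rownames(object@matrix), colnames(object@matrix)))
    msg <- c(msg, "substitution matrix must have identical row/col names")
  if (object@gapOpen < 0 || object@gapExtend <= 0)
    msg <- c(msg, "gap penalties must be positive")
  if (object@lambda <= 0 || object@K <= 0)
    msg <- c(msg, "lambda and K must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf("ScoringParams (%s): %dx%d matrix, gap %g/%g, lambda=%g K=%g\n",
              object@type, nrow(object@matrix), ncol(object@matrix),
              object@gapOpen, object@gapExtend, object@lambda, object@K))
})

#' Virome catalog
#'
#' A validated table of virome members (active phages, in-silico prophages
#' and lytic phages), one row per (pro)phage, together with the validation
#' report produced at load time. Invariant violations are collected in the
#' report rather than dropped, so census functions always see every
#' transcribed row.
#'
#' @slot entries a [S4Vectors::DataFrame] with one row per catalog entry.
#' @slot validation a data.frame of collected invariant violations
#'   (columns: name, issue).
#' @seealso [loadCatalog()], [viromeSize()], [countLysogens()]
#' @exportClass ViromeCatalog
setClass("ViromeCatalog", representation(
  entries = "DataFrame", validation = "data.frame"))

setMethod("show", "ViromeCatalog", function(object) {
  e <- object@entries
  cat(sprintf("ViromeCatalog with %d entries (%d active, %d prophage, %d lytic)\n",
              nrow(e), sum(e$lifestyle == "induced_active"),
              sum(e$lifestyle == "insilico_prophage"),
              sum(e$lifestyle == "lytic")))
  if (nrow(object@validation))
    cat(sprintf("  %d validation issue(s); see validationReport()\n",
                nrow(object@validation)))
})

#' @describeIn ViromeCatalog-class entry table accessor
#' @param x a `ViromeCatalog`
#' @export
catalogEntries <- function(x) {
  stopifnot(is(x, "ViromeCatalog"))
  x@entries
}

#' @describeIn ViromeCatalog-class validation report accessor
#' @export
validationReport <- function(x) {
  stopifnot(is(x, "ViromeCatalog"))
  x@validation
}

#' A called attachment site
#'
#' The result of [callAtt()]: the exact direct-repeat core duplicated as
#' attL/attR around an integrated prophage, the derived post-excision attB
#' and circularised attP junction sequences, and the site classification.
#'
#' @slot attCore the repeat core sequence (character).
#' @slot attL,attR 1-based inclusive genomic intervals of the two copies
#'   (`IRanges` of length 1 each).
#' @slot siteClass one of `"tRNA"`, `"gene_disruption"`, `"intergenic"`,
#'   `"other"`.
#' @slot targetFeature id of the reconstituted/disrupted feature, or `NA`.
#' @slot attB,attP derived sequences (core plus flanking context).
#' @slot trnaReconstituted logical; TRUE when excision restores an intact
#'   tRNA gene at the site.
#' @exportClass AttCall
setClass("AttCall", representation(
  attCore = "character", attL = "IRanges", attR = "IRanges",
  siteClass = "character", targetFeature = "character",
  attB = "character", attP = "character", trnaReconstituted = "logical"))

setMethod("show", "AttCall", function(object) {
  cat(sprintf("AttCall: %d-nt core '%s'\n  attL %d-%d, attR %d-%d, site class %s%s\n",
              nchar(object@attCore),
              if (nchar(object@attCore) > 40)
                paste0(substr(object@attCore, 1, 37), "...") else object@attCore,
              IRanges::start(object@attL), IRanges::end(object@attL),
              IRanges::start(object@attR), IRanges::end(object@attR),
              object@siteClass,
              if (!is.na(object@targetFeature))
                sprintf(" (target %s)", object@targetFeature) else ""))
})

#' @describeIn AttCall-class repeat core accessor
#' @param x an `AttCall`
#' @export
attCore <- function(x) {
  stopifnot(is(x, "AttCall"))
  x@attCore
}

#' Weighted phage similarity network
#'
#' An undirected graph whose nodes are (pro)phages (or individual proteins)
#' and whose edges record reciprocated protein similarity. Edge weight is
#' the number of reciprocally similar protein pairs; the pairs themselves
#' are retained so the weight is auditable.
#'
#' @slot nodes data.frame with at least a `name` column, plus optional
#'   attributes (family, host, lifestyle, ...).
#' @slot edges data.frame with columns `from`, `to`, `weight` and a list
#'   column `pairs` of character vectors ("a|b" member pairs).
#' @exportClass PhageNetwork
setClass("PhageNetwork", representation(
  nodes = "data.frame", edges = "data.frame"))

setValidity("PhageNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (nrow(ed)) {
    if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(ed$weight < 1)) msg <- c(msg, "edge weights must be >= 1")
    if (!is.null(ed$pairs) && any(ed$weight != lengths(ed$pairs)))
      msg <- c(msg, "edge weight must equal the number of member pairs")
    if (!all(c(ed$from, ed$to) %in% object@nodes$name))
      msg <- c(msg, "edge endpoints must be catalogued nodes")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhageNetwork", function(object) {
  cat(sprintf("PhageNetwork: %d nodes, %d edges (total weight %d)\n",
              nrow(object@nodes), nrow(object@edges),
              if (nrow(object@edges)) sum(object@edges$weight) else 0L))
})

#' @describeIn PhageNetwork-class node table accessor
#' @param x a `PhageNetwork`
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "PhageNetwork"))
  x@nodes
}

#' @describeIn PhageNetwork-class edge table accessor
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "PhageNetwork"))
  x@edges
}

#' Prophage completeness report
#'
#' Records which of the five modules required of a complete temperate-phage
#' genome (integration, lysogeny switch, DNA packaging, head-tail assembly,
#' lysis) are present in an annotated region.
#'
#' @slot presentModules,missingModules character vectors over the required
#'   module vocabulary.
#' @slot complete TRUE iff no required module is missing.
#' @exportClass CompletenessReport
setClass("CompletenessReport", representation(
  presentModules = "character", missingModules = "character",
  complete = "logical"))

setMethod("show", "CompletenessReport", function(object) {
  cat(sprintf("CompletenessReport: %s\n  present: %s\n  missing: %s\n",
              if (object@complete) "COMPLETE" else "incomplete",
              paste(object@presentModules, collapse = ", "),
              if (length(object@missingModules))
                paste(object@missingModules, collapse = ", ") else "(none)"))
})

#' @describeIn CompletenessReport-class TRUE iff all required modules present
#' @param x a `CompletenessReport`
#' @export
isComplete <- function(x) {
  stopifnot(is(x, "CompletenessReport"))
  x@complete
}
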