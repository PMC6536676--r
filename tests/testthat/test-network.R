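smallParams <- proteinScoringParams()

test_that("reciprocal pairing enforces identity, coverage and direction", {
  set.seed(301)
  base <- vapply(1:3, function(i) randSeq(150, AA20), character(1))
  A <- stats::setNames(base, paste0("a", 1:3))
  B <- stats::setNames(base, paste0("b", 1:3))
  rp <- reciprocalPairs(A, B)
  expect_equal(nrow(rp), 3)  # three identical homolog pairs
  expect_setequal(rp$protein_a, names(A))

  # 70 percent identity fails the 80 percent threshold
  low <- stats::setNames(mutateToIdentity(base[1], 70, seed = 1), "low")
  rpLow <- reciprocalPairs(A[1], stats::setNames(low, "b1"))
  expect_equal(nrow(rpLow), 0)
  # ...but qualifies once the threshold is relaxed below it
  rpRelax <- reciprocalPairs(A[1], stats::setNames(low, "b1"),
                             geneSharingThresholds(identityMin = 60))
  expect_equal(nrow(rpRelax), 1)

  # asymmetric coverage: a short protein inside a long one passes only
  # one direction and is excluded
  short <- substr(base[1], 40, 90)
  frag <- stats::setNames(short, "frag")
  rpAsym <- reciprocalPairs(A[1], frag)
  expect_equal(nrow(rpAsym), 0)
})

test_that("phage network recovers the planted shared matrix exactly", {
  sm <- matrix(0, 3, 3)
  sm[1, 2] <- sm[2, 1] <- 3
  sm[2, 3] <- sm[3, 2] <- 1
  pc <- generateProteomeClusters(3, sm, identityLevels = 90, seed = 17,
                                 nUnique = 4, proteinLength = 120)
  net <- buildPhageNetwork(pc$proteomes)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 2)
  w12 <- ed$weight[(ed$from == "phage01" & ed$to == "phage02") |
                     (ed$from == "phage02" & ed$to == "phage01")]
  expect_equal(w12, 3)
  expect_false(any((ed$from == "phage01" & ed$to == "phage03") |
                     (ed$from == "phage03" & ed$to == "phage01")))
  expect_equal(ed$weight, lengths(ed$pairs))

  # input order must not matter
  net2 <- buildPhageNetwork(rev(pc$proteomes))
  key <- function(n) {
    e <- networkEdges(n)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), e$weight))
  }
  expect_equal(key(net2), key(net))

  # weight is bounded by the smaller proteome
  sizes <- vapply(pc$proteomes, length, integer(1))
  for (r in seq_len(nrow(ed)))
    expect_lte(ed$weight[r], min(sizes[[ed$from[r]]], sizes[[ed$to[r]]]))
})

test_that("unrelated proteomes give an edgeless network of orphans", {
  pc <- generateProteomeClusters(3, matrix(0, 3, 3), seed = 19,
                                 nUnique = 3, proteinLength = 100)
  net <- buildPhageNetwork(pc$proteomes)
  expect_equal(nrow(networkEdges(net)), 0)
  co <- componentsAndOrphans(net)
  expect_length(co$orphans, 3)
  expect_length(co$components, 3)
})

test_that("a duplicated proteome is linked by an edge of full weight", {
  pc <- generateProteomeClusters(2, matrix(0, 2, 2), seed = 23,
                                 nUnique = 5, proteinLength = 100)
  dup <- list(x = pc$proteomes[[1]], y = pc$proteomes[[1]])
  net <- buildPhageNetwork(dup)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$weight, 5)
})

test_that("marker networks connect similar markers and flag missing ones", {
  set.seed(31)
  tyr <- randSeq(320, AA20)
  markers <- c(p1 = tyr, p2 = tyr, p3 = randSeq(320, AA20),
               p4 = NA_character_)
  net <- buildMarkerNetwork(markers)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$from, ed$to), c("p1", "p2"))
  expect_equal(ed$weight, 1)
  nodes <- networkNodes(net)
  expect_true(nodes$missing_marker[nodes$name == "p4"])
  co <- componentsAndOrphans(net)
  expect_setequal(co$orphans, c("p3", "p4"))
})

test_that("protein identity network applies identity over short-side coverage", {
  set.seed(37)
  base <- randSeq(200, AA20)
  prots <- c(m1 = base,
             m2 = mutateToIdentity(base, 85, seed = 2),
             m3 = mutateToIdentity(base, 70, seed = 3),
             m4 = randSeq(200, AA20))
  net <- buildProteinIdentityNetwork(prots)
  ed <- networkEdges(net)
  pairKey <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_true("m1 m2" %in% pairKey)   # 85 percent identity -> edge
  expect_false("m1 m3" %in% pairKey)  # 70 percent identity -> no edge
  expect_false(any(grepl("m4", pairKey)))
})

test_that("relaxing any threshold never removes an edge", {
  sm <- matrix(0, 3, 3)
  sm[1, 2] <- sm[2, 1] <- 2
  sm[1, 3] <- sm[3, 1] <- 1
  pc <- generateProteomeClusters(3, sm, identityLevels = 85, seed = 41,
                                 nUnique = 2, proteinLength = 120)
  strict <- geneSharingThresholds()
  edgeKeys <- function(thr) {
    e <- networkEdges(buildPhageNetwork(pc$proteomes, thr))
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  base <- edgeKeys(strict)
  relaxed <- list(
    geneSharingThresholds(evalueMax = 1e-5),
    geneSharingThresholds(queryCoverageMin = 50),
    geneSharingThresholds(identityMin = 60))
  for (thr in relaxed) expect_true(all(base %in% edgeKeys(thr)))
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(43)
  for (k in 1:15) {
    n <- sample(5:50, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    nEdge <- sample(0:(2 * n), 1)
    from <- sample(nodes, nEdge, replace = TRUE)
    to <- sample(nodes, nEdge, replace = TRUE)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    dedup <- !duplicated(paste(pmin(from, to), pmax(from, to)))
    from <- from[dedup]; to <- to[dedup]
    net <- new("PhageNetwork",
               nodes = data.frame(name = nodes, stringsAsFactors = FALSE),
               edges = if (length(from))
                 data.frame(from = from, to = to,
                            weight = rep(1L, length(from)),
                            pairs = I(as.list(paste(from, to, sep = "|"))),
                            stringsAsFactors = FALSE)
               else data.frame(from = character(), to = character(),
                               weight = integer(), pairs = I(list()),
                               stringsAsFactors = FALSE))
    got <- componentsAndOrphans(net)$components
    want <- oracleComponents(nodes, from, to)
    canon <- function(x) sort(vapply(x, function(v)
      paste(sort(v), collapse = ","), character(1)))
    expect_equal(canon(got), canon(want))
  }
})

test_that("network export round-trips through GraphML, GEXF and TSV", {
  sm <- matrix(0, 2, 2); sm[1, 2] <- sm[2, 1] <- 2
  pc <- generateProteomeClusters(2, sm, seed = 47, nUnique = 2,
                                 proteinLength = 100)
  attrs <- data.frame(name = c("phage01", "phage02"),
                      family = c("Siphoviridae", "Myoviridae"),
                      gc = c(61.5, 65.0), stringsAsFactors = FALSE)
  net <- buildPhageNetwork(pc$proteomes, nodeAttrs = attrs)

  cmp <- function(a, b) {
    na <- networkNodes(a); nb <- networkNodes(b)
    na <- na[order(na$name), ]; nb <- nb[order(nb$name), names(na)]
    rownames(na) <- rownames(nb) <- NULL
    expect_equal(nb, na)
    ea <- networkEdges(a); eb <- networkEdges(b)
    expect_equal(eb$weight, ea$weight)
    expect_equal(unclass(eb$pairs), unclass(ea$pairs),
                 ignore_attr = TRUE)
  }
  f1 <- tempfile(fileext = ".graphml")
  exportNetwork(net, f1, "graphml")
  cmp(importNetwork(f1, "graphml"), net)
  # numeric attribute type survives
  expect_type(networkNodes(importNetwork(f1, "graphml"))$gc, "double")

  f2 <- tempfile(fileext = ".gexf")
  exportNetwork(net, f2, "gexf")
  cmp(importNetwork(f2, "gexf"), net)
  expect_type(networkNodes(importNetwork(f2, "gexf"))$gc, "double")

  f3 <- tempfile(fileext = ".tsv")
  exportNetwork(net, f3, "tsv")
  tsv <- read.delim(f3)
  expect_equal(nrow(tsv), nrow(networkEdges(net)))

  expect_error(exportNetwork(net, tempfile(), "dot"), "arg")
})
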