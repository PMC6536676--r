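moduleFeat <- function(cats) {
  n <- length(cats)
  GenomicRanges::GRanges("host",
                         IRanges::IRanges(seq(1, by = 1000, length.out = n),
                                          width = 800),
                         strand = "+", type = "CDS",
                         ID = sprintf("g%02d", seq_len(n)),
                         product = cats, module_category = cats)
}

test_that("completeness requires all five phage modules", {
  full <- moduleFeat(c("integration", "lysogeny_switch", "replication",
                       "packaging", "head_tail", "lysis"))
  rep1 <- assessCompleteness(full)
  expect_true(isComplete(rep1))
  expect_length(rep1@missingModules, 0)

  noLysis <- moduleFeat(c("integration", "lysogeny_switch", "packaging",
                          "head_tail"))
  rep2 <- assessCompleteness(noLysis)
  expect_false(isComplete(rep2))
  expect_equal(rep2@missingModules, "lysis")

  rep3 <- assessCompleteness(GenomicRanges::GRanges())
  expect_false(isComplete(rep3))
  expect_length(rep3@missingModules, 5)

  # monotonicity: adding features never removes a present module
  set.seed(5)
  cats <- c("integration", "lysogeny_switch", "packaging", "head_tail",
            "lysis", "replication", "other")
  for (k in 1:20) {
    base <- sample(cats, sample(1:5, 1), replace = TRUE)
    extra <- sample(cats, sample(1:3, 1), replace = TRUE)
    before <- assessCompleteness(moduleFeat(base))@presentModules
    after <- assessCompleteness(moduleFeat(c(base, extra)))@presentModules
    expect_true(all(before %in% after))
  }
})

test_that("GC content counts unambiguous bases only", {
  expect_equal(gcContent("GCGC"), 100)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("ACGTN"), 50)  # N excluded from both sides
  expect_error(gcContent("NNNN"), "unambiguous")
  expect_error(gcContent(""), "empty")
  # brute-force counting oracle on a fixed 10-kb sequence
  set.seed(6)
  s <- randSeq(10000)
  chars <- strsplit(s, "")[[1]]
  expect_equal(gcContent(s), 100 * sum(chars %in% c("G", "C")) / 10000)
  # weighted-mean property: gc(concat) lies between the two parts
  a <- randSeq(3000); b <- randSeq(500)
  g <- gcContent(paste0(a, b))
  expect_gte(g, min(gcContent(a), gcContent(b)))
  expect_lte(g, max(gcContent(a), gcContent(b)))
})

test_that("GC boundary refinement recovers a planted prophage interval", {
  host <- generateHostGenome(hostGenomeSpec(length = 12000, gcTarget = 65,
                                            trnaGenes = NULL,
                                            cdsDensity = 0), seed = 201)
  lys <- simulateIntegration(host, prophageSpec(length = 3000, gcTarget = 58,
                                                attCoreLength = 0),
                             "intergenic", seed = 202)
  tr <- lys$truth
  ts <- IRanges::start(tr$prophage_interval)
  te <- IRanges::end(tr$prophage_interval)
  ref <- refineBoundariesByGc(lys$sequence, c(ts + 250, te - 250),
                              window = 500, step = 100, minContrast = 2.5)
  expect_true(ref$refined)
  expect_lte(abs(ref$interval[1] - ts), 500)
  expect_lte(abs(ref$interval[2] - te), 500)
  expect_equal(ref$backgroundGc, 65, tolerance = 0.02)
  expect_true(all(c("start", "end", "gc", "qualifying") %in%
                    names(ref$profile)))
})

test_that("refinement flags the no-contrast case and validates inputs", {
  host <- generateHostGenome(hostGenomeSpec(length = 9000, gcTarget = 65,
                                            trnaGenes = NULL,
                                            cdsDensity = 0), seed = 203)
  lys <- simulateIntegration(host, prophageSpec(length = 2500, gcTarget = 65,
                                                attCoreLength = 0),
                             "intergenic", seed = 204)
  iv <- c(IRanges::start(lys$truth$prophage_interval),
          IRanges::end(lys$truth$prophage_interval))
  ref <- refineBoundariesByGc(lys$sequence, iv)
  expect_false(ref$refined)
  expect_equal(ref$interval, iv)

  expect_error(refineBoundariesByGc(lys$sequence, iv, minContrast = 0),
               "minContrast")
  expect_error(refineBoundariesByGc(lys$sequence, c(1, 1e7)), "outside")
  expect_error(refineBoundariesByGc(lys$sequence, iv, window = 1e6),
               "window")
})

test_that("MTase locus classification follows the documented priority", {
  mk <- function(cats, ids = sprintf("g%02d", seq_along(cats))) {
    GenomicRanges::GRanges("host",
                           IRanges::IRanges(seq(1, by = 1000,
                                                length.out = length(cats)),
                                            width = 800),
                           strand = "+", type = "CDS", ID = ids,
                           product = cats, module_category = cats)
  }
  # sandwiched between ParB-like and terminase large subunit
  f1 <- mk(c("integration", "parB_like", "mtase", "terminase_large",
             "packaging"))
  expect_equal(classifyMtaseLocus("g03", f1), "ParB_Tls")
  # adjacent to the replication module
  f2 <- mk(c("other", "replication", "mtase", "other", "other"))
  expect_equal(classifyMtaseLocus("g03", f2), "near_replication")
  # directly downstream of the integrase
  f3 <- mk(c("integration", "mtase", "other", "other"))
  expect_equal(classifyMtaseLocus("g02", f3), "downstream_integrase")
  # no module within the window
  f4 <- mk(c("other", "other", "mtase", "other", "other", "lysis"))
  expect_equal(classifyMtaseLocus("g03", f4), "other")
  expect_error(classifyMtaseLocus("nope", f4), "not found")
})

test_that("product keywords map to module categories", {
  g <- GenomicRanges::GRanges("host", IRanges::IRanges(c(1, 1001, 2001),
                                                       width = 800),
                              strand = "+", type = "CDS",
                              ID = c("a", "b", "c"),
                              product = c("site-specific integrase",
                                          "terminase large subunit",
                                          "hypothetical protein"),
                              module_category = NA_character_)
  out <- categorizeByProduct(g)
  expect_equal(GenomicRanges::mcols(out)$module_category,
               c("integration", "packaging", "other"))
})
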