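test_that("direct-repeat finder reports planted and degenerate cases", {
  core <- "GCGTCTCGTTTACACTGAGA"  # a 20-nt attB-style core
  set.seed(101)
  left <- paste0(randSeq(400), core, randSeq(80))
  right <- paste0(randSeq(150), core, randSeq(330))
  reps <- findDirectRepeats(left, right, 12)
  expect_true(core %in% reps$core)
  top <- reps[1, ]
  expect_equal(top$core, core)
  expect_equal(top$left_start, 401)
  expect_equal(top$right_start, 151)

  # identical flanks: the full flank is the single maximal repeat
  fl <- randSeq(200)
  same <- findDirectRepeats(fl, fl, 12)
  expect_equal(nrow(same), 1)
  expect_equal(same$core, fl)
  expect_equal(same$length, 200)

  # unrelated 1-kb flanks contain no 12-mer repeat (verified fixed seed)
  set.seed(202)
  expect_equal(nrow(findDirectRepeats(randSeq(1000), randSeq(1000), 12)), 0)

  expect_error(findDirectRepeats("ACGTACGT", "ACGTACGT", 4), "minCoreLength")
})

test_that("direct-repeat finder agrees exactly with the exhaustive oracle", {
  set.seed(77)
  for (k in 1:12) {
    # small alphabets force plenty of chance repeats
    alpha <- if (k %% 2 == 0) c("A", "C") else DNA4
    a <- randSeq(sample(100:300, 1), alpha)
    b <- randSeq(sample(100:300, 1), alpha)
    if (k %% 3 == 0) {
      ins <- randSeq(15, alpha)
      a <- paste0(substr(a, 1, 40), ins, substr(a, 41, nchar(a)))
      b <- paste0(substr(b, 1, 90), ins, substr(b, 91, nchar(b)))
    }
    got <- findDirectRepeats(a, b, 8)
    want <- oracleRepeats(a, b, 8)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("case", k))
  }
})

test_that("att calling recovers the planted core, intervals and site class", {
  lys <- makeLysogen(seed = 31, coreLen = 20)
  tr <- lys$truth
  call <- callAtt(lys$sequence, tr$prophage_interval, lys$features)
  expect_s4_class(call, "AttCall")
  expect_identical(attCore(call), tr$att_core)
  expect_equal(IRanges::start(call@attL), IRanges::start(tr$attL))
  expect_equal(IRanges::start(call@attR), IRanges::start(tr$attR))
  expect_equal(call@siteClass, "tRNA")
  expect_true(call@trnaReconstituted)

  # excision property: removing [attL, attR) restores the host exactly,
  # with a single core copy left at the junction
  excised <- exciseProphage(lys$sequence, call)
  expect_identical(excised, as.character(lys$host$sequence))
  expect_equal(
    length(gregexpr(tr$att_core, excised, fixed = TRUE)[[1]]), 1)

  # the derived attB contains the core with host context on both sides
  expect_true(grepl(tr$att_core, call@attB, fixed = TRUE))
  expect_true(grepl(tr$att_core, call@attP, fixed = TRUE))
})

test_that("att calling returns nothing when the planted core is too short", {
  lys <- makeLysogen(seed = 53, coreLen = 10)  # below minCoreLength = 12
  # narrow flanks keep chance >= 12-mer repeats out of the search window
  call <- callAtt(lys$sequence, lys$truth$prophage_interval, lys$features,
                  flankBp = 300)
  expect_null(call)
})

test_that("tRNA-reconstituting candidates outrank longer non-tRNA repeats", {
  lys <- makeLysogen(seed = 61, coreLen = 16, cassetteLen = 800)
  tr <- lys$truth
  s <- as.character(lys$sequence)
  # plant a LONGER decoy repeat inside both flanks, away from the tRNA
  decoy <- randSeq(30)
  aL <- IRanges::start(tr$attL); aR <- IRanges::end(tr$attR)
  s2 <- paste0(substr(s, 1, aL - 400), decoy,
               substr(s, aL - 400 + 31, aR + 370), decoy,
               substr(s, aR + 370 + 31, nchar(s)))
  call <- callAtt(s2, c(aL, aR), lys$features)
  expect_equal(attCore(call), tr$att_core)
  expect_true(call@trnaReconstituted)
})

test_that("tRNA 3'-end reconstitution honours strand", {
  # plus strand: planted case is TRUE, distant repeat is FALSE
  lys <- makeLysogen(seed = 71, coreLen = 18)
  tr <- lys$truth
  f <- lys$features
  trna <- f[GenomicRanges::mcols(f)$type == "tRNA"]
  expect_true(checkTrnaReconstitution(tr$attL, tr$attR, trna))
  farL <- IRanges::shift(tr$attL, 500)
  expect_false(checkTrnaReconstitution(farL, tr$attR, trna))

  # minus strand: att copies sit at the genomic-left (3') end
  lysM <- makeLysogen(seed = 81, coreLen = 18, trnaStrand = "-")
  trM <- lysM$truth
  sM <- as.character(lysM$sequence)
  expect_identical(substr(sM, IRanges::start(trM$attL),
                          IRanges::end(trM$attL)), trM$att_core)
  expect_identical(substr(sM, IRanges::start(trM$attR),
                          IRanges::end(trM$attR)), trM$att_core)
  fM <- lysM$features
  trnaM <- fM[GenomicRanges::mcols(fM)$type == "tRNA"]
  expect_true(checkTrnaReconstitution(trM$attL, trM$attR, trnaM))
  callM <- callAtt(lysM$sequence, trM$prophage_interval, lysM$features)
  expect_identical(attCore(callM), trM$att_core)
  expect_equal(callM@siteClass, "tRNA")
})

test_that("site classification distinguishes tRNA, gene disruption and intergenic", {
  # gene disruption
  host <- generateHostGenome(hostGenomeSpec(length = 6000, gcTarget = 65,
                                            trnaGenes = NULL,
                                            cdsDensity = 0.5), seed = 91)
  target <- GenomicRanges::mcols(host$features)$ID[2]
  lys <- simulateIntegration(host, prophageSpec(length = 600,
                                                attCoreLength = 15),
                             target, seed = 92)
  call <- callAtt(lys$sequence, lys$truth$prophage_interval, lys$features)
  expect_equal(call@siteClass, "gene_disruption")
  expect_equal(call@targetFeature, target)

  # intergenic, with a repeat core taken from between genes
  host2 <- generateHostGenome(hostGenomeSpec(length = 8000, gcTarget = 65,
                                             trnaGenes = NULL,
                                             cdsDensity = 0.2), seed = 93)
  lys2 <- simulateIntegration(host2, prophageSpec(length = 600,
                                                  attCoreLength = 15),
                              "intergenic", seed = 94)
  call2 <- callAtt(lys2$sequence, lys2$truth$prophage_interval,
                   lys2$features)
  expect_equal(call2@siteClass, "intergenic")
})

test_that("att calling validates its interval argument", {
  lys <- makeLysogen(seed = 99, coreLen = 15)
  expect_error(callAtt(lys$sequence, c(10, 10 + nchar(as.character(lys$sequence))),
                       lys$features), "outside")
})
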