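mkMap <- function(markers, groups, cM) {
  new("GeneticMap",
      table = data.frame(marker = markers, group = groups,
                         index = stats::ave(seq_along(markers), groups,
                                            FUN = seq_along),
                         cM = cM, stringsAsFactors = FALSE),
      mappingFunction = "kosambi", lodThreshold = 3,
      segregation = data.frame())
}

test_that("anchoring orients by the bp-cM rank correlation", {
  map <- mkMap(c("m5", "m1", "m3", "m2", "m4"), rep("LG01", 5),
               c(4, 5, 5, 7, 7))
  fwd <- data.frame(marker = c("m1", "m2"), contig = "ctgF",
                    position = c(10000, 90000), stringsAsFactors = FALSE)
  rev <- data.frame(marker = c("m3", "m4"), contig = "ctgR",
                    position = c(90000, 10000), stringsAsFactors = FALSE)
  single <- data.frame(marker = "m5", contig = "ctgS", position = 5000,
                       stringsAsFactors = FALSE)
  anchors <- anchorContigs(map, rbind(fwd, rev, single))
  a <- function(ct) anchors[anchors$contig == ct, ]
  expect_identical(a("ctgF")$orientation, "+")
  expect_identical(a("ctgR")$orientation, "-")  # cM falls as bp rises
  expect_identical(a("ctgS")$orientation, "+")
  expect_false(a("ctgS")$orientationKnown)
  ## contigs rank by median cM within the chromosome
  expect_lt(a("ctgS")$rank, a("ctgF")$rank)
})

test_that("anchoring refuses an unsplit multi-group contig", {
  map <- mkMap(sprintf("m%d", 1:4), c("LG01", "LG01", "LG02", "LG02"),
               c(1, 2, 1, 2))
  assign <- data.frame(marker = sprintf("m%d", 1:4), contig = "ctgX",
                       position = c(1, 2, 3, 4) * 10000,
                       stringsAsFactors = FALSE)
  expect_error(anchorContigs(map, assign), "split")
})

test_that("terminal overlap detection applies the length and mismatch rules", {
  set.seed(50)
  ov <- randomSeq(4000)
  a <- Biostrings::DNAString(paste0(randomSeq(6000), ov))
  b <- Biostrings::DNAString(paste0(ov, randomSeq(6000)))
  res <- detectTerminalOverlap(a, b, maxWindow = 10000)
  expect_identical(res$overlapLen, 4000L)
  expect_identical(res$mismatches, 0L)
  expect_true(res$accepted)
  ## an exact 3000 bp overlap is accepted, 2500 bp is not
  for (len in c(3000L, 2500L)) {
    ovs <- randomSeq(len)
    aa <- Biostrings::DNAString(paste0(randomSeq(6000), ovs))
    bb <- Biostrings::DNAString(paste0(ovs, randomSeq(6000)))
    r <- detectTerminalOverlap(aa, bb, maxWindow = 8000)
    expect_identical(r$overlapLen, len)
    expect_identical(r$accepted, len >= 3000L)
  }
  ## 50 mismatches in 4000 bp (1.25%) exceed the 1% budget
  ovMut <- strsplit(ov, "")[[1]]
  pos <- sample(3969, 50)              # keep the terminal seed clean
  ovMut[pos] <- vapply(ovMut[pos], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  bMut <- Biostrings::DNAString(paste0(paste(ovMut, collapse = ""),
                                       randomSeq(6000)))
  rMut <- detectTerminalOverlap(a, bMut, maxWindow = 10000)
  expect_false(rMut$accepted)
  ## but 20 mismatches (0.5%) pass
  ov2 <- strsplit(ov, "")[[1]]
  pos2 <- sample(3969, 20)
  ov2[pos2] <- vapply(ov2[pos2], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  b2 <- Biostrings::DNAString(paste0(paste(ov2, collapse = ""), randomSeq(6000)))
  r2 <- detectTerminalOverlap(a, b2, maxWindow = 10000)
  expect_true(r2$accepted)
  expect_lt(r2$mismatches / r2$overlapLen, 0.01)
  ## window clamping warns
  expect_warning(detectTerminalOverlap(a, b, maxWindow = 1e6), "clamped")
})

test_that("merging keeps the overlap from the upstream contig", {
  set.seed(51)
  ov <- randomSeq(4000)
  a <- Biostrings::DNAString(paste0(randomSeq(4000), ov))
  b <- Biostrings::DNAString(paste0(ov, randomSeq(5000)))
  join <- detectTerminalOverlap(a, b, maxWindow = 8000)
  merged <- mergeOverlapping(a, b, join)
  expect_identical(length(merged), 8000L + 9000L - 4000L)
  expect_identical(as.character(Biostrings::subseq(merged, 1, 8000)),
                   as.character(a))
  expect_error(mergeOverlapping(a, b, list(accepted = FALSE)), "not accepted")
})

test_that("chained merges rebuild a fragmented chromosome exactly", {
  g <- simulateGenome(1, 150000, seed = 52)
  fr <- fragmentGenome(g, targetFragmentBp = 40000, overlapRange = c(3000, 6000),
                       randomOrient = FALSE, seed = 53)
  iv <- sourceIntervals(fr$truth)
  iv <- iv[order(iv$start), ]
  merged <- fr$contigs[[iv$contig[1]]]
  for (i in seq_len(nrow(iv))[-1]) {
    nxt <- fr$contigs[[iv$contig[i]]]
    join <- detectTerminalOverlap(merged, nxt, maxWindow = 30000)
    expect_true(join$accepted)
    merged <- mergeOverlapping(merged, nxt, join)
  }
  expect_identical(as.character(merged),
                   as.character(chromosomeSeqs(g)[[1]]))
})

test_that("pseudomolecule emission follows the 100-N gap convention", {
  ctgs <- Biostrings::DNAStringSet(c(c1 = randomSeq(5000, seed = 54),
                                     c2 = randomSeq(4000, seed = 55)))
  anchors <- data.frame(contig = c("c1", "c2"), chrom = "LG01",
                        medianCM = c(1, 2), orientation = "+",
                        orientationKnown = TRUE, nMarkers = 2L, rank = 1:2,
                        stringsAsFactors = FALSE)
  sp <- buildScaffoldPlan(ctgs, anchors, maxWindow = 4000)
  build <- buildPseudomolecules(sp$plan, ctgs)
  seq <- as.character(build$seqs[[1]])
  expect_identical(nchar(seq), 5000L + 4000L + 100L)
  gaps <- gregexpr("N+", seq)[[1]]
  expect_identical(length(gaps), 1L)
  expect_identical(attr(gaps, "match.length"), 100L)
  ## AGP arithmetic identity and byte-identical reconstruction
  agp <- build$agp
  wRows <- agp[agp$component_type == "W", ]
  expect_identical(sum(as.integer(wRows$component_end) -
                       as.integer(wRows$component_beg) + 1L) +
                   100L * sum(agp$component_type == "U"),
                   nchar(seq))
  expect_identical(as.character(agpToFasta(agp, ctgs)[[1]]), seq)
})

test_that("reverse-complementing an input contig leaves the output unchanged", {
  sc <- roundTripScenario(seed = 56)
  base <- runPipeline(sc$contigs, sc$gm)
  flipped <- sc$contigs
  ct <- names(flipped)[3]
  flipped[[ct]] <- Biostrings::reverseComplement(flipped[[ct]])
  gm <- sc$gm
  mi <- markerInfo(gm)
  onCt <- !is.na(mi$contig) & mi$contig == ct
  mi$position[onCt] <- Biostrings::width(flipped)[names(flipped) == ct] -
    mi$position[onCt] + 1L
  gm <- initialize(gm, markerInfo = mi)
  alt <- runPipeline(flipped, gm)
  expect_identical(as.character(alt$pseudomolecules),
                   as.character(base$pseudomolecules))
})

test_that("markerless contigs are placed only when all three criteria hold", {
  set.seed(57)
  chrA <- randomSeq(60000)
  chrB <- randomSeq(30000)
  ## three tiling pieces of chrA with 4 kb overlaps; the middle one is
  ## markerless and must come back via the guide
  p1 <- substring(chrA, 1, 24000)
  p2 <- substring(chrA, 20001, 44000)
  p3 <- substring(chrA, 40001, 60000)
  ctgs <- Biostrings::DNAStringSet(c(cA1 = p1, cMid = p2, cA3 = p3, cB = chrB))
  anchors <- data.frame(contig = c("cA1", "cA3", "cB"),
                        chrom = c("LG01", "LG01", "LG02"),
                        medianCM = c(1, 2, 1), orientation = "+",
                        orientationKnown = TRUE, nMarkers = 2L,
                        rank = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  sp <- buildScaffoldPlan(ctgs, anchors, maxWindow = 20000)
  expect_identical(sum(sp$plan@components$type == "U"), 1L)
  guide <- data.frame(contig = "cMid", chrom = "LG01", position = 20000,
                      strand = "+", stringsAsFactors = FALSE)
  pm <- placeMarkerless(sp$plan, ctgs, guide, maxWindow = 20000)
  expect_true(pm$log$placed)
  build <- buildPseudomolecules(pm$plan, ctgs)
  expect_identical(as.character(build$seqs[["LG01"]]), chrA)
  ## wrong guide chromosome -> criterion 1
  badGuide <- guide; badGuide$chrom <- "LG02"
  pmBad <- placeMarkerless(sp$plan, ctgs, badGuide, maxWindow = 20000,
                           posTol = 1e9)
  expect_false(pmBad$log$placed)
  expect_identical(pmBad$log$failedCriterion, "overlap_length")
  ## far-off guide position -> criterion 1 (guide consistency)
  farGuide <- guide; farGuide$position <- 59000
  pmFar <- placeMarkerless(sp$plan, ctgs, farGuide, maxWindow = 20000,
                           posTol = 5000)
  expect_false(pmFar$log$placed)
  expect_identical(pmFar$log$failedCriterion, "guide_consistency")
  ## an overlap of only ~3.4 kb fails criterion 2
  shortCtgs <- ctgs
  shortCtgs[["cMid"]] <- Biostrings::DNAString(substring(chrA, 20601, 43400))
  pmShort <- placeMarkerless(sp$plan, shortCtgs, guide, maxWindow = 20000)
  expect_false(pmShort$log$placed)
  expect_identical(pmShort$log$failedCriterion, "overlap_length")
  ## contig absent from the guide stays unplaced silently
  pmNone <- placeMarkerless(sp$plan, ctgs,
                            guide[guide$contig != "cMid", , drop = FALSE])
  expect_identical(nrow(pmNone$log), 0L)
  expect_true("cMid" %in% unplacedContigs(pmNone$plan))
})
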