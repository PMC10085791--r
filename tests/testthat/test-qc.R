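naiveN50 <- function(lengths) {
  # quadratic oracle: test every candidate length directly
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  min(lengths)
}

test_that("N50 matches the brute-force oracle", {
  expect_identical(n50(c(5, 4, 3, 2, 1)), 4)
  expect_identical(n50(42), 42)
  set.seed(60)
  for (i in 1:25) {
    lens <- sample(1:5000, sample(1:10, 1), replace = TRUE)
    expect_identical(n50(lens), naiveN50(lens))
  }
  expect_error(n50(numeric(0)), "no sequences")
})

test_that("gap accounting counts maximal N runs exactly", {
  seqs <- Biostrings::DNAStringSet(c(
    s1 = paste0(randomSeq(500, seed = 61), strrep("N", 100), randomSeq(400)),
    s2 = randomSeq(300)))
  st <- assemblyStats(seqs)
  expect_identical(st$nGaps, 1L)
  expect_identical(st$nNBases, 100L)
  expect_identical(unname(st$gapCounts), c(1L, 0L))
  expect_identical(st$totalLength, 1000L + 300L)
  expect_error(assemblyStats(Biostrings::DNAStringSet()), "empty")
})

test_that("telomere detection accepts constructed arrays and rejects random ends", {
  telo <- paste0(strrep("CCTAA", 60), randomSeq(5000, seed = 62))
  expect_true(detectTelomere(telo, "5p"))
  expect_false(detectTelomere(telo, "3p"))
  telo3 <- paste0(randomSeq(5000, seed = 63), strrep("TTAGG", 60))
  expect_true(detectTelomere(telo3, "3p"))
  expect_false(detectTelomere(telo3, "5p"))
  for (s in 1:20) {
    rnd <- randomSeq(10000, seed = 700 + s)
    expect_false(detectTelomere(rnd, "5p"))
    expect_false(detectTelomere(rnd, "3p"))
  }
  expect_false(detectTelomere("ACG", "5p"))  # shorter than one unit
  ## one mismatched unit per 10 is tolerated
  units <- rep("CCTAA", 30)
  units[c(10, 20)] <- "CCTTA"
  expect_true(detectTelomere(paste0(paste(units, collapse = ""),
                                    randomSeq(2000, seed = 64)), "5p"))
})

test_that("pseudomolecule classes honour the gap-free qualifier", {
  telo5 <- strrep("CCTAA", 30); telo3 <- strrep("TTAGG", 30)
  mk <- function(t5, t3, gap) {
    paste0(if (t5) telo5 else randomSeq(150),
           randomSeq(2000), if (gap) strrep("N", 100) else "",
           randomSeq(2000), if (t3) telo3 else randomSeq(150))
  }
  set.seed(65)
  seqs <- Biostrings::DNAStringSet(c(
    t2t = mk(TRUE, TRUE, FALSE),
    pairGap = mk(TRUE, TRUE, TRUE),     # both telomeres but gapped
    oneTel = mk(TRUE, FALSE, FALSE),
    oneTelGap = mk(FALSE, TRUE, TRUE),
    none = mk(FALSE, FALSE, FALSE)))
  cls <- classifyPseudomolecules(seqs)
  expect_identical(unname(cls$counts["pairOfTelomeres"]), 2L)
  expect_identical(unname(cls$counts["oneTelomere"]), 2L)
  expect_identical(unname(cls$counts["t2tGapFree"]), 1L)
  expect_lte(cls$counts["t2tGapFree"], cls$counts["pairOfTelomeres"])
  expect_lte(cls$counts["pairOfTelomeres"], length(seqs))
})

test_that("QV follows the k-mer survey identity", {
  g <- simulateGenome(1, 300000, seed = 66)
  ak <- kmerSet(g, 21)
  expect_identical(kmerQV(ak, ak)$qv, 99)       # a = 0 -> capped
  expect_equal(qvToAccuracy(40), 99.99)         # QV40 = 99.99% accuracy
  expect_equal(qvToErrorRate(40), 1e-4)
  ## a known missing fraction reproduces the closed form
  drop <- seq_len(2100)
  rkCodes <- kmerCodes(ak)[-drop]
  rk <- new("KmerSet", k = 21L, codes = rkCodes,
            counts = rep(1, length(rkCodes)))
  res <- kmerQV(ak, rk)
  a <- sum(kmerCounts(ak)[drop]) / sum(kmerCounts(ak))
  expect_equal(res$qv, -10 * log10(1 - (1 - a)^(1 / 21)))
  expect_error(kmerQV(ak, new("KmerSet", k = 15L, codes = numeric(0),
                              counts = numeric(0))), "share k")
})

test_that("map consistency counts exactly the out-of-order adjacencies", {
  pos <- data.frame(marker = sprintf("m%d", 1:6), chrom = "chr01",
                    bp = (1:6) * 10000, cM = c(0, 5, 10, 15, 20, 25),
                    stringsAsFactors = FALSE)
  expect_identical(mapConsistencyCheck(pos)$nViolations, 0L)
  swapped <- pos; swapped$cM <- c(0, 5, 15, 10, 20, 25)
  res <- mapConsistencyCheck(swapped)
  expect_identical(res$nViolations, 1L)
  expect_identical(res$violations$marker1, "m3")
  ## a chromosome mapped in the decreasing direction is consistent
  dec <- pos; dec$cM <- rev(pos$cM)
  expect_identical(mapConsistencyCheck(dec)$nViolations, 0L)
  ## unlocatable markers are reported separately
  lost <- pos; lost$bp[2] <- NA
  expect_identical(mapConsistencyCheck(lost)$unlocatable, "m2")
})

test_that("qcReport assembles the summary surface", {
  sc <- roundTripScenario(seed = 67)
  res <- runPipeline(sc$contigs, sc$gm)
  qc <- res$qc
  expect_s4_class(qc, "QCReport")
  expect_identical(unname(qcCounts(qc)["nGaps"]), 0L)
  expect_identical(unname(qcClasses(qc)["t2tGapFree"]), 3L)
  expect_identical(unname(qcLengths(qc)["totalLength"]),
                   sum(Biostrings::width(chromosomeSeqs(sc$genome))))
  expect_true(is.na(consensusQV(qc)))
})
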