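test_that("simulated genomes are seeded, telomere-capped and validated", {
  g1 <- simulateGenome(3, c(200000, 150000, 100000), seed = 1)
  g2 <- simulateGenome(3, c(200000, 150000, 100000), seed = 1)
  expect_identical(as.character(chromosomeSeqs(g1)),
                   as.character(chromosomeSeqs(g2)))
  seqs <- as.character(chromosomeSeqs(g1))
  expect_length(seqs, 3L)
  expect_true(all(startsWith(seqs, strrep("CCTAA", 60))))
  expect_true(all(endsWith(seqs, strrep("TTAGG", 60))))
  expect_error(simulateGenome(1, -5, seed = 1), "positive")
  expect_error(simulateGenome(1, 10000, telomereCopies = 0, seed = 1), ">= 1")
})

test_that("the telomere detector calls both ends of a constructed chromosome", {
  g <- simulateGenome(1, 50000, telomereCopies = 50, seed = 3)
  s <- chromosomeSeqs(g)[[1]]
  expect_true(detectTelomere(s, "5p"))
  expect_true(detectTelomere(s, "3p"))
})

test_that("autosomal F2 genotype frequencies converge to 1:2:1", {
  g <- simulateGenome(1, 100000, seed = 4)
  cr <- simulateCross(g, markerSpacingCM = 10, nProgeny = 10000,
                      missingRate = 0, recombRateCMperMb = 300, seed = 5)
  calls <- genotypeCalls(genotypes(cr))
  f2 <- names(which(individualRoles(genotypes(cr)) == "f2"))
  n <- length(f2)
  for (mk in rownames(calls)[1:2]) {
    obs <- table(factor(calls[mk, f2], c("AA", "AB", "BB"))) / n
    expected <- c(0.25, 0.5, 0.25)
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(obs - expected) <= 3 * se),
                info = paste("marker", mk))
  }
})

test_that("gamete recombination matches the Haldane prediction at 1 cM", {
  set.seed(6)
  r <- (1 - exp(-2 * 1 / 100)) / 2  # 0.0099007
  g <- linkscaf:::.haldaneGametes(rep(r, 1L), 20000L)
  obs <- mean(g[, 1] != g[, 2])
  se <- sqrt(r * (1 - r) / 20000)
  expect_lt(abs(obs - r), 3 * se)
})

test_that("ZW inheritance gives hemizygous all-female F2 and the F1 pattern", {
  g <- simulateGenome(2, c(100000, 80000), sexChromosome = TRUE, seed = 7)
  cr <- simulateCross(g, markerSpacingCM = 10, nProgeny = 300,
                      missingRate = 0, recombRateCMperMb = 300, seed = 8)
  gm <- genotypes(cr)
  calls <- genotypeCalls(gm)
  zMarkers <- rownames(calls)[startsWith(rownames(calls), "chr01")]
  f2 <- names(which(individualRoles(gm) == "f2"))
  expect_true(all(calls[zMarkers, f2] %in% c("AA", "BB")))
  expect_true(all(calls[zMarkers, "F1_female"] == "BB"))
  expect_true(all(calls[zMarkers, "F1_male"] == "AB"))
  z <- classifyZMarkers(gm)
  expect_true(all(z[zMarkers]))
  expect_false(any(z[setdiff(names(z), zMarkers)]))
  expect_error(simulateCross(g, nProgeny = 1, seed = 1), ">= 2")
})

test_that("fragmentation records truth and collapses back to the chromosomes", {
  g <- simulateGenome(2, c(120000, 100000), seed = 9)
  fr <- fragmentGenome(g, targetFragmentBp = 40000, overlapRange = c(2000, 4000),
                       nChimeras = 0, randomOrient = TRUE, seed = 10)
  iv <- sourceIntervals(fr$truth)
  expect_true(all(table(iv$contig) == 1L))  # no chimeras: one interval each
  ## overlap-collapsed concatenation reproduces each truth chromosome
  for (ch in names(chromosomeSeqs(g))) {
    sub <- iv[iv$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    rebuilt <- ""
    done <- 0L
    for (i in seq_len(nrow(sub))) {
      s <- fr$contigs[[sub$contig[i]]]
      if (sub$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      s <- as.character(s)
      rebuilt <- paste0(rebuilt, substring(s, done - sub$start[i] + 2L))
      done <- sub$end[i]
    }
    expect_identical(rebuilt, as.character(chromosomeSeqs(g)[[ch]]))
  }
  expect_error(fragmentGenome(g, targetFragmentBp = 3000,
                              overlapRange = c(2000, 4000), seed = 1),
               "smaller than the maximum overlap")
})

test_that("implanted chimeras have two source intervals and a junction", {
  g <- simulateGenome(3, c(120000, 100000, 90000), seed = 11)
  fr <- fragmentGenome(g, targetFragmentBp = 45000, overlapRange = c(2000, 4000),
                       nChimeras = 2, seed = 12)
  iv <- sourceIntervals(fr$truth)
  nParts <- table(iv$contig)
  expect_identical(sum(nParts == 2L), 2L)
  expect_length(chimeraJunctions(fr$truth), 2L)
  for (ct in names(chimeraJunctions(fr$truth))) {
    sub <- iv[iv$contig == ct, ]
    expect_identical(nrow(sub), 2L)
    expect_length(unique(sub$chrom), 2L)  # parts from different chromosomes
    j <- chimeraJunctions(fr$truth)[[ct]]
    expect_identical(as.integer(j), sub$end[1] - sub$start[1] + 1L)
  }
})

test_that("coverage dips mark junctions and only junctions", {
  g <- simulateGenome(3, c(120000, 100000, 90000), seed = 13)
  fr <- fragmentGenome(g, targetFragmentBp = 45000, overlapRange = c(2000, 4000),
                       nChimeras = 1, seed = 14)
  cov <- simulateCoverage(fr$contigs, fr$truth, meanDepth = 30, dipDepth = 2,
                          windowBp = 100, seed = 15)
  junctions <- chimeraJunctions(fr$truth)
  floor3sd <- 2 + 3 * sqrt(2)
  for (ct in names(coverageDepths(cov))) {
    d <- coverageDepths(cov)[[ct]]
    if (ct %in% names(junctions)) {
      jw <- ceiling(junctions[[ct]] / 100)
      expect_lte(abs(which.min(d) - jw), 2)
    } else {
      expect_true(all(d > floor3sd))
    }
  }
  expect_error(simulateCoverage(fr$contigs, fr$truth, meanDepth = 5,
                                dipDepth = 10), "below")
  ## degenerate: window larger than the contig gives a single-window track
  tiny <- Biostrings::DNAStringSet(c(ctgT = randomSeq(500, seed = 1)))
  emptyTruth <- new("FragmentationTruth",
                    intervals = data.frame(contig = "ctgT", part = 1L,
                                           chrom = "chr01", start = 1L,
                                           end = 500L, strand = "+"),
                    chimeraJunctions = stats::setNames(numeric(0), character(0)),
                    overlapRange = c(0, 0))
  cov1 <- simulateCoverage(tiny, emptyTruth, windowBp = 10000, seed = 1)
  expect_length(coverageDepths(cov1)$ctgT, 1L)
})

test_that("error-free read k-mer sets cover the source and empty sets are flagged", {
  g <- simulateGenome(1, 60000, seed = 16)
  ak <- kmerSet(g, 21)
  rk <- simulateKmerReadset(g, k = 21, perBaseError = 0, depth = 1, seed = 17)
  expect_true(all(kmerCodes(ak) %in% kmerCodes(rk)))
  rk0 <- simulateKmerReadset(g, k = 21, depth = 0)
  expect_length(kmerCodes(rk0), 0L)
  expect_warning(res <- kmerQV(ak, rk0), "non-estimable")
  expect_true(is.na(res$qv))
  expect_error(simulateKmerReadset(g, k = 20), "odd")
})

test_that("seeded determinism holds for every simulator", {
  g <- simulateGenome(2, c(50000, 40000), seed = 20)
  expect_identical(simulateCross(g, nProgeny = 30, recombRateCMperMb = 300,
                                 seed = 21),
                   simulateCross(g, nProgeny = 30, recombRateCMperMb = 300,
                                 seed = 21))
  f1 <- fragmentGenome(g, 20000, c(1000, 2000), seed = 22)
  f2 <- fragmentGenome(g, 20000, c(1000, 2000), seed = 22)
  expect_identical(as.character(f1$contigs), as.character(f2$contigs))
  expect_identical(sourceIntervals(f1$truth), sourceIntervals(f2$truth))
  expect_identical(simulateKmerReadset(g, 21, 1e-3, 2, seed = 23),
                   simulateKmerReadset(g, 21, 1e-3, 2, seed = 23))
})

test_that("mutateSequences places the exact substitution count", {
  s <- Biostrings::DNAStringSet(c(a = randomSeq(10000, seed = 24)))
  res <- mutateSequences(s, rate = 1e-3, seed = 25)
  expect_identical(res$nSubstitutions, 10L)
  diffs <- mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)),
                  as.character(s), as.character(res$seqs))
  expect_identical(unname(diffs), 10L)
})
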