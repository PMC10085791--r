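test_that("missingness filtering is strict at the 20% boundary", {
  n <- 102L
  f2 <- randomF2Calls(12, n, seed = 1)
  rownames(f2) <- c(sprintf("filler%02d", 1:9), "clean", "boundary", "over")
  f2["boundary", 1:20] <- NA      # 20/100 = 20.0% after 2 individuals drop
  f2["over", 1:21] <- NA          # 21/100 = 21%
  ## two individuals miss 25% of the 12 markers and must be removed first
  f2[c("filler01", "filler02", "filler03"), 101] <- NA
  f2[c("filler01", "filler02", "filler03"), 102] <- NA
  gm <- makeGenotypeMatrix(f2)
  out <- filterMissingness(gm, 0.20)
  kept <- rownames(genotypeCalls(out))
  expect_true("clean" %in% kept)
  expect_true("boundary" %in% kept)   # exactly 20% is retained
  expect_false("over" %in% kept)      # more than 20% is excluded
  f2ids <- names(which(individualRoles(out) == "f2"))
  expect_length(f2ids, 100L)          # the two bad individuals are gone
})

test_that("Z classification follows the three F1/F2 criteria", {
  f2 <- matrix(rep(c("AA", "BB"), 10), 1, 20,
               dimnames = list("z1", sprintf("F2_%02d", 1:20)))
  gmZ <- makeGenotypeMatrix(f2, f1f = "BB", f1m = "AB")
  expect_true(classifyZMarkers(gmZ)[["z1"]])
  f2het <- f2; f2het[1, 3] <- "AB"
  gmHet <- makeGenotypeMatrix(f2het, f1f = "BB", f1m = "AB")
  expect_false(classifyZMarkers(gmHet)[["z1"]])  # any F2 AB breaks criterion 3
  gmF1 <- makeGenotypeMatrix(f2, f1f = "AB", f1m = "AB")
  expect_false(classifyZMarkers(gmF1)[["z1"]])   # F1 female must be paternal hom
  gmNoF1 <- gmZ[, setdiff(colnames(genotypeCalls(gmZ)), "F1_female")]
  expect_error(classifyZMarkers(gmNoF1), "required")
})

test_that("the autosomal filter requires both F1 parents heterozygous", {
  f2 <- randomF2Calls(3, 30, seed = 2)
  rownames(f2) <- c("ok", "f1hom", "f1miss")
  gm <- makeGenotypeMatrix(f2)
  calls <- genotypeCalls(gm)
  calls["f1hom", "F1_female"] <- "AA"
  calls["f1miss", "F1_male"] <- NA
  gm <- initialize(gm, calls = calls)
  kept <- rownames(genotypeCalls(filterAutosomal(gm)))
  expect_identical(kept, "ok")
})

test_that("Z-to-backcross recoding replaces exactly the paternal homozygotes", {
  f2 <- matrix(c("AA", "BB", "BB", "AA"), 1, 4,
               dimnames = list("z1", sprintf("F2_%02d", 1:4)))
  gm <- makeGenotypeMatrix(f2, f1f = "BB", f1m = "AB")
  out <- convertZToBackcross(gm)
  f2ids <- names(which(individualRoles(out) == "f2"))
  expect_identical(unname(genotypeCalls(out)["z1", f2ids]),
                   c("AA", "AB", "AB", "AA"))
  expect_false(any(genotypeCalls(out) == "BB", na.rm = TRUE))
  ## all-maternal marker stays unchanged
  allA <- matrix("AA", 1, 4, dimnames = list("z2", sprintf("F2_%02d", 1:4)))
  gm2 <- makeGenotypeMatrix(allA, f1f = "BB", f1m = "AB")
  expect_identical(genotypeCalls(convertZToBackcross(gm2))["z2", f2ids],
                   genotypeCalls(gm2)["z2", f2ids])
  ## a marker failing the Z criteria is rejected
  gmAuto <- makeGenotypeMatrix(randomF2Calls(1, 20, seed = 3))
  expect_error(convertZToBackcross(gmAuto), "non-Z")
})

test_that("segregation chi-square matches hand-computed values", {
  mkCalls <- function(nAA, nAB, nBB = NULL) {
    v <- c(rep("AA", nAA), rep("AB", nAB), if (!is.null(nBB)) rep("BB", nBB))
    matrix(v, 1, length(v), dimnames = list("m", sprintf("F2_%03d", seq_along(v))))
  }
  perfect <- segregationTest(makeGenotypeMatrix(mkCalls(25, 50, 25)), "f2")
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
  skewed <- segregationTest(makeGenotypeMatrix(mkCalls(30, 50, 20)), "f2")
  expect_equal(skewed$chi2, 2.0)       # (30-25)^2/25 + 0 + (20-25)^2/25
  expect_identical(skewed$df, 2L)
  bc <- segregationTest(makeGenotypeMatrix(mkCalls(60, 40)), "backcross")
  expect_equal(bc$chi2, 4.0)           # (60-50)^2/50 + (40-50)^2/50
  expect_identical(bc$df, 1L)
  allNA <- matrix(NA_character_, 1, 10,
                  dimnames = list("m", sprintf("F2_%03d", 1:10)))
  empty <- segregationTest(makeGenotypeMatrix(allNA), "f2")
  expect_true(is.na(empty$chi2))       # zero informative -> non-estimable
})

test_that("backcross two-point estimates match the closed forms", {
  c1 <- rep("AA", 100)
  c2 <- c(rep("AB", 10), rep("AA", 90))   # 10 recombinants of 100
  res <- estimateRfBackcross(c1, c2)
  expect_equal(res$rHat, 0.10)
  expect_equal(res$lod, 90 * log10(1.8) + 10 * log10(0.2), tolerance = 1e-9)
  expect_equal(round(res$lod, 2), 15.98)
  null <- estimateRfBackcross(rep(c("AA", "AB"), 50), rep(c("AA", "AB", "AB", "AA"), 25))
  expect_equal(null$rHat, 0.5)
  expect_equal(null$lod, 0)
})

test_that("F2 EM agrees with the grid-search oracle and handles edge cases", {
  concordant <- rep(c("AA", "AB", "BB"), c(25, 50, 25))
  res <- estimateRfF2(concordant, concordant)
  expect_equal(res$rHat, 0)
  set.seed(11)
  indep1 <- sample(c("AA", "AB", "BB"), 4000, TRUE, c(1, 2, 1) / 4)
  indep2 <- sample(c("AA", "AB", "BB"), 4000, TRUE, c(1, 2, 1) / 4)
  resI <- estimateRfF2(indep1, indep2)
  expect_gt(resI$rHat, 0.45)
  expect_lt(resI$lod, 2)
  ## EM equals exhaustive-search MLE on simulated linked pairs
  g <- simulateGenome(1, 200000, seed = 12)
  worst <- 0
  for (s in 1:20) {
    cr <- simulateCross(g, markerSpacingCM = 8, nProgeny = 150,
                        missingRate = 0.05, recombRateCMperMb = 300,
                        seed = 100 + s)
    calls <- genotypeCalls(genotypes(cr))
    f2 <- names(which(individualRoles(genotypes(cr)) == "f2"))
    em <- estimateRfF2(calls[1, f2], calls[2, f2])
    grid <- gridSearchRfF2(calls[1, f2], calls[2, f2])
    worst <- max(worst, abs(em$rHat - grid))
  }
  expect_lte(worst, 1e-4)
})

test_that("grouping is the transitive closure of the LOD graph", {
  mkLod <- function(vals) {
    m <- matrix(vals, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    diag(m) <- NA
    m
  }
  allLinked <- mkLod(10)
  expect_length(unique(groupMarkers(allLinked, 3)), 1L)
  twoClusters <- matrix(0, 4, 4, dimnames = rep(list(c("A", "B", "C", "D")), 2))
  twoClusters["A", "B"] <- twoClusters["B", "A"] <- 8
  twoClusters["C", "D"] <- twoClusters["D", "C"] <- 8
  diag(twoClusters) <- NA
  grp <- groupMarkers(twoClusters, 3)
  expect_length(unique(grp), 2L)
  expect_identical(grp[["A"]], grp[["B"]])
  expect_identical(grp[["C"]], grp[["D"]])
  chain <- mkLod(0)
  chain["A", "B"] <- chain["B", "A"] <- 5
  chain["B", "C"] <- chain["C", "B"] <- 5
  expect_length(unique(groupMarkers(chain, 3)), 1L)  # A-B-C chained
})

test_that("mapping functions match hand-evaluated values and invert exactly", {
  expect_equal(mapDistance(0, "haldane"), 0)
  expect_equal(mapDistance(0, "kosambi"), 0)
  expect_equal(mapDistance(0.1, "haldane"), -50 * log(0.8))
  expect_equal(round(mapDistance(0.1, "haldane"), 3), 11.157)
  expect_equal(round(mapDistance(0.1, "kosambi"), 3), 10.137)
  r <- seq(0, 0.49, by = 0.01)
  for (fn in c("haldane", "kosambi"))
    expect_lt(max(abs(mapDistanceInverse(mapDistance(r, fn), fn) - r)), 1e-10)
  expect_warning(d <- mapDistance(0.5, "haldane"), "Inf")
  expect_identical(d, Inf)
})

test_that("marker ordering recovers simulated truth up to reversal", {
  g <- simulateGenome(1, 270000, seed = 13)
  cr <- simulateCross(g, markerSpacingCM = 10, nProgeny = 500,
                      missingRate = 0, recombRateCMperMb = 300, seed = 14)
  gm <- genotypes(cr)
  markers <- rownames(genotypeCalls(gm))
  expect_gte(length(markers), 8L)
  tp <- pairwiseRf(gm, "f2")
  ord <- orderMarkers(markers, tp$r)$marker
  expect_true(identical(ord, markers) || identical(ord, rev(markers)))
  ordRev <- orderMarkers(rev(markers), tp$r)$marker
  expect_identical(ord, ordRev)  # input order does not matter
  two <- orderMarkers(markers[1:2], tp$r)
  expect_identical(two$marker, markers[1:2])
  expect_equal(two$cM[1], 0)
  expect_equal(two$cM[2], mapDistance(tp$r[markers[1], markers[2]], "kosambi"))
})

test_that("buildGeneticMap recovers a small genome's group structure", {
  g <- simulateGenome(3, c(170000, 170000, 170000), sexChromosome = TRUE,
                      seed = 15)
  cr <- simulateCross(g, markerSpacingCM = 10, nProgeny = 150,
                      missingRate = 0.05, recombRateCMperMb = 300, seed = 16)
  map <- buildGeneticMap(genotypes(cr))
  tb <- mapTable(map)
  truthChrom <- substr(tb$marker, 1, 5)
  expect_identical(length(unique(tb$group)), 3L)
  ## groups coincide exactly with chromosomes
  expect_true(all(tapply(truthChrom, tb$group,
                         function(x) length(unique(x))) == 1L))
  zGroups <- unique(tb$group[truthChrom == "chr01"])
  expect_true(all(startsWith(zGroups, "LGZ")))
  expect_false(is.unsorted(tb$cM[tb$group == tb$group[1]]))
})

test_that("28 simulated chromosomes yield 27 autosomal + 1 Z major groups", {
  ## single-linkage at LOD 3 can be bridged by a rare spurious pair
  ## (~2e-4 per null pair); the partition must be exact in most seeds and
  ## no true group may ever be split.
  exact <- 0L
  for (s in 1:5) {
    g <- simulateGenome(28, 13340, sexChromosome = TRUE, telomereCopies = 20,
                        seed = 1000 + s)
    cr <- simulateCross(g, markerSpacingCM = 20, nProgeny = 150,
                        missingRate = 0.05, recombRateCMperMb = 3000,
                        seed = 2000 + s)
    map <- buildGeneticMap(genotypes(cr))
    tb <- mapTable(map)
    truthChrom <- substr(tb$marker, 1, 5)
    ## no split: each chromosome's markers sit in one group
    expect_true(all(tapply(tb$group, truthChrom,
                           function(x) length(unique(x))) == 1L))
    zGroups <- unique(tb$group[truthChrom == "chr01"])
    expect_length(zGroups, 1L)
    expect_true(startsWith(zGroups, "LGZ"))
    nAuto <- length(unique(tb$group[truthChrom != "chr01"]))
    if (nAuto == 27L) exact <- exact + 1L
  }
  expect_gte(exact, 3L)
})
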