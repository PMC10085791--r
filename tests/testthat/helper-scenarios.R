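# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed per call site.

# A genotype matrix built directly from an F2 call matrix (markers x F2),
# with canonical parent/F1 rows prepended.
makeGenotypeMatrix <- function(f2calls, contig = "ctg1",
                               position = seq_len(nrow(f2calls)) * 1000L,
                               f1f = "AB", f1m = "AB") {
  m <- nrow(f2calls)
  markers <- rownames(f2calls)
  if (is.null(markers)) markers <- sprintf("M%02d", seq_len(m))
  calls <- cbind(P_maternal = rep("AA", m), P_paternal = rep("BB", m),
                 F1_female = rep(f1f, length.out = m),
                 F1_male = rep(f1m, length.out = m), f2calls)
  rownames(calls) <- markers
  ids <- colnames(calls)
  roles <- stats::setNames(c("parent_maternal", "parent_paternal", "f1_female",
                             "f1_male", rep("f2", ncol(f2calls))), ids)
  mi <- data.frame(contig = rep(contig, length.out = m),
                   position = as.integer(rep(position, length.out = m)),
                   row.names = markers, stringsAsFactors = FALSE)
  new("GenotypeMatrix", calls = calls, roles = roles, markerInfo = mi,
      sex = stats::setNames(rep(NA_character_, length(ids)), ids))
}

# F2 call matrix for a marker simulated in isolation (for filter tests)
randomF2Calls <- function(m, n, seed = 1) {
  set.seed(seed)
  matrix(sample(c("AA", "AB", "BB"), m * n, TRUE, c(1, 2, 1) / 4), m, n,
         dimnames = list(NULL, sprintf("F2_%03d", seq_len(n))))
}

# The desk-scale study scenario: 3 chromosomes (~0.5 Mb), map scale
# ~50 cM per chromosome (physically down-scaled genome at 300 cM/Mb),
# 10 cM marker grid, ~2 fragments per chromosome with 3-8 kb exact
# terminal overlaps.
roundTripScenario <- function(seed, nChimeras = 0L, nProgeny = 200L,
                              withCoverage = nChimeras > 0L) {
  genome <- simulateGenome(3, c(180000L, 160000L, 140000L),
                           telomereCopies = 60L, seed = seed * 10L + 1L)
  cross <- simulateCross(genome, markerSpacingCM = 10, nProgeny = nProgeny,
                         missingRate = 0.05, recombRateCMperMb = 300,
                         seed = seed * 10L + 2L)
  frag <- fragmentGenome(genome, targetFragmentBp = 85000L,
                         overlapRange = c(3000L, 8000L),
                         nChimeras = nChimeras, seed = seed * 10L + 3L)
  assign <- mapMarkersToContigs(cross, frag$truth)
  gm <- genotypes(cross)
  mi <- markerInfo(gm)
  mi[assign$marker, "contig"] <- assign$contig
  mi[assign$marker, "position"] <- assign$position
  gm <- initialize(gm, markerInfo = mi)
  coverage <- if (withCoverage)
    simulateCoverage(frag$contigs, frag$truth, meanDepth = 30, dipDepth = 2,
                     windowBp = 100L, seed = seed * 10L + 4L) else NULL
  list(genome = genome, cross = cross, contigs = frag$contigs,
       truth = frag$truth, assign = assign, gm = gm, coverage = coverage)
}

# Independent grid-search oracle for the two-point F2 likelihood: same
# multinomial model, maximized by exhaustive search instead of EM.
gridSearchRfF2 <- function(calls1, calls2, grid = seq(1e-4, 0.5, by = 1e-4)) {
  keep <- !is.na(calls1) & !is.na(calls2)
  g1 <- match(calls1[keep], c("AA", "AB", "BB")) - 1L
  g2 <- match(calls2[keep], c("AA", "AB", "BB")) - 1L
  N <- table(factor(g1, 0:2), factor(g2, 0:2))
  ll <- vapply(grid, function(r) {
    p <- matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
                  r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
                  r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4), 3, 3, byrow = TRUE)
    sum(ifelse(N > 0, N * log(pmax(p, 1e-300)), 0))
  }, numeric(1L))
  grid[which.max(ll)]
}

# random DNA string without telomere structure
randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}
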