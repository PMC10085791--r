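#' @include AllClasses.R
NULL

## internal: coerce the various sequence containers to a named character vector
.asCharSeqs <- function(x) {
  if (is(x, "TruthGenome")) x <- x@seqs
  if (is(x, "DNAStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x)) return(x)
  stop("expected a TruthGenome, DNAStringSet or character vector")
}

.randomDNA <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a multi-chromosome genome with telomeric ends
#'
#' Generates random chromosome sequences of the requested lengths and GC
#' content, implanting `telomereCopies` tandem copies of the telomere unit
#' (`CCTAA` by default, the lepidopteran plus-strand motif) at the 5' end of
#' every chromosome and of its reverse complement (`TTAGG`) at the 3' end.
#' Optionally designates the first chromosome as the Z sex chromosome.
#'
#' @param nChromosomes Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths in bp (recycled to
#'   `nChromosomes`); each must exceed twice the telomere array length.
#' @param telomereCopies Tandem unit copies per end (>= 1).
#' @param gc GC fraction of the non-telomeric sequence.
#' @param sexChromosome Logical; if `TRUE` the first chromosome is the Z.
#' @param telomereUnit 5-mer telomere unit (plus strand, 5' form).
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @return A [TruthGenome-class].
#' @examples
#' g <- simulateGenome(2, c(60000, 40000), seed = 1)
#' g
#' @export
simulateGenome <- function(nChromosomes, lengths, telomereCopies = 60L,
                           gc = 0.38, sexChromosome = FALSE,
                           telomereUnit = "CCTAA", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (telomereCopies < 1L) stop("telomereCopies must be >= 1")
  lengths <- as.integer(rep_len(lengths, nChromosomes))
  teloLen <- nchar(telomereUnit) * telomereCopies
  if (any(lengths <= 2L * teloLen))
    stop("chromosome lengths must exceed twice the telomere array length")
  telo5 <- strrep(telomereUnit, telomereCopies)
  telo3 <- strrep(as.character(reverseComplement(DNAString(telomereUnit))),
                  telomereCopies)
  seqs <- vapply(lengths, function(L) {
    paste0(telo5, .randomDNA(L - 2L * teloLen, gc), telo3)
  }, character(1L))
  names(seqs) <- sprintf("chr%02d", seq_len(nChromosomes))
  new("TruthGenome", seqs = DNAStringSet(seqs),
      sexChromosome = if (sexChromosome) names(seqs)[1L] else NA_character_,
      telomereUnit = telomereUnit, telomereCopies = as.integer(telomereCopies))
}

## one set of n gametes over m linked markers under the Haldane model:
## independent recombination in each interval (no interference), phase known.
## rvec has length m-1. Returns n x m 0/1 matrix of transmitted alleles.
.haldaneGametes <- function(rvec, n) {
  m <- length(rvec) + 1L
  g <- matrix(0L, n, m)
  g[, 1L] <- rbinom(n, 1L, 0.5)
  for (j in seq_len(m - 1L)) {
    ## crossover in interval j flips the transmitted allele (XOR)
    g[, j + 1L] <- as.integer(g[, j] != rbinom(n, 1L, rvec[j]))
  }
  g
}

#' Simulate an F2 intercross over a truth genome
#'
#' Places markers on a regular genetic grid along every chromosome (linear
#' bp-to-cM relation at `recombRateCMperMb`), then simulates meiosis under
#' the Haldane (no-interference) model. Parents are fixed for opposite
#' homozygotes (`AA` maternal, `BB` paternal); F1 parents are heterozygous
#' at autosomal markers. If the genome carries a Z chromosome, ZW
#' inheritance is simulated: with all-female progeny each F2 carries one
#' paternally derived Z, so Z-linked calls are `AA` or `BB`, never `AB`;
#' the F1 female is `BB` (paternal homozygote) and the F1 male `AB` at
#' Z-linked markers. Missing calls are inserted at `missingRate` into the
#' F2 rows only.
#'
#' @param genome A [TruthGenome-class].
#' @param markerSpacingCM Marker spacing on the genetic grid in cM.
#' @param nProgeny Number of F2 individuals (>= 2).
#' @param missingRate Fraction of F2 calls masked as missing.
#' @param recombRateCMperMb Genetic length per physical Mb.
#' @param progenySex `"all_female"` (the sampled design) or `"mixed"`.
#' @param seed Integer seed.
#' @return A [SimulatedCross-class].
#' @export
simulateCross <- function(genome, markerSpacingCM = 5, nProgeny = 100L,
                          missingRate = 0.05, recombRateCMperMb = 3,
                          progenySex = c("all_female", "mixed"), seed = NULL) {
  progenySex <- match.arg(progenySex)
  if (!is.null(seed)) set.seed(seed)
  if (nProgeny < 2L) stop("nProgeny must be >= 2")
  if (markerSpacingCM <= 0) stop("markerSpacingCM must be positive")
  seqs <- chromosomeSeqs(genome)
  widths <- width(seqs)
  zChrom <- sexChromosome(genome)

  sex <- if (progenySex == "all_female") rep("female", nProgeny)
         else sample(c("female", "male"), nProgeny, replace = TRUE)

  truthList <- list(); callList <- list()
  for (ci in seq_along(seqs)) {
    chrom <- names(seqs)[ci]
    totalCM <- widths[ci] / 1e6 * recombRateCMperMb
    cMpos <- seq(markerSpacingCM / 2, totalCM, by = markerSpacingCM)
    if (!length(cMpos)) next
    bp <- pmax(1L, pmin(widths[ci], as.integer(round(cMpos / totalCM * widths[ci]))))
    m <- length(cMpos)
    markers <- sprintf("%s_M%03d", chrom, seq_len(m))
    rvec <- if (m > 1L) (1 - exp(-2 * diff(cMpos) / 100)) / 2 else numeric(0L)

    isZ <- !is.na(zChrom) && chrom == zChrom
    if (!isZ) {
      gm <- .haldaneGametes(rvec, nProgeny)  # maternal F1 gamete
      gp <- .haldaneGametes(rvec, nProgeny)  # paternal F1 gamete
      f2 <- matrix(GENOTYPE_CODES[gm + gp + 1L], nProgeny, m)
      f1f <- rep("AB", m); f1m <- rep("AB", m)
    } else {
      ## F1 male is Z(A)Z(B); his gametes recombine. F1 female is Z(B)W, so
      ## her Z gamete is the intact paternal haplotype (all B).
      gp <- .haldaneGametes(rvec, nProgeny)
      f2 <- matrix("", nProgeny, m)
      fem <- sex == "female"
      f2[fem, ] <- c("AA", "BB")[gp[fem, , drop = FALSE] + 1L]   # hemizygous Z
      if (any(!fem))
        f2[!fem, ] <- c("AB", "BB")[gp[!fem, , drop = FALSE] + 1L]  # B + gamete
      f1f <- rep("BB", m); f1m <- rep("AB", m)
    }
    calls <- rbind(rep("AA", m), rep("BB", m), f1f, f1m, f2)
    callList[[chrom]] <- calls
    truthList[[chrom]] <- data.frame(marker = markers, chrom = chrom,
                                     bp = bp, cM = cMpos,
                                     stringsAsFactors = FALSE)
  }
  if (!length(truthList)) stop("no markers fit on any chromosome; decrease markerSpacingCM")
  truth <- do.call(rbind, truthList)
  rownames(truth) <- NULL
  calls <- do.call(cbind, callList)  # individuals x markers
  ids <- c("P_maternal", "P_paternal", "F1_female", "F1_male",
           sprintf("F2_%03d", seq_len(nProgeny)))
  roles <- setNames(c("parent_maternal", "parent_paternal", "f1_female",
                      "f1_male", rep("f2", nProgeny)), ids)
  sexVec <- setNames(c("female", "male", "female", "male", sex), ids)
  dimnames(calls) <- list(ids, truth$marker)
  if (missingRate > 0) {
    f2idx <- which(roles == "f2")
    sub <- calls[f2idx, , drop = FALSE]
    sub[runif(length(sub)) < missingRate] <- NA_character_
    calls[f2idx, ] <- sub
  }
  mi <- data.frame(contig = truth$chrom, position = truth$bp,
                   row.names = truth$marker, stringsAsFactors = FALSE)
  gm <- new("GenotypeMatrix", calls = t(calls), roles = roles,
            markerInfo = mi, sex = sexVec)
  new("SimulatedCross", genotypes = gm, truthPositions = truth,
      nProgeny = as.integer(nProgeny), missingRate = missingRate,
      progenySex = progenySex)
}

#' Fragment a truth genome into an overlapping contig set
#'
#' Tiles every chromosome with roughly equal-sized fragments whose adjacent
#' ends share a sampled terminal overlap, emulating a draft assembly that
#' fragmented despite overlapping reads. Optionally implants chimeric
#' contigs by joining fragments from two different chromosomes, recording
#' the junction offsets. Contig order is shuffled and, when `randomOrient`,
#' each piece is placed on a random strand.
#'
#' @param genome A [TruthGenome-class].
#' @param targetFragmentBp Approximate fragment size in bp.
#' @param overlapRange Length-2 integer, (min, max) terminal overlap in bp.
#' @param nChimeras Number of two-part chimeric contigs to implant.
#' @param randomOrient Randomize the strand of each piece.
#' @param seed Integer seed.
#' @return A list with `contigs` (named [Biostrings::DNAStringSet]) and
#'   `truth` (a [FragmentationTruth-class]).
#' @export
fragmentGenome <- function(genome, targetFragmentBp, overlapRange = c(3000L, 8000L),
                           nChimeras = 0L, randomOrient = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (overlapRange[1L] < 0L) stop("overlap range minimum must be >= 0")
  if (nChimeras < 0L) stop("nChimeras must be >= 0")
  seqs <- chromosomeSeqs(genome)
  widths <- width(seqs)
  nPieces <- pmax(1L, as.integer(round(widths / targetFragmentBp)))
  if (any(widths / nPieces <= max(overlapRange)))
    stop("fragment size smaller than the maximum overlap")

  pieces <- list()
  for (ci in seq_along(seqs)) {
    np <- nPieces[ci]
    bounds <- round(seq(0, widths[ci], length.out = np + 1L))
    ov <- if (np > 1L)
      overlapRange[1L] + sample.int(overlapRange[2L] - overlapRange[1L] + 1L,
                                    np - 1L, replace = TRUE) - 1L
      else integer(0L)
    for (p in seq_len(np)) {
      start <- if (p == 1L) 1L else as.integer(bounds[p] + 1L - ov[p - 1L])
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = names(seqs)[ci], start = start,
        end = as.integer(bounds[p + 1L]), stringsAsFactors = FALSE)
    }
  }
  pieces <- do.call(rbind, pieces)
  npc <- nrow(pieces)

  ## choose chimera part pairs from different chromosomes, each piece used once
  chimPairs <- matrix(integer(0L), 0L, 2L)
  if (nChimeras > 0L) {
    avail <- seq_len(npc)
    for (i in seq_len(nChimeras)) {
      if (length(avail) < 2L || length(unique(pieces$chrom[avail])) < 2L)
        stop("not enough fragments on distinct chromosomes to implant chimeras")
      a <- sample(avail, 1L)
      b <- sample(avail[pieces$chrom[avail] != pieces$chrom[a]], 1L)
      chimPairs <- rbind(chimPairs, c(a, b))
      avail <- setdiff(avail, c(a, b))
    }
  }

  pieceStrand <- if (randomOrient) sample(c("+", "-"), npc, replace = TRUE)
                 else rep("+", npc)
  extract <- function(i) {
    s <- subseq(seqs[[pieces$chrom[i]]], pieces$start[i], pieces$end[i])
    if (pieceStrand[i] == "-") s <- reverseComplement(s)
    as.character(s)
  }

  inChimera <- if (nrow(chimPairs)) as.vector(chimPairs) else integer(0L)
  contigSeq <- character(0L); ivList <- list(); junctions <- numeric(0L)
  for (i in setdiff(seq_len(npc), inChimera)) {
    contigSeq <- c(contigSeq, extract(i))
    ivList[[length(ivList) + 1L]] <-
      cbind(pieces[i, , drop = FALSE], part = 1L, strand = pieceStrand[i],
            id = length(contigSeq))
  }
  for (r in seq_len(nrow(chimPairs))) {
    a <- chimPairs[r, 1L]; b <- chimPairs[r, 2L]
    sa <- extract(a); sb <- extract(b)
    contigSeq <- c(contigSeq, paste0(sa, sb))
    id <- length(contigSeq)
    ivList[[length(ivList) + 1L]] <-
      cbind(pieces[a, , drop = FALSE], part = 1L, strand = pieceStrand[a], id = id)
    ivList[[length(ivList) + 1L]] <-
      cbind(pieces[b, , drop = FALSE], part = 2L, strand = pieceStrand[b], id = id)
    junctions <- c(junctions, setNames(nchar(sa), id))
  }
  iv <- do.call(rbind, ivList)

  ord <- sample.int(length(contigSeq))  # shuffle assembly order
  newName <- setNames(sprintf("ctg%03d", order(ord)), seq_along(contigSeq))
  contigs <- DNAStringSet(setNames(contigSeq[ord], newName[as.character(ord)]))
  iv$contig <- newName[as.character(iv$id)]
  iv <- iv[order(iv$contig, iv$part), c("contig", "part", "chrom", "start", "end", "strand")]
  rownames(iv) <- NULL
  names(junctions) <- newName[names(junctions)]
  truth <- new("FragmentationTruth", intervals = iv,
               chimeraJunctions = junctions,
               overlapRange = as.numeric(overlapRange))
  list(contigs = contigs, truth = truth)
}

#' Map simulated markers onto fragmented contigs
#'
#' Transfers each marker from truth-chromosome coordinates to the
#' coordinates of the simulated contig that carries it, honouring piece
#' strand and chimera part offsets. A marker falling inside a terminal
#' overlap (present in two contigs) is assigned to the contig where it lies
#' deepest in the interior, mirroring a best unique read-mapping.
#'
#' @param cross A [SimulatedCross-class].
#' @param truth The [FragmentationTruth-class] from [fragmentGenome()].
#' @return `data.frame` with columns `marker`, `contig`, `position` (1-based
#'   on the contig), `chrom`, `bp`, `cM` (truth coordinates).
#' @export
mapMarkersToContigs <- function(cross, truth) {
  tp <- truthPositions(cross)
  iv <- sourceIntervals(truth)
  partLen <- iv$end - iv$start + 1L
  ## offset of each part within its contig
  offset <- integer(nrow(iv))
  for (ct in unique(iv$contig)) {
    idx <- which(iv$contig == ct)
    idx <- idx[order(iv$part[idx])]
    offset[idx] <- cumsum(c(0L, partLen[idx]))[seq_along(idx)]
  }
  out <- vector("list", nrow(tp))
  for (i in seq_len(nrow(tp))) {
    cand <- which(iv$chrom == tp$chrom[i] & iv$start <= tp$bp[i] & iv$end >= tp$bp[i])
    if (!length(cand)) next
    depth <- pmin(tp$bp[i] - iv$start[cand], iv$end[cand] - tp$bp[i])
    j <- cand[which.max(depth)]
    p <- if (iv$strand[j] == "+") tp$bp[i] - iv$start[j] + 1L
         else iv$end[j] - tp$bp[i] + 1L
    out[[i]] <- data.frame(marker = tp$marker[i], contig = iv$contig[j],
                           position = offset[j] + p, chrom = tp$chrom[i],
                           bp = tp$bp[i], cM = tp$cM[i], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a windowed read-coverage track
#'
#' Draws Poisson(`meanDepth`) depths for fixed-size windows tiling every
#' contig, then overwrites the windows within one window of each recorded
#' chimeric junction with Poisson(`dipDepth`) draws, creating the
#' low-coverage signal that marks a misjoin.
#'
#' @param contigs Named [Biostrings::DNAStringSet].
#' @param truth A [FragmentationTruth-class] (for junction positions); pass
#'   a truth with no chimeras for a flat track.
#' @param meanDepth Mean depth away from junctions.
#' @param dipDepth Mean depth at junction windows; must be `< meanDepth`.
#' @param windowBp Window size in bp.
#' @param seed Integer seed.
#' @return A [CoverageTrack-class].
#' @export
simulateCoverage <- function(contigs, truth, meanDepth = 30, dipDepth = 2,
                             windowBp = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dipDepth >= meanDepth) stop("dipDepth must be below meanDepth")
  junctions <- chimeraJunctions(truth)
  depths <- lapply(seq_along(contigs), function(i) {
    L <- width(contigs)[i]
    n <- as.integer(ceiling(L / windowBp))
    d <- rpois(n, meanDepth)
    nm <- names(contigs)[i]
    if (nm %in% names(junctions)) {
      j <- junctions[[nm]]
      idx <- unique(pmax(1L, pmin(n, ceiling(c(j - windowBp, j, j + windowBp) / windowBp))))
      d[idx] <- rpois(length(idx), dipDepth)
    }
    d
  })
  names(depths) <- names(contigs)
  new("CoverageTrack", depths = depths, window = as.integer(windowBp))
}

## aggregate duplicate codes; returns list(codes, counts)
.aggregateCodes <- function(codes, counts) {
  o <- order(codes)
  s <- codes[o]; cnt <- counts[o]
  newGrp <- c(TRUE, s[-1L] != s[-length(s)])
  gid <- cumsum(newGrp)
  list(codes = s[newGrp], counts = as.numeric(rowsum(cnt, gid)))
}

#' Build the canonical k-mer multiset of a sequence set
#'
#' @param seqs A [TruthGenome-class], [Biostrings::DNAStringSet] or
#'   character vector of DNA sequences.
#' @param k Odd k-mer size in 11..25.
#' @return A [KmerSet-class] counting every k-mer position (canonical form).
#' @export
kmerSet <- function(seqs, k = 21L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 11L || k > 25L) stop("k must be in 11..25")
  codes <- .canonicalKmerCodes(unname(.asCharSeqs(seqs)), k)
  if (!length(codes))
    return(new("KmerSet", k = k, codes = numeric(0L), counts = numeric(0L)))
  agg <- .aggregateCodes(codes, rep(1, length(codes)))
  new("KmerSet", k = k, codes = agg$codes, counts = agg$counts)
}

#' Simulate an error-bearing read k-mer set
#'
#' Emulates the k-mer content of sequencing reads at a given depth and
#' per-base error rate without simulating reads themselves: each of the
#' `depth` sampled copies of every genomic k-mer is error-free with
#' probability `(1 - perBaseError)^k`; errored copies emit a k-mer with one
#' random substitution instead. Canonicalization follows [kmerSet()].
#'
#' @param seqs Source sequences (genome or assembly).
#' @param k Odd k-mer size in 11..25.
#' @param perBaseError Per-base substitution error rate of the reads.
#' @param depth Copies sampled per genomic k-mer position (read depth);
#'   `0` returns an empty set.
#' @param seed Integer seed.
#' @return A [KmerSet-class].
#' @export
simulateKmerReadset <- function(seqs, k = 21L, perBaseError = 0, depth = 1L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 11L || k > 25L) stop("k must be in 11..25")
  if (depth < 0L) stop("depth must be >= 0")
  if (depth == 0L)
    return(new("KmerSet", k = k, codes = numeric(0L), counts = numeric(0L)))
  codes <- .canonicalKmerCodes(unname(.asCharSeqs(seqs)), k)
  pOk <- (1 - perBaseError)^k
  okCopies <- rbinom(length(codes), depth, pOk)
  errCopies <- depth - okCopies
  allCodes <- codes[okCopies > 0L]
  allCounts <- as.numeric(okCopies[okCopies > 0L])
  totErr <- sum(errCopies)
  if (totErr > 0L) {
    src <- rep(codes[errCopies > 0L], errCopies[errCopies > 0L])
    strs <- .kmerCodeToString(src, k)
    pos <- sample.int(k, totErr, replace = TRUE)
    old <- substring(strs, pos, pos)
    shift <- sample.int(3L, totErr, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    newb <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
    substring(strs, pos, pos) <- newb
    mut <- .canonicalKmerCodes(strs, k)
    allCodes <- c(allCodes, mut)
    allCounts <- c(allCounts, rep(1, length(mut)))
  }
  if (!length(allCodes))
    return(new("KmerSet", k = k, codes = numeric(0L), counts = numeric(0L)))
  agg <- .aggregateCodes(allCodes, allCounts)
  new("KmerSet", k = k, codes = agg$codes, counts = agg$counts)
}

#' Introduce a fixed number of substitutions into sequences
#'
#' Places `round(rate * length)` single-base substitutions at uniformly
#' sampled positions of each sequence (a fixed count rather than a binomial
#' draw, so the realized error rate is essentially exact). Used to
#' manufacture assemblies of known per-base error for QV calibration.
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector.
#' @param rate Target per-base substitution rate.
#' @param seed Integer seed.
#' @return List with `seqs` (mutated [Biostrings::DNAStringSet]) and
#'   `nSubstitutions`.
#' @export
mutateSequences <- function(seqs, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- .asCharSeqs(seqs)
  bases <- c("A", "C", "G", "T")
  total <- 0L
  out <- vapply(chars, function(s) {
    L <- nchar(s)
    nmut <- as.integer(round(L * rate))
    if (nmut == 0L) return(s)
    pos <- sample.int(L, nmut)
    old <- substring(s, pos, pos)
    shift <- sample.int(3L, nmut, replace = TRUE)
    newb <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
    newb[is.na(newb)] <- "A"  # non-ACGT positions become A
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    v[pos] <- newb
    total <<- total + nmut
    paste(v, collapse = "")
  }, character(1L))
  list(seqs = DNAStringSet(out), nSubstitutions = total)
}
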