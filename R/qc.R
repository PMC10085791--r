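#' @include AllClasses.R
NULL

#' N50 of a set of sequence lengths
#'
#' The length L such that sequences of length >= L cover at least half the
#' total.
#'
#' @param lengths Numeric vector of sequence lengths.
#' @return The N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("no sequences")
  s <- sort(unname(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

## maximal runs of N in one sequence: data.frame(start, end)
.gapRuns <- function(seqChar) {
  m <- gregexpr("N+", seqChar)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(0L), end = integer(0L)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Assembly length and gap statistics
#'
#' Computes total lengths, N50 values and exact gap accounting for an
#' assembly. A gap is any maximal run of N (length >= 1). When an AGP
#' table is given, the contig-level N50 is taken over its `W` component
#' lengths plus the unplaced sequences; otherwise over all input
#' sequences.
#'
#' @param seqs Pseudomolecule (or whole-assembly)
#'   [Biostrings::DNAStringSet].
#' @param unplaced Optional [Biostrings::DNAStringSet] of unplaced contigs.
#' @param agp Optional AGP `data.frame` for contig-level statistics.
#' @return Named list of statistics (`totalLength`, `n50`, `nGaps`,
#'   `nNBases`, per-sequence `gapCounts`, ...).
#' @export
assemblyStats <- function(seqs, unplaced = NULL, agp = NULL) {
  if (!length(seqs)) stop("empty input")
  allSeqs <- c(as.character(seqs),
               if (!is.null(unplaced)) as.character(unplaced))
  widths <- nchar(allSeqs)
  gapList <- lapply(allSeqs, .gapRuns)
  gapCounts <- vapply(gapList, nrow, integer(1L))
  nN <- vapply(gapList, function(g) sum(g$end - g$start + 1L), integer(1L))
  contigLengths <- if (!is.null(agp)) {
    w <- agp[agp$component_type == "W", ]
    c(as.integer(w$component_end) - as.integer(w$component_beg) + 1L,
      if (!is.null(unplaced)) width(unplaced))
  } else widths
  list(totalLength = sum(widths),
       pseudomoleculeLength = sum(width(seqs)),
       unplacedLength = if (is.null(unplaced)) 0L else sum(width(unplaced)),
       nSequences = length(allSeqs),
       nPseudomolecules = length(seqs),
       nUnplaced = if (is.null(unplaced)) 0L else length(unplaced),
       n50 = n50(widths),
       contigN50 = n50(contigLengths),
       longestPseudomolecule = max(width(seqs)),
       shortestSequence = min(widths),
       nGaps = sum(gapCounts),
       nNBases = sum(nN),
       gapCounts = setNames(gapCounts[seq_along(seqs)], names(seqs)))
}

#' Detect a telomeric repeat array at a sequence end
#'
#' Scans the outermost `windowBp` of the requested end for a tandem run of
#' the telomere unit: `CCTAA` at the 5' end, its reverse complement
#' `TTAGG` at the 3' end (lepidopteran strand convention). A run qualifies
#' when it contains at least `minUnits` consecutive unit copies, allowing
#' up to 1 inexact unit (single mismatch) per 10 units.
#'
#' @param seq [Biostrings::DNAString] or character.
#' @param end `"5p"` or `"3p"`.
#' @param motif The plus-strand 5' unit (default `CCTAA`).
#' @param windowBp Terminal window scanned (default 1000).
#' @param minUnits Minimum tandem copies (default 10).
#' @return Logical.
#' @export
detectTelomere <- function(seq, end = c("5p", "3p"), motif = "CCTAA",
                           windowBp = 1000L, minUnits = 10L) {
  end <- match.arg(end)
  seq <- .asDNAString(seq)
  u <- nchar(motif)
  if (length(seq) < u) return(FALSE)
  if (end == "3p") motif <- as.character(reverseComplement(DNAString(motif)))
  win <- if (end == "5p") subseq(seq, 1L, min(length(seq), windowBp))
         else subseq(seq, max(1L, length(seq) - windowBp + 1L), length(seq))
  hits <- matchPattern(DNAString(motif), win, max.mismatch = 1L)
  if (!length(hits)) return(FALSE)
  starts <- sort(unique(start(hits)))
  exact <- start(matchPattern(DNAString(motif), win, max.mismatch = 0L))
  ## maximal arithmetic runs with step = unit length
  runBreaks <- c(TRUE, diff(starts) != u)
  runId <- cumsum(runBreaks)
  for (g in unique(runId)) {
    run <- starts[runId == g]
    if (length(run) < minUnits) next
    nExact <- sum(run %in% exact)
    if ((length(run) - nExact) <= length(run) / 10) return(TRUE)
  }
  FALSE
}

#' Classify pseudomolecules by telomere and gap status
#'
#' Counts pseudomolecules carrying telomeric arrays at both ends
#' (`pairOfTelomeres`), at exactly one end (`oneTelomere`), and both-ended
#' gap-free pseudomolecules (`t2tGapFree`, the telomere-to-telomere class).
#'
#' @param seqs Pseudomolecule [Biostrings::DNAStringSet].
#' @param motif,windowBp,minUnits Telomere-call parameters (see
#'   [detectTelomere()]).
#' @return List with `counts` (named numeric) and `perSequence`
#'   (`data.frame`: `object`, `tel5`, `tel3`, `gaps`).
#' @export
classifyPseudomolecules <- function(seqs, motif = "CCTAA", windowBp = 1000L,
                                    minUnits = 10L) {
  chars <- as.character(seqs)
  tel5 <- vapply(chars, detectTelomere, logical(1L), end = "5p",
                 motif = motif, windowBp = windowBp, minUnits = minUnits)
  tel3 <- vapply(chars, detectTelomere, logical(1L), end = "3p",
                 motif = motif, windowBp = windowBp, minUnits = minUnits)
  gaps <- vapply(lapply(chars, .gapRuns), nrow, integer(1L))
  perSeq <- data.frame(object = names(seqs), tel5 = unname(tel5),
                       tel3 = unname(tel3), gaps = unname(gaps),
                       stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(pairOfTelomeres = sum(perSeq$tel5 & perSeq$tel3),
              oneTelomere = sum(xor(perSeq$tel5, perSeq$tel3)),
              t2tGapFree = sum(perSeq$tel5 & perSeq$tel3 & perSeq$gaps == 0L))
  list(counts = counts, perSequence = perSeq)
}

#' k-mer-survey consensus quality value (QV)
#'
#' Estimates the assembly consensus QV from the fraction `a` of assembly
#' k-mers (counted with multiplicity) absent from the read k-mer set:
#' the per-base error is `E = 1 - (1 - a)^(1/k)` and `QV = -10 log10(E)`.
#' A perfect assembly (`a = 0`) reports the configured cap. An empty read
#' set is non-estimable (`NA` with a warning).
#'
#' @param assemblyKmers [KmerSet-class] of the assembly.
#' @param readKmers [KmerSet-class] of the reads (same k).
#' @param cap QV reported when no assembly k-mer is unsupported.
#' @return List with `qv`, `errorRate`, `missingFraction`, `nKmers`.
#' @export
kmerQV <- function(assemblyKmers, readKmers, cap = 99) {
  if (kmerSize(assemblyKmers) != kmerSize(readKmers))
    stop("assembly and read k-mer sets must share k")
  if (!length(kmerCodes(readKmers))) {
    warning("empty read k-mer set; QV is non-estimable")
    return(list(qv = NA_real_, errorRate = NA_real_,
                missingFraction = NA_real_, nKmers = 0))
  }
  k <- kmerSize(assemblyKmers)
  total <- sum(kmerCounts(assemblyKmers))
  absent <- !(kmerCodes(assemblyKmers) %in% kmerCodes(readKmers))
  a <- sum(kmerCounts(assemblyKmers)[absent]) / total
  if (a == 0)
    return(list(qv = cap, errorRate = 0, missingFraction = 0, nKmers = total))
  E <- 1 - (1 - a)^(1 / k)
  list(qv = -10 * log10(E), errorRate = E, missingFraction = a,
       nKmers = total)
}

#' Convert a QV to percent base accuracy, and QV to error rate
#'
#' `QV = -10 log10(E)`; accuracy is `100 (1 - E)` percent. QV 40 is 99.99%
#' accuracy.
#'
#' @param qv Quality value(s).
#' @return Percent accuracy (or error rate).
#' @export
qvToAccuracy <- function(qv) 100 * (1 - 10^(-qv / 10))

#' @rdname qvToAccuracy
#' @export
qvToErrorRate <- function(qv) 10^(-qv / 10)

#' Physical-vs-genetic marker consistency check
#'
#' Orders the markers of each chromosome by final physical position, fixes
#' the chromosome-wide direction by the majority sign of the cM steps, and
#' reports every adjacent marker pair whose genetic order contradicts the
#' physical order (ties in cM are not violations). Markers that cannot be
#' located are reported separately.
#'
#' @param positions `data.frame` with columns `marker`, `chrom`, `bp`,
#'   `cM`; rows with `NA` bp are treated as unlocatable.
#' @return List with `violations` (`data.frame`: `chrom`, `marker1`,
#'   `marker2`), `nViolations` and `unlocatable` (character).
#' @export
mapConsistencyCheck <- function(positions) {
  unloc <- positions$marker[is.na(positions$bp)]
  positions <- positions[!is.na(positions$bp), ]
  out <- list()
  for (ch in unique(positions$chrom)) {
    sub <- positions[positions$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    d <- diff(sub$cM)
    dir <- sign(sum(sign(d)))
    if (dir == 0) dir <- 1
    bad <- which(sign(d) == -dir & d != 0)
    for (b in bad)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, marker1 = sub$marker[b], marker2 = sub$marker[b + 1L],
        stringsAsFactors = FALSE)
  }
  violations <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0L), marker1 = character(0L),
               marker2 = character(0L))
  list(violations = violations, nViolations = nrow(violations),
       unlocatable = unloc)
}

#' Plot physical versus genetic marker positions
#'
#' One panel per chromosome, physical bp on the x axis, cM on the y axis —
#' the standard visual check that a map and an assembly agree.
#'
#' @param positions As in [mapConsistencyCheck()].
#' @param file Optional PNG path; when `NULL`, plots to the active device.
#' @return Invisibly, the input.
#' @export
plotMapConsistency <- function(positions, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  chroms <- unique(positions$chrom)
  nc <- ceiling(sqrt(length(chroms)))
  nr <- ceiling(length(chroms) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (ch in chroms) {
    sub <- positions[positions$chrom == ch, ]
    graphics::plot(sub$bp / 1e6, sub$cM, pch = 19, cex = 0.6,
                   xlab = "physical position (Mb)", ylab = "genetic position (cM)",
                   main = ch)
  }
  invisible(positions)
}

#' Assemble a full QC report
#'
#' Combines [assemblyStats()], [classifyPseudomolecules()] and (when read
#' k-mers are given) [kmerQV()] into a [QCReport-class] mirroring the usual
#' assembly summary table.
#'
#' @param seqs Pseudomolecule [Biostrings::DNAStringSet].
#' @param unplaced Optional unplaced contigs.
#' @param agp Optional AGP table for contig-level N50.
#' @param readKmers Optional [KmerSet-class] of read k-mers for QV.
#' @param k k-mer size used for the QV (default 21).
#' @param motif,telomereWindowBp,telomereMinUnits Telomere-call parameters.
#' @param qvCap QV cap for a fully supported assembly.
#' @return A [QCReport-class].
#' @export
qcReport <- function(seqs, unplaced = NULL, agp = NULL, readKmers = NULL,
                     k = 21L, motif = "CCTAA", telomereWindowBp = 1000L,
                     telomereMinUnits = 10L, qvCap = 99) {
  st <- assemblyStats(seqs, unplaced = unplaced, agp = agp)
  cls <- classifyPseudomolecules(seqs, motif = motif,
                                 windowBp = telomereWindowBp,
                                 minUnits = telomereMinUnits)
  qv <- NA_real_
  if (!is.null(readKmers)) {
    ak <- kmerSet(c(as.character(seqs),
                    if (!is.null(unplaced)) as.character(unplaced)),
                  k = kmerSize(readKmers))
    qv <- kmerQV(ak, readKmers, cap = qvCap)$qv
  }
  new("QCReport",
      lengths = c(totalLength = st$totalLength,
                  pseudomoleculeLength = st$pseudomoleculeLength,
                  unplacedLength = st$unplacedLength,
                  n50 = st$n50, contigN50 = st$contigN50,
                  longestPseudomolecule = st$longestPseudomolecule,
                  shortestSequence = st$shortestSequence),
      counts = c(nPseudomolecules = st$nPseudomolecules,
                 nUnplaced = st$nUnplaced,
                 nGaps = st$nGaps, nNBases = st$nNBases),
      telomeres = cls$perSequence,
      classes = cls$counts,
      qv = qv)
}
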