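#' @include AllClasses.R
NULL

#' Anchor contigs to chromosomes by marker genetic positions
#'
#' Gives every markered contig a chromosome (its markers' linkage group), a
#' genetic position (the median cM of its markers) and an orientation (the
#' sign of the Spearman rank correlation between marker physical position
#' and cM; `unknown` and emitted as `+` with a flag when the contig has
#' fewer than two distinct cM values or a zero correlation). Contigs are
#' ranked within each chromosome by median cM; ties break by guide position
#' when a guide table is supplied, then by contig name (stable).
#'
#' A contig still carrying supported markers from two or more linkage
#' groups is an error: it must be split first (see [detectChimeras()]).
#' Stray markers below `minSupport` are outvoted by the majority group.
#'
#' @param map A [GeneticMap-class].
#' @param assign Marker assignments ([markerAssignments()] output or the
#'   remapped table after splitting).
#' @param guide Optional guide table (`contig`, `chrom`, `position`,
#'   `strand`).
#' @param minSupport Marker support defining a genuine group conflict.
#' @return `data.frame` with one row per anchored contig: `contig`,
#'   `chrom`, `medianCM`, `orientation`, `orientationKnown`, `nMarkers`,
#'   `rank`.
#' @export
anchorContigs <- function(map, assign, guide = NULL, minSupport = 2L) {
  tb <- mapTable(map)
  assign <- assign[assign$marker %in% tb$marker, , drop = FALSE]
  if (!"group" %in% colnames(assign) || !"cM" %in% colnames(assign)) {
    idx <- match(assign$marker, tb$marker)
    assign$group <- tb$group[idx]; assign$cM <- tb$cM[idx]
  }
  rows <- list()
  for (ct in unique(assign$contig)) {
    sub <- assign[assign$contig == ct, ]
    support <- table(sub$group)
    major <- names(support)[support >= minSupport]
    if (length(major) > 1L)
      stop("contig ", ct, " carries supported markers from groups ",
           paste(major, collapse = ", "), "; split it before anchoring")
    grp <- if (length(major) == 1L) major
           else names(support)[which.max(support)]
    sub <- sub[sub$group == grp, ]
    known <- length(unique(sub$cM)) >= 2L
    ori <- "+"
    if (known) {
      s <- suppressWarnings(cor(sub$position, sub$cM, method = "spearman"))
      if (is.na(s) || s == 0) known <- FALSE else ori <- ifelse(s > 0, "+", "-")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contig = ct, chrom = grp, medianCM = median(sub$cM),
      orientation = ori, orientationKnown = known, nMarkers = nrow(sub),
      stringsAsFactors = FALSE)
  }
  anchors <- do.call(rbind, rows)
  tie <- if (!is.null(guide)) {
    gp <- guide$position[match(anchors$contig, guide$contig)]
    ifelse(is.na(gp), Inf, gp)
  } else rep(0, nrow(anchors))
  anchors <- anchors[order(anchors$chrom, anchors$medianCM, tie, anchors$contig), ]
  anchors$rank <- stats::ave(seq_len(nrow(anchors)), anchors$chrom,
                             FUN = seq_along)
  rownames(anchors) <- NULL
  anchors
}

.asDNAString <- function(x) {
  if (is(x, "DNAString")) x else DNAString(as.character(x))
}

#' Detect a terminal overlap between two oriented neighbours
#'
#' Finds the longest end-anchored alignment between the 3' terminal window
#' of `a` and the 5' terminal window of `b` (both already in object
#' orientation): the terminal `seedLen`-mer of `a` is matched (allowing
#' `seedMaxMismatch` mismatches) inside `b`'s prefix window, and each hit
#' implies a candidate overlap length that is verified base-by-base.
#' Candidates are scanned longest-first and the first whose mismatch
#' fraction is below `maxMismatchFrac` wins; the overlap is accepted for
#' joining iff its length is at least `minJoinBp`. Gapped alignment is not
#' attempted: at the sub-percent divergence this join rule tolerates, an
#' indel simply truncates the usable overlap.
#'
#' @param a,b Upstream / downstream sequence ([Biostrings::DNAString] or
#'   character), `a` preceding `b` in the plan.
#' @param maxWindow Terminal window searched on each side, in bp; clamped
#'   (with a warning) when a sequence is shorter.
#' @param minJoinBp Minimum overlap length for an accepted join.
#' @param maxMismatchFrac Maximum mismatch fraction of the overlap.
#' @param seedLen,seedMaxMismatch Exact-ish seed parameters.
#' @return List: `overlapLen`, `mismatches`, `mismatchFrac`, `accepted`.
#' @export
detectTerminalOverlap <- function(a, b, maxWindow = 50000L, minJoinBp = 3000L,
                                  maxMismatchFrac = 0.01, seedLen = 31L,
                                  seedMaxMismatch = 1L) {
  a <- .asDNAString(a); b <- .asDNAString(b)
  la <- length(a); lb <- length(b)
  none <- list(overlapLen = 0L, mismatches = NA_integer_,
               mismatchFrac = NA_real_, accepted = FALSE)
  if (la < seedLen || lb < seedLen) return(none)
  if (maxWindow > la || maxWindow > lb)
    warning("terminal window exceeds a contig length; clamped")
  wb <- min(lb, maxWindow)
  seed <- subseq(a, la - seedLen + 1L, la)
  hits <- matchPattern(seed, subseq(b, 1L, wb),
                       max.mismatch = seedMaxMismatch, with.indels = FALSE)
  cand <- sort(unique(end(hits)), decreasing = TRUE)
  cand <- cand[cand <= la & cand >= seedLen]
  if (!length(cand)) return(none)
  bestFail <- NULL
  for (L in cand) {
    allowed <- ceiling(maxMismatchFrac * L)
    mm <- .suffixPrefixMismatches(as.character(subseq(a, la - L + 1L, la)),
                                  as.character(subseq(b, 1L, L)),
                                  L, allowed)
    if (mm / L < maxMismatchFrac)
      return(list(overlapLen = as.integer(L), mismatches = as.integer(mm),
                  mismatchFrac = mm / L, accepted = L >= minJoinBp))
    if (is.null(bestFail))
      bestFail <- list(overlapLen = as.integer(L), mismatches = as.integer(mm),
                       mismatchFrac = mm / L, accepted = FALSE)
  }
  bestFail
}

#' Merge two neighbours over an accepted terminal overlap
#'
#' The overlap bases are taken from the upstream sequence; the merged
#' length is `length(a) + length(b) - overlap`.
#'
#' @param a,b Oriented upstream / downstream sequences.
#' @param join An accepted overlap from [detectTerminalOverlap()].
#' @return The merged [Biostrings::DNAString].
#' @export
mergeOverlapping <- function(a, b, join) {
  if (!isTRUE(join$accepted)) stop("join was not accepted")
  a <- .asDNAString(a); b <- .asDNAString(b)
  if (join$overlapLen >= length(b)) return(a)  # b fully contained
  xscat(a, subseq(b, join$overlapLen + 1L, length(b)))
}

## oriented (object-strand) sequence of a contig
.orientedSeq <- function(contigs, ct, orientation) {
  s <- contigs[[ct]]
  if (orientation == "-") s <- reverseComplement(s)
  s
}

## object-side 5' trim of `ov` bases expressed in contig-own coordinates
.trimmedRange <- function(len, orientation, ov) {
  if (orientation == "-") c(1L, len - ov) else c(ov + 1L, len)
}

#' Build a scaffold plan from anchored contigs
#'
#' Walks the anchored order within every chromosome, detects terminal
#' overlaps between oriented neighbours, and records either a merge
#' (adjacent components with no gap; the downstream component range is
#' trimmed by the overlap, keeping the overlap bases from the upstream
#' contig) or a linkage-inferred gap of `gapLen` N. Contigs absent from
#' the anchor table are listed unplaced.
#'
#' @param contigs Named [Biostrings::DNAStringSet] of all contigs.
#' @param anchors Anchor table from [anchorContigs()].
#' @param minJoinBp,maxMismatchFrac,maxWindow Overlap-join parameters (see
#'   [detectTerminalOverlap()]).
#' @param gapLen Gap length convention in bp (default 100).
#' @return List with `plan` (a [ScaffoldPlan-class]) and `joins` (a log
#'   `data.frame` of every adjacency tested).
#' @export
buildScaffoldPlan <- function(contigs, anchors, minJoinBp = 3000L,
                              maxMismatchFrac = 0.01, maxWindow = 50000L,
                              gapLen = 100L) {
  comp <- list(); joins <- list()
  for (chrom in unique(anchors$chrom)) {
    sub <- anchors[anchors$chrom == chrom, ]
    sub <- sub[order(sub$rank), ]
    part <- 1L
    len1 <- width(contigs)[match(sub$contig[1L], names(contigs))]
    comp[[length(comp) + 1L]] <- data.frame(
      object = chrom, part = part, type = "W", contig = sub$contig[1L],
      componentBeg = 1L, componentEnd = len1,
      orientation = sub$orientation[1L], stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sub) - 1L)) {
      up <- sub$contig[i]; down <- sub$contig[i + 1L]
      join <- detectTerminalOverlap(
        .orientedSeq(contigs, up, sub$orientation[i]),
        .orientedSeq(contigs, down, sub$orientation[i + 1L]),
        maxWindow = maxWindow, minJoinBp = minJoinBp,
        maxMismatchFrac = maxMismatchFrac)
      joins[[length(joins) + 1L]] <- data.frame(
        object = chrom, upstream = up, downstream = down,
        overlapLen = join$overlapLen, mismatches = join$mismatches,
        accepted = join$accepted, stringsAsFactors = FALSE)
      lenD <- width(contigs)[match(down, names(contigs))]
      if (join$accepted && join$overlapLen < lenD) {
        rng <- .trimmedRange(lenD, sub$orientation[i + 1L], join$overlapLen)
      } else if (join$accepted) {
        next  # fully contained in the upstream overlap; contributes nothing
      } else {
        part <- part + 1L
        comp[[length(comp) + 1L]] <- data.frame(
          object = chrom, part = part, type = "U", contig = NA_character_,
          componentBeg = NA_integer_, componentEnd = NA_integer_,
          orientation = NA_character_, stringsAsFactors = FALSE)
        rng <- c(1L, lenD)
      }
      part <- part + 1L
      comp[[length(comp) + 1L]] <- data.frame(
        object = chrom, part = part, type = "W", contig = down,
        componentBeg = rng[1L], componentEnd = rng[2L],
        orientation = sub$orientation[i + 1L], stringsAsFactors = FALSE)
    }
  }
  components <- do.call(rbind, comp)
  rownames(components) <- NULL
  plan <- new("ScaffoldPlan", components = components,
              unplaced = setdiff(names(contigs), anchors$contig),
              gapLen = as.integer(gapLen))
  joins <- if (length(joins)) do.call(rbind, joins) else
    data.frame(object = character(0L), upstream = character(0L),
               downstream = character(0L), overlapLen = integer(0L),
               mismatches = integer(0L), accepted = logical(0L))
  list(plan = plan, joins = joins)
}

## object coordinates of every component row of a plan
.planCoordinates <- function(plan) {
  cp <- planComponents(plan)
  cp$length <- ifelse(cp$type == "U", plan@gapLen,
                      cp$componentEnd - cp$componentBeg + 1L)
  cp$objectEnd <- stats::ave(cp$length, cp$object, FUN = cumsum)
  cp$objectBeg <- cp$objectEnd - cp$length + 1L
  cp
}

## renumber parts 1..n within each object, preserving row order
.renumberParts <- function(components) {
  components$part <- stats::ave(seq_len(nrow(components)), components$object,
                                FUN = seq_along)
  components
}

#' Place a markerless contig into a draft plan using a guide alignment
#'
#' Attempts to insert contigs that carry no genetic markers at gap
#' boundaries (or chromosome ends) of the scaffold plan, applying three
#' criteria: (1) the insertion point must be consistent with the guide
#' alignment (same chromosome, within `posTol` bp of the guide position);
#' (2) the contig must share a terminal overlap longer than `minOverlapBp`
#' with the flanking sequence; (3) the overlap's mismatch fraction must be
#' below `maxMismatchFrac`. A contig failing any criterion stays unplaced
#' with the failed criterion recorded. When placed, each flank is joined by
#' overlap merge where one qualifies under the ordinary join rule
#' (`minJoinBp`), otherwise across a gap record.
#'
#' @param plan A [ScaffoldPlan-class].
#' @param contigs Named [Biostrings::DNAStringSet] including the unplaced
#'   contigs.
#' @param guide Guide table: `contig`, `chrom`, `position`, `strand`.
#' @param minOverlapBp Insertion overlap threshold (strict `>`; default
#'   3500).
#' @param maxMismatchFrac Maximum mismatch fraction (default 0.01).
#' @param posTol Guide-consistency tolerance in bp.
#' @param minJoinBp Ordinary neighbour-join threshold used for the flank
#'   joins of a placed contig.
#' @param maxWindow Terminal window for overlap search.
#' @return List with `plan` (updated) and `log` (one row per attempted
#'   contig: `contig`, `placed`, `object`, `failedCriterion`).
#' @export
placeMarkerless <- function(plan, contigs, guide, minOverlapBp = 3500L,
                            maxMismatchFrac = 0.01, posTol = 100000L,
                            minJoinBp = 3000L, maxWindow = 50000L) {
  log <- list()
  addLog <- function(ct, placed, object, failed)
    log[[length(log) + 1L]] <<- data.frame(
      contig = ct, placed = placed, object = object,
      failedCriterion = failed, stringsAsFactors = FALSE)
  for (ct in intersect(unplacedContigs(plan), guide$contig)) {
    g <- guide[guide$contig == ct, ][1L, ]
    cp <- .planCoordinates(plan)
    if (!g$chrom %in% cp$object) {
      addLog(ct, FALSE, NA_character_, "guide_consistency")
      next
    }
    sub <- cp[cp$object == g$chrom, ]
    ## candidate insertion points: before part 1, at every gap, after last part
    gapRows <- which(sub$type == "U")
    candAfter <- c(0L, gapRows, nrow(sub))  # insert after this row index
    candPos <- c(0, sub$objectEnd[gapRows], sub$objectEnd[nrow(sub)])
    keepOne <- !duplicated(candAfter)
    candAfter <- candAfter[keepOne]; candPos <- candPos[keepOne]
    best <- which.min(abs(candPos - g$position))
    if (abs(candPos[best] - g$position) > posTol) {
      addLog(ct, FALSE, g$chrom, "guide_consistency")
      next
    }
    after <- candAfter[best]
    upRow <- if (after >= 1L && sub$type[after] == "U") after - 1L else after
    downRow <- after + 1L
    if (downRow <= nrow(sub) && sub$type[downRow] == "U") downRow <- downRow + 1L
    cSeq <- .orientedSeq(contigs, ct, g$strand)
    ovUp <- if (upRow >= 1L)
      detectTerminalOverlap(.orientedSeq(contigs, sub$contig[upRow],
                                         sub$orientation[upRow]),
                            cSeq, maxWindow = maxWindow, minJoinBp = minJoinBp,
                            maxMismatchFrac = maxMismatchFrac) else NULL
    ovDown <- if (downRow <= nrow(sub))
      detectTerminalOverlap(cSeq,
                            .orientedSeq(contigs, sub$contig[downRow],
                                         sub$orientation[downRow]),
                            maxWindow = maxWindow, minJoinBp = minJoinBp,
                            maxMismatchFrac = maxMismatchFrac) else NULL
    okLen <- function(ov) !is.null(ov) && ov$overlapLen > minOverlapBp
    okMm <- function(ov) !is.null(ov) && !is.na(ov$mismatchFrac) &&
      ov$mismatchFrac < maxMismatchFrac
    qualifies <- (okLen(ovUp) && okMm(ovUp)) || (okLen(ovDown) && okMm(ovDown))
    if (!qualifies) {
      failed <- if (okLen(ovUp) || okLen(ovDown)) "mismatch_fraction"
                else "overlap_length"
      addLog(ct, FALSE, g$chrom, failed)
      next
    }
    ## build the replacement rows for the insertion point
    len <- width(contigs)[match(ct, names(contigs))]
    mergeUp <- !is.null(ovUp) && ovUp$accepted && ovUp$overlapLen < len
    mergeDown <- !is.null(ovDown) && ovDown$accepted
    beg <- 1L; end <- len
    if (mergeUp) {
      rng <- .trimmedRange(len, g$strand, ovUp$overlapLen)
      beg <- rng[1L]; end <- rng[2L]
    }
    newRows <- list()
    if (upRow >= 1L && !mergeUp)
      newRows[[length(newRows) + 1L]] <- data.frame(
        object = g$chrom, part = 0L, type = "U", contig = NA_character_,
        componentBeg = NA_integer_, componentEnd = NA_integer_,
        orientation = NA_character_, stringsAsFactors = FALSE)
    newRows[[length(newRows) + 1L]] <- data.frame(
      object = g$chrom, part = 0L, type = "W", contig = ct,
      componentBeg = beg, componentEnd = end, orientation = g$strand,
      stringsAsFactors = FALSE)
    if (downRow <= nrow(sub) && !mergeDown)
      newRows[[length(newRows) + 1L]] <- data.frame(
        object = g$chrom, part = 0L, type = "U", contig = NA_character_,
        componentBeg = NA_integer_, componentEnd = NA_integer_,
        orientation = NA_character_, stringsAsFactors = FALSE)
    ## downstream flank: additional object-side trim when merged
    components <- planComponents(plan)
    rowIds <- which(components$object == g$chrom)
    if (mergeDown && downRow <= nrow(sub)) {
      dr <- rowIds[downRow]
      if (components$orientation[dr] == "-")
        components$componentEnd[dr] <- components$componentEnd[dr] - ovDown$overlapLen
      else components$componentBeg[dr] <- components$componentBeg[dr] + ovDown$overlapLen
      if (components$componentBeg[dr] > components$componentEnd[dr])
        stop("markerless insertion would swallow its downstream neighbour")
    }
    before <- if (upRow >= 1L) rowIds[seq_len(upRow)] else integer(0L)
    afterIds <- if (downRow <= nrow(sub)) rowIds[downRow:nrow(sub)] else integer(0L)
    ## reassemble in object order: untouched objects keep their rows
    pieces <- list()
    for (obj in unique(components$object)) {
      if (obj != g$chrom) {
        pieces[[length(pieces) + 1L]] <- components[components$object == obj, ]
      } else {
        pieces[[length(pieces) + 1L]] <- components[before, , drop = FALSE]
        for (nr in newRows) pieces[[length(pieces) + 1L]] <- nr
        pieces[[length(pieces) + 1L]] <- components[afterIds, , drop = FALSE]
      }
    }
    components <- .renumberParts(do.call(rbind, pieces))
    rownames(components) <- NULL
    plan <- new("ScaffoldPlan", components = components,
                unplaced = setdiff(unplacedContigs(plan), ct),
                gapLen = plan@gapLen)
    addLog(ct, TRUE, g$chrom, NA_character_)
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(contig = character(0L), placed = logical(0L),
               object = character(0L), failedCriterion = character(0L))
  rownames(log) <- NULL
  list(plan = plan, log = log)
}

#' Emit pseudomolecule sequences and an AGP table from a plan
#'
#' Concatenates the oriented, trimmed components of every object, writing
#' exactly `gapLen` N for each gap record. The returned AGP (2.1
#' semantics, 1-based inclusive object coordinates) reconstructs the FASTA
#' byte-identically via [agpToFasta()].
#'
#' @param plan A [ScaffoldPlan-class].
#' @param contigs Named [Biostrings::DNAStringSet].
#' @return List with `seqs` (pseudomolecule [Biostrings::DNAStringSet]),
#'   `agp` (`data.frame` in AGP 2.1 column layout) and `unplaced`
#'   ([Biostrings::DNAStringSet]).
#' @export
buildPseudomolecules <- function(plan, contigs) {
  cp <- .planCoordinates(plan)
  missing <- setdiff(cp$contig[cp$type == "W"], names(contigs))
  if (length(missing))
    stop("plan references missing contig(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  gapRun <- strrep("N", plan@gapLen)
  seqs <- vapply(unique(cp$object), function(obj) {
    sub <- cp[cp$object == obj, ]
    parts <- vapply(seq_len(nrow(sub)), function(i) {
      if (sub$type[i] == "U") return(gapRun)
      s <- subseq(contigs[[sub$contig[i]]], sub$componentBeg[i],
                  sub$componentEnd[i])
      if (sub$orientation[i] == "-") s <- reverseComplement(s)
      as.character(s)
    }, character(1L))
    paste(parts, collapse = "")
  }, character(1L))
  agp <- data.frame(
    object = cp$object, object_beg = cp$objectBeg, object_end = cp$objectEnd,
    part_number = cp$part,
    component_type = cp$type,
    component_id = ifelse(cp$type == "W", cp$contig, plan@gapLen),
    component_beg = ifelse(cp$type == "W", cp$componentBeg, "scaffold"),
    component_end = ifelse(cp$type == "W", cp$componentEnd, "yes"),
    orientation = ifelse(cp$type == "W", cp$orientation, "map"),
    stringsAsFactors = FALSE)
  list(seqs = DNAStringSet(seqs),
       agp = agp,
       unplaced = contigs[unplacedContigs(plan)])
}

#' Reconstruct pseudomolecule FASTA from an AGP table
#'
#' @param agp AGP `data.frame` as produced by [buildPseudomolecules()] or
#'   read by [readAGP()].
#' @param contigs Named [Biostrings::DNAStringSet] of components.
#' @return [Biostrings::DNAStringSet] of reconstructed objects.
#' @export
agpToFasta <- function(agp, contigs) {
  seqs <- vapply(unique(agp$object), function(obj) {
    sub <- agp[agp$object == obj, ]
    sub <- sub[order(sub$part_number), ]
    parts <- vapply(seq_len(nrow(sub)), function(i) {
      if (sub$component_type[i] %in% c("U", "N"))
        return(strrep("N", as.integer(sub$component_id[i])))
      s <- subseq(contigs[[sub$component_id[i]]],
                  as.integer(sub$component_beg[i]),
                  as.integer(sub$component_end[i]))
      if (sub$orientation[i] == "-") s <- reverseComplement(s)
      as.character(s)
    }, character(1L))
    paste(parts, collapse = "")
  }, character(1L))
  DNAStringSet(seqs)
}

#' Rename the objects of a scaffold plan
#'
#' @param plan A [ScaffoldPlan-class].
#' @param mapping Named character vector, old name -> new name.
#' @return The renamed [ScaffoldPlan-class].
#' @export
renameScaffoldObjects <- function(plan, mapping) {
  components <- planComponents(plan)
  hit <- components$object %in% names(mapping)
  components$object[hit] <- mapping[components$object[hit]]
  new("ScaffoldPlan", components = components,
      unplaced = unplacedContigs(plan), gapLen = plan@gapLen)
}
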