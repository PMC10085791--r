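#' @include AllClasses.R
NULL

#' Detect chimeric contigs from linkage-group inconsistency
#'
#' A contig is called chimeric iff it carries at least `minSupport` markers
#' from each of two or more linkage groups: markers from different groups
#' on one contig mean the contig joins sequence from different
#' chromosomes. Groups below `minSupport` within a contig are ignored (a
#' single stray marker is more plausibly a genotyping error than a
#' misjoin). One call is emitted per boundary between consecutive group
#' blocks, with the search interval spanning from the innermost marker of
#' the left group to the innermost marker of the right group.
#'
#' @param assign Marker assignment table from [markerAssignments()] (or a
#'   `data.frame` with columns `marker`, `contig`, `position`, `group`).
#' @param minSupport Minimum markers per conflicting group (default 2).
#' @param contigs Optional [Biostrings::DNAStringSet]; when given, a marker
#'   referencing an unknown contig is an error.
#' @return `data.frame` of chimera calls: `contig`, `intervalStart`,
#'   `intervalEnd`, `leftGroup`, `rightGroup`, `nLeft`, `nRight`.
#' @export
detectChimeras <- function(assign, minSupport = 2L, contigs = NULL) {
  if (!is.null(contigs)) {
    unknown <- setdiff(assign$contig, names(contigs))
    if (length(unknown))
      stop("marker(s) reference unknown contig(s): ",
           paste(utils::head(unknown, 3L), collapse = ", "))
  }
  calls <- list()
  for (ct in unique(assign$contig)) {
    sub <- assign[assign$contig == ct, ]
    support <- table(sub$group)
    groups <- names(support)[support >= minSupport]
    if (length(groups) < 2L) next
    sub <- sub[sub$group %in% groups, ]
    med <- vapply(groups, function(g)
      median(sub$position[sub$group == g]), numeric(1L))
    groups <- groups[order(med)]
    for (b in seq_len(length(groups) - 1L)) {
      left <- groups[b]; right <- groups[b + 1L]
      s <- max(sub$position[sub$group == left])
      e <- min(sub$position[sub$group == right])
      calls[[length(calls) + 1L]] <- data.frame(
        contig = ct, intervalStart = min(s, e), intervalEnd = max(s, e),
        leftGroup = left, rightGroup = right,
        nLeft = sum(sub$group == left), nRight = sum(sub$group == right),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(contig = character(0L), intervalStart = integer(0L),
                      intervalEnd = integer(0L), leftGroup = character(0L),
                      rightGroup = character(0L), nLeft = integer(0L),
                      nRight = integer(0L), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Locate a chimera breakpoint at the coverage minimum
#'
#' Returns the centre of the minimum-depth window inside the call's search
#' interval (ties broken leftmost). Without coverage for the contig the
#' interval midpoint is returned, flagged low-confidence.
#'
#' @param call One row of the [detectChimeras()] table.
#' @param coverage A [CoverageTrack-class].
#' @return List with `breakpoint` (bp), `evidence` (minimum depth or `NA`)
#'   and `lowConfidence`.
#' @export
locateBreakpoint <- function(call, coverage) {
  ct <- call$contig
  depths <- coverageDepths(coverage)
  if (!ct %in% names(depths))
    return(list(breakpoint = as.integer(floor((call$intervalStart +
                                               call$intervalEnd) / 2)),
                evidence = NA_real_, lowConfidence = TRUE))
  d <- depths[[ct]]
  w <- coverageWindow(coverage)
  wStart <- max(1L, ceiling(call$intervalStart / w))
  wEnd <- min(length(d), ceiling(call$intervalEnd / w))
  idx <- wStart:wEnd
  best <- idx[which.min(d[idx])]  # which.min is leftmost on ties
  list(breakpoint = as.integer((best - 1L) * w + ceiling(w / 2)),
       evidence = d[best], lowConfidence = FALSE)
}

#' Split a contig at a breakpoint
#'
#' Replaces the contig by `<id>.1` (bases 1..bp) and `<id>.2` (bases
#' bp+1..end); the two pieces concatenate to the original sequence. Marker
#' assignments, when given, are remapped: positions at or left of the
#' breakpoint stay on `<id>.1`, the rest move to `<id>.2` with positions
#' shifted by the breakpoint.
#'
#' @param contigs Named [Biostrings::DNAStringSet].
#' @param id Contig to split.
#' @param bp Breakpoint, `0 < bp < length`; the base at `bp` is the last
#'   base of the first piece.
#' @param assign Optional marker assignment table to remap.
#' @return List with `contigs` (updated set) and `assign` (remapped table
#'   or `NULL`).
#' @export
splitContig <- function(contigs, id, bp, assign = NULL) {
  if (!id %in% names(contigs)) stop("unknown contig: ", id)
  L <- width(contigs)[names(contigs) == id]
  if (bp <= 0L || bp >= L) stop("breakpoint out of range (0 < bp < length)")
  s <- contigs[[id]]
  pieces <- DNAStringSet(list(subseq(s, 1L, bp), subseq(s, bp + 1L, L)))
  names(pieces) <- paste0(id, c(".1", ".2"))
  pos <- match(id, names(contigs))
  contigs <- c(contigs[seq_len(pos - 1L)], pieces,
               contigs[seq_len(length(contigs) - pos) + pos])
  if (!is.null(assign)) {
    hit <- assign$contig == id
    right <- hit & assign$position > bp
    assign$contig[hit & !right] <- paste0(id, ".1")
    assign$contig[right] <- paste0(id, ".2")
    assign$position[right] <- assign$position[right] - bp
  }
  list(contigs = contigs, assign = assign)
}

#' Flag artifactual contigs by modal read depth
#'
#' Flags contigs whose modal windowed depth falls below `low` (collapsed or
#' junk sequence) or above `high` (collapsed repeats), after the cutoffs of
#' coverage-histogram artifact screening. The modal depth is used rather
#' than the mean for robustness to repeat-induced spikes. Flags are
#' reported; removal is an explicit separate step.
#'
#' @param coverage A [CoverageTrack-class].
#' @param low,high Depth cutoffs (defaults 5 and 250).
#' @return `data.frame` with columns `contig`, `modalDepth`, `flag`
#'   (`keep`/`low_cov`/`high_cov`).
#' @export
flagArtifactContigs <- function(coverage, low = 5, high = 250) {
  depths <- coverageDepths(coverage)
  modal <- vapply(depths, function(d) {
    t <- tabulate(as.integer(round(d)) + 1L)
    which.max(t) - 1L  # leftmost mode
  }, numeric(1L))
  flag <- ifelse(modal < low, "low_cov", ifelse(modal > high, "high_cov", "keep"))
  data.frame(contig = names(depths), modalDepth = modal, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}
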