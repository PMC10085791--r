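#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one list, so a run
#' report can serialize them and any output is reproducible from config +
#' inputs. Defaults follow the linkage-map scaffolding protocol: 20%
#' missingness limit, LOD 3 grouping, 3 kb neighbour-join overlap, 3.5 kb
#' markerless-insertion overlap, 1% mismatch budget, 100-N gaps, depth
#' cutoffs 5/250 for artifact flagging, k = 21 for the QV.
#'
#' @param maxMissing Missingness limit for F2 individuals and markers.
#' @param lodThreshold Grouping LOD threshold.
#' @param mappingFunction `"kosambi"` or `"haldane"`.
#' @param dropDistorted,distortedAlpha Segregation-distortion filter.
#' @param minSupport Markers per group needed to call a chimera conflict.
#' @param minJoinBp Neighbour-join overlap threshold (accepted at `>=`).
#' @param minInsertOverlapBp Markerless-insertion overlap threshold
#'   (strict `>`).
#' @param maxMismatchFrac Mismatch budget of an overlap (indels count).
#' @param gapLen Gap length convention in bp.
#' @param covLow,covHigh Modal-depth cutoffs for artifact flagging.
#' @param telomereMotif,telomereWindowBp,telomereMinUnits Telomere call.
#' @param k,qvCap k-mer QV parameters.
#' @param maxWindow Terminal window for overlap search.
#' @param posTol Guide-consistency tolerance for markerless placement.
#' @param renameChromosomes Rename objects `chr01..` by descending length
#'   (the Z linkage group becomes `chrZ`).
#' @return Named list of settings.
#' @export
pipelineConfig <- function(maxMissing = 0.20, lodThreshold = 3,
                           mappingFunction = "kosambi",
                           dropDistorted = FALSE, distortedAlpha = 0.01,
                           minSupport = 2L, minJoinBp = 3000L,
                           minInsertOverlapBp = 3500L, maxMismatchFrac = 0.01,
                           gapLen = 100L, covLow = 5, covHigh = 250,
                           telomereMotif = "CCTAA", telomereWindowBp = 1000L,
                           telomereMinUnits = 10L, k = 21L, qvCap = 99,
                           maxWindow = 50000L, posTol = 100000L,
                           renameChromosomes = TRUE) {
  as.list(environment())
}

#' Final object coordinates of mapped markers
#'
#' Projects marker positions from contig coordinates to pseudomolecule
#' coordinates through a scaffold plan. Markers on unplaced contigs get
#' `NA`. Positions inside a trimmed overlap project into the upstream
#' merged copy of the identical sequence.
#'
#' @param plan A [ScaffoldPlan-class].
#' @param assign Marker assignment table (`marker`, `contig`, `position`).
#' @return `data.frame`: `marker`, `object`, `objectPos`.
#' @export
planMarkerPositions <- function(plan, assign) {
  cp <- .planCoordinates(plan)
  cp <- cp[cp$type == "W", ]
  idx <- match(assign$contig, cp$contig)
  pos <- ifelse(cp$orientation[idx] == "-",
                cp$objectBeg[idx] + (cp$componentEnd[idx] - assign$position),
                cp$objectBeg[idx] + (assign$position - cp$componentBeg[idx]))
  data.frame(marker = assign$marker, object = cp$object[idx],
             objectPos = as.integer(pmax(1, pos)), stringsAsFactors = FALSE,
             row.names = NULL)
}

## split every chimera call, walking each contig's calls left to right and
## tracking the coordinate shift as pieces peel off
.splitAllChimeras <- function(contigs, assign, calls, coverage) {
  breakpoints <- list()
  for (i in seq_len(nrow(calls))) {
    lb <- locateBreakpoint(calls[i, ], coverage)
    breakpoints[[i]] <- data.frame(
      contig = calls$contig[i], breakpoint = lb$breakpoint,
      evidence = lb$evidence, lowConfidence = lb$lowConfidence,
      stringsAsFactors = FALSE)
  }
  bps <- do.call(rbind, breakpoints)
  for (ct in unique(bps$contig)) {
    cuts <- sort(bps$breakpoint[bps$contig == ct])
    current <- ct; offset <- 0L
    for (j in seq_along(cuts)) {
      res <- splitContig(contigs, current, cuts[j] - offset, assign)
      contigs <- res$contigs; assign <- res$assign
      offset <- cuts[j]
      current <- paste0(current, ".2")
    }
  }
  list(contigs = contigs, assign = assign, breakpoints = bps)
}

#' Run the full linkage-map scaffolding pipeline
#'
#' Composes the stages in protocol order: linkage-map construction from
#' the genotype matrix; chimera detection from genetic/physical
#' inconsistency, breakpoint location at coverage minima and contig
#' splitting; artifact flagging by modal depth; marker anchoring;
#' overlap-aware scaffolding; guide-assisted markerless placement;
#' pseudomolecule and AGP emission; and QC including a reconstructed-map
#' consistency check on the final coordinates. The pipeline itself is
#' deterministic: identical inputs and config give identical outputs.
#'
#' @param contigs Named [Biostrings::DNAStringSet] of draft contigs.
#' @param genotypes A [GenotypeMatrix-class] whose `markerInfo` references
#'   the contigs.
#' @param coverage Optional [CoverageTrack-class].
#' @param guide Optional guide table (`contig`, `chrom`, `position`,
#'   `strand`).
#' @param readKmers Optional [KmerSet-class] of read k-mers for the QV.
#' @param config A [pipelineConfig()] list.
#' @param outDir Optional directory; when given, FASTA/AGP/TSV/JSON
#'   artifacts are written there.
#' @return List with `map`, `chimeras`, `breakpoints`, `artifactFlags`,
#'   `anchors`, `plan`, `joins`, `placementLog`, `pseudomolecules`, `agp`,
#'   `unplaced`, `markerPositions`, `consistency`, `qc`, `config`.
#' @export
runPipeline <- function(contigs, genotypes, coverage = NULL, guide = NULL,
                        readKmers = NULL, config = pipelineConfig(),
                        outDir = NULL) {
  map <- buildGeneticMap(genotypes, lodThreshold = config$lodThreshold,
                         mappingFunction = config$mappingFunction,
                         maxMissing = config$maxMissing,
                         dropDistorted = config$dropDistorted,
                         distortedAlpha = config$distortedAlpha)
  assign <- markerAssignments(map, genotypes)

  chimeras <- detectChimeras(assign, minSupport = config$minSupport,
                             contigs = contigs)
  breakpoints <- NULL
  if (nrow(chimeras)) {
    cov <- if (is.null(coverage))
      new("CoverageTrack", depths = setNames(list(), character(0L)),
          window = 100L) else coverage
    res <- .splitAllChimeras(contigs, assign, chimeras, cov)
    contigs <- res$contigs; assign <- res$assign
    breakpoints <- res$breakpoints
  }

  artifactFlags <- if (!is.null(coverage))
    flagArtifactContigs(coverage, low = config$covLow, high = config$covHigh)
  else NULL

  anchors <- anchorContigs(map, assign, guide = guide,
                           minSupport = config$minSupport)
  sp <- buildScaffoldPlan(contigs, anchors, minJoinBp = config$minJoinBp,
                          maxMismatchFrac = config$maxMismatchFrac,
                          maxWindow = config$maxWindow,
                          gapLen = config$gapLen)
  plan <- sp$plan
  placementLog <- NULL
  if (!is.null(guide)) {
    pm <- placeMarkerless(plan, contigs, guide,
                          minOverlapBp = config$minInsertOverlapBp,
                          maxMismatchFrac = config$maxMismatchFrac,
                          posTol = config$posTol,
                          minJoinBp = config$minJoinBp,
                          maxWindow = config$maxWindow)
    plan <- pm$plan; placementLog <- pm$log
  }

  if (isTRUE(config$renameChromosomes)) {
    cp <- .planCoordinates(plan)
    objLen <- tapply(cp$length, cp$object, sum)
    zObj <- grep("^LGZ", names(objLen), value = TRUE)
    autoObj <- setdiff(names(objLen), zObj)
    autoObj <- autoObj[order(-objLen[autoObj], autoObj)]
    mapping <- setNames(sprintf("chr%02d", seq_along(autoObj)), autoObj)
    if (length(zObj)) {
      zNames <- if (length(zObj) == 1L) "chrZ"
                else sprintf("chrZ%d", seq_along(zObj))
      mapping <- c(mapping, setNames(zNames, zObj))
    }
    plan <- renameScaffoldObjects(plan, mapping)
  }

  build <- buildPseudomolecules(plan, contigs)
  markerPositions <- planMarkerPositions(plan, assign)

  ## reconstruct the map on final coordinates and check co-monotonicity
  located <- !is.na(markerPositions$object)
  mi2 <- markerInfo(genotypes)
  mi2[markerPositions$marker[located], "contig"] <- markerPositions$object[located]
  mi2[markerPositions$marker[located], "position"] <- markerPositions$objectPos[located]
  genotypes2 <- initialize(genotypes, markerInfo = mi2)
  map2 <- buildGeneticMap(genotypes2, lodThreshold = config$lodThreshold,
                          mappingFunction = config$mappingFunction,
                          maxMissing = config$maxMissing,
                          dropDistorted = config$dropDistorted,
                          distortedAlpha = config$distortedAlpha)
  tb2 <- mapTable(map2)
  positions <- data.frame(
    marker = tb2$marker,
    chrom = mi2[tb2$marker, "contig"],
    bp = mi2[tb2$marker, "position"],
    cM = tb2$cM, stringsAsFactors = FALSE)
  positions <- positions[positions$chrom %in% unique(planComponents(plan)$object), ]
  consistency <- mapConsistencyCheck(positions)

  qc <- qcReport(build$seqs, unplaced = build$unplaced, agp = build$agp,
                 readKmers = readKmers, k = config$k,
                 motif = config$telomereMotif,
                 telomereWindowBp = config$telomereWindowBp,
                 telomereMinUnits = config$telomereMinUnits,
                 qvCap = config$qvCap)

  out <- list(map = map, chimeras = chimeras, breakpoints = breakpoints,
              artifactFlags = artifactFlags, anchors = anchors, plan = plan,
              joins = sp$joins, placementLog = placementLog,
              pseudomolecules = build$seqs, agp = build$agp,
              unplaced = build$unplaced, markerPositions = markerPositions,
              consistency = consistency, qc = qc, config = config)
  if (!is.null(outDir)) writePipelineArtifacts(out, outDir)
  out
}

#' Write every pipeline artifact to a directory
#'
#' FASTA (pseudomolecules, unplaced), AGP, linkage-map TSV, chimera and
#' join logs, the physical-vs-genetic consistency plot, the QC report
#' JSON, and a run-report JSON serializing every configured threshold.
#'
#' @param result A [runPipeline()] result list.
#' @param outDir Output directory (created if needed).
#' @export
writePipelineArtifacts <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outDir, x)
  writeFastaFile(result$pseudomolecules, fp("pseudomolecules.fasta"))
  if (length(result$unplaced))
    writeFastaFile(result$unplaced, fp("unplaced.fasta"))
  writeAGP(result$agp, fp("assembly.agp"))
  writeLinkageMapTSV(result$map, fp("linkage_map.tsv"))
  if (nrow(result$chimeras))
    write.table(cbind(result$chimeras, result$breakpoints[, -1L]),
                fp("chimeras.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$joins, fp("joins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(result$placementLog))
    write.table(result$placementLog, fp("markerless_placement.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- mapTable(result$map)
  mi <- result$markerPositions
  plotMapConsistency(
    data.frame(marker = mi$marker, chrom = mi$object, bp = mi$objectPos,
               cM = tb$cM[match(mi$marker, tb$marker)])[!is.na(mi$object), ],
    file = fp("map_consistency.png"))
  writeQCReportJSON(result$qc, fp("qc_report.json"))
  jsonlite::write_json(result$config, fp("run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
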