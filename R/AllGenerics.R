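#' @include AllClasses.R
NULL

#' Accessors for linkscaf classes
#'
#' Small accessor generics exposing the slots of the core S4 containers
#' without touching `@` directly.
#'
#' @param x An object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromosomeSeqs", function(x) standardGeneric("chromosomeSeqs"))
#' @rdname accessors
#' @export
setGeneric("sexChromosome", function(x) standardGeneric("sexChromosome"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("individualRoles", function(x) standardGeneric("individualRoles"))
#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname accessors
#' @export
setGeneric("truthPositions", function(x) standardGeneric("truthPositions"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("sourceIntervals", function(x) standardGeneric("sourceIntervals"))
#' @rdname accessors
#' @export
setGeneric("chimeraJunctions", function(x) standardGeneric("chimeraJunctions"))
#' @rdname accessors
#' @export
setGeneric("coverageDepths", function(x) standardGeneric("coverageDepths"))
#' @rdname accessors
#' @export
setGeneric("coverageWindow", function(x) standardGeneric("coverageWindow"))
#' @rdname accessors
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))
#' @rdname accessors
#' @export
setGeneric("mappingFunction", function(x) standardGeneric("mappingFunction"))
#' @rdname accessors
#' @export
setGeneric("planComponents", function(x) standardGeneric("planComponents"))
#' @rdname accessors
#' @export
setGeneric("unplacedContigs", function(x) standardGeneric("unplacedContigs"))
#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @rdname accessors
#' @export
setGeneric("kmerCodes", function(x) standardGeneric("kmerCodes"))
#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname accessors
#' @export
setGeneric("qcLengths", function(x) standardGeneric("qcLengths"))
#' @rdname accessors
#' @export
setGeneric("qcCounts", function(x) standardGeneric("qcCounts"))
#' @rdname accessors
#' @export
setGeneric("qcClasses", function(x) standardGeneric("qcClasses"))
#' @rdname accessors
#' @export
setGeneric("qcTelomeres", function(x) standardGeneric("qcTelomeres"))
#' @rdname accessors
#' @export
setGeneric("consensusQV", function(x) standardGeneric("consensusQV"))

#' @rdname accessors
#' @export
setMethod("chromosomeSeqs", "TruthGenome", function(x) x@seqs)
#' @rdname accessors
#' @export
setMethod("sexChromosome", "TruthGenome", function(x) x@sexChromosome)
#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("individualRoles", "GenotypeMatrix", function(x) x@roles)
#' @rdname accessors
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markerInfo)
#' @rdname accessors
#' @export
setMethod("genotypes", "SimulatedCross", function(x) x@genotypes)
#' @rdname accessors
#' @export
setMethod("truthPositions", "SimulatedCross", function(x) x@truthPositions)
#' @rdname accessors
#' @export
setMethod("sourceIntervals", "FragmentationTruth", function(x) x@intervals)
#' @rdname accessors
#' @export
setMethod("chimeraJunctions", "FragmentationTruth", function(x) x@chimeraJunctions)
#' @rdname accessors
#' @export
setMethod("coverageDepths", "CoverageTrack", function(x) x@depths)
#' @rdname accessors
#' @export
setMethod("coverageWindow", "CoverageTrack", function(x) x@window)
#' @rdname accessors
#' @export
setMethod("mapTable", "GeneticMap", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("mappingFunction", "GeneticMap", function(x) x@mappingFunction)
#' @rdname accessors
#' @export
setMethod("planComponents", "ScaffoldPlan", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("unplacedContigs", "ScaffoldPlan", function(x) x@unplaced)
#' @rdname accessors
#' @export
setMethod("kmerSize", "KmerSet", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("kmerCodes", "KmerSet", function(x) x@codes)
#' @rdname accessors
#' @export
setMethod("kmerCounts", "KmerSet", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("qcLengths", "QCReport", function(x) x@lengths)
#' @rdname accessors
#' @export
setMethod("qcCounts", "QCReport", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("qcClasses", "QCReport", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("qcTelomeres", "QCReport", function(x) x@telomeres)
#' @rdname accessors
#' @export
setMethod("consensusQV", "QCReport", function(x) x@qv)

#' Subset a GenotypeMatrix by markers and individuals
#'
#' @param x A [GenotypeMatrix-class].
#' @param i Marker names or indices.
#' @param j Individual names or indices.
#' @param ... Ignored.
#' @param drop Ignored; the class is always preserved.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  calls <- x@calls[i, j, drop = FALSE]
  new("GenotypeMatrix", calls = calls,
      roles = x@roles[colnames(calls)],
      markerInfo = x@markerInfo[rownames(calls), , drop = FALSE],
      sex = if (length(x@sex)) x@sex[colnames(calls)] else x@sex)
})

#' @rdname accessors
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@calls))

setMethod("show", "TruthGenome", function(object) {
  cat(sprintf("TruthGenome: %d chromosome(s), %s bp total\n",
              length(object@seqs),
              format(sum(width(object@seqs)), big.mark = ",")))
  cat(sprintf("  telomere unit %s x%d per end; Z chromosome: %s\n",
              object@telomereUnit, object@telomereCopies,
              ifelse(is.na(object@sexChromosome), "none", object@sexChromosome)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  tab <- table(factor(object@roles, levels = INDIVIDUAL_ROLES))
  cat(sprintf("GenotypeMatrix: %d markers x %d individuals\n",
              nrow(object@calls), ncol(object@calls)))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  miss <- mean(is.na(object@calls[, object@roles == "f2", drop = FALSE]))
  cat(sprintf("  F2 missingness: %.1f%%\n", 100 * miss))
})

setMethod("show", "SimulatedCross", function(object) {
  cat(sprintf("SimulatedCross: %d F2 progeny (%s), missing rate %.2f\n",
              object@nProgeny, object@progenySex, object@missingRate))
  show(object@genotypes)
})

setMethod("show", "FragmentationTruth", function(object) {
  cat(sprintf("FragmentationTruth: %d contig(s), %d chimera(s), overlaps %d-%d bp\n",
              length(unique(object@intervals$contig)),
              length(object@chimeraJunctions),
              object@overlapRange[1L], object@overlapRange[2L]))
})

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack: %d contig(s), window %d bp\n",
              length(object@depths), object@window))
})

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  cat(sprintf("GeneticMap: %d markers in %d linkage group(s) (%s, LOD >= %g)\n",
              nrow(tb), length(unique(tb$group)), object@mappingFunction,
              object@lodThreshold))
  sizes <- sort(table(tb$group), decreasing = TRUE)
  cat(sprintf("  group sizes: %s\n",
              paste(utils::head(sizes, 10L), collapse = ", ")))
})

setMethod("show", "ScaffoldPlan", function(object) {
  cp <- object@components
  cat(sprintf("ScaffoldPlan: %d object(s), %d placed contig(s), %d gap(s), %d unplaced\n",
              length(unique(cp$object)), sum(cp$type == "W"),
              sum(cp$type == "U"), length(object@unplaced)))
})

setMethod("show", "KmerSet", function(object) {
  cat(sprintf("KmerSet: k=%d, %d distinct k-mers, %s total\n",
              object@k, length(object@codes),
              format(sum(object@counts), big.mark = ",")))
})

setMethod("show", "QCReport", function(object) {
  l <- object@lengths; co <- object@counts; cl <- object@classes
  fmt <- function(x) format(x, big.mark = ",")
  cat("Assembly QC report\n")
  cat(sprintf("  Total length (bp):                 %s\n", fmt(l["totalLength"])))
  cat(sprintf("  Pseudomolecule length (bp):        %s\n", fmt(l["pseudomoleculeLength"])))
  cat(sprintf("  Unplaced length (bp):              %s\n", fmt(l["unplacedLength"])))
  cat(sprintf("  N50 (bp):                          %s\n", fmt(l["n50"])))
  cat(sprintf("  Num. pseudomolecules / unplaced:   %s / %s\n",
              fmt(co["nPseudomolecules"]), fmt(co["nUnplaced"])))
  cat(sprintf("  Num. gaps / Ns:                    %s / %s\n",
              fmt(co["nGaps"]), fmt(co["nNBases"])))
  cat(sprintf("  Pseudomolecules with telomere pair: %d (one: %d, T2T gap-free: %d)\n",
              cl["pairOfTelomeres"], cl["oneTelomere"], cl["t2tGapFree"]))
  cat(sprintf("  Consensus QV:                      %s\n",
              ifelse(is.na(object@qv), "not estimated", sprintf("%.3f", object@qv))))
})
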