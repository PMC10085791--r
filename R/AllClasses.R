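#' @import methods
#' @importClassesFrom Biostrings DNAStringSet DNAString
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement matchPattern
#'   subseq xscat letterFrequency readDNAStringSet writeXStringSet width
#'   start end
#' @importFrom stats rpois rbinom runif median cor pchisq setNames
#' @importFrom utils read.table write.table head tail
#' @useDynLib linkscaf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

GENOTYPE_CODES <- c("AA", "AB", "BB")
INDIVIDUAL_ROLES <- c("parent_maternal", "parent_paternal",
                      "f1_female", "f1_male", "f2")

#' Truth genome for simulation
#'
#' Container for a simulated multi-chromosome genome whose chromosome ends
#' carry tandem telomeric repeats: the telomere unit (default `CCTAA`, the
#' lepidopteran plus-strand motif) at the 5' end and its reverse complement
#' (`TTAGG`) at the 3' end. At most one chromosome may be designated the Z
#' sex chromosome.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of chromosome sequences with
#'   unique names.
#' @slot sexChromosome Name of the Z chromosome, or `NA_character_`.
#' @slot telomereUnit The 5-mer telomere unit on the plus strand.
#' @slot telomereCopies Number of tandem unit copies implanted at each end.
#' @export
setClass("TruthGenome",
  representation(seqs = "DNAStringSet", sexChromosome = "character",
                 telomereUnit = "character", telomereCopies = "integer"))

setValidity("TruthGenome", function(object) {
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm))
    return("chromosome names must be present and unique")
  if (!is.na(object@sexChromosome) && !object@sexChromosome %in% nm)
    return("sexChromosome must name a chromosome")
  unit <- object@telomereUnit
  if (nchar(unit) != 5L) return("telomereUnit must be a 5-mer")
  rcUnit <- as.character(reverseComplement(DNAString(unit)))
  seqs <- as.character(object@seqs)
  if (!all(startsWith(seqs, unit)))
    return("every chromosome must begin with the telomere unit")
  if (!all(endsWith(seqs, rcUnit)))
    return("every chromosome must end with the reverse-complement unit")
  TRUE
})

#' F2-intercross genotype matrix
#'
#' Genotype calls for an F2 intercross: two inbred parents, two F1 hybrid
#' parents and the F2 progeny, over a set of markers each tied to a contig
#' and a 1-based physical position. Calls use the four-symbol alphabet
#' `AA` (maternal homozygote), `AB` (heterozygote), `BB` (paternal
#' homozygote) and `NA` (missing).
#'
#' @slot calls Character matrix, markers x individuals, values in
#'   `AA`/`AB`/`BB`/`NA`.
#' @slot roles Named character vector giving each individual's role, one of
#'   `parent_maternal`, `parent_paternal`, `f1_female`, `f1_male`, `f2`.
#' @slot markerInfo `data.frame` with columns `contig` and `position`
#'   (1-based bp), one row per marker; `NA` contig marks unanchored markers.
#' @slot sex Named character vector (`"female"`/`"male"`/`NA`) per
#'   individual; informative for mixed-sex F2 sets under ZW inheritance.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", roles = "character",
                 markerInfo = "data.frame", sex = "character"))

setValidity("GenotypeMatrix", function(object) {
  calls <- object@calls
  if (!is.character(calls)) return("calls must be a character matrix")
  bad <- !is.na(calls) & !calls %in% GENOTYPE_CODES
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("invalid genotype code '%s' at marker '%s', individual '%s'",
                   calls[i[1L], i[2L]], rownames(calls)[i[1L]],
                   colnames(calls)[i[2L]]))
  }
  if (!identical(names(object@roles), colnames(calls)))
    return("roles must be named by the individuals (columns of calls)")
  if (!all(object@roles %in% INDIVIDUAL_ROLES))
    return("roles must be parent_maternal/parent_paternal/f1_female/f1_male/f2")
  mi <- object@markerInfo
  if (!all(c("contig", "position") %in% colnames(mi)))
    return("markerInfo needs 'contig' and 'position' columns")
  if (!identical(rownames(mi), rownames(calls)))
    return("markerInfo rows must match the markers (rows of calls)")
  if (length(object@sex) && !identical(names(object@sex), colnames(calls)))
    return("sex must be named by the individuals")
  TRUE
})

#' Simulated F2 cross with linked truth
#'
#' A [GenotypeMatrix] generated by simulated meiosis plus the true genetic
#' and physical coordinates of every marker, kept for recovery tests.
#'
#' @slot genotypes The simulated [GenotypeMatrix].
#' @slot truthPositions `data.frame` with columns `marker`, `chrom`, `bp`,
#'   `cM` giving the true location of each marker.
#' @slot nProgeny Number of F2 individuals simulated.
#' @slot missingRate Fraction of F2 calls masked as missing.
#' @slot progenySex `"all_female"` or `"mixed"`.
#' @export
setClass("SimulatedCross",
  representation(genotypes = "GenotypeMatrix", truthPositions = "data.frame",
                 nProgeny = "integer", missingRate = "numeric",
                 progenySex = "character"))

setValidity("SimulatedCross", function(object) {
  tp <- object@truthPositions
  if (!all(c("marker", "chrom", "bp", "cM") %in% colnames(tp)))
    return("truthPositions needs marker/chrom/bp/cM columns")
  for (ch in unique(tp$chrom)) {
    sub <- tp[tp$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    if (is.unsorted(sub$cM)) return("cM must be non-decreasing along each chromosome")
  }
  TRUE
})

#' Ground truth of a simulated fragmentation
#'
#' Records, for every simulated contig, the source interval(s) on the truth
#' genome (two intervals for implanted chimeras), the chimeric junction
#' offsets, and the sampled terminal-overlap range. This is the oracle used
#' by round-trip and chimera-recovery tests.
#'
#' @slot intervals `data.frame` with columns `contig`, `part`, `chrom`,
#'   `start`, `end` (1-based inclusive on the truth chromosome), `strand`.
#' @slot chimeraJunctions Named numeric vector: contig -> junction offset in
#'   contig coordinates (last base of the first part).
#' @slot overlapRange Numeric length-2, the (min, max) terminal overlap in bp.
#' @export
setClass("FragmentationTruth",
  representation(intervals = "data.frame", chimeraJunctions = "numeric",
                 overlapRange = "numeric"))

setValidity("FragmentationTruth", function(object) {
  iv <- object@intervals
  need <- c("contig", "part", "chrom", "start", "end", "strand")
  if (!all(need %in% colnames(iv)))
    return("intervals needs contig/part/chrom/start/end/strand columns")
  if (!all(iv$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  nParts <- table(iv$contig)
  chim <- names(object@chimeraJunctions)
  if (!all(chim %in% names(nParts)[nParts > 1L]))
    return("chimeraJunctions must name multi-part contigs")
  TRUE
})

#' Windowed read-coverage track
#'
#' Per-contig windowed read depth. Windows of fixed size tile each contig
#' from its first base; the last window may be shorter.
#'
#' @slot depths Named list of non-negative numeric vectors, one per contig.
#' @slot window Window size in bp.
#' @export
setClass("CoverageTrack",
  representation(depths = "list", window = "integer"))

setValidity("CoverageTrack", function(object) {
  if (is.null(names(object@depths))) return("depths must be named by contig")
  if (any(vapply(object@depths, function(d) any(d < 0), logical(1L))))
    return("depths must be non-negative")
  if (object@window < 1L) return("window must be >= 1")
  TRUE
})

#' Genetic linkage map
#'
#' Ordered markers grouped into linkage groups with cumulative genetic
#' positions in centimorgans.
#'
#' @slot table `data.frame` with columns `marker`, `group`, `index` (order
#'   within group) and `cM` (cumulative position from the first marker).
#' @slot mappingFunction `"kosambi"` or `"haldane"`.
#' @slot lodThreshold LOD threshold used for grouping.
#' @slot segregation `data.frame` of per-marker segregation chi-square
#'   results (may have zero rows).
#' @export
setClass("GeneticMap",
  representation(table = "data.frame", mappingFunction = "character",
                 lodThreshold = "numeric", segregation = "data.frame"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  if (!all(c("marker", "group", "index", "cM") %in% colnames(tb)))
    return("table needs marker/group/index/cM columns")
  if (anyDuplicated(tb$marker)) return("each marker belongs to exactly one group")
  for (g in unique(tb$group)) {
    sub <- tb[tb$group == g, ]
    sub <- sub[order(sub$index), ]
    if (is.unsorted(sub$cM)) return("cM must be non-decreasing within a group")
  }
  if (!object@mappingFunction %in% c("kosambi", "haldane"))
    return("mappingFunction must be 'kosambi' or 'haldane'")
  TRUE
})

#' Scaffold plan (AGP-equivalent)
#'
#' Ordered, oriented contig placements per chromosome with gap records, plus
#' the list of unplaced contigs. Adjacent `W` components with no intervening
#' gap record represent an accepted terminal-overlap merge: the overlap bases
#' are kept on the upstream contig and trimmed from the downstream component
#' range.
#'
#' @slot components `data.frame` with columns `object`, `part`, `type`
#'   (`"W"` contig / `"U"` gap), `contig` (`NA` for gaps), `componentBeg`,
#'   `componentEnd` (1-based in contig coordinates; gap length for `U`),
#'   `orientation` (`+`/`-`/`NA`).
#' @slot unplaced Character vector of unplaced contig names.
#' @slot gapLen Gap length convention in bp (100 by default).
#' @export
setClass("ScaffoldPlan",
  representation(components = "data.frame", unplaced = "character",
                 gapLen = "integer"))

setValidity("ScaffoldPlan", function(object) {
  cp <- object@components
  need <- c("object", "part", "type", "contig", "componentBeg",
            "componentEnd", "orientation")
  if (!all(need %in% colnames(cp)))
    return("components is missing required columns")
  if (!all(cp$type %in% c("W", "U"))) return("component type must be 'W' or 'U'")
  w <- cp[cp$type == "W", ]
  if (anyDuplicated(w$contig))
    return("every contig appears at most once in the plan")
  if (any(w$contig %in% object@unplaced))
    return("a contig cannot be both placed and unplaced")
  TRUE
})

#' Canonical k-mer multiset
#'
#' A set of canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) with multiplicities, 2-bit packed into numeric codes.
#'
#' @slot k Odd k-mer size, 11..25.
#' @slot codes Numeric vector of distinct canonical k-mer codes.
#' @slot counts Numeric vector of multiplicities, parallel to `codes`.
#' @export
setClass("KmerSet",
  representation(k = "integer", codes = "numeric", counts = "numeric"))

setValidity("KmerSet", function(object) {
  if (object@k %% 2L == 0L) return("k must be odd")
  if (object@k < 11L || object@k > 25L) return("k must be in 11..25")
  if (length(object@codes) != length(object@counts))
    return("codes and counts must be parallel")
  if (anyDuplicated(object@codes)) return("codes must be distinct")
  TRUE
})

#' Assembly quality-control report
#'
#' Length, gap, telomere, telomere-to-telomere (T2T) and consensus-QV
#' metrics of an assembly, in the shape of a standard assembly summary
#' table.
#'
#' @slot lengths Named numeric: `totalLength`, `pseudomoleculeLength`,
#'   `unplacedLength`, `n50`, `contigN50`, `longestPseudomolecule`,
#'   `shortestSequence`.
#' @slot counts Named numeric: `nPseudomolecules`, `nUnplaced`, `nGaps`,
#'   `nNBases`.
#' @slot telomeres `data.frame` per pseudomolecule: `object`, `tel5`,
#'   `tel3`, `gaps`.
#' @slot classes Named numeric: `pairOfTelomeres`, `oneTelomere`,
#'   `t2tGapFree`.
#' @slot qv Consensus QV (`NA` when not estimated).
#' @export
setClass("QCReport",
  representation(lengths = "numeric", counts = "numeric",
                 telomeres = "data.frame", classes = "numeric",
                 qv = "numeric"))

setValidity("QCReport", function(object) {
  cl <- object@classes
  if (all(c("t2tGapFree", "pairOfTelomeres") %in% names(cl)) &&
      !is.na(cl["t2tGapFree"]) && !is.na(cl["pairOfTelomeres"]) &&
      cl["t2tGapFree"] > cl["pairOfTelomeres"])
    return("t2tGapFree cannot exceed pairOfTelomeres")
  TRUE
})
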