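#' @include AllClasses.R
NULL

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings: names are truncated to the first token on
#' read; sequences are wrapped at 60 columns on write, so read-write round
#' trips are byte-identical on canonical files.
#'
#' @param path File path.
#' @return `readFastaFile`: a named [Biostrings::DNAStringSet].
#' @export
readFastaFile <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1L), 1L)
  seqs
}

#' @rdname readFastaFile
#' @param seqs A [Biostrings::DNAStringSet].
#' @export
writeFastaFile <- function(seqs, path) {
  writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read and write the genotype-matrix TSV dialect
#'
#' Tab-separated, one row per marker. Columns: `marker`, `contig`,
#' `position`, then one column per individual. Two comment lines precede
#' the header: `#roles` and `#sex`, giving the role and sex of every
#' individual column in order. Codes are `AA`, `AB`, `BB` and `NA`
#' (missing); anything else is an error naming the offending cell.
#'
#' @param path File path.
#' @return `readGenotypeTSV`: a [GenotypeMatrix-class].
#' @export
readGenotypeTSV <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  roleLine <- comments[startsWith(comments, "#roles")]
  if (!length(roleLine)) stop("missing '#roles' line in ", path)
  roles <- strsplit(sub("^#roles\t", "", roleLine[1L]), "\t")[[1L]]
  sexLine <- comments[startsWith(comments, "#sex")]
  sex <- if (length(sexLine)) strsplit(sub("^#sex\t", "", sexLine[1L]), "\t")[[1L]]
         else rep(NA_character_, length(roles))
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (!all(c("marker", "contig", "position") %in% colnames(tab)))
    stop("genotype TSV must start with marker/contig/position columns")
  ids <- setdiff(colnames(tab), c("marker", "contig", "position"))
  if (length(ids) != length(roles))
    stop("#roles length does not match the individual columns")
  calls <- as.matrix(tab[, ids, drop = FALSE])
  rownames(calls) <- tab$marker
  calls[calls == "NA" | calls == ""] <- NA_character_
  bad <- !is.na(calls) & !calls %in% GENOTYPE_CODES
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown genotype code '%s' at marker '%s', individual '%s'",
                 calls[i[1L], i[2L]], rownames(calls)[i[1L]], ids[i[2L]]))
  }
  mi <- data.frame(contig = tab$contig,
                   position = as.integer(tab$position),
                   row.names = tab$marker, stringsAsFactors = FALSE)
  mi$contig[mi$contig == "NA" | mi$contig == ""] <- NA_character_
  new("GenotypeMatrix", calls = calls, roles = setNames(roles, ids),
      markerInfo = mi, sex = setNames(sex, ids))
}

#' @rdname readGenotypeTSV
#' @param gm A [GenotypeMatrix-class].
#' @export
writeGenotypeTSV <- function(gm, path) {
  calls <- genotypeCalls(gm)
  mi <- markerInfo(gm)
  roles <- individualRoles(gm)
  sex <- gm@sex
  if (!length(sex)) sex <- setNames(rep(NA_character_, ncol(calls)), colnames(calls))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("#roles", unname(roles)), collapse = "\t"), con)
  writeLines(paste(c("#sex", unname(sex)), collapse = "\t"), con)
  tab <- data.frame(marker = rownames(calls), contig = mi$contig,
                    position = mi$position, calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a linkage map as TSV
#'
#' Columns `marker`, `group`, `index`, `cM`; the mapping function and LOD
#' threshold are recorded in a comment line.
#'
#' @param map A [GeneticMap-class].
#' @param path File path.
#' @export
writeLinkageMapTSV <- function(map, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#mapping_function\t%s\t#lod_threshold\t%g",
                     mappingFunction(map), map@lodThreshold), con)
  write.table(mapTable(map), con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write AGP 2.1
#'
#' Nine-column AGP with the `##agp-version 2.1` pragma. On read,
#' coordinates are validated: object parts must be 1-based, contiguous and
#' non-overlapping, and each `W` component span must equal its object
#' span; a violation is an error naming the line.
#'
#' @param path File path.
#' @return `readAGP`: the AGP as a `data.frame` in the column layout of
#'   [buildPseudomolecules()].
#' @export
readAGP <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  tab <- read.table(text = lines[keep], sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("object", "object_beg", "object_end",
                                  "part_number", "component_type",
                                  "component_id", "component_beg",
                                  "component_end", "orientation"),
                    colClasses = "character")
  lineNo <- which(keep)
  tab$object_beg <- as.integer(tab$object_beg)
  tab$object_end <- as.integer(tab$object_end)
  tab$part_number <- as.integer(tab$part_number)
  expectedBeg <- 1L
  lastObj <- ""
  for (i in seq_len(nrow(tab))) {
    if (tab$object[i] != lastObj) { expectedBeg <- 1L; lastObj <- tab$object[i] }
    if (tab$object_beg[i] != expectedBeg)
      stop(sprintf("AGP line %d: object coordinates not contiguous (expected beg %d, got %d)",
                   lineNo[i], expectedBeg, tab$object_beg[i]))
    span <- tab$object_end[i] - tab$object_beg[i] + 1L
    if (tab$component_type[i] == "W") {
      cspan <- as.integer(tab$component_end[i]) - as.integer(tab$component_beg[i]) + 1L
      if (cspan != span)
        stop(sprintf("AGP line %d: component span (%d) != object span (%d)",
                     lineNo[i], cspan, span))
    } else if (as.integer(tab$component_id[i]) != span) {
      stop(sprintf("AGP line %d: gap length != object span", lineNo[i]))
    }
    expectedBeg <- tab$object_end[i] + 1L
  }
  tab
}

#' @rdname readAGP
#' @param agp AGP `data.frame`.
#' @export
writeAGP <- function(agp, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write windowed coverage as bedGraph
#'
#' Four columns (`contig`, 0-based `start`, `end`, `depth`), one row per
#' window. All windows of a contig must share the track's window size
#' (the last may be shorter) and tile the contig from 0; a violation is an
#' error naming the line.
#'
#' @param path File path.
#' @return `readBedGraph`: a [CoverageTrack-class].
#' @export
readBedGraph <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  tab <- read.table(text = lines[keep], sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("contig", "start", "end", "depth"))
  lineNo <- which(keep)
  window <- max(tab$end - tab$start)
  depths <- list()
  for (ct in unique(tab$contig)) {
    idx <- which(tab$contig == ct)
    sub <- tab[idx, ]
    expected <- seq(0L, by = window, length.out = nrow(sub))
    off <- which(sub$start != expected)
    if (length(off))
      stop(sprintf("bedGraph line %d: windows do not tile contig '%s'",
                   lineNo[idx[off[1L]]], ct))
    depths[[ct]] <- sub$depth
  }
  new("CoverageTrack", depths = depths, window = as.integer(window))
}

#' @rdname readBedGraph
#' @param coverage A [CoverageTrack-class].
#' @export
writeBedGraph <- function(coverage, path) {
  w <- coverageWindow(coverage)
  depths <- coverageDepths(coverage)
  rows <- lapply(names(depths), function(ct) {
    d <- depths[[ct]]
    data.frame(contig = ct, start = (seq_along(d) - 1L) * w,
               end = seq_along(d) * w, depth = d, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a guide-alignment table (TSV or PAF)
#'
#' Accepts either a headered TSV with columns `contig`, `chrom`,
#' `position`, `strand`, or a PAF file (12+ unheadered columns), from
#' which query name, target name, target start and strand are taken.
#'
#' @param path File path.
#' @return `data.frame` with columns `contig`, `chrom`, `position`,
#'   `strand`.
#' @export
readGuideTSV <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  if (length(first) >= 12L && first[5L] %in% c("+", "-")) {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      fill = TRUE, header = FALSE)
    return(data.frame(contig = tab[[1L]], chrom = tab[[6L]],
                      position = as.integer(tab[[8L]]) + 1L,
                      strand = tab[[5L]], stringsAsFactors = FALSE))
  }
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("contig", "chrom", "position", "strand")
  if (!all(need %in% colnames(tab)))
    stop("guide table needs columns contig/chrom/position/strand")
  tab[, need]
}

#' Write a QC report as JSON
#'
#' Field names mirror the usual assembly summary table (total length, N50,
#' gap and N counts, telomere-pair and T2T counts, QV).
#'
#' @param report A [QCReport-class].
#' @param path File path.
#' @export
writeQCReportJSON <- function(report, path) {
  l <- qcLengths(report); co <- qcCounts(report); cl <- qcClasses(report)
  out <- list(
    total_length_bp = unname(l["totalLength"]),
    pseudomolecule_length_bp = unname(l["pseudomoleculeLength"]),
    unplaced_length_bp = unname(l["unplacedLength"]),
    n50_bp = unname(l["n50"]),
    contig_n50_bp = unname(l["contigN50"]),
    longest_pseudomolecule_bp = unname(l["longestPseudomolecule"]),
    shortest_sequence_bp = unname(l["shortestSequence"]),
    num_pseudomolecules = unname(co["nPseudomolecules"]),
    num_unplaced_contigs = unname(co["nUnplaced"]),
    num_gaps = unname(co["nGaps"]),
    num_n_bases = unname(co["nNBases"]),
    num_pseudomolecules_with_telomere_pair = unname(cl["pairOfTelomeres"]),
    num_pseudomolecules_with_one_telomere = unname(cl["oneTelomere"]),
    num_t2t_gap_free_pseudomolecules = unname(cl["t2tGapFree"]),
    qv = if (is.na(consensusQV(report))) NULL else unname(consensusQV(report)),
    telomeres = qcTelomeres(report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
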