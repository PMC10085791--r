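#' @include AllClasses.R
NULL

.f2Ids <- function(gm) names(which(individualRoles(gm) == "f2"))

.roleId <- function(gm, role) {
  id <- names(which(individualRoles(gm) == role))
  if (length(id)) id[1L] else NA_character_
}

## paternal homozygote symbol per marker ("BB" under the package coding;
## read from the paternal parent row when present)
.paternalType <- function(gm, markers = rownames(genotypeCalls(gm))) {
  pat <- .roleId(gm, "parent_paternal")
  if (is.na(pat)) return(setNames(rep("BB", length(markers)), markers))
  setNames(genotypeCalls(gm)[markers, pat], markers)
}

#' Filter individuals and markers by missingness
#'
#' Removes F2 individuals, then markers, whose fraction of missing F2 calls
#' strictly exceeds `maxMissing` (a call missing in exactly the threshold
#' fraction is retained). Individuals are filtered first so that poor
#' individuals do not drag down otherwise sound markers. Parent and F1 rows
#' are never removed and do not enter the fractions.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param maxMissing Maximum tolerated missing fraction (default 0.20).
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterMissingness <- function(gm, maxMissing = 0.20) {
  calls <- genotypeCalls(gm)
  f2 <- .f2Ids(gm)
  if (!length(f2)) stop("no F2 individuals present")
  indMiss <- colMeans(is.na(calls[, f2, drop = FALSE]))
  keepInd <- f2[indMiss <= maxMissing]
  if (!length(keepInd)) stop("all F2 individuals exceeded the missingness limit")
  markMiss <- rowMeans(is.na(calls[, keepInd, drop = FALSE]))
  keepMark <- rownames(calls)[markMiss <= maxMissing]
  keepCols <- c(setdiff(colnames(calls), f2), keepInd)
  gm[keepMark, colnames(calls)[colnames(calls) %in% keepCols]]
}

#' Classify Z-linked markers
#'
#' Labels a marker Z-linked iff (1) the F1 female call equals the paternal
#' homozygote, (2) the F1 male call is heterozygous, and (3) every
#' non-missing F2 call is a parental homozygote (never `AB`). These are the
#' expectations under ZW inheritance with all-female F2 progeny, where each
#' F2 female carries a single, paternally derived Z.
#'
#' @param gm A [GenotypeMatrix-class] with F1 rows present.
#' @return Named logical vector over markers.
#' @export
classifyZMarkers <- function(gm) {
  f1f <- .roleId(gm, "f1_female"); f1m <- .roleId(gm, "f1_male")
  if (is.na(f1f) || is.na(f1m))
    stop("F1 female and male rows are required to classify Z markers")
  calls <- genotypeCalls(gm)
  f2 <- .f2Ids(gm)
  pat <- .paternalType(gm)
  c1 <- !is.na(calls[, f1f]) & calls[, f1f] == pat & calls[, f1f] %in% c("AA", "BB")
  c2 <- !is.na(calls[, f1m]) & calls[, f1m] == "AB"
  f2calls <- calls[, f2, drop = FALSE]
  c3 <- rowSums(f2calls == "AB", na.rm = TRUE) == 0L
  setNames(c1 & c2 & c3, rownames(calls))
}

#' Retain autosomal markers with heterozygous F1 parents
#'
#' Keeps the markers at which both F1 parents are called `AB`; markers with
#' a missing F1 call cannot be verified and are dropped.
#'
#' @param gm A [GenotypeMatrix-class] with F1 rows present.
#' @param markers Optional subset of markers to consider (default all).
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterAutosomal <- function(gm, markers = rownames(genotypeCalls(gm))) {
  f1f <- .roleId(gm, "f1_female"); f1m <- .roleId(gm, "f1_male")
  if (is.na(f1f) || is.na(f1m)) stop("F1 rows are required")
  calls <- genotypeCalls(gm)[markers, , drop = FALSE]
  ok <- !is.na(calls[, f1f]) & calls[, f1f] == "AB" &
        !is.na(calls[, f1m]) & calls[, f1m] == "AB"
  gm[markers[ok], ]
}

#' Recode Z-linked markers to the backcross model
#'
#' Converts every paternal-homozygote call of the given Z-linked markers to
#' `AB`, adapting hemizygous Z genotypes to a backcross two-class model
#' (maternal homozygote vs heterozygote). Maternal homozygotes and missing
#' calls are unchanged. Passing a marker that does not satisfy the Z
#' criteria of [classifyZMarkers()] is an error.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param markers Markers to recode (default: all markers in `gm`).
#' @return The recoded [GenotypeMatrix-class], subset to `markers`.
#' @export
convertZToBackcross <- function(gm, markers = rownames(genotypeCalls(gm))) {
  z <- classifyZMarkers(gm)
  if (any(!z[markers]))
    stop("non-Z-linked marker passed to convertZToBackcross: ",
         paste(utils::head(markers[!z[markers]], 3L), collapse = ", "))
  gm <- gm[markers, ]
  calls <- genotypeCalls(gm)
  pat <- .paternalType(gm)
  recoded <- calls
  for (mk in rownames(calls))
    recoded[mk, !is.na(calls[mk, ]) & calls[mk, ] == pat[mk]] <- "AB"
  initialize(gm, calls = recoded)
}

#' Chi-square segregation test per marker
#'
#' Pearson chi-square against the expected F2 segregation (1:2:1 over
#' `AA:AB:BB` for the codominant F2 model; 1:1 over `AA:AB` for the
#' backcross model), with `df = classes - 1`. Missing calls are excluded
#' from the counts. Markers with zero informative individuals are flagged
#' non-estimable (`NA` statistics).
#'
#' @param gm A [GenotypeMatrix-class].
#' @param model `"f2"` or `"backcross"`.
#' @param markers Optional marker subset.
#' @return `data.frame` with columns `marker`, `n`, `chi2`, `df`, `p`.
#' @export
segregationTest <- function(gm, model = c("f2", "backcross"),
                            markers = rownames(genotypeCalls(gm))) {
  model <- match.arg(model)
  classes <- if (model == "f2") c("AA", "AB", "BB") else c("AA", "AB")
  expectedP <- if (model == "f2") c(1, 2, 1) / 4 else c(1, 1) / 2
  calls <- genotypeCalls(gm)[markers, .f2Ids(gm), drop = FALSE]
  res <- lapply(markers, function(mk) {
    obs <- vapply(classes, function(cl)
      sum(calls[mk, ] == cl, na.rm = TRUE), numeric(1L))
    n <- sum(obs)
    if (n == 0L)
      return(data.frame(marker = mk, n = 0L, chi2 = NA_real_,
                        df = NA_integer_, p = NA_real_))
    e <- expectedP * n
    chi2 <- sum((obs - e)^2 / e)
    df <- length(classes) - 1L
    data.frame(marker = mk, n = n, chi2 = chi2, df = df,
               p = pchisq(chi2, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## encode calls to integer dosage 0/1/2 (AA/AB/BB); NA preserved
.encodeCalls <- function(calls) {
  G <- matrix(match(calls, GENOTYPE_CODES) - 1L, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  G
}

## F2 coupling-phase two-point log10-likelihood for 3x3 count matrices
.f2LogLik10 <- function(r, N) {
  p <- list(`00` = (1 - r)^2 / 4, `01` = r * (1 - r) / 2, `02` = r^2 / 4,
            `10` = r * (1 - r) / 2, `11` = ((1 - r)^2 + r^2) / 2,
            `12` = r * (1 - r) / 2, `20` = r^2 / 4, `21` = r * (1 - r) / 2,
            `22` = (1 - r)^2 / 4)
  ll <- 0
  for (key in names(p)) {
    Nk <- N[[key]]
    term <- Nk * log10(pmax(p[[key]], 1e-300))
    term[Nk == 0] <- 0
    ll <- ll + term
  }
  ll
}

## all-pairs F2 EM over dosage matrix G (individuals x markers).
## Counts for every ordered genotype pair come from 9 cross-products, so the
## EM runs elementwise on marker x marker matrices.
.pairwiseRfF2 <- function(G, tol = 1e-6, maxIter = 100L) {
  X <- lapply(0:2, function(g) {
    M <- G == g; M[is.na(M)] <- FALSE; storage.mode(M) <- "numeric"; M
  })
  N <- list()
  for (g1 in 0:2) for (g2 in 0:2)
    N[[paste0(g1, g2)]] <- crossprod(X[[g1 + 1L]], X[[g2 + 1L]])
  n <- Reduce(`+`, N)
  ## recombinant gametes carried by each unambiguous class
  recConst <- N[["01"]] + N[["10"]] + N[["12"]] + N[["21"]] +
    2 * (N[["02"]] + N[["20"]])
  r <- matrix(0.25, nrow(n), ncol(n), dimnames = dimnames(n))
  for (it in seq_len(maxIter)) {
    w <- r^2 / (r^2 + (1 - r)^2)  # E[rec gametes]/2 in the double-het class
    rNew <- (recConst + 2 * w * N[["11"]]) / (2 * n)
    rNew[n == 0] <- NA_real_
    rNew <- pmin(pmax(rNew, 0), 0.5)
    done <- max(abs(rNew - r), na.rm = TRUE) < tol
    r <- rNew
    if (done) break
  }
  lod <- .f2LogLik10(r, N) - .f2LogLik10(matrix(0.5, nrow(n), ncol(n)), N)
  lod <- pmax(lod, 0)
  lod[n == 0] <- NA_real_
  diag(r) <- NA_real_; diag(lod) <- NA_real_
  list(r = r, lod = lod, n = n)
}

## all-pairs backcross estimator over dosage matrix G coded 0 (maternal
## homozygote) / 1 (heterozygote); closed form r = R/n.
.pairwiseRfBackcross <- function(G) {
  X0 <- G == 0L; X1 <- G == 1L
  X0[is.na(X0)] <- FALSE; X1[is.na(X1)] <- FALSE
  storage.mode(X0) <- "numeric"; storage.mode(X1) <- "numeric"
  ok <- !is.na(G); storage.mode(ok) <- "numeric"
  n <- crossprod(ok)
  R <- crossprod(X0, X1) + crossprod(X1, X0)
  r <- R / n
  r[n == 0] <- NA_real_
  r <- pmin(pmax(r, 0), 0.5)
  t1 <- (n - R) * log10(2 * (1 - r))
  t2 <- R * log10(2 * r)
  t2[R == 0] <- 0  # 0 * log10(0) convention
  lod <- pmax(t1 + t2, 0)
  lod[n == 0] <- NA_real_
  diag(r) <- NA_real_; diag(lod) <- NA_real_
  list(r = r, lod = lod, n = n)
}

#' All-pairs two-point recombination fractions and LOD scores
#'
#' Estimates the recombination fraction and LOD score (log10 likelihood
#' ratio against r = 0.5) for every marker pair among the F2 individuals.
#' The F2 model assumes codominant calls in known coupling phase (inbred
#' parental lines) and maximizes the 3x3 multinomial likelihood by EM over
#' the double-heterozygote ambiguity class (tolerance 1e-6, at most 100
#' iterations). The backcross model expects two-class calls (`AA`/`AB`,
#' e.g. after [convertZToBackcross()]) and uses the closed form r = R/n.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param model `"f2"` or `"backcross"`.
#' @param markers Optional marker subset.
#' @return List with marker x marker matrices `r`, `lod`, `n`.
#' @export
pairwiseRf <- function(gm, model = c("f2", "backcross"),
                       markers = rownames(genotypeCalls(gm))) {
  model <- match.arg(model)
  calls <- genotypeCalls(gm)[markers, .f2Ids(gm), drop = FALSE]
  G <- t(.encodeCalls(calls))  # individuals x markers
  if (model == "f2") return(.pairwiseRfF2(G))
  if (any(G == 2L, na.rm = TRUE)) {
    warning("BB calls treated as missing under the backcross model")
    G[G == 2L] <- NA_integer_
  }
  .pairwiseRfBackcross(G)
}

.twoPointFromVectors <- function(calls1, calls2, model) {
  calls <- rbind(m1 = calls1, m2 = calls2)
  G <- t(.encodeCalls(calls))
  res <- if (model == "f2") .pairwiseRfF2(G) else {
    if (any(G == 2L, na.rm = TRUE)) stop("backcross calls must be AA/AB")
    .pairwiseRfBackcross(G)
  }
  n <- res$n["m1", "m2"]
  if (n == 0) return(list(rHat = NA_real_, lod = NA_real_, n = 0L, model = model))
  list(rHat = res$r["m1", "m2"], lod = res$lod["m1", "m2"],
       n = as.integer(n), model = model)
}

#' Two-point estimate for one marker pair (F2 model)
#'
#' @param calls1,calls2 Character vectors of F2 calls (`AA`/`AB`/`BB`/`NA`)
#'   for the two markers, individual-aligned.
#' @return List with `rHat` (in `[0, 0.5]`), `lod`, `n`, `model`.
#' @seealso [pairwiseRf()] for the all-pairs version.
#' @export
estimateRfF2 <- function(calls1, calls2) .twoPointFromVectors(calls1, calls2, "f2")

#' Two-point estimate for one marker pair (backcross model)
#'
#' Closed-form r = R/n over the two-class calls, with
#' LOD = (n - R) log10(2(1 - r)) + R log10(2r) (0 log 0 = 0).
#'
#' @inheritParams estimateRfF2
#' @return List with `rHat`, `lod`, `n`, `model`.
#' @export
estimateRfBackcross <- function(calls1, calls2)
  .twoPointFromVectors(calls1, calls2, "backcross")

#' Group markers by single-linkage at a LOD threshold
#'
#' Two markers share a linkage group iff they are connected by a chain of
#' pairs with LOD at or above the threshold (transitive closure of the
#' LOD graph).
#'
#' @param lod Symmetric marker x marker LOD matrix (`NA` diagonal).
#' @param threshold Grouping LOD threshold (default 3).
#' @return Named integer vector: marker -> group id, numbered in order of
#'   first appearance.
#' @export
groupMarkers <- function(lod, threshold = 3) {
  n <- nrow(lod)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  hits <- which(!is.na(lod) & lod >= threshold & upper.tri(lod), arr.ind = TRUE)
  for (e in seq_len(nrow(hits))) {
    ra <- find(hits[e, 1L]); rb <- find(hits[e, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  ids <- match(roots, unique(roots))
  setNames(ids, rownames(lod))
}

#' Genetic mapping functions
#'
#' Converts a recombination fraction to a map distance in cM under the
#' Haldane (no interference) or Kosambi mapping function, and back.
#' `r >= 0.5` maps to `Inf` with a warning. The two functions compose to
#' the identity.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @param method `"kosambi"` (default) or `"haldane"`.
#' @return Map distance(s) in cM.
#' @examples
#' mapDistance(0.1, "haldane")   # 11.157 cM
#' mapDistance(0.1, "kosambi")   # 10.137 cM
#' @export
mapDistance <- function(r, method = c("kosambi", "haldane")) {
  method <- match.arg(method)
  if (any(r < 0, na.rm = TRUE)) stop("r must be >= 0")
  if (any(r >= 0.5, na.rm = TRUE))
    warning("r >= 0.5 has no finite map distance; returning Inf")
  d <- ifelse(r >= 0.5, Inf,
              if (method == "haldane") -50 * log(1 - 2 * r)
              else 25 * log((1 + 2 * r) / (1 - 2 * r)))
  d
}

#' @rdname mapDistance
#' @param d Map distance(s) in cM.
#' @export
mapDistanceInverse <- function(d, method = c("kosambi", "haldane")) {
  method <- match.arg(method)
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0")
  if (method == "haldane") (1 - exp(-d / 50)) / 2 else tanh(d / 50) / 2
}

#' Order the markers of one linkage group
#'
#' Seriation that minimizes the sum of adjacent recombination fractions:
#' the path is seeded greedily from the closest pair, extended at both ends
#' by nearest neighbour, then refined by 2-opt segment reversals until no
#' reversal improves the objective. The result is defined up to whole-group
#' reversal; the orientation with the lexicographically smaller first
#' marker name is returned, so reversing the input yields the identical
#' order. Cumulative cM positions are computed from the adjacent r values
#' under the chosen mapping function.
#'
#' @param markers Marker names of the group.
#' @param rf Marker x marker recombination-fraction matrix covering them.
#' @param mappingFunction `"kosambi"` or `"haldane"`.
#' @return `data.frame` with columns `marker`, `index`, `cM`.
#' @export
orderMarkers <- function(markers, rf, mappingFunction = c("kosambi", "haldane")) {
  mappingFunction <- match.arg(mappingFunction)
  m <- length(markers)
  if (m < 1L) stop("empty marker group")
  if (m == 1L)
    return(data.frame(marker = markers, index = 1L, cM = 0))
  D <- rf[markers, markers, drop = FALSE]
  D[is.na(D)] <- 0.5
  if (m > 2L && all(D[upper.tri(D)] >= 0.4999))
    warning("group is disconnected (all r ~ 0.5); order is arbitrary")
  if (m == 2L) {
    path <- c(1L, 2L)
  } else {
    ## greedy seeding from the tightest pair
    Dseed <- D; Dseed[lower.tri(Dseed, diag = TRUE)] <- Inf
    seed <- which(Dseed == min(Dseed), arr.ind = TRUE)[1L, ]
    path <- as.integer(seed)
    remaining <- setdiff(seq_len(m), path)
    while (length(remaining)) {
      dHead <- D[path[1L], remaining]
      dTail <- D[path[length(path)], remaining]
      if (min(dHead) <= min(dTail)) {
        k <- remaining[which.min(dHead)]; path <- c(k, path)
      } else {
        k <- remaining[which.min(dTail)]; path <- c(path, k)
      }
      remaining <- setdiff(remaining, path)
    }
    ## 2-opt refinement on the path objective
    repeat {
      improved <- FALSE
      for (i in seq_len(m - 1L)) {
        for (j in seq(i + 1L, m)) {
          delta <- 0
          if (i > 1L) delta <- delta + D[path[i - 1L], path[j]] - D[path[i - 1L], path[i]]
          if (j < m) delta <- delta + D[path[i], path[j + 1L]] - D[path[j], path[j + 1L]]
          if (delta < -1e-12) {
            path[i:j] <- rev(path[i:j])
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  ordered <- markers[path]
  if (ordered[length(ordered)] < ordered[1L]) ordered <- rev(ordered)
  rAdj <- D[cbind(match(ordered[-length(ordered)], markers),
                  match(ordered[-1L], markers))]
  rAdj <- pmin(rAdj, 0.4999)  # keep distances finite across weak adjacencies
  data.frame(marker = ordered, index = seq_along(ordered),
             cM = cumsum(c(0, mapDistance(rAdj, mappingFunction))))
}

#' Build a genetic linkage map from an F2 genotype matrix
#'
#' Full mapping pipeline: missingness filtering (individuals then markers),
#' Z-marker classification, the autosomal F1-heterozygosity filter,
#' backcross recoding of Z markers, per-marker segregation chi-square
#' (reported; optionally a filter), all-pairs two-point estimation (F2
#' model for autosomes, backcross model for Z), single-linkage grouping at
#' the LOD threshold, and per-group ordering with cumulative cM. Autosomal
#' groups are named `LG01`, `LG02`, ... by decreasing marker count; Z
#' groups `LGZ1`, ....
#'
#' @param gm A [GenotypeMatrix-class].
#' @param lodThreshold Grouping LOD threshold (default 3).
#' @param mappingFunction `"kosambi"` (default) or `"haldane"`.
#' @param maxMissing Missingness limit passed to [filterMissingness()].
#' @param dropDistorted Drop markers failing the segregation test at
#'   Bonferroni-adjusted `distortedAlpha` (default: report only).
#' @param distortedAlpha Nominal alpha for the distortion filter.
#' @return A [GeneticMap-class].
#' @export
buildGeneticMap <- function(gm, lodThreshold = 3,
                            mappingFunction = c("kosambi", "haldane"),
                            maxMissing = 0.20, dropDistorted = FALSE,
                            distortedAlpha = 0.01) {
  mappingFunction <- match.arg(mappingFunction)
  gm <- filterMissingness(gm, maxMissing)
  z <- classifyZMarkers(gm)
  zMarkers <- names(z)[z]
  gmA <- filterAutosomal(gm, markers = names(z)[!z])
  segA <- if (nrow(genotypeCalls(gmA)))
    segregationTest(gmA, "f2") else NULL
  gmZ <- if (length(zMarkers)) convertZToBackcross(gm, zMarkers) else NULL
  segZ <- if (!is.null(gmZ)) segregationTest(gmZ, "backcross") else NULL
  seg <- rbind(
    if (!is.null(segA)) cbind(segA, model = "f2"),
    if (!is.null(segZ)) cbind(segZ, model = "backcross"))
  if (dropDistorted && !is.null(seg)) {
    cut <- distortedAlpha / nrow(seg)  # Bonferroni across markers
    bad <- seg$marker[!is.na(seg$p) & seg$p < cut]
    if (length(bad)) {
      if (!is.null(gmA)) gmA <- gmA[setdiff(rownames(genotypeCalls(gmA)), bad), ]
      if (!is.null(gmZ)) gmZ <- gmZ[setdiff(rownames(genotypeCalls(gmZ)), bad), ]
    }
  }
  mapClass <- function(gmc, model, prefix) {
    if (is.null(gmc) || !nrow(genotypeCalls(gmc))) return(NULL)
    tp <- pairwiseRf(gmc, model)
    if (nrow(tp$r) == 1L) {
      grp <- setNames(1L, rownames(tp$r))
    } else grp <- groupMarkers(tp$lod, lodThreshold)
    sizes <- table(grp)
    rank <- setNames(rank(-as.vector(sizes), ties.method = "first"),
                     names(sizes))
    out <- lapply(names(sizes), function(g) {
      mk <- names(grp)[grp == as.integer(g)]
      ord <- orderMarkers(mk, tp$r, mappingFunction)
      ord$group <- sprintf("%s%02d", prefix, rank[[g]])
      ord
    })
    do.call(rbind, out)
  }
  tabA <- mapClass(gmA, "f2", "LG")
  tabZ <- mapClass(gmZ, "backcross", "LGZ")
  tab <- rbind(tabA, tabZ)
  if (is.null(tab)) stop("no markers survived filtering")
  tab <- tab[, c("marker", "group", "index", "cM")]
  rownames(tab) <- NULL
  new("GeneticMap", table = tab, mappingFunction = mappingFunction,
      lodThreshold = lodThreshold,
      segregation = if (is.null(seg)) data.frame() else seg)
}

#' Join a genetic map with marker physical positions
#'
#' Builds the marker assignment table used by chimera detection and contig
#' anchoring: one row per mapped marker with its contig, physical position,
#' linkage group and cM.
#'
#' @param map A [GeneticMap-class].
#' @param gm The [GenotypeMatrix-class] carrying `markerInfo`.
#' @return `data.frame` with columns `marker`, `contig`, `position`,
#'   `group`, `cM`.
#' @export
markerAssignments <- function(map, gm) {
  tb <- mapTable(map)
  mi <- markerInfo(gm)
  data.frame(marker = tb$marker,
             contig = mi[tb$marker, "contig"],
             position = mi[tb$marker, "position"],
             group = tb$group, cM = tb$cM,
             stringsAsFactors = FALSE, row.names = NULL)
}
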