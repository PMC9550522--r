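#' Dataset-level summary of a polyXY scan
#'
#' Computes the headline numbers of a scanned dataset: protein and residue
#' counts, region counts, regions per protein, the fraction of all residues
#' that lie inside polyXY regions (overlapping regions of different pairs
#' count their residues once per region), mean region length and the three
#' category fractions.
#'
#' @param proteins the scanned proteins (named character or
#'   \code{AAStringSet}).
#' @param regions the classified \linkS4class{PolyXYRegions} produced from
#'   exactly these proteins.
#' @return a one-row data.frame with columns nProteins, nResidues, nRegions,
#'   regionsPerProtein, regionResidueRatio, meanRegionLength, fracDirepeat,
#'   fracJoined, fracShuffled.
#' @export
summarizeDataset <- function(proteins, regions) {
  seqs <- .asSequences(proteins)
  if (length(seqs) == 0L) stop("no proteins supplied")
  nP <- length(seqs)
  nAA <- sum(nchar(seqs))
  nR <- nrow(regions)
  lens <- regionLength(regions)
  catTab <- table(factor(regions$category, levels = .CATEGORIES))
  fr <- if (nR > 0L) as.numeric(catTab) / nR else c(0, 0, 0)
  data.frame(nProteins = nP, nResidues = nAA, nRegions = nR,
             regionsPerProtein = nR / nP,
             regionResidueRatio = sum(lens) / nAA,
             meanRegionLength = if (nR > 0L) mean(lens) else 0,
             fracDirepeat = fr[1L], fracJoined = fr[2L], fracShuffled = fr[3L])
}

#' Amino-acid usage in polyXY regions versus background
#'
#' For each of the 20 standard amino acids, the background frequency over all
#' protein residues and the fraction of regions whose pair contains the amino
#' acid. Each region is counted once per pair member, so the region fractions
#' sum to 2 across the alphabet.
#'
#' @inheritParams summarizeDataset
#' @return a 20-row data.frame with columns aa, backgroundFreq,
#'   regionFraction.
#' @export
compositionUsage <- function(proteins, regions) {
  seqs <- .asSequences(proteins)
  allChars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  allChars <- allChars[allChars %in% .STANDARD_AA]
  bg <- table(factor(allChars, levels = .STANDARD_AA))
  bg <- as.numeric(bg) / sum(bg)
  nR <- nrow(regions)
  memberCounts <- vapply(.STANDARD_AA, function(a)
    sum(grepl(a, regions$pair, fixed = TRUE)), numeric(1))
  data.frame(aa = .STANDARD_AA, backgroundFreq = bg,
             regionFraction = if (nR > 0L) memberCounts / nR else
               rep(0, length(.STANDARD_AA)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative positions of regions within their proteins
#'
#' The relative position of a region is its midpoint \code{(start + end)/2}
#' divided by the protein length, a value strictly between 0 and 1.
#'
#' @param regions a \linkS4class{PolyXYRegions} object.
#' @param proteins the proteins the regions live on.
#' @return numeric vector of relative positions, one per region.
#' @export
positionProfiles <- function(regions, proteins) {
  seqs <- .asSequences(proteins)
  missing <- setdiff(unique(regions$proteinId), names(seqs))
  if (length(missing))
    stop("regions refer to proteins not supplied: ",
         paste(missing, collapse = ", "))
  L <- nchar(seqs)[regions$proteinId]
  unname((regions$start + regions$end) / 2 / L)
}

#' Compare two relative-position samples
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test between two samples of
#' relative positions, e.g. joined polyXY versus joined polyYX of the same
#' pair. Exact for small untied samples, normal approximation with tie
#' correction otherwise (the \code{stats::wilcox.test} default).
#'
#' @param positionsA,positionsB numeric vectors of relative positions.
#' @return a list with \code{U}, \code{p}, \code{n1}, \code{n2}.
#' @export
compareOrderPositions <- function(positionsA, positionsB) {
  if (length(positionsA) == 0L || length(positionsB) == 0L)
    stop("both position samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(positionsA, positionsB,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(positionsA), n2 = length(positionsB))
}

#' Distribution of direpeat unit counts
#'
#' Histogram of direpeat repeat numbers over the bins 3, 4, 5, 6 and >6
#' units, plus the fraction of direpeats with more than 3 units.
#'
#' @param regions a \linkS4class{PolyXYRegions} object containing only
#'   direpeats (subset with \code{\link{applyFilters}}), or an integer vector
#'   of unit counts.
#' @return a list with \code{counts} (named integer vector over the five
#'   bins), \code{n} and \code{fractionAbove3}.
#' @export
unitDistribution <- function(regions) {
  if (is.numeric(regions)) {
    units <- as.integer(regions)
  } else {
    if (nrow(regions) && any(regions$category != "direpeat"))
      stop("unitDistribution() expects direpeats only")
    units <- regions$nUnits
  }
  if (anyNA(units)) stop("missing unit counts")
  bins <- cut(units, breaks = c(2.5, 3.5, 4.5, 5.5, 6.5, Inf),
              labels = c("3", "4", "5", "6", ">6"))
  if (anyNA(bins)) stop("unit counts below 3 are impossible for direpeats")
  counts <- table(bins)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n = length(units),
       fractionAbove3 = if (length(units)) mean(units > 3L) else 0)
}

#' Joined-order counts
#'
#' Counts joined regions by their observed run order, e.g. \code{"VG"} for a
#' polyV run followed by a polyG run. The asymmetry between \code{"XY"} and
#' \code{"YX"} counts of the same pair is the joined-order asymmetry.
#'
#' @param regions a \linkS4class{PolyXYRegions} object; non-joined rows are
#'   ignored.
#' @return a data.frame with columns order, pair, count, sorted by
#'   decreasing count then order.
#' @export
joinedOrderCounts <- function(regions) {
  j <- regions[!is.na(regions$category) & regions$category == "joined", ,
               drop = FALSE]
  if (nrow(j) == 0L)
    return(data.frame(order = character(), pair = character(),
                      count = integer(), stringsAsFactors = FALSE))
  tab <- table(j$joinedOrder)
  ord <- names(tab)
  pairKey <- vapply(strsplit(ord, "", fixed = TRUE), function(x)
    paste(sort(x), collapse = ""), character(1))
  out <- data.frame(order = ord, pair = pairKey, count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$order), , drop = FALSE]
}
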