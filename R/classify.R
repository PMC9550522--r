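## Category logic. A pure polyXY region (exactly two residue types, each >= 2)
## falls in exactly one of three categories:
##   direpeat — a perfect 'XY' tandem repeat, allowing one lone X or Y at a
##              terminus or between units ("GLGLGLG", "GLGLLGL");
##   joined   — a polyX run immediately followed by a polyY run ("VVVGGG");
##   shuffled — everything else.
## Merged regions (mergeGap > 0) carry residues outside their pair and are
## always shuffled.

.runLengths <- function(chars) rle(chars)$lengths

## Direpeat test on the character vector of a pure two-type region.
## Equivalent to: the string equals (XY)^k, or (XY)^k with one extra X or Y
## inserted at a unit boundary or terminus. Operationally: no adjacent-equal
## position (perfect alternation; odd length means one lone terminal residue),
## or exactly one adjacent-equal position with odd total length (deleting one
## member of the equal pair leaves an even-length perfect tandem).
.isDirepeat <- function(chars) {
  n <- length(chars)
  defects <- sum(chars[-1L] == chars[-n])
  defects == 0L || (defects == 1L && n %% 2L == 1L)
}

.isJoined <- function(chars) {
  r <- .runLengths(chars)
  length(r) == 2L && all(r >= 2L)
}

#' Classify one region sequence
#'
#' Assigns a polyXY region to exactly one category: \code{direpeat} (tested
#' first), \code{joined}, or \code{shuffled} (the default). A sequence
#' containing residues outside its two-type pair — which only arises from
#' merged regions — is always shuffled.
#'
#' @param sequence the region sequence (a single string).
#' @param pair optional two-letter pair; defaults to the two residue types of
#'   \code{sequence}.
#' @return a list with \code{category}, \code{pair} (alphabetical),
#'   \code{nUnits} (direpeats, otherwise \code{NA}) and \code{joinedOrder}
#'   (joined, otherwise \code{NA}).
#' @examples
#' classifyRegion("VVVGGG")    # joined, order "VG"
#' classifyRegion("SRSRSR")    # direpeat, 3 units
#' classifyRegion("SSGGSGG")   # shuffled
#' @export
classifyRegion <- function(sequence, pair = NULL) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  types <- sort(unique(chars))
  if (is.null(pair)) {
    pair <- paste(types, collapse = "")
  } else {
    pair <- paste(sort(unlist(strsplit(toupper(pair), "", fixed = TRUE))),
                  collapse = "")
  }
  pure <- identical(paste(types, collapse = ""), pair) && length(types) == 2L
  if (pure && .isDirepeat(chars)) {
    list(category = "direpeat", pair = pair,
         nUnits = countDirepeatUnits(sequence), joinedOrder = NA_character_)
  } else if (pure && .isJoined(chars)) {
    list(category = "joined", pair = pair, nUnits = NA_integer_,
         joinedOrder = paste0(chars[1L], chars[length(chars)]))
  } else {
    list(category = "shuffled", pair = pair, nUnits = NA_integer_,
         joinedOrder = NA_character_)
  }
}

#' Classify all regions of a scan
#'
#' Applies \code{\link{classifyRegion}} to every region, filling the
#' \code{category}, \code{nUnits} and \code{joinedOrder} columns.
#'
#' @param regions a \linkS4class{PolyXYRegions} object.
#' @return the same object with classification columns set.
#' @export
classifyRegions <- function(regions) {
  if (nrow(regions) == 0L) return(regions)
  cls <- lapply(seq_len(nrow(regions)), function(i)
    classifyRegion(regions$sequence[i], regions$pair[i]))
  .withRegionCols(regions,
    category = vapply(cls, `[[`, character(1), "category"),
    nUnits = vapply(cls, `[[`, integer(1), "nUnits"),
    joinedOrder = vapply(cls, `[[`, character(1), "joinedOrder"))
}

#' Count repeated units of a direpeat
#'
#' Returns the number of complete two-residue 'XY' units. The single allowed
#' lone residue (the "adjacent half unit") does not count as a unit, so both
#' \code{"GLGLGL"} and \code{"GLGLGLG"} have 3 units.
#'
#' @param sequence a direpeat region sequence.
#' @return integer unit count.
#' @export
countDirepeatUnits <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!.isDirepeat(chars))
    stop("countDirepeatUnits() called on a non-direpeat sequence")
  length(chars) %/% 2L
}

#' Find joined/direpeat patterns embedded in shuffled regions
#'
#' Long shuffled regions can contain sub-spans that would qualify on their own
#' as joined or direpeat polyXY. For every shuffled region this enumerates all
#' sub-spans of at least \code{window} residues composed solely of the
#' region's pair and tests each against the two pattern definitions.
#'
#' @param regions a classified \linkS4class{PolyXYRegions} object, or a single
#'   region sequence string.
#' @param window minimum embedded-pattern length; defaults to the scan window
#'   recorded in the object metadata (6 for a bare string).
#' @return for a string: a list with \code{containsJoined} and
#'   \code{containsDirepeat}. For a regions object: the object with logical
#'   columns \code{containsJoined}/\code{containsDirepeat} added (\code{NA}
#'   for non-shuffled regions).
#' @examples
#' findEmbeddedPatterns("AAGGGAAA")   # contains a joined "GGGAAA"
#' @export
findEmbeddedPatterns <- function(regions, window = NULL) {
  if (is.character(regions) && length(regions) == 1L) {
    if (is.null(window)) window <- 6L
    return(.embedded(regions, as.integer(window)))
  }
  if (is.null(window))
    window <- S4Vectors::metadata(regions)$window %||% 6L
  cj <- cd <- rep(NA, nrow(regions))
  idx <- which(regions$category == "shuffled")
  for (i in idx) {
    e <- .embedded(regions$sequence[i], as.integer(window),
                   pair = regions$pair[i])
    cj[i] <- e$containsJoined
    cd[i] <- e$containsDirepeat
  }
  .withRegionCols(regions, containsJoined = cj, containsDirepeat = cd)
}

.embedded <- function(sequence, window, pair = NULL) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (is.null(pair)) {
    pairChars <- sort(unique(chars))
  } else {
    pairChars <- sort(unlist(strsplit(pair, "", fixed = TRUE)))
  }
  inPair <- chars %in% pairChars
  foundJ <- foundD <- FALSE
  for (a in seq_len(max(0L, n - window + 1L))) {
    if (foundJ && foundD) break
    for (b in seq(a + window - 1L, n)) {
      sub <- chars[a:b]
      if (!all(inPair[a:b])) next
      if (length(unique(sub)) != 2L || min(table(sub)) < 2L) next
      if (!foundD && .isDirepeat(sub)) foundD <- TRUE
      if (!foundJ && .isJoined(sub)) foundJ <- TRUE
      if (foundJ && foundD) break
    }
  }
  list(containsJoined = foundJ, containsDirepeat = foundD)
}
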