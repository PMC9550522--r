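#' @importClassesFrom S4Vectors DFrame
#' @import methods
NULL

.CATEGORIES <- c("direpeat", "joined", "shuffled")

.STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Scan parameters for polyXY detection
#'
#' Holds the tunable parameters of a polyXY scan: the sliding-window length
#' (which doubles as the minimum reportable region length), the merge gap for
#' joining close same-pair regions, and the optional post-classification
#' filters.
#'
#' @slot window integer(1), window length in residues; must be >= 4 (below 4
#'   no window can hold two residue types each twice). Default 6.
#' @slot mergeGap integer(1) in 0, 1, 2; regions of the same amino-acid pair
#'   separated by at most this many non-pair residues are merged. Default 0
#'   (no merging).
#' @slot pairFilter character; \code{NA} (no filter), a single residue
#'   (keep regions whose pair contains it: the "any X, specific Y" filter) or
#'   two residues (keep only that unordered pair).
#' @slot categoryFilter character; subset of \code{"direpeat"},
#'   \code{"joined"}, \code{"shuffled"}, or \code{NA} for no filter.
#' @slot minUnits integer(1) or \code{NA}; when set, keep only direpeats with
#'   at least this many repeated units.
#'
#' @examples
#' ScanParams()
#' ScanParams(window = 8L, mergeGap = 1L)
#' @export
setClass("ScanParams",
  representation(window = "integer", mergeGap = "integer",
                 pairFilter = "character", categoryFilter = "character",
                 minUnits = "integer"),
  prototype(window = 6L, mergeGap = 0L, pairFilter = NA_character_,
            categoryFilter = NA_character_, minUnits = NA_integer_))

setValidity("ScanParams", function(object) {
  msg <- character()
  if (length(object@window) != 1L || is.na(object@window) ||
      object@window < 4L)
    msg <- c(msg, "'window' must be a single integer >= 4")
  if (length(object@mergeGap) != 1L || is.na(object@mergeGap) ||
      !(object@mergeGap %in% 0:2))
    msg <- c(msg, "'mergeGap' must be 0, 1 or 2")
  pf <- object@pairFilter
  if (!all(is.na(pf))) {
    if (length(pf) > 2L || !all(pf %in% .STANDARD_AA))
      msg <- c(msg, "'pairFilter' must be 1 or 2 standard amino acids")
  }
  cf <- object@categoryFilter
  if (!all(is.na(cf)) && !all(cf %in% .CATEGORIES))
    msg <- c(msg, "'categoryFilter' must be a subset of direpeat/joined/shuffled")
  mu <- object@minUnits
  if (!is.na(mu) && mu < 3L)
    msg <- c(msg, "'minUnits' must be >= 3 (no shorter direpeat is reportable)")
  if (length(msg)) msg else TRUE
})

#' @param window,mergeGap,pairFilter,categoryFilter,minUnits see slot
#'   documentation above.
#' @rdname ScanParams-class
#' @export
ScanParams <- function(window = 6L, mergeGap = 0L, pairFilter = NA,
                       categoryFilter = NA, minUnits = NA) {
  new("ScanParams",
      window = as.integer(window), mergeGap = as.integer(mergeGap),
      pairFilter = toupper(as.character(pairFilter)),
      categoryFilter = as.character(categoryFilter),
      minUnits = as.integer(minUnits))
}

setMethod("show", "ScanParams", function(object) {
  cat("ScanParams: window =", object@window,
      "| mergeGap =", object@mergeGap, "\n")
  if (!all(is.na(object@pairFilter)))
    cat("  pair filter:", paste(object@pairFilter, collapse = "/"), "\n")
  if (!all(is.na(object@categoryFilter)))
    cat("  category filter:", paste(object@categoryFilter, collapse = ", "), "\n")
  if (!is.na(object@minUnits))
    cat("  min direpeat units:", object@minUnits, "\n")
})

.REGION_COLS <- c("proteinId", "start", "end", "pair", "sequence", "category",
                  "nUnits", "joinedOrder")

#' Detected polyXY regions
#'
#' A table of detected (and usually classified) polyXY regions, one row per
#' region, implemented as an \linkS4class{DFrame} extension so all the usual
#' \code{DataFrame} operations apply. Coordinates are 1-based and inclusive on
#' both ends. The \code{pair} column gives the two residue types in
#' alphabetical order (e.g. \code{"GS"}); \code{joinedOrder} records the order
#' actually observed for joined regions (e.g. \code{"VG"} for a polyV run
#' followed by a polyG run).
#'
#' Columns: \code{proteinId}, \code{start}, \code{end}, \code{pair},
#' \code{sequence}, \code{category} (\code{"direpeat"}, \code{"joined"},
#' \code{"shuffled"}, or \code{NA} before classification), \code{nUnits}
#' (direpeats only), \code{joinedOrder} (joined only). The scan window and
#' merge gap used are kept in \code{metadata()}.
#'
#' @aliases PolyXYRegions-class
#' @export
setClass("PolyXYRegions", contains = "DFrame")

setValidity("PolyXYRegions", function(object) {
  msg <- character()
  missing <- setdiff(.REGION_COLS, colnames(object))
  if (length(missing))
    return(paste("missing region columns:", paste(missing, collapse = ", ")))
  if (nrow(object)) {
    if (any(object$start < 1L) || any(object$end < object$start))
      msg <- c(msg, "need 1 <= start <= end for every region")
    if (any(nchar(object$pair) != 2L))
      msg <- c(msg, "'pair' must be two letters")
    bad <- !is.na(object$category) & !(object$category %in% .CATEGORIES)
    if (any(bad))
      msg <- c(msg, "unknown category value")
    if (any(nchar(object$sequence) != object$end - object$start + 1L))
      msg <- c(msg, "'sequence' length must equal end - start + 1")
  }
  if (length(msg)) msg else TRUE
})

#' @param df a data.frame or DataFrame with the region columns.
#' @param window,mergeGap scan parameters recorded in the object metadata.
#' @rdname PolyXYRegions-class
#' @export
PolyXYRegions <- function(df = NULL, window = 6L, mergeGap = 0L) {
  if (is.null(df))
    df <- data.frame(proteinId = character(), start = integer(),
                     end = integer(), pair = character(),
                     sequence = character(), category = character(),
                     nUnits = integer(), joinedOrder = character(),
                     stringsAsFactors = FALSE)
  dd <- S4Vectors::DataFrame(df)
  for (cc in setdiff(.REGION_COLS, colnames(dd)))
    dd[[cc]] <- switch(cc, nUnits = rep(NA_integer_, nrow(dd)),
                       rep(NA_character_, nrow(dd)))
  dd <- dd[, c(.REGION_COLS, setdiff(colnames(dd), .REGION_COLS)), drop = FALSE]
  dd$start <- as.integer(dd$start)
  dd$end <- as.integer(dd$end)
  dd$nUnits <- as.integer(dd$nUnits)
  out <- new("PolyXYRegions", dd)
  S4Vectors::metadata(out) <- list(window = as.integer(window),
                                   mergeGap = as.integer(mergeGap))
  out
}

setMethod("show", "PolyXYRegions", function(object) {
  md <- S4Vectors::metadata(object)
  cat("PolyXYRegions with", nrow(object), "regions",
      sprintf("(window = %s, mergeGap = %s)\n",
              md$window %||% "?", md$mergeGap %||% "?"))
  if (nrow(object)) {
    tab <- table(factor(object$category, levels = .CATEGORIES))
    cat(" ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                   collapse = " | "), "\n")
  }
  callNextMethod()
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## Rebuild a PolyXYRegions with some columns replaced (column assignment on
## a DFrame subclass does not route through the constructor).
.withRegionCols <- function(regions, ...) {
  md <- S4Vectors::metadata(regions)
  df <- as.data.frame(regions)
  upd <- list(...)
  for (nm in names(upd)) df[[nm]] <- upd[[nm]]
  out <- PolyXYRegions(df, window = md$window %||% 6L,
                       mergeGap = md$mergeGap %||% 0L)
  S4Vectors::metadata(out) <- md
  out
}

#' Accessors for PolyXYRegions columns
#'
#' @param x a \linkS4class{PolyXYRegions} object.
#' @return the corresponding per-region vector.
#' @name region-accessors
NULL

#' @rdname region-accessors
#' @export
regionPair <- function(x) x$pair

#' @rdname region-accessors
#' @export
regionCategory <- function(x) x$category

#' @rdname region-accessors
#' @export
regionLength <- function(x) x$end - x$start + 1L

#' @rdname region-accessors
#' @export
nUnits <- function(x) x$nUnits

#' @rdname region-accessors
#' @export
joinedOrder <- function(x) x$joinedOrder
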