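#' Test a single window for polyXY composition
#'
#' A window is part of a polyXY region when it contains exactly two distinct
#' residue types and each occurs at least twice. Any character outside the 20
#' standard amino acids (ambiguity codes such as B, J, O, U, X, Z, the stop
#' \code{*}, gaps) makes the window negative: an ambiguity code is not a bona
#' fide composition.
#'
#' @param windowSeq a single string; its length defines the window.
#' @return \code{FALSE} for a negative window, otherwise the unordered pair as
#'   a two-letter string in alphabetical order (e.g. \code{"GV"}).
#' @examples
#' windowIsPositive("VVVGGG")  # "GV"
#' windowIsPositive("AAAAAG")  # FALSE: second type occurs once
#' @export
windowIsPositive <- function(windowSeq) {
  stopifnot(is.character(windowSeq), length(windowSeq) == 1L)
  chars <- strsplit(toupper(windowSeq), "", fixed = TRUE)[[1]]
  if (!all(chars %in% .STANDARD_AA)) return(FALSE)
  tab <- table(chars)
  if (length(tab) != 2L || any(tab < 2L)) return(FALSE)
  paste(sort(names(tab)), collapse = "")
}

.asSequences <- function(proteins) {
  if (is(proteins, "XStringSet")) {
    seqs <- toupper(as.character(proteins))
    names(seqs) <- names(proteins)
  } else {
    seqs <- toupper(as.character(proteins))
    names(seqs) <- names(proteins)
    if (length(seqs) &&
        (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")))
      stop("protein sequences must be named (FASTA ids)")
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

## Merge overlapping (>= 1 shared position) positive windows of one pair.
## `starts` are sorted 1-based window starts; returns matrix of start/end.
.unionWindows <- function(starts, window) {
  ends <- starts + window - 1L
  keepStart <- integer(0)
  keepEnd <- integer(0)
  cs <- starts[1L]
  ce <- ends[1L]
  if (length(starts) > 1L) {
    for (i in 2L:length(starts)) {
      if (starts[i] <= ce) {           # strict overlap, not mere adjacency
        ce <- max(ce, ends[i])
      } else {
        keepStart <- c(keepStart, cs); keepEnd <- c(keepEnd, ce)
        cs <- starts[i]; ce <- ends[i]
      }
    }
  }
  cbind(start = c(keepStart, cs), end = c(keepEnd, ce))
}

#' Detect maximal polyXY regions
#'
#' Slides a window of \code{window} residues along every protein, marks
#' positive windows (see \code{\link{windowIsPositive}}) and unions
#' overlapping positive windows of the same unordered amino-acid pair into
#' maximal regions. Windows of different pairs never merge, so regions of
#' different pairs may overlap each other. Returned regions are unclassified
#' (\code{category} is \code{NA}); see \code{\link{classifyRegions}} or the
#' one-stop \code{\link{scanProteins}}.
#'
#' @param proteins a named character vector or \code{AAStringSet}.
#' @param window integer window length (and minimum region length), >= 4.
#' @return a \linkS4class{PolyXYRegions} object sorted by protein (input
#'   order), start, end, pair.
#' @examples
#' detectRegions(c(SMN_like = "MAMSSGGSGGGVPEQ"))
#' @export
detectRegions <- function(proteins, window = 6L) {
  window <- as.integer(window)
  if (window < 4L) stop("'window' must be >= 4")
  seqs <- .asSequences(proteins)
  rows <- vector("list", length(seqs))
  for (p in seq_along(seqs)) {
    s <- seqs[[p]]
    hits <- .scanWindowsC(s, window)
    if (nrow(hits) == 0L) next
    pairKey <- paste0(intToUtf8(hits[, 2L], multiple = TRUE),
                      intToUtf8(hits[, 3L], multiple = TRUE))
    perPair <- split(hits[, 1L], pairKey)
    spans <- lapply(names(perPair), function(pk) {
      m <- .unionWindows(sort(perPair[[pk]]), window)
      data.frame(proteinId = names(seqs)[p], start = m[, "start"],
                 end = m[, "end"], pair = pk, stringsAsFactors = FALSE)
    })
    rows[[p]] <- do.call(rbind, spans)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) return(PolyXYRegions(window = window))
  df$sequence <- substr(rep(seqs[df$proteinId], 1L), df$start, df$end)
  df <- df[order(match(df$proteinId, names(seqs)), df$start, df$end, df$pair), ,
           drop = FALSE]
  rownames(df) <- NULL
  PolyXYRegions(df, window = window, mergeGap = 0L)
}

#' Merge close same-pair regions
#'
#' Replaces two regions of the same amino-acid pair whose intervening gap is
#' at most \code{mergeGap} residues (necessarily residues outside the pair,
#' otherwise the detector would already have joined them) with one region
#' spanning both. Merging is applied transitively left-to-right; regions of
#' different pairs are never merged. Merged regions contain residues outside
#' their pair and are therefore categorized as shuffled on classification.
#'
#' @param regions a \linkS4class{PolyXYRegions} object from
#'   \code{\link{detectRegions}}.
#' @param proteins the same proteins the regions were detected on.
#' @param mergeGap 1 or 2.
#' @return a \linkS4class{PolyXYRegions} object; classification columns reset.
#' @export
mergeCloseRegions <- function(regions, proteins, mergeGap) {
  mergeGap <- as.integer(mergeGap)
  if (!(mergeGap %in% 1:2)) stop("'mergeGap' must be 1 or 2")
  seqs <- .asSequences(proteins)
  df <- as.data.frame(regions)[, c("proteinId", "start", "end", "pair")]
  if (nrow(df) == 0L)
    return(PolyXYRegions(window = S4Vectors::metadata(regions)$window,
                         mergeGap = mergeGap))
  out <- lapply(split(df, list(df$proteinId, df$pair), drop = TRUE),
    function(g) {
      g <- g[order(g$start), , drop = FALSE]
      i <- 1L
      while (i < nrow(g)) {
        gap <- g$start[i + 1L] - g$end[i] - 1L
        if (gap <= mergeGap) {
          g$end[i] <- g$end[i + 1L]
          g <- g[-(i + 1L), , drop = FALSE]
        } else i <- i + 1L
      }
      g
    })
  df <- do.call(rbind, out)
  df$sequence <- substr(seqs[df$proteinId], df$start, df$end)
  df <- df[order(match(df$proteinId, names(seqs)), df$start, df$end, df$pair), ,
           drop = FALSE]
  rownames(df) <- NULL
  PolyXYRegions(df, window = S4Vectors::metadata(regions)$window,
                mergeGap = mergeGap)
}

#' Filter classified regions
#'
#' Applies the search filters of the scan: a specific unordered pair, an
#' "any X, specific Y" single-residue filter, a category subset, and a
#' minimum direpeat unit count (which drops all non-direpeats when set).
#'
#' @param regions a classified \linkS4class{PolyXYRegions} object.
#' @param pair two residues (e.g. \code{c("G","V")} or \code{"GV"}): keep only
#'   this unordered pair.
#' @param anyWith one residue: keep regions whose pair contains it.
#' @param categories subset of \code{"direpeat"}, \code{"joined"},
#'   \code{"shuffled"}.
#' @param minUnits integer: keep only direpeats with at least this many units.
#' @return the filtered \linkS4class{PolyXYRegions}.
#' @export
applyFilters <- function(regions, pair = NULL, anyWith = NULL,
                         categories = NULL, minUnits = NULL) {
  keep <- rep(TRUE, nrow(regions))
  if (!is.null(pair)) {
    p <- toupper(unlist(strsplit(pair, "", fixed = TRUE)))
    if (length(p) != 2L) stop("'pair' must name exactly two residues")
    keep <- keep & regions$pair == paste(sort(p), collapse = "")
  }
  if (!is.null(anyWith)) {
    a <- toupper(anyWith)
    if (nchar(a) != 1L) stop("'anyWith' must be a single residue")
    keep <- keep & grepl(a, regions$pair, fixed = TRUE)
  }
  if (!is.null(categories))
    keep <- keep & regions$category %in% categories
  if (!is.null(minUnits))
    keep <- keep & !is.na(regions$nUnits) & regions$nUnits >= minUnits
  regions[keep, , drop = FALSE]
}

#' Scan proteins for polyXY regions
#'
#' The one-stop entry point: detect maximal polyXY regions, optionally merge
#' close same-pair regions, classify every region as direpeat, joined or
#' shuffled, and apply any filters in \code{params}.
#'
#' @param proteins a named character vector or \code{AAStringSet} (see
#'   \code{\link{readProteome}}).
#' @param params a \linkS4class{ScanParams} object.
#' @return a classified \linkS4class{PolyXYRegions} object.
#' @examples
#' scanProteins(c(p1 = "MAMSSGGSGGGVPEQ", p2 = "KKVVVGGGKK"))
#' @export
scanProteins <- function(proteins, params = ScanParams()) {
  stopifnot(is(params, "ScanParams"))
  validObject(params)
  regions <- detectRegions(proteins, window = params@window)
  if (params@mergeGap > 0L && nrow(regions) > 0L)
    regions <- mergeCloseRegions(regions, proteins, params@mergeGap)
  regions <- classifyRegions(regions)
  pf <- params@pairFilter
  pairArg <- if (sum(!is.na(pf)) == 2L) paste(pf, collapse = "") else NULL
  anyArg <- if (sum(!is.na(pf)) == 1L) pf[!is.na(pf)] else NULL
  cf <- params@categoryFilter
  applyFilters(regions,
               pair = pairArg, anyWith = anyArg,
               categories = if (all(is.na(cf))) NULL else cf,
               minUnits = if (is.na(params@minUnits)) NULL else params@minUnits)
}
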