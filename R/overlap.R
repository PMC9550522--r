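#' Test complete containment of a region in annotation intervals
#'
#' A polyXY region "overlaps" a domain or disordered region only when the
#' complete region lies within the annotated interval (boundary-inclusive);
#' partial overlap does not count.
#'
#' @param start,end 1-based inclusive region coordinates (vectors recycle).
#' @param intervals a data.frame of annotation intervals for the same protein
#'   (columns start, end).
#' @return logical: is the region fully contained in some interval?
#' @export
regionContained <- function(start, end, intervals) {
  if (NROW(intervals) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i)
    any(intervals$start <= start[i] & intervals$end >= end[i]), logical(1))
}

#' Random placement of a region within its protein
#'
#' Draws uniformly random start positions for a region of the same length in
#' the same protein, the baseline used to judge observed containment.
#'
#' @param regionLength region length in residues.
#' @param proteinLength protein length; must be >= regionLength.
#' @param n number of placements.
#' @return integer vector of n random 1-based starts in
#'   \code{[1, proteinLength - regionLength + 1]}.
#' @export
randomPlacement <- function(regionLength, proteinLength, n = 1L) {
  if (proteinLength < regionLength)
    stop("protein shorter than region")
  sample.int(proteinLength - regionLength + 1L, n, replace = TRUE)
}

#' Containment of polyXY in domains/disorder versus a random baseline
#'
#' For every region, tests complete containment within domain and within
#' disorder annotations of its protein, and draws \code{nRandom} same-length
#' random placements in the same protein as a baseline. Results are
#' aggregated per amino-acid pair (optionally also per category) and each
#' observed-versus-random contrast is tested with a two-sided Mann-Whitney U
#' test over the per-region values.
#'
#' @param regions a classified \linkS4class{PolyXYRegions} object.
#' @param proteins the proteins the regions were detected on.
#' @param annotations a data.frame from \code{\link{readAnnotations}}.
#' @param nRandom random placements per region (default 1).
#' @param seed integer seed making the report reproducible.
#' @param pairs optional character vector restricting to these pairs (e.g.
#'   the most prevalent ones).
#' @param byCategory also split results by region category.
#' @param annotatedOnly drop regions on proteins without any annotation
#'   record; by default such regions count as not contained.
#' @return a data.frame with one row per pair (x category) x annotation kind:
#'   pair, category, kind, observedFraction, randomFraction, U, p, nRegions,
#'   nRandom, seed.
#' @export
overlapAnalysis <- function(regions, proteins, annotations, nRandom = 1L,
                            seed = 1L, pairs = NULL, byCategory = FALSE,
                            annotatedOnly = FALSE) {
  if (nRandom < 1L) stop("'nRandom' must be >= 1")
  seqs <- .asSequences(proteins)
  df <- as.data.frame(regions)
  if (!is.null(pairs)) df <- df[df$pair %in% pairs, , drop = FALSE]
  if (NROW(annotations) > 0L &&
      !any(unique(df$proteinId) %in% annotations$proteinId))
    stop("no annotated proteins in common with the regions")
  if (annotatedOnly)
    df <- df[df$proteinId %in% annotations$proteinId, , drop = FALSE]
  if (nrow(df) == 0L) stop("no regions to analyse")

  set.seed(as.integer(seed))
  annByProt <- split(annotations, annotations$proteinId)
  kinds <- c("domain", "disorder")
  obs <- matrix(NA, nrow(df), 2L, dimnames = list(NULL, kinds))
  rnd <- matrix(NA_real_, nrow(df), 2L, dimnames = list(NULL, kinds))
  for (i in seq_len(nrow(df))) {
    ann <- annByProt[[df$proteinId[i]]]
    L <- nchar(seqs[[df$proteinId[i]]])
    len <- df$end[i] - df$start[i] + 1L
    starts <- randomPlacement(len, L, nRandom)
    for (k in kinds) {
      iv <- if (is.null(ann)) NULL else ann[ann$kind == k, , drop = FALSE]
      obs[i, k] <- regionContained(df$start[i], df$end[i], iv)
      rnd[i, k] <- mean(regionContained(starts, starts + len - 1L, iv))
    }
  }

  grp <- if (byCategory) paste(df$pair, df$category, sep = "\r") else df$pair
  rows <- list()
  for (g in sort(unique(grp))) {
    sel <- grp == g
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    for (k in kinds) {
      o <- obs[sel, k]
      r <- rnd[sel, k]
      wt <- suppressWarnings(stats::wilcox.test(as.numeric(o), r,
                                                alternative = "two.sided"))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = parts[1L],
        category = if (byCategory) parts[2L] else "all",
        kind = k, observedFraction = mean(o), randomFraction = mean(r),
        U = unname(wt$statistic), p = wt$p.value,
        nRegions = sum(sel), nRandom = nRandom, seed = as.integer(seed),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
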