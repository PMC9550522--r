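#' Reference window-by-window polyXY scanner
#'
#' A deliberately simple scanner that enumerates every window, tests it with
#' \code{\link{windowIsPositive}} and unions overlapping positive windows of
#' the same pair. It shares no code with the optimized scanner behind
#' \code{\link{detectRegions}} and serves two roles: the equivalence reference
#' in the test suite, and the definition of truth tables for synthetic
#' fixtures (accidental background polyXY are part of the truth, never
#' missed).
#'
#' @inheritParams detectRegions
#' @return a classified \linkS4class{PolyXYRegions} object.
#' @export
bruteForceScan <- function(proteins, window = 6L) {
  window <- as.integer(window)
  seqs <- .asSequences(proteins)
  rows <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < window) next
    pairs <- character(0)
    starts <- integer(0)
    for (i in seq_len(L - window + 1L)) {
      p <- windowIsPositive(substr(s, i, i + window - 1L))
      if (!isFALSE(p)) {
        pairs <- c(pairs, p)
        starts <- c(starts, i)
      }
    }
    if (!length(starts)) next
    for (pk in sort(unique(pairs))) {
      ss <- sort(starts[pairs == pk])
      cur <- c(ss[1L], ss[1L] + window - 1L)
      flush <- function(cur)
        data.frame(proteinId = id, start = cur[1L], end = cur[2L], pair = pk,
                   sequence = substr(s, cur[1L], cur[2L]),
                   stringsAsFactors = FALSE)
      for (st in ss[-1L]) {
        if (st <= cur[2L]) {
          cur[2L] <- st + window - 1L
        } else {
          rows[[length(rows) + 1L]] <- flush(cur)
          cur <- c(st, st + window - 1L)
        }
      }
      rows[[length(rows) + 1L]] <- flush(cur)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) return(PolyXYRegions(window = window))
  df <- df[order(match(df$proteinId, names(seqs)), df$start, df$end, df$pair), ,
           drop = FALSE]
  rownames(df) <- NULL
  classifyRegions(PolyXYRegions(df, window = window, mergeGap = 0L))
}

#' Specification of a synthetic fixture proteome
#'
#' Describes a proteome to simulate: background composition, protein count
#' and length range, planted polyXY regions of known pair/category, and an
#' optional annotation plan. Defaults emulate a small generic proteome:
#' uniform background over the 20 standard amino acids and protein lengths
#' of 100 to 400 residues.
#'
#' @param nProteins number of proteins.
#' @param lengthRange integer pair, min/max protein length.
#' @param backgroundFreq named numeric over (a subset of) the 20 standard
#'   amino acids, summing to 1; unnamed residues get 0.
#' @param plants a data.frame with columns \code{pair} (two letters),
#'   \code{category}, and optionally \code{length}, \code{nUnits} (direpeats)
#'   or \code{joinedOrder} (joined). One planted region per row.
#' @param annotationPlan \code{NULL}, or a list with \code{coverPlants}
#'   (\code{"disorder"} or \code{"domain"}: emit one interval of that kind
#'   containing each planted span, padded by \code{pad} residues each side)
#'   and optionally \code{randomDomains} (count of random domain intervals
#'   per protein) and \code{domainLength} (their length).
#' @param seed integer seed.
#' @return a \code{FixtureSpec} list (classed).
#' @export
fixtureSpec <- function(nProteins = 50L, lengthRange = c(100L, 400L),
                        backgroundFreq = NULL, plants = NULL,
                        annotationPlan = NULL, seed = 1L) {
  if (is.null(backgroundFreq)) {
    backgroundFreq <- stats::setNames(rep(1 / 20, 20), .STANDARD_AA)
  } else {
    if (!all(names(backgroundFreq) %in% .STANDARD_AA))
      stop("backgroundFreq names must be standard amino acids")
    if (abs(sum(backgroundFreq) - 1) > 1e-9)
      stop("backgroundFreq must sum to 1")
  }
  if (!is.null(plants)) {
    stopifnot(is.data.frame(plants), "pair" %in% names(plants),
              "category" %in% names(plants))
    if (!all(plants$category %in% .CATEGORIES))
      stop("unknown plant category")
  }
  structure(list(nProteins = as.integer(nProteins),
                 lengthRange = as.integer(lengthRange),
                 backgroundFreq = backgroundFreq,
                 plants = plants, annotationPlan = annotationPlan,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

## Build the planted motif string for one plant row.
.plantSequence <- function(pair, category, plantLength = NA, nUnits = NA,
                           joinedOrder = NA, window = 6L) {
  p <- sort(unlist(strsplit(toupper(pair), "", fixed = TRUE)))
  if (length(p) != 2L) stop("plant pair must be two residues")
  x <- p[1L]; y <- p[2L]
  if (category == "direpeat") {
    k <- if (!is.na(nUnits)) as.integer(nUnits)
         else max(3L, as.integer(ceiling((if (is.na(plantLength)) window
                                          else plantLength) / 2)))
    if (k < 3L) stop("direpeat plants need >= 3 units")
    paste(rep(c(x, y), k), collapse = "")
  } else if (category == "joined") {
    len <- if (is.na(plantLength)) window else as.integer(plantLength)
    if (len < window || len > 2L * (window - 2L))
      stop("joined plant length must be in [window, 2*(window-2)] so runs ",
           "stay short enough for every defining window to be positive")
    a <- len %/% 2L
    b <- len - a
    ord <- if (!is.na(joinedOrder))
      unlist(strsplit(toupper(joinedOrder), "", fixed = TRUE)) else c(x, y)
    if (!setequal(ord, p)) stop("joinedOrder letters must match the pair")
    paste0(strrep(ord[1L], a), strrep(ord[2L], b))
  } else {
    len <- if (is.na(plantLength)) max(window, 8L) else as.integer(plantLength)
    if (len < window) stop("shuffled plants must be at least window long")
    # period-4 'XXYY' pattern: every window holds both residues >= 2 and the
    # result is neither alternating nor two runs
    substr(strrep(paste0(x, x, y, y), ceiling(len / 4) + 1L), 1L, len)
  }
}

#' Generate a synthetic fixture proteome with oracle-defined truth
#'
#' Draws background residues from the spec's composition, inserts each
#' planted polyXY with guard flanks of two distinct non-pair residues on each
#' side (so the planted span cannot extend), and defines the truth table as
#' the output of \code{\link{bruteForceScan}} on the final sequences —
#' accidental background polyXY are therefore part of the truth. Annotation
#' intervals follow the spec's annotation plan.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir optional output directory; when given, writes
#'   \code{proteins.fasta}, \code{truth.tsv} and (if any)
#'   \code{annotations.tsv}.
#' @param window scan window defining the truth table.
#' @return a list with \code{proteins} (\code{AAStringSet}), \code{truth}
#'   (\linkS4class{PolyXYRegions}), \code{planted} (data.frame of planted
#'   spans) and \code{annotations} (data.frame or NULL).
#' @export
generateFixture <- function(spec, dir = NULL, window = 6L) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  freqs <- spec$backgroundFreq
  lets <- names(freqs)
  lens <- sample(spec$lengthRange[1L]:spec$lengthRange[2L],
                 spec$nProteins, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(lets, L, replace = TRUE, prob = freqs), collapse = ""),
    character(1))
  names(seqs) <- sprintf("SYNP%04d", seq_len(spec$nProteins))

  planted <- NULL
  if (!is.null(spec$plants) && nrow(spec$plants)) {
    pl <- spec$plants
    host <- sample(spec$nProteins, nrow(pl), replace = TRUE)
    occupied <- lapply(seq_len(spec$nProteins), function(i) integer(0))
    prows <- list()
    for (i in seq_len(nrow(pl))) {
      motif <- .plantSequence(pl$pair[i], pl$category[i],
                              plantLength = pl$length[i] %||NA% NA,
                              nUnits = pl$nUnits[i] %||NA% NA,
                              joinedOrder = pl$joinedOrder[i] %||NA% NA,
                              window = window)
      p <- sort(unlist(strsplit(toupper(pl$pair[i]), "", fixed = TRUE)))
      guards <- setdiff(.STANDARD_AA, p)[1:2]
      insert <- paste0(guards[1L], guards[2L], motif, guards[2L], guards[1L])
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        h <- host[i]
        L <- nchar(seqs[[h]])
        if (L < nchar(insert) + 2L) { h <- host[i] <- sample(spec$nProteins, 1L); next }
        s0 <- sample.int(L - nchar(insert) + 1L, 1L)
        span <- s0:(s0 + nchar(insert) - 1L)
        if (any(span %in% occupied[[h]])) { next }
        substr(seqs[[h]], s0, s0 + nchar(insert) - 1L) <- insert
        occupied[[h]] <- c(occupied[[h]], span)
        prows[[length(prows) + 1L]] <- data.frame(
          proteinId = names(seqs)[h], start = s0 + 2L,
          end = s0 + 1L + nchar(motif),
          pair = paste(p, collapse = ""), category = pl$category[i],
          sequence = motif, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place plant ", i,
                        " (proteins too short or too crowded)")
    }
    planted <- do.call(rbind, prows)
  }

  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- names(seqs)
  truth <- bruteForceScan(seqs, window = window)

  annotations <- NULL
  ap <- spec$annotationPlan
  if (!is.null(ap)) {
    rows <- list()
    if (!is.null(ap$coverPlants) && !is.null(planted)) {
      pad <- ap$pad %||% 5L
      for (i in seq_len(nrow(planted))) {
        L <- nchar(seqs[[planted$proteinId[i]]])
        rows[[length(rows) + 1L]] <- data.frame(
          proteinId = planted$proteinId[i],
          start = max(1L, planted$start[i] - pad),
          end = min(L, planted$end[i] + pad),
          kind = ap$coverPlants, name = sprintf("plant%03d", i),
          stringsAsFactors = FALSE)
      }
    }
    nd <- ap$randomDomains %||% 0L
    if (nd > 0L) {
      dl <- ap$domainLength %||% 40L
      for (h in seq_len(spec$nProteins)) {
        L <- nchar(seqs[[h]])
        if (L < dl) next
        for (d in seq_len(nd)) {
          s0 <- sample.int(L - dl + 1L, 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            proteinId = names(seqs)[h], start = s0, end = s0 + dl - 1L,
            kind = "domain", name = sprintf("DOM%04d.%d", h, d),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) annotations <- do.call(rbind, rows)
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeProteome(proteins, file.path(dir, "proteins.fasta"))
    writeRegionsTsv(truth, file.path(dir, "truth.tsv"))
    if (!is.null(annotations))
      writeAnnotations(annotations, file.path(dir, "annotations.tsv"))
  }
  list(proteins = proteins, truth = truth, planted = planted,
       annotations = annotations)
}

## NA-tolerant column access for optional plant columns.
`%||NA%` <- function(a, b) if (is.null(a)) b else a
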