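#' Read a protein FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped lines), takes the first
#' whitespace-delimited header token as the protein id, upper-cases the
#' sequences, and returns an \code{AAStringSet}. Duplicate ids are a hard
#' error: downstream per-protein statistics would silently double-count.
#'
#' @param path path to a FASTA file.
#' @return an \code{AAStringSet} named by protein id.
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(raw) == 0L) stop("no FASTA records in: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

.TSV_COLS <- c("protein_id", "start", "end", "pair", "sequence", "category",
               "n_units", "joined_order")

#' Write regions to TSV
#'
#' One row per region with columns \code{protein_id}, \code{start},
#' \code{end}, \code{pair} (two letters, alphabetical), \code{sequence},
#' \code{category}, \code{n_units} (empty unless direpeat) and
#' \code{joined_order} (empty unless joined). Tab-separated, no quoting,
#' Unix line endings.
#'
#' @param regions a \linkS4class{PolyXYRegions} object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeRegionsTsv <- function(regions, path) {
  df <- as.data.frame(regions)[, .REGION_COLS, drop = FALSE]
  names(df) <- .TSV_COLS
  df$n_units <- ifelse(is.na(df$n_units), "", as.character(df$n_units))
  df$joined_order <- ifelse(is.na(df$joined_order), "", df$joined_order)
  df$category <- ifelse(is.na(df$category), "", df$category)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a regions TSV
#'
#' Inverse of \code{\link{writeRegionsTsv}}.
#'
#' @param path a TSV written by \code{\link{writeRegionsTsv}}.
#' @param window,mergeGap scan parameters to record in the object metadata.
#' @return a \linkS4class{PolyXYRegions} object.
#' @export
readRegionsTsv <- function(path, window = 6L, mergeGap = 0L) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(protein_id = "character",
                                         start = "integer", end = "integer",
                                         pair = "character",
                                         sequence = "character",
                                         category = "character",
                                         n_units = "integer",
                                         joined_order = "character"),
                          na.strings = "")
  if (!identical(names(df), .TSV_COLS))
    stop("not a polyXY regions TSV (bad columns): ", path)
  names(df) <- .REGION_COLS
  if (nrow(df))
    df$category[is.na(df$category)] <- NA_character_
  PolyXYRegions(df, window = window, mergeGap = mergeGap)
}

#' Read annotation intervals
#'
#' Reads domain / predicted-disorder intervals from a tab-separated file with
#' columns \code{protein_id}, \code{start}, \code{end}, \code{kind}
#' (\code{"domain"} or \code{"disorder"}) and \code{name}. A header line is
#' optional. Coordinates are 1-based inclusive.
#'
#' @param path the TSV path.
#' @return a data.frame with columns proteinId, start, end, kind, name.
#' @export
readAnnotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  if (grepl("^protein_id\\b", lines[1L])) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 5L)
      stop("annotation row ", i, ": expected 5 tab-separated fields, got ",
           length(f))
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop("annotation row ", i, ": non-integer coordinates")
    if (start < 1L || end < start)
      stop("annotation row ", i, ": need 1 <= start <= end")
    if (!(f[4L] %in% c("domain", "disorder")))
      stop("annotation row ", i, ": unknown kind '", f[4L],
           "' (expected 'domain' or 'disorder')")
    out[[i]] <- data.frame(proteinId = f[1L], start = start, end = end,
                           kind = f[4L], name = f[5L],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write annotation intervals
#'
#' @param annotations a data.frame as returned by
#'   \code{\link{readAnnotations}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAnnotations <- function(annotations, path) {
  df <- annotations[, c("proteinId", "start", "end", "kind", "name")]
  names(df) <- c("protein_id", "start", "end", "kind", "name")
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write a protein set as FASTA
#'
#' @param proteins a named character vector or \code{AAStringSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeProteome <- function(proteins, path) {
  seqs <- .asSequences(proteins)
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
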