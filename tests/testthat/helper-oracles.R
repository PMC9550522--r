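# Independent reference implementations used to check the package against.
# These deliberately share no code with the scanner / classifier internals.

# Window-by-window detection oracle on one sequence: enumerate every window,
# tabulate characters directly, union overlapping same-pair intervals.
oracleDetect <- function(seq, window = 6L) {
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  hits <- list()
  if (L >= window) {
    for (i in seq_len(L - window + 1L)) {
      win <- chars[i:(i + window - 1L)]
      if (!all(win %in% standard)) next
      tab <- table(win)
      if (length(tab) == 2L && all(tab >= 2L))
        hits[[length(hits) + 1L]] <-
          list(start = i, pair = paste(sort(names(tab)), collapse = ""))
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      pair = character(), stringsAsFactors = FALSE))
  h <- data.frame(start = vapply(hits, `[[`, integer(1), "start"),
                  pair = vapply(hits, `[[`, character(1), "pair"),
                  stringsAsFactors = FALSE)
  out <- list()
  for (pk in unique(h$pair)) {
    ss <- sort(h$start[h$pair == pk])
    ee <- ss + window - 1L
    cs <- ss[1L]; ce <- ee[1L]
    for (j in seq_along(ss)[-1L]) {
      if (ss[j] <= ce) ce <- max(ce, ee[j])
      else {
        out[[length(out) + 1L]] <- data.frame(start = cs, end = ce, pair = pk)
        cs <- ss[j]; ce <- ee[j]
      }
    }
    out[[length(out) + 1L]] <- data.frame(start = cs, end = ce, pair = pk)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$pair), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# All direpeat strings of a given length over letters x/y: every placement of
# (xy)+ or (yx)+ with at most one extra lone x or y inserted at any position.
direpeatStrings <- function(len, x = "G", y = "L") {
  out <- character(0)
  canon <- function(a, b, k) paste(rep(c(a, b), k), collapse = "")
  if (len %% 2L == 0L && len >= 2L) {
    k <- len %/% 2L
    out <- c(out, canon(x, y, k), canon(y, x, k))
  }
  if (len %% 2L == 1L && len >= 3L) {
    k <- (len - 1L) %/% 2L
    for (base in c(canon(x, y, k), canon(y, x, k)))
      for (pos in 0:(len - 1L))
        for (ins in c(x, y))
          out <- c(out, paste0(substr(base, 1, pos), ins,
                               substr(base, pos + 1L, len - 1L)))
  }
  unique(out)
}

# Joined oracle: regex for a run of one letter (>= 2) then a run of the
# other (>= 2), both orders.
isJoinedOracle <- function(s, x = "G", y = "L") {
  grepl(sprintf("^%s{2,}%s{2,}$", x, y), s) ||
    grepl(sprintf("^%s{2,}%s{2,}$", y, x), s)
}

# Exact two-sided Mann-Whitney p-value by enumeration of all assignments of
# the pooled observations to the two groups (no ties assumed).
exactMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  uStat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u <- uStat(seq_len(n1))
  all <- utils::combn(length(pooled), n1)
  us <- apply(all, 2L, uStat)
  pLow <- mean(us <= u)
  pHigh <- mean(us >= u)
  min(1, 2 * min(pLow, pHigh))
}

# Random protein-like sequence over a given alphabet.
randomSeq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

regionsAsDf <- function(regions)
  as.data.frame(regions)[, c("proteinId", "start", "end", "pair", "sequence",
                             "category", "nUnits", "joinedOrder")]
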