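## Independent oracles and small helpers used across the suite.

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## circular extraction oracle: double the sequence and slice linearly
oracleExtract <- function(s, start, end, strand = "+") {
  L <- nchar(s)
  if (end < start) end <- end + L
  out <- substr(paste0(s, s), start, end)
  if (strand == "-") out <- plastomeKit::revComp(out)
  out
}

## quadratic brute-force maximal repeat oracle: for every diagonal of the
## sequence against itself (direct) and against its reverse complement
## (inverted), run-length encode positionwise equality and keep runs of at
## least minLen with disjoint copies. Entirely independent of the k-mer
## seeded finder.
oracleRepeatPairs <- function(s, minLen) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  rch <- strsplit(plastomeKit::revComp(s), "")[[1]]
  res <- list()
  addRun <- function(a1, a2, b1, b2, strand) {
    if (b1 < a1) { t1 <- a1; t2 <- a2; a1 <- b1; a2 <- b2; b1 <- t1; b2 <- t2 }
    if (b1 > a2)  # disjoint copies only
      res[[length(res) + 1L]] <<- data.frame(
        start1 = a1, end1 = a2, start2 = b1, end2 = b2,
        length = a2 - a1 + 1L, strand = strand)
  }
  ## direct: s vs s shifted by d
  for (d in seq_len(n - minLen)) {
    eq <- ch[seq_len(n - d)] == ch[seq_len(n - d) + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= minLen)) {
      i2 <- ends[k]; i1 <- i2 - r$lengths[k] + 1L
      addRun(i1, i2, i1 + d, i2 + d, "+")
    }
  }
  ## inverted: s vs revcomp(s) over all alignments (shift of r vs s)
  for (sh in (1L - n):(n - 1L)) {
    i <- max(1L, 1L - sh):min(n, n - sh)  # positions in s
    j <- i + sh                            # positions in r
    eq <- ch[i] == rch[j]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= minLen)) {
      e <- ends[k]; len <- r$lengths[k]
      a1 <- i[e - len + 1L]; a2 <- i[e]
      jj2 <- j[e]                          # last matched position in r
      b1 <- n - jj2 + 1L; b2 <- n - j[e - len + 1L] + 1L
      addRun(a1, a2, b1, b2, "-")
    }
  }
  if (!length(res))
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      length = integer(), strand = character()))
  out <- unique(do.call(rbind, res))
  out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## full Smith-Waterman oracle via Biostrings (never used in the
## implementation path)
oracleSwScore <- function(q, t, match = 2, mismatch = -3,
                          gapOpen = 5, gapExtend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  one <- function(qq) Biostrings::score(Biostrings::pairwiseAlignment(
    qq, t, type = "local", substitutionMatrix = mat,
    gapOpening = gapOpen, gapExtension = gapExtend))
  ## both query strands, as the seeded search reports either orientation
  max(one(q), one(plastomeKit::revComp(q)))
}

## plant a substring at a 1-based position
plantAt <- function(s, at, piece) {
  stopifnot(at + nchar(piece) - 1L <= nchar(s))
  substr(s, at, at + nchar(piece) - 1L) <- piece
  s
}

## mutate given positions to a different base
mutateAt <- function(s, at) {
  ch <- strsplit(s, "")[[1]]
  for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

pairKey <- function(df)
  sort(paste(df$start1, df$end1, df$start2, df$end2, df$strand))
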