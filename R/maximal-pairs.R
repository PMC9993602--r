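## Maximal exact repeated pairs, direct and inverted, by diagonal seeding.
##
## A maximal exact pair of length M >= k contributes a seed (shared k-mer)
## at every one of its M-k+1 offsets, so merging consecutive seed positions
## on a diagonal recovers the pair at exactly its maximal extent: no
## explicit extension step is needed for exact matching.

## collapse seed pairs (i, j) to per-diagonal runs; returns i1, i2, d
pairRunsFromSeeds <- function(i, j) {
  if (length(i) == 0L)
    return(data.frame(i1 = integer(), i2 = integer(), d = integer()))
  d <- j - i
  o <- order(d, i)
  d <- d[o]; i <- i[o]
  brk <- c(TRUE, diff(d) != 0L | diff(i) != 1L)
  s <- which(brk)
  e <- c(s[-1] - 1L, length(i))
  data.frame(i1 = i[s], i2 = i[e], d = d[s])
}

## all (position in a, position in b) pairs of shared k-mers
sharedKmerSeeds <- function(ka, kb) {
  common <- intersect(unique(ka), unique(kb))
  if (length(common) == 0L)
    return(list(i = integer(), j = integer()))
  fa <- factor(ka, levels = common)
  fb <- factor(kb, levels = common)
  ia <- which(!is.na(fa)); ib <- which(!is.na(fb))
  la <- split(ia, fa[ia]); lb <- split(ib, fb[ib])
  ## cross product per k-mer: each position in a paired with each in b
  i <- unlist(mapply(function(a, b) rep(a, each = length(b)),
                     la, lb, SIMPLIFY = FALSE), use.names = FALSE)
  j <- unlist(mapply(function(a, b) rep(b, times = length(a)),
                     la, lb, SIMPLIFY = FALSE), use.names = FALSE)
  list(i = i, j = j)
}

## maximal exact direct pairs within s, length >= k, non-overlapping copies.
## returns start1 < start2 rows: start1,end1,start2,end2,length,strand="+"
directMaximalPairs <- function(s, k) {
  km <- seqKmers(s, k)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  empty <- data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      length = integer(), strand = character())
  if (!any(dup)) return(empty)
  idx <- which(dup)
  grp <- split(idx, km[idx])
  i <- unlist(lapply(grp, function(g)
    rep(g, each = length(g))), use.names = FALSE)
  j <- unlist(lapply(grp, function(g)
    rep(g, times = length(g))), use.names = FALSE)
  keep <- j > i
  runs <- pairRunsFromSeeds(i[keep], j[keep])
  if (!nrow(runs)) return(empty)
  len <- runs$i2 - runs$i1 + k
  out <- data.frame(start1 = runs$i1, end1 = runs$i2 + k - 1L,
                    start2 = runs$i1 + runs$d,
                    end2 = runs$i2 + runs$d + k - 1L,
                    length = len, strand = "+")
  out[out$start2 > out$end1, , drop = FALSE]  # drop self-overlapping (tandem)
}

## maximal exact inverted pairs: s[A] == revcomp(s[B]), copies disjoint,
## canonicalized to start1 < start2; strand="-"
invertedMaximalPairs <- function(s, k) {
  n <- nchar(s)
  r <- revComp(s)
  seeds <- sharedKmerSeeds(seqKmers(s, k), seqKmers(r, k))
  empty <- data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      length = integer(), strand = character())
  if (length(seeds$i) == 0L) return(empty)
  runs <- pairRunsFromSeeds(seeds$i, seeds$j)
  if (!nrow(runs)) return(empty)
  a1 <- runs$i1; a2 <- runs$i2 + k - 1L
  j1 <- runs$i1 + runs$d; j2 <- runs$i2 + runs$d + k - 1L
  b1 <- n - j2 + 1L; b2 <- n - j1 + 1L
  out <- data.frame(start1 = a1, end1 = a2, start2 = b1, end2 = b2,
                    length = a2 - a1 + 1L, strand = "-")
  ## canonical orientation and dedup (each pair is seeded from both arms)
  flip <- out$start2 < out$start1
  tmp <- out[flip, c("start2", "end2", "start1", "end1")]
  out[flip, c("start1", "end1", "start2", "end2")] <- tmp
  out <- out[out$start2 > out$end1, , drop = FALSE]  # disjoint arms only
  out <- unique(out)
  rownames(out) <- NULL
  out
}

## both orientations, sorted by length desc then position
maximalRepeatPairs <- function(s, k) {
  out <- rbind(directMaximalPairs(s, k), invertedMaximalPairs(s, k))
  out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
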