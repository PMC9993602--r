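## Seeded affine-gap local alignment with BLASTn-style nucleotide scoring.

#' Scoring scheme for seeded local alignment
#'
#' Defaults follow the classical BLASTn nucleotide parameterization used
#' for plastid gene homology searches: reward +2, penalty -3, gap open 5,
#' gap extend 2 (a gap of length L costs 5 + 2L), word size 9, E-value
#' cutoff 1e-5, no low-complexity filtering. E-values use the
#' Karlin-Altschul form E = K*m*n*exp(-lambda*S) with the published
#' constants for reward/penalty (2,-3): lambda = 0.625, K = 0.41.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (negative).
#' @param gapOpen,gapExtend affine gap costs (>= 0).
#' @param seedWord exact seed word size (>= 4).
#' @param evalue E-value threshold for reported hits.
#' @param lambda,K Karlin-Altschul constants.
#' @return a named list of class `ScoringScheme`.
#' @export
scoringScheme <- function(match = 2, mismatch = -3, gapOpen = 5,
                          gapExtend = 2, seedWord = 9, evalue = 1e-5,
                          lambda = 0.625, K = 0.41) {
  stopifnot(match > 0, mismatch < 0, gapOpen >= 0, gapExtend >= 0,
            seedWord >= 4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend),
                 seedWord = as.integer(seedWord), evalue = evalue,
                 lambda = lambda, K = K),
            class = "ScoringScheme")
}

## positions of every k-mer of t, split by k-mer (built once per target)
targetSeedIndex <- function(t, w) {
  tk <- seqKmers(t, w)
  split(seq_along(tk), tk)
}

#' Seeded affine-gap local alignment
#'
#' Finds local alignments of `query` against `target` by exact seed-word
#' matching on both strands, ungapped X-drop extension of collinear seed
#' runs, clustering of surviving runs, and full affine-gap local dynamic
#' programming (Smith-Waterman) of the query against a window around each
#' cluster. Within the window the alignment is the optimal local alignment
#' under the scheme, so on pairs whose homology contains seed-length exact
#' stretches the top hit score equals the full Smith-Waterman score.
#' Circular targets are doubled before the search and hits deduplicated
#' modulo the genome length. Hits with E-value above the scheme threshold
#' are dropped; hits contained in a better hit are merged away.
#'
#' @param query character/DNAString query sequence.
#' @param target character/DNAString/[PlastomeRecord-class] target.
#' @param scheme a [scoringScheme()].
#' @param minUngapped minimum ungapped extension score for a seed run to
#'   proceed to gapped alignment (noise filter).
#' @param xdrop X-drop for ungapped extension.
#' @param diagBand diagonal tolerance when clustering runs into one
#'   gapped-alignment window.
#' @param targetIndex optional precomputed `targetSeedIndex()` of the
#'   (doubled, for circular targets) target, reused across queries.
#' @return data.frame of hits, ordered by (score desc, target start):
#'   `query_start`, `query_end`, `target_start`, `target_end` (1-based
#'   closed; on a circular target `target_end` may exceed the genome
#'   length for origin-wrapping hits), `strand`, `score`, `identity`,
#'   `evalue`, `matches`, `columns`.
#' @export
seededLocalAlign <- function(query, target, scheme = scoringScheme(),
                             minUngapped = 28, xdrop = 16, diagBand = 50,
                             targetIndex = NULL) {
  q <- seqChar(query)
  circular <- methods::is(target, "PlastomeRecord") &&
    isCircularGenome(target)
  t0 <- seqChar(target)
  L <- nchar(t0)
  if (nchar(q) == 0L || L == 0L) stop("empty query or target")
  t <- if (circular) paste0(t0, t0) else t0
  w <- scheme$seedWord
  if (is.null(targetIndex)) targetIndex <- targetSeedIndex(t, w)

  qlen <- nchar(q)
  hits <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") q else revComp(q)
    qk <- seqKmers(qs, w)
    pos <- targetIndex[qk]
    nper <- lengths(pos)
    if (sum(nper) == 0L) next
    i <- rep(seq_along(qk), nper)
    j <- unlist(pos, use.names = FALSE)
    runs <- pairRunsFromSeeds(i, j)
    if (!nrow(runs)) next
    ## ungapped X-drop filter
    keep <- logical(nrow(runs))
    for (r in seq_len(nrow(runs))) {
      ext <- ungapped_extend_cpp(qs, t, runs$i1[r], runs$i1[r] + runs$d[r],
                                 runs$i2[r] - runs$i1[r] + w,
                                 scheme$match, scheme$mismatch, xdrop)
      keep[r] <- ext[1] >= minUngapped
    }
    runs <- runs[keep, , drop = FALSE]
    if (!nrow(runs)) next
    ## cluster runs into candidate windows
    runs$t1 <- runs$i1 + runs$d
    runs$t2 <- runs$i2 + runs$d + w - 1L
    runs <- runs[order(runs$t1), , drop = FALSE]
    brk <- c(TRUE, diff(runs$t1) > qlen |
                   abs(diff(runs$d)) > diagBand)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      sub <- runs[grp == g, , drop = FALSE]
      w1 <- max(1L, min(sub$t1) - qlen - 20L)
      w2 <- min(nchar(t), max(sub$t2) + qlen + 20L)
      aln <- sw_align_cpp(qs, substr(t, w1, w2),
                          scheme$match, scheme$mismatch,
                          scheme$gapOpen, scheme$gapExtend)
      if (aln[1] <= 0L) next
      qa <- c(aln[2], aln[3])
      if (strand == "-") qa <- c(qlen - aln[3] + 1L, qlen - aln[2] + 1L)
      hits[[length(hits) + 1L]] <- data.frame(
        query_start = qa[1], query_end = qa[2],
        target_start = w1 + aln[4] - 1L, target_end = w1 + aln[5] - 1L,
        strand = strand, score = aln[1],
        matches = aln[6], columns = aln[7])
    }
  }
  emptyHits <- data.frame(query_start = integer(), query_end = integer(),
                          target_start = integer(), target_end = integer(),
                          strand = character(), score = integer(),
                          identity = numeric(), evalue = numeric(),
                          matches = integer(), columns = integer())
  if (!length(hits)) return(emptyHits)
  h <- do.call(rbind, hits)
  ## normalize circular coordinates and deduplicate doubled hits
  if (circular) {
    shiftDown <- h$target_start > L
    h$target_start[shiftDown] <- h$target_start[shiftDown] - L
    h$target_end[shiftDown] <- h$target_end[shiftDown] - L
    ## a hit of length > L cannot occur (window <= qlen-padded)
  }
  h <- h[!duplicated(h[, c("query_start", "query_end", "target_start",
                           "target_end", "strand")]), , drop = FALSE]
  h$identity <- h$matches / h$columns
  h$evalue <- scheme$K * qlen * L * exp(-scheme$lambda * h$score)
  h <- h[h$evalue <= scheme$evalue, , drop = FALSE]
  if (!nrow(h)) return(emptyHits)
  ## drop hits contained in a better hit (same strand, both intervals)
  h <- h[order(-h$score, h$target_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (r in seq_len(nrow(h))) {
    if (!keep[r]) next
    if (r < nrow(h)) {
      for (r2 in (r + 1L):nrow(h)) {
        if (!keep[r2]) next
        if (h$strand[r2] == h$strand[r] &&
            h$query_start[r2] >= h$query_start[r] &&
            h$query_end[r2] <= h$query_end[r] &&
            h$target_start[r2] >= h$target_start[r] &&
            h$target_end[r2] <= h$target_end[r])
          keep[r2] <- FALSE
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(-h$score, h$target_start), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("query_start", "query_end", "target_start", "target_end",
        "strand", "score", "identity", "evalue", "matches", "columns")]
}
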