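## Repeat-mediated isomeric configurations: alternative-genome
## construction, junction windows, spanning-read counting, and a
## short-read configuration check.

#' Build the alternative plastome configuration at an inverted-repeat pair
#'
#' Flip-flop recombination between two inverted repeat copies reverses the
#' segment between them. `isomer2` is the input genome with the interval
#' from the inner edge of the first copy to the inner edge of the second
#' reverse-complemented in place; the repeat copies themselves are left
#' untouched (the flip regenerates them identically, which is what makes
#' the two configurations interconvertible). Applying the construction
#' twice restores the input. A direct (non-inverted) pair is an error: the
#' flip would not regenerate direct repeats.
#'
#' @param record circular [PlastomeRecord-class].
#' @param repeatA,repeatB integer `c(start, end)` of the two arm copies
#'   (1-based closed, `repeatA` upstream, neither wrapping the origin).
#' @return an [IsomerPair-class].
#' @export
buildIsomer <- function(record, repeatA, repeatB) {
  stopifnot(methods::is(record, "PlastomeRecord"))
  L <- plastomeLength(record)
  repeatA <- as.integer(repeatA); repeatB <- as.integer(repeatB)
  if (repeatA[1] > repeatB[1]) { tmp <- repeatA; repeatA <- repeatB; repeatB <- tmp }
  if (repeatA[2] >= repeatB[1])
    stop("repeat copies must be disjoint")
  if (repeatB[2] > L || repeatA[1] < 1L)
    stop("repeat copies must not wrap the origin")
  sA <- extractInterval(record, repeatA[1], repeatA[2])
  sB <- extractInterval(record, repeatB[1], repeatB[2])
  if (identical(sA, sB) && !identical(sA, revComp(sA)))
    stop("repeat pair is direct, not inverted; no isomer is mediated")
  if (!identical(sB, revComp(sA)))
    stop("repeat copies are not reverse complements of each other")
  s <- seqChar(record)
  p <- repeatA[2] + 1L; q <- repeatB[1] - 1L
  if (q < p) stop("no segment between the repeat copies")
  s2 <- paste0(substr(s, 1L, repeatA[2]),
               revComp(substr(s, p, q)),
               substr(s, repeatB[1], L))

  ## carry features: reflect those wholly inside the flipped segment
  fl <- plastomeFeatures(record)
  if (length(fl)) {
    st <- GenomicRanges::start(fl); en <- GenomicRanges::end(fl)
    inside <- st >= p & en <= q
    outside <- en < p | st > q
    dropped <- !(inside | outside)
    if (any(dropped))
      message(sum(dropped), " feature(s) spanning a flip boundary dropped",
              " from isomer2")
    fl2 <- fl[!dropped]
    st2 <- GenomicRanges::start(fl2); en2 <- GenomicRanges::end(fl2)
    ins2 <- st2 >= p & en2 <= q
    ns <- ifelse(ins2, p + q - en2, st2)
    ne <- ifelse(ins2, p + q - st2, en2)
    sd <- as.character(GenomicRanges::strand(fl2))
    sd[ins2] <- ifelse(sd[ins2] == "+", "-", "+")
    IRanges::ranges(fl2) <- IRanges::IRanges(ns, ne)
    GenomicRanges::strand(fl2) <- sd
  } else fl2 <- fl
  iso2 <- PlastomeRecord(paste0(plastomeId(record), "_isomer2"), s2,
                         circular = isCircularGenome(record),
                         features = fl2)
  new("IsomerPair", isomer1 = record, isomer2 = iso2,
      repeatA = repeatA, repeatB = repeatB,
      repeatLength = repeatA[2] - repeatA[1] + 1L)
}

#' Junction windows of an isomer pair
#'
#' For each isomer, one window per repeat copy: the copy plus `flank` bp
#' on both sides (window length = repeat length + 2*flank), extracted
#' circularly. The windows of the two isomers share the repeat core and
#' the outer flank and differ in exactly the inner flank, which is what a
#' spanning read discriminates.
#'
#' @param pair an [IsomerPair-class].
#' @param flank flank size in bp (default 1000; must be >= 1 and small
#'   enough that the two windows do not overlap).
#' @return list of 4 windows, each `list(isomer, side, start, end, flank,
#'   coreLength, seq)`; attributes `flank` and `repeatLength`.
#' @export
junctionWindows <- function(pair, flank = 1000) {
  stopifnot(methods::is(pair, "IsomerPair"))
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 1L) stop("flank must be >= 1")
  L <- plastomeLength(pair@isomer1)
  a <- pair@repeatA; b <- pair@repeatB
  innerGap <- b[1] - a[2] - 1L
  outerGap <- L - (b[2] - a[1] + 1L)
  if (innerGap < 2L * flank || outerGap < 2L * flank)
    stop("flank so large that the two junction windows overlap")
  mk <- function(rec, iso, side, iv) {
    st <- modPos(iv[1] - flank, L)
    en <- iv[2] + flank
    list(isomer = iso, side = side, start = st, end = en, flank = flank,
         coreLength = pair@repeatLength,
         seq = extractInterval(rec, iv[1] - flank, iv[2] + flank))
  }
  out <- list(
    mk(pair@isomer1, "isomer1", "left", a),
    mk(pair@isomer1, "isomer1", "right", b),
    mk(pair@isomer2, "isomer2", "left", a),
    mk(pair@isomer2, "isomer2", "right", b))
  attr(out, "flank") <- flank
  attr(out, "repeatLength") <- pair@repeatLength
  out
}

#' Count junction-spanning long reads per isomer
#'
#' A read supports a window when its best local alignment to the window
#' (on either read strand) covers the entire repeat core and at least
#' `flankRequired` bp of flank on both sides at identity `minIdentity` or
#' better. Each read is assigned to at most one isomer, by best supported
#' window score; a read whose best scores tie across the two isomers
#' counts for neither. Per-isomer means are taken over the isomer's two
#' windows, and the inverted-isomer frequency is
#' `100 * mean2 / (mean1 + mean2)`.
#'
#' Candidate read/window pairs are screened with shared k-mers required in
#' both flanks before the affine-gap alignment (reusing the BLASTn-style
#' scoring 2/-3/5/2), so non-spanning reads are cheap to reject.
#'
#' @param windows from [junctionWindows()].
#' @param reads DNAStringSet, character vector, or FASTQ path.
#' @param minIdentity minimum alignment identity (default 0.8, tolerant
#'   of noisy long reads).
#' @param flankRequired bp of flank required on both sides (default: the
#'   window flank).
#' @param scheme a [scoringScheme()] for the window alignment.
#' @param seedK,seedStride k-mer size and read sampling stride of the
#'   candidate screen.
#' @return list of class `ReadSupport`: `counts` (named per-window),
#'   `mean1`, `mean2`, `frequency` (percent, `NA` when no read was
#'   counted), `n_reads`, `n_assigned`, `n_ambiguous`.
#' @export
countSpanningReads <- function(windows, reads, minIdentity = 0.8,
                               flankRequired = NULL,
                               scheme = scoringScheme(),
                               seedK = 21, seedStride = 50) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readLongReads(reads)
  rd <- if (methods::is(reads, "DNAStringSet")) as.character(reads)
        else as.character(reads)
  flank <- attr(windows, "flank")
  core <- attr(windows, "repeatLength")
  if (is.null(flankRequired)) flankRequired <- flank
  flankRequired <- as.integer(flankRequired)
  if (flankRequired > flank)
    stop("flankRequired exceeds the window flank")
  wlen <- nchar(windows[[1]]$seq)
  wkey <- vapply(windows, function(w)
    paste(w$isomer, w$side, sep = "."), character(1))

  counts <- setNames(rep(0L, length(windows)), wkey)
  nAssigned <- 0L; nAmbiguous <- 0L
  minSpan <- core + 2L * flankRequired

  if (length(rd)) {
    ## k-mer dictionary over each window on both strands
    dict <- list()
    for (i in seq_along(windows)) {
      for (strand in c("+", "-")) {
        ws <- if (strand == "+") windows[[i]]$seq
              else revComp(windows[[i]]$seq)
        km <- seqKmers(ws, seedK)
        dict[[paste(i, strand)]] <- split(seq_along(km), km)
      }
    }
    ## flank membership of a window position, in window-forward coords
    inLeft <- function(p) p <= flank - seedK + 1L
    inRight <- function(p) p >= flank + core + 1L

    for (ri in seq_along(rd)) {
      r <- rd[[ri]]
      rlen <- nchar(r)
      if (rlen < minSpan) next
      kp <- seq(1L, rlen - seedK + 1L, by = seedStride)
      rk <- substring(r, kp, kp + seedK - 1L)
      bestScore <- -1L
      bestIso <- character(); bestWin <- integer()
      for (i in seq_along(windows)) {
        for (strand in c("+", "-")) {
          idx <- dict[[paste(i, strand)]][rk]
          got <- !vapply(idx, is.null, logical(1))
          if (!any(got)) next
          rpos <- rep(kp[got], lengths(idx[got]))
          wpos <- unlist(idx[got], use.names = FALSE)
          ## window coords on the forward window for the flank screen
          wfwd <- if (strand == "+") wpos else wlen - wpos - seedK + 2L
          if (!(any(inLeft(wfwd)) && any(inRight(wfwd)))) next
          ws <- if (strand == "+") windows[[i]]$seq
                else revComp(windows[[i]]$seq)
          diag <- round(stats::median(rpos - wpos))
          margin <- max(100L, as.integer(0.15 * wlen))
          rs <- max(1L, diag + 1L - margin)
          re <- min(rlen, diag + wlen + margin)
          aln <- sw_align_cpp(ws, substr(r, rs, re),
                              scheme$match, scheme$mismatch,
                              scheme$gapOpen, scheme$gapExtend)
          if (aln[1] <= 0L) next
          w1 <- aln[2]; w2 <- aln[3]
          if (strand == "-") { tmp <- w1; w1 <- wlen - w2 + 1L; w2 <- wlen - tmp + 1L }
          idok <- aln[6] / aln[7] >= minIdentity
          spans <- w1 <= flank - flankRequired + 1L &&
                   w2 >= flank + core + flankRequired
          if (idok && spans) {
            if (aln[1] > bestScore) {
              bestScore <- aln[1]
              bestIso <- windows[[i]]$isomer
              bestWin <- i
            } else if (aln[1] == bestScore &&
                       !identical(windows[[i]]$isomer, bestIso)) {
              bestIso <- c(bestIso, windows[[i]]$isomer)
            }
          }
        }
      }
      if (length(unique(bestIso)) == 1L) {
        counts[bestWin] <- counts[bestWin] + 1L
        nAssigned <- nAssigned + 1L
      } else if (length(bestIso) > 1L) {
        nAmbiguous <- nAmbiguous + 1L
      }
    }
  } else {
    warning("empty read set: counts are zero and frequency undefined")
  }
  m1 <- mean(counts[grepl("^isomer1", names(counts))])
  m2 <- mean(counts[grepl("^isomer2", names(counts))])
  freq <- if ((m1 + m2) > 0) 100 * m2 / (m1 + m2) else NA_real_
  structure(list(counts = counts, mean1 = m1, mean2 = m2,
                 frequency = freq, n_reads = length(rd),
                 n_assigned = nAssigned, n_ambiguous = nAmbiguous),
            class = "ReadSupport")
}

#' @export
print.ReadSupport <- function(x, ...) {
  cat("ReadSupport:", x$n_reads, "reads,", x$n_assigned, "assigned\n")
  print(x$counts)
  cat("mean isomer1:", x$mean1, " mean isomer2:", x$mean2,
      " isomer2 frequency:",
      if (is.na(x$frequency)) "undefined" else
        paste0(round(x$frequency, 3), "%"), "\n")
  invisible(x)
}

#' Short-read configuration check at the isomer junctions
#'
#' A read pair supports an isomer when, within one of that isomer's
#' junction windows, one mate maps wholly into the flank on one side of
#' the repeat core and its mate wholly into the flank on the other side
#' (the repeat is too long for a single short read, but a pair can
#' straddle it). Each isomer is declared supported when at least
#' `minPairs` pairs do so.
#'
#' @param windows from [junctionWindows()].
#' @param mate1,mate2 DNAStringSet/character vectors of equal length
#'   (pairs in order); unequal lengths are an error (unpaired input).
#' @param minPairs support threshold (default 3).
#' @param scheme a [scoringScheme()].
#' @param minCoverage fraction of a mate that must align (default 0.9).
#' @return named logical `c(isomer1=, isomer2=)` with attribute
#'   `pair_counts`.
#' @export
shortReadConfigurationCheck <- function(windows, mate1, mate2,
                                        minPairs = 3,
                                        scheme = scoringScheme(),
                                        minCoverage = 0.9) {
  m1 <- as.character(mate1); m2 <- as.character(mate2)
  if (length(m1) != length(m2))
    stop("unpaired input: mate1 and mate2 differ in length")
  flank <- attr(windows, "flank")
  core <- attr(windows, "repeatLength")
  wlen <- nchar(windows[[1]]$seq)
  idx <- lapply(windows, function(w)
    targetSeedIndex(w$seq, scheme$seedWord))

  sideOf <- function(mate, win, wi) {
    h <- seededLocalAlign(mate, win$seq, scheme, targetIndex = idx[[wi]])
    if (!nrow(h)) return(NA_character_)
    h <- h[1L, ]
    if ((h$query_end - h$query_start + 1L) / nchar(mate) < minCoverage)
      return(NA_character_)
    if (h$target_end <= flank) return("left")
    if (h$target_start >= flank + core + 1L) return("right")
    NA_character_
  }
  support <- c(isomer1 = 0L, isomer2 = 0L)
  for (p in seq_along(m1)) {
    for (wi in seq_along(windows)) {
      w <- windows[[wi]]
      s1 <- sideOf(m1[[p]], w, wi)
      if (is.na(s1)) next
      s2 <- sideOf(m2[[p]], w, wi)
      if (is.na(s2) || s1 == s2) next
      support[[w$isomer]] <- support[[w$isomer]] + 1L
      break
    }
  }
  out <- support >= minPairs
  if (!any(out))
    warning("no isomer reached ", minPairs, " straddling pairs; pairs ",
            "whose insert is shorter than the repeat cannot straddle it")
  attr(out, "pair_counts") <- support
  out
}
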