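## Rearrangement scripting and read simulation for synthetic fixtures.

#' Apply a rearrangement script over an explicit block partition
#'
#' The (IR-reduced) genome is cut into blocks at `blockEnds`; each event
#' acts on a contiguous run of blocks in the *current* arrangement:
#' `list(type = "inversion", from, to)` reverses the run (flipping
#' orientation), `list(type = "translocation", from, to, after)` moves it
#' after position `after` of the remaining list (0 = front). The expected
#' signed permutation is composed on the block ids independently of the
#' sequence edit, which makes it an oracle for synteny typing. Applying a
#' script followed by its inverse restores the input sequence.
#'
#' @param record [PlastomeRecord-class] (features are not carried through
#'   a rearrangement and are dropped).
#' @param script list of events, applied in order.
#' @param blockEnds increasing block end positions; the last must be the
#'   genome length.
#' @return list: `record` (rearranged), `permutation` (signed block ids).
#' @export
applyRearrangement <- function(record, script, blockEnds) {
  stopifnot(methods::is(record, "PlastomeRecord"))
  L <- plastomeLength(record)
  blockEnds <- as.integer(blockEnds)
  if (is.unsorted(blockEnds, strictly = TRUE) ||
      blockEnds[length(blockEnds)] != L || any(blockEnds < 1L))
    stop("blockEnds must be strictly increasing and end at the genome length")
  s <- seqChar(record)
  starts <- c(1L, head(blockEnds, -1) + 1L)
  blocks <- lapply(seq_along(blockEnds), function(i)
    list(id = i, sign = 1L, seq = substr(s, starts[i], blockEnds[i])))

  for (ev in script) {
    n <- length(blocks)
    from <- ev$from; to <- ev$to
    if (is.null(ev$type) || from < 1L || to > n || from > to)
      stop("invalid rearrangement event")
    if (ev$type == "inversion") {
      seg <- rev(blocks[from:to])
      seg <- lapply(seg, function(b)
        list(id = b$id, sign = -b$sign, seq = revComp(b$seq)))
      blocks[from:to] <- seg
    } else if (ev$type == "translocation") {
      seg <- blocks[from:to]
      rest <- blocks[-(from:to)]
      after <- ev$after
      if (after < 0L || after > length(rest))
        stop("invalid translocation target")
      blocks <- append(rest, seg, after = after)
    } else stop("unknown event type: ", ev$type)
  }
  perm <- vapply(blocks, function(b) b$sign * b$id, numeric(1))
  s2 <- paste(vapply(blocks, `[[`, character(1), "seq"), collapse = "")
  list(record = PlastomeRecord(plastomeId(record), s2,
                               circular = isCircularGenome(record)),
       permutation = as.integer(perm))
}

#' Simulate long reads from one genome or an isomer mixture
#'
#' Reads are drawn from the circular template(s) with uniform start,
#' uniform length in `[minLen, maxLen]` and random strand; each read's
#' template is isomer2 with probability `isomer2Prop` (a plain
#' [PlastomeRecord-class] input fixes the proportion at 0). Errors are
#' injected per base at the given rates. Read names encode the template,
#' start, length and strand, so simulated sets carry their own ground
#' truth.
#'
#' @param x [IsomerPair-class] or [PlastomeRecord-class].
#' @param nReads number of reads.
#' @param minLen,maxLen read length range, bp (capped at the genome
#'   length).
#' @param errorRates named numeric `c(mismatch=, insertion=, deletion=)`,
#'   each in `[0, 0.2]`.
#' @param isomer2Prop probability a read derives from isomer2.
#' @param seed RNG seed.
#' @return named DNAStringSet.
#' @export
simulateLongReads <- function(x, nReads, minLen = 5000, maxLen = 15000,
                              errorRates = c(mismatch = 0, insertion = 0,
                                             deletion = 0),
                              isomer2Prop = 0, seed = 1) {
  if (methods::is(x, "IsomerPair")) {
    t1 <- seqChar(isomer1(x)); t2 <- seqChar(isomer2(x))
  } else {
    t1 <- seqChar(x); t2 <- NULL
    if (isomer2Prop > 0) stop("isomer2Prop > 0 requires an IsomerPair")
  }
  stopifnot(nReads > 0, all(errorRates >= 0), all(errorRates <= 0.2),
            isomer2Prop >= 0, isomer2Prop <= 1)
  L <- nchar(t1)
  minLen <- min(minLen, L); maxLen <- min(maxLen, L)
  d1 <- paste0(t1, t1)
  d2 <- if (!is.null(t2)) paste0(t2, t2) else NULL
  withSeed(seed, {
    tpl <- rbinom(nReads, 1L, isomer2Prop)
    starts <- sample.int(L, nReads, replace = TRUE)
    lens <- sample(seq.int(minLen, maxLen), nReads, replace = TRUE)
    strands <- sample(c("+", "-"), nReads, replace = TRUE)
    reads <- ifelse(tpl == 0L,
                    substring(d1, starts, starts + lens - 1L),
                    if (is.null(d2)) "" else
                      substring(d2, starts, starts + lens - 1L))
    neg <- strands == "-"
    if (any(neg))
      reads[neg] <- vapply(reads[neg], revComp, character(1),
                           USE.NAMES = FALSE)
    if (any(errorRates > 0))
      reads <- vapply(reads, injectErrors, character(1),
                      rates = errorRates, USE.NAMES = FALSE)
    names(reads) <- sprintf(
      "read%06d|template=%s|start=%d|len=%d|strand=%s",
      seq_len(nReads), c("isomer1", "isomer2")[tpl + 1L],
      starts, lens, strands)
    Biostrings::DNAStringSet(reads)
  })
}

injectErrors <- function(read, rates) {
  ch <- strsplit(read, "")[[1]]
  n <- length(ch)
  mis <- which(runif(n) < rates[["mismatch"]])
  if (length(mis))
    ch[mis] <- vapply(ch[mis], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
  del <- runif(n) < rates[["deletion"]]
  ins <- which(runif(n) < rates[["insertion"]])
  if (length(ins)) {
    add <- sample(DNA_BASES, length(ins), replace = TRUE)
    ch[ins] <- paste0(ch[ins], add)
  }
  paste(ch[!del], collapse = "")
}

#' Simulate paired short reads
#'
#' Fragments of uniform length in `[insertMin, insertMax]` are drawn from
#' the circular template(s); mate 1 is the fragment's first `readLen`
#' bases, mate 2 the reverse complement of its last `readLen`. Names
#' encode template and fragment coordinates.
#'
#' @inheritParams simulateLongReads
#' @param nPairs number of pairs.
#' @param readLen mate length, bp.
#' @param insertMin,insertMax fragment length range, bp.
#' @return list with DNAStringSets `mate1` and `mate2`.
#' @export
simulateShortReadPairs <- function(x, nPairs, readLen = 150,
                                   insertMin = 300, insertMax = 600,
                                   isomer2Prop = 0, seed = 1) {
  if (methods::is(x, "IsomerPair")) {
    t1 <- seqChar(isomer1(x)); t2 <- seqChar(isomer2(x))
  } else {
    t1 <- seqChar(x); t2 <- NULL
    if (isomer2Prop > 0) stop("isomer2Prop > 0 requires an IsomerPair")
  }
  L <- nchar(t1)
  stopifnot(insertMax >= insertMin, insertMin >= readLen)
  d1 <- paste0(t1, t1); d2 <- if (!is.null(t2)) paste0(t2, t2) else NULL
  withSeed(seed, {
    tpl <- rbinom(nPairs, 1L, isomer2Prop)
    starts <- sample.int(L, nPairs, replace = TRUE)
    ins <- sample(seq.int(insertMin, insertMax), nPairs, replace = TRUE)
    frag <- ifelse(tpl == 0L, substring(d1, starts, starts + ins - 1L),
                   if (is.null(d2)) "" else
                     substring(d2, starts, starts + ins - 1L))
    m1 <- substr(frag, 1L, readLen)
    m2 <- vapply(substring(frag, nchar(frag) - readLen + 1L, nchar(frag)),
                 revComp, character(1), USE.NAMES = FALSE)
    nm <- sprintf("pair%06d|template=%s|start=%d|insert=%d",
                  seq_len(nPairs), c("isomer1", "isomer2")[tpl + 1L],
                  starts, ins)
    r1 <- Biostrings::DNAStringSet(m1); names(r1) <- paste0(nm, "/1")
    r2 <- Biostrings::DNAStringSet(m2); names(r2) <- paste0(nm, "/2")
    list(mate1 = r1, mate2 = r2)
  })
}
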