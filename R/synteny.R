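## IR-reduced synteny blocks, signed permutations, breakpoint distance and
## structural-type clustering.

#' Remove the second inverted-repeat copy from a plastome
#'
#' Re-origins the genome to the LSC start (canonical LSC-IRb-SSC-IRa
#' reading) and excises the IRa arm, the standard preprocessing before
#' whole-plastome collinearity comparison (a duplicated arm otherwise
#' matches two places at once). Features wholly inside IRa are dropped;
#' features spanning an IRa boundary are truncated to their retained part
#' and flagged with a `truncated` metadata column. `ir_free` genomes are
#' returned unchanged.
#'
#' @param record [PlastomeRecord-class].
#' @param partition matching [QuadripartitePartition-class]; computed with
#'   defaults when `NULL`.
#' @return reduced [PlastomeRecord-class] (re-origined to LSC start).
#' @export
stripSecondIR <- function(record, partition = NULL) {
  stopifnot(methods::is(record, "PlastomeRecord"))
  if (is.null(partition)) partition <- detectInvertedRepeat(record)
  if (structureClass(partition) == "ir_free") return(record)
  L <- plastomeLength(record)
  irl <- irLength(partition)
  rot <- reoriginPlastome(record, modPos(partition@lsc[1], L))
  keepLen <- L - irl
  s <- substr(seqChar(rot), 1L, keepLen)
  fl <- plastomeFeatures(rot)
  if (length(fl)) {
    st <- GenomicRanges::start(fl)
    en <- GenomicRanges::end(fl)
    ## IRa occupies [keepLen+1, L]; features may wrap (en > L)
    inside <- st > keepLen & en <= L
    truncated <- rep(FALSE, length(fl))
    ## spanning JSA: starts before IRa, ends inside
    sp1 <- st <= keepLen & en > keepLen & en <= L
    en[sp1] <- keepLen
    truncated[sp1] <- TRUE
    ## spanning JLA (wraps the origin through IRa): keep the wrapped head
    sp2 <- st > keepLen & en > L
    st[sp2] <- 1L
    en[sp2] <- en[sp2] - L
    truncated[sp2] <- TRUE
    keep <- !inside
    fl <- fl[keep]
    IRanges::ranges(fl) <- IRanges::IRanges(st[keep], en[keep])
    fl$truncated <- truncated[keep]
  }
  PlastomeRecord(plastomeId(record), s, circular = TRUE, features = fl)
}

#' Build pairwise synteny blocks by unique-k-mer anchor chaining
#'
#' Anchors are k-mers occurring exactly once in each genome with an
#' unambiguous orientation; anchors sorted along genome `a` are chained
#' while consecutive anchors keep one orientation and advance consistently
#' in genome `b` with gaps at most `maxAnchorGap` on both genomes. Chains
#' spanning at least `minBlockLen` bp become blocks, numbered by position
#' in `a` (the reference order). Genomes should be IR-reduced first (see
#' [stripSecondIR()]).
#'
#' @param a,b [PlastomeRecord-class] or sequences.
#' @param k anchor k-mer size (default 21).
#' @param minBlockLen minimum block span in bp (default 500).
#' @param maxAnchorGap maximum gap between chained anchors, bp (default
#'   2000).
#' @return data.frame of blocks: `block_id`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, `orientation` (`+`/`-`), `anchor_count`.
#' @export
buildBlocks <- function(a, b, k = 21, minBlockLen = 500,
                        maxAnchorGap = 2000) {
  sa <- seqChar(a); sb <- seqChar(b)
  nb <- nchar(sb)
  ka <- seqKmers(sa, k)
  kbf <- seqKmers(sb, k)
  kbr <- seqKmers(revComp(sb), k)
  uniq <- function(x) !(duplicated(x) | duplicated(x, fromLast = TRUE))
  uA <- which(uniq(ka))
  uBf <- which(uniq(kbf))
  uBr <- which(uniq(kbr))
  ambiguous <- intersect(unique(kbf), unique(kbr))

  mkAnchors <- function(posB, kmersB, strand) {
    m <- match(ka[uA], kmersB[posB])
    sel <- !is.na(m)
    if (!any(sel)) return(NULL)
    pa <- uA[sel]
    pbi <- posB[m[sel]]
    drop <- ka[pa] %in% ambiguous
    pa <- pa[!drop]; pbi <- pbi[!drop]
    if (!length(pa)) return(NULL)
    pb <- if (strand == "+") pbi else nb - pbi - k + 2L
    data.frame(pa = pa, pb = pb, strand = strand)
  }
  anchors <- rbind(mkAnchors(uBf, kbf, "+"), mkAnchors(uBr, kbr, "-"))
  empty <- data.frame(block_id = integer(), a_start = integer(),
                      a_end = integer(), b_start = integer(),
                      b_end = integer(), orientation = character(),
                      anchor_count = integer())
  if (is.null(anchors) || !nrow(anchors)) {
    warning("no unique shared anchors between the two genomes")
    return(empty)
  }
  anchors <- anchors[order(anchors$pa), , drop = FALSE]
  n <- nrow(anchors)
  if (n == 1L) {
    brk <- TRUE
  } else {
    dpa <- diff(anchors$pa)
    dpb <- diff(anchors$pb)
    sameStrand <- anchors$strand[-1] == anchors$strand[-n]
    okB <- ifelse(anchors$strand[-1] == "+",
                  dpb > 0L & dpb <= maxAnchorGap,
                  dpb < 0L & -dpb <= maxAnchorGap)
    brk <- c(TRUE, !(sameStrand & dpa <= maxAnchorGap & okB))
  }
  grp <- cumsum(brk)
  rows <- lapply(split(seq_len(n), grp), function(ii) {
    pa <- anchors$pa[ii]; pb <- anchors$pb[ii]
    span <- max(pa) + k - 1L - min(pa) + 1L
    if (span < minBlockLen) return(NULL)
    data.frame(a_start = min(pa), a_end = max(pa) + k - 1L,
               b_start = min(pb), b_end = max(pb) + k - 1L,
               orientation = anchors$strand[ii[1]],
               anchor_count = length(ii))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no chain reached the minimum block length")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$a_start), , drop = FALSE]
  out <- cbind(block_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Signed permutation of synteny blocks
#'
#' Orders blocks by their position in genome `b` and signs each block id
#' by its orientation; block ids are the reference (`a`) order, so the
#' identity arrangement is `(+1, +2, ..., +n)`. The circular permutation
#' is canonicalized by rotating block 1 to the front when present.
#'
#' @param blocks data.frame from [buildBlocks()].
#' @return integer vector of signed block ids.
#' @export
signedPermutation <- function(blocks) {
  if (!nrow(blocks)) return(integer())
  o <- order(blocks$b_start)
  p <- ifelse(blocks$orientation[o] == "+",
              blocks$block_id[o], -blocks$block_id[o])
  at <- which(abs(p) == 1L)
  if (length(at) == 1L && at != 1L)
    p <- c(p[at:length(p)], p[seq_len(at - 1L)])
  as.integer(p)
}

#' Breakpoint distance of a signed circular permutation
#'
#' Counts adjacencies (including the circular closure) that are not
#' consecutive-and-consistently-signed in the identity arrangement. The
#' convention is orientation-symmetric: reversing the whole genome gives
#' distance 0.
#'
#' @param perm integer vector of signed block ids (each of 1..n once).
#' @return integer breakpoint count.
#' @examples
#' breakpointDistance(c(1, 2, 3))    # 0
#' breakpointDistance(c(1, -2, 3))   # 2
#' breakpointDistance(c(-3, -2, -1)) # 0 (whole-genome reversal)
#' @export
breakpointDistance <- function(perm) {
  n <- length(perm)
  if (n == 0L) return(0L)
  stopifnot(setequal(abs(perm), seq_len(n)))
  nxt <- function(x) {
    if (x > 0) { if (x == n) 1L else x + 1L }
    else { if (x == -1L) -n else x + 1L }
  }
  pairs <- cbind(perm, c(perm[-1], perm[1]))
  conserved <- apply(pairs, 1, function(ab)
    nxt(ab[1]) == ab[2] || nxt(-ab[2]) == -ab[1])
  sum(!conserved)
}

#' Cluster genomes into structural types by signed permutation
#'
#' Genomes sharing an identical signed block permutation (against a common
#' reference) form one structural type. Genome ids are sorted before
#' labelling, so type letters are stable across input orders: the first
#' distinct arrangement (in sorted-id order) is type A, the next B, and so
#' on.
#'
#' @param permutations named list of signed permutations (one per genome,
#'   all against the same reference).
#' @return list with `assignments` (data.frame `genome`, `type`) and
#'   `types` (data.frame `type`, `n`, `members`, `arrangement`).
#' @export
classifyStructuralTypes <- function(permutations) {
  stopifnot(length(permutations) > 0, !is.null(names(permutations)))
  ids <- sort(names(permutations))
  sig <- vapply(permutations[ids], paste, character(1), collapse = ",")
  usig <- unique(sig)
  type <- LETTERS[match(sig, usig)]
  assignments <- data.frame(genome = ids, type = type)
  types <- do.call(rbind, lapply(seq_along(usig), function(k) {
    data.frame(type = LETTERS[k], n = sum(sig == usig[k]),
               members = paste(ids[sig == usig[k]], collapse = ","),
               arrangement = usig[k])
  }))
  rownames(types) <- NULL
  list(assignments = assignments, types = types)
}
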