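## Nonredundant non-tandem repeat cataloguing and gene-context hotspots.

#' Find nonredundant repeat units (direct and inverted)
#'
#' Reports every maximal exact repeated pair of length at least `minLen`
#' (default 30 bp), in direct and inverted orientation, with
#' non-overlapping copies (self-overlapping, tandem-like matches are
#' excluded). A copy wholly contained within a copy of a longer unit at
#' the same locus is absorbed into the longer maximal match by
#' construction. Pairs are grouped into units by their canonical sequence
#' (the lexicographic minimum of a copy and its reverse complement); the
#' `+` strand copy equals the unit representative, the `-` strand copy its
#' reverse complement. With `excludeIr`, the genome-wide inverted-repeat
#' arm pair is removed first by analysing the IR-reduced sequence (see
#' [stripSecondIR()]), so the catalog reflects dispersed repeats, not the
#' quadripartite architecture.
#'
#' @param record [PlastomeRecord-class] (or character/DNAString sequence).
#' @param minLen minimum repeat unit length, bp.
#' @param excludeIr remove the genome-wide IR pair before cataloguing.
#' @param partition optional precomputed
#'   [QuadripartitePartition-class] used when `excludeIr = TRUE`.
#' @return a [RepeatCatalog-class].
#' @export
findRepeats <- function(record, minLen = 30, excludeIr = FALSE,
                        partition = NULL) {
  id <- if (methods::is(record, "PlastomeRecord")) plastomeId(record)
        else "sequence"
  if (excludeIr) {
    if (!methods::is(record, "PlastomeRecord"))
      stop("excludeIr requires a PlastomeRecord")
    if (is.null(partition)) partition <- detectInvertedRepeat(record)
    record <- stripSecondIR(record, partition)
  }
  s <- seqChar(record)
  if (nchar(s) < 2L * minLen) stop("sequence shorter than 2*minLen")
  pairs <- maximalRepeatPairs(s, as.integer(minLen))
  buildRepeatCatalog(id, s, pairs, as.integer(minLen))
}

buildRepeatCatalog <- function(id, s, pairs, minLen) {
  if (!nrow(pairs)) {
    return(new("RepeatCatalog", genomeId = id,
               genomeLength = nchar(s), minLength = minLen,
               units = data.frame(unit_id = character(),
                                  length = integer(),
                                  representative = character()),
               copies = data.frame(unit_id = character(),
                                   start = integer(), end = integer(),
                                   strand = character()),
               pairs = pairs))
  }
  ## enumerate copies with their sequences
  copy1 <- substr(rep(s, nrow(pairs)), pairs$start1, pairs$end1)
  copy2 <- ifelse(pairs$strand == "+",
                  substr(rep(s, nrow(pairs)), pairs$start2, pairs$end2),
                  vapply(seq_len(nrow(pairs)), function(r)
                    revComp(substr(s, pairs$start2[r], pairs$end2[r])),
                    character(1)))
  ## copy2 equals copy1 by construction; canonical unit key
  canon <- vapply(copy1, function(x) min(x, revComp(x)), character(1),
                  USE.NAMES = FALSE)
  cp <- data.frame(
    start = c(pairs$start1, pairs$start2),
    end = c(pairs$end1, pairs$end2),
    seq = c(copy1, copy1),
    pair_strand = c(rep("+", nrow(pairs)), pairs$strand),
    canon = c(canon, canon))
  ## the sequence at the second locus (genomic forward strand)
  cp$fwd <- c(copy1,
              vapply(seq_len(nrow(pairs)), function(r)
                substr(s, pairs$start2[r], pairs$end2[r]), character(1)))
  cp <- cp[!duplicated(cp[, c("start", "end", "canon")]), , drop = FALSE]

  ukeys <- unique(cp$canon[order(-nchar(cp$canon), cp$start)])
  unit_id <- paste0("R", seq_along(ukeys))
  names(unit_id) <- ukeys

  ## representative: forward-strand sequence of the first (leftmost) copy
  reps <- vapply(ukeys, function(kk) {
    sub <- cp[cp$canon == kk, , drop = FALSE]
    sub$fwd[which.min(sub$start)]
  }, character(1))

  cp$unit_id <- unname(unit_id[cp$canon])
  cp$strand <- ifelse(cp$fwd == reps[cp$canon], "+", "-")
  cp <- cp[order(match(cp$unit_id, unit_id), cp$start), , drop = FALSE]

  units <- data.frame(unit_id = unname(unit_id),
                      length = nchar(ukeys),
                      representative = unname(reps))
  copies <- data.frame(unit_id = cp$unit_id, start = cp$start,
                       end = cp$end, strand = cp$strand)
  rownames(copies) <- NULL
  new("RepeatCatalog", genomeId = id, genomeLength = nchar(s),
      minLength = minLen, units = units, copies = copies, pairs = pairs)
}

#' Localize repeat copies relative to genes
#'
#' A copy overlapping a gene is `internal` to it (distance 0; ties broken
#' by larger overlap, then lexicographically smaller gene name). Otherwise
#' the copy is `upstream` (on the gene's 5' side, strand-aware) or
#' `downstream` of the nearest gene within `upstreamWindow` bp, or
#' `intergenic_other` when no gene is that close. Distance is the number
#' of bases strictly between copy and gene. Equidistant genes tie-break to
#' the lexicographically smaller name.
#'
#' @param catalog [RepeatCatalog-class].
#' @param features exon-level feature GRanges.
#' @param upstreamWindow context window, bp (default 1000).
#' @return data.frame: one row per copy with `unit_id`, `start`, `end`,
#'   `strand`, `context`, `anchor_gene`, `distance`.
#' @export
localizeRepeats <- function(catalog, features, upstreamWindow = 1000) {
  stopifnot(methods::is(catalog, "RepeatCatalog"))
  cp <- repeatCopies(catalog)
  L <- catalog@genomeLength
  loci <- geneLoci(features, L)
  out <- cp
  out$context <- rep("intergenic_other", nrow(cp))
  out$anchor_gene <- rep(NA_character_, nrow(cp))
  out$distance <- rep(NA_integer_, nrow(cp))
  if (!nrow(cp)) return(out)
  if (!nrow(loci)) return(out)
  for (r in seq_len(nrow(cp))) {
    cs <- cp$start[r]; ce <- cp$end[r]
    ## overlap (internal): circular-aware interval intersection
    ovl <- pmin(ce, loci$end) - pmax(cs, loci$start) + 1L
    hit <- which(ovl > 0L)
    if (length(hit)) {
      hit <- hit[order(-ovl[hit], loci$gene[hit])]
      out$context[r] <- "internal"
      out$anchor_gene[r] <- loci$gene[hit[1]]
      out$distance[r] <- 0L
      next
    }
    ## gaps on both sides of each gene
    gapBefore <- (loci$start - ce - 1L) %% L  # copy upstream of gene start
    gapAfter <- (cs - loci$end - 1L) %% L     # copy downstream of gene end
    ## strand-aware: 5' side of a + gene is before its start; of a - gene
    ## after its end
    d5 <- ifelse(loci$strand == "-", gapAfter, gapBefore)
    d3 <- ifelse(loci$strand == "-", gapBefore, gapAfter)
    cand <- data.frame(gene = loci$gene,
                       context = rep(c("upstream", "downstream"),
                                     each = nrow(loci)),
                       distance = c(d5, d3))
    cand <- cand[cand$distance < upstreamWindow, , drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(cand$distance, cand$gene), , drop = FALSE]
      out$context[r] <- cand$context[1]
      out$anchor_gene[r] <- cand$gene[1]
      out$distance[r] <- cand$distance[1]
    }
  }
  out
}

#' Hotspot summary of repeat localizations
#'
#' Counts repeat copies in focal contexts (by default internal or
#' upstream) per anchor gene, and expresses each as a percentage of all
#' copies in the input (two decimals). Localizations may be pooled across
#' genomes before summarizing.
#'
#' @param localizations data.frame from [localizeRepeats()] (possibly
#'   row-bound across genomes), or any data.frame with `context` and
#'   `anchor_gene` columns.
#' @param focalContexts contexts counted toward a gene's hotspot tally.
#' @return data.frame: `gene`, `copies`, `percent`, sorted by count; the
#'   attribute `total` holds the overall copy count.
#' @examples
#' loc <- data.frame(context = rep(c("internal", "intergenic_other"),
#'                                 c(3, 7)),
#'                   anchor_gene = rep(c("accD", NA), c(3, 7)))
#' hotspotSummary(loc)  # accD 30.00%
#' @export
hotspotSummary <- function(localizations,
                           focalContexts = c("internal", "upstream")) {
  total <- nrow(localizations)
  if (total == 0L) {
    warning("no repeat copies; all percentages zero")
    out <- data.frame(gene = character(), copies = integer(),
                      percent = numeric())
    attr(out, "total") <- 0L
    return(out)
  }
  foc <- localizations[localizations$context %in% focalContexts &
                         !is.na(localizations$anchor_gene), , drop = FALSE]
  tab <- table(foc$anchor_gene)
  out <- data.frame(gene = as.character(names(tab)),
                    copies = as.integer(tab),
                    percent = round(100 * as.integer(tab) / total, 2),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$copies, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
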