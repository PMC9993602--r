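## Quadripartite architecture: IR detection, junction contexts, boundary
## comparison and the per-genome partition table.

#' Detect the inverted-repeat pair and partition a plastome
#'
#' Finds the disjoint segment pair maximizing length such that one segment
#' is the reverse complement of the other (exact by default), then labels
#' the longer inter-arm arc LSC and the shorter SSC. In the canonical
#' reading LSC-IRb-SSC-IRa, IRb is the arm whose downstream junction abuts
#' the SSC. Detection seeds on k-mers shared between the sequence and its
#' reverse complement and merges collinear seed runs, so an exact repeat is
#' recovered at precisely its maximal extent; assembled plastome IRs are
#' near-perfect copies, hence `maxMismatchRate = 0` by default. With a
#' positive rate, collinear runs on one diagonal are bridged when the
#' bridged bases keep the arm-wide mismatch fraction within the rate.
#'
#' @param record circular [PlastomeRecord-class].
#' @param minIrLen minimum arm length to report (bp, default 100); below
#'   this the genome is classed `ir_free`.
#' @param maxMismatchRate tolerated mismatch fraction within an arm
#'   (default 0, exact).
#' @param residualThreshold arms shorter than this (default 2000 bp) are
#'   classed `residual_ir`, the depleted regime of heavily contracted IRs.
#' @param seedK seed k-mer size (default 31; reduced to `minIrLen` when
#'   that is smaller).
#' @return a [QuadripartitePartition-class].
#' @export
detectInvertedRepeat <- function(record, minIrLen = 100,
                                 maxMismatchRate = 0,
                                 residualThreshold = 2000,
                                 seedK = 31) {
  stopifnot(methods::is(record, "PlastomeRecord"))
  if (!isCircularGenome(record))
    stop("quadripartite partition is defined on circular genomes only")
  L <- plastomeLength(record)
  if (L < 2L * minIrLen + 2L)
    stop("genome shorter than 2*minIrLen + 2")
  s <- seqChar(record)
  k <- min(as.integer(seedK), as.integer(minIrLen))

  best <- bestInvertedPair(s, k, minIrLen, maxMismatchRate)
  ## an arm abutting the linear boundary may be truncated by the origin:
  ## retry in a rotated frame and keep the longer solution
  if (is.null(best) || best$start1 == 1L || best$end2 == L) {
    shift <- L %/% 2L
    s2 <- paste0(substr(s, shift + 1L, L), substr(s, 1L, shift))
    alt <- bestInvertedPair(s2, k, minIrLen, maxMismatchRate)
    if (!is.null(alt) && (is.null(best) || alt$length > best$length)) {
      alt$start1 <- modPos(alt$start1 + shift, L)
      alt$start2 <- modPos(alt$start2 + shift, L)
      alt$end1 <- alt$start1 + alt$length - 1L
      alt$end2 <- alt$start2 + alt$length - 1L
      best <- alt
    }
  }

  if (is.null(best)) {
    return(new("QuadripartitePartition",
               genomeLength = L, irLength = 0L,
               structureClass = "ir_free",
               lsc = c(1L, L), ssc = c(NA_integer_, NA_integer_),
               irb = c(NA_integer_, NA_integer_),
               ira = c(NA_integer_, NA_integer_)))
  }
  buildPartition(best, L, residualThreshold)
}

bestInvertedPair <- function(s, k, minIrLen, maxMismatchRate) {
  pairs <- invertedMaximalPairs(s, k)
  if (maxMismatchRate > 0 && nrow(pairs) > 1L)
    pairs <- bridgeInvertedPairs(s, pairs, maxMismatchRate)
  pairs <- pairs[pairs$length >= minIrLen, , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  pairs <- pairs[order(-pairs$length, pairs$start1), , drop = FALSE]
  as.list(pairs[1L, ])
}

## bridge exact runs that lie on the same anti-diagonal (start1+end2 and
## end1+start2 invariants) when the implied mismatches stay within rate
bridgeInvertedPairs <- function(s, pairs, rate) {
  ad <- pairs$start1 + pairs$end2  # constant along one inverted diagonal
  out <- pairs
  for (a in unique(ad[duplicated(ad)])) {
    grp <- pairs[ad == a, , drop = FALSE]
    grp <- grp[order(grp$start1), , drop = FALSE]
    s1 <- grp$start1[1]; e1 <- grp$end1[nrow(grp)]
    merged_len <- e1 - s1 + 1L
    mism <- merged_len - sum(grp$length)
    if (mism >= 0 && mism / merged_len <= rate) {
      out <- rbind(out, data.frame(
        start1 = s1, end1 = e1,
        start2 = grp$start2[nrow(grp)], end2 = grp$end2[1],
        length = merged_len, strand = "-"))
    }
  }
  out
}

buildPartition <- function(best, L, residualThreshold) {
  a1 <- best$start1; a2 <- best$end1
  b1 <- best$start2; b2 <- best$end2
  irl <- best$length
  arc1 <- (b1 - a2 - 1L) %% L   # forward arc A -> B
  arc2 <- (a1 - b2 - 1L) %% L   # forward arc B -> A (may wrap)
  mk <- function(st, len) {
    if (len == 0L) return(c(NA_integer_, NA_integer_))
    c(modPos(st, L), modPos(st, L) + len - 1L)
  }
  ivA <- c(modPos(a1, L), modPos(a1, L) + irl - 1L)
  ivB <- c(modPos(b1, L), modPos(b1, L) + irl - 1L)
  iv1 <- mk(a2 + 1L, arc1)
  iv2 <- mk(b2 + 1L, arc2)
  if (arc1 >= arc2) {  # arc1 is LSC: order LSC(arc1) not canonical; SSC=arc2
    lsc <- iv1; ssc <- iv2
    ## SSC follows arm B, so B is IRb (its downstream junction abuts SSC)
    irb <- ivB; ira <- ivA
  } else {
    lsc <- iv2; ssc <- iv1
    irb <- ivA; ira <- ivB
  }
  cls <- if (irl < residualThreshold) "residual_ir" else "quadripartite"
  new("QuadripartitePartition",
      genomeLength = L, irLength = as.integer(irl),
      structureClass = cls,
      lsc = as.integer(lsc), ssc = as.integer(ssc),
      irb = as.integer(irb), ira = as.integer(ira))
}

## gene-locus table from exon-level features: one row per (gene, copy)
geneLoci <- function(features, L = NULL) {
  if (length(features) == 0L)
    return(data.frame(gene = character(), copy = integer(),
                      start = integer(), end = integer(),
                      strand = character(), kind = character()))
  key <- paste(features$gene, features$copy, sep = "\r")
  st <- GenomicRanges::start(features)
  en <- GenomicRanges::end(features)
  sd <- as.character(GenomicRanges::strand(features))
  kd <- features$kind
  gn <- features$gene
  cp <- features$copy
  idx <- split(seq_along(features), key)
  rows <- lapply(idx, function(ii) data.frame(
    gene = gn[ii[1]], copy = cp[ii[1]],
    start = min(st[ii]), end = max(en[ii]),
    strand = sd[ii[1]], kind = kd[ii[1]]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene context of the four quadripartite junctions
#'
#' For each junction (JLB = LSC/IRb, JSB = IRb/SSC, JSA = SSC/IRa,
#' JLA = IRa/LSC) reports the gene spanning the boundary, if any, else the
#' nearest gene on each side with its circular distance in bp. The junction
#' position is the last base of the upstream region; a gene ending exactly
#' there is nearest at distance 0, not spanning.
#'
#' @param partition a [QuadripartitePartition-class], not `ir_free`.
#' @param features exon-level feature GRanges (see
#'   [PlastomeRecord-class]).
#' @return data.frame with one row per junction: `junction`, `position`,
#'   `spanning_gene`, `left_gene`, `left_dist`, `right_gene`,
#'   `right_dist`.
#' @export
junctionContext <- function(partition, features) {
  stopifnot(methods::is(partition, "QuadripartitePartition"))
  if (structureClass(partition) == "ir_free")
    stop("junction context undefined for ir_free genomes")
  L <- partition@genomeLength
  if (length(features) == 0L)
    warning("no features supplied; junction contexts carry no genes")
  loci <- geneLoci(features, L)
  jpos <- c(JLB = partition@lsc[2], JSB = partition@irb[2],
            JSA = partition@ssc[2], JLA = partition@ira[2])
  jpos <- vapply(jpos, function(p) modPos(p, L), integer(1))

  rows <- lapply(names(jpos), function(j) {
    p <- jpos[[j]]
    span <- NA_character_
    ldist <- rdist <- NA_integer_
    lgene <- rgene <- NA_character_
    if (nrow(loci)) {
      ## covering both p and p+1 (circularly) means spanning
      covers <- function(pos) {
        off <- (pos - loci$start) %% L
        off <= (loci$end - loci$start)
      }
      sp <- covers(p) & covers(modPos(p + 1L, L))
      if (any(sp)) span <- loci$gene[which(sp)[1]]
      side <- loci[!sp, , drop = FALSE]
      if (nrow(side)) {
        gl <- (p - side$end) %% L
        gr <- (side$start - p - 1L) %% L
        il <- which.min(gl); ir <- which.min(gr)
        lgene <- side$gene[il]; ldist <- gl[il]
        rgene <- side$gene[ir]; rdist <- gr[ir]
      }
    }
    data.frame(junction = j, position = p, spanning_gene = span,
               left_gene = lgene, left_dist = ldist,
               right_gene = rgene, right_dist = rdist)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## genes wholly contained in either IR arm (set of gene names)
irResidentGenes <- function(partition, features) {
  L <- partition@genomeLength
  loci <- geneLoci(features, L)
  if (!nrow(loci)) return(character())
  contained <- function(arm) {
    if (any(is.na(arm))) return(rep(FALSE, nrow(loci)))
    off <- (loci$start - modPos(arm[1], L)) %% L
    off + (loci$end - loci$start) <= (arm[2] - arm[1])
  }
  sel <- contained(partition@irb) | contained(partition@ira)
  unique(loci$gene[sel])
}

## which single-copy region holds a gene (first locus wins)
sideOfGene <- function(gene, partition, features) {
  L <- partition@genomeLength
  loci <- geneLoci(features, L)
  loci <- loci[loci$gene == gene, , drop = FALSE]
  if (!nrow(loci)) return(NA_character_)
  inReg <- function(iv, s) {
    if (any(is.na(iv))) return(FALSE)
    off <- (s - modPos(iv[1], L)) %% L
    off <= (iv[2] - iv[1])
  }
  for (r in seq_len(nrow(loci))) {
    if (inReg(partition@ssc, loci$start[r])) return("SSC")
    if (inReg(partition@lsc, loci$start[r])) return("LSC")
  }
  "LSC"
}

#' Compare IR boundaries between two annotated genomes
#'
#' Genes wholly inside an IR arm of the target but not of the reference are
#' gains by the IR (expansion); the converse are losses (contraction).
#' Because both IR copies move together, gains/losses on the LSC side are
#' reported at JLB and JLA and those on the SSC side at JSB and JSA; a
#' gene's side is read from the genome in which it is single-copy.
#'
#' @param target,reference each a `list(partition =, features =)` pair for
#'   one genome; shared gene nomenclature is required.
#' @return data.frame: `junction`, `direction`
#'   (expansion/contraction/unchanged), `genes_gained_by_ir`,
#'   `genes_lost_by_ir` (comma-separated).
#' @export
compareBoundaries <- function(target, reference) {
  tg <- unique(geneLoci(target$features)$gene)
  rg <- unique(geneLoci(reference$features)$gene)
  if (!length(intersect(tg, rg)))
    stop("no shared gene names between target and reference")
  tIR <- irResidentGenes(target$partition, target$features)
  rIR <- irResidentGenes(reference$partition, reference$features)
  gained <- setdiff(intersect(tIR, rg), rIR)
  lost <- setdiff(intersect(rIR, tg), tIR)
  sideG <- vapply(gained, sideOfGene, character(1),
                  partition = reference$partition,
                  features = reference$features)
  sideL <- vapply(lost, sideOfGene, character(1),
                  partition = target$partition,
                  features = target$features)
  jside <- c(JLB = "LSC", JLA = "LSC", JSB = "SSC", JSA = "SSC")
  rows <- lapply(names(jside), function(j) {
    g <- gained[sideG == jside[[j]]]
    l <- lost[sideL == jside[[j]]]
    dir <- if (!length(g) && !length(l)) "unchanged"
           else if (length(g) >= length(l)) "expansion" else "contraction"
    data.frame(junction = j, direction = dir,
               genes_gained_by_ir = paste(sort(g), collapse = ","),
               genes_lost_by_ir = paste(sort(l), collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-genome partition summary table
#'
#' One row per genome: identifier, genome size, LSC/SSC/IR lengths (bp),
#' GC percentage of the whole sequence (two decimals) and structure class.
#'
#' @param records list of [PlastomeRecord-class].
#' @param partitions parallel list of [QuadripartitePartition-class];
#'   computed with default parameters when `NULL`.
#' @param ... passed to [detectInvertedRepeat()] when partitions are
#'   computed here.
#' @return data.frame with columns `id`, `genome_size`, `lsc`, `ssc`,
#'   `ir`, `gc_percent`, `structure_class`.
#' @export
partitionTable <- function(records, partitions = NULL, ...) {
  if (methods::is(records, "PlastomeRecord")) records <- list(records)
  if (is.null(partitions))
    partitions <- lapply(records, detectInvertedRepeat, ...)
  rows <- mapply(function(rec, part) {
    L <- plastomeLength(rec)
    gc <- sum(Biostrings::letterFrequency(plastomeSeq(rec), c("G", "C")))
    ivlen <- function(iv) if (any(is.na(iv))) 0L else iv[2] - iv[1] + 1L
    data.frame(id = plastomeId(rec), genome_size = L,
               lsc = ivlen(part@lsc), ssc = ivlen(part@ssc),
               ir = irLength(part),
               gc_percent = round(100 * gc / L, 2),
               structure_class = structureClass(part))
  }, records, partitions, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
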