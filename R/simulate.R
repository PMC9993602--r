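## Deterministic synthetic-plastome and read-set generator. Every planted
## element (IR arms, genes and their statuses, repeat copies, isomer arms,
## rearrangement scripts) is recorded in a manifest that downstream tests
## use as ground truth.

DNA_BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

randomSeqChars <- function(n, gc = 0.365) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

## random open reading frame: ATG + non-stop codons + TAA, length len (bp),
## base composition matched to the background GC
randomOrf <- function(len, gc = 0.365) {
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- len %/% 3 - 2L
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw <- function(n) {
    m <- matrix(sample(DNA_BASES, 3L * n, replace = TRUE, prob = p),
                nrow = 3L)
    paste0(m[1, ], m[2, ], m[3, ])
  }
  codons <- draw(ncod)
  repeat {
    bad <- which(codons %in% STOP_CODONS)
    if (!length(bad)) break
    codons[bad] <- draw(length(bad))
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Describe one gene for the synthetic generator
#'
#' @param name gene symbol.
#' @param kind `"PCG"`, `"tRNA"` or `"rRNA"`.
#' @param exons exon lengths in bp, transcription order (PCG total must be
#'   a multiple of 3).
#' @param introns intron lengths (one fewer than exons).
#' @param strand `"+"` or `"-"`.
#' @param region `"LSC"`, `"SSC"` or `"IR"` (IR genes are planted in IRb
#'   and mirrored into IRa).
#' @return a gene census entry (list).
#' @export
censusEntry <- function(name, kind = "PCG", exons = 900L,
                        introns = integer(), strand = "+",
                        region = "LSC") {
  stopifnot(length(introns) == length(exons) - 1L)
  if (kind == "PCG" && sum(exons) %% 3 != 0)
    stop("PCG '", name, "' exon total not a multiple of 3")
  list(name = name, kind = kind, exons = as.integer(exons),
       introns = as.integer(introns), strand = strand, region = region)
}

#' A default plastome gene census for synthetic genomes
#'
#' A compact census with the landmark genes the analyses anchor on (psbA,
#' matK, rbcL, accD in the LSC; ndhF, ycf1, rps15 in the SSC; rrn16,
#' trnM and intron-bearing rpl2 in the IR), scaled to the IR length: a
#' residual IR holds only trnM, larger IRs also the rRNA and rpl2.
#'
#' @param irLen IR arm length of the target genome (bp).
#' @return list of [censusEntry()] items.
#' @export
defaultGeneCensus <- function(irLen = 0) {
  census <- list(
    censusEntry("psbA", "PCG", 1062L, strand = "+", region = "LSC"),
    censusEntry("matK", "PCG", 1530L, strand = "-", region = "LSC"),
    censusEntry("rpoC1", "PCG", c(453L, 1611L), introns = 738L,
                strand = "-", region = "LSC"),
    censusEntry("atpA", "PCG", 1524L, strand = "-", region = "LSC"),
    censusEntry("rbcL", "PCG", 1428L, strand = "+", region = "LSC"),
    censusEntry("accD", "PCG", 1497L, strand = "+", region = "LSC"),
    censusEntry("ndhF", "PCG", 2220L, strand = "-", region = "SSC"),
    censusEntry("ycf1", "PCG", 1800L, strand = "+", region = "SSC"),
    censusEntry("rps15", "PCG", 273L, strand = "-", region = "SSC"))
  if (irLen >= 300)
    census <- c(census, list(
      censusEntry("trnM", "tRNA", 73L, strand = "+", region = "IR")))
  if (irLen >= 2500)
    census <- c(census, list(
      censusEntry("rrn16", "rRNA", 1491L, strand = "+", region = "IR")))
  if (irLen >= 5000)
    census <- c(census, list(
      censusEntry("rpl2", "PCG", c(393L, 435L), introns = 666L,
                  strand = "-", region = "IR")))
  census
}

#' Specify a synthetic plastome
#'
#' The generated genome is LSC + IRb + SSC + IRa (IRa the exact reverse
#' complement of IRb), origin at the LSC start; `irLen = 0` gives an
#' IR-free circle of LSC + SSC. Background composition is i.i.d. with the
#' given GC fraction.
#'
#' @param seed integer RNG seed; the same spec always yields a
#'   byte-identical genome.
#' @param lscLen,sscLen,irLen region lengths in bp (`lscLen >= sscLen`).
#' @param gc background GC fraction (default 0.365, within the observed
#'   plastome range).
#' @param census gene census (list of [censusEntry()]); default scaled to
#'   `irLen`.
#' @param pseudogenes named list: gene -> list(mode, frac) with mode one
#'   of `"truncate"`, `"premature_stop"`, `"fragment"`, `"delete"`
#'   (single-exon genes only).
#' @param repeats list of list(length, starts, strands) dispersed repeat
#'   plants (absolute start positions, strands relative to the first
#'   copy).
#' @param isomerRepeat optional list(length, start, innerGap): an inverted
#'   arm pair with `innerGap` bp between the inner edges.
#' @return list of class `PlastomeSpec`.
#' @export
plastomeSpec <- function(seed, lscLen, sscLen, irLen = 0, gc = 0.365,
                         census = defaultGeneCensus(irLen),
                         pseudogenes = list(), repeats = list(),
                         isomerRepeat = NULL) {
  stopifnot(lscLen >= sscLen, irLen >= 0, gc > 0, gc < 1)
  structure(list(seed = as.integer(seed), lscLen = as.integer(lscLen),
                 sscLen = as.integer(sscLen), irLen = as.integer(irLen),
                 gc = gc, census = census, pseudogenes = pseudogenes,
                 repeats = repeats, isomerRepeat = isomerRepeat),
            class = "PlastomeSpec")
}

## build the planted (genomic-orientation) segment and exon offsets for a
## gene entry; returns NULL planted for deleted genes
buildGeneSegment <- function(entry, plan) {
  if (entry$kind == "PCG") {
    orf <- randomOrf(sum(entry$exons))
    bounds <- cumsum(entry$exons)
    exSeq <- mapply(function(a, b) substr(orf, a, b),
                    c(1L, head(bounds, -1) + 1L), bounds)
  } else {
    exSeq <- vapply(entry$exons, function(l)
      paste(randomSeqChars(l), collapse = ""), character(1))
  }
  query <- paste(exSeq, collapse = "")
  inSeq <- vapply(entry$introns, function(l)
    paste(randomSeqChars(l), collapse = ""), character(1))

  status <- "intact"
  if (!is.null(plan)) {
    if (length(entry$exons) > 1L)
      stop("pseudogene mode on multi-exon gene '", entry$name, "'")
    mode <- plan$mode
    if (mode == "delete") {
      status <- "absent"
      return(list(query = query, exonSeqs = exSeq, planted = NULL,
                  status = status))
    } else if (mode == "truncate") {
      frac <- plan$frac %||% 0.5
      exSeq[1] <- substr(exSeq[1], 1L, round(frac * nchar(exSeq[1])))
      status <- "pseudogene_truncated"
    } else if (mode == "fragment") {
      frac <- plan$frac %||% 0.1
      exSeq[1] <- substr(exSeq[1], 1L, round(frac * nchar(exSeq[1])))
      status <- "fragment"
    } else if (mode == "premature_stop") {
      ncod <- nchar(exSeq[1]) %/% 3L
      at <- (ncod %/% 2L) * 3L + 1L
      substr(exSeq[1], at, at + 2L) <- "TAA"
      status <- "pseudogene_premature_stop"
    } else stop("unknown pseudogene mode: ", mode)
  }

  ## interleave exons and introns (transcription orientation)
  parts <- character(0)
  exOff <- matrix(0L, nrow = length(exSeq), ncol = 2)
  pos <- 0L
  for (i in seq_along(exSeq)) {
    exOff[i, ] <- c(pos + 1L, pos + nchar(exSeq[i]))
    parts <- c(parts, exSeq[i])
    pos <- pos + nchar(exSeq[i])
    if (i < length(exSeq)) {
      parts <- c(parts, inSeq[i])
      pos <- pos + nchar(inSeq[i])
    }
  }
  seg <- paste(parts, collapse = "")
  if (entry$strand == "-") {
    n <- nchar(seg)
    seg <- revComp(seg)
    exOff <- cbind(n - exOff[, 2] + 1L, n - exOff[, 1] + 1L)
  }
  list(query = query, exonSeqs = exSeq, planted = seg,
       exonOffsets = exOff, status = status)
}

#' Generate a synthetic plastome with ground-truth manifest
#'
#' Builds the background sequence, places the census genes region by
#' region with even intergenic spacing, applies the pseudogene plan,
#' plants dispersed repeats and the optional isomer arm pair, copies IRb
#' into IRa as its exact reverse complement (mirroring IR genes as second
#' copies), and finally blocks chance single-base extension at the edges
#' of every planted repeated element so that planted coordinates are the
#' maximal-match coordinates.
#'
#' @param spec a [plastomeSpec()].
#' @return list: `record` ([PlastomeRecord-class] with features),
#'   `manifest` (named list of every planted coordinate and status,
#'   including the full-length `queries` for gene calling).
#' @export
generatePlastome <- function(spec) {
  stopifnot(inherits(spec, "PlastomeSpec"))
  withSeed(spec$seed, generatePlastomeImpl(spec))
}

generatePlastomeImpl <- function(spec) {
  L <- spec$lscLen + spec$sscLen + 2L * spec$irLen
  hasIR <- spec$irLen > 0L
  regStart <- c(LSC = 1L,
                IR = spec$lscLen + 1L,
                SSC = spec$lscLen + spec$irLen + 1L)
  regLen <- c(LSC = spec$lscLen, IR = spec$irLen, SSC = spec$sscLen)
  if (!hasIR) { regStart[["SSC"]] <- spec$lscLen + 1L }

  v <- randomSeqChars(L, spec$gc)
  protected <- logical(L)

  genesDf <- NULL; exonsDf <- NULL
  queries <- character(); kinds <- character()
  exonQueries <- list()

  minGap <- 50L
  for (region in c("LSC", "IR", "SSC")) {
    entries <- Filter(function(e) e$region ==
                        if (region == "IR") "IR" else region, spec$census)
    if (region == "IR" && !hasIR) {
      if (length(entries)) stop("IR genes in an IR-free spec")
      next
    }
    if (!length(entries)) next
    built <- lapply(entries, function(e)
      buildGeneSegment(e, spec$pseudogenes[[e$name]]))
    planted <- !vapply(built, function(b) is.null(b$planted), logical(1))
    for (i in seq_along(entries)) {
      queries[[entries[[i]]$name]] <- built[[i]]$query
      kinds[[entries[[i]]$name]] <- entries[[i]]$kind
      exonQueries[[entries[[i]]$name]] <- unname(built[[i]]$exonSeqs)
    }
    pl <- built[planted]; en <- entries[planted]
    foot <- vapply(pl, function(b) nchar(b$planted), integer(1))
    free <- regLen[[region]] - sum(foot)
    ngap <- length(pl) + 1L
    if (free < minGap * ngap)
      stop("infeasible placement in ", region, ": genes ",
           paste(vapply(en, `[[`, character(1), "name"), collapse = ","),
           " need ", sum(foot) + minGap * ngap, " bp, region has ",
           regLen[[region]])
    gap <- free %/% ngap
    pos <- regStart[[region]] - 1L
    for (i in seq_along(pl)) {
      pos <- pos + gap
      gs <- pos + 1L; ge <- pos + foot[i]
      seg <- strsplit(pl[[i]]$planted, "")[[1]]
      v[gs:ge] <- seg
      protected[gs:ge] <- TRUE
      exOff <- pl[[i]]$exonOffsets
      nex <- nrow(exOff)
      rank <- seq_len(nex)
      if (en[[i]]$strand == "-") rank <- rev(rank)
      exonsDf <- rbind(exonsDf, data.frame(
        gene = en[[i]]$name, copy = 1L, exon_rank = rank,
        start = gs + exOff[, 1] - 1L, end = gs + exOff[, 2] - 1L,
        strand = en[[i]]$strand, kind = en[[i]]$kind,
        region = region))
      genesDf <- rbind(genesDf, data.frame(
        gene = en[[i]]$name, kind = en[[i]]$kind,
        strand = en[[i]]$strand, status = pl[[i]]$status,
        start = gs, end = ge, region = region))
      pos <- ge
    }
  }
  ## deleted genes still appear in the manifest
  for (e in spec$census) {
    pln <- spec$pseudogenes[[e$name]]
    if (!is.null(pln) && pln$mode == "delete")
      genesDf <- rbind(genesDf, data.frame(
        gene = e$name, kind = e$kind, strand = e$strand,
        status = "absent", start = NA_integer_, end = NA_integer_,
        region = e$region))
  }

  ## dispersed repeat plants
  repeatsDf <- NULL
  plantPairs <- list()   # for edge blocking: list(iv1, iv2, inverted)
  for (ri in seq_along(spec$repeats)) {
    rp <- spec$repeats[[ri]]
    len <- as.integer(rp$length)
    starts <- as.integer(rp$starts)
    strands <- rp$strands %||% rep("+", length(starts))
    unit <- randomSeqChars(len, spec$gc)
    ivs <- cbind(starts, starts + len - 1L)
    for (ci in seq_along(starts)) {
      iv <- ivs[ci, ]
      if (iv[2] > L) stop("repeat plant ", ri, " copy ", ci,
                          " exceeds genome")
      if (hasIR && iv[1] <= regStart[["SSC"]] - 1L &&
          iv[2] >= regStart[["IR"]])
        stop("repeat plant ", ri, " copy ", ci, " overlaps the IR arm")
      if (hasIR && iv[2] > spec$lscLen + spec$irLen + spec$sscLen)
        stop("repeat plant ", ri, " copy ", ci, " overlaps IRa")
      if (any(protected[iv[1]:iv[2]]))
        stop("repeat plant ", ri, " copy ", ci,
             " conflicts with a planted gene or repeat")
      seg <- if (strands[ci] == "+") unit else
        strsplit(revComp(paste(unit, collapse = "")), "")[[1]]
      v[iv[1]:iv[2]] <- seg
      protected[iv[1]:iv[2]] <- TRUE
      repeatsDf <- rbind(repeatsDf, data.frame(
        unit = paste0("P", ri), length = len,
        start = iv[1], end = iv[2], strand = strands[ci]))
    }
    for (ci in seq_len(length(starts) - 1L))
      for (cj in (ci + 1L):length(starts))
        plantPairs[[length(plantPairs) + 1L]] <- list(
          a = ivs[ci, ], b = ivs[cj, ],
          inverted = strands[ci] != strands[cj])
  }

  ## isomer arm pair
  isomerManifest <- NULL
  if (!is.null(spec$isomerRepeat)) {
    ir <- spec$isomerRepeat
    len <- as.integer(ir$length)
    a1 <- as.integer(ir$start); a2 <- a1 + len - 1L
    b1 <- a2 + as.integer(ir$innerGap) + 1L; b2 <- b1 + len - 1L
    if (b2 > L) stop("isomer arm pair exceeds genome")
    if (any(protected[c(a1:a2, b1:b2)]))
      stop("isomer arm pair conflicts with planted genes/repeats")
    unit <- randomSeqChars(len, spec$gc)
    v[a1:a2] <- unit
    v[b1:b2] <- strsplit(revComp(paste(unit, collapse = "")), "")[[1]]
    protected[c(a1:a2, b1:b2)] <- TRUE
    plantPairs[[length(plantPairs) + 1L]] <- list(
      a = c(a1, a2), b = c(b1, b2), inverted = TRUE)
    isomerManifest <- list(armA = c(a1, a2), armB = c(b1, b2),
                           length = len, innerGap = as.integer(ir$innerGap))
  }

  ## IRa = reverse complement of IRb; mirror IR genes as copy 2
  if (hasIR) {
    irbS <- regStart[["IR"]]; irbE <- irbS + spec$irLen - 1L
    iraS <- L - spec$irLen + 1L; iraE <- L
    irb <- v[irbS:irbE]
    v[iraS:iraE] <- rev(unname(COMP[irb]))
    protected[iraS:iraE] <- protected[iraS:iraE] | rev(protected[irbS:irbE])
    if (!is.null(exonsDf)) {
      mir <- exonsDf[exonsDf$region == "IR", , drop = FALSE]
      if (nrow(mir)) {
        ns <- iraS + (irbE - mir$end)
        ne <- iraS + (irbE - mir$start)
        mir$start <- ns; mir$end <- ne
        mir$strand <- ifelse(mir$strand == "+", "-", "+")
        mir$copy <- 2L
        exonsDf <- rbind(exonsDf, mir)
        mg <- genesDf[genesDf$region == "IR", , drop = FALSE]
        mg2 <- mg
        mg2$start <- iraS + (irbE - mg$end)
        mg2$end <- iraS + (irbE - mg$start)
        mg2$strand <- ifelse(mg$strand == "+", "-", "+")
        genesDf <- rbind(genesDf, mg2)
      }
    }
    plantPairs[[length(plantPairs) + 1L]] <- list(
      a = c(irbS, irbE), b = c(iraS, iraE), inverted = TRUE)
  }

  ## block single-base chance extension at planted repeated-element edges;
  ## iterate to a fixed point since fixes at shared flank positions can
  ## interact
  for (pass in 1:10) {
    v0 <- v
    for (pp in plantPairs)
      v <- blockEdgeExtension(v, pp$a, pp$b, pp$inverted, protected, L)
    if (identical(v, v0)) break
  }

  record <- PlastomeRecord(paste0("synth", spec$seed),
                           paste(v, collapse = ""), circular = TRUE,
                           features = exonsToGRanges(exonsDf,
                                                     paste0("synth",
                                                            spec$seed)))
  manifest <- list(
    seed = spec$seed, length = L, lsc = spec$lscLen, ssc = spec$sscLen,
    ir = spec$irLen, gc = spec$gc,
    regions = data.frame(
      region = if (hasIR) c("lsc", "irb", "ssc", "ira") else "lsc",
      start = if (hasIR) c(1L, regStart[["IR"]], regStart[["SSC"]],
                           L - spec$irLen + 1L) else 1L,
      end = if (hasIR) c(spec$lscLen, regStart[["IR"]] + spec$irLen - 1L,
                         regStart[["SSC"]] + spec$sscLen - 1L, L) else L),
    genes = genesDf, exons = exonsDf,
    queries = queries, kinds = kinds, exonQueries = exonQueries,
    repeats = repeatsDf, isomer = isomerManifest)
  list(record = record, manifest = manifest)
}

## prevent the maximal match containing the planted pair from extending a
## base past the planted edges; mutates unprotected flank bases only
blockEdgeExtension <- function(v, a, b, inverted, protected, L) {
  fix <- function(v, posKeep, posFix, want) {
    ## ensure v[posFix] != want; mutate only unprotected positions
    if (identical(v[posFix], want)) {
      if (!protected[posFix]) {
        v[posFix] <- sample(setdiff(DNA_BASES, want), 1L)
      } else if (!protected[posKeep]) {
        alt <- if (inverted) unname(COMP[v[posFix]]) else v[posFix]
        v[posKeep] <- sample(setdiff(DNA_BASES, c(v[posKeep], alt)), 1L)
      }
    }
    v
  }
  if (inverted) {
    ## outward: base left of a vs complement of base right of b
    pl <- modPos(a[1] - 1L, L); pr <- modPos(b[2] + 1L, L)
    v <- fix(v, pl, pr, unname(COMP[v[pl]]))
    ## inward: base right of a vs complement of base left of b
    pl <- modPos(a[2] + 1L, L); pr <- modPos(b[1] - 1L, L)
    v <- fix(v, pl, pr, unname(COMP[v[pl]]))
  } else {
    pl1 <- modPos(a[1] - 1L, L); pl2 <- modPos(b[1] - 1L, L)
    v <- fix(v, pl1, pl2, v[pl1])
    pr1 <- modPos(a[2] + 1L, L); pr2 <- modPos(b[2] + 1L, L)
    v <- fix(v, pr1, pr2, v[pr1])
  }
  v
}

exonsToGRanges <- function(exonsDf, id) {
  if (is.null(exonsDf) || !nrow(exonsDf)) return(emptyFeatures(id))
  gr <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(exonsDf$start, exonsDf$end),
    strand = exonsDf$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = exonsDf$gene, kind = exonsDf$kind,
    exon_rank = as.integer(exonsDf$exon_rank),
    copy = as.integer(exonsDf$copy %||% rep(1L, nrow(exonsDf))))
  gr
}
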