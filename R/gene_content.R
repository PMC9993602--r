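## Gene status classification, copy number, intron loss, status matrix.

#' Classify the status of a gene in a plastome
#'
#' Runs [seededLocalAlign()] of the full-length reference gene against the
#' (circular) genome, clusters hits into loci, and classifies by query
#' coverage of the best locus: coverage at least `intactCov` and (for
#' protein-coding genes) an in-frame translation without internal stop is
#' `intact`; high coverage with an internal stop codon is
#' `pseudogene_premature_stop`; coverage in `[fragCov, intactCov)` is
#' `pseudogene_truncated`; positive coverage below `fragCov` a `fragment`;
#' no hit `absent`. Copy number is the number of disjoint loci with
#' coverage at least `fragCov` (an IR-borne gene counts twice). The
#' reading frame for the stop-codon check is taken from the best hit's
#' query offset; RNA-editing rescue of internal stops is not modelled.
#'
#' @param gene gene symbol (reporting only).
#' @param query full-length reference gene sequence (character or
#'   DNAString); internal N is an error.
#' @param record target [PlastomeRecord-class].
#' @param scheme a [scoringScheme()].
#' @param intactCov,fragCov coverage thresholds (defaults 0.90 and 0.20).
#' @param kind `"PCG"`, `"tRNA"` or `"rRNA"`; the premature-stop check
#'   applies to PCGs only.
#' @param targetIndex optional precomputed seed index (see
#'   [seededLocalAlign()]).
#' @return one-row data.frame: `gene`, `kind`, `status`, `copy_number`,
#'   `coverage`, `n_hits`; the hit table is attached as attribute
#'   `evidence`.
#' @export
callGene <- function(gene, query, record, scheme = scoringScheme(),
                     intactCov = 0.90, fragCov = 0.20, kind = "PCG",
                     targetIndex = NULL) {
  q <- seqChar(query)
  if (grepl("N", q, fixed = TRUE))
    stop("query '", gene, "' contains internal N")
  hits <- seededLocalAlign(q, record, scheme, targetIndex = targetIndex)
  L <- plastomeLength(record)
  qlen <- nchar(q)

  res <- data.frame(gene = gene, kind = kind, status = "absent",
                    copy_number = 0L, coverage = 0, n_hits = nrow(hits))
  if (!nrow(hits)) {
    attr(res, "evidence") <- hits
    return(res)
  }
  grp <- clusterLociCircular(hits$target_start, hits$target_end, L)
  covByLocus <- vapply(split(seq_len(nrow(hits)), grp), function(ii) {
    iv <- IRanges::reduce(IRanges::IRanges(hits$query_start[ii],
                                           hits$query_end[ii]))
    sum(IRanges::width(iv)) / qlen
  }, numeric(1))
  scoreByLocus <- vapply(split(hits$score, grp), max, numeric(1))
  res$copy_number <- sum(covByLocus >= fragCov)
  bestLocus <- names(covByLocus)[order(-covByLocus, -scoreByLocus)][1]
  cov <- covByLocus[[bestLocus]]
  res$coverage <- round(cov, 4)

  if (cov >= intactCov) {
    if (kind != "PCG") {
      res$status <- "intact"
    } else {
      best <- hits[grp == bestLocus, , drop = FALSE]
      best <- best[which.max(best$score), , drop = FALSE]
      res$status <- if (hasInternalStop(best, record, qlen))
        "pseudogene_premature_stop" else "intact"
    }
  } else if (cov >= fragCov) {
    res$status <- "pseudogene_truncated"
  } else if (cov > 0) {
    res$status <- "fragment"
  }
  ## a fragment locus falls below fragCov but is still one (remnant) locus
  if (res$status != "absent" && res$copy_number == 0L)
    res$copy_number <- 1L
  if (res$status == "absent") res$copy_number <- 0L
  attr(res, "evidence") <- hits
  res
}

## translate the best hit's target segment in the query reading frame and
## look for a stop codon before the final codon of the query
hasInternalStop <- function(hit, record, qlen) {
  seg <- extractInterval(record, hit$target_start, hit$target_end,
                         strand = hit$strand)
  skip <- (3L - (hit$query_start - 1L) %% 3L) %% 3L
  seg <- substr(seg, skip + 1L, nchar(seg))
  nc <- nchar(seg) - nchar(seg) %% 3L
  if (nc < 6L) return(FALSE)
  seg <- substr(seg, 1L, nc)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seg),
                                           if.fuzzy.codon = "X"))
  ## the query's own terminal stop codon is not an internal stop: ignore
  ## a stop in the final codon position of the aligned query range
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  stops <- stops[stops > 0]
  if (!length(stops)) return(FALSE)
  lastCodonOfQuery <- (qlen %/% 3L)
  codonOffset <- (hit$query_start - 1L + skip) %/% 3L
  any(stops + codonOffset < lastCodonOfQuery)
}

## group circular intervals (end may exceed L) into overlapping loci
clusterLociCircular <- function(s, e, L) {
  n <- length(s)
  grp <- seq_len(n)
  ovl <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    o <- ovl(s[i], e[i], s[j], e[j]) ||
      ovl(s[i] + L, e[i] + L, s[j], e[j]) ||
      ovl(s[i], e[i], s[j] + L, e[j] + L)
    if (o) grp[grp == grp[j]] <- grp[i]
  }
  as.character(grp)
}

#' Classify many genes against one genome
#'
#' @param queries named character vector or DNAStringSet of full-length
#'   reference genes.
#' @param record target [PlastomeRecord-class].
#' @param kinds optional named vector of gene kinds (default all PCG).
#' @param ... passed to [callGene()].
#' @inheritParams callGene
#' @return data.frame with one row per gene (see [callGene()]).
#' @export
callGenes <- function(queries, record, scheme = scoringScheme(),
                      kinds = NULL, ...) {
  qs <- if (methods::is(queries, "DNAStringSet"))
    setNames(as.character(queries), names(queries)) else queries
  if (is.null(names(qs)) || any(!nzchar(names(qs))))
    stop("queries must be named by gene symbol")
  t0 <- seqChar(record)
  t <- if (isCircularGenome(record)) paste0(t0, t0) else t0
  idx <- targetSeedIndex(t, scheme$seedWord)
  rows <- lapply(names(qs), function(g) {
    kind <- if (!is.null(kinds) && g %in% names(kinds)) kinds[[g]] else "PCG"
    callGene(g, qs[[g]], record, scheme, kind = kind,
             targetIndex = idx, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect intron loss by exon-wise alignment
#'
#' Each exon of a multi-exon reference gene model is aligned independently
#' to the genome; consecutive exon hits separated on the target by less
#' than `junctionGap` bp are read as a lost intron. `lost` is `TRUE` when
#' fewer introns are found than the model expects.
#'
#' @param gene gene symbol.
#' @param exons character vector or DNAStringSet of exon sequences in
#'   transcription order; at least two.
#' @param record target [PlastomeRecord-class].
#' @param scheme a [scoringScheme()].
#' @param junctionGap bp threshold separating a retained intron from a
#'   fused exon junction (default 30).
#' @return one-row data.frame: `gene`, `introns_expected`,
#'   `introns_found`, `lost`, `undetermined`.
#' @export
detectIntronLoss <- function(gene, exons, record,
                             scheme = scoringScheme(), junctionGap = 30) {
  ex <- if (methods::is(exons, "DNAStringSet")) as.character(exons)
        else as.character(exons)
  if (length(ex) < 2L)
    stop("intron loss requires a reference model with >= 2 exons")
  L <- plastomeLength(record)
  best <- lapply(ex, function(e) {
    h <- seededLocalAlign(e, record, scheme)
    if (!nrow(h)) NULL else h[1L, ]
  })
  if (any(vapply(best, is.null, logical(1)))) {
    warning("exon(s) of '", gene, "' unmapped; intron status undetermined")
    return(data.frame(gene = gene, introns_expected = length(ex) - 1L,
                      introns_found = NA_integer_, lost = NA,
                      undetermined = TRUE))
  }
  found <- 0L
  for (i in seq_len(length(ex) - 1L)) {
    h1 <- best[[i]]; h2 <- best[[i + 1L]]
    gap <- if (h1$strand == "+")
      (h2$target_start - h1$target_end - 1L) %% L
    else
      (h1$target_start - h2$target_end - 1L) %% L
    if (gap >= junctionGap) found <- found + 1L
  }
  data.frame(gene = gene, introns_expected = length(ex) - 1L,
             introns_found = found,
             lost = found < length(ex) - 1L, undetermined = FALSE)
}

#' Gene status matrix across genomes
#'
#' Collapses per-gene calls to the four display symbols of a gene-content
#' matrix: `"2"` two copies (intact, copy number >= 2), `"1"` one intact
#' copy, `"P"` pseudogene or fragment (truncated, premature-stop or
#' fragment), `"-"` absent.
#'
#' @param callsByGenome named list of [callGenes()] data.frames, one per
#'   genome.
#' @return character matrix, genes in rows, genomes in columns.
#' @export
geneMatrix <- function(callsByGenome) {
  stopifnot(length(callsByGenome) > 0, !is.null(names(callsByGenome)))
  genes <- unique(unlist(lapply(callsByGenome, `[[`, "gene")))
  sym <- function(status, cn) {
    if (status == "absent") return("-")
    if (status == "intact") return(if (cn >= 2L) "2" else "1")
    "P"
  }
  m <- matrix("-", nrow = length(genes), ncol = length(callsByGenome),
              dimnames = list(genes, names(callsByGenome)))
  for (g in names(callsByGenome)) {
    df <- callsByGenome[[g]]
    for (r in seq_len(nrow(df)))
      m[df$gene[r], g] <- sym(df$status[r], df$copy_number[r])
  }
  m
}
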