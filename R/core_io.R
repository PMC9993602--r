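## Sequence / annotation input-output and circular-coordinate primitives.

#' Read plastome sequences from FASTA
#'
#' One [PlastomeRecord-class] per FASTA entry. Residues are uppercased;
#' ambiguity codes other than N are rejected (degenerate bases in an
#' assembly are treated as a defect, not data).
#'
#' @param path FASTA file (single- or multi-record).
#' @param circular logical, circularity flag applied to every record.
#' @return list of [PlastomeRecord-class].
#' @export
readPlastomes <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  lapply(seq_along(ss), function(i) {
    PlastomeRecord(ids[i], toupper(as.character(ss[[i]])),
                   circular = circular)
  })
}

#' Write plastome sequences to FASTA
#'
#' @param records list of [PlastomeRecord-class] (or a single record).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writePlastomes <- function(records, path) {
  if (methods::is(records, "PlastomeRecord")) records <- list(records)
  ss <- Biostrings::DNAStringSet(lapply(records, plastomeSeq))
  names(ss) <- vapply(records, plastomeId, character(1))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Reverse complement
#'
#' Standard complement (N maps to N); rejects residues outside A/C/G/T/N.
#'
#' @param x character, DNAString or [PlastomeRecord-class].
#' @return reverse complement, same basic type as the input (a character
#'   input returns character; a record returns a record with reversed
#'   features dropped).
#' @examples
#' revComp("AAAC")  # "GTTT"
#' @export
revComp <- function(x) {
  if (methods::is(x, "PlastomeRecord")) {
    return(PlastomeRecord(x@id, Biostrings::reverseComplement(x@sequence),
                          circular = x@circular))
  }
  chr <- is.character(x)
  if (chr) {
    if (grepl("[^ACGTNacgtn]", x))
      stop("invalid residue in sequence (only A/C/G/T/N allowed)")
    x <- Biostrings::DNAString(toupper(x))
  }
  rc <- Biostrings::reverseComplement(x)
  if (chr) as.character(rc) else rc
}

#' Extract a (possibly origin-wrapping) interval from a circular sequence
#'
#' Coordinates are 1-based closed. On a circular sequence the interval may
#' wrap the origin, given either as `end > length` (positions taken modulo
#' the genome length) or as `end < start` (wraps through the origin).
#' Strand `-` returns the reverse complement of the extracted segment.
#'
#' @param x [PlastomeRecord-class], DNAString or character.
#' @param start,end 1-based closed interval bounds.
#' @param strand `"+"` or `"-"`.
#' @return character, the extracted subsequence.
#' @examples
#' extractInterval("ACGTTT", 1, 4)            # "ACGT"
#' extractInterval("ACGTTT", 5, 8)            # wraps: "TTAC"
#' extractInterval("ACGTTT", 1, 4, strand="-")# "ACGT" reverse-complemented
#' @export
extractInterval <- function(x, start, end, strand = "+") {
  s <- seqChar(x)
  L <- nchar(s)
  circ <- if (methods::is(x, "PlastomeRecord")) isCircularGenome(x) else TRUE
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("NA interval bound")
  if (start < 1L || start > L) stop("interval start outside [1, length]")
  if (end < start) {
    if (!circ) stop("wrapping interval on a linear sequence")
    end <- end + L
  }
  len <- end - start + 1L
  if (len <= 0L) stop("zero-length interval")
  if (len > L) stop("interval longer than the genome")
  if (end > L && !circ) stop("interval exceeds linear sequence length")
  out <- if (end <= L) substr(s, start, end)
         else paste0(substr(s, start, L), substr(s, 1L, end - L))
  if (strand == "-") out <- revComp(out)
  out
}

#' Rotate a circular plastome to a new origin
#'
#' Returns a record whose position 1 is `newOrigin` of the input; feature
#' coordinates are remapped accordingly (features crossing the new origin
#' are represented with `end > length`).
#'
#' @param record [PlastomeRecord-class], circular.
#' @param newOrigin 1-based position that becomes position 1.
#' @return a re-origined [PlastomeRecord-class].
#' @export
reoriginPlastome <- function(record, newOrigin) {
  stopifnot(methods::is(record, "PlastomeRecord"))
  if (!isCircularGenome(record)) stop("re-origin defined on circles only")
  L <- plastomeLength(record)
  newOrigin <- modPos(as.integer(newOrigin), L)
  s <- seqChar(record)
  s2 <- if (newOrigin == 1L) s else
    paste0(substr(s, newOrigin, L), substr(s, 1L, newOrigin - 1L))
  fl <- plastomeFeatures(record)
  if (length(fl)) {
    st <- modPos(GenomicRanges::start(fl) - newOrigin + 1L, L)
    wd <- GenomicRanges::width(fl)
    IRanges::ranges(fl) <- IRanges::IRanges(start = st, width = wd)
  }
  PlastomeRecord(record@id, s2, circular = TRUE, features = fl)
}

## kind <-> GFF3 type mapping
kindToType <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
typeToKind <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")

#' Read gene annotations
#'
#' Parses exon-level gene features from GFF3 (via rtracklayer) or from a
#' minimal GenBank flat file (LOCUS/FEATURES/ORIGIN dialect, parsed
#' directly). File coordinates are 1-based inclusive in both dialects and
#' are kept 1-based closed internally. Multi-exon genes are joined by
#' shared `Parent`/`gene` attribute (GFF3) or by their `join(...)` location
#' (GenBank); exon ranks run 5' to 3' in transcription order, so on the
#' minus strand the genomically last segment is exon 1.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @param genomeLength optional; when given, features exceeding it raise an
#'   error.
#' @return For GFF3, a GRanges of exon-level features (mcols `gene`,
#'   `kind`, `exon_rank`, `copy`). For GenBank, a list with elements
#'   `record` (a full [PlastomeRecord-class] including the sequence) and
#'   `features`.
#' @export
readAnnotations <- function(path, format = c("gff3", "genbank"),
                            genomeLength = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    keep <- as.character(mc$type) %in% names(typeToKind)
    if (any(!keep & !as.character(mc$type) %in% c("gene", "region",
                                                  "exon", "source")))
      warning("skipping features of unknown kind: ",
              paste(unique(as.character(mc$type)[!keep &
                !as.character(mc$type) %in%
                  c("gene", "region", "exon", "source")]), collapse = ", "))
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    gene <- if (!is.null(mc$gene)) as.character(mc$gene) else NULL
    if (is.null(gene) && !is.null(mc$Name)) gene <- as.character(mc$Name)
    if (is.null(gene) && !is.null(mc$Parent))
      gene <- vapply(mc$Parent, function(p)
        if (length(p)) as.character(p[1]) else NA_character_, character(1))
    if (is.null(gene)) gene <- rep(NA_character_, length(gr))
    kind <- unname(typeToKind[as.character(mc$type)])
    copy <- if (!is.null(mc$copy)) as.integer(mc$copy) else rep(1L, length(gr))
    rank <- if (!is.null(mc$exon_rank)) as.integer(mc$exon_rank)
            else rep(NA_integer_, length(gr))
    out <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gr),
      ranges = IRanges::ranges(gr),
      strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      gene = gene, kind = kind, exon_rank = rank, copy = copy)
    out <- fillExonRanks(out)
    if (!is.null(genomeLength) &&
        any(GenomicRanges::end(out) > genomeLength))
      stop("feature exceeds sequence length ", genomeLength)
    out
  } else {
    parseGenBank(path, genomeLength = genomeLength)
  }
}

## assign missing exon ranks in transcription order within each gene locus
fillExonRanks <- function(gr) {
  if (!length(gr)) return(gr)
  key <- paste(gr$gene, gr$copy)
  rank <- gr$exon_rank
  for (k in unique(key[is.na(rank)])) {
    idx <- which(key == k)
    ord <- order(GenomicRanges::start(gr)[idx])
    if (as.character(GenomicRanges::strand(gr)[idx[1]]) == "-")
      ord <- rev(ord)
    rank[idx[ord]] <- seq_along(idx)
  }
  gr$exon_rank <- as.integer(rank)
  gr
}

#' Write gene annotations to GFF3
#'
#' One line per exon, type from the gene kind (CDS/tRNA/rRNA), with
#' `gene`, `kind`, `exon_rank` and `copy` attributes; round-trips through
#' [readAnnotations()].
#'
#' @param record [PlastomeRecord-class] whose features are written.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(record, path) {
  fl <- plastomeFeatures(record)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(plastomeId(record), length(fl)),
    ranges = IRanges::ranges(fl),
    strand = GenomicRanges::strand(fl))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = rep("plastomeKit", length(fl)),
    type = unname(kindToType[fl$kind]),
    phase = ifelse(fl$kind == "PCG", 0L, NA_integer_),
    ID = paste0(fl$gene, ".c", fl$copy, ".e", fl$exon_rank),
    gene = fl$gene, kind = fl$kind,
    exon_rank = fl$exon_rank, copy = fl$copy)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ---- minimal GenBank flat-file parser -------------------------------------
## No installed R package reads GenBank flat files, so a minimal parser for
## the LOCUS/FEATURES/ORIGIN dialect is provided here.

parseGbLocation <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
  if (any(lengths(m) != 3L)) {
    m1 <- regmatches(parts, regexec("^(\\d+)$", parts))
    stop("unsupported GenBank location: ", loc)
  }
  starts <- as.integer(vapply(m, `[`, character(1), 2L))
  ends <- as.integer(vapply(m, `[`, character(1), 3L))
  list(start = starts, end = ends, strand = strand)
}

parseGenBank <- function(path, genomeLength = NULL) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("malformed GenBank file: no LOCUS line")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", toks, ignore.case = TRUE))

  featStart <- grep("^FEATURES", lines)
  origStart <- grep("^ORIGIN", lines)
  if (!length(origStart)) stop("malformed GenBank file: no ORIGIN")
  featLines <- if (length(featStart))
    lines[(featStart[1] + 1L):(origStart[1] - 1L)] else character()

  ## fold continuation lines: a new feature starts with a key in column 6
  entries <- list()
  cur <- NULL
  for (ln in featLines) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = toks[1], loc = paste(toks[-1], collapse = ""),
                  quals = character())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (length(cur$quals)) {
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], txt)
      } else cur$loc <- paste0(cur$loc, txt)
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  rows <- list()
  unknown <- character()
  for (e in entries) {
    if (e$key %in% c("source", "gene", "misc_feature")) next
    if (!e$key %in% c("CDS", "tRNA", "rRNA")) {
      unknown <- c(unknown, e$key); next
    }
    loc <- parseGbLocation(e$loc)
    gq <- grep("^/gene=", e$quals, value = TRUE)
    gene <- if (length(gq)) gsub('^/gene="?|"?$', "", gq[1])
            else paste0("feature", length(rows) + 1L)
    nex <- length(loc$start)
    rank <- if (loc$strand == "-") rev(seq_len(nex)) else seq_len(nex)
    rows[[length(rows) + 1L]] <- data.frame(
      start = loc$start, end = loc$end, strand = loc$strand,
      gene = gene, kind = typeToKind[[e$key]], exon_rank = rank)
  }
  if (length(unknown))
    warning("skipping features of unknown kind: ",
            paste(unique(unknown), collapse = ", "))

  seqlines <- lines[(origStart[1] + 1L):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(seq)) stop("malformed GenBank file: empty sequence")

  df <- if (length(rows)) do.call(rbind, rows) else NULL
  fl <- emptyFeatures(id)
  if (!is.null(df)) {
    if (any(df$end > nchar(seq)) ||
        (!is.null(genomeLength) && any(df$end > genomeLength)))
      stop("feature exceeds sequence length")
    fl <- GenomicRanges::GRanges(
      seqnames = id,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand)
    S4Vectors::mcols(fl) <- S4Vectors::DataFrame(
      gene = df$gene, kind = df$kind,
      exon_rank = as.integer(df$exon_rank),
      copy = rep(1L, nrow(df)))
  }
  record <- PlastomeRecord(id, seq, circular = circular, features = fl)
  list(record = record, features = fl)
}

#' Read and write long reads (FASTQ, Phred+33)
#'
#' Thin wrappers over Biostrings FASTQ support. `writeLongReads` emits a
#' constant maximum quality when none is attached (synthetic reads carry
#' their truth in the read name, not the qualities).
#'
#' @param path FASTQ path.
#' @return `readLongReads`: a named DNAStringSet.
#' @export
readLongReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname readLongReads
#' @param reads named DNAStringSet.
#' @export
writeLongReads <- function(reads, path) {
  q <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads),
           function(w) paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}
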