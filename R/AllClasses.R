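#' PlastomeRecord: a circular plastid genome with gene features
#'
#' Container for one plastome: an identifier, the nucleotide sequence
#' (a [Biostrings::DNAString], uppercase, alphabet restricted to
#' A/C/G/T/N), a circularity flag, and gene features as a
#' [GenomicRanges::GRanges] with metadata columns `gene` (symbol),
#' `kind` (`"PCG"`, `"tRNA"` or `"rRNA"`), `exon_rank` (integer, 5' to 3'
#' in transcription order) and `copy` (integer locus index, distinguishing
#' the two IR-borne copies of a duplicated gene).
#'
#' Coordinates are 1-based and closed throughout, the Bioconductor
#' convention; an interval on the circle may extend past the sequence
#' length, in which case positions are taken modulo the genome length.
#'
#' @slot id character(1) accession-like identifier.
#' @slot sequence DNAString, the genome sequence.
#' @slot circular logical(1), whether the molecule is circular.
#' @slot features GRanges of exon-level gene features.
#'
#' @export
setClass("PlastomeRecord",
  representation(
    id = "character",
    sequence = "DNAString",
    circular = "logical",
    features = "GRanges"
  )
)

setValidity("PlastomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) == 0L)
    msg <- c(msg, "sequence must be non-empty")
  bad <- sum(Biostrings::letterFrequency(object@sequence,
    setdiff(Biostrings::DNA_ALPHABET, c("A", "C", "G", "T", "N"))))
  if (bad > 0L)
    msg <- c(msg, "sequence contains ambiguity codes other than N")
  if (length(object@features) > 0L) {
    need <- c("gene", "kind", "exon_rank")
    if (!all(need %in% names(S4Vectors::mcols(object@features))))
      msg <- c(msg, "features must carry mcols gene, kind, exon_rank")
    L <- length(object@sequence)
    if (any(GenomicRanges::start(object@features) < 1L) ||
        any(GenomicRanges::end(object@features) > 2L * L))
      msg <- c(msg, "feature coordinates outside [1, 2*genome length]")
    if (!object@circular &&
        any(GenomicRanges::end(object@features) > L))
      msg <- c(msg, "origin-wrapping features on a linear sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlastomeRecord
#'
#' @param id accession-like identifier.
#' @param sequence DNAString or character; lowercase input is uppercased.
#' @param circular logical, circularity flag (default `TRUE`).
#' @param features optional GRanges of exon-level features (see
#'   [PlastomeRecord-class]); defaults to an empty set.
#' @return A [PlastomeRecord-class] object.
#' @examples
#' p <- PlastomeRecord("px", "acgtACGTN")
#' plastomeLength(p)
#' @export
PlastomeRecord <- function(id, sequence, circular = TRUE, features = NULL) {
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(toupper(sequence))
  if (is.null(features))
    features <- emptyFeatures(id)
  new("PlastomeRecord", id = as.character(id), sequence = sequence,
      circular = isTRUE(circular), features = features)
}

emptyFeatures <- function(id = "genome") {
  gr <- GenomicRanges::GRanges(seqnames = character(), ranges = IRanges::IRanges(),
                               strand = character())
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = character(), kind = character(),
    exon_rank = integer(), copy = integer())
  gr
}

#' QuadripartitePartition: LSC/IRb/SSC/IRa architecture of a plastome
#'
#' Result of [detectInvertedRepeat()]. The four regions are stored as
#' integer `c(start, end)` pairs (1-based closed; `end` may exceed the
#' genome length when a region wraps the origin; `NA` when the region is
#' absent). `structureClass` is `"quadripartite"`, `"residual_ir"` (an IR
#' below the residual threshold, by default 2 kb, the depletion regime seen
#' in heavily contracted plastomes) or `"ir_free"` (no IR detected; by
#' convention the LSC is then the whole circle).
#'
#' @slot genomeLength integer(1).
#' @slot irLength integer(1), length of one IR arm (0 when ir_free).
#' @slot structureClass character(1).
#' @slot lsc,ssc,irb,ira integer(2) region intervals.
#' @export
setClass("QuadripartitePartition",
  representation(
    genomeLength = "integer",
    irLength = "integer",
    structureClass = "character",
    lsc = "integer", ssc = "integer", irb = "integer", ira = "integer"
  )
)

setValidity("QuadripartitePartition", function(object) {
  msg <- character()
  cls <- object@structureClass
  if (!cls %in% c("quadripartite", "residual_ir", "ir_free"))
    msg <- c(msg, "unknown structureClass")
  ivlen <- function(iv) if (any(is.na(iv))) 0L else iv[2] - iv[1] + 1L
  if (cls != "ir_free") {
    tot <- ivlen(object@lsc) + ivlen(object@ssc) + 2L * object@irLength
    if (tot != object@genomeLength)
      msg <- c(msg, "region lengths do not tile the genome")
    if (ivlen(object@lsc) < ivlen(object@ssc))
      msg <- c(msg, "LSC shorter than SSC")
    if (ivlen(object@irb) != object@irLength ||
        ivlen(object@ira) != object@irLength)
      msg <- c(msg, "IR arm lengths inconsistent with irLength")
  } else {
    if (object@irLength != 0L) msg <- c(msg, "ir_free with nonzero irLength")
  }
  if (length(msg)) msg else TRUE
})

#' RepeatCatalog: nonredundant repeat units and their copies
#'
#' Result of [findRepeats()]. `units` has one row per distinct repeat
#' sequence (`unit_id`, `length`, `representative`); `copies` one row per
#' genomic occurrence (`unit_id`, `start`, `end`, `strand`; `+` means the
#' copy equals the representative, `-` its reverse complement); `pairs`
#' the underlying maximal exact repeated pairs
#' (`start1,end1,start2,end2,length,strand`) from which units and copies
#' were derived.
#'
#' @slot genomeId character(1).
#' @slot genomeLength integer(1).
#' @slot minLength integer(1) minimum unit length used.
#' @slot units,copies,pairs data.frames as described.
#' @export
setClass("RepeatCatalog",
  representation(
    genomeId = "character",
    genomeLength = "integer",
    minLength = "integer",
    units = "data.frame",
    copies = "data.frame",
    pairs = "data.frame"
  )
)

setValidity("RepeatCatalog", function(object) {
  msg <- character()
  if (nrow(object@units) &&
      any(object@units$length < object@minLength))
    msg <- c(msg, "unit shorter than minimum length")
  if (nrow(object@copies) &&
      !all(object@copies$unit_id %in% object@units$unit_id))
    msg <- c(msg, "copy with unknown unit_id")
  if (length(msg)) msg else TRUE
})

#' IsomerPair: the two plastome configurations at an inverted-repeat pair
#'
#' Result of [buildIsomer()]. `isomer1` is the input (reference)
#' configuration; `isomer2` has the segment between the inner edges of the
#' two inverted repeat copies reverse-complemented in place, the
#' configuration generated by intramolecular flip-flop recombination. The
#' repeat copies themselves are identical in both configurations.
#'
#' @slot isomer1,isomer2 PlastomeRecord.
#' @slot repeatA,repeatB integer(2), the two arm intervals (1-based closed,
#'   `repeatA` upstream of `repeatB`).
#' @slot repeatLength integer(1).
#' @export
setClass("IsomerPair",
  representation(
    isomer1 = "PlastomeRecord",
    isomer2 = "PlastomeRecord",
    repeatA = "integer",
    repeatB = "integer",
    repeatLength = "integer"
  )
)

setValidity("IsomerPair", function(object) {
  msg <- character()
  if (plastomeLength(object@isomer1) != plastomeLength(object@isomer2))
    msg <- c(msg, "isomers differ in length")
  if (object@repeatLength != object@repeatA[2] - object@repeatA[1] + 1L)
    msg <- c(msg, "repeatLength inconsistent with repeatA")
  if (length(msg)) msg else TRUE
})

## ---- generics & accessors -------------------------------------------------

#' @rdname PlastomeRecord-class
#' @param x a PlastomeRecord.
#' @export
setGeneric("plastomeId", function(x) standardGeneric("plastomeId"))
#' @rdname PlastomeRecord-class
#' @export
setMethod("plastomeId", "PlastomeRecord", function(x) x@id)

#' @rdname PlastomeRecord-class
#' @export
setGeneric("plastomeSeq", function(x) standardGeneric("plastomeSeq"))
#' @rdname PlastomeRecord-class
#' @export
setMethod("plastomeSeq", "PlastomeRecord", function(x) x@sequence)

#' @rdname PlastomeRecord-class
#' @export
setGeneric("plastomeLength", function(x) standardGeneric("plastomeLength"))
#' @rdname PlastomeRecord-class
#' @export
setMethod("plastomeLength", "PlastomeRecord",
          function(x) length(x@sequence))

#' @rdname PlastomeRecord-class
#' @export
setGeneric("plastomeFeatures", function(x) standardGeneric("plastomeFeatures"))
#' @rdname PlastomeRecord-class
#' @export
setMethod("plastomeFeatures", "PlastomeRecord", function(x) x@features)

#' @rdname PlastomeRecord-class
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))
#' @rdname PlastomeRecord-class
#' @export
setMethod("isCircularGenome", "PlastomeRecord", function(x) x@circular)

setMethod("show", "PlastomeRecord", function(object) {
  cat("PlastomeRecord '", object@id, "': ",
      length(object@sequence), " bp, ",
      if (object@circular) "circular" else "linear", ", ",
      length(unique(paste(object@features$gene, object@features$copy))),
      " gene loci\n", sep = "")
})

#' @rdname QuadripartitePartition-class
#' @param x a QuadripartitePartition.
#' @export
setGeneric("structureClass", function(x) standardGeneric("structureClass"))
#' @rdname QuadripartitePartition-class
#' @export
setMethod("structureClass", "QuadripartitePartition",
          function(x) x@structureClass)

#' @rdname QuadripartitePartition-class
#' @export
setGeneric("irLength", function(x) standardGeneric("irLength"))
#' @rdname QuadripartitePartition-class
#' @export
setMethod("irLength", "QuadripartitePartition", function(x) x@irLength)

#' Region intervals of a quadripartite partition
#'
#' @param x a QuadripartitePartition.
#' @return data.frame with columns `region` (lsc/irb/ssc/ira), `start`,
#'   `end` (1-based closed, `end` may wrap past the genome length) and
#'   `length`; absent regions are omitted.
#' @export
setGeneric("partitionRegions", function(x) standardGeneric("partitionRegions"))
#' @rdname partitionRegions
#' @export
setMethod("partitionRegions", "QuadripartitePartition", function(x) {
  rows <- lapply(c("lsc", "irb", "ssc", "ira"), function(r) {
    iv <- slot(x, r)
    if (any(is.na(iv))) return(NULL)
    data.frame(region = r, start = iv[1], end = iv[2],
               length = iv[2] - iv[1] + 1L)
  })
  do.call(rbind, rows)
})

setMethod("show", "QuadripartitePartition", function(object) {
  cat("QuadripartitePartition (", object@structureClass, "): genome ",
      object@genomeLength, " bp, IR ", object@irLength, " bp\n", sep = "")
  print(partitionRegions(object))
})

#' @rdname RepeatCatalog-class
#' @param x a RepeatCatalog.
#' @export
setGeneric("repeatUnits", function(x) standardGeneric("repeatUnits"))
#' @rdname RepeatCatalog-class
#' @export
setMethod("repeatUnits", "RepeatCatalog", function(x) x@units)

#' @rdname RepeatCatalog-class
#' @export
setGeneric("repeatCopies", function(x) standardGeneric("repeatCopies"))
#' @rdname RepeatCatalog-class
#' @export
setMethod("repeatCopies", "RepeatCatalog", function(x) x@copies)

#' @rdname RepeatCatalog-class
#' @export
setGeneric("repeatPairs", function(x) standardGeneric("repeatPairs"))
#' @rdname RepeatCatalog-class
#' @export
setMethod("repeatPairs", "RepeatCatalog", function(x) x@pairs)

setMethod("show", "RepeatCatalog", function(object) {
  cat("RepeatCatalog for '", object@genomeId, "': ",
      nrow(object@units), " units, ", nrow(object@copies),
      " copies (min length ", object@minLength, " bp)\n", sep = "")
})

#' @rdname IsomerPair-class
#' @param x an IsomerPair.
#' @export
setGeneric("isomer1", function(x) standardGeneric("isomer1"))
#' @rdname IsomerPair-class
#' @export
setMethod("isomer1", "IsomerPair", function(x) x@isomer1)

#' @rdname IsomerPair-class
#' @export
setGeneric("isomer2", function(x) standardGeneric("isomer2"))
#' @rdname IsomerPair-class
#' @export
setMethod("isomer2", "IsomerPair", function(x) x@isomer2)

setMethod("show", "IsomerPair", function(object) {
  cat("IsomerPair: ", plastomeLength(object@isomer1), " bp genome, ",
      object@repeatLength, " bp inverted arms at [",
      object@repeatA[1], ",", object@repeatA[2], "] and [",
      object@repeatB[1], ",", object@repeatB[2], "]\n", sep = "")
})
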