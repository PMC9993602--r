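## End-to-end orchestration over a genome set with consolidated reports.

#' Run the full plastome analysis pipeline
#'
#' Orchestrates structure detection, repeat cataloguing (IR-excluded),
#' optional gene calling, synteny typing and the optional isomer analysis
#' over a set of genomes, writing TSV/JSON reports plus a provenance
#' block echoing every parameter actually used. Reports are deterministic
#' for a fixed config and seed.
#'
#' @param config named list or path to a JSON config with elements:
#'   `fasta` (character vector of FASTA paths; required), `gff` (optional
#'   parallel GFF3 paths), `queries` (optional FASTA of reference genes
#'   for gene calling), `outDir` (required), `seed` (default 1), and an
#'   optional `params` list overriding module defaults (`minIrLen`,
#'   `residualThreshold`, `repeatMinLen`, `upstreamWindow`,
#'   `syntenyK`, `minBlockLen`, `maxAnchorGap`, `intactCov`, `fragCov`),
#'   plus optional `isomer = list(genome, repeatA, repeatB, longReads,
#'   flank)`.
#' @return invisible list of in-memory results (`partition_table`,
#'   `repeat_catalogs`, `hotspots`, `gene_calls`, `gene_matrix`,
#'   `synteny`, `isomer_support`).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$fasta) || !length(config$fasta))
    stop("config validation: empty genome list ('fasta')")
  if (is.null(config$outDir)) stop("config validation: 'outDir' missing")
  for (p in c(config$fasta, config$gff))
    if (!file.exists(p)) stop("config validation: no such file: ", p)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  prm <- config$params %||% list()
  p <- list(minIrLen = prm$minIrLen %||% 100,
            residualThreshold = prm$residualThreshold %||% 2000,
            repeatMinLen = prm$repeatMinLen %||% 30,
            upstreamWindow = prm$upstreamWindow %||% 1000,
            syntenyK = prm$syntenyK %||% 21,
            minBlockLen = prm$minBlockLen %||% 500,
            maxAnchorGap = prm$maxAnchorGap %||% 2000,
            intactCov = prm$intactCov %||% 0.90,
            fragCov = prm$fragCov %||% 0.20)

  records <- list()
  for (i in seq_along(config$fasta)) {
    rs <- readPlastomes(config$fasta[i])
    for (r in rs) {
      if (!is.null(config$gff) && i <= length(config$gff)) {
        feats <- readAnnotations(config$gff[i], "gff3",
                                 genomeLength = plastomeLength(r))
        r@features <- feats
      }
      records[[plastomeId(r)]] <- r
    }
  }
  message("structure: ", length(records), " genome(s)")
  partitions <- lapply(records, detectInvertedRepeat,
                       minIrLen = p$minIrLen,
                       residualThreshold = p$residualThreshold)
  ptab <- partitionTable(unname(records), unname(partitions))
  write.table(ptab, file.path(config$outDir, "partition_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  message("repeats")
  catalogs <- list(); locs <- list()
  for (id in names(records)) {
    cat_ <- findRepeats(records[[id]], minLen = p$repeatMinLen,
                        excludeIr = structureClass(partitions[[id]]) !=
                          "ir_free",
                        partition = partitions[[id]])
    catalogs[[id]] <- cat_
    lc <- localizeRepeats(cat_, plastomeFeatures(
      stripSecondIR(records[[id]], partitions[[id]])),
      upstreamWindow = p$upstreamWindow)
    if (nrow(lc)) lc$genome <- id
    locs[[id]] <- lc
    write.table(lc, file.path(config$outDir,
                              paste0("repeats_", id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pooled <- do.call(rbind, locs)
  hot <- hotspotSummary(pooled)
  write.table(hot, file.path(config$outDir, "hotspot_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- NULL; gm <- NULL
  if (!is.null(config$queries)) {
    message("genes")
    qss <- Biostrings::readDNAStringSet(config$queries)
    calls <- lapply(records, function(r)
      callGenes(qss, r, intactCov = p$intactCov, fragCov = p$fragCov))
    gm <- geneMatrix(calls)
    write.table(cbind(gene = rownames(gm), as.data.frame(gm)),
                file.path(config$outDir, "gene_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  synteny <- NULL
  if (length(records) >= 2L) {
    message("synteny")
    reduced <- mapply(stripSecondIR, records, partitions,
                      SIMPLIFY = FALSE)
    refId <- sort(names(reduced))[1]
    perms <- list()
    for (id in names(reduced)) {
      if (id == refId) {
        perms[[id]] <- 1L
        next
      }
      bl <- buildBlocks(reduced[[refId]], reduced[[id]], k = p$syntenyK,
                        minBlockLen = p$minBlockLen,
                        maxAnchorGap = p$maxAnchorGap)
      perms[[id]] <- signedPermutation(bl)
    }
    synteny <- classifyStructuralTypes(perms)
    write.table(synteny$assignments,
                file.path(config$outDir, "structural_types.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  isoSupport <- NULL
  if (!is.null(config$isomer)) {
    message("isomer")
    iso <- config$isomer
    rec <- records[[iso$genome %||% names(records)[1]]]
    pair <- buildIsomer(rec, unlist(iso$repeatA), unlist(iso$repeatB))
    wins <- junctionWindows(pair, flank = iso$flank %||% 1000)
    isoSupport <- countSpanningReads(wins, iso$longReads)
    jsonlite::write_json(
      list(counts = as.list(isoSupport$counts),
           mean_isomer1 = isoSupport$mean1,
           mean_isomer2 = isoSupport$mean2,
           isomer2_frequency_percent = isoSupport$frequency,
           n_reads = isoSupport$n_reads,
           n_assigned = isoSupport$n_assigned),
      file.path(config$outDir, "isomer_support.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }

  provenance <- c(list(seed = seed,
                       genomes = names(records),
                       queries = config$queries %||% NA), p)
  jsonlite::write_json(provenance,
                       file.path(config$outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(partition_table = ptab, repeat_catalogs = catalogs,
                 hotspots = hot, gene_calls = calls, gene_matrix = gm,
                 synteny = synteny, isomer_support = isoSupport))
}
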