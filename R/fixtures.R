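## Canonical fixture suite: every structural scenario the pipeline must
## detect, generated deterministically from a seed.

#' Table-style partition specs used by the fixture suite
#'
#' LSC/SSC/IR length triples spanning the observed architecture range:
#' an IR-free genome, a residual 437 bp IR, a depleted ~2 kb IR, a
#' mid-size ~10 kb IR and a greatly expanded ~33 kb IR (total sizes
#' 110,388 to 143,493 bp).
#'
#' @return data.frame with columns `name`, `lsc`, `ssc`, `ir`.
#' @export
partitionFixtureSpecs <- function() {
  data.frame(
    name = c("ir0", "ir437", "ir1964", "ir10191", "ir33169"),
    lsc = c(80000L, 81002L, 83710L, 79737L, 53377L),
    ssc = c(33064L, 28512L, 32131L, 22890L, 23778L),
    ir = c(0L, 437L, 1964L, 10191L, 33169L))
}

geneStatusCensus <- function(nPerStatus, geneLen = 600L) {
  n <- 5L * nPerStatus
  names <- sprintf("gene%03d", seq_len(n))
  regions <- rep(c("LSC", "SSC"), c(3L * nPerStatus, 2L * nPerStatus))
  lapply(seq_len(n), function(i)
    censusEntry(names[i], "PCG", geneLen,
                strand = c("+", "-")[(i %% 2) + 1L],
                region = regions[i]))
}

geneStatusPlan <- function(nPerStatus) {
  n <- 5L * nPerStatus
  names <- sprintf("gene%03d", seq_len(n))
  plan <- list()
  grp <- rep(c("intact", "truncate", "premature_stop", "fragment",
               "delete"), each = nPerStatus)
  for (i in seq_len(n)) {
    if (grp[i] == "intact") next
    plan[[names[i]]] <- switch(grp[i],
      truncate = list(mode = "truncate", frac = 0.5),
      premature_stop = list(mode = "premature_stop"),
      fragment = list(mode = "fragment", frac = 0.1),
      delete = list(mode = "delete"))
  }
  plan
}

#' Synthetic genome carrying every gene status
#'
#' `nPerStatus` genes each planted intact, truncated to half length, with
#' a mid-gene stop codon, as a short (10%) fragment, and deleted
#' entirely; the manifest carries the full-length queries and the planned
#' status of every gene.
#'
#' @param seed RNG seed.
#' @param nPerStatus genes per status (default 20).
#' @return `generatePlastome()` result (record + manifest).
#' @export
geneStatusFixture <- function(seed = 1, nPerStatus = 20) {
  spec <- plastomeSpec(seed, lscLen = 50000L, sscLen = 20000L, irLen = 0L,
                       census = geneStatusCensus(nPerStatus),
                       pseudogenes = geneStatusPlan(nPerStatus))
  generatePlastome(spec)
}

#' Rearrangement fixture: 14 genomes in 5 structural types
#'
#' One 60 kb IR-free ancestor cut into six 10 kb blocks; five scripts
#' (identity, one inversion, two separated inversions, one translocation,
#' inversion plus translocation) are applied to make 14 genomes with
#' planted type memberships A(4), B(3), C(3), D(2), E(2).
#'
#' @param seed RNG seed.
#' @return list: `base` record, `genomes` (named list of records),
#'   `expectedType` (named character), `scripts`, `blockEnds`,
#'   `permutations` (planted 6-block signed permutations).
#' @export
rearrangementFixture <- function(seed = 1) {
  spec <- plastomeSpec(seed + 7L, lscLen = 40000L, sscLen = 20000L,
                       irLen = 0L, census = list())
  base <- generatePlastome(spec)$record
  blockEnds <- seq.int(10000L, 60000L, by = 10000L)
  scripts <- list(
    A = list(),
    B = list(list(type = "inversion", from = 2L, to = 3L)),
    C = list(list(type = "inversion", from = 2L, to = 2L),
             list(type = "inversion", from = 4L, to = 5L)),
    D = list(list(type = "translocation", from = 2L, to = 2L, after = 3L)),
    E = list(list(type = "inversion", from = 2L, to = 4L),
             list(type = "translocation", from = 5L, to = 5L, after = 1L)))
  members <- rep(c("A", "B", "C", "D", "E"), c(4L, 3L, 3L, 2L, 2L))
  ids <- sprintf("g%02d", seq_along(members))
  genomes <- list(); perms <- list()
  for (i in seq_along(ids)) {
    rr <- applyRearrangement(base, scripts[[members[i]]], blockEnds)
    rec <- rr$record
    rec@id <- ids[i]
    genomes[[ids[i]]] <- rec
    perms[[ids[i]]] <- rr$permutation
  }
  list(base = base, genomes = genomes,
       expectedType = setNames(members, ids),
       scripts = scripts, blockEnds = blockEnds, permutations = perms)
}

#' Isomer fixture: a 679 bp inverted pair bracketing 60 kb
#'
#' A 100 kb IR-free genome with a 679 bp inverted-repeat arm pair whose
#' inner edges are 60,000 bp apart, plus the derived [IsomerPair-class].
#'
#' @param seed RNG seed.
#' @return list: `record`, `manifest`, `pair`.
#' @export
isomerFixture <- function(seed = 1) {
  spec <- plastomeSpec(seed + 11L, lscLen = 70000L, sscLen = 30000L,
                       irLen = 0L,
                       isomerRepeat = list(length = 679L, start = 10000L,
                                           innerGap = 60000L))
  g <- generatePlastome(spec)
  pair <- buildIsomer(g$record, g$manifest$isomer$armA,
                      g$manifest$isomer$armB)
  c(g, list(pair = pair))
}

#' Generate the canonical fixture suite
#'
#' Emits (a) quadripartite genomes with IR arm lengths 0, 437, 1,964,
#' 10,191 and 33,169 bp; (b) a genome covering all five gene statuses;
#' (c) 14 genomes in 5 rearrangement types; (d) the 679 bp / 60 kb isomer
#' fixture with long-read sets at isomer2 proportions 0, 0.01 and 0.5 —
#' each with its ground-truth manifest. With `dir`, FASTA/GFF3/FASTQ and
#' JSON manifests are written to disk.
#'
#' @param seed master seed; component seeds derive from it.
#' @param nReads reads per isomer read set (default 2000; analyses
#'   needing other depths call [simulateLongReads()] directly).
#' @param proportions isomer2 proportions of the read sets.
#' @param dir optional output directory.
#' @return nested list with components `partitions`, `geneStatus`,
#'   `rearrangements`, `isomer`.
#' @export
fixtureSuite <- function(seed = 1, nReads = 2000,
                         proportions = c(0, 0.01, 0.5), dir = NULL) {
  specs <- partitionFixtureSpecs()
  partitions <- lapply(seq_len(nrow(specs)), function(i)
    generatePlastome(plastomeSpec(seed * 100L + i,
                                  lscLen = specs$lsc[i],
                                  sscLen = specs$ssc[i],
                                  irLen = specs$ir[i])))
  names(partitions) <- specs$name

  gs <- geneStatusFixture(seed)
  ra <- rearrangementFixture(seed)
  iso <- isomerFixture(seed)
  readSets <- lapply(seq_along(proportions), function(i)
    simulateLongReads(iso$pair, nReads = nReads,
                      isomer2Prop = proportions[i],
                      seed = seed * 1000L + i))
  names(readSets) <- paste0("p", proportions)
  iso$readSets <- readSets

  out <- list(partitions = partitions, geneStatus = gs,
              rearrangements = ra, isomer = iso)
  if (!is.null(dir)) writeFixtureSuite(out, dir)
  out
}

writeFixtureSuite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(suite$partitions)) {
    g <- suite$partitions[[nm]]
    writePlastomes(g$record, file.path(dir, paste0(nm, ".fasta")))
    writeAnnotations(g$record, file.path(dir, paste0(nm, ".gff3")))
    writeManifest(g$manifest, file.path(dir, paste0(nm, ".manifest.json")))
  }
  writePlastomes(suite$geneStatus$record,
                 file.path(dir, "gene_status.fasta"))
  writeManifest(suite$geneStatus$manifest,
                file.path(dir, "gene_status.manifest.json"))
  writePlastomes(unname(suite$rearrangements$genomes),
                 file.path(dir, "rearrangements.fasta"))
  writePlastomes(suite$isomer$record, file.path(dir, "isomer.fasta"))
  writeManifest(suite$isomer$manifest,
                file.path(dir, "isomer.manifest.json"))
  for (nm in names(suite$isomer$readSets))
    writeLongReads(suite$isomer$readSets[[nm]],
                   file.path(dir, paste0("reads_", nm, ".fastq")))
  invisible(dir)
}

writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
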