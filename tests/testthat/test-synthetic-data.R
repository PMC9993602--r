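test_that("generation is deterministic and honours the size arithmetic", {
  sp <- plastomeSpec(81, lscLen = 53377L, sscLen = 23778L, irLen = 33169L)
  g1 <- generatePlastome(sp)
  g2 <- generatePlastome(sp)
  expect_identical(as.character(plastomeSeq(g1$record)),
                   as.character(plastomeSeq(g2$record)))
  expect_equal(plastomeLength(g1$record), 143493L)
  expect_equal(g1$manifest$length,
               g1$manifest$lsc + g1$manifest$ssc + 2L * g1$manifest$ir)
  ## IR-free spec
  gf <- generatePlastome(plastomeSpec(82, lscLen = 60000L,
                                      sscLen = 30000L, irLen = 0L))
  expect_equal(plastomeLength(gf$record), 90000L)
  expect_identical(structureClass(detectInvertedRepeat(gf$record)),
                   "ir_free")
  ## infeasible placement is refused with the culprit named
  expect_error(generatePlastome(plastomeSpec(83, lscLen = 3000L,
                                             sscLen = 3000L, irLen = 0L)),
               "infeasible placement")
})

test_that("planted IR arms are exact reverse complements at exact extent", {
  g <- generatePlastome(plastomeSpec(84, lscLen = 30000L, sscLen = 12000L,
                                     irLen = 6000L))
  man <- g$manifest
  reg <- man$regions
  irb <- reg[reg$region == "irb", ]; ira <- reg[reg$region == "ira", ]
  expect_identical(
    extractInterval(g$record, irb$start, irb$end),
    revComp(extractInterval(g$record, ira$start, ira$end)))
  p <- detectInvertedRepeat(g$record)
  expect_equal(unname(p@irb), c(irb$start, irb$end))
  expect_equal(unname(p@ira), c(ira$start, ira$end))
})

test_that("generated FASTA/GFF3 re-read to the manifest coordinates", {
  g <- generatePlastome(plastomeSpec(85, lscLen = 20000L, sscLen = 8000L,
                                     irLen = 3000L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  writePlastomes(g$record, fa)
  writeAnnotations(g$record, gf)
  rec <- readPlastomes(fa)[[1]]
  feats <- readAnnotations(gf, "gff3")
  ex <- g$manifest$exons
  got <- data.frame(gene = feats$gene,
                    start = GenomicRanges::start(feats),
                    end = GenomicRanges::end(feats))
  got <- got[order(got$gene, got$start), ]
  want <- ex[order(ex$gene, ex$start), c("gene", "start", "end")]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$gene, want$gene)
})

test_that("planted ORFs start with ATG, end with a stop, none internal", {
  g <- generatePlastome(plastomeSpec(86, lscLen = 30000L, sscLen = 12000L,
                                     irLen = 6000L))
  for (q in g$manifest$queries[g$manifest$kinds == "PCG"]) {
    expect_identical(substr(q, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(q)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("rearrangement scripting composes and inverts cleanly", {
  ra <- rearrangementFixture(seed = 87)
  base <- ra$base
  ## empty script is the identity
  r0 <- applyRearrangement(base, list(), ra$blockEnds)
  expect_identical(as.character(plastomeSeq(r0$record)),
                   as.character(plastomeSeq(base)))
  expect_equal(r0$permutation, 1:6)
  ## script followed by its inverse restores the sequence
  script <- list(list(type = "inversion", from = 2L, to = 4L))
  fwd <- applyRearrangement(base, script, ra$blockEnds)
  back <- applyRearrangement(fwd$record, script, ra$blockEnds)
  expect_identical(as.character(plastomeSeq(back$record)),
                   as.character(plastomeSeq(base)))
  expect_error(applyRearrangement(base, list(list(type = "inversion",
                                                  from = 5L, to = 2L)),
                                  ra$blockEnds), "invalid")
})

test_that("long-read simulation is faithful to its own ground truth", {
  iso <- isomerFixture(seed = 88)
  ## proportion 0: every read is tagged isomer1
  r0 <- simulateLongReads(iso$pair, nReads = 50, isomer2Prop = 0,
                          seed = 89)
  expect_true(all(grepl("template=isomer1", names(r0))))
  ## error-free reads are exact circular substrings of their template
  d1 <- paste0(seqchar <- as.character(plastomeSeq(isomer1(iso$pair))),
               seqchar)
  for (i in sample(length(r0), 10)) {
    info <- strsplit(names(r0)[i], "\\|")[[1]]
    st <- as.integer(sub("start=", "", info[3]))
    len <- as.integer(sub("len=", "", info[4]))
    strand <- sub("strand=", "", info[5])
    want <- substr(d1, st, st + len - 1L)
    if (strand == "-") want <- revComp(want)
    expect_identical(as.character(r0[[i]]), want)
  }
  ## tagged isomer2 count is binomial around n*p
  rB <- simulateLongReads(iso$pair, nReads = 4000, minLen = 500,
                          maxLen = 1500, isomer2Prop = 0.01, seed = 90)
  n2 <- sum(grepl("template=isomer2", names(rB)))
  expect_lt(abs(n2 - 40), 3 * sqrt(4000 * 0.01 * 0.99) + 1e-9)
  ## error injection changes reads at roughly the requested rate
  rE <- simulateLongReads(iso$pair, nReads = 5, minLen = 2000,
                          maxLen = 2000,
                          errorRates = c(mismatch = 0.05, insertion = 0.01,
                                         deletion = 0.01), seed = 91)
  expect_false(any(vapply(seq_len(5), function(i) {
    info <- strsplit(names(rE)[i], "\\|")[[1]]
    st <- as.integer(sub("start=", "", info[3]))
    strand <- sub("strand=", "", info[5])
    want <- substr(d1, st, st + 1999L)
    if (strand == "-") want <- revComp(want)
    identical(as.character(rE[[i]]), want)
  }, logical(1))))
})

test_that("the fixture suite covers the planted scenarios", {
  fs <- fixtureSuite(seed = 2, nReads = 30, proportions = c(0, 0.5))
  ## (a) partition arithmetic for every spec
  specs <- partitionFixtureSpecs()
  for (i in seq_len(nrow(specs))) {
    rec <- fs$partitions[[specs$name[i]]]$record
    expect_equal(plastomeLength(rec),
                 specs$lsc[i] + specs$ssc[i] + 2L * specs$ir[i])
  }
  ## (c) five distinct planted arrangements
  expect_equal(length(unique(fs$rearrangements$expectedType)), 5L)
  ## (d) the repeat finder recovers one 679 bp inverted unit
  cat_ <- findRepeats(fs$isomer$record, minLen = 600)
  u <- repeatUnits(cat_)
  expect_equal(nrow(u), 1L)
  expect_equal(u$length, 679L)
  expect_setequal(repeatCopies(cat_)$strand, c("+", "-"))
  ## suite writes plain-text artefacts when asked
  td <- withr::local_tempdir()
  writeFixtureSuiteTest <- plastomeKit:::writeFixtureSuite
  writeFixtureSuiteTest(fs, td)
  expect_true(file.exists(file.path(td, "isomer.fasta")))
  expect_true(file.exists(file.path(td, "reads_p0.fastq")))
})
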