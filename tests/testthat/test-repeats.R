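test_that("a clean random sequence yields an empty catalog", {
  set.seed(31)
  cat_ <- findRepeats(randomDna(5000), minLen = 30)
  expect_equal(nrow(repeatUnits(cat_)), 0L)
  expect_equal(nrow(repeatCopies(cat_)), 0L)
  expect_error(findRepeats(randomDna(40), minLen = 30), "shorter")
})

test_that("planted direct and inverted copies are catalogued faithfully", {
  set.seed(32)
  bg <- randomDna(5000)
  unit <- randomDna(40)
  s <- plantAt(plantAt(bg, 1001, unit), 3001, unit)
  orc <- oracleRepeatPairs(s, 30)
  cat_ <- findRepeats(s, minLen = 30)
  expect_identical(pairKey(repeatPairs(cat_)), pairKey(orc))
  expect_equal(nrow(repeatUnits(cat_)), 1L)
  expect_equal(nrow(repeatCopies(cat_)), 2L)
  expect_equal(repeatUnits(cat_)$length, orc$length[1])

  s2 <- plantAt(plantAt(bg, 1001, unit), 3001, revComp(unit))
  cat2 <- findRepeats(s2, minLen = 30)
  expect_equal(nrow(repeatUnits(cat2)), 1L)
  expect_setequal(repeatCopies(cat2)$strand, c("+", "-"))
  ## copy fidelity invariant: every copy matches its representative
  u <- repeatUnits(cat2); cp <- repeatCopies(cat2)
  for (r in seq_len(nrow(cp))) {
    got <- extractInterval(s2, cp$start[r], cp$end[r], cp$strand[r])
    expect_identical(got, u$representative[u$unit_id == cp$unit_id[r]])
  }
})

test_that("finder equals the quadratic oracle on varied planted fixtures", {
  set.seed(33)
  for (i in 1:12) {
    n <- sample(800:3000, 1)
    s <- randomDna(n)
    nplant <- sample(0:3, 1)
    for (p in seq_len(nplant)) {
      len <- sample(30:80, 1)
      unit <- randomDna(len)
      pos <- sort(sample(seq(1, n - len, by = len + 10), 2))
      if (pos[2] - pos[1] > len) {
        s <- plantAt(s, pos[1], unit)
        s <- plantAt(s, pos[2],
                     if (runif(1) < 0.5) unit else revComp(unit))
      }
    }
    expect_identical(pairKey(repeatPairs(findRepeats(s, minLen = 30))),
                     pairKey(oracleRepeatPairs(s, 30)),
                     label = paste("fixture", i))
  }
})

test_that("raising the minimum length never adds units", {
  set.seed(34)
  s <- randomDna(4000)
  for (len in c(35, 60)) {
    unit <- randomDna(len)
    pos <- sample(seq(1, 3800, by = 400), 2)
    s <- plantAt(plantAt(s, pos[1], unit), pos[2], unit)
  }
  sizes <- vapply(c(30, 40, 50, 70), function(m)
    nrow(repeatUnits(findRepeats(s, minLen = m))), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("IR exclusion removes the architectural arm pair", {
  g <- generatePlastome(plastomeSpec(35, lscLen = 20000L, sscLen = 8000L,
                                     irLen = 3000L))
  part <- detectInvertedRepeat(g$record)
  with_ir <- findRepeats(g$record, minLen = 30)
  expect_true(max(repeatUnits(with_ir)$length) >= 3000)
  no_ir <- findRepeats(g$record, minLen = 30, excludeIr = TRUE,
                       partition = part)
  expect_true(nrow(repeatUnits(no_ir)) == 0 ||
                max(repeatUnits(no_ir)$length) < 3000)
})

test_that("localization classifies internal/upstream/downstream with ties", {
  census <- list(censusEntry("accD", "PCG", 900L, strand = "+",
                             region = "LSC"))
  g <- generatePlastome(plastomeSpec(36, lscLen = 20000L, sscLen = 8000L,
                                     irLen = 0L, census = census))
  acc <- g$manifest$genes[g$manifest$genes$gene == "accD", ]
  ## copies: inside accD; 200 bp 5' of it; far away
  unit <- randomDna(40)
  s <- seq_len(3)
  starts <- c(acc$start + 100L,            # internal
              acc$start - 200L - 40L,      # gap of exactly 200 bp 5'
              acc$end + 3000L)             # beyond the window
  s2 <- as.character(plastomeSeq(g$record))
  pre <- c("A", "G", "C"); post <- c("C", "T", "A")
  for (k in seq_along(starts)) {
    s2 <- plantAt(s2, starts[k], unit)
    ## distinct flank bases block cross-copy extension, keeping the
    ## planted coordinates exactly maximal
    substr(s2, starts[k] - 1L, starts[k] - 1L) <- pre[k]
    substr(s2, starts[k] + 40L, starts[k] + 40L) <- post[k]
  }
  cat_ <- findRepeats(s2, minLen = 30)
  loc <- localizeRepeats(cat_, plastomeFeatures(g$record),
                         upstreamWindow = 1000)
  li <- loc[loc$start == starts[1], ]
  expect_identical(li$context, "internal")
  expect_identical(li$anchor_gene, "accD")
  expect_equal(li$distance, 0L)
  lu <- loc[loc$start == starts[2], ]
  expect_identical(lu$context, "upstream")
  expect_equal(lu$distance, 200L)
  lf <- loc[loc$start == starts[3], ]
  expect_identical(lf$context, "intergenic_other")

  ## equidistant tie-break: lexicographically smaller gene wins
  gr <- GenomicRanges::GRanges(
    seqnames = "t", ranges = IRanges::IRanges(c(1000L, 1640L),
                                              c(1500L, 2200L)),
    strand = c("+", "+"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = c("zeta", "alpha"), kind = c("PCG", "PCG"),
    exon_rank = c(1L, 1L), copy = c(1L, 1L))
  cp <- new("RepeatCatalog", genomeId = "t", genomeLength = 5000L,
            minLength = 30L,
            units = data.frame(unit_id = "R1", length = 40L,
                               representative = strrep("A", 40)),
            copies = data.frame(unit_id = "R1", start = 1550L,
                                end = 1589L, strand = "+"),
            pairs = data.frame())
  loc2 <- localizeRepeats(cp, gr, upstreamWindow = 1000)
  ## gaps: 49 bp to zeta (downstream of it) and 50 to alpha; smaller wins
  expect_identical(loc2$anchor_gene, "zeta")
  expect_equal(loc2$distance, 49L)
})

test_that("hotspot percentages follow copy counts over the pooled total", {
  loc <- data.frame(
    context = rep(c("internal", "intergenic_other"), c(3, 7)),
    anchor_gene = rep(c("geneX", NA), c(3, 7)))
  hs <- hotspotSummary(loc)
  expect_equal(hs$percent[hs$gene == "geneX"], 30)
  expect_equal(attr(hs, "total"), 10L)
  expect_warning(h0 <- hotspotSummary(loc[0, ]), "zero")
  expect_equal(nrow(h0), 0L)
})
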