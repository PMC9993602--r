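test_that("isomer construction flips exactly the inter-repeat segment", {
  iso <- isomerFixture(seed = 61)
  pair <- iso$pair
  s1 <- strsplit(as.character(plastomeSeq(isomer1(pair))), "")[[1]]
  s2 <- strsplit(as.character(plastomeSeq(isomer2(pair))), "")[[1]]
  expect_equal(length(s1), length(s2))
  d <- which(s1 != s2)
  inner <- (pair@repeatA[2] + 1L):(pair@repeatB[1] - 1L)
  expect_true(length(d) > 0 && all(d %in% inner))
  ## the flipped inner segment is the reverse complement of the original
  expect_identical(paste(s2[inner], collapse = ""),
                   revComp(paste(s1[inner], collapse = "")))
  ## both repeat copies are regenerated identically
  for (iv in list(pair@repeatA, pair@repeatB))
    expect_identical(
      extractInterval(isomer2(pair), iv[1], iv[2]),
      extractInterval(isomer1(pair), iv[1], iv[2]))
  ## involution: flipping again restores the input
  again <- buildIsomer(isomer2(pair), pair@repeatA, pair@repeatB)
  expect_identical(as.character(plastomeSeq(isomer2(again))),
                   as.character(plastomeSeq(isomer1(pair))))
  ## a direct pair mediates no isomer
  s <- randomDna(5000, seed = 62)
  unit <- randomDna(100)
  s <- plantAt(plantAt(s, 1001, unit), 3001, unit)
  expect_error(buildIsomer(PlastomeRecord("d", s), c(1001L, 1100L),
                           c(3001L, 3100L)), "direct")
})

test_that("junction windows have repeat-plus-flank geometry", {
  iso <- isomerFixture(seed = 63)
  w <- junctionWindows(iso$pair, flank = 1000)
  expect_length(w, 4L)
  expect_true(all(vapply(w, function(x) nchar(x$seq), integer(1)) ==
                    679L + 2000L))
  ## the two isomers' windows share the core and differ in one flank
  w1 <- w[[1]]$seq; w3 <- w[[3]]$seq  # left windows of isomer1/isomer2
  core <- function(x) substr(x, 1001, 1000 + 679)
  expect_identical(core(w1), core(w3))
  expect_identical(substr(w1, 1, 1000), substr(w3, 1, 1000))  # outer
  expect_false(substr(w1, 1680, 2679) == substr(w3, 1680, 2679))
  expect_error(junctionWindows(iso$pair, flank = 0), "flank")
  expect_error(junctionWindows(iso$pair, flank = 40000), "overlap")
})

test_that("spanning-read counting assigns reads and estimates frequency", {
  iso <- isomerFixture(seed = 64)
  w <- junctionWindows(iso$pair, flank = 1000)
  ## reads solely from isomer1: zero isomer2 support
  r1 <- simulateLongReads(iso$pair, nReads = 150, isomer2Prop = 0,
                          seed = 65)
  rs1 <- countSpanningReads(w, r1)
  expect_equal(unname(rs1$counts[c("isomer2.left", "isomer2.right")]),
               c(0L, 0L))
  expect_equal(rs1$frequency, 0)
  expect_gt(rs1$n_assigned, 0)
  ## conservation: at most one isomer per read
  expect_lte(rs1$n_assigned + rs1$n_ambiguous, length(r1))

  ## a read shorter than repeat + 2*flank can never be counted
  short <- Biostrings::DNAStringSet(
    setNames(substr(w[[1]]$seq, 200, 2400), "short"))
  rs0 <- countSpanningReads(w, short)
  expect_equal(rs0$n_assigned, 0L)

  ## empty read set: zero counts, undefined frequency
  expect_warning(rsE <- countSpanningReads(w, character()), "empty")
  expect_true(is.na(rsE$frequency))

  ## balanced mixture: frequency near 50%
  rM <- simulateLongReads(iso$pair, nReads = 240, isomer2Prop = 0.5,
                          seed = 66)
  rsM <- countSpanningReads(w, rM)
  counted <- rsM$n_assigned
  se <- 100 * sqrt(0.25 / counted)
  expect_lt(abs(rsM$frequency - 50), 3 * se + 1e-9)
})

test_that("increasing the required flank never increases support", {
  iso <- isomerFixture(seed = 67)
  w <- junctionWindows(iso$pair, flank = 1200)
  r <- simulateLongReads(iso$pair, nReads = 120, isomer2Prop = 0.3,
                         seed = 68)
  n1 <- countSpanningReads(w, r, flankRequired = 800)$n_assigned
  n2 <- countSpanningReads(w, r, flankRequired = 1200)$n_assigned
  expect_lte(n2, n1)
  expect_error(countSpanningReads(w, r, flankRequired = 1500), "exceeds")
})

test_that("short-read pairs discriminate configurations by straddling", {
  iso <- isomerFixture(seed = 69)
  pair <- iso$pair
  w <- junctionWindows(pair, flank = 1000)
  p1 <- simulateShortReadPairs(pair, nPairs = 1500, readLen = 150,
                               insertMin = 1400, insertMax = 2000,
                               isomer2Prop = 0, seed = 70)
  chk1 <- shortReadConfigurationCheck(w, p1$mate1, p1$mate2)
  expect_true(chk1[["isomer1"]])
  expect_false(chk1[["isomer2"]])
  pM <- simulateShortReadPairs(pair, nPairs = 1500, readLen = 150,
                               insertMin = 1400, insertMax = 2000,
                               isomer2Prop = 0.5, seed = 71)
  chkM <- shortReadConfigurationCheck(w, pM$mate1, pM$mate2)
  expect_true(all(chkM))
  ## inserts shorter than the repeat cannot straddle it
  pS <- simulateShortReadPairs(pair, nPairs = 40, readLen = 150,
                               insertMin = 300, insertMax = 500,
                               isomer2Prop = 0, seed = 72)
  expect_warning(chkS <- shortReadConfigurationCheck(w, pS$mate1,
                                                     pS$mate2),
                 "straddl")
  expect_false(any(chkS))
  expect_error(shortReadConfigurationCheck(w, pS$mate1,
                                           pS$mate2[-1]), "unpaired")
})
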