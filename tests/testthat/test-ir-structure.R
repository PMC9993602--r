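test_that("a random circle without a planted IR is classed ir_free", {
  set.seed(21)
  rec <- PlastomeRecord("r", randomDna(10000))
  p <- detectInvertedRepeat(rec, minIrLen = 100)
  expect_identical(structureClass(p), "ir_free")
  expect_equal(irLength(p), 0L)
  expect_equal(p@lsc, c(1L, 10000L))  # whole-circle convention
  expect_error(detectInvertedRepeat(PlastomeRecord("l", randomDna(5000),
                                                   circular = FALSE)),
               "circular")
})

test_that("an exact planted inverted pair is recovered at exact extent", {
  ## miniature checked against the brute-force diagonal oracle
  set.seed(22)
  s <- randomDna(2000)
  arm <- randomDna(300)
  s <- plantAt(s, 401, arm)
  s <- plantAt(s, 1301, revComp(arm))
  orc <- oracleRepeatPairs(s, 100)
  best <- orc[orc$strand == "-", ][1, ]
  p <- detectInvertedRepeat(PlastomeRecord("m", s), minIrLen = 100,
                            residualThreshold = 100)
  expect_equal(unname(p@irb[1]), best$start1)
  expect_equal(irLength(p), best$length)

  ## 20 kb circle with a 1.5 kb planted pair at known offsets
  set.seed(23)
  s <- randomDna(20000)
  arm <- randomDna(1500)
  s <- plantAt(s, 3001, arm)
  s <- plantAt(s, 12001, revComp(arm))
  ## block chance single-base extension at the planted edges
  ch <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ch[13501] == comp[[ch[3000]]]) ch[13501] <- setdiff(c("A","C","G","T"), ch[13501])[1]
  if (ch[12000] == comp[[ch[4501]]]) ch[12000] <- setdiff(c("A","C","G","T"), ch[12000])[1]
  s <- paste(ch, collapse = "")
  p <- detectInvertedRepeat(PlastomeRecord("x", s), minIrLen = 100)
  expect_equal(unname(p@irb), c(3001L, 4500L))
  expect_equal(unname(p@ira), c(12001L, 13500L))
  expect_equal(irLength(p), 1500L)
})

test_that("partition tiles the circle and classes follow the IR length", {
  for (seed in 1:4) {
    irl <- c(437L, 1964L, 10191L, 33169L)[seed]
    g <- generatePlastome(plastomeSpec(seed + 40L,
                                       lscLen = 40000L, sscLen = 15000L,
                                       irLen = irl))
    p <- detectInvertedRepeat(g$record)
    reg <- partitionRegions(p)
    expect_equal(sum(reg$length), plastomeLength(g$record))
    ## pairwise disjoint on the circle: sorted starts partition [1, L]
    expect_setequal(reg$start, c(1L, cumsum(reg$length)[-4] + 1L))
    expect_identical(structureClass(p),
                     if (irl < 2000) "residual_ir" else "quadripartite")
    ## IRb/IRa are reverse complements
    expect_identical(
      extractInterval(g$record, p@irb[1], p@irb[2]),
      revComp(extractInterval(g$record, p@ira[1], p@ira[2])))
  }
})

test_that("re-origining inside the SSC leaves the partition invariant", {
  g <- generatePlastome(plastomeSpec(47, lscLen = 30000L, sscLen = 12000L,
                                     irLen = 6000L))
  p <- detectInvertedRepeat(g$record)
  L <- plastomeLength(g$record)
  shift <- p@ssc[1] + 500L   # origin inside SSC
  p2 <- detectInvertedRepeat(reoriginPlastome(g$record, shift))
  expect_equal(irLength(p2), irLength(p))
  back <- function(x) ((x + shift - 2L) %% L) + 1L
  expect_equal(back(p2@irb[1]), unname(p@irb[1]))
  expect_equal(back(p2@ira[1]), unname(p@ira[1]))
})

test_that("junction contexts report spanning and flanking genes", {
  ## gene straddling JLB by construction: custom census places trnK at the
  ## very end of the LSC? Build manually instead.
  g <- generatePlastome(plastomeSpec(48, lscLen = 20000L, sscLen = 8000L,
                                     irLen = 3000L))
  p <- detectInvertedRepeat(g$record)
  L <- plastomeLength(g$record)
  ## synthetic features: one spanning JLB (LSC end = 20000), one ending
  ## exactly at the junction, one 500 bp to its left
  gr <- GenomicRanges::GRanges(
    seqnames = plastomeId(g$record),
    ranges = IRanges::IRanges(start = c(19900L, 19800L, 19000L),
                              end = c(20050L, 20000L, 19200L)),
    strand = c("+", "+", "+"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = c("spanG", "endG", "farG"), kind = rep("PCG", 3),
    exon_rank = rep(1L, 3), copy = rep(1L, 3))
  jc <- junctionContext(p, gr)
  jlb <- jc[jc$junction == "JLB", ]
  expect_identical(jlb$spanning_gene, "spanG")
  expect_identical(jlb$left_gene, "endG")   # ends exactly at the junction
  expect_equal(jlb$left_dist, 0L)
  expect_error(junctionContext(detectInvertedRepeat(
    PlastomeRecord("f", randomDna(9000))), gr), "ir_free")
  expect_warning(junctionContext(p, plastomeKit:::emptyFeatures()),
                 "no features")
})

test_that("IR capture of named genes is visible in the partition", {
  ## emulate an IR that has expanded to capture trnH, psbA, matK, trnK
  census <- c(defaultGeneCensus(0), list(
    censusEntry("trnH", "tRNA", 74L, strand = "+", region = "IR"),
    censusEntry("psbA2", "PCG", 1062L, strand = "-", region = "IR"),
    censusEntry("matK2", "PCG", 1530L, strand = "-", region = "IR"),
    censusEntry("trnK", "tRNA", 72L, strand = "+", region = "IR")))
  census <- Filter(function(e) !(e$name %in% c("psbA", "matK")), census)
  g <- generatePlastome(plastomeSpec(49, lscLen = 30000L, sscLen = 12000L,
                                     irLen = 6000L, census = census))
  p <- detectInvertedRepeat(g$record)
  fl <- plastomeFeatures(g$record)
  inIra <- fl[GenomicRanges::start(fl) >= p@ira[1] &
              GenomicRanges::end(fl) <= p@ira[2]]
  expect_true(all(c("trnH", "psbA2", "matK2", "trnK") %in% inIra$gene))
})

test_that("boundary comparison reports IR gains and losses by side", {
  mkGenome <- function(seed, irGenes) {
    census <- c(defaultGeneCensus(0), irGenes)
    generatePlastome(plastomeSpec(seed, lscLen = 30000L, sscLen = 12000L,
                                  irLen = 6000L, census = census))
  }
  refIr <- list(censusEntry("rpl2", "PCG", 828L, strand = "-",
                            region = "IR"),
                censusEntry("trnM", "tRNA", 73L, strand = "+",
                            region = "IR"))
  ## in the contracted target, rpl2 has moved out of the IR into the LSC
  tgtIr <- list(censusEntry("trnM", "tRNA", 73L, strand = "+",
                            region = "IR"),
                censusEntry("rpl2", "PCG", 828L, strand = "-",
                            region = "LSC"))
  ref <- mkGenome(71, refIr); tgt <- mkGenome(72, tgtIr)
  cb <- compareBoundaries(
    list(partition = detectInvertedRepeat(tgt$record),
         features = plastomeFeatures(tgt$record)),
    list(partition = detectInvertedRepeat(ref$record),
         features = plastomeFeatures(ref$record)))
  lost <- unique(unlist(strsplit(cb$genes_lost_by_ir, ",")))
  expect_true("rpl2" %in% lost)
  expect_true(any(cb$direction == "contraction"))
  ## identity comparison is all-unchanged
  cb0 <- compareBoundaries(
    list(partition = detectInvertedRepeat(ref$record),
         features = plastomeFeatures(ref$record)),
    list(partition = detectInvertedRepeat(ref$record),
         features = plastomeFeatures(ref$record)))
  expect_true(all(cb0$direction == "unchanged"))
  expect_true(all(cb0$genes_gained_by_ir == ""))
})

test_that("partition table reports sizes and GC to two decimals", {
  expect_equal(partitionTable(PlastomeRecord("gc", strrep("GC", 200)),
                              list(new("QuadripartitePartition",
                                       genomeLength = 400L, irLength = 0L,
                                       structureClass = "ir_free",
                                       lsc = c(1L, 400L),
                                       ssc = c(NA_integer_, NA_integer_),
                                       irb = c(NA_integer_, NA_integer_),
                                       ira = c(NA_integer_, NA_integer_))
                                   ))$gc_percent, 100)
  rec <- PlastomeRecord("at", "ATGC")
  p <- new("QuadripartitePartition", genomeLength = 4L, irLength = 0L,
           structureClass = "ir_free", lsc = c(1L, 4L),
           ssc = c(NA_integer_, NA_integer_),
           irb = c(NA_integer_, NA_integer_),
           ira = c(NA_integer_, NA_integer_))
  expect_equal(partitionTable(rec, list(p))$gc_percent, 50)
})
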