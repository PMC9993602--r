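test_that("FASTA reading canonicalizes case and round-trips exactly", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 test", "acgtACGT", ">p2", "GGGTTTAAA"), tf)
  recs <- readPlastomes(tf)
  expect_length(recs, 2)
  expect_identical(as.character(plastomeSeq(recs[[1]])), "ACGTACGT")
  expect_identical(plastomeId(recs[[1]]), "p1")

  ## write-then-read round trip over 50 random records
  set.seed(101)
  recs <- lapply(1:50, function(i)
    PlastomeRecord(paste0("r", i), randomDna(sample(50:500, 1))))
  tf2 <- withr::local_tempfile(fileext = ".fasta")
  writePlastomes(recs, tf2)
  back <- readPlastomes(tf2)
  expect_identical(vapply(back, function(r) as.character(plastomeSeq(r)),
                          character(1)),
                   vapply(recs, function(r) as.character(plastomeSeq(r)),
                          character(1)))
})

test_that("empty and degenerate FASTA inputs are rejected", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), tf)
  expect_error(readPlastomes(tf), "empty")
  writeLines(c(">x", "ACGRRT"), tf)  # ambiguity beyond N
  expect_error(readPlastomes(tf), "ambiguity")
  expect_error(readPlastomes("no/such/file.fasta"), "no such file")
})

test_that("reverse complement is an involution with standard complement", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("AAAC"), "GTTT")
  expect_identical(revComp("ANT"), "ANT")
  expect_error(revComp("ACXGT"), "invalid residue")
  set.seed(7)
  for (i in 1:100) {
    s <- randomDna(sample(1:200, 1))
    expect_identical(revComp(revComp(s)), s)
  }
})

test_that("extractInterval agrees with the doubling oracle", {
  expect_identical(extractInterval("ACGTTT", 1, 4), "ACGT")
  expect_identical(extractInterval("ACGTTT", 5, 2), "TTAC")  # wraps
  expect_identical(extractInterval("ACGTTT", 1, 4, strand = "-"),
                   revComp("ACGT"))
  expect_error(extractInterval("ACGTTT", 3, 2 + 6 + 6), "longer")
  set.seed(11)
  s <- randomDna(200)
  for (i in 1:200) {
    a <- sample(200, 1)
    len <- sample(1:199, 1)
    b <- a + len - 1
    str <- sample(c("+", "-"), 1)
    expect_identical(extractInterval(s, a, b, str),
                     oracleExtract(s, a, b, str))
  }
})

test_that("GFF3 annotations round-trip and keep 1-based file coordinates", {
  g <- generatePlastome(plastomeSpec(61, lscLen = 12000, sscLen = 6000,
                                     irLen = 3000))
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotations(g$record, tf)
  back <- readAnnotations(tf, "gff3",
                          genomeLength = plastomeLength(g$record))
  fl <- plastomeFeatures(g$record)
  ord <- function(x) order(GenomicRanges::start(x), x$gene, x$exon_rank)
  back <- back[ord(back)]; fl <- fl[ord(fl)]
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(fl))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(fl))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(fl)))
  expect_equal(back$gene, fl$gene)
  expect_equal(back$exon_rank, fl$exon_rank)

  ## file text is 1-based inclusive: the GFF3 start column equals the
  ## internal 1-based start
  ln <- grep("\tCDS\t", readLines(tf), value = TRUE)[1]
  cols <- strsplit(ln, "\t")[[1]]
  gene1 <- sub(".*gene=([^;]+).*", "\\1", cols[9])
  sel <- fl[fl$gene == gene1]
  expect_true(as.integer(cols[4]) %in% GenomicRanges::start(sel))
})

test_that("multi-exon GFF3 lines sharing a gene group into one feature", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tx\tCDS\t1\t90\t.\t+\t0\tID=e1;Parent=gA",
               "chr\tx\tCDS\t200\t290\t.\t+\t0\tID=e2;Parent=gA"), tf)
  f <- readAnnotations(tf, "gff3")
  expect_length(f, 2)
  expect_equal(unique(unlist(f$gene)), "gA")
  expect_equal(GenomicRanges::start(f), c(1L, 200L))
  expect_equal(f$exon_rank, c(1L, 2L))
  expect_error(readAnnotations(tf, "gff3", genomeLength = 100), "exceeds")
})

test_that("GenBank join on the complement strand orders exons 5' to 3'", {
  gb <- c(
    "LOCUS       gbt    600 bp    DNA     circular PLN 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "     CDS             complement(join(100..200,300..400))",
    "                     /gene=\"rpl2\"",
    "     rRNA            450..550",
    "                     /gene=\"rrn5\"",
    "     repeat_region   10..20",
    "ORIGIN",
    vapply(seq(1, 600, by = 60), function(o)
      paste0(formatC(o, width = 9), " ",
             paste(rep("acgtacgtac", 6), collapse = " ")),
      character(1)),
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  expect_warning(res <- readAnnotations(tf, "genbank"), "unknown kind")
  f <- res$features
  rpl2 <- f[f$gene == "rpl2"]
  expect_equal(as.character(GenomicRanges::strand(rpl2)), c("-", "-"))
  ## genomically last segment transcribes first on the minus strand
  expect_equal(rpl2$exon_rank[GenomicRanges::start(rpl2) == 300], 1L)
  expect_equal(rpl2$exon_rank[GenomicRanges::start(rpl2) == 100], 2L)
  expect_true(isCircularGenome(res$record))
  expect_equal(plastomeLength(res$record), 600L)
})

test_that("FASTQ reads round-trip through write and read", {
  set.seed(5)
  reads <- Biostrings::DNAStringSet(c(a = randomDna(80), b = randomDna(120)))
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeLongReads(reads, tf)
  back <- readLongReads(tf)
  expect_identical(as.character(back), as.character(reads))
})
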