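# Sequence/table IO: round trips, validation errors, canonical ordering.

test_that("FASTA read/write round-trips and handles edge cases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_length(readFasta(f), 0)

  writeLines(c(">s1", "ACGT"), f)
  expect_identical(readFasta(f), c(s1 = "ACGT"))

  # lowercase and wrapped sequence lines are normalized
  writeLines(c(">s1 extra words", "acg", "t"), f)
  expect_identical(readFasta(f), c(s1 = "ACGT"))

  set.seed(42)
  seqs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(50:80, 1), replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- sprintf("r%03d", 1:100)
  writeFasta(seqs, f)
  expect_identical(readFasta(f), seqs)
})

test_that("malformed FASTA reports the offending line", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", ">s3", "ACGT"), f)
  expect_error(readFasta(f), "line 3")
  writeLines(c("ACGT"), f)
  expect_error(readFasta(f), "line 1")
  writeLines(c(">s1", "ACGT", ">s1", "ACGT"), f)
  expect_error(readFasta(f), "duplicated")
})

test_that("FASTQ read/write round-trips with Phred+33 qualities", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  x <- readFastq(f)
  expect_identical(x$seq, c(r1 = "ACGT"))
  expect_identical(x$qual$r1, rep(40L, 4))

  writeLines(character(0), f)
  expect_length(readFastq(f)$seq, 0)

  set.seed(7)
  seqs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("q%03d", 1:100)
  qual <- lapply(1:100, function(i) sample(2:40, 60, replace = TRUE))
  names(qual) <- names(seqs)
  writeFastq(seqs, f, qual)
  y <- readFastq(f)
  expect_identical(y$seq, seqs)
  expect_identical(y$qual, qual)
})

test_that("malformed FASTQ reports a line-numbered error", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(readFastq(f), "line 4")
  writeLines(c("@r1", "ACGT", "+"), f)
  expect_error(readFastq(f), "truncated")
})

test_that("mapping tables are validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- data.frame(sample = c("a", "b"), barcode = c("ACGTACGT", "TTGGCCAA"),
                  fwd_primer = "GAATTGCAGAACTCCGTG",
                  rev_primer = "ACCCGCTGAACTTAAGCATATGGATCCC")
  writeMapping(m, f)
  expect_equal(readMapping(f)$sample, c("a", "b"))

  m2 <- m
  m2$barcode <- c("ACGTACGT", "ACGTACGT")
  writeMapping(m2, f)
  expect_error(readMapping(f), "duplicate barcode")

  m3 <- m
  m3$barcode <- c("ACGTACGT", "TTGG")
  writeMapping(m3, f)
  expect_error(readMapping(f), "equal length")
})

test_that("simulated multi-sample mapping parses back to simulator truth", {
  tmpl <- simulateCladeTemplates(1, length = 300, seed = 3)
  g <- genomeModel("A1", "A", tmpl[[1]], n_rare_variants = 2)
  scen <- lapply(1:15, function(i)
    list(genomes = list(g), proportions = 1, n_reads = 5))
  names(scen) <- sprintf("s%02d", 1:15)
  sim <- simulateExperiment(scen, seed = 21)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMapping(sim$mapping, f)
  m <- readMapping(f)
  expect_identical(m$sample, names(scen))
  expect_identical(m$barcode, sim$mapping$barcode)
})

test_that("count tables round-trip losslessly with conserved totals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- dereplicate(list(s1 = character(0), s2 = character(0)))
  writeCountTable(empty, f)
  back <- readCountTable(f)
  expect_equal(nVariants(back), 0)

  vc <- variantCounts(c("ACGT", "AAAA", "CCCC"),
                      matrix(c(5L, 0L, 2L, 1L, 3L, 0L), ncol = 2,
                             dimnames = list(NULL, c("s1", "s2"))))
  writeCountTable(vc, f, header = "demo")
  back <- readCountTable(f)
  expect_identical(variantSequences(back), variantSequences(vc))
  expect_identical(countMatrix(back), countMatrix(vc))
  expect_equal(colSums(countMatrix(back)), colSums(countMatrix(vc)))
})

test_that("variant tables keep a canonical, bit-stable order", {
  vc <- variantCounts(c("TTTT", "AAAA", "CCCC"), c(2L, 5L, 2L))
  expect_identical(unname(variantSequences(vc)), c("AAAA", "CCCC", "TTTT"))
  expect_identical(variantIds(vc), c("v00001", "v00002", "v00003"))
  expect_error(variantCounts(c("ACGT", "ACGT"), c(1L, 2L)), "unique")
})

test_that("reference databases validate and round-trip via FASTA", {
  db <- referenceDb(c("A1", "B1"), c("ACGTACGT", "TTGGTTGG"), "GS")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeReferenceFasta(db, f)
  back <- readReferenceFasta(f)
  expect_identical(back$type_name, db$type_name)
  expect_identical(back$seq, db$seq)
  expect_identical(back$source_tag, db$source_tag)
  expect_error(referenceDb(c("A1", "A1"), c("ACGT", "ACGT"), "GS"),
               "duplicate")
})
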