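# Two-tier OTU framework: clustering, clade binning, length screen,
# representatives, annotation, full pipeline.

test_that("average-neighbour clustering matches the worked example", {
  dm <- matrix(c(0, .01, .05, .01, 0, .05, .05, .05, 0), 3, 3,
               dimnames = rep(list(c("a", "b", "c")), 2))
  part <- averageNeighborCluster(dm, 0.03)
  memb <- otuMembership(part)
  # {a,b} merge at 0.01; joining c would average 0.05 > 0.03
  expect_equal(nOtus(part), 2)
  expect_equal(memb[["a"]], memb[["b"]])
  expect_false(memb[["a"]] == memb[["c"]])

  single <- averageNeighborCluster(matrix(0, 1, 1,
                                          dimnames = list("x", "x")), 0.03)
  expect_equal(nOtus(single), 1)
  expect_error(averageNeighborCluster(matrix(numeric(0), 0, 0), 0.03),
               "empty")
})

test_that("clustering equals naive O(n^3) agglomeration on random matrices", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    dm <- randomDistanceMatrix(n)
    cutoff <- runif(1, 0.02, 0.45)
    got <- membershipToSets(otuMembership(averageNeighborCluster(dm, cutoff)))
    want <- partitionSets(naiveAverageNeighbor(dm, cutoff))
    expect_identical(got, want)
  }
})

test_that("merges at exactly the cut-off are performed (closed threshold)", {
  dm <- matrix(c(0, .03, .03, 0), 2, 2, dimnames = rep(list(c("a", "b")), 2))
  expect_equal(nOtus(averageNeighborCluster(dm, 0.03)), 1)
  expect_equal(nOtus(averageNeighborCluster(dm, 0.0299)), 2)
})

test_that("cluster count is non-increasing in the cut-off", {
  set.seed(101)
  dm <- randomDistanceMatrix(10)
  cuts <- seq(0, 0.5, by = 0.05)
  ns <- vapply(cuts, function(co)
    nOtus(averageNeighborCluster(dm, co)), integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_equal(ns[1], 10) # cutoff 0 -> one cluster per variant
})

test_that("clade assignment separates divergent groups, ordered by reads", {
  base <- repeatTemplate(100)
  tight <- variantCounts(c(base, substituteAt(base, 10), substituteAt(base, 50)),
                         c(3L, 2L, 1L))
  expect_equal(max(assignClades(tight, clade_cutoff = 0.15)), 1)

  L <- 200
  a <- oracleTemplate(L)
  b <- substituteAt(a, seq(1, 160, by = 4)) # ~0.2 divergent group
  vc <- variantCounts(c(a, substituteAt(a, 3), b, substituteAt(b, 7)),
                      c(10L, 5L, 100L, 50L))
  cl <- assignClades(vc, clade_cutoff = 0.15)
  expect_equal(max(cl), 2)
  # clade 1 must be the one with more reads (the b group)
  b_ids <- variantIds(vc)[match(c(b, substituteAt(b, 7)),
                                variantSequences(vc))]
  expect_true(all(cl[b_ids] == 1))
})

test_that("three simulated clades are recovered with truth labels", {
  tmpl <- simulateCladeTemplates(3, length = 300, seed = 55)
  genomes <- lapply(names(tmpl), function(cl)
    genomeModel(paste0(cl, "1"), cl, tmpl[[cl]], n_rare_variants = 5,
                max_intra_divergence = 0.02))
  libs <- lapply(seq_along(genomes), function(i)
    simulateRdnaLibrary(genomes[[i]], seed = 100 + i))
  seqs <- unlist(lapply(libs, `[[`, "sequence"))
  truth <- rep(names(tmpl), vapply(libs, nrow, integer(1)))
  vc <- variantCounts(seqs, rep(10L, length(seqs)))
  truth <- truth[match(variantSequences(vc), seqs)]
  cl <- assignClades(vc, clade_cutoff = 0.15)
  expect_equal(max(cl), 3)
  expect_equal(length(unique(paste(cl, truth))), 3) # clades == truth labels
})

test_that("length screen discards variants shorter than 90% of the clade", {
  same <- variantCounts(rep(c("AACC", "GGTT", "ACGT"), 1), c(3L, 2L, 1L))
  expect_length(lengthScreen(same)$discarded, 0)

  seqs <- c(vapply(1:9, function(i) substituteAt(repeatTemplate(300), i),
                   character(1)), repeatTemplate(200))
  vc <- variantCounts(seqs, rep(5L, 10))
  scr <- lengthScreen(vc, 0.90)
  expect_length(scr$discarded, 1)
  expect_equal(nchar(variantSequences(vc)[scr$discarded][[1]]), 200)

  # uniform lengths 250..340: exactly the reads shorter than the
  # nearest-rank threshold are dropped (brute-force cross-check)
  lens <- 250:340
  seqs2 <- vapply(lens, repeatTemplate, character(1))
  vc2 <- variantCounts(seqs2, rep(2L, length(lens)))
  scr2 <- lengthScreen(vc2, 0.90)
  thr <- sort(lens)[floor(0.1 * length(lens)) + 1]
  manual <- sum(lens < thr)
  expect_length(scr2$discarded, manual)
  expect_true(all(nchar(variantSequences(vc2)[scr2$discarded]) < thr))
})

test_that("representative is the most abundant member, ties by sequence", {
  vc <- variantCounts(c("AATT", "CCGG"), c(100L, 5L))
  expect_equal(pickRepresentative(vc), variantIds(vc)[1])
  expect_identical(variantSequences(vc)[[pickRepresentative(vc)]], "AATT")

  one <- variantCounts("ACGT", 3L)
  expect_equal(pickRepresentative(one), "v00001")

  tie <- variantCounts(c("AAC", "AAA"), c(7L, 7L))
  expect_identical(variantSequences(tie)[[pickRepresentative(tie)]], "AAA")
})

test_that("nearest reference returns the best-identity type", {
  L <- 320
  entry <- repeatTemplate(L)
  db <- referenceDb(c("A1", "B1"),
                    c(entry, substituteAt(entry, seq(1, 300, by = 4))), "GS")
  hit <- nearestReference(entry, db)
  expect_identical(hit$type_name, "A1")
  expect_equal(hit$pct_identity, 100)

  hit1 <- nearestReference(substituteAt(entry, 17), db)
  expect_identical(hit1$type_name, "A1")
  expect_equal(hit1$pct_identity, 100 * 319 / 320)

  expect_error(nearestReference(entry, data.frame()), "empty")
})

test_that("the full pipeline collapses an isoclonal culture to one OTU", {
  tmpl <- simulateCladeTemplates(2, length = 330, seed = 2)
  gB <- genomeModel("B1", "B", tmpl[["B"]], n_rare_variants = 29)
  sim <- simulateExperiment(
    list(cultB = list(genomes = list(gB), proportions = 1, n_reads = 4000)),
    seed = 19)
  res <- runPipeline(sim$reads, sim$mapping, sim$refdb)
  expect_equal(nrow(res$otuTable), 1)
  expect_identical(res$otuTable$type_name, "B1")
  # the single OTU holds >=99% of the retained reads (and >=94% of all
  # demultiplexed reads; the rest are singleton error variants)
  expect_gte(res$otuTable$cultB / sum(countMatrix(res$variants)), 0.99)
  expect_gte(res$otuTable$cultB / sum(res$report$kept), 0.94)
  # read counts conserved from variant table into the OTU table
  expect_equal(sum(res$otuTable$cultB), sum(countMatrix(res$variants)))
})

test_that("a two-species mixture yields exactly two annotated OTUs", {
  tmpl <- simulateCladeTemplates(2, length = 330, seed = 2)
  gA <- genomeModel("A1", "A", tmpl[["A"]], n_rare_variants = 10)
  gB <- genomeModel("B1", "B", tmpl[["B"]], n_rare_variants = 10,
                    rdna_copy_weight = 5)
  sim <- simulateExperiment(
    list(mix = list(genomes = list(gA, gB), proportions = c(0.5, 0.5),
                    n_reads = 4000)), seed = 23)
  res <- runPipeline(sim$reads, sim$mapping, sim$refdb)
  expect_equal(nrow(res$otuTable), 2)
  expect_setequal(res$otuTable$type_name, c("A1", "B1"))
})

test_that("an empty retained set raises a stage-labelled error", {
  m <- data.frame(sample = "s1", barcode = "ACACACAC",
                  fwd_primer = "GAATTGCAGAACTCCGTG",
                  rev_primer = "ACCCGCTGAACTTAAGCATATGGATCCC")
  db <- referenceDb("A1", repeatTemplate(300))
  reads <- c(r1 = "TTTTTTTT") # wrong barcode
  expect_error(runPipeline(reads, m, db), "demultiplex")
  # reads pass demux but fail the length screen
  reads2 <- stats::setNames(
    rep(paste0(m$barcode, m$fwd_primer, "ACGTACGT"), 3),
    paste0("r", 1:3))
  expect_error(runPipeline(reads2, m, db), "quality_filter")
})
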