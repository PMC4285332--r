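# Read-level stages: demultiplexing, primer trimming, filtering,
# dereplication, singleton removal, chimera flagging.

mk_mapping <- function() {
  data.frame(sample = c("s1", "s2"),
             barcode = c("ACACACAC", "GTGTGTGT"),
             fwd_primer = "GAATTGCAGAACTCCGTG",
             rev_primer = "ACCCGCTGAACTTAAGCATATGGATCCC",
             stringsAsFactors = FALSE)
}

test_that("demultiplex enforces barcode and forward-primer thresholds", {
  m <- mk_mapping()
  tmpl <- repeatTemplate(300)
  good <- paste0(m$barcode[1], m$fwd_primer[1], tmpl)
  bc1 <- paste0(substituteAt(m$barcode[1], 1), m$fwd_primer[1], tmpl)
  fp2 <- paste0(m$barcode[1], substituteAt(m$fwd_primer[1], c(3, 7)), tmpl)
  fp3 <- paste0(m$barcode[1], substituteAt(m$fwd_primer[1], c(3, 7, 11)), tmpl)
  reads <- c(r1 = good, r2 = bc1, r3 = fp2, r4 = fp3)
  dx <- demultiplex(reads, m)
  # exact read assigned with prefix removed; 1 barcode mismatch discarded;
  # 2 primer mismatches kept (2 <= 2); 3 discarded
  expect_identical(unname(dx$samples$s1), c(tmpl, tmpl))
  expect_identical(names(dx$samples$s1), c("r1", "r3"))
  expect_equal(dx$report["unassigned", "barcode"], 1)
  expect_equal(dx$report["s1", "fwd_primer"], 1)
  expect_equal(sum(dx$report$input),
               length(reads))
  expect_equal(sum(dx$report$kept) + sum(dx$report$barcode) +
                 sum(dx$report$fwd_primer), length(reads))
})

test_that("demultiplex is IUPAC-aware on the primer side", {
  m <- mk_mapping()
  m$fwd_primer <- "GAATTGCAGRACTCCGTG" # R = A/G at position 10
  tmpl <- repeatTemplate(300)
  readA <- paste0(m$barcode[1], "GAATTGCAGAACTCCGTG", tmpl)
  readG <- paste0(m$barcode[1], "GAATTGCAGGACTCCGTG", tmpl)
  dx <- demultiplex(c(a = readA, g = readG), m)
  expect_length(dx$samples$s1, 2)
  expect_equal(dx$report["s1", "fwd_primer"], 0)
})

test_that("reverse-primer trimming honours the overall error rate", {
  primer <- "ACCCGCTGAACTTAAGCA" # 18 nt, non-periodic
  insert <- repeatTemplate(280)
  clean <- paste0(insert, primer)
  mm2 <- paste0(insert, substituteAt(primer, c(4, 9)))
  mm3 <- paste0(insert, substituteAt(primer, c(4, 9, 14)))
  tr <- trimReversePrimer(c(a = clean, b = mm2, c = mm3), primer,
                          error_rate = 0.15)
  # 0/18 and 2/18 ~ 0.11 <= 0.15 are trimmed; 3/18 ~ 0.167 is not
  expect_identical(tr$trimmed, c(TRUE, TRUE, FALSE))
  expect_identical(unname(tr$seq[1:2]), c(insert, insert))
  expect_identical(unname(tr$seq[3]), mm3)

  none <- trimReversePrimer(c(x = insert), primer)
  expect_false(none$trimmed)
  expect_identical(unname(none$seq), insert)
})

test_that("reverse-primer trimming accepts partial 3' overlaps >= 8 nt", {
  primer <- "GTCAAGGTCCATGGTCAA"
  insert <- repeatTemplate(280)
  partial <- paste0(insert, substr(primer, 1, 10))
  tr <- trimReversePrimer(c(p = partial), primer)
  expect_true(tr$trimmed)
  expect_identical(unname(tr$seq), insert)
  short <- paste0(insert, substr(primer, 1, 5)) # below min overlap
  expect_false(trimReversePrimer(c(p = short), primer)$trimmed)
})

test_that("quality filter applies ambiguity, homopolymer and length rules", {
  p <- filterPolicy()
  shifted <- chartr("ACGT", "CGTA", repeatTemplate(148)) # starts with C
  run5 <- paste0(repeatTemplate(150), "AAAAA", shifted)
  short <- repeatTemplate(249)
  clean <- paste0(repeatTemplate(148), "AAAA", shifted)
  withN <- paste0(repeatTemplate(150), "N", repeatTemplate(149))
  qf <- qualityFilter(c(a = run5, b = short, c = clean, d = withN), p)
  expect_identical(names(qf$kept), "c")
  expect_identical(qf$reasons,
                   c(a = "homopolymer", b = "length", d = "ambiguity"))
  # idempotence
  again <- qualityFilter(qf$kept, p)
  expect_identical(again$kept, qf$kept)
  expect_length(again$reasons, 0)
})

test_that("dereplication tallies counts per sample and ignores read order", {
  s <- list(s1 = c("ACGT", "ACGT", "AAAA"), s2 = c("ACGT"))
  vc <- dereplicate(s)
  expect_equal(nVariants(vc), 2)
  expect_equal(variantTotals(vc)[["v00001"]], 3)
  expect_equal(countMatrix(vc)["v00001", ], c(s1 = 2L, s2 = 1L))

  shuffled <- list(s1 = rev(s$s1), s2 = s$s2)
  expect_identical(dereplicate(shuffled), vc)
  expect_equal(nVariants(dereplicate(list(s1 = character(0)))), 0)
})

test_that("zero-error simulated reads dereplicate to the simulator tally", {
  tmpl <- simulateCladeTemplates(1, length = 300, seed = 9)
  g <- genomeModel("A1", "A", tmpl[[1]], n_rare_variants = 9)
  rm0 <- readModel(barcode = "ACACACAC", substitution_rate = 0,
                   homopolymer_indel_rate = 0, chimera_rate = 0)
  sim <- simulateSample("s1", list(g), 1, 1000, rm0, seed = 13)
  ins <- substring(sim$reads,
                   nchar(rm0$barcode) + nchar(rm0$fwd_primer) + 1)
  ins <- substr(ins, 1, nchar(ins) - nchar(rm0$rev_primer))
  vc <- dereplicate(list(s1 = unname(ins)))
  truth_tally <- table(sim$truth$template_id)
  tmpl_seq <- sim$templates$sequence[match(names(truth_tally),
                                           sim$templates$template_id)]
  expect_equal(nVariants(vc), length(truth_tally))
  expect_equal(unname(variantTotals(vc)[match(tmpl_seq, variantSequences(vc))]),
               unname(as.integer(truth_tally)))
})

test_that("singleton removal drops dataset-wide singletons only", {
  vc <- variantCounts(c("AAAA", "CCCC", "GGGG"),
                      matrix(c(1L, 2L, 1L, 0L, 0L, 1L), ncol = 2,
                             dimnames = list(NULL, c("s1", "s2"))))
  out <- removeSingletons(vc)
  # total-1 variant removed; count 2 in one sample kept; 1+1 across samples kept
  expect_equal(nVariants(out), 2)
  expect_setequal(variantSequences(out), c("CCCC", "GGGG"))
  expect_identical(removeSingletons(out)@sequences, out@sequences)
})

test_that("constructed two-parent chimeras are flagged, parents are not", {
  p1 <- repeatTemplate(300)
  p2 <- substituteAt(p1, seq(5, 295, by = 15)) # ~20 subs spread along p1
  chim <- paste0(substr(p1, 1, 150), substr(p2, 151, 300))
  vc <- variantCounts(c(p1, p2, chim), c(100L, 90L, 9L))
  ch <- flagChimeras(vc)
  expect_length(ch$flagged, 1)
  expect_identical(setdiff(c(p1, p2, chim), variantSequences(ch$table)), chim)

  # single variant: nothing to flag; exact parent copy: not flagged
  expect_length(flagChimeras(variantCounts(p1, 10L))$flagged, 0)
  vc2 <- variantCounts(c(p1, p2), c(100L, 10L))
  expect_length(flagChimeras(vc2)$flagged, 0)
})

test_that("read conservation holds through demux and filtering", {
  m <- mk_mapping()
  tmpl <- simulateCladeTemplates(1, length = 300, seed = 31)
  g <- genomeModel("A1", "A", tmpl[[1]])
  rm1 <- readModel(barcode = m$barcode[1], substitution_rate = 0.002,
                   homopolymer_indel_rate = 0.001)
  sim <- simulateSample("s1", list(g), 1, 500, rm1, seed = 5)
  dx <- demultiplex(sim$reads, sim$mapping)
  rep <- dx$report
  expect_equal(sum(rep$input), length(sim$reads))
  expect_equal(sum(rep$kept) + sum(rep[, c("barcode", "fwd_primer")]),
               length(sim$reads))
  qf <- qualityFilter(dx$samples$s1)
  expect_equal(length(qf$kept) + length(qf$reasons), length(dx$samples$s1))
})
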