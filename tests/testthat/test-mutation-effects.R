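test_that("mutation tokens parse and malformed tokens error", {
  m <- parseMutation(c("G1734A", "C999T"), c("f645", "f814"), "CAD")
  expect_equal(m$pos, c(1734L, 999L))
  expect_equal(m$ref, c("G", "C"))
  expect_equal(m$alt, c("A", "T"))
  expect_error(parseMutation("G17G", "f", "g"), class = "tillingr_parse")
  expect_error(parseMutation("17GA", "f", "g"), class = "tillingr_parse")
})

test_that("classification matches the genetic code on forced examples", {
  calls <- classifyMutations(GeneModel("g", "ATGGGATAA"),
                             parseMutation("G4A", "f", "g"))
  expect_equal(calls$klass, "missense")
  expect_equal(paste0(calls$aa_ref, calls$aa_pos, calls$aa_alt), "G2R")

  calls <- classifyMutations(GeneModel("g", "ATGTGGTAA"),
                             parseMutation("G5A", "f", "g"))
  expect_equal(calls$klass, "truncation")
  expect_equal(calls$aa_alt, "*")

  calls <- classifyMutations(GeneModel("g", "ATGGGGTAA"),
                             parseMutation("G6A", "f", "g"))
  expect_equal(calls$klass, "silent")

  expect_error(
    classifyMutations(GeneModel("g", "ATGGGATAA"),
                      parseMutation("A4G", "f", "g")),
    class = "tillingr_ref_mismatch")
})

test_that("intronic calls, splice flags, N codons and stop-loss handling", {
  # exons 1-3 and 10-15 with a 6-bp intron at 4-9
  gm <- GeneModel("g", "ATGGTAAGTGGATAA", exons = rbind(c(1, 3), c(10, 15)))
  muts <- data.frame(family_id = "f", gene_id = "g",
                     pos = c(4L, 6L, 9L, 11L),
                     ref = c("G", "A", "T", "G"),
                     alt = c("A", "T", "C", "A"))
  calls <- classifyMutations(gm, muts)
  expect_equal(calls$klass, c("intronic", "intronic", "intronic", "missense"))
  expect_equal(calls$splice_adjacent, c(TRUE, FALSE, TRUE, FALSE))

  # N in the codon -> ambiguous
  gmN <- GeneModel("g", "ATGGNATAA")
  callsN <- classifyMutations(gmN, data.frame(family_id = "f", gene_id = "g",
                                              pos = 4L, ref = "G", alt = "A"))
  expect_equal(callsN$klass, "ambiguous")
  expect_equal(callsN$flag, "codon_contains_N")

  # stop-loss (TGA -> TGG, Trp) reported as missense with a flag
  gmS <- GeneModel("g", "ATGGGATGA")
  callsS <- classifyMutations(gmS, data.frame(family_id = "f", gene_id = "g",
                                              pos = 9L, ref = "A", alt = "G"))
  expect_equal(callsS$klass, "missense")
  expect_equal(callsS$flag, "stop_loss")
  expect_equal(callsS$aa_ref, "*")
})

test_that("classification equals the re-translation oracle on random genes", {
  set.seed(42)
  for (rep_i in 1:10) {
    gm <- randomGene(sprintf("g%02d", rep_i))
    muts <- allSnps(gm)
    got <- classifyMutations(gm, muts)$klass
    want <- vapply(seq_len(nrow(muts)), function(i)
      oracleClassify(gm, muts$pos[i], muts$alt[i]), character(1))
    expect_identical(got, want,
                     label = sprintf("all SNPs of %s", geneId(gm)))
  }
})

test_that("effect summaries compute half-up percentages and the spectrum", {
  expect_equal(unname(effectSummaryFromCounts(15, 51, 1)$percent),
               c(22.4, 76.1, 1.5))
  expect_equal(unname(effectSummaryFromCounts(24, 43, 7)$percent),
               c(32.4, 58.1, 9.5))
  pooled <- effectSummaryFromCounts(39, 94, 8, printed = c(silent = 27.6))
  expect_equal(unname(pooled$percent), c(27.7, 66.7, 5.7))
  # recomputed pooled silent % differs from the printed 27.6 and is flagged
  expect_equal(pooled$discrepancy$class, "silent")
  expect_equal(unname(effectSummaryFromCounts(1, 0, 0)$percent[1]), 100.0)

  gm <- GeneModel("g", "ATGTGGGGGTAA")
  muts <- parseMutation(c("G5A", "G8A"), "f", "g")
  calls <- classifyMutations(gm, muts)
  summ <- summarizeEffects(calls)
  expect_equal(summ$n_total, 2L)
  expect_equal(sum(summ$counts), summ$n_exonic)
  expect_equal(summ$n_canonical, 2L)
  expect_equal(summ$n_exonic + summ$n_intronic + summ$n_ambiguous,
               summ$n_total)

  # order invariance
  summRev <- summarizeEffects(calls[rev(seq_len(nrow(calls))), ])
  expect_equal(summRev$percent, summ$percent)

  # all-exon gene -> no intronic calls
  expect_equal(summ$n_intronic, 0L)
})

test_that("windowed GC/mutation table has the right geometry", {
  gm <- GeneModel("g", paste0(strrep("G", 100), strrep("A", 100)),
                  exons = cbind(1L, 198L))
  tab <- windowGCMutations(gm, window = 100)
  expect_equal(tab$gc_count, c(100L, 0L))

  gm250 <- GeneModel("g", strrep("ACGTA", 50), exons = cbind(1L, 249L))
  tab250 <- windowGCMutations(gm250, window = 100)
  expect_equal(nrow(tab250), 3L)
  expect_equal(tab250$partial, c(FALSE, FALSE, TRUE))
  expect_equal(tab250$end[3] - tab250$start[3] + 1L, 50L)

  # mutations land in the right windows
  muts <- data.frame(pos = c(1L, 150L, 250L))
  tabM <- windowGCMutations(gm250, muts, window = 100)
  expect_equal(tabM$mutation_count, c(1L, 1L, 1L))
})

test_that("mutations confined to G/C sites track window GC content", {
  set.seed(7)
  cfg <- simulationConfig(seed = 7, nFamilies = 2000,
                          doses = data.frame(label = "d",
                                             bp_per_mutation = 2000,
                                             fraction = 1),
                          geneSpecs = list(list(gene_id = "g",
                                                length = 600L,
                                                exons = cbind(1L, 600L),
                                                gc = 0.5)),
                          canonicalFraction = 1)
  models <- simulateGenes(cfg)
  sim <- simulateMutations(models, cfg)
  tab <- windowGCMutations(models[[1]], sim$truth, window = 50)
  ct <- suppressWarnings(
    cor.test(tab$gc_count, tab$mutation_count, method = "spearman"))
  expect_gt(ct$estimate, 0)
})

test_that("effect calls export to TSV and minimal VCF", {
  gm <- GeneModel("g", "ATGGGATAA")
  calls <- classifyMutations(gm, parseMutation("G4A", "f1", "g"))
  tsv <- tempfile(fileext = ".tsv")
  writeEffectCalls(calls, tsv)
  back <- read.delim(tsv)
  expect_equal(back$klass, "missense")

  vcf <- tempfile(fileext = ".vcf")
  writeEffectCalls(calls, vcf, format = "vcf")
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  expect_true(any(grepl("^g\t4\tf1\tG\tA\t.\t.\tEFFECT=missense", lines)))
})
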