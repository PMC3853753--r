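test_that("configuration is validated and the seed is mandatory", {
  expect_error(simulationConfig(), class = "tillingr_validation")
  expect_error(simulationConfig(seed = 1, canonicalFraction = 1.2),
               class = "tillingr_validation")
  expect_error(simulationConfig(seed = 1,
                                contextWeights = c(GGG = -1)),
               class = "tillingr_validation")
  cfg <- simulationConfig(seed = 1)
  expect_equal(cfg$canonicalFraction, 154 / 155)
  expect_equal(sort(names(cfg$contextWeights)),
               sort(emsTripletBias()$triplet))
})

test_that("simulated genes hit the GC target, carry an ORF and are seeded", {
  spec1k <- list(list(gene_id = "g", length = 1002L,
                      exons = cbind(1L, 1002L), gc = 0.5))
  cfg <- simulationConfig(seed = 5, geneSpecs = spec1k)
  gm <- simulateGenes(cfg)[[1]]
  seq <- geneSequence(gm)
  gc <- mean(strsplit(seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.05)
  expect_equal(substr(seq, 1, 3), "ATG")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))  # stop-free body

  gm2 <- simulateGenes(simulationConfig(seed = 5, geneSpecs = spec1k))[[1]]
  expect_identical(geneSequence(gm2), seq)                  # determinism

  gcAll <- simulateGenes(simulationConfig(
    seed = 5, geneSpecs = list(list(gene_id = "g", length = 99L,
                                    exons = cbind(1L, 99L), gc = 1))))[[1]]
  expect_true(all(strsplit(geneSequence(gcAll), "")[[1]] %in% c("G", "C")))

  expect_error(simulateGenes(simulationConfig(
    seed = 5, geneSpecs = list(list(gene_id = "g", length = 100L,
                                    exons = cbind(1L, 100L))))),
               class = "tillingr_validation")
})

test_that("intron GC runs below exon GC in the default amplicons", {
  models <- simulateGenes(simulationConfig(seed = 9))
  for (m in models) {
    chars <- strsplit(geneSequence(m), "")[[1]]
    ex <- as.data.frame(geneExons(m))
    exPos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
    inPos <- setdiff(seq_along(chars), exPos)
    expect_gt(mean(chars[exPos] %in% c("G", "C")),
              mean(chars[inPos] %in% c("G", "C")))
  }
})

test_that("simulated lesions follow the configured spectrum and detection", {
  cfg <- simulationConfig(seed = 6, nFamilies = 2000,
                          doses = data.frame(label = "d",
                                             bp_per_mutation = 500,
                                             fraction = 1),
                          geneSpecs = list(list(gene_id = "g",
                                                length = 900L,
                                                exons = cbind(1L, 900L),
                                                gc = 0.5)))
  models <- simulateGenes(cfg)
  sim <- simulateMutations(models, cfg)
  expect_identical(sim$detected, sim$truth)   # sensitivity 1.0

  # realized canonical fraction within 3 s.e. of 154/155
  canon <- with(sim$truth, (ref == "G" & alt == "A") |
                  (ref == "C" & alt == "T"))
  p <- 154 / 155
  se <- sqrt(p * (1 - p) / length(canon))
  expect_lt(abs(mean(canon) - p), 3 * se + 1e-12)

  # every lesion's ref matches the gene sequence
  seq <- geneSequence(models[[1]])
  expect_true(all(substring(seq, sim$truth$pos, sim$truth$pos) ==
                    sim$truth$ref))

  # Poisson mean: total count within 4 sd of expectation
  expected <- 2000 * 900 / 500
  expect_lt(abs(nrow(sim$truth) - expected), 4 * sqrt(expected))

  # thinned detection
  cfgT <- simulationConfig(seed = 6, nFamilies = 2000,
                           doses = cfg$doses, geneSpecs = cfg$geneSpecs,
                           detectionSensitivity = 0.5)
  simT <- simulateMutations(models, cfgT)
  expect_lt(nrow(simT$detected), nrow(simT$truth))

  # same seed -> identical output
  sim2 <- simulateMutations(models, cfg)
  expect_identical(sim2$truth, sim$truth)
})

test_that("uniform context weights yield null triplet ratios near 1", {
  # ~40,000 lesions: per-triplet sampling s.d. well below the 0.1 band
  cfg <- simulationConfig(
    seed = 8, nFamilies = 4000,
    doses = data.frame(label = "d", bp_per_mutation = 200, fraction = 1),
    geneSpecs = list(list(gene_id = "g", length = 2001L,
                          exons = cbind(1L, 2001L), gc = 0.5)),
    canonicalFraction = 1,
    contextWeights = c(GGG = 1))   # all triplets weight 1
  models <- simulateGenes(cfg)
  sim <- simulateMutations(models, cfg)
  expect_gt(nrow(sim$truth), 36000)
  spec <- contextSpectrum(models, sim$truth)
  tt <- spec@tripletTable
  expect_true(all(abs(tt$ratio[tt$expected_count > 0] - 1) < 0.1))
})

test_that("injected context bias is recovered as the top-ranked triplet", {
  bias <- emsTripletBias()
  cfg <- simulationConfig(
    seed = 10, nFamilies = 1500,
    doses = data.frame(label = "d", bp_per_mutation = 300, fraction = 1),
    geneSpecs = list(list(gene_id = "g", length = 3000L,
                          exons = cbind(1L, 3000L), gc = 0.5)),
    canonicalFraction = 1,
    contextWeights = setNames(bias$ratio, bias$triplet))
  models <- simulateGenes(cfg)
  sim <- simulateMutations(models, cfg)
  ranked <- rankTriplets(contextSpectrum(models, sim$truth))
  expect_equal(ranked$triplet[1], "GGG")
})

test_that("population tables honour rates and the seed", {
  cfg0 <- simulationConfig(seed = 12, nFamilies = 200,
                           sterilityRates = 0, phenotypeRates = 0.2,
                           plantsPerFamily = 3L)
  tab0 <- simulatePopulationTable(cfg0)
  expect_equal(sum(tab0$plants_sterile), 0L)

  cfg <- simulationConfig(seed = 13, nFamilies = 924,
                          sterilityRates = 0.184, phenotypeRates = 0.3,
                          plantsPerFamily = 3L)
  tab <- simulatePopulationTable(cfg)
  p <- 0.184
  n <- sum(tab$plants_germinated)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(sum(tab$plants_sterile) / n - p), 3 * se)

  expect_identical(simulatePopulationTable(cfg), tab)
  expect_silent(validateFamilyRecords(tab))
})

test_that("simulated class fractions match exhaustive enumeration", {
  # expected class probabilities under uniform-weight canonical placement
  # come from enumerating every exonic G>A / C>T on the simulated gene
  cfg <- simulationConfig(
    seed = 14, nFamilies = 1200,
    doses = data.frame(label = "d", bp_per_mutation = 400, fraction = 1),
    geneSpecs = list(list(gene_id = "g", length = 1200L,
                          exons = cbind(1L, 1200L), gc = 0.5)),
    canonicalFraction = 1, contextWeights = c(GGG = 1))
  models <- simulateGenes(cfg)
  m <- models[[1]]
  seq <- geneSequence(m)
  gcPos <- which(strsplit(seq, "")[[1]] %in% c("G", "C"))
  enum <- classifyMutations(m, data.frame(
    family_id = "e", gene_id = "g", pos = gcPos,
    ref = substring(seq, gcPos, gcPos),
    alt = ifelse(substring(seq, gcPos, gcPos) == "G", "A", "T")))
  expProp <- prop.table(table(factor(enum$klass,
                                     c("silent", "missense", "truncation"))))

  sim <- simulateMutations(models, cfg)
  calls <- classifyMutations(m, sim$truth)
  obs <- table(factor(calls$klass, c("silent", "missense", "truncation")))
  gof <- suppressWarnings(chisq.test(obs, p = as.numeric(expProp)))
  expect_gt(gof$p.value, 0.01)
})
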