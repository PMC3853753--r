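test_that("lesions are oriented so the mutated base is G", {
  expect_equal(normalizeToG("AAGTA", 3, "G", "A"), "AGT")
  expect_equal(normalizeToG("AACTA", 3, "C", "T"), "AGT")  # revcomp of ACT
  nc <- normalizeToG("AAATA", 3, "A", "G")
  expect_true(is.na(nc))
  expect_equal(attr(nc, "reason"), "non_canonical")
  edge <- normalizeToG("GAAAA", 1, "G", "A")
  expect_true(is.na(edge))
  expect_equal(attr(edge, "reason"), "no_context")
})

test_that("context tallies match hand counts on a toy sequence", {
  # sequence AGTCGA: interior positions 2..5 are G(2), C(4), G(5)
  #   G at 2 -> AGT; C at 4 -> revcomp(TCG) = CGA; G at 5 -> CGA
  gm <- GeneModel("t", "AGTCGA")
  muts <- data.frame(family_id = "f", gene_id = "t",
                     pos = c(2L, 4L), ref = c("G", "C"), alt = c("A", "T"))
  spec <- contextSpectrum(gm, muts)
  tt <- spec@tripletTable
  expect_equal(tt$expected_count[tt$triplet == "AGT"], 1L)
  expect_equal(tt$expected_count[tt$triplet == "CGA"], 2L)
  expect_equal(sum(tt$expected_count), 3L)
  expect_equal(tt$observed_count[tt$triplet == "AGT"], 1L)
  expect_equal(tt$observed_count[tt$triplet == "CGA"], 1L)
  # AGT: expected 1/3, observed 1/2 -> ratio 1.5
  expect_equal(tt$ratio[tt$triplet == "AGT"], (50) / (100 / 3))
  # frequency normalization invariants
  expect_equal(sum(tt$expected_freq), 100, tolerance = 1e-9)
  expect_equal(sum(tt$observed_freq), 100, tolerance = 1e-9)
  for (off in c(-1L, 1L)) {
    bt <- spec@baseTable[spec@baseTable$offset == off, ]
    expect_equal(sum(bt$expected_freq), 100, tolerance = 1e-9)
    expect_equal(sum(bt$observed_freq), 100, tolerance = 1e-9)
  }
  # NA ratio where expected count is zero
  expect_true(all(is.na(tt$ratio[tt$expected_count == 0])))
})

test_that("expected pool depends only on sequences, observed only on lesions", {
  set.seed(11)
  gm <- randomGene("g1", len = 400, twoExon = FALSE)
  seq <- geneSequence(gm)
  gpos <- which(strsplit(seq, "")[[1]] == "G")
  gpos <- gpos[gpos > 1 & gpos < nchar(seq)]
  mk <- function(p) data.frame(family_id = "f", gene_id = "g1", pos = p,
                               ref = "G", alt = "A")
  s1 <- contextSpectrum(gm, mk(gpos[1:3]))
  s2 <- contextSpectrum(gm, mk(gpos[4:6]))
  expect_equal(s1@tripletTable$expected_count, s2@tripletTable$expected_count)
  expect_false(identical(s1@tripletTable$observed_count,
                         s2@tripletTable$observed_count))
})

test_that("spectrum is invariant under scale and global reverse complement", {
  set.seed(12)
  gm <- randomGene("g1", len = 300, twoExon = FALSE)
  seq <- geneSequence(gm)
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars %in% c("G", "C"))
  pos <- pos[pos > 1 & pos < nchar(seq)][1:8]
  muts <- data.frame(family_id = "f", gene_id = "g1", pos = pos,
                     ref = chars[pos],
                     alt = ifelse(chars[pos] == "G", "A", "T"))
  spec <- contextSpectrum(gm, muts)

  # doubling sequences and lesions changes no frequency or ratio
  gm2 <- GeneModel("g2", seq)
  muts2 <- rbind(muts,
                 transform(muts, gene_id = "g2"))
  specD <- contextSpectrum(list(gm, gm2), muts2)
  expect_equal(specD@tripletTable$expected_freq,
               spec@tripletTable$expected_freq, tolerance = 1e-12)
  expect_equal(specD@tripletTable$observed_freq,
               spec@tripletTable$observed_freq, tolerance = 1e-12)
  expect_equal(specD@tripletTable$ratio, spec@tripletTable$ratio,
               tolerance = 1e-12)

  # global reverse complement with mirrored mutations: identical spectrum
  n <- nchar(seq)
  gmRC <- GeneModel("g1", revComp(seq))
  mutsRC <- data.frame(
    family_id = "f", gene_id = "g1", pos = n - muts$pos + 1L,
    ref = chartr("ACGT", "TGCA", muts$ref),
    alt = chartr("ACGT", "TGCA", muts$alt))
  specRC <- contextSpectrum(gmRC, mutsRC)
  expect_equal(specRC@tripletTable, spec@tripletTable, tolerance = 1e-12)
  expect_equal(specRC@baseTable, spec@baseTable, tolerance = 1e-12)
})

test_that("triplet ranking sorts by ratio with alphabetical tie-break", {
  ranked <- rankTriplets(emsTripletBias())
  expect_equal(head(ranked$triplet, 4), c("GGG", "CGT", "AGA", "GGA"))
  expect_equal(tail(ranked$triplet, 4), c("CGG", "TGT", "CGC", "AGT"))
  expect_equal(ranked$ratio_2dp[ranked$triplet == "GGG"], 1.86)

  ties <- data.frame(triplet = c("TGA", "AGA", "CGA"), ratio = 1)
  expect_equal(rankTriplets(ties)$triplet, c("AGA", "CGA", "TGA"))

  withNA <- data.frame(triplet = c("AGA", "CGA"), ratio = c(NA, 0.5))
  expect_equal(rankTriplets(withNA)$triplet, c("CGA", "AGA"))
})

test_that("divergence flags use relative divergence at the threshold", {
  gm <- GeneModel("t", "AGTCGA")
  muts <- data.frame(family_id = "f", gene_id = "t",
                     pos = 2L, ref = "G", alt = "A")
  spec <- contextSpectrum(gm, muts, threshold = 0.15)
  tt <- spec@tripletTable
  # AGT: expected 33.3, observed 100 -> divergence 2.0 >= 0.15
  expect_true(tt$flag[tt$triplet == "AGT"])
  # CGA: expected 66.7, observed 0 -> divergence 1.0 >= 0.15
  expect_true(tt$flag[tt$triplet == "CGA"])
  spec2 <- contextSpectrum(gm, muts, threshold = 2.5)
  expect_false(any(spec2@tripletTable$flag, na.rm = TRUE))
})

test_that("empty or non-canonical-only input raises an explicit error", {
  gm <- GeneModel("t", "AAATTT")
  expect_error(contextSpectrum(gm, data.frame(family_id = "f",
                                              gene_id = "t", pos = 2L,
                                              ref = "A", alt = "G")),
               class = "tillingr_empty_spectrum")
})
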