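#' Published EMS G-context triplet bias
#'
#' Observed frequency table of the 16 NGN triplets centered on all Gs
#' (expected) versus mutated Gs (observed), pooled over two lignin-gene
#' amplicons in an EMS flax TILLinG screen. The derived observed/expected
#' ratios are the default context weights of the simulator, so simulated
#' lesion placement reproduces a realistic EMS local-sequence bias
#' (purine-flanked Gs overrepresented, pyrimidine-flanked underrepresented).
#'
#' @return data.frame: \code{triplet}, \code{expected_freq},
#'   \code{observed_freq}, \code{ratio}.
#' @export
emsTripletBias <- function() {
  tab <- data.frame(
    triplet = c("GGG", "CGT", "AGA", "GGA", "TGA", "CGA", "GGT", "TGC",
                "GGC", "AGC", "AGG", "TGG", "CGG", "TGT", "CGC", "AGT"),
    expected_freq = c(7.69, 2.83, 6.68, 10.32, 8.50, 5.26, 6.68, 5.47,
                      6.07, 4.86, 8.30, 10.53, 4.45, 5.87, 2.63, 3.85),
    observed_freq = c(14.29, 5.19, 10.39, 14.94, 8.44, 5.19, 6.49, 5.19,
                      5.19, 3.90, 6.49, 7.14, 2.60, 3.25, 0.65, 0.65)
  )
  tab$ratio <- tab$observed_freq / tab$expected_freq
  tab
}

#' Simulation configuration for a synthetic EMS population
#'
#' Defaults reproduce the statistical structure of a real EMS TILLinG
#' screen: Poisson lesion counts per family at ~1 lesion / 41 kb screened,
#' 154/155 of lesions canonical G/C to A/T transitions, context-weighted
#' placement using the published triplet bias, and perfect detection.
#'
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param nFamilies number of M2 families.
#' @param doses data.frame with columns \code{label},
#'   \code{bp_per_mutation} and \code{fraction} (of families); default a
#'   single dose at 41,000 bp/mutation.
#' @param geneSpecs list of gene specs, each a list with \code{gene_id},
#'   \code{length}, \code{exons} (2-column matrix, or NULL for
#'   single-exon), \code{gc} (exonic GC target, default 0.5),
#'   \code{gc_intron} (default gc - 0.1).
#' @param canonicalFraction probability a lesion is G/C to A/T.
#' @param contextWeights named numeric of NGN triplet weights (> 0);
#'   unlisted triplets get weight 1. Default: ratios from
#'   \code{\link{emsTripletBias}}.
#' @param detectionSensitivity probability a real lesion is detected.
#' @param sterilityRates,phenotypeRates,germinationFailureRates named by
#'   dose label; per-plant sterility, per-family phenotype-category rates
#'   (a list of named vectors or single rate), per-family germination
#'   failure.
#' @param plantsPerFamily named by dose label; seeds sown per family.
#' @return validated config list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(
    seed,
    nFamilies = 3515L,
    doses = data.frame(label = "0.6", bp_per_mutation = 41000,
                       fraction = 1),
    geneSpecs = list(
      list(gene_id = "ampA", length = 869L,
           exons = rbind(c(1L, 309L), c(450L, 761L)), gc = 0.50),
      list(gene_id = "ampB", length = 981L,
           exons = rbind(c(1L, 435L), c(547L, 981L)), gc = 0.525)
    ),
    canonicalFraction = 154 / 155,
    contextWeights = NULL,
    detectionSensitivity = 1.0,
    sterilityRates = NULL,
    phenotypeRates = NULL,
    germinationFailureRates = NULL,
    plantsPerFamily = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stopClassed("tillingr_validation", "seed is mandatory")
  if (is.null(contextWeights)) {
    bias <- emsTripletBias()
    contextWeights <- stats::setNames(bias$ratio, bias$triplet)
  }
  if (any(contextWeights <= 0))
    stopClassed("tillingr_validation", "context weights must be > 0")
  probs <- c(canonicalFraction, detectionSensitivity)
  if (any(probs < 0 | probs > 1))
    stopClassed("tillingr_validation", "probabilities must be in [0,1]")
  if (abs(sum(doses$fraction) - 1) > 1e-8)
    stopClassed("tillingr_validation", "dose fractions must sum to 1")
  structure(list(
    seed = as.integer(seed), nFamilies = as.integer(nFamilies),
    doses = doses, geneSpecs = geneSpecs,
    canonicalFraction = canonicalFraction,
    contextWeights = contextWeights,
    detectionSensitivity = detectionSensitivity,
    sterilityRates = sterilityRates, phenotypeRates = phenotypeRates,
    germinationFailureRates = germinationFailureRates,
    plantsPerFamily = plantsPerFamily
  ), class = "SimulationConfig")
}

# sample m codons (no stops) whose base composition targets a GC fraction:
# codon weight = product of per-base probabilities with P(G) = P(C) = gc/2
sampleCodons <- function(m, gc) {
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[Biostrings::GENETIC_CODE != "*"]
  pBase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(codons, ""), function(b) prod(pBase[b]), numeric(1))
  if (all(w == 0))
    stopClassed("tillingr_validation",
                "no stop-free codon has positive weight at GC = %g", gc)
  sample(codons, m, replace = TRUE, prob = w)
}

#' Simulate gene models with a valid ORF
#'
#' Exonic sequence is an open reading frame (ATG, stop-free internal codons,
#' terminal stop) whose internal codons are drawn to match the target GC
#' fraction; introns are i.i.d. bases at a (typically lower) intron GC.
#' Exonic length must be a multiple of 3 and at least 9 bp.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return named list of \code{GeneModel}s, one per gene spec.
#' @export
simulateGenes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  models <- lapply(config$geneSpecs, function(sp) {
    len <- as.integer(sp$length)
    ex <- if (is.null(sp$exons)) cbind(1L, len) else sp$exons
    gc <- sp$gc %||% 0.5
    gcIntron <- sp$gc_intron %||% max(gc - 0.1, 0)
    exLen <- sum(ex[, 2] - ex[, 1] + 1L)
    if (exLen %% 3L != 0L || exLen < 9L)
      stopClassed("tillingr_validation",
                  "exon layout of '%s' incompatible with an ORF: exonic length %d",
                  sp$gene_id, exLen)
    nCodons <- exLen %/% 3L
    stopCodon <- if (gc >= 1) NULL else
      sample(c("TAA", "TAG", "TGA"), 1,
             prob = c((1 - gc)^2, (1 - gc) * gc, gc * (1 - gc)))
    cds <- if (gc >= 1) {
      # fully G/C exons cannot carry a real ATG/stop; degenerate case kept
      # for composition tests only
      paste(sampleCodons(nCodons, gc), collapse = "")
    } else {
      paste(c("ATG", sampleCodons(nCodons - 2L, gc), stopCodon),
            collapse = "")
    }
    seqChars <- rep("N", len)
    exPos <- unlist(mapply(seq.int, ex[, 1], ex[, 2], SIMPLIFY = FALSE))
    seqChars[exPos] <- strsplit(cds, "")[[1]]
    inPos <- setdiff(seq_len(len), exPos)
    if (length(inPos))
      seqChars[inPos] <- sample(c("A", "C", "G", "T"), length(inPos),
                                replace = TRUE,
                                prob = c((1 - gcIntron) / 2, gcIntron / 2,
                                         gcIntron / 2, (1 - gcIntron) / 2))
    GeneModel(sp$gene_id, paste(seqChars, collapse = ""), exons = ex)
  })
  stats::setNames(models, vapply(models, geneId, character(1)))
}

# per-site placement weights for canonical lesions on one gene; sites
# lacking a flank (or with N in it) or with an unlisted triplet get weight 1
canonicalSiteWeights <- function(model, contextWeights) {
  chars <- strsplit(geneSequence(model), "")[[1]]
  n <- length(chars)
  pos <- which(chars %in% c("G", "C"))
  if (!length(pos)) return(NULL)
  w <- rep(1, length(pos))
  inner <- pos > 1L & pos < n
  p <- pos[inner]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  tri <- ifelse(chars[p] == "G",
                paste0(chars[p - 1L], "G", chars[p + 1L]),
                paste0(comp[chars[p + 1L]], "G", comp[chars[p - 1L]]))
  cw <- unname(contextWeights[tri])
  cw[is.na(cw) | grepl("N", tri)] <- 1
  w[inner] <- cw
  list(pos = pos, ref = chars[pos], weight = w)
}

#' Simulate an EMS mutation screen
#'
#' Per family and gene, the lesion count is Poisson with mean
#' gene_length / bp_per_mutation for the family's dose. Canonical lesions
#' (probability \code{canonicalFraction}) are G>A or C>T placed on G/C
#' sites with probability proportional to the context weight of the
#' G-oriented triplet (sites lacking a flank get weight 1); the rest are
#' A>G / T>C placed uniformly on A/T sites. Context weighting redistributes
#' lesions among sites without changing the configured total density. The
#' detected subset thins truth by \code{detectionSensitivity}.
#'
#' @param models named list of \code{GeneModel}s (e.g. from
#'   \code{\link{simulateGenes}}).
#' @param config a \code{\link{simulationConfig}}.
#' @return list with mutation data.frames \code{truth} and \code{detected}
#'   (columns family_id, gene_id, pos, ref, alt, dose) and
#'   \code{family_dose}, the dose assignment.
#' @export
simulateMutations <- function(models, config) {
  stopifnot(inherits(config, "SimulationConfig"), length(models) > 0)
  set.seed(config$seed + 1L)
  siteW <- lapply(models, canonicalSiteWeights, config$contextWeights)
  atSites <- lapply(models, function(m) {
    chars <- strsplit(geneSequence(m), "")[[1]]
    list(pos = which(chars %in% c("A", "T")),
         ref = chars[chars %in% c("A", "T")])
  })
  doses <- config$doses
  nPerDose <- round(config$nFamilies * doses$fraction)
  nPerDose[1] <- config$nFamilies - sum(nPerDose[-1])
  famDose <- rep(doses$label, nPerDose)
  famIds <- sprintf("F%05d", seq_len(config$nFamilies))
  bpm <- rep(doses$bp_per_mutation, nPerDose)

  rows <- list()
  for (g in seq_along(models)) {
    model <- models[[g]]
    gLen <- nchar(geneSequence(model))
    counts <- stats::rpois(config$nFamilies, gLen / bpm)
    tot <- sum(counts)
    if (tot == 0) next
    famIdx <- rep(seq_len(config$nFamilies), counts)
    isCanon <- stats::runif(tot) < config$canonicalFraction
    pos <- integer(tot); ref <- character(tot); alt <- character(tot)
    sw <- siteW[[g]]; at <- atSites[[g]]
    nc <- sum(isCanon)
    if (nc > 0) {
      if (is.null(sw))
        stopClassed("tillingr_validation",
                    "no G/C site available in gene '%s'", geneId(model))
      pick <- sample.int(length(sw$pos), nc, replace = TRUE,
                         prob = sw$weight)
      pos[isCanon] <- sw$pos[pick]
      ref[isCanon] <- sw$ref[pick]
      alt[isCanon] <- ifelse(sw$ref[pick] == "G", "A", "T")
    }
    if (tot - nc > 0) {
      if (!length(at$pos))
        stopClassed("tillingr_validation",
                    "no A/T site available in gene '%s'", geneId(model))
      pick <- sample.int(length(at$pos), tot - nc, replace = TRUE)
      pos[!isCanon] <- at$pos[pick]
      ref[!isCanon] <- at$ref[pick]
      alt[!isCanon] <- ifelse(at$ref[pick] == "A", "G", "C")
    }
    rows[[g]] <- data.frame(
      family_id = famIds[famIdx], gene_id = geneId(model),
      pos = pos, ref = ref, alt = alt, dose = famDose[famIdx],
      stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), gene_id = character(),
               pos = integer(), ref = character(), alt = character(),
               dose = character())
  detected <- if (config$detectionSensitivity >= 1) truth else
    truth[stats::runif(nrow(truth)) < config$detectionSensitivity, ,
          drop = FALSE]
  rownames(truth) <- rownames(detected) <- NULL
  list(truth = truth, detected = detected,
       family_dose = data.frame(family_id = famIds, dose = famDose,
                                stringsAsFactors = FALSE))
}

#' Simulate a population phenotype table
#'
#' Per family: seeds sown per its dose, Bernoulli germination failure
#' (whole family), per-plant Bernoulli sterility, per-family Bernoulli
#' phenotype category flags, and per-plant intensity grades for flagged
#' families.
#'
#' @param config a \code{\link{simulationConfig}} with
#'   \code{sterilityRates}, \code{phenotypeRates},
#'   \code{germinationFailureRates} and \code{plantsPerFamily} set (named
#'   by dose label; scalars are recycled over doses).
#' @return family-record data.frame as accepted by
#'   \code{\link{summarizePopulation}}.
#' @export
simulatePopulationTable <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  doses <- config$doses
  getRate <- function(rates, label, default) {
    if (is.null(rates)) return(default)
    if (length(rates) == 1L && is.null(names(rates))) return(rates[[1]])
    rates[[label]] %||% default
  }
  nPerDose <- round(config$nFamilies * doses$fraction)
  nPerDose[1] <- config$nFamilies - sum(nPerDose[-1])
  famDose <- rep(doses$label, nPerDose)
  n <- config$nFamilies
  sown <- vapply(famDose, function(d)
    as.integer(getRate(config$plantsPerFamily, d, 5L)), integer(1))
  gfail <- vapply(famDose, function(d)
    getRate(config$germinationFailureRates, d, 0), numeric(1))
  ster <- vapply(famDose, function(d)
    getRate(config$sterilityRates, d, 0), numeric(1))
  pheno <- vapply(famDose, function(d)
    getRate(config$phenotypeRates, d, 0), numeric(1))

  failed <- stats::runif(n) < gfail
  germinated <- ifelse(failed, 0L, sown)
  sterile <- stats::rbinom(n, germinated, ster)
  flagged <- stats::runif(n) < pheno & germinated > 0
  grades <- vapply(seq_len(n), function(i) {
    if (germinated[i] == 0) return("")
    g <- if (flagged[i])
      sample(0:3, germinated[i], replace = TRUE,
             prob = c(0.25, 0.25, 0.25, 0.25))
    else rep(0L, germinated[i])
    paste(g, collapse = ";")
  }, character(1))
  data.frame(
    family_id = sprintf("F%05d", seq_len(n)),
    dose = famDose,
    seeds_sown = sown,
    plants_germinated = germinated,
    plants_sterile = sterile,
    flag_stem = flagged,
    grades = grades,
    stringsAsFactors = FALSE
  )
}
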