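# Shared fixtures and independent oracles.

# random gene with a multiple-of-3 exonic length; sequence fully random
# (classification treats internal stops per codon, so no ORF needed)
randomGene <- function(id, len = 300L, twoExon = TRUE) {
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  exons <- if (twoExon) {
    # two exons separated by an intron, exonic length a multiple of 3
    stopifnot(len >= 120L)
    e1 <- 3L * sample(10:20, 1)
    intron <- sample(10:30, 1)
    e2start <- e1 + intron + 1L
    e2len <- 3L * sample(5:floor((len - e2start + 1L) / 3), 1)
    rbind(c(1L, e1), c(e2start, e2start + e2len - 1L))
  } else {
    cbind(1L, len - (len %% 3L))
  }
  GeneModel(id, seq, exons = exons)
}

# every possible substitution at every position of a gene
allSnps <- function(model) {
  seq <- geneSequence(model)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  pos <- rep(seq_along(chars), each = 3L)
  ref <- chars[pos]
  alt <- unlist(lapply(chars, function(b) setdiff(bases, b)))
  data.frame(family_id = "f", gene_id = geneId(model),
             pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# Independent classification oracle: rebuild the full CDS with the
# substitution applied, translate both CDSs with Biostrings, and diff the
# two protein sequences. Never touches codonAt()/exonicPosition().
oracleClassify <- function(model, pos, alt) {
  seq <- geneSequence(model)
  ex <- as.data.frame(geneExons(model))
  exPos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
  if (!(pos %in% exPos)) return("intronic")
  mutSeq <- seq
  substr(mutSeq, pos, pos) <- alt
  cds <- function(s) paste(substring(s, ex$start, ex$end), collapse = "")
  # no.init.codon: a mutated first codon must translate by the plain code
  # (start-codon loss is a protein change, not an alternative initiator)
  aa <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cds(s)),
                          no.init.codon = TRUE)), "")[[1]]
  aaRef <- aa(seq); aaAlt <- aa(mutSeq)
  changed <- which(aaRef != aaAlt)
  if (!length(changed)) return("silent")
  if (aaAlt[changed[1]] == "*" && aaRef[changed[1]] != "*")
    return("truncation")
  "missense"
}

# deterministic population table hitting exact published-scale counts:
# nFamilies total, nFail non-germinating, nPlants plants spread over the
# germinated families, nSterile sterile plants, nPheno flagged families
fixedPopulationTable <- function(nFamilies, nFail, nPlants, nSterile,
                                 nPheno) {
  nGerm <- nFamilies - nFail
  plants <- rep(nPlants %/% nGerm, nGerm)
  extra <- nPlants - sum(plants)
  if (extra > 0) plants[seq_len(extra)] <- plants[seq_len(extra)] + 1L
  germinated <- c(plants, rep(0L, nFail))
  sterile <- integer(nFamilies)
  i <- 1L
  left <- nSterile
  while (left > 0L) {
    take <- min(germinated[i], left)
    sterile[i] <- take
    left <- left - take
    i <- i + 1L
  }
  data.frame(
    family_id = sprintf("F%05d", seq_len(nFamilies)),
    dose = "0.6",
    seeds_sown = pmax(germinated, 5L),
    plants_germinated = germinated,
    plants_sterile = sterile,
    flag_stem = c(rep(TRUE, nPheno), rep(FALSE, nFamilies - nPheno)),
    stringsAsFactors = FALSE
  )
}

# published two-amplicon screen geometry used across tests
screenTable <- function() {
  data.frame(amplicon = c("CAD", "C3H"),
             length_bp = c(869, 981),
             n_families = c(3515, 3515),
             n_mutations = c(76, 79))
}
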