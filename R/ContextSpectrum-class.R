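#' ContextSpectrum: expected vs observed sequence context around mutated Gs
#'
#' EMS alkylates G, so every canonical lesion (G>A on one strand, C>T on the
#' other) can be oriented so that the mutated base is a G. The spectrum
#' compares the flanking-base composition around all eligible Gs (the
#' expected pool: every G on the coding strand plus every C treated as a
#' reverse-strand G) with the composition around the mutated Gs, at offsets
#' -1 and +1, and tabulates the 16 NGN triplets with observed/expected
#' ratios.
#'
#' @slot offsets integer offsets analyzed (default -1, +1).
#' @slot baseTable data.frame of per-base expected/observed counts,
#'   frequencies (percent), fold change and divergence flag at each offset.
#' @slot tripletTable data.frame of the 16 NGN triplets with counts,
#'   frequencies (percent), ratio and divergence flag.
#' @slot threshold relative divergence threshold used for flags.
#' @slot nCanonical,nNonCanonical,nSkipped mutation bookkeeping: canonical
#'   lesions used, non-canonical lesions excluded, lesions skipped for
#'   lacking a flanking neighbour.
#'
#' @export
setClass("ContextSpectrum",
  representation(
    offsets = "integer",
    baseTable = "data.frame",
    tripletTable = "data.frame",
    threshold = "numeric",
    nCanonical = "integer",
    nNonCanonical = "integer",
    nSkipped = "integer"
  )
)

setMethod("show", "ContextSpectrum", function(object) {
  cat(sprintf(
    "ContextSpectrum: %d canonical lesions (%d non-canonical excluded, %d without context)\n",
    object@nCanonical, object@nNonCanonical, object@nSkipped))
  top <- rankTriplets(object)
  cat("  top triplets by observed/expected ratio:",
      paste(utils::head(top$triplet, 4), collapse = ", "), "\n")
  flagged <- object@baseTable[object@baseTable$flag, , drop = FALSE]
  if (nrow(flagged))
    cat("  flanking bases diverging >=", object@threshold * 100, "%:",
        paste(sprintf("%s at %+d (%.2fx)", flagged$base, flagged$offset,
                      flagged$fold), collapse = "; "), "\n")
})

#' Orient a lesion so the mutated base is G
#'
#' A G>A lesion keeps its coding-strand triplet; a C>T lesion is a G>A on
#' the opposite strand, so its context is the reverse complement of the
#' coding-strand triplet (the -1 and +1 neighbours swap and complement).
#' Anything that is not G>A or C>T is a non-canonical lesion and is excluded
#' from context analysis.
#'
#' @param sequence gene sequence (character).
#' @param pos 1-based position of the lesion.
#' @param ref,alt reference and alternate base.
#' @return 3-letter G-centered triplet, or \code{NA} with attribute
#'   \code{reason} = \code{"non_canonical"} / \code{"no_context"}.
#' @examples
#' normalizeToG("AAGTA", 3, "G", "A")  # "AGT"
#' normalizeToG("AACTA", 3, "C", "T")  # revcomp("ACT") = "AGT"
#' @export
normalizeToG <- function(sequence, pos, ref, alt) {
  if (!((ref == "G" && alt == "A") || (ref == "C" && alt == "T")))
    return(structure(NA_character_, reason = "non_canonical"))
  if (pos <= 1L || pos >= nchar(sequence))
    return(structure(NA_character_, reason = "no_context"))
  tri <- substr(sequence, pos - 1L, pos + 1L)
  if (ref == "C") tri <- revComp(tri)
  if (grepl("N", tri))
    return(structure(NA_character_, reason = "no_context"))
  tri
}

# all G-centered triplets over the eligible pool of one sequence:
# every G as-is, every C as reverse-strand G; interior positions only.
# optionally restricted to given positions (e.g. exonic only).
eligibleTriplets <- function(sequence, positions = NULL) {
  n <- nchar(sequence)
  if (n < 3L) return(character())
  chars <- strsplit(sequence, "")[[1]]
  idx <- 2:(n - 1L)
  if (!is.null(positions)) idx <- intersect(idx, positions)
  gIdx <- idx[chars[idx] == "G"]
  cIdx <- idx[chars[idx] == "C"]
  tri <- c(
    paste0(chars[gIdx - 1L], "G", chars[gIdx + 1L]),
    revComp(paste0(chars[cIdx - 1L], "C", chars[cIdx + 1L]))
  )
  tri[!grepl("N", tri)]
}

allTriplets <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, b, function(l, r) paste0(l, "G", r)))
}

#' Compute the context spectrum for a set of mutations
#'
#' The expected pool is the union of all supplied gene models (amplicons are
#' pooled); the observed pool is the set of G-oriented triplets of the
#' canonical (G/C to A/T) lesions. Positions lacking a -1 or +1 neighbour
#' are skipped from both tallies. Frequencies are percentages; the
#' divergence flag marks base/offset pairs and triplets where the relative
#' divergence |observed - expected| / expected meets \code{threshold}.
#'
#' @param models a \code{GeneModel} or list of them.
#' @param mutations mutation data.frame (\code{gene_id}, \code{pos},
#'   \code{ref}, \code{alt}).
#' @param threshold relative divergence threshold (default 0.15).
#' @param offsets flanking offsets (only -1/+1 supported; kept explicit for
#'   the report).
#' @param exonOnly restrict the expected pool to exonic positions.
#' @return a \code{\link{ContextSpectrum-class}} object.
#' @export
contextSpectrum <- function(models, mutations, threshold = 0.15,
                            offsets = c(-1L, 1L), exonOnly = FALSE) {
  if (methods::is(models, "GeneModel")) models <- list(models)
  names(models) <- vapply(models, geneId, character(1))

  expTri <- unlist(lapply(models, function(m) {
    posFilter <- if (exonOnly) {
      ex <- geneExons(m)
      unlist(mapply(seq.int, IRanges::start(ex), IRanges::end(ex),
                    SIMPLIFY = FALSE))
    } else NULL
    eligibleTriplets(geneSequence(m), posFilter)
  }), use.names = FALSE)
  if (!length(expTri))
    stopClassed("tillingr_empty_spectrum",
                "no eligible G contexts in the supplied sequences")

  unknown <- setdiff(unique(mutations$gene_id), names(models))
  if (length(unknown))
    stopClassed("tillingr_missing_record",
                "mutation references unknown gene '%s'", unknown[1])
  seqs <- vapply(models, geneSequence, character(1))
  mutSeq <- seqs[mutations$gene_id]
  canon <- (mutations$ref == "G" & mutations$alt == "A") |
    (mutations$ref == "C" & mutations$alt == "T")
  nNonCan <- sum(!canon)
  inner <- mutations$pos > 1L & mutations$pos < nchar(mutSeq)
  use <- canon & inner
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  left <- substring(mutSeq[use], mutations$pos[use] - 1L,
                    mutations$pos[use] - 1L)
  right <- substring(mutSeq[use], mutations$pos[use] + 1L,
                     mutations$pos[use] + 1L)
  obsTri <- ifelse(mutations$ref[use] == "G",
                   paste0(left, "G", right),
                   paste0(comp[right], "G", comp[left]))
  obsTri <- obsTri[!grepl("N", obsTri)]
  nSkip <- sum(canon) - length(obsTri)
  if (!length(obsTri))
    stopClassed("tillingr_empty_spectrum",
                "no canonical mutations with flanking context")

  tris <- allTriplets()
  expCnt <- table(factor(expTri, levels = tris))
  obsCnt <- table(factor(obsTri, levels = tris))
  expFreq <- 100 * as.numeric(expCnt) / sum(expCnt)
  obsFreq <- 100 * as.numeric(obsCnt) / sum(obsCnt)
  ratio <- ifelse(as.numeric(expCnt) > 0, obsFreq / expFreq, NA_real_)
  tripletTable <- data.frame(
    triplet = tris,
    expected_count = as.integer(expCnt), expected_freq = expFreq,
    observed_count = as.integer(obsCnt), observed_freq = obsFreq,
    ratio = ratio,
    flag = !is.na(ratio) & abs(obsFreq - expFreq) / ifelse(expFreq > 0, expFreq, NA) >= threshold
  )

  # per-offset base composition derived from the triplet tallies
  bases <- c("A", "C", "G", "T")
  baseTable <- do.call(rbind, lapply(offsets, function(off) {
    pick <- if (off == -1L) substr(tris, 1L, 1L) else substr(tris, 3L, 3L)
    eC <- vapply(bases, function(b) sum(expCnt[pick == b]), numeric(1))
    oC <- vapply(bases, function(b) sum(obsCnt[pick == b]), numeric(1))
    eF <- 100 * eC / sum(eC); oF <- 100 * oC / sum(oC)
    data.frame(offset = off, base = bases,
               expected_count = as.integer(eC), expected_freq = eF,
               observed_count = as.integer(oC), observed_freq = oF,
               fold = ifelse(eF > 0, oF / eF, NA_real_),
               flag = eF > 0 & abs(oF - eF) / eF >= threshold)
  }))
  rownames(baseTable) <- NULL

  methods::new("ContextSpectrum",
               offsets = as.integer(offsets), baseTable = baseTable,
               tripletTable = tripletTable, threshold = threshold,
               nCanonical = length(obsTri), nNonCanonical = nNonCan,
               nSkipped = nSkip)
}

#' @rdname rankTriplets
#' @export
setGeneric("rankTriplets", function(x, ...) standardGeneric("rankTriplets"))

#' Rank NGN triplets by observed/expected ratio
#'
#' Stable descending sort on the ratio; ties broken alphabetically by
#' triplet; undefined (NA) ratios last. The data.frame method accepts a
#' published frequency table with columns \code{triplet},
#' \code{expected_freq} and \code{observed_freq} (the ratio is recomputed
#' and also reported rounded to 2 decimals as conventionally printed), or a
#' precomputed \code{ratio} column.
#'
#' @param x a \code{ContextSpectrum} or data.frame.
#' @param ... unused.
#' @return data.frame sorted by ratio descending with a \code{ratio_2dp}
#'   column.
#' @export
setMethod("rankTriplets", "ContextSpectrum", function(x, ...) {
  rankTriplets(x@tripletTable)
})

#' @rdname rankTriplets
#' @export
setMethod("rankTriplets", "data.frame", function(x, ...) {
  if (!"ratio" %in% names(x)) {
    if (!all(c("expected_freq", "observed_freq") %in% names(x)))
      stopClassed("tillingr_validation",
                  "need 'ratio' or expected_freq/observed_freq columns")
    x$ratio <- ifelse(x$expected_freq > 0,
                      x$observed_freq / x$expected_freq, NA_real_)
  }
  x$ratio_2dp <- roundHalfUp(x$ratio, 2)
  o <- order(is.na(x$ratio), -ifelse(is.na(x$ratio), -Inf, x$ratio),
             x$triplet)
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Export a context spectrum report
#'
#' @param spec a \code{ContextSpectrum}.
#' @param path output path (TSV for the triplet table plus a sidecar
#'   \code{.bases.tsv}, or a single JSON file).
#' @param format \code{"tsv"} or \code{"json"}.
#' @return invisibly, \code{path}.
#' @export
writeContextSpectrum <- function(spec, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(spec@tripletTable, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(spec@baseTable, sub("(\\.tsv)?$", ".bases.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(offsets = spec@offsets, threshold = spec@threshold,
           n_canonical = spec@nCanonical,
           n_non_canonical = spec@nNonCanonical,
           n_skipped = spec@nSkipped,
           bases = spec@baseTable, triplets = spec@tripletTable),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
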