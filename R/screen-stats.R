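#' DensityEstimate: mutation density from a pooled amplicon screen
#'
#' Density is expressed as base pairs screened per detected mutation:
#' screened_bp = sum over amplicons of amplicon_length x families_screened,
#' bp_per_mutation = screened_bp / n_mutations. The 95\% interval is the
#' exact (chi-square form) Poisson interval on the mutation count,
#' propagated to bp_per_mutation (a larger count bound gives a smaller bp
#' bound, so the interval ends swap).
#'
#' @slot screenedBp total screened base pairs.
#' @slot nMutations total detected mutations.
#' @slot bpPerMutation point estimate, bp per mutation.
#' @slot ci numeric length-2, 95\% interval on bpPerMutation.
#' @slot perAmplicon data.frame of per-amplicon estimates.
#' @slot lowerBoundOnly TRUE when no mutations were seen and only a density
#'   lower bound is available.
#'
#' @export
setClass("DensityEstimate",
  representation(
    screenedBp = "numeric",
    nMutations = "integer",
    bpPerMutation = "numeric",
    ci = "numeric",
    perAmplicon = "data.frame",
    lowerBoundOnly = "logical"
  )
)

setMethod("show", "DensityEstimate", function(object) {
  if (object@lowerBoundOnly) {
    cat(sprintf(
      "DensityEstimate: 0 mutations in %.0f bp screened; density < 1/%.0f bp (95%% lower bound)\n",
      object@screenedBp, object@ci[1]))
  } else {
    cat(sprintf(
      "DensityEstimate: 1 mutation per %.0f bp (1/%d kb nearest, 1/%d kb floor)\n",
      object@bpPerMutation,
      kbDisplay(object, "nearest"), kbDisplay(object, "floor")))
    cat(sprintf("  %d mutations / %.0f bp screened; 95%% CI [%.0f, %.0f] bp/mutation\n",
                object@nMutations, object@screenedBp,
                object@ci[1], object@ci[2]))
  }
})

# exact Poisson 95% CI on a count (chi-square form)
poissonCountCI <- function(n, conf = 0.95) {
  a <- 1 - conf
  lo <- if (n == 0) 0 else stats::qchisq(a / 2, 2 * n) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * (n + 1)) / 2
  c(lo, hi)
}

#' Estimate mutation density from screen results
#'
#' @param results data.frame with columns \code{amplicon},
#'   \code{length_bp}, \code{n_families}, \code{n_mutations}; one row per
#'   amplicon.
#' @param conf confidence level for the Poisson interval.
#' @return a \code{\link{DensityEstimate-class}}. With zero total mutations
#'   only a lower bound on bp_per_mutation is available and
#'   \code{lowerBoundOnly} is set.
#' @examples
#' estimateDensity(data.frame(amplicon = "CAD", length_bp = 869,
#'                            n_families = 3515, n_mutations = 76))
#' @export
estimateDensity <- function(results, conf = 0.95) {
  need <- c("amplicon", "length_bp", "n_families", "n_mutations")
  if (!all(need %in% names(results)))
    stopClassed("tillingr_validation", "screen results need columns %s",
                paste(need, collapse = ", "))
  if (any(results$length_bp <= 0) || any(results$n_families <= 0) ||
      any(results$n_mutations < 0))
    stopClassed("tillingr_validation", "screen result counts out of range")
  screened <- results$length_bp * results$n_families
  per <- data.frame(
    amplicon = results$amplicon,
    screened_bp = screened,
    n_mutations = results$n_mutations,
    bp_per_mutation = ifelse(results$n_mutations > 0,
                             screened / results$n_mutations, NA_real_)
  )
  totBp <- sum(screened)
  totN <- as.integer(sum(results$n_mutations))
  countCI <- poissonCountCI(totN, conf)
  if (totN == 0) {
    # only an upper bound on the count -> lower bound on bp/mutation
    methods::new("DensityEstimate", screenedBp = totBp, nMutations = 0L,
                 bpPerMutation = Inf, ci = c(totBp / countCI[2], Inf),
                 perAmplicon = per, lowerBoundOnly = TRUE)
  } else {
    methods::new("DensityEstimate", screenedBp = totBp, nMutations = totN,
                 bpPerMutation = totBp / totN,
                 ci = c(totBp / countCI[2], totBp / countCI[1]),
                 perAmplicon = per, lowerBoundOnly = FALSE)
  }
}

#' @rdname kbDisplay
#' @export
setGeneric("kbDisplay", function(x, convention = c("nearest", "floor"))
  standardGeneric("kbDisplay"))

#' Display a density as "1/<kb> kb"
#'
#' Published screen densities are quoted to whole kilobases under two
#' coexisting conventions: round to the nearest kb, or truncate (floor).
#' Both are exposed; exact bp values should always accompany either.
#'
#' @param x a \code{DensityEstimate} or numeric bp-per-mutation.
#' @param convention \code{"nearest"} (half-up) or \code{"floor"}.
#' @return integer kb figure.
#' @examples
#' kbDisplay(41953, "floor")    # 41
#' kbDisplay(43648, "nearest")  # 44
#' @export
setMethod("kbDisplay", "DensityEstimate", function(x, convention) {
  kbDisplay(x@bpPerMutation, convention)
})

#' @rdname kbDisplay
#' @export
setMethod("kbDisplay", "numeric", function(x, convention) {
  convention <- match.arg(convention, c("nearest", "floor"))
  kb <- x / 1000
  as.integer(if (convention == "nearest") roundHalfUp(kb, 0) else floor(kb))
})

#' @rdname GeneModel-accessors
#' @export
setGeneric("bpPerMutation", function(x) standardGeneric("bpPerMutation"))
#' @rdname GeneModel-accessors
#' @export
setMethod("bpPerMutation", "DensityEstimate", function(x) x@bpPerMutation)

#' Extrapolate genome-wide mutation load
#'
#' @param d a \code{DensityEstimate} or numeric bp-per-mutation.
#' @param genomeSize genome size in bp.
#' @return list: \code{load} (expected mutations per genome), \code{ci}
#'   (propagated from the density interval, when available) and
#'   \code{display} (rounded to the nearest thousand when >= 1000).
#' @examples
#' genomeLoad(41953, 370e6)$display  # 9000
#' @export
genomeLoad <- function(d, genomeSize) {
  stopifnot(genomeSize > 0)
  if (methods::is(d, "DensityEstimate")) {
    load <- genomeSize / d@bpPerMutation
    ci <- sort(genomeSize / d@ci)
  } else {
    load <- genomeSize / d
    ci <- NULL
  }
  disp <- if (load >= 1000) roundHalfUp(load / 1000, 0) * 1000 else load
  list(load = load, ci = ci, display = disp)
}

#' Mutation saturation of an amplicon's protein space
#'
#' Two definitions are supported, since published saturation figures rarely
#' state their formula:
#' \itemize{
#'   \item \code{residues_hit}: percent of codons encoded by the amplicon's
#'     exons carrying at least one missense or truncation call;
#'   \item \code{distinct_protein_changes}: percent of all EMS-reachable
#'     protein-changing events (every exonic G>A and C>T that alters the
#'     protein, counted as distinct (codon, alternate amino acid) pairs)
#'     that were observed.
#' }
#'
#' @param calls effect calls for one gene (from
#'   \code{\link{classifyMutations}}).
#' @param model the \code{GeneModel}.
#' @param definition \code{"residues_hit"} or
#'   \code{"distinct_protein_changes"}.
#' @return list: \code{percent} (half-up, 2 decimals), \code{numerator},
#'   \code{denominator}.
#' @export
saturation <- function(calls, model,
                       definition = c("residues_hit",
                                      "distinct_protein_changes")) {
  definition <- match.arg(definition)
  stopifnot(methods::is(model, "GeneModel"))
  nCod <- (exonicLength(model) - cdsStart(model) + 1L) %/% 3L
  if (nCod < 1L)
    stopClassed("tillingr_validation", "gene model encodes no complete codon")
  changing <- calls[calls$klass %in% c("missense", "truncation"), ,
                    drop = FALSE]
  if (definition == "residues_hit") {
    num <- length(unique(changing$aa_pos))
    den <- nCod
  } else {
    reach <- emsReachableChanges(model)
    den <- nrow(reach)
    obs <- unique(paste(changing$aa_pos, changing$aa_alt))
    num <- sum(obs %in% paste(reach$aa_pos, reach$aa_alt))
  }
  list(percent = roundHalfUp(100 * num / den, 2),
       numerator = num, denominator = den)
}

# enumerate every distinct protein-changing (aa_pos, aa_alt) reachable by a
# canonical EMS event (exonic G>A or C>T) in the model
emsReachableChanges <- function(model) {
  seq <- geneSequence(model)
  ex <- geneExons(model)
  pos <- unlist(mapply(seq.int, IRanges::start(ex), IRanges::end(ex),
                       SIMPLIFY = FALSE))
  base <- substring(seq, pos, pos)
  keep <- base %in% c("G", "C")
  pos <- pos[keep]; base <- base[keep]
  if (!length(pos)) return(data.frame(aa_pos = integer(), aa_alt = character()))
  muts <- data.frame(family_id = "enum", gene_id = geneId(model),
                     pos = pos, ref = base,
                     alt = ifelse(base == "G", "A", "T"),
                     dose = NA_character_, stringsAsFactors = FALSE)
  calls <- classifyMutations(model, muts)
  chg <- calls[calls$klass %in% c("missense", "truncation"), , drop = FALSE]
  unique(chg[, c("aa_pos", "aa_alt")])
}

#' Families to screen for a target mutation class
#'
#' Per screened family, the probability of carrying a lesion of the desired
#' class in the target is p = (target_length / bp_per_mutation) x
#' class_fraction. The expectation method returns the number of families
#' whose expected yield is one hit, ceil(1/p); the confidence method returns
#' the smallest n with P(at least one hit) >= confidence,
#' ceil(log(1 - confidence) / log(1 - p)).
#'
#' @param bpPerMutation density (bp per mutation) or a
#'   \code{DensityEstimate}.
#' @param targetLength target size in bp.
#' @param classFraction fraction of lesions in the desired class (0, 1].
#' @param method \code{"expectation"} or \code{"confidence"}.
#' @param confidence level for the confidence method.
#' @return integer number of families (>= 1).
#' @examples
#' familiesToScreen(41000, 1000, 0.724)                        # 57
#' familiesToScreen(41000, 1000, 0.724, "confidence", 0.95)
#' @export
familiesToScreen <- function(bpPerMutation, targetLength, classFraction,
                             method = c("expectation", "confidence"),
                             confidence = 0.95) {
  method <- match.arg(method)
  if (methods::is(bpPerMutation, "DensityEstimate"))
    bpPerMutation <- bpPerMutation@bpPerMutation
  if (!(classFraction > 0 && classFraction <= 1))
    stopClassed("tillingr_validation", "classFraction must be in (0, 1]")
  p <- (targetLength / bpPerMutation) * classFraction
  if (p <= 0)
    stopClassed("tillingr_validation", "per-family hit probability is <= 0")
  if (p >= 1) return(1L)
  n <- switch(method,
              expectation = ceiling(1 / p),
              confidence = ceiling(log(1 - confidence) / log(1 - p)))
  as.integer(max(1, n))
}

#' Preset exonic class fractions
#'
#' Pooled class fractions observed in a two-amplicon lignin-gene screen of
#' an EMS flax population (missense 0.667, silent 0.276, truncation 0.057),
#' convenient as defaults for \code{\link{familiesToScreen}};
#' \code{protein_changing} is missense + truncation.
#'
#' @return named numeric vector of fractions.
#' @export
classFractionPresets <- function() {
  c(missense = 0.667, silent = 0.276, truncation = 0.057,
    protein_changing = 0.724)
}
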