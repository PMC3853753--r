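#' Parse a compact mutation token
#'
#' Tokens follow the nucleotide nomenclature used for TILLinG alleles:
#' reference base, 1-based gene-local position, alternate base, e.g.
#' \code{"G1734A"} or \code{"C999T"}.
#'
#' @param token character vector of tokens.
#' @param familyId,geneId recycled identifier columns.
#' @param dose optional EMS-dose label, recycled.
#' @return data.frame with columns \code{family_id}, \code{gene_id},
#'   \code{pos}, \code{ref}, \code{alt}, \code{dose}.
#' @examples
#' parseMutation("G1734A", "fam645", "CAD")
#' @export
parseMutation <- function(token, familyId, geneId, dose = NA_character_) {
  ok <- grepl("^[ACGT][0-9]+[ACGT]$", token)
  if (any(!ok))
    stopClassed("tillingr_parse",
                "malformed mutation token(s): %s",
                paste(token[!ok], collapse = ", "))
  ref <- substr(token, 1L, 1L)
  alt <- substring(token, nchar(token))
  pos <- as.integer(substr(token, 2L, nchar(token) - 1L))
  same <- ref == alt
  if (any(same))
    stopClassed("tillingr_parse",
                "mutation token(s) with ref == alt: %s",
                paste(token[same], collapse = ", "))
  data.frame(family_id = as.character(familyId),
             gene_id = as.character(geneId),
             pos = pos, ref = ref, alt = alt,
             dose = as.character(dose),
             stringsAsFactors = FALSE)
}

#' Read a mutation table from TSV
#'
#' Accepts either a \code{mutation} column of compact tokens (parsed with
#' \code{\link{parseMutation}}) or explicit \code{pos}, \code{ref},
#' \code{alt} columns; \code{family_id} and \code{gene_id} are required.
#'
#' @param path TSV path.
#' @return mutation data.frame as from \code{\link{parseMutation}}.
#' @export
readMutationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "gene_id")
  if (!all(need %in% names(tab)))
    stopClassed("tillingr_parse", "mutation table needs columns %s",
                paste(need, collapse = ", "))
  dose <- if ("dose" %in% names(tab)) tab$dose else NA_character_
  if ("mutation" %in% names(tab)) {
    parseMutation(tab$mutation, tab$family_id, tab$gene_id, dose)
  } else {
    if (!all(c("pos", "ref", "alt") %in% names(tab)))
      stopClassed("tillingr_parse",
                  "mutation table needs a 'mutation' column or pos/ref/alt")
    data.frame(family_id = as.character(tab$family_id),
               gene_id = as.character(tab$gene_id),
               pos = as.integer(tab$pos),
               ref = toupper(tab$ref), alt = toupper(tab$alt),
               dose = as.character(dose), stringsAsFactors = FALSE)
  }
}

# amino acid for a codon; "*" for stop; NA if codon contains N
translateCodon <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify point mutations against a gene model
#'
#' Each substitution is mapped through the exon structure and, when coding,
#' its codon is re-translated with the substitution applied. Classes follow
#' the standard three-way TILLinG scheme plus intronic:
#' \itemize{
#'   \item \code{silent} — amino acid unchanged;
#'   \item \code{missense} — amino acid changed (including stop-loss and
#'     start-codon loss, which carry a \code{flag}, since the three-way
#'     scheme has no separate class for them);
#'   \item \code{truncation} — premature stop gained;
#'   \item \code{intronic} — position outside all exons;
#'   \item \code{ambiguous} — codon contains N, or the position is exonic
#'     but has no complete codon (upstream of the start codon or in a
#'     truncated terminal codon).
#' }
#' \code{splice_adjacent} is informational only: TRUE when an intronic
#' position lies in the first or last 2 bases of its intron.
#'
#' @param model a \code{GeneModel}.
#' @param mutations data.frame with \code{pos}, \code{ref}, \code{alt}
#'   (e.g. from \code{\link{parseMutation}}).
#' @return the input with columns \code{klass}, \code{aa_ref}, \code{aa_pos},
#'   \code{aa_alt}, \code{splice_adjacent}, \code{flag} appended. \code{aa_*}
#'   are populated only for coding classes; stop is written \code{"*"}.
#' @examples
#' gm <- GeneModel("toy", "ATGTGGTAA")
#' classifyMutations(gm, parseMutation("G5A", "f1", "toy"))
#' @export
classifyMutations <- function(model, mutations) {
  stopifnot(methods::is(model, "GeneModel"))
  n <- nrow(mutations)
  seq <- geneSequence(model)
  klass <- character(n); aaRef <- rep(NA_character_, n)
  aaAlt <- rep(NA_character_, n); aaPos <- rep(NA_integer_, n)
  splice <- rep(FALSE, n); flag <- rep(NA_character_, n)
  introns <- intronRanges(model)
  for (i in seq_len(n)) {
    pos <- mutations$pos[i]
    ref <- mutations$ref[i]; alt <- mutations$alt[i]
    if (pos < 1L || pos > nchar(seq))
      stopClassed("tillingr_validation",
                  "position %d outside gene '%s' (length %d)",
                  pos, geneId(model), nchar(seq))
    have <- substr(seq, pos, pos)
    if (have != ref)
      stopClassed("tillingr_ref_mismatch",
                  "reference mismatch at %s:%d — expected %s, mutation says %s",
                  geneId(model), pos, have, ref)
    cdsPos <- exonicPosition(model, pos)
    if (is.na(cdsPos)) {
      klass[i] <- "intronic"
      if (length(introns)) {
        is_ <- IRanges::start(introns); ie <- IRanges::end(introns)
        j <- which(pos >= is_ & pos <= ie)
        splice[i] <- length(j) > 0 &&
          (pos - is_[j] < 2L || ie[j] - pos < 2L)
      }
      next
    }
    if (cdsPos < cdsStart(model)) {
      klass[i] <- "ambiguous"; flag[i] <- "upstream_of_start"
      next
    }
    cod <- tryCatch(codonAt(model, cdsPos), error = function(e) e)
    if (inherits(cod, "tillingr_incomplete_codon")) {
      klass[i] <- "ambiguous"; flag[i] <- "incomplete_codon"
      next
    }
    mutCodon <- cod$codon
    substr(mutCodon, cod$offset, cod$offset) <- alt
    aR <- translateCodon(cod$codon); aA <- translateCodon(mutCodon)
    if (is.na(aR) || is.na(aA)) {
      klass[i] <- "ambiguous"; flag[i] <- "codon_contains_N"
      next
    }
    aaRef[i] <- aR; aaAlt[i] <- aA; aaPos[i] <- cod$index
    if (aR == aA) {
      klass[i] <- "silent"
    } else if (aA == "*") {
      klass[i] <- "truncation"
    } else {
      klass[i] <- "missense"
      if (aR == "*") flag[i] <- "stop_loss"
      if (cod$index == 1L && cod$codon == "ATG") flag[i] <- "start_loss"
    }
  }
  out <- mutations
  out$klass <- klass; out$aa_ref <- aaRef; out$aa_pos <- aaPos
  out$aa_alt <- aaAlt; out$splice_adjacent <- splice; out$flag <- flag
  out
}

#' Summarize effect calls into class counts, percentages and spectrum
#'
#' Percentages are computed over exonic coding calls (silent + missense +
#' truncation) and rounded half-up to one decimal. The substitution spectrum
#' counts each ref>alt type over all calls and splits canonical EMS
#' transitions (G>A / C>T, i.e. G/C to A/T) from everything else.
#'
#' @param calls output of \code{\link{classifyMutations}} (rows from several
#'   genes may be concatenated).
#' @return an \code{EffectSummary} list: \code{n_total}, \code{n_exonic},
#'   \code{n_intronic}, \code{n_ambiguous}, \code{counts}, \code{percent},
#'   \code{spectrum}, \code{n_canonical}, \code{n_other}.
#' @export
summarizeEffects <- function(calls) {
  classes <- c("silent", "missense", "truncation")
  counts <- vapply(classes, function(k) sum(calls$klass == k), integer(1))
  nExonic <- sum(counts)
  summ <- list(
    n_total = nrow(calls),
    n_exonic = nExonic,
    n_intronic = sum(calls$klass == "intronic"),
    n_ambiguous = sum(calls$klass == "ambiguous"),
    counts = counts,
    percent = if (nExonic > 0) roundHalfUp(100 * counts / nExonic, 1)
              else stats::setNames(rep(NA_real_, 3), classes)
  )
  if (nrow(calls)) {
    sub <- paste0(calls$ref, ">", calls$alt)
    summ$spectrum <- table(sub)
    summ$n_canonical <- sum(sub %in% c("G>A", "C>T"))
    summ$n_other <- nrow(calls) - summ$n_canonical
  } else {
    summ$spectrum <- table(character())
    summ$n_canonical <- 0L; summ$n_other <- 0L
  }
  class(summ) <- "EffectSummary"
  summ
}

#' Effect summary from pre-tabulated class counts
#'
#' For published screens only the per-class counts are available; this
#' computes the same percentages as \code{\link{summarizeEffects}} from
#' counts alone. When printed reference percentages are supplied, recomputed
#' values that differ are flagged rather than silently reconciled.
#'
#' @param silent,missense,truncation class counts.
#' @param printed optional named numeric of published percentages to compare
#'   against (names among silent/missense/truncation).
#' @return list with \code{counts}, \code{n_exonic}, \code{percent} and, if
#'   \code{printed} given, a \code{discrepancy} data.frame of mismatches.
#' @examples
#' effectSummaryFromCounts(15, 51, 1)$percent  # 22.4 76.1 1.5
#' @export
effectSummaryFromCounts <- function(silent, missense, truncation,
                                    printed = NULL) {
  counts <- c(silent = silent, missense = missense, truncation = truncation)
  nEx <- sum(counts)
  pct <- roundHalfUp(100 * counts / nEx, 1)
  out <- list(counts = counts, n_exonic = nEx, percent = pct)
  if (!is.null(printed)) {
    printed <- printed[names(printed) %in% names(pct)]
    diff <- abs(pct[names(printed)] - printed) > 0.05
    out$discrepancy <- data.frame(
      class = names(printed)[diff],
      recomputed = unname(pct[names(printed)][diff]),
      printed = unname(printed[diff])
    )
  }
  class(out) <- "EffectSummary"
  out
}

#' @export
print.EffectSummary <- function(x, ...) {
  cat("Effect summary\n")
  if (!is.null(x$n_total))
    cat(sprintf("  total %d | exonic coding %d | intronic %d | ambiguous %d\n",
                x$n_total, x$n_exonic, x$n_intronic, x$n_ambiguous))
  for (k in names(x$counts))
    cat(sprintf("  %-10s %5d  (%s%%)\n", k, x$counts[[k]],
                format(x$percent[[k]], nsmall = 1)))
  if (!is.null(x$n_canonical))
    cat(sprintf("  G/C->A/T transitions: %d of %d\n",
                x$n_canonical, x$n_canonical + x$n_other))
  if (!is.null(x$discrepancy) && nrow(x$discrepancy))
    cat(sprintf("  NOTE recomputed %% differs from printed %%: %s\n",
                paste(sprintf("%s %.1f vs %.1f", x$discrepancy$class,
                              x$discrepancy$recomputed, x$discrepancy$printed),
                      collapse = "; ")))
  invisible(x)
}

#' Windowed G+C content and mutation counts along a gene
#'
#' Divides the gene into consecutive non-overlapping windows from position 1
#' and tabulates G+C bases and mutation counts per window, flagging windows
#' that overlap an intron and the final partial window. This is the standard
#' view for relating local mutation density to base composition.
#'
#' @param model a \code{GeneModel}.
#' @param calls mutation data.frame with a \code{pos} column (may be empty).
#' @param window window width in bp (default 100).
#' @return data.frame: \code{window}, \code{start}, \code{end},
#'   \code{gc_count}, \code{mutation_count}, \code{intron_overlap},
#'   \code{partial}.
#' @export
windowGCMutations <- function(model, calls = NULL, window = 100L) {
  stopifnot(methods::is(model, "GeneModel"), window >= 1L)
  seq <- geneSequence(model)
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = window)
  ends <- pmin(starts + window - 1L, n)
  introns <- intronRanges(model)
  gc <- vapply(seq_along(starts), function(i) {
    w <- substr(seq, starts[i], ends[i])
    sum(strsplit(w, "")[[1]] %in% c("G", "C"))
  }, integer(1))
  mut <- if (is.null(calls) || !nrow(calls)) integer(length(starts)) else
    vapply(seq_along(starts),
           function(i) sum(calls$pos >= starts[i] & calls$pos <= ends[i]),
           integer(1))
  iv <- if (length(introns))
    vapply(seq_along(starts), function(i)
      any(IRanges::start(introns) <= ends[i] &
            IRanges::end(introns) >= starts[i]), logical(1))
  else rep(FALSE, length(starts))
  data.frame(window = seq_along(starts), start = starts, end = ends,
             gc_count = gc, mutation_count = mut, intron_overlap = iv,
             partial = ends - starts + 1L < window)
}

#' Write effect calls as TSV or minimal VCF
#'
#' @param calls output of \code{\link{classifyMutations}}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"vcf"} (CHROM = gene id, 1-based POS,
#'   INFO carries EFFECT and protein change).
#' @return invisibly, \code{path}.
#' @export
writeEffectCalls <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Mutation effect class\">",
             "##INFO=<ID=AACHANGE,Number=1,Type=String,Description=\"Protein change\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    aach <- ifelse(is.na(calls$aa_pos), ".",
                   paste0(calls$aa_ref, calls$aa_pos, calls$aa_alt))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tEFFECT=%s;AACHANGE=%s",
                    calls$gene_id, calls$pos, calls$family_id,
                    calls$ref, calls$alt, calls$klass, aach)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
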