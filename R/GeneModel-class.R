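#' GeneModel: a gene-local coding-strand sequence with exon structure
#'
#' The coordinate frame for all mutation analysis. Positions are 1-based,
#' inclusive and gene-local on the coding strand, so a mutation token such as
#' \code{"G1734A"} indexes \code{geneSequence(model)} directly, introns
#' included. \code{cdsStart} is the 1-based position of the first base of the
#' start codon *within the concatenated exonic sequence* (default 1), which
#' absorbs any ambiguity about whether position 1 of the gene is the
#' transcription or translation start.
#'
#' @slot geneId single gene identifier.
#' @slot sequence \code{\link[Biostrings]{DNAString}} over \{A,C,G,T,N\}.
#' @slot exons \code{\link[IRanges]{IRanges}} of exon intervals, sorted,
#'   non-overlapping, within the sequence.
#' @slot cdsStart integer, 1-based offset of the start codon in the
#'   concatenated exonic sequence.
#'
#' @export
setClass("GeneModel",
  representation(
    geneId = "character",
    sequence = "DNAString",
    exons = "IRanges",
    cdsStart = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msgs <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msgs <- c(msgs, "geneId must be a single non-empty string")
  bad <- setdiff(
    unique(strsplit(as.character(object@sequence), "")[[1]]),
    c("A", "C", "G", "T", "N")
  )
  if (length(bad))
    msgs <- c(msgs, sprintf("sequence contains characters outside {A,C,G,T,N}: %s",
                            paste(bad, collapse = ",")))
  ex <- object@exons
  if (length(ex)) {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    if (any(s < 1L) || any(e > length(object@sequence)))
      msgs <- c(msgs, sprintf(
        "exon interval [%d,%d] outside sequence bounds [1,%d]",
        s[which(s < 1L | e > length(object@sequence))[1]],
        e[which(s < 1L | e > length(object@sequence))[1]],
        length(object@sequence)))
    if (is.unsorted(s))
      msgs <- c(msgs, "exons must be sorted by start position")
    if (length(ex) > 1L && any(s[-1L] <= e[-length(ex)]))
      msgs <- c(msgs, sprintf("overlapping exons: [%d,%d] and [%d,%d]",
                              s[which(s[-1L] <= e[-length(ex)])[1]],
                              e[which(s[-1L] <= e[-length(ex)])[1]],
                              s[which(s[-1L] <= e[-length(ex)])[1] + 1L],
                              e[which(s[-1L] <= e[-length(ex)])[1] + 1L]))
  }
  if (length(object@cdsStart) != 1L || is.na(object@cdsStart) ||
      object@cdsStart < 1L)
    msgs <- c(msgs, "cdsStart must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneModel
#'
#' Exon intervals are normalized: sorted ascending and merged when bookended
#' (end of one exon immediately followed by the start of the next). Truly
#' overlapping exons are an error.
#'
#' @param geneId gene identifier.
#' @param sequence DNA string (character or DNAString), upper-cased.
#' @param exons two-column matrix/data.frame of (start, end) or an
#'   \code{IRanges}; defaults to a single exon spanning the whole sequence.
#' @param cdsStart 1-based start-codon offset within the concatenated exonic
#'   sequence.
#' @return validated \code{GeneModel}.
#' @examples
#' gm <- GeneModel("toy", "ATGGGATAA")
#' exonicLength(gm)
#' @export
GeneModel <- function(geneId, sequence, exons = NULL, cdsStart = 1L) {
  seq <- Biostrings::DNAString(toupper(as.character(sequence)))
  if (is.null(exons)) {
    ex <- IRanges::IRanges(start = 1L, end = length(seq))
  } else if (methods::is(exons, "IRanges")) {
    ex <- exons
  } else {
    exons <- as.matrix(as.data.frame(exons)[, 1:2])
    storage.mode(exons) <- "integer"
    ex <- IRanges::IRanges(start = exons[, 1], end = exons[, 2])
  }
  ex <- normalizeExons(ex, length(seq))
  methods::new("GeneModel", geneId = as.character(geneId), sequence = seq,
               exons = ex, cdsStart = as.integer(cdsStart))
}

# sort; merge bookended neighbours; error on overlap / out-of-bounds
normalizeExons <- function(ex, seqLen) {
  if (!length(ex)) stopClassed("tillingr_validation", "gene model has no exons")
  o <- order(IRanges::start(ex), IRanges::end(ex))
  ex <- ex[o]
  s <- IRanges::start(ex); e <- IRanges::end(ex)
  if (any(s < 1L | e > seqLen | s > e)) {
    i <- which(s < 1L | e > seqLen | s > e)[1]
    stopClassed("tillingr_validation",
                "exon interval [%d,%d] invalid for sequence of length %d",
                s[i], e[i], seqLen)
  }
  if (length(ex) > 1L) {
    ov <- which(s[-1L] <= e[-length(ex)])
    if (length(ov))
      stopClassed("tillingr_validation",
                  "overlapping exons: [%d,%d] and [%d,%d]",
                  s[ov[1]], e[ov[1]], s[ov[1] + 1L], e[ov[1] + 1L])
    # merge bookended: end[i] + 1 == start[i+1]
    ex <- IRanges::reduce(ex, min.gapwidth = 1L)
  }
  ex
}

#' @rdname GeneModel-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("geneSequence", function(x) standardGeneric("geneSequence"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("cdsStart", function(x) standardGeneric("cdsStart"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("exonicLength", function(x) standardGeneric("exonicLength"))
#' @rdname GeneModel-accessors
#' @export
setGeneric("exonicSequence", function(x) standardGeneric("exonicSequence"))

#' Accessors for GeneModel
#'
#' @param x a \code{GeneModel}.
#' @return \code{geneId}: character; \code{geneSequence}: character DNA;
#'   \code{geneExons}: \code{IRanges}; \code{cdsStart}, \code{exonicLength}:
#'   integer; \code{exonicSequence}: character concatenated exonic DNA.
#' @name GeneModel-accessors
NULL

#' @rdname GeneModel-accessors
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)
#' @rdname GeneModel-accessors
#' @export
setMethod("geneSequence", "GeneModel", function(x) as.character(x@sequence))
#' @rdname GeneModel-accessors
#' @export
setMethod("geneExons", "GeneModel", function(x) x@exons)
#' @rdname GeneModel-accessors
#' @export
setMethod("cdsStart", "GeneModel", function(x) x@cdsStart)
#' @rdname GeneModel-accessors
#' @export
setMethod("exonicLength", "GeneModel", function(x) sum(IRanges::width(x@exons)))
#' @rdname GeneModel-accessors
#' @export
setMethod("exonicSequence", "GeneModel", function(x) {
  seq <- as.character(x@sequence)
  paste(substring(seq, IRanges::start(x@exons), IRanges::end(x@exons)),
        collapse = "")
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s': %d bp, %d exon(s), exonic %d bp, cdsStart %d\n",
              object@geneId, length(object@sequence), length(object@exons),
              sum(IRanges::width(object@exons)), object@cdsStart))
})

#' Load a gene model from FASTA plus exon structure
#'
#' The structure file is either a tab-separated table with columns
#' \code{gene_id}, \code{exon_start}, \code{exon_end} (gene-local, 1-based
#' inclusive) or a GFF3 file containing a \code{gene} feature and \code{exon}
#' features for \code{geneId}. GFF3 exon coordinates are mapped to gene-local
#' coordinates by subtracting the gene feature's start; minus-strand genes are
#' reverse-complemented at load so downstream code only ever sees the coding
#' strand.
#'
#' @param fastaPath path to a (multi-)FASTA file.
#' @param structurePath path to the exon TSV or GFF3 file (extension
#'   \code{.gff}/\code{.gff3} selects the GFF3 parser).
#' @param geneId record/feature identifier to load.
#' @param cdsStart passed to \code{\link{GeneModel}}.
#' @return a validated \code{GeneModel}.
#' @export
loadGeneModel <- function(fastaPath, structurePath, geneId, cdsStart = 1L) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!geneId %in% names(seqs))
    stopClassed("tillingr_missing_record",
                "no FASTA record '%s' in %s", geneId, fastaPath)
  seq <- as.character(seqs[[geneId]])
  if (grepl("\\.gff3?$", structurePath, ignore.case = TRUE)) {
    gff <- rtracklayer::import(structurePath)
    ids <- as.character(gff$ID %||% rep(NA, length(gff)))
    parents <- vapply(as.list(gff$Parent %||% vector("list", length(gff))),
                      function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                      character(1))
    geneFeat <- gff[!is.na(ids) & ids == geneId & gff$type == "gene"]
    if (!length(geneFeat))
      stopClassed("tillingr_missing_record",
                  "no gene feature '%s' in %s", geneId, structurePath)
    exFeat <- gff[gff$type == "exon" &
                    (parents == geneId |
                       as.character(GenomicRanges::seqnames(gff)) == geneId)]
    if (!length(exFeat))
      stopClassed("tillingr_missing_record",
                  "no exon features for '%s' in %s", geneId, structurePath)
    gStart <- GenomicRanges::start(geneFeat)[1]
    minus <- as.character(GenomicRanges::strand(geneFeat))[1] == "-"
    st <- GenomicRanges::start(exFeat) - gStart + 1L
    en <- GenomicRanges::end(exFeat) - gStart + 1L
    if (minus) {
      n <- nchar(seq)
      seq <- revComp(seq)
      tmp <- n - en + 1L
      en <- n - st + 1L
      st <- tmp
    }
    ex <- cbind(st, en)
  } else {
    tab <- utils::read.delim(structurePath, stringsAsFactors = FALSE)
    tab <- tab[tab$gene_id == geneId, , drop = FALSE]
    if (!nrow(tab))
      stopClassed("tillingr_missing_record",
                  "no exon rows for '%s' in %s", geneId, structurePath)
    ex <- cbind(tab$exon_start, tab$exon_end)
  }
  GeneModel(geneId, seq, exons = ex, cdsStart = cdsStart)
}

#' Write a gene model to FASTA and exon TSV
#'
#' Inverse of \code{\link{loadGeneModel}} with a TSV structure file; reloading
#' the written pair yields an identical model.
#'
#' @param model a \code{GeneModel}.
#' @param fastaPath,structurePath output paths.
#' @param append append to existing files (for multi-gene output).
#' @return invisibly, the two paths.
#' @export
writeGeneModel <- function(model, fastaPath, structurePath, append = FALSE) {
  cat(sprintf(">%s\n%s\n", geneId(model), geneSequence(model)),
      file = fastaPath, append = append)
  tab <- data.frame(gene_id = geneId(model),
                    exon_start = IRanges::start(geneExons(model)),
                    exon_end = IRanges::end(geneExons(model)))
  utils::write.table(tab, structurePath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append, append = append)
  invisible(c(fastaPath, structurePath))
}

#' Map a gene-local position to its coding-sequence position
#'
#' @param model a \code{GeneModel}.
#' @param pos integer vector of 1-based gene-local positions.
#' @return integer vector: the 1-based offset within the concatenated exonic
#'   sequence, or \code{NA} where the position is intronic.
#' @examples
#' gm <- GeneModel("g", paste(rep("A", 12), collapse = ""),
#'                 exons = rbind(c(1, 3), c(7, 12)))
#' exonicPosition(gm, c(8, 5))  # 5, NA
#' @export
exonicPosition <- function(model, pos) {
  stopifnot(methods::is(model, "GeneModel"))
  pos <- as.integer(pos)
  n <- length(model@sequence)
  if (any(is.na(pos)) || any(pos < 1L | pos > n))
    stopClassed("tillingr_validation",
                "position out of range [1,%d]", n)
  s <- IRanges::start(model@exons); e <- IRanges::end(model@exons)
  cum <- c(0L, cumsum(e - s + 1L))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(s)) {
    hit <- pos >= s[i] & pos <= e[i]
    out[hit] <- cum[i] + (pos[hit] - s[i] + 1L)
  }
  out
}

#' Extract the codon covering a coding-sequence position
#'
#' @param model a \code{GeneModel}.
#' @param cdsPos 1-based position within the concatenated exonic sequence;
#'   must be at or after \code{cdsStart(model)}.
#' @return list with \code{codon} (3-letter string), \code{index} (1-based
#'   codon number from the start codon) and \code{offset} (1, 2 or 3, the
#'   position within the codon).
#' @export
codonAt <- function(model, cdsPos) {
  stopifnot(methods::is(model, "GeneModel"))
  cdsPos <- as.integer(cdsPos)
  cds <- exonicSequence(model)
  if (cdsPos < cdsStart(model) || cdsPos > nchar(cds))
    stopClassed("tillingr_validation",
                "cdsPos %d outside coding range [%d,%d]",
                cdsPos, cdsStart(model), nchar(cds))
  rel <- cdsPos - cdsStart(model)      # 0-based from start codon
  idx <- rel %/% 3L + 1L
  off <- rel %% 3L + 1L
  from <- cdsStart(model) + (idx - 1L) * 3L
  if (from + 2L > nchar(cds))
    stopClassed("tillingr_incomplete_codon",
                "incomplete terminal codon at cds position %d", cdsPos)
  list(codon = substr(cds, from, from + 2L), index = idx, offset = off)
}

# intron intervals of a model as an IRanges (may be empty)
intronRanges <- function(model) {
  IRanges::gaps(model@exons, start = 1L, end = length(model@sequence))
}
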