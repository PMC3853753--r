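#' Validate family phenotype records
#'
#' A family record is one row per M2 family: \code{family_id}, \code{dose},
#' \code{seeds_sown}, \code{plants_germinated}, \code{plants_sterile},
#' zero or more logical/0-1 phenotype category columns named
#' \code{flag_<category>}, and an optional \code{grades} column of
#' semicolon-joined per-plant intensity grades in \{0,1,2,3\} (3 = weakest
#' visible, 1 = strongest, 0 = absent).
#'
#' @param records data.frame of family records.
#' @return the records, invisibly, after validation.
#' @export
validateFamilyRecords <- function(records) {
  need <- c("family_id", "seeds_sown", "plants_germinated", "plants_sterile")
  if (!all(need %in% names(records)))
    stopClassed("tillingr_validation", "family records need columns %s",
                paste(need, collapse = ", "))
  bad <- which(records$plants_sterile < 0 |
                 records$plants_sterile > records$plants_germinated |
                 records$plants_germinated > records$seeds_sown)
  if (length(bad))
    stopClassed("tillingr_validation",
                "count invariant violated for family %s (0 <= sterile <= germinated <= sown)",
                records$family_id[bad[1]])
  if ("grades" %in% names(records)) {
    g <- unlist(parseGrades(records$grades))
    if (length(g) && any(!g %in% 0:3))
      stopClassed("tillingr_validation", "grades must be in {0,1,2,3}")
  }
  invisible(records)
}

# "1;0;2" -> c(1L, 0L, 2L); empty/NA -> integer(0)
parseGrades <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

flagColumns <- function(records) grep("^flag_", names(records), value = TRUE)

#' Summarize a phenotyped mutant population
#'
#' A family counts as "with phenotype" when any category flag is set, and
#' "multiple" when at least two categories are set. Percentages are half-up
#' to one decimal over the denominators stated below:
#' \itemize{
#'   \item phenotype percentages over families with at least one germinated
#'     plant (non-germinating families cannot be phenotyped);
#'   \item germination failure over all sown families;
#'   \item sterility over all germinated plants, overall and per dose.
#' }
#'
#' @param records validated family records (see
#'   \code{\link{validateFamilyRecords}}).
#' @return list: \code{n_families}, \code{n_germinated_families},
#'   \code{n_plants}, \code{n_with_phenotype}, \code{pct_with_phenotype},
#'   \code{pct_germination_failure}, \code{n_sterile},
#'   \code{pct_sterile}, \code{per_dose} (data.frame), \code{per_category}
#'   (data.frame with single/multiple split), \code{family_grade} (named
#'   max grade per family, when grades supplied).
#' @export
summarizePopulation <- function(records) {
  if (!nrow(records))
    stopClassed("tillingr_validation", "no family records supplied")
  validateFamilyRecords(records)
  fc <- flagColumns(records)
  flagMat <- if (length(fc))
    as.matrix(records[, fc, drop = FALSE]) * 1 else
    matrix(0, nrow(records), 0)
  nCat <- rowSums(flagMat)
  germ <- records$plants_germinated > 0
  nGermFam <- sum(germ)
  nPlants <- sum(records$plants_germinated)
  nSterile <- sum(records$plants_sterile)
  withPheno <- nCat > 0 & germ

  perCategory <- if (length(fc)) data.frame(
    category = sub("^flag_", "", fc),
    n_families = colSums(flagMat[germ, , drop = FALSE] > 0),
    n_single = colSums(flagMat[germ & nCat == 1, , drop = FALSE] > 0),
    n_multiple = colSums(flagMat[germ & nCat >= 2, , drop = FALSE] > 0),
    row.names = NULL
  ) else data.frame(category = character(), n_families = integer(),
                    n_single = integer(), n_multiple = integer())

  perDose <- if ("dose" %in% names(records)) {
    sp <- split(records, records$dose)
    data.frame(
      dose = names(sp),
      n_families = vapply(sp, nrow, integer(1)),
      n_plants = vapply(sp, function(d) sum(d$plants_germinated), numeric(1)),
      n_sterile = vapply(sp, function(d) sum(d$plants_sterile), numeric(1)),
      pct_sterile = vapply(sp, function(d) {
        np <- sum(d$plants_germinated)
        if (np > 0) roundHalfUp(100 * sum(d$plants_sterile) / np, 1) else NA_real_
      }, numeric(1)),
      row.names = NULL
    )
  } else NULL

  familyGrade <- if ("grades" %in% names(records)) {
    g <- parseGrades(records$grades)
    stats::setNames(
      vapply(g, function(v) if (length(v)) max(v) else NA_integer_,
             integer(1)),
      records$family_id)
  } else NULL

  list(
    n_families = nrow(records),
    n_germinated_families = nGermFam,
    n_plants = nPlants,
    n_with_phenotype = sum(withPheno),
    pct_with_phenotype = if (nGermFam > 0)
      roundHalfUp(100 * sum(withPheno) / nGermFam, 1) else NA_real_,
    pct_germination_failure =
      roundHalfUp(100 * sum(!germ) / nrow(records), 1),
    n_sterile = nSterile,
    pct_sterile = if (nPlants > 0)
      roundHalfUp(100 * nSterile / nPlants, 1) else NA_real_,
    n_multiple_phenotype = sum(nCat >= 2 & germ),
    per_category = perCategory,
    per_dose = perDose,
    family_grade = familyGrade
  )
}

#' Genotype-phenotype concordance between mutant and control plants
#'
#' Compares the per-plant frequency of a graded phenotype between families
#' carrying a candidate mutation (cases) and a control set. A plant counts
#' as affected when its intensity grade is at least \code{gradeThreshold}
#' (grades use 1 = strongest ... 3 = weakest, 0 = absent, so the default
#' threshold 1 means any visible phenotype). A Fisher exact test on the
#' plant-level 2x2 table is reported as auxiliary evidence.
#'
#' @param caseRecords,controlRecords family records with a \code{grades}
#'   column (per-plant grades), or data.frames with \code{n_affected} and
#'   \code{n_plants} columns of pre-tabulated counts.
#' @param gradeThreshold minimum grade that counts as affected (>= 1).
#' @return list: \code{case_freq}, \code{control_freq} (half-up, 2
#'   decimals), \code{case_fraction}, \code{control_fraction} (exact),
#'   \code{table} (2x2 affected x group), \code{fisher_p},
#'   \code{case_families_affected} (families with >= 1 affected plant, when
#'   grades supplied).
#' @examples
#' cases <- data.frame(n_affected = 62, n_plants = 108)
#' controls <- data.frame(n_affected = 6, n_plants = 94)
#' concordance(cases, controls)$case_freq  # 0.57
#' @export
concordance <- function(caseRecords, controlRecords, gradeThreshold = 1L) {
  countGroup <- function(records) {
    if (all(c("n_affected", "n_plants") %in% names(records))) {
      list(aff = sum(records$n_affected), tot = sum(records$n_plants),
           famAff = NA_integer_)
    } else if ("grades" %in% names(records)) {
      g <- parseGrades(records$grades)
      affPerFam <- vapply(g, function(v)
        sum(v >= gradeThreshold & v > 0), integer(1))
      list(aff = sum(affPerFam),
           tot = sum(vapply(g, length, integer(1))),
           famAff = sum(affPerFam > 0))
    } else {
      stopClassed("tillingr_validation",
                  "records need 'grades' or n_affected/n_plants columns")
    }
  }
  cs <- countGroup(caseRecords)
  ct <- countGroup(controlRecords)
  if (cs$tot == 0 || ct$tot == 0)
    stopClassed("tillingr_validation", "zero plants in a group")
  tab <- matrix(c(cs$aff, cs$tot - cs$aff, ct$aff, ct$tot - ct$aff),
                nrow = 2,
                dimnames = list(c("affected", "unaffected"),
                                c("case", "control")))
  list(
    case_freq = roundHalfUp(cs$aff / cs$tot, 2),
    control_freq = roundHalfUp(ct$aff / ct$tot, 2),
    case_fraction = cs$aff / cs$tot,
    control_fraction = ct$aff / ct$tot,
    table = tab,
    fisher_p = stats::fisher.test(tab)$p.value,
    case_families_affected = cs$famAff
  )
}

#' Read / write phenotype tables
#'
#' One row per family; per-plant grades serialized as semicolon-joined
#' integers in the \code{grades} column.
#'
#' @param path TSV path.
#' @param records family records to write.
#' @return \code{readPhenotypeTable}: validated data.frame.
#' @export
readPhenotypeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("grades" %in% names(tab)) tab$grades <- as.character(tab$grades)
  validateFamilyRecords(tab)
  tab
}

#' @rdname readPhenotypeTable
#' @export
writePhenotypeTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
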