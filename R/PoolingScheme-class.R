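#' PoolingScheme: k-fold 1D pooling across 96-well plates
#'
#' Each family's DNA enters exactly one pool of at most k families; pools
#' fill plate wells row-major (A01, A02, ..., A12, B01, ...). A positive
#' pool implicates its members, which then require individual confirmation.
#'
#' @slot k pool size.
#' @slot plateRows,plateCols plate geometry (default 8 x 12).
#' @slot assignments data.frame: \code{family_id}, \code{pool},
#'   \code{plate}, \code{well}, \code{position_in_pool}.
#'
#' @export
setClass("PoolingScheme",
  representation(
    k = "integer",
    plateRows = "integer",
    plateCols = "integer",
    assignments = "data.frame"
  )
)

setValidity("PoolingScheme", function(object) {
  a <- object@assignments
  msgs <- character()
  if (anyDuplicated(a$family_id))
    msgs <- c(msgs, "family assigned to more than one pool")
  poolSizes <- table(a$pool)
  if (any(poolSizes > object@k))
    msgs <- c(msgs, sprintf("pool exceeds k = %d", object@k))
  if (length(msgs)) msgs else TRUE
})

#' @rdname PoolingScheme-accessors
#' @export
setGeneric("poolCount", function(x) standardGeneric("poolCount"))
#' @rdname PoolingScheme-accessors
#' @export
setGeneric("plateCount", function(x) standardGeneric("plateCount"))
#' @rdname PoolingScheme-accessors
#' @export
setGeneric("poolAssignments", function(x) standardGeneric("poolAssignments"))

#' Accessors for PoolingScheme
#'
#' @param x a \code{PoolingScheme}.
#' @return \code{poolCount}, \code{plateCount}: integer;
#'   \code{poolAssignments}: the assignment data.frame.
#' @name PoolingScheme-accessors
NULL

#' @rdname PoolingScheme-accessors
#' @export
setMethod("poolCount", "PoolingScheme",
          function(x) length(unique(x@assignments$pool)))
#' @rdname PoolingScheme-accessors
#' @export
setMethod("plateCount", "PoolingScheme",
          function(x) max(x@assignments$plate))
#' @rdname PoolingScheme-accessors
#' @export
setMethod("poolAssignments", "PoolingScheme", function(x) x@assignments)

setMethod("show", "PoolingScheme", function(object) {
  cat(sprintf(
    "PoolingScheme: %d families in %d pools of <= %d on %d plate(s) (%dx%d)\n",
    nrow(object@assignments), poolCount(object), object@k,
    plateCount(object), object@plateRows, object@plateCols))
})

wellLabel <- function(poolOnPlate, rows, cols) {
  r <- (poolOnPlate - 1L) %/% cols + 1L
  c <- (poolOnPlate - 1L) %% cols + 1L
  sprintf("%s%02d", LETTERS[r], c)
}

#' Design a k-fold 1D pooling scheme
#'
#' Families are assigned in input order, k per pool; pools fill wells
#' row-major; the last pool may be short. Plate count is
#' ceil(ceil(n/k) / (rows x cols)).
#'
#' @param familyIds unique family identifiers, in the desired fill order.
#' @param k pool size (default 8).
#' @param plateRows,plateCols plate geometry (default 8 x 12, a 96-well
#'   plate).
#' @return a \code{\link{PoolingScheme-class}}.
#' @examples
#' ps <- designPools(sprintf("F%04d", 1:3515), k = 8)
#' poolCount(ps)   # 440
#' plateCount(ps)  # 5
#' @export
designPools <- function(familyIds, k = 8L, plateRows = 8L, plateCols = 12L) {
  familyIds <- as.character(familyIds)
  if (!length(familyIds))
    stopClassed("tillingr_validation", "no families supplied")
  dup <- familyIds[duplicated(familyIds)]
  if (length(dup))
    stopClassed("tillingr_validation", "duplicate family id: %s", dup[1])
  k <- as.integer(k)
  n <- length(familyIds)
  pool <- (seq_len(n) - 1L) %/% k + 1L
  wellsPerPlate <- as.integer(plateRows) * as.integer(plateCols)
  plate <- (pool - 1L) %/% wellsPerPlate + 1L
  onPlate <- (pool - 1L) %% wellsPerPlate + 1L
  assignments <- data.frame(
    family_id = familyIds,
    pool = pool,
    plate = plate,
    well = wellLabel(onPlate, plateRows, plateCols),
    position_in_pool = (seq_len(n) - 1L) %% k + 1L,
    stringsAsFactors = FALSE
  )
  methods::new("PoolingScheme", k = k, plateRows = as.integer(plateRows),
               plateCols = as.integer(plateCols), assignments = assignments)
}

#' @rdname deconvolvePools
#' @export
setGeneric("deconvolvePools", function(scheme, positives)
  standardGeneric("deconvolvePools"))

#' Resolve positive pools to candidate families
#'
#' 1D pooling resolves a positive only to its pool; the pool's member list
#' is the candidate set, each requiring individual confirmation (e.g. by
#' sequencing family DNA).
#'
#' @param scheme a \code{PoolingScheme}.
#' @param positives data.frame with columns \code{plate}, \code{well}.
#' @return data.frame: \code{plate}, \code{well}, \code{family_id},
#'   \code{requires_confirmation} (always TRUE); zero rows for an empty
#'   positive list.
#' @export
setMethod("deconvolvePools", "PoolingScheme", function(scheme, positives) {
  a <- scheme@assignments
  empty <- data.frame(plate = integer(), well = character(),
                      family_id = character(),
                      requires_confirmation = logical())
  if (is.null(positives) || !nrow(positives)) return(empty)
  out <- lapply(seq_len(nrow(positives)), function(i) {
    hit <- a[a$plate == positives$plate[i] & a$well == positives$well[i], ,
             drop = FALSE]
    if (!nrow(hit))
      stopClassed("tillingr_validation", "unknown well %s on plate %s",
                  positives$well[i], positives$plate[i])
    data.frame(plate = hit$plate, well = hit$well,
               family_id = hit$family_id, requires_confirmation = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
})

#' Read / write a plate-map CSV
#'
#' Columns: plate, well, position_in_pool, family_id.
#'
#' @param scheme a \code{PoolingScheme}; for reading, the path.
#' @param path CSV path.
#' @param k,plateRows,plateCols geometry to assume when reading.
#' @return \code{writePlateMap}: invisibly the path; \code{readPlateMap}: a
#'   \code{PoolingScheme}.
#' @export
writePlateMap <- function(scheme, path) {
  a <- scheme@assignments[, c("plate", "well", "position_in_pool",
                              "family_id")]
  utils::write.csv(a, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePlateMap
#' @export
readPlateMap <- function(path, k = 8L, plateRows = 8L, plateCols = 12L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  wellsPerPlate <- as.integer(plateRows) * as.integer(plateCols)
  rowIdx <- match(substr(tab$well, 1, 1), LETTERS)
  colIdx <- as.integer(substr(tab$well, 2, 3))
  onPlate <- (rowIdx - 1L) * as.integer(plateCols) + colIdx
  tab$pool <- (tab$plate - 1L) * wellsPerPlate + onPlate
  methods::new("PoolingScheme", k = as.integer(k),
               plateRows = as.integer(plateRows),
               plateCols = as.integer(plateCols),
               assignments = tab[, c("family_id", "pool", "plate", "well",
                                     "position_in_pool")])
}
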