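#' @import methods
NULL

TAG_LENGTH <- 26L
TAG_ANCHOR <- "CATG"

#' TagLibrary: one SuperSAGE library of unitag counts
#'
#' An S4 container for a single DeepSuperSAGE library: the unitag count
#' vector after optional singlet exclusion, together with the total
#' sequenced-tag mass \code{totalSequenced} (the library size N used for
#' normalization, counted before singlets are removed) and the number of
#' excluded singlets.
#'
#' @slot libraryId character(1), e.g. "ET0" or "BT1.6".
#' @slot accession character(1), \code{"tolerant"} or \code{"sensitive"}.
#' @slot condition character(1), \code{"control"} or \code{"stress_bulk"}.
#' @slot counts named integer vector; names are 26-bp CATG-anchored unitag
#'   sequences, values are per-library counts (all >= 2 after singlet
#'   exclusion).
#' @slot totalSequenced integer(1), total tags sequenced before exclusion.
#' @slot singletsExcluded integer(1), number of singlet tags removed.
#'
#' @seealso [buildLibrary()] for the constructor used in practice.
#' @export
setClass("TagLibrary",
  representation(
    libraryId        = "character",
    accession        = "character",
    condition        = "character",
    counts           = "integer",
    totalSequenced   = "integer",
    singletsExcluded = "integer"
  )
)

setValidity("TagLibrary", function(object) {
  msg <- character()
  if (length(object@libraryId) != 1L || !nzchar(object@libraryId))
    msg <- c(msg, "libraryId must be a single non-empty string")
  if (length(object@totalSequenced) != 1L || is.na(object@totalSequenced) ||
      object@totalSequenced <= 0L)
    msg <- c(msg, "totalSequenced must be a single positive integer")
  cnt <- object@counts
  if (length(cnt)) {
    if (is.null(names(cnt)) || anyNA(names(cnt)))
      msg <- c(msg, "counts must be named by tag sequence")
    else {
      bad <- !isValidTag(names(cnt))
      if (any(bad))
        msg <- c(msg, sprintf("invalid tag sequence(s): %s",
                              paste(utils::head(names(cnt)[bad], 3L),
                                    collapse = ", ")))
    }
    if (any(cnt < 1L)) msg <- c(msg, "counts must be >= 1")
  }
  if (sum(as.numeric(cnt)) + object@singletsExcluded > object@totalSequenced)
    msg <- c(msg, "sum(counts) + singletsExcluded exceeds totalSequenced")
  if (length(msg)) msg else TRUE
})

#' @describeIn TagLibrary compact display
#' @param object a \code{TagLibrary}
#' @export
setMethod("show", "TagLibrary", function(object) {
  cat(sprintf("TagLibrary '%s' (%s, %s)\n", object@libraryId,
              object@accession, object@condition))
  cat(sprintf("  %d unitags; %s tags sequenced; %d singlets excluded\n",
              length(object@counts),
              format(object@totalSequenced, big.mark = ","),
              object@singletsExcluded))
})

#' @rdname TagLibrary-accessors
#' @name TagLibrary-accessors
#' @title Accessors for TagLibrary objects
#' @param x a \code{TagLibrary}
#' @return \code{libraryId}, \code{accession}, \code{condition}: character(1).
#'   \code{tagCounts}: named integer vector of unitag counts.
#'   \code{totalSequenced}, \code{singletsExcluded}: integer(1).
#' @examples
#' lib <- buildLibrary(rep(paste0("CATG", strrep("A", 22)), 3), "demo")
#' libraryId(lib)
#' tagCounts(lib)
#' totalSequenced(lib)
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname TagLibrary-accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname TagLibrary-accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname TagLibrary-accessors
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))
#' @rdname TagLibrary-accessors
#' @export
setGeneric("totalSequenced", function(x) standardGeneric("totalSequenced"))
#' @rdname TagLibrary-accessors
#' @export
setGeneric("singletsExcluded", function(x) standardGeneric("singletsExcluded"))

#' @rdname TagLibrary-accessors
#' @export
setMethod("libraryId", "TagLibrary", function(x) x@libraryId)
#' @rdname TagLibrary-accessors
#' @export
setMethod("accession", "TagLibrary", function(x) x@accession)
#' @rdname TagLibrary-accessors
#' @export
setMethod("condition", "TagLibrary", function(x) x@condition)
#' @rdname TagLibrary-accessors
#' @export
setMethod("tagCounts", "TagLibrary", function(x) x@counts)
#' @rdname TagLibrary-accessors
#' @export
setMethod("totalSequenced", "TagLibrary", function(x) x@totalSequenced)
#' @rdname TagLibrary-accessors
#' @export
setMethod("singletsExcluded", "TagLibrary", function(x) x@singletsExcluded)

#' Validate 26-bp CATG-anchored tag sequences
#'
#' A valid unitag is exactly 26 characters over \{A,C,G,T\} and starts with
#' the CATG restriction-site anchor.
#'
#' @param tags character vector of candidate tag sequences.
#' @return logical vector, one element per input.
#' @examples
#' isValidTag(c(paste0("CATG", strrep("A", 22)), "CATGAAA"))
#' @export
isValidTag <- function(tags) {
  !is.na(tags) &
    nchar(tags) == TAG_LENGTH &
    grepl("^CATG[ACGT]{22}$", tags)
}
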