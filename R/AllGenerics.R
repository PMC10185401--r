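#' @rdname accessors
#' @export
setGeneric("busHeader", function(x) standardGeneric("busHeader"))

#' @rdname accessors
#' @export
setGeneric("busRecords", function(x) standardGeneric("busRecords"))

#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname accessors
#' @export
setGeneric("bcLength", function(x) standardGeneric("bcLength"))

#' @rdname accessors
#' @export
setGeneric("umiLength", function(x) standardGeneric("umiLength"))

#' @rdname sortBus
#' @export
setGeneric("sortBus", function(x) standardGeneric("sortBus"))

#' @rdname writeBus
#' @export
setGeneric("writeBus", function(x, path) standardGeneric("writeBus"))

#' Accessors for BusData and BusHeader
#'
#' \code{busHeader} returns the \code{\linkS4class{BusHeader}};
#' \code{busRecords} the record \code{\link[S4Vectors]{DataFrame}};
#' \code{nRecords} the record count; \code{bcLength}/\code{umiLength} the
#' barcode/UMI lengths in nucleotides.
#'
#' @param x a \code{\linkS4class{BusData}} (or \code{BusHeader} for the
#'   length accessors).
#' @return See the individual descriptions.
#' @examples
#' x <- simulateBus(nCells = 3, meanUmisPerCell = 4, seed = 7)
#' nRecords(x)
#' bcLength(x)
#' head(busRecords(x))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("busHeader", "BusData", function(x) x@header)

#' @rdname accessors
#' @export
setMethod("busRecords", "BusData", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("nRecords", "BusData", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setMethod("bcLength", "BusHeader", function(x) x@bcLen)

#' @rdname accessors
#' @export
setMethod("bcLength", "BusData", function(x) x@header@bcLen)

#' @rdname accessors
#' @export
setMethod("umiLength", "BusHeader", function(x) x@umiLen)

#' @rdname accessors
#' @export
setMethod("umiLength", "BusData", function(x) x@header@umiLen)
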