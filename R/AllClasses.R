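#' BusHeader: metadata of a BUS file
#'
#' Header of a BUS file: format version, the nucleotide lengths of the
#' barcode and UMI (each between 1 and 32, so that the 2-bit encoding fits
#' an unsigned 64-bit integer), and a free-text field.
#'
#' @slot version integer(1), format version (1 for BUS v1).
#' @slot bcLen integer(1), barcode length in nucleotides, 1..32.
#' @slot umiLen integer(1), UMI length in nucleotides, 1..32.
#' @slot text character(1), free text carried in the header.
#'
#' @examples
#' BusHeader(bcLen = 16, umiLen = 12)
#' @export
setClass("BusHeader",
  representation(
    version = "integer",
    bcLen = "integer",
    umiLen = "integer",
    text = "character"
  ),
  prototype(version = 1L, bcLen = 16L, umiLen = 12L, text = "")
)

setValidity("BusHeader", function(object) {
  msg <- character()
  if (length(object@bcLen) != 1L || is.na(object@bcLen) ||
      object@bcLen < 1L || object@bcLen > 32L) {
    msg <- c(msg, "bcLen must be a single integer in 1..32")
  }
  if (length(object@umiLen) != 1L || is.na(object@umiLen) ||
      object@umiLen < 1L || object@umiLen > 32L) {
    msg <- c(msg, "umiLen must be a single integer in 1..32")
  }
  if (length(object@version) != 1L || is.na(object@version) ||
      object@version < 0L) {
    msg <- c(msg, "version must be a single non-negative integer")
  }
  if (length(object@text) != 1L || is.na(object@text)) {
    msg <- c(msg, "text must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' @param bcLen,umiLen barcode/UMI lengths in nucleotides (1..32).
#' @param version format version.
#' @param text free text stored in the header.
#' @rdname BusHeader-class
#' @export
BusHeader <- function(bcLen, umiLen, version = 1L, text = "") {
  new("BusHeader",
    version = as.integer(version), bcLen = as.integer(bcLen),
    umiLen = as.integer(umiLen), text = as.character(text)
  )
}

#' BusData: an in-memory BUS file
#'
#' Container for the records of a BUS file together with its header.
#' Barcodes and UMIs are held as nucleotide strings (the bijective image of
#' their 2-bit 64-bit-integer codes, so no precision is lost for sequences
#' up to 32 nt); equivalence-class ids, counts and flags are held as
#' doubles, which represent the full 32-bit field ranges exactly.
#'
#' @slot header a \code{\linkS4class{BusHeader}}.
#' @slot records a \code{\link[S4Vectors]{DataFrame}} with columns
#'   \code{barcode}, \code{umi} (character), \code{ec}, \code{count},
#'   \code{flags} (numeric).
#'
#' @examples
#' x <- BusData(
#'   barcode = c("AACG", "AACG"), umi = c("TT", "TG"),
#'   ec = c(0, 3), count = c(1, 2), flags = c(0, 0)
#' )
#' x
#' nRecords(x)
#' @export
setClass("BusData",
  representation(header = "BusHeader", records = "DataFrame")
)

setValidity("BusData", function(object) {
  rec <- object@records
  need <- c("barcode", "umi", "ec", "count", "flags")
  if (!all(need %in% colnames(rec))) {
    return(paste(
      "records must have columns",
      paste(need, collapse = ", ")
    ))
  }
  msg <- character()
  h <- object@header
  if (nrow(rec) > 0L) {
    if (!is.character(rec$barcode) ||
        !all(nchar(rec$barcode) == h@bcLen)) {
      msg <- c(msg, sprintf("all barcodes must be %d-nt strings", h@bcLen))
    }
    if (!is.character(rec$umi) || !all(nchar(rec$umi) == h@umiLen)) {
      msg <- c(msg, sprintf("all UMIs must be %d-nt strings", h@umiLen))
    }
    if (any(grepl("[^ACGT]", rec$barcode)) || any(grepl("[^ACGT]", rec$umi))) {
      msg <- c(msg, "barcodes and UMIs may contain only A, C, G, T")
    }
    for (col in c("ec", "count", "flags")) {
      v <- rec[[col]]
      if (!is.numeric(v) || any(!is.finite(v)) || any(v != floor(v))) {
        msg <- c(msg, sprintf("%s must be finite whole numbers", col))
      }
    }
    if (is.numeric(rec$ec) &&
        any(rec$ec < -2^31 | rec$ec >= 2^31, na.rm = TRUE)) {
      msg <- c(msg, "ec must fit a signed 32-bit integer")
    }
    for (col in c("count", "flags")) {
      v <- rec[[col]]
      if (is.numeric(v) && any(v < 0 | v >= 2^32, na.rm = TRUE)) {
        msg <- c(msg, sprintf("%s must fit an unsigned 32-bit integer", col))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param barcode,umi character vectors of nucleotide sequences.
#' @param ec,count,flags numeric vectors (whole numbers).
#' @param bcLen,umiLen sequence lengths; default taken from the first
#'   barcode/UMI.
#' @param version,text header fields.
#' @rdname BusData-class
#' @export
BusData <- function(barcode = character(), umi = character(), ec = numeric(),
                    count = numeric(), flags = numeric(),
                    bcLen = NULL, umiLen = NULL, version = 1L, text = "") {
  if (is.null(bcLen)) {
    bcLen <- if (length(barcode)) nchar(barcode[[1L]]) else 16L
  }
  if (is.null(umiLen)) {
    umiLen <- if (length(umi)) nchar(umi[[1L]]) else 12L
  }
  new("BusData",
    header = BusHeader(bcLen, umiLen, version = version, text = text),
    records = S4Vectors::DataFrame(
      barcode = as.character(barcode), umi = as.character(umi),
      ec = as.numeric(ec), count = as.numeric(count),
      flags = as.numeric(flags)
    )
  )
}

setMethod("show", "BusHeader", function(object) {
  cat(sprintf(
    "BusHeader (v%d): barcode %d nt, UMI %d nt%s\n",
    object@version, object@bcLen, object@umiLen,
    if (nzchar(object@text)) sprintf(", text \"%s\"", object@text) else ""
  ))
})

setMethod("show", "BusData", function(object) {
  cat(sprintf(
    "BusData with %d records (barcode %d nt, UMI %d nt)\n",
    nrow(object@records), object@header@bcLen, object@header@umiLen
  ))
  if (nrow(object@records) > 0L) {
    show(utils::head(object@records, 5L))
    if (nrow(object@records) > 5L) {
      cat(sprintf("... and %d more records\n", nrow(object@records) - 5L))
    }
  }
})

#' @describeIn BusData-class number of records.
#' @param x a \code{BusData}.
#' @export
setMethod("length", "BusData", function(x) nrow(x@records))

#' @describeIn BusData-class subset records by index, keeping the header.
#' @param i record indices.
#' @param j,drop,... ignored (records are always whole rows).
#' @export
setMethod("[", "BusData", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE])
})
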