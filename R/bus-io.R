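#' 2-bit nucleotide codec
#'
#' Barcodes and UMIs are 2-bit encoded (A=00, C=01, G=10, T=11, leftmost
#' base most significant) so that sequences of up to 32 nt fit an unsigned
#' 64-bit integer.  \code{encodeSequence} maps sequences to their integer
#' codes; \code{decodeSequence} inverts it given the sequence length.
#'
#' R numerics represent integers exactly only up to 2^53 (sequences of up
#' to 26 nt); \code{encodeSequence} warns when a code exceeds that bound,
#' and \code{decodeSequence} rejects such codes.  The file-level pipeline
#' (\code{\link{buszCompress}} and friends) works on native 64-bit integers
#' throughout and has no such limit.
#'
#' @param seq character vector of sequences over A/C/G/T, each 1..32 nt.
#' @param code numeric vector of non-negative integer codes, each
#'   \code{< 4^length}.
#' @param length sequence length in nucleotides, 1..32.
#' @return \code{encodeSequence}: a numeric vector of codes.
#'   \code{decodeSequence}: a character vector of sequences.
#' @examples
#' encodeSequence("ACGT") # 27
#' decodeSequence(27, 4) # "ACGT"
#' @export
encodeSequence <- function(seq) {
  wrapBuszErrors(cpp_encode_sequence(as.character(seq)))
}

#' @rdname encodeSequence
#' @export
decodeSequence <- function(code, length) {
  wrapBuszErrors(cpp_decode_sequence(as.numeric(code), as.integer(length)))
}

#' Read a plain BUS file
#'
#' Parses the BUS header (magic \code{"BUS\\0"}, version, barcode/UMI
#' lengths, free text, all little-endian) and the fixed 32-byte records
#' that follow (u64 barcode, u64 umi, i32 ec, u32 count, u32 flags, u32
#' padding).  A payload that is not a multiple of 32 bytes raises a
#' truncation error.  Nonzero padding bytes are tolerated on read; a
#' warning reports how many records carry them.
#'
#' @param path path to a BUS file.
#' @return a \code{\linkS4class{BusData}}.
#' @seealso \code{\link{writeBus}}, \code{\link{sortBus}}
#' @examples
#' x <- simulateBus(nCells = 3, meanUmisPerCell = 4, seed = 7)
#' f <- tempfile(fileext = ".bus")
#' writeBus(x, f)
#' y <- readBus(f)
#' identical(busRecords(x), busRecords(y))
#' @export
readBus <- function(path) {
  res <- wrapBuszErrors(cpp_read_bus(path.expand(path)))
  if (res$nonzeroPadding > 0) {
    warning(sprintf(
      "%d record(s) carry nonzero padding bytes; padding is not preserved",
      res$nonzeroPadding
    ))
  }
  new("BusData",
    header = BusHeader(res$bcLen, res$umiLen,
      version = res$version, text = res$text
    ),
    records = S4Vectors::DataFrame(
      barcode = res$records$barcode, umi = res$records$umi,
      ec = res$records$ec, count = res$records$count,
      flags = res$records$flags
    )
  )
}

#' Write a plain BUS file
#'
#' Serializes a \code{\linkS4class{BusData}} to the binary BUS layout:
#' header, then one 32-byte little-endian record per row with the padding
#' field written as zero.
#'
#' @param x a \code{\linkS4class{BusData}}.
#' @param path output path.
#' @return (invisibly) the number of bytes written, which always equals
#'   header size + 32 x number of records.
#' @rdname writeBus
#' @export
setMethod("writeBus", "BusData", function(x, path) {
  validObject(x)
  h <- x@header
  r <- x@records
  n <- wrapBuszErrors(cpp_write_bus(
    path.expand(path), h@version, h@bcLen, h@umiLen, h@text,
    r$barcode, r$umi, r$ec, r$count, r$flags
  ))
  invisible(n)
})

#' Sort and merge BUS records
#'
#' Sorts records lexicographically by (barcode, UMI, EC) -- the order the
#' compressor requires -- and merges records that share all three key
#' fields, summing their counts and OR-ing their flags.  The merge is the
#' first level of compression for sorted files: identical molecules
#' observed in several records collapse to one.  The operation is
#' idempotent and conserves the total count.
#'
#' @param x a \code{\linkS4class{BusData}} (any order, duplicates allowed).
#' @return a \code{\linkS4class{BusData}} whose records are strictly
#'   increasing in the (barcode, UMI, EC) key.
#' @examples
#' x <- BusData(
#'   barcode = c("CC", "AA", "AA"), umi = c("G", "T", "T"),
#'   ec = c(0, 2, 2), count = c(1, 1, 3), flags = c(0, 1, 4)
#' )
#' busRecords(sortBus(x)) # AA/T/2 merged: count 4, flags 5
#' @rdname sortBus
#' @export
setMethod("sortBus", "BusData", function(x) {
  validObject(x)
  r <- x@records
  res <- wrapBuszErrors(cpp_sort_merge(
    r$barcode, r$umi, r$ec, r$count, r$flags,
    x@header@bcLen, x@header@umiLen
  ))
  initialize(x, records = S4Vectors::DataFrame(
    barcode = res$barcode, umi = res$umi, ec = res$ec,
    count = res$count, flags = res$flags
  ))
})
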