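#' Compress or decompress a single block of records
#'
#' A BUSZ block holds up to \code{blockSize} sorted records; its payload is
#' the concatenation of five independently compressed, byte-aligned column
#' payloads (barcode, UMI, EC, count, flags -- the padding column is not
#' stored), each prefixed with a little-endian u32 byte count.  Barcode
#' deltas and UMI modified deltas are FRLE0-coded, ECs NewPFD-coded, counts
#' FRLE1-coded and flags FRLE0-coded.  These functions expose one block for
#' testing and inspection; whole files go through
#' \code{\link{buszCompress}}.
#'
#' @param x a \code{\linkS4class{BusData}} sorted by (barcode, UMI, EC)
#'   with ECs \code{>= 0} and counts \code{>= 1}; must be non-empty.
#' @param payload a raw vector produced by \code{compressBlock}.
#' @param n the number of records in the block.
#' @param bcLen,umiLen sequence lengths used to render the decoded
#'   barcodes/UMIs.
#' @param nPfd,f NewPFD parameters (must match between the two calls).
#' @return \code{compressBlock}: a raw vector. \code{decompressBlock}: a
#'   \code{\linkS4class{BusData}} with the records restored exactly
#'   (padding is implicitly zero).
#' @examples
#' x <- sortBus(simulateBus(nCells = 4, meanUmisPerCell = 10, seed = 1))
#' p <- compressBlock(x)
#' y <- decompressBlock(p, nRecords(x), bcLength(x), umiLength(x))
#' identical(busRecords(x), busRecords(y))
#' @export
compressBlock <- function(x, nPfd = 512, f = 0.9) {
  validObject(x)
  r <- busRecords(x)
  wrapBuszErrors(cpp_compress_block(
    r$barcode, r$umi, r$ec, r$count, r$flags,
    bcLength(x), umiLength(x), nPfd, f
  ))
}

#' @rdname compressBlock
#' @export
decompressBlock <- function(payload, n, bcLen, umiLen, nPfd = 512, f = 0.9) {
  res <- wrapBuszErrors(
    cpp_decompress_block(payload, n, bcLen, umiLen, nPfd, f)
  )
  BusData(
    barcode = res$barcode, umi = res$umi, ec = res$ec,
    count = res$count, flags = res$flags, bcLen = bcLen, umiLen = umiLen
  )
}

#' Compress a sorted BUS file to BUSZ
#'
#' Streams a sorted BUS file into the BUSZ container: a file header (magic
#' \code{"BUSZ0001"}, the copied BUS header fields, and the compression
#' parameters), then per block of \code{blockSize} records a block header
#' (record count and compressed payload size, both u32) followed by the
#' compressed payload, and finally an all-zero terminator block header.
#' Input order is verified while streaming; an out-of-order record raises a
#' sortedness error naming its index (the compressor never sorts -- run
#' \code{\link{sortBus}} first).  With \code{index = TRUE} a sibling index
#' file (magic \code{"BUSZIDX1"}; one (first barcode u64, payload bytes
#' u64) entry per block) is written for \code{\link{buszLookup}}.
#'
#' Records with nonzero padding bytes are accepted, but padding is restored
#' as zero on decompression; a warning reports how many records were
#' affected.
#'
#' @param input path to a sorted BUS file.
#' @param output path of the BUSZ file to write.
#' @param blockSize records per block (default 10000).
#' @param nPfd NewPFD sub-block size (default 512).
#' @param f NewPFD in-range fraction (default 0.9); stored in the header as
#'   parts per thousand.
#' @param index write the barcode index file alongside the output.
#' @param indexPath path of the index file (default \code{output + ".idx"}).
#' @return (invisibly) a list: \code{records}, \code{blocks},
#'   \code{bytesIn}, \code{bytesOut}, and \code{ratio} (uncompressed size /
#'   compressed size).
#' @seealso \code{\link{buszDecompress}}, \code{\link{buszLookup}},
#'   \code{\link{buszInspect}}
#' @examples
#' x <- simulateBus(nCells = 20, meanUmisPerCell = 50, seed = 11)
#' bus <- tempfile(fileext = ".bus")
#' busz <- tempfile(fileext = ".busz")
#' writeBus(x, bus)
#' s <- buszCompress(bus, busz, index = TRUE)
#' s$ratio > 1
#' @export
buszCompress <- function(input, output, blockSize = 10000, nPfd = 512,
                         f = 0.9, index = FALSE,
                         indexPath = paste0(output, ".idx")) {
  res <- wrapBuszErrors(cpp_compress_file(
    path.expand(input), path.expand(output),
    blockSize, nPfd, f, isTRUE(index), path.expand(indexPath)
  ))
  if (res$nonzeroPadding > 0) {
    warning(sprintf(
      "%d record(s) carry nonzero padding; padding will decompress as zero",
      res$nonzeroPadding
    ))
  }
  invisible(res[c("records", "blocks", "bytesIn", "bytesOut", "ratio")])
}

#' Decompress a BUSZ file back to plain BUS
#'
#' Reads the BUSZ container written by \code{\link{buszCompress}} and
#' restores the plain BUS file.  For any input produced from a sorted BUS
#' file with zeroed padding the output is byte-identical to that input.  A
#' plain BUS file raises a format error ("not a BUSZ file"); a stream that
#' ends mid-block raises a corruption error naming the block.
#'
#' @param input path to a BUSZ file.
#' @param output path of the BUS file to write.
#' @return (invisibly) a list: \code{records}, \code{blocks},
#'   \code{bytesIn}, \code{bytesOut}.
#' @export
buszDecompress <- function(input, output) {
  invisible(wrapBuszErrors(
    cpp_decompress_file(path.expand(input), path.expand(output))
  ))
}

#' Random access by barcode in a BUSZ file
#'
#' Retrieves all records of one barcode without decompressing the whole
#' file, using the index written by \code{buszCompress(..., index = TRUE)}:
#' block offsets are reconstructed from the cumulative index sizes, the
#' candidate blocks are the last block starting strictly below the query
#' plus every block starting exactly at it (a barcode's records may
#' straddle block boundaries), and only those blocks are decompressed.
#' Index/file disagreement (sizes or totals) raises an integrity error.
#'
#' @param input path to a BUSZ file.
#' @param barcode the query barcode as a nucleotide string of the file's
#'   barcode length.
#' @param indexPath path to the index file (default
#'   \code{input + ".idx"}).
#' @return a \code{\link[S4Vectors]{DataFrame}} of the matching records
#'   (possibly zero rows), identical to filtering the fully decompressed
#'   file.
#' @export
buszLookup <- function(input, barcode, indexPath = paste0(input, ".idx")) {
  if (!file.exists(indexPath)) {
    stop(structure(
      class = c("buszFormatError", "buszError", "error", "condition"),
      list(
        message = sprintf(
          "format: index file '%s' not found; re-compress with index = TRUE",
          indexPath
        ),
        call = sys.call()
      )
    ))
  }
  res <- wrapBuszErrors(cpp_lookup_barcode(
    path.expand(input), path.expand(indexPath), as.character(barcode)
  ))
  S4Vectors::DataFrame(
    barcode = res$barcode, umi = res$umi, ec = res$ec,
    count = res$count, flags = res$flags
  )
}

#' Inspect a BUS or BUSZ file
#'
#' Reports the header fields and, for BUSZ input, the compression
#' parameters, block and record counts and the total compressed bytes per
#' column; for BUS input, the record count (payload bytes / 32).
#'
#' @param path path to a BUS or BUSZ file.
#' @return a list with at least \code{type} ("bus" or "busz"),
#'   \code{version}, \code{bcLen}, \code{umiLen}, \code{text},
#'   \code{records} and \code{bytes}; BUSZ input adds \code{blockSize},
#'   \code{nPfd}, \code{f}, \code{blocks} and \code{columnBytes}.
#' @export
buszInspect <- function(path) {
  wrapBuszErrors(cpp_inspect(path.expand(path)))
}
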