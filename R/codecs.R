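#' Fibonacci universal coding
#'
#' Encodes positive integers by their Zeckendorf representation over the
#' Fibonacci numbers F1 = 1, F2 = 2, F3 = 3, F4 = 5, ...: the indicator
#' bits are emitted lowest index first and terminated by an extra 1 bit, so
#' every codeword ends in "11" and contains no other adjacent pair of 1s.
#' The code is prefix-free and needs no explicit length, which is why all
#' variable-length quantities in the BUSZ format (run lengths, deltas,
#' NewPFD headers and exception values) use it.  Zero is not encodable;
#' codecs that can see zeros add 1 before encoding.
#'
#' @param n numeric vector of positive integers (each \code{<= 2^53} for
#'   this numeric API; the internal pipeline encodes up to 2^64).
#' @param bits a bit buffer as returned by the encoder: a list with
#'   \code{bytes} (raw vector, MSB-first bits) and \code{nbits}.
#' @param count how many codewords to decode; \code{NULL} decodes until the
#'   buffer is exhausted (the buffer must then end exactly on a codeword).
#' @return \code{fibonacciEncode}: a bit buffer (list of \code{bytes} and
#'   \code{nbits}) holding the concatenated codewords.
#'   \code{fibonacciDecode}: the decoded numeric vector.
#' @examples
#' b <- fibonacciEncode(c(1, 4, 11))
#' fibonacciDecode(b) # 1 4 11
#' @export
fibonacciEncode <- function(n) {
  wrapBuszErrors(cpp_fib_encode(as.numeric(n)))
}

#' @rdname fibonacciEncode
#' @export
fibonacciDecode <- function(bits, count = NULL) {
  n <- if (is.null(count)) -1 else as.numeric(count)
  wrapBuszErrors(cpp_fib_decode(bits$bytes, bits$nbits, n))
}

#' Fixed-width bit packing
#'
#' Writes unsigned integers into a bit buffer MSB-first at the given widths
#' (the slot writer used by the NewPFD codec), and reads them back.  A
#' width of 0 writes and reads nothing.
#'
#' @param values numeric vector of non-negative integers.
#' @param widths integer vector of bit widths (0..64), recycled to
#'   \code{length(values)} when packing.
#' @param align if \code{TRUE}, pad the buffer with zero bits to the next
#'   byte boundary after packing.
#' @param bits a bit buffer (list of \code{bytes} and \code{nbits}).
#' @return \code{bitPack}: a bit buffer. \code{bitUnpack}: numeric vector of
#'   the values read at \code{widths}.
#' @examples
#' b <- bitPack(c(5, 1), c(3, 1))
#' b$nbits # 4
#' bitUnpack(b, c(3, 1)) # 5 1
#' @export
bitPack <- function(values, widths, align = FALSE) {
  widths <- rep_len(as.integer(widths), length(values))
  wrapBuszErrors(cpp_pack_bits(as.numeric(values), widths, isTRUE(align)))
}

#' @rdname bitPack
#' @export
bitUnpack <- function(bits, widths) {
  wrapBuszErrors(cpp_unpack_bits(bits$bytes, bits$nbits, as.integer(widths)))
}

#' Run-length token streams for zeros or ones
#'
#' RLE0 collapses each maximal run of zeros into a single (marker, length)
#' token and passes every other value through as a literal; RLE1 does the
#' same for runs of ones (and requires strictly positive input).  A run of
#' length 1 is still a token, so decoding needs no lookahead.
#'
#' @param values numeric vector; for \code{target = 1} all values must be
#'   \code{>= 1}.
#' @param target 0 or 1: which value is run-length collapsed.
#' @param tokens a token data.frame as returned by \code{rleEncode}.
#' @return \code{rleEncode}: a data.frame with columns \code{value},
#'   \code{length} and \code{run} (logical; \code{TRUE} rows are runs of
#'   \code{target}, literal rows have length 1).  \code{rleDecode}: the
#'   original numeric vector.
#' @examples
#' rleEncode(c(5, 0, 0, 0, 2), 0) # literal 5, run of 3 zeros, literal 2
#' @export
rleEncode <- function(values, target) {
  if (!(length(target) == 1L && target %in% c(0, 1))) {
    stop(structure(
      class = c("buszDomainError", "buszError", "error", "condition"),
      list(message = "domain: RLE target must be 0 or 1", call = sys.call())
    ))
  }
  values <- as.numeric(values)
  if (target == 1 && any(values < 1)) {
    stop(structure(
      class = c("buszDomainError", "buszError", "error", "condition"),
      list(
        message = "domain: RLE1 requires strictly positive values",
        call = sys.call()
      )
    ))
  }
  if (!length(values)) {
    return(data.frame(
      value = numeric(), length = numeric(), run = logical()
    ))
  }
  r <- rle(values)
  parts <- mapply(function(v, l) {
    if (v == target) {
      data.frame(value = v, length = l, run = TRUE)
    } else {
      data.frame(value = rep(v, l), length = rep(1, l), run = FALSE)
    }
  }, r$values, r$lengths, SIMPLIFY = FALSE)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @rdname rleEncode
#' @export
rleDecode <- function(tokens) {
  if (!nrow(tokens)) {
    return(numeric())
  }
  rep(tokens$value, tokens$length)
}

#' Fibonacci run-length codecs (FRLE0 / FRLE1)
#'
#' FRLE0 is the Fibonacci encoding of the RLE0 token stream: because the
#' Fibonacci code cannot represent zero, literal values v are written as
#' fib(v + 1), and a run of L zeros as the marker fib(1) followed by
#' fib(L) (run lengths are already \code{>= 1} and need no increment).
#' FRLE1 encodes strictly positive values: literals v != 1 as fib(v), runs
#' of L ones as fib(1) then fib(L).  These are the codecs for the barcode
#' deltas, UMI deltas and flags columns (FRLE0) and the count column
#' (FRLE1).
#'
#' @param values numeric vector: non-negative for FRLE0, strictly positive
#'   for FRLE1.
#' @param bits a bit buffer (list of \code{bytes} and \code{nbits}).
#' @param count number of values to decode.
#' @return Encoders return a bit buffer; decoders the numeric vector of
#'   \code{count} values.
#' @examples
#' b <- frle0Encode(c(5, 0, 0, 0, 2))
#' frle0Decode(b, 5)
#' @export
frle0Encode <- function(values) {
  wrapBuszErrors(cpp_frle0_encode(as.numeric(values)))
}

#' @rdname frle0Encode
#' @export
frle0Decode <- function(bits, count) {
  wrapBuszErrors(cpp_frle0_decode(bits$bytes, bits$nbits, as.numeric(count)))
}

#' @rdname frle0Encode
#' @export
frle1Encode <- function(values) {
  wrapBuszErrors(cpp_frle1_encode(as.numeric(values)))
}

#' @rdname frle0Encode
#' @export
frle1Decode <- function(bits, count) {
  wrapBuszErrors(cpp_frle1_decode(bits$bytes, bits$nbits, as.numeric(count)))
}

#' Delta coding of the barcode and UMI columns
#'
#' \code{deltaBarcodes} turns a non-decreasing barcode column into
#' non-negative differences; the first element is kept raw (a delta from an
#' implicit 0) so each block decompresses independently.
#' \code{deltaUmis} differences UMIs only between adjacent records of the
#' same cell; at a barcode change (and for the first record) the raw UMI
#' value is kept.  \code{undeltaBarcodes} / \code{undeltaUmis} invert the
#' two transforms.
#'
#' @param barcodes,umis numeric vectors of 2-bit codes (see
#'   \code{\link{encodeSequence}}); sorted as the compressor requires.
#' @param deltas numeric vector of differences.
#' @return numeric vectors of deltas (forward) or reconstructed values
#'   (inverse).
#' @examples
#' deltaBarcodes(c(7, 7, 7, 9)) # 7 0 0 2
#' deltaUmis(c(4, 6, 6, 2), c(1, 1, 1, 2)) # 4 2 0 2
#' @export
deltaBarcodes <- function(barcodes) {
  wrapBuszErrors(cpp_delta_barcodes(as.numeric(barcodes)))
}

#' @rdname deltaBarcodes
#' @export
undeltaBarcodes <- function(deltas) {
  wrapBuszErrors(cpp_undelta_barcodes(as.numeric(deltas)))
}

#' @rdname deltaBarcodes
#' @export
deltaUmis <- function(umis, barcodes) {
  wrapBuszErrors(cpp_delta_umis(as.numeric(umis), as.numeric(barcodes)))
}

#' @rdname deltaBarcodes
#' @export
undeltaUmis <- function(deltas, barcodes) {
  wrapBuszErrors(cpp_undelta_umis(as.numeric(deltas), as.numeric(barcodes)))
}

#' NewPFD codec for the equivalence-class column
#'
#' A patched frame-of-reference codec: the value list is split into
#' sub-blocks of \code{nPfd} consecutive values; within each sub-block the
#' base k is the sub-block minimum, and the slot width b is the smallest
#' number of bits such that at least \code{ceiling(f * m)} of the m offsets
#' (x - k) fit in b bits (b is capped at 32).  Offsets needing more than b
#' bits are exceptions: their low b bits stay in the fixed-width slots and
#' the remaining high bits are Fibonacci coded.  Each sub-block is written
#' as fib(b+1), fib(k+1), fib(#exceptions+1), then one (position-gap + 1,
#' high-bits) Fibonacci pair per exception, then the m b-bit slots.
#'
#' @param values numeric vector of non-negative integers.
#' @param nPfd sub-block size (default 512).
#' @param f in-range fraction in (0, 1] (default 0.9).
#' @param bits a bit buffer (list of \code{bytes} and \code{nbits}).
#' @param count number of values to decode.
#' @return \code{newpfdEncode}: a bit buffer with an additional
#'   \code{plan} data.frame (one row per sub-block: \code{k}, \code{b},
#'   \code{nValues}, \code{nExceptions}) for audits.
#'   \code{newpfdDecode}: the numeric vector of \code{count} values.
#' @examples
#' b <- newpfdEncode(c(7, 5, 6, 300, 5, 5, 6, 7), nPfd = 8, f = 0.75)
#' b$plan # k = 5, b = 2, one exception
#' newpfdDecode(b, 8, nPfd = 8)
#' @export
newpfdEncode <- function(values, nPfd = 512, f = 0.9) {
  wrapBuszErrors(cpp_newpfd_encode(as.numeric(values), nPfd, f))
}

#' @rdname newpfdEncode
#' @export
newpfdDecode <- function(bits, count, nPfd = 512) {
  wrapBuszErrors(
    cpp_newpfd_decode(bits$bytes, bits$nbits, as.numeric(count), nPfd)
  )
}
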