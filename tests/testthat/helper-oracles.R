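# Independent oracles and bit-level helpers.  Everything here is written
# naively and separately from the package's C++ codecs so the two
# implementations can be compared bit for bit.

# render a bit buffer (raw bytes + nbits, MSB-first) as a "0101..." string
bitString <- function(bits) {
  if (bits$nbits == 0) {
    return("")
  }
  v <- as.integer(rawToBits(bits$bytes)) # LSB-first within each byte
  m <- matrix(v, nrow = 8)
  msb <- as.vector(m[8:1, , drop = FALSE])
  paste(msb[seq_len(bits$nbits)], collapse = "")
}

stringToBitBuffer <- function(s) {
  v <- as.integer(strsplit(s, "")[[1]])
  pad <- c(v, rep(0L, (8 - length(v) %% 8) %% 8))
  m <- matrix(pad, nrow = 8)
  lsb <- as.vector(m[8:1, , drop = FALSE])
  list(bytes = packBits(as.raw(lsb), "raw"), nbits = length(v))
}

# greedy Zeckendorf oracle: Fibonacci codeword of n as a bit string,
# lowest-index bit first, "1" terminator appended
fibWords <- local({
  f <- c(1, 2)
  while (f[length(f)] < 2^53) f <- c(f, f[length(f)] + f[length(f) - 1])
  f
})

fibOracle <- function(n) {
  stopifnot(n >= 1)
  hi <- max(which(fibWords <= n))
  bits <- integer(hi)
  rem <- n
  for (i in hi:1) {
    if (fibWords[i] <= rem) {
      bits[i] <- 1L
      rem <- rem - fibWords[i]
    }
  }
  paste(c(bits, 1L), collapse = "")
}

# direct run-scanning oracle for RLE0/RLE1 token streams
rleOracle <- function(values, target) {
  out <- list()
  i <- 1
  while (i <= length(values)) {
    if (values[i] == target) {
      j <- i
      while (j <= length(values) && values[j] == target) j <- j + 1
      out[[length(out) + 1]] <-
        data.frame(value = target, length = j - i, run = TRUE)
      i <- j
    } else {
      out[[length(out) + 1]] <-
        data.frame(value = values[i], length = 1, run = FALSE)
      i <- i + 1
    }
  }
  if (!length(out)) {
    return(data.frame(value = numeric(), length = numeric(), run = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

bitWidthOracle <- function(x) {
  b <- 0
  while (x > 0) {
    x <- x %/% 2
    b <- b + 1
  }
  b
}

# naive bit-level NewPFD encoder: same documented layout, independent code
newpfdOracle <- function(values, nPfd, f) {
  out <- character(0)
  idx <- 1
  while (idx <= length(values)) {
    chunk <- values[idx:min(idx + nPfd - 1, length(values))]
    m <- length(chunk)
    k <- min(chunk)
    off <- chunk - k
    r <- ceiling(f * m)
    b <- min(bitWidthOracle(sort(off)[max(r, 1)]), 32)
    pos <- which(off %/% 2^b >= 1) - 1 # 0-based exception positions
    out <- c(out, fibOracle(b + 1), fibOracle(k + 1), fibOracle(length(pos) + 1))
    prev <- -1
    for (p in pos) {
      out <- c(out, fibOracle(p - prev - 1 + 1), fibOracle(off[p + 1] %/% 2^b))
      prev <- p
    }
    for (o in off) {
      slot <- o %% 2^b
      if (b > 0) {
        out <- c(out, paste(rev((slot %/% 2^(0:(b - 1))) %% 2), collapse = ""))
      }
    }
    idx <- idx + nPfd
  }
  paste(out, collapse = "")
}

# round-trip a BusData through a BUS file, BUSZ compression and back;
# returns TRUE when the decompressed file is byte-identical
roundTripsExactly <- function(x, blockSize = 10000, nPfd = 512, f = 0.9) {
  bus <- tempfile(fileext = ".bus")
  busz <- tempfile(fileext = ".busz")
  back <- tempfile(fileext = ".bus")
  on.exit(unlink(c(bus, busz, back)))
  writeBus(x, bus)
  buszCompress(bus, busz, blockSize = blockSize, nPfd = nPfd, f = f)
  buszDecompress(busz, back)
  identical(
    readBin(bus, "raw", file.size(bus)),
    readBin(back, "raw", file.size(back))
  )
}

# parse the block headers of a BUSZ file: data.frame(nRecords, nBytes)
readBlockHeaders <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  stopifnot(identical(readBin(con, "raw", 8), charToRaw("BUSZ0001")))
  invisible(readBin(con, "integer", 3, size = 4)) # version, bcLen, umiLen
  tlen <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "raw", tlen))
  invisible(readBin(con, "integer", 3, size = 4)) # blockSize, nPfd, fPpt
  out <- data.frame(nRecords = numeric(), nBytes = numeric())
  repeat {
    h <- readBin(con, "integer", 2, size = 4)
    if (h[1] == 0 && h[2] == 0) break
    out <- rbind(out, data.frame(nRecords = h[1], nBytes = h[2]))
    invisible(readBin(con, "raw", h[2]))
  }
  out
}
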