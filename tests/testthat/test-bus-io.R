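randomBus <- function(n, bcLen = 6, umiLen = 4, seed = 1) {
  set.seed(seed)
  BusData(
    barcode = replicate(n, paste(
      sample(c("A", "C", "G", "T"), bcLen, replace = TRUE),
      collapse = ""
    )),
    umi = replicate(n, paste(
      sample(c("A", "C", "G", "T"), umiLen, replace = TRUE),
      collapse = ""
    )),
    ec = sample.int(1000, n, replace = TRUE) - 1,
    count = sample.int(5, n, replace = TRUE),
    flags = sample(c(0, 0, 0, 1, 255), n, replace = TRUE),
    bcLen = bcLen, umiLen = umiLen
  )
}

test_that("write . read is the identity and sizes are header + 32n", {
  for (n in c(0, 1, 3, 200)) {
    x <- randomBus(n, seed = n + 10)
    f <- tempfile(fileext = ".bus")
    nb <- writeBus(x, f)
    expect_equal(nb, file.size(f))
    expect_equal(nb, 20 + 32 * n) # empty header text
    y <- readBus(f)
    expect_identical(busRecords(y), busRecords(x))
    expect_equal(bcLength(y), bcLength(x))
    expect_equal(umiLength(y), umiLength(x))
    unlink(f)
  }
})

test_that("header free text and version survive a round trip", {
  x <- BusData(
    barcode = "ACGT", umi = "TT", ec = 1, count = 2, flags = 0,
    version = 1, text = "produced by a unit test"
  )
  f <- tempfile(fileext = ".bus")
  writeBus(x, f)
  y <- readBus(f)
  expect_equal(busHeader(y)@text, "produced by a unit test")
  expect_equal(file.size(f), 20 + nchar("produced by a unit test") + 32)
  unlink(f)
})

test_that("bad magic and truncated payloads are rejected", {
  f <- tempfile(fileext = ".bus")
  writeBin(charToRaw("XYZ\1not a bus file at all"), f)
  expect_error(readBus(f), "magic", class = "buszFormatError")

  x <- randomBus(2, seed = 3)
  writeBus(x, f)
  # append one byte: payload becomes 65 bytes, not a multiple of 32
  con <- file(f, "ab")
  writeBin(as.raw(7), con)
  close(con)
  expect_error(readBus(f), "multiple of 32", class = "buszCorruptionError")
  unlink(f)
})

test_that("records serialize field-by-field as little-endian 8/8/4/4/4/4", {
  x <- BusData(
    barcode = "ACGT", umi = "GG", ec = 258, count = 513, flags = 7
  )
  f <- tempfile(fileext = ".bus")
  writeBus(x, f)
  bytes <- readBin(f, "raw", file.size(f))
  rec <- bytes[21:52] # header is 20 bytes (empty text)
  le <- function(b) sum(as.numeric(b) * 256^(seq_along(b) - 1))
  expect_equal(le(rec[1:8]), 27) # barcode "ACGT"
  expect_equal(le(rec[9:16]), 10) # umi "GG"
  expect_equal(le(rec[17:20]), 258)
  expect_equal(le(rec[21:24]), 513)
  expect_equal(le(rec[25:28]), 7)
  expect_equal(le(rec[29:32]), 0) # padding written as zero
  unlink(f)
})

test_that("sortBus orders by (barcode, UMI, EC) and merges identical keys", {
  x <- BusData(
    barcode = c("CC", "AA", "AA", "AA"), umi = c("G", "T", "T", "A"),
    ec = c(0, 2, 2, 9), count = c(1, 2, 3, 1), flags = c(0, 1, 4, 0)
  )
  y <- sortBus(x)
  r <- busRecords(y)
  expect_equal(r$barcode, c("AA", "AA", "CC"))
  expect_equal(r$umi, c("A", "T", "G"))
  expect_equal(r$ec, c(9, 2, 0))
  expect_equal(r$count, c(1, 5, 1)) # 2 + 3 summed
  expect_equal(r$flags, c(0, 5, 0)) # 1 | 4
})

test_that("sortBus is idempotent and conserves the total count", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 300
    x <- BusData( # tiny key space forces collisions
      barcode = sample(c("AA", "AC", "GA", "TT"), n, replace = TRUE),
      umi = sample(c("A", "C", "T"), n, replace = TRUE),
      ec = sample(0:3, n, replace = TRUE),
      count = sample.int(4, n, replace = TRUE),
      flags = sample(c(0, 1, 8), n, replace = TRUE)
    )
    y <- sortBus(x)
    expect_lt(nRecords(y), nRecords(x)) # collisions did occur
    expect_equal(sum(busRecords(y)$count), sum(busRecords(x)$count))
    expect_identical(busRecords(sortBus(y)), busRecords(y))
    k <- busRecords(y)
    expect_false(any(duplicated(paste(k$barcode, k$umi, k$ec))))
    ord <- order(k$barcode, k$umi, k$ec, method = "radix")
    expect_equal(ord, seq_len(nrow(k))) # ASCII A<C<G<T matches 2-bit order
  }
  expect_equal(nRecords(sortBus(BusData())), 0)
})

test_that("container validity catches malformed records and headers", {
  expect_error(BusHeader(0, 12), "1..32")
  expect_error(BusHeader(16, 40), "1..32")
  expect_error(
    BusData(barcode = "ACGT", umi = "TT", ec = 0.5, count = 1, flags = 0),
    "whole numbers"
  )
  expect_error(
    BusData(barcode = "ACGN", umi = "TT", ec = 0, count = 1, flags = 0),
    "only A, C, G, T"
  )
  expect_error(
    BusData(barcode = c("ACGT", "AC"), umi = c("T", "T"), ec = c(0, 0),
      count = c(1, 1), flags = c(0, 0)),
    "4-nt"
  )
  expect_error(
    BusData(barcode = "ACGT", umi = "TT", ec = 0, count = 2^32, flags = 0),
    "32-bit"
  )
})
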