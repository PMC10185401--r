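test_that("a single block compresses and decompresses record-exactly", {
  x <- BusData(
    barcode = "AAAA", umi = "AA", ec = 0, count = 1, flags = 0
  )
  p <- compressBlock(x)
  y <- decompressBlock(p, 1, 4, 2)
  expect_identical(busRecords(y), busRecords(x))

  z <- sortBus(simulateBus(nCells = 15, meanUmisPerCell = 30, seed = 5))
  p2 <- compressBlock(z, nPfd = 8, f = 0.5)
  y2 <- decompressBlock(p2, nRecords(z), bcLength(z), umiLength(z),
    nPfd = 8, f = 0.5
  )
  expect_identical(busRecords(y2), busRecords(z))
})

test_that("blocks of repeated barcodes beat the raw 32 bytes per record", {
  n <- 64
  x <- BusData(
    barcode = rep(strrep("ACGT", 4), n),
    umi = decodeSequence(seq(0, by = 2, length.out = n), 12),
    ec = rep(3, n), count = rep(1, n), flags = rep(0, n)
  )
  expect_lt(length(compressBlock(x)), 32 * n)
})

test_that("empty blocks and unsorted blocks are rejected", {
  expect_error(compressBlock(BusData()), class = "buszDomainError")
  x <- BusData(
    barcode = c("CC", "AA"), umi = c("A", "A"), ec = c(0, 0),
    count = c(1, 1), flags = c(0, 0)
  )
  expect_error(compressBlock(x), class = "buszSortError")
  neg <- BusData(
    barcode = "AA", umi = "A", ec = -1, count = 1, flags = 0
  )
  expect_error(compressBlock(neg), "negative EC", class = "buszDomainError")
})

test_that("an empty BUS file compresses to header + terminator and back", {
  bus <- tempfile()
  busz <- tempfile()
  back <- tempfile()
  writeBus(BusData(bcLen = 16, umiLen = 12), bus)
  s <- buszCompress(bus, busz)
  expect_equal(s$records, 0)
  expect_equal(s$blocks, 0)
  expect_equal(file.size(busz), 36 + 8) # BUSZ header + zero terminator
  buszDecompress(busz, back)
  expect_identical(
    readBin(bus, "raw", file.size(bus)),
    readBin(back, "raw", file.size(back))
  )
  unlink(c(bus, busz, back))
})

test_that("blocking follows ceiling division and block headers add up", {
  x <- simulateBus(nCells = 150, meanUmisPerCell = 200, seed = 9)
  expect_gt(nRecords(x), 25000)
  x <- x[seq_len(25000)]
  bus <- tempfile()
  busz <- tempfile()
  writeBus(x, bus)
  s <- buszCompress(bus, busz, blockSize = 10000)
  expect_equal(s$blocks, 3)
  hdr <- readBlockHeaders(busz)
  expect_equal(hdr$nRecords, c(10000, 10000, 5000))
  expect_equal(sum(hdr$nRecords), 25000)
  # sum of payload sizes accounts for the whole file minus headers/terminator
  expect_equal(36 + sum(8 + hdr$nBytes) + 8, file.size(busz))
  unlink(c(bus, busz))
})

test_that("compression refuses unsorted input, naming the offending record", {
  x <- BusData(
    barcode = c("AAAA", "CCCC", "AAGG"), umi = rep("TT", 3),
    ec = c(0, 0, 0), count = c(1, 1, 1), flags = c(0, 0, 0)
  )
  bus <- tempfile()
  writeBus(x, bus)
  expect_error(
    buszCompress(bus, tempfile()), "record 3",
    class = "buszSortError"
  )
  unlink(bus)
})

test_that("decompression rejects non-BUSZ input and truncated blocks", {
  bus <- tempfile()
  busz <- tempfile()
  writeBus(simulateBus(nCells = 3, meanUmisPerCell = 5, seed = 2), bus)
  expect_error(
    buszDecompress(bus, tempfile()), "not a BUSZ",
    class = "buszFormatError"
  )
  buszCompress(bus, busz)
  whole <- readBin(busz, "raw", file.size(busz))
  clipped <- tempfile()
  writeBin(whole[seq_len(length(whole) - 15)], clipped)
  expect_error(
    buszDecompress(clipped, tempfile()), "block",
    class = "buszCorruptionError"
  )
  unlink(c(bus, busz, clipped))
})

test_that("lossless round trip holds across block sizes and parameters", {
  set.seed(81)
  cases <- expand.grid(
    blockSize = c(1, 2, 7, 10000), nPfd = c(1, 8, 512),
    f = c(0.5, 0.9, 1.0)
  )
  x <- simulateBus(nCells = 8, meanUmisPerCell = 12, seed = 13)
  for (i in seq_len(nrow(cases))) {
    expect_true(roundTripsExactly(
      x, cases$blockSize[i], cases$nPfd[i], cases$f[i]
    ))
  }
})

test_that("nonzero padding warns and decompresses as zero", {
  x <- BusData(barcode = "AACC", umi = "GG", ec = 1, count = 1, flags = 0)
  bus <- tempfile()
  writeBus(x, bus)
  bytes <- readBin(bus, "raw", file.size(bus))
  bytes[length(bytes)] <- as.raw(9) # poke the padding field
  writeBin(bytes, bus)
  busz <- tempfile()
  back <- tempfile()
  expect_warning(buszCompress(bus, busz), "padding")
  buszDecompress(busz, back)
  restored <- readBin(back, "raw", file.size(back))
  expect_equal(as.integer(restored[length(restored)]), 0)
  unlink(c(bus, busz, back))
})

test_that("indexed lookup agrees with decompress-then-filter everywhere", {
  x <- adversarialBus("single_block_boundary_straddle")
  bus <- tempfile()
  busz <- tempfile()
  writeBus(x, bus)
  buszCompress(bus, busz, blockSize = 10, index = TRUE)
  ref <- busRecords(x)
  for (bc in unique(ref$barcode)) {
    hits <- buszLookup(busz, bc)
    want <- ref[ref$barcode == bc, ]
    expect_identical(as.data.frame(hits), as.data.frame(want),
      info = paste("barcode", bc)
    )
  }
  absent <- buszLookup(busz, "TTTTTTTA")
  expect_equal(nrow(absent), 0)
  unlink(c(bus, busz, paste0(busz, ".idx")))
})

test_that("lookup detects a stale or mismatched index", {
  x <- simulateBus(nCells = 6, meanUmisPerCell = 10, seed = 19)
  bus <- tempfile()
  busz <- tempfile()
  writeBus(x, bus)
  buszCompress(bus, busz, blockSize = 5, index = TRUE)
  idx <- paste0(busz, ".idx")
  bytes <- readBin(idx, "raw", file.size(idx))
  bytes[17] <- as.raw(255) # corrupt the first entry's block-size field
  writeBin(bytes, idx)
  expect_error(
    buszLookup(busz, busRecords(x)$barcode[1]),
    class = "buszIntegrityError"
  )
  expect_error(
    buszLookup(busz, busRecords(x)$barcode[1],
      indexPath = tempfile()
    ),
    "re-compress", class = "buszFormatError"
  )
  unlink(c(bus, busz, idx))
})

test_that("inspect reports structure for both formats", {
  x <- simulateBus(nCells = 10, meanUmisPerCell = 20, seed = 23)
  bus <- tempfile()
  busz <- tempfile()
  writeBus(x, bus)
  info <- buszInspect(bus)
  expect_equal(info$type, "bus")
  expect_equal(info$records, nRecords(x))
  expect_equal(info$records, (file.size(bus) - 20) / 32)

  buszCompress(bus, busz, blockSize = 50)
  zi <- buszInspect(busz)
  expect_equal(zi$type, "busz")
  expect_equal(zi$records, nRecords(x))
  expect_equal(zi$blocks, ceiling(nRecords(x) / 50))
  expect_equal(zi$blockSize, 50)
  expect_equal(zi$f, 0.9)
  expect_equal(sum(zi$columnBytes) + 5 * 4 * zi$blocks,
    sum(readBlockHeaders(busz)$nBytes)
  )
  unlink(c(bus, busz))
})
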