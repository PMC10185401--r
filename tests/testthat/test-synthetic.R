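test_that("the generator is deterministic and leaves the caller's RNG alone", {
  a <- simulateBus(nCells = 10, meanUmisPerCell = 15, seed = 99)
  set.seed(1)
  before <- .Random.seed
  b <- simulateBus(nCells = 10, meanUmisPerCell = 15, seed = 99)
  expect_identical(before, .Random.seed)
  expect_identical(busRecords(a), busRecords(b))

  f1 <- tempfile()
  f2 <- tempfile()
  writeBus(a, f1)
  writeBus(b, f2)
  expect_identical(
    readBin(f1, "raw", file.size(f1)),
    readBin(f2, "raw", file.size(f2))
  )
  unlink(c(f1, f2))
})

test_that("generated data are already sorted and merged", {
  for (seed in c(3, 17)) {
    x <- simulateBus(nCells = 25, meanUmisPerCell = 40, seed = seed)
    expect_identical(busRecords(sortBus(x)), busRecords(x))
    r <- busRecords(x)
    expect_true(all(r$count >= 1))
    expect_true(all(r$ec >= 0))
  }
  # degenerate configuration still yields at least one valid record
  tiny <- simulateBus(nCells = 1, meanUmisPerCell = 0, seed = 4)
  expect_gte(nRecords(tiny), 1)
  f <- tempfile()
  writeBus(tiny, f)
  expect_equal(nRecords(readBus(f)), nRecords(tiny))
  unlink(f)
})

test_that("count and flag frequencies track their configured probabilities", {
  x <- simulateBus(
    nCells = 100, meanUmisPerCell = 150, pCountGt1 = 0.1, pFlagSet = 0.02,
    seed = 7
  )
  r <- busRecords(x)
  n <- nrow(r)
  expect_gte(n, 1e4)
  # merging can only push counts up, so allow the 3-SE band around 0.9 to
  # widen slightly downwards
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(mean(r$count == 1) - 0.9), 3 * se + 0.01)
  expect_lt(mean(r$flags != 0), 0.05)
})

test_that("adversarial fixtures have their advertised shapes", {
  same <- adversarialBus("all_same_key")
  merged <- sortBus(same)
  expect_equal(nRecords(merged), 1)
  expect_equal(busRecords(merged)$count, sum(busRecords(same)$count))

  inc <- adversarialBus("strictly_increasing_everything")
  r <- busRecords(inc)
  expect_false(any(duplicated(r$barcode)))
  expect_true(all(diff(encodeSequence(r$barcode)) > 0))
  expect_true(all(diff(r$ec) > 0))

  mx <- adversarialBus("max_values")
  rm <- busRecords(mx)
  expect_true(any(rm$barcode == strrep("T", 32)))
  expect_true(any(rm$ec == 2^31 - 1))
  expect_true(any(rm$count == 2^32 - 1))

  straddle <- adversarialBus("single_block_boundary_straddle")
  runs <- rle(busRecords(straddle)$barcode)
  expect_equal(max(runs$lengths), 15) # spans blocks 1 and 2 at blockSize 10

  expect_error(adversarialBus("nonsense"))
})

test_that("extreme field values survive the full 64-bit compression path", {
  expect_true(roundTripsExactly(adversarialBus("max_values")))
  expect_true(roundTripsExactly(adversarialBus("max_values"), blockSize = 1))
  expect_true(roundTripsExactly(sortBus(adversarialBus("all_same_key"))))
  expect_true(roundTripsExactly(
    adversarialBus("strictly_increasing_everything"),
    blockSize = 7, nPfd = 8
  ))
})
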