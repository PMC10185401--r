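# RNG discipline: simulateBus()/adversarialBus() seed a local RNG stream and
# restore the caller's .Random.seed on exit, so the same seed always yields
# byte-identical files regardless of surrounding code.
withLocalSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

randomSeqs <- function(n, len) {
  if (n == 0) {
    return(character())
  }
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

uniqueRandomSeqs <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, randomSeqs(2L * (n - length(out)) + 4L, len)))
  }
  sort(out[seq_len(n)], method = "radix")
}

#' Simulate a sorted BUS dataset
#'
#' Deterministic generator of sorted, merged BUS data with the statistical
#' structure of real sorted single-cell output that the BUSZ codecs are
#' built around: long runs of repeated barcodes (many records per cell),
#' UMIs sorted within each cell, a higher-entropy equivalence-class column
#' drawn from a Zipf-like categorical distribution, counts that are mostly
#' 1, and flags that are mostly 0.  The defaults model a modest 10x-style
#' experiment (16 nt barcodes, 12 nt UMIs, ~600 cells x ~200 molecules,
#' about 1.2e5 records).
#'
#' @param nCells number of distinct cell barcodes.
#' @param meanUmisPerCell Poisson mean of molecules per cell; at least one
#'   record is always generated.
#' @param nEcs size of the equivalence-class universe.
#' @param ecConcentration Zipf exponent of the EC frequencies (0 = uniform;
#'   larger = more skewed, lower entropy).
#' @param pCountGt1 probability that a count exceeds 1 (excess is
#'   geometric).
#' @param pFlagSet probability that flags are nonzero.
#' @param bcLen,umiLen barcode/UMI lengths in nucleotides.
#' @param seed RNG seed; the same seed always yields the same records.
#' @return a sorted, merged \code{\linkS4class{BusData}} (so
#'   \code{sortBus(x)} is identical to \code{x}).
#' @examples
#' x <- simulateBus(nCells = 10, meanUmisPerCell = 20, seed = 42)
#' mean(busRecords(x)$count == 1) # counts are mostly 1
#' @export
simulateBus <- function(nCells = 600, meanUmisPerCell = 200, nEcs = 5000,
                        ecConcentration = 1, pCountGt1 = 0.05,
                        pFlagSet = 0.01, bcLen = 16, umiLen = 12,
                        seed = 20230502) {
  stopifnot(
    nCells >= 1, meanUmisPerCell >= 0, nEcs >= 1,
    pCountGt1 >= 0, pCountGt1 <= 1, pFlagSet >= 0, pFlagSet <= 1,
    bcLen >= 1, bcLen <= 32, umiLen >= 1, umiLen <= 32
  )
  withLocalSeed(seed, {
    bcs <- uniqueRandomSeqs(nCells, bcLen)
    nU <- rpois(nCells, meanUmisPerCell)
    if (sum(nU) == 0) nU[1] <- 1 # never an empty dataset
    n <- sum(nU)
    barcode <- rep(bcs, nU)
    umi <- randomSeqs(n, umiLen)
    w <- seq_len(nEcs)^(-ecConcentration)
    ec <- sample.int(nEcs, n, replace = TRUE, prob = w) - 1
    count <- 1 + ifelse(runif(n) < pCountGt1, rgeom(n, 0.5) + 1, 0)
    flags <- ifelse(runif(n) < pFlagSet, 1, 0)
    sortBus(BusData(
      barcode = barcode, umi = umi, ec = ec, count = count, flags = flags,
      bcLen = bcLen, umiLen = umiLen
    ))
  })
}

#' Adversarial BUS fixtures
#'
#' Degenerate datasets that stress the codecs at their edges:
#' \describe{
#'   \item{\code{all_same_key}}{many records sharing one (barcode, UMI, EC)
#'     key; \code{\link{sortBus}} collapses them to a single record.}
#'   \item{\code{strictly_increasing_everything}}{every column strictly
#'     increasing -- no runs for the RLE stages to exploit.}
#'   \item{\code{max_values}}{32 nt barcodes/UMIs at and around the maximum
#'     representable values (all-T sequences, EC \code{2^31 - 1}, count and
#'     flags \code{2^32 - 1}); exercises the full 64-bit path.}
#'   \item{\code{single_block_boundary_straddle}}{one barcode owning 15
#'     consecutive records so that, at \code{blockSize = 10}, its records
#'     straddle two blocks -- the \code{\link{buszLookup}} edge case.}
#' }
#'
#' @param kind one of the four fixture names above.
#' @param seed RNG seed for the randomized parts.
#' @return a \code{\linkS4class{BusData}}; all fixtures except
#'   \code{all_same_key} are already sorted.
#' @export
adversarialBus <- function(kind = c(
                             "all_same_key",
                             "strictly_increasing_everything",
                             "max_values",
                             "single_block_boundary_straddle"
                           ),
                           seed = 20230502) {
  kind <- match.arg(kind)
  withLocalSeed(seed, {
    switch(kind,
      all_same_key = BusData(
        barcode = rep("ACGTACGT", 20), umi = rep("TTAA", 20),
        ec = rep(7, 20), count = seq_len(20), flags = rep(0, 20)
      ),
      strictly_increasing_everything = {
        n <- 100
        BusData(
          barcode = decodeSequence(seq(0, by = 3, length.out = n), 8),
          umi = decodeSequence(seq(1, by = 2, length.out = n), 8),
          ec = seq_len(n) * 5, count = seq_len(n) + 1,
          flags = seq_len(n)
        )
      },
      max_values = {
        tmax <- strrep("T", 32)
        amin <- strrep("A", 32)
        BusData(
          barcode = c(amin, amin, tmax, tmax, tmax),
          umi = c(amin, tmax, amin, tmax, tmax),
          ec = c(0, 2^31 - 1, 0, 2^31 - 1, 2^31 - 1),
          count = c(1, 2^32 - 1, 1, 2^32 - 1, 2^32 - 1),
          flags = c(0, 2^32 - 1, 0, 2^32 - 1, 2^32 - 1)
        )
      },
      single_block_boundary_straddle = {
        bcs <- c(rep("AAAACCCC", 3), rep("CCCCGGGG", 15), rep("GGGGTTTT", 4))
        n <- length(bcs)
        umis <- unlist(lapply(rle(bcs)$lengths, function(k) {
          decodeSequence(sort(sample.int(2^8, k) - 1), 4)
        }))
        BusData(
          barcode = bcs, umi = umis,
          ec = sample.int(50, n, replace = TRUE) - 1,
          count = rep(1, n), flags = rep(0, n)
        )
      }
    )
  })
}
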