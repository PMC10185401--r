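---
title: "Columnar compression of sorted BUS files"
author: "buszr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Columnar compression of sorted BUS files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The data and the problem

A BUS file stores the intermediate result of single-cell RNA-seq
quantification as a flat sequence of fixed 32-byte binary records after a
small header. Each record carries a cell barcode and a UMI (both short
oligonucleotides, 2-bit encoded into unsigned 64-bit integers), an
equivalence-class (EC) id naming the set of transcripts the read is
compatible with, a read count, flags, and 4 bytes of padding. The fixed
layout makes the files fast to load, but large: an experiment of a few
million cells produces tens of gigabytes of BUS intermediates that are
worth archiving (they decouple alignment from downstream analysis).

Sorted BUS files are extremely redundant, and the redundancy is
*columnar*:

* the barcode column is long runs of the same value (all records of one
  cell are adjacent), so adjacent differences are mostly zero;
* the UMI column is non-decreasing within a cell, so within-cell
  differences are small and non-negative;
* the count column is almost always 1;
* the flags column is almost always 0;
* the EC column has much higher entropy than the other four, but values
  cluster around the common equivalence classes.

General-purpose compressors see this structure only through a 32-byte
stride. `buszr` instead transposes each block of records into columns and
gives every column its own codec.

## The compression scheme

The input must be sorted lexicographically by (barcode, UMI, EC); sorting
also merges records with identical keys (counts summed, flags OR-ed),
which is itself the first level of compression. `sortBus()` performs both.
The compressor verifies order while streaming and refuses unsorted input
rather than silently sorting; an explicit `sortBus()` step keeps file
semantics under the user's control.

Records are processed in blocks of `blockSize` records (default 10 000).
Within a block the five stored columns are compressed independently
(padding is dropped and restored as zero):

| column  | transform                           | entropy coder |
|---------|-------------------------------------|---------------|
| barcode | delta (first value raw)             | FRLE0         |
| UMI     | delta within a cell, raw at changes | FRLE0         |
| EC      | none                                | NewPFD        |
| count   | none                                | FRLE1         |
| flags   | none                                | FRLE0         |

**Fibonacci coding.** All variable-length integers use the Fibonacci
universal code over F1 = 1, F2 = 2, F3 = 3, F4 = 5, ...: the Zeckendorf
bits are written lowest index first and an extra 1 is appended, so every
codeword ends "11" and the code is prefix-free and self-synchronizing.
Small values get short codewords, which suits delta/run-length output
whose distribution is concentrated near zero. Fibonacci codes cannot
express 0, so FRLE0 adds one to literal values before coding (run lengths
are already positive).

**RLE0 / RLE1 and FRLE0 / FRLE1.** RLE0 collapses each maximal run of
zeros into a (marker, length) pair and passes other values through; RLE1
does the same for ones. FRLE0/FRLE1 are the Fibonacci encodings of those
token streams. A run of length 1 is still written as marker + length:
one uniform rule, no decoder lookahead.

**NewPFD for the EC column.** The EC list of a block is split into
sub-blocks of `nPfd` consecutive values (default 512). For each sub-block
of m values, the base k is the sub-block minimum and the slot width b is
the smallest width such that at least `ceiling(f * m)` offsets x − k fit
in b bits (default f = 0.9; the rank is taken on the actual sub-block
length, so a short final sub-block is handled identically). Offsets
needing more than b bits are exceptions: their low b bits stay in the
fixed-width slot array, and their positions (as gap-coded deltas) and
remaining high bits are Fibonacci coded in the sub-block header. Because
k is explicit per sub-block, ECs are encoded as-is with no intra-column
delta.

Each block is preceded by its record count and compressed byte size; the
stream ends with an all-zero block header, so a reader never depends on
the container's file size. An optional sibling index file stores (first
barcode, compressed size) per block, from which `buszLookup()`
reconstructs block offsets and decompresses only the one or two blocks
that can contain a query barcode (a barcode's run may straddle a block
boundary, so the preceding candidate block is always checked too).

## Tunable parameters

* `blockSize` (default 10 000 records): smaller blocks mean finer random
  access and less memory, at the cost of one raw barcode anchor and five
  column length prefixes per block. At `blockSize = 1` the format still
  round-trips, it just stops compressing.
* `nPfd` (default 512 values): the NewPFD sub-block. Smaller sub-blocks
  adapt k and b faster to local EC structure but pay a three-codeword
  header per sub-block.
* `f` (default 0.9): the fraction of values that must fit the slot width.
  Lower f narrows slots and produces more exceptions; f = 1 forbids
  exceptions entirely. f is recorded in the file header (as parts per
  thousand, avoiding floats in a binary header) purely as provenance —
  decoding reads b, k and the exception lists explicitly.

## Numerical and format choices

* One global bit order (MSB-first within each byte) for both Fibonacci
  codewords and fixed-width slots; one global byte order (little-endian)
  for all fixed-width integers.
* Codeword values up to 2^64 are supported internally (a delta of
  2^64 − 1 must encode as fib(value + 1)), so the encoder works in
  128-bit arithmetic; the R-facing numeric codec APIs reject values above
  2^53, the exact-integer limit of an R double. Barcodes and UMIs cross
  the R boundary as nucleotide strings, which are bijective with the
  64-bit codes and therefore lossless at any length up to 32 nt.
* The NewPFD slot width is capped at 32 bits. If an offset still exceeds
  the capped width it is simply treated as an exception, so losslessness
  never depends on the cap. For EC data (non-negative signed 32-bit ids)
  the cap is unreachable anyway.
* Exception metadata is interleaved per exception as (position gap, high
  bits), with gaps d_i = p_i − p_{i−1} − 1 from p_0 = −1 and every
  Fibonacci-coded quantity shifted by +1 exactly where 0 is possible
  (b, k, exception count, gaps) and nowhere else (high bits and run
  lengths are ≥ 1 by construction).
* Merging ties: counts are summed (conserving total reads) and flags are
  OR-ed (a set bit is never lost). Sorting is a single in-memory sort;
  external sorting of files larger than memory is out of scope.
* Degenerate inputs: empty files compress to header + terminator; an
  all-zero column of any length L costs two codewords (Θ(log L) bits);
  blocks are never empty; records with negative EC or zero count are
  rejected at compression time with the record index named.

## The synthetic generator

`simulateBus()` emulates exactly the features the codecs exploit: distinct
sorted barcodes, Poisson molecules per cell, per-cell sorted UMIs, ECs
from a Zipf-like categorical over `nEcs` classes (exponent
`ecConcentration` spans low- to high-entropy regimes), counts of 1 with
probability `1 − pCountGt1` (geometric excess otherwise) and flags zero
with probability `1 − pFlagSet`. The defaults — 600 cells × ~200
molecules, 16 nt barcodes, 12 nt UMIs, 5000 ECs, about 1.2 × 10^5
records — model a modest droplet experiment and are the conditions under
which the package's compression claims are evaluated.

What the generator does *not* emulate: real barcode whitelists,
sequencing-error structure, technology-specific barcode geometries, or
the empirical EC frequency distribution of a particular reference
transcriptome. Passing tests therefore demonstrate correctness
(losslessness, format compliance, index agreement) on data with realistic
*statistical shape*; absolute compression ratios on real files will vary
with their actual redundancy. `adversarialBus()` covers the opposite
regime: degenerate keys, strictly increasing columns with nothing to
run-length encode, all fields at their 64-/32-bit maxima, and a barcode
run placed to straddle a block boundary.

## Verification strategy and problem sizes

The test suite checks every codec against an independent oracle written
naively in R (greedy Zeckendorf for Fibonacci; a direct run scanner for
RLE; a separate bit-level NewPFD encoder), exhaustively for Fibonacci
codewords 1..10^4 and on ≥ 10^3 randomized NewPFD sub-blocks, and checks
the lossless contract end-to-end on 250+ generated files spanning 0 to
~1.2 × 10^5 records, block sizes {1, 2, 7, 10 000}, NewPFD sub-blocks
{1, 8, 512} and fractions {0.5, 0.9, 1.0}. These sizes keep the default
suite fast on a laptop while covering every block/sub-block boundary
case; nothing in the format depends on file size beyond u32 block
payloads.

## Known limitations

* Byte-level compatibility with other BUSZ writers is not guaranteed;
  this package's layout is fully specified in `docs/FORMAT.md` and
  round-trips through itself exactly.
* The compressor holds one block (not the whole file) in memory, but
  `sortBus()` sorts in memory; very large unsorted files should be sorted
  by an external tool first.
* Counts merged above 2^32 − 1 cannot be represented in the record and
  raise an error rather than wrapping.
* Nonzero padding bytes are not preserved (a warning reports how many
  records were affected); padding decompresses as zero by design.
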